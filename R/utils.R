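#' Evaluate code under a fixed RNG seed, restoring global RNG state afterwards
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that callers' RNG streams are never disturbed and identical
#' seeds give identical results.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-unit substream seed derived from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(i) * 7919
  as.integer(s %% 2147483629) + 1L
}

# Merge possibly-overlapping half-open intervals [start, end); kinds of merged
# intervals are concatenated with "+".
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  df <- df[order(df$start_s), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      j <- nrow(out)
      if (df$start_s[i] < out$end_s[j]) {
        out$end_s[j] <- max(out$end_s[j], df$end_s[i])
        kinds <- unique(c(strsplit(out$kind[j], "+", fixed = TRUE)[[1]], df$kind[i]))
        out$kind[j] <- paste(kinds, collapse = "+")
      } else {
        out <- rbind(out, df[i, , drop = FALSE])
      }
    }
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
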