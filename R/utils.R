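## internal helpers shared across modules

# round-half-up; base round() uses banker's rounding which would make the
# 80 um diameter map to an even neighbour depending on FP representation
round_half_up <- function(x) floor(x + 0.5)

# log-sum-exp along rows of a matrix
row_logsumexp <- function(lw) {
  m <- apply(lw, 1L, max)
  m + log(rowSums(exp(lw - m)))
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Deterministic 31-bit hash of the master seed plus an arbitrary character
#' label (condition fields, repeat index, ...).  Used so that every cell and
#' repeat of a simulation grid gets an independent, order-invariant seed.
#'
#' @param master_seed integer master seed.
#' @param ... further components (coerced to character) mixed into the hash.
#' @return a single integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, ...) {
  tokens <- unlist(lapply(list(master_seed, ...), as.character))
  bytes <- utf8ToInt(paste(tokens, collapse = "\r"))
  h <- 104729
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483645L + 1)
}

geometric_mean <- function(x) exp(mean(log(x)))

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 1 && x == floor(x)

check_integer_counts <- function(m, what = "counts") {
  bad <- which(!is.finite(m) | m < 0 | m != floor(m))
  if (length(bad)) {
    i <- bad[1L]
    stop_fmt("%s must be non-negative integers; entry [%d, %d] is %s",
             what, (i - 1L) %% nrow(m) + 1L, (i - 1L) %/% nrow(m) + 1L,
             format(m[i]))
  }
  invisible(TRUE)
}
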