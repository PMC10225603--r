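# Internal helpers: argument checking, seed derivation, checksums.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_arg <- function(msg, arg = NULL) {
  rlang::abort(msg, class = "ssstn_argument_error", arg = arg)
}

check_number <- function(x, arg, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_arg(sprintf("`%s` must be a single finite number.", arg), arg)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_arg(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.", arg, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), arg)
  }
  invisible(x)
}

check_count <- function(x, arg, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort_arg(sprintf("`%s` must be an integer >= %d.", arg, min), arg)
  }
  invisible(as.integer(x))
}

check_label <- function(label, K) {
  if (!is.numeric(label) || length(label) != 1L || !is.finite(label) ||
      label != round(label) || label < 1L || label > K) {
    abort_arg(sprintf("`label` = %s is not a valid class index in 1..%d.",
                      format(label), K), "label")
  }
  invisible(as.integer(label))
}

# Deterministic 32-bit seed derived from a base seed and stream labels.
# Keeps every derived seed in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 69069 + v * 2654435761) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# MD5 of any R object via native serialization; used for the
# frozen-classifier invariant and for config hashes in run manifests.
object_checksum <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L)
  close(con)
  unname(tools::md5sum(f))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

# Column-wise softmax of a matrix.
softmax_cols <- function(x) {
  z <- exp(sweep(x, 2L, apply(x, 2L, max), "-"))
  sweep(z, 2L, colSums(z), "/")
}
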