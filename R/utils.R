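# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive <- function(x, name) {
  if (!is_scalar_num(x) || x <= 0) stopf("`%s` must be a single positive number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stopf("`%s` must be finite and >= 0", name)
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed plus a stage index to a new 32-bit
#' seed so every random stage of a pipeline draws from an independent,
#' reproducible stream.
#'
#' @param master_seed Integer master seed.
#' @param index Nonnegative integer stage/replicate index.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master_seed, index) {
  # splitmix-style integer hash, kept in signed 32-bit range
  x <- (as.numeric(master_seed) %% 2147483647) + 1
  y <- (as.numeric(index) %% 2147483647) + 1
  h <- (x * 2654435761 + y * 40503 + 12345) %% 2147483629
  as.integer(h)
}
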