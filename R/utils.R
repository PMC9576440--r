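# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, open_lower = FALSE,
                         open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(field, "must be a single finite number")
  if (integer && x != round(x))
    stop_param(field, "must be an integer")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_param(field, sprintf("must lie in %s%s, %s%s",
                              if (open_lower) "(" else "[", format(lower),
                              format(upper), if (open_upper) ")" else "]"))
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Map Hounsfield intensities to the unit interval
#'
#' Linear rescaling of a clipped HU window to \[0, 1\]; this is the intensity
#' normalization applied to every image entering the network.
#'
#' @param x numeric array of HU intensities.
#' @param window length-2 numeric, HU clip bounds (low, high).
#' @return array of the same shape with values in \[0, 1\].
#' @export
normalize_hu <- function(x, window = c(-1000, 400)) {
  if (window[1] >= window[2]) stop_param("window", "low must be < high")
  (clip(x, window[1], window[2]) - window[1]) / (window[2] - window[1])
}

check_binary <- function(x, name = "mask") {
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1)))
    stop(sprintf("%s must be binary (values in {0, 1})", name), call. = FALSE)
  invisible(TRUE)
}

check_same_shape <- function(a, b, what = "arrays") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (length(da) != length(db) || any(da != db))
    stop(sprintf("shape mismatch: %s have dims [%s] vs [%s]", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# derive a child seed (< 2^31) from a base seed and a stream label
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + sum(utf8ToInt(stream)) %% 1000L
}
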