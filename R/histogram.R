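#' Gray-level histogram of an image
#'
#' Tallies, for each gray level `i` in `0..L-1`, the pixel count `n_i` and the
#' probability `p_i = n_i / n` where `n` is the total pixel count.  The
#' probabilities always sum to 1 and are the sole input of the threshold
#' selectors, which therefore do not depend on image size, only on the
#' intensity distribution.
#'
#' @param image a [gray_image()].
#' @return An object of class `gray_histogram`: list with `counts` (integer
#'   vector of length `L`, index `i + 1` holds `n_i`), `prob` (`p_i`),
#'   `total` (`n`) and `levels` (`L`).
#' @examples
#' img <- gray_image(matrix(c(10L, 10L, 200L, 200L), 2, 2))
#' h <- compute_histogram(img)
#' h$prob[c(11, 201)]  # p_10 and p_200
#' @export
compute_histogram <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  counts <- tabulate(image$pixels + 1L, nbins = image$levels)
  total <- image$width * image$height
  structure(
    list(counts = counts, prob = counts / total, total = total,
         levels = image$levels),
    class = "gray_histogram"
  )
}

#' Build a histogram directly from probabilities or counts
#'
#' Convenience constructor used when the intensity distribution is known
#' analytically (e.g. a discretized Gaussian mixture) rather than tallied
#' from pixels.  Probabilities are normalized to sum to 1.
#'
#' @param x non-negative numeric vector of length `L`: counts or unnormalized
#'   probability weights for levels `0..L-1`.
#' @return A `gray_histogram`.  When `x` is not integer-valued, `counts` is
#'   `NA` and `total` is `NA`; only `prob` is meaningful.
#' @export
histogram_from_weights <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop("weights must be finite and >= 0")
  s <- sum(x)
  if (s <= 0) stop("weights must have positive total mass")
  integral <- all(x == round(x))
  structure(
    list(counts = if (integral) as.integer(round(x)) else rep(NA_integer_, length(x)),
         prob = x / s,
         total = if (integral) as.integer(round(s)) else NA_integer_,
         levels = length(x)),
    class = "gray_histogram"
  )
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(x$prob > 0) - 1L
  cat(sprintf("<gray_histogram> L = %d, n = %s, %d populated levels in [%d, %d]\n",
              x$levels, format(x$total), length(nz), min(nz), max(nz)))
  invisible(x)
}
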