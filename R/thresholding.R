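#' Per-threshold class statistics
#'
#' A candidate threshold `t` splits the gray levels into a background class
#' `C0 = {0, ..., t}` and a foreground class `C1 = {t+1, ..., L-1}`.  This
#' returns the class probabilities `w0, w1` (always `w0 + w1 = 1`), class
#' means `m0, m1`, class variances `s0sq, s1sq` and class Shannon entropies
#' `H0, H1` (natural log).  Quantities of an empty class (`w = 0`) are
#' returned as `NA` — they are undefined, not zero — and such `t` must be
#' treated as invalid candidates by callers.
#'
#' Zero-probability levels contribute nothing to the entropies
#' (the `0 * log 0 = 0` limit convention).
#'
#' @param hist a `gray_histogram` (see [compute_histogram()]).
#' @param t integer threshold, `0 <= t <= L - 2`.
#' @return A list of class `threshold_class_stats` with elements
#'   `t, w0, w1, m0, m1, s0sq, s1sq, H0, H1`.
#' @examples
#' h <- histogram_from_weights(c(rep(0, 50), 1, rep(0, 149), 1, rep(0, 55)))
#' class_stats(h, 100)  # two point masses at 50 and 200
#' @export
class_stats <- function(hist, t) {
  stopifnot(inherits(hist, "gray_histogram"))
  L <- hist$levels
  t <- as.integer(t)
  if (is.na(t) || t < 0L || t > L - 2L)
    stop("threshold t must lie in 0..L-2 (got ", t, ")")
  p <- hist$prob
  i <- seq_len(L) - 1L            # gray levels 0..L-1
  lo <- i <= t
  w0 <- sum(p[lo]); w1 <- sum(p[!lo])

  one_class <- function(sel, w) {
    if (w <= 0) return(list(m = NA_real_, ssq = NA_real_, H = NA_real_))
    ps <- p[sel]; is <- i[sel]
    m <- sum(is * ps) / w
    ssq <- sum(ps * (is - m)^2) / w
    q <- ps[ps > 0] / w
    list(m = m, ssq = ssq, H = -sum(q * log(q)))
  }
  c0 <- one_class(lo, w0)
  c1 <- one_class(!lo, w1)
  structure(
    list(t = t, w0 = w0, w1 = w1, m0 = c0$m, m1 = c1$m,
         s0sq = c0$ssq, s1sq = c1$ssq, H0 = c0$H, H1 = c1$H),
    class = "threshold_class_stats"
  )
}

#' Foreground + background entropy at a threshold
#'
#' The maximum-entropy objective `f(t) = H0 + H1`, the sum of the Shannon
#' entropies (natural log) of the two classes induced by `t`.  `NA` when a
#' class is empty at `t` (undefined candidate).
#'
#' @inheritParams class_stats
#' @return `f(t)` as a scalar, or `NA` for an undefined candidate.
#' @export
entropy_sum <- function(hist, t) {
  s <- class_stats(hist, t)
  if (is.na(s$H0) || is.na(s$H1)) return(NA_real_)
  s$H0 + s$H1
}

#' Minimum-error (two-Gaussian) objective at a threshold
#'
#' The Kittler-Illingworth criterion
#' `J(t) = 1 + w0 log(s0^2 / w0^2) + w1 log(s1^2 / w1^2)`,
#' derived by fitting a two-component Gaussian mixture to the histogram and
#' minimizing the classification error.  Candidates with an empty class or a
#' zero class variance are undefined (`NA`): the log diverges there, and
#' flooring the variance instead would plant spurious minima.
#'
#' @inheritParams class_stats
#' @return `J(t)` as a scalar, or `NA` for an undefined candidate.
#' @export
min_error_objective <- function(hist, t) {
  s <- class_stats(hist, t)
  if (is.na(s$s0sq) || is.na(s$s1sq) || s$s0sq <= 0 || s$s1sq <= 0)
    return(NA_real_)
  1 + s$w0 * log(s$s0sq / s$w0^2) + s$w1 * log(s$s1sq / s$w1^2)
}

# Candidate thresholds keeping both classes non-empty:
# {min populated level, ..., max populated level - 1}.
candidate_range <- function(hist) {
  nz <- which(hist$prob > 0) - 1L
  if (length(nz) < 2L)
    stop("no valid threshold: histogram has mass on fewer than 2 gray levels")
  seq.int(min(nz), max(nz) - 1L)
}

new_threshold_scan <- function(method, t, objective, t_star, maximize) {
  valid <- !is.na(objective)
  structure(
    list(method = method, t = t, objective = objective, valid = valid,
         t_star = t_star, objective_star = objective[match(t_star, t)],
         maximize = maximize),
    class = "threshold_scan"
  )
}

#' Maximum-entropy threshold selection
#'
#' Scans every candidate threshold and selects the `t*` maximizing the summed
#' foreground/background entropy `f(t) = H0 + H1` (Kapur's criterion).  Ties
#' are broken to the smallest `t`, so the result is deterministic.  The full
#' objective trace is retained for inspection and export.
#'
#' @param hist a `gray_histogram` with mass on at least 2 distinct levels.
#' @return A `threshold_scan`: list with `method`, candidate `t` vector,
#'   `objective` trace, `valid` flags, selected `t_star` and
#'   `objective_star`.
#' @examples
#' img <- gray_image(matrix(sample(c(40L, 210L), 64, TRUE), 8, 8))
#' max_entropy_threshold(compute_histogram(img))$t_star
#' @export
max_entropy_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  t <- candidate_range(hist)
  f <- vapply(t, function(tt) entropy_sum(hist, tt), numeric(1))
  t_star <- t[which.max(f)]   # which.max: first (= smallest t) among ties
  new_threshold_scan("max_entropy", t, f, t_star, maximize = TRUE)
}

#' Minimum-error threshold selection
#'
#' Scans every candidate threshold and selects the `t*` minimizing the
#' two-Gaussian classification-error criterion `J(t)` (see
#' [min_error_objective()]).  Candidates with an empty class or zero class
#' variance are excluded; if no candidate survives (e.g. a two-point
#' histogram, where every split yields two zero-variance point masses) an
#' error is raised.  Ties are broken to the smallest `t`.
#'
#' @inheritParams max_entropy_threshold
#' @return A `threshold_scan` (see [max_entropy_threshold()]).
#' @export
min_error_threshold <- function(hist) {
  stopifnot(inherits(hist, "gray_histogram"))
  t <- candidate_range(hist)
  J <- vapply(t, function(tt) min_error_objective(hist, tt), numeric(1))
  if (all(is.na(J)))
    stop("no valid threshold: every candidate has an empty class or zero class variance")
  t_star <- t[which.min(J)]   # NAs never win which.min
  new_threshold_scan("min_error", t, J, t_star, maximize = FALSE)
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> method = %s, %d candidates (%d valid), t* = %d, %s(t*) = %.6g\n",
              x$method, length(x$t), sum(x$valid), x$t_star,
              if (x$method == "max_entropy") "f" else "J", x$objective_star))
  invisible(x)
}

#' @export
as.data.frame.threshold_scan <- function(x, ...) {
  data.frame(t = x$t, objective = x$objective, valid = x$valid)
}

#' Export a threshold scan as CSV
#'
#' Writes the objective trace (columns `t`, `objective`, `valid`) for
#' plotting or inspection.
#'
#' @param scan a `threshold_scan`.
#' @param path output file.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "threshold_scan"))
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}
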