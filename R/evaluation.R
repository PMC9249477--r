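#' Dice similarity coefficient
#'
#' Overlap between a gold-standard foreground pixel set `M` and a test set
#' `N`: `Dice(M, N) = 2|M intersect N| / (|M| + |N|)`.  Equals 1 iff the two
#' sets are identical, 0 iff they are disjoint.  Both masks empty is an
#' error (0/0 is undefined; only the disjoint and identical limits are
#' defined).
#'
#' @param gold,test logical matrices of equal dimensions (`TRUE` =
#'   foreground).
#' @return A scalar in `[0, 1]`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
#' dice(m, m)
#' @export
dice <- function(gold, test) {
  if (inherits(gold, "segmentation_result")) gold <- gold$mask
  if (inherits(test, "segmentation_result")) test <- test$mask
  stopifnot(is.matrix(gold), is.matrix(test))
  if (!all(dim(gold) == dim(test)))
    stop("mask dimensions differ: ", paste(dim(gold), collapse = "x"),
         " vs ", paste(dim(test), collapse = "x"))
  gold <- gold > 0; test <- test > 0
  m <- sum(gold); n <- sum(test)
  if (m + n == 0L)
    stop("Dice is undefined for two empty masks (0/0)")
  2 * sum(gold & test) / (m + n)
}

#' Holes and isolated points of a binary mask
#'
#' Quantifies the two artifact types plain thresholding is prone to:
#' *holes* — background 4-connected components that do not touch the image
#' border (background is taken 4-connected where foreground is 8-connected,
#' the standard dual pairing that avoids topological paradoxes) — and
#' *isolated points* — foreground 8-connected components smaller than
#' `min_size` pixels.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param min_size foreground components with fewer pixels than this count
#'   as isolated points (default 5).
#' @return A list with integer elements `holes` and `isolated_points`.
#' @export
artifact_counts <- function(mask, min_size = 5L) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  lab_bg <- label_components(!mask, 4L)
  n_bg <- attr(lab_bg, "n")
  holes <- 0L
  if (n_bg > 0L) {
    border <- unique(c(lab_bg[1, ], lab_bg[nrow(lab_bg), ],
                       lab_bg[, 1], lab_bg[, ncol(lab_bg)]))
    holes <- n_bg - length(setdiff(border, 0L))
  }
  lab_fg <- label_components(mask, 8L)
  n_fg <- attr(lab_fg, "n")
  isolated <- 0L
  if (n_fg > 0L) {
    sizes <- tabulate(lab_fg[lab_fg > 0L], nbins = n_fg)
    isolated <- sum(sizes < min_size)
  }
  list(holes = as.integer(holes), isolated_points = as.integer(isolated))
}

#' Full evaluation report for a segmentation
#'
#' Dice overlap against a gold standard plus the artifact counts of the test
#' mask, bundled with pixel-set sizes and the wall time spent computing the
#' report.  Timing is recorded for efficiency reporting only and is never a
#' correctness criterion.
#'
#' @inheritParams dice
#' @inheritParams artifact_counts
#' @return A list of class `evaluation_report`: `dice`, `gold_pixels`,
#'   `test_pixels`, `overlap_pixels`, `holes`, `isolated_points`, `elapsed`.
#' @export
evaluate_segmentation <- function(gold, test, min_size = 5L) {
  tm <- timed({
    if (inherits(test, "segmentation_result")) test <- test$mask
    d <- dice(gold, test)
    a <- artifact_counts(test, min_size = min_size)
    list(dice = d,
         gold_pixels = sum(gold > 0), test_pixels = sum(test > 0),
         overlap_pixels = sum((gold > 0) & (test > 0)),
         holes = a$holes, isolated_points = a$isolated_points)
  })
  structure(c(tm$result, list(elapsed = tm$elapsed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> Dice = %.4f (|M| = %d, |N| = %d, overlap = %d)\n",
              x$dice, x$gold_pixels, x$test_pixels, x$overlap_pixels))
  cat(sprintf("  holes: %d, isolated points: %d, elapsed: %.3f s\n",
              x$holes, x$isolated_points, x$elapsed))
  invisible(x)
}

#' Time a computation
#'
#' Wall-clock ("efficiency") timing of an expression: the elapsed time the
#' computer spends executing it, measured with R's monotonic process clock.
#'
#' @param expr expression to evaluate.
#' @return A list with `result` (the expression's value) and `elapsed`
#'   (seconds, `>= 0`).
#' @export
timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- expr
  list(result = result, elapsed = max(proc.time()[["elapsed"]] - t0, 0))
}
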