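#' The five articular-surface regions
#'
#' The tibial-plateau top view is divided into the central intercondylar
#' eminence band and four weight-bearing articular quadrants.
#'
#' @return Character vector of the five region names.
#' @export
plateau_regions <- function() {
  c("intercondylar", "anterolateral", "anteromedial",
    "posterolateral", "posteromedial")
}

articular_regions <- function() setdiff(plateau_regions(), "intercondylar")

grade_levels <- c("bad", "common", "good", "excellent")

as_grade <- function(x) factor(x, levels = grade_levels, ordered = TRUE)

# Band closures: the printed bands leave boundary values ambiguous
# ("5 mm" / "6-10 mm"); measurements are real-valued, so bands are closed
# half-open with boundary values joining the lower-scoring band.
points_collapse <- function(mm) {
  if (mm == 0) 6L else if (mm <= 5) 4L else if (mm <= 10) 2L else 0L
}
points_broadening <- function(mm) {
  if (mm == 0) 6L else if (mm < 5) 4L else if (mm <= 10) 2L else 0L
}
points_angulation <- function(deg) {
  if (deg == 0) 6L else if (deg < 10) 4L else if (deg <= 20) 2L else 0L
}

#' Articular-surface displacement score
#'
#' Rasmussen-style anatomical scoring of tibial-condyle fracture reduction.
#' Each of the three displacement categories — articular surface collapse
#' depth, plateau broadening, and varus/valgus angular deformity — is worth
#' 0/2/4/6 points (6 = none), for a displacement total of 0--18 points,
#' graded excellent (18), good (12--17), common (6--11) or bad (0--5).
#'
#' @param collapse_mm articular surface collapse depth, mm, `>= 0`.
#' @param broadening_mm plateau broadening, mm, `>= 0`.
#' @param angulation_deg angular deformity (varus or valgus), degrees, `>= 0`.
#' @return List with `collapse_pts`, `broadening_pts`, `angulation_pts`,
#'   `displacement_total`, `displacement_grade` (ordered factor).
#' @examples
#' score_displacement(0, 0, 0)$displacement_total   # 18, excellent
#' score_displacement(8, 12, 5)$displacement_total  # 2 + 0 + 4 = 6, common
#' @export
score_displacement <- function(collapse_mm, broadening_mm, angulation_deg) {
  vals <- c(collapse_mm, broadening_mm, angulation_deg)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("displacement measurements must be finite and >= 0")
  cp <- points_collapse(collapse_mm)
  bp <- points_broadening(broadening_mm)
  ap <- points_angulation(angulation_deg)
  total <- cp + bp + ap
  grade <- if (total == 18L) "excellent" else if (total >= 12L) "good"
           else if (total >= 6L) "common" else "bad"
  list(collapse_pts = cp, broadening_pts = bp, angulation_pts = ap,
       displacement_total = total, displacement_grade = as_grade(grade))
}

#' Damage-area and comminution score
#'
#' Damage-area points depend on how many of the four weight-bearing
#' articular quadrants are damaged: none (damage absent or confined to the
#' intercondylar eminence) scores 6, 1--2 quadrants 4, 3 quadrants 2, all 4
#' quadrants 0.  Intercondylar involvement alone never lowers the score.
#' Comminution points depend on the fracture-fragment count: 0 fragments
#' (fracture line through the intercondylar eminence only) scores 6, 1
#' fragment 4, 2 fragments 2, 3 or more 0.  A fragment count of 0 is only
#' consistent with damage confined to the intercondylar eminence.
#'
#' @param damaged_regions character vector, subset of [plateau_regions()].
#' @param fragment_count non-negative integer count of fracture fragments.
#' @return List with `damage_pts` and `comminution_pts`.
#' @examples
#' score_surface("intercondylar", 0)                      # 6 + 6
#' score_surface(c("anterolateral", "posteromedial"), 2)  # 4 + 2
#' @export
score_surface <- function(damaged_regions, fragment_count) {
  damaged_regions <- unique(as.character(damaged_regions))
  bad <- setdiff(damaged_regions, plateau_regions())
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "))
  fragment_count <- as.integer(fragment_count)
  if (is.na(fragment_count) || fragment_count < 0L)
    stop("fragment_count must be a non-negative integer")
  n_art <- length(intersect(damaged_regions, articular_regions()))
  if (fragment_count == 0L && n_art > 0L)
    stop("fragment_count 0 means the fracture line passes only through the ",
         "intercondylar eminence; articular-region damage is inconsistent")
  damage_pts <- if (n_art == 0L) 6L else if (n_art <= 2L) 4L
                else if (n_art == 3L) 2L else 0L
  comminution_pts <- if (fragment_count == 0L) 6L
                     else if (fragment_count == 1L) 4L
                     else if (fragment_count == 2L) 2L else 0L
  list(damage_pts = damage_pts, comminution_pts = comminution_pts)
}

#' Total imaging score
#'
#' Sums the three displacement categories and the damage-area and
#' comminution categories into the 0--30 point total imaging score, graded
#' excellent (28--30), good (20--27), common (10--19) or bad (0--9).
#'
#' @inheritParams score_displacement
#' @inheritParams score_surface
#' @return An object of class `imaging_score` holding all five sub-scores,
#'   `displacement_total`, `displacement_grade`, `total` and `total_grade`.
#' @examples
#' s <- imaging_score(0, 0, 0, "intercondylar", 0)
#' s$total  # 30, excellent
#' @export
imaging_score <- function(collapse_mm, broadening_mm, angulation_deg,
                          damaged_regions = character(0), fragment_count) {
  d <- score_displacement(collapse_mm, broadening_mm, angulation_deg)
  s <- score_surface(damaged_regions, fragment_count)
  total <- d$displacement_total + s$damage_pts + s$comminution_pts
  grade <- if (total >= 28L) "excellent" else if (total >= 20L) "good"
           else if (total >= 10L) "common" else "bad"
  structure(
    c(d, s,
      list(total = total, total_grade = as_grade(grade),
           measurements = list(collapse_mm = collapse_mm,
                               broadening_mm = broadening_mm,
                               angulation_deg = angulation_deg,
                               damaged_regions = damaged_regions,
                               fragment_count = fragment_count))),
    class = "imaging_score"
  )
}

#' @export
print.imaging_score <- function(x, ...) {
  cat("<imaging_score>\n")
  cat(sprintf("  displacement: collapse %d + broadening %d + angulation %d = %d/18 (%s)\n",
              x$collapse_pts, x$broadening_pts, x$angulation_pts,
              x$displacement_total, as.character(x$displacement_grade)))
  cat(sprintf("  damage area: %d/6, comminution: %d/6\n",
              x$damage_pts, x$comminution_pts))
  cat(sprintf("  total: %d/30 (%s)\n", x$total, as.character(x$total_grade)))
  invisible(x)
}

#' Divide a plateau top-view mask into the five regions
#'
#' Reproduces the drawing construction on the top view: a longitudinal
#' (vertical) line through the middle of the intercondylar crest and two
#' parallels at the base of the eminence bound a central band (the
#' intercondylar region); a horizontal line through the middle splits the
#' remaining foreground into the four articular quadrants.  The lines are
#' anchored at the foreground centroid, the band half-width is
#' `eminence_halfwidth_frac` times the foreground bounding-box width, and
#' smaller column indices are labeled lateral / smaller row indices anterior
#' (a labeling convention; true laterality depends on which knee is imaged).
#'
#' @param mask logical top-view plateau mask (non-empty).
#' @param eminence_halfwidth_frac half-width of the central band as a
#'   fraction of the foreground bounding-box width, in `(0, 0.5)`
#'   (default 0.15).
#' @return Integer matrix of region codes (0 = background, 1..5 indexing
#'   [plateau_regions()]), with attribute `regions` naming the codes.
#' @export
divide_plateau <- function(mask, eminence_halfwidth_frac = 0.15) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask)) stop("empty plateau mask")
  if (eminence_halfwidth_frac <= 0 || eminence_halfwidth_frac >= 0.5)
    stop("eminence_halfwidth_frac must lie in (0, 0.5)")
  rows <- row(mask)[mask]; cols <- col(mask)[mask]
  c_col <- mean(cols); c_row <- mean(rows)
  halfwidth <- eminence_halfwidth_frac * (max(cols) - min(cols) + 1L)
  regions <- plateau_regions()
  lab <- matrix(0L, nrow(mask), ncol(mask))
  rc <- row(mask); cc <- col(mask)
  central <- abs(cc - c_col) <= halfwidth
  lateral <- cc < c_col
  anterior <- rc < c_row
  lab[mask & central] <- 1L
  lab[mask & !central & anterior & lateral] <- 2L
  lab[mask & !central & anterior & !lateral] <- 3L
  lab[mask & !central & !anterior & lateral] <- 4L
  lab[mask & !central & !anterior & !lateral] <- 5L
  attr(lab, "regions") <- regions
  attr(lab, "centroid") <- c(row = c_row, col = c_col)
  attr(lab, "halfwidth") <- halfwidth
  lab
}

#' Count damaged regions from a damage mask
#'
#' A region counts as damaged when at least `min_overlap_px` damage pixels
#' fall inside it.
#'
#' @param regions region label map from [divide_plateau()].
#' @param damage logical damage mask (e.g. fracture-line pixels) of the same
#'   dimensions.
#' @param min_overlap_px minimum overlap in pixels (default 1).
#' @return Character vector of damaged region names (possibly empty), in
#'   [plateau_regions()] order.
#' @export
count_damaged_regions <- function(regions, damage, min_overlap_px = 1L) {
  stopifnot(is.matrix(regions), is.matrix(damage))
  if (!all(dim(regions) == dim(damage))) stop("dimension mismatch")
  names <- attr(regions, "regions")
  if (is.null(names)) names <- plateau_regions()
  overlap <- tabulate(regions[damage > 0], nbins = length(names))
  names[overlap >= min_overlap_px]
}
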