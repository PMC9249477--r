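#' Graph-cut segmentation parameters
#'
#' Parameters of the seeded two-terminal graph cut.  The energy minimized is
#' \deqn{E(A) = \lambda \sum_p R_p(A_p) + \sum_{(p,q)} B_{pq}\,[A_p \neq A_q]}
#' with region term `R_p(l) = -log P_l(I_p)` from smoothed seed-intensity
#' histograms and contrast boundary term
#' `B_pq = exp(-(I_p - I_q)^2 / (2 sigma^2)) / dist(p, q)`.
#'
#' @param lambda non-negative weight of the region term (default 1).
#' @param sigma boundary contrast scale in gray levels; `NULL` (default)
#'   estimates it per image as the median absolute 4-neighbor intensity
#'   difference, floored at 1 so constant regions stay well-defined.
#' @param connectivity 4 or 8 pixel neighborhood (default 8); diagonal links
#'   are down-weighted by `dist = sqrt(2)`.
#' @param seed_band half-width, in gray levels, of the uncertainty band
#'   around the threshold left unseeded (default 10).
#' @param hist_smoothing pseudocount added to each level of the seed
#'   histograms (default 1), keeping all region terms finite.
#' @param seed_filter `"none"` (default) seeds directly from pixel
#'   intensities; `"median"` seeds from a 3x3 median-filtered copy of the
#'   image, so single impulse-corrupted pixels cannot become hard seeds of
#'   the wrong class.  Only marker placement is filtered; the segmentation
#'   energy always uses the original intensities.
#' @param backend min-cut solver: `"dinic"` (bundled augmenting-path solver)
#'   or `"igraph"` (external); both return the same cut value.
#' @param invert if `TRUE`, treat the *dark* phase as foreground.  Default
#'   `FALSE`: bone is the bright phase in CT.
#' @return A list of class `graphcut_params`.
#' @export
graphcut_params <- function(lambda = 1, sigma = NULL, connectivity = 8L,
                            seed_band = 10, hist_smoothing = 1,
                            seed_filter = c("none", "median"),
                            backend = c("dinic", "igraph"), invert = FALSE) {
  backend <- match.arg(backend)
  seed_filter <- match.arg(seed_filter)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (lambda < 0) stop("lambda must be >= 0")
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (seed_band < 0) stop("seed_band must be >= 0")
  if (hist_smoothing < 0) stop("hist_smoothing must be >= 0")
  structure(
    list(lambda = lambda, sigma = sigma, connectivity = connectivity,
         seed_band = seed_band, hist_smoothing = hist_smoothing,
         seed_filter = seed_filter, backend = backend, invert = invert),
    class = "graphcut_params"
  )
}

# 3x3 median filter with replicate padding.
median_filter3 <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  pr <- px[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  stack <- vapply(seq_len(9L), function(k) {
    dr <- (k - 1L) %% 3L
    dc <- (k - 1L) %/% 3L
    as.vector(pr[dr + seq_len(nr), dc + seq_len(nc)])
  }, numeric(nr * nc))
  matrix(apply(stack, 1L, stats::median), nr, nc)
}

#' Seed-mask codes
#'
#' Seed masks are integer matrices with entries `SEED_FG` (1, foreground
#' seed), `SEED_BG` (-1, background seed) and `SEED_NONE` (0, unlabeled).
#' @format Integer constants.
#' @export
SEED_FG <- 1L
#' @rdname SEED_FG
#' @export
SEED_BG <- -1L
#' @rdname SEED_FG
#' @export
SEED_NONE <- 0L

#' Automatic threshold-marker generation
#'
#' Replaces the manual foreground/background marking of interactive graph
#' cuts: pixels brighter than `t* + seed_band` become foreground seeds,
#' pixels at or below `t* - seed_band` become background seeds, and the
#' uncertainty band in between is left unlabeled for the cut to decide.
#' If either seed class would be empty the band is halved repeatedly (and
#' snapped to 0 once below half a gray level) until both classes are
#' non-empty; at band 0 the split `I > t*` vs `I <= t*` is guaranteed
#' non-degenerate for any valid threshold, so only a single-level image
#' fails, with an ill-posed-input error.
#'
#' @param image a [gray_image()].
#' @param scan a `threshold_scan`, or a bare integer threshold `t*`.
#' @param params a [graphcut_params()].
#' @return An integer seed-mask matrix (see [SEED_FG]) with attributes
#'   `t_star` and `band` (the band actually used after shrinking).
#' @export
generate_markers <- function(image, scan, params = graphcut_params()) {
  stopifnot(inherits(image, "gray_image"), inherits(params, "graphcut_params"))
  t_star <- if (inherits(scan, "threshold_scan")) scan$t_star else as.integer(scan)
  if (is.na(t_star) || t_star < 0L || t_star > image$levels - 2L)
    stop("t_star out of range for this image")
  I <- image$pixels
  if (params$seed_filter == "median") I <- median_filter3(I)
  if (params$invert) {
    I <- (image$levels - 1L) - I
    t_star <- (image$levels - 2L) - t_star
  }
  band <- params$seed_band
  repeat {
    fg <- I > t_star + band
    bg <- I <= t_star - band
    if (any(fg) && any(bg)) break
    if (band == 0)
      stop("ill-posed input: cannot place both foreground and background seeds ",
           "(single-level image?)")
    band <- band / 2
    if (band < 0.5) band <- 0
  }
  seeds <- matrix(SEED_NONE, nrow(I), ncol(I))
  seeds[fg] <- SEED_FG
  seeds[bg] <- SEED_BG
  attr(seeds, "t_star") <- if (params$invert) (image$levels - 2L) - t_star else t_star
  attr(seeds, "band") <- band
  seeds
}

# Median absolute 4-neighbor difference, floored at 1 gray level.
estimate_sigma <- function(pixels) {
  dh <- abs(pixels[, -1, drop = FALSE] - pixels[, -ncol(pixels), drop = FALSE])
  dv <- abs(pixels[-1, , drop = FALSE] - pixels[-nrow(pixels), , drop = FALSE])
  max(stats::median(c(dh, dv)), 1)
}

# Neighbor pairs of an nr x nc grid in column-major linear indexing.
# Returns list(p, q, dist); each undirected pair appears once.
grid_neighbors <- function(nr, nc, connectivity) {
  idx <- matrix(seq_len(nr * nc), nr, nc)
  p <- c(idx[-nr, , drop = FALSE], idx[, -nc, drop = FALSE])
  q <- c(idx[-1, , drop = FALSE], idx[, -1, drop = FALSE])
  d <- rep(1, length(p))
  if (connectivity == 8L && nr > 1L && nc > 1L) {
    p <- c(p, idx[-nr, -nc], idx[-1, -nc])
    q <- c(q, idx[-1, -1], idx[-nr, -1])
    d <- c(d, rep(sqrt(2), 2L * (nr - 1L) * (nc - 1L)))
  }
  list(p = p, q = q, dist = d)
}

# Smoothed intensity likelihood of the seed class: P(i) with pseudocount.
seed_likelihood <- function(intensities, levels, pseudocount) {
  counts <- tabulate(intensities + 1L, nbins = levels)
  (counts + pseudocount) / (sum(counts) + pseudocount * levels)
}

#' Seeded graph-cut segmentation
#'
#' Computes the global minimum of the two-label energy described in
#' [graphcut_params()] by a single s-t min cut: terminal links carry the
#' region costs (infinite for seeds, enforcing them as hard constraints),
#' neighbor links carry the contrast costs.  The bundled solver is an
#' augmenting-path (Dinic) max-flow; `backend = "igraph"` delegates to
#' `igraph::max_flow()` on the identical graph.
#'
#' @param image a [gray_image()].
#' @param seeds integer seed mask (see [generate_markers()]); must contain at
#'   least one foreground and one background seed.
#' @param params a [graphcut_params()].
#' @return A logical matrix (`TRUE` = foreground) with attributes `energy`
#'   (the cut value) and `sigma` (the boundary scale used).
#' @export
segment_seeded <- function(image, seeds, params = graphcut_params()) {
  stopifnot(inherits(image, "gray_image"), inherits(params, "graphcut_params"))
  I <- image$pixels
  if (!is.matrix(seeds) || !all(dim(seeds) == dim(I)))
    stop("seed mask dimensions must match the image")
  fg <- seeds == SEED_FG
  bg <- seeds == SEED_BG
  if (!any(fg) || !any(bg))
    stop("ill-posed seeds: need at least one foreground and one background seed")

  npx <- length(I)
  sigma <- if (is.null(params$sigma)) estimate_sigma(I) else params$sigma

  p_fg <- seed_likelihood(I[fg], image$levels, params$hist_smoothing)
  p_bg <- seed_likelihood(I[bg], image$levels, params$hist_smoothing)
  if (any(p_fg[I + 1L] <= 0) || any(p_bg[I + 1L] <= 0))
    stop("region term is not finite; use a positive hist_smoothing pseudocount")
  r_fg <- -log(p_fg[I + 1L])          # cost of labeling each pixel foreground
  r_bg <- -log(p_bg[I + 1L])

  nb <- grid_neighbors(nrow(I), ncol(I), params$connectivity)
  b_pq <- exp(-(I[nb$p] - I[nb$q])^2 / (2 * sigma^2)) / nb$dist

  # source = foreground terminal, sink = background terminal;
  # cutting s->p puts p in background, so cap(s->p) = cost of background.
  cap_s <- params$lambda * r_bg
  cap_t <- params$lambda * r_fg
  inf_cap <- sum(cap_s[!fg]) + sum(cap_t[!bg]) + 2 * sum(b_pq) + 1
  cap_s[fg] <- inf_cap
  cap_t[bg] <- inf_cap

  s <- npx + 1L; t <- npx + 2L
  from <- c(rep(s, npx), seq_len(npx), nb$p, nb$q)
  to <- c(seq_len(npx), rep(t, npx), nb$q, nb$p)
  cap <- c(cap_s, cap_t, b_pq, b_pq)

  if (params$backend == "igraph") {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("backend 'igraph' requires the igraph package")
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    fl <- igraph::max_flow(g, source = s, target = t, capacity = cap)
    lab_fg <- rep(FALSE, npx)
    part <- as.integer(fl$partition1)
    lab_fg[part[part <= npx]] <- TRUE
    energy <- fl$value
  } else {
    fl <- maxflow_dinic(npx + 2L, from, to, cap, s, t)
    lab_fg <- fl$source_side[seq_len(npx)]
    energy <- fl$flow
  }

  out <- matrix(lab_fg, nrow(I), ncol(I))
  stopifnot(all(out[fg]), !any(out[bg]))   # hard constraints
  attr(out, "energy") <- energy
  attr(out, "sigma") <- sigma
  out
}

#' Fully automatic segmentation pipeline
#'
#' Histogram, threshold selection (`max_entropy` or `min_error`), automatic
#' marker generation and seeded graph cut, composed end to end.  The run
#' report records the selected threshold, seed counts, cut energy and wall
#' time of each stage.
#'
#' @param image a [gray_image()].
#' @param method threshold selector: `"max_entropy"` or `"min_error"`.
#' @param params a [graphcut_params()].
#' @return A list of class `segmentation_result`: `mask` (logical matrix),
#'   `t_star`, `objective_star`, `scan`, `seeds`, `seed_counts`, `energy`,
#'   `sigma`, `method`, `elapsed` (seconds, total and per stage).
#' @examples
#' ph <- generate_slice(phantom_spec(width = 32, height = 32, rng_seed = 7))
#' res <- segment_auto(ph$image, method = "max_entropy")
#' dice(ph$truth_mask, res$mask)
#' @export
segment_auto <- function(image, method = c("max_entropy", "min_error"),
                         params = graphcut_params()) {
  method <- match.arg(method)
  th <- timed({
    hist <- compute_histogram(image)
    if (method == "max_entropy") max_entropy_threshold(hist)
    else min_error_threshold(hist)
  })
  sd <- timed(generate_markers(image, th$result, params))
  gc <- timed(segment_seeded(image, sd$result, params))
  seeds <- sd$result
  structure(
    list(mask = gc$result,
         t_star = th$result$t_star,
         objective_star = th$result$objective_star,
         scan = th$result,
         seeds = seeds,
         seed_counts = c(foreground = sum(seeds == SEED_FG),
                         background = sum(seeds == SEED_BG),
                         unlabeled = sum(seeds == SEED_NONE)),
         energy = attr(gc$result, "energy"),
         sigma = attr(gc$result, "sigma"),
         method = method,
         elapsed = c(threshold = th$elapsed, seeds = sd$elapsed,
                     cut = gc$elapsed,
                     total = th$elapsed + sd$elapsed + gc$elapsed)),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> method = %s, t* = %d, energy = %.4g\n",
              x$method, x$t_star, x$energy))
  cat(sprintf("  seeds: %d fg / %d bg / %d unlabeled; foreground pixels: %d\n",
              x$seed_counts[["foreground"]], x$seed_counts[["background"]],
              x$seed_counts[["unlabeled"]], sum(x$mask)))
  cat(sprintf("  elapsed: %.3f s\n", x$elapsed[["total"]]))
  invisible(x)
}

#' Plain threshold segmentation
#'
#' The baseline the graph cut is compared against: label every pixel above
#' `t*` foreground, everything else background, with no spatial term.
#'
#' @param image a [gray_image()].
#' @param t_star integer threshold or a `threshold_scan`.
#' @param invert treat the dark phase as foreground.
#' @return A logical matrix.
#' @export
threshold_segment <- function(image, t_star, invert = FALSE) {
  stopifnot(inherits(image, "gray_image"))
  if (inherits(t_star, "threshold_scan")) t_star <- t_star$t_star
  if (invert) image$pixels <= t_star else image$pixels > t_star
}
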