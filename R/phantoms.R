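#' Phantom specification
#'
#' Describes a synthetic CT-like slice with exact ground truth.  Foreground
#' (bone) and background (soft tissue) intensities are drawn from Gaussian
#' distributions — the same two-Gaussian model the minimum-error threshold
#' assumes — clipped to `[0, 255]` and rounded half-to-even, so generated
#' images are platform-stable.  Defaults emulate a high-contrast trabecular
#' bone slice: bright bone (mean 200) on dark soft tissue (mean 60), both
#' with SD 5.
#'
#' @param width,height canvas size in pixels.
#' @param bone_shape one of `"disk"`, `"annulus"`, `"ellipse"`,
#'   `"rectangle"`.
#' @param shape_params named list of geometry parameters; missing entries
#'   get canvas-proportional defaults.  Recognized: `cx, cy` (center, pixels,
#'   x = column, y = row), `radius`, `inner_radius` (annulus), `a, b`
#'   (ellipse semi-axes), `half_w, half_h` (rectangle half-extents).
#' @param fg_mean,fg_sd,bg_mean,bg_sd intensity model (gray levels);
#'   means in `[0, 255]`, SDs `>= 0`.
#' @param fracture_lines list of fracture lines, each a list with `from =
#'   c(x, y)`, `to = c(x, y)` and `width` (pixels); fracture pixels take the
#'   background distribution and are excluded from the truth mask.
#' @param noise `"none"`, `"gaussian"` (additive, SD = `noise_amount` gray
#'   levels) or `"salt_pepper"` (fraction `noise_amount` of pixels forced to
#'   0 or 255).
#' @param noise_amount see `noise`.
#' @param rng_seed integer seed; every random draw of the phantom comes from
#'   one stream seeded with it, so equal specs give bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 64L, height = 64L, bone_shape = "disk",
                         shape_params = list(),
                         fg_mean = 200, fg_sd = 5, bg_mean = 60, bg_sd = 5,
                         fracture_lines = list(),
                         noise = c("none", "gaussian", "salt_pepper"),
                         noise_amount = 0, rng_seed = 1L) {
  noise <- match.arg(noise)
  bone_shape <- match.arg(bone_shape, c("disk", "annulus", "ellipse", "rectangle"))
  width <- as.integer(width); height <- as.integer(height)
  if (width < 4L || height < 4L) stop("canvas must be at least 4 x 4")
  means <- c(fg_mean, bg_mean)
  if (any(means < 0) || any(means > 255)) stop("means must lie in [0, 255]")
  if (fg_sd < 0 || bg_sd < 0) stop("intensity SDs must be >= 0")
  if (noise_amount < 0) stop("noise_amount must be >= 0")
  sp <- shape_defaults(bone_shape, shape_params, width, height)
  check_shape_fits(bone_shape, sp, width, height)
  structure(
    list(width = width, height = height, bone_shape = bone_shape,
         shape_params = sp, fg_mean = fg_mean, fg_sd = fg_sd,
         bg_mean = bg_mean, bg_sd = bg_sd, fracture_lines = fracture_lines,
         noise = noise, noise_amount = noise_amount,
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
}

shape_defaults <- function(shape, sp, width, height) {
  def <- list(cx = (width + 1) / 2, cy = (height + 1) / 2,
              radius = 0.35 * min(width, height),
              inner_radius = 0.15 * min(width, height),
              a = 0.42 * width, b = 0.38 * height,
              half_w = 0.35 * width, half_h = 0.35 * height)
  utils::modifyList(def, sp)
}

check_shape_fits <- function(shape, sp, width, height) {
  ext <- switch(shape,
    disk = c(sp$radius, sp$radius),
    annulus = c(sp$radius, sp$radius),
    ellipse = c(sp$a, sp$b),
    rectangle = c(sp$half_w, sp$half_h))
  if (shape == "annulus" && sp$inner_radius >= sp$radius)
    stop("annulus inner_radius must be smaller than radius")
  if (sp$cx - ext[1] < 0.5 || sp$cx + ext[1] > width + 0.5 ||
      sp$cy - ext[2] < 0.5 || sp$cy + ext[2] > height + 0.5)
    stop("shape does not fit inside the canvas")
  invisible(TRUE)
}

shape_mask <- function(spec) {
  sp <- spec$shape_params
  cc <- matrix(rep(seq_len(spec$width), each = spec$height),
               spec$height, spec$width)
  rr <- matrix(rep(seq_len(spec$height), spec$width),
               spec$height, spec$width)
  dx <- cc - sp$cx; dy <- rr - sp$cy
  switch(spec$bone_shape,
    disk = dx^2 + dy^2 <= sp$radius^2,
    annulus = {
      d2 <- dx^2 + dy^2
      d2 <= sp$radius^2 & d2 >= sp$inner_radius^2
    },
    ellipse = (dx / sp$a)^2 + (dy / sp$b)^2 <= 1,
    rectangle = abs(dx) <= sp$half_w & abs(dy) <= sp$half_h)
}

# Pixels within width/2 of the segment from -> to (x = column, y = row).
line_mask <- function(from, to, width, nr, nc) {
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  vx <- to[1] - from[1]; vy <- to[2] - from[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    d2 <- (cc - from[1])^2 + (rr - from[2])^2
  } else {
    tt <- pmin(pmax(((cc - from[1]) * vx + (rr - from[2]) * vy) / len2, 0), 1)
    d2 <- (cc - (from[1] + tt * vx))^2 + (rr - (from[2] + tt * vy))^2
  }
  d2 <= (width / 2)^2
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
with_phantom_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a CT-like slice phantom
#'
#' Renders the bone shape, carves out the fracture lines, samples foreground
#' and background intensities from their Gaussian models, applies optional
#' noise, and returns the image together with its exact ground truth.
#' Fracture pixels take background-distributed intensities and are excluded
#' from the truth mask.  Fully reproducible from `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_case`: `image` ([gray_image()]),
#'   `truth_mask` (logical), `damage_mask` (logical, fracture-line pixels
#'   inside the bone footprint), `region_truth` (character, for plateau
#'   phantoms), `spec`.
#' @examples
#' ph <- generate_slice(phantom_spec(width = 32, height = 32, rng_seed = 3))
#' sum(ph$truth_mask)
#' @export
generate_slice <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  footprint <- shape_mask(spec)
  damage <- matrix(FALSE, spec$height, spec$width)
  for (ln in spec$fracture_lines)
    damage <- damage | line_mask(ln$from, ln$to, ln$width,
                                 spec$height, spec$width)
  damage <- damage & footprint
  truth <- footprint & !damage
  px <- with_phantom_rng(spec$rng_seed, {
    img <- matrix(rnorm(spec$height * spec$width, spec$bg_mean, spec$bg_sd),
                  spec$height, spec$width)
    img[truth] <- rnorm(sum(truth), spec$fg_mean, spec$fg_sd)
    if (spec$noise == "gaussian" && spec$noise_amount > 0)
      img <- img + rnorm(length(img), 0, spec$noise_amount)
    if (spec$noise == "salt_pepper" && spec$noise_amount > 0) {
      n_sp <- round(spec$noise_amount * length(img))
      if (n_sp > 0) {
        at <- sample.int(length(img), n_sp)
        img[at] <- ifelse(runif(n_sp) < 0.5, 0, 255)
      }
    }
    round(pmin(pmax(img, 0), 255))   # clip, then round half-to-even
  })
  structure(
    list(image = gray_image(px), truth_mask = truth, damage_mask = damage,
         region_truth = character(0), spec = spec),
    class = "phantom_case"
  )
}

#' Generate a plateau top-view phantom with a target damage pattern
#'
#' Builds an elliptical plateau top view and routes short fracture-line
#' segments so that, under [divide_plateau()] with default parameters, the
#' damaged-region set equals `target_regions` exactly: the intercondylar
#' segment runs along the centroid column inside the central band, and each
#' articular segment sits at its quadrant's interior anchor point, clear of
#' the band and the midlines.  Unlike slice phantoms, `truth_mask` is the
#' *intact* footprint (the full ellipse): region division is defined on the
#' intact surface and the damage mask lies inside it.
#'
#' @param spec a [phantom_spec()]; its `bone_shape` is overridden to
#'   `"ellipse"`.
#' @param target_regions character vector, subset of [plateau_regions()].
#' @return A `phantom_case` (see [generate_slice()]) with `region_truth =
#'   target_regions` and `truth_mask` the intact ellipse.
#' @export
generate_plateau <- function(spec, target_regions = character(0)) {
  stopifnot(inherits(spec, "phantom_spec"))
  target_regions <- unique(as.character(target_regions))
  bad <- setdiff(target_regions, plateau_regions())
  if (length(bad))
    stop("unroutable target set: unknown region(s) ", paste(bad, collapse = ", "))
  spec$bone_shape <- "ellipse"
  sp <- shape_defaults("ellipse", spec$shape_params, spec$width, spec$height)
  check_shape_fits("ellipse", sp, spec$width, spec$height)
  spec$shape_params <- sp
  seg_half <- 0.12 * min(sp$a, sp$b)
  lines <- list()
  for (reg in target_regions) {
    if (reg == "intercondylar") {
      lines[[length(lines) + 1L]] <- list(
        from = c(sp$cx, sp$cy - 0.4 * sp$b),
        to = c(sp$cx, sp$cy + 0.4 * sp$b), width = 1)
    } else {
      sx <- if (grepl("lateral$", reg)) -1 else 1   # lateral = smaller columns
      sy <- if (grepl("^antero", reg)) -1 else 1    # anterior = smaller rows
      anchor <- c(sp$cx + sx * 0.6 * sp$a, sp$cy + sy * 0.5 * sp$b)
      lines[[length(lines) + 1L]] <- list(
        from = anchor - c(seg_half, 0), to = anchor + c(seg_half, 0), width = 1)
    }
  }
  spec$fracture_lines <- lines
  case <- generate_slice(spec)
  case$truth_mask <- case$truth_mask | case$damage_mask   # intact footprint
  case$region_truth <- intersect(plateau_regions(), target_regions)
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %d x %d %s, %d foreground px, %d damage px",
              x$spec$width, x$spec$height, x$spec$bone_shape,
              sum(x$truth_mask), sum(x$damage_mask)))
  if (length(x$region_truth))
    cat(", regions: ", paste(x$region_truth, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Write a phantom case to disk
#'
#' Writes `image.png`, `truth.png`, `damage.png` and `case.json` (the spec
#' and region truth) into a directory.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if missing).
#' @export
write_phantom_case <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_phantom_case requires the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gray_image(case$image, file.path(dir, "image.png"))
  write_mask(case$truth_mask, file.path(dir, "truth.png"))
  write_mask(case$damage_mask, file.path(dir, "damage.png"))
  meta <- case$spec
  class(meta) <- NULL
  meta$region_truth <- case$region_truth
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
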