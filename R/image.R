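#' Grayscale image container
#'
#' A `gray_image` wraps an integer pixel matrix together with its number of
#' gray levels `L`.  Pixels are stored row/column as an R matrix: `pixels[r, c]`
#' is the intensity of the pixel in (0-based) image row `r - 1` and column
#' `c - 1`, i.e. row-major with the origin at the top-left corner.  Every
#' intensity must lie in `0..L-1`; values at or above `L` are rejected rather
#' than clipped so that histogram probabilities stay exact.
#'
#' @param pixels integer (or whole-number numeric) matrix of intensities.
#' @param levels number of gray levels `L` (default 256 for 8-bit data).
#' @return An object of class `gray_image` with elements `pixels` (integer
#'   matrix), `levels`, `width` (columns), `height` (rows).
#' @examples
#' img <- gray_image(matrix(c(0L, 85L, 170L, 255L), 2, 2))
#' img$width
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L) stop("`levels` must be an integer >= 2")
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite")
  if (any(pixels != round(pixels))) stop("pixel intensities must be whole numbers")
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("pixel intensities must be >= 0")
  if (any(pixels >= levels))
    stop("pixel intensity ", max(pixels), " exceeds L - 1 = ", levels - 1L,
         "; intensities are rejected, not clipped")
  structure(
    list(pixels = pixels, levels = levels,
         width = ncol(pixels), height = nrow(pixels)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d pixels, L = %d, intensity range [%d, %d]\n",
              x$width, x$height, x$levels, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
as.matrix.gray_image <- function(x, ...) x$pixels

#' Read a single-channel 8-bit image (PGM or PNG)
#'
#' Accepts binary (`P5`) and plain (`P2`) PGM, and 8-bit single-channel
#' grayscale PNG.  Multi-channel (RGB/RGBA/gray+alpha) or 16-bit inputs are
#' rejected with an error naming the offending property, so that a loaded
#' image always satisfies the `gray_image` contract.
#'
#' @param path file path; format chosen by extension (`.pgm`, `.png`).
#' @param levels number of gray levels (default 256).
#' @return A [gray_image()].
#' @seealso [write_gray_image()]
#' @export
load_gray_image <- function(path, levels = 256L) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    pgm = read_pgm(path),
    png = read_png_gray(path),
    stop("unsupported image format: .", ext, " (use .pgm or .png)")
  )
  gray_image(px, levels = levels)
}

#' Write a grayscale image to PGM or PNG
#'
#' @param image a [gray_image()] with `levels <= 256`.
#' @param path output path; format chosen by extension.
#' @param ascii for PGM, write the plain-text `P2` variant instead of the
#'   binary `P5` variant.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path, ascii = FALSE) {
  stopifnot(inherits(image, "gray_image"))
  if (image$levels > 256L) stop("only 8-bit output (levels <= 256) is supported")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(image$pixels, path, ascii = ascii),
    png = png::writePNG(image$pixels / 255, target = path),
    stop("unsupported image format: .", ext, " (use .pgm or .png)")
  )
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_pnm_token(con)
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (magic '", magic, "', expected P2 or P5)")
  w <- as.integer(read_pnm_token(con))
  h <- as.integer(read_pnm_token(con))
  maxval <- as.integer(read_pnm_token(con))
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) stop("corrupt PGM header")
  if (is.na(maxval) || maxval != 255L)
    stop("unsupported PGM bit depth: maxval ", maxval, " (expected 255, 8-bit)")
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("corrupt PGM: expected ", n, " pixels, got ", length(vals))
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# One whitespace-delimited header token, skipping '#' comments.
read_pnm_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

write_pgm <- function(px, path, ascii = FALSE) {
  h <- nrow(px); w <- ncol(px)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(as.vector(t(px)), file = con, ncolumns = min(w, 16L))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.vector(t(px))), con)
  }
  invisible(path)
}

read_png_gray <- function(path) {
  arr <- png::readPNG(path, info = TRUE)
  info <- attr(arr, "info")
  if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth != 8L)
    stop("unsupported PNG bit depth: ", info$bit.depth, " (expected 8)")
  if (length(dim(arr)) == 3L)
    stop("unsupported PNG channel count: ", dim(arr)[3L],
         " (expected 1, single-channel grayscale)")
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Read / write binary masks as PNG
#'
#' Masks are logical matrices (`TRUE` = foreground).  On disk they are 8-bit
#' grayscale PNGs with values 0 (background) and 255 (foreground); when
#' reading, any nonzero pixel counts as foreground.
#'
#' @param path file path (`.png`).
#' @return `read_mask()`: a logical matrix.
#' @export
read_mask <- function(path) {
  read_png_gray(path) > 0
}

#' @rdname read_mask
#' @param mask logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}
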