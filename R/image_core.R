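#' Raster image container
#'
#' An `lfa_image` is an H x W x C numeric array of intensities on the
#' common scale \eqn{[0, 1]}, with C = 1 (grayscale) or C = 3 (RGB).
#' All pixel operations in the package consume and produce this type, so
#' thresholds, offsets and band intensities always live on a single scale
#' regardless of the bit depth of the source file.
#'
#' Coordinates are 0-based and row-major with the origin at the top-left
#' pixel; rectangles are half-open (see [img_rect()]). This convention is
#' stated here once and used everywhere in the package.
#'
#' @param pixels numeric array: H x W (promoted to C = 1), H x W x 1 or
#'   H x W x 3, values in \eqn{[0, 1]}.
#' @param source_path optional path the image was read from.
#' @return An `lfa_image` object.
#' @export
lfa_image <- function(pixels, source_path = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L || !dim(pixels)[3] %in% c(1L, 3L))
    stop("image must be H x W x C with C = 1 or 3, got dims ",
         paste(dim(pixels), collapse = " x "), call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must be finite and within [0, 1]", call. = FALSE)
  structure(pixels, class = "lfa_image", source_path = source_path)
}

#' @export
print.lfa_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lfa_image> %d x %d px, %d channel%s, range [%.4f, %.4f]\n",
              d[1], d[2], d[3], if (d[3] > 1) "s" else "",
              min(x), max(x)))
  invisible(x)
}

#' @export
is_lfa_image <- function(x) inherits(x, "lfa_image")

n_channels <- function(img) dim(img)[3]

#' Rectangular region of an image
#'
#' Half-open pixel rectangle `[row0, row1) x [col0, col1)` in 0-based
#' coordinates, so a full H x W image is `img_rect(0, 0, H, W)` and a
#' single pixel at the origin is `img_rect(0, 0, 1, 1)`.
#'
#' @param row0,col0 top-left corner (inclusive).
#' @param row1,col1 bottom-right corner (exclusive).
#' @return An `img_rect` object.
#' @export
img_rect <- function(row0, col0, row1, col1) {
  v <- c(row0 = row0, col0 = col0, row1 = row1, col1 = col1)
  if (anyNA(v) || any(v != floor(v)))
    stop("rectangle coordinates must be integers", call. = FALSE)
  if (row0 < 0 || col0 < 0 || row1 <= row0 || col1 <= col0)
    stop("invalid rectangle: need 0 <= row0 < row1 and 0 <= col0 < col1",
         call. = FALSE)
  structure(as.integer(v), names = names(v), class = "img_rect")
}

rect_height <- function(rect) rect[["row1"]] - rect[["row0"]]
rect_width  <- function(rect) rect[["col1"]] - rect[["col0"]]

check_rect_in_image <- function(rect, img) {
  d <- dim(img)
  if (rect[["row1"]] > d[1] || rect[["col1"]] > d[2])
    stop(sprintf("rectangle [%d,%d)x[%d,%d) exceeds image %d x %d",
                 rect[["row0"]], rect[["row1"]], rect[["col0"]],
                 rect[["col1"]], d[1], d[2]), call. = FALSE)
  invisible(rect)
}

file_ext <- function(path) tolower(sub(".*\\.", "", basename(path)))

#' Read a raster image
#'
#' Reads PNG, TIFF (8- or 16-bit) or JPEG files into an [lfa_image()].
#' Integer sample values are rescaled to \eqn{[0, 1]} by dividing by the
#' type maximum (255 or 65535). An alpha channel, if present, is dropped
#' with a message; alpha-aware compositing is out of scope.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return An `lfa_image`.
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  ext <- file_ext(path)
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      x <- EBImage::readImage(path)
      a <- EBImage::imageData(x)
      # EBImage stores (x = width, y = height[, channel]); reorder to H x W
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  )
  if (is.matrix(px)) dim(px) <- c(dim(px), 1L)
  nc <- dim(px)[3]
  if (nc %in% c(2L, 4L)) {
    message("dropping alpha channel of ", path)
    px <- px[, , seq_len(nc - 1L), drop = FALSE]
    nc <- dim(px)[3]
  }
  if (!nc %in% c(1L, 3L))
    stop("unsupported channel count ", nc, " in ", path, call. = FALSE)
  lfa_image(pmin(pmax(px, 0), 1), source_path = path)
}

#' Write a raster image
#'
#' @param img an `lfa_image`.
#' @param path output path; format taken from the extension
#'   (png/tif/tiff/jpg/jpeg).
#' @param bits bit depth for TIFF output (8 or 16); PNG is written 8-bit.
#'   Lossless round-trips are guaranteed only for PNG and TIFF.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, bits = 8L) {
  stopifnot(is_lfa_image(img), bits %in% c(8L, 16L))
  px <- unclass(img)
  if (dim(px)[3] == 1L) px <- px[, , 1L]
  switch(file_ext(path),
    png = png::writePNG(px, target = path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = bits),
    jpg = ,
    jpeg = {
      a <- if (is.matrix(px)) t(px) else aperm(px, c(2L, 1L, 3L))
      cm <- if (is.matrix(px)) "Grayscale" else "Color"
      EBImage::writeImage(EBImage::Image(a, colormode = cm), path,
                          quality = 95L)
    },
    stop("unsupported output format for ", path, call. = FALSE)
  )
  invisible(path)
}

#' Rotate an image
#'
#' Multiples of 90 degrees are exact, lossless index permutations.
#' Any other angle is rendered by bilinear interpolation onto the
#' bounding canvas of the rotated frame, with out-of-image area filled
#' with 0. Positive angles rotate clockwise.
#'
#' @param img an `lfa_image`.
#' @param degrees rotation angle in degrees.
#' @return The rotated `lfa_image`.
#' @export
rotate_image <- function(img, degrees) {
  stopifnot(is_lfa_image(img), is.finite(degrees))
  deg <- degrees %% 360
  if (deg %% 90 == 0) {
    k <- (deg %/% 90) %% 4
    px <- unclass(img)
    for (i in seq_len(k)) px <- rot90cw(px)
    return(lfa_image(px, source_path = attr(img, "source_path")))
  }
  px <- unclass(img)
  a <- if (dim(px)[3] == 1L) t(px[, , 1L]) else aperm(px, c(2L, 1L, 3L))
  cm <- if (dim(px)[3] == 1L) "Grayscale" else "Color"
  r <- EBImage::rotate(EBImage::Image(a, colormode = cm), deg,
                       filter = "bilinear", bg.col = "black")
  ra <- EBImage::imageData(r)
  out <- if (length(dim(ra)) == 2L) t(ra) else aperm(ra, c(2L, 1L, 3L))
  lfa_image(pmin(pmax(out, 0), 1), source_path = attr(img, "source_path"))
}

# clockwise quarter turn: new[r, c] = old[H + 1 - c, r]
rot90cw <- function(px) {
  d <- dim(px)
  out <- array(0, c(d[2], d[1], d[3]))
  for (ch in seq_len(d[3]))
    out[, , ch] <- t(px[rev(seq_len(d[1])), , ch])
  out
}

#' Flip an image
#'
#' `horizontal` mirrors left-right (reverses columns); `vertical` mirrors
#' top-bottom (reverses rows). Both are exact involutions.
#'
#' @param img an `lfa_image`.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return The flipped `lfa_image`.
#' @export
flip_image <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  px <- unclass(img)
  px <- if (axis == "horizontal")
    px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  else
    px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
  lfa_image(px, source_path = attr(img, "source_path"))
}

#' Crop an image
#'
#' @param img an `lfa_image`.
#' @param rect an [img_rect()] fully inside the image.
#' @return The cropped `lfa_image` of size
#'   `(row1 - row0) x (col1 - col0)`.
#' @export
crop_image <- function(img, rect) {
  stopifnot(is_lfa_image(img), inherits(rect, "img_rect"))
  check_rect_in_image(rect, img)
  px <- unclass(img)[(rect[["row0"]] + 1L):rect[["row1"]],
                     (rect[["col0"]] + 1L):rect[["col1"]], , drop = FALSE]
  lfa_image(px, source_path = attr(img, "source_path"))
}

#' Convert to grayscale
#'
#' Two weighting schemes plus single-channel extraction:
#' \describe{
#'   \item{luminance}{\eqn{0.2126 R + 0.7152 G + 0.0722 B}, the
#'     luminance-preserving colour approach.}
#'   \item{gray}{\eqn{(R + G + B) / 3}.}
#'   \item{red/green/blue}{that channel verbatim, to filter out unwanted
#'     colour channels (useful for colour-labelled assays).}
#' }
#' A 1-channel input is returned unchanged with a message.
#'
#' @param img an `lfa_image`.
#' @param mode one of `"luminance"`, `"gray"`, `"red"`, `"green"`, `"blue"`.
#' @return A 1-channel `lfa_image`.
#' @export
to_grayscale <- function(img,
                         mode = c("luminance", "gray", "red", "green",
                                  "blue")) {
  mode <- match.arg(mode)
  stopifnot(is_lfa_image(img))
  if (n_channels(img) == 1L) {
    message("image is already grayscale; returned unchanged")
    return(img)
  }
  px <- unclass(img)
  g <- switch(mode,
    luminance = 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3],
    gray      = (px[, , 1] + px[, , 2] + px[, , 3]) / 3,
    red       = px[, , 1],
    green     = px[, , 2],
    blue      = px[, , 3])
  # weights sum to 1 so g stays in [0,1]; clamp guards rounding only
  lfa_image(array(pmin(pmax(g, 0), 1), dim = c(dim(px)[1:2], 1L)),
            source_path = attr(img, "source_path"))
}

#' Invert an image (photographic negative)
#'
#' Each pixel p is replaced by 1 - p. Used when bands are brighter than
#' the background (fluorescent labels), so that downstream thresholding
#' can always assume dark-background/bright-signal after inversion or the
#' converse, consistently.
#'
#' @param img an `lfa_image`.
#' @return The inverted `lfa_image`.
#' @export
invert_image <- function(img) {
  stopifnot(is_lfa_image(img))
  lfa_image(1 - unclass(img), source_path = attr(img, "source_path"))
}

# ---- non-destructive edit state ------------------------------------------

#' Non-destructive edit state
#'
#' Wraps an image together with the ordered list of edits applied to it,
#' so the original can be restored at any time and the current image can
#' be reproduced bit-exactly by replaying the edits.
#'
#' `add_edit()` applies one edit and records it; `reset_edits()` returns
#' to the pristine original; `replay_edits()` recomputes the current
#' image from the original (used to verify determinism and to replay
#' analysis logs).
#'
#' @param img an `lfa_image`.
#' @return An `edit_state` object with fields `original`, `current`,
#'   `edits`.
#' @export
edit_state <- function(img) {
  stopifnot(is_lfa_image(img))
  structure(list(original = img, current = img, edits = list()),
            class = "edit_state")
}

#' @rdname edit_state
#' @param state an `edit_state`.
#' @param op `"rotate"`, `"flip"` or `"crop"`.
#' @param ... parameters of the edit: `degrees` for rotate, `axis` for
#'   flip, `rect` for crop.
#' @export
add_edit <- function(state, op = c("rotate", "flip", "crop"), ...) {
  op <- match.arg(op)
  edit <- c(list(op = op), list(...))
  state$current <- apply_edit_op(state$current, edit)
  state$edits <- c(state$edits, list(edit))
  state
}

#' @rdname edit_state
#' @export
reset_edits <- function(state) {
  state$current <- state$original
  state$edits <- list()
  state
}

#' @rdname edit_state
#' @export
replay_edits <- function(state) {
  img <- state$original
  for (edit in state$edits) img <- apply_edit_op(img, edit)
  img
}

apply_edit_op <- function(img, edit) {
  switch(edit$op,
    rotate = rotate_image(img, edit$degrees),
    flip   = flip_image(img, edit$axis),
    crop   = crop_image(img, if (inherits(edit$rect, "img_rect")) edit$rect
                             else do.call(img_rect, as.list(edit$rect))),
    stop("unknown edit operation: ", edit$op, call. = FALSE))
}
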