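#' Grid specification for strip segmentation
#'
#' Describes how a rectangular region of interest is subdivided into the
#' analysis grid: `n_strips` equal-width columns (one per LFA device in
#' the image) and `2 * n_lines - 1` rows. The extra rows arise because a
#' background rectangle is inserted between every pair of adjacent signal
#' lines; these inter-line rectangles are what the quantile background
#' method samples. Two lines on three strips therefore produce a 3 x 3
#' grid.
#'
#' By default rows and columns are equal subdivisions (remainder pixels
#' go to the last row/column). `row_fractions`/`col_fractions` override
#' this with explicit interior boundary positions as fractions of the
#' region, for assays with irregular band spacing.
#'
#' @param region an [img_rect()] delimiting the region of interest.
#' @param n_lines number of signal bands per strip (L >= 1).
#' @param n_strips number of strips in the image (S >= 1).
#' @param row_fractions,col_fractions optional strictly increasing
#'   interior boundary fractions in (0, 1); lengths `2 * n_lines - 2`
#'   and `n_strips - 1`.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(region, n_lines, n_strips,
                      row_fractions = NULL, col_fractions = NULL) {
  stopifnot(inherits(region, "img_rect"))
  if (n_lines < 1L || n_strips < 1L)
    stop("need n_lines >= 1 and n_strips >= 1", call. = FALSE)
  n_rows <- 2L * as.integer(n_lines) - 1L
  if (!is.null(row_fractions)) check_fractions(row_fractions, n_rows - 1L)
  if (!is.null(col_fractions)) check_fractions(col_fractions, n_strips - 1L)
  structure(list(region = region,
                 n_lines = as.integer(n_lines),
                 n_strips = as.integer(n_strips),
                 row_fractions = row_fractions,
                 col_fractions = col_fractions),
            class = "grid_spec")
}

check_fractions <- function(f, n) {
  if (length(f) != n || any(f <= 0) || any(f >= 1) || is.unsorted(f, strictly = TRUE))
    stop("boundary fractions must be ", n,
         " strictly increasing values in (0, 1)", call. = FALSE)
}

#' Build the analysis grid
#'
#' Splits the region into the `(2L - 1) x S` lattice of cell rectangles.
#' Rows alternate roles starting and ending with `line` (0-based rows
#' 0, 2, 4, ... are lines; odd rows are the inter-line background
#' rectangles). Cells tile the region exactly: no overlap, no gap.
#'
#' @param spec a [grid_spec()].
#' @return An `lfa_grid`: list with `cells` (data frame of rectangles
#'   with `grid_row`, `grid_col`, `role`, `row0`, `col0`, `row1`,
#'   `col1`), `n_rows`, `n_lines`, `n_strips`, `roles`, `region`.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  region <- spec$region
  n_rows <- 2L * spec$n_lines - 1L
  h <- rect_height(region); w <- rect_width(region)
  if (h < n_rows)
    stop("region too small: height ", h, " px cannot hold ", n_rows,
         " grid rows", call. = FALSE)
  if (w < spec$n_strips)
    stop("region too small: width ", w, " px cannot hold ", spec$n_strips,
         " strip columns", call. = FALSE)
  row_b <- boundaries(region[["row0"]], region[["row1"]], n_rows,
                      spec$row_fractions)
  col_b <- boundaries(region[["col0"]], region[["col1"]], spec$n_strips,
                      spec$col_fractions)
  roles <- ifelse(seq_len(n_rows) %% 2L == 1L, "line", "background")
  cells <- expand.grid(grid_row = seq_len(n_rows) - 1L,
                       grid_col = seq_len(spec$n_strips) - 1L,
                       KEEP.OUT.ATTRS = FALSE)
  cells$role <- roles[cells$grid_row + 1L]
  cells$row0 <- row_b[cells$grid_row + 1L]
  cells$row1 <- row_b[cells$grid_row + 2L]
  cells$col0 <- col_b[cells$grid_col + 1L]
  cells$col1 <- col_b[cells$grid_col + 2L]
  structure(list(cells = cells, n_rows = n_rows, n_lines = spec$n_lines,
                 n_strips = spec$n_strips, roles = roles, region = region),
            class = "lfa_grid")
}

# interior boundaries: equal split with remainder pixels in the last
# segment, or user fractions rounded to pixels
boundaries <- function(from, to, n, fractions = NULL) {
  if (is.null(fractions)) {
    step <- (to - from) %/% n
    b <- from + step * (0:(n - 1L))
  } else {
    b <- c(from, from + round(fractions * (to - from)))
    if (anyDuplicated(b) || any(diff(b) < 1))
      stop("boundary fractions collapse to empty grid rows/columns",
           call. = FALSE)
  }
  as.integer(c(b, to))
}

#' @export
print.lfa_grid <- function(x, ...) {
  cat(sprintf("<lfa_grid> %d rows (%d lines) x %d strips on [%d,%d)x[%d,%d)\n",
              x$n_rows, x$n_lines, x$n_strips,
              x$region[["row0"]], x$region[["row1"]],
              x$region[["col0"]], x$region[["col1"]]))
  invisible(x)
}

#' Cell rectangle lookup
#'
#' @param grid an `lfa_grid`.
#' @param row,col 0-based grid row / strip column indices.
#' @return An [img_rect()] for that cell.
#' @export
grid_cell <- function(grid, row, col) {
  stopifnot(inherits(grid, "lfa_grid"))
  if (row < 0 || row >= grid$n_rows || col < 0 || col >= grid$n_strips)
    stop(sprintf("grid index (%d, %d) out of range %d x %d",
                 row, col, grid$n_rows, grid$n_strips), call. = FALSE)
  cl <- grid$cells[grid$cells$grid_row == row & grid$cells$grid_col == col, ]
  img_rect(cl$row0, cl$col0, cl$row1, cl$col1)
}

#' Pixel intensities of one grid cell
#'
#' @param img a 1-channel `lfa_image`.
#' @param grid an `lfa_grid`.
#' @param row,col 0-based grid indices.
#' @return Numeric vector of the cell's pixel intensities.
#' @export
cell_pixels <- function(img, grid, row, col) {
  stopifnot(is_lfa_image(img))
  if (n_channels(img) != 1L)
    stop("cell_pixels needs a single-channel image; convert with to_grayscale()",
         call. = FALSE)
  r <- grid_cell(grid, row, col)
  check_rect_in_image(r, img)
  as.vector(unclass(img)[(r[["row0"]] + 1L):r[["row1"]],
                         (r[["col0"]] + 1L):r[["col1"]], 1L])
}

#' Pixel intensities of one strip column
#'
#' Union of [cell_pixels()] over the rows of the requested role within
#' strip column `col`. With `roles = "background"` and L = 1 there are
#' no background rows and the result is empty.
#'
#' @param img a 1-channel `lfa_image`.
#' @param grid an `lfa_grid`.
#' @param col 0-based strip column.
#' @param roles `"all"`, `"line"` or `"background"`.
#' @return Numeric vector of intensities (possibly empty).
#' @export
strip_pixels <- function(img, grid, col, roles = c("all", "line", "background")) {
  roles <- match.arg(roles)
  rows <- seq_len(grid$n_rows) - 1L
  if (roles != "all") rows <- rows[grid$roles == roles]
  unlist(lapply(rows, function(r) cell_pixels(img, grid, r, col)),
         use.names = FALSE)
}
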