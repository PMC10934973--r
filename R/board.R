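#' Geometric model of the hole-pattern calibration target
#'
#' The target is a planar board with square through-holes centered in the
#' cells of a checkerboard-parity grid, and an optional solid plane mounted
#' behind it. Defaults describe an A4 board (297 mm x 210 mm) with a 6 x 6
#' grid of 20 mm holes in the cells where `(row + col)` is even (0-based),
#' giving 18 holes, and a solid plane 100 mm behind. Rows run along the short
#' side (y), columns along the long side (x); the board's local frame has the
#' front plane at `z = 0` centered on the origin, with the back plane at
#' `z = back_offset` (farther from the camera).
#'
#' @param width board long side, mm.
#' @param height board short side, mm.
#' @param n_rows,n_cols grid dimensions (rows along the short side).
#' @param hole_size hole edge length, mm; must be smaller than a grid cell.
#' @param hole_parity `"even"` or `"odd"`: which checkerboard parity
#'   (0-based `row + col`) carries holes.
#' @param back_offset distance of the solid back plane behind the front
#'   plane, mm (> 0).
#' @param back_plane_present logical; whether the solid back plane is part of
#'   the target.
#' @return An object of class `board_spec`.
#' @examples
#' spec <- board_spec()
#' nrow(hole_centers(spec))  # 18
#' @export
board_spec <- function(width = 297, height = 210, n_rows = 6, n_cols = 6,
                       hole_size = 20, hole_parity = c("even", "odd"),
                       back_offset = 100, back_plane_present = FALSE) {
  hole_parity <- match.arg(hole_parity)
  for (nm in c("width", "height", "hole_size", "back_offset")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0)
      abort_parameter(sprintf("%s must be a positive number", nm))
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    abort_parameter("n_rows and n_cols must be >= 1")
  if (hole_size >= width / n_cols || hole_size >= height / n_rows)
    abort_parameter("hole_size must be smaller than one grid cell")
  structure(list(width = width, height = height, n_rows = n_rows,
                 n_cols = n_cols, hole_size = hole_size,
                 hole_parity = hole_parity, back_offset = back_offset,
                 back_plane_present = isTRUE(back_plane_present)),
            class = "board_spec")
}

#' @export
print.board_spec <- function(x, ...) {
  cat(sprintf(
    "<board_spec> %g x %g mm, %d x %d grid, %d holes of %g mm, back plane %s\n",
    x$width, x$height, x$n_rows, x$n_cols, nrow(hole_centers(x)),
    x$hole_size,
    if (x$back_plane_present) sprintf("at %g mm", x$back_offset) else "absent"))
  invisible(x)
}

# TRUE for cells that carry a hole, 1-based (row, col)
cell_has_hole <- function(spec, row, col) {
  p <- (row - 1L + col - 1L) %% 2L
  if (spec$hole_parity == "even") p == 0L else p == 1L
}

#' Nominal hole centers of a board
#'
#' Hole centers in the board's local frame, in canonical row-major order
#' (row 1..n_rows ascending y, columns ascending x within each row).
#'
#' @param spec a `board_spec`.
#' @return data.frame with columns `row`, `col`, `x`, `y` (mm; local frame,
#'   `z = 0`).
#' @export
hole_centers <- function(spec) {
  cw <- spec$width / spec$n_cols
  ch <- spec$height / spec$n_rows
  g <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  g <- g[cell_has_hole(spec, g$row, g$col), c("row", "col")]
  g <- g[order(g$row, g$col), ]
  rownames(g) <- NULL
  data.frame(row = g$row, col = g$col,
             x = -spec$width / 2 + (g$col - 0.5) * cw,
             y = -spec$height / 2 + (g$row - 0.5) * ch)
}

# Strictly-inside-a-hole predicate for local-frame (x, y); vectorized.
inside_hole <- function(spec, x, y) {
  cw <- spec$width / spec$n_cols
  ch <- spec$height / spec$n_rows
  col <- pmax(1L, pmin(spec$n_cols, floor((x + spec$width / 2) / cw) + 1L))
  row <- pmax(1L, pmin(spec$n_rows, floor((y + spec$height / 2) / ch) + 1L))
  cx <- -spec$width / 2 + (col - 0.5) * cw
  cy <- -spec$height / 2 + (row - 0.5) * ch
  cell_has_hole(spec, row, col) &
    abs(x - cx) < spec$hole_size / 2 &
    abs(y - cy) < spec$hole_size / 2
}
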