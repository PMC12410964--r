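#' Compute the chamber crop grid for an arena
#'
#' Divides the camera frame into \code{rows x cols} crop rectangles after
#' removing outer margins and inter-chamber gaps. Cell widths within a row
#' (and heights within a column) differ by at most 1 px: the remainder
#' pixels of the integer division are assigned to the lowest-index columns
#' (left-to-right) and rows (top-to-bottom), deterministically. With zero
#' margins and gaps the rectangles tile the frame exactly.
#'
#' @param layout an [ArenaLayout-class].
#' @return A data.frame (crop manifest) with columns \code{chamber_id},
#'   \code{row}, \code{col} (0-based grid indices), \code{x0}, \code{y0}
#'   (top-left, 0-based pixels), \code{width}, \code{height}, in row-major
#'   order.
#' @examples
#' computeCropGrid(ArenaLayout(100, 100, rows = 2, cols = 2))
#' @export
computeCropGrid <- function(layout) {
  validObject(layout)
  usableW <- layout@frameWidth - 2 * layout@marginX -
    (layout@cols - 1L) * layout@gapX
  usableH <- layout@frameHeight - 2 * layout@marginY -
    (layout@rows - 1L) * layout@gapY
  if (usableW < layout@cols || usableH < layout@rows)
    stop("invalid layout: usable area (frame minus margins and gaps) ",
         "leaves no room for ", layout@rows, "x", layout@cols, " chambers")
  widths <- .splitEven(usableW, layout@cols)
  heights <- .splitEven(usableH, layout@rows)
  x0 <- layout@marginX + c(0, cumsum(widths[-layout@cols])) +
    (seq_len(layout@cols) - 1L) * layout@gapX
  y0 <- layout@marginY + c(0, cumsum(heights[-layout@rows])) +
    (seq_len(layout@rows) - 1L) * layout@gapY
  grid <- expand.grid(col = seq_len(layout@cols) - 1L,
                      row = seq_len(layout@rows) - 1L)
  data.frame(
    chamber_id = sprintf("chamber_%02d", seq_len(nrow(grid))),
    row = grid$row, col = grid$col,
    x0 = x0[grid$col + 1L], y0 = y0[grid$row + 1L],
    width = widths[grid$col + 1L], height = heights[grid$row + 1L],
    stringsAsFactors = FALSE
  )
}

# integer split of `total` px into `n` parts differing by <= 1, remainder
# to the lowest indices
.splitEven <- function(total, n) {
  base <- total %/% n
  rem <- total %% n
  base + as.numeric(seq_len(n) <= rem)
}

#' Write a crop manifest CSV
#'
#' Exports the crop grid in a form consumable by external video-cropping
#' tools (one row per chamber: \code{chamber_id,row,col,x0,y0,width,height}).
#'
#' @param grid the data.frame returned by [computeCropGrid()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCropManifest <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Point-in-chamber predicate
#'
#' Tests whether points lie inside the chamber rectangle. Intervals are
#' half-open: the minimum edge is inside, the maximum edge is outside.
#'
#' @param geom a [ChamberGeometry-class].
#' @param x,y pixel coordinates (vectorised).
#' @return Logical vector.
#' @export
containsPoint <- function(geom, x, y) {
  x >= geom@xMin & x < geom@xMax & y >= geom@yMin & y < geom@yMax
}

#' Which side of the virtual midline a point lies on
#'
#' Returns -1 for the low side of the chamber midline along the long axis
#' and +1 for the high side. A point exactly on the midline keeps the side
#' given in \code{prevSide} (hysteresis, so grazing the line does not
#' register a crossing when evaluated in sequence); standalone queries
#' (\code{prevSide = NULL}) resolve ties to -1.
#'
#' @param geom a [ChamberGeometry-class].
#' @param x,y pixel coordinates of a single point inside the chamber.
#' @param prevSide previously held side (-1 or +1), or NULL.
#' @return -1 or +1.
#' @export
midlineSide <- function(geom, x, y, prevSide = NULL) {
  if (!containsPoint(geom, x, y))
    stop("point (", x, ", ", y, ") is outside the chamber")
  coordAlong <- if (geom@longAxis == "horizontal") x else y
  if (coordAlong < geom@midline) return(-1)
  if (coordAlong > geom@midline) return(+1)
  if (is.null(prevSide)) -1 else prevSide
}

# held-side sequence with the hysteresis tie rule, vectorised;
# first-frame ties resolve to -1
.heldSides <- function(coordAlong, midline) {
  s <- sign(coordAlong - midline)
  if (!length(s)) return(s)
  if (s[1L] == 0) s[1L] <- -1
  if (any(s == 0)) {
    # carry the last nonzero side forward over exact-midline frames
    idx <- seq_along(s)
    idx[s == 0] <- 0L
    s <- s[cummax(idx)]
  }
  s
}

#' Standard chamber geometries
#'
#' Convenience constructors for the two chamber formats used throughout:
#' the locomotion chamber (23 x 15 mm, food wall at the low end of the
#' long axis) and the two-choice food-preference chamber (50 x 10 mm, one
#' food at each extremity of the long axis). Both use a default scale of
#' 5 px/mm (0.2 mm/px) and a horizontal long axis with the midline at the
#' chamber centre.
#'
#' @param pxPerMm pixel scale (default 5).
#' @return A [ChamberGeometry-class].
#' @export
locomotionChamber <- function(pxPerMm = 5) {
  ChamberGeometry(
    xMin = 0, yMin = 0, xMax = 23 * pxPerMm, yMax = 15 * pxPerMm,
    foodRegions = list(food = c(0, 2 * pxPerMm)),
    mmPerPx = 1 / pxPerMm
  )
}

#' @rdname locomotionChamber
#' @export
preferenceChamber <- function(pxPerMm = 5) {
  ChamberGeometry(
    xMin = 0, yMin = 0, xMax = 50 * pxPerMm, yMax = 10 * pxPerMm,
    foodRegions = list(sugar = c(0, 3 * pxPerMm),
                       yeast = c(47 * pxPerMm, 50 * pxPerMm)),
    mmPerPx = 1 / pxPerMm
  )
}
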