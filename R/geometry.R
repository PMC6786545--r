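# Pixel grids, outline polygons and scanline rasterization.
#
# Coordinate convention used throughout the package: pixel indices are
# 0-based, and the centre of pixel (row r, col c) sits at continuous
# coordinates (x = c + 0.5, y = r + 0.5). Masks are stored as logical
# matrices indexed [row, col] in the usual R 1-based way.

#' Define an image grid
#'
#' An `image_grid` is the pixel lattice that masks live on: a height and a
#' width in pixels, plus optional physical pixel spacing carried as metadata.
#' All geometry in the package is computed in pixel units; `pixel_spacing`
#' is never used in any computation, it simply travels with the grid so that
#' physical provenance (e.g. an MR in-slice resolution in mm) is not lost.
#'
#' @param height Number of pixel rows (positive integer).
#' @param width Number of pixel columns (positive integer).
#' @param pixel_spacing Optional numeric pair `(row, col)` of mm per pixel;
#'   both components must be positive.
#'
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(96, 96, pixel_spacing = c(0.49, 0.49))
#' @export
image_grid <- function(height, width, pixel_spacing = NULL) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (length(height) != 1L || is.na(height) || height < 1L)
    stop("`height` must be a single positive integer")
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("`width` must be a single positive integer")
  if (!is.null(pixel_spacing)) {
    pixel_spacing <- as.numeric(pixel_spacing)
    if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
        any(pixel_spacing <= 0))
      stop("`pixel_spacing` must be two positive numbers (row, col)")
  }
  structure(list(height = height, width = width,
                 pixel_spacing = pixel_spacing),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  sp <- if (is.null(x$pixel_spacing)) "unspecified"
        else paste0(format(x$pixel_spacing), " mm", collapse = " x ")
  cat("<image_grid> ", x$height, " x ", x$width,
      " px (spacing ", sp, ")\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  a$height == b$height && a$width == b$width
}

#' Coerce to an outline polygon
#'
#' A polygon is an ordered sequence of at least three `(x, y)` vertices in
#' image coordinates, implicitly closed (the last vertex connects back to
#' the first). Accepts a two-column matrix or a data frame with columns
#' `x` and `y`.
#'
#' @param x Two-column numeric matrix, or data frame with columns `x`, `y`.
#' @return A two-column numeric matrix with columns `x`, `y`.
#' @export
as_polygon <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x)))
      stop("polygon data frame needs columns `x` and `y`")
    x <- cbind(x = as.numeric(x$x), y = as.numeric(x$y))
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stop("a polygon must be a two-column (x, y) matrix")
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y")
  if (nrow(x) < 3L)
    stop("degenerate polygon: fewer than 3 points")
  if (any(!is.finite(x)))
    stop("polygon contains non-finite coordinates")
  x
}

# All vertices (numerically) on one line, including the all-identical case.
polygon_is_collinear <- function(p, tol = 1e-9) {
  v1 <- p[2L, ] - p[1L, ]
  cross <- (p[, 1] - p[1L, 1]) * v1[2L] - (p[, 2] - p[1L, 2]) * v1[1L]
  scale <- max(1, max(abs(p)))
  all(abs(cross) < tol * scale)
}

new_binary_mask <- function(pixels, grid) {
  structure(list(grid = grid, pixels = pixels), class = "binary_mask")
}

#' Construct a binary mask from a logical matrix
#'
#' @param pixels Logical (or 0/1) matrix with `grid$height` rows and
#'   `grid$width` columns; `TRUE` marks segment pixels.
#' @param grid An [image_grid()] the matrix must match exactly.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(pixels, grid) {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (any(is.na(pixels))) stop("mask pixels must not be NA")
  if (nrow(pixels) != grid$height || ncol(pixels) != grid$width)
    stop("mask dimensions do not match the grid")
  new_binary_mask(pixels, grid)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", x$grid$height, " x ", x$grid$width,
      " px, area ", mask_area(x), "\n", sep = "")
  invisible(x)
}

#' Number of segment pixels in a mask
#'
#' @param mask A `binary_mask`.
#' @return Integer pixel count.
#' @export
mask_area <- function(mask) {
  sum(mask$pixels)
}

#' Rasterize a polygon outline to a binary mask
#'
#' Scanline fill under the even-odd rule: a pixel is on iff its centre
#' `(c + 0.5, r + 0.5)` lies strictly inside the polygon. For each pixel
#' row the crossings of the polygon edges with the horizontal line through
#' the pixel centres are collected and pixels between odd/even crossing
#' pairs are filled. Edges are treated half-open in y (an edge covers
#' `[min(y), max(y))`), so a scanline passing exactly through a shared
#' vertex is counted once, and adjacent polygons tile the plane without
#' double cover. A centre lying exactly on an edge is not inside (strict
#' interior). Polygon parts outside the grid are clipped. Self-intersecting
#' polygons are accepted and filled under even-odd semantics.
#'
#' @param poly A polygon acceptable to [as_polygon()].
#' @param grid An [image_grid()].
#' @return A `binary_mask` on `grid`. A polygon whose vertices are all
#'   collinear (zero area) yields an empty mask with a warning; fewer than
#'   three vertices is an error.
#' @examples
#' g <- image_grid(6, 6)
#' sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
#' mask_area(rasterize_polygon(sq, g)) # 16
#' @export
rasterize_polygon <- function(poly, grid) {
  poly <- as_polygon(poly)
  h <- grid$height
  w <- grid$width
  px <- matrix(FALSE, h, w)
  if (polygon_is_collinear(poly)) {
    warning("degenerate polygon (all vertices collinear); returning empty mask")
    return(new_binary_mask(px, grid))
  }
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  keep <- y1 != y2          # horizontal edges never cross a scanline
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (length(x1) == 0L) return(new_binary_mask(px, grid))
  ylo <- pmin(y1, y2)
  yhi <- pmax(y1, y2)
  r0 <- max(0L, as.integer(ceiling(min(ylo) - 0.5)))
  r1 <- min(h - 1L, as.integer(floor(max(yhi) - 0.5)))
  if (r0 > r1) return(new_binary_mask(px, grid))
  xc <- seq_len(w) - 0.5
  dxdy <- (x2 - x1) / (y2 - y1)
  for (r in r0:r1) {
    yc <- r + 0.5
    cr <- ylo <= yc & yc < yhi
    if (!any(cr)) next
    xs <- sort(x1[cr] + dxdy[cr] * (yc - y1[cr]))
    # inside iff an odd number of crossings lie strictly to the right
    px[r + 1L, ] <- (length(xs) - findInterval(xc, xs)) %% 2L == 1L
  }
  new_binary_mask(px, grid)
}

#' Create an outline record
#'
#' One annotator's outline(s) for one image: at least one polygon region,
#' plus annotator / image identity and an optional session number. Multiple
#' regions are merged by set union at rasterization time ([rasterize_record()]).
#'
#' @param annotator_id,image_id Identifiers (coerced to character).
#' @param regions A list of polygons acceptable to [as_polygon()], or a
#'   single polygon.
#' @param session Positive integer session number, or `NA` if unknown.
#' @return An object of class `outline_record`.
#' @export
outline_record <- function(annotator_id, image_id, regions, session = NA_integer_) {
  if (!is.list(regions) || is.data.frame(regions)) regions <- list(regions)
  if (length(regions) < 1L) stop("an outline record needs at least one region")
  regions <- lapply(regions, as_polygon)
  session <- as.integer(session)
  if (!is.na(session) && session < 1L)
    stop("`session` must be a positive integer or NA")
  structure(list(annotator_id = as.character(annotator_id),
                 image_id = as.character(image_id),
                 session = session,
                 regions = regions),
            class = "outline_record")
}

#' @export
print.outline_record <- function(x, ...) {
  cat("<outline_record> annotator ", x$annotator_id, ", image ", x$image_id,
      ", session ", ifelse(is.na(x$session), "?", x$session), ", ",
      length(x$regions), " region(s)\n", sep = "")
  invisible(x)
}

#' Rasterize all regions of an outline record
#'
#' Each region polygon is rasterized with [rasterize_polygon()] and the
#' results are combined by set union, so overlapping regions merge rather
#' than punch holes.
#'
#' @param rec An [outline_record()].
#' @param grid An [image_grid()].
#' @return A `binary_mask`. If every region of the record is degenerate
#'   (zero area) this is an error; individual degenerate regions among
#'   valid ones only warn.
#' @export
rasterize_record <- function(rec, grid) {
  if (!inherits(rec, "outline_record")) stop("`rec` must be an outline_record")
  masks <- lapply(rec$regions, rasterize_polygon, grid = grid)
  px <- Reduce(`|`, lapply(masks, `[[`, "pixels"))
  degenerate <- vapply(rec$regions, polygon_is_collinear, logical(1))
  if (all(degenerate))
    stop("all regions of record (", rec$annotator_id, ", ", rec$image_id,
         ") are degenerate")
  new_binary_mask(px, grid)
}
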