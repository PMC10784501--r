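#' Axis-aligned bounding box
#'
#' Boxes use 0-based pixel coordinates with origin at the top-left corner and
#' the half-open convention `[x, x + w) x [y, y + h)`, so the discrete area of
#' a box is exactly `w * h` pixels and box IoU agrees with the pixel-set IoU
#' of a rectangular mask covering the same extent.
#'
#' @param x,y left edge and top edge in pixels.
#' @param w,h width and height in pixels; both must be positive.
#' @return A numeric vector `c(x, y, w, h)` of class `"bbox"`.
#' @export
#' @examples
#' bbox(0, 0, 10, 20)
bbox <- function(x, y, w, h) {
  assert_that(is_number(x) && is_number(y) && is_number(w) && is_number(h),
              "bbox coordinates must be finite numbers")
  assert_that(w > 0 && h > 0, "bbox width and height must be positive")
  structure(c(x = x, y = y, w = w, h = h), class = "bbox")
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  assert_that(is.numeric(b) && length(b) == 4L, "expected a length-4 box")
  bbox(b[[1]], b[[2]], b[[3]], b[[4]])
}

#' Polygonal instance mask
#'
#' A mask is a list of one or more rings, each an ordered matrix of (x, y)
#' vertices in pixels. Rings are combined by the even-odd rule, so additional
#' rings may encode holes or disjoint parts. Rasterization assigns a pixel to
#' the mask iff its center lies inside (even-odd crossing count), which
#' decides every boundary pixel deterministically.
#'
#' @param rings a list of numeric matrices with two columns (x, y) and at
#'   least three rows, or a single such matrix.
#' @return An object of class `"mask_poly"`.
#' @export
#' @examples
#' m <- mask_poly(rect_ring(0, 0, 10, 10))
mask_poly <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  assert_that(is.list(rings) && length(rings) >= 1L,
              "mask must have at least one ring")
  for (r in rings) {
    assert_that(is.matrix(r) && ncol(r) == 2L && nrow(r) >= 3L,
                "each mask ring must be a k x 2 matrix with k >= 3 vertices")
    assert_that(all(is.finite(r)), "mask vertices must be finite")
  }
  structure(lapply(rings, function(r) {
    r <- unname(as.matrix(r)); storage.mode(r) <- "double"; r
  }), class = "mask_poly")
}

as_mask_poly <- function(m) {
  if (inherits(m, "mask_poly")) return(m)
  mask_poly(m)
}

#' Rectangle ring helper
#'
#' Convenience constructor for the counter-clockwise ring of the half-open
#' rectangle `[x, x + w) x [y, y + h)`; rasterizing [mask_poly()] of this ring
#' yields exactly the pixels of the equally-sized [bbox()].
#'
#' @inheritParams bbox
#' @return A 4 x 2 vertex matrix.
#' @export
rect_ring <- function(x, y, w, h) {
  cbind(c(x, x + w, x + w, x), c(y, y, y + h, y + h))
}

#' Intersection over union of two boxes
#'
#' Overlap ratio under the half-open pixel convention: intersection area over
#' union area. Symmetric, in `[0, 1]`, and equal to the pixel-set IoU of the
#' corresponding rectangular masks.
#'
#' @param a,b boxes ([bbox()] or length-4 numeric `c(x, y, w, h)`).
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' bbox_iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10))  # 1/3
bbox_iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  iw <- min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1])
  ih <- min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  unname(inter / (a[3] * a[4] + b[3] * b[4] - inter))
}

#' Pairwise IoU matrix of two box sets
#'
#' @param A,B numeric matrices with columns (x, y, w, h); one box per row.
#' @return An `nrow(A)` x `nrow(B)` matrix of IoU values.
#' @export
bbox_iou_matrix <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 4)
  B <- matrix(as.numeric(B), ncol = 4)
  n <- nrow(A); m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  iw <- outer(A[, 1] + A[, 3], B[, 1] + B[, 3], pmin) -
    outer(A[, 1], B[, 1], pmax)
  ih <- outer(A[, 2] + A[, 4], B[, 2] + B[, 4], pmin) -
    outer(A[, 2], B[, 2], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  uni <- outer(A[, 3] * A[, 4], B[, 3] * B[, 4], `+`) - inter
  iou <- inter / uni
  iou[uni <= 0] <- 0
  iou
}

#' Pixel-set IoU of two polygon masks
#'
#' Both masks are rasterized at the frame size under the pixel-center
#' even-odd rule and the IoU of the two pixel sets is returned. An empty
#' union is defined as IoU 0.
#'
#' @param a,b masks ([mask_poly()] or ring list/matrix).
#' @param frame_size integer `c(width, height)` in pixels.
#' @return A fraction in `[0, 1]`; 1 iff the rasterizations are equal.
#' @export
mask_iou <- function(a, b, frame_size) {
  a <- as_mask_poly(a); b <- as_mask_poly(b)
  assert_that(length(frame_size) == 2L && all(frame_size >= 1),
              "frame_size must be c(width, height)")
  cpp_mask_iou(unclass(a), unclass(b),
               as.integer(frame_size[1]), as.integer(frame_size[2]))
}

# intersection pixel count and areas: c(inter, areaA, areaB)
mask_overlap <- function(a, b, frame_size) {
  cpp_mask_overlap(unclass(as_mask_poly(a)), unclass(as_mask_poly(b)),
                   as.integer(frame_size[1]), as.integer(frame_size[2]))
}

#' Rasterize a polygon mask to a logical matrix
#'
#' @inheritParams mask_iou
#' @param mask a [mask_poly()].
#' @return A logical matrix with `frame_size[2]` rows (image rows) and
#'   `frame_size[1]` columns; `[i, j]` is pixel (x = j - 1, y = i - 1).
#' @export
rasterize_mask <- function(mask, frame_size) {
  mask <- as_mask_poly(mask)
  W <- as.integer(frame_size[1]); H <- as.integer(frame_size[2])
  idx <- cpp_poly_pixels(unclass(mask), W, H)
  out <- matrix(FALSE, nrow = H, ncol = W)
  # linear index ix + iy*W -> row iy+1, col ix+1
  out[cbind(idx %/% W + 1L, idx %% W + 1L)] <- TRUE
  out
}

# tight bounds of the frame-clipped raster as a bbox (+ pixel count attr)
mask_tight_bbox <- function(mask, frame_w, frame_h) {
  b <- cpp_mask_bounds(unclass(as_mask_poly(mask)),
                       as.integer(frame_w), as.integer(frame_h))
  if (b[5] == 0) return(NULL)
  out <- bbox(b[1], b[2], b[3] - b[1] + 1, b[4] - b[2] + 1)
  attr(out, "pixels") <- b[5]
  out
}

# translate / scale mask rings (about a fixed point)
shift_mask <- function(mask, dx, dy) {
  mask_poly(lapply(unclass(as_mask_poly(mask)), function(r) {
    r[, 1] <- r[, 1] + dx; r[, 2] <- r[, 2] + dy; r
  }))
}

scale_mask <- function(mask, factor, center) {
  mask_poly(lapply(unclass(as_mask_poly(mask)), function(r) {
    r[, 1] <- center[1] + (r[, 1] - center[1]) * factor
    r[, 2] <- center[2] + (r[, 2] - center[2]) * factor
    r
  }))
}
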