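# COCO-dialect readers/writers, MOTChallenge export, letterbox transforms.
#
# The dialect: a JSON object with `images` (id, width, height, file_name),
# `categories` (single category "b"), `annotations` carrying `bbox`
# [x, y, w, h], `segmentation` (list of flat polygon rings, or an
# uncompressed RLE object on read), plus `score` for detections and
# `instance_id` for ground truth / tracking output. An `info` block records
# fps. Image ids are 1-based; frame index = image id - 1.

coco_skeleton <- function(seq) {
  nf <- n_frames(seq)
  list(
    info = list(fps = seq_fps(seq), frame_w = frame_width(seq),
                frame_h = frame_height(seq), n_frames = nf),
    images = lapply(seq_len(nf), function(i) list(
      id = i, width = frame_width(seq), height = frame_height(seq),
      file_name = sprintf("frame_%06d.png", i - 1L))),
    categories = list(list(id = 1L, name = "b"))
  )
}

mask_to_segmentation <- function(mask) {
  lapply(unclass(as_mask_poly(mask)), function(r) as.numeric(t(r)))
}

# uncompressed COCO RLE (column-major runs, counts alternating background/
# foreground) -> one 1-px-wide rectangle ring per foreground run; even-odd
# rasterization of those rings reproduces the pixel set exactly
rle_to_rings <- function(counts, size) {
  h <- size[[1]]; w <- size[[2]]
  counts <- as.numeric(counts)
  pos <- 0
  rings <- list()
  fg <- FALSE
  for (cnt in counts) {
    if (fg && cnt > 0) {
      first <- pos; last <- pos + cnt - 1
      cols <- (first %/% h):(last %/% h)
      for (cc in cols) {
        y1 <- if (cc == cols[1]) first %% h else 0
        y2 <- if (cc == cols[length(cols)]) last %% h else h - 1
        rings[[length(rings) + 1L]] <- rect_ring(cc, y1, 1, y2 - y1 + 1)
      }
    }
    pos <- pos + cnt
    fg <- !fg
  }
  rings
}

segmentation_to_mask <- function(seg, ann_id) {
  if (is.list(seg) && !is.null(seg$counts)) {
    rings <- rle_to_rings(seg$counts, unlist(seg$size))
    if (length(rings) == 0)
      stop("annotation ", ann_id, ": empty RLE segmentation", call. = FALSE)
    return(mask_poly(rings))
  }
  if (!is.list(seg)) seg <- list(seg)
  rings <- lapply(seg, function(flat) {
    flat <- as.numeric(unlist(flat))
    if (length(flat) < 6 || length(flat) %% 2 != 0)
      stop("annotation ", ann_id,
           ": polygon ring must have at least 3 (x, y) vertex pairs",
           call. = FALSE)
    matrix(flat, ncol = 2, byrow = TRUE)
  })
  mask_poly(rings)
}

read_coco <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  assert_that(!is.null(doc$images) && !is.null(doc$annotations),
              paste(path, "is not a COCO-dialect annotation file"))
  doc
}

coco_common <- function(doc) {
  ids <- vapply(doc$images, function(im) as.integer(im$id), integer(1))
  ord <- order(ids)
  w <- as.integer(doc$images[[ord[1]]]$width)
  h <- as.integer(doc$images[[ord[1]]]$height)
  fps <- doc$info$fps %||% 1
  list(n_frames = length(ids), frame_w = w, frame_h = h, fps = fps,
       frame_of = setNames(seq_along(ord) - 1L, ids[ord]))
}

parse_annotations <- function(doc, meta, want_score, want_id) {
  anns <- doc$annotations
  n <- length(anns)
  out <- data.frame(frame = integer(n), x = numeric(n), y = numeric(n),
                    w = numeric(n), h = numeric(n))
  score <- numeric(n); iid <- integer(n); label <- character(n)
  masks <- vector("list", n)
  cat_name <- setNames(
    vapply(doc$categories, function(ct) as.character(ct$name), character(1)),
    vapply(doc$categories, function(ct) as.character(ct$id), character(1)))
  for (i in seq_len(n)) {
    a <- anns[[i]]
    aid <- a$id %||% i
    img <- as.character(a$image_id)
    if (is.na(meta$frame_of[img]))
      stop("annotation ", aid, ": unknown image_id ", img, call. = FALSE)
    out$frame[i] <- meta$frame_of[[img]]
    bb <- as.numeric(unlist(a$bbox))
    if (length(bb) != 4 || any(!is.finite(bb)) || bb[3] <= 0 || bb[4] <= 0)
      stop("annotation ", aid, ": malformed bbox", call. = FALSE)
    out$x[i] <- bb[1]; out$y[i] <- bb[2]; out$w[i] <- bb[3]; out$h[i] <- bb[4]
    masks[[i]] <- segmentation_to_mask(a$segmentation, aid)
    label[i] <- cat_name[[as.character(a$category_id %||% 1)]] %||% "b"
    if (want_score) {
      if (is.null(a$score))
        stop("annotation ", aid, ": detection without a score", call. = FALSE)
      score[i] <- as.numeric(a$score)
    }
    if (want_id) {
      id <- a$instance_id %||% a$track_id %||% a$attributes$track_id
      if (is.null(id))
        stop("annotation ", aid, ": missing instance/track identifier",
             call. = FALSE)
      iid[i] <- as.integer(id)
    }
  }
  out$label <- label
  if (want_score) out$score <- score
  if (want_id) out$instance_id <- iid
  out$mask <- masks
  out
}

#' Read ground-truth annotations from a COCO-dialect file
#'
#' Every annotation becomes one object with frame index, persistent instance
#' id, bounding box and mask polygon; image dimensions and frame rate are
#' taken from the `images` and `info` blocks. Malformed records raise an
#' error naming the offending annotation; duplicated `(frame, instance_id)`
#' pairs are a validation error.
#'
#' @param path path to a COCO-dialect JSON file.
#' @return A [gt_sequence()].
#' @export
read_coco_ground_truth <- function(path) {
  doc <- read_coco(path)
  meta <- coco_common(doc)
  objects <- parse_annotations(doc, meta, want_score = FALSE, want_id = TRUE)
  gt_sequence(objects, meta$fps, meta$frame_w, meta$frame_h, meta$n_frames)
}

#' Read detections from a COCO-dialect file
#'
#' @inheritParams read_coco_ground_truth
#' @return A [det_sequence()].
#' @export
read_coco_detections <- function(path) {
  doc <- read_coco(path)
  meta <- coco_common(doc)
  objects <- parse_annotations(doc, meta, want_score = TRUE, want_id = FALSE)
  det_sequence(objects, meta$fps, meta$frame_w, meta$frame_h, meta$n_frames)
}

#' Read a tracking result from a COCO-dialect file
#'
#' @inheritParams read_coco_ground_truth
#' @return A [tracking_result()].
#' @export
read_coco_tracking <- function(path) {
  doc <- read_coco(path)
  meta <- coco_common(doc)
  objects <- parse_annotations(doc, meta, want_score = TRUE, want_id = TRUE)
  objects$track_id <- objects$instance_id
  tracking_result(objects, meta$fps, meta$frame_w, meta$frame_h,
                  meta$n_frames)
}

#' Write a sequence to a COCO-dialect file
#'
#' Ground truth and tracking results carry `instance_id`; detections and
#' tracking results carry `score`. Masks are always written as polygons.
#'
#' @param seq a [det_sequence()], [gt_sequence()] or [tracking_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(seq, path) {
  doc <- coco_skeleton(seq)
  objs <- as.data.frame(seq)
  doc$annotations <- lapply(seq_len(nrow(objs)), function(i) {
    o <- objs[i, ]
    ann <- list(id = i, image_id = o$frame + 1L, category_id = 1L,
                bbox = c(o$x, o$y, o$w, o$h),
                area = o$w * o$h,
                segmentation = mask_to_segmentation(o$mask[[1]]))
    if (!is.null(objs$score)) ann$score <- o$score
    if (!is.null(objs$instance_id)) ann$instance_id <- o$instance_id
    if (!is.null(objs$track_id)) ann$instance_id <- o$track_id
    ann
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a tracking result as MOTChallenge text
#'
#' One row per output: `frame, id, bb_left, bb_top, bb_width, bb_height,
#' conf, -1, -1, -1`. Frame numbers are 1-based in this export only, per that
#' format's convention.
#'
#' @param res a [tracking_result()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motchallenge <- function(res, path) {
  assert_that(inherits(res, "tracking_result"),
              "res must be a tracking_result")
  objs <- as.data.frame(res)
  rows <- data.frame(frame = objs$frame + 1L, id = objs$track_id,
                     bb_left = objs$x, bb_top = objs$y,
                     bb_width = objs$w, bb_height = objs$h,
                     conf = objs$score, a = -1, b = -1, c = -1)
  write.table(rows, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Letterbox specification
#'
#' Describes the resize used to feed 1920x1080 frames to a square detector
#' input (512x512 by default): pad the rectangle to a square with zeros, then
#' scale by `model_size / max(src_w, src_h)`. Padding defaults to the
#' bottom/right (pad_top = pad_left = 0) so original coordinates are
#' unchanged before scaling; other conventions are recoverable by setting the
#' pad fields.
#'
#' @param src_w,src_h source frame size in pixels.
#' @param model_size square model input side in pixels.
#' @param pad_top,pad_left padding placed above/left of the source image, in
#'   source pixels; must be nonnegative and leave the padded image inside the
#'   square.
#' @return A `letterbox_spec` object.
#' @export
letterbox_spec <- function(src_w, src_h, model_size = 512,
                           pad_top = 0, pad_left = 0) {
  assert_that(is_count(src_w, 1) && is_count(src_h, 1) &&
                is_count(model_size, 1), "sizes must be positive integers")
  side <- max(src_w, src_h)
  scale <- model_size / side
  assert_that(scale > 0, "letterbox scale must be positive")
  assert_that(pad_top >= 0 && pad_left >= 0 &&
                pad_top + src_h <= side && pad_left + src_w <= side,
              "padding must be nonnegative and fit inside the square")
  structure(list(src_w = src_w, src_h = src_h, model_size = model_size,
                 pad_top = pad_top, pad_left = pad_left, scale = scale),
            class = "letterbox_spec")
}

#' Transform coordinates between original and model resolution
#'
#' `to_model_coords()` maps original-frame coordinates into the letterboxed
#' square model input (`out = (in + pad) * scale`); `from_model_coords()` is
#' its exact inverse. Both are affine, so containment and the IoU of any two
#' boxes are preserved exactly. Inputs may be a point matrix (n x 2), a
#' [bbox()] or a [mask_poly()].
#'
#' @param p a two-column point matrix (or length-2 vector), [bbox()] or
#'   [mask_poly()].
#' @param spec a [letterbox_spec()].
#' @return The same kind of object in the other coordinate system.
#' @export
to_model_coords <- function(p, spec) {
  assert_that(inherits(spec, "letterbox_spec"), "spec must be letterbox_spec")
  transform_coords(p, spec$scale, spec$pad_left, spec$pad_top)
}

#' @rdname to_model_coords
#' @export
from_model_coords <- function(p, spec) {
  assert_that(inherits(spec, "letterbox_spec"), "spec must be letterbox_spec")
  transform_coords(p, 1 / spec$scale, -spec$pad_left * spec$scale,
                   -spec$pad_top * spec$scale)
}

# out = (in + c(px, py)) * s for points; boxes scale w/h without offset
transform_coords <- function(p, s, px, py) {
  if (inherits(p, "bbox")) {
    return(bbox((p[[1]] + px) * s, (p[[2]] + py) * s, p[[3]] * s, p[[4]] * s))
  }
  if (inherits(p, "mask_poly")) {
    return(mask_poly(lapply(unclass(p), function(r) {
      cbind((r[, 1] + px) * s, (r[, 2] + py) * s)
    })))
  }
  if (is.numeric(p) && is.null(dim(p)) && length(p) == 2L) {
    return(c((p[1] + px) * s, (p[2] + py) * s))
  }
  assert_that(is.matrix(p) && ncol(p) == 2L,
              "p must be a point, n x 2 matrix, bbox or mask_poly")
  cbind((p[, 1] + px) * s, (p[, 2] + py) * s)
}
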