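# Sequence containers. A sequence is a flat data.frame of per-object rows
# (one row per object per frame, frame indices 0-based) with a `mask` list
# column, carrying fps / frame size / frame count as attributes. Frames with
# no objects simply have no rows; `n_frames` keeps the true sequence length.

new_sequence <- function(objects, fps, frame_w, frame_h, n_frames, class) {
  assert_that(is.data.frame(objects), "objects must be a data.frame")
  assert_that(is_number(fps) && fps > 0, "fps must be a positive number")
  assert_that(is_count(frame_w, 1) && is_count(frame_h, 1),
              "frame dimensions must be positive integers")
  assert_that(is_count(n_frames, 0), "n_frames must be a nonnegative integer")
  if (nrow(objects) > 0) {
    assert_that(all(objects$frame >= 0 & objects$frame < n_frames),
                "frame indices must lie in [0, n_frames)")
    assert_that(all(objects$w > 0) && all(objects$h > 0),
                "all boxes must have positive width and height")
    objects$mask <- lapply(objects$mask, as_mask_poly)
    objects <- objects[order(objects$frame), , drop = FALSE]
    rownames(objects) <- NULL
  }
  structure(objects,
            fps = fps, frame_w = frame_w, frame_h = frame_h,
            n_frames = as.integer(n_frames),
            class = c(class, "bee_sequence", "data.frame"))
}

#' Detection sequence
#'
#' Container for per-frame detections-with-masks ("DetM" records): one row
#' per detection with bounding box, mask polygon, confidence score and
#' category label (`"b"` for bee bodies in this single-class system).
#'
#' @param objects data.frame with columns `frame` (0-based integer), `x`,
#'   `y`, `w`, `h` (pixels), `score` (in `[0, 1]`), `label` (character) and a
#'   list column `mask` of [mask_poly()] objects.
#' @param fps frame rate in frames/second.
#' @param frame_w,frame_h frame dimensions in pixels.
#' @param n_frames number of frames spanned (defaults to `max(frame) + 1`).
#' @return A `det_sequence` object.
#' @export
det_sequence <- function(objects, fps, frame_w, frame_h, n_frames = NULL) {
  need <- c("frame", "x", "y", "w", "h", "score", "label", "mask")
  assert_that(all(need %in% names(objects)),
              paste("detection objects need columns:",
                    paste(need, collapse = ", ")))
  if (nrow(objects) > 0)
    assert_that(all(objects$score >= 0 & objects$score <= 1),
                "detection scores must lie in [0, 1]")
  n_frames <- n_frames %||%
    (if (nrow(objects) > 0) max(objects$frame) + 1L else 0L)
  new_sequence(objects[need], fps, frame_w, frame_h, n_frames,
               "det_sequence")
}

#' Ground-truth sequence
#'
#' Like [det_sequence()] but each object carries a persistent
#' `instance_id` across frames instead of a score; within a frame instance
#' ids must be unique.
#'
#' @param objects data.frame with columns `frame`, `instance_id`, `x`, `y`,
#'   `w`, `h`, `label` and list column `mask`.
#' @inheritParams det_sequence
#' @return A `gt_sequence` object.
#' @export
gt_sequence <- function(objects, fps, frame_w, frame_h, n_frames = NULL) {
  need <- c("frame", "instance_id", "x", "y", "w", "h", "label", "mask")
  assert_that(all(need %in% names(objects)),
              paste("ground-truth objects need columns:",
                    paste(need, collapse = ", ")))
  if (nrow(objects) > 0) {
    key <- paste(objects$frame, objects$instance_id)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("duplicate (frame, instance_id): ", dup, call. = FALSE)
    }
  }
  n_frames <- n_frames %||%
    (if (nrow(objects) > 0) max(objects$frame) + 1L else 0L)
  new_sequence(objects[need], fps, frame_w, frame_h, n_frames,
               "gt_sequence")
}

#' Tracking result
#'
#' Per-frame tracker outputs: `(track_id, bbox, mask)` rows, where every mask
#' originated from a detection matched in that frame. Track ids are unique
#' within a frame.
#'
#' @param objects data.frame with columns `frame`, `track_id`, `x`, `y`, `w`,
#'   `h`, `score` and list column `mask`.
#' @inheritParams det_sequence
#' @return A `tracking_result` object.
#' @export
tracking_result <- function(objects, fps, frame_w, frame_h, n_frames = NULL) {
  need <- c("frame", "track_id", "x", "y", "w", "h", "score", "mask")
  assert_that(all(need %in% names(objects)),
              paste("tracking objects need columns:",
                    paste(need, collapse = ", ")))
  if (nrow(objects) > 0) {
    key <- paste(objects$frame, objects$track_id)
    assert_that(!anyDuplicated(key),
                "track ids must be unique within a frame")
  }
  n_frames <- n_frames %||%
    (if (nrow(objects) > 0) max(objects$frame) + 1L else 0L)
  new_sequence(objects[need], fps, frame_w, frame_h, n_frames,
               "tracking_result")
}

#' @export
print.bee_sequence <- function(x, ...) {
  cat(sprintf("<%s> %d objects over %d frames (%g fps, %dx%d px)\n",
              class(x)[1], nrow(x), n_frames(x), seq_fps(x),
              frame_width(x), frame_height(x)))
  if (nrow(x) > 0) {
    show <- as.data.frame(x)[seq_len(min(6L, nrow(x))),
                             setdiff(names(x), "mask")]
    print(show)
    if (nrow(x) > 6) cat("...\n")
  }
  invisible(x)
}

#' Sequence metadata accessors
#'
#' @param x a sequence (`det_sequence`, `gt_sequence` or `tracking_result`).
#' @return Frame count, frame rate, or frame dimensions.
#' @export
n_frames <- function(x) attr(x, "n_frames")

#' @rdname n_frames
#' @export
seq_fps <- function(x) attr(x, "fps")

#' @rdname n_frames
#' @export
frame_width <- function(x) attr(x, "frame_w")

#' @rdname n_frames
#' @export
frame_height <- function(x) attr(x, "frame_h")

# rows of frame f as a plain data.frame
frame_objects <- function(x, f) {
  as.data.frame(x)[x$frame == f, , drop = FALSE]
}

rebuild_sequence <- function(x, objects, fps = seq_fps(x), nf = n_frames(x)) {
  cls <- class(x)[1]
  fn <- switch(cls,
               det_sequence = det_sequence,
               gt_sequence = gt_sequence,
               tracking_result = tracking_result)
  fn(objects, fps, frame_width(x), frame_height(x), nf)
}

#' Filter detections by confidence score
#'
#' Keeps detections whose score is greater than or equal to `min_score` (the
#' stated minimum is accepted), preserving frame structure and metadata. The
#' default 0.7 is the detector operating point used throughout.
#'
#' @param dets a [det_sequence()].
#' @param min_score acceptance threshold in `[0, 1]`.
#' @return A filtered [det_sequence()].
#' @export
filter_by_score <- function(dets, min_score = 0.7) {
  assert_that(inherits(dets, "det_sequence"), "dets must be a det_sequence")
  assert_that(is_number(min_score) && min_score >= 0 && min_score <= 1,
              "min_score must lie in [0, 1]")
  keep <- as.data.frame(dets)[dets$score >= min_score, , drop = FALSE]
  rebuild_sequence(dets, keep)
}

#' Downsample a sequence to a lower frame rate
#'
#' Keeps frames `0, k, 2k, ...` with `k = fps / target_fps` (which must be a
#' whole number; no resampling or interpolation is performed), renumbers the
#' kept frames contiguously from 0, and records the original frame indices in
#' the `"original_frames"` attribute.
#'
#' @param seq a [det_sequence()] or [gt_sequence()].
#' @param target_fps target frame rate; must divide `seq_fps(seq)`.
#' @return A sequence of the same kind at `target_fps`.
#' @export
#' @examples
#' # 300 frames at 30 fps -> 100 frames at 10 fps
downsample_sequence <- function(seq, target_fps) {
  assert_that(inherits(seq, "bee_sequence"), "seq must be a sequence")
  assert_that(is_number(target_fps) && target_fps > 0,
              "target_fps must be positive")
  k <- seq_fps(seq) / target_fps
  if (abs(k - round(k)) > 1e-9)
    stop("fps ", seq_fps(seq), " is not divisible by target fps ",
         target_fps, "; resampling is not supported", call. = FALSE)
  k <- as.integer(round(k))
  old <- if (n_frames(seq) == 0L) integer(0) else
    seq.int(0L, n_frames(seq) - 1L, by = k)
  objects <- as.data.frame(seq)[seq$frame %% k == 0, , drop = FALSE]
  objects$frame <- objects$frame %/% k
  out <- rebuild_sequence(seq, objects, fps = target_fps, nf = length(old))
  attr(out, "original_frames") <- old
  out
}
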