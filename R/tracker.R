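# Tracking core: IoU-gated Hungarian association plus track lifecycle.
#
# Per frame: predict every live track, associate detections to predicted
# boxes by maximum total IoU, update matched tracks (attaching the matched
# detection's mask), open a new track for every unmatched detection,
# age unmatched tracks, and delete tracks unseen for more than t_lost frames.
# A deleted target that reappears receives a fresh id. Outputs carry the
# matched detection's box and mask; coasting (predicted-only) tracks emit no
# output row because the output mask must come from a detection.

#' Tracker configuration
#'
#' @param iou_min association gate: assigned pairs with IoU below this are
#'   demoted to unmatched on both sides (0.5, i.e. 50% overlap, by default).
#' @param t_lost number of consecutive undetected frames after which a track
#'   is terminated (a track missing for `t_lost + 1` frames is deleted).
#' @param min_hits matched-frame count a track needs before its outputs are
#'   reported (1 = every detection can open a reported track); tracks younger
#'   than `min_hits` frames are reported during warm-up.
#' @param association `"bbox"` (default; predicted box IoU, the fast SORT
#'   convention) or `"mask"` (pixel mask IoU between the detection mask and
#'   the last matched mask, box-gated).
#' @param p0,q,r Kalman covariance diagonals: initial state (7), process (7)
#'   and measurement (4) noise.
#' @return A `tracker_config` object.
#' @export
tracker_config <- function(iou_min = 0.5, t_lost = 1, min_hits = 1,
                           association = c("bbox", "mask"),
                           p0 = kf_default_p0, q = kf_default_q,
                           r = kf_default_r) {
  assert_that(is_number(iou_min) && iou_min > 0 && iou_min < 1,
              "iou_min must lie in (0, 1)")
  assert_that(is_count(t_lost, 1), "t_lost must be a positive integer")
  assert_that(is_count(min_hits, 1), "min_hits must be a positive integer")
  association <- match.arg(association)
  assert_that(length(p0) == 7 && length(q) == 7 && length(r) == 4 &&
                all(c(p0, q, r) > 0), "covariance diagonals must be positive")
  structure(list(iou_min = iou_min, t_lost = as.integer(t_lost),
                 min_hits = as.integer(min_hits), association = association,
                 p0 = p0, q = q, r = r),
            class = "tracker_config")
}

#' Solve a linear assignment problem
#'
#' Minimum-cost one-to-one assignment (Hungarian/Jonker-Volgenant); every row
#' of the smaller dimension is assigned. Deterministic: equal-cost optima are
#' resolved toward lower indices.
#'
#' @param cost a numeric cost matrix.
#' @return An integer vector of length `nrow(cost)`: the column assigned to
#'   each row, or `NA` for rows left unassigned (only when `nrow > ncol`).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  assert_that(all(is.finite(cost)), "cost matrix must be finite")
  if (n <= m) return(as.integer(cpp_hungarian(cost)))
  cols <- as.integer(cpp_hungarian(t(cost)))  # assign the smaller side
  out <- rep(NA_integer_, n)
  out[cols] <- seq_len(m)
  out
}

#' Associate detections with predicted tracks by maximum total IoU
#'
#' The assignment cost is `1 - IoU` between each detection and each predicted
#' track location; the Hungarian algorithm finds the assignment maximizing
#' total IoU. Assigned pairs with IoU below `iou_min` are demoted to
#' unmatched on both sides, so no emitted match overlaps less than the gate.
#'
#' @param dets detection boxes: an n x 4 matrix (x, y, w, h), or a
#'   precomputed n x m IoU matrix when `tracks` is `NULL`.
#' @param tracks predicted track boxes: an m x 4 matrix, or `NULL` when
#'   `dets` already is an IoU matrix.
#' @param iou_min association gate in (0, 1).
#' @return `list(matches = <k x 2 matrix of (det, track) indices>,
#'   unmatched_dets, unmatched_tracks)`.
#' @export
associate <- function(dets, tracks, iou_min = 0.5) {
  iou <- if (is.null(tracks)) as.matrix(dets)
         else bbox_iou_matrix(dets, tracks)
  n <- nrow(iou); m <- ncol(iou)
  if (n == 0L || m == 0L) {
    return(list(matches = matrix(0L, 0, 2, dimnames = list(NULL,
                  c("det", "track"))),
                unmatched_dets = seq_len(n), unmatched_tracks = seq_len(m)))
  }
  assign <- solve_assignment(1 - iou)
  det_idx <- which(!is.na(assign))
  trk_idx <- assign[det_idx]
  keep <- iou[cbind(det_idx, trk_idx)] >= iou_min
  matches <- cbind(det = det_idx[keep], track = trk_idx[keep])
  list(matches = matches,
       unmatched_dets = setdiff(seq_len(n), matches[, 1]),
       unmatched_tracks = setdiff(seq_len(m), matches[, 2]))
}

new_track <- function(id, det_row, config) {
  b <- bbox(det_row$x, det_row$y, det_row$w, det_row$h)
  list(id = id, kf = kf_init(b, config$p0), hits = 1L,
       time_since_update = 0L, age = 1L,
       bbox = b, mask = det_row$mask[[1]], score = det_row$score,
       predicted = b)
}

track_boxes <- function(tracks) {
  if (length(tracks) == 0) return(matrix(0, 0, 4))
  do.call(rbind, lapply(tracks, function(t) as.numeric(t$predicted)))
}

# association scores between detections and tracks per config
association_iou <- function(det_df, tracks, config, frame_size) {
  det_boxes <- as.matrix(det_df[, c("x", "y", "w", "h")])
  iou <- bbox_iou_matrix(det_boxes, track_boxes(tracks))
  if (config$association == "mask" && length(tracks) > 0 &&
      nrow(det_df) > 0) {
    cand <- which(iou > 0, arr.ind = TRUE)
    miou <- matrix(0, nrow(iou), ncol(iou))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      miou[i, j] <- mask_iou(det_df$mask[[i]], tracks[[j]]$mask, frame_size)
    }
    iou <- miou
  }
  iou
}

#' Advance the tracker by one frame
#'
#' Applies the per-frame pipeline: predict all tracks, associate, update
#' matched tracks (attach the matched detection's mask, reset
#' `time_since_update`, increment `hits`), create a new track for every
#' unmatched detection, increment `time_since_update` on unmatched tracks,
#' and delete tracks with `time_since_update > t_lost`. The frame outputs are
#' the tracks matched this frame whose `hits >= min_hits` (or that are still
#' in their first `min_hits` frames of life).
#'
#' @param tracks the live track list from the previous frame (possibly
#'   `list()`); carries the next fresh id in attribute `"next_id"`.
#' @param frame_dets a data.frame of this frame's detections (columns `x`,
#'   `y`, `w`, `h`, `score` and list column `mask`).
#' @param config a [tracker_config()].
#' @param frame_size `c(width, height)`, needed for mask association.
#' @return `list(tracks = <updated list>, outputs = <data.frame of
#'   (track_id, x, y, w, h, score, mask)>)`.
#' @export
tracker_step <- function(tracks, frame_dets, config,
                         frame_size = c(NA, NA)) {
  # ids are never reused: the counter survives attribute-dropping subsets
  next_id <- max(attr(tracks, "next_id") %||% 1L,
                 if (length(tracks)) max(vapply(tracks, `[[`, integer(1),
                                                "id")) + 1L else 1L)
  # 1. predict
  for (i in seq_along(tracks)) {
    pr <- kf_predict(tracks[[i]]$kf, config$q)
    tracks[[i]]$kf <- pr$state
    tracks[[i]]$predicted <- pr$bbox
    tracks[[i]]$age <- tracks[[i]]$age + 1L
  }
  nd <- nrow(frame_dets)
  # 2. associate
  iou <- if (nd > 0 && length(tracks) > 0)
    association_iou(frame_dets, tracks, config, frame_size)
  else matrix(0, nd, length(tracks))
  asc <- associate(iou, NULL, config$iou_min)
  # 3. update matched
  matched_trk <- logical(length(tracks))
  for (k in seq_len(nrow(asc$matches))) {
    d <- asc$matches[k, 1]; tix <- asc$matches[k, 2]
    det <- frame_dets[d, ]
    tracks[[tix]]$kf <- kf_update(tracks[[tix]]$kf,
                                  bbox(det$x, det$y, det$w, det$h),
                                  config$r)
    tracks[[tix]]$hits <- tracks[[tix]]$hits + 1L
    tracks[[tix]]$time_since_update <- 0L
    tracks[[tix]]$bbox <- bbox(det$x, det$y, det$w, det$h)
    tracks[[tix]]$mask <- det$mask[[1]]
    tracks[[tix]]$score <- det$score
    matched_trk[tix] <- TRUE
  }
  # 4. new track per unmatched detection
  for (d in asc$unmatched_dets) {
    tracks[[length(tracks) + 1L]] <- new_track(next_id, frame_dets[d, ],
                                               config)
    matched_trk <- c(matched_trk, TRUE)
    next_id <- next_id + 1L
  }
  # 5. age unmatched, 6. delete stale
  keep <- rep(TRUE, length(tracks))
  for (i in seq_along(tracks)) {
    if (!matched_trk[i]) {
      tracks[[i]]$time_since_update <- tracks[[i]]$time_since_update + 1L
      if (tracks[[i]]$time_since_update > config$t_lost) keep[i] <- FALSE
    }
  }
  # outputs: matched this frame, past warm-up
  report <- vapply(tracks, function(t) {
    t$time_since_update == 0L &&
      (t$hits >= config$min_hits || t$age <= config$min_hits)
  }, logical(1)) & keep
  out <- tracks[report]
  outputs <- data.frame(
    track_id = vapply(out, function(t) t$id, integer(1)),
    x = vapply(out, function(t) t$bbox[[1]], numeric(1)),
    y = vapply(out, function(t) t$bbox[[2]], numeric(1)),
    w = vapply(out, function(t) t$bbox[[3]], numeric(1)),
    h = vapply(out, function(t) t$bbox[[4]], numeric(1)),
    score = vapply(out, function(t) t$score %||% 1, numeric(1)))
  outputs$mask <- lapply(out, function(t) t$mask)
  tracks <- tracks[keep]
  attr(tracks, "next_id") <- next_id
  list(tracks = tracks, outputs = outputs)
}

#' Run the tracker over a detection sequence
#'
#' Applies [tracker_step()] over all frames in order. Deterministic given the
#' input and configuration; track ids are positive integers assigned in
#' creation order.
#'
#' @param dets a [det_sequence()].
#' @param config a [tracker_config()].
#' @return A [tracking_result()].
#' @export
#' @examples
#' cfg <- scene_config(n_agents = 5, fps = 5, duration = 2, seed = 7,
#'                     placement = "grid")
#' gt <- simulate_scene(cfg)
#' dets <- corrupt_detections(gt, corruption_config(seed = 8))
#' res <- run_tracker(dets, tracker_config())
run_tracker <- function(dets, config = tracker_config()) {
  assert_that(inherits(dets, "det_sequence"), "dets must be a det_sequence")
  assert_that(inherits(config, "tracker_config"),
              "config must be a tracker_config")
  frame_size <- c(frame_width(dets), frame_height(dets))
  tracks <- list()
  det_df <- as.data.frame(dets)
  per_frame <- split(seq_len(nrow(det_df)), det_df$frame)
  rows <- vector("list", n_frames(dets))
  for (f in seq_len(n_frames(dets)) - 1L) {
    idx <- per_frame[[as.character(f)]]
    frame_dets <- det_df[idx %||% integer(0), , drop = FALSE]
    step <- tracker_step(tracks, frame_dets, config, frame_size)
    tracks <- step$tracks
    if (nrow(step$outputs) > 0) {
      step$outputs$frame <- f
      rows[[f + 1L]] <- step$outputs
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  objects <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(frame = integer(0), track_id = integer(0), x = numeric(0),
               y = numeric(0), w = numeric(0), h = numeric(0),
               score = numeric(0), mask = I(list()))
  tracking_result(objects, seq_fps(dets), frame_width(dets),
                  frame_height(dets), n_frames(dets))
}
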