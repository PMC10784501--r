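# Per-track trajectory extraction and active/inactive classification.

#' Extract per-id trajectories from a tracking result
#'
#' One record per track id. Centers are box centers (a mask-centroid variant
#' is available via `centers = "mask"`). Frames where a track produced no
#' output (coasting) are left as gaps, not interpolated; `path_length` sums
#' Euclidean steps between consecutive observed frames only, so occlusion
#' gaps do not inflate the path. `duration` is the spanned time
#' `(last - first + 1) / fps` in seconds and `mean_speed = path_length /
#' duration` in px/s.
#'
#' @param res a [tracking_result()] with a frame rate.
#' @param centers `"bbox"` (box centers) or `"mask"` (mask pixel centroids).
#' @return A data.frame with one row per track: `track_id`, `n_points`,
#'   `first_frame`, `last_frame`, `path_length` (px), `duration` (s),
#'   `mean_speed` (px/s), and a list column `points` of per-frame
#'   `(frame, x, y)` tables.
#' @export
extract_trajectories <- function(res, centers = c("bbox", "mask")) {
  assert_that(inherits(res, "tracking_result"),
              "res must be a tracking_result")
  centers <- match.arg(centers)
  fps <- seq_fps(res)
  assert_that(is_number(fps) && fps > 0, "result must carry a frame rate")
  df <- as.data.frame(res)
  if (nrow(df) == 0) {
    out <- data.frame(track_id = integer(0), n_points = integer(0),
                      first_frame = integer(0), last_frame = integer(0),
                      path_length = numeric(0), duration = numeric(0),
                      mean_speed = numeric(0))
    out$points <- list()
    return(out)
  }
  if (centers == "bbox") {
    df$cx <- df$x + df$w / 2
    df$cy <- df$y + df$h / 2
  } else {
    frame_size <- c(frame_width(res), frame_height(res))
    cent <- t(vapply(df$mask, function(m) mask_centroid(m, frame_size),
                     numeric(2)))
    df$cx <- cent[, 1]; df$cy <- cent[, 2]
  }
  ids <- sort(unique(df$track_id))
  recs <- lapply(ids, function(id) {
    p <- df[df$track_id == id, c("frame", "cx", "cy")]
    p <- p[order(p$frame), ]
    names(p) <- c("frame", "x", "y")
    consec <- diff(p$frame) == 1
    steps <- sqrt(diff(p$x)^2 + diff(p$y)^2)
    path <- sum(steps[consec])
    dur <- (p$frame[nrow(p)] - p$frame[1] + 1) / fps
    data.frame(track_id = id, n_points = nrow(p),
               first_frame = p$frame[1], last_frame = p$frame[nrow(p)],
               path_length = path, duration = dur,
               mean_speed = path / dur)
  })
  out <- do.call(rbind, recs)
  out$points <- lapply(ids, function(id) {
    p <- df[df$track_id == id, c("frame", "x", "y", "w", "h")]
    data.frame(frame = p$frame, x = p$x + p$w / 2, y = p$y + p$h / 2)
  })
  rownames(out) <- NULL
  out
}

mask_centroid <- function(mask, frame_size) {
  W <- as.integer(frame_size[1])
  idx <- cpp_poly_pixels(unclass(as_mask_poly(mask)), W,
                         as.integer(frame_size[2]))
  c(mean(idx %% W) + 0.5, mean(idx %/% W) + 0.5)
}

#' Classify a trajectory as active or inactive
#'
#' Threshold rule on mean speed: a track is inactive iff its mean speed is
#' below `threshold` px/s. The default of 5 px/s separates near-stationary
#' agents (sub-pixel per-frame jitter) from walking agents by a wide margin;
#' no field-validated criterion exists, so the threshold is exposed.
#'
#' @param t one trajectory record (a row of [extract_trajectories()] output,
#'   or anything with a `mean_speed` field) or a numeric mean speed.
#' @param threshold px/s decision boundary.
#' @return `list(label = "active" | "inactive", threshold_used = threshold)`.
#' @export
classify_activity <- function(t, threshold = 5) {
  speed <- if (is.numeric(t)) t else t$mean_speed
  assert_that(is.numeric(speed) && all(is.finite(speed)),
              "mean speed must be numeric")
  list(label = ifelse(speed < threshold, "inactive", "active"),
       threshold_used = threshold)
}

#' Write trajectories as tabular text
#'
#' Writes a long per-point table `(track_id, frame, x, y)` to `path` and the
#' per-track summary (path length, duration, mean speed, activity label) to
#' `paste0(path, ".summary.tsv")`.
#'
#' @param traj output of [extract_trajectories()].
#' @param path output path for the per-point table.
#' @param threshold px/s activity threshold used for the summary labels.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path, threshold = 5) {
  pts <- do.call(rbind, lapply(seq_len(nrow(traj)), function(i) {
    cbind(track_id = traj$track_id[i], traj$points[[i]])
  }))
  if (is.null(pts)) pts <- data.frame(track_id = integer(0),
                                      frame = integer(0),
                                      x = numeric(0), y = numeric(0))
  write.table(pts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- traj[, setdiff(names(traj), "points"), drop = FALSE]
  summ$label <- classify_activity(traj, threshold)$label
  write.table(summ, paste0(path, ".summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
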