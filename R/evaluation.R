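# Evaluation stack: instance-segmentation average precision at a fixed IoU
# operating point, CLEAR MOT (MOTA / MOTP / recall) on boxes, and MOTS
# (MOTSA / MOTSP / recall) on masks.
#
# MOTP convention: mean IoU of matches x 100 (the MOTChallenge convention,
# matching the percent scale these metrics are reported on), not the original
# distance-error formulation.

# mask IoU matrix between two object tables, gated by box overlap (a mask is
# contained in its tight box, so disjoint boxes imply mask IoU 0)
mask_iou_matrix <- function(A, B, frame_size) {
  biou <- bbox_iou_matrix(as.matrix(A[, c("x", "y", "w", "h")]),
                          as.matrix(B[, c("x", "y", "w", "h")]))
  out <- matrix(0, nrow(A), nrow(B))
  cand <- which(biou > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    out[i, j] <- mask_iou(A$mask[[i]], B$mask[[j]], frame_size)
  }
  out
}

#' Instance-segmentation average precision
#'
#' Detections are pooled over all frames, sorted by descending score, and
#' each is greedily matched to the not-yet-matched ground-truth object in its
#' frame with the highest IoU; a detection is a true positive when that IoU
#' is at least `iou_thresh` (the 0.5 operating point by default), otherwise a
#' false positive. Unmatched ground truths are false negatives. AP is the
#' area under the precision-recall curve; with a single category, mAP equals
#' AP.
#'
#' @param gt a [gt_sequence()].
#' @param dets a [det_sequence()] with scores.
#' @param iou_thresh match threshold (a prediction is correct when
#'   IoU >= `iou_thresh`).
#' @param iou_type `"mask"` (pixel IoU, default) or `"bbox"`.
#' @param interpolation `"all"` (area under the exact precision envelope,
#'   the modern COCO-style convention) or `"11point"`.
#' @return An `ap_result`: list with `ap`, `map`, the precision/recall
#'   curve, TP/FP/FN counts, and a `degenerate` flag (no ground truth and no
#'   detections reports AP 1 with `degenerate = TRUE`).
#' @export
compute_ap <- function(gt, dets, iou_thresh = 0.5,
                       iou_type = c("mask", "bbox"),
                       interpolation = c("all", "11point")) {
  assert_that(inherits(gt, "gt_sequence"), "gt must be a gt_sequence")
  assert_that(inherits(dets, "det_sequence"), "dets must be a det_sequence")
  iou_type <- match.arg(iou_type)
  interpolation <- match.arg(interpolation)
  frame_size <- c(frame_width(gt), frame_height(gt))
  gt_df <- as.data.frame(gt)
  det_df <- as.data.frame(dets)
  n_gt <- nrow(gt_df)
  if (n_gt == 0 && nrow(det_df) == 0) {
    return(structure(list(ap = 1, map = 1, precision = numeric(0),
                          recall = numeric(0), tp = 0, fp = 0, fn = 0,
                          n_gt = 0, degenerate = TRUE),
                     class = "ap_result"))
  }
  ord <- order(-det_df$score, det_df$frame, seq_len(nrow(det_df)))
  det_df <- det_df[ord, , drop = FALSE]
  gt_used <- logical(n_gt)
  gt_by_frame <- split(seq_len(n_gt), gt_df$frame)
  is_tp <- logical(nrow(det_df))
  for (i in seq_len(nrow(det_df))) {
    cand <- gt_by_frame[[as.character(det_df$frame[i])]]
    cand <- cand[!gt_used[cand]]
    if (length(cand) == 0) next
    biou <- drop(bbox_iou_matrix(
      matrix(as.numeric(det_df[i, c("x", "y", "w", "h")]), 1),
      as.matrix(gt_df[cand, c("x", "y", "w", "h")])))
    ious <- if (iou_type == "bbox") {
      biou
    } else {
      # a mask lies inside its tight box: disjoint boxes mean mask IoU 0
      v <- numeric(length(cand))
      for (k in which(biou > 0))
        v[k] <- mask_iou(det_df$mask[[i]], gt_df$mask[[cand[k]]], frame_size)
      v
    }
    best <- which.max(ious)
    if (ious[best] >= iou_thresh) {
      is_tp[i] <- TRUE
      gt_used[cand[best]] <- TRUE
    }
  }
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  precision <- tp / (tp + fp)
  recall <- if (n_gt > 0) tp / n_gt else rep(0, length(tp))
  ap <- if (length(tp) == 0) 0 else
    ap_from_curve(precision, recall, interpolation)
  structure(list(ap = ap, map = ap, precision = precision, recall = recall,
                 tp = sum(is_tp), fp = sum(!is_tp), fn = n_gt - sum(is_tp),
                 n_gt = n_gt, degenerate = FALSE),
            class = "ap_result")
}

ap_from_curve <- function(precision, recall, interpolation) {
  # precision envelope: p_env(r) = max precision at recall >= r
  mrec <- c(0, recall)
  mpre <- c(0, precision)
  for (i in rev(seq_len(length(mpre) - 1))) {
    mpre[i] <- max(mpre[i], mpre[i + 1])
  }
  if (interpolation == "11point") {
    pts <- seq(0, 1, by = 0.1)
    return(mean(vapply(pts, function(r) {
      ok <- mrec >= r
      if (any(ok)) max(mpre[ok]) else 0
    }, numeric(1))))
  }
  steps <- which(diff(mrec) > 0)
  sum((mrec[steps + 1] - mrec[steps]) * mpre[steps + 1])
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> AP = %.4f (TP %d, FP %d, FN %d, GT %d)%s\n",
              x$ap, x$tp, x$fp, x$fn, x$n_gt,
              if (x$degenerate) " [degenerate: no GT, no detections]" else ""))
  invisible(x)
}

# shared matching walk for the two tracking metrics.
# score_fun(gt_rows, res_rows) -> IoU-like matrix; `strict` selects > vs >=.
mot_walk <- function(gt, res, thresh, score_fun, strict) {
  assert_that(n_frames(gt) == n_frames(res),
              sprintf("frame-count mismatch: gt has %d frames, result %d",
                      n_frames(gt), n_frames(res)))
  gt_df <- as.data.frame(gt)
  res_df <- as.data.frame(res)
  gt_frames <- split(seq_len(nrow(gt_df)), gt_df$frame)
  res_frames <- split(seq_len(nrow(res_df)), res_df$frame)
  last_match <- integer(0)  # gt id -> result id of its last match
  total <- list(gt = nrow(gt_df), match = 0L, fn = 0L, fp = 0L, idsw = 0L,
                iou_sum = 0)
  per_frame <- vector("list", n_frames(gt))
  for (f in seq_len(n_frames(gt)) - 1L) {
    gi <- gt_frames[[as.character(f)]] %||% integer(0)
    ri <- res_frames[[as.character(f)]] %||% integer(0)
    g_rows <- gt_df[gi, , drop = FALSE]
    r_rows <- res_df[ri, , drop = FALSE]
    iou <- score_fun(g_rows, r_rows)
    ok <- function(v) if (strict) v > thresh else v >= thresh
    matched_g <- integer(0); matched_r <- integer(0)
    # carry over still-valid previous correspondences
    if (length(gi) && length(ri)) {
      for (a in seq_along(gi)) {
        gid <- as.character(g_rows$instance_id[a])
        prev <- last_match[gid]
        if (!is.na(prev) && length(prev)) {
          b <- match(prev, r_rows$track_id)
          if (!is.na(b) && !(b %in% matched_r) && ok(iou[a, b])) {
            matched_g <- c(matched_g, a); matched_r <- c(matched_r, b)
            total$match <- total$match + 1L
            total$iou_sum <- total$iou_sum + iou[a, b]
          }
        }
      }
      # Hungarian on the remainder, maximizing IoU
      rem_g <- setdiff(seq_along(gi), matched_g)
      rem_r <- setdiff(seq_along(ri), matched_r)
      if (length(rem_g) && length(rem_r)) {
        sub <- iou[rem_g, rem_r, drop = FALSE]
        sub[!ok(sub)] <- 0  # ineligible pairs never outbid eligible ones
        asc <- associate(sub, NULL, iou_min = .Machine$double.eps)
        for (k in seq_len(nrow(asc$matches))) {
          a <- rem_g[asc$matches[k, 1]]; b <- rem_r[asc$matches[k, 2]]
          if (!ok(iou[a, b])) next
          gid <- as.character(g_rows$instance_id[a])
          prev <- last_match[gid]
          if (!is.na(prev) && length(prev) && prev != r_rows$track_id[b])
            total$idsw <- total$idsw + 1L
          last_match[gid] <- r_rows$track_id[b]
          matched_g <- c(matched_g, a); matched_r <- c(matched_r, b)
          total$match <- total$match + 1L
          total$iou_sum <- total$iou_sum + iou[a, b]
        }
      }
    }
    fn <- length(gi) - length(matched_g)
    fp <- length(ri) - length(matched_r)
    total$fn <- total$fn + fn
    total$fp <- total$fp + fp
    per_frame[[f + 1L]] <- data.frame(frame = f, gt = length(gi),
                                      matches = length(matched_g),
                                      fn = fn, fp = fp)
  }
  total$per_frame <- do.call(rbind, per_frame)
  total
}

#' CLEAR MOT tracking metrics
#'
#' Per frame, previous-frame correspondences whose box IoU still reaches
#' `iou_min` are carried over; the remaining objects are matched by the
#' Hungarian algorithm maximizing IoU. Unmatched ground truths count as
#' misses (FN), unmatched results as false positives (FP), and a ground
#' truth matched to a different result id than its last match counts as an
#' identity switch (IDSW).
#'
#' `MOTA = 100 (1 - (FN + FP + IDSW) / GT)`, `MOTP` is the mean IoU of
#' matches x 100, and `recall = 100 matches / GT`.
#'
#' @param gt a [gt_sequence()].
#' @param res a [tracking_result()] over the same frames.
#' @param iou_min box IoU needed for a correspondence (default 0.5).
#' @return A `clear_mot_report` with `MOTA`, `MOTP`, `recall`, the total
#'   counts and a per-frame count table.
#' @export
clear_mot <- function(gt, res, iou_min = 0.5) {
  assert_that(inherits(gt, "gt_sequence"), "gt must be a gt_sequence")
  assert_that(inherits(res, "tracking_result"),
              "res must be a tracking_result")
  score_fun <- function(g, r)
    bbox_iou_matrix(as.matrix(g[, c("x", "y", "w", "h")]),
                    as.matrix(r[, c("x", "y", "w", "h")]))
  tot <- mot_walk(gt, res, iou_min, score_fun, strict = FALSE)
  structure(list(
    MOTA = 100 * (1 - (tot$fn + tot$fp + tot$idsw) / tot$gt),
    MOTP = if (tot$match > 0) 100 * tot$iou_sum / tot$match else NA_real_,
    recall = 100 * tot$match / tot$gt,
    n_gt = tot$gt, matches = tot$match, fn = tot$fn, fp = tot$fp,
    idsw = tot$idsw, per_frame = tot$per_frame),
    class = "clear_mot_report")
}

#' @export
print.clear_mot_report <- function(x, ...) {
  cat(sprintf(paste0("<clear_mot_report> MOTA %.2f%%  MOTP %.2f%%  ",
                     "recall %.2f%%\n  GT %d, matches %d, FN %d, FP %d, ",
                     "IDSW %d\n"),
              x$MOTA, x$MOTP, x$recall, x$n_gt, x$matches, x$fn, x$fp,
              x$idsw))
  invisible(x)
}

#' MOTS tracking-and-segmentation metrics
#'
#' The mask-level analogue of [clear_mot()]: per frame, ground truth and
#' result masks are matched on pixel IoU with a strict threshold
#' (`IoU > 0.5`, the MOTS convention, vs `>=` for [compute_ap()]); TP, FP,
#' FN and ID switches are counted as in CLEAR MOT.
#'
#' `MOTSA = 100 (TP - FP - IDS) / GT`, `MOTSP = 100 * (sum of TP IoUs) / TP`,
#' `recall = 100 TP / GT`; the soft variant
#' `sMOTSA = 100 (sum IoU - FP - IDS) / GT` is reported as an extra field.
#'
#' Result masks within a frame must be pairwise non-overlapping; violations
#' raise a validation error listing the offending pairs (disable the check
#' with `validate_overlap = FALSE` for diagnostic runs).
#'
#' @param gt a [gt_sequence()].
#' @param res a [tracking_result()] over the same frames.
#' @param iou_thresh strict mask IoU threshold (match requires IoU greater
#'   than this).
#' @param validate_overlap check that result masks do not overlap.
#' @return A `mots_report` with `MOTSA`, `MOTSP`, `sMOTSA`, `recall`, counts
#'   and a per-frame table.
#' @export
mots_eval <- function(gt, res, iou_thresh = 0.5, validate_overlap = TRUE) {
  assert_that(inherits(gt, "gt_sequence"), "gt must be a gt_sequence")
  assert_that(inherits(res, "tracking_result"),
              "res must be a tracking_result")
  frame_size <- c(frame_width(gt), frame_height(gt))
  if (validate_overlap) validate_result_masks(res, frame_size)
  score_fun <- function(g, r) mask_iou_matrix(g, r, frame_size)
  tot <- mot_walk(gt, res, iou_thresh, score_fun, strict = TRUE)
  structure(list(
    MOTSA = 100 * (tot$match - tot$fp - tot$idsw) / tot$gt,
    MOTSP = if (tot$match > 0) 100 * tot$iou_sum / tot$match else NA_real_,
    sMOTSA = 100 * (tot$iou_sum - tot$fp - tot$idsw) / tot$gt,
    recall = 100 * tot$match / tot$gt,
    n_gt = tot$gt, tp = tot$match, fn = tot$fn, fp = tot$fp,
    ids = tot$idsw, iou_sum = tot$iou_sum, per_frame = tot$per_frame),
    class = "mots_report")
}

#' @export
print.mots_report <- function(x, ...) {
  cat(sprintf(paste0("<mots_report> MOTSA %.2f%%  MOTSP %.2f%%  ",
                     "recall %.2f%%  (sMOTSA %.2f%%)\n  GT %d, TP %d, ",
                     "FN %d, FP %d, IDS %d\n"),
              x$MOTSA, x$MOTSP, x$recall, x$sMOTSA, x$n_gt, x$tp, x$fn,
              x$fp, x$ids))
  invisible(x)
}

validate_result_masks <- function(res, frame_size) {
  res_df <- as.data.frame(res)
  bad <- character(0)
  for (f in unique(res_df$frame)) {
    rows <- res_df[res_df$frame == f, , drop = FALSE]
    if (nrow(rows) < 2) next
    biou <- bbox_iou_matrix(as.matrix(rows[, c("x", "y", "w", "h")]),
                            as.matrix(rows[, c("x", "y", "w", "h")]))
    cand <- which(biou > 0 & upper.tri(biou), arr.ind = TRUE)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      ov <- mask_overlap(rows$mask[[i]], rows$mask[[j]], frame_size)
      if (ov[1] > 0)
        bad <- c(bad, sprintf("frame %d: tracks %d and %d share %d px",
                              as.integer(f), as.integer(rows$track_id[i]),
                              as.integer(rows$track_id[j]),
                              as.integer(ov[1])))
    }
  }
  if (length(bad))
    stop("overlapping result masks:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Write a metrics report to text files
#'
#' Writes the scalar metrics as flat `key = value` lines to `path` and, when
#' the report carries per-frame counts, a tab-separated per-frame table to
#' `paste0(path, ".frames.tsv")`. Suitable for regression diffing.
#'
#' @param report an `ap_result`, `clear_mot_report` or `mots_report`.
#' @param path output path for the flat key-value file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  scalars <- Filter(function(v) is.numeric(v) && length(v) == 1, report)
  lines <- sprintf("%s = %.6f", names(scalars), as.numeric(scalars))
  writeLines(c(paste0("# ", class(report)[1]), lines), path)
  if (!is.null(report$per_frame))
    write.table(report$per_frame, paste0(path, ".frames.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
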