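# Evaluation stack: AP, CLEAR MOT, MOTS.

two_frame_gt <- function() {
  make_gt(data.frame(frame = rep(0:1, each = 2), instance_id = rep(1:2, 2),
                     x = rep(c(10, 60), 2), y = 10, w = 20, h = 10))
}

test_that("a perfect detector scores AP 1 regardless of scores", {
  gt <- two_frame_gt()
  df <- as.data.frame(gt)[c("frame", "x", "y", "w", "h")]
  withr::with_seed(3, df$score <- runif(nrow(df), 0.5, 1))
  dets <- make_dets(df)
  expect_equal(compute_ap(gt, dets)$ap, 1)
  expect_equal(compute_ap(gt, dets, iou_type = "bbox")$ap, 1)
})

test_that("PR accumulation matches hand-walked curves", {
  # 1 GT, 2 predictions on it (TP ranked first): AP = 1 all-point
  gt <- make_gt(data.frame(frame = 0, instance_id = 1, x = 10, y = 10,
                           w = 20, h = 10))
  dets <- make_dets(data.frame(frame = 0, x = c(10, 10), y = 10, w = 20,
                               h = 10, score = c(0.9, 0.8)))
  r <- compute_ap(gt, dets)
  expect_equal(r$tp, 1)
  expect_equal(r$fp, 1)
  expect_equal(r$ap, 1)
  # 2 GT, 1 TP prediction: recall caps at 0.5, AP = 0.5
  gt2 <- make_gt(data.frame(frame = 0, instance_id = 1:2, x = c(10, 60),
                            y = 10, w = 20, h = 10))
  dets2 <- make_dets(data.frame(frame = 0, x = 10, y = 10, w = 20, h = 10,
                                score = 0.9))
  r2 <- compute_ap(gt2, dets2)
  expect_equal(max(r2$recall), 0.5)
  expect_equal(r2$ap, 0.5)
})

test_that("AP edge cases: no detections, nothing at all", {
  gt <- two_frame_gt()
  none <- make_dets(data.frame(frame = integer(0), x = numeric(0),
                               y = numeric(0), w = numeric(0),
                               h = numeric(0), score = numeric(0)))
  expect_equal(compute_ap(gt, none)$ap, 0)
  empty_gt <- make_gt(data.frame(frame = integer(0), instance_id = integer(0),
                                 x = numeric(0), y = numeric(0),
                                 w = numeric(0), h = numeric(0)),
                      n_frames = 2)
  r <- compute_ap(empty_gt, none)
  expect_equal(r$ap, 1)
  expect_true(r$degenerate)
})

test_that("AP is invariant to frame order and monotone score transforms", {
  withr::with_seed(17, {
    df <- data.frame(frame = rep(0:4, each = 4), instance_id = rep(1:4, 5),
                     x = rep(c(5, 45, 85, 125), 5) + rnorm(20, 0, 1),
                     y = 10, w = 22, h = 12)
    gt <- make_gt(df)
    ddf <- df[sample(nrow(df) - 3), c("frame", "x", "y", "w", "h")]
    ddf$x <- ddf$x + rnorm(nrow(ddf), 0, 2)
    ddf$score <- runif(nrow(ddf), 0.2, 0.95)
  })
  dets <- make_dets(ddf)
  base <- compute_ap(gt, dets)
  # positive monotone transform of scores
  ddf2 <- ddf; ddf2$score <- plogis(5 * ddf$score - 2)
  expect_equal(compute_ap(gt, make_dets(ddf2))$ap, base$ap)
  # frame relabeling (reverse order)
  flip <- function(d) { d$frame <- 4 - d$frame; d }
  expect_equal(compute_ap(make_gt(flip(df)), make_dets(flip(ddf)))$ap,
               base$ap)
})

test_that("relabeled perfect tracking scores 100 on both metric families", {
  gt <- two_frame_gt()
  df <- as.data.frame(gt)[c("frame", "x", "y", "w", "h")]
  df$track_id <- c(7, 9)[as.data.frame(gt)$instance_id]  # fixed bijection
  res <- make_result(df)
  cm <- clear_mot(gt, res)
  expect_equal(cm$MOTA, 100)
  expect_equal(cm$MOTP, 100)
  expect_equal(cm$idsw, 0)
  ms <- mots_eval(gt, res)
  expect_equal(ms$MOTSA, 100)
  expect_equal(ms$MOTSP, 100)
  expect_equal(ms$recall, 100)
})

test_that("hand-counted single-frame scenario gives MOTA 70, recall 80", {
  # 10 GT; 8 matched exactly, 2 missed, 1 false positive
  gt <- make_gt(data.frame(frame = 0, instance_id = 1:10,
                           x = 40 * (0:9), y = 10, w = 20, h = 10),
                frame_w = 500)
  df <- data.frame(frame = 0, track_id = 1:9,
                   x = c(40 * (0:7), 40 * 9 + 21), y = c(rep(10, 8), 40),
                   w = 20, h = 10)
  res <- make_result(df, frame_w = 500)
  cm <- clear_mot(gt, res)
  expect_equal(cm$matches, 8)
  expect_equal(cm$fn, 2)
  expect_equal(cm$fp, 1)
  expect_equal(cm$MOTA, 70)
  expect_equal(cm$recall, 80)
})

test_that("an identity handover counts exactly one switch", {
  # one GT tracked by id 1 for 5 frames then id 2 for 5 frames
  gt <- make_gt(data.frame(frame = 0:9, instance_id = 1, x = 10, y = 10,
                           w = 20, h = 10))
  df <- data.frame(frame = 0:9, track_id = rep(c(1, 2), each = 5),
                   x = 10, y = 10, w = 20, h = 10)
  cm <- clear_mot(gt, make_result(df))
  expect_equal(cm$idsw, 1)
  expect_equal(cm$MOTA, 90)
})

test_that("carried-over matches are kept over higher-IoU newcomers", {
  # frame 0: gt1 <- id1. frame 1: id1 still overlaps gt1 above the gate but
  # id2 overlaps it better; the previous correspondence must persist.
  gt <- make_gt(data.frame(frame = 0:1, instance_id = 1, x = c(10, 10),
                           y = 10, w = 20, h = 10))
  df <- data.frame(frame = c(0, 1, 1), track_id = c(1, 1, 2),
                   x = c(10, 14, 10), y = 10, w = 20, h = 10)
  cm <- clear_mot(gt, make_result(df))
  expect_equal(cm$idsw, 0)
  expect_equal(cm$fp, 1)
})

test_that("MOTS counts and percentages follow the mask formulas", {
  # 2 frames x 5 GT = 10 GT total; frame 1: one id handover, one miss with a
  # false positive elsewhere -> TP 9, FP 1, IDS 1, MOTSA = 70
  gt <- make_gt(data.frame(frame = rep(0:1, each = 5),
                           instance_id = rep(1:5, 2),
                           x = rep(40 * (0:4), 2), y = 10, w = 20, h = 10),
                frame_w = 500)
  df <- data.frame(
    frame = c(rep(0, 5), rep(1, 4), 1),
    track_id = c(1:5, 9, 2:4, 6),
    x = c(40 * (0:4), 40 * (0:3), 470), y = c(rep(10, 9), 60),
    w = 20, h = 10)
  ms <- mots_eval(gt, make_result(df, frame_w = 500))
  expect_equal(ms$tp, 9)
  expect_equal(ms$fp, 1)
  expect_equal(ms$ids, 1)
  expect_equal(ms$MOTSA, 70)
  expect_equal(ms$recall, 90)
  # MOTSP: all TP IoUs exactly 0.8 (8x10 result inside 10x10 gt)
  gt2 <- make_gt(data.frame(frame = 0, instance_id = 1:3, x = c(0, 20, 40),
                            y = 0, w = 10, h = 10))
  df2 <- data.frame(frame = 0, track_id = 1:3, x = c(0, 20, 40), y = 0,
                    w = 8, h = 10)
  ms2 <- mots_eval(gt2, make_result(df2))
  expect_equal(ms2$MOTSP, 80)
})

test_that("MOTS matching is strict at the threshold; AP is not", {
  # IoU exactly 0.5: 10x10 vs 10x5 contained
  gt <- make_gt(data.frame(frame = 0, instance_id = 1, x = 0, y = 0,
                           w = 10, h = 10))
  dfr <- data.frame(frame = 0, track_id = 1, x = 0, y = 0, w = 10, h = 5)
  ms <- mots_eval(gt, make_result(dfr))
  expect_equal(ms$tp, 0)   # > 0.5 required
  dets <- make_dets(data.frame(frame = 0, x = 0, y = 0, w = 10, h = 5,
                               score = 0.9))
  expect_equal(compute_ap(gt, dets)$tp, 1)  # >= 0.5 suffices
})

test_that("overlapping result masks are rejected with the offending pair", {
  gt <- make_gt(data.frame(frame = 0, instance_id = 1, x = 0, y = 0,
                           w = 10, h = 10))
  df <- data.frame(frame = 0, track_id = 1:2, x = c(0, 5), y = 0,
                   w = 10, h = 10)
  expect_error(mots_eval(gt, make_result(df)), "tracks 1 and 2")
})

test_that("box and mask walks agree when masks are their own boxes", {
  withr::with_seed(23, {
    gt_df <- data.frame(frame = rep(0:3, each = 3),
                        instance_id = rep(1:3, 4),
                        x = rep(c(5, 60, 115), 4) + rnorm(12, 0, 2),
                        y = 20, w = 30, h = 14)
    res_df <- gt_df
    res_df$track_id <- res_df$instance_id + 10
    res_df$x <- res_df$x + rnorm(12, 0, 2)
    drop <- sample(12, 2)
  })
  gt <- make_gt(gt_df)
  res <- make_result(res_df[-drop, names(res_df) != "instance_id"])
  cm <- clear_mot(gt, res)
  ms <- mots_eval(gt, res)
  expect_equal(cm$matches, ms$tp)
  expect_equal(cm$fn, ms$fn)
  expect_equal(cm$fp, ms$fp)
  expect_equal(cm$idsw, ms$ids)
})

test_that("frame-count mismatches are a validation error", {
  gt <- two_frame_gt()
  res <- make_result(data.frame(frame = 0, track_id = 1, x = 10, y = 10,
                                w = 20, h = 10), n_frames = 1)
  expect_error(clear_mot(gt, res), "frame-count mismatch")
})

test_that("metric reports serialize as flat key-value plus per-frame table", {
  gt <- two_frame_gt()
  df <- as.data.frame(gt)[c("frame", "x", "y", "w", "h")]
  df$track_id <- as.data.frame(gt)$instance_id
  path <- withr::local_tempfile(fileext = ".txt")
  write_metrics_report(clear_mot(gt, make_result(df)), path)
  lines <- readLines(path)
  expect_true(any(grepl("^MOTA = 100", lines)))
  frames <- read.table(paste0(path, ".frames.tsv"), header = TRUE)
  expect_equal(nrow(frames), 2)
})
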