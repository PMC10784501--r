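# I/O: COCO dialect round trips, score filter, letterbox transforms,
# frame-rate downsampling, MOTChallenge export.

test_that("COCO ground-truth round trip preserves the object set", {
  gt <- make_gt(data.frame(frame = rep(0:1, each = 3),
                           instance_id = rep(1:3, 2),
                           x = rep(c(10, 50, 90), 2),
                           y = rep(c(10, 30, 50), 2),
                           w = 20, h = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(gt, path)
  back <- read_coco_ground_truth(path)
  expect_equal(nrow(back), 6)
  expect_equal(sort(unique(back$instance_id)), 1:3)
  expect_equal(n_frames(back), n_frames(gt))
  expect_equal(seq_fps(back), seq_fps(gt))
  expect_equal(back$x, gt$x, tolerance = 1e-9)
  # second round trip is bit-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_coco(back, path2)
  again <- read_coco_ground_truth(path2)
  expect_equal(as.data.frame(again)[names(again) != "mask"],
               as.data.frame(back)[names(back) != "mask"])
  expect_equal(unclass(again$mask[[1]]), unclass(back$mask[[1]]))
})

test_that("empty annotation lists and malformed polygons are handled", {
  gt <- make_gt(data.frame(frame = 0, instance_id = 1, x = 5, y = 5,
                           w = 10, h = 10), n_frames = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(gt, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$annotations <- list()
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  empty <- read_coco_ground_truth(path)
  expect_equal(nrow(empty), 0)
  expect_equal(n_frames(empty), 2)
  # two-vertex polygon names the offending record
  write_coco(gt, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$annotations[[1]]$segmentation <- list(c(0, 0, 5, 5))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_coco_ground_truth(path), "annotation 1")
  # duplicated (frame, instance_id)
  write_coco(gt, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$annotations[[2]] <- doc$annotations[[1]]
  doc$annotations[[2]]$id <- 2
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_coco_ground_truth(path), "duplicate")
})

test_that("uncompressed RLE segmentations are accepted on read", {
  gt <- make_gt(data.frame(frame = 0, instance_id = 1, x = 2, y = 1,
                           w = 3, h = 2), frame_w = 6, frame_h = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(gt, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  # pixels (x,y) in [2,5) x [1,3): column-major runs over a 4 x 6 grid
  # col 2: rows 1-2 -> start 9 len 2; col 3: start 13 len 2; col 4: 17 len 2
  doc$annotations[[1]]$segmentation <-
    list(counts = c(9, 2, 2, 2, 2, 2, 5), size = c(4, 6))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  back <- read_coco_ground_truth(path)
  expect_equal(rasterize_mask(back$mask[[1]], c(6, 4)),
               rasterize_mask(rect_mask(2, 1, 3, 2), c(6, 4)))
})

test_that("detections require scores and round trip through COCO", {
  dets <- make_dets(data.frame(frame = c(0, 0, 1), x = c(1, 30, 1),
                               y = c(1, 5, 2), w = 10, h = 8,
                               score = c(0.6, 0.7, 0.9)))
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(dets, path)
  back <- read_coco_detections(path)
  expect_equal(back$score, dets$score)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$annotations[[1]]$score <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_coco_detections(path), "without a score")
})

test_that("filter_by_score keeps the boundary and preserves structure", {
  dets <- make_dets(data.frame(frame = c(0, 0, 1), x = c(1, 30, 1),
                               y = c(1, 5, 2), w = 10, h = 8,
                               score = c(0.6, 0.7, 0.9)))
  kept <- filter_by_score(dets, 0.7)
  expect_equal(nrow(kept), 2)           # 0.7 itself is accepted
  expect_equal(kept$score, c(0.7, 0.9))
  expect_equal(n_frames(kept), n_frames(dets))
  expect_equal(nrow(filter_by_score(dets, 0)), 3)    # identity
  expect_equal(nrow(filter_by_score(dets, 1)), 0)    # all below 1
})

test_that("letterbox maps 1920x1080 into a 512 square as expected", {
  spec <- letterbox_spec(1920, 1080, 512)
  expect_equal(spec$scale, 512 / 1920)
  # bottom-right corner of the content region
  expect_equal(to_model_coords(c(1920, 1080), spec), c(512, 288))
  expect_equal(to_model_coords(c(0, 0), spec), c(0, 0))
  expect_error(letterbox_spec(1920, 1080, 512, pad_top = 900),
               "fit inside")
})

test_that("letterbox transforms round trip and preserve IoU", {
  spec <- letterbox_spec(1920, 1080, 512, pad_top = 420)
  withr::with_seed(5, {
    for (k in 1:100) {
      b <- bbox(runif(1, 0, 1800), runif(1, 0, 600), runif(1, 5, 100),
                runif(1, 5, 100))
      back <- from_model_coords(to_model_coords(b, spec), spec)
      expect_equal(as.numeric(back), as.numeric(b), tolerance = 1e-6)
    }
    # affine: IoU of any two boxes is preserved exactly
    for (k in 1:20) {
      b1 <- bbox(runif(1, 0, 500), runif(1, 0, 500), runif(1, 10, 200),
                 runif(1, 10, 200))
      b2 <- bbox(runif(1, 0, 500), runif(1, 0, 500), runif(1, 10, 200),
                 runif(1, 10, 200))
      expect_equal(bbox_iou(to_model_coords(b1, spec),
                            to_model_coords(b2, spec)),
                   bbox_iou(b1, b2), tolerance = 1e-12)
    }
  })
  # masks transform consistently with points
  m <- mask_poly(rect_ring(100, 50, 30, 20))
  m2 <- to_model_coords(m, spec)
  expect_equal(unclass(m2)[[1]][1, ],
               to_model_coords(c(100, 50), spec))
})

test_that("downsampling keeps every k-th frame and renumbers from 0", {
  df <- data.frame(frame = 0:299, instance_id = 1, x = 1, y = 1,
                   w = 5, h = 5)
  gt30 <- make_gt(df, fps = 30)
  for (tf in c(5, 10, 15)) {
    down <- downsample_sequence(gt30, tf)
    expect_equal(n_frames(down), tf * 10)
    expect_equal(seq_fps(down), tf)
    expect_equal(down$frame, 0:(tf * 10 - 1))
    expect_equal(attr(down, "original_frames"),
                 seq.int(0, 299, by = 30 / tf))
  }
  expect_equal(n_frames(downsample_sequence(gt30, 30)), 300)  # identity
  expect_error(downsample_sequence(gt30, 7), "not divisible")
  # composition: 30 -> 15 -> 5 equals 30 -> 5
  two_step <- downsample_sequence(downsample_sequence(gt30, 15), 5)
  one_step <- downsample_sequence(gt30, 5)
  expect_equal(two_step$frame, one_step$frame)
  expect_equal(attr(two_step, "original_frames") >= 0, rep(TRUE, 50))
})

test_that("MOTChallenge export is 1-based and comma-separated", {
  res <- make_result(data.frame(frame = c(0, 1), track_id = c(3, 3),
                                x = c(10, 12), y = c(5, 5), w = 8, h = 6,
                                score = 0.9))
  path <- withr::local_tempfile(fileext = ".txt")
  write_motchallenge(res, path)
  rows <- read.table(path, sep = ",")
  expect_equal(rows$V1, c(1, 2))
  expect_equal(rows$V2, c(3, 3))
  expect_equal(rows$V3, c(10, 12))
  expect_equal(rows$V8, c(-1, -1))
})
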