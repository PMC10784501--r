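# Synthetic dense-swarm scene generator and detector-noise model. The
# generator emulates the statistical structure of observation-hive footage
# that the tracker assumes: 1920x1080 frames, hundreds of bee-sized
# elliptical agents, a mix of active walkers and near-stationary (inactive)
# agents, occlusion with a visibility rule for ground-truth inclusion, and a
# configurable detector corruption (misses, false positives, localization
# jitter, mask perturbation, scores).

#' Scene configuration
#'
#' Defaults emulate the recorded study conditions: 1920x1080 frames,
#' about 370 bee-sized agents, 10-second sequences, and the 80% visibility
#' rule for ground-truth inclusion. The motion statistics (speed, heading
#' noise, inactive fraction) are order-of-magnitude choices derived from the
#' imaging geometry (40 cm field of view over 1920 px, a 13 mm bee body being
#' roughly 62 px long); no quantitative motion statistics are available for
#' dense hive scenes.
#'
#' @param frame_w,frame_h frame size in pixels.
#' @param n_agents number of agents.
#' @param fps frame rate in frames/second.
#' @param duration sequence length in seconds.
#' @param body_a,body_b ellipse half-axes in pixels (length, width).
#' @param speed_mean,speed_sd active-agent speed distribution in px/frame at
#'   the configured fps (per-agent base speed, truncated positive).
#' @param heading_sd per-frame heading noise, radians.
#' @param inactive_fraction fraction of agents in the near-stationary regime.
#' @param inactive_jitter_sd positional jitter of inactive agents, px/frame
#'   (displacement clamped to 1 px).
#' @param visibility_min agents whose visible (in-frame, un-occluded) pixel
#'   fraction falls below this are omitted from ground truth in that frame
#'   (mirrors the annotation rule of only labeling bodies over 80% visible).
#' @param n_vertices vertices of each ellipse polygon.
#' @param placement `"uniform"` random placement over the frame, or `"grid"`:
#'   each agent is confined to a private grid cell (reflecting cell walls),
#'   so the scene is well separated and occlusion-free by construction.
#' @param boundary `"reflect"` keeps agents inside the frame for the whole
#'   sequence (ids persist); `"exit"` lets agents wander out of frame and
#'   back, exercising track creation/deletion.
#' @param seed integer seed; the scene is deterministic given the config.
#' @return A `scene_config` object.
#' @export
scene_config <- function(frame_w = 1920, frame_h = 1080, n_agents = 370,
                         fps = 10, duration = 10,
                         body_a = 31, body_b = 11,
                         speed_mean = 4, speed_sd = 1.5,
                         heading_sd = 0.1,
                         inactive_fraction = 0.4,
                         inactive_jitter_sd = 0.15,
                         visibility_min = 0.8,
                         n_vertices = 20,
                         placement = c("uniform", "grid"),
                         boundary = c("reflect", "exit"),
                         seed = 1) {
  placement <- match.arg(placement)
  boundary <- match.arg(boundary)
  assert_that(is_count(n_agents, 1), "n_agents must be a positive integer")
  assert_that(body_a > 0 && body_b > 0 && body_b <= body_a,
              "half-axes must satisfy 0 < body_b <= body_a")
  assert_that(2 * body_a < min(frame_w, frame_h),
              "agent ellipse must fit inside the frame")
  assert_that(inactive_fraction >= 0 && inactive_fraction <= 1,
              "inactive_fraction must lie in [0, 1]")
  assert_that(visibility_min > 0 && visibility_min <= 1,
              "visibility_min must lie in (0, 1]")
  assert_that(is_count(n_vertices, 8), "need at least 8 ellipse vertices")
  structure(list(frame_w = frame_w, frame_h = frame_h, n_agents = n_agents,
                 fps = fps, duration = duration, body_a = body_a,
                 body_b = body_b, speed_mean = speed_mean,
                 speed_sd = speed_sd, heading_sd = heading_sd,
                 inactive_fraction = inactive_fraction,
                 inactive_jitter_sd = inactive_jitter_sd,
                 visibility_min = visibility_min, n_vertices = n_vertices,
                 placement = placement, boundary = boundary,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Well-separated benign scene configuration
#'
#' Convenience constructor for the benign tracking regime: agents confined to
#' private grid cells (occlusion-free for any duration) with gentle, bounded
#' motion (slow walking speed, small bounded turn rate). Under these bounds
#' the worst-case inter-frame box IoU of an agent — including a cell-wall
#' bounce, where the constant-velocity prediction overshoots by twice the
#' speed — stays comfortably above the 0.5 association gate, so a tracker fed
#' uncorrupted detections of such a scene preserves every identity by
#' construction.
#'
#' @inheritParams scene_config
#' @param ... further arguments passed to [scene_config()].
#' @return A `scene_config`.
#' @export
well_separated_scene <- function(n_agents = 20, fps = 10, duration = 10,
                                 seed = 1, ...) {
  scene_config(n_agents = n_agents, fps = fps, duration = duration,
               placement = "grid", speed_mean = 1.5, speed_sd = 0.5,
               heading_sd = 0.08, seed = seed, ...)
}

ellipse_ring <- function(cx, cy, a, b, heading, n_vertices) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ex <- a * cos(th); ey <- b * sin(th)
  cbind(cx + ex * cos(heading) - ey * sin(heading),
        cy + ex * sin(heading) + ey * cos(heading))
}

#' Simulate a dense-swarm ground-truth sequence
#'
#' Each agent advances along its heading with Gaussian heading noise
#' (inactive agents only jitter, at most 1 px/frame) and is rendered as an
#' oriented ellipse polygon aligned to its heading. Agents reflect off the
#' frame boundary (or exit, per the config). Per frame, agents are painted in
#' id order (higher id occludes lower); an agent whose visible (in-frame and
#' un-occluded) pixel fraction is below `visibility_min` is omitted from the
#' ground truth for that frame. Bounding boxes are the tight bounds of the
#' rasterized mask. Deterministic given the config seed.
#'
#' @param cfg a [scene_config()].
#' @return A [gt_sequence()]; each row additionally records the agent's
#'   activity regime in the attribute `"agent_regime"` (named logical vector,
#'   `TRUE` = inactive, indexed by agent id).
#' @export
simulate_scene <- function(cfg) {
  assert_that(inherits(cfg, "scene_config"), "cfg must be a scene_config")
  W <- cfg$frame_w; H <- cfg$frame_h; n <- cfg$n_agents
  nf <- as.integer(round(cfg$fps * cfg$duration))
  margin <- cfg$body_a
  with_local_seed(cfg$seed, {
    # reflection limits per agent: the frame for uniform placement; a private
    # cell for grid placement, so grid scenes stay occlusion-free (agents are
    # well separated by construction, for any duration)
    if (cfg$placement == "grid") {
      ncol_g <- ceiling(sqrt(n * W / H))
      nrow_g <- ceiling(n / ncol_g)
      cw <- W / ncol_g; ch <- H / nrow_g
      assert_that(cw > 2 * margin && ch > 2 * margin,
                  "grid placement: too many agents for private cells")
      cell <- cbind(col = (seq_len(n) - 1L) %% ncol_g,
                    row = (seq_len(n) - 1L) %/% ncol_g)
      lim <- cbind(x0 = cell[, 1] * cw + margin,
                   x1 = (cell[, 1] + 1) * cw - margin,
                   y0 = cell[, 2] * ch + margin,
                   y1 = (cell[, 2] + 1) * ch - margin)
      pos <- cbind((lim[, "x0"] + lim[, "x1"]) / 2,
                   (lim[, "y0"] + lim[, "y1"]) / 2)
    } else {
      lim <- cbind(x0 = rep(margin, n), x1 = rep(W - margin, n),
                   y0 = rep(margin, n), y1 = rep(H - margin, n))
      pos <- cbind(runif(n, margin, W - margin),
                   runif(n, margin, H - margin))
    }
    heading <- runif(n, 0, 2 * pi)
    # per-agent base speed, truncated to mean +- 2 sd (walking speeds are
    # bounded; keeps the worst-case inter-frame displacement finite)
    speed <- pmin(pmax(rnorm(n, cfg$speed_mean, cfg$speed_sd), 0.3),
                  cfg$speed_mean + 2 * cfg$speed_sd)
    inactive <- rep(FALSE, n)
    if (cfg$inactive_fraction > 0)
      inactive[sample.int(n, round(n * cfg$inactive_fraction))] <- TRUE
    rows <- vector("list", nf)
    for (f in seq_len(nf) - 1L) {
      rings <- lapply(seq_len(n), function(i)
        list(ellipse_ring(pos[i, 1], pos[i, 2], cfg$body_a, cfg$body_b,
                          heading[i], cfg$n_vertices)))
      vis <- cpp_paint_visibility(rings, W, H)
      frac <- ifelse(vis[, 1] > 0, vis[, 3] / vis[, 1], 0)
      keep <- which(frac >= cfg$visibility_min & vis[, 2] > 0)
      if (length(keep)) {
        rows[[f + 1L]] <- data.frame(
          frame = f, instance_id = keep,
          x = vis[keep, 4], y = vis[keep, 5],
          w = vis[keep, 6] - vis[keep, 4] + 1,
          h = vis[keep, 7] - vis[keep, 5] + 1,
          label = "b")
        rows[[f + 1L]]$mask <- lapply(keep, function(i)
          mask_poly(rings[[i]]))
      }
      # advance; heading steps are bounded uniform with the configured sd
      # (a body can only rotate so far in one frame)
      dh <- runif(n, -sqrt(3) * cfg$heading_sd, sqrt(3) * cfg$heading_sd)
      jit <- matrix(rnorm(2 * n, 0, cfg$inactive_jitter_sd), ncol = 2)
      jit <- pmin(pmax(jit, -1), 1)
      heading[!inactive] <- heading[!inactive] + dh[!inactive]
      step_x <- ifelse(inactive, jit[, 1], speed * cos(heading))
      step_y <- ifelse(inactive, jit[, 2], speed * sin(heading))
      pos[, 1] <- pos[, 1] + step_x
      pos[, 2] <- pos[, 2] + step_y
      if (cfg$boundary == "reflect") {
        for (d in 1:2) {
          b0 <- lim[, if (d == 1) "x0" else "y0"]
          b1 <- lim[, if (d == 1) "x1" else "y1"]
          lo <- pos[, d] < b0; hi <- pos[, d] > b1
          pos[lo, d] <- 2 * b0[lo] - pos[lo, d]
          pos[hi, d] <- 2 * b1[hi] - pos[hi, d]
          refl <- lo | hi
          if (any(refl))
            heading[refl] <- if (d == 1) pi - heading[refl]
                             else -heading[refl]
        }
      }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    objects <- if (length(rows)) do.call(rbind, rows) else
      data.frame(frame = integer(0), instance_id = integer(0),
                 x = numeric(0), y = numeric(0), w = numeric(0),
                 h = numeric(0), label = character(0), mask = I(list()))
    out <- gt_sequence(objects, cfg$fps, W, H, nf)
    attr(out, "agent_regime") <- setNames(inactive, seq_len(n))
    out
  })
}

#' Detector corruption configuration
#'
#' Parameterizes the synthetic detector-noise model that turns a ground-truth
#' sequence into realistic detections: independent misses, center
#' localization jitter, mask boundary perturbation, spurious detections, and
#' confidence scores.
#'
#' @param miss_rate probability that a true object is dropped.
#' @param fp_rate expected number of spurious detections per frame
#'   (Poisson).
#' @param jitter_sd standard deviation of the box/mask center jitter, px.
#' @param mask_erode_dilate maximum radial mask boundary perturbation, px
#'   (each mask is grown or shrunk by a uniform draw in +-this amount).
#' @param score_mean,score_sd confidence score distribution (normal, clipped
#'   to `[0, 1]`).
#' @param seed integer seed; corruption is deterministic given config and
#'   input.
#' @return A `corruption_config` object.
#' @export
corruption_config <- function(miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                              mask_erode_dilate = 0,
                              score_mean = 0.9, score_sd = 0.05, seed = 1) {
  assert_that(miss_rate >= 0 && miss_rate <= 1,
              "miss_rate must lie in [0, 1]")
  assert_that(fp_rate >= 0, "fp_rate must be nonnegative")
  assert_that(jitter_sd >= 0 && mask_erode_dilate >= 0,
              "noise magnitudes must be nonnegative")
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd,
                 mask_erode_dilate = mask_erode_dilate,
                 score_mean = score_mean, score_sd = score_sd,
                 seed = as.integer(seed)),
            class = "corruption_config")
}

#' Corrupt a ground-truth sequence into detections
#'
#' Each object is independently dropped with probability `miss_rate`;
#' survivors receive Gaussian center jitter and a radial mask perturbation,
#' and their boxes are recomputed as the tight bounds of the perturbed mask.
#' `Poisson(fp_rate)` spurious elliptical detections are added per frame at
#' random positions. Scores are sampled and clipped to `[0, 1]`; instance ids
#' are stripped.
#'
#' The miss decision consumes one uniform draw per object before any other
#' randomness, so runs with the same seed and increasing `miss_rate` are
#' monotonically coupled: an object dropped at rate p is dropped at every
#' rate above p.
#'
#' @param gt a [gt_sequence()].
#' @param cfg a [corruption_config()].
#' @return A [det_sequence()].
#' @export
corrupt_detections <- function(gt, cfg) {
  assert_that(inherits(gt, "gt_sequence"), "gt must be a gt_sequence")
  assert_that(inherits(cfg, "corruption_config"),
              "cfg must be a corruption_config")
  W <- frame_width(gt); H <- frame_height(gt)
  gt_df <- as.data.frame(gt)
  n <- nrow(gt_df)
  with_local_seed(cfg$seed, {
    miss_u <- runif(n)
    jit <- matrix(rnorm(2 * n, 0, cfg$jitter_sd), ncol = 2)
    grow <- runif(n, -cfg$mask_erode_dilate, cfg$mask_erode_dilate)
    scores <- pmin(pmax(rnorm(n, cfg$score_mean, cfg$score_sd), 0), 1)
    keep <- which(miss_u >= cfg$miss_rate)
    out <- gt_df[keep, c("frame", "x", "y", "w", "h", "label"), drop = FALSE]
    out$score <- scores[keep]
    masks <- vector("list", length(keep))
    for (k in seq_along(keep)) {
      i <- keep[k]
      m <- gt_df$mask[[i]]
      if (cfg$jitter_sd > 0) m <- shift_mask(m, jit[i, 1], jit[i, 2])
      if (cfg$mask_erode_dilate > 0) {
        cx <- out$x[k] + out$w[k] / 2 + jit[i, 1]
        cy <- out$y[k] + out$h[k] / 2 + jit[i, 2]
        reff <- sqrt(out$w[k] * out$h[k] / pi)
        m <- scale_mask(m, max(0.2, (reff + grow[i]) / reff), c(cx, cy))
      }
      if (cfg$jitter_sd > 0 || cfg$mask_erode_dilate > 0) {
        tb <- mask_tight_bbox(m, W, H)
        if (is.null(tb)) { masks[k] <- list(NULL); next }
        out$x[k] <- tb[[1]]; out$y[k] <- tb[[2]]
        out$w[k] <- tb[[3]]; out$h[k] <- tb[[4]]
      }
      masks[[k]] <- m
    }
    out$mask <- masks
    drop_empty <- vapply(masks, is.null, logical(1))
    out <- out[!drop_empty, , drop = FALSE]
    # spurious detections
    if (cfg$fp_rate > 0 && n_frames(gt) > 0) {
      med_w <- if (n > 0) median(gt_df$w) else 60
      med_h <- if (n > 0) median(gt_df$h) else 30
      a0 <- med_w / 2; b0 <- max(med_h / 2, a0 / 3)
      fp_rows <- list()
      for (f in seq_len(n_frames(gt)) - 1L) {
        nfp <- rpois(1, cfg$fp_rate)
        for (k in seq_len(nfp)) {
          cx <- runif(1, a0, W - a0); cy <- runif(1, a0, H - a0)
          hd <- runif(1, 0, 2 * pi)
          m <- mask_poly(ellipse_ring(cx, cy, a0, b0, hd, 16))
          tb <- mask_tight_bbox(m, W, H)
          if (is.null(tb)) next
          fp_rows[[length(fp_rows) + 1L]] <- data.frame(
            frame = f, x = tb[[1]], y = tb[[2]], w = tb[[3]], h = tb[[4]],
            label = "b",
            score = pmin(pmax(rnorm(1, cfg$score_mean, cfg$score_sd), 0), 1),
            mask = I(list(m)))
        }
      }
      if (length(fp_rows)) out <- rbind(out, do.call(rbind, fp_rows))
    }
    det_sequence(out, seq_fps(gt), W, H, n_frames(gt))
  })
}
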