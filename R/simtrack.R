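#' Default zone geometry for a simulated pen
#'
#' Rectangular stand-ins for the zone sketches of a top-down litter-area
#' camera: an exclusion strip along the left edge (ramp / upper levels),
#' a green strip next to it (exits), a yellow margin around the image
#' periphery, and a central focal rectangle.
#'
#' @param resolution `c(width, height)` in pixels.
#' @return a [zone_set()].
#' @export
default_zone_set <- function(resolution = c(2304, 1296)) {
  w <- resolution[1L]
  h <- resolution[2L]
  excl_w <- round(0.08 * w)
  green_w <- round(0.10 * w)
  margin <- round(0.12 * min(w, h))
  zone_set(
    focal = rect_poly(excl_w + green_w + margin, margin, w - margin, h - margin),
    yellow = rect_poly(excl_w + green_w, 0, w, h),
    green = rect_poly(excl_w, 0, excl_w + green_w, h),
    exclusion = rect_poly(0, 0, excl_w, h)
  )
}

#' Configuration of the frame-level tracking simulator
#'
#' The simulator is a stand-in for the physical recording chain, not a
#' model of real hen dynamics: each bird follows an independent
#' correlated random walk with Gaussian steps and reflecting boundaries,
#' leaves the camera's field of view according to an alternating renewal
#' process (exponential on/off dwell times), and suffers occlusion
#' episodes plus per-frame detection flicker while present. Detection
#' artifacts (impossibly large markers, same-millisecond duplicates,
#' unregistered marker ids, teleport jumps) are injected at configurable
#' rates and flagged in the ground truth.
#'
#' @param fps frames per second (default 20).
#' @param px_per_cm pixel-to-centimetre conversion (default 8).
#' @param resolution `c(width, height)` of the frame in pixels.
#' @param zones a [zone_set()]; defaults to [default_zone_set()].
#' @param marker_side_px side length of the emitted marker square.
#' @param step_sd_cm per-frame standard deviation of the random-walk step
#'   (cm); `step_rho` is the velocity autocorrelation of the walk.
#' @param away_rate rate (per second) of leaving the recordable area;
#'   `away_mean_s` mean off-camera dwell (seconds).
#' @param occlusion_rate rate (per second) of occlusion episodes while
#'   present; `occlusion_mean_s` mean episode length.
#' @param flicker_prob per-frame probability of a missed detection while
#'   present and unoccluded; `edge_dropout_prob` additional per-frame
#'   miss probability while in the yellow zone.
#' @param giant_rate,dup_rate,unregistered_rate,teleport_rate expected
#'   artifact counts per bird-hour.
#' @param bounds optional movement bounding rectangle `c(x0, y0, x1, y1)`
#'   (e.g. the focal rectangle, to pin birds to one zone); defaults to
#'   the recordable area right of the exclusion strip.
#' @return object of class `tracking_sim_config`.
#' @export
tracking_sim_config <- function(fps = 20, px_per_cm = 8,
                                resolution = c(2304, 1296),
                                zones = NULL,
                                marker_side_px = 32,
                                step_sd_cm = 0.18, step_rho = 0.8,
                                away_rate = 1 / 340, away_mean_s = 60,
                                occlusion_rate = 1 / 25, occlusion_mean_s = 20,
                                flicker_prob = 0.10, edge_dropout_prob = 0.30,
                                giant_rate = 0, dup_rate = 0,
                                unregistered_rate = 0, teleport_rate = 0,
                                bounds = NULL) {
  if (fps <= 0) abort("`fps` must be positive.")
  probs <- c(flicker_prob, edge_dropout_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  if (any(c(away_rate, away_mean_s, occlusion_rate, occlusion_mean_s,
            giant_rate, dup_rate, unregistered_rate, teleport_rate) < 0)) {
    abort("rates must be non-negative.")
  }
  if (is.null(zones)) zones <- default_zone_set(resolution)
  if (is.null(bounds)) {
    x0 <- max(zones$exclusion[, 1L]) %||% 0
    bounds <- c(x0 + 1, 1, resolution[1L] - 1, resolution[2L] - 1)
  }
  structure(
    list(fps = fps, px_per_cm = px_per_cm, resolution = resolution,
         zones = zones, marker_side_px = marker_side_px,
         step_sd_cm = step_sd_cm, step_rho = step_rho,
         away_rate = away_rate, away_mean_s = away_mean_s,
         occlusion_rate = occlusion_rate, occlusion_mean_s = occlusion_mean_s,
         flicker_prob = flicker_prob, edge_dropout_prob = edge_dropout_prob,
         giant_rate = giant_rate, dup_rate = dup_rate,
         unregistered_rate = unregistered_rate, teleport_rate = teleport_rate,
         bounds = bounds),
    class = "tracking_sim_config"
  )
}

# alternating renewal process: episodes of "state on" (e.g. away, occluded)
# returns logical vector of length n_frames (TRUE = state active)
renewal_episodes <- function(n_frames, fps, rate_per_s, mean_dur_s) {
  state <- rep(FALSE, n_frames)
  if (rate_per_s <= 0 || mean_dur_s <= 0 || n_frames == 0L) return(state)
  t <- 0
  total_s <- n_frames / fps
  repeat {
    t <- t + rexp(1L, rate_per_s)
    if (t >= total_s) break
    dur <- rexp(1L, 1 / mean_dur_s)
    f0 <- floor(t * fps) + 1L
    f1 <- min(n_frames, floor((t + dur) * fps))
    if (f1 >= f0) state[f0:f1] <- TRUE
    t <- t + dur
  }
  state
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  if (width <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * width)
  y <- ifelse(y > width, 2 * width - y, y)
  y + lo
}

#' Simulate a raw detection stream with ground truth
#'
#' Emits one row per detected marker per frame in the raw-stream dialect
#' (`marker_id, c1x..c4y, frame, pen, timestamp`), plus the full ground
#' truth needed to audit downstream modules: true per-frame positions and
#' states, presence/occlusion episodes, and flags for every injected
#' artifact row. Marker squares are emitted axis-aligned; centre and
#' shoelace area are rotation-invariant so downstream maths is
#' unaffected.
#'
#' @param config a [tracking_sim_config()].
#' @param roster tibble with columns `wingtag`, `pen`, `marker_id`.
#' @param n_hours recorded hours per pen (consecutive wall-clock hours).
#' @param minutes_per_hour recorded minutes within each hour (default 60;
#'   smaller values give desk-scale streams).
#' @param seed integer seed.
#' @param start_time POSIXct start of the first hour.
#' @return list with `detections` (tibble; extra column `artifact` is
#'   `NA` for genuine rows), `truth` (list: `states` per bird-frame with
#'   presence/occlusion/detection flags and true positions, `schedule`
#'   of recorded minutes per pen-day-hour) and `config`.
#' @export
simulate_tracking_stream <- function(config, roster, n_hours = 1,
                                     minutes_per_hour = 60, seed = 1L,
                                     start_time = as.POSIXct("2026-04-18 07:00:00",
                                                             tz = "UTC")) {
  stopifnot(inherits(config, "tracking_sim_config"))
  roster <- as_tibble(roster)
  if (nrow(roster) == 0L) abort("empty roster.")
  if (anyDuplicated(roster[, c("pen", "marker_id")])) {
    abort("marker ids must be unique within pen.")
  }
  fps <- config$fps
  frames_per_hour <- as.integer(round(minutes_per_hour * 60 * fps))
  hour_stride <- as.integer(round(3600 * fps))
  set.seed(as.integer(seed))

  half <- config$marker_side_px / 2
  zs <- config$zones
  b <- config$bounds
  step_sd_px <- config$step_sd_cm * config$px_per_cm

  all_det <- list()
  all_states <- list()
  for (bi in seq_len(nrow(roster))) {
    wt <- roster$wingtag[bi]
    pen <- roster$pen[bi]
    mid <- roster$marker_id[bi]
    for (h in seq_len(n_hours)) {
      nf <- frames_per_hour
      frame0 <- (h - 1L) * hour_stride
      # correlated random walk with reflecting bounds
      vx <- stats::filter(rnorm(nf, 0, step_sd_px * sqrt(1 - config$step_rho^2)),
                          config$step_rho, method = "recursive")
      vy <- stats::filter(rnorm(nf, 0, step_sd_px * sqrt(1 - config$step_rho^2)),
                          config$step_rho, method = "recursive")
      x <- reflect_into(runif(1L, b[1L], b[3L]) + cumsum(as.numeric(vx)), b[1L], b[3L])
      y <- reflect_into(runif(1L, b[2L], b[4L]) + cumsum(as.numeric(vy)), b[2L], b[4L])
      away <- renewal_episodes(nf, fps, config$away_rate, config$away_mean_s)
      occl <- renewal_episodes(nf, fps, config$occlusion_rate, config$occlusion_mean_s)
      zone <- classify_zone(x, y, zs)
      miss_p <- config$flicker_prob +
        ifelse(!is.na(zone) & zone == "yellow", config$edge_dropout_prob, 0)
      flick <- runif(nf) < miss_p
      detected <- !away & !occl & !flick
      st <- tibble(
        wingtag = wt, pen = pen, frame = frame0 + seq_len(nf) - 1L,
        x = x, y = y, present = !away, occluded = occl, detected = detected,
        hour = h
      )
      all_states[[length(all_states) + 1L]] <- st
      if (any(detected)) {
        dx <- x[detected]; dy <- y[detected]
        det <- tibble(
          marker_id = mid,
          c1x = dx - half, c1y = dy - half,
          c2x = dx + half, c2y = dy - half,
          c3x = dx + half, c3y = dy + half,
          c4x = dx - half, c4y = dy + half,
          frame = st$frame[detected],
          pen = pen,
          artifact = NA_character_
        )
        all_det[[length(all_det) + 1L]] <- det
      }
    }
  }
  det <- bind_rows(all_det)
  states <- bind_rows(all_states)

  # ---- artifact injection -------------------------------------------------
  n_bird_hours <- nrow(roster) * n_hours
  art <- list()
  mk_square <- function(cx, cy, side) {
    tibble(c1x = cx - side / 2, c1y = cy - side / 2,
           c2x = cx + side / 2, c2y = cy - side / 2,
           c3x = cx + side / 2, c3y = cy + side / 2,
           c4x = cx - side / 2, c4y = cy + side / 2)
  }
  n_giant <- stats::rpois(1L, config$giant_rate * n_bird_hours)
  if (n_giant > 0) {
    rows <- roster[sample.int(nrow(roster), n_giant, replace = TRUE), ]
    sq <- mk_square(runif(n_giant, b[1L], b[3L]), runif(n_giant, b[2L], b[4L]),
                    config$marker_side_px * runif(n_giant, 15, 30))
    art[[length(art) + 1L]] <- bind_cols(
      tibble(marker_id = rows$marker_id), sq,
      tibble(frame = sample.int(frames_per_hour, n_giant, replace = TRUE) - 1L,
             pen = rows$pen, artifact = "giant_marker")
    )
  }
  n_unreg <- stats::rpois(1L, config$unregistered_rate * n_bird_hours)
  if (n_unreg > 0) {
    pens <- sample(unique(roster$pen), n_unreg, replace = TRUE)
    sq <- mk_square(runif(n_unreg, b[1L], b[3L]), runif(n_unreg, b[2L], b[4L]),
                    config$marker_side_px)
    art[[length(art) + 1L]] <- bind_cols(
      tibble(marker_id = max(roster$marker_id) + sample.int(50L, n_unreg, TRUE)),
      sq,
      tibble(frame = sample.int(frames_per_hour, n_unreg, replace = TRUE) - 1L,
             pen = pens, artifact = "unregistered")
    )
  }
  if (nrow(det) > 0) {
    n_dup <- min(stats::rpois(1L, config$dup_rate * n_bird_hours), nrow(det))
    if (n_dup > 0) {
      src <- det[sample.int(nrow(det), n_dup), ]
      shift <- runif(n_dup, 200, 600) * sample(c(-1, 1), n_dup, TRUE)
      dup <- src
      dup[, c("c1x", "c2x", "c3x", "c4x")] <-
        dup[, c("c1x", "c2x", "c3x", "c4x")] + shift
      dup$artifact <- "millisecond_duplicate"
      art[[length(art) + 1L]] <- dup
    }
    n_tel <- min(stats::rpois(1L, config$teleport_rate * n_bird_hours), nrow(det))
    if (n_tel > 0) {
      idx <- sample.int(nrow(det), n_tel)
      jump <- runif(n_tel, 800, 1500) * sample(c(-1, 1), n_tel, TRUE)
      det[idx, c("c1x", "c2x", "c3x", "c4x")] <-
        det[idx, c("c1x", "c2x", "c3x", "c4x")] + jump
      det$artifact[idx] <- "teleport"
    }
  }
  det <- bind_rows(c(list(det), art))

  # a pixel detector cannot report coordinates outside the frame
  for (cc in c("c1x", "c2x", "c3x", "c4x")) {
    det[[cc]] <- pmin(pmax(det[[cc]], 0), config$resolution[1L])
  }
  for (cc in c("c1y", "c2y", "c3y", "c4y")) {
    det[[cc]] <- pmin(pmax(det[[cc]], 0), config$resolution[2L])
  }

  det$timestamp <- start_time + det$frame / fps
  det <- arrange(det, .data$pen, .data$frame, .data$marker_id)
  det <- det[, c("marker_id", "c1x", "c1y", "c2x", "c2y", "c3x", "c3y",
                 "c4x", "c4y", "frame", "pen", "timestamp", "artifact")]

  schedule <- distinct(states, .data$pen, .data$hour) |>
    mutate(
      day = as.Date(start_time + (.data$hour - 1L) * 3600, tz = "UTC"),
      hour_of_day = as.integer(format(start_time + (.data$hour - 1L) * 3600,
                                      "%H", tz = "UTC")),
      recorded_minutes = minutes_per_hour
    ) |>
    select("pen", "day", hour = "hour_of_day", "recorded_minutes")

  states$timestamp <- start_time + states$frame / fps
  list(detections = det, truth = list(states = states, schedule = schedule),
       config = config)
}

#' Write a detection stream in the raw CSV dialect
#'
#' Drops any auxiliary columns (e.g. the simulator's `artifact` flag) and
#' writes `marker_id, c1x..c4y, frame, pen, timestamp` with millisecond
#' ISO-8601 timestamps.
#'
#' @param detections detection tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  cols <- c("marker_id", "c1x", "c1y", "c2x", "c2y", "c3x", "c3y",
            "c4x", "c4y", "frame", "pen", "timestamp")
  out <- detections[, cols]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}
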