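#' Segment detection runs
#'
#' Splits each bird's ordered detection frames into maximal runs in which
#' consecutive detections are separated by fewer than `gap_tolerance`
#' missing frames. With the default tolerance of 70 frames (3.5 s at
#' 20 fps) a run is not broken by dropouts shorter than a qualifying
#' detection-loss event; `gap_tolerance = 1` gives strictly consecutive
#' frames.
#'
#' @param detections tibble with at least `wingtag`, `pen`, `frame`
#'   (sorted by frame within bird; unsorted input is an error).
#' @param gap_tolerance maximum number of missing frames bridged inside
#'   a run (default 70).
#' @return tibble of runs: `pen`, `wingtag`, `run`, `start_frame`,
#'   `end_frame`, `n_detected_frames`.
#' @export
segment_runs <- function(detections, gap_tolerance = 70) {
  if (gap_tolerance < 1) abort("`gap_tolerance` must be >= 1 frame.")
  det <- as_tibble(detections)
  if (nrow(det) == 0L) {
    return(tibble(pen = character(), wingtag = character(), run = integer(),
                  start_frame = integer(), end_frame = integer(),
                  n_detected_frames = integer()))
  }
  det |>
    group_by(.data$pen, .data$wingtag) |>
    group_modify(function(d, key) {
      f <- unique(d$frame)
      if (is.unsorted(f)) abort("detections must be sorted by frame within bird.")
      gap <- c(0L, diff(f)) - 1L          # missing frames before each detection
      run_id <- cumsum(gap >= gap_tolerance) + 1L
      tibble(
        run = unique(run_id),
        start_frame = as.integer(tapply(f, run_id, min)),
        end_frame = as.integer(tapply(f, run_id, max)),
        n_detected_frames = as.integer(tapply(f, run_id, length))
      )
    }) |>
    ungroup()
}

#' Duration of a detection-loss event
#'
#' The time span between the frame where a bird was last seen and the
#' frame where it was re-detected, as the frame-index difference over the
#' frame rate: a bird last seen in frame 5 and re-detected in frame 75 at
#' 20 fps was lost for (75 - 5) / 20 = 3.5 seconds.
#'
#' @param last_seen_frame,reappear_frame frame indices
#'   (`reappear_frame > last_seen_frame`).
#' @param fps frames per second.
#' @return duration in seconds (vectorised).
#' @export
dle_duration <- function(last_seen_frame, reappear_frame, fps = 20) {
  if (fps <= 0) abort("`fps` must be positive.")
  if (any(reappear_frame <= last_seen_frame)) {
    abort("`reappear_frame` must exceed `last_seen_frame`.")
  }
  (reappear_frame - last_seen_frame) / fps
}

#' Categorize a detection gap by its endpoint zones
#'
#' `Away` when neither the disappearance nor the reappearance lies in the
#' focal zone (the bird most likely left the detectable area); `Focal`
#' when both do (loss under optimal conditions, i.e. occlusion or
#' detection-power limits); `Uncertain` otherwise.
#'
#' @param disappear_zone,reappear_zone character vectors with values in
#'   `"green"`, `"yellow"`, `"focal"`.
#' @return character vector `"Away"`, `"Uncertain"` or `"Focal"` (`NA`
#'   when an endpoint zone is `NA`).
#' @export
categorize_gap <- function(disappear_zone, reappear_zone) {
  ok <- c("green", "yellow", "focal")
  bad <- (!disappear_zone %in% ok | !reappear_zone %in% ok) &
    !(is.na(disappear_zone) | is.na(reappear_zone))
  if (any(bad)) abort("zones must be one of 'green', 'yellow', 'focal'.")
  dplyr::case_when(
    is.na(disappear_zone) | is.na(reappear_zone) ~ NA_character_,
    disappear_zone == "focal" & reappear_zone == "focal" ~ "Focal",
    disappear_zone != "focal" & reappear_zone != "focal" ~ "Away",
    TRUE ~ "Uncertain"
  )
}

#' Detect and classify detection-loss events
#'
#' Every gap between consecutive detection runs of a bird becomes an
#' event carrying the positions and zones of disappearance and
#' reappearance, its duration and its category. The `qualified` flag
#' marks events satisfying the study definition: a non-detection span of
#' at least `min_gap_frames` frames (reappear - last_seen, default 70,
#' i.e. 3.5 s at 20 fps) preceded by a run of at least
#' `min_prior_run_frames` detected frames (default 1200, one minute).
#'
#' @param detections filtered detection tibble (`wingtag`, `pen`,
#'   `frame`, `center_x`, `center_y`).
#' @param zones a [zone_set()].
#' @param fps frames per second.
#' @param gap_tolerance run-segmentation tolerance (see
#'   [segment_runs()]).
#' @param min_gap_frames,min_prior_run_frames qualification thresholds.
#' @return tibble of events: identities, boundary frames and positions,
#'   zones, `duration_s`, `category`, `qualified`.
#' @export
detect_dles <- function(detections, zones, fps = 20, gap_tolerance = 70,
                        min_gap_frames = 70, min_prior_run_frames = 1200) {
  det <- as_tibble(detections)
  need <- c("wingtag", "pen", "frame", "center_x", "center_y")
  if (!all(need %in% names(det))) {
    abort("detections need columns wingtag, pen, frame, center_x, center_y.")
  }
  runs <- segment_runs(det, gap_tolerance = gap_tolerance)
  if (nrow(runs) == 0L) return(empty_dle_table())
  pos_key <- paste(det$pen, det$wingtag, det$frame)
  lookup <- function(pens, wts, frames, col) {
    i <- match(paste(pens, wts, frames), pos_key)
    if (anyNA(i)) abort("position missing at a run boundary frame.")
    det[[col]][i]
  }
  ev <- runs |>
    group_by(.data$pen, .data$wingtag) |>
    mutate(
      next_start = lead(.data$start_frame),
      prior_frames = .data$n_detected_frames
    ) |>
    ungroup() |>
    filter(!is.na(.data$next_start))
  if (nrow(ev) == 0L) return(empty_dle_table())
  out <- tibble(
    pen = ev$pen,
    wingtag = ev$wingtag,
    last_seen_frame = ev$end_frame,
    reappear_frame = ev$next_start,
    duration_s = dle_duration(ev$end_frame, ev$next_start, fps),
    disappear_x = lookup(ev$pen, ev$wingtag, ev$end_frame, "center_x"),
    disappear_y = lookup(ev$pen, ev$wingtag, ev$end_frame, "center_y"),
    reappear_x = lookup(ev$pen, ev$wingtag, ev$next_start, "center_x"),
    reappear_y = lookup(ev$pen, ev$wingtag, ev$next_start, "center_y"),
    prior_run_frames = ev$prior_frames
  )
  out$disappear_zone <- classify_zone(out$disappear_x, out$disappear_y, zones)
  out$reappear_zone <- classify_zone(out$reappear_x, out$reappear_y, zones)
  out$category <- categorize_gap(out$disappear_zone, out$reappear_zone)
  out$qualified <- (out$reappear_frame - out$last_seen_frame) >= min_gap_frames &
    out$prior_run_frames >= min_prior_run_frames
  out
}

empty_dle_table <- function() {
  tibble(pen = character(), wingtag = character(),
         last_seen_frame = integer(), reappear_frame = integer(),
         duration_s = numeric(), disappear_x = numeric(),
         disappear_y = numeric(), reappear_x = numeric(),
         reappear_y = numeric(), prior_run_frames = integer(),
         disappear_zone = character(), reappear_zone = character(),
         category = character(), qualified = logical())
}

#' Minutes detected per hour
#'
#' Minutes are the number of detected frames over `fps * 60`; the trait
#' value is the square root of the minutes.
#'
#' @param n_detected_frames frame counts (vectorised, >= 0).
#' @param fps frames per second.
#' @return tibble with `minutes` and `mdh` (sqrt minutes).
#' @export
compute_mdh <- function(n_detected_frames, fps = 20) {
  if (any(n_detected_frames < 0)) abort("negative frame count.")
  minutes <- n_detected_frames / (fps * 60)
  tibble(minutes = minutes, mdh = sqrt(minutes))
}

#' Walking speed within an hour
#'
#' Sums Euclidean distances between successive detections of a bird,
#' excluding steps that span a detection-loss gap of at least
#' `min_gap_frames` frames (the teleport between disappearance and
#' reappearance is not walking), converts pixels to centimetres, divides
#' by the raw minutes detected and square-root transforms.
#'
#' @param positions tibble with `frame`, `x`, `y`, sorted by frame, for
#'   one bird-hour.
#' @param minutes_detected_raw raw minutes detected in the hour (> 0).
#' @param px_per_cm pixel-to-centimetre conversion (default 8).
#' @param min_gap_frames steps spanning at least this many frames are
#'   excluded from the path (default 70).
#' @return list with `path_cm`, `speed_raw` (cm/min) and `wsh`
#'   (sqrt(cm/min)).
#' @export
compute_wsh <- function(positions, minutes_detected_raw, px_per_cm = 8,
                        min_gap_frames = 70) {
  if (minutes_detected_raw <= 0) {
    abort("walking speed undefined for zero detected minutes; code the record missing.")
  }
  f <- positions$frame
  if (is.unsorted(f)) abort("positions must be sorted by frame.")
  if (length(f) < 2L) {
    return(list(path_cm = 0, speed_raw = 0, wsh = 0))
  }
  step <- sqrt(diff(positions$x)^2 + diff(positions$y)^2)
  keep <- diff(f) < min_gap_frames
  path_cm <- sum(step[keep]) / px_per_cm
  speed <- path_cm / minutes_detected_raw
  list(path_cm = path_cm, speed_raw = speed, wsh = sqrt(speed))
}

# ---- hourly accounting ----------------------------------------------------

floor_hour <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 3600) * 3600,
             origin = "1970-01-01", tz = "UTC")
}

# split detections into bird-day-hour groups with within-hour frame offsets
hourly_groups <- function(det, fps) {
  hstart <- floor_hour(det$timestamp)
  det$day <- as.Date(hstart)
  det$hour <- as.integer(format(hstart, "%H", tz = "UTC"))
  det$offset <- as.integer(round(as.numeric(det$timestamp - hstart,
                                            units = "secs") * fps))
  det
}

#' Hourly time budget
#'
#' Partitions every recorded bird-day-hour into the proportion of time
#' detected and, for the non-detected remainder, the Away / Uncertain /
#' Focal categories of the gap covering it plus an `unclassified` bucket
#' for time without classifiable endpoints (before the first and after
#' the last detection of the hour). All gaps between consecutive
#' detections are endpoint-categorized, so the five shares sum to one
#' exactly. Hours in the schedule with no detections at all are fully
#' `unclassified`.
#'
#' @param detections filtered detection tibble (`wingtag`, `pen`,
#'   `frame`, `timestamp`, `center_x`, `center_y`).
#' @param zones a [zone_set()].
#' @param schedule tibble `pen, day, hour, recorded_minutes`; every bird
#'   of a pen is accountable for every scheduled hour of that pen.
#' @param roster tibble `pen, wingtag` (birds accountable per pen).
#' @param fps frames per second.
#' @return tibble with one row per bird-day-hour and columns `detected`,
#'   `away`, `uncertain`, `focal`, `unclassified` (proportions) plus
#'   `n_detected_frames` and `n_focal_dles` (focal-category gap count).
#' @export
hourly_time_budget <- function(detections, zones, schedule, roster,
                               fps = 20) {
  det <- hourly_groups(as_tibble(detections), fps)
  sched <- as_tibble(schedule)
  if (any(sched$recorded_minutes <= 0)) abort("recorded minutes must be positive.")
  roster <- distinct(as_tibble(roster)[, c("pen", "wingtag")])
  base <- inner_join(sched, roster, by = "pen", relationship = "many-to-many")

  det <- inner_join(det, sched, by = c("pen", "day", "hour"))
  per_group <- det |>
    group_by(.data$pen, .data$wingtag, .data$day, .data$hour) |>
    group_modify(function(d, key) {
      slots <- as.integer(round(d$recorded_minutes[1L] * 60 * fps))
      d <- arrange(d, .data$offset)
      d <- d[!duplicated(d$offset), ]
      ofs <- d$offset
      x <- d$center_x
      y <- d$center_y
      n_det <- length(unique(ofs))
      if (max(ofs) > slots - 1L) {
        abort("detected minutes exceed the recorded minutes of the hour.")
      }
      gap_len <- diff(ofs) - 1L
      gi <- which(gap_len > 0L)
      cat_time <- c(Away = 0L, Uncertain = 0L, Focal = 0L)
      n_focal <- 0L
      if (length(gi) > 0L) {
        z1 <- classify_zone(x[gi], y[gi], zones)
        z2 <- classify_zone(x[gi + 1L], y[gi + 1L], zones)
        cat <- categorize_gap(z1, z2)
        for (cc in names(cat_time)) {
          cat_time[cc] <- sum(gap_len[gi][!is.na(cat) & cat == cc])
        }
        unclass_gap <- sum(gap_len[gi][is.na(cat)])
        n_focal <- sum(!is.na(cat) & cat == "Focal")
      } else {
        unclass_gap <- 0L
      }
      edge <- min(ofs) + (slots - 1L - max(ofs))
      tibble(
        n_detected_frames = n_det,
        detected = n_det / slots,
        away = cat_time[["Away"]] / slots,
        uncertain = cat_time[["Uncertain"]] / slots,
        focal = cat_time[["Focal"]] / slots,
        unclassified = (edge + unclass_gap) / slots,
        n_focal_dles = n_focal
      )
    }) |>
    ungroup()

  out <- left_join(base, per_group,
                   by = c("pen", "wingtag", "day", "hour"))
  empty <- is.na(out$detected)
  out$n_detected_frames[empty] <- 0L
  out$detected[empty] <- 0
  out$away[empty] <- 0
  out$uncertain[empty] <- 0
  out$focal[empty] <- 0
  out$unclassified[empty] <- 1
  out$n_focal_dles[empty] <- 0L
  out
}

#' Aggregate hourly time budgets
#'
#' Hourly proportions are averaged within each individual over its
#' recorded hours (all days), then the individual means are averaged
#' across individuals, both unweighted. The mean hourly count of
#' focal-zone disappearance events per individual is carried along.
#'
#' @param budgets output of [hourly_time_budget()].
#' @return list with `individual` (one row per wingtag) and `population`
#'   (one-row tibble of means).
#' @export
aggregate_time_budget <- function(budgets) {
  shares <- c("detected", "away", "uncertain", "focal", "unclassified")
  individual <- budgets |>
    group_by(.data$pen, .data$wingtag) |>
    summarise(across(all_of(c(shares, "n_focal_dles")), mean),
              n_hours = dplyr::n(), .groups = "drop")
  population <- individual |>
    summarise(across(all_of(c(shares, "n_focal_dles")), mean))
  list(individual = individual, population = population)
}

#' Assemble the hourly phenotype table
#'
#' One row per rostered bird per scheduled pen-day-hour with the three
#' traits: `dh01` is 1 when the bird had at least one detection run of
#' `min_prior_run_frames` (default 1200) detected frames within the hour,
#' `mdh` is the square root of the minutes detected (Eq.-style frame
#' count over `fps * 60`), and `wsh` the square root of the average
#' walking speed (cm/min). When `dh01` is 0, `mdh` and `wsh` are coded
#' missing. Runs are split at wall-clock hour boundaries, so each hour
#' is accounted on its own.
#'
#' @inheritParams hourly_time_budget
#' @param px_per_cm pixel-to-centimetre conversion (default 8).
#' @param gap_tolerance run-segmentation tolerance in frames.
#' @param min_gap_frames step-exclusion / DLE threshold in frames.
#' @param min_prior_run_frames detected-frame count a run needs for
#'   `dh01 = 1` (default 1200 = one minute at 20 fps).
#' @return tibble with columns `marker_id` (when present in the roster),
#'   `wingtag`, `hour`, `pen`, `day`, `dh01`, `minutes_detected`, `mdh`,
#'   `path_cm`, `speed_cm_min`, `wsh`.
#' @export
assemble_phenotypes <- function(detections, schedule, roster, fps = 20,
                                px_per_cm = 8, gap_tolerance = 70,
                                min_gap_frames = 70,
                                min_prior_run_frames = 1200) {
  det <- hourly_groups(as_tibble(detections), fps)
  sched <- as_tibble(schedule)
  roster <- as_tibble(roster)
  base <- inner_join(sched, distinct(roster[, intersect(
    c("pen", "wingtag", "marker_id"), names(roster))]),
    by = "pen", relationship = "many-to-many")
  if (anyDuplicated(base[, c("wingtag", "day", "hour")])) {
    abort("conflicting duplicate bird-day-hour keys.")
  }

  per_group <- det |>
    group_by(.data$pen, .data$wingtag, .data$day, .data$hour) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$offset)
      d <- d[!duplicated(d$offset), ]
      n_det <- nrow(d)
      # runs within the hour (offsets restart at each hour boundary)
      gap <- c(0L, diff(d$offset)) - 1L
      run <- cumsum(gap >= gap_tolerance) + 1L
      longest <- max(tapply(rep(1L, n_det), run, sum))
      md <- compute_mdh(n_det, fps)
      w <- compute_wsh(
        tibble(frame = d$offset, x = d$center_x, y = d$center_y),
        md$minutes, px_per_cm = px_per_cm, min_gap_frames = min_gap_frames
      )
      tibble(
        dh01 = as.numeric(longest >= min_prior_run_frames),
        minutes_detected = md$minutes, mdh = md$mdh,
        path_cm = w$path_cm, speed_cm_min = w$speed_raw, wsh = w$wsh
      )
    }) |>
    ungroup()

  out <- left_join(base, per_group, by = c("pen", "wingtag", "day", "hour"))
  none <- is.na(out$dh01)
  out$dh01[none] <- 0
  out$minutes_detected[none] <- 0
  nd <- out$dh01 == 0
  out$mdh[nd] <- NA_real_
  out$wsh[nd] <- NA_real_
  out$path_cm[nd] <- NA_real_
  out$speed_cm_min[nd] <- NA_real_
  cols <- intersect(c("marker_id", "wingtag", "hour", "pen", "day", "dh01",
                      "minutes_detected", "mdh", "path_cm", "speed_cm_min",
                      "wsh"), names(out))
  out[, cols]
}

#' Density plot of individual time-budget shares
#'
#' @param budgets output of [hourly_time_budget()].
#' @return a ggplot object showing the distribution of individual mean
#'   proportions per category.
#' @export
plot_time_budget <- function(budgets) {
  agg <- aggregate_time_budget(budgets)$individual |>
    tidyr::pivot_longer(all_of(c("detected", "away", "uncertain", "focal",
                                 "unclassified")),
                        names_to = "category", values_to = "proportion")
  ggplot2::ggplot(agg, ggplot2::aes(.data$proportion,
                                    colour = .data$category)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "individual mean hourly proportion", y = "density") +
    ggplot2::theme_minimal()
}
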