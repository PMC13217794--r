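#' Read a raw detection CSV
#'
#' Parses the raw-stream dialect `marker_id, c1x..c4y, frame, pen,
#' timestamp` (ISO-8601 timestamps with milliseconds). Malformed rows can
#' either abort the read or be skipped with a message.
#'
#' @param path CSV file.
#' @param expected_resolution optional `c(width, height)`; when given, a
#'   per-pen resolution verdict is attached as attribute
#'   `"resolution_verdict"` (pens whose coordinates exceed the expected
#'   frame are flagged `wrong_resolution`).
#' @param on_error `"fail"` (default) or `"skip"` malformed rows.
#' @return tibble of detections.
#' @export
read_detections <- function(path, expected_resolution = NULL,
                            on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  det <- readr::read_csv(
    path,
    col_types = readr::cols(
      marker_id = readr::col_integer(),
      c1x = readr::col_double(), c1y = readr::col_double(),
      c2x = readr::col_double(), c2y = readr::col_double(),
      c3x = readr::col_double(), c3y = readr::col_double(),
      c4x = readr::col_double(), c4y = readr::col_double(),
      frame = readr::col_integer(),
      pen = readr::col_character(),
      timestamp = readr::col_datetime(format = "")
    ),
    progress = FALSE
  )
  need <- c("marker_id", "c1x", "c1y", "c2x", "c2y", "c3x", "c3y",
            "c4x", "c4y", "frame", "pen", "timestamp")
  if (!all(need %in% names(det))) {
    abort("detection file header does not match the raw-stream dialect.")
  }
  prob <- readr::problems(det)
  bad <- rep(FALSE, nrow(det))
  if (nrow(prob) > 0) {
    if (on_error == "fail") {
      abort(sprintf("malformed detection rows (first at file line %d).",
                    min(prob$row)))
    }
    # problems() reports file lines (header included)
    idx <- unique(pmin(pmax(prob$row - 1L, 1L), nrow(det)))
    bad[idx] <- TRUE
  }
  num_cols <- setdiff(need, c("pen", "timestamp"))
  bad <- bad | !complete.cases(det[, num_cols])
  if (any(bad)) {
    if (on_error == "fail") {
      abort(sprintf("malformed detection rows at lines: %s",
                    paste(head(which(bad), 5L) + 1L, collapse = ", ")))
    }
    inform(sprintf("skipping %d malformed detection row(s).", sum(bad)))
    det <- det[!bad, ]
  }
  if (!is.null(expected_resolution)) {
    attr(det, "resolution_verdict") <-
      resolution_check(det, expected_resolution)
  }
  det
}

#' Flag pens recorded at the wrong resolution
#'
#' A pen whose corner coordinates exceed the expected frame dimensions
#' was recorded at a different resolution; mixing pixel spaces would
#' distort areas and distances, so such pens are excluded wholesale.
#'
#' @param detections detection tibble.
#' @param expected_resolution `c(width, height)` in pixels.
#' @return tibble with columns `pen`, `max_x`, `max_y`,
#'   `wrong_resolution`.
#' @export
resolution_check <- function(detections, expected_resolution) {
  if (nrow(detections) == 0L) {
    return(tibble(pen = character(), max_x = numeric(), max_y = numeric(),
                  wrong_resolution = logical()))
  }
  detections |>
    group_by(pen = .data$pen) |>
    summarise(
      max_x = max(.data$c1x, .data$c2x, .data$c3x, .data$c4x),
      max_y = max(.data$c1y, .data$c2y, .data$c3y, .data$c4y),
      .groups = "drop"
    ) |>
    mutate(wrong_resolution = .data$max_x > expected_resolution[1L] |
             .data$max_y > expected_resolution[2L])
}

#' Attach wingtag identities from the roster
#'
#' Joins detections to the backpack-placement roster by (pen, marker id).
#' Marker numbers are unique within a pen but repeat across pens, so the
#' join is pen-wise. Rows whose marker was never documented at placement
#' are flagged `unregistered` (they are removed by [filter_pipeline()]).
#'
#' @param detections detection tibble.
#' @param roster tibble with columns `pen`, `marker_id`, `wingtag`;
#'   duplicate (pen, marker_id) keys are an error.
#' @return detections with columns `wingtag` and `unregistered` appended.
#' @export
attach_identities <- function(detections, roster) {
  roster <- as_tibble(roster)
  if (anyDuplicated(roster[, c("pen", "marker_id")])) {
    abort("duplicate (pen, marker_id) keys in roster.")
  }
  out <- left_join(detections,
                   roster[, c("pen", "marker_id", "wingtag")],
                   by = c("pen", "marker_id"))
  out$unregistered <- is.na(out$wingtag)
  out
}

#' Filtering configuration
#'
#' @param exclusion_polygon vertex matrix bounding positions on the upper
#'   levels / ramp, or `NULL`.
#' @param area_outlier_quantile upper quantile of the per-pen marker-area
#'   distribution above which rows are dropped (default 0.999; replaces
#'   the histogram inspection with an auditable cut-off).
#' @param distance_window_s length of the per-bird distance windows in
#'   seconds (default 10).
#' @param distance_outlier_quantile upper quantile of the per-pen
#'   windowed-distance distribution above which whole windows are dropped
#'   (default 0.999).
#' @param expected_resolution optional `c(width, height)`; pens exceeding
#'   it are excluded.
#' @param fps frames per second (default 20).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(exclusion_polygon = NULL,
                          area_outlier_quantile = 0.999,
                          distance_window_s = 10,
                          distance_outlier_quantile = 0.999,
                          expected_resolution = NULL,
                          fps = 20) {
  if (area_outlier_quantile <= 0 || area_outlier_quantile >= 1 ||
      distance_outlier_quantile <= 0 || distance_outlier_quantile >= 1) {
    abort("outlier quantiles must lie strictly in (0, 1).")
  }
  if (distance_window_s <= 0) abort("`distance_window_s` must be positive.")
  structure(
    list(exclusion_polygon = exclusion_polygon,
         area_outlier_quantile = area_outlier_quantile,
         distance_window_s = distance_window_s,
         distance_outlier_quantile = distance_outlier_quantile,
         expected_resolution = expected_resolution,
         fps = fps),
    class = "filter_config"
  )
}

timestamp_ms <- function(ts) round(as.numeric(ts) * 1000)

#' Multi-step filtering of the raw detection stream
#'
#' Applies, within each pen and in this order: (1) drop detections whose
#' centre lies inside the exclusion polygon (upper levels / ramp);
#' (2) drop markers not documented in the roster; (3) drop rows whose
#' marker area exceeds the per-pen upper quantile of the empirical area
#' distribution (impossibly large false-positive markers); (4) drop all
#' rows of any (pen, marker, millisecond) seen at more than one distinct
#' position within the same millisecond; (5) compute per-bird summed
#' displacement over consecutive `distance_window_s` windows and drop all
#' rows of windows above the per-pen upper quantile (tracking artifacts /
#' identity swaps); (6) drop pens recorded at a resolution other than
#' `expected_resolution`.
#'
#' Outlier cut-offs are realized order statistics (type-1 quantiles), so
#' on a clean stream whose upper tail is unremarkable the cut-off
#' coincides with the observed maximum and nothing is removed; the
#' realized cut-offs are returned for audit and can be frozen and passed
#' back via `area_cutoffs` / `distance_cutoffs` (re-running the filter on
#' its own output with frozen cut-offs removes zero rows).
#'
#' @param detections raw detection tibble.
#' @param roster tibble `pen, marker_id, wingtag`.
#' @param config a [filter_config()].
#' @param area_cutoffs,distance_cutoffs optional frozen per-pen cut-off
#'   tables (`pen`, `cutoff`) from a previous run, overriding the
#'   quantile computation.
#' @return list with `detections` (filtered, with `wingtag`, `center_x`,
#'   `center_y`, `area_px2` appended), `report` (one-row tibble of
#'   per-step removal counts satisfying
#'   `rows_in - sum(removed) = rows_out`) and `cutoffs` (realized per-pen
#'   area and distance thresholds, for audit).
#' @export
filter_pipeline <- function(detections, roster, config = filter_config(),
                            area_cutoffs = NULL, distance_cutoffs = NULL) {
  stopifnot(inherits(config, "filter_config"))
  det <- as_tibble(detections)
  rows_in <- nrow(det)
  counts <- c(exclusion_zone = 0L, unregistered = 0L, area_outlier = 0L,
              millisecond_duplicate = 0L, distance_outlier = 0L,
              wrong_resolution = 0L)
  if (rows_in == 0L) {
    report <- tibble(rows_in = 0L, !!!as.list(counts), rows_out = 0L)
    return(list(detections = det, report = report,
                cutoffs = list(area = tibble(), distance = tibble())))
  }

  det$center_x <- (det$c1x + det$c2x + det$c3x + det$c4x) / 4
  det$center_y <- (det$c1y + det$c2y + det$c3y + det$c4y) / 4
  det$area_px2 <- detection_areas(det)

  # (1) exclusion polygon
  if (!is.null(config$exclusion_polygon)) {
    inside <- points_in_polygon(det$center_x, det$center_y,
                                as.matrix(config$exclusion_polygon))
    counts["exclusion_zone"] <- sum(inside)
    det <- det[!inside, ]
  }

  # (2) unregistered markers
  det <- attach_identities(det, roster)
  counts["unregistered"] <- sum(det$unregistered)
  det <- det[!det$unregistered, ]
  det$unregistered <- NULL

  # (3) per-pen area outliers
  area_cut <- area_cutoffs
  if (is.null(area_cut)) {
    area_cut <- det |>
      group_by(.data$pen) |>
      summarise(cutoff = quantile(.data$area_px2, config$area_outlier_quantile,
                                  names = FALSE, type = 1),
                .groups = "drop")
  }
  if (nrow(det) > 0) {
    cut_i <- area_cut$cutoff[match(det$pen, area_cut$pen)]
    drop <- det$area_px2 > cut_i * (1 + 1e-9)
    counts["area_outlier"] <- sum(drop)
    det <- det[!drop, ]
  }

  # (4) same-millisecond multi-location markers
  if (nrow(det) > 0) {
    ms <- timestamp_ms(det$timestamp)
    key <- paste(det$pen, det$marker_id, ms)
    pos <- paste(round(det$center_x, 6), round(det$center_y, 6))
    n_pos <- tapply(pos, key, function(v) length(unique(v)))
    drop <- n_pos[key] > 1L
    counts["millisecond_duplicate"] <- sum(drop)
    det <- det[!drop, ]
  }

  # (5) windowed distance outliers
  dist_cut <- tibble(pen = character(), cutoff = numeric())
  if (nrow(det) > 0) {
    win_frames <- config$distance_window_s * config$fps
    det <- arrange(det, .data$pen, .data$wingtag, .data$frame)
    wd <- det |>
      group_by(.data$pen, .data$wingtag) |>
      mutate(step = c(0, sqrt(diff(.data$center_x)^2 + diff(.data$center_y)^2)),
             window = .data$frame %/% win_frames) |>
      group_by(.data$pen, .data$wingtag, .data$window) |>
      mutate(window_dist = sum(.data$step)) |>
      ungroup()
    dist_cut <- distance_cutoffs
    if (is.null(dist_cut)) {
      dist_cut <- wd |>
        distinct(.data$pen, .data$wingtag, .data$window, .data$window_dist) |>
        group_by(.data$pen) |>
        summarise(cutoff = quantile(.data$window_dist,
                                    config$distance_outlier_quantile,
                                    names = FALSE, type = 1),
                  .groups = "drop")
    }
    cut_i <- dist_cut$cutoff[match(wd$pen, dist_cut$pen)]
    drop <- wd$window_dist > cut_i * (1 + 1e-9) + 1e-9
    counts["distance_outlier"] <- sum(drop)
    det <- wd[!drop, ]
    det$step <- det$window <- det$window_dist <- NULL
  }

  # (6) wrong-resolution pens
  if (!is.null(config$expected_resolution) && nrow(det) > 0) {
    verdict <- resolution_check(det, config$expected_resolution)
    bad_pens <- verdict$pen[verdict$wrong_resolution]
    drop <- det$pen %in% bad_pens
    counts["wrong_resolution"] <- sum(drop)
    det <- det[!drop, ]
  }

  report <- tibble(rows_in = rows_in, !!!as.list(counts),
                   rows_out = nrow(det))
  list(detections = det, report = report,
       cutoffs = list(area = area_cut, distance = dist_cut))
}
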