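#' Centre of a detected marker
#'
#' The position of a bird in a frame is the arithmetic mean of the four
#' corner coordinates of its detected marker.
#'
#' @param corners numeric matrix with 4 rows and 2 columns (x, y), one row
#'   per corner.
#' @return numeric vector `c(x, y)`.
#' @examples
#' marker_center(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
#' @export
marker_center <- function(corners) {
  corners <- as.matrix(corners)
  if (nrow(corners) != 4L || ncol(corners) != 2L) {
    abort("`corners` must be a 4 x 2 matrix of (x, y) pairs.")
  }
  if (!all(is.finite(corners))) {
    abort("non-finite corner coordinate.")
  }
  c(mean(corners[, 1L]), mean(corners[, 2L]))
}

#' Area of a detected marker
#'
#' Shoelace (polygon) area of the quadrilateral spanned by the four corner
#' coordinates, in squared pixels. Corners are assumed to be in a
#' consistent winding order; the absolute value is returned, so both
#' clockwise and counter-clockwise orders are accepted.
#'
#' @inheritParams marker_center
#' @return scalar area in px^2.
#' @examples
#' marker_area(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
#' @export
marker_area <- function(corners) {
  corners <- as.matrix(corners)
  if (nrow(corners) != 4L || ncol(corners) != 2L) {
    abort("`corners` must be a 4 x 2 matrix of (x, y) pairs.")
  }
  if (!all(is.finite(corners))) {
    abort("non-finite corner coordinate.")
  }
  shoelace_area(corners[, 1L], corners[, 2L])
}

# vectorised shoelace over columns c1x..c4x / c1y..c4y of a detection table
detection_areas <- function(det) {
  xs <- cbind(det$c1x, det$c2x, det$c3x, det$c4x)
  ys <- cbind(det$c1y, det$c2y, det$c3y, det$c4y)
  nxt <- c(2L, 3L, 4L, 1L)
  s <- rowSums(xs * ys[, nxt] - xs[, nxt] * ys)
  abs(s) / 2
}

shoelace_area <- function(x, y) {
  n <- length(x)
  nxt <- c(seq_len(n)[-1L], 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Define the zone geometry of a pen
#'
#' The recordable litter area is split into three zones used to attribute
#' detection losses to a probable cause: a central `focal` zone (optimal
#' detection conditions, losses attributed to occlusion), a `yellow` zone
#' near the image periphery (lens distortion / distance), and a `green`
#' zone bordering the exits towards ramp and upper levels (true absences).
#' An `exclusion` polygon bounds marker positions that belong to the upper
#' levels or the ramp and are discarded outright.
#'
#' Each polygon is a numeric matrix of vertices with columns x and y, in
#' pixel space (origin top-left, y increasing downward). Polygons must be
#' simple (non-self-intersecting). Classification tests polygons in the
#' priority order focal, yellow, green, so overlapping definitions resolve
#' deterministically to the earlier zone.
#'
#' @param exclusion,green,yellow,focal polygons (vertex matrices, columns
#'   x and y). `exclusion` may be `NULL` when no exclusion area applies.
#' @return an object of class `zone_set`.
#' @export
zone_set <- function(focal, yellow, green, exclusion = NULL) {
  check_poly <- function(p, name) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L || !all(is.finite(p))) {
      abort(sprintf("`%s` must be a finite n x 2 vertex matrix with n >= 3.", name))
    }
    colnames(p) <- c("x", "y")
    p
  }
  structure(
    list(
      focal = check_poly(focal, "focal"),
      yellow = check_poly(yellow, "yellow"),
      green = check_poly(green, "green"),
      exclusion = check_poly(exclusion, "exclusion")
    ),
    class = "zone_set"
  )
}

#' @export
print.zone_set <- function(x, ...) {
  cat("<zone_set>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  %-9s (none)\n", nm))
    } else {
      cat(sprintf("  %-9s %d vertices\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}

# points strictly classified by even-odd point-in-polygon
points_in_polygon <- function(x, y, poly) {
  if (length(x) == 0L) return(logical(0))
  as.logical(mgcv::in.out(rbind(poly, poly[1L, , drop = FALSE]),
                          cbind(as.numeric(x), as.numeric(y))))
}

#' Classify points into litter-area zones
#'
#' Tests each point against the focal, yellow and green polygons in that
#' priority order. Points falling in none of the three zones are returned
#' as `NA` (unclassifiable; e.g. inside the exclusion polygon).
#'
#' @param x,y numeric vectors of pixel coordinates.
#' @param zones a [zone_set()].
#' @return character vector with values `"focal"`, `"yellow"`, `"green"`
#'   or `NA`.
#' @export
classify_zone <- function(x, y, zones) {
  stopifnot(inherits(zones, "zone_set"))
  out <- rep(NA_character_, length(x))
  for (nm in c("focal", "yellow", "green")) {
    poly <- zones[[nm]]
    if (is.null(poly)) next
    idx <- is.na(out) & points_in_polygon(x, y, poly)
    out[idx] <- nm
  }
  out
}

#' Axis-aligned rectangular polygon
#'
#' Convenience constructor for rectangular zone polygons.
#'
#' @param x0,y0,x1,y1 opposite corners in pixel coordinates.
#' @return a 4 x 2 vertex matrix.
#' @export
rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Read or write zone polygons as YAML
#'
#' Zone geometry is configuration, not data; a YAML file with one named
#' vertex list per zone (`focal`, `yellow`, `green`, optionally
#' `exclusion`, each a list of `[x, y]` pairs) keeps it versionable
#' alongside the recording metadata.
#'
#' @param zones a [zone_set()].
#' @param path YAML file path.
#' @return `read_zone_yaml()` returns a [zone_set()]; `write_zone_yaml()`
#'   returns `path` invisibly.
#' @export
write_zone_yaml <- function(zones, path) {
  stopifnot(inherits(zones, "zone_set"))
  obj <- lapply(zones[!vapply(zones, is.null, TRUE)], function(p) {
    lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_zone_yaml
#' @export
read_zone_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  poly <- function(nm) {
    if (is.null(obj[[nm]])) return(NULL)
    do.call(rbind, lapply(obj[[nm]], as.numeric))
  }
  zone_set(focal = poly("focal"), yellow = poly("yellow"),
           green = poly("green"), exclusion = poly("exclusion"))
}
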