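# Catheter geometry: electrodes, bipolar pairs, inner/outer loops.

PAIR_INDEX_INNER <- c(1L, 3L, 5L, 7L, 9L)
PAIR_INDEX_OUTER <- c(11L, 13L, 15L, 17L, 19L)
PAIR_INDEX_ALL <- c(PAIR_INDEX_INNER, PAIR_INDEX_OUTER)

#' Build a five-branch, 20-electrode mapping-catheter layout
#'
#' Constructs the star-shaped ("PentaRay"-style) catheter geometry used
#' throughout the package: 20 electrodes spaced along 5 branches at 72
#' degree intervals, grouped into 10 bipolar pairs that form an inner loop
#' (pair indices 1, 3, 5, 7, 9) and an outer loop (11, 13, 15, 17, 19).
#' Pair `k + 10` lies on the same branch as pair `k`. The layout is planar
#' (constant z) before any snapping to a surface mesh.
#'
#' Each branch carries 4 electrodes: two straddling `inner_radius` and two
#' straddling `outer_radius`, separated along the branch by `electrode_gap`,
#' so that every bipolar midpoint lies exactly at its loop radius.
#'
#' @param center numeric length-3, catheter center in mm.
#' @param orientation rotation of the branches about the z axis, radians.
#' @param inner_radius,outer_radius loop radii in mm; must satisfy
#'   `0 < inner_radius < outer_radius`.
#' @param electrode_gap spacing between the two electrodes of a pair along
#'   the branch, mm. Must be smaller than `2 * inner_radius` and than
#'   `outer_radius - inner_radius`.
#' @return An object of class `catheter_layout`: a list with data frames
#'   `electrodes` (electrode_id, branch, loop, x, y, z) and `pairs`
#'   (pair_index, loop, branch, electrode_1, electrode_2, x, y, z where
#'   x, y, z is the pair midpoint), plus the construction parameters.
#' @examples
#' lay <- pentaray_layout()
#' nrow(lay$electrodes)  # 20
#' nrow(lay$pairs)       # 10
#' @seealso [pair_channels()], [snap_to_surface()]
#' @export
pentaray_layout <- function(center = c(0, 0, 0), orientation = 0,
                            inner_radius = 5, outer_radius = 15,
                            electrode_gap = 2) {
  if (!is.numeric(center) || length(center) != 3L || any(!is.finite(center))) {
    stop("invalid geometry: 'center' must be a finite length-3 numeric vector")
  }
  stopifnot_scalar(orientation, "orientation")
  if (!is.numeric(inner_radius) || !is.numeric(outer_radius) ||
      inner_radius <= 0 || outer_radius <= 0 || inner_radius >= outer_radius) {
    stop("invalid geometry: radii must satisfy 0 < inner_radius < outer_radius")
  }
  stopifnot_scalar(electrode_gap, "electrode_gap", positive = TRUE)
  if (electrode_gap >= 2 * inner_radius || electrode_gap >= outer_radius - inner_radius) {
    stop("invalid geometry: 'electrode_gap' too large for the requested radii")
  }

  branches <- 1:5
  angles <- orientation + 2 * pi * (branches - 1) / 5
  half <- electrode_gap / 2
  radii <- c(inner_radius - half, inner_radius + half,
             outer_radius - half, outer_radius + half)

  el <- do.call(rbind, lapply(branches, function(b) {
    u <- c(cos(angles[b]), sin(angles[b]), 0)
    pos <- t(vapply(radii, function(r) center + r * u, numeric(3)))
    data.frame(
      electrode_id = (b - 1L) * 4L + 1:4,
      branch = b,
      loop = c("inner", "inner", "outer", "outer"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    )
  }))

  pr <- do.call(rbind, lapply(branches, function(b) {
    ids <- (b - 1L) * 4L + 1:4
    data.frame(
      pair_index = c(2L * b - 1L, 2L * b + 9L),
      loop = c("inner", "outer"),
      branch = b,
      electrode_1 = ids[c(1L, 3L)],
      electrode_2 = ids[c(2L, 4L)]
    )
  }))
  mid <- t(vapply(seq_len(nrow(pr)), function(i) {
    a <- as.numeric(el[el$electrode_id == pr$electrode_1[i], c("x", "y", "z")])
    b <- as.numeric(el[el$electrode_id == pr$electrode_2[i], c("x", "y", "z")])
    (a + b) / 2
  }, numeric(3)))
  pr$x <- mid[, 1]; pr$y <- mid[, 2]; pr$z <- mid[, 3]
  pr <- pr[order(pr$pair_index), ]
  rownames(pr) <- NULL

  structure(
    list(electrodes = el, pairs = pr, center = as.numeric(center),
         orientation = orientation, inner_radius = inner_radius,
         outer_radius = outer_radius, electrode_gap = electrode_gap),
    class = "catheter_layout"
  )
}

#' @export
print.catheter_layout <- function(x, ...) {
  cat("Catheter layout: 20 electrodes on 5 branches, 10 bipolar pairs\n")
  cat(sprintf("  center      : (%.2f, %.2f, %.2f) mm\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  orientation : %.4f rad\n", x$orientation))
  cat(sprintf("  loop radii  : inner %.1f mm (pairs %s), outer %.1f mm (pairs %s)\n",
              x$inner_radius, paste(PAIR_INDEX_INNER, collapse = ","),
              x$outer_radius, paste(PAIR_INDEX_OUTER, collapse = ",")))
  invisible(x)
}

#' List the bipolar recording channels of a layout
#'
#' Returns the 10 bipolar pairs (= EGM channels) in ascending `pair_index`
#' order, optionally restricted to one loop.
#'
#' @param layout a [pentaray_layout()] object.
#' @param loop `"all"`, `"inner"` or `"outer"`.
#' @return data frame of bipolar pairs (one row per channel).
#' @export
pair_channels <- function(layout, loop = c("all", "inner", "outer")) {
  loop <- match.arg(loop)
  stopifnot(inherits(layout, "catheter_layout"))
  pr <- layout$pairs[order(layout$pairs$pair_index), ]
  if (loop != "all") pr <- pr[pr$loop == loop, ]
  rownames(pr) <- NULL
  pr
}

# midpoints as a 10 x 3 matrix, rows named by pair index (ascending)
pair_midpoints <- function(layout) {
  pr <- pair_channels(layout)
  m <- as.matrix(pr[, c("x", "y", "z")])
  rownames(m) <- pr$pair_index
  m
}

#' Read / write a catheter layout as JSON
#'
#' The JSON schema has fields `center`, `orientation_rad`, `inner_radius_mm`,
#' `outer_radius_mm` and optionally `electrode_gap_mm`.
#'
#' @param path file path.
#' @param layout a `catheter_layout` object.
#' @return `read_layout_json()` returns a `catheter_layout`;
#'   `write_layout_json()` returns `path` invisibly.
#' @export
read_layout_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("center", "orientation_rad", "inner_radius_mm", "outer_radius_mm")) {
    if (is.null(cfg[[f]])) stop("layout JSON is missing field '", f, "'")
  }
  pentaray_layout(center = as.numeric(cfg$center),
                  orientation = cfg$orientation_rad,
                  inner_radius = cfg$inner_radius_mm,
                  outer_radius = cfg$outer_radius_mm,
                  electrode_gap = cfg$electrode_gap_mm %||% 2)
}

#' @rdname read_layout_json
#' @export
write_layout_json <- function(layout, path) {
  stopifnot(inherits(layout, "catheter_layout"))
  jsonlite::write_json(
    list(center = layout$center, orientation_rad = layout$orientation,
         inner_radius_mm = layout$inner_radius,
         outer_radius_mm = layout$outer_radius,
         electrode_gap_mm = layout$electrode_gap),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
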