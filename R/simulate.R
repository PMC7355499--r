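# Synthetic activation-time data: focal sources firing irregularly,
# normally distributed conduction velocity, Gaussian LAT noise, and
# earliest-arrival collision of wavefronts.

#' Construct an activation-time matrix
#'
#' An activation matrix holds local activation times (LATs, ms) for `T`
#' activation cycles (rows) at the 10 bipolar pairs (columns, named by pair
#' index: inner loop 1,3,5,7,9 then outer loop 11,13,15,17,19).
#'
#' @param lat numeric matrix `T x 10`; column names must be the 10 pair
#'   indices (any order; columns are reordered).
#' @param activation_ids optional integer row ids (default `1:T`).
#' @return object of class `activation_matrix` (a numeric matrix with a
#'   `loop` attribute mapping columns to loops).
#' @export
activation_matrix <- function(lat, activation_ids = NULL) {
  lat <- as.matrix(lat)
  if (is.null(colnames(lat))) {
    if (ncol(lat) != 10L) stop("activation matrix must have 10 pair columns")
    colnames(lat) <- as.character(PAIR_INDEX_ALL)
  }
  want <- as.character(PAIR_INDEX_ALL)
  if (!setequal(colnames(lat), want)) {
    stop("activation matrix columns must be the pair indices ",
         paste(want, collapse = ", "))
  }
  lat <- lat[, want, drop = FALSE]
  if (nrow(lat) < 1L) stop("activation matrix needs T >= 1 activations")
  rownames(lat) <- as.character(activation_ids %||% seq_len(nrow(lat)))
  structure(lat,
            loop = stats::setNames(rep(c("inner", "outer"), each = 5L), want),
            class = c("activation_matrix", class(lat)))
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf("Activation matrix: %d activations x %d bipolar pairs (ms)\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more activations\n")
  invisible(x)
}

pair_loops <- function(lat) {
  attr(lat, "loop") %||%
    stats::setNames(ifelse(as.integer(colnames(lat)) <= 9, "inner", "outer"),
                    colnames(lat))
}

#' Define a focal source
#'
#' @param location either a numeric length-3 position (mm; planar mode) or a
#'   single mesh vertex id (mesh mode).
#' @param onsets strictly increasing firing times, ms.
#' @param label `"abnormal"` (ectopic trigger) or `"normal"` (sinus-driven).
#' @return object of class `focal_source`.
#' @export
focal_source <- function(location, onsets, label = c("abnormal", "normal")) {
  label <- match.arg(label)
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1L || any(diff(onsets) <= 0)) {
    stop("'onsets' must be a non-empty strictly increasing vector (ms)")
  }
  structure(list(location = location, onsets = onsets, label = label),
            class = "focal_source")
}

#' Generate irregular firing schedules for focal sources
#'
#' Inter-onset intervals are drawn from a normal law with mean
#' `mean_interval_ms` and standard deviation `jitter * mean_interval_ms`
#' (so the interval coefficient of variation equals `jitter`), rejected
#' below `refractory_ms`. Source start times are staggered so sources
#' interleave rather than fire in lockstep.
#'
#' @param n_sources 1 or 2 sources.
#' @param n_activations onsets per source.
#' @param mean_interval_ms mean inter-onset interval, ms.
#' @param jitter fractional interval jitter (interval CV); 0 gives a
#'   perfectly periodic schedule.
#' @param refractory_ms minimum allowed inter-onset interval, ms; must be
#'   below `mean_interval_ms`.
#' @param seed optional RNG seed (schedules are reproducible under a fixed
#'   seed).
#' @return list of numeric onset vectors, one per source.
#' @export
activation_schedule <- function(n_sources, n_activations,
                                mean_interval_ms = 400, jitter = 0.2,
                                refractory_ms = 150, seed = NULL) {
  if (!n_sources %in% c(1L, 2L)) stop("'n_sources' must be 1 or 2")
  if (n_activations < 1L) stop("'n_activations' must be >= 1")
  stopifnot_scalar(mean_interval_ms, "mean_interval_ms", positive = TRUE)
  if (jitter < 0) stop("'jitter' must be >= 0")
  if (refractory_ms >= mean_interval_ms) {
    stop("refractory violated: 'refractory_ms' must be below 'mean_interval_ms'")
  }
  with_seed(seed, {
    lapply(seq_len(n_sources), function(s) {
      # start one interval into the recording: the time origin of a recording
      # is arbitrary and must not coincide with a firing instant (source
      # onsets sit strictly inside the feasible region t >= 0)
      start <- mean_interval_ms + (s - 1) * mean_interval_ms / n_sources
      iv <- numeric(n_activations - 1L)
      if (n_activations > 1L) {
        sd <- jitter * mean_interval_ms
        for (k in seq_len(n_activations - 1L)) {
          repeat {
            x <- stats::rnorm(1L, mean_interval_ms, sd)
            if (x >= refractory_ms) break
          }
          iv[k] <- x
        }
      }
      start + cumsum(c(0, iv))
    })
  })
}

#' Simulate a LAT matrix from focal sources
#'
#' Arrival times follow the geodesic (or planar Euclidean) eikonal model:
#' the wave from a source firing at onset `t` reaches sensor `j` at
#' `t + d_j / CV*`, where `d_j` is the source-to-sensor distance and `CV*`
#' is drawn once per activation cycle from a positive-truncated
#' `N(cv_mean, cv_sd^2)`. Gaussian observation noise `N(0, lat_sd^2)` is
#' added to every LAT. With `firing = "exclusive"` each cycle is one
#' source's firing (cycles = the pooled, time-ordered onsets of all
#' sources); with `"overlapping"` all sources fire in every cycle and each
#' sensor records the earliest arrival (wavefront-collision rule).
#'
#' @param sources list of [focal_source()] objects. In planar mode their
#'   locations are 3-vectors; in mesh mode, vertex ids.
#' @param layout a [pentaray_layout()].
#' @param mesh optional `surface_mesh`; when supplied, sensor sites are the
#'   snapped pair midpoints and distances are mesh geodesics.
#' @param cv_mean,cv_sd conduction-velocity law, mm/ms.
#' @param lat_sd LAT observation noise SD, ms.
#' @param firing `"exclusive"` or `"overlapping"` (see Details).
#' @param seed optional RNG seed; a fixed seed gives a bit-identical matrix.
#' @return an [activation_matrix()] with attributes `truth` (list: sources,
#'   per-source sensor distances, cycle onsets, cv draws) and
#'   `source_of_record` (generating source per activation and pair).
#' @export
simulate_lat_matrix <- function(sources, layout, mesh = NULL,
                                cv_mean = 0.8, cv_sd = 0.04, lat_sd = 1,
                                firing = c("exclusive", "overlapping"),
                                seed = NULL) {
  firing <- match.arg(firing)
  stopifnot(inherits(layout, "catheter_layout"))
  if (inherits(sources, "focal_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1L)
  stopifnot_scalar(cv_mean, "cv_mean", positive = TRUE)
  if (cv_sd < 0 || lat_sd < 0) stop("'cv_sd' and 'lat_sd' must be >= 0")

  # per-source distance to each of the 10 sensors (pair-index order)
  if (is.null(mesh)) {
    mid <- pair_midpoints(layout)
    dists <- lapply(sources, function(s) {
      loc <- as.numeric(s$location)
      if (length(loc) != 3L) stop("planar mode needs 3-vector source locations")
      sqrt(rowSums(sweep(mid, 2, loc, "-")^2))
    })
  } else {
    mesh <- with_mesh_graph(mesh)
    snap <- snap_to_surface(layout, mesh)
    dists <- lapply(sources, function(s) {
      if (length(s$location) != 1L) stop("mesh mode needs vertex-id source locations")
      f <- geodesic_field(mesh, s$location)
      stats::setNames(f$distance[snap], names(snap))
    })
  }
  if (any(vapply(dists, function(d) any(!is.finite(d)), logical(1)))) {
    stop("a sensor is unreachable from a source")
  }

  with_seed(seed, {
    if (firing == "exclusive") {
      ev <- do.call(rbind, lapply(seq_along(sources), function(s) {
        data.frame(source = s, onset = sources[[s]]$onsets)
      }))
      ev <- ev[order(ev$onset), ]
      T <- nrow(ev)
      cv <- rnorm_pos(T, cv_mean, cv_sd)
      lat <- t(vapply(seq_len(T), function(t) {
        ev$onset[t] + dists[[ev$source[t]]] / cv[t]
      }, numeric(10)))
      rec <- matrix(ev$source, T, 10)
      onsets <- ev$onset
    } else {
      T <- max(vapply(sources, function(s) length(s$onsets), integer(1)))
      cv <- rnorm_pos(T, cv_mean, cv_sd)
      lat <- matrix(NA_real_, T, 10)
      rec <- matrix(NA_integer_, T, 10)
      onsets <- numeric(T)
      for (t in seq_len(T)) {
        arr <- vapply(seq_along(sources), function(s) {
          if (t <= length(sources[[s]]$onsets)) {
            sources[[s]]$onsets[t] + dists[[s]] / cv[t]
          } else {
            rep(Inf, 10)
          }
        }, numeric(10))  # 10 x n_sources
        rec[t, ] <- apply(arr, 1, which.min)
        lat[t, ] <- apply(arr, 1, min)
        onsets[t] <- min(vapply(seq_along(sources), function(s)
          if (t <= length(sources[[s]]$onsets)) sources[[s]]$onsets[t] else Inf,
          numeric(1)))
      }
    }
    if (lat_sd > 0) lat <- lat + matrix(stats::rnorm(length(lat), 0, lat_sd), nrow(lat))
    colnames(lat) <- names(dists[[1]]) %||% as.character(PAIR_INDEX_ALL)
    out <- activation_matrix(lat)
    attr(out, "truth") <- list(sources = sources, distances = dists,
                               onsets = onsets, cv = cv, cv_mean = cv_mean,
                               cv_sd = cv_sd, lat_sd = lat_sd)
    attr(out, "source_of_record") <- rec
    out
  })
}

#' Synthesize toy bipolar electrogram traces from a LAT matrix
#'
#' Each channel is a sum of biphasic template pulses (derivative-of-Gaussian
#' shape, unit peak amplitude) centered at the channel's LATs, plus white
#' noise of standard deviation `1/snr`. The template's steepest slope falls
#' at the pulse center, so maximum-change LAT extraction recovers the
#' generating times. This is a deliberately simple trace generator for
#' exercising the LAT-extraction path, not a model of fractionated
#' electrogram morphology.
#'
#' @param lat an [activation_matrix()] (may have zero rows via `lat[0, ]`).
#' @param sample_rate sampling rate, Hz.
#' @param snr ratio of pulse peak amplitude to noise SD; `Inf` = noiseless.
#' @param pulse_width_ms Gaussian width parameter of the template, ms.
#' @param duration_ms optional total duration; defaults to covering all LATs.
#' @param seed optional RNG seed.
#' @return object of class `egm_trace`: list with `signal` (samples x 10
#'   matrix, mV), `time` (ms), `sample_rate`, `duration_ms`.
#' @export
synthesize_egm <- function(lat, sample_rate = 1000, snr = 20,
                           pulse_width_ms = 2, duration_ms = NULL,
                           seed = NULL) {
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar(pulse_width_ms, "pulse_width_ms", positive = TRUE)
  lat <- as.matrix(lat)
  w <- pulse_width_ms
  support <- 4 * w
  duration_ms <- duration_ms %||%
    (if (length(lat) && any(is.finite(lat))) max(lat, na.rm = TRUE) + 2 * support else 10 * support)
  time <- seq(0, duration_ms, by = 1000 / sample_rate)
  sig <- matrix(0, length(time), 10)
  colnames(sig) <- colnames(lat) %||% as.character(PAIR_INDEX_ALL)
  overlapping <- character(0)
  for (j in seq_len(ncol(sig))) {
    lats <- if (ncol(lat)) lat[, j] else numeric(0)
    lats <- lats[is.finite(lats)]
    if (length(lats) > 1 && min(diff(sort(lats))) < 2 * support) {
      overlapping <- c(overlapping, colnames(sig)[j])
    }
    for (t0 in lats) {
      tau <- time - t0
      idx <- abs(tau) <= support
      sig[idx, j] <- sig[idx, j] -
        (tau[idx] / w) * exp(0.5 - tau[idx]^2 / (2 * w^2))
    }
  }
  if (length(overlapping)) {
    warning("overlapping pulses within channel(s) ",
            paste(overlapping, collapse = ", "))
  }
  if (is.finite(snr)) {
    with_seed(seed, {
      sig <- sig + matrix(stats::rnorm(length(sig), 0, 1 / snr), nrow(sig))
    })
  }
  structure(list(signal = sig, time = time, sample_rate = sample_rate,
                 duration_ms = duration_ms, pulse_width_ms = w),
            class = "egm_trace")
}

#' @export
print.egm_trace <- function(x, ...) {
  cat(sprintf("EGM trace: %d channels, %.0f ms at %g Hz\n",
              ncol(x$signal), x$duration_ms, x$sample_rate))
  invisible(x)
}

#' Extract local activation times from an EGM trace
#'
#' Within each activation window and channel, the LAT is the time of the
#' maximum absolute first difference of the signal (maximum change). A flat
#' window yields `NA` with a warning.
#'
#' @param trace an [synthesize_egm()] trace.
#' @param windows numeric n x 2 matrix of `(start, end)` ms; windows must be
#'   non-overlapping and inside the trace.
#' @return an [activation_matrix()] (one row per window; may contain `NA`).
#' @export
extract_lat <- function(trace, windows) {
  stopifnot(inherits(trace, "egm_trace"))
  windows <- matrix(as.numeric(windows), ncol = 2)
  if (nrow(windows) < 1L) stop("empty window list")
  if (any(windows[, 2] <= windows[, 1])) stop("empty window: end must exceed start")
  o <- order(windows[, 1])
  if (any(windows[o, 1][-1] < windows[o, 2][-nrow(windows)])) {
    stop("windows must be non-overlapping")
  }
  if (min(windows) < min(trace$time) || max(windows) > max(trace$time)) {
    stop("windows must lie within the trace duration")
  }
  step <- 1000 / trace$sample_rate
  lat <- matrix(NA_real_, nrow(windows), ncol(trace$signal))
  colnames(lat) <- colnames(trace$signal)
  flat <- FALSE
  for (i in seq_len(nrow(windows))) {
    idx <- which(trace$time >= windows[i, 1] & trace$time <= windows[i, 2])
    if (length(idx) < 2L) stop("empty window: fewer than two samples inside")
    for (j in seq_len(ncol(trace$signal))) {
      d <- abs(diff(trace$signal[idx, j]))
      if (max(d) < 1e-9) { flat <- TRUE; next }
      k <- which.max(d)
      lat[i, j] <- trace$time[idx[k]] + step / 2
    }
  }
  if (flat) warning("flat signal in at least one window/channel; LAT flagged NA")
  activation_matrix(lat)
}

#' Segment an EGM trace into activation windows
#'
#' Splits the trace wherever all channels stay below an amplitude threshold
#' for at least `gap_ms`. On clean synthetic traces the window count equals
#' the number of generated activation cycles.
#'
#' @param trace an `egm_trace`.
#' @param gap_ms minimum quiescent gap separating windows, ms; must exceed
#'   the pulse support.
#' @param threshold amplitude threshold (same units as the signal); default
#'   is 25% of the maximum absolute amplitude.
#' @return numeric n x 2 matrix of `(start, end)` windows, ms.
#' @export
segment_activations <- function(trace, gap_ms = 80, threshold = NULL) {
  stopifnot(inherits(trace, "egm_trace"))
  stopifnot_scalar(gap_ms, "gap_ms", positive = TRUE)
  amp <- apply(abs(trace$signal), 1, max)
  threshold <- threshold %||% (0.25 * max(amp))
  active <- amp >= threshold
  if (!any(active)) return(matrix(numeric(0), 0, 2))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge active runs separated by quiescence shorter than gap_ms
  step <- 1000 / trace$sample_rate
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * step
      if (gap < gap_ms) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  pad <- min(gap_ms / 2, 4 * (trace$pulse_width_ms %||% 5))
  out <- cbind(pmax(trace$time[merged$start] - pad, min(trace$time)),
               pmin(trace$time[merged$end] + pad, max(trace$time)))
  # keep padded windows disjoint
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      if (out[i, 1] <= out[i - 1, 2]) {
        mid <- (out[i - 1, 2] + out[i, 1]) / 2
        out[i - 1, 2] <- mid - step / 2
        out[i, 1] <- mid + step / 2
      }
    }
  }
  colnames(out) <- c("start_ms", "end_ms")
  out
}
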