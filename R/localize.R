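# Conduction-velocity estimation and robust least-squares source
# localization with Monte-Carlo uncertainty propagation.

#' Geometry bundle for localizing one path's source
#'
#' Collects the four path sensors' sites and distances. In planar mode
#' (`mesh = NULL`) sensors are the pair midpoints and all distances are
#' Euclidean in the catheter plane; in mesh mode sensors are snapped to
#' mesh vertices and distances are edge-graph geodesics (one Dijkstra field
#' per sensor, so the distance from every candidate vertex to every sensor
#' is available at once, using geodesic symmetry).
#'
#' @param layout a [pentaray_layout()].
#' @param path a path row (elements `FO`, `FI`, `LI`, `LO`).
#' @param mesh optional `surface_mesh`.
#' @return object of class `source_geometry`: list with `mode`, `sensors`
#'   (4 x 3 sites, rows FO/FI/LI/LO), `sensor_dist` (4 x 4), and in mesh
#'   mode `mesh`, `sensor_vertices`, `fields` (4 geodesic fields).
#' @export
source_geometry <- function(layout, path, mesh = NULL) {
  stopifnot(inherits(layout, "catheter_layout"))
  pidx <- as.integer(unlist(path[c("FO", "FI", "LI", "LO")]))
  if (length(unique(pidx)) < 4L) {
    stop("the four path sensors must be pairwise distinct")
  }
  mid <- pair_midpoints(layout)
  sensors <- mid[as.character(pidx), , drop = FALSE]
  rownames(sensors) <- c("FO", "FI", "LI", "LO")
  if (is.null(mesh)) {
    sd_ <- as.matrix(stats::dist(sensors))
    structure(list(mode = "planar", sensors = sensors, sensor_dist = sd_,
                   path = pidx),
              class = "source_geometry")
  } else {
    mesh <- with_mesh_graph(mesh)
    snap <- snap_to_surface(layout, mesh)
    sv <- snap[as.character(pidx)]
    fields <- lapply(sv, function(v) geodesic_field(mesh, v))
    sd_ <- matrix(0, 4, 4, dimnames = list(rownames(sensors), rownames(sensors)))
    for (a in 1:4) for (b in 1:4) sd_[a, b] <- fields[[a]]$distance[sv[b]]
    structure(list(mode = "mesh", sensors = sensors, sensor_dist = sd_,
                   mesh = mesh, sensor_vertices = sv, fields = fields,
                   path = pidx),
              class = "source_geometry")
  }
}

#' Estimate conduction velocity from a path
#'
#' For each of the `choose(4, 2) = 6` sensor pairs `(a, b)` along the path,
#' the conduction velocity is the inter-sensor distance divided by the
#' absolute median (over path-matched activations) LAT difference. Pairs
#' whose median time difference is below `min_dt_ms` are excluded with a
#' warning (near-simultaneous sensors give unstable, inflated velocities).
#' The CV law parameters are the mean and SD of the remaining values.
#'
#' @param lat an [activation_matrix()].
#' @param matched a [filter_path_matched()] result.
#' @param geometry a [source_geometry()].
#' @param min_dt_ms exclusion tolerance on the median time difference, ms.
#' @return object of class `cv_estimate`: list with `mean`, `sd` (mm/ms),
#'   `values` (usable pairwise CVs), `pairs` (labels), `excluded`.
#' @export
estimate_cv <- function(lat, matched, geometry, min_dt_ms = 0.5) {
  stopifnot(inherits(matched, "path_matched"),
            inherits(geometry, "source_geometry"))
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  sub <- lat[matched$rows, as.character(geometry$path), drop = FALSE]
  combos <- utils::combn(4, 2)
  labs <- c("FO", "FI", "LI", "LO")
  vals <- numeric(0); pairs <- character(0); excluded <- character(0)
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]; b <- combos[2, k]
    dt <- stats::median(sub[, b] - sub[, a])
    lab <- paste(labs[a], labs[b], sep = "-")
    if (abs(dt) < min_dt_ms) {
      excluded <- c(excluded, lab)
      next
    }
    vals <- c(vals, geometry$sensor_dist[a, b] / abs(dt))
    pairs <- c(pairs, lab)
  }
  if (length(excluded)) {
    warning("pairwise CV excluded for near-simultaneous sensors: ",
            paste(excluded, collapse = ", "))
  }
  if (length(vals) < 2L) {
    stop("fewer than 2 usable pairwise CV estimates; ",
         "check the path geometry or lower 'min_dt_ms'")
  }
  structure(list(mean = mean(vals), sd = stats::sd(vals), values = vals,
                 pairs = pairs, excluded = excluded),
            class = "cv_estimate")
}

#' @export
print.cv_estimate <- function(x, ...) {
  cat(sprintf("Conduction velocity: mean %.3f mm/ms, sd %.3f (%d pairwise values)\n",
              x$mean, x$sd, length(x$values)))
  invisible(x)
}

# Closed-form per-activation onsets and SSE for one candidate location.
#   d: distances candidate -> 4 sensors; sub: T* x 4 LATs (cols FO,FI,LI,LO)
# Optimal onset t_k = clip(mean_e(lat_ek - d_e/cv), 0, lat_FO,k - tol).
onset_sse <- function(d, sub, cv, t_tol = 1e-6) {
  dd <- d / cv
  t_k <- rowMeans(sub) - mean(dd)
  t_k <- pmin(pmax(t_k, 0), sub[, 1] - t_tol)
  resid <- sub - rep(dd, each = nrow(sub)) - t_k  # column-wise recycling
  list(t = t_k, sse = sum(resid^2))
}

# Vectorized SSE over G candidates. D: G x 4 distances; sub: T* x 4 LATs.
grid_sse <- function(D, sub, cv, t_tol = 1e-6) {
  G <- nrow(D); Ts <- nrow(sub)
  base_t <- rowMeans(sub)                       # length Ts
  tmat <- outer(-rowMeans(D) / cv, base_t, "+") # G x Ts
  upper <- matrix(sub[, 1] - t_tol, G, Ts, byrow = TRUE)
  tmat <- pmin(pmax(tmat, 0), upper)
  sse <- numeric(G)
  for (e in 1:4) {
    r <- outer(D[, e] / cv, sub[, e], function(a, b) a - b) + tmat
    sse <- sse + rowSums(r^2)
  }
  sse
}

#' Fit a source location for one path
#'
#' Minimizes the robust least-squares objective
#' `sum_k sum_e (d_e(s0)/cv + t_k - lat_{e,k})^2` over candidate source
#' locations `s0` and per-activation source onsets `t_k`, subject to
#' `0 <= t_k < lat_{FO,k}` and `d_e(s0) <= rho_max` for every path sensor.
#' For fixed `s0` and `cv` the optimal onsets have the closed form
#' `t_k = clip(mean_e(lat_{e,k} - d_e/cv), 0, lat_{FO,k} - tol)`. In mesh
#' mode the location search is exhaustive over candidate vertices using the
#' precomputed sensor distance fields; in planar mode a coarse in-plane
#' grid seeds a Nelder-Mead polish. The fit is deterministic given its
#' inputs.
#'
#' @param lat an [activation_matrix()].
#' @param matched a [filter_path_matched()] result.
#' @param geometry a [source_geometry()].
#' @param cv conduction velocity to use, mm/ms (> 0).
#' @param rho_max maximum admissible source-to-sensor distance, mm.
#' @param grid_spacing planar coarse-grid spacing, mm.
#' @param t_tol strictness margin for the onset upper bound, ms.
#' @return object of class `source_fit`: list with `location` (xyz, mm),
#'   `vertex` (mesh mode), `onsets`, `sse`, `cv`, and `flatness` (relative
#'   SSE range across the top decile of candidates; near-zero values signal
#'   a poorly identified, flat objective).
#' @export
fit_source_location <- function(lat, matched, geometry, cv, rho_max = 50,
                                grid_spacing = 2.5, t_tol = 1e-6) {
  stopifnot(inherits(geometry, "source_geometry"))
  stopifnot_scalar(cv, "cv", positive = TRUE)
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  sub <- lat[matched$rows, as.character(geometry$path), drop = FALSE]
  if (geometry$mode == "mesh") {
    fit_source_mesh(sub, geometry, cv, rho_max, t_tol)
  } else {
    fit_source_planar(sub, geometry, cv, rho_max, grid_spacing, t_tol)
  }
}

candidate_distances_mesh <- function(geometry) {
  vapply(geometry$fields, function(f) f$distance, numeric(nrow(geometry$mesh$vertices)))
}

fit_source_mesh <- function(sub, geometry, cv, rho_max, t_tol = 1e-6,
                            D = NULL) {
  D <- D %||% candidate_distances_mesh(geometry)
  feas <- which(apply(D, 1, max) <= rho_max)
  if (length(feas) == 0L) {
    stop("all candidate vertices violate the source-to-sensor bound; ",
         "increase 'rho_max'")
  }
  sse <- grid_sse(D[feas, , drop = FALSE], sub, cv, t_tol)
  best <- which.min(sse)
  v <- feas[best]
  ord <- sort(sse)
  top <- ord[seq_len(max(1L, ceiling(length(ord) / 10)))]
  flat <- (max(top) - min(top)) / max(min(top), 1e-12)
  o <- onset_sse(D[v, ], sub, cv, t_tol)
  structure(list(location = geometry$mesh$vertices[v, ], vertex = v,
                 onsets = o$t, sse = o$sse, cv = cv, flatness = flat),
            class = "source_fit")
}

fit_source_planar <- function(sub, geometry, cv, rho_max, grid_spacing = 2.5,
                              t_tol = 1e-6, grid = NULL) {
  S <- geometry$sensors
  z0 <- mean(S[, 3])
  if (is.null(grid)) grid <- planar_grid(S, rho_max, grid_spacing)
  sse <- grid_sse_unclipped(grid, sub, cv)
  feas <- grid$Dmax <= rho_max
  if (!any(feas)) {
    stop("all planar candidates violate the source-to-sensor bound; ",
         "increase 'rho_max'")
  }
  sse[!feas] <- Inf
  start <- grid$xy[which.min(sse), ]
  obj <- function(xy) {
    d <- sqrt((S[, 1] - xy[1])^2 + (S[, 2] - xy[2])^2 + (S[, 3] - z0)^2)
    pen <- sum(pmax(d - rho_max, 0)^2) * 1e6
    onset_sse(d, sub, cv, t_tol)$sse + pen
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  xy <- opt$par
  dfun <- function(p) sqrt((S[, 1] - p[1])^2 + (S[, 2] - p[2])^2 + (S[, 3] - z0)^2)
  d <- dfun(xy)
  if (any(d > rho_max)) {
    # boundary optimum: the penalized polish can overshoot by a hair;
    # project back onto the feasible set along the line to the sensor centroid
    ctr <- colMeans(S)[1:2]
    lo <- 0; hi <- 1
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (any(dfun(xy + mid * (ctr - xy)) > rho_max)) lo <- mid else hi <- mid
    }
    xy <- xy + hi * (ctr - xy)
    d <- dfun(xy)
    if (any(d > rho_max + 1e-6)) {
      stop("fitted source violates the source-to-sensor bound; increase 'rho_max'")
    }
  }
  o <- onset_sse(d, sub, cv, t_tol)
  fin <- sse[is.finite(sse)]
  ordv <- sort(fin)
  top <- ordv[seq_len(max(1L, ceiling(length(ordv) / 10)))]
  flat <- (max(top) - min(top)) / max(min(top), 1e-12)
  structure(list(location = c(xy[1], xy[2], z0), vertex = NA_integer_,
                 onsets = o$t, sse = o$sse, cv = cv, flatness = flat),
            class = "source_fit")
}

# Precompute the planar candidate grid, its sensor distances, and the
# centered quantities used by the fast closed-form grid scan.
planar_grid <- function(S, rho_max, spacing) {
  ctr <- colMeans(S)
  half <- rho_max
  gx <- seq(ctr[1] - half, ctr[1] + half, by = spacing)
  gy <- seq(ctr[2] - half, ctr[2] + half, by = spacing)
  xy <- as.matrix(expand.grid(x = gx, y = gy))
  z0 <- mean(S[, 3])
  D <- vapply(1:4, function(e) {
    sqrt((xy[, 1] - S[e, 1])^2 + (xy[, 2] - S[e, 2])^2 + (z0 - S[e, 3])^2)
  }, numeric(nrow(xy)))
  Dc <- D - rowMeans(D)
  list(xy = xy, D = D, Dc = Dc, A = rowSums(Dc^2), Dmax = apply(D, 1, max),
       feasible = function(rho) apply(D, 1, max) <= rho)
}

# O(G) grid scan of the unclipped profile objective: with unconstrained
# per-activation onsets the SSE separates into centered distance and LAT
# terms. Used only to seed the exact (clipped) polish.
grid_sse_unclipped <- function(grid, sub, cv) {
  xc <- sub - rowMeans(sub)
  nrow(sub) * grid$A / cv^2 - 2 * (grid$Dc %*% colSums(xc))[, 1] / cv +
    sum(xc^2)
}

#' @export
print.source_fit <- function(x, ...) {
  cat(sprintf("Source fit: (%.2f, %.2f, %.2f) mm, SSE %.4g ms^2, cv %.3f mm/ms\n",
              x$location[1], x$location[2], x$location[3], x$sse, x$cv))
  invisible(x)
}

#' Monte-Carlo source localization
#'
#' Repeats the robust least-squares fit over `replicates` draws: each
#' replicate samples a conduction velocity from the positive-truncated
#' `N(mean, sd^2)` of the [estimate_cv()] law, redraws the path-matched
#' activation subset (without replacement, `trials` at a time), and refits
#' the source location. The point estimate is the mean of the replicate
#' locations (mesh mode: the vertex minimizing the mean geodesic distance
#' to the replicate estimates); the dispersion of the replicate cloud
#' quantifies the localization uncertainty.
#'
#' @param lat an [activation_matrix()].
#' @param matched a [filter_path_matched()] result.
#' @param geometry a [source_geometry()].
#' @param cv a [estimate_cv()] result, or a single numeric CV (then no CV
#'   uncertainty is propagated).
#' @param replicates Monte-Carlo replicates `M`.
#' @param trials activations per replicate; default all matched.
#' @param rho_max maximum source-to-sensor distance, mm.
#' @param seed optional RNG seed (fixed seed gives identical results).
#' @inheritParams fit_source_location
#' @return object of class `localization_result`: list with `locations`
#'   (`M x 3`), `point_estimate`, `vertex`, `dispersion` (per-axis SD and
#'   mean distance to the point estimate, mm), `sse`, `cv_draws`, `path`,
#'   `T_star`.
#' @export
monte_carlo_localize <- function(lat, matched, geometry, cv,
                                 replicates = 100, trials = NULL,
                                 rho_max = 50, grid_spacing = 2.5,
                                 seed = NULL, t_tol = 1e-6) {
  if (is.numeric(cv)) cv <- structure(list(mean = cv, sd = 0), class = "cv_estimate")
  stopifnot(inherits(cv, "cv_estimate"))
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  sub_all <- lat[matched$rows, as.character(geometry$path), drop = FALSE]
  n <- nrow(sub_all)
  trials <- min(trials %||% n, n)
  cv_sd <- if (is.na(cv$sd)) 0 else cv$sd
  mesh_mode <- geometry$mode == "mesh"
  D <- if (mesh_mode) candidate_distances_mesh(geometry) else NULL
  grid <- if (!mesh_mode) planar_grid(geometry$sensors, rho_max, grid_spacing) else NULL
  with_seed(seed, {
    loc <- matrix(NA_real_, replicates, 3)
    vert <- integer(replicates)
    sse <- numeric(replicates)
    draws <- numeric(replicates)
    for (m in seq_len(replicates)) {
      cv_m <- rnorm_pos(1L, cv$mean, cv_sd)
      rows <- if (trials < n) sort(sample.int(n, trials)) else seq_len(n)
      sub <- sub_all[rows, , drop = FALSE]
      fit <- if (mesh_mode) {
        fit_source_mesh(sub, geometry, cv_m, rho_max, t_tol, D = D)
      } else {
        fit_source_planar(sub, geometry, cv_m, rho_max, t_tol = t_tol,
                          grid = grid)
      }
      loc[m, ] <- fit$location
      vert[m] <- if (mesh_mode) fit$vertex else NA_integer_
      sse[m] <- fit$sse
      draws[m] <- cv_m
    }
    if (mesh_mode) {
      tab <- table(vert)
      uniq <- as.integer(names(tab))
      acc <- numeric(nrow(geometry$mesh$vertices))
      for (i in seq_along(uniq)) {
        f <- geodesic_field(geometry$mesh, uniq[i])
        acc <- acc + as.integer(tab[i]) * f$distance
      }
      v_hat <- which.min(acc)
      point <- geometry$mesh$vertices[v_hat, ]
      spread <- acc[v_hat] / replicates
    } else {
      v_hat <- NA_integer_
      point <- colMeans(loc)
      spread <- mean(sqrt(rowSums(sweep(loc, 2, point, "-")^2)))
    }
    structure(list(locations = loc, point_estimate = as.numeric(point),
                   vertex = v_hat,
                   dispersion = list(axis_sd = apply(loc, 2, stats::sd),
                                     mean_spread = spread),
                   sse = sse, cv_draws = draws,
                   path = geometry$path, T_star = matched$T_star,
                   replicates = replicates),
              class = "localization_result")
  })
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("Localization (%d replicates, T* = %d): point estimate (%.2f, %.2f, %.2f) mm\n",
              x$replicates, x$T_star, x$point_estimate[1], x$point_estimate[2],
              x$point_estimate[3]))
  cat(sprintf("  spread %.2f mm; cv draws %.3f +/- %.3f mm/ms\n",
              x$dispersion$mean_spread, mean(x$cv_draws), stats::sd(x$cv_draws)))
  invisible(x)
}

#' Pool source estimates across catheter placements
#'
#' Combines per-placement localization results into a pooled point cloud.
#' When ground-truth source locations are supplied (simulation studies),
#' each estimate is assigned to its nearest truth and per-truth pooled
#' centroids and errors are reported.
#'
#' @param results list of `localization_result` objects (possibly nested:
#'   one list per placement).
#' @param truth optional numeric `k x 3` matrix of true source locations.
#' @return object of class `placement_summary`: data frame `estimates`
#'   (placement, rank, x, y, z), overall `centroid` and `spread`, and when
#'   `truth` is given a data frame `by_truth` (pooled centroid, error, and
#'   estimate count per true source).
#' @export
aggregate_placements <- function(results, truth = NULL) {
  flat <- list(); plc <- integer(0); rnk <- integer(0)
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (inherits(r, "localization_result")) r <- list(r)
    for (j in seq_along(r)) {
      if (is.null(r[[j]])) next
      flat[[length(flat) + 1L]] <- r[[j]]$point_estimate
      plc <- c(plc, i); rnk <- c(rnk, j)
    }
  }
  if (length(flat) == 0L) stop("no localization results to aggregate")
  est <- do.call(rbind, flat)
  df <- data.frame(placement = plc, source_rank = rnk,
                   x = est[, 1], y = est[, 2], z = est[, 3])
  centroid <- colMeans(est)
  spread <- mean(sqrt(rowSums(sweep(est, 2, centroid, "-")^2)))
  out <- list(estimates = df, centroid = as.numeric(centroid), spread = spread)
  if (!is.null(truth)) {
    truth <- matrix(as.numeric(truth), ncol = 3)
    d2 <- vapply(seq_len(nrow(truth)), function(k) {
      rowSums(sweep(est, 2, truth[k, ], "-")^2)
    }, numeric(nrow(est)))
    d2 <- matrix(d2, nrow = nrow(est))
    assign_ <- apply(d2, 1, which.min)
    df$truth <- assign_
    df$dist_to_truth <- sqrt(d2[cbind(seq_len(nrow(est)), assign_)])
    by <- do.call(rbind, lapply(seq_len(nrow(truth)), function(k) {
      sel <- assign_ == k
      if (!any(sel)) {
        return(data.frame(truth = k, n = 0L, cx = NA, cy = NA, cz = NA,
                          centroid_error = NA))
      }
      ctr <- colMeans(est[sel, , drop = FALSE])
      data.frame(truth = k, n = sum(sel), cx = ctr[1], cy = ctr[2], cz = ctr[3],
                 centroid_error = sqrt(sum((ctr - truth[k, ])^2)))
    }))
    out$estimates <- df
    out$by_truth <- by
    out$truth <- truth
  }
  structure(out, class = "placement_summary")
}

#' @export
print.placement_summary <- function(x, ...) {
  cat(sprintf("Pooled source estimates: %d estimates from %d placements\n",
              nrow(x$estimates), length(unique(x$estimates$placement))))
  cat(sprintf("  overall centroid (%.2f, %.2f, %.2f) mm, spread %.2f mm\n",
              x$centroid[1], x$centroid[2], x$centroid[3], x$spread))
  if (!is.null(x$by_truth)) {
    for (k in seq_len(nrow(x$by_truth))) {
      b <- x$by_truth[k, ]
      cat(sprintf("  true source %d: %d estimates, pooled centroid error %.2f mm\n",
                  b$truth, b$n, b$centroid_error))
    }
  }
  invisible(x)
}
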