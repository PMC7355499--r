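test_that("six pairwise conduction velocities; a planar wave over collinear
          sensors gives the exact CV", {
  # 1-D wave along x over four collinear sensors: every pairwise estimate
  # equals the generating velocity
  lay <- pentaray_layout()
  cv0 <- 0.6
  xs <- c(-15, -5, 5, 15)
  sensors <- cbind(xs, 0, 0)
  rownames(sensors) <- c("FO", "FI", "LI", "LO")
  geom <- structure(list(mode = "planar", sensors = sensors,
                         sensor_dist = as.matrix(dist(sensors)),
                         path = c(11L, 1L, 9L, 19L)),
                    class = "source_geometry")
  onsets <- seq(0, by = 300, length.out = 10)
  m <- matrix(500, 10, 10,
              dimnames = list(1:10, as.character(c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19))))
  for (j in seq_along(xs)) {
    m[, as.character(geom$path[j])] <- onsets + (xs[j] + 20) / cv0
  }
  lat <- activation_matrix(m, activation_ids = 1:10)
  matched <- structure(list(path = as.list(geom$path), rows = 1:10,
                            activation_ids = rownames(lat), T_star = 10L),
                       class = "path_matched")
  cv <- estimate_cv(lat, matched, geom)
  expect_length(cv$values, 6L)
  expect_equal(cv$values, rep(cv0, 6), tolerance = 1e-9)
  expect_equal(cv$sd, 0, tolerance = 1e-9)
})

test_that("CV recovered from a simulated focal wave is close to the
          generating value", {
  sc <- planar_scenario(src = c(35, -8, 0), n = 35, lat_sd = 0.3,
                        cv_sd = 0.02, seed = 11)
  fit <- focalfit(sc$lat, sigma = 0.3, seed = 12)
  m <- fit$matched[[1]]
  g <- source_geometry(sc$layout, fit$paths[1, ])
  cv <- suppressWarnings(estimate_cv(sc$lat, m, g))
  # chord-vs-wavepath bias keeps this within ~10 percent
  expect_equal(cv$mean, sc$cv_mean, tolerance = 0.1)
})

test_that("planar noiseless localization recovers the source to within the
          solver tolerance", {
  sc <- planar_scenario(src = c(28, 14, 0), lat_sd = 0, cv_sd = 0)
  fit <- focalfit(sc$lat, sigma = 0, seed = 1)
  g <- source_geometry(sc$layout, fit$paths[1, ])
  sf <- fit_source_location(sc$lat, fit$matched[[1]], g, cv = sc$cv_mean)
  expect_lt(sqrt(sum((sf$location - c(28, 14, 0))^2)), 0.1)
  expect_lt(sf$sse, 1e-10)
  # onset constraints hold
  latFO <- sc$lat[fit$matched[[1]]$rows, as.character(g$path[1])]
  expect_true(all(sf$onsets >= 0))
  expect_true(all(sf$onsets < latFO))
})

test_that("a source at a sensor site is a feasible boundary case", {
  lay <- pentaray_layout()
  site <- pair_midpoints(lay)["13", ]
  src <- focal_source(site + c(0, 0, 0), activation_schedule(1, 20, seed = 2)[[1]])
  lat <- simulate_lat_matrix(src, lay, cv_sd = 0, lat_sd = 0, seed = 3)
  fit <- focalfit(lat, sigma = 0, seed = 4)
  g <- source_geometry(lay, fit$paths[1, ])
  sf <- fit_source_location(lat, fit$matched[[1]], g, cv = 0.8)
  expect_lt(sqrt(sum((sf$location - site)^2)), 0.1)
  d_fo <- sqrt(sum((sf$location - g$sensors["FO", ])^2))
  expect_lt(d_fo, 0.1)  # fitted distance term ~0 at the entry sensor
})

test_that("mesh-mode fit equals an independent brute-force vertex
          enumeration", {
  ico <- icosphere_mesh(subdivisions = 2, radius = 30)  # 162 vertices
  lay <- pentaray_layout(center = c(0, 0, 31))
  src <- focal_source(10L, activation_schedule(1, 15, seed = 5)[[1]])
  lat <- simulate_lat_matrix(src, lay, mesh = ico, cv_sd = 0, lat_sd = 0.4,
                             seed = 6)
  fit <- focalfit(lat, sigma = 0.4, seed = 7)
  g <- source_geometry(lay, fit$paths[1, ], mesh = ico)
  m <- fit$matched[[1]]
  cv <- 0.8
  rho <- 60
  sf <- fit_source_location(lat, m, g, cv, rho_max = rho)

  # independent oracle: loop every vertex, clipped closed-form onsets
  sub <- unclass(lat)[m$rows, as.character(g$path), drop = FALSE]
  oracle <- rep(Inf, nrow(ico$vertices))
  for (v in seq_len(nrow(ico$vertices))) {
    d <- vapply(g$fields, function(f) f$distance[v], numeric(1))
    if (max(d) > rho) next
    t_k <- rowMeans(sub) - mean(d / cv)
    t_k <- pmin(pmax(t_k, 0), sub[, 1] - 1e-6)
    sse <- 0
    for (e in 1:4) sse <- sse + sum((d[e] / cv + t_k - sub[, e])^2)
    oracle[v] <- sse
  }
  mn <- min(oracle)
  expect_equal(sf$sse, mn, tolerance = 1e-9)
  expect_lte(oracle[sf$vertex], mn + 1e-9 * max(1, mn))
  # optimality sanity: SSE at the fit is no worse than at the true source
  d_true <- vapply(g$fields, function(f) f$distance[10L], numeric(1))
  t_true <- pmin(pmax(rowMeans(sub) - mean(d_true / cv), 0), sub[, 1] - 1e-6)
  sse_true <- sum((rep(d_true / cv, each = nrow(sub)) + t_true - sub)^2)
  expect_lte(sf$sse, sse_true + 1e-9)
})

test_that("Monte-Carlo localization is deterministic under a fixed seed and
          degenerate without noise", {
  sc <- planar_scenario(src = c(26, 6, 0), lat_sd = 0, cv_sd = 0)
  fit <- focalfit(sc$lat, sigma = 0, seed = 1)
  g <- source_geometry(sc$layout, fit$paths[1, ])
  m <- fit$matched[[1]]
  mc1 <- monte_carlo_localize(sc$lat, m, g, cv = sc$cv_mean, replicates = 20,
                              seed = 42)
  mc2 <- monte_carlo_localize(sc$lat, m, g, cv = sc$cv_mean, replicates = 20,
                              seed = 42)
  expect_identical(mc1$locations, mc2$locations)
  # sigma_c = 0 and sigma = 0: all replicates identical, dispersion 0
  expect_equal(mc1$dispersion$mean_spread, 0, tolerance = 1e-6)
  expect_equal(max(apply(mc1$locations, 2, sd)), 0, tolerance = 1e-6)
})

test_that("replicate dispersion grows with conduction-velocity uncertainty", {
  sc <- planar_scenario(src = c(30, 0, 0), n = 35, lat_sd = 0.5, cv_sd = 0,
                        seed = 21)
  fit <- focalfit(sc$lat, sigma = 0.5, seed = 22)
  g <- source_geometry(sc$layout, fit$paths[1, ])
  m <- fit$matched[[1]]
  sds <- c(0.01, 0.05, 0.1, 0.2)
  disp <- vapply(seq_along(sds), function(i) {
    cv <- structure(list(mean = 0.8, sd = sds[i]), class = "cv_estimate")
    monte_carlo_localize(sc$lat, m, g, cv, replicates = 60,
                         seed = 50)$dispersion$mean_spread
  }, numeric(1))
  expect_gt(cor(sds, disp, method = "spearman"), 0)
})

test_that("placement aggregation pools, assigns to truth, and benefits from
          multiple placements", {
  # all placements agreeing exactly collapse to the common point
  mk <- function(p) structure(list(point_estimate = p,
                                   locations = matrix(p, 1)),
                              class = "localization_result")
  agg <- aggregate_placements(list(mk(c(1, 2, 0)), mk(c(1, 2, 0))))
  expect_equal(agg$centroid, c(1, 2, 0))
  expect_equal(agg$spread, 0)

  # seeded placements around a known source: the pooled centroid beats the
  # worst single placement
  set.seed(77)
  lay0 <- pentaray_layout()
  src_pos <- c(10, -5, 0)
  res <- list()
  for (i in 1:8) {
    ang <- 2 * pi * i / 8
    lay <- pentaray_layout(center = c(10 + 18 * cos(ang), -5 + 18 * sin(ang), 0),
                           orientation = ang / 3)
    src <- focal_source(src_pos, activation_schedule(1, 35, seed = i)[[1]])
    lat <- simulate_lat_matrix(src, lay, cv_sd = 0.04, lat_sd = 0.5,
                               seed = 10 + i)
    fit <- suppressWarnings(focalfit(lat, layout = lay, sigma = 0.5,
                                     seed = 20 + i))
    g <- source_geometry(lay, fit$paths[1, ])
    cv <- suppressWarnings(estimate_cv(lat, fit$matched[[1]], g))
    res[[i]] <- monte_carlo_localize(lat, fit$matched[[1]], g, cv,
                                     replicates = 30, trials = 30,
                                     seed = 30 + i)
  }
  agg <- aggregate_placements(res, truth = rbind(src_pos))
  worst <- max(agg$estimates$dist_to_truth)
  expect_lt(agg$by_truth$centroid_error[1], worst)
})

test_that("localization accuracy improves when the catheter is nearer the
          source", {
  src_pos <- c(0, 0, 0)
  radii <- c(8, 15, 25, 35, 45)
  err <- vapply(seq_along(radii), function(i) {
    lay <- pentaray_layout(center = c(radii[i], 3, 0), orientation = 0.4 * i)
    src <- focal_source(src_pos, activation_schedule(1, 35, seed = i)[[1]])
    lat <- simulate_lat_matrix(src, lay, cv_sd = 0.04, lat_sd = 0.5,
                               seed = 40 + i)
    fit <- suppressWarnings(focalfit(lat, layout = lay, sigma = 0.5,
                                     seed = 50 + i))
    g <- source_geometry(lay, fit$paths[1, ])
    cv <- suppressWarnings(estimate_cv(lat, fit$matched[[1]], g))
    mc <- monte_carlo_localize(lat, fit$matched[[1]], g, cv, replicates = 40,
                               trials = 30, rho_max = 70, seed = 60 + i)
    sqrt(sum((mc$point_estimate - src_pos)^2))
  }, numeric(1))
  expect_gt(cor(radii, err, method = "spearman"), 0)
})
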