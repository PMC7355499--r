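test_that("source counting reproduces both worked-example case studies and
          simple limits", {
  expect_equal(infer_source_count(worked_example_probs(1), alpha = 0.1), 2L)
  # case 2: driven by the inner-loop last-activation probabilities
  expect_equal(infer_source_count(worked_example_probs(2), alpha = 0.1), 2L)
  # one dominant pair everywhere -> 1
  one <- do.call(rbind, lapply(c("inner", "outer"), function(lp) {
    do.call(rbind, lapply(c("first", "last"), function(md) {
      data.frame(loop = lp, pair_index = if (lp == "inner") c(1, 3, 5, 7, 9)
                 else c(11, 13, 15, 17, 19),
                 mode = md, p_star = c(0.9, 0.025, 0.025, 0.025, 0.025))
    }))
  }))
  one$p_value <- activation_pvalue(one$p_star)
  expect_equal(infer_source_count(one, 0.1), 1L)
  # nothing significant -> 1 with a warning
  u <- one
  u$p_star <- 0.2
  u$p_value <- activation_pvalue(0.2)
  expect_warning(n <- infer_source_count(u, 0.1), "low confidence")
  expect_equal(n, 1L)
})

test_that("rank extraction reproduces the printed path sets of both case
          studies", {
  p1 <- extract_probable_paths(worked_example_probs(1), n_sources = 2)
  expect_equal(unlist(p1[1, c("FO", "FI", "LI", "LO")], use.names = FALSE),
               c(13L, 3L, 9L, 17L))
  expect_equal(unlist(p1[2, c("FO", "FI", "LI", "LO")], use.names = FALSE),
               c(11L, 1L, 7L, 15L))

  p2 <- extract_probable_paths(worked_example_probs(2), n_sources = 2)
  expect_equal(unlist(p2[1, c("FO", "FI", "LI", "LO")], use.names = FALSE),
               c(13L, 3L, 7L, 17L))
  expect_equal(unlist(p2[2, c("FO", "FI", "LI", "LO")], use.names = FALSE),
               c(13L, 3L, 9L, 19L))
  # the shared entry pairs are flagged, and the sub-uniform-level rank-2
  # candidates were replaced by the rank-1 entries
  e2 <- attr(p2, "entries")
  expect_true(all(e2$shared[e2$source_rank == 2 & e2$entry %in% c("FO", "FI")]))
  expect_false(any(e2$shared[e2$source_rank == 1]))
  # the rank-2 outer-last entry (pair 19) is kept but flagged non-significant
  lo2 <- e2[e2$source_rank == 2 & e2$entry == "LO", ]
  expect_equal(lo2$pair_index, 19L)
  expect_false(lo2$significant)
})

test_that("single dominant source yields the obvious path", {
  one <- do.call(rbind, lapply(c("inner", "outer"), function(lp) {
    do.call(rbind, lapply(c("first", "last"), function(md) {
      idx <- if (lp == "inner") c(1L, 3L, 5L, 7L, 9L) else c(11L, 13L, 15L, 17L, 19L)
      p <- rep(0.025, 5)
      p[if (md == "first") 2 else 4] <- 0.9
      data.frame(loop = lp, pair_index = idx, mode = md, p_star = p)
    }))
  }))
  one$p_value <- activation_pvalue(one$p_star)
  p <- extract_probable_paths(one, n_sources = 1)
  expect_equal(unlist(p[1, c("FO", "FI", "LI", "LO")], use.names = FALSE),
               c(13L, 3L, 7L, 17L))
})

test_that("path-matched selection is exhaustive for one noiseless source and
          disjoint for two interleaved sources", {
  sc <- planar_scenario(lat_sd = 0, cv_sd = 0)
  fit <- focalfit(sc$lat, sigma = 0, seed = 1)
  m <- filter_path_matched(sc$lat, fit$paths[1, ], strictness = "full")
  expect_equal(m$T_star, nrow(sc$lat))

  lay <- pentaray_layout()
  sched <- activation_schedule(2, 30, seed = 5)
  srcs <- list(focal_source(c(35, 4, 0), sched[[1]]),
               focal_source(c(-30, 12, 0), sched[[2]]))
  lat2 <- simulate_lat_matrix(srcs, lay, cv_sd = 0, lat_sd = 0, seed = 6)
  fit2 <- focalfit(lat2, sigma = 0, seed = 7)
  expect_equal(fit2$n_sources, 2L)
  m1 <- filter_path_matched(lat2, fit2$paths[1, ])
  m2 <- filter_path_matched(lat2, fit2$paths[2, ])
  expect_length(intersect(m1$activation_ids, m2$activation_ids), 0)
  expect_equal(m1$T_star + m2$T_star, nrow(lat2))

  # an impossible path errors
  bogus <- data.frame(source_rank = 1, FO = 11, FI = 1, LI = 1, LO = 11)
  bogus$LO <- setdiff(c(11, 13, 15, 17, 19),
                      c(fit$paths$FO, fit$paths$LO))[1]
  expect_error(filter_path_matched(sc$lat, bogus), "no activation matches")
})

test_that("with one noiseless source the inferred path equals the
          geodesic-order path at several catheter poses", {
  set.seed(99)
  for (rep in 1:4) {
    ctr <- c(runif(1, -10, 10), runif(1, -10, 10), 0)
    lay <- pentaray_layout(center = ctr, orientation = runif(1, 0, 2 * pi))
    src_pos <- c(runif(1, 20, 40) * cos(runif(1, 0, 2 * pi)),
                 runif(1, 20, 40) * sin(runif(1, 0, 2 * pi)), 0)
    src <- focal_source(src_pos, activation_schedule(1, 35, seed = rep)[[1]])
    lat <- simulate_lat_matrix(src, lay, cv_sd = 0, lat_sd = 0, seed = rep)
    fit <- focalfit(lat, sigma = 0, seed = rep)
    d <- sqrt(rowSums(sweep(pair_midpoints(lay), 2, src_pos, "-")^2))
    expect_equal(fit$paths$FO[1], as.integer(names(which.min(d[6:10]))))
    expect_equal(fit$paths$FI[1], as.integer(names(which.min(d[1:5]))))
    expect_equal(fit$paths$LI[1], as.integer(names(which.max(d[1:5]))))
    expect_equal(fit$paths$LO[1], as.integer(names(which.max(d[6:10]))))
  }
})

test_that("path-matched fraction decreases as LAT noise grows", {
  lay <- pentaray_layout()
  src <- focal_source(c(30, 10, 0), activation_schedule(1, 60, seed = 3)[[1]])
  frac <- vapply(c(0, 2, 8), function(sg) {
    lat <- simulate_lat_matrix(src, lay, cv_sd = 0, lat_sd = sg, seed = 4)
    fit0 <- focalfit(simulate_lat_matrix(src, lay, cv_sd = 0, lat_sd = 0,
                                         seed = 4),
                     sigma = 0, seed = 5)
    m <- tryCatch(filter_path_matched(lat, fit0$paths[1, ], "full"),
                  error = function(e) list(T_star = 0))
    m$T_star / nrow(lat)
  }, numeric(1))
  expect_true(all(diff(frac) < 0))
  expect_equal(frac[1], 1)
})
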