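test_that("resampling returns identical copies when unperturbed and carries
          the configured noise variance", {
  sc <- planar_scenario(n = 20, lat_sd = 0, cv_sd = 0)
  reps <- resample_lats(sc$lat, resamples = 5, trials = NULL, sigma = 0,
                        seed = 1)
  for (r in reps) expect_equal(unclass(r), unclass(sc$lat), ignore_attr = TRUE)

  reps1 <- resample_lats(sc$lat, resamples = 3, trials = 10, sigma = 1, seed = 2)
  reps2 <- resample_lats(sc$lat, resamples = 3, trials = 10, sigma = 1, seed = 2)
  expect_identical(reps1, reps2)
  expect_true(all(vapply(reps1, nrow, integer(1)) == 10L))

  # Monte-Carlo check of the perturbation variance
  big <- resample_lats(sc$lat, resamples = 200, trials = NULL, sigma = 0.7,
                       seed = 3)
  pert <- vapply(big, function(r) as.numeric(r - unclass(sc$lat)),
                 numeric(length(sc$lat)))
  expect_equal(var(as.numeric(pert)), 0.49, tolerance = 0.03)

  expect_error(resample_lats(sc$lat, trials = 100), "exceeds")
})

test_that("indicators mark the extreme pair with smallest-index tie-breaks
          and counts tally to T", {
  m <- matrix(0, 3, 10, dimnames = list(NULL, as.character(c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19))))
  m[, 6:10] <- rbind(c(1, 2, 3, 4, 5),   # first 11, last 19
                     c(2, 1, 1, 3, 4),   # tie between 13 and 15 -> 13
                     c(5, 4, 3, 2, 1))   # first 19, last 11
  m[, 1:5] <- m[, 6:10]
  lat <- activation_matrix(m)
  f <- compute_indicators(lat, "first")
  expect_equal(unname(which(f$outer[1, ] == 1L)), 1L)  # pair 11
  expect_equal(unname(which(f$outer[2, ] == 1L)), 2L)  # tie -> pair 13
  expect_equal(unname(which(f$outer[3, ] == 1L)), 5L)  # pair 19
  l <- compute_indicators(lat, "last")
  expect_equal(unname(which(l$outer[1, ] == 1L)), 5L)
  expect_true(all(rowSums(f$outer) == 1L) && all(rowSums(f$inner) == 1L))

  cnt <- count_first_last(f)
  expect_equal(sum(cnt$outer), 3)
  expect_equal(sum(cnt$inner), 3)

  # random indicators match a brute-force tally
  set.seed(8)
  r <- matrix(rnorm(300), 30, 10,
              dimnames = list(NULL, colnames(m)))
  latr <- activation_matrix(r)
  cf <- count_first_last(compute_indicators(latr, "first"))
  brute <- table(factor(apply(r[, 6:10], 1, which.min), levels = 1:5))
  expect_equal(unname(cf$outer), as.numeric(brute))

  # missing LATs exclude the activation from that loop only
  r[1, 2] <- NA
  expect_warning(fi <- compute_indicators(activation_matrix(r), "first"),
                 "excluded")
  expect_equal(nrow(fi$inner), 29L)
  expect_equal(nrow(fi$outer), 30L)
})

test_that("empirical-likelihood bounds match the independent binary closed
          form and collapse correctly in degenerate cases", {
  # frozen worked value (computed from the two-group profile equation):
  # T = 30, n1 = 15, alpha = 0.05 -> (0.3267, 0.6733)
  b <- el_probability_bounds(rep(c(1, 0), each = 15), alpha = 0.05)
  expect_equal(unname(b), c(0.3266582, 0.6733418), tolerance = 1e-6)

  # oracle agreement across a spread of (T, n1)
  for (T in c(10, 30, 100)) {
    for (n1 in unique(c(0L, 1L, T %/% 3, T %/% 2, T - 1L, T))) {
      z <- c(rep(1, n1), rep(0, T - n1))
      got <- el_probability_bounds(z, alpha = 0.05)
      want <- el_binary_oracle(n1, T, 0.05)
      expect_equal(unname(got), unname(want), tolerance = 1e-6,
                   label = sprintf("T=%d n1=%d", T, n1))
    }
  }

  # all-ones sample pins the upper bound at 1
  expect_equal(unname(el_probability_bounds(rep(1, 20), 0.1)[2]), 1)
  # alpha -> 1 collapses the interval onto the sample mean
  b2 <- el_probability_bounds(c(rep(1, 12), rep(0, 18)), alpha = 0.9999)
  expect_equal(unname(b2), c(0.4, 0.4), tolerance = 1e-3)

  # direct weight optimization oracle at tiny T (constrained optim over w)
  z <- c(1, 1, 0, 0, 0, 1, 0, 0, 1, 0)
  got <- el_probability_bounds(z, alpha = 0.1)
  q <- qchisq(0.9, 1)
  for (side in c(1, -1)) {
    # optimize over the softmax parameterization to respect the constraints
    fn <- function(theta) {
      w <- exp(theta) / sum(exp(theta))
      stat <- -2 * sum(log(10 * w))
      side * sum(w * z) + 1e4 * max(stat - q, 0)^2
    }
    opt <- optim(rep(0, 10), fn, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    w <- exp(opt$par) / sum(exp(opt$par))
    bound <- sum(w * z)
    target <- if (side == 1) got[["lb"]] else got[["ub"]]
    expect_equal(bound, target, tolerance = 1e-3)
  }
})

test_that("EL interval width is non-increasing in T at fixed empirical mean", {
  widths <- vapply(c(10, 30, 100), function(T) {
    z <- c(rep(1, T * 0.3), rep(0, T * 0.7))
    b <- el_probability_bounds(z, alpha = 0.05)
    b[["ub"]] - b[["lb"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("constrained multinomial MLE reproduces closed forms and respects
          the box", {
  expect_equal(unname(multinomial_mle(c(10, 20, 0, 0, 0))),
               c(1 / 3, 2 / 3, 0, 0, 0))
  expect_equal(unname(multinomial_mle(c(6, 6, 6, 6, 6), lb = 0.05, ub = 0.9)),
               rep(0.2, 5))
  # frozen oracle case: counts (28,1,1,0,0), lb = 0.05
  p <- multinomial_mle(c(28, 1, 1, 0, 0), lb = 0.05)
  oracle <- mle_grid_oracle(c(28, 1, 1, 0, 0), lb = rep(0.05, 5),
                            ub = rep(1, 5))
  expect_equal(unname(p), unname(oracle), tolerance = 1e-3)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_true(all(p >= 0.05 - 1e-12))

  # aggregation across replicates = summing counts
  reps <- list(c(3, 1, 0, 0, 0), c(2, 2, 1, 0, 0), c(5, 0, 0, 0, 0))
  expect_equal(multinomial_mle(reps), multinomial_mle(Reduce(`+`, reps)))

  expect_error(multinomial_mle(c(1, 1, 1, 1, 1), lb = 0.3), "lower bounds")
  expect_error(multinomial_mle(c(1, 1, 1, 1, 1), ub = 0.1), "upper bounds")
})

test_that("activation p-values are monotone, bounded by one half, and round
          with the reporting floor", {
  expect_equal(report_pvalue(activation_pvalue(0.31)), 0.06)
  expect_equal(report_pvalue(activation_pvalue(0.20)), 0.16)
  expect_equal(activation_pvalue(0), 0.5)
  expect_equal(report_pvalue(activation_pvalue(0.9)), 0.01)  # floored
  p <- activation_pvalue(seq(0, 1, by = 0.05))
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 0.5))
})

test_that("significant pairs are selected below alpha and ordered by
          probability", {
  probs <- worked_example_probs(1)
  sig <- significant_pairs(probs, alpha = 0.1)
  expect_equal(sig[["first.outer"]], c(13L, 11L))
  expect_equal(sig[["first.inner"]], c(3L, 1L))
  expect_equal(sig[["last.outer"]], c(17L, 15L))
  expect_equal(sig[["last.inner"]], c(9L, 7L))
  # uniform probabilities: nothing significant at alpha = 0.1
  u <- data.frame(loop = "outer", pair_index = c(11L, 13L, 15L, 17L, 19L),
                  mode = "first", p_star = 0.2,
                  p_value = activation_pvalue(0.2))
  expect_equal(significant_pairs(u, 0.1)[["first.outer"]], integer(0))
  # a certain pair is significant on its own
  s <- data.frame(loop = "inner", pair_index = 1L, mode = "first",
                  p_star = 1, p_value = activation_pvalue(1))
  expect_equal(significant_pairs(s, 0.1)[["first.inner"]], 1L)
})
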