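# Activation-order statistics: resampling, first/last indicators,
# multinomial counts, empirical-likelihood probability bounds, constrained
# multinomial maximum likelihood, and the activation-probability test.

#' Perturb-and-subsample LAT replicates
#'
#' Generates `M` replicate activation matrices. Each replicate restricts the
#' observed matrix to `trials` randomly selected activations (without
#' replacement, ids kept in ascending order) and perturbs every LAT with
#' i.i.d. `N(0, sigma^2)` noise, propagating the LAT observation-noise model
#' into the downstream estimates.
#'
#' @param lat an [activation_matrix()].
#' @param resamples number of replicates `M`.
#' @param trials activations per replicate `T`; `NULL` keeps all. Must not
#'   exceed the number of observed activations.
#' @param sigma LAT noise SD, ms (>= 0).
#' @param seed optional RNG seed.
#' @return list of `M` activation matrices.
#' @export
resample_lats <- function(lat, resamples = 100, trials = NULL, sigma = 1,
                          seed = NULL) {
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  if (resamples < 1L) stop("'resamples' must be >= 1")
  if (sigma < 0) stop("'sigma' must be >= 0")
  n <- nrow(lat)
  trials <- trials %||% n
  if (trials > n) {
    stop("'trials' (", trials, ") exceeds the available activations (", n, ")")
  }
  with_seed(seed, {
    lapply(seq_len(resamples), function(m) {
      ids <- sort(sample.int(n, trials))
      x <- lat[ids, , drop = FALSE]
      if (sigma > 0) x <- x + matrix(stats::rnorm(length(x), 0, sigma), nrow(x))
      activation_matrix(x, activation_ids = rownames(lat)[ids])
    })
  })
}

#' First/last activation indicators per loop
#'
#' For every activation and loop, marks the pair with the minimal (mode
#' `"first"`) or maximal (mode `"last"`) LAT among the loop's five pairs.
#' Exact ties are broken toward the smallest pair index. Activations with a
#' missing LAT in a loop are excluded from that loop with a warning.
#'
#' @param lat an [activation_matrix()].
#' @param mode `"first"` or `"last"`.
#' @return object of class `indicator_sample`: list with binary matrices
#'   `inner` and `outer` (activations x 5 pairs) and the `mode`.
#' @export
compute_indicators <- function(lat, mode = c("first", "last")) {
  mode <- match.arg(mode)
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  loops <- pair_loops(lat)
  out <- list()
  for (lp in c("inner", "outer")) {
    cols <- names(loops)[loops == lp]
    sub <- lat[, cols, drop = FALSE]
    ok <- rowSums(is.na(sub)) == 0L
    if (any(!ok)) {
      warning(sum(!ok), " activation(s) with missing LATs excluded from the ",
              lp, " loop")
    }
    sub <- sub[ok, , drop = FALSE]
    z <- matrix(0L, nrow(sub), length(cols),
                dimnames = list(rownames(sub), cols))
    if (nrow(sub)) {
      pick <- apply(sub, 1, if (mode == "first") which.min else which.max)
      # which.min/which.max return the first extreme -> smallest pair index
      z[cbind(seq_len(nrow(sub)), pick)] <- 1L
    }
    out[[lp]] <- z
  }
  structure(c(out, list(mode = mode)), class = "indicator_sample")
}

#' Multinomial counts of first/last activations
#'
#' Column sums of the indicator sample: `n[i, j]` is the number of
#' activations in which pair `j` of loop `i` was first (or last). Per loop,
#' the counts sum to the number of included activations.
#'
#' @param sample an [compute_indicators()] result.
#' @return list with named count vectors `inner` and `outer`, the per-loop
#'   totals `T`, and the `mode`.
#' @export
count_first_last <- function(sample) {
  stopifnot(inherits(sample, "indicator_sample"))
  list(inner = colSums(sample$inner), outer = colSums(sample$outer),
       T = c(inner = nrow(sample$inner), outer = nrow(sample$outer)),
       mode = sample$mode)
}

# -2 log empirical-likelihood ratio for the mean of data z at mu.
# Inner problem solved through the Lagrange multiplier eta:
#   w_t = 1 / (n (1 + eta (z_t - mu))),  sum_t w_t (z_t - mu) = 0.
el_log_ratio_stat <- function(z, mu) {
  n <- length(z)
  zbar <- mean(z)
  if (abs(mu - zbar) < 1e-14) return(0)
  lo <- min(z); hi <- max(z)
  if (mu <= lo || mu >= hi) return(Inf)
  g <- function(eta) sum((z - mu) / (1 + eta * (z - mu)))
  eps <- 1e-11
  eta_lo <- -1 / (hi - mu) + eps
  eta_hi <- 1 / (mu - lo) - eps
  eta <- stats::uniroot(g, c(eta_lo, eta_hi), tol = 1e-13)$root
  2 * sum(log1p(eta * (z - mu)))
}

#' Empirical-likelihood bounds for an activation probability
#'
#' Profile empirical-likelihood confidence bounds for the mean of a binary
#' indicator vector: the minimum and maximum of `sum_t w_t z_t` over weight
#' vectors with `sum w = 1`, `w >= 0`, subject to
#' `-2 sum_t log(T w_t) <= chisq(1, 1 - alpha)`. Solved by root-finding on
#' the profile statistic, whose inner weight problem is solved through its
#' Lagrange multiplier. When the sample is all zeros (or all ones) the
#' interval is anchored at 0 (or 1) and the other bound solves the
#' one-sided equation `-2 T log(1 - mu) = chisq` (respectively its mirror).
#'
#' @param z binary 0/1 vector of length `T >= 2`, or an `indicator_sample`
#'   (then bounds are computed for every loop and pair).
#' @param alpha significance level in (0, 1); the bounds are a `1 - alpha`
#'   confidence interval.
#' @return for a vector: named numeric `c(lb, ub)` clipped to `[0, 1]`; for
#'   an `indicator_sample`: data frame with columns `loop`, `pair_index`,
#'   `lb`, `ub`.
#' @references Owen, A. (2001) Empirical Likelihood. Chapman & Hall/CRC.
#' @export
el_probability_bounds <- function(z, alpha = 0.1) {
  if (inherits(z, "indicator_sample")) {
    rows <- list()
    for (lp in c("inner", "outer")) {
      m <- z[[lp]]
      for (j in colnames(m)) {
        b <- el_probability_bounds(m[, j], alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          loop = lp, pair_index = as.integer(j), lb = b[["lb"]], ub = b[["ub"]])
      }
    }
    return(do.call(rbind, rows))
  }
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  z <- as.numeric(z)
  n <- length(z)
  if (n < 2L) stop("empirical-likelihood bounds need T >= 2 observations")
  if (any(!z %in% c(0, 1))) stop("indicator data must be binary 0/1")
  q <- stats::qchisq(1 - alpha, df = 1)
  n1 <- sum(z)
  if (n1 == 0L) {
    return(c(lb = 0, ub = min(1, 1 - exp(-q / (2 * n)))))
  }
  if (n1 == n) {
    return(c(lb = max(0, exp(-q / (2 * n))), ub = 1))
  }
  zbar <- n1 / n
  f <- function(mu) el_log_ratio_stat(z, mu) - q
  eps <- 1e-12
  lb <- stats::uniroot(f, c(eps, zbar), tol = 1e-12)$root
  ub <- stats::uniroot(f, c(zbar, 1 - eps), tol = 1e-12)$root
  c(lb = max(0, lb), ub = min(1, ub))
}

#' Box-constrained multinomial maximum likelihood
#'
#' Maximizes the multinomial log-likelihood `sum_j c_j log p_j` over the
#' probability simplex intersected with the box `lb_j <= p_j <= ub_j`,
#' where `c_j` are the first/last counts aggregated over all resampling
#' replicates (summing counts across replicates is equivalent to summing
#' the replicate log-likelihoods). The KKT solution is the water-filling
#' form `p_j = clip(c_j / lambda, lb_j, ub_j)` with `lambda` chosen so the
#' probabilities sum to one (found by monotone root-finding, then made
#' exact on the final active set). With an inactive box this reduces to the
#' closed form `c_j / sum(c)`.
#'
#' @param counts either a single named count vector, or a list of count
#'   vectors / a matrix with one replicate per row (summed).
#' @param lb,ub box bounds per pair (recycled scalars allowed). The box must
#'   be feasible: `sum(lb) <= 1 <= sum(ub)`.
#' @return named probability vector summing to 1 within 1e-12.
#' @export
multinomial_mle <- function(counts, lb = 0, ub = 1) {
  if (is.list(counts)) counts <- do.call(rbind, counts)
  if (is.matrix(counts)) counts <- colSums(counts)
  counts <- as.numeric_named(counts)
  D <- length(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  lb <- rep_len(as.numeric(lb), D)
  ub <- rep_len(as.numeric(ub), D)
  if (any(lb > ub)) stop("infeasible box: lb exceeds ub for some pair")
  if (sum(lb) > 1 + 1e-12) {
    stop("infeasible box: lower bounds sum to ", signif(sum(lb), 6), " > 1")
  }
  if (sum(ub) < 1 - 1e-12) {
    stop("infeasible box: upper bounds sum to ", signif(sum(ub), 6), " < 1")
  }
  c_ <- counts
  if (sum(c_) == 0) c_ <- rep(1, D)  # no information: uniform water-filling
  S <- function(lam) sum(pmin(pmax(c_ / lam, lb), ub))
  lam_lo <- 1e-12 * sum(c_)
  lam_hi <- 1e12 * sum(c_)
  if (S(lam_lo) < 1) {
    p <- ub  # only possible when sum(ub) == 1 within tolerance
  } else if (S(lam_hi) > 1) {
    p <- lb
  } else {
    lam <- stats::uniroot(function(l) S(l) - 1, c(lam_lo, lam_hi),
                          tol = 1e-14)$root
    p <- pmin(pmax(c_ / lam, lb), ub)
    free <- c_ / lam > lb & c_ / lam < ub
    if (any(free) && sum(c_[free]) > 0) {
      # exact lambda on the identified active set
      lam <- sum(c_[free]) / (1 - sum(p[!free]))
      p[free] <- c_[free] / lam
    }
  }
  p <- p / sum(p)
  names(p) <- names(counts)
  p
}

as.numeric_named <- function(x) {
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' Activation-order hypothesis test
#'
#' Tests whether a pair's estimated first/last activation probability `p*`
#' is compatible with no preferential activation. The statistic is the
#' ratio of `p*` to the uniform probability `1/D`, i.e. `z = p* * D`,
#' referred to a standard normal upper tail: `p = 1 - Phi(z)`. The raw
#' p-value lies in `(0, 0.5]`; `report_pvalue()` applies the 2-decimal
#' rounding with a 0.01 floor used in reported tables.
#'
#' @param p_star probability estimate(s) in `[0, 1]`.
#' @param D pairs per loop (default 5).
#' @return raw upper-tail p-value(s).
#' @export
activation_pvalue <- function(p_star, D = 5) {
  if (any(p_star < 0 | p_star > 1)) stop("'p_star' must lie in [0, 1]")
  if (D < 2) stop("'D' must be >= 2")
  1 - stats::pnorm(p_star * D)
}

#' @rdname activation_pvalue
#' @param p raw p-value(s).
#' @export
report_pvalue <- function(p) {
  pmax(round(p, 2), 0.01)
}

#' Significant pairs per loop, ordered by probability
#'
#' @param probs an activation-probability data frame (see [focalfit()];
#'   columns `loop`, `pair_index`, `mode`, `p_star`, `p_value`).
#' @param alpha significance level; pairs with raw p-value below `alpha`
#'   are returned, ordered by descending `p_star`.
#' @return named list `mode.loop -> integer vector of pair indices`.
#' @export
significant_pairs <- function(probs, alpha = 0.1) {
  stopifnot(is.data.frame(probs))
  out <- list()
  for (md in unique(probs$mode)) {
    for (lp in unique(probs$loop)) {
      sub <- probs[probs$mode == md & probs$loop == lp, ]
      sub <- sub[sub$p_value < alpha, ]
      sub <- sub[order(-sub$p_star, sub$pair_index), ]
      out[[paste(md, lp, sep = ".")]] <- as.integer(sub$pair_index)
    }
  }
  out
}

# Assemble the per-pair probability table for one activation matrix:
# EL bounds from the observed indicators, MLE from counts aggregated over
# the perturbed resamples, and the hypothesis test.
estimate_activation_probs <- function(lat, alpha = 0.1, resamples = 100,
                                      trials = NULL, sigma = 1, seed = NULL) {
  reps <- resample_lats(lat, resamples = resamples, trials = trials,
                        sigma = sigma, seed = seed)
  rows <- list()
  for (md in c("first", "last")) {
    obs_ind <- compute_indicators(lat, md)
    bounds <- el_probability_bounds(obs_ind, alpha)
    agg <- lapply(reps, function(r) count_first_last(compute_indicators(r, md)))
    for (lp in c("inner", "outer")) {
      cnt <- colSums(do.call(rbind, lapply(agg, `[[`, lp)))
      b <- bounds[bounds$loop == lp, ]
      b <- b[match(as.integer(names(cnt)), b$pair_index), ]
      p <- multinomial_mle(cnt, lb = b$lb, ub = b$ub)
      pv <- activation_pvalue(p, D = length(p))
      rows[[length(rows) + 1L]] <- data.frame(
        loop = lp, pair_index = as.integer(names(cnt)), mode = md,
        p_star = as.numeric(p), lb = b$lb, ub = b$ub,
        count = as.numeric(cnt),
        p_value = pv, p_reported = report_pvalue(pv)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
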