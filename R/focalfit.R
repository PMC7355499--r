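# The main model interface: fit activation-order probabilities, count
# sources, extract wave paths; predict() performs source localization.

#' Fit the activation-order model to a LAT matrix
#'
#' The central fitting function of the package. The first/last activation
#' order of the bipolar pairs in each catheter loop is modeled as a
#' multinomial distribution with `D = 5` outcomes. The fit:
#'
#' 1. generates `resamples` perturbed replicates of the LAT matrix
#'    (Gaussian LAT noise of SD `sigma`, random subsets of `trials`
#'    activations), propagating LAT uncertainty ([resample_lats()]);
#' 2. computes first/last indicators and multinomial counts per loop
#'    ([compute_indicators()], [count_first_last()]);
#' 3. derives robust empirical-likelihood bounds for each activation
#'    probability at level `1 - alpha` ([el_probability_bounds()]);
#' 4. maximizes the multinomial likelihood over the simplex intersected
#'    with those bounds ([multinomial_mle()]);
#' 5. tests each probability against the uniform level `1/D`
#'    ([activation_pvalue()]);
#' 6. infers the number of sources and their most probable wave paths
#'    ([infer_source_count()], [extract_probable_paths()]) and selects the
#'    activations consistent with each path ([filter_path_matched()]).
#'
#' @param lat an [activation_matrix()] (or coercible matrix) of LATs, ms.
#' @param layout optional [pentaray_layout()]; stored for later
#'   localization via [predict.focalfit()].
#' @param alpha significance level for bounds, tests and path flags.
#' @param resamples number of perturb-and-subsample replicates `M`.
#' @param trials activations per replicate `T`; defaults to
#'   `min(30, nrow(lat))`.
#' @param sigma LAT observation-noise SD used in the resampling, ms.
#' @param strictness path-matching strictness, see [filter_path_matched()].
#' @param seed optional RNG seed; fixed seed gives reproducible fits.
#' @return An object of class `focalfit`, a list with components
#'   `probabilities` (per loop/pair/mode: `p_star`, EL `lb`/`ub`,
#'   aggregated `count`, raw and reported p-values), `n_sources`, `paths`
#'   (a [extract_probable_paths()] table), `matched` (per-path activation
#'   subsets; `NULL` where no activation matched), `lat`, `layout`,
#'   `config` and `call`.
#' @examples
#' lay <- pentaray_layout()
#' src <- focal_source(c(25, 5, 0), activation_schedule(1, 40, seed = 1)[[1]])
#' lat <- simulate_lat_matrix(src, lay, lat_sd = 0.5, seed = 2)
#' fit <- focalfit(lat, layout = lay, sigma = 0.5, seed = 3)
#' fit
#' coef(fit)
#' @seealso [predict.focalfit()] for source localization,
#'   [summary.focalfit()], [plot.focalfit()]
#' @export
focalfit <- function(lat, layout = NULL, alpha = 0.1, resamples = 100,
                     trials = NULL, sigma = 1,
                     strictness = c("outer_only", "full"), seed = NULL) {
  strictness <- match.arg(strictness)
  cl <- match.call()
  lat <- activation_matrix(lat, activation_ids = rownames(lat))
  trials <- trials %||% min(30L, nrow(lat))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  probs <- estimate_activation_probs(lat, alpha = alpha, resamples = resamples,
                                     trials = trials, sigma = sigma,
                                     seed = seed)
  n_sources <- suppressWarnings(infer_source_count(probs, alpha))
  paths <- extract_probable_paths(probs, n_sources = n_sources, alpha = alpha)
  matched <- lapply(seq_len(nrow(paths)), function(r) {
    tryCatch(filter_path_matched(lat, paths[r, ], strictness = strictness),
             error = function(e) {
               warning("path ", r, ": ", conditionMessage(e))
               NULL
             })
  })
  structure(list(probabilities = probs, n_sources = n_sources, paths = paths,
                 matched = matched, lat = lat, layout = layout,
                 config = list(alpha = alpha, resamples = resamples,
                               trials = trials, sigma = sigma,
                               strictness = strictness, seed = seed),
                 call = cl),
            class = "focalfit")
}

#' @export
print.focalfit <- function(x, ...) {
  cat("Activation-order model fit\n")
  cat(sprintf("  %d activations, M = %d resamples of T = %d trials, sigma = %g ms, alpha = %g\n",
              nrow(x$lat), x$config$resamples, x$config$trials,
              x$config$sigma, x$config$alpha))
  cat(sprintf("  inferred sources: %d\n", x$n_sources))
  print(x$paths)
  ts <- vapply(x$matched, function(m) if (is.null(m)) 0L else m$T_star, integer(1))
  cat("  path-matched activations (T*):", paste(ts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.focalfit <- function(object, ...) {
  p <- object$probabilities
  m <- matrix(NA_real_, 10, 2,
              dimnames = list(as.character(PAIR_INDEX_ALL), c("first", "last")))
  for (md in c("first", "last")) {
    sub <- p[p$mode == md, ]
    m[as.character(sub$pair_index), md] <- sub$p_star
  }
  m
}

#' Summarize an activation-order fit
#'
#' @param object a [focalfit()] object.
#' @param ... unused.
#' @return object of class `summary.focalfit` with the probability table
#'   (significance-starred), source count, and paths.
#' @export
summary.focalfit <- function(object, ...) {
  p <- object$probabilities
  p$sig <- ifelse(p$p_value < object$config$alpha, "*", "")
  structure(list(probabilities = p, n_sources = object$n_sources,
                 paths = object$paths, config = object$config),
            class = "summary.focalfit")
}

#' @export
print.summary.focalfit <- function(x, ...) {
  cat("Activation-order probabilities (p* with EL bounds; * = p <",
      x$config$alpha, ")\n")
  for (md in c("first", "last")) {
    for (lp in c("outer", "inner")) {
      sub <- x$probabilities[x$probabilities$mode == md &
                               x$probabilities$loop == lp, ]
      cat(sprintf("  %s loop, %s activated:\n", lp, md))
      for (i in seq_len(nrow(sub))) {
        cat(sprintf("    pair %2d: p* = %.2f [%.2f, %.2f], p-value %.2f %s\n",
                    sub$pair_index[i], sub$p_star[i], sub$lb[i], sub$ub[i],
                    sub$p_reported[i], sub$sig[i]))
      }
    }
  }
  cat(sprintf("Inferred sources: %d\n", x$n_sources))
  print(x$paths)
  invisible(x)
}

#' Residual activation frequencies
#'
#' Difference between the observed first/last relative frequencies (over
#' all activations of the fitted matrix) and the fitted probabilities.
#'
#' @param object a [focalfit()] object.
#' @param ... unused.
#' @return data frame with columns `loop`, `pair_index`, `mode`,
#'   `observed`, `fitted`, `residual`.
#' @export
residuals.focalfit <- function(object, ...) {
  out <- list()
  for (md in c("first", "last")) {
    cnt <- count_first_last(compute_indicators(object$lat, md))
    for (lp in c("inner", "outer")) {
      obs <- cnt[[lp]] / cnt$T[[lp]]
      sub <- object$probabilities[object$probabilities$mode == md &
                                    object$probabilities$loop == lp, ]
      fit <- sub$p_star[match(as.integer(names(obs)), sub$pair_index)]
      out[[length(out) + 1L]] <- data.frame(
        loop = lp, pair_index = as.integer(names(obs)), mode = md,
        observed = as.numeric(obs), fitted = fit,
        residual = as.numeric(obs) - fit)
    }
  }
  do.call(rbind, out)
}

#' Simulate activation-order outcomes from a fitted model
#'
#' Draws first/last activated pairs for each loop from the fitted
#' multinomial probabilities.
#'
#' @param object a [focalfit()] object.
#' @param nsim number of simulated samples.
#' @param seed optional RNG seed.
#' @param trials activations per simulated sample; defaults to the fit's
#'   trial count.
#' @param ... unused.
#' @return list of `nsim` data frames with columns `loop`, `mode`,
#'   `pair_index` count columns (one row per loop/mode, counts over pairs).
#' @export
simulate.focalfit <- function(object, nsim = 1, seed = NULL, trials = NULL, ...) {
  trials <- trials %||% object$config$trials
  p <- object$probabilities
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      rows <- list()
      for (md in c("first", "last")) {
        for (lp in c("inner", "outer")) {
          sub <- p[p$mode == md & p$loop == lp, ]
          cnt <- as.numeric(stats::rmultinom(1, trials, sub$p_star))
          rows[[length(rows) + 1L]] <- data.frame(
            loop = lp, mode = md, pair_index = sub$pair_index, count = cnt)
        }
      }
      do.call(rbind, rows)
    })
  })
}

#' Plot fitted activation probabilities
#'
#' One barplot panel per loop and mode showing the fitted probabilities
#' with their empirical-likelihood bounds as whiskers; the dashed line is
#' the uniform level `1/D`.
#'
#' @param x a [focalfit()] object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.focalfit <- function(x, ...) {
  p <- x$probabilities
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (md in c("first", "last")) {
    for (lp in c("outer", "inner")) {
      sub <- p[p$mode == md & p$loop == lp, ]
      b <- graphics::barplot(sub$p_star, names.arg = sub$pair_index,
                             ylim = c(0, 1), col = "grey80",
                             xlab = "pair index", ylab = "probability",
                             main = sprintf("%s loop, %s", lp, md), ...)
      graphics::arrows(b, sub$lb, b, sub$ub, angle = 90, code = 3,
                       length = 0.04)
      graphics::abline(h = 1 / nrow(sub), lty = 2)
    }
  }
  invisible(x)
}

#' Localize the fitted sources
#'
#' Runs conduction-velocity estimation and Monte-Carlo robust least-squares
#' localization for every path of a fitted activation-order model. This is
#' the prediction step of the model: it maps the fitted wave paths to
#' spatial source-location estimates.
#'
#' @param object a [focalfit()] object.
#' @param layout catheter layout; defaults to the one stored in the fit.
#' @param mesh optional `surface_mesh` for geodesic (mesh-mode)
#'   localization; `NULL` uses planar Euclidean distances.
#' @param cv optional fixed conduction velocity (mm/ms); by default the CV
#'   law is estimated from each path via [estimate_cv()].
#' @param replicates Monte-Carlo replicates per path.
#' @param trials activations per replicate; default all matched.
#' @param rho_max maximum source-to-sensor distance, mm.
#' @param min_dt_ms tolerance for excluding near-simultaneous sensor pairs
#'   in the CV estimate, ms.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of class `focal_localization`: one
#'   [monte_carlo_localize()] result per path (`NULL` for paths without
#'   matched activations, with a warning).
#' @export
predict.focalfit <- function(object, layout = NULL, mesh = NULL, cv = NULL,
                             replicates = 100, trials = NULL, rho_max = 50,
                             min_dt_ms = 0.5, seed = NULL, ...) {
  layout <- layout %||% object$layout
  if (is.null(layout)) {
    stop("a catheter layout is required (pass 'layout' or fit with one)")
  }
  seeds <- derive_seeds(seed, nrow(object$paths))
  out <- vector("list", nrow(object$paths))
  for (r in seq_len(nrow(object$paths))) {
    matched <- object$matched[[r]]
    if (is.null(matched)) {
      warning("path ", r, " has no matched activations; skipped")
      next
    }
    geom <- tryCatch(source_geometry(layout, object$paths[r, ], mesh = mesh),
                     error = function(e) {
                       warning("path ", r, ": ", conditionMessage(e))
                       NULL
                     })
    if (is.null(geom)) next
    cv_r <- if (is.null(cv)) {
      estimate_cv(object$lat, matched, geom, min_dt_ms = min_dt_ms)
    } else {
      cv
    }
    out[[r]] <- monte_carlo_localize(object$lat, matched, geom, cv_r,
                                     replicates = replicates, trials = trials,
                                     rho_max = rho_max, seed = seeds[[r]])
  }
  class(out) <- "focal_localization"
  out
}

#' @export
print.focal_localization <- function(x, ...) {
  cat("Source localization:\n")
  for (r in seq_along(x)) {
    if (is.null(x[[r]])) {
      cat(sprintf("  path %d: not localized\n", r))
    } else {
      cat(sprintf("  path %d: ", r))
      print(x[[r]])
    }
  }
  invisible(x)
}
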