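# Shared fixtures, all generated in code.

pair_midpoints <- focalmap:::pair_midpoints

default_layout <- function() pentaray_layout()

# single triangle OFF text
single_triangle_off <- function(path) {
  writeLines(c("OFF", "3 1 0",
               "0 0 0", "1 0 0", "0 1 0",
               "3 0 1 2"), path)
  path
}

# minimal ascii PLY square (two triangles)
square_ply <- function(path) {
  writeLines(c(
    "ply", "format ascii 1.0",
    "element vertex 4",
    "property float x", "property float y", "property float z",
    "element face 2",
    "property list uchar int vertex_indices",
    "end_header",
    "0 0 0", "1 0 0", "1 1 0", "0 1 0",
    "3 0 1 2", "3 0 2 3"), path)
  path
}

# quick planar single-source scenario used by several files
planar_scenario <- function(src = c(30, 10, 0), n = 40, lat_sd = 0,
                            cv_sd = 0, cv_mean = 0.8, seed = 1) {
  lay <- pentaray_layout()
  sched <- activation_schedule(1, n, seed = seed)
  s <- focal_source(src, sched[[1]])
  lat <- simulate_lat_matrix(s, lay, cv_mean = cv_mean, cv_sd = cv_sd,
                             lat_sd = lat_sd, seed = seed + 1)
  list(layout = lay, source = s, lat = lat, cv_mean = cv_mean)
}

# independent binary-data EL oracle: equal weights within the ones-group and
# zeros-group, bound solves the two-group profile equation
el_binary_oracle <- function(n1, T, alpha) {
  q <- stats::qchisq(1 - alpha, 1)
  stat <- function(mu) {
    s <- 0
    if (n1 > 0) s <- s + n1 * log(T * mu / n1)
    if (n1 < T) s <- s + (T - n1) * log(T * (1 - mu) / (T - n1))
    -2 * s
  }
  if (n1 == 0) {
    return(c(lb = 0, ub = 1 - exp(-q / (2 * T))))
  }
  if (n1 == T) {
    return(c(lb = exp(-q / (2 * T)), ub = 1))
  }
  mu_hat <- n1 / T
  lb <- stats::uniroot(function(m) stat(m) - q, c(1e-12, mu_hat),
                       tol = 1e-13)$root
  ub <- stats::uniroot(function(m) stat(m) - q, c(mu_hat, 1 - 1e-12),
                       tol = 1e-13)$root
  c(lb = lb, ub = ub)
}

# nested brute-force grid search over the probability simplex within a box,
# refined from a coarse step down to 'final_step' resolution
mle_grid_oracle <- function(counts, lb, ub, final_step = 1e-3) {
  D <- length(counts)
  lb <- rep_len(lb, D); ub <- rep_len(ub, D)
  loglik <- function(p) {
    if (any(p < lb - 1e-12) || any(p > ub + 1e-12) || any(p < 0)) return(-Inf)
    sum(ifelse(counts > 0, counts * log(pmax(p, 1e-300)), 0))
  }
  eval_grid <- function(center, half, step) {
    axes <- lapply(seq_len(D - 1), function(j) {
      g <- seq(max(lb[j], center[j] - half), min(ub[j], center[j] + half),
               by = step)
      unique(pmin(pmax(g, lb[j]), ub[j]))
    })
    grid <- as.matrix(expand.grid(axes))
    last <- 1 - rowSums(grid)
    ok <- last >= lb[D] - 1e-12 & last <= ub[D] + 1e-12
    grid <- cbind(grid, last)[ok, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    ll <- apply(grid, 1, loglik)
    grid[which.max(ll), ]
  }
  center <- rep(1 / D, D)
  half <- 1
  for (step in c(0.05, 0.01, 0.002, final_step)) {
    best <- eval_grid(center, half, step)
    if (!is.null(best)) center <- best
    half <- step * 3
  }
  center
}
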