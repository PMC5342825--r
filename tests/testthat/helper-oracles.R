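# Independent oracles used across tests. Each is a deliberately naive
# implementation (double loops, exhaustive recursion, closed forms) kept
# separate from the package's code paths.

# pooled-window stimulus-locked mean: double loop over grid points and
# transitions, no sorting or cumulative sums
brute_force_stimlock <- function(times_s, dff, transitions, window_s,
                                 shift_s, pre_s, post_s) {
  rt <- numeric(0)
  v <- numeric(0)
  for (tt in transitions) {
    rt <- c(rt, times_s - tt)
    v <- c(v, dff)
  }
  k <- 0:floor((pre_s + post_s) / shift_s)
  grid <- -pre_s + k * shift_s
  mean_dff <- rep(NA_real_, length(grid))
  n <- integer(length(grid))
  for (i in seq_along(grid)) {
    sel <- rt >= grid[i] - window_s / 2 & rt < grid[i] + window_s / 2
    n[i] <- sum(sel)
    if (n[i] > 0) mean_dff[i] <- mean(v[sel])
  }
  keep <- n >= 1
  list(grid_s = grid[keep], mean_dff = mean_dff[keep], n_per_bin = n[keep])
}

# exhaustive maximum-cardinality matching under a distance threshold
max_matching_count <- function(a_pts, b_pts, threshold) {
  na <- nrow(a_pts)
  nb <- nrow(b_pts)
  if (na == 0 || nb == 0) return(0L)
  d <- sqrt(pmax(outer(rowSums(a_pts^2), rowSums(b_pts^2), "+") -
                   2 * a_pts %*% t(b_pts), 0))
  best <- 0L
  rec <- function(ai, used_b, count) {
    if (count + (na - ai + 1) <= best) return()
    if (ai > na) {
      best <<- max(best, count)
      return()
    }
    rec(ai + 1L, used_b, count)
    for (bi in seq_len(nb)) {
      if (!used_b[bi] && d[ai, bi] < threshold) {
        used_b[bi] <- TRUE
        rec(ai + 1L, used_b, count + 1L)
        used_b[bi] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0L)
  best
}

# two-tailed Fisher p by explicit hypergeometric enumeration over all
# tables with the observed margins (probability-mass rule; the relative
# epsilon mirrors the convention of standard implementations)
fisher_enumeration_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# one-way fixed-effects ANOVA from the textbook sums of squares
anova_closed_form <- function(groups) {
  k <- length(groups)
  n <- sum(lengths(groups))
  grand <- mean(unlist(groups))
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - grand)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) {
    sum((g - mean(g))^2)
  }, numeric(1)))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# pooled-variance two-sample t statistic and two-sided p, closed form
t_closed_form <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

# minimal noiseless trace configuration shared by several tests
noiseless_cfg <- function(seed = 3, n_cycles = 10, base_amplitude = 0.2,
                          ...) {
  sim_config(seed = seed, noise_sd = 0, param_jitter = 0, n_rois = 1,
             genotypes = "no_flp_control", compartments = "M5",
             n_cycles = n_cycles, base_amplitude = base_amplitude, ...)
}
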