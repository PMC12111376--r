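# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-formula evaluation, hand-rolled bisection,
# grid searches, per-pixel loops, sum-of-squares partitions and a numerically
# integrated studentized-range CDF.

oracle_gab <- function(m0, C, b, aw) {
  m0 * b * C * aw / ((1 - b * aw) * (1 - b * aw + C * b * aw))
}

oracle_gt <- function(Tgi, eps, W, Tgw = -135) {
  k <- 1 - W
  (k * Tgi + eps * W * Tgw) / (k + eps * W)
}

# plain bisection, derivative-free, no uniroot
oracle_bisect <- function(f, lo, hi, tol = 1e-10, itmax = 200) {
  flo <- f(lo)
  for (i in seq_len(itmax)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# coarse grid search for the GAB parameters around a known truth
oracle_grid_gab <- function(data, truth, span = 0.5, n = 15) {
  grid <- expand.grid(
    m0 = seq(truth$m0 * (1 - span), truth$m0 * (1 + span), length.out = n),
    C = seq(truth$C * (1 - span), truth$C * (1 + span), length.out = n),
    b = pmin(seq(truth$b * (1 - span), truth$b * (1 + span), length.out = n),
             0.9999)
  )
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((data$moisture_db - oracle_gab(grid$m0[i], grid$C[i], grid$b[i],
                                       data$aw))^2)
  }, numeric(1))
  list(params = grid[which.min(sse), ], sse = min(sse))
}

oracle_grid_afo <- function(t, y, truth, span = 0.5, n = 15) {
  grid <- expand.grid(
    Y0 = seq(truth$Y0 * (1 - span), truth$Y0 * (1 + span), length.out = n),
    Yinf = seq(truth$Yinf * (1 - span), truth$Yinf * (1 + span),
               length.out = n),
    k = seq(truth$k * (1 - span), truth$k * (1 + span), length.out = n)
  )
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    mu <- grid$Yinf[i] - (grid$Yinf[i] - grid$Y0[i]) * exp(-grid$k[i] * t)
    sum((y - mu)^2)
  }, numeric(1))
  list(params = grid[which.min(sse), ], sse = min(sse))
}

# one-way between-subjects ANOVA from scratch
oracle_oneway_F <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  F <- (ss_b / df1) / (ss_w / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# balanced one-way repeated-measures partition, one obs per cell
oracle_rm_F <- function(values, time, subject) {
  time <- factor(time); subject <- factor(subject)
  a <- nlevels(time); s <- nlevels(subject)
  gm <- mean(values)
  tmean <- tapply(values, time, mean)
  smean <- tapply(values, subject, mean)
  ss_time <- s * sum((tmean - gm)^2)
  ss_subj <- a * sum((smean - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  df1 <- a - 1; df2 <- (a - 1) * (s - 1)
  F <- (ss_time / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# studentized range CDF by direct double integration (k means, df error df)
oracle_srange_cdf <- function(q, k, df) {
  inner <- function(s) {
    # P(range of k std normals < q*s)
    g <- function(z) stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    k * stats::integrate(g, -Inf, Inf, rel.tol = 1e-9)$value
  }
  # s = sqrt(chi2_df / df) density
  dens <- function(s) 2 * df^(df / 2) * s^(df - 1) * exp(-df * s^2 / 2) /
    (2^(df / 2) * gamma(df / 2))
  f <- function(s) vapply(s, function(si) dens(si) * inner(si), numeric(1))
  stats::integrate(f, 0, Inf, rel.tol = 1e-7)$value
}

oracle_srange_crit <- function(k, df, alpha = 0.05) {
  oracle_bisect(function(q) oracle_srange_cdf(q, k, df) - (1 - alpha),
                0.5, 20, tol = 1e-6)
}

# per-pixel loop over an RGB array
oracle_mask_count <- function(img, rg) {
  n <- 0L
  for (i in seq_len(dim(img)[1])) for (j in seq_len(dim(img)[2])) {
    if (img[i, j, 1] >= rg$r_min && img[i, j, 1] <= rg$r_max &&
        img[i, j, 2] >= rg$g_min && img[i, j, 2] <= rg$g_max &&
        img[i, j, 3] >= rg$b_min && img[i, j, 3] <= rg$b_max) n <- n + 1L
  }
  n
}

# brute-force sliding-window equilibrium detection on a dense time grid
oracle_equilibrium <- function(t, m, rel_threshold = 1e-4, window = 8.5) {
  interp <- stats::approxfun(t, m)
  for (i in seq_along(t)) {
    t1 <- t[i] + window
    if (t1 > max(t)) return(list(reached = FALSE, t_eq = NA_real_))
    grid <- sort(unique(c(t[t >= t[i] & t <= t1], seq(t[i], t1, length.out = 400))))
    vals <- interp(grid)
    if ((max(vals) - min(vals)) / vals[1] < rel_threshold)
      return(list(reached = TRUE, t_eq = t[i]))
  }
  list(reached = FALSE, t_eq = NA_real_)
}

# random synthetic RGB image as integer array
random_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}
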