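# shared fixtures, all built in code

default_cp <- function() input_curve_fn(input_model_params())

# a dense 5-min-frame schedule covering 0-90 min, used for late-window
# recovery checks
long_schedule <- function() frame_schedule(seq(0, 85 * 60, by = 300),
                                           rep(300, 18))

# noise-free tissue TAC on a schedule for given kinetic parameters and the
# default parametric input
sim_tac <- function(kp, schedule, cp = default_cp()) {
  tmax <- max(schedule$end_s) / 60
  grid <- unique(c(seq(0, min(5, tmax), by = 0.01),
                   seq(min(5, tmax), tmax, by = 0.05), tmax))
  ct <- simulate_tissue_curve(kp, cp, grid)
  frame_average(stats::approxfun(grid, ct, rule = 2), schedule)
}

# input function sampled from a known mono-exponential plasma curve
exp_input <- function(lambda = 0.05, c0 = 1,
                      times = c(0, 4.5, 7.5, 10, 20, 30)) {
  input_function(times, c0 * exp(-lambda * times))
}

# tiny noise-free configuration for deterministic cohort checks
noise_free_config <- function() {
  cfg <- default_config()
  cfg$noise <- lapply(cfg$noise, function(x) 0)
  cfg
}

# brute-force pooled-variance two-sample t-test (independent oracle)
oracle_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), n1 + n2 - 2)
  list(t = t, p = p)
}

# exhaustive-permutation two-sided rank-sum p-value (independent oracle);
# uses the Mann-Whitney U of the first sample and the R convention
# p = min(1, 2 * smaller tail including the observed value)
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (u_obs > n1 * n2 / 2) p <- 2 * mean(u_all >= u_obs)
  else p <- 2 * mean(u_all <= u_obs)
  min(p, 1)
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
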