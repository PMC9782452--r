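# two-group statistics, age adjustment, correlation, FDR, voxel maps

test_that("group comparison matches an independent t formula oracle", {
  x <- c(12.1, 15.3, 11.8, 14.2, 13.9, 12.5)
  y <- c(16.4, 17.2, 15.8, 18.1, 16.9)
  gc <- compare_groups(c(x, y), rep(c("a", "b"), c(6, 5)), test = "t")
  or <- oracle_t(x, y)
  expect_equal(gc$statistic, or$t, tolerance = 1e-10)
  expect_equal(gc$p, or$p, tolerance = 1e-10)
  expect_equal(unname(gc$n), c(6L, 5L))
  expect_equal(unname(gc$estimate), c(mean(x), mean(y)))

  # identical groups: t = 0, p = 1
  gc0 <- compare_groups(rep(5, 8), rep(c("a", "b"), 4), test = "t")
  expect_equal(gc0$statistic, 0)
  expect_equal(gc0$p, 1)

  # missing values are excluded and the n's reflect it
  gc2 <- compare_groups(c(x, NA, y), rep(c("a", "b"), c(7, 5)))
  expect_equal(unname(gc2$n), c(6L, 5L))

  expect_error(compare_groups(x, rep("a", 6)), "two groups")
  expect_error(compare_groups(c(1, 2), c("a", "b")), "at least 2")
})

test_that("Wilcoxon p equals exhaustive permutation enumeration", {
  set.seed(31)
  for (rep_i in 1:5) {
    x <- stats::rnorm(4, 10, 2)
    y <- stats::rnorm(4, 12, 2)
    gc <- compare_groups(c(x, y), rep(c("a", "b"), each = 4),
                         test = "wilcoxon")
    expect_equal(gc$p, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("chi-squared comparison works for categorical variables", {
  vals <- rep(c("yes", "no", "yes", "yes"), c(10, 12, 3, 5))
  grp <- rep(c("a", "a", "b", "b"), c(10, 12, 3, 5))
  gc <- compare_groups(vals, grp, test = "chi2")
  want <- suppressWarnings(stats::chisq.test(table(vals, grp),
                                             correct = FALSE))
  expect_equal(gc$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(gc$p, want$p.value, tolerance = 1e-12)
})

test_that("age adjustment removes the age slope and preserves the mean", {
  set.seed(7)
  age <- stats::runif(20, 20, 35)
  val <- 50 + 1.5 * age + stats::rnorm(20, 0, 3)
  adj <- age_adjust(val, age)
  expect_equal(mean(adj), mean(val), tolerance = 1e-12)
  # idempotent: adjusted values have zero age slope
  expect_equal(age_adjust(adj, age), adj, tolerance = 1e-10)
  expect_lt(abs(stats::cov(adj, age) / stats::var(age)), 1e-10)

  # closed form: value = 2 * age collapses to the constant 2 * mean(age)
  v2 <- age_adjust(2 * age, age)
  expect_equal(v2, rep(2 * mean(age), 20), tolerance = 1e-10)

  # equal ages or zero slope leave values unchanged
  expect_equal(age_adjust(val, rep(30, 20)), val)
  flat <- rep(c(4, 6), 10)
  expect_equal(mean(age_adjust(flat, age)), 5, tolerance = 1e-12)
  expect_error(age_adjust(1:5, 1:4), "same length")
})

test_that("correlation matches the closed-form r and t-based p", {
  set.seed(12)
  x <- stats::rnorm(10)
  y <- 0.6 * x + stats::rnorm(10, 0, 0.8)
  co <- correlate(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(8 / (1 - r^2))
  expect_equal(co$r, r, tolerance = 1e-10)
  expect_equal(co$p, 2 * stats::pt(-abs(tstat), 8), tolerance = 1e-10)

  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)

  # per-group strata are reported alongside the overall row
  g <- rep(c("a", "b"), 5)
  cog <- correlate(x, y, groups = g)
  expect_equal(cog$stratum, c("overall", "a", "b"))
  expect_equal(cog$n, c(10L, 5L, 5L))
  expect_error(correlate(x, rep(1, 10)), "zero variance")
  expect_error(correlate(1:2, 2:1), "fewer than 3")
})

test_that("BH adjustment equals the step-up hand computation", {
  # p(i) * m / i then running minimum from the largest p
  got <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(got$adjusted, rep(0.04, 4))
  expect_equal(bh_fdr(0.013)$adjusted, 0.013)
  p <- c(0.5, 0.001, 0.02, 0.9, 0.04)
  expect_equal(bh_fdr(p)$adjusted, oracle_bh(p))
  # dominance: adjusted >= raw elementwise
  expect_true(all(bh_fdr(p)$adjusted >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("voxelwise comparison finds planted signal and nothing else", {
  dims <- c(8, 8, 4)
  n <- 10
  set.seed(55)
  noise_maps <- function() lapply(seq_len(n), function(i)
    array(stats::rnorm(prod(dims)), dims))
  a <- noise_maps()
  b <- noise_maps()
  # plant a 3x3x2 block with a 2-SD effect in group a
  block <- array(FALSE, dims)
  block[3:5, 4:6, 2:3] <- TRUE
  a <- lapply(a, function(m) { m[block] <- m[block] + 2; m })
  res <- voxelwise_group_map(a, b, q = 0.05)
  jac <- sum(res$mask & block) / sum(res$mask | block)
  expect_gt(jac, 0.5)
  # clusters partition the mask
  expect_equal(sum(res$cluster_sizes), sum(res$mask))
  expect_equal(max(res$cluster_labels), length(res$cluster_sizes))

  # identical noise-free groups: zero variance everywhere, empty mask
  flat <- lapply(1:3, function(i) array(1, dims))
  res0 <- voxelwise_group_map(flat, flat)
  expect_equal(sum(res0$mask), 0L)
  expect_true(all(is.na(res0$p)))

  expect_error(voxelwise_group_map(a, lapply(b, function(m) m[, , 1:2])),
               "shape")
  expect_error(voxelwise_group_map(a[1], b), "at least 2")
})

test_that("label permutation keeps the FDR mask essentially empty", {
  dims <- c(6, 6, 3)
  set.seed(77)
  maps <- lapply(1:12, function(i) array(stats::rnorm(prod(dims)), dims))
  counts <- vapply(1:40, function(i) {
    idx <- sample(12, 6)
    sum(voxelwise_group_map(maps[idx], maps[-idx])$mask)
  }, numeric(1))
  # under the null, BH controls discoveries: the mean mask size over
  # permutations stays near zero
  expect_lt(mean(counts), 1)
})

test_that("26-connectivity labeling separates diagonal-touching blocks", {
  m <- array(FALSE, c(4, 4, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE   # corner-touches the first voxel: same component
  m[4, 4, 3] <- TRUE   # isolated
  lab <- fdgclamp:::label_components(m)
  expect_equal(length(lab$sizes), 2L)
  expect_equal(sort(lab$sizes), c(1L, 2L))
  expect_equal(lab$labels[1, 1, 1], lab$labels[2, 2, 2])
})
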