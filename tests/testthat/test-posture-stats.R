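# independent oracle: exact two-sided signed-rank p-value by enumerating all
# 2^n sign assignments explicitly
enumerate_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

test_that("five positive differences give exact two-sided p = 0.0625", {
  wt <- wilcoxon_signed_rank(c(1.2, 0.7, 3.1, 2.2, 0.4))
  expect_equal(wt$method, "exact")
  expect_equal(wt$p_value, 0.0625)
  expect_equal(enumerate_p(c(1.2, 0.7, 3.1, 2.2, 0.4)), 0.0625)
})

test_that("symmetric difference pairs give p near 1", {
  wt <- wilcoxon_signed_rank(c(1.5, -1.5, 2.5, -2.5, 3.5, -3.5))
  expect_gte(wt$p_value, 0.8)
})

test_that("exact p matches full sign enumeration, with and without ties", {
  set.seed(40)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    d <- if (rep %% 3 == 0) sample(c(-3:-1, 1:3), n, replace = TRUE)  # ties
         else rnorm(n)
    d <- d[d != 0]
    if (length(d) < 2) next
    wt <- wilcoxon_signed_rank(d)
    expect_equal(wt$method, "exact")
    expect_equal(wt$p_value, enumerate_p(d), tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test on tie-free data", {
  set.seed(41)
  for (rep in 1:20) {
    d <- rnorm(sample(6:20, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("exact p is invariant to relabeling and to global sign flip", {
  set.seed(42)
  d <- rnorm(10)
  p <- wilcoxon_signed_rank(d)$p_value
  expect_equal(wilcoxon_signed_rank(sample(d))$p_value, p)
  expect_equal(wilcoxon_signed_rank(-d)$p_value, p)
})

test_that("normal approximation converges to the exact p at the crossover", {
  set.seed(43)
  diffs <- numeric(40)
  for (rep in 1:40) {
    d <- rnorm(25)
    pe <- wilcoxon_signed_rank(d, exact_limit = 25)$p_value
    pa <- wilcoxon_signed_rank(d, exact_limit = 10)$p_value
    diffs[rep] <- abs(pe - pa)
  }
  expect_lt(max(diffs), 0.01)
})

test_that("zero differences are discarded; all-zero input degenerates to p = 1", {
  wt <- wilcoxon_signed_rank(c(0, 0, 1.5, -0.5, 2.5))
  expect_equal(wt$n_eff, 3L)
  expect_warning(wt0 <- wilcoxon_signed_rank(rep(0, 5)), "degenerate")
  expect_equal(wt0$p_value, 1)
})

test_that("descriptive table reproduces closed-form statistics", {
  sn <- make_snapshots(
    rep(c("a", "b", "c"), each = 2), "standing",
    rep(c("unguided", "guided"), 3),
    rep(c("2018-01-01 10:00:00", "2018-01-02 10:00:00"), 3),
    matrix(c(10, 10, 20, 20, 30, 30), 6, 5))
  pairs <- extract_pairs(sn)
  dt <- descriptive_table(pairs)
  s1t0 <- dt[dt$sensor == 1 & dt$role == "t0", ]
  expect_equal(s1t0$mean, 20)
  expect_equal(s1t0$median, 20)
  expect_equal(s1t0$sd, 10)       # sample SD, n - 1 denominator
  expect_equal(s1t0$min, 10)
  expect_equal(s1t0$max, 30)
  expect_equal(s1t0$iqr, 10)      # type-7 quartiles of {10,20,30}
})

test_that("constant angles give zero spread", {
  sn <- make_snapshots(
    rep(c("a", "b"), each = 2), "sitting",
    rep(c("unguided", "guided"), 2),
    rep(c("2018-01-01 10:00:00", "2018-01-02 10:00:00"), 2),
    matrix(7, 4, 5))
  dt <- descriptive_table(extract_pairs(sn))
  expect_true(all(dt$sd == 0 & dt$iqr == 0 & dt$min == dt$max))
})

test_that("per-sensor tests flag planted shifts and spare null sensors", {
  set.seed(44)
  n <- 60
  t0 <- matrix(rnorm(n * 5, sd = 5), n, 5)
  t1 <- t0 + cbind(matrix(rnorm(n * 3, mean = 4), n, 3),  # shifted sensors 1-3
                   matrix(rnorm(n * 2, mean = 0), n, 2))  # null sensors 4-5
  sn <- make_snapshots(
    rep(paste0("u", 1:n), each = 2), "standing",
    rep(c("unguided", "guided"), n),
    rep(c("2018-01-01 10:00:00", "2018-01-02 10:00:00"), n),
    matrix(rbind(t0, t1)[rep(1:n, each = 2) + rep(c(0, n), n), ], 2 * n, 5))
  wx <- wilcoxon_per_sensor(extract_pairs(sn))
  expect_true(all(wx$significant[wx$sensor <= 3]))
  expect_true(all(wx$p_value[wx$sensor <= 3] < 1e-6))
  expect_equal(wx$p_display[wx$sensor == 1], "< 1e-06")
  expect_true(all(wx$p_value[wx$sensor >= 4] > 0.001))
})

test_that("type-I error at alpha 0.05 is calibrated under the null", {
  set.seed(45)
  reps <- 2000
  rejections <- 0L
  for (r in seq_len(reps)) {
    d <- rnorm(100)   # symmetric zero-median noise between t0 and t1
    if (wilcoxon_signed_rank(d)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
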