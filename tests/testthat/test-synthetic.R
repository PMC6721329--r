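test_that("null generator reproduces t0 exactly at t1", {
  cfg <- generator_config(n_users = 15, baseline_sd = rep(0, 5),
                          archetypes = list(archetype("null", rep(0, 5),
                                                      sd = 0)),
                          seed = 1)
  db <- generate_database(cfg)
  pairs <- extract_pairs(db$snapshots, quiet = TRUE)
  for (s in 1:5)
    expect_equal(pairs[[paste0("t1_angle_", s)]],
                 pairs[[paste0("t0_angle_", s)]])
})

test_that("noise-free archetype shifts baseline means to the guided profile", {
  b <- baseline_angles("standing")
  cfg <- generator_config("standing", n_users = 10,
                          baseline_mean = b$t0_mean, baseline_sd = rep(0, 5),
                          archetypes = list(archetype("shift",
                                                      b$t1_mean - b$t0_mean,
                                                      sd = 0)),
                          seed = 2)
  pairs <- extract_pairs(generate_database(cfg)$snapshots, quiet = TRUE)
  t1_means <- vapply(1:5, function(s)
    mean(pairs[[paste0("t1_angle_", s)]]), numeric(1))
  expect_equal(t1_means, c(22.5, 13.8, -0.1, -8.2, -7.6), tolerance = 1e-12)
})

test_that("generated t0 angles converge to the configured distribution", {
  cfg <- generator_config("sitting", n_users = 10000, seed = 3)
  db <- generate_database(cfg)
  t0 <- db$snapshots[db$snapshots$guidance == "unguided", ]
  b <- baseline_angles("sitting")
  for (s in 1:5) {
    a <- t0[[paste0("angle_", s)]]
    se <- b$t0_sd[s] / sqrt(length(a))
    expect_lt(abs(mean(a) - b$t0_mean[s]), 5 * se)
    expect_lt(abs(sd(a) - b$t0_sd[s]) / b$t0_sd[s], 0.05)
  }
})

test_that("generation is byte-identical under the same seed", {
  cfg <- generator_config(n_users = 30, seed = 9)
  a <- generate_database(cfg)
  b <- generate_database(cfg)
  expect_identical(a, b)
  cfg2 <- generator_config(n_users = 30, seed = 10)
  expect_false(identical(generate_database(cfg2)$snapshots$angle_1,
                         a$snapshots$angle_1))
})

test_that("generator output feeds the reader/pair-extractor unchanged", {
  cfg <- generator_config("hinging", n_users = 12, seed = 4)
  db <- generate_database(cfg)
  path <- tempfile(fileext = ".csv")
  write_posture_table(db$snapshots, path)
  pairs <- extract_pairs(read_snapshots(path), quiet = TRUE)
  expect_equal(nrow(pairs), 12L)
  expect_true(all(pairs$t1_timestamp > pairs$t0_timestamp))
  expect_setequal(pairs$pair_id, db$truth$pair_id)
})

test_that("time gaps are positive with a median near the configured value", {
  cfg <- generator_config(n_users = 4000, gap_median_days = 2, seed = 5)
  pairs <- extract_pairs(generate_database(cfg)$snapshots, quiet = TRUE)
  gap_days <- as.numeric(difftime(pairs$t1_timestamp, pairs$t0_timestamp,
                                  units = "days"))
  expect_true(all(gap_days > 0))
  expect_lt(abs(median(gap_days) - 2) / 2, 0.15)
})

test_that("contaminated mode widens the tails without moving the center much", {
  base <- generator_config(n_users = 5000, seed = 6)
  wide <- generator_config(n_users = 5000, contamination = 0.05, seed = 6)
  a0 <- generate_database(base)$snapshots$angle_1
  a1 <- generate_database(wide)$snapshots$angle_1
  expect_gt(sd(a1), sd(a0))
  expect_lt(abs(median(a1) - median(a0)), 1)
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(archetypes = list(archetype("z", rep(0, 5),
                                                            weight = 0))),
               "weights")
  expect_error(archetype("bad", 1:4), "5")
  expect_error(generator_config(n_users = 0), "n_users")
})

test_that("opposite archetypes are recovered end to end", {
  ok <- 0L
  for (s in 1:5) {
    arch <- list(archetype("fwd", c(8, 8, 8, 8, 8), sd = 1),
                 archetype("back", c(-8, -8, -8, -8, -8), sd = 1))
    cfg <- run_config(generator = generator_config(
      n_users = 80, archetypes = arch, seed = s), seed = s, k = 2,
      perplexity = 20)
    res <- run_all(cfg)
    if (adjusted_rand(res$clustering$labels, res$truth$archetype) >= 0.8)
      ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})
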