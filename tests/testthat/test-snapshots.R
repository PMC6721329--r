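test_that("read_snapshots parses valid rows, types and angle values", {
  path <- snapshot_csv(c(
    "u1,standing,unguided,2018-01-01T10:00:00,19.6,10.1,-4.1,-12.3,-12.0",
    "u1,standing,guided,2018-01-03 09:30:00,22.5,13.8,-0.1,-8.2,-7.6"))
  sn <- read_snapshots(path)
  expect_s3_class(sn, "posture_snapshots")
  expect_equal(nrow(sn), 2L)
  expect_equal(unname(unlist(sn[1, paste0("angle_", 1:5)])),
               c(19.6, 10.1, -4.1, -12.3, -12.0))
  expect_equal(levels(sn$position), c("standing", "sitting", "hinging"))
  expect_true(inherits(sn$timestamp, "POSIXct"))
  expect_equal(as.numeric(difftime(sn$timestamp[2], sn$timestamp[1],
                                   units = "secs")), 2 * 86400 - 1800)
})

test_that("read_snapshots handles empty data and remaps arbitrary headers", {
  empty <- snapshot_csv(character())
  expect_equal(nrow(read_snapshots(empty)), 0L)

  path <- tempfile(fileext = ".csv")
  writeLines(c("subj;pos;mode;when;tau1;tau2;tau3;tau4;tau5",
               "a;sitting;guided;2019-05-05T05:05:05;1;2;3;4;5"), path)
  sn <- read_snapshots(path, sep = ";", columns = c(
    user_id = "subj", position = "pos", guidance = "mode", timestamp = "when",
    angle_1 = "tau1", angle_2 = "tau2", angle_3 = "tau3", angle_4 = "tau4",
    angle_5 = "tau5"))
  expect_equal(sn$user_id, "a")
  expect_equal(sn$angle_5, 5)
})

test_that("malformed rows raise row-addressed errors", {
  expect_error(read_snapshots(snapshot_csv(
    "u1,standing,unguided,2018-01-01T10:00:00,1,2,3,4")), "missing|row")
  expect_error(read_snapshots(snapshot_csv(c(
    "u1,standing,unguided,2018-01-01T10:00:00,1,2,3,4,5",
    "u2,flying,unguided,2018-01-01T10:00:00,1,2,3,4,5"))), "row 2")
  expect_error(read_snapshots(snapshot_csv(
    "u1,standing,unguided,2018-01-01T10:00:00,1,2,3,4,bad")), "row 1")
  expect_error(read_snapshots(snapshot_csv(
    "u1,standing,unguided,not-a-time,1,2,3,4,5")), "timestamp")
  expect_error(read_snapshots(snapshot_csv(
    "u1,standing,unguided,2018-01-01T10:00:00,1,2,3,4,181")), "180")
})

test_that("extract_pairs picks earliest unguided and latest guided", {
  sn <- make_snapshots(
    rep("u", 4), "standing", c("unguided", "unguided", "guided", "guided"),
    c("2018-01-01 10:00:00", "2018-01-02 10:00:00",
      "2018-01-03 10:00:00", "2018-01-04 10:00:00"),
    matrix(seq_len(20), 4, 5))
  p <- extract_pairs(sn)
  expect_equal(nrow(p), 1L)
  expect_equal(p$t0_timestamp, sn$timestamp[1])
  expect_equal(p$t1_timestamp, sn$timestamp[4])
  # brute force: over all candidate (unguided, guided) pairs, min t0 / max t1
  un <- sn[sn$guidance == "unguided", ]; gu <- sn[sn$guidance == "guided", ]
  expect_equal(p$t0_timestamp, min(un$timestamp))
  expect_equal(p$t1_timestamp, max(gu$timestamp))
})

test_that("incomplete users yield no pair; forced choice yields that pair", {
  sn <- make_snapshots(
    c("only_guided", "only_guided", "both", "both"),
    "sitting", c("guided", "guided", "unguided", "guided"),
    c("2018-01-01 10:00:00", "2018-01-02 10:00:00",
      "2018-01-01 10:00:00", "2018-01-02 10:00:00"),
    matrix(1, 4, 5))
  expect_message(p <- extract_pairs(sn), "skipped")
  expect_equal(p$user_id, "both")
  expect_equal(unname(p$t0_angle_1), 1)
})

test_that("extract_pairs properties: idempotence and extremality", {
  set.seed(42)
  n <- 60
  sn <- make_snapshots(
    sample(paste0("u", 1:8), n, replace = TRUE),
    sample(c("standing", "sitting", "hinging"), n, replace = TRUE),
    sample(c("unguided", "guided"), n, replace = TRUE),
    as.POSIXct("2018-01-01", tz = "UTC") + sample.int(1e6, n),
    matrix(rnorm(n * 5), n, 5))
  p <- extract_pairs(sn, quiet = TRUE)
  for (i in seq_len(nrow(p))) {
    g <- sn[sn$user_id == p$user_id[i] & sn$position == p$position[i], ]
    expect_true(all(g$timestamp[g$guidance == "unguided"] >= p$t0_timestamp[i]))
    expect_true(all(g$timestamp[g$guidance == "guided"] <= p$t1_timestamp[i]))
    expect_true(p$t1_timestamp[i] >= p$t0_timestamp[i])
  }
  # idempotence: re-extracting from the paired snapshots returns the same pairs
  resn <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) make_snapshots(
    rep(p$user_id[i], 2), as.character(p$position[i]),
    c("unguided", "guided"),
    format(c(p$t0_timestamp[i], p$t1_timestamp[i]), tz = "UTC"),
    rbind(unlist(p[i, paste0("t0_angle_", 1:5)]),
          unlist(p[i, paste0("t1_angle_", 1:5)])))))
  p2 <- extract_pairs(as_snapshots(resn), quiet = TRUE)
  ord <- function(d) d[order(d$pair_id), c("pair_id", "t0_timestamp",
                                           "t1_timestamp", "t0_angle_1")]
  expect_equal(ord(p2), ord(p), ignore_attr = TRUE)
})

test_that("summarize_database computes duration statistics and counts", {
  sn <- make_snapshots(
    c("a", "a", "b", "b"), "standing",
    c("unguided", "guided", "unguided", "guided"),
    c("2018-01-01 10:00:00", "2018-01-01 11:00:00",
      "2018-01-01 10:00:00", "2018-01-01 13:00:00"),
    matrix(0, 4, 5))
  s <- summarize_database(extract_pairs(sn))
  st <- s[s$position == "standing", ]
  expect_equal(st$n_pairs, 2L)
  expect_equal(st$min_fmt, "0 01:00:00")
  expect_equal(st$mean_fmt, "0 02:00:00")
  expect_equal(st$median_fmt, "0 02:00:00")
  expect_equal(st$max_fmt, "0 03:00:00")
  full <- s[s$position == "full", ]
  expect_equal(full$n_pairs, sum(s$n_pairs[s$position != "full"]))
  # single pair: all four statistics collapse to its delta
  one <- summarize_database(extract_pairs(sn[sn$user_id == "a", ]))
  expect_equal(one$min_secs[1], one$max_secs[1])
  expect_equal(one$mean_secs[1], one$median_secs[1])
})

test_that("durations format as 'd hh:mm:ss'", {
  expect_equal(format_duration(0), "0 00:00:00")
  expect_equal(format_duration(86400 + 3661), "1 01:01:01")
  expect_equal(format_duration(443 * 86400 + 3 * 3600 + 38 * 60 + 5),
               "443 03:38:05")
})

test_that("posture tables round-trip through delimited text", {
  sn <- make_snapshots(c("a", "a"), "hinging", c("unguided", "guided"),
                       c("2018-01-01 10:00:00", "2018-01-02 10:00:00"),
                       matrix(c(75.5, 81.8), 2, 5))
  path <- tempfile(fileext = ".csv")
  write_posture_table(sn, path)
  back <- read_snapshots(path)
  expect_equal(back$timestamp, sn$timestamp)
  expect_equal(back$angle_3, sn$angle_3)
})
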