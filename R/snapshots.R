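POSITIONS <- c("standing", "sitting", "hinging")
GUIDANCE  <- c("unguided", "guided")
ANGLE_COLS <- paste0("angle_", 1:5)

#' Read a snapshot database from delimited text
#'
#' Reads a table of posture snapshots, one row per snapshot. Each snapshot is
#' a single timestamped frame of the five forward tilt angles (degrees, sensor
#' 1 lowest on the spine) together with a user id, the captured position
#' (`standing`, `sitting` or `hinging`) and whether the posture was assumed
#' with (`guided`) or without (`unguided`) a trainer's guidance.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter; comma by default.
#' @param columns Optional named character vector mapping the canonical column
#'   names (`user_id`, `position`, `guidance`, `timestamp`, `angle_1` ..
#'   `angle_5`) to the header names actually used in the file, e.g.
#'   `c(user_id = "subject", angle_1 = "tau1")`. Columns not mentioned keep
#'   their canonical name. This adapts arbitrary on-disk schemas without
#'   rewriting files.
#' @return A `data.frame` of class `posture_snapshots` with columns `user_id`
#'   (character), `position` and `guidance` (factors over their closed enums),
#'   `timestamp` (`POSIXct`, UTC) and `angle_1` .. `angle_5` (numeric
#'   degrees). Row order follows the file.
#' @details Timestamps are parsed as ISO-8601 (`YYYY-MM-DDTHH:MM:SS`, a space
#'   separator is also accepted) and treated as timezone-naive wall-clock
#'   times stored in UTC. Malformed rows (bad angle, bad timestamp, unknown
#'   position or guidance label) raise an error naming the offending data row.
#' @seealso [extract_pairs()], [summarize_database()], [generate_database()]
#' @export
read_snapshots <- function(path, sep = ",", columns = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           fill = TRUE)  # short rows surface as row errors
  canonical <- c("user_id", "position", "guidance", "timestamp", ANGLE_COLS)
  lookup <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), canonical)
    if (length(bad)) stop("unknown canonical column(s) in mapping: ",
                          paste(bad, collapse = ", "))
    lookup[names(columns)] <- columns
  }
  missing <- lookup[!lookup %in% names(raw)]
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  as_snapshots(data.frame(
    user_id   = raw[[lookup["user_id"]]],
    position  = raw[[lookup["position"]]],
    guidance  = raw[[lookup["guidance"]]],
    timestamp = raw[[lookup["timestamp"]]],
    angle_1 = raw[[lookup["angle_1"]]], angle_2 = raw[[lookup["angle_2"]]],
    angle_3 = raw[[lookup["angle_3"]]], angle_4 = raw[[lookup["angle_4"]]],
    angle_5 = raw[[lookup["angle_5"]]],
    stringsAsFactors = FALSE))
}

#' Coerce and validate a snapshot table
#'
#' Validates the closed enums, parses timestamps and angles, and enforces the
#' plausibility bound |tilt| <= 180 degrees on all five angles.
#'
#' @param df A data.frame with columns `user_id`, `position`, `guidance`,
#'   `timestamp`, `angle_1` .. `angle_5` (character or already typed).
#' @return The validated `posture_snapshots` data.frame.
#' @export
as_snapshots <- function(df) {
  need <- c("user_id", "position", "guidance", "timestamp", ANGLE_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(df)
  row_err <- function(i, what, value)
    stop(sprintf("row %d: %s (got '%s')", i, what, value), call. = FALSE)

  pos <- as.character(df$position)
  bad <- which(!pos %in% POSITIONS)
  if (length(bad)) row_err(bad[1], "unknown position", pos[bad[1]])
  gui <- as.character(df$guidance)
  bad <- which(!gui %in% GUIDANCE)
  if (length(bad)) row_err(bad[1], "unknown guidance label", gui[bad[1]])

  if (inherits(df$timestamp, "POSIXct")) {
    ts <- df$timestamp
  } else {
    ts_chr <- sub("T", " ", as.character(df$timestamp), fixed = TRUE)
    ts <- as.POSIXct(strptime(ts_chr, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                     tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      miss <- is.na(ts)
      if (!any(miss)) break
      ts[miss] <- as.POSIXct(strptime(ts_chr[miss], fmt, tz = "UTC"),
                             tz = "UTC")
    }
  }
  bad <- which(is.na(ts))
  if (length(bad)) row_err(bad[1], "unparseable timestamp",
                           as.character(df$timestamp)[bad[1]])

  ang <- matrix(NA_real_, n, 5)
  for (j in 1:5) {
    v <- df[[ANGLE_COLS[j]]]
    suppressWarnings(num <- as.numeric(as.character(v)))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad)) row_err(bad[1], paste0("unparseable or non-finite ",
                                            ANGLE_COLS[j]),
                             as.character(v)[bad[1]])
    bad <- which(abs(num) > 180)
    if (length(bad)) row_err(bad[1],
                             paste0(ANGLE_COLS[j], " outside [-180, 180]"),
                             num[bad[1]])
    ang[, j] <- num
  }

  out <- data.frame(user_id = as.character(df$user_id),
                    position = factor(pos, levels = POSITIONS),
                    guidance = factor(gui, levels = GUIDANCE),
                    timestamp = ts, stringsAsFactors = FALSE)
  out[ANGLE_COLS] <- as.data.frame(ang)
  class(out) <- c("posture_snapshots", "data.frame")
  out
}

#' Extract one before/after posture pair per user and position
#'
#' For every (user, position) that has at least one unguided and at least one
#' guided snapshot, emits exactly one pair: the earliest unguided snapshot by
#' timestamp (`t0`, the most unlearned realization of the position) and the
#' latest guided snapshot (`t1`, the user's current best guided realization).
#' Users lacking either kind for a position contribute no pair. Timestamp ties
#' are broken by input row order, so extraction is reproducible.
#'
#' @param snapshots A `posture_snapshots` data.frame (see [read_snapshots()]).
#' @param quiet Suppress the message reporting skipped incomplete groups.
#' @return A `data.frame` of class `posture_pairs`: `pair_id`, `user_id`,
#'   `position`, `t0_timestamp`, `t1_timestamp`, `t0_angle_1` .. `t0_angle_5`,
#'   `t1_angle_1` .. `t1_angle_5`. `t1_timestamp >= t0_timestamp` always holds
#'   (a guided snapshot earlier than every unguided one cannot be selected
#'   together with a later unguided one; groups where the latest guided
#'   precedes the earliest unguided are dropped as inconsistent).
#' @export
extract_pairs <- function(snapshots, quiet = FALSE) {
  snapshots <- as_snapshots(snapshots)
  key <- paste(snapshots$user_id, as.character(snapshots$position), sep = "\r")
  idx <- split(seq_len(nrow(snapshots)), key)
  rows <- lapply(idx, function(i) {
    g <- snapshots[i, , drop = FALSE]
    un <- which(g$guidance == "unguided")
    gu <- which(g$guidance == "guided")
    if (!length(un) || !length(gu)) return(NULL)
    i0 <- un[which.min(g$timestamp[un])]   # which.min keeps first on ties
    i1 <- gu[which.max(rank(g$timestamp[gu], ties.method = "last"))]
    if (g$timestamp[i1] < g$timestamp[i0]) return(NULL)
    cbind(data.frame(user_id = g$user_id[1],
                     position = as.character(g$position[1]),
                     t0_timestamp = g$timestamp[i0],
                     t1_timestamp = g$timestamp[i1],
                     stringsAsFactors = FALSE),
          stats::setNames(g[i0, ANGLE_COLS], paste0("t0_", ANGLE_COLS)),
          stats::setNames(g[i1, ANGLE_COLS], paste0("t1_", ANGLE_COLS)))
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(user_id = character(), position = character(),
                        t0_timestamp = as.POSIXct(character(), tz = "UTC"),
                        t1_timestamp = as.POSIXct(character(), tz = "UTC"))
    for (cn in c(paste0("t0_", ANGLE_COLS), paste0("t1_", ANGLE_COLS)))
      pairs[[cn]] <- numeric()
  }
  # stable order: by user then position, matching first appearance in input
  ord <- order(match(paste(pairs$user_id, pairs$position, sep = "\r"), key))
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$position <- factor(pairs$position, levels = POSITIONS)
  pairs <- cbind(pair_id = paste(pairs$user_id, pairs$position, sep = ":"),
                 pairs, stringsAsFactors = FALSE)
  if (!quiet && skipped > 0)
    message(skipped, " user/position group(s) lacked an unguided or guided ",
            "snapshot and were skipped")
  class(pairs) <- c("posture_pairs", "data.frame")
  pairs
}

#' Summarize a pair database
#'
#' Per-position and overall pair counts, user counts and statistics of the
#' time passed between the unguided (`t0`) and guided (`t1`) snapshot of each
#' pair, in the style of a study's database-description table.
#'
#' @param pairs A `posture_pairs` data.frame from [extract_pairs()].
#' @return A `data.frame` of class `pairdb_summary` with one row per position
#'   plus a final `"full"` row: `position`, `n_pairs`, `n_users`, and time
#'   differences `min`, `mean`, `median`, `max` both in seconds
#'   (`*_secs`) and formatted `"d hh:mm:ss"` (`*_fmt`).
#' @export
summarize_database <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  one <- function(p, label) {
    if (nrow(p) == 0L) {
      d <- data.frame(position = label, n_pairs = 0L, n_users = 0L)
      for (s in c("min", "mean", "median", "max")) {
        d[[paste0(s, "_secs")]] <- NA_real_
        d[[paste0(s, "_fmt")]]  <- NA_character_
      }
      return(d)
    }
    dt <- as.numeric(difftime(p$t1_timestamp, p$t0_timestamp, units = "secs"))
    vals <- c(min = min(dt), mean = mean(dt), median = stats::median(dt),
              max = max(dt))
    d <- data.frame(position = label, n_pairs = nrow(p),
                    n_users = length(unique(p$user_id)))
    for (s in names(vals)) {
      d[[paste0(s, "_secs")]] <- unname(vals[s])
      d[[paste0(s, "_fmt")]]  <- format_duration(vals[s])
    }
    d
  }
  out <- do.call(rbind, c(
    lapply(POSITIONS, function(pos)
      one(pairs[pairs$position == pos, , drop = FALSE], pos)),
    list(one(pairs, "full"))))
  rownames(out) <- NULL
  class(out) <- c("pairdb_summary", "data.frame")
  out
}

#' Format a duration in seconds as "d hh:mm:ss"
#'
#' @param secs Nonnegative duration(s) in seconds.
#' @return Character vector; days unpadded, hours/minutes/seconds zero-padded
#'   to two digits. Fractional seconds are truncated.
#' @export
format_duration <- function(secs) {
  stopifnot(all(is.na(secs) | secs >= 0))
  s <- floor(as.numeric(secs))
  d <- s %/% 86400; r <- s %% 86400
  ifelse(is.na(s), NA_character_,
         sprintf("%d %02d:%02d:%02d", d, r %/% 3600, (r %% 3600) %/% 60,
                 r %% 60))
}

#' Write snapshots or pairs back to delimited text
#'
#' @param x A `posture_snapshots` or `posture_pairs` data.frame.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_posture_table <- function(x, path, sep = ",") {
  df <- as.data.frame(x)
  for (cn in names(df))
    if (inherits(df[[cn]], "POSIXct"))
      df[[cn]] <- format(df[[cn]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
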