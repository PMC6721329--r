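# Per-pair geometric change features: for each spine-curve point except the
# pinned P1, the Euclidean length of its displacement between the unguided
# and guided curve and the unit direction of that displacement.

FEATURE_LEVELS <- c(0L, 2L, 3L, 4L, 5L)  # P1 is pinned to the origin

#' 15-dimensional change feature of one posture pair
#'
#' For the five spine-curve points `Pj`, `j` in {0, 2, 3, 4, 5} (the pinned
#' `P1` carries no information), computes the displacement length
#' `lj = ||Pj(t1) - Pj(t0)||` and the normalized displacement direction
#' `dj = (Pj(t1) - Pj(t0)) / lj`. Lengths below `tol` are treated as zero and
#' their direction set to the zero vector (the direction of a null
#' displacement is undefined).
#'
#' @param curve_t0,curve_t1 `spine_curve` objects of the unguided and guided
#'   snapshot, built with the same segment length `L`.
#' @param tol Length (model units) below which a displacement counts as zero.
#' @param pair_id Optional identifier.
#' @return Object of class `pair_feature`: list with `directions` (5 x 2
#'   matrix), `lengths` (5 numeric), `vector` (the flattened 15-vector in
#'   layout `d0x, d0y, d2x, d2y, ..., d5x, d5y, l0, l2, l3, l4, l5`) and
#'   `pair_id`.
#' @export
pair_feature <- function(curve_t0, curve_t1, tol = 1e-9,
                         pair_id = NA_character_) {
  stopifnot(inherits(curve_t0, "spine_curve"), inherits(curve_t1, "spine_curve"))
  if (!isTRUE(all.equal(curve_t0$L, curve_t1$L)))
    stop("curves built with different segment lengths L")
  rows <- paste0("P", FEATURE_LEVELS)
  diff <- curve_t1$points[rows, , drop = FALSE] -
          curve_t0$points[rows, , drop = FALSE]
  len <- sqrt(rowSums(diff^2))
  dir <- diff / ifelse(len > 0, len, 1)
  zero <- len < tol
  len[zero] <- 0
  dir[zero, ] <- 0
  v <- c(t(dir), len)
  names(v) <- c(paste0(rep(paste0("d", FEATURE_LEVELS), each = 2), c("x", "y")),
                paste0("l", FEATURE_LEVELS))
  structure(list(directions = dir, lengths = len, vector = v,
                 pair_id = pair_id),
            class = "pair_feature")
}

#' Feature matrix for a pair table
#'
#' Reconstructs both spine curves of every pair and stacks the per-pair
#' 15-dimensional change features into a matrix.
#'
#' @param pairs A `posture_pairs` data.frame.
#' @param L Segment arc length (model units) used for both curves.
#' @param tol Zero-displacement tolerance, see [pair_feature()].
#' @return Numeric matrix, one row per pair (rownames = `pair_id`), 15 named
#'   columns.
#' @export
pair_features <- function(pairs, L = 1, tol = 1e-9) {
  t0 <- as.matrix(pairs[paste0("t0_", ANGLE_COLS)])
  t1 <- as.matrix(pairs[paste0("t1_", ANGLE_COLS)])
  feats <- vapply(seq_len(nrow(pairs)), function(i) {
    pair_feature(reconstruct_curve(t0[i, ], L), reconstruct_curve(t1[i, ], L),
                 tol = tol)$vector
  }, numeric(15))
  m <- t(feats)
  rownames(m) <- pairs$pair_id
  m
}

#' Write a feature matrix as delimited text
#'
#' @param features Matrix from [pair_features()].
#' @param path Output path.
#' @param sep Delimiter.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, sep = ",") {
  df <- data.frame(pair_id = rownames(features), features, row.names = NULL,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
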