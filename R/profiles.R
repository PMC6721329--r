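# Cluster profiling: each cluster of posture pairs is summarized as a bundle
# of offset spine shapes. At every point level 0..5 the horizontal (x)
# distribution of the member shapes is condensed into percentile bands
# (1/99 outer band, 25/75 inner band, median) plus tallies of the sign
# annotations, mirroring the overlay visualization of shape ensembles.

BUNDLE_PROBS <- c(p01 = 0.01, p25 = 0.25, p50 = 0.50, p75 = 0.75, p99 = 0.99)

#' Percentile-band bundle statistics per cluster
#'
#' @param offsets List of `offset_shape` objects (see [offset_shapes()]).
#' @param clustering An `mst_clustering` whose `labels` align with `offsets`
#'   (same order and, when both carry names, the same pair ids), or a bare
#'   integer label vector.
#' @param probs Percentile ranks of the bands (default 1, 25, 50, 75, 99).
#'   Percentiles use linear interpolation between closest order statistics
#'   (`stats::quantile` type 7), so bands are bit-reproducible.
#' @return `data.frame` of class `bundle_stats`: one row per cluster x point
#'   level with columns `cluster`, `level`, `n`, `p01`, `p25`, `p50`, `p75`,
#'   `p99`, `n_plus`, `n_zero`, `n_minus`. Per-cluster geometric flags are
#'   attached as attribute `"flags"` (see [bundle_flags()]).
#' @export
bundle_stats <- function(offsets, clustering, probs = BUNDLE_PROBS) {
  labels <- if (inherits(clustering, "mst_clustering")) clustering$labels
            else clustering
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (length(offsets) != length(labels))
    stop("offsets and cluster labels have different lengths")
  ids <- vapply(offsets, function(o) o$pair_id, character(1))
  if (!is.null(names(labels)) && !anyNA(ids) &&
      !identical(unname(ids), unname(names(labels))))
    stop("offsets and cluster labels are not aligned by pair id")
  xs <- vapply(offsets, function(o) o$points[, "x"], numeric(6))   # 6 x N
  sg <- vapply(offsets, function(o) o$signs, character(6))
  rows <- lapply(sort(unique(labels)), function(cl) {
    mem <- which(labels == cl)
    do.call(rbind, lapply(1:6, function(lv) {
      x <- xs[lv, mem]
      q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
      s <- sg[lv, mem]
      data.frame(cluster = cl, level = lv - 1L, n = length(mem),
                 p01 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p99 = q[5],
                 n_plus = sum(s == "+"), n_zero = sum(s == "o"),
                 n_minus = sum(s == "-"))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flags") <- bundle_flags(out)
  class(out) <- c("bundle_stats", "data.frame")
  out
}

#' Geometric per-cluster flags from bundle statistics
#'
#' Machine-checkable versions of the qualitative geometric separations used
#' to read clusters of postural change:
#' * `base_sign_unanimous` / `base_sign`: do all members agree on the sign of
#'   the base point (level 0) offset, and which sign is it?
#' * `upper_slant_sign`: the sign of the median offset at the topmost level
#'   (level 5) -- the direction the upper part of the bundle leans.
#' * `crossing_level` / `n_crossings`: where the median offset curve changes
#'   sign between consecutive levels among levels 2..5. `crossing_level` is
#'   the level *below* the lowest sign change (NA when the median curve never
#'   changes sign there); `n_crossings` counts all sign changes, so
#'   ambiguous multi-crossing bundles are reported rather than guessed at.
#'
#' @param stats A `bundle_stats` data.frame (or compatible).
#' @return `data.frame`, one row per cluster.
#' @export
bundle_flags <- function(stats) {
  sgn <- function(x) ifelse(x > 0, 1L, ifelse(x < 0, -1L, 0L))
  do.call(rbind, lapply(split(stats, stats$cluster), function(s) {
    s <- s[order(s$level), ]
    base <- s[s$level == 0L, ]
    unanimous <- (base$n_plus == base$n) || (base$n_minus == base$n) ||
                 (base$n_zero == base$n)
    base_sign <- if (base$n_plus == base$n) "+"
                 else if (base$n_minus == base$n) "-"
                 else if (base$n_zero == base$n) "o" else "mixed"
    med <- s$p50[s$level %in% 2:5]
    ch <- which(sgn(med[-1]) != sgn(med[-length(med)]) & sgn(med[-1]) != 0)
    data.frame(cluster = s$cluster[1],
               base_sign_unanimous = unanimous, base_sign = base_sign,
               upper_slant_sign = c("-", "o", "+")[sgn(s$p50[s$level == 5L]) + 2L],
               crossing_level = if (length(ch)) 1L + ch[1] else NA_integer_,
               n_crossings = length(ch))
  }))
}

#' Write bundle statistics as delimited text
#'
#' @param stats A `bundle_stats` data.frame.
#' @param path Output path.
#' @param sep Delimiter.
#' @return `path`, invisibly.
#' @export
write_bundles <- function(stats, path, sep = ",") {
  utils::write.table(as.data.frame(stats), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
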