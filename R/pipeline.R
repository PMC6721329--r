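# End-to-end orchestration: snapshots -> pairs -> spine curves -> change
# features -> PCA -> t-SNE map -> MST clustering -> offset-shape bundles and
# angle statistics, with all intermediates and a provenance manifest written
# to an artifact directory, plus a perplexity-stability sweep.

#' Run configuration for the full pipeline
#'
#' @param input Path to a snapshot CSV (see [read_snapshots()]), or `NULL`
#'   to simulate via `generator`.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param position Optional position filter applied after pair extraction.
#' @param k Number of clusters. Default depends on position: 4 for standing
#'   and sitting, 6 for hip hinging.
#' @param L Spine-curve segment length (model units).
#' @param variance_threshold Retained-variance fraction for [pca_reduce()].
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed Integer seed driving the embedding (and simulation, unless the
#'   generator carries its own).
#' @param out_dir Artifact directory; `NULL` to skip writing files.
#' @param sep CSV delimiter for all written tables.
#' @param columns Column mapping passed to [read_snapshots()].
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL, position = NULL,
                       k = NULL, L = 1, variance_threshold = 0.95,
                       perplexity = 30, seed = 1L, out_dir = NULL,
                       sep = ",", columns = NULL) {
  if (is.null(input) && is.null(generator))
    stop("provide an input path or a generator_config")
  if (!is.null(position)) position <- match.arg(position, POSITIONS)
  if (is.null(k)) {
    pos <- if (!is.null(position)) position
           else if (!is.null(generator)) generator$position else "standing"
    k <- if (pos == "hinging") 6L else 4L
  }
  stopifnot(k >= 1, L > 0)
  structure(list(input = input, generator = generator, position = position,
                 k = as.integer(k), L = L,
                 variance_threshold = variance_threshold,
                 perplexity = perplexity, seed = as.integer(seed),
                 out_dir = out_dir, sep = sep, columns = columns),
            class = "run_config")
}

#' Run the full posture-change clustering pipeline
#'
#' Reads (or simulates) a snapshot database, extracts one before/after pair
#' per user and position, reconstructs both spine curves per pair, computes
#' the 15-dimensional change features, reduces them with PCA to the
#' retained-variance target, embeds the scores into a 2D map with t-SNE,
#' clusters the map by cutting the heaviest edges of its Euclidean minimum
#' spanning tree, and profiles each cluster as an offset-spine-shape bundle.
#' Angle-level descriptive statistics and per-sensor Wilcoxon tests are
#' computed alongside. When `config$out_dir` is set, every intermediate is
#' written as delimited text together with a JSON provenance manifest that
#' suffices to re-run the analysis bit-identically.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_result`: `pairs`, `summary`, `features`,
#'   `pca`, `map`, `clustering`, `offsets`, `bundles`, `descriptives`,
#'   `wilcoxon`, `truth` (when simulated), `manifest`.
#' @export
run_all <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  truth <- NULL
  if (!is.null(config$input)) {
    say("reading ", config$input)
    snapshots <- read_snapshots(config$input, sep = config$sep,
                                columns = config$columns)
  } else {
    say("simulating ", config$generator$n_users, " users")
    sim <- generate_database(config$generator)
    snapshots <- sim$snapshots
    truth <- sim$truth
  }
  pairs <- extract_pairs(snapshots, quiet = quiet)
  if (!is.null(config$position))
    pairs <- pairs[pairs$position == config$position, , drop = FALSE]
  if (nrow(pairs) < max(2L, config$k))
    stop("pipeline stage extract_pairs: only ", nrow(pairs),
         " pair(s) available, need at least max(2, k)")
  say(nrow(pairs), " pairs")
  summary <- summarize_database(pairs)
  features <- pair_features(pairs, L = config$L)
  pca <- pca_reduce(features, config$variance_threshold)
  say("PCA kept ", pca$n_components, " components")
  map <- tsne_embed(pca$scores, perplexity = config$perplexity,
                    seed = config$seed)
  clustering <- mst_cluster(map, config$k)
  offsets <- offset_shapes(pairs, L = config$L)
  bundles <- bundle_stats(offsets, clustering)
  descriptives <- descriptive_table(pairs)
  wilcoxon <- wilcoxon_per_sensor(pairs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("posturecluster")),
    r_version = as.character(getRversion()),
    seed = config$seed, k = config$k, L = config$L,
    perplexity = config$perplexity,
    variance_threshold = config$variance_threshold,
    position = config$position, input = config$input,
    simulated = is.null(config$input),
    generator_seed = if (!is.null(config$generator)) config$generator$seed,
    n_pairs = nrow(pairs), pca_components = pca$n_components)
  res <- structure(list(pairs = pairs, summary = summary, features = features,
                        pca = pca, map = map, clustering = clustering,
                        offsets = offsets, bundles = bundles,
                        descriptives = descriptives, wilcoxon = wilcoxon,
                        truth = truth, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_artifacts(res, config)
  res
}

write_artifacts <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_posture_table(res$pairs, p("pairs.csv"), sep = config$sep)
  write_features(res$features, p("features.csv"), sep = config$sep)
  write_map(res$map, p("map.csv"), sep = config$sep)
  utils::write.table(
    data.frame(pair_id = res$pairs$pair_id, cluster = res$clustering$labels),
    p("labels.csv"), sep = config$sep, row.names = FALSE, quote = FALSE)
  write_bundles(res$bundles, p("bundles.csv"), sep = config$sep)
  utils::write.table(attr(res$bundles, "flags"), p("bundle_flags.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  utils::write.table(res$descriptives, p("descriptives.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  utils::write.table(res$wilcoxon, p("wilcoxon.csv"), sep = config$sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(res$summary), p("summary.csv"),
                     sep = config$sep, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(config$out_dir)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 = identical partitions, ~0 = chance agreement.
#'
#' @param a,b Label vectors of equal length (any types coercible to factor).
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Perplexity-stability sweep
#'
#' Re-embeds and re-clusters the same feature set for each perplexity value
#' and measures how stable the clustering is: cluster sizes per perplexity
#' and the pairwise adjusted Rand index between all sweep labelings. Runs
#' whose ARI against the reference perplexity falls below `ari_threshold`
#' are flagged.
#'
#' @param config A [run_config()]; its `perplexity` entry is ignored in favor
#'   of `perplexities`.
#' @param perplexities Sweep values (default 25, 30, 35, 40).
#' @param reference Perplexity whose labeling anchors the stability flags
#'   (default 30; falls back to the value closest to 30 if absent).
#' @param ari_threshold Flagging threshold (default 0.9).
#' @return List of class `perplexity_sweep`: `sizes` (data.frame perplexity x
#'   cluster sizes), `ari` (symmetric matrix of pairwise ARIs), `flags`
#'   (data.frame with `perplexity`, `ari_to_reference`, `stable`), `labels`
#'   (matrix, one column per perplexity).
#' @export
perplexity_sweep <- function(config, perplexities = c(25, 30, 35, 40),
                             reference = 30, ari_threshold = 0.9) {
  stopifnot(inherits(config, "run_config"), length(perplexities) >= 2L)
  base <- config
  base$out_dir <- NULL
  # one shared front end: pairs and PCA scores do not depend on perplexity
  first <- run_all(`class<-`(utils::modifyList(
    unclass(base), list(perplexity = perplexities[1])), "run_config"))
  scores <- first$pca$scores
  k <- config$k
  labels <- matrix(NA_integer_, nrow(scores), length(perplexities),
                   dimnames = list(rownames(scores), perplexities))
  labels[, 1] <- first$clustering$labels
  for (idx in seq_along(perplexities)[-1]) {
    map <- tsne_embed(scores, perplexity = perplexities[idx],
                      seed = config$seed)
    labels[, idx] <- mst_cluster(map, k)$labels
  }
  sizes <- t(apply(labels + 1L, 2, tabulate, nbins = k))
  sizes <- data.frame(perplexity = perplexities, sizes)
  names(sizes)[-1] <- paste0("cluster_", seq_len(k) - 1L)
  m <- length(perplexities)
  ari <- matrix(1, m, m, dimnames = list(perplexities, perplexities))
  for (a in seq_len(m - 1)) for (b in (a + 1):m)
    ari[a, b] <- ari[b, a] <- adjusted_rand(labels[, a], labels[, b])
  ref_idx <- which(perplexities == reference)
  if (!length(ref_idx)) ref_idx <- which.min(abs(perplexities - reference))
  flags <- data.frame(perplexity = perplexities,
                      ari_to_reference = ari[, ref_idx[1]],
                      stable = ari[, ref_idx[1]] >= ari_threshold)
  structure(list(sizes = sizes, ari = ari, flags = flags, labels = labels,
                 reference = perplexities[ref_idx[1]], truth = first$truth),
            class = "perplexity_sweep")
}
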