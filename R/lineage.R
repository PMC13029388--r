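#' Hierarchical clustering of one stratum's samples
#'
#' Agglomerative clustering (average linkage / UPGMA by default; the
#' original analysis does not name the method) of a Bray-Curtis matrix.
#' Samples are ordered lexicographically before clustering so that
#' equal-distance merges resolve deterministically toward the
#' lexicographically smallest member.
#'
#' @param d `dist` or symmetric matrix over the stratum's samples.
#' @param method `"average"`, `"complete"` or `"ward.D2"`.
#' @return an [stats::hclust] object, or `NULL` (with a warning) when the
#'   stratum has fewer than 3 samples.
#' @export
cluster_stratum <- function(d, method = c("average", "complete", "ward.D2")) {
  method <- match.arg(method)
  m <- as.matrix(d)
  if (nrow(m) < 3) {
    vi_warn("stratum has fewer than 3 samples; no dendrogram")
    return(NULL)
  }
  ord <- order(rownames(m))
  stats::hclust(stats::as.dist(m[ord, ord]), method = method)
}

#' Export a dendrogram as Newick with heights
#'
#' @param hc an [stats::hclust] object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}

#' Classify mother-daughter pairs by the first-quartile rule
#'
#' Each mother-daughter pair is labelled *clustered* when its Bray-Curtis
#' distance falls within (<=, inclusive) the first quartile (25th
#' percentile, linear interpolation) of the overall distance distribution.
#' By default the distribution is all pairwise distances among the
#' stratum's samples (upper triangle) — clustering is per chateau x
#' compartment, and a global pool would mix compartment effects; set
#' `scope = "md"` to use only the mother-daughter distances themselves
#' (sensitivity mode).
#'
#' Under exchangeability of daughters (no inheritance) a mother-daughter
#' pair is a random draw from the pool, so the long-run clustered
#' proportion calibrates to 0.25.
#'
#' @param d `dist` or matrix over (at least) the stratum's samples.
#' @param design a [build_family_design()] result for the stratum.
#' @param scope `"stratum"` (all pairs; default) or `"md"`.
#' @return data.frame: `lineage`, `mother`, `daughter`, `distance`,
#'   `q1_threshold`, `clustered`.
#' @export
classify_pairs <- function(d, design, scope = c("stratum", "md")) {
  scope <- match.arg(scope)
  m <- as.matrix(d)
  fams <- design$families
  keep <- vapply(fams, function(f) {
    ok <- f$mother %in% rownames(m) && all(f$daughters %in% rownames(m))
    if (!ok) vi_warn("family '%s': sample(s) missing from distances; skipped",
                     f$mother)
    ok
  }, logical(1))
  fams <- fams[keep]
  if (!length(fams)) vi_stop("no family fully covered by the distance matrix")
  rows <- do.call(rbind, lapply(names(fams), function(lin) {
    f <- fams[[lin]]
    data.frame(lineage = lin, mother = f$mother, daughter = f$daughters,
               distance = m[f$mother, f$daughters],
               stringsAsFactors = FALSE)
  }))
  # "stratum": the full pairwise distribution over every sample the caller
  # put in d (subset d to the chateau x compartment stratum upstream)
  pool <- if (scope == "stratum") upper_vals(m) else rows$distance
  q1 <- as.numeric(stats::quantile(pool, 0.25, type = 7))
  rows$q1_threshold <- q1
  rows$clustered <- rows$distance <= q1
  rownames(rows) <- NULL
  rows
}

#' Per-stratum proportions of clustered mother-daughter pairs
#'
#' @param classifications one or more [classify_pairs()] results; pass a
#'   named list to get one row per stratum, or a single data.frame.
#' @param conf_level confidence level of the exact (Clopper-Pearson)
#'   binomial interval.
#' @return data.frame: `stratum`, `n_pairs`, `n_clustered`, `proportion`,
#'   `ci_lower`, `ci_upper`.
#' @export
pair_proportions <- function(classifications, conf_level = 0.95) {
  if (is.data.frame(classifications)) {
    classifications <- list(all = classifications)
  }
  out <- lapply(names(classifications), function(st) {
    cl <- classifications[[st]]
    n <- nrow(cl)
    k <- sum(cl$clustered)
    bt <- stats::binom.test(k, n, conf.level = conf_level)
    data.frame(stratum = st, n_pairs = n, n_clustered = k,
               proportion = k / n,
               ci_lower = bt$conf.int[1L], ci_upper = bt$conf.int[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
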