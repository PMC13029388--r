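#' Abundance-weighted beta mean nearest taxon distance
#'
#' For a pair of communities j, k:
#' `bMNTD = 1/2 [ sum_i f_ij min_{i' in k} d(i, i') +
#'                sum_i f_ik min_{i' in j} d(i, i') ]`
#' where `f` are within-sample relative abundances, `d` the patristic
#' distance, and the minimum runs over taxa present in the other sample
#' (a shared taxon may match itself at distance 0). Identical communities
#' therefore give 0.
#'
#' @param table a [community_table] (or counts matrix).
#' @param tree an [ape::phylo] tree covering every taxon that is non-zero
#'   in the pair.
#' @param pair character vector of two sample ids.
#' @return non-negative scalar.
#' @export
beta_mntd <- function(table, tree, pair) {
  counts <- if (inherits(table, "community_table")) table$counts else table
  stopifnot(length(pair) == 2L, all(pair %in% colnames(counts)))
  f <- relative_abundance(counts[, pair, drop = FALSE])
  present <- rownames(f)[rowSums(f) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    vi_stop("taxon '%s' is abundant in the pair but missing from the tree",
            missing[1L])
  }
  dmat <- patristic_distances(tree)[present, present, drop = FALSE]
  bmntd_pair(f[present, 1L], f[present, 2L], dmat)
}

# core kernel: fj, fk relative abundances over the same taxa as dmat rows
bmntd_pair <- function(fj, fk, dmat) {
  j <- which(fj > 0)
  k <- which(fk > 0)
  if (!length(j) || !length(k)) vi_stop("empty sample in pair")
  sub <- dmat[j, k, drop = FALSE]
  min_jk <- apply(sub, 1L, min)  # nearest taxon in k, for each taxon of j
  min_kj <- apply(sub, 2L, min)
  0.5 * (sum(fj[j] * min_jk) + sum(fk[k] * min_kj))
}

#' Beta nearest taxon index against a taxa-shuffle null
#'
#' Standardizes observed bMNTD against a null distribution obtained by
#' shuffling taxon labels across all tips of the tree (abundances fixed):
#' `bNTI = (obs - mean_null) / sd_null`. |bNTI| > 2 is conventionally read
#' as deterministic assembly (reported, never enforced). The null stream is
#' seeded, so a fixed seed reproduces values exactly.
#'
#' @param table a [community_table].
#' @param tree tree covering all taxa of `table` that are non-zero in any
#'   involved sample.
#' @param pairs two-column matrix or data.frame of sample ids.
#' @param n_null number of tip shuffles (>= 99).
#' @param seed integer seed.
#' @return data.frame: `sample_1`, `sample_2`, `beta_mntd`, `null_mean`,
#'   `null_sd`, `beta_nti` (`NA` + `degenerate = TRUE` when the null sd is
#'   0), `n_null`, `seed`.
#' @export
beta_nti <- function(table, tree, pairs, n_null = 999L, seed = 1L) {
  if (n_null < 99) vi_stop("n_null must be >= 99")
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  counts <- table$counts
  used <- unique(as.vector(pairs))
  f <- relative_abundance(counts[, used, drop = FALSE])
  present <- rownames(f)[rowSums(f) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    vi_stop("taxon '%s' is abundant in a pair but missing from the tree",
            missing[1L])
  }
  dmat <- patristic_distances(tree)
  dmat <- dmat[present, present, drop = FALSE]
  f <- f[present, , drop = FALSE]
  n_tax <- length(present)

  obs <- vapply(seq_len(nrow(pairs)), function(r) {
    bmntd_pair(f[, pairs[r, 1L]], f[, pairs[r, 2L]], dmat)
  }, numeric(1))

  nulls <- with_seed(derive_seed(seed, "bnti-null"), {
    vapply(seq_len(n_null), function(b) {
      perm <- sample.int(n_tax)
      dp <- dmat[perm, perm]
      vapply(seq_len(nrow(pairs)), function(r) {
        bmntd_pair(f[, pairs[r, 1L]], f[, pairs[r, 2L]], dp)
      }, numeric(1))
    }, numeric(nrow(pairs)))
  })
  nulls <- matrix(nulls, nrow = nrow(pairs))  # pairs x n_null
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1L, stats::sd)
  # degenerate null: when the null distribution is a point mass at the
  # observed value (e.g. identical presence sets, where every shuffle
  # leaves each taxon nearest itself), the deviation is exactly 0; a point
  # mass elsewhere leaves bNTI undefined and is flagged
  at_obs <- abs(obs - mu) < 1e-12
  bnti <- ifelse(sdv > 0, (obs - mu) / sdv, ifelse(at_obs, 0, NA_real_))
  degen <- sdv == 0 & !at_obs
  if (any(degen)) vi_warn("%d pair(s) with null sd 0: bNTI undefined",
                          sum(degen))
  data.frame(sample_1 = pairs[, 1L], sample_2 = pairs[, 2L],
             beta_mntd = obs, null_mean = mu, null_sd = sdv,
             beta_nti = bnti,
             degenerate = degen, n_null = n_null, seed = seed,
             stringsAsFactors = FALSE)
}

#' Per-pair stochasticity from observed and expected similarity
#'
#' Given observed similarity `G = 1 - D` and its null expectation `E`:
#' when `G >= E`, selection excess `SS = (G - E) / (1 - E)`; otherwise
#' `SS = (E - G) / E`. The stochasticity ratio of the pair is `ST = 1 - SS`:
#' 1 when observation matches the null exactly, 0 when communities are as
#' far from the null as the similarity scale allows (in either direction).
#'
#' @param g_obs,e_null numeric vectors in `[0, 1]`.
#' @return data.frame with `ss` and `st`.
#' @export
stochasticity_ratio <- function(g_obs, e_null) {
  eps <- 1e-12
  ss <- ifelse(g_obs >= e_null,
               (g_obs - e_null) / pmax(1 - e_null, eps),
               (e_null - g_obs) / pmax(e_null, eps))
  ss <- pmin(pmax(ss, 0), 1)
  data.frame(ss = ss, st = 1 - ss)
}

# n_null null draws of each sample's community under the PF null model:
# richness fixed per sample, taxon occurrence probability proportional to
# occupancy frequency in the pool, abundance of selected taxa proportional
# to their pool-wide relative abundance.
pf_null_profiles <- function(rel, occ, pool_ab) {
  nt <- nrow(rel)
  out <- matrix(0, nrow = nt, ncol = ncol(rel), dimnames = dimnames(rel))
  eligible <- which(occ > 0)
  for (s in seq_len(ncol(rel))) {
    richness <- sum(rel[, s] > 0)
    k <- min(richness, length(eligible))
    sel <- if (k == length(eligible)) {
      eligible
    } else {
      sample(eligible, k, prob = occ[eligible])
    }
    ab <- pool_ab[sel]
    if (sum(ab) == 0) ab <- rep(1, length(sel))
    out[sel, s] <- ab / sum(ab)
  }
  out
}

#' Pairwise stochasticity-ratio matrix under the PF null
#'
#' Computes, for every pair among `sample_ids`, the observed similarity
#' (1 - Ruzicka or Bray-Curtis on relative abundances), the null expected
#' similarity under the PF null model (see [stochasticity_ratio()] for the
#' normalization), and the per-pair stochasticity `ST`. Occupancy
#' frequencies and pool abundances are taken from `pool` — by default the
#' whole table, since a pool restricted to one family would reproduce any
#' family-wide filtering inside the null and mask determinism.
#'
#' @param table a [community_table].
#' @param sample_ids samples to cover (default: all).
#' @param pool [community_table] or counts matrix supplying the regional
#'   species pool.
#' @param metric `"ruzicka"` (abundance-weighted Jaccard; default, the NST
#'   convention) or `"bray"`.
#' @param n_null number of null draws.
#' @param seed integer seed.
#' @return list with symmetric matrices `st`, `g_obs`, `e_null` and the
#'   settings (`metric`, `null_model`, `n_null`, `seed`).
#' @export
nst_pair_matrix <- function(table, sample_ids = NULL, pool = NULL,
                            metric = c("ruzicka", "bray"),
                            n_null = 1000L, seed = 1L) {
  metric <- match.arg(metric)
  vmethod <- if (metric == "ruzicka") "jaccard" else "bray"
  counts <- table$counts
  sample_ids <- sample_ids %||% colnames(counts)
  rel <- relative_abundance(counts[, sample_ids, drop = FALSE])
  pool_counts <- if (is.null(pool)) {
    counts
  } else if (inherits(pool, "community_table")) {
    pool$counts
  } else {
    pool
  }
  pool_counts <- pool_counts[rownames(rel), , drop = FALSE]
  occ <- rowMeans(pool_counts > 0)
  pool_ab <- rowSums(pool_counts)
  pool_ab <- pool_ab / sum(pool_ab)

  g_obs <- 1 - as.matrix(vegan::vegdist(t(rel), method = vmethod))
  e_sum <- matrix(0, nrow = ncol(rel), ncol = ncol(rel))
  with_seed(derive_seed(seed, "nst-null"), {
    for (b in seq_len(n_null)) {
      nullp <- pf_null_profiles(rel, occ, pool_ab)
      e_sum <- e_sum + (1 - as.matrix(vegan::vegdist(t(nullp),
                                                     method = vmethod)))
    }
  })
  e_null <- e_sum / n_null
  dimnames(e_null) <- dimnames(g_obs)
  st <- matrix(stochasticity_ratio(as.vector(g_obs),
                                   as.vector(e_null))$st,
               nrow = nrow(g_obs), dimnames = dimnames(g_obs))
  diag(st) <- NA_real_
  list(st = st, g_obs = g_obs, e_null = e_null, metric = metric,
       null_model = "PF", n_null = n_null, seed = seed)
}

#' Normalized stochasticity ratio of one mother-daughter family
#'
#' `NST = mean` over the family's sample pairs of the per-pair
#' stochasticity `ST` (see [stochasticity_ratio()]), clamped to `[0, 1]`
#' and conventionally read on the percent scale: above 50% stochastic
#' assembly dominates, below 50% deterministic filtering.
#'
#' @param table a [community_table].
#' @param family a `list(mother =, daughters =)` element of a
#'   [build_family_design()] result, or a character vector of >= 2 sample
#'   ids.
#' @param pool,metric,n_null,seed passed to [nst_pair_matrix()]; `pairs`
#'   may also be a precomputed [nst_pair_matrix()] result to reuse across
#'   families.
#' @param pairs optional precomputed [nst_pair_matrix()] result.
#' @return one-row data.frame: `family`, `n_samples`, `mean_dissimilarity`,
#'   `null_expectation` (both on the similarity scale's complement), `nst`
#'   in `[0, 1]`, `clamped` flag, `metric`, `null_model`, `n_null`; or
#'   `NULL` with a warning for a family of fewer than 2 samples.
#' @export
nst <- function(table, family, pool = NULL,
                metric = c("ruzicka", "bray"), n_null = 1000L, seed = 1L,
                pairs = NULL) {
  metric <- match.arg(metric)
  ids <- if (is.list(family)) c(family$mother, family$daughters) else family
  fam_id <- if (is.list(family)) family$mother else ids[1L]
  if (length(ids) < 2L) {
    vi_warn("family '%s' has fewer than 2 samples; skipped", fam_id)
    return(NULL)
  }
  pm <- pairs %||% nst_pair_matrix(table, sample_ids = ids, pool = pool,
                                   metric = metric, n_null = n_null,
                                   seed = seed)
  st <- pm$st[ids, ids, drop = FALSE]
  g <- pm$g_obs[ids, ids, drop = FALSE]
  e <- pm$e_null[ids, ids, drop = FALSE]
  vals <- upper_vals(st)
  raw <- mean(vals)
  data.frame(family = fam_id, n_samples = length(ids),
             mean_dissimilarity = mean(1 - upper_vals(g)),
             null_expectation = mean(1 - upper_vals(e)),
             nst = min(max(raw, 0), 1), clamped = raw < 0 || raw > 1,
             metric = pm$metric, null_model = pm$null_model,
             n_null = pm$n_null, stringsAsFactors = FALSE)
}

#' Mother-daughter assignment permutation test
#'
#' The exchangeability null of the whole framework: within one stratum, the
#' observed per-mother statistic (mean of `statistic_fn` over her true
#' daughters) is compared against a null distribution obtained by
#' repeatedly reassigning the stratum's daughters to mothers uniformly at
#' random, preserving family sizes. Reassignment never crosses strata —
#' mixing chateaux would conflate the site effect with this null.
#' `Z = (obs - null_mean) / null_sd`; two-sided
#' `p = (1 + #{|null - null_mean| >= |obs - null_mean|}) / (1 + n_perm)`.
#'
#' With few families the test has a documented resolution floor: e.g. two
#' families of one daughter admit only 2 assignments, so p >= 1/2.
#'
#' @param statistic_fn `function(mother_id, daughter_ids)` returning a
#'   scalar (see [md_stat_from_matrix()] for the common pairwise case).
#' @param design a [build_family_design()] result (>= 2 families).
#' @param n_perm number of random reassignments.
#' @param seed integer seed.
#' @return data.frame, one row per mother: `lineage`, `mother`,
#'   `n_daughters`, `observed`, `null_mean`, `null_sd`, `z_score`,
#'   `p_value`, `stars` (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001),
#'   `n_perm`, `seed`.
#' @export
md_permutation_test <- function(statistic_fn, design, n_perm = 999L,
                                seed = 1L) {
  fams <- design$families
  if (length(fams) < 2L) {
    vi_stop("need >= 2 families in the stratum (reassignment is vacuous)")
  }
  mothers <- vapply(fams, `[[`, character(1), "mother")
  sizes <- vapply(fams, function(f) length(f$daughters), integer(1))
  daughters <- unlist(lapply(fams, `[[`, "daughters"), use.names = FALSE)
  obs <- vapply(seq_along(fams), function(i) {
    statistic_fn(mothers[i], fams[[i]]$daughters)
  }, numeric(1))

  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  nulls <- with_seed(derive_seed(seed, "md-perm"), {
    vapply(seq_len(n_perm), function(b) {
      shuffled <- sample(daughters)
      vapply(seq_along(fams), function(i) {
        statistic_fn(mothers[i], shuffled[starts[i]:ends[i]])
      }, numeric(1))
    }, numeric(length(fams)))
  })
  nulls <- matrix(nulls, nrow = length(fams))  # families x n_perm
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1L, stats::sd)
  # same point-mass convention as beta_nti: a null concentrated at the
  # observed value is zero deviation, not undefined
  at_obs <- abs(obs - mu) < 1e-12
  degen <- sdv == 0 & !at_obs
  if (any(degen)) vi_warn("%d mother(s) with null sd 0: Z undefined",
                          sum(degen))
  p <- vapply(seq_along(fams), function(i) {
    (1 + sum(abs(nulls[i, ] - mu[i]) >= abs(obs[i] - mu[i]))) / (1 + n_perm)
  }, numeric(1))
  stars <- ifelse(p < 0.001, "***",
                  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  data.frame(lineage = names(fams), mother = mothers, n_daughters = sizes,
             observed = obs, null_mean = mu, null_sd = sdv,
             z_score = ifelse(sdv > 0, (obs - mu) / sdv,
                              ifelse(at_obs, 0, NA_real_)),
             p_value = p, stars = stars, n_perm = n_perm, seed = seed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Family statistic from a precomputed pairwise matrix
#'
#' Builds the `statistic_fn` used by [md_permutation_test()] from a named
#' pairwise matrix (e.g. Bray-Curtis distances, per-pair bNTI, or the `st`
#' matrix of [nst_pair_matrix()]): the family statistic is the mean of the
#' mother-daughter entries (`include_daughter_pairs = TRUE` also averages
#' the daughter-daughter entries, the within-family NST convention).
#'
#' @param m symmetric matrix with sample ids as dimnames.
#' @param include_daughter_pairs also average daughter-daughter entries.
#' @return `function(mother_id, daughter_ids)`.
#' @export
md_stat_from_matrix <- function(m, include_daughter_pairs = FALSE) {
  m <- as.matrix(m)
  force(include_daughter_pairs)
  function(mother_id, daughter_ids) {
    vals <- m[mother_id, daughter_ids]
    if (include_daughter_pairs && length(daughter_ids) > 1L) {
      dd <- m[daughter_ids, daughter_ids, drop = FALSE]
      vals <- c(vals, upper_vals(dd))
    }
    mean(vals, na.rm = TRUE)
  }
}
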