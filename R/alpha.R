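#' Alpha-diversity panel
#'
#' Per-sample richness and diversity indices: observed richness,
#' bias-corrected Chao1 (`S_obs + F1 (F1 - 1) / (2 (F2 + 1))`), ACE (rare
#' threshold 10), Shannon (nats), Gini-Simpson (`1 - sum p^2`), inverse
#' Simpson, Fisher's alpha (root of `S = a log(1 + N / a)`), and Pielou
#' evenness (`H / log S_obs`). Chao1, ACE and Fisher's alpha are estimated
#' from singleton/doubleton structure and therefore require raw integer
#' counts; relative data are rejected. No rarefaction is applied; the
#' library size is recorded as a covariate instead.
#'
#' Empty samples cannot occur inside a valid [community_table]; a sample
#' with a single taxon gets Pielou `NA` (evenness undefined at `S = 1`).
#'
#' @param table a [community_table] with integer counts.
#' @return data.frame, one row per sample: `sample_id`, `library_size`,
#'   `observed_richness`, `chao1`, `ace`, `shannon`, `simpson`,
#'   `inv_simpson`, `fisher_alpha`, `pielou`.
#' @export
alpha_panel <- function(table) {
  counts <- if (inherits(table, "community_table")) table$counts else table
  if (any(abs(counts - round(counts)) > 1e-8)) {
    vi_stop("alpha_panel needs raw integer counts (Chao1/ACE/Fisher are undefined on relative data)")
  }
  x <- t(counts)  # vegan wants samples in rows
  est <- vegan::estimateR(x)  # S.obs, S.chao1, S.ACE
  sh <- vegan::diversity(x, index = "shannon")
  si <- vegan::diversity(x, index = "simpson")
  inv <- vegan::diversity(x, index = "invsimpson")
  sobs <- est["S.obs", ]
  fa <- mapply(fisher_alpha_solve, rowSums(x), sobs)
  # with no rare taxa (all abundances > 10) the ACE correction vanishes
  # and the estimator is S_obs itself; vegan leaves it NaN there
  ace <- ifelse(is.nan(est["S.ACE", ]), sobs, est["S.ACE", ])
  data.frame(sample_id = rownames(x),
             library_size = rowSums(x),
             observed_richness = as.numeric(sobs),
             chao1 = as.numeric(est["S.chao1", ]),
             ace = as.numeric(ace),
             shannon = as.numeric(sh),
             simpson = as.numeric(si),
             inv_simpson = as.numeric(inv),
             fisher_alpha = as.numeric(fa),
             pielou = ifelse(sobs > 1, as.numeric(sh) / log(as.numeric(sobs)),
                             NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Fisher's log-series alpha: the root of S = a log(1 + N / a), found by
# bracketed root-finding. As a -> Inf the left side tends to N, so S = N
# (all singletons) has no finite root and returns NA.
fisher_alpha_solve <- function(n_total, s_obs, tol = 1e-10) {
  if (s_obs >= n_total) return(NA_real_)
  f <- function(a) a * log(1 + n_total / a) - s_obs
  lo <- 1e-8
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Wilcoxon rank-sum contrasts of alpha diversity between generations
#'
#' For each index, tests PM vs PF with a two-sided Wilcoxon rank-sum test
#' (exact p when both groups have <= 20 samples and no ties, normal
#' approximation with tie correction otherwise) within one chateau x
#' compartment stratum, or across all samples in `records` when no stratum
#' is given.
#'
#' @param records output of [alpha_panel()].
#' @param metadata per-sample metadata (data.frame with `sample_id`,
#'   `generation`, `chateau`, `compartment`).
#' @param chateau,compartment optional stratum selectors.
#' @param indices which index columns to test.
#' @return data.frame with one row per index: `index`, `n_pm`, `n_pf`,
#'   `statistic` (rank-sum W), `p_value`, `direction` (`"PM"` or `"PF"`,
#'   the generation with the higher median; `"tie"` if equal).
#' @export
compare_generations <- function(records, metadata, chateau = NULL,
                                compartment = NULL,
                                indices = c("observed_richness", "chao1",
                                            "ace", "shannon", "simpson",
                                            "inv_simpson", "fisher_alpha",
                                            "pielou")) {
  md <- metadata
  if (!is.null(chateau)) md <- md[md$chateau == chateau, , drop = FALSE]
  if (!is.null(compartment)) {
    md <- md[md$compartment == compartment, , drop = FALSE]
  }
  rec <- merge(records, md[, c("sample_id", "generation")], by = "sample_id")
  out <- lapply(indices, function(ix) {
    pm <- rec[[ix]][rec$generation == "PM"]
    pf <- rec[[ix]][rec$generation == "PF"]
    pm <- pm[!is.na(pm)]; pf <- pf[!is.na(pf)]
    if (length(pm) < 2 || length(pf) < 2) {
      vi_warn("index '%s': fewer than 2 samples in a generation; NA row", ix)
      return(data.frame(index = ix, n_pm = length(pm), n_pf = length(pf),
                        statistic = NA_real_, p_value = NA_real_,
                        direction = NA_character_,
                        stringsAsFactors = FALSE))
    }
    exact <- length(pm) <= 20 && length(pf) <= 20 &&
      !anyDuplicated(c(pm, pf))
    wt <- suppressWarnings(
      stats::wilcox.test(pm, pf, exact = exact, correct = !exact))
    dir <- if (stats::median(pm) > stats::median(pf)) "PM"
      else if (stats::median(pm) < stats::median(pf)) "PF" else "tie"
    data.frame(index = ix, n_pm = length(pm), n_pf = length(pf),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               direction = dir, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
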