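#' Configuration for the lineage-structured community simulator
#'
#' The generator emulates a multi-estate mass-selection trial: each site
#' ("chateau") holds mother vines (generation PM), each mother has a fixed
#' number of clonal daughters (PF), and every vine is sampled in each
#' compartment. Taxa carry phylogenetically correlated environmental optima
#' (Brownian motion on a Yule tree) and samples assemble by Gaussian
#' environmental filtering around a one-dimensional environment axis; a
#' daughter's expected composition mixes her mother's *realized* community
#' (fraction `v`, vertical transmission) with her own environmental pool
#' (fraction `1 - v`).
#'
#' Environment of a sample = `compartment_effect * code(compartment)` +
#' `site_effect * code(site)` + `generation_effect * code(generation)`,
#' with compartment codes -1/0/1 (leaf/root/soil), site codes evenly spaced
#' on \[-1, 1\], and generation codes +1/2 (PM), -1/2 (PF). The defaults put
#' compartment >> site >> generation, the effect hierarchy of a multi-site
#' field trial of this kind.
#'
#' @param n_taxa number of taxa (tree tips).
#' @param n_sites number of chateaux (ignored when `site_families` given).
#' @param compartments subset of `c("leaf", "root", "soil")`.
#' @param families_per_site,daughters_per_mother family structure applied
#'   to every site, unless `site_families` is supplied.
#' @param site_families optional list, one element per site, each
#'   `c(n_families, n_daughters)`; `preset = "four-estates"` installs the
#'   four-estate structure 15x5, 10x3, 12x3, 10x1 (47 mothers and 151
#'   daughters per compartment).
#' @param depth expected library size; realized sizes are Poisson(`depth`)
#'   per sample to mimic uneven sequencing effort.
#' @param v vertical-transmission fraction in `[0, 1]`.
#' @param sigma_sel environmental-filtering width (> 0; larger = weaker
#'   selection; `1e9` is effectively neutral).
#' @param site_effect,compartment_effect,generation_effect environment
#'   shifts (same units as the trait axis).
#' @param bm_rate Brownian-motion variance accumulated root-to-tip (the
#'   tree has depth 1), i.e. tip optima have sd `sqrt(bm_rate)`.
#' @param kingdom marker label stored in the metadata ("bacteria" or
#'   "fungi"); tables for different kingdoms are generated by separate
#'   calls and never mixed.
#' @param seed master seed; every sample draws from its own substream so
#'   adding samples never perturbs existing ones.
#' @param preset `"four-estates"` to install the four-estate family structure.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 120L, n_sites = 4L,
                       compartments = c("leaf", "root", "soil"),
                       families_per_site = 10L, daughters_per_mother = 3L,
                       site_families = NULL,
                       depth = 10000L, v = 0.3, sigma_sel = 1,
                       site_effect = 1, compartment_effect = 6,
                       generation_effect = 0.2,
                       bm_rate = 25, kingdom = "bacteria",
                       seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    if (preset != "four-estates") vi_stop("unknown preset '%s'", preset)
    site_families <- list(c(15L, 5L), c(10L, 3L), c(12L, 3L), c(10L, 1L))
  }
  if (is.null(site_families)) {
    site_families <- rep(list(c(families_per_site, daughters_per_mother)),
                         n_sites)
  }
  n_sites <- length(site_families)
  stopifnot(n_taxa >= 2, n_sites >= 1, depth >= 1,
            v >= 0, v <= 1, sigma_sel > 0,
            all(vapply(site_families, function(s) all(s >= 1), logical(1))))
  compartments <- match.arg(compartments, c("leaf", "root", "soil"),
                            several.ok = TRUE)
  structure(list(n_taxa = as.integer(n_taxa), n_sites = n_sites,
                 compartments = compartments,
                 site_families = site_families,
                 depth = depth, v = v, sigma_sel = sigma_sel,
                 site_effect = site_effect,
                 compartment_effect = compartment_effect,
                 generation_effect = generation_effect,
                 bm_rate = bm_rate, kingdom = kingdom,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve taxon environmental optima by Brownian motion
#'
#' Optima start at 0 at the root and accumulate Gaussian increments with
#' variance `bm_rate` per unit branch length, so closely related taxa have
#' correlated optima — the phylogenetic signal that the beta-NTI framework
#' assumes.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param bm_rate variance per unit branch length (0 gives all-zero optima).
#' @param seed integer seed.
#' @return named numeric vector of per-tip optima.
#' @export
evolve_optima <- function(tree, bm_rate, seed = 1L) {
  if (bm_rate == 0) {
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  }
  with_seed(derive_seed(seed, "optima"),
            ape::rTraitCont(tree, model = "BM", sigma = sqrt(bm_rate),
                            root.value = 0))
}

# Expected relative abundances under Gaussian environmental filtering,
# computed in log space so extreme selection never underflows to all-zero.
filter_probs <- function(optima, env, sigma_sel, base_abundance) {
  logw <- log(base_abundance) - (optima - env)^2 / (2 * sigma_sel^2)
  if (all(!is.finite(logw))) vi_stop("all-zero filtering weights")
  w <- exp(logw - max(logw[is.finite(logw)]))
  w / sum(w)
}

#' Assemble one sample by environmental filtering
#'
#' Expected relative abundance of taxon i is proportional to
#' `base_i * exp(-(optimum_i - env)^2 / (2 * sigma_sel^2))`; counts are a
#' single multinomial draw of size `depth`.
#'
#' @param optima per-taxon environmental optima.
#' @param env realized environment of the sample (scalar).
#' @param sigma_sel filtering width (> 0).
#' @param base_abundance per-taxon base (neutral) abundances, > 0.
#' @param depth library size (>= 1).
#' @param seed integer seed.
#' @return list with `counts` (integer vector) and `p` (expected relative
#'   abundances, summing to 1).
#' @export
assemble_sample <- function(optima, env, sigma_sel, base_abundance, depth,
                            seed = 1L) {
  if (depth < 1) vi_stop("depth must be >= 1")
  p <- filter_probs(optima, env, sigma_sel, base_abundance)
  counts <- with_seed(seed, stats::rmultinom(1L, size = depth, prob = p))[, 1L]
  list(counts = stats::setNames(counts, names(optima)), p = p)
}

# compartment codes on the environment axis
comp_code <- c(leaf = -1, root = 0, soil = 1)

#' Simulate a full mother-daughter study
#'
#' Generates the phylogeny, taxon optima, base abundances, one PM sample
#' per family per compartment and `n_daughters` PF samples, together with
#' complete metadata, a synthetic taxonomy (nested clade cuts of the tree),
#' the per-stratum family designs and a truth object for parameter-recovery
#' tests. Daughter expected composition is
#' `v * f_mother_realized + (1 - v) * p_env(daughter)`: inheritance acts on
#' what the mother actually hosts, not on her expectation.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_study` with elements `table`
#'   ([community_table]), `tree`, `optima`, `base_abundance`, `designs`
#'   (list of [build_family_design()] results, one per chateau x
#'   compartment), and `truth` (list: `env` named vector, `expected_p`
#'   taxa x samples matrix).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  tree <- simulate_tree(config$n_taxa, seed)
  taxa <- tree$tip.label
  optima <- evolve_optima(tree, config$bm_rate, seed)[taxa]
  base <- with_seed(derive_seed(seed, "base-abundance"),
                    stats::setNames(stats::rlnorm(config$n_taxa, 0, 1), taxa))

  sites <- sprintf("CH%d", seq_len(config$n_sites))
  site_code <- if (config$n_sites == 1) {
    stats::setNames(0, sites)
  } else {
    stats::setNames(seq(-1, 1, length.out = config$n_sites), sites)
  }
  gen_code <- c(PM = 0.5, PF = -0.5)

  # enumerate vines, then one sample per vine per compartment
  vines <- do.call(rbind, lapply(seq_along(sites), function(s) {
    nf <- config$site_families[[s]][1L]
    nd <- config$site_families[[s]][2L]
    do.call(rbind, lapply(seq_len(nf), function(f) {
      lin <- sprintf("L%02d", f)
      rbind(
        data.frame(chateau = sites[s], lineage = lin, generation = "PM",
                   vine = sprintf("%s.%s.M", sites[s], lin),
                   stringsAsFactors = FALSE),
        data.frame(chateau = sites[s], lineage = lin, generation = "PF",
                   vine = sprintf("%s.%s.D%d", sites[s], lin, seq_len(nd)),
                   stringsAsFactors = FALSE))
    }))
  }))

  meta <- do.call(rbind, lapply(config$compartments, function(cp) {
    data.frame(sample_id = paste(vines$vine, cp, sep = "."),
               chateau = vines$chateau, compartment = cp,
               generation = vines$generation, lineage = vines$lineage,
               vine_id = vines$vine, kingdom = config$kingdom,
               stringsAsFactors = FALSE)
  }))

  env <- config$compartment_effect * comp_code[meta$compartment] +
    config$site_effect * site_code[meta$chateau] +
    config$generation_effect * gen_code[meta$generation]
  env <- stats::setNames(as.numeric(env), meta$sample_id)

  counts <- matrix(0L, nrow = config$n_taxa, ncol = nrow(meta),
                   dimnames = list(taxa, meta$sample_id))
  expected_p <- matrix(NA_real_, nrow = config$n_taxa, ncol = nrow(meta),
                       dimnames = list(taxa, meta$sample_id))

  draw <- function(sample_id, p) {
    s <- derive_seed(seed, paste0("counts:", sample_id))
    with_seed(s, {
      n <- max(1L, stats::rpois(1L, config$depth))
      stats::rmultinom(1L, size = n, prob = p)[, 1L]
    })
  }

  is_pm <- meta$generation == "PM"
  for (j in which(is_pm)) {
    sid <- meta$sample_id[j]
    p <- filter_probs(optima, env[sid], config$sigma_sel, base)
    expected_p[, j] <- p
    counts[, j] <- draw(sid, p)
  }
  mother_of <- function(j) {
    meta$sample_id[is_pm & meta$chateau == meta$chateau[j] &
                     meta$compartment == meta$compartment[j] &
                     meta$lineage == meta$lineage[j]]
  }
  for (j in which(!is_pm)) {
    sid <- meta$sample_id[j]
    p_env <- filter_probs(optima, env[sid], config$sigma_sel, base)
    mom <- mother_of(j)
    f_mom <- counts[, mom] / sum(counts[, mom])
    p <- config$v * f_mom + (1 - config$v) * p_env
    expected_p[, j] <- p
    counts[, j] <- draw(sid, p)
  }

  table <- community_table(counts, meta, synthetic_taxonomy(tree, config))
  designs <- list()
  for (ch in sites) {
    for (cp in config$compartments) {
      key <- paste(ch, cp, sep = ".")
      designs[[key]] <- build_family_design(table, chateau = ch,
                                            compartment = cp)
    }
  }
  structure(list(table = table, tree = tree, optima = optima,
                 base_abundance = base, designs = designs,
                 truth = list(env = env, expected_p = expected_p),
                 config = config),
            class = "sim_study")
}

# Synthetic ranked taxonomy from nested clade cuts of the tree: coarse cuts
# give phyla, finer cuts classes/orders/families, genus is per-taxon.
synthetic_taxonomy <- function(tree, config) {
  n <- length(tree$tip.label)
  h <- stats::hclust(stats::as.dist(patristic_distances(tree)),
                     method = "average")
  cut_k <- function(k, tag) {
    k <- max(1L, min(n, k))
    sprintf("%s%02d", tag, stats::cutree(h, k = k)[tree$tip.label])
  }
  data.frame(taxon_id = tree$tip.label,
             kingdom = config$kingdom,
             phylum = cut_k(ceiling(n / 40), "Phy"),
             class = cut_k(ceiling(n / 20), "Cls"),
             order = cut_k(ceiling(n / 12), "Ord"),
             family = cut_k(ceiling(n / 6), "Fam"),
             genus = cut_k(ceiling(n / 2), "Gen"),
             stringsAsFactors = FALSE)
}

#' Write a simulated study to disk
#'
#' Writes `counts.tsv`, `metadata.tsv`, `taxonomy.tsv`, `tree.nwk` and
#' `truth.json` (environment and simulation parameters) into `dir`.
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_community(sim$table, dir)
  tp <- file.path(dir, "tree.nwk")
  ape::write.tree(sim$tree, tp)
  jp <- file.path(dir, "truth.json")
  cfg <- unclass(sim$config)
  cfg$compartments <- as.list(cfg$compartments)
  jsonlite::write_json(list(config = cfg,
                            env = as.list(sim$truth$env)),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tree = tp, truth = jp))
}
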