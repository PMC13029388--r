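#' Assemble a run configuration
#'
#' A run takes either file inputs (`counts`, `metadata`, optional
#' `taxonomy`, `tree`) or a simulator specification, and executes the
#' enabled stages with per-stage seeds derived deterministically from the
#' global seed, so a rerun of the same configuration is byte-identical.
#'
#' @param input named list of paths (`counts`, `metadata`, `taxonomy`,
#'   `tree`), or `NULL` to simulate.
#' @param simulate arguments for [sim_config()] (list), or a ready
#'   `sim_config`; ignored when `input` is given.
#' @param out_dir output directory.
#' @param stages stages to run, subset of `c("alpha", "ordination",
#'   "permanova", "lefse", "lineage", "assembly")`.
#' @param factors PERMANOVA factors, tested marginally and sequentially.
#' @param n_perm permutations for PERMANOVA and the mother-daughter test.
#' @param n_null null draws for bNTI tip shuffles and NST.
#' @param lefse_rank taxonomic rank for biomarker discovery.
#' @param linkage,quartile_scope lineage-stage settings
#'   (see [cluster_stratum()], [classify_pairs()]).
#' @param nst_metric `"ruzicka"` or `"bray"`.
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = list(), out_dir = "vinherit_run",
                       stages = c("alpha", "ordination", "permanova",
                                  "lefse", "lineage", "assembly"),
                       factors = c("compartment", "chateau", "generation"),
                       n_perm = 999L, n_null = 199L,
                       lefse_rank = "family",
                       linkage = "average", quartile_scope = "stratum",
                       nst_metric = "ruzicka", seed = 1L) {
  stages <- match.arg(stages, c("alpha", "ordination", "permanova",
                                "lefse", "lineage", "assembly"),
                      several.ok = TRUE)
  structure(list(input = input, simulate = simulate, out_dir = out_dir,
                 stages = stages, factors = factors,
                 n_perm = as.integer(n_perm), n_null = as.integer(n_null),
                 lefse_rank = lefse_rank, linkage = linkage,
                 quartile_scope = quartile_scope, nst_metric = nst_metric,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages on the configured input (or simulation) and
#' writes figure-ready TSV tables plus a JSON manifest recording every
#' stage seed and parameter. Stage outputs are pure functions of the input
#' and the stage seed: rerunning the same configuration reproduces every
#' file byte-identically.
#'
#' Files written (per enabled stage): `alpha.tsv` + `alpha_tests.tsv`,
#' `ordination.tsv`, `permanova.tsv`, `lefse.tsv`, `pairs.tsv` +
#' `proportions.tsv` + `dendrograms.nwk`, `bnti_pairs.tsv` +
#' `nst_families.tsv` + `zscores.tsv`, and `manifest.json`.
#'
#' @param config a [run_config()], a list of its arguments, or a YAML path.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- list()
  written <- character()

  # --- input -------------------------------------------------------------
  if (!is.null(config$input)) {
    table <- read_community(config$input$counts, config$input$metadata,
                            config$input$taxonomy %||% NULL)
    tree <- if (!is.null(config$input$tree)) {
      read_tree(config$input$tree, table)
    } else {
      NULL
    }
  } else {
    simargs <- config$simulate
    if (!inherits(simargs, "sim_config")) {
      simargs$seed <- simargs$seed %||% derive_seed(seed, "simulate")
      simargs <- do.call(sim_config, simargs)
    }
    sim <- simulate_study(simargs)
    table <- sim$table
    tree <- sim$tree
    out$sim <- sim
  }
  if ("assembly" %in% config$stages && is.null(tree)) {
    vi_stop("assembly stage enabled but no tree available")
  }
  md <- table$metadata
  strata <- unique(md[md$generation %in% c("PM", "PF"),
                      c("chateau", "compartment")])
  strata <- strata[order(strata$chateau, strata$compartment), , drop = FALSE]

  # --- H1: structure and composition ------------------------------------
  if ("alpha" %in% config$stages) {
    out$alpha <- alpha_panel(table)
    written <- c(written, write_tsv(out$alpha,
                                    file.path(config$out_dir, "alpha.tsv")))
    tests <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      tt <- suppressWarnings(
        compare_generations(out$alpha, md, chateau = strata$chateau[i],
                            compartment = strata$compartment[i]))
      cbind(chateau = strata$chateau[i],
            compartment = strata$compartment[i], tt)
    }))
    out$alpha_tests <- tests
    written <- c(written,
                 write_tsv(tests, file.path(config$out_dir,
                                            "alpha_tests.tsv")))
  }

  d_all <- NULL
  if (any(c("ordination", "permanova") %in% config$stages)) {
    d_all <- bray_curtis(table)
  }
  if ("ordination" %in% config$stages) {
    ord <- pcoa(d_all)
    k <- min(4L, ncol(ord$coordinates))
    df <- data.frame(sample_id = rownames(ord$coordinates),
                     ord$coordinates[, seq_len(k), drop = FALSE],
                     stringsAsFactors = FALSE)
    df <- merge(df, md, by = "sample_id", sort = TRUE)
    attr(ord, "prop_variance_written") <- ord$prop_variance[seq_len(k)]
    out$ordination <- ord
    written <- c(written,
                 write_tsv(df, file.path(config$out_dir, "ordination.tsv")))
  }
  if ("permanova" %in% config$stages) {
    pr_m <- permanova(d_all, md, config$factors, n_perm = config$n_perm,
                      seed = derive_seed(seed, "permanova"),
                      mode = "marginal")
    pr_s <- permanova(d_all, md, config$factors, n_perm = config$n_perm,
                      seed = derive_seed(seed, "permanova"),
                      mode = "sequential")
    out$permanova <- rbind(pr_m, pr_s)
    written <- c(written,
                 write_tsv(out$permanova,
                           file.path(config$out_dir, "permanova.tsv")))
  }
  if ("lefse" %in% config$stages) {
    agg <- aggregate_rank(table, config$lefse_rank)
    cls <- paste(agg$metadata$generation, agg$metadata$compartment,
                 sep = "-")
    out$lefse <- lefse(agg, cls, seed = derive_seed(seed, "lefse"))
    written <- c(written,
                 write_tsv(out$lefse, file.path(config$out_dir,
                                                "lefse.tsv")))
  }

  # --- H2: lineage resemblance ------------------------------------------
  if ("lineage" %in% config$stages) {
    pairs_list <- list()
    dendro_path <- file.path(config$out_dir, "dendrograms.nwk")
    if (file.exists(dendro_path)) file.remove(dendro_path)
    nwk <- character()
    for (i in seq_len(nrow(strata))) {
      ch <- strata$chateau[i]; cp <- strata$compartment[i]
      key <- paste(ch, cp, sep = ".")
      sub <- subset_samples(table, chateau == ch, compartment == cp)
      if (ncol(sub$counts) < 3) next
      d <- bray_curtis(sub)
      hc <- cluster_stratum(d, method = config$linkage)
      if (!is.null(hc)) {
        nwk <- c(nwk, paste0("[", key, "] ",
                             ape::write.tree(ape::as.phylo(hc))))
      }
      design <- tryCatch(build_family_design(sub), error = function(e) NULL)
      if (is.null(design)) next
      pairs_list[[key]] <- classify_pairs(d, design,
                                          scope = config$quartile_scope)
    }
    writeLines(nwk, dendro_path)
    written <- c(written, dendro_path)
    pairs_df <- do.call(rbind, lapply(names(pairs_list), function(k) {
      cbind(stratum = k, pairs_list[[k]])
    }))
    out$pairs <- pairs_df
    out$proportions <- pair_proportions(pairs_list)
    written <- c(written,
                 write_tsv(pairs_df, file.path(config$out_dir, "pairs.tsv")),
                 write_tsv(out$proportions,
                           file.path(config$out_dir, "proportions.tsv")))
  }

  # --- H3: assembly processes -------------------------------------------
  if ("assembly" %in% config$stages) {
    bnti_rows <- list(); nst_rows <- list(); z_rows <- list()
    for (i in seq_len(nrow(strata))) {
      ch <- strata$chateau[i]; cp <- strata$compartment[i]
      key <- paste(ch, cp, sep = ".")
      sub <- subset_samples(table, chateau == ch, compartment == cp)
      design <- tryCatch(build_family_design(sub), error = function(e) NULL)
      if (is.null(design) || length(design$families) < 2) next
      mothers <- vapply(design$families, `[[`, character(1), "mother")
      daughters <- unlist(lapply(design$families, `[[`, "daughters"),
                          use.names = FALSE)
      cross <- expand.grid(mothers, daughters, stringsAsFactors = FALSE)
      tr <- beta_nti(sub, tree, cross, n_null = config$n_null,
                     seed = derive_seed(seed, paste0("bnti:", key)))
      bmat <- matrix(NA_real_, length(mothers), length(daughters),
                     dimnames = list(mothers, daughters))
      bmat[cbind(tr$sample_1, tr$sample_2)] <- tr$beta_nti
      is_md <- mapply(function(m, d) {
        any(vapply(design$families, function(f) {
          f$mother == m && d %in% f$daughters
        }, logical(1)))
      }, tr$sample_1, tr$sample_2)
      bnti_rows[[key]] <- cbind(stratum = key, tr[is_md, , drop = FALSE])

      pm <- nst_pair_matrix(sub, pool = table, metric = config$nst_metric,
                            n_null = config$n_null,
                            seed = derive_seed(seed, paste0("nst:", key)))
      fam_nst <- do.call(rbind, lapply(names(design$families), function(l) {
        r <- nst(sub, design$families[[l]], pairs = pm)
        if (!is.null(r)) cbind(stratum = key, lineage = l, r)
      }))
      nst_rows[[key]] <- fam_nst

      z_b <- md_permutation_test(md_stat_from_matrix(bmat), design,
                                 n_perm = config$n_perm,
                                 seed = derive_seed(seed,
                                                    paste0("zb:", key)))
      z_n <- md_permutation_test(
        md_stat_from_matrix(pm$st, include_daughter_pairs = TRUE), design,
        n_perm = config$n_perm,
        seed = derive_seed(seed, paste0("zn:", key)))
      z_rows[[key]] <- rbind(cbind(stratum = key, statistic = "mean_bnti",
                                   z_b),
                             cbind(stratum = key, statistic = "nst", z_n))
    }
    out$bnti_pairs <- do.call(rbind, bnti_rows)
    out$nst_families <- do.call(rbind, nst_rows)
    out$zscores <- do.call(rbind, z_rows)
    written <- c(written,
                 write_tsv(out$bnti_pairs,
                           file.path(config$out_dir, "bnti_pairs.tsv")),
                 write_tsv(out$nst_families,
                           file.path(config$out_dir, "nst_families.tsv")),
                 write_tsv(out$zscores,
                           file.path(config$out_dir, "zscores.tsv")))
  }

  manifest <- list(
    package = "vinherit",
    version = as.character(utils::packageVersion("vinherit")),
    seed = seed,
    stage_seeds = list(
      simulate = derive_seed(seed, "simulate"),
      permanova = derive_seed(seed, "permanova"),
      lefse = derive_seed(seed, "lefse")),
    stages = config$stages,
    parameters = list(factors = config$factors, n_perm = config$n_perm,
                      n_null = config$n_null,
                      lefse_rank = config$lefse_rank,
                      linkage = config$linkage,
                      quartile_scope = config$quartile_scope,
                      nst_metric = config$nst_metric),
    assumptions = list(
      bnti_null = "taxa shuffle across all tree tips, scoped per stratum",
      md_permutation_scope = "within chateau x compartment stratum",
      nst_null_model = "PF, occupancy pool = full table"),
    outputs = basename(written))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
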