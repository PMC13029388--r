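# Small programmatic fixtures shared across test files.

# minimal valid metadata for a set of sample ids
toy_metadata <- function(sample_ids, generation = "PM",
                         chateau = "CH1", compartment = "root",
                         lineage = "L01") {
  n <- length(sample_ids)
  data.frame(sample_id = sample_ids,
             chateau = rep_len(chateau, n),
             compartment = rep_len(compartment, n),
             generation = rep_len(generation, n),
             lineage = rep_len(lineage, n),
             vine_id = paste0("V", seq_len(n)),
             stringsAsFactors = FALSE)
}

# taxa x samples toy table with arbitrary counts
toy_table <- function(counts, ...) {
  community_table(counts, toy_metadata(colnames(counts), ...))
}

# random community table: n_taxa x n_samples, lognormal-multinomial
random_table <- function(n_taxa, n_samples, depth = 1000, seed = 1, ...) {
  set.seed(seed)
  base <- rlnorm(n_taxa)
  counts <- sapply(seq_len(n_samples), function(j) {
    rmultinom(1, depth, base * rlnorm(n_taxa, 0, 0.3))[, 1]
  })
  dimnames(counts) <- list(sprintf("T%04d", seq_len(n_taxa)),
                           sprintf("S%02d", seq_len(n_samples)))
  toy_table(counts, ...)
}

# brute-force patristic distance: sum of branch lengths on the unique
# tip-to-tip path, found by walking each tip to the root and summing the
# edges outside the shared prefix (independent of stats::cophenetic)
brute_patristic <- function(tree, tip_a, tip_b) {
  path_to_root <- function(tip) {
    node <- match(tip, tree$tip.label)
    edges <- integer()
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  ea <- path_to_root(tip_a)
  eb <- path_to_root(tip_b)
  shared <- intersect(ea, eb)
  sum(tree$edge.length[setdiff(c(ea, eb), shared)])
}

# brute-force abundance-weighted beta-MNTD: explicit double loop over all
# cross-taxon minima (independent of the package kernel)
brute_bmntd <- function(xj, xk, dmat) {
  fj <- xj / sum(xj)
  fk <- xk / sum(xk)
  pj <- which(fj > 0)
  pk <- which(fk > 0)
  term_j <- 0
  for (i in pj) {
    term_j <- term_j + fj[i] * min(sapply(pk, function(ip) dmat[i, ip]))
  }
  term_k <- 0
  for (i in pk) {
    term_k <- term_k + fk[i] * min(sapply(pj, function(ip) dmat[i, ip]))
  }
  0.5 * (term_j + term_k)
}

# exact two-sided rank-sum p by full enumeration of group assignments
enumerate_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- combn(length(pooled), m)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# simulator scenario used by the exchangeability / calibration tests:
# one stratum, no generation shift, selection off unless given
exch_config <- function(seed, v = 0, sigma_sel = 1e9, n_fam = 10L,
                        n_daughters = 3L, n_taxa = 80L, depth = 5000L, ...) {
  sim_config(n_taxa = n_taxa,
             site_families = list(c(n_fam, n_daughters)),
             compartments = "root", depth = depth, v = v,
             sigma_sel = sigma_sel, generation_effect = 0, seed = seed, ...)
}

# all permutations of 1:n (n small), as a list of integer vectors
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}
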