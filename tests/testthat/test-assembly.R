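test_that("beta-MNTD matches hand cases", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  counts <- cbind(j = c(A = 5, B = 0, C = 0), k = c(A = 0, B = 3, C = 0),
                  same = c(A = 5, B = 0, C = 0))
  tab <- toy_table(counts)
  # singleton communities A vs B: d(A,B) = 2 both ways -> 2
  expect_equal(beta_mntd(tab, tree, c("j", "k")), 2, tolerance = 1e-12)
  # identical communities: every nearest-taxon distance is 0
  expect_equal(beta_mntd(tab, tree, c("j", "same")), 0)
  # taxon missing from tree is a hard error
  counts2 <- rbind(counts, D = c(1, 1, 1))
  tree_noD <- tree
  expect_error(beta_mntd(toy_table(counts2), tree_noD, c("j", "k")),
               "missing from the tree")
})

test_that("beta-MNTD equals the brute-force oracle on random instances", {
  worst <- 0
  for (i in 1:100) {
    set.seed(i)
    n <- sample(3:8, 1)
    tree <- simulate_tree(n, seed = i)
    counts <- cbind(j = rpois(n, 3), k = rpois(n, 3))
    rownames(counts) <- tree$tip.label
    if (sum(counts[, 1]) == 0) counts[1, 1] <- 1
    if (sum(counts[, 2]) == 0) counts[2, 2] <- 1
    dmat <- patristic_distances(tree)[rownames(counts), rownames(counts)]
    got <- beta_mntd(toy_table(counts), tree, c("j", "k"))
    want <- brute_bmntd(counts[, 1], counts[, 2], dmat)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
})

test_that("beta-MNTD agrees with picante's nearest-taxon turnover", {
  tree <- simulate_tree(12, seed = 5)
  set.seed(5)
  counts <- cbind(j = rpois(12, 4), k = rpois(12, 4))
  rownames(counts) <- tree$tip.label
  got <- beta_mntd(toy_table(counts), tree, c("j", "k"))
  comm <- t(counts) / colSums(counts)
  ref <- as.numeric(picante::comdistnt(comm, patristic_distances(tree),
                                       abundance.weighted = TRUE))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("beta-NTI is deterministic, scale-free and bounded for identical pairs", {
  tree <- simulate_tree(15, seed = 2)
  set.seed(2)
  counts <- cbind(a = rpois(15, 5) + 1, b = rpois(15, 5) + 1,
                  c = rpois(15, 2))
  rownames(counts) <- tree$tip.label
  tab <- toy_table(counts)
  pairs <- rbind(c("a", "b"), c("a", "c"))
  r1 <- beta_nti(tab, tree, pairs, n_null = 99, seed = 9)
  r2 <- beta_nti(tab, tree, pairs, n_null = 99, seed = 9)
  expect_identical(r1, r2)

  # rescaling branch lengths rescales bMNTD but leaves the z-score alone
  tree10 <- tree
  tree10$edge.length <- tree10$edge.length * 10
  r10 <- beta_nti(tab, tree10, pairs, n_null = 99, seed = 9)
  expect_equal(r10$beta_mntd, r1$beta_mntd * 10, tolerance = 1e-9)
  expect_equal(r10$beta_nti, r1$beta_nti, tolerance = 1e-9)

  # identical communities: point-mass null at 0 -> bNTI = 0 (never > 0)
  same <- cbind(x = counts[, "a"], y = counts[, "a"])
  rs <- beta_nti(toy_table(same), tree, rbind(c("x", "y")), n_null = 99,
                 seed = 1)
  expect_equal(rs$beta_nti, 0)
  expect_false(rs$degenerate)
})

test_that("stochasticity ratio has its definitional fixed points", {
  # observation equal to the null expectation: pure stochasticity
  expect_equal(stochasticity_ratio(0.4, 0.4)$st, 1)
  # identical communities against a null expecting less similarity:
  # maximal selection signal
  expect_equal(stochasticity_ratio(1, 0.6)$ss, 1)
  expect_equal(stochasticity_ratio(1, 0.6)$st, 0)
  # symmetric treatment of divergence below the null
  expect_equal(stochasticity_ratio(0, 0.5)$ss, 1)
  expect_true(all(stochasticity_ratio(runif(50), runif(50))$ss >= 0))
})

test_that("NST is 0 for identical families and near 1 when nulls match", {
  # sparse table: per-sample richness well below the pool's taxon count,
  # otherwise the occurrence null is degenerate (every draw = full pool)
  pool <- random_table(80, 12, depth = 150, seed = 6)
  counts <- pool$counts
  counts[, 2] <- counts[, 1]  # family of two identical samples
  tab <- toy_table(counts)
  r <- nst(tab, c("S01", "S02"), pool = pool, n_null = 60, seed = 3)
  expect_equal(r$nst, 0, tolerance = 1e-12)

  fam <- list(mother = "S01", daughters = c("S03", "S04"))
  r2 <- nst(pool, fam, pool = pool, n_null = 60, seed = 3)
  expect_true(r2$nst >= 0 && r2$nst <= 1)
  expect_warning(nst(pool, "S01"), "fewer than 2")
})

test_that("the assignment permutation test is exact on degenerate designs", {
  # constant statistic: null is a point mass at the observation
  ids <- c("m1", "m2", "d1", "d2")
  md <- toy_metadata(ids, generation = c("PM", "PM", "PF", "PF"),
                     lineage = c("L1", "L2", "L1", "L2"))
  counts <- matrix(1:8, 2, 4, dimnames = list(c("A", "B"), ids))
  des <- build_family_design(community_table(counts, md))
  zc <- md_permutation_test(function(m, d) 1, des, n_perm = 50, seed = 1)
  expect_equal(zc$z_score, c(0, 0))
  expect_equal(zc$p_value, c(1, 1))

  # two families of one daughter: only 2 assignments exist, so p >= 1/2
  m <- matrix(c(0, 1, 2, 3, 1, 0, 4, 5, 2, 4, 0, 6, 3, 5, 6, 0), 4, 4,
              dimnames = list(ids, ids))
  zd <- md_permutation_test(md_stat_from_matrix(m), des, n_perm = 199,
                            seed = 2)
  expect_true(all(zd$p_value >= 0.5))
})

test_that("permutation p-values are near-uniform for exchangeable daughters", {
  pvals <- unlist(lapply(1:6, function(s) {
    sim <- simulate_study(exch_config(seed = s, n_fam = 8, n_daughters = 3,
                                      n_taxa = 60, depth = 3000))
    des <- sim$designs[["CH1.root"]]
    dm <- as.matrix(bray_curtis(sim$table))
    md_permutation_test(md_stat_from_matrix(dm), des, n_perm = 199,
                        seed = s)$p_value
  }))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("filtering versus neutral regimes separate in mean |bNTI|", {
  mean_abs <- function(sigma, seed) {
    sim <- simulate_study(exch_config(seed = seed, sigma_sel = sigma,
                                      n_fam = 8, n_daughters = 3,
                                      n_taxa = 60, depth = 3000,
                                      bm_rate = 25))
    des <- sim$designs[["CH1.root"]]
    prs <- do.call(rbind, lapply(des$families,
                                 function(f) cbind(f$mother, f$daughters)))
    tr <- beta_nti(sim$table, sim$tree, prs, n_null = 99, seed = seed)
    mean(abs(tr$beta_nti), na.rm = TRUE)
  }
  wins <- sapply(1:5, function(s) mean_abs(0.5, s) > mean_abs(1e9, s))
  expect_gte(sum(wins), 4)
})
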