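test_that("tree simulation is deterministic, seed-sensitive and ultrametric", {
  t1 <- simulate_tree(50, seed = 1)
  t2 <- simulate_tree(50, seed = 1)
  t3 <- simulate_tree(50, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1), ape::write.tree(t3)))
  depths <- ape::node.depth.edgelength(t1)[seq_len(50)]
  expect_true(all(abs(depths - 1) < 1e-9))

  cherry <- simulate_tree(2, seed = 3)
  d2 <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(d2[1], d2[2])
})

test_that("Brownian optima have the BM covariance structure", {
  expect_equal(unname(evolve_optima(simulate_tree(10, 1), 0, seed = 5)),
               rep(0, 10))
  # fixed 3-tip tree: cherry (A,B) shares a path of length 0.5 from the
  # root, so cov(A, B) = 0.5 * rate and var(A) = 1 * rate
  tree <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  rate <- 2
  draws <- t(sapply(1:600, function(s) evolve_optima(tree, rate, seed = s)))
  expect_equal(unname(cov(draws[, "A"], draws[, "B"])), 0.5 * rate,
               tolerance = 0.2)
  expect_equal(unname(var(draws[, "A"])), rate, tolerance = 0.2)
  expect_identical(evolve_optima(tree, rate, seed = 9),
                   evolve_optima(tree, rate, seed = 9))
})

test_that("environmental filtering shapes assembly probabilities", {
  optima <- c(a = 0, b = 10)
  base <- c(a = 1, b = 1)
  # selection off: p proportional to base abundances
  res <- assemble_sample(optima, env = 0, sigma_sel = 1e9,
                         base_abundance = c(a = 3, b = 1), depth = 100)
  expect_equal(unname(res$p), c(0.75, 0.25), tolerance = 1e-12)
  # strong selection: taxon at distance 10 with sigma 1 is suppressed by
  # a factor exp(-50): effectively absent
  res2 <- assemble_sample(optima, env = 0, sigma_sel = 1,
                          base_abundance = base, depth = 1000, seed = 1)
  expect_equal(res2$p[["b"]] / res2$p[["a"]], exp(-50), tolerance = 1e-8)
  expect_equal(res2$counts[["b"]], 0)
  expect_error(assemble_sample(optima, 0, 1, base, depth = 0), "depth")
})

test_that("simulated study has coherent metadata, truth and library sizes", {
  cfg <- sim_config(n_taxa = 40, site_families = list(c(3, 2), c(2, 2)),
                    compartments = c("leaf", "root"), depth = 800, seed = 11)
  sim <- simulate_study(cfg)
  tab <- sim$table
  # one PM + n daughters per family per compartment
  expect_equal(ncol(tab$counts), (3 * 3 + 2 * 3) * 2)
  expect_true(all(colSums(abs(sim$truth$expected_p)) - 1 < 1e-12))
  # Poisson(depth) library sizes: all within 5 sd of depth
  libs <- colSums(tab$counts)
  expect_true(all(abs(libs - 800) < 5 * sqrt(800)))
  # every PF lineage has its PM in the same chateau
  md <- tab$metadata
  for (i in which(md$generation == "PF")) {
    expect_true(any(md$generation == "PM" & md$chateau == md$chateau[i] &
                      md$compartment == md$compartment[i] &
                      md$lineage == md$lineage[i]))
  }
})

test_that("same seed reproduces the study; extra daughters leave existing samples untouched", {
  cfg <- sim_config(n_taxa = 30, site_families = list(c(2, 2)),
                    compartments = "root", depth = 500, seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$table$counts, s2$table$counts)

  cfg3 <- sim_config(n_taxa = 30, site_families = list(c(2, 3)),
                     compartments = "root", depth = 500, seed = 21)
  s3 <- simulate_study(cfg3)
  shared <- intersect(colnames(s1$table$counts), colnames(s3$table$counts))
  expect_gt(length(shared), 0)
  expect_identical(s1$table$counts[, shared], s3$table$counts[, shared])
})

test_that("full vertical transmission copies the mother's realized community", {
  cfg <- sim_config(n_taxa = 60, site_families = list(c(2, 1)),
                    compartments = "root", depth = 1e6, v = 1,
                    sigma_sel = 1e9, generation_effect = 0, seed = 31)
  sim <- simulate_study(cfg)
  for (fam in sim$designs[["CH1.root"]]$families) {
    f_mom <- sim$table$counts[, fam$mother] / sum(sim$table$counts[, fam$mother])
    f_dau <- sim$table$counts[, fam$daughters] / sum(sim$table$counts[, fam$daughters])
    expect_lt(sum(abs(f_mom - f_dau)), 0.01)
  }
})

test_that("v = 0 makes daughters exchangeable between mothers", {
  own <- c(); other <- c()
  for (s in 1:20) {
    sim <- simulate_study(exch_config(seed = s, n_fam = 4, n_daughters = 2,
                                      n_taxa = 50, depth = 2000))
    dm <- as.matrix(bray_curtis(sim$table))
    fams <- sim$designs[["CH1.root"]]$families
    mothers <- sapply(fams, `[[`, "mother")
    for (f in fams) {
      own <- c(own, dm[f$mother, f$daughters])
      other <- c(other, dm[setdiff(mothers, f$mother), f$daughters])
    }
  }
  expect_gt(wilcox.test(own, other)$p.value, 0.01)
})

test_that("mean mother-daughter distance is non-increasing in v", {
  mean_md <- function(v) {
    vals <- sapply(1:4, function(s) {
      sim <- simulate_study(exch_config(seed = s, v = v, n_fam = 5,
                                        n_daughters = 2, n_taxa = 50,
                                        depth = 2000))
      dm <- as.matrix(bray_curtis(sim$table))
      mean(unlist(lapply(sim$designs[["CH1.root"]]$families,
                         function(f) dm[f$mother, f$daughters])))
    })
    mean(vals)
  }
  curve <- sapply(c(0, 0.4, 0.8, 1), mean_md)
  expect_true(all(diff(curve) <= 0))
})

test_that("the preset reproduces the four-estate family structure", {
  cfg <- sim_config(preset = "four-estates", n_taxa = 10, depth = 50, seed = 1)
  sim <- simulate_study(cfg)
  md <- sim$table$metadata
  leaf <- md[md$compartment == "leaf", ]
  expect_equal(sum(leaf$generation == "PM"), 47)
  expect_equal(sum(leaf$generation == "PF"), 15 * 5 + 10 * 3 + 12 * 3 + 10)
  expect_equal(length(unique(md$chateau)), 4)
})

test_that("a written simulation loads back identically", {
  cfg <- sim_config(n_taxa = 20, site_families = list(c(2, 1)),
                    compartments = "root", depth = 300, seed = 5)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_community(file.path(dir, "counts.tsv"),
                         file.path(dir, "metadata.tsv"),
                         file.path(dir, "taxonomy.tsv"))
  expect_identical(back$counts, sim$table$counts)
  tree <- read_tree(file.path(dir, "tree.nwk"), back)
  expect_setequal(tree$tip.label, sim$tree$tip.label)
})
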