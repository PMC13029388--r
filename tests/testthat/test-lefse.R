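make_taxonomy <- function(taxa, family, order = "O1") {
  data.frame(taxon_id = taxa, kingdom = "bacteria", phylum = "P1",
             class = "C1", order = order, family = family,
             stringsAsFactors = FALSE)
}

test_that("rank aggregation sums counts and pools unassigned taxa", {
  counts <- cbind(s1 = c(3, 4, 2), s2 = c(1, 0, 5))
  rownames(counts) <- c("A", "B", "C")
  md <- toy_metadata(c("s1", "s2"))
  tax <- make_taxonomy(c("A", "B", "C"), c("F1", "F1", "F2"))
  agg <- aggregate_rank(community_table(counts, md, tax), "family")
  expect_equal(agg$counts["F1", "s1"], 7)
  expect_equal(agg$counts["F2", "s2"], 5)

  # all-distinct families leave values unchanged (relabelled rows)
  tax2 <- make_taxonomy(c("A", "B", "C"), c("F1", "F2", "F3"))
  agg2 <- aggregate_rank(community_table(counts, md, tax2), "family")
  expect_equal(sort(as.vector(agg2$counts[, "s1"])),
               sort(unname(counts[, "s1"])))

  # empty labels pool under the nearest labelled ancestor
  tax3 <- make_taxonomy(c("A", "B", "C"), c("F1", "", ""), order = "OrdX")
  agg3 <- aggregate_rank(community_table(counts, md, tax3), "family")
  expect_true("unclassified OrdX" %in% rownames(agg3$counts))
  expect_equal(agg3$counts["unclassified OrdX", "s2"], 5)

  expect_error(aggregate_rank(community_table(counts, md, tax), "species"),
               "unknown rank")
})

# planted two-class table: features in `up` have `fold`-times higher
# expected abundance in class B
planted_table <- function(n_feat = 25, n_per_class = 8, up = 1:3,
                          fold = 5, seed = 1) {
  set.seed(seed)
  base <- rep(100, n_feat)
  mk <- function(mult) {
    lam <- base
    lam[up] <- lam[up] * mult
    rpois(n_feat, lam)
  }
  counts <- cbind(sapply(seq_len(n_per_class), function(i) mk(1)),
                  sapply(seq_len(n_per_class), function(i) mk(fold)))
  dimnames(counts) <- list(sprintf("F%02d", seq_len(n_feat)),
                           sprintf("s%02d", seq_len(2 * n_per_class)))
  cls <- rep(c("A", "B"), each = n_per_class)
  list(table = toy_table(counts), classes = cls)
}

test_that("lefse finds planted biomarkers with the right direction", {
  pt <- planted_table(seed = 2)
  res <- lefse(pt$table, pt$classes, seed = 1)
  expect_true(all(c("F01", "F02", "F03") %in% res$taxon[1:5]))
  expect_true(all(res$enriched_class[res$taxon %in% c("F01", "F02", "F03")]
                  == "B"))
  expect_true(all(is.finite(res$lda_score)))
  expect_true(all(res$kw_p < 0.05))
})

test_that("a feature present in only one class is enriched there", {
  pt <- planted_table(seed = 3)
  counts <- pt$table$counts
  counts["F10", ] <- c(rep(2000, 8), rep(0, 8))  # exclusive to class A
  res <- lefse(toy_table(counts), pt$classes, seed = 1)
  r <- res[res$taxon == "F10", ]
  expect_equal(r$enriched_class, "A")
  expect_gt(r$lda_score, 0)
})

test_that("constant features are excluded and larger gaps score higher", {
  pt <- planted_table(seed = 4)
  # fixed library sizes so the middle feature is constant in relative
  # abundance: it must be screened out
  set.seed(44)
  a <- c(rpois(8, 300), rpois(8, 900))
  counts <- rbind(FA = a, F20 = 500, FB = 2000 - a)
  colnames(counts) <- sprintf("s%02d", 1:16)
  res <- lefse(toy_table(counts), pt$classes, seed = 1)
  expect_false("F20" %in% res$taxon)
  expect_true("FA" %in% res$taxon)

  # same variance, 10x the class-mean gap: strictly larger effect size
  counts2 <- pt$table$counts * 0 + 100
  counts2["F01", ] <- c(rep(1000, 8), rep(1400, 8)) + rep(c(-3, 3), 8)
  counts2["F02", ] <- c(rep(1000, 8), rep(5000, 8)) + rep(c(-3, 3), 8)
  res2 <- lefse(toy_table(counts2), pt$classes, alpha = 0.1, seed = 1)
  s1 <- res2$lda_score[res2$taxon == "F01"]
  s2 <- res2$lda_score[res2$taxon == "F02"]
  expect_gt(s2, s1)
})

test_that("output is invariant to sample and feature order", {
  pt <- planted_table(seed = 5)
  res <- lefse(pt$table, pt$classes, seed = 7)
  cn <- colnames(pt$table$counts)
  rn <- rownames(pt$table$counts)
  set.seed(8)
  perm_s <- sample(length(cn)); perm_f <- sample(length(rn))
  shuffled <- pt$table$counts[perm_f, perm_s]
  md <- toy_metadata(cn[perm_s])
  cls <- pt$classes[perm_s]
  res2 <- lefse(community_table(shuffled, md), cls, seed = 7)
  expect_equal(res, res2)
})

test_that("KW screen is calibrated under shuffled class labels", {
  frac <- sapply(1:20, function(s) {
    tab <- random_table(50, 16, seed = 300 + s)
    set.seed(400 + s)
    cls <- sample(rep(c("A", "B"), each = 8))
    x <- t(relative_abundance(tab))
    p <- apply(x, 2, function(v) {
      suppressWarnings(kruskal.test(v, factor(cls))$p.value)
    })
    mean(p < 0.05, na.rm = TRUE)
  })
  # expected alpha = 0.05 within 3 s.e. of the pooled mean
  se <- sqrt(0.05 * 0.95 / (50 * 20))
  expect_lt(abs(mean(frac) - 0.05), 3 * se + 0.01)
})
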