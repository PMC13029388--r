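#' Aggregate a community table to a taxonomic rank
#'
#' Counts are summed over taxa sharing the rank label. Taxa with a missing
#' (empty) label at the requested rank are pooled per nearest labelled
#' ancestor rank as `"unclassified <parent>"`, SILVA-style.
#'
#' @param table a [community_table] with taxonomy.
#' @param rank one of the taxonomy's rank columns (e.g. `"family"`).
#' @return a [community_table] whose taxa are the rank labels; its taxonomy
#'   keeps the ranks at and above `rank`.
#' @export
aggregate_rank <- function(table, rank) {
  tax <- table$taxonomy
  if (is.null(tax)) vi_stop("table has no taxonomy")
  ranks <- setdiff(names(tax), "taxon_id")
  if (!rank %in% ranks) vi_stop("unknown rank '%s'", rank)
  ri <- match(rank, ranks)
  labels <- tax[[rank]]
  blank <- is.na(labels) | labels == ""
  if (any(blank)) {
    parent <- vapply(which(blank), function(i) {
      above <- rev(seq_len(ri - 1L))
      for (k in above) {
        if (!is.na(tax[[ranks[k]]][i]) && tax[[ranks[k]]][i] != "") {
          return(tax[[ranks[k]]][i])
        }
      }
      "root"
    }, character(1))
    labels[blank] <- paste("unclassified", parent)
  }
  agg <- rowsum(table$counts, group = labels, reorder = TRUE)
  keep_ranks <- ranks[seq_len(ri - 1L)]
  tax_out <- unique(data.frame(
    taxon_id = labels,
    tax[, keep_ranks, drop = FALSE],
    stringsAsFactors = FALSE))
  tax_out <- tax_out[!duplicated(tax_out$taxon_id), , drop = FALSE]
  community_table(agg, table$metadata, tax_out)
}

#' LEfSe-style biomarker discovery
#'
#' Kruskal-Wallis screen (chi-squared approximation with tie correction, no
#' multiple-testing correction, per LEfSe convention) on per-sample relative
#' abundances, followed by a bootstrap-averaged single-discriminant LDA
#' effect size for the surviving features. Abundances are scaled to parts
#' per million and floored at 1 (LEfSe's 1e-6 floor); each bootstrap draws
#' 2/3 of the samples within every class, fits [MASS::lda()], and scores
#' feature `f` as `|w_f| * max_pairwise |class-mean difference of f|` along
#' the first discriminant; the effect size is `log10` of the bootstrap mean
#' (floored at 1e-10). Unlike the original tool there is no subclass
#' (inner Wilcoxon) loop: the intended contrasts are single-level classes
#' such as generation x compartment.
#'
#' @param table a [community_table] (typically rank-aggregated).
#' @param class_factor metadata column name, or a vector of class labels
#'   aligned to the samples.
#' @param alpha Kruskal-Wallis screening level.
#' @param lda_threshold report only features with `lda_score >=` this
#'   (log10 scale; LEfSe's conventional 2.0).
#' @param n_boot bootstrap rounds.
#' @param top_k keep at most this many records (by decreasing score).
#' @param seed integer seed.
#' @return data.frame sorted by decreasing `lda_score`: `taxon`,
#'   `enriched_class` (class with the highest mean relative abundance),
#'   `kw_p`, `lda_score`, plus one `mean_<class>` column per class
#'   (mean relative abundance).
#' @export
lefse <- function(table, class_factor, alpha = 0.05, lda_threshold = 2.0,
                  n_boot = 30L, top_k = 30L, seed = 1L) {
  counts <- table$counts
  classes <- if (length(class_factor) == 1L && is.character(class_factor)) {
    cls <- table$metadata[[class_factor]]
    if (is.null(cls)) vi_stop("unknown metadata column '%s'", class_factor)
    cls
  } else {
    class_factor
  }
  classes <- factor(classes)
  if (nlevels(classes) < 2) vi_stop("need >= 2 classes")
  if (any(table(classes) < 3)) vi_stop("need >= 3 samples per class")

  x <- t(relative_abundance(counts)) * 1e6  # samples x features, ppm
  x[x < 1] <- 1                             # LEfSe 1e-6 abundance floor
  # order-invariance: fix feature and sample order
  x <- x[order(rownames(x)), order(colnames(x)), drop = FALSE]
  classes <- classes[match(rownames(x), colnames(counts))]

  keep <- apply(x, 2L, function(v) length(unique(v)) > 1)
  kw_p <- rep(NA_real_, ncol(x))
  kw_p[keep] <- apply(x[, keep, drop = FALSE], 2L, function(v) {
    suppressWarnings(stats::kruskal.test(v, classes)$p.value)
  })
  surv <- which(!is.na(kw_p) & kw_p < alpha)
  if (!length(surv)) {
    return(data.frame(taxon = character(), enriched_class = character(),
                      kw_p = numeric(), lda_score = numeric()))
  }

  xs <- x[, surv, drop = FALSE]
  lv <- levels(classes)
  eff <- matrix(0, nrow = n_boot, ncol = ncol(xs))
  with_seed(derive_seed(seed, "lefse-boot"), {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(lv, function(cl) {
        i <- which(classes == cl)
        sample(i, max(2L, floor(length(i) * 2 / 3)))
      }))
      xb <- xs[idx, , drop = FALSE]
      cb <- droplevels(classes[idx])
      ok <- apply(xb, 2L, stats::sd) > 0
      if (!any(ok) || nlevels(cb) < 2) next
      fit <- tryCatch(
        suppressWarnings(MASS::lda(xb[, ok, drop = FALSE], grouping = cb)),
        error = function(e) NULL)
      if (is.null(fit)) next
      w <- fit$scaling[, 1L]
      w <- w / sqrt(sum(w^2))
      cm <- apply(xb[, ok, drop = FALSE], 2L,
                  function(v) tapply(v, cb, mean))
      gap <- apply(cm, 2L, function(m) max(m) - min(m))
      eff[b, ok] <- abs(w) * gap
    }
  })
  score <- log10(pmax(colMeans(eff), 1e-10))

  cls_means <- apply(xs, 2L, function(v) tapply(v, classes, mean)) / 1e6
  enriched <- lv[apply(cls_means, 2L, which.max)]
  out <- data.frame(taxon = colnames(xs), enriched_class = enriched,
                    kw_p = kw_p[surv], lda_score = score,
                    stringsAsFactors = FALSE)
  mm <- t(cls_means)
  colnames(mm) <- paste0("mean_", lv)
  out <- cbind(out, as.data.frame(mm, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out <- out[out$lda_score >= lda_threshold, , drop = FALSE]
  out <- out[order(-abs(out$lda_score), out$taxon), , drop = FALSE]
  utils::head(out, top_k)
}
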