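#' Bray-Curtis dissimilarity matrix
#'
#' `D_jk = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`, computed on
#' column-normalized relative abundances by default (`normalize = FALSE`
#' uses raw counts). Entries lie in `[0, 1]`; identical samples give 0 and
#' samples with disjoint taxa give 1.
#'
#' @param table a [community_table] or counts matrix (taxa x samples).
#' @param normalize column-normalize to relative abundances first.
#' @return a `dist` object over samples, with attribute `metric`.
#' @export
bray_curtis <- function(table, normalize = TRUE) {
  counts <- if (inherits(table, "community_table")) table$counts else table
  if (ncol(counts) < 2) vi_stop("need >= 2 samples")
  libs <- colSums(counts)
  if (any(libs == 0)) {
    vi_stop("sample '%s' has library size 0", colnames(counts)[libs == 0][1L])
  }
  x <- if (normalize) sweep(counts, 2L, libs, "/") else counts
  d <- vegan::vegdist(t(x), method = "bray")
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of `-D^2 / 2` followed by eigendecomposition.
#' Axes with eigenvalue above `1e-8 * max(eigenvalue)` are kept; negative
#' eigenvalue mass is reported and no correction is applied. On distances
#' with an exact Euclidean embedding the retained axes reproduce the input
#' distances exactly.
#'
#' @param d a `dist` object or symmetric matrix of dissimilarities.
#' @return list of class `pcoa_result`: `coordinates` (samples x axes,
#'   column-centered), `eigenvalues` (retained, decreasing),
#'   `prop_variance` (share of the positive eigenvalue sum), and
#'   `negative_mass` (|sum of negative eigenvalues| / sum |eigenvalues|).
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) vi_stop("PCoA needs >= 3 samples")
  if (max(abs(m - t(m))) > 1e-12) vi_stop("distance matrix not symmetric")
  a <- -0.5 * m^2
  # Gower double-centering: G = A - row means - col means + grand mean
  g <- a - outer(rowMeans(a), rep(1, n)) -
    outer(rep(1, n), colMeans(a)) + mean(a)
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- eig$values > 1e-8 * max(eig$values)
  vals <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals),
                                                      nrow = length(vals))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_along(vals))
  neg <- eig$values[eig$values < 0]
  structure(list(coordinates = coords,
                 eigenvalues = vals,
                 prop_variance = vals / sum(eig$values[eig$values > 0]),
                 negative_mass = if (length(neg)) {
                   sum(abs(neg)) / sum(abs(eig$values))
                 } else 0),
            class = "pcoa_result")
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Anderson's permutational multivariate ANOVA, partitioning squared
#' dissimilarities among factor levels, with p-values from free permutation
#' of sample labels (`p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`). In
#' `mode = "marginal"` each factor is fit separately (its R2 is exactly
#' `SS_between / SS_total`); `mode = "sequential"` fits all factors in the
#' order given with Type-I sums of squares. Fitting is delegated to
#' [vegan::adonis2()]; a `strata` factor restricts permutations to blocks.
#'
#' @param d a `dist` object over samples.
#' @param metadata data.frame aligned to the samples of `d` (matched by
#'   `sample_id` against `labels(d)`).
#' @param factors character vector of metadata column names.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream; recorded in the
#'   result.
#' @param mode `"marginal"` (each factor alone) or `"sequential"`.
#' @param strata optional metadata column restricting permutations.
#' @param permutations optional explicit permutation matrix (rows =
#'   permutations), overriding `n_perm`; used for exact enumeration.
#' @return data.frame with `factor`, `df`, `sum_of_squares`, `pseudo_f`,
#'   `r2`, `p_value`, `n_perm`, `seed`, `mode`.
#' @export
permanova <- function(d, metadata, factors, n_perm = 999, seed = 1L,
                      mode = c("marginal", "sequential"), strata = NULL,
                      permutations = NULL) {
  mode <- match.arg(mode)
  ids <- labels(d)
  if (is.null(ids)) vi_stop("distance matrix has no sample labels")
  if (!all(ids %in% metadata$sample_id)) {
    vi_stop("metadata missing sample '%s'",
            setdiff(ids, metadata$sample_id)[1L])
  }
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  for (f in factors) {
    if (!f %in% names(md)) vi_stop("unknown factor '%s'", f)
    lv <- unique(md[[f]])
    if (length(lv) < 2) vi_stop("factor '%s' is constant", f)
    sizes <- table(md[[f]])
    if (any(sizes == 1)) {
      vi_warn("factor '%s': level(s) with a single sample: %s", f,
              paste(names(sizes)[sizes == 1], collapse = ", "))
    }
    md[[f]] <- factor(md[[f]])
  }
  perm_arg <- if (!is.null(permutations)) {
    permutations
  } else if (!is.null(strata)) {
    permute::how(blocks = md[[strata]], nperm = n_perm)
  } else {
    n_perm
  }
  fit_one <- function(rhs) {
    form <- stats::as.formula(paste("d ~", rhs))
    with_seed(derive_seed(seed, paste0("permanova:", rhs)),
              vegan::adonis2(form, data = md, permutations = perm_arg,
                             by = "terms"))
  }
  rows <- if (mode == "marginal") {
    lapply(factors, function(f) {
      a <- fit_one(f)
      data.frame(factor = f, df = a$Df[1L],
                 sum_of_squares = a$SumOfSqs[1L],
                 pseudo_f = a$F[1L], r2 = a$R2[1L],
                 p_value = a[["Pr(>F)"]][1L],
                 stringsAsFactors = FALSE)
    })
  } else {
    a <- fit_one(paste(factors, collapse = " + "))
    k <- seq_along(factors)
    list(data.frame(factor = factors, df = a$Df[k],
                    sum_of_squares = a$SumOfSqs[k],
                    pseudo_f = a$F[k], r2 = a$R2[k],
                    p_value = a[["Pr(>F)"]][k],
                    stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$n_perm <- if (is.matrix(perm_arg)) nrow(perm_arg) else n_perm
  out$seed <- seed
  out$mode <- mode
  out
}
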