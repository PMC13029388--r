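#' Community table: taxa-by-sample counts with aligned metadata and taxonomy
#'
#' The single container every analysis stage consumes. Counts are held as a
#' non-negative integer matrix with taxa in rows and samples in columns;
#' `metadata` carries one record per sample and `taxonomy` one ranked
#' lineage per taxon. Bacterial and fungal tables are always kept separate
#' (the `kingdom` metadata column tags which marker a table came from);
#' no operation in the package mixes kingdoms.
#'
#' @param counts numeric matrix, taxa x samples, non-negative integers;
#'   rownames are taxon ids, colnames sample ids.
#' @param metadata data.frame with columns `sample_id`, `chateau`,
#'   `compartment`, `generation`, `lineage`, `vine_id` and optionally
#'   `kingdom`. Every column of `counts` must have a record.
#' @param taxonomy optional data.frame with column `taxon_id` followed by
#'   ranked lineage columns (`kingdom`, `phylum`, `class`, `order`,
#'   `family`, `genus`); missing ranks are empty strings.
#' @return an object of class `community_table` with elements `counts`,
#'   `taxon_ids`, `sample_ids`, `metadata`, `taxonomy`.
#' @export
community_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    vi_stop("counts must have taxon rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    vi_stop("duplicate taxon id: %s",
            rownames(counts)[duplicated(rownames(counts))][1L])
  }
  if (anyDuplicated(colnames(counts))) {
    vi_stop("duplicate sample id: %s",
            colnames(counts)[duplicated(colnames(counts))][1L])
  }
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    vi_stop("negative count for taxon '%s' in sample '%s'",
            rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]])
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    vi_stop("counts must be integers (got non-integer values)")
  }
  counts <- round(counts)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "chateau", "compartment", "generation",
           "lineage", "vine_id")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) vi_stop("metadata missing column(s): %s",
                            paste(miss, collapse = ", "))
  absent <- setdiff(colnames(counts), metadata$sample_id)
  if (length(absent)) {
    vi_stop("sample '%s' has no metadata record", absent[1L])
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL

  zero_lib <- colSums(counts) == 0
  if (any(zero_lib)) {
    vi_stop("sample '%s' has library size 0", colnames(counts)[zero_lib][1L])
  }

  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
    if (!"taxon_id" %in% names(taxonomy)) {
      vi_stop("taxonomy must have a 'taxon_id' column")
    }
    tmiss <- setdiff(rownames(counts), taxonomy$taxon_id)
    if (length(tmiss)) vi_stop("taxon '%s' missing from taxonomy", tmiss[1L])
    taxonomy <- taxonomy[match(rownames(counts), taxonomy$taxon_id), ,
                         drop = FALSE]
    rownames(taxonomy) <- NULL
    rank_cols <- setdiff(names(taxonomy), "taxon_id")
    for (rc in rank_cols) {
      taxonomy[[rc]][is.na(taxonomy[[rc]])] <- ""
    }
  }

  flagged <- rownames(counts)[rowSums(counts) == 0]
  structure(
    list(counts = counts,
         taxon_ids = rownames(counts),
         sample_ids = colnames(counts),
         metadata = metadata,
         taxonomy = taxonomy,
         zero_taxa = flagged),
    class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  chateaux:     %s\n",
              paste(sort(unique(x$metadata$chateau)), collapse = ", ")))
  cat(sprintf("  compartments: %s\n",
              paste(sort(unique(x$metadata$compartment)), collapse = ", ")))
  cat(sprintf("  generations:  %s\n",
              paste(sort(unique(x$metadata$generation)), collapse = ", ")))
  if (length(x$zero_taxa)) {
    cat(sprintf("  %d all-zero taxa retained (flagged)\n",
                length(x$zero_taxa)))
  }
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Read a community table from TSV files
#'
#' The counts file is UTF-8 TSV with a header row of sample ids and the
#' taxon id in the first column (taxa rows x sample columns). A transposed
#' file is auto-detected — only when its row labels match the metadata
#' sample ids while its column labels do not — and silently corrected;
#' any other mismatch is an error, since silent transposition is the
#' classic microbiome bug.
#'
#' Column names in the metadata file can be remapped through `col_map`
#' (e.g. `col_map = c(chateau = "Site")` when the deposited file says
#' `Site`), so externally produced tables need no editing.
#'
#' @param counts_path,metadata_path,taxonomy_path TSV paths; taxonomy is
#'   optional (`NULL`).
#' @param col_map named character vector mapping required metadata column
#'   names to the names actually present in the file.
#' @return a [community_table].
#' @export
read_community <- function(counts_path, metadata_path, taxonomy_path = NULL,
                           col_map = NULL) {
  raw <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  counts <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(counts) <- as.character(raw[[1L]])

  metadata <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                                check.names = FALSE,
                                stringsAsFactors = FALSE,
                                quote = "", comment.char = "")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(metadata)) {
        names(metadata)[names(metadata) == col_map[[std]]] <- std
      }
    }
  }
  if (!"sample_id" %in% names(metadata)) {
    vi_stop("metadata missing column(s): sample_id")
  }

  # orientation check: columns should be samples
  col_hit <- mean(colnames(counts) %in% metadata$sample_id)
  row_hit <- mean(rownames(counts) %in% metadata$sample_id)
  if (col_hit < 1 && row_hit == 1) {
    counts <- t(counts)
  } else if (col_hit < 1) {
    vi_stop("sample '%s' has no metadata record",
            setdiff(colnames(counts), metadata$sample_id)[1L])
  }

  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    taxonomy <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE,
                                  quote = "", comment.char = "",
                                  colClasses = "character")
  }
  community_table(counts, metadata, taxonomy)
}

#' Write a community table to TSV files
#'
#' Inverse of [read_community()]: `write_community` then `read_community`
#' reproduces the counts bit-exactly.
#'
#' @param table a [community_table].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return invisibly, the paths written.
#' @export
write_community <- function(table, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cpath <- file.path(dir, paste0(prefix, "counts.tsv"))
  mpath <- file.path(dir, paste0(prefix, "metadata.tsv"))
  cdf <- data.frame(taxon_id = rownames(table$counts),
                    table$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(cdf, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$metadata, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(counts = cpath, metadata = mpath)
  if (!is.null(table$taxonomy)) {
    tpath <- file.path(dir, paste0(prefix, "taxonomy.tsv"))
    utils::write.table(table$taxonomy, tpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, taxonomy = tpath)
  }
  invisible(paths)
}

#' Subset a community table to a set of samples
#'
#' @param table a [community_table].
#' @param ... logical filter expressions over metadata columns
#'   (e.g. `compartment == "root"`), combined with AND.
#' @param sample_ids explicit character vector of samples to keep
#'   (intersected with the filters when both are given).
#' @param drop_zero_taxa drop taxa with all-zero counts after subsetting.
#' @return a [community_table].
#' @export
subset_samples <- function(table, ..., sample_ids = NULL,
                           drop_zero_taxa = FALSE) {
  conds <- substitute(list(...))
  keep <- sample_ids %||% table$metadata$sample_id
  if (length(conds) > 1L) {
    mask <- rep(TRUE, nrow(table$metadata))
    for (k in 2:length(conds)) {
      mask <- mask & eval(conds[[k]], table$metadata, parent.frame())
    }
    keep <- intersect(keep, table$metadata$sample_id[mask])
  }
  keep <- intersect(table$sample_ids, keep)
  if (!length(keep)) vi_stop("no samples left after subsetting")
  counts <- table$counts[, keep, drop = FALSE]
  if (drop_zero_taxa) counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[tax$taxon_id %in% rownames(counts), ,
                                drop = FALSE]
  community_table(counts,
                  table$metadata[table$metadata$sample_id %in% keep, ,
                                 drop = FALSE],
                  tax)
}

#' Relative abundances (column-normalized counts)
#'
#' @param table a [community_table] or a counts matrix.
#' @return matrix of per-sample proportions; columns sum to 1.
#' @export
relative_abundance <- function(table) {
  counts <- if (inherits(table, "community_table")) table$counts else table
  libs <- colSums(counts)
  if (any(libs == 0)) {
    vi_stop("sample '%s' has library size 0", colnames(counts)[libs == 0][1L])
  }
  sweep(counts, 2L, libs, "/")
}

#' Build the mother-daughter family design for one stratum
#'
#' A family is one mother (PM) sample plus the samples of her clonal
#' daughters (PF) sharing her lineage code, all within a single chateau x
#' compartment (x kingdom) stratum. Families are the exchangeability unit
#' of every permutation test in the package.
#'
#' @param table a [community_table].
#' @param chateau,compartment stratum selectors; `NULL` keeps all levels
#'   (useful when the table was pre-subset).
#' @return an object of class `family_design`: list with `stratum` (named
#'   list) and `families` (named list of `list(mother=, daughters=)`,
#'   keyed by lineage).
#' @export
build_family_design <- function(table, chateau = NULL, compartment = NULL) {
  md <- table$metadata
  keep <- rep(TRUE, nrow(md))
  if (!is.null(chateau)) keep <- keep & md$chateau == chateau
  if (!is.null(compartment)) keep <- keep & md$compartment == compartment
  md <- md[keep, , drop = FALSE]
  pm <- md[md$generation == "PM", , drop = FALSE]
  pf <- md[md$generation == "PF", , drop = FALSE]
  if (!nrow(pm) || !nrow(pf)) {
    vi_stop("stratum needs at least one PM and one PF sample")
  }
  dup <- pm$lineage[duplicated(pm$lineage)]
  if (length(dup)) {
    vi_stop("ambiguous mother: two PM samples share lineage '%s'", dup[1L])
  }
  orphan <- setdiff(unique(pf$lineage), pm$lineage)
  if (length(orphan)) {
    vi_warn("PF lineage(s) with no matching mother omitted: %s",
            paste(orphan, collapse = ", "))
    pf <- pf[pf$lineage %in% pm$lineage, , drop = FALSE]
  }
  childless <- setdiff(pm$lineage, unique(pf$lineage))
  pm <- pm[!pm$lineage %in% childless, , drop = FALSE]
  if (!nrow(pm)) vi_stop("no complete mother-daughter family in stratum")
  families <- lapply(seq_len(nrow(pm)), function(i) {
    list(mother = pm$sample_id[i],
         daughters = pf$sample_id[pf$lineage == pm$lineage[i]])
  })
  names(families) <- pm$lineage
  structure(list(stratum = list(chateau = chateau, compartment = compartment),
                 families = families),
            class = "family_design")
}

#' @export
print.family_design <- function(x, ...) {
  sizes <- vapply(x$families, function(f) length(f$daughters), integer(1))
  cat(sprintf("family_design: %d families (%d daughters) in stratum %s/%s\n",
              length(x$families), sum(sizes),
              x$stratum$chateau %||% "*", x$stratum$compartment %||% "*"))
  invisible(x)
}

# all sample ids covered by a design, mothers first
design_samples <- function(design) {
  unique(unlist(lapply(design$families,
                       function(f) c(f$mother, f$daughters)),
                use.names = FALSE))
}
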