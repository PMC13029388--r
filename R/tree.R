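#' Read a rooted phylogeny and prune it to the table's taxa
#'
#' @param newick_path path to a Newick 1.0 file with branch lengths.
#' @param table a [community_table]; tips not in the table are dropped with
#'   a warning. Table taxa missing from the tree are allowed here (only the
#'   phylogenetic turnover stage requires full coverage and errors there).
#' @return an [ape::phylo] tree.
#' @export
read_tree <- function(newick_path, table = NULL) {
  tree <- ape::read.tree(newick_path)
  if (is.null(tree)) vi_stop("could not parse Newick file '%s'", newick_path)
  if (is.null(tree$edge.length)) vi_stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) vi_stop("tree has negative branch lengths")
  if (any(is.na(tree$tip.label)) || any(tree$tip.label == "")) {
    vi_stop("tree has unlabelled tips")
  }
  if (!is.null(table)) {
    extra <- setdiff(tree$tip.label, table$taxon_ids)
    if (length(extra)) {
      vi_warn("dropping %d tree tip(s) absent from table: %s",
              length(extra),
              paste(utils::head(extra, 5L), collapse = ", "))
      tree <- ape::drop.tip(tree, extra)
    }
    missing <- setdiff(table$taxon_ids, tree$tip.label)
    if (length(missing)) {
      vi_warn("%d table taxa missing from tree (turnover stage will error)",
              length(missing))
    }
  }
  tree
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' Sum of branch lengths along the path between each pair of tips;
#' symmetric with zero diagonal.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return numeric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Tips are labelled `T0001`, `T0002`, ... and the tree is rescaled to unit
#' depth so that trait-evolution rates are per total tree depth.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed; the same seed always yields the same Newick
#'   string.
#' @return an ultrametric [ape::phylo] tree of depth 1.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) vi_stop("n_taxa must be >= 2")
  tree <- with_seed(derive_seed(seed, "yule-tree"),
                    ape::rphylo(n_taxa, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("T%04d", seq_len(n_taxa))
  tree
}
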