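#' A phylogeny with branch-class labels
#'
#' Wraps an \pkg{ape} \code{phylo} tree together with one class label per
#' branch. Branch classes are what branch-partitioned omega models refer to:
#' in the gene-duplication setting the conventional classes are \code{pre}
#' (branches predating the duplication), \code{stem_g1} / \code{stem_g5}
#' (the branches immediately postdating it) and \code{g1} / \code{g5} (the
#' two paralog crown clades), but labels are arbitrary strings.
#'
#' @param phy an \code{ape::phylo} tree with branch lengths in expected
#'   codon substitutions per codon (non-negative, finite). Missing branch
#'   lengths default to 0.1.
#' @param edge_class character vector of class labels, one per row of
#'   \code{phy$edge}, or a single label recycled to all branches.
#' @return object of class \code{labeled_tree}: list(\code{phy},
#'   \code{edge_class}).
#' @export
labeled_tree <- function(phy, edge_class = "all") {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  if (length(edge_class) == 1L)
    edge_class <- rep(edge_class, nrow(phy$edge))
  if (length(edge_class) != nrow(phy$edge))
    stop("need one class per branch (", nrow(phy$edge), ")")
  structure(list(phy = phy, edge_class = as.character(edge_class)),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("labeled_tree:", length(x$phy$tip.label), "tips,",
      nrow(x$phy$edge), "branches; classes:",
      paste(sort(unique(x$edge_class)), collapse = ", "), "\n")
  invisible(x)
}

# Node identifier used in label files: tip label for tips, "node<k>" for
# internal nodes (ape numbering).
#' @noRd
node_id <- function(phy, node) {
  ifelse(node <= length(phy$tip.label), phy$tip.label[node],
         paste0("node", node))
}

#' Read a labelled tree from Newick plus a branch-class map
#'
#' Two labelling conventions are supported. A separate TSV (columns
#' \code{node}, \code{class}) maps each branch, identified by its child node
#' (tip label, or \code{node<k>} in ape numbering), to a class. Alternatively
#' inline \code{#class} tags in the Newick string (appended to a tip label or
#' after a closing parenthesis) label the subtending branch; untagged
#' branches get class \code{"all"}.
#'
#' @param newick_path path to a Newick file (tags allowed).
#' @param labels_path optional path to the TSV label map.
#' @return a \code{labeled_tree}.
#' @export
read_labeled_tree <- function(newick_path, labels_path = NULL) {
  txt <- paste(readLines(newick_path, warn = FALSE), collapse = "")
  has_tags <- grepl("#", txt, fixed = TRUE)
  clean <- gsub("\\s*#[A-Za-z0-9_.]+", "", txt)
  phy <- ape::read.tree(text = clean)
  lt <- labeled_tree(phy)
  if (has_tags && is.null(labels_path)) {
    tagged <- ape::read.tree(text = gsub("\\s*#([A-Za-z0-9_.]+)", "_TAG_\\1", txt))
    # tags ride on tip labels or internal node labels of the tagged parse
    tag_of <- function(lab) sub("^.*_TAG_", "", lab)
    has <- function(lab) grepl("_TAG_", lab)
    n_tip <- length(phy$tip.label)
    node_tag <- rep(NA_character_, n_tip + phy$Nnode)
    node_tag[seq_len(n_tip)][has(tagged$tip.label)] <-
      tag_of(tagged$tip.label[has(tagged$tip.label)])
    if (!is.null(tagged$node.label)) {
      intn <- n_tip + seq_len(phy$Nnode)
      node_tag[intn][has(tagged$node.label)] <-
        tag_of(tagged$node.label[has(tagged$node.label)])
    }
    cls <- node_tag[phy$edge[, 2]]
    cls[is.na(cls)] <- "all"
    lt$edge_class <- cls
  }
  if (!is.null(labels_path)) {
    map <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    ids <- node_id(phy, phy$edge[, 2])
    m <- match(ids, map$node)
    if (anyNA(m)) stop("label map missing branch(es): ",
                       paste(ids[is.na(m)], collapse = ", "))
    lt$edge_class <- map$class[m]
  }
  lt
}

#' Write a labelled tree as Newick plus a branch-class TSV
#'
#' @param tree a \code{labeled_tree}.
#' @param newick_path output Newick path.
#' @param labels_path output TSV path (columns node, class).
#' @return invisibly, NULL.
#' @export
write_labeled_tree <- function(tree, newick_path, labels_path) {
  ape::write.tree(tree$phy, file = newick_path)
  d <- data.frame(node = node_id(tree$phy, tree$phy$edge[, 2]),
                  class = tree$edge_class, stringsAsFactors = FALSE)
  utils::write.table(d, labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Build a duplication-shaped labelled tree
#'
#' Two paralog crown clades (pectinate, with evenly spaced split depths)
#' joined at a duplication node, plus a pre-duplication outgroup lineage.
#' Branches are auto-labelled \code{pre} (outgroup lineage and the branch
#' below the duplication node), \code{stem_g1} / \code{stem_g5} (the two
#' branches immediately postdating the duplication) and \code{g1} /
#' \code{g5} (within-clade branches). Branch lengths are in expected codon
#' substitutions per codon.
#'
#' @param n_g1,n_g5 number of species per paralog clade (each >= 2;
#'   \code{n_g5} defaults to \code{n_g1}).
#' @param stem_depth length of each stem branch.
#' @param crown_depth tip depth of each crown clade (splits evenly spaced).
#' @param outgroup_depth length of the outgroup branch; the branch from the
#'   root to the duplication node has length \code{outgroup_depth -
#'   stem_depth - crown_depth} (floored at a small positive value) so the
#'   tree is approximately ultrametric.
#' @return a \code{labeled_tree} with tips \code{g1_sp1..}, \code{g5_sp1..},
#'   \code{outgroup}.
#' @export
make_duplication_tree <- function(n_g1 = 7L, n_g5 = n_g1 - 1L,
                                  stem_depth = 0.18,
                                  crown_depth = 0.105,
                                  outgroup_depth = 0.5) {
  if (n_g1 < 2L || n_g5 < 2L) stop("need at least 2 species per clade")
  clade_newick <- function(prefix, n, depth) {
    # pectinate clade, ultrametric: splits at depths step, 2*step, ...
    step <- depth / (n - 1)
    s <- sprintf("(%s_sp1:%.10f,%s_sp2:%.10f)", prefix, step, prefix, step)
    if (n >= 3L) for (k in 3:n) {
      s <- sprintf("(%s:%.10f,%s_sp%d:%.10f)",
                   s, step, prefix, k, step * (k - 1))
    }
    s
  }
  g1 <- clade_newick("g1", n_g1, crown_depth)
  g5 <- clade_newick("g5", n_g5, crown_depth)
  root_to_dup <- max(outgroup_depth - stem_depth - crown_depth, 0.01)
  nwk <- sprintf("(outgroup:%.10f,(%s:%.10f,%s:%.10f):%.10f);",
                 outgroup_depth, g1, stem_depth, g5, stem_depth, root_to_dup)
  phy <- ape::read.tree(text = nwk)
  # classify edges by the tip set below each child node
  n_tip <- length(phy$tip.label)
  below <- function(node) {
    if (node <= n_tip) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  is_g1_tip <- grepl("^g1_", phy$tip.label)
  is_g5_tip <- grepl("^g5_", phy$tip.label)
  cls <- character(nrow(phy$edge))
  for (e in seq_len(nrow(phy$edge))) {
    tips <- below(phy$edge[e, 2])
    if (setequal(tips, phy$tip.label[is_g1_tip])) cls[e] <- "stem_g1"
    else if (setequal(tips, phy$tip.label[is_g5_tip])) cls[e] <- "stem_g5"
    else if (all(grepl("^g1_", tips))) cls[e] <- "g1"
    else if (all(grepl("^g5_", tips))) cls[e] <- "g5"
    else cls[e] <- "pre"
  }
  labeled_tree(phy, cls)
}
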