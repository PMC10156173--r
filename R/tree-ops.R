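# Canonical split keys -------------------------------------------------
#
# A bipartition of the leaf set is represented by the side that does NOT
# contain the lexicographically smallest leaf, sorted and joined with a
# single space (leaf ids never contain whitespace).  This gives a
# well-defined equality for splits regardless of which side is listed,
# and doubles as the "edge id" used by the rooting functions: every edge
# of an unrooted tree corresponds to exactly one key.

#' Canonical key of a bipartition side
#'
#' @param taxa character vector: one side of the split.
#' @param all_taxa the full leaf set of the tree.
#' @return a single string identifying the split.
#' @export
split_key <- function(taxa, all_taxa) {
  ref <- min(all_taxa)
  side <- if (ref %in% taxa) setdiff(all_taxa, taxa) else taxa
  paste(sort(side), collapse = " ")
}

#' Leaf sets of all internal nodes of a tree
#' @noRd
node_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, function(i) tree$tip.label[i])
}

#' Nontrivial bipartitions of a tree
#'
#' Returns the set of nontrivial splits (both sides with at least two
#' leaves) induced by the internal edges of `tree`, as canonical keys
#' (see [split_key()]).  Rooted trees are assessed on their unrooted
#' topology, so the two edges incident to the root collapse to one
#' split.
#'
#' @param tree a `phylo` object.
#' @return character vector of canonical split keys (possibly empty).
#' @examples
#' tree_bipartitions(read_newick("(A,B,(C,D));"))
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  n <- length(labs)
  sets <- node_tip_sets(tree)
  keep <- vapply(sets, function(s) length(s) >= 2L && length(s) <= n - 2L,
                 logical(1))
  unique(vapply(sets[keep], split_key, character(1), all_taxa = labs))
}

# All edges of the unrooted topology as canonical keys, including the
# trivial (pendant) edges; used to enumerate candidate root positions.
all_edge_keys <- function(tree) {
  labs <- tree$tip.label
  triv <- vapply(labs, function(x) split_key(x, labs), character(1))
  unique(c(unname(triv), tree_bipartitions(tree)))
}

# The leaf side (not containing the reference leaf) encoded by a key.
key_to_side <- function(key) strsplit(key, " ", fixed = TRUE)[[1]]

#' Reroot a tree on the edge defined by a leaf-set split
#'
#' Places the root on the edge separating `taxa` from all other leaves,
#' subdividing that edge.  The unrooted bipartition set is unchanged.
#'
#' @param tree a `phylo` object (rooted input is unrooted first).
#' @param taxa character vector: one side of an existing split, or a
#'   canonical key produced by [split_key()].
#' @param position fraction in `[0,1]` of the edge length assigned to
#'   the `taxa` side of the new root (ignored when the tree has no
#'   branch lengths).
#' @return a rooted `phylo` object.
#' @export
reroot_at_split <- function(tree, taxa, position = 0.5) {
  stopifnot(inherits(tree, "phylo"), position >= 0, position <= 1)
  labs <- tree$tip.label
  if (length(taxa) == 1L && grepl(" ", taxa, fixed = TRUE))
    taxa <- key_to_side(taxa)
  if (!all(taxa %in% labs))
    concord_error("concord_unknown_edge", "split names taxa absent from tree")
  key <- split_key(taxa, labs)
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (!key %in% all_edge_keys(ut))
    concord_error("concord_unknown_edge",
                  "no edge of the tree matches the requested split")
  side <- key_to_side(key)
  if (length(side) == length(labs) - 1L) {
    # pendant edge of the reference leaf: outgroup is that single leaf
    side_for_root <- setdiff(labs, side)
  } else side_for_root <- side
  out <- ape::root(ut, outgroup = side_for_root, resolve.root = TRUE)
  if (!is.null(out$edge.length)) {
    rt <- length(out$tip.label) + 1L
    kids <- which(out$edge[, 1] == rt)
    if (length(kids) == 2L) {
      total <- sum(out$edge.length[kids])
      sets <- lapply(kids, function(k) tip_set_below(out, out$edge[k, 2]))
      frac_taxa <- if (setequal(sets[[1]], taxa)) position else 1 - position
      out$edge.length[kids[1]] <- total * frac_taxa
      out$edge.length[kids[2]] <- total * (1 - frac_taxa)
    }
  }
  out
}

tip_set_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Restrict a tree to a taxon subset
#'
#' Induced subtree on `taxa`: leaves outside the set are removed,
#' degree-2 nodes are suppressed and their branch lengths summed.
#'
#' @param tree a `phylo` object.
#' @param taxa taxon ids to keep (must share at least 2 with the tree).
#' @return the restricted `phylo` object.
#' @export
restrict_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  keep <- intersect(tree$tip.label, taxa)
  if (length(keep) < 2L)
    concord_error("concord_degenerate_restriction",
                  "fewer than 2 leaves survive the restriction")
  if (length(keep) == length(tree$tip.label)) return(tree)
  attr_sup <- !is.null(attr(tree, "support"))
  out <- ape::keep.tip(tree, keep)
  if (attr_sup) attr(out, "support") <- NULL  # supports not projected
  out
}

#' Test monophyly in a rooted tree
#'
#' @param tree a rooted `phylo` object.
#' @param taxa taxon ids (subset of the leaves).
#' @return `TRUE` iff some node's descendant leaf set equals `taxa`
#'   (singletons are trivially monophyletic).
#' @export
is_clade <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    concord_error("concord_unrooted", "monophyly test requires a rooted tree")
  if (!all(taxa %in% tree$tip.label))
    concord_error("concord_bad_taxa", "taxa are not a subset of the leaves")
  taxa <- unique(taxa)
  if (length(taxa) <= 1L) return(TRUE)
  sets <- node_tip_sets(tree)
  any(vapply(sets, function(s) length(s) == length(taxa) && setequal(s, taxa),
             logical(1)))
}

#' Shared-split comparison of two trees
#'
#' Both trees are restricted to their shared taxa and compared on
#' nontrivial bipartitions, quantifying tanglegram-style congruence.
#'
#' @param tree_a,tree_b `phylo` objects sharing at least 4 leaves.
#' @return a list with `shared`, `total_a`, `total_b` (split counts) and
#'   `fraction` = shared / mean(total_a, total_b).  When neither tree
#'   has an informative split the fraction is 1 (nothing to disagree
#'   about).
#' @export
shared_split_fraction <- function(tree_a, tree_b) {
  common <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(common) < 4L)
    concord_error("concord_bad_taxa", "trees share fewer than 4 taxa")
  ra <- restrict_tree(tree_a, common)
  rb <- restrict_tree(tree_b, common)
  ba <- tree_bipartitions(ra)
  bb <- tree_bipartitions(rb)
  shared <- length(intersect(ba, bb))
  denom <- mean(c(length(ba), length(bb)))
  list(shared = shared, total_a = length(ba), total_b = length(bb),
       fraction = if (denom == 0) 1 else shared / denom)
}
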