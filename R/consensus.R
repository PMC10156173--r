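# Threshold meta-consensus across gene trees with unequal taxon sets ---
#
# Each candidate clade is assessed in each gene tree that can evaluate
# it (>= 2 members present, >= 1 leaf outside); support is monophyly of
# the present members.  Clades with agreement fraction >= 0.5 are placed
# in the consensus topology greedily in a fixed rank order, drawn solid
# when the fraction reaches the display threshold (0.70 by default) and
# dashed otherwise.

clade_key <- function(taxa) paste(sort(unique(taxa)), collapse = " ")

#' Can a gene tree evaluate a candidate clade?
#'
#' @param tree rooted `phylo` object.
#' @param clade taxon-id set.
#' @return `TRUE` iff the tree has at least 2 leaves inside the clade
#'   and at least 1 outside (so monophyly is non-vacuous).
#' @export
clade_evaluable <- function(tree, clade) {
  inside <- sum(tree$tip.label %in% clade)
  inside >= 2L && (length(tree$tip.label) - inside) >= 1L
}

#' Does a gene tree support a candidate clade?
#'
#' @inheritParams clade_evaluable
#' @return `TRUE` iff the clade members present in the tree are
#'   monophyletic.  Calling this on a non-evaluable tree is an error.
#' @export
clade_supported <- function(tree, clade) {
  if (!clade_evaluable(tree, clade))
    concord_error("concord_contract", "clade is not evaluable in this tree")
  is_clade(tree, intersect(tree$tip.label, clade))
}

#' Per-clade agreement across a set of gene trees
#'
#' @param trees named list of rooted `phylo` objects (>= 2); one gene
#'   may contribute several trees (isoforms), each counted separately.
#' @param candidates list of taxon-id sets.
#' @param threshold solid/dashed display threshold in `(0,1]`
#'   (inclusive: a fraction equal to the threshold is solid).
#' @param min_evaluable minimum number of evaluable trees for a
#'   candidate to be considered well-sampled; below it the record is
#'   flagged `insufficient_data`.
#' @return data frame with one row per candidate: `clade` (space-joined
#'   key), `size`, `n_evaluable`, `n_supporting`, `fraction`, `status`
#'   (`solid`/`dashed`, `NA` if never evaluable), `insufficient_data`.
#' @export
agreement_table <- function(trees, candidates, threshold = 0.70,
                            min_evaluable = 1L) {
  stopifnot(length(trees) >= 2L, threshold > 0, threshold <= 1,
            min_evaluable >= 1L)
  if (length(candidates) == 0L)
    concord_error("concord_bad_input", "empty candidate set")
  rows <- lapply(candidates, function(cl) {
    ev <- vapply(trees, clade_evaluable, logical(1), clade = cl)
    sup <- vapply(trees[ev], clade_supported, logical(1), clade = cl)
    n_ev <- sum(ev); n_sup <- sum(sup)
    frac <- if (n_ev > 0L) n_sup / n_ev else NA_real_
    data.frame(clade = clade_key(cl), size = length(unique(cl)),
               n_evaluable = n_ev, n_supporting = n_sup, fraction = frac,
               status = if (is.na(frac)) NA_character_ else
                 if (frac >= threshold) "solid" else "dashed",
               insufficient_data = n_ev < min_evaluable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

compatible_sets <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0L || i == length(a) || i == length(b)
}

#' Greedy threshold consensus of gene trees
#'
#' Candidate clades are the leaf sets of all internal nodes of all gene
#' trees (each tree's full leaf set excluded).  They are ranked by
#' agreement fraction (desc), number of evaluable trees (desc), clade
#' size (desc), then lexicographically, and accepted greedily when
#' compatible (nested or disjoint) with everything already accepted.
#' Only clades with fraction >= 0.5 and enough evaluable trees are
#' placed; accepted clades at or above `threshold` are annotated solid,
#' the rest dashed.
#'
#' @inheritParams agreement_table
#' @return object of class `consensus_topology`: list with `tree` (a
#'   rooted, possibly multifurcating `phylo` over the union of all
#'   taxa), `agreements` (the full [agreement_table()] with an
#'   `accepted` column) and `edges` (rows for accepted clades only).
#' @export
threshold_consensus <- function(trees, threshold = 0.70, min_evaluable = 1L) {
  stopifnot(length(trees) >= 2L)
  all_taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  cand_keys <- unique(unlist(lapply(trees, function(tr) {
    sets <- node_tip_sets(tr)
    sets <- sets[vapply(sets, length, integer(1)) >= 2L]
    sets <- sets[!vapply(sets, setequal, logical(1), y = all_taxa)]
    vapply(sets, clade_key, character(1))
  })))
  if (is.null(cand_keys) || length(cand_keys) == 0L)
    concord_error("concord_bad_input", "gene trees contain no candidate clades")
  candidates <- lapply(cand_keys, key_to_side)
  tab <- agreement_table(trees, candidates, threshold, min_evaluable)
  ord <- order(-tab$fraction, -tab$n_evaluable, -tab$size, tab$clade)
  accepted <- list()
  acc_flag <- logical(nrow(tab))
  for (i in ord) {
    if (is.na(tab$fraction[i]) || tab$fraction[i] < 0.5) next
    if (tab$insufficient_data[i]) next
    cl <- candidates[[i]]
    if (all(vapply(accepted, compatible_sets, logical(1), b = cl))) {
      accepted <- c(accepted, list(cl))
      acc_flag[i] <- TRUE
    }
  }
  tab$accepted <- acc_flag
  tree <- assemble_from_clades(all_taxa, accepted)
  structure(list(tree = tree, agreements = tab,
                 edges = tab[tab$accepted, , drop = FALSE],
                 threshold = threshold),
            class = "consensus_topology")
}

# Build a rooted (possibly multifurcating) tree from a pairwise
# compatible clade collection over `all_taxa`.
assemble_from_clades <- function(all_taxa, clades) {
  build <- function(taxa, pool) {
    inside <- pool[vapply(pool, function(p)
      length(p) < length(taxa) && all(p %in% taxa), logical(1))]
    maximal <- inside[!vapply(seq_along(inside), function(i)
      any(vapply(seq_along(inside), function(j)
        i != j && all(inside[[i]] %in% inside[[j]]) &&
          length(inside[[i]]) < length(inside[[j]]), logical(1))),
      logical(1))]
    # drop duplicates (same set can appear once only)
    keys <- vapply(maximal, clade_key, character(1))
    maximal <- maximal[!duplicated(keys)]
    covered <- unlist(maximal)
    singles <- setdiff(taxa, covered)
    parts <- c(vapply(maximal, function(m) build(m, inside), character(1)),
               singles)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(build(all_taxa, clades), ";")
  ape::read.tree(text = txt)
}

#' @export
print.consensus_topology <- function(x, ...) {
  cat(sprintf("Threshold consensus (threshold %.2f): %d taxa, %d placed clades (%d solid)\n",
              x$threshold, length(x$tree$tip.label), nrow(x$edges),
              sum(x$edges$status == "solid")))
  invisible(x)
}

#' Write an annotated consensus Newick
#'
#' Internal nodes carry a comment block
#' `[&status=solid,frac=0.83,n=9]` describing their agreement record.
#'
#' @param consensus a `consensus_topology`.
#' @param file optional output path.
#' @return the annotated Newick string (invisibly when written).
#' @export
write_consensus_newick <- function(consensus, file = NULL) {
  stopifnot(inherits(consensus, "consensus_topology"))
  tr <- consensus$tree
  ann <- setNames(
    sprintf("[&status=%s,frac=%.4g,n=%d]", consensus$edges$status,
            consensus$edges$fraction, consensus$edges$n_evaluable),
    consensus$edges$clade)
  build <- function(node) {
    n <- length(tr$tip.label)
    if (node <= n) return(tr$tip.label[node])
    kids <- tr$edge[tr$edge[, 1] == node, 2]
    inner <- paste(vapply(kids, build, character(1)), collapse = ",")
    key <- clade_key(tip_set_below(tr, node))
    paste0("(", inner, ")", if (key %in% names(ann)) ann[[key]] else "")
  }
  txt <- paste0(build(length(tr$tip.label) + 1L), ";")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
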