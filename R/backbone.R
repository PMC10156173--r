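# Backbone concordance -------------------------------------------------
#
# The backbone is an ordered ladder of lineages, earliest-branching
# first (default: Gloeobacterales, then Thermostichales, then the higher
# crown).  A rooted tree is concordant when, for every suffix of the
# order past the first lineage, the union of the remaining lineages is
# monophyletic.  The earliest lineage is allowed to be a basal grade.

#' Backbone specification
#'
#' @param lineages ordered lineage labels, earliest-branching first.
#' @param outgroup label treated as outgroup and excluded before
#'   constraint checking (set `NULL` to keep all taxa).
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(lineages = c("GLOEO", "THERMO", "HIGHER"),
                          outgroup = "OUTGROUP") {
  if (length(lineages) < 2L || anyDuplicated(lineages))
    concord_error("concord_bad_spec", "need >= 2 distinct lineage labels")
  structure(list(lineages = lineages, outgroup = outgroup),
            class = "backbone_spec")
}

#' Test a rooted tree against the nested backbone
#'
#' Taxa labelled with the outgroup label or `AMBIGUOUS` are removed
#' before checking and listed in the report.  For the default three-
#' lineage backbone the constraints are "THERMO+HIGHER monophyletic" and
#' "HIGHER monophyletic"; the earliest lineage may be paraphyletic at
#' the root.  A constraint whose taxon union is empty or spans every
#' retained leaf is flagged inapplicable rather than failed.
#'
#' @param tree a rooted `phylo` object.
#' @param clades clade map (named vector or data frame).
#' @param spec a [backbone_spec()].
#' @return an object of class `concordance_report`: list with
#'   `concordant`, `constraints` (data frame: constraint, n_taxa,
#'   status in pass/fail/inapplicable), `excluded`, `scenario`.
#' @export
check_backbone <- function(tree, clades, spec = backbone_spec()) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree))
    concord_error("concord_unrooted", "check_backbone requires a rooted tree")
  cm <- as_clade_map(clades)
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(cm))
  if (length(unmapped))
    concord_error("concord_bad_taxa",
                  paste("taxa missing from clade map:", unmapped[1L]))
  drop_labels <- c("AMBIGUOUS", spec$outgroup)
  excluded <- tips[cm[tips] %in% drop_labels]
  kept <- setdiff(tips, excluded)
  if (length(kept) < 2L)
    concord_error("concord_degenerate_restriction",
                  "fewer than 2 leaves remain after exclusions")
  wt <- restrict_tree(tree, kept)
  lin <- spec$lineages
  rows <- lapply(seq.int(2L, length(lin)), function(i) {
    union_lin <- lin[i:length(lin)]
    taxa <- kept[cm[kept] %in% union_lin]
    name <- paste0(paste(union_lin, collapse = "+"), " monophyletic")
    status <-
      if (length(taxa) == 0L || length(taxa) == length(kept)) "inapplicable"
      else if (is_clade(wt, taxa)) "pass"
      else "fail"
    data.frame(constraint = name, n_taxa = length(taxa), status = status,
               stringsAsFactors = FALSE)
  })
  constraints <- do.call(rbind, rows)
  applicable <- constraints$status != "inapplicable"
  structure(list(
    concordant = all(constraints$status[applicable] == "pass"),
    constraints = constraints,
    excluded = excluded,
    scenario = NA_character_), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Backbone concordance report",
      if (!is.na(x$scenario)) sprintf("(scenario: %s)", x$scenario), "\n")
  cat("  concordant:", x$concordant, "\n")
  for (i in seq_len(nrow(x$constraints)))
    cat(sprintf("  %-40s %s\n", x$constraints$constraint[i],
                x$constraints$status[i]))
  if (length(x$excluded))
    cat("  excluded:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Rooting scenario
#'
#' A named root placement: the root is put on the edge separating `taxa`
#' from all other leaves ("between X and all other sequences").
#'
#' @param name scenario name carried into reports.
#' @param taxa character vector defining one side of the root split.
#' @return an object of class `rooting_scenario`.
#' @export
rooting_scenario <- function(name, taxa) {
  stopifnot(is.character(name), length(name) == 1L, length(taxa) >= 1L)
  structure(list(name = name, taxa = unique(taxa)),
            class = "rooting_scenario")
}

#' Evaluate a rooting scenario against the backbone
#'
#' Reroots the tree on the scenario's split (refusing approximate
#' matches: if the bipartition is not an edge of the tree the scenario
#' is inapplicable, which is itself a result) and runs
#' [check_backbone()].
#'
#' @param tree a `phylo` object (unrooted or rooted; rooting is
#'   discarded).
#' @param clades clade map.
#' @param scenario a [rooting_scenario()].
#' @param spec a [backbone_spec()].
#' @return a `concordance_report` carrying the scenario name.
#' @export
evaluate_rooting <- function(tree, clades, scenario, spec = backbone_spec()) {
  stopifnot(inherits(scenario, "rooting_scenario"))
  rooted <- tryCatch(
    reroot_at_split(tree, scenario$taxa),
    concord_unknown_edge = function(e)
      concord_error("concord_inapplicable_scenario", paste0(
        "scenario '", scenario$name,
        "' does not correspond to an edge of the tree")))
  rep <- check_backbone(rooted, clades, spec)
  rep$scenario <- scenario$name
  rep$root_split <- split_key(intersect(scenario$taxa, tree$tip.label),
                              tree$tip.label)
  rep
}

#' Enumerate all root placements concordant with the backbone
#'
#' Every edge of the unrooted topology (pendant edges included) is tried
#' as a root position and checked with [check_backbone()].
#'
#' @inheritParams evaluate_rooting
#' @return character vector of canonical split keys (see [split_key()])
#'   of the edges whose rooting is concordant.
#' @export
enumerate_concordant_rootings <- function(tree, clades,
                                          spec = backbone_spec()) {
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  keys <- all_edge_keys(ut)
  ok <- vapply(keys, function(k) {
    rep <- tryCatch(check_backbone(reroot_at_split(ut, k), clades, spec),
                    concord_error = function(e) NULL)
    !is.null(rep) && rep$concordant
  }, logical(1))
  unname(keys[ok])
}

#' Lineage coherence: monophyly plus expected basal member
#'
#' Tests the vertical-inheritance signature of a lineage in a rooted
#' gene tree: the lineage's taxa form a clade, and a designated taxon is
#' the earliest branch (sister to all remaining lineage members) within
#' that clade.
#'
#' @param tree rooted `phylo` object.
#' @param clades clade map.
#' @param lineage lineage label to test.
#' @param expected_basal taxon id expected as the earliest branch; must
#'   belong to the lineage.
#' @return list with logicals `monophyletic` and `basal_matches`.
#' @export
lineage_coherence <- function(tree, clades, lineage, expected_basal) {
  cm <- as_clade_map(clades)
  taxa <- intersect(tree$tip.label, names(cm)[cm == lineage])
  if (!expected_basal %in% names(cm)[cm == lineage])
    concord_error("concord_bad_taxa",
                  "expected_basal does not belong to the lineage")
  if (!expected_basal %in% taxa)
    concord_error("concord_bad_taxa", "expected_basal not present in tree")
  if (length(taxa) < 3L)
    concord_error("concord_bad_taxa", "lineage has fewer than 3 leaves in tree")
  mono <- is_clade(tree, taxa)
  basal <- mono && is_clade(tree, setdiff(taxa, expected_basal))
  list(monophyletic = mono, basal_matches = basal)
}

#' Chronology window between divergence and latest acquisition
#'
#' Converts two dates (in Gya, billions of years before present) into
#' the length in million years of the window during which a lineage
#' would have had to remain a single population under an HGT scenario:
#' the time from its divergence to the latest possible gene acquisition.
#'
#' @param t_divergence divergence time (Gya), e.g. 2.5.
#' @param t_acquisition_latest latest acquisition time (Gya), e.g. 2.1.
#' @return window length in million years (My).
#' @examples
#' scenario_window(2.5, 2.1)  # 400 My
#' @export
scenario_window <- function(t_divergence, t_acquisition_latest) {
  stopifnot(is.numeric(t_divergence), is.numeric(t_acquisition_latest))
  if (t_divergence <= 0 || t_acquisition_latest <= 0)
    concord_error("concord_bad_input", "times must be positive (Gya)")
  if (t_acquisition_latest > t_divergence)
    concord_error("concord_negative_window", paste(
      "acquisition postdates divergence: the window would be negative;",
      "swap the arguments if the dates were reversed"))
  # dates are stated at Gya resolution; round away floating-point dust
  round((t_divergence - t_acquisition_latest) * 1000, 6)
}
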