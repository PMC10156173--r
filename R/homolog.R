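# Ortholog/paralog discrimination from pairwise-identity breadth -------
#
# Orthologs of a single-domain protein keep close relatives across a
# broad panel of assemblies; paralogs born by ancient duplication and
# accelerated divergence have close relatives in few.  The profile is
# built from full-length global alignments (the homologs of interest
# are single-domain proteins), not local BLAST-style HSPs.

#' Percent identity and coverage of a global pairwise alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1).  Identity is computed over aligned residue-pair
#' columns only (gap columns excluded); coverage is the number of
#' aligned residue pairs divided by the length of the shorter sequence.
#'
#' @param a,b ungapped amino-acid strings (or single rows of a protein
#'   record data frame).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return list with `identity_pct` in `[0,100]` and `coverage` in
#'   `[0,1]`.
#' @export
pairwise_identity <- function(a, b, gap_opening = 11, gap_extension = 1) {
  a <- as_sequence(a); b <- as_sequence(b)
  if (nchar(a) == 0L || nchar(b) == 0L)
    concord_error("concord_bad_input", "empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  pc <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  paired <- pc != "-" & sc != "-"
  n_pair <- sum(paired)
  ident <- if (n_pair == 0L) 0 else 100 * sum(pc[paired] == sc[paired]) / n_pair
  list(identity_pct = ident,
       coverage = n_pair / min(nchar(a), nchar(b)),
       n_aligned = n_pair)
}

as_sequence <- function(x) {
  if (is.data.frame(x)) x <- x$sequence
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

blosum62_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})

#' Best-hit identity profile of a query across a panel of assemblies
#'
#' @param query ungapped amino-acid string or one protein record row.
#' @param panel data frame of protein records (`id`, `assembly`,
#'   `sequence`) covering one or more assemblies.
#' @param min_coverage hits with alignment coverage below this are
#'   ignored; an assembly with no hit passing it is marked absent.
#' @return data frame with one row per panel assembly: `assembly`,
#'   `hit_id`, `identity_pct`, `coverage`, `absent`.
#' @export
best_hit_profile <- function(query, panel, min_coverage = 0.5) {
  if (!is.data.frame(panel) || nrow(panel) == 0L)
    concord_error("concord_bad_input", "empty panel")
  q <- as_sequence(query)
  rows <- lapply(split(panel, panel$assembly), function(pp) {
    hits <- lapply(seq_len(nrow(pp)), function(i)
      pairwise_identity(q, pp$sequence[i]))
    idt <- vapply(hits, `[[`, numeric(1), "identity_pct")
    cov <- vapply(hits, `[[`, numeric(1), "coverage")
    ok <- cov >= min_coverage
    if (!any(ok))
      return(data.frame(assembly = pp$assembly[1L], hit_id = NA_character_,
                        identity_pct = NA_real_, coverage = NA_real_,
                        absent = TRUE, stringsAsFactors = FALSE))
    ranked <- order(-idt, -cov, pp$id)
    best <- ranked[ranked %in% which(ok)][1L]
    data.frame(assembly = pp$assembly[1L], hit_id = pp$id[best],
               identity_pct = idt[best], coverage = cov[best],
               absent = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a homolog from its identity-breadth profile
#'
#' Breadth is the fraction of panel assemblies whose best hit reaches
#' the identity threshold.  Broad breadth is the ortholog-like
#' signature; narrow breadth (close relatives confined to few
#' assemblies) is the paralog-like signature.
#'
#' @param profile output of [best_hit_profile()].
#' @param identity_threshold percent identity defining a "close
#'   relative" (default 30).
#' @param breadth_threshold breadth at or above which the call is
#'   ortholog-like (default 0.6).
#' @param paralog_breadth breadth strictly below which the call is
#'   paralog-like (default 0.2); in between the call is indeterminate.
#' @return list with `label` (`ortholog-like` / `paralog-like` /
#'   `indeterminate`), `breadth`, and the parameters used.
#' @export
classify_homolog <- function(profile, identity_threshold = 30,
                             breadth_threshold = 0.6,
                             paralog_breadth = 0.2) {
  if (!is.data.frame(profile) || nrow(profile) == 0L)
    concord_error("concord_bad_input", "empty profile")
  if (identity_threshold < 0 || identity_threshold > 100 ||
      breadth_threshold <= 0 || breadth_threshold > 1 ||
      paralog_breadth < 0 || paralog_breadth >= breadth_threshold)
    concord_error("concord_bad_input", "thresholds out of range")
  close_rel <- !profile$absent & profile$identity_pct >= identity_threshold
  breadth <- mean(close_rel)
  label <- if (breadth >= breadth_threshold) "ortholog-like"
    else if (breadth < paralog_breadth) "paralog-like"
    else "indeterminate"
  list(label = label, breadth = breadth,
       identity_threshold = identity_threshold,
       breadth_threshold = breadth_threshold,
       paralog_breadth = paralog_breadth)
}
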