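# Supermatrix (catenation) design --------------------------------------
#
# A reference protein set (length-filtered) is screened against each
# assembly's proteins by global-alignment identity; each cell of the
# presence matrix is complete / partial / absent.  Catenations are then
# designed around required assemblies: the proteins complete in every
# required assembly, ordered greedily to keep as many additional
# assemblies complete as possible.

#' Build a protein presence/completeness matrix
#'
#' @param reference data frame of reference protein records (`id`,
#'   `sequence`); proteins shorter than `min_length` are dropped.
#' @param assemblies data frame of protein records (`id`, `assembly`,
#'   `sequence`) covering all panel assemblies.
#' @param min_length minimum reference protein length (default 128, the
#'   conventional cutoff for length-stable ribosomal proteins).
#' @param complete_fraction a detected homolog is complete when its
#'   alignment coverage reaches this fraction (default 0.9), partial
#'   otherwise.
#' @param detect_identity minimum percent identity for a homolog to
#'   count as detected at all (default 30); below it the cell is
#'   absent.
#' @return object of class `presence_matrix`: character matrix
#'   (proteins x assemblies) with values `complete`/`partial`/`absent`
#'   and attributes `lengths` (reference lengths) and `params`.
#' @export
build_presence_matrix <- function(reference, assemblies, min_length = 128,
                                  complete_fraction = 0.9,
                                  detect_identity = 30) {
  stopifnot(min_length >= 1, complete_fraction > 0, complete_fraction <= 1)
  ref <- reference[nchar(reference$sequence) >= min_length, , drop = FALSE]
  if (nrow(ref) == 0L)
    concord_error("concord_bad_input",
                  "no reference protein passes the length filter")
  asm_names <- sort(unique(assemblies$assembly))
  m <- matrix("absent", nrow = nrow(ref), ncol = length(asm_names),
              dimnames = list(ref$id, asm_names))
  by_asm <- split(assemblies, assemblies$assembly)
  for (i in seq_len(nrow(ref))) {
    for (a in asm_names) {
      pp <- by_asm[[a]]
      best_id <- -Inf; best_cov <- 0
      for (j in seq_len(nrow(pp))) {
        h <- pairwise_identity(ref$sequence[i], pp$sequence[j])
        # completeness is coverage of the REFERENCE, so truncated
        # homologs register as partial even when fully aligned
        ref_cov <- h$n_aligned / nchar(ref$sequence[i])
        if (h$identity_pct > best_id ||
            (h$identity_pct == best_id && ref_cov > best_cov)) {
          best_id <- h$identity_pct; best_cov <- ref_cov
        }
      }
      if (best_id >= detect_identity)
        m[i, a] <- if (best_cov >= complete_fraction) "complete" else "partial"
    }
  }
  structure(m, class = c("presence_matrix", "matrix"),
            lengths = setNames(nchar(ref$sequence), ref$id),
            params = list(min_length = min_length,
                          complete_fraction = complete_fraction,
                          detect_identity = detect_identity))
}

#' Design catenations around required assemblies
#'
#' For each required assembly set, the plan's proteins are those
#' complete in every required assembly, ordered greedily: at each step
#' the protein keeping the largest number of additional assemblies
#' complete is appended (ties broken by reference length descending,
#' then name).  The plan's included assemblies are those complete for
#' every plan protein.  Plans with fewer than 2 proteins are flagged
#' unusable.
#'
#' @param matrix a `presence_matrix`.
#' @param required list of character vectors of assembly names; one
#'   plan is designed per element.
#' @return list of `catenation_plan` objects: each a list with
#'   `proteins` (ordered), `assemblies`, `required`, `usable`,
#'   `diagnostic`.
#' @export
design_catenations <- function(matrix, required) {
  stopifnot(inherits(matrix, "presence_matrix"), length(required) >= 1L)
  lens <- attr(matrix, "lengths")
  m <- matrix
  attributes(m) <- list(dim = dim(matrix), dimnames = dimnames(matrix))
  lapply(required, function(req) {
    if (length(req) == 0L)
      concord_error("concord_bad_input", "empty required assembly set")
    missing_asm <- setdiff(req, colnames(m))
    if (length(missing_asm))
      concord_error("concord_bad_input",
                    paste("unknown assembly:", missing_asm[1L]))
    pool <- rownames(m)[apply(m[, req, drop = FALSE] == "complete", 1, all)]
    if (length(pool) < 2L)
      return(structure(list(proteins = pool, assemblies = req,
                            required = req, usable = FALSE,
                            diagnostic = sprintf(
                              "%d protein(s) complete in all required assemblies",
                              length(pool))),
                       class = "catenation_plan"))
    chosen <- character(0)
    remaining <- pool
    while (length(remaining)) {
      kept <- vapply(remaining, function(p) {
        prots <- c(chosen, p)
        sum(apply(m[prots, , drop = FALSE] == "complete", 2, all))
      }, integer(1))
      ord <- order(-kept, -lens[remaining], remaining)
      pick <- remaining[ord[1L]]
      chosen <- c(chosen, pick)
      remaining <- setdiff(remaining, pick)
    }
    asm <- colnames(m)[apply(m[chosen, , drop = FALSE] == "complete", 2, all)]
    structure(list(proteins = chosen, assemblies = asm, required = req,
                   usable = TRUE, diagnostic = NA_character_),
              class = "catenation_plan")
  })
}

#' @export
print.catenation_plan <- function(x, ...) {
  if (x$usable)
    cat(sprintf("Catenation plan: %d proteins (%s), %d assemblies\n",
                length(x$proteins), paste(x$proteins, collapse = ", "),
                length(x$assemblies)))
  else
    cat("Unusable catenation plan:", x$diagnostic, "\n")
  invisible(x)
}

#' Concatenate per-protein alignments following a plan
#'
#' @param alignments named list (protein -> alignment as a named
#'   character vector keyed by assembly).
#' @param plan a `catenation_plan` (or a list with `proteins` and
#'   `assemblies`); protein order comes from the plan, not the list.
#' @return list with `alignment` (named character vector, one row per
#'   included assembly) and `partitions` (data frame: protein, start,
#'   end, 1-based inclusive, tiling `1..total`).
#' @export
concatenate_alignments <- function(alignments, plan) {
  prots <- plan$proteins
  asm <- plan$assemblies
  missing_aln <- setdiff(prots, names(alignments))
  if (length(missing_aln))
    concord_error("concord_bad_input",
                  paste("no alignment for protein:", missing_aln[1L]))
  widths <- integer(length(prots))
  for (k in seq_along(prots)) {
    aln <- alignments[[prots[k]]]
    validate_alignment(aln)
    absent <- setdiff(asm, names(aln))
    if (length(absent))
      concord_error("concord_missing_sequence", sprintf(
        "protein %s lacks a sequence for assembly %s", prots[k], absent[1L]))
    widths[k] <- nchar(aln[[1L]])
  }
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rows <- vapply(asm, function(a)
    paste(vapply(prots, function(p) alignments[[p]][[a]], character(1)),
          collapse = ""), character(1))
  list(alignment = setNames(rows, asm),
       partitions = data.frame(protein = prots, start = starts, end = ends,
                               stringsAsFactors = FALSE))
}

#' Write a RAxML-style partition file
#' @param partitions partition data frame from
#'   [concatenate_alignments()].
#' @param file output path.
#' @export
write_partition_file <- function(partitions, file) {
  writeLines(sprintf("PROT, %s = %d-%d", partitions$protein,
                     partitions$start, partitions$end), file)
  invisible(file)
}

#' Write an alignment in relaxed PHYLIP format
#' @param aln named character vector alignment.
#' @param file output path.
#' @export
write_phylip <- function(aln, file) {
  validate_alignment(aln)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln), nchar(aln[[1L]])), con)
  writeLines(paste(names(aln), unname(aln)), con)
  invisible(file)
}
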