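# LxNxLR motif conservation scoring ------------------------------------
#
# Motif positions are given in ungapped 1-based coordinates of a
# reference sequence and mapped through the alignment to columns.  Each
# sequence's residue at each motif position is classified as identity,
# conservative (per-position residue class, not a global similarity
# matrix), nonconservative, or missing (gap or X: absence of data is
# not evidence of loss).  Residue flags (e.g. Gly or Ser in place of
# the critical Asn) are emitted independently of status.

#' Motif specification
#'
#' @param reference id of the reference sequence anchoring the
#'   coordinates.
#' @param positions strictly increasing ungapped 1-based positions in
#'   the reference.
#' @param expected expected residue at each position.
#' @param conservative list of character vectors: residues counted as
#'   conservative substitutions at each position.
#' @param flags list of named character vectors per position: maps an
#'   observed residue to a flag name (e.g. `c(G = "gly_substituted")`).
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(reference, positions, expected, conservative,
                       flags = vector("list", length(positions))) {
  stopifnot(length(positions) == length(expected),
            length(positions) == length(conservative),
            length(positions) == length(flags))
  if (any(diff(positions) <= 0))
    concord_error("concord_bad_spec", "positions must be strictly increasing")
  for (i in seq_along(expected))
    if (expected[i] %in% conservative[[i]])
      concord_error("concord_bad_spec",
                    "expected residue cannot be in its own conservative set")
  structure(list(reference = reference, positions = as.integer(positions),
                 expected = toupper(expected),
                 conservative = lapply(conservative, toupper), flags = flags),
            class = "motif_spec")
}

#' The default LxNxLR bilin-binding motif specification
#'
#' The four informative positions of the LxNxLR motif of GUN4 (the two
#' `x` wildcards are not scored): Leu, Asn, Leu, Arg.  Conservative
#' substitutions are Ile, Val or Met for Leu and Asp for Asn; nothing is
#' accepted for Arg.  Gly or Ser at the Asn position (the critical
#' bilin-proximal residue, Asn211 in Synechocystis numbering, Asn219 in
#' Chlamydomonas) is flagged `gly_substituted` / `ser_substituted`.
#'
#' @param reference reference sequence id.
#' @param positions ungapped reference positions of L, N, L, R (in that
#'   order).
#' @return a [motif_spec()].
#' @export
lxnxlr_spec <- function(reference, positions) {
  stopifnot(length(positions) == 4L)
  motif_spec(reference, positions,
             expected = c("L", "N", "L", "R"),
             conservative = list(c("I", "V", "M"), "D",
                                 c("I", "V", "M"), character(0)),
             flags = list(NULL,
                          c(G = "gly_substituted", S = "ser_substituted"),
                          NULL, NULL))
}

#' Map ungapped reference positions to alignment columns
#'
#' Column `c` maps position `p` when the reference row has exactly `p`
#' non-gap characters in columns `1..c` and column `c` itself is
#' non-gap.
#'
#' @param aln named character vector alignment.
#' @param reference reference row name.
#' @param positions ungapped 1-based positions in the reference.
#' @return integer vector of 1-based alignment columns, named by
#'   position.
#' @export
map_positions <- function(aln, reference, positions) {
  validate_alignment(aln)
  if (!reference %in% names(aln))
    concord_error("concord_bad_input", "reference sequence not in alignment")
  chars <- strsplit(aln[[reference]], "")[[1]]
  nongap <- chars != "-"
  idx <- cumsum(nongap)
  if (any(positions < 1L) || any(positions > sum(nongap)))
    concord_error("concord_bad_input",
                  "position beyond the reference's ungapped length")
  cols <- vapply(positions, function(p) which(nongap & idx == p)[1L],
                 integer(1))
  setNames(cols, positions)
}

#' Score motif conservation across an alignment
#'
#' @param aln named character vector alignment containing the spec's
#'   reference.
#' @param spec a [motif_spec()].
#' @return object of class `motif_report`: data frame with one row per
#'   (sequence, motif position): `seq_id`, `position`, `column`,
#'   `observed`, `status` (`identity`/`conservative`/`nonconservative`/
#'   `missing`), `flag` (`NA` if none).  The attribute `n_degraded`
#'   holds the per-sequence count of nonconservative positions and
#'   `lacks_ge2` the headline "lacks >= 2 of the motif residues"
#'   predicate (missing positions do not count as degraded).
#' @export
score_motif <- function(aln, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  cols <- map_positions(aln, spec$reference, spec$positions)
  rows <- lapply(names(aln), function(id) {
    chars <- strsplit(aln[[id]], "")[[1]]
    obs <- chars[cols]
    status <- vapply(seq_along(obs), function(i) {
      o <- obs[i]
      if (o %in% c("-", "X")) "missing"
      else if (o == spec$expected[i]) "identity"
      else if (o %in% spec$conservative[[i]]) "conservative"
      else "nonconservative"
    }, character(1))
    flag <- vapply(seq_along(obs), function(i) {
      fm <- spec$flags[[i]]
      if (!is.null(fm) && obs[i] %in% names(fm)) unname(fm[[obs[i]]])
      else NA_character_
    }, character(1))
    data.frame(seq_id = id, position = spec$positions,
               column = unname(cols), observed = obs, status = status,
               flag = flag, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  degraded <- tapply(rep$status == "nonconservative", rep$seq_id, sum)
  degraded <- degraded[names(aln)]
  structure(rep, class = c("motif_report", "data.frame"),
            n_degraded = setNames(as.integer(degraded), names(aln)),
            lacks_ge2 = setNames(as.integer(degraded) >= 2L, names(aln)))
}

#' Summarize motif conservation by group
#'
#' @param report a `motif_report` from [score_motif()].
#' @param groups named character vector mapping every scored sequence to
#'   a group (e.g. lineage label or ortholog/paralog).
#' @return list with `by_group` (data frame: group, n_seq, counts of
#'   sequences retaining 0..k positions as identity or conservative,
#'   n_lacks_ge2, fraction_lacks_ge2), `per_sequence` (data frame:
#'   seq_id, group, n_retained, n_degraded, lacks_ge2, flags) and
#'   `flag_counts` (table of flags by group).
#' @export
summarize_motif <- function(report, groups) {
  stopifnot(inherits(report, "motif_report"))
  ids <- unique(report$seq_id)
  missing_grp <- setdiff(ids, names(groups))
  if (length(missing_grp))
    concord_error("concord_bad_input",
                  paste("sequence without group:", missing_grp[1L]))
  k <- length(unique(report$position))
  per <- do.call(rbind, lapply(ids, function(id) {
    sub <- report[report$seq_id == id, ]
    retained <- sum(sub$status %in% c("identity", "conservative"))
    degraded <- sum(sub$status == "nonconservative")
    data.frame(seq_id = id, group = unname(groups[id]),
               n_retained = retained, n_degraded = degraded,
               lacks_ge2 = degraded >= 2L,
               flags = paste(sub$flag[!is.na(sub$flag)], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  by_group <- do.call(rbind, lapply(split(per, per$group), function(g) {
    ret_counts <- vapply(0:k, function(r) sum(g$n_retained == r), integer(1))
    out <- data.frame(group = g$group[1L], n_seq = nrow(g),
                      n_lacks_ge2 = sum(g$lacks_ge2),
                      fraction_lacks_ge2 = mean(g$lacks_ge2),
                      stringsAsFactors = FALSE)
    for (r in 0:k) out[[paste0("retain_", r)]] <- ret_counts[r + 1L]
    out
  }))
  rownames(by_group) <- NULL
  flags <- report$flag[!is.na(report$flag)]
  flag_grp <- unname(groups[report$seq_id[!is.na(report$flag)]])
  list(by_group = by_group, per_sequence = per,
       flag_counts = if (length(flags)) table(group = flag_grp, flag = flags)
       else table(character(0)))
}
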