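# Synthetic data generator ---------------------------------------------
#
# Emulates the statistical structure of a genome/MAG panel for early
# cyanobacterial evolution: a ladder species tree with three nested
# ingroup clades plus an outgroup, gene trees derived from it by
# topology noise (NNI), horizontal transfer (one SPR per affected
# gene) and duplication (paralog subtree with accelerated rates), and
# protein sequences evolved under the 20-state Poisson model with a
# motif block that is conserved in orthologs and degraded in paralogs.
# Everything is a pure function of (config, seed).

#' Simulation configuration
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param n_gloeo,n_thermo,n_higher,n_outgroup clade sizes (taxa).
#' @param bl_meanlog,bl_sdlog log-normal branch-length parameters
#'   (substitutions/site).
#' @param n_genes number of gene families to simulate.
#' @param p_hgt per-gene probability of one horizontal transfer (SPR).
#' @param p_duplication per-gene probability of a duplication creating
#'   a paralog subtree.
#' @param p_nni per-internal-edge probability of a nearest-neighbor
#'   interchange (topology noise).
#' @param missingness per-(gene, taxon) deletion probability emulating
#'   incomplete MAGs.
#' @param seq_length protein length in residues.
#' @param gamma_shape optional gamma shape for among-site rate
#'   variation (`NULL` = uniform rates).
#' @param bl_jitter_sd log-normal sd of multiplicative branch-length
#'   jitter applied to gene trees.
#' @param motif_positions ungapped positions of the four informative
#'   motif residues (L, N, L, R frame).
#' @param motif_degrade_n number of motif positions degraded in
#'   paralogs at the duplication point (>= 2 by design).
#' @param paralog_rate_mult branch-length multiplier inside the paralog
#'   subtree.
#' @param hgt_recipient,hgt_donor lineage labels: the transferred leaf
#'   is drawn from the recipient lineage and regrafted inside the donor
#'   lineage's clade.
#' @param dup_source,dup_host lineage labels: the duplicated subtree is
#'   a cherry drawn inside `dup_source`; the copy is grafted as sister
#'   to the clade of `dup_host` (`"ingroup"` = sister to all
#'   non-outgroup taxa).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_gloeo = 4L, n_thermo = 4L, n_higher = 6L,
                       n_outgroup = 2L,
                       bl_meanlog = log(0.1), bl_sdlog = 0.5,
                       n_genes = 10L,
                       p_hgt = 0, p_duplication = 0, p_nni = 0,
                       missingness = 0,
                       seq_length = 300L, gamma_shape = NULL,
                       bl_jitter_sd = 0.2,
                       motif_positions = c(101L, 103L, 105L, 106L),
                       motif_degrade_n = 2L,
                       paralog_rate_mult = 3,
                       hgt_recipient = "THERMO", hgt_donor = "HIGHER",
                       dup_source = "GLOEO", dup_host = "ingroup") {
  if (missing(seed) || is.null(seed))
    concord_error("concord_bad_spec", "a seed is mandatory")
  probs <- c(p_hgt, p_duplication, p_nni, missingness)
  stopifnot(all(probs >= 0), all(probs <= 1),
            n_gloeo >= 1, n_thermo >= 1, n_higher >= 1, n_outgroup >= 1,
            seq_length > max(motif_positions), motif_degrade_n >= 2L,
            motif_degrade_n <= 4L, paralog_rate_mult > 0)
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "sim_config")
}

motif_block <- function(config) {
  list(positions = config$motif_positions,
       expected = c("L", "N", "L", "R"),
       conservative = list(c("I", "V", "M"), "D", c("I", "V", "M"),
                           character(0)))
}

# Random labelled-history topology on n tips (coalescent topology with
# all branch lengths replaced afterwards).
random_clade_tree <- function(labels, config) {
  n <- length(labels)
  if (n == 1L) return(NULL)
  tr <- ape::rcoal(n, tip.label = sample(labels))
  tr$edge.length <- NULL
  tr
}

subtree_newick <- function(labels, config) {
  if (length(labels) == 1L) return(labels)
  tr <- random_clade_tree(labels, config)
  sub(";$", "", ape::write.tree(tr))
}

#' Simulate the ladder species tree
#'
#' Topology `(outgroup,(GLOEO,(THERMO,HIGHER)));` with random
#' within-clade topologies (uniform labelled histories) and log-normal
#' branch lengths.
#'
#' @param config a [sim_config()].
#' @return list with `tree` (rooted `phylo`) and `clades` (named
#'   character vector clade map).
#' @export
simulate_species_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  taxa <- list(
    OUTGROUP = sprintf("O%02d", seq_len(config$n_outgroup)),
    GLOEO = sprintf("G%02d", seq_len(config$n_gloeo)),
    THERMO = sprintf("T%02d", seq_len(config$n_thermo)),
    HIGHER = sprintf("H%02d", seq_len(config$n_higher)))
  nwk <- sprintf("(%s,(%s,(%s,%s)));",
                 subtree_newick(taxa$OUTGROUP, config),
                 subtree_newick(taxa$GLOEO, config),
                 subtree_newick(taxa$THERMO, config),
                 subtree_newick(taxa$HIGHER, config))
  tree <- ape::read.tree(text = nwk)
  tree$edge.length <- stats::rlnorm(nrow(tree$edge), config$bl_meanlog,
                                    config$bl_sdlog)
  clades <- setNames(rep(names(taxa), lengths(taxa)), unlist(taxa))
  list(tree = tree, clades = clades)
}

# One NNI around internal edge (u -> v): a random child of v trades
# places with a random sibling of v.
apply_nni <- function(tree, edge_row) {
  u <- tree$edge[edge_row, 1]; v <- tree$edge[edge_row, 2]
  vc <- tree$edge[tree$edge[, 1] == v, 2]
  sibs <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  if (!length(vc) || !length(sibs)) return(tree)
  s <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
  c1 <- if (length(vc) == 1L) vc else sample(vc, 1L)
  i_s <- which(tree$edge[, 1] == u & tree$edge[, 2] == s)
  i_c <- which(tree$edge[, 1] == v & tree$edge[, 2] == c1)
  tree$edge[i_s, 1] <- v
  tree$edge[i_c, 1] <- u
  ape::read.tree(text = ape::write.tree(tree))
}

#' Simulate one gene tree from the species tree
#'
#' Starts from the species topology; applies an NNI with probability
#' `p_nni` per internal edge, then with probability `p_hgt` one SPR
#' moving a random leaf of the recipient lineage into the donor
#' lineage's clade; branch lengths are jittered multiplicatively.
#'
#' @param species output of [simulate_species_tree()].
#' @param config a [sim_config()].
#' @param gene_index integer; offsets the seed so genes are independent
#'   but jointly reproducible.
#' @return list with `tree` (rooted `phylo`) and `truth` (list: `gene`,
#'   `mode` = vertical/hgt, `hgt_taxon`, `hgt_donor`, `hgt_exits`,
#'   `paralog_taxa` (empty), `labels` named ortholog/paralog vector).
#' @export
simulate_gene_tree <- function(species, config, gene_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L + gene_index)
  tree <- species$tree
  clades <- species$clades
  n <- length(tree$tip.label)
  n_internal <- sum(tree$edge[, 2] > n)
  n_moves <- sum(stats::runif(n_internal) < config$p_nni)
  for (i in seq_len(n_moves)) {
    internal <- which(tree$edge[, 2] > n)
    e <- if (length(internal) == 1L) internal else sample(internal, 1L)
    tree <- apply_nni(tree, e)
  }
  mode <- "vertical"; hgt_taxon <- NA_character_; hgt_exits <- FALSE
  if (stats::runif(1) < config$p_hgt) {
    recip <- intersect(tree$tip.label,
                       names(clades)[clades == config$hgt_recipient])
    donor <- intersect(tree$tip.label,
                       names(clades)[clades == config$hgt_donor])
    if (length(recip) >= 1L && length(donor) >= 2L) {
      mode <- "hgt"
      hgt_taxon <- if (length(recip) == 1L) recip else sample(recip, 1L)
      tree <- spr_move_leaf(tree, hgt_taxon, donor, config)
      hgt_exits <- TRUE  # regraft lands strictly inside the donor clade
    }
  }
  tree$edge.length <- tree$edge.length *
    stats::rlnorm(nrow(tree$edge), 0, config$bl_jitter_sd)
  labels <- setNames(rep("ortholog", length(tree$tip.label)),
                     tree$tip.label)
  list(tree = tree,
       truth = list(gene = sprintf("gene_%02d", gene_index), mode = mode,
                    hgt_taxon = hgt_taxon, hgt_donor = config$hgt_donor,
                    hgt_exits = hgt_exits, paralog_taxa = character(0),
                    labels = labels))
}

# Prune `leaf` and regraft it along a random edge strictly inside the
# clade spanned by `donor_taxa`.
spr_move_leaf <- function(tree, leaf, donor_taxa, config) {
  pruned <- ape::drop.tip(tree, leaf)
  donor_taxa <- setdiff(donor_taxa, leaf)
  mrca <- ape::getMRCA(pruned, donor_taxa)
  inside <- clade_descendant_nodes(pruned, mrca)
  attach_node <- if (length(inside) == 1L) inside else sample(inside, 1L)
  edge_row <- which(pruned$edge[, 2] == attach_node)
  pos <- stats::runif(1) * pruned$edge.length[edge_row]
  newbl <- stats::rlnorm(1, config$bl_meanlog, config$bl_sdlog)
  phytools::bind.tip(pruned, leaf, edge.length = newbl,
                     where = attach_node, position = pos)
}

# All nodes (tips and internals) strictly below `node`.
clade_descendant_nodes <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- kids
  for (k in kids[kids > length(tree$tip.label)])
    out <- c(out, clade_descendant_nodes(tree, k))
  out
}

#' Graft a duplicated (paralog) subtree onto a gene tree
#'
#' Models an ancient duplication with subsequent accelerated
#' divergence: a cherry (2-leaf clade) inside the `dup_source` lineage
#' is copied, its tips renamed with the suffix `_para`, and the copy
#' grafted as sister to the `dup_host` clade (`"ingroup"` = all
#' non-outgroup taxa).  The duplication is dated at the graft point:
#' branch lengths inside the copy are multiplied by
#' `paralog_rate_mult` and its stem is extended so that the mean
#' root-to-tip depth of the copy below the graft point equals
#' `paralog_rate_mult` times the host clade's mean depth there -- the
#' paralogs have evolved at the accelerated rate for the whole time
#' since the duplication.
#'
#' @param gene output of [simulate_gene_tree()] (list with `tree` and
#'   `truth`), or a bare `phylo` tree.
#' @param config a [sim_config()].
#' @param clades clade map for the tree's taxa.
#' @param seed optional seed override (defaults to `config$seed + 5000`).
#' @return list with `tree` and updated `truth`.
#' @export
simulate_duplication <- function(gene, config, clades, seed = NULL) {
  set.seed(seed %||% (config$seed + 5000L))
  if (inherits(gene, "phylo")) gene <- list(tree = gene, truth = list(
    mode = "vertical", paralog_taxa = character(0),
    labels = setNames(rep("ortholog", length(gene$tip.label)),
                      gene$tip.label)))
  tree <- gene$tree
  if (length(tree$tip.label) < 4L)
    concord_error("concord_bad_input", "gene tree has fewer than 4 leaves")
  src <- intersect(tree$tip.label, names(clades)[clades == config$dup_source])
  cherry <- find_cherry(tree, src)
  if (is.null(cherry))
    cherry <- find_cherry(tree, tree$tip.label)
  sub <- ape::extract.clade(tree, cherry$node)
  sub$edge.length <- sub$edge.length * config$paralog_rate_mult
  sub$tip.label <- paste0(sub$tip.label, "_para")
  host <- if (identical(config$dup_host, "ingroup"))
    intersect(tree$tip.label, names(clades)[clades != "OUTGROUP"])
  else intersect(tree$tip.label, names(clades)[clades == config$dup_host])
  host_mrca <- ape::getMRCA(tree, host)
  host_row <- which(tree$edge[, 2] == host_mrca)
  # after NNI/HGT noise the host group may reach back to the root, which
  # has no stem edge; then the copy is added as a child of the root
  graft_above <- if (length(host_row)) tree$edge.length[host_row] / 2 else 0
  # date the duplication at the graft point: the copy's depth there is
  # paralog_rate_mult times the host clade's mean depth
  depths <- ape::node.depth.edgelength(tree)
  host_depth <- graft_above +
    mean(depths[match(host, tree$tip.label)]) - depths[host_mrca]
  sub_depths <- ape::node.depth.edgelength(sub)
  sub_depth <- mean(sub_depths[seq_along(sub$tip.label)])
  sub$root.edge <- max(config$paralog_rate_mult * host_depth - sub_depth,
                       0.01)
  out <- ape::bind.tree(tree, sub, where = host_mrca,
                        position = graft_above)
  truth <- gene$truth
  truth$mode <- if (identical(truth$mode, "vertical")) "duplication+vertical"
    else paste0("duplication+", truth$mode)
  truth$paralog_taxa <- sub$tip.label
  truth$labels <- c(truth$labels,
                    setNames(rep("paralog", length(sub$tip.label)),
                             sub$tip.label))
  list(tree = out, truth = truth)
}

# First cherry (internal node whose children are 2 tips) whose tips are
# all inside `taxa`; NULL if none.
find_cherry <- function(tree, taxa) {
  n <- length(tree$tip.label)
  for (node in (n + 1L):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 2L && all(kids <= n) &&
        all(tree$tip.label[kids] %in% taxa))
      return(list(node = node, tips = tree$tip.label[kids]))
  }
  NULL
}

#' Evolve protein sequences along a gene tree
#'
#' Site-independent 20-state Poisson substitution model (all exchange
#' rates equal, equal frequencies, scaled to mean rate 1): along a
#' branch of length `t` a site changes with probability
#' `(19/20)(1 - exp(-(20/19) t))` and, given a change, moves uniformly
#' to one of the 19 other residues.  Optional gamma-distributed site
#' rates.  The four motif positions are held at their expected residues
#' (L, N, L, R) on ortholog lineages; at the stem of the paralog clade
#' `motif_degrade_n` of them are switched to residues outside the
#' identity-or-conservative set and thereafter evolve within that
#' nonconservative residue set only (the degraded site never reverts).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param config a [sim_config()].
#' @param truth truth record (for `paralog_taxa`); `NULL` means all
#'   ortholog.
#' @param seed optional seed override (defaults to `config$seed + 9000`).
#' @return named character vector of ungapped equal-length sequences
#'   (an alignment that is true by construction).
#' @export
evolve_sequences <- function(tree, config, truth = NULL, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    concord_error("concord_bad_input", "all branch lengths must be present")
  set.seed(seed %||% (config$seed + 9000L))
  mb <- motif_block(config)
  L <- config$seq_length
  rates <- if (is.null(config$gamma_shape)) rep(1, L)
    else stats::rgamma(L, shape = config$gamma_shape,
                       rate = config$gamma_shape)
  aa_idx <- seq_along(AA_ALPHABET)
  root_seq <- sample(aa_idx, L, replace = TRUE)
  root_seq[mb$positions] <- match(mb$expected, AA_ALPHABET)
  # per-position residue indices allowed after degradation
  nonconserv <- lapply(seq_along(mb$positions), function(i)
    setdiff(aa_idx, match(c(mb$expected[i], mb$conservative[[i]]),
                          AA_ALPHABET)))
  paralog_taxa <- if (is.null(truth)) character(0) else truth$paralog_taxa
  para_mrca <- if (length(paralog_taxa) >= 2L)
    ape::getMRCA(tree, paralog_taxa)
  else if (length(paralog_taxa) == 1L)
    which(tree$tip.label == paralog_taxa)
  else NA_integer_
  n <- length(tree$tip.label)
  # site modes: 0 free, 1 frozen motif (ortholog), 2 degraded motif
  out <- matrix(NA_integer_, nrow = n, ncol = L)
  evolve_branch <- function(seq, t, mode, motif_slot) {
    p_change <- (19 / 20) * (1 - exp(-(20 / 19) * t * rates))
    change <- stats::runif(L) < p_change
    change[mode == 1L] <- FALSE
    idx <- which(change)
    for (s in idx) {
      slot <- motif_slot[s]
      allowed <- if (mode[s] == 2L) nonconserv[[slot]] else aa_idx
      allowed <- setdiff(allowed, seq[s])
      if (length(allowed)) seq[s] <- if (length(allowed) == 1L) allowed
        else sample(allowed, 1L)
    }
    seq
  }
  motif_slot <- integer(L)
  motif_slot[mb$positions] <- seq_along(mb$positions)
  walk <- function(node, seq, mode) {
    kids <- which(tree$edge[, 1] == node)
    for (k in kids) {
      child <- tree$edge[k, 2]
      t <- tree$edge.length[k]
      cmode <- mode
      cseq <- seq
      if (!is.na(para_mrca) && child == para_mrca) {
        # duplication stem: degrade the motif, release the rest of it
        deg <- sort(sample(seq_along(mb$positions), config$motif_degrade_n))
        cmode[mb$positions] <- 0L
        for (d in deg) {
          p <- mb$positions[d]
          cmode[p] <- 2L
          cseq[p] <- if (length(nonconserv[[d]]) == 1L) nonconserv[[d]]
            else sample(nonconserv[[d]], 1L)
        }
      }
      cseq <- evolve_branch(cseq, t, cmode, motif_slot)
      if (child <= n) out[child, ] <<- cseq
      else walk(child, cseq, cmode)
    }
  }
  mode0 <- integer(L)
  mode0[mb$positions] <- 1L
  walk(n + 1L, root_seq, mode0)
  aln <- apply(out, 1, function(v) paste(AA_ALPHABET[v], collapse = ""))
  setNames(aln, tree$tip.label)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes `species.nwk`, `clades.tsv`, per-gene trees
#' (`gene_XX.nwk`) and ungapped alignments (`gene_XX.fasta`) with
#' missing taxa removed, `truth.tsv`, and a YAML echo of the
#' configuration.  Rerunning with the same config yields byte-identical
#' files.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `species`, `clades`, `genes` (per
#'   gene: `tree`, `alignment`, `truth`) and `files`.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  species <- simulate_species_tree(config)
  genes <- vector("list", config$n_genes)
  clades_full <- species$clades
  for (g in seq_len(config$n_genes)) {
    gene <- simulate_gene_tree(species, config, g)
    set.seed(config$seed + 3000L + g)
    if (stats::runif(1) < config$p_duplication)
      gene <- simulate_duplication(gene, config, species$clades,
                                   seed = config$seed + 5000L + g)
    aln <- evolve_sequences(gene$tree, config, gene$truth,
                            seed = config$seed + 9000L + g)
    # missingness mask (paralog copies are never protected)
    set.seed(config$seed + 7000L + g)
    tips <- gene$tree$tip.label
    drop <- tips[stats::runif(length(tips)) < config$missingness]
    if (length(tips) - length(drop) < 3L)
      drop <- utils::head(drop, max(0L, length(tips) - 3L))
    if (length(drop)) {
      gene$tree <- ape::drop.tip(gene$tree, drop)
      aln <- aln[setdiff(names(aln), drop)]
    }
    gene$truth$masked <- drop
    gene$alignment <- aln
    genes[[g]] <- gene
  }
  # paralog tips inherit the clade label of their source taxon
  para <- unique(unlist(lapply(genes, function(g) g$truth$paralog_taxa)))
  if (length(para))
    clades_full <- c(clades_full,
                     setNames(species$clades[sub("_para$", "", para)], para))
  files <- c(species = file.path(outdir, "species.nwk"),
             clades = file.path(outdir, "clades.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             config = file.path(outdir, "config.yaml"))
  write_newick(species$tree, files[["species"]])
  write_clade_map(clades_full, files[["clades"]])
  truth_df <- do.call(rbind, lapply(genes, function(g) {
    tr <- g$truth
    data.frame(gene = tr$gene, mode = tr$mode,
               hgt_taxon = tr$hgt_taxon %||% NA_character_,
               hgt_exits = isTRUE(tr$hgt_exits),
               paralog_taxa = paste(tr$paralog_taxa, collapse = ","),
               masked = paste(tr$masked, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(truth_df, files[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- unclass(config)
  cfg$gamma_shape <- cfg$gamma_shape %||% "none"
  writeLines(yaml::as.yaml(cfg), files[["config"]])
  for (g in seq_len(config$n_genes)) {
    nwk <- file.path(outdir, sprintf("gene_%02d.nwk", g))
    fa <- file.path(outdir, sprintf("gene_%02d.fasta", g))
    write_newick(genes[[g]]$tree, nwk)
    write_fasta_alignment(genes[[g]]$alignment, fa)
    files <- c(files, nwk, fa)
  }
  invisible(list(species = species$tree, clades = clades_full,
                 genes = genes, files = files))
}
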