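test_that("species trees are concordant ladders and seed-reproducible", {
  cfg <- sim_config(seed = 7, n_gloeo = 2, n_thermo = 2, n_higher = 2,
                    n_outgroup = 1)
  sp <- simulate_species_tree(cfg)
  expect_true(check_backbone(sp$tree, sp$clades)$concordant)
  sp2 <- simulate_species_tree(cfg)
  expect_identical(write_newick(sp$tree), write_newick(sp2$tree))
  # different seeds explore different within-clade topologies
  cfgs <- lapply(1:40, function(s) sim_config(seed = s, n_higher = 4))
  tops <- vapply(cfgs, function(cc) {
    t <- simulate_species_tree(cc)$tree
    ape::write.tree(ape::keep.tip(t, c("H01", "H02", "H03", "H04")))
  }, character(1))
  expect_gt(length(unique(tops)), 1)
})

test_that("zero-noise gene trees equal the species topology", {
  skip_if_not_installed("phangorn")
  cfg <- sim_config(seed = 11, p_nni = 0, p_hgt = 0)
  sp <- simulate_species_tree(cfg)
  for (g in 1:5) {
    gt <- simulate_gene_tree(sp, cfg, g)
    expect_equal(gt$truth$mode, "vertical")
    expect_equal(phangorn::RF.dist(gt$tree, sp$tree), 0)
  }
})

test_that("forced HGT from THERMO into HIGHER always breaks coherence", {
  cfg <- sim_config(seed = 13, p_hgt = 1, n_thermo = 4, n_higher = 5)
  sp <- simulate_species_tree(cfg)
  for (g in 1:10) {
    gt <- simulate_gene_tree(sp, cfg, g)
    expect_equal(gt$truth$mode, "hgt")
    expect_true(gt$truth$hgt_exits)
    res <- lineage_coherence(gt$tree, sp$clades, "THERMO",
                             gt$truth$hgt_taxon)
    expect_false(res$monophyletic)
    # the transplanted leaf sits inside the donor clade
    higher <- names(sp$clades)[sp$clades == "HIGHER"]
    expect_true(is_clade(gt$tree, c(higher, gt$truth$hgt_taxon)))
  }
})

test_that("duplication grafts a rate-accelerated monophyletic paralog clade", {
  cfg <- sim_config(seed = 17, paralog_rate_mult = 3)
  sp <- simulate_species_tree(cfg)
  ratios <- numeric(0)
  for (r in 1:100) {
    gt <- simulate_gene_tree(sp, cfg, r)
    d <- simulate_duplication(gt, cfg, sp$clades, seed = cfg$seed + r)
    expect_equal(length(d$tree$tip.label), length(gt$tree$tip.label) + 2)
    expect_true(is_clade(d$tree, d$truth$paralog_taxa))
    expect_setequal(unique(d$truth$labels[d$truth$paralog_taxa]), "paralog")
    # the copy's depth below the duplication point is the rate
    # multiplier times the host (ortholog) clade's depth there
    tr <- d$tree
    dd <- ape::node.depth.edgelength(tr)
    pm <- ape::getMRCA(tr, d$truth$paralog_taxa)
    graft <- tr$edge[tr$edge[, 2] == pm, 1]
    para_depth <- mean(dd[match(d$truth$paralog_taxa, tr$tip.label)]) -
      dd[graft]
    host <- names(sp$clades)[sp$clades != "OUTGROUP"]
    host_depth <- mean(dd[match(host, tr$tip.label)]) - dd[graft]
    ratios <- c(ratios, para_depth / host_depth)
  }
  expect_lt(abs(mean(ratios) - 3), 0.15)
  expect_true(all(abs(ratios - 3) < 0.05 * 3 + 0.1))
})

test_that("sequence divergence follows the Poisson-model saturation curve", {
  for (t in c(0.05, 0.2, 0.5)) {
    cfg <- sim_config(seed = 19 + round(100 * t), seq_length = 10000L)
    tree <- read_newick(sprintf("(A:%g,B:%g);", t, t))
    aln <- evolve_sequences(tree, cfg, NULL)
    a <- strsplit(aln[["A"]], "")[[1]]
    b <- strsplit(aln[["B"]], "")[[1]]
    free <- setdiff(seq_len(cfg$seq_length), cfg$motif_positions)
    obs <- mean(a[free] != b[free])
    expected <- (19 / 20) * (1 - exp(-(20 / 19) * 2 * t))
    se <- sqrt(expected * (1 - expected) / length(free))
    expect_lt(abs(obs - expected), 3 * se)
  }
})

test_that("zero total tree length leaves all sequences at the root state", {
  cfg <- sim_config(seed = 23, seq_length = 60,
                    motif_positions = c(10L, 12L, 14L, 15L))
  tree <- read_newick("((A:0,B:0):0,(C:0,D:0):0);")
  aln <- evolve_sequences(tree, cfg, NULL)
  expect_length(unique(unname(aln)), 1)
})

test_that("paralog motif degradation holds in every replicate", {
  cfg <- sim_config(seed = 29, seq_length = 200)
  sp <- simulate_species_tree(cfg)
  for (r in 1:20) {
    gt <- simulate_gene_tree(sp, cfg, r)
    d <- simulate_duplication(gt, cfg, sp$clades, seed = cfg$seed + r)
    aln <- evolve_sequences(d$tree, cfg, d$truth, seed = cfg$seed + 500L + r)
    spec <- lxnxlr_spec(setdiff(names(aln), d$truth$paralog_taxa)[1],
                        cfg$motif_positions)
    lacks <- attr(score_motif(aln, spec), "lacks_ge2")
    expect_true(all(lacks[d$truth$paralog_taxa]))
    expect_false(any(lacks[setdiff(names(aln), d$truth$paralog_taxa)]))
  }
})

test_that("generated datasets have the right shape and missingness", {
  cfg <- sim_config(seed = 31, n_genes = 30, missingness = 0.3)
  out <- generate_dataset(cfg, file.path(tempdir(), "simshape"))
  expect_length(out$genes, 30)
  n_taxa <- length(out$species$tip.label)
  kept <- vapply(out$genes, function(g) length(g$tree$tip.label),
                 numeric(1))
  # mean retained fraction within binomial tolerance of 0.7
  p_hat <- mean(kept) / n_taxa
  se <- sqrt(0.3 * 0.7 / (30 * n_taxa))
  expect_lt(abs(p_hat - 0.7), 4 * se)
  # alignments and trees agree on taxa
  for (g in out$genes[1:5])
    expect_setequal(names(g$alignment), g$tree$tip.label)
})

test_that("dataset generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 37, n_genes = 4, p_hgt = 0.3,
                    p_duplication = 0.5, p_nni = 0.1, missingness = 0.2)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e7),
                     readBin(file.path(d2, f), "raw", n = 1e7))
  # and a different seed changes the draw
  cfg2 <- sim_config(seed = 38, n_genes = 4, p_hgt = 0.3,
                     p_duplication = 0.5, p_nni = 0.1, missingness = 0.2)
  d3 <- file.path(tempdir(), "det3")
  generate_dataset(cfg2, d3)
  expect_false(identical(
    readLines(file.path(d1, "species.nwk")),
    readLines(file.path(d3, "species.nwk"))))
})

test_that("NNI noise perturbs topology but keeps the leaf set", {
  skip_if_not_installed("phangorn")
  cfg <- sim_config(seed = 41, p_nni = 0.5)
  sp <- simulate_species_tree(cfg)
  rf <- vapply(1:10, function(g) {
    gt <- simulate_gene_tree(sp, cfg, g)
    expect_setequal(gt$tree$tip.label, sp$tree$tip.label)
    phangorn::RF.dist(gt$tree, sp$tree)
  }, numeric(1))
  expect_gt(sum(rf), 0)
})
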