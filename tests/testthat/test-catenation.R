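random_protein2 <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

make_reference <- function(n = 5, len = 140) {
  set.seed(101)
  data.frame(id = sprintf("P%02d", seq_len(n)),
             sequence = vapply(seq_len(n), function(i)
               random_protein2(len + i), character(1)),
             stringsAsFactors = FALSE)
}

test_that("presence states: complete, truncated, absent, length filter", {
  ref <- make_reference(3)
  ref$sequence[3] <- substr(ref$sequence[3], 1, 100)  # below min_length
  asm <- rbind(
    data.frame(id = "full1", assembly = "good",
               sequence = ref$sequence[1]),
    data.frame(id = "full2", assembly = "good",
               sequence = ref$sequence[2]),
    data.frame(id = "halved", assembly = "frag",
               sequence = substr(ref$sequence[1], 1, 70)))
  pm <- build_presence_matrix(ref, asm, min_length = 128)
  expect_equal(rownames(pm), c("P01", "P02"))  # P03 filtered out
  expect_equal(pm["P01", "good"], "complete")
  expect_equal(pm["P02", "good"], "complete")
  expect_equal(pm["P01", "frag"], "partial")
  expect_equal(pm["P02", "frag"], "absent")
  expect_error(build_presence_matrix(ref, asm, min_length = 1000),
               class = "concord_bad_input")
})

test_that("a synthetic MAG retaining 4 of 23 proteins shows 4 complete", {
  set.seed(103)
  ref <- data.frame(id = sprintf("R%02d", 1:23),
                    sequence = vapply(1:23, function(i)
                      random_protein2(130), character(1)))
  keep <- sample(23, 4)
  asm <- data.frame(id = ref$id[keep], assembly = "mag",
                    sequence = ref$sequence[keep])
  pm <- build_presence_matrix(ref, asm)
  expect_equal(sum(pm[, "mag"] == "complete"), 4)
})

test_that("catenation design: all-complete, disjoint, universal protein", {
  mk <- function(m, lens) structure(
    m, class = c("presence_matrix", "matrix"),
    lengths = stats::setNames(lens, rownames(m)),
    params = list())
  full <- mk(matrix("complete", 3, 2,
                    dimnames = list(c("a", "b", "c"), c("x", "y"))),
             c(150, 140, 130))
  plan <- design_catenations(full, list(c("x", "y")))[[1]]
  expect_true(plan$usable)
  expect_setequal(plan$proteins, c("a", "b", "c"))
  expect_setequal(plan$assemblies, c("x", "y"))
  # greedy order is deterministic: ties broken by length then name
  expect_equal(plan$proteins, c("a", "b", "c"))

  # two assemblies with disjoint complete sets -> two disjoint plans
  disj <- mk(matrix(c("complete", "complete", "absent", "absent",
                      "absent", "absent", "complete", "complete"),
                    4, 2, dimnames = list(c("p1", "p2", "p3", "p4"),
                                          c("x", "y"))),
             c(150, 140, 130, 120))
  plans <- design_catenations(disj, list("x", "y"))
  expect_setequal(plans[[1]]$proteins, c("p1", "p2"))
  expect_setequal(plans[[2]]$proteins, c("p3", "p4"))
  expect_length(intersect(plans[[1]]$proteins, plans[[2]]$proteins), 0)

  # a universally complete protein appears in every usable plan
  uni <- mk(matrix(c("complete", "complete", "complete",
                     "complete", "absent", "complete"),
                   3, 2, dimnames = list(c("u", "v", "w"), c("x", "y"))),
            c(150, 140, 130))
  plans2 <- design_catenations(uni, list("x", "y", c("x", "y")))
  for (p in plans2) expect_true("u" %in% p$proteins)

  # no protein complete in all required -> unusable with diagnostic
  bad <- design_catenations(disj, list(c("x", "y")))[[1]]
  expect_false(bad$usable)
  expect_match(bad$diagnostic, "complete in all required")
})

test_that("removing a required assembly never shrinks the protein pool", {
  set.seed(107)
  for (i in 1:10) {
    m <- matrix(sample(c("complete", "partial", "absent"), 24, TRUE,
                       prob = c(0.6, 0.2, 0.2)),
                6, 4, dimnames = list(paste0("p", 1:6), paste0("a", 1:4)))
    pm <- structure(m, class = c("presence_matrix", "matrix"),
                    lengths = stats::setNames(rep(130, 6), paste0("p", 1:6)),
                    params = list())
    req <- c("a1", "a2")
    p_both <- design_catenations(pm, list(req))[[1]]
    p_one <- design_catenations(pm, list("a1"))[[1]]
    expect_true(all(p_both$proteins %in% p_one$proteins))
  }
})

test_that("concatenation tiles partitions and follows plan order", {
  alns <- list(
    A = c(x = "AAAAAAAAAA", y = "CCCCCCCCCC"),
    B = c(x = "DDDDDDDDDDDDDDD", y = "EEEEEEEEEEEEEEE"))
  plan <- list(proteins = c("A", "B"), assemblies = c("x", "y"))
  out <- concatenate_alignments(alns, plan)
  expect_equal(out$partitions$start, c(1, 11))
  expect_equal(out$partitions$end, c(10, 25))
  expect_equal(nchar(out$alignment[["x"]]), 25)
  # tiling invariant
  expect_equal(out$partitions$start[-1], utils::head(out$partitions$end, -1) + 1)
  # order comes from the plan, not the list
  out2 <- concatenate_alignments(rev(alns), plan)
  expect_identical(out2$alignment, out$alignment)
  # single-protein plan is the identity
  one <- concatenate_alignments(alns, list(proteins = "A",
                                           assemblies = c("x", "y")))
  expect_identical(one$alignment, alns$A[c("x", "y")])
  # missing sequence is a hard, named error
  expect_error(
    concatenate_alignments(alns, list(proteins = c("A", "B"),
                                      assemblies = c("x", "z"))),
    "assembly z", class = "concord_missing_sequence")
})

test_that("partition and PHYLIP writers emit the expected formats", {
  alns <- list(A = c(x = "AAAA", y = "CCCC"), B = c(x = "DD", y = "EE"))
  out <- concatenate_alignments(alns, list(proteins = c("A", "B"),
                                           assemblies = c("x", "y")))
  pf <- tempfile(); write_partition_file(out$partitions, pf)
  expect_equal(readLines(pf), c("PROT, A = 1-4", "PROT, B = 5-6"))
  ph <- tempfile(); write_phylip(out$alignment, ph)
  lines <- readLines(ph)
  expect_equal(lines[1], "2 6")
  expect_equal(lines[2], "x AAAADD")
})
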