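# Independent brute-force oracles used across the suite.  These share
# no code with the package internals beyond ape's basic tree container.

# --- tree utilities ---------------------------------------------------

# descendant tip labels of every node, by naive edge recursion
oracle_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  lapply((n + 1L):(n + tree$Nnode), below)
}

# monophyly by exhaustive enumeration of node leaf sets
oracle_monophyletic <- function(tree, taxa) {
  if (length(taxa) <= 1L) return(TRUE)
  any(vapply(oracle_tip_sets(tree),
             function(s) setequal(s, taxa), logical(1)))
}

# canonical split key, reimplemented (side not holding the min leaf)
oracle_key <- function(taxa, all_taxa) {
  ref <- min(all_taxa)
  side <- if (ref %in% taxa) setdiff(all_taxa, taxa) else taxa
  paste(sort(side), collapse = " ")
}

# nontrivial splits of a tree by enumerating node leaf sets
oracle_splits <- function(tree) {
  labs <- tree$tip.label
  sets <- oracle_tip_sets(tree)
  keep <- vapply(sets, function(s)
    length(s) >= 2L && length(s) <= length(labs) - 2L, logical(1))
  unique(vapply(sets[keep], oracle_key, character(1), all_taxa = labs))
}

# projection of a split set onto a taxon subset (trivial splits removed)
oracle_project_splits <- function(tree, keep_taxa) {
  labs <- tree$tip.label
  sets <- oracle_tip_sets(tree)
  out <- character(0)
  for (s in sets) {
    a <- intersect(s, keep_taxa)
    b <- setdiff(keep_taxa, a)
    if (length(a) >= 2L && length(b) >= 2L)
      out <- c(out, oracle_key(a, keep_taxa))
  }
  unique(out)
}

# random clade map over a tree's tips covering all three backbone labels
random_clade_map <- function(tree, labels = c("GLOEO", "THERMO", "HIGHER")) {
  tips <- tree$tip.label
  repeat {
    cm <- sample(labels, length(tips), replace = TRUE)
    if (all(labels %in% cm)) break
  }
  stats::setNames(cm, tips)
}

# backbone constraint check written directly against ape primitives
oracle_backbone_ok <- function(rooted, cm,
                               lineages = c("GLOEO", "THERMO", "HIGHER")) {
  tips <- rooted$tip.label
  for (i in 2:length(lineages)) {
    taxa <- tips[cm[tips] %in% lineages[i:length(lineages)]]
    if (length(taxa) == 0L || length(taxa) == length(tips)) next
    if (!oracle_monophyletic(rooted, taxa)) return(FALSE)
  }
  TRUE
}

# all concordant rootings of an unrooted tree by explicit reroot+check
oracle_concordant_rootings <- function(ut, cm) {
  labs <- ut$tip.label
  n <- length(labs)
  sides <- lapply(seq_len(nrow(ut$edge)), function(i) {
    child <- ut$edge[i, 2]
    if (child <= n) labs[child]
    else {
      below <- function(node) {
        if (node <= n) return(labs[node])
        kids <- ut$edge[ut$edge[, 1] == node, 2]
        unlist(lapply(kids, below))
      }
      below(child)
    }
  })
  keys <- unique(vapply(sides, oracle_key, character(1), all_taxa = labs))
  ok <- vapply(keys, function(k) {
    side <- strsplit(k, " ", fixed = TRUE)[[1]]
    og <- if (length(side) == n - 1L) setdiff(labs, side) else side
    rooted <- ape::root(ut, outgroup = og, resolve.root = TRUE)
    oracle_backbone_ok(rooted, cm)
  }, logical(1))
  sort(unname(keys[ok]))
}

# --- alignment oracle -------------------------------------------------

# Gotoh global alignment with affine gaps under BLOSUM62, with pointer
# matrices recorded during the fill.  Returns the optimal score, the
# number of co-optimal alignments, and the percent identity (over
# aligned residue pairs) of one optimal alignment; identity is only
# well-defined when the optimum is unique.  Gap of length k costs
# gap_open + k * gap_ext.
oracle_global_identity <- function(a, b, gap_open = 11, gap_ext = 1) {
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); E <- M; F_ <- M
  pM <- matrix(0L, n + 1, m + 1); pE <- pM; pF <- pM  # 1=M, 2=E, 3=F
  cM <- matrix(0, n + 1, m + 1); cE <- cM; cF <- cM   # co-optimal counts
  M[1, 1] <- 0; cM[1, 1] <- 1
  for (i in 2:(n + 1)) {
    F_[i, 1] <- -(gap_open + (i - 1) * gap_ext)
    pF[i, 1] <- if (i == 2) 1L else 3L
    cF[i, 1] <- 1
  }
  for (j in 2:(m + 1)) {
    E[1, j] <- -(gap_open + (j - 1) * gap_ext)
    pE[1, j] <- if (j == 2) 1L else 2L
    cE[1, j] <- 1
  }
  argmax_all <- function(v) which(v == max(v))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[x[i - 1], y[j - 1]]
      cand <- c(M[i - 1, j - 1], E[i - 1, j - 1], F_[i - 1, j - 1])
      amax <- argmax_all(cand)
      pM[i, j] <- amax[1L]
      M[i, j] <- cand[amax[1L]] + s
      cM[i, j] <- sum(c(cM[i - 1, j - 1], cE[i - 1, j - 1],
                        cF[i - 1, j - 1])[amax])
      candE <- c(M[i, j - 1] - gap_open - gap_ext, E[i, j - 1] - gap_ext,
                 F_[i, j - 1] - gap_open - gap_ext)
      amax <- argmax_all(candE)
      pE[i, j] <- amax[1L]
      E[i, j] <- candE[amax[1L]]
      cE[i, j] <- sum(c(cM[i, j - 1], cE[i, j - 1], cF[i, j - 1])[amax])
      candF <- c(M[i - 1, j] - gap_open - gap_ext,
                 E[i - 1, j] - gap_open - gap_ext, F_[i - 1, j] - gap_ext)
      amax <- argmax_all(candF)
      pF[i, j] <- amax[1L]
      F_[i, j] <- candF[amax[1L]]
      cF[i, j] <- sum(c(cM[i - 1, j], cE[i - 1, j], cF[i - 1, j])[amax])
    }
  }
  i <- n + 1; j <- m + 1
  finals <- c(M[i, j], E[i, j], F_[i, j])
  best <- max(finals)
  n_opt <- sum(c(cM[i, j], cE[i, j], cF[i, j])[argmax_all(finals)])
  state <- which.max(finals)
  matches <- 0L; pairs <- 0L
  while (i > 1 || j > 1) {
    if (state == 1L) {
      pairs <- pairs + 1L
      if (x[i - 1] == y[j - 1]) matches <- matches + 1L
      state <- pM[i, j]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      state <- pE[i, j]; j <- j - 1
    } else {
      state <- pF[i, j]; i <- i - 1
    }
  }
  list(score = best, n_optimal = n_opt,
       identity_pct = if (pairs == 0L) 0 else 100 * matches / pairs)
}

# optimal global alignment score as computed by Biostrings itself
bio_global_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = B, gapOpening = gap_open, gapExtension = gap_ext,
    type = "global"))
}

# --- consensus oracle -------------------------------------------------

# majority-rule clade counter for rooted trees on equal taxon sets
oracle_majority_clades <- function(trees) {
  all_taxa <- sort(trees[[1]]$tip.label)
  counts <- list()
  for (tr in trees) {
    sets <- oracle_tip_sets(tr)
    for (s in sets) {
      if (length(s) < 2L || length(s) == length(all_taxa)) next
      k <- paste(sort(s), collapse = " ")
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  names(counts)[vapply(counts, function(x) x > length(trees) / 2,
                       logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# correlated rooted gene trees: base topology disturbed by k random NNIs
perturbed_trees <- function(base, n_trees, moves) {
  lapply(seq_len(n_trees), function(i) {
    tr <- base
    if (moves > 0) tr <- phangorn::rNNI(base, moves = moves)
    ape::root(ape::unroot(tr), outgroup = base$tip.label[1],
              resolve.root = TRUE)
  })
}
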