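test_that("pairwise distances match closed forms with pairwise deletion", {
  aln <- protein_alignment(c(a = "AAAA", b = "AAAT", c = "AAAA"))
  d <- p_distance(aln, "p")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(p_distance(aln, "poisson")["a", "b"], -log(0.75))

  gapped <- protein_alignment(c(a = "AA-A", b = "AAT-"))
  expect_equal(p_distance(gapped)["a", "b"], 0)   # only columns 1-2 compared

  nt <- codon_alignment(c(a = "ATGAAA", b = "ATGAAT"))
  expect_equal(p_distance(nt, "jc")["a", "b"],
               -0.75 * log(1 - 4 * (1 / 6) / 3))
  sat <- protein_alignment(c(a = "AAAA", b = "CCCC"))
  expect_warning(dp <- p_distance(sat, "poisson"), "saturated")
  expect_identical(dp["a", "b"], Inf)
})

test_that("distance implementation agrees with ape on related sequences", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 2, n_g1 = 2, n_g2 = 2,
                                             n_codons = 120, seed = 8))
  aln <- sim$alignment
  ours <- p_distance(aln, "jc")
  bin <- ape::as.DNAbin(strsplit(apply(unclass(aln), 1, paste, collapse = ""),
                                 ""))
  theirs <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                    pairwise.deletion = TRUE))
  expect_equal(ours, theirs[rownames(ours), colnames(ours)],
               tolerance = 1e-10)
})

test_that("neighbor joining recovers additive trees exactly", {
  # the classic 4-taxon case with known branch lengths
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  d <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(d)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # random additive matrices, n <= 8, against the generating path lengths
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    ra <- random_additive(n, seed)
    nj <- neighbor_joining(ra$d)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(nj), ra$tree), 0,
                 ignore_attr = TRUE)
  }
})

test_that("neighbor joining matches ape::nj on random additive matrices", {
  for (seed in 26:30) {
    ra <- random_additive(7, seed)
    ours <- neighbor_joining(ra$d)
    theirs <- ape::nj(ra$d)
    expect_equal(ape::dist.topo(ours, theirs), 0, ignore_attr = TRUE)
  }
})

test_that("three-taxon trees solve the three-point formula", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nj <- neighbor_joining(d)
  lens <- setNames(nj$edge.length, nj$tip.label[nj$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("degenerate equidistant matrices give zero internal branches", {
  d <- matrix(1, 5, 5) - diag(5)
  dimnames(d) <- list(letters[1:5], letters[1:5])
  nj <- neighbor_joining(d)
  internal <- nj$edge[, 2] > length(nj$tip.label)
  expect_true(all(abs(nj$edge.length[internal]) < 1e-12))
})

test_that("bootstrap support behaves at the limits and finds planted clades", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 3, n_g1 = 3, n_g2 = 3,
                                             n_codons = 120, seed = 21))
  aa <- translate_codons(sim$alignment, permissive = TRUE)
  b1 <- bootstrap_nj(aa, n_reps = 1, seed = 1)
  expect_true(all(b1$node.support[!is.na(b1$node.support)] %in% c(0, 100)))

  b <- bootstrap_nj(aa, n_reps = 100, seed = 7)
  # the branch separating the two planted focal groups is strongly supported
  key_groups <- split(names(sim$groups), sim$groups)
  parts <- ape::prop.part(b)
  labs <- attr(parts, "labels")
  found <- FALSE
  for (p in parts) {
    side <- labs[p]
    if (setequal(side, c(key_groups$g1, key_groups$g2)) ||
        setequal(side, key_groups$bg)) {
      found <- TRUE
      idx <- which(vapply(parts, function(q) setequal(labs[q], side), TRUE))[1]
      expect_gte(b$node.support[idx], 95)
    }
  }
  expect_true(found)

  ident <- protein_alignment(c(a = "MKVL", b = "MKVL", c = "MKVL",
                               d = "MKVL"))
  bi <- bootstrap_nj(ident, n_reps = 20, seed = 3, collapse = 70)
  expect_lt(bi$Nnode, length(bi$tip.label) - 1)     # collapsed to a star
})

test_that("bootstrap supports are invariant to taxon input order", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 2, n_g1 = 3, n_g2 = 2,
                                             n_codons = 90, seed = 33))
  aa <- translate_codons(sim$alignment, permissive = TRUE)
  b1 <- bootstrap_nj(aa, n_reps = 30, seed = 5)
  perm <- protein_alignment(unclass(aa)[rev(rownames(aa)), ])
  b2 <- bootstrap_nj(perm, n_reps = 30, seed = 5)
  key <- function(b) {
    sup <- b$node.support
    names(sup) <- vapply(seq_len(b$Nnode), function(i) {
      tips <- ape::extract.clade(b, length(b$tip.label) + i)$tip.label
      paste(sort(tips), collapse = ",")
    }, "")
    sort(sup[!is.na(sup)])
  }
  expect_equal(unname(key(b1)), unname(key(b2)))
})

test_that("clade labeling enforces monophyly and labels whole subtrees", {
  tr <- read_newick(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  lab <- label_clades(tr, c(a = 0, b = 0, c = 1, d = 1))
  tips_part <- lab$edge.partition[match(1:4, lab$edge[, 2])]
  names(tips_part) <- tr$tip.label
  expect_identical(tips_part, c(a = 0L, b = 0L, c = 1L, d = 1L))
  expect_identical(sum(lab$edge.partition == 1L), 3L)  # c, d, and their stem

  all_bg <- label_clades(tr, c(a = 0, b = 0, c = 0, d = 0))
  expect_true(all(all_bg$edge.partition == 0L))

  expect_error(label_clades(tr, c(a = 1, b = 0, c = 1, d = 0)),
               "not monophyletic")
})
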