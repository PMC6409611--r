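test_that("RSCU matches hand counts and definitional limits", {
  # TTT x2, TTC x1: two-codon Phe family
  v <- rscu("TTTTTTTTC")
  expect_equal(v[["TTT"]], 4 / 3)
  expect_equal(v[["TTC"]], 2 / 3)
  # every synonymous codon used once -> all RSCU 1 for used families
  all_once <- paste(cladiv:::RSCU_CODONS, collapse = "")
  v1 <- rscu(all_once)
  expect_true(all(abs(v1 - 1) < 1e-12))
  # single codon of a 4-codon family
  v4 <- rscu("GGG")
  expect_equal(v4[["GGG"]], 4)
  expect_true(all(v4[c("GGA", "GGC", "GGT")] == 0))
  expect_true("G" %in% setdiff(names(table(attr(v4, "counts"))), NA) ||
              length(attr(v4, "absent_aa")) > 0)
  expect_error(rscu("TTTT"), "multiple of 3")
})

test_that("per-family RSCU sums equal family sizes exactly", {
  fam <- split(cladiv:::RSCU_CODONS, cladiv:::SENSE_AA[cladiv:::RSCU_CODONS])
  for (seed in 1:5) {
    aln <- random_codon_aln(1, 200, seed)
    v <- rscu(apply(unclass(aln), 1, paste, collapse = "")[[1]])
    for (aa in names(fam)) {
      s <- sum(v[fam[[aa]]])
      if (s > 0) expect_equal(s, length(fam[[aa]]), tolerance = 1e-12)
    }
  }
})

test_that("the RSCU matrix keeps the fixed 59-codon contract", {
  aln <- random_codon_aln(6, 120, seed = 3)
  m <- rscu_matrix(aln)
  expect_identical(ncol(m), 59L)
  expect_false(any(c("ATG", "TGG", cladiv:::STOP_CODONS) %in% colnames(m)))
  # identical taxa give identical rows
  dup <- codon_alignment(setNames(rep(apply(unclass(aln), 1, paste,
                                            collapse = "")[1], 2),
                                  c("x", "y")))
  md <- rscu_matrix(dup)
  expect_equal(md["x", ], md["y", ])
  # whole-alignment region equals the no-region call
  expect_equal(unclass(rscu_matrix(aln, 0, ncol(aln))), unclass(m))
  # gaps are skipped
  g <- codon_alignment(c(x = "TTT---TTC", y = "TTTTTCTTC"),
                       permissive = TRUE)
  mg <- rscu_matrix(g)
  expect_equal(mg["x", "TTT"], 1)
})

test_that("correspondence analysis reproduces closed-form cases", {
  # identical rows: independence, zero inertia, all points at the origin
  x <- matrix(rep(c(3, 1, 2, 6), 4), 4, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), paste0("c", 1:4)))
  ca <- correspondence_analysis(x)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(abs(ca$row_coords) < 1e-8))

  # 2x2 diagonal table: one dimension carrying all inertia, opposite signs
  d <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("a", "b"), c("u", "v")))
  cd <- correspondence_analysis(d)
  expect_equal(cd$inertia[1], 1)
  expect_equal(cd$total_inertia, 1)            # chi-square 20 / total 20
  expect_lt(cd$row_coords[1, 1] * cd$row_coords[2, 1], 0)

  expect_error(correspondence_analysis(matrix(-1, 2, 2)), "non-negative")
})

test_that("CA total inertia equals the chi-square statistic over the total", {
  set.seed(7)
  x <- matrix(rpois(48, 8) + 1, 6, 8,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:8)))
  ca <- correspondence_analysis(x)
  chi2 <- suppressWarnings(stats::chisq.test(x))$statistic
  expect_equal(ca$total_inertia, unname(chi2) / sum(x), tolerance = 1e-10)
})

test_that("CA embeddings preserve chi-square distances and row-order symmetry", {
  set.seed(11)
  x <- matrix(rpois(30, 10) + 1, 5, 6,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:6)))
  ca <- correspondence_analysis(x)
  # full-rank embedding distances equal chi-square distances of row profiles
  P <- x / sum(x)
  prof <- P / rowSums(P)
  cc <- colSums(P)
  chid <- as.matrix(stats::dist(prof %*% diag(1 / sqrt(cc))))
  emb <- as.matrix(stats::dist(ca$row_coords_full))
  expect_equal(emb, chid, tolerance = 1e-8, ignore_attr = TRUE)
  # row permutation only permutes (and possibly flips) coordinates
  ca2 <- correspondence_analysis(x[c(3, 1, 5, 2, 4), ])
  d1 <- as.matrix(stats::dist(ca$row_coords))
  d2 <- as.matrix(stats::dist(ca2$row_coords))[rownames(d1), colnames(d1)]
  expect_equal(d2, d1, tolerance = 1e-8)
  # scaling the table leaves coordinates unchanged
  ca3 <- correspondence_analysis(x * 7)
  expect_equal(abs(ca3$row_coords), abs(ca$row_coords), tolerance = 1e-8)
})

test_that("CA agrees with the MASS implementation", {
  skip_if_not_installed("MASS")
  set.seed(13)
  x <- matrix(rpois(40, 6) + 1, 5, 8,
              dimnames = list(paste0("r", 1:5), paste0("c", 1:8)))
  ca <- correspondence_analysis(x)
  mc <- MASS::corresp(x, nf = 2)
  # MASS returns standard coordinates; principal = standard x singular value
  for (k in 1:2) {
    ours <- ca$row_coords[, k]
    theirs <- mc$rscore[, k] * mc$cor[k]
    expect_lt(min(max(abs(ours - theirs)), max(abs(ours + theirs))), 1e-8)
  }
})

test_that("group separation scores planted codon bias and rejects misuse", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 2, n_g1 = 10, n_g2 = 2,
                                             n_codons = 150,
                                             omega2 = c(1, 1, 1), seed = 51))
  focal <- names(sim$groups)[sim$groups == "g1"]
  sub <- codon_alignment(unclass(sim$alignment)[focal, ], permissive = TRUE)
  set.seed(51)
  groups <- setNames(sample(rep(c("g1", "g2"), 5)), focal)
  prefs <- opposite_preferences(c("g1", "g2"))
  biased <- plant_codon_bias(sub, groups, strength = 0.8, seed = 1,
                             preferences = prefs)
  ca_b <- correspondence_analysis(rscu_matrix(biased))
  sep_b <- group_separation(ca_b, groups)
  expect_gt(sep_b$silhouette, 0.5)
  expect_identical(nrow(sep_b$centroids), 2L)
  expect_error(group_separation(ca_b, setNames(rep("g", length(focal)), focal)),
               "at least 2 groups")
  # degenerate embedding: identical rows in both groups
  same <- codon_alignment(setNames(rep("TTTTTCGGA", 4),
                                   c("p1", "p2", "q1", "q2")))
  ca_same <- correspondence_analysis(rscu_matrix(same))
  sep0 <- group_separation(ca_same, c(p1 = "p", p2 = "p", q1 = "q", q2 = "q"))
  expect_true(sep0$degenerate)
  expect_equal(sep0$silhouette, 0)
})
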