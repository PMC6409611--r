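test_that("consensus picks the modal residue with alphabetical ties", {
  aln <- protein_alignment(c(s1 = "AAT", s2 = "AAT", s3 = "ATA", s4 = "TTA"))
  cp <- consensus_profile(aln)
  expect_identical(cp$consensus[1], "A")
  expect_equal(cp$frequency[1], 0.75)
  expect_identical(cp$consensus[2], "A")       # A vs T tie -> alphabetical
  expect_equal(cp$frequency[2], 0.5)
  gap <- protein_alignment(c(s1 = "A-", s2 = "A-"))
  cg <- consensus_profile(gap)
  expect_identical(cg$consensus[2], "-")
  expect_equal(cg$frequency[2], 0)
  ident <- protein_alignment(c(a = "MKV", b = "MKV"))
  expect_true(all(consensus_profile(ident)$frequency == 1))
})

test_that("signature matrix tokens follow the consensus/gap/residue rule", {
  aln <- two_group_protein(5, 3, 100, between = 0.03, within = 0, seed = 5)
  sig <- signature_matrix(aln)
  ident_rows <- rownames(sig)[1:5]                  # majority group == consensus
  expect_true(all(sig[ident_rows, ] == "."))
  expect_identical(sum(sig["b1", ] != "."), 3L)

  gapped <- protein_alignment(c(x = "MK-", y = "MK-", z = "MKV"))
  sg <- signature_matrix(gapped)
  expect_identical(unname(sg[c("x", "y"), 3]), c("-", "-"))
  expect_false(is.null(attr(sig, "colors")))
  expect_error(signature_matrix(aln, leaf_order = c("a1", "a2")),
               "permutation")
})

test_that("proteotype calling implements the 10% divergence rule", {
  ident <- protein_alignment(c(a = "MKVL", b = "MKVL", c = "MKVL"))
  expect_identical(call_proteotypes(ident)$n_proteotypes, 1L)

  aln <- two_group_protein(6, 4, 100, between = 0.20, within = 0.02, seed = 9)
  pt <- call_proteotypes(aln, threshold = 0.10)
  expect_identical(pt$n_proteotypes, 2L)
  # larger group gets id 1
  expect_true(all(pt$proteotype[paste0("a", 1:6)] == 1L))
  expect_true(all(pt$proteotype[paste0("b", 1:4)] == 2L))
  expect_identical(call_proteotypes(aln, threshold = 1.0)$n_proteotypes, 1L)
})

test_that("proteotype calls are invariant to row and column order", {
  aln <- two_group_protein(5, 5, 80, between = 0.3, within = 0.03, seed = 13)
  pt <- call_proteotypes(aln)
  m <- unclass(aln)
  perm_rows <- protein_alignment(m[sample(nrow(m)), ])
  perm_cols <- protein_alignment(m[, sample(ncol(m))])
  expect_identical(call_proteotypes(perm_rows)$proteotype[names(pt$proteotype)],
                   pt$proteotype)
  expect_identical(call_proteotypes(perm_cols)$proteotype, pt$proteotype)
})

test_that("the number of proteotypes is non-increasing in the threshold", {
  aln <- two_group_protein(5, 5, 80, between = 0.25, within = 0.05, seed = 17)
  counts <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.5, 1.0),
                   function(th) call_proteotypes(aln, th)$n_proteotypes, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("intergroup identity summarizes cross-group percent identity", {
  ident <- protein_alignment(c(a = "MKVLMKVLMK", b = "MKVLMKVLMK"))
  res <- intergroup_identity(ident, c(a = 1L, b = 2L), 1, 2)
  expect_equal(unlist(res[c("mean", "min", "max")]),
               c(mean = 100, min = 100, max = 100))

  # two 10-column groups sharing exactly 6 residues per cross pair
  aln <- protein_alignment(c(a1 = "MKVLDESTAG", a2 = "MKVLDESTAG",
                             b1 = "MKVLDEWYCH", b2 = "MKVLDEWYCH"))
  res <- intergroup_identity(aln, c(a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L), 1, 2)
  expect_equal(res$mean, 60.0)

  disjoint <- protein_alignment(c(a = "AAAA", b = "CCCC"))
  expect_equal(intergroup_identity(disjoint, c(a = 1L, b = 2L), 1, 2)$mean, 0)
})

test_that("assortment tables order regions and flag co-membership changes", {
  # mirrors a recombination narrative: x and y share a proteotype for the
  # early regions, then part ways after region 2
  regions <- list(
    e1a  = c(x = 1L, y = 1L, z = 2L),
    hvl1 = c(x = 1L, y = 1L, z = 1L),
    hvl2 = c(x = 2L, y = 1L, z = 1L),
    hexon = c(x = 1L, y = 2L, z = 2L))
  tab <- assortment_table(regions)
  expect_identical(colnames(tab), names(regions))
  expect_identical(unname(tab["x", ]), c(1L, 1L, 2L, 1L))

  # x and y share ids through hvl1, then differ from hvl2 on: one boundary
  bp <- assortment_breakpoints(tab, "x", "y")
  expect_identical(bp$from, "hvl1")
  expect_identical(bp$to, "hvl2")
  # alternating share/differ pattern across four regions: three boundaries
  alt <- assortment_table(list(r1 = c(u = 1L, v = 1L), r2 = c(u = 1L, v = 2L),
                               r3 = c(u = 1L, v = 1L), r4 = c(u = 1L, v = 2L)))
  expect_identical(nrow(assortment_breakpoints(alt, "u", "v")), 3L)

  same <- assortment_table(list(r1 = c(x = 1L, y = 1L), r2 = c(x = 1L, y = 1L)))
  expect_identical(nrow(assortment_breakpoints(same, "x", "y")), 0L)
  never <- assortment_table(list(r1 = c(x = 1L, y = 2L), r2 = c(x = 1L, y = 2L)))
  expect_identical(nrow(assortment_breakpoints(never, "x", "y")), 0L)
  expect_error(assortment_table(list(r1 = c(x = 1L), r2 = c(y = 1L))),
               "same taxon set")
  expect_error(assortment_breakpoints(tab, "x", "nope"), "unknown taxon")
})

test_that("single-region assortment equals its assignment and anchors sort rows", {
  one <- assortment_table(list(e1a = c(x = 2L, y = 1L, z = 1L)), anchor = "e1a")
  expect_identical(unname(one[, "e1a"]), c(1L, 1L, 2L))  # sorted by anchor id
  expect_identical(rownames(one), c("y", "z", "x"))
})
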