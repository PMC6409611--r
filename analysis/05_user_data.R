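#!/usr/bin/env Rscript
# Stage 5 (optional): run the identical analysis chain on user-supplied
# sequences instead of simulated data.
#
# Reproducing the published full-data numbers (ln-likelihoods, kappa, the
# inter-clade CR3 identity, the proteotype memberships) requires the
# GenBank E1A sequences, which are not redistributed here. Supply:
#
#   data/user/codon_alignment.fasta   in-frame codon alignment (13S CDS)
#   data/user/tree.nwk                unrooted tree with branch lengths
#   data/user/partitions.tsv          columns: taxon, null_partition,
#                                     alt_partition (0 = background)
#   data/user/regions.tsv             columns: name, start, end
#                                     (nucleotide columns, 0-based,
#                                     half-open; include a "cr3" row)
#
# and run: Rscript analysis/05_user_data.R

suppressMessages(library(cladiv))

indir <- "data/user"
out <- "results/user_data"
need <- file.path(indir, c("codon_alignment.fasta", "tree.nwk",
                           "partitions.tsv", "regions.tsv"))
if (!all(file.exists(need))) {
  cat("User data not found under", indir, "- nothing to do.\n")
  cat("See the header of this script for the expected files.\n")
  quit(save = "no", status = 0)
}
dir.create(out, recursive = TRUE, showWarnings = FALSE)

aln <- codon_alignment(read_fasta(need[1], "DNA"), permissive = TRUE)
tree <- read_newick(need[2])
parts <- read.table(need[3], header = TRUE, sep = "\t")
null_map <- setNames(parts$null_partition, parts$taxon)
alt_map <- setNames(parts$alt_partition, parts$taxon)
regions <- read_region_map(need[4])
cr3 <- regions[regions$name == "cr3", ]
if (nrow(cr3) != 1) stop("regions.tsv must contain exactly one 'cr3' row")

# proteotyping at the 10% rule, whole protein and CR3
aa <- translate_codons(aln, permissive = TRUE)
pt <- call_proteotypes(aa, 0.10)
aa_cr3 <- extract_region(aa, cr3$start %/% 3, cr3$end %/% 3)
pt_cr3 <- call_proteotypes(aa_cr3, 0.10)
write.table(data.frame(taxon = names(pt$proteotype),
                       proteotype_full = pt$proteotype,
                       proteotype_cr3 = pt_cr3$proteotype[names(pt$proteotype)]),
            file.path(out, "proteotypes.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
ids <- sort(unique(pt_cr3$proteotype))
if (length(ids) >= 2) {
  idres <- intergroup_identity(aa_cr3, pt_cr3, ids[1], ids[2])
  cat(sprintf("CR3 inter-group identity: mean %.1f%% (%.1f-%.1f%%)\n",
              idres$mean, idres$min, idres$max))
}

# clade-divergence test, full gene and CR3-excised (joint branch-length
# estimation, as for a definitive analysis; this is the slow step)
for (variant in c("full", "cr3_excised")) {
  a <- if (variant == "full") aln else excise_region(aln, cr3$start, cr3$end)
  tst <- cmc_test(a, tree, null_map, alt_map, n_starts = 3)
  tab <- cmc_report(tst, labels = paste0(c("null_", "alt_"), variant))
  write.table(tab, file.path(out, paste0("cmc_", variant, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: LR = %.2f, df = %d, p = %.3g\n", variant, tst$lrt$LR,
              tst$lrt$df, tst$lrt$p))
}

# RSCU + CA over CR3 for the focal (non-background) taxa
focal <- parts$taxon[parts$alt_partition != 0]
sub <- codon_alignment(unclass(aln)[focal, ], permissive = TRUE)
m <- rscu_matrix(sub, cr3$start, cr3$end)
ca <- correspondence_analysis(m)
grp <- setNames(paste0("g", parts$alt_partition), parts$taxon)[focal]
sep <- group_separation(ca, grp)
cat(sprintf("CR3 RSCU-CA silhouette between subclades: %.3f\n",
            sep$silhouette))
write.table(data.frame(taxon = rownames(ca$row_coords), group = grp,
                       round(ca$row_coords, 5)),
            file.path(out, "ca_coords_cr3.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Outputs in", out, "\n")
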