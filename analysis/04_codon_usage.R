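#!/usr/bin/env Rscript
# Stage 4: codon-usage-bias analysis of the simulated study.
#
# Computes RSCU over the 59 informative codons for the focal taxa,
# restricted to the divergent window, embeds taxa in two dimensions by
# correspondence analysis, and quantifies group separation by mean
# silhouette width — once for the plain alignment (no planted bias) and
# once for the copy with strong group-specific codon bias.

suppressMessages(library(cladiv))

simdir <- "results/sim"
out <- "results/codon_usage"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(simdir, "alignment_biased.fasta")))
  stop("run analysis/01_simulate.R first")

parts <- read.table(file.path(simdir, "partitions.tsv"), header = TRUE,
                    sep = "\t")
groups <- setNames(parts$group, parts$taxon)
focal <- parts$taxon[parts$group != "bg"]
cfg <- read.table(file.path(simdir, "config.tsv"), header = TRUE, sep = "\t")
win <- as.integer(cfg$value[match(c("window_start", "window_len"), cfg$key)])

analyze <- function(fasta, label, region) {
  aln <- codon_alignment(read_fasta(file.path(simdir, fasta), "DNA"),
                         permissive = TRUE)
  sub <- codon_alignment(unclass(aln)[focal, ], permissive = TRUE)
  if (identical(region, "window")) {
    m <- rscu_matrix(sub, 3 * win[1], 3 * (win[1] + win[2]))
  } else {
    m <- rscu_matrix(excise_region(sub, 3 * win[1], 3 * (win[1] + win[2])))
  }
  ca <- correspondence_analysis(m)
  sep <- group_separation(ca, groups[focal])
  write.table(cbind(taxon = rownames(m), round(as.data.frame(unclass(m)), 4)),
              file.path(out, paste0("rscu_", label, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  coords <- data.frame(taxon = rownames(ca$row_coords),
                       group = groups[rownames(ca$row_coords)],
                       round(ca$row_coords, 5))
  write.table(coords, file.path(out, paste0("ca_coords_", label, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-10s inertia dim1 %.1f%%, dim2 %.1f%%; silhouette %.3f\n",
              label, 100 * ca$inertia[1], 100 * ca$inertia[2],
              sep$silhouette))
  c(dim1 = unname(ca$inertia[1]), dim2 = unname(ca$inertia[2]),
    silhouette = sep$silhouette)
}

cat("RSCU (59 codons) + correspondence analysis:\n")
# outside the window the groups share one evolutionary regime (the
# 12S-like contrast); inside it they diverge, and planting synonymous
# bias on top sharpens the separation further (the CR3-like contrast)
outside <- analyze("alignment.fasta", "outside_window", "rest")
window_plain <- analyze("alignment.fasta", "window_plain", "window")
window_biased <- analyze("alignment_biased.fasta", "window_biased", "window")
write.table(data.frame(dataset = c("outside_window", "window_plain",
                                   "window_biased"),
                       rbind(round(outside, 4), round(window_plain, 4),
                             round(window_biased, 4))),
            file.path(out, "separation_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Group separation should rise from the outside-window baseline to the\n")
cat("divergent window, and further once synonymous bias is planted.\n")
cat("Outputs in", out, "\n")
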