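# Genetic-code constants shared by the codon model, translation and RSCU.

NUC <- c("T", "C", "A", "G")

# all 64 codons in TCAG order (the conventional codon-table order)
CODONS <- as.vector(outer(outer(NUC, NUC, paste0), NUC, paste0))
CODONS <- CODONS[order(match(substr(CODONS, 1, 1), NUC),
                       match(substr(CODONS, 2, 2), NUC),
                       match(substr(CODONS, 3, 3), NUC))]

GENETIC_CODE_TABLE <- {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc[CODONS]
}

STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)           # 61
SENSE_AA <- GENETIC_CODE_TABLE[SENSE_CODONS]

# the 59 informative codons for RSCU: sense codons minus the single-codon
# families Met (ATG) and Trp (TGG)
RSCU_CODONS <- SENSE_CODONS[!SENSE_CODONS %in% c("ATG", "TGG")]

# purine/purine or pyrimidine/pyrimidine substitutions
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "*", "-")
DNA_ALPHABET <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "-")
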