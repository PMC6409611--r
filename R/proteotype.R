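#' Column-wise consensus profile of a protein alignment
#'
#' For each column, the most frequent non-gap residue (ties broken
#' alphabetically) and its frequency among non-gap residues. All-gap
#' columns get consensus `-` with frequency 0.
#'
#' @param aln a `protein_alignment`.
#' @return list with `consensus` (character vector), `frequency` (numeric),
#'   and `counts` (residues x columns count matrix).
#' @export
consensus_profile <- function(aln) {
  m <- unclass(aln)
  residues <- sort(setdiff(unique(as.vector(m)), "-"))
  counts <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(match(m[, j], residues), nbins = length(residues))
  }, numeric(length(residues)))
  counts <- matrix(counts, nrow = length(residues),
                   dimnames = list(residues, NULL))
  cons <- character(ncol(m))
  freq <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    tot <- sum(counts[, j])
    if (tot == 0) { cons[j] <- "-"; freq[j] <- 0; next }
    best <- which(counts[, j] == max(counts[, j]))[1L]  # rows sorted: tie -> alphabetical
    cons[j] <- residues[best]
    freq[j] <- counts[best, j] / tot
  }
  list(consensus = cons, frequency = freq, counts = counts)
}

# fixed residue -> display color lookup (stable across figures/exports)
PROTEOTYPE_COLORS <- c(
  A = "#cc6677", C = "#ddcc77", D = "#117733", E = "#88ccee", F = "#882255",
  G = "#44aa99", H = "#999933", I = "#aa4499", K = "#332288", L = "#661100",
  M = "#6699cc", N = "#aa4466", P = "#4477aa", Q = "#228833", R = "#ee6677",
  S = "#ccbb44", T = "#ee8866", V = "#bbcc33", W = "#9988dd", X = "#777777",
  Y = "#ffaabb", `*` = "#000000")

#' Signature matrix of non-consensus residues
#'
#' Rows (in `leaf_order`, typically the ladderized tree order) carry `.`
#' where the residue matches the column consensus, `-` for gaps, and the
#' literal residue otherwise — the matrix behind a proteotype figure, where
#' consensus positions are white, gaps black, and every other residue gets
#' a unique color (see the attached `colors` map).
#'
#' @param aln a `protein_alignment`.
#' @param leaf_order permutation of the alignment's taxa.
#' @return character matrix with attribute `colors`.
#' @export
signature_matrix <- function(aln, leaf_order = rownames(aln)) {
  m <- unclass(aln)
  if (!setequal(leaf_order, rownames(m)) ||
      length(leaf_order) != nrow(m))
    stop("leaf_order must be a permutation of the alignment taxa")
  cons <- consensus_profile(aln)$consensus
  m <- m[leaf_order, , drop = FALSE]
  sig <- m
  sig[m == rep(cons, each = nrow(m))] <- "."
  sig[m == "-"] <- "-"
  structure(sig, colors = PROTEOTYPE_COLORS)
}

# pairwise signature divergence: fraction of columns, non-gap in both
# sequences, where the residues differ
signature_divergence <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !gap[i, ] & !gap[j, ]
      if (!any(both)) { d[i, j] <- d[j, i] <- NA_real_; next }
      d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both]) / sum(both)
    }
  }
  d
}

#' Call proteotypes at a divergence threshold
#'
#' Operationalizes the 10% divergence rule: pairwise signature divergence
#' between taxa (fraction of mutually ungapped columns that differ) is
#' clustered by single linkage; clusters are split wherever the linkage
#' distance reaches the threshold. Proteotype ids are assigned by
#' decreasing cluster size, ties by first-taxon order. The per-taxon
#' divergence from the alignment consensus is also reported.
#'
#' @param aln a `protein_alignment`.
#' @param threshold divergence fraction in (0, 1]; the classic rule is 0.10.
#' @return list of class `proteotype_assignment`: `proteotype` (named
#'   integer vector), `divergence` (named fraction-from-consensus),
#'   `threshold`, `n_proteotypes`, `pairwise` (divergence matrix).
#' @export
call_proteotypes <- function(aln, threshold = 0.10) {
  stopifnot(threshold > 0, threshold <= 1)
  m <- unclass(aln)
  taxa <- rownames(m)
  d <- signature_divergence(aln)
  if (anyNA(d)) stop("taxon pair with no mutually ungapped columns")
  cl <- if (nrow(m) == 1L) {
    1L
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    stats::cutree(hc, h = threshold - 1e-12)
  }
  # relabel: decreasing cluster size, ties by first occurrence
  sizes <- table(cl)
  first <- vapply(names(sizes), function(g) min(which(cl == g)), 0L)
  ord <- order(-as.numeric(sizes), first)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  ids <- setNames(as.integer(relabel[as.character(cl)]), taxa)
  cons <- consensus_profile(aln)$consensus
  div <- vapply(seq_len(nrow(m)), function(i) {
    ok <- m[i, ] != "-" & cons != "-"
    if (!any(ok)) return(0)
    sum(m[i, ok] != cons[ok]) / sum(ok)
  }, 0)
  structure(list(proteotype = ids, divergence = setNames(div, taxa),
                 threshold = threshold,
                 n_proteotypes = max(ids), pairwise = d),
            class = "proteotype_assignment")
}

#' @export
print.proteotype_assignment <- function(x, ...) {
  cat(x$n_proteotypes, "proteotype(s) at threshold", x$threshold, "\n")
  for (k in seq_len(x$n_proteotypes)) {
    members <- names(x$proteotype)[x$proteotype == k]
    cat(sprintf("  %d (%d taxa): %s\n", k, length(members),
                paste(members, collapse = ", ")))
  }
  invisible(x)
}

#' Percent identity between two proteotype groups
#'
#' Percent identity for every cross-group pair over mutually ungapped
#' columns, summarized as mean/min/max (percent, reported to 0.1).
#'
#' @param aln a `protein_alignment`.
#' @param assignment a `proteotype_assignment` (or named integer vector).
#' @param group_a,group_b proteotype ids to compare.
#' @return list with `mean`, `min`, `max` (percent) and the per-pair matrix.
#' @export
intergroup_identity <- function(aln, assignment, group_a, group_b) {
  ids <- if (inherits(assignment, "proteotype_assignment"))
    assignment$proteotype else assignment
  a <- names(ids)[ids == group_a]
  b <- names(ids)[ids == group_b]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  m <- unclass(aln)
  pid <- matrix(NA_real_, length(a), length(b), dimnames = list(a, b))
  for (i in a) {
    for (j in b) {
      both <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(both)) stop("no comparable columns between ", i, " and ", j)
      pid[i, j] <- 100 * sum(m[i, both] == m[j, both]) / sum(both)
    }
  }
  list(mean = round(mean(pid), 1), min = round(min(pid), 1),
       max = round(max(pid), 1), pairwise = pid)
}

#' Genome-ordered assortment table of per-region proteotypes
#'
#' Combines per-region proteotype assignments into a taxa x regions matrix
#' ordered by genomic position; ids are per-region and not comparable
#' across columns. Rows can be sorted by the id vector of an anchor region
#' (the natural anchor being the region under study).
#'
#' @param assignments named list of `proteotype_assignment`s (or named id
#'   vectors), in genomic position order.
#' @param anchor optional region name to sort rows by.
#' @return integer matrix (taxa x regions) of class `assortment_table`.
#' @export
assortment_table <- function(assignments, anchor = NULL) {
  ids <- lapply(assignments, function(a)
    if (inherits(a, "proteotype_assignment")) a$proteotype else a)
  taxa <- names(ids[[1]])
  for (v in ids) {
    if (!setequal(names(v), taxa))
      stop("all regions must cover the same taxon set")
  }
  tab <- vapply(ids, function(v) as.integer(v[taxa]), integer(length(taxa)))
  rownames(tab) <- taxa
  if (!is.null(anchor)) {
    stopifnot(anchor %in% colnames(tab))
    tab <- tab[order(tab[, anchor], rownames(tab)), , drop = FALSE]
  }
  structure(tab, class = c("assortment_table", "matrix", "array"))
}

#' Proteotype co-membership breakpoints for a taxon pair
#'
#' Region boundaries where a pair of taxa switches between sharing and not
#' sharing a proteotype id — the signature of a recombination event ending
#' between the two regions.
#'
#' @param table an `assortment_table`.
#' @param taxon_a,taxon_b taxa present in the table.
#' @return data.frame with `from`, `to` region names of each boundary
#'   (zero rows if the sharing pattern never changes).
#' @export
assortment_breakpoints <- function(table, taxon_a, taxon_b) {
  if (!all(c(taxon_a, taxon_b) %in% rownames(table)))
    stop("unknown taxon")
  share <- table[taxon_a, ] == table[taxon_b, ]
  flips <- which(share[-1] != share[-length(share)])
  data.frame(from = colnames(table)[flips],
             to = colnames(table)[flips + 1L],
             stringsAsFactors = FALSE)
}
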