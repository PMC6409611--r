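#' Relative synonymous codon usage of one coding sequence
#'
#' RSCU(c) = count(c) * n / sum(counts of the n synonymous codons of c's
#' amino acid). Computed over the 59 informative codons (61 sense codons
#' minus the single-codon families ATG/Met and TGG/Trp); stop codons are
#' ignored. Gapped or ambiguous codons are skipped. Codons of amino acids
#' absent from the sequence get RSCU 0 and are flagged.
#'
#' @param seq an in-frame nucleotide string, character vector of codons, or
#'   one row of a `codon_alignment`.
#' @return numeric 59-vector named by codon, with attributes `counts`
#'   (codon counts) and `absent_aa` (amino acids with zero count).
#' @export
rscu <- function(seq) {
  if (length(seq) == 1L && !is.matrix(seq)) {
    if (nchar(seq) %% 3L != 0L) stop("sequence length not a multiple of 3")
    seq <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  }
  counts <- table(factor(seq[seq %in% SENSE_CODONS], levels = SENSE_CODONS))
  counts <- setNames(as.numeric(counts), SENSE_CODONS)
  fam <- split(RSCU_CODONS, SENSE_AA[RSCU_CODONS])
  out <- setNames(rep(0, length(RSCU_CODONS)), RSCU_CODONS)
  absent <- character(0)
  for (aa in names(fam)) {
    cods <- fam[[aa]]
    tot <- sum(counts[cods])
    if (tot == 0) { absent <- c(absent, aa); next }
    out[cods] <- counts[cods] * length(cods) / tot
  }
  structure(out, counts = counts[RSCU_CODONS], absent_aa = absent)
}

#' RSCU matrix of a codon alignment
#'
#' One RSCU 59-vector per taxon, optionally restricted to a region of the
#' alignment first (e.g. a divergent sub-window such as CR3).
#'
#' @param aln a `codon_alignment`.
#' @param start,end optional 0-based half-open nucleotide-column bounds
#'   restricting the counted region (codon multiples).
#' @return taxa x 59 numeric matrix of class `rscu_matrix`, with
#'   `absent_aa` (per-taxon list) and `counts` attributes.
#' @export
rscu_matrix <- function(aln, start = NULL, end = NULL) {
  if (!is.null(start)) aln <- extract_region(aln, start, end)
  cm <- codon_strings(unclass(aln))
  rows <- lapply(seq_len(nrow(cm)), function(i) rscu(cm[i, ]))
  m <- do.call(rbind, lapply(rows, as.numeric))
  dimnames(m) <- list(rownames(cm), RSCU_CODONS)
  structure(m,
            absent_aa = setNames(lapply(rows, attr, "absent_aa"),
                                 rownames(cm)),
            counts = do.call(rbind, lapply(rows, attr, "counts")),
            class = c("rscu_matrix", "matrix", "array"))
}

#' Correspondence analysis of a non-negative matrix
#'
#' Classical CA: with P the matrix divided by its grand total, r and c the
#' row/column margins, the standardized residuals
#' S = Dr^-1/2 (P - r c') Dc^-1/2 are decomposed by SVD; row principal
#' coordinates are Dr^-1/2 U Sigma and column coordinates Dc^-1/2 V Sigma.
#' Rows or columns with zero sum are dropped (and recorded). Total inertia
#' equals the chi-square statistic of the table divided by its grand total.
#'
#' @param x non-negative matrix (e.g. an `rscu_matrix`).
#' @param n_dim dimensions to retain (default 2).
#' @return list of class `ca_result`: `row_coords`, `col_coords`,
#'   `singular_values`, `inertia` (per-dimension fractions),
#'   `total_inertia`, `dropped_rows`, `dropped_cols`.
#' @export
correspondence_analysis <- function(x, n_dim = 2L) {
  x <- unclass(x)
  if (any(x < 0)) stop("matrix must be non-negative")
  rs <- rowSums(x); cs <- colSums(x)
  dropped_rows <- rownames(x)[rs == 0]
  dropped_cols <- colnames(x)[cs == 0]
  x <- x[rs > 0, cs > 0, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L) stop("degenerate matrix for CA")
  total <- sum(x)
  P <- x / total
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - r %o% cc) / sqrt(r %o% cc)
  sv <- svd(S)
  keep <- sv$d > 1e-12
  d <- sv$d[keep]
  ndim <- min(n_dim, length(d))
  if (length(d) == 0L) {
    # independence: all profiles identical, everything at the origin
    rc <- matrix(0, nrow(x), n_dim,
                 dimnames = list(rownames(x), paste0("Dim", seq_len(n_dim))))
    ccoord <- matrix(0, ncol(x), n_dim,
                     dimnames = list(colnames(x), paste0("Dim", seq_len(n_dim))))
    return(structure(list(row_coords = rc, col_coords = ccoord,
                          singular_values = numeric(0), inertia = numeric(0),
                          total_inertia = 0,
                          dropped_rows = dropped_rows,
                          dropped_cols = dropped_cols),
                     class = "ca_result"))
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  row_coords <- (U / sqrt(r)) * rep(d, each = nrow(U))
  col_coords <- (V / sqrt(cc)) * rep(d, each = nrow(V))
  dimnames(row_coords) <- list(rownames(x), paste0("Dim", seq_along(d)))
  dimnames(col_coords) <- list(colnames(x), paste0("Dim", seq_along(d)))
  structure(list(
    row_coords = row_coords[, seq_len(ndim), drop = FALSE],
    col_coords = col_coords[, seq_len(ndim), drop = FALSE],
    row_coords_full = row_coords,
    singular_values = d,
    inertia = d^2 / sum(d^2),
    total_inertia = sum(d^2),
    dropped_rows = dropped_rows, dropped_cols = dropped_cols
  ), class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows,",
      nrow(x$col_coords), "columns\n")
  cat(sprintf("  total inertia %.4f; first dims: %s\n", x$total_inertia,
              paste(sprintf("%.1f%%", 100 * utils::head(x$inertia, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Silhouette separation of labeled groups in a CA embedding
#'
#' Mean silhouette width (Euclidean, 2-D coordinates) of the given group
#' labels — a quantitative stand-in for visually judging group separation
#' in a CA plot. Degenerate embeddings (all points coincident) score 0 and
#' are flagged.
#'
#' @param ca a `ca_result`.
#' @param groups named vector of group labels covering the embedded rows.
#' @return list with `silhouette` (mean width), `centroids`, `degenerate`.
#' @export
group_separation <- function(ca, groups) {
  coords <- ca$row_coords
  g <- groups[rownames(coords)]
  if (anyNA(g)) stop("groups must cover all embedded taxa")
  if (length(unique(g)) < 2L) stop("need at least 2 groups")
  if (any(table(g) == 0L)) stop("empty group")
  cent <- do.call(rbind, lapply(split(seq_len(nrow(coords)), g), function(i)
    colMeans(coords[i, , drop = FALSE])))
  d <- stats::dist(coords)
  if (max(d) < 1e-12) {
    return(list(silhouette = 0, centroids = cent, degenerate = TRUE))
  }
  sil <- cluster::silhouette(as.integer(factor(g)), d)
  list(silhouette = mean(sil[, "sil_width"]), centroids = cent,
       degenerate = FALSE)
}
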