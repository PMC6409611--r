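#' Read a FASTA file into a named character vector of sequences
#'
#' Identifiers are the first whitespace-delimited token of each header line;
#' sequences are uppercased and, for nucleotide input, `U` is normalized to
#' `T`. Characters outside the declared alphabet, duplicate identifiers and
#' empty files are errors.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"AA"` for amino-acid sequences or `"DNA"` for nucleotide
#'   sequences (the gap character `-` is part of both alphabets).
#' @return named character vector, one element per record, in file order.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "DNA") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  check_alphabet(seqs, alphabet)
  seqs
}

check_alphabet <- function(seqs, alphabet) {
  allowed <- if (alphabet == "AA") AA_ALPHABET else DNA_ALPHABET
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) stop("empty sequence for id ", names(seqs)[i])
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad)) {
      stop(sprintf("invalid %s character '%s' in record '%s' at column %d",
                   alphabet, ch[bad[1]], names(seqs)[i], bad[1]))
    }
  }
  invisible(seqs)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector, or an alignment object
#'   (`protein_alignment` / `codon_alignment`).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.matrix(seqs)) seqs <- apply(seqs, 1L, paste, collapse = "")
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

aln_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths: ",
         paste(range(lens), collapse = "-"))
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Construct a protein alignment
#'
#' A `protein_alignment` is a character matrix (taxa x columns) over the
#' amino-acid alphabet plus the gap character `-`.
#'
#' @param seqs named character vector of equal-length amino-acid sequences,
#'   or a character matrix with rownames.
#' @return object of class `protein_alignment`.
#' @export
protein_alignment <- function(seqs) {
  m <- if (is.matrix(seqs)) seqs else aln_matrix(seqs)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("taxa must have unique non-empty names")
  if (ncol(m) < 1L) stop("alignment must have at least one column")
  bad <- !m %in% AA_ALPHABET
  if (any(bad)) stop("invalid amino-acid character: ", m[which(bad)[1]])
  structure(m, class = c("protein_alignment", "matrix", "array"))
}

#' Construct an in-frame codon alignment
#'
#' A `codon_alignment` is a character matrix (taxa x nucleotide columns)
#' whose length is a multiple of three. Each codon triplet must be fully
#' gapped (`---`) or fully ungapped, and ungapped codons must not be internal
#' stop codons under the standard genetic code (a terminal stop is allowed).
#'
#' @param seqs named character vector of equal-length nucleotide sequences,
#'   or a character matrix with rownames.
#' @param permissive if `TRUE`, internal stop codons are tolerated (they
#'   translate to `*`) instead of raising an error.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(seqs, permissive = FALSE) {
  m <- if (is.matrix(seqs)) seqs else aln_matrix(seqs)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("taxa must have unique non-empty names")
  if (ncol(m) %% 3L != 0L)
    stop("alignment length ", ncol(m), " is not a multiple of 3")
  if (ncol(m) == 0L) stop("alignment must have at least one codon")
  bad <- !m %in% DNA_ALPHABET
  if (any(bad)) stop("invalid nucleotide character: ", m[which(bad)[1]])
  cm <- codon_strings(m)
  gap_count <- nchar(gsub("[^-]", "", cm))
  partial <- gap_count > 0L & gap_count < 3L
  if (any(partial)) {
    idx <- which(partial, arr.ind = TRUE)[1L, ]
    stop(sprintf("partial gap codon '%s' in taxon '%s' at codon %d",
                 cm[idx[1], idx[2]], rownames(m)[idx[1]], idx[2]))
  }
  if (!permissive) {
    internal <- cm[, -ncol(cm), drop = FALSE]
    stops <- matrix(internal %in% STOP_CODONS, nrow = nrow(cm))
    if (any(stops)) {
      idx <- which(stops, arr.ind = TRUE)[1L, ]
      stop(sprintf("internal stop codon '%s' in taxon '%s' at codon %d",
                   internal[idx[1], idx[2]], rownames(m)[idx[1]], idx[2]))
    }
  }
  structure(m, class = c("codon_alignment", "matrix", "array"),
            permissive = permissive)
}

# taxa x codon matrix of 3-letter codon strings
codon_strings <- function(m) {
  nc <- ncol(m) %/% 3L
  out <- matrix("", nrow(m), nc, dimnames = list(rownames(m), NULL))
  for (j in seq_len(nc)) {
    out[, j] <- paste0(m[, 3L * j - 2L], m[, 3L * j - 1L], m[, 3L * j])
  }
  out
}

#' Number of codon columns of a codon alignment
#' @param aln a `codon_alignment`.
#' @export
n_codons <- function(aln) ncol(aln) %/% 3L

#' Translate a codon alignment to a protein alignment
#'
#' Standard genetic code; `---` translates to `-`; any codon containing an
#' ambiguity character translates to `X`. Internal stop codons are an error
#' naming the taxon and codon unless `permissive`, in which case `*` is
#' emitted.
#'
#' @param aln a `codon_alignment`.
#' @param permissive tolerate internal stop codons.
#' @return a `protein_alignment` with `ncol(aln)/3` columns.
#' @export
translate_codons <- function(aln, permissive = isTRUE(attr(aln, "permissive"))) {
  cm <- codon_strings(unclass(aln))
  aa <- matrix("X", nrow(cm), ncol(cm), dimnames = dimnames(cm))
  known <- cm %in% CODONS
  aa[known] <- GENETIC_CODE_TABLE[cm[known]]
  aa[cm == "---"] <- "-"
  if (!permissive) {
    internal <- aa[, -ncol(aa), drop = FALSE] == "*"
    if (any(internal)) {
      idx <- which(internal, arr.ind = TRUE)[1L, ]
      stop(sprintf("internal stop codon in taxon '%s' at codon %d",
                   rownames(cm)[idx[1]], idx[2]))
    }
  }
  protein_alignment(aa)
}

#' Region maps: named intervals in alignment coordinates
#'
#' Regions are 0-based, half-open `[start, end)` intervals in alignment
#' columns (nucleotide columns for codon alignments, residue columns for
#' protein alignments). They must be non-overlapping and within bounds.
#'
#' @param name character vector of region names.
#' @param start,end integer vectors of 0-based half-open bounds.
#' @return a `data.frame` with class `region_map`.
#' @export
region_map <- function(name, start, end) {
  stopifnot(length(name) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(end <= start))
    stop("regions must satisfy 0 <= start < end")
  o <- order(start)
  if (length(start) > 1L && any(start[o][-1L] < end[o][-length(end)]))
    stop("regions overlap")
  structure(data.frame(name = as.character(name), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("region_map", "data.frame"))
}

#' @rdname region_map
#' @param path TSV file with columns name/start/end.
#' @export
read_region_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  region_map(df$name, df$start, df$end)
}

#' @rdname region_map
#' @param regions a `region_map`.
#' @export
write_region_map <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

check_region <- function(aln, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > ncol(aln) || start >= end)
    stop(sprintf("region [%d,%d) out of bounds for %d columns",
                 start, end, ncol(aln)))
  if (inherits(aln, "codon_alignment") && (start %% 3L || end %% 3L))
    stop("codon alignment regions must start and end on codon boundaries")
  c(start, end)
}

#' Extract or excise a region of an alignment
#'
#' `extract_region` returns columns `[start, end)`; `excise_region` returns
#' the complement with column order preserved. The two calls partition the
#' alignment's columns. For codon alignments, bounds must be codon multiples.
#'
#' @param aln a `protein_alignment` or `codon_alignment`.
#' @param start,end 0-based half-open column bounds, or `region` a one-row
#'   `region_map` entry.
#' @return an alignment of the same class.
#' @export
extract_region <- function(aln, start, end) {
  b <- check_region(aln, start, end)
  rebuild_alignment(aln, unclass(aln)[, (b[1] + 1L):b[2], drop = FALSE])
}

#' @rdname extract_region
#' @export
excise_region <- function(aln, start, end) {
  b <- check_region(aln, start, end)
  keep <- setdiff(seq_len(ncol(aln)), (b[1] + 1L):b[2])
  if (!length(keep)) stop("excising the whole alignment leaves no columns")
  rebuild_alignment(aln, unclass(aln)[, keep, drop = FALSE])
}

rebuild_alignment <- function(template, m) {
  if (inherits(template, "codon_alignment"))
    codon_alignment(m, permissive = isTRUE(attr(template, "permissive")))
  else protein_alignment(m)
}

#' Read a Newick tree with optional `$k` clade-partition tags
#'
#' Clade-partition labels follow the `$k` convention: a `$k` suffix on a tip
#' or internal-node label assigns partition `k` to the branch leading to that
#' node and to all branches of its subtree (until overridden deeper). Edges
#' not covered by any tag belong to the background partition 0.
#'
#' @param path path to a Newick file (or a literal Newick string via `text`).
#' @param text optional Newick string, used instead of `path`.
#' @return an [ape::read.tree] `phylo` object with an `edge.partition`
#'   integer vector (one entry per edge row) attached.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("malformed Newick input")
  if (!is.null(tr$edge.length) && anyNA(tr$edge.length))
    stop("malformed Newick: unparseable branch length")
  ntip <- length(tr$tip.label)
  node_part <- rep(NA_integer_, ntip + tr$Nnode)
  strip <- function(labels) {
    hit <- regmatches(labels, regexpr("\\$[0-9]+$", labels))
    part <- rep(NA_integer_, length(labels))
    has <- grepl("\\$[0-9]+$", labels)
    part[has] <- as.integer(sub("\\$", "", regmatches(labels,
                                 regexpr("\\$[0-9]+$", labels))))
    list(labels = sub("\\$[0-9]+$", "", labels), part = part)
  }
  s <- strip(tr$tip.label)
  tr$tip.label <- s$labels
  node_part[seq_len(ntip)] <- s$part
  if (!is.null(tr$node.label)) {
    s <- strip(tr$node.label)
    tr$node.label <- s$labels
    node_part[ntip + seq_len(tr$Nnode)] <- s$part
  }
  tr$edge.partition <- propagate_partitions(tr, node_part)
  tr
}

# partition of each edge = nearest labeled node at or below its child end
propagate_partitions <- function(tr, node_part) {
  edges <- tr$edge
  part <- integer(nrow(edges))
  ord <- rev(ape::postorder(tr))          # preorder over edges
  root <- length(tr$tip.label) + 1L
  node_state <- rep(0L, max(edges))
  if (!is.na(node_part[root])) node_state[root] <- node_part[root]
  for (e in ord) {
    child <- edges[e, 2L]
    inherit <- node_state[edges[e, 1L]]
    node_state[child] <- if (!is.na(node_part[child])) node_part[child] else inherit
    part[e] <- node_state[child]
  }
  part
}

#' Write a Newick tree, emitting `$k` clade-partition tags
#'
#' The inverse of [read_newick()]: any edge whose partition differs from its
#' parent edge's partition gets a `$k` suffix on its child node label.
#'
#' @param tree a `phylo`, optionally with `edge.partition`.
#' @param path output path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  tr <- tree
  ntip <- length(tr$tip.label)
  if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
  if (!is.null(tr$edge.partition)) {
    edges <- tr$edge
    parent_part <- integer(max(edges))
    parent_part[length(tr$tip.label) + 1L] <- 0L
    for (e in rev(ape::postorder(tr))) {
      child <- edges[e, 2L]
      p <- tr$edge.partition[e]
      if (p != parent_part[edges[e, 1L]]) {
        if (child <= ntip) {
          tr$tip.label[child] <- paste0(tr$tip.label[child], "$", p)
        } else {
          i <- child - ntip
          tr$node.label[i] <- paste0(tr$node.label[i], "$", p)
        }
      }
      parent_part[child] <- p
    }
  }
  txt <- ape::write.tree(tr)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
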