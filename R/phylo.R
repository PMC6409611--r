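#' Pairwise distances from an alignment
#'
#' Distances are computed with pairwise deletion: for each pair of taxa only
#' columns where both carry an unambiguous non-gap state are compared.
#' Models: `"p"` (mismatch proportion), `"poisson"` (-ln(1-p), protein),
#' `"jc"` (Jukes-Cantor, nucleotide). Saturated pairs (p beyond the model
#' domain) give `Inf` with a warning.
#'
#' @param aln a `protein_alignment` or `codon_alignment` (or plain character
#'   matrix of residues).
#' @param model distance model.
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
p_distance <- function(aln, model = c("p", "poisson", "jc")) {
  model <- match.arg(model)
  m <- unclass(aln)
  core <- if (inherits(aln, "protein_alignment")) {
    setdiff(AA_ALPHABET, c("X", "-", "*"))
  } else {
    c("A", "C", "G", "T")
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  ok <- matrix(m %in% core, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- ok[i, ] & ok[j, ]
      nc <- sum(both)
      if (nc == 0L) {
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     rownames(m)[i], rownames(m)[j]))
      }
      p <- sum(m[i, both] != m[j, both]) / nc
      v <- switch(model,
        p = p,
        poisson = if (p >= 1) Inf else -log(1 - p),
        jc = if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3))
      if (!is.finite(v)) {
        warning(sprintf("saturated distance between '%s' and '%s'",
                        rownames(m)[i], rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration by Q-matrix minimization. Ties in Q are broken
#' by the lowest (i, j) pair in canonical node order (alphabetical taxon
#' order, then internal-node creation order), making the result
#' deterministic and invariant to the input row order.
#' Negative estimated branch lengths are clamped to zero with the deficit
#' moved to the sibling branch. The returned tree is unrooted (trifurcating
#' root node).
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return an [ape::read.tree] `phylo` object.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (any(!is.finite(d))) stop("non-finite distances")
  taxa <- rownames(d)
  fmt <- function(x) sprintf("%.12g", x)
  # active node representations as partial Newick strings
  labs <- taxa
  ids <- rank(taxa, ties.method = "first")   # canonical (alphabetical) key
  next_id <- length(taxa) + 1L
  D <- d
  while (length(labs) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- cbind(pmin(ids[cand[, 1]], ids[cand[, 2]]),
                 pmax(ids[cand[, 1]], ids[cand[, 2]]))
    pick <- order(key[, 1], key[, 2])[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    newlab <- paste0("(", labs[i], ":", fmt(vi), ",", labs[j], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    labs <- c(labs[keep], newlab)
    ids <- c(ids[keep], next_id)
    next_id <- next_id + 1L
    D <- D2
  }
  # final three-point resolution
  o <- order(ids)
  labs <- labs[o]
  D <- D[o, o, drop = FALSE]
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  txt <- paste0("(", labs[1], ":", fmt(va), ",", labs[2], ":", fmt(vb), ",",
                labs[3], ":", fmt(vc), ");")
  ape::read.tree(text = txt)
}

# canonical encoding of the non-trivial bipartitions of an unrooted tree:
# each split keyed by the sorted taxon list of its smaller side (ties by
# lexicographically first side)
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) <= 1L || length(other) <= 1L) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = ",") < paste(other, collapse = ","))) {
      side
    } else other
    out <- c(out, paste(key, collapse = ","))
  }
  unique(out)
}

#' Neighbor-joining with bootstrap support
#'
#' Alignment columns (codon triplets for codon alignments) are resampled
#' with replacement `n_reps` times; the support of each internal branch of
#' the full-data tree is the percentage of replicate trees containing the
#' same bipartition. Branches below `collapse` percent support can be
#' collapsed into multifurcations.
#'
#' @param aln alignment.
#' @param n_reps number of bootstrap replicates (paper-style default 500).
#' @param seed RNG seed (mandatory, for reproducibility).
#' @param model distance model passed to [p_distance()].
#' @param collapse support threshold (percent) below which internal branches
#'   are collapsed; `NULL` keeps the binary tree.
#' @return `phylo` with `$node.support` (percent, `NA` for the root) and
#'   supports in `$node.label`.
#' @export
bootstrap_nj <- function(aln, n_reps = 500L, seed, model = "p",
                         collapse = NULL) {
  stopifnot(n_reps >= 1L)
  if (missing(seed)) stop("a seed is required")
  m <- unclass(aln)
  main <- neighbor_joining(p_distance(aln, model))
  main_bp <- bipartitions(main)
  counts <- setNames(numeric(length(main_bp)), main_bp)
  codon <- inherits(aln, "codon_alignment")
  nunits <- if (codon) ncol(m) %/% 3L else ncol(m)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    take <- sample.int(nunits, nunits, replace = TRUE)
    cols <- if (codon) as.vector(rbind(3 * take - 2, 3 * take - 1, 3 * take)) else take
    rep_m <- m[, cols, drop = FALSE]
    rep_aln <- if (codon) codon_alignment(rep_m, permissive = TRUE)
               else protein_alignment(rep_m)
    rep_tree <- tryCatch(neighbor_joining(p_distance(rep_aln, model)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    hits <- intersect(bipartitions(rep_tree), main_bp)
    counts[hits] <- counts[hits] + 1
  }
  support <- 100 * counts / n_reps
  tree <- annotate_support(main, support)
  if (!is.null(collapse)) tree <- collapse_low_support(tree, collapse)
  tree
}

# attach percent supports (named by bipartition key) to internal nodes
annotate_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  node_sup <- rep(NA_real_, tree$Nnode)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  tips <- sort(tree$tip.label)
  for (k in seq_along(parts)) {
    side <- sort(labs[parts[[k]]])
    other <- setdiff(tips, side)
    if (length(side) <= 1L || length(other) <= 1L) next
    key <- if (length(side) < length(other) ||
               (length(side) == length(other) &&
                paste(side, collapse = ",") < paste(other, collapse = ","))) {
      side
    } else other
    key <- paste(key, collapse = ",")
    if (key %in% names(support)) node_sup[k] <- support[[key]]
  }
  tree$node.support <- node_sup
  tree$node.label <- ifelse(is.na(node_sup), "", sprintf("%g", node_sup))
  tree
}

#' Collapse poorly supported internal branches into multifurcations
#'
#' @param tree `phylo` with `$node.support` percent values.
#' @param threshold support percentage; internal branches whose child node
#'   has support below it are contracted.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(!is.null(tree$node.support))
  ntip <- length(tree$tip.label)
  drop_nodes <- ntip + which(!is.na(tree$node.support) &
                             tree$node.support < threshold)
  if (!length(drop_nodes)) return(tree)
  edges <- tree$edge
  parent <- integer(max(edges))
  parent[edges[, 2]] <- edges[, 1]
  resolve <- function(v) {
    while (v %in% drop_nodes) v <- parent[v]
    v
  }
  keep_edge <- !(edges[, 2] %in% drop_nodes)
  new_parent <- vapply(edges[keep_edge, 1], resolve, 0)
  sub <- cbind(new_parent, edges[keep_edge, 2])
  lens <- tree$edge.length[keep_edge]
  # rebuild via Newick text
  ntot <- max(edges)
  kids <- split(seq_len(nrow(sub)), sub[, 1])
  lab <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    rows <- kids[[as.character(v)]]
    paste0("(", paste(vapply(rows, function(r) {
      paste0(lab(sub[r, 2]), ":", sprintf("%.12g", lens[r]))
    }, ""), collapse = ","), ")")
  }
  root <- ntip + 1L
  ape::read.tree(text = paste0(lab(root), ";"))
}

#' Label clade partitions on a tree from a taxon-to-partition map
#'
#' Partition 0 is the background; every other partition's leaf set must be
#' monophyletic (form a clade under some rooting of the unrooted tree).
#' All branches within a partition's subtree, including its stem branch,
#' receive that partition's label; remaining branches are background.
#'
#' @param tree a `phylo`.
#' @param map named integer vector assigning each tip a partition.
#' @return the tree with an `edge.partition` vector attached (exported to
#'   Newick `$k` tags by [write_newick()]).
#' @export
label_clades <- function(tree, map) {
  tips <- tree$tip.label
  if (!all(tips %in% names(map)))
    stop("partition map missing taxa: ",
         paste(setdiff(tips, names(map)), collapse = ", "))
  part <- as.integer(map[tips])
  ks <- sort(unique(part))
  if (!all(ks >= 0L)) stop("partition labels must be >= 0")
  ntip <- length(tips)
  edges <- tree$edge
  epart <- integer(nrow(edges))
  # descendant tip sets per node
  desc <- vector("list", max(edges))
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- edges[e, 1]; ch <- edges[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (k in setdiff(ks, 0L)) {
    tk <- which(part == k)
    node <- NULL; complement <- FALSE
    for (v in seq_len(max(edges))) {
      dv <- desc[[v]]
      if (length(dv) == length(tk) && setequal(dv, tk)) { node <- v; break }
    }
    if (is.null(node)) {
      # the partition may still be a clade under rerooting: its complement
      # forms a subtree in the stored rooting
      for (v in seq_len(max(edges))) {
        dv <- desc[[v]]
        if (length(dv) == ntip - length(tk) &&
            setequal(dv, setdiff(seq_len(ntip), tk))) {
          node <- v; complement <- TRUE; break
        }
      }
    }
    if (is.null(node)) {
      stop(sprintf("partition %d is not monophyletic (leaves: %s)",
                   k, paste(tips[tk], collapse = ", ")))
    }
    inside <- edges[, 1] %in% c(node, node_descendants(edges, node, ntip))
    sel <- if (complement) !inside else inside | (edges[, 2] == node)
    epart[sel] <- k
  }
  tree$edge.partition <- epart
  tree
}

node_descendants <- function(edges, node, ntip) {
  out <- integer(0)
  frontier <- node
  while (length(frontier)) {
    ch <- edges[edges[, 1] %in% frontier, 2]
    out <- c(out, ch)
    frontier <- ch[ch > ntip]
  }
  out
}
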