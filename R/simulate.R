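#' Simulate a Yule tree scaled to a target depth
#'
#' Pure-birth topology with branch lengths rescaled so the mean
#' root-to-tip path length equals `depth` (expected substitutions per
#' codon). Deterministic for a given seed.
#'
#' @param n_taxa number of tips (>= 3).
#' @param depth target mean root-to-tip length.
#' @param seed RNG seed (mandatory).
#' @return rooted binary `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, depth = 0.3, seed) {
  stopifnot(n_taxa >= 3)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_taxa)]
  tr$edge.length <- tr$edge.length * depth / mean(depths)
  tr
}

#' Build a two-subclade study tree with background taxa
#'
#' The backbone of the study design: a background clade and a focal clade
#' split into two subclades (group1, group2), each simulated as a Yule
#' subtree and grafted with stem branches. Returns the tree plus the
#' taxon-to-partition maps for the null labeling (focal species combined,
#' partition 1) and the alternate labeling (group1 = 1, group2 = 2).
#'
#' @param n_bg,n_g1,n_g2 taxa per clade (each >= 2).
#' @param depth mean root-to-tip depth within each subtree.
#' @param stem stem branch length for each clade.
#' @param seed RNG seed.
#' @return list with `tree`, `null_map`, `alt_map`, `groups` (per-taxon
#'   "bg"/"g1"/"g2").
#' @export
simulate_study_tree <- function(n_bg = 6, n_g1 = 5, n_g2 = 5,
                                depth = 0.2, stem = 0.15, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_bg >= 2, n_g1 >= 2, n_g2 >= 2)
  subclade <- function(n, s, prefix) {
    if (n == 2L) {
      return(sprintf("(%s1:%.6g,%s2:%.6g)", prefix, depth, prefix, depth))
    }
    tr <- simulate_tree(n, depth, s)
    tr$tip.label <- paste0(prefix, seq_len(n))
    sub(";$", "", write_newick(tr))
  }
  nb <- subclade(n_bg, seed, "bg")
  n1 <- subclade(n_g1, seed + 1L, "g1_")
  n2 <- subclade(n_g2, seed + 2L, "g2_")
  g <- function(nwk, len) sprintf("%s:%.6g", nwk, len)
  txt <- paste0("(", g(nb, stem), ",(", g(n1, stem), ",", g(n2, stem),
                sprintf("):%.6g);", stem))
  tree <- ape::read.tree(text = txt)
  groups <- setNames(rep(c("bg", "g1", "g2"), c(n_bg, n_g1, n_g2)),
                     c(paste0("bg", seq_len(n_bg)),
                       paste0("g1_", seq_len(n_g1)),
                       paste0("g2_", seq_len(n_g2))))
  null_map <- setNames(ifelse(groups == "bg", 0L, 1L), names(groups))
  alt_map <- setNames(c(bg = 0L, g1 = 1L, g2 = 2L)[groups], names(groups))
  list(tree = tree, null_map = null_map, alt_map = alt_map, groups = groups)
}

#' Simulation configuration for clade-divergent codon alignments
#'
#' Defaults emulate the study conditions: a 253-codon gene with a 62-codon
#' divergent window (the CR3-like sub-region, placed at codons 132..193 so
#' it spans the zinc-finger positions), two focal subclades plus
#' background, three site classes, and divergent-class omegas that differ
#' between partitions only inside the window (outside it every branch uses
#' the background divergent omega).
#'
#' @param n_bg,n_g1,n_g2 taxa per clade.
#' @param n_codons gene length in codons.
#' @param window_start,window_len divergent window, 0-based codons.
#' @param p site-class proportions (purifying, neutral, divergent).
#' @param omega0 purifying omega.
#' @param omega2 divergent-class omega per partition
#'   (background, group1, group2).
#' @param kappa transition/transversion ratio.
#' @param pi sense-codon frequencies (default uniform).
#' @param depth,stem tree dimensions (see [simulate_study_tree()]).
#' @param seed RNG seed (mandatory).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_bg = 6, n_g1 = 5, n_g2 = 5, n_codons = 253,
                       window_start = NULL, window_len = NULL,
                       p = c(0.35, 0.25, 0.40), omega0 = 0.1,
                       omega2 = c(1, 0.2, 3.0), kappa = 2,
                       pi = NULL, depth = 0.3, stem = 0.3, seed) {
  if (missing(seed)) stop("a seed is required")
  # canonical geometry where it fits (62-codon window at codon 132);
  # shorter genes get a proportionally placed window
  if (is.null(window_start))
    window_start <- min(132L, max(0L, n_codons - 62L))
  if (is.null(window_len))
    window_len <- min(62L, n_codons - window_start)
  stopifnot(abs(sum(p) - 1) < 1e-8, length(omega2) == 3,
            window_start >= 0, window_start + window_len <= n_codons)
  if (is.null(pi)) pi <- setNames(rep(1 / 61, 61), SENSE_CODONS)
  check_pi(pi)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a codon alignment with planted clade-divergent structure
#'
#' The generative twin of the Clade model C likelihood: sites draw a class
#' from (p0, p1, p2); codons start at the root from `pi` and evolve along
#' each branch under the GY94 process, with the divergent class using the
#' branch partition's omega inside the divergent window and the background
#' divergent omega elsewhere. Stop codons cannot arise (the generator is
#' restricted to sense codons). Branch lengths are expected substitutions
#' per codon under the configured mixture.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (a `codon_alignment`), `tree` (with
#'   alternate-model `edge.partition`), `null_map`, `alt_map`, `groups`,
#'   and `truth` (site classes, window, generating parameters).
#' @export
simulate_codon_alignment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  study <- simulate_study_tree(cf$n_bg, cf$n_g1, cf$n_g2, cf$depth, cf$stem,
                               seed = cf$seed)
  tree <- label_clades(study$tree, study$alt_map)
  set.seed(cf$seed + 1000L)
  S <- cf$n_codons
  classes <- sample.int(3L, S, replace = TRUE, prob = cf$p) - 1L
  in_window <- seq_len(S) - 1L >= cf$window_start &
    seq_len(S) - 1L < cf$window_start + cf$window_len
  scale <- cf$p[1] * gy94_rate(cf$kappa, cf$omega0, cf$pi) +
    cf$p[2] * gy94_rate(cf$kappa, 1, cf$pi) +
    cf$p[3] * gy94_rate(cf$kappa, cf$omega2[1], cf$pi)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- matrix(NA_integer_, max(tree$edge), S)
  states[root, ] <- sample.int(61L, S, replace = TRUE, prob = cf$pi)
  decs <- new.env(parent = emptyenv())
  get_dec <- function(om) {
    key <- sprintf("%.17g", om)
    d <- decs[[key]]
    if (is.null(d)) { d <- gy94_decomp(cf$kappa, om, cf$pi); decs[[key]] <- d }
    d
  }
  part <- tree$edge.partition
  for (e in rev(ape::postorder(tree))) {         # preorder
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e] / scale
    # per-site omega on this edge
    om_site <- rep(cf$omega0, S)
    om_site[classes == 1L] <- 1
    om_site[classes == 2L] <- cf$omega2[1]
    div <- classes == 2L & in_window
    om_site[div] <- cf$omega2[part[e] + 1L]
    child_state <- integer(S)
    for (om in unique(om_site)) {
      sel <- which(om_site == om)
      P <- decomp_probs(get_dec(om), t_e)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      for (s0 in unique(states[parent, sel])) {
        here <- sel[states[parent, sel] == s0]
        child_state[here] <- sample.int(61L, length(here), replace = TRUE,
                                        prob = P[s0, ])
      }
    }
    states[child, ] <- child_state
  }
  tipseq <- vapply(seq_len(ntip), function(i)
    paste(SENSE_CODONS[states[i, ]], collapse = ""), "")
  names(tipseq) <- tree$tip.label
  aln <- codon_alignment(tipseq)
  list(alignment = aln, tree = tree,
       null_map = study$null_map, alt_map = study$alt_map,
       groups = study$groups,
       truth = list(site_class = classes, in_window = in_window,
                    config = cf, scale = scale))
}

#' Plant group-specific synonymous codon bias
#'
#' Within each group, codons are resampled toward the group's preferred
#' synonymous codon with probability `strength`; amino-acid sequences are
#' unchanged, so dN/dS structure is untouched while RSCU profiles diverge.
#'
#' @param aln a `codon_alignment`.
#' @param groups named group labels covering the alignment taxa.
#' @param strength resampling probability in `[0, 1]`.
#' @param seed RNG seed.
#' @param preferences optional named list (one element per group) of
#'   amino-acid -> preferred-codon maps; by default each group samples its
#'   own preferred codon per amino-acid family.
#' @return a `codon_alignment`.
#' @export
plant_codon_bias <- function(aln, groups, strength, seed,
                             preferences = NULL) {
  stopifnot(strength >= 0, strength <= 1)
  if (missing(seed)) stop("a seed is required")
  if (strength == 0) return(aln)
  m <- unclass(aln)
  taxa <- rownames(m)
  if (!all(taxa %in% names(groups))) stop("groups must cover all taxa")
  fam <- split(SENSE_CODONS, SENSE_AA)
  fam <- fam[vapply(fam, length, 0L) > 1L]
  set.seed(seed)
  glev <- unique(groups[taxa])
  if (is.null(preferences)) {
    preferences <- lapply(glev, function(g)
      vapply(fam, function(cods) cods[sample.int(length(cods), 1L)], ""))
    names(preferences) <- glev
  }
  cm <- codon_strings(m)
  for (i in seq_len(nrow(cm))) {
    pref <- preferences[[groups[taxa[i]]]]
    known <- cm[i, ] %in% SENSE_CODONS
    aa <- GENETIC_CODE_TABLE[cm[i, known]]
    target <- pref[aa]
    hit <- !is.na(target) & stats::runif(sum(known)) < strength
    repl <- cm[i, known]
    repl[hit] <- target[hit]
    cm[i, known] <- repl
  }
  seqs <- apply(cm, 1L, paste, collapse = "")
  codon_alignment(setNames(seqs, taxa),
                  permissive = isTRUE(attr(aln, "permissive")))
}

#' Opposite codon preferences for two groups
#'
#' Deterministic maximally distinct preference maps: the first group
#' prefers the alphabetically first codon of every synonymous family, the
#' second the last. Useful for planting strong, reproducible bias.
#'
#' @param group_names length-2 character vector.
#' @export
opposite_preferences <- function(group_names) {
  fam <- split(SENSE_CODONS, SENSE_AA)
  fam <- fam[vapply(fam, length, 0L) > 1L]
  out <- list(vapply(fam, function(x) sort(x)[1], ""),
              vapply(fam, function(x) sort(x)[length(x)], ""))
  names(out) <- group_names
  out
}

#' Write the canonical simulated fixture bundle
#'
#' A small, fully seeded dataset exercising every pipeline stage: codon
#' alignment (FASTA), alternate- and null-labeled trees (Newick with `$k`
#' tags), taxon partition maps (TSV), per-site truth (TSV), and the
#' configuration (TSV). Byte-identical for a given seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed.
#' @param config optional [sim_config()]; defaults to the canonical
#'   253-codon, 16-taxon setup.
#' @return invisible character vector of written paths.
#' @export
make_fixture_set <- function(out_dir, seed, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_codon_alignment(config)
  paths <- c(
    alignment = file.path(out_dir, "alignment.fasta"),
    tree_alt = file.path(out_dir, "tree_alt.nwk"),
    tree_null = file.path(out_dir, "tree_null.nwk"),
    partitions = file.path(out_dir, "partitions.tsv"),
    truth = file.path(out_dir, "site_truth.tsv"),
    config = file.path(out_dir, "config.tsv"))
  write_fasta(sim$alignment, paths["alignment"])
  write_newick(sim$tree, paths["tree_alt"])
  write_newick(label_clades(sim$tree, sim$null_map), paths["tree_null"])
  utils::write.table(
    data.frame(taxon = names(sim$alt_map),
               group = sim$groups[names(sim$alt_map)],
               null_partition = as.integer(sim$null_map),
               alt_partition = as.integer(sim$alt_map)),
    paths["partitions"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(codon = seq_along(sim$truth$site_class) - 1L,
               site_class = sim$truth$site_class,
               in_window = as.integer(sim$truth$in_window)),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  cf <- config
  scalars <- cf[c("n_bg", "n_g1", "n_g2", "n_codons", "window_start",
                  "window_len", "omega0", "kappa", "depth", "stem", "seed")]
  cfg <- data.frame(key = c(names(scalars), "p", "omega2"),
                    value = c(vapply(scalars, format, ""),
                              paste(cf$p, collapse = ","),
                              paste(cf$omega2, collapse = ",")))
  utils::write.table(cfg, paths["config"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
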