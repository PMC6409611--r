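# Shared fixture builders and independent oracles for the test suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

# protein alignment with two planted groups: `between` fraction of columns
# differ between groups, `within` fraction of per-taxon noise
two_group_protein <- function(n1 = 5, n2 = 5, ncols = 100,
                              between = 0.25, within = 0.02, seed = 1) {
  set.seed(seed)
  base <- sample(AA20, ncols, replace = TRUE)
  alt <- base
  flip <- sample(ncols, round(between * ncols))
  alt[flip] <- vapply(alt[flip], function(a) sample(setdiff(AA20, a), 1), "")
  mutate <- function(v) {
    k <- rbinom(1, ncols, within)
    if (k > 0) {
      at <- sample(ncols, k)
      v[at] <- vapply(v[at], function(a) sample(setdiff(AA20, a), 1), "")
    }
    paste(v, collapse = "")
  }
  seqs <- c(vapply(seq_len(n1), function(i) mutate(base), ""),
            vapply(seq_len(n2), function(i) mutate(alt), ""))
  names(seqs) <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  protein_alignment(seqs)
}

# random tree with strictly positive branch lengths and its additive
# (path-length) distance matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Exhaustive-state oracle for the clade-model likelihood: sums over every
# joint assignment of internal-node codon states. Usable only for tiny
# trees (<= 2 internal nodes) and a few sites.
brute_cmc_loglik <- function(aln, tree, params) {
  pi <- params$pi
  part <- tree$edge.partition %||% rep(0L, nrow(tree$edge))
  scale <- params$p[1] * cladiv:::gy94_rate(params$kappa, params$omega0, pi) +
    params$p[2] * cladiv:::gy94_rate(params$kappa, 1, pi) +
    params$p[3] * cladiv:::gy94_rate(params$kappa, params$omega2[1], pi)
  enc <- cladiv:::encode_codons(aln)
  enc <- enc[tree$tip.label, , drop = FALSE]
  ntip <- nrow(enc)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internal))))
  edges <- tree$edge
  Pset <- function(omega_edge) {
    lapply(seq_len(nrow(edges)), function(e)
      transition_probs(
        build_rate_matrix(params$kappa, omega_edge[e], pi, normalize = FALSE),
        tree$edge.length[e] / scale, pi))
  }
  site_lik <- function(Ps, obs) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(v) {
        if (v <= ntip) obs[v] else grid[g, match(v, internal)]
      }
      pr <- pi[grid[g, 1L]]            # internal[1] is the root
      for (e in seq_len(nrow(edges))) {
        a <- assign_state(edges[e, 1L]); b <- assign_state(edges[e, 2L])
        if (is.na(b)) next             # missing tip: marginalize (P rows sum 1)
        pr <- pr * Ps[[e]][a, b]
      }
      tot <- tot + pr
    }
    tot
  }
  P0 <- Pset(rep(params$omega0, nrow(edges)))
  P1 <- Pset(rep(1, nrow(edges)))
  P2 <- Pset(params$omega2[part + 1L])
  sum(vapply(seq_len(ncol(enc)), function(s) {
    obs <- enc[, s]
    log(params$p[1] * site_lik(P0, obs) + params$p[2] * site_lik(P1, obs) +
          params$p[3] * site_lik(P2, obs))
  }, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

uniform_pi <- function() setNames(rep(1 / 61, 61), cladiv:::SENSE_CODONS)

# random sense-codon sequences as a codon alignment
random_codon_aln <- function(n_taxa, n_codons, seed) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_taxa), function(i)
    paste(sample(cladiv:::SENSE_CODONS, n_codons, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- paste0("t", seq_len(n_taxa))
  codon_alignment(seqs)
}
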