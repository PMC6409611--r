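# Felsenstein pruning over the 61-codon state space with Clade model C
# site classes: class 0 purifying (omega0 < 1), class 1 neutral (omega = 1),
# class 2 "divergent" with a separate omega per clade partition of the tree.

# Encode a codon alignment as a taxa x sites matrix of sense-codon indices
# (1..61); gaps, ambiguous codons and terminal stops become NA (missing
# data, all-ones partial likelihoods).
encode_codons <- function(aln) {
  cm <- codon_strings(unclass(aln))
  idx <- matrix(match(cm, SENSE_CODONS), nrow = nrow(cm),
                dimnames = list(rownames(cm), NULL))
  idx
}

# Compress to unique site patterns; returns index matrix, weights.
compress_patterns <- function(idx) {
  key <- apply(idx, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  list(patterns = idx[, first, drop = FALSE],
       weights = as.numeric(table(key)[key[first]]),
       map = match(key, key[first]))
}

# prepared data: tip partial-likelihood matrices + postordered edges
prepare_pruning <- function(aln, tree) {
  taxa <- rownames(aln)
  if (!setequal(taxa, tree$tip.label))
    stop("alignment taxa and tree tips do not match")
  idx <- encode_codons(aln)[tree$tip.label, , drop = FALSE]
  pat <- compress_patterns(idx)
  S <- ncol(pat$patterns)
  ntip <- nrow(idx)
  tips <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    m <- matrix(0, 61, S)
    known <- !is.na(pat$patterns[i, ])
    m[cbind(pat$patterns[i, known], which(known))] <- 1
    m[, !known] <- 1
    tips[[i]] <- m
  }
  po <- ape::postorder(tree)
  list(tips = tips, S = S, weights = pat$weights, postorder = po,
       edge = tree$edge, ntip = ntip,
       nnode = tree$Nnode, root = ntip + 1L)
}

# One pruning pass: per-edge omega given by omega_edge, all edges share
# kappa/pi; returns per-pattern log-likelihoods. `decomp_cache` is an
# environment reused across passes to share eigendecompositions.
prune_pass <- function(prep, tree_lengths, omega_edge, kappa, pi,
                       decomp_cache = new.env(parent = emptyenv())) {
  S <- prep$S
  get_dec <- function(omega) {
    key <- sprintf("%.17g|%.17g", kappa, omega)
    d <- decomp_cache[[key]]
    if (is.null(d)) {
      d <- gy94_decomp(kappa, omega, pi)
      decomp_cache[[key]] <- d
    }
    d
  }
  nmax <- max(prep$edge)
  partial <- vector("list", nmax)
  logscale <- matrix(0, 1, S)
  for (e in prep$postorder) {
    parent <- prep$edge[e, 1L]
    child <- prep$edge[e, 2L]
    cp <- if (child <= prep$ntip) prep$tips[[child]] else partial[[child]]
    P <- decomp_probs(get_dec(omega_edge[e]), tree_lengths[e])
    contrib <- P %*% cp
    contrib[contrib < 0] <- 0
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      sc <- .colSums(partial[[parent]], 61, S)
      sc[sc <= 0] <- 1
      partial[[parent]] <- partial[[parent]] /
        rep(sc, each = 61)
      logscale <- logscale + log(sc)
    }
  }
  lik <- as.numeric(pi %*% partial[[prep$root]])
  bad <- lik <= 0
  if (any(bad)) {
    stop("zero site likelihood at pattern(s) ",
         paste(which(bad), collapse = ", "))
  }
  log(lik) + as.numeric(logscale)
}

#' Clade model C log-likelihood
#'
#' Mixture over three site classes: purifying (`omega0`), neutral (1) and a
#' divergent class whose omega depends on each branch's clade partition
#' (`omega2[k+1]` on branches labeled `k`). Gap and ambiguous codons are
#' missing data. Branch lengths are interpreted as expected substitutions
#' per codon: the generator is rescaled by the mixture-average substitution
#' rate (class-2 contribution taken at the background partition's omega).
#'
#' @param aln a `codon_alignment`.
#' @param tree `phylo` with `edge.partition` labels (see [label_clades()]).
#' @param params list with `kappa`, `p` (length-3 class proportions),
#'   `omega0`, `omega2` (one value per partition, background first) and
#'   optionally `pi` (61 sense-codon frequencies; default F3x4 from the
#'   alignment).
#' @return total log-likelihood (numeric scalar).
#' @export
cmc_loglik <- function(aln, tree, params) {
  prep <- prepare_pruning(aln, tree)
  pi <- params$pi %||% codon_frequencies(aln, "f3x4")
  part <- tree$edge.partition %||% rep(0L, nrow(tree$edge))
  K <- max(part) + 1L
  stopifnot(length(params$omega2) == K,
            abs(sum(params$p) - 1) < 1e-8, all(params$p >= 0))
  scale <- params$p[1] * gy94_rate(params$kappa, params$omega0, pi) +
    params$p[2] * gy94_rate(params$kappa, 1, pi) +
    params$p[3] * gy94_rate(params$kappa, params$omega2[1], pi)
  tl <- tree$edge.length / scale
  cache <- new.env(parent = emptyenv())
  ne <- nrow(tree$edge)
  l0 <- prune_pass(prep, tl, rep(params$omega0, ne), params$kappa, pi, cache)
  l1 <- prune_pass(prep, tl, rep(1, ne), params$kappa, pi, cache)
  l2 <- prune_pass(prep, tl, params$omega2[part + 1L], params$kappa, pi, cache)
  mix <- mix_loglik(cbind(l0, l1, l2), params$p)
  sum(prep$weights * mix)
}

# per-site mixture log-likelihood from per-class log-likelihood columns
mix_loglik <- function(lmat, p) {
  m <- apply(lmat, 1L, max)
  m + log(as.numeric(exp(lmat - m) %*% p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- analytic derivatives ------------------------------------------------
#
# dP(t)/dtheta through the eigendecomposition: with B = D^1/2 Q D^-1/2 =
# U diag(lambda) U', and dB the similarity transform of dQ/dtheta,
# dP = L (F * (U' dB U)) R where F_ij is the divided difference
# (e^(lambda_i t) - e^(lambda_j t)) / (lambda_i - lambda_j). The per-site
# derivative of the log-likelihood is assembled edge by edge from outer
# (above-edge) and inner (below-edge) partials.

# decomposition bundle with the G matrices needed for kappa/omega
# derivatives; cached alongside the plain decomposition
gy94_decomp_grad <- function(kappa, omega, pi) {
  st <- codon_struct()
  n <- length(pi)
  dec <- gy94_decomp(kappa, omega, pi)
  U <- dec$L * sqrt(pi)                # back to the orthogonal eigenvectors
  mk_dB <- function(dQ) {
    sq <- sqrt(pi)
    B <- dQ * (sq %o% (1 / sq))
    crossprod(U, (B + t(B)) / 2) %*% U
  }
  # dQ/domega: nonsynonymous single-step entries (with their diagonal)
  dQw <- matrix(0, n, n)
  nons <- st$single & !st$synonymous
  dQw[nons] <- ifelse(st$transition[nons], kappa, 1) *
    rep(pi, each = n)[nons]
  diag(dQw) <- -rowSums(dQw)
  # dQ/dkappa: transition entries, omega-weighted where nonsynonymous
  dQk <- matrix(0, n, n)
  tr <- st$transition
  dQk[tr] <- ifelse(st$synonymous[tr], 1, omega) *
    rep(pi, each = n)[tr]
  diag(dQk) <- -rowSums(dQk)
  dec$Gw <- mk_dB(dQw)
  dec$Gk <- mk_dB(dQk)
  dec
}

# divided-difference matrix F for one branch length
dd_matrix <- function(lambda, t) {
  n <- length(lambda)
  el <- exp(lambda * t)
  num <- outer(el, el, `-`)
  den <- outer(lambda, lambda, `-`)
  F <- num / den
  close <- abs(den) < 1e-9
  F[close] <- t * rep(el, n)[col(num)][close]
  diag(F) <- t * el
  F
}

# One class pass with per-site log-likelihoods and (optionally) analytic
# derivatives with respect to each edge's length, each distinct free omega
# (grouped by `omega_group`, NA = not free), and kappa.
class_pass <- function(prep, tl, omega_edge, kappa, pi, decomp_cache,
                       grad = FALSE, omega_group = NULL) {
  S <- prep$S
  ne <- nrow(prep$edge)
  get_dec <- function(omega) {
    key <- sprintf("%.17g|%.17g|%d", kappa, omega, as.integer(grad))
    d <- decomp_cache[[key]]
    if (is.null(d)) {
      d <- if (grad) gy94_decomp_grad(kappa, omega, pi)
           else gy94_decomp(kappa, omega, pi)
      decomp_cache[[key]] <- d
    }
    d
  }
  if (!grad) {
    return(list(l = prune_pass_tl(prep, tl, omega_edge, get_dec, pi)))
  }
  nmax <- max(prep$edge)
  # forward sweep: scaled messages per edge, partials per node
  msg <- vector("list", ne)
  amsg <- vector("list", ne)
  Pmat <- vector("list", ne)
  partial <- vector("list", nmax)
  A <- vector("list", nmax)
  kids <- vector("list", nmax)
  for (e in prep$postorder) {
    parent <- prep$edge[e, 1L]; child <- prep$edge[e, 2L]
    kids[[parent]] <- c(kids[[parent]], e)
    cp <- if (child <= prep$ntip) prep$tips[[child]] else partial[[child]]
    dec <- get_dec(omega_edge[e])
    P <- decomp_probs(dec, tl[e])
    Pmat[[e]] <- P
    m <- P %*% cp
    m[m < 0] <- 0
    sc <- .colSums(m, 61, S)
    sc[sc <= 0] <- 1e-300
    m <- m / rep(sc, each = 61)
    ca <- if (child <= prep$ntip) 0 else A[[child]]
    msg[[e]] <- m
    amsg[[e]] <- ca + log(sc)
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- m
      A[[parent]] <- amsg[[e]]
    } else {
      partial[[parent]] <- partial[[parent]] * m
      A[[parent]] <- A[[parent]] + amsg[[e]]
    }
  }
  root <- prep$root
  lik <- as.numeric(pi %*% partial[[root]])
  lik[lik <= 0] <- 1e-300
  l <- log(lik) + A[[root]]
  # backward sweep: outer partial O[e] at the parent end of each edge
  O <- vector("list", ne)
  Bv <- vector("list", ne)
  Dn <- vector("list", nmax)
  Bn <- vector("list", nmax)
  Dn[[root]] <- matrix(pi, 61, S)
  Bn[[root]] <- rep(0, S)
  for (e in rev(prep$postorder)) {      # preorder
    parent <- prep$edge[e, 1L]; child <- prep$edge[e, 2L]
    sibs <- setdiff(kids[[parent]], e)
    o <- Dn[[parent]]
    b <- Bn[[parent]]
    for (s_e in sibs) {
      o <- o * msg[[s_e]]
      b <- b + amsg[[s_e]]
    }
    O[[e]] <- o; Bv[[e]] <- b
    if (child > prep$ntip) {
      dn <- crossprod(Pmat[[e]], o)
      dn[dn < 0] <- 0
      sc <- .colSums(dn, 61, S)
      sc[sc <= 0] <- 1e-300
      Dn[[child]] <- dn / rep(sc, each = 61)
      Bn[[child]] <- b + log(sc)
    }
  }
  # per-edge derivative terms
  ogroups <- sort(unique(omega_group[!is.na(omega_group)]))
  dt <- matrix(0, ne, S)
  domega <- matrix(0, length(ogroups), S,
                   dimnames = list(as.character(ogroups), NULL))
  dkappa <- rep(0, S)
  for (e in seq_len(ne)) {
    child <- prep$edge[e, 2L]
    cp <- if (child <= prep$ntip) prep$tips[[child]] else partial[[child]]
    ca <- if (child <= prep$ntip) 0 else A[[child]]
    dec <- get_dec(omega_edge[e])
    Wv <- dec$R %*% cp
    OL <- crossprod(dec$L, O[[e]])
    fac <- exp(Bv[[e]] + ca - l)
    el <- exp(dec$lambda * tl[e])
    dt[e, ] <- .colSums(OL * ((dec$lambda * el) * Wv), 61, S) * fac
    F <- dd_matrix(dec$lambda, tl[e])
    dkappa <- dkappa + .colSums(OL * ((F * dec$Gk) %*% Wv), 61, S) * fac
    g <- omega_group[e]
    if (!is.na(g)) {
      gi <- match(g, ogroups)
      domega[gi, ] <- domega[gi, ] +
        .colSums(OL * ((F * dec$Gw) %*% Wv), 61, S) * fac
    }
  }
  list(l = l, dt = dt, domega = domega, dkappa = dkappa)
}

# objective-only pass sharing the decomposition accessor
prune_pass_tl <- function(prep, tl, omega_edge, get_dec, pi) {
  S <- prep$S
  nmax <- max(prep$edge)
  partial <- vector("list", nmax)
  logscale <- rep(0, S)
  for (e in prep$postorder) {
    parent <- prep$edge[e, 1L]; child <- prep$edge[e, 2L]
    cp <- if (child <= prep$ntip) prep$tips[[child]] else partial[[child]]
    P <- decomp_probs(get_dec(omega_edge[e]), tl[e])
    contrib <- P %*% cp
    contrib[contrib < 0] <- 0
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      sc <- .colSums(partial[[parent]], 61, S)
      sc[sc <= 0] <- 1e-300
      partial[[parent]] <- partial[[parent]] / rep(sc, each = 61)
      logscale <- logscale + log(sc)
    }
  }
  lik <- as.numeric(pi %*% partial[[prep$root]])
  if (any(lik <= 0)) {
    stop("zero site likelihood at pattern(s) ",
         paste(which(lik <= 0), collapse = ", "))
  }
  log(lik) + logscale
}
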