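# Goldman-Yang (GY94) codon rate matrix machinery.
#
# Precomputed structure over the 61 sense codons: which pairs differ at a
# single nucleotide position, whether that change is a transition, and
# whether it is synonymous.

codon_pair_structure <- function() {
  n <- length(SENSE_CODONS)
  split1 <- substr(SENSE_CODONS, 1, 1)
  split2 <- substr(SENSE_CODONS, 2, 2)
  split3 <- substr(SENSE_CODONS, 3, 3)
  diff1 <- outer(split1, split1, `!=`)
  diff2 <- outer(split2, split2, `!=`)
  diff3 <- outer(split3, split3, `!=`)
  ndiff <- diff1 + diff2 + diff3
  single <- ndiff == 1L
  ts <- matrix(FALSE, n, n)
  for (pos in 1:3) {
    s <- get(paste0("split", pos))
    only <- single & get(paste0("diff", pos))
    ts[only] <- ts[only] | outer(s, s, function(a, b) is_transition(a, b))[only]
  }
  syn <- outer(SENSE_AA, SENSE_AA, `==`)
  list(single = single, transition = ts & single, synonymous = syn)
}

.codon_struct <- NULL
codon_struct <- function() {
  if (is.null(.codon_struct)) {
    utils::assignInMyNamespace(".codon_struct", codon_pair_structure())
  }
  .codon_struct
}

#' GY94 codon rate matrix
#'
#' Builds the 61 x 61 generator of the Goldman-Yang codon substitution
#' model: substitutions changing more than one codon position have rate 0;
#' a single-position change from codon i to j has rate
#' `pi[j] * kappa^[transition] * omega^[nonsynonymous]`. The diagonal makes
#' rows sum to zero. With `normalize = TRUE` the generator is rescaled so
#' the expected substitution rate at stationarity, `-sum(pi * diag(Q))`,
#' equals 1 (branch lengths then read as expected substitutions per codon
#' at this omega).
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi equilibrium frequencies over the 61 sense codons (sum 1).
#' @param normalize rescale to unit expected rate.
#' @return 61 x 61 matrix with codon dimnames.
#' @export
build_rate_matrix <- function(kappa, omega, pi, normalize = TRUE) {
  check_pi(pi)
  stopifnot(kappa > 0, omega >= 0)
  st <- codon_struct()
  n <- length(SENSE_CODONS)
  mult <- matrix(0, n, n)
  mult[st$single] <- 1
  mult[st$transition] <- kappa
  mult[st$single & !st$synonymous] <-
    mult[st$single & !st$synonymous] * omega
  Q <- mult * rep(pi, each = n)        # q_ij ~ pi_j
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    r <- -sum(pi * diag(Q))
    if (r <= 0) stop("degenerate rate matrix")
    Q <- Q / r
  }
  dimnames(Q) <- list(SENSE_CODONS, SENSE_CODONS)
  Q
}

check_pi <- function(pi) {
  if (length(pi) != length(SENSE_CODONS) || any(pi <= 0) ||
      abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be ", length(SENSE_CODONS),
         " strictly positive frequencies summing to 1")
  }
  invisible(pi)
}

# expected substitution rate -sum(pi q_ii) of the *unnormalized* GY94
# generator at the given omega
gy94_rate <- function(kappa, omega, pi) {
  Q <- build_rate_matrix(kappa, omega, pi, normalize = FALSE)
  -sum(pi * diag(Q))
}

# Symmetric eigendecomposition of the reversible generator; P(t) is then
# L %*% (exp(lambda t) * R) for any t without re-decomposition.
gy94_decomp <- function(kappa, omega, pi) {
  Q <- build_rate_matrix(kappa, omega, pi, normalize = FALSE)
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq))           # D^1/2 Q D^-1/2, symmetric
  B <- (B + t(B)) / 2                  # guard rounding asymmetry
  e <- eigen(B, symmetric = TRUE)
  list(L = e$vectors / sq,             # D^-1/2 U (column-wise over rows)
       R = t(e$vectors) * rep(sq, each = length(sq)),
       lambda = e$values)
}

decomp_probs <- function(dec, t) {
  if (t < 0) stop("t must be >= 0")
  dec$L %*% (exp(dec$lambda * t) * dec$R)
}

#' Transition probabilities of a codon generator
#'
#' `P(t) = exp(Qt)`, computed by symmetric eigendecomposition when the
#' stationary frequencies of the reversible generator are supplied, and by
#' a general eigendecomposition otherwise.
#'
#' @param Q generator matrix (rows sum to zero).
#' @param t time (branch length), >= 0.
#' @param pi optional stationary frequencies making `Q` reversible.
#' @return stochastic matrix `P(t)` with rows summing to 1.
#' @export
transition_probs <- function(Q, t, pi = NULL) {
  if (t < 0) stop("t must be >= 0")
  if (!is.null(pi)) {
    sq <- sqrt(pi)
    B <- Q * (sq %o% (1 / sq))
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    P <- (e$vectors / sq) %*% (exp(e$values * t) *
                               (t(e$vectors) * rep(sq, each = length(sq))))
  } else {
    e <- eigen(Q)
    P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  }
  dimnames(P) <- dimnames(Q)
  P
}

#' Empirical codon frequencies from a codon alignment
#'
#' `"f3x4"` (default): products of position-specific nucleotide frequencies,
#' renormalized over the 61 sense codons. `"f61"`: observed sense-codon
#' frequencies with a small pseudocount. `"uniform"`: 1/61 each.
#'
#' @param aln a `codon_alignment`.
#' @param method frequency estimator.
#' @return numeric vector over the 61 sense codons, summing to 1.
#' @export
codon_frequencies <- function(aln, method = c("f3x4", "f61", "uniform")) {
  method <- match.arg(method)
  if (method == "uniform") {
    return(setNames(rep(1 / 61, 61), SENSE_CODONS))
  }
  cm <- codon_strings(unclass(aln))
  obs <- cm[cm %in% CODONS]
  if (!length(obs)) stop("no unambiguous codons in alignment")
  if (method == "f61") {
    cnt <- table(factor(obs, levels = SENSE_CODONS)) + 0.5
    f <- as.numeric(cnt) / sum(cnt)
    return(setNames(f, SENSE_CODONS))
  }
  fpos <- lapply(1:3, function(p) {
    nt <- substr(obs, p, p)
    cnt <- table(factor(nt, levels = NUC)) + 0.5
    as.numeric(cnt) / sum(cnt)
  })
  f <- vapply(SENSE_CODONS, function(cd) {
    fpos[[1]][match(substr(cd, 1, 1), NUC)] *
      fpos[[2]][match(substr(cd, 2, 2), NUC)] *
      fpos[[3]][match(substr(cd, 3, 3), NUC)]
  }, 0)
  f / sum(f)
}
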