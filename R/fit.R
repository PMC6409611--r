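#' Free-parameter count of a Clade model C fit
#'
#' Branch lengths of the unrooted binary tree (2n - 3), plus kappa, two
#' free site-class proportions, omega0, and one divergent-class omega per
#' clade partition. Codon frequencies are empirical and not counted.
#'
#' @param n_taxa number of taxa n.
#' @param K number of clade partitions (background included).
#' @return integer parameter count.
#' @export
np_cmc <- function(n_taxa, K) {
  stopifnot(n_taxa >= 3, K >= 1)
  as.integer((2 * n_taxa - 3) + 1 + 2 + 1 + K)
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, accurate in the far
#' tail (computed in the log domain).
#'
#' @param x statistic, >= 0.
#' @param df degrees of freedom, >= 1.
#' @export
chi2_sf <- function(x, df) {
  stopifnot(x >= 0, df >= 1)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio test between nested clade-model fits
#'
#' @param fit_null,fit_alt `cmc_fit` objects on the same data, with
#'   `fit_alt` the more complex (higher `np`) model.
#' @return list with `LR` (2 x delta lnL), `df`, `p`, and a `negative_LR`
#'   flag set when the statistic is below zero (non-convergence).
#' @export
lrt <- function(fit_null, fit_alt) {
  if (fit_alt$np <= fit_null$np)
    stop("fit_alt must have more free parameters than fit_null")
  LR <- 2 * (fit_alt$lnL - fit_null$lnL)
  df <- fit_alt$np - fit_null$np
  list(LR = LR, df = df, p = chi2_sf(max(LR, 0), df),
       negative_LR = LR < 0)
}

#' Likelihood ratio and p-value from two printed log-likelihoods
#'
#' Convenience for recomputing a report row from its lnL entries.
#'
#' @param lnL_null,lnL_alt log-likelihoods of the nested fits.
#' @param df degrees of freedom (parameter-count difference).
#' @export
lrt_from_lnl <- function(lnL_null, lnL_alt, df = 1L) {
  LR <- 2 * (lnL_alt - lnL_null)
  list(LR = LR, df = df, p = chi2_sf(max(LR, 0), df), negative_LR = LR < 0)
}

# EM profiling of the site-class proportions given per-class per-pattern
# log-likelihood columns
profile_p <- function(lmat, w, p_init = rep(1 / 3, 3),
                      tol = 1e-10, maxit = 500L) {
  p <- 0.999 * p_init + 0.001 / 3     # keep away from the boundary
  p <- p / sum(p)
  m <- pmax(lmat[, 1L], lmat[, 2L], lmat[, 3L])
  e <- exp(lmat - m)
  W <- sum(w)
  for (it in seq_len(maxit)) {
    d <- as.numeric(e %*% p)
    pnew <- p * as.numeric(crossprod(e, w / d)) / W
    if (max(abs(pnew - p)) < tol) { p <- pnew; break }
    p <- pnew
  }
  lnL <- sum(w * (m + log(as.numeric(e %*% p))))
  list(p = p, lnL = lnL)
}

# Objective factory: negative profiled log-likelihood (and its analytic
# gradient) over transformed parameters. Per-class caching keeps repeated
# single-parameter evaluations cheap; the gradient is exact (site-class
# proportions are profiled out, so the envelope theorem applies).
make_cmc_objective <- function(prep, edge_part, K, pi, fix_bl, input_bl) {
  ne <- length(input_bl)
  st <- new.env(parent = emptyenv())
  st$p <- rep(1 / 3, 3)
  st$dec <- new.env(parent = emptyenv())
  unpack <- function(th) {
    kappa <- exp(th[1L])
    omega0 <- stats::plogis(th[2L])
    omega2 <- exp(th[3L:(2L + K)])
    tl <- if (fix_bl) exp(th[3L + K]) * input_bl else exp(th[(3L + K):(2L + K + ne)])
    list(kappa = kappa, omega0 = omega0, omega2 = omega2, tl = tl)
  }
  run_pass <- function(slot, key, grad, tl, omega_edge, kappa, ogroup) {
    stored <- st[[paste0("key", slot)]]
    have <- st[[paste0("pass", slot)]]
    if (identical(stored, key) && !is.null(have) &&
        (!grad || !is.null(have$dt))) {
      return(have)
    }
    res <- class_pass(prep, tl, omega_edge, kappa, pi, st$dec,
                      grad = grad, omega_group = ogroup)
    st[[paste0("key", slot)]] <- key
    st[[paste0("pass", slot)]] <- res
    res
  }
  passes <- function(th, grad) {
    pr <- unpack(th)
    if (length(ls(st$dec)) > 120L) st$dec <- new.env(parent = emptyenv())
    p0 <- run_pass("0", c(pr$kappa, pr$omega0, pr$tl), grad, pr$tl,
                   rep(pr$omega0, ne), pr$kappa, rep(0L, ne))
    p1 <- run_pass("1", c(pr$kappa, pr$tl), grad, pr$tl,
                   rep(1, ne), pr$kappa, rep(NA_integer_, ne))
    p2 <- run_pass("2", c(pr$kappa, pr$omega2, pr$tl), grad, pr$tl,
                   pr$omega2[edge_part + 1L], pr$kappa, edge_part)
    list(pr = pr, p0 = p0, p1 = p1, p2 = p2)
  }
  fn <- function(th) {
    ps <- passes(th, grad = FALSE)
    pp <- profile_p(cbind(ps$p0$l, ps$p1$l, ps$p2$l), prep$weights, st$p)
    st$p <- pp$p
    -pp$lnL
  }
  gr <- function(th) {
    ps <- passes(th, grad = TRUE)
    lmat <- cbind(ps$p0$l, ps$p1$l, ps$p2$l)
    pp <- profile_p(lmat, prep$weights, st$p)
    st$p <- pp$p
    p <- pp$p
    m <- pmax(lmat[, 1], lmat[, 2], lmat[, 3])
    e <- exp(lmat - m)
    denom <- as.numeric(e %*% p)
    r <- e * rep(p, each = nrow(e)) / denom      # responsibilities S x 3
    w <- prep$weights
    pr <- ps$pr
    # per-site combined derivatives
    dk <- r[, 1] * ps$p0$dkappa + r[, 2] * ps$p1$dkappa +
      r[, 3] * ps$p2$dkappa
    dw0 <- r[, 1] * ps$p0$domega[1, ]
    dw2 <- vapply(seq_len(K), function(k) {
      row <- match(as.character(k - 1L), rownames(ps$p2$domega))
      if (is.na(row)) rep(0, length(w)) else r[, 3] * ps$p2$domega[row, ]
    }, numeric(length(w)))
    dt <- ps$p0$dt * rep(r[, 1], each = ne) +
      ps$p1$dt * rep(r[, 2], each = ne) +
      ps$p2$dt * rep(r[, 3], each = ne)
    g <- numeric(length(th))
    g[1] <- sum(w * dk) * pr$kappa
    g[2] <- sum(w * dw0) * pr$omega0 * (1 - pr$omega0)
    g[3:(2 + K)] <- as.numeric(w %*% dw2) * pr$omega2
    dte <- as.numeric(dt %*% w)                  # dlnL/dt_e
    if (fix_bl) {
      g[3 + K] <- sum(dte * pr$tl)
    } else {
      g[(3 + K):(2 + K + ne)] <- dte * pr$tl
    }
    -g
  }
  list(fn = fn, gr = gr, state = st, unpack = unpack)
}

#' Fit Clade model C by maximum likelihood
#'
#' Maximizes the Clade model C likelihood over kappa, the site-class
#' proportions (profiled out by an inner EM), omega0, and one divergent
#' omega per clade partition; branch lengths are jointly optimized by
#' default, or held at the input tree's lengths (times a free global rate
#' multiplier) with `fix_branch_lengths = TRUE`. Box-constrained
#' quasi-Newton on log/logit-transformed parameters, with multiple starts.
#'
#' @param aln a `codon_alignment`.
#' @param tree `phylo` with `edge.partition` (see [label_clades()]); branch
#'   lengths in expected substitutions per codon.
#' @param freq codon-frequency estimator (see [codon_frequencies()]), or
#'   supply `pi` directly.
#' @param pi optional explicit sense-codon frequencies.
#' @param fix_branch_lengths keep input branch lengths (plus one free rate
#'   multiplier) instead of optimizing each length.
#' @param n_starts number of optimization starts (default 3: neutral,
#'   spread, random).
#' @param init optional warm-start parameter list (`kappa`, `p`, `omega0`,
#'   `omega2`, and `tl`/`rho` as produced by a previous fit).
#' @param seed seed for the random start.
#' @param control overrides for `iter.max`, `eval.max`, `rel.tol`.
#' @return object of class `cmc_fit`: fitted parameters, `lnL`, `np`,
#'   convergence diagnostics.
#' @export
fit_cmc <- function(aln, tree, freq = "f3x4", pi = NULL,
                    fix_branch_lengths = FALSE, n_starts = 3L,
                    init = NULL, seed = 1L, control = list()) {
  if (is.null(tree$edge.partition))
    stop("tree has no edge.partition labels; run label_clades() first")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  prep <- prepare_pruning(aln, tree)
  if (is.null(pi)) pi <- codon_frequencies(aln, freq)
  check_pi(pi)
  part <- tree$edge.partition
  K <- max(part) + 1L
  ne <- nrow(tree$edge)
  ctrl <- utils::modifyList(list(iter.max = 300L, eval.max = 1500L,
                                 rel.tol = 1e-8), control)
  obj <- make_cmc_objective(prep, part, K, pi, fix_branch_lengths,
                            tree$edge.length)

  pack <- function(kappa, omega0, omega2, bl_par) {
    c(log(kappa), stats::qlogis(omega0), log(omega2), log(bl_par))
  }
  # starting branch parameters convert substitutions/codon into the
  # unnormalized generator's time units
  start_bl <- function(kappa, p, omega0, omega2) {
    rate <- p[1] * gy94_rate(kappa, omega0, pi) +
      p[2] * gy94_rate(kappa, 1, pi) + p[3] * gy94_rate(kappa, omega2[1], pi)
    if (fix_branch_lengths) 1 / rate else pmax(tree$edge.length / rate, 1e-7)
  }
  starts <- list()
  base_p <- rep(1 / 3, 3)
  if (n_starts >= 1)
    starts[[1]] <- pack(2, 0.1, rep(1, K), start_bl(2, base_p, 0.1, rep(1, K)))
  if (n_starts >= 2) {
    om <- 0.5 * 2^(2 * (seq_len(K) - 1))    # spread: 0.5, 2, 8, ...
    starts[[length(starts) + 1]] <- pack(2, 0.05, om,
                                         start_bl(2, base_p, 0.05, om))
  }
  if (n_starts >= 3) {
    set.seed(seed)
    kap <- exp(stats::rnorm(1, log(2), 0.5))
    om0 <- stats::runif(1, 0.02, 0.5)
    om <- exp(stats::rnorm(K, 0, 1))
    starts[[length(starts) + 1]] <- pack(kap, om0, om,
                                         start_bl(kap, base_p, om0, om))
  }
  if (!is.null(init)) {
    blp <- if (fix_branch_lengths) init$rho %||% 1 else init$tl_internal
    if (is.null(blp)) blp <- start_bl(init$kappa, init$p, init$omega0,
                                      init$omega2)
    starts[[length(starts) + 1]] <- pack(init$kappa,
                                         min(max(init$omega0, 1e-6), 1 - 1e-6),
                                         pmax(init$omega2, 1e-4), blp)
    if (!is.null(init$p)) obj$state$p <- init$p
  }
  if (!length(starts)) stop("n_starts = 0 requires an init")
  nbl <- if (fix_branch_lengths) 1L else ne
  lower <- c(log(0.05), stats::qlogis(1e-6), rep(log(1e-4), K),
             rep(log(1e-8), nbl))
  upper <- c(log(100), stats::qlogis(1 - 1e-6), rep(log(99), K),
             rep(log(1e3), nbl))
  best <- NULL
  for (s in starts) {
    res <- stats::nlminb(s, obj$fn, gradient = obj$gr,
                         lower = lower, upper = upper,
                         control = list(iter.max = ctrl$iter.max,
                                        eval.max = ctrl$eval.max,
                                        rel.tol = ctrl$rel.tol))
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  final <- obj$fn(best$par)            # repopulate cache at the optimum
  pr <- obj$unpack(best$par)
  p_hat <- obj$state$p
  rate_hat <- p_hat[1] * gy94_rate(pr$kappa, pr$omega0, pi) +
    p_hat[2] * gy94_rate(pr$kappa, 1, pi) +
    p_hat[3] * gy94_rate(pr$kappa, pr$omega2[1], pi)
  np <- if (fix_branch_lengths) 4L + K + 1L else np_cmc(prep$ntip, K)
  if (fix_branch_lengths) {
    warning("branch lengths fixed to the input tree (plus a global rate ",
            "multiplier); Np = ", np,
            " is not comparable to full joint-estimation fits",
            call. = FALSE)
  }
  structure(list(
    kappa = pr$kappa, p = p_hat, omega0 = pr$omega0, omega2 = pr$omega2,
    lnL = -best$objective, np = np, K = K,
    branch_lengths = pr$tl * rate_hat,
    tl_internal = pr$tl, rho = if (fix_branch_lengths) exp(best$par[3 + K]),
    pi = pi, n_taxa = prep$ntip,
    fix_branch_lengths = fix_branch_lengths,
    convergence = best$convergence, iterations = best$iterations,
    message = best$message
  ), class = "cmc_fit")
}

#' @export
print.cmc_fit <- function(x, ...) {
  cat("Clade model C fit:", x$n_taxa, "taxa,", x$K, "partitions\n")
  cat(sprintf("  lnL = %.4f  (Np = %d)\n", x$lnL, x$np))
  cat(sprintf("  kappa = %.3f\n", x$kappa))
  cat(sprintf("  site classes: p0 = %.3f (omega0 = %.3f), p1 = %.3f (omega = 1), p2 = %.3f\n",
              x$p[1], x$omega0, x$p[2], x$p[3]))
  cat("  divergent-class omega by partition:",
      paste(sprintf("%.3f", x$omega2), collapse = ", "), "\n")
  if (x$convergence != 0) cat("  WARNING: optimizer did not converge:",
                              x$message, "\n")
  invisible(x)
}

#' Nested clade-divergence test (null vs alternate partitioning)
#'
#' Fits the null labeling (focal species as one clade) and the alternate
#' labeling (focal subclades split), warm-starting the alternate fit from
#' the null solution so the statistic cannot go negative by optimization
#' failure, and returns the likelihood-ratio test.
#'
#' @param aln a `codon_alignment`.
#' @param tree unlabeled `phylo`.
#' @param null_map,alt_map named taxon-to-partition integer vectors for the
#'   two labelings; alternate partitions must refine the null's.
#' @param n_starts starts for the null fit.
#' @param alt_n_starts fresh starts for the alternate fit in addition to the
#'   warm start from the null solution (0 = warm start only).
#' @param ... passed to [fit_cmc()].
#' @return list with `fit_null`, `fit_alt`, `lrt`.
#' @export
cmc_test <- function(aln, tree, null_map, alt_map, n_starts = 3L,
                     alt_n_starts = n_starts, ...) {
  tips <- tree$tip.label
  t0 <- label_clades(tree, null_map)
  t1 <- label_clades(tree, alt_map)
  # exact nesting: an edge inside a null partition whose alternate label
  # fell back to background (the combined clade's stem branch) is assigned
  # to the first alternate partition refining that null partition
  orphan <- which(t1$edge.partition == 0L & t0$edge.partition != 0L)
  if (length(orphan)) {
    ks <- sort(unique(alt_map[tips]))
    names(ks) <- ks
    alt_parent <- vapply(ks, function(k) {
      pk <- unique(null_map[tips[alt_map[tips] == k]])
      if (length(pk) != 1L)
        stop("alternate partition ", k, " does not refine the null labeling")
      pk
    }, 0L)
    for (e in orphan) {
      cand <- as.integer(names(alt_parent)[alt_parent ==
                                           t0$edge.partition[e]])
      t1$edge.partition[e] <- cand[cand != 0L][1L]
    }
  }
  fit0 <- fit_cmc(aln, t0, n_starts = n_starts, ...)
  # map each alternate partition onto the null partition of its taxa
  altK <- max(alt_map[tips]) + 1L
  om_init <- vapply(seq_len(altK) - 1L, function(k) {
    taxa_k <- tips[alt_map[tips] == k]
    parent <- unique(null_map[taxa_k])
    if (length(parent) != 1L)
      stop("alternate partition ", k, " does not refine the null labeling")
    fit0$omega2[parent + 1L]
  }, 0)
  warm <- list(kappa = fit0$kappa, p = fit0$p, omega0 = fit0$omega0,
               omega2 = om_init, rho = fit0$rho, tl_internal = fit0$tl_internal)
  fit1 <- fit_cmc(aln, t1, init = warm, n_starts = alt_n_starts, ...)
  list(fit_null = fit0, fit_alt = fit1, lrt = lrt(fit0, fit1))
}

#' Report table for clade-divergence tests
#'
#' One row per fitted model with Np, lnL, kappa, and LR/df/p on the
#' alternate row, in the shape of a published clade-model comparison table.
#'
#' @param test result of [cmc_test()].
#' @param labels length-2 model names.
#' @export
cmc_report <- function(test, labels = c("null_combined", "alternate_split")) {
  data.frame(
    Model = labels,
    Np = c(test$fit_null$np, test$fit_alt$np),
    lnL = c(test$fit_null$lnL, test$fit_alt$lnL),
    kappa = c(test$fit_null$kappa, test$fit_alt$kappa),
    Null = c(NA, labels[1]),
    LR = c(NA, test$lrt$LR),
    df = c(NA, test$lrt$df),
    p = c(NA, test$lrt$p),
    stringsAsFactors = FALSE
  )
}
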