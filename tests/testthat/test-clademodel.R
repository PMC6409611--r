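test_that("the GY94 generator has the required structure", {
  pi <- uniform_pi()
  Q <- build_rate_matrix(2.3, 0.4, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)  # unit rate
  # detailed balance under the reversible parameterization
  set.seed(1)
  pr <- rexp(61) + 0.1; pr <- pr / sum(pr); names(pr) <- names(pi)
  Qr <- build_rate_matrix(1.7, 2.2, pr, normalize = FALSE)
  expect_lt(max(abs(pr * Qr - t(pr * Qr))), 1e-14)
  # multi-step changes are forbidden
  st <- cladiv:::codon_struct()
  expect_true(all(Q[!st$single & !diag(61)] == 0))
  # omega = 0 kills all nonsynonymous rates
  Q0 <- build_rate_matrix(2, 0, pi, normalize = FALSE)
  expect_true(all(Q0[st$single & !st$synonymous] == 0))
})

test_that("transition probabilities are stochastic and form a semigroup", {
  pi <- uniform_pi()
  Q <- build_rate_matrix(2, 0.5, pi)
  expect_equal(transition_probs(Q, 0, pi), diag(61), ignore_attr = TRUE,
               tolerance = 1e-12)
  P <- transition_probs(Q, 0.7, pi)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_equal(transition_probs(Q, 0.2, pi) %*% transition_probs(Q, 0.5, pi),
               P, tolerance = 1e-8)
  expect_error(transition_probs(Q, -1, pi), ">= 0")
})

test_that("pruning equals the exhaustive-state oracle on tiny instances", {
  pi <- uniform_pi()
  for (seed in 1:6) {
    set.seed(seed)
    ntaxa <- sample(3:4, 1)
    tree_txt <- if (ntaxa == 3) "(a:0.2,b:0.35,c:0.15);" else
      "((a:0.2,b:0.35)$1:0.25,c:0.15,d:0.4);"
    tr <- read_newick(text = tree_txt)
    nsites <- sample(1:3, 1)
    seqs <- vapply(seq_len(ntaxa), function(i)
      paste(sample(cladiv:::SENSE_CODONS, nsites, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- letters[seq_len(ntaxa)]
    aln <- codon_alignment(seqs)
    params <- list(kappa = exp(rnorm(1, log(2), 0.3)),
                   p = as.numeric(rexp(3) + 0.2),
                   omega0 = runif(1, 0.05, 0.6),
                   omega2 = c(exp(rnorm(1)), exp(rnorm(1)))[
                     seq_len(max(tr$edge.partition) + 1)],
                   pi = pi)
    params$p <- params$p / sum(params$p)
    expect_equal(cmc_loglik(aln, tr, params),
                 brute_cmc_loglik(aln, tr, params), tolerance = 1e-8)
  }
})

test_that("two taxa at vanishing distance recover the stationary frequency", {
  pi <- uniform_pi()
  tr <- read_newick(text = "(a:1e-9,b:1e-9);")
  aln <- codon_alignment(c(a = "ATG", b = "ATG"))
  params <- list(kappa = 2, p = c(0.3, 0.3, 0.4), omega0 = 0.1,
                 omega2 = 1, pi = pi)
  expect_equal(cmc_loglik(aln, tr, params), log(pi[["ATG"]]),
               tolerance = 1e-6)
})

test_that("equal divergent omegas collapse K partitions to the simpler model", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 2, n_g1 = 2, n_g2 = 2,
                                             n_codons = 40, seed = 19))
  t_null <- label_clades(sim$tree, sim$null_map)
  t_alt <- label_clades(sim$tree, sim$alt_map)
  # make the alternate labeling nest exactly (combined-clade stem -> group 1)
  orphan <- t_alt$edge.partition == 0L & t_null$edge.partition == 1L
  t_alt$edge.partition[orphan] <- 1L
  base <- list(kappa = 2.1, p = c(0.4, 0.3, 0.3), omega0 = 0.15,
               pi = uniform_pi())
  l2 <- cmc_loglik(sim$alignment, t_null, c(base, list(omega2 = c(0.8, 2.5))))
  l3 <- cmc_loglik(sim$alignment, t_alt,
                   c(base, list(omega2 = c(0.8, 2.5, 2.5))))
  expect_equal(l3, l2, tolerance = 1e-10)
})

test_that("the likelihood is invariant to taxon order and rerooting", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 3, n_g1 = 2, n_g2 = 2,
                                             n_codons = 50, seed = 23))
  tr <- label_clades(sim$tree, sim$alt_map)
  params <- list(kappa = 1.8, p = c(0.5, 0.2, 0.3), omega0 = 0.2,
                 omega2 = c(1, 0.5, 2), pi = uniform_pi())
  l <- cmc_loglik(sim$alignment, tr, params)
  perm <- codon_alignment(unclass(sim$alignment)[rev(rownames(sim$alignment)), ])
  expect_equal(cmc_loglik(perm, tr, params), l, tolerance = 1e-9)
  rerooted <- ape::root(sim$tree, outgroup = "bg2", resolve.root = TRUE)
  rerooted <- label_clades(rerooted, sim$alt_map)
  expect_equal(cmc_loglik(sim$alignment, rerooted, params), l,
               tolerance = 1e-6)
})

test_that("analytic gradients match finite differences", {
  sim <- simulate_codon_alignment(sim_config(n_bg = 2, n_g1 = 2, n_g2 = 2,
                                             n_codons = 40, seed = 29))
  tree <- label_clades(sim$tree, sim$alt_map)
  prep <- cladiv:::prepare_pruning(sim$alignment, tree)
  pi <- codon_frequencies(sim$alignment)
  obj <- cladiv:::make_cmc_objective(prep, tree$edge.partition, 3L, pi,
                                     TRUE, tree$edge.length)
  th <- c(log(2.2), stats::qlogis(0.15), log(c(0.9, 0.6, 1.8)), log(4))
  g <- obj$gr(th)
  fd <- vapply(seq_along(th), function(i) {
    h <- 1e-6
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (obj$fn(tp) - obj$fn(tm)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - fd) / (abs(fd) + 1e-3)), 1e-3)
})

test_that("parameter counting follows the clade-model bookkeeping", {
  expect_identical(np_cmc(60, 2), 123L)
  expect_identical(np_cmc(60, 3), 124L)
  expect_identical(np_cmc(60, 3) - np_cmc(60, 2), 1L)
  expect_identical(np_cmc(16, 2), 35L)   # (2n-3) + 4 + K
})

test_that("likelihood-ratio helpers reproduce published-style arithmetic", {
  r <- lrt_from_lnl(-7622.25, -7589.64, df = 1)
  expect_equal(r$LR, 65.22, tolerance = 1e-10)
  r2 <- lrt_from_lnl(-5826.58, -5825.29, df = 1)
  expect_equal(r2$LR, 2.58, tolerance = 1e-10)
  expect_equal(round(r2$p, 3), 0.108)
  same <- lrt_from_lnl(-100, -100)
  expect_equal(same$LR, 0)
  expect_equal(same$p, 1)
})

test_that("chi-square tails are accurate into the far tail", {
  expect_equal(chi2_sf(0, 1), 1)
  expect_equal(round(chi2_sf(2.58, 1), 3), 0.108)
  expect_equal(chi2_sf(65.22, 1), 6.70e-16, tolerance = 2e-3)
  expect_equal(chi2_sf(200, 1), stats::pchisq(200, 1, lower.tail = FALSE))
  expect_error(chi2_sf(-1, 1))
})

test_that("lrt validates nesting direction", {
  f0 <- structure(list(lnL = -100, np = 7L), class = "cmc_fit")
  f1 <- structure(list(lnL = -98, np = 8L), class = "cmc_fit")
  r <- lrt(f0, f1)
  expect_equal(r$LR, 4)
  expect_identical(r$df, 1L)
  expect_error(lrt(f1, f0), "more free parameters")
})

test_that("fitting recovers planted divergent omegas", {
  sim <- simulate_codon_alignment(
    sim_config(n_bg = 4, n_g1 = 4, n_g2 = 4, n_codons = 300,
               window_start = 0, window_len = 300,
               omega2 = c(1, 0.5, 3.0), seed = 31))
  fit <- suppressWarnings(fit_cmc(sim$alignment, sim$tree,
                                  fix_branch_lengths = TRUE, n_starts = 2))
  expect_identical(fit$K, 3L)
  expect_lt(abs(fit$omega2[2] - 0.5) / 0.5, 0.5)
  expect_lt(abs(fit$omega2[3] - 3.0) / 3.0, 0.5)
  expect_gt(fit$omega2[3], fit$omega2[2])
  expect_identical(fit$np, 4L + 3L + 1L)  # fixed-length mode bookkeeping
})

test_that("codon frequency estimators are valid distributions", {
  aln <- random_codon_aln(5, 80, seed = 41)
  for (m in c("f3x4", "f61", "uniform")) {
    f <- codon_frequencies(aln, m)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f > 0))
    expect_identical(length(f), 61L)
  }
})
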