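# In-test oracle for the pair likelihood: builds the codon rate matrix from
# first principles (Biostrings code table), exponentiates it by plain
# eigendecomposition, and integrates the coalescent time with
# stats::integrate.
oracle_pair_loglik <- function(seq1, seq2, mu, kappa, omega) {
  cods <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  c1 <- substring(seq1, seq(1, nchar(seq1), 3), seq(3, nchar(seq1), 3))
  c2 <- substring(seq2, seq(1, nchar(seq2), 3), seq(3, nchar(seq2), 3))
  tab <- tabulate(match(c(c1, c2), cods), nbins = length(cods))
  freqs <- (tab + 0.5) / sum(tab + 0.5 * length(cods))
  K <- length(cods)
  Q <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K) {
    if (i == j) next
    a <- strsplit(cods[i], "")[[1]]; b <- strsplit(cods[j], "")[[1]]
    d <- which(a != b)
    if (length(d) != 1) next
    r <- ifelse(b[d] == ts_partner[[a[d]]], kappa, 1)
    if (Biostrings::GENETIC_CODE[cods[i]] != Biostrings::GENETIC_CODE[cods[j]])
      r <- r * omega
    Q[i, j] <- r * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(freqs * diag(Q)))
  e <- eigen(Q)
  Pt <- function(d) Re(e$vectors %*% diag(exp(e$values * d)) %*%
                         solve(e$vectors))
  i1 <- match(c1, cods); i2 <- match(c2, cods)
  site_ll <- function(t) {
    P <- Pt(mu * t)
    sum(log(freqs[i1] * pmax(P[cbind(i1, i2)], 1e-300)))
  }
  ref <- site_ll(1)  # center the exponent for a stable integrand
  val <- stats::integrate(function(tv)
    vapply(tv, function(t) exp(site_ll(t) - ref) * exp(-t), 0),
    lower = 0, upper = 60, rel.tol = 1e-10)$value
  ref + log(val)
}

toy_pair <- rbind(
  strsplit(codrep("TTT", 30), "")[[1]],
  strsplit(paste(c(rep("TTT", 29), "TTC"), collapse = ""), "")[[1]])

test_that("the quadrature likelihood converges to an adaptive integration oracle", {
  want <- oracle_pair_loglik(paste(toy_pair[1, ], collapse = ""),
                             paste(toy_pair[2, ], collapse = ""),
                             0.05, 2, 0.5)
  fine <- composite_loglik(toy_pair, 0.05, 2, 0.5, quad_nodes = 160)
  expect_lt(abs(fine - want), 1e-3)
  got16 <- composite_loglik(toy_pair, 0.05, 2, 0.5, quad_nodes = 16)
  expect_lt(abs(got16 - want), 0.5)
})

test_that("the likelihood of a synonymous-difference pair decreases in omega beyond its maximum", {
  lls <- vapply(c(0.5, 1, 2, 4, 8), function(om)
    composite_loglik(toy_pair, 0.05, 2, om), 0)
  expect_true(all(diff(lls) < 0))
})

test_that("the composite likelihood is invariant to haplotype order and flat in omega for monomorphic data", {
  set.seed(3)
  g <- generate_gene_dataset(synthetic_config(L_codons = 80L), "GRP",
                             seed = 52)
  m <- alignment_matrix(g$symp_A)
  l1 <- composite_loglik(m, 0.05, 2, 0.5)
  l2 <- composite_loglik(m[sample(nrow(m)), ], 0.05, 2, 0.5)
  expect_equal(l1, l2, tolerance = 1e-10)
  # monomorphic data: likelihood is maximized as mu shrinks to the prior
  # floor, where any residual omega dependence (via the rate normalization)
  # vanishes
  mono <- do.call(rbind, rep(list(strsplit(codrep("ACG", 50), "")[[1]]), 4))
  expect_gt(composite_loglik(mono, 1e-4, 2, 1),
            composite_loglik(mono, 0.1, 2, 1))
  expect_gt(composite_loglik(mono, 1e-5, 2, 1),
            composite_loglik(mono, 1e-3, 2, 1))
  expect_equal(composite_loglik(mono, 1e-5, 2, 0.2),
               composite_loglik(mono, 1e-5, 2, 2.0), tolerance = 1e-6)
})

test_that("the MCMC is seeded-deterministic and flags uninformative samples", {
  set.seed(4)
  g <- generate_gene_dataset(synthetic_config(L_codons = 60L), "GRP",
                             seed = 61)
  mc <- mcmc_config(iterations = 300, thinning = 3, burn_in_fraction = 0.2,
                    seed = 17)
  r1 <- run_mcmc(g$symp_A, mc)
  r2 <- run_mcmc(g$symp_A, mc)
  expect_identical(r1$draws, r2$draws)
  expect_true(all(r1$draws > 0))
  mono <- codon_alignment(rep(codrep("ACG", 40), 6),
                          ids = paste0("s", 1:6))
  rmono <- run_mcmc(mono, mc)
  expect_equal(rmono$na_reason, "Not enough variation")
  expect_null(rmono$draws)
})

test_that("with the likelihood switched off the sampler reproduces the truncated reciprocal prior", {
  mc <- mcmc_config(iterations = 30000, thinning = 10,
                    burn_in_fraction = 0.1, seed = 31, proposal_sd = 3)
  r <- run_mcmc(NULL, mc, use_likelihood = FALSE)
  lo <- log(1e-6); hi <- log(1e3)
  expect_true(all(r$draws >= 1e-6 & r$draws <= 1e3))
  for (p in c("mu", "kappa", "omega")) {
    q <- quantile(log(r$draws[, p]), c(0.25, 0.5, 0.75))
    theo <- lo + c(0.25, 0.5, 0.75) * (hi - lo)
    expect_lt(max(abs(q - theo)), 1.0)  # log-scale agreement within MC error
  }
})

test_that("combine_runs concatenates matching runs and flags disjoint ones", {
  draws <- matrix(rlnorm(300, c(-2, 1, -0.5), 0.2), ncol = 3, byrow = TRUE,
                  dimnames = list(NULL, c("mu", "kappa", "omega")))
  mk_run <- function(d, id) structure(
    list(draws = d, acceptance = c(mu = .3, kappa = .3, omega = .3),
         na_reason = NULL, run_id = id, config = mcmc_config(seed = 1)),
    class = "posterior_sample")
  r1 <- mk_run(draws, "run1"); r2 <- mk_run(draws, "run2")
  cb <- combine_runs(r1, r2)
  expect_true(cb$matched)
  expect_equal(nrow(cb$sample$draws), 200L)
  r3 <- mk_run(draws * 25, "run3")  # disjoint credible intervals
  cb2 <- combine_runs(r1, r3)
  expect_false(cb2$matched)
  expect_null(cb2$sample)
})

test_that("posterior differences summarize omega_pop1 - omega_pop2", {
  mk_run <- function(omegas) structure(
    list(draws = cbind(mu = rep(0.1, length(omegas)),
                       kappa = rep(2, length(omegas)), omega = omegas),
         acceptance = NULL, na_reason = NULL, run_id = "r",
         config = mcmc_config(seed = 1)), class = "posterior_sample")
  # point masses: difference exactly 0.2, zero-width interval, excludes 0
  d <- posterior_difference(mk_run(rep(0.5, 100)), mk_run(rep(0.3, 100)),
                            seed = 2)
  expect_equal(d$mean_diff, 0.2)
  expect_equal(d$cri_low, 0.2); expect_equal(d$cri_high, 0.2)
  expect_false(d$contains_zero)
  # a sample against a shifted copy: mean -1, excludes zero
  set.seed(5); w <- rlnorm(500, -0.7, 0.1)
  d2 <- posterior_difference(mk_run(w), mk_run(w + 1), seed = 3)
  expect_lt(abs(d2$mean_diff + 1), 0.05)
  expect_false(d2$contains_zero)
  # self-comparison centers on zero
  d3 <- posterior_difference(mk_run(w), mk_run(w), seed = 4)
  expect_lt(abs(d3$mean_diff), 0.05)
  expect_true(d3$contains_zero)
  # NA propagation mirrors the not-enough-variation verdict
  na_run <- structure(list(draws = NULL, acceptance = NULL,
                           na_reason = "Not enough variation", run_id = "r",
                           config = mcmc_config(seed = 1)),
                      class = "posterior_sample")
  dna <- posterior_difference(na_run, mk_run(w))
  expect_true(is.na(dna$mean_diff))
  expect_equal(dna$na_reason, "Not enough variation")
})
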