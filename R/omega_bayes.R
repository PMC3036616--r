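## Bayesian constant-omega inference from a population sample of coding
## haplotypes. The likelihood is a pairwise composite approximation: each
## unordered haplotype pair is modelled under an NY98-style codon
## substitution model (transition bias kappa, nonsynonymous weight omega,
## empirical codon frequencies) at a divergence mu * t, with the pair
## coalescent time t ~ Exponential(1) integrated out by Gauss-Laguerre
## quadrature. Metropolis-Hastings with log-scale random walks samples
## (mu, kappa, omega) under reciprocal priors truncated to a positive box.

#' MCMC configuration for the constant-omega model
#'
#' @param iterations Total Metropolis-Hastings iterations (default 250000).
#'   One randomly chosen parameter is updated per iteration.
#' @param thinning Keep every \code{thinning}-th iteration (default 1000).
#' @param burn_in_fraction Fraction of iterations discarded from the start
#'   (default 0.2); burn-in is automated rather than judged from traces.
#' @param init_mu,init_kappa,init_omega Initial parameter values (defaults
#'   0.1, 3.0, 0.5).
#' @param prior_lower,prior_upper Truncation bounds making the reciprocal
#'   (1/x) prior proper (defaults 1e-6 and 1e3, shared by all parameters).
#' @param proposal_sd Standard deviation of the log-scale Gaussian random
#'   walk (default 0.4).
#' @param quad_nodes Gauss-Laguerre nodes for the coalescent-time
#'   integration (default 16).
#' @param seed Optional integer seed.
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(iterations = 250000L, thinning = 1000L,
                        burn_in_fraction = 0.2, init_mu = 0.1,
                        init_kappa = 3.0, init_omega = 0.5,
                        prior_lower = 1e-6, prior_upper = 1e3,
                        proposal_sd = 0.4, quad_nodes = 16L, seed = NULL) {
  stopifnot(iterations >= 1, thinning >= 1, burn_in_fraction >= 0,
            burn_in_fraction < 1, prior_lower > 0,
            prior_upper > prior_lower, quad_nodes >= 2)
  retained <- floor(iterations * (1 - burn_in_fraction) / thinning)
  if (retained < 50)
    warning("fewer than 50 retained draws with this iterations/thinning setting")
  structure(list(iterations = as.integer(iterations),
                 thinning = as.integer(thinning),
                 burn_in_fraction = burn_in_fraction,
                 init_mu = init_mu, init_kappa = init_kappa,
                 init_omega = init_omega, prior_lower = prior_lower,
                 prior_upper = prior_upper, proposal_sd = proposal_sd,
                 quad_nodes = as.integer(quad_nodes), seed = seed),
            class = "mcmc_config")
}

# Single-nucleotide codon neighbour structure of the 61 sense codons:
# for each ordered sense pair differing at one position, whether the change
# is a transition and whether it is synonymous.
.codon_model_struct <- local({
  cods <- names(.genetic_code)[.genetic_code != "*"]
  K <- length(cods)
  splitc <- strsplit(cods, "")
  from <- integer(0); to <- integer(0); ts <- logical(0); syn <- logical(0)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    d <- which(splitc[[i]] != splitc[[j]])
    if (length(d) != 1L) next
    b1 <- splitc[[i]][d]; b2 <- splitc[[j]][d]
    from <- c(from, i); to <- c(to, j)
    ts <- c(ts, b2 == c(A = "G", G = "A", C = "T", T = "C")[[b1]])
    syn <- c(syn, .genetic_code[cods[i]] == .genetic_code[cods[j]])
  }
  list(codons = cods, K = K, from = from, to = to, ts = ts, syn = syn)
})

# NY98-style rate matrix, normalized to one expected substitution per codon
# site per unit divergence, and its symmetric eigendecomposition.
.codon_eigen <- function(kappa, omega, freqs) {
  st <- .codon_model_struct
  K <- st$K
  Q <- matrix(0, K, K)
  rate <- ifelse(st$ts, kappa, 1) * ifelse(st$syn, 1, omega)
  Q[cbind(st$from, st$to)] <- rate * freqs[st$to]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  if (scale <= 0) return(NULL)
  Q <- Q / scale
  ds <- sqrt(freqs)
  S <- Q * (ds %o% (1 / ds))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       A = e$vectors / ds,          # A[x,k] = U[x,k] / sqrt(pi_x)
       B = t(e$vectors * ds))       # B[k,y] = U[y,k] * sqrt(pi_y)
}

# Site-pattern summary of an alignment for the composite likelihood:
# unique haplotypes (restricted to complete, stop-free codon columns),
# pair weights, and per-pair codon-pair counts referencing a shared index.
.pair_pattern_data <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  cods_idx <- .clean_codons(.clean_cols(m))
  st <- .codon_model_struct
  hap <- vapply(seq_len(n), function(i) {
    paste(m[i, ], collapse = "")
  }, "")
  # codon index matrix, dropping columns with stops or unresolved codons
  cmat <- matrix(0L, n, length(cods_idx))
  keep <- rep(TRUE, length(cods_idx))
  for (jj in seq_along(cods_idx)) {
    ci <- cods_idx[jj]
    cod <- substring(hap, 3L * ci - 2L, 3L * ci)
    idx <- match(cod, st$codons)
    if (anyNA(idx)) { keep[jj] <- FALSE; next }
    cmat[, jj] <- idx
  }
  cmat <- cmat[, keep, drop = FALSE]
  if (ncol(cmat) == 0L) stop("no analyzable codons for the codon model")
  key <- apply(cmat, 1L, paste, collapse = ",")
  utab <- table(key)
  ukey <- names(utab)
  H <- cmat[match(ukey, key), , drop = FALSE]
  cntu <- as.integer(utab)
  u <- nrow(H)
  # empirical codon frequencies with a small regularizing pseudocount
  tab <- tabulate(as.integer(t(cmat)), nbins = st$K)
  freqs <- (tab + 0.5) / sum(tab + 0.5 * st$K)
  pair_id <- integer(0); upos_all <- integer(0); cnt_all <- numeric(0)
  w <- numeric(0); pid <- 0L
  lin_all <- list()
  for (i in seq_len(u)) for (j in i:u) {
    wp <- if (i == j) choose(cntu[i], 2) else cntu[i] * cntu[j]
    if (wp == 0) next
    pid <- pid + 1L
    w[pid] <- wp
    li <- H[i, ] + st$K * (H[j, ] - 1L)
    t1 <- table(li)
    lin_all[[pid]] <- cbind(as.integer(names(t1)), as.numeric(t1))
  }
  npairs <- pid
  allidx <- unlist(lapply(lin_all, function(x) x[, 1]))
  uidx <- sort(unique(allidx))
  entries <- do.call(rbind, lapply(seq_len(npairs), function(p) {
    cbind(p, match(lin_all[[p]][, 1], uidx), lin_all[[p]][, 2])
  }))
  xs <- ((uidx - 1L) %% st$K) + 1L
  ys <- ((uidx - 1L) %/% st$K) + 1L
  # composite-likelihood calibration: the C(n,2) pairs overlap on one
  # genealogy, so the summed pair log-likelihood is rescaled to the
  # information of the n - 1 effectively independent contrasts a sample of
  # n contributes; without this the posterior curvature is overstated by
  # roughly n/2 and credible intervals are badly anti-conservative
  list(n = n, n_unique = u, n_sites = ncol(cmat), npairs = npairs,
       weights = w, entries = entries, xs = xs, ys = ys, freqs = freqs,
       scale = (n - 1) / sum(w),
       segregating = any(apply(cmat, 2L, function(z) length(unique(z)) > 1L)))
}

# Composite log-likelihood given precomputed pattern data and (optionally
# cached) eigendecomposition.
.composite_ll <- function(pd, mu, kappa, omega, quad, eig) {
  if (is.null(eig)) return(-Inf)
  nq <- length(quad$x)
  m <- length(pd$xs)
  M1 <- eig$A[pd$xs, , drop = FALSE]
  M2 <- t(eig$B)[pd$ys, , drop = FALSE]
  M12 <- M1 * M2
  lp <- log(pd$freqs[pd$xs])
  ll_entries <- matrix(0, m, nq)
  for (q in seq_len(nq)) {
    pv <- as.vector(M12 %*% exp(eig$values * mu * quad$x[q]))
    ll_entries[, q] <- lp + log(pmax(pv, 1e-300))
  }
  ll_pairs <- rowsum(pd$entries[, 3] * ll_entries[pd$entries[, 2], , drop = FALSE],
                     pd$entries[, 1])
  lw <- log(quad$w)
  persite <- sweep(ll_pairs, 2L, lw, "+")
  mx <- apply(persite, 1L, max)
  lse <- mx + log(rowSums(exp(persite - mx)))
  pd$scale * sum(pd$weights * lse)
}

#' Composite log-likelihood of a population sample under the constant-omega model
#'
#' Sums, over all unordered haplotype pairs, the log-probability of the pair
#' under the codon substitution model at divergence mu * t, integrating the
#' pair coalescent time t ~ Exponential(1) by Gauss-Laguerre quadrature.
#' Because the pairs share a single genealogy, the summed pair
#' log-likelihood is rescaled by (n - 1) / C(n, 2) so its information
#' content matches the n - 1 effectively independent contrasts in the
#' sample; posterior credible intervals are otherwise severely
#' anti-conservative.
#'
#' @param aln A \code{codon_alignment} (n >= 2) or character matrix.
#' @param mu Scaled mutation rate (expected substitutions per codon site per
#'   coalescent time unit).
#' @param kappa Transition/transversion rate ratio.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param quad_nodes Number of quadrature nodes (default 16).
#' @return The composite log-likelihood (-Inf at unusable parameter values).
#' @export
composite_loglik <- function(aln, mu, kappa, omega, quad_nodes = 16L) {
  if (any(c(mu, kappa, omega) <= 0)) return(-Inf)
  pd <- .pair_pattern_data(aln)
  quad <- pracma::gaussLaguerre(quad_nodes)
  names(quad) <- c("x", "w")
  eig <- .codon_eigen(kappa, omega, pd$freqs)
  .composite_ll(pd, mu, kappa, omega, quad, eig)
}

#' Run the constant-omega MCMC on one population sample
#'
#' Metropolis-Hastings with independent log-scale Gaussian random-walk
#' proposals; one of (mu, kappa, omega) is updated per iteration. The
#' truncated reciprocal prior is uniform on the log scale, so the
#' acceptance ratio is the likelihood ratio within the support box.
#' Samples with fewer than two distinct haplotypes (no segregating
#' variation) are flagged \code{"Not enough variation"} and produce no
#' draws.
#'
#' @param aln A \code{codon_alignment} with at least 2 sequences.
#' @param config An \code{mcmc_config}.
#' @param run_id Label attached to the run.
#' @param use_likelihood Internal switch; FALSE samples the prior only
#'   (used to validate the sampler against the known truncated reciprocal
#'   prior).
#' @return An object of class \code{posterior_sample}: \code{draws} (matrix
#'   with columns mu, kappa, omega), \code{acceptance} rates per parameter,
#'   \code{na_reason} (NULL for informative runs), \code{run_id},
#'   \code{config}.
#' @export
run_mcmc <- function(aln, config = mcmc_config(), run_id = "run1",
                     use_likelihood = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  pd <- if (use_likelihood) .pair_pattern_data(aln) else NULL
  if (use_likelihood && (pd$n_unique < 2L || !pd$segregating)) {
    return(structure(list(draws = NULL, acceptance = NULL,
                          na_reason = "Not enough variation",
                          run_id = run_id, config = config),
                     class = "posterior_sample"))
  }
  quad <- pracma::gaussLaguerre(config$quad_nodes)
  names(quad) <- c("x", "w")
  lo <- log(config$prior_lower); hi <- log(config$prior_upper)
  y <- log(c(mu = config$init_mu, kappa = config$init_kappa,
             omega = config$init_omega))
  eig_cache <- NULL; cache_key <- c(NA_real_, NA_real_)
  get_eig <- function(kappa, omega) {
    if (!identical(cache_key, c(kappa, omega))) {
      eig_cache <<- .codon_eigen(kappa, omega, pd$freqs)
      cache_key <<- c(kappa, omega)
    }
    eig_cache
  }
  ll <- function(yv) {
    if (!use_likelihood) return(0)
    x <- exp(yv)
    .composite_ll(pd, x[1], x[2], x[3], quad, get_eig(x[2], x[3]))
  }
  cur_ll <- ll(y)
  n_iter <- config$iterations
  prop <- integer(3); acc <- integer(3)
  keep_at <- seq_len(n_iter)
  burn <- floor(config$burn_in_fraction * n_iter)
  keep_at <- keep_at[keep_at > burn & keep_at %% config$thinning == 0L]
  draws <- matrix(NA_real_, length(keep_at), 3L,
                  dimnames = list(NULL, c("mu", "kappa", "omega")))
  ki <- 1L
  # restore eigen cache coherence when a (kappa, omega) proposal is rejected
  for (it in seq_len(n_iter)) {
    p <- sample.int(3L, 1L)
    ynew <- y
    ynew[p] <- y[p] + rnorm(1L, 0, config$proposal_sd)
    prop[p] <- prop[p] + 1L
    if (ynew[p] >= lo && ynew[p] <= hi) {
      new_ll <- ll(ynew)
      if (is.finite(new_ll) && log(runif(1)) < new_ll - cur_ll) {
        y <- ynew; cur_ll <- new_ll
        acc[p] <- acc[p] + 1L
      }
    }
    if (ki <= length(keep_at) && it == keep_at[ki]) {
      draws[ki, ] <- exp(y)
      ki <- ki + 1L
    }
  }
  structure(list(draws = draws,
                 acceptance = setNames(acc / pmax(prop, 1L),
                                       c("mu", "kappa", "omega")),
                 na_reason = NULL, run_id = run_id, config = config),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  if (!is.null(x$na_reason)) {
    cat(sprintf("posterior_sample %s: NA (%s)\n", x$run_id, x$na_reason))
  } else {
    q <- quantile(x$draws[, "omega"], c(0.025, 0.5, 0.975))
    cat(sprintf("posterior_sample %s: %d draws; omega median %.3f [%.3f, %.3f]\n",
                x$run_id, nrow(x$draws), q[2], q[1], q[3]))
  }
  invisible(x)
}

#' Combine two independent MCMC runs after a convergence cross-check
#'
#' Runs are concatenated only when, for every parameter, the two run means
#' and both 95% credible-interval endpoints agree within
#' \code{tolerance} pooled standard deviations; otherwise a mismatch flag
#' is raised and no combined sample is returned (more iterations are
#' needed).
#'
#' @param run1,run2 \code{posterior_sample}s from the same data and
#'   configuration, differing in seed.
#' @param tolerance Agreement tolerance in pooled-SD units (default 0.5).
#' @return List with \code{matched} (logical), \code{sample} (the combined
#'   \code{posterior_sample}, or NULL on mismatch) and a per-parameter
#'   diagnostic table.
#' @export
combine_runs <- function(run1, run2, tolerance = 0.5) {
  if (!is.null(run1$na_reason) || !is.null(run2$na_reason)) {
    reason <- c(run1$na_reason, run2$na_reason)[1]
    return(list(matched = NA, sample = structure(
      list(draws = NULL, acceptance = NULL, na_reason = reason,
           run_id = "combined", config = run1$config),
      class = "posterior_sample"), diagnostics = NULL))
  }
  pars <- colnames(run1$draws)
  diag_tab <- do.call(rbind, lapply(pars, function(p) {
    d1 <- run1$draws[, p]; d2 <- run2$draws[, p]
    sd_pool <- sd(c(d1, d2))
    q1 <- quantile(d1, c(0.025, 0.975)); q2 <- quantile(d2, c(0.025, 0.975))
    if (sd_pool == 0) {
      ok <- mean(d1) == mean(d2)
      dev <- 0
    } else {
      dev <- max(abs(mean(d1) - mean(d2)), abs(q1 - q2)) / sd_pool
      ok <- dev <= tolerance
    }
    data.frame(parameter = p, max_deviation_sd = dev, matched = ok)
  }))
  if (!all(diag_tab$matched))
    return(list(matched = FALSE, sample = NULL, diagnostics = diag_tab))
  comb <- run1
  comb$draws <- rbind(run1$draws, run2$draws)
  comb$run_id <- "combined"
  list(matched = TRUE, sample = comb, diagnostics = diag_tab)
}

#' Posterior difference of omega between two populations
#'
#' Randomly pairs \code{draws_B} omega draws (with replacement) from each
#' posterior sample and summarizes the distribution of
#' omega_pop1 - omega_pop2: posterior mean, equal-tailed 95% credible
#' interval, and whether the interval contains zero (in which case the two
#' omega values are not significantly different).
#'
#' @param sample_pop1,sample_pop2 \code{posterior_sample}s (typically
#'   combined runs) for the two populations.
#' @param draws_B Number of difference draws (default: the larger retained
#'   sample size).
#' @param seed Optional seed for the pairing.
#' @return An object of class \code{omega_comparison}: \code{mean_diff},
#'   \code{cri_low}, \code{cri_high}, \code{contains_zero},
#'   \code{na_reason} (set when either sample is flagged uninformative).
#' @export
posterior_difference <- function(sample_pop1, sample_pop2, draws_B = NULL,
                                 seed = NULL) {
  na1 <- sample_pop1$na_reason; na2 <- sample_pop2$na_reason
  if (!is.null(na1) || !is.null(na2)) {
    return(structure(list(mean_diff = NA_real_, cri_low = NA_real_,
                          cri_high = NA_real_, contains_zero = NA,
                          na_reason = c(na1, na2)[1]),
                     class = "omega_comparison"))
  }
  if (!is.null(seed)) set.seed(seed)
  w1 <- sample_pop1$draws[, "omega"]; w2 <- sample_pop2$draws[, "omega"]
  if (is.null(draws_B)) draws_B <- max(length(w1), length(w2))
  d <- sample(w1, draws_B, replace = TRUE) - sample(w2, draws_B, replace = TRUE)
  ci <- unname(quantile(d, c(0.025, 0.975)))
  structure(list(mean_diff = mean(d), cri_low = ci[1], cri_high = ci[2],
                 contains_zero = ci[1] <= 0 && ci[2] >= 0,
                 na_reason = NULL),
            class = "omega_comparison")
}

#' @export
print.omega_comparison <- function(x, ...) {
  if (!is.null(x$na_reason)) {
    cat(sprintf("omega comparison: NA (%s)\n", x$na_reason))
  } else {
    cat(sprintf("omega difference: mean %.3f, 95%% CrI [%.3f, %.3f] -> %s\n",
                x$mean_diff, x$cri_low, x$cri_high,
                ifelse(x$contains_zero, "not significantly different",
                       "significantly different")))
  }
  invisible(x)
}
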