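## Two-lineage synthetic data generator: structured-coalescent genealogies
## (lineages A and B splitting tau coalescent units ago, optional migration
## between the sympatric demes), codon sequences evolved with a
## transition-biased mutation process and a per-mutation nonsynonymous
## acceptance filter giving each gene class a known dN/dS truth.

#' Configuration for the synthetic two-lineage study design
#'
#' Defaults emulate the study conditions: at least 10 diploid individuals
#' per population (20 haplotypes), 300 codons per gene, per-gene diversity
#' giving within-population pi of a few parts per thousand, and a split
#' deep enough that between-lineage p-distance falls in the few-percent to
#' ~0.12 range observed between the two cryptic lineages.
#'
#' @param tau Split time of lineages A and B, in coalescent units (default 12).
#' @param theta_A,theta_B Per-gene diversity parameter of each lineage
#'   (default 10; per-site theta is then theta / (3 L_codons)).
#' @param m_sym Migration rate between the sympatric A and B demes
#'   (default 0; introgression is limited in the contact zone).
#' @param omega_grp,omega_control Nonsynonymous acceptance probability for
#'   candidate gamete-recognition genes (default 0.6) and control genes
#'   (default 0.1), which is the realized dN/dS truth of each class.
#' @param n_individuals Diploid individuals per population (default 10,
#'   giving 2n haplotypes).
#' @param L_codons Codons per gene (default 300).
#' @param kappa_true Transition/transversion proposal bias (default 2).
#' @param haploid Simulate a haploid, organelle-like gene (mtCOI-style):
#'   one haplotype per individual.
#' @param seed Optional integer seed.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(tau = 12, theta_A = 10, theta_B = 10,
                             m_sym = 0, omega_grp = 0.6, omega_control = 0.1,
                             n_individuals = 10L, L_codons = 300L,
                             kappa_true = 2, haploid = FALSE, seed = NULL) {
  stopifnot(tau >= 0, theta_A >= 0, theta_B >= 0, m_sym >= 0,
            omega_grp > 0, omega_control > 0, n_individuals >= 2,
            L_codons >= 1, kappa_true > 0)
  structure(list(tau = tau, theta_A = theta_A, theta_B = theta_B,
                 m_sym = m_sym, omega_grp = omega_grp,
                 omega_control = omega_control,
                 n_individuals = as.integer(n_individuals),
                 L_codons = as.integer(L_codons), kappa_true = kappa_true,
                 haploid = haploid, seed = seed),
            class = "synthetic_config")
}

# Structured-coalescent genealogy for the 4-population design. Tips are
# labelled with deme (A/B) and sympatric flag; sympatric lineages may
# migrate between demes at rate m_sym per lineage until the split time tau,
# when the demes merge. Deme B's coalescence rate is scaled by
# theta_A/theta_B (population size proportional to theta), so mutations can
# be dropped at the single rate theta_A/2 per lineage.
.sim_genealogy <- function(n_per_pop, tau, theta_A, theta_B, m_sym) {
  demes <- rep(c("A", "A", "B", "B"), each = n_per_pop)
  symp <- rep(c(TRUE, FALSE, TRUE, FALSE), each = n_per_pop)
  N <- length(demes)
  act <- data.frame(node = seq_len(N), deme = demes, symp = symp,
                    stringsAsFactors = FALSE)
  times <- numeric(2L * N - 1L)
  child1 <- integer(2L * N - 1L); child2 <- integer(2L * N - 1L)
  nxt <- N + 1L
  t <- 0; merged <- (tau == 0)
  if (merged) act$deme <- "anc"
  # deme sizes scale with theta; with degenerate theta values fall back to
  # equal sizes (theta = 0 disables mutation, not the genealogy)
  rate_B <- if (theta_A > 0 && theta_B > 0) theta_A / theta_B else 1
  while (nrow(act) > 1L) {
    kA <- sum(act$deme == "A"); kB <- sum(act$deme == "B")
    kanc <- sum(act$deme == "anc")
    r_cA <- kA * (kA - 1) / 2
    r_cB <- kB * (kB - 1) / 2 * rate_B
    r_canc <- kanc * (kanc - 1) / 2
    r_mig <- if (!merged) m_sym * sum(act$symp) else 0
    total <- r_cA + r_cB + r_canc + r_mig
    if (total == 0) { t <- tau } else { t <- t + rexp(1, total) }
    if (!merged && t >= tau) {
      t <- tau; merged <- TRUE; act$deme <- "anc"
      next
    }
    u <- runif(1) * total
    if (u < r_mig) {
      cand <- which(act$symp)
      i <- cand[sample.int(length(cand), 1L)]
      act$deme[i] <- if (act$deme[i] == "A") "B" else "A"
    } else {
      u <- u - r_mig
      d <- if (u < r_cA) "A" else if (u < r_cA + r_cB) "B" else "anc"
      cand <- which(act$deme == d)
      ij <- cand[sample.int(length(cand), 2L)]
      times[nxt] <- t
      child1[nxt] <- act$node[ij[1]]; child2[nxt] <- act$node[ij[2]]
      act$node[ij[1]] <- nxt
      act$symp[ij[1]] <- act$symp[ij[1]] || act$symp[ij[2]]
      act <- act[-ij[2], ]
      nxt <- nxt + 1L
    }
  }
  list(root = nxt - 1L, times = times, child1 = child1, child2 = child2,
       n_tips = N)
}

# Transition partner of each base.
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# Evolve codon sequences down a genealogy. Mutation attempts fall at rate
# theta/2 per lineage per unit time; each picks a uniform nucleotide site
# and a new base with transition weight kappa; attempts creating a stop
# codon are redrawn, nonsynonymous attempts are retained with probability
# omega_class. Returns a character matrix of codons (tips x L_codons) plus
# the count of stop-rejected draws.
.evolve_sequences <- function(gen, L_codons, theta, kappa, omega_class) {
  root_seq <- sample(sense_codons(), L_codons, replace = TRUE)
  n_stop_redraws <- 0L
  tips <- vector("list", gen$n_tips)
  mutate_branch <- function(seq, blen) {
    n_mut <- rpois(1L, blen * theta / 2)
    for (m in seq_len(n_mut)) {
      for (try in 1:100) {
        s <- sample.int(3L * L_codons, 1L)
        ci <- (s - 1L) %/% 3L + 1L; pos <- (s - 1L) %% 3L + 1L
        cod <- strsplit(seq[ci], "")[[1]]
        alts <- setdiff(c("A", "C", "G", "T"), cod[pos])
        w <- ifelse(alts == .TS_PARTNER[[cod[pos]]], kappa, 1)
        newb <- sample(alts, 1L, prob = w)
        newcod <- cod; newcod[pos] <- newb
        newc <- paste(newcod, collapse = "")
        if (.genetic_code[newc] == "*") {
          n_stop_redraws <<- n_stop_redraws + 1L
          next
        }
        if (.genetic_code[newc] != .genetic_code[seq[ci]] &&
            runif(1) > omega_class) break  # nonsynonymous attempt rejected
        seq[ci] <- newc
        break
      }
    }
    seq
  }
  recurse <- function(node, seq, node_time) {
    if (node <= gen$n_tips) { tips[[node]] <<- seq; return(invisible()) }
    for (ch in c(gen$child1[node], gen$child2[node])) {
      blen <- node_time - gen$times[ch]
      recurse(ch, mutate_branch(seq, blen), gen$times[ch])
    }
  }
  recurse(gen$root, root_seq, gen$times[gen$root])
  list(tips = tips, n_stop_redraws = n_stop_redraws)
}

#' Generate one gene's synthetic dataset
#'
#' Produces the four population samples of the study design (sympatric and
#' allopatric samples of lineages A and B) plus a 2 + 2 divergence panel
#' (two allopatric haplotypes per lineage, matching a design that sequences
#' two individuals per lineage for divergence estimation).
#'
#' @param config A \code{synthetic_config}.
#' @param gene_class \code{"GRP"} (elevated nonsynonymous acceptance) or
#'   \code{"control"}.
#' @param gene_name Gene label.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return An object of class \code{gene_dataset}: list with
#'   \code{codon_alignment}s \code{symp_A}, \code{allo_A}, \code{symp_B},
#'   \code{allo_B}, \code{panel_A}, \code{panel_B}, and a \code{truth} list
#'   recording the generating parameters.
#' @export
generate_gene_dataset <- function(config, gene_class = c("GRP", "control"),
                                  gene_name = "gene", seed = NULL) {
  gene_class <- match.arg(gene_class)
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  omega_class <- if (gene_class == "GRP") config$omega_grp else config$omega_control
  n_hap <- if (config$haploid) config$n_individuals else 2L * config$n_individuals
  gen <- .sim_genealogy(n_hap, config$tau, config$theta_A, config$theta_B,
                        config$m_sym)
  ev <- .evolve_sequences(gen, config$L_codons, config$theta_A,
                          config$kappa_true, omega_class)
  seqs <- vapply(ev$tips, paste, "", collapse = "")
  grp <- rep(1:4, each = n_hap)  # sympA, alloA, sympB, alloB
  mk <- function(i, lin, ctx, prefix) {
    codon_alignment(seqs[grp == i],
                    ids = paste0(prefix, "_", seq_len(n_hap)),
                    gene_name = gene_name, lineage = lin, context = ctx)
  }
  allo_A <- mk(2, "A", "allopatric", "alloA")
  allo_B <- mk(4, "B", "allopatric", "alloB")
  panel <- function(allo, lin) {
    codon_alignment(allo$sequences[1:2], ids = paste0("panel", lin, "_", 1:2),
                    gene_name = gene_name, lineage = lin,
                    context = "divergence_panel")
  }
  structure(list(
    symp_A = mk(1, "A", "sympatric", "sympA"),
    allo_A = allo_A,
    symp_B = mk(3, "B", "sympatric", "sympB"),
    allo_B = allo_B,
    panel_A = panel(allo_A, "A"),
    panel_B = panel(allo_B, "B"),
    truth = list(gene_name = gene_name, gene_class = gene_class,
                 omega_class = omega_class, tau = config$tau,
                 theta_A = config$theta_A, theta_B = config$theta_B,
                 m_sym = config$m_sym, kappa_true = config$kappa_true,
                 L_codons = config$L_codons, haploid = config$haploid,
                 seed = seed, n_stop_redraws = ev$n_stop_redraws)
  ), class = "gene_dataset")
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat(sprintf("gene_dataset '%s' (%s, omega* = %.2f): 4 populations x %d haplotypes, %d codons\n",
              x$truth$gene_name, x$truth$gene_class, x$truth$omega_class,
              length(x$symp_A$sequences), x$truth$L_codons))
  invisible(x)
}

#' Package haplotypes into diploid individuals
#'
#' Pairs consecutive haplotypes into individuals. Optionally emulates the
#' cloning-based allele discovery of the study design: with up to
#' \code{n_clones} clones sequenced per individual, a heterozygote's second
#' allele is missed (and the individual miscalled homozygous) with
#' probability (1/2)^(n_clones - 1) under fair allele sampling.
#'
#' @param haplotypes Character vector of 2 x n_individuals haplotypes.
#' @param n_individuals Number of individuals.
#' @param clone_miss Emulate allele discovery by cloning (default FALSE).
#' @param n_clones Clones sequenced per individual (default 8).
#' @return Data frame with columns \code{individual}, \code{allele1},
#'   \code{allele2}, \code{miscalled_homozygous}.
#' @export
diploid_packaging <- function(haplotypes, n_individuals, clone_miss = FALSE,
                              n_clones = 8L) {
  if (length(haplotypes) != 2L * n_individuals)
    stop("need exactly 2 * n_individuals haplotypes")
  a1 <- haplotypes[seq(1L, by = 2L, length.out = n_individuals)]
  a2 <- haplotypes[seq(2L, by = 2L, length.out = n_individuals)]
  miss <- rep(FALSE, n_individuals)
  if (clone_miss) {
    p_miss <- 0.5^(n_clones - 1L)
    het <- a1 != a2
    miss <- het & (runif(n_individuals) < p_miss)
    a2[miss] <- a1[miss]
  }
  data.frame(individual = seq_len(n_individuals), allele1 = a1, allele2 = a2,
             miscalled_homozygous = miss, stringsAsFactors = FALSE)
}
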