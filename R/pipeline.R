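## End-to-end orchestration: generate or accept per-gene datasets, run the
## divergence screen (candidate vs control rank test), the polymorphism /
## neutrality / MK battery with coalescent nulls, and the Bayesian
## sympatric-vs-allopatric omega comparison.

#' Build a run manifest from gene datasets
#'
#' @param genes List of \code{gene_dataset} objects (see
#'   \code{\link{generate_gene_dataset}}) or structures with the same
#'   fields built from files.
#' @param coalsim_reps Replicates for the coalescent null distributions
#'   (default 1000).
#' @param rho_gene Per-gene recombination parameter passed to the
#'   simulations (default 0; supply observed-data estimates when available).
#' @param mcmc MCMC configuration for the omega stage.
#' @param seed Global seed; per-stage and per-gene seeds are derived as
#'   seed + a running counter (documented fan-out scheme).
#' @return An object of class \code{run_manifest}.
#' @export
run_manifest <- function(genes, coalsim_reps = 1000L, rho_gene = 0,
                         mcmc = mcmc_config(), seed = 1L) {
  stopifnot(is.list(genes))
  nm <- vapply(genes, function(g) g$truth$gene_name, "")
  if (anyDuplicated(nm)) stop("duplicate gene names in manifest")
  structure(list(genes = genes, coalsim_reps = as.integer(coalsim_reps),
                 rho_gene = rho_gene, mcmc = mcmc, seed = as.integer(seed)),
            class = "run_manifest")
}

#' Generate a full synthetic manifest
#'
#' Emulates the study design at batch level: a set of candidate
#' gamete-recognition genes with elevated nonsynonymous acceptance and a
#' set of control genes, each with four population samples and a
#' divergence panel.
#'
#' @param config A \code{synthetic_config} (class-specific omega values are
#'   taken from it).
#' @param n_grp,n_control Number of candidate and control genes (defaults
#'   15 and 9).
#' @param seed Global seed; gene g uses seed + g.
#' @param ... Passed on to \code{\link{run_manifest}}.
#' @return A \code{run_manifest}.
#' @export
synthesize_manifest <- function(config = synthetic_config(), n_grp = 15L,
                                n_control = 9L, seed = 1L, ...) {
  classes <- c(rep("GRP", n_grp), rep("control", n_control))
  genes <- lapply(seq_along(classes), function(g) {
    generate_gene_dataset(config, classes[g],
                          gene_name = sprintf("%s_%02d", tolower(classes[g]), g),
                          seed = seed + g)
  })
  run_manifest(genes, seed = seed, ...)
}

#' Divergence stage: per-gene averaged omega and the candidate-vs-control rank test
#'
#' For each gene with a 2 + 2 divergence panel, computes the NG86 omega
#' averaged over the four cross-lineage pairs, flags candidates
#' (averaged omega strictly above 0.5), and compares candidate
#' gamete-recognition genes against controls with the one-tailed
#' Mann-Whitney U test (alternative: GRP omega stochastically greater).
#'
#' @param manifest A \code{run_manifest}.
#' @return List with \code{table} (gene, class, mean dN/dS/omega, candidate
#'   flag), \code{U}, \code{p_value} (NA when either class has no defined
#'   omega), and \code{skipped} gene names.
#' @export
run_divergence_stage <- function(manifest) {
  rows <- list(); skipped <- character(0)
  for (g in manifest$genes) {
    if (is.null(g$panel_A) || is.null(g$panel_B)) {
      skipped <- c(skipped, g$truth$gene_name)
      message("divergence stage: no panel for ", g$truth$gene_name, "; skipped")
      next
    }
    avg <- mean_cross_type_omega(g$panel_A, g$panel_B)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g$truth$gene_name, class = g$truth$gene_class,
      mean_dN = avg$dN, mean_dS = avg$dS, mean_omega = avg$omega,
      candidate = classify_candidate(avg$omega),
      n_omega_undefined = avg$n_omega_undefined,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), class = character(0),
               mean_dN = numeric(0), mean_dS = numeric(0),
               mean_omega = numeric(0), candidate = logical(0),
               n_omega_undefined = integer(0))
  grp <- tab$mean_omega[tab$class == "GRP" & !is.na(tab$mean_omega)]
  ctl <- tab$mean_omega[tab$class == "control" & !is.na(tab$mean_omega)]
  if (length(grp) && length(ctl)) {
    mw <- mann_whitney_one_tailed(grp, ctl)
    U <- mw$U; p <- mw$p_value
  } else { U <- NA_real_; p <- NA_real_ }
  attr(tab, "decision_rule") <-
    "candidate iff mean pairwise omega > 0.5 (strict); one-tailed Mann-Whitney, GRP greater"
  list(table = tab, U = U, p_value = p, skipped = skipped)
}

# Population labels used by the population-level stages.
.POPS <- c("symp_A", "allo_A", "symp_B", "allo_B")

#' Population stage: summary statistics, neutrality tests with coalescent
#' nulls, MK tables, and the CI-overlap decisions
#'
#' For each gene: a per-population summary table (n, theta, pi by site
#' class); Tajima's D, Fu & Li's D*/F* and Fay & Wu's H (polarized by the
#' other lineage's consensus) with 95% CIs and one-tailed p-values from
#' neutral coalescent simulations run at the observed per-gene Watterson
#' theta; McDonald-Kreitman tables for the sympatric A-vs-B and allopatric
#' A-vs-B comparisons; and, for each statistic and lineage, the sympatric
#' vs allopatric CI-overlap significance decision (both directions must
#' exclude).
#'
#' @param manifest A \code{run_manifest}.
#' @param reps Override for the number of coalescent replicates.
#' @return List of data.frames: \code{summary}, \code{neutrality},
#'   \code{mk}, \code{decisions}.
#' @export
run_population_stage <- function(manifest, reps = NULL) {
  if (is.null(reps)) reps <- manifest$coalsim_reps
  sum_rows <- list(); neu_rows <- list(); mk_rows <- list(); dec_rows <- list()
  seed_counter <- manifest$seed
  stat_defs <- list(
    D = function(s) tajimas_d(s),
    D_star = function(s) fu_li_star(s)$D_star,
    F_star = function(s) fu_li_star(s)$F_star,
    H = function(s) fay_wu_h(s)$H)
  for (g in manifest$genes) {
    gene <- g$truth$gene_name
    cons <- list(A = consensus_sequence(.pool_lineage(g, "B")),
                 B = consensus_sequence(.pool_lineage(g, "A")))
    nulls <- list()
    for (pop in .POPS) {
      aln <- g[[pop]]
      ps <- polymorphism_summary(aln)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        gene = gene, population = pop, n = ps$n, theta = ps$theta_w,
        pi_total = ps$pi_total, pi_syn = ps$pi_syn,
        pi_nonsyn = ps$pi_nonsyn, S = ps$S, L = ps$L,
        stringsAsFactors = FALSE)
      lin <- if (grepl("_A$", pop)) "A" else "B"
      ns <- neutrality_stats(aln, outgroup = cons[[lin]])
      pop_nulls <- list()
      if (ps$n >= 4L && ps$S >= 1L) {
        cfg <- coalescent_config(n = ps$n, theta_gene = ps$theta_w * ps$L,
                                 rho_gene = manifest$rho_gene, L = ps$L,
                                 reps = reps, seed = seed_counter)
        seed_counter <- seed_counter + 1L
        sims <- simulate_replicates(cfg)
        for (st in names(stat_defs)) {
          obs <- ns[[st]]
          vals <- vapply(sims, function(s)
            as.numeric(suppressWarnings(stat_defs[[st]](s))), 0)
          ok <- !is.na(vals)
          pop_nulls[[st]] <- if (sum(ok) >= length(vals) / 2) {
            v <- vals[ok]
            ci <- unname(quantile(v, c(0.025, 0.975)))
            med <- median(v)
            cnt <- if (is.na(obs)) NA_integer_
                   else if (obs >= med) sum(v >= obs) else sum(v <= obs)
            p <- if (is.na(obs)) NA_real_
                 else if (cnt == 0L) 1 / (length(v) + 1) else cnt / length(v)
            structure(list(stat_name = st, null_mean = mean(v),
                           ci_low = ci[1], ci_high = ci[2], p_value = p,
                           observed = obs, reps_used = sum(ok),
                           n_na = sum(!ok)), class = "null_summary")
          } else NULL
        }
      }
      for (st in names(stat_defs)) {
        nl <- pop_nulls[[st]]
        neu_rows[[length(neu_rows) + 1L]] <- data.frame(
          gene = gene, population = pop, statistic = st,
          observed = if (st == "H") ns$H else ns[[st]],
          H_norm = if (st == "H") ns$H_norm else NA_real_,
          p_value = if (is.null(nl)) NA_real_ else nl$p_value,
          ci_low = if (is.null(nl)) NA_real_ else nl$ci_low,
          ci_high = if (is.null(nl)) NA_real_ else nl$ci_high,
          outgroup = if (st == "H")
            paste0("consensus of lineage ", ifelse(lin == "A", "B", "A"))
          else NA_character_,
          stringsAsFactors = FALSE)
      }
      nulls[[pop]] <- pop_nulls
    }
    for (cmp in list(c("symp_A", "symp_B", "sympatric"),
                     c("allo_A", "allo_B", "allopatric"))) {
      mk <- mk_table(g[[cmp[1]]], g[[cmp[2]]])
      mk_rows[[length(mk_rows) + 1L]] <- data.frame(
        gene = gene, comparison = paste0(cmp[3], " A vs ", cmp[3], " B"),
        FS = mk$FS, PS = mk$PS, FN = mk$FN, PN = mk$PN,
        p_value = mk$p_two_tailed, stringsAsFactors = FALSE)
    }
    for (lin in c("A", "B")) {
      sp <- paste0("symp_", lin); ap <- paste0("allo_", lin)
      for (st in names(stat_defs)) {
        ns_s <- nulls[[sp]][[st]]; ns_a <- nulls[[ap]][[st]]
        sig <- if (is.null(ns_s) || is.null(ns_a)) NA
               else ci_overlap_test(ns_s, ns_a)
        dec_rows[[length(dec_rows) + 1L]] <- data.frame(
          gene = gene, lineage = lin, statistic = st, significant = sig,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_or <- function(rows, proto) if (length(rows)) do.call(rbind, rows) else proto
  out <- list(
    summary = empty_or(sum_rows, data.frame(
      gene = character(0), population = character(0), n = integer(0),
      theta = numeric(0), pi_total = numeric(0), pi_syn = numeric(0),
      pi_nonsyn = numeric(0), S = integer(0), L = integer(0))),
    neutrality = empty_or(neu_rows, data.frame(
      gene = character(0), population = character(0), statistic = character(0),
      observed = numeric(0), H_norm = numeric(0), p_value = numeric(0),
      ci_low = numeric(0), ci_high = numeric(0), outgroup = character(0))),
    mk = empty_or(mk_rows, data.frame(
      gene = character(0), comparison = character(0), FS = integer(0),
      PS = integer(0), FN = integer(0), PN = integer(0), p_value = numeric(0))),
    decisions = empty_or(dec_rows, data.frame(
      gene = character(0), lineage = character(0), statistic = character(0),
      significant = logical(0))))
  attr(out, "decision_rule") <- paste(
    "CI-overlap: significant only if the sympatric 95% CI excludes the",
    "allopatric observed value AND vice versa; one-tailed simulation p on",
    "the side of the observed deviation")
  out
}

.pool_lineage <- function(g, lin) {
  rbind(.aln_matrix(g[[paste0("symp_", lin)]]),
        .aln_matrix(g[[paste0("allo_", lin)]]))
}

#' Omega stage: Bayesian sympatric-vs-allopatric comparison per gene
#'
#' For each gene and each of the four populations, runs the constant-omega
#' MCMC twice with different seeds, combines the runs after the
#' convergence cross-check, and summarizes the posterior difference of
#' omega for the sympatric-vs-allopatric comparison within each lineage.
#' Populations without variation yield an "NA (Not enough variation)"
#' verdict.
#'
#' @param manifest A \code{run_manifest}; its \code{mcmc} configuration is
#'   used, with per-run seeds fanned out from the global seed.
#' @return Data frame with one row per gene x lineage: posterior mean
#'   difference, 95% credible interval, and verdict.
#' @export
run_omega_stage <- function(manifest) {
  rows <- list()
  seed_counter <- manifest$seed + 10000L
  for (g in manifest$genes) {
    samples <- list()
    for (pop in .POPS) {
      cfg1 <- manifest$mcmc; cfg1$seed <- seed_counter
      cfg2 <- manifest$mcmc; cfg2$seed <- seed_counter + 1L
      seed_counter <- seed_counter + 2L
      r1 <- run_mcmc(g[[pop]], cfg1, run_id = paste0(g$truth$gene_name, "_", pop, "_run1"))
      r2 <- run_mcmc(g[[pop]], cfg2, run_id = paste0(g$truth$gene_name, "_", pop, "_run2"))
      cb <- combine_runs(r1, r2)
      samples[[pop]] <- if (isFALSE(cb$matched)) {
        warning("runs did not match for ", g$truth$gene_name, " ", pop,
                "; using first run only (more iterations advised)")
        r1
      } else cb$sample
    }
    for (lin in c("A", "B")) {
      cmpr <- posterior_difference(samples[[paste0("symp_", lin)]],
                                   samples[[paste0("allo_", lin)]],
                                   seed = seed_counter)
      seed_counter <- seed_counter + 1L
      verdict <- if (!is.null(cmpr$na_reason))
        paste0("NA (", cmpr$na_reason, ")")
      else if (cmpr$contains_zero) "not significant (CrI contains zero)"
      else "significant (CrI excludes zero)"
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$truth$gene_name,
        comparison = sprintf("Sympatric %s vs Allopatric %s", lin, lin),
        mean_diff = cmpr$mean_diff, cri_low = cmpr$cri_low,
        cri_high = cmpr$cri_high,
        contains_zero = if (is.null(cmpr$na_reason)) cmpr$contains_zero else NA,
        verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(0), comparison = character(0), mean_diff = numeric(0),
    cri_low = numeric(0), cri_high = numeric(0), contains_zero = logical(0),
    verdict = character(0))
  attr(out, "decision_rule") <-
    "omega values differ significantly only if the 95% CrI of the posterior difference excludes zero"
  out
}

#' Write a stage report as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_report_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
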