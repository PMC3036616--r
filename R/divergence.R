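## Pairwise NG86 divergence and the GRP-vs-control rank comparison.

#' Pathway-averaged synonymous/nonsynonymous difference counts for a codon pair
#'
#' For codons differing at k positions, all k! orders of introducing the
#' single-nucleotide changes are enumerated; pathways passing through a stop
#' codon are excluded, and each step of every remaining pathway is classified
#' synonymous or nonsynonymous by translation. Counts are averaged over
#' pathways with equal weights. If every pathway is blocked by stops the
#' stop exclusion is relaxed for that codon pair (stop-crossing steps then
#' count as nonsynonymous).
#'
#' @param c1,c2 Sense codons of equal length 3.
#' @return Numeric vector \code{c(syn, nonsyn)} summing to the number of
#'   differing positions.
#' @export
ng86_codon_diffs <- function(c1, c2) {
  a <- strsplit(toupper(c1), "")[[1]]
  b <- strsplit(toupper(c2), "")[[1]]
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (k == 1L) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
      out
    }
    perms(pos)
  }
  score_path <- function(ord, allow_stop) {
    cur <- a; syn <- 0; non <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- .genetic_code[paste(cur, collapse = "")]
      aa2 <- .genetic_code[paste(nxt, collapse = "")]
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (!is.na(aa1) && aa1 == aa2) syn <- syn + 1 else non <- non + 1
      cur <- nxt
    }
    c(syn, non)
  }
  sc <- Filter(Negate(is.null), lapply(paths, score_path, allow_stop = FALSE))
  if (length(sc) == 0L)
    sc <- lapply(paths, score_path, allow_stop = TRUE)
  m <- colMeans(do.call(rbind, sc))
  c(syn = m[[1]], nonsyn = m[[2]])
}

#' NG86 pairwise divergence with Jukes-Cantor correction
#'
#' Nei-Gojobori (1986) counting: synonymous and nonsynonymous site counts
#' are averaged between the two sequences; differences are counted with
#' equal-weight averaging over all minimal mutational pathways for
#' multi-difference codons (pathways through stop codons excluded). The
#' Jukes-Cantor correction d = -(3/4) log(1 - 4p/3) is applied separately to
#' the synonymous and nonsynonymous proportions. Codons containing N or '-'
#' in either sequence are skipped (pairwise deletion at codon granularity).
#'
#' @param seq_x,seq_y Equal-length in-frame coding sequences (strings), or
#'   \code{codon_alignment}s of one sequence each.
#' @return An object of class \code{pairwise_divergence}: list with
#'   \code{dN}, \code{dS}, \code{omega} (NA when dS = 0), \code{pN},
#'   \code{pS}, site and difference counts, \code{codons_used}, and a
#'   \code{saturated} flag set when a proportion is at or beyond the 3/4
#'   Jukes-Cantor ceiling (the corresponding distance is then NA and the
#'   raw proportion remains available).
#' @export
ng86_pairwise <- function(seq_x, seq_y) {
  if (inherits(seq_x, "codon_alignment")) seq_x <- seq_x$sequences[[1]]
  if (inherits(seq_y, "codon_alignment")) seq_y <- seq_y$sequences[[1]]
  seq_x <- toupper(seq_x); seq_y <- toupper(seq_y)
  if (nchar(seq_x) != nchar(seq_y)) stop("sequences differ in length")
  if (nchar(seq_x) %% 3L != 0L) stop("sequence length not a multiple of 3")
  cx <- codon_split(seq_x); cy <- codon_split(seq_y)
  ok <- !grepl("[N-]", cx) & !grepl("[N-]", cy)
  syn_sites <- 0; nonsyn_sites <- 0; syn_d <- 0; nonsyn_d <- 0; used <- 0L
  for (i in which(ok)) {
    if (.genetic_code[cx[i]] == "*" || .genetic_code[cy[i]] == "*") next
    syn_sites <- syn_sites +
      (.ng86_site_table[cx[i], "syn"] + .ng86_site_table[cy[i], "syn"]) / 2
    nonsyn_sites <- nonsyn_sites +
      (.ng86_site_table[cx[i], "nonsyn"] + .ng86_site_table[cy[i], "nonsyn"]) / 2
    if (cx[i] != cy[i]) {
      d <- .codon_diffs_cached(cx[i], cy[i])
      syn_d <- syn_d + d[["syn"]]; nonsyn_d <- nonsyn_d + d[["nonsyn"]]
    }
    used <- used + 1L
  }
  if (used == 0L) stop("no analyzable codons in this pair")
  pS <- if (syn_sites > 0) syn_d / syn_sites else NA_real_
  pN <- if (nonsyn_sites > 0) nonsyn_d / nonsyn_sites else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(list(d = NA_real_, sat = FALSE))
    if (p >= 0.75) return(list(d = NA_real_, sat = TRUE))
    list(d = -0.75 * log(1 - 4 * p / 3), sat = FALSE)
  }
  jS <- jc(pS); jN <- jc(pN)
  dS <- jS$d; dN <- jN$d
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  structure(list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
                 syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                 syn_diffs = syn_d, nonsyn_diffs = nonsyn_d,
                 codons_used = used, saturated = jS$sat || jN$sat),
            class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat(sprintf("NG86 pairwise divergence: dN = %.4f, dS = %.4f, omega = %s (%d codons)\n",
              x$dN, x$dS, ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega)),
              x$codons_used))
  invisible(x)
}

#' Average cross-lineage divergence over a 2 x 2 panel
#'
#' Computes \code{\link{ng86_pairwise}} for every lineage-A x lineage-B
#' sequence combination (the study design sequences two individuals per
#' lineage, giving four combinations) and averages dN, dS and the defined
#' omega values arithmetically.
#'
#' @param typeA_panel,typeB_panel \code{codon_alignment}s (or character
#'   vectors) holding the divergence-panel sequences of each lineage.
#' @return List with \code{dN}, \code{dS}, \code{omega} (arithmetic means;
#'   omega averaged over pairs where it is defined, NA if none),
#'   \code{n_pairs}, \code{n_omega_undefined}, and the per-pair results.
#' @export
mean_cross_type_omega <- function(typeA_panel, typeB_panel) {
  sa <- if (inherits(typeA_panel, "codon_alignment")) typeA_panel$sequences else typeA_panel
  sb <- if (inherits(typeB_panel, "codon_alignment")) typeB_panel$sequences else typeB_panel
  if (length(sa) < 1L || length(sb) < 1L) stop("both panels must be non-empty")
  pairs <- list()
  for (x in sa) for (y in sb)
    pairs[[length(pairs) + 1L]] <- ng86_pairwise(x, y)
  dn <- vapply(pairs, `[[`, 0, "dN")
  ds <- vapply(pairs, `[[`, 0, "dS")
  om <- vapply(pairs, `[[`, 0, "omega")
  def <- !is.na(om)
  list(dN = mean(dn), dS = mean(ds),
       omega = if (any(def)) mean(om[def]) else NA_real_,
       n_pairs = length(pairs), n_omega_undefined = sum(!def),
       pairs = pairs)
}

#' Positive-selection candidate screen on averaged omega
#'
#' A gene is flagged as a positive-selection candidate when its averaged
#' pairwise omega strictly exceeds 0.5; below 1 this conservative pairwise
#' threshold still indicates likely selection at a subset of residues.
#'
#' @param omega_mean Averaged pairwise omega.
#' @param threshold Screen threshold (default 0.5, strict inequality).
#' @return \code{TRUE}/\code{FALSE}, or \code{NA} when omega is undefined.
#' @export
classify_candidate <- function(omega_mean, threshold = 0.5) {
  if (is.na(omega_mean)) return(NA)
  omega_mean > threshold
}

#' One-tailed Mann-Whitney U test (first group stochastically greater)
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; the normal approximation with tie correction otherwise.
#'
#' @param group_grp Values of the group hypothesized to be larger
#'   (candidate gamete recognition genes).
#' @param group_control Values of the reference group.
#' @return List with \code{U} and \code{p_value}.
#' @export
mann_whitney_one_tailed <- function(group_grp, group_control) {
  group_grp <- group_grp[!is.na(group_grp)]
  group_control <- group_control[!is.na(group_control)]
  if (length(group_grp) == 0L || length(group_control) == 0L)
    stop("both groups must be non-empty")
  if (length(unique(c(group_grp, group_control))) == 1L) {
    warning("all values tied across both groups; p = 1")
    return(list(U = length(group_grp) * length(group_control) / 2, p_value = 1))
  }
  ties <- anyDuplicated(c(group_grp, group_control)) > 0L
  use_exact <- (length(group_grp) + length(group_control)) <= 12L && !ties
  wt <- suppressWarnings(
    wilcox.test(group_grp, group_control, alternative = "greater",
                exact = use_exact, correct = FALSE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
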