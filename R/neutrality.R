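## Frequency-spectrum neutrality statistics: Tajima's D, Fu & Li's D* and
## F* (outgroup-free star statistics), Fay & Wu's H.

#' Variance coefficients for the neutrality statistics
#'
#' All coefficients are functions of the sample size only: Tajima's (1989)
#' a1, a2, b1, b2, c1, c2, e1, e2 and the Fu & Li (1993) star-statistic
#' coefficients with the standard published corrections (Simonsen et al.
#' 1995), u_D*, v_D*, u_F*, v_F*.
#'
#' @param n Sample size (number of alleles), at least 4.
#' @return Named list of coefficients.
#' @export
neutrality_coefficients <- function(n) {
  if (n < 4L) stop("coefficients require n >= 4")
  a1 <- .harmonic(n); a2 <- .harmonic2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  an1 <- a1 + 1 / n  # a_{n+1}
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v_Ds <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
             2 * (n * a1 * (a1 + 1)) / (n - 1)^2) / (a1^2 + a2)
  u_Ds <- (n / (n - 1)) * (a1 - n / (n - 1)) - v_Ds
  v_Fs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
             (2 / (n - 1)) * (4 * a2 - 6 + 8 / n)) / (a1^2 + a2)
  u_Fs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
             2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a1 - v_Fs
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2, c_n = cn, d_n = dn,
       u_Dstar = u_Ds, v_Dstar = v_Ds, u_Fstar = u_Fs, v_Fstar = v_Fs)
}

# Folded site summary common to the statistics: sample size, segregating
# sites, mean pairwise differences (per-gene scale) and singleton count.
# Accepts a codon_alignment / matrix, or a coalescent_sample from the
# simulator (which carries derived allele counts directly).
.site_spectrum <- function(x) {
  if (inherits(x, "coalescent_sample")) {
    n <- x$n; i <- x$counts
    return(list(n = n, S = length(i),
                pi_gene = if (length(i)) sum(2 * i * (n - i)) / (n * (n - 1)) else 0,
                eta_s = sum(i == 1L | i == n - 1L)))
  }
  m <- .aln_matrix(x)
  n <- nrow(m)
  keep <- .clean_cols(m)
  mm <- m[, keep, drop = FALSE]
  S <- 0L; eta <- 0L; pairdiff <- 0
  for (j in seq_len(ncol(mm))) {
    tab <- tabulate(factor(mm[, j], levels = c("A", "C", "G", "T")))
    tab <- tab[tab > 0L]
    if (length(tab) < 2L) next
    S <- S + 1L
    eta <- eta + min(sum(tab == 1L), length(tab) - 1L)
    pairdiff <- pairdiff + choose(n, 2) - sum(choose(tab, 2))
  }
  list(n = n, S = S, pi_gene = pairdiff / choose(n, 2), eta_s = eta)
}

#' Tajima's D
#'
#' D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1)) with pi the mean pairwise
#' difference count on the per-gene scale.
#'
#' @param x A \code{codon_alignment}, character matrix, or
#'   \code{coalescent_sample}.
#' @return D, or NA when S = 0 or n < 4 (with a warning for small n).
#' @export
tajimas_d <- function(x) {
  sp <- .site_spectrum(x)
  if (sp$n < 4L) { warning("Tajima's D requires n >= 4; returning NA"); return(NA_real_) }
  if (sp$S == 0L) return(NA_real_)
  k <- neutrality_coefficients(sp$n)
  (sp$pi_gene - sp$S / k$a1) / sqrt(k$e1 * sp$S + k$e2 * sp$S * (sp$S - 1))
}

#' Fu & Li's D* and F* (outgroup-free)
#'
#' Star statistics contrasting the total singleton count eta_s with S
#' (for D*) and with pi (for F*), using the corrected coefficient set of
#' \code{\link{neutrality_coefficients}}. A singleton is an allele observed
#' in exactly one sequence.
#'
#' @inheritParams tajimas_d
#' @return List with \code{D_star} and \code{F_star}; both NA when S = 0.
#' @export
fu_li_star <- function(x) {
  sp <- .site_spectrum(x)
  if (sp$n < 4L) { warning("Fu & Li's statistics require n >= 4"); return(list(D_star = NA_real_, F_star = NA_real_)) }
  if (sp$S == 0L) return(list(D_star = NA_real_, F_star = NA_real_))
  n <- sp$n; S <- sp$S; eta_s <- sp$eta_s
  k <- neutrality_coefficients(n)
  Ds <- ((n / (n - 1)) * S - k$a1 * eta_s) /
    sqrt(k$u_Dstar * S + k$v_Dstar * S^2)
  Fs <- (sp$pi_gene - ((n - 1) / n) * eta_s) /
    sqrt(k$u_Fstar * S + k$v_Fstar * S^2)
  list(D_star = Ds, F_star = Fs)
}

# Derived-allele counts at polarizable segregating sites. The outgroup
# (here: a consensus sequence of the other lineage) fixes the ancestral
# state; sites where the outgroup base is missing or absent from the sample
# are unpolarizable and excluded.
.polarized_counts <- function(m, outgroup) {
  og <- strsplit(toupper(outgroup), "")[[1]]
  if (length(og) != ncol(m)) stop("outgroup length does not match alignment")
  keep <- .clean_cols(m)
  counts <- integer(0); pairdiffs <- 0; n <- nrow(m)
  n_seg <- 0L
  for (j in which(keep)) {
    tab <- table(m[, j])
    if (length(tab) < 2L) next
    n_seg <- n_seg + 1L
    anc <- og[j]
    if (anc %in% c("N", "-") || !(anc %in% names(tab))) next
    der <- tab[names(tab) != anc]
    counts <- c(counts, as.integer(der))
    tabn <- as.integer(tab)
    pairdiffs <- pairdiffs + choose(n, 2) - sum(choose(tabn, 2))
  }
  list(n = n, counts = counts, pi_sub = pairdiffs / choose(n, 2),
       n_segregating = n_seg)
}

#' Fay & Wu's H with its normalized form
#'
#' theta_H = sum_i S_i 2 i^2 / (n (n-1)) over derived-allele counts i;
#' H = pi - theta_H, computed on the polarizable-site subset. The
#' normalized form follows the standard variance normalization of
#' (pi - theta_L) using Watterson's estimates of theta and theta^2
#' (Zeng et al. 2006).
#'
#' @param x A \code{codon_alignment} or matrix (polarized against
#'   \code{outgroup}), or a \code{coalescent_sample} whose derived states
#'   are known from the simulated genealogy (outgroup then ignored).
#' @param outgroup Consensus sequence of the other lineage used to assign
#'   ancestral states; required for alignment input.
#' @return List with \code{H}, \code{H_norm}, \code{theta_H} and the number
#'   of polarizable sites; all NA when no site can be polarized.
#' @export
fay_wu_h <- function(x, outgroup = NULL) {
  if (inherits(x, "coalescent_sample")) {
    pol <- list(n = x$n, counts = x$counts,
                pi_sub = if (length(x$counts))
                  sum(2 * x$counts * (x$n - x$counts)) / (x$n * (x$n - 1)) else 0)
  } else {
    if (is.null(outgroup)) stop("alignment input requires an outgroup sequence")
    pol <- .polarized_counts(.aln_matrix(x), outgroup)
  }
  n <- pol$n; i <- pol$counts
  if (n < 4L) { warning("Fay & Wu's H requires n >= 4"); return(list(H = NA_real_, H_norm = NA_real_, theta_H = NA_real_, n_polarizable = 0L)) }
  if (length(i) == 0L)
    return(list(H = NA_real_, H_norm = NA_real_, theta_H = NA_real_,
                n_polarizable = 0L))
  i <- i[i >= 1L & i <= n - 1L]
  S <- length(i)
  theta_H <- sum(2 * i^2) / (n * (n - 1))
  theta_L <- sum(i) / (n - 1)
  H <- pol$pi_sub - theta_H
  a1 <- .harmonic(n); b2 <- .harmonic2(n + 1L)  # b_{n+1} = sum_{1}^{n} 1/i^2
  theta_w <- S / a1
  theta_sq <- S * (S - 1) / (a1^2 + .harmonic2(n))
  v <- (n - 2) / (6 * (n - 1)) * theta_w +
    (18 * n^2 * (3 * n + 2) * b2 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * theta_sq
  H_norm <- if (v > 0) (pol$pi_sub - theta_L) / sqrt(v) else NA_real_
  list(H = H, H_norm = H_norm, theta_H = theta_H, n_polarizable = S)
}

#' Consensus sequence of an alignment (per-column majority)
#'
#' Used to polarize Fay & Wu's H: the consensus of the other lineage serves
#' as the outgroup. Ties are broken toward the alphabetically first base;
#' columns that are all-missing yield N.
#'
#' @param aln A \code{codon_alignment} or matrix.
#' @return A single consensus string.
#' @export
consensus_sequence <- function(aln) {
  m <- .aln_matrix(aln)
  paste(apply(m, 2L, function(col) {
    col <- col[col != "N" & col != "-"]
    if (length(col) == 0L) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[[1L]]
  }), collapse = "")
}

#' All neutrality statistics for one population sample
#'
#' @param aln A \code{codon_alignment} or matrix.
#' @param outgroup Outgroup consensus for polarizing Fay & Wu's H; when
#'   NULL, H is reported NA.
#' @return An object of class \code{neutrality_stats} with fields \code{D},
#'   \code{D_star}, \code{F_star}, \code{H}, \code{H_norm}, \code{theta_H},
#'   \code{eta_s} and \code{S}.
#' @export
neutrality_stats <- function(aln, outgroup = NULL) {
  sp <- .site_spectrum(aln)
  fl <- suppressWarnings(fu_li_star(aln))
  fw <- if (!is.null(outgroup) || inherits(aln, "coalescent_sample"))
    suppressWarnings(fay_wu_h(aln, outgroup))
  else list(H = NA_real_, H_norm = NA_real_, theta_H = NA_real_)
  structure(list(D = suppressWarnings(tajimas_d(aln)),
                 D_star = fl$D_star, F_star = fl$F_star,
                 H = fw$H, H_norm = fw$H_norm, theta_H = fw$theta_H,
                 eta_s = sp$eta_s, S = sp$S, n = sp$n),
            class = "neutrality_stats")
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat(sprintf("n = %d, S = %d: D = %.3f, D* = %.3f, F* = %.3f, H = %.3f (norm %.3f)\n",
              x$n, x$S, x$D, x$D_star, x$F_star, x$H, x$H_norm))
  invisible(x)
}
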