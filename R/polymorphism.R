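## Per-population summary statistics: S, Watterson's theta, nucleotide
## diversity overall and by NG86 site class, Hudson's FST.

# Per-codon NG86 site counts, precomputed for the 61 sense codons.
.ng86_site_table <- local({
  cods <- names(.genetic_code)[.genetic_code != "*"]
  m <- t(vapply(cods, function(cd) {
    s <- ng86_codon_sites(cd); c(s$syn_sites, s$nonsyn_sites)
  }, numeric(2)))
  colnames(m) <- c("syn", "nonsyn")
  m
})

# Memoized pathway-averaged codon difference counts.
.codon_diff_cache <- new.env(parent = emptyenv())
.codon_diffs_cached <- function(c1, c2) {
  key <- if (c1 < c2) paste0(c1, c2) else paste0(c2, c1)
  hit <- .codon_diff_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- ng86_codon_diffs(c1, c2)
  .codon_diff_cache[[key]] <- val
  val
}

.aln_matrix <- function(aln) {
  if (inherits(aln, "codon_alignment")) alignment_matrix(aln)
  else if (is.matrix(aln)) aln
  else do.call(rbind, strsplit(toupper(as.character(aln)), ""))
}

# Columns free of missing data (complete deletion per column).
.clean_cols <- function(m) {
  colSums(m == "N" | m == "-") == 0L
}

# Codon indices whose three columns are all clean.
.clean_codons <- function(clean) {
  L <- length(clean)
  idx <- matrix(clean, nrow = 3L)
  which(colSums(idx) == 3L)
}

#' Number of segregating sites
#'
#' Counts alignment columns showing at least two distinct states among
#' non-missing characters (N and '-' are ignored, so a column variable only
#' through missing data is not counted).
#'
#' @param aln A \code{codon_alignment}, character matrix or character vector
#'   of equal-length sequences.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln) {
  m <- .aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  sum(apply(m, 2L, function(col) {
    length(unique(col[col != "N" & col != "-"])) >= 2L
  }))
}

# Harmonic numbers a_n = sum_{i=1}^{n-1} 1/i and b_n = sum 1/i^2.
.harmonic <- function(n) sum(1 / seq_len(n - 1L))
.harmonic2 <- function(n) sum(1 / seq_len(n - 1L)^2)

#' Watterson's theta per site
#'
#' theta_W = S / (a_n L) with a_n the (n-1)-th harmonic number. S and L are
#' taken over columns free of missing data (complete deletion per column).
#'
#' @inheritParams segregating_sites
#' @return theta_W per site.
#' @export
watterson_theta <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("Watterson's theta undefined for n < 2")
  keep <- .clean_cols(m)
  L <- sum(keep)
  if (L < 1L) stop("no complete columns")
  S <- segregating_sites(m[, keep, drop = FALSE])
  S / (.harmonic(n) * L)
}

# Pairwise difference count per column from state counts:
# choose(n,2) - sum_a choose(n_a,2).
.col_pair_diffs <- function(col) {
  tab <- tabulate(factor(col, levels = c("A", "C", "G", "T")))
  n <- sum(tab)
  choose(n, 2) - sum(choose(tab, 2))
}

# Mean pairwise differences on the per-gene scale (clean columns only).
.pi_gene <- function(m) {
  keep <- .clean_cols(m)
  mm <- m[, keep, drop = FALSE]
  n <- nrow(mm)
  sum(apply(mm, 2L, .col_pair_diffs)) / choose(n, 2)
}

#' Nucleotide diversity per site, overall or by NG86 site class
#'
#' pi is the mean proportion of differences over all unordered sequence
#' pairs. For \code{site_class = "all"} the denominator is the number of
#' complete (missing-free) columns. For the synonymous and nonsynonymous
#' classes, differences within each codon are split by equal-weight pathway
#' averaging and divided by the NG86 fractional class sites averaged over
#' the whole sample; codons containing missing data in any sequence are
#' excluded.
#'
#' @inheritParams segregating_sites
#' @param site_class \code{"all"}, \code{"synonymous"} or
#'   \code{"nonsynonymous"}.
#' @return pi per (class) site; NA if the class has zero sites.
#' @export
nucleotide_diversity <- function(aln, site_class = c("all", "synonymous",
                                                     "nonsynonymous")) {
  site_class <- match.arg(site_class)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("pi undefined for n < 2")
  if (site_class == "all") {
    keep <- .clean_cols(m)
    L <- sum(keep)
    if (L < 1L) return(NA_real_)
    tot <- sum(apply(m[, keep, drop = FALSE], 2L, .col_pair_diffs))
    return(tot / (choose(n, 2) * L))
  }
  cls <- if (site_class == "synonymous") "syn" else "nonsyn"
  codons <- .clean_codons(.clean_cols(m))
  if (length(codons) == 0L) return(NA_real_)
  sites <- 0; diffs <- 0
  for (ci in codons) {
    cols <- (3L * (ci - 1L) + 1L):(3L * ci)
    cod <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    aa <- .genetic_code[cod]
    if (any(aa == "*")) next  # terminal stop codons carry no NG86 sites
    sites <- sites + mean(.ng86_site_table[cod, cls])
    tab <- table(cod)
    if (length(tab) > 1L) {
      cs <- names(tab)
      for (i in seq_along(cs)[-length(cs)])
        for (j in (i + 1L):length(cs)) {
          d <- .codon_diffs_cached(cs[i], cs[j])
          diffs <- diffs + tab[[i]] * tab[[j]] * d[[cls]]
        }
    }
  }
  if (sites <= 0) return(NA_real_)
  (diffs / choose(n, 2)) / sites
}

#' Per-population polymorphism summary
#'
#' Replicates the standard per-gene, per-population summary: sample size,
#' sites analyzed, segregating sites, Watterson's theta and nucleotide
#' diversity overall and by site class.
#'
#' @inheritParams segregating_sites
#' @return An object of class \code{polymorphism_summary}: list with
#'   \code{n}, \code{L}, \code{S}, \code{theta_w}, \code{pi_total},
#'   \code{pi_syn}, \code{pi_nonsyn}.
#' @export
polymorphism_summary <- function(aln) {
  m <- .aln_matrix(aln)
  keep <- .clean_cols(m)
  structure(list(
    n = nrow(m),
    L = sum(keep),
    S = segregating_sites(m[, keep, drop = FALSE]),
    theta_w = watterson_theta(m),
    pi_total = nucleotide_diversity(m, "all"),
    pi_syn = nucleotide_diversity(m, "synonymous"),
    pi_nonsyn = nucleotide_diversity(m, "nonsynonymous")
  ), class = "polymorphism_summary")
}

#' @export
print.polymorphism_summary <- function(x, ...) {
  cat(sprintf("n = %d, L = %d, S = %d, theta_w = %.4f, pi = %.4f (syn %.4f, nonsyn %.4f)\n",
              x$n, x$L, x$S, x$theta_w, x$pi_total, x$pi_syn, x$pi_nonsyn))
  invisible(x)
}

#' Hudson-style FST between two population samples
#'
#' FST = 1 - mean(pi_within) / pi_between, where pi_within is the per-site
#' diversity inside each population (averaged with equal weight) and
#' pi_between the mean per-site difference proportion over all between-
#' population sequence pairs. Negative estimates are reported as computed.
#'
#' @param pop1,pop2 Alignments of the same gene with equal lengths.
#' @return FST estimate; NA when pi_between is zero.
#' @export
hudson_fst <- function(pop1, pop2) {
  m1 <- .aln_matrix(pop1); m2 <- .aln_matrix(pop2)
  if (ncol(m1) != ncol(m2)) stop("alignments differ in length")
  pooled_clean <- .clean_cols(rbind(m1, m2))
  L <- sum(pooled_clean)
  if (L < 1L) stop("no complete columns")
  a <- m1[, pooled_clean, drop = FALSE]
  b <- m2[, pooled_clean, drop = FALSE]
  pw <- function(m) {
    n <- nrow(m)
    if (n < 2L) return(0)
    sum(apply(m, 2L, .col_pair_diffs)) / (choose(n, 2) * L)
  }
  between <- 0
  for (j in seq_len(L))
    between <- between + sum(outer(a[, j], b[, j], "!="))
  pi_b <- between / (nrow(a) * nrow(b) * L)
  if (pi_b == 0) return(NA_real_)
  1 - mean(c(pw(a), pw(b))) / pi_b
}
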