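## McDonald-Kreitman contingency tables and Fisher's exact test.

#' Fisher's exact two-tailed test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins: the two-tailed p-value is
#' the sum of probabilities of all tables whose point probability does not
#' exceed that of the observed table (relative tolerance 1e-7 on the
#' comparison, guarding against floating-point ties).
#'
#' @param FS,PS,FN,PN Nonnegative integer cell counts laid out as the
#'   fixed/polymorphic x synonymous/nonsynonymous table.
#' @return Two-tailed p-value in [0, 1]; NA when a row or column margin is
#'   zero (the test is then undefined).
#' @export
fisher_exact_two_tailed <- function(FS, PS, FN, PN) {
  cells <- c(FS, PS, FN, PN)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  # rows: synonymous / nonsynonymous; columns: fixed / polymorphic
  r1 <- FS + PS; r2 <- FN + PN; c1 <- FS + FN; c2 <- PS + PN
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(NA_real_)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- probs[support == FS]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' McDonald-Kreitman table between two population samples
#'
#' Classifies variable nucleotide sites of a shared gene as fixed between
#' the populations (every allele in one population differs from every
#' allele in the other, neither being polymorphic there) or polymorphic
#' (segregating within either population, pooled count). Each difference is
#' classified synonymous or nonsynonymous in its codon context: fixed
#' codon-level changes spanning several positions are split by equal-weight
#' pathway averaging; polymorphic variants are classified against the
#' pooled majority codon. Fractional pathway counts are resolved to
#' integers at the table level by largest-remainder rounding (Fisher's test
#' needs integers); the raw fractional counts are kept alongside.
#'
#' Sites fixed in one population but polymorphic in the other count as
#' polymorphic. Codons containing missing data in any sequence are skipped.
#'
#' @param pop1,pop2 \code{codon_alignment}s (or matrices) of the same gene,
#'   equal aligned lengths, each with at least 2 sequences.
#' @return An object of class \code{mk_table}: list with integer \code{FS},
#'   \code{PS}, \code{FN}, \code{PN}, the fractional counts in \code{raw},
#'   and \code{p_two_tailed}.
#' @export
mk_table <- function(pop1, pop2) {
  m1 <- .aln_matrix(pop1); m2 <- .aln_matrix(pop2)
  if (ncol(m1) != ncol(m2)) stop("alignments differ in length")
  if (nrow(m1) < 2L || nrow(m2) < 2L) stop("each population needs n >= 2")
  if (ncol(m1) %% 3L != 0L) stop("length not a multiple of 3")
  pooled <- rbind(m1, m2)
  codons <- .clean_codons(.clean_cols(pooled))
  fs <- 0; ps <- 0; fn <- 0; pn <- 0
  for (ci in codons) {
    cols <- (3L * (ci - 1L) + 1L):(3L * ci)
    b1 <- m1[, cols, drop = FALSE]; b2 <- m2[, cols, drop = FALSE]
    allb <- pooled[, cols, drop = FALSE]
    if (length(unique(apply(allb, 1L, paste, collapse = ""))) == 1L) next
    maj <- function(col) names(sort(table(col), decreasing = TRUE))[[1L]]
    cons1 <- apply(b1, 2L, maj); cons2 <- apply(b2, 2L, maj)
    cons_all <- apply(allb, 2L, maj)
    mono1 <- apply(b1, 2L, function(z) length(unique(z)) == 1L)
    mono2 <- apply(b2, 2L, function(z) length(unique(z)) == 1L)
    fixed_pos <- which(mono1 & mono2 & cons1 != cons2)
    # fixed differences: pathway-averaged change between the two fixed states
    if (length(fixed_pos) > 0L) {
      x <- cons1; y <- cons1; y[fixed_pos] <- cons2[fixed_pos]
      d <- ng86_codon_diffs(paste(x, collapse = ""), paste(y, collapse = ""))
      fs <- fs + d[["syn"]]; fn <- fn + d[["nonsyn"]]
    }
    # polymorphic mutations: per position segregating within either
    # population, each non-majority allele classified in the context of the
    # pooled majority codon
    for (p in 1:3) {
      if (mono1[p] && mono2[p]) next
      alleles <- unique(allb[, p])
      ref <- cons_all
      for (a in setdiff(alleles, ref[p])) {
        var <- ref; var[p] <- a
        aa_ref <- .genetic_code[paste(ref, collapse = "")]
        aa_var <- .genetic_code[paste(var, collapse = "")]
        if (is.na(aa_var) || aa_var == "*" || is.na(aa_ref) || aa_ref == "*") {
          # change creating/leaving a stop in majority context: classify as
          # nonsynonymous (it alters the protein)
          pn <- pn + 1
        } else if (aa_var == aa_ref) ps <- ps + 1 else pn <- pn + 1
      }
    }
  }
  raw <- c(FS = fs, PS = ps, FN = fn, PN = pn)
  counts <- .largest_remainder(raw)
  p <- fisher_exact_two_tailed(counts[["FS"]], counts[["PS"]],
                               counts[["FN"]], counts[["PN"]])
  structure(list(FS = counts[["FS"]], PS = counts[["PS"]],
                 FN = counts[["FN"]], PN = counts[["PN"]],
                 raw = raw, p_two_tailed = p),
            class = "mk_table")
}

# Largest-remainder rounding preserving the (rounded) grand total.
.largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(round(fl)), names(x))
}

#' @export
print.mk_table <- function(x, ...) {
  cat(sprintf("MK table: FS = %d, PS = %d, FN = %d, PN = %d; Fisher two-tailed p = %s\n",
              x$FS, x$PS, x$FN, x$PN,
              ifelse(is.na(x$p_two_tailed), "NA", format(x$p_two_tailed, digits = 3))))
  invisible(x)
}
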