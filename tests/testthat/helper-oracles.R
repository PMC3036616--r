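# Independent oracles used across the suite. They deliberately avoid the
# package's own code paths: translation goes through Biostrings'
# GENETIC_CODE table, probabilities through explicit choose() enumeration.

BASES <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Brute-force NG86 site counts: enumerate the 9 single-base neighbours.
oracle_ng86_sites <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(codon)
  syn_total <- 0
  for (pos in 1:3) {
    nsyn <- 0; nvalid <- 0
    for (b in BASES[BASES != nt[pos]]) {
      mut <- nt
      mut[pos] <- b
      maa <- oracle_translate(paste(mut, collapse = ""))
      if (maa == "*") next
      nvalid <- nvalid + 1
      if (maa == aa) nsyn <- nsyn + 1
    }
    if (nvalid > 0) syn_total <- syn_total + nsyn / nvalid
  }
  c(syn = syn_total, nonsyn = 3 - syn_total)
}

# Exact two-tailed Fisher probability by full enumeration with fixed
# margins, point probabilities from choose() products.
oracle_fisher <- function(FS, PS, FN, PN) {
  r1 <- FS + PS; r2 <- FN + PN; c1 <- FS + FN
  N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (N - c1) == 0) return(NA_real_)
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_vals, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  }, 0)
  p_obs <- probs[a_vals == FS]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mean pairwise difference proportion by direct double loop.
oracle_pi <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1])
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
    tot <- tot + sum(a != b)
  }
  tot / (choose(n, 2) * L)
}

# Build a codon_alignment from codon vectors (one character vector of
# codons per sequence).
aln_from_codons <- function(..., lineage = "A", context = "sympatric") {
  seqs <- vapply(list(...), paste, "", collapse = "")
  codon_alignment(seqs, lineage = lineage, context = context)
}

# Repeat a codon L times into a sequence string.
codrep <- function(codon, L) paste(rep(codon, L), collapse = "")
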