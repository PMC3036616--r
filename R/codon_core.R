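#' @importFrom stats quantile rexp runif rnorm rbinom rpois sd median var
#'   setNames dhyper wilcox.test
#' @importFrom utils combn write.table
NULL

## Standard genetic code (translation table 1), codons in TCAG order.
.GC_BASES <- c("T", "C", "A", "G")

.genetic_code <- local({
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(.GC_BASES, .GC_BASES, paste0))), .GC_BASES, paste0)))
  stats::setNames(aa, codons)
})

#' The 61 sense codons of the standard genetic code
#'
#' @return Character vector of the 61 codons that do not encode a stop.
#' @export
sense_codons <- function() {
  names(.genetic_code)[.genetic_code != "*"]
}

#' Translate a single codon
#'
#' Translates a 3-mer over \{A,C,G,T\} with the standard genetic code
#' (translation table 1). Stop codons return \code{"*"}.
#'
#' @param codon A single 3-character string.
#' @return One-letter amino-acid symbol, or \code{"*"} for a stop codon.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L)
    stop("codon must be a single 3-character string")
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon))
    stop("untranslatable codon (ambiguity or gap character): ", codon)
  unname(.genetic_code[codon])
}

.is_stop <- function(codon) {
  !is.na(.genetic_code[codon]) && .genetic_code[codon] == "*"
}

#' Nei-Gojobori synonymous and nonsynonymous site counts for one codon
#'
#' Classifies each of the nine single-nucleotide neighbours of a sense codon
#' as synonymous or nonsynonymous by translation. Each codon position
#' contributes a synonymous fraction equal to (number of synonymous changes)
#' / (number of changes not creating a stop codon); changes to stop codons
#' are excluded from both numerator and denominator. Positions where all
#' three changes create stops contribute zero synonymous and one
#' nonsynonymous site, so the two site counts always sum to 3.
#'
#' @param codon A sense codon (3-mer over \{A,C,G,T\}).
#' @return A list with numeric fields \code{syn_sites} and
#'   \code{nonsyn_sites}, summing to 3.
#' @examples
#' ng86_codon_sites("GGG")  # fourfold degenerate third position: 1 syn site
#' @export
ng86_codon_sites <- function(codon) {
  codon <- toupper(codon)
  aa <- translate_codon(codon)
  if (aa == "*") stop("stop codon has no NG86 site decomposition: ", codon)
  nt <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0L; n_valid <- 0L
    for (b in setdiff(.GC_BASES, nt[pos])) {
      mut <- nt; mut[pos] <- b
      maa <- .genetic_code[paste(mut, collapse = "")]
      if (maa == "*") next
      n_valid <- n_valid + 1L
      if (maa == aa) n_syn <- n_syn + 1L
    }
    if (n_valid > 0L) syn <- syn + n_syn / n_valid
  }
  list(syn_sites = syn, nonsyn_sites = 3 - syn)
}

#' Construct a codon alignment
#'
#' A \code{codon_alignment} holds the in-frame haplotype sample for one gene
#' and one population context: equal-length coding sequences over
#' \{A,C,G,T,N,-\}, with unique allele identifiers, a lineage label (the two
#' cryptic lineages are called "A" and "B") and a sampling context.
#'
#' @param sequences Character vector of equal-length nucleotide strings whose
#'   length is a multiple of 3; reading frame starts at position 1.
#' @param ids Character vector of unique allele identifiers (default
#'   \code{seq_1 ...}).
#' @param gene_name Gene label.
#' @param lineage \code{"A"} or \code{"B"}.
#' @param context \code{"sympatric"}, \code{"allopatric"} or
#'   \code{"divergence_panel"}.
#' @return An object of class \code{codon_alignment}.
#' @export
codon_alignment <- function(sequences, ids = NULL, gene_name = "gene",
                            lineage = c("A", "B"),
                            context = c("sympatric", "allopatric",
                                        "divergence_panel")) {
  lineage <- match.arg(lineage)
  context <- match.arg(context)
  sequences <- toupper(as.character(sequences))
  n <- length(sequences)
  if (n < 1L) stop("alignment needs at least one sequence")
  if (is.null(ids)) ids <- paste0("seq_", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids and sequences differ in length")
  if (anyDuplicated(ids)) stop("allele ids must be unique")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  L <- lens[[1]]
  if (L %% 3L != 0L)
    stop("alignment length ", L, " is not a multiple of 3 (frame violation)")
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("invalid characters in record(s): ", paste(ids[bad], collapse = ", "))
  # no internal stop codon in any ungapped, unambiguous codon
  for (i in seq_len(n)) {
    cods <- codon_split(sequences[i])
    clean <- !grepl("[N-]", cods)
    internal <- clean & seq_along(cods) < length(cods)
    if (any(internal & .genetic_code[cods] == "*", na.rm = TRUE))
      stop("internal stop codon in record ", ids[i])
  }
  structure(list(gene_name = gene_name, lineage = lineage, context = context,
                 sequences = sequences, ids = ids, length = L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: gene %s, lineage %s, %s\n  %d sequences x %d nt (%d codons)\n",
              x$gene_name, x$lineage, x$context,
              length(x$sequences), x$length, x$length %/% 3L))
  invisible(x)
}

#' Split a sequence into codons
#' @param seq A nucleotide string with length a multiple of 3.
#' @return Character vector of 3-mers.
#' @export
codon_split <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq(1L, L, by = 3L), seq(3L, L, by = 3L))
}

#' Alignment as a character matrix (one row per sequence)
#' @param aln A \code{codon_alignment}.
#' @return Character matrix of single characters, n x L.
#' @export
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, ""))
  rownames(m) <- aln$ids
  m
}

#' Read a codon alignment from FASTA
#'
#' Headers use the dialect \code{"alleleID|lineage|context"}, e.g.
#' \code{">HMB_01a|A|allopatric"}. Lineage and context of the alignment are
#' taken from the first record; all records must agree.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param gene_name Gene label to attach (default: file name without
#'   extension).
#' @return A \code{codon_alignment}.
#' @export
read_codon_fasta <- function(path, gene_name = NULL) {
  if (is.null(gene_name))
    gene_name <- sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no FASTA records in ", path)
  hdr <- strsplit(names(ss), "|", fixed = TRUE)
  if (any(lengths(hdr) != 3L))
    stop("FASTA headers must be 'alleleID|lineage|context'")
  ids <- vapply(hdr, `[[`, "", 1L)
  lin <- unique(vapply(hdr, `[[`, "", 2L))
  ctx <- unique(vapply(hdr, `[[`, "", 3L))
  if (length(lin) != 1L || length(ctx) != 1L)
    stop("all records in one file must share lineage and context")
  codon_alignment(as.character(ss), ids = ids, gene_name = gene_name,
                  lineage = lin, context = ctx)
}

#' Write a codon alignment to FASTA
#'
#' Inverse of \code{\link{read_codon_fasta}}: headers are
#' \code{"alleleID|lineage|context"}; reading the file back reproduces the
#' ids and sequences exactly.
#'
#' @param aln A \code{codon_alignment}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_codon_fasta <- function(aln, path) {
  ss <- Biostrings::DNAStringSet(aln$sequences)
  names(ss) <- paste(aln$ids, aln$lineage, aln$context, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
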