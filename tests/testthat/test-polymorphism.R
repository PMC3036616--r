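test_that("segregating sites counts observed states, ignoring missing data", {
  mono <- aln_from_codons(rep("ATG", 5), rep("ATG", 5))
  expect_equal(segregating_sites(mono), 0L)
  aln <- codon_alignment(c("ATGTTTGGA", "ATGTTCGGA", "CTGTTCGGT"))
  expect_equal(segregating_sites(aln), 3L)
  # a column variable only through N is not segregating
  alnN <- codon_alignment(c("ATGTTT", "ATGTTN"))
  expect_equal(segregating_sites(alnN), 0L)
})

test_that("Watterson's theta matches S/(a_n L)", {
  # n = 2: a_2 = 1
  a <- codon_alignment(c(paste(rep("ATGGGTAAACCC", 25), collapse = ""),
                         paste(c("CTGGGTAAACCA", rep("ATGGGTAAACCC", 24)),
                               collapse = "")))
  S <- segregating_sites(a)
  expect_equal(S, 2L)
  expect_equal(watterson_theta(a), 2 / 300)
  # n = 4 with a_4 = 1 + 1/2 + 1/3
  set.seed(2)
  base <- rep("ATGGGTTTACCC", 25)
  seqs <- replicate(4, paste(base, collapse = ""))
  m <- do.call(rbind, strsplit(seqs, ""))
  cols <- seq(3, by = 27, length.out = 11)  # 11 third positions, syn changes
  for (k in seq_along(cols)) m[1 + (k %% 2), cols[k]] <- "T"
  # rebuild valid sequences (third-position T in ATG -> ATT = Ile, fine)
  aln4 <- codon_alignment(apply(m, 1, paste, collapse = ""))
  S4 <- segregating_sites(aln4)
  expect_equal(watterson_theta(aln4), S4 / ((1 + 1 / 2 + 1 / 3) * 300))
  expect_equal(watterson_theta(aln_from_codons(rep("ATG", 4), rep("ATG", 4))), 0)
})

test_that("nucleotide diversity equals the direct pairwise oracle", {
  s1 <- paste(rep("ATGGGTTTACCC", 25), collapse = "")  # 300 nt
  s2 <- sub("^ATGGGT", "ATGGGA", s1)                   # 1 diff
  s2 <- sub("CCC$", "CCA", s2)                         # 2 diffs
  aln <- codon_alignment(c(s1, s2))
  expect_equal(nucleotide_diversity(aln, "all"), 2 / 300)
  expect_equal(nucleotide_diversity(aln_from_codons(rep("GGG", 8),
                                                    rep("GGG", 8)), "all"), 0)
  set.seed(21)
  seqs <- vapply(1:6, function(i)
    paste(sample(sense_codons(), 30, replace = TRUE), collapse = ""), "")
  # remove internal stops risk: sense codons only, no stops possible
  aln6 <- codon_alignment(seqs)
  expect_equal(nucleotide_diversity(aln6, "all"), oracle_pi(seqs),
               tolerance = 1e-12)
})

test_that("class-specific diversity follows the NG86 site partition", {
  # ten TTT codons, one synonymous third-position difference
  x <- codrep("TTT", 10)
  y <- paste(c(rep("TTT", 9), "TTC"), collapse = "")
  aln <- codon_alignment(c(x, y))
  syn_sites <- (10 * oracle_ng86_sites("TTT")[["syn"]] +
                9 * oracle_ng86_sites("TTT")[["syn"]] +
                oracle_ng86_sites("TTC")[["syn"]]) / 2
  expect_equal(nucleotide_diversity(aln, "synonymous"), 1 / syn_sites,
               tolerance = 1e-12)
  expect_equal(nucleotide_diversity(aln, "nonsynonymous"), 0)
})

test_that("total diversity decomposes exactly over site classes", {
  set.seed(33)
  g <- generate_gene_dataset(synthetic_config(L_codons = 120L), "GRP",
                             seed = 404)
  aln <- g$symp_A
  ps <- polymorphism_summary(aln)
  m <- alignment_matrix(aln)
  # recover the class site counts to check the weighted decomposition
  syn_sites <- 0
  for (ci in seq_len(ncol(m) / 3)) {
    cod <- apply(m[, (3 * ci - 2):(3 * ci), drop = FALSE], 1, paste,
                 collapse = "")
    syn_sites <- syn_sites + mean(vapply(cod, function(cd)
      oracle_ng86_sites(cd)[["syn"]], 0))
  }
  nonsyn_sites <- ps$L - syn_sites
  expect_equal(ps$pi_total * ps$L,
               ps$pi_syn * syn_sites + ps$pi_nonsyn * nonsyn_sites,
               tolerance = 1e-8)
  expect_gte(ps$pi_syn, 0)
  expect_gte(ps$pi_nonsyn, 0)
})

test_that("Watterson's theta is unbiased on neutral coalescent simulations", {
  theta <- 6; n <- 12L; reps <- 800L
  cfg <- coalescent_config(n = n, theta_gene = theta, reps = reps, seed = 515)
  an <- sum(1 / seq_len(n - 1))
  tw <- vapply(simulate_replicates(cfg),
               function(s) length(s$counts) / an, 0)
  se <- sd(tw) / sqrt(reps)
  expect_lt(abs(mean(tw) - theta), 3 * se)
})

test_that("Hudson's FST behaves at the panmictic and fixed-difference extremes", {
  set.seed(9)
  seqs <- vapply(1:12, function(i)
    paste(sample(sense_codons(), 40, replace = TRUE), collapse = ""), "")
  same1 <- codon_alignment(seqs, lineage = "A")
  same2 <- codon_alignment(seqs, lineage = "B")
  # duplicated panels: FST ~ 1/n from the zero-distance cross pairs
  expect_lt(abs(hudson_fst(same1, same2)), 0.2)
  fixedA <- aln_from_codons(rep("GGG", 20), rep("GGG", 20))
  fixedB <- aln_from_codons(rep("GGA", 20), rep("GGA", 20))
  expect_equal(hudson_fst(fixedA, fixedB), 1)
  # no between-population variation -> undefined
  expect_true(is.na(hudson_fst(fixedA, fixedA)))
})

test_that("FST on a constructed 2+2 design matches hand computation", {
  # pop1: two sequences differing at 1 site of 30; pop2: both carry a
  # fixed difference at another site
  s1 <- codrep("GGG", 10)
  s2 <- paste(c(rep("GGG", 9), "GGA"), collapse = "")
  s3 <- paste(c("GGC", rep("GGG", 9)), collapse = "")
  s4 <- paste(c("GGC", rep("GGG", 8), "GGA"), collapse = "")
  p1 <- codon_alignment(c(s1, s2)); p2 <- codon_alignment(c(s3, s4))
  pw1 <- 1 / 30; pw2 <- 1 / 30
  pb <- mean(c(1, 2, 1, 2) / 30)  # the four cross pairs
  expect_equal(hudson_fst(p1, p2), 1 - mean(c(pw1, pw2)) / pb,
               tolerance = 1e-12)
})
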