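test_that("identical sequences give zero divergence and undefined omega", {
  s <- codrep("GGA", 30)
  d <- ng86_pairwise(s, s)
  expect_equal(d$dN, 0)
  expect_equal(d$dS, 0)
  expect_true(is.na(d$omega))
  # a sequence with no synonymous sites at all has undefined dS
  dm <- ng86_pairwise(codrep("ATG", 10), codrep("ATG", 10))
  expect_true(is.na(dm$dS))
  expect_equal(dm$dN, 0)
})

test_that("single synonymous difference reproduces the Jukes-Cantor oracle", {
  x <- codrep("TTT", 10)
  y <- paste(c(rep("TTT", 9), "TTC"), collapse = "")
  d <- ng86_pairwise(x, y)
  # 10 TTT-like codons contribute 1/3 synonymous site each
  syn_sites <- 10 * oracle_ng86_sites("TTT")[["syn"]]
  pS <- 1 / syn_sites
  expect_equal(d$pS, pS, tolerance = 1e-12)
  expect_equal(d$dS, -0.75 * log(1 - 4 * pS / 3), tolerance = 1e-12)
  expect_equal(d$dS, 0.3831, tolerance = 1e-4)
  expect_equal(d$dN, 0)
  expect_equal(d$omega, 0)  # dS > 0, so omega is defined (and zero)
})

test_that("single nonsynonymous difference reproduces the enumeration oracle", {
  x <- codrep("TTT", 10)
  y <- paste(c(rep("TTT", 9), "GTT"), collapse = "")
  d <- ng86_pairwise(x, y)
  nonsyn_sites <- 9 * oracle_ng86_sites("TTT")[["nonsyn"]] +
    (oracle_ng86_sites("TTT")[["nonsyn"]] + oracle_ng86_sites("GTT")[["nonsyn"]]) / 2
  pN <- 1 / nonsyn_sites
  expect_equal(d$pN, pN, tolerance = 1e-12)
  expect_equal(d$dN, -0.75 * log(1 - 4 * pN / 3), tolerance = 1e-12)
  expect_equal(d$dN, 0.0390, tolerance = 1e-3)
  expect_equal(d$dS, 0)
})

test_that("pairwise divergence is symmetric and skips ambiguous codons", {
  set.seed(11)
  cods <- sample(sense_codons(), 40, replace = TRUE)
  x <- paste(cods, collapse = "")
  cods2 <- cods
  cods2[c(3, 17, 30)] <- sample(sense_codons(), 3)
  y <- paste(cods2, collapse = "")
  d1 <- ng86_pairwise(x, y); d2 <- ng86_pairwise(y, x)
  expect_equal(d1$dN, d2$dN)
  expect_equal(d1$dS, d2$dS)
  # codon with N in one sequence is removed from both site and diff counts
  yN <- sub("^...", "NNN", y)
  dN1 <- ng86_pairwise(x, yN)
  expect_equal(dN1$codons_used, 39L)
})

test_that("saturated proportions are flagged instead of corrected", {
  # maximize differences: alternate highly diverged codons
  x <- codrep("GGG", 5)
  y <- codrep("CCC", 5)
  d <- ng86_pairwise(x, y)
  expect_true(d$saturated)
  expect_true(is.na(d$dN) || is.na(d$dS))
  expect_false(is.na(d$pN))
})

test_that("multi-difference codons average over stop-free pathways", {
  # TTA (Leu) vs ATG (Met): check pathway averaging sums to the number of
  # differing positions and never routes through a stop
  d <- ng86_codon_diffs("TTA", "ATG")
  expect_equal(unname(d[["syn"]] + d[["nonsyn"]]), 2)
  # TTT -> TTC is synonymous (Phe/Phe), single step
  expect_equal(unname(ng86_codon_diffs("TTT", "TTC")[["syn"]]), 1)
  expect_equal(unname(ng86_codon_diffs("TTT", "GTT")[["nonsyn"]]), 1)
})

test_that("cross-type averaging combines the four pairs arithmetically", {
  a <- codon_alignment(c(codrep("GGA", 20), codrep("GGA", 20)),
                       ids = c("a1", "a2"), lineage = "A",
                       context = "divergence_panel")
  b <- codon_alignment(c(codrep("GGA", 20), codrep("GGA", 20)),
                       ids = c("b1", "b2"), lineage = "B",
                       context = "divergence_panel")
  avg <- mean_cross_type_omega(a, b)
  expect_equal(avg$dN, 0); expect_equal(avg$dS, 0)
  expect_true(is.na(avg$omega))
  expect_equal(avg$n_pairs, 4L)
  expect_equal(avg$n_omega_undefined, 4L)
  # consistency with individually computed pairs on mildly diverged panels
  set.seed(5)
  base <- sample(sense_codons(), 60, replace = TRUE)
  mutate_some <- function(cods, k) {
    idx <- sample(length(cods), k)
    cods[idx] <- sample(sense_codons(), k, replace = TRUE)
    paste(cods, collapse = "")
  }
  cods <- c(mutate_some(base, 2), mutate_some(base, 3),
            mutate_some(base, 5), mutate_some(base, 6))
  pa <- codon_alignment(cods[1:2], ids = c("a1", "a2"), lineage = "A",
                        context = "divergence_panel")
  pb <- codon_alignment(cods[3:4], ids = c("b1", "b2"), lineage = "B",
                        context = "divergence_panel")
  avg2 <- mean_cross_type_omega(pa, pb)
  oms <- vapply(seq_len(2), function(i) vapply(seq_len(2), function(j)
    ng86_pairwise(cods[i], cods[2 + j])$omega, 0), numeric(2))
  expect_equal(avg2$omega, mean(oms[!is.na(oms)]), tolerance = 1e-12)
})

test_that("candidate screen applies the strict 0.5 threshold", {
  expect_true(classify_candidate(0.618))
  expect_false(classify_candidate(0.366))
  expect_false(classify_candidate(0.5))
  expect_true(is.na(classify_candidate(NA_real_)))
})

test_that("one-tailed Mann-Whitney matches exact enumeration", {
  # all 20 labelings of {1..6} into 3+3: only one puts {4,5,6} on top
  r <- mann_whitney_one_tailed(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$p_value, 1 / 20)
  r2 <- mann_whitney_one_tailed(c(3, 4), c(1, 2))
  expect_equal(r2$p_value, 1 / 6, tolerance = 1e-12)
  r3 <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_gte(r3$p_value, 0.5)
  expect_warning(mann_whitney_one_tailed(c(1, 1), c(1, 1)), "tied")
})

test_that("NG86 recovers the generator's omega truth over replicate gene panels", {
  for (om_star in c(0.25, 1.0)) {
    cfg <- synthetic_config(omega_grp = om_star)
    oms <- vapply(1:50, function(i) {
      g <- generate_gene_dataset(cfg, "GRP", seed = 9000 + i)
      mean_cross_type_omega(g$panel_A, g$panel_B)$omega
    }, 0)
    expect_lt(abs(mean(oms, na.rm = TRUE) - om_star) / om_star, 0.2)
  }
})

test_that("Jukes-Cantor correction agrees with p to first order", {
  p <- 0.01
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_lt(abs(d - p) / p, 0.01)
})
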