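test_that("site patterns classify by definition", {
  expect_equal(classify_site_pattern("A", "B", "B"), "ABBA")
  expect_equal(classify_site_pattern("B", "A", "B"), "BABA")
  expect_equal(classify_site_pattern("A", "A", "B"), "uninformative")
  expect_equal(classify_site_pattern("B", "B", "B"), "uninformative")
  expect_equal(classify_site_pattern("A", "B", "A"), "uninformative")
  expect_equal(classify_site_pattern(NA, "B", "B"), "uninformative")
})

test_that("joint archaic states follow the XXBAA/XXABA/XXBBA rule", {
  tab <- data.table::data.table(
    state_NEA = c("B", "A", "B", "A", NA),
    state_DEN = c("A", "B", "B", "A", "B"))
  expect_equal(classify_archaic_state(tab),
               c("XXBAA", "XXABA", "XXBBA", "other", "other"))
})

test_that("D matches its arithmetic definition and the brute-force oracle", {
  # counts ABBA=105, BABA=95 -> D = 0.05
  expect_equal((105 - 95) / (105 + 95), 0.05)
  tab <- random_table(n_sites = 40, seed = 11)
  d <- compute_d(tab, "P1", "P2")
  expect_equal(d$D, oracle_d(tab, "P1", "P2"))
  expect_true(abs(d$D) <= 1)
  # antisymmetry
  d21 <- compute_d(tab, "P2", "P1")
  expect_equal(d$D, -d21$D)
  expect_equal(d$abba, d21$baba)
  # same individual on both sides -> undefined, flagged not an error
  same <- compute_d(tab, "P1", "P1")
  expect_true(same$undefined)
  expect_true(is.na(same$D))
})

test_that("conditioned D restricts sites by the zygosity of the named human", {
  tab <- random_table(n_sites = 60, seed = 12)
  full <- compute_d(tab, "P1", "P2")
  het1 <- compute_d(tab, "P1", "P2", conditioning = "het-in-P1")
  hom1 <- compute_d(tab, "P1", "P2", conditioning = "hom-in-P1")
  # the two conditionings partition the informative sites
  expect_equal(het1$abba + hom1$abba, full$abba)
  expect_equal(het1$baba + hom1$baba, full$baba)
  # oracle for the het-in-P1 restriction
  sub <- tab[tab$gt_P1 == 1L]
  expect_equal(het1$D, oracle_d(sub, "P1", "P2"))
})

test_that("haplotype-mode D is reproducible under a fixed seed", {
  tab <- random_table(n_sites = 60, seed = 13)
  d1 <- compute_d(tab, "P1", "P2", mode = "haplotype", seed = 5)
  d2 <- compute_d(tab, "P1", "P2", mode = "haplotype", seed = 5)
  expect_identical(d1$D, d2$D)
})

test_that("nd follows sum(d_i)/N with N counting all human-biallelic sites", {
  # 10 callable sites, two qualifying with frequencies 0.25 and 0.75
  x <- data.table::data.table(
    chrom = "chr1", pos = 1:10 * 10L, allele_A = "A", allele_B = "G",
    mutation_class = "transition",
    state_NEA = c("B", "B", rep("A", 8)),
    state_DEN = "A",
    freq_P1 = c(0.25, 0.75, rep(0.5, 8)), n_P1 = 8L, gt_P1 = 1L)
  tab <- as_site_table(x, "P1", c("chimp", "NEA", "DEN"))
  r <- compute_nd(tab, "P1", "NEA")
  expect_equal(r$nd, 0.10)
  expect_equal(r$N, 10L)
  # XXBBA sites contribute to neither numerator
  x2 <- data.table::copy(x)
  x2[1:2, state_DEN := "B"]
  tab2 <- as_site_table(x2, "P1", c("chimp", "NEA", "DEN"))
  expect_equal(compute_nd(tab2, "P1", "NEA")$numerator, 0)
  expect_equal(compute_nd(tab2, "P1", "DEN")$numerator, 0)
})

test_that("nd variants agree with the oracle; transitions and transversions partition the numerator", {
  tab <- random_table(n_sites = 50, seed = 14)
  for (arch in c("NEA", "DEN")) {
    for (cls in c("both", "transitions", "transversions")) {
      got <- compute_nd(tab, "P1", arch, mutation_class = cls)
      ref <- oracle_nd(tab, "P1", arch, mclass = cls)
      expect_equal(got$nd, ref$nd)
      expect_equal(got$N, ref$N)
    }
    ts <- compute_nd(tab, "P2", arch, mutation_class = "transitions")
    tv <- compute_nd(tab, "P2", arch, mutation_class = "transversions")
    both <- compute_nd(tab, "P2", arch, mutation_class = "both")
    expect_equal(ts$numerator + tv$numerator, both$numerator)
    expect_equal(ts$N + tv$N, both$N)
  }
})

test_that("conditioning can only remove qualifying sites, and panel populations sit at exactly zero", {
  tab <- random_table(n_sites = 80, seed = 15)
  for (p in c("P1", "P2", "P3")) {
    un <- compute_nd(tab, p, "NEA", conditioned = FALSE)
    co <- compute_nd(tab, p, "NEA", conditioned = TRUE, panel = "P3")
    expect_lte(co$nd, un$nd)
    expect_equal(co$nd, oracle_nd(tab, p, "NEA", TRUE, panel = "P3")$nd)
  }
  in_panel <- compute_nd(tab, "P3", "DEN", conditioned = TRUE, panel = "P3")
  expect_identical(in_panel$nd, 0)
  expect_error(compute_nd(tab, "P1", "NEA", conditioned = TRUE),
               "non-empty conditioning panel")
})

test_that("f4 matches the oracle and its exchange symmetries", {
  tab <- random_table(n_sites = 50, seed = 16)
  r <- compute_f4(tab, "P1", "P2", "NEA", "chimp")
  expect_equal(r$f4, oracle_f4(tab, "P1", "P2", "NEA", "chimp"))
  r_swap12 <- compute_f4(tab, "P2", "P1", "NEA", "chimp")
  r_swap34 <- compute_f4(tab, "P1", "P2", "chimp", "NEA")
  expect_equal(r$f4, -r_swap12$f4)
  expect_equal(r$f4, -r_swap34$f4)
  # 5-site toy table against a hand computation
  x <- data.table::data.table(
    chrom = "c", pos = 1:5, allele_A = "A", allele_B = "C",
    mutation_class = "transversion", state_NEA = "B", state_DEN = "A",
    freq_P1 = c(1, 0.5, 0.2, 0, 1), n_P1 = 10L,
    freq_P2 = c(0, 0.5, 0.6, 1, 0.4), n_P2 = 10L)
  toy <- as_site_table(x, c("P1", "P2"), c("chimp", "NEA", "DEN"))
  hand <- mean((x$freq_P1 - x$freq_P2) * (1 - 0))
  expect_equal(compute_f4(toy, "P1", "P2", "NEA", "chimp")$f4, hand)
  # identical frequencies on one side -> exactly 0
  x$freq_P2 <- x$freq_P1
  toy0 <- as_site_table(x, c("P1", "P2"), c("chimp", "NEA", "DEN"))
  expect_equal(compute_f4(toy0, "P1", "P2", "NEA", "chimp")$f4, 0)
})

test_that("AFD matches the oracle and its boundary cases", {
  tab <- random_table(n_sites = 50, seed = 17)
  expect_equal(compute_afd(tab, "P1", "P2")$value, oracle_afd(tab, "P1", "P2"))
  expect_equal(compute_afd(tab, "P1", "P1")$value, 0)
  x <- data.table::data.table(
    chrom = "c", pos = 1:4, allele_A = "A", allele_B = "C",
    mutation_class = "transversion", state_NEA = "A", state_DEN = "A",
    freq_P1 = c(1, 1, 0, 0), n_P1 = 10L, freq_P2 = c(0, 0, 1, 1), n_P2 = 10L)
  toy <- as_site_table(x, c("P1", "P2"), c("chimp", "NEA", "DEN"))
  expect_equal(compute_afd(toy, "P1", "P2")$value, 1)  # fixed differences
})

test_that("Hudson FST matches the oracle, and boundary cases behave", {
  tab <- random_table(n_sites = 50, seed = 18)
  expect_equal(compute_fst(tab, "P1", "P2")$value, oracle_fst(tab, "P1", "P2"))
  # fully fixed differences -> 1
  x <- data.table::data.table(
    chrom = "c", pos = 1:6, allele_A = "A", allele_B = "C",
    mutation_class = "transversion", state_NEA = "A", state_DEN = "A",
    freq_P1 = 1, n_P1 = 20L, freq_P2 = 0, n_P2 = 20L)
  toy <- as_site_table(x, c("P1", "P2"), c("chimp", "NEA", "DEN"))
  expect_equal(compute_fst(toy, "P1", "P2")$value, 1)
  # monomorphic everywhere -> flagged
  x$freq_P1 <- 0
  x$freq_P2 <- 0
  mono <- as_site_table(x, c("P1", "P2"), c("chimp", "NEA", "DEN"))
  expect_true(compute_fst(mono, "P1", "P2")$undefined)
})

test_that("heterozygosity follows 2p(1-p) averaged over called sites", {
  x <- data.table::data.table(
    chrom = "c", pos = 1:10, allele_A = "A", allele_B = "C",
    mutation_class = "transversion", state_NEA = "A", state_DEN = "A",
    freq_P1 = c(0.5, rep(0, 9)), n_P1 = 10L)
  tab <- as_site_table(x, "P1", c("chimp", "NEA", "DEN"))
  expect_equal(compute_heterozygosity(tab, "P1")$H, 0.05)
  x$freq_P1 <- c(rep(1, 5), rep(0, 5))
  fixed <- as_site_table(x, "P1", c("chimp", "NEA", "DEN"))
  expect_equal(compute_heterozygosity(fixed, "P1")$H, 0)
  tab2 <- random_table(n_sites = 50, seed = 19)
  expect_equal(compute_heterozygosity(tab2, "P3")$H, oracle_h(tab2, "P3"))
})

test_that("nd rescaling to genomic fraction is a linear anchor", {
  expect_equal(nd_to_genome_fraction(0.003, reference_nd = 0.002,
                                     reference_fraction = 0.02), 0.03)
  expect_error(nd_to_genome_fraction(0.1, 0, 0.02), "positive")
})
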