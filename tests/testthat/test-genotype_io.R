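test_that("archaic call filter applies the depth and majority thresholds", {
  expect_true(filter_archaic_call(c(A = 14, G = 1))$pass)   # 14/15 > 0.8
  expect_equal(filter_archaic_call(c(A = 14, G = 1))$base, "A")
  expect_false(filter_archaic_call(c(A = 9))$pass)          # below 10 reads
  expect_false(filter_archaic_call(c(A = 250))$pass)        # "fewer than 250"
  expect_false(filter_archaic_call(c(A = 15, G = 5))$pass)  # 0.75 <= 0.8
  expect_true(filter_archaic_call(c(A = 249))$pass)
  expect_error(filter_archaic_call(c(A = -1, G = 5)), "malformed")
  expect_error(filter_archaic_call(numeric(0)), "non-empty")
})

test_that("vectorized filter agrees with the scalar rule and is monotone in min_depth", {
  set.seed(7)
  n <- 200
  calls <- data.table::data.table(
    chrom = "1", pos = seq_len(n),
    A = rpois(n, 8), C = rpois(n, 2), G = rpois(n, 1), T = 0)
  out <- filter_archaic_calls(calls)
  # scalar agreement
  for (i in sample(n, 25)) {
    sc <- filter_archaic_call(unlist(calls[i, .(A, C, G, T)]))
    expect_equal(i %in% out$pos, sc$pass)
    if (sc$pass) expect_equal(out[pos == i]$base, sc$base)
  }
  # raising min_depth never increases the number of passing calls
  n_pass <- vapply(c(0, 5, 10, 15, 20),
                   function(md) nrow(filter_archaic_calls(calls,
                                                          min_depth = md)),
                   numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("transition/transversion classification is exhaustive and exclusive", {
  expect_equal(classify_mutation("A", "G"), "transition")
  expect_equal(classify_mutation("C", "T"), "transition")
  expect_equal(classify_mutation("A", "C"), "transversion")
  expect_error(classify_mutation("A", "A"), "differ")
  expect_error(classify_mutation("A", "N"), "A/C/G/T")
  bases <- c("A", "C", "G", "T")
  pairs <- t(combn(bases, 2))
  cls <- classify_mutation(pairs[, 1], pairs[, 2])
  expect_true(all(cls %in% c("transition", "transversion")))
  expect_equal(sum(cls == "transition"), 2L)  # AG and CT only
  expect_equal(classify_mutation(pairs[, 2], pairs[, 1]), cls)  # symmetric
})

test_that("site table assembly joins taxa, drops bad records and polarizes on the chimpanzee", {
  vcf <- write_human_vcf_fixture(tempfile(fileext = ".vcf"))
  panel <- read_population_panel(
    write_panel_fixture(tempfile()),
    write_coords_fixture(tempfile()),
    conditioning_panel = "POPA")
  human <- read_human_vcf(vcf)
  expect_equal(human$dropped, 2L)  # one multiallelic, one indel
  tab <- build_site_table(
    human, list(NEA = archaic_fixture("NEA"), DEN = archaic_fixture("DEN")),
    read_outgroup_alleles(write_outgroup_fixture(tempfile())), panel,
    focal_samples = c(POPA = "S1", POPB = "S3"))
  expect_s3_class(tab, "aligned_site_table")
  expect_equal(nrow(tab), 5L)
  # chimpanzee defines allele A even where it carries the VCF ALT
  s300 <- tab[pos == 300]
  expect_equal(s300$allele_A, "T")
  expect_equal(s300$allele_B, "G")
  expect_equal(s300$state_NEA, "A")
  expect_equal(s300$state_DEN, "B")
  expect_equal(s300$freq_POPA, 0.25)  # S1 = T/T, S2 = G/T on the B=G allele
  # missing genotype reduces the call count
  expect_equal(tab[pos == 600]$n_POPA, 2L)
  expect_equal(tab[pos == 600]$freq_POPA, 0.5)
  # frequencies in [0, 1], classes exhaustive
  expect_true(all(tab$freq_POPA >= 0 & tab$freq_POPA <= 1))
  expect_true(all(tab$mutation_class %in% c("transition", "transversion")))
})

test_that("building a table twice from the same inputs is identical, and TSV round-trips bit-exactly", {
  vcf <- write_human_vcf_fixture(tempfile(fileext = ".vcf"))
  panel <- population_panel(
    data.frame(sample = c("S1", "S2", "S3", "S4"),
               population = c("POPA", "POPA", "POPB", "POPB"),
               region = c("Africa", "Africa", "Europe", "Europe")))
  og <- read_outgroup_alleles(write_outgroup_fixture(tempfile()))
  arch <- list(NEA = archaic_fixture("NEA"), DEN = archaic_fixture("DEN"))
  t1 <- build_site_table(read_human_vcf(vcf), arch, og, panel)
  t2 <- build_site_table(read_human_vcf(vcf), arch, og, panel)
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  f <- tempfile(fileext = ".tsv")
  write_site_table(t1, f)
  t3 <- read_site_table(f)
  expect_identical(as.data.frame(t1), as.data.frame(t3))
  expect_identical(attr(t1, "populations"), attr(t3, "populations"))
  f2 <- tempfile(fileext = ".tsv")
  write_site_table(t3, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("panel invariants are enforced", {
  expect_error(population_panel(
    data.frame(sample = c("S1", "S1"), population = c("P", "Q"),
               region = c("r", "r"))), "exactly one population")
  expect_error(population_panel(
    data.frame(sample = c("S1", "S2"), population = c("P", "P"),
               region = c("r1", "r2"))), "exactly one region")
  expect_error(population_panel(
    data.frame(sample = "S1", population = "P", region = "r"),
    conditioning_panel = "X"), "absent")
})
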