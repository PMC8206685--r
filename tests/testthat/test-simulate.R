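test_that("demography validation catches inconsistent configurations", {
  expect_error(demography_config(ooa_time = 5e4), "strictly increasing")
  expect_error(demography_config(nea_pulse = 1.2), "pulse fraction")
  expect_error(demography_config(num_fragments = 0), "at least one fragment")
  expect_error(demography_config(n_human = 0), "sample sizes")
  # theta and rho are derived consistently: theta = 4 N0 mu L
  cfg <- demography_config()
  expect_equal(4 * cfg$N0 * cfg$mutation_rate * cfg$fragment_length, 200)
})

test_that("the exported ms command reproduces the canonical scaled event times", {
  ms <- export_ms_command(demography_config("ms_example",
                                            migration_rate = 0.25))
  expect_match(ms, "^\\./ms 741 1000 -t 200 -I 10 1 20 20 100 100 100 100 100 100 100 ",
               fixed = FALSE)
  for (tok in c("-es 0.04 10 0.97", "-ej 0.0401 11 3", "-es 0.06 5 0.97",
                "-ej 0.042 10 9", "-ej 0.044 9 8", "-ej 0.046 8 7",
                "-ej 0.048 7 6", "-ej 0.05 6 5", "-en 0.0685 5 0.007",
                "-ej 0.07 5 4", "-ej 0.4 3 2", "-ej 0.5 4 2", "-ej 6 2 1",
                "-m 5 6 1", "-m 10 9 1")) {
    expect_true(grepl(tok, ms, fixed = TRUE), label = paste("token:", tok))
  }
  # prose convention moves the archaic split and pulse sizes
  ms2 <- export_ms_command(demography_config("prose"))
  expect_true(grepl("-ej 0.45 3 2", ms2, fixed = TRUE))
  expect_true(grepl("0.966", ms2, fixed = TRUE))
  # zero pulses -> no admixture edges
  ms0 <- export_ms_command(demography_config(nea_pulse = 0, den_pulse = 0))
  expect_false(grepl("-es", ms0, fixed = TRUE))
  # exporting twice is identical
  expect_identical(ms2, export_ms_command(demography_config("prose")))
})

test_that("the event list matches the configured schedule in generations", {
  cfg <- demography_config()
  model <- build_demography(cfg)
  ev <- model$events
  expect_equal(ev[type == "pulse" & dest == "NEA"]$time_gen, 60000 / 25)
  expect_equal(ev[type == "pulse" & dest == "DEN"]$time_gen, 40000 / 25)
  joins <- ev[type == "join" & grepl("NONAF", pop) & dest != "AFR"]
  expect_equal(sort(joins$time_gen), sort(seq(42000, 50000, 2000) / 25))
  expect_equal(ev[type == "size_change"]$value, 0.007 * cfg$N0)
  expect_equal(max(ev$time_gen), 6e6 / 25)
  # migration matrix: adjacent pairs only, migrants/generation over N0
  expect_equal(nrow(model$migration), 5L)
  expect_equal(unique(model$migration$rate), cfg$migration_rate / cfg$N0)
})

test_that("simulation is reproducible under a fixed seed and emits coherent tables", {
  cfg <- tiny_config()
  s1 <- simulate_fragments(cfg, seed = 77)
  s2 <- simulate_fragments(cfg, seed = 77)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  t1 <- sim_to_site_table(s1)
  t2 <- sim_to_site_table(s2)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  s3 <- simulate_fragments(cfg, seed = 78)
  expect_false(identical(nrow(s1), nrow(s3)) &&
                 identical(as.data.frame(s1), as.data.frame(s3)))
  # round-tripping the simulated table through TSV preserves statistics
  f <- tempfile(fileext = ".tsv")
  write_site_table(t1, f)
  t3 <- read_site_table(f)
  expect_equal(compute_d(t3, "AFR", "NONAF1")$D,
               compute_d(t1, "AFR", "NONAF1")$D)
  expect_equal(compute_nd(t3, "NONAF6", "DEN")$nd,
               compute_nd(t1, "NONAF6", "DEN")$nd)
})

test_that("site-table conversion equals a hand derivation on a constructed replicate", {
  sim <- tiny_sim()
  tab <- tiny_table()
  expect_equal(nrow(tab), nrow(sim))
  i <- which(sim$chimp_ac == 0L)[1:200]
  j <- which(sim$chimp_ac == 1L)[1:200]
  # chimpanzee ancestral: B frequency is the derived count over sample size
  expect_equal(tab$freq_AFR[i], sim$AFR_ac[i] / 100)
  expect_equal(tab$gt_NONAF3[i], sim$NONAF3_gt[i])
  # chimpanzee derived: orientation flips
  expect_equal(tab$freq_AFR[j], 1 - sim$AFR_ac[j] / 100)
  expect_equal(tab$gt_NONAF3[j], 2L - sim$NONAF3_gt[j])
  # archaic individual rule: homozygotes only, heterozygotes missing
  k <- which(!is.na(tab$state_NEA))
  expect_true(all(tab$gt_NEA[k] %in% c(0L, 2L)))
  expect_true(all(is.na(tab$state_NEA[tab$gt_NEA == 1L])))
  # panel rule: B requires fixation across all 20 archaic lineages
  tabp <- sim_to_site_table(sim, archaic_rule = "panel")
  kb <- which(tabp$state_NEA == "B")
  expect_true(all(tabp$ac_NEA[kb] == tabp$an_NEA[kb]))
  # ts/tv partition covers every site and matches the allele pair
  expect_true(all(tab$mutation_class %in% c("transition", "transversion")))
  expect_equal(tab$mutation_class,
               classify_mutation(tab$allele_A, tab$allele_B))
  # chimpanzee defines A: polarization is idempotent (same seed, same table)
  expect_identical(as.data.frame(sim_to_site_table(sim)), as.data.frame(tab))
})

test_that("single-fragment edge cases behave", {
  # a replicate with no segregating sites is impossible at this theta, but
  # an empty input errors clearly rather than producing a malformed table
  sim <- tiny_sim()
  empty <- sim[0L]
  data.table::setattr(empty, "config", attr(sim, "config"))
  data.table::setattr(empty, "seed", attr(sim, "seed"))
  data.table::setattr(empty, "sample_sizes", attr(sim, "sample_sizes"))
  data.table::setattr(empty, "taxa", attr(sim, "taxa"))
  data.table::setattr(empty, "class", class(sim))
  expect_error(sim_to_site_table(empty), "no segregating sites")
})

test_that("African mutation-rate scaling adds African-private variation only", {
  base <- simulate_fragments(tiny_config(nea_pulse = 0, den_pulse = 0),
                             seed = 301)
  hot <- simulate_fragments(tiny_config(nea_pulse = 0, den_pulse = 0,
                                        african_mutation_scale = 4),
                            seed = 301)
  expect_gt(nrow(hot), nrow(base))
  tb <- sim_to_site_table(base)
  th <- sim_to_site_table(hot)
  # African diversity rises; a non-African population is barely touched
  expect_gt(compute_heterozygosity(th, "AFR")$H /
              compute_heterozygosity(tb, "AFR")$H, 1.02)
  # ... while the non-African 2p(1-p) total is untouched (the extra sites
  # only enlarge its divisor)
  hb <- compute_heterozygosity(tb, "NONAF4")
  hh <- compute_heterozygosity(th, "NONAF4")
  expect_equal(hh$H * hh$n_sites, hb$H * hb$n_sites)
  # the added sites carry derived alleles in Africans and nowhere else
  extra <- hot[!paste(frag, pos) %in% paste(base$frag, base$pos)]
  expect_true(all(extra$AFR_ac > 0))
  expect_true(all(extra$NONAF1_ac == 0 & extra$NONAF6_ac == 0 &
                    extra$NEA_ac == 0 & extra$DEN_ac == 0 &
                    extra$chimp_ac == 0))
})

test_that("optional great-ape outgroups flow through the table and f4", {
  cfg <- demography_config(num_fragments = 8, fragment_length = 1e5,
                           include_great_apes = TRUE)
  tab <- simulate_site_table(cfg, seed = 401)
  expect_true(all(c("state_GOR", "state_ORA") %in% names(tab)))
  # single-genome outgroups: states called from the one sampled lineage
  expect_true(all(tab$state_GOR %in% c("A", "B")))
  # substituting a great ape for the archaic still yields a defined f4
  f_nea <- compute_f4(tab, "AFR", "NONAF1", "NEA", "chimp")
  f_gor <- compute_f4(tab, "AFR", "NONAF1", "GOR", "chimp")
  expect_false(f_gor$undefined)
  expect_gt(f_gor$n_sites, 0)
  # the deeper outgroup is derived (relative to chimp-A) at more sites
  expect_gt(sum(tab$state_ORA == "B"), sum(tab$state_NEA == "B", na.rm = TRUE))
  expect_false(f_nea$undefined)
})
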