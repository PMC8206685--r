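#' Simulate independent fragments under a configured demography
#'
#' Runs the coalescent (msprime, via the bundled python helper) for
#' `config$num_fragments` independent fragments and returns one row per
#' segregating site with derived-allele counts per population and the derived
#' dosage of one diploid reference individual per population. Deterministic
#' under a fixed seed.
#'
#' @param config a `demography_config`.
#' @param seed integer random seed (drives both the genealogies and the
#'   mutations).
#' @param python path to the python interpreter; defaults to
#'   `getOption("archstats.python")` or `python` on the PATH.
#' @return a `sim_fragments` data.table (columns `frag`, `pos`, `<pop>_ac`,
#'   `<pop>_gt`) with the config and seed as attributes.
#' @export
simulate_fragments <- function(config, seed,
                               python = getOption("archstats.python",
                                                  Sys.which("python"))) {
  stopifnot(inherits(config, "demography_config"))
  if (!nzchar(python)) {
    stop("no python interpreter found; set options(archstats.python = ...)")
  }
  seed <- as.integer(seed)
  model <- build_demography(config)
  script <- system.file("python", "coalsim.py", package = "archstats")
  if (!nzchar(script)) stop("bundled coalsim.py not found; reinstall archstats")
  out <- tempfile(fileext = ".feather")
  on.exit(unlink(c(out, paste0(out, ".json"))), add = TRUE)
  spec <- list(
    seed = seed,
    num_fragments = config$num_fragments,
    fragment_length = config$fragment_length,
    mutation_rate = config$mutation_rate,
    recombination_rate = config$rho /
      (4 * config$N0 * config$fragment_length),
    african_mutation_scale = config$african_mutation_scale,
    african_pop = "AFR",
    human_pops = demography_populations(config),
    populations = model$populations,
    migration = model$migration,
    events = model$events,
    out = out)
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file), add = TRUE)
  jsonlite::write_json(spec, cfg_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  status <- system2(python, c(script, cfg_file), stdout = "", stderr = "")
  if (status != 0L) {
    stop("coalescent simulation failed (python exit status ", status, ")")
  }
  x <- data.table::as.data.table(arrow::read_feather(out))
  meta <- jsonlite::fromJSON(paste0(out, ".json"))
  data.table::setattr(x, "config", config)
  data.table::setattr(x, "seed", seed)
  data.table::setattr(x, "sample_sizes", unlist(meta$sample_sizes))
  data.table::setattr(x, "taxa", meta$taxa)
  data.table::setattr(x, "class",
                      c("sim_fragments", class(data.table::data.table())))
  x[]
}

#' @export
print.sim_fragments <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Simulated fragments: %d sites on %d x %g kb fragments (seed %d)\n",
              nrow(x), cfg$num_fragments, cfg$fragment_length / 1e3,
              attr(x, "seed")))
  NextMethod()
  invisible(x)
}

#' Convert simulated fragments to an aligned site table
#'
#' Polarizes every site on the chimpanzee lineage (the chimpanzee allele is
#' "A"), computes per-population B-allele frequencies, assigns archaic allele
#' states and draws nucleotide identities (and hence the
#' transition/transversion class) with a seeded generator at a configurable
#' transition fraction. Fragments become pseudo-chromosomes `frag0001`, ...,
#' so genome-scan operations apply unchanged.
#'
#' @param sim a `sim_fragments` table.
#' @param archaic_rule how to call archaic allele states: `"individual"`
#'   (default; one diploid archaic genome, homozygote calls only, mirroring
#'   the filtered single reference genomes of the real data) or `"panel"`
#'   (state B when the B-allele frequency across all sampled archaic lineages
#'   is at least `panel_threshold`, A when at most `1 - panel_threshold`).
#' @param panel_threshold frequency threshold for the panel rule.
#' @param ts_fraction fraction of mutations drawn as transitions (the
#'   genome-wide transition:transversion ratio of about 2:1 gives 2/3).
#' @param base_seed seed for the nucleotide assignment.
#' @return an `aligned_site_table`.
#' @export
sim_to_site_table <- function(sim, archaic_rule = c("individual", "panel"),
                              panel_threshold = 1, ts_fraction = 2 / 3,
                              base_seed = NULL) {
  stopifnot(inherits(sim, "sim_fragments"))
  archaic_rule <- match.arg(archaic_rule)
  cfg <- attr(sim, "config")
  sizes <- attr(sim, "sample_sizes")
  taxa <- attr(sim, "taxa")
  pops <- demography_populations(cfg)
  if (is.null(base_seed)) base_seed <- attr(sim, "seed")

  n <- nrow(sim)
  if (n == 0L) {
    stop("no segregating sites in the simulation output")
  }
  chimp_derived <- sim$chimp_ac > 0L

  out <- data.table::data.table(
    chrom = sprintf("frag%04d", sim$frag),
    pos = sim$pos)

  # nucleotide assignment: ancestral base uniform, derived base a transition
  # partner with probability ts_fraction, else one of the two transversions
  withr_seed(base_seed, {
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, n, replace = TRUE)
    is_ts <- stats::runif(n) < ts_fraction
    ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    der <- ifelse(is_ts, ts_partner[anc],
                  ifelse(stats::runif(n) < 0.5, tv1[anc], tv2[anc]))
  })
  out[, allele_A := ifelse(chimp_derived, der, anc)]
  out[, allele_B := ifelse(chimp_derived, anc, der)]
  out[, mutation_class := ifelse(is_ts, "transition", "transversion")]

  # derived -> B-allele orientation
  bfreq <- function(ac, an) ifelse(chimp_derived, 1 - ac / an, ac / an)
  bdos <- function(gt) ifelse(chimp_derived, 2L - gt, gt)

  for (tx in setdiff(taxa, "chimp")) {
    an <- sizes[[tx]]
    ac <- sim[[paste0(tx, "_ac")]]
    out[, paste0("ac_", tx) := ifelse(chimp_derived, an - ac, ac)]
    out[, paste0("an_", tx) := an]
    if (archaic_rule == "individual" && paste0(tx, "_gt") %in% names(sim)) {
      g <- bdos(sim[[paste0(tx, "_gt")]])
      out[, paste0("gt_", tx) := g]
      out[, paste0("state_", tx) :=
            ifelse(g == 2L, "B", ifelse(g == 0L, "A", NA_character_))]
    } else {
      f <- bfreq(ac, an)
      out[, paste0("state_", tx) :=
            ifelse(f >= panel_threshold, "B",
                   ifelse(f <= 1 - panel_threshold, "A", NA_character_))]
    }
  }

  tot_b <- 0L
  tot_n <- 0L
  for (p in pops) {
    an <- sizes[[p]]
    ac <- sim[[paste0(p, "_ac")]]
    bc <- ifelse(chimp_derived, an - ac, ac)
    out[, paste0("freq_", p) := bc / an]
    out[, paste0("n_", p) := as.integer(an)]
    out[, paste0("gt_", p) := bdos(sim[[paste0(p, "_gt")]])]
    tot_b <- tot_b + bc
    tot_n <- tot_n + an
  }
  out[, hpoly := tot_b > 0L & tot_b < tot_n]
  as_site_table(out, populations = pops, taxa = taxa,
                drop_counts = c(multiallelic = 0L))
}

#' One-call simulation to site table
#'
#' @inheritParams simulate_fragments
#' @inheritParams sim_to_site_table
#' @param ... passed to [sim_to_site_table()].
#' @return an `aligned_site_table`.
#' @export
simulate_site_table <- function(config, seed, ...) {
  sim_to_site_table(simulate_fragments(config, seed), ...)
}

#' Migration-rate sweep experiment
#'
#' Runs one full simulation per migration rate (seeds derived
#' deterministically from the master seed) and tabulates the statistics
#' underlying the migration-sweep figures: per-population nd_NEA and nd_DEN
#' (conditioned on the African panel and unconditioned) and heterozygosity;
#' AFD and FST for every population pair; and the African versus first
#' non-African D statistic.
#'
#' @param config a `demography_config` (its `migration_rate` is overridden).
#' @param rates numeric vector of migration rates (migrants per generation).
#' @param seed master seed.
#' @param pairs population pairs for AFD/FST as a two-column matrix or
#'   `"terminal"` (first vs last non-African, default) or `"all"`.
#' @return tidy data.table: rate, statistic, population, value, n_sites plus
#'   attributes `seed` and `seeds` (per-rate).
#' @export
run_migration_sweep <- function(config, rates = c(1, 10, 20, 50), seed = 1L,
                                pairs = c("terminal", "all")) {
  stopifnot(inherits(config, "demography_config"))
  if (any(rates <= 0)) stop("migration rates must be positive")
  if (is.character(pairs)) pairs <- match.arg(pairs)
  pops <- demography_populations(config)
  nonaf <- setdiff(pops, "AFR")
  pair_m <- if (is.matrix(pairs)) {
    pairs
  } else if (identical(pairs, "all")) {
    t(utils::combn(pops, 2L))
  } else {
    matrix(c(nonaf[1L], nonaf[length(nonaf)]), ncol = 2L)
  }
  seeds <- as.integer((seed + 7919L * seq_along(rates)) %% .Machine$integer.max)
  rows <- list()
  for (i in seq_along(rates)) {
    cfg_i <- config
    cfg_i$migration_rate <- rates[i]
    validate_demography(cfg_i)
    tab <- simulate_site_table(cfg_i, seeds[i])
    for (p in pops) {
      for (cond in c(FALSE, TRUE)) {
        for (arch in c("NEA", "DEN")) {
          r <- compute_nd(tab, p, arch, conditioned = cond, panel = "AFR")
          rows[[length(rows) + 1L]] <- data.table::data.table(
            rate = rates[i],
            statistic = paste0("nd_", arch, if (cond) "_cond"),
            population = p, value = r$nd, n_sites = r$N)
        }
      }
      h <- compute_heterozygosity(tab, p)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        rate = rates[i], statistic = "H", population = p, value = h$H,
        n_sites = h$n_sites)
    }
    for (k in seq_len(nrow(pair_m))) {
      lab <- paste(pair_m[k, ], collapse = "|")
      a <- compute_afd(tab, pair_m[k, 1L], pair_m[k, 2L])
      f <- compute_fst(tab, pair_m[k, 1L], pair_m[k, 2L])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        rate = rates[i], statistic = "AFD", population = lab, value = a$value,
        n_sites = a$n_sites)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        rate = rates[i], statistic = "FST", population = lab, value = f$value,
        n_sites = f$n_sites)
    }
    d <- compute_d(tab, "AFR", nonaf[1L], archaic = "NEA")
    rows[[length(rows) + 1L]] <- data.table::data.table(
      rate = rates[i], statistic = "D", population = paste0("AFR|", nonaf[1L]),
      value = d$D, n_sites = d$n_informative)
  }
  res <- data.table::rbindlist(rows)
  data.table::setattr(res, "seed", seed)
  data.table::setattr(res, "seeds", seeds)
  res[]
}
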