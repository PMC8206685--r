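#' Configuration of the serial-founder out-of-Africa demography
#'
#' Parameters of the simulated scenario: a chimpanzee outgroup; Neanderthal
#' and Denisovan sister lineages splitting from humans at `archaic_split`
#' years ago and from each other at `nea_den_split`; one African population;
#' and `n_nonafrican` serially founded non-African populations linked by
#' bidirectional migration between adjacent neighbours. The founding lineage
#' leaves Africa at `ooa_time`, passes a bottleneck (size factor
#' `bottleneck_factor` between `bottleneck_start` and `ooa_time`), receives a
#' Neanderthal pulse, then splits every `founding_interval` years starting at
#' `founding_start`; the last-founded population receives a Denisovan pulse.
#'
#' Scaling: with `N0` diploids, `mutation_rate` per bp per generation and
#' 500 kb fragments, the per-fragment scaled mutation rate is
#' theta = 4 N0 mu L = 200, and one coalescent time unit is 4 N0 = 40000
#' generations (1 Myr at 25 years per generation), so the chimpanzee split
#' sits at 6 time units. `migration_rate` is expressed in migrant individuals
#' per generation between a pair of adjacent non-African populations
#' (backward rate `migration_rate / N0` per generation, i.e. an ms -m value of
#' `4 * migration_rate`).
#'
#' @param convention `"prose"` (450 kyr Neanderthal-Denisovan split, 3.4%
#'   pulses) or `"ms_example"` (400 kyr, 3.0%, matching the printed example
#'   command rather than the stated scenario).
#' @param N0 diploid reference population size.
#' @param generation_years years per generation.
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param fragment_length fragment length in bp.
#' @param num_fragments number of independent fragments.
#' @param rho scaled recombination rate 4 N0 r L per fragment.
#' @param chimp_split,archaic_split,nea_den_split,ooa_time split times in
#'   years before present.
#' @param bottleneck_start,bottleneck_factor out-of-Africa bottleneck: the
#'   founding non-African population has size `bottleneck_factor * N0`
#'   between `bottleneck_start` and `ooa_time` years ago.
#' @param founding_start,founding_interval,n_nonafrican serial founding
#'   schedule of the non-African populations.
#' @param nea_pulse,nea_pulse_time Neanderthal admixture pulse fraction and
#'   time (into the first non-African population).
#' @param den_pulse,den_pulse_time Denisovan admixture pulse fraction and
#'   time (into the last non-African population).
#' @param migration_rate migrants per generation between adjacent non-African
#'   populations (symmetric).
#' @param african_migration_rate migrants per generation between the African
#'   and the first non-African population (0 disables).
#' @param n_chimp,n_archaic,n_human haploid sample sizes (chimpanzee, each
#'   archaic, each human population).
#' @param african_mutation_scale multiplier on the mutation rate of branches
#'   private to the African sample (heterozygosity-linked mutation-rate
#'   extension; 1 disables).
#' @param include_great_apes add gorilla and orangutan outgroup lineages
#'   (splits at 9 and 14 Myr; an extension beyond the core scenario).
#' @return a validated `demography_config` object.
#' @export
demography_config <- function(convention = c("prose", "ms_example"),
                              N0 = 10000,
                              generation_years = 25,
                              mutation_rate = 1e-8,
                              fragment_length = 5e5,
                              num_fragments = 1000,
                              rho = 100,
                              chimp_split = 6e6,
                              archaic_split = 5e5,
                              nea_den_split = NULL,
                              ooa_time = 7e4,
                              bottleneck_start = 6.85e4,
                              bottleneck_factor = 0.007,
                              founding_start = 5e4,
                              founding_interval = 2e3,
                              n_nonafrican = 6,
                              nea_pulse = NULL,
                              nea_pulse_time = 6e4,
                              den_pulse = NULL,
                              den_pulse_time = 4e4,
                              migration_rate = 1,
                              african_migration_rate = 0,
                              n_chimp = 1, n_archaic = 20, n_human = 100,
                              african_mutation_scale = 1,
                              include_great_apes = FALSE) {
  convention <- match.arg(convention)
  if (is.null(nea_den_split)) {
    nea_den_split <- if (convention == "prose") 4.5e5 else 4e5
  }
  default_pulse <- if (convention == "prose") 0.034 else 0.03
  if (is.null(nea_pulse)) nea_pulse <- default_pulse
  if (is.null(den_pulse)) den_pulse <- default_pulse
  cfg <- structure(as.list(environment()), class = "demography_config")
  validate_demography(cfg)
  cfg
}

validate_demography <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$N0 > 0, "N0 must be positive")
  chk(cfg$num_fragments >= 1, "need at least one fragment")
  chk(cfg$fragment_length > 0, "fragment length must be positive")
  chk(cfg$nea_pulse >= 0 && cfg$nea_pulse < 1,
      "Neanderthal pulse fraction must be in [0, 1)")
  chk(cfg$den_pulse >= 0 && cfg$den_pulse < 1,
      "Denisovan pulse fraction must be in [0, 1)")
  chk(cfg$n_nonafrican >= 1, "need at least one non-African population")
  chk(cfg$migration_rate >= 0 && cfg$african_migration_rate >= 0,
      "migration rates must be non-negative")
  chk(all(c(cfg$n_chimp, cfg$n_archaic, cfg$n_human) > 0),
      "sample sizes must be positive")
  last_founding <- cfg$founding_start -
    (cfg$n_nonafrican - 2) * cfg$founding_interval
  times <- c(den_pulse_time = cfg$den_pulse_time,
             last_founding = if (cfg$n_nonafrican > 1) last_founding else NA,
             founding_start = if (cfg$n_nonafrican > 1) cfg$founding_start
                              else NA,
             nea_pulse_time = cfg$nea_pulse_time,
             bottleneck_start = cfg$bottleneck_start,
             ooa_time = cfg$ooa_time,
             nea_den_split = cfg$nea_den_split,
             archaic_split = cfg$archaic_split,
             chimp_split = cfg$chimp_split)
  times <- times[!is.na(times)]
  if (is.unsorted(times, strictly = TRUE)) {
    bad <- names(times)[c(diff(times) <= 0, FALSE)]
    problems <- c(problems, paste0(
      "event times must be strictly increasing into the past; violated at: ",
      paste(bad, collapse = ", ")))
  }
  if (length(problems) > 0L) {
    stop("invalid demography configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' @export
print.demography_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Serial-founder demography (%s convention)\n",
    "  N0 = %d diploids, theta/fragment = %.4g, rho/fragment = %.4g\n",
    "  %d fragments x %g kb; samples: chimp %d, archaics %d, humans %d x %d\n",
    "  splits (kyr): chimp %g, archaic %g, Nea-Den %g, out-of-Africa %g\n",
    "  bottleneck: factor %g between %g and %g kyr\n",
    "  pulses: Neanderthal %.3g @ %g kyr, Denisovan %.3g @ %g kyr\n",
    "  migration: %g migrants/gen (adjacent non-African), %g (African)\n"),
    x$convention, x$N0,
    4 * x$N0 * x$mutation_rate * x$fragment_length, x$rho,
    x$num_fragments, x$fragment_length / 1e3,
    x$n_chimp, x$n_archaic, x$n_nonafrican + 1L, x$n_human,
    x$chimp_split / 1e3, x$archaic_split / 1e3, x$nea_den_split / 1e3,
    x$ooa_time / 1e3, x$bottleneck_factor, x$bottleneck_start / 1e3,
    x$ooa_time / 1e3, x$nea_pulse, x$nea_pulse_time / 1e3, x$den_pulse,
    x$den_pulse_time / 1e3, x$migration_rate, x$african_migration_rate))
  invisible(x)
}

#' Population labels of a demography configuration
#' @param config a `demography_config`.
#' @return character vector: human population labels (AFR, NONAF1, ...).
#' @export
demography_populations <- function(config) {
  c("AFR", if (config$n_nonafrican >= 1)
    paste0("NONAF", seq_len(config$n_nonafrican)))
}

#' Build the explicit demographic model (backward-time event list)
#'
#' Renders the configuration as populations, an initial migration matrix and
#' a time-ordered list of backward-time events (mass migrations for pulses
#' and joins, size changes for the bottleneck), in generations. This is the
#' structure executed by the coalescent engine and exported as an ms-style
#' command for audit.
#'
#' @param config a `demography_config`.
#' @return list with `populations` (data.table: name, size, samples),
#'   `migration` (data.table: pop_a, pop_b, rate per generation) and `events`
#'   (data.table: time_gen, type, pop, dest, value), sorted by time.
#' @export
build_demography <- function(config) {
  validate_demography(config)
  gy <- config$generation_years
  Tg <- function(years) years / gy
  nn <- config$n_nonafrican
  nonaf <- paste0("NONAF", seq_len(nn))
  pops <- data.table::data.table(
    name = c("chimp", "NEA", "DEN",
             if (config$include_great_apes) c("GOR", "ORA"),
             "AFR", nonaf),
    size = config$N0,
    samples = c(config$n_chimp, config$n_archaic, config$n_archaic,
                if (config$include_great_apes) c(1L, 1L),
                rep(config$n_human, nn + 1L)))

  mig <- data.table::data.table(pop_a = character(), pop_b = character(),
                                rate = numeric())
  if (nn > 1L && config$migration_rate > 0) {
    mig <- data.table::data.table(
      pop_a = nonaf[-nn], pop_b = nonaf[-1L],
      rate = config$migration_rate / config$N0)
  }
  if (config$african_migration_rate > 0) {
    mig <- rbind(mig, data.table::data.table(
      pop_a = "AFR", pop_b = nonaf[1L],
      rate = config$african_migration_rate / config$N0))
  }

  ev <- list()
  add <- function(time_gen, type, pop, dest = NA_character_,
                  value = NA_real_) {
    ev[[length(ev) + 1L]] <<- data.table::data.table(
      time_gen = time_gen, type = type, pop = pop, dest = dest, value = value)
  }
  # Denisovan pulse into the last-founded population
  if (config$den_pulse > 0 && nn >= 1L) {
    add(Tg(config$den_pulse_time), "pulse", nonaf[nn], "DEN", config$den_pulse)
  }
  # serial founding joins, youngest first; migration with the dying deme off
  if (nn > 1L) {
    for (k in seq_len(nn - 1L)) {
      ty <- config$founding_start - (nn - 1L - k) * config$founding_interval
      src <- nonaf[nn - k + 1L]
      dst <- nonaf[nn - k]
      add(Tg(ty), "join", src, dst, 1)
      add(Tg(ty), "migration_off", src)
    }
  }
  if (config$nea_pulse > 0) {
    add(Tg(config$nea_pulse_time), "pulse", nonaf[1L], "NEA", config$nea_pulse)
  }
  add(Tg(config$bottleneck_start), "size_change", nonaf[1L],
      value = config$bottleneck_factor * config$N0)
  add(Tg(config$ooa_time), "join", nonaf[1L], "AFR", 1)
  add(Tg(config$ooa_time), "migration_off", nonaf[1L])
  add(Tg(config$nea_den_split), "join", "DEN", "NEA", 1)
  add(Tg(config$archaic_split), "join", "AFR", "NEA", 1)
  add(Tg(config$chimp_split), "join", "NEA", "chimp", 1)
  if (config$include_great_apes) {
    add(Tg(9e6), "join", "GOR", "chimp", 1)
    add(Tg(14e6), "join", "ORA", "chimp", 1)
  }
  events <- data.table::rbindlist(ev)
  data.table::setorder(events, time_gen)
  list(populations = pops, migration = mig, events = events)
}

#' Export the configuration as an ms-style command string
#'
#' Renders the scenario in the classic coalescent-simulator syntax (times in
#' units of 4 N0 generations, sizes relative to N0, -es/-ej/-en/-em events)
#' for audit against published command lines. Note that under the
#' migrants-per-generation convention an adjacent-deme rate of `r` appears as
#' an `-m` value of `4 r`.
#'
#' @param config a `demography_config`.
#' @return a single character string.
#' @export
export_ms_command <- function(config) {
  validate_demography(config)
  unit <- 4 * config$N0 * config$generation_years  # years per coalescent unit
  Tms <- function(years) format(years / unit, trim = TRUE)
  nn <- config$n_nonafrican
  npop <- 3L + 1L + nn
  sizes <- c(config$n_chimp, config$n_archaic, config$n_archaic,
             rep(config$n_human, nn + 1L))
  theta <- 4 * config$N0 * config$mutation_rate * config$fragment_length
  parts <- c(sprintf("./ms %d %d -t %g", sum(sizes), config$num_fragments,
                     theta),
             sprintf("-I %d %s", npop, paste(sizes, collapse = " ")),
             sprintf("-r %g %d", config$rho, config$fragment_length))
  # demes: 1 chimp, 2 NEA, 3 DEN, 4 AFR, 5..(4+nn) non-Africans
  d_nonaf <- function(i) 4L + i
  if (nn > 1L && config$migration_rate > 0) {
    mval <- 4 * config$migration_rate
    for (i in seq_len(nn - 1L)) {
      parts <- c(parts,
                 sprintf("-m %d %d %g", d_nonaf(i), d_nonaf(i + 1L), mval),
                 sprintf("-m %d %d %g", d_nonaf(i + 1L), d_nonaf(i), mval))
    }
  }
  if (config$african_migration_rate > 0) {
    mval <- 4 * config$african_migration_rate
    parts <- c(parts, sprintf("-m 4 %d %g", d_nonaf(1L), mval),
               sprintf("-m %d 4 %g", d_nonaf(1L), mval))
  }
  newdeme <- npop
  ms_events <- character()
  if (config$den_pulse > 0) {
    newdeme <- newdeme + 1L
    ms_events <- c(ms_events,
      sprintf("-es %s %d %g", Tms(config$den_pulse_time), d_nonaf(nn),
              1 - config$den_pulse),
      sprintf("-ej %s %d 3", Tms(config$den_pulse_time + 1e-4 * unit),
              newdeme))
  }
  if (config$nea_pulse > 0) {
    newdeme <- newdeme + 1L
    ms_events <- c(ms_events,
      sprintf("-es %s %d %g", Tms(config$nea_pulse_time), d_nonaf(1L),
              1 - config$nea_pulse),
      sprintf("-ej %s %d 2", Tms(config$nea_pulse_time + 1e-4 * unit),
              newdeme))
  }
  if (nn > 1L) {
    for (k in seq_len(nn - 1L)) {
      ty <- config$founding_start - (nn - 1L - k) * config$founding_interval
      ms_events <- c(ms_events, sprintf("-ej %s %d %d", Tms(ty),
                                        d_nonaf(nn - k + 1L), d_nonaf(nn - k)))
    }
  }
  ms_events <- c(ms_events,
    sprintf("-en %s %d %g", Tms(config$bottleneck_start), d_nonaf(1L),
            config$bottleneck_factor),
    sprintf("-ej %s %d 4", Tms(config$ooa_time), d_nonaf(1L)),
    sprintf("-ej %s 3 2", Tms(config$nea_den_split)),
    sprintf("-ej %s 4 2", Tms(config$archaic_split)),
    sprintf("-ej %s 2 1", Tms(config$chimp_split)))
  paste(c(parts, ms_events), collapse = " ")
}
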