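#' Run a named end-to-end analysis recipe
#'
#' Orchestrates simulate -> statistics -> outputs with stage logging and a
#' reproducibility manifest. Available recipes:
#'
#' * `fig10_sweep` -- migration-rate sweep; per-rate nd/H/AFD/FST/D tables
#'   and profile plots across the non-African populations.
#' * `afd_calibration` -- AFD and FST between the terminal non-African
#'   populations at the lowest and highest sweep rates.
#' * `nd_variants` -- one simulation; nd for every population in the four
#'   variants (conditioned or not x transitions/transversions).
#' * `window_scan` -- one simulation; megabase-window f4 track, outlier
#'   filtering and leave-one-out chromosome correlations.
#'
#' @param name recipe name.
#' @param config a `demography_config`.
#' @param out_dir output directory (created).
#' @param seed master seed.
#' @param rates migration rates for the sweep recipes.
#' @param plot also write simple scatter/line PDF figures.
#' @return the manifest (invisibly); outputs are tab-separated files under
#'   `out_dir`.
#' @export
run_recipe <- function(name = c("fig10_sweep", "afd_calibration",
                                "nd_variants", "window_scan"),
                       config = demography_config(), out_dir, seed = 1L,
                       rates = c(1, 10, 20, 50), plot = TRUE) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown recipe '", name[1L], "'; available: fig10_sweep, ",
         "afd_calibration, nd_variants, window_scan")
  })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  outputs <- character()
  log_stage <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  emit <- function(x, file) {
    path <- file.path(out_dir, file)
    data.table::fwrite(x, path, sep = "\t")
    outputs <<- c(outputs, path)
    path
  }

  if (name == "fig10_sweep") {
    log_stage("stage simulate+stats: sweep over rates %s",
              paste(rates, collapse = ", "))
    sw <- run_migration_sweep(config, rates = rates, seed = seed)
    emit(sw, "sweep_statistics.tsv")
    if (plot) {
      pops <- setdiff(demography_populations(config), "AFR")
      pdf_path <- file.path(out_dir, "nd_profiles.pdf")
      grDevices::pdf(pdf_path, width = 9, height = 4)
      graphics::par(mfrow = c(1, 2))
      for (st in c("nd_NEA_cond", "nd_DEN_cond")) {
        sub <- sw[sw$statistic == st & sw$population %in% pops, ]
        graphics::plot(NULL, xlim = c(1, length(pops)),
                       ylim = range(sub$value, na.rm = TRUE),
                       xlab = "founding order", ylab = st, main = st,
                       xaxt = "n")
        graphics::axis(1, at = seq_along(pops), labels = pops, las = 2,
                       cex.axis = 0.7)
        for (k in seq_along(rates)) {
          s2 <- sub[sub$rate == rates[k], ]
          graphics::lines(match(s2$population, pops), s2$value, type = "b",
                          pch = 16, col = k)
        }
        graphics::legend("topleft", legend = rates, col = seq_along(rates),
                         lty = 1, pch = 16, cex = 0.7, title = "migrants/gen")
      }
      grDevices::dev.off()
      outputs <- c(outputs, pdf_path)
    }
  } else if (name == "afd_calibration") {
    r2 <- range(rates)
    log_stage("stage simulate+stats: AFD calibration at rates %g and %g",
              r2[1], r2[2])
    sw <- run_migration_sweep(config, rates = unique(r2), seed = seed)
    emit(sw[sw$statistic %in% c("AFD", "FST"), ], "afd_calibration.tsv")
  } else if (name == "nd_variants") {
    log_stage("stage simulate: %d fragments", config$num_fragments)
    tab <- simulate_site_table(config, seed)
    log_stage("stage stats: nd variants over %d sites", nrow(tab))
    nd <- nd_table(tab, panel = "AFR", conditioned = c(FALSE, TRUE),
                   mutation_class = c("transitions", "transversions", "both"))
    emit(nd, "nd_variants.tsv")
  } else if (name == "window_scan") {
    log_stage("stage simulate: %d fragments", config$num_fragments)
    tab <- simulate_site_table(config, seed)
    pops <- demography_populations(config)
    log_stage("stage scan: windowed f4 over %d sites", nrow(tab))
    tr <- windowed_f4(tab, "AFR", pops[2L], "NEA", "DEN",
                      window_bp = min(1e6, config$fragment_length))
    fl <- filter_window_outliers(tr)
    emit(fl$track, "window_f4.tsv")
    nd_m <- nd_by_chromosome(tab, focal_archaic = "NEA")
    loo <- leave_one_out_correlation(nd_m)
    emit(data.table::data.table(chrom = names(loo$per_row), r = loo$per_row),
         "leave_one_out_r.tsv")
    log_stage("excluded fraction %.3f; mean leave-one-out r %.3f",
              fl$excluded_fraction, loo$mean_r)
  }

  manifest <- list(
    recipe = name,
    seed = seed,
    package_version = as.character(utils::packageVersion("archstats")),
    config = config[setdiff(names(config), "")],
    rates = rates,
    outputs = data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs))),
    started = format(t0, "%Y-%m-%d %H:%M:%S %Z"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
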