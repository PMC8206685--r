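#' Derived-archaic-allele frequency statistic nd
#'
#' nd is the average frequency, in a focal human population, of alleles that
#' are derived in one archaic (allele "B" in the Neanderthal for nd_NEA, in
#' the Denisovan for nd_DEN) while the other archaic and the chimpanzee are
#' ancestral ("A"). It is computed as a probability: the sum of qualifying
#' B-allele frequencies divided by N, the total number of sites biallelic in
#' humans with base calls in all taxa (in the requested mutation class), not
#' only the qualifying ones. With `conditioned = TRUE` a qualifying site must
#' additionally carry no B allele in any conditioning-panel population with
#' called genotypes (sites at which the whole panel is uncalled do not
#' qualify), so panel populations have nd = 0 by construction.
#'
#' @param table an `aligned_site_table`.
#' @param population focal human population.
#' @param focal_archaic `"NEA"` or `"DEN"`.
#' @param conditioned require the B allele to be absent from the conditioning
#'   panel.
#' @param mutation_class `"both"`, `"transitions"` or `"transversions"`.
#' @param panel character vector of conditioning-panel population names
#'   (required when `conditioned = TRUE`).
#' @return object of class `nd_stat`: list with `nd`, `numerator`, `N` and the
#'   call parameters.
#' @export
compute_nd <- function(table, population, focal_archaic = c("NEA", "DEN"),
                       conditioned = FALSE,
                       mutation_class = c("both", "transitions",
                                          "transversions"),
                       panel = NULL) {
  focal_archaic <- match.arg(focal_archaic)
  mutation_class <- match.arg(mutation_class)
  fcol <- paste0("freq_", population)
  if (!fcol %in% names(table)) stop("unknown population: ", population)
  if (conditioned && (is.null(panel) || length(panel) == 0L)) {
    stop("conditioned nd requires a non-empty conditioning panel")
  }

  cls <- switch(mutation_class,
                both = rep(TRUE, nrow(table)),
                transitions = table$mutation_class == "transition",
                transversions = table$mutation_class == "transversion")
  state <- classify_archaic_state(table)
  want <- if (focal_archaic == "NEA") "XXBAA" else "XXABA"
  qual <- cls & state == want
  if (conditioned) {
    absent <- rep(TRUE, nrow(table))
    called <- rep(FALSE, nrow(table))
    for (p in panel) {
      fp <- table[[paste0("freq_", p)]]
      np <- table[[paste0("n_", p)]]
      has <- !is.na(np) & np > 0L
      absent <- absent & (!has | fp == 0)
      called <- called | has
    }
    qual <- qual & absent & called
  }
  N <- sum(cls & table$hpoly)
  numerator <- sum(table[[fcol]][qual], na.rm = TRUE)
  structure(list(nd = if (N > 0) numerator / N else 0,
                 numerator = numerator, N = N,
                 n_qualifying = sum(qual),
                 population = population, focal_archaic = focal_archaic,
                 conditioned = conditioned, mutation_class = mutation_class),
            class = "nd_stat")
}

#' @export
print.nd_stat <- function(x, ...) {
  cat(sprintf("nd_%s(%s%s, %s) = %.6g  [sum d_i = %.4g over %d sites, N = %d]\n",
              x$focal_archaic, x$population,
              if (x$conditioned) ", conditioned" else "",
              x$mutation_class, x$nd, x$numerator, x$n_qualifying, x$N))
  invisible(x)
}

#' nd table over populations and statistic variants
#'
#' @param table an `aligned_site_table`.
#' @param populations populations to evaluate (default: all in the table).
#' @param panel conditioning-panel populations.
#' @param conditioned,mutation_class vectors of variants to cross.
#' @return tidy data.table: population, focal_archaic, conditioned,
#'   mutation_class, nd, numerator, N.
#' @export
nd_table <- function(table, populations = site_table_populations(table),
                     panel = NULL,
                     conditioned = c(FALSE, TRUE),
                     mutation_class = "both") {
  grid <- data.table::CJ(population = populations,
                         focal_archaic = c("NEA", "DEN"),
                         conditioned = conditioned,
                         mutation_class = mutation_class)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i]
    r <- compute_nd(table, g$population, g$focal_archaic, g$conditioned,
                    g$mutation_class, panel = panel)
    data.table::data.table(g, nd = r$nd, numerator = r$numerator, N = r$N)
  })
  data.table::rbindlist(rows)
}

#' Rescale nd to an approximate genomic fraction
#'
#' Anchors nd linearly on a reference population with an assumed genomic
#' fraction (e.g. French at 2% Neanderthal, Papuans at 5% Denisovan): an nd
#' 1.5x the reference corresponds to a fraction 1.5x the reference fraction.
#'
#' @param nd nd value(s) to convert.
#' @param reference_nd nd of the anchor population.
#' @param reference_fraction assumed genomic fraction of the anchor.
#' @return numeric genomic fraction(s).
#' @export
nd_to_genome_fraction <- function(nd, reference_nd, reference_fraction) {
  if (reference_nd <= 0) stop("reference nd must be positive")
  nd / reference_nd * reference_fraction
}
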