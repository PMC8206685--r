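#' Average allele frequency difference (AFD) between two populations
#'
#' Mean over table sites of |pA - pB| for the B allele, a simple biallelic
#' genetic distance. The average runs over all sites at which both
#' populations are called (the full callable site set, not only sites
#' polymorphic within humans), so monomorphic sites contribute zeros to the
#' mean exactly as they do in the simulated site tables.
#'
#' @param table an `aligned_site_table`.
#' @param pop_a,pop_b population names.
#' @param by_chrom also return per-chromosome sums for jackknife errors.
#' @return object of class `pairwise_dist`: list with `statistic = "AFD"`,
#'   `value`, `n_sites`, optionally `per_chrom`.
#' @export
compute_afd <- function(table, pop_a, pop_b, by_chrom = FALSE) {
  fa <- table[[paste0("freq_", pop_a)]]
  fb <- table[[paste0("freq_", pop_b)]]
  if (is.null(fa)) stop("unknown population: ", pop_a)
  if (is.null(fb)) stop("unknown population: ", pop_b)
  na_ <- table[[paste0("n_", pop_a)]]
  nb_ <- table[[paste0("n_", pop_b)]]
  keep <- !is.na(fa) & !is.na(fb) & na_ > 0L & nb_ > 0L
  n <- sum(keep)
  if (n == 0L) {
    return(structure(list(statistic = "AFD", value = NA_real_, n_sites = 0L,
                          undefined = TRUE, pops = c(pop_a, pop_b)),
                     class = "pairwise_dist"))
  }
  d <- abs(fa - fb)
  d[!keep] <- 0
  res <- list(statistic = "AFD", value = sum(d) / n, n_sites = n,
              undefined = FALSE, pops = c(pop_a, pop_b))
  if (by_chrom) {
    dt <- data.table::data.table(chrom = table$chrom, d = d,
                                 k = as.integer(keep))
    res$per_chrom <- dt[, .(sum_d = sum(d), n_sites = sum(k)), by = chrom]
  }
  structure(res, class = "pairwise_dist")
}

#' Hudson's FST between two populations
#'
#' Per-site Hudson estimator with sample-size correction, combined across
#' sites as a ratio of averages (numerator and denominator summed separately
#' before dividing), which is robust to rare variants. Sites require at least
#' two called alleles in each population.
#'
#' @inheritParams compute_afd
#' @return object of class `pairwise_dist` with `statistic = "FST"`.
#' @export
compute_fst <- function(table, pop_a, pop_b, by_chrom = FALSE) {
  fa <- table[[paste0("freq_", pop_a)]]
  fb <- table[[paste0("freq_", pop_b)]]
  if (is.null(fa)) stop("unknown population: ", pop_a)
  if (is.null(fb)) stop("unknown population: ", pop_b)
  na_ <- table[[paste0("n_", pop_a)]]
  nb_ <- table[[paste0("n_", pop_b)]]
  keep <- !is.na(fa) & !is.na(fb) & na_ >= 2L & nb_ >= 2L
  num <- (fa - fb)^2 - fa * (1 - fa) / pmax(1L, na_ - 1L) -
    fb * (1 - fb) / pmax(1L, nb_ - 1L)
  den <- fa * (1 - fb) + fb * (1 - fa)
  num[!keep] <- 0
  den[!keep] <- 0
  if (sum(den) <= 0) {
    return(structure(list(statistic = "FST", value = NA_real_,
                          n_sites = sum(keep), undefined = TRUE,
                          pops = c(pop_a, pop_b)), class = "pairwise_dist"))
  }
  res <- list(statistic = "FST", value = sum(num) / sum(den),
              n_sites = sum(keep), undefined = FALSE, pops = c(pop_a, pop_b))
  if (by_chrom) {
    dt <- data.table::data.table(chrom = table$chrom, num = num, den = den)
    res$per_chrom <- dt[, .(num = sum(num), den = sum(den)), by = chrom]
  }
  structure(res, class = "pairwise_dist")
}

#' @export
print.pairwise_dist <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s(%s, %s): undefined\n", x$statistic, x$pops[1], x$pops[2]))
  } else {
    cat(sprintf("%s(%s, %s) = %.5g  [n = %d sites]\n", x$statistic,
                x$pops[1], x$pops[2], x$value, x$n_sites))
  }
  invisible(x)
}

#' Mean expected heterozygosity of a population
#'
#' Mean over table sites of 2p(1-p) computed from sample B-allele
#' frequencies. Sites where the population is uncalled are excluded from the
#' divisor.
#'
#' @param table an `aligned_site_table`.
#' @param population population name.
#' @param by_chrom also return per-chromosome sums.
#' @return list with `H`, `n_sites`, optionally `per_chrom`.
#' @export
compute_heterozygosity <- function(table, population, by_chrom = FALSE) {
  f <- table[[paste0("freq_", population)]]
  if (is.null(f)) stop("unknown population: ", population)
  np <- table[[paste0("n_", population)]]
  keep <- !is.na(f) & np > 0L
  h <- 2 * f * (1 - f)
  h[!keep] <- 0
  res <- list(H = if (sum(keep)) sum(h) / sum(keep) else NA_real_,
              n_sites = sum(keep), population = population)
  if (by_chrom) {
    dt <- data.table::data.table(chrom = table$chrom, h = h,
                                 k = as.integer(keep))
    res$per_chrom <- dt[, .(sum_h = sum(h), n_sites = sum(k)), by = chrom]
  }
  res
}

#' Heterozygosity loss relative to a reference population
#'
#' The out-of-Africa bottleneck calibration: loss = 1 - H_pop / H_ref,
#' conventionally with an African reference.
#'
#' @param table an `aligned_site_table`.
#' @param population bottlenecked population.
#' @param reference reference population (e.g. the African population).
#' @return list with `loss`, `H_pop`, `H_ref`.
#' @export
heterozygosity_loss <- function(table, population, reference) {
  hp <- compute_heterozygosity(table, population)
  hr <- compute_heterozygosity(table, reference)
  list(loss = 1 - hp$H / hr$H, H_pop = hp$H, H_ref = hr$H,
       population = population, reference = reference)
}
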