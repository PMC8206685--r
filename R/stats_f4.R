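#' The f4 statistic
#'
#' f4(P1, P2; P3, P4) is the mean over sites of the product of paired
#' B-allele frequency differences (p1 - p2)(p3 - p4). Taxa may be human
#' populations (sample frequencies), non-human taxa with allele states
#' (frequency 0 or 1; single genomes via `gt_` columns contribute 0, 1/2 or
#' 1), or the chimpanzee (always 0 after polarization). Because the paired
#' differences are expected to be uncorrelated without introgression or
#' shared drift, the Pearson correlation of the two difference vectors is
#' reported alongside the mean product.
#'
#' @param table an `aligned_site_table`.
#' @param p1,p2,p3,p4 taxon/population/individual names resolvable in the
#'   table.
#' @return object of class `f4_stat`: list with `f4`, `n_sites`,
#'   `correlation`, `undefined` flag.
#' @export
compute_f4 <- function(table, p1, p2, p3, p4) {
  who <- c(p1, p2, p3, p4)
  if (anyDuplicated(who)) stop("the four taxa must be distinct")
  f <- lapply(who, function(w) resolve_freq(table, w))
  keep <- Reduce(`&`, lapply(f, function(v) !is.na(v)))
  d12 <- f[[1]][keep] - f[[2]][keep]
  d34 <- f[[3]][keep] - f[[4]][keep]
  n <- sum(keep)
  if (n == 0L) {
    return(structure(list(f4 = NA_real_, n_sites = 0L, correlation = NA_real_,
                          undefined = TRUE, taxa = who), class = "f4_stat"))
  }
  r <- if (n >= 3L && stats::var(d12) > 0 && stats::var(d34) > 0) {
    stats::cor(d12, d34)
  } else NA_real_
  structure(list(f4 = mean(d12 * d34), n_sites = n, correlation = r,
                 undefined = FALSE, taxa = who), class = "f4_stat")
}

#' @export
print.f4_stat <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("f4(%s, %s; %s, %s): undefined (no shared callable sites)\n",
                x$taxa[1], x$taxa[2], x$taxa[3], x$taxa[4]))
  } else {
    cat(sprintf("f4(%s, %s; %s, %s) = %.3e  [n = %d, r(paired diffs) = %.3f]\n",
                x$taxa[1], x$taxa[2], x$taxa[3], x$taxa[4],
                x$f4, x$n_sites, x$correlation))
  }
  invisible(x)
}
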