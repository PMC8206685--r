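#' Classify a four-taxon site pattern as ABBA or BABA
#'
#' With the chimpanzee fixed as allele "A" and the archaic carrying "B",
#' informative sites are those where the two humans differ: ABBA means the
#' second human shares the archaic allele, BABA the first.
#'
#' @param p1,p2 alleles carried by the two humans ("A"/"B", vectors recycle).
#' @param archaic allele state of the archaic taxon ("A"/"B"/NA).
#' @return character vector: `"ABBA"`, `"BABA"` or `"uninformative"`.
#' @export
classify_site_pattern <- function(p1, p2, archaic) {
  out <- rep("uninformative", max(length(p1), length(p2), length(archaic)))
  ok <- !is.na(p1) & !is.na(p2) & !is.na(archaic) & archaic == "B"
  out[ok & p1 == "A" & p2 == "B"] <- "ABBA"
  out[ok & p1 == "B" & p2 == "A"] <- "BABA"
  out
}

#' Classify the joint archaic allele state of each site
#'
#' Writing the two human alleles as X, a site is `XXBAA` when the Neanderthal
#' alone carries the derived allele (Denisovan and chimpanzee ancestral),
#' `XXABA` when the Denisovan alone does, and `XXBBA` when both archaics share
#' the same derived allele (such sites contribute to neither nd numerator).
#'
#' @param table an `aligned_site_table` with `state_NEA` and `state_DEN`.
#' @return character vector: `"XXBAA"`, `"XXABA"`, `"XXBBA"` or `"other"`.
#' @export
classify_archaic_state <- function(table) {
  nea <- table$state_NEA
  den <- table$state_DEN
  out <- rep("other", nrow(table))
  ok <- !is.na(nea) & !is.na(den)
  out[ok & nea == "B" & den == "A"] <- "XXBAA"
  out[ok & nea == "A" & den == "B"] <- "XXABA"
  out[ok & nea == "B" & den == "B"] <- "XXBBA"
  out
}

#' The ABBA-BABA D statistic between two diploid humans
#'
#' D = (ABBA - BABA) / (ABBA + BABA) over sites where the chimpanzee carries
#' "A" and the archaic taxon carries "B". By default each human contributes
#' fractionally at heterozygous sites (a site is ABBA with weight equal to the
#' B dosage of the second human times the A dosage of the first, divided by
#' 4); `mode = "haplotype"` instead samples one allele per individual per site
#' under a fixed seed. Conditioning restricts the informative sites to those
#' heterozygous or homozygous in one of the two humans before counting.
#'
#' @param table an `aligned_site_table` carrying `gt_` columns for the two
#'   individuals.
#' @param p1,p2 names of the two focal humans (their `gt_<name>` columns),
#'   conventionally an African (p1) and a non-African (p2).
#' @param archaic taxon used as P3, e.g. `"NEA"`.
#' @param conditioning one of `"none"`, `"het-in-P1"`, `"hom-in-P1"`,
#'   `"het-in-P2"`, `"hom-in-P2"`.
#' @param mode `"frequency"` (fractional counting, default) or `"haplotype"`.
#' @param seed RNG seed for haplotype mode.
#' @param by_chrom also return per-chromosome ABBA/BABA counts (for
#'   Monte-Carlo/jackknife errors).
#' @return object of class `d_stat`: list with `D`, `abba`, `baba`,
#'   `n_informative`, `undefined` flag, and optionally `per_chrom`.
#' @export
compute_d <- function(table, p1, p2, archaic = "NEA",
                      conditioning = c("none", "het-in-P1", "hom-in-P1",
                                       "het-in-P2", "hom-in-P2"),
                      mode = c("frequency", "haplotype"), seed = 1L,
                      by_chrom = FALSE) {
  conditioning <- match.arg(conditioning)
  mode <- match.arg(mode)
  if (identical(p1, p2)) {
    return(structure(list(D = NA_real_, abba = 0, baba = 0, n_informative = 0L,
                          undefined = TRUE, conditioning = conditioning,
                          p1 = p1, p2 = p2, archaic = archaic),
                     class = "d_stat"))
  }
  g1 <- dosage_of(table, p1)
  g2 <- dosage_of(table, p2)
  st <- table[[paste0("state_", archaic)]]
  if (is.null(st)) stop("no allele states for archaic taxon '", archaic, "'")
  keep <- !is.na(g1) & !is.na(g2) & !is.na(st) & st == "B"
  keep <- keep & switch(conditioning,
    "none" = TRUE,
    "het-in-P1" = g1 == 1L, "hom-in-P1" = g1 != 1L,
    "het-in-P2" = g2 == 1L, "hom-in-P2" = g2 != 1L)
  if (mode == "haplotype") {
    withr_seed(seed, {
      g1 <- stats::rbinom(length(g1), 1L, g1 / 2) * 2L
      g2 <- stats::rbinom(length(g2), 1L, g2 / 2) * 2L
    })
  }
  w1 <- g1 / 2
  w2 <- g2 / 2
  abba_w <- (1 - w1) * w2
  baba_w <- w1 * (1 - w2)
  abba_w[!keep] <- 0
  baba_w[!keep] <- 0
  abba <- sum(abba_w)
  baba <- sum(baba_w)
  res <- list(D = if (abba + baba > 0) (abba - baba) / (abba + baba)
                  else NA_real_,
              abba = abba, baba = baba,
              n_informative = sum(keep & (abba_w + baba_w > 0)),
              undefined = abba + baba <= 0,
              conditioning = conditioning, p1 = p1, p2 = p2, archaic = archaic)
  if (by_chrom) {
    dt <- data.table::data.table(chrom = table$chrom, abba = abba_w,
                                 baba = baba_w)
    res$per_chrom <- dt[, .(abba = sum(abba), baba = sum(baba)), by = chrom]
  }
  structure(res, class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("D(%s, %s; %s, chimp): undefined (no informative sites)\n",
                x$p1, x$p2, x$archaic))
  } else {
    cat(sprintf(
      "D(%s, %s; %s, chimp) = %.4f  [ABBA = %.1f, BABA = %.1f, n = %d%s]\n",
      x$p1, x$p2, x$archaic, x$D, x$abba, x$baba, x$n_informative,
      if (x$conditioning != "none") paste0(", ", x$conditioning) else ""))
  }
  invisible(x)
}

## dosage vector (0/1/2 B alleles) for an individual gt column
dosage_of <- function(table, who) {
  gcol <- paste0("gt_", who)
  if (!gcol %in% names(table)) {
    stop("no diploid genotypes for '", who,
         "' in the table (expected column ", gcol, ")")
  }
  table[[gcol]]
}

## evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' Block jackknife standard error over chromosomes/fragments
#'
#' Leave-one-block-out standard error of a ratio-of-sums statistic given a
#' per-block table of numerator/denominator contributions.
#'
#' @param per_block data.table/data.frame with block label column and the
#'   numeric contribution columns.
#' @param fun function(table) -> scalar computing the statistic from summed
#'   contributions.
#' @return list with `estimate`, `se`, `n_blocks`.
#' @export
jackknife_se <- function(per_block, fun) {
  per_block <- data.table::as.data.table(per_block)
  n <- nrow(per_block)
  if (n < 2L) return(list(estimate = fun(per_block), se = NA_real_,
                          n_blocks = n))
  est <- fun(per_block)
  loo <- vapply(seq_len(n), function(i) fun(per_block[-i]), numeric(1))
  list(estimate = est,
       se = sqrt((n - 1) * mean((loo - mean(loo))^2)),
       n_blocks = n)
}
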