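#' Filter an archaic base call
#'
#' Single ancient genomes are accepted only where they are confidently
#' homozygous: total read depth at least `min_depth` and strictly below
#' `max_depth`, and more than a fraction `majority` of reads supporting one
#' base. Candidate heterozygous sites (majority fraction at or below the
#' threshold) are treated as missing, not as errors.
#'
#' @param base_counts named numeric vector of per-base read counts, names in
#'   A/C/G/T.
#' @param min_depth minimum total reads (inclusive).
#' @param max_depth maximum total reads (exclusive).
#' @param majority required fraction of reads for the called base (strict).
#' @return list with `pass` (logical) and `base` (the called base, or `NA`).
#' @examples
#' filter_archaic_call(c(A = 14, G = 1))          # pass, base "A"
#' filter_archaic_call(c(A = 15, G = 5))          # fail: 0.75 <= 0.8
#' @export
filter_archaic_call <- function(base_counts, min_depth = 10, max_depth = 250,
                                majority = 0.8) {
  if (length(base_counts) == 0L) stop("base_counts must be non-empty")
  if (any(is.na(base_counts)) || any(base_counts < 0)) {
    stop("malformed archaic call record: negative or missing base counts")
  }
  bad <- setdiff(names(base_counts), c("A", "C", "G", "T"))
  if (is.null(names(base_counts)) || length(bad) > 0L) {
    stop("base counts must be named with bases A/C/G/T")
  }
  depth <- sum(base_counts)
  top <- which.max(base_counts)
  ok <- depth >= min_depth && depth < max_depth &&
    base_counts[[top]] / depth > majority
  list(pass = ok, base = if (ok) names(base_counts)[top] else NA_character_,
       depth = depth)
}

#' Vectorized archaic call filter
#'
#' @param calls data.frame/data.table with columns `chrom`, `pos` and one
#'   count column per base (`A`, `C`, `G`, `T`).
#' @inheritParams filter_archaic_call
#' @return data.table `chrom`, `pos`, `base` for passing sites only.
#' @export
filter_archaic_calls <- function(calls, min_depth = 10, max_depth = 250,
                                 majority = 0.8) {
  calls <- data.table::as.data.table(calls)
  bases <- c("A", "C", "G", "T")
  present <- intersect(bases, names(calls))
  if (length(present) == 0L) stop("no base-count columns (A/C/G/T) found")
  m <- as.matrix(calls[, .SD, .SDcols = present])
  m[is.na(m)] <- 0
  if (any(m < 0)) stop("malformed archaic call record: negative base counts")
  depth <- rowSums(m)
  top <- max.col(m, ties.method = "first")
  topn <- m[cbind(seq_len(nrow(m)), top)]
  pass <- depth >= min_depth & depth < max_depth & topn / depth > majority
  out <- calls[pass, .(chrom = normalize_chrom(chrom), pos = pos)]
  out[, base := present[top[pass]]]
  out[]
}

#' Classify a biallelic substitution as transition or transversion
#'
#' @param base1,base2 the two observed bases (vectors recycle).
#' @return character vector, `"transition"` (A<->G, C<->T) or
#'   `"transversion"`.
#' @export
classify_mutation <- function(base1, base2) {
  b1 <- toupper(base1)
  b2 <- toupper(base2)
  ok <- b1 %in% c("A", "C", "G", "T") & b2 %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("invalid site: bases must be in A/C/G/T")
  if (any(b1 == b2)) stop("invalid site: the two bases must differ")
  purine <- function(b) b %in% c("A", "G")
  ifelse(purine(b1) == purine(b2), "transition", "transversion")
}

#' Normalize chromosome labels ("chr1" <-> "1")
#' @param x character vector of chromosome labels.
#' @return labels without a "chr" prefix.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read a sample -> population -> region panel
#'
#' @param panel_file tab-separated file with columns `sample`, `population`,
#'   `region` (header optional, detected).
#' @param coords_file optional tab-separated file `population`, `lat`, `lon`
#'   in decimal degrees.
#' @param conditioning_panel character vector of population names making up
#'   the conditioning panel (e.g. the non-admixed African populations).
#' @return a `population_panel` object.
#' @export
read_population_panel <- function(panel_file, coords_file = NULL,
                                  conditioning_panel = character()) {
  p <- data.table::fread(panel_file, header = "auto")
  if (ncol(p) < 3L) stop("panel file needs sample, population, region columns")
  data.table::setnames(p, 1:3, c("sample", "population", "region"))
  coords <- NULL
  if (!is.null(coords_file)) {
    coords <- data.table::fread(coords_file, header = "auto")
    data.table::setnames(coords, 1:3, c("population", "lat", "lon"))
  }
  population_panel(p, coords, conditioning_panel)
}

#' Construct a population panel
#'
#' @param samples data.frame with columns `sample`, `population`, `region`.
#' @param coords optional data.frame with `population`, `lat`, `lon`.
#' @param conditioning_panel populations whose joint absence of the derived
#'   archaic allele defines the conditioned nd statistics.
#' @return a `population_panel` object (list with `samples`, `coords`,
#'   `conditioning_panel`).
#' @export
population_panel <- function(samples, coords = NULL,
                             conditioning_panel = character()) {
  samples <- data.table::as.data.table(samples)
  if (anyDuplicated(samples$sample)) {
    stop("every sample must belong to exactly one population")
  }
  p2r <- unique(samples[, .(population, region)])
  if (anyDuplicated(p2r$population)) {
    stop("every population must belong to exactly one region")
  }
  extra <- setdiff(conditioning_panel, samples$population)
  if (length(extra) > 0L) {
    stop("conditioning panel populations absent from the panel: ",
         paste(extra, collapse = ", "))
  }
  structure(list(samples = samples,
                 coords = if (!is.null(coords)) data.table::as.data.table(coords),
                 conditioning_panel = conditioning_panel),
            class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  cat(sprintf("Population panel: %d samples, %d populations, %d regions\n",
              nrow(x$samples), length(unique(x$samples$population)),
              length(unique(x$samples$region))))
  if (length(x$conditioning_panel)) {
    cat("Conditioning panel:", paste(x$conditioning_panel, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Read human genotypes from a VCF
#'
#' Biallelic SNVs only; indels and multiallelic records are dropped (counted).
#' Missing genotypes reduce the per-population call count.
#'
#' @param file path to a VCF (may be bgzipped).
#' @return list with `sites` (data.table `chrom`, `pos`, `ref`, `alt`),
#'   `dosage` (matrix sites x samples of ALT-allele dosage 0/1/2, NA for
#'   missing) and `dropped` (count of excluded records).
#' @export
read_human_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- data.table::as.data.table(vcfR::getFIX(v))
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep[is.na(keep)] <- FALSE
  dropped <- sum(!keep)
  fix <- fix[keep]
  gt <- gt[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt)
  list(sites = data.table::data.table(chrom = normalize_chrom(fix$CHROM),
                                      pos = as.integer(fix$POS),
                                      ref = fix$REF, alt = fix$ALT),
       dosage = dos, dropped = dropped)
}

## "0/1"-style genotype strings -> ALT dosage
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[!(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))] <- NA
  matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read archaic base counts from a VCF with AD/DP fields
#'
#' Returns raw per-site base counts suitable for [filter_archaic_calls()].
#' Sites without an AD field fall back to DP assigned to the genotype call.
#'
#' @param file path to a single-genome VCF.
#' @return data.table `chrom`, `pos` and base-count columns `A`,`C`,`G`,`T`.
#' @export
read_archaic_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- data.table::as.data.table(vcfR::getFIX(v))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP"), error = function(e) NULL)
  n <- nrow(fix)
  out <- data.table::data.table(chrom = normalize_chrom(fix$CHROM),
                                pos = as.integer(fix$POS),
                                A = 0, C = 0, G = 0, T = 0)
  alleles <- cbind(fix$REF, fix$ALT)
  for (i in seq_len(n)) {
    als <- c(alleles[i, 1L], strsplit(alleles[i, 2L], ",", fixed = TRUE)[[1]])
    if (!is.null(ad) && !is.na(ad[i, 1L])) {
      cnt <- as.numeric(strsplit(ad[i, 1L], ",", fixed = TRUE)[[1]])
    } else if (!is.null(dp) && !is.na(dp[i, 1L])) {
      cnt <- c(as.numeric(dp[i, 1L]), rep(0, length(als) - 1L))
    } else {
      cnt <- rep(0, length(als))
    }
    for (j in seq_along(als)) {
      b <- als[j]
      if (b %in% c("A", "C", "G", "T") && j <= length(cnt)) {
        data.table::set(out, i, b, out[[b]][i] + cnt[j])
      }
    }
  }
  out[]
}

#' Read outgroup alleles
#'
#' Either a per-site call set (TSV `chrom`, `pos`, `base`) or an
#' ancestral-allele annotation of the same shape; both reduce to a
#' chrom/pos/base lookup.
#'
#' @param file path to the tab-separated allele table.
#' @return data.table `chrom`, `pos`, `base`.
#' @export
read_outgroup_alleles <- function(file) {
  x <- data.table::fread(file, header = "auto")
  data.table::setnames(x, 1:3, c("chrom", "pos", "base"))
  x[, chrom := normalize_chrom(chrom)]
  x[, base := toupper(base)]
  x[]
}

#' Assemble the aligned multi-taxon site table from variant calls
#'
#' Joins human genotypes, filtered archaic calls and the outgroup allele
#' source on (chrom, pos); keeps sites with a call in every requested taxon
#' and a biallelic state overall; polarizes alleles so the chimpanzee carries
#' "A"; computes per-population B-allele frequencies and the
#' transition/transversion class.
#'
#' @param human result of [read_human_vcf()].
#' @param archaic_calls named list of filtered call tables (chrom, pos, base),
#'   one per archaic/great-ape taxon, e.g. `list(NEA = ..., DEN = ...)`.
#' @param outgroup chimpanzee allele table (chrom, pos, base); sites without a
#'   chimpanzee call are dropped.
#' @param panel a `population_panel` covering the VCF samples.
#' @param focal_samples optional named character vector population -> sample
#'   id; those samples' diploid dosages are retained as `gt_<POP>` columns.
#' @return an `aligned_site_table`.
#' @export
build_site_table <- function(human, archaic_calls, outgroup, panel,
                             focal_samples = NULL) {
  stopifnot(inherits(panel, "population_panel"))
  sites <- data.table::copy(human$sites)
  sites[, row := .I]
  drop_counts <- c(multiallelic = as.integer(human$dropped),
                   no_outgroup = 0L, no_archaic = 0L, triallelic = 0L)

  og <- data.table::as.data.table(outgroup)
  data.table::setnames(og, 1:3, c("chrom", "pos", "base"))
  og[, chrom := normalize_chrom(chrom)]
  sites <- merge(sites, og[, .(chrom, pos, chimp = base)],
                 by = c("chrom", "pos"), all.x = TRUE, sort = FALSE)
  drop_counts["no_outgroup"] <- sum(is.na(sites$chimp))
  sites <- sites[!is.na(chimp)]

  for (tx in names(archaic_calls)) {
    ac <- data.table::as.data.table(archaic_calls[[tx]])
    data.table::setnames(ac, 1:3, c("chrom", "pos", "base"))
    ac[, chrom := normalize_chrom(chrom)]
    data.table::setnames(ac, "base", paste0("base_", tx))
    sites <- merge(sites, ac, by = c("chrom", "pos"), all.x = TRUE,
                   sort = FALSE)
    miss <- is.na(sites[[paste0("base_", tx)]])
    drop_counts["no_archaic"] <- drop_counts["no_archaic"] + sum(miss)
    sites <- sites[!miss]
  }

  # biallelic across all taxa: every taxon base must be ref or alt,
  # and the chimpanzee base must be one of the two human alleles
  taxa_bases <- c("chimp", paste0("base_", names(archaic_calls)))
  ok <- rep(TRUE, nrow(sites))
  for (tb in taxa_bases) {
    ok <- ok & (sites[[tb]] == sites$ref | sites[[tb]] == sites$alt)
  }
  drop_counts["triallelic"] <- sum(!ok)
  sites <- sites[ok]
  if (nrow(sites) == 0L) stop("no sites survived the multi-taxon join")

  # polarization: chimpanzee allele is A
  sites[, allele_A := chimp]
  sites[, allele_B := ifelse(chimp == ref, alt, ref)]
  sites[, mutation_class := classify_mutation(allele_A, allele_B)]

  dos <- human$dosage[sites$row, , drop = FALSE]
  # dosage counts ALT; flip where ALT is the A allele
  flip <- sites$allele_B == sites$ref
  dos[flip, ] <- 2 - dos[flip, , drop = FALSE]

  smp <- panel$samples
  pops <- unique(smp$population)
  out <- sites[, .(chrom, pos, allele_A, allele_B, mutation_class)]
  for (tx in names(archaic_calls)) {
    out[, paste0("state_", tx) :=
          ifelse(sites[[paste0("base_", tx)]] == sites$allele_A, "A", "B")]
  }
  for (p in pops) {
    cols <- intersect(smp[smp$population == p, ]$sample, colnames(dos))
    if (length(cols) == 0L) next
    sub <- dos[, cols, drop = FALSE]
    out[, paste0("n_", p) := as.integer(2L * rowSums(!is.na(sub)))]
    out[, paste0("freq_", p) := rowSums(sub, na.rm = TRUE) /
          pmax(1L, 2L * rowSums(!is.na(sub)))]
  }
  if (!is.null(focal_samples)) {
    for (p in names(focal_samples)) {
      s <- focal_samples[[p]]
      if (!s %in% colnames(dos)) stop("focal sample not in VCF: ", s)
      out[, paste0("gt_", p) := as.integer(dos[, s])]
    }
  }
  pops <- intersect(pops, sub("^freq_", "", grep("^freq_", names(out),
                                                 value = TRUE)))
  as_site_table(out, populations = pops,
                taxa = c("chimp", names(archaic_calls)),
                drop_counts = drop_counts)
}
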