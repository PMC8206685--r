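#' Per-chromosome nd matrix
#'
#' Computes nd separately for each chromosome (or simulated fragment group)
#' and population, the input of the leave-one-out consistency analysis.
#'
#' @param table an `aligned_site_table`.
#' @param populations populations to evaluate (default: all).
#' @param focal_archaic `"NEA"` or `"DEN"`.
#' @param groups optional named vector mapping chromosome label -> group
#'   label (e.g. to pool simulated fragments into pseudo-chromosomes).
#' @inheritParams compute_nd
#' @return a `chrom_stat_matrix`: numeric matrix, rows = chromosomes, columns
#'   = populations, with an `excluded` attribute (empty).
#' @export
nd_by_chromosome <- function(table, populations = site_table_populations(table),
                             focal_archaic = "NEA", conditioned = FALSE,
                             mutation_class = "both", panel = NULL,
                             groups = NULL) {
  chroms <- if (is.null(groups)) table$chrom else unname(groups[table$chrom])
  labs <- sort(unique(chroms))
  m <- matrix(NA_real_, length(labs), length(populations),
              dimnames = list(labs, populations))
  for (lab in labs) {
    sub <- table[chroms == lab]
    data.table::setattr(sub, "populations", attr(table, "populations"))
    data.table::setattr(sub, "taxa", attr(table, "taxa"))
    data.table::setattr(sub, "class", class(table))
    for (p in populations) {
      m[lab, p] <- compute_nd(sub, p, focal_archaic, conditioned,
                              mutation_class, panel = panel)$nd
    }
  }
  structure(m, excluded = character(), class = "chrom_stat_matrix")
}

#' Drop chromosomes from a chromosome-by-population matrix
#'
#' By default drops chromosome 21, which in the real alignments contributes
#' 20-50-fold fewer usable sites than other chromosomes of similar size.
#'
#' @param matrix a `chrom_stat_matrix` (or plain matrix with row names).
#' @param labels chromosome labels to drop (`"chr21"`/`"21"` equivalent).
#' @return the matrix without those rows; dropped labels recorded in the
#'   `excluded` attribute.
#' @export
exclude_chromosomes <- function(matrix, labels = "chr21") {
  labs <- normalize_chrom(labels)
  rows <- normalize_chrom(rownames(matrix))
  hit <- rows %in% labs
  missing <- setdiff(labs, rows)
  if (length(missing) > 0L && length(labels) > 0L) {
    warning("labels not present, no-op for: ", paste(missing, collapse = ", "))
  }
  if (all(hit)) stop("excluding all chromosomes leaves an empty matrix")
  out <- matrix[!hit, , drop = FALSE]
  structure(out,
            excluded = c(attr(matrix, "excluded"), rownames(matrix)[hit]),
            class = "chrom_stat_matrix")
}

#' Leave-one-out chromosome consistency correlations
#'
#' For each chromosome, the Pearson correlation between its across-population
#' statistic vector and the mean vector over all other chromosomes. Under
#' drift following a single admixture event these correlations have no
#' consistent sign; a high mean r says the across-population profile is a
#' genome-wide property.
#'
#' @param matrix a `chrom_stat_matrix` (rows chromosomes, columns
#'   populations).
#' @return list with `per_row` (named vector of r, NA where a row has zero
#'   variance) and `mean_r`.
#' @export
leave_one_out_correlation <- function(matrix) {
  m <- unclass(matrix)
  if (nrow(m) < 3L || ncol(m) < 3L) {
    stop("need at least 3 chromosomes and 3 populations")
  }
  rs <- vapply(seq_len(nrow(m)), function(i) {
    own <- m[i, ]
    rest <- colMeans(m[-i, , drop = FALSE], na.rm = TRUE)
    if (stats::var(own) == 0 || stats::var(rest) == 0) return(NA_real_)
    stats::cor(own, rest)
  }, numeric(1))
  names(rs) <- rownames(m)
  list(per_row = rs, mean_r = mean(rs, na.rm = TRUE))
}

#' f4 in non-overlapping genomic windows
#'
#' Tiles each chromosome with half-open windows `[start, end)` anchored at
#' position 1 and computes f4 within each; windows with no usable site are
#' reported with a missing value, not zero. The site-count-weighted mean of
#' window values reproduces the global f4 exactly.
#'
#' @param table an `aligned_site_table` (sorted by chrom, pos).
#' @param p1,p2,p3,p4 taxa as in [compute_f4()].
#' @param window_bp window size in bp.
#' @return a `window_stat_track` data.table: chrom, start, end, f4, n_sites.
#' @export
windowed_f4 <- function(table, p1, p2, p3, p4, window_bp = 1e6) {
  o <- order(table$chrom, table$pos)
  if (!identical(o, seq_len(nrow(table)))) {
    stop("site table must be sorted by chrom, pos; sort before scanning")
  }
  f <- lapply(c(p1, p2, p3, p4), function(w) resolve_freq(table, w))
  keep <- Reduce(`&`, lapply(f, function(v) !is.na(v)))
  prod_ <- (f[[1]] - f[[2]]) * (f[[3]] - f[[4]])
  prod_[!keep] <- 0
  dt <- data.table::data.table(
    chrom = table$chrom,
    start = (table$pos - 1L) %/% as.integer(window_bp) *
      as.integer(window_bp) + 1L,
    v = prod_, k = as.integer(keep))
  agg <- dt[, .(f4 = ifelse(sum(k) > 0, sum(v) / sum(k), NA_real_),
                n_sites = sum(k)), by = .(chrom, start)]
  # complete tiling: windows with no sites at all appear as missing values
  grid <- dt[, .(start = seq.int(1L, max(start), by = as.integer(window_bp))),
             by = chrom]
  agg <- merge(grid, agg, by = c("chrom", "start"), all.x = TRUE)
  agg[is.na(n_sites), n_sites := 0L]
  agg[, end := start + as.integer(window_bp)]
  data.table::setcolorder(agg, c("chrom", "start", "end", "f4", "n_sites"))
  data.table::setattr(agg, "taxa", c(p1, p2, p3, p4))
  data.table::setattr(agg, "class",
                      c("window_stat_track", class(data.table::data.table())))
  agg[]
}

#' Filter window outliers
#'
#' Drops windows with fewer than `min_sites` usable sites and absolute values
#' above `clip` (the megabase-scale f4 plots clip at 0.004), reporting the
#' excluded fraction. The exact rule behind the published exclusion fractions
#' is not specified anywhere; this one is declared and configurable.
#'
#' @param track a `window_stat_track`.
#' @param min_sites minimum usable sites per window.
#' @param clip absolute-value clip (Inf disables).
#' @param value_col column to clip.
#' @return list with `track` (filtered) and `excluded_fraction`.
#' @export
filter_window_outliers <- function(track, min_sites = 20L, clip = 0.004,
                                   value_col = "f4") {
  if (nrow(track) == 0L) stop("empty track")
  v <- track[[value_col]]
  keep <- track$n_sites >= min_sites & !is.na(v) & abs(v) <= clip
  list(track = track[keep],
       excluded_fraction = 1 - sum(keep) / nrow(track))
}

#' Correlate two window tracks
#'
#' Pearson correlation over windows shared (same chrom and start) between two
#' tracks, typically after outlier filtering.
#'
#' @param track_a,track_b `window_stat_track`s.
#' @param value_col value column name.
#' @return list with `r`, `n`, `p`, `flag`.
#' @export
correlate_tracks <- function(track_a, track_b, value_col = "f4") {
  a <- track_a[!is.na(track_a[[value_col]]),
               c("chrom", "start", value_col), with = FALSE]
  b <- track_b[!is.na(track_b[[value_col]]),
               c("chrom", "start", value_col), with = FALSE]
  data.table::setnames(a, value_col, "va")
  data.table::setnames(b, value_col, "vb")
  j <- merge(a, b, by = c("chrom", "start"))
  if (nrow(j) < 3L) {
    return(list(r = NA_real_, n = nrow(j), p = NA_real_,
                flag = "fewer than 3 shared windows"))
  }
  ct <- stats::cor.test(j$va, j$vb)
  list(r = unname(ct$estimate), n = nrow(j), p = ct$p.value, flag = NA_character_)
}
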