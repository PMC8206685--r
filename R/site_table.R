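#' Aligned multi-taxon site table
#'
#' The substrate of every statistic in the package: one row per biallelic SNV
#' at which base calls exist for all requested taxa. Alleles are polarized so
#' that the chimpanzee outgroup always carries allele "A"; "B" is the other
#' observed allele. Columns:
#'
#' * `chrom`, `pos` -- 1-based coordinates (simulated fragments use
#'   pseudo-chromosome labels `frag0001`, ...).
#' * `allele_A`, `allele_B` -- the two observed bases.
#' * `mutation_class` -- `"transition"` or `"transversion"`.
#' * `state_<TAXON>` -- archaic/great-ape allele state, `"A"`, `"B"` or `NA`
#'   (e.g. `state_NEA`, `state_DEN`).
#' * `freq_<POP>`, `n_<POP>` -- B-allele frequency and number of called
#'   alleles per human population.
#' * `gt_<POP>` -- B-allele dosage (0/1/2) of one focal diploid individual
#'   per population, used by the individual-based D statistic. Simulated
#'   tables also carry `gt_NEA`/`gt_DEN` (one diploid archaic individual) and
#'   `ac_<TAXON>`/`an_<TAXON>` archaic panel counts.
#' * `hpoly` -- TRUE if the site is polymorphic within the pooled human
#'   samples (the "biallelic in humans" divisor set of the nd statistics).
#'
#' @param x data.table with the columns above.
#' @param populations character vector of human population names.
#' @param taxa character vector of non-human taxon names with state columns.
#' @param drop_counts named integer vector of sites discarded during
#'   construction (multiallelic, missing outgroup, ...).
#' @return `x` with class `aligned_site_table` and metadata attributes.
#' @export
as_site_table <- function(x, populations, taxa,
                          drop_counts = c(multiallelic = 0L)) {
  x <- data.table::as.data.table(x)
  need <- c("chrom", "pos", "allele_A", "allele_B", "mutation_class")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("site table is missing columns: ", paste(miss, collapse = ", "))
  }
  fcols <- paste0("freq_", populations)
  miss <- setdiff(fcols, names(x))
  if (length(miss) > 0L) {
    stop("site table is missing frequency columns: ",
         paste(miss, collapse = ", "))
  }
  for (fc in fcols) {
    bad <- !is.na(x[[fc]]) & (x[[fc]] < 0 | x[[fc]] > 1)
    if (any(bad)) stop("frequencies outside [0,1] in column ", fc)
  }
  if (!"hpoly" %in% names(x)) {
    nb <- rowSums(as.matrix(x[, .SD, .SDcols = fcols]) *
                    as.matrix(x[, .SD, .SDcols = paste0("n_", populations)]),
                  na.rm = TRUE)
    nn <- rowSums(as.matrix(x[, .SD, .SDcols = paste0("n_", populations)]),
                  na.rm = TRUE)
    x[, hpoly := nb > 0 & nb < nn]
  }
  data.table::setattr(x, "populations", populations)
  data.table::setattr(x, "taxa", taxa)
  data.table::setattr(x, "drop_counts", drop_counts)
  data.table::setattr(x, "class",
                      c("aligned_site_table", class(data.table::data.table())))
  x[]
}

#' @export
print.aligned_site_table <- function(x, ...) {
  cat(sprintf("Aligned site table: %d sites, %d populations (%s), taxa: %s\n",
              nrow(x), length(attr(x, "populations")),
              paste(attr(x, "populations"), collapse = ", "),
              paste(attr(x, "taxa"), collapse = ", ")))
  dc <- attr(x, "drop_counts")
  if (!is.null(dc) && sum(dc) > 0) {
    cat("Dropped during construction:",
        paste(sprintf("%s=%d", names(dc), dc), collapse = ", "), "\n")
  }
  NextMethod()
  invisible(x)
}

#' Population names of a site table
#' @param table an `aligned_site_table`.
#' @return character vector.
#' @export
site_table_populations <- function(table) attr(table, "populations")

#' Write / read an aligned site table as tab-separated text
#'
#' The serialization is a plain TSV with a `#archstats` header line carrying
#' the population/taxon metadata as JSON; `read_site_table()` round-trips it
#' bit-exactly.
#'
#' @param table an `aligned_site_table`.
#' @param file path.
#' @return `write_site_table()` returns `file` invisibly; `read_site_table()`
#'   returns the table.
#' @export
write_site_table <- function(table, file) {
  stopifnot(inherits(table, "aligned_site_table"))
  meta <- jsonlite::toJSON(list(
    populations = attr(table, "populations"),
    taxa = attr(table, "taxa"),
    drop_counts = as.list(attr(table, "drop_counts"))
  ), auto_unbox = TRUE)
  writeLines(paste0("#archstats ", as.character(meta)), file)
  data.table::fwrite(table, file, sep = "\t", quote = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(file)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(file) {
  hdr <- readLines(file, n = 1L)
  if (!startsWith(hdr, "#archstats ")) {
    stop("not an archstats site table: missing '#archstats' header in ", file)
  }
  meta <- jsonlite::fromJSON(sub("^#archstats ", "", hdr))
  x <- data.table::fread(file, sep = "\t", skip = 1L, header = TRUE,
                         colClasses = list(character = "chrom"))
  as_site_table(x, populations = meta$populations, taxa = meta$taxa,
                drop_counts = unlist(meta$drop_counts))
}

## resolve a taxon/population/sample reference to a B-allele frequency vector
## pops -> freq_<pop>; taxa -> state column as 0/1; gt columns -> dosage/2
resolve_freq <- function(table, who) {
  pops <- attr(table, "populations")
  taxa <- attr(table, "taxa")
  if (who %in% pops) return(table[[paste0("freq_", who)]])
  if (who %in% taxa) {
    if (identical(who, "chimp")) return(rep(0, nrow(table)))
    st <- table[[paste0("state_", who)]]
    return(ifelse(is.na(st), NA_real_, as.numeric(st == "B")))
  }
  gcol <- paste0("gt_", who)
  if (gcol %in% names(table)) return(table[[gcol]] / 2)
  if (who %in% names(table)) return(table[[who]])
  stop("unknown taxon/population/sample: '", who, "'")
}
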