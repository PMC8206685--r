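# tiny in-code VCF / panel fixtures for the genotype IO tests

write_human_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    # ref=chimp allele at most sites; site 300 has chimp==alt; site 400
    # triallelic; site 500 an indel; site 600 has a missing genotype
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0\t1/1",
    "1\t300\t.\tG\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0\t0/0",
    "1\t400\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2\t0/0",
    "1\t500\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0\t0/0",
    "1\t600\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0/1\t1/1\t0/0",
    "2\t150\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1\t0/0")
  writeLines(lines, path)
  path
}

write_panel_fixture <- function(path) {
  writeLines(c("sample\tpopulation\tregion",
               "S1\tPOPA\tAfrica", "S2\tPOPA\tAfrica",
               "S3\tPOPB\tEurope", "S4\tPOPB\tEurope"), path)
  path
}

write_coords_fixture <- function(path) {
  writeLines(c("population\tlat\tlon",
               "POPA\t9.02\t38.75", "POPB\t51.5\t-0.1"), path)
  path
}

write_outgroup_fixture <- function(path) {
  writeLines(c("chrom\tpos\tbase",
               "chr1\t100\tA", "chr1\t200\tC", "chr1\t300\tT",
               "chr1\t400\tA", "chr1\t600\tT", "chr2\t150\tG"), path)
  path
}

# archaic calls already filtered: chrom, pos, base
archaic_fixture <- function(taxon = "NEA") {
  if (taxon == "NEA") {
    data.frame(chrom = c("1", "1", "1", "1", "2"),
               pos = c(100L, 200L, 300L, 600L, 150L),
               base = c("G", "C", "T", "T", "G"))
  } else {
    data.frame(chrom = c("1", "1", "1", "1", "2"),
               pos = c(100L, 200L, 300L, 600L, 150L),
               base = c("A", "C", "G", "C", "A"))
  }
}
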