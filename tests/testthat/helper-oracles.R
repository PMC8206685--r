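# Brute-force reference implementations: explicit per-site loops written
# directly from the statistic definitions, independent of the vectorized
# package code they check.

oracle_d <- function(tab, p1, p2, archaic = "NEA") {
  abba <- baba <- 0
  for (i in seq_len(nrow(tab))) {
    st <- tab[[paste0("state_", archaic)]][i]
    g1 <- tab[[paste0("gt_", p1)]][i]
    g2 <- tab[[paste0("gt_", p2)]][i]
    if (is.na(st) || st != "B" || is.na(g1) || is.na(g2)) next
    w1 <- g1 / 2
    w2 <- g2 / 2
    abba <- abba + (1 - w1) * w2
    baba <- baba + w1 * (1 - w2)
  }
  if (abba + baba == 0) NA_real_ else (abba - baba) / (abba + baba)
}

oracle_nd <- function(tab, pop, arch = "NEA", conditioned = FALSE,
                      mclass = "both", panel = NULL) {
  num <- 0
  N <- 0L
  other <- if (arch == "NEA") "DEN" else "NEA"
  for (i in seq_len(nrow(tab))) {
    cls_ok <- mclass == "both" ||
      (mclass == "transitions" && tab$mutation_class[i] == "transition") ||
      (mclass == "transversions" && tab$mutation_class[i] == "transversion")
    if (!cls_ok) next
    if (isTRUE(tab$hpoly[i])) N <- N + 1L
    sa <- tab[[paste0("state_", arch)]][i]
    so <- tab[[paste0("state_", other)]][i]
    if (is.na(sa) || is.na(so) || sa != "B" || so != "A") next
    if (conditioned) {
      any_called <- FALSE
      absent <- TRUE
      for (p in panel) {
        np <- tab[[paste0("n_", p)]][i]
        if (!is.na(np) && np > 0) {
          any_called <- TRUE
          if (tab[[paste0("freq_", p)]][i] > 0) absent <- FALSE
        }
      }
      if (!any_called || !absent) next
    }
    fv <- tab[[paste0("freq_", pop)]][i]
    if (!is.na(fv)) num <- num + fv
  }
  list(nd = if (N > 0) num / N else 0, numerator = num, N = N)
}

oracle_f4 <- function(tab, w1, w2, w3, w4) {
  f <- function(w, i) {
    if (paste0("freq_", w) %in% names(tab)) return(tab[[paste0("freq_", w)]][i])
    if (w == "chimp") return(0)
    st <- tab[[paste0("state_", w)]][i]
    if (is.na(st)) NA_real_ else as.numeric(st == "B")
  }
  tot <- 0
  n <- 0L
  for (i in seq_len(nrow(tab))) {
    v <- c(f(w1, i), f(w2, i), f(w3, i), f(w4, i))
    if (any(is.na(v))) next
    tot <- tot + (v[1] - v[2]) * (v[3] - v[4])
    n <- n + 1L
  }
  if (n == 0L) NA_real_ else tot / n
}

oracle_afd <- function(tab, a, b) {
  s <- 0
  n <- 0L
  for (i in seq_len(nrow(tab))) {
    fa <- tab[[paste0("freq_", a)]][i]
    fb <- tab[[paste0("freq_", b)]][i]
    na_ <- tab[[paste0("n_", a)]][i]
    nb_ <- tab[[paste0("n_", b)]][i]
    if (is.na(fa) || is.na(fb) || na_ == 0 || nb_ == 0) next
    s <- s + abs(fa - fb)
    n <- n + 1L
  }
  if (n == 0L) NA_real_ else s / n
}

oracle_fst <- function(tab, a, b) {
  num <- den <- 0
  for (i in seq_len(nrow(tab))) {
    pa <- tab[[paste0("freq_", a)]][i]
    pb <- tab[[paste0("freq_", b)]][i]
    na_ <- tab[[paste0("n_", a)]][i]
    nb_ <- tab[[paste0("n_", b)]][i]
    if (is.na(pa) || is.na(pb) || na_ < 2 || nb_ < 2) next
    num <- num + (pa - pb)^2 - pa * (1 - pa) / (na_ - 1) -
      pb * (1 - pb) / (nb_ - 1)
    den <- den + pa * (1 - pb) + pb * (1 - pa)
  }
  if (den <= 0) NA_real_ else num / den
}

oracle_h <- function(tab, pop) {
  s <- 0
  n <- 0L
  for (i in seq_len(nrow(tab))) {
    f <- tab[[paste0("freq_", pop)]][i]
    np <- tab[[paste0("n_", pop)]][i]
    if (is.na(f) || np == 0) next
    s <- s + 2 * f * (1 - f)
    n <- n + 1L
  }
  if (n == 0L) NA_real_ else s / n
}

# random small site table for property tests (two human pops + archaics)
random_table <- function(n_sites = 50, pops = c("P1", "P2", "P3"),
                         seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  aA <- sample(bases, n_sites, replace = TRUE)
  aB <- vapply(aA, function(b) sample(setdiff(bases, b), 1L), "")
  x <- data.table::data.table(
    chrom = sample(c("chr1", "chr2", "chr3"), n_sites, replace = TRUE),
    pos = seq_len(n_sites) * 10L,
    allele_A = aA, allele_B = aB,
    mutation_class = archstats::classify_mutation(aA, aB),
    state_NEA = sample(c("A", "B", NA), n_sites, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)),
    state_DEN = sample(c("A", "B", NA), n_sites, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)))
  data.table::setorder(x, chrom, pos)
  for (p in pops) {
    nn <- sample(c(0L, 8L, 10L), n_sites, replace = TRUE,
                 prob = c(0.05, 0.2, 0.75))
    x[, paste0("n_", p) := nn]
    x[, paste0("freq_", p) := ifelse(nn > 0, round(stats::runif(n_sites) *
                                                     nn) / nn, NA_real_)]
    x[, paste0("gt_", p) := sample(0:2, n_sites, replace = TRUE)]
  }
  archstats::as_site_table(x, populations = pops,
                           taxa = c("chimp", "NEA", "DEN"))
}
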