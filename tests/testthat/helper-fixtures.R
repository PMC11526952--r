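# Shared fixture builders. Everything is generated in code at test time.

# A small structured landscape + parameters used across tests.
small_system <- function(rows = 3, cols = 3, mu = 1e-7, N = 50, m = 0.05) {
  list(landscape = build_lattice(rows, cols),
       params = gd_params(mu = mu, deme_size = N, mig = m))
}

# Closed-form two-deme equilibrium (structured coalescent):
# E[T] within = 4N, between = 4N + 1/(2m); pi = 2 mu E[T].
two_deme_closed_form <- function(N, mu, m) {
  list(pi_w = 8 * N * mu, pi_b = 8 * N * mu + mu / m)
}

# Write a tiny plain-text VCF with given dosage matrix (individuals x loci).
write_test_vcf <- function(dosages, path, chrom = "1") {
  n <- nrow(dosages); L <- ncol(dosages)
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- sprintf("ind%02d", seq_len(n))
  gt <- apply(dosages, c(1, 2), function(d) {
    if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1]
  })
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(L), function(l) {
    paste(c(chrom, l * 100, sprintf("snp%d", l), "A", "T", ".", "PASS",
            ".", "GT", gt[, l]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A deterministic synthetic panel with north-south allele-frequency
# structure, for extinction-curve tests.
make_test_panel <- function(n_per_group = 6, loci = 40, seed = 42) {
  set.seed(seed)
  groups <- data.frame(
    gx = rep(c(0, 5, 10), each = n_per_group),
    gy = rep(c(0, 5, 10), times = n_per_group)
  )
  n <- nrow(groups)
  p_north <- runif(loci, 0.05, 0.5)
  p_south <- pmin(p_north + runif(loci, 0, 0.4), 0.95)
  G <- matrix(NA_integer_, n, loci)
  for (i in seq_len(n)) {
    w <- groups$gy[i] / 10
    p <- w * p_north + (1 - w) * p_south
    G[i, ] <- rbinom(loci, 2, p)
  }
  rownames(G) <- sprintf("ind%02d", seq_len(n))
  coords <- data.frame(id = rownames(G),
                       x = groups$gx + runif(n, 0, 1),
                       y = groups$gy + runif(n, 0, 1))
  gd_panel(G, coords)
}
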