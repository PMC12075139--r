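# Fixture builders and independent oracles shared across test files.

# simple random panel via the package simulator
make_panel <- function(n_animals = 50, n_snps = 200, n_chromosomes = 2,
                       n_families = 5, seed = 1, ...) {
  simulate_genotypes(n_animals, n_snps, n_chromosomes = n_chromosomes,
                     n_families = n_families, seed = seed, ...)
}

# a blended GRM from a fresh simulated panel
make_blended_grm <- function(n_animals = 50, n_snps = 300, seed = 1,
                             beta = 0.05) {
  pan <- make_panel(n_animals, n_snps, n_chromosomes = 2,
                    n_families = max(2, n_animals %/% 10), seed = seed)
  zc <- center_genotypes(pan, allele_frequencies(pan))
  list(panel = pan, zc = zc, grm = blend_grm(build_grm(zc), beta = beta))
}

# reproducible normal draws without touching the suite's RNG stream
with_seed_rnorm <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::rnorm(n)
}

# builds a genotype column from genotype counts (n2 = #code2, n1, n0, nNA)
geno_col <- function(n2, n1, n0, nNA = 0) {
  c(rep(2L, n2), rep(1L, n1), rep(0L, n0), rep(NA_integer_, nNA))
}

# 100-animal, 10-SNP panel with one SNP per QC failure mode
make_adversarial_qc_panel <- function() {
  cols <- list(
    clean_hwe_half = geno_col(25, 50, 25),        # kept
    non_autosome   = geno_col(25, 50, 25),        # autosome
    low_call       = geno_col(20, 40, 25, 15),    # call_rate
    rare           = geno_col(0, 4, 96),          # MAF 0.02 -> maf
    hwe_excess     = geno_col(50, 30, 20),        # |0.30-0.455| = 0.155 -> hwe
    clean_p3       = geno_col(9, 42, 49),         # kept
    all_het        = geno_col(0, 100, 0),         # hwe (dev 0.5)
    monomorphic    = geno_col(0, 0, 100),         # maf
    nonauto_rare   = geno_col(0, 2, 98),          # autosome wins over maf
    lowcall_hwe    = geno_col(25, 60, 0, 15)      # call_rate wins over hwe
  )
  codes <- do.call(cbind, cols)
  chrom <- c(1, 30, 1, 1, 2, 2, 2, 3, 31, 3)
  map <- data.frame(snp_id = names(cols), chromosome = chrom,
                    position_bp = as.integer(
                      stats::ave(seq_along(chrom), chrom, FUN = seq_along)) * 1000L)
  genotype_panel(codes, sprintf("a%03d", 1:100), map)
}

# independent rule-by-rule QC oracle: straight loops, no shared code paths
brute_force_qc <- function(panel, thr) {
  m <- ncol(panel$codes)
  fate <- character(m)
  for (j in seq_len(m)) {
    g <- panel$codes[, j]
    called <- g[!is.na(g)]
    cr <- length(called) / length(g)
    p <- if (length(called) > 0) sum(called) / (2 * length(called)) else NA
    maf <- min(p, 1 - p)
    het <- if (length(called) > 0) mean(called == 1) else NA
    dev <- abs(het - 2 * p * (1 - p))
    fate[j] <-
      if (!(panel$snp_map$chromosome[j] %in% thr$autosomes)) "autosome"
      else if (length(called) == 0 || cr < thr$call_rate_min) "call_rate"
      else if (maf < thr$maf_min) "maf"
      else if (dev > thr$hwe_dev_max) "hwe"
      else "kept"
  }
  fate
}

# dense-inverse back-solve oracle (never touches the APY code path)
dense_backsolve <- function(zc, Gb, u, sigma_a2, beta = 0.05, b = 1,
                            sigma_u2 = NULL) {
  if (is.null(sigma_u2)) sigma_u2 <- sigma_a2 / zc$scale_k
  (1 - beta) * b * (sigma_u2 / sigma_a2) *
    as.numeric(t(zc$Z) %*% solve(Gb, u))
}

# writes a PLINK --recode A style file for a panel (NA for missing)
write_plink_raw <- function(panel, path) {
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(panel$snp_map$snp_id, "_A"))
  rows <- vapply(seq_along(panel$animal_ids), function(i) {
    paste(c("fam1", panel$animal_ids[i], "0", "0", "0", "-9",
            panel$codes[i, ]), collapse = " ")
  }, character(1))
  writeLines(c(paste(hdr, collapse = " "), rows), path)
}
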