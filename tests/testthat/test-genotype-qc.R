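test_that("genotype panels round-trip through matrix TSV and reject mismatches", {
  pan <- make_panel(8, 12, n_chromosomes = 2, n_families = 2, seed = 3,
                    miss_rate = 0.05)
  gpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  write_genotypes(pan, gpath, mpath)
  back <- read_genotypes(gpath, mpath, "matrix-tsv")
  expect_identical(back$codes, pan$codes)
  expect_identical(back$snp_map, pan$snp_map)
  expect_identical(back$animal_ids, pan$animal_ids)

  # map rows != genotype columns
  bad_map <- rbind(pan$snp_map,
                   data.frame(snp_id = "extra", chromosome = 9L,
                              position_bp = 1L))
  bpath <- tempfile(fileext = ".tsv")
  utils::write.table(bad_map, bpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_genotypes(gpath, bpath, "matrix-tsv"),
               class = "apygwas_format_error")
})

test_that("plink-raw and matrix-tsv dialects parse to the same panel", {
  codes <- matrix(c(0L, 1L, 2L, 1L,
                    2L, 0L, 1L, 0L,
                    1L, 1L, NA, 2L,
                    0L, 2L, 0L, 1L,
                    2L, 2L, 1L, 0L), nrow = 4)
  map <- data.frame(snp_id = paste0("s", 1:5),
                    chromosome = c(1L, 1L, 1L, 2L, 2L),
                    position_bp = c(100L, 200L, 300L, 100L, 200L))
  pan <- genotype_panel(codes, paste0("A", 1:4), map)

  gpath <- tempfile(fileext = ".tsv"); mpath <- tempfile(fileext = ".tsv")
  write_genotypes(pan, gpath, mpath)
  rpath <- tempfile(fileext = ".raw")
  write_plink_raw(pan, rpath)

  from_tsv <- read_genotypes(gpath, mpath, "matrix-tsv")
  from_raw <- read_genotypes(rpath, mpath, "plink-raw")
  expect_identical(from_raw$codes, from_tsv$codes)
  expect_identical(from_raw$snp_map, from_tsv$snp_map)
})

test_that("reader sorts the map and rejects duplicate positions and bad codes", {
  codes <- matrix(c(0L, 1L, 2L, 0L, 1L, 2L), nrow = 2)
  map <- data.frame(snp_id = c("b", "a", "c"),
                    chromosome = c(1L, 1L, 1L),
                    position_bp = c(200L, 100L, 300L))
  gpath <- tempfile(fileext = ".tsv"); mpath <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(animal_id = c("x", "y"),
                                b = codes[, 1], a = codes[, 2], c = codes[, 3]),
                     gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  pan <- read_genotypes(gpath, mpath, "matrix-tsv")
  expect_identical(pan$snp_map$snp_id, c("a", "b", "c"))
  expect_identical(unname(pan$codes[, "a"]), codes[, 2])

  map$position_bp <- c(100L, 100L, 300L)   # duplicate after sort
  utils::write.table(map, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotypes(gpath, mpath, "matrix-tsv"),
               class = "apygwas_format_error")

  expect_error(genotype_panel(matrix(c(0L, 3L), 1),
                              "x",
                              data.frame(snp_id = c("a", "b"),
                                         chromosome = 1L,
                                         position_bp = c(1L, 2L))),
               class = "apygwas_format_error")
})

test_that("allele frequencies count allele copies among non-missing calls", {
  map <- data.frame(snp_id = paste0("s", 1:3), chromosome = 1L,
                    position_bp = c(10L, 20L, 30L))
  codes <- cbind(c(2L, 2L, 2L, 2L, 2L),
                 c(0L, 1L, 2L, 0L, 2L),
                 c(0L, 0L, 1L, 2L, NA))
  pan <- genotype_panel(codes, paste0("a", 1:5), map)
  p <- allele_frequencies(pan)
  expect_equal(unname(p[1]), 1)                 # fixed
  expect_equal(unname(p[2]), 0.5)               # {0,1,2,0,2} -> 5/10
  expect_equal(unname(p[3]), 3 / 8)             # hand count over 4 calls

  all_na <- genotype_panel(cbind(c(1L, 1L), c(NA_integer_, NA_integer_)),
                           c("a", "b"),
                           data.frame(snp_id = c("ok", "void"),
                                      chromosome = 1L,
                                      position_bp = c(1L, 2L)))
  expect_error(allele_frequencies(all_na), "void",
               class = "apygwas_numerical_error")
})

test_that("the hand-computed HWE deviation example is removed by the HWE filter", {
  # 50 AA + 30 AB + 20 BB: p = 0.65, MAF = 0.35 (passes), het_obs = 0.30,
  # het_exp = 0.455, |dev| = 0.155 > 0.15
  codes <- cbind(geno_col(50, 30, 20), geno_col(25, 50, 25))
  pan <- genotype_panel(codes, sprintf("a%03d", 1:100),
                        data.frame(snp_id = c("dev", "ok"), chromosome = 1L,
                                   position_bp = c(1L, 2L)))
  res <- qc_filter(pan, qc_thresholds())
  expect_identical(res$report$fate$fate, c("hwe", "kept"))
  expect_identical(unname(res$report$removed_by_filter["hwe"]), 1L)
})

test_that("qc_filter agrees with an independent rule-by-rule oracle", {
  pan <- make_adversarial_qc_panel()
  thr <- qc_thresholds()
  res <- qc_filter(pan, thr)
  oracle <- brute_force_qc(pan, thr)
  expect_identical(res$report$fate$fate, oracle)
  expect_identical(unname(res$report$removed_by_filter),
                   unname(vapply(c("autosome", "call_rate", "maf", "hwe"),
                                 function(f) sum(oracle == f), integer(1))))
  expect_identical(res$report$removed_by_filter,
                   c(autosome = 2L, call_rate = 2L, maf = 2L, hwe = 2L))
  expect_identical(res$report$n_retained_snps, 2L)

  # also on a large random panel with missingness
  pan2 <- make_panel(150, 400, n_chromosomes = 3, n_families = 10,
                     seed = 17, miss_rate = 0.08)
  res2 <- qc_filter(pan2, thr)
  expect_identical(res2$report$fate$fate, brute_force_qc(pan2, thr))
})

test_that("pass-through panel loses nothing and QC is idempotent and conservative", {
  # MAF 0.5, exact HWE, full call rate, autosomal
  codes <- do.call(cbind, replicate(6, geno_col(25, 50, 25), simplify = FALSE))
  pan <- genotype_panel(codes, sprintf("a%03d", 1:100),
                        data.frame(snp_id = paste0("s", 1:6), chromosome = 1L,
                                   position_bp = (1:6) * 10L))
  res <- qc_filter(pan, qc_thresholds())
  expect_identical(res$report$n_retained_snps, 6L)
  expect_identical(sum(res$report$removed_by_filter), 0L)

  # idempotence on a filtered random panel
  pan2 <- make_panel(120, 300, n_chromosomes = 3, n_families = 8, seed = 23,
                     miss_rate = 0.05)
  first <- qc_filter(pan2, qc_thresholds())
  second <- qc_filter(first$panel, qc_thresholds())
  expect_identical(second$report$n_retained_snps, first$report$n_retained_snps)
  expect_identical(sum(second$report$removed_by_filter), 0L)

  # conservation: fate table partitions the inputs
  expect_identical(first$report$n_input_snps,
                   first$report$n_retained_snps +
                     sum(first$report$removed_by_filter))
  expect_identical(first$report$fate$snp_id, pan2$snp_map$snp_id)
})

test_that("tighter thresholds never retain more SNPs", {
  pan <- make_panel(150, 300, n_chromosomes = 3, n_families = 8, seed = 31,
                    miss_rate = 0.07)
  # strict settings may empty the panel, which warns by design
  kept <- function(thr) suppressWarnings(qc_filter(pan, thr))$report$n_retained_snps
  k_maf <- vapply(c(0.01, 0.05, 0.1, 0.2),
                  function(m) kept(qc_thresholds(maf_min = m)), integer(1))
  expect_true(all(diff(k_maf) <= 0))
  k_cr <- vapply(c(0.5, 0.9, 0.95, 0.99),
                 function(cr) kept(qc_thresholds(call_rate_min = cr)),
                 integer(1))
  expect_true(all(diff(k_cr) <= 0))
  k_hwe <- vapply(c(0.3, 0.15, 0.05, 0.01),
                  function(h) kept(qc_thresholds(hwe_dev_max = h)),
                  integer(1))
  expect_true(all(diff(k_hwe) <= 0))
})
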