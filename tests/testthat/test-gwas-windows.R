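test_that("per-SNP variances follow sigma_ai2 = a_i^2 * 2 p_i (1 - p_i)", {
  expect_equal(snp_variances(0, 0.3), 0)
  expect_equal(snp_variances(1, 0.5), 0.5)
  expect_equal(snp_variances(c(1, 2), c(0.1, 0.3)), c(0.18, 1.68))
  expect_error(snp_variances(c(1, 2), 0.5), class = "apygwas_argument_error")
})

test_that("back-solving is linear, respects the identity-G limit, and matches the dense oracle", {
  fx <- make_blended_grm(50, 200, seed = 81)
  apy <- build_apy_inverse(fx$grm, 1:50)
  params <- backsolve_params(sigma_a2 = 1)

  # u_hat = 0 -> a_hat = 0
  eff0 <- backsolve_snp_effects(fx$zc, apy, rep(0, 50), params)
  expect_true(all(eff0$effects == 0))
  expect_true(all(eff0$per_snp_variance == 0))

  # identity-G toy: beta = 0, b = 1, sigma_u2 = sigma_a2 -> a_hat = Z'u
  zi <- structure(list(Z = diag(4), p = rep(0.5, 4), scale_k = 1,
                       animal_ids = letters[1:4], snp_ids = paste0("s", 1:4)),
                  class = "centered_genotypes")
  gi <- structure(list(G = diag(4), beta = 0, blend_target = "identity",
                       is_blended = TRUE, animal_ids = letters[1:4]),
                  class = "grm")
  u <- c(1, -2, 0.5, 3)
  eff_i <- backsolve_snp_effects(zi, build_apy_inverse(gi, 1:4), u,
                                 backsolve_params(1, beta = 0, b = 1,
                                                  sigma_u2 = 1))
  expect_equal(eff_i$effects, as.numeric(t(diag(4)) %*% u), tolerance = 1e-12)

  # dense-inverse oracle with a full-rank core
  u2 <- with_seed_rnorm(50, 82)
  eff <- backsolve_snp_effects(fx$zc, apy, u2, params)
  oracle <- dense_backsolve(fx$zc, fx$grm$G, u2, sigma_a2 = 1)
  expect_lt(max(abs(eff$effects - oracle)), 1e-8)

  # scale equivariance: c * u -> c * a_hat, c^2 * variances
  eff3 <- backsolve_snp_effects(fx$zc, apy, 3 * u2, params)
  expect_equal(eff3$effects, 3 * eff$effects, tolerance = 1e-10)
  expect_equal(eff3$per_snp_variance, 9 * eff$per_snp_variance,
               tolerance = 1e-10)

  expect_error(backsolve_snp_effects(fx$zc, apy, u2[-1], params),
               class = "apygwas_argument_error")
})

test_that("window scan enumerates within-chromosome windows correctly", {
  map5 <- data.frame(snp_id = paste0("s", 1:5), chromosome = 1L,
                     position_bp = (1:5) * 100L)
  wt <- window_scan(rep(1, 5), map5, 3, denominator = "snp_sum")
  expect_identical(nrow(wt), 3L)
  expect_equal(wt$variance, rep(3, 3))
  expect_equal(wt$start_bp, c(100L, 200L, 300L))
  expect_equal(wt$end_bp, c(300L, 400L, 500L))
  # constant field: ties broken by (chromosome, start_bp)
  expect_identical(wt$rank, 1:3)

  # chromosomes shorter than the window yield nothing
  map22 <- data.frame(snp_id = paste0("s", 1:4), chromosome = c(1L, 1L, 2L, 2L),
                      position_bp = c(1L, 2L, 1L, 2L))
  expect_warning(wt0 <- window_scan(rep(1, 4), map22, 3,
                                    denominator = "snp_sum"))
  expect_identical(nrow(wt0), 0L)

  # brute-force enumeration example
  map4 <- data.frame(snp_id = paste0("s", 1:4), chromosome = 1L,
                     position_bp = (1:4) * 10L)
  wt2 <- window_scan(c(1, 2, 3, 4), map4, 2, denominator = "snp_sum")
  expect_equal(wt2$variance, c(3, 5, 7))
  expect_equal(wt2$pct_of_additive, c(30, 50, 70))
  expect_identical(wt2$rank, c(3L, 2L, 1L))

  # sigma_a2 denominator
  wt3 <- window_scan(c(1, 2, 3, 4), map4, 2, denominator = "sigma_a2",
                     sigma_a2 = 20)
  expect_equal(wt3$pct_of_additive, c(15, 25, 35))
})

test_that("disjoint tiling conserves the total per-SNP variance", {
  for (s in 1:10) {
    v <- abs(with_seed_rnorm(60, 900 + s))
    map <- data.frame(snp_id = paste0("s", 1:60),
                      chromosome = rep(1:3, each = 20),
                      position_bp = rep(100L * (1:20), 3))
    wt <- window_scan(v, map, 5, step = 5, denominator = "snp_sum")
    expect_identical(nrow(wt), 12L)
    expect_equal(sum(wt$variance), sum(v), tolerance = 1e-14)
    expect_equal(sum(wt$pct_of_additive), 100, tolerance = 1e-10)
  }
})

test_that("window percentages are invariant to SNP reordering within a window", {
  map <- data.frame(snp_id = paste0("s", 1:6), chromosome = 1L,
                    position_bp = (1:6) * 10L)
  v <- c(5, 1, 2, 7, 3, 4)
  wt <- window_scan(v, map, 3, step = 3, denominator = "snp_sum")
  v_perm <- c(2, 5, 1, 3, 4, 7)   # permuted inside each tile
  wt_perm <- window_scan(v_perm, map, 3, step = 3, denominator = "snp_sum")
  expect_equal(wt$pct_of_additive, wt_perm$pct_of_additive)
})

test_that("top-window selection honors fraction, count and the greedy policy", {
  map <- data.frame(snp_id = paste0("s", 1:2011), chromosome = 1L,
                    position_bp = (1:2011) * 100L)
  v <- abs(with_seed_rnorm(2011, 7))
  wt <- window_scan(v, map, 12, denominator = "snp_sum")
  expect_identical(nrow(wt), 2000L)

  # fraction 1.0 keep-all returns everything
  expect_identical(nrow(select_top_windows(wt, "fraction", 1, "keep-all")),
                   2000L)
  # top 1% of 2000 windows = 20 windows
  expect_identical(nrow(select_top_windows(wt, "fraction", 0.01, "keep-all")),
                   20L)

  kept <- select_top_windows(wt, "count", 15, "greedy-nonoverlap")
  expect_identical(nrow(kept), 15L)
  # mutually disjoint SNP ranges
  lo <- kept$first_snp_index; hi <- lo + kept$n_snps - 1L
  for (i in 1:14) for (j in (i + 1):15) {
    expect_true(hi[i] < lo[j] || hi[j] < lo[i])
  }
})

test_that("greedy non-overlap matches the exhaustive disjoint-triple oracle", {
  map <- data.frame(snp_id = paste0("s", 1:12), chromosome = 1L,
                    position_bp = (1:12) * 50L)
  v <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0.5, 0.25)  # strictly decreasing
  wt <- window_scan(v, map, 3, denominator = "snp_sum")  # 10 windows
  expect_identical(wt$rank, 1:10)

  kept <- select_top_windows(wt, "count", 3, "greedy-nonoverlap")

  # oracle: among all disjoint triples, the one minimizing summed rank
  trips <- utils::combn(10, 3)
  disjoint <- apply(trips, 2, function(t3) {
    lo <- wt$first_snp_index[t3]; hi <- lo + 2L
    all(hi[1] < lo[2], hi[2] < lo[3])
  })
  sums <- colSums(matrix(wt$rank[trips], 3))[disjoint]
  best <- trips[, disjoint, drop = FALSE][, which.min(sums)]
  expect_setequal(kept$window_id, wt$window_id[best])
})

test_that("Ne-based window sizing reproduces the analytic segment arithmetic", {
  spec <- window_size_from_ne(196)
  expect_equal(spec$rounded$segment_length_morgans, 0.00128)
  expect_equal(spec$rounded$span_morgans, 0.0102)
  expect_equal(spec$rounded$span_mb, 1.02)
  expect_equal(spec$segment_length_morgans, 1 / 784, tolerance = 1e-15)

  spec2 <- window_size_from_ne(250, n_segments = 8)
  expect_equal(spec2$segment_length_morgans, 0.001)
  expect_equal(spec2$span_morgans, 0.008)

  spec3 <- window_size_from_ne(196, snps_per_mb = 171.5)
  expect_identical(spec3$window_snps, as.integer(round(spec3$span_mb * 171.5)))
})

test_that("top windows recover simulated QTL better than uniform placement", {
  hits <- logical(5)
  for (s in 1:5) {
    pan <- simulate_genotypes(400, 2000, n_chromosomes = 4,
                              n_families = 40, seed = 1000 + s)
    tr <- simulate_truth(pan, 20, sigma_a2 = 1, h2 = 0.5, seed = 2000 + s)
    y <- simulate_phenotypes(tr, seed = 3000 + s)
    zc <- center_genotypes(pan)
    gb <- blend_grm(build_grm(zc), 0.05)
    u <- as.numeric(solve_gblup(gb, y, 1, tr$sigma_e2)$gebv[, 1])
    apy <- build_apy_inverse(gb, seq_len(400))
    eff <- backsolve_snp_effects(zc, apy, u, backsolve_params(1))
    wt <- window_scan(eff$per_snp_variance, pan$snp_map, 25, sigma_a2 = 1)
    top <- select_top_windows(wt, "count", 20, "greedy-nonoverlap")

    contains_qtl <- function(tab) {
      vapply(seq_len(nrow(tab)), function(i) {
        any(tr$qtl_indices >= tab$first_snp_index[i] &
              tr$qtl_indices <= tab$first_snp_index[i] + tab$n_snps[i] - 1L)
      }, logical(1))
    }
    frac_top <- mean(contains_qtl(top))
    frac_all <- mean(contains_qtl(wt))   # uniform-placement expectation
    hits[s] <- frac_top > frac_all
  }
  expect_gte(sum(hits), 4)
})
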