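#' Simulate a multi-chromosome genotype panel with family structure
#'
#' Founder genotypes are drawn binomially from per-locus base allele
#' frequencies (uniform on `[maf_low, maf_high]`); the remaining animals are
#' produced by gene dropping: at every locus one allele is transmitted from
#' each of two parents. Families follow a two-generation half/full-sib
#' design: each family has a sire and a dam as its first two members and
#' full-sib offspring after them, and consecutive pairs of families share a
#' sire, creating half-sib ties across families. This guarantees non-trivial
#' off-diagonal structure in the genomic relationship matrix, which APY core
#' selection relies on.
#'
#' SNPs are split as evenly as possible across chromosomes and placed on a
#' uniform physical grid (chromosome length `chrom_length_bp`, default 100 Mb).
#'
#' @param n_animals,n_snps,n_chromosomes Panel dimensions.
#' @param maf_low,maf_high Base allele-frequency bounds, `0 < maf_low <=
#'   maf_high <= 0.5`.
#' @param n_families Number of families (>= 1).
#' @param seed Integer seed; the simulator is a pure function of it.
#' @param miss_rate Fraction of calls set to missing (default 0), to exercise
#'   the call-rate filter.
#' @param chrom_length_bp Physical length of each chromosome in bp.
#' @return A [genotype_panel()]. Attributes `pedigree` (data.frame with
#'   columns `animal`, `sire`, `dam`; `NA` for founders) and `base_freq`
#'   record the simulation ground truth.
#' @export
simulate_genotypes <- function(n_animals, n_snps, n_chromosomes = 1L,
                               maf_low = 0.1, maf_high = 0.5,
                               n_families = 1L, seed = 1L,
                               miss_rate = 0, chrom_length_bp = 1e8) {
  assert_that(n_animals >= 1 && n_snps >= 1 && n_chromosomes >= 1,
              "n_animals, n_snps and n_chromosomes must be positive")
  assert_that(n_chromosomes <= n_snps,
              "need at least one SNP per chromosome")
  assert_that(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5,
              "require 0 < maf_low <= maf_high <= 0.5")
  assert_that(n_families >= 1 && n_families <= n_animals,
              "n_families must be in [1, n_animals]")
  assert_that(miss_rate >= 0 && miss_rate < 1, "miss_rate must be in [0, 1)")

  with_rng(seed, {
    p <- stats::runif(n_snps, maf_low, maf_high)

    # contiguous family blocks of near-equal size
    fam <- sort(rep_len(seq_len(n_families), n_animals))
    codes <- matrix(NA_integer_, n_animals, n_snps)
    sire <- rep(NA_integer_, n_animals)
    dam <- rep(NA_integer_, n_animals)

    transmit <- function(parent_codes) {
      # one allele per locus, sampled from the parent's two
      stats::rbinom(n_snps, 1L, parent_codes / 2)
    }

    fam_first <- match(seq_len(n_families), fam)
    for (f in seq_len(n_families)) {
      members <- which(fam == f)
      founders <- members[seq_len(min(2L, length(members)))]
      for (i in founders) {
        codes[i, ] <- stats::rbinom(n_snps, 2L, p)
      }
      if (length(members) > 2L) {
        # sire shared between consecutive family pairs -> half sibs
        sire_fam <- if (f %% 2L == 0L && length(which(fam == f - 1L)) >= 1L)
          f - 1L else f
        s <- fam_first[sire_fam]
        d <- members[2L]
        for (i in members[-(1:2)]) {
          codes[i, ] <- transmit(codes[s, ]) + transmit(codes[d, ])
          sire[i] <- s
          dam[i] <- d
        }
      }
    }

    if (miss_rate > 0) {
      drop <- which(stats::runif(length(codes)) < miss_rate)
      codes[drop] <- NA_integer_
    }

    per_chrom <- rep(n_snps %/% n_chromosomes, n_chromosomes)
    extra <- n_snps %% n_chromosomes
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    map <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch) {
      k <- per_chrom[ch]
      spacing <- max(1L, as.integer(chrom_length_bp %/% (k + 1L)))
      data.frame(chromosome = ch, position_bp = spacing * seq_len(k))
    }))
    map$snp_id <- sprintf("snp%d_%d", map$chromosome,
                          stats::ave(map$position_bp, map$chromosome,
                                     FUN = seq_along))
    map <- map[, c("snp_id", "chromosome", "position_bp")]

    panel <- genotype_panel(codes, sprintf("ani%04d", seq_len(n_animals)), map)
    attr(panel, "pedigree") <- data.frame(animal = seq_len(n_animals),
                                          sire = sire, dam = dam)
    attr(panel, "base_freq") <- p
    panel
  })
}

#' Simulate sparse QTL effects and true breeding values
#'
#' Samples `n_qtl` loci without replacement, draws standard-normal raw
#' effects there (zero elsewhere), and rescales them so that the empirical
#' variance of `Z %*% effects` equals `sigma_a2` exactly, where `Z` is the
#' panel's allele-frequency-centered genotype matrix. The residual variance
#' follows from the requested heritability:
#' `sigma_e2 = sigma_a2 * (1 - h2) / h2`.
#'
#' @param panel A [genotype_panel()].
#' @param n_qtl Number of causal loci, `1 <= n_qtl <= n_snps`.
#' @param sigma_a2 Target additive genetic variance (> 0).
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param seed Integer seed.
#' @return A list of class `truth_set` with fields `true_effects`,
#'   `qtl_indices`, `true_bv`, `sigma_a2`, `sigma_e2`, `h2`.
#' @export
simulate_truth <- function(panel, n_qtl, sigma_a2 = 1, h2 = 0.5, seed = 1L) {
  assert_that(n_qtl >= 1 && n_qtl <= n_snps(panel),
              "n_qtl must be in [1, n_snps]")
  assert_that(sigma_a2 > 0, "sigma_a2 must be positive")
  assert_that(h2 > 0 && h2 < 1, "h2 must be in (0, 1)")

  p <- allele_frequencies(panel)
  zc <- center_genotypes(panel, p)
  with_rng(seed, {
    qtl <- sort(sample.int(n_snps(panel), n_qtl))
    raw <- stats::rnorm(n_qtl)
    bv_raw <- as.numeric(zc$Z[, qtl, drop = FALSE] %*% raw)
    v <- stats::var(bv_raw)
    if (v <= 0) {
      numerical_error("QTL genotypes carry no variation; cannot scale effects")
    }
    scl <- sqrt(sigma_a2 / v)
    effects <- numeric(n_snps(panel))
    effects[qtl] <- raw * scl
    structure(
      list(true_effects = effects,
           qtl_indices = qtl,
           true_bv = bv_raw * scl,
           sigma_a2 = sigma_a2,
           sigma_e2 = sigma_a2 * (1 - h2) / h2,
           h2 = h2),
      class = "truth_set"
    )
  })
}

#' Simulate phenotypes from a truth set
#'
#' `y = mu + true_bv + e`, `e ~ N(0, sigma_e2)`.
#'
#' @param truth A `truth_set` from [simulate_truth()].
#' @param seed Integer seed.
#' @param mu Overall mean (default 0).
#' @return Numeric phenotype vector.
#' @export
simulate_phenotypes <- function(truth, seed = 1L, mu = 0) {
  assert_that(inherits(truth, "truth_set"), "truth must be a truth_set")
  with_rng(seed, {
    n <- length(truth$true_bv)
    mu + truth$true_bv + stats::rnorm(n, 0, sqrt(truth$sigma_e2))
  })
}

#' GBLUP breeding-value prediction on genotyped animals
#'
#' Animal-model BLUP with a single mean fixed effect:
#' `u_hat = sigma_a2 * G_b %*% solve(sigma_a2 * G_b + sigma_e2 * I, y - mean(y))`.
#' Used by the simulator to produce GEBVs with the shrinkage structure that
#' back-solving assumes.
#'
#' @param grm A (blended) [build_grm()] object.
#' @param phenotypes Numeric vector, one per animal in the GRM.
#' @param sigma_a2,sigma_e2 Variance components (> 0).
#' @param trait_name Column name for the resulting GEBV table.
#' @return A [gebv_table()] with one trait column.
#' @export
solve_gblup <- function(grm, phenotypes, sigma_a2, sigma_e2,
                        trait_name = "trait1") {
  assert_that(inherits(grm, "grm"), "grm must be a grm object")
  n <- nrow(grm$G)
  assert_that(length(phenotypes) == n,
              "phenotype length must match GRM dimension")
  assert_that(sigma_a2 > 0 && sigma_e2 > 0,
              "variance components must be positive")
  yc <- phenotypes - mean(phenotypes)
  V <- sigma_a2 * grm$G + diag(sigma_e2, n)
  sol <- tryCatch(solve(V, yc), error = function(e) {
    numerical_error(sprintf(
      "GBLUP system is singular (blend the GRM first?): %s", conditionMessage(e)))
  })
  u <- sigma_a2 * as.numeric(grm$G %*% sol)
  ids <- if (!is.null(grm$animal_ids)) grm$animal_ids
         else sprintf("ani%04d", seq_len(n))
  gebv_table(ids, matrix(u, ncol = 1), trait_name, sigma_a2)
}
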