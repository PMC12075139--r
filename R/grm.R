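#' Center genotypes by twice the allele frequency
#'
#' Builds `Z[i, j] = codes[i, j] - 2 p_j`. Missing dosages are replaced by
#' their locus mean `2 p_j`, i.e. by zero after centering, so they contribute
#' no relationship signal. Also records the VanRaden scale
#' `scale_k = 2 * sum(p * (1 - p))`.
#'
#' @param panel A [genotype_panel()].
#' @param p Allele frequencies, one per SNP (typically
#'   [allele_frequencies()] of the same panel).
#' @return A list of class `centered_genotypes`: `Z`, `p`, `scale_k`,
#'   `animal_ids`, `snp_ids`.
#' @export
center_genotypes <- function(panel, p = allele_frequencies(panel)) {
  assert_that(inherits(panel, "genotype_panel"), "panel required")
  assert_that(length(p) == n_snps(panel),
              "p must have one entry per SNP")
  assert_that(all(p >= 0 & p <= 1), "allele frequencies must lie in [0, 1]")
  Z <- sweep(panel$codes, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  structure(
    list(Z = unname(Z), p = as.numeric(p),
         scale_k = 2 * sum(p * (1 - p)),
         animal_ids = panel$animal_ids,
         snp_ids = panel$snp_map$snp_id),
    class = "centered_genotypes"
  )
}

#' Build the VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` (VanRaden's first method). The result
#' is unblended; see [blend_grm()].
#'
#' @param zc A [center_genotypes()] result.
#' @return A list of class `grm`: `G`, `beta` (0), `blend_target`,
#'   `is_blended`, `animal_ids`.
#' @export
build_grm <- function(zc) {
  assert_that(inherits(zc, "centered_genotypes"), "centered genotypes required")
  if (zc$scale_k <= 0) {
    numerical_error("all loci are fixed (2*sum(p(1-p)) = 0); GRM undefined")
  }
  G <- tcrossprod(zc$Z) / zc$scale_k
  structure(list(G = G, beta = 0, blend_target = NA_character_,
                 is_blended = FALSE, animal_ids = zc$animal_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d x %d, %s (beta = %g), mean diag = %.4f\n",
              nrow(x$G), ncol(x$G),
              if (x$is_blended) "blended" else "unblended",
              x$beta, mean(diag(x$G))))
  invisible(x)
}

#' Blend a GRM towards a positive-definite target
#'
#' `G_b = (1 - beta) * G + beta * T` with `T` the identity by default (a
#' supplied matrix, e.g. a pedigree relationship block, is also accepted).
#' Blending guarantees invertibility when `G` is rank-deficient.
#'
#' @param grm A [build_grm()] result.
#' @param beta Blending weight in `[0, 1]` (default 0.05).
#' @param target Optional target matrix; identity when `NULL`.
#' @return A blended `grm` object.
#' @export
blend_grm <- function(grm, beta = 0.05, target = NULL) {
  assert_that(inherits(grm, "grm"), "grm required")
  assert_that(beta >= 0 && beta <= 1, "beta must be in [0, 1]")
  n <- nrow(grm$G)
  if (is.null(target)) {
    Gb <- (1 - beta) * grm$G
    diag(Gb) <- diag(Gb) + beta
    tgt <- "identity"
  } else {
    target <- as.matrix(target)
    assert_that(all(dim(target) == dim(grm$G)),
                "blend target dimension must match the GRM")
    Gb <- (1 - beta) * grm$G + beta * target
    tgt <- "supplied-matrix"
  }
  structure(list(G = Gb, beta = beta, blend_target = tgt,
                 is_blended = TRUE, animal_ids = grm$animal_ids),
            class = "grm")
}

#' APY core size from the singular values of Z
#'
#' The eigenvalues of `G` are obtained by squaring the singular values of the
#' centered SNP matrix `Z`; the core size is the smallest `k` whose leading
#' eigenvalues explain at least `variance_threshold` of the total variance in
#' `G` (cumulative sum of squared singular values over their total).
#'
#' @param zc A [center_genotypes()] result.
#' @param variance_threshold Fraction of variance to capture, in `(0, 1]`
#'   (default 0.98).
#' @return Integer core size.
#' @export
select_core_size <- function(zc, variance_threshold = 0.98) {
  assert_that(inherits(zc, "centered_genotypes"), "centered genotypes required")
  assert_that(variance_threshold > 0 && variance_threshold <= 1,
              "variance_threshold must be in (0, 1]")
  s <- svd(zc$Z, nu = 0, nv = 0)$d
  tot <- sum(s^2)
  if (tot <= 0) {
    numerical_error("Z is identically zero; core size undefined")
  }
  frac <- cumsum(s^2) / tot
  # guard the threshold against cumulative-sum roundoff at 1.0
  as.integer(which(frac >= variance_threshold - 1e-12)[1L])
}

#' Randomly select core animals
#'
#' Uniform sample without replacement, deterministic given `seed`, returned
#' sorted.
#'
#' @param n_total Number of genotyped animals.
#' @param n_core Core size, `1 <= n_core <= n_total`.
#' @param seed Integer seed.
#' @return Sorted integer vector of core indices.
#' @export
select_core_animals <- function(n_total, n_core, seed = 1L) {
  assert_that(n_total >= 1, "n_total must be positive")
  assert_that(n_core >= 1 && n_core <= n_total,
              "n_core must be in [1, n_total]")
  with_rng(seed, sort(sample.int(n_total, n_core)))
}
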