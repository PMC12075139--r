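#' Back-solving parameters
#'
#' Constants of the SNP-effect back-solving equation
#' `a_hat = (1 - beta) * b * (sigma_u2 / sigma_a2) * Z' G_APY^{-1} u_hat`:
#' the blending weight `beta` used when the GRM was blended, a tuning
#' parameter `b`, the per-SNP variance `sigma_u2` and the additive genetic
#' variance `sigma_a2`. When `sigma_u2` is not supplied it defaults to
#' `sigma_a2 / (2 * sum(p * (1 - p)))`, the standard relation between SNP
#' and genetic variance under the VanRaden scaling.
#'
#' @param sigma_a2 Additive genetic variance (> 0).
#' @param beta Blending weight in `[0, 1]` (default 0.05).
#' @param b Tuning parameter (> 0, default 1).
#' @param sigma_u2 Optional per-SNP variance (> 0).
#' @return A list of class `backsolve_params`.
#' @export
backsolve_params <- function(sigma_a2, beta = 0.05, b = 1, sigma_u2 = NULL) {
  assert_that(sigma_a2 > 0, "sigma_a2 must be positive")
  assert_that(beta >= 0 && beta <= 1, "beta must be in [0, 1]")
  assert_that(b > 0, "b must be positive")
  assert_that(is.null(sigma_u2) || sigma_u2 > 0, "sigma_u2 must be positive")
  structure(list(sigma_a2 = sigma_a2, beta = beta, b = b,
                 sigma_u2 = sigma_u2),
            class = "backsolve_params")
}

#' Back-solve per-SNP effects from GEBVs through the APY inverse
#'
#' Computes `a_hat = (1 - beta) * b * (sigma_u2 / sigma_a2) *
#' Z' (G_APY^{-1} u_hat)`, with the matrix-vector product performed through
#' [apy_matvec()] so the full inverse is never formed, and fills the per-SNP
#' additive variances `sigma_ai2 = a_hat_i^2 * 2 p_i (1 - p_i)`.
#'
#' @param zc [center_genotypes()] of the post-QC panel (same animal order as
#'   the GRM/APY inverse).
#' @param apy An [build_apy_inverse()] object over the same animals.
#' @param gebv Numeric GEBV vector, one per animal.
#' @param params A [backsolve_params()].
#' @param trait_name Label carried into the result.
#' @return A list of class `snp_effects`: `effects`, `per_snp_variance`,
#'   `trait_name`, `p`, `snp_ids`.
#' @export
backsolve_snp_effects <- function(zc, apy, gebv, params,
                                  trait_name = "trait1") {
  assert_that(inherits(zc, "centered_genotypes"), "centered genotypes required")
  assert_that(inherits(apy, "apy_inverse"), "apy_inverse required")
  assert_that(inherits(params, "backsolve_params"), "backsolve_params required")
  n <- nrow(zc$Z)
  assert_that(apy$n_total == n,
              "APY inverse and Z must cover the same animals")
  assert_that(length(gebv) == n,
              sprintf("gebv has length %d but the panel has %d animals",
                      length(gebv), n))
  sigma_u2 <- if (is.null(params$sigma_u2)) params$sigma_a2 / zc$scale_k
              else params$sigma_u2
  ginv_u <- apy_matvec(apy, as.numeric(gebv))
  a_hat <- (1 - params$beta) * params$b * (sigma_u2 / params$sigma_a2) *
    as.numeric(crossprod(zc$Z, ginv_u))
  structure(
    list(effects = a_hat,
         per_snp_variance = snp_variances(a_hat, zc$p),
         trait_name = trait_name,
         p = zc$p,
         snp_ids = zc$snp_ids),
    class = "snp_effects"
  )
}

#' Additive genetic variance attributed to each SNP
#'
#' `sigma_ai2 = a_hat_i^2 * 2 p_i (1 - p_i)`.
#'
#' @param effects Estimated SNP effects.
#' @param p Allele frequencies used for centering.
#' @return Non-negative numeric vector.
#' @export
snp_variances <- function(effects, p) {
  assert_that(length(effects) == length(p),
              "effects and p must have equal length")
  assert_that(all(p >= 0 & p <= 1), "p must lie in [0, 1]")
  effects^2 * 2 * p * (1 - p)
}

#' Write per-SNP effects and variances as TSV
#'
#' @param eff A `snp_effects` object.
#' @param path Destination.
#' @return Invisibly, `path`.
#' @export
write_snp_effects <- function(eff, path) {
  utils::write.table(
    data.frame(snp_id = eff$snp_ids, effect = eff$effects,
               p = eff$p, variance = eff$per_snp_variance,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
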