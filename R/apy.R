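#' Build the APY inverse of a blended GRM
#'
#' The Algorithm for Proven and Young partitions animals into a core set c
#' (whose block `G_cc` is inverted directly) and noncore animals n handled by
#' recursion on the core. The inverse has the block form
#'
#' \deqn{G_{APY}^{-1} = \begin{pmatrix} G_{cc}^{-1} & 0 \\ 0 & 0 \end{pmatrix}
#'   + \begin{pmatrix} -G_{cc}^{-1} G_{cn} \\ I \end{pmatrix} M_{nn}^{-1}
#'   \begin{pmatrix} -G_{nc} G_{cc}^{-1} & I \end{pmatrix}}
#'
#' with the diagonal `M_nn` given by
#' `m_jj = g_jj - g_jc' G_cc^{-1} g_jc` for every noncore animal j. Only the
#' factors (`G_cc^{-1}`, `G_cn`, `diag(M_nn)`) are stored, so the full n x n
#' inverse is never materialized; see [apy_matvec()].
#'
#' @param grm_blended A blended [blend_grm()] object (positive definite on
#'   the core block).
#' @param core_indices Integer indices of the core animals (any order;
#'   stored sorted).
#' @return A list of class `apy_inverse`: `core_indices`, `noncore_indices`,
#'   `Gcc_inv`, `Gcn`, `Mnn_diag`, `n_total`, `animal_ids`.
#' @export
build_apy_inverse <- function(grm_blended, core_indices) {
  assert_that(inherits(grm_blended, "grm"), "grm required")
  G <- grm_blended$G
  n <- nrow(G)
  core <- sort(unique(as.integer(core_indices)))
  assert_that(length(core) >= 1 && all(core >= 1L & core <= n),
              "core indices must be a non-empty subset of 1..n")
  noncore <- setdiff(seq_len(n), core)

  Gcc <- G[core, core, drop = FALSE]
  ch <- tryCatch(chol(Gcc), error = function(e) {
    numerical_error(sprintf(
      "core block of G is not positive definite (blend first?): %s",
      conditionMessage(e)))
  })
  Gcc_inv <- chol2inv(ch)

  if (length(noncore) > 0L) {
    Gcn <- G[core, noncore, drop = FALSE]
    Mnn <- diag(G)[noncore] - colSums(Gcn * (Gcc_inv %*% Gcn))
    tol <- 1e-10 * max(diag(G))
    if (any(Mnn <= tol)) {
      j <- noncore[which(Mnn <= tol)[1L]]
      id <- if (!is.null(grm_blended$animal_ids)) grm_blended$animal_ids[j]
            else as.character(j)
      numerical_error(sprintf(
        "APY recursion variance m_jj <= 0 for animal %s (index %d): core too small or G not positive definite",
        id, j))
    }
  } else {
    Gcn <- matrix(0, length(core), 0)
    Mnn <- numeric(0)
  }

  structure(
    list(core_indices = core, noncore_indices = noncore,
         Gcc_inv = Gcc_inv, Gcn = Gcn, Mnn_diag = Mnn,
         n_total = n, animal_ids = grm_blended$animal_ids),
    class = "apy_inverse"
  )
}

#' @export
print.apy_inverse <- function(x, ...) {
  cat(sprintf("apy_inverse: %d animals (%d core, %d noncore)\n",
              x$n_total, length(x$core_indices), length(x$noncore_indices)))
  invisible(x)
}

#' Multiply the APY inverse onto a vector without materializing it
#'
#' For `v = (v_c, v_n)` in core/noncore order the product is computed as
#' `w = (v_n - G_nc G_cc^{-1} v_c) / m` and
#' `(G_cc^{-1} (v_c - G_cn w), w)`, re-permuted to the original animal
#' order. Cost is one core solve plus work linear in the noncore count.
#'
#' @param apy An [build_apy_inverse()] object.
#' @param v Numeric vector of length `n_total`.
#' @return `G_APY^{-1} %*% v` as a numeric vector in original animal order.
#' @export
apy_matvec <- function(apy, v) {
  assert_that(inherits(apy, "apy_inverse"), "apy_inverse required")
  assert_that(length(v) == apy$n_total,
              sprintf("v has length %d but the APY inverse covers %d animals",
                      length(v), apy$n_total))
  vc <- v[apy$core_indices]
  out <- numeric(apy$n_total)
  t1 <- as.numeric(apy$Gcc_inv %*% vc)
  if (length(apy$noncore_indices) > 0L) {
    vn <- v[apy$noncore_indices]
    w <- (vn - as.numeric(crossprod(apy$Gcn, t1))) / apy$Mnn_diag
    out[apy$core_indices] <-
      as.numeric(apy$Gcc_inv %*% (vc - as.numeric(apy$Gcn %*% w)))
    out[apy$noncore_indices] <- w
  } else {
    out[apy$core_indices] <- t1
  }
  out
}

#' Assemble the dense APY inverse (small instances / validation only)
#'
#' Materializes `G_APY^{-1}` from its stored factors by evaluating the block
#' formula, re-permuted to the original animal order. Intended for testing
#' and desk-scale inspection; defeats the purpose of APY at scale.
#'
#' @param apy An [build_apy_inverse()] object.
#' @return Dense `n_total x n_total` matrix.
#' @export
apy_dense_inverse <- function(apy) {
  assert_that(inherits(apy, "apy_inverse"), "apy_inverse required")
  n <- apy$n_total
  core <- apy$core_indices
  noncore <- apy$noncore_indices
  out <- matrix(0, n, n)
  if (length(noncore) == 0L) {
    out[core, core] <- apy$Gcc_inv
    return(out)
  }
  A <- -apy$Gcc_inv %*% apy$Gcn              # core x noncore
  Minv <- 1 / apy$Mnn_diag
  out[core, core] <- apy$Gcc_inv + A %*% (Minv * t(A))
  out[core, noncore] <- sweep(A, 2L, Minv, `*`)
  out[noncore, core] <- t(out[core, noncore])
  out[noncore, noncore] <- diag(Minv, length(noncore))
  out
}
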