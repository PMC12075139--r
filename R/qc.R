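#' Marker quality-control thresholds
#'
#' Defaults follow routine beef-cattle panel QC: SNPs are kept when they are
#' autosomal, have call rate above `call_rate_min`, minor allele frequency at
#' least `maf_min`, and deviate from Hardy-Weinberg equilibrium — measured as
#' the absolute difference between observed and expected heterozygote
#' frequencies — by at most `hwe_dev_max`.
#'
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]` (default 0.05).
#' @param hwe_dev_max Maximum `|het_obs - 2p(1-p)|`, in `[0, 1]` (default 0.15).
#' @param call_rate_min Minimum fraction of non-missing calls (default 0.90).
#' @param autosomes Chromosome ids treated as autosomal (default `1:29`, the
#'   bovine autosomes).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, hwe_dev_max = 0.15,
                          call_rate_min = 0.90, autosomes = 1:29) {
  assert_that(maf_min >= 0 && maf_min <= 0.5, "maf_min must be in [0, 0.5]")
  assert_that(hwe_dev_max >= 0 && hwe_dev_max <= 1,
              "hwe_dev_max must be in [0, 1]")
  assert_that(call_rate_min >= 0 && call_rate_min <= 1,
              "call_rate_min must be in [0, 1]")
  structure(list(maf_min = maf_min, hwe_dev_max = hwe_dev_max,
                 call_rate_min = call_rate_min,
                 autosomes = as.integer(autosomes)),
            class = "qc_thresholds")
}

#' Observed allele frequencies of a genotype panel
#'
#' For SNP i, `p_i` is the frequency of the counted allele:
#' (sum of non-missing dosages) / (2 x number of non-missing calls).
#'
#' @param panel A [genotype_panel()].
#' @return Numeric vector in `[0, 1]`, one entry per SNP.
#' @export
allele_frequencies <- function(panel) {
  assert_that(inherits(panel, "genotype_panel"), "panel required")
  n_called <- colSums(!is.na(panel$codes))
  if (any(n_called == 0L)) {
    bad <- panel$snp_map$snp_id[which(n_called == 0L)[1L]]
    numerical_error(sprintf("SNP %s has no non-missing calls", bad))
  }
  colSums(panel$codes, na.rm = TRUE) / (2 * n_called)
}

#' Apply marker quality-control filters
#'
#' Filters are applied in a fixed attribution order — (1) non-autosome,
#' (2) call rate, (3) MAF, (4) HWE heterozygote deviation — and each removed
#' SNP is attributed to the FIRST filter it fails, so the per-filter counts
#' partition the removals deterministically. Animals are never filtered.
#'
#' @param panel A [genotype_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return A list with `panel` (the filtered [genotype_panel()], SNP order
#'   preserved) and `report` (class `qc_report`: `n_input_snps`,
#'   `removed_by_filter` named counts, `n_retained_snps`, and a per-SNP
#'   `fate` data.frame).
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds()) {
  assert_that(inherits(panel, "genotype_panel"), "panel required")
  assert_that(inherits(thresholds, "qc_thresholds"), "thresholds required")

  codes <- panel$codes
  m <- ncol(codes)
  n_called <- colSums(!is.na(codes))
  call_rate <- n_called / nrow(codes)
  p <- ifelse(n_called > 0, colSums(codes, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(p, 1 - p)
  het_obs <- ifelse(n_called > 0,
                    colSums(codes == 1L, na.rm = TRUE) / n_called, NA)
  hwe_dev <- abs(het_obs - 2 * p * (1 - p))

  fail_autosome <- !(panel$snp_map$chromosome %in% thresholds$autosomes)
  fail_callrate <- n_called == 0L | call_rate < thresholds$call_rate_min
  fail_maf <- !is.na(maf) & maf < thresholds$maf_min
  fail_hwe <- !is.na(hwe_dev) & hwe_dev > thresholds$hwe_dev_max

  fate <- rep("kept", m)
  fate[fail_hwe] <- "hwe"
  fate[fail_maf] <- "maf"
  fate[fail_callrate] <- "call_rate"
  fate[fail_autosome] <- "autosome"

  keep <- fate == "kept"
  removed <- c(autosome = sum(fate == "autosome"),
               call_rate = sum(fate == "call_rate"),
               maf = sum(fate == "maf"),
               hwe = sum(fate == "hwe"))
  if (!any(keep)) {
    warning("qc_filter removed every SNP; the output panel is empty")
  }

  out_panel <- genotype_panel(codes[, keep, drop = FALSE],
                              panel$animal_ids,
                              panel$snp_map[keep, , drop = FALSE])
  report <- structure(
    list(n_input_snps = m,
         removed_by_filter = removed,
         n_retained_snps = sum(keep),
         fate = data.frame(snp_id = panel$snp_map$snp_id, fate = fate,
                           stringsAsFactors = FALSE),
         thresholds = thresholds,
         filter_order = c("autosome", "call_rate", "maf", "hwe")),
    class = "qc_report"
  )
  list(panel = out_panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d SNPs in, %d retained\n",
              x$n_input_snps, x$n_retained_snps))
  cat(sprintf("  removed: %s\n",
              paste(sprintf("%s=%d", names(x$removed_by_filter),
                            x$removed_by_filter), collapse = ", ")))
  invisible(x)
}

#' Write a QC report as a fate TSV plus a one-line JSON summary
#'
#' @param report A `qc_report` from [qc_filter()].
#' @param tsv_path Per-SNP fate table destination.
#' @param json_path Summary destination.
#' @return Invisibly, the two paths.
#' @export
write_qc_report <- function(report, tsv_path, json_path) {
  utils::write.table(report$fate, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(n_input_snps = report$n_input_snps,
         removed_by_filter = as.list(report$removed_by_filter),
         n_retained_snps = report$n_retained_snps,
         filter_order = report$filter_order),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv_path, json_path))
}
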