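#' Sliding-window scan of per-SNP variances
#'
#' Within each chromosome, window j covers `window_size` adjacent SNPs
#' starting at SNP j for `j = 1, 1 + step, ...`; windows never span two
#' chromosomes, and a chromosome with fewer SNPs than `window_size` yields no
#' windows. Each window's variance is the sum of its members' per-SNP
#' variances; `pct_of_additive` expresses it as a percentage of either the
#' additive genetic variance (`denominator = "sigma_a2"`, how GWAS window
#' tables are usually reported) or the total across all SNPs
#' (`"snp_sum"`, self-normalized). Windows are ranked by descending variance
#' with ties broken by (chromosome, start_bp).
#'
#' @param variances Per-SNP variances aligned with `snp_map`.
#' @param snp_map SNP map `data.frame` (sorted by chromosome, position).
#' @param window_size Number of adjacent SNPs per window (>= 1).
#' @param step Offset between consecutive window starts (default 1; use
#'   `step = window_size` for a disjoint tiling).
#' @param denominator `"sigma_a2"` or `"snp_sum"`.
#' @param sigma_a2 Additive genetic variance; required when
#'   `denominator = "sigma_a2"`.
#' @return A `data.frame` of class `window_table` with columns `window_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `first_snp_index` (into `snp_map`),
#'   `n_snps`, `variance`, `pct_of_additive`, `rank`.
#' @export
window_scan <- function(variances, snp_map, window_size, step = 1L,
                        denominator = c("sigma_a2", "snp_sum"),
                        sigma_a2 = NULL) {
  denominator <- match.arg(denominator)
  assert_that(length(variances) == nrow(snp_map),
              "one variance per mapped SNP required")
  assert_that(window_size >= 1, "window_size must be >= 1")
  assert_that(step >= 1, "step must be >= 1")
  if (denominator == "sigma_a2") {
    assert_that(!is.null(sigma_a2) && sigma_a2 > 0,
                "sigma_a2 required when denominator = 'sigma_a2'")
    denom <- sigma_a2
  } else {
    denom <- sum(variances)
  }

  chroms <- unique(snp_map$chromosome)
  pieces <- lapply(chroms, function(ch) {
    idx <- which(snp_map$chromosome == ch)
    k <- length(idx)
    if (k < window_size) return(NULL)
    starts <- seq.int(1L, k - window_size + 1L, by = step)
    cs <- c(0, cumsum(variances[idx]))
    data.frame(
      chromosome = ch,
      start_bp = snp_map$position_bp[idx[starts]],
      end_bp = snp_map$position_bp[idx[starts + window_size - 1L]],
      first_snp_index = idx[starts],
      n_snps = window_size,
      variance = cs[starts + window_size] - cs[starts]
    )
  })
  tab <- do.call(rbind, pieces)
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("window_size exceeds every chromosome; no windows produced")
    tab <- data.frame(chromosome = integer(), start_bp = integer(),
                      end_bp = integer(), first_snp_index = integer(),
                      n_snps = integer(), variance = numeric())
  }
  tab$pct_of_additive <- if (denom > 0) 100 * tab$variance / denom
                         else rep(NA_real_, nrow(tab))
  ord <- order(-tab$variance, tab$chromosome, tab$start_bp)
  tab$rank <- integer(nrow(tab))
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- cbind(window_id = seq_len(nrow(tab)), tab)
  class(tab) <- c("window_table", "data.frame")
  tab
}

#' Keep the top-ranked windows
#'
#' `mode = "fraction"` keeps the best `ceiling(value * n_windows)` windows;
#' `mode = "count"` keeps exactly `value`. With
#' `overlap_policy = "greedy-nonoverlap"` the table is walked in rank order
#' and any window sharing a SNP with an already-kept window is discarded, so
#' the report lists distinct genomic regions even when step-1 windows overlap
#' heavily; `"keep-all"` returns the raw top slice.
#'
#' @param table A [window_scan()] result.
#' @param mode `"fraction"` or `"count"`.
#' @param value Fraction in (0, 1] or window count.
#' @param overlap_policy `"keep-all"` or `"greedy-nonoverlap"`.
#' @return The kept rows, in rank order, same class as the input.
#' @export
select_top_windows <- function(table, mode = c("fraction", "count"),
                               value,
                               overlap_policy = c("keep-all",
                                                  "greedy-nonoverlap")) {
  mode <- match.arg(mode)
  overlap_policy <- match.arg(overlap_policy)
  n <- nrow(table)
  if (n == 0L) return(table)
  if (mode == "fraction") {
    assert_that(value > 0 && value <= 1, "fraction must be in (0, 1]")
    quota <- as.integer(ceiling(value * n))
  } else {
    assert_that(value >= 1 && value <= n,
                "count must be in [1, n_windows]")
    quota <- as.integer(value)
  }
  ord <- table[order(table$rank), , drop = FALSE]
  if (overlap_policy == "keep-all") {
    out <- ord[seq_len(quota), , drop = FALSE]
  } else {
    kept <- logical(0)
    kept_rows <- integer(0)
    covered_lo <- integer(0)
    covered_hi <- integer(0)
    for (r in seq_len(n)) {
      lo <- ord$first_snp_index[r]
      hi <- lo + ord$n_snps[r] - 1L
      if (!any(lo <= covered_hi & hi >= covered_lo)) {
        kept_rows <- c(kept_rows, r)
        covered_lo <- c(covered_lo, lo)
        covered_hi <- c(covered_hi, hi)
        if (length(kept_rows) == quota) break
      }
    }
    out <- ord[kept_rows, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Window size from effective population size
#'
#' In a population of effective size `Ne`, the mean length of an independent
#' chromosome (Stam) segment is `1 / (4 * Ne)` Morgans, and eight such
#' segments approximate the span capturing most QTL variance. The span in Mb
#' follows from the Morgan-to-Mb conversion (default 100 Mb per Morgan, i.e.
#' 1 cM = 1 Mb), and a window size in SNPs follows from the panel's marker
#' density when supplied.
#'
#' @param ne Effective population size (>= 1).
#' @param n_segments Number of Stam segments spanned (default 8).
#' @param mb_per_morgan Physical length per Morgan (default 100).
#' @param snps_per_mb Marker density; `window_snps` is 0 when omitted.
#' @return A list of class `window_size_spec` with full-precision fields
#'   (`segment_length_morgans`, `span_morgans`, `span_mb`, `window_snps`) and
#'   their conventionally rounded forms (5, 4 and 2 decimals) in `rounded`.
#' @export
window_size_from_ne <- function(ne, n_segments = 8L, mb_per_morgan = 100,
                                snps_per_mb = 0) {
  assert_that(ne >= 1, "ne must be >= 1")
  assert_that(n_segments >= 1, "n_segments must be >= 1")
  assert_that(mb_per_morgan > 0, "mb_per_morgan must be positive")
  assert_that(snps_per_mb >= 0, "snps_per_mb must be non-negative")
  seg <- 1 / (4 * ne)
  span_m <- n_segments * seg
  span_mb <- span_m * mb_per_morgan
  structure(
    list(ne = as.integer(ne), n_segments = as.integer(n_segments),
         segment_length_morgans = seg,
         span_morgans = span_m,
         span_mb = span_mb,
         window_snps = if (snps_per_mb > 0) as.integer(round(span_mb * snps_per_mb))
                       else 0L,
         rounded = list(segment_length_morgans = round(seg, 5),
                        span_morgans = round(span_m, 4),
                        span_mb = round(span_mb, 2))),
    class = "window_size_spec"
  )
}

#' @export
print.window_size_spec <- function(x, ...) {
  cat(sprintf(
    "window_size_spec: Ne = %d -> Stam segment %.5f Morgans; %d segments span %.4f Morgans = %.2f Mb%s\n",
    x$ne, x$rounded$segment_length_morgans, x$n_segments,
    x$rounded$span_morgans, x$rounded$span_mb,
    if (x$window_snps > 0) sprintf(" (~%d SNPs)", x$window_snps) else ""))
  invisible(x)
}

#' Write a window table as TSV
#'
#' @param table A [window_scan()] (or [select_top_windows()]) result.
#' @param path Destination.
#' @param trait Optional trait label prepended as a column.
#' @return Invisibly, `path`.
#' @export
write_window_table <- function(table, path, trait = NULL) {
  out <- as.data.frame(table)
  if (!is.null(trait)) out <- cbind(trait = trait, out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
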