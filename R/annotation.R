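#' Read gene intervals from BED or GFF3
#'
#' Parsing is delegated to `rtracklayer::import()`; BED's 0-based half-open
#' coordinates are converted to 1-based inclusive (rtracklayer does this on
#' import), GFF3 is taken as 1-based inclusive, and only gene-level records
#' (GFF3 `type == "gene"`) are kept. Biotype is read from the
#' `biotype`/`gene_biotype` attribute when present, else `"unknown"`.
#'
#' @param path File path.
#' @param format_name `"bed"` or `"gff3"`.
#' @return A `data.frame` of class `gene_interval_set` with columns
#'   `gene_id`, `gene_name`, `biotype`, `chromosome`, `start_bp`, `end_bp`,
#'   `strand`.
#' @export
read_gene_intervals <- function(path, format_name = c("bed", "gff3")) {
  format_name <- match.arg(format_name)
  assert_that(file.exists(path), sprintf("file not found: %s", path))

  # cheap structural pre-check so malformed lines are reported by number
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  min_fields <- if (format_name == "bed") 3L else 9L
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < min_fields)) {
    format_error(sprintf("malformed %s line %d in %s (%d field(s), expected >= %d)",
                         format_name, body[which(nf < min_fields)[1L]], path,
                         nf[which(nf < min_fields)[1L]], min_fields))
  }

  gr <- tryCatch(
    rtracklayer::import(path, format = if (format_name == "bed") "BED" else "GFF3"),
    error = function(e) format_error(sprintf("cannot parse %s as %s: %s",
                                             path, format_name,
                                             conditionMessage(e))))

  if (format_name == "gff3") {
    is_gene <- as.character(gr$type) == "gene"
    gr <- gr[is_gene]
    if (length(gr) == 0L) {
      warning("no gene-level records in GFF3 input; returning an empty set")
    }
  }

  meta <- S4Vectors::mcols(gr)
  pick <- function(cols, default) {
    for (cl in cols) {
      if (cl %in% names(meta)) {
        v <- as.character(meta[[cl]])
        if (any(!is.na(v) & nzchar(v))) return(ifelse(is.na(v), default, v))
      }
    }
    rep(default, length(gr))
  }
  gene_id <- if (format_name == "bed") pick("name", "gene") else
    pick(c("gene_id", "ID", "Name"), "gene")
  gene_name <- if (format_name == "bed") gene_id else
    pick(c("Name", "gene_name", "gene_id", "ID"), "gene")
  biotype <- pick(c("biotype", "gene_biotype"), "unknown")

  out <- data.frame(
    gene_id = gene_id,
    gene_name = gene_name,
    biotype = biotype,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-")] <- "."
  class(out) <- c("gene_interval_set", "data.frame")
  out
}

#' Annotate top windows with overlapping genes
#'
#' A gene is reported for a window when their 1-based inclusive intervals
#' intersect on the same chromosome; any overlap of at least 1 bp counts, so
#' genes extending beyond a window's edges are included (set
#' `containment = TRUE` to require the gene fully inside the window).
#' Output is sorted by (trait, window rank, gene start).
#'
#' @param top A ranked [window_scan()]/[select_top_windows()] table.
#' @param genes A [read_gene_intervals()] set.
#' @param trait Trait label for the output (a `trait` column in `top` wins).
#' @param containment Require full gene containment instead of any overlap.
#' @return A `data.frame` of class `annotation_table` with columns `trait`,
#'   `window_id`, `chrom`, `window_start`, `window_end`, `gene_id`,
#'   `gene_name`, `biotype`, `overlap_bp`.
#' @export
annotate_windows <- function(top, genes, trait = "trait1",
                             containment = FALSE) {
  assert_that(is.data.frame(top), "window table required")
  assert_that(is.data.frame(genes), "gene interval set required")
  empty <- data.frame(trait = character(), window_id = integer(),
                      chrom = character(), window_start = integer(),
                      window_end = integer(), gene_id = character(),
                      gene_name = character(), biotype = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("annotation_table", "data.frame")
  if (nrow(top) == 0L || nrow(genes) == 0L) return(empty)

  wchr <- as.character(top$chromosome)
  gchr <- as.character(genes$chromosome)
  if (length(intersect(unique(wchr), unique(gchr))) == 0L) {
    format_error(paste0(
      "no chromosome name shared between windows (", paste(unique(wchr), collapse = ","),
      ") and genes (", paste(unique(gchr), collapse = ","),
      "); supply a rename map to harmonize naming"))
  }

  wgr <- GenomicRanges::GRanges(wchr,
                                IRanges::IRanges(top$start_bp, top$end_bp))
  ggr <- GenomicRanges::GRanges(gchr,
                                IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(
    ggr, wgr, type = if (containment) "within" else "any")
  if (length(hits) == 0L) return(empty)

  gi <- S4Vectors::queryHits(hits)
  wi <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(ggr)[gi], IRanges::ranges(wgr)[wi]))

  out <- data.frame(
    trait = if ("trait" %in% names(top)) as.character(top$trait[wi]) else trait,
    window_id = top$window_id[wi],
    chrom = wchr[wi],
    window_start = top$start_bp[wi],
    window_end = top$end_bp[wi],
    gene_id = genes$gene_id[gi],
    gene_name = genes$gene_name[gi],
    biotype = genes$biotype[gi],
    overlap_bp = as.integer(ov),
    stringsAsFactors = FALSE
  )
  out$.gene_start <- genes$start_bp[gi]
  out$.rank <- if ("rank" %in% names(top)) top$rank[wi] else wi
  out <- out[!duplicated(out[, c("window_id", "gene_id")]), , drop = FALSE]
  out <- out[order(out$trait, out$.rank, out$.gene_start), , drop = FALSE]
  out$.gene_start <- NULL
  out$.rank <- NULL
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}
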