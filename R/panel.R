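#' Construct a genotype panel
#'
#' A genotype panel couples an animals-by-SNPs matrix of allele dosages
#' (0/1/2, `NA` for missing) with a SNP map (SNP id, chromosome, physical
#' position in bp) and animal identifiers. It is the substrate every
#' downstream stage (quality control, relationship matrix, back-solving)
#' operates on.
#'
#' @param codes Integer matrix, animals in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param animal_ids Character vector of row identifiers.
#' @param snp_map `data.frame` with columns `snp_id`, `chromosome`
#'   (positive integer), `position_bp` (positive integer), one row per column
#'   of `codes`, in column order.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(codes, animal_ids, snp_map) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  assert_that(length(animal_ids) == nrow(codes),
              "animal_ids length must equal number of genotype rows")
  assert_that(is.data.frame(snp_map) &&
                all(c("snp_id", "chromosome", "position_bp") %in% names(snp_map)),
              "snp_map must have columns snp_id, chromosome, position_bp")
  assert_that(nrow(snp_map) == ncol(codes),
              sprintf("snp_map has %d rows but genotype matrix has %d columns",
                      nrow(snp_map), ncol(codes)))
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) {
    idx <- which(bad)[1L]
    format_error(sprintf(
      "genotype codes must be 0/1/2/NA; offending entry at row %d, column %d",
      (idx - 1L) %% nrow(codes) + 1L, (idx - 1L) %/% nrow(codes) + 1L))
  }
  snp_map <- data.frame(
    snp_id = as.character(snp_map$snp_id),
    chromosome = as.integer(snp_map$chromosome),
    position_bp = as.integer(snp_map$position_bp),
    stringsAsFactors = FALSE
  )
  assert_that(all(snp_map$chromosome >= 1L) && all(snp_map$position_bp >= 1L),
              "chromosomes and positions must be positive integers")
  for (chr in unique(snp_map$chromosome)) {
    pos <- snp_map$position_bp[snp_map$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      format_error(sprintf(
        "positions on chromosome %d are not strictly increasing (duplicate or unsorted map)",
        chr))
    }
  }
  dimnames(codes) <- list(as.character(animal_ids), snp_map$snp_id)
  structure(
    list(codes = codes,
         animal_ids = as.character(animal_ids),
         snp_map = snp_map),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d animals x %d SNPs on %d chromosome(s), %.3f%% missing\n",
              nrow(x$codes), ncol(x$codes),
              length(unique(x$snp_map$chromosome)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

n_animals <- function(panel) nrow(panel$codes)
n_snps <- function(panel) ncol(panel$codes)

#' Read a genotype panel from disk
#'
#' Two dialects are supported. `matrix-tsv` is a TSV with a header of SNP ids
#' and a leading `animal_id` column; dosages are 0/1/2 with `NA` for missing.
#' `plink-raw` is the PLINK `--recode A` layout: a header row and six leading
#' metadata columns (FID IID PAT MAT SEX PHENOTYPE) followed by one dosage
#' column per SNP. Both require a companion map TSV with columns
#' `snp_id`, `chromosome`, `position_bp`. The map is sorted by
#' (chromosome, position) and the genotype columns are re-ordered to match.
#'
#' @param genotype_path Path to the genotype file.
#' @param map_path Path to the SNP map TSV.
#' @param format_name `"matrix-tsv"` or `"plink-raw"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(genotype_path, map_path,
                           format_name = c("matrix-tsv", "plink-raw")) {
  format_name <- match.arg(format_name)
  assert_that(file.exists(genotype_path),
              sprintf("genotype file not found: %s", genotype_path))
  assert_that(file.exists(map_path),
              sprintf("map file not found: %s", map_path))
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("snp_id", "chromosome", "position_bp") %in% names(map))) {
    format_error("map file must have header snp_id, chromosome, position_bp")
  }

  if (format_name == "matrix-tsv") {
    tab <- utils::read.table(genotype_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1L] != "animal_id") {
      format_error("matrix-tsv genotype file must start with an animal_id column")
    }
    ids <- as.character(tab[[1L]])
    codes <- as.matrix(tab[, -1L, drop = FALSE])
    snp_ids <- colnames(codes)
  } else {
    tab <- utils::read.table(genotype_path, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (ncol(tab) < 7L || !identical(toupper(names(tab)[1:6]), meta)) {
      format_error("plink-raw file must have 6 leading columns FID IID PAT MAT SEX PHENOTYPE")
    }
    ids <- as.character(tab$IID)
    codes <- as.matrix(tab[, -(1:6), drop = FALSE])
    # PLINK appends the counted allele to the SNP name (snp_A); strip it so
    # dosage columns align with map snp_ids
    snp_ids <- sub("_[ACGT0-9]+$", "", colnames(codes))
  }

  if (ncol(codes) != nrow(map)) {
    format_error(sprintf(
      "dimension mismatch: %d genotype columns but %d map rows",
      ncol(codes), nrow(map)))
  }
  if (!setequal(snp_ids, map$snp_id) && !all(snp_ids == map$snp_id)) {
    format_error("SNP ids in genotype header do not match the map")
  }
  suppressWarnings(storage.mode(codes) <- "integer")
  colnames(codes) <- snp_ids

  ord <- order(map$chromosome, map$position_bp)
  map <- map[ord, , drop = FALSE]
  codes <- codes[, map$snp_id, drop = FALSE]
  genotype_panel(codes, ids, map)
}

#' Write a genotype panel as matrix TSV plus map TSV
#'
#' @param panel A [genotype_panel()].
#' @param genotype_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genotypes <- function(panel, genotype_path, map_path) {
  tab <- data.frame(animal_id = panel$animal_ids,
                    panel$codes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$snp_map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotype_path, map_path))
}

#' Construct a GEBV table
#'
#' Holds genomic estimated breeding values (one column per trait) and the
#' additive genetic variance of each trait, the two quantities back-solving
#' consumes.
#'
#' @param animal_ids Character vector.
#' @param gebv Numeric matrix, animals x traits.
#' @param trait_names Character vector, one per column of `gebv`.
#' @param sigma_a2_per_trait Positive numeric vector, one per trait.
#' @return An object of class `gebv_table`.
#' @export
gebv_table <- function(animal_ids, gebv, trait_names, sigma_a2_per_trait) {
  gebv <- as.matrix(gebv)
  assert_that(length(animal_ids) == nrow(gebv),
              "animal_ids length must equal number of GEBV rows")
  assert_that(length(trait_names) == ncol(gebv),
              "one trait name per GEBV column required")
  assert_that(length(sigma_a2_per_trait) == ncol(gebv) &&
                all(sigma_a2_per_trait > 0),
              "sigma_a2_per_trait must be positive, one value per trait")
  dimnames(gebv) <- list(as.character(animal_ids), trait_names)
  structure(
    list(animal_ids = as.character(animal_ids), gebv = gebv,
         trait_names = as.character(trait_names),
         sigma_a2_per_trait = stats::setNames(as.numeric(sigma_a2_per_trait),
                                              trait_names)),
    class = "gebv_table"
  )
}

#' Write / read a GEBV table as TSV (+ JSON variance components)
#'
#' @param gt A [gebv_table()].
#' @param path Output TSV path (`animal_id` column then one column per trait).
#' @param varcomp_path Optional JSON sidecar with `sigma_a2` per trait.
#' @return Invisibly, `path`.
#' @export
write_gebvs <- function(gt, path, varcomp_path = NULL) {
  tab <- data.frame(animal_id = gt$animal_ids, gt$gebv,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(varcomp_path)) {
    jsonlite::write_json(list(sigma_a2 = as.list(gt$sigma_a2_per_trait)),
                         varcomp_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_gebvs
#' @param sigma_a2_per_trait Named or unnamed positive vector; required when
#'   no `varcomp_path` is given.
#' @export
read_gebvs <- function(path, varcomp_path = NULL, sigma_a2_per_trait = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "animal_id") {
    format_error("GEBV file must start with an animal_id column")
  }
  traits <- names(tab)[-1L]
  if (!is.null(varcomp_path)) {
    vc <- jsonlite::read_json(varcomp_path, simplifyVector = TRUE)
    sigma_a2_per_trait <- unlist(vc$sigma_a2)[traits]
  }
  assert_that(!is.null(sigma_a2_per_trait),
              "sigma_a2_per_trait (or a varcomp JSON) is required")
  gebv_table(tab$animal_id, as.matrix(tab[, -1L, drop = FALSE]),
             traits, sigma_a2_per_trait)
}
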