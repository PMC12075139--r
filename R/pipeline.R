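#' Validate a pipeline configuration
#'
#' A configuration is a plain named list (or a YAML/JSON file deserializing
#' to one) with the stage inputs and knobs:
#'
#' * `genotypes`, `map`: genotype panel paths (matrix-tsv dialect unless
#'   `genotype_format` says otherwise); `gebvs` + `varcomp` (or
#'   `sigma_a2` named list): the GEBV inputs; optional `genes` +
#'   `gene_format`; `outdir`.
#' * `qc`: named list of [qc_thresholds()] arguments (optional).
#' * `beta`, `b`: blending weight and back-solve tuning parameter.
#' * exactly one of `core_size` / `core_variance_threshold`; `seed` for the
#'   random core draw.
#' * window sizing: exactly one of `window_snps` / `ne` (with optional
#'   `n_segments`, `mb_per_morgan`; marker density is measured from the map);
#'   `step`, `top_mode`, `top_value`, `overlap_policy`, `denominator`.
#'
#' @param config Named list or path to a YAML/JSON file.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  assert_that(is.list(config), "config must be a named list or a file path")
  has <- function(x) !is.null(config[[x]])
  for (f in c("genotypes", "map", "gebvs", "outdir")) {
    assert_that(has(f), sprintf("config field '%s' is required", f))
  }
  assert_that(xor(has("core_size"), has("core_variance_threshold")),
              "exactly one of core_size / core_variance_threshold must be set")
  assert_that(xor(has("window_snps"), has("ne")),
              "exactly one of window_snps / ne must be set")
  defaults <- list(genotype_format = "matrix-tsv", beta = 0.05, b = 1,
                   seed = 1L, step = 1L, top_mode = "fraction",
                   top_value = 0.01, overlap_policy = "greedy-nonoverlap",
                   denominator = "sigma_a2", n_segments = 8L,
                   mb_per_morgan = 100, gene_format = "bed", qc = list())
  for (nm in names(defaults)) {
    if (!has(nm)) config[[nm]] <- defaults[[nm]]
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Run the GWAS pipeline end to end
#'
#' Sequences QC, GRM construction, blending, core selection, APY inversion,
#' per-trait back-solving, window scanning, top-window selection and (when a
#' gene file is supplied) positional annotation. All stage outputs are
#' written under `config$outdir` as TSV, plus a `manifest.json` recording
#' package version, seeds, thresholds, the realized core size and variance
#' explained, and per-stage row counts. Rerunning with the same config and
#' inputs reproduces every artifact bit-identically except the manifest
#' timestamp.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  panel <- stage("read", read_genotypes(config$genotypes, config$map,
                                        config$genotype_format))
  thr <- stage("qc", do.call(qc_thresholds, config$qc))
  qc <- stage("qc", qc_filter(panel, thr))
  write_qc_report(qc$report,
                  file.path(config$outdir, "qc_fate.tsv"),
                  file.path(config$outdir, "qc_summary.json"))

  gt <- stage("gebvs", read_gebvs(
    config$gebvs,
    varcomp_path = config$varcomp,
    sigma_a2_per_trait = if (!is.null(config$sigma_a2)) unlist(config$sigma_a2) else NULL))
  keep <- match(qc$panel$animal_ids, gt$animal_ids)
  assert_that(!anyNA(keep), "every genotyped animal needs a GEBV row")

  p <- stage("grm", allele_frequencies(qc$panel))
  zc <- stage("grm", center_genotypes(qc$panel, p))
  gb <- stage("grm", blend_grm(build_grm(zc), beta = config$beta))

  n_core <- if (!is.null(config$core_size)) as.integer(config$core_size)
            else stage("core", select_core_size(zc, config$core_variance_threshold))
  realized <- {
    s <- svd(zc$Z, nu = 0, nv = 0)$d
    sum(s[seq_len(min(n_core, length(s)))]^2) / sum(s^2)
  }
  core <- stage("core", select_core_animals(nrow(gb$G), n_core,
                                            seed = config$seed))
  apy <- stage("apy", build_apy_inverse(gb, core))
  jsonlite::write_json(
    list(beta = config$beta, seed = config$seed, n_core = n_core,
         variance_explained = realized, core_indices = core),
    file.path(config$outdir, "apy_core.json"), auto_unbox = TRUE, digits = NA)

  window_snps <- if (!is.null(config$window_snps)) {
    as.integer(config$window_snps)
  } else {
    span_mb <- sum(tapply(qc$panel$snp_map$position_bp,
                          qc$panel$snp_map$chromosome, max)) / 1e6
    dens <- n_snps(qc$panel) / span_mb
    spec <- window_size_from_ne(config$ne, config$n_segments,
                                config$mb_per_morgan, snps_per_mb = dens)
    spec$window_snps
  }

  genes <- if (!is.null(config$genes)) {
    stage("annotation", read_gene_intervals(config$genes, config$gene_format))
  } else NULL

  counts <- list(n_animals = n_animals(qc$panel),
                 snps_in = qc$report$n_input_snps,
                 snps_retained = qc$report$n_retained_snps,
                 n_core = n_core, window_snps = window_snps,
                 per_trait = list())

  for (trait in gt$trait_names) {
    u <- gt$gebv[keep, trait]
    params <- backsolve_params(sigma_a2 = gt$sigma_a2_per_trait[[trait]],
                               beta = config$beta, b = config$b,
                               sigma_u2 = config$sigma_u2)
    eff <- stage("backsolve",
                 backsolve_snp_effects(zc, apy, u, params, trait_name = trait))
    write_snp_effects(eff, file.path(config$outdir,
                                     sprintf("snp_effects_%s.tsv", trait)))
    wt <- stage("windows", window_scan(
      eff$per_snp_variance, qc$panel$snp_map, window_snps,
      step = config$step, denominator = config$denominator,
      sigma_a2 = gt$sigma_a2_per_trait[[trait]]))
    write_window_table(wt, file.path(config$outdir,
                                     sprintf("windows_%s.tsv", trait)), trait)
    top <- stage("windows", select_top_windows(
      wt, mode = config$top_mode, value = config$top_value,
      overlap_policy = config$overlap_policy))
    write_window_table(top, file.path(config$outdir,
                                      sprintf("top_windows_%s.tsv", trait)),
                       trait)
    ann_rows <- NA_integer_
    if (!is.null(genes)) {
      ann <- stage("annotation", annotate_windows(top, genes, trait = trait))
      utils::write.table(ann,
                         file.path(config$outdir,
                                   sprintf("annotation_%s.tsv", trait)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ann_rows <- nrow(ann)
    }
    counts$per_trait[[trait]] <- list(n_windows = nrow(wt),
                                      n_top_windows = nrow(top),
                                      n_annotation_rows = ann_rows)
  }

  manifest <- list(
    package = "apygwas",
    version = as.character(utils::packageVersion("apygwas")),
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    beta = config$beta, b = config$b,
    qc_thresholds = thr[c("maf_min", "hwe_dev_max", "call_rate_min")],
    core = list(n_core = n_core, variance_explained = realized),
    window = list(window_snps = window_snps, step = config$step,
                  top_mode = config$top_mode, top_value = config$top_value,
                  overlap_policy = config$overlap_policy,
                  denominator = config$denominator),
    counts = counts)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
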