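#' Validate a pipeline configuration
#'
#' Checks paths, thresholds and sizes before any computation. A config is a
#' named list; see [run_pipeline()] for recognized fields.
#'
#' @param config Named list, or path to a JSON file holding one.
#' @return The normalized config list, invisibly on error-free validation.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(max_missing = 0.20, min_maf = 0.05, min_call_rate = 0.50,
                   min_reproducibility = 0.995, require_mapped = TRUE,
                   bootstrap_n = 1000, resample_n = 211, resample_reps = 100,
                   seed = 1L)
  config <- utils::modifyList(defaults, config)
  for (fld in c("genotype", "map", "groups", "out_dir")) {
    if (is.null(config[[fld]])) {
      rlang::abort(paste0("config field missing: ", fld),
                   class = "gbsdiv_config_error")
    }
  }
  for (fld in c("max_missing", "min_maf", "min_call_rate", "min_reproducibility")) {
    v <- config[[fld]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      rlang::abort(paste0("config threshold out of [0, 1]: ", fld, " = ", v),
                   class = "gbsdiv_config_error")
    }
  }
  if (config$min_maf > 0.5) {
    rlang::abort("min_maf cannot exceed 0.5 (minor allele frequency bound)",
                 class = "gbsdiv_config_error")
  }
  if (config$bootstrap_n < 1 || config$resample_n < 1) {
    rlang::abort("bootstrap_n and resample_n must be >= 1",
                 class = "gbsdiv_config_error")
  }
  invisible(config)
}

#' Run the full diversity pipeline
#'
#' Orchestrates marker QC, diversity summaries, diversity partitioning,
#' the bootstrapped neighbor-joining tree, and (when inputs are supplied)
#' gene-marker frequency tables and band-novelty reports, writing a report
#' bundle to `config$out_dir`. Every output table starts with comment lines
#' recording seed, thresholds and package version, and a `manifest.json`
#' captures versions, the seed, thresholds and input checksums. A stage
#' failure aborts with the stage name and underlying cause.
#'
#' Recognized config fields: `genotype`, `map`, `groups` (input paths),
#' optional `gene_calls` (CSV: accession, allele_id, call), `gene_panel`
#' (TSV: allele_id, gene, expected_bp), `band_observations` (CSV:
#' accession, allele_id, observed_bp), thresholds `max_missing`, `min_maf`,
#' `min_call_rate`, `min_reproducibility`, `require_mapped`, sizes
#' `bootstrap_n`, `resample_n`, `resample_reps`, plus `seed` and `out_dir`.
#'
#' @param config Named list or JSON path; see
#'   [validate_pipeline_config()].
#' @return The manifest (list), invisibly. Side effect: files under
#'   `out_dir` (`filter_log.tsv`, `diversity_table.tsv`,
#'   `differentiation.tsv`, `tree.nwk`, `gene_frequencies.tsv`,
#'   `band_novelty.tsv`, `manifest.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("gbsdiv %s", as.character(utils::packageVersion("gbsdiv"))),
           sprintf("seed=%d", config$seed),
           sprintf("max_missing=%g min_maf=%g min_call_rate=%g min_reproducibility=%g",
                   config$max_missing, config$min_maf, config$min_call_rate,
                   config$min_reproducibility))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "gbsdiv_stage_error", parent = e)
    })
  }

  geno <- stage("read", read_genotype_matrix(config$genotype))
  map <- stage("read", read_marker_map(config$map))
  groups <- stage("read", read_groups(config$groups))

  filtered <- stage("qc", filter_markers(
    geno, map, max_missing = config$max_missing, min_maf = config$min_maf,
    min_call_rate = config$min_call_rate,
    require_mapped = config$require_mapped,
    min_reproducibility = config$min_reproducibility))
  write_tsv_with_header(filter_log(filtered),
                        file.path(config$out_dir, "filter_log.tsv"), hdr)

  div_tab <- stage("diversity", diversity_table(filtered, map, groups))
  write_tsv_with_header(div_tab,
                        file.path(config$out_dir, "diversity_table.tsv"), hdr)

  diff <- stage("differentiation",
                differentiation_stats(filtered, groups,
                                      grouping_label = "germplasm_sets"))
  write_tsv_with_header(format_differentiation(diff),
                        file.path(config$out_dir, "differentiation.tsv"), hdr)

  tree <- stage("tree", bootstrap_support(filtered, n_reps = config$bootstrap_n,
                                          seed = config$seed))
  write_newick(tree, file.path(config$out_dir, "tree.nwk"))

  outputs <- c("filter_log.tsv", "diversity_table.tsv", "differentiation.tsv",
               "tree.nwk")

  if (!is.null(config$gene_calls)) {
    calls <- stage("genes", utils::read.csv(config$gene_calls,
                                            colClasses = "character"))
    freqs <- stage("genes", allele_frequency_table(
      tibble::as_tibble(calls), groups))
    write_tsv_with_header(freqs,
                          file.path(config$out_dir, "gene_frequencies.tsv"), hdr)
    outputs <- c(outputs, "gene_frequencies.tsv")
    if (!is.null(config$band_observations) && !is.null(config$gene_panel)) {
      panel <- stage("genes", utils::read.delim(config$gene_panel))
      obs <- stage("genes", utils::read.csv(config$band_observations))
      flags <- stage("genes", flag_novel_bands(tibble::as_tibble(obs),
                                               tibble::as_tibble(panel)))
      write_tsv_with_header(flags,
                            file.path(config$out_dir, "band_novelty.tsv"), hdr)
      outputs <- c(outputs, "band_novelty.tsv")
    }
  }

  inputs <- c(genotype = config$genotype, map = config$map,
              groups = config$groups)
  manifest <- list(
    package = "gbsdiv",
    version = as.character(utils::packageVersion("gbsdiv")),
    seed = config$seed,
    thresholds = config[c("max_missing", "min_maf", "min_call_rate",
                          "min_reproducibility")],
    bootstrap_n = config$bootstrap_n,
    inputs = as.list(tools::md5sum(inputs)),
    n_accessions = nrow(geno),
    n_markers_in = ncol(geno),
    n_markers_kept = ncol(filtered),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_tsv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_differentiation <- function(diff) {
  diff |>
    dplyr::mutate(dplyr::across(c("Ht", "Hs", "Gst"), ~ round(.x, 3)),
                  Nm = round(.data$Nm, 3))
}
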