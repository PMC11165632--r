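# End-to-end orchestration from a single structured config: simulate ->
# geochem -> matrix/pan -> modules -> BiNI -> network, with a
# machine-readable JSON report. Identical config + seed gives an identical
# report.

RUN_CONFIG_KEYS <- c("seed", "out_dir", "stages", "thresholds", "synthetic")
RUN_STAGE_KEYS <- c("geochem", "pan", "modules", "bini", "network")
RUN_THRESHOLD_KEYS <- c("twofold_ratio", "bini_threshold", "fragment_tol",
                        "precursor_tol", "cosine_min", "matched_min",
                        "min_cluster_size", "library_cosine_min")

#' Default pipeline run configuration
#'
#' @param seed integer seed; fans out to fixed per-stage offsets so each
#'   generator is also reproducible standalone.
#' @param out_dir output directory for stage files and the JSON report.
#' @param stages named logical toggles (`geochem`, `pan`, `modules`,
#'   `bini`, `network`); every stage defaults to on.
#' @param thresholds named list of analysis thresholds; unknown keys are
#'   rejected.
#' @param synthetic extra arguments for [synthetic_config()].
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("orepan_run_"),
                       stages = list(), thresholds = list(),
                       synthetic = list()) {
  defaults_st <- stats::setNames(as.list(rep(TRUE, length(RUN_STAGE_KEYS))),
                                 RUN_STAGE_KEYS)
  defaults_th <- list(twofold_ratio = 2, bini_threshold = 900,
                      fragment_tol = 0.03, precursor_tol = 0.03,
                      cosine_min = 0.65, matched_min = 4,
                      min_cluster_size = 3, library_cosine_min = 0.5)
  unknown <- setdiff(names(stages), RUN_STAGE_KEYS)
  if (length(unknown)) {
    stop_("unknown stage toggle(s): %s", paste(unknown, collapse = ", "))
  }
  unknown <- setdiff(names(thresholds), RUN_THRESHOLD_KEYS)
  if (length(unknown)) {
    stop_("unknown threshold key(s): %s", paste(unknown, collapse = ", "))
  }
  th <- utils::modifyList(defaults_th, thresholds)
  if (any(unlist(th[c("twofold_ratio", "bini_threshold", "fragment_tol",
                      "precursor_tol", "cosine_min", "matched_min",
                      "min_cluster_size", "library_cosine_min")]) <= 0)) {
    stop_("thresholds must be positive")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = utils::modifyList(defaults_st, stages),
                 thresholds = th, synthetic = synthetic),
            class = "run_config")
}

#' Read a pipeline config from YAML
#'
#' Unknown top-level keys are rejected before any stage runs.
#'
#' @param path YAML file with any of: `seed`, `out_dir`, `stages`,
#'   `thresholds`, `synthetic`.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop_("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

run_stage <- function(report, name, out_dir, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    writeLines(sprintf("stage %s: %s", name, conditionMessage(res)),
               file.path(out_dir, "FAILED"))
    stop_("stage '%s' failed: %s", name, conditionMessage(res))
  }
  report$stages[[name]] <- res
  report
}

#' Run the full pipeline on synthetic inputs
#'
#' Generates every input with [write_synthetic()], then executes the
#' enabled stages in dependency order and writes `report.json` into the
#' output directory. The report echoes the parameters, carries md5
#' checksums of the generated input files, and summarizes each stage
#' (fold enrichments, pan fractions and unique-KO counts, module screen,
#' BiNI ranking, network component count and library match fraction).
#'
#' @param config a `run_config`, a path to a YAML config, or a plain list
#'   of [run_config()] arguments.
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  th <- config$thresholds
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  scfg <- do.call(synthetic_config,
                  c(list(seed = config$seed), config$synthetic))

  inputs <- file.path(out_dir, "inputs")
  files <- write_synthetic(scfg, inputs)
  report <- list(parameters = list(seed = config$seed,
                                   thresholds = th,
                                   stages = config$stages),
                 input_checksums = stats::setNames(
                   as.list(unname(tools::md5sum(unname(files)))),
                   names(files)),
                 stages = list())

  ko <- generate_ko_datasets(scfg)
  sp <- generate_spectra(scfg)
  bgc <- generate_bgc_tables(scfg)
  geo <- generate_geochem(scfg)

  if (isTRUE(config$stages$geochem)) {
    report <- run_stage(report, "geochem", out_dir, {
      tab <- fold_enrichment_table(geo$table, geo$reference)
      write_geochem(geo$table, file.path(out_dir, "geochem_folds.csv"))
      ext <- flag_extremes(geo$table)
      list(max_fold = max(tab$fold, na.rm = TRUE),
           n_censored = sum(tab$censored),
           highest_sites = stats::setNames(as.list(ext$highest_site),
                                           ext$analyte))
    })
  }

  matrix <- build_matrix(ko$annotations)
  matrix <- normalize_cpm(matrix)
  sets <- ko_presence_sets(matrix)[ko$datasets]
  partition <- pan_summary(sets)
  venn <- venn_partition(sets)

  if (isTRUE(config$stages$pan)) {
    report <- run_stage(report, "pan", out_dir, {
      write_matrix(matrix, file.path(out_dir, "taxon_ko_matrix.tsv"))
      write_pan(partition, venn, out_dir)
      uniq <- vapply(partition$labels,
                     function(d) length(unique_kos(partition, d)),
                     integer(1))
      list(n_orthologues = nrow(partition$table),
           fractions = stats::setNames(as.list(partition$summary$fraction),
                                       partition$summary$class),
           unique_kos = as.list(uniq))
    })
  }

  if (isTRUE(config$stages$modules)) {
    report <- run_stage(report, "modules", out_dir, {
      map <- generate_module_map(names(ko$truth$ko_class),
                                 seed = config$seed)
      ab <- aggregate_by_module(matrix, map, weight = "cpm")
      screen <- module_twofold(ab, "PMT_Actinomycetota",
                               "Topaz_Actinomycetota",
                               ratio = th$twofold_ratio)
      excl <- exclusive_pathway_proportions(
        partition, map,
        c(PMT = "PMT_Actinomycetota", Topaz = "Topaz_Actinomycetota"))
      utils::write.table(ab$modules,
                         file.path(out_dir, "module_abundance.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(n_modules = length(unique(ab$modules$module)),
           n_flagged_twofold = sum(screen$status == "flagged"),
           n_exclusive_pathways = length(unique(excl$pathway)))
    })
  }

  if (isTRUE(config$stages$bini)) {
    report <- run_stage(report, "bini", out_dir, {
      scores <- rank_strains(bini_score(bgc$table,
                                        threshold = th$bini_threshold))
      utils::write.table(scores, file.path(out_dir, "bini_scores.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(top_strain = scores$strain[1],
           top_score = scores$score[1],
           scores = stats::setNames(as.list(scores$score), scores$strain))
    })
  }

  if (isTRUE(config$stages$network)) {
    report <- run_stage(report, "network", out_dir, {
      nodes <- cluster_spectra(sp$spectra,
                               precursor_tol = th$precursor_tol,
                               cosine_min = th$cosine_min,
                               fragment_tol = th$fragment_tol,
                               min_cluster_size = th$min_cluster_size)
      net <- build_network(nodes, tol = th$fragment_tol,
                           cosine_min = th$cosine_min,
                           matched_min = th$matched_min)
      write_network(net, out_dir)
      # library: the first replicate of every other compound, so half the
      # planted compounds have a reference spectrum
      first_rep <- sp$spectra[!duplicated(sp$truth$compound)]
      lib <- first_rep[seq_along(first_rep) %% 2 == 1]
      lm <- library_match(net, lib, cosine_min = th$library_cosine_min,
                          matched_min = th$matched_min,
                          tol = th$fragment_tol)
      list(n_nodes = length(nodes),
           n_edges = nrow(net$edges),
           n_components = length(unique(net$membership$component)),
           n_discarded_clusters = attr(nodes, "n_discarded"),
           library_matched_fraction = attr(lm, "matched_fraction"))
    })
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  class(report) <- "orepan_report"
  invisible(report)
}
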