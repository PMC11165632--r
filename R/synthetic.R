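# Synthetic inputs with planted ground truth for every pipeline stage:
# four taxon-KO count datasets with a configurable core/softcore/shell/cloud
# composition, MS/MS spectrum collections with planted compound families,
# per-strain BGC tables with known distance sums, and geochemistry tables
# with known fold factors. Each generator seeds the RNG from the config
# seed plus a fixed per-generator offset, so stages are reproducible both
# inside the pipeline and standalone.

SYNTH_DATASETS <- c("PMT_Actinomycetota", "PMT_Bacteria",
                    "Topaz_Actinomycetota", "Topaz_Bacteria")

#' Configuration for the synthetic-data generators
#'
#' Defaults are the desk-scale study conditions exercised by the test
#' suite: 400 orthologues split evenly over the four pan classes, six
#' strains, three planted compound families with four replicate spectra per
#' compound, zero m/z noise, and the enrichment multipliers observed for
#' the most inhospitable site (chloride 16.8x, sulphate 15.1x, nitrate
#' 4.5x over crustal reference values).
#'
#' @param seed integer RNG seed.
#' @param n_kos number of distinct KO identifiers.
#' @param target_fractions named fractions for core/softcore/shell/cloud;
#'   must be non-negative and sum to 1 within 1e-9.
#' @param mean_count,dispersion negative-binomial count model for present
#'   (dataset, KO) cells: counts are `1 + rnbinom(mu = mean_count - 1,
#'   size = dispersion)`, strictly positive and over-dispersed.
#' @param reads_per_dataset nominal mapped-read total per dataset (used as
#'   an explicit normalization total where one is wanted).
#' @param n_strains number of strains for BGC tables and spectra.
#' @param n_compound_families,compounds_per_family,replicates_per_compound
#'   layout of the planted spectral families.
#' @param peaks_per_spectrum integer range (lower, upper) of peaks per
#'   compound spectrum; the lower bound must be at least 4 or planted
#'   families would be undetectable at the 4-matched-ion threshold.
#' @param mz_noise_sd Gaussian m/z noise per replicate peak, in Da (>= 0).
#' @param bgc_per_strain integer range of clusters per strain.
#' @param distance_range range of gene-cluster-family distances.
#' @param geochem_folds named positive fold factors (analyte -> fold) for
#'   the enriched synthetic site.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_kos = 400L,
                             target_fractions = c(core = 0.25,
                                                  softcore = 0.25,
                                                  shell = 0.25,
                                                  cloud = 0.25),
                             mean_count = 20,
                             dispersion = 2,
                             reads_per_dataset = 100000L,
                             n_strains = 6L,
                             n_compound_families = 3L,
                             compounds_per_family = 3L,
                             replicates_per_compound = 4L,
                             peaks_per_spectrum = c(8L, 12L),
                             mz_noise_sd = 0,
                             bgc_per_strain = c(6L, 42L),
                             distance_range = c(600, 1400),
                             geochem_folds = c(chloride = 16.8,
                                               sulphate = 15.1,
                                               nitrate = 4.5,
                                               fluoride = 0.1)) {
  cfg <- list(seed = as.integer(seed), n_kos = as.integer(n_kos),
              target_fractions = target_fractions,
              mean_count = mean_count, dispersion = dispersion,
              reads_per_dataset = as.integer(reads_per_dataset),
              n_strains = as.integer(n_strains),
              n_compound_families = as.integer(n_compound_families),
              compounds_per_family = as.integer(compounds_per_family),
              replicates_per_compound = as.integer(replicates_per_compound),
              peaks_per_spectrum = as.integer(peaks_per_spectrum),
              mz_noise_sd = mz_noise_sd,
              bgc_per_strain = as.integer(bgc_per_strain),
              distance_range = distance_range,
              geochem_folds = geochem_folds)
  tf <- cfg$target_fractions
  if (!setequal(names(tf), PAN_CLASSES)) {
    stop_("target_fractions must be named core/softcore/shell/cloud")
  }
  if (any(tf < 0) || abs(sum(tf) - 1) > 1e-9) {
    stop_("target_fractions must be non-negative and sum to 1")
  }
  counts <- c(cfg$n_kos, cfg$reads_per_dataset, cfg$n_strains,
              cfg$n_compound_families, cfg$compounds_per_family,
              cfg$replicates_per_compound, cfg$peaks_per_spectrum,
              cfg$bgc_per_strain)
  if (any(counts <= 0)) stop_("all counts must be strictly positive")
  if (cfg$mz_noise_sd < 0) stop_("mz_noise_sd must be >= 0")
  if (cfg$mean_count <= 1 || cfg$dispersion <= 0) {
    stop_("mean_count must exceed 1 and dispersion must be positive")
  }
  if (any(cfg$distance_range < 0) ||
      cfg$distance_range[1] > cfg$distance_range[2]) {
    stop_("distance_range must be an ordered pair of non-negative reals")
  }
  if (any(cfg$geochem_folds <= 0)) stop_("geochem_folds must be positive")
  structure(cfg, class = "synthetic_config")
}

as_synthetic_config <- function(config) {
  if (inherits(config, "synthetic_config")) return(config)
  do.call(synthetic_config, config)
}

plant_classes <- function(n_kos, target_fractions) {
  tf <- target_fractions[PAN_CLASSES]
  raw <- n_kos * tf
  short <- names(tf)[tf > 0 & raw < 1]
  if (length(short)) {
    stop_("class(es) %s: n_kos x fraction < 1, no KO can be assigned",
          paste(short, collapse = ", "))
  }
  base <- floor(raw)
  need <- n_kos - sum(base)
  if (need > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  rep(PAN_CLASSES, times = base)
}

#' Generate the four taxon-KO count datasets with planted pan classes
#'
#' Each KO is assigned a pan class according to the target fractions
#' (largest-remainder rounding keeps realized fractions within 1/n_kos of
#' the targets), then a uniformly random presence mask with the matching
#' popcount; present cells receive strictly positive over-dispersed
#' negative-binomial counts. Annotation tables (one query row per count,
#' eggNOG-mapper dialect) are emitted alongside the count matrix so the
#' full ingest path can be exercised; a small number of rows from excluded
#' ("Other") organisms is included.
#'
#' @param config a `synthetic_config` (or argument list for one).
#' @return list with `counts` (long data.frame `dataset`, `ko`, `count`),
#'   `annotations` (data.frame `query`, `KEGG_ko`, `taxon_group`,
#'   `environment`), `datasets` (the four labels), and `truth` (list with
#'   `ko_class`, a named character vector KO -> planted class, and
#'   `ko_mask`).
#' @export
generate_ko_datasets <- function(config) {
  config <- as_synthetic_config(config)
  set.seed(config$seed + 101L)
  n <- config$n_kos
  classes <- plant_classes(n, config$target_fractions)
  kos <- sprintf("K%05d", sample.int(99999L, n))
  pop <- c(core = 4L, softcore = 3L, shell = 2L, cloud = 1L)[classes]
  combos <- lapply(1:4, function(k) utils::combn(4L, k))
  mask <- matrix(FALSE, n, 4, dimnames = list(kos, SYNTH_DATASETS))
  for (r in seq_len(n)) {
    ch <- combos[[pop[r]]]
    mask[r, ch[, sample.int(ncol(ch), 1L)]] <- TRUE
  }
  cells <- which(mask, arr.ind = TRUE)
  counts <- data.frame(dataset = SYNTH_DATASETS[cells[, 2]],
                       ko = kos[cells[, 1]],
                       count = 1L + stats::rnbinom(nrow(cells),
                                                   mu = config$mean_count - 1,
                                                   size = config$dispersion),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$dataset, counts$ko), , drop = FALSE]
  rownames(counts) <- NULL
  ann <- do.call(rbind, lapply(SYNTH_DATASETS, function(d) {
    sub <- counts[counts$dataset == d, , drop = FALSE]
    total <- sum(sub$count)
    env <- sub("_.*$", "", d)
    grp <- sub("^[^_]*_", "", d)
    main <- data.frame(query = sprintf("%s_q%06d", d, seq_len(total)),
                       KEGG_ko = paste0("ko:", rep(sub$ko, sub$count)),
                       taxon_group = grp, environment = env,
                       stringsAsFactors = FALSE)
    n_other <- max(1L, round(total * 0.02))
    other <- data.frame(query = sprintf("%s_other%04d", d,
                                        seq_len(n_other)),
                        KEGG_ko = paste0("ko:K",
                                         sprintf("%05d",
                                                 sample.int(99999L,
                                                            n_other))),
                        taxon_group = "Other", environment = env,
                        stringsAsFactors = FALSE)
    rbind(main, other)
  }))
  rownames(ann) <- NULL
  truth <- list(ko_class = stats::setNames(classes, kos),
                ko_mask = mask)
  list(counts = counts, annotations = ann, datasets = SYNTH_DATASETS,
       truth = truth)
}

#' Generate MS/MS spectrum collections with planted compound families
#'
#' Each family owns a block of fragment m/z values on a 0.1 Da grid inside
#' a family-specific window; compounds of a family share the family's core
#' fragments (>= 4, high intensity) plus low-intensity compound-specific
#' peaks, so within-family consensus pairs exceed the 0.65 cosine / 4
#' matched-ion edge thresholds while cross-family pairs share no fragment.
#' Family windows are separated by more than the largest possible precursor
#' mass difference, so precursor-shifted matching cannot cross families
#' either: at zero noise, network components recover the planted families
#' for any seed, by construction. Replicate spectra per compound make the
#' minimum-cluster-size filter survivable.
#'
#' @param config a `synthetic_config`.
#' @return list with `spectra` (list of `ms_spectrum`) and `truth` (list:
#'   `compound_family` and `compound`, named by spectrum id; `strain`,
#'   named by compound id).
#' @export
generate_spectra <- function(config) {
  config <- as_synthetic_config(config)
  if (config$peaks_per_spectrum[1] < 4) {
    stop_(paste("peaks_per_spectrum lower bound < 4 would make planted",
                "families undetectable at the 4-matched-ion threshold"))
  }
  set.seed(config$seed + 202L)
  nf <- config$n_compound_families
  cpf <- config$compounds_per_family
  reps <- config$replicates_per_compound
  lo <- config$peaks_per_spectrum[1]
  hi <- config$peaks_per_spectrum[2]
  core_size <- max(4L, min(6L, lo))
  n_compounds <- nf * cpf
  window_width <- 60
  gap <- 10 * n_compounds + 100
  prec_base <- 150 + nf * (window_width + gap) + 200
  strains <- sprintf("strain%02d", rep_len(seq_len(config$n_strains),
                                           n_compounds))
  spectra <- list()
  fam_of <- character(0)
  cmp_of <- character(0)
  strain_of_cmp <- character(0)
  for (f in seq_len(nf)) {
    grid <- seq(150 + (f - 1) * (window_width + gap),
                by = 0.1, length.out = window_width * 10)
    grid <- round(grid, 1)
    core_mz <- sample(grid, core_size)
    pool <- setdiff(grid, core_mz)
    for (ci in seq_len(cpf)) {
      g <- (f - 1) * cpf + ci
      cmp_id <- sprintf("F%02dC%02d", f, ci)
      n_peaks <- if (hi > lo) sample(lo:hi, 1L) else lo
      n_unique <- n_peaks - core_size
      uniq_mz <- if (n_unique > 0) sample(pool, n_unique) else numeric(0)
      pool <- setdiff(pool, uniq_mz)
      mz <- c(core_mz, uniq_mz)
      intensity <- c(stats::runif(core_size, 80, 100),
                     stats::runif(n_unique, 1, 5))
      precursor <- prec_base + 10 * g
      strain_of_cmp[cmp_id] <- strains[g]
      for (r in seq_len(reps)) {
        sid <- sprintf("%sR%02d", cmp_id, r)
        noisy_mz <- mz + stats::rnorm(length(mz), 0, config$mz_noise_sd)
        spectra[[length(spectra) + 1L]] <-
          ms_spectrum(id = sid, pepmass = precursor, mz = noisy_mz,
                   intensity = intensity, strain = strains[g])
        fam_of[sid] <- sprintf("F%02d", f)
        cmp_of[sid] <- cmp_id
      }
    }
  }
  list(spectra = spectra,
       truth = list(compound_family = fam_of, compound = cmp_of,
                    strain = strain_of_cmp))
}

#' Generate per-strain BGC tables with known distance sums
#'
#' @param config a `synthetic_config`.
#' @return list with `table` (data.frame `strain`, `region`, `type`,
#'   `distance`) and `truth` (list with `strain_bini`, named numeric:
#'   strain -> sum(d)/n of its generated table).
#' @export
generate_bgc_tables <- function(config) {
  config <- as_synthetic_config(config)
  set.seed(config$seed + 303L)
  strains <- sprintf("strain%02d", seq_len(config$n_strains))
  types <- c("NRPS", "T1PKS", "T2PKS", "T3PKS", "terpene", "RiPP",
             "siderophore", "betalactone", "other")
  lo <- config$bgc_per_strain[1]
  hi <- config$bgc_per_strain[2]
  rows <- lapply(strains, function(s) {
    n <- if (hi > lo) sample(lo:hi, 1L) else lo
    data.frame(strain = s,
               region = sprintf("%s.region%03d", s, seq_len(n)),
               type = sample(types, n, replace = TRUE),
               distance = round(stats::runif(n, config$distance_range[1],
                                             config$distance_range[2]), 2),
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  bini <- tapply(table$distance, table$strain, function(d) sum(d) / length(d))
  list(table = table,
       truth = list(strain_bini = stats::setNames(as.numeric(bini),
                                                  names(bini))))
}

#' Generate a geochemistry table with known fold factors
#'
#' One enriched site carries the configured fold factors exactly
#' (`observed = reference x fold`); a background site sits near or below
#' the detection limits so the table always contains censored `"<limit"`
#' cells.
#'
#' @param config a `synthetic_config`.
#' @return list with `table` (long geochemistry data.frame), `reference`
#'   (named analyte vector), and `truth` (data.frame `site`, `analyte`,
#'   `fold`, `censored`).
#' @export
generate_geochem <- function(config) {
  config <- as_synthetic_config(config)
  reference <- c(chloride = 145, sulphate = 350, nitrate = 19,
                 fluoride = 585)
  limits <- c(chloride = 50, sulphate = 50, nitrate = 10, fluoride = 10)
  folds <- config$geochem_folds
  absent <- setdiff(names(folds), names(reference))
  if (length(absent)) {
    stop_("no reference value for analyte(s): %s",
          paste(absent, collapse = ", "))
  }
  background <- c(chloride = 0.2, sulphate = 0.1, nitrate = 0.4,
                  fluoride = 0.01)[names(folds)]
  site_folds <- list(Enriched = folds, Background = background)
  rows <- lapply(names(site_folds), function(site) {
    fl <- site_folds[[site]]
    obs <- reference[names(fl)] * fl
    cen <- obs < limits[names(fl)]
    data.frame(site = site, analyte = names(fl),
               value = ifelse(cen, limits[names(fl)], obs),
               censored = unname(cen), fold = unname(fl),
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  table <- long[c("site", "analyte", "value", "censored")]
  truth <- long[c("site", "analyte", "fold", "censored")]
  list(table = table, reference = reference[unique(table$analyte)],
       truth = truth)
}

#' Generate a KO -> pathway -> module mapping table
#'
#' Assigns each KO to one of `n_pathways` pathways, grouped into 13 pathway
#' modules and 2 signature modules, mirroring the usual KEGG organization
#' of desk-scale functional maps.
#'
#' @param kos character vector of KO identifiers.
#' @param seed RNG seed.
#' @param n_pathways number of pathway labels (default 48).
#' @return module map data.frame (`ko`, `pathway`, `module`).
#' @export
generate_module_map <- function(kos, seed = 1L, n_pathways = 48L) {
  set.seed(seed + 505L)
  modules <- c(sprintf("pathway_module_%02d", 1:13),
               "signature_module_01", "signature_module_02")
  pathways <- sprintf("pathway%02d", seq_len(n_pathways))
  path_module <- stats::setNames(sample(modules, n_pathways, replace = TRUE),
                                 pathways)
  pw <- sample(pathways, length(kos), replace = TRUE)
  data.frame(ko = kos, pathway = pw, module = unname(path_module[pw]),
             stringsAsFactors = FALSE)
}

#' Generate a Bracken-style taxonomy profile
#'
#' @param config a `synthetic_config`.
#' @param sample sample label.
#' @param n_taxa number of genera.
#' @return data.frame in the seven-column taxonomy-report layout plus
#'   `sample`.
#' @export
generate_taxon_profile <- function(config, sample = "PMT", n_taxa = 15L) {
  config <- as_synthetic_config(config)
  set.seed(config$seed + 606L + sum(utf8ToInt(sample)))
  w <- sort(stats::rexp(n_taxa), decreasing = TRUE)
  reads <- as.integer(round(w / sum(w) * config$reads_per_dataset))
  df <- data.frame(name = sprintf("genus_%02d", seq_len(n_taxa)),
                   taxonomy_id = 1000L + seq_len(n_taxa),
                   taxonomy_lvl = "G",
                   kraken_assigned_reads = pmax(0L, reads - 5L),
                   added_reads = pmin(reads, 5L),
                   new_est_reads = reads,
                   fraction_total_reads = reads / sum(reads),
                   stringsAsFactors = FALSE)
  df$sample <- sample
  df
}

#' Write every synthetic input in its on-disk exchange format
#'
#' Emits eggNOG-style annotation TSVs (one per dataset), the planted count
#' matrix, the module map, the MGF spectrum collection, the BGC TSV, the
#' geochemistry CSV with its reference table, taxonomy reports, and the
#' planted truth as JSON.
#'
#' @param config a `synthetic_config`.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_synthetic <- function(config, dir) {
  config <- as_synthetic_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ko <- generate_ko_datasets(config)
  sp <- generate_spectra(config)
  bgc <- generate_bgc_tables(config)
  geo <- generate_geochem(config)
  map <- generate_module_map(names(ko$truth$ko_class), seed = config$seed)
  files <- character(0)
  for (d in ko$datasets) {
    f <- file.path(dir, sprintf("%s.annotations.tsv", d))
    utils::write.table(ko$annotations[startsWith(ko$annotations$query,
                                                 paste0(d, "_")), ],
                       f, sep = "\t", row.names = FALSE, quote = FALSE)
    files[paste0("annotations_", d)] <- f
  }
  files["counts"] <- file.path(dir, "ko_counts.tsv")
  utils::write.table(ko$counts, files["counts"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files["module_map"] <- file.path(dir, "module_map.tsv")
  utils::write.table(map, files["module_map"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files["spectra"] <- file.path(dir, "spectra.mgf")
  write_mgf(sp$spectra, files["spectra"])
  files["bgc"] <- file.path(dir, "bgc.tsv")
  write_bgc_table(bgc$table, files["bgc"])
  files["geochem"] <- file.path(dir, "geochem.csv")
  write_geochem(geo$table, files["geochem"])
  files["reference"] <- file.path(dir, "geochem_reference.csv")
  utils::write.csv(data.frame(analyte = names(geo$reference),
                              value = as.numeric(geo$reference)),
                   files["reference"], row.names = FALSE, quote = FALSE)
  for (s in c("PMT", "Topaz")) {
    f <- file.path(dir, sprintf("%s.taxonomy.tsv", s))
    utils::write.table(generate_taxon_profile(config, s), f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files[paste0("taxonomy_", s)] <- f
  }
  files["truth"] <- file.path(dir, "planted_truth.json")
  truth <- list(ko_class = as.list(ko$truth$ko_class),
                compound_family = as.list(sp$truth$compound_family),
                strain_bini = as.list(bgc$truth$strain_bini),
                geochem_fold = geo$truth)
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(files)
}
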