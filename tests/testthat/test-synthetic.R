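test_that("configs validate their invariants", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(target_fractions = c(core = 0.5,
                                                     softcore = 0.2,
                                                     shell = 0.2,
                                                     cloud = 0.2)),
               "sum to 1")
  expect_error(synthetic_config(target_fractions = c(a = 1, b = 0, c = 0,
                                                     d = 0)),
               "named")
  expect_error(synthetic_config(n_kos = 0), "positive")
  expect_error(synthetic_config(mz_noise_sd = -1), ">= 0")
  expect_error(generate_spectra(synthetic_config(
    peaks_per_spectrum = c(3L, 6L))), "lower bound")
  expect_error(generate_ko_datasets(synthetic_config(
    n_kos = 10, target_fractions = c(core = 0.99, softcore = 0.01,
                                     shell = 0, cloud = 0))),
    "softcore")
})

test_that("generators are deterministic for a fixed seed", {
  cfg <- synthetic_config(seed = 42, n_kos = 60)
  expect_identical(generate_ko_datasets(cfg), generate_ko_datasets(cfg))
  expect_identical(generate_spectra(cfg), generate_spectra(cfg))
  expect_identical(generate_bgc_tables(cfg), generate_bgc_tables(cfg))
  expect_identical(generate_geochem(cfg), generate_geochem(cfg))

  # byte-identical files too
  d1 <- tempfile()
  d2 <- tempfile()
  f1 <- write_synthetic(cfg, d1)
  f2 <- write_synthetic(cfg, d2)
  expect_identical(unname(tools::md5sum(unname(f1))),
                   unname(tools::md5sum(unname(f2))))

  # a different seed changes the data
  other <- generate_ko_datasets(synthetic_config(seed = 43, n_kos = 60))
  expect_false(identical(other$counts,
                         generate_ko_datasets(cfg)$counts))
})

test_that("degenerate fractions put every KO everywhere", {
  cfg <- synthetic_config(seed = 1, n_kos = 25,
                          target_fractions = c(core = 1, softcore = 0,
                                               shell = 0, cloud = 0))
  sim <- generate_ko_datasets(cfg)
  expect_true(all(rowSums(sim$truth$ko_mask) == 4))
  per_ds <- table(sim$counts$dataset)
  expect_true(all(per_ds == 25))
  expect_true(all(sim$counts$count >= 1))
})

test_that("planted classes and realized fractions respect the targets", {
  cfg <- synthetic_config(seed = 8, n_kos = 400)
  sim <- generate_ko_datasets(cfg)
  expect_length(sim$truth$ko_class, 400)
  expect_false(anyDuplicated(names(sim$truth$ko_class)) > 0)
  realized <- table(factor(sim$truth$ko_class,
                           c("core", "softcore", "shell", "cloud"))) / 400
  expect_true(all(abs(realized - 0.25) < 1 / 400))
  # the realized presence pattern matches the planted class
  expect_equal(unname(rowSums(sim$truth$ko_mask)),
               unname(c(core = 4L, softcore = 3L, shell = 2L,
                        cloud = 1L)[sim$truth$ko_class]))
})

test_that("planted spectra share fragments within families only", {
  sim <- generate_spectra(synthetic_config(seed = 4, mz_noise_sd = 0))
  expect_length(sim$spectra, 3 * 3 * 4)
  expect_setequal(names(sim$truth$compound_family),
                  vapply(sim$spectra, `[[`, character(1), "id"))
  shared <- function(x, y) sum(round(x, 4) %in% round(y, 4))
  first_rep <- sim$spectra[!duplicated(sim$truth$compound)]
  fam <- sim$truth$compound_family[!duplicated(sim$truth$compound)]
  for (i in seq_along(first_rep)) {
    for (j in seq_len(i - 1)) {
      n <- shared(first_rep[[i]]$mz, first_rep[[j]]$mz)
      if (fam[i] == fam[j]) expect_gte(n, 4) else expect_lt(n, 4)
    }
  }
})

test_that("planted BiNI truths equal the score of the generated tables", {
  sim <- generate_bgc_tables(synthetic_config(seed = 12))
  scores <- bini_score(sim$table)
  expect_equal(stats::setNames(scores$score, scores$strain),
               sim$truth$strain_bini[scores$strain])
  expect_true(all(scores$n >= 6 & scores$n <= 42))
})

test_that("geochem observations are reference times planted fold", {
  sim <- generate_geochem(synthetic_config(seed = 2))
  unc <- !sim$table$censored
  expect_equal(sim$table$value[unc],
               unname(sim$reference[sim$table$analyte[unc]] *
                        sim$truth$fold[unc]))
  expect_gte(sum(sim$table$censored), 1)
  # censored cells survive the CSV dialect
  path <- tempfile(fileext = ".csv")
  write_geochem(sim$table, path)
  back <- read_geochem(path)
  key <- function(df) df[order(df$site, df$analyte), ]
  expect_equal(key(back)$value, key(sim$table)$value)
  expect_equal(key(back)$censored, key(sim$table)$censored)
})

test_that("module maps cover the requested KOs without duplicates", {
  kos <- sprintf("K%05d", 1:50)
  map <- generate_module_map(kos, seed = 3)
  expect_setequal(map$ko, kos)
  expect_false(anyDuplicated(map[c("ko", "pathway")]) > 0)
  expect_lte(length(unique(map$module)), 15)
})

test_that("synthetic taxonomy profiles are valid reports", {
  prof <- generate_taxon_profile(synthetic_config(seed = 6), "PMT")
  path <- tempfile(fileext = ".tsv")
  utils::write.table(prof, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_taxon_profile(path)
  expect_equal(nrow(back), nrow(prof))
  ra <- relative_abundance(back, "G")
  expect_equal(sum(ra$pct), 100)
})
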