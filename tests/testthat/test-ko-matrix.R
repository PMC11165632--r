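test_that("taxonomy reports parse, with format errors named", {
  path <- toy_bracken_file(bracken_rows(c("t1", "t2", "t3"),
                                        c(80L, 15L, 5L)))
  prof <- read_taxon_profile(path)
  expect_equal(nrow(prof), 3)
  expect_true(all(c("name", "new_est_reads", "sample") %in% names(prof)))

  bad <- bracken_rows(c("t1", "t2"), c(5L, 5L))
  bad$fraction_total_reads[2] <- 1.2
  expect_error(read_taxon_profile(toy_bracken_file(bad)), "\\[0, 1\\]")

  noc <- bracken_rows("t1", 10L)
  noc$new_est_reads <- NULL
  expect_error(read_taxon_profile(toy_bracken_file(noc)), "new_est_reads")

  empty <- tempfile()
  file.create(empty)
  expect_warning(prof0 <- read_taxon_profile(empty), "empty")
  expect_equal(nrow(prof0), 0)
})

test_that("matrix building counts queries per (dataset, KO)", {
  ann <- toy_annotations(sprintf("q%02d", 1:10), rep("ko:K00001", 10))
  mat <- build_matrix(ann)
  expect_equal(mat$raw, 10L)
  expect_equal(mat$ko, "K00001")
  expect_equal(mat$dataset, "PMT_Actinomycetota")
})

test_that("a query with m KO identifiers adds one count to each", {
  ann <- toy_annotations(c("q1", "q2"),
                         c("ko:K00001,ko:K00002", "ko:K00001"))
  mat <- build_matrix(ann)
  expect_equal(mat$raw[mat$ko == "K00001"], 2L)
  expect_equal(mat$raw[mat$ko == "K00002"], 1L)
  # conservation: total counts equal total KO multiplicities
  expect_equal(sum(mat$raw), 3L)
})

test_that("excluded groups, duplicates, and malformed KOs are handled", {
  ann <- toy_annotations(c("q1", "q2"), c("ko:K00001", "ko:K00002"),
                         group = "Other")
  expect_warning(mat <- build_matrix(ann), "excluded")
  expect_equal(nrow(mat), 0)

  dup <- toy_annotations(c("q1", "q1"), c("ko:K00001", "ko:K00002"))
  expect_error(build_matrix(dup), "duplicate")

  bad <- toy_annotations("q1", "ko:K1")
  expect_error(build_matrix(bad), "malformed")

  # unannotated rows ("-") contribute nothing but are legal
  none <- toy_annotations(c("q1", "q2"), c("-", "ko:K00003"))
  expect_equal(sum(build_matrix(none)$raw), 1L)
})

test_that("matrix building conserves KO multiplicities on synthetic data", {
  sim <- generate_ko_datasets(synthetic_config(seed = 11, n_kos = 50))
  mat <- build_matrix(sim$annotations)
  kept <- sim$annotations[sim$annotations$taxon_group != "Other", ]
  expect_equal(sum(mat$raw), nrow(kept))
  # raw counts agree with the planted count table
  merged <- merge(as.data.frame(mat), sim$counts, by = c("dataset", "ko"))
  expect_equal(merged$raw, merged$count)
})

test_that("CPM normalization follows raw * 1e6 / total", {
  mat <- new_taxon_ko_matrix(
    data.frame(dataset = "d1", ko = c("K00001", "K00002"), raw = c(5L, 5L)))
  out <- normalize_cpm(mat, c(d1 = 10))
  expect_equal(out$cpm, c(5e5, 5e5))
  one <- new_taxon_ko_matrix(
    data.frame(dataset = "d1", ko = "K00001", raw = 3L))
  expect_equal(normalize_cpm(one, c(d1 = 3))$cpm, 1e6)
})

test_that("CPM is invariant under joint scaling and errors on zero totals", {
  mat <- new_taxon_ko_matrix(
    data.frame(dataset = "d1", ko = sprintf("K%05d", 1:4),
               raw = c(3L, 9L, 1L, 7L)))
  base <- normalize_cpm(mat, c(d1 = 20))
  scaled <- mat
  scaled$raw <- scaled$raw * 7L
  expect_equal(normalize_cpm(scaled, c(d1 = 140))$cpm, base$cpm)
  expect_error(normalize_cpm(mat, c(d1 = 0)), "0")
})

test_that("relative abundance pools sub-threshold and unknown taxa", {
  prof <- read_taxon_profile(toy_bracken_file(
    bracken_rows(c("t1", "t2", "t3"), c(80L, 15L, 5L))))
  ra <- relative_abundance(prof, "S")
  expect_equal(sort(ra$pct, decreasing = TRUE), c(80, 15, 5))
  expect_equal(sum(ra$pct), 100)

  prof2 <- read_taxon_profile(toy_bracken_file(
    bracken_rows(c("t1", "t2", "t3"), c(990L, 6L, 4L))))
  ra2 <- relative_abundance(prof2, "S")
  expect_equal(nrow(ra2), 2)
  expect_equal(ra2$pct[ra2$taxon == "<1%"], 1)

  # all taxa below threshold collapse into one 100 % bucket
  prof3 <- read_taxon_profile(toy_bracken_file(
    bracken_rows(sprintf("t%d", 1:200), rep(1L, 200))))
  ra3 <- relative_abundance(prof3, "S")
  expect_equal(nrow(ra3), 1)
  expect_equal(ra3$pct, 100)

  expect_error(relative_abundance(prof, "G"), "rank")
})

test_that("twofold screen is boundary-inclusive with an exclusivity policy", {
  scr <- twofold_screen(c(f1 = 2.0, f2 = 1.9, f3 = 0.5),
                        c(f1 = 1.0, f2 = 1.0, f4 = 3.0))
  expect_equal(scr$status[scr$feature == "f1"], "flagged")
  expect_equal(scr$higher[scr$feature == "f1"], "a")
  expect_equal(scr$status[scr$feature == "f2"], "not_flagged")
  expect_equal(scr$status[scr$feature == "f3"], "exclusive_a")
  expect_equal(scr$status[scr$feature == "f4"], "exclusive_b")
  expect_error(twofold_screen(c(f1 = -1), c(f1 = 1)), "non-negative")
})

test_that("twofold screen flags the same features in either direction", {
  set.seed(9)
  for (rep in 1:20) {
    a <- stats::setNames(stats::rexp(15), sprintf("f%02d", 1:15))
    b <- stats::setNames(stats::rexp(15), sprintf("f%02d", 3:17))
    ab <- twofold_screen(a, b)
    ba <- twofold_screen(b, a)
    expect_equal(ab$feature[ab$status == "flagged"],
                 ba$feature[ba$status == "flagged"])
    expect_equal(ab$feature[ab$status == "exclusive_a"],
                 ba$feature[ba$status == "exclusive_b"])
  }
})

test_that("matrix TSV round-trips", {
  sim <- generate_ko_datasets(synthetic_config(seed = 5, n_kos = 30))
  mat <- normalize_cpm(build_matrix(sim$annotations))
  path <- tempfile(fileext = ".tsv")
  write_matrix(mat, path)
  back <- read_matrix(path)
  expect_equal(back$raw, mat$raw)
  expect_equal(back$cpm, mat$cpm, tolerance = 1e-12)
})
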