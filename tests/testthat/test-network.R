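test_that("MGF files parse and round-trip", {
  sp <- list(toy_spec("s1", 500.5, c(100.1, 200.2, 300.3),
                      c(10, 20, 30), strain = "strainA"),
             toy_spec("s2", 410.25, c(150.15, 250.25), c(5.5, 6.6)))
  path <- tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "s1")
  expect_equal(back[[1]]$mz, sp[[1]]$mz, tolerance = 1e-4)
  expect_equal(back[[1]]$intensity, sp[[1]]$intensity, tolerance = 1e-3)
  expect_equal(back[[1]]$strain, "strainA")
  expect_equal(back[[2]]$pepmass, 410.25, tolerance = 1e-4)
})

test_that("unsorted peaks are sorted on load; missing PEPMASS errors", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=400.0", "CHARGE=1+",
               "300.0 1.0", "100.0 2.0", "200.0 3.0", "END IONS"), path)
  sp <- read_mgf(path)[[1]]
  expect_equal(sp$mz, c(100, 200, 300))
  expect_equal(sp$intensity, c(2, 3, 1))

  bad <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=y", "100.0 1.0", "END IONS"), bad)
  expect_error(read_mgf(bad), "block 1.*PEPMASS")
})

test_that("a spectrum against itself scores 1 with all peaks matched", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    mz <- sort(stats::runif(n, 100, 900))
    mz <- mz[c(TRUE, diff(mz) > 0.1)]  # keep peaks apart beyond tol
    s <- toy_spec("s", 950, mz, stats::runif(length(mz), 1, 100))
    mc <- modified_cosine(s, s)
    expect_equal(mc$score, 1.0)
    expect_equal(mc$matched, length(mz))
  }
})

test_that("disjoint spectra score zero and empty peak lists error", {
  a <- toy_spec("a", 500, c(100, 200, 300))
  b <- toy_spec("b", 500, c(101, 201, 301))
  expect_equal(modified_cosine(a, b), list(score = 0, matched = 0L))
  expect_error(modified_cosine(a, toy_spec("e", 500, numeric(0))), "empty")
})

test_that("precursor-shifted fragments match under the delta rule", {
  # b is a with every fragment (and the precursor) shifted by +14 Da
  a <- toy_spec("a", 500, c(100, 200, 300, 400), c(10, 40, 20, 5))
  b <- toy_spec("b", 514, c(114, 214, 314, 414), c(10, 40, 20, 5))
  mc <- modified_cosine(a, b)
  expect_equal(mc$score, 1.0)
  expect_equal(mc$matched, 4L)
})

test_that("the matcher attains the exhaustive one-to-one optimum", {
  set.seed(11)
  for (rep in 1:30) {
    pair <- random_spectrum_pair(8, shift = rep %% 2 == 0)
    got <- modified_cosine(pair$a, pair$b)
    expect_equal(got$score,
                 oracle_modified_cosine(pair$a, pair$b),
                 tolerance = 1e-9)
    expect_lte(got$matched, min(length(pair$a$mz), length(pair$b$mz)))
    expect_true(got$score >= 0 && got$score <= 1)
  }
})

test_that("the modified cosine is symmetric", {
  set.seed(19)
  for (rep in 1:20) {
    pair <- random_spectrum_pair(8, shift = TRUE)
    ab <- modified_cosine(pair$a, pair$b)
    ba <- modified_cosine(pair$b, pair$a)
    expect_equal(ab$score, ba$score, tolerance = 1e-9)
    expect_equal(ab$matched, ba$matched)
  }
})

test_that("identical replicates cluster to one consensus node", {
  reps <- lapply(1:5, function(i) {
    toy_spec(sprintf("r%d", i), 500, c(100, 200, 300), c(10, 20, 30))
  })
  nodes <- cluster_spectra(reps)
  expect_length(nodes, 1)
  expect_equal(nodes[[1]]$member_count, 5L)
  expect_equal(nodes[[1]]$mz, c(100, 200, 300))
  expect_equal(nodes[[1]]$intensity, c(10, 20, 30))
  expect_equal(attr(nodes, "n_discarded"), 0L)
})

test_that("clusters below the minimum size are discarded", {
  reps <- lapply(1:2, function(i) {
    toy_spec(sprintf("r%d", i), 500, c(100, 200, 300), c(10, 20, 30))
  })
  expect_message(nodes <- cluster_spectra(reps), "discarded")
  expect_length(nodes, 0)
  expect_equal(attr(nodes, "n_discarded"), 1L)
})

test_that("zero-noise planted families are recovered as components", {
  sim <- generate_spectra(synthetic_config(seed = 23, mz_noise_sd = 0))
  nodes <- cluster_spectra(sim$spectra)
  # one consensus node per planted compound
  expect_length(nodes, 9)
  net <- build_network(nodes)
  # components = planted families
  fam_of_node <- vapply(net$nodes, function(n) {
    unique(sim$truth$compound_family[n$members])
  }, character(1))
  comp_of_node <- net$membership$component[
    match(vapply(net$nodes, `[[`, character(1), "id"),
          net$membership$node)]
  expect_equal(length(unique(comp_of_node)), 3)
  # same family <=> same component: each family collapses to one component
  fam_comp <- split(comp_of_node, fam_of_node)
  expect_length(fam_comp, 3)
  expect_true(all(lengths(lapply(fam_comp, unique)) == 1))

  # impossible threshold leaves no edges
  empty <- build_network(nodes, cosine_min = 1.01)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(unique(empty$membership$component)), length(nodes))
  # undirected without duplicate pairs
  key <- apply(net$edges[c("node1", "node2")], 1,
               function(r) paste(sort(r), collapse = "|"))
  expect_false(any(duplicated(key)))
})

test_that("library matching finds planted references and nothing else", {
  a <- toy_spec("a", 500, c(100, 200, 300, 400), c(1, 2, 3, 4))
  b <- toy_spec("b", 640, c(111, 222, 333, 444), c(1, 2, 3, 4))
  lib <- list(toy_spec("ref_a", 500, c(100, 200, 300, 400), c(1, 2, 3, 4)))
  hits <- library_match(list(a, b), lib)
  expect_equal(hits$library_id, c("ref_a", NA))
  expect_equal(hits$cosine[1], 1.0)
  expect_equal(attr(hits, "matched_fraction"), 0.5)
  expect_error(library_match(list(a), list()), "empty")
})

test_that("half-covered planted compounds give a half match fraction", {
  # singleton families so no cross-compound library hit is possible
  cfg <- synthetic_config(seed = 29, n_compound_families = 4,
                          compounds_per_family = 1)
  sim <- generate_spectra(cfg)
  nodes <- cluster_spectra(sim$spectra)
  expect_length(nodes, 4)
  first_rep <- sim$spectra[!duplicated(sim$truth$compound)]
  lib <- first_rep[c(1, 3)]
  hits <- library_match(nodes, lib)
  expect_equal(attr(hits, "matched_fraction"), 0.5)
})

test_that("class composition reports per-strain percentages with no-match", {
  nodes <- list(toy_spec("a", 500, c(100, 200, 300, 400), strain = "s1"),
                toy_spec("b", 510, c(100, 200, 300, 400), strain = "s1"),
                toy_spec("c", 520, c(100, 200, 300, 400), strain = "s2"),
                toy_spec("d", 530, c(100, 200, 300, 400), strain = "s2"))
  comp <- class_composition(nodes,
                            c(a = "organic acids", b = "lipids"))
  overall <- comp[comp$strain == "overall", ]
  expect_equal(overall$pct[overall$superclass == "no match"], 50)
  expect_equal(sum(overall$pct), 100)
  s2 <- comp[comp$strain == "s2", ]
  expect_equal(s2$superclass, "no match")
  expect_equal(s2$pct, 100)
  expect_warning(class_composition(nodes, strains = c("s1", "ghost")),
                 "ghost")
  # unlabelled everywhere -> a single 100 % no-match category
  all_un <- class_composition(nodes)
  expect_true(all(all_un$superclass == "no match"))
})

test_that("network files are written", {
  sim <- generate_spectra(synthetic_config(seed = 23))
  nodes <- cluster_spectra(sim$spectra)
  net <- build_network(nodes)
  dir <- tempfile()
  files <- write_network(net, dir)
  expect_true(all(file.exists(files)))
  edges <- utils::read.delim(file.path(dir, "edges.tsv"))
  expect_equal(nrow(edges), nrow(net$edges))
})
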