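# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain enumeration so they stay independent of the implementation paths
# they check.

toy_spec <- function(id, pepmass, mz, intensity = rep(1, length(mz)),
                     ...) {
  ms_spectrum(id = id, pepmass = pepmass, mz = mz, intensity = intensity,
              ...)
}

# Random spectrum pair whose peaks are jittered draws from a shared base
# grid, so the 0.03 Da tolerance creates genuine (and occasionally
# ambiguous) candidate matches.
random_spectrum_pair <- function(n_max = 8, shift = FALSE) {
  base <- sort(stats::runif(8, 100, 500))
  na <- sample(3:n_max, 1)
  nb <- sample(3:n_max, 1)
  mza <- sample(base, na) + stats::runif(na, -0.012, 0.012)
  mzb <- sample(base, nb) + stats::runif(nb, -0.012, 0.012)
  pa <- stats::runif(1, 520, 600)
  pb <- if (shift) pa - sample(base, 1) + sample(base, 1) else pa
  list(a = toy_spec("a", pa, mza, stats::runif(na, 1, 100)),
       b = toy_spec("b", pb, mzb, stats::runif(nb, 1, 100)))
}

# Exhaustive maximum over all one-to-one peak matchings (no pruning):
# enumerate every conflict-free subset of candidate pairs.
oracle_modified_cosine <- function(a, b, tol = 0.03) {
  wa <- sqrt(a$intensity)
  wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$intensity)
  wb <- wb / sqrt(sum(wb^2))
  delta <- a$pepmass - b$pepmass
  cand <- list()
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      if (abs(a$mz[i] - b$mz[j]) <= tol ||
          abs(a$mz[i] - b$mz[j] - delta) <= tol) {
        cand[[length(cand) + 1]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  best <- 0
  n <- length(cand)
  rec <- function(k, used_a, used_b, s) {
    if (k > n) {
      best <<- max(best, s)
      return(invisible())
    }
    rec(k + 1, used_a, used_b, s)
    i <- cand[[k]][1]
    j <- cand[[k]][2]
    if (!(i %in% used_a) && !(j %in% used_b)) {
      rec(k + 1, c(used_a, i), c(used_b, j), s + cand[[k]][3])
    }
  }
  rec(1, integer(0), integer(0), 0)
  best
}

# Independent per-element tabulation of pan classes and Venn regions.
oracle_pan_counts <- function(ko_sets) {
  universe <- unique(unlist(ko_sets))
  pop <- vapply(universe, function(k) {
    sum(vapply(ko_sets, function(s) k %in% s, logical(1)))
  }, integer(1))
  c(core = sum(pop == 4), softcore = sum(pop == 3),
    shell = sum(pop == 2), cloud = sum(pop == 1))
}

oracle_venn_counts <- function(ko_sets) {
  labels <- names(ko_sets)
  universe <- unique(unlist(ko_sets))
  keys <- vapply(universe, function(k) {
    paste(labels[vapply(ko_sets, function(s) k %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(keys)
}

random_ko_sets <- function(n_kos = 100) {
  universe <- sprintf("K%05d", seq_len(n_kos))
  sets <- lapply(1:4, function(i) {
    universe[stats::runif(n_kos) < stats::runif(1, 0.2, 0.8)]
  })
  names(sets) <- c("A", "B", "C", "D")
  sets
}

toy_bracken_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

bracken_rows <- function(names, reads, lvl = "S") {
  data.frame(name = names, taxonomy_id = seq_along(names),
             taxonomy_lvl = lvl, kraken_assigned_reads = reads,
             added_reads = 0L, new_est_reads = reads,
             fraction_total_reads = reads / sum(reads),
             stringsAsFactors = FALSE)
}

toy_annotations <- function(query, ko, group = "Actinomycetota",
                            env = "PMT") {
  data.frame(query = query, KEGG_ko = ko, taxon_group = group,
             environment = env, stringsAsFactors = FALSE)
}
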