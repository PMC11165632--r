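# Desk-scale classical molecular networking: modified-cosine spectral
# similarity (fragment matches at zero shift or shifted by the precursor
# mass difference), greedy consensus clustering with a minimum cluster size,
# thresholded network construction, library matching, and per-strain
# chemical-class composition.

candidate_pairs <- function(a, b, tol) {
  delta <- a$pepmass - b$pepmass
  na <- length(a$mz)
  nb <- length(b$mz)
  d0 <- abs(outer(a$mz, b$mz, "-"))
  ds <- abs(outer(a$mz, b$mz, "-") - delta)
  ok <- d0 <= tol | ds <= tol
  which(ok, arr.ind = TRUE)
}

# Exact maximum-weight one-to-one matching over candidate peak pairs by
# branch-and-bound over pairs sorted by decreasing weight. Exact up to the
# stated spectrum size; pruning uses the suffix weight sum as an upper
# bound, so the returned score is the true optimum.
match_exact <- function(i, j, w, na, nb) {
  ord <- order(w, decreasing = TRUE)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  m <- length(w)
  suffix <- rev(cumsum(rev(w)))
  best <- 0
  best_n <- 0L
  used_a <- logical(na)
  used_b <- logical(nb)
  rec <- function(k, s, n) {
    if (s > best) {
      best <<- s
      best_n <<- n
    }
    if (k > m || s + suffix[k] <= best) return(invisible())
    if (!used_a[i[k]] && !used_b[j[k]]) {
      used_a[i[k]] <<- TRUE
      used_b[j[k]] <<- TRUE
      rec(k + 1L, s + w[k], n + 1L)
      used_a[i[k]] <<- FALSE
      used_b[j[k]] <<- FALSE
    }
    rec(k + 1L, s, n)
  }
  rec(1L, 0, 0L)
  list(score = best, matched = best_n)
}

match_greedy <- function(i, j, w, na, nb) {
  ord <- order(w, decreasing = TRUE)
  used_a <- logical(na)
  used_b <- logical(nb)
  s <- 0
  n <- 0L
  for (k in ord) {
    if (!used_a[i[k]] && !used_b[j[k]]) {
      used_a[i[k]] <- TRUE
      used_b[j[k]] <- TRUE
      s <- s + w[k]
      n <- n + 1L
    }
  }
  list(score = s, matched = n)
}

#' Modified cosine similarity between two spectra
#'
#' Peaks are matched when their m/z values agree within `tol`, directly or
#' after shifting one spectrum by the precursor mass difference; each peak
#' participates in at most one match regardless of shift class. Intensities
#' are square-root transformed and each spectrum's weight vector normalized
#' to unit length, so the score lies in \[0, 1\] and a spectrum against
#' itself scores exactly 1. The matching maximizes the score: exact
#' maximum-weight one-to-one matching is used whenever both spectra have at
#' most `exact_max` peaks, and greedy matching above that size.
#'
#' @param a,b `ms_spectrum` objects (non-empty peak lists).
#' @param tol fragment mass tolerance in Da (default 0.03).
#' @param exact_max exact-matching size cutoff (default 12 peaks).
#' @param intensity_transform `"sqrt"` (convention for networking) or
#'   `"linear"`.
#' @return list with `score` (in \[0, 1\]) and `matched` (number of matched
#'   fragment ions).
#' @export
modified_cosine <- function(a, b, tol = 0.03, exact_max = 12,
                            intensity_transform = c("sqrt", "linear")) {
  intensity_transform <- match.arg(intensity_transform)
  if (!length(a$mz) || !length(b$mz)) {
    stop_("modified cosine is undefined for an empty peak list")
  }
  tf <- if (intensity_transform == "sqrt") sqrt else identity
  wa <- tf(a$intensity)
  wb <- tf(b$intensity)
  norm_a <- sqrt(sum(wa^2))
  norm_b <- sqrt(sum(wb^2))
  if (norm_a == 0 || norm_b == 0) {
    stop_("modified cosine is undefined for all-zero intensities")
  }
  wa <- wa / norm_a
  wb <- wb / norm_b
  pairs <- candidate_pairs(a, b, tol)
  if (!nrow(pairs)) return(list(score = 0, matched = 0L))
  i <- pairs[, 1]
  j <- pairs[, 2]
  w <- wa[i] * wb[j]
  res <- if (length(a$mz) <= exact_max && length(b$mz) <= exact_max) {
    match_exact(i, j, w, length(a$mz), length(b$mz))
  } else {
    match_greedy(i, j, w, length(a$mz), length(b$mz))
  }
  res$score <- min(res$score, 1)
  res
}

merge_consensus <- function(members, tol, id) {
  mz <- unlist(lapply(members, `[[`, "mz"))
  intensity <- unlist(lapply(members, `[[`, "intensity"))
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  grp <- cumsum(c(1, diff(mz) > tol))
  cmz <- as.numeric(tapply(mz * intensity, grp, sum) /
                      tapply(intensity, grp, sum))
  flat <- which(tapply(intensity, grp, sum) == 0)
  if (length(flat)) {
    cmz[flat] <- as.numeric(tapply(mz, grp, mean))[flat]
  }
  cint <- as.numeric(tapply(intensity, grp, sum)) / length(members)
  tic <- vapply(members, function(s) sum(s$intensity), numeric(1))
  pep <- sum(vapply(members, `[[`, numeric(1), "pepmass") * (tic + 1)) /
    sum(tic + 1)
  ms_spectrum(id = id, pepmass = pep,
           mz = cmz, intensity = cint,
           charge = members[[1]]$charge,
           strain = unique(stats::na.omit(unlist(lapply(members, `[[`,
                                                        "strain")))),
           members = unlist(lapply(members, `[[`, "members")),
           member_count = sum(vapply(members, `[[`, integer(1),
                                     "member_count")))
}

#' Greedy consensus clustering of near-identical spectra
#'
#' Seeds with the most intense unassigned spectrum (by total ion current),
#' absorbs every unassigned spectrum within `precursor_tol` of the seed
#' precursor whose modified cosine against the seed reaches `cosine_min`,
#' and iterates. Consensus peaks are the intensity-weighted merge of the
#' member peaks. Clusters with fewer members than `min_cluster_size` are
#' discarded (their number is reported in attribute `"n_discarded"`).
#'
#' @param spectra list of `ms_spectrum` objects.
#' @param precursor_tol precursor m/z window in Da (default 0.03).
#' @param cosine_min minimum cosine to join a cluster (default 0.65).
#' @param fragment_tol fragment tolerance used inside the cosine and the
#'   peak merge (default 0.03 Da).
#' @param min_cluster_size minimum member count a consensus spectrum needs
#'   to survive (default 3).
#' @return list of consensus `ms_spectrum` objects with `member_count` and
#'   `members` filled in; attribute `"n_discarded"` counts dropped clusters.
#' @export
cluster_spectra <- function(spectra, precursor_tol = 0.03,
                            cosine_min = 0.65, fragment_tol = 0.03,
                            min_cluster_size = 3) {
  if (!length(spectra)) stop_("no spectra to cluster")
  tic <- vapply(spectra, function(s) sum(s$intensity), numeric(1))
  pep <- vapply(spectra, `[[`, numeric(1), "pepmass")
  unassigned <- seq_along(spectra)
  nodes <- list()
  n_discarded <- 0L
  k <- 0L
  while (length(unassigned)) {
    seed <- unassigned[which.max(tic[unassigned])]
    cand <- unassigned[abs(pep[unassigned] - pep[seed]) <= precursor_tol]
    take <- vapply(cand, function(c) {
      c == seed ||
        modified_cosine(spectra[[seed]], spectra[[c]],
                        tol = fragment_tol)$score >= cosine_min
    }, logical(1))
    mem <- cand[take]
    if (length(mem) >= min_cluster_size) {
      k <- k + 1L
      nodes[[length(nodes) + 1L]] <-
        merge_consensus(spectra[mem], fragment_tol,
                        id = sprintf("node%03d_%s", k, spectra[[seed]]$id))
    } else {
      n_discarded <- n_discarded + 1L
    }
    unassigned <- setdiff(unassigned, mem)
  }
  if (n_discarded) {
    message(sprintf("discarded %d cluster(s) below the minimum size",
                    n_discarded))
  }
  structure(nodes, n_discarded = n_discarded)
}

#' Build a molecular network from consensus spectra
#'
#' Edges connect node pairs whose modified cosine reaches `cosine_min` with
#' at least `matched_min` matched fragment ions; the graph is undirected
#' with no self-edges, and connected components (singletons included) are
#' enumerated.
#'
#' @param nodes list of consensus `ms_spectrum` objects.
#' @param tol fragment mass tolerance in Da (default 0.03).
#' @param cosine_min edge cosine threshold (default 0.65).
#' @param matched_min minimum matched fragment ions per edge (default 4).
#' @return object of class `spectral_network`: `nodes`, `edges`
#'   (data.frame `node1`, `node2`, `cosine`, `matched`), and `membership`
#'   (data.frame `node`, `component`).
#' @export
build_network <- function(nodes, tol = 0.03, cosine_min = 0.65,
                          matched_min = 4) {
  if (!length(nodes)) stop_("network needs at least one node")
  ids <- vapply(nodes, `[[`, character(1), "id")
  edges <- data.frame(node1 = character(0), node2 = character(0),
                      cosine = numeric(0), matched = integer(0),
                      stringsAsFactors = FALSE)
  if (length(nodes) >= 2) {
    pairs <- utils::combn(length(nodes), 2)
    rows <- lapply(seq_len(ncol(pairs)), function(p) {
      u <- pairs[1, p]
      v <- pairs[2, p]
      mc <- modified_cosine(nodes[[u]], nodes[[v]], tol = tol)
      if (mc$score >= cosine_min && mc$matched >= matched_min) {
        data.frame(node1 = ids[u], node2 = ids[v], cosine = mc$score,
                   matched = mc$matched, stringsAsFactors = FALSE)
      }
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  structure(list(nodes = nodes, edges = edges,
                 membership = data.frame(node = names(comp),
                                         component = as.integer(comp),
                                         stringsAsFactors = FALSE)),
            class = "spectral_network")
}

#' @export
print.spectral_network <- function(x, ...) {
  cat(sprintf("<spectral_network> %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), nrow(x$edges),
              length(unique(x$membership$component))))
  invisible(x)
}

#' Match network nodes against a spectral library
#'
#' For each node, the best-scoring library spectrum passing both the cosine
#' and the matched-ion thresholds, or no match.
#'
#' @param nodes list of consensus `ms_spectrum` objects (or a
#'   `spectral_network`).
#' @param library non-empty list of library `ms_spectrum` objects.
#' @param cosine_min library cosine threshold (default 0.5).
#' @param matched_min minimum matched peaks (default 4).
#' @param tol fragment mass tolerance in Da (default 0.03).
#' @return data.frame (`node`, `library_id`, `cosine`, `matched`), `NA`
#'   where nothing passed; the fraction of matched nodes is in attribute
#'   `"matched_fraction"`.
#' @export
library_match <- function(nodes, library, cosine_min = 0.5,
                          matched_min = 4, tol = 0.03) {
  if (inherits(nodes, "spectral_network")) nodes <- nodes$nodes
  if (!length(library)) stop_("library is empty")
  rows <- lapply(nodes, function(nd) {
    best <- NULL
    for (ls in library) {
      mc <- modified_cosine(nd, ls, tol = tol)
      if (mc$score >= cosine_min && mc$matched >= matched_min &&
          (is.null(best) || mc$score > best$cosine)) {
        best <- data.frame(node = nd$id, library_id = ls$id,
                           cosine = mc$score, matched = mc$matched,
                           stringsAsFactors = FALSE)
      }
    }
    best %||% data.frame(node = nd$id, library_id = NA_character_,
                         cosine = NA_real_, matched = NA_integer_,
                         stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "matched_fraction") <- mean(!is.na(out$library_id))
  out
}

#' Per-strain chemical superclass composition of a network
#'
#' @param network a `spectral_network` (or a list of consensus spectra).
#' @param node_classes named character vector, node id -> superclass label;
#'   nodes without a label fall into the `"no match"` category.
#' @param strains strains to report (default: every strain seen on a node);
#'   a requested strain absent from the network draws a warning.
#' @return data.frame (`strain`, `superclass`, `count`, `pct`); the strain
#'   `"overall"` aggregates the whole network. Percentages per strain sum
#'   to 100.
#' @export
class_composition <- function(network, node_classes = character(0),
                              strains = NULL) {
  nodes <- if (inherits(network, "spectral_network")) network$nodes
           else network
  ids <- vapply(nodes, `[[`, character(1), "id")
  cls <- ifelse(ids %in% names(node_classes) &
                  !is.na(node_classes[ids]) & nzchar(node_classes[ids]),
                node_classes[ids], "no match")
  node_strains <- lapply(nodes, `[[`, "strain")
  seen <- sort(unique(stats::na.omit(unlist(node_strains))))
  strains <- strains %||% seen
  missing <- setdiff(strains, seen)
  if (length(missing)) {
    warn_("strain(s) absent from the network: %s",
          paste(missing, collapse = ", "))
  }
  one <- function(label, idx) {
    if (!length(idx)) return(NULL)
    counts <- table(cls[idx])
    data.frame(strain = label, superclass = names(counts),
               count = as.integer(counts),
               pct = as.numeric(counts) / length(idx) * 100,
               stringsAsFactors = FALSE)
  }
  rows <- c(list(one("overall", seq_along(nodes))),
            lapply(strains, function(st) {
              one(st, which(vapply(node_strains,
                                   function(ns) st %in% ns, logical(1))))
            }))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write a network as edge-list and node-table TSV (plus GraphML)
#'
#' @param network a `spectral_network`.
#' @param dir output directory.
#' @return files written, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "edges.tsv")
  utils::write.table(network$edges, f1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  node_tab <- data.frame(
    id = vapply(network$nodes, `[[`, character(1), "id"),
    strains = vapply(network$nodes,
                     function(n) paste(n$strain, collapse = ";"),
                     character(1)),
    members = vapply(network$nodes, `[[`, integer(1), "member_count"),
    precursor = vapply(network$nodes, `[[`, numeric(1), "pepmass"),
    stringsAsFactors = FALSE)
  node_tab$component <-
    network$membership$component[match(node_tab$id,
                                       network$membership$node)]
  f2 <- file.path(dir, "nodes.tsv")
  utils::write.table(node_tab, f2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = node_tab)
  f3 <- file.path(dir, "network.graphml")
  igraph::write_graph(g, f3, format = "graphml")
  invisible(c(f1, f2, f3))
}
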