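# Aggregation of the taxon-KO matrix into KEGG pathway / pathway-module
# relative abundances, twofold screening at module level, and the pathway
# breakdown of each environment's exclusive (dataset-unique) orthologues.

#' Read a KO -> pathway -> module mapping table
#'
#' @param path 3-column TSV (`ko`, `pathway`, `module`). Duplicate
#'   (KO, pathway) rows are rejected; a KO may map to several pathways.
#' @return data.frame with the three columns.
#' @export
read_module_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_module_map(map)
}

validate_module_map <- function(map) {
  assert_columns(map, c("ko", "pathway", "module"), "module map")
  if (!nrow(map)) stop_("module map is empty")
  dup <- map[duplicated(map[c("ko", "pathway")]), , drop = FALSE]
  if (nrow(dup)) {
    stop_("duplicate (KO, pathway) row(s) in module map: %s",
          paste(utils::head(paste(dup$ko, dup$pathway, sep = "/"), 5),
                collapse = ", "))
  }
  map
}

#' Aggregate a taxon-KO matrix into pathway / module relative abundances
#'
#' Per dataset, the value of a module is the summed weight of its member
#' KOs as a percentage of the dataset's total KO weight. A KO mapping to k
#' modules contributes its full weight to each of the k (flagged in the
#' `multi_module_kos` element, so fractional splitting can be applied
#' upstream if preferred); KOs absent from the map are pooled as
#' `"unmapped"`.
#'
#' @param matrix a `taxon_ko_matrix`; when `weight = "cpm"` and the matrix
#'   has no `cpm` column it is normalized with default totals first.
#' @param map module map (see [read_module_map()]).
#' @param weight `"cpm"` (abundance-weighted, the default) or `"presence"`
#'   (each present KO counts 1).
#' @return object of class `module_abundance`: data.frames `modules` and
#'   `pathways` (`dataset`, label, `weight`, `pct`) and the character
#'   vector `multi_module_kos`.
#' @export
aggregate_by_module <- function(matrix, map, weight = c("cpm", "presence")) {
  weight <- match.arg(weight)
  map <- validate_module_map(map)
  assert_columns(matrix, c("dataset", "ko", "raw"), "taxon-KO matrix")
  if (weight == "cpm" && is.null(matrix$cpm)) {
    matrix <- normalize_cpm(matrix)
  }
  present <- matrix[matrix$raw >= 1, , drop = FALSE]
  present$w <- if (weight == "cpm") present$cpm else 1
  unmapped <- setdiff(unique(present$ko), unique(map$ko))
  if (length(unmapped)) {
    warn_("%d KO(s) not covered by the module map (pooled as 'unmapped')",
          length(unmapped))
  }
  per_ko_modules <- tapply(map$module, map$ko,
                           function(m) length(unique(m)))
  multi <- names(per_ko_modules)[per_ko_modules > 1]

  aggregate_level <- function(level) {
    joined <- merge(present, map[c("ko", level)], by = "ko")
    un <- present[present$ko %in% unmapped, , drop = FALSE]
    if (nrow(un)) {
      un[[level]] <- "unmapped"
      joined <- rbind(joined[c("dataset", "ko", level, "w")],
                      un[c("dataset", "ko", level, "w")])
    } else {
      joined <- joined[c("dataset", "ko", level, "w")]
    }
    total <- tapply(present$w, present$dataset, sum)
    agg <- stats::aggregate(list(weight = joined$w),
                            joined[c("dataset", level)], sum)
    agg$pct <- agg$weight / as.numeric(total[agg$dataset]) * 100
    names(agg)[names(agg) == level] <- level
    agg <- agg[order(agg$dataset, agg[[level]]), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  }

  structure(list(modules = aggregate_level("module"),
                 pathways = aggregate_level("pathway"),
                 multi_module_kos = multi,
                 weight = weight),
            class = "module_abundance")
}

#' Twofold screen between two datasets at module (or pathway) level
#'
#' Delegates to [twofold_screen()] on the percentage relative abundances of
#' the two datasets.
#'
#' @param abundance a `module_abundance`.
#' @param dataset_a,dataset_b dataset labels present in the abundance table.
#' @param level `"module"` (default) or `"pathway"`.
#' @param ratio flagging threshold (default 2).
#' @return the [twofold_screen()] data.frame over module/pathway labels.
#' @export
module_twofold <- function(abundance, dataset_a, dataset_b,
                           level = c("module", "pathway"), ratio = 2) {
  level <- match.arg(level)
  tab <- if (level == "module") abundance$modules else abundance$pathways
  for (d in c(dataset_a, dataset_b)) {
    if (!d %in% tab$dataset) stop_("dataset '%s' not in abundance table", d)
  }
  pick <- function(d) {
    sub <- tab[tab$dataset == d, , drop = FALSE]
    stats::setNames(sub$pct, sub[[level]])
  }
  twofold_screen(pick(dataset_a), pick(dataset_b), ratio = ratio)
}

#' Pathway breakdown of each environment's exclusive orthologues
#'
#' "Exclusive" orthologues of an environment are the cloud KOs unique to
#' that environment's Actinomycetota dataset. Each exclusive KO contributes
#' one unit per mapped pathway (unmapped KOs contribute one unit to an
#' `"unmapped"` bucket), so per environment the proportions sum to 100.
#'
#' @param partition a `pan_partition` over the four datasets.
#' @param map module map.
#' @param datasets named character vector: environment label -> the
#'   partition dataset label holding that environment's Actinomycetota KOs.
#' @return data.frame (`environment`, `pathway`, `count`, `pct`).
#' @export
exclusive_pathway_proportions <- function(partition, map, datasets) {
  map <- validate_module_map(map)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    stop_("datasets must be a named vector (environment -> dataset label)")
  }
  rows <- lapply(names(datasets), function(env) {
    u <- unique_kos(partition, datasets[[env]])
    if (!length(u)) {
      warn_("environment '%s' has no exclusive orthologues", env)
      return(NULL)
    }
    hits <- map[map$ko %in% u, c("ko", "pathway"), drop = FALSE]
    un <- setdiff(u, hits$ko)
    if (length(un)) {
      hits <- rbind(hits, data.frame(ko = un, pathway = "unmapped",
                                     stringsAsFactors = FALSE))
    }
    counts <- table(hits$pathway)
    data.frame(environment = env, pathway = names(counts),
               count = as.integer(counts),
               pct = as.numeric(counts) / nrow(hits) * 100,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(environment = character(0), pathway = character(0),
                      count = integer(0), pct = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
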