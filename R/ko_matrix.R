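# Taxon-KO abundance matrices: ingest taxonomy-abundance reports
# (Bracken-style TSV) and KO annotation tables (eggNOG-mapper-style TSV),
# build raw counts per (dataset, KO), normalize to counts per million, and
# screen twofold differences between environments.

BRACKEN_COLUMNS <- c("name", "taxonomy_id", "taxonomy_lvl",
                     "kraken_assigned_reads", "added_reads",
                     "new_est_reads", "fraction_total_reads")

#' Read a Bracken-style taxonomy abundance report
#'
#' @param path TSV with the seven standard columns (`name`, `taxonomy_id`,
#'   `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`, `new_est_reads`,
#'   `fraction_total_reads`).
#' @param sample sample label attached to every row (defaults to the file
#'   name without extension).
#' @return data.frame of the report rows plus a `sample` column. An empty
#'   file yields an empty profile with a warning.
#' @export
read_taxon_profile <- function(path,
                               sample = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop_("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    warn_("empty taxonomy report: %s", path)
    empty <- stats::setNames(
      data.frame(character(0), integer(0), character(0), integer(0),
                 integer(0), integer(0), numeric(0),
                 stringsAsFactors = FALSE),
      BRACKEN_COLUMNS)
    empty$sample <- character(0)
    return(empty)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, BRACKEN_COLUMNS, sprintf("taxonomy report %s", path))
  bad <- which(df$fraction_total_reads < 0 | df$fraction_total_reads > 1)
  if (length(bad)) {
    stop_("fraction_total_reads outside [0, 1] on data line(s): %s",
          paste(bad, collapse = ", "))
  }
  bad <- which(df$new_est_reads < 0)
  if (length(bad)) {
    stop_("negative new_est_reads on data line(s): %s",
          paste(bad, collapse = ", "))
  }
  df$sample <- sample
  df
}

#' Read a KO annotation table (eggNOG-mapper dialect)
#'
#' Uses the `query` and `KEGG_ko` columns (a leading `#` on the header of
#' the first column is tolerated); `"-"` means no KO annotation. Extra
#' columns such as `taxon_group` and `environment` are preserved.
#'
#' @param path TSV path.
#' @return data.frame with at least `query` and `KEGG_ko`.
#' @export
read_ko_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1] <- sub("^X\\.", "", names(df)[1])
  names(df) <- sub("^#", "", names(df))
  assert_columns(df, c("query", "KEGG_ko"),
                 sprintf("annotation table %s", path))
  df
}

split_ko_field <- function(kegg_ko) {
  parts <- strsplit(as.character(kegg_ko), ",", fixed = TRUE)
  lapply(parts, function(p) {
    p <- trimws(p)
    p <- p[!(p %in% c("", "-"))]
    sub("^ko:", "", p)
  })
}

#' Build the raw taxon-KO count matrix from annotation rows
#'
#' Each dataset is an (environment, taxon group) pair; rows labelled with an
#' excluded taxon group (by default `"Other"`, i.e. non-bacterial hits) are
#' dropped. The raw count of (dataset, KO) is the number of queries in that
#' dataset annotated with that KO; a query carrying m KO identifiers
#' contributes one count to each of the m KOs.
#'
#' @param annotations data.frame with columns `query`, `KEGG_ko`
#'   (comma-separated `ko:Kddddd` identifiers, `"-"` for none),
#'   `taxon_group`, and `environment`.
#' @param drop_groups taxon-group labels to exclude (default `"Other"`).
#' @return long-form data.frame (`dataset`, `ko`, `raw`) of class
#'   `taxon_ko_matrix`, with the per-dataset kept annotation-row counts in
#'   attribute `"annotation_rows"`.
#' @export
build_matrix <- function(annotations, drop_groups = "Other") {
  assert_columns(annotations,
                 c("query", "KEGG_ko", "taxon_group", "environment"),
                 "annotation table")
  ann <- annotations
  ann$dataset <- paste(ann$environment, ann$taxon_group, sep = "_")
  dup <- ann[duplicated(ann[c("dataset", "query")]), , drop = FALSE]
  if (nrow(dup)) {
    stop_("duplicate query id(s) within a dataset (double counting): %s",
          paste(utils::head(unique(paste(dup$dataset, dup$query, sep = "/")),
                            5), collapse = ", "))
  }
  keep <- !(ann$taxon_group %in% drop_groups)
  if (!any(keep)) {
    warn_("every annotation row is in an excluded taxon group; empty matrix")
    out <- data.frame(dataset = character(0), ko = character(0),
                      raw = integer(0), stringsAsFactors = FALSE)
    return(new_taxon_ko_matrix(out, integer(0)))
  }
  ann <- ann[keep, , drop = FALSE]
  kos <- split_ko_field(ann$KEGG_ko)
  flat <- unlist(kos, use.names = FALSE)
  bad <- flat[!grepl("^K[0-9]{5}$", flat)]
  if (length(bad)) {
    stop_("malformed KO identifier(s): %s",
          paste(unique(bad), collapse = ", "))
  }
  long <- data.frame(dataset = rep(ann$dataset, lengths(kos)), ko = flat,
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(raw = rep(1L, nrow(long))),
                          long[c("dataset", "ko")], sum)
  agg <- agg[order(agg$dataset, agg$ko), , drop = FALSE]
  rownames(agg) <- NULL
  rows <- table(ann$dataset)
  new_taxon_ko_matrix(agg,
                      stats::setNames(as.integer(rows), names(rows)))
}

#' Construct a taxon-KO matrix from a long-form data.frame
#'
#' @param df data.frame with columns `dataset`, `ko`, `raw` (and optionally
#'   `cpm`).
#' @param annotation_rows optional named per-dataset annotation-row counts.
#' @return a `taxon_ko_matrix`.
#' @export
new_taxon_ko_matrix <- function(df, annotation_rows = NULL) {
  assert_columns(df, c("dataset", "ko", "raw"), "taxon-KO matrix")
  if (any(df$raw < 0)) stop_("raw counts must be non-negative")
  structure(df, annotation_rows = annotation_rows,
            class = c("taxon_ko_matrix", "data.frame"))
}

#' Normalize a taxon-KO matrix to counts per million
#'
#' `cpm = raw * 1e6 / mapped_total` cell-wise, so that per dataset the CPM
#' column sums to one million when the mapped total equals the raw-count
#' sum. CPM is always recomputed from the raw counts; raw is never mutated.
#'
#' @param matrix a `taxon_ko_matrix` (long form: `dataset`, `ko`, `raw`).
#' @param mapped_totals optional named integer vector, dataset -> mapped
#'   read total. When omitted, the per-dataset raw-count sum is used, which
#'   makes each dataset's CPM sum exactly 1e6.
#' @return the matrix with a recomputed `cpm` column.
#' @export
normalize_cpm <- function(matrix, mapped_totals = NULL) {
  assert_columns(matrix, c("dataset", "ko", "raw"), "taxon-KO matrix")
  sums <- tapply(matrix$raw, matrix$dataset, sum)
  totals <- mapped_totals %||% sums
  absent <- setdiff(names(sums), names(totals))
  if (length(absent)) {
    stop_("no mapped total for dataset(s): %s", paste(absent, collapse = ", "))
  }
  zero <- names(sums)[sums > 0 & totals[names(sums)] <= 0]
  if (length(zero)) {
    stop_("mapped total is 0 for dataset(s) with non-zero counts: %s",
          paste(zero, collapse = ", "))
  }
  matrix$cpm <- matrix$raw * 1e6 / as.numeric(totals[matrix$dataset])
  matrix$cpm[is.na(matrix$cpm)] <- 0
  matrix
}

#' Per-dataset KO presence sets
#'
#' Presence is raw count >= 1; no CPM floor is applied.
#'
#' @param matrix a `taxon_ko_matrix`.
#' @return named list, dataset -> character vector of present KOs.
#' @export
ko_presence_sets <- function(matrix) {
  assert_columns(matrix, c("dataset", "ko", "raw"), "taxon-KO matrix")
  present <- matrix[matrix$raw >= 1, , drop = FALSE]
  split(present$ko, present$dataset)
}

#' Relative abundance at a taxonomic rank with a pooled low-abundance bucket
#'
#' Taxa below `min_pct` percent, together with unknown taxa, are pooled into
#' a single `"<min_pct%"` bucket, matching the usual genus-level stacked-bar
#' presentation.
#'
#' @param profile taxonomy profile from [read_taxon_profile()].
#' @param rank taxonomy level code to keep (e.g. `"G"`, `"S"`).
#' @param min_pct pooling threshold in percent (default 1).
#' @param unknown_labels taxon names treated as unknown regardless of
#'   abundance.
#' @return data.frame (`taxon`, `pct`) whose percentages sum to 100.
#' @export
relative_abundance <- function(profile, rank, min_pct = 1,
                               unknown_labels = c("", "unknown",
                                                  "unclassified")) {
  assert_columns(profile, c("name", "taxonomy_lvl", "new_est_reads"),
                 "taxonomy profile")
  sub <- profile[profile$taxonomy_lvl == rank, , drop = FALSE]
  if (!nrow(sub)) stop_("no rows at rank '%s'", rank)
  total <- sum(sub$new_est_reads)
  if (total <= 0) stop_("no reads at rank '%s'", rank)
  pct <- sub$new_est_reads / total * 100
  pooled <- pct < min_pct | is.na(sub$name) |
    tolower(sub$name) %in% tolower(unknown_labels)
  out <- data.frame(taxon = sub$name[!pooled], pct = pct[!pooled],
                    stringsAsFactors = FALSE)
  if (any(pooled)) {
    bucket <- sprintf("<%s%%", format(min_pct))
    out <- rbind(out, data.frame(taxon = bucket, pct = sum(pct[pooled]),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(-out$pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen features for at-least-twofold differences between two conditions
#'
#' A feature is flagged when `max(a, b) / min(a, b) >= ratio` with both
#' sides positive (the boundary is inclusive: 2.0 vs 1.0 is "at least
#' twofold"). Features with a positive value on one side only are reported
#' as `exclusive_a` / `exclusive_b`, never as infinitely enriched.
#'
#' @param a,b named non-negative numeric vectors of abundances; missing
#'   names are treated as 0 (absent).
#' @param ratio flagging threshold (default 2).
#' @return data.frame (`feature`, `value_a`, `value_b`, `ratio`, `status`,
#'   `higher`) where `status` is one of `flagged`, `not_flagged`,
#'   `exclusive_a`, `exclusive_b`, `absent`.
#' @export
twofold_screen <- function(a, b, ratio = 2) {
  for (v in list(a, b)) {
    if (length(v) && (is.null(names(v)) || any(!nzchar(names(v))))) {
      stop_("abundance vectors must be fully named")
    }
    if (any(v < 0, na.rm = TRUE)) stop_("abundances must be non-negative")
  }
  feats <- sort(union(names(a), names(b)))
  va <- ifelse(feats %in% names(a), a[feats], 0)
  vb <- ifelse(feats %in% names(b), b[feats], 0)
  va[is.na(va)] <- 0
  vb[is.na(vb)] <- 0
  r <- ifelse(va > 0 & vb > 0, pmax(va, vb) / pmin(va, vb), NA_real_)
  status <- ifelse(va > 0 & vb > 0,
                   ifelse(r >= ratio, "flagged", "not_flagged"),
                   ifelse(va > 0, "exclusive_a",
                          ifelse(vb > 0, "exclusive_b", "absent")))
  higher <- ifelse(status == "flagged", ifelse(va > vb, "a", "b"),
                   NA_character_)
  data.frame(feature = feats, value_a = unname(va), value_b = unname(vb),
             ratio = unname(r), status = status, higher = higher,
             stringsAsFactors = FALSE)
}

#' Write a taxon-KO matrix as long-form TSV
#'
#' @param matrix a `taxon_ko_matrix` (with or without `cpm`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  utils::write.table(as.data.frame(matrix), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-form taxon-KO matrix TSV
#'
#' @param path TSV written by [write_matrix()].
#' @return a `taxon_ko_matrix`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new_taxon_ko_matrix(df[intersect(c("dataset", "ko", "raw", "cpm"),
                                   names(df))])
}
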