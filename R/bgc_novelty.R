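# Biosynthetic novelty index (BiNI) of an isolate: sum(d) / n over its n
# predicted biosynthetic gene clusters, where d is each cluster's distance
# to its nearest gene cluster family in a reference catalogue. Distances
# above 900 flag individually novel clusters; the flag is NOT a filter on
# which distances enter the sum (published scores below 900 are only
# arithmetically possible when sub-threshold distances are summed).

#' Read a per-strain BGC summary table
#'
#' @param path TSV with columns `strain`, `region`, `type`, `distance`
#'   (empty / NA = no distance available for that cluster).
#' @return validated data.frame.
#' @export
read_bgc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_bgc_table(df)
}

validate_bgc_table <- function(table) {
  assert_columns(table, c("strain", "region", "type", "distance"),
                 "BGC table")
  if (any(table$distance < 0, na.rm = TRUE)) {
    stop_("BGC distances must be non-negative")
  }
  dup <- table[duplicated(table[c("strain", "region")]), , drop = FALSE]
  if (nrow(dup)) {
    stop_("duplicate region id(s) within a strain: %s",
          paste(utils::head(paste(dup$strain, dup$region, sep = "/"), 5),
                collapse = ", "))
  }
  table
}

#' Write a BGC table as TSV
#' @param table BGC table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bgc_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' BiNI score per strain
#'
#' `score = sum(d) / n` where n is the total cluster count of the strain
#' (clusters with a missing distance still count in n but contribute 0 to
#' the sum; `coverage` reports the fraction of clusters with a distance so
#' the effect is visible).
#'
#' @param table BGC table (`strain`, `region`, `type`, `distance`).
#' @param strains optional character vector restricting which strains to
#'   score; strains absent from the table are skipped with a warning.
#' @param threshold per-cluster novelty threshold; a cluster is novel when
#'   its distance is strictly greater (default 900).
#' @return data.frame of class `bini_table`: `strain`, `n`, `sum_d`,
#'   `score`, `n_novel`, `coverage`.
#' @export
bini_score <- function(table, strains = NULL, threshold = 900) {
  table <- validate_bgc_table(table)
  want <- strains %||% sort(unique(table$strain))
  absent <- setdiff(want, table$strain)
  if (length(absent)) {
    warn_("strain(s) with no clusters skipped: %s",
          paste(absent, collapse = ", "))
    want <- setdiff(want, absent)
  }
  rows <- lapply(want, function(s) {
    d <- table$distance[table$strain == s]
    n <- length(d)
    cov <- mean(!is.na(d))
    if (cov == 0) {
      warn_("strain '%s' has no cluster distances; score is 0", s)
    }
    data.frame(strain = s, n = n, sum_d = sum(d, na.rm = TRUE),
               score = sum(d, na.rm = TRUE) / n,
               n_novel = sum(novelty_flag(d, threshold), na.rm = TRUE),
               coverage = cov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("bini_table", "data.frame"))
}

#' Per-cluster novelty flag
#'
#' @param d numeric vector of gene-cluster-family distances.
#' @param threshold strict threshold (default 900): 901 is novel, 900 is
#'   not.
#' @return logical vector; a missing distance yields `NA` ("unknown"),
#'   never `FALSE`.
#' @export
novelty_flag <- function(d, threshold = 900) {
  d > threshold
}

#' Rank strains by descending BiNI score
#'
#' @param scores a `bini_table` (or any data.frame with `strain` and
#'   `score`).
#' @return the table sorted by descending score, ties broken by strain
#'   label (ascending).
#' @export
rank_strains <- function(scores) {
  assert_columns(scores, c("strain", "score"), "BiNI table")
  if (!nrow(scores)) stop_("no scored strains to rank")
  out <- scores[order(-scores$score, scores$strain), , drop = FALSE]
  rownames(out) <- NULL
  out
}
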