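# Pan-metagenome orthologue classification over four datasets: an
# orthologue present in every dataset is "core", in exactly three
# "softcore", in exactly two "shell", and in only one "cloud". The classes
# are mutually exclusive (a literal "at least three" softcore would overlap
# core; the published percentages sum to ~100, so exact popcounts are used).

PAN_CLASSES <- c("core", "softcore", "shell", "cloud")

#' Classify a 4-dataset presence mask into a pan-metagenome class
#'
#' @param mask logical (or 0/1) vector of length 4, or a matrix with 4
#'   columns (one row per orthologue).
#' @return factor with levels core, softcore, shell, cloud. A popcount of 0
#'   (absent everywhere) is an error: such an orthologue must never reach
#'   classification.
#' @examples
#' classify_pan(c(1, 1, 1, 1))  # core
#' classify_pan(c(1, 0, 1, 0))  # shell
#' @export
classify_pan <- function(mask) {
  if (is.null(dim(mask))) mask <- matrix(mask, nrow = 1)
  if (ncol(mask) != 4) stop_("presence mask must have exactly 4 datasets")
  storage.mode(mask) <- "integer"
  if (any(!mask %in% c(0L, 1L))) stop_("mask entries must be 0/1 or logical")
  pop <- rowSums(mask)
  if (any(pop == 0)) {
    stop_("orthologue absent from every dataset cannot be classified")
  }
  factor(c("cloud", "shell", "softcore", "core")[pop], levels = PAN_CLASSES)
}

#' Pan-metagenome partition of four KO sets
#'
#' @param ko_sets named list of exactly four character vectors (the KO
#'   identifiers present in each dataset).
#' @return object of class `pan_partition`: `labels` (the four dataset
#'   labels in input order), `table` (data.frame `ko`, `mask` as a 4-bit
#'   string in label order, `class`), and `summary` (per-class `count` and
#'   `fraction` over the union).
#' @export
pan_summary <- function(ko_sets) {
  if (!is.list(ko_sets) || length(ko_sets) != 4 ||
      is.null(names(ko_sets)) || any(!nzchar(names(ko_sets))) ||
      anyDuplicated(names(ko_sets))) {
    stop_("pan classification is defined for exactly 4 uniquely labelled sets")
  }
  labels <- names(ko_sets)
  universe <- sort(unique(unlist(ko_sets, use.names = FALSE)))
  if (!length(universe)) stop_("all four KO sets are empty")
  pres <- vapply(ko_sets, function(s) universe %in% s,
                 logical(length(universe)))
  pres <- matrix(pres, ncol = 4, dimnames = list(NULL, labels))
  cls <- classify_pan(pres)
  mask <- apply(pres, 1, function(b) paste(as.integer(b), collapse = ""))
  counts <- table(cls)
  summary <- data.frame(class = PAN_CLASSES,
                        count = as.integer(counts[PAN_CLASSES]),
                        fraction = as.numeric(counts[PAN_CLASSES]) /
                          length(universe),
                        stringsAsFactors = FALSE)
  structure(list(labels = labels,
                 table = data.frame(ko = universe, mask = mask,
                                    class = cls, stringsAsFactors = FALSE),
                 summary = summary),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf("Pan partition of %d orthologues over datasets: %s\n",
              nrow(x$table), paste(x$labels, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Orthologues unique to one dataset
#'
#' The cloud orthologues whose single presence bit is the given dataset.
#'
#' @param partition a `pan_partition`.
#' @param dataset one of `partition$labels`.
#' @return character vector of KO identifiers.
#' @export
unique_kos <- function(partition, dataset) {
  if (!inherits(partition, "pan_partition")) stop_("not a pan_partition")
  i <- match(dataset, partition$labels)
  if (is.na(i)) {
    stop_("unknown dataset '%s' (have: %s)", dataset,
          paste(partition$labels, collapse = ", "))
  }
  tab <- partition$table
  tab$ko[tab$class == "cloud" & substr(tab$mask, i, i) == "1"]
}

#' Four-set Venn partition
#'
#' Counts the 15 disjoint regions of a four-set Venn diagram (every
#' non-empty subset of the dataset labels); region counts sum to the size of
#' the union.
#'
#' @param ko_sets named list of exactly four character vectors.
#' @return data.frame (`region`, `degree`, `count`) covering all 15 regions
#'   (zero counts included), with the member KOs in attribute `"members"`
#'   (a named list keyed by region).
#' @export
venn_partition <- function(ko_sets) {
  part <- pan_summary(ko_sets)
  labels <- part$labels
  region_key <- function(bits) {
    paste(labels[as.logical(bits)], collapse = "&")
  }
  all_regions <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(4, k), 2, function(idx) {
      bits <- integer(4)
      bits[idx] <- 1L
      region_key(bits)
    })
  }))
  ko_region <- vapply(strsplit(part$table$mask, ""), function(b) {
    region_key(as.integer(b))
  }, character(1))
  counts <- table(factor(ko_region, levels = all_regions))
  members <- split(part$table$ko, factor(ko_region, levels = all_regions))
  out <- data.frame(region = all_regions,
                    degree = lengths(strsplit(all_regions, "&", fixed = TRUE)),
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "members") <- members
  out
}

#' Write pan-partition outputs (class table, Venn regions, summary)
#'
#' Produces `pan_classes.tsv` (KO, mask, class), `venn_regions.tsv`,
#' `venn_regions.txt` (one region per block, mirroring the four-set Venn web
#' tool's text export), and `pan_summary.json`.
#'
#' @param partition a `pan_partition`.
#' @param venn output of [venn_partition()] on the same sets.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_pan <- function(partition, venn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "pan_classes.tsv")
  utils::write.table(partition$table, f1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  f2 <- file.path(dir, "venn_regions.tsv")
  utils::write.table(venn[c("region", "degree", "count")], f2, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  f3 <- file.path(dir, "venn_regions.txt")
  members <- attr(venn, "members")
  txt <- unlist(lapply(venn$region, function(r) {
    c(sprintf("%s : %d", r, length(members[[r]])),
      paste(members[[r]], collapse = " "))
  }))
  writeLines(txt, f3)
  f4 <- file.path(dir, "pan_summary.json")
  jsonlite::write_json(partition$summary, f4, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3, f4))
}
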