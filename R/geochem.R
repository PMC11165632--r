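# Soil elemental-analysis tables: fold enrichment against crustal reference
# values and extreme-value flagging. Censored measurements ("<50") carry the
# detection limit and never enter fold computation or "highest" flags.

#' Fold enrichment of an observed concentration over a reference value
#'
#' Computes `observed / reference` rounded half-up to one decimal, the
#' precision at which soil enrichment multipliers are conventionally
#' reported (e.g. 2440 p.p.m. chloride over a 145 p.p.m. crustal reference
#' gives 16.8). Censored observations are not computable and yield `NA`.
#'
#' @param observed numeric vector of concentrations (p.p.m.).
#' @param reference numeric vector of reference concentrations (p.p.m.),
#'   recycled against `observed`.
#' @param censored logical vector; `TRUE` marks below-detection-limit cells,
#'   whose fold is reported as `NA` (not computable), never a number.
#' @param digits decimal places of the reported fold (default 1).
#' @return numeric vector of folds, `NA` where censored.
#' @examples
#' fold_enrichment(2440, 145)   # 16.8
#' fold_enrichment(86, 19)      # 4.5
#' @export
fold_enrichment <- function(observed, reference, censored = FALSE,
                            digits = 1) {
  if (!is.numeric(observed) || !is.numeric(reference)) {
    stop_("observed and reference must be numeric")
  }
  if (anyNA(reference) || any(reference <= 0)) {
    stop_("reference values must all be present and > 0")
  }
  if (any(!censored & (is.na(observed) | observed < 0))) {
    stop_("uncensored observed values must be present and >= 0")
  }
  fold <- round_half_up(observed / reference, digits)
  fold[rep_len(censored, length(fold))] <- NA_real_
  fold
}

#' Fold enrichment for a whole geochemistry table
#'
#' @param table long-form geochemistry table as returned by [read_geochem()]:
#'   columns `site`, `analyte`, `value`, `censored` (for censored rows,
#'   `value` holds the detection limit).
#' @param reference named numeric vector, analyte -> reference p.p.m. Every
#'   analyte present in `table` must be covered.
#' @return the input table with a `fold` column (`NA` for censored cells).
#' @export
fold_enrichment_table <- function(table, reference) {
  assert_columns(table, c("site", "analyte", "value", "censored"),
                 "geochemistry table")
  absent <- setdiff(unique(table$analyte), names(reference))
  if (length(absent)) {
    stop_("no reference value for analyte(s): %s",
          paste(absent, collapse = ", "))
  }
  table$fold <- fold_enrichment(table$value, reference[table$analyte],
                                censored = table$censored)
  table
}

#' Flag per-analyte extreme values
#'
#' Mirrors the dagger/double-dagger annotation of elemental-analysis tables:
#' per analyte, the highest value over uncensored measurements, and the
#' lowest value where censored cells tie as joint lowest whenever their
#' detection limit does not exceed the minimum uncensored value. Ties are
#' reported as sets.
#'
#' @param table long-form geochemistry table (`site`, `analyte`, `value`,
#'   `censored`).
#' @return data.frame with one row per analyte: `analyte`, `highest_site`
#'   (`NA` when every cell is censored), `highest_value`, list-columns
#'   `lowest_sites`, and `lowest_value`, `lowest_censored`.
#' @export
flag_extremes <- function(table) {
  assert_columns(table, c("site", "analyte", "value", "censored"),
                 "geochemistry table")
  analytes <- unique(table$analyte)
  rows <- lapply(analytes, function(a) {
    sub <- table[table$analyte == a, , drop = FALSE]
    unc <- sub[!sub$censored, , drop = FALSE]
    cen <- sub[sub$censored, , drop = FALSE]
    if (nrow(unc)) {
      hi <- unc[unc$value == max(unc$value), , drop = FALSE]
      highest_site <- hi$site[1]
      highest_value <- hi$value[1]
      min_unc <- min(unc$value)
    } else {
      highest_site <- NA_character_
      highest_value <- NA_real_
      min_unc <- Inf
    }
    low_cen <- cen[cen$value <= min_unc, , drop = FALSE]
    if (nrow(low_cen)) {
      lowest_sites <- low_cen$site
      lowest_value <- min(low_cen$value)
      lowest_censored <- TRUE
    } else if (nrow(unc)) {
      lowest_sites <- unc$site[unc$value == min_unc]
      lowest_value <- min_unc
      lowest_censored <- FALSE
    } else {
      lowest_sites <- character(0)
      lowest_value <- NA_real_
      lowest_censored <- NA
    }
    data.frame(analyte = a, highest_site = highest_site,
               highest_value = highest_value,
               lowest_sites = I(list(lowest_sites)),
               lowest_value = lowest_value,
               lowest_censored = lowest_censored,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_censored_cell <- function(x) {
  x <- trimws(as.character(x))
  censored <- grepl("^<", x)
  value <- suppressWarnings(as.numeric(sub("^<\\s*", "", x)))
  if (anyNA(value[nzchar(x)])) {
    bad <- x[nzchar(x) & is.na(value)]
    stop_("cannot parse concentration cell(s): %s",
          paste(unique(bad), collapse = ", "))
  }
  list(value = value, censored = censored)
}

#' Read a wide geochemistry CSV
#'
#' Expects the conventional elemental-analysis layout: a `site` column, an
#' optional `location` column (ignored), an optional `pH` column, and one
#' column per analyte. Censored cells are encoded as `"<N"` where N is the
#' detection limit.
#'
#' @param path CSV file path.
#' @return long-form data.frame (`site`, `analyte`, `value`, `censored`)
#'   with the per-site pH (if present) attached as attribute `"ph"`.
#' @export
read_geochem <- function(path) {
  wide <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  names(wide)[1] <- tolower(names(wide)[1])
  assert_columns(wide, "site", "geochemistry CSV")
  drop <- tolower(names(wide)) %in% c("site", "location", "ph")
  analytes <- names(wide)[!drop]
  if (!length(analytes)) stop_("geochemistry CSV has no analyte columns")
  long <- do.call(rbind, lapply(analytes, function(a) {
    cell <- parse_censored_cell(wide[[a]])
    data.frame(site = wide$site, analyte = a, value = cell$value,
               censored = cell$censored, stringsAsFactors = FALSE)
  }))
  if (any(!long$censored & long$value < 0)) {
    stop_("uncensored concentrations must be >= 0")
  }
  if (any(long$censored & long$value <= 0)) {
    stop_("censoring limits must be > 0")
  }
  ph_col <- which(tolower(names(wide)) == "ph")
  if (length(ph_col)) {
    attr(long, "ph") <- stats::setNames(as.numeric(wide[[ph_col[1]]]),
                                        wide$site)
  }
  long
}

#' Write a geochemistry table as wide CSV with "<N" censoring
#'
#' Inverse of [read_geochem()] up to column order; censored cells round-trip
#' as their `"<limit"` string form.
#'
#' @param table long-form geochemistry table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_geochem <- function(table, path) {
  assert_columns(table, c("site", "analyte", "value", "censored"),
                 "geochemistry table")
  sites <- unique(table$site)
  analytes <- unique(table$analyte)
  fmt_num <- function(v) {
    ifelse(v == round(v), format(v, trim = TRUE, scientific = FALSE),
           format(v, trim = TRUE))
  }
  wide <- data.frame(site = sites, stringsAsFactors = FALSE)
  for (a in analytes) {
    sub <- table[table$analyte == a, , drop = FALSE]
    cells <- ifelse(sub$censored,
                    paste0("<", fmt_num(sub$value)),
                    fmt_num(sub$value))
    wide[[a]] <- cells[match(sites, sub$site)]
  }
  ph <- attr(table, "ph")
  if (!is.null(ph)) wide$pH <- unname(ph[sites])
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an analyte reference table (analyte,value CSV)
#'
#' @param path CSV with columns `analyte` and `value` (p.p.m.).
#' @return named numeric vector analyte -> reference concentration.
#' @export
read_geochem_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("analyte", "value"), "reference CSV")
  stats::setNames(as.numeric(df$value), df$analyte)
}
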