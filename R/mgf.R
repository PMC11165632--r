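# Minimal MGF (Mascot Generic Format) reader/writer for MS/MS spectra.
# None of the installed mass-spectrometry readers handle MGF, so the
# BEGIN IONS / END IONS block format is parsed directly.

#' Construct an MS/MS spectrum
#'
#' Peaks are sorted ascending by m/z on construction.
#'
#' @param id spectrum identifier.
#' @param pepmass precursor m/z in Da (> 0).
#' @param mz,intensity numeric peak vectors (m/z > 0, intensity >= 0).
#' @param charge positive integer precursor charge.
#' @param strain optional strain label the spectrum originates from.
#' @param members,member_count consensus bookkeeping: the member spectrum
#'   ids merged into this spectrum and their number (1 for a raw spectrum).
#' @return object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(id, pepmass, mz, intensity, charge = 1L,
                     strain = NA_character_, members = id,
                     member_count = length(members)) {
  if (!is.numeric(pepmass) || length(pepmass) != 1 || pepmass <= 0) {
    stop_("spectrum '%s': PEPMASS must be a single positive number", id)
  }
  if (length(mz) != length(intensity)) {
    stop_("spectrum '%s': mz and intensity lengths differ", id)
  }
  if (any(mz <= 0) || any(intensity < 0)) {
    stop_("spectrum '%s': m/z must be > 0 and intensities >= 0", id)
  }
  o <- order(mz)
  structure(list(id = as.character(id), pepmass = as.numeric(pepmass),
                 charge = as.integer(charge),
                 strain = unique(as.character(strain)),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 members = as.character(members),
                 member_count = as.integer(member_count)),
            class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum %s> precursor %.4f (%d+), %d peaks, %d member(s)\n",
              x$id, x$pepmass, x$charge, length(x$mz), x$member_count))
  invisible(x)
}

#' Read an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with PEPMASS, CHARGE, TITLE (and an
#' optional STRAIN key). Peaks arriving unsorted are sorted on load.
#'
#' @param path MGF file path.
#' @return list of `ms_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop_("malformed MGF: unbalanced BEGIN IONS / END IONS in %s", path)
  }
  spectra <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1):(ends[b] - 1)]
    block <- block[nzchar(block)]
    is_kv <- grepl("^[A-Za-z]+=", block)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    pep <- get("PEPMASS")
    if (is.na(pep)) stop_("MGF block %d: missing PEPMASS", b)
    pepmass <- as.numeric(strsplit(pep, "\\s+")[[1]][1])
    charge <- get("CHARGE")
    charge <- if (is.na(charge)) 1L else as.integer(sub("[+-]$", "", charge))
    title <- get("TITLE")
    id <- if (is.na(title)) sprintf("spectrum_%d", b) else title
    peak_lines <- block[!is_kv]
    peaks <- do.call(rbind, lapply(strsplit(peak_lines, "\\s+"), function(p) {
      as.numeric(p[1:2])
    }))
    if (is.null(peaks)) peaks <- matrix(numeric(0), ncol = 2)
    spectra[[b]] <- ms_spectrum(id = id, pepmass = pepmass, charge = charge,
                             strain = get("STRAIN"),
                             mz = peaks[, 1], intensity = peaks[, 2])
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Round-trips through [read_mgf()] preserve peaks to 1e-4 Da in m/z and
#' 1e-3 in intensity.
#'
#' @param spectra list of `ms_spectrum` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$id), con)
    writeLines(sprintf("PEPMASS=%.5f", s$pepmass), con)
    writeLines(sprintf("CHARGE=%d+", s$charge), con)
    if (length(s$strain) == 1 && !is.na(s$strain)) {
      writeLines(sprintf("STRAIN=%s", s$strain), con)
    }
    writeLines(sprintf("%.5f %.4f", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
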