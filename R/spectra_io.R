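#' Construct an MS2 spectrum record
#'
#' An `ms2_spectrum` holds one MS2 scan: its source file, the verbatim TITLE
#' line content, precursor m/z, optional precursor charge, and the peak list.
#' Peaks are stored as a two-column numeric matrix (`mz`, `intensity`) sorted
#' ascending by m/z; downstream tolerance searches rely on that ordering.
#'
#' @param title spectrum title, non-empty character scalar, stored verbatim
#' @param peaks two-column numeric matrix or data.frame of (m/z, intensity);
#'   intensities must be non-negative
#' @param precursor_mz precursor m/z in Thomson (may be `NA`)
#' @param precursor_charge integer charge state >= 1, or `NA` when absent
#' @param source_file originating file name (informational)
#' @return an object of class `ms2_spectrum`
#' @export
ms2_spectrum <- function(title, peaks, precursor_mz = NA_real_,
                         precursor_charge = NA_integer_,
                         source_file = NA_character_) {
  if (!is.character(title) || length(title) != 1L || !nzchar(title))
    stopf("spectrum title must be a non-empty string")
  peaks <- as.matrix(peaks)
  if (length(peaks) == 0L) {
    peaks <- matrix(numeric(0), ncol = 2L)
  }
  if (ncol(peaks) != 2L)
    stopf("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  if (any(peaks[, 2L] < 0, na.rm = TRUE))
    stopf("peak intensities must be non-negative")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  dimnames(peaks) <- list(NULL, c("mz", "intensity"))
  structure(
    list(source_file = source_file, title = title,
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = as.integer(precursor_charge),
         peaks = peaks),
    class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s\n  precursor m/z %.4f charge %s, %d peaks\n",
              x$title, x$precursor_mz,
              ifelse(is.na(x$precursor_charge), "?", x$precursor_charge),
              nrow(x$peaks)))
  invisible(x)
}

#' Read an MGF file
#'
#' Parses a Mascot Generic Format file into a list of [ms2_spectrum()]
#' records, one per `BEGIN IONS`/`END IONS` block, in file order. Titles are
#' preserved byte-for-byte (no case folding or trimming beyond the `TITLE=`
#' prefix), because spectrum identifiers from search engines must match
#' exactly. Peak lists are sorted ascending by m/z even if the file is not.
#' `CHARGE` lines with a trailing `+`/`-` are handled; a missing `CHARGE`
#' is allowed.
#'
#' @param path path to an MGF file
#' @return list of `ms2_spectrum` objects
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stopf("MGF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  src <- basename(path)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (identical(line, "BEGIN IONS")) {
      begin_line <- i
      title <- NA_character_
      pepmass <- NA_real_
      charge <- NA_integer_
      mz <- numeric(0); inten <- numeric(0)
      i <- i + 1L
      ended <- FALSE
      while (i <= n) {
        line <- lines[[i]]
        if (identical(line, "END IONS")) { ended <- TRUE; i <- i + 1L; break }
        if (identical(line, "BEGIN IONS"))
          stopf("MGF parse error at line %d: unterminated block starting at line %d",
                i, begin_line)
        if (grepl("^TITLE=", line)) {
          title <- sub("^TITLE=", "", line)
        } else if (grepl("^PEPMASS=", line)) {
          pepmass <- parse_num(strsplit(sub("^PEPMASS=", "", line), "[ \t]+")[[1]][1])
        } else if (grepl("^CHARGE=", line)) {
          charge <- as.integer(parse_num(sub("[+-]$", "", sub("^CHARGE=", "", line))))
        } else if (grepl("^[A-Z]+=", line) || !nzchar(trimws(line))) {
          # other KEY=value headers and blank lines are tolerated
        } else {
          parts <- strsplit(trimws(line), "[ \t]+")[[1]]
          vals <- parse_num(parts)
          if (length(vals) < 2L || anyNA(vals[1:2]))
            stopf("MGF parse error at line %d: non-numeric peak line %s",
                  i, dQuote(line))
          mz <- c(mz, vals[1L]); inten <- c(inten, vals[2L])
        }
        i <- i + 1L
      }
      if (!ended)
        stopf("MGF parse error: block starting at line %d has no END IONS", begin_line)
      if (is.na(title))
        stopf("MGF parse error: block starting at line %d has no TITLE", begin_line)
      spectra[[length(spectra) + 1L]] <-
        ms2_spectrum(title = title, peaks = cbind(mz, inten),
                     precursor_mz = pepmass, precursor_charge = charge,
                     source_file = src)
    } else {
      i <- i + 1L
    }
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()]: `read_mgf(write_mgf(s, path))` reproduces titles,
#' precursor fields and peak lists (m/z written with 6 decimals, intensities
#' with 4).
#'
#' @param spectra list of `ms2_spectrum` objects (may be empty)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mgf <- function(spectra, path) {
  out <- character(0)
  for (sp in spectra) {
    stopifnot(inherits(sp, "ms2_spectrum"))
    block <- c("BEGIN IONS", paste0("TITLE=", sp$title))
    if (!is.na(sp$precursor_mz))
      block <- c(block, paste0("PEPMASS=", fmt_num(sp$precursor_mz, 6L)))
    if (!is.na(sp$precursor_charge))
      block <- c(block, sprintf("CHARGE=%d+", sp$precursor_charge))
    if (nrow(sp$peaks) > 0L)
      block <- c(block, paste(fmt_num(sp$peaks[, 1L], 6L),
                              fmt_num(sp$peaks[, 2L], 4L)))
    out <- c(out, block, "END IONS", "")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(out)) writeLines(out, con)
  invisible(path)
}
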