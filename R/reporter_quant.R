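#' Reporter-ion reference table
#'
#' Builds the table of reporter channel labels and theoretical monoisotopic
#' m/z values used for ppm matching. The built-in `"tmtpro18"` plex is
#' computed from the TMTpro reporter ion elemental composition
#' (C8H16N+, 126.127726 Th for channel 126) plus exact 13C-12C and 15N-14N
#' mass differences, which reproduces the published channel masses; any other
#' plex can be supplied as a data.frame with columns `label` and `mz`.
#'
#' @param plex `"tmtpro18"`, or a data.frame with columns `label` (unique
#'   character) and `mz` (strictly increasing numeric, Thomson)
#' @param tol_ppm tolerance used only to warn when adjacent channels are
#'   closer than twice the tolerance window (overlap risk)
#' @return a `reporter_ref` data.frame with columns `label`, `mz`
#' @export
reporter_ref <- function(plex = "tmtpro18", tol_ppm = 15) {
  if (is.character(plex) && length(plex) == 1L) {
    if (plex != "tmtpro18") stopf("unknown built-in plex: %s", plex)
    d13C <- 13.00335483507 - 12            # 13C - 12C
    d15N <- 15.0001088989 - 14.0030740048  # 15N - 14N
    e    <- 0.000548579909                 # electron mass
    base <- 8 * 12 + 16 * 1.00782503207 + 14.0030740048 - e  # C8H16N+
    labels <- c("126", paste0(rep(127:134, each = 2), c("N", "C")), "135N")
    k <- c(0, rep(1:8, each = 2), 9)        # nominal mass offset from 126
    isN <- grepl("N$", labels)
    mz <- base + ifelse(isN, (k - 1) * d13C + d15N, k * d13C)
    ref <- data.frame(label = labels, mz = mz, stringsAsFactors = FALSE)
    plex_name <- "tmtpro18"
  } else {
    ref <- as.data.frame(plex)
    if (!all(c("label", "mz") %in% names(ref)))
      stopf("custom plex needs columns 'label' and 'mz'")
    ref <- ref[, c("label", "mz")]
    ref$label <- as.character(ref$label)
    plex_name <- "custom"
  }
  if (anyDuplicated(ref$label)) stopf("reporter labels must be unique")
  if (is.unsorted(ref$mz, strictly = TRUE))
    stopf("reporter m/z values must be strictly increasing")
  gaps <- diff(ref$mz)
  win <- 2 * ref$mz[-1] * tol_ppm * 1e-6
  if (any(gaps <= win))
    warnf("adjacent reporter channels closer than twice the %g ppm tolerance; matches may overlap", tol_ppm)
  structure(ref, class = c("reporter_ref", "data.frame"), plex_name = plex_name)
}

#' Match reporter ions in one spectrum
#'
#' Scans the low-mass region of an MS2 spectrum (peaks up to
#' `max(ref$mz) + 1` Th) and matches peaks against each reporter channel
#' within a ppm tolerance: a peak matches channel c when
#' `|mz - ref_mz| / ref_mz * 1e6 <= tol_ppm` (boundary inclusive). When
#' several peaks fall within tolerance of one channel their intensities are
#' summed; the reported absolute delta m/z is that of the most intense
#' matched peak. A peak lying within tolerance of two channels (possible
#' only at tolerances well above the recommended range) is assigned to the
#' nearer channel only. Channels with no match get intensity 0 and `NA`
#' delta. Tolerances above 20 ppm trigger a warning because they exceed half
#' the spacing of adjacent reporter ions.
#'
#' @param spectrum an [ms2_spectrum()]
#' @param ref a [reporter_ref()]
#' @param tol_ppm matching tolerance in ppm (> 0; default 15)
#' @return list with `intensity` and `delta_mz` (named per channel),
#'   `mgf_file` and `spectrum_title`
#' @export
match_reporters <- function(spectrum, ref, tol_ppm = 15) {
  stopifnot(inherits(spectrum, "ms2_spectrum"), inherits(ref, "reporter_ref"))
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0)
    stopf("tol_ppm must be a single positive number")
  if (tol_ppm > 20)
    warnf("tolerance %g ppm exceeds 20 ppm; adjacent reporter ions may be integrated together", tol_ppm)
  nchan <- nrow(ref)
  intensity <- stats::setNames(numeric(nchan), ref$label)
  delta <- stats::setNames(rep(NA_real_, nchan), ref$label)
  pk <- spectrum$peaks
  if (nrow(pk)) {
    sel <- pk[, 1L] <= max(ref$mz) + 1
    pk <- pk[sel, , drop = FALSE]
  }
  if (nrow(pk)) {
    # nearest channel per peak, then the inclusive ppm test; nearest-first
    # assignment guarantees a peak is never counted in two channels
    idx <- findInterval(pk[, 1L], ref$mz)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nchan)
    nearer <- ifelse(abs(pk[, 1L] - ref$mz[lo]) <= abs(pk[, 1L] - ref$mz[hi]), lo, hi)
    dmz <- abs(pk[, 1L] - ref$mz[nearer])
    # tiny relative slack keeps the inclusive boundary robust to the
    # floating-point rounding of mz = ref * (1 +/- tol * 1e-6)
    ok <- dmz / ref$mz[nearer] * 1e6 <= tol_ppm * (1 + 1e-9)
    if (any(ok)) {
      ch <- nearer[ok]
      iv <- pk[ok, 2L]
      dv <- dmz[ok]
      for (c_i in unique(ch)) {
        m <- ch == c_i
        intensity[c_i] <- sum(iv[m])
        delta[c_i] <- dv[m][which.max(iv[m])]
      }
    }
  }
  list(mgf_file = spectrum$source_file, spectrum_title = spectrum$title,
       intensity = intensity, delta_mz = delta)
}

#' Extract a reporter-ion table from a directory of MGF files
#'
#' Runs [match_reporters()] over every spectrum of every `.mgf` file in a
#' directory and assembles the extraction table: one row per MS2 spectrum,
#' with columns `mgf_file`, `spectrum_title`, one raw-intensity column per
#' channel (named by the channel label) and one absolute delta m/z column per
#' channel (`dmz_<label>`). Row order is deterministic: file name
#' (lexicographic), then spectrum order within the file.
#'
#' @param mgf_dir directory containing at least one `.mgf` file
#' @param ref a [reporter_ref()]
#' @param tol_ppm matching tolerance in ppm
#' @param normalize if `TRUE`, append channel-total normalized columns via
#'   [normalize_channel_totals()]. Off by default: total-signal equality
#'   across channels does not hold for fractionated or intentionally
#'   unbalanced designs.
#' @param out optional path; when given the table is also written
#'   tab-delimited with a header row
#' @return data.frame (the extraction table)
#' @export
extract_table <- function(mgf_dir, ref, tol_ppm = 15, normalize = FALSE,
                          out = NULL) {
  files <- sort(list.files(mgf_dir, pattern = "\\.mgf$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stopf("no MGF files found in directory: %s", mgf_dir)
  rows <- list()
  for (f in files) {
    for (sp in read_mgf(f)) {
      rows[[length(rows) + 1L]] <- match_reporters(sp, ref, tol_ppm = tol_ppm)
    }
  }
  tab <- data.frame(
    mgf_file = vapply(rows, `[[`, "", "mgf_file"),
    spectrum_title = vapply(rows, `[[`, "", "spectrum_title"),
    stringsAsFactors = FALSE, check.names = FALSE)
  im <- do.call(rbind, lapply(rows, `[[`, "intensity"))
  dm <- do.call(rbind, lapply(rows, `[[`, "delta_mz"))
  colnames(dm) <- paste0("dmz_", ref$label)
  tab <- cbind(tab, as.data.frame(im, check.names = FALSE),
               as.data.frame(dm, check.names = FALSE))
  rownames(tab) <- NULL
  if (isTRUE(normalize)) tab <- normalize_channel_totals(tab, ref)
  if (!is.null(out)) write_reporter_table(tab, out)
  tab
}

#' Channel-total normalization of a reporter table
#'
#' For each channel c, the factor is `f_c = total_c / max(total)` over the
#' whole table; normalized values are `raw / f_c`, so after normalization
#' every channel's total equals the pre-normalization maximum channel total.
#' Appends columns `norm_<label>`; raw columns are retained. A channel whose
#' total is zero has no defined factor and passes through unchanged with a
#' warning. This assumes equal total signal per channel and is therefore not
#' applied by default.
#'
#' @param tab extraction table from [extract_table()]
#' @param ref the [reporter_ref()] used to build it
#' @return `tab` with `norm_<label>` columns appended
#' @export
normalize_channel_totals <- function(tab, ref) {
  if (!nrow(tab)) stopf("empty reporter table")
  raw <- as.matrix(tab[, ref$label, drop = FALSE])
  totals <- colSums(raw)
  if (max(totals) <= 0) stopf("all channel totals are zero")
  f <- totals / max(totals)
  zero <- f == 0
  if (any(zero)) {
    warnf("channel(s) with zero total left unnormalized: %s",
          paste(ref$label[zero], collapse = ", "))
    f[zero] <- 1
  }
  norm <- sweep(raw, 2L, f, "/")
  colnames(norm) <- paste0("norm_", ref$label)
  cbind(tab, as.data.frame(norm, check.names = FALSE))
}

#' Write a reporter extraction table
#'
#' Tab-delimited, UTF-8, header row, numeric cells with 4 decimals (deltas
#' with 6); unmatched deltas are empty cells.
#'
#' @param tab extraction table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_reporter_table <- function(tab, path) {
  out <- tab
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      digits <- if (grepl("^dmz_", names(out)[j])) 6L else 4L
      out[[j]] <- fmt_num(out[[j]], digits)
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a reporter extraction table written by [write_reporter_table()]
#' @param path file path
#' @return data.frame with numeric channel columns
#' @export
read_reporter_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  for (j in seq_along(tab))
    if (!names(tab)[j] %in% c("mgf_file", "spectrum_title"))
      tab[[j]] <- parse_num(as.character(tab[[j]]))
  tab
}
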