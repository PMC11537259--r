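#' @name plink_csv_dialect
#' @title The hierarchical cross-link CSV dialect
#' @description
#' pLink2-style "cross-linked peptides" reports are hierarchical CSV files
#' with three row levels, distinguished here by the number of leading empty
#' fields:
#'
#' * protein header rows (no leading empty field):
#'   `Protein_Order,Proteins,Protein_Type`
#' * peptide header rows (one leading empty field):
#'   `,Peptide_Order,Peptide,Peptide_Type,Proteins`
#' * PSM rows (two leading empty fields):
#'   `,,Spectrum_Order,Title,Charge,Score`
#'
#' The three header lines appear once at the top of the file, then data rows
#' follow in hierarchical order (each peptide under its protein, each PSM
#' under its peptide). Site notation: a cross-linked peptide pair is written
#' `"PEPTKA(5)-MSEQKR(4)"` (link position in parentheses, 1-based within the
#' peptide), a loop-linked peptide `"PEPKTLK(4)(7)"`, a monolinked peptide
#' `"PEPTK(5)"`, and a regular peptide has no parentheses. The peptide-level
#' `Proteins` field carries protein sites in the same notation, with `-`
#' separating the two sides and `;` separating alternative protein mappings
#' of a shared peptide (accessions must therefore not contain `-` or `;`).
#' When reporter intensities have been attached, per-channel columns are
#' appended at every level (plus a `Quantified` flag on PSM rows).
NULL

PEPTIDE_TYPES <- c("Cross-Linked" = "cross", "Loop-Linked" = "loop",
                   "Mono-Linked" = "mono", "Regular" = "regular")

# split one CSV line honoring double-quoted fields (tolerant reader:
# quoted commas occur in real protein lists)
csv_split_lines <- function(lines) {
  stripped <- gsub('"[^"]*"', "", lines)
  nfields <- lengths(regmatches(stripped, gregexpr(",", stripped, fixed = TRUE))) + 1L
  maxf <- max(nfields, 1L)
  tab <- utils::read.csv(text = paste(lines, collapse = "\n"), header = FALSE,
                         colClasses = "character",
                         col.names = paste0("V", seq_len(maxf)),
                         stringsAsFactors = FALSE, blank.lines.skip = FALSE,
                         na.strings = character(0), fill = TRUE)
  as.matrix(tab)
}

csv_quote <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  need <- grepl('[",]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Parse a hierarchical cross-link CSV report
#'
#' Reads a pLink2-style report (see [plink_csv_dialect]) into a
#' `plink_report`: three data.frames (`proteins`, `peptides`, `csms`) that
#' preserve the hierarchy through `protein_order` / `peptide_order` keys.
#' Counts of protein headers, peptide headers and PSM rows are preserved
#' exactly; malformed rows are errors (with their line number), never
#' silently skipped, because silent row loss corrupts quantification.
#'
#' @param path path to the CSV file
#' @return object of class `plink_report`
#' @export
parse_plink_csv <- function(path) {
  if (!file.exists(path)) stopf("pLink CSV not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty pLink CSV: %s", path)
  m <- csv_split_lines(lines)
  lead0 <- nzchar(m[, 1L])
  lead1 <- !lead0 & nzchar(m[, 2L])
  lead2 <- !lead0 & !lead1 & ncol(m) >= 3L & nzchar(m[, 3L])
  level <- ifelse(lead0, 0L, ifelse(lead1, 1L, ifelse(lead2, 2L, NA_integer_)))
  if (anyNA(level))
    stopf("pLink CSV parse error at line %d: unrecognized row shape",
          which(is.na(level))[1L])
  is_header <- (level == 0L & m[, 1L] == "Protein_Order") |
               (level == 1L & m[, 2L] == "Peptide_Order") |
               (level == 2L & m[, 3L] == "Spectrum_Order")
  chan_prot <- character(0)
  hdr0 <- which(is_header & level == 0L)
  if (length(hdr0)) {
    extras <- m[hdr0[1L], -(1:3)]
    chan_prot <- extras[nzchar(extras)]
  }
  hdr2 <- which(is_header & level == 2L)
  chan_psm <- character(0)
  if (length(hdr2)) {
    extras <- m[hdr2[1L], -(1:6)]
    chan_psm <- setdiff(extras[nzchar(extras)], "Quantified")
  }
  channels <- if (length(chan_psm)) chan_psm else chan_prot

  proteins <- list(); peptides <- list(); csms <- list()
  cur_prot <- NA_integer_; cur_pep <- NA_integer_
  for (i in seq_len(nrow(m))) {
    if (is_header[i]) next
    row <- m[i, ]
    if (level[i] == 0L) {
      cur_prot <- as.integer(row[1L])
      rec <- list(protein_order = cur_prot, proteins = row[2L],
                  protein_type = row[3L])
      if (length(channels)) {
        v <- parse_num(row[4:(3 + length(channels))])
        names(v) <- channels
        rec$intensity <- list(v)
      }
      proteins[[length(proteins) + 1L]] <- rec
    } else if (level[i] == 1L) {
      if (is.na(cur_prot))
        stopf("pLink CSV parse error at line %d: peptide row before any protein header", i)
      cur_pep <- as.integer(row[2L])
      rec <- list(peptide_order = cur_pep, protein_order = cur_prot,
                  peptide = row[3L], peptide_type = row[4L], proteins = row[5L])
      if (length(channels)) {
        v <- parse_num(row[6:(5 + length(channels))])
        names(v) <- channels
        rec$intensity <- list(v)
      }
      peptides[[length(peptides) + 1L]] <- rec
    } else {
      if (is.na(cur_pep))
        stopf("pLink CSV parse error at line %d: PSM row before any peptide header", i)
      rec <- list(spectrum_order = as.integer(row[3L]),
                  peptide_order = cur_pep, protein_order = cur_prot,
                  title = row[4L], charge = as.integer(parse_num(row[5L])),
                  score = parse_num(row[6L]))
      if (length(channels)) {
        v <- parse_num(row[7:(6 + length(channels))])
        names(v) <- channels
        rec$intensity <- list(v)
        q <- if (ncol(m) >= 7L + length(channels)) row[7L + length(channels)] else ""
        rec$quantified <- identical(q, "TRUE")
      }
      csms[[length(csms) + 1L]] <- rec
    }
  }
  bind <- function(recs) {
    if (!length(recs)) return(NULL)
    cols <- names(recs[[1L]])
    out <- lapply(cols, function(cn) {
      vals <- lapply(recs, `[[`, cn)
      if (is.list(recs[[1L]][[cn]])) I(lapply(vals, `[[`, 1L)) else unlist(vals)
    })
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  structure(list(proteins = bind(proteins), peptides = bind(peptides),
                 csms = bind(csms), channels = channels, provenance = path),
            class = "plink_report")
}

#' @export
print.plink_report <- function(x, ...) {
  cat(sprintf("<plink_report> %d protein headers, %d peptide headers, %d PSMs%s\n",
              NROW(x$proteins), NROW(x$peptides), NROW(x$csms),
              if (length(x$channels)) sprintf(" (%d reporter channels attached)",
                                              length(x$channels)) else ""))
  invisible(x)
}

#' Write a hierarchical cross-link CSV report
#'
#' Inverse of [parse_plink_csv()]: all original fields are preserved and any
#' attached reporter intensity columns are appended at each hierarchy level
#' (see [plink_csv_dialect]).
#'
#' @param report a `plink_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_plink_csv <- function(report, path) {
  stopifnot(inherits(report, "plink_report"))
  ch <- report$channels
  fmt_int <- function(v) fmt_num(unname(v), 4L)
  lines <- c(
    paste(c("Protein_Order", "Proteins", "Protein_Type", ch), collapse = ","),
    paste(c("", "Peptide_Order", "Peptide", "Peptide_Type", "Proteins", ch),
          collapse = ","),
    paste(c("", "", "Spectrum_Order", "Title", "Charge", "Score", ch,
            if (length(ch)) "Quantified"), collapse = ","))
  if (!length(ch)) lines <- sub(",+$", "", lines)
  body <- character(0)
  for (pi in seq_len(NROW(report$proteins))) {
    pr <- report$proteins[pi, ]
    fields <- csv_quote(c(pr$protein_order, pr$proteins, pr$protein_type))
    if (length(ch)) fields <- c(fields, fmt_int(pr$intensity[[1L]]))
    body <- c(body, paste(fields, collapse = ","))
    peps <- report$peptides[report$peptides$protein_order == pr$protein_order, ,
                            drop = FALSE]
    for (qi in seq_len(NROW(peps))) {
      pe <- peps[qi, ]
      fields <- csv_quote(c("", pe$peptide_order, pe$peptide, pe$peptide_type,
                            pe$proteins))
      if (length(ch)) fields <- c(fields, fmt_int(pe$intensity[[1L]]))
      body <- c(body, paste(fields, collapse = ","))
      psms <- report$csms[report$csms$peptide_order == pe$peptide_order, ,
                          drop = FALSE]
      for (si in seq_len(NROW(psms))) {
        ps <- psms[si, ]
        fields <- csv_quote(c("", "", ps$spectrum_order, ps$title, ps$charge,
                              formatC(ps$score, format = "g", digits = 8)))
        if (length(ch))
          fields <- c(fields, fmt_int(ps$intensity[[1L]]),
                      as.character(isTRUE(ps$quantified)))
        body <- c(body, paste(fields, collapse = ","))
      }
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, body), con)
  invisible(path)
}

# parse "PEPTK(5)-MSEQR(3)" / "PEPKTLK(4)(7)" / "PEPTK(5)" / "PEPTIDER"
parse_peptide_token <- function(tok) {
  sides <- strsplit(tok, "-", fixed = TRUE)[[1L]]
  parse_side <- function(s) {
    seqs <- gsub("\\(\\d+\\)", "", s)
    pos <- as.integer(unlist(regmatches(s, gregexpr("(?<=\\()\\d+(?=\\))", s,
                                                    perl = TRUE))))
    list(seq = seqs, pos = pos)
  }
  if (length(sides) == 2L) {
    a <- parse_side(sides[1L]); b <- parse_side(sides[2L])
    list(peptide_a = a$seq, peptide_b = b$seq,
         link_pos_a = a$pos[1L], link_pos_b = b$pos[1L])
  } else {
    a <- parse_side(sides[1L])
    list(peptide_a = a$seq, peptide_b = "",
         link_pos_a = if (length(a$pos)) a$pos[1L] else NA_integer_,
         link_pos_b = if (length(a$pos) > 1L) a$pos[2L] else NA_integer_)
  }
}

# parse a protein-sites token like "P1(104);P3(88)-P2(55)" into the two
# sides' alternative (accession, site) lists
parse_protein_token <- function(tok) {
  sides <- strsplit(tok, "-", fixed = TRUE)[[1L]]
  parse_side <- function(s) {
    alts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    acc <- sub("\\(.*$", "", alts)
    has <- grepl("\\(\\d+\\)", alts)
    pos <- rep(NA_integer_, length(alts))
    pos[has] <- as.integer(sub("^[^(]*\\((\\d+)\\).*$", "\\1", alts[has]))
    data.frame(accession = acc, site = pos, stringsAsFactors = FALSE)
  }
  a <- parse_side(sides[1L])
  if (length(sides) == 2L) list(a = a, b = parse_side(sides[2L]))
  else {
    # loop/mono: positions may both sit on side a as "P1(10)(15)"
    pos2 <- as.integer(unlist(regmatches(sides[1L],
              gregexpr("(?<=\\()\\d+(?=\\))", sides[1L], perl = TRUE))))
    if (length(pos2) >= 2L) {
      acc <- sub("\\(.*$", "", strsplit(sides[1L], ";", fixed = TRUE)[[1L]][1L])
      list(a = data.frame(accession = acc, site = pos2[1L],
                          stringsAsFactors = FALSE),
           b = data.frame(accession = acc, site = pos2[2L],
                          stringsAsFactors = FALSE))
    } else list(a = a, b = NULL)
  }
}

#' Flatten a report into CSM records
#'
#' Joins the three hierarchy levels into one data.frame with one row per
#' PSM: peptide sequences, link positions (1-based within the peptide),
#' protein mappings (side tokens, `;`-separated alternatives), link type
#' (`cross`, `loop`, `mono`, `regular`), score, title, and any attached
#' reporter intensities as an `intensity` list-column.
#'
#' @param report a `plink_report`
#' @return data.frame of CSM records
#' @export
csm_records <- function(report) {
  stopifnot(inherits(report, "plink_report"))
  if (!NROW(report$csms)) return(NULL)
  pep <- report$peptides[match(report$csms$peptide_order,
                               report$peptides$peptide_order), ]
  ptok <- strsplit(pep$proteins, "-", fixed = TRUE)
  parsed <- lapply(pep$peptide, parse_peptide_token)
  out <- data.frame(
    spectrum_title = report$csms$title,
    peptide_a = vapply(parsed, `[[`, "", "peptide_a"),
    peptide_b = vapply(parsed, `[[`, "", "peptide_b"),
    link_pos_a = vapply(parsed, function(p) as.integer(p$link_pos_a), 1L),
    link_pos_b = vapply(parsed, function(p) as.integer(p$link_pos_b), 1L),
    proteins_a = vapply(ptok, `[[`, "", 1L),
    proteins_b = vapply(ptok, function(t) if (length(t) > 1L) t[[2L]] else "", ""),
    link_type = unname(PEPTIDE_TYPES[pep$peptide_type]),
    score = report$csms$score,
    charge = report$csms$charge,
    stringsAsFactors = FALSE)
  if (length(report$channels)) {
    out$intensity <- report$csms$intensity
    out$quantified <- if (!is.null(report$csms$quantified))
      report$csms$quantified else !vapply(out$intensity, anyNA, TRUE)
  }
  out
}

#' Normalize spectrum titles for matching
#'
#' `"exact"` strips leading/trailing whitespace only. `"scan"` reduces a
#' `file.scan.scan.charge(.ext)?.dta`-style title to `file.scan.charge`,
#' which reconciles converters that disagree on title decorations.
#'
#' @param titles character vector
#' @param rule `"exact"` or `"scan"`
#' @return normalized character vector
#' @export
normalize_title <- function(titles, rule = c("exact", "scan")) {
  rule <- match.arg(rule)
  t <- trimws(titles)
  if (rule == "scan")
    t <- sub("^(.*)\\.(\\d+)\\.\\2\\.(\\d+)(\\.\\d+)?\\.dta$", "\\1.\\2.\\3", t,
             perl = TRUE)
  t
}

#' Attach reporter intensities to PSMs
#'
#' Matches each PSM's spectrum title against the reporter extraction table
#' (after the configured title normalization) and attaches that row's
#' per-channel intensities. PSMs without a matching table row carry an
#' explicit no-quant flag (`quantified = FALSE`, zero intensities) and are
#' counted in a message. Duplicate normalized titles in the table are an
#' error: the mapping would be ambiguous.
#'
#' @param report a `plink_report`
#' @param table reporter table from [extract_table()]
#' @param title_rule see [normalize_title()]
#' @return the annotated `plink_report`
#' @export
attach_reporters <- function(report, table, title_rule = c("exact", "scan")) {
  stopifnot(inherits(report, "plink_report"))
  title_rule <- match.arg(title_rule)
  channels <- setdiff(names(table),
                      c("mgf_file", "spectrum_title",
                        grep("^(dmz_|norm_)", names(table), value = TRUE)))
  if (!length(channels)) stopf("reporter table has no channel columns")
  key <- normalize_title(table$spectrum_title, title_rule)
  if (anyDuplicated(key))
    stopf("duplicate spectrum titles in reporter table (after '%s' normalization): %s",
          title_rule, key[duplicated(key)][1L])
  idx <- match(normalize_title(report$csms$title, title_rule), key)
  im <- as.matrix(table[, channels, drop = FALSE])
  ints <- lapply(seq_len(NROW(report$csms)), function(i) {
    v <- if (is.na(idx[i])) rep(0, length(channels)) else im[idx[i], ]
    stats::setNames(as.numeric(v), channels)
  })
  report$csms$intensity <- I(ints)
  report$csms$quantified <- !is.na(idx)
  n_miss <- sum(is.na(idx))
  if (n_miss) message(sprintf("attach_reporters: %d of %d PSMs had no matching spectrum (no-quant)",
                              n_miss, length(idx)))
  report$channels <- channels
  report
}

#' Roll reporter intensities up the hierarchy
#'
#' Channel-wise sums: each peptide header receives the sum over its PSMs,
#' each protein header the sum over its peptides. No-quant PSMs contribute
#' zero, so per-channel totals are conserved across all three levels.
#'
#' @param report a `plink_report` with reporters attached
#' @return the report with `intensity` columns on `peptides` and `proteins`
#' @export
rollup <- function(report) {
  stopifnot(inherits(report, "plink_report"))
  if (!length(report$channels)) stopf("attach reporters before rollup")
  ch <- report$channels
  psm_mat <- do.call(rbind, report$csms$intensity)
  pep_sum <- rowsum(psm_mat, group = report$csms$peptide_order)
  pep_idx <- match(as.character(report$peptides$peptide_order),
                   rownames(pep_sum))
  report$peptides$intensity <- I(lapply(seq_len(NROW(report$peptides)),
    function(i) {
      v <- if (is.na(pep_idx[i])) rep(0, length(ch)) else pep_sum[pep_idx[i], ]
      stats::setNames(as.numeric(v), ch)
    }))
  pep_mat <- do.call(rbind, report$peptides$intensity)
  prot_sum <- rowsum(pep_mat, group = report$peptides$protein_order)
  prot_idx <- match(as.character(report$proteins$protein_order),
                    rownames(prot_sum))
  report$proteins$intensity <- I(lapply(seq_len(NROW(report$proteins)),
    function(i) {
      v <- if (is.na(prot_idx[i])) rep(0, length(ch)) else prot_sum[prot_idx[i], ]
      stats::setNames(as.numeric(v), ch)
    }))
  report
}
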