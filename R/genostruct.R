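#' Read a missense mutation table
#'
#' Tab-delimited with columns `gene`, `cell_line`, `position` (1-based
#' residue), as exportable from catalogues of somatic mutations. Only
#' missense entries should be supplied; the package does not interpret
#' variant classes.
#'
#' @param path TSV path
#' @return data.frame of mutation entries
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("gene", "cell_line", "position") %in% names(df)))
    stopf("mutation table needs columns gene, cell_line, position")
  df$position <- as.integer(df$position)
  if (any(df$position < 1L)) stopf("mutation positions must be >= 1")
  df
}

#' Binary mutation presence matrix
#'
#' Gene x cell line matrix where 1 marks at least one missense mutation of
#' that gene in that cell line and 0 its absence.
#'
#' @param mutations mutation entries (see [read_mutation_table()])
#' @param cell_lines optional full set of cell lines for the columns
#' @return integer matrix
#' @export
mutation_binary_matrix <- function(mutations, cell_lines = NULL) {
  if (is.null(cell_lines)) cell_lines <- sort(unique(mutations$cell_line))
  genes <- sort(unique(mutations$gene))
  m <- matrix(0L, length(genes), length(cell_lines),
              dimnames = list(genes, cell_lines))
  idx <- cbind(match(mutations$gene, genes),
               match(mutations$cell_line, cell_lines))
  m[idx[!is.na(idx[, 2L]), , drop = FALSE]] <- 1L
  m
}

#' Aggregate mutation positions per gene into label strings
#'
#' Formats, per gene, the string `"GENE | LINE_pos; LINE_pos; ..."` in the
#' input row order, the convention used to annotate mutated cross-links.
#'
#' @param mutations mutation entries
#' @return named character vector (one label per gene)
#' @export
aggregate_mutation_labels <- function(mutations) {
  vapply(split(mutations, mutations$gene)[unique(mutations$gene)],
         function(d) sprintf("%s | %s", d$gene[1L],
                             paste0(d$cell_line, "_", d$position,
                                    collapse = "; ")),
         "")
}

#' Regress protein abundance out of intralink profiles
#'
#' For each intralinked residue pair, fits ordinary least squares of the
#' cross-link's scaled-log2 profile (y) on its protein's scaled-log2
#' abundance profile (x), with intercept, across samples. The residuals are
#' the net cross-linking differences: what remains of the cross-link's
#' variation after its protein's expression is accounted for. The protein
#' matrix must have been normalized and scaled the same way as the
#' cross-link data. Intralinks whose protein is absent from the protein
#' matrix are skipped and counted; a predictor with zero variance leaves
#' the slope undefined, in which case the intercept-only residuals are
#' returned with a warning.
#'
#' @param xl a `residue_pair_quant` at stage `scaled_log2`; only intra rows
#'   are used
#' @param prot numeric matrix of protein scaled-log2 values, rownames =
#'   accessions, columns = the same samples as `xl`
#' @return object of class `regressed_profiles`: list with `keys`,
#'   `residuals` (pairs x samples), `slope`, `intercept`, `accession`,
#'   `n_skipped`
#' @export
regress_out_protein <- function(xl, prot) {
  stopifnot(inherits(xl, "residue_pair_quant"))
  if (xl$stage != "scaled_log2")
    stopf("regress_out_protein expects stage 'scaled_log2', got '%s'", xl$stage)
  if (!identical(colnames(prot), xl$samples))
    stopf("protein matrix columns must equal the cross-link samples")
  intra <- xl$keys$is_intra
  keys <- xl$keys[intra, , drop = FALSE]
  vals <- xl$values[intra, , drop = FALSE]
  have <- keys$protein_a %in% rownames(prot)
  n_skipped <- sum(!have)
  if (n_skipped)
    message(sprintf("regress_out_protein: %d intralink(s) skipped (protein not quantified)",
                    n_skipped))
  keys <- keys[have, , drop = FALSE]
  vals <- vals[have, , drop = FALSE]
  if (!nrow(vals)) stopf("no intralinks with a quantified protein")
  n <- nrow(vals)
  resid <- matrix(NA_real_, n, ncol(vals), dimnames = dimnames(vals))
  slope <- numeric(n); intercept <- numeric(n)
  for (i in seq_len(n)) {
    x <- prot[keys$protein_a[i], ]
    y <- vals[i, ]
    if (stats::var(x) == 0) {
      warnf("zero-variance protein profile for %s; intercept-only model used",
            keys$protein_a[i])
      slope[i] <- NA_real_
      intercept[i] <- mean(y)
      resid[i, ] <- y - mean(y)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      slope[i] <- fit$coefficients[2L]
      intercept[i] <- fit$coefficients[1L]
      resid[i, ] <- fit$residuals
    }
  }
  structure(list(keys = keys, residuals = resid, slope = slope,
                 intercept = intercept, accession = keys$protein_a,
                 samples = xl$samples, n_skipped = n_skipped),
            class = "regressed_profiles")
}

#' @export
print.regressed_profiles <- function(x, ...) {
  cat(sprintf("<regressed_profiles> %d intralinks x %d samples (%d skipped)\n",
              nrow(x$residuals), ncol(x$residuals), x$n_skipped))
  invisible(x)
}

#' Overlap missense mutations with cross-link intervals
#'
#' A (pair, cell line) overlap exists when some missense mutation of the
#' pair's gene in that cell line lies within the closed interval
#' `[min(pos_a, pos_b), max(pos_a, pos_b)]` — boundary mutations alter a
#' cross-linked residue itself and count as inside. Gene symbols are mapped
#' to accessions through an explicit mapping table (no network lookups);
#' mutations of unmapped genes are reported and excluded.
#'
#' @param pairs data.frame of intralink keys (columns `protein_a`, `pos_a`,
#'   `pos_b`, `key`), e.g. intra rows of [to_residue_pairs()] output
#' @param mutations mutation entries (`gene`, `cell_line`, `position`)
#' @param gene_map data.frame mapping `gene` to `accession`
#' @return data.frame with one row per (pair, cell line) overlap: `key`,
#'   `cell_line`, `positions` (`;`-collapsed), `n_mutations`
#' @export
mutation_overlap <- function(pairs, mutations, gene_map) {
  if (!all(c("gene", "accession") %in% names(gene_map)))
    stopf("gene_map needs columns gene, accession")
  acc <- gene_map$accession[match(mutations$gene, gene_map$gene)]
  if (anyNA(acc)) {
    bad <- unique(mutations$gene[is.na(acc)])
    message(sprintf("mutation_overlap: unmapped gene(s) excluded: %s",
                    paste(bad, collapse = ", ")))
  }
  mut <- mutations[!is.na(acc), , drop = FALSE]
  mut$accession <- acc[!is.na(acc)]
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    lo <- min(pairs$pos_a[i], pairs$pos_b[i])
    hi <- max(pairs$pos_a[i], pairs$pos_b[i])
    hit <- mut[mut$accession == pairs$protein_a[i] &
               mut$position >= lo & mut$position <= hi, , drop = FALSE]
    if (!nrow(hit)) next
    for (cl in unique(hit$cell_line)) {
      p <- hit$position[hit$cell_line == cl]
      out[[length(out) + 1L]] <- data.frame(
        key = pairs$key[i], cell_line = cl,
        positions = paste(sort(p), collapse = ";"),
        n_mutations = length(p), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(key = character(0), cell_line = character(0),
                      positions = character(0), n_mutations = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select mutation-associated structural events
#'
#' For each (intralink, mutated cell line) overlap, an event is kept when
#' the regressed log2 value satisfies both filters: absolute value above
#' `lfc_cut` (default 0.4) and above `sd_mult` (default 2) times the sample
#' standard deviation of that pair's values across all cell lines. Replicate
#' channels of one cell line are averaged before testing (switchable). The
#' retained value is discretized to its sign: -1 for decreased, +1 for
#' increased cross-linking in the mutated line. No multiple-testing
#' correction is applied; the thresholds themselves are the selection rule.
#'
#' @param profiles a `regressed_profiles`
#' @param overlaps output of [mutation_overlap()]
#' @param replicate_map named character vector sample -> cell line; when
#'   `NULL`, sample labels are taken as cell lines directly
#' @param lfc_cut absolute regressed-log2 cutoff
#' @param sd_mult multiplier of the per-pair SD across cell lines
#' @param average_replicates average replicate channels per cell line before
#'   filtering (default `TRUE`)
#' @return data.frame of events: `key`, `cell_line`, `residual`, `sign`,
#'   `positions`
#' @export
select_events <- function(profiles, overlaps, replicate_map = NULL,
                          lfc_cut = 0.4, sd_mult = 2,
                          average_replicates = TRUE) {
  stopifnot(inherits(profiles, "regressed_profiles"))
  resid <- profiles$residuals
  if (is.null(replicate_map))
    replicate_map <- stats::setNames(colnames(resid), colnames(resid))
  lines <- replicate_map[colnames(resid)]
  if (average_replicates) {
    mat <- t(rowsum(t(resid), group = lines) / as.vector(table(lines)[sort(unique(lines))]))
  } else {
    mat <- resid
    colnames(mat) <- lines
  }
  row_sd <- apply(mat, 1L, stats::sd)
  out <- list()
  for (j in seq_len(nrow(overlaps))) {
    key <- overlaps$key[j]; cl <- overlaps$cell_line[j]
    i <- match(key, rownames(mat))
    if (is.na(i) || !cl %in% colnames(mat)) next
    vals <- mat[i, colnames(mat) == cl]
    for (r in vals) {
      if (abs(r) > lfc_cut && abs(r) > sd_mult * row_sd[i]) {
        out[[length(out) + 1L]] <- data.frame(
          key = key, cell_line = cl, residual = r,
          sign = ifelse(r < 0, -1L, 1L),
          positions = overlaps$positions[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(key = character(0), cell_line = character(0),
                      residual = numeric(0), sign = integer(0),
                      positions = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
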