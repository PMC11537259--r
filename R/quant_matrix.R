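#' Residue-pair quantification matrix
#'
#' Container for summed reporter intensities keyed by canonical protein
#' residue pairs (rows) and samples/channels (columns), tagged with its
#' processing stage: `raw` (summed intensities), `normalized` (sample
#' totals equalized), `scaled_log2` (row-mean scaled, log2), or `regressed`
#' (protein abundance regressed out).
#'
#' @param keys data.frame with columns `protein_a`, `pos_a`, `protein_b`,
#'   `pos_b`, `origin`, `key` (unique)
#' @param values numeric matrix, `nrow(keys)` x `length(samples)`
#' @param samples sample (channel) labels
#' @param stage processing-stage tag
#' @return object of class `residue_pair_quant`
#' @export
residue_pair_quant <- function(keys, values, samples,
                               stage = c("raw", "normalized", "scaled_log2",
                                         "regressed")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (nrow(values) != nrow(keys))
    stopf("values and keys disagree on row count")
  if (ncol(values) != length(samples))
    stopf("values and samples disagree on column count")
  if (anyDuplicated(keys$key)) stopf("duplicated residue-pair keys")
  if (stage %in% c("raw", "normalized") && any(values < 0, na.rm = TRUE))
    stopf("%s-stage values must be non-negative", stage)
  dimnames(values) <- list(keys$key, samples)
  structure(list(keys = keys, samples = samples, values = values,
                 stage = stage),
            class = "residue_pair_quant")
}

#' @export
print.residue_pair_quant <- function(x, ...) {
  cat(sprintf("<residue_pair_quant> %d residue pairs x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Aggregate CSM reporter intensities to unique residue pairs
#'
#' Channel-wise sum of reporter intensities over all CSMs of each canonical
#' residue pair. Only cross-links and long loop-links (sequence distance of
#' at least 5 amino acids, enforced upstream in [to_residue_pairs()]) enter;
#' shared-peptide links are excluded here, and monolinks, regular peptides
#' and short loops never reach this stage. CSMs without attached
#' quantification are dropped with a message.
#'
#' @param csms CSM records with an `intensity` list-column
#'   (see [attach_reporters()], [csm_records()])
#' @param annotations output of [to_residue_pairs()] on the same CSMs
#' @return a `residue_pair_quant` at stage `raw`
#' @export
aggregate_pairs <- function(csms, annotations) {
  csm_key <- attr(annotations, "csm_key")
  if (is.null(csm_key)) stopf("annotations lack the csm_key attribute")
  if (is.null(csms$intensity)) stopf("CSMs carry no reporter intensities")
  shared <- annotations$key[annotations$shared_peptide]
  quantified <- if (!is.null(csms$quantified)) csms$quantified else
    !vapply(csms$intensity, anyNA, TRUE)
  keep <- !is.na(csm_key) & !(csm_key %in% shared) & quantified
  n_noquant <- sum(!is.na(csm_key) & !(csm_key %in% shared) & !quantified)
  if (n_noquant)
    message(sprintf("aggregate_pairs: %d unquantified CSM(s) dropped", n_noquant))
  if (!any(keep)) stopf("no quantifiable CSMs after filtering")
  mat <- do.call(rbind, csms$intensity[keep])
  summed <- rowsum(mat, group = csm_key[keep])
  keys <- annotations[match(rownames(summed), annotations$key),
                      c("protein_a", "pos_a", "protein_b", "pos_b", "origin",
                        "is_intra", "csm_count", "key")]
  rownames(keys) <- NULL
  residue_pair_quant(keys, summed, colnames(mat), stage = "raw")
}

#' Sample-total normalization
#'
#' For each sample s the normalization factor is
#' `f_s = total_s / max_t(total_t)` over the aggregated matrix; values are
#' divided by their sample's factor, so afterwards every sample total equals
#' the pre-normalization maximum total. Rank order of pairs within a sample
#' and all cross-pair ratios within a sample are preserved. A sample with
#' zero total has no defined factor and is an error.
#'
#' @param q a `residue_pair_quant` at stage `raw`
#' @return a `residue_pair_quant` at stage `normalized`
#' @export
normalize_samples <- function(q) {
  stopifnot(inherits(q, "residue_pair_quant"))
  if (q$stage != "raw") stopf("normalize_samples expects stage 'raw', got '%s'", q$stage)
  totals <- colSums(q$values)
  if (any(totals <= 0))
    stopf("sample(s) with non-positive total: %s",
          paste(q$samples[totals <= 0], collapse = ", "))
  f <- totals / max(totals)
  out <- sweep(q$values, 2L, f, "/")
  res <- residue_pair_quant(q$keys, out, q$samples, stage = "normalized")
  attr(res, "factors") <- stats::setNames(f, q$samples)
  res
}

#' Row-mean scaling and log2 transform
#'
#' Each row is divided by its mean across samples and log2-transformed:
#' `v' = log2(v / mean(v))`, so every retained row has linear-scale mean
#' exactly 1 before the log. Rows containing any zero are excluded
#' (complete-case) and counted in a message: the downstream comparisons
#' assume profiles with no missing values, and a pseudo-count would silently
#' distort ratios.
#'
#' @param q a `residue_pair_quant` at stage `normalized`
#' @return a `residue_pair_quant` at stage `scaled_log2`; attribute
#'   `n_dropped` counts the excluded zero-containing rows
#' @export
scale_log2 <- function(q) {
  stopifnot(inherits(q, "residue_pair_quant"))
  if (q$stage != "normalized")
    stopf("scale_log2 expects stage 'normalized', got '%s'", q$stage)
  has_zero <- apply(q$values <= 0, 1L, any)
  if (any(has_zero))
    message(sprintf("scale_log2: %d row(s) with zero intensities dropped", sum(has_zero)))
  v <- q$values[!has_zero, , drop = FALSE]
  if (!nrow(v)) stopf("no rows left after removing zero-containing rows")
  out <- log2(v / rowMeans(v))
  res <- residue_pair_quant(q$keys[!has_zero, , drop = FALSE], out, q$samples,
                            stage = "scaled_log2")
  attr(res, "n_dropped") <- sum(has_zero)
  res
}

#' Replicate coefficients of variation
#'
#' Per residue pair and per replicated cell line, CV% = sample standard
#' deviation / mean x 100, computed on the normalized (pre-log) intensities.
#' Cell lines represented by a single sample yield no CV. Both per-cell-line
#' and pooled medians are attached, since a summary "median CV" can be read
#' either way.
#'
#' @param q a `residue_pair_quant` at stage `normalized`
#' @param replicate_map named character vector: sample label -> cell line
#' @return matrix of CV percentages (pairs x replicated cell lines) with
#'   attributes `median_per_line` and `median_pooled`
#' @export
replicate_cv <- function(q, replicate_map) {
  stopifnot(inherits(q, "residue_pair_quant"))
  if (q$stage != "normalized")
    stopf("replicate_cv expects stage 'normalized', got '%s'", q$stage)
  if (is.null(names(replicate_map)) || !all(q$samples %in% names(replicate_map)))
    stopf("replicate_map must name every sample")
  lines <- replicate_map[q$samples]
  replicated <- names(which(table(lines) >= 2L))
  if (!length(replicated)) stopf("no cell line has two or more samples")
  cv <- sapply(replicated, function(cl) {
    v <- q$values[, lines == cl, drop = FALSE]
    apply(v, 1L, function(x) stats::sd(x) / mean(x) * 100)
  })
  cv <- matrix(cv, nrow = nrow(q$values),
               dimnames = list(rownames(q$values), replicated))
  attr(cv, "median_per_line") <- apply(cv, 2L, stats::median, na.rm = TRUE)
  attr(cv, "median_pooled") <- stats::median(cv, na.rm = TRUE)
  cv
}

#' Write a residue-pair quantification matrix
#'
#' Tab-delimited with a `# stage:` metadata header line, key columns, then
#' one column per sample.
#'
#' @param q a `residue_pair_quant`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_quant_matrix <- function(q, path) {
  stopifnot(inherits(q, "residue_pair_quant"))
  df <- cbind(q$keys[, c("protein_a", "pos_a", "protein_b", "pos_b", "origin")],
              as.data.frame(q$values, check.names = FALSE))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", q$stage), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  num <- vapply(df, is.numeric, TRUE) & !names(df) %in% c("pos_a", "pos_b")
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]], 6L)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' Read a matrix written by [write_quant_matrix()]
#' @param path file path
#' @return a `residue_pair_quant`
#' @export
read_quant_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- sub("^# stage: *", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  keycols <- c("protein_a", "pos_a", "protein_b", "pos_b", "origin")
  keys <- df[, keycols]
  keys$key <- paste0(keys$protein_a, ":", keys$pos_a, "--",
                     keys$protein_b, ":", keys$pos_b)
  vals <- as.matrix(df[, setdiff(names(df), keycols), drop = FALSE])
  residue_pair_quant(keys, vals, colnames(vals), stage = stage)
}
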