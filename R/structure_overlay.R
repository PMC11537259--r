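#' Construct a structure model
#'
#' Per-residue C-alpha coordinates and model confidence (pLDDT, 0-100) for
#' one protein model, e.g. an AlphaFold prediction. Residue indices must be
#' strictly increasing 1-based sequence positions.
#'
#' @param accession protein accession the model belongs to
#' @param index integer residue indices (strictly increasing)
#' @param xyz numeric matrix (n x 3) of CA coordinates in Angstrom
#' @param plddt per-residue confidence in `[0, 100]`
#' @return object of class `structure_model` (a data.frame)
#' @export
structure_model <- function(accession, index, xyz, plddt) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stopf("xyz must have 3 columns")
  if (is.unsorted(index, strictly = TRUE))
    stopf("residue indices must be strictly increasing")
  if (any(plddt < 0 | plddt > 100))
    stopf("pLDDT values must lie in [0, 100]")
  df <- data.frame(index = as.integer(index), x = xyz[, 1L], y = xyz[, 2L],
                   z = xyz[, 3L], plddt = as.numeric(plddt))
  structure(df, class = c("structure_model", "data.frame"),
            accession = accession)
}

#' Read C-alpha coordinates and pLDDT from a model PDB file
#'
#' Parses `ATOM` records of a PDB file (AlphaFold v4 flavour,
#' `AF-<accession>-F1-model_v4.pdb`), keeping CA atoms only. pLDDT is read
#' from the B-factor column, per the AlphaFold convention of storing
#' per-residue confidence there.
#'
#' @param path PDB file path
#' @param accession accession to record; default parses the AlphaFold
#'   file-name pattern, falling back to the base file name
#' @return a [structure_model()]
#' @export
read_structure_pdb <- function(path, accession = NULL) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  if (is.null(accession)) {
    bn <- basename(path)
    accession <- if (grepl("^AF-.+-F[0-9]+-model_v[0-9]+", bn))
      sub("^AF-(.+)-F[0-9]+-model_v[0-9]+.*$", "\\1", bn)
    else tools::file_path_sans_ext(bn)
  }
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  name <- trimws(substr(atoms, 13L, 16L))
  ca <- atoms[name == "CA"]
  if (!length(ca)) stopf("no CA atoms in %s", path)
  structure_model(
    accession = accession,
    index = as.integer(substr(ca, 23L, 26L)),
    xyz = cbind(as.numeric(substr(ca, 31L, 38L)),
                as.numeric(substr(ca, 39L, 46L)),
                as.numeric(substr(ca, 47L, 54L))),
    plddt = as.numeric(substr(ca, 61L, 66L)))
}

#' Write a structure model as a CA-only PDB file
#'
#' Fixed-width PDB `ATOM` records with the pLDDT in the B-factor column;
#' round-trips through [read_structure_pdb()].
#'
#' @param model a [structure_model()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(nrow(model)), model$index, model$x, model$y, model$z, model$plddt)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Euclidean CA-CA distance of an intralink
#'
#' Distance in Angstrom between the C-alpha atoms of the two linked residues
#' on the model. A site absent from the model gives an explicit `NA`
#' ("unmappable"), never a silent skip; isoform-style index mismatches are
#' thereby surfaced to the caller.
#'
#' @param model a [structure_model()]
#' @param pos_a,pos_b 1-based residue positions
#' @return distance in Angstrom, or `NA` if either site is missing
#' @export
link_distance <- function(model, pos_a, pos_b) {
  stopifnot(inherits(model, "structure_model"))
  ia <- match(pos_a, model$index)
  ib <- match(pos_b, model$index)
  ifelse(is.na(ia) | is.na(ib), NA_real_,
         sqrt((model$x[ia] - model$x[ib])^2 +
              (model$y[ia] - model$y[ib])^2 +
              (model$z[ia] - model$z[ib])^2))
}

#' Mean per-residue model confidence
#'
#' @param model a [structure_model()]
#' @return arithmetic mean pLDDT (0-100)
#' @export
mean_plddt <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (!nrow(model)) stopf("empty structure model")
  mean(model$plddt)
}

#' Per-protein distance profile against the cross-linker constraint
#'
#' For every protein with at least `min_intralinks` mappable intralinked
#' residue pairs (cross-link origin only; long loop-links are excluded from
#' the count), computes the mean and standard deviation of the CA-CA
#' distances, the mean CSM count, the mean model pLDDT, and classifies the
#' protein as `"shorter"` (mean distance strictly below `constraint`) or
#' `"longer"` (otherwise). Proteins below the intralink threshold are
#' omitted. `"shorter"` proteins are in better agreement with the expected
#' maximum span of the cross-linker.
#'
#' @param models named list of [structure_model()]s (names = accessions)
#' @param annotations output of [to_residue_pairs()]
#' @param min_intralinks minimum mappable intralinks per protein (default 6)
#' @param constraint distance constraint in Angstrom (default 20)
#' @return data.frame: `accession`, `n_intralinks`, `mean_dist`, `sd_dist`,
#'   `mean_csms`, `mean_plddt`, `class`, sorted by class then `sd_dist`
#' @export
protein_distance_profile <- function(models, annotations, min_intralinks = 6L,
                                     constraint = 20) {
  intra <- annotations[annotations$is_intra & annotations$origin == "cross", ,
                       drop = FALSE]
  res <- list()
  for (acc in intersect(unique(intra$protein_a), names(models))) {
    sub <- intra[intra$protein_a == acc, , drop = FALSE]
    d <- link_distance(models[[acc]], sub$pos_a, sub$pos_b)
    ok <- !is.na(d)
    if (sum(ok) < min_intralinks) next
    res[[acc]] <- data.frame(
      accession = acc, n_intralinks = sum(ok),
      mean_dist = mean(d[ok]), sd_dist = stats::sd(d[ok]),
      mean_csms = mean(sub$csm_count[ok]),
      mean_plddt = mean_plddt(models[[acc]]),
      class = if (mean(d[ok]) < constraint) "shorter" else "longer",
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(accession = character(0), n_intralinks = integer(0),
                      mean_dist = numeric(0), sd_dist = numeric(0),
                      mean_csms = numeric(0), mean_plddt = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$class != "shorter", out$sd_dist), ]
  rownames(out) <- NULL
  out
}

#' Read a disorder-region table
#'
#' Tab-delimited with columns `accession`, `start`, `end` (1-based,
#' inclusive), e.g. as exported from a curated disorder repository.
#'
#' @param path TSV path
#' @return data.frame of regions
#' @export
read_disorder_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!all(c("accession", "start", "end") %in% names(df)))
    stopf("disorder table needs columns accession, start, end")
  if (any(df$start > df$end)) stopf("disorder regions with start > end")
  df
}

#' Overlay disorder regions on residue pairs
#'
#' For each link, `in_disprot` flags whether either protein of the pair has
#' at least one catalogued disorder region, and `in_disordered_region`
#' whether, additionally, either linked residue falls inside such a region
#' (closed interval: a link at a region boundary is inside). The summary
#' gives the fraction of links with a catalogued protein and, among those,
#' the fraction with a side linked inside a disordered region.
#'
#' @param annotations output of [to_residue_pairs()]
#' @param regions disorder-region data.frame (`accession`, `start`, `end`)
#' @return `annotations` with the two flag columns; attribute `summary` is
#'   a named numeric with `frac_in_disprot` and `frac_link_in_region`
#' @export
disorder_overlap <- function(annotations, regions) {
  by_acc <- split(regions, regions$accession)
  in_region <- function(acc, pos) {
    r <- by_acc[[acc]]
    !is.null(r) && any(pos >= r$start & pos <= r$end)
  }
  n <- nrow(annotations)
  flag1 <- logical(n); flag2 <- logical(n)
  for (i in seq_len(n)) {
    a <- annotations$protein_a[i]; b <- annotations$protein_b[i]
    flag1[i] <- a %in% names(by_acc) || b %in% names(by_acc)
    flag2[i] <- flag1[i] && (in_region(a, annotations$pos_a[i]) ||
                             in_region(b, annotations$pos_b[i]))
  }
  annotations$in_disprot <- flag1
  annotations$in_disordered_region <- flag2
  attr(annotations, "summary") <- c(
    frac_in_disprot = mean(flag1),
    frac_link_in_region = if (any(flag1)) mean(flag2[flag1]) else NA_real_)
  annotations
}
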