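# canonical residue-pair key: "(accA,posA)" <= "(accB,posB)" lexicographically
# (accession compare first, numeric position as tiebreak), so each unordered
# residue pair has exactly one key string "accA:posA--accB:posB"
canonical_pair <- function(acc_a, pos_a, acc_b, pos_b) {
  swap <- (acc_b < acc_a) | (acc_b == acc_a & pos_b < pos_a)
  ka <- ifelse(swap, acc_b, acc_a); pa <- ifelse(swap, pos_b, pos_a)
  kb <- ifelse(swap, acc_a, acc_b); pb <- ifelse(swap, pos_a, pos_b)
  list(protein_a = ka, pos_a = pa, protein_b = kb, pos_b = pb,
       key = paste0(ka, ":", pa, "--", kb, ":", pb))
}

as_seq_vector <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 0L) {
    character(0)
  } else if (inherits(fasta, "AAStringSet")) {
    stats::setNames(as.character(fasta), names(fasta))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    fasta
  } else if (length(fasta) == 1L && is.character(fasta) && file.exists(fasta)) {
    s <- Biostrings::readAAStringSet(fasta)
    nm <- sub("\\s.*$", "", names(s))
    stats::setNames(as.character(s), nm)
  } else stopf("fasta must be an AAStringSet, a named character vector, or a file path")
}

#' Map CSMs to protein residue pairs
#'
#' Converts cross-link and loop-link spectrum matches to canonical protein
#' residue pairs. The protein site of each link is the peptide's offset in
#' the protein plus the within-peptide link position minus one (1-based
#' both); every claimed (accession, site, peptide) triple is validated
#' against the FASTA, and a peptide that does not occur at its claimed
#' offset is a consistency error naming the CSM. CSMs collapsing to the
#' same canonical key (including A/B-swapped duplicates) are merged with
#' their CSM counts summed. A cross-link where either peptide maps to more
#' than one protein is flagged `shared_peptide`; such links are retained
#' here but excluded from residue-pair quantification and from the xiFDR
#' input downstream. Loop links are kept only when their sequence distance
#' is at least `loop_min` residues ("long" loop links, origin `long_loop`);
#' shorter loops, monolinks and regular peptides contribute no pair.
#'
#' @param csms CSM records from [csm_records()]
#' @param fasta protein sequences (`AAStringSet`, named character vector, or
#'   FASTA file path)
#' @param loop_min minimum loop sequence distance, in amino acids, for a
#'   loop link to count as a residue pair (default 5)
#' @return data.frame of link annotations (one row per canonical pair) with
#'   columns `protein_a`, `pos_a`, `protein_b`, `pos_b`, `origin`,
#'   `is_intra`, `shared_peptide`, `loop_seq_distance`, `csm_count`, `key`;
#'   attribute `csm_key` maps each input CSM to its pair key (`NA` for CSMs
#'   that contribute no pair)
#' @export
to_residue_pairs <- function(csms, fasta, loop_min = 5L) {
  seqs <- as_seq_vector(fasta)
  n <- NROW(csms)
  csm_key <- rep(NA_character_, n)
  rec <- vector("list", n)
  check_site <- function(acc, site, pep, link_pos, i) {
    if (!acc %in% names(seqs))
      stopf("CSM %d (%s): accession %s not in FASTA", i, csms$spectrum_title[i], acc)
    off <- site - link_pos + 1L
    if (off < 1L || substr(seqs[[acc]], off, off + nchar(pep) - 1L) != pep)
      stopf("CSM %d (%s): peptide %s not found in %s at offset %d",
            i, csms$spectrum_title[i], pep, acc, off)
  }
  for (i in seq_len(n)) {
    lt <- csms$link_type[i]
    if (lt == "cross") {
      pa <- parse_protein_token(paste0(csms$proteins_a[i], "-", csms$proteins_b[i]))
      shared <- length(unique(pa$a$accession)) > 1L ||
                length(unique(pa$b$accession)) > 1L
      acc_a <- pa$a$accession[1L]; site_a <- pa$a$site[1L]
      acc_b <- pa$b$accession[1L]; site_b <- pa$b$site[1L]
      check_site(acc_a, site_a, csms$peptide_a[i], csms$link_pos_a[i], i)
      check_site(acc_b, site_b, csms$peptide_b[i], csms$link_pos_b[i], i)
      cp <- canonical_pair(acc_a, site_a, acc_b, site_b)
      rec[[i]] <- data.frame(protein_a = cp$protein_a, pos_a = cp$pos_a,
                             protein_b = cp$protein_b, pos_b = cp$pos_b,
                             origin = "cross", shared_peptide = shared,
                             loop_seq_distance = NA_integer_, key = cp$key,
                             stringsAsFactors = FALSE)
      csm_key[i] <- cp$key
    } else if (lt == "loop") {
      ld <- loop_distance(csms[i, , drop = FALSE])
      if (ld$distance < loop_min) next
      pt <- parse_protein_token(csms$proteins_a[i])
      acc <- pt$a$accession[1L]
      check_site(acc, pt$a$site[1L], csms$peptide_a[i], csms$link_pos_a[i], i)
      cp <- canonical_pair(acc, pt$a$site[1L], acc, pt$b$site[1L])
      rec[[i]] <- data.frame(protein_a = cp$protein_a, pos_a = cp$pos_a,
                             protein_b = cp$protein_b, pos_b = cp$pos_b,
                             origin = "long_loop", shared_peptide = FALSE,
                             loop_seq_distance = ld$distance, key = cp$key,
                             stringsAsFactors = FALSE)
      csm_key[i] <- cp$key
    }
  }
  rec <- rec[!vapply(rec, is.null, TRUE)]
  if (!length(rec)) {
    ann <- data.frame(protein_a = character(0), pos_a = integer(0),
                      protein_b = character(0), pos_b = integer(0),
                      origin = character(0), is_intra = logical(0),
                      shared_peptide = logical(0),
                      loop_seq_distance = integer(0), csm_count = integer(0),
                      key = character(0), stringsAsFactors = FALSE)
    attr(ann, "csm_key") <- csm_key
    return(ann)
  }
  all <- do.call(rbind, rec)
  ann <- all[!duplicated(all$key), , drop = FALSE]
  cnt <- table(all$key)
  ann$csm_count <- as.integer(cnt[ann$key])
  ann$shared_peptide <- as.logical(tapply(all$shared_peptide, all$key, any)[ann$key])
  ann$is_intra <- ann$protein_a == ann$protein_b
  ann <- ann[order(ann$key), c("protein_a", "pos_a", "protein_b", "pos_b",
                               "origin", "is_intra", "shared_peptide",
                               "loop_seq_distance", "csm_count", "key")]
  rownames(ann) <- NULL
  attr(ann, "csm_key") <- csm_key
  ann
}

#' Intra/inter composition of a link set
#'
#' @param annotations output of [to_residue_pairs()]
#' @return named numeric: percentage of intra- and interprotein links
#'   (sums to 100)
#' @export
intra_inter_fractions <- function(annotations) {
  n <- nrow(annotations)
  if (!n) return(c(intra = NA_real_, inter = NA_real_))
  p <- mean(annotations$is_intra) * 100
  c(intra = p, inter = 100 - p)
}

#' Sequence distance of a loop link
#'
#' The distance between the two linked positions of a loop-linked peptide,
#' expressed as the number of amino acids between them, i.e. the absolute
#' difference of the 1-based sites (adjacent lysines give 1). A loop link is
#' "long" when this distance is at least 5 residues; shorter loops bridge
#' neighbouring positions and carry little structural information.
#'
#' @param csm a single CSM record (data.frame row) with `link_type == "loop"`
#' @return list with `distance` (integer, amino acids) and `is_long`
#' @export
loop_distance <- function(csm) {
  if (NROW(csm) != 1L || csm$link_type != "loop")
    stopf("loop_distance expects a single loop-linked CSM")
  d <- abs(csm$link_pos_b - csm$link_pos_a)
  list(distance = as.integer(d), is_long = d >= 5L)
}

#' Build an entrapment target+decoy FASTA
#'
#' Appends to the true target sequences one shuffled decoy per entry: a
#' seeded uniformly random permutation of the residues, preserving length
#' and amino-acid composition exactly. Decoy accessions get a configurable
#' prefix, from which downstream decoy flags are derived. The same seed
#' always produces a byte-identical file. Optionally the C-terminal residue
#' is held fixed (tryptic-terminus preservation, off by default).
#'
#' @param targets protein sequences (`AAStringSet`, named character vector,
#'   or FASTA file path)
#' @param seed integer seed for the permutation
#' @param decoy_prefix accession prefix for decoys
#' @param preserve_termini keep the last residue in place when shuffling
#' @param path optional output FASTA path
#' @return named character vector of target followed by decoy sequences
#' @export
make_entrapment_fasta <- function(targets, seed, decoy_prefix = "DECOY_",
                                  preserve_termini = FALSE, path = NULL) {
  seqs <- as_seq_vector(targets)
  if (!length(seqs)) stopf("no target sequences supplied")
  decoys <- with_seed(seed, vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    if (preserve_termini && length(ch) > 1L) {
      head_ch <- ch[-length(ch)]
      paste0(paste(sample(head_ch), collapse = ""), ch[length(ch)])
    } else paste(sample(ch), collapse = "")
  }, ""))
  names(decoys) <- paste0(decoy_prefix, names(seqs))
  out <- c(seqs, decoys)
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(out), path, width = 60L)
  }
  out
}

#' Build the CSM-level input table for external PPI-FDR filtering
#'
#' Formats CSMs for a target-decoy PPI FDR tool (xiFDR-style columns).
#' Cross-links containing a peptide shared between proteins are excluded;
#' decoy flags are derived from the entrapment accession prefix. PPI-level
#' FDR itself is delegated to the external tool.
#'
#' @param csms CSM records from [csm_records()]
#' @param annotations output of [to_residue_pairs()] on the same CSMs
#' @param decoy_prefix accession prefix marking decoys
#' @return data.frame with one row per retained CSM
#' @export
xifdr_input <- function(csms, annotations, decoy_prefix = "DECOY_") {
  key <- attr(annotations, "csm_key")
  shared <- annotations$shared_peptide[match(key, annotations$key)]
  keep <- csms$link_type == "cross" & !is.na(key) & !shared
  rows <- which(keep)
  build <- function(i) {
    pa <- parse_protein_token(csms$proteins_a[i])$a[1L, ]
    pb <- parse_protein_token(csms$proteins_b[i])$a[1L, ]
    data.frame(
      PSMID = csms$spectrum_title[i],
      PepSeq1 = csms$peptide_a[i], PepSeq2 = csms$peptide_b[i],
      LinkPos1 = csms$link_pos_a[i], LinkPos2 = csms$link_pos_b[i],
      Protein1 = pa$accession, Protein2 = pb$accession,
      PepPos1 = pa$site - csms$link_pos_a[i] + 1L,
      PepPos2 = pb$site - csms$link_pos_b[i] + 1L,
      IsDecoy1 = startsWith(pa$accession, decoy_prefix),
      IsDecoy2 = startsWith(pb$accession, decoy_prefix),
      Charge = csms$charge[i], Score = csms$score[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(rows, build))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
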