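# monoisotopic residue masses (Da)
AA_MONO <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
             V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
             I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
             K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
             F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
PROTON <- 1.007276
WATER <- 18.010565

#' Cross-linker and fixed-modification mass specification
#'
#' Masses for an NHS-ester phosphonate-handle lysine cross-linker
#' (PhoX/TBDSPP class): the intact linker bridging two sites adds
#' 209.972 Da, a hydrolyzed dead-end 227.982 Da and an amidated dead-end
#' 226.998 Da, targeting lysine side chains and the protein N-terminus.
#' Fixed modifications: carbamidomethyl-C (+57.021464 Da) and the TMTpro
#' label (+304.207146 Da) at the peptide N-terminus and lysines.
#'
#' @return named list of masses (Da) and the reactive-residue rule
#' @export
phox_crosslinker <- function() {
  list(linker_mass = 209.972,
       monolink_hydrolyzed = 227.982,
       monolink_amidated = 226.998,
       reactive_residue = "K",
       reactive_nterm = TRUE,
       fixed_mods = c(carbamidomethyl_C = 57.021464,
                      tmtpro = 304.207146))
}

# labeled peptide monoisotopic mass under the fixed-modification scheme
peptide_mass <- function(seq, spec = phox_crosslinker()) {
  ch <- strsplit(seq, "")[[1L]]
  sum(AA_MONO[ch]) + WATER +
    spec$fixed_mods[["tmtpro"]] +                                  # N-terminus
    sum(ch == "C") * spec$fixed_mods[["carbamidomethyl_C"]] +
    sum(ch == "K") * spec$fixed_mods[["tmtpro"]]
}

#' Simulation configuration
#'
#' The stated world of the synthetic generator, mirroring the multiplexed
#' cross-linking study design it stands in for: 18 TMTpro channels covering
#' 14 cell lines, the first four in technical duplicate; roughly 9% of
#' cross-links interprotein; lognormal (log2-additive Gaussian) reporter
#' noise; loop links split between short (< 5 AA) and long spans.
#'
#' @param n_proteins number of synthetic proteins
#' @param protein_length min/max protein length (residues)
#' @param n_crosslinks number of cross-linked residue pairs
#' @param n_looplinks number of loop-linked peptides (half long, half short)
#' @param n_monolinks number of monolinked peptides
#' @param n_regular number of regular (linear) peptides
#' @param interlink_fraction fraction of cross-links joining two proteins
#' @param shared_fraction fraction of cross-links given a shared peptide
#' @param cell_lines cell-line labels (default `CL01`..`CL14`)
#' @param n_replicated how many leading cell lines are run in duplicate
#' @param noise_sd_log2 SD of the per-channel log2 noise on reporter
#'   intensities (0.15 ~ a 10-11 percent CV, comfortably under the
#'   15 percent replicate-CV ceiling the workflow is expected to meet)
#' @param base_log2,base_sd mean and SD of per-pair baseline log2 intensity
#' @param protein_effect_sd SD of per-protein, per-cell-line abundance
#'   effects (shared by a protein's cross-links, removable by regression)
#' @param planted_effects data.frame with columns `pair` (index into the
#'   cross-link list), `cell_line`, `shift` (log2) — ground-truth structural
#'   events; each also deposits a missense mutation inside the pair interval
#' @param n_background_mutations random missense mutations elsewhere
#' @param disorder_fraction fraction of proteins given disorder regions
#' @param mgf_files number of MGF files the spectra are spread over
#' @param seed RNG seed; the full bundle is byte-identical under a fixed seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_proteins = 30L, protein_length = c(150L, 400L),
                       n_crosslinks = 120L, n_looplinks = 40L,
                       n_monolinks = 20L, n_regular = 20L,
                       interlink_fraction = 0.092, shared_fraction = 0.05,
                       cell_lines = sprintf("CL%02d", 1:14),
                       n_replicated = 4L, noise_sd_log2 = 0.15,
                       base_log2 = 16, base_sd = 1.5,
                       protein_effect_sd = 0.5,
                       planted_effects = NULL,
                       n_background_mutations = 30L,
                       disorder_fraction = 0.3, mgf_files = 2L, seed = 1L) {
  reps <- c(rep(cell_lines[seq_len(n_replicated)], each = 2L),
            cell_lines[-seq_len(n_replicated)])
  channels <- reporter_ref("tmtpro18")$label
  if (length(reps) != length(channels))
    stopf("cell-line design must fill the %d channels (got %d samples)",
          length(channels), length(reps))
  structure(list(
    n_proteins = n_proteins, protein_length = protein_length,
    n_crosslinks = n_crosslinks, n_looplinks = n_looplinks,
    n_monolinks = n_monolinks, n_regular = n_regular,
    interlink_fraction = interlink_fraction, shared_fraction = shared_fraction,
    cell_lines = cell_lines, channels = channels,
    replicate_map = stats::setNames(reps, channels),
    noise_sd_log2 = noise_sd_log2, base_log2 = base_log2, base_sd = base_sd,
    protein_effect_sd = protein_effect_sd, planted_effects = planted_effects,
    n_background_mutations = n_background_mutations,
    disorder_fraction = disorder_fraction, mgf_files = mgf_files,
    seed = as.integer(seed)), class = "sim_config")
}

random_protein <- function(len) {
  # lysine-enriched so tryptic cross-linkable sites are plentiful
  aa <- names(AA_MONO)
  w <- rep(1, length(aa)); w[aa == "K"] <- 3
  paste(sample(aa, len, replace = TRUE, prob = w), collapse = "")
}

#' Toy structure model generator
#'
#' `extended`: CA atoms on a straight line at 3.8 Angstrom per residue, so
#' the distance between residues i and j is exactly `3.8 * |i - j|`.
#' `compact`: a 3.8 Angstrom/step random walk reflected into a 30 Angstrom
#' sphere, so all pairwise distances stay below 60 Angstrom.
#'
#' @param length number of residues (>= 2)
#' @param fold `"extended"` or `"compact"`
#' @param seed RNG seed
#' @param plddt per-residue confidence; scalar recycled, default drawn
#'   uniformly in `[60, 95]`
#' @param accession accession label for the model
#' @return a [structure_model()]
#' @export
toy_structure <- function(length, fold = c("extended", "compact"), seed = 1L,
                          plddt = NULL, accession = "TOY") {
  fold <- match.arg(fold)
  if (length < 2L) stopf("toy structure needs at least 2 residues")
  with_seed(seed, {
    if (is.null(plddt)) plddt <- round(stats::runif(length, 60, 95), 2L)
    plddt <- rep_len(round(plddt, 2L), length)
    if (fold == "extended") {
      xyz <- cbind(3.8 * (seq_len(length) - 1L), 0, 0)
    } else {
      xyz <- matrix(0, length, 3L)
      for (i in 2:length) {
        step <- stats::rnorm(3L)
        step <- step / sqrt(sum(step^2)) * 3.8
        p <- xyz[i - 1L, ] + step
        r <- sqrt(sum(p^2))
        if (r > 30) p <- p * (30 / r)   # reflect back onto the sphere
        xyz[i, ] <- p
      }
      xyz <- round(xyz, 3L)
    }
    structure_model(accession, seq_len(length), xyz, plddt)
  })
}

# helper: pick a peptide window covering protein position `site`
peptide_window <- function(seq, site) {
  len <- nchar(seq)
  start <- max(1L, site - sample(2:6, 1L))
  end <- min(len, start + sample(7:13, 1L))
  if (end < site) end <- min(len, site + 2L)
  list(pep = substr(seq, start, end), start = start,
       link_pos = site - start + 1L)
}

#' Generate a fully synthetic, ground-truthed input bundle
#'
#' Emits every input format the pipeline consumes — FASTA proteome,
#' hierarchical cross-link CSV, MGF spectra carrying the reporter ions,
#' protein abundance matrix, mutation table with gene map, disorder table
#' and toy model PDB files — together with the ground truth: the expected
#' raw residue-pair matrix and the planted structural events. Reporter
#' intensities are lognormal around per-channel means composed of a pair
#' baseline, the protein's per-cell-line abundance effect and any planted
#' log2 shift; the protein matrix shares the same abundance effects, so
#' regression can remove them. Peptide precursor masses follow the
#' cross-linker and fixed-modification masses of [phox_crosslinker()].
#' The same seed always yields a byte-identical bundle.
#'
#' @param config a [sim_config()]
#' @param out_dir directory to write the bundle into (created)
#' @return invisible list: file paths, the truth `residue_pair_quant`,
#'   planted event table, per-protein models, and the config
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "mgf"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  spec <- phox_crosslinker()
  with_seed(config$seed, {
    ## proteome ---------------------------------------------------------
    acc <- sprintf("PX%04d", seq_len(config$n_proteins))
    genes <- sprintf("GENE%04d", seq_len(config$n_proteins))
    lens <- sample(config$protein_length[1L]:config$protein_length[2L],
                   config$n_proteins, replace = TRUE)
    seqs <- stats::setNames(vapply(lens, random_protein, ""), acc)

    ## link site plan (positions forced to K afterwards) ----------------
    xl <- data.frame(acc_a = character(0), site_a = integer(0),
                     acc_b = character(0), site_b = integer(0),
                     shared = logical(0), stringsAsFactors = FALSE)
    for (i in seq_len(config$n_crosslinks)) {
      inter <- stats::runif(1) < config$interlink_fraction
      pa <- sample(config$n_proteins, 1L)
      pb <- if (inter) sample(setdiff(seq_len(config$n_proteins), pa), 1L) else pa
      sa <- sample(10:(lens[pa] - 10L), 1L)
      sb <- sample(setdiff(10:(lens[pb] - 10L), if (pa == pb) sa), 1L)
      xl[i, ] <- list(acc[pa], sa, acc[pb], sb,
                      stats::runif(1) < config$shared_fraction)
    }
    loops <- data.frame(acc = acc[sample(config$n_proteins, config$n_looplinks,
                                         replace = TRUE)])
    loops$site_a <- vapply(loops$acc, function(a)
      sample(10:(nchar(seqs[[a]]) - 40L), 1L), 1L)
    loops$span <- c(sample(1:4, ceiling(config$n_looplinks / 2), replace = TRUE),
                    sample(5:25, floor(config$n_looplinks / 2), replace = TRUE))[
                      seq_len(config$n_looplinks)]
    loops$site_b <- loops$site_a + loops$span
    monos <- data.frame(acc = acc[sample(config$n_proteins, config$n_monolinks,
                                         replace = TRUE)])
    monos$site <- vapply(monos$acc, function(a)
      sample(10:(nchar(seqs[[a]]) - 10L), 1L), 1L)

    set_k <- function(a, pos) {
      s <- seqs[[a]]
      for (p in pos) substr(s, p, p) <- "K"
      seqs[[a]] <<- s
    }
    for (i in seq_len(nrow(xl))) {
      set_k(xl$acc_a[i], xl$site_a[i]); set_k(xl$acc_b[i], xl$site_b[i])
    }
    for (i in seq_len(nrow(loops))) set_k(loops$acc[i], c(loops$site_a[i], loops$site_b[i]))
    for (i in seq_len(nrow(monos))) set_k(monos$acc[i], monos$site[i])

    ## peptides; shared peptides get a copy appended to another protein -
    xl$pep_a <- character(nrow(xl)); xl$lp_a <- integer(nrow(xl))
    xl$pep_b <- character(nrow(xl)); xl$lp_b <- integer(nrow(xl))
    xl$alt_a <- character(nrow(xl))
    for (i in seq_len(nrow(xl))) {
      wa <- peptide_window(seqs[[xl$acc_a[i]]], xl$site_a[i])
      wb <- peptide_window(seqs[[xl$acc_b[i]]], xl$site_b[i])
      xl$pep_a[i] <- wa$pep; xl$lp_a[i] <- wa$link_pos
      xl$pep_b[i] <- wb$pep; xl$lp_b[i] <- wb$link_pos
      if (xl$shared[i]) {
        host <- sample(setdiff(acc, c(xl$acc_a[i], xl$acc_b[i])), 1L)
        off <- nchar(seqs[[host]]) + 1L
        seqs[[host]] <- paste0(seqs[[host]], wa$pep)
        xl$alt_a[i] <- sprintf("%s(%d)", host, off + wa$link_pos - 1L)
      }
    }
    loops$pep <- character(nrow(loops))
    loops$lp_a <- integer(nrow(loops)); loops$lp_b <- integer(nrow(loops))
    for (i in seq_len(nrow(loops))) {
      s <- seqs[[loops$acc[i]]]
      start <- max(1L, loops$site_a[i] - 2L)
      end <- min(nchar(s), loops$site_b[i] + 2L)
      loops$pep[i] <- substr(s, start, end)
      loops$lp_a[i] <- loops$site_a[i] - start + 1L
      loops$lp_b[i] <- loops$site_b[i] - start + 1L
    }
    monos$pep <- character(nrow(monos)); monos$lp <- integer(nrow(monos))
    for (i in seq_len(nrow(monos))) {
      w <- peptide_window(seqs[[monos$acc[i]]], monos$site[i])
      monos$pep[i] <- w$pep; monos$lp[i] <- w$link_pos
    }
    regular <- data.frame(acc = acc[sample(config$n_proteins, config$n_regular,
                                           replace = TRUE)])
    regular$pep <- vapply(regular$acc, function(a) {
      start <- sample(1:(nchar(seqs[[a]]) - 12L), 1L)
      substr(seqs[[a]], start, start + sample(7:12, 1L))
    }, "")

    ## intensity model --------------------------------------------------
    nch <- length(config$channels)
    line_of <- config$replicate_map[config$channels]
    prot_eff <- matrix(stats::rnorm(config$n_proteins * length(config$cell_lines),
                                    0, config$protein_effect_sd),
                       config$n_proteins,
                       dimnames = list(acc, config$cell_lines))
    planted <- config$planted_effects
    pair_mean_log2 <- function(acc_a, pair_idx) {
      b <- stats::rnorm(1L, config$base_log2, config$base_sd)
      mu <- b + prot_eff[acc_a, line_of]
      if (!is.null(planted)) {
        hit <- planted$pair == pair_idx
        for (j in which(hit))
          mu[line_of == planted$cell_line[j]] <-
            mu[line_of == planted$cell_line[j]] + planted$shift[j]
      }
      mu
    }

    ## CSMs + spectra ---------------------------------------------------
    mk_title <- function(filebase, scan, charge)
      sprintf("%s.%d.%d.%d.0.dta", filebase, scan, scan, charge)
    csm_list <- list(); spectra <- vector("list", 0L)
    scan <- 1000L
    filebases <- sprintf("sim_run%d", seq_len(config$mgf_files))
    add_csm <- function(kind, pep_tok, prot_tok, mass, mu_log2) {
      n_csm <- if (is.null(mu_log2)) 1L else sample(1:3, 1L)
      for (k in seq_len(n_csm)) {
        scan <<- scan + 1L
        charge <- sample(3:5, 1L)
        fb <- filebases[(scan %% config$mgf_files) + 1L]
        title <- mk_title(fb, scan, charge)
        if (is.null(mu_log2)) {
          ints <- round(2^stats::rnorm(nch, config$base_log2 - 2, 1), 4L)
        } else {
          ints <- round(2^(mu_log2 - log2(n_csm) +
                           stats::rnorm(nch, 0, config$noise_sd_log2)), 4L)
        }
        csm_list[[length(csm_list) + 1L]] <<- list(
          kind = kind, pep = pep_tok, prot = prot_tok, title = title,
          charge = charge, score = signif(10^stats::runif(1, -8, -2), 6L),
          file = fb, intensity = stats::setNames(ints, config$channels))
        ref <- reporter_ref("tmtpro18")
        jit <- stats::runif(nch, -5, 5) * 1e-6
        rep_pk <- cbind(round(ref$mz * (1 + jit), 6L), ints)
        noise_n <- sample(5:15, 1L)
        noise_pk <- cbind(round(stats::runif(noise_n, 200, 1500), 6L),
                          round(10^stats::runif(noise_n, 2, 5), 4L))
        spectra[[length(spectra) + 1L]] <<- ms2_spectrum(
          title = title, peaks = rbind(rep_pk, noise_pk),
          precursor_mz = round((mass + charge * PROTON) / charge, 6L),
          precursor_charge = charge, source_file = paste0(fb, ".mgf"))
      }
    }
    for (i in seq_len(nrow(xl))) {
      pep_tok <- sprintf("%s(%d)-%s(%d)", xl$pep_a[i], xl$lp_a[i],
                         xl$pep_b[i], xl$lp_b[i])
      side_a <- sprintf("%s(%d)", xl$acc_a[i], xl$site_a[i])
      if (nzchar(xl$alt_a[i])) side_a <- paste0(side_a, ";", xl$alt_a[i])
      prot_tok <- sprintf("%s-%s(%d)", side_a, xl$acc_b[i], xl$site_b[i])
      mass <- peptide_mass(xl$pep_a[i], spec) + peptide_mass(xl$pep_b[i], spec) +
        spec$linker_mass
      add_csm("cross", pep_tok, prot_tok, mass, pair_mean_log2(xl$acc_a[i], i))
    }
    for (i in seq_len(nrow(loops))) {
      pep_tok <- sprintf("%s(%d)(%d)", loops$pep[i], loops$lp_a[i], loops$lp_b[i])
      prot_tok <- sprintf("%s(%d)(%d)", loops$acc[i], loops$site_a[i],
                          loops$site_b[i])
      mass <- peptide_mass(loops$pep[i], spec) + spec$linker_mass
      mu <- if (loops$span[i] >= 5L)
        pair_mean_log2(loops$acc[i], nrow(xl) + i) else NULL
      add_csm("loop", pep_tok, prot_tok, mass, mu)
    }
    for (i in seq_len(nrow(monos))) {
      add_csm("mono", sprintf("%s(%d)", monos$pep[i], monos$lp[i]),
              sprintf("%s(%d)", monos$acc[i], monos$site[i]),
              peptide_mass(monos$pep[i], spec) + spec$monolink_hydrolyzed, NULL)
    }
    for (i in seq_len(nrow(regular))) {
      add_csm("regular", regular$pep[i], regular$acc[i],
              peptide_mass(regular$pep[i], spec), NULL)
    }

    ## write MGF files --------------------------------------------------
    for (fb in filebases) {
      sel <- vapply(spectra, function(s) s$source_file == paste0(fb, ".mgf"), TRUE)
      write_mgf(spectra[sel], file.path(out_dir, "mgf", paste0(fb, ".mgf")))
    }

    ## write the cross-link CSV -----------------------------------------
    kind_label <- c(cross = "Cross-Linked", loop = "Loop-Linked",
                    mono = "Mono-Linked", regular = "Regular")
    ptok_protein <- vapply(csm_list, function(cs) {
      accs <- unique(unlist(lapply(strsplit(cs$prot, "-", fixed = TRUE)[[1L]],
        function(s) sub("\\(.*$", "", strsplit(s, ";", fixed = TRUE)[[1L]][1L]))))
      paste(accs, collapse = "-")
    }, "")
    pep_id <- vapply(csm_list, function(cs) paste(cs$kind, cs$pep, cs$prot), "")
    prot_groups <- unique(ptok_protein)
    lines_out <- c("Protein_Order,Proteins,Protein_Type",
                   ",Peptide_Order,Peptide,Peptide_Type,Proteins",
                   ",,Spectrum_Order,Title,Charge,Score")
    pep_order <- 0L; spec_order <- 0L
    for (gi in seq_along(prot_groups)) {
      g <- prot_groups[gi]
      members <- which(ptok_protein == g)
      n_prot <- length(unique(strsplit(g, "-", fixed = TRUE)[[1L]]))
      ptype <- if (grepl("-", g)) "Inter-Protein" else "Intra-Protein"
      lines_out <- c(lines_out, paste(csv_quote(c(gi, g, ptype)), collapse = ","))
      for (pid in unique(pep_id[members])) {
        rows <- members[pep_id[members] == pid]
        cs0 <- csm_list[[rows[1L]]]
        pep_order <- pep_order + 1L
        lines_out <- c(lines_out, paste(csv_quote(
          c("", pep_order, cs0$pep, kind_label[[cs0$kind]], cs0$prot)),
          collapse = ","))
        for (r in rows) {
          cs <- csm_list[[r]]
          spec_order <- spec_order + 1L
          lines_out <- c(lines_out, paste(csv_quote(
            c("", "", spec_order, cs$title, cs$charge,
              formatC(cs$score, format = "g", digits = 8))), collapse = ","))
        }
      }
    }
    plink_path <- file.path(out_dir, "plink_results.csv")
    con <- file(plink_path, open = "wb"); writeLines(lines_out, con); close(con)

    ## FASTA, protein matrix, mutations, disorder, structures -----------
    fasta_path <- file.path(out_dir, "proteome.fasta")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta_path,
                                width = 60L)
    prot_base <- stats::rnorm(config$n_proteins, 18, 1)
    prot_mat <- round(2^(prot_base + prot_eff[, line_of] +
                         matrix(stats::rnorm(config$n_proteins * nch, 0, 0.05),
                                config$n_proteins)), 4L)
    dimnames(prot_mat) <- list(acc, config$channels)
    prot_path <- file.path(out_dir, "protein_matrix.tsv")
    pm <- data.frame(accession = rownames(prot_mat),
                     as.data.frame(prot_mat, check.names = FALSE),
                     check.names = FALSE)
    con <- file(prot_path, open = "wb")
    writeLines(paste(names(pm), collapse = "\t"), con)
    writeLines(do.call(paste, c(cbind(pm[1], lapply(pm[-1], fmt_num, 4L)),
                                sep = "\t")), con)
    close(con)

    gene_map <- data.frame(gene = genes, accession = acc,
                           stringsAsFactors = FALSE)
    muts <- data.frame(gene = character(0), cell_line = character(0),
                       position = integer(0), stringsAsFactors = FALSE)
    if (!is.null(planted)) {
      for (j in seq_len(nrow(planted))) {
        i <- planted$pair[j]
        if (i > nrow(xl) || xl$acc_a[i] != xl$acc_b[i])
          stopf("planted effect %d does not reference an intra cross-link", j)
        lo <- min(xl$site_a[i], xl$site_b[i]); hi <- max(xl$site_a[i], xl$site_b[i])
        muts <- rbind(muts, data.frame(
          gene = genes[match(xl$acc_a[i], acc)],
          cell_line = planted$cell_line[j],
          position = as.integer(round((lo + hi) / 2)),
          stringsAsFactors = FALSE))
      }
    }
    for (b in seq_len(config$n_background_mutations)) {
      pi <- sample(config$n_proteins, 1L)
      muts <- rbind(muts, data.frame(
        gene = genes[pi], cell_line = sample(config$cell_lines, 1L),
        position = sample(nchar(seqs[[pi]]), 1L), stringsAsFactors = FALSE))
    }
    write_tsv <- function(df, path, numcols = character(0)) {
      con <- file(path, open = "wb")
      writeLines(paste(names(df), collapse = "\t"), con)
      if (nrow(df)) writeLines(do.call(paste, c(df, sep = "\t")), con)
      close(con)
      path
    }
    mut_path <- write_tsv(muts, file.path(out_dir, "mutations.tsv"))
    map_path <- write_tsv(gene_map, file.path(out_dir, "gene_map.tsv"))

    dis_n <- max(1L, round(config$disorder_fraction * config$n_proteins))
    dis_prot <- sample(config$n_proteins, dis_n)
    dis <- do.call(rbind, lapply(dis_prot, function(pi) {
      k <- sample(1:2, 1L)
      start <- sort(sample(1:(nchar(seqs[[pi]]) - 30L), k))
      data.frame(accession = acc[pi], start = start,
                 end = pmin(nchar(seqs[[pi]]), start + sample(15:40, k,
                                                              replace = TRUE)),
                 stringsAsFactors = FALSE)
    }))
    dis_path <- write_tsv(dis, file.path(out_dir, "disorder.tsv"))

    models <- list()
    for (pi in seq_len(config$n_proteins)) {
      models[[acc[pi]]] <- toy_structure(nchar(seqs[[pi]]), "compact",
                                         seed = config$seed + pi,
                                         accession = acc[pi])
      write_structure_pdb(models[[acc[pi]]],
                          file.path(out_dir, "models",
                                    sprintf("AF-%s-F1-model_v4.pdb", acc[pi])))
    }

    ## ground truth ------------------------------------------------------
    csm_keys <- vapply(csm_list, function(cs) {
      if (cs$kind == "cross") {
        pt <- parse_protein_token(cs$prot)
        canonical_pair(pt$a$accession[1L], pt$a$site[1L],
                       pt$b$accession[1L], pt$b$site[1L])$key
      } else if (cs$kind == "loop") {
        pt <- parse_protein_token(cs$prot)
        if (abs(pt$b$site[1L] - pt$a$site[1L]) >= 5L)
          canonical_pair(pt$a$accession[1L], pt$a$site[1L],
                         pt$b$accession[1L], pt$b$site[1L])$key
        else NA_character_
      } else NA_character_
    }, "")
    shared_keys <- unique(csm_keys[vapply(csm_list, function(cs)
      grepl(";", cs$prot), TRUE) & !is.na(csm_keys)])
    keep <- !is.na(csm_keys) & !(csm_keys %in% shared_keys)
    truth_mat <- rowsum(do.call(rbind, lapply(csm_list[keep], `[[`, "intensity")),
                        group = csm_keys[keep])
    ord <- order(rownames(truth_mat))
    truth_mat <- truth_mat[ord, , drop = FALSE]
    split_key <- strsplit(rownames(truth_mat), "--", fixed = TRUE)
    parse_k <- function(s) strsplit(s, ":", fixed = TRUE)[[1L]]
    truth_keys <- data.frame(
      protein_a = vapply(split_key, function(k) parse_k(k[1L])[1L], ""),
      pos_a = as.integer(vapply(split_key, function(k) parse_k(k[1L])[2L], "")),
      protein_b = vapply(split_key, function(k) parse_k(k[2L])[1L], ""),
      pos_b = as.integer(vapply(split_key, function(k) parse_k(k[2L])[2L], "")),
      origin = ifelse(vapply(csm_list[match(rownames(truth_mat),
                                            csm_keys)], `[[`, "", "kind") == "loop",
                      "long_loop", "cross"),
      key = rownames(truth_mat), stringsAsFactors = FALSE)
    truth <- residue_pair_quant(truth_keys, truth_mat, config$channels,
                                stage = "raw")
    truth_path <- file.path(out_dir, "truth_raw.tsv")
    write_quant_matrix(truth, truth_path)

    truth_events <- if (is.null(planted)) NULL else data.frame(
      key = vapply(planted$pair, function(i)
        canonical_pair(xl$acc_a[i], xl$site_a[i], xl$acc_b[i], xl$site_b[i])$key, ""),
      cell_line = planted$cell_line,
      sign = ifelse(planted$shift < 0, -1L, 1L), stringsAsFactors = FALSE)

    invisible(list(
      dirs = list(root = out_dir, mgf = file.path(out_dir, "mgf"),
                  models = file.path(out_dir, "models")),
      paths = list(plink = plink_path, fasta = fasta_path,
                   protein_matrix = prot_path, mutations = mut_path,
                   gene_map = map_path, disorder = dis_path,
                   truth_raw = truth_path),
      truth_raw = truth, truth_events = truth_events, models = models,
      replicate_map = config$replicate_map, config = config))
  })
}

#' Read a protein abundance matrix
#'
#' Tab-delimited, first column `accession`, remaining columns one per
#' sample/channel (raw abundances).
#'
#' @param path TSV path
#' @return numeric matrix with accession rownames
#' @export
read_protein_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Normalize and scale a protein abundance matrix
#'
#' Applies the same two-step normalization used for the cross-link matrix:
#' sample totals equalized to the maximum total, then each row scaled to its
#' mean and log2-transformed (zero-containing rows dropped).
#'
#' @param m raw protein matrix (accessions x samples)
#' @return scaled-log2 matrix
#' @export
scale_protein_matrix <- function(m) {
  totals <- colSums(m)
  if (any(totals <= 0)) stopf("protein matrix has sample(s) with zero total")
  m <- sweep(m, 2L, totals / max(totals), "/")
  keep <- apply(m > 0, 1L, all)
  m <- m[keep, , drop = FALSE]
  log2(m / rowMeans(m))
}
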