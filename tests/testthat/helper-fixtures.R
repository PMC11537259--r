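# shared in-code fixtures: everything is generated at test time

ref18 <- reporter_ref("tmtpro18")

# a spectrum with reporter peaks planted exactly at the reference m/z
planted_spectrum <- function(intensities, title = "run1.1.1.3.0.dta",
                             extra_peaks = NULL, jitter_ppm = 0) {
  mz <- ref18$mz * (1 + jitter_ppm * 1e-6)
  peaks <- cbind(mz, intensities)
  if (!is.null(extra_peaks)) peaks <- rbind(peaks, extra_peaks)
  ms2_spectrum(title = title, peaks = peaks, precursor_mz = 1500.5,
               precursor_charge = 3L, source_file = "run1.mgf")
}

# linear-scan oracle for reporter matching: per channel, sum every peak
# within the inclusive ppm window (independent of the package's
# nearest-channel search path)
brute_force_reporters <- function(spectrum, ref, tol_ppm = 15) {
  pk <- spectrum$peaks
  vapply(ref$mz, function(m) {
    sel <- abs(pk[, 1] - m) / m * 1e6 <= tol_ppm
    sum(pk[sel, 2])
  }, numeric(1))
}

# deterministic random spectra for property tests
random_spectra <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    # mix of peaks near reporter masses (within and beyond tolerance) and
    # unrelated high-mass peaks
    n_rep <- sample(0:18, 1)
    rep_mz <- sample(ref18$mz, n_rep, replace = TRUE) *
      (1 + runif(n_rep, -30, 30) * 1e-6)
    n_hi <- sample(0:20, 1)
    mz <- c(rep_mz, runif(n_hi, 140, 1600))
    ms2_spectrum(title = sprintf("r.%d.%d.3.0.dta", i, i),
                 peaks = cbind(mz, round(10^runif(length(mz), 1, 5), 4)),
                 precursor_mz = 900, source_file = "r.mgf")
  })
}

# a small hand-built hierarchical report: 2 proteins, 3 peptides, 5 PSMs
# sequences are constructed so every peptide occurs at its claimed offset
tiny_world <- function() {
  base <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "G", "S", "T", "V", "L", "D", "E"), n, TRUE),
          collapse = "")
  }
  pa <- base(120, 11); pb <- base(90, 12)
  substr(pa, 104, 104) <- "K"; substr(pa, 30, 30) <- "K"
  substr(pb, 55, 55) <- "K"
  substr(pa, 60, 60) <- "K"; substr(pa, 66, 66) <- "K"  # loop sites, span 6
  fasta <- c(PA = pa, PB = pb)
  pep_a <- substr(pa, 100, 110)   # link_pos 5 -> site 104
  pep_a2 <- substr(pa, 27, 36)    # link_pos 4 -> site 30
  pep_b <- substr(pb, 52, 60)     # link_pos 4 -> site 55
  pep_loop <- substr(pa, 58, 68)  # link positions 3 and 9 -> sites 60, 66
  lines <- c(
    "Protein_Order,Proteins,Protein_Type",
    ",Peptide_Order,Peptide,Peptide_Type,Proteins",
    ",,Spectrum_Order,Title,Charge,Score",
    "1,PA-PB,Inter-Protein",
    sprintf(",1,%s(5)-%s(4),Cross-Linked,PA(104)-PB(55)", pep_a, pep_b),
    ",,1,run1.100.100.3.0.dta,3,1e-05",
    ",,2,run1.101.101.4.0.dta,4,2e-06",
    sprintf(",2,%s(4)-%s(4),Cross-Linked,PA(30)-PB(55)", pep_a2, pep_b),
    ",,3,run1.102.102.3.0.dta,3,5e-07",
    ",,4,run2.200.200.3.0.dta,3,3e-04",
    "2,PA,Intra-Protein",
    sprintf(",3,%s(3)(9),Loop-Linked,PA(60)(66)", pep_loop),
    ",,5,run2.201.201.3.0.dta,3,1e-03")
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  list(path = path, fasta = fasta, titles = sprintf(
    c("run1.%d.%d.3.0.dta", "run1.%d.%d.4.0.dta", "run1.%d.%d.3.0.dta",
      "run2.%d.%d.3.0.dta", "run2.%d.%d.3.0.dta"),
    c(100, 101, 102, 200, 201), c(100, 101, 102, 200, 201)))
}

# reporter table with planted per-title intensities for attach tests
planted_table <- function(titles, seed = 1) {
  set.seed(seed)
  ints <- matrix(round(runif(length(titles) * 18, 10, 1000), 4),
                 nrow = length(titles))
  colnames(ints) <- ref18$label
  dmz <- matrix(0, nrow = length(titles), ncol = 18,
                dimnames = list(NULL, paste0("dmz_", ref18$label)))
  cbind(data.frame(mgf_file = "r.mgf", spectrum_title = titles,
                   stringsAsFactors = FALSE),
        as.data.frame(ints, check.names = FALSE),
        as.data.frame(dmz, check.names = FALSE))
}

# matrix-level simulation for regression / event-recovery tests: cross-link
# profiles share their protein's per-cell-line effect, one planted shift
sim_regression_world <- function(n_pairs = 200, shift = -1, noise_sd = 0.1,
                                 seed = 1) {
  set.seed(seed)
  channels <- ref18$label
  rep_map <- sim_config()$replicate_map
  lines <- rep_map[channels]
  cell_lines <- sort(unique(lines))
  n_prot <- 50
  prots <- sprintf("PR%03d", seq_len(n_prot))
  pair_prot <- prots[(seq_len(n_pairs) - 1) %% n_prot + 1]
  eff <- matrix(rnorm(n_prot * length(cell_lines), 0, 0.5), n_prot,
                dimnames = list(prots, cell_lines))
  mutated_line <- setNames(sample(cell_lines, n_pairs, TRUE),
                           sprintf("p%03d", seq_len(n_pairs)))
  target_line <- mutated_line[1]
  xl_log2 <- t(vapply(seq_len(n_pairs), function(i) {
    mu <- 16 + eff[pair_prot[i], lines]
    if (i == 1) mu[lines == target_line] <- mu[lines == target_line] + shift
    mu + rnorm(length(channels), 0, noise_sd)
  }, numeric(length(channels))))
  keys <- data.frame(protein_a = pair_prot, pos_a = seq_len(n_pairs) * 2L,
                     protein_b = pair_prot, pos_b = seq_len(n_pairs) * 2L + 40L,
                     origin = "cross", is_intra = TRUE,
                     key = sprintf("%s:%d--%s:%d", pair_prot,
                                   seq_len(n_pairs) * 2L, pair_prot,
                                   seq_len(n_pairs) * 2L + 40L),
                     stringsAsFactors = FALSE)
  q_raw <- residue_pair_quant(keys, 2^xl_log2, channels, stage = "raw")
  prot_raw <- 2^(18 + eff[, lines] + matrix(rnorm(n_prot * length(channels),
                                                  0, 0.02), n_prot))
  colnames(prot_raw) <- channels
  overlaps <- data.frame(key = keys$key, cell_line = unname(mutated_line),
                         positions = "50", n_mutations = 1L,
                         stringsAsFactors = FALSE)
  list(q_raw = q_raw, prot_raw = prot_raw, overlaps = overlaps,
       rep_map = rep_map, truth = list(key = keys$key[1],
                                       cell_line = unname(target_line),
                                       sign = ifelse(shift < 0, -1L, 1L)))
}
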