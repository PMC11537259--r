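scaled_quant <- function(values, prots) {
  n <- nrow(values)
  keys <- data.frame(protein_a = prots, pos_a = seq_len(n),
                     protein_b = prots, pos_b = seq_len(n) + 20L,
                     origin = "cross", is_intra = TRUE,
                     key = sprintf("%s:%d--%s:%d", prots, seq_len(n), prots,
                                   seq_len(n) + 20L),
                     stringsAsFactors = FALSE)
  residue_pair_quant(keys, values, colnames(values), stage = "scaled_log2")
}

test_that("OLS regression matches the closed-form oracle", {
  s <- paste0("s", 1:3)
  # closed form for x = [1,2,3], y = [1,1,4]:
  # slope = Sxy/Sxx = 3/2, intercept = ybar - slope*xbar = -1,
  # residuals = y - (intercept + slope x) = [0.5, -1, 0.5]
  prot <- matrix(c(1, 2, 3), 1, dimnames = list("P1", s))
  q <- scaled_quant(matrix(c(1, 1, 4), 1, dimnames = list(NULL, s)), "P1")
  r <- regress_out_protein(q, prot)
  expect_equal(r$slope, 1.5)
  expect_equal(r$intercept, -1)
  expect_equal(unname(r$residuals[1, ]), c(0.5, -1, 0.5))

  # perfect fit: y == x -> all-zero residuals
  q2 <- scaled_quant(matrix(c(1, 2, 3), 1, dimnames = list(NULL, s)), "P1")
  expect_equal(unname(regress_out_protein(q2, prot)$residuals[1, ]),
               c(0, 0, 0))
  # affine invariance: y = x + 0.7 -> all-zero residuals
  q3 <- scaled_quant(matrix(c(1, 2, 3) + 0.7, 1, dimnames = list(NULL, s)), "P1")
  expect_equal(unname(regress_out_protein(q3, prot)$residuals[1, ]),
               c(0, 0, 0))
})

test_that("residuals sum to zero and are orthogonal to the predictor", {
  set.seed(11)
  s <- paste0("s", 1:18)
  prots <- sprintf("P%02d", 1:10)
  prot <- matrix(rnorm(10 * 18), 10, dimnames = list(prots, s))
  q <- scaled_quant(matrix(rnorm(40 * 18), 40, dimnames = list(NULL, s)),
                    rep(prots, 4))
  r <- regress_out_protein(q, prot)
  for (i in seq_len(nrow(r$residuals))) {
    expect_lt(abs(sum(r$residuals[i, ])), 1e-9)
    expect_lt(abs(sum(r$residuals[i, ] * prot[r$accession[i], ])), 1e-9)
  }
})

test_that("zero-variance predictors fall back to the intercept model", {
  s <- paste0("s", 1:4)
  prot <- matrix(5, 1, 4, dimnames = list("P1", s))
  q <- scaled_quant(matrix(c(1, 2, 3, 4), 1, dimnames = list(NULL, s)), "P1")
  expect_warning(r <- regress_out_protein(q, prot), "zero-variance")
  expect_true(is.na(r$slope))
  expect_equal(unname(r$residuals[1, ]), c(1, 2, 3, 4) - 2.5)
})

test_that("missing proteins are skipped and counted", {
  s <- paste0("s", 1:3)
  prot <- matrix(c(1, 2, 3), 1, dimnames = list("P1", s))
  q <- scaled_quant(matrix(rnorm(6), 2, dimnames = list(NULL, s)),
                    c("P1", "P9"))
  expect_message(r <- regress_out_protein(q, prot), "skipped")
  expect_equal(r$n_skipped, 1L)
  expect_equal(nrow(r$residuals), 1L)
})

test_that("mutation overlap reproduces the MCM7 worked example", {
  # printed mutation aggregation: MCM7 | LS411N_284; SNU1040_611;
  # SNU1040_353; HCC2998_231
  muts <- data.frame(gene = "MCM7",
                     cell_line = c("LS411N", "SNU1040", "SNU1040", "HCC2998"),
                     position = c(284L, 611L, 353L, 231L),
                     stringsAsFactors = FALSE)
  gmap <- data.frame(gene = "MCM7", accession = "P33993",
                     stringsAsFactors = FALSE)
  pairs <- data.frame(protein_a = "P33993", pos_a = c(145L, 596L),
                      pos_b = c(557L, 648L),
                      key = c("P33993:145--P33993:557",
                              "P33993:596--P33993:648"),
                      stringsAsFactors = FALSE)
  ovl <- mutation_overlap(pairs, muts, gmap)
  # intralink 145-557 encompasses LS411N (284), SNU1040 (353), HCC2998 (231)
  got <- ovl$cell_line[ovl$key == pairs$key[1]]
  expect_setequal(got, c("LS411N", "SNU1040", "HCC2998"))
  expect_length(setdiff(got, "SNU1040"), 2L)  # two additional cell lines
  # intralink 596-648 encompasses only SNU1040 at 611
  expect_identical(ovl$cell_line[ovl$key == pairs$key[2]], "SNU1040")
  expect_identical(ovl$positions[ovl$key == pairs$key[2]], "611")
  # label string convention
  expect_identical(unname(aggregate_mutation_labels(muts)),
                   "MCM7 | LS411N_284; SNU1040_611; SNU1040_353; HCC2998_231")
})

test_that("mutation overlap is boundary-inclusive and reports unmapped genes", {
  muts <- data.frame(gene = c("G1", "G2"), cell_line = "CL",
                     position = c(100L, 5L), stringsAsFactors = FALSE)
  gmap <- data.frame(gene = "G1", accession = "A1", stringsAsFactors = FALSE)
  pairs <- data.frame(protein_a = "A1", pos_a = 100L, pos_b = 200L,
                      key = "A1:100--A1:200", stringsAsFactors = FALSE)
  expect_message(ovl <- mutation_overlap(pairs, muts, gmap), "G2")
  expect_equal(nrow(ovl), 1L)  # mutation exactly at pos_a overlaps
})

test_that("binary mutation matrix is consistent with the entries", {
  muts <- data.frame(gene = c("G1", "G1", "G2"),
                     cell_line = c("A", "A", "B"), position = c(1L, 5L, 9L))
  m <- mutation_binary_matrix(muts, cell_lines = c("A", "B", "C"))
  expect_identical(m["G1", ], c(A = 1L, B = 0L, C = 0L))
  expect_identical(m["G2", ], c(A = 0L, B = 1L, C = 0L))
})

test_that("select_events applies both filters, signs, and monotonicity", {
  mk_prof <- function(resid_row) {
    cl <- paste0("c", 1:10)
    structure(list(
      keys = data.frame(protein_a = "P", key = "k1"),
      residuals = matrix(resid_row, 1, dimnames = list("k1", cl)),
      slope = 1, intercept = 0, accession = "P", samples = cl,
      n_skipped = 0L), class = "regressed_profiles")
  }
  ovl <- data.frame(key = "k1", cell_line = "c1", positions = "10",
                    n_mutations = 1L, stringsAsFactors = FALSE)
  # residual -0.5, row SD ~0.1 -> event with sign -1
  row <- c(-0.5, rnorm(9, 0, 0.0001) + 0.05)
  ev <- select_events(mk_prof(row), ovl)
  expect_equal(nrow(ev), 1L); expect_equal(ev$sign, -1L)
  # residual 0.3 fails the 0.4 cutoff regardless of SD
  row2 <- c(0.3, rep(0.001, 9))
  expect_equal(nrow(select_events(mk_prof(row2), ovl)), 0L)
  # residual 0.6 fails the 2xSD filter when the row is noisy (SD 0.4)
  set.seed(2)
  row3 <- c(0.6, rnorm(9, 0, 0.45))
  prof3 <- mk_prof(row3)
  if (sd(prof3$residuals[1, ]) > 0.3)
    expect_equal(nrow(select_events(prof3, ovl)), 0L)
  # monotone: raising either threshold never adds events
  set.seed(14)
  for (i in 1:20) {
    prof <- mk_prof(rnorm(10, 0, 0.4))
    n1 <- nrow(select_events(prof, ovl, lfc_cut = 0.4, sd_mult = 2))
    expect_gte(n1, nrow(select_events(prof, ovl, lfc_cut = 0.6, sd_mult = 2)))
    expect_gte(n1, nrow(select_events(prof, ovl, lfc_cut = 0.4, sd_mult = 3)))
  }
})

test_that("no events are selected when cross-links equal protein profiles", {
  set.seed(15)
  s <- paste0("s", 1:18)
  prots <- sprintf("P%02d", 1:20)
  prot <- matrix(rnorm(20 * 18), 20, dimnames = list(prots, s))
  q <- scaled_quant(prot[rep(1:20, 2), ], rep(prots, 2))
  colnames(q$values) <- s
  r <- regress_out_protein(q, prot)
  ovl <- data.frame(key = r$keys$key, cell_line = "s1",
                    positions = "1", n_mutations = 1L)
  expect_equal(nrow(select_events(r, ovl, replicate_map = setNames(s, s),
                                  lfc_cut = 1e-6, sd_mult = 0)), 0L)
})
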