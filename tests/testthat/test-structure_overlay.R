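test_that("link_distance matches the Euclidean oracle", {
  # 3-4-5 triangle
  m <- structure_model("P", 1:2, rbind(c(0, 0, 0), c(3, 4, 0)), c(90, 90))
  expect_equal(link_distance(m, 1, 2), 5)
  expect_equal(link_distance(m, 1, 1), 0)          # degenerate
  expect_equal(link_distance(m, 2, 1), link_distance(m, 1, 2))  # symmetric
  expect_true(is.na(link_distance(m, 1, 99)))      # unmappable is explicit

  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    xyz <- matrix(rnorm(n * 3, sd = 20), n)
    mod <- structure_model("P", seq_len(n), xyz, rep(80, n))
    a <- sample(n, 1); b <- sample(n, 1)
    expect_equal(link_distance(mod, a, b),
                 sqrt(sum((xyz[a, ] - xyz[b, ])^2)), tolerance = 1e-9)
  }
})

test_that("PDB round-trip preserves coordinates and pLDDT", {
  mod <- toy_structure(40, "compact", seed = 5, accession = "PX1")
  p <- tempfile(fileext = ".pdb")
  write_structure_pdb(mod, p)
  back <- read_structure_pdb(p, accession = "PX1")
  expect_identical(attr(back, "accession"), "PX1")
  expect_equal(back$x, mod$x, tolerance = 1e-3)
  expect_equal(back$plddt, mod$plddt, tolerance = 1e-2)
  # AlphaFold-style name yields the accession
  p2 <- file.path(tempdir(), "AF-Q99999-F1-model_v4.pdb")
  write_structure_pdb(mod, p2)
  expect_identical(attr(read_structure_pdb(p2), "accession"), "Q99999")
})

test_that("toy structures obey their geometric contracts", {
  ext <- toy_structure(20, "extended", seed = 1)
  expect_equal(link_distance(ext, 1, 11), 38)      # 3.8 A per residue
  expect_equal(link_distance(ext, 5, 5), 0)
  cmp <- toy_structure(200, "compact", seed = 2)
  d <- as.matrix(dist(cmp[, c("x", "y", "z")]))
  expect_lt(max(d), 60)                            # inside a 30 A sphere
})

test_that("mean_plddt is the arithmetic mean", {
  m <- structure_model("P", 1:3, matrix(0, 3, 3), c(90, 70, 80))
  expect_equal(mean_plddt(m), 80)
  m2 <- structure_model("P", 1:5, matrix(0, 5, 3), rep(55, 5))
  expect_equal(mean_plddt(m2), 55)
  set.seed(3)
  pl <- runif(30, 0, 100)
  m3 <- structure_model("P", 1:30, matrix(rnorm(90), 30), pl)
  expect_equal(mean_plddt(m3), sum(pl) / 30)
})

test_that("distance profiles apply the intralink threshold and 20 A classes", {
  mk_ann <- function(acc, pairs, origin = "cross") {
    data.frame(protein_a = acc, pos_a = pairs[, 1], protein_b = acc,
               pos_b = pairs[, 2], origin = origin, is_intra = TRUE,
               shared_peptide = FALSE, loop_seq_distance = NA_integer_,
               csm_count = 2L,
               key = sprintf("%s:%d--%s:%d", acc, pairs[, 1], acc, pairs[, 2]),
               stringsAsFactors = FALSE)
  }
  ext <- toy_structure(100, "extended", seed = 1, accession = "PE")
  models <- list(PE = ext)
  # 6 intralinks all spanning 4 residues -> distances 15.2 A -> "shorter"
  short_pairs <- cbind(seq(1, 51, 10), seq(5, 55, 10))
  prof <- protein_distance_profile(models, mk_ann("PE", short_pairs))
  expect_equal(prof$class, "shorter")
  expect_equal(prof$mean_dist, 15.2)
  expect_equal(prof$sd_dist, 0)
  # 5 intralinks -> below the threshold -> omitted
  prof5 <- protein_distance_profile(models, mk_ann("PE", short_pairs[1:5, ]))
  expect_equal(nrow(prof5), 0L)
  # spans of 7 residues -> 26.6 A -> "longer"
  long_pairs <- cbind(seq(1, 51, 10), seq(8, 58, 10))
  expect_equal(protein_distance_profile(models, mk_ann("PE", long_pairs))$class,
               "longer")
  # boundary: mean exactly 20 A is "longer" (strict < for shorter)
  m20 <- structure_model("PB", 1:12,
                         cbind(rep(c(0, 20), 6), 0, 0), rep(90, 12))
  b_pairs <- cbind(seq(1, 11, 2), seq(2, 12, 2))
  expect_equal(protein_distance_profile(list(PB = m20),
                                        mk_ann("PB", b_pairs))$class, "longer")
  # long loop-links do not count toward the intralink threshold
  loops <- mk_ann("PE", short_pairs, origin = "long_loop")
  expect_equal(nrow(protein_distance_profile(models, loops)), 0L)
})

test_that("disorder overlap uses closed intervals and reports both fractions", {
  ann <- data.frame(
    protein_a = c("A", "A", "B", "C"), pos_a = c(75, 10, 20, 5),
    protein_b = c("A", "A", "B", "C"), pos_b = c(200, 20, 100, 9),
    key = paste0("k", 1:4), stringsAsFactors = FALSE)
  regions <- data.frame(accession = c("A", "B"), start = c(50, 100),
                        end = c(100, 150))
  out <- disorder_overlap(ann, regions)
  # side at 75 inside [50,100] -> both flags
  expect_true(out$in_disprot[1]); expect_true(out$in_disordered_region[1])
  # protein catalogued but both sides outside every region
  expect_true(out$in_disprot[2]); expect_false(out$in_disordered_region[2])
  # boundary position 100 is inside (closed interval)
  expect_true(out$in_disordered_region[3])
  # protein not catalogued at all
  expect_false(out$in_disprot[4])
  s <- attr(out, "summary")
  expect_equal(unname(s["frac_in_disprot"]), 3 / 4)
  expect_equal(unname(s["frac_link_in_region"]), 2 / 3)

  # hand-enumerated toy set of 20 links
  set.seed(6)
  ann20 <- data.frame(protein_a = sample(LETTERS[1:5], 20, TRUE),
                      pos_a = sample(1:300, 20), stringsAsFactors = FALSE)
  ann20$protein_b <- ann20$protein_a
  ann20$pos_b <- ann20$pos_a + sample(5:50, 20, TRUE)
  ann20$key <- paste0("k", 1:20)
  reg <- data.frame(accession = c("A", "B", "B"), start = c(10, 50, 200),
                    end = c(120, 90, 260))
  out20 <- disorder_overlap(ann20, reg)
  hand1 <- ann20$protein_a %in% c("A", "B")
  inr <- function(acc, pos)
    any(acc == reg$accession & pos >= reg$start & pos <= reg$end)
  hand2 <- hand1 & (mapply(inr, ann20$protein_a, ann20$pos_a) |
                    mapply(inr, ann20$protein_b, ann20$pos_b))
  expect_identical(out20$in_disprot, hand1)
  expect_identical(out20$in_disordered_region, unname(hand2))
})
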