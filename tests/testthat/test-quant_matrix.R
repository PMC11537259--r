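make_quant <- function(values, stage = "raw") {
  n <- nrow(values)
  keys <- data.frame(protein_a = sprintf("P%02d", seq_len(n)),
                     pos_a = seq_len(n), protein_b = sprintf("P%02d", seq_len(n)),
                     pos_b = seq_len(n) + 10L, origin = "cross",
                     is_intra = TRUE,
                     key = sprintf("P%02d:%d--P%02d:%d", seq_len(n), seq_len(n),
                                   seq_len(n), seq_len(n) + 10L),
                     stringsAsFactors = FALSE)
  residue_pair_quant(keys, values, colnames(values), stage = stage)
}

test_that("aggregate_pairs sums CSMs per pair and honours exclusions", {
  w <- tiny_world()
  rep <- attach_reporters(parse_plink_csv(w$path), planted_table(w$titles))
  cs <- csm_records(rep)
  ann <- to_residue_pairs(cs, w$fasta)
  q <- aggregate_pairs(cs, ann)
  expect_s3_class(q, "residue_pair_quant")
  expect_identical(q$stage, "raw")
  # the two-CSM pair is the channel-wise sum of its CSMs
  i <- which(rownames(q$values) == "PA:104--PB:55")
  expect_equal(q$values[i, ], cs$intensity[[1]] + cs$intensity[[2]])
  # permutation invariance in CSM order
  perm <- sample(nrow(cs))
  cs2 <- cs[perm, ]
  ann2 <- to_residue_pairs(cs2, w$fasta)
  q2 <- aggregate_pairs(cs2, ann2)
  expect_equal(q2$values[rownames(q$values), ], q$values)
})

test_that("short loops are excluded from aggregation, long loops included", {
  w <- tiny_world()
  rep <- attach_reporters(parse_plink_csv(w$path), planted_table(w$titles))
  cs <- csm_records(rep)
  # loop at sites 60/66 (distance 6): included by default, excluded at
  # loop_min above it
  q5 <- aggregate_pairs(cs, to_residue_pairs(cs, w$fasta, loop_min = 5L))
  expect_true("PA:60--PA:66" %in% rownames(q5$values))
  q7 <- aggregate_pairs(cs, to_residue_pairs(cs, w$fasta, loop_min = 7L))
  expect_false("PA:60--PA:66" %in% rownames(q7$values))
})

test_that("normalize_samples equalizes totals and preserves ranks", {
  v <- rbind(c(60, 150, 30), c(40, 50, 20))
  colnames(v) <- c("s1", "s2", "s3")   # totals 100, 200, 50
  q <- make_quant(v)
  n <- normalize_samples(q)
  expect_equal(unname(attr(n, "factors")), c(0.5, 1, 0.25))
  expect_equal(unname(colSums(n$values)), c(200, 200, 200))
  # equal totals -> identity
  ve <- rbind(c(10, 20), c(30, 20)); colnames(ve) <- c("a", "b")
  expect_equal(normalize_samples(make_quant(ve))$values, make_quant(ve)$values)
  # property: random matrices end with equal totals; within-sample ratios kept
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(runif(60, 1, 100), 10); colnames(m) <- paste0("s", 1:6)
    qq <- normalize_samples(make_quant(m))
    tot <- colSums(qq$values)
    expect_lt(diff(range(tot)) / max(tot), 1e-9)
    expect_equal(qq$values[, 1] / qq$values[2, 1],
                 m[, 1] / m[2, 1], tolerance = 1e-12, ignore_attr = TRUE)
  }
  # zero-total sample is a named error
  vz <- rbind(c(1, 0), c(2, 0)); colnames(vz) <- c("ok", "dead")
  expect_error(normalize_samples(make_quant(vz)), "dead")
})

test_that("scale_log2 centers rows on mean 1 and drops zero rows", {
  v <- rbind(c(2, 4, 6), c(5, 5, 5)); colnames(v) <- paste0("s", 1:3)
  q <- normalize_samples(make_quant(v))
  # bypass sample normalization effects by scaling a pre-normalized object
  q$values <- v
  s <- scale_log2(q)
  expect_equal(unname(s$values[1, ]), c(-1, 0, log2(1.5)), tolerance = 1e-12)
  expect_equal(unname(s$values[2, ]), c(0, 0, 0))
  # zero-containing rows are dropped with a message
  vz <- rbind(c(1, 2, 3), c(0, 5, 5)); colnames(vz) <- paste0("s", 1:3)
  qz <- make_quant(vz, stage = "raw"); qz$stage <- "normalized"
  expect_message(sz <- scale_log2(qz), "1 row")
  expect_equal(nrow(sz$values), 1L)
  expect_equal(attr(sz, "n_dropped"), 1L)
  # property: linear-scale mean of every retained row is exactly 1
  set.seed(8)
  m <- matrix(rlnorm(200 * 6), 200); colnames(m) <- paste0("s", 1:6)
  qq <- make_quant(m); qq$stage <- "normalized"
  ss <- scale_log2(qq)
  expect_true(all(abs(rowMeans(2^ss$values) - 1) < 1e-12))
})

test_that("replicate CV follows SD/mean x 100 on pre-log values", {
  v <- cbind(a1 = c(90, 50), a2 = c(110, 50), b = c(7, 8))
  q <- make_quant(v); q$stage <- "normalized"
  cv <- replicate_cv(q, c(a1 = "A", a2 = "A", b = "B"))
  expect_equal(colnames(cv), "A")      # singleton group emits no CV
  expect_equal(unname(cv[1, "A"]), sd(c(90, 110)) / 100 * 100)
  expect_equal(unname(cv[1, "A"]), 14.142136, tolerance = 1e-6)
  expect_equal(unname(cv[2, "A"]), 0)  # identical replicates
  expect_error(replicate_cv(q, c(a1 = "A", b = "B")), "every sample")
})

test_that("simulated 15% lognormal noise gives a median CV in [12, 18]%", {
  # Monte-Carlo oracle: duplicate channels drawn around a common mean with
  # multiplicative noise of CV 15%
  # 4 replicates keep the n-1 SD estimator close enough to the true scale
  # (with duplicates the estimator's median sits near 10%, an estimator
  # property, not a pipeline one)
  set.seed(123)
  n <- 1000
  sdlog <- sqrt(log(1 + 0.15^2))
  mu <- rlnorm(n, meanlog = log(1e5), sdlog = 1)
  v <- sapply(1:4, function(j) mu * rlnorm(n, -sdlog^2 / 2, sdlog))
  colnames(v) <- paste0("r", 1:4)
  keys <- data.frame(protein_a = "P", pos_a = seq_len(n), protein_b = "P",
                     pos_b = seq_len(n) + 1L, origin = "cross",
                     is_intra = TRUE, key = paste0("k", seq_len(n)),
                     stringsAsFactors = FALSE)
  q <- residue_pair_quant(keys, v, colnames(v), stage = "raw")
  q$stage <- "normalized"
  cv <- replicate_cv(q, setNames(rep("X", 4), colnames(v)))
  med <- attr(cv, "median_pooled")
  expect_gt(med, 12); expect_lt(med, 18)
})

test_that("quant matrices round-trip through disk with their stage", {
  set.seed(2)
  m <- matrix(runif(30, 1, 100), 5); colnames(m) <- paste0("s", 1:6)
  q <- make_quant(m)
  p <- tempfile(fileext = ".tsv")
  write_quant_matrix(q, p)
  back <- read_quant_matrix(p)
  expect_identical(back$stage, "raw")
  expect_equal(back$values, q$values, tolerance = 1e-6)
})
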