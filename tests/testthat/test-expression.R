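# small deterministic design used across these tests
make_meta <- function(replicates = 4, drop = TRUE) {
  simulate_counts(counts_sim_config(n_transcripts = 1, replicates = replicates,
                                    drop_library = drop),
                  seed = 1)$meta
}

test_that("cpm_normalize scales every library to one million", {
  set.seed(3)
  m <- matrix(rpois(300, 20), 50, 6,
              dimnames = list(sprintf("t%02d", 1:50), sprintf("lib%d", 1:6)))
  cpm <- cpm_normalize(m)
  expect_equal(unname(colSums(cpm)), rep(1e6, 6))
  expect_equal(cpm_normalize(matrix(5, 1, 3))[1, ], rep(1e6, 3)) # single transcript

  m0 <- m
  m0[, 2] <- 0
  expect_error(cpm_normalize(m0), "lib2", class = "allochrony_validation_error")
})

test_that("read_counts_mtx round-trips a sparse matrix with id sidecars", {
  td <- tempfile("mtx")
  dir.create(td)
  set.seed(41)
  m <- matrix(rpois(40, 2), 10, 4,
              dimnames = list(sprintf("t%02d", 1:10), sprintf("lib%d", 1:4)))
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), file.path(td, "c.mtx"))
  writeLines(rownames(m), file.path(td, "rows.txt"))
  writeLines(colnames(m), file.path(td, "cols.txt"))
  back <- read_counts_mtx(file.path(td, "c.mtx"), file.path(td, "rows.txt"),
                          file.path(td, "cols.txt"))
  expect_equal(back, m)
  expect_error(read_counts_mtx(file.path(td, "c.mtx"), file.path(td, "rows.txt"),
                               file.path(td, "rows.txt")),
               "do not match", class = "allochrony_validation_error")
})

test_that("filter_weak applies the CPM >= 1 in >= 7 libraries rule and is idempotent", {
  n_lib <- 23
  keep7 <- rep(0, n_lib)
  keep7[1:7] <- 1
  keep6 <- rep(0, n_lib)
  keep6[1:6] <- 1
  zero <- rep(0, n_lib)
  # filler tops every library up to exactly 1e6 reads, so counts are CPM
  filler <- 1e6 - keep7 - keep6 - zero
  m <- rbind(filler, keep7, keep6, zero)
  dimnames(m) <- list(c("filler", "keep7", "keep6", "zero"),
                      sprintf("lib%02d", 1:n_lib))
  out <- filter_weak(m)
  expect_setequal(rownames(out), c("filler", "keep7"))
  log <- attr(out, "filter_log")
  expect_equal(log$n_input, 4)
  expect_equal(log$n_kept, 2)
  expect_setequal(log$dropped, c("keep6", "zero"))

  again <- filter_weak(out)
  expect_equal(rownames(again), rownames(out))
  expect_equal(as.vector(again), as.vector(out))

  expect_error(filter_weak(m[, 1:5], min_libraries = 7),
               class = "allochrony_validation_error")
})

test_that("contrast_table covers the nine contrasts with the stated sign conventions", {
  meta <- make_meta()
  n_lib <- nrow(meta) # 23 with the dropped Z 1.3h library
  expect_equal(n_lib, 23)
  set.seed(8)
  m <- matrix(rnbinom(200 * n_lib, mu = 50, size = 20), 200, n_lib,
              dimnames = list(sprintf("t%03d", 1:200), meta$library_id))
  ct <- contrast_table(m, meta)
  expect_s3_class(ct, "contrast_table")
  expect_equal(sort(unique(ct$contrast)), sort(names(CONTRAST_GROUPS)))
  expect_equal(nrow(ct), 200 * 9)
  expect_true(all(ct$q_value >= ct$p_value - 1e-12))
  expect_true(all(ct$q_value >= 0 & ct$q_value <= 1))

  # identical group means -> log_fc 0, p 1 (constant transcript)
  flat <- matrix(30, 2, n_lib, dimnames = list(c("a", "b"), meta$library_id))
  ctf <- contrast_table(flat, meta)
  expect_true(all(ctf$log_fc == 0))
  expect_true(all(ctf$p_value == 1))

  # 4x mean CPM ratio -> log_fc = 2 as the prior count vanishes; the second
  # transcript compensates so library totals (and hence CPM scaling) are equal
  e4 <- meta$library_id[meta$strain == "E" & meta$timepoint == "4h"]
  quad <- matrix(30, 2, n_lib, dimnames = list(c("a", "b"), meta$library_id))
  quad["b", ] <- 120
  quad["a", e4] <- 120
  quad["b", e4] <- 30
  lfc <- contrast_table(quad, meta, prior_count = 1e-9)
  lfc_a <- lfc[lfc$transcript == "a" & lfc$contrast == "E_vs_Z.4h", "log_fc"]
  expect_equal(lfc_a, 2, tolerance = 1e-6)

  # sign: higher in E -> positive; higher at the earlier timepoint -> positive
  expect_gt(lfc_a, 0)
  lfc_within <- lfc[lfc$transcript == "a" & lfc$contrast == "E.photophase_vs_4h", "log_fc"]
  expect_lt(lfc_within, 0)

  # metadata/matrix mismatch errors name the orphans
  expect_error(contrast_table(m[, -1], meta), meta$library_id[1],
               class = "allochrony_validation_error")
  # a contrast group below 2 libraries errors and names the contrast
  small <- meta[!(meta$strain == "Z" & meta$timepoint == "1.3h" & meta$replicate > 1), ]
  expect_error(contrast_table(m[, small$library_id], small), "fewer than 2",
               class = "allochrony_validation_error")
})

test_that("reversing a contrast's groups negates log_fc and preserves p", {
  meta <- make_meta()
  set.seed(9)
  m <- matrix(rnbinom(50 * 23, mu = 80, size = 10), 50, 23,
              dimnames = list(sprintf("t%02d", 1:50), meta$library_id))
  # relabelling the strains swaps a and b in every between-strain contrast
  meta_swapped <- meta
  meta_swapped$strain <- ifelse(meta$strain == "E", "Z", "E")
  ct <- contrast_table(m, meta)
  cts <- contrast_table(m, meta_swapped)
  for (tp in c("photophase", "1.3h", "4h")) {
    a <- ct[ct$contrast == paste0("E_vs_Z.", tp), ]
    b <- cts[cts$contrast == paste0("E_vs_Z.", tp), ]
    expect_equal(b$log_fc, -a$log_fc)
    expect_equal(b$p_value, a$p_value)
  }
})

test_that("BH correction matches the step-up hand computation", {
  meta <- make_meta()
  # independent check of the adjustment on a fixed p-vector
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(stats::p.adjust(p, "BH"), rep(0.04, 4))
  # monotone in the p-value ranking within each contrast
  set.seed(10)
  m <- matrix(rnbinom(100 * 23, mu = 60, size = 5), 100, 23,
              dimnames = list(sprintf("t%03d", 1:100), meta$library_id))
  ct <- contrast_table(m, meta)
  one <- ct[ct$contrast == "E_vs_Z.4h", ]
  o <- order(one$p_value)
  expect_true(all(diff(one$q_value[o]) >= -1e-12))
})

test_that("strain_timepoint_means averages available replicates in fixed order", {
  meta <- make_meta()
  cpm <- matrix(seq_len(23), 1, 23, dimnames = list("t1", meta$library_id))
  mp <- strain_timepoint_means(cpm, meta)
  expect_equal(colnames(mp), c("E.photophase", "E.1.3h", "E.4h",
                               "Z.photophase", "Z.1.3h", "Z.4h"))
  z13 <- meta$library_id[meta$strain == "Z" & meta$timepoint == "1.3h"]
  expect_length(z13, 3) # dropped library
  expect_equal(mp[1, "Z.1.3h"], mean(cpm[1, z13]))

  # permuting library order leaves the profile unchanged
  perm <- sample(23)
  expect_equal(strain_timepoint_means(cpm[, perm, drop = FALSE], meta), mp)

  # constant transcript -> constant profile
  const <- matrix(7, 1, 23, dimnames = list("c", meta$library_id))
  expect_true(all(strain_timepoint_means(const, meta) == 7))

  expect_error(strain_timepoint_means(cpm, meta[meta$strain == "E", ]),
               "empty group", class = "allochrony_validation_error")
})

test_that("profile_correlations: exact values, skipping, and t(4) p-values", {
  prof <- rbind(a = c(1, 2, 3, 4, 5, 6),
                b = c(2, 4, 6, 8, 10, 12),   # same shape as a -> r = 1
                c = 7 - c(1, 2, 3, 4, 5, 6), # reflection -> r = -1
                k = rep(5, 6))               # constant -> skipped
  expect_warning(pc <- profile_correlations(prof), "constant")
  ab <- pc[pc$transcript_a == "a" & pc$transcript_b == "b", ]
  ac <- pc[pc$transcript_a == "a" & pc$transcript_b == "c", ]
  expect_equal(ab$r, 1)
  expect_equal(ac$r, -1)
  expect_false("k" %in% c(pc$transcript_a, pc$transcript_b))
  expect_true(all(pc$p_value > 0 & pc$p_value <= 1))

  # p-values match numerical integration of the t density with 4 df
  t_density <- function(x) gamma(2.5) / (sqrt(4 * pi) * gamma(2)) * (1 + x^2 / 4)^(-2.5)
  for (r in c(-0.82, -0.3, 0.5, 0.91, 0.97)) {
    tstat <- r * sqrt(4 / (1 - r^2))
    p_num <- 2 * stats::integrate(t_density, abs(tstat), Inf,
                                  rel.tol = 1e-12)$value
    expect_equal(profile_cor_test(r), p_num, tolerance = 1e-9)
  }

  # alpha restriction
  set.seed(12)
  prof2 <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("t%02d", 1:10), NULL))
  all_pairs <- profile_correlations(prof2)
  sig <- profile_correlations(prof2, alpha = 0.05)
  expect_equal(sig, all_pairs[all_pairs$p_value < 0.05, ], ignore_attr = TRUE)
})

test_that("cap_logfc clamps for display and flags significance", {
  tb <- data.frame(transcript = c("a", "b", "c"), contrast = "E_vs_Z.photophase",
                   log_fc = c(2.691, -2.86, 1.4),
                   p_value = c(0.001, 0.001, 0.5), q_value = c(0.012, 0.016, 0.7))
  capped <- cap_logfc(tb)
  expect_equal(capped$log_fc_capped, c(2, -2, 1.4))
  expect_equal(capped$log_fc, tb$log_fc) # original column untouched
  expect_equal(capped$marker, c("*", "*", ""))
  expect_error(cap_logfc(tb, lo = 2, hi = -2), class = "allochrony_validation_error")
})
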