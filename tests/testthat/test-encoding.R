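test_that("normalization extrema match a brute-force oracle and degenerate columns map to 0", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 4L, length_range = c(20L, 30L),
                                        seed = 3L))
  stats <- fit_normalization(ds$chains, provenance = "oracle-check")
  stacked_pssm <- do.call(rbind, lapply(ds$chains, `[[`, "pssm"))
  stacked_hmm <- 2^(-do.call(rbind, lapply(ds$chains, `[[`, "hmm")) / 1000)
  for (j in 1:20) {
    expect_identical(stats$pssm$min[[j]], as.numeric(min(stacked_pssm[, j])))
    expect_identical(stats$pssm$max[[j]], as.numeric(max(stacked_pssm[, j])))
    expect_identical(stats$hmm$min[[j]], min(stacked_hmm[, j], na.rm = TRUE))
    expect_identical(stats$hmm$max[[j]], max(stacked_hmm[, j], na.rm = TRUE))
  }
  expect_identical(stats$provenance, "oracle-check")
  expect_error(fit_normalization(list()), "empty")

  # single residue, all scores equal: min == max, scaling yields 0
  one <- ds$chains[[1]]
  one$pssm <- matrix(3L, 1, 20)
  one$hmm <- matrix(1000, 1, 20)
  s1 <- fit_normalization(list(one))
  expect_identical(s1$pssm$min, s1$pssm$max)
  expect_identical(s1$pssm$constant, 1:20)
  expect_true(all(encode_pssm(one, s1) == 0))
})

test_that("min-max encoding hits endpoints, midpoint, and clamps out-of-range values", {
  stats <- structure(list(
    pssm = list(min = rep(-2, 20), max = rep(6, 20), constant = integer(0)),
    hmm = list(min = rep(0, 20), max = rep(1, 20), constant = integer(0)),
    provenance = "fixed"), class = "norm_stats")
  x <- matrix(rep(c(-2, 6, 2, -5, 9), each = 20), 5, 20, byrow = TRUE)
  enc <- encode_pssm(x, stats)
  expect_equal(enc[1, 1], 0, ignore_attr = TRUE)    # x = min
  expect_equal(enc[2, 1], 1, ignore_attr = TRUE)    # x = max
  expect_equal(enc[3, 1], 0.5, ignore_attr = TRUE)  # midpoint
  expect_equal(enc[4, 1], 0, ignore_attr = TRUE)    # below training min, clamped
  expect_equal(enc[5, 1], 1, ignore_attr = TRUE)    # above training max, clamped
})

test_that("hhm scores convert to emission probabilities before scaling", {
  expect_equal(hhm_score_to_prob(0), 1)
  expect_equal(hhm_score_to_prob(1000), 0.5)
  expect_equal(hhm_score_to_prob(3000), 0.125)
  expect_error(hhm_score_to_prob(-5), "negative")
  # strictly decreasing in the score for present cells
  s <- seq(0, 6000, by = 250)
  expect_true(all(diff(hhm_score_to_prob(s)) < 0))

  stats <- structure(list(
    pssm = list(min = rep(0, 20), max = rep(1, 20), constant = integer(0)),
    hmm = list(min = rep(0, 20), max = rep(1, 20), constant = integer(0)),
    provenance = "fixed"), class = "norm_stats")
  m <- matrix(NA_real_, 2, 20)
  m[1, 1] <- 0
  enc <- encode_hmm(m, stats)
  expect_equal(enc[1, 1], 1, ignore_attr = TRUE)          # score 0 -> probability 1
  expect_equal(enc[2, 1], 0, ignore_attr = TRUE)          # absent -> probability 0
  expect_error(encode_hmm(matrix(-1, 1, 20), stats), "negative")
})

test_that("DSSP encoding is a 14-d vector with exact trigonometry and RSA", {
  df <- data.frame(resnum = 1:3, chain = "A", aa = c("A", "G", "W"),
                   ss = c("H", "L", "E"), acc = c(129, 52, 600),
                   phi = c(-90, NA, 45), psi = c(90, 30, NA),
                   stringsAsFactors = FALSE)
  enc <- encode_dssp(df)
  expect_identical(dim(enc), c(3L, 14L))
  expect_equal(rowSums(enc[, 1:9]), rep(1, 3))          # one-hot block
  expect_equal(enc[1, "H"], 1, ignore_attr = TRUE)
  expect_equal(enc[1, 10], 0, ignore_attr = TRUE)    # sin(-90deg) = -1 -> rescaled 0
  expect_equal(enc[1, 11], 0.5, ignore_attr = TRUE)  # cos(-90deg) = 0 -> 0.5
  expect_equal(enc[1, 12], 1, ignore_attr = TRUE)    # sin(90deg) = 1 -> 1
  expect_equal(enc[1, 14], 1, ignore_attr = TRUE)    # acc = maxASA(A) = 129 -> rsa 1
  expect_equal(enc[2, 10:11], c(0.5, 0.5), ignore_attr = TRUE)  # undefined phi -> neutral
  expect_equal(enc[2, 14], 0.5, ignore_attr = TRUE)  # 52 / 104 for glycine
  expect_equal(enc[3, 14], 1, ignore_attr = TRUE)    # above maxASA, capped
  expect_error(encode_dssp(transform(df, ss = c("H", "Q", "E"))), "Q")

  raw <- encode_dssp(df, trig_raw = TRUE)
  expect_equal(raw[1, 10], -1, ignore_attr = TRUE)
  expect_equal(raw[2, 10:11], c(0, 0), ignore_attr = TRUE)
})

test_that("uncovered residues get the NONE state and neutral fillers", {
  df <- data.frame(resnum = c(1L, 3L), chain = "A", aa = c("A", "C"),
                   ss = c("H", "E"), acc = c(10, 10), phi = c(-60, -120),
                   psi = c(-45, 130), stringsAsFactors = FALSE)
  enc <- encode_dssp(df, L = 3L, coverage = c(TRUE, FALSE, TRUE))
  expect_equal(enc[2, "NONE"], 1, ignore_attr = TRUE)
  expect_equal(rowSums(enc[, 1:9]), rep(1, 3))
  expect_equal(enc[2, 10:13], rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(enc[2, 14], 0, ignore_attr = TRUE)
})

test_that("fit+apply on the training set itself lands every feature in [0,1] with tight columns", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 6L, length_range = c(30L, 50L),
                                        seed = 11L))
  stats <- fit_normalization(ds$chains)
  enc <- lapply(ds$chains, encode_chain, stats = stats)
  P <- do.call(rbind, lapply(enc, `[[`, "pssm_feat"))
  H <- do.call(rbind, lapply(enc, `[[`, "hmm_feat"))
  D <- do.call(rbind, lapply(enc, `[[`, "dssp_feat"))
  for (M in list(P, H, D)) {
    expect_true(all(is.finite(M)))
    expect_true(all(M >= 0 & M <= 1))
  }
  nonconst <- setdiff(1:20, stats$pssm$constant)
  expect_equal(unname(apply(P[, nonconst], 2, min)), rep(0, length(nonconst)))
  expect_equal(unname(apply(P[, nonconst], 2, max)), rep(1, length(nonconst)))
})

test_that("normalization statistics round-trip bit-identically through JSON", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 3L, length_range = c(15L, 25L),
                                        seed = 7L))
  stats <- fit_normalization(ds$chains, provenance = "roundtrip")
  path <- withr::local_tempfile(fileext = ".json")
  save_norm_stats(stats, path)
  back <- load_norm_stats(path)
  expect_identical(back$pssm$min, stats$pssm$min)
  expect_identical(back$pssm$max, stats$pssm$max)
  expect_identical(back$hmm$min, stats$hmm$min)
  expect_identical(back$hmm$max, stats$hmm$max)
  expect_identical(back$provenance, stats$provenance)
})
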