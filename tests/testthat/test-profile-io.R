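test_that("PSSM round-trips through the ascii dialect", {
  path <- withr::local_tempfile(fileext = ".pssm")
  fx <- write_tiny_pssm(path)
  got <- read_pssm(path)
  expect_identical(unname(got$scores), unname(fx$scores) + 0)
  expect_identical(got$residue_letters, fx$letters)
  expect_identical(colnames(got$scores), ppisite:::PSSM_ALPHABET)

  # generator-written file equals the generator's in-memory ground truth
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  for (ch in ds$chains) {
    parsed <- read_pssm(file.path(dir, paste0(ch$record$protein_id, ".pssm")))
    expect_equal(unname(parsed$scores), unname(ch$pssm) + 0)
    expect_identical(parsed$residue_letters, ch$record$sequence)
  }
})

test_that("malformed or empty PSSM bodies raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".pssm")
  write_tiny_pssm(path)
  lines <- readLines(path)
  body_row <- grep("^    2 ", lines)[[1]]
  f <- strsplit(trimws(lines[[body_row]]), "\\s+")[[1]]
  lines[[body_row]] <- paste(f[1:41], collapse = " ")  # 39 score columns
  writeLines(lines, path)
  expect_error(read_pssm(path), paste0("line ", body_row))

  empty <- withr::local_tempfile(fileext = ".pssm")
  writeLines(readLines(path)[1:3], empty)
  expect_error(read_pssm(empty), "no residue rows")

  not_pssm <- withr::local_tempfile()
  writeLines(c("just", "text"), not_pssm)
  expect_error(read_pssm(not_pssm), "header")
})

test_that(".hhm round-trips, including '*' absent cells and score 0", {
  path <- withr::local_tempfile(fileext = ".hhm")
  m <- matrix(NA_real_, 2, 20)  # degenerate all-absent profile
  write_hhm(m, "MK", path)
  got <- read_hhm(path)
  expect_true(all(is.na(got$match_scores)))
  expect_identical(dim(got$match_scores), c(2L, 20L))

  m[1, 3] <- 0  # explicit zero is a real score, not absent
  write_hhm(m, "MK", path)
  got <- read_hhm(path)
  expect_identical(unname(got$match_scores[1, 3]), 0)
  expect_identical(sum(!is.na(got$match_scores)), 1L)

  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  for (ch in ds$chains) {
    parsed <- read_hhm(file.path(dir, paste0(ch$record$protein_id, ".hhm")))
    expect_equal(unname(parsed$match_scores), unname(ch$hmm) + 0)
  }
})

test_that(".hhm structural errors are caught", {
  path <- withr::local_tempfile(fileext = ".hhm")
  write_hhm(matrix(1000, 3, 20), "MKL", path)
  lines <- readLines(path)
  writeLines(lines[trimws(lines) != "#"], path)
  expect_error(read_hhm(path), "#")

  write_hhm(matrix(1000, 3, 20), "MKL", path)
  lines <- readLines(path)
  lines <- sub("^LENG  3", "LENG  5", lines)
  writeLines(lines, path)
  expect_error(read_hhm(path), "LENG")
})

test_that("DSSP fields parse from their fixed columns", {
  path <- withr::local_tempfile(fileext = ".dssp")
  df <- data.frame(resnum = 1:3, chain = "A", aa = c("M", "K", "L"),
                   ss = c("H", "L", "E"), acc = c(80, 120, 15),
                   phi = c(-60, NA, -120), psi = c(-45, 100, NA),
                   stringsAsFactors = FALSE)
  write_dssp(df, path)
  got <- read_dssp(path)
  expect_identical(nrow(got), 3L)
  expect_identical(got$ss, c("H", "L", "E"))  # blank column is the loop state
  expect_equal(got$acc, c(80, 120, 15))
  expect_equal(got$phi, c(-60, NA, -120))     # 360.0 sentinel -> undefined
  expect_equal(got$psi, c(-45, 100, NA))
  expect_identical(attr(got, "n_breaks"), 0L)

  # chain-break rows are skipped and counted; L = non-break rows
  df2 <- rbind(df[1:2, ],
               data.frame(resnum = 0, chain = "A", aa = "!", ss = "L",
                          acc = 0, phi = NA, psi = NA),
               df[3, ])
  write_dssp(df2, path)
  got2 <- read_dssp(path)
  expect_identical(nrow(got2), 3L)
  expect_identical(attr(got2, "n_breaks"), 1L)

  writeLines(c("not", "dssp"), path)
  expect_error(read_dssp(path), "RESIDUE")
})

test_that("align_profiles binds consistent inputs and rejects mismatches", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  chains <- load_dataset(dir)
  expect_length(chains, 3L)
  for (id in names(chains)) {
    orig <- Filter(function(ch) ch$record$protein_id == id, ds$chains)[[1]]
    expect_equal(unname(chains[[id]]$pssm), unname(orig$pssm) + 0)
    expect_equal(unname(chains[[id]]$hmm), unname(orig$hmm) + 0)
    expect_identical(chains[[id]]$record$labels, orig$record$labels)
    expect_identical(nrow(chains[[id]]$dssp), nchar(orig$record$sequence))
  }

  ch <- ds$chains[[1]]
  L <- nchar(ch$record$sequence)
  short_dssp <- ch$dssp[-3, ]  # DSSP missing one residue: placed by resnum
  bound <- align_profiles(ch$record,
                          structure(list(scores = ch$pssm,
                                         residue_letters = ch$record$sequence),
                                    class = "raw_pssm"),
                          structure(list(match_scores = ch$hmm,
                                         residue_letters = ch$record$sequence),
                                    class = "raw_hhm"),
                          short_dssp)
  expect_identical(which(!bound$dssp_coverage), 3L)

  # length mismatch names all four lengths
  expect_error(
    align_profiles(ch$record,
                   structure(list(scores = ch$pssm[-1, ],
                                  residue_letters = substr(ch$record$sequence, 2, L)),
                             class = "raw_pssm"),
                   structure(list(match_scores = ch$hmm,
                                  residue_letters = ch$record$sequence),
                             class = "raw_hhm"),
                   ch$dssp),
    paste0("sequence ", L, ", PSSM ", L - 1))
})

test_that("letter comparison tolerates X and small disagreement only", {
  rec <- protein_record("XTOL", "ACDEFGHIKLACDEFGHIKL")
  L <- 20L
  seq_x <- paste0("X", substr(rec$sequence, 2, L))
  mk_pssm <- function(letters) structure(
    list(scores = matrix(0L, L, 20), residue_letters = letters),
    class = "raw_pssm")
  mk_hmm <- function(letters) structure(
    list(match_scores = matrix(1000, L, 20), residue_letters = letters),
    class = "raw_hhm")
  dssp <- data.frame(resnum = seq_len(L), chain = "A",
                     aa = strsplit(rec$sequence, "")[[1]], ss = "L",
                     acc = 10, phi = -60, psi = -40, stringsAsFactors = FALSE)
  # X at a disagreeing position is tolerated
  expect_s3_class(align_profiles(rec, mk_pssm(seq_x), mk_hmm(rec$sequence), dssp),
                  "chain_profiles")
  # 3 of 20 real mismatches (15%) is not
  bad <- paste0("WWW", substr(rec$sequence, 4, L))
  expect_error(align_profiles(rec, mk_pssm(bad), mk_hmm(rec$sequence), dssp),
               "mismatch")
})

test_that("labels and fasta round-trip", {
  dir <- withr::local_tempdir()
  labs <- c(A1 = "0101", B2 = "111")
  write_labels(labs, file.path(dir, "labels.txt"))
  expect_identical(read_labels(file.path(dir, "labels.txt")), labs)
  write_fasta(c(A1 = "MKLV"), file.path(dir, "a.fasta"))
  expect_identical(read_fasta(file.path(dir, "a.fasta")), c(A1 = "MKLV"))
})
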