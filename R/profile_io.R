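# Parsers and writers for the three per-residue profile dialects consumed by
# the pipeline: PSI-BLAST ascii PSSM, HHblits .hhm, and classic DSSP text
# output, plus FASTA sequences and plain-text 0/1 label strings.

#' Column alphabet of a PSI-BLAST ascii PSSM (log-odds block)
#' @keywords internal
PSSM_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

#' Column alphabet of an HHblits .hhm match-emission block
#' @keywords internal
HHM_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                  "M","N","P","Q","R","S","T","V","W","Y")

#' Secondary-structure state space
#'
#' The eight DSSP structure classes (alpha-helix H, 3-10 helix G, pi-helix I,
#' turn T, beta-bridge B, beta-strand E, bend S, and loop/irregular L, which
#' DSSP denotes by a blank column) plus a ninth `NONE` state for residues the
#' DSSP output does not cover at all.
#' @export
SS_STATES <- c("H","G","I","T","B","E","S","L","NONE")

#' Construct a per-chain protein record
#'
#' @param protein_id Chain identifier (conventionally PDB id + chain letter).
#' @param sequence Amino-acid sequence over the 20 standard letters plus `X`.
#' @param labels Optional integer vector of 0/1 binding-site labels, one per
#'   residue (1 = interface residue).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein_id, sequence, labels = NULL) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("protein record '", protein_id, "': empty sequence")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(PSSM_ALPHABET, "X"))
  if (length(bad))
    stop("protein record '", protein_id, "': invalid residue letters: ",
         paste(unique(bad), collapse = ","))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nchar(sequence))
      stop("protein record '", protein_id, "': ", length(labels),
           " labels for ", nchar(sequence), " residues")
    if (!all(labels %in% c(0L, 1L)))
      stop("protein record '", protein_id, "': labels must be 0/1")
  }
  structure(list(protein_id = as.character(protein_id),
                 sequence = sequence, labels = labels),
            class = "protein_record")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to a FASTA file
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read per-chain 0/1 label strings
#'
#' One line per chain: `<id><TAB><0/1 string>`, label string as long as the
#' chain sequence.
#' @param path Label file.
#' @return Named character vector of 0/1 strings.
#' @export
read_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    stop("label file '", path, "': line ", bad[[1]],
         " is not '<id>\\t<0/1 string>'")
  out <- vapply(parts, `[[`, "", 2L)
  names(out) <- vapply(parts, `[[`, "", 1L)
  if (any(grepl("[^01]", out)))
    stop("label file '", path, "': labels must be 0/1 strings")
  out
}

#' @rdname read_labels
#' @param labels Named character vector of 0/1 strings.
#' @export
write_labels <- function(labels, path) {
  writeLines(paste(names(labels), labels, sep = "\t"), path)
  invisible(path)
}

label_string_to_int <- function(s) as.integer(strsplit(s, "")[[1]])

#' Read a PSI-BLAST ascii PSSM
#'
#' Parses the `-out_ascii_pssm` dialect: header, a 40-column body (20 log-odds
#' scores followed by 20 weighted observed percentages per residue), trailing
#' statistics. Only the log-odds block is retained.
#'
#' @param path PSSM file.
#' @return An object of class `raw_pssm`: list with `scores` (L x 20 integer
#'   matrix, columns in PSI-BLAST order) and `residue_letters` (length-L
#'   string echoed from the file).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- NA_integer_
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) == 40L && all(nchar(f) == 1L) && all(f %in% LETTERS)) {
      hdr <- i
      break
    }
  }
  if (is.na(hdr))
    stop("'", path, "': not a PSI-BLAST ascii PSSM (no 40-letter column header)")
  scores <- list()
  letters <- character()
  i <- hdr + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    pos <- suppressWarnings(as.integer(f[[1]]))
    if (is.na(pos)) break  # trailing statistics block
    vals <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (length(vals) < 40L || anyNA(vals[seq_len(40L)]))
      stop("'", path, "' line ", i,
           ": malformed PSSM row (expected 40 numeric score columns)")
    letters <- c(letters, f[[2]])
    scores[[length(scores) + 1L]] <- vals[1:20]
    i <- i + 1L
  }
  if (!length(scores))
    stop("'", path, "': PSSM body contains no residue rows")
  m <- do.call(rbind, scores)
  dimnames(m) <- list(NULL, PSSM_ALPHABET)
  structure(list(scores = m, residue_letters = paste(letters, collapse = "")),
            class = "raw_pssm")
}

#' Write a PSI-BLAST-style ascii PSSM
#'
#' Emits the `-out_ascii_pssm` layout (header line, 40-column body, trailing
#' statistics) so that files written here round-trip through [read_pssm()].
#'
#' @param scores L x 20 matrix of integer log-odds, PSI-BLAST column order.
#' @param letters Length-L residue string (or character vector).
#' @param path Output file.
#' @export
write_pssm <- function(scores, letters, path) {
  if (length(letters) == 1L) letters <- strsplit(letters, "")[[1]]
  stopifnot(nrow(scores) == length(letters), ncol(scores) == 20L)
  pct <- pmin(pmax((round(scores) + 8L) * 5L, 0L), 99L)  # filler percentage block
  hdr <- paste0("           ",
                paste(sprintf("%3s", PSSM_ALPHABET), collapse = ""), " ",
                paste(sprintf("%3s", PSSM_ALPHABET), collapse = ""))
  rows <- vapply(seq_len(nrow(scores)), function(i) {
    paste0(sprintf("%5d %s  ", i, letters[[i]]),
           paste(sprintf("%3d", round(scores[i, ])), collapse = " "), "  ",
           paste(sprintf("%3d", pct[i, ]), collapse = " "),
           sprintf("  %4.2f %8.2f", 0.50, 1.00))
  }, "")
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted observed",
          "percentages rounded down, information per position, and relative",
          "weight of gapless real matches to pseudocounts"),
    hdr, rows, "",
    "                      K         Lambda",
    "Standard Ungapped    0.1347     0.3157",
    "Standard Gapped      0.0410     0.2670",
    "PSI Ungapped         0.1347     0.3157",
    "PSI Gapped           0.0410     0.2670"), path)
  invisible(path)
}

#' Read an HHblits .hhm profile
#'
#' Parses the `.hhm` layout: header (with a `LENG` line), a `#` delimiter,
#' NULL/HMM header lines, then per-residue blocks of 20 match-emission scores
#' (the -1000*log2 probability encoding; `*` denotes an absent/negligible
#' emission) followed by a transition line, which is discarded.
#'
#' @param path `.hhm` file.
#' @return An object of class `raw_hhm`: list with `match_scores` (L x 20
#'   matrix, `NA` marking `*` cells, columns in HH-suite alphabetical order)
#'   and `residue_letters`.
#' @export
read_hhm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  leng <- NA_integer_
  for (ln in lines) {
    if (startsWith(ln, "LENG")) {
      leng <- suppressWarnings(as.integer(strsplit(trimws(ln), "\\s+")[[1]][[2]]))
      break
    }
  }
  hash <- which(trimws(lines) == "#")
  if (!length(hash))
    stop("'", path, "': not an .hhm profile (missing '#' delimiter line)")
  scores <- list()
  letters <- character()
  i <- hash[[1]] + 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "//") break
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) >= 22L && nchar(f[[1]]) == 1L && f[[1]] %in% LETTERS &&
        !is.na(suppressWarnings(as.integer(f[[2]])))) {
      cells <- f[3:22]
      vals <- suppressWarnings(as.numeric(ifelse(cells == "*", NA, cells)))
      if (any(is.na(vals) & cells != "*"))
        stop("'", path, "' line ", i, ": non-numeric .hhm match score")
      letters <- c(letters, f[[1]])
      scores[[length(scores) + 1L]] <- vals
    }
    i <- i + 1L
  }
  if (!length(scores))
    stop("'", path, "': no residue blocks found after '#'")
  if (!is.na(leng) && length(scores) != leng)
    stop("'", path, "': ", length(scores),
         " residue blocks but header declares LENG ", leng)
  m <- do.call(rbind, scores)
  dimnames(m) <- list(NULL, HHM_ALPHABET)
  structure(list(match_scores = m,
                 residue_letters = paste(letters, collapse = "")),
            class = "raw_hhm")
}

#' Write an HHblits-style .hhm profile
#'
#' @param match_scores L x 20 matrix of non-negative integers, `NA` for `*`.
#' @param letters Length-L residue string or character vector.
#' @param path Output file.
#' @param name Profile name for the header.
#' @export
write_hhm <- function(match_scores, letters, path, name = "chain") {
  if (length(letters) == 1L) letters <- strsplit(letters, "")[[1]]
  L <- nrow(match_scores)
  stopifnot(L == length(letters), ncol(match_scores) == 20L)
  cell <- function(v) ifelse(is.na(v), "*", sprintf("%d", round(v)))
  blocks <- unlist(lapply(seq_len(L), function(i) {
    c(paste(c(letters[[i]], sprintf("%d", i), cell(match_scores[i, ]),
              sprintf("%d", i)), collapse = "\t"),
      paste(c("", rep("0", 7), "1000", "1000", "1000"), collapse = "\t"),
      "")
  }))
  writeLines(c(
    "HHsearch 1.5",
    paste0("NAME  ", name),
    sprintf("LENG  %d match states, %d columns in multiple alignment", L, L),
    "FILT  filtered with hhfilter",
    "SEQ",
    paste0(">", name),
    paste(letters, collapse = ""),
    "#",
    paste(c("NULL", rep("3706", 20)), collapse = "\t"),
    paste(c("HMM", HHM_ALPHABET), collapse = "\t"),
    paste(c("", "M->M", "M->I", "M->D", "I->M", "I->I", "D->M", "D->D",
            "Neff", "Neff_I", "Neff_D"), collapse = "\t"),
    paste(c("", "0", rep("*", 6), "0", "0", "0"), collapse = "\t"),
    blocks,
    "//"), path)
  invisible(path)
}

# classic DSSP fixed-column offsets (1-based, inclusive)
.dssp_cols <- list(resnum = c(6L, 10L), chain = c(12L, 12L), aa = c(14L, 14L),
                   ss = c(17L, 17L), acc = c(35L, 38L),
                   phi = c(104L, 109L), psi = c(110L, 115L))

#' Read classic DSSP text output
#'
#' One record per residue row. The blank SS column is the DSSP loop/irregular
#' class and parses to state `"L"`; lowercase SS-bridge cysteine letters map
#' back to `C`; the 360.0 torsion sentinel parses to `NA` (undefined); chain
#' break pseudo-residues (`!`) are skipped and counted in the `n_breaks`
#' attribute.
#'
#' @param path DSSP output file.
#' @param chain Optional chain letter; if given, only rows of that chain are
#'   kept.
#' @return An object of class `raw_dssp`: data frame with columns `resnum`,
#'   `chain`, `aa`, `ss`, `acc`, `phi`, `psi`.
#' @export
read_dssp <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (!length(hdr))
    stop("'", path, "': not DSSP output (no '  #  RESIDUE' header line)")
  body <- lines[seq(hdr[[1]] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  fld <- function(ln, key) {
    rng <- .dssp_cols[[key]]
    substr(ln, rng[[1]], rng[[2]])
  }
  n_breaks <- 0L
  recs <- list()
  for (k in seq_along(body)) {
    ln <- body[[k]]
    aa <- fld(ln, "aa")
    if (aa == "!" || aa == "*") {
      n_breaks <- n_breaks + 1L
      next
    }
    ch <- fld(ln, "chain")
    if (!is.null(chain) && ch != chain) next
    if (grepl("[a-z]", aa)) aa <- "C"  # SS-bridge cysteine convention
    ss <- fld(ln, "ss")
    if (ss == " " || ss == "-") ss <- "L"
    if (!ss %in% SS_STATES)
      stop("'", path, "': unknown secondary-structure code '", ss, "'")
    num <- function(key) suppressWarnings(as.numeric(fld(ln, key)))
    phi <- num("phi"); psi <- num("psi")
    recs[[length(recs) + 1L]] <- data.frame(
      resnum = as.integer(num("resnum")), chain = ch, aa = toupper(aa),
      ss = ss, acc = num("acc"),
      phi = if (!is.na(phi) && phi == 360) NA_real_ else phi,
      psi = if (!is.na(psi) && psi == 360) NA_real_ else psi,
      stringsAsFactors = FALSE)
  }
  if (!length(recs))
    stop("'", path, "': DSSP output contains no residue rows")
  out <- do.call(rbind, recs)
  if (any(out$acc < 0, na.rm = TRUE))
    stop("'", path, "': negative solvent-accessible area")
  attr(out, "n_breaks") <- n_breaks
  class(out) <- c("raw_dssp", class(out))
  out
}

#' Write classic DSSP-format text output
#'
#' @param dssp Data frame with columns `resnum`, `chain`, `aa`, `ss`, `acc`,
#'   `phi`, `psi` (`NA` angles are written as the 360.0 sentinel, loop state
#'   `"L"` as a blank column). Rows with `aa == "!"` are written as chain
#'   breaks.
#' @param path Output file.
#' @export
write_dssp <- function(dssp, path) {
  hb <- sprintf("%11s", "0, 0.0")
  fmt_row <- function(serial, resnum, chainid, aa, ss, acc, phi, psi) {
    if (aa == "!") {
      return(paste0(sprintf("%5d", serial), sprintf("%5s", ""), "  ",
                    " !              0   0    0"))
    }
    paste0(sprintf("%5d", serial), sprintf("%5d", resnum), " ",
           substr(chainid, 1, 1), " ", aa, "  ",
           if (ss == "L") " " else ss,
           strrep(" ", 8),
           sprintf("%4d", 0L), sprintf("%4d", 0L), " ",
           sprintf("%4d", as.integer(round(acc))), " ",
           hb, hb, hb, hb,
           sprintf("%8.3f", 0), sprintf("%6.1f", 360), sprintf("%6.1f", 360),
           sprintf("%6.1f", if (is.na(phi)) 360 else phi),
           sprintf("%6.1f", if (is.na(psi)) 360 else psi),
           sprintf("%7.1f", 0), sprintf("%7.1f", 0), sprintf("%7.1f", 0))
  }
  rows <- vapply(seq_len(nrow(dssp)), function(i) {
    r <- dssp[i, ]
    fmt_row(i, r$resnum, r$chain, r$aa, r$ss, r$acc, r$phi, r$psi)
  }, "")
  n_res <- sum(dssp$aa != "!")
  writeLines(c(
    paste0("==== Secondary Structure Definition by the program DSSP, ",
           "CMBI version 3.1.4                          ==== DATE=2026-01-01        ."),
    "REFERENCE W. KABSCH AND C.SANDER, BIOPOLYMERS 22 (1983) 2577-2637                                                              .",
    "HEADER    SYNTHETIC CHAIN                                                        .",
    sprintf("%5d%3d%3d%3d%3d TOTAL NUMBER OF RESIDUES, NUMBER OF CHAINS, NUMBER OF SS-BRIDGES(TOTAL,INTRACHAIN,INTERCHAIN)                .",
            n_res, 1L, 0L, 0L, 0L),
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    ",
           "N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"),
    rows), path)
  invisible(path)
}

letter_mismatch_frac <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  keep <- a != "X" & b != "X"
  if (!any(keep)) return(0)
  mean(a[keep] != b[keep])
}

#' Bind raw profiles to a protein record
#'
#' Verifies that the PSSM, HMM and DSSP profiles describe the same chain as
#' the sequence record: equal lengths (DSSP may cover a subset of residues, in
#' which case its `resnum` column places rows and uncovered positions are
#' recorded) and matching residue letters (case-insensitive, `X` tolerated,
#' at most 5% disagreement per source).
#'
#' @param record A [protein_record()].
#' @param pssm A `raw_pssm`.
#' @param hmm A `raw_hhm`.
#' @param dssp A `raw_dssp`.
#' @return An object of class `chain_profiles` binding the three raw matrices
#'   to the record, with a logical `dssp_coverage` vector.
#' @export
align_profiles <- function(record, pssm, hmm, dssp) {
  L <- nchar(record$sequence)
  lp <- nrow(pssm$scores)
  lh <- nrow(hmm$match_scores)
  ld <- nrow(dssp)
  if (lp != L || lh != L || ld > L)
    stop("profile length mismatch for '", record$protein_id,
         "': sequence ", L, ", PSSM ", lp, ", HMM ", lh, ", DSSP ", ld)
  coverage <- rep(TRUE, L)
  dssp_order <- seq_len(ld)
  if (ld < L) {
    pos <- dssp$resnum
    if (anyDuplicated(pos) || any(pos < 1L | pos > L))
      stop("'", record$protein_id, "': DSSP covers ", ld, " of ", L,
           " residues but resnum does not map into the sequence")
    coverage <- rep(FALSE, L)
    coverage[pos] <- TRUE
  }
  check <- function(letters, what) {
    frac <- letter_mismatch_frac(letters$ref, letters$got)
    if (frac > 0.05)
      stop("'", record$protein_id, "': ", round(100 * frac, 1),
           "% residue-letter mismatch between sequence and ", what)
  }
  check(list(ref = record$sequence, got = pssm$residue_letters), "PSSM")
  check(list(ref = record$sequence, got = hmm$residue_letters), "HMM")
  seq_cov <- paste(strsplit(record$sequence, "")[[1]][which(coverage)],
                   collapse = "")
  check(list(ref = seq_cov, got = paste(dssp$aa[dssp_order], collapse = "")),
        "DSSP")
  structure(list(record = record,
                 pssm = pssm$scores,
                 hmm = hmm$match_scores,
                 dssp = as.data.frame(dssp),
                 dssp_coverage = coverage),
            class = "chain_profiles")
}

#' @export
print.chain_profiles <- function(x, ...) {
  cat(sprintf("chain_profiles: %s (%d residues, DSSP covers %d, %s)\n",
              x$record$protein_id, nchar(x$record$sequence),
              sum(x$dssp_coverage),
              if (is.null(x$record$labels)) "unlabelled" else
                sprintf("%d interface residues", sum(x$record$labels))))
  invisible(x)
}
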