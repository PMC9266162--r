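# Conversion of raw profiles into the three normalized per-residue feature
# matrices (L x 20 PSSM, L x 20 HMM, L x 14 DSSP) and management of
# training-set min-max normalization statistics.

#' Theoretical maximum solvent-accessible surface areas (A^2)
#'
#' Per-residue-type maxima from the Tien et al. (2013) theoretical scale,
#' used to convert absolute accessible area into relative solvent
#' accessibility. `X` (unknown residue) uses the mean over the 20 types.
#' @export
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174, X = 202)

#' Convert .hhm match scores to emission probabilities
#'
#' The `.hhm` encoding stores `s = -1000 * log2(p)`; this inverts it,
#' `p = 2^(-s/1000)`. Absent (`*`) cells, recorded as `NA`, stay `NA` here
#' (they are excluded when fitting normalization extrema and become
#' probability 0 at encoding time).
#'
#' @param scores Matrix (or vector) of non-negative .hhm scores, `NA` = absent.
#' @return Probabilities in (0, 1], same shape.
#' @export
hhm_score_to_prob <- function(scores) {
  if (any(scores < 0, na.rm = TRUE))
    stop("negative .hhm match score violates the profile contract")
  2^(-scores / 1000)
}

#' Fit min-max normalization statistics on a training set
#'
#' Per-column minima and maxima across all residues of all training chains,
#' separately for the PSSM log-odds and the HMM emission probabilities.
#' Absent HMM cells are excluded from the extrema. Columns whose maximum
#' equals their minimum are recorded; scaling maps them to 0.
#'
#' @param chains List of `chain_profiles` (or any list whose elements carry
#'   `pssm` and `hmm` matrices).
#' @param provenance Tag identifying the training set (kept with the stats
#'   and checked downstream to guard against train/test leakage).
#' @return An object of class `norm_stats`.
#' @export
fit_normalization <- function(chains, provenance = "training") {
  if (!length(chains)) stop("cannot fit normalization on an empty collection")
  pssm_all <- do.call(rbind, lapply(chains, function(ch) ch$pssm))
  hmm_all <- hhm_score_to_prob(
    do.call(rbind, lapply(chains, function(ch) ch$hmm)))
  rng <- function(m) {
    mn <- as.numeric(apply(m, 2, min, na.rm = TRUE))
    mx <- as.numeric(apply(m, 2, max, na.rm = TRUE))
    mn[!is.finite(mn)] <- 0  # all-absent column
    mx[!is.finite(mx)] <- 0
    list(min = mn, max = mx, constant = which(mx == mn))
  }
  structure(list(pssm = rng(pssm_all), hmm = rng(hmm_all),
                 provenance = as.character(provenance)),
            class = "norm_stats")
}

minmax_scale <- function(x, mn, mx) {
  d <- mx - mn
  safe <- ifelse(d == 0, 1, d)
  out <- sweep(sweep(x, 2, mn, "-"), 2, safe, "/")
  if (any(d == 0)) out[, d == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Encode a PSSM profile as normalized features
#'
#' Columnwise `x' = (x - min) / (max - min)` with the extrema taken from the
#' training-set statistics; values outside the training range are clamped to
#' `[0, 1]`.
#'
#' @param raw A `raw_pssm`, `chain_profiles`, or plain L x 20 matrix.
#' @param stats A fitted [fit_normalization()] object.
#' @return L x 20 matrix in `[0, 1]`.
#' @export
encode_pssm <- function(raw, stats) {
  m <- if (is.matrix(raw)) raw else if (inherits(raw, "raw_pssm")) raw$scores
       else raw$pssm
  stopifnot(inherits(stats, "norm_stats"), ncol(m) == 20L)
  minmax_scale(m, stats$pssm$min, stats$pssm$max)
}

#' Encode an HMM profile as normalized features
#'
#' Scores become emission probabilities via [hhm_score_to_prob()], absent
#' cells become probability 0, then min-max scaling on the probability scale
#' (the scale on which the statistics were fitted), clamped to `[0, 1]`.
#'
#' @inheritParams encode_pssm
#' @param raw A `raw_hhm`, `chain_profiles`, or plain L x 20 score matrix.
#' @return L x 20 matrix in `[0, 1]`.
#' @export
encode_hmm <- function(raw, stats) {
  m <- if (is.matrix(raw)) raw else if (inherits(raw, "raw_hhm")) raw$match_scores
       else raw$hmm
  stopifnot(inherits(stats, "norm_stats"), ncol(m) == 20L)
  p <- hhm_score_to_prob(m)
  p[is.na(p)] <- 0
  minmax_scale(p, stats$hmm$min, stats$hmm$max)
}

#' Encode DSSP output as a 14-dimensional structural feature matrix
#'
#' Columns 1-9: one-hot over the nine secondary-structure states
#' ([SS_STATES]; exactly one 1 per residue, the 9th dimension marking absence
#' of a DSSP assignment). Columns 10-13: `sin`/`cos` of the phi and psi
#' backbone torsions, rescaled from `[-1, 1]` to `[0, 1]` via `(v + 1) / 2`
#' unless `trig_raw = TRUE`; undefined angles map to the rescaled neutral
#' (0.5, or 0 raw). Column 14: relative solvent accessibility, absolute area
#' divided by the residue type's [MAX_ASA], capped at 1.
#'
#' Residues the DSSP file does not cover (`coverage` FALSE) get the `NONE`
#' one-hot, neutral trigonometry and RSA 0.
#'
#' @param dssp A `raw_dssp` data frame (or `chain_profiles`).
#' @param L Chain length; defaults to the number of DSSP rows.
#' @param coverage Logical length-L vector, TRUE where a DSSP row exists.
#' @param trig_raw Keep torsion trigonometry on the raw `[-1, 1]` scale.
#' @return L x 14 matrix.
#' @export
encode_dssp <- function(dssp, L = NULL, coverage = NULL, trig_raw = FALSE) {
  if (inherits(dssp, "chain_profiles")) {
    coverage <- dssp$dssp_coverage
    L <- length(coverage)
    dssp <- dssp$dssp
  }
  if (is.null(L)) L <- nrow(dssp)
  if (is.null(coverage)) coverage <- rep(TRUE, L)
  stopifnot(sum(coverage) == nrow(dssp), length(coverage) == L)
  out <- matrix(0, L, 14)
  colnames(out) <- c(SS_STATES, "sin_phi", "cos_phi", "sin_psi", "cos_psi", "rsa")
  # uncovered residues: NONE state, neutral trig, rsa 0
  out[!coverage, match("NONE", SS_STATES)] <- 1
  if (!trig_raw) out[!coverage, 10:13] <- 0.5
  if (nrow(dssp)) {
    idx <- which(coverage)
    ss_i <- match(dssp$ss, SS_STATES)
    if (anyNA(ss_i))
      stop("unknown secondary-structure code: ",
           paste(unique(dssp$ss[is.na(ss_i)]), collapse = ","))
    out[cbind(idx, ss_i)] <- 1
    trig <- cbind(sin(dssp$phi * pi / 180), cos(dssp$phi * pi / 180),
                  sin(dssp$psi * pi / 180), cos(dssp$psi * pi / 180))
    trig[is.na(trig)] <- 0  # undefined angle -> raw neutral
    if (!trig_raw) trig <- (trig + 1) / 2
    out[idx, 10:13] <- trig
    mx <- MAX_ASA[dssp$aa]
    mx[is.na(mx)] <- MAX_ASA[["X"]]
    out[idx, 14] <- pmin(dssp$acc / mx, 1)
  }
  out
}

#' Encode one chain into its three aligned feature matrices
#'
#' @param chain A `chain_profiles` object.
#' @param stats Fitted [fit_normalization()] statistics.
#' @param trig_raw Passed to [encode_dssp()].
#' @return An object of class `residue_profile_set` with `pssm_feat`,
#'   `hmm_feat` (L x 20) and `dssp_feat` (L x 14).
#' @export
encode_chain <- function(chain, stats, trig_raw = FALSE) {
  stopifnot(inherits(chain, "chain_profiles"))
  structure(list(record = chain$record,
                 pssm_feat = encode_pssm(chain, stats),
                 hmm_feat = encode_hmm(chain, stats),
                 dssp_feat = encode_dssp(chain, trig_raw = trig_raw),
                 stats_provenance = stats$provenance),
            class = "residue_profile_set")
}

#' Persist normalization statistics as JSON
#'
#' Written at full precision so that extrema round-trip bit-identically.
#' @param stats A `norm_stats` object.
#' @param path Output JSON file.
#' @export
save_norm_stats <- function(stats, path) {
  stopifnot(inherits(stats, "norm_stats"))
  jsonlite::write_json(
    list(pssm = list(min = stats$pssm$min, max = stats$pssm$max,
                     constant = as.integer(stats$pssm$constant)),
         hmm = list(min = stats$hmm$min, max = stats$hmm$max,
                    constant = as.integer(stats$hmm$constant)),
         provenance = jsonlite::unbox(stats$provenance)),
    path, digits = I(17))  # 17 significant digits: doubles round-trip exactly
  invisible(path)
}

#' @rdname save_norm_stats
#' @export
load_norm_stats <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(pssm = list(min = as.numeric(x$pssm$min),
                             max = as.numeric(x$pssm$max),
                             constant = as.integer(x$pssm$constant)),
                 hmm = list(min = as.numeric(x$hmm$min),
                            max = as.numeric(x$hmm$max),
                            constant = as.integer(x$hmm$constant)),
                 provenance = x$provenance),
            class = "norm_stats")
}

#' @export
print.norm_stats <- function(x, ...) {
  cat("norm_stats fitted on:", x$provenance, "\n",
      " pssm log-odds range [", min(x$pssm$min), ",", max(x$pssm$max), "]\n",
      " hmm probability range [", signif(min(x$hmm$min), 3), ",",
      signif(max(x$hmm$max), 3), "]\n")
  invisible(x)
}
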