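# Sliding-window extraction: for each residue i, the (2a+1) x m block of
# feature rows for residues i-a .. i+a, zero-padded past the chain termini.

#' Sliding-window configuration
#'
#' @param a Half-width (number of neighbours on each side); the window length
#'   is `n = 2a + 1`, odd by construction. Default `a = 9` (window 19).
#' @return An object of class `window_config`.
#' @export
window_config <- function(a = 9L) {
  a <- as.integer(a)
  if (is.na(a) || a < 1L) stop("window half-width must be an integer >= 1")
  structure(list(a = a, n = 2L * a + 1L), class = "window_config")
}

window_one <- function(X, a) {
  L <- nrow(X)
  n <- 2L * a + 1L
  m <- ncol(X)
  padded <- rbind(matrix(0, a, m), X, matrix(0, a, m))
  # row (i, j) of window i is padded row i + j - 1; i cycles fastest, matching
  # the column-major layout of an (L, n, m) array
  idx <- rep(seq_len(L), n) + rep(0:(n - 1L), each = L)
  array(padded[idx, , drop = FALSE], c(L, n, m))
}

#' Extract per-residue local feature windows
#'
#' For every residue of the chain, cuts the `n x m` block of neighbouring
#' feature rows out of each of the three feature matrices. Rows that fall
#' outside the chain (within `a` of a terminus) are the zero vector, so each
#' residue always yields exactly one window of identical shape and row `a + 1`
#' (1-based) of every window is the residue's own feature row.
#'
#' @param features A `residue_profile_set` from [encode_chain()].
#' @param config A [window_config()].
#' @return An object of class `window_batch`: arrays `pssm` (L x n x 20),
#'   `hmm` (L x n x 20), `dssp` (L x n x 14), plus labels (if known),
#'   protein ids and 1-based positions.
#' @export
extract_windows <- function(features, config = window_config()) {
  stopifnot(inherits(features, "residue_profile_set"),
            inherits(config, "window_config"))
  L <- nrow(features$pssm_feat)
  structure(list(
    pssm = window_one(features$pssm_feat, config$a),
    hmm = window_one(features$hmm_feat, config$a),
    dssp = window_one(features$dssp_feat, config$a),
    labels = features$record$labels,
    protein_id = rep(features$record$protein_id, L),
    positions = seq_len(L),
    a = config$a, n = config$n,
    center = config$a + 1L), class = "window_batch")
}

#' Concatenate window batches from several chains
#'
#' @param batches List of `window_batch` objects with equal window length.
#' @return A single `window_batch`; labels are kept only if every input
#'   batch carries them.
#' @export
bind_windows <- function(batches) {
  stopifnot(length(batches) > 0)
  n <- batches[[1]]$n
  if (!all(vapply(batches, `[[`, 0L, "n") == n))
    stop("cannot bind window batches of different window lengths")
  sizes <- vapply(batches, function(b) dim(b$pssm)[[1]], 0L)
  N <- sum(sizes)
  bind_arr <- function(key) {
    m <- dim(batches[[1]][[key]])[[3]]
    out <- array(0, c(N, n, m))
    off <- 0L
    for (b in batches) {
      Lb <- dim(b[[key]])[[1]]
      out[off + seq_len(Lb), , ] <- b[[key]]
      off <- off + Lb
    }
    out
  }
  have_labels <- all(vapply(batches, function(b) !is.null(b$labels), TRUE))
  structure(list(
    pssm = bind_arr("pssm"), hmm = bind_arr("hmm"), dssp = bind_arr("dssp"),
    labels = if (have_labels) unlist(lapply(batches, `[[`, "labels")) else NULL,
    protein_id = unlist(lapply(batches, `[[`, "protein_id")),
    positions = unlist(lapply(batches, `[[`, "positions")),
    a = batches[[1]]$a, n = n, center = batches[[1]]$center),
    class = "window_batch")
}

#' Subset a window batch by sample index
#' @param batch A `window_batch`.
#' @param idx Integer indices of samples (residues) to keep.
#' @return A `window_batch` with the selected samples.
#' @export
subset_windows <- function(batch, idx) {
  structure(list(
    pssm = batch$pssm[idx, , , drop = FALSE],
    hmm = batch$hmm[idx, , , drop = FALSE],
    dssp = batch$dssp[idx, , , drop = FALSE],
    labels = if (!is.null(batch$labels)) batch$labels[idx] else NULL,
    protein_id = batch$protein_id[idx],
    positions = batch$positions[idx],
    a = batch$a, n = batch$n, center = batch$center),
    class = "window_batch")
}
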