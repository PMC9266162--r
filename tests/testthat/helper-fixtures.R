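# Shared fixture builders: tiny in-code profiles and a cached toy dataset.

# hand-written 3-residue PSSM fixture with known integers
write_tiny_pssm <- function(path, scores = NULL, letters = "MKL") {
  if (is.null(scores))
    scores <- matrix(rep(c(-2L, 0L, 5L), each = 20), 3, 20, byrow = FALSE)
  write_pssm(scores, letters, path)
  list(scores = scores, letters = letters)
}

random_chain_features <- function(L, seed = 1) {
  set.seed(seed)
  rec <- protein_record(sprintf("TST%03dA", L),
                        paste(sample(ppisite:::PSSM_ALPHABET, L, replace = TRUE),
                              collapse = ""))
  structure(list(record = rec,
                 pssm_feat = matrix(runif(L * 20), L, 20),
                 hmm_feat = matrix(runif(L * 20), L, 20),
                 dssp_feat = matrix(runif(L * 14), L, 14)),
            class = "residue_profile_set")
}

# small random labelled window batch for model tests
random_window_batch <- function(B, n = 19L, seed = 1, labelled = TRUE) {
  set.seed(seed)
  mk <- function(m) array(runif(B * n * m), c(B, n, m))
  structure(list(pssm = mk(20), hmm = mk(20), dssp = mk(14),
                 labels = if (labelled) rbinom(B, 1, 0.3) else NULL,
                 protein_id = rep("TOY", B), positions = seq_len(B),
                 a = (n - 1L) %/% 2L, n = as.integer(n),
                 center = (n - 1L) %/% 2L + 1L),
            class = "window_batch")
}

# the bundled toy dataset, generated once per test session
toy_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- worked_toy()
    cache
  }
})

# brute-force confusion/ranking metrics used as the independent oracle
oracle_metrics <- function(labels, scores, threshold) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    pos <- scores[[i]] >= threshold
    if (pos && labels[[i]] == 1) tp <- tp + 1L
    else if (pos) fp <- fp + 1L
    else if (labels[[i]] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  n <- length(labels)
  den_prec <- tp + fp
  den_rec <- tp + fn
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  # AUROC: all positive/negative pairs, ties count one half
  pos_s <- scores[labels == 1]
  neg_s <- scores[labels == 0]
  auroc <- NA_real_
  if (length(pos_s) && length(neg_s)) {
    wins <- 0
    for (ps in pos_s) for (ns in neg_s)
      wins <- wins + if (ps > ns) 1 else if (ps == ns) 0.5 else 0
    auroc <- wins / (length(pos_s) * length(neg_s))
  }
  # AUPRC: step integration over distinct thresholds, descending
  auprc <- NA_real_
  if (length(pos_s) && length(neg_s)) {
    thr <- sort(unique(scores), decreasing = TRUE)
    prev_rec <- 0
    auprc <- 0
    for (t in thr) {
      tpk <- sum(scores >= t & labels == 1)
      fpk <- sum(scores >= t & labels == 0)
      rec <- tpk / length(pos_s)
      prec <- tpk / (tpk + fpk)
      auprc <- auprc + (rec - prev_rec) * prec
      prev_rec <- rec
    }
  }
  list(acc = (tp + tn) / n,
       precision = if (den_prec == 0) 0 else tp / den_prec,
       recall = if (den_rec == 0) 0 else tp / den_rec,
       f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
       mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
       auroc = auroc, auprc = auprc,
       counts = c(tp = tp, tn = tn, fp = fp, fn = fn))
}
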