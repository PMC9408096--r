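# Independent oracles used to check the package's implementations. Each is
# deliberately written as the most naive correct computation, sharing no
# code path with the functions under test.

# sliding-window k-mer counter: extract every window explicitly, drop those
# containing N, tabulate, divide by the full sequence length
naive_kmer_freq <- function(seq, ks) {
  L <- nchar(seq)
  unlist(lapply(ks, function(k) {
    words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
    counts <- setNames(numeric(length(words)), words)
    if (L >= k) {
      win <- substring(seq, seq_len(L - k + 1L), k:L)
      win <- win[!grepl("N", win, fixed = TRUE)]
      tb <- table(win)
      counts[names(tb)] <- as.numeric(tb)
    }
    counts / L
  }))
}

# all-pairs ROC-AUC: every (positive, negative) pair scores 1, 1/2 or 0
allpairs_auc <- function(labels, scores) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == 0L]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# threshold metrics recomputed from reconstructed label/prediction vectors:
# accuracy as a match rate, MCC as the Pearson correlation of the two
# binary vectors, F1 through the 2TP/(2TP+FP+FN) identity
oracle_metrics <- function(tp, tn, fp, fn) {
  tp <- unname(tp); tn <- unname(tn); fp <- unname(fp); fn <- unname(fn)
  truth <- c(rep(1, tp + fn), rep(0, tn + fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  mcc <- suppressWarnings(stats::cor(truth, pred))
  c(accuracy = mean(truth == pred),
    sensitivity = if (tp + fn > 0) mean(pred[truth == 1] == 1) else 0,
    specificity = if (tn + fp > 0) mean(pred[truth == 0] == 0) else 0,
    precision = if (tp + fp > 0) mean(truth[pred == 1] == 1) else 0,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    mcc = if (is.na(mcc)) 0 else mcc)
}

# brute-force running-sum enrichment: explicit position-by-position walk
brute_es <- function(genes, scores, set_genes, p = 1) {
  hit <- genes %in% set_genes
  n <- length(genes)
  nh <- sum(hit)
  w <- abs(scores)^p
  hw <- sum(w[hit])
  rs <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (hit[i]) w[i] / hw else -1 / (n - nh)
    rs[i] <- acc
  }
  # shared tie convention: a positive/negative deviation tie is positive
  if (max(rs) >= -min(rs) - 1e-12) max(rs) else min(rs)
}

# a small planted-signal expression dataset ready for training
make_planted_dataset <- function(n_pos = 60, n_neg = 60, n_features = 40,
                                 n_signal = 8, effect = 2, seed = 1) {
  stopifnot(n_features %% 8 == 0)
  cfg <- sim_config(n_positive = n_pos, n_negative = n_neg,
                    n_tissues = 2, n_age_stages = 4,
                    samples_per_cell = n_features / 8,
                    signal_features = n_signal, effect_size = effect,
                    seed = seed)
  se <- simulate_expression(cfg)
  fm <- assemble_features(names(se$labels), expr = se$expr,
                          mode = "expression")
  list(data = labeled_dataset(fm, se$labels),
       signal = se$signal_samples, expr = se$expr, cfg = cfg)
}

# minmax-scale a whole labeled dataset in place (test convenience)
scale_dataset <- function(data) {
  sc <- fit_minmax(data$features)
  labeled_dataset(apply_minmax(data$features, sc), data$labels)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
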