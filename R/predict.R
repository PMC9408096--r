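# Candidate prioritization: consensus prediction over a three-model
# ensemble at a probability threshold, mean-probability ranking, and a
# preranked gene-set enrichment statistic (weighted Kolmogorov-Smirnov-style
# running sum) with a permutation p-value.

#' Consensus prediction over a three-model ensemble
#'
#' Scores every instance with each of exactly three trained models (trained
#' on the same feature set), calls each model at the threshold (boundary
#' `>=` is positive), flags the consensus (all three positive) and records
#' the arithmetic mean probability.
#'
#' @param models List of exactly three `trained_model` objects sharing one
#'   training feature set.
#' @param features A [feature_matrix()] of instances to score.
#' @param threshold Probability threshold (default 0.5).
#' @return Object of class `candidate_table`: `data.frame` with columns
#'   `gene`, one probability column `p_<code>` per model (codes: lr, svm,
#'   rf, xgb, ann, made unique if families repeat), `p_mean`, `consensus`.
#' @export
consensus_predict <- function(models, features, threshold = 0.5) {
  if (length(models) != 3L) stop("consensus requires exactly 3 models")
  stopifnot(all(vapply(models, inherits, logical(1), "trained_model")))
  fsets <- lapply(models, function(m) sort(m$feature_names))
  if (!all(vapply(fsets, identical, logical(1), fsets[[1L]]))) {
    stop("models were trained on different feature sets")
  }
  probs <- vapply(models, predict_proba, numeric(nrow(features)),
                  features = features)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  codes <- make.unique(unname(
    FAMILY_CODE[vapply(models, function(m) m$spec$family, character(1))]),
    sep = "")
  colnames(probs) <- paste0("p_", codes)
  out <- data.frame(gene = rownames(features), probs,
                    p_mean = rowMeans(probs),
                    consensus = rowSums(probs >= threshold) == 3L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, threshold = threshold,
            class = c("candidate_table", "data.frame"))
}

#' Rank candidates by mean ensemble probability
#'
#' Descending mean probability; ties break by gene ID ascending, so the
#' ranking is strictly ordered and deterministic.
#'
#' @param table A `candidate_table` from [consensus_predict()].
#' @return Object of class `ranked_list`: `data.frame` with columns `gene`,
#'   `score` (the mean probability), ordered.
#' @export
rank_candidates <- function(table) {
  stopifnot(inherits(table, "candidate_table"))
  o <- order(-table$p_mean, table$gene)
  out <- data.frame(gene = table$gene[o], score = table$p_mean[o],
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_list", "data.frame"))
}

# Weighted running-sum enrichment statistic of one gene set against a ranked
# list. Hits step up by |score|^p normalized by the sum over set members;
# misses step down by 1/(N - n_set). Returns the signed deviation of
# maximum magnitude and the full running sum.
running_sum_es <- function(genes, scores, set_genes, weight_exponent = 1.0) {
  hit <- genes %in% set_genes
  n <- length(genes)
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set is disjoint from the ranked list")
  if (n_hit == n) {
    # all hits, no misses: the sum climbs to exactly 1 at the last position
    w <- abs(scores)^weight_exponent
    if (sum(w) == 0) stop("zero total hit weight")
    rs <- cumsum(w / sum(w))
    return(list(es = 1.0, running_sum = rs, position = n, hit = hit))
  }
  w <- abs(scores)^weight_exponent
  hit_w <- sum(w[hit])
  if (hit_w == 0) stop("zero total hit weight in the gene set")
  steps <- ifelse(hit, w / hit_w, -1 / (n - n_hit))
  rs <- cumsum(steps)
  # signed extremum; an (effective) tie between the largest positive and
  # largest negative deviation resolves to the positive one
  max_pos <- max(rs)
  min_neg <- min(rs)
  if (max_pos >= -min_neg - 1e-12) {
    pos <- which.max(rs)
  } else {
    pos <- which.min(rs)
  }
  list(es = rs[pos], running_sum = rs, position = pos, hit = hit)
}

#' Preranked gene-set enrichment
#'
#' Walks the ranked list computing a weighted Kolmogorov-Smirnov-style
#' running sum: at a gene in the set the sum increases by
#' `|score|^weight_exponent / sum(set |score|^weight_exponent)`, otherwise
#' it decreases by `1/(N - n_set)`. The enrichment score (ES) is the signed
#' deviation of maximum magnitude. The nominal p-value is the fraction of
#' same-sign enrichment scores of random gene sets of identical size that
#' are at least as extreme, with a plus-one correction so p is never
#' exactly 0.
#'
#' @param ranked A `ranked_list` (or `data.frame` with columns `gene`,
#'   `score`, ordered by decreasing score).
#' @param set A [gene_set()]; must intersect the ranked list.
#' @param weight_exponent Score weight exponent `p` (default 1, the
#'   standard "weighted" statistic).
#' @param n_permutations Number of random gene sets for the null
#'   (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Object of class `enrichment_result`: list with `es`,
#'   `running_sum`, `es_position`, `nominal_p`, `n_permutations`,
#'   `leading_edge` (set members up to the ES extremum for positive ES,
#'   from it onward for negative ES), `set_name`, `n_set_in_list`.
#' @export
preranked_enrichment <- function(ranked, set, weight_exponent = 1.0,
                                 n_permutations = 1000L, seed = 1L) {
  stopifnot(is.data.frame(ranked), all(c("gene", "score") %in% names(ranked)))
  genes <- ranked$gene
  scores <- ranked$score
  obs <- running_sum_es(genes, scores, set$genes, weight_exponent)
  n <- length(genes)
  n_hit <- sum(obs$hit)

  perm_es <- with_seed(seed, {
    w <- abs(scores)^weight_exponent
    miss_step <- -1 / max(1L, n - n_hit)
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(n, n_hit)
      hit_i <- logical(n); hit_i[idx] <- TRUE
      hw <- sum(w[hit_i])
      if (hw == 0) return(0)
      steps <- ifelse(hit_i, w / hw, miss_step)
      rs <- cumsum(steps)
      if (max(rs) >= -min(rs) - 1e-12) max(rs) else min(rs)
    }, numeric(1))
  })
  same_sign <- perm_es[sign(perm_es) == sign(obs$es)]
  nominal_p <- (1 + sum(abs(same_sign) >= abs(obs$es))) /
    (1 + length(same_sign))

  le_genes <- if (obs$es >= 0) {
    genes[seq_len(obs$position)][obs$hit[seq_len(obs$position)]]
  } else {
    genes[obs$position:n][obs$hit[obs$position:n]]
  }
  structure(list(es = obs$es, running_sum = obs$running_sum,
                 es_position = obs$position, nominal_p = nominal_p,
                 n_permutations = n_permutations,
                 leading_edge = le_genes, set_name = set$name,
                 n_set_in_list = n_hit),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> set '%s' (%d in list): ES = %.4f at rank %d, nominal p %s %.4g (%d permutations)\n",
              x$set_name, x$n_set_in_list, x$es, x$es_position,
              if (x$nominal_p <= 1 / (x$n_permutations + 1)) "<" else "=",
              x$nominal_p, x$n_permutations))
  invisible(x)
}
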