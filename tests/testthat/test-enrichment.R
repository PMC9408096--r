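# Consensus ensemble prediction, mean-probability ranking, and the
# preranked running-sum enrichment statistic with its permutation null.

fake_candidate_table <- function(p1, p2, p3, genes = NULL) {
  n <- length(p1)
  genes <- genes %||% sprintf("g%02d", seq_len(n))
  probs <- cbind(p_svm = p1, p_ann = p2, p_rf = p3)
  structure(data.frame(gene = genes, probs, p_mean = rowMeans(probs),
                       consensus = rowSums(probs >= 0.5) == 3L),
            threshold = 0.5, class = c("candidate_table", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("consensus requires agreement of all three models at the boundary", {
  tab <- fake_candidate_table(c(0.6, 0.6, 0.5), c(0.8, 0.4, 0.5),
                              c(0.7, 0.9, 0.5))
  expect_identical(tab$consensus, c(TRUE, FALSE, TRUE))
  expect_equal(tab$p_mean[1], 0.7)
})

test_that("consensus prediction wires three real models together", {
  pd <- make_planted_dataset(n_pos = 30, n_neg = 30, n_features = 16,
                             n_signal = 4, effect = 2, seed = 61)
  ds <- scale_dataset(pd$data)
  models <- lapply(c("maxmargin", "random_forest", "ann1"),
                   function(f) train_model(model_spec(f, seed = 3), ds))
  tab <- consensus_predict(models, ds$features)
  expect_identical(names(tab),
                   c("gene", "p_svm", "p_rf", "p_ann", "p_mean", "consensus"))
  # consensus size bounded by the smallest single-model positive count
  single_pos <- vapply(c("p_svm", "p_rf", "p_ann"),
                       function(cn) sum(tab[[cn]] >= 0.5), integer(1))
  expect_lte(sum(tab$consensus), min(single_pos))
  expect_error(consensus_predict(models[1:2], ds$features), "exactly 3")

  # models trained on different feature sets are rejected
  other <- train_model(model_spec("logreg", seed = 1),
                       labeled_dataset(ds$features[, 1:8], ds$labels))
  expect_error(consensus_predict(c(models[1:2], list(other)), ds$features),
               "different feature sets")
})

test_that("candidates rank by descending mean probability, ties by gene ID", {
  tab <- fake_candidate_table(c(0.9, 0.7, 0.8, 0.8), c(0.9, 0.7, 0.8, 0.8),
                              c(0.9, 0.7, 0.8, 0.8),
                              genes = c("g1", "g2", "gb", "ga"))
  rl <- rank_candidates(tab)
  expect_identical(rl$gene, c("g1", "ga", "gb", "g2"))
  expect_identical(rl$score, sort(tab$p_mean, decreasing = TRUE))
})

test_that("running-sum ES matches hand cases and the brute-force oracle", {
  ranked <- data.frame(gene = c("a", "b", "c", "d"),
                       score = c(3, 2, 1, 0.5))
  # set = top gene: the sum jumps to +1 at position 1
  r1 <- preranked_enrichment(ranked, gene_set("s", "a"),
                             n_permutations = 10, seed = 1)
  expect_equal(r1$es, 1.0)
  expect_identical(r1$es_position, 1L)
  expect_identical(r1$leading_edge, "a")

  # set = entire list: all hits, no misses, ES 1 at the last position
  r2 <- preranked_enrichment(ranked, gene_set("s", ranked$gene),
                             n_permutations = 10, seed = 1)
  expect_equal(r2$es, 1.0)
  expect_identical(r2$es_position, 4L)

  expect_error(preranked_enrichment(ranked, gene_set("s", "zz")),
               "disjoint")

  set.seed(62)
  for (i in 1:120) {
    n <- sample(5:60, 1)
    rl <- data.frame(gene = sprintf("g%03d", 1:n),
                     score = sort(round(rnorm(n), 3), decreasing = TRUE))
    m <- sample(1:(n - 1), 1)
    set <- gene_set("s", sample(rl$gene, m))
    p <- sample(c(0, 1, 1.5), 1)
    got <- preranked_enrichment(rl, set, weight_exponent = p,
                                n_permutations = 5, seed = i)
    expect_equal(got$es, brute_es(rl$gene, rl$score, set$genes, p),
                 tolerance = 1e-12)
  }
})

test_that("the running sum starts from zero steps and returns to zero", {
  set.seed(63)
  rl <- data.frame(gene = sprintf("g%03d", 1:50),
                   score = sort(rnorm(50), decreasing = TRUE))
  set <- gene_set("s", sample(rl$gene, 12))
  r <- preranked_enrichment(rl, set, n_permutations = 5, seed = 2)
  expect_equal(r$running_sum[50], 0, tolerance = 1e-9)
  expect_identical(length(r$running_sum), 50L)
})

test_that("permutation p-values obey the plus-one floor and null uniformity", {
  set.seed(64)
  rl <- data.frame(gene = sprintf("g%03d", 1:80),
                   score = sort(abs(rnorm(80)) + 3, decreasing = TRUE))
  # a maximally enriched set cannot reach p = 0
  top_set <- gene_set("s", rl$gene[1:5])
  r <- preranked_enrichment(rl, top_set, n_permutations = 200, seed = 3)
  expect_gte(r$nominal_p, 1 / 201)

  # random sets under the exchangeable null: p roughly uniform
  ps <- vapply(1:120, function(i) {
    set <- gene_set("s", sample(rl$gene, 10))
    preranked_enrichment(rl, set, n_permutations = 99, seed = 1000 + i)$nominal_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("enrichment agrees in direction with an established implementation", {
  skip_if_not_installed("fgsea")
  set.seed(65)
  n <- 100
  rl <- data.frame(gene = sprintf("g%03d", 1:n),
                   score = sort(rnorm(n, 0, 2), decreasing = TRUE))
  set <- gene_set("s", rl$gene[c(1:8, 60:64)])
  ours <- preranked_enrichment(rl, set, n_permutations = 100, seed = 4)
  stats_vec <- setNames(rl$score, rl$gene)
  suppressWarnings(
    fg <- fgsea::fgsea(list(s = set$genes), stats_vec, nperm = 100))
  # same statistic family; magnitudes agree closely, signs exactly
  expect_equal(sign(ours$es), sign(fg$ES))
  expect_equal(ours$es, fg$ES, tolerance = 0.05)
})
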