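# Sequence (k-mer) and expression feature encoding: overlapping k-mer
# frequencies of the concatenated 5'+3' UTR normalized by sequence length,
# log2(RPKM + 1) transformation, and min-max scaling fitted on training data
# only.

#' k-mer configuration
#'
#' @param ks Integer vector of word lengths (default `1:3`). The feature
#'   space is the union of all `4^k` DNA words per `k`, ordered
#'   lexicographically within each `k` (the `A < C < G < T` convention).
#' @return Object of class `kmer_config` with elements `ks`,
#'   `feature_names`.
#' @export
#' @examples
#' length(kmer_config(1:3)$feature_names)  # 4 + 16 + 64 = 84
kmer_config <- function(ks = 1:3) {
  ks <- sort(unique(as.integer(ks)))
  if (length(ks) == 0L || any(ks < 1L)) stop("ks must be positive integers")
  names_per_k <- lapply(ks, function(k) {
    Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  })
  structure(list(ks = ks, feature_names = unlist(names_per_k)),
            class = "kmer_config")
}

#' k-mer frequency features of UTR sequences
#'
#' For each transcript the 5' UTR is concatenated with the 3' UTR (in that
#' order) and, for every `k` in the configuration, each of the `4^k` words is
#' counted over all overlapping windows; windows containing `N` contribute to
#' no word. Counts are divided by the concatenated sequence length `L`
#' (not by the number of windows), so for an `N`-free sequence the
#' frequencies of a single `k` sum to `(L - k + 1) / L`.
#'
#' Transcripts whose concatenated UTR is shorter than `max(ks)` (including
#' empty ones) cannot be encoded; they are excluded with a warning and
#' listed in the `"excluded"` attribute of the result.
#'
#' @param transcripts `data.frame` with columns `gene_id`, `utr5`, `utr3`
#'   (one row per gene; see [choose_longest_cds()]).
#' @param cfg A [kmer_config()].
#' @return A [feature_matrix()] of kind `"sequence"`, one row per encodable
#'   gene.
#' @export
kmer_frequencies <- function(transcripts, cfg = kmer_config()) {
  stopifnot(inherits(cfg, "kmer_config"))
  seqs <- paste0(transcripts$utr5, transcripts$utr3)
  L <- nchar(seqs)
  ok <- L >= max(cfg$ks)
  if (!any(ok)) stop("no transcript has a concatenated UTR of length >= max(ks)")
  if (any(!ok)) {
    warning(sprintf("kmer_frequencies: %d transcript(s) with UTR shorter than %d excluded",
                    sum(!ok), max(cfg$ks)))
  }
  ss <- Biostrings::DNAStringSet(seqs[ok])
  blocks <- lapply(cfg$ks, function(k) {
    Biostrings::oligonucleotideFrequency(ss, width = k) / L[ok]
  })
  vals <- do.call(cbind, blocks)
  rownames(vals) <- transcripts$gene_id[ok]
  stopifnot(identical(colnames(vals), cfg$feature_names))
  out <- feature_matrix(vals, "sequence")
  attr(out, "excluded") <- transcripts$gene_id[!ok]
  out
}

#' log2(RPKM + 1) transformation
#'
#' @param expr An [expr_matrix()] of RPKM values.
#' @return An [expr_matrix()] with every value replaced by `log2(v + 1)`.
#' @export
log_transform <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  expr$values <- log2(expr$values + 1)
  expr
}

#' Fit a min-max scaler on a reference (training) matrix
#'
#' @param reference A [feature_matrix()] (or plain numeric matrix).
#' @return Object of class `minmax_scaler` storing per-feature `min`,
#'   `max` and the feature names.
#' @export
fit_minmax <- function(reference) {
  stopifnot(is.matrix(reference))
  structure(list(min = apply(reference, 2L, min),
                 max = apply(reference, 2L, max),
                 feature_names = colnames(reference)),
            class = "minmax_scaler")
}

#' Apply a fitted min-max scaler
#'
#' Transforms each feature to `(v - min) / (max - min)`. Constant features
#' (`max == min`) map to 0. Values from non-reference data may fall outside
#' `[0, 1]`; they are clipped (count reported via the `"n_clipped"`
#' attribute).
#'
#' @param m A [feature_matrix()] (or numeric matrix) with the scaler's
#'   feature columns.
#' @param s A `minmax_scaler` from [fit_minmax()].
#' @param clip Clip transformed values into `[0, 1]` (default `TRUE`).
#' @return Matrix of the same class/shape as `m`.
#' @export
apply_minmax <- function(m, s, clip = TRUE) {
  stopifnot(inherits(s, "minmax_scaler"))
  if (!identical(colnames(m), s$feature_names)) {
    if (!setequal(colnames(m), s$feature_names)) {
      stop("feature names do not match the scaler's reference matrix")
    }
    m <- m[, s$feature_names, drop = FALSE]
  }
  rng <- s$max - s$min
  rng[rng == 0] <- 1  # constant feature: (v - min)/1 = 0 for reference values
  scaled <- sweep(sweep(unclass(m), 2L, s$min, "-"), 2L, rng, "/")
  n_clipped <- 0L
  if (clip) {
    n_clipped <- sum(scaled < 0 | scaled > 1)
    scaled[scaled < 0] <- 0
    scaled[scaled > 1] <- 1
  }
  out <- if (inherits(m, "feature_matrix")) {
    feature_matrix(scaled, feature_kind(m))
  } else scaled
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Assemble sequence and/or expression features for a set of genes
#'
#' Builds the instance x feature matrix used for training and prediction.
#' Expression features are the per-sample `log2(RPKM + 1)` values (one
#' feature per brain sample); sequence features are UTR k-mer frequencies.
#' `mode = "both"` concatenates the two blocks horizontally and keeps only
#' genes with all required inputs; genes missing a required input are
#' excluded and listed in the `"excluded"` attribute.
#'
#' Min-max scaling is deliberately NOT applied here: it must be fitted on
#' training folds only (see [repeated_cv()] and [train_model()] callers).
#'
#' @param genes Character vector of gene IDs to encode.
#' @param transcripts UTR table (see [read_utr_fasta()]); may contain
#'   several transcripts per gene, reduced by [choose_longest_cds()].
#'   Required for `mode` `"sequence"`/`"both"`.
#' @param expr An [expr_matrix()] of RPKM values. Required for `mode`
#'   `"expression"`/`"both"`.
#' @param cfg A [kmer_config()].
#' @param mode One of `"sequence"`, `"expression"`, `"both"`.
#' @return A [feature_matrix()].
#' @export
assemble_features <- function(genes, transcripts = NULL, expr = NULL,
                              cfg = kmer_config(),
                              mode = c("expression", "sequence", "both")) {
  mode <- match.arg(mode)
  genes <- unique(normalize_gene_ids(genes))
  seq_block <- NULL
  if (mode %in% c("sequence", "both")) {
    if (is.null(transcripts) || nrow(transcripts) == 0L) {
      stop("mode '", mode, "' requires transcript UTR sequences")
    }
    tx <- choose_longest_cds(transcripts[transcripts$gene_id %in% genes, ,
                                         drop = FALSE])
    if (nrow(tx) == 0L) stop("no transcripts for the requested genes")
    seq_block <- suppressWarnings(kmer_frequencies(tx, cfg))
  }
  expr_block <- NULL
  if (mode %in% c("expression", "both")) {
    if (is.null(expr)) stop("mode '", mode, "' requires an expression matrix")
    le <- log_transform(expr)
    present <- intersect(genes, rownames(le$values))
    if (!length(present)) stop("no requested gene is present in the expression matrix")
    expr_block <- feature_matrix(le$values[present, , drop = FALSE],
                                 "expression")
  }
  out <- switch(mode,
    sequence = seq_block[intersect(genes, rownames(seq_block)), , drop = FALSE],
    expression = expr_block,
    both = {
      shared <- intersect(rownames(seq_block), rownames(expr_block))
      if (!length(shared)) stop("no gene has both sequence and expression features")
      feature_matrix(
        cbind(unclass(seq_block[shared, , drop = FALSE]),
              unclass(expr_block[shared, , drop = FALSE])),
        c(feature_kind(seq_block), feature_kind(expr_block)))
    })
  excluded <- setdiff(genes, rownames(out))
  if (length(excluded)) {
    message(sprintf("assemble_features: %d gene(s) excluded for missing inputs",
                    length(excluded)))
  }
  attr(out, "excluded") <- excluded
  out
}
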