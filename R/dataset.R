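# Compilation of labeled training instances from multi-study localization
# lists: ortholog mapping to human IDs, the >=2-study overlap rule, exclusion
# of positives from the negative list, and the expression-support filter
# (RPKM > 1 in at least 1% of brain samples).

#' Map a study list to human gene IDs
#'
#' Replaces each source-species gene by the union of its human orthologs.
#' One-to-many orthologs expand the set; unmapped genes are dropped and
#' counted (attribute `"n_unmapped"`), with a warning.
#'
#' @param study A [study_list()].
#' @param orthologs An [ortholog_map()].
#' @return A [study_list()] in human ID space (empty-set result keeps class
#'   but carries zero genes via attribute if all genes are unmapped, in
#'   which case an error is raised by the constructor; callers see the
#'   warning first).
#' @export
map_to_human <- function(study, orthologs) {
  hits <- lookup_orthologs(orthologs, study$genes)
  n_unmapped <- sum(lengths(hits) == 0L)
  if (n_unmapped > 0L) {
    warning(sprintf("map_to_human: %d/%d genes in study '%s' have no human ortholog",
                    n_unmapped, length(study$genes), study$study_id))
  }
  human <- unique(unlist(hits, use.names = FALSE))
  if (length(human) == 0L) {
    stop("map_to_human: no genes in study '", study$study_id,
         "' could be mapped")
  }
  out <- study_list(study$study_id, study$label, human)
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_mapped") <- length(study$genes) - n_unmapped
  out
}

#' Select genes supported by a minimum number of studies
#'
#' Returns genes reported by at least `min_studies` distinct studies of the
#' same localization label. Within a study a gene counts once (set
#' semantics).
#'
#' @param studies List of [study_list()] objects sharing one label.
#' @param label Expected label; all studies are checked against it.
#' @param min_studies Minimum number of supporting studies (default 2).
#' @return Sorted character vector of gene IDs.
#' @export
select_by_overlap <- function(studies, label = c("dendritic", "somatic"),
                              min_studies = 2L) {
  label <- match.arg(label)
  min_studies <- as.integer(min_studies)
  if (min_studies < 1L) stop("min_studies must be >= 1")
  if (length(studies) < min_studies) {
    stop(sprintf("need at least %d studies, got %d",
                 min_studies, length(studies)))
  }
  labs <- vapply(studies, `[[`, "", "label")
  if (!all(labs == label)) stop("all studies must carry label '", label, "'")
  counts <- table(unlist(lapply(studies, function(s) unique(s$genes))))
  sort(names(counts)[counts >= min_studies])
}

#' Exclude positives from a negative gene set
#'
#' Any candidate negative overlapping the positive set is removed, so the
#' final classes are disjoint.
#'
#' @param negatives,positives Character vectors of gene IDs.
#' @return `negatives` minus `positives`, sorted.
#' @export
exclude_positives <- function(negatives, positives) {
  sort(setdiff(negatives, positives))
}

#' Filter genes by expression support
#'
#' Retains gene `g` iff its RPKM exceeds `rpkm_threshold` (strictly) in at
#' least `ceiling(min_sample_fraction * n_samples)` samples (never fewer
#' than 1). Genes absent from the matrix are dropped and counted in the
#' `"n_absent"` attribute.
#'
#' @param genes Character vector of gene IDs.
#' @param expr An [expr_matrix()] of RPKM values.
#' @param rpkm_threshold Strict RPKM cutoff (default 1).
#' @param min_sample_fraction Minimum supporting fraction of samples
#'   (default 0.01).
#' @return Sorted character vector of retained gene IDs.
#' @export
filter_by_expression_support <- function(genes, expr, rpkm_threshold = 1.0,
                                         min_sample_fraction = 0.01) {
  stopifnot(rpkm_threshold > 0, min_sample_fraction > 0)
  present <- intersect(genes, rownames(expr$values))
  n_absent <- length(setdiff(genes, present))
  n_req <- max(1L, ceiling(min_sample_fraction * ncol(expr$values)))
  if (length(present)) {
    support <- rowSums(expr$values[present, , drop = FALSE] > rpkm_threshold)
    keep <- names(support)[support >= n_req]
  } else {
    keep <- character(0)
  }
  out <- sort(keep)
  attr(out, "n_absent") <- n_absent
  attr(out, "n_dropped_low_expression") <- length(present) - length(keep)
  out
}

#' Assemble the final labeled dataset
#'
#' Intersects the positive and negative gene sets with the instances that
#' have encoded features, asserts label purity, and fills a compilation
#' report.
#'
#' @param positives,negatives Character vectors of human gene IDs (disjoint;
#'   overlap is an error — run [exclude_positives()] first).
#' @param features A [feature_matrix()] whose rownames are gene IDs.
#' @return List with elements `dataset` (a [labeled_dataset()]) and
#'   `report` (a `compilation_report` list of counts).
#' @export
build_labeled_dataset <- function(positives, negatives, features) {
  if (length(intersect(positives, negatives))) {
    stop("positives and negatives overlap; run exclude_positives() first")
  }
  feat_genes <- rownames(features)
  pos_in <- intersect(positives, feat_genes)
  neg_in <- intersect(negatives, feat_genes)
  report <- structure(list(
    n_positive_before_filter = length(positives),
    n_negative_before_filter = length(negatives),
    n_positive_after_filter = length(pos_in),
    n_negative_after_filter = length(neg_in),
    n_positive_without_features = length(positives) - length(pos_in),
    n_negative_without_features = length(negatives) - length(neg_in)
  ), class = "compilation_report")
  if (length(pos_in) == 0L || length(neg_in) == 0L) {
    stop(sprintf("empty class after assembly (%d positives, %d negatives with features)",
                 length(pos_in), length(neg_in)))
  }
  ids <- c(sort(pos_in), sort(neg_in))
  labels <- setNames(c(rep(1L, length(pos_in)), rep(0L, length(neg_in))), ids)
  ds <- labeled_dataset(features[ids, , drop = FALSE], labels)
  stopifnot(length(intersect(names(ds$labels)[ds$labels == 1L],
                             names(ds$labels)[ds$labels == 0L])) == 0L)
  list(dataset = ds, report = report)
}

#' @export
print.compilation_report <- function(x, ...) {
  cat("<compilation_report>\n")
  for (n in names(x)) cat(sprintf("  %s: %s\n", n, x[[n]]))
  invisible(x)
}

#' Compile a labeled dataset from study lists end to end
#'
#' Convenience wrapper chaining [map_to_human()], [select_by_overlap()],
#' [exclude_positives()], [filter_by_expression_support()] and
#' [build_labeled_dataset()]. Exclusion of positives happens after ortholog
#' mapping, i.e. in human ID space.
#'
#' @param positive_studies,negative_studies Lists of [study_list()] objects.
#' @param orthologs An [ortholog_map()], or `NULL` when lists are already in
#'   human ID space.
#' @param expr An [expr_matrix()] for the expression-support filter, or
#'   `NULL` to skip filtering.
#' @param features A [feature_matrix()].
#' @param min_studies,rpkm_threshold,min_sample_fraction Passed through.
#' @return As [build_labeled_dataset()], with per-study mapping counts added
#'   to the report.
#' @export
compile_dataset <- function(positive_studies, negative_studies,
                            features, orthologs = NULL, expr = NULL,
                            min_studies = 2L, rpkm_threshold = 1.0,
                            min_sample_fraction = 0.01) {
  map1 <- function(studies) {
    if (is.null(orthologs)) return(studies)
    lapply(studies, map_to_human, orthologs = orthologs)
  }
  pos_mapped <- map1(positive_studies)
  neg_mapped <- map1(negative_studies)
  pos <- select_by_overlap(pos_mapped, "dendritic", min_studies)
  neg <- select_by_overlap(neg_mapped, "somatic", min_studies)
  neg <- exclude_positives(neg, pos)
  if (!is.null(expr)) {
    pos <- filter_by_expression_support(pos, expr, rpkm_threshold,
                                        min_sample_fraction)
    neg <- filter_by_expression_support(neg, expr, rpkm_threshold,
                                        min_sample_fraction)
  }
  out <- build_labeled_dataset(pos, neg, features)
  out$report$per_study_mapped <- lapply(c(pos_mapped, neg_mapped), function(s) {
    list(study_id = s$study_id, label = s$label,
         n_mapped = attr(s, "n_mapped") %||% length(s$genes),
         n_unmapped = attr(s, "n_unmapped") %||% 0L)
  })
  out$report$n_selected_positive <- length(pos)
  out$report$n_selected_negative <- length(neg)
  out
}
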