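# Domain containers and readers/writers for every external format the
# pipeline touches: study gene lists (one ID per line), ortholog maps (TSV),
# UTR FASTA (dialect below), BrainSpan-style expression matrices (TSV values
# + TSV sample metadata), feature matrices (TSV + JSON sidecar), GMT gene
# sets.

# ---- gene identifiers -------------------------------------------------------

#' Normalize gene identifiers
#'
#' Trims surrounding whitespace and strips Ensembl-style version suffixes
#' (`ENSG00000123456.5` -> `ENSG00000123456`) so that identifiers from
#' different sources compare equal by plain string equality.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_gene_ids(c(" ENSG00000000001.5 ", "Shank1"))
normalize_gene_ids <- function(ids) {
  ids <- trimws(as.character(ids))
  if (any(grepl("\\s", ids))) {
    stop("gene identifiers must not contain internal whitespace: ",
         paste(head(ids[grepl("\\s", ids)], 3L), collapse = ", "))
  }
  sub("\\.[0-9]+$", "", ids)
}

# ---- study lists ------------------------------------------------------------

#' Construct a localization study list
#'
#' One study's set of dendritically or somatically localized gene IDs.
#'
#' @param study_id Short token naming the study.
#' @param label Either `"dendritic"` (positive class) or `"somatic"`.
#' @param genes Character vector of gene IDs; deduplicated with set semantics.
#' @return An object of class `study_list` with elements `study_id`, `label`,
#'   `genes` (sorted unique character vector).
#' @export
study_list <- function(study_id, label = c("dendritic", "somatic"), genes) {
  label <- match.arg(label)
  genes <- normalize_gene_ids(genes)
  genes <- sort(unique(genes[nzchar(genes)]))
  if (length(genes) == 0L) stop("empty gene list for study '", study_id, "'")
  structure(list(study_id = as.character(study_id), label = label,
                 genes = genes),
            class = "study_list")
}

#' @export
print.study_list <- function(x, ...) {
  cat(sprintf("<study_list> %s (%s): %d genes\n",
              x$study_id, x$label, length(x$genes)))
  invisible(x)
}

#' Read a study gene list from a plain-text file
#'
#' One gene ID per line; blank lines and lines starting with `#` are ignored.
#' Duplicate IDs are collapsed to a set; the number of duplicate lines is
#' reported as a message and stored in the `"n_duplicates"` attribute.
#'
#' @param path File path.
#' @param label Localization label of the list (`"dendritic"` or `"somatic"`).
#' @param study_id Study identifier; defaults to the file name without
#'   extension.
#' @return A [study_list()].
#' @export
read_gene_list <- function(path, label = c("dendritic", "somatic"),
                           study_id = tools::file_path_sans_ext(basename(path))) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty gene list: ", path)
  ids <- normalize_gene_ids(lines)
  n_dup <- length(ids) - length(unique(ids))
  if (n_dup > 0L) {
    message(sprintf("read_gene_list: %d duplicate line(s) collapsed in %s",
                    n_dup, path))
  }
  out <- study_list(study_id, label, ids)
  attr(out, "n_duplicates") <- n_dup
  out
}

# ---- ortholog map -----------------------------------------------------------

#' Construct an ortholog map
#'
#' A many-to-many mapping from source-species gene IDs to human gene IDs.
#' Lookups of unmapped IDs return the empty set rather than an error.
#'
#' @param source Character vector of source gene IDs.
#' @param human Character vector (same length) of human gene IDs.
#' @return An object of class `ortholog_map` (a two-column `data.frame`).
#' @export
ortholog_map <- function(source, human) {
  df <- unique(data.frame(source = normalize_gene_ids(source),
                          human = normalize_gene_ids(human),
                          stringsAsFactors = FALSE))
  df <- df[nzchar(df$source) & nzchar(df$human), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' Read an ortholog map from a two-column TSV
#'
#' Columns: source gene ID, human gene ID (header optional; detected when the
#' first line matches `source<TAB>human`).
#'
#' @param path File path.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("ortholog map must have two columns: ", path)
  ortholog_map(dt[[1L]], dt[[2L]])
}

#' Look up human orthologs of source gene IDs
#'
#' @param map An [ortholog_map()].
#' @param ids Character vector of source gene IDs.
#' @return Named list mapping each input ID to a character vector of human
#'   IDs (possibly empty).
#' @export
lookup_orthologs <- function(map, ids) {
  ids <- normalize_gene_ids(ids)
  hits <- split(map$human, map$source)
  out <- lapply(ids, function(i) unique(hits[[i]] %||% character(0)))
  names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- UTR sequences ----------------------------------------------------------

#' Read UTR sequences from FASTA
#'
#' The FASTA dialect carries, per record, a header of the form
#' `>transcript_id|gene_id|utr5` or `>transcript_id|gene_id|utr3`, optionally
#' followed by `|cds=<n>` giving the transcript's coding-sequence length in
#' nucleotides (used by [choose_longest_cds()]). The two UTR records of a
#' transcript are merged into one row. Sequences are upper-cased and `U` is
#' mapped to `T`; characters outside `A,C,G,T,U,N` are an error naming the
#' offending record.
#'
#' @param path FASTA file path.
#' @param id_map Optional `data.frame` with columns `transcript_id`,
#'   `gene_id` overriding the header gene IDs; transcripts absent from the
#'   map are skipped with a warning.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`, `utr5`,
#'   `utr3`, `cds_length`. Skipped-record counts are attached as attribute
#'   `"n_skipped"`.
#' @export
read_utr_fasta <- function(path, id_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  headers <- names(seqs)
  chars <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTUN]", chars)
  if (any(bad)) {
    stop("invalid sequence characters in record(s): ",
         paste(head(headers[bad], 3L), collapse = ", "))
  }
  chars <- chartr("U", "T", chars)

  parts <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 3L)) {
    stop("malformed FASTA header (need transcript|gene|utr5/utr3): ",
         headers[which(n_fields < 3L)[1L]])
  }
  tx <- trimws(vapply(parts, `[[`, "", 1L))
  gene <- normalize_gene_ids(vapply(parts, `[[`, "", 2L))
  region <- tolower(trimws(vapply(parts, `[[`, "", 3L)))
  if (!all(region %in% c("utr5", "utr3"))) {
    stop("FASTA region tag must be utr5 or utr3: ",
         headers[which(!region %in% c("utr5", "utr3"))[1L]])
  }
  cds <- vapply(parts, function(p) {
    hit <- grep("^cds=", p[-seq_len(3L)], value = TRUE)
    if (length(hit)) as.numeric(sub("^cds=", "", hit[1L])) else 0
  }, numeric(1))

  n_skipped <- 0L
  if (!is.null(id_map)) {
    id_map$gene_id <- normalize_gene_ids(id_map$gene_id)
    idx <- match(tx, id_map$transcript_id)
    drop <- is.na(idx)
    n_skipped <- sum(drop & !duplicated(tx))
    if (any(drop)) {
      warning(sprintf("read_utr_fasta: %d record(s) without gene mapping skipped",
                      sum(drop)))
      tx <- tx[!drop]; gene <- gene[!drop]; region <- region[!drop]
      chars <- chars[!drop]; cds <- cds[!drop]; idx <- idx[!drop]
    }
    gene <- id_map$gene_id[idx]
  }
  if (length(tx) == 0L) stop("no mappable records in FASTA: ", path)

  out <- data.frame(transcript_id = unique(tx), stringsAsFactors = FALSE)
  out$gene_id <- gene[match(out$transcript_id, tx)]
  pick <- function(which_region) {
    m <- match(paste(out$transcript_id, which_region),
               paste(tx, region))
    ifelse(is.na(m), "", chars[m])
  }
  out$utr5 <- pick("utr5")
  out$utr3 <- pick("utr3")
  out$cds_length <- vapply(out$transcript_id,
                           function(t) max(cds[tx == t]), numeric(1))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Select one transcript per gene by longest coding sequence
#'
#' When a gene has several transcripts, the one with the longest annotated
#' coding sequence supplies the UTRs; ties break on transcript ID
#' (lexicographic) for determinism.
#'
#' @param transcripts `data.frame` as returned by [read_utr_fasta()].
#' @return Subset with one row per `gene_id`.
#' @export
choose_longest_cds <- function(transcripts) {
  o <- order(transcripts$gene_id, -transcripts$cds_length,
             transcripts$transcript_id)
  t2 <- transcripts[o, , drop = FALSE]
  t2[!duplicated(t2$gene_id), , drop = FALSE]
}

# ---- expression matrix ------------------------------------------------------

#' Construct an expression matrix
#'
#' A gene x sample matrix of RPKM values plus per-sample metadata
#' (developmental age stage and brain tissue code), the layout of
#' BrainSpan-style developmental atlases.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). Must be complete and non-negative.
#' @param samples `data.frame` with columns `sample_id`, `age_stage`,
#'   `tissue_code`; row order must match the column order of `values`.
#' @return An object of class `expr_matrix`: list with elements `values`,
#'   `samples`.
#' @export
expr_matrix <- function(values, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("expression matrix contains missing cells")
  if (any(values < 0)) stop("expression matrix contains negative values")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need gene rownames and sample colnames")
  }
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "age_stage", "tissue_code") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  if (!identical(colnames(values), samples$sample_id)) {
    miss_meta <- setdiff(colnames(values), samples$sample_id)
    miss_vals <- setdiff(samples$sample_id, colnames(values))
    if (length(miss_meta) || length(miss_vals)) {
      stop("sample mismatch between values and metadata; missing from metadata: [",
           paste(miss_meta, collapse = ","), "]; missing from values: [",
           paste(miss_vals, collapse = ","), "]")
    }
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  }
  rownames(values) <- normalize_gene_ids(rownames(values))
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d tissues, %d age stages)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$tissue_code)),
              length(unique(x$samples$age_stage))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV files
#'
#' @param values_path TSV of RPKM values: first column gene IDs, remaining
#'   columns one per sample (header = sample IDs).
#' @param samples_path TSV of sample metadata with columns `sample_id`,
#'   `age_stage`, `tissue_code`.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(values_path, samples_path) {
  for (p in c(values_path, samples_path)) {
    if (!file.exists(p)) stop("no such file: ", p)
  }
  dt <- data.table::fread(values_path, sep = "\t", header = TRUE)
  genes <- as.character(dt[[1L]])
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", values_path)
  rownames(vals) <- genes
  samp <- as.data.frame(data.table::fread(samples_path, sep = "\t",
                                          header = TRUE,
                                          colClasses = "character"))
  message(sprintf("read_expression_matrix: %d genes x %d samples",
                  nrow(vals), ncol(vals)))
  expr_matrix(vals, samp)
}

#' Write an expression matrix to TSV files
#'
#' Inverse of [read_expression_matrix()]; values round-trip bit-identically.
#'
#' @param x An [expr_matrix()].
#' @param values_path,samples_path Output TSV paths.
#' @return Invisibly, `x`.
#' @export
write_expression_matrix <- function(x, values_path, samples_path) {
  dt <- data.table::data.table(gene_id = rownames(x$values),
                               fmt_full_precision(x$values))
  data.table::fwrite(dt, values_path, sep = "\t")
  data.table::fwrite(x$samples, samples_path, sep = "\t")
  invisible(x)
}

# doubles as text with 17 significant digits, the shortest width guaranteed
# to round-trip IEEE-754 exactly through fread's parser
fmt_full_precision <- function(m) {
  out <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
                dimnames = dimnames(m))
  as.data.frame(out, stringsAsFactors = FALSE)
}

# ---- feature matrix ---------------------------------------------------------

#' Construct a feature matrix
#'
#' Instances x named features, each feature tagged by provenance
#' (`"sequence"` or `"expression"`).
#'
#' @param values Numeric matrix; rownames = instance (gene) IDs, colnames =
#'   unique feature names.
#' @param kind Character vector, one of `"sequence"`/`"expression"` per
#'   column (recycled if length 1).
#' @return Object of class `feature_matrix` (a numeric matrix with a
#'   `feature_kind` attribute).
#' @export
feature_matrix <- function(values, kind) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("feature names must be present and unique")
  }
  if (is.null(rownames(values))) stop("instance (gene) rownames required")
  kind <- rep_len(as.character(kind), ncol(values))
  stopifnot(all(kind %in% c("sequence", "expression")))
  structure(values, feature_kind = kind, class = c("feature_matrix", "matrix", "array"))
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- attr(x, "feature_kind")
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) {
    if (missing(j)) new_kind <- kind
    else new_kind <- setNames(kind, colnames(unclass(x)))[colnames(y)]
    return(feature_matrix(y, unname(new_kind)))
  }
  y
}

#' Provenance tags of a feature matrix
#' @param x A [feature_matrix()].
#' @return Character vector of per-feature kinds.
#' @export
feature_kind <- function(x) attr(x, "feature_kind")

#' @export
print.feature_matrix <- function(x, ...) {
  k <- table(feature_kind(x))
  cat(sprintf("<feature_matrix> %d instances x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(k), k), collapse = ", ")))
  invisible(x)
}

#' Write / read a feature matrix (TSV + JSON sidecar)
#'
#' The TSV stores instance IDs in the first column; the sidecar JSON
#' (same path with extension `.json`) stores feature names and kinds so the
#' round trip is lossless and order-preserving.
#'
#' @param x A [feature_matrix()].
#' @param path TSV output path.
#' @return Invisibly, `x`.
#' @export
write_feature_matrix <- function(x, path) {
  dt <- data.table::data.table(instance = rownames(x),
                               fmt_full_precision(unclass(x)))
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(
    list(feature_names = colnames(x), feature_kind = feature_kind(x)),
    paste0(path, ".json"))
  invisible(x)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(vals) <- as.character(dt[[1L]])
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    vals <- vals[, meta$feature_names, drop = FALSE]
    feature_matrix(vals, meta$feature_kind)
  } else {
    feature_matrix(vals, "expression")
  }
}

# ---- labeled dataset --------------------------------------------------------

#' Construct a labeled dataset
#'
#' @param features A [feature_matrix()].
#' @param labels Integer/numeric vector of 0/1 labels (1 = dendritic /
#'   positive), named by instance ID or in row order of `features`.
#' @param single_class_ok Permit a single-class dataset (only sensible for
#'   independent test sets scored at a fixed threshold; default `FALSE`).
#' @return Object of class `labeled_dataset`: list with `features`, `labels`
#'   (named integer vector aligned to `rownames(features)`).
#' @export
labeled_dataset <- function(features, labels, single_class_ok = FALSE) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), rownames(features))) {
      stop("label names do not match feature instances")
    }
    labels <- labels[rownames(features)]
  } else {
    if (length(labels) != nrow(features)) stop("one label per instance required")
    names(labels) <- rownames(features)
  }
  if (length(unique(labels)) < 2L && !single_class_ok) {
    stop("both classes must be present in a labeled dataset")
  }
  structure(list(features = features, labels = labels),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d instances (%d positive / %d negative), %d features\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$features)))
  invisible(x)
}

# ---- gene sets --------------------------------------------------------------

#' Construct a gene set
#' @param name Set name.
#' @param genes Character vector of member gene IDs.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  structure(list(name = as.character(name),
                 genes = sort(unique(normalize_gene_ids(genes)))),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT: ", path)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1L])
    gene_set(f[1L], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set()] objects.
#' @param path Output path.
#' @param description Description field (second GMT column).
#' @return Invisibly, `sets`.
#' @export
write_gmt <- function(sets, path, description = "synloc") {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}
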