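# Synthetic-data generation for the whole pipeline: a developmental brain
# expression matrix with plantable class signal on contiguous (age stage,
# tissue) sample blocks, UTR sequences with optional k-mer enrichment in the
# positive class, and multi-study localization lists with an ortholog map
# and ground-truth bookkeeping. Everything the pipeline consumes can be
# generated here, so no external download is ever required.

AGE_STAGE_POOL <- c("8 pcw", "12 pcw", "16 pcw", "24 pcw", "35 pcw",
                    "4 mos", "10 mos", "2 yrs", "8 yrs", "13 yrs",
                    "21 yrs", "40 yrs")
TISSUE_POOL <- c("OFC", "HIP", "S1C", "DFC", "AMY", "MD", "STR",
                 "V1C", "CBC", "IPC")

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic fixtures. Defaults give a
#' 600-gene (300 positive / 300 negative), 200-sample design: 5 tissues x 8
#' age stages x 5 samples per cell, with class signal planted on the 20
#' samples of the 4 earliest (age, tissue) blocks as a +2 shift of mean
#' log2 expression - a planted analog of the early-development cortical
#' signal the expression features are expected to carry.
#'
#' @param n_positive,n_negative Class sizes (defaults 300/300).
#' @param n_tissues,n_age_stages,samples_per_cell Sample-grid layout
#'   (defaults 5, 8, 5; at most 10 tissues / 12 age stages).
#' @param signal_features Number of samples (expression features) carrying
#'   class signal (default 20); rounded up to whole (age, tissue) blocks.
#' @param effect_size Mean log2-expression shift of positives on signal
#'   samples (default 2).
#' @param noise_sd Gaussian sd of log2 expression (default 1).
#' @param baseline_log2 Mean background log2 expression (default 2, i.e.
#'   RPKM around 4, so the RPKM > 1 support filter has nontrivial action on
#'   low-expression genes).
#' @param utr_length_range Integer pair, uniform range of concatenated UTR
#'   lengths (default `c(100, 400)`, split roughly 1:2 between 5' and 3').
#' @param kmer_bias Optional named numeric vector of enrichment factors,
#'   e.g. `c(ACG = 4)`: listed k-mers are emitted this many times more often
#'   than a single base while generating positive-class UTRs.
#' @param seed Integer master seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_positive = 300L, n_negative = 300L,
                       n_tissues = 5L, n_age_stages = 8L,
                       samples_per_cell = 5L, signal_features = 20L,
                       effect_size = 2.0, noise_sd = 1.0,
                       baseline_log2 = 2.0,
                       utr_length_range = c(100L, 400L),
                       kmer_bias = NULL, seed = 1L) {
  stopifnot(n_positive > 0, n_negative > 0, n_tissues > 0,
            n_tissues <= length(TISSUE_POOL),
            n_age_stages > 0, n_age_stages <= length(AGE_STAGE_POOL),
            samples_per_cell > 0, signal_features >= 0,
            effect_size >= 0, noise_sd > 0,
            length(utr_length_range) == 2L,
            utr_length_range[1] >= 10L,
            utr_length_range[2] >= utr_length_range[1])
  n_samples <- n_tissues * n_age_stages * samples_per_cell
  if (signal_features > n_samples) stop("more signal features than samples")
  structure(list(n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 n_tissues = as.integer(n_tissues),
                 n_age_stages = as.integer(n_age_stages),
                 samples_per_cell = as.integer(samples_per_cell),
                 signal_features = as.integer(signal_features),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_log2 = baseline_log2,
                 utr_length_range = as.integer(utr_length_range),
                 kmer_bias = kmer_bias, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(cfg) {
  n <- cfg$n_positive + cfg$n_negative
  sprintf("G%05d", seq_len(n))
}

sim_labels <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  setNames(c(rep(1L, cfg$n_positive), rep(0L, cfg$n_negative)), ids)
}

#' Simulate a developmental brain expression matrix
#'
#' Background log2 expression is Gaussian
#' (`baseline_log2`, `noise_sd`) per gene x sample, exponentiated to the
#' RPKM scale (log-normal marginals). Positive-class genes are shifted by
#' `effect_size` on the signal samples: the first
#' `ceiling(signal_features / samples_per_cell)` cells of the (age stage x
#' tissue) grid in age-major order, i.e. contiguous early-development
#' blocks, truncated to exactly `signal_features` samples. With
#' `effect_size = 0` the classes are exchangeable.
#'
#' @param cfg A [sim_config()].
#' @return List with `expr` (an [expr_matrix()] of RPKM values), `labels`
#'   (named 0/1 vector), `signal_samples` (character vector of sample IDs
#'   carrying signal).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ages <- AGE_STAGE_POOL[seq_len(cfg$n_age_stages)]
  tissues <- TISSUE_POOL[seq_len(cfg$n_tissues)]
  grid <- expand.grid(replicate = seq_len(cfg$samples_per_cell),
                      tissue_code = tissues, age_stage = ages,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%03d_%s_%s", seq_len(nrow(grid)),
                        gsub(" ", "", grid$age_stage), grid$tissue_code),
    age_stage = grid$age_stage, tissue_code = grid$tissue_code,
    stringsAsFactors = FALSE)
  labels <- sim_labels(cfg)
  n_genes <- length(labels)
  n_samples <- nrow(samples)
  signal_samples <- samples$sample_id[seq_len(cfg$signal_features)]
  logv <- with_seed(cfg$seed, {
    m <- matrix(rnorm(n_genes * n_samples, cfg$baseline_log2, cfg$noise_sd),
                n_genes, n_samples)
    if (cfg$signal_features > 0 && cfg$effect_size > 0) {
      m[labels == 1L, seq_len(cfg$signal_features)] <-
        m[labels == 1L, seq_len(cfg$signal_features)] + cfg$effect_size
    }
    m
  })
  vals <- 2^logv
  dimnames(vals) <- list(names(labels), samples$sample_id)
  list(expr = expr_matrix(vals, samples), labels = labels,
       signal_samples = signal_samples)
}

# emit one random UTR sequence of (at least) the target length from a token
# alphabet of single bases plus optionally up-weighted k-mers
emit_sequence <- function(len, kmer_bias = NULL) {
  tokens <- c("A", "C", "G", "T")
  weights <- rep(1, 4)
  if (!is.null(kmer_bias)) {
    tokens <- c(tokens, names(kmer_bias))
    weights <- c(weights, as.numeric(kmer_bias))
  }
  # expected token length; oversample then trim
  n_draw <- ceiling(len / min(nchar(tokens))) + 8L
  draw <- sample(tokens, n_draw, replace = TRUE, prob = weights / sum(weights))
  substr(paste(draw, collapse = ""), 1L, len)
}

#' Simulate UTR sequences
#'
#' I.i.d. uniform nucleotides with concatenated length uniform in
#' `utr_length_range`, split roughly 1:2 between the 5' and 3' UTR (3' UTRs
#' of neuronal mRNAs are typically the longer carrier of localization
#' elements). When `kmer_bias` is set, positive-class sequences are emitted
#' from a token process in which each listed k-mer is drawn `factor` times
#' as often as a single base, multiplicatively enriching it.
#'
#' @param cfg A [sim_config()].
#' @param labels Named 0/1 label vector (defaults to the config's own).
#' @return `data.frame` with columns `transcript_id`, `gene_id`, `utr5`,
#'   `utr3`, `cds_length` (as [read_utr_fasta()] returns).
#' @export
simulate_utrs <- function(cfg, labels = sim_labels(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 1L, {
    lens <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                   length(labels), replace = TRUE)
    utr5_len <- pmax(5L, round(lens / 3))
    seqs <- vapply(seq_along(labels), function(i) {
      bias <- if (labels[i] == 1L) cfg$kmer_bias else NULL
      emit_sequence(lens[i], bias)
    }, character(1))
    data.frame(
      transcript_id = paste0(names(labels), ".t1"),
      gene_id = names(labels),
      utr5 = substr(seqs, 1L, utr5_len),
      utr3 = substr(seqs, utr5_len + 1L, lens),
      cds_length = sample(300:3000, length(labels), replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Simulate multi-study localization lists and an ortholog map
#'
#' Emits `n_studies` pseudo-studies per localization label, in a rodent-like
#' source ID space, together with a partly many-to-many ortholog map back to
#' the human gene IDs of `labels`. A gene joins at least two studies with
#' probability `overlap_fraction` (two or three, equally likely), otherwise
#' exactly one. Some genes are reported under different source aliases in
#' different studies (exercising ortholog union semantics before overlap
#' counting); a fraction of list entries are decoy IDs absent from the map;
#' and a few aliases additionally map to extra human genes that never reach
#' two studies. Ground-truth bookkeeping (which human genes appear in >= 2
#' studies per label) is returned for assertions.
#'
#' @param cfg A [sim_config()].
#' @param labels Named 0/1 label vector (defaults to the config's own).
#' @param n_studies Studies per label (default 3, minimum 2).
#' @param overlap_fraction Probability that a gene is supported by >= 2
#'   studies (default 0.8).
#' @param unmapped_fraction Fraction of extra decoy entries per study with
#'   no ortholog mapping (default 0.05).
#' @return List with `positive_studies`, `negative_studies` (lists of
#'   [study_list()]), `orthologs` (an [ortholog_map()]), and `truth` (list
#'   with `selected_positive`, `selected_negative`: the human genes planted
#'   in >= 2 studies per label).
#' @export
simulate_study_lists <- function(cfg, labels = sim_labels(cfg),
                                 n_studies = 3L, overlap_fraction = 0.8,
                                 unmapped_fraction = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), n_studies >= 2L,
            overlap_fraction >= 0, overlap_fraction <= 1)
  with_seed(cfg$seed + 2L, {
    genes <- names(labels)
    n_in <- vapply(genes, function(g) {
      if (runif(1) < overlap_fraction) sample(2:min(3L, n_studies), 1L) else 1L
    }, integer(1))
    membership <- lapply(seq_along(genes), function(i) {
      sort(sample(seq_len(n_studies), n_in[i]))
    })
    # two source aliases for ~20% of genes; the alias used differs by study
    n_alias <- ifelse(runif(length(genes)) < 0.2, 2L, 1L)
    aliases <- lapply(seq_along(genes), function(i) {
      sprintf("rn_%s_%d", genes[i], seq_len(n_alias[i]))
    })
    map_source <- unlist(aliases)
    map_human <- rep(genes, n_alias)
    # a few second aliases additionally map to extra human genes; with up to
    # three studies the second alias is only ever used in study 2, so these
    # extra humans never reach two studies and never pass the overlap rule
    if (n_studies <= 3L && any(n_alias == 2L)) {
      extra_idx <- which(n_alias == 2L)[seq_len(min(5L, sum(n_alias == 2L)))]
      extra_h <- sprintf("HX%04d", seq_along(extra_idx))
      map_source <- c(map_source, vapply(aliases[extra_idx], `[[`, "", 2L))
      map_human <- c(map_human, extra_h)
    }

    build_side <- function(side_label, lab_value) {
      side_idx <- which(labels == lab_value)
      lapply(seq_len(n_studies), function(s) {
        members <- side_idx[vapply(membership[side_idx],
                                   function(m) s %in% m, logical(1))]
        src <- vapply(members, function(i) {
          a <- aliases[[i]]
          a[1L + (length(a) > 1L && s %% 2L == 0L)]
        }, character(1))
        n_decoy <- ceiling(unmapped_fraction * max(1L, length(src)))
        decoys <- sprintf("rn_decoy_%s%d_%03d", side_label, s,
                          seq_len(n_decoy))
        study_list(sprintf("%s_study_%d", side_label, s),
                   if (lab_value == 1L) "dendritic" else "somatic",
                   c(src, decoys))
      })
    }
    pos_studies <- build_side("pos", 1L)
    neg_studies <- build_side("neg", 0L)
    truth <- list(
      selected_positive = sort(genes[labels == 1L & n_in >= 2L]),
      selected_negative = sort(genes[labels == 0L & n_in >= 2L]))
    list(positive_studies = pos_studies, negative_studies = neg_studies,
         orthologs = ortholog_map(map_source, map_human), truth = truth)
  })
}

#' Write a complete set of synthetic fixtures to disk
#'
#' Materializes everything the command-line pipeline consumes: study gene
#' lists, ortholog map TSV, UTR FASTA (in the dialect of
#' [read_utr_fasta()]), expression value + sample metadata TSVs, a GMT gene
#' set (the planted positive genes, standing in for a curated synaptic-gene
#' catalogue), and a ground-truth JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixtures <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim_e <- simulate_expression(cfg)
  tx <- simulate_utrs(cfg, sim_e$labels)
  lists <- simulate_study_lists(cfg, sim_e$labels)
  paths <- list()

  paths$expression <- file.path(dir, "expression.tsv")
  paths$samples <- file.path(dir, "samples.tsv")
  write_expression_matrix(sim_e$expr, paths$expression, paths$samples)

  paths$utr_fasta <- file.path(dir, "utrs.fasta")
  fasta_lines <- unlist(lapply(seq_len(nrow(tx)), function(i) {
    c(sprintf(">%s|%s|utr5|cds=%d", tx$transcript_id[i], tx$gene_id[i],
              tx$cds_length[i]), tx$utr5[i],
      sprintf(">%s|%s|utr3|cds=%d", tx$transcript_id[i], tx$gene_id[i],
              tx$cds_length[i]), tx$utr3[i])
  }))
  writeLines(fasta_lines, paths$utr_fasta)

  all_studies <- c(lists$positive_studies, lists$negative_studies)
  paths$study_lists <- vapply(all_studies, function(s) {
    p <- file.path(dir, paste0(s$study_id, ".txt"))
    writeLines(c(sprintf("# %s (%s)", s$study_id, s$label), s$genes), p)
    p
  }, character(1))

  paths$orthologs <- file.path(dir, "orthologs.tsv")
  data.table::fwrite(as.data.frame(unclass(lists$orthologs)),
                     paths$orthologs, sep = "\t")

  paths$gene_sets <- file.path(dir, "synaptic_reference.gmt")
  write_gmt(list(gene_set("synthetic_synaptic_reference",
                          names(sim_e$labels)[sim_e$labels == 1L])),
            paths$gene_sets, description = "planted positive genes")

  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(labels = as.list(sim_e$labels),
         signal_samples = sim_e$signal_samples,
         selected_positive = lists$truth$selected_positive,
         selected_negative = lists$truth$selected_negative,
         config = unclass(cfg)[setdiff(names(unclass(cfg)), "kmer_bias")]),
    paths$truth, auto_unbox = TRUE, null = "null")
  invisible(paths)
}
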