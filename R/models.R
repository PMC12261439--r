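# Two-stage scoring --------------------------------------------------------
#
# Stage 1 ("general") filters candidates on the 30 general features; stage 2
# ("specific") assigns each surviving (candidate, cell) pair an expression
# probability from all 51 features. Both are probability random forests with
# 100 trees and maximum depth 12, trained on chromosomes 1-9 and evaluated on
# the remainder so reported accuracy is out-of-sample.

#' Label candidates against a unified ground truth
#'
#' A candidate is positive when its full (chrom, strand, junction list)
#' exactly matches a chain in the union of all cells' ground-truth
#' transcripts (or the reference annotation when per-cell truth is
#' unavailable).
#'
#' @param features general-mode feature table from [assemble_feature_matrix()]
#' @param truth_keys character vector of ground-truth chain keys
#' @return `features` with a `label` column in \{0, 1\}
#' @export
label_general <- function(features, truth_keys) {
  if (length(truth_keys) == 0L) {
    warning("empty ground truth: all labels 0")
  }
  features$label <- as.integer(features$chain_key %in% truth_keys)
  features
}

#' Label (candidate, cell) pairs against per-cell ground truth
#'
#' @param features specific-mode feature table
#' @param truth_by_cell named list: cell id -> character vector of that
#'   cell's expressed chain keys
#' @return `features` with a `label` column; pairs whose cell is absent from
#'   the truth are labelled 0 with a warning
#' @export
label_specific <- function(features, truth_by_cell) {
  missing <- setdiff(unique(features$cell), names(truth_by_cell))
  if (length(missing)) {
    warning("cells absent from ground truth labelled 0: ",
            paste(missing, collapse = ", "))
  }
  features$label <- vapply(seq_len(nrow(features)), function(i) {
    tk <- truth_by_cell[[features$cell[i]]]
    as.integer(!is.null(tk) && features$chain_key[i] %in% tk)
  }, 0L)
  features
}

# "chr" prefixes are accepted; comparison is on the bare chromosome name
norm_chrom <- function(x) sub("^chr", "", x)

#' Split labelled examples by chromosome
#'
#' @param examples data.frame with a `chrom` column
#' @param train_chroms chromosomes reserved for training (default 1-9)
#' @return list with `train` and `test` data.frames (disjoint, exhaustive)
#' @export
split_by_chromosome <- function(examples, train_chroms = as.character(1:9)) {
  in_train <- norm_chrom(examples$chrom) %in% norm_chrom(train_chroms)
  if (!any(in_train) && nrow(examples) > 0L) {
    warning("no examples on training chromosomes")
  }
  list(train = examples[in_train, , drop = FALSE],
       test = examples[!in_train, , drop = FALSE])
}

#' @importFrom ranger ranger
fit_rf <- function(features, cols, seed) {
  y <- factor(features$label, levels = c(0L, 1L))
  if (length(unique(features$label)) < 2L) {
    stop("training set contains a single class; cannot fit a forest")
  }
  ranger::ranger(x = features[cols], y = y,
                 num.trees = 100, max.depth = 12,
                 probability = TRUE, seed = seed, num.threads = 1)
}

predict_rf <- function(fit, features, cols) {
  as.numeric(stats::predict(fit, data = features[cols],
                            num.threads = 1)$predictions[, "1"])
}

#' Train the candidate-level (general) forest
#'
#' @param train labelled general-mode feature table (training chromosomes)
#' @param seed RNG seed for the forest
#' @return fitted `ranger` model
#' @export
train_general <- function(train, seed = 42) {
  fit_rf(train, GENERAL_FEATURES, seed)
}

#' Predict general candidate scores
#' @param model fitted general model
#' @param features general-mode feature table
#' @return numeric probabilities in \[0, 1\]
#' @export
predict_general <- function(model, features) {
  predict_rf(model, features, GENERAL_FEATURES)
}

#' Filter candidates on the general score
#'
#' Candidates scoring below `theta` are discarded; a candidate exactly at the
#' threshold is kept. The filter controls false positives and balances the
#' classes seen by the specific model.
#'
#' @param candidates result of [search_all()]
#' @param scores general scores aligned with `candidates`
#' @param theta score threshold (default 0.2)
#' @return the surviving candidates, each with a `general_score` field
#' @export
filter_general <- function(candidates, scores, theta = 0.2) {
  stopifnot(length(candidates) == length(scores))
  keep <- which(scores >= theta)
  out <- candidates[keep]
  for (i in seq_along(out)) out[[i]]$general_score <- scores[keep[i]]
  out
}

#' Train the per-cell (specific) forest on all 51 features
#'
#' @param train labelled specific-mode feature table built from the filtered
#'   candidate set
#' @param seed RNG seed
#' @return fitted `ranger` model
#' @export
train_specific <- function(train, seed = 42) {
  fit_rf(train, c(GENERAL_FEATURES, CELL_FEATURES), seed)
}

#' Predict per-cell expression probabilities
#' @param model fitted specific model
#' @param features specific-mode feature table
#' @return numeric probabilities in \[0, 1\]
#' @export
predict_specific <- function(model, features) {
  predict_rf(model, features, c(GENERAL_FEATURES, CELL_FEATURES))
}

#' Score every eligible (candidate, cell) pair and emit per-cell assemblies
#'
#' @param filtered candidates surviving [filter_general()]
#' @param index the `fragment_index` of the input assemblies
#' @param model fitted specific model
#' @param tau emission threshold: a candidate enters a cell's final assembly
#'   when its probability is at least `tau` (default 0.5); the full scored
#'   pair table is returned regardless of `tau`
#' @return list with `pairs` (data.frame `candidate_id`, `cell`, `chrom`,
#'   `chain_key`, `prob`) and `assemblies` (named list, one scored assembly
#'   per cell, each writable by [write_scored_gtf()])
#' @export
score_cells <- function(filtered, index, model, tau = 0.5) {
  cells <- index$cells
  empty_asm <- function(cc) list(cell = cc, transcripts = list())
  if (length(filtered) == 0L) {
    return(list(pairs = data.frame(candidate_id = character(0),
                                   cell = character(0), chrom = character(0),
                                   chain_key = character(0),
                                   prob = numeric(0)),
                assemblies = stats::setNames(lapply(cells, empty_asm),
                                             cells)))
  }
  feats <- assemble_feature_matrix(filtered, index, mode = "specific")
  prob <- predict_specific(model, feats)
  pairs <- data.frame(candidate_id = feats$candidate_id, cell = feats$cell,
                      chrom = feats$chrom, chain_key = feats$chain_key,
                      prob = prob, stringsAsFactors = FALSE)
  by_id <- stats::setNames(filtered, vapply(filtered, `[[`, "", "id"))
  assemblies <- stats::setNames(lapply(cells, function(cc) {
    sel <- pairs[pairs$cell == cc & pairs$prob >= tau, , drop = FALSE]
    txs <- lapply(seq_len(nrow(sel)), function(i) {
      cand <- by_id[[sel$candidate_id[i]]]
      list(id = cand$id, chrom = cand$chrom, strand = cand$strand,
           exons = cand$exons, score = sel$prob[i],
           gene = sprintf("comp_%05d", cand$component))
    })
    list(cell = cc, transcripts = txs)
  }), cells)
  list(pairs = pairs, assemblies = assemblies)
}

#' Bundle the two fitted models with their metadata
#'
#' @param general,specific fitted models
#' @param theta general-score threshold
#' @param seed training seed
#' @param train_chroms chromosomes used for training
#' @return a `model_bundle`
#' @export
model_bundle <- function(general, specific, theta = 0.2, seed = 42,
                         train_chroms = as.character(1:9)) {
  structure(list(general = general, specific = specific, theta = theta,
                 schema = FEATURE_SCHEMA_VERSION,
                 meta = list(seed = seed, train_chroms = train_chroms)),
            class = "model_bundle")
}

#' Persist / restore a model bundle
#'
#' The bundle is written as an RDS archive next to a plain-JSON manifest
#' recording the feature-schema version, threshold, seed and training
#' chromosomes, so a bundle can be identified without loading it.
#'
#' @param bundle a `model_bundle`
#' @param path output path (`.rds`); the manifest gets extension
#'   `.manifest.json`
#' @export
save_model_bundle <- function(bundle, path) {
  saveRDS(bundle, path)
  manifest <- list(schema = bundle$schema, theta = bundle$theta,
                   seed = bundle$meta$seed,
                   train_chroms = bundle$meta$train_chroms)
  jsonlite::write_json(manifest, sub("\\.rds$", ".manifest.json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$schema, FEATURE_SCHEMA_VERSION)) {
    stop("model bundle schema '", bundle$schema,
         "' does not match this package's '", FEATURE_SCHEMA_VERSION, "'")
  }
  bundle
}
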