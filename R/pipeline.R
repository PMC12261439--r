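# Pipeline -----------------------------------------------------------------

as_assemblies <- function(input, score_attribute = "cov") {
  if (is.character(input)) read_cell_gtfs(input, score_attribute) else input
}

as_truth <- function(truth, cells) {
  if (is.character(truth) && length(truth) == 1L) {
    if (grepl("\\.gtf$", truth)) {
      # reference-annotation mode: the same truth for every cell
      keys <- read_reference_chains(truth)$chain_key
      return(stats::setNames(rep(list(unique(keys)), length(cells)), cells))
    }
    return(read_truth_tsv(truth))
  }
  truth
}

#' Assemble candidate full-length transcripts from per-cell inputs
#'
#' Runs the first half of the method: load assemblies, build the transcript
#' fragment graph, and enumerate candidate paths by merging-score.
#'
#' @param input directory of per-cell GTFs, or a list of `cell_assembly`
#'   objects
#' @param score_attribute transcript score attribute for GTF inputs
#' @param params a [search_params()]
#' @param out_dir optional directory for `candidates.gtf`,
#'   `candidates.tsv` and a JSON manifest of stage counts
#' @return list with `assemblies`, `graph`, `candidates` and `counts`
#' @export
run_assemble <- function(input, score_attribute = "cov",
                         params = search_params(), out_dir = NULL) {
  assemblies <- as_assemblies(input, score_attribute)
  if (length(assemblies) == 0L) stop("no input assemblies")
  graph <- build_graph(assemblies)
  candidates <- search_all(graph, params)
  counts <- list(
    cells = length(assemblies),
    fragments = length(graph$index$fragments),
    vertices = length(graph$vertices),
    edges = nrow(graph$edges),
    components = length(unique(graph$comp)),
    candidates = length(candidates))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_candidates(candidates, file.path(out_dir, "candidates.gtf"),
                      file.path(out_dir, "candidates.tsv"))
    jsonlite::write_json(counts, file.path(out_dir, "assemble.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(assemblies = assemblies, graph = graph, candidates = candidates,
       counts = counts)
}

#' Run the full pipeline: assemble, train, score, evaluate
#'
#' Candidates are labelled against the ground truth, both forests are trained
#' on the training chromosomes (default 1-9), every candidate is scored, the
#' general filter is applied at `theta`, each eligible (candidate, cell) pair
#' receives an expression probability, and per-cell assemblies are emitted at
#' `tau`. Evaluation is restricted to held-out chromosomes. When `truth` is a
#' reference GTF (no per-cell truth), both models fall back to the unified
#' annotation labels.
#'
#' @param input directory of per-cell GTFs or list of `cell_assembly`
#' @param truth per-cell truth (named list of chain keys or a `truth.tsv`
#'   path) or a reference GTF path; ignored when `bundle` is given
#' @param bundle optional pre-trained `model_bundle` (inference mode)
#' @param train_chroms training chromosomes
#' @param theta general-filter threshold
#' @param tau per-cell emission threshold
#' @param seed RNG seed for model training
#' @param params a [search_params()]
#' @param score_attribute GTF score attribute
#' @param out_dir optional output directory (per-cell scored GTFs,
#'   candidate set, evaluation TSV, JSON manifest)
#' @return list with `candidates`, `filtered`, `bundle`, `pairs`,
#'   `scored_assemblies`, `eval` (held-out per-cell table) and `counts`
#' @export
run_full <- function(input, truth = NULL, bundle = NULL,
                     train_chroms = as.character(1:9),
                     theta = 0.2, tau = 0.5, seed = 42,
                     params = search_params(), score_attribute = "cov",
                     out_dir = NULL) {
  if (is.null(truth) && is.null(bundle)) {
    stop("either ground truth (training mode) or a model bundle ",
         "(inference mode) is required")
  }
  asm_stage <- run_assemble(input, score_attribute, params)
  assemblies <- asm_stage$assemblies
  index <- asm_stage$graph$index
  candidates <- asm_stage$candidates
  truth_by_cell <- if (!is.null(truth))
    as_truth(truth, vapply(assemblies, `[[`, "", "cell")) else NULL

  feats_gen <- assemble_feature_matrix(candidates, index, "general")
  if (is.null(bundle)) {
    union_keys <- unique(unlist(truth_by_cell))
    labelled <- label_general(feats_gen, union_keys)
    split_gen <- split_by_chromosome(labelled, train_chroms)
    general <- train_general(split_gen$train, seed = seed)
  } else {
    general <- bundle$general
  }
  gen_scores <- predict_general(general, feats_gen)
  filtered <- filter_general(candidates, gen_scores, theta)

  if (is.null(bundle)) {
    specific <- NULL
    if (length(filtered) > 0L) {
      feats_spec <- assemble_feature_matrix(filtered, index, "specific")
      labelled_spec <- label_specific(feats_spec, truth_by_cell)
      split_spec <- split_by_chromosome(labelled_spec, train_chroms)
      specific <- train_specific(split_spec$train, seed = seed)
    }
    bundle <- model_bundle(general, specific, theta = theta, seed = seed,
                           train_chroms = train_chroms)
  }
  scored <- score_cells(filtered, index, bundle$specific, tau)

  eval_tab <- NULL
  if (!is.null(truth_by_cell)) {
    test_pred <- lapply(split(scored$pairs, scored$pairs$cell), function(d) {
      d <- d[!norm_chrom(d$chrom) %in% norm_chrom(train_chroms), ,
             drop = FALSE]
      data.frame(chain_key = d$chain_key, score = d$prob,
                 stringsAsFactors = FALSE)
    })
    # cells with no scored pair still get an (empty) row
    for (cc in setdiff(names(truth_by_cell), names(test_pred))) {
      test_pred[[cc]] <- data.frame(chain_key = character(0),
                                    score = numeric(0))
    }
    test_truth <- lapply(truth_by_cell, function(k)
      k[!norm_chrom(chrom_of_key(k)) %in% norm_chrom(train_chroms)])
    eval_tab <- evaluate_dataset(test_pred, test_truth)
  }

  counts <- c(asm_stage$counts,
              list(filtered = length(filtered),
                   scored_pairs = nrow(scored$pairs),
                   emitted = sum(vapply(scored$assemblies,
                                        function(a) length(a$transcripts),
                                        0L))))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "cells"), recursive = TRUE,
               showWarnings = FALSE)
    export_candidates(candidates, file.path(out_dir, "candidates.gtf"),
                      file.path(out_dir, "candidates.tsv"))
    for (a in scored$assemblies) {
      write_scored_gtf(a, file.path(out_dir, "cells",
                                    paste0(a$cell, ".gtf")))
    }
    if (!is.null(eval_tab)) {
      write_eval_tsv(eval_tab, file.path(out_dir, "evaluation.tsv"))
    }
    jsonlite::write_json(
      c(counts, list(theta = theta, tau = tau, seed = seed,
                     train_chroms = train_chroms,
                     pn = params$pn, pc = params$pc)),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(candidates = candidates, filtered = filtered, bundle = bundle,
       pairs = scored$pairs, scored_assemblies = scored$assemblies,
       eval = eval_tab, counts = counts)
}
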