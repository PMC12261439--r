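# Evaluation ---------------------------------------------------------------
#
# A predicted multi-exon transcript "matches" when its intron chain (chrom,
# strand, full junction list) is identical to a ground-truth chain. Duplicate
# predictions of one chain earn matching credit once; every occurrence counts
# in the denominator. Precision = matching / assembled. Adjusted precision
# compares two methods at equal sensitivity by discarding the lower-scoring
# predictions of the more sensitive one.

#' Match a scored prediction set against a truth chain set
#'
#' @param predictions data.frame with columns `chain_key` and `score`
#' @param truth_keys character vector of ground-truth chain keys
#' @return an `eval_result`: `n_assembled`, `n_matching` (distinct matched
#'   chains), `precision` (`NA` when nothing was assembled), and `detail`,
#'   the predictions with a logical `match` flag
#' @export
match_transcripts <- function(predictions, truth_keys) {
  stopifnot(all(c("chain_key", "score") %in% names(predictions)))
  match_flag <- predictions$chain_key %in% truth_keys
  n_assembled <- nrow(predictions)
  n_matching <- length(unique(predictions$chain_key[match_flag]))
  detail <- predictions
  detail$match <- match_flag
  structure(list(
    n_assembled = n_assembled, n_matching = n_matching,
    precision = if (n_assembled > 0L) n_matching / n_assembled else NA_real_,
    detail = detail), class = "eval_result")
}

#' Precision at matched sensitivity
#'
#' Removes predictions one at a time in increasing score order (ties broken
#' by chain key) until the distinct-match count first equals
#' `target_matches`, then returns the precision of the retained set. This is
#' the point on the method's precision-recall curve with the target's
#' sensitivity. Returns `NA` when the result cannot reach the target.
#'
#' @param result an `eval_result` from [match_transcripts()]
#' @param target_matches matching-transcript count of the comparator method
#' @return numeric precision, or `NA`
#' @export
adjusted_precision <- function(result, target_matches) {
  if (result$n_matching < target_matches) return(NA_real_)
  d <- result$detail
  ord <- order(d$score, d$chain_key)   # removal order: worst first
  keep <- rep(TRUE, nrow(d))
  matched_count <- function() {
    length(unique(d$chain_key[keep & d$match]))
  }
  cur <- result$n_matching
  for (i in ord) {
    if (cur <= target_matches) break
    keep[i] <- FALSE
    cur <- matched_count()
    if (cur < target_matches) {        # overshot: this removal was the last
      keep[i] <- TRUE                  # matched copy; put it back and stop
      cur <- target_matches
      break
    }
  }
  n_keep <- sum(keep)
  if (n_keep == 0L) return(NA_real_)
  length(unique(d$chain_key[keep & d$match])) / n_keep
}

#' Evaluate per-cell predictions in cell-specific and general mode
#'
#' Cell-specific mode scores each cell's predictions against that cell's own
#' truth; general mode scores them against the union of all cells' truths.
#' The gap between the two quantifies how well transcripts are assigned to
#' the right cells rather than merely being correct somewhere.
#'
#' @param predictions_by_cell named list: cell id -> data.frame with
#'   `chain_key` and `score`
#' @param truth_by_cell named list: cell id -> character vector of truth keys
#' @return data.frame with one row per cell (`n_assembled`,
#'   `n_match_specific`, `precision_specific`, `n_match_general`,
#'   `precision_general`); attribute `summary` holds medians and means
#' @export
evaluate_dataset <- function(predictions_by_cell, truth_by_cell) {
  unmatched <- setdiff(names(predictions_by_cell), names(truth_by_cell))
  if (length(unmatched)) {
    stop("cells without ground truth: ", paste(unmatched, collapse = ", "))
  }
  union_keys <- unique(unlist(truth_by_cell))
  rows <- lapply(names(predictions_by_cell), function(cc) {
    pred <- predictions_by_cell[[cc]]
    spec <- match_transcripts(pred, truth_by_cell[[cc]])
    gen <- match_transcripts(pred, union_keys)
    data.frame(cell = cc, n_assembled = spec$n_assembled,
               n_match_specific = spec$n_matching,
               precision_specific = spec$precision,
               n_match_general = gen$n_matching,
               precision_general = gen$precision,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  num <- c("n_assembled", "n_match_specific", "precision_specific",
           "n_match_general", "precision_general")
  attr(out, "summary") <- data.frame(
    metric = num,
    median = vapply(num, function(k) stats::median(out[[k]], na.rm = TRUE), 0),
    mean = vapply(num, function(k) mean(out[[k]], na.rm = TRUE), 0))
  out
}

# chromosome of a canonical chain key ("chrom|strand|d,a,...")
chrom_of_key <- function(keys) vapply(strsplit(keys, "|", fixed = TRUE),
                                      `[[`, "", 1L)

#' Per-cell scored predictions from raw input assemblies
#'
#' Turns the input fragments themselves into a prediction table per cell so
#' the method's output can be compared against its own input at matched
#' sensitivity.
#'
#' @param assemblies list of `cell_assembly` objects
#' @return named list of data.frames with `chain_key` and `score`
#' @export
input_predictions <- function(assemblies) {
  out <- lapply(assemblies, function(a) {
    data.frame(
      chain_key = vapply(a$fragments, function(f)
        chain_key(f$chrom, f$strand, f$chain), ""),
      score = vapply(a$fragments, `[[`, 0, "score"),
      stringsAsFactors = FALSE)
  })
  stats::setNames(out, vapply(assemblies, `[[`, "", "cell"))
}

#' Compare scored output against a baseline at matched sensitivity
#'
#' For every cell, the scored predictions are cut back (lowest probabilities
#' first) until they match the baseline's cell-specific matching count; the
#' resulting adjusted precision is compared with the baseline's raw
#' precision. Cells where neither side assembles anything are dropped.
#'
#' @param scored_by_cell,baseline_by_cell named lists of per-cell prediction
#'   data.frames (`chain_key`, `score`)
#' @param truth_by_cell named list of per-cell truth keys
#' @return data.frame per cell: baseline matches/precision and the scored
#'   set's adjusted precision at the baseline's sensitivity (`NA` when the
#'   scored set is less sensitive than the baseline in that cell)
#' @export
matched_sensitivity_comparison <- function(scored_by_cell, baseline_by_cell,
                                           truth_by_cell) {
  cells <- intersect(names(scored_by_cell), names(baseline_by_cell))
  rows <- lapply(cells, function(cc) {
    base <- match_transcripts(baseline_by_cell[[cc]], truth_by_cell[[cc]])
    scored <- match_transcripts(scored_by_cell[[cc]], truth_by_cell[[cc]])
    data.frame(
      cell = cc,
      baseline_matches = base$n_matching,
      baseline_precision = base$precision,
      scored_matches = scored$n_matching,
      scored_precision = scored$precision,
      scored_adjusted_precision = adjusted_precision(scored,
                                                     base$n_matching),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a per-cell evaluation table (and optional summary) as TSV
#' @param eval_table result of [evaluate_dataset()]
#' @param path output TSV path
#' @export
write_eval_tsv <- function(eval_table, path) {
  utils::write.table(eval_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
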