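# Feature schema ------------------------------------------------------------
#
# Three categories mirror the method's design: junction-coverage statistics
# (how well each splice junction of the candidate is supported), cell-support
# statistics (how broadly the candidate is supported across cells), and
# fragment-connecting statistics (whether the candidate preserves an input
# chain or was stitched from several fragments). Summaries use min / median /
# mean / max / population standard deviation (population so n = 1 gives 0).

FEATURE_SCHEMA_VERSION <- "txfuse-features-1"

GENERAL_FEATURES <- c(
  "js_min", "js_median", "js_mean", "js_max", "js_sd",
  "jcells_min", "jcells_median", "jcells_mean", "jcells_max", "jcells_sd",
  "jfrags_min", "jfrags_median", "jfrags_mean", "jfrags_max", "jfrags_sd",
  "n_junctions", "bottleneck", "merging_score",
  "n_cells_supporting", "prop_cells_supporting",
  "n_cells_full_chain", "prop_cells_full_chain",
  "n_vertices", "single_fragment", "longest_fragment_frac",
  "overlap_min", "overlap_mean", "overlap_max",
  "total_support_score", "n_compatible_fragments")

CELL_FEATURES <- c(
  "c_js_min", "c_js_median", "c_js_mean", "c_js_max", "c_js_sd",
  "c_jfrags_min", "c_jfrags_median", "c_jfrags_mean", "c_jfrags_max",
  "c_jfrags_sd",
  "c_bottleneck", "c_n_fragments", "c_total_score",
  "c_frac_junctions_expressed", "c_full_chain",
  "c_best_frag_score", "c_best_frag_frac", "c_n_junctions_expressed",
  "c_library_size", "c_bj_rank", "cand_merging_score")

stat5 <- function(x, prefix) {
  if (length(x) == 0L) x <- 0
  m <- mean(x)
  stats::setNames(
    c(min(x), stats::median(x), m, max(x), sqrt(mean((x - m)^2))),
    paste0(prefix, c("_min", "_median", "_mean", "_max", "_sd")))
}

#' Junction-coverage feature block of a candidate
#'
#' Per-junction scores J(j, p) summarised over the path, restricted to one
#' cell's fragments when `cell` is given, together with the bottleneck.
#'
#' @param candidate one element of [search_all()]'s result
#' @param index a `fragment_index`
#' @param cell optional cell id
#' @return named numeric vector (5 summary stats + bottleneck)
#' @export
junction_coverage_features <- function(candidate, index, cell = NULL) {
  js <- junction_scores(candidate$chrom, candidate$strand, candidate$chain,
                        index, cell)
  c(stat5(js, if (is.null(cell)) "js" else "c_js"),
    stats::setNames(if (length(js)) min(js) else 0,
                    if (is.null(cell)) "bottleneck" else "c_bottleneck"))
}

#' Cell-support feature block of a candidate
#'
#' Per-junction supporting-cell counts plus counts and proportions of cells
#' with any compatible fragment and of cells containing the full chain.
#'
#' @inheritParams junction_coverage_features
#' @return named numeric vector
#' @export
cell_support_features <- function(candidate, index) {
  sup <- path_support(candidate$chrom, candidate$strand, candidate$chain,
                      index)
  n_cells <- length(index$cells)
  jcells <- vapply(seq_len(ncol(sup$contains)), function(j)
    length(unique(sup$cell[sup$contains[, j]])), 0L)
  full <- vapply(sup$frag_idx, function(i)
    chain_contains(index$fragments[[i]]$chain, candidate$chain), TRUE)
  cells_sup <- unique(sup$cell)
  cells_full <- unique(sup$cell[full])
  c(stat5(jcells, "jcells"),
    n_cells_supporting = length(cells_sup),
    prop_cells_supporting = length(cells_sup) / max(1L, n_cells),
    n_cells_full_chain = length(cells_full),
    prop_cells_full_chain = length(cells_full) / max(1L, n_cells))
}

#' Fragment-connecting feature block of a candidate
#'
#' Describes how the candidate was stitched together: number of constituent
#' vertices, overlap lengths between consecutive vertices, whether the chain
#' is a single input fragment, and the chain fraction covered by the longest
#' single compatible fragment.
#'
#' @inheritParams junction_coverage_features
#' @return named numeric vector
#' @export
fragment_connecting_features <- function(candidate, index) {
  sup <- path_support(candidate$chrom, candidate$strand, candidate$chain,
                      index)
  nv <- length(candidate$vertices)
  ov <- candidate$overlaps
  if (length(ov) == 0L) ov <- 0
  frac <- if (length(sup$frag_idx)) {
    max(rowSums(sup$contains)) / candidate$NJ
  } else 0
  c(n_vertices = nv,
    single_fragment = as.numeric(nv == 1L),
    longest_fragment_frac = frac,
    overlap_min = min(ov), overlap_mean = mean(ov), overlap_max = max(ov))
}

# everything computed in one pass per candidate so the general row and all
# eligible per-cell rows reuse the same support scan
candidate_feature_rows <- function(candidate, index) {
  chrom <- candidate$chrom; strand <- candidate$strand
  chain <- candidate$chain
  np <- chain_len(chain)
  sup <- path_support(chrom, strand, chain, index)

  js <- as.numeric(colSums(sup$contains * sup$score))
  bj <- if (np) min(js) else 0
  jfrags <- as.numeric(colSums(sup$contains))
  general <- c(
    stat5(js, "js"),
    cell_support_features(candidate, index)[
      c("jcells_min", "jcells_median", "jcells_mean", "jcells_max",
        "jcells_sd", "n_cells_supporting", "prop_cells_supporting",
        "n_cells_full_chain", "prop_cells_full_chain")],
    stat5(jfrags, "jfrags"),
    n_junctions = np, bottleneck = bj, merging_score = bj * np,
    fragment_connecting_features(candidate, index),
    total_support_score = sum(sup$score),
    n_compatible_fragments = length(sup$frag_idx))
  general <- general[GENERAL_FEATURES]

  # which cells express each path junction (any fragment, compatibility not
  # required: this is the eligibility notion, deliberately weaker)
  keys <- junction_keys(chrom, strand, chain)
  expr_cells <- lapply(keys, function(k)
    unique(index$cell[index$by_junction[[k]]]))
  eligible <- sort(unique(unlist(expr_cells)))

  lib_size <- table(index$cell)
  cell_rows <- list()
  cell_bjs <- numeric(0)
  for (cc in eligible) {
    rows <- sup$cell == cc
    c_js <- as.numeric(colSums(sup$contains[rows, , drop = FALSE] *
                                 sup$score[rows]))
    c_jfrags <- as.numeric(colSums(sup$contains[rows, , drop = FALSE]))
    c_bj <- if (np) min(c_js) else 0
    cell_bjs[cc] <- c_bj
    n_expr <- sum(vapply(expr_cells, function(e) cc %in% e, TRUE))
    full <- any(vapply(sup$frag_idx[rows], function(i)
      chain_contains(index$fragments[[i]]$chain, chain), TRUE))
    best_score <- if (any(rows)) max(sup$score[rows]) else 0
    best_frac <- if (any(rows))
      max(rowSums(sup$contains[rows, , drop = FALSE])) / np else 0
    cell_rows[[cc]] <- c(
      stat5(c_js, "c_js"), stat5(c_jfrags, "c_jfrags"),
      c_bottleneck = c_bj, c_n_fragments = sum(rows),
      c_total_score = sum(sup$score[rows]),
      c_frac_junctions_expressed = n_expr / np,
      c_full_chain = as.numeric(full),
      c_best_frag_score = best_score, c_best_frag_frac = best_frac,
      c_n_junctions_expressed = n_expr,
      c_library_size = as.numeric(lib_size[cc] %||% 0),
      c_bj_rank = NA_real_,  # filled once all eligible cells are known
      cand_merging_score = candidate$F)
  }
  for (cc in eligible) {
    cell_rows[[cc]]["c_bj_rank"] <- mean(cell_bjs <= cell_bjs[cc])
    cell_rows[[cc]] <- cell_rows[[cc]][CELL_FEATURES]
  }
  list(general = general, cells = cell_rows, eligible = eligible)
}

#' Assemble the feature matrix for a candidate set
#'
#' In `"general"` mode, one row per candidate with the 30 general features.
#' In `"specific"` mode, one row per eligible (candidate, cell) pair with all
#' 51 features (30 general + 21 cell-specific); a pair is eligible when at
#' least one junction of the candidate occurs in some fragment of the cell.
#'
#' @param candidates result of [search_all()]
#' @param index a `fragment_index`
#' @param mode `"general"` or `"specific"`
#' @return data.frame with id columns `candidate_id`, `cell` (`NA` in
#'   general mode), `chrom`, `chain_key`, followed by the feature columns;
#'   attribute `schema` records the schema version
#' @export
assemble_feature_matrix <- function(candidates, index,
                                    mode = c("general", "specific")) {
  mode <- match.arg(mode)
  fcols <- if (mode == "general") GENERAL_FEATURES else
    c(GENERAL_FEATURES, CELL_FEATURES)
  info <- list(); feats <- list()
  for (cand in candidates) {
    rows <- candidate_feature_rows(cand, index)
    if (mode == "general") {
      info[[length(info) + 1L]] <- data.frame(
        candidate_id = cand$id, cell = NA_character_, chrom = cand$chrom,
        chain_key = cand$key, stringsAsFactors = FALSE)
      feats[[length(feats) + 1L]] <- rows$general
    } else {
      for (cc in rows$eligible) {
        info[[length(info) + 1L]] <- data.frame(
          candidate_id = cand$id, cell = cc, chrom = cand$chrom,
          chain_key = cand$key, stringsAsFactors = FALSE)
        feats[[length(feats) + 1L]] <- c(rows$general, rows$cells[[cc]])
      }
    }
  }
  if (length(info) == 0L) {
    out <- cbind(data.frame(candidate_id = character(0),
                            cell = character(0), chrom = character(0),
                            chain_key = character(0)),
                 as.data.frame(matrix(numeric(0), 0L, length(fcols),
                                      dimnames = list(NULL, fcols))))
  } else {
    fm <- do.call(rbind, feats)
    colnames(fm) <- fcols
    out <- cbind(do.call(rbind, info), as.data.frame(fm))
    rownames(out) <- NULL
  }
  stopifnot(all(is.finite(as.matrix(out[fcols]))))
  attr(out, "schema") <- FEATURE_SCHEMA_VERSION
  out
}

#' Write a feature table as TSV
#' @param features result of [assemble_feature_matrix()]
#' @param path output TSV
#' @export
write_feature_tsv <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# schema=", attr(features, "schema")), con)
  utils::write.table(features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
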