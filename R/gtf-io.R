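#' Read one cell's scored transcript assembly from GTF
#'
#' Loads the exon records of a per-cell assembly (Ensembl GTF dialect,
#' `gene_id`/`transcript_id` attributes mandatory) into transcript fragments.
#' Each transcript must carry a numeric confidence score in a transcript
#' attribute (default `"cov"`); if any score falls outside \[0, 1\] the whole
#' cell is min-max normalised (`(x - min) / (max - min)`) so scores are
#' comparable across assemblers that report raw coverages. Single-exon
#' transcripts are discarded (and counted), because the method extends
#' fragments by their splice junctions and a transcript without junctions
#' cannot take part in chain merging.
#'
#' @param path GTF file path
#' @param cell_id cell identifier; defaults to the file name without extension
#' @param score_attribute name of the transcript attribute holding the score
#' @param normalize if `TRUE` (default), apply per-cell min-max normalisation
#'   when scores fall outside \[0, 1\]; if `FALSE`, out-of-range scores are an
#'   error
#' @return a `cell_assembly`: list with `cell`, `fragments` (each fragment a
#'   list with `id`, `cell`, `chrom`, `strand`, `exons` matrix, `score`,
#'   `chain`), and `n_single_exon`, the number of discarded transcripts
#' @export
read_cell_gtf <- function(path, cell_id = NULL,
                          score_attribute = "cov", normalize = TRUE) {
  if (is.null(cell_id)) cell_id <- sub("\\.[^.]*$", "", basename(path))
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) {
    return(structure(list(cell = cell_id, fragments = list(),
                          n_single_exon = 0L),
                     class = "cell_assembly"))
  }
  if (!"transcript_id" %in% names(mc)) {
    stop("GTF '", path, "' has no transcript_id attribute")
  }
  exon <- gr[mc$type == "exon"]
  if (length(exon) == 0L) {
    return(structure(list(cell = cell_id, fragments = list(),
                          n_single_exon = 0L),
                     class = "cell_assembly"))
  }
  tx_of <- as.character(S4Vectors::mcols(exon)$transcript_id)

  # transcript-level score: first non-NA value of the attribute over all
  # records of the transcript (assemblers differ in where they put it);
  # score_attribute = NULL loads unscored transcripts (reference mode) as 1
  if (is.null(score_attribute)) {
    scores <- stats::setNames(as.list(rep(1, length(unique(tx_of)))),
                              unique(tx_of))
  } else {
    if (!score_attribute %in% names(mc)) {
      stop("score attribute '", score_attribute, "' absent from '", path, "'")
    }
    score_all <- suppressWarnings(
      as.numeric(as.character(mc[[score_attribute]])))
    tx_all <- as.character(mc$transcript_id)
    first_score <- tapply(score_all, tx_all, function(v) v[!is.na(v)][1L])
    if (anyNA(first_score)) {
      stop("transcript(s) without numeric '", score_attribute, "' in '",
           path, "': ",
           paste(utils::head(names(first_score)[is.na(first_score)], 3L),
                 collapse = ", "))
    }
    scores <- normalize_scores(first_score, normalize, path)
  }

  chroms <- as.character(GenomicRanges::seqnames(exon))
  strands <- as.character(GenomicRanges::strand(exon))
  strands[strands == "*"] <- "."
  starts <- GenomicRanges::start(exon)
  ends <- GenomicRanges::end(exon)

  fragments <- list()
  n_single <- 0L
  for (tx in unique(tx_of)) {
    i <- which(tx_of == tx)
    ex <- collapse_exons(starts[i], ends[i], tx)
    if (nrow(ex) < 2L) { n_single <- n_single + 1L; next }
    frag <- list(id = tx, cell = cell_id,
                 chrom = chroms[i[1L]], strand = strands[i[1L]],
                 exons = ex, score = unname(scores[[tx]]))
    frag$chain <- intron_chain_of(frag)
    fragments[[length(fragments) + 1L]] <- frag
  }
  structure(list(cell = cell_id, fragments = fragments,
                 n_single_exon = n_single),
            class = "cell_assembly")
}

# Cheap structural scan so malformed lines are reported with their number;
# full parsing is rtracklayer's job.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, " in '", path,
         "': expected 9 tab-separated fields, found ", nf[nf < 9L][1L])
  }
  invisible(TRUE)
}

normalize_scores <- function(scores, normalize, path) {
  v <- as.numeric(scores)
  if (any(v < 0 | v > 1)) {
    if (!normalize) {
      stop("scores outside [0, 1] in '", path,
           "' and normalisation disabled")
    }
    rng <- range(v)
    v <- if (rng[1L] == rng[2L]) rep(1, length(v)) else
      (v - rng[1L]) / (rng[2L] - rng[1L])
  }
  stats::setNames(as.list(pmin(pmax(v, 0), 1)), names(scores))
}

# Sort, drop duplicate exon records, merge bookended exons, reject overlaps.
collapse_exons <- function(starts, ends, tx) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  keep <- !duplicated(cbind(starts, ends))
  starts <- starts[keep]; ends <- ends[keep]
  out_s <- starts[1L]; out_e <- ends[1L]
  if (length(starts) > 1L) {
    for (k in 2:length(starts)) {
      last <- length(out_e)
      if (starts[k] <= out_e[last]) {
        stop("overlapping exons within transcript '", tx, "'")
      }
      if (starts[k] == out_e[last] + 1L) {
        out_e[last] <- ends[k]            # bookended: one contiguous exon
      } else {
        out_s <- c(out_s, starts[k]); out_e <- c(out_e, ends[k])
      }
    }
  }
  cbind(start = as.integer(out_s), end = as.integer(out_e))
}

#' Read all per-cell GTFs from a directory
#'
#' @param dir directory containing one `.gtf` file per cell; the file name
#'   (without extension) is the cell id
#' @inheritParams read_cell_gtf
#' @return list of `cell_assembly` objects, named by cell id
#' @export
read_cell_gtfs <- function(dir, score_attribute = "cov", normalize = TRUE) {
  paths <- sort(list.files(dir, pattern = "\\.gtf$", full.names = TRUE))
  if (length(paths) == 0L) stop("no .gtf files in '", dir, "'")
  out <- lapply(paths, read_cell_gtf, score_attribute = score_attribute,
                normalize = normalize)
  stats::setNames(out, vapply(out, `[[`, "", "cell"))
}

#' Read a reference annotation's multi-exon intron chains
#'
#' @param path reference GTF
#' @return data.frame with one row per multi-exon transcript: `transcript_id`,
#'   `chrom`, `strand`, `n_junctions`, and the canonical `chain_key`
#' @export
read_reference_chains <- function(path) {
  asm <- read_cell_gtf(path, cell_id = "__ref__", score_attribute = NULL)
  frs <- asm$fragments
  data.frame(
    transcript_id = vapply(frs, `[[`, "", "id"),
    chrom = vapply(frs, `[[`, "", "chrom"),
    strand = vapply(frs, `[[`, "", "strand"),
    n_junctions = vapply(frs, function(f) chain_len(f$chain), 0L),
    chain_key = vapply(frs, function(f) chain_key(f$chrom, f$strand, f$chain),
                       ""),
    stringsAsFactors = FALSE)
}

#' Write a scored per-cell assembly as GTF
#'
#' Each transcript is written with `gene_id`, `transcript_id`, `cell_id` and a
#' `prob` attribute carrying its per-cell expression probability. Records are
#' grouped by chromosome, then transcript start. The file round-trips through
#' [read_cell_gtf()] with `score_attribute = "prob"`.
#'
#' @param assembly list with `cell` and `transcripts`, each transcript a list
#'   with `id`, `chrom`, `strand`, `exons` and `score` in \[0, 1\] (see
#'   [score_cells()])
#' @param path output file
#' @export
write_scored_gtf <- function(assembly, path) {
  txs <- assembly$transcripts
  probs <- vapply(txs, `[[`, 0, "score")
  if (length(txs) && any(probs < 0 | probs > 1)) {
    stop("transcript probabilities must lie in [0, 1]")
  }
  write_transcripts_gtf(
    txs, path, score_attr = "prob",
    extra = list(cell_id = rep(assembly$cell %||% "NA", length(txs))),
    header = paste0("# txfuse scored assembly; cell=",
                    assembly$cell %||% "NA", "; transcripts=", length(txs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared GTF writer: `txs` is a list of transcript records (id, chrom, strand,
# exons, score, optional gene). Delegates formatting to rtracklayer.
write_transcripts_gtf <- function(txs, path, score_attr = "cov",
                                  extra = NULL, header = NULL) {
  if (length(txs) == 0L) {
    writeLines(header %||% "# txfuse; 0 transcripts", path)
    return(invisible(path))
  }
  ord <- order(vapply(txs, `[[`, "", "chrom"),
               vapply(txs, function(t) t$exons[1L, 1L], 0L))
  txs <- txs[ord]
  if (!is.null(extra)) extra <- lapply(extra, `[`, ord)

  rows_per_tx <- vapply(txs, function(t) nrow(t$exons) + 1L, 0L)
  rep_tx <- rep(seq_along(txs), rows_per_tx)
  type <- unlist(lapply(rows_per_tx, function(n) c("transcript",
                                                   rep("exon", n - 1L))))
  start <- unlist(lapply(txs, function(t) c(t$exons[1L, 1L], t$exons[, 1L])))
  end <- unlist(lapply(txs, function(t) c(t$exons[nrow(t$exons), 2L],
                                          t$exons[, 2L])))
  strand <- vapply(txs, `[[`, "", "strand")[rep_tx]
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(txs, `[[`, "", "chrom")[rep_tx],
    ranges = IRanges::IRanges(start, end), strand = strand)
  mc <- S4Vectors::DataFrame(
    source = "txfuse", type = type,
    gene_id = vapply(txs, function(t) t$gene %||% t$id, "")[rep_tx],
    transcript_id = vapply(txs, `[[`, "", "id")[rep_tx])
  if (!is.null(extra)) for (nm in names(extra)) mc[[nm]] <- extra[[nm]][rep_tx]
  mc[[score_attr]] <- sprintf("%.6f", vapply(txs, `[[`, 0, "score"))[rep_tx]
  S4Vectors::mcols(gr) <- mc
  tmp <- tempfile(fileext = ".gtf")
  rtracklayer::export(gr, tmp, format = "gtf")
  lines <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  lines <- lines[!startsWith(lines, "#")]
  writeLines(c(header %||% "# txfuse", lines), path)
  invisible(path)
}
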