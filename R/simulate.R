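# Synthetic data -----------------------------------------------------------
#
# Emulates, at desk scale, the structure of per-cell short-read assemblies:
# a planted multi-isoform annotation whose isoforms share junctions, per-cell
# expression with dropout, fragmentation of expressed transcripts into
# overlapping sub-chains with incomplete terminal exons, truth-correlated
# noisy confidence scores, and decoy fragments carrying conflicting
# junctions. Genes rotate over chromosomes 1..n_chroms so both sides of the
# chromosome 1-9 train/test split are populated.

#' Simulation configuration
#'
#' @param n_genes number of genes
#' @param n_cells number of cells
#' @param isoforms_per_gene inclusive range of isoforms per gene
#' @param exons_per_isoform inclusive range of exons per isoform
#' @param expression_prob probability that a given isoform is expressed in a
#'   given cell
#' @param frag_lambda Poisson rate for extra fragments per expressed
#'   transcript (a transcript is cut into `1 + Pois(frag_lambda)` pieces,
#'   capped by its junction count)
#' @param overlap_range inclusive range of junction overlap between
#'   consecutive fragments of one transcript (minimum 1, otherwise the true
#'   chain could not be rebuilt as a graph path)
#' @param dropout_prob probability that a fragment is lost
#' @param decoy_rate expected decoy fragments per true fragment
#' @param signal_range uniform range of the score signal for true fragments
#' @param noise_sd Gaussian score noise (scores are clamped to \[0, 1\])
#' @param decoy_score_range uniform score range for decoy fragments
#' @param n_chroms chromosomes to rotate genes over
#' @param seed RNG seed; a fixed seed reproduces byte-identical output
#' @export
sim_config <- function(n_genes = 50, n_cells = 10,
                       isoforms_per_gene = c(2L, 4L),
                       exons_per_isoform = c(3L, 8L),
                       expression_prob = 0.3,
                       frag_lambda = 1.2,
                       overlap_range = c(1L, 2L),
                       dropout_prob = 0.1,
                       decoy_rate = 0.15,
                       signal_range = c(0.4, 0.9),
                       noise_sd = 0.1,
                       decoy_score_range = c(0.05, 0.5),
                       n_chroms = 18L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$expression_prob >= 0, cfg$expression_prob <= 1,
            cfg$dropout_prob >= 0, cfg$dropout_prob <= 1,
            cfg$overlap_range[1L] >= 1L)
  structure(cfg, class = "sim_config")
}

rint <- function(rng) if (rng[1L] == rng[2L]) rng[1L] else
  sample(seq.int(rng[1L], rng[2L]), 1L)

#' Simulate a planted multi-isoform annotation
#'
#' Each gene gets a pool of exon "slots" with shared boundaries; isoforms are
#' ordered slot subsets forced to share one anchor junction, so distinct
#' isoforms of a gene overlap in junctions (the regime that exercises
#' compatibility checks) while slot skipping creates conflicting junctions.
#'
#' @param config a [sim_config()]
#' @return list with `isoforms` (each: `id`, `gene`, `chrom`, `strand`,
#'   `exons`, `chain`, `chain_key`) and `chain_keys`, the registry of all
#'   annotated chains
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed)
  isoforms <- list()
  for (g in seq_len(config$n_genes)) {
    chrom <- as.character(((g - 1L) %% config$n_chroms) + 1L)
    base <- 100000L + ((g - 1L) %/% config$n_chroms) * 100000L
    strand <- sample(c("+", "-"), 1L)
    n_slots <- max(config$exons_per_isoform[2L] + 2L, 8L)
    widths <- sample(80:300, n_slots, replace = TRUE)
    gaps <- sample(100:1000, n_slots - 1L, replace = TRUE)
    starts <- base + cumsum(c(0L, widths[-n_slots] + gaps))
    slots <- cbind(start = starts, end = starts + widths - 1L)
    anchor <- sample(seq_len(n_slots - 1L), 1L)   # slot pair in every isoform

    n_iso <- rint(config$isoforms_per_gene)
    seen <- character(0)
    for (k in seq_len(n_iso)) {
      for (try in 1:20) {
        size <- max(2L, rint(config$exons_per_isoform))
        pick <- sort(unique(c(anchor, anchor + 1L,
                              sample(n_slots, min(size, n_slots)))))
        sig <- paste(pick, collapse = ",")
        if (!sig %in% seen) { seen <- c(seen, sig); break }
        pick <- NULL
      }
      if (is.null(pick)) next
      ex <- slots[pick, , drop = FALSE]
      iso <- list(id = sprintf("iso_g%04d_%02d", g, k),
                  gene = sprintf("gene_%04d", g),
                  chrom = chrom, strand = strand, exons = ex, score = 1)
      iso$chain <- intron_chain_of(iso)
      iso$chain_key <- chain_key(chrom, strand, iso$chain)
      isoforms[[length(isoforms) + 1L]] <- iso
    }
  }
  # slot-subset isoforms of one gene can coincide in chain when terminal
  # slots differ but junctions agree; keep one representative per chain
  isoforms <- isoforms[!duplicated(vapply(isoforms, `[[`, "", "chain_key"))]
  list(isoforms = isoforms,
       chain_keys = vapply(isoforms, `[[`, "", "chain_key"))
}

# cut a chain of L junctions into m overlapping windows [s_i, e_i]
fragment_windows <- function(L, m, overlap_range) {
  m <- min(m, L)
  if (m == 1L) return(cbind(1L, L))
  e <- unique(pmin(L, ceiling(seq_len(m) * L / m)))
  m <- length(e)
  s <- integer(m); s[1L] <- 1L
  for (i in seq_len(m - 1L)) {
    ov <- rint(overlap_range)
    # start inside the previous window so >= 1 junction is shared
    s[i + 1L] <- min(e[i], max(s[i] + 1L, e[i] - ov + 1L))
  }
  cbind(s, e)
}

# exon matrix of a fragment covering junction window [s, e] of an isoform,
# with randomly truncated terminal exons (incomplete fragment ends)
fragment_exons <- function(iso, s, e) {
  ex <- iso$exons[s:(e + 1L), , drop = FALSE]
  w1 <- ex[1L, 2L] - ex[1L, 1L]
  wn <- ex[nrow(ex), 2L] - ex[nrow(ex), 1L]
  ex[1L, 1L] <- ex[1L, 1L] + sample.int(max(1L, w1 %/% 2L), 1L) - 1L
  ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - sample.int(max(1L, wn %/% 2L), 1L) + 1L
  ex
}

#' Simulate per-cell truths and fragmented, scored input assemblies
#'
#' Each expressed (isoform, cell) is cut into fragments whose chains are
#' contiguous sub-chains overlapping their neighbours by at least one
#' junction, so with no dropout the true chain is reconstructible as a graph
#' path. Fragments are lost with `dropout_prob`; scores are a truth-correlated
#' signal plus Gaussian noise, clamped to \[0, 1\]. Decoy fragments, built by
#' displacing one acceptor of a real sub-chain to a non-annotated position,
#' are injected at `decoy_rate` and carry low scores.
#'
#' @param annotation result of [simulate_annotation()]
#' @param config the same [sim_config()]
#' @return list with `assemblies` (list of `cell_assembly`) and
#'   `truth_by_cell` (named list: cell -> expressed chain keys)
#' @export
simulate_cells <- function(annotation, config) {
  set.seed(config$seed + 1L)
  cells <- sprintf("cell%03d", seq_len(config$n_cells))
  assemblies <- list()
  truth_by_cell <- list()
  for (cc in cells) {
    frags <- list()
    truth <- character(0)
    n_true <- 0L
    for (iso in annotation$isoforms) {
      if (stats::runif(1) >= config$expression_prob) next
      truth <- c(truth, iso$chain_key)
      L <- chain_len(iso$chain)
      m <- 1L + min(stats::rpois(1L, config$frag_lambda), L - 1L)
      win <- fragment_windows(L, m, config$overlap_range)
      for (r in seq_len(nrow(win))) {
        if (stats::runif(1) < config$dropout_prob) next
        n_true <- n_true + 1L
        ex <- fragment_exons(iso, win[r, 1L], win[r, 2L])
        score <- min(1, max(0, stats::runif(1, config$signal_range[1L],
                                            config$signal_range[2L]) +
                              stats::rnorm(1, 0, config$noise_sd)))
        frag <- list(id = sprintf("%s_f%02d", iso$id, r), cell = cc,
                     chrom = iso$chrom, strand = iso$strand,
                     exons = ex, score = score)
        frag$chain <- intron_chain_of(frag)
        frags[[length(frags) + 1L]] <- frag
      }
    }
    n_decoy <- stats::rpois(1L, config$decoy_rate * max(1L, n_true))
    for (dk in seq_len(n_decoy)) {
      decoy <- make_decoy(annotation, config, cc, dk)
      if (!is.null(decoy)) frags[[length(frags) + 1L]] <- decoy
    }
    assemblies[[cc]] <- structure(
      list(cell = cc, fragments = frags, n_single_exon = 0L),
      class = "cell_assembly")
    truth_by_cell[[cc]] <- unique(truth)
  }
  list(assemblies = assemblies, truth_by_cell = truth_by_cell)
}

# sub-chain of a random isoform with one acceptor displaced into its intron:
# overlaps the real junction's interval without matching it (a conflict)
make_decoy <- function(annotation, config, cell, k) {
  iso <- annotation$isoforms[[sample(length(annotation$isoforms), 1L)]]
  L <- chain_len(iso$chain)
  if (L < 2L) return(NULL)
  s <- sample(L - 1L, 1L); e <- min(L, s + rint(c(1L, 2L)))
  ex <- iso$exons[s:(e + 1L), , drop = FALSE]
  j <- sample(nrow(ex) - 1L, 1L)           # displace acceptor of junction j
  shift <- sample(10:40, 1L)
  if (ex[j + 1L, 1L] - shift <= ex[j, 2L] + 1L) return(NULL)
  ex[j + 1L, 1L] <- ex[j + 1L, 1L] - shift
  frag <- list(id = sprintf("decoy_%s_%03d", cell, k), cell = cell,
               chrom = iso$chrom, strand = iso$strand, exons = ex,
               score = stats::runif(1, config$decoy_score_range[1L],
                                    config$decoy_score_range[2L]))
  frag$chain <- intron_chain_of(frag)
  frag
}

#' Write a simulated scene to disk as a self-contained fixture
#'
#' Produces `ref.gtf` (the planted annotation), `cells/<cell>.gtf` (scored
#' per-cell inputs, `cov` attribute), `truth.tsv` (cell id, chain key) and
#' `config.json` (the configuration echo).
#'
#' @param scene result of [simulate_cells()]
#' @param annotation result of [simulate_annotation()]
#' @param config the [sim_config()] used
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(scene, annotation, config, dir) {
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  write_transcripts_gtf(annotation$isoforms, file.path(dir, "ref.gtf"),
                        score_attr = "cov",
                        header = "# txfuse synthetic reference annotation")
  for (asm in scene$assemblies) {
    write_transcripts_gtf(asm$fragments,
                          file.path(dir, "cells", paste0(asm$cell, ".gtf")),
                          score_attr = "cov",
                          header = paste0("# txfuse synthetic assembly ",
                                          asm$cell))
  }
  truth <- do.call(rbind, lapply(names(scene$truth_by_cell), function(cc) {
    keys <- scene$truth_by_cell[[cc]]
    if (length(keys) == 0L) return(NULL)
    data.frame(cell = cc, chain_key = keys, stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) truth <- data.frame(cell = character(0),
                                          chain_key = character(0))
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a fixture's per-cell truth table
#' @param path `truth.tsv` written by [write_fixture()]
#' @return named list: cell id -> character vector of chain keys
#' @export
read_truth_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(list())
  split(tab$chain_key, tab$cell)
}

#' Generate a standard end-to-end fixture
#'
#' Scales: `tiny` (3 genes x 3 cells, unit tests), `small` (50 genes x 10
#' cells, integration), `medium` (300 genes x 30 cells, full-pipeline runs).
#' All scales rotate genes over 18 chromosomes so training (1-9) and held-out
#' chromosomes are both populated.
#'
#' @param scale `"tiny"`, `"small"` or `"medium"`
#' @param dir optional directory; when given, the fixture is written there
#'   via [write_fixture()]
#' @param seed RNG seed
#' @param ... overrides passed to [sim_config()]
#' @return list with `config`, `annotation`, `assemblies`, `truth_by_cell`
#'   and `dir` (or `NULL`)
#' @export
make_end_to_end_fixture <- function(scale = c("tiny", "small", "medium"),
                                    dir = NULL, seed = 1L, ...) {
  scale <- match.arg(scale)
  dims <- switch(scale,
                 tiny = c(3L, 3L), small = c(50L, 10L), medium = c(300L, 30L))
  config <- sim_config(n_genes = dims[1L], n_cells = dims[2L],
                       seed = seed, ...)
  annotation <- simulate_annotation(config)
  scene <- simulate_cells(annotation, config)
  if (!is.null(dir)) write_fixture(scene, annotation, config, dir)
  list(config = config, annotation = annotation,
       assemblies = scene$assemblies, truth_by_cell = scene$truth_by_cell,
       dir = dir)
}
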