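#' Path search parameters
#'
#' `pn` caps the number of highest merging-score paths kept per vertex during
#' the dynamic program and `pc` caps the number of paths reported per
#' connected component. Both are the method's efficiency heuristic: the
#' merging-score is not prefix-monotone, so capping can in principle discard
#' a path that would later become optimal; the defaults trade that risk for
#' speed. Use `Inf` to disable a cap.
#'
#' @param pn paths kept per vertex (default 15)
#' @param pc paths kept per component (default 100)
#' @export
search_params <- function(pn = 15, pc = 100) {
  stopifnot(pn >= 1, pc >= 1)
  structure(list(pn = pn, pc = pc), class = "search_params")
}

# All fragments compatible with the path chain, plus a logical matrix saying
# which path junctions each compatible fragment contains. `cell` restricts
# the fragment set to one cell. Results are memoised per chain on the
# (immutable) index, since the dynamic program and the feature extractor
# revisit the same chains many times.
path_support <- function(chrom, strand, chain, index, cell = NULL) {
  key <- chain_key(chrom, strand, chain)
  full <- index$support_cache[[key]]
  if (is.null(full)) {
    keys <- junction_keys(chrom, strand, chain)
    cand <- unique(unlist(lapply(keys, function(k) index$by_junction[[k]])))
    np <- chain_len(chain)
    pd <- chain_donors(chain); pa <- chain_acceptors(chain)
    keep <- logical(length(cand))
    contains <- matrix(FALSE, length(cand), np)
    for (r in seq_along(cand)) {
      i <- cand[r]
      res <- compat_da(index$fd[[i]], index$fa[[i]], pd, pa)
      keep[r] <- res$compatible
      contains[r, ] <- res$contains
    }
    full <- list(frag_idx = cand[keep], cell = index$cell[cand[keep]],
                 score = index$score[cand[keep]],
                 contains = contains[keep, , drop = FALSE])
    index$support_cache[[key]] <- full
  }
  if (is.null(cell)) return(full)
  rows <- full$cell == cell
  list(frag_idx = full$frag_idx[rows], cell = full$cell[rows],
       score = full$score[rows],
       contains = full$contains[rows, , drop = FALSE])
}

#' Junction scores of a candidate path
#'
#' For every junction j of the path, J(j, p) is the total score of all
#' transcript fragments (across all cells, or one cell if `cell` is given)
#' that contain j and are compatible with the path.
#'
#' @param chrom,strand,chain path location and intron chain
#' @param index a `fragment_index`
#' @param cell optional cell id restricting the supporting fragments
#' @return numeric vector, one score per path junction
#' @export
junction_scores <- function(chrom, strand, chain, index, cell = NULL) {
  sup <- path_support(chrom, strand, chain, index, cell)
  as.numeric(colSums(sup$contains * sup$score))
}

#' Score of a single junction within a path
#' @param j 1-based junction position within the path chain
#' @inheritParams junction_scores
#' @export
junction_score <- function(j, chrom, strand, chain, index, cell = NULL) {
  np <- chain_len(chain)
  if (j < 1L || j > np) stop("junction position ", j, " not in path")
  junction_scores(chrom, strand, chain, index, cell)[j]
}

#' Merging-score of a path chain
#'
#' F(p) = BJ(p) x NJ(p): the bottleneck junction score (minimum J(j, p) over
#' the path's junctions) times the number of junctions. The product rewards
#' both consistent junction support and extension into longer chains.
#'
#' @inheritParams junction_scores
#' @return list with `F`, `BJ` (bottleneck) and `NJ` (junction count)
#' @export
merging_score <- function(chrom, strand, chain, index) {
  js <- junction_scores(chrom, strand, chain, index)
  bj <- if (length(js)) min(js) else 0
  list(F = bj * length(js), BJ = bj, NJ = length(js))
}

# total deterministic ranking: F desc, NJ desc, chain lexicographic asc
rank_paths <- function(paths) {
  order(-vapply(paths, `[[`, 0, "F"),
        -vapply(paths, `[[`, 0L, "NJ"),
        vapply(paths, function(p) chain_sort_key(p$chain), ""))
}

#' Enumerate high merging-score paths in one component
#'
#' Processes vertices in topological order. Every vertex seeds its own
#' single-vertex path; paths kept at a predecessor are extended along each
#' incoming edge, and the merging-score of each extension is recomputed from
#' scratch on the merged chain (compatibility of fragments can change as the
#' chain grows, so incremental scores would be wrong). At most `pn` paths are
#' kept per vertex and the `pc` best are returned for the component.
#'
#' @param component a `fragment_graph` component
#' @param params a [search_params()] object
#' @param index the `fragment_index` (defaults to the component's own)
#' @return list of paths, each with `vidx` (vertex positions within the
#'   component, in path order), `overlaps`, `chain`, `F`, `BJ`, `NJ`
#' @export
search_component <- function(component, params = search_params(),
                             index = component$index) {
  vs <- component$vertices
  topo <- topological_order(component)
  chrom <- vs[[1L]]$chrom; strand <- vs[[1L]]$strand
  incoming <- split(seq_len(nrow(component$edges)), component$edges$to)
  kept <- vector("list", length(vs))

  score_path <- function(vidx, overlaps, chain) {
    ms <- merging_score(chrom, strand, chain, index)
    list(vidx = vidx, overlaps = overlaps, chain = chain,
         F = ms$F, BJ = ms$BJ, NJ = ms$NJ)
  }

  # The same merged chain is often reachable through several vertex routes
  # (windows of one transcript at different granularities). When a trim is
  # needed, such duplicates are identical candidates and would waste cap
  # slots, so keep one representative per chain — chosen input-order
  # independently (fewest vertices, then sorted constituent chain keys) —
  # before applying the cap. Without a trim the full path set is preserved,
  # which keeps the uncapped search identical to exhaustive enumeration.
  trim <- function(paths, cap) {
    if (length(paths) <= cap) return(paths)
    ck <- vapply(paths, function(p) paste(p$chain, collapse = ","), "")
    if (anyDuplicated(ck)) {
      nv <- vapply(paths, function(p) length(p$vidx), 0L)
      sig <- vapply(paths, function(p)
        paste(sort(vapply(vs[p$vidx], `[[`, "", "key")), collapse = ";"), "")
      reps <- vapply(split(seq_along(paths), ck), function(ix)
        ix[order(nv[ix], sig[ix])][1L], 0L)
      paths <- paths[sort(reps)]
    }
    o <- rank_paths(paths)
    paths[o[seq_len(min(cap, length(o)))]]
  }

  for (v in topo) {
    paths <- list(score_path(v, integer(0), vs[[v]]$chain))
    for (ei in incoming[[as.character(v)]]) {
      u <- component$edges$from[ei]
      k <- component$edges$overlap[ei]
      for (p in kept[[u]]) {
        paths[[length(paths) + 1L]] <- score_path(
          c(p$vidx, v), c(p$overlaps, k),
          merge_chains(p$chain, vs[[v]]$chain, k))
      }
    }
    kept[[v]] <- trim(paths, params$pn)
  }

  all_paths <- unlist(kept, recursive = FALSE)
  if (length(all_paths) > params$pc) {
    all_paths <- trim(all_paths, params$pc)
  }
  all_paths[rank_paths(all_paths)]
}

#' Search all components and assemble the global candidate set
#'
#' Runs [search_component()] per weak component, then deduplicates candidate
#' chains globally, keeping the highest-scoring instance of each chain.
#' Terminal exon coordinates of a candidate are the extremes observed among
#' supporting fragments of its first and last constituent vertex, preserving
#' all observed exonic sequence at the (possibly incomplete) transcript ends.
#'
#' @param graph a `fragment_graph` from [build_graph()]
#' @param params a [search_params()] object
#' @return list of candidates; each has `id`, `chrom`, `strand`, `chain`,
#'   `key`, `exons`, `F`, `BJ`, `NJ`, `component`, `vertices` (constituent
#'   vertex objects in path order) and `overlaps`
#' @export
search_all <- function(graph, params = search_params()) {
  comps <- connected_components(graph)
  cands <- list()
  for (ci in seq_along(comps)) {
    comp <- comps[[ci]]
    for (p in search_component(comp, params, graph$index)) {
      verts <- comp$vertices[p$vidx]
      cands[[length(cands) + 1L]] <- list(
        chrom = verts[[1L]]$chrom, strand = verts[[1L]]$strand,
        chain = p$chain,
        key = chain_key(verts[[1L]]$chrom, verts[[1L]]$strand, p$chain),
        F = p$F, BJ = p$BJ, NJ = p$NJ,
        component = ci, vertices = verts, overlaps = p$overlaps)
    }
  }
  if (length(cands) == 0L) return(list())
  # Global dedup: one instance per distinct chain. Score ties are exact for a
  # repeated chain (F is recomputed from the chain alone), so pick the
  # representative by an input-order-independent signature: fewest constituent
  # vertices, then the sorted constituent chain keys.
  keys <- vapply(cands, `[[`, "", "key")
  nv <- vapply(cands, function(cc) length(cc$vertices), 0L)
  sig <- vapply(cands, function(cc)
    paste(sort(vapply(cc$vertices, `[[`, "", "key")), collapse = ";"), "")
  reps <- vapply(split(seq_along(cands), keys), function(ix)
    ix[order(nv[ix], sig[ix])][1L], 0L)
  cands <- cands[sort(reps)]
  cands <- cands[rank_paths(cands)]
  frags <- graph$index$fragments
  for (i in seq_along(cands)) {
    cand <- cands[[i]]
    first_sup <- cand$vertices[[1L]]$supports$frag_idx
    last_sup <- cand$vertices[[length(cand$vertices)]]$supports$frag_idx
    start <- min(vapply(frags[first_sup],
                        function(f) f$exons[1L, 1L], 0L))
    end <- max(vapply(frags[last_sup],
                      function(f) f$exons[nrow(f$exons), 2L], 0L))
    cand$exons <- exons_from_chain(cand$chain, start, end)
    cand$id <- sprintf("cand_%05d", i)
    cands[[i]] <- cand
  }
  cands
}

# Rebuild the exon matrix of a chain given terminal exon boundaries.
exons_from_chain <- function(chain, first_start, last_end) {
  n <- chain_len(chain)
  d <- chain[seq(1L, by = 2L, length.out = n)]
  a <- chain[seq(2L, by = 2L, length.out = n)]
  cbind(start = as.integer(c(first_start, a)),
        end = as.integer(c(d, last_end)))
}

#' Export a candidate set as GTF plus a TSV sidecar
#'
#' @param candidates result of [search_all()]
#' @param gtf_path,tsv_path output files
#' @export
export_candidates <- function(candidates, gtf_path, tsv_path = NULL) {
  txs <- lapply(candidates, function(cand) {
    list(id = cand$id, chrom = cand$chrom, strand = cand$strand,
         exons = cand$exons, score = min(1, cand$F / max(1, cand$NJ)),
         gene = sprintf("comp_%05d", cand$component))
  })
  write_transcripts_gtf(txs, gtf_path, score_attr = "fscore",
                        header = "# txfuse candidate transcripts")
  if (!is.null(tsv_path)) {
    sidecar <- data.frame(
      candidate_id = vapply(candidates, `[[`, "", "id"),
      component = vapply(candidates, `[[`, 0L, "component"),
      NJ = vapply(candidates, `[[`, 0L, "NJ"),
      BJ = vapply(candidates, `[[`, 0, "BJ"),
      F = vapply(candidates, `[[`, 0, "F"),
      n_cells = vapply(candidates, function(cand)
        length(unique(unlist(lapply(cand$vertices,
                                    function(v) v$supports$cell)))), 0L),
      fragment_ids = vapply(candidates, function(cand)
        paste(unlist(lapply(cand$vertices, function(v)
          paste(v$supports$cell, v$supports$frag_id, sep = ":"))),
          collapse = ","), ""))
    utils::write.table(sidecar, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(gtf_path)
}
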