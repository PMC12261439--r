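#' Index all fragments of a set of cell assemblies
#'
#' Flattens the per-cell assemblies and builds a junction-keyed lookup so
#' that, for any candidate path, the fragments sharing at least one of its
#' junctions can be retrieved without scanning every cell.
#'
#' @param assemblies list of `cell_assembly` objects
#' @return a `fragment_index`: `fragments` (flat list), `cells` (all cell
#'   ids, including cells that contributed no multi-exon fragment), `cell`
#'   and `score` vectors aligned with `fragments`, and `by_junction`, an
#'   environment mapping junction keys to fragment indices
#' @export
fragment_index <- function(assemblies) {
  frags <- unlist(lapply(assemblies, `[[`, "fragments"), recursive = FALSE)
  cells <- vapply(assemblies, `[[`, "", "cell")
  by_junction <- new.env(parent = emptyenv(), size = max(64L, length(frags)))
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    for (k in junction_keys(f$chrom, f$strand, f$chain)) {
      by_junction[[k]] <- c(by_junction[[k]], i)
    }
  }
  structure(list(
    fragments = frags,
    cells = sort(unname(cells)),
    cell = vapply(frags, `[[`, "", "cell"),
    score = vapply(frags, `[[`, 0, "score"),
    fd = lapply(frags, function(f) chain_donors(f$chain)),
    fa = lapply(frags, function(f) chain_acceptors(f$chain)),
    by_junction = by_junction,
    support_cache = new.env(parent = emptyenv())),
    class = "fragment_index")
}

#' Build the transcript fragment graph
#'
#' One vertex per distinct (chrom, strand, intron chain) across all cells;
#' identical chains from different cells collapse into a single vertex that
#' records every supporting (cell, fragment, score). A directed edge u -> v
#' exists when some suffix of u's chain equals a prefix of v's chain and v
#' extends strictly beyond the overlap, so that concatenation yields a
#' conflict-free longer chain; chains equal to or contained in another chain
#' get no edge. Because every edge strictly extends the chain rightwards the
#' graph is a DAG.
#'
#' @param assemblies list of `cell_assembly` objects
#' @return a `fragment_graph`: `vertices` (each with `chrom`, `strand`,
#'   `chain`, `key`, `supports` data.frame), `edges` data.frame
#'   (`from`, `to`, `overlap`), `comp` component id per vertex, and the
#'   `fragment_index` used to build it
#' @export
build_graph <- function(assemblies) {
  idx <- fragment_index(assemblies)
  frags <- idx$fragments

  keys <- vapply(frags, function(f) chain_key(f$chrom, f$strand, f$chain), "")
  ukeys <- unique(keys)
  vid_of <- match(keys, ukeys)
  vertices <- vector("list", length(ukeys))
  for (v in seq_along(ukeys)) {
    members <- which(vid_of == v)
    f1 <- frags[[members[1L]]]
    sup <- data.frame(
      cell = vapply(frags[members], `[[`, "", "cell"),
      frag_id = vapply(frags[members], `[[`, "", "id"),
      score = vapply(frags[members], `[[`, 0, "score"),
      frag_idx = members, stringsAsFactors = FALSE)
    sup <- sup[order(sup$cell, sup$frag_id), , drop = FALSE]
    vertices[[v]] <- list(chrom = f1$chrom, strand = f1$strand,
                          chain = f1$chain, key = ukeys[v], supports = sup)
  }

  # candidate edge pairs must share a junction; gather them from a
  # junction -> vertex posting list instead of all-pairs comparison
  post <- new.env(parent = emptyenv())
  for (v in seq_along(vertices)) {
    vx <- vertices[[v]]
    for (k in junction_keys(vx$chrom, vx$strand, vx$chain)) {
      post[[k]] <- c(post[[k]], v)
    }
  }
  pair_from <- integer(0); pair_to <- integer(0)
  for (k in ls(post)) {
    vs <- unique(post[[k]])
    if (length(vs) > 1L) {
      g <- expand.grid(from = vs, to = vs)
      g <- g[g$from != g$to, , drop = FALSE]
      pair_from <- c(pair_from, g$from); pair_to <- c(pair_to, g$to)
    }
  }
  if (length(pair_from)) {
    dup <- duplicated(cbind(pair_from, pair_to))
    pair_from <- pair_from[!dup]; pair_to <- pair_to[!dup]
  }
  ef <- integer(0); et <- integer(0); eo <- integer(0)
  for (i in seq_along(pair_from)) {
    u <- vertices[[pair_from[i]]]; v <- vertices[[pair_to[i]]]
    k <- suffix_prefix_overlap(u$chain, v$chain)
    if (k >= 1L) {
      ef <- c(ef, pair_from[i]); et <- c(et, pair_to[i]); eo <- c(eo, k)
    }
  }
  edges <- data.frame(from = ef, to = et, overlap = eo)

  comp <- weak_components(length(vertices), edges)
  structure(list(vertices = vertices, edges = edges, comp = comp,
                 index = idx), class = "fragment_graph")
}

# union-find over undirected edge set
weak_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges$from[i]); b <- find(edges$to[i])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Split a fragment graph into weakly connected components
#'
#' @param graph a `fragment_graph`
#' @return list of `fragment_graph` components; isolated vertices form
#'   singleton components. Each component keeps `orig` (original vertex ids)
#'   and shares the parent's `fragment_index`.
#' @export
connected_components <- function(graph) {
  ids <- sort(unique(graph$comp))
  lapply(ids, function(cid) {
    vs <- which(graph$comp == cid)
    remap <- integer(length(graph$vertices)); remap[vs] <- seq_along(vs)
    e <- graph$edges[graph$edges$from %in% vs & graph$edges$to %in% vs, ,
                     drop = FALSE]
    e$from <- remap[e$from]; e$to <- remap[e$to]
    structure(list(vertices = graph$vertices[vs], edges = e,
                   comp = rep(1L, length(vs)), orig = vs,
                   index = graph$index), class = "fragment_graph")
  })
}

#' Deterministic topological order of a component
#'
#' Because every edge leads from a chain to one extending it on the right,
#' sorting vertices by (first junction donor, first acceptor, chain length,
#' lexicographic chain) is a valid topological order; the sort also makes the
#' order byte-deterministic regardless of input ordering.
#'
#' @param component a `fragment_graph` (one weak component)
#' @return integer vector of vertex positions in topological order
#' @export
topological_order <- function(component) {
  vs <- component$vertices
  o <- order(vapply(vs, function(v) v$chain[1L], 0L),
             vapply(vs, function(v) v$chain[2L], 0L),
             vapply(vs, function(v) chain_len(v$chain), 0L),
             vapply(vs, function(v) chain_sort_key(v$chain), ""),
             vapply(vs, function(v) v$supports$cell[1L], ""))
  pos <- match(seq_along(vs), o)
  bad <- pos[component$edges$from] >= pos[component$edges$to]
  if (any(bad)) stop("internal invariant violated: edge against topological order")
  o
}

#' Export a fragment graph's edges as TSV (debug aid)
#' @param graph a `fragment_graph`
#' @param path output TSV path
#' @export
export_graph_tsv <- function(graph, path) {
  e <- graph$edges
  out <- data.frame(
    source = vapply(graph$vertices[e$from], `[[`, "", "key"),
    target = vapply(graph$vertices[e$to], `[[`, "", "key"),
    overlap_len = e$overlap)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
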