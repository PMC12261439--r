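# In-code fixture builders and independent oracles.

# junction / exon helpers -----------------------------------------------------

# a fragment from an explicit exon matrix
frag <- function(id, cell, exons, score, chrom = "1", strand = "+") {
  f <- list(id = id, cell = cell, chrom = chrom, strand = strand,
            exons = matrix(as.integer(exons), ncol = 2L, byrow = TRUE,
                           dimnames = list(NULL, c("start", "end"))),
            score = score)
  f$chain <- intron_chain_of(f)
  f
}

# a fragment defined directly by its junction list c(d1,a1,d2,a2,...); exons
# are reconstructed with 50 bp terminal flanks
frag_j <- function(id, cell, junctions, score, chrom = "1", strand = "+") {
  j <- as.integer(junctions)
  d <- j[c(TRUE, FALSE)]; a <- j[c(FALSE, TRUE)]
  exons <- cbind(c(d[1L] - 50L, a), c(d, a[length(a)] + 50L))
  frag(id, cell, t(exons), score, chrom, strand)
}

asm <- function(cell, ...) {
  structure(list(cell = cell, fragments = list(...), n_single_exon = 0L),
            class = "cell_assembly")
}

key_of <- function(f) txfuse:::chain_key(f$chrom, f$strand, f$chain)

# standard junction coordinates shared by many tests
J1 <- c(200L, 300L); J2 <- c(400L, 500L); J3 <- c(600L, 700L)
J4 <- c(800L, 900L); J5 <- c(1000L, 1100L)

# independent oracles ----------------------------------------------------------
# Naive re-implementations used to cross-check the package; deliberately
# written as plain double loops with no shared code path.

oracle_junctions <- function(chain) {
  n <- length(chain) / 2
  lapply(seq_len(n), function(i) chain[c(2 * i - 1, 2 * i)])
}

oracle_compatible <- function(frag_chain, path_chain) {
  fj <- oracle_junctions(frag_chain)
  pj <- oracle_junctions(path_chain)
  shared <- FALSE
  for (a in fj) for (b in pj) if (all(a == b)) shared <- TRUE
  if (!shared) return(FALSE)
  for (a in fj) {
    exact <- any(vapply(pj, function(b) all(a == b), TRUE))
    if (exact) next
    for (b in pj) {
      if (a[1] + 1 <= b[2] - 1 && b[1] + 1 <= a[2] - 1) return(FALSE)
    }
  }
  TRUE
}

# merging-score of a chain computed from a flat fragment list
oracle_F <- function(chain, fragments, chrom = "1", strand = "+") {
  pj <- oracle_junctions(chain)
  J <- numeric(length(pj))
  for (f in fragments) {
    if (f$chrom != chrom || f$strand != strand) next
    if (!oracle_compatible(f$chain, chain)) next
    fj <- oracle_junctions(f$chain)
    for (i in seq_along(pj)) {
      for (a in fj) if (all(a == pj[[i]])) J[i] <- J[i] + f$score
    }
  }
  list(F = min(J) * length(J), BJ = min(J), NJ = length(J), J = J)
}

# naive maximal suffix/prefix overlap and chain merge
oracle_merge <- function(a, b) {
  la <- length(a) / 2; lb <- length(b) / 2
  for (k in seq(min(la, lb - 1), 1)) {
    if (k < 1) break
    if (identical(a[seq(2 * (la - k) + 1, 2 * la)], b[seq(1, 2 * k)])) {
      return(c(a, b[seq(2 * k + 1, 2 * lb)]))
    }
  }
  NULL
}

# all directed paths of a component by exhaustive DFS, each scored from
# scratch with oracle_F
oracle_enumerate <- function(component, fragments) {
  nv <- length(component$vertices)
  out_edges <- split(seq_len(nrow(component$edges)), component$edges$from)
  paths <- list()
  grow <- function(vseq, chain) {
    paths[[length(paths) + 1L]] <<- list(vidx = vseq, chain = chain)
    for (ei in out_edges[[as.character(vseq[length(vseq)])]]) {
      to <- component$edges$to[ei]
      merged <- oracle_merge(chain, component$vertices[[to]]$chain)
      if (!is.null(merged)) grow(c(vseq, to), merged)
    }
  }
  for (v in seq_len(nv)) grow(v, component$vertices[[v]]$chain)
  chrom <- component$vertices[[1]]$chrom
  strand <- component$vertices[[1]]$strand
  for (i in seq_along(paths)) {
    sc <- oracle_F(paths[[i]]$chain, fragments, chrom, strand)
    paths[[i]]$F <- sc$F; paths[[i]]$BJ <- sc$BJ; paths[[i]]$NJ <- sc$NJ
  }
  paths
}

# random multi-cell scene whose graph has small, varied components: a few
# master chains over a shared junction pool, cut into random windows
random_scene <- function(seed, n_cells = 3) {
  set.seed(seed)
  n_pool <- sample(4:7, 1)
  donors <- integer(n_pool); acceptors <- integer(n_pool)
  pos <- 100L
  for (i in seq_len(n_pool)) {       # disjoint introns with exon gaps between
    donors[i] <- pos + sample(30:150, 1)
    acceptors[i] <- donors[i] + sample(50:200, 1)
    pos <- acceptors[i]
  }
  masters <- lapply(seq_len(sample(1:2, 1)), function(i) {
    idx <- sort(sample(n_pool, sample(3:n_pool, 1)))
    as.integer(rbind(donors[idx], acceptors[idx]))
  })
  assemblies <- lapply(seq_len(n_cells), function(ci) {
    frs <- list()
    for (m in masters) {
      L <- length(m) / 2
      n_win <- sample(1:3, 1)
      for (w in seq_len(n_win)) {
        s <- sample(L, 1); e <- min(L, s + sample(0:2, 1))
        sub <- m[seq(2 * s - 1, 2 * e)]
        frs[[length(frs) + 1L]] <- frag_j(
          sprintf("f%d_%d_%d", ci, length(frs), w), sprintf("c%d", ci),
          sub, round(runif(1, 0.1, 1), 3))
      }
    }
    structure(list(cell = sprintf("c%d", ci), fragments = frs,
                   n_single_exon = 0L), class = "cell_assembly")
  })
  assemblies
}
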