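#' @keywords internal
"_PACKAGE"

# An intron chain is stored as an integer vector c(d1, a1, d2, a2, ...):
# junction i spans the intron (d_i, a_i) where d_i is the last base of the
# upstream exon and a_i the first base of the downstream exon (1-based GTF
# coordinates). Chains are always handled together with a (chrom, strand)
# pair and junctions are sorted by donor with d_i < a_i - 1.

#' Number of junctions in a chain
#' @param chain integer vector of interleaved donor/acceptor coordinates
#' @return integer count of junctions
#' @keywords internal
chain_len <- function(chain) length(chain) %/% 2L

#' Derive the intron chain of a multi-exon transcript fragment
#'
#' Junction k has donor = end of exon k and acceptor = start of exon k+1.
#'
#' @param fragment a transcript fragment as returned by [read_cell_gtf()]
#' @return integer chain vector with one (donor, acceptor) pair per intron
#' @export
intron_chain_of <- function(fragment) {
  exons <- fragment$exons
  n <- nrow(exons)
  if (n < 2L) stop("intron_chain_of() requires a fragment with >= 2 exons")
  as.integer(rbind(exons[-n, 2L], exons[-1L, 1L]))
}

#' Canonical string key identifying a chain on a (chrom, strand)
#' @keywords internal
chain_key <- function(chrom, strand, chain) {
  paste(chrom, strand, paste(chain, collapse = ","), sep = "|")
}

# donors / acceptors of a chain (donors are strictly increasing, so a donor
# identifies its junction uniquely within one chain)
chain_donors <- function(chain) chain[c(TRUE, FALSE)]
chain_acceptors <- function(chain) chain[c(FALSE, TRUE)]

# Per-junction keys, used for indexing fragments by junction.
junction_keys <- function(chrom, strand, chain) {
  if (length(chain) == 0L) return(character(0))
  paste(chrom, strand, chain_donors(chain), chain_acceptors(chain),
        sep = "|")
}

# Deterministic lexicographic sort key (zero-padded so "9" < "10").
chain_sort_key <- function(chain) {
  paste(sprintf("%011d", chain), collapse = ",")
}

# Maximal k >= 1 such that the last k junctions of `a` equal the first k
# junctions of `b` AND b extends strictly beyond the overlap (k < len(b)).
# Returns 0 when no such k exists. Equal chains yield 0.
suffix_prefix_overlap <- function(a, b) {
  la <- chain_len(a); lb <- chain_len(b)
  for (k in seq(min(la, lb - 1L), 1L)) {
    if (k < 1L) break
    if (identical(a[seq.int(2L * (la - k) + 1L, 2L * la)],
                  b[seq.int(1L, 2L * k)])) {
      return(k)
    }
  }
  0L
}

# TRUE when `small` occurs as a contiguous junction run inside `big`.
chain_contains <- function(big, small) {
  lb <- chain_len(big); ls <- chain_len(small)
  if (ls > lb) return(FALSE)
  for (off in 0:(lb - ls)) {
    if (identical(big[seq.int(2L * off + 1L, 2L * (off + ls))], small)) {
      return(TRUE)
    }
  }
  FALSE
}

# Merge a path chain with the chain of the next vertex given the edge
# overlap k (the vertex chain's first k junctions equal the path's last k).
merge_chains <- function(path_chain, vertex_chain, overlap) {
  c(path_chain, vertex_chain[seq_len(length(vertex_chain) - 2L * overlap) +
                               2L * overlap])
}

#' Test compatibility of a fragment chain with a candidate path chain
#'
#' A fragment is compatible with a path when it shares at least one junction
#' (exact donor/acceptor match) and none of its junctions conflicts with the
#' path. A fragment junction conflicts when it is not itself a path junction
#' but its intron interval overlaps the intron interval of some path
#' junction. Both chains must already be on the same (chrom, strand).
#'
#' @param frag_chain,path_chain integer chain vectors
#' @return logical scalar
#' @export
is_compatible <- function(frag_chain, path_chain) {
  compat_da(chain_donors(frag_chain), chain_acceptors(frag_chain),
            chain_donors(path_chain), chain_acceptors(path_chain))$compatible
}

# Core compatibility test on pre-split donor/acceptor vectors. Returns the
# verdict plus, per path junction, whether the fragment contains it exactly.
compat_da <- function(fd, fa, pd, pa) {
  m <- match(fd, pd)                    # donors are unique within a chain
  exact <- !is.na(m) & fa == pa[m]
  exact[is.na(exact)] <- FALSE
  if (!any(exact)) {
    return(list(compatible = FALSE, contains = logical(length(pd))))
  }
  bad <- which(!exact)
  conflict <- FALSE
  for (i in bad) {
    # intron interval of junction (d, a) is [d + 1, a - 1]
    if (any(fd[i] + 1L <= pa - 1L & fa[i] - 1L >= pd + 1L)) {
      conflict <- TRUE; break
    }
  }
  if (conflict) {
    return(list(compatible = FALSE, contains = logical(length(pd))))
  }
  pm <- match(pd, fd)
  contains <- !is.na(pm) & pa == fa[pm]
  contains[is.na(contains)] <- FALSE
  list(compatible = TRUE, contains = contains)
}
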