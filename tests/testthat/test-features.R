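# Feature hand checks use the four-fragment scene whose merging scores were
# derived by hand in test-path-search.R.

feat_assemblies <- function() list(
  asm("c1", frag_j("tc11", "c1", c(J1, J2), 0.5),
            frag_j("tc12", "c1", c(J3, J4), 0.7)),
  asm("c2", frag_j("tc21", "c2", c(J2, J3), 0.6)),
  asm("c3", frag_j("tc32", "c3", c(J4, J5), 0.8)))

full_candidate <- function(g) {
  cands <- search_all(g)
  keys <- vapply(cands, `[[`, "", "key")
  cands[[which(keys == txfuse:::chain_key("1", "+", c(J1, J2, J3, J4, J5)))]]
}

test_that("summary statistics match hand calculations", {
  s <- txfuse:::stat5(c(0.4, 0.9), "x")
  expect_equal(unname(s), c(0.4, 0.65, 0.65, 0.9, 0.25))
  expect_equal(names(s), c("x_min", "x_median", "x_mean", "x_max", "x_sd"))
  # population sd: a single value has spread zero, empty input gives zeros
  expect_equal(unname(txfuse:::stat5(7, "x")), c(7, 7, 7, 7, 0))
  expect_equal(unname(txfuse:::stat5(numeric(0), "x")), c(0, 0, 0, 0, 0))
})

test_that("general features of the full-length candidate match hand values", {
  g <- build_graph(feat_assemblies())
  cand <- full_candidate(g)
  fm <- assemble_feature_matrix(list(cand), g$index, mode = "general")
  expect_equal(nrow(fm), 1L)
  expect_equal(ncol(fm), 4L + 30L)
  expect_equal(colnames(fm)[5:34], txfuse:::GENERAL_FEATURES)
  r <- fm[1, ]

  js <- c(0.5, 1.1, 1.3, 1.5, 0.8)
  expect_equal(r$js_min, 0.5)
  expect_equal(r$js_median, 1.1)
  expect_equal(r$js_mean, mean(js))
  expect_equal(r$js_max, 1.5)
  expect_equal(r$js_sd, sqrt(mean((js - mean(js))^2)))

  expect_equal(c(r$jcells_min, r$jcells_median, r$jcells_max), c(1, 2, 2))
  expect_equal(r$jcells_mean, mean(c(1, 2, 2, 2, 1)))
  expect_equal(c(r$jfrags_min, r$jfrags_max, r$jfrags_mean), c(1, 2, 1.6))

  expect_equal(r$n_junctions, 5)
  expect_equal(r$bottleneck, 0.5)
  expect_equal(r$merging_score, 2.5)
  expect_equal(r$n_cells_supporting, 3)
  expect_equal(r$prop_cells_supporting, 1)
  expect_equal(r$n_cells_full_chain, 0)
  expect_equal(r$prop_cells_full_chain, 0)
  expect_equal(r$n_vertices, 4)
  expect_equal(r$single_fragment, 0)
  expect_equal(r$longest_fragment_frac, 2 / 5)
  expect_equal(c(r$overlap_min, r$overlap_mean, r$overlap_max), c(1, 1, 1))
  expect_equal(r$total_support_score, 2.6)
  expect_equal(r$n_compatible_fragments, 4)
})

test_that("cell-specific rows cover eligible cells with hand-checked values", {
  g <- build_graph(feat_assemblies())
  cand <- full_candidate(g)
  fm <- assemble_feature_matrix(list(cand), g$index, mode = "specific")
  expect_equal(ncol(fm), 4L + 51L)
  expect_setequal(fm$cell, c("c1", "c2", "c3"))

  r1 <- fm[fm$cell == "c1", ]
  c_js <- c(0.5, 0.5, 0.7, 0.7, 0)       # c1 fragments: tc11, tc12
  expect_equal(r1$c_js_min, 0)
  expect_equal(r1$c_js_max, 0.7)
  expect_equal(r1$c_js_mean, mean(c_js))
  expect_equal(r1$c_bottleneck, 0)
  expect_equal(r1$c_n_fragments, 2)
  expect_equal(r1$c_total_score, 1.2)
  expect_equal(r1$c_n_junctions_expressed, 4)
  expect_equal(r1$c_frac_junctions_expressed, 0.8)
  expect_equal(r1$c_full_chain, 0)
  expect_equal(r1$c_best_frag_score, 0.7)
  expect_equal(r1$c_best_frag_frac, 2 / 5)
  expect_equal(r1$c_library_size, 2)
  expect_equal(r1$cand_merging_score, 2.5)
  # every cell misses at least one junction, so all cell bottlenecks are 0
  expect_equal(fm$c_bj_rank, c(1, 1, 1))
  # general columns are repeated unchanged on each cell row
  expect_equal(unique(fm$merging_score), 2.5)
})

test_that("a cell sharing one junction is eligible, an unrelated cell is not", {
  g <- build_graph(list(
    asm("c1", frag_j("A", "c1", c(J1, J2), 0.5)),
    asm("c2", frag_j("B", "c2", c(J2, J3), 0.5)),
    asm("c3", frag_j("Z", "c3", c(5000L, 5100L), 0.5))))
  cands <- search_all(g)
  fm <- assemble_feature_matrix(cands, g$index, mode = "specific")
  merged_key <- txfuse:::chain_key("1", "+", c(J1, J2, J3))
  expect_setequal(fm$cell[fm$chain_key == merged_key], c("c1", "c2"))
  zkey <- txfuse:::chain_key("1", "+", c(5000L, 5100L))
  expect_equal(fm$cell[fm$chain_key == zkey], "c3")
})

test_that("a full-chain single-vertex candidate has the expected flags", {
  g <- build_graph(list(asm("c1", frag_j("solo", "c1", c(J1, J2), 0.6)),
                        asm("c2", frag_j("solo2", "c2", c(J1, J2), 0.4))))
  cand <- search_all(g)[[1]]
  fm <- assemble_feature_matrix(list(cand), g$index, mode = "general")
  expect_equal(fm$n_vertices, 1)
  expect_equal(fm$single_fragment, 1)
  expect_equal(fm$longest_fragment_frac, 1)
  expect_equal(c(fm$overlap_min, fm$overlap_mean, fm$overlap_max), c(0, 0, 0))
  expect_equal(fm$n_cells_full_chain, 2)
  expect_equal(fm$prop_cells_full_chain, 1)
  sp <- assemble_feature_matrix(list(cand), g$index, mode = "specific")
  expect_equal(sp$c_full_chain, c(1, 1))
})

test_that("exported feature blocks agree with the assembled matrix", {
  g <- build_graph(feat_assemblies())
  cand <- full_candidate(g)
  fm <- assemble_feature_matrix(list(cand), g$index, mode = "general")
  jc <- junction_coverage_features(cand, g$index)
  expect_equal(unname(jc["js_min"]), fm$js_min)
  expect_equal(unname(jc["bottleneck"]), fm$bottleneck)
  cs <- cell_support_features(cand, g$index)
  expect_equal(unname(cs["n_cells_supporting"]), fm$n_cells_supporting)
  fc <- fragment_connecting_features(cand, g$index)
  expect_equal(unname(fc["n_vertices"]), fm$n_vertices)
  # per-cell junction coverage restricted to c2
  jc2 <- junction_coverage_features(cand, g$index, cell = "c2")
  expect_equal(unname(jc2["c_js_max"]), 0.6)
  expect_equal(unname(jc2["c_bottleneck"]), 0)
})

test_that("feature matrices are deterministic and input-order invariant", {
  a <- random_scene(201)
  g1 <- build_graph(a)
  g2 <- build_graph(rev(lapply(a, function(x) {
    x$fragments <- rev(x$fragments); x
  })))
  norm <- function(g) {
    fm <- assemble_feature_matrix(search_all(g), g$index, mode = "specific")
    fm <- fm[order(fm$chain_key, fm$cell), setdiff(colnames(fm), "candidate_id")]
    rownames(fm) <- NULL
    fm
  }
  expect_equal(norm(g1), norm(g2))
  expect_identical(norm(g1), norm(g1))
})

test_that("feature values are finite and schema-stamped on random scenes", {
  for (seed in 211:214) {
    g <- build_graph(random_scene(seed))
    for (mode in c("general", "specific")) {
      fm <- assemble_feature_matrix(search_all(g), g$index, mode = mode)
      expect_equal(attr(fm, "schema"), txfuse:::FEATURE_SCHEMA_VERSION)
      num <- as.matrix(fm[setdiff(colnames(fm),
                                  c("candidate_id", "cell", "chrom",
                                    "chain_key"))])
      expect_true(all(is.finite(num)))
      # bottleneck consistency with the path-search scores
      expect_equal(fm$merging_score, fm$bottleneck * fm$n_junctions)
    }
  }
})

test_that("empty candidate sets give empty, well-formed matrices", {
  idx <- fragment_index(list(asm("c1")))
  fm <- assemble_feature_matrix(list(), idx, mode = "specific")
  expect_equal(nrow(fm), 0L)
  expect_equal(ncol(fm), 4L + 51L)
})

test_that("feature TSVs round-trip with the schema header", {
  g <- build_graph(feat_assemblies())
  fm <- assemble_feature_matrix(search_all(g), g$index, mode = "general")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(fm, p)
  expect_equal(readLines(p, n = 1),
               paste0("# schema=", txfuse:::FEATURE_SCHEMA_VERSION))
  back <- utils::read.delim(p, comment.char = "#")
  expect_equal(nrow(back), nrow(fm))
  expect_equal(back$merging_score, fm$merging_score)
})
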