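test_that("hamming_distance is the symmetric difference size", {
  expect_equal(hamming_distance(c("a", "b"), c("a", "b")), 0L)
  expect_equal(hamming_distance("m.263A>G", character(0)), 1L)
  expect_equal(hamming_distance(c("a", "b", "c"), c("b", "d")), 3L)
})

test_that("two haplotypes at distance 1 give a single branch network", {
  ht <- hap_table_from_sets(list(A = character(0), B = "m.100A>G"))
  net <- build_haplotype_network(ht)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$length, 1L)
  expect_equal(net$n_cycles, 0L)
  expect_equal(net$n_latent, 0L)
  res <- enumerate_resolutions(net)
  expect_length(res, 1L)
})

test_that("a chain of haplotypes yields the unique path MST", {
  ht <- hap_table_from_sets(list(A = character(0), B = "m.100A>G",
                                 C = c("m.100A>G", "m.200C>T")))
  net <- build_haplotype_network(ht)
  expect_equal(nrow(net$edges), 2L)
  expect_true(all(net$edges$length == 1L))
  expect_equal(net$mst_weight, 2L)
  ## brute-force enumeration agrees the MST is unique
  expect_equal(brute_force_n_mst(ht$variants), 1)
})

test_that("the rectangle of equidistant haplotypes forms one loop of 4 MSTs", {
  sets <- list(A = character(0), B = "m.100A>G", C = "m.200C>T",
               D = c("m.100A>G", "m.200C>T"))
  ht <- hap_table_from_sets(sets)
  net <- build_haplotype_network(ht)
  expect_equal(nrow(net$edges), 4L)
  expect_true(all(net$edges$length == 1L))
  expect_equal(net$n_cycles, 1L)
  expect_equal(brute_force_n_mst(sets), 4)
  res <- enumerate_resolutions(net)
  expect_length(res, 4L)
  ## every resolution is a spanning tree of MST weight
  for (r in res) {
    expect_length(r, 3L)
    expect_equal(sum(net$edges$length[r]), net$mst_weight)
  }
})

two_rectangle_sets <- function() {
  ## two unit-edge rectangles sharing only the corner haplotype {a,b}:
  ## independent loops whose resolution counts multiply
  list(H1 = character(0), H2 = "a", H3 = "b", H4 = c("a", "b"),
       H5 = c("a", "b", "c"), H6 = c("a", "b", "d"),
       H7 = c("a", "b", "c", "d"))
}

test_that("independent loops multiply: two rectangles give 4 x 4 resolutions", {
  sets <- two_rectangle_sets()
  ht <- hap_table_from_sets(sets)
  net <- build_haplotype_network(ht)
  expect_equal(net$n_cycles, 2L)
  n_oracle <- brute_force_n_mst(sets)
  res <- enumerate_resolutions(net, max_resolutions = 100L)
  expect_equal(length(res), n_oracle)
  expect_equal(length(res), 16L)
})

test_that("resolution count beyond the cap raises a capacity error", {
  net <- build_haplotype_network(hap_table_from_sets(two_rectangle_sets()))
  expect_error(enumerate_resolutions(net, max_resolutions = 4L), "16")
})

test_that("union-of-MSTs matches brute-force enumeration on random sets", {
  set.seed(11)
  for (rep in 1:12) {
    h <- sample(4:7, 1)
    sets <- random_hap_sets(h)
    ht <- hap_table_from_sets(sets)
    net <- build_haplotype_network(ht)
    oracle <- brute_force_msn(sets)
    got <- as.matrix(net$edges[, c("from", "to")])
    dimnames(got) <- NULL
    oracle_edges <- oracle$edges
    dimnames(oracle_edges) <- NULL
    ## membership counts are all 1, so ids are ordered by variant key; map
    ## back through the haplotype table to the original set names
    key_of <- vapply(ht$variants, paste, character(1), collapse = ";")
    orig_key <- vapply(sets, paste, character(1), collapse = ";")
    id_map <- stats::setNames(names(orig_key)[match(key_of, orig_key)],
                              names(key_of))
    got <- cbind(id_map[got[, 1]], id_map[got[, 2]])
    sw <- got[, 1] > got[, 2]
    got[sw, ] <- got[sw, c(2, 1)]
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    dimnames(got) <- NULL
    expect_identical(got, oracle_edges)
    expect_equal(net$mst_weight, oracle$mst_weight)
    ## all resolutions are minimum spanning trees
    res <- enumerate_resolutions(net, max_resolutions = 10000L)
    expect_equal(length(res), brute_force_n_mst(sets))
    for (r in res) {
      expect_equal(sum(net$edges$length[r]), oracle$mst_weight)
    }
  }
})

test_that("branches carry multi-variant edges and valid bipartitions", {
  ## path with a length-2 edge: one latent node, branch defined by 2 variants
  ht <- hap_table_from_sets(list(A = character(0), B = "m.100A>G",
                                 C = c("m.100A>G", "m.200C>T", "m.300G>A")))
  net <- build_haplotype_network(ht)
  expect_equal(net$n_latent, 1L)
  br <- enumerate_branches(net)
  expect_equal(nrow(br), 2L)
  two <- br[br$n_variants == 2L, ]
  expect_setequal(two$variants[[1]], c("m.200C>T", "m.300G>A"))
  ## bipartition sizes on a 3-node path are {1,2}
  expect_setequal(br$n_clade, c(1L, 2L))
  ## cut property: |side_a| + |side_b| = number of observed haplotypes
  for (b in seq_len(nrow(br))) {
    expect_equal(br$n_clade[b] +
                   length(setdiff(net$nodes$haplotype_id, br$clade[[b]])),
                 nrow(net$nodes))
  }
})

test_that("branch enumeration is deterministic and clades form a laminar family", {
  set.seed(23)
  sets <- random_hap_sets(8)
  net <- build_haplotype_network(hap_table_from_sets(sets))
  res <- enumerate_resolutions(net, max_resolutions = 10000L)
  br1 <- enumerate_branches(net, res[[1]])
  br2 <- enumerate_branches(net, res[[1]])
  expect_identical(br1, br2)
  expect_equal(nrow(br1), nrow(net$nodes) - 1L)
  ## laminar: any two clades are nested or disjoint
  for (i in seq_len(nrow(br1))) {
    for (j in seq_len(nrow(br1))) {
      a <- br1$clade[[i]]; b <- br1$clade[[j]]
      inter <- length(intersect(a, b))
      expect_true(inter == 0 || inter == length(a) || inter == length(b))
    }
  }
  ## loops must be resolved before branch enumeration
  if (net$n_cycles > 0) {
    expect_error(enumerate_branches(net), "loops")
  }
})

test_that("network exports write GraphML and JSON with latent placeholders", {
  ht <- hap_table_from_sets(list(A = character(0), B = "m.100A>G",
                                 C = c("m.100A>G", "m.200C>T", "m.300G>A")))
  net <- build_haplotype_network(ht)
  g1 <- withr::local_tempfile(fileext = ".graphml")
  j1 <- withr::local_tempfile(fileext = ".json")
  network_to_graphml(net, g1)
  network_to_json(net, j1)
  g <- igraph::read_graph(g1, format = "graphml")
  ## 3 observed + 1 latent node; one graph edge per variant segment
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  js <- jsonlite::read_json(j1, simplifyVector = TRUE)
  expect_equal(sum(js$nodes$observed), 3)
  expect_equal(sum(!js$nodes$observed), 1)
  expect_setequal(js$edges$variant, c("m.100A>G", "m.200C>T", "m.300G>A"))
})

test_that("degenerate networks are rejected", {
  ht1 <- hap_table_from_sets(list(A = "m.100A>G"))
  expect_error(build_haplotype_network(ht1), "at least 2")
})
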