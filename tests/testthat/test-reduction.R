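test_that("merge eligibility requires non-kinase, equal DGE, shared cluster", {
  fx <- worked_example_fixture()
  g <- fx$graph
  cl <- fx$clusters
  expect_true(merge_eligible(g, cl, "d", "f"))
  expect_false(merge_eligible(g, cl, "k2", "k3"))    # kinases excluded
  expect_false(merge_eligible(g, cl, "d", "e"))      # DGE mismatch
  expect_false(merge_eligible(g, cl, "e", "f"))      # cluster mismatch

  # node without a cluster assignment acts as its own singleton cluster
  cl2 <- cl[cl$gene_id != "f", ]
  expect_false(merge_eligible(g, cl2, "d", "f"))
})

test_that("merge groups are the components of the eligibility subgraph", {
  fx <- worked_example_fixture()
  groups <- find_merge_groups(fx$graph, fx$clusters)
  parts <- partition_from_tbl(groups)
  nonsingle <- Filter(function(x) length(x) > 1, parts)
  expect_equal(canonical_partition(nonsingle),
               canonical_partition(list(c("a", "b"), c("c", "e"),
                                        c("d", "f", "g"))))

  # graph with no eligible pair: identity partition
  singleton_cl <- tibble::tibble(gene_id = fx$graph$nodes$gene_id,
                                 cluster = paste0("solo_",
                                                  fx$graph$nodes$gene_id))
  groups2 <- find_merge_groups(fx$graph, singleton_cl)
  expect_equal(length(unique(groups2$group)), 13L)
})

test_that("group merging takes medians and collapses incident edges", {
  fx <- worked_example_fixture()
  m <- merge_group(fx$graph, c("d", "f", "g"))
  # DGA values {absent, 1.9, 2.3} -> median of {0, 1.9, 2.3} = 1.9
  expect_equal(m$node$dga_disease, 1.9)
  expect_equal(m$node$dge, "normal")
  expect_false(m$node$is_kinase)
  expect_setequal(m$node$members[[1]], c("d", "f", "g"))
  # two edges to outside neighbour e (600, 800) collapse to their median
  expect_equal(m$edges$weight[m$edges$to == "e"], 700)
  expect_equal(m$edges$weight[m$edges$to == "k4"], 830)
  expect_equal(nrow(m$edges), 2L)

  # identical annotations are unchanged by the median
  g <- fx$graph
  idx <- g$nodes$gene_id %in% c("d", "f", "g")
  g$nodes$dga_disease[idx] <- 2.5
  g$nodes$dga_disgenet[idx] <- 0.4
  m2 <- merge_group(g, c("d", "f", "g"))
  expect_equal(m2$node$dga_disease, 2.5)
  expect_equal(m2$node$dga_disgenet, 0.4)

  expect_error(merge_group(fx$graph, c("k1", "a")), "kinase")
})

test_that("worked-example reduction yields 9 nodes with three virtual merges", {
  fx <- worked_example_fixture()
  red <- reduce_graph(fx$graph, fx$clusters)
  expect_equal(nrow(red$graph$nodes), 9L)
  expect_equal(sum(red$graph$nodes$is_virtual), 3L)
  expect_equal(sum(red$graph$nodes$is_kinase), 4L)
  st <- reduction_stats(red$map)
  expect_equal(st$node_reduction_pct, 100 * (1 - 9 / 13), tolerance = 1e-9)
  expect_equal(st$kinase_fraction_before, 4 / 13)
  expect_equal(st$kinase_fraction_after, 4 / 9)
  expect_identical(red$graph$label, fx$graph$label)
  expect_identical(red$graph$tissue, fx$graph$tissue)
})

test_that("an all-kinase graph reduces to itself", {
  nodes <- tibble::tibble(gene_id = c("x", "y", "z"), is_kinase = TRUE,
                          dge = "up")
  edges <- tibble::tibble(from = c("x", "y"), to = c("y", "z"),
                          weight = c(600, 700))
  g <- cancer_graph(nodes, edges)
  red <- reduce_graph(g, tibble::tibble(gene_id = c("x", "y", "z"),
                                        cluster = "bp1"))
  expect_equal(nrow(red$graph$nodes), 3L)
  expect_equal(red$map$stats$nodes_before, red$map$stats$nodes_after)
  expect_equal(reduction_stats(red$map)$node_reduction_pct, 0)
})

test_that("reduction matches the union-find oracle on random graphs", {
  for (seed in 1:25) {
    n <- sample(10:60, 1)
    g <- random_cancer_graph(n, seed)
    cl <- random_clusters(g, sample(2:5, 1), seed + 100)
    mine <- partition_from_tbl(find_merge_groups(g, cl))
    oracle <- canonical_partition(uf_partition_oracle(g, cl))
    expect_equal(mine, oracle, info = paste("seed", seed))
  }
})

test_that("reduction is idempotent, monotone, connectivity-preserving and leaves no eligible pair", {
  for (seed in c(3, 9)) {
    g <- random_cancer_graph(120, seed, kinase_frac = 0.1)
    cl <- random_clusters(g, 4, seed + 1)
    red <- reduce_graph(g, cl)
    r <- red$graph

    # no adjacent pair of surviving original nodes is still eligible
    orig <- r$nodes$gene_id[!r$nodes$is_virtual]
    e <- r$edges[r$edges$from %in% orig & r$edges$to %in% orig, ]
    if (nrow(e) > 0) {
      expect_false(any(merge_eligible(r, cl, e$from, e$to)))
    }

    # monotone in node/edge counts; kinase fraction never decreases
    s <- red$map$stats
    expect_lte(s$nodes_after, s$nodes_before)
    expect_lte(s$edges_after, s$edges_before)
    expect_gte(s$kinase_fraction_after, s$kinase_fraction_before)
    merged_any <- s$nodes_after < s$nodes_before
    if (merged_any) {
      expect_gt(s$kinase_fraction_after, s$kinase_fraction_before)
    }

    # connectivity preserved: components map onto components
    ig1 <- igraph::graph_from_data_frame(
      g$edges[, 1:2], directed = FALSE,
      vertices = data.frame(name = g$nodes$gene_id))
    ig2 <- igraph::graph_from_data_frame(
      r$edges[, 1:2], directed = FALSE,
      vertices = data.frame(name = r$nodes$gene_id))
    comp1 <- igraph::components(ig1)$membership
    comp2 <- igraph::components(ig2)$membership
    amap <- red$map$assignment
    for (cc in unique(comp1)) {
      nodes_in <- names(comp1)[comp1 == cc]
      expect_length(unique(comp2[unique(amap[nodes_in])]), 1L)
    }

    # idempotence under the virtual-nodes-never-re-merge rule
    red2 <- reduce_graph(r, cl)
    expect_equal(nrow(red2$graph$nodes), nrow(r$nodes))
    expect_equal(nrow(red2$graph$edges), nrow(r$edges))
  }
})

test_that("the partition covers all nodes exactly once", {
  g <- random_cancer_graph(40, 13)
  cl <- random_clusters(g, 3, 14)
  groups <- find_merge_groups(g, cl)
  expect_setequal(groups$gene_id, g$nodes$gene_id)
  expect_equal(anyDuplicated(groups$gene_id), 0L)
})
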