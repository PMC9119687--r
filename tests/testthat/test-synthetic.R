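test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 80L, kinase_fraction = 0.05, n_cell_lines = 6L,
                    n_drugs = 3L, inf_gr50_fraction = 0.1)
  g1 <- generate_omics_tables(cfg, seed = 7)
  g2 <- generate_omics_tables(cfg, seed = 7)
  for (nm in names(omics_schemas())) {
    expect_identical(g1$tables[[nm]], g2$tables[[nm]], info = nm)
  }
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_omics_tables(cfg, seed = 8)
  expect_false(identical(g1$tables$ppi, g3$tables$ppi))
})

test_that("scaffold honours size, kinase count, and sub-threshold fraction", {
  cfg <- sim_config(n_genes = 500L, kinase_fraction = 0.02,
                    sub_threshold_fraction = 0.2)
  sc <- generate_scaffold(cfg, seed = 3)
  expect_length(sc$genes, 500L)
  expect_length(sc$kinases, 10L)           # round(0.02 * 500)
  m <- nrow(sc$ppi)
  kept <- nrow(build_ppi_network(sc$ppi, 500))
  removed_frac <- 1 - kept / m
  expect_equal(removed_frac, 0.2, tolerance = 0.03)   # exact by construction
  # connected scale-free scaffold
  ig <- igraph::graph_from_data_frame(sc$ppi[, 1:2], directed = FALSE)
  expect_true(igraph::is_connected(ig))

  expect_error(generate_scaffold(sim_config(n_genes = 20L,
                                            kinase_fraction = 0.01)),
               "infeasible")
})

test_that("profiles respect rates, ranges and tissue coverage", {
  cfg <- sim_config(n_genes = 500L, kinase_fraction = 0.04,
                    n_cell_lines = 12L, n_tissues = 5L, n_drugs = 6L,
                    dge_rates = c(up = 0.2, down = 0.3))
  sc <- generate_scaffold(cfg, seed = 9)
  pr <- generate_profiles(sc, cfg, seed = 10)

  expect_true(all(pr$kip$pic50 >= 6.3))
  expect_setequal(unique(pr$kip$gene_id), sc$kinases)  # kinases recoverable

  dis <- pr$dga[pr$dga$source == "DISEASE", ]
  expect_true(all(dis$score >= 1 & dis$score <= 10))
  dgn <- pr$dga[pr$dga$source == "DisGeNET", ]
  expect_true(all(dgn$score >= 0.01 & dgn$score <= 1))

  # category frequencies near the generating rates (binomial tolerance,
  # n = 12 * 500 draws)
  frac_up <- mean(pr$dge$category == "up")
  frac_down <- mean(pr$dge$category == "down")
  expect_equal(frac_up, 0.2, tolerance = 0.05)
  expect_equal(frac_down, 0.3, tolerance = 0.05)

  expect_equal(sort(unique(pr$cell_lines$tissue)),
               sprintf("tissue_%02d", 1:5))
  expect_true(all(table(pr$cell_lines$tissue) >= 1))
})

test_that("planted labels follow the signal rule", {
  # degenerate rule: zero strength leaves sigmoid(0) = 0.5 positives
  cfg0 <- sim_config(n_genes = 100L, kinase_fraction = 0.1,
                     n_cell_lines = 40L, n_drugs = 10L,
                     signal_strength = 0, signal_offset = 0,
                     noise_rate = 0)
  sc <- generate_scaffold(cfg0, seed = 2)
  pr <- generate_profiles(sc, cfg0, seed = 3)
  pl <- plant_labels(sc, pr, cfg0, seed = 4)
  expect_equal(mean(pl$gr$gr_max < 0), 0.5, tolerance = 0.06)

  # strong noise-free signal: labels equal the thresholded count exactly
  cfg1 <- sim_config(n_genes = 100L, kinase_fraction = 0.1,
                     n_cell_lines = 20L, n_drugs = 5L,
                     signal_strength = 1e4, noise_rate = 0)
  sc1 <- generate_scaffold(cfg1, seed = 5)
  pr1 <- generate_profiles(sc1, cfg1, seed = 6)
  pl1 <- plant_labels(sc1, pr1, cfg1, seed = 7)
  expect_equal(pl1$truth$label, as.integer(pl1$truth$s >= 1))

  # the emitted GRmax sign encodes the label and magnitudes are in (0, 1]
  expect_equal(as.integer(pl1$gr$gr_max < 0), pl1$truth$label)
  expect_true(all(abs(pl1$gr$gr_max) > 0 & abs(pl1$gr$gr_max) <= 1))

  # the planted signal is traceable to the input tables: recompute s for a
  # few pairs straight from the profile tables
  idx <- c(1, 25, 60)
  for (i in idx) {
    cl <- pl1$truth$cell_line[i]; dr <- pl1$truth$drug[i]
    up_genes <- pr1$dge$gene_id[pr1$dge$cell_line == cl &
                                  pr1$dge$category == "up"]
    strong <- pr1$dga$gene_id[pr1$dga$disease == cl &
                                pr1$dga$source == "DISEASE" &
                                pr1$dga$score > cfg1$dga_cut]
    inhib <- pr1$kip$gene_id[pr1$kip$drug == dr]
    s_hand <- length(Reduce(intersect,
                            list(up_genes, strong, inhib, sc1$kinases)))
    expect_equal(pl1$truth$s[i], s_hand)
  }
})

test_that("infinite-GR50 planting produces the expected rejection count", {
  cfg <- sim_config(n_genes = 60L, kinase_fraction = 0.1,
                    n_cell_lines = 50L, n_drugs = 20L,
                    inf_gr50_fraction = 0.1)
  gen <- generate_omics_tables(cfg, seed = 12)
  lab <- label_from_gr(gen$tables$gr)
  expect_equal(sum(!lab$accepted), 100L)       # 10% of 1000, exact count
})

test_that("the worked-example fixture carries the published annotations", {
  fx <- worked_example_fixture()
  nd <- fx$graph$nodes
  k1 <- nd[nd$gene_id == "k1", ]
  expect_equal(k1$dge, "up")
  expect_equal(k1$dga_disease, 5.2)
  expect_equal(k1$pic50, 6.8)
  expect_equal(nd$pic50[nd$gene_id == "k3"], 8.8)
  expect_equal(nd$dga_disease[nd$gene_id == "k4"], 3.4)
  expect_equal(nd$dga_disease[nd$gene_id %in% c("e", "f", "g")],
               c(2.6, 1.9, 2.3))
  expect_identical(fx$graph$label, 1L)
  expect_equal(sum(nd$is_kinase), 4L)
  expect_equal(nrow(nd), 13L)
})
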