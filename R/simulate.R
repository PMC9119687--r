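#' Configuration of the synthetic-data generator
#'
#' The generator emulates the six input tables at desk scale: a connected
#' scale-free PPI scaffold with STRING-style confidence scores, a small
#' kinase complement (2% of genes by default, the regime of real
#' kinome-annotated PPI networks), categorical differential expression per
#' cell line, bounded disease-association scores from two sources, sparse
#' kinase-inhibition profiles with pIC50 at or above the retention
#' threshold, and growth-rate records whose labels follow a planted
#' mechanism: the log-odds of a cytotoxic response grow with the number
#' of kinases that are simultaneously up-regulated in the cell line,
#' inhibited by the drug, and strongly disease-associated.
#'
#' @param n_genes Number of genes/proteins in the scaffold.
#' @param kinase_fraction Fraction of genes flagged as kinases (default
#'   0.02).
#' @param pa_m Edges attached per node in the preferential-attachment
#'   scaffold (default 2).
#' @param sub_threshold_fraction Fraction of PPI edges drawn below the 500
#'   confidence threshold, to exercise edge filtering (default 0).
#' @param n_cell_lines,n_tissues,n_drugs Cohort sizes.
#' @param dge_rates Named vector `c(up = , down = )` of per-gene
#'   probabilities for the non-normal categories.
#' @param n_clusters Number of biological-process clusters.
#' @param cluster_coherence Probability that a gene keeps its spatially
#'   coherent (graph-proximity) cluster rather than a random one.
#' @param kip_density Probability that a given drug inhibits a given
#'   kinase.
#' @param pic50_range Range of emitted pIC50 values (all at or above the
#'   6.3 retention threshold by default).
#' @param dga_density Probability that a gene carries a disease
#'   association score for a given cell line's disease (per source).
#' @param signal_strength Slope of the planted label rule on the
#'   signal-kinase count.
#' @param signal_offset Count threshold of the rule: the cytotoxic
#'   probability is `sigmoid(signal_strength * (s - signal_offset))`.
#' @param dga_cut Minimum DISEASE score for a kinase to count as a signal
#'   kinase (default 5).
#' @param noise_rate Label flip probability (default 0.05).
#' @param inf_gr50_fraction Fraction of GR records given an infinite GR50
#'   (rejected downstream).
#' @param multi_gr50_fraction Fraction of (cell line, drug) pairs
#'   duplicated with a second GR50 measurement (rejected downstream).
#' @param seed Default seed for [generate_omics_tables()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 150L, kinase_fraction = 0.02, pa_m = 2L,
                       sub_threshold_fraction = 0,
                       n_cell_lines = 20L, n_tissues = 4L, n_drugs = 5L,
                       dge_rates = c(up = 0.25, down = 0.25),
                       n_clusters = 12L, cluster_coherence = 0.9,
                       kip_density = 0.6, pic50_range = c(6.3, 10),
                       dga_density = 0.8,
                       signal_strength = 10, signal_offset = 0.5,
                       dga_cut = 5, noise_rate = 0.05,
                       inf_gr50_fraction = 0, multi_gr50_fraction = 0,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              kinase_fraction = kinase_fraction, pa_m = as.integer(pa_m),
              sub_threshold_fraction = sub_threshold_fraction,
              n_cell_lines = as.integer(n_cell_lines),
              n_tissues = as.integer(n_tissues),
              n_drugs = as.integer(n_drugs),
              dge_rates = dge_rates, n_clusters = as.integer(n_clusters),
              cluster_coherence = cluster_coherence,
              kip_density = kip_density, pic50_range = pic50_range,
              dga_density = dga_density,
              signal_strength = signal_strength,
              signal_offset = signal_offset, dga_cut = dga_cut,
              noise_rate = noise_rate,
              inf_gr50_fraction = inf_gr50_fraction,
              multi_gr50_fraction = multi_gr50_fraction,
              seed = as.integer(seed))
  probs <- c(cfg$sub_threshold_fraction, cfg$cluster_coherence,
             cfg$kip_density, cfg$dga_density, cfg$noise_rate,
             cfg$inf_gr50_fraction, cfg$multi_gr50_fraction,
             cfg$dge_rates)
  stopifnot(all(probs >= 0 & probs <= 1), sum(cfg$dge_rates) <= 1,
            cfg$n_tissues <= cfg$n_cell_lines)
  structure(cfg, class = "sim_config")
}

#' Generate the gene universe, PPI scaffold, kinase flags and clusters
#'
#' Draws a connected preferential-attachment (scale-free) graph,
#' STRING-style confidence scores in \[500, 1000\] (with an optional
#' sub-threshold fraction in \[0, 500) for filter testing), a random
#' kinase subset of the configured size, and spatially coherent
#' biological-process clusters grown from random seed genes by graph
#' proximity.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `genes`, `kinases`, `ppi` (tibble `protein_a`,
#'   `protein_b`, `score`) and `clusters` (tibble `gene_id`, `cluster`).
#' @export
generate_scaffold <- function(config = sim_config(), seed = config$seed) {
  n <- config$n_genes
  n_kin <- round(config$kinase_fraction * n)
  if (n_kin < 1L) {
    stop("infeasible config: kinase_fraction * n_genes < 1", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n))
  ig <- igraph::sample_pa(n, power = 1, m = config$pa_m, directed = FALSE)
  el <- igraph::as_edgelist(ig, names = FALSE)
  m <- nrow(el)
  score <- round(stats::runif(m, 500, 1000), 1)
  n_sub <- round(config$sub_threshold_fraction * m)
  if (n_sub > 0L) {
    sub <- sample.int(m, n_sub)
    score[sub] <- round(stats::runif(n_sub, 0, 499.9), 1)
  }
  ppi <- tibble::tibble(protein_a = genes[el[, 1]],
                        protein_b = genes[el[, 2]], score = score)
  kinases <- sort(sample(genes, n_kin))

  seeds <- sample.int(n, min(config$n_clusters, n))
  dmat <- igraph::distances(ig, v = seeds)
  nearest <- apply(dmat, 2L, which.min)       # ties -> lowest seed index
  cluster <- paste0("bp", nearest)
  recluster <- stats::runif(n) > config$cluster_coherence
  cluster[recluster] <- paste0("bp", sample.int(length(seeds),
                                                sum(recluster),
                                                replace = TRUE))
  list(genes = genes, kinases = kinases, ppi = ppi,
       clusters = tibble::tibble(gene_id = genes, cluster = cluster))
}

#' Generate per-cell-line and per-drug annotation tables
#'
#' Assigns each cell line a tissue (round-robin, so every tissue group is
#' non-empty), draws a categorical DGE profile per cell line, DISEASE
#' (\[1, 10\]) and DisGeNET (\[0.01, 1\]) association scores with the
#' configured density (the disease term is the cell-line identifier), and
#' a sparse kinase-inhibition profile per drug with pIC50 in the
#' configured range.  Every kinase is guaranteed at least one inhibition
#' record so that kinase identity is recoverable from the KIP table.
#'
#' @param scaffold Output of [generate_scaffold()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `cell_lines` (tibble `cell_line`, `tissue`), `dge`,
#'   `dga`, `kip` tibbles.
#' @export
generate_profiles <- function(scaffold, config = sim_config(),
                              seed = config$seed) {
  set.seed(seed)
  genes <- scaffold$genes
  n_g <- length(genes)
  cls <- sprintf("CL%03d", seq_len(config$n_cell_lines))
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  cell_lines <- tibble::tibble(
    cell_line = cls,
    tissue = rep(tissues, length.out = length(cls)))

  p_up <- config$dge_rates[["up"]]
  p_down <- config$dge_rates[["down"]]
  dge <- tidyr::expand_grid(cell_line = cls, gene_id = genes)
  u <- stats::runif(nrow(dge))
  dge$category <- ifelse(u < p_up, "up",
                         ifelse(u < p_up + p_down, "down", "normal"))
  dge <- dge[, c("gene_id", "cell_line", "category")]

  dga_one <- function(source, lo, hi) {
    grid <- tidyr::expand_grid(disease = cls, gene_id = genes)
    keep <- stats::runif(nrow(grid)) < config$dga_density
    grid <- grid[keep, ]
    grid$score <- round(stats::runif(nrow(grid), lo, hi), 2)
    grid$source <- source
    grid
  }
  dga <- dplyr::bind_rows(dga_one("DISEASE", 1, 10),
                          dga_one("DisGeNET", 0.01, 1))

  drugs <- sprintf("drug%02d", seq_len(config$n_drugs))
  kip <- tidyr::expand_grid(drug = drugs, gene_id = scaffold$kinases)
  kip <- kip[stats::runif(nrow(kip)) < config$kip_density, ]
  orphan <- setdiff(scaffold$kinases, unique(kip$gene_id))
  if (length(orphan) > 0L) {
    kip <- dplyr::bind_rows(kip, tibble::tibble(
      drug = sample(drugs, length(orphan), replace = TRUE),
      gene_id = orphan))
  }
  kip$pic50 <- round(stats::runif(nrow(kip), config$pic50_range[1],
                                  config$pic50_range[2]), 2)
  list(cell_lines = cell_lines, dge = dge, dga = dga, kip = kip)
}

#' Plant growth-rate labels on the (cell line, drug) grid
#'
#' For each pair, the signal `s` counts kinases that are up-regulated in
#' the cell line, inhibited by the drug, and carry a DISEASE association
#' above `dga_cut`.  The cytotoxic probability is
#' `sigmoid(signal_strength * (s - signal_offset))`, the drawn label is
#' flipped with `noise_rate`, and GRmax magnitude is sampled in (0, 1\]
#' with the sign encoding the label (negative = cytotoxic).  Configured
#' fractions of records get an infinite GR50 or a duplicated measurement
#' to exercise the downstream filters.
#'
#' @param scaffold,profiles Outputs of the two generators above.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with `gr` (tibble `cell_line`, `drug`, `gr50`, `gr_max`,
#'   `tissue`) and `truth` (per-pair diagnostics: `s`, `p_pos`, the
#'   noise-free label, and the emitted label).
#' @export
plant_labels <- function(scaffold, profiles, config = sim_config(),
                         seed = config$seed) {
  set.seed(seed)
  grid <- tidyr::expand_grid(cell_line = profiles$cell_lines$cell_line,
                             drug = unique(profiles$kip$drug))
  up <- profiles$dge[profiles$dge$category == "up", ]
  up_key <- paste(up$cell_line, up$gene_id)
  dis <- profiles$dga[profiles$dga$source == "DISEASE" &
                        profiles$dga$score > config$dga_cut, ]
  dis_key <- paste(dis$disease, dis$gene_id)
  kip_key <- paste(profiles$kip$drug, profiles$kip$gene_id)

  grid$s <- vapply(seq_len(nrow(grid)), function(i) {
    k <- scaffold$kinases
    sum(paste(grid$cell_line[i], k) %in% up_key &
          paste(grid$cell_line[i], k) %in% dis_key &
          paste(grid$drug[i], k) %in% kip_key)
  }, numeric(1))
  grid$p_pos <- sigmoid(config$signal_strength *
                          (grid$s - config$signal_offset))
  clean <- stats::rbinom(nrow(grid), 1L, grid$p_pos)
  flip <- stats::runif(nrow(grid)) < config$noise_rate
  label <- ifelse(flip, 1L - clean, clean)

  mag <- stats::runif(nrow(grid), .Machine$double.eps, 1)
  gr <- tibble::tibble(
    cell_line = grid$cell_line, drug = grid$drug,
    gr50 = round(stats::runif(nrow(grid), 0.001, 10), 4),
    gr_max = round(ifelse(label == 1L, -mag, mag), 4),
    tissue = profiles$cell_lines$tissue[match(grid$cell_line,
                                              profiles$cell_lines$cell_line)])
  n_inf <- round(config$inf_gr50_fraction * nrow(gr))
  if (n_inf > 0L) gr$gr50[sample.int(nrow(gr), n_inf)] <- Inf
  n_multi <- round(config$multi_gr50_fraction * nrow(gr))
  if (n_multi > 0L) {
    dup <- gr[sample.int(nrow(gr), n_multi), ]
    dup$gr50 <- dup$gr50 * 2 + 0.01
    gr <- dplyr::bind_rows(gr, dup)
  }
  truth <- tibble::tibble(cell_line = grid$cell_line, drug = grid$drug,
                          s = grid$s, p_pos = grid$p_pos,
                          label_clean = clean, label = label)
  list(gr = gr, truth = truth)
}

#' Generate a complete set of validated omics tables
#'
#' Runs [generate_scaffold()], [generate_profiles()] and [plant_labels()]
#' with seeds derived from `seed`, assembles the six tables, and validates
#' them with [validate_omics_tables()] (the generator's output always
#' passes the readers' schema checks).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `tables` (an `omics_tables`), `truth` (planted-label
#'   diagnostics) and `scaffold`.
#' @export
generate_omics_tables <- function(config = sim_config(),
                                  seed = config$seed) {
  scaffold <- generate_scaffold(config, seed)
  profiles <- generate_profiles(scaffold, config, seed + 1L)
  planted <- plant_labels(scaffold, profiles, config, seed + 2L)
  tables <- validate_omics_tables(list(
    ppi = scaffold$ppi, dge = profiles$dge, dga = profiles$dga,
    kip = profiles$kip, gr = planted$gr,
    go_clusters = scaffold$clusters))
  list(tables = tables, truth = planted$truth, scaffold = scaffold)
}

#' The worked-example subnetwork fixture
#'
#' A 13-node breast-adenocarcinoma subnetwork for the MDA-MB-468 cell
#' line treated with dasatinib: four kinase nodes (EGFR, JAK2, JAK1, SRC,
#' here named `k1`-`k4`) and nine non-kinase proteins (`a`-`i`).  EGFR is
#' up-regulated and CBL down-regulated; DGA scores 5.2 (EGFR), 3.4 (SRC),
#' 2.6/1.9/2.3 (STAT3/HSP90AA1/PXN); dasatinib pIC50 6.8 on EGFR and 8.8
#' on JAK1; the GRmax of -0.96 makes the instance label positive
#' (cytotoxic).  The cluster table co-clusters exactly the three
#' biological-process groups a-b, c-e, and d-f-g, so one reduction pass
#' merges them into three virtual nodes.  The edge set is a synthetic
#' reconstruction consistent with those group memberships.
#'
#' @return List with `graph` (a labeled `cancer_graph`) and `clusters`
#'   (tibble `gene_id`, `cluster`).
#' @export
worked_example_fixture <- function() {
  nodes <- tibble::tibble(
    gene_id  = c("k1", "k2", "k3", "k4",
                 "a", "b", "c", "d", "e", "f", "g", "h", "i"),
    is_kinase = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 9)),
    dge = c("up", "normal", "normal", "normal",
            "normal", "normal", "up", "normal", "up", "normal", "normal",
            "normal", "down"),
    dga_disease = c(5.2, NA, NA, 3.4, NA, NA, NA, NA, 2.6, 1.9, 2.3,
                    NA, NA),
    dga_disgenet = NA_real_,
    pic50 = c(6.8, NA, 8.8, NA, rep(NA_real_, 9)),
    is_virtual = FALSE
  )
  edges <- tibble::tribble(
    ~from, ~to, ~weight,
    "k1", "k2", 700,
    "k1", "k3", 650,
    "k2", "k3", 800,
    "k1", "a",  520,
    "a",  "b",  610,
    "b",  "k2", 540,
    "k1", "e",  900,
    "k3", "e",  860,
    "c",  "e",  750,
    "d",  "e",  600,
    "e",  "f",  800,
    "d",  "f",  720,
    "f",  "g",  560,
    "g",  "k4", 830,
    "k4", "h",  910,
    "h",  "i",  640,
    "k1", "i",  580
  )
  clusters <- tibble::tibble(
    gene_id = c("a", "b", "c", "e", "d", "f", "g", "h", "i",
                "k1", "k2", "k3", "k4"),
    cluster = c("bp_stem", "bp_stem", "bp_il10", "bp_il10",
                "bp_oxy", "bp_oxy", "bp_oxy", "bp_adapt", "bp_ubiq",
                "bp_k1", "bp_k2", "bp_k3", "bp_k4"))
  graph <- cancer_graph(nodes, edges, cell_line = "MDA-MB-468",
                        drug = "dasatinib", tissue = "breast tissue",
                        label = 1L)
  list(graph = graph, clusters = clusters)
}
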