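# Shared fixtures and independent oracles used across the suite.

# Minimal well-formed omics tables (two cell lines, two drugs).
tiny_tables <- function() {
  validate_omics_tables(list(
    ppi = tibble::tibble(
      protein_a = c("gA", "gA", "gB", "gC", "gK1"),
      protein_b = c("gB", "gC", "gC", "gK1", "gK2"),
      score = c(700, 650, 520, 900, 610)),
    dge = tibble::tibble(
      gene_id = c("gA", "gB", "gK1", "gA"),
      cell_line = c("CL1", "CL1", "CL1", "CL2"),
      category = c("up", "up", "up", "down")),
    dga = tibble::tibble(
      disease = c("CL1", "CL1", "CL2"),
      gene_id = c("gK1", "gA", "gB"),
      score = c(6.5, 2.2, 0.4),
      source = c("DISEASE", "DISEASE", "DisGeNET")),
    kip = tibble::tibble(
      drug = c("d1", "d1", "d2"),
      gene_id = c("gK1", "gK2", "gK1"),
      pic50 = c(7.5, 6.0, 6.9)),
    gr = tibble::tibble(
      cell_line = c("CL1", "CL1", "CL2", "CL2"),
      drug = c("d1", "d2", "d1", "d2"),
      gr50 = c(0.5, 1.2, Inf, 2.0),
      gr_max = c(-0.7, 0.3, -0.2, 0.9),
      tissue = c("breast", "breast", "skin", "skin")),
    go_clusters = tibble::tibble(
      gene_id = c("gA", "gB", "gC", "gK1", "gK2"),
      cluster = c("bp1", "bp1", "bp1", "bp2", "bp2"))
  ))
}

# Random annotated graph for property tests.
random_cancer_graph <- function(n, seed, p_edge = 2.5 / n,
                                kinase_frac = 0.2) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  ig <- igraph::sample_gnp(n, p_edge)
  el <- igraph::as_edgelist(ig, names = FALSE)
  edges <- tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]],
                          weight = round(runif(nrow(el), 500, 1000)))
  nodes <- tibble::tibble(
    gene_id = ids,
    is_kinase = runif(n) < kinase_frac,
    dge = sample(c("up", "down", "normal"), n, replace = TRUE),
    dga_disease = ifelse(runif(n) < 0.5, round(runif(n, 1, 10), 2), NA),
    dga_disgenet = ifelse(runif(n) < 0.5, round(runif(n, 0.01, 1), 2), NA),
    pic50 = NA_real_,
    is_virtual = FALSE)
  kin <- which(nodes$is_kinase)
  hit <- kin[runif(length(kin)) < 0.5]
  nodes$pic50[hit] <- round(runif(length(hit), 6.3, 10), 2)
  cancer_graph(nodes, edges, cell_line = paste0("cl", seed),
               drug = "dX", tissue = "t1",
               label = sample(0:1, 1))
}

random_clusters <- function(graph, n_clusters, seed) {
  set.seed(seed)
  tibble::tibble(gene_id = graph$nodes$gene_id,
                 cluster = paste0("bp", sample.int(n_clusters,
                                                   nrow(graph$nodes),
                                                   replace = TRUE)))
}

# Independent union-find oracle for the merge partition: enumerate all
# eligible adjacent pairs and union them.
uf_partition_oracle <- function(graph, clusters) {
  ids <- graph$nodes$gene_id
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  cl <- clusters$cluster[match(ids, clusters$gene_id)]
  cl[is.na(cl)] <- paste0(".na.", ids[is.na(cl)])
  nodes <- graph$nodes
  for (r in seq_len(nrow(graph$edges))) {
    i <- match(graph$edges$from[r], ids)
    j <- match(graph$edges$to[r], ids)
    ok <- !nodes$is_kinase[i] && !nodes$is_kinase[j] &&
      !nodes$is_virtual[i] && !nodes$is_virtual[j] &&
      nodes$dge[i] == nodes$dge[j] && cl[i] == cl[j]
    if (ok) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  split(ids, roots)
}

# Canonical form of a partition for comparison.
canonical_partition <- function(groups) {
  g <- lapply(unname(groups), function(x) sort(x))
  g[order(vapply(g, `[`, character(1), 1))]
}

partition_from_tbl <- function(tbl) {
  canonical_partition(split(tbl$gene_id, tbl$group))
}

# Scalar re-implementation of the attention matrix (loops, no linear
# algebra shortcuts).
attention_oracle <- function(X, adj, beta) {
  n <- nrow(X)
  G <- matrix(0, n, n)
  cosv <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) return(0)
    sum(a * b) / (na * nb)
  }
  for (i in seq_len(n)) {
    supp <- sort(unique(c(i, which(adj[i, ] != 0))))
    w <- vapply(supp, function(j) exp(beta * cosv(X[i, ], X[j, ])),
                numeric(1))
    G[i, supp] <- w / sum(w)
  }
  G
}

# Scalar unrolled Set2Set oracle.
set2set_oracle <- function(X, W, b, steps) {
  h <- ncol(X)
  sig <- function(x) 1 / (1 + exp(-x))
  q_star <- numeric(2 * h); hh <- numeric(h); cc <- numeric(h)
  for (s in seq_len(steps)) {
    z <- c(q_star, hh)
    gates <- numeric(4 * h)
    for (k in seq_len(4 * h)) gates[k] <- sum(z * W[, k]) + b[k]
    gi <- sig(gates[1:h]); gf <- sig(gates[h + 1:h])
    go <- sig(gates[2 * h + 1:h]); gg <- tanh(gates[3 * h + 1:h])
    cc <- gf * cc + gi * gg
    hh <- go * tanh(cc)
    e <- apply(X, 1, function(row) sum(row * hh))
    a <- exp(e - max(e)); a <- a / sum(a)
    r <- numeric(h)
    for (i in seq_len(nrow(X))) r <- r + a[i] * X[i, ]
    q_star <- c(hh, r)
  }
  q_star
}

# All-pairs AUC oracle with ties counted one half.
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Reorder the nodes of a graph (edges keep their id references).
permute_graph <- function(g, perm) {
  cancer_graph(g$nodes[perm, ], g$edges, cell_line = g$cell_line,
               drug = g$drug, tissue = g$tissue, label = g$label,
               validate = FALSE)
}
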