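path3 <- function() {
  # 3-node path with the hand-checked feature vectors
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  list(X = X, A = A)
}

test_that("attention rows are stochastic with support N(i) u {i}", {
  for (seed in 1:10) {
    g <- random_cancer_graph(sample(5:40, 1), seed)
    A <- graph_adjacency(g)
    G <- attention_matrix(encode_features(g), A, beta = runif(1, -2, 2))
    expect_equal(unname(rowSums(G)), rep(1, nrow(A)), tolerance = 1e-10)
    expect_true(all(G[!((A != 0) | diag(TRUE, nrow(A)))] == 0))
  }
})

test_that("beta = 0 and identical features both give uniform attention", {
  p <- path3()
  G0 <- attention_matrix(p$X, p$A, beta = 0)
  deg1 <- rowSums(p$A) + 1
  expect_equal(G0, (((p$A != 0) | diag(TRUE, 3)) * 1) / deg1)

  Xsame <- matrix(1, 3, 2)
  G1 <- attention_matrix(Xsame, p$A, beta = 1.7)
  expect_equal(G1, (((p$A != 0) | diag(TRUE, 3)) * 1) / deg1)
})

test_that("attention matches the scalar hand evaluation on the 3-node path", {
  p <- path3()
  G <- attention_matrix(p$X, p$A, beta = 1)
  expect_equal(G, attention_oracle(p$X, p$A, beta = 1), tolerance = 1e-12)
  # spot-check one entry fully by hand: gamma_12 = e^cos(x1,x2) /
  # (e^cos(x1,x1) + e^cos(x1,x2)) with cos(x1,x2) = 0
  expect_equal(G[1, 2], exp(0) / (exp(1) + exp(0)), tolerance = 1e-12)
})

test_that("large beta concentrates attention on the most similar neighbour", {
  X <- rbind(c(1, 0), c(1, 0), c(0, 1))      # node 2 parallel to node 1
  A <- matrix(1, 3, 3) - diag(3)             # triangle
  g_prev <- -Inf
  for (beta in c(1, 5, 20, 80)) {
    G <- attention_matrix(X, A, beta)
    expect_gt(G[1, 2], g_prev)               # monotone sharpening
    g_prev <- G[1, 2]
  }
  G <- attention_matrix(X, A, 80)
  # the dominant neighbour ties with self-attention (cosine 1 for both)
  # while the dissimilar neighbour's weight vanishes
  expect_equal(G[1, 2], 0.5, tolerance = 1e-10)
  expect_lt(G[1, 3], 1e-10)
})

test_that("equal propagation is the symmetric-normalised operator", {
  # two nodes, one edge: propagation swaps the rows
  A <- rbind(c(0, 1), c(1, 0))
  X <- rbind(c(1, 2), c(3, 4))
  expect_equal(equal_propagation(A, X), X[2:1, ])

  # star: entry (center, leaf) = 1/sqrt(3)
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1
  P <- oncographnn:::equal_operator(A)
  expect_equal(P[1, 2], 1 / sqrt(3))
  expect_equal(P[2, 1], 1 / sqrt(3))

  # edgeless graph: identity pass-through
  A0 <- matrix(0, 3, 3)
  expect_equal(equal_propagation(A0, X <- matrix(rnorm(9), 3)), X)
})

test_that("conv block reproduces the update formula", {
  # identity theta, eps = 0, single isolated node: X' = 2x
  x <- matrix(c(0.2, 0.7), 1, 2)
  block <- list(beta = 1, eps = 0, W1 = diag(2), b1 = c(0, 0),
                W2 = diag(2), b2 = c(0, 0))
  expect_equal(conv_block_forward(x, matrix(0, 1, 1), block), 2 * x)

  # small graph: equals attention oracle + propagation + theta, step by step
  set.seed(2)
  g <- random_cancer_graph(12, 21)
  X <- encode_features(g)
  A <- graph_adjacency(g)
  block <- list(beta = 0.8, eps = 0.3, W1 = matrix(rnorm(7 * 4), 7, 4),
                b1 = rnorm(4), W2 = matrix(rnorm(16), 4, 4), b2 = rnorm(4))
  G <- attention_oracle(X, A, 0.8)
  H <- G %*% X + 1.3 * X
  expected <- pmax(sweep(pmax(sweep(H %*% block$W1, 2, block$b1, "+"),
                              0) %*% block$W2, 2, block$b2, "+"), 0)
  expect_equal(unname(conv_block_forward(X, A, block)), unname(expected),
               tolerance = 1e-12)
  expect_equal(dim(conv_block_forward(X, A, block)), c(12L, 4L))
})

test_that("disabling attention reproduces the closed-form equal operator", {
  for (seed in 1:5) {
    g <- random_cancer_graph(15, seed + 40)
    X <- encode_features(g)
    A <- graph_adjacency(g)
    block <- list(beta = 1, eps = 0.1, W1 = diag(7), b1 = numeric(7),
                  W2 = diag(7), b2 = numeric(7), attention_enabled = FALSE)
    d <- rowSums(A)
    Dm <- diag(ifelse(d > 0, 1 / sqrt(d), 0))
    P <- Dm %*% A %*% Dm
    iso <- d == 0
    if (any(iso)) diag(P)[iso] <- 1
    expect_equal(unname(conv_block_forward(X, A, block)),
                 unname(pmax(P %*% X + 1.1 * X, 0)), tolerance = 1e-12)
  }
})

test_that("jumping-knowledge max-pool is the element-wise maximum", {
  m1 <- rbind(c(1, 5), c(0, 2))
  m2 <- rbind(c(3, 2), c(1, 1))
  expect_equal(jk_max_pool(list(m1, m2)), rbind(c(3, 5), c(1, 2)))
  expect_equal(jk_max_pool(list(m1, m1, m1)), m1)

  set.seed(5)
  ms <- replicate(3, matrix(rnorm(24), 6, 4), simplify = FALSE)
  brute <- ms[[1]]
  for (i in seq_len(6)) for (j in seq_len(4)) {
    brute[i, j] <- max(ms[[1]][i, j], ms[[2]][i, j], ms[[3]][i, j])
  }
  expect_equal(jk_max_pool(ms), brute)
  expect_error(jk_max_pool(list(m1, matrix(0, 3, 3))), "shape")
})

test_that("Set2Set readout is permutation-invariant and matches the unrolled oracle", {
  set.seed(8)
  h <- 4
  X <- matrix(rnorm(6 * h), 6, h)
  params <- list(W = matrix(rnorm(3 * h * 4 * h, sd = 0.3), 3 * h, 4 * h),
                 b = rnorm(4 * h, sd = 0.1))
  out <- set2set_readout(X, params, steps = 2)
  expect_length(out, 2 * h)
  expect_equal(out, set2set_oracle(X, params$W, params$b, 2),
               tolerance = 1e-12)

  for (i in 1:5) {
    perm <- sample(6)
    expect_equal(set2set_readout(X[perm, ], params, steps = 3),
                 set2set_readout(X, params, steps = 3), tolerance = 1e-5)
  }

  # single node: attention weight is exactly 1 at every step, so the
  # read vector equals that node's embedding
  x1 <- X[1, , drop = FALSE]
  out1 <- set2set_readout(x1, params, steps = 3)
  expect_equal(out1[h + seq_len(h)], unname(x1[1, ]), tolerance = 1e-12)
  expect_error(set2set_readout(X[0, , drop = FALSE], params), "empty")
})

test_that("analytic gradients agree with numerical differentiation", {
  ns <- asNamespace("oncographnn")
  set.seed(42)
  fx <- worked_example_fixture()$graph
  for (attn in c(TRUE, FALSE)) {
    cfg <- gnn_config(hidden_dim = 5, classifier_dim = 4, dropout = 0,
                      seed = 3, attention_enabled = attn)
    model <- init_gnn(cfg, seed = 3)
    # keep every ReLU unit active so the loss is smooth at the test point
    for (nm in grep("_b[12]$", names(model$params), value = TRUE)) {
      model$params[[nm]] <- model$params[[nm]] + 0.3
    }
    gd <- ns$gnn_graph_data(fx)
    loss <- function(p) {
      -log(ns$gnn_forward(p, cfg, gd, keep_cache = TRUE)$cache$p[2])
    }
    fw <- ns$gnn_forward(model$params, cfg, gd, keep_cache = TRUE)
    gr <- ns$gnn_backward(model$params, cfg, gd, fw$cache, 1L)
    eps <- 1e-6
    for (nm in names(model$params)) {
      idx <- sample(seq_along(model$params[[nm]]),
                    min(3, length(model$params[[nm]])))
      for (i in idx) {
        pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (loss(pp) - loss(pm)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                     info = paste(nm, i, "attention:", attn))
      }
    }
  }
})

test_that("model output is a probability, permutation-invariant, and 3-hop local", {
  fx <- worked_example_fixture()$graph
  model <- init_gnn(gnn_config(seed = 2), seed = 2)
  p <- model_forward(fx, model)
  expect_gte(p, 0); expect_lte(p, 1)

  for (seed in 1:5) {
    perm <- sample(nrow(fx$nodes))
    expect_equal(model_forward(permute_graph(fx, perm), model), p,
                 tolerance = 1e-5)
  }

  # locality: on a path, perturbing a node more than n_blocks hops away
  # leaves a node's post-JK embedding unchanged
  ns <- asNamespace("oncographnn")
  n <- 8
  nodes <- tibble::tibble(
    gene_id = sprintf("p%d", 1:n), is_kinase = FALSE,
    dge = "normal", dga_disease = seq(1, 8), dga_disgenet = NA_real_,
    pic50 = NA_real_, is_virtual = FALSE)
  edges <- tibble::tibble(from = sprintf("p%d", 1:(n - 1)),
                          to = sprintf("p%d", 2:n), weight = 600)
  g1 <- cancer_graph(nodes, edges)
  nodes2 <- nodes
  nodes2$dga_disease[n] <- 9.9           # perturb the far end (7 hops)
  nodes2$dge[n] <- "up"
  g2 <- cancer_graph(nodes2, edges)
  cfg <- gnn_config(seed = 4)
  model <- init_gnn(cfg, seed = 4)
  agg1 <- ns$gnn_forward(model$params, cfg, ns$gnn_graph_data(g1),
                         keep_cache = TRUE)$cache$jk$agg
  agg2 <- ns$gnn_forward(model$params, cfg, ns$gnn_graph_data(g2),
                         keep_cache = TRUE)$cache$jk$agg
  expect_equal(agg1[1:4, ], agg2[1:4, ], tolerance = 1e-12)  # > 3 hops away
  expect_false(isTRUE(all.equal(agg1[n, ], agg2[n, ])))

  expect_error(model_forward(structure(list(X = NULL), class = "cancer_graph"),
                             model), "feature")
})

test_that("checkpoints restore the model exactly", {
  dir <- withr::local_tempdir()
  model <- init_gnn(gnn_config(hidden_dim = 6, seed = 9), seed = 9)
  fx <- worked_example_fixture()$graph
  p1 <- model_forward(fx, model)
  save_checkpoint(model, file.path(dir, "m.json"))
  back <- load_checkpoint(file.path(dir, "m.json"))
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(model_forward(fx, back), p1, tolerance = 1e-12)
  expect_equal(unclass(back$config), unclass(model$config))
})
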