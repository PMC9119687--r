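#' GNN hyperparameter configuration
#'
#' Defaults follow the architecture used throughout the package: three
#' attention-propagation + GIN-update blocks (a fourth adds nothing on
#' graphs whose diameter information is exhausted after a few hops),
#' jumping-knowledge max-pooling over the per-block embeddings, a
#' three-step Set2Set readout, and a two-layer classifier head trained
#' with cross-entropy.
#'
#' @param n_blocks Number of graph convolution blocks (>= 1, default 3).
#' @param hidden_dim Embedding width of every block (default 16).
#' @param set2set_steps Set2Set processing steps (default 3).
#' @param classifier_dim Hidden width of the classifier head (default 16).
#' @param dropout Dropout rate on the classifier hidden layer during
#'   training (default 0.1).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param epochs Training epochs (default 30).
#' @param batch_size Graphs per gradient step (default 32).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param attention_enabled `FALSE` replaces the attention propagation by
#'   the symmetric-normalised equal propagation operator (the
#'   GIN-with-equal-propagation ablation).
#' @return A `gnn_config` list.
#' @export
gnn_config <- function(n_blocks = 3L, hidden_dim = 16L, set2set_steps = 3L,
                       classifier_dim = 16L, dropout = 0.1,
                       learning_rate = 0.01, epochs = 30L, batch_size = 32L,
                       seed = 1L, attention_enabled = TRUE) {
  stopifnot(n_blocks >= 1L, hidden_dim > 0L, set2set_steps >= 1L,
            classifier_dim > 0L, dropout >= 0, dropout < 1,
            learning_rate > 0, epochs >= 1L, batch_size >= 1L)
  structure(list(n_blocks = as.integer(n_blocks),
                 hidden_dim = as.integer(hidden_dim),
                 set2set_steps = as.integer(set2set_steps),
                 classifier_dim = as.integer(classifier_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 attention_enabled = isTRUE(attention_enabled)),
            class = "gnn_config")
}

#' Initialise a GNN model
#'
#' Draws all trainable parameters: per block a scalar attention
#' temperature `beta` (init 1), a GIN self-weight `eps` (init 0), and the
#' two-layer transform weights (uniform Glorot); the Set2Set LSTM weights;
#' and the classifier head.  Uses the R RNG, so results are reproducible
#' under `set.seed()` / `config$seed`.
#'
#' @param config A [gnn_config()].
#' @param in_dim Input feature dimension (7 for [encode_features()]).
#' @param seed Optional seed; defaults to `config$seed`.
#' @return A `gnn_model` object with elements `params` (flat named list)
#'   and `config`.
#' @export
init_gnn <- function(config = gnn_config(), in_dim = 7L, seed = NULL) {
  set.seed(seed %||% config$seed)
  h <- config$hidden_dim
  glorot <- function(nin, nout) {
    s <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -s, s), nin, nout)
  }
  params <- list()
  d_in <- in_dim
  for (t in seq_len(config$n_blocks)) {
    params[[paste0("block", t, "_beta")]] <- 1
    params[[paste0("block", t, "_eps")]] <- 0
    params[[paste0("block", t, "_W1")]] <- glorot(d_in, h)
    params[[paste0("block", t, "_b1")]] <- numeric(h)
    params[[paste0("block", t, "_W2")]] <- glorot(h, h)
    params[[paste0("block", t, "_b2")]] <- numeric(h)
    d_in <- h
  }
  params$s2s_W <- glorot(3L * h, 4L * h)
  params$s2s_b <- c(numeric(h), rep(1, h), numeric(2L * h))  # forget bias 1
  params$cls_W1 <- glorot(2L * h, config$classifier_dim)
  params$cls_b1 <- numeric(config$classifier_dim)
  params$cls_W2 <- glorot(config$classifier_dim, 2L)
  params$cls_b2 <- numeric(2L)
  structure(list(params = params, config = config, in_dim = in_dim),
            class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gnn_model> %d blocks (hidden %d, attention %s), Set2Set %d steps, classifier %d\n",
    cfg$n_blocks, cfg$hidden_dim,
    ifelse(cfg$attention_enabled, "on", "off"),
    cfg$set2set_steps, cfg$classifier_dim))
  cat(sprintf("  %d trainable parameters\n",
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

block_par <- function(params, t) {
  list(beta = params[[paste0("block", t, "_beta")]],
       eps = params[[paste0("block", t, "_eps")]],
       W1 = params[[paste0("block", t, "_W1")]],
       b1 = params[[paste0("block", t, "_b1")]],
       W2 = params[[paste0("block", t, "_W2")]],
       b2 = params[[paste0("block", t, "_b2")]])
}

# Precompute per-graph quantities used by every forward/backward pass.
gnn_graph_data <- function(g) {
  X0 <- g$X %||% encode_features(g)
  A <- graph_adjacency(g)
  n <- nrow(X0)
  list(X0 = X0, mask = (A != 0) | diag(TRUE, n), P = equal_operator(A),
       label = g$label, n = n)
}

# Full forward pass; drop_mask (vector or NULL) applies inverted dropout
# to the classifier hidden layer.
gnn_forward <- function(params, config, gdata, drop_mask = NULL,
                        keep_cache = FALSE) {
  X <- gdata$X0
  blocks <- vector("list", config$n_blocks)
  outs <- vector("list", config$n_blocks)
  for (t in seq_len(config$n_blocks)) {
    cache <- block_forward(X, gdata$mask, gdata$P, block_par(params, t),
                           attention = config$attention_enabled)
    if (!all(is.finite(cache$Xout))) {
      stop("non-finite values in convolution block ", t, call. = FALSE)
    }
    blocks[[t]] <- cache
    outs[[t]] <- cache$Xout
    X <- cache$Xout
  }
  jk <- jk_forward(outs)
  s2s <- set2set_forward(jk$agg, list(W = params$s2s_W, b = params$s2s_b),
                         config$set2set_steps)
  q <- s2s$q_star
  u1p <- drop(q %*% params$cls_W1) + params$cls_b1
  u1 <- pmax(u1p, 0)
  ud <- if (is.null(drop_mask)) u1 else u1 * drop_mask
  logits <- drop(ud %*% params$cls_W2) + params$cls_b2
  p <- softmax_vec(logits)
  res <- list(prob = p[2L], logits = logits)
  if (keep_cache) {
    res$cache <- list(blocks = blocks, jk = jk, s2s = s2s, q = q,
                      u1p = u1p, u1 = u1, ud = ud, drop_mask = drop_mask,
                      p = p)
  }
  res
}

# Backward pass for one graph given the forward cache; returns the
# gradient of the cross-entropy loss for `label` (0/1) w.r.t. every
# parameter, as a flat named list aligned with `params`.
gnn_backward <- function(params, config, gdata, cache, label) {
  grads <- lapply(params, function(p) p * 0)
  target <- c(1 - label, label)
  dlogits <- cache$p - target
  grads$cls_W2 <- outer(cache$ud, dlogits)
  grads$cls_b2 <- dlogits
  dud <- drop(params$cls_W2 %*% dlogits)
  du1 <- if (is.null(cache$drop_mask)) dud else dud * cache$drop_mask
  du1p <- du1 * (cache$u1p > 0)
  grads$cls_W1 <- outer(cache$q, du1p)
  grads$cls_b1 <- du1p
  dq <- drop(params$cls_W1 %*% du1p)

  s2s <- set2set_backward(cache$s2s, cache$jk$agg,
                          list(W = params$s2s_W, b = params$s2s_b), dq)
  grads$s2s_W <- s2s$dW
  grads$s2s_b <- s2s$db

  dblocks <- jk_backward(cache$jk, s2s$dX, config$n_blocks)
  dX_next <- NULL
  for (t in rev(seq_len(config$n_blocks))) {
    dXout <- dblocks[[t]]
    if (!is.null(dX_next)) dXout <- dXout + dX_next
    bb <- block_backward(cache$blocks[[t]], block_par(params, t), dXout)
    pre <- paste0("block", t, "_")
    grads[[paste0(pre, "beta")]] <- bb$grads$beta
    grads[[paste0(pre, "eps")]] <- bb$grads$eps
    grads[[paste0(pre, "W1")]] <- bb$grads$W1
    grads[[paste0(pre, "b1")]] <- bb$grads$b1
    grads[[paste0(pre, "W2")]] <- bb$grads$W2
    grads[[paste0(pre, "b2")]] <- bb$grads$b2
    dX_next <- bb$dX
  }
  grads
}

#' Predicted probability of a cytotoxic response for one graph
#'
#' Runs the full deterministic forward pass (no dropout): three
#' convolution blocks, jumping-knowledge max-pooling, Set2Set readout,
#' classifier head, softmax.  The output is invariant to node reordering.
#'
#' @param graph A reduced, feature-encoded `cancer_graph`.
#' @param model A `gnn_model` from [init_gnn()] or [train_model()].
#' @return Probability in \[0, 1\] of the positive (cytotoxic) class.
#' @export
model_forward <- function(graph, model) {
  if (is.null(graph$X)) stop("graph has no encoded feature matrix",
                             call. = FALSE)
  gnn_forward(model$params, model$config, gnn_graph_data(graph))$prob
}

#' Predict drug response for a list of graphs
#'
#' @param model A `gnn_model`.
#' @param graphs List of `cancer_graph` objects.
#' @param threshold Decision threshold on the cytotoxic-class probability
#'   (default 0.5).
#' @return Tibble with `cell_line`, `drug`, `tissue`, `label` (may be
#'   `NA`), `prob`, `pred`.
#' @export
predict_response <- function(model, graphs, threshold = 0.5) {
  tibble::tibble(
    cell_line = vapply(graphs, function(g) g$cell_line, character(1)),
    drug = vapply(graphs, function(g) g$drug, character(1)),
    tissue = vapply(graphs, function(g) g$tissue, character(1)),
    label = vapply(graphs, function(g) as.integer(g$label), integer(1)),
    prob = vapply(graphs, model_forward, numeric(1), model = model),
    pred = NA_integer_
  ) |>
    dplyr::mutate(pred = as.integer(.data$prob >= threshold))
}

checkpoint_format_version <- "1.0"

#' Save a model checkpoint
#'
#' Writes the configuration and every named parameter array (with shapes)
#' to a single JSON file.
#'
#' @param model A `gnn_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  ser <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.numeric(p))
  })
  obj <- list(format_version = checkpoint_format_version,
              config = unclass(model$config), in_dim = model$in_dim,
              params = ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return The restored `gnn_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, checkpoint_format_version)) {
    stop("checkpoint format version mismatch", call. = FALSE)
  }
  cfg <- do.call(gnn_config, obj$config[names(formals(gnn_config))])
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  structure(list(params = params, config = cfg,
                 in_dim = as.integer(obj$in_dim)),
            class = "gnn_model")
}
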