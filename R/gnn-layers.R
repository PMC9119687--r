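#' Attention propagation matrix
#'
#' Computes the row-stochastic propagation matrix \eqn{\Gamma} whose entry
#' \eqn{\gamma_{i,j}} is the softmax, over node \eqn{i}'s neighbourhood
#' \eqn{N(i) \cup \{i\}}, of \eqn{\beta \cos(x_i, x_j)}: the attention a
#' node pays to each neighbour is driven purely by feature-space cosine
#' similarity, sharpened or inverted by the trainable temperature
#' \eqn{\beta}.  Edge confidence weights do not enter the attention;
#' adjacency only defines the neighbourhoods.  Cosine with an all-zero
#' feature row is defined as 0 (norms are floored at 1e-12).
#'
#' @param X Numeric node-feature matrix (one row per node, no all-zero
#'   rows expected for the raw encoding; zero rows are tolerated via the
#'   floor).
#' @param adj Symmetric adjacency matrix (any nonzero entry is an edge) or
#'   a `cancer_graph`.
#' @param beta Scalar attention temperature.
#' @return Row-stochastic matrix with support exactly
#'   \eqn{N(i) \cup \{i\}}.
#' @export
attention_matrix <- function(X, adj, beta) {
  if (inherits(adj, "cancer_graph")) adj <- graph_adjacency(adj)
  n <- nrow(X)
  if (nrow(adj) != n || ncol(adj) != n) {
    stop("adjacency dimensions do not match the feature matrix",
         call. = FALSE)
  }
  att <- attention_forward(X, (adj != 0) | diag(TRUE, n), beta)
  att$Gamma
}

# Forward with cache: mask must include the diagonal.
attention_forward <- function(X, mask, beta, floor = 1e-12) {
  norms <- sqrt(rowSums(X^2))
  nf <- pmax(norms, floor)
  Xn <- X / nf
  C <- tcrossprod(Xn)
  S <- beta * C
  S[!mask] <- -Inf
  S <- S - apply(S, 1L, max)            # all rows have >= 1 support entry
  E <- exp(S)
  Gamma <- E / rowSums(E)
  list(Gamma = Gamma, C = C, Xn = Xn, nf = nf, norms = norms, mask = mask)
}

#' Symmetric-normalised equal propagation
#'
#' The attention-free propagation operator
#' \eqn{X' = D^{-1/2} A D^{-1/2} X}, which transmits information equally
#' to all neighbours regardless of their content.  Used as the ablation
#' baseline when attention is disabled.  Isolated nodes pass their
#' features through unchanged.
#'
#' @param A Symmetric 0/1 adjacency matrix with zero diagonal, or a
#'   `cancer_graph`.
#' @param X Node-feature matrix.
#' @return Propagated feature matrix of the same shape.
#' @export
equal_propagation <- function(A, X) {
  equal_operator(A) %*% X
}

# D^{-1/2} A D^{-1/2} with identity rows for isolated nodes.
equal_operator <- function(A) {
  if (inherits(A, "cancer_graph")) A <- graph_adjacency(A)
  A <- (A != 0) * 1
  d <- rowSums(A)
  inv <- ifelse(d > 0, 1 / sqrt(d), 0)
  P <- A * outer(inv, inv)
  iso <- d == 0
  if (any(iso)) diag(P)[iso] <- 1
  P
}

#' One graph convolution block: attention propagation + GIN update
#'
#' Applies \eqn{X' = \Theta(\Gamma X + (1 + \epsilon) X)}: neighbour
#' features aggregated through the attention propagation matrix
#' \eqn{\Gamma} (or the equal-propagation operator when attention is
#' disabled), combined with the \eqn{(1+\epsilon)}-scaled self features as
#' in the graph isomorphism network update, then transformed by the
#' two-layer network \eqn{\Theta} (ReLU activations).
#'
#' @param X Input embedding matrix (n x in_dim).
#' @param graph A `cancer_graph` or symmetric adjacency matrix.
#' @param block Block parameter list with elements `beta`, `eps`, `W1`,
#'   `b1`, `W2`, `b2`, and optionally `attention_enabled` (default
#'   `TRUE`).
#' @return Updated embedding matrix (n x out_dim).
#' @export
conv_block_forward <- function(X, graph, block) {
  adj <- if (inherits(graph, "cancer_graph")) graph_adjacency(graph) else graph
  attn <- block$attention_enabled %||% TRUE
  mask <- (adj != 0) | diag(TRUE, nrow(adj))
  P <- if (attn) NULL else equal_operator(adj)
  out <- block_forward(X, mask, P, block, attention = attn)
  if (!all(is.finite(out$Xout))) {
    stop("non-finite values in convolution block output", call. = FALSE)
  }
  out$Xout
}

block_forward <- function(X, mask, P, par, attention = TRUE) {
  if (attention) {
    att <- attention_forward(X, mask, par$beta)
    Gamma <- att$Gamma
  } else {
    att <- NULL
    Gamma <- P
  }
  H <- Gamma %*% X + (1 + par$eps) * X
  Z1p <- sweep(H %*% par$W1, 2L, par$b1, "+")
  Z1 <- pmax(Z1p, 0)
  Z2p <- sweep(Z1 %*% par$W2, 2L, par$b2, "+")
  Xout <- pmax(Z2p, 0)
  list(X = X, att = att, Gamma = Gamma, H = H, Z1p = Z1p, Z1 = Z1,
       Z2p = Z2p, Xout = Xout, attention = attention)
}

# Backward through one block.  Returns gradient w.r.t. the block input and
# parameter gradients.  The cosine-similarity path into the input features
# is included.
block_backward <- function(cache, par, dXout, floor = 1e-12) {
  dZ2p <- dXout * (cache$Z2p > 0)
  dW2 <- crossprod(cache$Z1, dZ2p)
  db2 <- colSums(dZ2p)
  dZ1 <- tcrossprod(dZ2p, par$W2)
  dZ1p <- dZ1 * (cache$Z1p > 0)
  dW1 <- crossprod(cache$H, dZ1p)
  db1 <- colSums(dZ1p)
  dH <- tcrossprod(dZ1p, par$W1)

  X <- cache$X
  deps <- sum(dH * X)
  dX <- crossprod(cache$Gamma, dH) + (1 + par$eps) * dH

  dbeta <- 0
  if (cache$attention) {
    att <- cache$att
    dGamma <- tcrossprod(dH, X)
    rowdot <- rowSums(cache$Gamma * dGamma)
    dS <- cache$Gamma * (dGamma - rowdot)   # zero off the support
    dbeta <- sum(dS * att$C)
    dC <- par$beta * dS
    dXn <- (dC + t(dC)) %*% att$Xn
    dXcos <- (dXn - att$Xn * rowSums(dXn * att$Xn)) / att$nf
    dXcos[att$norms < floor, ] <- 0
    dX <- dX + dXcos
  }
  list(dX = dX, grads = list(beta = dbeta, eps = deps, W1 = dW1, b1 = db1,
                             W2 = dW2, b2 = db2))
}

#' Jumping-knowledge max-pool aggregation
#'
#' Element-wise maximum of the per-block embedding matrices: for each node
#' and feature coordinate, the most informative block wins, letting the
#' network choose an effective neighbourhood radius per coordinate without
#' extra parameters.
#'
#' @param embeddings List of matrices of identical shape (one per block).
#' @return Matrix of the same shape.
#' @export
jk_max_pool <- function(embeddings) {
  stopifnot(length(embeddings) >= 1L)
  dims <- dim(embeddings[[1]])
  for (m in embeddings) {
    if (!identical(dim(m), dims)) {
      stop("jumping-knowledge inputs must share one shape", call. = FALSE)
    }
  }
  Reduce(pmax, embeddings)
}

# Max-pool with argmax cache (first block attaining the max wins ties).
jk_forward <- function(embeddings) {
  agg <- embeddings[[1]]
  which_max <- array(1L, dim = dim(agg))
  for (t in seq_along(embeddings)[-1]) {
    upd <- embeddings[[t]] > agg
    agg[upd] <- embeddings[[t]][upd]
    which_max[upd] <- t
  }
  list(agg = agg, which_max = which_max)
}

jk_backward <- function(cache, dagg, n_blocks) {
  lapply(seq_len(n_blocks), function(t) dagg * (cache$which_max == t))
}

#' Set2Set readout
#'
#' Permutation-invariant pooling of a node-embedding set: a recurrent
#' (LSTM) query vector attends over the nodes at each step, the
#' attention-weighted sum of node embeddings is concatenated back onto
#' the query, and after the final step the concatenated vector (length
#' `2 * ncol(X)`) summarises the graph.  Attention weights are the
#' softmax of dot products between the query and node embeddings.
#'
#' @param X Node-embedding matrix (n x h), n >= 1.
#' @param params List with `W` (3h x 4h LSTM weight matrix, gate order
#'   input/forget/output/candidate) and `b` (length 4h bias); see
#'   [init_gnn()] for initialisation.
#' @param steps Number of processing steps (>= 1).
#' @return Numeric vector of length 2h.
#' @export
set2set_readout <- function(X, params, steps = 3L) {
  stopifnot(steps >= 1L)
  if (nrow(X) == 0L) stop("empty node set", call. = FALSE)
  set2set_forward(X, params, steps)$q_star
}

set2set_forward <- function(X, params, steps) {
  h <- ncol(X)
  q_star <- numeric(2L * h)
  hh <- numeric(h)
  cc <- numeric(h)
  caches <- vector("list", steps)
  for (s in seq_len(steps)) {
    z <- c(q_star, hh)
    gates <- drop(z %*% params$W) + params$b
    gi <- sigmoid(gates[seq_len(h)])
    gf <- sigmoid(gates[h + seq_len(h)])
    go <- sigmoid(gates[2L * h + seq_len(h)])
    gg <- tanh(gates[3L * h + seq_len(h)])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    hh_prev <- hh
    hh <- go * tc
    e <- drop(X %*% hh)
    a <- softmax_vec(e)
    r <- drop(crossprod(X, a))
    caches[[s]] <- list(z = z, gi = gi, gf = gf, go = go, gg = gg,
                        c_prev = c_prev, cc = cc, tc = tc, hh = hh,
                        a = a, r = r)
    q_star <- c(hh, r)
  }
  list(q_star = q_star, caches = caches, steps = steps)
}

set2set_backward <- function(cache, X, params, dq_star) {
  h <- ncol(X)
  dW <- params$W * 0
  db <- params$b * 0
  dX <- X * 0
  dh_carry <- numeric(h)
  dc_carry <- numeric(h)
  for (s in rev(seq_len(cache$steps))) {
    st <- cache$caches[[s]]
    dhh <- dq_star[seq_len(h)]
    dr <- dq_star[h + seq_len(h)]
    # r = X^T a
    da <- drop(X %*% dr)
    dX <- dX + outer(st$a, dr)
    # a = softmax(e), e = X q  (q = hh)
    de <- st$a * (da - sum(st$a * da))
    dhh <- dhh + drop(crossprod(X, de)) + dh_carry
    dX <- dX + outer(de, st$hh)
    # LSTM cell
    dgo <- dhh * st$tc
    dc <- dhh * st$go * (1 - st$tc^2) + dc_carry
    dgi <- dc * st$gg
    dgg <- dc * st$gi
    dgf <- dc * st$c_prev
    dc_carry <- dc * st$gf
    dgates <- c(dgi * st$gi * (1 - st$gi),
                dgf * st$gf * (1 - st$gf),
                dgo * st$go * (1 - st$go),
                dgg * (1 - st$gg^2))
    dW <- dW + outer(st$z, dgates)
    db <- db + dgates
    dz <- drop(params$W %*% dgates)
    dq_star <- dz[seq_len(2L * h)]       # x = previous q_star
    dh_carry <- dz[2L * h + seq_len(h)]
  }
  list(dX = dX, dW = dW, db = db)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}
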