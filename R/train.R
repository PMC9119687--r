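#' Train the GNN on a set of labeled graphs
#'
#' Minimises the cross-entropy of the two-class softmax output with
#' mini-batch Adam.  All randomness (initialisation, epoch shuffling,
#' dropout) is driven by `config$seed`, so a fixed seed reproduces the
#' training log exactly.
#'
#' @param graphs List of labeled, reduced `cancer_graph` objects; both
#'   classes must be present.
#' @param config A [gnn_config()].
#' @param quiet Suppress per-epoch messages.
#' @return A `gnn_fit` object: the trained `gnn_model` plus a `log` tibble
#'   (`epoch`, `loss`) of mean training loss per epoch.
#' @export
train_model <- function(graphs, config = gnn_config(), quiet = TRUE) {
  labels <- vapply(graphs, function(g) as.integer(g$label), integer(1))
  if (anyNA(labels)) stop("all training graphs must be labeled",
                          call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  set.seed(config$seed)
  model <- init_gnn(config, in_dim = ncol(graphs[[1]]$X %||%
                                            encode_features(graphs[[1]])),
                    seed = config$seed)
  gdata <- lapply(graphs, gnn_graph_data)
  opt <- adam_init(model$params, config$learning_rate)
  n <- length(graphs)
  log <- tibble::tibble(epoch = integer(0), loss = numeric(0))
  hdim <- config$classifier_dim
  use_dropout <- config$dropout > 0

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        dm <- if (use_dropout) {
          (stats::runif(hdim) >= config$dropout) / (1 - config$dropout)
        } else NULL
        fw <- gnn_forward(model$params, config, gdata[[i]], drop_mask = dm,
                          keep_cache = TRUE)
        y <- labels[i]
        p <- max(fw$cache$p[y + 1L], 1e-12)
        ep_loss <- ep_loss - log(p)
        g <- gnn_backward(model$params, config, gdata[[i]], fw$cache, y)
        acc <- if (is.null(acc)) g else
          Map(function(a, b) a + b, acc, g)
      }
      acc <- lapply(acc, function(g) g / length(idx))
      upd <- adam_step(opt, model$params, acc)
      model$params <- upd$params
      opt <- upd$opt
    }
    log <- dplyr::bind_rows(log,
                            tibble::tibble(epoch = epoch, loss = ep_loss / n))
    if (!quiet) message(sprintf("epoch %3d  loss %.4f", epoch, ep_loss / n))
  }
  structure(list(model = model, log = log,
                 n_train = n, class_counts = table(labels)),
            class = "gnn_fit")
}

#' @export
print.gnn_fit <- function(x, ...) {
  cat(sprintf("<gnn_fit> trained on %d graphs, final loss %.4f (%d epochs)\n",
              x$n_train, utils::tail(x$log$loss, 1), nrow(x$log)))
  invisible(x)
}

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1t <- 1 - opt$beta1^opt$t
  b2t <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[nm]] / b1t
    vhat <- opt$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(params = params, opt = opt)
}
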