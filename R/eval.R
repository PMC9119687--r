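#' Leave-one-tissue-out fold assignment
#'
#' Builds one cross-validation fold per distinct tissue group: all
#' instances whose cell line originates from that tissue form the
#' validation set and everything else forms the training set.  Because
#' each cell line belongs to exactly one tissue, no cell line (and no
#' tissue) is ever shared between training and validation — the split
#' that keeps performance estimates honest when many instances share
#' cell lines.  Folds are ordered by tissue name, so the assignment is
#' deterministic and independent of any model seed.
#'
#' @param instances Tibble with at least `instance_id` and `cell_line`
#'   columns, or a list of `cancer_graph` objects.
#' @param tissue_of Either `NULL` (tissue taken from a `tissue` column /
#'   graph field) or a tibble `cell_line`, `tissue`.
#' @return Tibble with `fold`, `held_out_tissue`, `train_ids`, `val_ids`
#'   (list-columns of instance ids).
#' @export
make_tissue_folds <- function(instances, tissue_of = NULL) {
  inst <- instances_table(instances)
  if (!is.null(tissue_of)) {
    tissue_of <- tibble::as_tibble(tissue_of)
    inst$tissue <- tissue_of$tissue[match(inst$cell_line,
                                          tissue_of$cell_line)]
  }
  if (anyNA(inst$tissue)) stop("every instance needs a tissue group",
                               call. = FALSE)
  tissues <- sort(unique(inst$tissue))
  if (length(tissues) < 2L) {
    stop("cannot cross-validate with a single tissue group", call. = FALSE)
  }
  tibble::tibble(
    fold = seq_along(tissues),
    held_out_tissue = tissues,
    train_ids = lapply(tissues,
                       function(ts) inst$instance_id[inst$tissue != ts]),
    val_ids = lapply(tissues,
                     function(ts) inst$instance_id[inst$tissue == ts])
  )
}

instances_table <- function(instances) {
  if (is.data.frame(instances)) return(tibble::as_tibble(instances))
  tibble::tibble(
    instance_id = vapply(instances,
                         function(g) paste(g$cell_line, g$drug, sep = "|"),
                         character(1)),
    cell_line = vapply(instances, function(g) g$cell_line, character(1)),
    tissue = vapply(instances, function(g) g$tissue, character(1)),
    label = vapply(instances, function(g) as.integer(g$label), integer(1))
  )
}

#' Classification metrics for drug-response prediction
#'
#' AUC is computed with the rank statistic (ties counted one half);
#' precision, recall, balanced accuracy (mean of per-class recalls, which
#' corrects for class imbalance) and the F-measure (harmonic mean of
#' precision and recall) are computed at the given decision threshold.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted probabilities in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report`: list with `auc`, `balanced_accuracy`,
#'   `precision`, `recall`, `f_measure`, `n_pos`, `n_neg`, and a
#'   `roc_points` tibble (`fpr`, `tpr` stepping through every score
#'   cutoff).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one instance of each class",
         call. = FALSE)
  }
  r <- rank(scores)                      # average ranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  recall_neg <- tn / (tn + fp)
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0

  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord] == 1) / n_pos
  fpr <- cumsum(labels[ord] == 0) / n_neg
  keep <- rev(!duplicated(rev(scores[ord])))   # last index per tied block
  roc <- tibble::tibble(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))

  structure(list(auc = auc,
                 balanced_accuracy = (recall + recall_neg) / 2,
                 precision = precision, recall = recall, f_measure = f,
                 n_pos = n_pos, n_neg = n_neg, roc_points = roc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> AUC %.3f | bal.acc %.3f | precision %.3f | recall %.3f | F %.3f (%d+/%d-)\n",
              x$auc, x$balanced_accuracy, x$precision, x$recall,
              x$f_measure, x$n_pos, x$n_neg))
  invisible(x)
}

#' Tissue-level grouped cross-validation
#'
#' For every leave-one-tissue-out fold, a fresh model is initialised with
#' a fold-specific seed (derived from `config$seed` so folds never share
#' initialisation state), trained on the training tissues only, and
#' evaluated on the held-out tissue.  Fold assignment is independent of
#' the model seed.
#'
#' @param graphs List of labeled, reduced `cancer_graph` objects.
#' @param config A [gnn_config()].
#' @param tissue_of Optional `cell_line` to `tissue` mapping tibble (see
#'   [make_tissue_folds()]).
#' @param threshold Decision threshold passed to [compute_metrics()].
#' @param quiet Suppress per-fold messages.
#' @return A `cv_result`: list with `folds` (fold table), `per_fold`
#'   (tibble of fold metrics), `summary` (mean and sd per metric),
#'   `pooled_roc` (ROC over the pooled out-of-fold predictions, labeled
#'   as such next to the per-fold curves in `roc`), and `predictions`.
#' @export
cross_validate <- function(graphs, config = gnn_config(), tissue_of = NULL,
                           threshold = 0.5, quiet = TRUE) {
  inst <- instances_table(graphs)
  if (!is.null(tissue_of)) {
    tissue_of <- tibble::as_tibble(tissue_of)
    inst$tissue <- tissue_of$tissue[match(inst$cell_line,
                                          tissue_of$cell_line)]
  }
  folds <- make_tissue_folds(inst)
  ids <- inst$instance_id
  per_fold <- vector("list", nrow(folds))
  roc <- vector("list", nrow(folds))
  preds <- vector("list", nrow(folds))
  for (k in seq_len(nrow(folds))) {
    tr <- graphs[ids %in% folds$train_ids[[k]]]
    va <- graphs[ids %in% folds$val_ids[[k]]]
    cfg <- config
    cfg$seed <- (config$seed + 1009L * k) %% .Machine$integer.max
    fit <- train_model(tr, cfg)
    pr <- predict_response(fit$model, va, threshold)
    m <- compute_metrics(pr$label, pr$prob, threshold)
    per_fold[[k]] <- tibble::tibble(
      fold = k, held_out_tissue = folds$held_out_tissue[k],
      n_val = nrow(pr), auc = m$auc,
      balanced_accuracy = m$balanced_accuracy, precision = m$precision,
      recall = m$recall, f_measure = m$f_measure)
    roc[[k]] <- dplyr::mutate(m$roc_points, fold = k,
                              held_out_tissue = folds$held_out_tissue[k])
    preds[[k]] <- dplyr::mutate(pr, fold = k)
    if (!quiet) message(sprintf("fold %d (%s): AUC %.3f", k,
                                folds$held_out_tissue[k], m$auc))
  }
  per_fold <- dplyr::bind_rows(per_fold)
  predictions <- dplyr::bind_rows(preds)
  pooled <- compute_metrics(predictions$label, predictions$prob, threshold)
  metric_cols <- c("auc", "balanced_accuracy", "precision", "recall",
                   "f_measure")
  summ <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(cl) mean(per_fold[[cl]]),
                  numeric(1)),
    sd = vapply(metric_cols, function(cl) stats::sd(per_fold[[cl]]),
                numeric(1))
  )
  structure(list(folds = folds, per_fold = per_fold, summary = summ,
                 roc = dplyr::bind_rows(roc),
                 pooled_roc = pooled$roc_points,
                 pooled_metrics = pooled, predictions = predictions,
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  a <- x$summary[x$summary$metric == "auc", ]
  cat(sprintf("<cv_result> %d tissue folds, AUC %.3f +/- %.3f\n",
              nrow(x$per_fold), a$mean, a$sd))
  invisible(x)
}
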