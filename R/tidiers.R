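#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "balanced_accuracy", "precision", "recall",
               "f_measure"),
    value = c(x$auc, x$balanced_accuracy, x$precision, x$recall,
              x$f_measure))
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(auc = x$auc, balanced_accuracy = x$balanced_accuracy,
                 precision = x$precision, recall = x$recall,
                 f_measure = x$f_measure, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @export
tidy.cv_result <- function(x, ...) x$per_fold

#' @export
glance.cv_result <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(n_folds = nrow(x$per_fold))
  for (i in seq_len(nrow(s))) {
    out[[s$metric[i]]] <- s$mean[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
  }
  out
}

#' @export
tidy.gnn_fit <- function(x, ...) x$log

#' @export
glance.gnn_fit <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, epochs = nrow(x$log),
                 final_loss = utils::tail(x$log$loss, 1))
}

#' @export
tidy.reduction_map <- function(x, ...) reduction_stats(x)

#' ROC curve of a metrics report
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Per-fold and pooled ROC curves of a cross-validation
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object: one thin curve per held-out tissue plus the
#'   pooled out-of-fold curve.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(.data$fpr, .data$tpr,
                               group = .data$held_out_tissue,
                               colour = .data$held_out_tissue)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(alpha = 0.7) +
    ggplot2::geom_step(data = object$pooled_roc,
                       ggplot2::aes(.data$fpr, .data$tpr),
                       inherit.aes = FALSE, linewidth = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Held-out tissue",
                  title = "Leave-one-tissue-out ROC (bold: pooled)") +
    ggplot2::theme_minimal()
}

#' Training-loss curve
#'
#' @param object A `gnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gnn_fit <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Mean cross-entropy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
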