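#' Tidy a cross-validation report
#'
#' @param x A `pmgae_cv` object.
#' @param ... Unused.
#' @return Tibble of per-fold metrics (one row per repeat x fold).
#' @method tidy pmgae_cv
#' @export
tidy.pmgae_cv <- function(x, ...) {
  x$per_fold
}

#' One-row summary of a cross-validation report
#'
#' @param x A `pmgae_cv` object.
#' @param ... Unused.
#' @return One-row tibble of metric means across folds and repeats.
#' @method glance pmgae_cv
#' @export
glance.pmgae_cv <- function(x, ...) {
  x$mean
}

#' @export
print.pmgae_cv <- function(x, ...) {
  cat("cross-validation report:", max(x$per_fold$repeat_id), "repeat(s) x",
      max(x$per_fold$fold), "folds\n")
  m <- glance(x)
  cat(sprintf("  mean AUC %.4f  AUPR %.4f  Acc %.4f  MCC %.4f\n",
              m$auc, m$aupr, m$accuracy, m$mcc))
  invisible(x)
}

#' Tidy a graph-auto-encoder fit
#'
#' @param x A `pmgae_gae` object.
#' @param ... Unused.
#' @return Tibble with `epoch` and reconstruction `loss`.
#' @method tidy pmgae_gae
#' @export
tidy.pmgae_gae <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' One-row summary of a graph-auto-encoder fit
#'
#' @param x A `pmgae_gae` object.
#' @param ... Unused.
#' @return One-row tibble: node count, embedding dim, epochs, first/final
#'   loss.
#' @method glance pmgae_gae
#' @export
glance.pmgae_gae <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$Z), embedding_dim = ncol(x$Z), epochs = x$epochs,
    initial_loss = x$loss_history[1],
    final_loss = x$loss_history[length(x$loss_history)]
  )
}

#' Plot the training loss curve of a graph-auto-encoder fit
#'
#' @param object A `pmgae_gae` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmgae_gae
#' @export
autoplot.pmgae_gae <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "reconstruction loss",
                  title = "Graph auto-encoder training") +
    ggplot2::theme_minimal()
}

# ROC / PR point sets from pooled per-fold predictions
roc_pr_points <- function(predictions) {
  grp <- dplyr::group_by(predictions, .data$repeat_id, .data$fold)
  dplyr::reframe(grp, {
    ord <- order(.data$score, decreasing = TRUE)
    lab <- .data$label[ord]
    tp <- cumsum(lab); fp <- cumsum(1 - lab)
    tibble::tibble(
      fpr = fp / max(sum(lab == 0), 1),
      tpr = tp / max(sum(lab == 1), 1),
      precision = tp / (tp + fp),
      recall = tp / max(sum(lab == 1), 1)
    )
  })
}

#' Plot ROC and precision-recall curves of a cross-validation report
#'
#' One curve per fold, pooled across repeats.
#'
#' @param object A `pmgae_cv` object.
#' @param type `"roc"` (default) or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmgae_cv
#' @export
autoplot.pmgae_cv <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  pts <- roc_pr_points(object$predictions)
  pts$curve <- interaction(pts$repeat_id, pts$fold)
  if (type == "roc") {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                      group = .data$curve)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           color = "grey60") +
      ggplot2::geom_line(alpha = 0.5, color = "steelblue") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    title = sprintf("ROC per fold (mean AUC %.3f)",
                                    glance(object)$auc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$recall, y = .data$precision,
                                      group = .data$curve)) +
      ggplot2::geom_line(alpha = 0.5, color = "firebrick") +
      ggplot2::labs(x = "recall", y = "precision",
                    title = sprintf("Precision-recall per fold (mean AUPR %.3f)",
                                    glance(object)$aupr)) +
      ggplot2::theme_minimal()
  }
}
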