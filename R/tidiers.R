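#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_col labs facet_wrap
#' @export
ggplot2::autoplot

#' @rdname count_parameters
#' @param x object to tidy/plot.
#' @param ... unused.
#' @export
tidy.param_audit <- function(x, ...) x$layers

#' @rdname count_parameters
#' @export
glance.param_audit <- function(x, ...) {
  tibble::tibble(total = x$total, trainable_total = x$trainable_total,
                 n_layers = nrow(x$layers))
}

#' @rdname self_train
#' @param x object to tidy/plot.
#' @param ... unused.
#' @export
tidy.self_train_state <- function(x, ...) x$history

#' @rdname self_train
#' @export
glance.self_train_state <- function(x, ...) {
  tibble::tibble(rounds = x$round,
                 labeled = length(x$labeled_ids),
                 unlabeled = length(x$unlabeled_ids),
                 test = length(x$test_ids),
                 pseudo_labeled = length(x$pseudo_label_map),
                 final_test_acc = if (nrow(x$history)) dplyr::last(x$history$test_acc)
                                  else NA_real_)
}

#' @rdname evaluate_model
#' @param x object to tidy/plot.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(glance.eval_report(x), -dplyr::all_of(c("magnification", "n")),
                      names_to = "metric", values_to = "value")
}

#' @rdname evaluate_model
#' @export
glance.eval_report <- function(x, ...) magnification_report(list(x), x$magnification)

#' Training-curve plot
#'
#' Loss and accuracy per epoch.
#'
#' @param object `train_history` tibble from [train_model()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.train_history <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(c("loss", "accuracy")),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, title = "Training history")
}

#' Self-training progress plot
#'
#' Labeled-pool growth and train/test accuracy per round.
#'
#' @param object `self_train_state`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.self_train_state <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h, dplyr::all_of(c("labeled_size", "train_acc", "test_acc")),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$round, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "self-training round", y = NULL,
         title = "Pseudo-label self-training progress")
}

#' ROC curve plot
#'
#' Per-class ROC curves with the chance diagonal.
#'
#' @param object `eval_report` with ROC points.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc_points)) abort("report carries no ROC points")
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr, colour = .data$class)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    labs(x = "false-positive rate", y = "true-positive rate",
         title = sprintf("ROC (%s magnification)", object$magnification))
}

#' Count-summary plot
#'
#' Images per magnification and class.
#'
#' @param object `count_summary`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.count_summary <- function(object, ...) {
  ggplot(object$table,
         aes(x = factor(.data$magnification), y = .data$count, fill = .data$class_label)) +
    geom_col(position = "dodge") +
    labs(x = "magnification (X)", y = "images", fill = "class",
         title = "Sample counts by magnification and class")
}

#' @importFrom rlang .data
NULL
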