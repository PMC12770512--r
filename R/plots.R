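#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_line
#'   geom_point geom_errorbar labs scale_fill_gradient theme_minimal
#'   facet_wrap
NULL

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame.table(unclass(object),
                                              responseName = "count"))
  names(df)[1:2] <- c("true", "predicted")
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), colour = "grey20") +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted class", y = "true class", fill = "count") +
    theme_minimal()
}

#' Accuracy and loss curves of a training run
#'
#' @param object A `training_history` tibble (from [train_model()]).
#' @param ... Unused.
#' @return A ggplot object faceted into accuracy and loss panels.
#' @export
autoplot.training_history <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = -"epoch",
                              names_to = "series", values_to = "value")
  long$panel <- ifelse(grepl("loss", long$series), "loss", "accuracy")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$series)) +
    geom_line() +
    facet_wrap(~panel, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Per-fold metric values with the summary interval
#'
#' @param object A `fold_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$fold, y = .data$value)) +
    geom_point() +
    geom_errorbar(data = tibble::tibble(fold = mean(df$fold),
                                        value = object$mean),
                  aes(ymin = object$ci_low, ymax = object$ci_high),
                  width = 0.2, colour = "steelblue") +
    geom_point(data = tibble::tibble(fold = mean(df$fold), value = object$mean),
               colour = "steelblue", size = 3) +
    labs(x = "fold", y = "metric value") +
    theme_minimal()
}
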