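#' @importFrom ggplot2 ggplot aes geom_tile geom_line geom_errorbar
#'   geom_crossbar geom_hline geom_vline scale_fill_gradient labs theme_minimal
#'   scale_x_log10 geom_rect geom_point
NULL

#' Confusion-matrix heat map
#'
#' Row-normalized prediction fractions, true classes on the y axis.
#'
#' @param object A `sers_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sers_eval <- function(object, ...) {
  cm <- object$confusion
  df <- tibble::as_tibble(as.table(cm / pmax(rowSums(cm), 1)), .name_repair = "minimal")
  names(df) <- c("true", "predicted", "fraction")
  ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$fraction)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#08519c", limits = c(0, 1)) +
    labs(x = "Predicted class", y = "True class", fill = "Fraction",
         title = sprintf("Holdout accuracy %.1f%%", 100 * object$accuracy)) +
    theme_minimal()
}

#' Prediction-interval box plot with detection limits
#'
#' Per-class central 50% boxes and 99% whiskers of the regression
#' predictions, the control (limit-of-blank) band, and vertical markers at
#' the LOD and LOQ.
#'
#' @param object A `sers_limits`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sers_limits <- function(object, ...) {
  iv <- object$intervals[object$intervals$class != 0, ]
  p <- ggplot(iv, aes(x = .data$concentration_molar)) +
    geom_rect(xmin = -Inf, xmax = Inf, ymin = object$lob[1], ymax = object$lob[2],
              fill = "grey85", alpha = 0.5) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.1) +
    geom_crossbar(aes(y = .data$median, ymin = .data$q25, ymax = .data$q75),
                  width = 0.2, fill = "white") +
    scale_x_log10() +
    labs(x = "Concentration (mol/L)", y = "Predicted class index",
         title = "Prediction intervals with LOB band") +
    theme_minimal()
  if (!is.na(object$lod)) p <- p + geom_vline(xintercept = object$lod, linetype = "dashed")
  if (!is.na(object$loq)) p <- p + geom_vline(xintercept = object$loq, linetype = "dotted")
  p
}

#' Training-history curves
#'
#' @param object A trained `sers_cnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sers_cnn <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, cols = c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    geom_line() +
    labs(x = "Epoch", y = "Loss", colour = NULL) +
    theme_minimal()
}

#' Class-averaged spectra
#'
#' Mean intensity trace per class, vertically offset for readability.
#'
#' @param ds A `sers_dataset`.
#' @param offset Vertical offset between consecutive classes.
#' @return A ggplot object.
#' @export
plot_spectra <- function(ds, offset = 0) {
  wn <- wavenumbers(ds)
  mat <- intensity_matrix(ds)
  cls <- sort(unique(ds$class_index))
  means <- lapply(seq_along(cls), function(i) {
    m <- colMeans(mat[ds$class_index == cls[i], , drop = FALSE])
    tibble::tibble(wavenumber = wn, intensity = m + (i - 1) * offset,
                   class_index = factor(cls[i]))
  })
  ggplot(dplyr::bind_rows(means),
         aes(x = .data$wavenumber, y = .data$intensity,
             colour = .data$class_index)) +
    geom_line() +
    labs(x = expression(paste("Raman shift (", cm^-1, ")")),
         y = "Intensity (a.u.)", colour = "Class") +
    theme_minimal()
}
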