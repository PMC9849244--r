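# ---------------------------------------------------------------------------
# Tidy accessors and plots for fit/evaluation objects, plus the contour
# overlay writer.
# ---------------------------------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-epoch training log
#' @param x Fit object.
#' @param ... Unused.
#' @return Tibble with epoch, learning rate, training loss and validation
#'   metrics.
#' @export
tidy.slhardnet_fit <- function(x, ...) x$log

#' One-row fit summary
#' @param x Fit object.
#' @param ... Unused.
#' @export
glance.slhardnet_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), best_epoch = x$best_epoch,
                 best_val_DIC = x$best_metric,
                 n_params = n_params(x$model),
                 loss = x$config$loss, lr = x$config$lr,
                 seed = x$config$seed)
}

#' Per-image evaluation metrics
#' @param x Evaluation object.
#' @param ... Unused.
#' @export
tidy.slhardnet_eval <- function(x, ...) x$per_image

#' One-row evaluation summary
#' @param x Evaluation object.
#' @param ... Unused.
#' @export
glance.slhardnet_eval <- function(x, ...) {
  cbind(x$summary[1, -1], tibble::tibble(n_images = nrow(x$per_image),
                                         threshold = x$threshold))
}

#' Training-curve plot
#' @param object Fit object.
#' @param ... Unused.
#' @return A ggplot of loss and validation Dice against epoch.
#' @export
autoplot.slhardnet_fit <- function(object, ...) {
  df <- object$log
  long <- rbind(
    data.frame(epoch = df$epoch, value = df$train_loss, what = "training loss"),
    data.frame(epoch = df$epoch, value = df$val_DIC, what = "validation DIC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Metric distribution plot
#'
#' Box plots of the per-image metrics, the standard view for comparing
#' evaluation runs or loss functions.
#'
#' @param object Evaluation object.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @export
autoplot.slhardnet_eval <- function(object, metrics = c("DIC", "JAC"), ...) {
  df <- object$per_image
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(metric = m, value = df[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4) +
    ggplot2::labs(x = NULL, y = "score")
}

mask_contour <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  er <- mask
  er[2:H, ] <- er[2:H, ] * mask[1:(H - 1), ]
  er[1:(H - 1), ] <- er[1:(H - 1), ] * mask[2:H, ]
  er[, 2:W] <- er[, 2:W] * mask[, 1:(W - 1)]
  er[, 1:(W - 1)] <- er[, 1:(W - 1)] * mask[, 2:W]
  mask == 1 & er == 0
}

#' Write a contour overlay image
#'
#' Draws the ground-truth contour in green and the predicted contour in
#' blue over the input image and writes a PNG.
#'
#' @param image (h, w, 3) array in `[0,1]`.
#' @param pred Binary prediction mask.
#' @param gt Optional binary ground-truth mask.
#' @param path Output PNG path.
#' @export
write_overlay <- function(image, pred, gt = NULL, path) {
  img <- image
  if (!is.null(gt)) {
    cg <- mask_contour(gt)
    for (c in 1:3) {
      plane <- img[, , c]
      plane[cg] <- c(0, 1, 0)[c]
      img[, , c] <- plane
    }
  }
  cp <- mask_contour(pred)
  for (c in 1:3) {
    plane <- img[, , c]
    plane[cp] <- c(0, 0, 1)[c]
    img[, , c] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
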