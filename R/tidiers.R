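#' Tidy the training trace of a fitted model
#'
#' One row per epoch with the per-pair mean of the total objective, its
#' prediction and reconstruction components, and the validation AUC (NA
#' when no validation split was used).
#'
#' @param x an `anmf_model`.
#' @param ... unused.
#' @return A tibble with columns `epoch`, `loss`, `pred_loss`,
#'   `drug_recon`, `disease_recon`, `val_auc`.
#' @method tidy anmf_model
#' @export
tidy.anmf_model <- function(x, ...) {
  x$report
}

#' One-row summary of a fitted model
#'
#' @param x an `anmf_model`.
#' @param ... unused.
#' @return A tibble with `model`, `k`, `n_neg`, `epochs_run`, `best_epoch`,
#'   `final_loss`, `val_auc`.
#' @method glance anmf_model
#' @export
glance.anmf_model <- function(x, ...) {
  tibble::tibble(
    model = if (x$control$use_sim) "anmf" else "gmf",
    k = x$control$k,
    n_neg = x$control$n_neg,
    epochs_run = nrow(x$report),
    best_epoch = x$best_epoch,
    final_loss = if (nrow(x$report)) x$report$loss[nrow(x$report)] else NA_real_,
    val_auc = x$best_val_auc
  )
}

#' Training-trace plot
#'
#' Loss components per epoch on a free y scale, with the validation AUC in
#' its own panel when available.
#'
#' @param object a fitted `anmf_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot anmf_model
#' @export
autoplot.anmf_model <- function(object, ...) {
  rep <- object$report
  if (!nrow(rep)) stop("model has no training report", call. = FALSE)
  long <- tidyr::pivot_longer(rep, -"epoch",
                              names_to = "component", values_to = "value")
  long <- dplyr::filter(long, !is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training trace") +
    ggplot2::theme_minimal()
}
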