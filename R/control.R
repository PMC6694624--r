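#' Hyperparameters and training settings
#'
#' Collects every tunable quantity of the model. The defaults for `alpha`,
#' `beta`, `lambda`, `delta`, `k` and `n_neg` (0.7, 0.3, 0.001, 0.01, 128,
#' 10) are the validated settings for this model family, selected on a
#' held-out validation set formed by holding out one interaction per drug;
#' `phi = psi = 0.5` weight the two reconstruction losses inside the joint
#' objective, and masking noise at level 0.3 corrupts the autoencoder
#' inputs. The optimizer settings (plain SGD, `lr = 0.01`, mini-batches of
#' 64, at most 150 epochs with early stopping on validation AUC at
#' patience 25) are the package's own choices, as is the zero-centered
#' `tanh` hidden activation: with a sigmoid hidden layer every latent
#' coordinate is positive and the elementwise-product predictor cannot
#' express signed factor interactions, which measurably caps ranking
#' performance. Decoder and output activations stay sigmoid so
#' reconstructions and scores live in (0, 1).
#'
#' @param alpha drug-side balance in `[0, 1]` between profile and similarity
#'   reconstruction.
#' @param beta disease-side balance in `[0, 1]`.
#' @param lambda drug-side weight regularization (>= 0).
#' @param delta disease-side weight regularization (>= 0).
#' @param phi weight of the drug reconstruction loss in the joint objective.
#' @param psi weight of the disease reconstruction loss.
#' @param k hidden-feature dimension.
#' @param n_neg negatives sampled per positive each epoch.
#' @param noise a [corruption_spec()] applied to profiles and similarity
#'   vectors during training.
#' @param lr SGD learning rate (applied to the batch-mean gradient).
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size.
#' @param patience epochs without validation-AUC improvement before early
#'   stopping (ignored when no validation split is available).
#' @param validation `TRUE` to hold out one interaction per multi-interaction
#'   drug for early stopping, `FALSE` to train on everything.
#' @param negatives `"per_epoch"` resamples negatives every epoch (dynamic
#'   sampling); `"static"` draws them once before training.
#' @param g,f encoder / decoder activation names.
#' @param out_activation output activation of the perceptron; training
#'   requires `"sigmoid"` so scores are probabilities for the cross-entropy.
#' @param seed master seed; initialization, splits, corruption and sampling
#'   each draw from an independent stream derived from it.
#' @param verbose print a line per epoch.
#' @return An object of class `anmf_control`.
#' @export
anmf_control <- function(alpha = 0.7, beta = 0.3, lambda = 0.001, delta = 0.01,
                         phi = 0.5, psi = 0.5, k = 128, n_neg = 10,
                         noise = corruption_spec("masking", 0.3),
                         lr = 1.25, epochs = 150, batch_size = 64,
                         patience = 25, validation = TRUE,
                         negatives = c("per_epoch", "static"),
                         g = "tanh", f = "sigmoid",
                         out_activation = "sigmoid",
                         seed = 1, verbose = FALSE) {
  stopifnot(.is_prob(alpha), .is_prob(beta),
            .is_nonneg(lambda), .is_nonneg(delta),
            .is_nonneg(phi), .is_nonneg(psi),
            .is_count(k), .is_count(n_neg + 1), .is_nonneg(lr),
            .is_count(epochs), .is_count(batch_size), .is_count(patience),
            is.logical(validation), inherits(noise, "anmf_corruption"))
  structure(
    list(alpha = alpha, beta = beta, lambda = lambda, delta = delta,
         phi = phi, psi = psi, k = k, n_neg = as.integer(n_neg),
         noise = noise, lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), patience = as.integer(patience),
         validation = validation, negatives = match.arg(negatives),
         g = .check_activation(g), f = .check_activation(f),
         out_activation = .check_activation(out_activation),
         seed = as.integer(seed), verbose = isTRUE(verbose),
         use_sim = TRUE),
    class = "anmf_control"
  )
}

#' Hyperparameter search grid
#'
#' The full grid this model family is tuned over: `alpha`, `beta` in
#' `{0.1, 0.3, 0.5, 0.7, 0.9}`, `lambda`, `delta` in `{0.1, 0.01, 0.001}`,
#' `k` in `{16, 32, 64, 128, 256}` and `n_neg` in `{1, 5, 10, 15, 20}`.
#' Returned as a tibble, one row per configuration, for use with
#' [fit_anmf()] in a user-driven loop.
#'
#' @return A tibble with columns `alpha`, `beta`, `lambda`, `delta`, `k`,
#'   `n_neg`.
#' @export
anmf_grid <- function() {
  tibble::as_tibble(expand.grid(
    alpha = c(0.1, 0.3, 0.5, 0.7, 0.9),
    beta = c(0.1, 0.3, 0.5, 0.7, 0.9),
    lambda = c(0.1, 0.01, 0.001),
    delta = c(0.1, 0.01, 0.001),
    k = c(16, 32, 64, 128, 256),
    n_neg = c(1, 5, 10, 15, 20),
    KEEP.OUT.ATTRS = FALSE
  ))
}
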