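#' Score one drug-disease pair from hidden features
#'
#' The generalized-matrix-factorization predictor: the elementwise product
#' of the two hidden features is passed through a single-layer perceptron,
#' `F_out(h' (drug_z * disease_z))`. With the default sigmoid output the
#' score is the probability, in `(0, 1)`, that the drug treats the disease.
#' There is no bias term in the output layer.
#'
#' @param h fusion weight vector, length `k`.
#' @param drug_z,disease_z hidden features, length `k`.
#' @param out_activation activation name for `F_out`.
#' @return Scalar score.
#' @export
predict_pair <- function(h, drug_z, disease_z, out_activation = "sigmoid") {
  if (length(drug_z) != length(disease_z) || length(h) != length(drug_z)) {
    stop("h, drug_z and disease_z must share one hidden dimension",
         call. = FALSE)
  }
  act <- .act_fun(.check_activation(out_activation))
  act(sum(h * drug_z * disease_z))
}

#' Binary cross-entropy between a predicted score and a 0/1 target
#'
#' `-(target * log(score) + (1 - target) * log(1 - score))`, with the score
#' clipped to `[1e-12, 1 - 1e-12]` before the logarithms for numeric safety.
#' Minimizing this drives the predicted probability toward the target.
#'
#' @param score predicted probability (vectorized).
#' @param target 0 or 1 (vectorized, recycled against `score`).
#' @return Non-negative numeric vector.
#' @export
prediction_loss <- function(score, target) {
  if (!all(target %in% c(0, 1))) stop("target must be 0 or 1", call. = FALSE)
  s <- .clip01(score)
  -(target * log(s) + (1 - target) * log(1 - s))
}

# Hidden features for every drug and disease at once, corruption-free
# (inference mode). Profiles come from the model's training matrix.
.hidden_features <- function(model) {
  g <- .act_fun(model$control$g)
  R <- model$train_R
  Zd <- g(R %*% t(model$drug_encoder$W1) +
            model$drug_sim %*% t(model$drug_encoder$V1) +
            rep(1, nrow(R)) %o% model$drug_encoder$b_enc)
  Ze <- g(t(R) %*% t(model$disease_encoder$W1) +
            model$disease_sim %*% t(model$disease_encoder$V1) +
            rep(1, ncol(R)) %o% model$disease_encoder$b_enc)
  list(drug = Zd, disease = Ze)
}

#' Score every drug-disease pair
#'
#' Runs the model in inference mode (no input corruption): hidden features
#' are computed from the clean training profiles and similarity vectors, and
#' every pair is scored with the perceptron. Deterministic for a fixed model.
#'
#' @param model a fitted or initialized [fit_anmf()] model.
#' @return An `m x n` numeric matrix of scores with drug/disease identifiers
#'   as dimnames.
#' @export
predict_matrix <- function(model) {
  stopifnot(inherits(model, "anmf_model"))
  Z <- .hidden_features(model)
  out <- .act_fun(model$control$out_activation)
  scores <- out(sweep(Z$drug, 2, model$h, `*`) %*% t(Z$disease))
  dimnames(scores) <- list(model$drug_ids, model$disease_ids)
  scores
}

#' @export
predict.anmf_model <- function(object, type = c("matrix", "tibble"), ...) {
  type <- match.arg(type)
  scores <- predict_matrix(object)
  if (type == "matrix") return(scores)
  tibble::tibble(
    drug_id = rep(rownames(scores), times = ncol(scores)),
    disease_id = rep(colnames(scores), each = nrow(scores)),
    score = as.vector(scores)
  )
}

#' Ranked novel-indication candidates per drug
#'
#' For every drug, ranks its unverified diseases by predicted score and
#' returns the top `n` — the repositioning shortlist.
#'
#' @param model a fitted model.
#' @param n list length per drug.
#' @param exclude_known drop pairs already verified in the training matrix
#'   (default TRUE).
#' @return A tibble with columns `drug_id`, `disease_id`, `score`, `rank`.
#' @export
top_predictions <- function(model, n = 10, exclude_known = TRUE) {
  scores <- predict_matrix(model)
  if (exclude_known) scores[model$train_R == 1] <- -Inf
  out <- lapply(seq_len(nrow(scores)), function(i) {
    ord <- order(scores[i, ], decreasing = TRUE)[seq_len(min(n, ncol(scores)))]
    ord <- ord[is.finite(scores[i, ord])]
    tibble::tibble(
      drug_id = rownames(scores)[i],
      disease_id = colnames(scores)[ord],
      score = scores[i, ord],
      rank = seq_along(ord)
    )
  })
  dplyr::bind_rows(out)
}
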