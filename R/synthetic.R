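#' Planted-factor synthetic drug-disease data
#'
#' Generates a dataset with the statistical shape the model assumes, so that
#' every stage of the pipeline can be exercised without external downloads.
#' Drug factors `U` (`m x k_true`) and disease factors `V` (`n x k_true`)
#' are drawn i.i.d. standard normal; the true treatment probability is
#' `T = sigmoid(U %*% t(V) + noise - c)`, with i.i.d. `N(0, noise_sd^2)`
#' observation noise and the offset `c` chosen (by root finding) so the mean
#' of `T` equals the target density. The sigmoid link keeps the planted
#' model inside the family the predictor can represent, which is what makes
#' parameter-recovery checks meaningful. Associations are sampled as
#' `Bernoulli(T)` (default) or as the top `density * m * n` cells of `T`.
#'
#' Similarities are built from the same factors: the cosine similarity of
#' the factor rows, affinely mapped from `[-1, 1]` to `[0, 1]` (mimicking
#' Tanimoto-like bounded similarities without modelling chemistry), mixed
#' with symmetric uniform noise by weight `sim_signal`, unit diagonal
#' enforced. At `sim_signal = 1` the similarity is the mapped cosine
#' exactly; at 0 it is pure noise, statistically independent of the factors.
#'
#' The default shape (593 drugs, 313 diseases, density 0.0104) emulates the
#' standard benchmark collection for this task.
#'
#' @param m,n numbers of drugs and diseases.
#' @param k_true planted factor dimension.
#' @param density target fraction of positive cells, in (0, 1).
#' @param sim_signal mixing weight in `[0, 1]` of factor-derived vs. random
#'   similarity.
#' @param noise_sd standard deviation of the logit-scale observation noise.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param mode `"bernoulli"` (default) or `"top"` sparsification.
#' @return A list of class `anmf_synthetic`: `dataset` (an [anmf_dataset]),
#'   and `truth` with the planted `U`, `V`, the probability matrix `prob`
#'   and the fitted offset `threshold`.
#' @export
synthetic_dataset <- function(m = 593, n = 313, k_true = 8, density = 0.0104,
                              sim_signal = 0.8, noise_sd = 0.5, seed = 1,
                              mode = c("bernoulli", "top")) {
  stopifnot(.is_count(m), .is_count(n), .is_count(k_true),
            is.numeric(density), density > 0, density < 1,
            .is_prob(sim_signal), .is_nonneg(noise_sd))
  mode <- match.arg(mode)
  .with_seed(seed, {
    U <- matrix(rnorm(m * k_true), m, k_true)
    V <- matrix(rnorm(n * k_true), n, k_true)
    L <- tcrossprod(U, V)
    if (noise_sd > 0) L <- L + matrix(rnorm(m * n, sd = noise_sd), m, n)
    off <- uniroot(function(c) mean(plogis(L - c)) - density,
                   lower = -50, upper = 50, extendInt = "downX",
                   tol = 1e-10)$root
    T_prob <- plogis(L - off)
    R <- matrix(0, m, n)
    if (mode == "bernoulli") {
      R[] <- rbinom(m * n, 1L, T_prob)
    } else {
      k_pos <- max(1L, round(density * m * n))
      R[order(T_prob, decreasing = TRUE)[seq_len(k_pos)]] <- 1
    }
    drug_sim <- .factor_similarity(U, sim_signal)
    disease_sim <- .factor_similarity(V, sim_signal)
    dataset <- anmf_dataset(
      R, drug_sim, disease_sim,
      drug_ids = sprintf("drug_%04d", seq_len(m)),
      disease_ids = sprintf("disease_%04d", seq_len(n))
    )
    structure(
      list(dataset = dataset,
           truth = list(U = U, V = V, prob = T_prob, threshold = off)),
      class = "anmf_synthetic"
    )
  })
}

# sim_signal * [0,1]-mapped cosine similarity of factor rows
# + (1 - sim_signal) * random symmetric uniform noise; unit diagonal.
.factor_similarity <- function(F, sim_signal) {
  Fn <- F / sqrt(rowSums(F^2))
  mapped <- (tcrossprod(Fn) + 1) / 2
  A <- matrix(runif(nrow(F)^2), nrow(F))
  S <- sim_signal * mapped + (1 - sim_signal) * (A + t(A)) / 2
  diag(S) <- 1
  # clamp cosine rounding spill just outside [0, 1]
  pmin(pmax(S, 0), 1)
}

#' @export
print.anmf_synthetic <- function(x, ...) {
  cat("<anmf_synthetic> planted k =", ncol(x$truth$U), "\n")
  print(x$dataset)
  invisible(x)
}
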