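#' Input corruption for denoising autoencoders
#'
#' `corruption_spec()` describes how the clean interaction profile and
#' similarity vector are corrupted before encoding. `"masking"` zeroes each
#' coordinate independently with probability `level`, leaving survivors
#' unchanged (no 1/(1-level) rescaling: the decoder reconstructs the clean
#' vector, so inflation has no role here). `"gaussian"` adds i.i.d.
#' `N(0, level^2)` noise. `"none"` is the identity. The default, masking at
#' level 0.3, is the setting under which the model's reference results were
#' obtained; Gaussian corruption is retained as an option.
#'
#' @param kind one of `"masking"`, `"gaussian"`, `"none"`.
#' @param level masking probability in `[0, 1]`, or Gaussian standard
#'   deviation (`>= 0`).
#' @param seed optional integer; when set, [corrupt()] draws from a private
#'   stream seeded with it (leaving the caller's RNG untouched), making the
#'   corruption a deterministic function of its input.
#' @return An object of class `anmf_corruption`.
#' @export
corruption_spec <- function(kind = c("masking", "gaussian", "none"),
                            level = 0.3, seed = NULL) {
  kind <- match.arg(kind)
  if (!.is_nonneg(level)) stop("corruption level must be >= 0", call. = FALSE)
  if (kind == "masking" && level > 1) {
    stop("masking level must be <= 1", call. = FALSE)
  }
  structure(list(kind = kind, level = level, seed = seed),
            class = "anmf_corruption")
}

#' Corrupt a vector or matrix
#'
#' Applies the corruption described by `spec` elementwise; matrices are
#' corrupted entry by entry (each row is an independently corrupted vector).
#'
#' @param x numeric vector or matrix with finite entries.
#' @param spec an [corruption_spec()].
#' @return An object shaped like `x`.
#' @export
corrupt <- function(x, spec = corruption_spec()) {
  stopifnot(inherits(spec, "anmf_corruption"))
  if (!all(is.finite(x))) stop("input to corrupt() must be finite", call. = FALSE)
  if (spec$kind == "none" || spec$level == 0) return(x)
  .with_seed(spec$seed, {
    if (spec$kind == "masking") {
      x * (runif(length(x)) >= spec$level)
    } else {
      x + rnorm(length(x), sd = spec$level)
    }
  })
}

#' Initialize the parameters of one additional autoencoder
#'
#' One encoder maps a corrupted interaction profile (length `p`) plus a
#' corrupted similarity vector (length `q`) to a `k`-dimensional hidden
#' feature, and decodes the hidden feature back to both inputs. Weights are
#' drawn uniformly in `±sqrt(6 / (fan_in + fan_out))` (Glorot range); biases
#' start at zero.
#'
#' @param p length of the interaction profile (number of diseases for the
#'   drug-side encoder, number of drugs for the disease-side encoder).
#' @param q length of the similarity vector.
#' @param k hidden dimension.
#' @return An object of class `anmf_encoder_params`: list with `W1` (k x p),
#'   `V1` (k x q), `b_enc` (k), `W2` (p x k), `b_dec_profile` (p), `V2`
#'   (q x k), `b_dec_sim` (q).
#' @export
init_encoder_params <- function(p, q, k) {
  stopifnot(.is_count(p), .is_count(q), .is_count(k))
  glorot <- function(rows, cols) {
    r <- sqrt(6 / (rows + cols))
    matrix(runif(rows * cols, -r, r), rows, cols)
  }
  structure(
    list(
      W1 = glorot(k, p), V1 = glorot(k, q), b_enc = numeric(k),
      W2 = glorot(p, k), b_dec_profile = numeric(p),
      V2 = glorot(q, k), b_dec_sim = numeric(q)
    ),
    class = "anmf_encoder_params", p = p, q = q, k = k
  )
}

.check_encoder_shapes <- function(params, profile = NULL, sim = NULL, z = NULL) {
  p <- nrow(params$W2); q <- nrow(params$V2); k <- ncol(params$W2)
  if (!is.null(profile) && length(profile) != p) {
    stop("profile length ", length(profile), " != ", p, call. = FALSE)
  }
  if (!is.null(sim) && length(sim) != q) {
    stop("similarity vector length ", length(sim), " != ", q, call. = FALSE)
  }
  if (!is.null(z) && length(z) != k) {
    stop("hidden feature length ", length(z), " != ", k, call. = FALSE)
  }
  invisible(TRUE)
}

#' Encode a corrupted profile and similarity vector into a hidden feature
#'
#' Computes `g(W1 %*% profile + V1 %*% sim + b_enc)` — the hidden feature of
#' a drug (or, with the disease-side encoder, of a disease).
#'
#' @param params an [init_encoder_params()] object.
#' @param profile corrupted interaction profile, length `p`.
#' @param sim corrupted similarity vector, length `q`.
#' @param g activation name (`"sigmoid"`, `"identity"`, `"tanh"`).
#' @return Numeric `k`-vector.
#' @export
encode <- function(params, profile, sim, g = "sigmoid") {
  .check_encoder_shapes(params, profile = profile, sim = sim)
  act <- .act_fun(.check_activation(g))
  as.vector(act(params$W1 %*% profile + params$V1 %*% sim + params$b_enc))
}

#' Decode a hidden feature
#'
#' `decode_profile()` reconstructs the interaction profile,
#' `f(W2 %*% z + b_dec_profile)`; `decode_similarity()` reconstructs the
#' similarity vector, `f(V2 %*% z + b_dec_sim)`.
#'
#' @param params an [init_encoder_params()] object.
#' @param z hidden feature, length `k`.
#' @param f activation name.
#' @return Numeric vector of length `p` (profile) or `q` (similarity).
#' @export
decode_profile <- function(params, z, f = "sigmoid") {
  .check_encoder_shapes(params, z = z)
  act <- .act_fun(.check_activation(f))
  as.vector(act(params$W2 %*% z + params$b_dec_profile))
}

#' @rdname decode_profile
#' @export
decode_similarity <- function(params, z, f = "sigmoid") {
  .check_encoder_shapes(params, z = z)
  act <- .act_fun(.check_activation(f))
  as.vector(act(params$V2 %*% z + params$b_dec_sim))
}

#' Autoencoder reconstruction loss
#'
#' The per-entity feature-extraction loss:
#' `balance * ||profile - profile_hat||^2 +
#'  (1 - balance) * ||sim - sim_hat||^2 +
#'  reg * (||W1||^2 + ||W2||^2 + ||V1||^2 + ||V2||^2)`.
#' Targets are the clean (uncorrupted) vectors; the reconstructions come
#' from decoding the corrupted input. Regularization sums squared Frobenius
#' norms of the four weight matrices only — biases are excluded, as is
#' standard.
#'
#' @param params an [init_encoder_params()] object (supplies the weights for
#'   the regularization term).
#' @param profile,sim clean target vectors.
#' @param profile_hat,sim_hat reconstructed vectors.
#' @param balance equilibrium weight in `[0, 1]` between profile and
#'   similarity reconstruction (the drug-side default in this model is 0.7,
#'   the disease-side default 0.3).
#' @param reg regularization weight `>= 0` (drug-side default 0.001,
#'   disease-side default 0.01).
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(params, profile, sim, profile_hat, sim_hat,
                                balance, reg) {
  if (!.is_prob(balance)) stop("balance must lie in [0, 1]", call. = FALSE)
  if (!.is_nonneg(reg)) stop("reg must be >= 0", call. = FALSE)
  .check_encoder_shapes(params, profile = profile, sim = sim)
  stopifnot(length(profile_hat) == length(profile),
            length(sim_hat) == length(sim))
  balance * sum((profile - profile_hat)^2) +
    (1 - balance) * sum((sim - sim_hat)^2) +
    reg * (sum(params$W1^2) + sum(params$W2^2) +
             sum(params$V1^2) + sum(params$V2^2))
}
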