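# Shared fixtures and independent oracles, built in code at test time.

toy_dataset <- function() {
  anmf_dataset(
    R = matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
    drug_sim = matrix(c(1, 0.4, 0.4, 1), 2, 2),
    disease_sim = matrix(c(1, 0.2, 0.2, 1), 2, 2),
    drug_ids = c("drugA", "drugB"), disease_ids = c("disX", "disY")
  )
}

rand_dataset <- function(m = 8, n = 6, k_true = 2, density = 0.3, seed = 1) {
  synthetic_dataset(m = m, n = n, k_true = k_true, density = density,
                    sim_signal = 0.8, noise_sd = 0.5, seed = seed)$dataset
}

tiny_control <- function(...) {
  args <- utils::modifyList(
    list(k = 3, epochs = 3, batch_size = 8, n_neg = 2, validation = FALSE),
    list(...)
  )
  do.call(anmf_control, args)
}

# independent naive triple-loop matrix-vector product: (A x)_i
naive_matvec <- function(A, x) {
  out <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    acc <- 0
    for (j in seq_len(ncol(A))) acc <- acc + A[i, j] * x[j]
    out[i] <- acc
  }
  out
}

# brute-force AUC: pairwise P(pos > neg) + 1/2 P(tie)
oracle_auc <- function(pos, neg) {
  acc <- 0
  for (p in pos) for (q in neg) {
    acc <- acc + (p > q) + 0.5 * (p == q)
  }
  acc / (length(pos) * length(neg))
}

# exhaustive per-threshold precision/recall sweep, step summation
oracle_aupr <- function(pos, neg) {
  scores <- c(pos, neg)
  labels <- c(rep(1, length(pos)), rep(0, length(neg)))
  thresholds <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (th in thresholds) {
    sel <- scores >= th
    tp <- sum(labels[sel])
    precision <- tp / sum(sel)
    recall <- tp / length(pos)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# exhaustive per-drug full-sort hit ranks (pessimistic ties)
oracle_hit_ratio <- function(scores, split, n) {
  test <- split$test_positives
  cand <- split_candidates(split)
  cand_ij <- cbind((cand - 1L) %% split$m + 1L, (cand - 1L) %/% split$m + 1L)
  hits <- 0
  for (t in seq_len(nrow(test))) {
    i <- test[t, 1]; j <- test[t, 2]
    pool <- cand_ij[cand_ij[, 1] == i, 2]
    all_scores <- c(scores[i, j], scores[cbind(i, pool)])
    ord <- order(all_scores, decreasing = TRUE)
    # pessimistic: among ties the positive sorts last
    tied_above <- sum(all_scores[-1] >= all_scores[1])
    if (1 + tied_above <= n) hits <- hits + 1
  }
  hits / nrow(test)
}

# parameter vector <-> model, for finite-difference gradient checks
model_param_vector <- function(model) {
  unlist(c(model$drug_encoder[], model$disease_encoder[], list(h = model$h)),
         use.names = FALSE)
}

model_with_params <- function(model, v) {
  i <- 1L
  for (side in c("drug_encoder", "disease_encoder")) {
    for (nm in names(model[[side]])) {
      len <- length(model[[side]][[nm]])
      model[[side]][[nm]][] <- v[i:(i + len - 1L)]
      i <- i + len
    }
  }
  model$h <- v[i:(i + length(model$h) - 1L)]
  model
}

central_diff_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# analytic gradient of joint_loss, flattened in model_param_vector() order;
# tensors the objective does not touch (the frozen similarity weights of the
# ablation) contribute zeros, matching the finite differences.
analytic_full_grads <- function(model, pairs, targets) {
  hp <- model$control
  R <- model$train_R; tR <- t(R)
  di <- pairs[, 1]; ej <- pairs[, 2]
  dU <- if (hp$use_sim) model$drug_sim[di, , drop = FALSE]
  eU <- if (hp$use_sim) model$disease_sim[ej, , drop = FALSE]
  res <- anmf:::.anmf_batch(
    list(drug = model$drug_encoder, disease = model$disease_encoder,
         h = model$h),
    hp,
    dX = R[di, , drop = FALSE], dXc = R[di, , drop = FALSE],
    dU = dU, dUc = dU,
    eX = tR[ej, , drop = FALSE], eXc = tR[ej, , drop = FALSE],
    eU = eU, eUc = eU,
    targets = targets, grads = TRUE
  )
  flat_side <- function(enc, gr) {
    unlist(lapply(names(enc), function(nm) {
      g <- gr[[nm]]
      if (is.null(g)) array(0, dim(enc[[nm]]) %||% length(enc[[nm]])) else g
    }), use.names = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  c(flat_side(model$drug_encoder, res$grads$drug),
    flat_side(model$disease_encoder, res$grads$disease),
    res$grads$h)
}
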