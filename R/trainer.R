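# Joint forward/backward pass over one mini-batch of (drug, disease) pairs.
#
# All loss values are SUMS over the batch (the joint objective is a sum over
# R+ u R-); the SGD caller divides gradients by the batch size. Per-pair
# loss: cross-entropy(score, target)
#       + phi * [alpha ||dX - dXhat||^2 + (1-alpha) ||dU - dUhat||^2 + lambda * Omega_drug]
#       + psi * [beta  ||eX - eXhat||^2 + (1-beta)  ||eU - eUhat||^2 + delta  * Omega_disease]
# where Omega is the summed squared Frobenius norm of that encoder's four
# weight matrices, charged once per pair occurrence.
#
# Matrix arguments are B x len row blocks: d* = drug side (X profile over
# diseases, U similarity over drugs), e* = disease side; *c = corrupted.
.anmf_batch <- function(state, hp, dX, dXc, dU, dUc, eX, eXc, eU, eUc,
                        targets, grads = TRUE) {
  B <- length(targets)
  g  <- .act_fun(hp$g);  dg <- .act_deriv_from_output(hp$g)
  f  <- .act_fun(hp$f);  df <- .act_deriv_from_output(hp$f)
  de <- state$drug; ee <- state$disease; h <- state$h
  alpha <- if (hp$use_sim) hp$alpha else 1
  beta  <- if (hp$use_sim) hp$beta  else 1

  ones <- rep(1, B)
  Ad <- tcrossprod(dXc, de$W1) + ones %o% de$b_enc
  Ae <- tcrossprod(eXc, ee$W1) + ones %o% ee$b_enc
  if (hp$use_sim) {
    Ad <- Ad + tcrossprod(dUc, de$V1)
    Ae <- Ae + tcrossprod(eUc, ee$V1)
  }
  Zd <- g(Ad)
  Ze <- g(Ae)

  dShat <- f(tcrossprod(Zd, de$W2) + ones %o% de$b_dec_profile)
  eShat <- f(tcrossprod(Ze, ee$W2) + ones %o% ee$b_dec_profile)
  if (hp$use_sim) {
    dMhat <- f(tcrossprod(Zd, de$V2) + ones %o% de$b_dec_sim)
    eMhat <- f(tcrossprod(Ze, ee$V2) + ones %o% ee$b_dec_sim)
  }

  P <- Zd * Ze
  score <- .act_fun(hp$out_activation)(drop(P %*% h))
  pred_sum <- sum(prediction_loss(score, targets))

  omega_d <- sum(de$W1^2) + sum(de$W2^2) + sum(de$V1^2) + sum(de$V2^2)
  omega_e <- sum(ee$W1^2) + sum(ee$W2^2) + sum(ee$V1^2) + sum(ee$V2^2)
  drug_sum <- alpha * sum((dX - dShat)^2) + B * hp$lambda * omega_d
  dis_sum  <- beta  * sum((eX - eShat)^2) + B * hp$delta * omega_e
  if (hp$use_sim) {
    drug_sum <- drug_sum + (1 - alpha) * sum((dU - dMhat)^2)
    dis_sum  <- dis_sum  + (1 - beta)  * sum((eU - eMhat)^2)
  }
  total <- pred_sum + hp$phi * drug_sum + hp$psi * dis_sum

  out <- list(total = total, prediction = pred_sum,
              drug_recon = drug_sum, disease_recon = dis_sum, n = B)
  if (!grads) return(out)

  # --- backward (gradients of `total`) ---
  dt <- score - targets                       # sigmoid + cross-entropy
  grad_h <- drop(crossprod(P, dt))
  dZd <- (dt %o% h) * Ze
  dZe <- (dt %o% h) * Zd

  bk <- function(enc, Z, dZ_pred, Shat, X, Mhat, U, bal, reg, wt) {
    dC <- (2 * bal * wt) * (Shat - X) * df(Shat)
    gW2 <- crossprod(dC, Z) + (2 * wt * reg * B) * enc$W2
    gb2 <- colSums(dC)
    dZ <- dZ_pred + dC %*% enc$W2
    if (hp$use_sim) {
      dD <- (2 * (1 - bal) * wt) * (Mhat - U) * df(Mhat)
      gV2 <- crossprod(dD, Z) + (2 * wt * reg * B) * enc$V2
      gb3 <- colSums(dD)
      dZ <- dZ + dD %*% enc$V2
    } else {
      gV2 <- NULL; gb3 <- NULL
    }
    dA <- dZ * dg(Z)
    list(dA = dA, W2 = gW2, b_dec_profile = gb2, V2 = gV2, b_dec_sim = gb3)
  }

  bd <- bk(de, Zd, dZd, dShat, dX, if (hp$use_sim) dMhat, dU,
           alpha, hp$lambda, hp$phi)
  be <- bk(ee, Ze, dZe, eShat, eX, if (hp$use_sim) eMhat, eU,
           beta, hp$delta, hp$psi)

  finish <- function(bkout, enc, Xc, Uc, reg, wt) {
    gr <- list(
      W1 = crossprod(bkout$dA, Xc) + (2 * wt * reg * B) * enc$W1,
      b_enc = colSums(bkout$dA),
      W2 = bkout$W2, b_dec_profile = bkout$b_dec_profile
    )
    if (hp$use_sim) {
      gr$V1 <- crossprod(bkout$dA, Uc) + (2 * wt * reg * B) * enc$V1
      gr$V2 <- bkout$V2
      gr$b_dec_sim <- bkout$b_dec_sim
    }
    gr
  }

  out$grads <- list(
    drug = finish(bd, de, dXc, dUc, hp$lambda, hp$phi),
    disease = finish(be, ee, eXc, eUc, hp$delta, hp$psi),
    h = grad_h
  )
  out
}

.pairs_to_indices <- function(pairs, drug_ids, disease_ids) {
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.character(pairs)) stop("pairs must be a 2-column matrix/data frame",
                                call. = FALSE)
  stopifnot(ncol(pairs) >= 2)
  di <- pairs[, 1]; ej <- pairs[, 2]
  if (is.character(di)) di <- match(di, drug_ids)
  if (is.character(ej)) ej <- match(ej, disease_ids)
  di <- as.integer(di); ej <- as.integer(ej)
  if (anyNA(di) || anyNA(ej)) stop("unresolvable identifier in pairs",
                                   call. = FALSE)
  cbind(drug = di, disease = ej)
}

#' Joint training objective on a batch of pairs
#'
#' Evaluates the full objective — prediction cross-entropy plus `phi` times
#' the drug reconstruction loss plus `psi` times the disease reconstruction
#' loss, summed over the given pairs — with corruption disabled (clean
#' inputs), so the value is a deterministic function of the model state.
#'
#' @param model an [fit_anmf()] / [init_anmf()] model.
#' @param pairs 2-column matrix, data frame or tibble of (drug, disease)
#'   indices or identifiers.
#' @param targets 0/1 vector, one per pair.
#' @return The scalar loss, with a `"components"` attribute holding the
#'   named sums `prediction`, `drug_recon`, `disease_recon` (unweighted).
#' @export
joint_loss <- function(model, pairs, targets) {
  stopifnot(inherits(model, "anmf_model"))
  idx <- .pairs_to_indices(pairs, model$drug_ids, model$disease_ids)
  if (nrow(idx) == 0L) stop("empty batch", call. = FALSE)
  stopifnot(length(targets) == nrow(idx))
  hp <- model$control
  R <- model$train_R; tR <- t(R)
  di <- idx[, 1]; ej <- idx[, 2]
  dU <- if (hp$use_sim) model$drug_sim[di, , drop = FALSE]
  eU <- if (hp$use_sim) model$disease_sim[ej, , drop = FALSE]
  res <- .anmf_batch(
    list(drug = model$drug_encoder, disease = model$disease_encoder,
         h = model$h),
    hp,
    dX = R[di, , drop = FALSE], dXc = R[di, , drop = FALSE],
    dU = dU, dUc = dU,
    eX = tR[ej, , drop = FALSE], eXc = tR[ej, , drop = FALSE],
    eU = eU, eUc = eU,
    targets = targets, grads = FALSE
  )
  structure(res$total,
            components = c(prediction = res$prediction,
                           drug_recon = res$drug_recon,
                           disease_recon = res$disease_recon))
}

#' Sample unobserved pairs as training negatives
#'
#' Draws `n_neg` unobserved (zero) cells of the training matrix per observed
#' positive, uniformly and without replacement within the draw. When fewer
#' unobserved cells exist than requested, all of them are returned with a
#' warning. Sampled negatives never collide with positives.
#'
#' @param train_R binary training matrix.
#' @param n_neg negatives per positive (N).
#' @param seed optional integer seed for a private stream.
#' @return A tibble with integer columns `drug`, `disease`.
#' @export
sample_negatives <- function(train_R, n_neg, seed = NULL) {
  stopifnot(is.matrix(train_R), .is_count(n_neg + 1))
  zeros <- which(train_R == 0)
  want <- as.integer(n_neg) * sum(train_R == 1)
  if (want > length(zeros)) {
    warning("only ", length(zeros), " unobserved cells available (wanted ",
            want, "); using all of them", call. = FALSE)
    want <- length(zeros)
  }
  take <- .with_seed(seed, sample(zeros, want))
  m <- nrow(train_R)
  tibble::tibble(
    drug = as.integer((take - 1L) %% m + 1L),
    disease = as.integer((take - 1L) %/% m + 1L)
  )
}

#' Initialize an untrained model
#'
#' Builds the two encoders and the perceptron weights for a dataset, using
#' the initialization stream derived from `control$seed`. [fit_anmf()] with
#' `lr = 0` leaves this state unchanged.
#'
#' @param dataset an [anmf_dataset].
#' @param control an [anmf_control()].
#' @param train_R optional replacement training matrix (e.g. one CV fold);
#'   defaults to `dataset$R`.
#' @return An `anmf_model` at epoch 0.
#' @export
init_anmf <- function(dataset, control = anmf_control(), train_R = NULL) {
  stopifnot(inherits(dataset, "anmf_dataset"),
            inherits(control, "anmf_control"))
  R <- train_R %||% dataset$R
  m <- nrow(R); n <- ncol(R); k <- control$k
  seeds <- .derive_seeds(control$seed, 2L)
  params <- .with_seed(seeds[1], {
    list(
      drug = init_encoder_params(p = n, q = m, k = k),
      disease = init_encoder_params(p = m, q = n, k = k),
      h = {
        r <- sqrt(6 / (k + 1))
        runif(k, -r, r)
      }
    )
  })
  if (!control$use_sim) {
    params$drug$V1[] <- 0; params$drug$V2[] <- 0
    params$disease$V1[] <- 0; params$disease$V2[] <- 0
  }
  structure(
    list(drug_encoder = params$drug, disease_encoder = params$disease,
         h = params$h, control = control,
         train_R = R, drug_sim = dataset$drug_sim,
         disease_sim = dataset$disease_sim,
         drug_ids = dataset$drug_ids, disease_ids = dataset$disease_ids,
         report = tibble::tibble(), best_epoch = 0L, best_val_auc = NA_real_),
    class = "anmf_model"
  )
}

#' Fit the full model by negative-sampling SGD
#'
#' Learns both autoencoders and the perceptron jointly by minimizing the
#' combined objective (prediction cross-entropy over positives plus sampled
#' negatives, plus the weighted reconstruction losses of every drug and
#' disease occurring in a batch) with plain mini-batch stochastic gradient
#' descent. Each epoch the input corruption is redrawn and, in the default
#' dynamic mode, the negatives are resampled from the unobserved cells.
#' When `control$validation` is `TRUE`, one interaction per
#' multi-interaction drug is held out and training stops early once the
#' held-out AUC fails to improve for `patience` epochs; the parameters of
#' the best epoch are kept. Runs are deterministic for a fixed
#' `control$seed`.
#'
#' @param dataset an [anmf_dataset].
#' @param control an [anmf_control()].
#' @param train_R optional replacement training matrix (e.g. a CV fold's
#'   training rendering of `dataset$R`); evaluation positives must be 0 here.
#' @return An object of class `anmf_model`. `model$report` is a tibble with
#'   one row per epoch (`epoch`, `loss`, `pred_loss`, `drug_recon`,
#'   `disease_recon`, `val_auc`; losses are per-pair means).
#' @seealso [fit_gmf()] for the ablation without similarity information,
#'   [predict_matrix()], [evaluate_split()].
#' @export
fit_anmf <- function(dataset, control = anmf_control(), train_R = NULL) {
  stopifnot(inherits(dataset, "anmf_dataset"),
            inherits(control, "anmf_control"))
  if (control$out_activation != "sigmoid") {
    stop("training requires a sigmoid output activation", call. = FALSE)
  }
  R_full <- train_R %||% dataset$R
  seeds <- .derive_seeds(control$seed, 6L)
  # independent streams: [1] init (inside init_anmf), [2] validation split,
  # [3] corruption epochs, [4] negative-sampling epochs, [5] batch shuffles
  corrupt_seeds <- .with_seed(seeds[3], sample.int(.Machine$integer.max - 1L,
                                                   control$epochs))
  sample_seeds <- .with_seed(seeds[4], sample.int(.Machine$integer.max - 1L,
                                                  control$epochs))
  shuffle_seeds <- .with_seed(seeds[5], sample.int(.Machine$integer.max - 1L,
                                                   control$epochs))

  val_pairs <- NULL
  Rtr <- R_full
  if (control$validation) {
    vsplit <- make_validation_split(R_full, seed = seeds[2])
    if (nrow(vsplit$test_positives) > 0L) {
      val_pairs <- vsplit$test_positives
      Rtr <- split_train_matrix(vsplit)
      dimnames(Rtr) <- dimnames(R_full)
    }
  }

  model <- init_anmf(dataset, control, train_R = Rtr)
  state <- list(drug = model$drug_encoder, disease = model$disease_encoder,
                h = model$h)
  # unnamed working copies keep dimnames out of the weight tensors
  Rtr <- unname(Rtr)
  DS <- unname(model$drug_sim)
  ES <- unname(model$disease_sim)
  tRtr <- t(Rtr)
  pos <- which(Rtr == 1, arr.ind = TRUE)
  if (nrow(pos) == 0L) stop("training matrix has no positives", call. = FALSE)
  spec <- corruption_spec(control$noise$kind, control$noise$level)
  # negative-evaluation pool for validation AUC: every unverified pair
  if (!is.null(val_pairs)) {
    cand <- which(R_full == 0)
  }

  static_neg <- NULL
  report <- vector("list", control$epochs)
  best <- list(auc = -Inf, epoch = 0L, state = state)
  stall <- 0L

  for (epoch in seq_len(control$epochs)) {
    cm <- .with_seed(corrupt_seeds[epoch], {
      out <- list(Xc = corrupt(Rtr, spec), Yc = corrupt(tRtr, spec))
      if (control$use_sim) {
        out$DSc <- corrupt(DS, spec)
        out$ESc <- corrupt(ES, spec)
      }
      out
    })
    Xc <- cm$Xc; Yc <- cm$Yc; DSc <- cm$DSc; ESc <- cm$ESc
    if (control$negatives == "static") {
      if (is.null(static_neg)) {
        static_neg <- sample_negatives(Rtr, control$n_neg,
                                       seed = sample_seeds[1])
      }
      neg <- static_neg
    } else {
      neg <- sample_negatives(Rtr, control$n_neg, seed = sample_seeds[epoch])
    }
    nm <- cbind(neg$drug, neg$disease)
    if (nrow(nm) && any(Rtr[nm] != 0)) {
      stop("internal error: sampled negative collides with a positive")
    }
    pairs <- rbind(pos, nm)
    targets <- c(rep(1, nrow(pos)), rep(0, nrow(nm)))
    ord <- .with_seed(shuffle_seeds[epoch], sample.int(nrow(pairs)))
    pairs <- pairs[ord, , drop = FALSE]
    targets <- targets[ord]

    sums <- c(total = 0, prediction = 0, drug = 0, disease = 0)
    starts <- seq(1L, nrow(pairs), by = control$batch_size)
    for (s in starts) {
      b <- s:min(s + control$batch_size - 1L, nrow(pairs))
      di <- pairs[b, 1]; ej <- pairs[b, 2]
      if (control$use_sim) {
        dU <- DS[di, , drop = FALSE]
        dUc <- DSc[di, , drop = FALSE]
        eU <- ES[ej, , drop = FALSE]
        eUc <- ESc[ej, , drop = FALSE]
      } else {
        dU <- dUc <- eU <- eUc <- NULL
      }
      res <- .anmf_batch(
        state, control,
        dX = Rtr[di, , drop = FALSE], dXc = Xc[di, , drop = FALSE],
        dU = dU, dUc = dUc,
        eX = tRtr[ej, , drop = FALSE], eXc = Yc[ej, , drop = FALSE],
        eU = eU, eUc = eUc,
        targets = targets[b], grads = control$lr > 0
      )
      if (!is.finite(res$total)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; try a smaller learning rate", call. = FALSE)
      }
      # the joint objective must decompose exactly into its components
      stopifnot(abs(res$total -
                      (res$prediction + control$phi * res$drug_recon +
                         control$psi * res$disease_recon)) <=
                  1e-8 * max(1, abs(res$total)))
      sums <- sums + c(res$total, res$prediction, res$drug_recon,
                       res$disease_recon)
      if (control$lr > 0) {
        sc <- control$lr / res$n
        for (side in c("drug", "disease")) {
          g <- res$grads[[side]]
          for (nm2 in names(g)) {
            state[[side]][[nm2]] <- state[[side]][[nm2]] - sc * g[[nm2]]
          }
        }
        state$h <- state$h - sc * res$grads$h
      }
    }

    val_auc <- NA_real_
    if (!is.null(val_pairs)) {
      model$drug_encoder <- state$drug
      model$disease_encoder <- state$disease
      model$h <- state$h
      scores <- predict_matrix(model)
      val_auc <- ranking_auc(scores[val_pairs], scores[cand])
      if (val_auc > best$auc + 1e-12) {
        best <- list(auc = val_auc, epoch = epoch, state = state)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
    }
    np <- nrow(pairs)
    report[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = sums[["total"]] / np,
      pred_loss = sums[["prediction"]] / np,
      drug_recon = sums[["drug"]] / np,
      disease_recon = sums[["disease"]] / np,
      val_auc = val_auc
    )
    if (control$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val_auc %s", epoch,
                      sums[["total"]] / np,
                      ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
    }
    if (!is.null(val_pairs) && stall >= control$patience) break
  }

  if (!is.null(val_pairs) && best$epoch > 0L) {
    state <- best$state
    model$best_epoch <- best$epoch
    model$best_val_auc <- best$auc
  } else {
    model$best_epoch <- length(Filter(Negate(is.null), report))
  }
  model$drug_encoder <- state$drug
  model$disease_encoder <- state$disease
  model$h <- state$h
  model$report <- dplyr::bind_rows(report)
  model$validation_pairs <- val_pairs
  model
}

#' Fit the similarity-free ablation (GMF baseline)
#'
#' The same pipeline with the auxiliary-information pathway disabled: the
#' similarity encoder/decoder weights are frozen at zero and the similarity
#' reconstruction terms are dropped (equivalently `alpha = beta = 1`).
#' Comparing this baseline with the full model isolates the contribution of
#' the similarity matrices.
#'
#' @inheritParams fit_anmf
#' @return An `anmf_model` with `control$use_sim = FALSE`.
#' @export
fit_gmf <- function(dataset, control = anmf_control(), train_R = NULL) {
  control$use_sim <- FALSE
  fit_anmf(dataset, control, train_R = train_R)
}

#' @export
print.anmf_model <- function(x, ...) {
  cat("<anmf_model> ", if (x$control$use_sim) "ANMF" else "GMF (no similarity)",
      ", k = ", x$control$k, ", ", length(x$drug_ids), " drugs x ",
      length(x$disease_ids), " diseases\n", sep = "")
  if (nrow(x$report)) {
    cat("  trained ", nrow(x$report), " epochs; best epoch ", x$best_epoch,
        if (!is.na(x$best_val_auc))
          paste0(" (validation AUC ", signif(x$best_val_auc, 4), ")"),
        "\n", sep = "")
  } else {
    cat("  untrained (epoch 0)\n")
  }
  invisible(x)
}
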