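#' Save and load model checkpoints as plain text
#'
#' A checkpoint is a directory of tab-separated arrays — one file per named
#' parameter tensor of each encoder (`drug_W1.tsv`, `disease_V2.tsv`, ...,
#' biases as single-column files) plus `h.tsv` and the training matrix —
#' together with `manifest.json` recording shapes, hyperparameters,
#' identifiers and the package version. Values are written with 17
#' significant digits, so a load-save round trip is bit-exact.
#'
#' @param model an `anmf_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (write) or an `anmf_model` (read), invisibly for write.
#' @export
write_model <- function(model, dir) {
  stopifnot(inherits(model, "anmf_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tensors <- .model_tensors(model)
  for (nm in names(tensors)) {
    .write_plain_matrix(tensors[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  ctl <- model$control
  ctl$noise <- unclass(ctl$noise)
  manifest <- list(
    package = "anmf", version = as.character(utils::packageVersion("anmf")),
    control = unclass(ctl),
    shapes = lapply(tensors, function(t) if (is.matrix(t)) dim(t) else length(t)),
    drug_ids = model$drug_ids, disease_ids = model$disease_ids,
    best_epoch = model$best_epoch, best_val_auc = model$best_val_auc
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ctl <- manifest$control
  noise <- corruption_spec(ctl$noise$kind, ctl$noise$level)
  control <- anmf_control(
    alpha = ctl$alpha, beta = ctl$beta, lambda = ctl$lambda, delta = ctl$delta,
    phi = ctl$phi, psi = ctl$psi, k = ctl$k, n_neg = ctl$n_neg, noise = noise,
    lr = ctl$lr, epochs = ctl$epochs, batch_size = ctl$batch_size,
    patience = ctl$patience, validation = ctl$validation,
    negatives = ctl$negatives, g = ctl$g, f = ctl$f,
    out_activation = ctl$out_activation, seed = ctl$seed
  )
  control$use_sim <- ctl$use_sim
  rd <- function(nm) .read_plain_matrix(file.path(dir, paste0(nm, ".tsv")))
  enc <- function(side) {
    structure(
      list(W1 = rd(paste0(side, "_W1")), V1 = rd(paste0(side, "_V1")),
           b_enc = drop(rd(paste0(side, "_b_enc"))),
           W2 = rd(paste0(side, "_W2")),
           b_dec_profile = drop(rd(paste0(side, "_b_dec_profile"))),
           V2 = rd(paste0(side, "_V2")),
           b_dec_sim = drop(rd(paste0(side, "_b_dec_sim")))),
      class = "anmf_encoder_params"
    )
  }
  train_R <- rd("train_R")
  drug_sim <- rd("drug_sim"); disease_sim <- rd("disease_sim")
  dimnames(train_R) <- list(manifest$drug_ids, manifest$disease_ids)
  dimnames(drug_sim) <- list(manifest$drug_ids, manifest$drug_ids)
  dimnames(disease_sim) <- list(manifest$disease_ids, manifest$disease_ids)
  structure(
    list(drug_encoder = enc("drug"), disease_encoder = enc("disease"),
         h = drop(rd("h")), control = control, train_R = train_R,
         drug_sim = drug_sim, disease_sim = disease_sim,
         drug_ids = manifest$drug_ids, disease_ids = manifest$disease_ids,
         report = tibble::tibble(), best_epoch = manifest$best_epoch,
         best_val_auc = manifest$best_val_auc %||% NA_real_),
    class = "anmf_model"
  )
}

.model_tensors <- function(model) {
  out <- list(h = model$h, train_R = model$train_R,
              drug_sim = model$drug_sim, disease_sim = model$disease_sim)
  for (side in c("drug", "disease")) {
    enc <- model[[paste0(side, "_encoder")]]
    for (nm in names(enc)) out[[paste0(side, "_", nm)]] <- enc[[nm]]
  }
  out
}

.write_plain_matrix <- function(x, path) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  writeLines(apply(matrix(sprintf("%.17g", x), nrow(x)), 1, paste,
                   collapse = "\t"), path)
}

.read_plain_matrix <- function(path) {
  unname(as.matrix(read.delim(path, header = FALSE)))
}
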