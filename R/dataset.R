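#' Assemble and validate a drug-disease dataset
#'
#' Bundles the three inputs of the model: the binary drug-disease association
#' matrix `R` (`R[i, j] = 1` iff drug `i` is verified to treat disease `j`),
#' a drug-drug similarity matrix and a disease-disease similarity matrix,
#' both with values in `[0, 1]` (e.g. Tanimoto scores for drugs, text-mining
#' scores for diseases).
#'
#' Validation enforces: binary `R`; similarity dimensions matching the number
#' of drugs / diseases; unique identifiers; similarity values in `[0, 1]`.
#' Similarity matrices that are asymmetric beyond `1e-8` are repaired as
#' `(S + t(S)) / 2` with a warning — both similarity sources are nominally
#' symmetric, and silent failure would be worse than repair. A diagonal that
#' is not exactly 1 is tolerated with a warning.
#'
#' @param R binary matrix, drugs in rows, diseases in columns.
#' @param drug_sim square numeric matrix, one row/column per drug.
#' @param disease_sim square numeric matrix, one row/column per disease.
#' @param drug_ids,disease_ids character identifiers; default to the dimnames
#'   of `R` or, failing that, of the similarity matrices.
#'
#' @return An object of class `anmf_dataset`: a list with elements
#'   `drug_ids`, `disease_ids`, `R`, `drug_sim`, `disease_sim`, all matrices
#'   carrying the identifiers as dimnames.
#'
#' @examples
#' d <- anmf_dataset(
#'   R = matrix(c(1, 0, 0, 1), 2, 2),
#'   drug_sim = diag(2), disease_sim = diag(2),
#'   drug_ids = c("DB01", "DB02"), disease_ids = c("OM01", "OM02")
#' )
#' dataset_stats(d)
#' @export
anmf_dataset <- function(R, drug_sim, disease_sim,
                         drug_ids = NULL, disease_ids = NULL) {
  R <- as.matrix(R)
  drug_sim <- as.matrix(drug_sim)
  disease_sim <- as.matrix(disease_sim)

  if (is.null(drug_ids)) {
    drug_ids <- rownames(R) %||% rownames(drug_sim) %||%
      sprintf("drug_%03d", seq_len(nrow(R)))
  }
  if (is.null(disease_ids)) {
    disease_ids <- colnames(R) %||% rownames(disease_sim) %||%
      sprintf("disease_%03d", seq_len(ncol(R)))
  }
  drug_ids <- as.character(drug_ids)
  disease_ids <- as.character(disease_ids)

  m <- nrow(R); n <- ncol(R)
  if (length(drug_ids) != m) stop("drug_ids length != nrow(R)", call. = FALSE)
  if (length(disease_ids) != n) stop("disease_ids length != ncol(R)", call. = FALSE)
  if (anyDuplicated(drug_ids)) {
    stop("duplicate drug identifier: ", drug_ids[duplicated(drug_ids)][1],
         call. = FALSE)
  }
  if (anyDuplicated(disease_ids)) {
    stop("duplicate disease identifier: ",
         disease_ids[duplicated(disease_ids)][1], call. = FALSE)
  }
  if (!all(R %in% c(0, 1))) {
    bad <- which(!(R %in% c(0, 1)))[1]
    stop("association matrix must be binary; found value ", R[bad],
         call. = FALSE)
  }
  storage.mode(R) <- "double"

  drug_sim <- .validate_sim(drug_sim, m, "drug_sim")
  disease_sim <- .validate_sim(disease_sim, n, "disease_sim")

  dimnames(R) <- list(drug_ids, disease_ids)
  dimnames(drug_sim) <- list(drug_ids, drug_ids)
  dimnames(disease_sim) <- list(disease_ids, disease_ids)

  structure(
    list(drug_ids = drug_ids, disease_ids = disease_ids,
         R = R, drug_sim = drug_sim, disease_sim = disease_sim),
    class = "anmf_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_sim <- function(S, size, label) {
  if (nrow(S) != size || ncol(S) != size) {
    stop(label, " must be ", size, "x", size, ", got ",
         nrow(S), "x", ncol(S), call. = FALSE)
  }
  if (!all(is.finite(S))) stop(label, " contains non-finite values", call. = FALSE)
  if (min(S) < -1e-8 || max(S) > 1 + 1e-8) {
    stop(label, " values must lie in [0, 1]", call. = FALSE)
  }
  asym <- max(abs(S - t(S)))
  if (asym > 1e-8) {
    warning(label, " asymmetric (max |S - t(S)| = ", signif(asym, 3),
            "); symmetrized as (S + t(S))/2", call. = FALSE)
    S <- (S + t(S)) / 2
  }
  if (max(abs(diag(S) - 1)) > 1e-6) {
    warning(label, " diagonal differs from 1 (max dev ",
            signif(max(abs(diag(S) - 1)), 3), ")", call. = FALSE)
  }
  storage.mode(S) <- "double"
  S
}

#' @export
print.anmf_dataset <- function(x, ...) {
  s <- dataset_stats(x)
  cat("<anmf_dataset> ", s$n_drugs, " drugs x ", s$n_diseases, " diseases, ",
      s$n_interactions, " verified associations (sparsity ",
      signif(s$sparsity, 4), ")\n", sep = "")
  invisible(x)
}

#' Dataset summary statistics
#'
#' Counts of drugs, diseases and verified associations, and the sparsity
#' (associations divided by all possible drug-disease pairs). For the
#' benchmark collections in this field these are, e.g., 593 drugs, 313
#' diseases and 1933 associations (sparsity 1.041e-2).
#'
#' @param d an [anmf_dataset].
#' @return A one-row tibble with columns `n_drugs`, `n_diseases`,
#'   `n_interactions`, `sparsity`.
#' @export
dataset_stats <- function(d) {
  stopifnot(inherits(d, "anmf_dataset"))
  m <- nrow(d$R); n <- ncol(d$R); k <- sum(d$R)
  tibble::tibble(
    n_drugs = m, n_diseases = n, n_interactions = as.integer(k),
    sparsity = k / (m * n)
  )
}

.resolve_index <- function(d, key, which = c("drug", "disease")) {
  which <- match.arg(which)
  ids <- if (which == "drug") d$drug_ids else d$disease_ids
  if (is.character(key)) {
    i <- match(key, ids)
    if (is.na(i)) stop("unknown ", which, " identifier: ", key, call. = FALSE)
    return(i)
  }
  i <- as.integer(key)
  if (length(i) != 1L || is.na(i) || i < 1L || i > length(ids)) {
    stop(which, " index out of range: ", key, " (valid 1..", length(ids), ")",
         call. = FALSE)
  }
  i
}

#' Interaction profiles
#'
#' `drug_profile()` returns row `i` of the association matrix — the vector of
#' known relationships between drug `i` and every disease. `disease_profile()`
#' returns column `j` — the relationships between disease `j` and every drug.
#' These are the raw inputs that the autoencoders reconstruct.
#'
#' @param d an [anmf_dataset].
#' @param drug,disease a string identifier or a 1-based index.
#' @return A named numeric vector (a copy; modifying it does not touch `d`).
#' @export
drug_profile <- function(d, drug) {
  stopifnot(inherits(d, "anmf_dataset"))
  d$R[.resolve_index(d, drug, "drug"), ]
}

#' @rdname drug_profile
#' @export
disease_profile <- function(d, disease) {
  stopifnot(inherits(d, "anmf_dataset"))
  d$R[, .resolve_index(d, disease, "disease")]
}
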