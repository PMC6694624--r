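# An evaluation split: verified associations partitioned into training and
# test positives; every unverified pair is a candidate (the negative pool at
# evaluation time). Candidates are implicit — they are recomputed from the
# dimensions and the positive sets, never stored.
.new_split <- function(train_positives, test_positives, m, n, label = NA) {
  colnames(train_positives) <- colnames(test_positives) <- c("drug", "disease")
  structure(
    list(train_positives = train_positives, test_positives = test_positives,
         m = m, n = n, label = label),
    class = "anmf_split"
  )
}

#' @export
print.anmf_split <- function(x, ...) {
  cat("<anmf_split> ", nrow(x$train_positives), " train / ",
      nrow(x$test_positives), " test positives over ", x$m, "x", x$n,
      " pairs", if (!is.na(x$label)) paste0(" [", x$label, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Training matrix and candidate pool of a split
#'
#' `split_train_matrix()` renders the training positives as a binary `m x n`
#' matrix (test positives are zero — unobserved during training).
#' `split_candidates()` returns the linear indices of all unverified cells:
#' neither a training nor a test positive.
#'
#' @param split an `anmf_split`.
#' @return A matrix, resp. an integer vector of linear indices.
#' @export
split_train_matrix <- function(split) {
  stopifnot(inherits(split, "anmf_split"))
  R <- matrix(0, split$m, split$n)
  R[split$train_positives] <- 1
  R
}

#' @rdname split_train_matrix
#' @export
split_candidates <- function(split) {
  stopifnot(inherits(split, "anmf_split"))
  verified <- c(
    (split$train_positives[, 2] - 1L) * split$m + split$train_positives[, 1],
    (split$test_positives[, 2] - 1L) * split$m + split$test_positives[, 1]
  )
  setdiff(seq_len(split$m * split$n), verified)
}

#' Ten-fold (or k-fold) cross-validation splits
#'
#' Randomly partitions all verified associations into `n_folds` near-equal
#' subsets (sizes differ by at most one). Fold `f`'s split uses subset `f`
#' as test positives and the remaining subsets as training positives; every
#' unverified pair is a candidate. Assignment is by association (pair), not
#' by drug.
#'
#' @param dataset an [anmf_dataset].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed; the same seed reproduces the same folds.
#' @return A list of `anmf_split` objects, length `n_folds`.
#' @export
make_cv_splits <- function(dataset, n_folds = 10, seed = 1) {
  stopifnot(inherits(dataset, "anmf_dataset"), .is_count(n_folds))
  pos <- which(dataset$R == 1, arr.ind = TRUE)
  if (nrow(pos) < n_folds) {
    stop("fewer verified associations (", nrow(pos), ") than folds (",
         n_folds, ")", call. = FALSE)
  }
  ord <- .with_seed(seed, sample.int(nrow(pos)))
  fold <- rep_len(seq_len(n_folds), nrow(pos))[order(ord)]
  m <- nrow(dataset$R); n <- ncol(dataset$R)
  lapply(seq_len(n_folds), function(f) {
    .new_split(pos[fold != f, , drop = FALSE], pos[fold == f, , drop = FALSE],
               m, n, label = paste0("cv fold ", f))
  })
}

#' Validation holdout: one interaction per drug
#'
#' For every drug with at least two training positives, moves one randomly
#' chosen positive into the validation (test) set; drugs with a single
#' positive keep it in training, so the new-drug experiment — which needs
#' those drugs intact — is not contaminated. Warns and returns an empty
#' validation set if every drug has at most one positive.
#'
#' @param R binary training matrix (or an [anmf_dataset], whose `R` is used).
#' @param seed integer seed.
#' @return An `anmf_split`.
#' @export
make_validation_split <- function(R, seed = 1) {
  if (inherits(R, "anmf_dataset")) R <- R$R
  stopifnot(is.matrix(R))
  eligible <- which(rowSums(R) >= 2)
  held <- .with_seed(seed, {
    do.call(rbind, lapply(eligible, function(i) {
      j <- which(R[i, ] == 1)
      cbind(i, j[sample.int(length(j), 1L)])
    }))
  })
  if (is.null(held)) {
    warning("no drug has two or more positives; empty validation set",
            call. = FALSE)
    held <- matrix(integer(), 0, 2)
  }
  pos <- which(R == 1, arr.ind = TRUE)
  keep <- !(paste(pos[, 1], pos[, 2]) %in% paste(held[, 1], held[, 2]))
  .new_split(pos[keep, , drop = FALSE], held, nrow(R), ncol(R),
             label = "validation holdout")
}

#' New-drug (cold-start) split
#'
#' Every drug with exactly one verified association contributes that
#' association to the test set; all remaining verified associations form the
#' training set. Models trained on this split see no interactions for the
#' test drugs and must rank their indication from the similarity pathway
#' alone.
#'
#' @param dataset an [anmf_dataset].
#' @return An `anmf_split`.
#' @export
make_new_drug_split <- function(dataset) {
  stopifnot(inherits(dataset, "anmf_dataset"))
  R <- dataset$R
  single <- which(rowSums(R) == 1)
  if (!length(single)) {
    stop("no drug has exactly one verified association; ",
         "the new-drug scenario is undefined", call. = FALSE)
  }
  test <- cbind(single, vapply(single, function(i) which(R[i, ] == 1)[1], 1L))
  pos <- which(R == 1, arr.ind = TRUE)
  keep <- !(pos[, 1] %in% single)
  .new_split(pos[keep, , drop = FALSE], test, nrow(R), ncol(R),
             label = "new drug")
}
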