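#' Area under the ROC curve for a two-sample score comparison
#'
#' Computed by the midrank (Mann-Whitney) statistic, which equals the area
#' under the TPR-FPR curve swept over all thresholds, with tied
#' positive/candidate scores contributing 1/2.
#'
#' @param pos scores of the (test) positives.
#' @param neg scores of the candidates.
#' @return A value in `[0, 1]`.
#' @export
ranking_auc <- function(pos, neg) {
  if (!length(pos) || !length(neg)) {
    stop("both score sets must be nonempty", call. = FALSE)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (as.numeric(length(pos)) * length(neg))
}

#' Area under the precision-recall curve
#'
#' Descending-score sweep with one operating point per distinct score value
#' and step-wise (non-interpolated) summation `sum((R_i - R_{i-1}) * P_i)`.
#' With all scores equal there is a single point and the area equals the
#' prevalence.
#'
#' @inheritParams ranking_auc
#' @return A value in `[0, 1]`.
#' @export
ranking_aupr <- function(pos, neg) {
  if (!length(pos) || !length(neg)) {
    stop("both score sets must be nonempty", call. = FALSE)
  }
  scores <- c(pos, neg)
  labels <- c(rep(1, length(pos)), rep(0, length(neg)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  tp <- cumsum(labels)
  fp <- cumsum(1 - labels)
  # operating points: last index of every tied block
  keep <- c(scores[-1] != scores[-length(scores)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / length(pos)
  sum(diff(c(0, recall)) * precision)
}

#' Hit ratio at a top-n cutoff
#'
#' For each test positive (i, j), ranks its score among the candidate pairs
#' of the same drug i (its unverified diseases). Ties are broken
#' pessimistically — tied candidates count as ranked above the positive, so
#' a constant-score model scores no hits. A positive is a hit when its rank
#' is `<= n`; the hit ratio is hits divided by the number of test positives.
#' `pool = "global"` instead ranks each positive within the full candidate
#' set of all drugs.
#'
#' @param scores `m x n` score matrix covering all pairs.
#' @param split an `anmf_split` (its test positives are scored against its
#'   candidates).
#' @param n cutoff (may be a vector).
#' @param pool `"per_drug"` (default, the convention of the neural
#'   collaborative-filtering lineage) or `"global"`.
#' @return A numeric vector of hit ratios, one per cutoff, named `hr_at_<n>`.
#' @export
hit_ratio <- function(scores, split, n = c(1, 5, 10),
                      pool = c("per_drug", "global")) {
  stopifnot(is.matrix(scores), inherits(split, "anmf_split"))
  pool <- match.arg(pool)
  test <- split$test_positives
  if (!nrow(test)) stop("split has no test positives", call. = FALSE)
  cand <- split_candidates(split)
  if (pool == "per_drug") {
    cand_drug <- (cand - 1L) %% split$m + 1L
    by_drug <- split(scores[cand], cand_drug)
    ranks <- vapply(seq_len(nrow(test)), function(t) {
      s <- scores[test[t, 1], test[t, 2]]
      pool_scores <- by_drug[[as.character(test[t, 1])]]
      1L + sum(pool_scores >= s)
    }, integer(1))
  } else {
    cand_scores <- scores[cand]
    ranks <- vapply(seq_len(nrow(test)), function(t) {
      1L + sum(cand_scores >= scores[test[t, 1], test[t, 2]])
    }, integer(1))
  }
  out <- vapply(n, function(cut) mean(ranks <= cut), numeric(1))
  names(out) <- paste0("hr_at_", n)
  out
}

#' Evaluate a model on a split
#'
#' Scores every pair with [predict_matrix()], then measures AUC and AUPR of
#' the test positives against all candidate (unverified) pairs, and the hit
#' ratio at the requested cutoffs. Training pairs are excluded from every
#' ranking pool. The model must have been trained on the split's training
#' matrix (as [run_cv()] arranges).
#'
#' @param model a fitted `anmf_model`.
#' @param split an `anmf_split`.
#' @param cutoffs hit-ratio cutoffs.
#' @param hr_pool passed to [hit_ratio()].
#' @return A one-row tibble: `auc`, `aupr`, then one `hr_at_<n>` column per
#'   cutoff.
#' @export
evaluate_split <- function(model, split, cutoffs = c(1, 5, 10),
                           hr_pool = c("per_drug", "global")) {
  stopifnot(inherits(model, "anmf_model"), inherits(split, "anmf_split"))
  scores <- predict_matrix(model)
  pos <- scores[split$test_positives]
  neg <- scores[split_candidates(split)]
  hr <- hit_ratio(scores, split, n = cutoffs, pool = match.arg(hr_pool))
  out <- tibble::tibble(auc = ranking_auc(pos, neg),
                        aupr = ranking_aupr(pos, neg))
  for (nm in names(hr)) out[[nm]] <- hr[[nm]]
  out
}

#' Cross-validated evaluation
#'
#' Retrains the model from scratch on each fold's training matrix (negatives
#' are sampled only from cells unverified in that fold — held-out positives
#' are eligible negatives by construction, as they are candidates at test
#' time) and evaluates it on the fold's test positives against all
#' candidates. Reports per-fold metrics, their mean and standard deviation,
#' and pooled metrics over the concatenated fold scores — the two reporting
#' conventions in use for this protocol.
#'
#' @param dataset an [anmf_dataset].
#' @param control an [anmf_control()]; fold `f` trains with seed
#'   `control$seed + f - 1`.
#' @param n_folds number of folds.
#' @param seed seed for the fold assignment.
#' @param model `"anmf"` (full) or `"gmf"` (similarity-free ablation).
#' @param cutoffs hit-ratio cutoffs.
#' @return A list of class `anmf_cv`: `folds` (tibble, one row per fold),
#'   `summary` (mean, sd and pooled rows).
#' @export
run_cv <- function(dataset, control = anmf_control(), n_folds = 10, seed = 1,
                   model = c("anmf", "gmf"), cutoffs = c(1, 5, 10)) {
  model <- match.arg(model)
  splits <- make_cv_splits(dataset, n_folds = n_folds, seed = seed)
  fitter <- if (model == "anmf") fit_anmf else fit_gmf
  pooled_pos <- list(); pooled_neg <- list()
  rows <- lapply(seq_along(splits), function(f) {
    sp <- splits[[f]]
    Rtr <- split_train_matrix(sp)
    dimnames(Rtr) <- dimnames(dataset$R)
    ctl <- control
    ctl$seed <- control$seed + f - 1L
    fit <- fitter(dataset, ctl, train_R = Rtr)
    scores <- predict_matrix(fit)
    pooled_pos[[f]] <<- scores[sp$test_positives]
    pooled_neg[[f]] <<- scores[split_candidates(sp)]
    dplyr::bind_cols(tibble::tibble(fold = f),
                     evaluate_split(fit, sp, cutoffs = cutoffs))
  })
  folds <- dplyr::bind_rows(rows)
  metric_cols <- setdiff(names(folds), "fold")
  pooled <- tibble::tibble(
    stat = "pooled",
    auc = ranking_auc(unlist(pooled_pos), unlist(pooled_neg)),
    aupr = ranking_aupr(unlist(pooled_pos), unlist(pooled_neg))
  )
  summary <- dplyr::bind_rows(
    dplyr::summarise(folds, stat = "mean",
                     dplyr::across(dplyr::all_of(metric_cols), mean)),
    dplyr::summarise(folds, stat = "sd",
                     dplyr::across(dplyr::all_of(metric_cols), stats::sd)),
    pooled
  )
  structure(list(folds = folds, summary = summary, model = model),
            class = "anmf_cv")
}

#' @export
print.anmf_cv <- function(x, ...) {
  cat("<anmf_cv> ", toupper(x$model), ", ", nrow(x$folds), " folds\n", sep = "")
  print(x$summary)
  invisible(x)
}
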