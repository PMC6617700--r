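# Codon-employment diagnostic classifier.
#
# Per-patient score: the Pearson correlation between the patient's
# (subset-restricted) CEC vector and a trained reference direction — the
# unit-normalized disease-minus-control mean CEC difference from the
# training samples. A cutoff on the score axis is trained on 80% splits and
# evaluated on the held-out 20%, repeated with re-randomized splits.

#' Per-patient diagnostic scores
#'
#' Correlates each sample's CEC vector with a reference direction; higher
#' scores are more disease-like by construction of the reference (disease
#' minus control). Entries undefined in either vector are excluded pairwise;
#' a patient with more than 50% undefined codons is returned as NA.
#'
#' @param cec_matrix 61 x samples matrix of per-sample CECs (see
#'   [sample_cec_matrix()]).
#' @param reference_direction Named 61-entry numeric vector.
#' @return Named numeric vector of scores.
#' @export
patient_scores <- function(cec_matrix, reference_direction) {
  ref <- reference_direction[rownames(cec_matrix)]
  vapply(seq_len(ncol(cec_matrix)), function(j) {
    v <- cec_matrix[, j]
    ok <- !is.na(v) & !is.na(ref)
    if (sum(ok) < ceiling(length(v) / 2)) return(NA_real_)
    suppressWarnings(stats::cor(v[ok], ref[ok]))
  }, numeric(1L)) |> stats::setNames(colnames(cec_matrix))
}

#' Fit the diagnostic model on a set of training samples
#'
#' @param cec_matrix 61 x samples CEC matrix.
#' @param labels Named character vector ("control"/"disease") covering the
#'   training samples.
#' @param train_ids Sample ids used for training.
#' @param cutoff_rule `"midpoint"` (midpoint of the class score means,
#'   default) or `"youden"` (maximizer of sensitivity + specificity on the
#'   training scores).
#' @return List of class `diagnostic_model`: `reference_direction` (unit
#'   norm over defined entries), `cutoff`, `train_ids`, `cutoff_rule`.
#' @export
fit_diagnostic <- function(cec_matrix, labels, train_ids,
                           cutoff_rule = c("midpoint", "youden")) {
  cutoff_rule <- match.arg(cutoff_rule)
  ctrl_ids <- train_ids[labels[train_ids] == "control"]
  dis_ids <- train_ids[labels[train_ids] == "disease"]
  if (length(ctrl_ids) < 2L || length(dis_ids) < 2L) {
    stop("need at least 2 training samples per class")
  }
  ref <- rowMeans(cec_matrix[, dis_ids, drop = FALSE], na.rm = TRUE) -
    rowMeans(cec_matrix[, ctrl_ids, drop = FALSE], na.rm = TRUE)
  nrm <- sqrt(sum(ref^2, na.rm = TRUE))
  if (!is.finite(nrm) || nrm == 0) stop("degenerate reference direction")
  ref <- ref / nrm
  scores <- patient_scores(cec_matrix[, train_ids, drop = FALSE], ref)
  cutoff <- if (cutoff_rule == "midpoint") {
    (mean(scores[ctrl_ids], na.rm = TRUE) +
       mean(scores[dis_ids], na.rm = TRUE)) / 2
  } else {
    youden_cutoff(scores, labels[train_ids])
  }
  structure(list(reference_direction = ref, cutoff = cutoff,
                 train_ids = train_ids, cutoff_rule = cutoff_rule),
            class = "diagnostic_model")
}

youden_cutoff <- function(scores, labels) {
  ok <- !is.na(scores)
  s <- scores[ok]
  l <- labels[names(s)]
  cand <- sort(unique(s))
  cand <- (c(-1, cand) + c(cand, 1)) / 2
  j <- vapply(cand, function(cut) {
    mean(s[l == "disease"] > cut) + mean(s[l == "control"] <= cut)
  }, numeric(1L))
  cand[which.max(j)]
}

#' Evaluate a fitted diagnostic model
#'
#' @param model A `diagnostic_model`.
#' @param cec_matrix 61 x samples CEC matrix.
#' @param labels Named label vector.
#' @param ids Sample ids to evaluate (default: all columns).
#' @return Named numeric vector `c(sensitivity, specificity)` (NA when a
#'   class is absent).
#' @export
evaluate_diagnostic <- function(model, cec_matrix, labels,
                                ids = colnames(cec_matrix)) {
  scores <- patient_scores(cec_matrix[, ids, drop = FALSE],
                           model$reference_direction)
  call_disease <- scores > model$cutoff
  dis <- ids[labels[ids] == "disease"]
  ctrl <- ids[labels[ids] == "control"]
  c(sensitivity = if (length(dis)) mean(call_disease[dis], na.rm = TRUE) else NA_real_,
    specificity = if (length(ctrl)) mean(!call_disease[ctrl], na.rm = TRUE) else NA_real_)
}

#' Cross-validated diagnostic performance
#'
#' Repeatedly splits the cohort into stratified training (default 80%) and
#' test groups, fits the reference direction and cutoff on the training
#' samples only, and scores the held-out samples. Per-sample CEC vectors are
#' computed once up front (they do not depend on the split).
#'
#' @param profiles `composition_profile` of the cohort's genes.
#' @param abundance Genes x samples abundance matrix.
#' @param labels Named character vector ("control"/"disease").
#' @param subset Optional gene subset used for the CECs (default GP1 usage:
#'   pass the GP1 ids; NULL scores all genes).
#' @param train_frac Training fraction (default 0.8).
#' @param n_reps Number of random splits (default 1000).
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @param cutoff_rule Passed to [fit_diagnostic()].
#' @param transform Abundance transform (default log2p1).
#' @param cec_matrix Optional precomputed 61 x samples CEC matrix (overrides
#'   `profiles`/`abundance`/`subset`).
#' @param shuffle_labels Permutation-null mode: randomly permute the sample
#'   labels at every repetition before splitting (default FALSE). Under this
#'   null the expected sensitivity and specificity are 0.5.
#' @return List of class `diagnostic_performance`: `sensitivity` and
#'   `specificity` (mean, sd, quantiles), `per_rep` (n_reps x 2 matrix),
#'   `n_reps`, `split_seeds`.
#' @export
cross_validated_diagnostics <- function(profiles, abundance, labels,
                                        subset = NULL, train_frac = 0.8,
                                        n_reps = 1000, seed = 1,
                                        cutoff_rule = "midpoint",
                                        transform = "log2p1",
                                        cec_matrix = NULL,
                                        shuffle_labels = FALSE) {
  if (is.null(cec_matrix)) {
    cec_matrix <- sample_cec_matrix(profiles, abundance, subset = subset,
                                    transform = transform)
  }
  ids <- colnames(cec_matrix)
  ctrl <- ids[labels[ids] == "control"]
  dis <- ids[labels[ids] == "disease"]
  for (cls in list(c("control", length(ctrl)), c("disease", length(dis)))) {
    n_cls <- as.integer(cls[2])
    if (floor(train_frac * n_cls) < 2L || n_cls - floor(train_frac * n_cls) < 1L) {
      stop("class '", cls[1], "' too small to stratify at train_frac = ",
           train_frac)
    }
  }
  split_seeds <- (seed + 1000L * seq_len(n_reps)) %% .Machine$integer.max
  per_rep <- matrix(NA_real_, n_reps, 2L,
                    dimnames = list(NULL, c("sensitivity", "specificity")))
  for (i in seq_len(n_reps)) {
    set.seed(as.integer(split_seeds[i]))
    lab_i <- labels
    cls_ctrl <- ctrl
    cls_dis <- dis
    if (shuffle_labels) {
      lab_i <- stats::setNames(sample(labels[ids]), ids)
      cls_ctrl <- ids[lab_i[ids] == "control"]
      cls_dis <- ids[lab_i[ids] == "disease"]
    }
    train <- c(sample(cls_ctrl, floor(train_frac * length(cls_ctrl))),
               sample(cls_dis, floor(train_frac * length(cls_dis))))
    test <- setdiff(ids, train)
    model <- fit_diagnostic(cec_matrix, lab_i, train,
                            cutoff_rule = cutoff_rule)
    per_rep[i, ] <- evaluate_diagnostic(model, cec_matrix, lab_i, test)
  }
  summarize_performance(per_rep, split_seeds)
}

summarize_performance <- function(per_rep, split_seeds = NULL) {
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  stat <- function(col) {
    v <- per_rep[, col]
    list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
         quantiles = stats::quantile(v, qs, na.rm = TRUE, names = TRUE))
  }
  structure(list(sensitivity = stat("sensitivity"),
                 specificity = stat("specificity"),
                 per_rep = per_rep, n_reps = nrow(per_rep),
                 split_seeds = split_seeds),
            class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("diagnostic_performance over %d repetitions: sensitivity %.3f +/- %.3f, specificity %.3f +/- %.3f\n",
              x$n_reps, x$sensitivity$mean, x$sensitivity$sd,
              x$specificity$mean, x$specificity$sd))
  invisible(x)
}

#' Cross-study cutoff transfer
#'
#' Fits the diagnostic model once on the full training cohort and evaluates
#' it once on the full test cohort (gene universes intersected for the CECs).
#'
#' @param train,test Lists with elements `profiles`, `abundance`, `labels`
#'   (as for [cross_validated_diagnostics()]).
#' @param subset Gene subset for scoring (intersected with both universes).
#' @param cutoff_rule,transform As in [cross_validated_diagnostics()].
#' @return List: `performance` (named sensitivity/specificity vector) and
#'   `model`.
#' @export
transfer_diagnostics <- function(train, test, subset = NULL,
                                 cutoff_rule = "midpoint",
                                 transform = "log2p1") {
  if (!is.null(subset)) {
    shared <- intersect(intersect(subset, rownames(train$abundance)),
                        rownames(test$abundance))
    if (length(shared) == 0L) stop("empty subset intersection between cohorts")
    if (length(shared) < length(subset)) {
      message("subset restricted to ", length(shared), " shared genes")
    }
    subset <- shared
  }
  train_cec <- sample_cec_matrix(train$profiles, train$abundance,
                                 subset = subset, transform = transform)
  model <- fit_diagnostic(train_cec, train$labels, colnames(train_cec),
                          cutoff_rule = cutoff_rule)
  test_cec <- sample_cec_matrix(test$profiles, test$abundance,
                                subset = subset, transform = transform)
  perf <- evaluate_diagnostic(model, test_cec, test$labels)
  list(performance = perf, model = model)
}

#' Diagnostic robustness to multiplicative abundance noise
#'
#' For each fold factor f, every abundance value is multiplied independently
#' by a factor drawn log-uniformly from \[1/f, f\] ("randomly changed, up or
#' down, by a fold factor"), and the cross-validated diagnostics are rerun
#' on the perturbed matrix. `n_noise_reps` independent perturbations are
#' averaged per fold factor.
#'
#' @inheritParams cross_validated_diagnostics
#' @param fold_factors Numeric vector of fold factors >= 1 (f = 1 leaves the
#'   data untouched).
#' @param n_noise_reps Perturbation replicates per fold factor (default 3).
#' @param cv_reps Cross-validation repetitions per perturbation (default 50).
#' @return Data frame with columns `fold_factor`, `sensitivity`,
#'   `specificity` (means over perturbations and splits).
#' @export
noise_robustness <- function(profiles, abundance, labels, subset = NULL,
                             fold_factors = c(1, 2, 5, 10),
                             n_noise_reps = 3, cv_reps = 50, train_frac = 0.8,
                             seed = 1, transform = "log2p1") {
  if (any(fold_factors < 1)) stop("fold factors must be >= 1")
  rows <- lapply(fold_factors, function(f) {
    reps <- vapply(seq_len(n_noise_reps), function(r) {
      noise_seed <- (seed + 131L * r + 7919L * round(100 * f)) %% .Machine$integer.max
      set.seed(as.integer(noise_seed))
      pert <- if (f > 1) {
        abundance * exp(matrix(stats::runif(length(abundance),
                                            -log(f), log(f)),
                               nrow(abundance), ncol(abundance)))
      } else {
        abundance
      }
      dimnames(pert) <- dimnames(abundance)
      perf <- cross_validated_diagnostics(profiles, pert, labels,
                                          subset = subset,
                                          train_frac = train_frac,
                                          n_reps = cv_reps, seed = seed,
                                          transform = transform)
      c(perf$sensitivity$mean, perf$specificity$mean)
    }, numeric(2L))
    data.frame(fold_factor = f, sensitivity = mean(reps[1, ]),
               specificity = mean(reps[2, ]))
  })
  do.call(rbind, rows)
}
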