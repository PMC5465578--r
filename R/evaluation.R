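# Evaluation protocol: rank AUC, confusion metrics, stratified k-fold CV,
# label-noise robustness experiments, and PPV-targeted threshold
# calibration.

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from midranks: the probability that a
#' randomly chosen positive outscores a randomly chosen negative, with ties
#' counted as 1/2. Equals the normalised Mann-Whitney U statistic. 0.5
#' corresponds to a model with no predictive power, 1.0 to perfect
#' separation.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) true labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metrics at a threshold
#'
#' Exact integer confusion counts and the derived ratios. PPV (precision,
#' `TP/(TP+FP)`) is reported as `NA` -- not 0 and not 100% -- when nothing
#' is predicted positive; sensitivity/specificity are likewise `NA` when
#' their class is absent.
#'
#' @param predicted logical vector of positive calls.
#' @param labels logical vector of true labels (same length).
#' @param threshold the threshold the predictions were made at (metadata,
#'   carried into the report).
#' @return object of class `"metrics_report"`: list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `sensitivity`, `specificity`, `ppv`, `threshold`,
#'   `n`.
#' @export
confusion_metrics <- function(predicted, labels, threshold = NA_real_) {
  predicted <- as.logical(predicted)
  labels <- as.logical(labels)
  if (length(predicted) != length(labels)) {
    stop("predicted and labels differ in length", call. = FALSE)
  }
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  tp <- sum(predicted & labels)
  fp <- sum(predicted & !labels)
  tn <- sum(!predicted & !labels)
  fn <- sum(!predicted & labels)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(labels),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    threshold = threshold,
    n = length(labels)
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics (n =", x$n, ", threshold =", x$threshold, ")\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy %.4f  sensitivity %s  specificity %s  PPV %s\n",
              x$accuracy,
              ifelse(is.na(x$sensitivity), "NA", sprintf("%.4f", x$sensitivity)),
              ifelse(is.na(x$specificity), "NA", sprintf("%.4f", x$specificity)),
              ifelse(is.na(x$ppv), "NA", sprintf("%.4f", x$ppv))))
  invisible(x)
}

#' Fold enrichment of positive predictions
#'
#' Ratio of the PPV to the baseline positive rate: how many times more
#' likely a predicted-positive pair is to be a true positive than a
#' randomly chosen pair. A PPV of 0.02 over a baseline rate of 78/113,526
#' is a ~29-fold enrichment.
#'
#' @param ppv positive predictive value.
#' @param baseline_rate fraction of positives in the whole universe.
#' @return enrichment factor.
#' @export
fold_enrichment <- function(ppv, baseline_rate) {
  if (baseline_rate <= 0) stop("baseline rate must be positive", call. = FALSE)
  ppv / baseline_rate
}

#' Minimum-positive-sample gate
#'
#' Models trained on too few positive pairs are not predictive (AUC near
#' chance), so an ADR is only modelled when it has at least `minimum`
#' positive pairs (default 50).
#'
#' @param positives_count number of positive pairs for the ADR.
#' @param minimum required minimum (default 50, inclusive).
#' @return logical.
#' @export
min_positives_gate <- function(positives_count, minimum = 50L) {
  positives_count >= minimum
}

# Internal: ddi scores for a row subset under fitted weights.
score_pairs_core <- function(w, s_drug, X, i1, i2, idx) {
  s_pair <- drop(X[idx, , drop = FALSE] %*% w)
  s_pair - pmax(s_drug[i1[idx]], s_drug[i2[idx]])
}

#' Stratified k-fold cross-validation of an ADR model
#'
#' Positive and baseline pairs are independently segregated at random into
#' `k` groups; each group is held out once while the model is fitted on
#' the other `k - 1`. Held-out DDI scores are pooled across folds for the
#' primary metrics (pooled metrics are stable when positives are rare);
#' per-fold metrics are reported as well. Normalised scores use each
#' training fold's own `model_max`.
#'
#' @param drugs `profile_matrix` of single-drug profiles.
#' @param pairs data.frame of the pair universe (columns `drug1`, `drug2`).
#' @param positives character vector of positive pair ids, or logical
#'   along the deduplicated pairs.
#' @param k number of folds (default 10).
#' @param seed master seed controlling fold assignment.
#' @param threshold decision threshold on the raw DDI score (default 0).
#' @return object of class `"cv_result"`: list with `scores` (data.frame
#'   `pair_id`, `fold`, `ddi`, `ddi_normalized`, `label`), `pooled`
#'   (`metrics_report` at `threshold`), `auc` (pooled), `per_fold`
#'   (data.frame of fold metrics), `k`, `seed`, `threshold`.
#' @export
kfold_cv <- function(drugs, pairs, positives, k = 10L, seed = 1L,
                     threshold = 0) {
  X <- pair_profiles(drugs, pairs)
  ids <- rownames(X$m)
  n <- length(ids)
  if (is.logical(positives)) {
    pos <- positives
    if (length(pos) != n) stop("positives length mismatch", call. = FALSE)
  } else {
    pos <- ids %in% as.character(positives)
  }
  if (sum(pos) < k || sum(!pos) < k) {
    stop("need at least k pairs in each class for ", k, "-fold CV",
         call. = FALSE)
  }
  i1 <- match(sub("\\|.*$", "", ids), rownames(drugs$m))
  i2 <- match(sub("^.*\\|", "", ids), rownames(drugs$m))

  set.seed(derive_seed(seed, 0L))
  fold <- integer(n)
  fold[pos]  <- sample(rep_len(seq_len(k), sum(pos)))
  fold[!pos] <- sample(rep_len(seq_len(k), sum(!pos)))

  all_rows <- vector("list", k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    train <- which(fold != f)
    test  <- which(fold == f)
    fit <- fit_core(drugs$m, X$m, i1, i2, train, pos[train])
    ddi <- score_pairs_core(fit$w, fit$s_drug, X$m, i1, i2, test)
    norm <- if (fit$model_max > 0) 100 * ddi / fit$model_max else
      rep(NA_real_, length(ddi))
    all_rows[[f]] <- data.frame(
      pair_id = ids[test], fold = f, ddi = ddi, ddi_normalized = norm,
      label = pos[test], stringsAsFactors = FALSE
    )
    mr <- confusion_metrics(classify(ddi, threshold), pos[test], threshold)
    per_fold[[f]] <- data.frame(
      fold = f,
      auc = if (any(pos[test]) && any(!pos[test]))
        auc_rank(ddi, pos[test]) else NA_real_,
      accuracy = mr$accuracy, sensitivity = mr$sensitivity,
      specificity = mr$specificity, ppv = mr$ppv
    )
  }
  scores <- do.call(rbind, all_rows)
  pooled <- confusion_metrics(classify(scores$ddi, threshold), scores$label,
                              threshold)
  structure(list(
    scores = scores,
    pooled = pooled,
    auc = auc_rank(scores$ddi, scores$label),
    per_fold = do.call(rbind, per_fold),
    k = k, seed = seed, threshold = threshold
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold cross-validation (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  pooled AUC: %.4f\n", x$auc))
  print(x$pooled)
  invisible(x)
}

#' Label-noise robustness experiment
#'
#' Repeats the train/test split experiment probing sensitivity to the
#' training-set composition, for three model types:
#'
#' * **Type I** — a fraction `f` of the positive pairs plus half of the
#'   baseline pairs form the training set; all remaining pairs are the
#'   test set. Probes the effect of the number of positives.
#' * **Type II** — as type I, but half of the test-set positives are
#'   additionally placed in the training *baseline* class (planted false
#'   negatives).
#' * **Type III** — as type I, but test-set baseline pairs, as many as
#'   there are true training positives, are added to the training
#'   *positive* class (planted false positives).
#'
#' Each repeat redraws the selections from a deterministic sub-seed that
#' depends on the fraction and repeat but not on the model type, so the
#' three types share the same base split and types II/III reduce exactly
#' to type I when the planted-noise count is zero. AUC is computed on the
#' held-out test set with its true labels.
#'
#' @param world a [generate_world()] result, or any list with elements
#'   `drugs` (`profile_matrix`), `pairs` (data.frame `drug1`, `drug2`) and
#'   `labels` (a `pair_label_table`).
#' @param types subset of `c("I", "II", "III")`.
#' @param fractions positive-training fractions (default
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`).
#' @param repeats repeats per (type, fraction) cell (default 50).
#' @param seed master seed.
#' @param adr_code which ADR's labels to use (default: first in the label
#'   table).
#' @return data.frame of class `"robustness_result"` with columns
#'   `model_type`, `fraction`, `rep`, `auc`.
#' @export
robustness_experiment <- function(world, types = c("I", "II", "III"),
                                  fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                  repeats = 50L, seed = 1L,
                                  adr_code = NULL) {
  types <- match.arg(types, c("I", "II", "III"), several.ok = TRUE)
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("fractions must be in (0, 1)", call. = FALSE)
  }
  drugs <- world$drugs
  X <- pair_profiles(drugs, world$pairs)
  ids <- rownames(X$m)
  adr_code <- adr_code %||% world$labels$adr_code[1L]
  pos_ids <- world$labels$pair_id[world$labels$adr_code == adr_code]
  pos <- ids %in% pos_ids
  if (!any(pos)) stop("no positive pairs for ADR ", adr_code, call. = FALSE)
  i1 <- match(sub("\\|.*$", "", ids), rownames(drugs$m))
  i2 <- match(sub("^.*\\|", "", ids), rownames(drugs$m))
  pos_idx <- which(pos)
  base_idx <- which(!pos)

  out <- list()
  for (fx in seq_along(fractions)) {
    f <- fractions[fx]
    n_tp <- round(f * length(pos_idx))
    if (n_tp < 1L) {
      stop("infeasible design: fraction ", f, " selects no positives",
           call. = FALSE)
    }
    for (r in seq_len(repeats)) {
      sub_seed <- derive_seed(seed, fx, r)
      for (ty in types) {
        # same sub-seed for every type: base draws are shared, noise draws
        # come afterwards and are skipped when the noise count is zero
        set.seed(sub_seed)
        train_pos <- sample(pos_idx, n_tp)
        train_base <- sample(base_idx, floor(length(base_idx) / 2))
        test <- setdiff(seq_along(ids), c(train_pos, train_base))
        test_pos <- intersect(test, pos_idx)
        test_base <- intersect(test, base_idx)

        train <- c(train_pos, train_base)
        train_lab <- c(rep(TRUE, length(train_pos)),
                       rep(FALSE, length(train_base)))
        if (ty == "II") {
          n_fn <- floor(length(test_pos) / 2)
          if (n_fn > 0L) {
            fn_extra <- sample(test_pos, n_fn)
            train <- c(train, fn_extra)
            train_lab <- c(train_lab, rep(FALSE, n_fn))
          }
        } else if (ty == "III") {
          n_fp <- length(train_pos)
          if (n_fp > length(test_base)) {
            stop("infeasible design: not enough test baseline pairs for ",
                 "type III false positives", call. = FALSE)
          }
          if (n_fp > 0L) {
            fp_extra <- sample(test_base, n_fp)
            train <- c(train, fp_extra)
            train_lab <- c(train_lab, rep(TRUE, n_fp))
          }
        }
        fit <- fit_core(drugs$m, X$m, i1, i2, train, train_lab)
        ddi <- score_pairs_core(fit$w, fit$s_drug, X$m, i1, i2, test)
        out[[length(out) + 1L]] <- data.frame(
          model_type = ty, fraction = f, rep = r,
          auc = auc_rank(ddi, pos[test]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("robustness_result", "data.frame")
  res
}

#' @export
summary.robustness_result <- function(object, ...) {
  agg <- stats::aggregate(auc ~ model_type + fraction, data = object,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(model_type = agg$model_type, fraction = agg$fraction,
                    mean_auc = agg$auc[, "mean"], sd_auc = agg$auc[, "sd"])
  out[order(out$model_type, out$fraction), ]
}

#' Metrics across a grid of normalised-score thresholds
#'
#' Recomputes pooled cross-validated confusion metrics at each normalised
#' DDI-score threshold in `grid` (strictly-greater classification).
#'
#' @param cv a [kfold_cv()] result.
#' @param grid numeric thresholds on the 0-100 normalised scale (default
#'   `seq(0, 90, 10)`).
#' @return data.frame: one row per threshold with counts and metrics.
#' @export
threshold_sweep <- function(cv, grid = seq(0, 90, by = 10)) {
  s <- cv$scores
  if (anyNA(s$ddi_normalized)) {
    stop("normalised scores unavailable (degenerate fold model)",
         call. = FALSE)
  }
  rows <- lapply(grid, function(t) {
    mr <- confusion_metrics(s$ddi_normalized > t, s$label, t)
    data.frame(threshold = t, tp = mr$tp, fp = mr$fp, tn = mr$tn, fn = mr$fn,
               accuracy = mr$accuracy, sensitivity = mr$sensitivity,
               specificity = mr$specificity, ppv = mr$ppv)
  })
  do.call(rbind, rows)
}

#' PPV-targeted threshold calibration
#'
#' For each target PPV, finds the smallest normalised DDI-score threshold
#' on the grid whose pooled cross-validated PPV reaches the target.
#' Thresholds where nothing is predicted positive have undefined PPV and
#' never satisfy a target; targets no grid threshold reaches are reported
#' as unreachable (`NA` threshold), never as 100% PPV.
#'
#' @param drugs,pairs,positives as in [kfold_cv()]; ignored when `cv` is
#'   supplied.
#' @param targets PPV targets (default `c(0.10, 0.20, 0.30, 0.40, 0.50)`).
#' @param grid normalised thresholds to search (default `seq(0, 90, 10)`;
#'   configurable to finer grids).
#' @param k,seed cross-validation parameters.
#' @param cv optionally a precomputed [kfold_cv()] result to calibrate on.
#' @return data.frame of class `"ppv_calibration"`: `target`, `threshold`
#'   (`NA` when unreachable), `ppv` achieved at that threshold,
#'   `reachable`; the full sweep is attached as attribute `"sweep"`.
#' @export
calibrate_ppv_thresholds <- function(drugs = NULL, pairs = NULL,
                                     positives = NULL,
                                     targets = seq(0.1, 0.5, by = 0.1),
                                     grid = seq(0, 90, by = 10),
                                     k = 10L, seed = 1L, cv = NULL) {
  if (is.null(cv)) {
    cv <- kfold_cv(drugs, pairs, positives, k = k, seed = seed)
  }
  sweep <- threshold_sweep(cv, grid)
  rows <- lapply(targets, function(tg) {
    ok <- which(!is.na(sweep$ppv) & sweep$ppv >= tg)
    if (length(ok) == 0L) {
      data.frame(target = tg, threshold = NA_real_, ppv = NA_real_,
                 reachable = FALSE)
    } else {
      i <- ok[which.min(sweep$threshold[ok])]
      data.frame(target = tg, threshold = sweep$threshold[i],
                 ppv = sweep$ppv[i], reachable = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "sweep") <- sweep
  class(out) <- c("ppv_calibration", "data.frame")
  out
}
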