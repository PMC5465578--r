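# Per-ADR scoring model: Laplacian-corrected feature weights, additive
# scores, and the synergy (DDI) score for drug pairs.

#' Laplacian-corrected feature weights
#'
#' For an ADR with `m` positive pairs among `n` training pairs, the naive
#' per-feature probability estimate `n_a/n_b` (positives with the feature
#' over rows with the feature) is unreliable when `n_b` is small: a feature
#' seen once, in a positive row, would get probability 1. Adding `K = n/m`
#' virtual rows at the baseline rate `m/n` corrects this to
#' `(n_a + 1) / (n_b + n/m)`, which tends to the baseline as `n_b -> 0`.
#' The weight is the log-ratio of corrected estimate to baseline:
#'
#' `w = log((n_a + 1) / (n_b + n/m)) - log(m/n)`
#'
#' using the natural logarithm. Features never observed in training
#' (`n_b = 0`) are given weight exactly 0, the Laplacian limit. Positive
#' weights mark features enriched in positive pairs; negative weights mark
#' depleted ones.
#'
#' @param n_b integer vector: training rows with the feature set.
#' @param n_a integer vector: positive training rows with the feature set.
#' @param n total number of training rows.
#' @param m number of positive training rows (`0 < m <= n`).
#' @return numeric weight vector, same length as `n_b`.
#' @export
#' @examples
#' laplacian_weights(5, 4, 100, 10)  # log(1/3) - log(0.1) ~ 1.204
laplacian_weights <- function(n_b, n_a, n, m) {
  if (m <= 0) stop("no positive samples (m = 0)", call. = FALSE)
  if (m > n) stop("m cannot exceed n", call. = FALSE)
  if (any(n_a > n_b) || any(n_b > n) || any(n_a < 0)) {
    stop("counts must satisfy 0 <= n_a <= n_b <= n", call. = FALSE)
  }
  w <- log((n_a + 1) / (n_b + n / m)) - log(m / n)
  w[n_b == 0] <- 0
  w
}

# Internal: fit weights + training DDI scores given precomputed matrices.
# D: drug matrix, X: pair matrix, i1/i2: drug row indices per pair,
# train: integer indices into rows of X, pos: logical along train.
fit_core <- function(D, X, i1, i2, train, pos) {
  n <- length(train)
  m <- sum(pos)
  if (m == 0L) stop("no positive samples", call. = FALSE)
  Xt <- X[train, , drop = FALSE]
  n_b <- colSums(Xt)
  n_a <- colSums(Xt[pos, , drop = FALSE])
  w <- laplacian_weights(n_b, n_a, n, m)
  s_drug <- drop(D %*% w)
  s_pair <- drop(Xt %*% w)
  ddi <- s_pair - pmax(s_drug[i1[train]], s_drug[i2[train]])
  list(w = w, n = n, m = m, n_b = n_b, n_a = n_a,
       s_drug = s_drug, ddi_train = ddi, model_max = max(ddi))
}

#' Fit a per-ADR synergy scoring model
#'
#' Fits the additive scoring model for one adverse drug reaction from a
#' training universe of drug pairs, of which the `positives` are the pairs
#' reported for the ADR and the rest are baseline samples. Rows of the
#' design are drug-*pair* profiles (the OR of the constituent drug
#' profiles); per-feature counts are taken over pair profiles and converted
#' to weights with [laplacian_weights()]. The same pair-trained weights
#' score both single drugs and pairs, which puts `S(drug)` and `S(pair)` on
#' one scale as the synergy score requires.
#'
#' The fitted object stores the maximum DDI score over the training pair
#' universe (`model_max`), used to normalise scores to a 0-100 scale.
#'
#' @param drugs `profile_matrix` of single-drug profiles.
#' @param pairs data.frame of training pairs (columns `drug1`, `drug2`, or
#'   first two columns positionally). Pairs are unordered and deduplicated.
#' @param positives character vector of positive pair ids (`min|max` form,
#'   see [pair_id()]) or a logical vector along the deduplicated pairs.
#' @param adr_code label for the ADR this model predicts.
#' @return object of class `"adr_model"` with components `adr_code`,
#'   `weights` (named numeric), `features`, `n`, `m`, `n_b`, `n_a`,
#'   `log_base`, `model_max`.
#' @seealso [predict.adr_model()], [ddi_score()], [write_adr_model()]
#' @export
adr_model <- function(drugs, pairs, positives, adr_code = "ADR") {
  X <- pair_profiles(drugs, pairs)
  ids <- rownames(X$m)
  if (is.logical(positives)) {
    if (length(positives) != length(ids)) {
      stop("logical positives must match the deduplicated pairs", call. = FALSE)
    }
    pos <- positives
  } else {
    pos <- ids %in% as.character(positives)
  }
  if (!any(pos)) stop("no positive samples", call. = FALSE)
  i1 <- match(sub("\\|.*$", "", ids), rownames(drugs$m))
  i2 <- match(sub("^.*\\|", "", ids), rownames(drugs$m))
  fit <- fit_core(drugs$m, X$m, i1, i2, seq_along(ids), pos)
  structure(list(
    adr_code  = adr_code,
    weights   = stats::setNames(fit$w, colnames(X$m)),
    features  = X$index,
    n         = fit$n,
    m         = fit$m,
    n_b       = fit$n_b,
    n_a       = fit$n_a,
    log_base  = "natural",
    model_max = fit$model_max
  ), class = "adr_model")
}

#' @export
print.adr_model <- function(x, ...) {
  cat("ADR synergy model:", x$adr_code, "\n")
  cat("  training pairs:", x$n, "(", x$m, "positive, baseline rate",
      signif(x$m / x$n, 3), ")\n")
  cat("  features:", length(x$weights), "(",
      sum(x$weights != 0), "nonzero weights )\n")
  cat("  max training DDI score:", signif(x$model_max, 4), "\n")
  invisible(x)
}

#' @export
summary.adr_model <- function(object, n_top = 10L, ...) {
  w <- sort(object$weights, decreasing = TRUE)
  out <- list(
    adr_code = object$adr_code, n = object$n, m = object$m,
    baseline = object$m / object$n,
    n_features = length(w), n_nonzero = sum(w != 0),
    n_positive_weight = sum(w > 0),
    model_max = object$model_max,
    top_weights = utils::head(w, n_top),
    bottom_weights = utils::tail(w, n_top)
  )
  class(out) <- "summary.adr_model"
  out
}

#' @export
print.summary.adr_model <- function(x, ...) {
  cat("ADR synergy model:", x$adr_code, "\n")
  cat(sprintf("  N = %d pairs, M = %d positive (baseline %.4f)\n",
              x$n, x$m, x$baseline))
  cat(sprintf("  %d features: %d nonzero, %d positive weights\n",
              x$n_features, x$n_nonzero, x$n_positive_weight))
  cat(sprintf("  max training DDI score: %.4f\n", x$model_max))
  cat("  largest weights:\n")
  print(signif(x$top_weights, 4))
  invisible(x)
}

#' @export
coef.adr_model <- function(object, ...) object$weights

#' Weight spectrum plot
#'
#' Bar plot of the fitted per-feature weights in feature order, showing how
#' broadly the model's score is distributed across drug-protein
#' interactions (a model dominated by one or two spikes relies on very few
#' interactions).
#'
#' @param x an `adr_model`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.adr_model <- function(x, ...) {
  graphics::barplot(unname(x$weights), border = NA,
                    xlab = "drug-protein interaction feature",
                    ylab = "weight",
                    main = paste("Weights:", x$adr_code), ...)
  invisible(x)
}

#' Score a single profile under a fitted model
#'
#' The additive score is the dot product of the binary profile with the
#' weight vector: each interaction the drug (or pair) has contributes its
#' feature weight. An all-zero profile scores exactly 0.
#'
#' @param profile named 0/1 vector aligned to the model's features.
#' @param model an `adr_model`.
#' @return numeric score.
#' @export
score_profile <- function(profile, model) {
  if (length(profile) != length(model$weights) ||
      (!is.null(names(profile)) &&
       !identical(names(profile), names(model$weights)))) {
    stop("profile is not aligned with the model's features", call. = FALSE)
  }
  sum(as.numeric(profile) * model$weights)
}

#' Synergy (DDI) score for one drug pair
#'
#' Scores both single-drug profiles and their OR-combined pair profile
#' under the same model, and returns the synergy score
#' `ddi = S(pair) - max(S(drug_i), S(drug_j))`. A pair is synergistic for
#' the ADR when `ddi > 0`: the combined profile must outscore the stronger
#' single drug. Identical profiles give `ddi = 0` exactly (the combined
#' profile adds nothing), and the score is symmetric in its two arguments.
#'
#' @param model an `adr_model`.
#' @param p_i,p_j `interaction_profile` vectors aligned to the model.
#' @return one-row data.frame with `s_i`, `s_j`, `s_pair`, `ddi`,
#'   `ddi_normalized` (see [normalize_scores()]; `NA` if the model's
#'   `model_max` is not positive).
#' @export
ddi_score <- function(model, p_i, p_j) {
  s_i <- score_profile(p_i, model)
  s_j <- score_profile(p_j, model)
  s_pair <- score_profile(combine_pair(p_i, p_j), model)
  ddi <- s_pair - max(s_i, s_j)
  norm <- if (is.finite(model$model_max) && model$model_max > 0) {
    100 * ddi / model$model_max
  } else NA_real_
  data.frame(s_i = s_i, s_j = s_j, s_pair = s_pair,
             ddi = ddi, ddi_normalized = norm)
}

#' Normalise DDI scores to the model's 0-100 scale
#'
#' Divides each score by the model's maximum training-universe DDI score
#' and multiplies by 100, so the training maximum maps to 100.
#' Prediction-time scores may exceed 100 and are not capped. A model whose
#' maximum score is not positive cannot be normalised (degenerate model)
#' and signals an error rather than silently clipping.
#'
#' @param scores numeric vector of DDI scores.
#' @param model_max positive maximum training DDI score.
#' @return numeric vector on the 0-100 scale.
#' @export
normalize_scores <- function(scores, model_max) {
  stop_if_not_scalar_number(model_max, "model_max")
  if (model_max <= 0) {
    stop("normalization error: model_max must be positive (degenerate model)",
         call. = FALSE)
  }
  100 * scores / model_max
}

#' Classify a DDI score against a threshold
#'
#' Strictly-greater comparison: the synergy definition requires the pair
#' score to be *higher* than the best single-drug score, so a DDI score of
#' exactly 0 is negative at the default threshold.
#'
#' @param ddi numeric vector of DDI scores.
#' @param threshold decision threshold (default 0).
#' @return logical vector.
#' @export
classify <- function(ddi, threshold = 0) {
  ddi > threshold
}

#' Predict synergy scores for drug pairs
#'
#' Scores a set of drug pairs under a fitted model: single-drug scores,
#' pair score, DDI score, normalised DDI score and the categorical call at
#' the given threshold. `above_training_max` flags normalised scores
#' exceeding 100 (pairs scoring beyond anything seen in training).
#'
#' @param object an `adr_model`.
#' @param drugs `profile_matrix` of single-drug profiles aligned to the
#'   model's features.
#' @param pairs data.frame of pairs to score (columns `drug1`, `drug2`).
#' @param threshold decision threshold on the raw DDI score (default 0).
#' @param ... unused.
#' @return data.frame: `drug1`, `drug2`, `pair_id`, `adr_code`, `s_i`,
#'   `s_j`, `s_pair`, `ddi`, `ddi_normalized`, `positive`,
#'   `above_training_max`.
#' @export
predict.adr_model <- function(object, drugs, pairs, threshold = 0, ...) {
  if (!identical(colnames(drugs$m), names(object$weights))) {
    stop("drug profiles are not aligned with the model's features",
         call. = FALSE)
  }
  X <- pair_profiles(drugs, pairs)
  ids <- rownames(X$m)
  d1 <- sub("\\|.*$", "", ids)
  d2 <- sub("^.*\\|", "", ids)
  w <- object$weights
  s_drug <- drop(drugs$m %*% w)
  s_pair <- drop(X$m %*% w)
  s_i <- s_drug[match(d1, rownames(drugs$m))]
  s_j <- s_drug[match(d2, rownames(drugs$m))]
  ddi <- s_pair - pmax(s_i, s_j)
  norm <- if (is.finite(object$model_max) && object$model_max > 0) {
    normalize_scores(ddi, object$model_max)
  } else rep(NA_real_, length(ddi))
  data.frame(
    drug1 = d1, drug2 = d2, pair_id = ids, adr_code = object$adr_code,
    s_i = unname(s_i), s_j = unname(s_j), s_pair = s_pair, ddi = ddi,
    ddi_normalized = norm,
    positive = classify(ddi, threshold),
    above_training_max = !is.na(norm) & norm > 100,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Serialization

#' Write / read a fitted model as a JSON artifact
#'
#' One artifact per ADR: `adr_code`, training counts `n` and `m`, log base,
#' `model_max`, the full feature universe, and the nonzero weights as a
#' sparse map keyed by `protein_id:category`. Round-trips losslessly (full
#' double precision) into a model usable for prediction.
#'
#' @param model an `adr_model`.
#' @param path output path (`.json`).
#' @export
write_adr_model <- function(model, path) {
  nz <- model$weights[model$weights != 0]
  obj <- list(
    adr_code  = model$adr_code,
    n         = model$n,
    m         = model$m,
    log_base  = model$log_base,
    model_max = model$model_max,
    features  = names(model$weights),
    weights   = as.list(nz)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_adr_model
#' @export
read_adr_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feat <- as.character(obj$features)
  w <- stats::setNames(numeric(length(feat)), feat)
  if (length(obj$weights) > 0) {
    wn <- unlist(obj$weights)
    w[names(wn)] <- as.numeric(wn)
  }
  protein <- sub(":[^:]*$", "", feat)
  category <- sub("^.*:", "", feat)
  idx <- data.frame(protein_id = protein, category = category, name = feat,
                    stringsAsFactors = FALSE)
  class(idx) <- c("feature_index", "data.frame")
  structure(list(
    adr_code  = obj$adr_code,
    weights   = w,
    features  = idx,
    n         = as.integer(obj$n),
    m         = as.integer(obj$m),
    n_b       = NULL,
    n_a       = NULL,
    log_base  = obj$log_base,
    model_max = as.numeric(obj$model_max)
  ), class = "adr_model")
}
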