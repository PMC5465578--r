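# Pipeline commands: the programmatic surface behind the command-line
# entry point (inst/cli/ddisyn.R). Each cmd_* function is a thin
# orchestration layer over the profile, model and evaluation functions,
# reading/writing the package's plain-text artifact formats.

resolve_profiles <- function(profiles) {
  if (inherits(profiles, "profile_matrix")) profiles else
    read_profiles(profiles)
}

resolve_labels <- function(labels) {
  if (inherits(labels, "pair_label_table")) labels else
    read_pair_labels(labels)
}

all_pairs_of <- function(drug_ids) {
  comb <- utils::combn(sort(drug_ids), 2L)
  data.frame(drug1 = comb[1L, ], drug2 = comb[2L, ],
             stringsAsFactors = FALSE)
}

#' Build profile artifacts from an interaction table
#'
#' Reads a STITCH-flavoured interaction TSV, applies the confidence /
#' organism / category filter, encodes binary profiles, prunes all-zero
#' feature columns and optionally writes the matrix as TSV. Counts at each
#' stage are logged (records read, records retained, drugs profiled,
#' features before and after pruning) and attached to the result as
#' attribute `"stage_counts"`.
#'
#' @param interactions path to the interaction TSV (or an
#'   `interaction_records` data.frame).
#' @param out optional output path for the profile TSV.
#' @param min_confidence,organism passed to [filter_interactions()].
#' @param quiet suppress stage-count messages.
#' @return the pruned `profile_matrix`, invisibly.
#' @export
cmd_build_profiles <- function(interactions, out = NULL,
                               min_confidence = 0.40, organism = "human",
                               quiet = FALSE) {
  rec <- if (inherits(interactions, "interaction_records")) interactions else
    read_interactions(interactions)
  say <- function(...) if (!quiet) message(...)
  n0 <- nrow(rec)
  flt <- filter_interactions(rec, min_confidence = min_confidence,
                             organism = organism)
  say("interaction records: ", n0, " read, ", nrow(flt),
      " retained after filtering (confidence >= ", min_confidence,
      ", organism ", organism, ", 4 categories)")
  if (nrow(flt) == 0L) {
    warning("no interactions retained; empty profile matrix", call. = FALSE)
    idx <- build_feature_index(flt)
    pm <- profile_matrix(matrix(integer(0), nrow = 0, ncol = 0,
                                dimnames = list(character(0), character(0))),
                         idx)
    attr(pm, "stage_counts") <- c(records_read = n0, records_retained = 0,
                                  drugs = 0, features_initial = 0,
                                  features_pruned = 0)
    if (!is.null(out)) write_profiles(pm, out)
    return(invisible(pm))
  }
  idx <- build_feature_index(flt)
  pm <- encode_profiles(flt, idx)
  say("profiles: ", nrow(pm$m), " drugs x ", ncol(pm$m),
      " features (", length(unique(idx$protein_id)), " proteins x 4)")
  pruned <- prune_features(pm)
  say("pruning all-zero feature columns: ", ncol(pm$m), " -> ",
      ncol(pruned$m))
  attr(pruned, "stage_counts") <- c(
    records_read = n0, records_retained = nrow(flt), drugs = nrow(pruned$m),
    features_initial = ncol(pm$m), features_pruned = ncol(pruned$m))
  if (!is.null(out)) write_profiles(pruned, out)
  invisible(pruned)
}

#' Train one model per ADR passing the positive-count gate
#'
#' The training universe for every ADR is all unordered pairs of profiled
#' drugs; positives are the pairs the label table reports for that ADR
#' (restricted to profiled drugs), everything else is baseline. ADRs with
#' fewer than `min_positives` positive pairs are skipped with a logged
#' reason. Model artifacts are written as one JSON file per ADR.
#'
#' @param profiles `profile_matrix` or path to a profile TSV.
#' @param labels `pair_label_table` or path to a label CSV.
#' @param out_dir optional directory for `model_<adr>.json` artifacts.
#' @param min_positives gate on positive pair count (default 50).
#' @param quiet suppress messages.
#' @return list with `models` (named list of `adr_model`s) and `skipped`
#'   (data.frame of gated-out ADRs with counts), invisibly.
#' @export
cmd_train <- function(profiles, labels, out_dir = NULL,
                      min_positives = 50L, quiet = FALSE) {
  pm <- resolve_profiles(profiles)
  lab <- resolve_labels(labels)
  say <- function(...) if (!quiet) message(...)
  drug_ids <- rownames(pm$m)
  lab <- lab[lab$drug1 %in% drug_ids & lab$drug2 %in% drug_ids, ,
             drop = FALSE]
  pairs <- all_pairs_of(drug_ids)
  models <- list()
  skipped <- list()
  for (adr in sort(unique(lab$adr_code))) {
    pos <- lab$pair_id[lab$adr_code == adr]
    if (!min_positives_gate(length(pos), min_positives)) {
      say("skipping ", adr, ": ", length(pos), " positive pairs (< ",
          min_positives, ")")
      skipped[[length(skipped) + 1L]] <- data.frame(
        adr_code = adr, n_positives = length(pos),
        stringsAsFactors = FALSE)
      next
    }
    fit <- adr_model(pm, pairs, pos, adr_code = adr)
    say("trained ", adr, ": N = ", fit$n, ", M = ", fit$m,
        ", model_max = ", signif(fit$model_max, 4))
    models[[adr]] <- fit
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_adr_model(fit, file.path(out_dir,
                                     paste0("model_", adr, ".json")))
    }
  }
  if (length(models) == 0L) {
    stop("no ADR passed the minimum-positive gate; nothing to train",
         call. = FALSE)
  }
  invisible(list(models = models,
                 skipped = if (length(skipped)) do.call(rbind, skipped) else
                   data.frame(adr_code = character(0),
                              n_positives = integer(0))))
}

resolve_models <- function(models) {
  if (inherits(models, "adr_model")) return(stats::setNames(list(models),
                                                            models$adr_code))
  if (is.list(models) && all(vapply(models, inherits, logical(1),
                                    "adr_model"))) {
    return(stats::setNames(models,
                           vapply(models, `[[`, character(1), "adr_code")))
  }
  files <- list.files(models, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no model artifacts found in ", models,
                                call. = FALSE)
  ms <- lapply(sort(files), read_adr_model)
  stats::setNames(ms, vapply(ms, `[[`, character(1), "adr_code"))
}

#' Batch prediction of synergy scores
#'
#' Three query modes mirroring a lookup service: one drug (score it
#' against every other profiled drug, under all models), one pair (score
#' that pair under all models), or one ADR (score every pair under that
#' ADR's model and keep the synergistic calls, `ddi > 0`). With no query,
#' all pairs are scored under all models. Output is sorted by normalised
#' score, descending.
#'
#' @param models directory of model JSON artifacts, a list of
#'   `adr_model`s, or a single model.
#' @param profiles `profile_matrix` or path to a profile TSV.
#' @param drug,pair,adr at most one of: a drug id, a length-2 vector of
#'   drug ids, or an ADR code.
#' @param threshold decision threshold on the raw DDI score.
#' @param calibration optional [calibrate_ppv_thresholds()] result used to
#'   attach a `ppv_tier` (the highest target PPV whose calibrated
#'   threshold the pair's normalised score exceeds).
#' @param out optional CSV output path.
#' @return data.frame with columns `drug_1`, `drug_2`, `adr_code`,
#'   `ddi_score`, `ddi_normalized`, `positive_flag`, `ppv_tier`.
#' @export
cmd_predict <- function(models, profiles, drug = NULL, pair = NULL,
                        adr = NULL, threshold = 0, calibration = NULL,
                        out = NULL) {
  pm <- resolve_profiles(profiles)
  ms <- resolve_models(models)
  drug_ids <- rownames(pm$m)
  if (!is.null(pair)) {
    if (length(pair) != 2L) stop("pair must be two drug ids", call. = FALSE)
    if (!all(pair %in% drug_ids)) stop("unknown drug id in pair",
                                       call. = FALSE)
    pairs <- data.frame(drug1 = pair[1L], drug2 = pair[2L],
                        stringsAsFactors = FALSE)
  } else if (!is.null(drug)) {
    if (!drug %in% drug_ids) stop("unknown drug id: ", drug, call. = FALSE)
    others <- setdiff(drug_ids, drug)
    pairs <- data.frame(drug1 = drug, drug2 = others,
                        stringsAsFactors = FALSE)
  } else {
    pairs <- all_pairs_of(drug_ids)
  }
  if (!is.null(adr)) {
    if (!adr %in% names(ms)) stop("unknown ADR code: ", adr, call. = FALSE)
    ms <- ms[adr]
  }
  res <- lapply(ms, function(m) predict(m, pm, pairs, threshold = threshold))
  res <- do.call(rbind, res)
  if (!is.null(adr)) res <- res[res$ddi > 0, , drop = FALSE]
  tier <- rep(NA_real_, nrow(res))
  if (!is.null(calibration)) {
    cal <- calibration[calibration$reachable, , drop = FALSE]
    if (nrow(cal) > 0L) {
      for (i in order(cal$target)) {
        hit <- !is.na(res$ddi_normalized) &
          res$ddi_normalized > cal$threshold[i]
        tier[hit] <- cal$target[i]
      }
    }
  }
  out_df <- data.frame(
    drug_1 = res$drug1, drug_2 = res$drug2, adr_code = res$adr_code,
    ddi_score = res$ddi, ddi_normalized = res$ddi_normalized,
    positive_flag = res$positive, ppv_tier = tier,
    stringsAsFactors = FALSE
  )
  ord <- order(-out_df$ddi_normalized, out_df$adr_code, out_df$drug_1,
               out_df$drug_2)
  out_df <- out_df[ord, , drop = FALSE]
  rownames(out_df) <- NULL
  if (!is.null(out)) utils::write.csv(out_df, out, row.names = FALSE)
  out_df
}

#' Cross-validated evaluation of every trainable ADR
#'
#' Runs stratified k-fold cross-validation for each ADR passing the
#' positive-count gate and writes a tidy metrics table: one row per ADR
#' and fold plus a pooled row (`fold = "pooled"`), with AUC, accuracy,
#' sensitivity, specificity and PPV at the given threshold.
#'
#' @inheritParams cmd_train
#' @param k,seed,threshold cross-validation parameters.
#' @param out optional CSV output path.
#' @return data.frame of metrics (and the list of `cv_result`s as
#'   attribute `"cv"`).
#' @export
cmd_evaluate <- function(profiles, labels, out = NULL, k = 10L, seed = 1L,
                         min_positives = 50L, threshold = 0,
                         quiet = FALSE) {
  pm <- resolve_profiles(profiles)
  lab <- resolve_labels(labels)
  drug_ids <- rownames(pm$m)
  lab <- lab[lab$drug1 %in% drug_ids & lab$drug2 %in% drug_ids, ,
             drop = FALSE]
  pairs <- all_pairs_of(drug_ids)
  rows <- list()
  cvs <- list()
  for (adr in sort(unique(lab$adr_code))) {
    pos <- lab$pair_id[lab$adr_code == adr]
    if (!min_positives_gate(length(pos), min_positives)) next
    cv <- kfold_cv(pm, pairs, pos, k = k, seed = seed,
                   threshold = threshold)
    cvs[[adr]] <- cv
    pf <- cv$per_fold
    rows[[length(rows) + 1L]] <- rbind(
      data.frame(adr_code = adr, n_positives = length(pos),
                 fold = as.character(pf$fold), threshold = threshold,
                 auc = pf$auc, accuracy = pf$accuracy,
                 sensitivity = pf$sensitivity,
                 specificity = pf$specificity, ppv = pf$ppv,
                 stringsAsFactors = FALSE),
      data.frame(adr_code = adr, n_positives = length(pos),
                 fold = "pooled", threshold = threshold, auc = cv$auc,
                 accuracy = cv$pooled$accuracy,
                 sensitivity = cv$pooled$sensitivity,
                 specificity = cv$pooled$specificity, ppv = cv$pooled$ppv,
                 stringsAsFactors = FALSE)
    )
  }
  if (length(rows) == 0L) {
    stop("no ADR passed the minimum-positive gate; nothing to evaluate",
         call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  attr(res, "cv") <- cvs
  res
}

#' PPV threshold calibration for every trainable ADR
#'
#' @inheritParams cmd_evaluate
#' @param targets,grid passed to [calibrate_ppv_thresholds()].
#' @return data.frame: `adr_code`, `target`, `threshold`, `ppv`,
#'   `reachable`.
#' @export
cmd_calibrate <- function(profiles, labels, out = NULL,
                          targets = seq(0.1, 0.5, by = 0.1),
                          grid = seq(0, 90, by = 10), k = 10L, seed = 1L,
                          min_positives = 50L) {
  pm <- resolve_profiles(profiles)
  lab <- resolve_labels(labels)
  drug_ids <- rownames(pm$m)
  lab <- lab[lab$drug1 %in% drug_ids & lab$drug2 %in% drug_ids, ,
             drop = FALSE]
  pairs <- all_pairs_of(drug_ids)
  rows <- list()
  for (adr in sort(unique(lab$adr_code))) {
    pos <- lab$pair_id[lab$adr_code == adr]
    if (!min_positives_gate(length(pos), min_positives)) next
    cal <- calibrate_ppv_thresholds(pm, pairs, pos, targets = targets,
                                    grid = grid, k = k, seed = seed)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(adr_code = adr, stringsAsFactors = FALSE), cal)
  }
  if (length(rows) == 0L) {
    stop("no ADR passed the minimum-positive gate", call. = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}

#' Run the robustness simulation grid
#'
#' Generates a synthetic world from `config` and runs the type I/II/III
#' robustness experiment over the fraction grid, writing one CSV row per
#' (model type, fraction, repeat).
#'
#' @param config a [world_config()].
#' @param out optional CSV output path.
#' @param types,fractions,repeats,seed passed to
#'   [robustness_experiment()].
#' @return the `robustness_result` data.frame (world attached as
#'   attribute `"world"`).
#' @export
cmd_simulate <- function(config = world_config(), out = NULL,
                         types = c("I", "II", "III"),
                         fractions = c(0.1, 0.3, 0.5, 0.7, 0.9),
                         repeats = 50L, seed = 1L) {
  world <- generate_world(config)
  res <- robustness_experiment(world, types = types, fractions = fractions,
                               repeats = repeats, seed = seed)
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE)
  }
  attr(res, "world") <- world
  res
}
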