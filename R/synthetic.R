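# Synthetic benchmark worlds: drug-protein interaction profiles with
# planted causal structure and configurable label noise, so the whole
# pipeline is testable without any external database.

#' Define a planted causal rule
#'
#' A rule states which (protein, category) interactions a drug *pair* must
#' jointly cover for the pair to be labelled positive for the rule's ADR.
#'
#' * `case_I` — a new ADR requiring simultaneous interaction with two (or
#'   more) proteins. Carrier drugs each hold only part of the required
#'   feature set, so no single drug triggers the ADR; a pair whose union
#'   covers all required features does. Needs at least 2 required
#'   features.
#' * `case_II` — enhancement of an existing ADR. The first required
#'   feature is the "solo" feature whose carriers can trigger the ADR
#'   alone with low probability `solo_rate`; the remaining feature(s) are
#'   enhancers carried by a second drug group. Pairs combining a solo
#'   carrier with an enhancer carrier are labelled positive with
#'   probability 1.
#'
#' @param adr_code ADR label for pairs satisfying this rule.
#' @param required_features character vector of feature names
#'   (`protein:category`), or `NULL` to let [generate_world()] assign
#'   unused binding features automatically.
#' @param rule_type `"case_I"` or `"case_II"`.
#' @param solo_rate for `case_II`: probability that a pair covering only
#'   the solo feature is labelled positive (default 0.05).
#' @param carrier_fraction per-group carrier fraction override (default:
#'   the world's).
#' @return list of class `"ddi_rule"`.
#' @export
ddi_rule <- function(adr_code, required_features = NULL,
                     rule_type = c("case_I", "case_II"),
                     solo_rate = 0.05, carrier_fraction = NULL) {
  rule_type <- match.arg(rule_type)
  if (!is.null(required_features)) {
    if (length(required_features) < 1L) {
      stop("required_features must be non-empty", call. = FALSE)
    }
    if (rule_type == "case_I" && length(required_features) < 2L) {
      stop("case_I rules need at least 2 required features", call. = FALSE)
    }
    if (rule_type == "case_II" && length(required_features) < 2L) {
      stop("case_II rules need a solo feature and at least one enhancer",
           call. = FALSE)
    }
  }
  structure(list(adr_code = adr_code, required_features = required_features,
                 rule_type = rule_type, solo_rate = solo_rate,
                 carrier_fraction = carrier_fraction),
            class = "ddi_rule")
}

#' Configuration of a synthetic world
#'
#' Defaults describe a desk-scale benchmark: 200 drugs by 300 proteins
#' (1,200 protein-category features), sparse background interactions, and
#' one planted two-protein Case-I rule. `background_density` is the i.i.d.
#' per-bit probability of a background interaction; causal-rule features
#' are controlled entirely by the generator (cleared, then injected into
#' carrier groups) so that rule semantics hold exactly.
#'
#' @param n_drugs,n_proteins world dimensions.
#' @param background_density per-bit background activation probability in
#'   `(0, 1)`.
#' @param rules list of [ddi_rule()]s (default: one Case-I rule).
#' @param label_fp_rate,label_fn_rate label-noise rates in `[0, 1)`
#'   applied to the generated labels via [inject_label_noise()].
#' @param carrier_fraction fraction of drugs in each carrier group
#'   (default 0.2).
#' @param bystander_copies number of noisy copies of each causal column
#'   planted into non-causal columns (default 0; used to emulate
#'   correlated off-target interactions).
#' @param bystander_flip per-bit flip probability for bystander copies.
#' @param seed RNG seed; the whole world is reproducible from it.
#' @return list of class `"world_config"`.
#' @export
world_config <- function(n_drugs = 200L, n_proteins = 300L,
                         background_density = 0.05,
                         rules = list(ddi_rule("ADR_1")),
                         label_fp_rate = 0, label_fn_rate = 0,
                         carrier_fraction = 0.2,
                         bystander_copies = 0L, bystander_flip = 0.05,
                         seed = 1L) {
  if (background_density <= 0 || background_density >= 1) {
    stop("background_density must be in (0, 1)", call. = FALSE)
  }
  if (label_fp_rate < 0 || label_fp_rate >= 1 ||
      label_fn_rate < 0 || label_fn_rate >= 1) {
    stop("label noise rates must be in [0, 1)", call. = FALSE)
  }
  if (!all(vapply(rules, inherits, logical(1), "ddi_rule"))) {
    stop("rules must be a list of ddi_rule objects", call. = FALSE)
  }
  structure(list(n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 background_density = background_density, rules = rules,
                 label_fp_rate = label_fp_rate, label_fn_rate = label_fn_rate,
                 carrier_fraction = carrier_fraction,
                 bystander_copies = as.integer(bystander_copies),
                 bystander_flip = bystander_flip,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Generate a synthetic drug-protein world with planted causal structure
#'
#' Draws background interaction bits i.i.d. at `background_density`, then
#' plants each rule: the rule's feature columns are cleared and injected
#' only into disjoint carrier groups such that no single drug carries all
#' required features of a Case-I rule. Pair labels are then assigned by
#' rule satisfaction on the OR-combined pair profile — for Case I, a pair
#' is positive exactly when its union covers all required features while
#' neither constituent does alone. Optional bystander columns (noisy
#' copies of causal columns) and label noise are added last. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [world_config()].
#' @return list of class `"synthetic_world"`: `drugs` (`profile_matrix`),
#'   `pairs` (data.frame of all unordered pairs), `labels`
#'   (`pair_label_table`, after noise), `labels_clean` (before noise),
#'   `rules` (with resolved feature names and carrier groups), `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nd <- config$n_drugs
  np <- config$n_proteins
  wd <- max(3L, nchar(as.character(nd)))
  wp <- max(3L, nchar(as.character(np)))
  drugs_ids <- sprintf("D%0*d", wd, seq_len(nd))
  proteins <- sprintf("P%0*d", wp, seq_len(np))
  cats <- ddi_categories()
  idx <- data.frame(
    protein_id = rep(proteins, each = length(cats)),
    category = rep(cats, times = np), stringsAsFactors = FALSE)
  idx$name <- paste(idx$protein_id, idx$category, sep = ":")
  class(idx) <- c("feature_index", "data.frame")
  nf <- nrow(idx)

  D <- matrix(stats::rbinom(nd * nf, 1L, config$background_density),
              nrow = nd, ncol = nf, dimnames = list(drugs_ids, idx$name))
  storage.mode(D) <- "integer"

  # resolve rule features (unused binding features for unspecified rules)
  rules <- config$rules
  auto_protein <- 1L
  taken <- unlist(lapply(rules, function(r) r$required_features))
  for (k in seq_along(rules)) {
    if (is.null(rules[[k]]$required_features)) {
      feats <- character(2L)
      for (j in 1:2) {
        repeat {
          cand <- paste0(proteins[auto_protein], ":binding")
          auto_protein <- auto_protein + 1L
          if (auto_protein > np) stop("not enough proteins for rules",
                                      call. = FALSE)
          if (!cand %in% taken) break
        }
        feats[j] <- cand
        taken <- c(taken, cand)
      }
      rules[[k]]$required_features <- feats
    }
    if (!all(rules[[k]]$required_features %in% idx$name)) {
      stop("rule features not present in the feature index", call. = FALSE)
    }
  }

  # clear all causal columns, then inject carriers
  causal <- unique(unlist(lapply(rules, function(r) r$required_features)))
  D[, causal] <- 0L
  avail <- seq_len(nd)
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    frac <- r$carrier_fraction %||% config$carrier_fraction
    n_grp <- max(1L, round(frac * nd))
    if (2L * n_grp > length(avail)) {
      stop("infeasible config: not enough drugs for carrier groups",
           call. = FALSE)
    }
    picked <- sample(avail, 2L * n_grp)
    avail <- setdiff(avail, picked)
    grp_a <- picked[seq_len(n_grp)]
    grp_b <- picked[(n_grp + 1L):(2L * n_grp)]
    feats <- r$required_features
    if (r$rule_type == "case_I") {
      half <- ceiling(length(feats) / 2)
      fa <- feats[seq_len(half)]
      fb <- feats[(half + 1L):length(feats)]
    } else {
      fa <- feats[1L]                      # solo feature
      fb <- feats[-1L]                     # enhancer feature(s)
    }
    D[grp_a, fa] <- 1L
    D[grp_b, fb] <- 1L
    rules[[k]]$carriers_a <- drugs_ids[sort(grp_a)]
    rules[[k]]$carriers_b <- drugs_ids[sort(grp_b)]
  }

  # bystanders: noisy copies of causal columns in non-causal slots
  if (config$bystander_copies > 0L) {
    pool <- setdiff(seq_len(nf), match(causal, idx$name))
    need <- config$bystander_copies * length(causal)
    if (need > length(pool)) {
      stop("infeasible config: not enough columns for bystanders",
           call. = FALSE)
    }
    targets <- sample(pool, need)
    t0 <- 0L
    for (cc in causal) {
      for (b in seq_len(config$bystander_copies)) {
        t0 <- t0 + 1L
        flips <- stats::rbinom(nd, 1L, config$bystander_flip)
        D[, targets[t0]] <- as.integer(xor(D[, cc] == 1L, flips == 1L))
      }
    }
  }

  drugs_pm <- profile_matrix(D, idx)

  # all unordered pairs
  comb <- utils::combn(nd, 2L)
  i1 <- comb[1L, ]; i2 <- comb[2L, ]
  pairs <- data.frame(drug1 = drugs_ids[i1], drug2 = drugs_ids[i2],
                      pair_id = paste(drugs_ids[i1], drugs_ids[i2],
                                      sep = "|"),
                      stringsAsFactors = FALSE)

  # labels by rule satisfaction on the combined profile
  lab_rows <- list()
  for (r in rules) {
    req <- match(r$required_features, idx$name)
    kreq <- length(req)
    Dr <- D[, req, drop = FALSE]
    cnt <- rowSums(Dr)
    joint <- rowSums((Dr[i1, , drop = FALSE] + Dr[i2, , drop = FALSE]) > 0L)
    if (r$rule_type == "case_I") {
      sat <- joint == kreq & cnt[i1] < kreq & cnt[i2] < kreq
    } else {
      solo_col <- Dr[, 1L]
      full <- joint == kreq & cnt[i1] < kreq & cnt[i2] < kreq
      solo_only <- (solo_col[i1] | solo_col[i2]) & !full
      draw <- stats::rbinom(length(i1), 1L, r$solo_rate) == 1L
      sat <- full | (solo_only & draw)
    }
    if (any(sat)) {
      lab_rows[[length(lab_rows) + 1L]] <- data.frame(
        drug1 = drugs_ids[i1[sat]], drug2 = drugs_ids[i2[sat]],
        adr_code = r$adr_code, stringsAsFactors = FALSE)
    }
  }
  if (length(lab_rows) == 0L) {
    stop("infeasible config: no positive pairs generated", call. = FALSE)
  }
  lab <- do.call(rbind, lab_rows)
  labels_clean <- pair_label_table(lab$drug1, lab$drug2, lab$adr_code)

  labels <- labels_clean
  if (config$label_fp_rate > 0 || config$label_fn_rate > 0) {
    labels <- inject_label_noise(labels_clean, config$label_fp_rate,
                                 config$label_fn_rate, pairs$pair_id)
  }

  structure(list(drugs = drugs_pm, pairs = pairs, labels = labels,
                 labels_clean = labels_clean, rules = rules,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$drugs$m), "drugs x", ncol(x$drugs$m),
      "features;", nrow(x$pairs), "pairs\n")
  cat("  rules:", length(x$rules), "; positive (pair, ADR) labels:",
      nrow(x$labels), "\n")
  for (r in x$rules) {
    cat("  -", r$adr_code, "(", r$rule_type, "):",
        paste(r$required_features, collapse = " + "), "\n")
  }
  invisible(x)
}

#' Inject false-positive / false-negative label noise
#'
#' Removes a fraction `fn_rate` of each ADR's true positive pairs and adds
#' `round(fp_rate * n_positives)` false positives drawn uniformly from the
#' unlabelled part of the pair universe (pairs not originally positive for
#' that ADR), so added false positives are disjoint from the remaining
#' true positives. Counts are relative to the original positive count.
#'
#' @param labels a `pair_label_table` of positive associations.
#' @param fp_rate,fn_rate noise rates in `[0, 1)` (`fp_rate = 1` is also
#'   accepted, matching designs that plant as many false positives as
#'   there are true positives).
#' @param universe character vector of all candidate pair ids.
#' @param seed optional seed; when `NULL`, the current RNG stream is used.
#' @return noisy `pair_label_table`.
#' @export
inject_label_noise <- function(labels, fp_rate, fn_rate, universe,
                               seed = NULL) {
  if (fp_rate < 0 || fn_rate < 0 || fn_rate >= 1 || fp_rate > 1) {
    stop("noise rates must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, 99L))
  if (fp_rate == 0 && fn_rate == 0) return(labels)
  out <- list()
  for (adr in unique(labels$adr_code)) {
    sub <- labels[labels$adr_code == adr, , drop = FALSE]
    n0 <- nrow(sub)
    n_rm <- round(fn_rate * n0)
    keep <- sub
    if (n_rm > 0L) keep <- sub[-sample.int(n0, n_rm), , drop = FALSE]
    n_fp <- round(fp_rate * n0)
    if (n_fp > 0L) {
      cand <- setdiff(universe, sub$pair_id)
      if (n_fp > length(cand)) {
        stop("universe too small for requested false positives",
             call. = FALSE)
      }
      fp_ids <- sample(cand, n_fp)
      keep <- rbind(keep, data.frame(
        drug1 = sub("\\|.*$", "", fp_ids),
        drug2 = sub("^.*\\|", "", fp_ids),
        adr_code = adr, pair_id = fp_ids, stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- keep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pair_label_table", "data.frame")
  res
}

#' Write a synthetic world in the external table dialects
#'
#' Emits the same file formats the readers consume: a STITCH-flavoured
#' interaction TSV (`chemical`, `protein` with `9606.` taxid prefix,
#' `mode`, `combined_score` on the 0-1000 integer scale) and a pair-ADR
#' label CSV (`drug1`, `drug2`, `adr_code`), so the full pipeline can run
#' end-to-end on generated data.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if missing).
#' @param score integer confidence written for every interaction (default
#'   900, i.e. 0.9 -- above the 0.40 filter).
#' @return named character vector of the two file paths.
#' @export
write_world <- function(world, dir, score = 900L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- world$drugs$m
  idx <- world$drugs$index
  wh <- which(m == 1L, arr.ind = TRUE)
  ord <- order(rownames(m)[wh[, 1L]], wh[, 2L])
  wh <- wh[ord, , drop = FALSE]
  inter <- data.frame(
    chemical = rownames(m)[wh[, 1L]],
    protein = paste0("9606.", idx$protein_id[wh[, 2L]]),
    mode = idx$category[wh[, 2L]],
    combined_score = score,
    stringsAsFactors = FALSE
  )
  p_inter <- file.path(dir, "interactions.tsv")
  utils::write.table(inter, p_inter, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_lab <- file.path(dir, "labels.csv")
  utils::write.csv(world$labels[, c("drug1", "drug2", "adr_code")], p_lab,
                   row.names = FALSE, quote = FALSE)
  c(interactions = p_inter, labels = p_lab)
}
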