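# Drug-protein interaction profiles: parsing, filtering, binary encoding,
# pair combination and feature pruning.

#' Interaction categories encoded per protein
#'
#' Each retained protein occupies a block of four bits in a profile, one per
#' interaction category, in this fixed order: binding (B), inhibition (I),
#' activation (A), catalysis (C).
#'
#' @export
ddi_categories <- function() c("binding", "inhibition", "activation", "catalysis")

#' Combine per-source interaction confidences
#'
#' Independent evidence sources for one chemical-protein interaction are
#' combined with the noisy-OR rule `1 - prod(1 - c_n)`, where `c_n` is the
#' confidence from source `n`. Monotone non-decreasing in every source and
#' absorbed by any certain (1.0) source.
#'
#' @param per_source numeric vector of per-source confidences, each in
#'   `[0, 1]`; must be non-empty.
#' @return single combined confidence in `[0, 1]`.
#' @export
#' @examples
#' combine_confidences(c(0.5, 0.5))  # 0.75
combine_confidences <- function(per_source) {
  if (length(per_source) == 0L) {
    stop("per_source must be non-empty", call. = FALSE)
  }
  if (!is.numeric(per_source) || anyNA(per_source) ||
      any(per_source < 0 | per_source > 1)) {
    stop("all per-source confidences must be in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - per_source)
}

#' Construct a table of interaction records
#'
#' Light validating constructor for the in-memory record format shared by
#' the readers, filters and encoders: one row per
#' (chemical, protein, category) interaction with a combined confidence.
#'
#' @param chemical_id,protein_id character vectors (opaque identifiers).
#' @param category character vector; each entry one of [ddi_categories()]
#'   or `"other"`.
#' @param confidence numeric vector in `[0, 1]`.
#' @param organism character vector tag (default `"human"`).
#' @return data.frame with class `"interaction_records"`.
#' @export
interaction_records <- function(chemical_id, protein_id, category, confidence,
                                organism = "human") {
  n <- length(chemical_id)
  organism <- rep_len(as.character(organism), n)
  category <- as.character(category)
  ok <- category %in% c(ddi_categories(), "other")
  if (!all(ok)) {
    stop("unknown interaction category: ",
         paste(unique(category[!ok]), collapse = ", "), call. = FALSE)
  }
  if (anyNA(confidence) || any(confidence < 0 | confidence > 1)) {
    stop("confidence values must be in [0, 1]", call. = FALSE)
  }
  out <- data.frame(
    chemical_id = as.character(chemical_id),
    protein_id  = as.character(protein_id),
    organism    = organism,
    category    = category,
    confidence  = as.numeric(confidence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Filter interaction records by confidence, organism and category
#'
#' Keeps records with combined confidence at or above `min_confidence`
#' (0.40 is the boundary of "medium" confidence and is retained), matching
#' the target organism, and belonging to one of the retained interaction
#' categories. Row order is preserved; the filter is idempotent.
#'
#' @param records an `interaction_records` data.frame.
#' @param min_confidence inclusive lower bound on confidence (default 0.40).
#' @param organism organism tag to retain (default `"human"`).
#' @param categories character vector of categories to retain.
#' @return filtered `interaction_records`.
#' @export
filter_interactions <- function(records, min_confidence = 0.40,
                                organism = "human",
                                categories = ddi_categories()) {
  stop_if_not_scalar_number(min_confidence, "min_confidence")
  keep <- records$confidence >= min_confidence &
    records$organism == organism &
    records$category %in% categories
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the feature index over (protein, category) pairs
#'
#' Every distinct protein in the filtered records gets a block of four
#' consecutive features, one per category in the fixed order B, I, A, C.
#' Proteins are ordered lexicographically (byte order, locale-independent)
#' so the index is deterministic.
#'
#' @param records filtered `interaction_records`.
#' @return data.frame of class `"feature_index"` with columns `protein_id`,
#'   `category` and `name` (`protein_id:category`); row order is feature
#'   order.
#' @export
build_feature_index <- function(records) {
  proteins <- sort(unique(as.character(records$protein_id)), method = "radix")
  cats <- ddi_categories()
  idx <- data.frame(
    protein_id = rep(proteins, each = length(cats)),
    category   = rep(cats, times = length(proteins)),
    stringsAsFactors = FALSE
  )
  idx$name <- paste(idx$protein_id, idx$category, sep = ":")
  class(idx) <- c("feature_index", "data.frame")
  idx
}

#' @export
print.feature_index <- function(x, ...) {
  cat("Feature index:", nrow(x), "features over",
      length(unique(x$protein_id)), "proteins x 4 categories\n")
  invisible(x)
}

#' Encode one drug's binary interaction profile
#'
#' A bit is 1 exactly when a retained record exists for that drug, protein
#' and category; all other bits are 0. Records whose (protein, category)
#' feature is missing from the index are an error: the index must be built
#' from a superset of the records.
#'
#' @param drug_id identifier of the drug to encode.
#' @param records filtered `interaction_records`.
#' @param index a `feature_index`.
#' @return named integer 0/1 vector of class `"interaction_profile"`,
#'   aligned to `index$name`.
#' @export
encode_profile <- function(drug_id, records, index) {
  rec <- records[records$chemical_id == drug_id, , drop = FALSE]
  bits <- integer(nrow(index))
  names(bits) <- index$name
  if (nrow(rec) > 0L) {
    key <- paste(rec$protein_id, rec$category, sep = ":")
    pos <- match(key, index$name)
    if (anyNA(pos)) {
      stop("record feature(s) not present in index: ",
           paste(unique(key[is.na(pos)]), collapse = ", "), call. = FALSE)
    }
    bits[pos] <- 1L
  }
  structure(bits, class = "interaction_profile", drug_id = drug_id)
}

#' Encode profiles for all drugs in a record table
#'
#' @inheritParams encode_profile
#' @param drop_empty drop drugs whose profile is all zero (with a warning
#'   listing them). Drugs without any retained interaction carry no signal
#'   and are excluded from modelling.
#' @return a [profile_matrix()].
#' @export
encode_profiles <- function(records, index, drop_empty = TRUE) {
  drugs <- sort(unique(records$chemical_id), method = "radix")
  m <- matrix(0L, nrow = length(drugs), ncol = nrow(index),
              dimnames = list(drugs, index$name))
  if (nrow(records) > 0L) {
    key <- paste(records$protein_id, records$category, sep = ":")
    col <- match(key, index$name)
    if (anyNA(col)) {
      stop("record feature(s) not present in index: ",
           paste(unique(key[is.na(col)]), collapse = ", "), call. = FALSE)
    }
    row <- match(records$chemical_id, drugs)
    m[cbind(row, col)] <- 1L
  }
  pm <- profile_matrix(m, index)
  if (drop_empty) {
    empty <- rownames(pm$m)[rowSums(pm$m) == 0L]
    if (length(empty) > 0L) {
      warning("excluding ", length(empty),
              " drug(s) with no retained interactions: ",
              paste(empty, collapse = ", "), call. = FALSE)
      pm$m <- pm$m[!rownames(pm$m) %in% empty, , drop = FALSE]
    }
  }
  pm
}

#' Profile matrix container
#'
#' Binary matrix of interaction profiles (rows: drugs or drug pairs,
#' columns: features) together with its feature index.
#'
#' @param m integer 0/1 matrix with row names (ids) and column names equal
#'   to `index$name`.
#' @param index the `feature_index` the columns are aligned to.
#' @return object of class `"profile_matrix"`: list with elements `m` and
#'   `index`.
#' @export
profile_matrix <- function(m, index) {
  if (nrow(m) > 0L && is.null(rownames(m))) {
    stop("profile matrix needs row ids", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate row ids in profile matrix", call. = FALSE)
  }
  if (ncol(m) != nrow(index) ||
      !identical(colnames(m) %||% character(0),
                 index$name %||% character(0))) {
    stop("matrix columns are not aligned to the feature index", call. = FALSE)
  }
  if (length(m) > 0 && !all(m %in% c(0L, 1L))) {
    stop("profile matrix entries must be 0/1", call. = FALSE)
  }
  structure(list(m = m, index = index), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Profile matrix:", nrow(x$m), "rows x", ncol(x$m), "features;",
      "density", signif(mean(x$m), 3), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$m)

#' Combine two profiles into a drug-pair profile (logical OR)
#'
#' The pair profile has a bit on wherever either or both constituent drugs
#' interact: the union of the two interaction sets. Both profiles must be
#' aligned to the same feature set.
#'
#' @param p_i,p_j `interaction_profile` vectors (or plain named 0/1
#'   vectors) over identical features.
#' @return combined `interaction_profile`.
#' @export
combine_pair <- function(p_i, p_j) {
  if (length(p_i) != length(p_j) || !identical(names(p_i), names(p_j))) {
    stop("profiles are aligned to different feature indices", call. = FALSE)
  }
  out <- as.integer(p_i | p_j)
  names(out) <- names(p_i)
  structure(out, class = "interaction_profile",
            drug_id = pair_id(attr(p_i, "drug_id") %||% "i",
                              attr(p_j, "drug_id") %||% "j"))
}

#' Build pair profiles for a set of drug pairs
#'
#' Applies the OR combination row-wise. Pairs are unordered and are
#' deduplicated under the canonical `min|max` id.
#'
#' @param drugs a `profile_matrix` of single-drug profiles.
#' @param pairs data.frame with columns `drug1`, `drug2` (or first two
#'   columns used positionally).
#' @return a `profile_matrix` of pair profiles with row ids `min|max`.
#' @export
pair_profiles <- function(drugs, pairs) {
  d1 <- as.character(pairs[[1L]])
  d2 <- as.character(pairs[[2L]])
  ids <- pair_id(d1, d2)
  keep <- !duplicated(ids)
  d1 <- d1[keep]; d2 <- d2[keep]; ids <- ids[keep]
  i1 <- match(d1, rownames(drugs$m))
  i2 <- match(d2, rownames(drugs$m))
  if (anyNA(i1) || anyNA(i2)) {
    missing <- unique(c(d1[is.na(i1)], d2[is.na(i2)]))
    stop("drug(s) not present in profile matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- drugs$m[i1, , drop = FALSE] + drugs$m[i2, , drop = FALSE]
  m[m > 1L] <- 1L
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  profile_matrix(m, drugs$index)
}

#' Drop all-zero feature columns
#'
#' Features never observed in any row carry no information (any weight on
#' them contributes nothing to any score), so they are removed and the
#' feature index remapped. Row scores under any weight vector restricted to
#' the surviving features are unchanged.
#'
#' @param pm a `profile_matrix`.
#' @return pruned `profile_matrix`.
#' @export
prune_features <- function(pm) {
  keep <- colSums(pm$m) > 0L
  idx <- pm$index[keep, , drop = FALSE]
  rownames(idx) <- NULL
  class(idx) <- c("feature_index", "data.frame")
  profile_matrix(pm$m[, keep, drop = FALSE], idx)
}

# ---------------------------------------------------------------------------
# Readers / writers

#' Read a STITCH-flavoured chemical-protein interaction table
#'
#' Accepts tab-separated tables with (case-insensitive) columns for the
#' chemical (`chemical`, `item_id_a`, `chemical_id`, `drug`), the protein
#' (`protein`, `item_id_b`, `protein_id`), the interaction category
#' (`mode`, `category`, `action`; optional — missing categories become
#' `"binding"`) and the confidence. Confidence is taken from a
#' `combined_score`/`score`/`confidence` column when present; otherwise
#' per-source columns named `score_*` are combined with the noisy-OR rule
#' ([combine_confidences()]). Integer scores on a 0-1000 scale are divided
#' by 1000 when the maximum exceeds 1. When protein ids carry a
#' `taxid.` prefix (e.g. `9606.ENSP...`), the organism is inferred from the
#' prefix (`9606` is reported as `"human"`) and the prefix is stripped from
#' the protein id; otherwise an `organism` column is used, defaulting to
#' `"human"`.
#'
#' @param path path to a TSV file.
#' @return `interaction_records` data.frame.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands) {
    hit <- match(cands, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  c_chem <- pick(c("chemical", "item_id_a", "chemical_id", "drug"))
  c_prot <- pick(c("protein", "item_id_b", "protein_id"))
  if (is.na(c_chem) || is.na(c_prot)) {
    stop("interaction table needs chemical and protein columns", call. = FALSE)
  }
  c_cat <- pick(c("mode", "category", "action"))
  c_score <- pick(c("combined_score", "score", "confidence"))
  c_org <- pick("organism")

  chem <- as.character(df[[c_chem]])
  prot <- as.character(df[[c_prot]])
  category <- if (is.na(c_cat)) rep("binding", nrow(df)) else
    tolower(as.character(df[[c_cat]]))

  if (!is.na(c_score)) {
    conf <- as.numeric(df[[c_score]])
  } else {
    src <- which(startsWith(nm, "score_"))
    if (length(src) == 0L) {
      stop("no combined confidence column and no per-source score_* columns",
           call. = FALSE)
    }
    sm <- as.matrix(df[, src, drop = FALSE])
    storage.mode(sm) <- "double"
    if (max(sm, na.rm = TRUE) > 1) sm <- sm / 1000
    sm[is.na(sm)] <- 0
    conf <- apply(sm, 1L, combine_confidences)
  }
  if (length(conf) > 0L && max(conf, na.rm = TRUE) > 1) conf <- conf / 1000

  # organism from taxid prefix of the protein id when present
  has_prefix <- grepl("^[0-9]+\\.", prot)
  organism <- if (is.na(c_org)) rep("human", nrow(df)) else
    as.character(df[[c_org]])
  taxid <- sub("\\..*$", "", prot[has_prefix])
  organism[has_prefix] <- ifelse(taxid == "9606", "human", taxid)
  prot[has_prefix] <- sub("^[0-9]+\\.", "", prot[has_prefix])

  interaction_records(chem, prot, category, conf, organism)
}

#' Read a pair-ADR label table
#'
#' Comma-separated table of positive (drug1, drug2, ADR) associations in
#' the style of pharmacovigilance pair-event tables. Columns are matched by
#' name (`drug1`/`drug_1`/`stitch_id1`, `drug2`/..., `adr_code`/`event`/
#' `adr`/`umls_cui`) and fall back to the first three columns. Pairs are
#' canonicalised to unordered ids and duplicate (pair, ADR) rows dropped.
#'
#' @param path path to a CSV file.
#' @return data.frame with columns `drug1`, `drug2`, `adr_code`, `pair_id`.
#' @export
read_pair_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(df))
  pick <- function(cands, default) {
    hit <- match(cands, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) default else hit[1L]
  }
  c1 <- pick(c("drug1", "drug_1", "stitch_id1", "drug_a"), 1L)
  c2 <- pick(c("drug2", "drug_2", "stitch_id2", "drug_b"), 2L)
  ca <- pick(c("adr_code", "event", "adr", "umls_cui", "event_umls_id"), 3L)
  pair_label_table(df[[c1]], df[[c2]], df[[ca]])
}

#' Construct a pair-ADR label table
#'
#' @param drug1,drug2 character vectors of drug ids.
#' @param adr_code character vector of ADR codes (e.g. UMLS CUIs).
#' @return data.frame with canonical `pair_id`, deduplicated, of class
#'   `"pair_label_table"`.
#' @export
pair_label_table <- function(drug1, drug2, adr_code) {
  d1 <- as.character(drug1); d2 <- as.character(drug2)
  lo <- pmin(d1, d2); hi <- pmax(d1, d2)
  out <- data.frame(
    drug1 = lo, drug2 = hi,
    adr_code = as.character(adr_code),
    pair_id = paste(lo, hi, sep = "|"),
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(paste(out$pair_id, out$adr_code)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_label_table", "data.frame")
  out
}

#' Write / read a profile matrix as TSV
#'
#' Plain text round-trip format: one header row of feature names
#' (`protein_id:category`), one row per drug/pair with the row id in the
#' first column.
#'
#' @param pm a `profile_matrix`.
#' @param path output path.
#' @export
write_profiles <- function(pm, path) {
  df <- data.frame(id = rownames(pm$m), pm$m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  feat <- colnames(m)
  protein <- sub(":[^:]*$", "", feat)
  category <- sub("^.*:", "", feat)
  idx <- data.frame(protein_id = protein, category = category, name = feat,
                    stringsAsFactors = FALSE)
  class(idx) <- c("feature_index", "data.frame")
  profile_matrix(m, idx)
}
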