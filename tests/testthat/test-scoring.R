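# Laplacian-corrected weights, additive scoring and the synergy (DDI)
# score.

test_that("Laplacian-corrected weights match hand evaluation", {
  # corrected estimate (4+1)/(5+10) = 1/3 against baseline 0.1
  expect_equal(laplacian_weights(5, 4, 100, 10), log(1 / 3) - log(0.1),
               tolerance = 1e-12)
  expect_equal(round(laplacian_weights(5, 4, 100, 10), 4), 1.2040)
  # unobserved feature: corrected estimate equals baseline, weight exactly 0
  expect_identical(laplacian_weights(0, 0, 100, 10), 0)
  # the uncorrected estimate the correction exists to fix: N_A=N_B=1 -> 100%
  expect_equal(1 / 1, 1.0)
  # corrected, the same counts give far less than certainty
  w11 <- laplacian_weights(1, 1, 100, 10)
  expect_lt((1 + 1) / (1 + 10), 1.0)
  expect_equal(w11, log(2 / 11) - log(0.1))
  expect_error(laplacian_weights(5, 4, 100, 0), "no positive")
  expect_error(laplacian_weights(5, 6, 100, 10), "0 <= n_a <= n_b")
})

test_that("corrected probability estimate stays in (0, 1] for valid counts", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    m <- sample(1:n, 1)
    n_b <- sample(0:n, 1)
    n_a <- sample(0:n_b, 1)
    est <- (n_a + 1) / (n_b + n / m)
    expect_gt(est, 0)
    expect_lte(est, 1 + 1e-12)
  }
})

test_that("additive score equals the per-bit loop oracle", {
  set.seed(5)
  nm <- paste0("P", 1:8, ":binding")
  idx <- data.frame(protein_id = paste0("P", 1:8), category = "binding",
                    name = nm, stringsAsFactors = FALSE)
  for (i in 1:30) {
    w <- rnorm(8)
    model <- structure(list(weights = stats::setNames(w, nm),
                            model_max = 1, adr_code = "X"),
                       class = "adr_model")
    bits <- random_profile(8, nm)
    expect_equal(score_profile(bits, model), score_loop(bits, w))
  }
  # all-zero profile scores exactly 0
  model <- structure(list(weights = stats::setNames(rnorm(8), nm),
                          model_max = 1), class = "adr_model")
  expect_identical(score_profile(stats::setNames(integer(8), nm), model), 0)
  # one-hot profile returns that feature's weight
  onehot <- stats::setNames(c(1L, integer(7)), nm)
  expect_equal(score_profile(onehot, model), model$weights[[1]])
  # misaligned profile is an error
  expect_error(score_profile(stats::setNames(integer(5), nm[1:5]), model),
               "not aligned")
})

test_that("synergy score follows the max rule and inclusion-exclusion", {
  nm <- c("A:binding", "B:binding", "C:binding")
  w <- stats::setNames(c(1, 1, 0.3), nm)
  model <- structure(list(weights = w, model_max = 2, adr_code = "X"),
                     class = "adr_model")
  p_i <- stats::setNames(c(1L, 0L, 0L), nm)
  p_j <- stats::setNames(c(0L, 1L, 0L), nm)
  # toy Case-I pair: each drug carries one required interaction
  sc <- ddi_score(model, p_i, p_j)
  expect_equal(sc$s_i, 1); expect_equal(sc$s_j, 1)
  expect_equal(sc$s_pair, 2); expect_equal(sc$ddi, 1)
  expect_equal(sc$ddi_normalized, 50)
  # identical profiles can never synergise
  expect_equal(ddi_score(model, p_i, p_i)$ddi, 0)
  # subset profile adds nothing: ddi <= 0
  p_sub <- stats::setNames(c(1L, 0L, 0L), nm)
  p_sup <- stats::setNames(c(1L, 1L, 1L), nm)
  expect_lte(ddi_score(model, p_sup, p_sub)$ddi, 0)
  # symmetry
  expect_equal(ddi_score(model, p_i, p_j)$ddi, ddi_score(model, p_j, p_i)$ddi)
})

test_that("inclusion-exclusion s_pair = s_i + s_j - s_shared on random pairs", {
  set.seed(9)
  nm <- paste0("P", 1:12, ":binding")
  for (i in 1:200) {
    w <- rnorm(12)
    model <- structure(list(weights = stats::setNames(w, nm), model_max = 1),
                       class = "adr_model")
    a <- random_profile(12, nm)
    b <- random_profile(12, nm)
    s_shared <- sum((a & b) * w)
    sc <- ddi_score(model, a, b)
    expect_equal(sc$s_pair, sc$s_i + sc$s_j - s_shared, tolerance = 1e-12)
  }
})

test_that("changing the log base rescales weights without changing calls or ranks", {
  set.seed(21)
  w <- fixture_world(seed = 21, n_drugs = 30, n_proteins = 20)
  m_nat <- adr_model(w$drugs, w$pairs, w$labels$pair_id)
  # base-10 weights are the natural-log weights divided by ln(10)
  w10 <- m_nat$weights / log(10)
  m10 <- m_nat; m10$weights <- w10; m10$model_max <- m_nat$model_max / log(10)
  pred_nat <- predict(m_nat, w$drugs, w$pairs)
  pred_10 <- predict(m10, w$drugs, w$pairs)
  expect_equal(pred_10$ddi * log(10), pred_nat$ddi, tolerance = 1e-10)
  expect_identical(pred_10$positive, pred_nat$positive)
  # ranks compared after rounding: rescaling is exact up to float round-off,
  # which can split near-exact ties
  expect_equal(rank(signif(pred_10$ddi, 8)),
               rank(signif(pred_nat$ddi / log(10), 8)))
  expect_equal(auc_rank(pred_10$ddi, pred_nat$pair_id %in% w$labels$pair_id),
               auc_rank(pred_nat$ddi, pred_nat$pair_id %in% w$labels$pair_id),
               tolerance = 1e-3)
})

test_that("fitting counts features over pair profiles and zeroes unseen features", {
  nm <- paste0("P", 1:3, ":binding")
  idx <- data.frame(protein_id = paste0("P", 1:3), category = "binding",
                    name = nm, stringsAsFactors = FALSE)
  m <- matrix(c(1L, 0L, 0L,
                0L, 1L, 0L,
                0L, 0L, 0L,
                1L, 1L, 0L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("d", 1:4), nm))
  drugs <- profile_matrix(m, idx)
  pairs <- data.frame(drug1 = c("d1", "d1", "d2", "d3"),
                      drug2 = c("d2", "d3", "d3", "d4"))
  fit <- adr_model(drugs, pairs, positives = "d1|d2")
  expect_equal(fit$n, 4L); expect_equal(fit$m, 1L)
  # pair profiles: d1|d2 = 110, d1|d3 = 100, d2|d3 = 010, d3|d4 = 110
  expect_equal(unname(fit$n_b), c(3, 3, 0))
  expect_equal(unname(fit$n_a), c(1, 1, 0))
  # feature never seen in training pairs gets weight exactly 0
  expect_identical(unname(fit$weights[3]), 0)
  expect_error(adr_model(drugs, pairs, positives = character(0)),
               "no positive")
})

test_that("a feature exclusive to positive rows gets the top weight among equals", {
  # three features with identical n_b = 2 but different n_a: the one seen
  # in all and only positive pairs must carry the largest weight
  nm <- paste0("P", 1:3, ":binding")
  idx <- data.frame(protein_id = paste0("P", 1:3), category = "binding",
                    name = nm, stringsAsFactors = FALSE)
  m <- matrix(c(1L, 0L, 0L,   # d1 (positive partner)
                1L, 1L, 0L,   # d2 (positive partner)
                0L, 1L, 1L,   # d3
                0L, 0L, 1L),  # d4
              nrow = 4, byrow = TRUE, dimnames = list(paste0("d", 1:4), nm))
  drugs <- profile_matrix(m, idx)
  pairs <- data.frame(drug1 = c("d1", "d1", "d2", "d3"),
                      drug2 = c("d2", "d4", "d3", "d4"))
  # pair profiles: d1|d2=110, d1|d4=101, d2|d3=111, d3|d4=011
  fit <- adr_model(drugs, pairs, positives = c("d1|d2", "d2|d3"))
  n_b <- unname(fit$n_b); n_a <- unname(fit$n_a)
  expect_equal(n_b, c(3, 3, 3))
  expect_equal(n_a, c(2, 2, 1))
  # all three features share n_b = 3; the two seen mostly in positives
  # dominate the third
  expect_equal(fit$weights[[1]], fit$weights[[2]])
  expect_gt(fit$weights[[1]], fit$weights[[3]])
  # within equal n_b, weight is strictly increasing in n_a
  expect_gt(laplacian_weights(2, 2, 4, 2), laplacian_weights(2, 1, 4, 2))
})

test_that("normalisation maps the model maximum to 100 and rejects degenerates", {
  expect_equal(normalize_scores(4, 4), 100)
  expect_equal(normalize_scores(2, 4), 50)
  expect_equal(normalize_scores(c(-1, 0, 8), 4), c(-25, 0, 200))
  expect_error(normalize_scores(1, 0), "degenerate")
  expect_error(normalize_scores(1, -2), "degenerate")
})

test_that("classification is strictly greater than the threshold", {
  expect_true(classify(0.1, 0))
  expect_false(classify(0, 0))     # a synergy score must be *higher* than 0
  expect_false(classify(-1, 0))
  expect_false(classify(-1, 5))
  expect_equal(classify(c(-1, 0, 1e-9, 3), 0), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("model JSON artifact round-trips and predicts identically", {
  w <- fixture_world(seed = 31, n_drugs = 30, n_proteins = 20)
  fit <- adr_model(w$drugs, w$pairs, w$labels$pair_id, adr_code = "C0001")
  tmp <- tempfile(fileext = ".json")
  write_adr_model(fit, tmp)
  back <- read_adr_model(tmp)
  expect_equal(back$adr_code, fit$adr_code)
  expect_equal(back$n, fit$n); expect_equal(back$m, fit$m)
  expect_equal(back$model_max, fit$model_max)
  expect_equal(back$weights, fit$weights)
  p1 <- predict(fit, w$drugs, w$pairs)
  p2 <- predict(back, w$drugs, w$pairs)
  expect_equal(p2$ddi, p1$ddi)
  expect_equal(p2$ddi_normalized, p1$ddi_normalized)
})
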