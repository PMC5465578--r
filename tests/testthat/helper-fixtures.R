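# Shared fixtures and independent oracles used across test files.

# Small hand-written record table spanning all filter dimensions.
fixture_records <- function() {
  interaction_records(
    chemical_id = c("d1", "d1", "d1", "d2", "d2", "d3", "d3", "d4"),
    protein_id  = c("pA", "pA", "pB", "pB", "pC", "pA", "pC", "pD"),
    category    = c("binding", "inhibition", "binding", "binding",
                    "activation", "binding", "other", "catalysis"),
    confidence  = c(0.9, 0.55, 0.40, 0.39, 0.8, 0.7, 0.95, 0.41),
    organism    = c("human", "human", "human", "human", "human", "mouse",
                    "human", "human")
  )
}

# Random 0/1 profile aligned to a toy feature set.
random_profile <- function(n_bits, names = paste0("P", seq_len(n_bits), ":binding"),
                           p = 0.5) {
  stats::setNames(rbinom(n_bits, 1L, p), names)
}

# Independent O(n^2) AUC oracle: fraction of correctly ordered
# (positive, negative) pairs, ties counted as 1/2.
auc_pair_counting <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Independent per-bit loop oracle for the additive score.
score_loop <- function(bits, weights) {
  s <- 0
  for (i in seq_along(bits)) s <- s + bits[[i]] * weights[[i]]
  s
}

# Tiny deterministic world for pipeline tests: small enough that every
# ADR still clears a reduced positive-count gate.
fixture_world <- function(seed = 42, n_drugs = 40, n_proteins = 30) {
  generate_world(world_config(n_drugs = n_drugs, n_proteins = n_proteins,
                              background_density = 0.08,
                              carrier_fraction = 0.25, seed = seed))
}
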