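# Small shared helpers.

#' Canonical identifier for an unordered drug pair
#'
#' Pairs are unordered: `(a, b)` and `(b, a)` are the same combination, so
#' the canonical id is `min|max`. Vectorised.
#'
#' @param drug1,drug2 character vectors of drug identifiers.
#' @return character vector of pair ids.
#' @export
#' @examples
#' pair_id("D2", "D1")  # "D1|D2"
pair_id <- function(drug1, drug2) {
  d1 <- as.character(drug1)
  d2 <- as.character(drug2)
  paste(pmin(d1, d2), pmax(d1, d2), sep = "|")
}

# Deterministically derive a sub-seed from a master seed and an index path.
# Keeps results for any single repeat/fold reproducible in isolation and
# stays inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  s <- as.double(abs(as.integer(seed)) %% 2147483647L)
  for (k in c(...)) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
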