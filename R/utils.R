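# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# signal a non-fatal, machine-filterable note (Heywood cases, clipping,
# continuity corrections). These are warnings with a subclass so simulation
# harnesses can count and muffle them without losing user-facing visibility.
dichrel_note <- function(msg, class) {
  warn(msg, class = c(class, "dichrel_note"))
}

is_square_symmetric <- function(x) {
  is.matrix(x) && nrow(x) == ncol(x) && nrow(x) >= 2 &&
    is.numeric(x) && max(abs(x - t(x))) <= 1e-8 * max(1, max(abs(x)))
}

# coerce user input (matrix or data frame of 0/1) to a validated integer matrix
as_response_matrix <- function(responses, arg = "responses") {
  if (is.data.frame(responses)) {
    responses <- as.matrix(responses)
  }
  if (!is.matrix(responses) || !is.numeric(responses)) {
    abort(sprintf("`%s` must be a numeric matrix or data frame of 0/1 scores.", arg))
  }
  if (anyNA(responses)) {
    bad <- which(is.na(responses), arr.ind = TRUE)[1, ]
    abort(sprintf("`%s` has a missing value at row %d, column %d; complete data are required.",
                  arg, bad[1], bad[2]))
  }
  if (!all(responses %in% c(0, 1))) {
    bad <- which(!(responses %in% c(0, 1)))[1]
    rc <- arrayInd(bad, dim(responses))
    abort(sprintf("`%s` has a non-binary entry (%g) at row %d, column %d.",
                  arg, responses[bad], rc[1], rc[2]))
  }
  storage.mode(responses) <- "integer"
  responses
}

# derive a deterministic 31-bit child seed from a root seed and an index,
# so every simulation cell is reproducible independently of execution order
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}
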