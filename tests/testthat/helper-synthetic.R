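# Small cohorts and hand-built objects shared across test files.

# default mechanics at a size where everything runs in seconds
small_config <- function(...) {
  synthetic_config(n_per_class = c("I" = 40L, "I1/2" = 14L, "II" = 10L), ...)
}

# deterministic, perfectly separable conditions: disjoint always-on
# signatures, no background, no noise, single structure
separable_config <- function(n_per_class = c("I" = 30L, "I1/2" = 12L, "II" = 8L),
                             ...) {
  synthetic_config(
    n_per_class = n_per_class,
    signature_bits = list(
      "I"    = data.frame(position = 1:4,   category = 1L, on_probability = 1),
      "I1/2" = data.frame(position = 11:14, category = 1L, on_probability = 1),
      "II"   = data.frame(position = 21:24, category = 1L, on_probability = 1)
    ),
    background_on_probability = 0,
    structure_noise = 0,
    structures_per_inhibitor = 1L,
    ecfp_signal_strength = 0.95,
    ecfp_background_rate = 0,
    ...
  )
}

# no class dependence anywhere: identical signatures for all classes,
# zero structural signal
null_config <- function(n_per_class = c("I" = 40L, "I1/2" = 14L, "II" = 10L)) {
  shared <- data.frame(position = 1:5, category = 1L, on_probability = 0.3)
  synthetic_config(
    n_per_class = n_per_class,
    signature_bits = list("I" = shared, "I1/2" = shared, "II" = shared),
    ecfp_signal_strength = 0
  )
}

# fingerprint from explicit on-bit positions (1-based)
fp_from_on <- function(on, len = 595L, tag = "IFP_595") {
  bits <- integer(len)
  bits[on] <- 1L
  names <- if (tag == "IFP_595") kinmode:::ifp595_names() else paste0("f", seq_len(len))
  fingerprint(bits, tag, names)
}

# interaction record from a cells matrix (85 x 7 by default)
record_from_cells <- function(cells, structure_id = "s1", inhibitor_id = "i1") {
  kinmode:::new_interaction_record(structure_id, inhibitor_id, cells)
}

random_record <- function(p = 0.2) {
  cells <- matrix(stats::rbinom(85L * 7L, 1L, p), nrow = 85L, ncol = 7L,
                  dimnames = list(paste0("P", 1:85), paste0("C", 1:7)))
  record_from_cells(cells)
}

make_dataset <- function(mat, labels, tag = "IFP_85",
                         ids = sprintf("inh_%04d", seq_len(nrow(mat)))) {
  kinmode:::new_fingerprint_dataset(
    mat, labels, ids, colnames(mat) %||% paste0("f", seq_len(ncol(mat))), tag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
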