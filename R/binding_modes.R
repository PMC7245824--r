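#' Binding mode labels
#'
#' The three crystallographically defined kinase inhibitor binding modes
#' handled by this package, in their canonical order: type I (active
#' "DFG in / alphaC-helix in" conformation), type I1/2 (intermediate
#' "DFG in / alphaC-helix out"), and type II (inactive "DFG out").
#' Serialized as `"I"`, `"I1/2"` and `"II"` throughout.
#'
#' @format Character vector of length 3.
#' @export
BINDING_MODES <- c("I", "I1/2", "II")

#' Coerce labels to a binding-mode factor
#'
#' @param x character or factor vector of binding-mode labels.
#' @return factor with levels `I`, `I1/2`, `II` (fixed order).
#' @export
binding_mode_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), BINDING_MODES)
  if (length(bad) > 0L) {
    stop("unknown binding mode label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = BINDING_MODES)
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
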