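#' Synthetic cohort configuration
#'
#' Builds the configuration object driving the synthetic cohort generator.
#' The generator emulates a KLIFS-style collection of crystallographically
#' characterized kinase inhibitors: three imbalanced binding-mode classes,
#' per-structure residue-interaction records on an 85-position x 7-category
#' grid with class-conditional signature interactions plus correlated
#' redundant copies, several structures per inhibitor with independent
#' bit-flip noise (so the consensus rule is exercised), and a sparse,
#' higher-dimensional, weaker-signal hashed feature set standing in for
#' atom environment (ECFP4-like) fingerprints.
#'
#' @param n_per_class named integer vector of inhibitors per binding mode;
#'   names must be `"I"`, `"I1/2"`, `"II"`. The default reproduces the
#'   1424 / 394 / 190 composition (2008 inhibitors in total) of the
#'   kinase inhibitor cohort the pipeline is designed around.
#' @param n_positions number of binding-site residue positions (85).
#' @param n_categories number of interaction categories per position (7).
#' @param signature_bits named list (one entry per binding mode) of data
#'   frames with columns `position`, `category`, `on_probability`: the
#'   class-conditional signature interactions.
#' @param background_on_probability probability that a non-signature,
#'   non-reserved cell is "on".
#' @param redundancy_factor number of correlated copies written for each
#'   signature cell, at reserved cells taken from the end of the
#'   position-major grid. This is the controllable mechanism behind the
#'   high redundancy that makes interaction fingerprints information-rich.
#' @param structures_per_inhibitor simulated complex structures per
#'   inhibitor (consensus fingerprints merge them).
#' @param structure_noise per-structure probability of flipping each cell.
#' @param ecfp_vocab_size size of the hashed feature identifier vocabulary
#'   for the atom-environment-like representation (identifiers are
#'   0-based integers below this value).
#' @param ecfp_signal_features_per_class number of reserved identifiers
#'   carrying class signal in the atom-environment-like representation.
#' @param ecfp_signal_strength probability offset added to
#'   `ecfp_background_rate` for a class member's own signal identifiers.
#' @param ecfp_background_rate inclusion probability of all other
#'   identifiers.
#' @param seed default master seed used by [generate_dataset()].
#' @return object of class `synth_config` (a validated list).
#' @seealso [default_config()], [generate_dataset()]
#' @export
synthetic_config <- function(n_per_class = c("I" = 1424L, "I1/2" = 394L, "II" = 190L),
                             n_positions = 85L,
                             n_categories = 7L,
                             signature_bits = default_signature_bits(),
                             background_on_probability = 0.015,
                             redundancy_factor = 7L,
                             structures_per_inhibitor = 3L,
                             structure_noise = 0.01,
                             ecfp_vocab_size = 4000L,
                             ecfp_signal_features_per_class = 10L,
                             ecfp_signal_strength = 0.13,
                             ecfp_background_rate = 0.005,
                             seed = 101L) {
  config <- list(
    n_per_class = n_per_class,
    n_positions = as.integer(n_positions),
    n_categories = as.integer(n_categories),
    signature_bits = signature_bits,
    background_on_probability = background_on_probability,
    redundancy_factor = as.integer(redundancy_factor),
    structures_per_inhibitor = as.integer(structures_per_inhibitor),
    structure_noise = structure_noise,
    ecfp_vocab_size = as.integer(ecfp_vocab_size),
    ecfp_signal_features_per_class = as.integer(ecfp_signal_features_per_class),
    ecfp_signal_strength = ecfp_signal_strength,
    ecfp_background_rate = ecfp_background_rate,
    seed = as.integer(seed)
  )
  class(config) <- "synth_config"
  validate_config(config)
  config
}

#' Default class-conditional signature interactions
#'
#' Type I and type II occupy disjoint ten-position blocks (category 1).
#' The intermediate type I1/2 mode -- which combines binding
#' characteristics of both neighbours -- has no positions of its own:
#' its signature is the union of both blocks at intermediate
#' probabilities, so it genuinely sits between type I and type II in
#' interaction space and is the hardest class to separate, the ordering
#' observed for real cohorts. Type II gets the most reliable signature,
#' mirroring the distinctive back-pocket contacts of that binding mode.
#'
#' @return named list of data frames (`position`, `category`,
#'   `on_probability`), one per binding mode.
#' @export
default_signature_bits <- function() {
  list(
    "I"    = data.frame(position = 1:10,  category = 1L, on_probability = 0.48),
    "I1/2" = data.frame(position = c(1:10, 21:30), category = 1L,
                        on_probability = c(rep(0.36, 10), rep(0.30, 10))),
    "II"   = data.frame(position = 21:30, category = 1L, on_probability = 0.62)
  )
}

#' Default synthetic cohort configuration
#'
#' Pure convenience wrapper: returns [synthetic_config()] with all
#' defaults, i.e. the 1424 / 394 / 190 (total 2008) class composition and
#' the documented generator settings. Two calls compare equal.
#'
#' @return `synth_config` object.
#' @export
default_config <- function() {
  synthetic_config()
}

validate_config <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!identical(sort(names(config$n_per_class)), sort(BINDING_MODES))) {
    stop("n_per_class must be named with exactly the three binding modes ",
         paste(BINDING_MODES, collapse = ", "))
  }
  if (any(config$n_per_class < 1L)) stop("class counts must be positive")
  probs <- c(config$background_on_probability, config$structure_noise,
             config$ecfp_signal_strength, config$ecfp_background_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (config$ecfp_signal_strength + config$ecfp_background_rate > 1) {
    stop("ecfp_background_rate + ecfp_signal_strength must not exceed 1")
  }
  if (config$redundancy_factor < 1L) stop("redundancy_factor must be >= 1")
  if (config$structures_per_inhibitor < 1L) {
    stop("structures_per_inhibitor must be >= 1")
  }
  if (!identical(sort(names(config$signature_bits)), sort(BINDING_MODES))) {
    stop("signature_bits must be a named list over the three binding modes")
  }
  for (mode in BINDING_MODES) {
    sb <- config$signature_bits[[mode]]
    if (!all(c("position", "category", "on_probability") %in% names(sb))) {
      stop("signature_bits entries need position, category, on_probability")
    }
    if (any(sb$position < 1L | sb$position > config$n_positions) ||
        any(sb$category < 1L | sb$category > config$n_categories)) {
      stop("signature cell outside the ", config$n_positions, " x ",
           config$n_categories, " interaction grid (class ", mode, ")")
    }
    if (any(sb$on_probability < 0 | sb$on_probability > 1)) {
      stop("signature on_probability must lie in [0, 1]")
    }
  }
  if (3L * config$ecfp_signal_features_per_class > config$ecfp_vocab_size) {
    stop("reserved signal identifiers exceed ecfp_vocab_size")
  }
  # reserved copy cells are taken from the end of the position-major grid
  layout <- signature_layout(config)
  if (length(intersect(layout$signature_flat, layout$copy_flat)) > 0L ||
      min(layout$copy_flat) < 1L) {
    stop("signature cells and their ", config$redundancy_factor,
         " redundant copies do not fit the interaction grid")
  }
  invisible(config)
}

# Flat (position-major, 1-based) cell layout of signature bits and their
# reserved redundant-copy cells. Copy blocks are keyed by *distinct*
# signature cell (classes sharing a cell share its copies, so overlap in
# signatures carries over to the redundant region) and fill the tail of
# the grid: copy k of the u-th distinct cell (order of first appearance,
# class-major) sits at flat index n_cells - U*R + (u-1)*R + k.
signature_layout <- function(config) {
  n_cells <- config$n_positions * config$n_categories
  per_class <- lapply(BINDING_MODES, function(mode) {
    sb <- config$signature_bits[[mode]]
    as.integer((sb$position - 1L) * config$n_categories + sb$category)
  })
  names(per_class) <- BINDING_MODES
  distinct <- unique(unlist(per_class, use.names = FALSE))
  r <- config$redundancy_factor
  copy_start <- n_cells - length(distinct) * r
  copy_of <- function(u) as.integer(copy_start + (u - 1L) * r + seq_len(r))
  copy_per_class <- lapply(per_class, function(cells) {
    as.integer(unlist(lapply(match(cells, distinct), copy_of)))
  })
  list(
    signature_flat = distinct,
    signature_per_class = per_class,
    copy_flat = as.integer(unlist(lapply(seq_along(distinct), copy_of))),
    copy_per_class = copy_per_class
  )
}

new_interaction_record <- function(structure_id, inhibitor_id, cells) {
  structure(
    list(structure_id = structure_id, inhibitor_id = inhibitor_id,
         cells = cells),
    class = "interaction_record"
  )
}

# flat position-major vector -> 85 x 7 integer matrix
flat_to_cells <- function(flat, n_positions, n_categories) {
  m <- matrix(as.integer(flat), nrow = n_positions, ncol = n_categories,
              byrow = TRUE)
  dimnames(m) <- list(paste0("P", seq_len(n_positions)),
                      paste0("C", seq_len(n_categories)))
  m
}

#' Generate per-structure residue interaction records
#'
#' For each inhibitor a base interaction profile is drawn once: its
#' class's signature cells switch on with their `on_probability`, each
#' signature draw is duplicated into `redundancy_factor` reserved copy
#' cells at the tail of the position-major grid (correlated redundancy),
#' and every remaining cell switches on with
#' `background_on_probability`. Each of the
#' `structures_per_inhibitor` records is then the base profile with every
#' cell independently flipped with probability `structure_noise`, so
#' records of one inhibitor are noisy replicates, as complex structures
#' of the same inhibitor are.
#'
#' @param config `synth_config`.
#' @param labels binding-mode labels, one per inhibitor (character or
#'   factor); names, if present, are used as inhibitor identifiers.
#' @param rng_seed integer seed.
#' @return named list mapping inhibitor id to a list of
#'   `interaction_record` objects (one per structure).
#' @export
generate_interaction_profiles <- function(config, labels, rng_seed) {
  validate_config(config)
  labels <- binding_mode_factor(labels)
  ids <- names(labels) %||% sprintf("inh_%04d", seq_along(labels))
  layout <- signature_layout(config)
  n_cells <- config$n_positions * config$n_categories
  r <- config$redundancy_factor
  # background cells for a class: everything but its own signature and copies
  bg_cells <- lapply(BINDING_MODES, function(mode) {
    setdiff(seq_len(n_cells),
            c(layout$signature_per_class[[mode]],
              layout$copy_per_class[[mode]]))
  })
  names(bg_cells) <- BINDING_MODES

  with_seed(rng_seed, {
    out <- vector("list", length(labels))
    names(out) <- ids
    for (i in seq_along(labels)) {
      mode <- as.character(labels[[i]])
      sb <- config$signature_bits[[mode]]
      base <- integer(n_cells)
      sig_draw <- stats::rbinom(nrow(sb), 1L, sb$on_probability)
      base[layout$signature_per_class[[mode]]] <- sig_draw
      base[layout$copy_per_class[[mode]]] <- rep(sig_draw, each = r)
      bg <- bg_cells[[mode]]
      base[bg] <- stats::rbinom(length(bg), 1L,
                                config$background_on_probability)
      recs <- vector("list", config$structures_per_inhibitor)
      for (j in seq_len(config$structures_per_inhibitor)) {
        cells <- if (config$structure_noise > 0) {
          flips <- stats::rbinom(n_cells, 1L, config$structure_noise)
          as.integer(xor(base, flips))
        } else {
          base
        }
        recs[[j]] <- new_interaction_record(
          structure_id = sprintf("%s_s%d", ids[[i]], j),
          inhibitor_id = ids[[i]],
          cells = flat_to_cells(cells, config$n_positions,
                                config$n_categories)
        )
      }
      out[[i]] <- recs
    }
    out
  })
}

#' Generate sparse hashed structural feature sets
#'
#' Emulates atom-environment (ECFP4-like) fingerprints as sets of 0-based
#' integer feature identifiers below `ecfp_vocab_size`. Each binding mode
#' reserves `ecfp_signal_features_per_class` identifiers (class-major
#' blocks starting at identifier 0); a class member includes its own
#' class's identifiers with probability
#' `ecfp_background_rate + ecfp_signal_strength`, and every other
#' identifier with `ecfp_background_rate`. The representation is
#' deliberately higher-dimensional, sparser, and weaker in signal than
#' the interaction grid.
#'
#' @inheritParams generate_interaction_profiles
#' @return named list mapping inhibitor id to a sorted integer vector of
#'   feature identifiers.
#' @export
generate_structural_features <- function(config, labels, rng_seed) {
  validate_config(config)
  labels <- binding_mode_factor(labels)
  ids <- names(labels) %||% sprintf("inh_%04d", seq_along(labels))
  m <- config$ecfp_signal_features_per_class
  vocab <- config$ecfp_vocab_size
  # class-conditional inclusion probability over the whole vocabulary
  p_by_class <- lapply(seq_along(BINDING_MODES), function(j) {
    p <- rep(config$ecfp_background_rate, vocab)
    own <- (j - 1L) * m + seq_len(m)  # 1-based column for 0-based ids
    p[own] <- min(1, config$ecfp_background_rate + config$ecfp_signal_strength)
    p
  })
  names(p_by_class) <- BINDING_MODES

  with_seed(rng_seed, {
    out <- vector("list", length(labels))
    names(out) <- ids
    for (i in seq_along(labels)) {
      p <- p_by_class[[as.character(labels[[i]])]]
      out[[i]] <- as.integer(which(stats::runif(vocab) < p) - 1L)
    }
    out
  })
}

#' Generate a labeled synthetic cohort
#'
#' Labels are assigned by exact class counts (not sampled), so the
#' configured composition is reproduced bit-exactly in every cohort.
#' Interaction records and structural feature sets are generated with
#' sub-seeds derived from the master seed by fixed offsets
#' (+1000 for interactions, +2000 for structural features).
#'
#' @param config `synth_config`.
#' @param seed master seed; defaults to `config$seed`.
#' @return object of class `labeled_cohort`: list with `inhibitor_ids`,
#'   `labels` (binding-mode factor), `interaction_records`,
#'   `structural_features`, and the `config` used.
#' @export
generate_dataset <- function(config = default_config(), seed = config$seed) {
  validate_config(config)
  seed <- as.integer(seed)
  counts <- config$n_per_class[BINDING_MODES]
  labels <- binding_mode_factor(rep(BINDING_MODES, times = counts))
  ids <- sprintf("inh_%04d", seq_along(labels))
  names(labels) <- ids
  cohort <- list(
    inhibitor_ids = ids,
    labels = labels,
    interaction_records = generate_interaction_profiles(
      config, labels, rng_seed = seed + 1000L),
    structural_features = generate_structural_features(
      config, labels, rng_seed = seed + 2000L),
    config = config
  )
  class(cohort) <- "labeled_cohort"
  cohort
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("Labeled synthetic kinase inhibitor cohort\n")
  cat("  inhibitors:", length(x$inhibitor_ids), "\n")
  tab <- table(x$labels)
  cat("  class composition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  structures per inhibitor:", x$config$structures_per_inhibitor, "\n")
  invisible(x)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n per class:",
      paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
            collapse = ", "), "\n")
  cat("  interaction grid:", x$n_positions, "positions x", x$n_categories,
      "categories; redundancy", x$redundancy_factor, "\n")
  cat("  structures/inhibitor:", x$structures_per_inhibitor,
      " structure noise:", x$structure_noise, "\n")
  cat("  ECFP-like vocab:", x$ecfp_vocab_size, "\n")
  invisible(x)
}
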