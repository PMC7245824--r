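#' Fingerprint constructor
#'
#' A fingerprint is a named binary vector with a representation tag.
#' Recognised tags: `IFP_85` (one bit per binding-site residue position),
#' `IFP_595` (seven interaction-category bits per position,
#' position-major), `ECFP4_folded` (1024 bits, modulo folding),
#' `ECFP4_unfolded` (dataset-dependent feature set), `CONCAT`.
#'
#' @param bits integer/logical 0-1 vector.
#' @param tag representation tag.
#' @param feature_names optional names, same length as `bits`.
#' @return object of class `fingerprint`.
#' @export
fingerprint <- function(bits, tag, feature_names = names(bits)) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(bits < 0L | bits > 1L)) {
    stop("fingerprint bits must be 0/1")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_along(bits))
  }
  if (length(feature_names) != length(bits)) {
    stop("feature_names must match bit vector length")
  }
  expected <- c(IFP_85 = 85L, IFP_595 = 595L, ECFP4_folded = 1024L)
  if (tag %in% names(expected) && length(bits) != expected[[tag]]) {
    stop(tag, " fingerprints must have ", expected[[tag]], " bits, got ",
         length(bits))
  }
  names(bits) <- feature_names
  structure(list(tag = tag, bits = bits), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s: %d bits, %d on>\n", x$tag, length(x$bits),
              sum(x$bits)))
  invisible(x)
}

ifp595_names <- function(n_positions = 85L, n_categories = 7L) {
  as.vector(t(outer(seq_len(n_positions), seq_len(n_categories),
                    function(p, c) paste0("P", p, ".C", c))))
}

#' Expand a residue interaction record into the 595-bit IFP
#'
#' Flattens the 85 x 7 interaction grid position-major: bits
#' `7*(p-1)+1 .. 7*(p-1)+7` hold the seven interaction categories of
#' residue position `p`, permitting multiple interactions per residue.
#'
#' @param record `interaction_record`.
#' @return `fingerprint` with tag `IFP_595`.
#' @export
build_ifp595 <- function(record) {
  stopifnot(inherits(record, "interaction_record"))
  cells <- record$cells
  fingerprint(as.integer(t(cells)), "IFP_595",
              ifp595_names(nrow(cells), ncol(cells)))
}

#' Collapse a 595-bit IFP to the 85-bit position fingerprint
#'
#' Bit `p` of the result records the presence of *any* interaction at
#' residue position `p`: the OR over that position's seven category bits.
#'
#' @param ifp595 `fingerprint` with tag `IFP_595`.
#' @return `fingerprint` with tag `IFP_85`.
#' @export
collapse_to_ifp85 <- function(ifp595) {
  stopifnot(inherits(ifp595, "fingerprint"))
  if (!identical(ifp595$tag, "IFP_595") || length(ifp595$bits) != 595L) {
    stop("collapse_to_ifp85() expects a 595-bit IFP_595 fingerprint")
  }
  m <- matrix(ifp595$bits, nrow = 85L, ncol = 7L, byrow = TRUE)
  fingerprint(as.integer(rowSums(m) > 0L), "IFP_85", paste0("P", 1:85))
}

#' Consensus fingerprint across structures
#'
#' Per-bit majority vote over fingerprints of the same representation;
#' an exact tie is set "on". With a single input the fingerprint is
#' returned unchanged. Used to merge the per-structure fingerprints of an
#' inhibitor crystallized in several complexes into one final IFP.
#'
#' @param fps non-empty list of `fingerprint` objects sharing tag and
#'   length.
#' @return consensus `fingerprint`, same tag.
#' @export
consensus_fingerprint <- function(fps) {
  if (length(fps) == 0L) stop("consensus requires at least one fingerprint")
  stopifnot(all(vapply(fps, inherits, logical(1), "fingerprint")))
  tags <- unique(vapply(fps, function(f) f$tag, character(1)))
  lens <- unique(vapply(fps, function(f) length(f$bits), integer(1)))
  if (length(tags) != 1L || length(lens) != 1L) {
    stop("consensus requires fingerprints of one representation and length")
  }
  mat <- do.call(rbind, lapply(fps, function(f) f$bits))
  fingerprint(as.integer(colMeans(mat) >= 0.5), tags,
              names(fps[[1L]]$bits))
}

#' Fold a feature identifier set by modulo mapping
#'
#' Bit `j` (0-based) of the folded fingerprint is set iff some identifier
#' maps to `j` under `id mod width`; colliding identifiers share a bit.
#'
#' @param feature_ids non-negative integer identifiers.
#' @param width folded length (default 1024).
#' @return `fingerprint` with tag `ECFP4_folded` when `width` is 1024,
#'   otherwise a generic `FOLDED` tag.
#' @export
fold_features <- function(feature_ids, width = 1024L) {
  width <- as.integer(width)
  if (width < 1L) stop("width must be >= 1")
  feature_ids <- as.integer(feature_ids)
  if (any(feature_ids < 0L)) stop("feature identifiers must be non-negative")
  bits <- integer(width)
  bits[unique(feature_ids %% width) + 1L] <- 1L
  tag <- if (width == 1024L) "ECFP4_folded" else "FOLDED"
  fingerprint(bits, tag, paste0("b", seq_len(width) - 1L))
}

new_fingerprint_dataset <- function(matrix, labels, inhibitor_ids,
                                    feature_names, tag) {
  storage.mode(matrix) <- "integer"
  if (anyDuplicated(inhibitor_ids)) stop("duplicate inhibitor ids")
  if (nrow(matrix) != length(labels) ||
      nrow(matrix) != length(inhibitor_ids) ||
      ncol(matrix) != length(feature_names)) {
    stop("misaligned fingerprint dataset components")
  }
  dimnames(matrix) <- list(inhibitor_ids, feature_names)
  structure(
    list(matrix = matrix, labels = binding_mode_factor(labels),
         inhibitor_ids = inhibitor_ids, feature_names = feature_names,
         tag = tag),
    class = "fingerprint_dataset"
  )
}

#' @export
print.fingerprint_dataset <- function(x, ...) {
  cat(sprintf("<fingerprint_dataset %s: %d inhibitors x %d features>\n",
              x$tag, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Build the unfolded feature matrix from identifier sets
#'
#' The feature vocabulary is the sorted union of all identifiers across
#' the data set, fixed once; column `j` of row `i` is 1 iff inhibitor
#' `i`'s set contains vocabulary identifier `j`. This mirrors a variably
#' sized, per-dataset feature set.
#'
#' @param feature_sets named list mapping inhibitor id to integer
#'   identifier vector.
#' @param labels binding-mode labels aligned with `feature_sets`.
#' @return `fingerprint_dataset` with tag `ECFP4_unfolded`.
#' @export
build_unfolded_matrix <- function(feature_sets, labels) {
  if (length(feature_sets) == 0L) stop("feature_sets must be non-empty")
  ids <- names(feature_sets) %||% sprintf("inh_%04d", seq_along(feature_sets))
  vocab <- sort(unique(unlist(feature_sets, use.names = FALSE)))
  mat <- matrix(0L, nrow = length(feature_sets), ncol = length(vocab))
  for (i in seq_along(feature_sets)) {
    mat[i, match(feature_sets[[i]], vocab)] <- 1L
  }
  new_fingerprint_dataset(mat, labels, ids, paste0("id", vocab),
                          "ECFP4_unfolded")
}

#' Build consensus IFP_85 and IFP_595 datasets from a cohort
#'
#' For every inhibitor the per-structure 595-bit and 85-bit fingerprints
#' are built and, when an inhibitor has more than one structure, merged
#' by [consensus_fingerprint()] -- independently for the two
#' representations, so a tie can resolve differently in the collapsed and
#' expanded form.
#'
#' @param cohort `labeled_cohort`.
#' @return list with elements `ifp85` and `ifp595`
#'   (`fingerprint_dataset`s, row-aligned with the cohort).
#' @export
build_ifp_datasets <- function(cohort) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  n <- length(cohort$inhibitor_ids)
  m595 <- matrix(0L, nrow = n, ncol = 595L)
  m85 <- matrix(0L, nrow = n, ncol = 85L)
  for (i in seq_len(n)) {
    recs <- cohort$interaction_records[[cohort$inhibitor_ids[[i]]]]
    if (length(recs) == 0L) {
      stop("inhibitor ", cohort$inhibitor_ids[[i]],
           " has no interaction records")
    }
    fps595 <- lapply(recs, build_ifp595)
    fps85 <- lapply(fps595, collapse_to_ifp85)
    m595[i, ] <- consensus_fingerprint(fps595)$bits
    m85[i, ] <- consensus_fingerprint(fps85)$bits
  }
  list(
    ifp85 = new_fingerprint_dataset(m85, cohort$labels,
                                    cohort$inhibitor_ids,
                                    paste0("P", 1:85), "IFP_85"),
    ifp595 = new_fingerprint_dataset(m595, cohort$labels,
                                     cohort$inhibitor_ids,
                                     ifp595_names(), "IFP_595")
  )
}

#' Build folded and unfolded atom-environment datasets from a cohort
#'
#' @param cohort `labeled_cohort`.
#' @param width folded fingerprint length (default 1024).
#' @return list with elements `folded` and `unfolded`
#'   (`fingerprint_dataset`s).
#' @export
build_ecfp_datasets <- function(cohort, width = 1024L) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  sets <- cohort$structural_features[cohort$inhibitor_ids]
  folded <- do.call(rbind, lapply(sets, function(s) fold_features(s, width)$bits))
  list(
    folded = new_fingerprint_dataset(folded, cohort$labels,
                                     cohort$inhibitor_ids,
                                     paste0("b", seq_len(width) - 1L),
                                     if (width == 1024L) "ECFP4_folded" else "FOLDED"),
    unfolded = build_unfolded_matrix(sets, cohort$labels)
  )
}

#' Concatenate two fingerprint datasets column-wise
#'
#' @param a,b `fingerprint_dataset`s over identical inhibitors in
#'   identical order.
#' @return `fingerprint_dataset` with tag `CONCAT`; feature names are
#'   prefixed with their source tag.
#' @export
concatenate_datasets <- function(a, b) {
  stopifnot(inherits(a, "fingerprint_dataset"),
            inherits(b, "fingerprint_dataset"))
  if (!identical(a$inhibitor_ids, b$inhibitor_ids)) {
    stop("datasets must cover the same inhibitors in the same order")
  }
  new_fingerprint_dataset(
    cbind(a$matrix, b$matrix),
    a$labels,
    a$inhibitor_ids,
    c(paste0(a$tag, ":", a$feature_names),
      paste0(b$tag, ":", b$feature_names)),
    "CONCAT"
  )
}

#' Read KLIFS-style interaction bitstrings
#'
#' Parses a TSV with columns `structure_id`, `inhibitor_id`, `bits` where
#' `bits` is a 595-character 0/1 string in position-major order
#' (characters `7*(p-1)+1 .. 7*(p-1)+7` are categories 1..7 of residue
#' position `p`).
#'
#' @param path TSV file path.
#' @return list of `interaction_record` objects.
#' @export
read_klifs_bitstrings <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("structure_id", "inhibitor_id", "bits")
  if (!all(need %in% names(df))) {
    stop("expected columns ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    s <- df$bits[[i]]
    if (nchar(s) != 595L) {
      stop("row ", i, " (structure ", df$structure_id[[i]],
           "): bitstring has ", nchar(s), " characters, expected 595")
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (!all(chars %in% c("0", "1"))) {
      stop("row ", i, " (structure ", df$structure_id[[i]],
           "): bitstring contains characters other than 0/1")
    }
    v <- as.integer(chars == "1")
    new_interaction_record(df$structure_id[[i]], df$inhibitor_id[[i]],
                           flat_to_cells(v, 85L, 7L))
  })
}

#' Write interaction records as KLIFS-style bitstrings
#'
#' Inverse of [read_klifs_bitstrings()]; round-trips exactly.
#'
#' @param records list of `interaction_record` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_klifs_bitstrings <- function(records, path) {
  df <- data.frame(
    structure_id = vapply(records, function(r) r$structure_id, character(1)),
    inhibitor_id = vapply(records, function(r) r$inhibitor_id, character(1)),
    bits = vapply(records, function(r) {
      paste(as.integer(t(r$cells)), collapse = "")
    }, character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
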