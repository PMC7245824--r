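#' Write a labeled cohort to plain-text files
#'
#' Serializes a cohort into `labels.tsv` (inhibitor_id, binding_mode),
#' `interactions.tsv` (structure_id, inhibitor_id, 595-character
#' position-major 0/1 bitstring), `features.txt` (one line per
#' inhibitor: id followed by space-separated integer feature
#' identifiers), and `config.yaml`.
#'
#' @param cohort `labeled_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(inhibitor_id = cohort$inhibitor_ids,
               binding_mode = as.character(cohort$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_klifs_bitstrings(
    unlist(cohort$interaction_records, recursive = FALSE, use.names = FALSE),
    file.path(dir, "interactions.tsv"))
  lines <- vapply(cohort$inhibitor_ids, function(id) {
    paste(c(id, cohort$structural_features[[id]]), collapse = " ")
  }, character(1))
  writeLines(lines, file.path(dir, "features.txt"))
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a labeled cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return `labeled_cohort`.
#' @export
read_cohort <- function(dir) {
  labels_df <- utils::read.delim(file.path(dir, "labels.tsv"),
                                 colClasses = "character")
  labels <- binding_mode_factor(labels_df$binding_mode)
  names(labels) <- labels_df$inhibitor_id
  records <- read_klifs_bitstrings(file.path(dir, "interactions.tsv"))
  rec_by_inh <- split(records,
                      factor(vapply(records, function(r) r$inhibitor_id,
                                    character(1)),
                             levels = labels_df$inhibitor_id))
  lines <- readLines(file.path(dir, "features.txt"))
  feats <- lapply(strsplit(lines, " ", fixed = TRUE), function(parts) {
    as.integer(parts[-1L])
  })
  names(feats) <- vapply(strsplit(lines, " ", fixed = TRUE), `[[`, character(1), 1L)
  config <- read_config(file.path(dir, "config.yaml"))
  structure(
    list(inhibitor_ids = labels_df$inhibitor_id, labels = labels,
         interaction_records = rec_by_inh,
         structural_features = feats[labels_df$inhibitor_id],
         config = config),
    class = "labeled_cohort"
  )
}

#' Write a synthetic configuration as YAML
#'
#' @param config `synth_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  x <- unclass(config)
  x$n_per_class <- as.list(x$n_per_class)
  x$signature_bits <- lapply(x$signature_bits, function(df) {
    list(position = df$position, category = df$category,
         on_probability = df$on_probability)
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a synthetic configuration from YAML
#'
#' @param path YAML file written by [write_config()].
#' @return validated `synth_config`.
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  sig <- lapply(x$signature_bits, function(s) {
    data.frame(position = as.integer(s$position),
               category = as.integer(s$category),
               on_probability = as.numeric(s$on_probability))
  })
  synthetic_config(
    n_per_class = stats::setNames(as.integer(unlist(x$n_per_class)),
                                  names(x$n_per_class)),
    n_positions = x$n_positions,
    n_categories = x$n_categories,
    signature_bits = sig,
    background_on_probability = x$background_on_probability,
    redundancy_factor = x$redundancy_factor,
    structures_per_inhibitor = x$structures_per_inhibitor,
    structure_noise = x$structure_noise,
    ecfp_vocab_size = x$ecfp_vocab_size,
    ecfp_signal_features_per_class = x$ecfp_signal_features_per_class,
    ecfp_signal_strength = x$ecfp_signal_strength,
    ecfp_background_rate = x$ecfp_background_rate,
    seed = x$seed
  )
}

#' Write a fingerprint dataset as a sparse MatrixMarket triple
#'
#' Writes `<name>.mtx` (sparse binary matrix), `<name>_rows.tsv`
#' (inhibitor_id, label) and `<name>_features.txt`.
#'
#' @param ds `fingerprint_dataset`.
#' @param dir output directory.
#' @param name file stem (default the representation tag).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, name = ds$tag) {
  stopifnot(inherits(ds, "fingerprint_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(ds$matrix, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, paste0(name, ".mtx")))
  utils::write.table(
    data.frame(inhibitor_id = ds$inhibitor_ids,
               label = as.character(ds$labels)),
    file.path(dir, paste0(name, "_rows.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(ds$feature_names, file.path(dir, paste0(name, "_features.txt")))
  invisible(dir)
}

#' Read a fingerprint dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @param name file stem (the representation tag used when writing).
#' @return `fingerprint_dataset`.
#' @export
read_dataset <- function(dir, name) {
  m <- as.matrix(Matrix::readMM(file.path(dir, paste0(name, ".mtx"))))
  rows <- utils::read.delim(file.path(dir, paste0(name, "_rows.tsv")),
                            colClasses = "character")
  features <- readLines(file.path(dir, paste0(name, "_features.txt")))
  new_fingerprint_dataset(m, rows$label, rows$inhibitor_id, features, name)
}
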