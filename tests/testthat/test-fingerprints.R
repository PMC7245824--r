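test_that("595-bit expansion flattens the interaction grid position-major", {
  cells <- matrix(0L, 85, 7)
  fp0 <- build_ifp595(record_from_cells(cells))
  expect_equal(sum(fp0$bits), 0L)
  expect_length(fp0$bits, 595L)

  cells[10, c(2, 5)] <- 1L
  fp <- build_ifp595(record_from_cells(cells))
  expect_equal(which(fp$bits == 1L), c(7L * 9L + 2L, 7L * 9L + 5L),
               ignore_attr = TRUE)

  # popcount oracle on random records
  set.seed(42)
  for (i in 1:10) {
    r <- random_record()
    expect_equal(sum(build_ifp595(r)$bits), sum(r$cells))
  }
})

test_that("collapse to 85 bits is the OR over the seven categories", {
  expect_equal(sum(collapse_to_ifp85(fp_from_on(integer(0)))$bits), 0L)

  one <- fp_from_on(7L * 41L + 3L)  # only position 42, category 3
  expect_equal(which(collapse_to_ifp85(one)$bits == 1L), 42L,
               ignore_attr = TRUE)

  # brute-force OR-reduction oracle
  set.seed(7)
  for (i in 1:10) {
    r <- random_record()
    got <- collapse_to_ifp85(build_ifp595(r))$bits
    oracle <- as.integer(apply(r$cells, 1L, function(row) any(row == 1L)))
    expect_equal(unname(got), oracle)
  }
  expect_error(collapse_to_ifp85(fold_features(1:3)), "IFP_595")
})

test_that("consensus is a per-bit majority with ties set on", {
  on <- fp_from_on(1:5, len = 10L, tag = "X")
  off <- fp_from_on(integer(0), len = 10L, tag = "X")
  expect_equal(consensus_fingerprint(list(on, off))$bits, on$bits)  # tie -> on
  expect_equal(consensus_fingerprint(list(on, on, off))$bits, on$bits)
  expect_equal(consensus_fingerprint(list(off, off, on))$bits, off$bits)
  expect_equal(consensus_fingerprint(list(on))$bits, on$bits)

  # permutation invariance and replicate idempotence on random inputs
  set.seed(11)
  fps <- lapply(1:5, function(i) fp_from_on(sample(595, 40)))
  expect_equal(consensus_fingerprint(fps)$bits,
               consensus_fingerprint(rev(fps))$bits)
  expect_equal(consensus_fingerprint(c(fps, fps))$bits,
               consensus_fingerprint(fps)$bits)

  expect_error(consensus_fingerprint(list()), "at least one")
  expect_error(consensus_fingerprint(list(on, fp_from_on(1, len = 3L, tag = "Y"))),
               "one representation")
})

test_that("modulo folding maps identifiers onto fixed-width bits", {
  f <- fold_features(c(6L, 1030L), 1024L)
  expect_equal(which(f$bits == 1L), 7L, ignore_attr = TRUE)  # 0-based bit 6
  expect_equal(sum(fold_features(integer(0))$bits), 0L)
  expect_equal(which(fold_features(c(0L, 1023L, 1024L))$bits == 1L),
               c(1L, 1024L), ignore_attr = TRUE)
  expect_error(fold_features(c(-1L, 2L)), "non-negative")

  # fold(S union T) == fold(S) | fold(T)
  set.seed(3)
  for (i in 1:10) {
    s <- sample(0:4999, 30)
    t <- sample(0:4999, 30)
    expect_equal(fold_features(union(s, t))$bits,
                 as.integer(fold_features(s)$bits | fold_features(t)$bits),
                 ignore_attr = TRUE)
  }
})

test_that("unfolded matrix uses the sorted dataset-wide vocabulary", {
  ds <- build_unfolded_matrix(list(a = c(1L, 2L), b = c(2L, 3L)),
                              labels = c("I", "II"))
  expect_equal(ds$feature_names, c("id1", "id2", "id3"))
  expect_equal(unname(ds$matrix), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))
  # identical sets give identical rows; row sums equal set sizes
  sets <- list(x = c(5L, 9L, 40L), y = c(5L, 9L, 40L), z = 2L)
  ds2 <- build_unfolded_matrix(sets, labels = c("I", "I", "II"))
  expect_equal(ds2$matrix[1, ], ds2$matrix[2, ])
  expect_equal(unname(rowSums(ds2$matrix)), lengths(sets),
               ignore_attr = TRUE)
  expect_error(build_unfolded_matrix(list(), labels = character(0)),
               "non-empty")
})

test_that("cohort-level IFP datasets apply the consensus per representation", {
  cfg <- small_config(structure_noise = 0, structures_per_inhibitor = 3L)
  cohort <- generate_dataset(cfg, seed = 2)
  ds <- build_ifp_datasets(cohort)
  expect_equal(nrow(ds$ifp85$matrix), length(cohort$inhibitor_ids))
  expect_equal(nrow(ds$ifp595$matrix), length(cohort$inhibitor_ids))
  # with zero structure noise the consensus equals any single structure,
  # and the 85-bit row is the OR-collapse of the 595-bit row
  for (i in c(1L, 20L, 60L)) {
    rec <- cohort$interaction_records[[cohort$inhibitor_ids[i]]][[1]]
    expect_equal(unname(ds$ifp595$matrix[i, ]),
                 unname(build_ifp595(rec)$bits))
    collapsed <- matrix(ds$ifp595$matrix[i, ], nrow = 85, byrow = TRUE)
    expect_equal(unname(ds$ifp85$matrix[i, ]),
                 as.integer(rowSums(collapsed) > 0))
  }
})

test_that("concatenation aligns rows and stacks features", {
  cohort <- generate_dataset(small_config(), seed = 3)
  ifp <- build_ifp_datasets(cohort)
  ecfp <- build_ecfp_datasets(cohort)
  cc <- concatenate_datasets(ifp$ifp85, ecfp$folded)
  expect_equal(ncol(cc$matrix), 85L + 1024L)
  expect_identical(cc$tag, "CONCAT")
  expect_equal(unname(rowSums(cc$matrix)),
               unname(rowSums(ifp$ifp85$matrix) + rowSums(ecfp$folded$matrix)))
  bad <- ecfp$folded
  bad$inhibitor_ids <- rev(bad$inhibitor_ids)
  expect_error(concatenate_datasets(ifp$ifp85, bad), "same inhibitors")
})

test_that("KLIFS-style bitstrings round-trip exactly", {
  set.seed(9)
  records <- lapply(1:6, function(i) {
    r <- random_record()
    r$structure_id <- paste0("s", i)
    r$inhibitor_id <- paste0("inh", (i + 1) %/% 2)
    r
  })
  path <- withr::local_tempfile(fileext = ".tsv")
  write_klifs_bitstrings(records, path)
  back <- read_klifs_bitstrings(path)
  expect_length(back, 6L)
  for (i in seq_along(records)) {
    expect_identical(back[[i]]$structure_id, records[[i]]$structure_id)
    expect_equal(unname(back[[i]]$cells), unname(records[[i]]$cells))
  }

  # the ordering convention: first character is position 1, category 1
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("structure_id\tinhibitor_id\tbits",
               paste0("s1\ti1\t", paste0("1", strrep("0", 594)))), path2)
  rec <- read_klifs_bitstrings(path2)[[1]]
  expect_equal(rec$cells[1, 1], 1L, ignore_attr = TRUE)
  expect_equal(sum(rec$cells), 1L)

  writeLines(c("structure_id\tinhibitor_id\tbits", "s1\ti1\t0101"), path2)
  expect_error(read_klifs_bitstrings(path2), "595")
  writeLines(c("structure_id\tinhibitor_id\tbits",
               paste0("sX\ti1\t", strrep("2", 595))), path2)
  expect_error(read_klifs_bitstrings(path2), "sX")
})
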