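test_that("default configuration reproduces the cohort composition", {
  cfg <- default_config()
  expect_equal(sum(cfg$n_per_class), 2008L)
  expect_equal(cfg$n_per_class[["I"]], 1424L)
  expect_equal(cfg$n_per_class[["I1/2"]], 394L)
  expect_equal(cfg$n_per_class[["II"]], 190L)
  expect_length(cfg$n_per_class, 3L)
  expect_identical(default_config(), default_config())
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(synthetic_config(background_on_probability = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_per_class = c("I" = 0L, "I1/2" = 1L, "II" = 1L)),
               "positive")
  expect_error(synthetic_config(redundancy_factor = 0L), "redundancy")
  expect_error(
    synthetic_config(signature_bits = list(
      "I" = data.frame(position = 99, category = 1, on_probability = 0.5),
      "I1/2" = data.frame(position = 1, category = 1, on_probability = 0.5),
      "II" = data.frame(position = 2, category = 1, on_probability = 0.5))),
    "grid")
  # copies that cannot fit in the reserved tail region
  expect_error(
    synthetic_config(signature_bits = list(
      "I" = data.frame(position = 1:50, category = 1, on_probability = 0.5),
      "I1/2" = data.frame(position = 1:50, category = 2, on_probability = 0.5),
      "II" = data.frame(position = 1:50, category = 3, on_probability = 0.5)),
      redundancy_factor = 7L),
    "fit")
})

test_that("interaction profiles honour the deterministic limits", {
  # no structure noise: all structures of an inhibitor are identical
  cfg <- small_config(structure_noise = 0, structures_per_inhibitor = 3L)
  labels <- binding_mode_factor(rep(BINDING_MODES, times = c(3, 2, 2)))
  recs <- generate_interaction_profiles(cfg, labels, rng_seed = 5)
  for (r in recs) {
    expect_identical(r[[1]]$cells, r[[2]]$cells)
    expect_identical(r[[1]]$cells, r[[3]]$cells)
  }

  # zero background, one certain signature bit: every record of that
  # class has exactly 1 + redundancy_factor cells on
  cfg2 <- synthetic_config(
    n_per_class = c("I" = 2L, "I1/2" = 2L, "II" = 4L),
    signature_bits = list(
      "I" = data.frame(position = 1, category = 1, on_probability = 0),
      "I1/2" = data.frame(position = 2, category = 1, on_probability = 0),
      "II" = data.frame(position = 3, category = 1, on_probability = 1)),
    background_on_probability = 0, structure_noise = 0,
    redundancy_factor = 4L, structures_per_inhibitor = 2L)
  labels2 <- binding_mode_factor(rep(BINDING_MODES, times = c(2, 2, 4)))
  recs2 <- generate_interaction_profiles(cfg2, labels2, rng_seed = 1)
  for (i in which(labels2 == "II")) {
    for (r in recs2[[i]]) expect_equal(sum(r$cells), 1L + 4L)
  }
  for (i in which(labels2 != "II")) {
    for (r in recs2[[i]]) expect_equal(sum(r$cells), 0L)
  }

  expect_identical(generate_interaction_profiles(cfg, labels, rng_seed = 9),
                   generate_interaction_profiles(cfg, labels, rng_seed = 9))
})

test_that("shared signature cells share their redundant copies", {
  # I and I1/2 share position 1; with certain signatures and no noise the
  # copy cells of the shared bit must be on for members of both classes
  cfg <- synthetic_config(
    n_per_class = c("I" = 2L, "I1/2" = 2L, "II" = 2L),
    signature_bits = list(
      "I" = data.frame(position = 1, category = 1, on_probability = 1),
      "I1/2" = data.frame(position = 1, category = 1, on_probability = 1),
      "II" = data.frame(position = 2, category = 1, on_probability = 1)),
    background_on_probability = 0, structure_noise = 0,
    redundancy_factor = 2L, structures_per_inhibitor = 1L)
  labels <- binding_mode_factor(rep(BINDING_MODES, each = 2))
  recs <- generate_interaction_profiles(cfg, labels, rng_seed = 2)
  flat <- function(r) as.integer(t(r$cells))
  on_i <- which(flat(recs[[1]][[1]]) == 1L)
  on_ih <- which(flat(recs[[3]][[1]]) == 1L)
  expect_identical(on_i, on_ih)       # identical cells including copies
  expect_length(on_i, 3L)             # parent + 2 copies
})

test_that("structural feature sets follow the class-conditional model", {
  cfg <- small_config(ecfp_signal_strength = 0.95, ecfp_background_rate = 0)
  labels <- binding_mode_factor(rep(BINDING_MODES, times = c(3, 3, 3)))
  # strength ~1, background 0: members carry almost surely only their own
  # class block; with strength exactly 1 the sets are the full block
  cfg1 <- small_config(ecfp_signal_strength = 1, ecfp_background_rate = 0)
  sets <- generate_structural_features(cfg1, labels, rng_seed = 3)
  m <- cfg1$ecfp_signal_features_per_class
  blocks <- list("I" = 0:(m - 1), "I1/2" = m:(2 * m - 1), "II" = (2 * m):(3 * m - 1))
  for (i in seq_along(labels)) {
    expect_identical(sets[[i]], as.integer(blocks[[as.character(labels[i])]]))
  }
  # null signal: inclusion probabilities identical across classes
  cfg0 <- small_config(ecfp_signal_strength = 0, ecfp_background_rate = 1)
  sets0 <- generate_structural_features(cfg0, labels, rng_seed = 3)
  for (s in sets0) expect_identical(s, 0:(cfg0$ecfp_vocab_size - 1L))
  expect_identical(generate_structural_features(cfg, labels, rng_seed = 8),
                   generate_structural_features(cfg, labels, rng_seed = 8))
})

test_that("generated cohorts have exact class counts and are seeded", {
  cfg <- small_config()
  cohort <- generate_dataset(cfg, seed = 4)
  expect_length(cohort$inhibitor_ids, 64L)
  tab <- table(cohort$labels)
  expect_equal(as.integer(tab[BINDING_MODES]),
               as.integer(cfg$n_per_class[BINDING_MODES]))
  expect_true(all(lengths(cohort$interaction_records) ==
                    cfg$structures_per_inhibitor))
  expect_true(all(unlist(cohort$structural_features) < cfg$ecfp_vocab_size))
  cohort2 <- generate_dataset(cfg, seed = 4)
  expect_identical(cohort[names(cohort) != "config"],
                   cohort2[names(cohort2) != "config"])
})
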