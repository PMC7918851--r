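test_that("plate generator is deterministic and mask-consistent", {
  cfg <- small_config(seed = 7)
  a <- generate_plate_image(cfg, "w1")
  b <- generate_plate_image(cfg, "w1")
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth$mask, b$truth$mask)

  # a different well id gets its own noise/colony stream
  c2 <- generate_plate_image(cfg, "w2")
  expect_false(identical(a$pixels, c2$pixels))

  # recomputing the fraction from the returned mask is exact
  expect_identical(sum(a$truth$mask) / sum(a$well_mask),
                   a$truth$true_area_fraction)
})

test_that("empty wells and single-disk geometry give the expected areas", {
  cfg <- small_config(seed = 3)
  empty <- generate_plate_image(cfg, "empty", n_colonies = 0)
  expect_identical(empty$truth$true_area_fraction, 0)
  expect_true(all(abs(empty$pixels[, , 1] -
                        cfg$background_color[1]) < 6 * cfg$pixel_noise_sd + 1))

  # one disk of fixed radius r in a well of radius R covers ~ r^2 / R^2
  r <- 10
  cfg1 <- small_config(seed = 11, colony_radius_meanlog = log(r),
                       colony_radius_sdlog = 0)
  img <- generate_plate_image(cfg1, "disk", n_colonies = 1)
  expected <- r^2 / cfg1$well_radius^2
  rel_err <- abs(img$truth$true_area_fraction - expected) / expected
  expect_lt(rel_err, 2 / r + 2 / cfg1$well_radius)
})

test_that("ct table plants effects on targets and leaves housekeepers flat", {
  cfg <- synthetic_config(seed = 5, ct_noise_sd = 0)
  ct <- generate_ct_table(cfg)
  expect_true(all(ct$ct[ct$gene %in% housekeeping_genes] == cfg$ct_baseline))

  # planted +x means the target amplifies x cycles earlier than baseline
  planted <- attr(ct, "truth")
  one <- planted[planted$gene == "CCL2" &
                   planted$medium_kind == "CMCAF_post-cisplatin", ][1, ]
  got <- ct$ct[ct$gene == "CCL2" & ct$caf_id == one$caf_id &
                 ct$medium_kind == "CMCAF_post-cisplatin"]
  expect_equal(unique(got), cfg$ct_baseline - one$log2fc)

  # replicate structure and determinism
  expect_identical(ct, generate_ct_table(cfg))
  expect_equal(sum(ct$gene == "VEGFA" & ct$caf_id == "none" &
                     ct$medium_kind == "fresh"), cfg$n_replicates)
})

test_that("generators reject invalid planted parameters", {
  expect_error(synthetic_config(seed = 1,
                                planted_uptake_fraction = setNames(
                                  rep(1.2, 7), caf_ids())),
               "\\[0, 1\\]")
  bad_lfc <- data.frame(gene = "NOTAGENE", caf_id = "M5.1",
                        medium_kind = "CMCAF", log2fc = 1)
  expect_error(synthetic_config(seed = 1, planted_log2fc = bad_lfc),
               "absent from the assay panel")
  expect_error(synthetic_config(seed = 1, image_size = -4))
})

test_that("platinum table encodes the planted uptake and release", {
  base <- list(seed = 2, conc_noise_sd = 0)

  zero <- do.call(synthetic_config, c(base, list(
    planted_uptake_fraction = setNames(rep(0, 7), caf_ids()))))
  tab0 <- generate_platinum_table(zero)
  bal0 <- platinum_mass_balance(tab0)
  expect_equal(bal0$n_uptake_nmol, rep(0, 7))

  full <- do.call(synthetic_config, c(base, list(
    planted_uptake_fraction = setNames(rep(1, 7), caf_ids()))))
  bal1 <- platinum_mass_balance(generate_platinum_table(full))
  expect_equal(bal1$n_uptake_nmol, rep(10, 7))  # entire 5 uM x 2 mL dose

  frac <- do.call(synthetic_config, c(base, list(
    planted_uptake_fraction = setNames(rep(0.4, 7), caf_ids()))))
  balf <- platinum_mass_balance(generate_platinum_table(frac))
  expect_equal(balf$n_uptake_nmol, rep(4, 7))
  # release never exceeds uptake in noise-free tables
  expect_true(all(balf$n_released_nmol <= balf$n_uptake_nmol + 1e-12))
})

test_that("clinical fixture matches the cohort characteristics", {
  clin <- clinical_fixture()
  expect_equal(nrow(clin), 7)
  expect_equal(sum(clin$recurrence), 2)
  expect_equal(sum(clin$p16), 3)
  expect_equal(sum(clin$gender == "F"), 1)
  expect_equal(sum(clin$tumor_location == "larynx"), 3)
  m7 <- clin[clin$patient == "M7.1", ]
  expect_equal(m7$recurrence, 1)
  expect_equal(m7$p16, 1)
})

test_that("flow sample generator plants a recoverable positive fraction", {
  cfg <- synthetic_config(seed = 4)
  fs <- generate_flow_sample(cfg, n_events = 5000, positive_fraction = 0.96)
  expect_equal(fs$true_positive_fraction, 0.96, tolerance = 0.02)
  expect_identical(fs$events,
                   generate_flow_sample(cfg, n_events = 5000,
                                        positive_fraction = 0.96)$events)
})
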