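test_that("housekeeper reference is the mean of ACTB and PSMB2", {
  expect_equal(reference_ct(data.frame(gene = c("ACTB", "PSMB2"),
                                       ct = c(18, 22))), 20)
  expect_equal(reference_ct(data.frame(gene = c("ACTB", "PSMB2"),
                                       ct = c(20, 20))), 20)
  # replicates are averaged per housekeeper before combining
  expect_equal(reference_ct(data.frame(gene = c("ACTB", "ACTB", "PSMB2"),
                                       ct = c(17, 19, 22))), 20)
  expect_error(reference_ct(data.frame(gene = "ACTB", ct = 18), "S1"),
               "PSMB2.*S1")
})

test_that("delta-delta-Ct arithmetic behaves as one doubling per cycle", {
  expect_equal(log2_fold_change(20, 20, 20, 20), 0)
  expect_equal(log2_fold_change(19, 20, 20, 20), 1)
  expect_equal(log2_fold_change(22, 20, 20, 20), -2)
})

test_that("noise-free generation closes to the planted fold changes", {
  cfg <- synthetic_config(seed = 31, ct_noise_sd = 0)
  expr <- relative_expression(generate_ct_table(cfg))
  planted <- attr(generate_ct_table(cfg), "truth")
  for (i in seq_len(nrow(planted))) {
    row <- expr[expr$gene == planted$gene[i] &
                  expr$caf_id == planted$caf_id[i] &
                  expr$medium_kind == planted$medium_kind[i], ]
    expect_equal(row$log2fc, planted$log2fc[i], tolerance = 1e-12)
  }
  # unplanted combinations are exactly 0
  zero <- expr[expr$caf_id == "none" & expr$medium_kind == "depleted", ]
  expect_equal(zero$log2fc, rep(0, nrow(zero)), tolerance = 1e-12)
})

test_that("fold changes are invariant to per-sample Ct shifts", {
  cfg <- synthetic_config(seed = 32)
  ct <- generate_ct_table(cfg)
  expr0 <- relative_expression(ct)

  shifted <- ct
  keys <- paste(ct$caf_id, ct$cisplatin, ct$medium_kind)
  shifts <- withr::with_seed(1, setNames(runif(length(unique(keys)), -3, 3),
                                         unique(keys)))
  shifted$ct <- ct$ct + shifts[keys]
  expr1 <- relative_expression(shifted)
  expect_equal(expr1$log2fc, expr0$log2fc, tolerance = 1e-10)
})

test_that("calibrator choices are transitive", {
  cfg <- synthetic_config(seed = 33)
  ct <- generate_ct_table(cfg)
  vs_fresh <- relative_expression(ct, "fresh_medium")
  vs_depl <- relative_expression(ct, "depleted_medium")
  # log2fc(x vs fresh) - log2fc(x vs depleted) = log2fc(depleted vs fresh)
  depl_vs_fresh <- vs_fresh[vs_fresh$caf_id == "none" &
                              vs_fresh$medium_kind == "depleted", ]
  key <- function(df) paste(df$caf_id, df$medium_kind, df$cisplatin, df$gene)
  m <- match(key(vs_fresh), key(vs_depl))
  delta <- vs_fresh$log2fc - vs_depl$log2fc[m]
  expected <- setNames(depl_vs_fresh$log2fc, depl_vs_fresh$gene)
  expect_equal(delta, unname(expected[vs_fresh$gene]), tolerance = 1e-10)
})

test_that("replicate noise leaves the estimate near the planted value", {
  # planted +1 with 0.2-cycle noise and 3 replicates: estimate within 3 SE
  errs <- vapply(1:25, function(s) {
    cfg <- synthetic_config(
      seed = 1000 + s, ct_noise_sd = 0.2,
      planted_log2fc = data.frame(gene = "VEGFA", caf_id = "M5.1",
                                  medium_kind = "CMCAF", log2fc = 1))
    expr <- relative_expression(generate_ct_table(cfg))
    expr$log2fc[expr$gene == "VEGFA" & expr$caf_id == "M5.1" &
                  expr$medium_kind == "CMCAF"] - 1
  }, numeric(1))
  # se of a delta-delta estimate: two mean-of-3 target terms plus two
  # mean-of-6 housekeeper references
  se <- sqrt(2 * (0.2^2 / 3) + 2 * (0.2^2 / 6))
  expect_lt(mean(abs(errs)), 3 * se)
  expect_lt(abs(mean(errs)), 3 * se / sqrt(length(errs)))
})

test_that("pairwise baselining zeroes every untreated arm", {
  cfg <- synthetic_config(seed = 34)
  expr <- relative_expression(generate_ct_table(cfg))
  pw <- pairwise_baseline(expr)
  base <- pw[pw$arm == "baseline", ]
  expect_true(all(base$log2fc == 0))
  expect_true(all(pw$calibrator == "caf_no_cisplatin_pairwise"))

  # treated arm is the difference of the two arms' fold changes
  one <- expr[expr$caf_id == "M5.1" & expr$gene == "VEGFA", ]
  want <- one$log2fc[one$medium_kind == "CMCAF_post-cisplatin"] -
    one$log2fc[one$medium_kind == "CMCAF"]
  got <- pw$log2fc[pw$caf_id == "M5.1" & pw$gene == "VEGFA" &
                     pw$arm == "treated"]
  expect_equal(got, want)

  # an unpaired CAF is rejected by name
  broken <- expr[!(expr$caf_id == "M7.1" &
                     expr$medium_kind == "CMCAF_post-cisplatin"), ]
  expect_error(pairwise_baseline(broken), "M7.1")
})

test_that("undetected assays are censored at 45 cycles and propagate", {
  rec <- data.frame(ct = c(20, NA, 30), undetected = c(FALSE, TRUE, FALSE))
  out <- handle_undetected(rec)
  expect_equal(out$ct, c(20, 45, 30))
  expect_equal(out$undetected, c(FALSE, TRUE, FALSE))
  expect_error(handle_undetected(data.frame(ct = 50, undetected = FALSE)),
               "45")

  # an all-undetected gene yields a missing, not infinite, fold change
  cfg <- synthetic_config(seed = 35, ct_noise_sd = 0)
  ct <- generate_ct_table(cfg)
  sel <- ct$gene == "BCL2" & ct$caf_id == "M5.1" & ct$medium_kind == "CMCAF"
  ct$undetected[sel] <- TRUE
  expr <- relative_expression(ct)
  row <- expr[expr$gene == "BCL2" & expr$caf_id == "M5.1" &
                expr$medium_kind == "CMCAF", ]
  expect_true(is.na(row$log2fc))
  expect_equal(row$n_undetected, 3)

  # one of three undetected enters the mean at Ct = 45
  ct2 <- generate_ct_table(cfg)
  sel2 <- which(ct2$gene == "BCL2" & ct2$caf_id == "M5.1" &
                  ct2$medium_kind == "CMCAF")
  ct2$undetected[sel2[1]] <- TRUE
  expr2 <- relative_expression(ct2)
  row2 <- expr2[expr2$gene == "BCL2" & expr2$caf_id == "M5.1" &
                  expr2$medium_kind == "CMCAF", ]
  expect_equal(row2$log2fc, -(mean(c(45, 25, 25)) - 25), tolerance = 1e-12)
  expect_equal(row2$n_undetected, 1)
})
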