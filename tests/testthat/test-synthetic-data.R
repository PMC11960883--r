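# Synthetic cohort generator: templates, severity deformations, exact error
# injection and tier recovery.

test_that("severity-0 noise-free kinematics equal the templates exactly", {
  k0 <- generate_kinematics(0, noise_sd = 0)
  ref <- generate_cohort(synthetic_config(n_subjects = 2, seed = 1))$reference
  expect_identical(k0, ref$mean_curves)
  expect_error(generate_kinematics(1.5), "severity")
})

test_that("severity deformations hit their stated magnitudes by construction", {
  k0 <- generate_kinematics(0, noise_sd = 0)
  k1 <- generate_kinematics(1, noise_sd = 0)
  f0 <- lapply(k0, curve_features)
  f1 <- lapply(k1, curve_features)
  expect_equal(f1$KneeFlx[["MEAN"]] - f0$KneeFlx[["MEAN"]], 15)
  expect_equal(f1$HipFlx[["ROM"]] - f0$HipFlx[["ROM"]], -10)
  expect_equal(f1$AnkleDorsi[["MAX"]] - f0$AnkleDorsi[["MAX"]], -10)
})

test_that("mean GPS against the template reference increases with severity", {
  ref <- reference_profile(generate_kinematics(0, noise_sd = 0))
  set.seed(17)
  mean_gps <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(sv) {
    mean(replicate(200, {
      rec <- subject_record("X", "left", generate_kinematics(sv, noise_sd = 4),
                            list(hip = rnorm(60)), list(hip = rnorm(60)))
      gait_profile_score(rec, ref)
    }))
  }, numeric(1))
  expect_true(all(diff(mean_gps) > 0))
})

test_that("moment templates are physiological and non-degenerate", {
  set.seed(23)
  for (sv in c(0, 0.5, 1)) {
    m <- generate_moments(sv)
    for (j in names(m)) expect_gt(standardized_peak(m[[j]]), 0)
    expect_true(max(m$ankle) >= 1.0 && max(m$ankle) <= 1.8)
    # hip is biphasic: extensor early, flexor late
    expect_gt(m$hip[1], 0)
    expect_lt(m$hip[60], 0)
  }
  # jitter off -> deterministic curves
  expect_identical(generate_moments(0.3, amplitude_jitter_sd = 0),
                   generate_moments(0.3, amplitude_jitter_sd = 0))
})

test_that("inject_prediction_error hits its target exactly", {
  set.seed(19)
  m <- generate_moments(0.2, amplitude_jitter_sd = 0)$knee
  expect_identical(inject_prediction_error(m, 0), m)
  for (target in c(0.03, 0.18, 0.45)) {
    p <- inject_prediction_error(m, target)
    expect_equal(nrmse(m, p), target, tolerance = 1e-6)
  }
  expect_error(inject_prediction_error(rep(1, 60), 0.1), "degenerate")

  # subphase weighting concentrates the error in the requested bin
  p1 <- inject_prediction_error(m, 0.2, subphase_weights = c(1, 0, 0, 0, 0))
  sub <- subphase_nrmse(m, p1, 5L)
  expect_gt(sub[1], 0)
  expect_equal(sub[2:5], rep(0, 4))
})

test_that("generate_cohort is reproducible and validates its config", {
  cfg <- synthetic_config(n_subjects = 25, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_length(a$records, 25L)
  expect_equal(nrow(a$ground_truth), 25L * 3L)

  # paired sides share the subject's severity
  pp <- generate_cohort(synthetic_config(n_subjects = 5, seed = 3,
                                         paired_sides = TRUE))
  expect_length(pp$records, 10L)
  sv <- tapply(pp$ground_truth$severity, pp$ground_truth$subject_id,
               function(x) length(unique(x)))
  expect_true(all(sv == 1))

  expect_error(synthetic_config(n_subjects = -1, severity_coupling = -2),
               "n_subjects.*\n.*severity_coupling")
  expect_error(synthetic_config(tier_targets = list(Green = c(0.05, 0.2),
                                                    Yellow = c(0.15, 0.25),
                                                    Red = c(0.3, 0.5))),
               "non-overlapping")
})

test_that("tier recovery is exact on unflagged records", {
  syn <- generate_cohort(synthetic_config(n_subjects = 120, seed = 29))
  expect_false(any(syn$ground_truth$flagged))   # relative mode: never flagged
  for (joint in c("hip", "knee", "ankle")) {
    lab <- label_cohort(syn$records, joint)
    gt <- syn$ground_truth[syn$ground_truth$joint == joint, ]
    key <- paste(lab$results$subject_id, lab$results$side)
    gt_key <- paste(gt$subject_id, gt$side)
    expect_identical(as.character(lab$results$label),
                     gt$tier[match(key, gt_key)])
  }
})

test_that("absolute tier mode flags records whose own thresholds disagree", {
  syn <- generate_cohort(synthetic_config(n_subjects = 80, seed = 13,
                                          tier_mode = "absolute"))
  gt <- syn$ground_truth
  for (joint in unique(gt$joint)) {
    lab <- label_cohort(syn$records, joint)
    gj <- gt[gt$joint == joint, ]
    key <- paste(lab$results$subject_id, lab$results$side)
    gj <- gj[match(key, paste(gj$subject_id, gj$side)), ]
    agree <- as.character(lab$results$label) == gj$tier
    expect_true(all(agree[!gj$flagged]))      # recovery 100% off the flags
    expect_true(all(!agree[gj$flagged]))      # flags are exactly the clashes
  }
})

test_that("severity coupling 0 matches base tier frequencies (binomial error)", {
  syn <- generate_cohort(synthetic_config(n_subjects = 2000, seed = 101,
                                          severity_coupling = 0,
                                          joints = "hip"))
  gt <- syn$ground_truth
  base <- c(Green = 0.84, Yellow = 0.15, Red = 0.01)
  for (lb in names(base)) {
    phat <- mean(gt$tier == lb)
    se <- sqrt(base[[lb]] * (1 - base[[lb]]) / 2000)
    expect_lt(abs(phat - base[[lb]]), 4 * se)
  }
})

test_that("positive severity coupling associates severity with Red labels", {
  syn <- generate_cohort(synthetic_config(n_subjects = 2000, seed = 57,
                                          severity_coupling = 1.5,
                                          joints = "ankle"))
  gt <- syn$ground_truth
  ct <- cor.test(gt$severity, as.numeric(gt$tier == "Red"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
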