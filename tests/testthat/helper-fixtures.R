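# Shared fixtures: small deterministic records built in code.

tile60 <- function(pattern) rep_len(pattern, 60L)

# A deterministic, physiologically shaped record. `moment_offset` shifts all
# predicted moments by a constant, giving a closed-form nRMSE per joint.
make_record <- function(id = "S01", side = "left", moment_offset = 0,
                        kin_shift = 0) {
  t <- seq(0, 1, length.out = 60L)
  kin <- list(PelvicTilt = 15 + 2 * sin(2 * pi * t) + kin_shift,
              HipFlx = 18 + 21 * cos(pi * t) + kin_shift,
              KneeFlx = 20 - 6 * cos(pi * t) + 7 * cos(2 * pi * t) + kin_shift,
              AnkleDorsi = 3 - 8 * cos(2 * pi * t) + 6 * sin(pi * t) + kin_shift)
  meas <- list(hip = 0.05 + 0.85 * cos(pi * t),
               knee = 0.05 + 0.35 * cos(2 * pi * t) + 0.2 * sin(pi * t),
               ankle = 3.28 * t^1.8 * sin(pi * t))
  pred <- lapply(meas, function(m) m + moment_offset)
  subject_record(id, side, kin, meas, pred)
}

make_cohort <- function(n = 4L, moment_offsets = rep(0, n)) {
  lapply(seq_len(n), function(i) {
    make_record(sprintf("S%02d", i), "left", moment_offset = moment_offsets[i])
  })
}

# Reference equal to the unshifted kinematics of make_record().
make_reference <- function() {
  reference_profile(make_record()$kinematics, "test template reference")
}
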