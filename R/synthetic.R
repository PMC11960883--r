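## Synthetic cohort generator: CP-like stance kinematics driven by a crouch
## severity parameter, physiological moment templates, and predicted moments
## whose injected error hits controllable nRMSE tiers.

stance_grid <- function(n_points = STANCE_N) {
  seq(0, 1, length.out = n_points)
}

## Fixed low-order Fourier templates over the stance parameter t in [0, 1]
## (harmonics of period 2 so the curves need not be periodic over stance).
## Coefficients chosen once so that severity-0 MAX/ROM/MEAN land in ranges
## plausible for mildly involved CP cohorts; see the methods vignette.
kinematic_templates <- function(t = stance_grid()) {
  list(
    PelvicTilt = 15.5 + 2.0 * sin(2 * pi * t) + 1.5 * cos(pi * t),
    HipFlx     = 18.0 + 21.0 * cos(pi * t) + 2.0 * sin(2 * pi * t),
    KneeFlx    = 19.25 - 6.5 * cos(pi * t) + 7.25 * cos(2 * pi * t),
    AnkleDorsi = 3.0 + 2.5 * cos(pi * t) - 8.5 * cos(2 * pi * t) +
                 7.0 * sin(pi * t))
}

## Smooth zero-mean noise: random low-order Fourier series scaled to the
## requested pointwise standard deviation.
smooth_noise <- function(sd, t = stance_grid(), n_harmonics = 3L) {
  if (sd <= 0) return(rep(0, length(t)))
  e <- rep(0, length(t))
  for (k in seq_len(n_harmonics)) {
    e <- e + stats::rnorm(1) * cos(k * pi * t) + stats::rnorm(1) * sin(k * pi * t)
  }
  s <- stats::sd(e)
  if (s == 0) return(rep(0, length(t)))
  e / s * sd
}

#' Generate severity-dependent CP-like stance kinematics
#'
#' Each curve is a fixed low-order Fourier template plus a severity-scaled
#' deformation emulating increasing crouch: at severity 1 the knee
#' flexion/extension MEAN is shifted up by +15 degrees, the hip
#' flexion/extension ROM is reduced by 10 degrees, and the ankle
#' dorsiflexion MAX is reduced by 10 degrees (an equinus tendency), plus
#' optional smooth subject-level noise. At severity 0 with noise off the
#' templates are returned exactly — these template curves double as the
#' typically-developed GPS reference of a synthetic run.
#'
#' @param severity crouch severity in `[0, 1]`.
#' @param noise_sd pointwise standard deviation (degrees) of the smooth
#'   subject noise added to every curve; 0 disables it. Draws from the
#'   current RNG stream.
#' @return named list of numeric(60) curves (degrees) for the four sagittal
#'   variables.
#' @export
generate_kinematics <- function(severity, noise_sd = 0) {
  if (!is.finite(severity) || severity < 0 || severity > 1) {
    stop("severity must be in [0, 1]", call. = FALSE)
  }
  t <- stance_grid()
  tmpl <- kinematic_templates(t)
  out <- tmpl
  # crouch: knee persistently more flexed
  out$KneeFlx <- tmpl$KneeFlx + 15 * severity
  # stiff hip: shrink excursion about the mean so ROM drops by 10 deg/severity
  hip_rom <- max(tmpl$HipFlx) - min(tmpl$HipFlx)
  shrink <- 1 - severity * 10 / hip_rom
  out$HipFlx <- mean(tmpl$HipFlx) + (tmpl$HipFlx - mean(tmpl$HipFlx)) * shrink
  # equinus tendency: whole ankle curve shifted down, MAX drops by 10 deg
  out$AnkleDorsi <- tmpl$AnkleDorsi - 10 * severity
  if (noise_sd > 0) {
    out <- lapply(out, function(curve) curve + smooth_noise(noise_sd, t))
  }
  out
}

#' Generate physiological measured joint-moment templates
#'
#' Stance-phase sagittal moment templates in Nm/kg: a biphasic
#' extensor-to-flexor hip moment, a knee flexion/extension wave, and an ankle
#' moment rising monotonically to a late-stance plantarflexor peak of about
#' 1.4 Nm/kg. Subject-level amplitude jitter (multiplicative, clamped so the
#' ankle peak stays within `peak_band`) draws from the current RNG stream;
#' severity mildly attenuates the push-off amplitude (up to -10% at
#' severity 1). All templates are non-constant by construction.
#'
#' @param severity crouch severity in `[0, 1]`.
#' @param amplitude_jitter_sd sd of the multiplicative amplitude jitter;
#'   0 disables it.
#' @param peak_band admissible band (Nm/kg) for the ankle plantarflexor peak.
#' @return named list of numeric(60) curves (Nm/kg) for hip, knee, ankle.
#' @export
generate_moments <- function(severity, amplitude_jitter_sd = 0.1,
                             peak_band = c(1.0, 1.8)) {
  if (!is.finite(severity) || severity < 0 || severity > 1) {
    stop("severity must be in [0, 1]", call. = FALSE)
  }
  t <- stance_grid()
  hip <- 0.05 + 0.85 * cos(pi * t) + 0.15 * sin(2 * pi * t)
  knee <- 0.05 + 0.35 * cos(2 * pi * t) + 0.20 * sin(pi * t)
  ankle <- 3.28 * t^1.8 * sin(pi * t)          # peak ~1.4 Nm/kg near 70% stance
  jitter <- function() {
    if (amplitude_jitter_sd <= 0) 1 else max(0.5, 1 + stats::rnorm(1) * amplitude_jitter_sd)
  }
  atten <- 1 - 0.1 * severity
  hip <- hip * jitter() * atten
  knee <- knee * jitter() * atten
  a_amp <- jitter() * atten
  # clamp so the plantarflexor peak stays physiological
  peak0 <- max(ankle)
  a_amp <- min(max(a_amp, peak_band[1L] / peak0), peak_band[2L] / peak0)
  ankle <- ankle * a_amp
  list(hip = hip, knee = knee, ankle = ankle)
}

#' Inject smooth prediction error hitting an exact nRMSE target
#'
#' Stands in for an upstream moment-predicting model: the "predicted" curve
#' is the measured curve plus smooth low-order Fourier noise, rescaled so
#' that `nrmse(measured, predicted)` equals `target_nrmse` exactly (to
#' machine precision). Optional subphase weights concentrate the error in
#' chosen stance bins to emulate phase-dependent error patterns.
#'
#' @param measured numeric(60) non-degenerate measured curve.
#' @param target_nrmse requested nRMSE (`>= 0`); 0 returns the measured curve.
#' @param subphase_weights optional non-negative weights, one per equal
#'   subphase (length must divide 60); error in each bin is multiplied by the
#'   bin weight before the exact rescaling.
#' @param n_harmonics number of Fourier harmonics in the raw error shape.
#' @return numeric(60) predicted curve.
#' @export
inject_prediction_error <- function(measured, target_nrmse,
                                    subphase_weights = NULL,
                                    n_harmonics = 4L) {
  n <- length(measured)
  measured <- check_curve(measured, "measured", n_points = n)
  if (!is.finite(target_nrmse) || target_nrmse < 0) {
    stop("target_nrmse must be finite and >= 0", call. = FALSE)
  }
  p2p <- max(measured) - min(measured)
  if (p2p <= 0) {
    stop("degenerate trace: cannot inject error into a flat measured curve",
         call. = FALSE)
  }
  if (target_nrmse == 0) return(measured)
  t <- stance_grid(n)
  e <- rep(0, n)
  for (k in seq_len(n_harmonics)) {
    e <- e + stats::rnorm(1) * cos(k * pi * t) + stats::rnorm(1) * sin(k * pi * t)
  }
  if (all(e == 0)) e <- cos(pi * t)  # probability-zero fallback
  if (!is.null(subphase_weights)) {
    if (any(subphase_weights < 0) || all(subphase_weights == 0)) {
      stop("subphase_weights must be non-negative with a positive entry",
           call. = FALSE)
    }
    if (n %% length(subphase_weights) != 0L) {
      stop("length(subphase_weights) must divide the grid length", call. = FALSE)
    }
    e <- e * rep(subphase_weights, each = n %/% length(subphase_weights))
  }
  measured + e * (target_nrmse * p2p) / sqrt(mean(e^2))
}

#' Configuration of a synthetic cohort run
#'
#' Collects and validates every knob of the generator. Defaults state the
#' cohort the pipeline is designed around: 500 subjects, uniform crouch
#' severity, per-joint base tier probabilities matching the hip/knee/ankle
#' label populations reported for CP cohorts (84/15/1, 60/33/7 and 50/40/10
#' percent), severity-coupled odds shifting toward Red, and error targets
#' drawn relative to each record's own kinetic limits so tier recovery is
#' exact.
#'
#' @param n_subjects cohort size (records; one side per subject by default).
#' @param seed master seed; every downstream draw derives from it.
#' @param severity_distribution `"uniform"` on `[0, 1]` or `"beta"`.
#' @param beta_shape two shape parameters used when
#'   `severity_distribution = "beta"`.
#' @param tier_mode `"relative"` (default): targets drawn relative to the
#'   record's own LKL/UKL, making intended tiers exactly recoverable;
#'   `"absolute"`: targets drawn uniformly in `tier_targets` bands, records
#'   whose own thresholds contradict the drawn tier are flagged.
#' @param tier_targets named list of absolute nRMSE bands per tier (used in
#'   `"absolute"` mode).
#' @param tier_probabilities_base named list (per joint) of base
#'   Green/Yellow/Red probabilities.
#' @param severity_coupling non-negative real; 0 leaves tier odds at base,
#'   larger values shift odds toward Red as severity rises. The shift is a
#'   mean-zero transfer in the severity quantile, so for coupling in
#'   `[0, 1]` the *marginal* tier frequencies still equal the base
#'   probabilities while Red becomes severity-linked.
#' @param kinematic_noise_sd smooth subject noise on kinematics, degrees.
#' @param moment_jitter_sd multiplicative amplitude jitter on moments.
#' @param joints joints to generate.
#' @param paired_sides generate left and right records per subject sharing
#'   one severity (default `FALSE`: one left side per subject).
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 500L, seed = 1L,
                             severity_distribution = c("uniform", "beta"),
                             beta_shape = c(2, 2),
                             tier_mode = c("relative", "absolute"),
                             tier_targets = list(Green = c(0.05, 0.12),
                                                 Yellow = c(0.15, 0.25),
                                                 Red = c(0.30, 0.50)),
                             tier_probabilities_base =
                               list(hip = c(0.84, 0.15, 0.01),
                                    knee = c(0.60, 0.33, 0.07),
                                    ankle = c(0.50, 0.40, 0.10)),
                             severity_coupling = 1,
                             kinematic_noise_sd = 4,
                             moment_jitter_sd = 0.1,
                             joints = JOINTS,
                             paired_sides = FALSE) {
  severity_distribution <- match.arg(severity_distribution)
  tier_mode <- match.arg(tier_mode)
  problems <- character()
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    problems <- c(problems, "n_subjects must be a positive integer")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    problems <- c(problems, "seed must be a finite integer")
  }
  if (length(beta_shape) != 2L || any(beta_shape <= 0)) {
    problems <- c(problems, "beta_shape must be two positive reals")
  }
  bands <- do.call(rbind, tier_targets[MOMENT_LABELS])
  if (is.null(bands) || nrow(bands) != 3L || any(bands[, 1L] >= bands[, 2L])) {
    problems <- c(problems, "tier_targets must give (lo, hi) bands with lo < hi for Green/Yellow/Red")
  } else if (bands["Green", 2L] > bands["Yellow", 1L] ||
             bands["Yellow", 2L] > bands["Red", 1L]) {
    problems <- c(problems, "tier_targets bands must be ordered and non-overlapping")
  }
  joints <- intersect(joints, JOINTS)
  if (!length(joints)) problems <- c(problems, "joints must be a subset of hip/knee/ankle")
  for (j in joints) {
    p <- tier_probabilities_base[[j]]
    if (is.null(p) || length(p) != 3L || any(p < 0) || any(p > 1) ||
        abs(sum(p) - 1) > 1e-6) {
      problems <- c(problems,
                    paste0("tier_probabilities_base$", j,
                           " must be 3 probabilities summing to 1"))
    }
  }
  if (!is.numeric(severity_coupling) || severity_coupling < 0) {
    problems <- c(problems, "severity_coupling must be >= 0")
  }
  if (kinematic_noise_sd < 0) {
    problems <- c(problems, "kinematic_noise_sd must be >= 0")
  }
  if (length(problems)) {
    stop("invalid synthetic configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 severity_distribution = severity_distribution,
                 beta_shape = beta_shape, tier_mode = tier_mode,
                 tier_targets = tier_targets,
                 tier_probabilities_base = tier_probabilities_base,
                 severity_coupling = severity_coupling,
                 kinematic_noise_sd = kinematic_noise_sd,
                 moment_jitter_sd = moment_jitter_sd,
                 joints = joints, paired_sides = paired_sides),
            class = "synthetic_config")
}

## Severity-coupled tier probabilities via a mean-zero probability transfer:
## mass d(u) = coupling * (2u - 1) * c0 moves from Green to Yellow/Red
## (split by their base shares), where u is the severity quantile and
## c0 = min(P(Green), P(Yellow) + P(Red)). Because E[2u - 1] = 0, the
## marginal tier frequencies equal the base probabilities exactly for
## coupling <= 1 (beyond that, clamping to [0, 1] bends the marginals);
## P(Red | u) is non-decreasing in u for any coupling >= 0.
tier_probs <- function(base, severity_quantile, coupling) {
  yr <- base[2L] + base[3L]
  if (yr == 0 || coupling == 0) return(base)
  c0 <- min(base[1L], yr)
  d <- coupling * (2 * severity_quantile - 1) * c0
  d <- min(max(d, -yr), base[1L])
  p <- c(base[1L] - d, base[2L:3L] * (1 + d / yr))
  p / sum(p)
}

## Draw a target nRMSE for a tier relative to the record's own limits.
relative_target <- function(tier, limits) {
  u <- stats::runif(1)
  switch(tier,
         Green = (0.30 + 0.60 * u) * limits$lkl,
         Yellow = limits$lkl + (0.15 + 0.70 * u) * (limits$ukl - limits$lkl),
         Red = (1.20 + 1.30 * u) * limits$ukl)
}

#' Generate a synthetic cohort with ground truth and GPS reference
#'
#' Produces `n_subjects` records (one left side each unless
#' `paired_sides = TRUE`). Per record: a severity draw, severity-deformed
#' noisy kinematics, measured moment templates with amplitude jitter, a tier
#' draw per joint with severity-coupled odds, and a predicted moment whose
#' injected error hits the tier's target nRMSE exactly. The GPS reference is
#' the severity-0 noise-free kinematic template set.
#'
#' Reproducibility: the master seed drives one draw of per-record seeds;
#' each record is then generated under its own seed, so the cohort is
#' bit-reproducible and records are insensitive to cohort-size changes
#' before them.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort`: `records` (list of
#'   [subject_record()]), `ground_truth` (data frame: subject_id, side,
#'   joint, severity, tier, target_nrmse, flagged), `reference`
#'   (a [reference_profile()]) and `config`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  sides <- if (config$paired_sides) c("left", "right") else "left"
  record_seeds <- with_seed(config$seed,
                            matrix(sample.int(.Machine$integer.max - 1L,
                                              n * length(sides)),
                                   nrow = n))
  records <- vector("list", n * length(sides))
  gt <- vector("list", n * length(sides))
  idx <- 0L
  for (i in seq_len(n)) {
    sid <- sprintf("S%04d", i)
    # severity is shared across the two sides of one subject
    severity <- with_seed(record_seeds[i, 1L], draw_severity(config))
    for (s in seq_along(sides)) {
      idx <- idx + 1L
      out <- with_seed(record_seeds[i, s],
                       generate_record(sid, sides[s], severity, config))
      records[[idx]] <- out$record
      gt[[idx]] <- out$truth
    }
  }
  reference <- reference_profile(generate_kinematics(0, noise_sd = 0),
                                 description = "severity-0 noise-free synthetic template (typically-developed stand-in)")
  structure(list(records = records,
                 ground_truth = do.call(rbind, gt),
                 reference = reference,
                 config = config),
            class = "synthetic_cohort")
}

draw_severity <- function(config) {
  if (config$severity_distribution == "uniform") stats::runif(1)
  else stats::rbeta(1, config$beta_shape[1L], config$beta_shape[2L])
}

generate_record <- function(sid, side, severity, config) {
  # burn the severity draw so kinematics differ from the severity stream
  invisible(draw_severity(config))
  kin <- generate_kinematics(severity, noise_sd = config$kinematic_noise_sd)
  moments <- generate_moments(severity,
                              amplitude_jitter_sd = config$moment_jitter_sd)
  measured <- moments[config$joints]
  predicted <- list()
  truth <- list()
  u <- if (config$severity_distribution == "uniform") severity
       else stats::pbeta(severity, config$beta_shape[1L], config$beta_shape[2L])
  for (joint in config$joints) {
    p <- tier_probs(config$tier_probabilities_base[[joint]], u,
                    config$severity_coupling)
    tier <- sample(MOMENT_LABELS, 1L, prob = p)
    limits <- kinetic_limits(measured[[joint]])
    if (config$tier_mode == "relative") {
      target <- relative_target(tier, limits)
      flagged <- FALSE
    } else {
      band <- config$tier_targets[[tier]]
      target <- stats::runif(1, band[1L], band[2L])
      flagged <- as.character(assign_label(target, limits)) != tier
    }
    predicted[[joint]] <- inject_prediction_error(measured[[joint]], target)
    truth[[joint]] <- data.frame(subject_id = sid, side = side,
                                 joint = joint, severity = severity,
                                 tier = tier, target_nrmse = target,
                                 flagged = flagged)
  }
  list(record = subject_record(sid, side, kin, measured, predicted,
                               severity = severity),
       truth = do.call(rbind, truth))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$records), "records | joints:",
      paste(x$config$joints, collapse = ", "),
      "| seed:", x$config$seed, "\n")
  tab <- table(x$ground_truth$joint, x$ground_truth$tier)
  print(tab)
  invisible(x)
}
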