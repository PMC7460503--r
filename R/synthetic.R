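# Synthetic generation of phase-labeled lower-leg acceleration signals.

#' Gait phase labels
#'
#' The four-phase division of the gait cycle used throughout the package,
#' in cyclic order: heel strike (HS), flat foot (FF), heel off (HO) and
#' swing (SW). Integer phase codes 0, 1, 2, 3 index this vector (code 0 =
#' "HS").
#'
#' @return Character vector of the four phase names.
#' @export
phase_levels <- function() c("HS", "FF", "HO", "SW")

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so simulation never perturbs the global stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed (< 2^31) from a master seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483629)
}

#' Describe one walking condition
#'
#' A gait profile bundles everything the simulator needs to emit one
#' subject's steady-state treadmill walk: speed, cadence, the within-cycle
#' phase split, per-axis amplitude scaling and the noise level.
#'
#' Defaults follow the treadmill study conditions the package emulates:
#' stance (HS + FF + HO) occupies about 60% of the cycle and swing about
#' 40%, with a deliberately short heel-strike phase (8% of the cycle)
#' because initial contact is the briefest and hardest-to-detect event.
#' Cadence is modeled as `0.9 * speed` strides per second so the three
#' study speeds (0.78, 1.0, 1.25 m/s) give distinct, monotonically
#' increasing stride rates.
#'
#' @param speed Walking speed in m/s.
#' @param cadence Stride rate in cycles per second; default `0.9 * speed`.
#' @param phase_fractions Numeric length-4 vector of cycle fractions for
#'   (HS, FF, HO, SW); must be positive and sum to 1.
#' @param amp_scale Length-3 multiplier applied to the (x, y, z) signal
#'   amplitudes; models sensor placement / subject differences.
#' @param noise_sd Standard deviation, in g, of the additive AR(1) sensor
#'   noise (the stationary SD, not the innovation SD).
#' @param ar_coef AR(1) coefficient of the noise process; values near 1
#'   mimic the smoothing of an in-sensor Kalman filter.
#' @param seed Integer RNG seed owned by this profile.
#' @return An object of class `"gait_profile"`.
#' @examples
#' p <- gait_profile(speed = 1.0)
#' rec <- synthesize_recording(p, duration_s = 5)
#' table(rec$labels) / length(rec$labels)
#' @export
gait_profile <- function(speed = 1.0,
                         cadence = 0.9 * speed,
                         phase_fractions = c(0.08, 0.32, 0.20, 0.40),
                         amp_scale = c(1, 1, 1),
                         noise_sd = 0.05,
                         ar_coef = 0.9,
                         seed = 1L) {
  if (!is.numeric(speed) || length(speed) != 1L || speed <= 0) {
    stop("invalid profile: `speed` must be a single positive number")
  }
  if (!is.numeric(cadence) || length(cadence) != 1L || cadence <= 0) {
    stop("invalid profile: `cadence` must be a single positive number")
  }
  if (!is.numeric(phase_fractions) || length(phase_fractions) != 4L ||
      any(phase_fractions <= 0)) {
    stop("invalid profile: `phase_fractions` must be 4 positive numbers")
  }
  if (abs(sum(phase_fractions) - 1) > 1e-9) {
    stop("invalid profile: `phase_fractions` must sum to 1 (got ",
         format(sum(phase_fractions)), ")")
  }
  if (!is.numeric(amp_scale) || length(amp_scale) != 3L) {
    stop("invalid profile: `amp_scale` must have length 3")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("invalid profile: `noise_sd` must be >= 0")
  }
  if (!is.numeric(ar_coef) || length(ar_coef) != 1L ||
      ar_coef < 0 || ar_coef >= 1) {
    stop("invalid profile: `ar_coef` must lie in [0, 1)")
  }
  structure(
    list(
      speed = speed,
      cadence = cadence,
      phase_fractions = stats::setNames(phase_fractions, phase_levels()),
      amp_scale = amp_scale,
      noise_sd = noise_sd,
      ar_coef = ar_coef,
      seed = as.integer(seed)
    ),
    class = "gait_profile"
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("Gait profile: speed", x$speed, "m/s, cadence",
      format(x$cadence, digits = 4), "cycles/s\n")
  cat("  phase fractions:",
      paste(sprintf("%s=%.3f", names(x$phase_fractions), x$phase_fractions),
            collapse = " "), "\n")
  cat("  noise sd:", x$noise_sd, "g (AR coef", x$ar_coef, "), seed:",
      x$seed, "\n")
  invisible(x)
}

# Integer per-phase sample counts of one cycle at sampling rate fs.
phase_durations <- function(profile, fs) {
  cycle_len <- fs / profile$cadence
  d <- pmax(1L, as.integer(round(profile$phase_fractions * cycle_len)))
  names(d) <- phase_levels()
  d
}

#' Per-sample phase schedule
#'
#' Lays out the cyclic phase sequence HS -> FF -> HO -> SW over
#' `n_samples` samples. Each cycle spans `fs / cadence` samples, and each
#' phase receives `round(fraction * cycle_length)` consecutive samples
#' (at least one).
#'
#' @param profile A [gait_profile()].
#' @param n_samples Number of samples to label (>= 1).
#' @param fs Sampling rate in Hz.
#' @return Integer vector of phase codes in `{0, 1, 2, 3}`.
#' @export
make_phase_schedule <- function(profile, n_samples, fs = 200) {
  stopifnot(inherits(profile, "gait_profile"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("invalid profile: `fs` must be a single positive number")
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1) {
    stop("`n_samples` must be >= 1")
  }
  d <- phase_durations(profile, fs)
  rep_len(rep.int(0:3, d), as.integer(n_samples))
}

# Per-phase, per-axis waveform description. Each phase contributes a
# smooth bump centred in the phase; amplitudes are chosen so that every
# phase has a distinct triaxial signature and the clean signal stays
# inside [-1, 2] g even with the maximal 1.2x subject multiplier
# (heel-strike carries the largest transient, as an impact should).
phase_template_params <- function() {
  list(
    # rows: HS, FF, HO, SW; columns: x, y, z
    amp = matrix(
      c( 1.55, -0.70,  0.45,
         0.25,  0.35, -0.55,
         0.70,  1.05,  0.30,
        -0.60,  0.30,  1.30),
      nrow = 4, byrow = TRUE,
      dimnames = list(phase_levels(), c("x", "y", "z"))
    ),
    baseline = c(x = 0.10, y = 0.00, z = 0.15)
  )
}

# Clean (noise-free) per-axis template evaluated at cycle positions
# pos in [0, 1). Gaussian bumps are wrapped across the cycle boundary so
# the signal is exactly cycle-periodic and smooth everywhere.
template_signal <- function(pos, durations, amp_scale) {
  tp <- phase_template_params()
  C <- sum(durations)
  frac <- durations / C
  centers <- (cumsum(durations) - durations / 2) / C
  widths <- frac / 3
  out <- matrix(0, nrow = length(pos), ncol = 3)
  for (axis in 1:3) {
    s <- rep(tp$baseline[axis], length(pos))
    for (k in 1:4) {
      delta <- (pos - centers[k] + 0.5) %% 1 - 0.5  # wrapped distance
      s <- s + tp$amp[k, axis] * amp_scale[axis] *
        exp(-0.5 * (delta / widths[k])^2)
    }
    out[, axis] <- s
  }
  out
}

#' Synthesize one labeled acceleration recording
#'
#' Emits a steady-state treadmill walk for one subject: per-axis sums of
#' phase-specific smooth bumps (exactly cycle-periodic when `noise_sd = 0`)
#' plus stationary AR(1) noise, clipped to the empirical \[-1, 2\] g range
#' of calf-worn accelerometry, with a per-sample phase label from
#' [make_phase_schedule()].
#'
#' @param profile A [gait_profile()].
#' @param duration_s Recording length in seconds (> 0).
#' @param subject_id Identifier stored with the recording.
#' @param fs Sampling rate in Hz (default 200).
#' @return An object of class `"accel_recording"`: a list with elements
#'   `fs`, `t`, `ax`, `ay`, `az` (g units), `labels` (codes 0-3),
#'   `subject_id` and `speed`.
#' @export
synthesize_recording <- function(profile, duration_s, subject_id = "S1",
                                 fs = 200) {
  stopifnot(inherits(profile, "gait_profile"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop("`duration_s` must be a single positive number")
  }
  n <- as.integer(round(duration_s * fs))
  labels <- make_phase_schedule(profile, n, fs)
  d <- phase_durations(profile, fs)
  C <- sum(d)
  pos <- ((seq_len(n) - 1L) %% C) / C
  clean <- template_signal(pos, d, profile$amp_scale)
  noise <- matrix(0, nrow = n, ncol = 3)
  if (profile$noise_sd > 0) {
    noise <- with_seed(profile$seed, {
      innov_sd <- profile$noise_sd * sqrt(1 - profile$ar_coef^2)
      vapply(1:3, function(axis) {
        e <- stats::rnorm(n, sd = innov_sd)
        e[1] <- stats::rnorm(1, sd = profile$noise_sd)
        as.numeric(stats::filter(e, profile$ar_coef, method = "recursive"))
      }, numeric(n))
    })
  }
  sig <- pmin(pmax(clean + noise, -1), 2)
  structure(
    list(
      fs = fs,
      t = (seq_len(n) - 1L) / fs,
      ax = sig[, 1], ay = sig[, 2], az = sig[, 3],
      labels = labels,
      subject_id = subject_id,
      speed = profile$speed
    ),
    class = "accel_recording"
  )
}

#' @export
print.accel_recording <- function(x, ...) {
  cat("Acceleration recording:", length(x$ax), "samples @", x$fs, "Hz (",
      format(length(x$ax) / x$fs, digits = 4), "s ), subject",
      x$subject_id, ",", x$speed, "m/s\n")
  prop <- table(factor(x$labels, levels = 0:3, labels = phase_levels()))
  cat("  phase proportions:",
      paste(sprintf("%s=%.3f", names(prop), prop / length(x$labels)),
            collapse = " "), "\n")
  invisible(x)
}

#' Simulate a cohort of subjects at one treadmill speed
#'
#' Draws per-subject variation around a base profile -- per-axis amplitude
#' multipliers uniform on (0.8, 1.2) and a cadence jitter of up to +/- 5% --
#' and synthesizes `repeats` independent recordings per subject. All
#' randomness descends deterministically from `seed`.
#'
#' @param speed Treadmill speed in m/s.
#' @param subjects Number of subjects.
#' @param duration_s Length of each recording in seconds.
#' @param repeats Recordings per subject.
#' @param seed Master seed for the cohort.
#' @param profile Optional base [gait_profile()]; default uses
#'   `gait_profile(speed = speed)`.
#' @return List of [synthesize_recording()] results, one per
#'   subject x repeat.
#' @export
simulate_cohort <- function(speed = 1.0, subjects = 4, duration_s = 60,
                            repeats = 1, seed = 1L, profile = NULL) {
  base <- if (is.null(profile)) gait_profile(speed = speed) else profile
  stopifnot(inherits(base, "gait_profile"))
  draws <- with_seed(seed, {
    lapply(seq_len(subjects), function(i) {
      list(amp = stats::runif(3, 0.8, 1.2),
           jitter = stats::runif(1, -0.05, 0.05))
    })
  })
  recs <- list()
  for (i in seq_len(subjects)) {
    for (r in seq_len(repeats)) {
      p <- gait_profile(
        speed = base$speed,
        cadence = base$cadence * (1 + draws[[i]]$jitter),
        phase_fractions = base$phase_fractions,
        amp_scale = base$amp_scale * draws[[i]]$amp,
        noise_sd = base$noise_sd,
        ar_coef = base$ar_coef,
        seed = derive_seed(seed, i * 1000L + r)
      )
      recs[[length(recs) + 1L]] <- synthesize_recording(
        p, duration_s, subject_id = sprintf("S%02d", i)
      )
    }
  }
  recs
}

#' Simulate recordings from a gait profile
#'
#' `simulate()` method for [gait_profile()] objects: returns `nsim`
#' recordings with per-subject variation, equivalent to a
#' [simulate_cohort()] of `nsim` subjects walking this profile.
#'
#' @param object A [gait_profile()].
#' @param nsim Number of subjects/recordings.
#' @param seed Master seed; defaults to the profile's own seed.
#' @param duration_s Recording length in seconds.
#' @param ... Unused.
#' @return List of `"accel_recording"` objects.
#' @export
simulate.gait_profile <- function(object, nsim = 1, seed = NULL,
                                  duration_s = 10, ...) {
  if (is.null(seed)) seed <- object$seed
  simulate_cohort(speed = object$speed, subjects = nsim,
                  duration_s = duration_s, repeats = 1, seed = seed,
                  profile = object)
}

#' Write a recording to CSV
#'
#' Plain-text serialization with header `t,ax,ay,az,phase`; time in
#' seconds (6 decimals), accelerations in g (9 decimals, so a read/write
#' round trip preserves values to well under 1e-9), phase codes 0-3.
#'
#' @param rec An `"accel_recording"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  lines <- c(
    "t,ax,ay,az,phase",
    sprintf("%.6f,%.9f,%.9f,%.9f,%d", rec$t, rec$ax, rec$ay, rec$az,
            rec$labels)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording()]. The file must carry the header columns
#' `t`, `ax`, `ay`, `az`, `phase`; any missing column, non-numeric cell or
#' phase code outside `{0, 1, 2, 3}` raises a parse error that names the
#' offending line.
#'
#' @param path CSV file path.
#' @param fs Sampling rate to record on the result (default 200 Hz).
#' @param subject_id,speed Metadata to attach.
#' @return An `"accel_recording"`.
#' @export
read_recording <- function(path, fs = 200, subject_id = NA_character_,
                           speed = NA_real_) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  needed <- c("t", "ax", "ay", "az", "phase")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("parse error in '", path, "' line 1: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  num <- list()
  for (col in c("t", "ax", "ay", "az")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop("parse error in '", path, "' line ", bad[1] + 1L,
           ": non-numeric value in column '", col, "'")
    }
    num[[col]] <- v
  }
  ph <- suppressWarnings(as.numeric(df$phase))
  bad <- which(is.na(ph) | ph != round(ph) | ph < 0 | ph > 3)
  if (length(bad) > 0) {
    stop("parse error in '", path, "' line ", bad[1] + 1L,
         ": phase code must be one of 0,1,2,3 (got '", df$phase[bad[1]], "')")
  }
  structure(
    list(
      fs = fs,
      t = num$t,
      ax = num$ax, ay = num$ay, az = num$az,
      labels = as.integer(ph),
      subject_id = subject_id,
      speed = speed
    ),
    class = "accel_recording"
  )
}
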