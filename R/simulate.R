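#' Quasi-uniform radial OPM helmet layout
#'
#' Places `n` radial magnetometers on a spherical cap of the given radius
#' using a Fibonacci spiral, emulating a rigid OPM helmet covering one
#' hemisphere.  Orientations are radial (unit position vectors).
#'
#' @param n number of sensors (default 31).
#' @param radius helmet radius in meters (default 0.10).
#' @param cap_angle_deg half-angle of the cap from the +z pole, degrees.
#' @return A `sensor_array`.
#' @export
opm_helmet <- function(n = 31, radius = 0.10, cap_angle_deg = 75) {
  z_min <- cos(cap_angle_deg * pi / 180)
  k <- seq_len(n)
  z <- z_min + (1 - z_min) * (k - 0.5) / n
  phi <- k * pi * (3 - sqrt(5))  # golden angle
  r_xy <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(r_xy * cos(phi), r_xy * sin(phi), z)
  sensor_array(sprintf("opm%02d", k), pos, pos / radius)
}

#' Current-dipole source description
#'
#' A sinusoidal-burst current dipole: moment
#' `q(t) = peak_moment * sin(2 pi frequency t)` inside the active window,
#' zero outside, identical over trials.
#'
#' @param position 3-vector, meters, strictly inside the sensor shell.
#' @param moment_direction unit 3-vector; its tangential component (the
#'   part visible to a radial spherical-conductor model) must be nonzero.
#' @param peak_moment peak dipole moment in nA.m (default 50).
#' @param frequency oscillation frequency in Hz (default 10).
#' @param active_tmin,active_tmax active window in seconds (default 0-0.5).
#' @param n_trials number of trials (default 300).
#' @return An object of class `dipole_source`.
#' @export
dipole_source <- function(position, moment_direction, peak_moment = 50,
                          frequency = 10, active_tmin = 0, active_tmax = 0.5,
                          n_trials = 300) {
  position <- as.numeric(position)
  moment_direction <- as.numeric(moment_direction)
  if (abs(sqrt(sum(moment_direction^2)) - 1) > 1e-9) {
    stop("moment_direction must be a unit vector")
  }
  tang <- moment_direction -
    position * sum(moment_direction * position) / sum(position^2)
  if (sqrt(sum(tang^2)) < 1e-9) {
    warning("moment is purely radial; a radial spherical-conductor model sees nothing")
  }
  structure(
    list(position = position, moment_direction = moment_direction,
         peak_moment = peak_moment, frequency = frequency,
         active_tmin = active_tmin, active_tmax = active_tmax,
         n_trials = n_trials),
    class = "dipole_source"
  )
}

#' Radial magnetic lead field of a spherical conductor
#'
#' Closed-form radial field of a current dipole in a spherically symmetric
#' conductor: at sensor position r with radial axis r-hat,
#' `B_r = (mu0 / 4 pi) ((pos x Q) . r-hat) / |r - pos|^3`.  Volume currents
#' contribute nothing to the radial component, and a radial dipole
#' (Q parallel to pos) is magnetically silent.
#'
#' @param sensors a `sensor_array` with radial orientations.
#' @param pos dipole position, 3-vector in meters, inside the sensor shell.
#' @param moment dipole moment 3-vector in nA.m.
#' @return Numeric vector of per-channel fields in fT.
#' @export
radial_lead_field <- function(sensors, pos, moment) {
  pos <- as.numeric(pos)
  q_am <- as.numeric(moment) * 1e-9          # nA.m -> A.m
  rad <- sqrt(rowSums(sensors$positions^2))
  if (any(sqrt(sum(pos^2)) >= rad)) {
    stop("dipole must lie strictly inside every sensor radius")
  }
  diff <- sweep(sensors$positions, 2, pos)
  d3 <- rowSums(diff^2)^1.5
  if (any(d3 < 1e-18)) stop("a sensor coincides with the source position")
  pxq <- c(pos[2] * q_am[3] - pos[3] * q_am[2],
           pos[3] * q_am[1] - pos[1] * q_am[3],
           pos[1] * q_am[2] - pos[2] * q_am[1])
  b_t <- 1e-7 * (sensors$orientations %*% pxq) / d3  # tesla
  as.numeric(b_t) * 1e15                              # -> fT
}

#' Simulate the clean evoked sensor signal
#'
#' Evaluates the dipole waveform on the epoch time axis and maps it
#' through the radial lead field.  Trials are identical (the source is
#' deterministic); variability enters later through interference.
#'
#' @param sensors a `sensor_array`.
#' @param src a `dipole_source`.
#' @param srate sampling rate, Hz (default 1000).
#' @param tmin,tmax epoch window, seconds (default -0.2 to 0.8).
#' @return An object of class `simulation_truth`: `B_sim` (clean
#'   `epoched_recording`), `dipole`, `interference_rank` (filled by
#'   [assemble_dataset()]), `seed` (likewise).
#' @export
simulate_evoked <- function(sensors, src, srate = 1000, tmin = -0.2, tmax = 0.8) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(src, "dipole_source"))
  if (src$frequency >= srate / 2) stop("source frequency must be below Nyquist")
  if (src$active_tmin < tmin || src$active_tmax > tmax) {
    stop("active window must lie inside the epoch window")
  }
  i0 <- round(tmin * srate); i1 <- round(tmax * srate)
  times <- (i0:i1) / srate
  wave <- ifelse(times >= src$active_tmin & times < src$active_tmax,
                 src$peak_moment * sin(2 * pi * src$frequency * times), 0)
  # field per nA.m along moment_direction; linear in the moment
  lead <- radial_lead_field(sensors, src$position, src$moment_direction)
  field <- outer(lead, wave)  # channels x time, fT
  data <- array(0, dim = c(length(lead), src$n_trials, length(times)))
  for (k in seq_len(src$n_trials)) data[, k, ] <- field
  structure(
    list(B_sim = epoched_recording(data, srate, times, sensors$channel_ids),
         dipole = src, sensors = sensors,
         interference_rank = NA_integer_, seed = NA_integer_),
    class = "simulation_truth"
  )
}

#' Low-rank interference model
#'
#' Environmental interference is modeled as `rank` fixed spatial patterns,
#' each driven by an independent stationary timecourse, plus independent
#' white sensor noise.  Two pattern presets are provided:
#'
#' * `"msr"` (default for `rank <= 4`): a uniform field plus orthogonal
#'   first-order gradient fields, evaluated at the (radial) sensors --
#'   the far-field topographies that dominate residual interference
#'   inside a magnetically shielded room.  Such smooth patterns overlap a
#'   focal dipolar topography only weakly, which is why moderate
#'   subspace dimensions remove interference without destroying the
#'   evoked signal.
#' * `"random"`: random unit vectors with pairwise angles of at least 30
#'   degrees (rejection-sampled), a generic low-rank stand-in.
#'
#' Each component timecourse is a mixture of band-limited Gaussian noise
#' and a fixed-frequency sinusoidal line with random phase
#' (`line_fraction` of the component's power).  Real empty-room spectra
#' carry such narrowband peaks (mains-related and mechanical lines);
#' because their frequencies are stable, they stay phase-coherent across
#' stimulus-locked trials and are not removed by trial averaging -- the
#' very reason subspace projection is needed on evoked data.
#'
#' @param n_channels channel count the patterns live in.
#' @param rank number of interference components (default 4).
#' @param component_rms RMS amplitude of each component timecourse in fT
#'   at unit spatial pattern norm (default 1000).
#' @param band spectral band of the broadband part, Hz (default 1-40, the
#'   analysis band, so that the subspace dimension rather than the
#'   spectrum is what the estimator must find).
#' @param sensor_noise_sd white sensor-noise SD per channel in fT
#'   (default 30).
#' @param patterns `"msr"`, `"random"`, or an explicit channels x rank
#'   pattern matrix.  The `"msr"` preset needs a `sensor_array` at
#'   simulation time and `rank <= 4`.
#' @param line_freqs per-component line frequencies in Hz (recycled);
#'   integers keep the lines trial-coherent at a 1 s stimulus period.
#'   Default `c(3, 7, 13, 21)`.
#' @param line_fraction fraction of each component's power in its line,
#'   in `[0, 1]` (default 0.5; 0 gives pure broadband noise).
#' @return An object of class `interference_model`.
#' @export
interference_model <- function(n_channels, rank = 4, component_rms = 1000,
                               band = c(1, 40), sensor_noise_sd = 30,
                               patterns = c("msr", "random"),
                               line_freqs = c(3, 7, 13, 21),
                               line_fraction = 0.5) {
  if (rank < 0 || rank > n_channels) stop("rank must lie in [0, n_channels]")
  if (rank == 0 && sensor_noise_sd <= 0) {
    stop("need rank >= 1 or positive sensor noise")
  }
  if (is.character(patterns)) {
    patterns <- match.arg(patterns)
    if (patterns == "msr" && rank > 4) {
      stop("the 'msr' preset provides at most 4 far-field patterns")
    }
  } else {
    patterns <- as.matrix(patterns)
    if (ncol(patterns) != rank || nrow(patterns) != n_channels) {
      stop("patterns must be n_channels x rank")
    }
    if (qr(patterns)$rank < rank) stop("patterns must be linearly independent")
  }
  if (line_fraction < 0 || line_fraction > 1) {
    stop("line_fraction must lie in [0, 1]")
  }
  structure(
    list(n_channels = n_channels, rank = rank, component_rms = component_rms,
         band = band, sensor_noise_sd = sensor_noise_sd, patterns = patterns,
         line_freqs = rep_len(line_freqs, max(rank, 1L)),
         line_fraction = line_fraction),
    class = "interference_model"
  )
}

# Far-field patterns as seen by the sensor array: uniform field along z
# plus three symmetric traceless first-order gradients.
msr_patterns <- function(sensors, rank) {
  P <- sensors$positions; O <- sensors$orientations
  grad <- function(G) rowSums((P %*% G) * O)
  pats <- cbind(O[, 3],
                grad(diag(c(1, -1, 0))),
                grad(diag(c(0, 1, -1))),
                grad(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)))
  pats <- pats[, seq_len(rank), drop = FALSE]
  sweep(pats, 2, sqrt(colSums(pats^2)), "/")
}

draw_patterns <- function(n_channels, rank, min_angle_deg = 30) {
  cos_max <- cos(min_angle_deg * pi / 180)
  pats <- matrix(0, n_channels, rank)
  j <- 1L
  tries <- 0L
  while (j <= rank) {
    v <- stats::rnorm(n_channels)
    v <- v / sqrt(sum(v^2))
    if (j == 1L || all(abs(crossprod(pats[, seq_len(j - 1L), drop = FALSE], v)) < cos_max)) {
      pats[, j] <- v
      j <- j + 1L
    }
    tries <- tries + 1L
    if (tries > 10000L) stop("could not draw patterns with the requested separation")
  }
  pats
}

#' Simulate an interference (or empty-room) recording
#'
#' A pure function of `(model, duration, srate, seed)`: the same seed
#' reproduces the same recording exactly.
#'
#' @param sensors a `sensor_array` (supplies channel count and ids).
#' @param model an `interference_model`.
#' @param duration length in seconds.
#' @param srate sampling rate, Hz.
#' @param seed RNG seed.
#' @return A `continuous_recording`; the realized pattern matrix is
#'   attached as attribute `patterns`.
#' @export
simulate_interference <- function(sensors, model, duration, srate = 1000, seed) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(model, "interference_model"))
  n_ch <- length(sensors$channel_ids)
  if (model$n_channels != n_ch) stop("model channel count does not match sensors")
  n_t <- round(duration * srate)
  set.seed(seed)
  pats <- if (is.matrix(model$patterns)) {
    model$patterns
  } else if (model$rank == 0) {
    matrix(0, n_ch, 0)
  } else if (identical(model$patterns, "msr")) {
    msr_patterns(sensors, model$rank)
  } else {
    draw_patterns(n_ch, model$rank)
  }
  data <- matrix(0, n_ch, n_t)
  if (model$rank > 0) {
    filt <- butter_band(model$band[1], model$band[2], srate)
    tt <- (seq_len(n_t) - 1) / srate
    lf <- model$line_fraction
    tc <- matrix(0, model$rank, n_t)
    for (r in seq_len(model$rank)) {
      w <- signal::filtfilt(filt, stats::rnorm(n_t))
      w <- w / stats::sd(w)
      line <- sqrt(2) * sin(2 * pi * model$line_freqs[r] * tt +
                              stats::runif(1, 0, 2 * pi))
      tc[r, ] <- model$component_rms *
        (sqrt(1 - lf) * w + sqrt(lf) * line)
    }
    data <- pats %*% tc
  }
  if (model$sensor_noise_sd > 0) {
    data <- data + matrix(stats::rnorm(n_ch * n_t, sd = model$sensor_noise_sd),
                          n_ch, n_t)
  }
  rec <- continuous_recording(data, srate, sensors$channel_ids)
  attr(rec, "patterns") <- pats
  rec
}

#' Assemble a raw evoked dataset from truth and interference
#'
#' Raw epochs are the clean evoked signal plus consecutive slices of the
#' first interference realization, one per trial with no reuse.  By
#' default the slices tile the recording back to back (`stride` equal to
#' the epoch length); passing the stimulus period as `stride` instead
#' cuts the slices at stimulus-locked spacing, the way epochs fall on a
#' continuous recording with a fixed inter-stimulus interval.  The
#' second, statistically matched but independent realization is returned
#' untouched as the empty-room recording used for subspace estimation.
#'
#' @param truth a `simulation_truth` from [simulate_evoked()].
#' @param interference `continuous_recording` added to the evoked signal.
#' @param emptyroom independent `continuous_recording` for subspace
#'   estimation.
#' @param rank true interference rank, recorded in the returned truth.
#' @param seed seed recorded in the returned truth.
#' @param stride spacing between consecutive trial slices in samples;
#'   default the epoch length (non-overlapping tiling).
#' @return List with `epochs` (raw `epoched_recording`), `emptyroom`, and
#'   the updated `truth`.
#' @export
assemble_dataset <- function(truth, interference, emptyroom,
                             rank = NA_integer_, seed = NA_integer_,
                             stride = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  ep <- truth$B_sim
  if (!identical(interference$channel_ids, ep$channel_ids) ||
      interference$srate != ep$srate) {
    stop("interference recording does not match the evoked sensors/srate")
  }
  n_t <- dim(ep$data)[3]
  if (is.null(stride)) stride <- n_t
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be a positive sample count")
  need <- (ep$n_trials - 1) * stride + n_t
  if (ncol(interference$data) < need) {
    stop(sprintf("insufficient interference duration: need %d samples, have %d",
                 need, ncol(interference$data)))
  }
  data <- ep$data
  for (k in seq_len(ep$n_trials)) {
    sl <- ((k - 1) * stride + 1):((k - 1) * stride + n_t)
    data[, k, ] <- data[, k, ] + interference$data[, sl]
  }
  truth$interference_rank <- rank
  truth$seed <- seed
  list(
    epochs = epoched_recording(data, ep$srate, ep$times, ep$channel_ids),
    emptyroom = emptyroom,
    truth = truth
  )
}

#' Default simulated-study configuration
#'
#' The conditions emulated throughout the package's tests: a 50 nA.m,
#' 10 Hz dipole active 0-500 ms of each 1 s trial, 300 trials, measured by
#' 31 radial magnetometers on a 10 cm helmet; rank-4 interference with
#' 1000 fT component RMS in 1-40 Hz plus 30 fT white sensor noise; the
#' source sits 7 cm from the head center under the cap with a tangential
#' moment.
#'
#' @param n_trials number of trials (default 300).
#' @param rank interference rank (default 4).
#' @param component_rms interference component RMS, fT (default 1000).
#' @param sensor_noise_sd sensor-noise SD, fT (default 30).
#' @param srate sampling rate, Hz (default 1000).
#' @param patterns pattern preset or matrix, see [interference_model()].
#' @param line_fraction per-component line-power fraction, see
#'   [interference_model()].
#' @param period stimulus period in seconds (default 1): spacing at which
#'   trial slices are cut from the interference recording.
#' @return A named list of simulation settings.
#' @export
sim_config <- function(n_trials = 300, rank = 4, component_rms = 1000,
                       sensor_noise_sd = 30, srate = 1000,
                       patterns = "msr", line_fraction = 0.5, period = 1) {
  list(n_trials = n_trials, rank = rank, component_rms = component_rms,
       sensor_noise_sd = sensor_noise_sd, srate = srate,
       patterns = patterns, line_fraction = line_fraction, period = period,
       tmin = -0.2, tmax = 0.8, band = c(1, 40),
       source_radius = 0.07, peak_moment = 50, frequency = 10,
       active = c(0, 0.5))
}

#' Generate a complete synthetic evoked dataset
#'
#' One call builds the helmet, dipole, clean evoked signal, two
#' independent interference realizations (one mixed into the raw epochs,
#' one returned as the empty-room recording), all reproducible from
#' `seed`.
#'
#' @param config settings from [sim_config()].
#' @param seed integer seed; sub-seeds for the two interference
#'   realizations are derived from it.
#' @return List with `epochs`, `emptyroom`, `truth`, `sensors`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  sensors <- opm_helmet()
  # source under the cap: along +z tilted toward the cap interior
  pos <- config$source_radius * c(0, 0, 1)
  dir <- c(1, 0, 0)  # tangential (perpendicular to the radial +z)
  src <- dipole_source(pos, dir, peak_moment = config$peak_moment,
                       frequency = config$frequency,
                       active_tmin = config$active[1],
                       active_tmax = config$active[2],
                       n_trials = config$n_trials)
  truth <- simulate_evoked(sensors, src, srate = config$srate,
                           tmin = config$tmin, tmax = config$tmax)
  n_t <- dim(truth$B_sim$data)[3]
  stride <- round(config$period * config$srate)
  dur <- ceiling(((config$n_trials - 1) * stride + n_t) / config$srate) + 1
  model <- interference_model(length(sensors$channel_ids), rank = config$rank,
                              component_rms = config$component_rms,
                              band = config$band,
                              sensor_noise_sd = config$sensor_noise_sd,
                              patterns = config$patterns,
                              line_fraction = config$line_fraction)
  seed <- as.integer(seed)
  sub_seed <- (abs(seed) %% 1000000000L) * 2L  # keep derived seeds < 2^31
  interf <- simulate_interference(sensors, model, dur, config$srate,
                                  seed = sub_seed)
  # same patterns for the matched empty-room realization, fresh timecourses
  model2 <- model
  model2$patterns <- attr(interf, "patterns")
  emptyroom <- simulate_interference(sensors, model2, dur, config$srate,
                                     seed = sub_seed + 1L)
  ds <- assemble_dataset(truth, interf, emptyroom, rank = config$rank,
                         seed = seed, stride = stride)
  ds$sensors <- sensors
  ds
}
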