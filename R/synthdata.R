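#' Synthetic spherical forward model
#'
#' Builds a simplified EEG forward model on a spherical geometry: sensors
#' quasi-uniformly covering the unit sphere (a Fibonacci lattice),
#' sources at random interior positions with radius in \[0.3, 0.9\], and a
#' gain matrix from a radially oriented unit current dipole in an infinite
#' homogeneous medium (projection of the dipole field onto the sensor
#' direction, inverse-square distance law). Column norms therefore fall off
#' with source depth, which is what the depth-weighted inverse compensates.
#' A subset of `n_nodes` sources, spread over the interior by greedy
#' farthest-point selection, serves as the parcellation's node seed points.
#'
#' @param n_sensors number of scalp sensors (>= 8).
#' @param n_sources number of candidate cortical sources.
#' @param n_nodes number of node seed sources (<= `n_sources`); the default
#'   148 mirrors a 74-regions-per-hemisphere cortical parcellation.
#' @param seed integer RNG seed; identical seeds give identical models.
#' @return an object of class `forward_model` with elements `gain`
#'   (n_sensors x n_sources), `source_pos`, `sensor_pos`, `node_seeds`.
#' @export
make_forward_model <- function(n_sensors = 62, n_sources = 500,
                               n_nodes = 148, seed = 1) {
  if (n_nodes > n_sources)
    stop("n_nodes (", n_nodes, ") must not exceed n_sources (", n_sources, ")")
  if (n_sensors < 8) stop("need at least 8 sensors")
  set.seed(seed)

  # Fibonacci lattice over the full unit sphere
  i <- seq_len(n_sensors)
  z <- (2 * i - 1) / n_sensors - 1
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  sensor_pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)

  # sources: uniform in the volume of the shell with radius in [0.3, 0.9],
  # each with a fixed random dipole orientation
  u <- matrix(rnorm(3 * n_sources), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- (runif(n_sources) * (0.9^3 - 0.3^3) + 0.3^3)^(1 / 3)
  source_pos <- u * rad
  orientation <- matrix(rnorm(3 * n_sources), ncol = 3)
  orientation <- orientation / sqrt(rowSums(orientation^2))

  gain <- matrix(0, n_sensors, n_sources)
  for (j in seq_len(n_sources)) {
    d <- sweep(sensor_pos, 2, source_pos[j, ])          # sensor - source
    dist2 <- rowSums(d^2)
    # dipole potential: cos(angle to moment) / distance^2
    gain[, j] <- (d %*% orientation[j, ]) / dist2^1.5
  }
  if (any(colSums(gain^2) == 0)) stop("degenerate gain column")

  node_seeds <- farthest_points(source_pos, n_nodes)
  structure(list(gain = gain, source_pos = source_pos,
                 sensor_pos = sensor_pos, orientation = orientation,
                 node_seeds = node_seeds, seed = seed),
            class = "forward_model")
}

# Greedy farthest-point subset: deterministic, spreads picks over space.
farthest_points <- function(pos, k) {
  n <- nrow(pos)
  picked <- integer(k)
  picked[1] <- which.max(rowSums(pos^2))  # start from the outermost point
  mind <- colSums((t(pos) - pos[picked[1], ])^2)
  if (k > 1) for (i in 2:k) {
    picked[i] <- which.max(mind)
    mind <- pmin(mind, colSums((t(pos) - pos[picked[i], ])^2))
  }
  picked
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d sensors x %d sources, %d node seeds\n",
              nrow(x$gain), ncol(x$gain), length(x$node_seeds)))
  invisible(x)
}

#' Band-coupling specification for one synthetic group
#'
#' Ground-truth knobs for one simulated group: per-band coupling level
#' `c` in \[0, 1\] (the variance fraction each node's narrowband component
#' shares with a common driver, so `c` monotonically controls the expected
#' pairwise PLV in that band), per-band amplitudes (standard deviations of
#' the narrowband components, arbitrary source units), and corruption rates
#' used by [simulate_cohort()].
#'
#' @param label group label.
#' @param coupling named numeric vector of coupling levels over (a subset
#'   of) the canonical bands; unnamed bands default to 0.1.
#' @param amplitudes named numeric vector of band amplitudes; defaults give
#'   an alpha-dominant resting spectrum so clean epochs pass the
#'   theta/alpha < 1 drowsiness screen.
#' @param artifact_rate fraction of 2-s segments receiving a +/-100 uV
#'   single-sample spike.
#' @param drowsy_fraction fraction of 2-s segments receiving a theta burst
#'   that drives theta power above alpha power.
#' @param eog_gain scalp projection gain of the simulated EOG signal.
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(label = "group",
                          coupling = c(theta = 0.1),
                          amplitudes = NULL,
                          artifact_rate = 0,
                          drowsy_fraction = 0,
                          eog_gain = 0.5) {
  bands <- eeg_bands()$name
  cvec <- setNames(rep(0.1, length(bands)), bands)
  if (length(coupling)) {
    if (is.null(names(coupling)) || !all(names(coupling) %in% bands))
      stop("coupling must be named with canonical band names")
    cvec[names(coupling)] <- coupling
  }
  if (any(cvec < 0 | cvec > 1)) stop("coupling levels must lie in [0, 1]")
  avec <- setNames(c(1.0, 0.8, 1.5, 0.7, 0.6, 0.4), bands)
  if (!is.null(amplitudes)) {
    if (is.null(names(amplitudes)) || !all(names(amplitudes) %in% bands))
      stop("amplitudes must be named with canonical band names")
    avec[names(amplitudes)] <- amplitudes
  }
  if (drowsy_fraction < 0 || drowsy_fraction > 1)
    stop("drowsy_fraction must lie in [0, 1]")
  if (artifact_rate < 0 || artifact_rate > 1)
    stop("artifact_rate must lie in [0, 1]")
  structure(list(label = label, coupling = cvec, amplitudes = avec,
                 artifact_rate = artifact_rate,
                 drowsy_fraction = drowsy_fraction, eog_gain = eog_gain),
            class = "coupling_spec")
}

#' Simulate phase-coupled node source signals
#'
#' For each canonical band, every node receives
#' `amp * (sqrt(1 - c) * own_noise + sqrt(c) * shared_driver)`, where both
#' the private noise and the shared driver are white noise band-passed to
#' the band and standardized to unit variance. Narrowband noise (rather
#' than sinusoids) keeps phase estimates non-degenerate, and `c`
#' monotonically controls the expected pairwise PLV in that band. Band
#' components are summed.
#'
#' @param fm a [make_forward_model()] object (defines the node count).
#' @param spec a [coupling_spec()].
#' @param duration_s signal duration in seconds (>= 2).
#' @param fs sampling rate in Hz (>= 200, and above twice the highest band
#'   edge).
#' @param seed integer RNG seed.
#' @return numeric matrix, n_nodes x samples (arbitrary source units).
#' @export
simulate_coupled_sources <- function(fm, spec, duration_s, fs, seed = 1) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (duration_s < 2) stop("duration_s must be >= 2")
  if (fs < 200) stop("fs must be >= 200")
  set.seed(seed)
  n_nodes <- length(fm$node_seeds)
  ns <- round(duration_s * fs)
  bands <- eeg_bands()
  out <- matrix(0, ns, n_nodes)              # samples x nodes while building
  for (k in seq_len(nrow(bands))) {
    bname <- bands$name[k]
    cb <- spec$coupling[[bname]]
    ab <- spec$amplitudes[[bname]]
    # white noise -> band-pass -> unit variance; driver first, then privates
    raw <- matrix(rnorm(ns * (n_nodes + 1L)), nrow = ns)
    nb <- filtfilt_band(raw, fs, bands[k, ])
    sds <- sqrt(colMeans(nb^2) - colMeans(nb)^2)
    nb <- nb / rep(sds, each = ns)
    # driver (column 1) recycles down each private column
    out <- out + ab * (sqrt(1 - cb) * nb[, -1, drop = FALSE] +
                         sqrt(cb) * nb[, 1])
  }
  t(out)
}

# band-pass down columns of a samples x signals matrix
filtfilt_band <- function(m, fs, band, order = 3) {
  d <- butter_design(order, c(band$lo, band$hi) / (fs / 2), "pass")
  filtfilt_zi(d$b, d$a, m)
}

#' Simulate an EOG channel
#'
#' Slow (< 4 Hz) baseline wander plus randomly timed blink-like pulses.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate (Hz).
#' @param seed RNG seed.
#' @param sd_uV overall standard deviation of the output, in microvolts.
#' @param blink_rate_hz expected blink rate (events per second).
#' @return numeric vector of length `round(duration_s * fs)` (microvolts).
#' @export
simulate_eog <- function(duration_s, fs, seed = 1, sd_uV = 30,
                         blink_rate_hz = 0.25) {
  set.seed(seed)
  ns <- round(duration_s * fs)
  d <- butter_design(3, min(4 / (fs / 2), 0.99), "low")
  drift <- filtfilt_zi(d$b, d$a, rnorm(ns))
  n_blinks <- max(1L, rpois(1, blink_rate_hz * duration_s))
  blink <- numeric(ns)
  width <- round(0.2 * fs)
  shape <- exp(-((seq_len(width) - width / 2)^2) / (2 * (width / 6)^2))
  for (t0 in sample.int(ns - width, n_blinks)) {
    blink[t0:(t0 + width - 1L)] <- blink[t0:(t0 + width - 1L)] + 3 * shape
  }
  x <- drift / sd(drift) + blink
  x / sd(x) * sd_uV
}

#' Project node source signals to the scalp
#'
#' Computes `gain[, node_seeds] %*% node_signals`, adds an EOG contribution
#' with a frontal topography (gain decaying as `exp(-d / 0.5)` with `d` the
#' sensor's distance from the frontal pole of the sensor sphere), adds white
#' sensor noise, and appends the EOG signal itself as an extra channel
#' labeled `"EOG"`.
#'
#' @param fm a [make_forward_model()] object.
#' @param node_signals n_nodes x samples matrix (rows follow
#'   `fm$node_seeds`).
#' @param fs sampling rate of `node_signals` (Hz), recorded in the output.
#' @param sensor_noise_sd white sensor noise standard deviation (uV).
#' @param eog_signal optional EOG vector (uV), same sample count.
#' @param eog_gain scalar gain applied to the EOG topography.
#' @param seed RNG seed for the sensor noise.
#' @return a [raw_recording()] (channels x samples, uV) whose last channel
#'   is `"EOG"` when an EOG signal is given.
#' @export
project_to_scalp <- function(fm, node_signals, fs = 1000,
                             sensor_noise_sd = 1, eog_signal = NULL,
                             eog_gain = 0, seed = 1) {
  if (nrow(node_signals) != length(fm$node_seeds))
    stop("node_signals must have one row per node seed")
  ns <- ncol(node_signals)
  scalp <- fm$gain[, fm$node_seeds, drop = FALSE] %*% node_signals
  labels <- sprintf("E%02d", seq_len(nrow(scalp)))
  eog_channels <- character()
  if (!is.null(eog_signal)) {
    if (length(eog_signal) != ns)
      stop("eog_signal length must match node_signals sample count")
    frontal <- c(1, 0, 0.5) / sqrt(1.25)
    d <- sqrt(colSums((t(fm$sensor_pos) - frontal)^2))
    topo <- exp(-d / 0.5)
    scalp <- scalp + eog_gain * outer(topo, eog_signal)
    scalp <- rbind(scalp, EOG = eog_signal)
    labels <- c(labels, "EOG")
    eog_channels <- "EOG"
  }
  if (sensor_noise_sd > 0) {
    set.seed(seed)
    n_sens <- nrow(fm$gain)           # EOG channel stays noise-free
    scalp[seq_len(n_sens), ] <- scalp[seq_len(n_sens), ] +
      matrix(rnorm(n_sens * ns, sd = sensor_noise_sd), n_sens, ns)
  }
  raw_recording(unname(scalp), fs = fs, labels = labels,
                eog_channels = eog_channels)
}

#' Cohort specification
#'
#' @param groups list of [coupling_spec()] objects, each with an `n`
#'   attribute set via the `n_subjects` argument here, or a named list
#'   `list(spec = coupling_spec, n = count)`.
#' @param n_subjects integer vector, one count per group.
#' @param duration_s per-subject recording duration (seconds).
#' @param fs sampling rate (Hz); must exceed twice the highest band edge
#'   (55 Hz).
#' @param covariate_mean,covariate_sd parameters of the premorbid-IQ-like
#'   covariate drawn per subject.
#' @param sensor_noise_sd scalp sensor noise (uV).
#' @param seed master RNG seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_subjects, duration_s = 300, fs = 1000,
                        covariate_mean = 100, covariate_sd = 10,
                        sensor_noise_sd = 1, seed = 1) {
  stopifnot(length(groups) == length(n_subjects), all(n_subjects >= 1))
  if (fs <= 2 * 55) stop("fs must exceed twice the highest band edge (55 Hz)")
  if (!all(vapply(groups, inherits, logical(1), "coupling_spec")))
    stop("groups must be coupling_spec objects")
  structure(list(groups = groups, n_subjects = as.integer(n_subjects),
                 duration_s = duration_s, fs = fs,
                 covariate_mean = covariate_mean, covariate_sd = covariate_sd,
                 sensor_noise_sd = sensor_noise_sd, seed = seed),
            class = "cohort_spec")
}

#' Simulate a multi-group cohort with recorded ground truth
#'
#' Generates one scalp recording per subject: coupled node sources projected
#' through the forward model, rescaled so the strongest EEG channel has a
#' 10 uV RMS (making the microvolt thresholds downstream meaningful), EOG
#' contamination, then injected corruption with exact bookkeeping —
#' `drowsy_fraction` of the 2-s segments receive a Hann-windowed 6 Hz burst
#' (25 uV) that drives theta power above alpha power, and `artifact_rate`
#' of the remaining segments receive a single-sample +/-100 uV spike on one
#' channel. The returned ground truth lists the corrupted segment indices
#' per subject, so preprocessing screens can be validated exactly.
#'
#' Each subject's metadata row carries the group label, a premorbid-IQ-like
#' covariate, and a synthetic functioning score constructed to decrease with
#' the group's theta coupling (`score = 100 - 40 * c_theta + N(0, 5)`).
#'
#' @param spec a [cohort_spec()].
#' @param fm optional [make_forward_model()]; defaults to a 62-sensor,
#'   500-source, 148-node model derived from the cohort seed.
#' @return list with `recordings` (list of [raw_recording()]),
#'   `metadata` (data frame: subject, group, covariate, score),
#'   `ground_truth` (per subject: integer vectors `drowsy`, `artifact`),
#'   and `fm`.
#' @export
simulate_cohort <- function(spec, fm = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  if (is.null(fm)) fm <- make_forward_model(seed = spec$seed)
  n_total <- sum(spec$n_subjects)
  sub_seeds <- sample.int(.Machine$integer.max, 3L * n_total)
  n_seg <- floor(spec$duration_s / 2)
  seg_len <- round(2 * spec$fs)

  recordings <- vector("list", n_total)
  gt <- vector("list", n_total)
  meta <- data.frame(subject = character(n_total), group = character(n_total),
                     covariate = numeric(n_total), score = numeric(n_total),
                     stringsAsFactors = FALSE)
  covs <- rnorm(n_total, spec$covariate_mean, spec$covariate_sd)
  score_noise <- rnorm(n_total, 0, 5)

  idx <- 0L
  for (g in seq_along(spec$groups)) {
    gs <- spec$groups[[g]]
    for (s in seq_len(spec$n_subjects[g])) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", gs$label, s)
      src <- simulate_coupled_sources(fm, gs, spec$duration_s, spec$fs,
                                      seed = sub_seeds[3L * idx - 2L])
      eog <- simulate_eog(spec$duration_s, spec$fs,
                          seed = sub_seeds[3L * idx - 1L])
      # scale sources so the projected EEG background has max channel RMS 10 uV
      proj <- fm$gain[, fm$node_seeds, drop = FALSE] %*% src
      fac <- 10 / max(sqrt(rowMeans(proj^2)))
      raw <- project_to_scalp(fm, src * fac, fs = spec$fs,
                              sensor_noise_sd = spec$sensor_noise_sd,
                              eog_signal = eog, eog_gain = gs$eog_gain,
                              seed = sub_seeds[3L * idx])

      n_drowsy <- round(gs$drowsy_fraction * n_seg)
      n_art <- round(gs$artifact_rate * n_seg)
      pick <- sample.int(n_seg, n_drowsy + n_art)
      drowsy <- sort(pick[seq_len(n_drowsy)])
      artifact <- sort(pick[seq_len(n_art) + n_drowsy])
      ei <- eeg_idx(raw)
      for (sg in drowsy) {
        tt <- ((sg - 1L) * seg_len + 1L):(sg * seg_len)
        env <- 0.5 - 0.5 * cos(2 * pi * seq_along(tt) / length(tt))
        burst <- 25 * env * sin(2 * pi * 6 * (tt - 1) / spec$fs)
        # spatially varying gain so the burst survives average referencing
        topo <- 1 + 0.8 * sin(2 * pi * seq_along(ei) / length(ei) +
                                runif(1, 0, 2 * pi))
        raw$data[ei, tt] <- raw$data[ei, tt] + outer(topo, burst)
      }
      for (sg in artifact) {
        t0 <- (sg - 1L) * seg_len + sample.int(seg_len, 1L)
        ch <- ei[sample.int(length(ei), 1L)]
        raw$data[ch, t0] <- raw$data[ch, t0] + sample(c(-100, 100), 1L)
      }
      recordings[[idx]] <- raw
      gt[[idx]] <- list(drowsy = drowsy, artifact = artifact)
      meta$subject[idx] <- sid
      meta$group[idx] <- gs$label
      meta$covariate[idx] <- covs[idx]
      meta$score[idx] <- 100 - 40 * gs$coupling[["theta"]] + score_noise[idx]
      names(recordings)[idx] <- names(gt)[idx] <- sid
    }
  }
  list(recordings = recordings, metadata = meta, ground_truth = gt, fm = fm)
}
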