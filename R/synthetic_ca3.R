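#' Spike train container
#'
#' Ordered event times in seconds plus a recording duration. The unit of both
#' naturalistic input patterns and neuron output.
#'
#' @param times Strictly increasing event times, s, within `[0, duration)`.
#' @param duration Recording duration, s.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  if (!is.numeric(times)) stop("'times' must be numeric", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("'duration' must be a single positive number", call. = FALSE)
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0) || any(times >= duration))
      stop("event times must lie in [0, duration)", call. = FALSE)
    if (any(diff(times) <= 0))
      stop("event times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, duration = as.numeric(duration)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d events over %g s (mean rate %.3g Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Parameters of the naturalistic CA3 spike-train generator
#'
#' The generator emulates the discharge of a CA3 pyramidal place cell during
#' open-field exploration. A slow rate envelope (an out-of-field baseline
#' plus Gaussian place-field traversals) sets the expected discharge; a
#' fraction `theta_depth` of that discharge is organized into theta-locked
#' spike packets — per theta cycle, a Poisson-distributed number of spikes
#' emitted at gamma-range intra-packet intervals (`packet_isi`) — while the
#' remainder is an inhomogeneous Poisson process on the same envelope. Each
#' spike can additionally seed a complex-spike burst (a geometric number of
#' extra spikes at `burst_isi` intervals), and a presynaptic refractory gap
#' `min_isi` is enforced by thinning. This reproduces the characteristic
#' interval structure of such cells: theta-period gaps, gamma intervals
#' within packets, and occasional 2-6 ms complex-spike intervals.
#'
#' @param duration Recording length, s (default 600, a 10-minute session).
#' @param baseline_rate Out-of-field envelope rate, Hz.
#' @param field_event_rate Expected place-field traversals per minute.
#' @param field_peak_rate Peak in-field envelope rate, Hz.
#' @param field_width Gaussian envelope standard deviation, s.
#' @param theta_frequency Theta packet frequency, Hz.
#' @param theta_depth Fraction of the discharge organized into theta-locked
#'   packets, in `[0, 1]` (0 gives a plain inhomogeneous Poisson process).
#' @param packet_size Mean number of spikes per packet (>= 1); the per-cycle
#'   packet probability scales as envelope / (theta_frequency * packet_size),
#'   so larger packets make active cycles rarer but denser.
#' @param packet_isi Range of intra-packet (gamma) inter-spike intervals, ms.
#' @param packet_jitter Standard deviation of the packet start time within
#'   the cycle, ms.
#' @param burst_prob Probability that a spike seeds a complex-spike burst,
#'   in `[0, 1]`.
#' @param burst_mean_extra Mean number of extra spikes per burst (geometric).
#' @param burst_isi Range of intra-burst inter-spike intervals, ms.
#' @param min_isi Minimum inter-spike interval, ms.
#' @param seed Integer seed; the train is a deterministic function of the
#'   parameter set including the seed.
#' @return An object of class `ca3_pattern_params`.
#' @export
ca3_pattern_params <- function(duration = 600, baseline_rate = 12,
                               field_event_rate = 2, field_peak_rate = 6,
                               field_width = 0.3, theta_frequency = 8,
                               theta_depth = 0.9, packet_size = 2,
                               packet_isi = c(8, 18),
                               packet_jitter = 12, burst_prob = 0.1,
                               burst_mean_extra = 1.5,
                               burst_isi = c(2.5, 5), min_isi = 2,
                               seed = 1) {
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  rates <- c(baseline_rate, field_event_rate, field_peak_rate)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (theta_depth < 0 || theta_depth > 1)
    stop("'theta_depth' must lie in [0, 1]", call. = FALSE)
  if (field_width <= 0) stop("'field_width' must be positive", call. = FALSE)
  if (min_isi < 0) stop("'min_isi' must be non-negative", call. = FALSE)
  if (burst_prob < 0 || burst_prob > 1)
    stop("'burst_prob' must lie in [0, 1]", call. = FALSE)
  if (burst_mean_extra < 0)
    stop("'burst_mean_extra' must be non-negative", call. = FALSE)
  if (packet_size < 1)
    stop("'packet_size' must be >= 1", call. = FALSE)
  structure(list(duration = duration, baseline_rate = baseline_rate,
                 field_event_rate = field_event_rate,
                 field_peak_rate = field_peak_rate, field_width = field_width,
                 theta_frequency = theta_frequency, theta_depth = theta_depth,
                 packet_size = packet_size, packet_isi = packet_isi,
                 packet_jitter = packet_jitter,
                 burst_prob = burst_prob, burst_mean_extra = burst_mean_extra,
                 burst_isi = burst_isi, min_isi = min_isi,
                 seed = as.integer(seed)),
            class = "ca3_pattern_params")
}

# slow rate envelope (Hz) at times t, given field traversal centres (s)
ca3_envelope <- function(t, params, centres) {
  envelope <- rep(params$baseline_rate, length(t))
  for (c0 in centres)
    envelope <- envelope + params$field_peak_rate *
      exp(-0.5 * ((t - c0) / params$field_width)^2)
  envelope
}

#' Generate a naturalistic CA3 spike train
#'
#' Draws place-field traversal times (Poisson number with mean
#' `field_event_rate * duration / 60`, centres uniform over the session) to
#' form the slow rate envelope, emits theta-locked spike packets (per theta
#' cycle, a Poisson count with mean `theta_depth * envelope / theta_frequency`
#' placed at gamma-range intervals) plus an inhomogeneous Poisson remainder
#' at rate `(1 - theta_depth) * envelope`, decorates spikes with
#' complex-spike bursts (with probability `burst_prob` a spike is followed
#' by a geometric number of extra spikes at intra-burst intervals drawn from
#' `burst_isi`), and removes events violating the `min_isi` refractory gap.
#' Identical parameters and seed give an identical train.
#'
#' @param params A [ca3_pattern_params()] object.
#' @return A [spike_train()] (times in seconds).
#' @export
generate_ca3_pattern <- function(params) {
  stopifnot(inherits(params, "ca3_pattern_params"))
  with_seed(params$seed, {
    n_fields <- stats::rpois(1, params$field_event_rate * params$duration / 60)
    centres  <- sort(stats::runif(n_fields, 0, params$duration))
    period <- 1 / params$theta_frequency
    cycle_starts <- seq(0, params$duration - period, by = period)
    # theta-locked packets: a packet occurs in a cycle with probability
    # proportional to the envelope (capped at one per cycle); its spike
    # count is 1 + Poisson with the mean chosen so the packeted rate tracks
    # the envelope — once every cycle carries a packet (place-field
    # traversals), further envelope increases enlarge the packets instead
    mu <- params$theta_depth *
      ca3_envelope(cycle_starts + period / 2, params, centres) * period
    q <- pmin(1, mu / params$packet_size)
    has_packet <- stats::runif(length(cycle_starts)) < q
    mean_count <- ifelse(q > 0, pmax(mu / pmax(q, 1e-12), 1), 1)
    counts <- ifelse(has_packet,
                     1L + stats::rpois(length(cycle_starts),
                                       mean_count - 1), 0L)
    packet_times <- unlist(lapply(which(counts > 0), function(i) {
      t0 <- cycle_starts[i] +
        abs(stats::rnorm(1, 0, params$packet_jitter / 1000))
      gaps <- stats::runif(counts[i], params$packet_isi[1],
                           params$packet_isi[2]) / 1000
      t0 + cumsum(gaps) - gaps[1]
    }))
    # non-packeted remainder: inhomogeneous Poisson by thinning
    rem_rate <- (1 - params$theta_depth)
    grid <- seq(0, params$duration, by = 1e-2)
    lambda_max <- rem_rate * max(ca3_envelope(grid, params, centres))
    pois_times <- numeric(0)
    if (lambda_max > 0) {
      n_cand <- stats::rpois(1, lambda_max * params$duration)
      cand <- sort(stats::runif(n_cand, 0, params$duration))
      keep <- stats::runif(n_cand) <
        rem_rate * ca3_envelope(cand, params, centres) / lambda_max
      pois_times <- cand[keep]
    }
    times <- sort(c(packet_times, pois_times))
    # complex-spike bursts: geometric tail of extra spikes at short intervals
    if (length(times) && params$burst_prob > 0 &&
        params$burst_mean_extra > 0) {
      seeds_burst <- stats::runif(length(times)) < params$burst_prob
      n_extra <- stats::rgeom(length(times),
                              1 / (1 + params$burst_mean_extra))
      extras <- unlist(lapply(which(seeds_burst & n_extra > 0), function(i) {
        gaps <- stats::runif(n_extra[i], params$burst_isi[1],
                             params$burst_isi[2]) / 1000
        times[i] + cumsum(gaps)
      }))
      times <- sort(c(times, extras))
    }
    times <- times[times < params$duration & times >= 0]
    # refractory thinning: drop events closer than min_isi to the last kept
    if (length(times) > 1 && params$min_isi > 0) {
      gap <- params$min_isi / 1000
      kept <- numeric(length(times))
      kept[1] <- times[1]
      m <- 1L
      for (tt in times[-1]) {
        if (tt - kept[m] >= gap) {
          m <- m + 1L
          kept[m] <- tt
        }
      }
      times <- kept[seq_len(m)]
    }
    spike_train(unique(times), params$duration)
  })
}

#' Summary statistics of a spike train
#'
#' Event count, mean rate, and the coefficient of variation of inter-spike
#' intervals (population standard deviation over mean). A CV near 1 indicates
#' Poisson-like irregularity; bursty trains exceed 1.
#'
#' @param train A `spike_train`.
#' @return A list with `n_events`, `mean_rate` (Hz) and `isi_cv`.
#' @export
summarize_spike_train <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  n <- length(train$times)
  if (n < 3) stop("at least 3 events are required for the ISI CV",
                  call. = FALSE)
  list(n_events = n, mean_rate = n / train$duration,
       isi_cv = isi_cv(train$times))
}

#' Read a spike-time file
#'
#' Plain-text file with one event time (seconds) per row; an optional single
#' header line is skipped when `header = TRUE`. Files must be sorted,
#' non-negative and numeric; violations raise an error naming the offending
#' line.
#'
#' @param path File path.
#' @param header Whether the first line is a header to skip.
#' @param duration Optional duration, s; defaults to the last event time
#'   rounded up to the next second.
#' @return A [spike_train()].
#' @export
read_spike_file <- function(path, header = FALSE, duration = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (header && length(lines)) {
    lines <- lines[-1]
    offset <- 1L
  }
  lines <- trimws(lines)
  keep <- nzchar(lines)
  line_no <- which(keep) + offset
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals))
    stop(sprintf("non-numeric entry at line %d of %s",
                 line_no[which(is.na(vals))[1]], path), call. = FALSE)
  if (any(vals < 0))
    stop(sprintf("negative time at line %d of %s",
                 line_no[which(vals < 0)[1]], path), call. = FALSE)
  if (length(vals) > 1 && any(diff(vals) <= 0))
    stop(sprintf("unsorted or duplicate time at line %d of %s",
                 line_no[which(diff(vals) <= 0)[1] + 1L], path),
         call. = FALSE)
  if (is.null(duration))
    duration <- if (length(vals)) ceiling(max(vals) + 1e-6) else 1
  spike_train(vals, duration)
}

#' Write a spike train to a plain-text file
#'
#' One event time (seconds) per row, formatted to microsecond precision so a
#' write/read round trip reproduces the train to 1e-6 s.
#'
#' @param train A `spike_train`.
#' @param path Output path.
#' @param header Optional header string written as the first line.
#' @return `path`, invisibly.
#' @export
write_spike_file <- function(train, path, header = NULL) {
  stopifnot(inherits(train, "spike_train"))
  lines <- sprintf("%.6f", train$times)
  if (!is.null(header)) lines <- c(header, lines)
  writeLines(lines, path)
  invisible(path)
}

#' The five shipped naturalistic input patterns
#'
#' Convenience wrapper returning the fixture patterns (seeds 1-5) that play
#' the role of the five recorded CA3 neurons. All other generator parameters
#' are the shipped defaults.
#'
#' @param duration Pattern length, s (default 600).
#' @param seeds Integer seeds, one per pattern.
#' @return A list of [spike_train()] objects.
#' @export
ca3_fixture_patterns <- function(duration = 600, seeds = 1:5) {
  lapply(seeds, function(s)
    generate_ca3_pattern(ca3_pattern_params(duration = duration, seed = s)))
}
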