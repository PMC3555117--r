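#' Coefficient of variation of inter-spike intervals
#'
#' `CV = sd(ISI) / mean(ISI)` using the population (n-denominator) standard
#' deviation. Equals 0 for a perfectly periodic train and 1 for a Poisson
#' process.
#'
#' @param times Event times (any fixed unit), strictly increasing, >= 3
#'   events.
#' @return The ISI CV.
#' @export
isi_cv <- function(times) {
  if (inherits(times, "spike_train")) times <- times$times
  if (length(times) < 3)
    stop("at least 3 events are required for the ISI CV", call. = FALSE)
  isi <- diff(times)
  m <- mean(isi)
  # population sd: n denominator
  sqrt(mean((isi - m)^2)) / m
}

#' Spike probability
#'
#' The ratio between the number of output spikes and the number of stimuli,
#' expressed as a percentage. Values above 100% are possible only when the
#' neuron emits more spikes than it receives stimuli and are flagged with a
#' warning.
#'
#' @param n_output_spikes Output spike count.
#' @param n_stimuli Stimulus count (> 0).
#' @return Percentage.
#' @export
spike_probability <- function(n_output_spikes, n_stimuli) {
  if (!is.numeric(n_stimuli) || n_stimuli <= 0)
    stop("'n_stimuli' must be positive", call. = FALSE)
  if (n_output_spikes < 0)
    stop("'n_output_spikes' must be non-negative", call. = FALSE)
  p <- 100 * n_output_spikes / n_stimuli
  if (p > 100)
    warning("more output spikes than stimuli: spike probability exceeds 100%")
  p
}

#' Instantaneous-frequency distribution of a spike train
#'
#' Each inter-spike interval contributes one event at frequency `1 / ISI`.
#' The histogram is normalized to per-ISI probabilities, so the bin masses
#' sum to 1 when the bins cover the observed range (and to less than 1
#' otherwise).
#'
#' @param train A [spike_train()] or numeric event times in seconds.
#' @param bins Strictly increasing bin edges, Hz.
#' @return An object of class `frequency_histogram`: list with `edges`,
#'   `probability` (one per bin, right-closed bins `(lo, hi]` with the first
#'   bin closed on both sides), and `n_events` (number of ISIs).
#' @export
instantaneous_frequency <- function(train, bins) {
  times <- if (inherits(train, "spike_train")) train$times else train
  if (length(times) < 2)
    stop("at least 2 spikes are required", call. = FALSE)
  if (!is.numeric(bins) || length(bins) < 2 || any(diff(bins) <= 0))
    stop("'bins' must be strictly increasing edges", call. = FALSE)
  freq <- 1 / diff(times)
  k <- length(bins) - 1L
  # right-closed bins (lo, hi]; first bin closed on both sides; values
  # outside the edge range are dropped (so masses then sum to < 1)
  idx <- findInterval(freq, bins, left.open = TRUE)
  idx[freq == bins[1]] <- 1L
  idx <- idx[idx >= 1L & idx <= k]
  counts <- tabulate(idx, nbins = k)
  structure(list(edges = bins, probability = counts / length(freq),
                 n_events = length(freq)),
            class = "frequency_histogram")
}

#' @export
print.frequency_histogram <- function(x, ...) {
  cat(sprintf("Instantaneous-frequency histogram over %d ISIs\n", x$n_events))
  lab <- sprintf("(%g, %g]", x$edges[-length(x$edges)], x$edges[-1])
  for (i in seq_along(x$probability))
    cat(sprintf("  %-14s %.4f\n", lab[i], x$probability[i]))
  invisible(x)
}

#' Probability of firing within a frequency band
#'
#' Fraction of inter-spike intervals whose instantaneous frequency `1 / ISI`
#' falls inside the closed interval `[f_low, f_high]`. The conventional
#' hippocampal bands are theta (4-8 Hz) and gamma (40-80 Hz).
#'
#' @param train A [spike_train()] or numeric event times in seconds.
#' @param band `c(f_low, f_high)`, Hz.
#' @return Probability in `[0, 1]`.
#' @export
band_probability <- function(train, band) {
  times <- if (inherits(train, "spike_train")) train$times else train
  if (length(times) < 2)
    stop("at least 2 spikes are required", call. = FALSE)
  stopifnot(is.numeric(band), length(band) == 2L, band[1] <= band[2])
  freq <- 1 / diff(times)
  mean(freq >= band[1] & freq <= band[2])
}

#' Compare two conditions with the study's statistical contracts
#'
#' Three kinds of comparison: `"paired-mean"` runs a paired t-test on
#' per-pattern values after a Shapiro-Wilk normality check of the paired
#' differences (a warning is issued if normality is rejected at 0.05, since
#' the t-test assumes it); `"distribution"` runs a two-sample
#' Kolmogorov-Smirnov test; `"normality"` runs Shapiro-Wilk on the pooled
#' difference (paired) samples. Significance is declared at p < 0.05.
#'
#' @param a,b Numeric vectors (paired and equal length for `"paired-mean"`
#'   and `"normality"`).
#' @param kind Comparison kind.
#' @return A list with `kind`, `statistic`, `p_value`, `significant` and, for
#'   the paired test, `normality_p`.
#' @export
compare_conditions <- function(a, b,
                               kind = c("paired-mean", "distribution",
                                        "normality")) {
  kind <- match.arg(kind)
  if (kind %in% c("paired-mean", "normality") && length(a) != length(b))
    stop("paired comparisons require equal-length inputs", call. = FALSE)
  if (length(a) < 3 || length(b) < 3)
    stop("at least 3 values per condition are required", call. = FALSE)
  if (kind == "paired-mean") {
    d <- a - b
    norm_p <- if (stats::sd(d) > 0) stats::shapiro.test(d)$p.value else NA_real_
    if (!is.na(norm_p) && norm_p < 0.05)
      warning("paired differences deviate from normality (Shapiro-Wilk p < 0.05)")
    if (stats::sd(d) == 0) {
      res <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      res <- list(statistic = unname(tt$statistic), p.value = tt$p.value)
    }
    out <- list(kind = kind, statistic = res$statistic, p_value = res$p.value,
                significant = res$p.value < 0.05, normality_p = norm_p)
  } else if (kind == "distribution") {
    ks <- suppressWarnings(stats::ks.test(a, b))
    out <- list(kind = kind, statistic = unname(ks$statistic),
                p_value = ks$p.value, significant = ks$p.value < 0.05)
  } else {
    sw <- stats::shapiro.test(a - b)
    out <- list(kind = kind, statistic = unname(sw$statistic),
                p_value = sw$p.value, significant = sw$p.value < 0.05)
  }
  out
}

#' Standard error of the mean
#'
#' Uses the sample (n - 1) standard deviation, the aggregation convention for
#' "mean over trials plus or minus SEM" tables.
#'
#' @param x Numeric vector.
#' @return `sd(x) / sqrt(length(x))`.
#' @export
sem <- function(x) stats::sd(x) / sqrt(length(x))
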