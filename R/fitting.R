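#' Specification of a least-squares synapse fit
#'
#' Declares which short-term-plasticity parameters are free, their bounds,
#' the fixed values of the rest, and the observed normalized amplitude
#' curves. The objective compares normalized amplitudes only: the absolute
#' strength `A` cancels in the normalization and is never a free parameter
#' here (it is set separately from the first-pulse magnitude).
#'
#' @param free Character vector, subset of
#'   `c("U", "tau_in", "tau_rec", "tau_facil")`.
#' @param observations A list of observations, each a list with `frequency`
#'   (Hz) and `amplitudes` (normalized amplitude sequence, first element 1).
#' @param fixed An `stp_params` supplying values for the non-free parameters
#'   (and starting geometry for the free ones).
#' @param bounds Named list of `c(lo, hi)` per free parameter; defaults:
#'   U in \[0.01, 1\], time constants in \[0.1, 2000\] ms.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free, observations, fixed = stp_params(U = 0.15),
                     bounds = NULL) {
  par_names <- c("U", "tau_in", "tau_rec", "tau_facil")
  if (!length(free) || !all(free %in% par_names))
    stop("'free' must name at least one of ", paste(par_names, collapse = ", "),
         call. = FALSE)
  default_bounds <- list(U = c(0.01, 1), tau_in = c(0.1, 2000),
                         tau_rec = c(0.1, 2000), tau_facil = c(0.1, 2000))
  bounds <- utils::modifyList(default_bounds, bounds %||% list())
  for (f in free) {
    b <- bounds[[f]]
    if (any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop("bounds for '", f, "' must be finite, positive and increasing",
           call. = FALSE)
  }
  if (!is.list(observations) || !length(observations))
    stop("'observations' must be a non-empty list", call. = FALSE)
  observations <- lapply(observations, function(ob) {
    stopifnot(is.numeric(ob$frequency), is.numeric(ob$amplitudes))
    ob
  })
  n_points <- sum(vapply(observations, function(ob) length(ob$amplitudes),
                         integer(1)))
  if (n_points < length(free))
    stop("need at least as many observation points as free parameters",
         call. = FALSE)
  structure(list(free = free, bounds = bounds[free], fixed = fixed,
                 observations = observations),
            class = "fit_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# model-predicted normalized curves for a candidate parameter vector
fit_model_curves <- function(theta, spec) {
  pars <- spec$fixed
  for (i in seq_along(spec$free)) pars[[spec$free[i]]] <- theta[i]
  pars <- stp_params(U = pars$U, tau_in = pars$tau_in, tau_rec = pars$tau_rec,
                     tau_facil = pars$tau_facil, A = pars$A)
  lapply(spec$observations, function(ob)
    train_amplitudes(pars, length(ob$amplitudes), ob$frequency)$normalized)
}

fit_sse <- function(theta, spec) {
  model <- fit_model_curves(theta, spec)
  sum(vapply(seq_along(model), function(i)
    sum((spec$observations[[i]]$amplitudes - model[[i]])^2), numeric(1)))
}

#' Least-squares fit of synapse parameters to normalized amplitude curves
#'
#' Minimizes the sum of squared differences between observed and
#' model-predicted normalized EPSC amplitudes over the free parameters, using
#' multi-start bounded local optimization (`L-BFGS-B`). Starts are laid out
#' deterministically: for each free parameter, `n_starts` values spaced
#' linearly (for `U`) or log-spaced (for time constants) across its bounds,
#' combined level-by-level, so repeated fits of the same specification give
#' identical results.
#'
#' @param spec A [fit_spec()].
#' @param n_starts Number of optimization starts (>= 8 recommended).
#' @return A list with `par` (named fitted values), `sse`, `residuals` (per
#'   observation), `converged`, and `starts` (per-start summary).
#' @export
fit_stp <- function(spec, n_starts = 8) {
  stopifnot(inherits(spec, "fit_spec"))
  k <- length(spec$free)
  lower <- vapply(spec$free, function(f) spec$bounds[[f]][1], numeric(1))
  upper <- vapply(spec$free, function(f) spec$bounds[[f]][2], numeric(1))
  levels <- seq(0.05, 0.95, length.out = n_starts)
  start_mat <- vapply(seq_len(k), function(j) {
    f <- spec$free[j]
    if (f == "U") lower[j] + levels * (upper[j] - lower[j])
    else exp(log(lower[j]) + levels * (log(upper[j]) - log(lower[j])))
  }, numeric(n_starts))
  start_mat <- matrix(start_mat, nrow = n_starts)
  best <- NULL
  starts <- data.frame(start_id = seq_len(n_starts), sse = NA_real_,
                       converged = FALSE)
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(start_mat[s, ], fit_sse, spec = spec,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    starts$sse[s] <- res$value
    starts$converged[s] <- res$convergence == 0
    if (res$convergence == 0 && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best))
    stop("fit failure: no optimization start converged; ",
         "starts tried: ", n_starts, "; best SSE seen: ",
         format(suppressWarnings(min(starts$sse, na.rm = TRUE))),
         call. = FALSE)
  par <- stats::setNames(best$par, spec$free)
  model <- fit_model_curves(best$par, spec)
  residuals <- lapply(seq_along(model), function(i)
    spec$observations[[i]]$amplitudes - model[[i]])
  list(par = par, sse = best$value, residuals = residuals,
       converged = TRUE, starts = starts)
}

#' Rank alternative parameter scenarios against a reference curve
#'
#' Fits each scenario (a [fit_spec()] whose observations are replaced by the
#' reference curve) and returns a table ranked by the achieved sum of squared
#' errors. Used to ask whether distinct parameter changes — e.g. raising the
#' release probability alone versus jointly lowering it and shortening the
#' facilitation time constant — can produce near-identical amplitude curves.
#'
#' @param reference A list with `frequency` and `amplitudes` (normalized), or
#'   a list of such observations.
#' @param scenarios Named list of [fit_spec()] objects (their `observations`
#'   are ignored and replaced by `reference`).
#' @return A data frame with one row per scenario: `scenario`, `sse`,
#'   `max_abs_diff` and the fitted parameter values (`NA` where not free),
#'   ordered by increasing SSE.
#' @export
compare_scenarios <- function(reference, scenarios) {
  if (!is.null(reference$frequency)) reference <- list(reference)
  stopifnot(is.list(scenarios), length(scenarios) >= 1)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario_", seq_along(scenarios))
  rows <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    sc$observations <- reference
    fit <- fit_stp(sc)
    model <- fit_model_curves(unname(fit$par), sc)
    mad <- max(vapply(seq_along(model), function(i)
      max(abs(reference[[i]]$amplitudes - model[[i]])), numeric(1)))
    pars <- stats::setNames(rep(NA_real_, 4),
                            c("U", "tau_in", "tau_rec", "tau_facil"))
    pars[sc$free] <- fit$par
    data.frame(scenario = nm, sse = fit$sse, max_abs_diff = mad, t(pars))
  })
  out <- do.call(rbind, rows)
  out[order(out$sse), , drop = FALSE]
}

#' Fit a sigmoid input-output curve
#'
#' Fits `y = a / (1 + b * exp(-c * x))` to spike probability (%) versus
#' synaptic conductance (nS) by Levenberg-Marquardt least squares, with `a`
#' optionally held fixed at the empirical saturating probability. Starting
#' values come from a log-linearisation of the interior points.
#'
#' @param x Conductances, nS.
#' @param y Spike probabilities, percent.
#' @param a_fixed Optional fixed asymptote.
#' @return An object of class `sigmoid_fit`: list with `a`, `b`, `c`,
#'   `fitted`, `sse` and `a_was_fixed`.
#' @export
fit_sigmoid <- function(x, y, a_fixed = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  need <- if (is.null(a_fixed)) 3L else 2L
  if (length(x) < need)
    stop("need at least ", need, " points", call. = FALSE)
  if (stats::sd(y) < 1e-12)
    stop("fit failure: response is constant, slope not identifiable",
         call. = FALSE)
  a0 <- a_fixed %||% (max(y) * 1.05)
  interior <- which(y > 0.01 * a0 & y < 0.99 * a0)
  if (length(interior) >= 2) {
    lin <- stats::lm(log(a0 / y[interior] - 1) ~ x[interior])
    b0 <- exp(unname(stats::coef(lin)[1]))
    c0 <- -unname(stats::coef(lin)[2])
  } else {
    b0 <- 50
    c0 <- 1 / max(abs(x) + 1e-9)
  }
  if (!is.finite(b0) || b0 <= 0) b0 <- 50
  if (!is.finite(c0) || c0 <= 0) c0 <- 1 / max(abs(x) + 1e-9)
  dat <- data.frame(x = x, y = y)
  fit <- if (is.null(a_fixed)) {
    minpack.lm::nlsLM(y ~ a / (1 + b * exp(-c * x)), data = dat,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(a = 1e-6, b = 1e-9, c = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(y ~ a_fixed / (1 + b * exp(-c * x)), data = dat,
                      start = list(b = b0, c = c0),
                      lower = c(b = 1e-9, c = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  a <- if (is.null(a_fixed)) unname(cf["a"]) else a_fixed
  structure(list(a = a, b = unname(cf["b"]), c = unname(cf["c"]),
                 fitted = stats::fitted(fit),
                 sse = sum(stats::residuals(fit)^2),
                 a_was_fixed = !is.null(a_fixed)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit: y = %.4g / (1 + %.4g * exp(-%.4g * x))%s\n",
              x$a, x$b, x$c,
              if (x$a_was_fixed) "  [a fixed]" else ""))
  cat(sprintf("  SSE: %.4g\n", x$sse))
  invisible(x)
}
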