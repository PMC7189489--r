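#' Per-condition psychophysical dataset
#'
#' One row per stimulus condition: the model's kernel score (NCC predictor),
#' the number of trials, and the number of trials on which deformation was
#' reported. The report proportion is derived as `n_reports / n_trials`.
#'
#' @param condition Condition labels.
#' @param ncc NCC predictor per condition.
#' @param n_trials Trials per condition (>= 1).
#' @param n_reports Deformation reports per condition (0 <= reports <= trials).
#' @return A data frame of class `psycho_dataset` with a `proportion` column.
#' @export
psycho_dataset <- function(condition, ncc, n_trials, n_reports) {
  n <- length(condition)
  stopifnot(length(ncc) == n, all(is.finite(ncc)))
  n_trials <- rep_len(as.integer(n_trials), n)
  n_reports <- rep_len(as.integer(n_reports), n)
  if (any(n_trials < 1)) stop("n_trials must be >= 1", call. = FALSE)
  if (any(n_reports < 0) || any(n_reports > n_trials)) {
    stop("n_reports must lie in [0, n_trials]", call. = FALSE)
  }
  d <- data.frame(condition = condition, ncc = ncc, n_trials = n_trials,
                  n_reports = n_reports,
                  proportion = n_reports / n_trials)
  class(d) <- c("psycho_dataset", "data.frame")
  d
}

#' Fit an exponential link between NCC and report proportion
#'
#' Least-squares fit of `p = a * exp(b * ncc)` to the per-condition report
#' proportions (optionally `p = a * exp(b * ncc) + c` with `offset = TRUE`).
#' The nonlinear fit is seeded by a log-linear regression of
#' `log(p + 1e-3)` on the NCC, which makes the fit deterministic and avoids
#' local minima. The coefficient of determination is computed on the
#' proportion scale: `r2 = 1 - SS_res / SS_tot`.
#'
#' @param dataset A [psycho_dataset()], or anything with `ncc` and
#'   `proportion` columns.
#' @param weights Optional per-condition weights (e.g. `n_trials` for
#'   binomial weighting); default unweighted.
#' @param offset If `TRUE`, fit the three-parameter variant with an additive
#'   offset.
#' @return An `exp_fit` object: `a`, `b` (and `c` if `offset`), `r2`,
#'   `fitted`, `residuals`, `degenerate` flag, and `convergence` diagnostics.
#'   Constant proportions give `degenerate = TRUE` and `r2 = NA` (SS_tot is
#'   zero). A constant predictor is an error.
#' @export
fit_exponential <- function(dataset, weights = NULL, offset = FALSE) {
  x <- dataset$ncc
  p <- dataset$proportion
  stopifnot(length(x) >= 3, length(x) == length(p))
  if (stats::sd(x) == 0) {
    stop("degenerate predictor: all NCC values are equal", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(p))
  degenerate <- stats::sd(p) == 0
  if (degenerate) {
    # constant proportions: the flat curve a*exp(0*x) fits exactly, but
    # SS_tot = 0 leaves r2 undefined
    out <- list(a = mean(p), b = 0, c = if (offset) 0 else NULL,
                r2 = NA_real_, fitted = rep(mean(p), length(p)),
                residuals = p - mean(p), ss_res = 0, ss_tot = 0,
                degenerate = TRUE,
                convergence = list(converged = TRUE, iterations = 0L,
                                   message = "degenerate: constant proportions"))
    class(out) <- "exp_fit"
    return(out)
  }
  init <- stats::lm(log(p + 1e-3) ~ x)
  start <- list(a = exp(stats::coef(init)[[1]]), b = stats::coef(init)[[2]])
  form <- p ~ a * exp(b * x)
  if (offset) {
    start$c <- 0
    form <- p ~ a * exp(b * x) + c
  }
  fit <- minpack.lm::nlsLM(form, data = data.frame(x = x, p = p),
                           start = start, weights = weights,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  fitted <- as.numeric(stats::predict(fit))
  res <- p - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((p - mean(p))^2)
  r2 <- if (degenerate) NA_real_ else 1 - ss_res / ss_tot
  conv <- fit$convInfo
  out <- list(a = cf[["a"]], b = cf[["b"]],
              c = if (offset) cf[["c"]] else NULL,
              r2 = r2, fitted = fitted, residuals = res,
              ss_res = ss_res, ss_tot = ss_tot,
              degenerate = degenerate,
              convergence = list(converged = isTRUE(conv$isConv),
                                 iterations = conv$finIter,
                                 message = conv$stopMessage))
  if (!isTRUE(conv$isConv)) {
    warning("exponential fit did not converge: ", conv$stopMessage,
            call. = FALSE)
  }
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> p = %.4g * exp(%.4g * ncc)%s   r2 = %s%s\n",
              x$a, x$b,
              if (!is.null(x$c)) sprintf(" + %.4g", x$c) else "",
              if (is.na(x$r2)) "NA (degenerate)" else sprintf("%.4f", x$r2),
              if (x$degenerate) " [constant proportions]" else ""))
  invisible(x)
}

#' Sweep kernel spatial frequency against behavior
#'
#' For each kernel frequency: score every condition's map with
#' [max_ncc_over_phase()], fit the exponential link to the report
#' proportions, and record r2. The frequency whose kernel best predicts
#' behavior is the sweep's argmax.
#'
#' @param maps A list of `energy_map`/`direction_map`, one per condition, in
#'   the same order as `dataset` rows.
#' @param dataset A [psycho_dataset()] (its `ncc` column is ignored; the
#'   sweep recomputes the predictor per kernel frequency).
#' @param fs Kernel frequencies to sweep (cpd).
#' @param alpha Kernel preferred direction (deg).
#' @param n_phases Phase-grid size.
#' @param weights Passed to [fit_exponential()].
#' @return A data frame `f`, `r2`, `a`, `b` with attributes `best_f` and
#'   `ncc_matrix` (conditions x frequencies).
#' @export
kernel_frequency_sweep <- function(maps, dataset,
                                   fs = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4),
                                   alpha = 0, n_phases = 32, weights = NULL) {
  stopifnot(is.list(maps), length(maps) == nrow(dataset))
  nccs <- sapply(fs, function(f) {
    vapply(maps, function(m) {
      max_ncc_over_phase(f, m, alpha = alpha, n_phases = n_phases)$ncc
    }, numeric(1))
  })
  nccs <- matrix(nccs, nrow = length(maps), ncol = length(fs),
                 dimnames = list(NULL, paste0("f", fs)))
  rows <- lapply(seq_along(fs), function(j) {
    d <- dataset
    d$ncc <- nccs[, j]
    fit <- fit_exponential(d, weights = weights)
    data.frame(f = fs[j], r2 = fit$r2, a = fit$a, b = fit$b)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_f") <- out$f[which.max(out$r2)]
  attr(out, "ncc_matrix") <- nccs
  out
}

#' Simulate a synthetic observer
#'
#' Bernoulli deformation reports whose per-condition probability follows the
#' exponential link: `p = clamp(a * exp(b * ncc), 0, 1)`; reports are
#' binomial draws, seeded and reproducible.
#'
#' @param true_a,true_b Generating link parameters.
#' @param nccs Per-condition NCC predictors.
#' @param n_trials Trials per condition.
#' @param seed Integer seed.
#' @param condition Optional condition labels.
#' @return A [psycho_dataset()].
#' @export
simulate_observer <- function(true_a, true_b, nccs, n_trials = 20,
                              seed = 1, condition = NULL) {
  stopifnot(is.finite(true_a), is.finite(true_b), n_trials >= 1,
            all(is.finite(nccs)))
  if (true_a < 0) stop("true_a must be >= 0 for a probability link", call. = FALSE)
  if (is.null(condition)) condition <- seq_along(nccs)
  p <- pmin(pmax(true_a * exp(true_b * nccs), 0), 1)
  reports <- withr::with_seed(seed, stats::rbinom(length(p), n_trials, p))
  psycho_dataset(condition, nccs, n_trials, reports)
}

#' Build a balanced pseudo-randomized trial schedule
#'
#' Every session contains each factor combination exactly `repetitions`
#' times, in an order shuffled independently per session from the run seed,
#' so `total = sessions * prod(levels) * repetitions`.
#'
#' @param factors Named list of factor levels, e.g.
#'   `list(deform_sf = c(0.1, ...))`.
#' @param sessions Number of sessions.
#' @param repetitions Repetitions of each combination per session.
#' @param seed Integer seed for the per-session shuffles.
#' @return A `trial_schedule`: `trials` data frame (session, trial, factor
#'   columns), `total_trials`, and the design.
#' @export
build_trial_schedule <- function(factors, sessions, repetitions, seed = 1) {
  stopifnot(is.list(factors), length(factors) >= 1, sessions >= 1,
            repetitions >= 1)
  if (any(vapply(factors, length, integer(1)) == 0)) {
    stop("every factor needs at least one level", call. = FALSE)
  }
  combos <- expand.grid(factors, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  per_session <- nrow(combos) * repetitions
  trials <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(sessions), function(s) {
      block <- combos[rep(seq_len(nrow(combos)), times = repetitions), ,
                      drop = FALSE]
      block <- block[sample.int(nrow(block)), , drop = FALSE]
      cbind(session = s, trial = seq_len(per_session), block)
    }))
  })
  rownames(trials) <- NULL
  out <- list(trials = trials,
              total_trials = as.integer(sessions * per_session),
              sessions = as.integer(sessions),
              repetitions = as.integer(repetitions),
              factors = factors)
  class(out) <- "trial_schedule"
  out
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d sessions x %s levels x %d reps = %d trials\n",
              x$sessions,
              paste(vapply(x$factors, length, integer(1)), collapse = " x "),
              x$repetitions, x$total_trials))
  invisible(x)
}
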