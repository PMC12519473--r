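#' Model-performance R-squared
#'
#' Squared Pearson correlation between time-averaged observations and the
#' matching model predictions — the performance metric used to judge each
#' sampler series. Undefined (error) when either vector is constant.
#'
#' @param observed per-time mean observed values (length >= 3)
#' @param predicted model predictions at the same times
#' @return R^2 in `[0, 1]`
#' @export
model_r2 <- function(observed, predicted) {
  stop_if(length(observed) != length(predicted), "length mismatch")
  stop_if(length(observed) < 3, "need at least 3 time points")
  stop_if(stats::sd(observed) == 0 || stats::sd(predicted) == 0,
          "R^2 undefined: zero variance")
  stats::cor(observed, predicted)^2
}

#' Log10 sum-of-squares objective
#'
#' Weighted sum of squared differences between log10(obs + eps) and
#' log10(pred + eps). The offset eps guards censored zeros; by default it
#' is half the smallest positive observed value (mirroring the pipeline's
#' censor-to-zero rule), or 1 if no observation is positive.
#'
#' @param observed observed values, >= 0
#' @param predicted predicted values at the same points
#' @param weights scalar or per-point weights
#' @param eps log offset; `NULL` for the default rule
#' @return scalar objective, >= 0
#' @export
objective_sse_log <- function(observed, predicted, weights = 1, eps = NULL) {
  stop_if(any(observed < 0), "negative observation")
  stop_if(length(observed) != length(predicted), "length mismatch")
  if (is.null(eps)) {
    pos <- observed[observed > 0]
    eps <- if (length(pos)) min(pos) / 2 else 1
  }
  sum(weights * (log10(observed + eps) - log10(pmax(predicted, 0) + eps))^2)
}

# Per-(matrix, day) replicate means for one peak/group of a congener table.
series_means <- function(data, peak_id, group, matrices) {
  d <- data[data$peak_id == peak_id & data$group == group &
              data$matrix %in% matrices, , drop = FALSE]
  stop_if(nrow(d) == 0, sprintf("no rows for peak '%s', group '%s'", peak_id, group))
  agg <- stats::aggregate(mass_ng ~ matrix + day, data = d, FUN = mean)
  agg[order(agg$matrix, agg$day), ]
}

# Model observables (PUF ng; SPME apparent ng/cm) at the requested days.
predict_observables <- function(cfg, params, cong, y0, days, tol = 1e-8) {
  system <- assemble_system(cfg, params, cong)
  traj <- rtm_simulate(system, y0, sort(unique(days)), tol = tol)
  b <- bioavailability_factor(params$k_cell, cfg$x_cells)
  idx <- match(days, traj$times)
  data.frame(day = days,
             PUF = traj$states[idx, "m_puf"],
             SPME = apparent_spme_mass(traj$states[idx, "m_spme"],
                                       traj$states[idx, "c_w"], b,
                                       params$alpha_fiber, cfg, params$spme))
}

#' Calibrate reactive-transport parameters against sampler time series
#'
#' Fits a named subset of [rtm_params()] fields to observed PUF and/or
#' SPME time series by bounded multi-start local optimisation (seeded
#' Latin-hypercube starts, `nlminb`). The objective is the (log10 or
#' linear) sum of squared differences between per-day replicate means and
#' the model's sampler observables; the SPME observable includes the
#' cell-fouling observation model when `alpha_fiber > 0`.
#'
#' @param data a congener table (see [read_congener_table()]) holding the
#'   series to fit
#' @param cfg a [microcosm_config()]
#' @param base_params an [rtm_params()]; fields not being fitted keep these
#'   values
#' @param cong the [congener()] whose series is fitted
#' @param y0 initial state (see [initial_state()])
#' @param free named list of `c(lower, upper)` bounds for each free
#'   parameter, e.g. `list(k_bio = c(0, 20))`
#' @param group which group's series to fit, `"control"` or `"treatment"`
#' @param series which observables enter, subset of `c("PUF", "SPME")`
#' @param weights named weights per series (default 1 each)
#' @param objective `"log10-SSE"` (default) or `"linear-SSE"`
#' @param days which sampling days to use; default all days present
#' @param n_starts number of Latin-hypercube starts (>= 1)
#' @param seed integer seed making the start set reproducible
#' @param tol integration tolerance passed to [rtm_simulate()]
#' @return an object of class `rtm_fit` with estimates, bounds-hit flags,
#'   objective value, per-series R^2, convergence diagnostics and enough
#'   context to [predict()] and [plot()] the fitted model
#' @examples
#' \donttest{
#' cong <- default_congeners()[["PCB4"]]
#' cfg <- microcosm_config()
#' truth <- rtm_params(k_bio = 0.5)
#' des <- synth_design(congeners = default_congeners()["PCB4"],
#'                     control_params = rtm_params(),
#'                     treatment_params = truth, noise_cv = c(PUF = 0, SPME = 0),
#'                     seed = 1)
#' tab <- generate_experiment(des)
#' fit <- rtm_fit(tab, cfg, truth, cong, initial_state(cfg, truth, 1000),
#'                free = list(k_bio = c(0, 5)), group = "treatment", seed = 1)
#' coef(fit)
#' }
#' @export
rtm_fit <- function(data, cfg, base_params, cong, y0,
                    free = list(k_bio = c(0, 20)),
                    group = c("treatment", "control"),
                    series = c("PUF", "SPME"),
                    weights = NULL,
                    objective = c("log10-SSE", "linear-SSE"),
                    days = NULL, n_starts = 8, seed = 1, tol = 1e-8) {
  group <- match.arg(group)
  objective <- match.arg(objective)
  series <- match.arg(series, c("PUF", "SPME"), several.ok = TRUE)
  stop_if(length(free) < 1, "at least one free parameter required")
  lower <- vapply(free, `[`, numeric(1), 1)
  upper <- vapply(free, `[`, numeric(1), 2)
  stop_if(any(!is.finite(lower)) || any(!is.finite(upper)) ||
            any(lower >= upper), "bounds must be finite with lower < upper")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(series)), series)

  obs <- series_means(data, cong$peak_id, group, series)
  if (!is.null(days)) obs <- obs[obs$day %in% days, , drop = FALSE]
  stop_if(nrow(obs) < length(free),
          "fewer informative points than free parameters")
  eps_by_series <- vapply(series, function(m) {
    pos <- obs$mass_ng[obs$matrix == m & obs$mass_ng > 0]
    if (length(pos)) min(pos) / 2 else 1
  }, numeric(1))

  obj_fun <- function(theta) {
    p <- tryCatch(set_params(base_params, as.list(stats::setNames(theta, names(free)))),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    # predict once over the union of days, then pick per series
    pred_all <- tryCatch(predict_observables(cfg, p, cong, y0,
                                             sort(unique(obs$day)), tol = tol),
                         error = function(e) NULL)
    if (is.null(pred_all)) return(1e10)
    total <- 0
    for (m in series) {
      o <- obs[obs$matrix == m, ]
      pr <- pred_all[[m]][match(o$day, pred_all$day)]
      total <- total + if (objective == "log10-SSE")
        objective_sse_log(o$mass_ng, pr, weights[[m]], eps_by_series[[m]])
      else sum(weights[[m]] * (o$mass_ng - pr)^2)
    }
    if (!is.finite(total)) 1e10 else total
  }

  k <- length(free)
  set.seed(seed)
  starts <- lhs::randomLHS(max(n_starts, 1), k)
  starts <- sweep(sweep(starts, 2, upper - lower, `*`), 2, lower, `+`)
  # screen all starts by a single objective evaluation, then refine the most
  # promising half with bounded local optimisation; the finite-difference
  # step is scaled to the parameter range so integrator noise in the
  # objective does not corrupt the numerical gradient
  start_obj <- apply(starts, 1, obj_fun)
  n_refine <- max(2, ceiling(nrow(starts) / 2))
  refine <- order(start_obj)[seq_len(min(n_refine, nrow(starts)))]
  fd_step <- pmax(1e-4 * (upper - lower), 1e-8)
  fits <- vector("list", length(refine))
  for (i in seq_along(refine)) {
    fits[[i]] <- tryCatch(
      stats::optim(starts[refine[i], ], obj_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(ndeps = fd_step, factr = 1e7)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  stop_if(!any(ok), "all optimisation starts failed")
  objs <- vapply(fits[ok], `[[`, numeric(1), "value")
  best <- fits[ok][[which.min(objs)]]
  est <- stats::setNames(best$par, names(free))

  p_hat <- set_params(base_params, as.list(est))
  pred_all <- predict_observables(cfg, p_hat, cong, y0, sort(unique(obs$day)),
                                  tol = tol)
  r2 <- sapply(series, function(m) {
    o <- obs[obs$matrix == m, ]
    pr <- pred_all[[m]][match(o$day, pred_all$day)]
    if (length(o$mass_ng) >= 3 && stats::sd(o$mass_ng) > 0 && stats::sd(pr) > 0)
      model_r2(o$mass_ng, pr) else NA_real_
  })
  span <- upper - lower
  structure(list(estimates = est, lower = lower, upper = upper,
                 bounds_hit = (est - lower < 1e-8 * span) |
                              (upper - est < 1e-8 * span),
                 objective = best$value, objective_type = objective,
                 r2 = r2, convergence = best$convergence,
                 message = best$message, n_starts = n_starts, seed = seed,
                 observed = obs, predicted = pred_all,
                 eps = eps_by_series, weights = weights, group = group,
                 series = series, config = cfg, params = p_hat,
                 base_params = base_params, congener = cong, y0 = y0,
                 tol = tol),
            class = "rtm_fit")
}

#' @export
print.rtm_fit <- function(x, ...) {
  cat(sprintf("<rtm_fit> %s, %s group, %s regime\n", x$congener$peak_id,
              x$group, x$config$regime))
  cat("estimates:\n")
  print(signif(x$estimates, 4))
  cat(sprintf("objective (%s): %.6g | converged: %s\n", x$objective_type,
              x$objective, x$convergence == 0))
  invisible(x)
}

#' @export
summary.rtm_fit <- function(object, ...) {
  x <- object
  cat(sprintf("Calibrated reactive-transport fit: %s (%d Cl), %s group, %s microcosm\n",
              x$congener$peak_id, x$congener$n_cl, x$group, x$config$regime))
  est <- data.frame(estimate = x$estimates, lower = x$lower, upper = x$upper,
                    at_bound = x$bounds_hit)
  print(signif_df(est, 4))
  cat(sprintf("\nObjective (%s): %.6g over %d mean observations\n",
              x$objective_type, x$objective, nrow(x$observed)))
  for (m in x$series)
    cat(sprintf("  R^2 (%s): %s\n", m,
                if (is.na(x$r2[[m]])) "undefined" else sprintf("%.3f", x$r2[[m]])))
  cat(sprintf("Multi-start: %d Latin-hypercube starts, seed %d; convergence code %d\n",
              x$n_starts, x$seed, x$convergence))
  invisible(x)
}

signif_df <- function(df, digits) {
  for (i in seq_along(df)) if (is.numeric(df[[i]])) df[[i]] <- signif(df[[i]], digits)
  df
}

#' @export
coef.rtm_fit <- function(object, ...) object$estimates

#' Predict sampler observables or a full trajectory from a fitted model
#'
#' @param object an `rtm_fit`
#' @param times days at which to predict; default the fitted days
#' @param what `"observables"` for PUF/apparent-SPME masses,
#'   `"trajectory"` for the full compartment trajectory
#' @param ... ignored
#' @return a data.frame of observables, or an `rtm_trajectory`
#' @export
predict.rtm_fit <- function(object, times = NULL,
                            what = c("observables", "trajectory"), ...) {
  what <- match.arg(what)
  if (is.null(times)) times <- sort(unique(object$observed$day))
  if (what == "observables")
    predict_observables(object$config, object$params, object$congener,
                        object$y0, times, tol = object$tol)
  else
    rtm_simulate(assemble_system(object$config, object$params, object$congener),
                 object$y0, times, tol = object$tol)
}

#' @export
residuals.rtm_fit <- function(object, type = c("log10", "linear"), ...) {
  type <- match.arg(type)
  obs <- object$observed
  res <- numeric(nrow(obs))
  for (m in object$series) {
    i <- obs$matrix == m
    pr <- object$predicted[[m]][match(obs$day[i], object$predicted$day)]
    res[i] <- if (type == "log10")
      log10(obs$mass_ng[i] + object$eps[[m]]) - log10(pmax(pr, 0) + object$eps[[m]])
    else obs$mass_ng[i] - pr
  }
  stats::setNames(res, paste(obs$matrix, obs$day, sep = "_d"))
}

#' @export
plot.rtm_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$series)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in x$series) {
    o <- x$observed[x$observed$matrix == m, ]
    pr <- x$predicted[[m]][match(o$day, x$predicted$day)]
    ylim <- range(c(o$mass_ng, pr), na.rm = TRUE)
    graphics::plot(o$day, o$mass_ng, pch = 19, xlab = "day",
                   ylab = if (m == "PUF") "ng per PUF" else "ng per cm fiber",
                   main = sprintf("%s %s", x$congener$peak_id, m), ylim = ylim, ...)
    graphics::lines(x$predicted$day, x$predicted[[m]], col = "steelblue")
  }
  invisible(x)
}

#' Simulate replicate sampler tables from a fitted model
#'
#' Draws `nsim` synthetic triplicate congener tables from the fitted
#' parameters with mean-preserving lognormal replicate noise — the same
#' observation model the synthetic-experiment generator uses.
#'
#' @param object an `rtm_fit`
#' @param nsim number of tables
#' @param seed integer seed
#' @param noise_cv named noise CVs per matrix
#' @param n_replicates replicates per day
#' @param ... ignored
#' @return a list of congener tables (data.frames)
#' @export
simulate.rtm_fit <- function(object, nsim = 1, seed = NULL,
                             noise_cv = c(PUF = 0.25, SPME = 0.35),
                             n_replicates = 3, ...) {
  if (!is.null(seed)) set.seed(seed)
  days <- sort(unique(object$observed$day))
  pred <- predict_observables(object$config, object$params, object$congener,
                              object$y0, days, tol = object$tol)
  lapply(seq_len(nsim), function(s) {
    rows <- list()
    for (m in object$series) for (j in seq_along(days)) {
      mu <- pred[[m]][j]
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = "simulated", day = days[j],
        replicate = seq_len(n_replicates), group = object$group, matrix = m,
        peak_id = object$congener$peak_id,
        mass_ng = mu * rlnorm_mean1(n_replicates, noise_cv[[m]]))
    }
    do.call(rbind, rows)
  })
}

#' Fit selected parameters (functional alias of [rtm_fit()])
#'
#' @inheritParams rtm_fit
#' @param ... passed to [rtm_fit()]
#' @return an `rtm_fit`
#' @export
fit_parameters <- function(data, cfg, base_params, cong, y0, ...) {
  rtm_fit(data, cfg, base_params, cong, y0, ...)
}
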