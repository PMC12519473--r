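# Mean-preserving multiplicative lognormal noise: E[factor] = 1, CV = cv.
rlnorm_mean1 <- function(n, cv) {
  check_num(cv, "cv", 0)
  stop_if(cv >= 2, "noise_cv must be < 2")
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Design of a synthetic microcosm experiment
#'
#' Bundles everything needed to emulate one bioaugmentation experiment:
#' the mixing regime and geometry, per-group true parameters, the sediment
#' inventory per congener, sacrificial-sampling days, replicate count and
#' replicate noise. Scenario presets reproduce the three study designs:
#' a shaken freshwater-sediment experiment (`"AVL_S"`, sampled days
#' 3/11/16/35, sediment 6350 ng/g at 51% lower-chlorinated), and two
#' nonshaken experiments (`"AVL_NS"` same sediment, `"NBH_NS"` estuarine
#' sediment at 59000 ng/g, 44% LC), both sampled days 16/35/75.
#'
#' @param scenario `"AVL_S"`, `"AVL_NS"` or `"NBH_NS"`
#' @param congeners named list of [congener()] objects
#' @param config base [microcosm_config()] (cell dose is applied per
#'   group); default derived from the scenario regime
#' @param control_params,treatment_params true [rtm_params()] per group;
#'   defaults: native control activity 0.2 1/d, bioaugmented 17 1/d
#'   (shaken) or 0.5 1/d (nonshaken) with cell sorption (k_cell = 8 L/g)
#'   and, nonshaken, fiber fouling (alpha_fiber = 0.25)
#' @param x_cells_treatment cell dose in the treatment liquid, g/L
#' @param sed_conc named initial sediment concentrations, ng/g; default
#'   splits the scenario's total inventory over the congener list, LC
#'   share first
#' @param sampling_days sacrificial sampling days
#' @param n_replicates replicates per day (>= 2; experiments used 3)
#' @param noise_cv named multiplicative lognormal CV per matrix
#' @param seed integer seed
#' @return an object of class `synth_design`
#' @export
synth_design <- function(scenario = c("AVL_S", "AVL_NS", "NBH_NS"),
                         congeners = default_congeners(),
                         config = NULL,
                         control_params = NULL, treatment_params = NULL,
                         x_cells_treatment = 0.5,
                         sed_conc = NULL,
                         sampling_days = NULL,
                         n_replicates = 3,
                         noise_cv = c(PUF = 0.25, SPME = 0.35),
                         seed = 1) {
  scenario <- match.arg(scenario)
  shaken <- scenario == "AVL_S"
  if (is.null(config))
    config <- microcosm_config(regime = if (shaken) "shaken" else "nonshaken")
  if (is.null(sampling_days))
    sampling_days <- if (shaken) c(3, 11, 16, 35) else c(16, 35, 75)
  if (is.null(control_params))
    control_params <- rtm_params(k_bio = 0.2)
  if (is.null(treatment_params))
    treatment_params <- rtm_params(k_bio = if (shaken) 17 else 0.5,
                                   k_cell = 8,
                                   alpha_fiber = if (shaken) 0 else 0.25)
  if (is.null(sed_conc)) {
    tot <- if (scenario == "NBH_NS") 59000 else 6350
    lc_frac <- if (scenario == "NBH_NS") 0.44 else 0.51
    lc_ids <- names(congeners)[vapply(congeners, is_lc, logical(1))]
    hc_ids <- setdiff(names(congeners), lc_ids)
    sed_conc <- stats::setNames(numeric(length(congeners)), names(congeners))
    if (length(lc_ids)) sed_conc[lc_ids] <- tot * lc_frac / length(lc_ids)
    if (length(hc_ids)) sed_conc[hc_ids] <- tot * (1 - lc_frac) / length(hc_ids)
  }
  stop_if(n_replicates < 2, "n_replicates must be >= 2")
  stop_if(any(noise_cv < 0) || any(noise_cv >= 2), "noise_cv must be in [0, 2)")
  stop_if(!all(c("PUF", "SPME") %in% names(noise_cv)),
          "noise_cv needs entries for PUF and SPME")
  stop_if(!all(names(congeners) %in% names(sed_conc)),
          "sed_conc must cover every congener")
  structure(list(scenario = scenario, congeners = congeners, config = config,
                 control_params = control_params,
                 treatment_params = treatment_params,
                 x_cells_treatment = x_cells_treatment, sed_conc = sed_conc,
                 sampling_days = sampling_days, n_replicates = n_replicates,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synth_design")
}

#' @export
print.synth_design <- function(x, ...) {
  cat(sprintf("<synth_design> %s (%s), %d congeners, days {%s}, %d replicates, noise CV PUF %.2f / SPME %.2f, seed %d\n",
              x$scenario, x$config$regime, length(x$congeners),
              paste(x$sampling_days, collapse = ","), x$n_replicates,
              x$noise_cv[["PUF"]], x$noise_cv[["SPME"]], x$seed))
  invisible(x)
}

#' Generate a complete synthetic experiment
#'
#' Simulates the reactive-transport model for each group and congener of a
#' [synth_design()], reads the PUF mass and the apparent (fouling-aware)
#' SPME mass at the sacrificial sampling days, and draws triplicate
#' replicate values with mean-preserving multiplicative lognormal noise.
#' Deterministic given the design seed. The noiseless truth (per-group
#' parameters and sampler means) is attached as attribute `"truth"` so
#' recovery tests need no side files.
#'
#' @param design a [synth_design()]
#' @param tol integration tolerance
#' @return a congener table (see [read_congener_table()]) with attribute
#'   `"truth"`
#' @export
generate_experiment <- function(design, tol = 1e-8) {
  stop_if(!inherits(design, "synth_design"), "design must be a synth_design")
  set.seed(design$seed)
  rows <- list()
  truth <- list(control = list(params = design$control_params),
                treatment = list(params = design$treatment_params))
  for (grp in c("control", "treatment")) {
    p <- truth[[grp]]$params
    cfg <- design$config
    cfg$x_cells <- if (grp == "treatment") design$x_cells_treatment else 0
    means <- list()
    for (id in names(design$congeners)) {
      cong <- design$congeners[[id]]
      y0 <- initial_state(cfg, p, sed_conc = design$sed_conc[[id]])
      obs <- predict_observables(cfg, p, cong, y0, design$sampling_days,
                                 tol = tol)
      means[[id]] <- obs
      for (m in c("PUF", "SPME")) for (j in seq_along(design$sampling_days)) {
        mu <- obs[[m]][j]
        rows[[length(rows) + 1L]] <- data.frame(
          experiment_id = design$scenario,
          day = design$sampling_days[j],
          replicate = seq_len(design$n_replicates),
          group = grp, matrix = m, peak_id = id,
          mass_ng = mu * rlnorm_mean1(design$n_replicates,
                                      design$noise_cv[[m]]))
      }
    }
    truth[[grp]]$means <- means
    truth[[grp]]$x_cells <- cfg$x_cells
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "truth") <- truth
  validate_congener_table(tab)
}

#' Generate a laboratory blank set
#'
#' Per-peak blank masses drawn as `level` times mean-preserving lognormal
#' noise, emulating the blank sets used to compute limits of
#' quantification (n = 19 PUF, n = 3 SPME in the experiments).
#'
#' @param matrix `"PUF"` or `"SPME"`
#' @param n number of blanks (>= 2)
#' @param level mean blank mass, ng (scalar or named per peak)
#' @param cv blank coefficient of variation
#' @param seed integer seed
#' @param peaks character vector of peak ids
#' @return a [blank_set()]
#' @export
generate_blanks <- function(matrix = c("PUF", "SPME"), n = 19, level = 1,
                            cv = 0.3, seed = 1,
                            peaks = names(default_congeners())) {
  matrix <- match.arg(matrix)
  stop_if(n < 2, "n must be >= 2")
  set.seed(as.integer(seed))
  lev <- if (length(level) == 1) stats::setNames(rep(level, length(peaks)), peaks)
         else level[peaks]
  masses <- lapply(peaks, function(pk) lev[[pk]] * rlnorm_mean1(n, cv))
  names(masses) <- peaks
  blank_set(matrix, masses)
}

#' Generate surrogate recoveries per homologue
#'
#' Truncated-normal recovery draws per homologue group, emulating the
#' labelled-surrogate recoveries used for homologue-wise mass correction
#' (reported means spanned roughly 0.64 to 0.92 with SDs near 0.15).
#'
#' @param homologues integer chlorine counts needing a recovery
#' @param mean_by_homologue named mean recovery per homologue (fractions in
#'   (0, 1.5]); scalar recycled; default 0.8
#' @param sd recovery standard deviation (>= 0)
#' @param seed integer seed
#' @param truncation `c(lower, upper)` open/closed truncation bounds,
#'   default (0, 1.5]
#' @return a data.frame with columns `homologue`, `recovery`
#' @export
generate_recoveries <- function(homologues, mean_by_homologue = 0.8,
                                sd = 0.14, seed = 1,
                                truncation = c(0, 1.5)) {
  stop_if(sd < 0, "sd must be >= 0")
  mh <- if (length(mean_by_homologue) == 1)
    stats::setNames(rep(mean_by_homologue, length(homologues)),
                    as.character(homologues))
  else mean_by_homologue[as.character(homologues)]
  stop_if(anyNA(mh) || any(mh <= 0) || any(mh > 1.5),
          "mean recoveries must be in (0, 1.5]")
  set.seed(as.integer(seed))
  rec <- vapply(mh, function(mu) {
    if (sd == 0) return(mu)
    for (i in 1:10000) {
      r <- stats::rnorm(1, mu, sd)
      if (r > truncation[1] && r <= truncation[2]) return(r)
    }
    stop("truncated-normal rejection sampling failed", call. = FALSE)
  }, numeric(1))
  data.frame(homologue = as.integer(homologues), recovery = unname(rec))
}
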