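#' Bioavailability factor for cell-sorbed aqueous PCB
#'
#' With degrader cells suspended in the liquid phase, part of the aqueous
#' PCB pool sorbs to cell biomass via a linear isotherm. The freely
#' dissolved fraction of the TOTAL aqueous concentration is
#' B = 1 / (1 + k_cell * x_cells); air exchange, SPME uptake, sediment
#' exchange and biodegradation all act on B*c_w.
#'
#' @param k_cell cell-water partition coefficient, L/g dry cells
#' @param x_cells suspended cell concentration, g/L
#' @return B in (0, 1]; equals 1 when no cells are present
#' @examples
#' bioavailability_factor(4, 1)  # 0.2
#' @export
bioavailability_factor <- function(k_cell, x_cells) {
  check_num(k_cell, "k_cell", 0)
  check_num(x_cells, "x_cells", 0)
  1 / (1 + k_cell * x_cells)
}

state_names <- function(cfg, params) {
  if (cfg$regime == "shaken")
    c("s_fast", "s_slow", "c_w", "c_a", "m_puf", "m_spme", "m_degraded")
  else
    c(paste0("c_shell", seq_len(params$particle$n_shells)),
      "c_pw", "c_w", "c_a", "m_puf", "m_spme", "m_degraded")
}

#' Assemble the shaken-microcosm ODE system
#'
#' Builds the per-congener right-hand side for a well-mixed (shaken) flask:
#' two-site fast/slow linear-driving-force exchange between sorbed sediment
#' and the freely dissolved phase, a two-film air-water exchange term,
#' first-order biodegradation of the freely dissolved pool, and both
#' passive-sampler uptake equations. Every term is reconciled to ng/d.
#'
#' State order: `s_fast`, `s_slow` (ng/g), `c_w`, `c_a` (ng/L), `m_puf`
#' (ng), `m_spme` (ng/cm), `m_degraded` (ng).
#'
#' @param cfg a [microcosm_config()] with `regime = "shaken"`
#' @param params an [rtm_params()]
#' @param cong a [congener()]
#' @return a rate function `function(t, y, parms)` in [deSolve] form, with
#'   attributes `cfg`, `params`, `congener`, `state_names`
#' @export
assemble_shaken_system <- function(cfg, params, cong) {
  stop_if(cfg$regime != "shaken",
          "config is nonshaken; use assemble_nonshaken_system()")
  stop_if(!inherits(cong, "congener"), "cong must be a congener")
  b <- bioavailability_factor(params$k_cell, cfg$x_cells)
  kd_g <- kd_l_per_g(cong$k_d)
  ex_aw <- exchange_l_per_d(params$v_aw, params$a_aw)
  puf <- params$puf; spme <- params$spme
  ex_puf <- exchange_l_per_d(puf$k_puf, puf$a_face)
  cap_puf <- puf$v_puf * puf$k_puf_a
  m_eq_spme <- spme$k_fw * spme$v_coat_per_cm
  fib_len <- spme$fiber_length_total
  f_fast <- params$f_fast; f_avail <- params$f_avail
  k_fast <- params$k_fast; k_slow <- params$k_slow
  k_bio <- params$k_bio; k_h <- cong$k_h
  m_sed <- cfg$m_sed; v_w <- cfg$v_w; v_a <- cfg$v_a

  rhs <- function(t, y, parms) {
    c_free <- b * y[3L]
    ds_f <- -k_fast * (y[1L] - f_fast * f_avail * kd_g * c_free)
    ds_s <- -k_slow * (y[2L] - (1 - f_fast) * f_avail * kd_g * c_free)
    aw_flux <- ex_aw * (c_free - y[4L] / k_h)             # ng/d, water -> air
    deg <- k_bio * c_free * v_w                           # ng/d
    spme_rate <- spme$k_sp * (m_eq_spme * c_free - y[6L]) # (ng/cm)/d
    puf_rate <- ex_puf * (y[4L] - y[5L] / cap_puf)        # ng/d
    dc_w <- (-m_sed * (ds_f + ds_s) - aw_flux - deg - fib_len * spme_rate) / v_w
    dc_a <- (aw_flux - puf_rate) / v_a
    list(c(ds_f, ds_s, dc_w, dc_a, puf_rate, spme_rate, deg))
  }
  structure(rhs, cfg = cfg, params = params, congener = cong,
            state_names = state_names(cfg, params), b = b)
}

#' Assemble the nonshaken-microcosm ODE system
#'
#' Builds the per-congener right-hand side for a quiescent flask with a
#' settled sediment bed: intraparticle radial diffusion (finite-volume
#' shells, surface Dirichlet at the porewater concentration) releases PCB
#' to porewater; porewater exchanges with the overlying water across a
#' liquid boundary-layer film, k_bl * a_int * (c_pw - B*c_w); overlying
#' water exchanges with the headspace, is degraded (freely dissolved pool
#' only — cells sit in the overlying water, so porewater carries no cell
#' sorption), and feeds the SPME fiber; the PUF samples the headspace.
#'
#' State order: `c_shell1..n` (ng/L, innermost first), `c_pw`, `c_w`, `c_a`
#' (ng/L), `m_puf` (ng), `m_spme` (ng/cm), `m_degraded` (ng).
#'
#' @inheritParams assemble_shaken_system
#' @param cfg a [microcosm_config()] with `regime = "nonshaken"`
#' @return a rate function in [deSolve] form (see
#'   [assemble_shaken_system()] for attributes)
#' @export
assemble_nonshaken_system <- function(cfg, params, cong) {
  stop_if(cfg$regime != "nonshaken",
          "config is shaken; use assemble_shaken_system()")
  stop_if(!inherits(cong, "congener"), "cong must be a congener")
  grid <- params$particle
  stop_if(grid$n_shells < 3L, "particle grid needs at least 3 shells")
  n <- grid$n_shells
  geom <- build_grid(grid)
  b <- bioavailability_factor(params$k_cell, cfg$x_cells)
  ex_aw <- exchange_l_per_d(params$v_aw, params$a_aw)
  ex_bl <- exchange_l_per_d(params$k_bl, params$a_int)
  puf <- params$puf; spme <- params$spme
  ex_puf <- exchange_l_per_d(puf$k_puf, puf$a_face)
  cap_puf <- puf$v_puf * puf$k_puf_a
  m_eq_spme <- spme$k_fw * spme$v_coat_per_cm
  fib_len <- spme$fiber_length_total
  k_bio <- params$k_bio; k_h <- cong$k_h
  v_w <- cfg$v_w; v_a <- cfg$v_a; v_pw <- cfg$v_pw
  d_app <- grid$d_eff / grid$retardation
  dr_int <- diff(geom$r_center)
  dr_surf <- geom$r_edge[n + 1] - geom$r_center[n]
  a_int_edges <- geom$area[2:n]
  a_surf <- geom$area[n + 1]
  vol <- geom$volume
  n_part <- grid$n_particles_equiv
  flux_scale <- grid$porosity * grid$d_eff * a_surf / 1000  # ng/d per (ng/L/cm)

  i_pw <- n + 1L; i_w <- n + 2L; i_a <- n + 3L
  i_puf <- n + 4L; i_spme <- n + 5L

  rhs <- function(t, y, parms) {
    c_sh <- y[1:n]
    grad_surf <- (y[i_pw] - c_sh[n]) / dr_surf
    flux_edge <- c(0, d_app * a_int_edges * diff(c_sh) / dr_int,
                   d_app * a_surf * grad_surf)
    dc_sh <- (flux_edge[-1] - flux_edge[-(n + 1)]) / vol
    release <- -n_part * flux_scale * grad_surf        # ng/d, bed -> porewater
    c_free <- b * y[i_w]
    bed_flux <- ex_bl * (y[i_pw] - c_free)             # ng/d, porewater -> water
    aw_flux <- ex_aw * (c_free - y[i_a] / k_h)
    deg <- k_bio * c_free * v_w
    spme_rate <- spme$k_sp * (m_eq_spme * c_free - y[i_spme])
    puf_rate <- ex_puf * (y[i_a] - y[i_puf] / cap_puf)
    dc_pw <- (release - bed_flux) / v_pw
    dc_w <- (bed_flux - aw_flux - deg - fib_len * spme_rate) / v_w
    dc_a <- (aw_flux - puf_rate) / v_a
    list(c(dc_sh, dc_pw, dc_w, dc_a, puf_rate, spme_rate, deg))
  }
  structure(rhs, cfg = cfg, params = params, congener = cong,
            state_names = state_names(cfg, params), b = b, geom = geom)
}

#' Assemble the ODE system for any mixing regime
#' @inheritParams assemble_shaken_system
#' @return a rate function (see [assemble_shaken_system()])
#' @export
assemble_system <- function(cfg, params, cong) {
  if (cfg$regime == "shaken") assemble_shaken_system(cfg, params, cong)
  else assemble_nonshaken_system(cfg, params, cong)
}

#' Initial state vector for a microcosm run
#'
#' Places the PCB inventory where the experiment starts it: sorbed to
#' sediment. For shaken flasks the sorbed inventory is split between the
#' fast and slow sites by `f_fast`; for nonshaken flasks it is spread
#' uniformly through the particle shells (pore + sorbed, via retardation).
#' Water, headspace and samplers start clean unless stated.
#'
#' @param cfg a [microcosm_config()]
#' @param params an [rtm_params()]
#' @param sed_conc initial sediment concentration, ng/g dry sediment
#' @param c_w,c_a optional initial aqueous/headspace concentrations, ng/L
#' @return a named state vector understood by the assembled systems
#' @export
initial_state <- function(cfg, params, sed_conc = 0, c_w = 0, c_a = 0) {
  check_num(sed_conc, "sed_conc", 0)
  nm <- state_names(cfg, params)
  y <- stats::setNames(numeric(length(nm)), nm)
  y["c_w"] <- c_w; y["c_a"] <- c_a
  if (cfg$regime == "shaken") {
    y["s_fast"] <- params$f_fast * sed_conc
    y["s_slow"] <- (1 - params$f_fast) * sed_conc
  } else {
    grid <- params$particle
    v_tot_l <- 4 / 3 * pi * grid$radius^3 / 1000
    cap <- grid$retardation * grid$porosity * v_tot_l * grid$n_particles_equiv
    y[seq_len(grid$n_shells)] <- sed_conc * cfg$m_sed / cap
  }
  y
}

#' Integrate an assembled microcosm system
#'
#' Stiff-capable integration (lsoda) of a rate function built by
#' [assemble_system()]. Small negative values produced by the integrator
#' (magnitude below `10 * tol * scale`, where scale is the largest state
#' magnitude seen) are clipped to zero; larger negatives abort with the
#' last good time in the message.
#'
#' @param system a rate function from [assemble_shaken_system()],
#'   [assemble_nonshaken_system()] or [assemble_system()]
#' @param y0 named initial state (see [initial_state()])
#' @param times strictly increasing output times, d (0 is prepended if
#'   absent)
#' @param tol relative integration tolerance (also scales the absolute
#'   tolerance)
#' @return an object of class `rtm_trajectory`: a list with `times`,
#'   `states` (time x state matrix), `congener`, `config`, `params`
#' @export
rtm_simulate <- function(system, y0, times, tol = 1e-8) {
  stop_if(is.unsorted(times, strictly = TRUE), "times must be strictly increasing")
  stop_if(any(y0 < 0), "y0 must be non-negative")
  nm <- attr(system, "state_names")
  stop_if(length(y0) != length(nm), "y0 has wrong length for this system")
  t_out <- if (times[1] > 0) c(0, times) else times
  scale <- max(abs(y0), 1)
  sol <- deSolve::lsoda(y = stats::setNames(as.numeric(y0), nm),
                        times = t_out, func = system, parms = NULL,
                        rtol = tol, atol = tol * scale * 1e-3)
  istate <- attr(sol, "istate")[1]
  if (is.null(istate)) istate <- 2L
  stop_if(istate < 0 || nrow(sol) < length(t_out),
          sprintf("integrator failed after t = %.6g d",
                  sol[nrow(sol), 1]))
  states <- sol[, -1, drop = FALSE]
  big <- max(abs(states))
  neg_floor <- -10 * tol * max(big, scale)
  if (min(states) < neg_floor) {
    bad_row <- which(states == min(states), arr.ind = TRUE)[1, 1]
    stop(sprintf("state went negative beyond tolerance (min %.3g) near t = %.6g d",
                 min(states), t_out[bad_row]), call. = FALSE)
  }
  states[states < 0] <- 0
  keep <- match(times, t_out)
  structure(list(times = times,
                 states = states[keep, , drop = FALSE],
                 congener = attr(system, "congener"),
                 config = attr(system, "cfg"),
                 params = attr(system, "params")),
            class = "rtm_trajectory")
}

#' Closed-form equilibrium distribution of a conservative system
#'
#' With biodegradation off, the sealed flask relaxes to a partitioning
#' equilibrium in which every available phase is in linear equilibrium with
#' the freely dissolved concentration c_free: sorbed sediment at
#' f_avail*Kd*c_free, headspace at Kh*c_free, porewater and particle pores
#' at c_free, PUF and SPME at their partition capacities. The total mass is
#' distributed over these capacities exactly.
#'
#' @inheritParams assemble_shaken_system
#' @param total_mass total PCB inventory to distribute, ng
#' @return a named state vector summing (via [total_mass()]) to
#'   `total_mass` exactly
#' @export
equilibrium_state <- function(cfg, params, cong, total_mass) {
  stop_if(params$k_bio != 0, "equilibrium_state requires k_bio = 0")
  check_num(total_mass, "total_mass", 0)
  b <- bioavailability_factor(params$k_cell, cfg$x_cells)
  kd_g <- kd_l_per_g(cong$k_d)
  puf <- params$puf; spme <- params$spme
  cap_w <- cfg$v_w / b                            # total aqueous per unit c_free
  cap_a <- cong$k_h * cfg$v_a
  cap_puf <- puf$v_puf * puf$k_puf_a * cong$k_h
  cap_spme <- spme$k_fw * spme$v_coat_per_cm * spme$fiber_length_total
  if (cfg$regime == "shaken") {
    cap_sed <- params$f_avail * kd_g * cfg$m_sed
    cap_bed <- 0
  } else {
    grid <- params$particle
    v_tot_l <- 4 / 3 * pi * grid$radius^3 / 1000
    cap_sed <- grid$retardation * grid$porosity * v_tot_l * grid$n_particles_equiv
    cap_bed <- cfg$v_pw
  }
  cap_total <- cap_w + cap_a + cap_puf + cap_spme + cap_sed + cap_bed
  stop_if(cap_total <= 0, "all phase capacities are zero")
  c_free <- total_mass / cap_total
  y <- initial_state(cfg, params)
  y["c_w"] <- c_free / b
  y["c_a"] <- cong$k_h * c_free
  y["m_puf"] <- puf$v_puf * puf$k_puf_a * y["c_a"]
  y["m_spme"] <- spme$k_fw * spme$v_coat_per_cm * c_free
  if (cfg$regime == "shaken") {
    y["s_fast"] <- params$f_fast * params$f_avail * kd_g * c_free
    y["s_slow"] <- (1 - params$f_fast) * params$f_avail * kd_g * c_free
  } else {
    y[seq_len(params$particle$n_shells)] <- c_free
    y["c_pw"] <- c_free
  }
  y
}

#' Total PCB mass in a microcosm state
#'
#' Sums mass (ng) over every compartment — sorbed sediment (or particle
#' shells and porewater), water, headspace, both samplers — plus the
#' cumulative degraded mass, so the sum is a conserved quantity along any
#' trajectory.
#'
#' @param state named state vector or one row of a trajectory's `states`
#' @param cfg a [microcosm_config()]
#' @param params an [rtm_params()]
#' @return total mass, ng
#' @export
total_mass <- function(state, cfg, params) {
  spme <- params$spme
  common <- state[["c_w"]] * cfg$v_w + state[["c_a"]] * cfg$v_a +
    state[["m_puf"]] + state[["m_spme"]] * spme$fiber_length_total +
    state[["m_degraded"]]
  if (cfg$regime == "shaken") {
    common + (state[["s_fast"]] + state[["s_slow"]]) * cfg$m_sed
  } else {
    grid <- params$particle
    common + state[["c_pw"]] * cfg$v_pw +
      particle_mass(grid, state[seq_len(grid$n_shells)])
  }
}

#' @export
print.rtm_trajectory <- function(x, ...) {
  cat(sprintf("<rtm_trajectory> %s, %s regime, %d time points over %.3g d, %d state variables\n",
              x$congener$peak_id, x$config$regime, length(x$times),
              max(x$times), ncol(x$states)))
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x an `rtm_trajectory`
#' @param row.names,optional,... ignored (method signature)
#' @return a data.frame with columns `time` (d), `compartment`, `value`,
#'   `units`
#' @export
as.data.frame.rtm_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  nm <- colnames(x$states)
  units <- ifelse(grepl("^c_", nm), "ng/L",
           ifelse(nm %in% c("s_fast", "s_slow"), "ng/g",
           ifelse(nm == "m_spme", "ng/cm", "ng")))
  data.frame(time = rep(x$times, times = length(nm)),
             compartment = rep(nm, each = length(x$times)),
             value = as.vector(x$states),
             units = rep(units, each = length(x$times)))
}

#' Write a trajectory as tidy CSV
#' @param x an `rtm_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
plot.rtm_trajectory <- function(x, compartments = c("c_w", "c_a", "m_puf", "m_spme"),
                                log = "", ...) {
  nm <- intersect(compartments, colnames(x$states))
  old <- graphics::par(mfrow = c(2, ceiling(length(nm) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cc in nm)
    graphics::plot(x$times, x$states[, cc], type = "l", xlab = "time (d)",
                   ylab = cc, main = cc, log = log, ...)
  invisible(x)
}
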