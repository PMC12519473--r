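#' Microcosm configuration
#'
#' Geometry and phase inventory of one sealed sediment microcosm flask.
#' Defaults reproduce the experimental setup: 10 g dry sediment and 100 mL
#' of mineral medium (a 1:10 sediment:liquid ratio) in a 250 mL Erlenmeyer
#' flask, leaving roughly 150 mL of headspace.
#'
#' @param m_sed dry sediment mass, g (default 10)
#' @param v_w liquid volume, L (default 0.1)
#' @param v_a headspace volume, L (default 0.15)
#' @param regime mixing regime, `"shaken"` or `"nonshaken"`
#' @param x_cells suspended degrader-cell concentration in the liquid, g/L
#'   dry weight (0 for non-bioaugmented controls)
#' @param v_pw bed porewater volume, L (nonshaken only; default 0.004 L,
#'   i.e. 10 g sediment at particle density 2.5 g/cm3 and bed porosity 0.5)
#' @param temp_note free-text metadata (not used in any computation)
#' @return an object of class `microcosm_config`
#' @export
microcosm_config <- function(m_sed = 10, v_w = 0.1, v_a = 0.15,
                             regime = c("shaken", "nonshaken"),
                             x_cells = 0, v_pw = 0.004, temp_note = "") {
  regime <- match.arg(regime)
  check_num(m_sed, "m_sed", 0, allow_zero_lower = FALSE)
  check_num(v_w, "v_w", 0, allow_zero_lower = FALSE)
  check_num(v_a, "v_a", 0, allow_zero_lower = FALSE)
  check_num(v_pw, "v_pw", 0, allow_zero_lower = FALSE)
  check_num(x_cells, "x_cells", 0)
  structure(list(m_sed = m_sed, v_w = v_w, v_a = v_a, regime = regime,
                 x_cells = x_cells, v_pw = v_pw, temp_note = temp_note),
            class = "microcosm_config")
}

#' @export
print.microcosm_config <- function(x, ...) {
  cat(sprintf("<microcosm_config> %s | sediment %.3g g, water %.3g L, headspace %.3g L, cells %.3g g/L\n",
              x$regime, x$m_sed, x$v_w, x$v_a, x$x_cells))
  invisible(x)
}

#' Polyurethane-foam (PUF) passive air sampler specification
#'
#' Geometry defaults match the cylinders deployed in the flask neck
#' (height 2.5 cm, radius 1.9 cm). Uptake is modelled as air-side
#' film-limited transfer across the exposed face toward a linear
#' PUF-air partition equilibrium.
#'
#' @param height cylinder height, cm
#' @param radius cylinder radius, cm
#' @param k_puf air-side uptake velocity, cm/d
#' @param k_puf_a dimensionless PUF-air partition coefficient
#'   (ng/L PUF per ng/L air)
#' @return an object of class `puf_spec`; `v_puf` (L) and `a_face` (cm^2)
#'   are derived from the geometry
#' @export
puf_spec <- function(height = 2.5, radius = 1.9, k_puf = 500, k_puf_a = 5000) {
  for (nm in c("height", "radius", "k_puf", "k_puf_a"))
    check_num(get(nm), nm, 0, allow_zero_lower = FALSE)
  structure(list(height = height, radius = radius, k_puf = k_puf,
                 k_puf_a = k_puf_a,
                 a_face = pi * radius^2,
                 v_puf = cm3_to_l(pi * radius^2 * height)),
            class = "puf_spec")
}

#' Solid-phase microextraction (SPME) fiber specification
#'
#' A polydimethylsiloxane-coated fiber sampling the freely dissolved aqueous
#' phase; ~30 cm of fiber per flask, 10 micrometre coating. Mass is tracked
#' per cm of fiber. `v_coat_per_cm` defaults to the annular coating volume
#' of a 110 micrometre core with a 10 micrometre PDMS layer
#' (~3.8e-9 L/cm).
#'
#' @param coating_thickness PDMS layer thickness, micrometres
#' @param fiber_length_total deployed fiber length, cm
#' @param k_fw dimensionless fiber-water partition coefficient
#' @param k_sp water-side first-order uptake rate toward fiber-water
#'   equilibrium, 1/d
#' @param v_coat_per_cm coating volume per cm of fiber, L/cm
#' @return an object of class `spme_spec`
#' @export
spme_spec <- function(coating_thickness = 10, fiber_length_total = 30,
                      k_fw = 30000, k_sp = 2, v_coat_per_cm = 3.8e-9) {
  for (nm in c("coating_thickness", "fiber_length_total", "k_fw", "k_sp",
               "v_coat_per_cm"))
    check_num(get(nm), nm, 0, allow_zero_lower = FALSE)
  structure(list(coating_thickness = coating_thickness,
                 fiber_length_total = fiber_length_total,
                 k_fw = k_fw, k_sp = k_sp, v_coat_per_cm = v_coat_per_cm),
            class = "spme_spec")
}

#' Sediment-particle radial diffusion grid
#'
#' Parameters of the intraparticle radial diffusion model: a single
#' representative sorbing sphere, discretised into `n_shells` finite
#' volumes. Local sorption is lumped into one retardation factor
#' (1 + rho*Kd*(1-eps)/eps for a linear local-equilibrium isotherm),
#' so effective transport runs at `d_eff/retardation`. The shell mesh is
#' graded toward the particle surface (edge radii R*(1-(1-u)^grading)) to
#' resolve the early-time uptake boundary layer.
#'
#' @param radius particle radius, cm
#' @param n_shells number of radial finite-volume shells, >= 3
#' @param d_eff effective pore diffusivity, cm^2/d
#' @param retardation dimensionless retardation factor, >= 1
#' @param porosity intraparticle porosity, in (0,1)
#' @param n_particles_equiv number of equivalent particles representing the
#'   whole sediment inventory; default scales the default 10 g inventory by
#'   particle volume at density 2.5 g/cm^3
#' @param grading mesh-grading exponent (1 = uniform shells; 2 refines the
#'   surface, the default)
#' @return an object of class `particle_grid`
#' @export
particle_grid <- function(radius = 5e-3, n_shells = 30, d_eff = 1e-6,
                          retardation = 100, porosity = 0.4,
                          n_particles_equiv = NULL, grading = 2) {
  check_num(radius, "radius", 0, allow_zero_lower = FALSE)
  n_shells <- as.integer(n_shells)
  stop_if(n_shells < 3L, "n_shells must be >= 3")
  check_num(d_eff, "d_eff", 0, allow_zero_lower = FALSE)
  check_num(retardation, "retardation", 1)
  stop_if(porosity <= 0 || porosity >= 1, "porosity must be in (0,1)")
  check_num(grading, "grading", 0, allow_zero_lower = FALSE)
  if (is.null(n_particles_equiv)) {
    v_particle <- 4 / 3 * pi * radius^3          # cm^3
    n_particles_equiv <- 10 / (2.5 * v_particle) # 10 g at 2.5 g/cm^3
  }
  check_num(n_particles_equiv, "n_particles_equiv", 0, allow_zero_lower = FALSE)
  structure(list(radius = radius, n_shells = n_shells, d_eff = d_eff,
                 retardation = retardation, porosity = porosity,
                 n_particles_equiv = n_particles_equiv, grading = grading),
            class = "particle_grid")
}

#' Reactive-transport model parameters
#'
#' All rate and partition parameters of one simulated flask. Biodegradation
#' is first order in the freely dissolved aqueous concentration; the
#' bioavailability factor B = 1/(1 + k_cell*x_cells) gives the freely
#' dissolved fraction of the total aqueous pool when sorbing degrader cells
#' are suspended in the liquid. Sediment exchange is two-site fast/slow
#' linear driving force (shaken) or intraparticle radial diffusion plus a
#' porewater boundary-layer film (nonshaken).
#'
#' @param k_bio first-order biodegradation rate acting on the freely
#'   dissolved overlying-water pool, 1/d
#' @param k_cell cell-water partition coefficient, L/g (defines B)
#' @param f_avail fraction of the sediment PCB inventory available for
#'   sorption/desorption exchange, in `[0,1]`
#' @param f_fast fraction of the available pool in the fast site, in `[0,1]`
#' @param k_fast,k_slow first-order desorption rate constants, 1/d
#' @param v_aw air-water mass-transfer velocity, cm/d
#' @param a_aw air-water interfacial area, cm^2 (default: a 250 mL
#'   Erlenmeyer cross-section of ~38 cm^2)
#' @param k_bl liquid boundary-layer mass-transfer velocity at the
#'   sediment-water interface, cm/d (nonshaken)
#' @param a_int sediment-water interfacial area, cm^2 (nonshaken)
#' @param alpha_fiber fraction of the cell-sorbed aqueous pool attributed to
#'   fouled SPME fiber in the observation model, in `[0,1]`
#' @param particle a [particle_grid()] (nonshaken particle model)
#' @param puf a [puf_spec()]
#' @param spme a [spme_spec()]
#' @return an object of class `rtm_params`
#' @export
rtm_params <- function(k_bio = 0, k_cell = 0, f_avail = 1, f_fast = 0.5,
                       k_fast = 1, k_slow = 0.01, v_aw = 50, a_aw = 38,
                       k_bl = 2, a_int = 38, alpha_fiber = 0,
                       particle = particle_grid(), puf = puf_spec(),
                       spme = spme_spec()) {
  for (nm in c("k_bio", "k_cell", "k_fast", "k_slow", "v_aw", "a_aw",
               "k_bl", "a_int"))
    check_num(get(nm), nm, 0)
  check_num(f_avail, "f_avail", 0, 1)
  check_num(f_fast, "f_fast", 0, 1)
  check_num(alpha_fiber, "alpha_fiber", 0, 1)
  stop_if(!inherits(particle, "particle_grid"), "particle must be a particle_grid")
  stop_if(!inherits(puf, "puf_spec"), "puf must be a puf_spec")
  stop_if(!inherits(spme, "spme_spec"), "spme must be a spme_spec")
  structure(list(k_bio = k_bio, k_cell = k_cell, f_avail = f_avail,
                 f_fast = f_fast, k_fast = k_fast, k_slow = k_slow,
                 v_aw = v_aw, a_aw = a_aw, k_bl = k_bl, a_int = a_int,
                 alpha_fiber = alpha_fiber, particle = particle,
                 puf = puf, spme = spme),
            class = "rtm_params")
}

#' @export
print.rtm_params <- function(x, ...) {
  cat(sprintf("<rtm_params> k_bio=%.3g /d, k_cell=%.3g L/g, f_avail=%.2f, f_fast=%.2f, k_fast=%.3g, k_slow=%.3g /d\n",
              x$k_bio, x$k_cell, x$f_avail, x$f_fast, x$k_fast, x$k_slow))
  cat(sprintf("  air-water: v_aw=%.3g cm/d x %.3g cm2 | bed film: k_bl=%.3g cm/d x %.3g cm2 | alpha_fiber=%.2f\n",
              x$v_aw, x$a_aw, x$k_bl, x$a_int, x$alpha_fiber))
  invisible(x)
}

#' Update a subset of flat rtm_params fields by name
#' @keywords internal
set_params <- function(p, values) {
  for (nm in names(values)) {
    stop_if(!nm %in% names(p) || nm %in% c("particle", "puf", "spme"),
            "unknown or non-scalar rtm_params field: ", nm)
    p[[nm]] <- values[[nm]]
  }
  do.call(rtm_params, p)
}

#' Write a microcosm configuration and parameter set to a YAML file
#'
#' Flat keys mirror the field names of [microcosm_config()] and
#' [rtm_params()]; nested blocks `particle`, `puf`, `spme` hold the
#' sub-model specs. Units are as documented on the constructors.
#'
#' @param cfg a `microcosm_config`
#' @param params an `rtm_params`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_rtm_config <- function(cfg, params, path) {
  pl <- unclass(params)
  pl$particle <- unclass(pl$particle)
  pl$puf <- unclass(pl$puf)[c("height", "radius", "k_puf", "k_puf_a")]
  pl$spme <- unclass(pl$spme)
  yaml::write_yaml(list(config = unclass(cfg), params = pl), path)
  invisible(path)
}

#' Read a microcosm configuration and parameter set from a YAML file
#'
#' @param path file written by [write_rtm_config()] (or hand-authored with
#'   the same keys)
#' @return a list with elements `config` (a `microcosm_config`) and
#'   `params` (an `rtm_params`)
#' @export
read_rtm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  stop_if(is.null(raw$config) || is.null(raw$params),
          "config file must contain 'config' and 'params' blocks")
  cfg <- do.call(microcosm_config,
                 raw$config[names(raw$config) %in% names(formals(microcosm_config))])
  pl <- raw$params
  if (!is.null(pl$particle)) pl$particle <- do.call(particle_grid,
      pl$particle[names(pl$particle) %in% names(formals(particle_grid))])
  if (!is.null(pl$puf)) pl$puf <- do.call(puf_spec,
      pl$puf[names(pl$puf) %in% names(formals(puf_spec))])
  if (!is.null(pl$spme)) pl$spme <- do.call(spme_spec,
      pl$spme[names(pl$spme) %in% names(formals(spme_spec))])
  params <- do.call(rtm_params, pl[names(pl) %in% names(formals(rtm_params))])
  list(config = cfg, params = params)
}
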