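#' PUF passive-sampler uptake rate
#'
#' Air-side film-limited uptake of gas-phase PCB onto a polyurethane foam
#' cylinder, relaxing toward the linear PUF-air partition equilibrium:
#' rate = k_puf * A_face * (c_a - m_puf/(V_puf*k_puf_a)), converted to ng/d.
#' Zero at equilibrium.
#'
#' @param spec a [puf_spec()]
#' @param c_a headspace concentration, ng/L
#' @param m_puf mass currently on the PUF, ng
#' @return uptake rate, ng/d (negative = off-gassing)
#' @export
puf_uptake_rate <- function(spec, c_a, m_puf) {
  stop_if(!inherits(spec, "puf_spec"), "spec must be a puf_spec")
  check_num(c_a, "c_a", 0)
  check_num(m_puf, "m_puf", 0)
  exchange_l_per_d(spec$k_puf, spec$a_face) *
    (c_a - m_puf / (spec$v_puf * spec$k_puf_a))
}

#' SPME fiber uptake rate
#'
#' First-order relaxation of the PDMS coating load (per cm of fiber) toward
#' its equilibrium with the freely dissolved aqueous concentration:
#' rate = k_sp * (k_fw * v_coat_per_cm * c_free - m_spme).
#'
#' @param spec a [spme_spec()]
#' @param c_free freely dissolved aqueous concentration, ng/L
#' @param m_spme current coating load, ng/cm
#' @return uptake rate, (ng/cm)/d
#' @export
spme_uptake_rate <- function(spec, c_free, m_spme) {
  stop_if(!inherits(spec, "spme_spec"), "spec must be a spme_spec")
  check_num(c_free, "c_free", 0)
  check_num(m_spme, "m_spme", 0)
  spec$k_sp * (spec$k_fw * spec$v_coat_per_cm * c_free - m_spme)
}

#' Apparent (reported) SPME mass under cell fouling
#'
#' When sorbing degrader cells attach to the fiber, the extracted mass
#' includes PCB carried by those cells in addition to the true PDMS coating
#' load. The observation model attributes a fraction `alpha_fiber` of the
#' cell-sorbed aqueous pool (1-B of the total aqueous mass) to the deployed
#' fiber, spread over its length:
#' apparent = m_spme + alpha_fiber * (1-B) * c_w * v_w / fiber_length.
#' Fouling affects only what the fiber REPORTS, not the system dynamics.
#'
#' @param m_spme true coating load, ng/cm
#' @param c_w total aqueous concentration (dissolved + cell-sorbed), ng/L
#' @param b bioavailability factor (freely dissolved fraction), in `[0,1]`
#' @param alpha_fiber fouling attribution fraction, in `[0,1]`
#' @param cfg a [microcosm_config()] (supplies the liquid volume)
#' @param spec a [spme_spec()] (supplies the fiber length)
#' @return apparent mass per cm of fiber, ng/cm; always >= `m_spme`
#' @export
apparent_spme_mass <- function(m_spme, c_w, b, alpha_fiber, cfg, spec) {
  check_num(m_spme, "m_spme", 0)
  check_num(c_w, "c_w", 0)
  check_num(b, "b", 0, 1)
  check_num(alpha_fiber, "alpha_fiber", 0, 1)
  m_spme + alpha_fiber * (1 - b) * c_w * cfg$v_w / spec$fiber_length_total
}
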