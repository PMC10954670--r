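# Model parameters.
#
# All quantities are nondimensional: the length unit is one columnar cell
# width, the energy unit is arbitrary, and damping coefficients are 1 for
# every node class by default (time is measured in units of C * length^2 /
# energy).  Published values for the spring constants are not available in
# numeric form, so the defaults below are calibrated so that the model
# reproduces the qualitative shape behaviours used for validation: a flat
# columnar layer with basally dominant contractility bends into a uniform
# arc, medial perturbations of contractility / ECM stiffness / cell-ECM
# adhesion flatten the medial domain, and mitotic rounding drives apical
# nuclear migration.

#' Morse potential parameters
#'
#' Volume exclusion between node pairs is modelled with a Morse potential
#' \deqn{E_v(d) = U e^{-d/\xi} - W e^{-d/\gamma},}
#' truncated at a finite cutoff.  The truncated potential is shifted by its
#' value at the cutoff so that the energy is continuous when pairs cross the
#' interaction range (the shift is a small constant per pair and does not
#' change forces inside the cutoff).
#'
#' @param U repulsion well height (energy), >= 0.
#' @param W attraction scale (energy), >= 0 (0 gives pure repulsion).
#' @param xi repulsion decay length, > 0.
#' @param gamma attraction decay length, > 0.
#' @param cutoff interaction cutoff; must be at least `3 * max(xi, gamma)`
#'   so the truncated tail is negligible.
#' @return an object of class `morse_params`.
#' @export
morse_params <- function(U, W, xi, gamma, cutoff) {
  stopifnot(U >= 0, W >= 0, xi > 0, gamma > 0, cutoff > 0)
  if (cutoff < 3 * max(xi, gamma) - 1e-12) {
    stop("morse_params: cutoff must be >= 3 * max(xi, gamma)")
  }
  shift <- U * exp(-cutoff / xi) - W * exp(-cutoff / gamma)
  structure(list(U = U, W = W, xi = xi, gamma = gamma,
                 cutoff = cutoff, shift = shift),
            class = "morse_params")
}

#' Default mechanical parameter set
#'
#' Returns the full list of mechanical parameters used by the energy and
#' force routines.  Components:
#' \describe{
#' \item{membrane}{linear spring stiffness `k` and quadratic bending
#'   stiffness `k_bend` of the cell membrane; rest lengths and rest angles
#'   are taken from the constructed geometry.}
#' \item{contractile}{apical and basal actomyosin contractile spring
#'   stiffnesses `k_apical` (k_api,cont) and `k_basal` (k_bas,cont), their
#'   rest lengths, the rest length `L0_mitotic` of the transient
#'   constriction springs active during mitotic rounding, and the
#'   `spacing` used when allocating springs along the lateral sides.}
#' \item{adhesion}{stiffness and rest length of lateral cell-cell
#'   (E-cadherin), columnar-squamous (apical) and cell-ECM (Integrin,
#'   basal) adhesion springs, plus the pairing range `max_range`.}
#' \item{area}{`k_vol`, the strength of the cytoplasmic area
#'   (2D volume) constraint.}
#' \item{ecm}{ECM segment stiffness `k` (k_ecm), its regionally scaled
#'   counterpart applies through profiles (k_ecm,c), cosine bending
#'   stiffness `k_bend` with rest angle `theta0 = pi`, and the strain
#'   threshold / cadence used by ECM remodeling.}
#' \item{morse}{`morse_params` per interaction class: `mm`
#'   membrane-membrane across cells, `nm` nucleus-membrane, `nn`
#'   nucleus-nucleus within a cell (nucleus size term), `nx`
#'   nucleus-nucleus across cells, `me` membrane-ECM, `ne` nucleus-ECM.}
#' \item{damping}{damping coefficient per node class.}
#' \item{exclusion_skin}{extra margin added to the Morse cutoff when
#'   building the exclusion pair list, so the list stays valid between
#'   periodic rebuilds.}
#' }
#'
#' @return a named list of parameters.
#' @export
default_params <- function() {
  list(
    membrane = list(k = 30, k_bend = 2, k_squamous = 8,
                    k_bend_squamous = 5),
    contractile = list(k_apical = 0.6, k_basal = 5,
                       L0_apical = 0.3, L0_basal = 0.15,
                       L0_mitotic = 0.12, spacing = 0.5),
    adhesion = list(k_lateral = 8, k_apical = 1, k_basal = 8,
                    L0_lateral = 0, L0_apical = 0.2, L0_basal = 0.15,
                    max_range = 0.7),
    area = list(k_vol = 30),
    ecm = list(k = 1, k_bend = 0.5, theta0 = pi,
               tension_threshold = 0.3, min_segment = 0.1),
    morse = list(
      mm = morse_params(U = 0.6, W = 0, xi = 0.06, gamma = 0.12, cutoff = 0.5),
      nm = morse_params(U = 3.0, W = 0, xi = 0.16, gamma = 0.32, cutoff = 1.1),
      nn = morse_params(U = 1.2, W = 0.6, xi = 0.10, gamma = 0.20, cutoff = 1.0),
      nx = morse_params(U = 2.0, W = 0, xi = 0.16, gamma = 0.32, cutoff = 1.1),
      me = morse_params(U = 0.6, W = 0, xi = 0.06, gamma = 0.12, cutoff = 0.5),
      ne = morse_params(U = 2.0, W = 0, xi = 0.14, gamma = 0.28, cutoff = 1.0)
    ),
    damping = list(membrane = 1, nucleus = 1, ecm = 1),
    boundary_stiffness = 1,
    exclusion_skin = 0.3,
    same_cell_membrane_exclusion = TRUE,
    nucleus_cross_cell = TRUE
  )
}

#' Default cell growth and division parameters
#'
#' Rates are per unit simulation time (they multiply the time step).
#'
#' @param epsilon target-area growth rate (area per unit time).
#' @param omega0_max_factor cap on the target area as a multiple of the
#'   initial target area; must be < 2 because the cross-sectional area does
#'   not double even when the 3D cell volume doubles.
#' @param delta cell-cycle progression rate (the cell cycle length is
#'   `1/delta`).
#' @param gp_mit growth-progress threshold at which mitotic rounding
#'   starts; must lie in (gp0 range, 1).
#' @param gp0_max fresh cells draw their initial growth progress uniformly
#'   from `[0, gp0_max]`.
#' @param h_rate ramp rate of the basal constriction front `H0` during
#'   mitotic rounding (length per unit time).
#' @param p_inplane probability that a division introduces the new cell in
#'   the simulated cross-section plane (in-plane division).
#' @param max_divisions maximal number of divisions per lineage.
#' @param contractile_boost multiplier applied to basal constriction
#'   springs during mitotic rounding.
#' @param exclusion_boost multiplier applied to the volume-exclusion
#'   coefficient of a mitotic cell's nodes.
#' @return a named list of growth parameters.
#' @export
growth_params <- function(epsilon = 0.2,
                          omega0_max_factor = 1.45,
                          delta = 0.08,
                          gp_mit = 0.86,
                          gp0_max = 0.3,
                          h_rate = 3,
                          p_inplane = 0.5,
                          max_divisions = 10,
                          contractile_boost = 4,
                          exclusion_boost = 2) {
  stopifnot(epsilon >= 0, delta > 0, gp_mit > 0, gp_mit < 1,
            gp0_max >= 0, gp0_max < gp_mit,
            h_rate > 0, p_inplane >= 0, p_inplane <= 1,
            max_divisions >= 0, contractile_boost > 0, exclusion_boost > 0,
            omega0_max_factor > 1, omega0_max_factor < 2)
  list(epsilon = epsilon, omega0_max_factor = omega0_max_factor,
       delta = delta, gp_mit = gp_mit, gp0_max = gp0_max,
       h_rate = h_rate, p_inplane = p_inplane,
       max_divisions = max_divisions,
       contractile_boost = contractile_boost,
       exclusion_boost = exclusion_boost)
}
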