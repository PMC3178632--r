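#' Force-field parameters
#'
#' All interaction constants of the coarse-grained model.  Subunits are
#' spheres of diameter `a` (the length unit) that repel when overlapping
#' (WCA form, contact at `a`).  Chain neighbors are bonded harmonically about
#' rest length `a`; bundle crosslinks are harmonic about the filament spacing
#' `d0`.  Filaments are stiffened by a `k_bend (1 - cos theta)` potential.
#' Each subunit carries a unit polarization vector that marks its binding
#' site: an alignment potential holds it at angle `theta0` to the adjacent
#' chain bonds (perpendicular in the standard, side-binding model) and
#' nearest-/next-nearest-neighbor couplings impose a helical pitch.  ParB
#' binds ParA through a short-ranged separable potential: a radial well of
#' depth `eps_b` at distance `r_b`, vanishing smoothly at `range_b`, times
#' bounded angular factors that are maximal when the two polarization vectors
#' point toward each other along the inter-subunit axis.
#'
#' @param a subunit diameter (simulation length unit).
#' @param k_bond intra-chain bond stiffness (kT/a^2).
#' @param k_crosslink ParA crosslink stiffness (kT/a^2).
#' @param d0 crosslink rest length = initial filament spacing (a).
#' @param k_bend_parA,k_bend_parB bending stiffness (kT); the standard model
#'   has a flexible ParB polymer, `k_bend_parB = 0`.
#' @param k_align polarization-to-bond alignment strength (kT).
#' @param theta0_deg target angle between polarization and chain bonds
#'   (degrees); 90 in the standard model, 180 points tips outward for the
#'   tip-binding variant.
#' @param k_helix_nn,k_helix_nnn helical coupling strengths (kT).
#' @param psi_nn_parA_deg,psi_nnn_parA_deg,psi_nn_parB_deg,psi_nnn_parB_deg
#'   helical pitch angles per species (degrees); zero pitch with equal
#'   strengths gives the non-helical variant.
#' @param eps_b ParB-ParA binding energy (kT); the binding potential's global
#'   minimum is exactly `-eps_b`.
#' @param r_b distance of the binding minimum (a).
#' @param range_b binding cutoff (a).
#' @param w_ang_parA,w_ang_parB angular selectivity widths (dimensionless, on
#'   the cosine scale) of the ParA and ParB orientation factors.
#' @param binding_form `"ORIENTED"` (both polarization factors),
#'   `"TIP_NO_PARB_POLAR"` or `"SIDE_NO_PARB_POLAR"` (variants without a ParB
#'   orientation factor).
#' @param wall_radius optional cylindrical confinement radius about the x
#'   axis (a); `<= 0` disables it.
#' @param k_wall harmonic wall stiffness (kT/a^2).
#' @return an object of class `pb_forcefield` (a validated named list).
#' @export
ff_params <- function(a = 1, k_bond = 100, k_crosslink = 50, d0 = 1.5,
                      k_bend_parA = 50, k_bend_parB = 0,
                      k_align = 10, theta0_deg = 90,
                      k_helix_nn = 10, k_helix_nnn = 10,
                      psi_nn_parA_deg = 60, psi_nnn_parA_deg = 120,
                      psi_nn_parB_deg = 36, psi_nnn_parB_deg = 72,
                      eps_b = 6, r_b = 1, range_b = 1.5,
                      w_ang_parA = 0.6, w_ang_parB = 0.6,
                      binding_form = "ORIENTED",
                      wall_radius = -1, k_wall = 50) {
  p <- list(a = a, k_bond = k_bond, k_crosslink = k_crosslink, d0 = d0,
            k_bend_parA = k_bend_parA, k_bend_parB = k_bend_parB,
            k_align = k_align, theta0_deg = theta0_deg,
            k_helix_nn = k_helix_nn, k_helix_nnn = k_helix_nnn,
            psi_nn_parA_deg = psi_nn_parA_deg, psi_nnn_parA_deg = psi_nnn_parA_deg,
            psi_nn_parB_deg = psi_nn_parB_deg, psi_nnn_parB_deg = psi_nnn_parB_deg,
            eps_b = eps_b, r_b = r_b, range_b = range_b,
            w_ang_parA = w_ang_parA, w_ang_parB = w_ang_parB,
            binding_form = binding_form, wall_radius = wall_radius, k_wall = k_wall)
  validate_ff(p)
}

validate_ff <- function(p) {
  stiff <- c("k_bond", "k_crosslink", "k_bend_parA", "k_bend_parB", "k_align",
             "k_helix_nn", "k_helix_nnn", "eps_b")
  for (s in stiff)
    if (p[[s]] < 0) stop("force-field constant '", s, "' must be >= 0")
  if (p$a <= 0) stop("subunit diameter 'a' must be positive")
  if (p$r_b > p$range_b) stop("r_b must not exceed range_b")
  if (p$d0 < p$a) stop("filament spacing d0 must be >= the subunit diameter a")
  forms <- c("ORIENTED", "TIP_NO_PARB_POLAR", "SIDE_NO_PARB_POLAR")
  if (!p$binding_form %in% forms)
    stop("binding_form must be one of: ", paste(forms, collapse = ", "))
  p$binding_form_code <- if (p$binding_form == "ORIENTED") 0L else 1L
  class(p) <- "pb_forcefield"
  p
}

pair_result <- function(res) {
  structure(list(energy = res$energy,
                 force_on_i = as.numeric(res$force_i),
                 force_on_j = as.numeric(res$force_j),
                 torque_on_i = as.numeric(res$torque_i),
                 torque_on_j = as.numeric(res$torque_j)),
            class = "pb_pair")
}

#' Excluded-volume (WCA) pair interaction
#'
#' Purely repulsive, with energy and force identically zero at and beyond
#' contact (`|r_ij| >= a`).
#'
#' @param r_ij 3-vector from subunit j to subunit i.
#' @param params a [ff_params()] object.
#' @return list with `energy`, `force_on_i`, `force_on_j`, and (zero)
#'   torques.
#' @export
excluded_volume <- function(r_ij, params) {
  if (sqrt(sum(r_ij^2)) <= 1e-12) stop("overlapping subunit centers (r = 0)")
  pair_result(ff_pair_cpp("ev", as.numeric(r_ij), c(0, 0, 0),
                          c(1, 0, 0), c(1, 0, 0), params))
}

#' Harmonic chain bond
#' @inheritParams excluded_volume
#' @return as [excluded_volume()]; energy `(k_bond/2)(|r_ij| - a)^2`.
#' @export
bond <- function(r_ij, params) {
  pair_result(ff_pair_cpp("bond", as.numeric(r_ij), c(0, 0, 0),
                          c(1, 0, 0), c(1, 0, 0), params))
}

#' Harmonic bundle crosslink (rest length d0)
#' @inheritParams excluded_volume
#' @return as [excluded_volume()].
#' @export
crosslink <- function(r_ij, params) {
  pair_result(ff_pair_cpp("crosslink", as.numeric(r_ij), c(0, 0, 0),
                          c(1, 0, 0), c(1, 0, 0), params))
}

#' Bending potential over three consecutive chain subunits
#'
#' `U = k (1 - cos theta)` in the angle between consecutive bond vectors;
#' zero for the straight configuration.
#'
#' @param r_prev,r_mid,r_next positions of the consecutive subunits.
#' @param params a [ff_params()] object.
#' @param species `"PARA"` or `"PARB"`: selects the bending stiffness.
#' @return list with `energy` and `force_prev`, `force_mid`, `force_next`.
#' @export
bending <- function(r_prev, r_mid, r_next, params, species = "PARA") {
  k <- if (species == "PARA") params$k_bend_parA else params$k_bend_parB
  ff_bend_cpp(as.numeric(r_prev), as.numeric(r_mid), as.numeric(r_next), k)
}

#' Polarization-to-bond alignment potential
#'
#' Holds the polarization vector at angle `theta0` to each adjacent chain
#' bond: `U = (k_align/2) (cos theta - cos theta0)^2` per bond.
#'
#' @param p_i unit polarization vector.
#' @param bond_vectors matrix (one row per adjacent bond) of bond vectors,
#'   oriented tip-to-anchor along the chain.
#' @param params a [ff_params()] object.
#' @return list with `energy`, `dUdp` (gradient w.r.t. `p_i`), `torque`
#'   (`-p x dUdp`), and `dUdbond` (per-bond gradient; the force on the bond's
#'   far endpoint is `-dUdbond`, on the near endpoint `+dUdbond`).
#' @export
polarization_alignment <- function(p_i, bond_vectors, params) {
  if (abs(sqrt(sum(p_i^2)) - 1) > 1e-6) stop("p_i must be a unit vector")
  bv <- matrix(as.numeric(bond_vectors), ncol = 3)
  ff_align_cpp(as.numeric(p_i), bv, params$k_align, params$theta0_deg)
}

#' Helical coupling between polarization vectors on one chain
#'
#' `U = (k/2)(p_i . p_j - cos psi)^2`, minimized when the angle between the
#' two polarization vectors equals the configured pitch angle.
#'
#' @param p_i,p_j unit polarization vectors of the chain (next-)nearest
#'   neighbors.
#' @param neighbor_order `"nn"` or `"nnn"`.
#' @param params a [ff_params()] object.
#' @param species `"PARA"` or `"PARB"`: selects the pitch angle.
#' @return list with `energy`, `dUdp_i`, `dUdp_j`, `torque_i`, `torque_j`.
#' @export
helical_coupling <- function(p_i, p_j, neighbor_order = c("nn", "nnn"),
                             params, species = "PARA") {
  neighbor_order <- match.arg(neighbor_order)
  k <- if (neighbor_order == "nn") params$k_helix_nn else params$k_helix_nnn
  psi <- if (species == "PARA") {
    if (neighbor_order == "nn") params$psi_nn_parA_deg else params$psi_nnn_parA_deg
  } else {
    if (neighbor_order == "nn") params$psi_nn_parB_deg else params$psi_nnn_parB_deg
  }
  ff_helix_cpp(as.numeric(p_i), as.numeric(p_j), k, psi)
}

#' Site-specific ParB-ParA binding potential
#'
#' Separable radial x angular attraction with global minimum exactly
#' `-eps_b` at `|r_ij| = r_b` with the two polarization vectors antiparallel
#' and collinear with the inter-subunit axis; smoothly zero beyond
#' `range_b`.  The `TIP_NO_PARB_POLAR` / `SIDE_NO_PARB_POLAR` forms drop the
#' ParB orientation factor.
#'
#' @param r_ij 3-vector from the ParA subunit i to the ParB subunit j.
#' @param p_i,p_j unit polarization vectors of the ParA and ParB subunits.
#' @param params a [ff_params()] object.
#' @return list with `energy` (in `[-eps_b, 0]`), `force_on_i`, `force_on_j`,
#'   `torque_on_i`, `torque_on_j`.
#' @export
binding <- function(r_ij, p_i, p_j, params) {
  pair_result(ff_pair_cpp("binding", c(0, 0, 0), as.numeric(r_ij),
                          as.numeric(p_i), as.numeric(p_j), params))
}

#' Total forces, torques, and binding-energy table for a system
#'
#' Aggregates every interaction over the system (with an optional Verlet pair
#' list).  Internal forces sum to zero; the returned per-pair binding-energy
#' table feeds the hydrolysis threshold rule of the chemistry module.
#'
#' @param state a [pb_state()].
#' @param params a [ff_params()] object.
#' @param chem optional [chemistry_params()]: sets the binding eligibility
#'   mode (defaults to side-binding).
#' @param use_neighbor_list logical; `FALSE` forces a brute-force all-pairs
#'   evaluation (oracle path).
#' @return list with `forces` (N x 3), `torques` (N x 3), total `energy`,
#'   `max_binding` (strongest pair |energy| per subunit), and
#'   `binding_pairs` (data.frame: `para_id`, `parb_id`, `energy`).
#' @export
total_forces <- function(state, params, chem = NULL, use_neighbor_list = TRUE) {
  bm <- if (is.null(chem)) 0L else chem$binding_mode_code
  a <- state_args(state)
  out <- compute_forces_cpp(a$pos, a$pol, a$species, a$nuc, a$alpha, a$anchored,
                            a$chains, a$chainAnchored, a$xlinks, a$t, a$n_para0,
                            params, bm, use_neighbor_list)
  out$binding_pairs <- as.data.frame(out$binding_pairs)
  out
}
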