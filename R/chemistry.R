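#' Chemistry parameters
#'
#' Stochastic biochemistry coupling binding to disassembly.  A polymerized
#' ParA-ATP subunit whose strongest instantaneous ParB binding energy
#' magnitude reaches `eps_threshold` hydrolyzes (ATP -> ADP, irreversible) at
#' rate `k_h`; a hydrolyzed subunit at a free filament tip depolymerizes at
#' rate `k_d` (tip-only disassembly), or, in the severing variant, any
#' interior hydrolyzed subunit may additionally cut its filament at rate
#' `k_d`.  Per-step conversion probabilities are `1 - exp(-k dt)`.
#'
#' @param k_h hydrolysis rate (1/tau0) per bound ATP subunit.
#' @param k_d depolymerization/severing rate (1/tau0) per eligible subunit.
#' @param eps_threshold binding-energy magnitude (kT) licensing hydrolysis;
#'   defaults to half the binding energy `eps_b` if that is supplied.
#' @param binding_mode `"SIDE"` (all polymerized ParA-ATP may bind ParB) or
#'   `"TIP_ONLY"` (only free-tip subunits).
#' @param disassembly_mode `"TIP_ONLY"` or `"SEVERING"` (severing acts in
#'   addition to tip depolymerization).
#' @param remove_monomer_distance optional culling distance (a): free
#'   monomers farther than this from every polymer are dropped from the
#'   dynamics (speed option, off by default, excluded from conservation
#'   checks).
#' @param chemistry_on master switch (relaxation runs disable chemistry).
#' @param eps_b binding energy used only to default `eps_threshold`.
#' @return an object of class `pb_chemistry`.
#' @export
chemistry_params <- function(k_h = 5e-3, k_d = 2e-4, eps_threshold = NULL,
                             binding_mode = "SIDE", disassembly_mode = "TIP_ONLY",
                             remove_monomer_distance = NULL, chemistry_on = TRUE,
                             eps_b = 6) {
  if (k_h < 0 || k_d < 0) stop("rates must be >= 0")
  if (is.null(eps_threshold)) eps_threshold <- 0.5 * eps_b
  if (!binding_mode %in% c("SIDE", "TIP_ONLY"))
    stop("binding_mode must be SIDE or TIP_ONLY")
  if (!disassembly_mode %in% c("TIP_ONLY", "SEVERING"))
    stop("disassembly_mode must be TIP_ONLY or SEVERING")
  p <- list(k_h = k_h, k_d = k_d, eps_threshold = eps_threshold,
            binding_mode = binding_mode, disassembly_mode = disassembly_mode,
            remove_monomer_distance = remove_monomer_distance,
            chemistry_on = isTRUE(chemistry_on))
  p$binding_mode_code <- if (binding_mode == "SIDE") 0L else 1L
  p$disassembly_mode_code <- if (disassembly_mode == "TIP_ONLY") 0L else 1L
  class(p) <- "pb_chemistry"
  p
}

#' ParA subunits eligible to bind ParB
#'
#' `SIDE` mode: every polymerized ParA subunit (including severed fragments
#' and hydrolyzed subunits still in a filament -- a subunit loses its ParB
#' affinity only when it depolymerizes).  `TIP_ONLY` mode: the free-tip
#' subunit of each filament (both terminal subunits of a never-anchored
#' chain).  Depolymerized monomers are never eligible.
#'
#' @param state a [pb_state()].
#' @param params a [chemistry_params()] object.
#' @return sorted integer vector of eligible ParA subunit ids.
#' @export
eligible_binders <- function(state, params) {
  m <- chain_membership(state)
  if (params$binding_mode == "SIDE") {
    ids <- which(state$species == "PARA" & m$chain_id > 0)
  } else {
    ids <- integer(0)
    for (c in seq_along(state$chains)) {
      ch <- state$chains[[c]]
      if (length(ch) == 0 || state$species[ch[1]] != "PARA") next
      ids <- c(ids, ch[1])
      if (!state$chain_anchored[c] && length(ch) > 1) ids <- c(ids, ch[length(ch)])
    }
  }
  sort(unique(ids))
}

chem_call <- function(state, what, params, dt, seed, maxbind = NULL) {
  a <- state_args(state)
  if (is.null(maxbind)) maxbind <- numeric(n_subunits(state))
  out <- chem_step_cpp(a$pos, a$pol, a$species, a$nuc, a$alpha, a$anchored,
                       a$chains, a$chainAnchored, a$xlinks, a$t, a$n_para0,
                       what, maxbind, params$eps_threshold, params$k_h,
                       params$k_d, dt, as.integer(seed))
  new <- state
  new$nucleotide <- .NUC_LEVELS[out$nucleotide + 1L]
  new$chains <- out$chains
  new$chain_anchored <- out$chain_anchored
  new$crosslinks <- if (nrow(out$crosslinks)) out$crosslinks else matrix(integer(0), 0, 2)
  ev <- as.data.frame(out$events)
  ev$kind <- .EVENT_KINDS[ev$kind + 1L]
  list(state = new, events = ev)
}

#' ParB-stimulated hydrolysis step
#'
#' Each polymerized ParA-ATP subunit whose strongest current binding energy
#' magnitude is at least `eps_threshold` converts to ADP with probability
#' `1 - exp(-k_h dt)`.  ADP is permanent.
#'
#' @param state a [pb_state()].
#' @param pair_binding_energies either the `binding_pairs` data.frame from
#'   [total_forces()] or a per-subunit numeric vector of strongest binding
#'   magnitudes.
#' @param params a [chemistry_params()] object.
#' @param dt chemistry time step.
#' @param seed RNG seed for this step.
#' @return list with the updated `state` and an `events` data.frame.
#' @export
hydrolysis_step <- function(state, pair_binding_energies, params, dt, seed = 1L) {
  n <- n_subunits(state)
  if (is.data.frame(pair_binding_energies)) {
    mb <- numeric(n)
    tb <- pair_binding_energies
    if (nrow(tb)) {
      agg <- tapply(-tb$energy, tb$para_id, max)
      mb[as.integer(names(agg))] <- agg
    }
  } else {
    mb <- as.numeric(pair_binding_energies)
    stopifnot(length(mb) == n)
  }
  chem_call(state, "hydrolysis", params, dt, seed, maxbind = mb)
}

#' Tip-only depolymerization step
#'
#' Each hydrolyzed (ADP) subunit currently at a free filament tip detaches
#' with probability `1 - exp(-k_d dt)`, losing every interaction except
#' excluded volume; the neighbor toward the anchor becomes the new tip.
#' Anchored terminal subunits never depolymerize.
#'
#' @inheritParams hydrolysis_step
#' @return list with the updated `state` and an `events` data.frame.
#' @export
depolymerization_step <- function(state, params, dt, seed = 1L) {
  chem_call(state, "depolymerization", params, dt, seed)
}

#' Severing step
#'
#' Each interior ADP subunit cuts its filament with probability
#' `1 - exp(-k_d dt)`: the severed subunit becomes a free monomer and the two
#' flanking runs become separate chains.  Fragments keep their bonds and
#' their ability to bind ParB; crosslinks spanning the cut are removed;
#' fragments are not anchored.
#'
#' @inheritParams hydrolysis_step
#' @return list with the updated `state` and an `events` data.frame.
#' @export
severing_step <- function(state, params, dt, seed = 1L) {
  if (params$disassembly_mode != "SEVERING")
    stop("severing_step requires disassembly_mode = 'SEVERING'")
  chem_call(state, "severing", params, dt, seed)
}

#' Audit system topology
#'
#' Verifies subunit-count conservation since t = 0, that every chain
#' references live, unique subunits, that each anchored-built filament has
#' exactly one anchored end (its pole-side terminal subunit), and that no
#' ATP subunit is a detached monomer.
#'
#' @param state a [pb_state()].
#' @return list with logical `pass` and a character vector `diagnostics`.
#' @export
audit_topology <- function(state) {
  diag <- character(0)
  n <- n_subunits(state)
  n_para <- sum(state$species == "PARA")
  if (n_para != state$n_para0)
    diag <- c(diag, sprintf("ParA count %d differs from initial %d", n_para, state$n_para0))
  all_ids <- unlist(state$chains)
  if (length(all_ids)) {
    if (any(all_ids < 1 | all_ids > n))
      diag <- c(diag, "chain references out-of-range subunit id")
    if (anyDuplicated(all_ids))
      diag <- c(diag, "subunit appears in more than one chain position")
  }
  for (c in seq_along(state$chains)) {
    ch <- state$chains[[c]]
    if (length(ch) == 0) { diag <- c(diag, sprintf("chain %d is empty", c)); next }
    anch <- state$anchored[ch]
    if (state$chain_anchored[c]) {
      if (sum(anch) != 1 || !anch[length(ch)])
        diag <- c(diag, sprintf("anchored chain %d lacks exactly one anchored pole end", c))
    } else if (any(anch)) {
      diag <- c(diag, sprintf("unanchored chain %d contains an anchored subunit", c))
    }
  }
  m <- chain_membership(state)
  mono_atp <- state$species == "PARA" & m$chain_id == 0 & state$nucleotide == "ATP"
  if (any(mono_atp))
    diag <- c(diag, sprintf("%d detached ATP subunit(s)", sum(mono_atp)))
  if (nrow(state$crosslinks)) {
    xl <- as.vector(state$crosslinks)
    if (any(m$chain_id[xl] == 0))
      diag <- c(diag, "crosslink references a depolymerized subunit")
  }
  list(pass = length(diag) == 0, diagnostics = diag)
}
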