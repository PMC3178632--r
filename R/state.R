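#' Create a system state
#'
#' A `pb_state` bundles the positions, polarization vectors, species and
#' nucleotide labels, per-subunit drag factors, anchoring flags, and topology
#' (chains and crosslinks) of every subunit at one time point.  ParA chains
#' are stored tip-to-anchor: element 1 is the free (disassembling) tip at
#' small x, the last element sits at the pole (large x) and is anchored when
#' the bundle is anchored.
#'
#' @param pos N x 3 matrix of positions (units of the subunit diameter a).
#' @param pol N x 3 matrix of unit polarization vectors.
#' @param species character vector: `"PARA"`, `"PARB_BIND"`, `"PARB_INERT"`.
#' @param nucleotide character vector: `"ATP"`, `"ADP"`, `"NONE"` (non-ParA
#'   subunits must be `"NONE"`).
#' @param alpha per-subunit drag factor (multiplies the reference drag).
#' @param anchored logical vector; anchored subunits never move.
#' @param chains list of integer vectors of subunit ids (1-based).
#' @param chain_anchored logical, one per chain: built with an anchored end.
#' @param crosslinks m x 2 integer matrix of crosslinked subunit pairs.
#' @param time simulation time of this state.
#' @param n_para0 initial ParA subunit count (conservation reference).
#' @return an object of class `pb_state`.
#' @export
pb_state <- function(pos, pol, species, nucleotide, alpha, anchored,
                     chains, chain_anchored, crosslinks,
                     time = 0, n_para0 = sum(species == "PARA")) {
  n <- nrow(pos)
  stopifnot(nrow(pol) == n, length(species) == n, length(nucleotide) == n,
            length(alpha) == n, length(anchored) == n,
            length(chains) == length(chain_anchored))
  if (is.null(dim(crosslinks))) crosslinks <- matrix(integer(0), 0, 2)
  species_code(species); nuc_code(nucleotide)  # validate labels
  nrm <- sqrt(rowSums(pol^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("polarization vectors must be unit length")
  if (any(nucleotide != "NONE" & species != "PARA"))
    stop("nucleotide state must be NONE unless species is PARA")
  st <- list(pos = pos, pol = pol, species = species, nucleotide = nucleotide,
             alpha = as.numeric(alpha), anchored = as.logical(anchored),
             chains = lapply(chains, as.integer),
             chain_anchored = as.logical(chain_anchored),
             crosslinks = matrix(as.integer(crosslinks), ncol = 2),
             time = time, n_para0 = as.integer(n_para0))
  class(st) <- "pb_state"
  st
}

#' Number of subunits in a state
#' @param state a `pb_state`.
#' @return integer count.
#' @export
n_subunits <- function(state) nrow(state$pos)

#' Per-subunit chain membership
#'
#' @param state a `pb_state`.
#' @return list with integer vectors `chain_id` and `chain_index` (both 0 for
#'   monomers not belonging to any chain).
#' @export
chain_membership <- function(state) {
  n <- n_subunits(state)
  id <- integer(n); idx <- integer(n)
  for (c in seq_along(state$chains)) {
    ch <- state$chains[[c]]
    id[ch] <- c
    idx[ch] <- seq_along(ch)
  }
  list(chain_id = id, chain_index = idx)
}

#' @export
print.pb_state <- function(x, ...) {
  m <- chain_membership(x)
  cat("pb_state:", n_subunits(x), "subunits at t =", format(x$time), "\n")
  cat("  ParA:", sum(x$species == "PARA"),
      "(", sum(x$species == "PARA" & m$chain_id > 0), "polymerized )",
      " ParB:", sum(x$species != "PARA"), "\n")
  cat("  chains:", length(x$chains), " crosslinks:", nrow(x$crosslinks), "\n")
  invisible(x)
}

# pack a state into the argument list the C++ core expects
state_args <- function(state) {
  list(pos = state$pos, pol = state$pol,
       species = species_code(state$species),
       nuc = nuc_code(state$nucleotide),
       alpha = state$alpha, anchored = state$anchored,
       chains = state$chains, chainAnchored = state$chain_anchored,
       xlinks = state$crosslinks, t = state$time, n_para0 = state$n_para0)
}

# rebuild a pb_state from the list a C++ call returns
state_from_core <- function(old, out) {
  pb_state(pos = out$pos, pol = out$pol, species = old$species,
           nucleotide = .NUC_LEVELS[out$nucleotide + 1L],
           alpha = old$alpha, anchored = old$anchored,
           chains = out$chains, chain_anchored = out$chain_anchored,
           crosslinks = if (nrow(out$crosslinks)) out$crosslinks else matrix(integer(0), 0, 2),
           time = if (!is.null(out$time)) out$time else old$time,
           n_para0 = old$n_para0)
}
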