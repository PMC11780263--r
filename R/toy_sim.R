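#' Configuration of an overdamped Langevin bead-spring simulation
#'
#' First-order (Brownian) dynamics: the cheapest scheme with the correct
#' Boltzmann stationary distribution. Units are reduced but chosen to
#' read like GROMACS conventions: lengths in nm, energies in kJ/mol
#' (`kT = 2.494` is ~300 K), spring constants in kJ mol^-1 nm^-2,
#' friction in reduced inverse time with `friction = 1`.
#'
#' The default timestep keeps `dt * k_max / friction` below 0.1 for the
#' default backbone spring stiffness (the stability limit of the Euler
#' scheme); raise `dt` only together with softer springs.
#'
#' @param n_steps integration steps.
#' @param dt timestep (reduced time).
#' @param kT thermal energy (kJ/mol); 0 gives steepest-descent-like
#'   noiseless relaxation.
#' @param friction friction coefficient gamma (inverse time).
#' @param seed RNG seed; the trajectory is bit-reproducible given the
#'   seed.
#' @param bonded_backbone add stiff chain springs between consecutive
#'   beads of each chain (rest length = observed distance in the start
#'   structure unless `backbone_r0` is set).
#' @param backbone_k chain spring constant (kJ mol^-1 nm^-2).
#' @param backbone_r0 fixed chain spring rest length (nm), or `NULL` for
#'   the observed start-structure distances.
#' @param report_every record a frame every this many steps.
#' @param sanity_bound abort if any coordinate exceeds this (nm).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 100000, dt = 5e-5, kT = 2.494,
                       friction = 1, seed = 1, bonded_backbone = TRUE,
                       backbone_k = 1250, backbone_r0 = NULL,
                       report_every = 200, sanity_bound = 1000) {
  stopifnot(n_steps >= 1, dt > 0, kT >= 0, friction > 0,
            report_every >= 1, sanity_bound > 0)
  structure(list(n_steps = as.integer(n_steps), dt = dt, kT = kT,
                 friction = friction, seed = as.integer(seed),
                 bonded_backbone = isTRUE(bonded_backbone),
                 backbone_k = backbone_k, backbone_r0 = backbone_r0,
                 report_every = as.integer(report_every),
                 sanity_bound = sanity_bound),
            class = "sim_config")
}

# Constraint table of a network plus optional backbone chain springs.
sim_constraints <- function(start, net, cfg) {
  cn <- net$constraints[, c("i", "j", "d0", "k")]
  if (cfg$bonded_backbone) {
    b <- start$beads
    x <- coords(start)
    i <- which(b$chain[-nrow(b)] == b$chain[-1] &
               diff(b$resid) == 1L)
    if (length(i)) {
      r0 <- if (is.null(cfg$backbone_r0))
        sqrt(rowSums((x[i, , drop = FALSE] - x[i + 1, , drop = FALSE])^2))
      else rep(cfg$backbone_r0, length(i))
      cn <- rbind(cn, data.frame(i = i, j = i + 1L, d0 = r0,
                                 k = rep(cfg$backbone_k, length(i))))
    }
  }
  cn
}

#' Run overdamped Langevin dynamics on a bead-spring network
#'
#' Integrates `x <- x - (dt/gamma) grad U + sqrt(2 kT dt/gamma) xi`
#' with `U = sum 1/2 k (d - d0)^2` over the elastic network (plus chain
#' springs when `cfg$bonded_backbone`). The returned frameset starts
#' with the initial coordinates, followed by one frame every
#' `cfg$report_every` steps. Deterministic given `cfg$seed`.
#'
#' @param start [bead_structure] starting coordinates.
#' @param net `elastic_network` whose indices refer to `start`.
#' @param cfg [sim_config].
#' @return A [frameset]; attribute `"seed"` records the seed used.
#' @export
run_langevin <- function(start, net, cfg = sim_config()) {
  cn <- sim_constraints(start, net, cfg)
  nb <- n_beads(start)
  if (nrow(cn) && (max(cn$i, cn$j) > nb || min(cn$i, cn$j) < 1))
    stop("network indices out of range for the start structure")
  set.seed(cfg$seed)
  fr <- langevin_core(coords(start), as.integer(cn$i), as.integer(cn$j),
                      cn$d0, cn$k, cfg$n_steps, cfg$dt, cfg$kT,
                      cfg$friction, cfg$report_every, cfg$sanity_bound)
  xyz <- array(0, dim = c(nb, 3, dim(fr)[3] + 1))
  xyz[, , 1] <- coords(start)
  xyz[, , -1] <- fr
  out <- frameset(xyz, start$beads,
                  times = cfg$dt * cfg$report_every *
                    (0:(dim(xyz)[3] - 1)))
  attr(out, "seed") <- cfg$seed
  out
}

#' Potential energy of a configuration under a constraint table
#'
#' `U = sum 1/2 k (d - d0)^2` over the network (and chain springs if the
#' config enables them) — used to verify noiseless relaxation.
#'
#' @param xyz n x 3 coordinates (nm).
#' @param start the [bead_structure] the network refers to.
#' @param net `elastic_network`.
#' @param cfg [sim_config] (controls backbone springs).
#' @return energy (kJ/mol).
#' @export
network_energy <- function(xyz, start, net, cfg = sim_config()) {
  cn <- sim_constraints(start, net, cfg)
  d <- sqrt(rowSums((xyz[cn$i, , drop = FALSE] -
                     xyz[cn$j, , drop = FALSE])^2))
  sum(0.5 * cn$k * (d - cn$d0)^2)
}

# Carry a network built on `other` onto `own`'s bead indexing through a
# residue map (own -> other); constraints with unmapped endpoints are
# dropped.
transfer_network <- function(net_other, map_own_to_other, n_own) {
  inv <- rep(NA_integer_, max(map_own_to_other$pairs$idx_b))
  inv[map_own_to_other$pairs$idx_b] <- map_own_to_other$pairs$idx_a
  cn <- net_other$constraints
  oi <- ifelse(cn$i <= length(inv), inv[cn$i], NA_integer_)
  oj <- ifelse(cn$j <= length(inv), inv[cn$j], NA_integer_)
  ok <- !is.na(oi) & !is.na(oj)
  i <- pmin(oi[ok], oj[ok]); j <- pmax(oi[ok], oj[ok])
  new_elastic_network(data.frame(i = i, j = j, d0 = cn$d0[ok],
                                 k = cn$k[ok]),
                      net_other$params,
                      paste0(net_other$state_label, ":transferred"))
}

#' Interstate sampling assay: single-state networks vs the common network
#'
#' Runs three Langevin simulations from state A under (1) state A's full
#' elastic network, (2) state B's full network carried onto A's topology
#' (reference distances of the other state), and (3) the
#' common-constraints (ComDYN) filtered network. For each run it reports
#' the minimum RMSD reached to either state and the fraction of frames
#' inside an RMSD basin around each state. A full single-state network
#' pins the simulation to its state; the common network should reach
#' conformations close to both states and the intermediates between
#' them.
#'
#' The default simulation length and temperature are calibrated on the
#' default rocker bundle of [bundle_spec()]: `kT = 1` keeps local
#' fluctuations under the full network well inside the basin radius
#' while the hinge mode freed by the filter explores the interstate
#' path, and 4e5 steps give the hinge time to diffuse into the far
#' basin.
#'
#' @param state_a,state_b [bead_structure] of the two states.
#' @param map [map_residues()] result relating A to B.
#' @param params [en_params].
#' @param cfg [sim_config]; `cfg$seed` seeds all three runs.
#' @param basin_frac basin radius as a fraction of the interstate RMSD
#'   (a frame is "in" a state's basin if its RMSD to that state is below
#'   `basin_frac * rmsd(A, B)`).
#' @param burn_in fraction of initial frames discarded before computing
#'   the metrics, so each run is scored on its relaxed ensemble (the run
#'   under the other state's network needs this to leave the shared
#'   starting point before being measured).
#' @return data.frame with one row per run (`network` in
#'   `c("full_A", "full_B", "comdyn")`) and columns `n_constraints`,
#'   `min_rmsd_to_a`, `min_rmsd_to_b`, `frac_basin_a`, `frac_basin_b`;
#'   attributes `"interstate_rmsd"` and `"basin_cut"` (nm).
#' @export
transition_assay <- function(state_a, state_b, map, params = en_params(),
                             cfg = sim_config(n_steps = 400000, kT = 1,
                                              report_every = 500),
                             basin_frac = 0.6, burn_in = 0.2) {
  net_a <- build_network(state_a, params)
  net_b <- build_network(state_b, params)
  net_b_on_a <- transfer_network(net_b, map, n_beads(state_a))
  net_cd <- comdyn_filter(net_a, state_a, state_b, map, params)$filtered

  xa <- coords(state_a)
  # compare on the mapped bead subset so homolog pairs are handled too
  ia <- map$pairs$idx_a; ib <- map$pairs$idx_b
  xb_on_a <- coords(state_b)[ib, , drop = FALSE]
  xa_sub <- xa[ia, , drop = FALSE]
  d_ab <- fit_rmsd(xa_sub, xb_on_a)
  basin_cut <- basin_frac * d_ab

  run_one <- function(net, label) {
    fr <- run_langevin(state_a, net, cfg)
    use <- seq(floor(burn_in * n_frames(fr)) + 1, n_frames(fr))
    ra <- rb <- numeric(length(use))
    for (k in seq_along(use)) {
      xs <- fr$xyz[ia, , use[k], drop = FALSE][, , 1]
      ra[k] <- fit_rmsd(xs, xa_sub)
      rb[k] <- fit_rmsd(xs, xb_on_a)
    }
    data.frame(network = label, n_constraints = nrow(net$constraints),
               min_rmsd_to_a = min(ra), min_rmsd_to_b = min(rb),
               frac_basin_a = mean(ra < basin_cut),
               frac_basin_b = mean(rb < basin_cut),
               stringsAsFactors = FALSE)
  }
  out <- rbind(run_one(net_a, "full_A"),
               run_one(net_b_on_a, "full_B"),
               run_one(net_cd, "comdyn"))
  attr(out, "interstate_rmsd") <- d_ab
  attr(out, "basin_cut") <- basin_cut
  out
}
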