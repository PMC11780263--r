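#' Specification of a synthetic two-state helix bundle
#'
#' Describes an idealized ring of transmembrane-like helices in two
#' conformational states, with closed-form geometry so every inter-bead
#' distance and its interstate change is known exactly. Two motion types
#' are available:
#'
#' \describe{
#'   \item{rocker (default)}{the two halves of the ring are rigid
#'     domains; state B rotates one domain by `hinge_deg` about a
#'     horizontal hinge axis through the bundle centre at mid-height
#'     (the axis pierces the two inter-domain seams). This is the
#'     alternating-access archetype: all intra-domain distances are
#'     exactly state-invariant, seam contacts far from the hinge change
#'     strongly, and only a thin seam band near mid-height changes by
#'     less than the common-constraints threshold. The common network
#'     therefore reduces to two rigid bodies joined by a mid-height
#'     hinge, with the interstate rotation as its single soft degree of
#'     freedom.}
#'   \item{breathe}{the ring radius at the "in" end (z = 0) differs
#'     between the states (`radius_a` vs `radius_b`) and splay (tilt)
#'     angles change the radius linearly along z; with the default
#'     splays each state's out-end radius equals the other state's
#'     in-end radius, a symmetric in-closes/out-opens motion. Useful for
#'     closed-form order-parameter truth, since segment centroid
#'     distances follow directly from the radii.}
#' }
#'
#' By default each helix winds at 100 degrees/residue on a 0.23 nm
#' radius around its axis (the C-alpha geometry of an ideal alpha
#' helix). The wind matters mechanically: it gives the elastic
#' constraints out-of-plane orientations, so collective bending and
#' shearing of the bundle meet first-order restoring forces and a full
#' single-state network genuinely pins its state. `twist = FALSE` gives
#' straight rods of beads, handy when a closed-form segment-centroid
#' truth is wanted (centroid order parameters are insensitive to the
#' wind).
#'
#' With six helices the adjacent-helix separation equals the ring
#' radius; the defaults (0.8 nm for rocker, 0.7 vs 0.9 nm for breathe)
#' keep every separation inside the default 0.5-0.9 nm elastic shell,
#' so each state's full network braces the bundle at every height.
#'
#' @param n_helices number of helices in the ring (even, so the rocker
#'   domains split cleanly).
#' @param residues_per_helix beads per helix.
#' @param helix_rise axial bead spacing, nm/residue.
#' @param motion "rocker" or "breathe".
#' @param hinge_deg rocker rotation angle in degrees (default 28,
#'   giving an interstate backbone RMSD of ~0.26 nm: the moving domain's
#'   helix ends swing far beyond the 0.1 nm common-constraints
#'   threshold while the seam band kept by the filter stays thin).
#' @param radius_a,radius_b ring radius at the "in" end (z = 0), nm;
#'   `NULL` gives 0.8/0.8 (rocker) or 0.7/0.9 (breathe).
#' @param splay_a,splay_b tilt angles in degrees (positive tilts
#'   helices outwards with increasing z); `NULL` gives 0 for rocker and
#'   the symmetric-rocker default for breathe (each state's out-end
#'   radius equals the other state's in-end radius).
#' @param noise_sigma isotropic Gaussian coordinate noise, nm.
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @param twist helical winding on (default) or straight rods.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 6, residues_per_helix = 24,
                        helix_rise = 0.15,
                        motion = c("rocker", "breathe"), hinge_deg = 28,
                        radius_a = NULL, radius_b = NULL,
                        splay_a = NULL, splay_b = NULL,
                        noise_sigma = 0, seed = 1, twist = TRUE) {
  motion <- match.arg(motion)
  stopifnot(n_helices >= 2, residues_per_helix >= 1, helix_rise > 0,
            noise_sigma >= 0)
  if (motion == "rocker" && n_helices %% 2 != 0)
    stop("rocker motion needs an even helix count")
  if (is.null(radius_a)) radius_a <- if (motion == "rocker") 0.8 else 0.7
  if (is.null(radius_b)) radius_b <- if (motion == "rocker") radius_a else 0.9
  stopifnot(radius_a > 0, radius_b > 0)
  height <- (residues_per_helix - 1) * helix_rise
  if (is.null(splay_a))
    splay_a <- if (motion == "rocker") 0 else
      atan2(radius_b - radius_a, height) * 180 / pi
  if (is.null(splay_b))
    splay_b <- if (motion == "rocker") 0 else
      atan2(radius_a - radius_b, height) * 180 / pi
  structure(list(n_helices = as.integer(n_helices),
                 residues_per_helix = as.integer(residues_per_helix),
                 helix_rise = helix_rise, motion = motion,
                 hinge_deg = hinge_deg,
                 radius_a = radius_a, radius_b = radius_b,
                 splay_a = splay_a, splay_b = splay_b,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 twist = isTRUE(twist)),
            class = "bundle_spec")
}

# Ideal coordinates of one state. Helices sit at ring phases offset by
# half a sector so that no helix lies on the rocker seam plane (y = 0);
# the first n/2 helices are the fixed domain (y > 0), the rest the
# moving domain.
bundle_coords <- function(spec, radius, splay_deg, hinge_rad = 0) {
  nh <- spec$n_helices; nr <- spec$residues_per_helix
  phi <- 2 * pi * (seq_len(nh) - 1) / nh + pi / nh
  z <- (seq_len(nr) - 1) * spec$helix_rise
  r <- radius + tan(splay_deg * pi / 180) * z
  x <- matrix(0, nh * nr, 3)
  for (h in seq_len(nh)) {
    rows <- (h - 1) * nr + seq_len(nr)
    x[rows, 1] <- r * cos(phi[h])
    x[rows, 2] <- r * sin(phi[h])
    x[rows, 3] <- z
    if (spec$twist) {
      # wind at 0.23 nm around the axis; 100 deg per residue
      psi <- (seq_len(nr) - 1) * 100 * pi / 180
      u <- c(cos(phi[h] + pi / 2), sin(phi[h] + pi / 2), 0)  # tangent
      v <- c(cos(phi[h]), sin(phi[h]), 0)                     # radial
      x[rows, ] <- x[rows, ] + 0.23 * (outer(cos(psi), v) + outer(sin(psi), u))
    }
  }
  if (hinge_rad != 0) {
    zmid <- max(z) / 2
    moving <- rep(seq_len(nh) > nh / 2, each = nr)
    y0 <- x[moving, 2]; z0 <- x[moving, 3] - zmid
    x[moving, 2] <- y0 * cos(hinge_rad) - z0 * sin(hinge_rad)
    x[moving, 3] <- zmid + y0 * sin(hinge_rad) + z0 * cos(hinge_rad)
  }
  x
}

bundle_beads <- function(spec, xyz) {
  nh <- spec$n_helices; nr <- spec$residues_per_helix
  data.frame(chain = rep(LETTERS[seq_len(nh)], each = nr),
             resid = rep(seq_len(nr), nh),
             resname = "ALA",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-state helix bundle with known ground truth
#'
#' Emits the two conformational states of the bundle described by a
#' [bundle_spec], the identity residue map between them, in/out segment
#' definitions for each helix (first and last `seg_len` residues), and a
#' truth table listing, for every elastic-network-eligible bead pair in
#' either state, its distance in both states and the interstate |delta
#' d|. The truth table is computed by a direct double loop over bead
#' pairs, independent of [build_network()]'s implementation, so the kept
#' set of [comdyn_filter()] is known a priori. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [bundle_spec].
#' @param params [en_params] defining eligibility for the truth table.
#' @param seg_len segment window length (default 10).
#' @return list with `state_a`, `state_b` ([bead_structure]), `map`
#'   (identity `residue_map`), `segments` (list of [segment_def]), and
#'   `truth` (data.frame `i`, `j`, `d_a`, `d_b`, `delta_d`, `en_a`,
#'   `en_b` over pairs eligible in at least one state).
#' @export
make_two_state_bundle <- function(spec = bundle_spec(),
                                  params = en_params(), seg_len = 10) {
  xa <- bundle_coords(spec, spec$radius_a, spec$splay_a)
  xb <- bundle_coords(spec, spec$radius_b, spec$splay_b,
                      hinge_rad = if (spec$motion == "rocker")
                        spec$hinge_deg * pi / 180 else 0)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    xa <- xa + matrix(stats::rnorm(length(xa), 0, spec$noise_sigma), ncol = 3)
    xb <- xb + matrix(stats::rnorm(length(xb), 0, spec$noise_sigma), ncol = 3)
  }
  state_a <- bead_structure(bundle_beads(spec, xa), "A", "synthetic")
  state_b <- bead_structure(bundle_beads(spec, xb), "B", "synthetic")
  map <- map_residues(state_a, state_b, mode = "identity")

  nh <- spec$n_helices; nr <- spec$residues_per_helix
  if (nr < seg_len)
    stop("residues_per_helix smaller than segment length")
  segments <- list()
  for (h in seq_len(nh)) {
    segments[[2 * h - 1]] <- segment_def(h, "in", LETTERS[h],
                                         1, seg_len, length = seg_len)
    segments[[2 * h]] <- segment_def(h, "out", LETTERS[h],
                                     nr - seg_len + 1, nr, length = seg_len)
  }

  # truth table by naive enumeration, independent of build_network()
  b <- state_a$beads
  n <- nrow(b)
  rows <- vector("list", 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (b$chain[i] == b$chain[j] &&
          abs(b$resid[i] - b$resid[j]) < params$min_seq_sep) next
      da <- sqrt(sum((xa[i, ] - xa[j, ])^2))
      db <- sqrt(sum((xb[i, ] - xb[j, ])^2))
      ea <- da >= params$lower_cutoff && da <= params$upper_cutoff
      eb <- db >= params$lower_cutoff && db <= params$upper_cutoff
      if (ea || eb)
        rows[[length(rows) + 1]] <- data.frame(
          i = i, j = j, d_a = da, d_b = db, delta_d = abs(da - db),
          en_a = ea, en_b = eb)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(state_a = state_a, state_b = state_b, map = map,
       segments = segments, truth = truth)
}

#' Gaussian-mixture distance series emulating basin sampling
#'
#' Draws a distance series from a mixture of Gaussian basins, to stand in
#' for order-parameter traces of simulations that sample one or several
#' conformational basins: a two-basin mixture mimics a wild type visiting
#' both states, a single displaced component mimics a pathogenic-like
#' mutant locked away from them. Overlap and shift of such series against
#' each other are analytically known from the mixture parameters.
#'
#' @param basin_centers basin mean distances, nm.
#' @param weights mixture weights (normalized to sum 1).
#' @param sigma common component standard deviation, nm.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param label series label.
#' @return A `distance_series` (see [segment_distance()]).
#' @export
make_mutant_like_series <- function(basin_centers, weights = NULL,
                                    sigma = 0.05, n = 1000, seed = 1,
                                    label = "synthetic") {
  k <- length(basin_centers)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0)
    stop("invalid mixture weights")
  weights <- weights / sum(weights)
  set.seed(seed)
  comp <- sample.int(k, n, replace = TRUE, prob = weights)
  distance_series(stats::rnorm(n, basin_centers[comp], sigma), label)
}
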