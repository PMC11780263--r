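#' Elastic-network build and filter parameters
#'
#' Parameters follow the standard MARTINI martinize elastic-network
#' convention: harmonic restraints between backbone beads whose reference
#' distance lies in a 0.5-0.9 nm shell, with force constant 500
#' kJ mol^-1 nm^-2, applied only between residues at least `min_seq_sep`
#' apart along the chain (closer neighbours are handled by the bonded
#' terms of the coarse-grained topology, not by the elastic network).
#' `comdyn_threshold` is the common-constraints cutoff: a constraint is
#' retained in the interstate (ComDYN) network only if its reference
#' distance differs by at most this amount (default 0.1 nm, i.e. 1 A)
#' between the two conformational states.
#'
#' @param lower_cutoff,upper_cutoff distance shell in nm.
#' @param force_constant spring constant, kJ mol^-1 nm^-2.
#' @param min_seq_sep minimum |resid(i) - resid(j)| within a chain;
#'   cross-chain pairs are always eligible.
#' @param comdyn_threshold interstate agreement cutoff in nm.
#' @return An object of class `en_params`.
#' @export
en_params <- function(lower_cutoff = 0.5, upper_cutoff = 0.9,
                      force_constant = 500, min_seq_sep = 3,
                      comdyn_threshold = 0.1) {
  stopifnot(lower_cutoff >= 0, lower_cutoff < upper_cutoff,
            force_constant > 0, comdyn_threshold > 0, min_seq_sep >= 0)
  structure(list(lower_cutoff = lower_cutoff, upper_cutoff = upper_cutoff,
                 force_constant = force_constant,
                 min_seq_sep = as.integer(min_seq_sep),
                 comdyn_threshold = comdyn_threshold),
            class = "en_params")
}

#' @export
print.en_params <- function(x, ...) {
  cat(sprintf(paste0("en_params: shell %.2f-%.2f nm, k = %g kJ/mol/nm^2, ",
                     "min_seq_sep %d, comdyn threshold %.2f nm\n"),
              x$lower_cutoff, x$upper_cutoff, x$force_constant,
              x$min_seq_sep, x$comdyn_threshold))
  invisible(x)
}

new_elastic_network <- function(constraints, params, state_label = "") {
  constraints <- as.data.frame(constraints)
  structure(list(constraints = constraints, params = params,
                 state_label = state_label),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network '%s': %d constraints\n",
              x$state_label, nrow(x$constraints)))
  invisible(x)
}

#' Build a backbone elastic network for one conformational state
#'
#' All and only the bead pairs whose observed distance lies in
#' `[lower_cutoff, upper_cutoff]` and whose sequence separation (within a
#' chain) is at least `min_seq_sep` become harmonic constraints, with the
#' observed distance as the reference length `d0`. The network therefore
#' encodes — and pins the protein to — the particular conformational
#' state it was built from.
#'
#' @param s [bead_structure] (at least 2 beads).
#' @param params [en_params].
#' @return An `elastic_network`: list with `constraints` (data.frame `i`,
#'   `j` bead indices with i < j, `d0` nm, `k`), `params`, `state_label`.
#' @export
build_network <- function(s, params = en_params()) {
  if (n_beads(s) < 2) stop("need at least 2 beads")
  x <- coords(s)
  d <- as.matrix(stats::dist(x))
  b <- s$beads
  same_chain <- outer(b$chain, b$chain, "==")
  seq_sep <- abs(outer(b$resid, b$resid, "-"))
  eligible <- d >= params$lower_cutoff & d <= params$upper_cutoff &
    (!same_chain | seq_sep >= params$min_seq_sep)
  eligible[lower.tri(eligible, diag = TRUE)] <- FALSE
  idx <- which(eligible, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  new_elastic_network(
    data.frame(i = unname(idx[, 1]), j = unname(idx[, 2]),
               d0 = d[idx], k = rep(params$force_constant, nrow(idx))),
    params, s$label)
}

#' Filter an elastic network to the interstate common constraints
#'
#' The core of the ComDYN scheme: keep only those constraints of a
#' single-state elastic network whose reference distance agrees, within
#' `comdyn_threshold`, with the distance between the corresponding beads
#' in the other conformational state. Constraints pinning one state are
#' removed, so the remaining common network maintains the fold while
#' permitting the interstate transition. The filter is applied per state:
#' filtering state A's network against state B is independent of the
#' reverse, and the kept counts generally differ.
#'
#' Constraints with an endpoint that has no counterpart in the other state
#' cannot be checked; by default they are dropped (`unmapped = "drop"`,
#' the conservative choice), or retained with `unmapped = "keep"`.
#'
#' @param net `elastic_network` built from `own`.
#' @param own the [bead_structure] the network was built from.
#' @param other the [bead_structure] of the other conformational state.
#' @param map [map_residues()] result relating `own` to `other`.
#' @param params [en_params]; `params$comdyn_threshold` is the cutoff.
#' @param unmapped policy for constraints with unmapped endpoints.
#' @param strict if `TRUE` use a strict `<` comparison instead of the
#'   default inclusive `<=`.
#' @return An object of class `comdyn_result`: list with `filtered`
#'   (the reduced `elastic_network`), `n_input`, `n_kept`,
#'   `kept_fraction`, and `dropped` (data.frame of dropped pairs with
#'   their interstate |delta d|, `NA` where an endpoint was unmapped).
#' @export
comdyn_filter <- function(net, own, other, map, params = net$params,
                          unmapped = c("drop", "keep"), strict = FALSE) {
  unmapped <- match.arg(unmapped)
  if (!inherits(map, "residue_map") || nrow(map$pairs) == 0)
    stop("empty or invalid residue map")
  cn <- net$constraints
  lut <- rep(NA_integer_, n_beads(own))
  lut[map$pairs$idx_a] <- map$pairs$idx_b
  mi <- lut[cn$i]; mj <- lut[cn$j]
  xo <- coords(other)
  dd <- rep(NA_real_, nrow(cn))
  ok <- !is.na(mi) & !is.na(mj)
  if (any(ok))
    dd[ok] <- abs(sqrt(rowSums((xo[mi[ok], , drop = FALSE] -
                                xo[mj[ok], , drop = FALSE])^2)) - cn$d0[ok])
  thr <- params$comdyn_threshold
  pass <- if (strict) dd < thr else dd <= thr
  keep <- ifelse(is.na(dd), unmapped == "keep", pass)
  res <- structure(list(
    filtered = new_elastic_network(cn[keep, , drop = FALSE], net$params,
                                   paste0(net$state_label, ":comdyn")),
    n_input = nrow(cn), n_kept = sum(keep),
    kept_fraction = sum(keep) / nrow(cn),
    dropped = cbind(cn[!keep, c("i", "j", "d0"), drop = FALSE],
                    delta_d = dd[!keep])),
    class = "comdyn_result")
  rownames(res$filtered$constraints) <- NULL
  rownames(res$dropped) <- NULL
  res
}

#' @export
print.comdyn_result <- function(x, ...) {
  cat(sprintf("comdyn_result: kept %d of %d constraints (%.1f%%)\n",
              x$n_kept, x$n_input, 100 * x$kept_fraction))
  invisible(x)
}

#' Write an elastic network as a GROMACS itp bonded section
#'
#' Produces a `[ bonds ]` section with lines `i j funct d0 k` (1-based
#' atom indices, `d0` in nm to 5 decimals) and a header comment recording
#' the build parameters and, when the network came through
#' [comdyn_filter()], the kept/input counts.
#'
#' @param net `elastic_network`.
#' @param path output file.
#' @param funct GROMACS bond function type: 1 (harmonic bond) or 6
#'   (harmonic restraint without exclusions).
#' @param counts optional `c(n_kept, n_input)` recorded in the header.
#' @return `path`, invisibly.
#' @export
write_topology <- function(net, path, funct = 1, counts = NULL) {
  if (!funct %in% c(1, 6)) stop("funct must be 1 or 6")
  p <- net$params
  hdr <- c(
    sprintf("; elastic network '%s'", net$state_label),
    sprintf("; lower_cutoff %.5f nm, upper_cutoff %.5f nm, k %g, min_seq_sep %d, comdyn_threshold %.5f nm",
            p$lower_cutoff, p$upper_cutoff, p$force_constant,
            p$min_seq_sep, p$comdyn_threshold),
    if (!is.null(counts)) sprintf("; kept %d of %d constraints", counts[1], counts[2]),
    "[ bonds ]",
    "; i  j  funct  d0(nm)  k")
  cn <- net$constraints
  lines <- sprintf("%d %d %d %.5f %g", cn$i, cn$j, funct, cn$d0, cn$k)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an elastic network from a GROMACS itp bonded section
#'
#' Inverse of [write_topology()]. Comment and section-header lines are
#' ignored; every data line must parse as `i j funct d0 k` with a known
#' funct (1 or 6), otherwise an error naming the line number is raised.
#'
#' @param path itp-style file written by [write_topology()].
#' @param params [en_params] to attach (the file header is a comment and
#'   is not parsed back).
#' @return An `elastic_network`.
#' @export
read_topology <- function(path, params = en_params()) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*(;|\\[|$)", raw)
  lns <- which(keep)
  if (length(lns) == 0) return(new_elastic_network(
    data.frame(i = integer(0), j = integer(0), d0 = numeric(0),
               k = numeric(0)), params))
  rows <- lapply(lns, function(n) {
    f <- strsplit(trimws(raw[n]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(f) != 5 || anyNA(v))
      stop("malformed topology line ", n, ": '", raw[n], "'")
    if (!v[3] %in% c(1, 6))
      stop("unknown funct ", v[3], " at line ", n)
    v
  })
  m <- do.call(rbind, rows)
  new_elastic_network(
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
               d0 = m[, 4], k = m[, 5]),
    params)
}

#' End-to-end interstate constraint counts for two PDB structures
#'
#' Convenience pipeline reproducing the published verification numbers for
#' a transporter with two solved conformational states: read both
#' structures as backbone beads, map residues by end-gap-free global
#' sequence alignment (the structures may be close homologs rather than
#' the same protein), build each state's elastic network, and filter each
#' against the other state. For the GLUT1 inward-open (PDB 5EQI) /
#' GLUT3 outward-occluded (PDB 4ZW9) pair with default [en_params()] this
#' yields the common-constraints counts of the ComDYN verification
#' analysis.
#'
#' @param pdb_a,pdb_b PDB files for the two states.
#' @param chain_a,chain_b chains to use.
#' @param params [en_params].
#' @param mode residue pairing mode, see [map_residues()].
#' @return data.frame with one row per state: `state`, `n_input`,
#'   `n_kept`, `kept_percent`.
#' @export
interstate_constraint_counts <- function(pdb_a, pdb_b,
                                         chain_a = "A", chain_b = "A",
                                         params = en_params(),
                                         mode = "alignment") {
  a <- read_structure(pdb_a, chain = chain_a, label = "A")
  b <- read_structure(pdb_b, chain = chain_b, label = "B")
  m_ab <- map_residues(a, b, mode = mode)
  m_ba <- reverse_map(m_ab)
  res_a <- comdyn_filter(build_network(a, params), a, b, m_ab, params)
  res_b <- comdyn_filter(build_network(b, params), b, a, m_ba, params)
  data.frame(state = c("A", "B"),
             n_input = c(res_a$n_input, res_b$n_input),
             n_kept = c(res_a$n_kept, res_b$n_kept),
             kept_percent = 100 * c(res_a$kept_fraction, res_b$kept_fraction))
}

#' Swap the two sides of a residue map
#' @param map a `residue_map`
#' @return the `residue_map` relating b to a
#' @export
reverse_map <- function(map) {
  p <- map$pairs
  map$pairs <- data.frame(idx_a = p$idx_b, idx_b = p$idx_a,
                          chain_a = p$chain_b, resid_a = p$resid_b,
                          chain_b = p$chain_a, resid_b = p$resid_a,
                          stringsAsFactors = FALSE)
  cov <- map$coverage_a; map$coverage_a <- map$coverage_b
  map$coverage_b <- cov
  map
}
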