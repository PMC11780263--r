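#' Binned density estimate of a distance series
#'
#' Normalized histogram over uniform bins: the default, fully transparent
#' estimator behind the overlap and shift metrics. Two series intended
#' for comparison must be binned over a shared `range` so their bin edges
#' coincide (see [compare_ensembles()], which arranges this).
#'
#' @param series a [distance_series] or numeric vector (nm).
#' @param bin_width bin width in nm (default 0.05).
#' @param range optional `c(lo, hi)`; the grid is extended outwards to
#'   whole bins. Default: the series range.
#' @return An object of class `distance_distribution`: list with
#'   `bin_edges` (nm), `density` (nm^-1, integrates to 1), `n_samples`,
#'   `peak` (centre of the modal bin; ties broken towards the smaller
#'   distance).
#' @export
estimate_distribution <- function(series, bin_width = 0.05, range = NULL) {
  x <- if (inherits(series, "distance_series")) series$values
       else as.numeric(series)
  if (length(x) == 0) stop("empty series")
  if (is.null(range)) range <- base::range(x)
  if (diff(range) < 0 || (diff(range) == 0 && length(unique(x)) > 1))
    stop("zero-width range")
  lo <- floor(range[1] / bin_width) * bin_width
  nbin <- max(1L, ceiling((range[2] - lo) / bin_width + 1e-9))
  edges <- lo + bin_width * (0:nbin)
  if (any(x < edges[1] - 1e-12) || any(x > edges[nbin + 1] + 1e-12))
    stop("samples outside the binning range")
  k <- pmin(pmax(floor((x - lo) / bin_width) + 1L, 1L), nbin)
  counts <- tabulate(k, nbins = nbin)
  dens <- counts / (length(x) * bin_width)
  centers <- (edges[-1] + edges[-(nbin + 1)]) / 2
  structure(list(bin_edges = edges, density = dens,
                 n_samples = length(x),
                 peak = centers[which.max(dens)]),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution: %d bins [%.3f, %.3f] nm, peak %.3f nm, n = %d\n",
              length(x$density), min(x$bin_edges), max(x$bin_edges),
              x$peak, x$n_samples))
  invisible(x)
}

check_same_bins <- function(p, q) {
  if (length(p$bin_edges) != length(q$bin_edges) ||
      max(abs(p$bin_edges - q$bin_edges)) > 1e-9)
    stop("distributions have mismatched bin edges; bin them over a shared range")
}

#' Overlap fraction between two distance distributions
#'
#' The integral of the pointwise minimum of the two normalized densities:
#' 1 for identical distributions, 0 for disjoint supports. Symmetric, and
#' equal to 1 minus half the L1 distance between the densities. Small
#' overlap between a mutant's and the wild type's sampled distances flags
#' a strong change in the conformational ensemble.
#'
#' @param p,q [estimate_distribution()] results on identical bin edges.
#' @return overlap fraction in \[0, 1\].
#' @export
overlap <- function(p, q) {
  check_same_bins(p, q)
  bw <- diff(p$bin_edges[1:2])
  sum(pmin(p$density, q$density)) * bw
}

#' Peak shift between two distance distributions
#'
#' Difference in modal peak position, `mut$peak - ref$peak` (nm).
#' Positive means the mutant-like distribution peaks at a larger distance
#' (an "opening" motion); negative indicates "closing".
#'
#' @param mut,ref [estimate_distribution()] results on identical bin
#'   edges (mutant-like and reference/wild-type-like).
#' @return signed shift in nm.
#' @export
shift <- function(mut, ref) {
  check_same_bins(mut, ref)
  mut$peak - ref$peak
}

#' Overlap and shift between two sampled distance series
#'
#' Bins both series over the union of their ranges (so bin edges are
#' shared) and reports the overlap fraction and peak shift, the two
#' metrics used to compare a mutant's sampled order-parameter
#' distribution against a (typically pooled wild-type) reference.
#'
#' @param mut_series,ref_series [distance_series] or numeric vectors;
#'   the reference is conventionally the pooled wild-type ensemble.
#' @param bin_width bin width in nm.
#' @return list with `overlap` (fraction), `shift` (nm), and the two
#'   `distance_distribution` objects (`mut`, `ref`).
#' @export
compare_ensembles <- function(mut_series, ref_series, bin_width = 0.05) {
  vm <- if (inherits(mut_series, "distance_series")) mut_series$values
        else as.numeric(mut_series)
  vr <- if (inherits(ref_series, "distance_series")) ref_series$values
        else as.numeric(ref_series)
  if (length(vm) == 0 || length(vr) == 0) stop("empty series")
  rng <- range(c(vm, vr))
  pm <- estimate_distribution(vm, bin_width, rng)
  pr <- estimate_distribution(vr, bin_width, rng)
  list(overlap = overlap(pm, pr), shift = shift(pm, pr),
       mut = pm, ref = pr)
}

#' Pool several distance series into one
#'
#' Concatenates series (e.g. the two wild-type state simulations) into a
#' single reference series.
#'
#' @param ... [distance_series] or numeric vectors.
#' @param label label of the pooled series.
#' @return A [distance_series].
#' @export
pool_series <- function(..., label = "pooled") {
  vals <- unlist(lapply(list(...), function(s)
    if (inherits(s, "distance_series")) s$values else as.numeric(s)))
  distance_series(vals, label, allow_zero = TRUE)
}

#' Overlap/shift table for matched series of order parameters
#'
#' Applies [compare_ensembles()] to each pair of same-labelled series and
#' returns a table in the layout of a mutant-vs-wild-type comparison:
#' overlap in percent and shift in nm, with flags for strong changes
#' (defaults: overlap below 60%, |shift| above 0.15 nm).
#'
#' @param mut_list,ref_list lists of [distance_series]; matched by
#'   `pair_label`.
#' @param bin_width histogram bin width, nm.
#' @param overlap_flag flag overlaps below this fraction.
#' @param shift_flag flag absolute shifts above this value (nm).
#' @return data.frame with `pair_label`, `overlap_percent`, `shift_nm`,
#'   `flagged`.
#' @export
stats_table <- function(mut_list, ref_list, bin_width = 0.05,
                        overlap_flag = 0.6, shift_flag = 0.15) {
  ref_labels <- vapply(ref_list, function(s) s$pair_label, "")
  rows <- lapply(mut_list, function(ms) {
    k <- match(ms$pair_label, ref_labels)
    if (is.na(k)) stop("no reference series for ", ms$pair_label)
    cmp <- compare_ensembles(ms, ref_list[[k]], bin_width)
    data.frame(pair_label = ms$pair_label,
               overlap_percent = 100 * cmp$overlap,
               shift_nm = cmp$shift,
               flagged = cmp$overlap < overlap_flag ||
                 abs(cmp$shift) > shift_flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
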