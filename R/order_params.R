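#' Coordinate ensemble sharing one bead table
#'
#' A `frameset` holds an ordered sequence of coordinate frames (nm) for
#' the beads of a [bead_structure]; every frame has the same bead count
#' and ordering.
#'
#' @param xyz numeric array of dimension (n_beads, 3, n_frames), or a
#'   list of n_beads x 3 matrices, or a single matrix (one frame).
#' @param beads bead table (data.frame as in [bead_structure]) or a
#'   `bead_structure` whose table is reused.
#' @param times optional per-frame times (ps).
#' @return An object of class `frameset`.
#' @export
frameset <- function(xyz, beads, times = NULL) {
  if (inherits(beads, "bead_structure")) beads <- beads$beads
  if (is.list(xyz) && !is.array(xyz))
    xyz <- array(unlist(xyz), dim = c(nrow(xyz[[1]]), 3, length(xyz)))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3, dim(xyz)[3] >= 1)
  if (dim(xyz)[1] != nrow(beads))
    stop("frame bead count does not match bead table")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frameset")
  if (!is.null(times) && length(times) != dim(xyz)[3])
    stop("times length must equal frame count")
  structure(list(xyz = xyz, beads = beads, times = times),
            class = "frameset")
}

#' @export
print.frameset <- function(x, ...) {
  cat(sprintf("frameset: %d frames x %d beads\n", n_frames(x),
              dim(x$xyz)[1]))
  invisible(x)
}

#' Number of frames in a frameset
#' @param f a `frameset`
#' @return integer
#' @export
n_frames <- function(f) dim(f$xyz)[3]

#' Extract one frame as a coordinate matrix
#' @param f a `frameset`
#' @param i frame index
#' @return n x 3 matrix (nm)
#' @export
frame_coords <- function(f, i) f$xyz[, , i]

#' Write a frameset as a multi-model PDB file
#'
#' Frames become MODEL/ENDMDL blocks of CA ATOM records (nm converted to
#' Angstrom).
#'
#' @param f a [frameset]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_frameset <- function(f, path) {
  b <- f$beads
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(f))) {
    writeLines(sprintf("MODEL %8d", k), con)
    m <- f$xyz[, , k] * 10
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(b)), b$resname, b$chain, b$resid,
      m[, 1], m[, 2], m[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a frameset from a multi-model PDB or whitespace XYZ stream
#'
#' Two dialects are accepted:
#' \describe{
#'   \item{pdb}{multi-model PDB of CA records (as written by
#'     [write_frameset()]); the bead table is taken from the first model.}
#'   \item{xyz}{whitespace-separated stream, one line `x y z` (nm) per
#'     bead, frames separated by blank lines; a `beads` table or
#'     [bead_structure] must be supplied.}
#' }
#'
#' @param path input file.
#' @param format "pdb" or "xyz" (default guessed from the extension).
#' @param beads bead table for the xyz dialect.
#' @return A [frameset].
#' @export
read_frameset <- function(path, format = NULL, beads = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.(xyz|dat|txt)$", path, ignore.case = TRUE))
      "xyz" else "pdb"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    row0 <- which(pdb$atom$type == "ATOM" & pdb$atom$elety == "CA")
    at <- pdb$atom[row0, , drop = FALSE]
    if (nrow(at) == 0) stop("no C-alpha atoms in ", path)
    nf <- nrow(pdb$xyz)
    xyz <- array(0, dim = c(nrow(at), 3, nf))
    cols <- as.vector(t(cbind(3 * (row0 - 1) + 1,
                              3 * (row0 - 1) + 2,
                              3 * (row0 - 1) + 3)))
    for (k in seq_len(nf))
      xyz[, , k] <- matrix(pdb$xyz[k, cols], ncol = 3, byrow = TRUE) / 10
    bt <- data.frame(chain = at$chain, resid = at$resno, resname = at$resid,
                     x = xyz[, 1, 1], y = xyz[, 2, 1], z = xyz[, 3, 1],
                     stringsAsFactors = FALSE)
    frameset(xyz, bt)
  } else {
    if (is.null(beads)) stop("xyz format requires a beads table")
    if (inherits(beads, "bead_structure")) beads <- beads$beads
    lines <- trimws(readLines(path))
    groups <- split(lines[lines != ""], cumsum(lines == "")[lines != ""])
    frames <- lapply(groups, function(g) {
      m <- do.call(rbind, lapply(strsplit(g, "\\s+"), as.numeric))
      if (ncol(m) != 3 || nrow(m) != nrow(beads))
        stop("xyz frame does not match bead table")
      m
    })
    frameset(frames, beads)
  }
}

#' Per-frame distance series for a named helix pair
#'
#' @param values numeric vector of distances (nm), all finite and > 0
#'   unless `allow_zero`.
#' @param pair_label label such as "TM5/TM11(in)".
#' @param allow_zero permit zero distances (identical segments).
#' @return An object of class `distance_series`.
#' @export
distance_series <- function(values, pair_label = "", allow_zero = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0 || !all(is.finite(values)))
    stop("distance series must be non-empty and finite")
  if (!allow_zero && any(values <= 0))
    stop("distance series must be strictly positive")
  structure(list(pair_label = pair_label, values = values),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance_series %s: %d frames, mean %.3f nm\n",
              x$pair_label, length(x$values), mean(x$values)))
  invisible(x)
}

#' Inter-segment centroid distance over an ensemble
#'
#' For every frame, the Euclidean distance between the unweighted
#' centroids of the two segments' beads — the order parameter used to
#' follow inter-helix opening/closing motions at the intracellular and
#' extracellular faces of a transporter. Both segments must be on the
#' same side of the membrane.
#'
#' @param frames a [frameset].
#' @param a,b [segment_def] objects with `a$side == b$side`.
#' @return A [distance_series] labelled "TMx/TMy(side)".
#' @export
segment_distance <- function(frames, a, b) {
  if (a$side != b$side)
    stop("segments must be on the same side (got ", a$side, " vs ", b$side, ")")
  ia <- segment_indices(a, frames$beads)
  ib <- segment_indices(b, frames$beads)
  nf <- n_frames(frames)
  vals <- vapply(seq_len(nf), function(k) {
    ca <- colMeans(frames$xyz[ia, , k, drop = FALSE][, , 1, drop = TRUE])
    cb <- colMeans(frames$xyz[ib, , k, drop = FALSE][, , 1, drop = TRUE])
    sqrt(sum((ca - cb)^2))
  }, 0)
  distance_series(vals, sprintf("TM%d/TM%d(%s)", a$tm, b$tm, a$side),
                  allow_zero = TRUE)
}

#' All order parameters around the transporter helix ring
#'
#' Computes [segment_distance()] for every adjacent helix pair around the
#' central ring, on both sides, plus any configured extra (cross-rim)
#' pairs. The default ring follows the six transporter-region helices in
#' order TM2-TM1-TM5-TM8-TM7-TM11 and back to TM2, giving 6 pairs x 2
#' sides = 12 series; cross-rim pairs such as TM5/TM11 can be added via
#' `extra_pairs`.
#'
#' @param frames a [frameset].
#' @param segments list of [segment_def] covering both sides of every
#'   ring member.
#' @param ring helix numbers in ring order (closed cyclically).
#' @param extra_pairs optional list of `c(tm_x, tm_y)` pairs added on
#'   both sides.
#' @return list of [distance_series].
#' @export
ring_distances <- function(frames, segments, ring = c(2, 1, 5, 8, 7, 11),
                           extra_pairs = NULL) {
  seg_key <- vapply(segments, segment_label, "")
  get_seg <- function(tm, side) {
    k <- match(sprintf("TM%d/%s", tm, side), seg_key)
    if (is.na(k)) stop("missing segment definition TM", tm, "/", side)
    segments[[k]]
  }
  pairs <- lapply(seq_along(ring), function(k)
    c(ring[k], ring[if (k == length(ring)) 1 else k + 1]))
  pairs <- c(pairs, extra_pairs)
  out <- list()
  for (p in pairs)
    for (side in c("in", "out"))
      out[[length(out) + 1]] <-
        segment_distance(frames, get_seg(p[1], side), get_seg(p[2], side))
  out
}

#' Write distance series to a TSV file
#'
#' One column per series (header = pair label), one row per frame.
#'
#' @param series list of [distance_series] of equal length.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  df <- as.data.frame(lapply(series, function(s) s$values))
  names(df) <- vapply(series, function(s) s$pair_label, "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read distance series from a TSV file written by [write_series_tsv()]
#' @param path TSV file
#' @return list of [distance_series]
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  lapply(names(df), function(nm)
    distance_series(df[[nm]], nm, allow_zero = TRUE))
}
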