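#' Bead structure: one backbone bead per residue at the C-alpha position
#'
#' A `bead_structure` is the coarse-grained representation used throughout
#' the package: every residue contributes exactly one bead, placed at the
#' coordinates of its C-alpha atom, with coordinates stored in nanometres
#' (PDB Angstrom input is divided by 10). No side-chain beads are modelled;
#' the elastic network and all analyses operate on backbone beads only.
#'
#' @param beads data.frame with columns `chain`, `resid`, `resname`,
#'   `x`, `y`, `z` (nm). Residues must be unique per (chain, resid) and
#'   strictly increasing in resid within each chain.
#' @param label short text tag for the conformational state (e.g. "IO",
#'   "OO").
#' @param source provenance string (file path or "synthetic").
#' @return An object of class `bead_structure`.
#' @export
bead_structure <- function(beads, label = "", source = "") {
  stopifnot(is.data.frame(beads))
  req <- c("chain", "resid", "resname", "x", "y", "z")
  if (!all(req %in% names(beads)))
    stop("beads must have columns: ", paste(req, collapse = ", "))
  beads <- beads[, req]
  beads$chain <- as.character(beads$chain)
  beads$resid <- as.integer(beads$resid)
  key <- paste(beads$chain, beads$resid)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid) bead: ", key[duplicated(key)][1])
  for (ch in unique(beads$chain)) {
    r <- beads$resid[beads$chain == ch]
    if (is.unsorted(r, strictly = TRUE))
      stop("resids not strictly increasing within chain ", ch)
  }
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite bead coordinates")
  structure(list(beads = beads, label = label, source = source),
            class = "bead_structure")
}

#' @export
print.bead_structure <- function(x, ...) {
  cat(sprintf("bead_structure '%s': %d beads, %d chain(s) [%s]\n",
              x$label, nrow(x$beads), length(unique(x$beads$chain)),
              x$source))
  invisible(x)
}

#' Number of beads
#' @param s a `bead_structure`
#' @return integer bead count
#' @export
n_beads <- function(s) nrow(s$beads)

#' Bead coordinate matrix
#' @param s a `bead_structure`
#' @return numeric n x 3 matrix (nm)
#' @export
coords <- function(s) unname(as.matrix(s$beads[, c("x", "y", "z")]))

#' Read a structure from a PDB file as one bead per residue
#'
#' Parses ATOM records, keeps the C-alpha atom of each residue of the
#' requested chain, and converts Angstrom to nm. For altloc-duplicated
#' C-alphas the highest-occupancy altloc is kept (ties broken towards
#' altloc "A", then alphabetically). HETATM records are ignored. Residues
#' without a C-alpha are skipped with a message. Residues with insertion
#' codes are assigned a synthetic strictly monotone resid (and a message is
#' emitted), so that downstream residue maps can use integer keys.
#'
#' @param path PDB file.
#' @param chain chain identifier(s); `NULL` keeps all chains.
#' @param label state label stored on the result (e.g. "IO").
#' @param model model number for multi-model files (default 1).
#' @return A [bead_structure] with coordinates in nm.
#' @export
read_structure <- function(path, chain = NULL, label = "", model = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  at$row0 <- seq_len(nrow(at))  # position in file order = xyz column block
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- unique(at$chain)
  at <- at[at$chain %in% chain & at$elety == "CA", , drop = FALSE]
  if (nrow(at) == 0)
    stop("no C-alpha atoms for chain '", paste(chain, collapse = ","),
         "' in ", path)
  if (model > 1) {
    if (is.null(pdb$xyz) || nrow(pdb$xyz) < model)
      stop("model ", model, " not present in ", path)
    m <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- m[at$row0, 1]; at$y <- m[at$row0, 2]; at$z <- m[at$row0, 3]
  }
  # altloc policy: per residue keep highest occupancy, ties -> "A", then
  # alphabetical
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  rkey <- paste(at$chain, at$resno, ins)
  if (anyDuplicated(rkey)) {
    keep <- unlist(lapply(split(seq_len(nrow(at)), rkey)[unique(rkey)],
      function(ix) {
        if (length(ix) == 1) return(ix)
        occ <- at$o[ix]; occ[is.na(occ)] <- 1
        ix <- ix[occ == max(occ)]
        alt <- ifelse(is.na(at$alt[ix]), "", at$alt[ix])
        ix[order(alt != "A", alt)][1]
      }))
    at <- at[sort(keep), , drop = FALSE]
    ins <- ins[sort(keep)]
  }
  resid <- at$resno
  per_chain_ok <- all(vapply(split(resid, at$chain), function(r)
    !is.unsorted(r, strictly = TRUE), TRUE))
  if (any(ins != "") || !per_chain_ok) {
    message("read_structure: insertion codes / non-monotone resids in ",
            basename(path), "; assigning synthetic monotone resids")
    resid <- stats::ave(seq_along(at$resno), at$chain, FUN = seq_along)
  }
  bead_structure(
    data.frame(chain = at$chain, resid = resid, resname = at$resid,
               x = at$x / 10, y = at$y / 10, z = at$z / 10,
               stringsAsFactors = FALSE),
    label = label, source = path)
}

#' Write a bead structure as a single-model PDB file
#'
#' Beads are written as CA ATOM records (coordinates converted nm to
#' Angstrom). The inverse of [read_structure()] up to PDB coordinate
#' precision (0.001 nm).
#'
#' @param s a [bead_structure]
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  b <- s$beads
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(s))) * 10,
                   resno = b$resid, chain = b$chain, resid = b$resname,
                   elety = rep("CA", nrow(b)))
  invisible(path)
}

one_letter <- function(resname) {
  aa <- bio3d::aa321(resname)
  aa[is.na(aa) | aa == ""] <- "X"
  aa
}

#' Residue correspondence between two bead structures
#'
#' Establishes a partial bijection between the residues of structure `a`
#' and structure `b`. Three modes:
#' \describe{
#'   \item{identity}{pair residues sharing (chain, resid); for identical
#'     constructs or two states of the same protein.}
#'   \item{alignment}{pair residues at aligned non-gap columns of an
#'     end-gap-free global sequence alignment (BLOSUM62, gap open 10,
#'     gap extend 0.5), chain by chain in order of appearance; for
#'     homologs such as GLUT1 vs GLUT3.}
#'   \item{explicit}{a user-supplied table of paired residues, e.g. from a
#'     published table of structurally conserved segments.}
#' }
#'
#' @param a,b [bead_structure] objects.
#' @param mode one of "alignment", "identity", "explicit".
#' @param pairs for mode "explicit": data.frame with columns `resid_a`,
#'   `resid_b` and optionally `chain_a`, `chain_b` (default first chain).
#' @param min_coverage coverage below which a warning is issued
#'   (default 0.5).
#' @return An object of class `residue_map`: list with `pairs` (data.frame
#'   `idx_a`, `idx_b`, `chain_a`, `resid_a`, `chain_b`, `resid_b`),
#'   `coverage_a`, `coverage_b`, and for alignment mode `identity` (the
#'   fraction of identical residues over aligned columns).
#' @export
map_residues <- function(a, b, mode = c("alignment", "identity", "explicit"),
                         pairs = NULL, min_coverage = 0.5) {
  mode <- match.arg(mode)
  ba <- a$beads; bb <- b$beads
  if (mode == "identity") {
    ka <- paste(ba$chain, ba$resid); kb <- paste(bb$chain, bb$resid)
    common <- intersect(ka, kb)
    idx_a <- match(common, ka); idx_b <- match(common, kb)
  } else if (mode == "explicit") {
    if (is.null(pairs)) stop("mode 'explicit' requires a pairs table")
    chain_a <- if ("chain_a" %in% names(pairs)) pairs$chain_a else ba$chain[1]
    chain_b <- if ("chain_b" %in% names(pairs)) pairs$chain_b else bb$chain[1]
    idx_a <- match(paste(chain_a, pairs$resid_a), paste(ba$chain, ba$resid))
    idx_b <- match(paste(chain_b, pairs$resid_b), paste(bb$chain, bb$resid))
    if (anyNA(idx_a) || anyNA(idx_b))
      stop("explicit pairs reference residues absent from a structure")
    if (anyDuplicated(idx_a) || anyDuplicated(idx_b))
      stop("explicit pairs are not a bijection")
  } else {
    chains_a <- unique(ba$chain); chains_b <- unique(bb$chain)
    nch <- min(length(chains_a), length(chains_b))
    idx_a <- integer(0); idx_b <- integer(0); nid <- 0L; ncol_al <- 0L
    for (k in seq_len(nch)) {
      ia <- which(ba$chain == chains_a[k]); ib <- which(bb$chain == chains_b[k])
      al <- align_indices(one_letter(ba$resname[ia]),
                          one_letter(bb$resname[ib]))
      idx_a <- c(idx_a, ia[al$i]); idx_b <- c(idx_b, ib[al$j])
      nid <- nid + al$n_identical; ncol_al <- ncol_al + length(al$i)
    }
  }
  if (length(idx_a) == 0) stop("empty residue map: no residues could be paired")
  pr <- data.frame(idx_a = idx_a, idx_b = idx_b,
                   chain_a = ba$chain[idx_a], resid_a = ba$resid[idx_a],
                   chain_b = bb$chain[idx_b], resid_b = bb$resid[idx_b],
                   stringsAsFactors = FALSE)
  out <- structure(list(pairs = pr,
                        coverage_a = nrow(pr) / nrow(ba),
                        coverage_b = nrow(pr) / nrow(bb),
                        mode = mode),
                   class = "residue_map")
  if (mode == "alignment") out$identity <- nid / ncol_al
  if (out$coverage_a < min_coverage || out$coverage_b < min_coverage)
    warning(sprintf("residue map coverage below %.2f (a: %.2f, b: %.2f)",
                    min_coverage, out$coverage_a, out$coverage_b))
  out
}

# End-gap-free global alignment of two one-letter sequences; returns the
# paired residue positions (1-based within each sequence).
align_indices <- function(sa, sb) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(sa, collapse = "")),
    Biostrings::AAString(paste(sb, collapse = "")),
    type = "overlap", substitutionMatrix = BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  # alignedPattern/alignedSubject include unaligned flanks, so position
  # counters start at 1 of each full sequence
  i <- cumsum(pa != "-"); j <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  list(i = i[keep], j = j[keep],
       n_identical = sum(pa[keep] == pb[keep]))
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("residue_map (%s): %d pairs, coverage a %.2f / b %.2f",
              x$mode, nrow(x$pairs), x$coverage_a, x$coverage_b))
  if (!is.null(x$identity)) cat(sprintf(", identity %.2f", x$identity))
  cat("\n")
  invisible(x)
}

#' Define a 10-residue helix segment used as an order-parameter anchor
#'
#' @param tm transmembrane helix number (counted from the N-terminus).
#' @param side "in" (intracellular) or "out" (extracellular).
#' @param chain chain identifier.
#' @param start,end inclusive residue range; must span exactly `length`
#'   residues.
#' @param length required span length (default 10).
#' @return An object of class `segment_def`.
#' @export
segment_def <- function(tm, side, chain, start, end, length = 10) {
  side <- match.arg(side, c("in", "out"))
  if (end - start + 1L != length)
    stop(sprintf("segment TM%s/%s: span %d-%d is %d residues, expected %d",
                 tm, side, start, end, end - start + 1L, length))
  structure(list(tm = as.integer(tm), side = side, chain = as.character(chain),
                 start = as.integer(start), end = as.integer(end)),
            class = "segment_def")
}

#' @export
print.segment_def <- function(x, ...) {
  cat(sprintf("segment TM%d/%s chain %s resid %d-%d\n",
              x$tm, x$side, x$chain, x$start, x$end))
  invisible(x)
}

segment_label <- function(s) sprintf("TM%d/%s", s$tm, s$side)

# Bead indices of a segment within a bead table; hard error if any residue
# is missing.
segment_indices <- function(seg, beads) {
  want <- seg$start:seg$end
  idx <- match(paste(seg$chain, want), paste(beads$chain, beads$resid))
  if (anyNA(idx))
    stop(sprintf("segment TM%d/%s: residues %s absent from structure",
                 seg$tm, seg$side,
                 paste(want[is.na(idx)], collapse = ",")))
  idx
}

#' Load and validate helix segment definitions from a YAML config
#'
#' The config is a YAML list under key `segments`, each entry with fields
#' `tm`, `side`, `chain`, `start`, `end`. Every segment is validated
#' against the structure (all residues present, span of the configured
#' length) and every (tm, side) pair must be unique.
#'
#' @param path YAML file.
#' @param structure [bead_structure] the segments refer to.
#' @param length required segment length (default 10).
#' @return list of [segment_def] objects.
#' @export
load_segments <- function(path, structure, length = 10) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$segments)) cfg$segments else cfg
  segs <- lapply(entries, function(e) {
    s <- segment_def(e$tm, e$side, e$chain, e$start, e$end, length = length)
    segment_indices(s, structure$beads)  # existence check
    s
  })
  key <- vapply(segs, segment_label, "")
  if (anyDuplicated(key))
    stop("duplicate segment definition: ", key[duplicated(key)][1])
  segs
}

#' Write helix segment definitions to a YAML config
#' @param segments list of [segment_def]
#' @param path output YAML file
#' @return `path`, invisibly
#' @export
write_segments <- function(segments, path) {
  yaml::write_yaml(list(segments = lapply(segments, function(s)
    list(tm = s$tm, side = s$side, chain = s$chain,
         start = s$start, end = s$end))), path)
  invisible(path)
}
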