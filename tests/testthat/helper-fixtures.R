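# Shared fixture builders and independent oracles.

# A bead structure from a plain coordinate matrix (nm), single chain.
cloud_structure <- function(xyz, chain = "A", label = "cloud") {
  bead_structure(data.frame(chain = chain, resid = seq_len(nrow(xyz)),
                            resname = "ALA", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE),
                 label, "synthetic")
}

random_cloud <- function(n, seed, spread = 2) {
  set.seed(seed)
  cloud_structure(matrix(stats::runif(3 * n, 0, spread), ncol = 3))
}

# Brute-force all-pairs elastic-network enumeration: the oracle for
# build_network(), written as the obvious O(n^2) double loop.
brute_force_network <- function(s, params) {
  x <- coords(s)
  b <- s$beads
  rows <- list()
  n <- nrow(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (b$chain[i] == b$chain[j] &&
          abs(b$resid[i] - b$resid[j]) < params$min_seq_sep) next
      d <- sqrt(sum((x[i, ] - x[j, ])^2))
      if (d >= params$lower_cutoff && d <= params$upper_cutoff)
        rows[[length(rows) + 1]] <- c(i, j, d)
    }
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), j = integer(0), d0 = numeric(0)))
  m <- do.call(rbind, rows)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), d0 = m[, 3])
}

# Horn's quaternion method for optimal superposition RMSD: an
# independent oracle for the SVD-based Kabsch fit.
quaternion_rmsd <- function(mobile, target) {
  xm <- sweep(mobile, 2, colMeans(mobile))
  xt <- sweep(target, 2, colMeans(target))
  M <- crossprod(xm, xt)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(xm^2) + sum(xt^2) - 2 * lambda) / nrow(mobile)
  sqrt(max(msd, 0))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_res)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Minimal hand-written PDB text (Angstrom coordinates).
pdb_lines <- function(resno, x, y, z, chain = "A", elety = "CA",
                      resname = "ALA", alt = "", occ = 1, type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, seq_along(resno),
          ifelse(nchar(elety) < 4, paste0(" ", elety), elety),
          alt, resname, chain, resno, x, y, z, occ, 0)
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
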