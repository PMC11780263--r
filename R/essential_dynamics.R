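#' Least-squares superposition of two coordinate sets
#'
#' Optimal rigid-body fit (Kabsch algorithm via singular value
#' decomposition) of `mobile` onto `target`; a proper rotation
#' (determinant +1) is enforced, so mirror images are never matched by
#' reflection.
#'
#' @param mobile,target n x 3 coordinate matrices (nm), n >= 3.
#' @return list with `xyz` (fitted mobile coordinates), `rmsd` (the
#'   minimized value, nm), `rotation` (3 x 3), and `translation` such
#'   that `fitted = (mobile - centroid_mobile) \%*\% rotation +
#'   translation`.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) != nrow(target) || ncol(mobile) != 3 || ncol(target) != 3)
    stop("coordinate sets must be matched n x 3 matrices")
  if (nrow(mobile) < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  xm <- sweep(mobile, 2, cm); xt <- sweep(target, 2, ct)
  C <- crossprod(xm, xt)
  sv <- svd(C)
  if (min(sv$d) < 1e-14 && sum(sv$d > 1e-14) < 2)
    stop("degenerate (rank-deficient) configuration")
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  fitted <- xm %*% R
  rmsd <- sqrt(mean(rowSums((fitted - xt)^2)))
  list(xyz = sweep(fitted, 2, ct, "+"), rmsd = rmsd,
       rotation = R, translation = ct)
}

#' RMSD after optimal superposition
#' @param a,b matched n x 3 coordinate matrices (nm)
#' @return RMSD in nm
#' @export
fit_rmsd <- function(a, b) superpose(a, b)$rmsd

pool_frames <- function(ensembles) {
  if (inherits(ensembles, "frameset")) ensembles <- list(ensembles)
  nb <- dim(ensembles[[1]]$xyz)[1]
  for (f in ensembles)
    if (dim(f$xyz)[1] != nb) stop("ensembles have differing bead counts")
  list(xyz = array(unlist(lapply(ensembles, function(f) f$xyz)),
                   dim = c(nb, 3, sum(vapply(ensembles, n_frames, 0L)))),
       beads = ensembles[[1]]$beads,
       sizes = vapply(ensembles, n_frames, 0L))
}

#' Essential dynamics model of a pooled ensemble
#'
#' Fits every frame of the pooled ensemble(s) to a reference by
#' least-squares superposition over the selected beads, then
#' eigendecomposes the (mass-unweighted) covariance matrix of the fitted
#' selected coordinates. The leading eigenvectors are the largest
#' collective motions of the ensemble; for a two-state transporter
#' ensemble pooled over both wild-type simulations, eigenvector 1
#' captures the interstate opening/closing transition.
#'
#' The covariance uses the 1/N normalization, so the variance of the
#' training-ensemble projections along eigenvector k equals eigenvalue k
#' exactly.
#'
#' @param ensembles a [frameset] or list of framesets (pooled).
#' @param selection integer bead indices analyzed (e.g. the structurally
#'   conserved helical segments); default all beads.
#' @param reference fitting reference: a [bead_structure], an n x 3
#'   matrix, or `NULL` for the first frame of the first ensemble.
#' @param orient optional [bead_structure] or coordinate matrix whose
#'   projection is forced non-positive on every eigenvector (fixes the
#'   sign ambiguity of PCA; conventionally the outward-like starting
#'   structure, so the transition runs left to right along EV1).
#' @return An object of class `ed_model`: `reference` (selection
#'   coordinates used for fitting), `mean` (3s vector), `eigenvectors`
#'   (3s x 3s, columns, descending), `eigenvalues` (nm^2), `selection`.
#' @export
fit_ed <- function(ensembles, selection = NULL, reference = NULL,
                   orient = NULL) {
  pooled <- pool_frames(ensembles)
  nf <- dim(pooled$xyz)[3]
  if (nf < 2) stop("need at least 2 frames")
  nb <- dim(pooled$xyz)[1]
  if (is.null(selection)) selection <- seq_len(nb)
  if (length(selection) == 0) stop("empty selection")
  ref <- if (is.null(reference)) pooled$xyz[, , 1]
         else if (inherits(reference, "bead_structure")) coords(reference)
         else as.matrix(reference)
  ref_sel <- ref[selection, , drop = FALSE]
  X <- matrix(0, nf, 3 * length(selection))
  for (k in seq_len(nf)) {
    fit <- superpose(pooled$xyz[selection, , k], ref_sel)
    X[k, ] <- as.vector(t(fit$xyz))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / nf
  eg <- eigen(cv, symmetric = TRUE)
  ev <- eg$values
  ev[ev < 0 & ev > -1e-12] <- 0
  model <- structure(list(reference = ref_sel, mean = mu,
                          eigenvectors = eg$vectors, eigenvalues = ev,
                          selection = selection),
                     class = "ed_model")
  if (!is.null(orient)) {
    pr <- project_ed_coords(if (inherits(orient, "bead_structure"))
      coords(orient) else as.matrix(orient), model,
      n_vec = length(model$eigenvalues))
    flip <- pr > 0
    model$eigenvectors[, flip] <- -model$eigenvectors[, flip]
  }
  model
}

#' @export
print.ed_model <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("ed_model: %d beads, EV1 %.1f%%, EV2 %.1f%% of variance\n",
              length(x$selection),
              100 * x$eigenvalues[1] / tot, 100 * x$eigenvalues[2] / tot))
  invisible(x)
}

project_ed_coords <- function(xyz, model, n_vec = 2) {
  sel <- if (nrow(xyz) == length(model$selection)) seq_len(nrow(xyz))
         else model$selection
  fit <- superpose(xyz[sel, , drop = FALSE], model$reference)
  drop((as.vector(t(fit$xyz)) - model$mean) %*%
         model$eigenvectors[, seq_len(n_vec), drop = FALSE])
}

#' Project frames onto the leading essential-dynamics eigenvectors
#'
#' Every frame is fitted to the model's reference over the model
#' selection, centred by the model mean, and dotted with the first
#' `n_vec` eigenvectors — the coordinates of the frame in the essential
#' subspace (e.g. for a two-dimensional transition landscape plot).
#'
#' @param frames a [frameset], [bead_structure], or n x 3 matrix.
#' @param model an [fit_ed()] model.
#' @param n_vec number of eigenvectors (default 2).
#' @return matrix n_frames x n_vec of projections (nm).
#' @export
project_ed <- function(frames, model, n_vec = 2) {
  if (inherits(frames, "bead_structure")) frames <- frameset(coords(frames), frames)
  if (is.matrix(frames)) {
    return(matrix(project_ed_coords(frames, model, n_vec), nrow = 1))
  }
  nf <- n_frames(frames)
  out <- matrix(0, nf, n_vec)
  for (k in seq_len(nf))
    out[k, ] <- project_ed_coords(frames$xyz[, , k], model, n_vec)
  colnames(out) <- paste0("ev", seq_len(n_vec))
  out
}
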