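# Geometric observables: superposition, RMSD, RMSF, centre-of-mass distances
# and the hinge angle. All distances in Angstrom, times in ns.

#' Least-squares superposition of a trajectory
#'
#' Superposes every frame onto a reference (optimal rotation + translation,
#' Kabsch) over the atoms of `fitSelection`, and applies the transform to all
#' atoms. The default fit set for domain-motion analysis is all C-alpha atoms
#' of the full complex with the first frame as reference, so that global
#' drift, not inter-domain motion, is removed.
#'
#' @param traj a [Trajectory-class]
#' @param fitSelection a [ResidueSelection-class] with at least 3
#'   non-collinear atoms
#' @param reference frame index (default 1) or an external natoms x 3 matrix
#'   covering all atoms of the topology
#' @return a new, superposed [Trajectory-class]
#' @export
superpose <- function(traj, fitSelection, reference = 1L) {
  stopifnot(is(traj, "Trajectory"), is(fitSelection, "ResidueSelection"))
  idx <- fitSelection@atomIndices
  if (length(idx) < 3L) stop("degeneracy error: fit selection needs >= 3 atoms")
  ref <- if (is.matrix(reference)) .xyzToRow(reference) else traj@xyz[reference, ]
  refFit <- matrix(ref[.xyzCols(idx)], ncol = 3L, byrow = TRUE)
  sv <- svd(scale(refFit, scale = FALSE))
  if (sum(sv$d > 1e-8 * max(sv$d)) < 2L)
    stop("degeneracy error: fit selection is collinear")
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = traj@xyz,
                           fixed.inds = .xyzCols(idx), mobile.inds = .xyzCols(idx))
  new("Trajectory", topology = traj@topology,
      xyz = matrix(fitted, nrow = nFrames(traj)), times = traj@times)
}

#' RMSD time series
#'
#' Per-frame root-mean-square deviation of the selected atoms from a
#' reference frame, in Angstrom. No refitting is performed here: superpose
#' first (or pass an already-fitted trajectory) so the values measure
#' conformational change, not rigid drift.
#'
#' @param traj a [Trajectory-class] (already superposed)
#' @param selection a [ResidueSelection-class]
#' @param reference frame index or external natoms x 3 matrix
#' @return data.frame `time_ns`, `value` (Angstrom), `label`
#' @export
rmsdTimeSeries <- function(traj, selection, reference = 1L) {
  stopifnot(is(traj, "Trajectory"), is(selection, "ResidueSelection"))
  cols <- .xyzCols(selection@atomIndices)
  ref <- if (is.matrix(reference)) .xyzToRow(reference)[cols]
         else traj@xyz[reference, cols]
  if (length(ref) != length(cols))
    stop("mismatch error: reference does not cover the selection")
  dev <- sweep(traj@xyz[, cols, drop = FALSE], 2L, ref)
  vals <- sqrt(rowSums(dev^2) / length(selection@atomIndices))
  .timeSeries(traj@times, vals, paste0("rmsd:", selection@domain))
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each residue's C-alpha about its time-mean
#' position, over an optional frame window:
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`. The trajectory is assumed
#' superposed. Requires at least 2 frames.
#'
#' @param traj a [Trajectory-class] (already superposed)
#' @param selection a [ResidueSelection-class]; only its C-alpha atoms enter
#' @param window optional integer vector of frame indices
#' @return data.frame `chain`, `resno`, `resname`, `rmsf_A`
#' @export
rmsfProfile <- function(traj, selection, window = NULL) {
  stopifnot(is(traj, "Trajectory"), is(selection, "ResidueSelection"))
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (length(window) < 2L)
    stop("insufficient-data error: RMSF needs >= 2 frames")
  a <- traj@topology@atoms
  idx <- selection@atomIndices
  idx <- idx[a$name[idx] == "CA"]
  if (length(idx) == 0L) stop("selection contains no C-alpha atoms")
  cols <- .xyzCols(idx)
  X <- traj@xyz[window, cols, drop = FALSE]
  dev <- sweep(X, 2L, colMeans(X))
  msd <- colSums(dev^2) / length(window)            # per coordinate column
  perAtom <- sqrt(colSums(matrix(msd, nrow = 3L)))  # sum x+y+z per atom
  data.frame(chain = a$chain[idx], resno = a$resno[idx], resname = a$resname[idx],
             rmsf_A = perAtom, stringsAsFactors = FALSE)
}

#' Centre-of-mass distance time series
#'
#' Per-frame Euclidean distance between the (optionally mass-weighted)
#' centroids of two selections, in Angstrom. No periodic-image correction is
#' applied: inputs are required to be pre-imaged with the complex whole.
#'
#' @param traj a [Trajectory-class]
#' @param selA,selB [ResidueSelection-class] objects (warned if overlapping)
#' @param massWeighted use atomic masses (default TRUE)
#' @return data.frame `time_ns`, `value` (Angstrom), `label`
#' @export
comDistanceTimeSeries <- function(traj, selA, selB, massWeighted = TRUE) {
  stopifnot(is(traj, "Trajectory"),
            is(selA, "ResidueSelection"), is(selB, "ResidueSelection"))
  if (length(intersect(selA@atomIndices, selB@atomIndices)) > 0L)
    warning("selections overlap; their centres of mass are not independent")
  ca <- .comSeries(traj, selA, massWeighted)
  cb <- .comSeries(traj, selB, massWeighted)
  vals <- sqrt(rowSums((ca - cb)^2))
  .timeSeries(traj@times, vals,
              paste0("com:", selA@domain, "-", selB@domain))
}

#' Hinge-angle time series
#'
#' Per-frame angle (degrees) at the geometric centroid of `selApex`
#' subtended by the centroids of `selA` and `selB`. Used for the rotational
#' detachment of a domain about a hinge helix: apex = hinge helix, arms = the
#' mutation-site residue and a distal helix of the rotating domain. Centroids
#' are unweighted.
#'
#' @param traj a [Trajectory-class]
#' @param selApex,selA,selB [ResidueSelection-class] objects
#' @return data.frame `time_ns`, `value` (degrees in `[0, 180]`), `label`
#' @export
hingeAngleTimeSeries <- function(traj, selApex, selA, selB) {
  stopifnot(is(traj, "Trajectory"))
  ap <- .comSeries(traj, selApex, massWeighted = FALSE)
  va <- .comSeries(traj, selA, massWeighted = FALSE) - ap
  vb <- .comSeries(traj, selB, massWeighted = FALSE) - ap
  na <- sqrt(rowSums(va^2))
  nb <- sqrt(rowSums(vb^2))
  if (any(na < 1e-9) || any(nb < 1e-9))
    stop("undefined-angle error: coincident centroids in frame ",
         which(na < 1e-9 | nb < 1e-9)[1L])
  cosphi <- pmin(1, pmax(-1, rowSums(va * vb) / (na * nb)))
  .timeSeries(traj@times, acos(cosphi) * 180 / pi,
              paste0("hinge:", selApex@domain))
}
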