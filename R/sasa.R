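# Shrake-Rupley solvent-accessible surface area. Implemented here because no
# installed R package computes SASA; test points are placed on a
# golden-section spiral, which keeps the quadrature error of an isolated
# sphere well below 1% at the default 960 points.

#' Solvent-accessible surface area time series
#'
#' Per-frame Shrake-Rupley SASA of a selection, in square Angstrom, computed
#' in the context of the full complex: atoms outside the selection still
#' occlude its surface. Atom radii come from the Bondi table; an element
#' without a tabulated radius raises a parameterization error naming it.
#'
#' @param traj a [Trajectory-class]
#' @param selection a [ResidueSelection-class] (heavy atoms recommended)
#' @param probeRadius probe radius in Angstrom (default 1.4, water)
#' @param nPoints sphere test points per atom (default 960)
#' @param frames optional frame indices (default all)
#' @return data.frame `time_ns`, `value` (Angstrom^2), `label`
#' @export
sasaTimeSeries <- function(traj, selection, probeRadius = 1.4, nPoints = 960L,
                           frames = NULL) {
  stopifnot(is(traj, "Trajectory"), is(selection, "ResidueSelection"),
            probeRadius >= 0)
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  a <- traj@topology@atoms
  radii <- .bondiRadii[a$element]
  if (any(is.na(radii))) {
    bad <- unique(a$element[is.na(radii)])
    stop("parameterization error: no radius for element(s): ",
         paste(bad, collapse = ", "))
  }
  radii <- unname(radii) + probeRadius
  sphere <- .spherePoints(nPoints)
  selIdx <- selection@atomIndices
  vals <- vapply(frames, function(f) {
    X <- .rowToXYZ(traj@xyz[f, ])
    .sasaFrame(X, radii, selIdx, sphere)
  }, numeric(1))
  .timeSeries(traj@times[frames], vals, paste0("sasa:", selection@domain))
}

.sasaFrame <- function(X, radii, selIdx, sphere) {
  n <- nrow(X)
  total <- 0
  maxR <- max(radii)
  for (i in selIdx) {
    ri <- radii[i]
    d2 <- rowSums(sweep(X, 2L, X[i, ])^2)
    nb <- which(d2 < (ri + maxR)^2 & d2 > 1e-12)
    nb <- nb[sqrt(d2[nb]) < ri + radii[nb]]
    pts <- sweep(sphere * ri, 2L, X[i, ], `+`)
    if (length(nb)) {
      acc <- rep(TRUE, nrow(pts))
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- rowSums(sweep(pts[acc, , drop = FALSE], 2L, X[j, ])^2)
        acc[acc] <- dj2 > radii[j]^2
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    total <- total + frac * 4 * pi * ri^2
  }
  total
}
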