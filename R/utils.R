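# Internal helpers shared across modules.

# standard atomic weights (amu) for the elements that occur in protein work
.elementMasses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
                    MG = 24.305, CA = 40.078, "NA" = 22.99, K = 39.098,
                    CL = 35.45, MN = 54.938)

# Bondi van der Waals radii (Angstrom) for SASA
.bondiRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Infer the element from an atom name using the PDB convention: strip leading
# digits, take the leading one/two characters. Two-letter elements are only
# accepted when they are known (avoids reading "CA" [C-alpha] as calcium).
.elementFromName <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("^[0-9' ]+", "", trimws(nm))
    if (nchar(s) == 0L) return("X")
    two <- toupper(substr(s, 1L, 2L))
    one <- toupper(substr(s, 1L, 1L))
    if (two %in% c("FE", "ZN", "MG", "MN", "SE", "BR") && nchar(s) == 2L) two else one
  }, character(1), USE.NAMES = FALSE)
}

.massFromElement <- function(element) {
  m <- .elementMasses[toupper(element)]
  m[is.na(m)] <- 12.011  # fall back to carbon rather than refuse plumbing
  unname(m)
}

# node id used throughout the network/DF layers
.nodeId <- function(chain, resno) paste0(chain, ":", resno)

# expand a frames x 3n coordinate matrix row into an n x 3 matrix
.rowToXYZ <- function(row) matrix(row, ncol = 3L, byrow = TRUE)

.xyzToRow <- function(m) as.numeric(t(m))

# column index triplets for a set of atom indices in the 3n layout
.xyzCols <- function(atomIdx) {
  as.integer(rbind(3L * atomIdx - 2L, 3L * atomIdx - 1L, 3L * atomIdx))
}

# centre of mass of selected atoms for every frame; returns frames x 3
.comSeries <- function(traj, sel, massWeighted = TRUE) {
  idx <- sel@atomIndices
  w <- if (massWeighted) traj@topology@atoms$mass[idx] else rep(1, length(idx))
  w <- w / sum(w)
  X <- traj@xyz[, 3L * idx - 2L, drop = FALSE]
  Y <- traj@xyz[, 3L * idx - 1L, drop = FALSE]
  Z <- traj@xyz[, 3L * idx, drop = FALSE]
  cbind(X %*% w, Y %*% w, Z %*% w)
}

# centred running mean over a time window (ns); width 0 returns the input
.runningMean <- function(values, times, widthNs) {
  if (is.null(widthNs) || widthNs <= 0) return(values)
  n <- length(values)
  out <- numeric(n)
  half <- widthNs / 2
  j0 <- 1L
  j1 <- 1L
  for (i in seq_len(n)) {
    while (times[j0] < times[i] - half) j0 <- j0 + 1L
    while (j1 < n && times[j1 + 1L] <= times[i] + half) j1 <- j1 + 1L
    out[i] <- mean(values[j0:j1])
  }
  out
}

# rotation matrix: angle (radians) about unit axis (Rodrigues)
.rotationMatrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + s1 * K + (1 - c1) * (K %*% K)
}

# near-uniform points on the unit sphere (golden-section spiral)
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# adjusted Rand index between two labelings (same names or same order)
.adjustedRandIndex <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxidx <- (ai + bj) / 2
  if (abs(maxidx - expected) < 1e-12) return(1)
  (sumij - expected) / (maxidx - expected)
}

# frame indices whose times fall in [startNs, endNs]
.framesInWindow <- function(traj, startNs, endNs) {
  which(traj@times >= startNs - 1e-9 & traj@times <= endNs + 1e-9)
}

#' Frame indices of the trailing time window
#'
#' Convenience selector for analyses performed on the final stretch of a
#' trajectory (e.g. the trailing 200 ns conventionally used for dynamical
#' network analysis).
#'
#' @param traj a [Trajectory-class]
#' @param ns window length in nanoseconds (default 200)
#' @return integer vector of frame indices
#' @export
lastWindow <- function(traj, ns = 200) {
  stopifnot(is(traj, "Trajectory"))
  tEnd <- traj@times[length(traj@times)]
  .framesInWindow(traj, tEnd - ns, tEnd)
}

#' Frame indices of a time window
#'
#' @param traj a [Trajectory-class]
#' @param startNs,endNs window bounds in nanoseconds (inclusive)
#' @return integer vector of frame indices
#' @export
timeWindow <- function(traj, startNs, endNs) {
  stopifnot(is(traj, "Trajectory"), startNs <= endNs)
  .framesInWindow(traj, startNs, endNs)
}

# tidy TimeSeries constructor: data.frame(time_ns, value, label)
.timeSeries <- function(times, values, label) {
  stopifnot(length(times) == length(values))
  if (any(!is.finite(values)))
    stop("time series values must be finite")
  data.frame(time_ns = times, value = values, label = label,
             stringsAsFactors = FALSE)
}
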