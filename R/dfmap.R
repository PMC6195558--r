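# Distance-fluctuation (plasticity) maps: the variance of every pairwise
# C-alpha distance over a trajectory window. Pairwise distances are
# frame-internal, so no superposition is required and the map is invariant
# under per-frame rigid transformations.

#' Distance-fluctuation matrix
#'
#' `DF_ij = < (d_ij - <d_ij>)^2 >` over the window frames, where `d_ij` is
#' the distance between the C-alpha atoms of residues i and j and `< >` is
#' the time average (moment definition, 1/n). Computed with a numerically
#' stable two-pass algorithm. Entries are in Angstrom^2; values below about
#' 0.3 Angstrom^2 are conventionally read as rigid-body-like coordination.
#'
#' @param traj a [Trajectory-class]
#' @param selection a [ResidueSelection-class]; its C-alpha atoms become the
#'   nodes (one atom per residue required)
#' @param window optional integer vector of frame indices (>= 2 frames)
#' @return symmetric matrix with zero diagonal; dimnames are node ids
#'   `"chain:resno"`, attribute `window_ns` records the time span used
#' @export
distanceFluctuationMatrix <- function(traj, selection, window = NULL) {
  stopifnot(is(traj, "Trajectory"), is(selection, "ResidueSelection"))
  if (is.null(window)) window <- seq_len(nFrames(traj))
  if (length(window) < 2L)
    stop("insufficient-data error: need >= 2 frames for distance fluctuations")
  a <- traj@topology@atoms
  idx <- selection@atomIndices
  idx <- idx[a$name[idx] == "CA"]
  if (anyDuplicated(paste(a$chain[idx], a$resno[idx])))
    stop("selection must provide one C-alpha per residue")
  n <- length(idx)
  if (n < 2L) stop("need >= 2 residues")
  ids <- .nodeId(a$chain[idx], a$resno[idx])
  nf <- length(window)
  # two-pass variance over per-frame distance vectors
  dbar <- numeric(n * (n - 1L) / 2L)
  for (f in window) {
    X <- .rowToXYZ(traj@xyz[f, ])[idx, , drop = FALSE]
    dbar <- dbar + as.numeric(dist(X))
  }
  dbar <- dbar / nf
  acc <- numeric(length(dbar))
  for (f in window) {
    X <- .rowToXYZ(traj@xyz[f, ])[idx, , drop = FALSE]
    dv <- as.numeric(dist(X)) - dbar
    acc <- acc + dv * dv
  }
  acc <- acc / nf
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  m[lower.tri(m)] <- acc
  m <- m + t(m)
  attr(m, "window_ns") <- range(traj@times[window])
  m
}

#' Inter-domain distance-fluctuation summary
#'
#' Extracts the block of a DF matrix connecting two domains and summarizes
#' it: mean DF and the fraction of residue pairs below the rigidity
#' threshold. For a domain against itself the diagonal is excluded.
#'
#' @param dfmat matrix from [distanceFluctuationMatrix()]
#' @param map a [DomainMap-class]
#' @param domA,domB entry names in `map`
#' @param threshold rigidity threshold in Angstrom^2 (default 0.3)
#' @return list with `block` (sub-matrix), `meanDF`, `fractionBelow`,
#'   `threshold`, `nPairs`
#' @export
interdomainDFSummary <- function(dfmat, map, domA, domB, threshold = 0.3) {
  stopifnot(is(map, "DomainMap"))
  ids <- rownames(dfmat)
  pick <- function(nm) {
    if (!nm %in% names(map@entries))
      stop("key error: domain '", nm, "' not in map")
    r <- map@entries[[nm]]
    sel <- rep(FALSE, length(ids))
    ch <- sub(":.*$", "", ids)
    no <- as.integer(sub("^.*:", "", ids))
    for (i in seq_len(nrow(r)))
      sel <- sel | (ch == r$chain[i] & no >= r$start[i] & no <= r$end[i])
    which(sel)
  }
  ia <- pick(domA); ib <- pick(domB)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("key error: domain rows absent from the matrix")
  block <- dfmat[ia, ib, drop = FALSE]
  vals <- as.numeric(block)
  if (identical(domA, domB)) {
    keep <- as.numeric(row(block)) != as.numeric(col(block))
    vals <- vals[keep]
  }
  list(block = block, meanDF = mean(vals),
       fractionBelow = mean(vals < threshold),
       threshold = threshold, nPairs = length(vals))
}

#' Write a DF matrix in long form
#'
#' CSV columns: `res_i`, `res_j`, `df_A2` (upper triangle only).
#'
#' @param dfmat matrix from [distanceFluctuationMatrix()]
#' @param path output file
#' @return invisibly, the path
#' @export
writeDFLongCSV <- function(dfmat, path) {
  ids <- rownames(dfmat)
  ut <- which(upper.tri(dfmat), arr.ind = TRUE)
  df <- data.frame(res_i = ids[ut[, 1L]], res_j = ids[ut[, 2L]],
                   df_A2 = dfmat[ut], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
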