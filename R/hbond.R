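# Hydrogen-bond and salt-bridge detection, per-frame inter-domain counts and
# windowed per-pair occupancy tables.

#' Hydrogen-bond geometric criteria
#'
#' Defaults follow the GROMACS hbond convention: donor-acceptor distance
#' <= 3.5 Angstrom and hydrogen-donor-acceptor angle <= 30 degrees. A
#' heavy-atom fallback (distance criterion only, between N/O atoms) is
#' available for reduced systems without explicit hydrogens.
#'
#' @param distanceCutoff donor-acceptor distance cutoff in Angstrom (> 0)
#' @param angleCutoff hydrogen-donor-acceptor angle cutoff in degrees
#'   (0 < angle < 90)
#' @param heavyAtomOnly if TRUE, apply the distance criterion between
#'   donor/acceptor heavy atoms only (no hydrogens required)
#' @return a list of class criteria used by the detection functions
#' @export
hbondCriteria <- function(distanceCutoff = 3.5, angleCutoff = 30,
                          heavyAtomOnly = FALSE) {
  stopifnot(distanceCutoff > 0, angleCutoff > 0, angleCutoff < 90)
  list(distanceCutoff = distanceCutoff, angleCutoff = angleCutoff,
       heavyAtomOnly = heavyAtomOnly)
}

# Precompute donor/hydrogen/acceptor candidates for a selection pair.
.hbondContext <- function(traj, selA, selB, criteria) {
  a <- traj@topology@atoms
  polar <- function(sel) {
    idx <- sel@atomIndices
    idx[a$element[idx] %in% c("N", "O")]
  }
  hydIn <- function(sel) {
    idx <- sel@atomIndices
    idx[a$element[idx] == "H"]
  }
  pa <- polar(selA); pb <- polar(selB)
  if (!criteria$heavyAtomOnly) {
    ha <- hydIn(selA); hb <- hydIn(selB)
    if (length(ha) + length(hb) == 0L)
      stop("topology error: no hydrogens in the selections; ",
           "request the heavy-atom fallback (heavyAtomOnly = TRUE)")
    # candidate hydrogens per donor: same residue, element H
    hFor <- function(donors, hyd) {
      lapply(donors, function(d)
        hyd[a$chain[hyd] == a$chain[d] & a$resno[hyd] == a$resno[d]])
    }
    list(a = a, donA = pa, donB = pb, accA = pa, accB = pb,
         hA = hFor(pa, ha), hB = hFor(pb, hb), criteria = criteria)
  } else {
    list(a = a, donA = pa, donB = pb, accA = pa, accB = pb, criteria = criteria)
  }
}

# One frame: matrix with columns donor, hydrogen (NA in fallback), acceptor.
.hbondPairsFrame <- function(ctx, X) {
  crit <- ctx$criteria
  out <- list()
  sides <- list(list(don = ctx$donA, hs = ctx$hA, acc = ctx$accB),
                list(don = ctx$donB, hs = ctx$hB, acc = ctx$accA))
  for (s in sides) {
    if (length(s$don) == 0L || length(s$acc) == 0L) next
    for (k in seq_along(s$don)) {
      d <- s$don[k]
      dv <- sweep(X[s$acc, , drop = FALSE], 2L, X[d, ])
      dist <- sqrt(rowSums(dv^2))
      near <- which(dist <= crit$distanceCutoff & dist > 1e-9)
      if (length(near) == 0L) next
      if (crit$heavyAtomOnly) {
        out[[length(out) + 1L]] <- cbind(d, NA_integer_, s$acc[near])
      } else {
        hs <- s$hs[[k]]
        if (length(hs) == 0L) next
        hv <- sweep(X[hs, , drop = FALSE], 2L, X[d, ])
        hd <- sqrt(rowSums(hv^2))
        hs <- hs[hd < 1.25]; hv <- hv[hd < 1.25, , drop = FALSE]
        if (length(hs) == 0L) next
        for (ai in near) {
          av <- dv[ai, ] / dist[ai]
          cosang <- (hv %*% av) / sqrt(rowSums(hv^2))
          ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
          best <- which.min(ang)
          if (ang[best] <= crit$angleCutoff)
            out[[length(out) + 1L]] <- cbind(d, hs[best], s$acc[ai])
        }
      }
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 3L))
  prs <- do.call(rbind, out)
  if (crit$heavyAtomOnly && nrow(prs) > 1L) {
    # both directions were scanned: keep each unordered atom pair once,
    # oriented with the nitrogen (if any) as donor
    a <- ctx$a
    key <- paste(pmin(prs[, 1L], prs[, 3L]), pmax(prs[, 1L], prs[, 3L]))
    prs <- prs[!duplicated(key), , drop = FALSE]
    flip <- a$element[prs[, 1L]] == "O" & a$element[prs[, 3L]] == "N"
    if (any(flip)) prs[flip, c(1L, 3L)] <- prs[flip, c(3L, 1L)]
  }
  prs
}

#' Detect hydrogen bonds in one frame
#'
#' All donor-H...acceptor triples with the donor in one selection and the
#' acceptor in the other (both directions considered) that pass the distance
#' and angle criteria. With `heavyAtomOnly` criteria, N/O pairs within the
#' distance cutoff are reported and the hydrogen column is NA.
#'
#' @param traj a [Trajectory-class]
#' @param frame 1-based frame index
#' @param selA,selB [ResidueSelection-class] objects
#' @param criteria from [hbondCriteria()]
#' @return data.frame with donor/acceptor residue and atom descriptors plus
#'   the frame index; zero rows when no bond is present
#' @export
detectHbondsFrame <- function(traj, frame, selA, selB, criteria = hbondCriteria()) {
  stopifnot(is(traj, "Trajectory"), frame >= 1L, frame <= nFrames(traj))
  ctx <- .hbondContext(traj, selA, selB, criteria)
  prs <- .hbondPairsFrame(ctx, frameCoords(traj, frame))
  a <- traj@topology@atoms
  d <- prs[, 1L]; ac <- prs[, 3L]
  data.frame(
    donorChain = a$chain[d], donorResno = a$resno[d], donorResname = a$resname[d],
    donorAtom = a$name[d],
    hydrogenAtom = ifelse(is.na(prs[, 2L]), NA_character_, a$name[prs[, 2L]]),
    acceptorChain = a$chain[ac], acceptorResno = a$resno[ac],
    acceptorResname = a$resname[ac], acceptorAtom = a$name[ac],
    frame = rep(as.integer(frame), nrow(prs)), stringsAsFactors = FALSE)
}

#' Inter-domain hydrogen-bond count time series
#'
#' Number of hydrogen bonds between two selections per frame. The raw count
#' is canonical; `smoothNs` additionally applies a centred running mean of
#' the given width.
#'
#' @param traj a [Trajectory-class]
#' @param selA,selB [ResidueSelection-class] objects
#' @param criteria from [hbondCriteria()]
#' @param smoothNs optional running-mean window in ns (NULL = raw)
#' @param frames optional frame indices (default all)
#' @return data.frame `time_ns`, `value`, `label`
#' @export
interdomainHbondCount <- function(traj, selA, selB, criteria = hbondCriteria(),
                                  smoothNs = NULL, frames = NULL) {
  stopifnot(is(traj, "Trajectory"))
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  ctx <- .hbondContext(traj, selA, selB, criteria)
  counts <- vapply(frames, function(f)
    nrow(.hbondPairsFrame(ctx, frameCoords(traj, f))), numeric(1))
  if (!is.null(smoothNs)) counts <- .runningMean(counts, traj@times[frames], smoothNs)
  .timeSeries(traj@times[frames], counts,
              paste0("hbonds:", selA@domain, "-", selB@domain))
}

# residue-pair key helper: canonical direction = (selA residue, selB residue)
.pairLabel <- function(chainA, resnameA, resnoA, chainB, resnameB, resnoB) {
  sprintf("%s:%s%d--%s:%s%d", chainA, resnameA, resnoA, chainB, resnameB, resnoB)
}

# Build tiling windows over [t0, tEnd]; the last window absorbs the remainder.
.makeWindows <- function(times, windowNs) {
  t0 <- times[1L]; tEnd <- times[length(times)]
  if (length(times) > 1L && windowNs < min(diff(times)) - 1e-9)
    stop("resolution error: window shorter than the frame spacing")
  if (windowNs > tEnd - t0 + 1e-9) {
    starts <- t0
  } else {
    starts <- seq(t0, tEnd - 1e-9, by = windowNs)
  }
  ends <- c(starts[-1L], tEnd + 1e-9)
  data.frame(start_ns = starts, end_ns = pmin(ends, tEnd),
             label = sprintf("%g-%gns", starts, round(pmin(ends, tEnd), 3)),
             stringsAsFactors = FALSE)
}

.windowIndex <- function(times, windows) {
  findInterval(times, c(windows$start_ns, Inf), rightmost.closed = FALSE,
               left.open = FALSE)
}

# shared occupancy assembly: bondedPairs = list per analysed frame of
# character pair keys; pairInfo = data.frame keyed by label
.occupancyTable <- function(times, windows, framePairs, pairInfo) {
  widx <- .windowIndex(times, windows)
  widx[widx > nrow(windows)] <- nrow(windows)
  labels <- pairInfo$label
  occ <- matrix(0, nrow(pairInfo), nrow(windows))
  denom <- tabulate(widx, nbins = nrow(windows))
  for (f in seq_along(framePairs)) {
    hit <- unique(framePairs[[f]])
    if (length(hit))
      occ[match(hit, labels), widx[f]] <- occ[match(hit, labels), widx[f]] + 1
  }
  occ <- sweep(occ, 2L, pmax(denom, 1L), `/`)
  new("OccupancyTable", pairs = pairInfo, occupancy = occ, windows = windows)
}

#' Windowed hydrogen-bond occupancy per residue pair
#'
#' For every residue pair ever bonded between the two selections, the
#' fraction of frames within each consecutive time window in which at least
#' one hydrogen bond links the pair. Windows tile the analysed interval; the
#' trailing partial window absorbs the remainder. Use [occupancyFlags()] for
#' the strict sub-50% marking.
#'
#' @param traj a [Trajectory-class]
#' @param selA,selB [ResidueSelection-class] objects
#' @param criteria from [hbondCriteria()]
#' @param windowNs window length in ns (e.g. 50)
#' @param frames optional frame indices (default all)
#' @return an [OccupancyTable-class]
#' @export
pairOccupancy <- function(traj, selA, selB, criteria = hbondCriteria(),
                          windowNs = 50, frames = NULL) {
  stopifnot(is(traj, "Trajectory"), windowNs > 0)
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  times <- traj@times[frames]
  windows <- .makeWindows(times, windowNs)
  ctx <- .hbondContext(traj, selA, selB, criteria)
  a <- traj@topology@atoms
  inA <- seq_len(nrow(a)) %in% selA@atomIndices
  framePairs <- vector("list", length(frames))
  seen <- list()
  for (k in seq_along(frames)) {
    prs <- .hbondPairsFrame(ctx, frameCoords(traj, frames[k]))
    if (nrow(prs) == 0L) { framePairs[[k]] <- character(0); next }
    # orient every record as (selA residue, selB residue)
    d <- prs[, 1L]; ac <- prs[, 3L]
    aFirst <- ifelse(inA[d], d, ac)
    bSecond <- ifelse(inA[d], ac, d)
    key <- .pairLabel(a$chain[aFirst], a$resname[aFirst], a$resno[aFirst],
                      a$chain[bSecond], a$resname[bSecond], a$resno[bSecond])
    framePairs[[k]] <- key
    new <- !(key %in% names(seen))
    for (i in which(new & !duplicated(key)))
      seen[[key[i]]] <- c(aFirst[i], bSecond[i])
  }
  if (length(seen) == 0L) {
    pairInfo <- data.frame(chainA = character(0), resnoA = integer(0),
                           resnameA = character(0), chainB = character(0),
                           resnoB = integer(0), resnameB = character(0),
                           label = character(0), stringsAsFactors = FALSE)
  } else {
    ij <- do.call(rbind, seen)
    pairInfo <- data.frame(
      chainA = a$chain[ij[, 1L]], resnoA = a$resno[ij[, 1L]],
      resnameA = a$resname[ij[, 1L]], chainB = a$chain[ij[, 2L]],
      resnoB = a$resno[ij[, 2L]], resnameB = a$resname[ij[, 2L]],
      label = names(seen), stringsAsFactors = FALSE)
    ord <- order(pairInfo$chainA, pairInfo$resnoA, pairInfo$chainB, pairInfo$resnoB)
    pairInfo <- pairInfo[ord, , drop = FALSE]
    rownames(pairInfo) <- NULL
  }
  .occupancyTable(times, windows, framePairs, pairInfo)
}

# charged side-chain atoms by residue name
.saltAtoms <- function(a, idx) {
  pos <- idx[a$resname[idx] %in% c("LYS", "ARG", "HIS", "HSP") &
             a$element[idx] == "N" & !(a$name[idx] %in% c("N"))]
  neg <- idx[a$resname[idx] %in% c("ASP", "GLU") &
             a$element[idx] == "O" & !(a$name[idx] %in% c("O"))]
  list(pos = pos, neg = neg)
}

#' Windowed salt-bridge occupancy per residue pair
#'
#' A bridge exists in a frame when any side-chain nitrogen of a basic residue
#' (LYS/ARG/HIS) in one selection lies within `cutoff` of any side-chain
#' carboxylate oxygen of an acidic residue (ASP/GLU) in the other. Windowing
#' as in [pairOccupancy()].
#'
#' @param traj a [Trajectory-class]
#' @param selA,selB [ResidueSelection-class] objects
#' @param cutoff N(+)...O(-) distance cutoff in Angstrom (default 4.0)
#' @param windowNs window length in ns
#' @param frames optional frame indices
#' @return an [OccupancyTable-class]
#' @export
detectSaltBridges <- function(traj, selA, selB, cutoff = 4.0, windowNs = 50,
                              frames = NULL) {
  stopifnot(is(traj, "Trajectory"), cutoff > 0)
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  times <- traj@times[frames]
  windows <- .makeWindows(times, windowNs)
  a <- traj@topology@atoms
  sa <- .saltAtoms(a, selA@atomIndices)
  sb <- .saltAtoms(a, selB@atomIndices)
  # candidate atom pairs in both charge orientations, oriented (selA, selB)
  cand <- rbind(
    if (length(sa$pos) && length(sb$neg))
      expand.grid(i = sa$pos, j = sb$neg, KEEP.OUT.ATTRS = FALSE),
    if (length(sa$neg) && length(sb$pos))
      expand.grid(i = sa$neg, j = sb$pos, KEEP.OUT.ATTRS = FALSE))
  framePairs <- vector("list", length(frames))
  seen <- list()
  if (!is.null(cand) && nrow(cand)) {
    for (k in seq_along(frames)) {
      X <- frameCoords(traj, frames[k])
      dd <- sqrt(rowSums((X[cand$i, , drop = FALSE] - X[cand$j, , drop = FALSE])^2))
      hit <- which(dd <= cutoff)
      if (length(hit) == 0L) { framePairs[[k]] <- character(0); next }
      i <- cand$i[hit]; j <- cand$j[hit]
      key <- .pairLabel(a$chain[i], a$resname[i], a$resno[i],
                        a$chain[j], a$resname[j], a$resno[j])
      framePairs[[k]] <- key
      for (q in which(!(key %in% names(seen)) & !duplicated(key)))
        seen[[key[q]]] <- c(i[q], j[q])
    }
  } else {
    framePairs <- replicate(length(frames), character(0), simplify = FALSE)
  }
  if (length(seen) == 0L) {
    pairInfo <- data.frame(chainA = character(0), resnoA = integer(0),
                           resnameA = character(0), chainB = character(0),
                           resnoB = integer(0), resnameB = character(0),
                           label = character(0), stringsAsFactors = FALSE)
  } else {
    ij <- do.call(rbind, seen)
    pairInfo <- data.frame(
      chainA = a$chain[ij[, 1L]], resnoA = a$resno[ij[, 1L]],
      resnameA = a$resname[ij[, 1L]], chainB = a$chain[ij[, 2L]],
      resnoB = a$resno[ij[, 2L]], resnameB = a$resname[ij[, 2L]],
      label = names(seen), stringsAsFactors = FALSE)
    rownames(pairInfo) <- NULL
  }
  .occupancyTable(times, windows, framePairs, pairInfo)
}

#' Write an occupancy table as CSV
#'
#' Rows are residue-pair labels, columns the window labels.
#'
#' @param table an [OccupancyTable-class]
#' @param path output file
#' @return invisibly, the path
#' @export
writeOccupancyCSV <- function(table, path) {
  m <- occupancy(table)
  df <- data.frame(pair = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
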