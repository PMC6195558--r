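# Synthetic multi-domain trajectories with planted ground truth: correlated
# Gaussian displacements (Cholesky of the block correlation matrix) around a
# fixed mean structure, scheduled pseudo hydrogen-bond / salt-bridge sites,
# and a scripted rigid-body detachment (hinge rotation plus an exact
# centre-of-mass separation step). The generator drives every validation
# stage of the pipeline; it emulates motional statistics and contact
# schedules, not protein stereochemistry.

# run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Declare a scheduled pseudo-contact
#'
#' Builds one row of the contact table of a [SyntheticSpec-class]. A
#' `"hbond"` contact plants backbone-like donor atoms (N, HN) on the donor
#' residue and an acceptor O on the acceptor residue; a `"salt"` contact
#' plants a charged side-chain nitrogen (NZ/NH1 with hydrogen) and a
#' carboxylate oxygen (OE1/OE2), which is detected by both the hydrogen-bond
#' and the salt-bridge layer. While a contact is scheduled "on" the
#' donor-acceptor distance is held at 2.9 Angstrom (3.4 for salt) with a 5
#' degree hydrogen deviation; while "off" the acceptor site sits 6 Angstrom
#' away, outside every default cutoff.
#'
#' @param id contact identifier
#' @param donorDomain,donorRes,donorResname donor residue (domain name,
#'   residue number, residue name)
#' @param acceptorDomain,acceptorRes,acceptorResname acceptor residue
#' @param type `"hbond"` or `"salt"`
#' @param on two-column matrix of inclusive frame intervals during which the
#'   contact is formed
#' @return one-row data.frame suitable for `rbind`
#' @export
contactSchedule <- function(id, donorDomain, donorRes, donorResname,
                            acceptorDomain, acceptorRes, acceptorResname,
                            type = c("hbond", "salt"), on) {
  type <- match.arg(type)
  if (is.vector(on)) on <- matrix(on, ncol = 2L, byrow = TRUE)
  data.frame(id = id, donorDomain = donorDomain, donorRes = as.integer(donorRes),
             donorResname = donorResname, acceptorDomain = acceptorDomain,
             acceptorRes = as.integer(acceptorRes),
             acceptorResname = acceptorResname, type = type,
             on = I(list(on)), stringsAsFactors = FALSE)
}

.emptyContacts <- function() {
  data.frame(id = character(0), donorDomain = character(0),
             donorRes = integer(0), donorResname = character(0),
             acceptorDomain = character(0), acceptorRes = integer(0),
             acceptorResname = character(0), type = character(0),
             on = I(list()), stringsAsFactors = FALSE)
}

#' Build a synthetic-trajectory specification
#'
#' See [SyntheticSpec-class] for slot semantics and
#' [generateTrajectory()] for the generation model.
#'
#' @param domains data.frame (`name`, `chain`, `startRes`, `endRes`, `cx`,
#'   `cy`, `cz`, `sigma`)
#' @param rhoIntra planted intra-domain correlation
#' @param rhoInter planted inter-domain correlation (scalar or named matrix)
#' @param layout `"blob"` or `"helix"`
#' @param meanCoords optional explicit mean structure (beads x 3)
#' @param contacts contact table from [contactSchedule()] rows
#' @param hinge,detach optional scripted-detachment descriptions
#' @param nframes,dtNs,seed frame count, spacing (ns), random seed
#' @return a validated [SyntheticSpec-class]
#' @export
syntheticSpec <- function(domains, rhoIntra = 0.7, rhoInter = 0.05,
                          layout = c("blob", "helix"), meanCoords = NULL,
                          contacts = .emptyContacts(), hinge = list(),
                          detach = list(), nframes = 1000L, dtNs = 1,
                          seed = 1L) {
  layout <- match.arg(layout)
  new("SyntheticSpec", domains = domains, rhoIntra = rhoIntra,
      rhoInter = rhoInter, layout = layout, meanCoords = meanCoords,
      contacts = contacts, hinge = hinge, detach = detach,
      nframes = as.integer(nframes), dtNs = dtNs, seed = as.integer(seed))
}

# ---- layouts ---------------------------------------------------------------

# compact quasi-random blob: n beads in a sphere sized to protein-like density
.blobLayout <- function(n, center, minSep = 3.4) {
  radius <- max(4, (3 * 120 * n / (4 * pi))^(1 / 3))
  pts <- matrix(NA_real_, n, 3L)
  k <- 0L
  tries <- 0L
  while (k < n) {
    p <- stats::runif(3L, -radius, radius)
    if (sum(p^2) > radius^2) next
    tries <- tries + 1L
    if (k == 0L || min(sqrt(rowSums(sweep(pts[seq_len(k), , drop = FALSE],
                                          2L, p)^2))) >= minSep) {
      k <- k + 1L
      pts[k, ] <- p
    } else if (tries > 2000L * n) {
      minSep <- minSep * 0.95  # relax packing rather than loop forever
      tries <- 0L
    }
  }
  sweep(pts, 2L, center, `+`)
}

# alpha-helical trace: consecutive beads 3.8 A apart
.helixLayout <- function(n, center) {
  i <- seq_len(n)
  r <- 2.3; rise <- 1.5; step <- 100 * pi / 180
  pts <- cbind(r * cos(i * step), r * sin(i * step), rise * i)
  sweep(pts, 2L, center - colMeans(pts), `+`)
}

.autoLayout <- function(spec) {
  d <- spec@domains
  nper <- d$endRes - d$startRes + 1L
  if (spec@layout == "helix") {
    return(.helixLayout(sum(nper), c(mean(d$cx), mean(d$cy), mean(d$cz))))
  }
  do.call(rbind, lapply(seq_len(nrow(d)), function(k)
    .blobLayout(nper[k], c(d$cx[k], d$cy[k], d$cz[k]))))
}

# ---- generation ------------------------------------------------------------

.beadTable <- function(spec) {
  d <- spec@domains
  rows <- lapply(seq_len(nrow(d)), function(k) {
    resno <- d$startRes[k]:d$endRes[k]
    data.frame(domain = d$name[k], chain = d$chain[k], resno = resno,
               resname = "GLY", sigma = d$sigma[k], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.plantedCorrelation <- function(spec, beads) {
  d <- spec@domains
  n <- nrow(beads)
  dom <- match(beads$domain, d$name)
  K <- nrow(d)
  R <- matrix(NA_real_, K, K, dimnames = list(d$name, d$name))
  if (is.matrix(spec@rhoInter)) {
    R[rownames(spec@rhoInter), colnames(spec@rhoInter)] <- spec@rhoInter
    R[is.na(R)] <- 0
  } else {
    R[] <- spec@rhoInter
  }
  diag(R) <- spec@rhoIntra
  C <- R[dom, dom]
  diag(C) <- 1
  ids <- .nodeId(beads$chain, beads$resno)
  dimnames(C) <- list(ids, ids)
  C
}

# detachment fraction per frame
.lambdaSchedule <- function(spec) {
  lam <- rep(0, spec@nframes)
  if (length(spec@detach)) {
    de <- spec@detach
    lam[de$frame:spec@nframes] <- 1
    if (!is.null(de$transientFrames)) {
      tf <- de$transientFrames
      frac <- if (is.null(de$transientFraction)) 0.3 else de$transientFraction
      lam[tf[1L]:tf[2L]] <- frac
    }
  }
  lam
}

# rigid transform of the moving domain for a detachment fraction lambda,
# defined on the mean structure; returns function(points) -> points
.detachTransform <- function(meanX, beads, spec, lambda) {
  if (lambda == 0 || !length(spec@detach)) return(identity)
  de <- spec@detach
  mv <- beads$domain == de$domain
  rf <- beads$domain == de$reference
  G0 <- colMeans(meanX[mv, , drop = FALSE])
  C0 <- colMeans(meanX[rf, , drop = FALSE])
  d0 <- sqrt(sum((G0 - C0)^2))
  target <- d0 + lambda * de$deltaA
  if (length(spec@hinge)) {
    hg <- spec@hinge
    pivotSel <- mv & beads$resno >= hg$pivotRes[1L] & beads$resno <= hg$pivotRes[2L]
    armSel <- mv & beads$resno >= hg$armRes[1L] & beads$resno <= hg$armRes[2L]
    tgtSel <- beads$domain == hg$targetDomain & beads$resno == hg$targetRes
    H <- colMeans(meanX[pivotSel, , drop = FALSE])
    B <- colMeans(meanX[armSel, , drop = FALSE])
    A <- colMeans(meanX[tgtSel, , drop = FALSE])
    nhat <- .crossProd(A - H, B - H)
    nhat <- nhat / sqrt(sum(nhat^2))
    dTheta <- (hg$angleEndDeg - hg$angleStartDeg) * pi / 180 * lambda
    # pick the rotation sense that opens the apex angle
    openAngle <- function(R) {
      Brot <- as.numeric(R %*% (B - H)) + H
      v1 <- A - H; v2 <- Brot - H
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
    }
    R1 <- .rotationMatrix(nhat, dTheta)
    R2 <- .rotationMatrix(nhat, -dTheta)
    R <- if (openAngle(R1) >= openAngle(R2)) R1 else R2
    G1 <- as.numeric(R %*% (G0 - H)) + H
    v <- G1 - C0
    # axial translation preserving the apex angle exactly
    bq <- 2 * sum(v * nhat)
    cq <- sum(v^2) - target^2
    disc <- bq^2 - 4 * cq
    if (disc >= 0) {
      roots <- c((-bq + sqrt(disc)) / 2, (-bq - sqrt(disc)) / 2)
      tshift <- roots[which.min(abs(roots))] * nhat
    } else {
      # unreachable along the axis: small radial correction instead
      u <- v / sqrt(sum(v^2))
      tshift <- (target - sqrt(sum(v^2))) * u
    }
    function(points) sweep(points, 2L, H) %*% t(R) +
      matrix(H + tshift, nrow(points), 3L, byrow = TRUE)
  } else {
    u <- (G0 - C0) / d0
    shift <- lambda * de$deltaA * u
    function(points) sweep(points, 2L, shift, `+`)
  }
}

.crossProd <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# site-atom naming: pick the first unused name per residue
.siteAtomNames <- function(type, used) {
  cand <- if (type == "hbond") {
    list(don = c("N", "ND1", "ND2"), hyd = c("HN", "HD1", "HD2"),
         acc = c("O", "OD1", "OD2"))
  } else {
    list(don = c("NH1", "NZ", "NH2"), hyd = c("HH1", "HZ", "HH2"),
         acc = c("OE1", "OE2", "OE3"))
  }
  k <- 1L
  while (cand$don[k] %in% used$don || cand$acc[k] %in% used$acc) k <- k + 1L
  list(don = cand$don[k], hyd = cand$hyd[k], acc = cand$acc[k], slot = k)
}

#' Generate a synthetic trajectory with ground truth
#'
#' Frames are drawn as mean structure + correlated Gaussian displacements
#' (Cholesky factor of the planted block correlation matrix, per axis), the
#' scripted rigid-body detachment transform is applied to the moving domain
#' from its onset frame onward, and scheduled contact sites are placed at
#' bonded (2.9/3.4 Angstrom, 5 degree deviation) or broken (6 Angstrom)
#' geometry per frame. Output is deterministic for a fixed seed.
#'
#' @param spec a [SyntheticSpec-class]
#' @return list with `topology` ([Topology-class]), `trajectory`
#'   ([Trajectory-class]) and `truth` ([GroundTruth-class])
#' @export
generateTrajectory <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  beads <- .beadTable(spec)
  n <- nrow(beads)
  meanX <- if (!is.null(spec@meanCoords)) spec@meanCoords else
    .withSeed(spec@seed + 104729L, .autoLayout(spec))
  stopifnot(nrow(meanX) == n)
  # contact residues adopt their declared residue names
  ct <- spec@contacts
  if (nrow(ct)) {
    for (i in seq_len(nrow(ct))) {
      di <- which(beads$domain == ct$donorDomain[i] & beads$resno == ct$donorRes[i])
      ai <- which(beads$domain == ct$acceptorDomain[i] & beads$resno == ct$acceptorRes[i])
      if (length(di) != 1L || length(ai) != 1L)
        stop("spec error: contact '", ct$id[i], "' references unknown residues")
      beads$resname[di] <- ct$donorResname[i]
      beads$resname[ai] <- ct$acceptorResname[i]
    }
  }
  C <- .plantedCorrelation(spec, beads)
  ch <- tryCatch(chol(C), error = function(e) {
    big <- if (is.matrix(spec@rhoInter))
      paste(rownames(which(spec@rhoInter == max(spec@rhoInter), arr.ind = TRUE))[1L],
            collapse = "") else "inter-domain"
    stop("spec error: planted correlation matrix is not positive semidefinite ",
         "(check the ", big, " correlation block)")
  })
  nf <- spec@nframes
  lam <- .lambdaSchedule(spec)
  openNoiseA <- if (length(spec@detach) && !is.null(spec@detach$openNoiseA))
    spec@detach$openNoiseA else 0
  set.seed(spec@seed)
  U <- array(0, c(nf, n, 3L))
  for (ax in 1:3)
    U[, , ax] <- (matrix(stats::rnorm(nf * n), nf, n) %*% ch) * rep(beads$sigma, each = nf)
  # transforms cached per distinct lambda
  lamVals <- unique(lam)
  transforms <- lapply(lamVals, function(l) .detachTransform(meanX, beads, spec, l))
  names(transforms) <- as.character(lamVals)
  mvIdx <- if (length(spec@detach)) which(beads$domain == spec@detach$domain) else integer(0)

  # assemble atom table: CA beads plus contact site atoms, grouped by residue
  siteRows <- list()
  sitePlan <- list()
  if (nrow(ct)) {
    usedNames <- list()
    for (i in seq_len(nrow(ct))) {
      di <- which(beads$domain == ct$donorDomain[i] & beads$resno == ct$donorRes[i])
      ai <- which(beads$domain == ct$acceptorDomain[i] & beads$resno == ct$acceptorRes[i])
      keyD <- paste(beads$chain[di], beads$resno[di])
      keyA <- paste(beads$chain[ai], beads$resno[ai])
      used <- list(don = unlist(lapply(sitePlan, function(s)
                     if (s$keyD == keyD) s$names$don)),
                   acc = unlist(lapply(sitePlan, function(s)
                     if (s$keyA == keyA) s$names$acc)))
      nm <- .siteAtomNames(ct$type[i], used)
      onv <- rep(FALSE, nf)
      iv <- ct$on[[i]]
      if (length(iv)) for (r in seq_len(nrow(iv))) onv[iv[r, 1L]:iv[r, 2L]] <- TRUE
      sitePlan[[i]] <- list(contact = i, donorBead = di, acceptorBead = ai,
                            donorDomainBeads = which(beads$domain == ct$donorDomain[i]),
                            keyD = keyD, keyA = keyA, names = nm,
                            on = onv, type = ct$type[i],
                            donLen = if (ct$type[i] == "hbond") 1.5 else 2.0,
                            onLen = if (ct$type[i] == "hbond") 2.9 else 3.4,
                            offLen = 6.0)
    }
  }
  atomRows <- list()
  coordPlan <- list()   # per atom: list(type, bead | site role)
  serial <- 0L
  for (b in seq_len(n)) {
    serial <- serial + 1L
    atomRows[[length(atomRows) + 1L]] <- data.frame(
      serial = serial, name = "CA", element = "C", mass = 12.011,
      resno = beads$resno[b], resname = beads$resname[b], chain = beads$chain[b],
      stringsAsFactors = FALSE)
    coordPlan[[length(coordPlan) + 1L]] <- list(kind = "bead", bead = b)
    for (s in sitePlan) {
      if (s$donorBead == b) {
        for (role in c("don", "hyd")) {
          serial <- serial + 1L
          atomRows[[length(atomRows) + 1L]] <- data.frame(
            serial = serial, name = s$names[[role]],
            element = if (role == "don") "N" else "H",
            mass = if (role == "don") 14.007 else 1.008,
            resno = beads$resno[b], resname = beads$resname[b],
            chain = beads$chain[b], stringsAsFactors = FALSE)
          coordPlan[[length(coordPlan) + 1L]] <- list(kind = role, site = s)
        }
      }
      if (s$acceptorBead == b) {
        serial <- serial + 1L
        atomRows[[length(atomRows) + 1L]] <- data.frame(
          serial = serial, name = s$names$acc, element = "O", mass = 15.999,
          resno = beads$resno[b], resname = beads$resname[b],
          chain = beads$chain[b], stringsAsFactors = FALSE)
        coordPlan[[length(coordPlan) + 1L]] <- list(kind = "acc", site = s)
      }
    }
  }
  atomTab <- do.call(rbind, atomRows)
  topo <- newTopology(atomTab)
  natom <- nrow(atomTab)
  beadAtom <- integer(n)
  siteAtoms <- list()
  for (k in seq_along(coordPlan)) {
    pl <- coordPlan[[k]]
    if (pl$kind == "bead") beadAtom[pl$bead] <- k
    else siteAtoms[[length(siteAtoms) + 1L]] <- c(pl, list(atom = k))
  }

  xyz <- matrix(0, nf, 3L * natom)
  X <- matrix(0, natom, 3L)
  for (f in seq_len(nf)) {
    Xb <- meanX + U[f, , ]
    if (length(mvIdx) && lam[f] > 0) {
      tr <- transforms[[as.character(lam[f])]]
      Xb[mvIdx, ] <- tr(Xb[mvIdx, , drop = FALSE])
      if (openNoiseA > 0)
        Xb[mvIdx, ] <- Xb[mvIdx, ] +
          matrix(stats::rnorm(3L * length(mvIdx), sd = openNoiseA),
                 length(mvIdx), 3L)
    }
    X[beadAtom, ] <- Xb
    for (pl in siteAtoms) {
      s <- pl$site
      D <- Xb[s$donorBead, ]; Acc <- Xb[s$acceptorBead, ]
      dir <- Acc - D
      nd <- sqrt(sum(dir^2))
      dir <- if (nd < 1e-6) c(1, 0, 0) else dir / nd
      Nd <- D + s$donLen * dir
      # broken-state direction: outward from the donor domain, orthogonal to
      # the bond axis, so a parked acceptor site cannot stray near the site
      # atoms of neighbouring contacts
      ctr <- colMeans(Xb[s$donorDomainBeads, , drop = FALSE])
      out <- Nd - ctr
      out <- out - sum(out * dir) * dir
      if (sum(out^2) < 1e-8) {
        out <- .crossProd(dir, c(0, 0, 1))
        if (sum(out^2) < 1e-8) out <- .crossProd(dir, c(0, 1, 0))
      }
      out <- out / sqrt(sum(out^2))
      if (pl$kind == "don") X[pl$atom, ] <- Nd
      else if (pl$kind == "hyd") {
        h <- as.numeric(.rotationMatrix(out, 5 * pi / 180) %*% dir)
        X[pl$atom, ] <- Nd + 1.0 * h
      } else {  # acceptor site
        X[pl$atom, ] <- if (s$on[f]) Nd + s$onLen * dir else Nd + s$offLen * out
      }
    }
    xyz[f, ] <- .xyzToRow(X)
  }
  traj <- newTrajectory(topo, xyz, times = (seq_len(nf) - 1L) * spec@dtNs)

  # ground truth
  memb <- match(beads$domain, spec@domains$name)
  names(memb) <- .nodeId(beads$chain, beads$resno)
  hingeAngles <- c(NA_real_, NA_real_)
  if (length(spec@hinge) && length(spec@detach)) {
    hg <- spec@hinge
    measure <- function(l) {
      tr <- .detachTransform(meanX, beads, spec, l)
      Xm <- meanX
      if (l > 0) Xm[mvIdx, ] <- tr(Xm[mvIdx, , drop = FALSE])
      pivotSel <- beads$domain == hg$domain &
        beads$resno >= hg$pivotRes[1L] & beads$resno <= hg$pivotRes[2L]
      armSel <- beads$domain == hg$domain &
        beads$resno >= hg$armRes[1L] & beads$resno <= hg$armRes[2L]
      tgtSel <- beads$domain == hg$targetDomain & beads$resno == hg$targetRes
      H <- colMeans(Xm[pivotSel, , drop = FALSE])
      B <- colMeans(Xm[armSel, , drop = FALSE])
      A <- colMeans(Xm[tgtSel, , drop = FALSE])
      v1 <- A - H; v2 <- B - H
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    }
    hingeAngles <- c(measure(0), measure(1))
  }
  de <- spec@detach
  stepOnsets <- rep(NA_real_, 4L)
  names(stepOnsets) <- paste0("step", 1:4)
  if (length(de) && !is.null(de$stepFrames))
    stepOnsets[] <- (de$stepFrames - 1L) * spec@dtNs
  truth <- new("GroundTruth",
               membership = as.integer(memb) |> stats::setNames(names(memb)),
               correlation = C,
               detachFrame = if (length(de)) de$frame else NA_real_,
               detachDeltaA = if (length(de)) de$deltaA else NA_real_,
               transientFrames = if (length(de) && !is.null(de$transientFrames))
                 as.numeric(de$transientFrames) else c(NA_real_, NA_real_),
               hingeAngles = hingeAngles,
               contacts = ct,
               stepOnsetsNs = stepOnsets)
  list(topology = topo, trajectory = traj, truth = truth)
}

#' Derive the domain map of a synthetic spec
#'
#' @param spec a [SyntheticSpec-class]
#' @return a [DomainMap-class] with one entry per domain
#' @export
specDomainMap <- function(spec) {
  d <- spec@domains
  entries <- lapply(seq_len(nrow(d)), function(k)
    data.frame(chain = d$chain[k], start = d$startRes[k], end = d$endRes[k],
               stringsAsFactors = FALSE))
  names(entries) <- d$name
  new("DomainMap", entries = entries)
}

#' Four-block planted-partition spec
#'
#' Four equal domains on a single continuous helical chain with strong
#' intra-block and weak inter-block planted correlations; the canonical
#' test bed for correlation recovery and community detection.
#'
#' @param beadsPerBlock beads per block (default 6)
#' @param nframes frames (default 10000)
#' @param rhoIntra,rhoInter planted correlations (defaults 0.8 / 0.05)
#' @param sigma per-bead noise in Angstrom (default 0.5)
#' @param dtNs frame spacing (default 0.1 ns)
#' @param seed random seed
#' @return a [SyntheticSpec-class]
#' @export
fourBlockSpec <- function(beadsPerBlock = 6L, nframes = 10000L,
                          rhoIntra = 0.8, rhoInter = 0.05, sigma = 0.5,
                          dtNs = 0.1, seed = 1L) {
  b <- as.integer(beadsPerBlock)
  domains <- data.frame(
    name = paste0("block", 1:4), chain = "A",
    startRes = (0:3) * b + 1L, endRes = (1:4) * b,
    cx = 0, cy = 0, cz = 0, sigma = sigma, stringsAsFactors = FALSE)
  syntheticSpec(domains, rhoIntra = rhoIntra, rhoInter = rhoInter,
                layout = "helix", nframes = nframes, dtNs = dtNs, seed = seed)
}

#' Two-domain detachment spec
#'
#' Two compact domains with a pure-translation centre-of-mass separation step
#' of `deltaA` Angstrom at `detachFrame`; near noise-free by default so the
#' planted step can be measured to high precision.
#'
#' @param nBeads beads per domain
#' @param deltaA separation step in Angstrom (default 5)
#' @param detachFrame first detached frame (default: past the midpoint)
#' @param nframes frames (default 1000)
#' @param sigma per-bead noise (default 1e-4, effectively noise-free)
#' @param dtNs frame spacing in ns
#' @param seed random seed
#' @return a [SyntheticSpec-class]
#' @export
twoDomainSpec <- function(nBeads = 20L, deltaA = 5, detachFrame = NULL,
                          nframes = 1000L, sigma = 1e-4, dtNs = 1, seed = 1L) {
  if (is.null(detachFrame)) detachFrame <- nframes %/% 2L + 1L
  domains <- data.frame(
    name = c("anchor", "mobile"), chain = c("A", "B"),
    startRes = c(1L, 1L), endRes = c(nBeads, nBeads),
    cx = c(30, 0), cy = 0, cz = 0, sigma = sigma, stringsAsFactors = FALSE)
  syntheticSpec(domains, rhoIntra = 0.5, rhoInter = 0.05,
                detach = list(domain = "mobile", reference = "anchor",
                              deltaA = deltaA, frame = as.integer(detachFrame)),
                nframes = nframes, dtNs = dtNs, seed = seed)
}

#' PI3K-like detachment preset
#'
#' A packaged study-condition spec mirroring the phenomenology of the
#' regulatory-domain detachment: five domains (nSH2, helical, C2, kinase,
#' iSH2) at C-alpha resolution, a hinge-helix rotation taking the apex angle
#' from 60 to 90 degrees, an exact 5 Angstrom centre-of-mass separation step,
#' a four-stage contact schedule (4 -> 2 -> 0 -> 1 -> 0 bonds across the
#' nSH2-helical interface) with a transient re-attachment, persistent
#' nSH2-C2 contacts, and raised incoherent flexibility of the detached
#' domain while open (higher RMSF and distance fluctuations, decorrelated
#' communication, as detachment produces in practice). Step onsets are planted at 20/50/67/80% of the simulated time
#' (200/500/670/800 ns at the defaults).
#'
#' @param nframes frames (default 2000)
#' @param dtNs frame spacing in ns (default 0.5, i.e. 1000 ns total)
#' @param seed random seed (default 7)
#' @return a [SyntheticSpec-class] with explicit mean coordinates
#' @export
pi3kLikePreset <- function(nframes = 2000L, dtNs = 0.5, seed = 7L) {
  nframes <- as.integer(nframes)
  f1 <- as.integer(floor(0.20 * nframes)) + 1L
  f2 <- as.integer(floor(0.50 * nframes)) + 1L
  f3 <- as.integer(floor(0.67 * nframes)) + 1L
  f4 <- as.integer(floor(0.80 * nframes)) + 1L
  domains <- data.frame(
    name = c("C2", "helical", "kinase", "nSH2", "iSH2"),
    chain = c("A", "A", "A", "B", "B"),
    startRes = c(335L, 526L, 699L, 322L, 429L),
    endRes = c(478L, 643L, 808L, 428L, 560L),
    cx = 0, cy = 0, cz = 0, sigma = 0.35, stringsAsFactors = FALSE)
  contacts <- rbind(
    contactSchedule("L380-K545", "helical", 545L, "LYS", "nSH2", 380L, "LEU",
                    "hbond", c(1L, f1 - 1L)),
    contactSchedule("K382-Q546", "nSH2", 382L, "LYS", "helical", 546L, "GLN",
                    "hbond", c(1L, f1 - 1L)),
    contactSchedule("R340-E542", "nSH2", 340L, "ARG", "helical", 542L, "GLU",
                    "salt", rbind(c(1L, f2 - 1L), c(f3, f4 - 1L))),
    contactSchedule("R358-E542", "nSH2", 358L, "ARG", "helical", 542L, "GLU",
                    "salt", c(1L, f2 - 1L)),
    contactSchedule("S418-D372", "nSH2", 418L, "SER", "C2", 372L, "ASP",
                    "hbond", c(1L, nframes)),
    contactSchedule("T420-N374", "nSH2", 420L, "THR", "C2", 374L, "ASN",
                    "hbond", c(1L, nframes)))
  spec <- syntheticSpec(
    domains, rhoIntra = 0.7, rhoInter = 0.1, contacts = contacts,
    hinge = list(domain = "nSH2", pivotRes = c(339L, 347L),
                 armRes = c(400L, 410L), targetDomain = "helical",
                 targetRes = 545L, angleStartDeg = 60, angleEndDeg = 90),
    detach = list(domain = "nSH2", reference = "helical", deltaA = 5,
                  frame = f2, transientFrames = c(f3, f4 - 1L),
                  transientFraction = 0.3, openNoiseA = 0.8,
                  stepFrames = c(step1 = f1, step2 = f2, step3 = f3, step4 = f4)),
    nframes = nframes, dtNs = dtNs, seed = seed)
  spec@meanCoords <- .presetMeanCoords(spec)
  spec
}

# Explicit preset geometry: blobs for the domain bodies, exact placements for
# the hinge helix (all nine beads, including residue 340, sit on the rotation
# axis, so the pivot centroid is exact and never moves), the arm helix, the
# mutation-site residue (apex angle exactly 60 degrees at lambda = 0) and the
# interface contact residues; the pivot-to-core distance is solved so the
# hinge rotation alone produces the full separation step (axial translation
# residual ~0, hence persistent kinase anchor contacts). E542 sits 7.2 A from
# R340 - close enough for the scripted salt bridge, too far for a contact
# edge, so network communication across that pair is carried by the other
# interface pairs and is lost on detachment.
.presetMeanCoords <- function(spec) {
  beads <- .beadTable(spec)
  idxOf <- function(domain, res) which(beads$domain == domain & beads$resno %in% res)
  .withSeed(20260927L, {
    X <- matrix(0, nrow(beads), 3L)
    centers <- list(nSH2 = c(0, 0, 0), C2 = c(0, -30, -8),
                    kinase = c(8, -16, 16), iSH2 = c(26, 6, 0))
    for (d in c("nSH2", "C2", "kinase", "iSH2")) {
      ii <- which(beads$domain == d)
      X[ii, ] <- .blobLayout(length(ii), centers[[d]])
    }
    bhat <- c(0, 1, 0)
    nhat <- c(1, 0, 0)
    zhat <- c(0, 0, 1)
    u60 <- as.numeric(.rotationMatrix(nhat, -60 * pi / 180) %*% bhat)
    hel <- which(beads$domain == "helical")
    helLocal <- .blobLayout(length(hel), c(0, 0, 0))
    armOff <- .blobLayout(11L, c(0, 0, 0), minSep = 1.0) * 0.15
    armOff <- sweep(armOff, 2L, colMeans(armOff))  # arm centroid exactly at Bc
    ii <- which(beads$domain == "nSH2")
    hingeLoc <- match(idxOf("nSH2", 339:347), ii)
    armLoc <- match(idxOf("nSH2", 400:410), ii)
    # full geometry as a deterministic function of the pivot distance rho
    build <- function(rho) {
      H <- c(0, -rho, 0)
      Bc <- H + 20 * bhat
      A <- H + 25 * u60
      Xn <- X[ii, , drop = FALSE]
      Xn[hingeLoc, ] <- matrix(H, 9L, 3L, byrow = TRUE) +
        outer(seq(-6, 6, length.out = 9L), nhat)
      Xn[armLoc, ] <- sweep(armOff, 2L, Bc, `+`)
      # interface residues relative to the nSH2 body centroid
      Gblob <- colMeans(Xn)
      what <- Gblob - A; what <- what / sqrt(sum(what^2))
      Xn[match(idxOf("nSH2", 380L), ii), ] <- A + 5.5 * what
      Q <- A + 6.5 * nhat
      Xn[match(idxOf("nSH2", 382L), ii), ] <- Q + 5.5 * what
      r340 <- Xn[match(idxOf("nSH2", 340L), ii), ]
      ehat <- A - r340; ehat <- ehat / sqrt(sum(ehat^2))
      E <- r340 + 7.2 * ehat
      ghat <- .crossProd(ehat, nhat); ghat <- ghat / sqrt(sum(ghat^2))
      Xn[match(idxOf("nSH2", 358L), ii), ] <- E + 9 * ghat
      c2face <- c(0, -14, -4)
      Xn[match(idxOf("nSH2", 418L), ii), ] <- c2face
      Xn[match(idxOf("nSH2", 420L), ii), ] <- c2face + 4 * zhat
      G0 <- colMeans(Xn)
      ahat <- A - G0; ahat <- ahat / sqrt(sum(ahat^2))
      Chel <- A + 14 * ahat
      # rotation sense that opens the apex angle
      openAngle <- function(Rm) {
        Brot <- as.numeric(Rm %*% (colMeans(Xn[armLoc, , drop = FALSE]) - H)) + H
        v1 <- A - H; v2 <- Brot - H
        acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      }
      R <- .rotationMatrix(nhat, 30 * pi / 180)
      if (openAngle(R) < openAngle(.rotationMatrix(nhat, -30 * pi / 180)))
        R <- .rotationMatrix(nhat, -30 * pi / 180)
      G1 <- as.numeric(R %*% (G0 - H)) + H
      list(F = sqrt(sum((G1 - Chel)^2)) - sqrt(sum((G0 - Chel)^2)) - 5,
           Xn = Xn, H = H, A = A, E = E, Q = Q, Chel = Chel)
    }
    lo <- 6; hi <- 24
    rho <- if (build(lo)$F * build(hi)$F < 0)
      stats::uniroot(function(r) build(r)$F, c(lo, hi), tol = 1e-9)$root
    else 10  # fallback; the generator then solves the residual axially
    sol <- build(rho)
    X[ii, ] <- sol$Xn
    # helical blob pinned so bead 545 sits at A, 546 at Q, 542 at E
    loc545 <- match(idxOf("helical", 545L), hel)
    X[hel, ] <- sweep(helLocal, 2L, sol$A - helLocal[loc545, ], `+`)
    X[idxOf("helical", 546L), ] <- sol$Q
    X[idxOf("helical", 542L), ] <- sol$E
    # persistent nSH2-C2 partners
    X[idxOf("C2", 372L), ] <- c(0, -20, -4)
    X[idxOf("C2", 374L), ] <- c(0, -20, 0)
    # kinase anchor beads flanking the (static) hinge axis
    kdir <- c(0, -0.6, 0.8)
    X[idxOf("kinase", 806L), ] <- sol$H + 4.8 * kdir + 1.5 * nhat
    X[idxOf("kinase", 807L), ] <- sol$H + 4.8 * kdir
    X[idxOf("kinase", 808L), ] <- sol$H + 4.8 * kdir - 1.5 * nhat
    X
  })
}
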