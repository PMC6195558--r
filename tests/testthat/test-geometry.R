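test_that("superposition removes rigid transforms exactly and matches a quaternion oracle", {
  set.seed(31)
  n <- 12L
  topo <- mkTopo(rep("CA", n), rep("C", n), seq_len(n), rep("A", n))
  ref <- matrix(rnorm(3 * n, sd = 5), n, 3L)
  sel <- allCASelection(topo)

  # pure translation recovered exactly
  tr <- mkTraj(topo, list(ref, sweep(ref, 2L, c(4, -2, 7), `+`)))
  fit <- superpose(tr, sel)
  expect_lt(max(abs(frameCoords(fit, 2) - ref)), 1e-10)

  # 90-degree rotation about z recovered exactly (RMSD 0 after fit)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3L, 3L, byrow = TRUE)
  tr <- mkTraj(topo, list(ref, ref %*% t(Rz)))
  fit <- superpose(tr, sel)
  expect_lt(rmsdTimeSeries(fit, sel)$value[2], 1e-10)

  # noisy frames match the independent Horn quaternion fit within 1e-8 A
  noisy <- ref + matrix(rnorm(3 * n, sd = 1), n, 3L)
  tr <- mkTraj(topo, list(ref, noisy))
  fit <- superpose(tr, sel)
  oracle <- quaternionFit(ref, noisy)
  rmsdPkg <- sqrt(mean(rowSums((frameCoords(fit, 2) - ref)^2)))
  rmsdOra <- sqrt(mean(rowSums((oracle - ref)^2)))
  expect_lt(abs(rmsdPkg - rmsdOra), 1e-8)

  # idempotence: fitting a fitted trajectory changes nothing
  fit2 <- superpose(fit, sel)
  expect_lt(max(abs(coordMatrix(fit2) - coordMatrix(fit))), 1e-10)

  # collinear fit set is rejected
  lin <- cbind(seq_len(n), 0, 0)
  trLin <- mkTraj(topo, list(lin, lin))
  expect_error(superpose(trLin, sel), "collinear")
})

test_that("RMSD reproduces hand-computable and brute-force values", {
  topo <- mkTopo(rep("CA", 4), rep("C", 4), 1:4, rep("A", 4))
  ref <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  moved <- ref; moved[2, 3] <- 2   # one atom displaced by 2 A among N = 4
  tr <- mkTraj(topo, list(ref, moved))
  r <- rmsdTimeSeries(tr, allCASelection(topo))
  expect_identical(r$value[1], 0)          # reference frame is exactly 0
  expect_equal(r$value[2], sqrt(4 / 4))    # sqrt(2^2 / 4) = 1.0

  set.seed(5)
  topo10 <- mkTopo(rep("CA", 10), rep("C", 10), 1:10, rep("A", 10))
  f1 <- matrix(rnorm(30), 10); f2 <- matrix(rnorm(30), 10)
  tr <- mkTraj(topo10, list(f1, f2))
  r <- rmsdTimeSeries(tr, allCASelection(topo10))
  expect_equal(r$value[2], sqrt(mean(rowSums((f2 - f1)^2))), tolerance = 1e-12)
})

test_that("RMSF is zero for a static trajectory and matches sigma*sqrt(3) for iid noise", {
  topo <- mkTopo(rep("CA", 3), rep("C", 3), 1:3, rep("A", 3))
  ref <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  trStatic <- mkTraj(topo, list(ref, ref, ref))
  expect_equal(rmsfProfile(trStatic, allCASelection(topo))$rmsf_A, rep(0, 3))
  expect_error(rmsfProfile(mkTraj(topo, list(ref)), allCASelection(topo)),
               "insufficient-data")
})

test_that("COM distances match hand values, symmetry cases and rigid-motion invariance", {
  topo <- mkTopo(c("CA", "CA"), c("C", "C"), 1:2, c("A", "B"))
  f <- rbind(c(0, 0, 0), c(0, 0, 10))
  tr <- mkTraj(topo, list(f, f, f))
  d <- comDistanceTimeSeries(tr, selOf(topo, 1L), selOf(topo, 2L))
  expect_equal(d$value, rep(10, 3))

  # equal-mass pair straddling the origin vs a point at (d, 0, 0)
  topo3 <- mkTopo(rep("CA", 3), rep("C", 3), 1:3, c("A", "A", "B"))
  f <- rbind(c(0, 5, 0), c(0, -5, 0), c(7, 0, 0))
  tr3 <- mkTraj(topo3, list(f))
  d <- comDistanceTimeSeries(tr3, selOf(topo3, 1:2), selOf(topo3, 3L))
  expect_equal(d$value, 7)

  # invariance under per-frame global rotation + translation
  set.seed(8)
  topo10 <- mkTopo(rep("CA", 10), rep("C", 10), 1:10,
                   c(rep("A", 5), rep("B", 5)))
  base <- matrix(rnorm(30, sd = 4), 10)
  frames <- lapply(1:6, function(i) {
    R <- trajnet:::.rotationMatrix(rnorm(3), runif(1, 0, pi))
    sweep(base %*% t(R), 2L, rnorm(3, sd = 20), `+`)
  })
  tr10 <- mkTraj(topo10, frames)
  d <- comDistanceTimeSeries(tr10, selOf(topo10, 1:5), selOf(topo10, 6:10))
  expect_lt(diff(range(d$value)), 1e-9)

  expect_warning(
    comDistanceTimeSeries(tr10, selOf(topo10, 1:5), selOf(topo10, 4:8)),
    "overlap")
})

test_that("hinge angle matches collinear, right-angle and COM-reduction oracles", {
  topo <- mkTopo(rep("CA", 3), rep("C", 3), 1:3, c("A", "B", "C"))
  # apex central, arms collinear on opposite sides: 180 degrees
  f <- rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0))
  tr <- mkTraj(topo, list(f))
  phi <- hingeAngleTimeSeries(tr, selOf(topo, 2L), selOf(topo, 1L), selOf(topo, 3L))
  expect_equal(phi$value, 180)
  # right angle
  f <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  tr <- mkTraj(topo, list(f))
  phi <- hingeAngleTimeSeries(tr, selOf(topo, 2L), selOf(topo, 1L), selOf(topo, 3L))
  expect_equal(phi$value, 90)
  # multi-atom selections reduce to the single-point angle of the centroids
  set.seed(12)
  topo9 <- mkTopo(rep("CA", 9), rep("C", 9), 1:9,
                  c(rep("A", 3), rep("B", 3), rep("C", 3)))
  f <- matrix(rnorm(27, sd = 6), 9)
  tr9 <- mkTraj(topo9, list(f))
  phi <- hingeAngleTimeSeries(tr9, selOf(topo9, 4:6), selOf(topo9, 1:3),
                              selOf(topo9, 7:9))
  ap <- colMeans(f[4:6, ]); va <- colMeans(f[1:3, ]) - ap; vb <- colMeans(f[7:9, ]) - ap
  expected <- acos(sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))) * 180 / pi
  expect_equal(phi$value, expected, tolerance = 1e-12)
  # coincident centroids are an error
  fBad <- f; fBad[1:3, ] <- f[4:6, ]
  expect_error(hingeAngleTimeSeries(mkTraj(topo9, list(fBad)), selOf(topo9, 4:6),
                                    selOf(topo9, 1:3), selOf(topo9, 7:9)),
               "undefined-angle")
})

test_that("Shrake-Rupley SASA matches closed forms for spheres and burial", {
  # isolated atom: exact sphere area within quadrature tolerance (<= 1%)
  topo1 <- mkTopo("C", "C", 1L, "A")
  tr1 <- mkTraj(topo1, list(matrix(c(0, 0, 0), 1)))
  s <- sasaTimeSeries(tr1, selOf(topo1, 1L))
  expect_equal(s$value, 4 * pi * 3.1^2, tolerance = 0.01)

  # fully buried atom: enclosed by a dense shell
  shell <- trajnet:::.spherePoints(80L) * 2.0
  topoB <- mkTopo(rep("C", 81), rep("C", 81), 1:81,
                  c("A", rep("B", 80)))
  trB <- mkTraj(topoB, list(rbind(c(0, 0, 0), shell)))
  s <- sasaTimeSeries(trB, selOf(topoB, 1L))
  expect_lt(s$value, 1)

  # two-atom system vs analytic two-sphere overlap (within 2%)
  topo2 <- mkTopo(c("C", "C"), c("C", "C"), 1:2, c("A", "B"))
  tr2 <- mkTraj(topo2, list(rbind(c(0, 0, 0), c(2.4, 0, 0))))
  s <- sasaTimeSeries(tr2, selOf(topo2, 1L))
  expect_equal(s$value, twoSphereArea(3.1, 3.1, 2.4), tolerance = 0.02)

  # unknown element radius is a parameterization error naming the element
  topoX <- mkTopo("FE", "FE", 1L, "A")
  trX <- mkTraj(topoX, list(matrix(0, 1, 3)))
  expect_error(sasaTimeSeries(trX, selOf(topoX, 1L)), "FE")
})
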