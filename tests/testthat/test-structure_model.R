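.readBackCoords <- function(gro) {
  lines <- readLines(gro)
  n <- as.integer(trimws(lines[2]))
  al <- lines[3:(2 + n)]
  cbind(as.numeric(substr(al, 21, 28)),
        as.numeric(substr(al, 29, 36)),
        as.numeric(substr(al, 37, 44))) * 10
}

test_that("hand-written PDB topology parses with correct counts and inferred elements", {
  pdb <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00",
    "ATOM      4  N   GLY A   2       3.300   1.500   0.000  1.00  0.00",
    "ATOM      5  CA  GLY A   2       4.700   1.600   0.000  1.00  0.00",
    "ATOM      6  O   GLY A   2       5.300   2.700   0.000  1.00  0.00",
    "ATOM      7  CA  SER B   1       8.000   0.000   0.000  1.00  0.00",
    "ATOM      8  OG  SER B   1       9.200   0.700   0.000  1.00  0.00",
    "ATOM      9  CB  SER B   1       8.600  -1.300   0.000  1.00  0.00",
    "END")
  writeLines(lines, pdb)
  topo <- readTopology(pdb)
  expect_equal(nAtoms(topo), 9L)
  expect_equal(nrow(residues(topo)), 3L)
  expect_equal(sort(unique(atoms(topo)$chain)), c("A", "B"))
  # element columns were absent: inferred from atom-name leading characters
  expect_equal(atoms(topo)$element, c("N", "C", "C", "N", "C", "O", "C", "O", "C"))
  expect_true(all(atoms(topo)$mass > 0))
})

test_that("duplicate atom serials are rejected with the offending line", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      1  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "END"), pdb)
  expect_error(readTopology(pdb), "duplicate atom serial 1 at line 2")
})

test_that("GRO round trip reproduces the generator's declared layout", {
  sys <- generateTrajectory(twoDomainSpec(nBeads = 5L, nframes = 2L))
  gro <- tempfile(fileext = ".gro")
  writeGRO(sys$topology, frameCoords(sys$trajectory, 1), gro)
  topo2 <- readTopology(gro)
  a1 <- atoms(sys$topology); a2 <- atoms(topo2)
  expect_equal(nrow(a2), nrow(a1))
  expect_equal(a2$name, a1$name)
  expect_equal(a2$resno, a1$resno)
  expect_equal(a2$resname, a1$resname)
  # chains recovered from the residue-number restart convention
  expect_equal(a2$chain, a1$chain)
  # GRO stores nm to 3 decimals: 0.01 A resolution
  expect_lt(max(abs(.readBackCoords(gro) - frameCoords(sys$trajectory, 1))), 0.006)
})

test_that("DCD round trip is exact to single precision", {
  sys <- generateTrajectory(fourBlockSpec(beadsPerBlock = 4L, nframes = 20L))
  dcd <- tempfile(fileext = ".dcd")
  writeDCD(sys$trajectory, dcd)
  back <- readTrajectory(sys$topology, dcd, dtNs = 0.1)
  expect_equal(nFrames(back), 20L)
  expect_lt(max(abs(coordMatrix(back) - coordMatrix(sys$trajectory))), 1e-3)
})

test_that("multi-model PDB trajectories load with one frame per MODEL and stride works", {
  sys <- generateTrajectory(fourBlockSpec(beadsPerBlock = 3L, nframes = 3L))
  pdb <- tempfile(fileext = ".pdb")
  writeMultiModelPDB(sys$trajectory, pdb)
  topo <- readTopology(pdb)
  tr <- readTrajectory(topo, pdb)
  expect_equal(nFrames(tr), 3L)
  expect_lt(max(abs(coordMatrix(tr) - coordMatrix(sys$trajectory))), 1e-3)

  sys2 <- generateTrajectory(fourBlockSpec(beadsPerBlock = 3L, nframes = 100L))
  dcd <- tempfile(fileext = ".dcd")
  writeDCD(sys2$trajectory, dcd)
  tr10 <- readTrajectory(sys2$topology, dcd, stride = 10L, dtNs = 2)
  expect_equal(nFrames(tr10), 10L)
  # synthesized times: stride x save interval
  expect_equal(frameTimes(tr10), seq(0, by = 20, length.out = 10))
})

test_that("atom-count mismatches and empty trajectories are rejected", {
  sys <- generateTrajectory(fourBlockSpec(beadsPerBlock = 3L, nframes = 3L))
  dcd <- tempfile(fileext = ".dcd")
  writeDCD(sys$trajectory, dcd)
  other <- generateTrajectory(fourBlockSpec(beadsPerBlock = 4L, nframes = 2L))$topology
  expect_error(readTrajectory(other, dcd), "mismatch")
})

test_that("domain selection respects names, subsets and chain disambiguation", {
  pf <- presetFixture()
  map <- specDomainMap(pf$spec)
  nsh2 <- selectDomain(pf$topology, map, "nSH2", "CA")
  expect_equal(nAtoms(nsh2), 107L)  # residues 322-428
  expect_error(selectDomain(pf$topology, map, "nope"), "key error")
  # overlapping residue-number ranges on different chains stay disjoint
  c2 <- selectDomain(pf$topology, map, "C2", "all")
  nsh2all <- selectDomain(pf$topology, map, "nSH2", "all")
  expect_length(intersect(atomIndices(c2), atomIndices(nsh2all)), 0L)
  # heavy subset drops hydrogens, CA subset keeps exactly one atom per residue
  heavy <- selectDomain(pf$topology, map, "nSH2", "heavy")
  a <- atoms(pf$topology)
  expect_false(any(a$element[atomIndices(heavy)] == "H"))
  expect_true(any(a$element[atomIndices(nsh2all)] == "H"))
  expect_equal(nrow(residues(nsh2)), 107L)
})

test_that("the packaged domain-map fixture parses and matches its documented ranges", {
  cfg <- system.file("extdata", "pi3ka_domains.cfg", package = "trajnet")
  map <- readDomainMap(cfg)
  expect_true(all(c("nSH2", "helical", "C2", "kinase", "iSH2",
                    "activation_loop", "helix_339_347", "helix_400_410",
                    "ialpha3") %in% domainNames(map)))
  e <- map@entries
  expect_equal(unname(unlist(e$nSH2)), c("B", "322", "428"))
  expect_equal(unname(unlist(e$helical)), c("A", "526", "643"))
  expect_equal(unname(unlist(e$activation_loop)), c("A", "933", "958"))
  # write/read round trip
  out <- tempfile(fileext = ".cfg")
  writeDomainMap(map, out)
  expect_equal(readDomainMap(out)@entries, map@entries)
})

test_that("invalid domain maps are rejected", {
  expect_error(domainMap(x = "A:10-5"), "start > end")
  expect_error(domainMap(x = "A:1-10, A:5-20"), "overlapping")
  expect_error(domainMap(x = "A1-10"), "cannot parse")
})

test_that("selections for distinct entries on distinct chains are disjoint", {
  sys <- generateTrajectory(twoDomainSpec(nBeads = 8L, nframes = 2L))
  map <- specDomainMap(twoDomainSpec(nBeads = 8L, nframes = 2L))
  s1 <- selectDomain(sys$topology, map, "mobile", "all")
  s2 <- selectDomain(sys$topology, map, "anchor", "all")
  expect_length(intersect(atomIndices(s1), atomIndices(s2)), 0L)
})
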