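---
title: "Quantifying regulatory-domain detachment in MD ensembles with trajnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regulatory-domain detachment in MD ensembles with trajnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajnet)
```

# The problem

The oncogenic charge-reversal mutation E545K in the helical domain of the
lipid kinase PI3K&alpha; (catalytic subunit p110&alpha;, regulatory subunit
p85&alpha;) weakens the inhibitory contact that the nSH2 domain of p85&alpha;
makes with the helical domain. In unbiased molecular-dynamics ensembles this
shows up as a spontaneous, stepwise detachment of nSH2: a handful of
interfacial hydrogen bonds break in a defined order, the nSH2&ndash;helical
centre-of-mass distance jumps by about 5 &Aring;, the domain rotates by about
30&deg; around a hinge helix (residues 339&ndash;347 of p85&alpha;), and the
allosteric communication between the two subunits collapses.

`trajnet` packages the trajectory-analysis layer needed to characterize such
an event quantitatively: geometric observables, hydrogen-bond/salt-bridge
occupancy, distance-fluctuation (plasticity) maps, correlation-weighted
dynamical network analysis, and rule-based annotation of the detachment
steps. Every stage is validated against a synthetic-trajectory generator
that plants known ground truth.

# Data model and conventions

* All coordinates are held in &Aring;ngstr&ouml;m internally; GRO input (nm)
  is converted on ingest. Distance-fluctuation values are therefore directly
  comparable to the conventional 0.3 &Aring;&sup2; rigidity threshold.
* Residue numbers are taken verbatim from the input file (crystal
  numbering), because every residue label of interest (E545, L380, R340,
  &hellip;) is conventionally quoted in that numbering. Chains are mandatory
  disambiguators &mdash; the same residue number exists on both subunits of a
  heterodimer; node ids are `"chain:resno"`.
* GRO files carry no chain field. The reader starts a new chain whenever the
  residue number decreases; the writers order chains so that this convention
  round-trips.
* No periodic-boundary unwrapping is performed. Inputs must be pre-imaged
  with the complex whole, which holds for the intended use (a single protein
  complex centred in its box).
* Missing masses default to standard atomic weights; elements missing from a
  PDB are inferred from the leading characters of the atom name.

# Observables

**Superposition** fits every frame onto a reference (first frame by default)
by least squares over a fit selection. The recommended fit set is all
C&alpha; atoms of the full complex: a global fit removes diffusion and
overall tumbling while leaving inter-domain motion &mdash; the signal &mdash;
intact. Per-domain fits are possible by passing a domain selection instead.

**RMSD / RMSF.** RMSD is computed per frame against the reference over a
selection; RMSF per residue at C&alpha; as the root time-mean squared
displacement about the time-mean position, over a stated frame window. For
region summaries (e.g. an activation loop) report the mean of the
per-residue values &plusmn; their SD across residues. RMSF requires a
superposed trajectory; the function does not refit, so the fit choice is
explicit in the workflow.

**Centre-of-mass distances** are mass-weighted by default (a flag disables
weighting). **The hinge angle** &phi; is measured at the unweighted centroid
of the hinge helix, subtended by the mutation-site residue and a distal
helix of the rotating domain (residues 400&ndash;410 in the packaged
fixture); mass weighting is deliberately not applied because the observable
is purely geometric. **SASA** uses Shrake&ndash;Rupley with Bondi radii, a
1.4 &Aring; probe and 960 golden-spiral test points per atom (quadrature
error below 1% for an isolated sphere), always in the context of the full
complex so that burial by other domains is respected.

# Hydrogen bonds and occupancy

The geometric criterion defaults to donor&ndash;acceptor distance &le; 3.5
&Aring; and hydrogen&ndash;donor&ndash;acceptor angle &le; 30&deg; &mdash;
the defaults of the GROMACS `hbond` tool, a natural choice for ensembles
produced and analysed with GROMACS-era tooling. A heavy-atom fallback
(distance-only, between N/O atoms) supports reduced representations without
explicit hydrogens. Salt bridges use side-chain N(+)&hellip;O(&minus;)
pairs of basic/acidic residues within 4.0 &Aring;.

Counts are reported raw per frame (a 5-ns running mean is available for
plotting, but the raw series is canonical for analysis). Occupancy tables
give, per residue pair and per consecutive time window (50 ns by default,
the granularity at which such tables are conventionally printed), the
fraction of frames with at least one bond between the pair. Cells strictly
below 0.5 are flagged; a cell at exactly 0.50 is not, so the flag means
"formed in a minority of frames". Windows tile the analysed interval; a
trailing remainder is absorbed into the last window.

# Distance-fluctuation maps

`DF_ij = <(d_ij - <d_ij>)^2>` is the variance (moment definition, 1/n) of
the scalar C&alpha;&ndash;C&alpha; distance over the analysis window,
computed with a two-pass algorithm for numerical stability. Because pairwise
distances are frame-internal, no superposition is required and DF is exactly
invariant under per-frame rigid transformations. Values below 0.3
&Aring;&sup2; indicate rigid-body-like coordination capable of propagating
allosteric signals; `interdomainDFSummary()` reports the fraction of an
inter-domain block below that threshold, the quantity that collapses when a
domain detaches. The default window is the trailing 200 ns, the same window
used for network analysis; intra-domain blocks are reported alongside
inter-domain ones.

# Dynamical network analysis

Nodes are residues at C&alpha;. Motional correlation is the scalar
normalized covariance of 3-D displacement vectors,
`C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` &mdash; the dot-product
convention, not per-axis Pearson; both exist in the literature, so the
choice is stated explicitly. Edges exist only between residues in physical
contact: any heavy-atom pair within 4.5 &Aring; in at least 75% of window
frames, excluding same-chain sequence neighbours (|i&minus;j| &le; 1). For
C&alpha;-only systems a C&alpha; distance with a larger cutoff (6.5 &Aring;
in the synthetic work here) substitutes. Edge weight is the communication
cost `w = -log |C|` with |C| clamped to [1e-8, 1].

Shortest paths (Dijkstra, implemented with deterministic lexicographic
tie-breaking so runs are exactly reproducible) are read as dominant
communication routes; disconnected pairs yield an explicit no-path result.
Communities come from the Girvan&ndash;Newman procedure: repeatedly remove
the edge with the highest weighted edge betweenness (recomputed after each
removal, ties broken by sorted endpoint labels) and keep the partition along
the dendrogram that maximizes modularity. Modularity is scored with the
correlation strength |C| as the affinity weight &mdash; modularity expects
affinities, not costs; scoring with the cost would reward exactly the wrong
partitions. This is configurable (`affinity = "uniform"`). Inter-community
edges ranked by betweenness give the critical edges, and their endpoints the
critical nodes, of inter-domain communication.

Two properties of this procedure deserve emphasis:

* On modular graphs &mdash; dense, strongly correlated blocks joined by weak
  bridges, the regime the method addresses and the regime real domain
  architectures produce &mdash; the retained partition matches exhaustive
  modularity maximization (verified against full partition enumeration on
  8-node two-block graphs in the test suite).
* On sparse, banded, or weight-adversarial graphs a divisive dendrogram need
  not contain the best partition at all: a single very strong (low-cost)
  intra-block edge can attract maximal betweenness and be removed first. In
  the synthetic four-block system this occasionally costs one boundary
  residue or splits one block, so planted-community recovery is exact for
  most but not all random seeds. This is a property of the algorithm, not of
  its implementation, and is the reason the oracle-equivalence tests are run
  on modular graphs.

# Event detection

`classifyStates()` labels each frame from the smoothed (centred running
mean, 10 ns default) centre-of-mass distance: the baseline is the mean over
a baseline window (first 100 ns by default); frames at or above baseline +
`openOffset` are `open`; sub-threshold excursions between two open segments
shorter than `dwellNs` are `transient`. The canonical detachment magnitude
is 5 &Aring; and that is the default `openOffset`; for noisy data we
recommend, and use throughout the synthetic analyses, a detection offset of
about 80% of the expected step (4 &Aring;), because a threshold exactly
equal to the step magnitude sits on the plateau boundary where the smoothed
signal crosses it with arbitrary sign. The default dwell is 50 ns; the
re-attachment episode in the system that motivated this package lasts about
130 ns, so analyses of that system pass `dwellNs = 150` &mdash; the step
annotation below is deliberately insensitive to this choice.

`annotateSteps()` overlays the four-step mechanism:

1. **Step 1** &mdash; first sustained drop of the total inter-domain
   hydrogen-bond count, found by comparing means of adjacent 50-ns windows
   against a drop threshold (1.5 bonds by default). A transparent two-window
   change point is used instead of a fitted model: it is exactly testable
   and its latency is bounded by the window.
2. **Step 2** &mdash; first open-state onset at which the designated
   critical pair (by default R340&ndash;E542, the last bond holding the
   interface) is lost.
3. **Step 3** &mdash; first re-attachment segment (transient *or* closed
   between two opens) during which the critical pair is re-formed. Accepting
   a closed segment here decouples the step annotation from the dwell
   parameter.
4. **Step 4** &mdash; onset of the final open segment, with the pair absent.

Later steps are omitted when their trigger never occurs, so annotated steps
are always strictly ordered in time, and annotation is idempotent.

# The synthetic generator

`generateTrajectory()` draws frames as a fixed mean structure plus
correlated Gaussian displacements: per axis, iid normals multiplied by the
Cholesky factor of the planted block correlation matrix (intra-domain
&rho; on the off-diagonal within blocks, inter-domain &rho; across), scaled
by a per-domain positional &sigma;. Scheduled pseudo-contacts plant donor
(N, H) and acceptor (O) sites whose geometry is scripted per frame: formed
= 2.9 &Aring; donor&ndash;acceptor at 5&deg; hydrogen deviation (3.4 &Aring;
for salt bridges), broken = 6 &Aring;, parked orthogonally outward from the
donor domain so broken sites cannot collide with neighbouring contacts.

The scripted detachment applies, from its onset frame, a rigid rotation of
the moving domain about an axis through the hinge-helix centroid,
perpendicular to the plane of the apex-angle construction, plus an axial
translation solving a quadratic so the centre-of-mass separation step equals
the planted &Delta; exactly; translation along that axis provably leaves a
90&deg; apex angle unchanged, which is how the packaged preset plants both
the 60&deg;&rarr;90&deg; hinge rotation and the 5 &Aring; step exactly. A
partial re-attachment episode uses the same transform at a fractional
amplitude. The open-state extra flexibility of the detached domain is
modelled as *incoherent* per-bead noise (`openNoiseA`): it raises the
detached domain's RMSF and its distance fluctuations and decorrelates its
motion &mdash; which is what detachment does to communication. A rigid-body
wobble was considered and rejected at design time: coherent rigid motion
leaks through the global superposition into apparent cross-domain
correlations and *shortens* communication paths, the opposite of the physics
being emulated. One consequence is that intra-domain DF also rises in the
open state, whereas a real detached domain stays internally rigid; analyses
of intra-domain rigidity should therefore not be validated against the
generator's open phase.

`pi3kLikePreset()` packages the study conditions: five domains at C&alpha;
resolution with the crystal-numbering ranges of the heterodimer (nSH2
B:322&ndash;428, helical A:526&ndash;643, C2 A:335&ndash;478, a kinase
segment A:699&ndash;808, iSH2 B:429&ndash;560), per-bead &sigma; = 0.35
&Aring; (so that closed-state inter-domain DF sits below 0.3
&Aring;&sup2;, as rigid coordination requires), intra/inter correlations
0.7/0.1, 2000 frames at 0.5 ns (a 1 &mu;s trajectory), step onsets planted
at 200/500/670/800 ns, a 4 &rarr; 2 &rarr; 0 &rarr; 1 &rarr; 0 contact
schedule across the nSH2&ndash;helical interface (L380&ndash;K545 and
K382&ndash;Q546 break first; R340&ndash;E542 and R358&ndash;E542 carry the
interface until the detachment; R340&ndash;E542 re-forms transiently),
persistent nSH2&ndash;C2 contacts, hinge beads placed on the rotation axis
(so kinase anchor contacts survive the rotation, as the hinge helix's kinase
interface does), and `openNoiseA` = 0.8 &Aring;. The four-block spec
(`fourBlockSpec()`: 4 blocks &times; 6 beads, &rho; = 0.8/0.05, 10&#8308;
frames) is the test bed for correlation recovery; its block size was fixed
by a design-time power analysis so that the sampling error of the maximum
correlation deviation stays below 0.02 at 10&#8308; frames.

```{r preset, eval = FALSE}
sys <- generateTrajectory(pi3kLikePreset())
map <- specDomainMap(pi3kLikePreset())
com <- comDistanceTimeSeries(sys$trajectory,
                             selectDomain(sys$topology, map, "nSH2", "CA"),
                             selectDomain(sys$topology, map, "helical", "CA"))
tl <- classifyStates(com, c(0, 100), openOffset = 4, dwellNs = 150)
```

# What passing the synthetic tests does and does not show

The generator emulates motional statistics (block correlations), contact
schedules and a scripted rigid-body event. It does not model bonded
geometry, sterics, solvent, force-field energetics or the kinetics of
barrier crossing. Tests passing on it therefore validate the *measurement
chain* &mdash; that the observables, occupancies, DF maps, networks and
event rules recover exactly what was planted &mdash; not that any particular
biological system behaves this way. Reproduction of published values from
real microsecond ensembles additionally depends on analysis choices the
original work leaves unstated (hydrogen-bond geometry, contact rule,
correlation node choice), so rank orders and qualitative structure are the
right level of comparison there.

# Numerical choices and degenerate inputs

* Superposition requires &ge; 3 non-collinear fit atoms; collinear sets are
  rejected. Fitting is idempotent to 1e-10 &Aring;.
* DF uses the 1/n moment definition so the alternating-distance closed form
  `((a-b)/2)^2` is exact; two-pass accumulation keeps it stable over long
  windows.
* Static (zero-variance) nodes get NA correlations and no edges rather than
  a 0/0.
* |C| is clamped to [1e-8, 1] before taking the log, so a numerically zero
  correlation yields a finite, maximal edge cost (~18.4).
* Dijkstra and Girvan&ndash;Newman break ties lexicographically (string
  order of node ids, sorted endpoint pairs), making every result
  reproducible run to run.
* Occupancy windows shorter than the frame spacing are rejected; a window
  boundary at exactly 50% occupancy is not flagged.
* An edgeless graph yields singleton communities with modularity 0 by
  convention (the modularity formula is undefined at zero total weight).

# Problem sizes used in the shipped analyses

The packaged test and acceptance analyses run the preset at 2000 frames
(about 630 beads), the four-block system at 10&#8308; frames (24 beads), the
graph-oracle checks on &le; 8-node graphs against full enumeration, and the
analytic RMSF limit at 10&#8309; frames on 4 atoms. These sizes make every
planted quantity statistically decidable (e.g. correlation recovery to
&plusmn;0.02) while keeping a full validation run in the low minutes on one
CPU.

# Limitations

* Hydrogen-bond detection assumes hydrogens bonded to their donor lie within
  1.25 &Aring; in the same residue; exotic naming schemes may need curation.
* The contact prefilter assumes residues do not travel more than ~6 &Aring;
  plus their side-chain reach between sampled frames relative to each other;
  for very diffusive systems pass an explicit window.
* Girvan&ndash;Newman recomputes betweenness after every removal; graphs
  beyond a few thousand edges become slow, which is adequate for single
  complexes but not for very large assemblies.
* The CLI front end (`inst/scripts/trajnet.R`) is a thin convenience wrapper;
  the R functions are the supported interface.
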