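# ecdyn

Essential collective dynamics (ECD) analysis of molecular trajectories in
R, for structural biologists and simulators who want to turn
molecular-dynamics output into interpretable statements about correlated
motion: which parts of a protein move together, which residues are
flexible, how computed flexibility compares with crystallographic
B-factors, and which residues form a protein–protein interface.

## The method

From a trajectory segment with frames $x_t \in \mathbb{R}^{3N}$ (superposed
to remove rigid-body motion), ECD diagonalizes the fluctuation covariance

$$C = \langle (x - \langle x \rangle)(x - \langle x \rangle)^\top \rangle$$

and keeps the leading $m$ eigenvectors — the essential collective
coordinates — covering 90% of the displacement by default. Each atom maps
to an image point in $\mathbb{R}^m$ whose $k$-th component is the norm of
eigenvector $k$'s 3-entry block for that atom. Three descriptors follow:

* **Correlation maps** — dimensionless distances $d_{ij}$ between atom
  images, averaged over trajectory segments; small $d_{ij}$ = strongly
  coupled motion.
* **Flexibility profiles** — $F_i$, the distance between atom $i$'s image
  and the centroid of all C$\alpha$ images, with across-segment standard
  deviations; high $F_i$ marks flexible loops and hinges.
* **Dynamic domains** — single-linkage clusters of the image at an
  interdomain distance $d_c$ (default 0.0015 for ~200-residue maps, or
  selected on a data-driven grid by maximizing domain count and spread
  subject to the largest domain holding >10% of atoms).

Around the core the package provides trajectory I/O (multi-model PDB, DCD,
plain text), an atom-selection grammar, Kabsch superposition, RMSD,
B-factor extraction/normalization/comparison, distance-cutoff interface
contact classification (4.0 / 3.5 / 4.5 / 5.0 Å for H-bond-range polar /
polar / non-polar / nearest-neighbor), and an overdamped-Langevin
elastic-network generator whose exact Gaussian equilibrium law
(`analyticCovariance()`, `analyticMSF()`) makes every pipeline stage
testable without external data.

## Worked example

Simulate a two-domain elastic network with known ground truth, then run the
full ECD analysis:

```r
library(ecdyn)

spec <- makeBlockSystem(nBlocks = 2, seed = 42)   # 15+40 atoms, 6 hinges
traj <- generateENMTrajectory(spec)
#> INFO  [ecdyn] simulated 61 atoms: 19295 burn-in + 40000 production steps, 2000 frames

sel <- selectAtoms(traj, "name CA")
ens <- segmentTrajectory(traj, 20, 100, take = "tail")
map <- correlationMap(ens, sel)
#> INFO  [ecdyn] correlation map 61 x 61 over 20 segment(s); m in [21, 32]

thr  <- selectThreshold(map)
#> INFO  [ecdyn] selected d_c = 0.359101 (2 domains, spread 15, largest fraction 0.66)
part <- clusterDomains(map, thr$threshold)
domainSummary(part, atomTable(traj))
#>   rank size  fraction                ranges
#> 1    1   40 0.6557377 A:22-61 (40 residues)
#> 2    2   15 0.2459016  A:1-15 (15 residues)

fl  <- flexibilityProfile(ens, sel)
lab <- spec@blockLabels
round(c(hinge  = mean(fl@meanFlex[lab == "hinge"]),
        block1 = mean(fl@meanFlex[lab == "block1"]),
        block2 = mean(fl@meanFlex[lab == "block2"])), 3)
#>  hinge block1 block2
#>  1.214  0.312  0.222
```

The two planted rigid blocks are recovered exactly as the two dynamic
domains (residues 1–15 and 22–61); the six flexible hinge atoms joining
them are correctly left unassigned, and their flexibility descriptor is
about five times that of the block interiors — the signature of a flexible
linker between rigid domains. The per-segment essential spaces used
21–32 collective coordinates to cover 90% of the displacement.

`runAnalyze()` wraps the same workflow behind a single configuration list
(or JSON/YAML file) and writes TSV/JSON artifacts plus a resolved-config
copy; `runSimulate()` does the same for the generator. A thin command-line
wrapper ships in `inst/scripts/ecd-pipeline.R`.

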