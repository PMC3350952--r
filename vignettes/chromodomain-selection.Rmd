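---
title: "Detecting positive selection on retrotransposon chromodomains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting positive selection on retrotransposon chromodomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromosel)
```

## The scientific problem

Chromoviruses are Ty3/Gypsy LTR retrotransposons whose integrase carries a
C-terminal chromodomain (CHD), a ~50 amino-acid module that in cellular
proteins reads methylated histone tails and is thought to target new
insertions into heterochromatin. Plant retroelement chromodomains fall into
two groups: group I (CHD_I) resembles classical chromodomains and keeps the
aromatic-cage residue homologous to Y24 of the *Drosophila* HP1
chromodomain, while group II (CHD_II) has lost Y24 (and usually Y48) but
retains W45. Because clade-specific CHD variants (Tekay-, Reina-,
Galadriel-like) carry distinct conserved motifs, a natural question is
whether their divergence was driven by positive selection on a few codons
along particular branches of the element phylogeny.

`chromosel` implements the full analysis path for that question on
user-supplied or simulated data: structural annotation of elements in
genomic sequence, chromodomain extraction and group classification,
distance-based phylogenetics with bootstrap support, and codon-model tests
of positive selection on labeled branches with family-wise error control.

## Structural annotation

An intact chromovirus has the layout

```
TSD | 5'LTR | (spacer) PBS | Gag-Pol ORF (CCHC-PR-RT-RNH-INT-CHD) | PPT | 3'LTR | TSD
```

`annotate_genome()` reconstructs this from sequence alone:

* **LTR pairs** (`find_ltr_pairs`) are found by a seed-and-extend search:
  exact shared k-mers (k = 20, or 12 for inputs under 20 kb) anchor
  candidate diagonals, the matched core is extended outward under a +1/−1
  score, and boundaries are snapped to positions where both copies start
  `TG` and end `CA` — the inverted terminal dinucleotides. The published
  workflows delimit LTR boundaries interactively; this reconstruction is
  validated on synthetic truth only. Defaults: length 100–1500 bp,
  interior ≤ 10 kb, identity ≥ 80 %.
* **Identity** is always matches / global-alignment length (match +1,
  mismatch −1, gap open 2, gap extend 0.5), so gaps count against identity.
  The literature rarely states its identity definition; this one is fixed
  and reported with every result.
* **TSD** (`detect_tsd`): longest exact duplication of 4–6 bp on the two
  immediate flanks (longer wins ties).
* **PBS** (`find_pbs`): longest reverse-complement match (≥ 11 bp, spacer
  ≤ 2) to the 3' end of a library tRNA. The shipped library is a single
  synthetic tRNA-Met 3' end (`default_trna_3ends()`); real screens should
  supply their own. The 11 bp floor is the smallest PBS reported for these
  elements; the PPT floor (12) sits just below the smallest reported tract.
* **PPT** (`find_ppt`): longest purine run ≥ 12 bp ending ≤ 2 bp before the
  3' LTR.
* **ORFs and domains**: ATG-to-stop ORFs ≥ 300 nt on both strands;
  degenerate elements are handled by `reconstruct_pseudo_orf`, which
  translates through in-frame stops and records their positions without
  repairing frameshifts. Domain order is checked against
  CCHC < PR < RT < RNH < INT < CHD. CCHC is located by its literal
  C-X2-C-X4-H-X4-C pattern and the chromodomain by motif scanning; the
  other domains are located by sentinel peptides because similarity-search
  domain assignment is outside the package's scope.
* **Families** (`cluster_families`): single-linkage clustering at > 80 %
  nucleotide identity, with members additionally required to share ≥ 50 %
  LTR identity with the family exemplar; consensus reconstruction
  (`build_consensus`) is column-majority with gaps winning only above 50 %.

All internal coordinates are 0-based half-open; everything emitted (GFF3 via
`write_gff3`, report tables) is 1-based inclusive, with a single conversion
layer (`to_gff_coords`).

## Chromodomain classification

Classification rests on the three aromatic-cage residues in dmHP1 numbering
(Y24, W45, Y48), anchored to each peptide by the best placement of the
chromo-box (Y/f)-(L/F/Y)-(L/I/V)-K-(W/y)-(k/r)-g. Position 1 of that
placement is the Y24 slot; alignment positions 28 and 31 (configurable
offsets) are the W45 and Y48 slots. Patterns are scored as weighted
consensus motifs — prominent residues 1.0, minor residues 0.5, threshold
70 % of the maximum — because the literature gives consensus notation, not
a scoring rule; the threshold is exposed in `motif_pattern()`. The group
call is a total function of the three flags: W45 and Y24 give CHD_I, W45
without Y24 gives CHD_II, and a missing W45 leaves the peptide
unclassified. Y48 is recorded as evidence but never decides the group,
since group II domains "usually" rather than always lose it. Clade motifs
(the Galadriel box variant, the Tekay (K/R)-X-(L/T)-R-X-(k/r) and
EEXTWEXE motifs, and the near-universal TWE core) are detected
independently and reported alongside. Only alignment positions 1/28/31 are
hard-wired; the full column-to-residue mapping of published figure
alignments is figure-derived and therefore left configurable rather than
guessed.

## Codon models and the selection tests

The substitution process is the Goldman–Yang codon model over the 61 sense
codons: single-nucleotide changes have rate pi_j, kappa pi_j, omega pi_j or
omega kappa pi_j for synonymous/nonsynonymous transversions/transitions.
Codon frequencies are equal by default (F3x4 available); kappa is estimated
jointly in every fit (the model family requires it) with initial value 2.

The site-class models are:

* **M0**: one omega everywhere.
* **M1a**: proportion p0 with 0 < omega0 < 1, the rest neutral.
* **Model A** (branch-site): classes 0 (omega0), 1 (neutral), 2a and 2b,
  which behave like 0 and 1 on background branches but take omega2 ≥ 1 on
  the foreground branches, with p2a = (1−p0−p1) p0/(p0+p1) and
  p2b = (1−p0−p1) p1/(p0+p1). The null fixes omega2 = 1.
* **Extended clade model C**: classes 0 and 1 as above plus a divergent
  class whose omega differs freely between branch types, including the
  background — one omega per declared type, which is this package's
  concrete reading of a clade model generalised to more than two branch
  types. With one foreground type its parameter count exceeds M1a by 3,
  the df used for the clade-site test.

**Rate scaling.** Site classes must not be rescaled to unit rate
independently: a positively selected class evolves faster, and that excess
nonsynonymous rate on the foreground branch is most of the branch-site
signal. Each class's generator is therefore kept raw and branch lengths
are divided by the *mixture-average* raw rate of the branch's type, so a
branch length is the expected number of substitutions per codon averaged
over classes (the convention of the reference ML implementations) while
classes keep their relative speeds. A single-class model reduces exactly
to the usual unit-scaled process.

**Likelihood and optimisation.** Felsenstein pruning runs over
pattern-compressed alignments with per-edge rescaling (underflow-safe at
any tree size); model A's classes 2a/2b reuse all partial results from
classes 0/1 on unchanged branches. Fits use bounded L-BFGS-B with a
forward-difference gradient on transformed parameters (logistic for
proportions and omega0, log for kappa; omega2 raw on [1, 999] so boundary
fits are visible), and a staged three-start strategy: the default start
and two fixed jitters each run a few exploratory iterations, the best is
run to convergence, and a final polish pass at a tighter tolerance makes
the reported optimum stable under refitting. Staging keeps multi-start
robustness against secondary optima at roughly the cost of a single full
fit; for the null model one start is the alternative fit's estimates. A fit of omega2 at the
upper bound is flagged and reported as "unbounded", mirroring the infinity
entries of published tables. Branch lengths are estimated once per dataset
under M0 (a single start; the M0 surface is unimodal in practice) and held
fixed for all site-class fits — this reduces dimensionality at desk scale;
whether the original analyses re-estimated lengths per model is unstated,
so likelihood-ratio statistics can shift slightly relative to a per-model
protocol.

**Tests.** The branch-site test compares model A against its omega2 = 1
null; because the null sits on the boundary, the statistic is referred to
the mixture 1/2 chi2_0 + 1/2 chi2_1 (`mixture_chi2_pvalue`), with a
chi-square(1) fallback flag for conservatism comparisons. The clade-site
test compares extended clade model C with M1a on chi-square df equal to
the parameter-count difference. Scanning several branches
(`scan_branches`) treats each named clade's stem as foreground in turn and
adjusts the raw p-values with Hommel's FWER procedure (base R
`p.adjust`; the test suite cross-checks it against a closure-principle
Simes oracle). Negative statistics within 1e-6 of zero are clamped with a
warning; every test also reports a third-codon-position Jukes–Cantor
distance as a synonymous-saturation guard (warning above 3).

**Site identification.** `site_posteriors` computes naive empirical Bayes
posteriors for membership in classes 2a/2b at the MLEs, with flags at 0.90
and 0.95. A `grid_EB` variant averages the posterior over a
likelihood-weighted uniform grid on (p0, p1, omega2) as a lightweight
treatment of parameter uncertainty; the full Bayes empirical Bayes
integration of the codeml literature is deliberately not reimplemented,
and outputs are labeled with the method used.

## The synthetic-data generator

`simulate_codon_alignment` evolves codon sites along a labeled tree under
any site-class model: classes drawn from the model proportions, root codons
from the stationary frequencies, per-branch transition sampling with the
same mixture scaling as the likelihood, all bit-reproducible given a seed
and with per-site class truth and ancestral states recorded.

The standard study conditions for the calibration experiments are 8 taxa,
500 codons, p0 = 0.5, p1 = 0.3, omega0 = 0.1, kappa = 2, and the tree of
`default_selection_tree()`: a balanced topology whose foreground stem
(0.4 expected substitutions per codon; tips 0.3, inner branches 0.15)
reflects the deep divergence of anciently separated retroelement clades —
on shallow trees a single short foreground branch simply carries too little
signal for a calibrated test, which is a property of the method, not of
the implementation. Under these conditions the branch-site test rejects
in well over 80 % of omega2 = 6 replicates and stays within its nominal
level under omega2 = 1 (the mixture null is conservative).

`plant_elements` builds toy genomes: i.i.d. uniform ACGT background (the
simplest null for motif false positives) with elements assembled as
5'LTR + spacer + PBS + Gag-Pol ORF + PPT + 3'LTR, flanked by the TSD on
both sides, LTR pairs mutated to a requested divergence with TG/CA termini
protected. The default inventory (`default_element_specs()`) covers a
5 bp CCTAT TSD with 13 bp/1-spacer PBS and 14-purine PPT, a 6 bp GTTTCT
TSD with 12 bp/2-spacer PBS, and an 11 bp/0-spacer PBS case — the feature
combinations reported for the real element families this generator
emulates. Untranslated spacers are shaped so planted feature boundaries
are unambiguous (an in-frame stop precedes the ORF's ATG; a pyrimidine
precedes the PPT; the base after the PBS cannot extend the tRNA
complementarity); without such guards "exact coordinate" recovery would be
ill-posed at random-flank boundaries. What the generator does **not**
emulate: indels and alignment error, nested or truncated insertions, rate
heterogeneity beyond the discrete classes, non-uniform base composition,
and solo LTRs. Passing the round-trip tests therefore shows the detectors
are correct on clean signal, not that they are robust to the full
messiness of real genomes.

## Numerical choices and conventions

* Gapped/ambiguous/stop-containing codon columns are removed before any
  likelihood work (the "cleandata" convention; the original analyses do
  not state their choice), with removed column indices kept for site
  numbering.
* NJ is implemented in-package because its contract here fixes the
  tie-break (lexicographically smallest pair) and negative-branch handling
  (clamp to zero, deficit moved to the sister, topology unchanged);
  `ape::nj` serves as an independent cross-check in the tests. Distance
  saturation raises errors rather than infinities.
* Bootstrap support counts bipartitions of the point tree in replicate
  trees (`ape::prop.clades`), is invariant to taxon order, and is
  bit-reproducible under a fixed seed.
* One global integer seed drives every stochastic component, with child
  streams derived per element/stage; callers' RNG state is never
  disturbed.
* Problem sizes used by the test suite: 20 replicates per branch-site
  calibration arm at 500 codons; 5 replicates at 400 codons for the
  clade-site power property; 50 brute-force pruning checks on 3–4 taxon
  trees; 100 background genomes of 10 kb for the false-positive rate; 20
  random 5-taxon matrices for NJ exactness.

## A worked example

```{r example, eval = FALSE}
tr <- default_selection_tree()
sim <- simulate_codon_alignment(tr, model_a(2, 0.5, 0.3, 0.1, 6, "FG"),
                                500, seed = 1)
res <- branch_site_test(sim$alignment, tr, foreground = "FG")
res
site_posteriors(res$alt_fit, sim$alignment, tr)
```

## Known limitations

Branch lengths fixed after M0 (see above); NEB/grid-EB rather than full
BEB; no amino-acid exchangeability matrices or gamma rate variation; no ML
tree search (externally built trees are accepted via `read_newick`, NJ is
the built-in fallback); annotation is validated on synthetic truth, not on
curated real elements; published parameter estimates that depend on the
original sequence data cannot be reproduced without that data and are not
targets of this package's tests.
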