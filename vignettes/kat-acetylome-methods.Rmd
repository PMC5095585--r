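---
title: "Calling KAT-dependent acetyl sites and characterizing them: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling KAT-dependent acetyl sites and characterizing them: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katomics)
```

# The analysis problem

Lysine acetyltransferases such as KAT2A (GCN5) and KAT2B (PCAF) modify
hundreds of substrates. A practical way to map their substrate space is
differential acetylomics: enrich acetylated peptides, identify them by
tandem MS in several control replicates and again after knocking the
enzymes down, and treat sites that disappear on knockdown as candidate
enzyme-dependent substrates. Spectral counting of acetylated peptides in
this regime is sparse and semi-quantitative, so the analysis works on
*presence/absence across replicates* rather than intensity models; no
distributional test is applied, and none is implemented here by design.
This package implements that calling scheme end to end, together with the
downstream analyses such screens typically feed: sequence-context logos of
the called sites, structural-feature comparison of replicate molecular
dynamics (MD) ensembles of a substrate kinase, and quantification of
centrosomal fluorescent signal in cells.

# PSM filtering and site mapping

Identification quality is enforced with the classic ion-trap SEQUEST
filters: charge-dependent XCorr minima (1.5, 2.5, 3.0 for 1+, 2+, 3+, and
3.2 above 3+), a deltaCn ceiling of 0.3, a minimum length of 7 residues,
and rejection of tryptic peptides whose C-terminal residue is an
acetylated lysine. All score comparisons are boundary-inclusive: the
printed thresholds are pass marks, so a 2+ PSM with XCorr exactly 2.5 is
retained. Rules are applied in a fixed order and each rejected PSM is
tallied under the *first* rule it fails, so the per-rule tallies plus the
retained count always partition the input — useful for auditing a filter
run. Missed cleavages are counted and recorded but not re-enforced by
default, since the permitted maximum (3) was already applied during
database search; a strict mode re-enforces it.

The C-terminal acetyl-K rule deserves a note: trypsin does not cleave
after acetylated lysine, so a fully tryptic peptide *ending* in acetyl-K
is chemically implausible and indicates a mis-assignment. The synthetic
generator respects the same chemistry: host peptides for planted sites end
at the first cleavage site *after* the modified lysine (a missed cleavage
at the acetyl-K), keeping the modification internal.

Acetyl positions are lifted from peptide to protein coordinates as
`start + position_in_peptide − 1`, 1-based, which reproduces kinase-domain
site numbering such as K45/K46 on their host peptide starting at residue
34. Peptides shared by several accessions credit each of them (the
inflation risk is documented; a `unique_only` mode drops shared peptides
instead). Mapping validates that the target residue is lysine and fails
loudly otherwise.

# The calling rule and its operating characteristics

A site is called enzyme-dependent when present in at least
`min_ctrl_present = 3` of 5 control replicates and at most
`max_kd_present = 0` of 3 knockdown replicates. Both the site-level call
and a protein-level view (via per-protein aggregation) are provided,
since screens report both counts. The rule is monotone — an extra control
detection can only help a site, an extra knockdown detection can only
remove it — and the test suite checks the decision against brute-force
enumeration of all 2^5 × 2^3 presence patterns.

Under independent per-replicate detection with probability `p`, the
probability that a knockdown-lost site is called is
`P(Binomial(5, p) ≥ 3)`; at `p = 0.9` that is 0.99144, and the synthetic
pipeline reproduces it within Monte-Carlo error at 1000 planted sites. A
site that remains detectable in knockdown at the same rate is called with
probability `0.99144 × (1 − p)^3 ≈ 0.001`: the zero-tolerance knockdown
arm, not the 3-of-5 control arm, is what gives the rule its specificity.
These closed forms are what the acceptance checks compare against.

The overlap of called proteins with a reference acetylome is reported as
`100 × in_reference / targets` to one decimal; 251 of 398 gives 63.1%.

# Abundance factor

To compare a protein's acetylation across conditions measured in
independent runs (e.g. *in vitro* acetyltransferase assays with different
enzymes), each acetylated peptide's spectral count is divided by the
condition's total spectral count for the protein — normalizing run-to-run
loading — and the normalized values are summed. Peptide identity is the
sequence plus the *set* of acetylated positions; charge states are
collapsed because charge is instrumental, not chemical. The statistic is
invariant under uniform scaling of a condition's counts and additive over
disjoint peptide sets; both properties are tested. A condition with
acetylated peptides but no positive total is an error rather than a
silent zero, since the ratio is undefined.

# Sequence-context logos

Windows of ±10 residues are extracted around each acetylated lysine.
Near a protein terminus the window is padded with `X` and pads are
excluded from the per-position denominators; the alternative — dropping
short windows — would bias the logo against terminal sites. The
background is sampled uniformly without replacement from all lysine
positions in the proteome, by default 0.05% of them; known acetyl sites
can optionally be excluded from the sampling frame, but are not by
default (at realistic acetylation densities the contamination is
negligible). The central K column is computed but flagged for exclusion
from display, as a constant column carries no information.

Two track modes are produced. Absolute mode reports the information
content `log2(20) − H` per position (0 for a uniform column, log2(20) ≈
4.32 bits for a single-letter column), with letters sized by frequency.
Relative mode reports per-letter `log2(fg/bg)`; zero frequencies are
replaced by the pseudo-frequency `1/(n + 20)` of their own matrix, which
keeps the track finite and exactly antisymmetric under
foreground/background exchange. The standard small-sample entropy
correction `(20 − 1)/(2 ln 2 · n)` is available but off by default —
window counts in this setting are in the thousands, where the bias is
below 0.007 bits.

# Replicate MD ensemble features

Trajectory ensembles are plain `frames × atoms × 3` arrays with a minimal
topology (atom name, element, residue id/name) — deliberately
format-agnostic, since the features below need nothing more. All analyses
run on a configurable time window, defaulting to 20–50 ns, the
post-equilibration span for 50 ns replicate simulations; per-frame
superposition RMSD against a reference is provided to verify that choice
on real data.

Hydrogen-bond occupancy is the fraction of window frames satisfying an
explicit geometric criterion. The default is heavy-atom
donor–acceptor ≤ 3.5 Å; with explicit hydrogens, H···acceptor ≤ 2.4 Å and
a donor–H–acceptor angle ≥ 120° are additionally required. The criterion
is stated and configurable because published H-bond module defaults vary
between MD packages; narrowing any cutoff can only lower occupancy, and
that monotonicity is tested. Backbone-to-side-chain distances use the
mass-weighted centre of the heavy side-chain atoms (glycine is a hard
error, not a silent zero). Dihedrals use the standard four-atom signed
torsion in the IUPAC convention, validated against an independent formula
and against `bio3d` to sub-nanodegree agreement.

"Reproducible difference" between two replicate ensembles is formalized
as: per-replicate summary ranges disjoint *and* ensemble means differing
by at least `delta_min`. Per-replicate summaries (not pooled frames) are
the unit of evidence because replicates, not frames, are independent.
Under exchangeability the disjoint-range event alone has probability
`2/C(nA+nB, nA)` — 2/70 ≈ 0.0286 for 4 vs 4 — which bounds the false-flag
rate at `delta_min = 0` and is verified empirically on null ensembles.
The comparison returns the full per-replicate audit table so any flag can
be inspected.

# Centrosomal signal quantification

Focus detection finds local intensity maxima above
`background + k × noise`, merging maxima closer than a minimum separation
(brightest wins). The default noise scale is the upper-half quantile
spread `q(0.8413) − median`, which equals the Gaussian σ and remains
valid on dark channels where zero-clamping breaks the MAD. Quantification
sums the signal channel over a circular ROI of 20 px diameter around each
focus; pixel membership is "pixel centre within radius 10.0, inclusive",
which makes the member count a fixed, enumerable 317 pixels. The scalar
background estimated outside all cell masks (median by default) times the
member-pixel count is subtracted, and per-cell totals are the sum over
the cell's foci. ROIs of nearby foci are summed independently —
double-counting is possible and flagged, mirroring per-focus summation —
and border-clipped ROIs are flagged. Phenotype classification reports the
fractions of cells with >4 foci (amplification), <3 (underduplication)
and the normal 3–4 band, plus a joint two-marker rule (>4 centriole
marker and >2 centrosome marker foci) for interphase data.

# What the synthetic generators emulate — and what they do not

The acetylome generator reproduces the *statistical* structure the
calling rule assumes: 5 + 3 replicates, Bernoulli detection per site per
replicate (0.9 in control by default, 0 for dependent and 0.9 for
independent sites in knockdown), and zero-truncated Poisson spectral
counts (mean 2) decoupled from detection. Detection rates and count
distributions are free parameters of the generator, not claims about any
real experiment, which does not publish them. Sequences default to
uniform amino-acid composition — the known null that logo tests need — with
a human-like composition available; a `k_rich_flank_prob` option plants
lysine-rich flanks around dependent sites to mimic the lysine-context
preference seen in real KAT substrates. The generator does not simulate
spectra, retention times, search-engine score distributions beyond
threshold-passing values, or protein-inference ambiguity, so passing
tests demonstrate correctness of the calling arithmetic, not robustness
to search-engine pathologies.

Trajectory ensembles are Gaussian fluctuations (default SD 0.3 Å) around
a reference conformation — no physics — with scheduled H-bonds toggled
between 2.8 Å (satisfying the criterion) and 6.0 Å, and dihedral basins
planted by building reference backbones with prescribed φ/ψ via ideal
internal coordinates. Default replication is 4 × 51 frames spanning
0–50 ns. Images place disjoint disc cells with Gaussian foci
(σ = 2 px, discrete integral within 1% of the nominal intensity),
constant in-cell and outside-cell background levels, and clamped Gaussian
read noise; there is no realistic cell morphology or optics. Tests on
these inputs validate the measurement arithmetic, not segmentation or
deconvolution, which are out of scope (masks are inputs).

# Numerical and design choices

* All generators are pure functions of their configuration and seed; the
  experiment stage offsets the seed so proteome and detection draws come
  from distinct streams.
* Output orderings are deterministic (lexicographic by accession and
  position) for reproducible diffs.
* Protein coordinates are 1-based everywhere.
* Evidence presence is defined as spectral count ≥ 1; replicates without
  records still occupy all-zero columns so the rule's denominators are
  fixed by design, not by data.
* The deltaCn filter is applied to every PSM row independently; whether
  published filters applied it to top-ranked PSMs only is ambiguous, and
  per-row filtering is the stricter reading.
* Torsions are reported in (−180°, 180°], with −180° mapped to +180°.
* Problem sizes used in tests and in the acceptance script (1000 planted
  sites, 1000 null features, 201-frame trajectories, 256×256 px images)
  were chosen to make binomial/Monte-Carlo error bands a few tenths of a
  percent while keeping the full suite fast enough to run habitually.

# Known limitations

* Presence/absence calling inherits the stringency of its design: a site
  detected once in knockdown is discarded outright, so sensitivity to
  partially dependent sites is low by construction.
* Shared-peptide crediting can inflate protein counts in default mode.
* The ensemble comparison's disjoint-range criterion is conservative with
  only 2–3 replicates per side (null rate 2/C(4,2) = 1/3 at 2 vs 2) and
  should be used with ≥ 4 replicates.
* Overlapping ROIs double-count signal, faithfully to per-focus
  summation; the per-focus table flags proximity cases so users can
  decide.
* Binary MD formats (DCD/XTC) and image segmentation are intentionally
  out of scope; arrays and label masks are the interchange contracts.
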