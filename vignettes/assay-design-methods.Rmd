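---
title: "Designing competitive allele-specific PCR assays with asqdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing competitive allele-specific PCR assays with asqdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asqdesign)
```

## The assay this package designs

Competitive allele-specific PCR (KASP, PACE, and the four-channel ASQ
variant) genotypes a known SNP or InDel in a single closed-tube
reaction.  For each allele a short unlabelled allele-specific primer
(ASP) is synthesized whose 3'-terminal region matches only that allele;
all ASPs compete for the same locus against a single shared common
(reverse) primer.  Each ASP carries a 5' tail - the sequence of a
fluorophore-labelled universal probe (UP) - so that after the first
amplification rounds the amplicon of allele *i* contains the complement
of UP *i*.  From then on UP *i* is incorporated and its fluorophore
separated from the universal quencher oligo (Uni-Q), which otherwise
sits annealed flush against the probe with the 3' quencher directly
opposite the 5' fluorophore (contact quenching).  Reading fluorescence
per channel at the low-temperature step of each late cycle calls the
genotype: one signal for a homozygote, two for a heterozygote, up to
four channels for multi-allelic sites.

`asqdesign` implements the full desk side of this workflow: parsing
templates with polymorphic sites, thermodynamic and sequence-quality
metrics, ASP/common-primer design with cassette tails, interaction
screening, and tabular export.  `design_assay()` orchestrates the
pipeline; every stage is also exported on its own.

## Input model

Templates arrive as FASTA, `name<TAB>sequence` lines, or an aligned
FASTA of allele sequences.  A polymorphic site is written either in
bracket notation - `[C/G]`, `[-/CT]`, up to four variants, only the
differing bases inside the brackets, `-` or an empty field for a null
allele - or as an IUPAC degenerate base (`S` is identical to `[C/G]`).
Internally a template is an invariant backbone plus an ordered list of
sites; coordinates are 0-based half-open internally and 1-based
inclusive in all reports, the convention of primer-design tools.
Alignment input converts runs of adjacent variant columns into single
merged sites, so gap runs survive as InDel alleles.  Circular templates
are accepted; a site too close to the sequence origin is handled by
rotating the origin to the far side of the template before design, and
reported coordinates then refer to the rotated frame (noted in the
design object).

A minimum usable flank (default 35 nt, configurable) is required on the
primer-bearing side.  The limit is a deliberate surface: it is roughly
the longest 5'-extension the Tm equalizer may request, and no published
value exists for the original implementation.

## Thermodynamic model

Duplex enthalpy and entropy are summed from the unified ten-parameter
nearest-neighbor set with terminal initiation terms and a symmetry
correction for self-complementary sequences; the parameter table ships
as a plain-text file under `inst/extdata/`.  ΔG°37 is reported directly
from those sums (1 M NaCl reference state).  The melting temperature

Tm = ΔH / (ΔS + R ln C) , C = oligo concentration / 2

treats the stated "oligonucleotide concentration" as a per-strand
concentration with both strands equimolar (total strand concentration
divided by four); self-complementary duplexes use the concentration
unchanged.  The 1 M Tm is then corrected for ions with the
reciprocal-temperature divalent correction of Owczarzy and colleagues:
magnesium-dominated above √[Mg²⁺]/[mon] = 6, competitive (modified a,
d, g coefficients) between 0.22 and 6, monovalent-only below 0.22.
Free magnesium is total Mg²⁺ minus total dNTP (dNTPs chelate Mg²⁺
nearly stoichiometrically), floored at zero.

This exact combination was selected by a calibration gate rather than
by formula fiat: under the assay read conditions (200 nM oligo, 55 mM
KCl, 2.2 mM free Mg²⁺) it reproduces the published metric rows of the
shipped universal probe set - quencher 53.3 °C, probes 66.5-67.9 °C,
ΔG −16.7 to −26.8 kcal/mol - to within 0.05 °C and 0.12 kcal/mol, and
the quencher's 55 °C duplex Tm at its 500 nM working concentration
within 0.3 °C.  The acceptance tests keep that gate.

One property of the published piecewise correction is worth knowing:
at the regime boundary (√[Mg²⁺]/[mon] = 0.22, about 0.15 mM Mg²⁺ at
55 mM K⁺) the predicted Tm steps down by up to ~1.4 °C for GC-rich
oligos.  We do not smooth this; monotonicity in Mg²⁺ holds within the
magnesium-dominated regime where PCR operates.

Molecular weight uses the linear 5'-OH convention (residue masses minus
one bridge equivalent of 61.96 g/mol); the 260 nm extinction
coefficient uses the standard nearest-neighbor method (dimer values
minus internal monomers).  The reported "product Tm" of an amplicon is
the usual long-duplex GC/length approximation - an annotation, never a
design criterion.

## Sequence-quality screens

Linguistic complexity (LC) is the vocabulary ratio over word sizes 1-3:
observed distinct k-mers divided by the maximum possible,
`min(4^k, n − k + 1)`, summed over k and expressed in percent.  The
definition is normative here because it reproduces the five published
probe-set LC values (100, 86, 95, 89, 92) exactly.  Windowed LC below a
threshold (defaults: 20 nt window, 70 %) masks a region from primer
placement, as do G-quadruplex motifs, matched by the standard consensus
`G₃₊(N₁₋₇G₃₊)₃` on either strand (C-tracts for the minus strand).  Both
defaults are configurable; no published values exist.  Note that with
the 70 % threshold roughly 5 % of uniformly random 20-mers are masked -
the screen is intentionally conservative near primer 3' ends.

## Primer design

**Allele-discriminating 3' ends.**  For each allele the engine builds
the string `allele + downstream flank` and takes the shortest prefix
(≤ 12 nt) that differs from every other allele's prefix of the same
length; the ASP for that allele ends in exactly this string, so its 3'
terminus can pair perfectly only on its own allele.  For pure SNPs the
minimal prefix is one base and the configured placement mode shifts the
variable base away from the terminus: `first` (terminal base),
`penultimate` (default - one template base follows the variable base),
`antepenultimate`, or `auto`.  For InDels, including null alleles, the
discriminating end is determined automatically, crossing the
deletion junction or entering the insertion as needed; sites whose
alleles cannot be told apart within 12 nt are rejected as
undesignable.

**Auto placement.**  The published description says only that automatic
offset selection is thermodynamic.  Our surrogate: for each offset 1-3
that admits an in-window primer set, score the set by the weakest
pairwise 3'-destabilization proxy (|ΔG| of the 3'-terminal segment that
mismatches the competing allele) and keep the offset maximizing it,
preferring the penultimate position on ties.  This is a documented
stand-in, not a reconstruction.

**Tm equalization.**  Candidates for one allele share their fixed 3'
end and differ only in 5' start (core lengths 18-36 nt).  The equalizer
selects one candidate per allele such that all melting temperatures lie
in the target window (63 ± 1 °C by default) and the pairwise spread is
minimal - the low-Tm allele is 5'-extended toward its GC-richer
competitors, never altered at the 3' end.  The search is exhaustive
over in-window candidates (capped with a nearest-to-target reduction
at 2·10⁵ combinations, far beyond practical cases).

**Common primer.**  On the opposite strand, candidates are enumerated
over all placements for which every allele's amplicon (ASP 5' end
through common-primer 5' end, inclusive, on the allele-substituted
template) lies within the configured 100-200 bp range; masked regions
are excluded, the Tm window applies, and ranking is by closeness to
the mean ASP Tm, then primer quality, then leftmost placement.

**Primer quality (PQ).**  No numeric definition of the published PQ
exists, so the package documents its own: 100 minus weighted penalties
for Tm deviation from the window (weight 30), 3'-terminal pentamer
free energy outside −9…−5 kcal/mol (25), self-dimer/hairpin structure
stronger than −6 kcal/mol (25), LC below 70 % (10), and GC outside
40-60 % (10), each scaled linearly and capped.  PQ depends only on the
candidate and the conditions.

**Orchestration.**  `design_assay()` attempts both strands (and, in
auto mode, all offsets), attaches cassette tails (allele order maps to
cassette channel order - a convention, the channels are
interchangeable), re-screens the full tailed primers for dimers,
scans every primer core against every allele template for non-specific
binding sites (≤ 2 mismatches tolerated, 3'-terminal 3 bases exact),
and returns the best passing direction, ranked by screen status, mean
core PQ, amplicon centering, plus strand, leftmost start - a fully
deterministic order.  The other direction is kept as an alternative;
if every direction fails, a structured error lists the per-direction
causes.

## The FRET cassette system

The shipped default is the four-channel universal set: 13-nt tail
`ccagctgaacggt` shared by all probes, 6-nt channel barcodes ACGGCA
(FAM), CGTTGC (HEX/JOE/VIC), AGCCGA (Cy3/TAMRA), GCGTCA (Cy5/Liz), and
the single quencher `accgttcagctgg` (3' BHQ1/Eclipse), which is the
exact reverse complement of the tail.  Case is annotation: lowercase
tail, uppercase barcode.  `validate_cassette()` checks the structural
invariants (tail/quencher complementarity, quencher shorter than the
probes, 6-nt distinct non-cross-complementary barcodes) and the
thermodynamic ones (quencher duplex melting near the 55 °C read
temperature at 500 nM; probe Tm in 66-68 °C).  `design_custom_cassette()`
searches seeded and deterministically for a fresh tail (12-14 nt) and
barcodes filtered for GC 33-83 %, no homotrinucleotide, pairwise
Hamming distance ≥ 3, and clean cross-dimer screens - those filter
values are package choices, configurable, with no published
counterpart.

## Interaction screening

Dimers are scored by ungapped antiparallel alignment over all offsets:
the hit is the longest contiguous Watson-Crick run (wobbles excluded),
scored by its nearest-neighbor ΔG, worst hit kept with a leftmost
tie-break.  Hairpins enumerate all stems ≥ 4 bp with loops ≥ 3 nt.  A
screen fails at ΔG ≤ −9 kcal/mol anywhere or ≤ −6 kcal/mol when a 3'
terminus lies inside the paired run - invented, configurable defaults;
the published tool names the checks but not its cutoffs.  Screening
runs on the full tailed sequences (a tail can create structure the core
lacks; the shared tail itself contains the 6-bp palindrome CAGCTG,
which is why tailed sets are re-screened rather than assumed clean).
Binding-site scans are restricted to the supplied templates; genome
-scale specificity is out of scope by design.  `compatibility_report()`
assembles the symmetric pairwise matrix, per-template binding counts
and product-size overlap flags (< 10 bp apart) for multiplexes.

## Synthetic fixtures: what they do and do not show

`generate_fixture_templates()` produces seeded templates: uniformly
random flanks of configurable GC content (default 0.5, 160 nt per
side - enough for a centered 100-200 bp amplicon either way) around one
bracket site of the requested class (2/3/4-allele SNP, 1-30 nt InDel,
mixed).  Because ASP 3' ends are pinned to the site, default fixtures
resample their flanks until the 60-nt site neighbourhood is unmasked
for every allele - they emulate *designable* loci, the way a scientist
would shortlist assay targets; the `low_complexity` and `g4` toggles
deliberately embed failing motifs for negative tests.  What passing
designs on these fixtures demonstrate is structural correctness of the
engine (placement, discrimination, equalization, screening) - not
wet-lab performance on real genomes, which involves paralogs,
polyploidy and chemistry that no desk test reaches.  Even on clean
fixtures a fraction of templates is legitimately undesignable (GC-rich
neighbourhoods where no 18-36-mer lands in the 2 °C window on either
strand); the engine reports these as structured failures rather than
relaxing its constraints.

## Numerical and reproducibility choices

Tie-breaks are fixed everywhere (leftmost offsets, penultimate-first
auto mode, plus strand before minus); identical inputs, options and
seeds give byte-identical exports, which the tests assert at the file
level.  Exports use fixed-format numbers (Tm/ΔG to 0.1, GC to 0.1, LC
rounded to integer, MW to 0.01), UTF-8, tab separation, "." decimals
regardless of locale.  Seeded routines (fixtures, custom cassettes)
run on a private RNG stream and restore the caller's `.Random.seed`.
The recommended annealing temperature is min(core Tm) − 2 °C - a
package convention, exposed in the options.

## Known limitations

No mismatch or dangling-end thermodynamics (deliberate-mismatch ASP
strategies are explicitly not implemented); no gapped dimer alignment;
no genome-wide specificity search; no fluorescence spectra model -
fluorophore and quencher names are opaque labels; probe (TaqMan/MGB)
and isothermal designs are out of scope.  The PQ score and the
auto-placement criterion are documented package constructions standing
in for unpublished internals of the original tool.
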