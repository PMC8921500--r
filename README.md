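# asqdesign

Design engine for **competitive allele-specific PCR genotyping assays**
(KASP / PACE / four-channel ASQ).  Given template sequences carrying SNP
or InDel polymorphic sites — up to four alleles per site — the package
designs the complete single-tube assay: one allele-specific primer (ASP)
per allele with a universal FRET-cassette tail, a shared common (reverse)
primer, and a 100–200 bp amplicon, all thermodynamically equalized and
screened for dimers, hairpins, non-specific binding and multiplex
conflicts.  It is written for geneticists and breeders who develop
fluorescence-read genotyping markers and for bioinformaticians building
assay-design pipelines.

## How the assay works

Each allele *i* gets an unlabelled primer whose 3′-terminal region pairs
perfectly only with allele *i* (for SNPs the variable base sits by
default at the *penultimate* 3′ position; for InDels a unique ≤ 12-nt 3′
end is derived from the allele and its downstream flank).  All ASPs
compete against one common primer.  The 5′ tail of ASP *i* equals the
sequence of universal probe UP *i* — a 13-nt universal tail plus a 6-nt
channel barcode, 5′-labelled with a channel fluorophore.  A single
quencher oligo (Uni-Q), the exact reverse complement of the universal
tail, contact-quenches every free probe.  Amplification of allele *i*
incorporates UP *i* and releases its fluorescence; channels are read at
the 55 °C step of each late cycle.

## The numerical core

* **Duplex thermodynamics** — unified nearest-neighbor ΔH/ΔS sums with
  initiation terms;
  `Tm = ΔH / (ΔS + R ln(C/2)) − 273.15` for non-self-complementary
  duplexes at per-strand concentration `C`, followed by the
  reciprocal-temperature monovalent/divalent (Mg²⁺) correction with free
  Mg²⁺ = [Mg²⁺] − [dNTP].  ΔG°₃₇ comes straight from the ΔH/ΔS sums.
* **Linguistic complexity** —
  `LC = 100 · Σₖ Vₖ / Σₖ min(4ᵏ, n−k+1)` over word sizes k = 1..3, the
  vocabulary-ratio measure used to mask low-complexity regions
  (windowed, 20 nt / 70 % defaults) alongside G-quadruplex motifs
  `G₃₊(N₁₋₇G₃₊)₃`.
* **Tm equalization** — per allele, candidates share a fixed 3′ end and
  vary only the 5′ start; the selected set lies in the 62–64 °C window
  with minimal pairwise spread.
* **Interaction screens** — ungapped antiparallel dimer alignment scored
  by the ΔG of the longest Watson–Crick run (fail at ≤ −9 kcal/mol, or
  ≤ −6 with a 3′ terminus involved), hairpin enumeration, and
  binding-site scans across all allele templates.

## Worked example

```r
library(asqdesign)

fa  <- generate_fixture_templates(42, n = 1, site_kinds = "snp2")
tpl <- parse_templates(fa)[[1]]   # 320-nt template, one [A/T] site
d   <- design_assay(tpl)
print(d)
```

```
assay_design: fixture_1_snp2 site 1 (SNP), ASPs on plus strand
fixture_1_snp2_s1_ASP_A [ASP/plus] CCAGCTGAACGGTACGGCATCCGATACAGCTGAGTACCCTATAT  (44 nt, Tm 77.7, core Tm 63.8, dG -58.6, GC 52.3, LC 79, PQ 45)
fixture_1_snp2_s1_ASP_T [ASP/plus] CCAGCTGAACGGTCGTTGCCCGATACAGCTGAGTACCCTATTT  (43 nt, Tm 78.7, core Tm 63.4, dG -58.7, GC 53.5, LC 89, PQ 45)
fixture_1_snp2_s1_C [common/minus] CTCGGCAGGAGCATGTTG  (18 nt, Tm 63.4, dG -24.0, GC 61.1, LC 86, PQ 86)
  amplicons: 113/112 bp; product Tm ~87.9 C; anneal at 61.4 C
  channels: A=UP1, T=UP2; screens: pass
```

Reading the output: each ASP is shown as ordered (19-nt probe tail +
target-binding core); the **core Tm** values (63.8 / 63.4 °C) are the
equalized annealing temperatures inside the 62–64 °C window, while the
full-primer Tm includes the tail.  The A-allele ASP ends `…TAT**A**T` —
variable base at the penultimate position — and competes with the
T-allele ASP for the same locus; both pair with the 18-nt common primer
to give 113/112 bp products read on FAM (UP1) and HEX (UP2).
`export_table(d, "design.tsv")` writes the full per-primer metric table
(location, length, Tm, GC, MW, ε₂₆₀, LC, PQ, channel, amplicon) plus
per-pair rows with the recommended annealing temperature and product
size/Tm; `emit_protocol_sheet(d, 15)` prints the 15-µl reaction recipe
and the two-round thermal profile.

A command-line front end covering the same pipeline (plus per-oligo
metrics, cassette validation/design, compatibility checks on user primer
lists and fixture generation) is available via `run_cli()` or the
`inst/cli/asqdesign` script.

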