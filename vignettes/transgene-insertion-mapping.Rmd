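---
title: "Mapping a BAC transgene insertion: models, parameters and design choices"
author: "BACtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a BAC transgene insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BACtrace)
```

BACtrace characterizes a BAC-transgenic line from a hemizygous carrier:
linkage localization, breakpoint discovery from paired-end sequencing,
passenger-gene copy number, and relative expression. This vignette explains
the models behind each step, the parameters that matter, what the synthetic
data emulate (and do not), and the numerical choices the implementation
makes.

## The two-point linkage model

An informative backcross segregates the transgene (present/absent) against
a floxed marker locus (F/F vs F/W). Under independent assortment the four
two-locus classes are equally likely (25% each); linkage depletes the two
recombinant classes. The estimator is the simple ratio
$\hat\theta = R/n$ over designated recombinant classes, genetic distance is
$100\,\hat\theta$ cM (no Haldane/Kosambi mapping function — at the short
distances that matter here the difference is below display precision, and
the direct proportionality matches how such tables are reported), and the
evidence is the LOD score against free recombination ($\theta = \tfrac12$).

Two LOD forms are implemented deliberately. `lodTable()` evaluates the
literal formula printed in the linkage table this package is patterned
after, $Z = n\,\log_{10}\!\big((1-\theta)/\tfrac12\big)$, in which the
recombinant term carries exponent zero and drops out. `lodStandard()` is
the textbook statistic
$Z = \log_{10}\!\big[\theta^R(1-\theta)^{NR}/(\tfrac12)^{R+NR}\big]$.
For the reference cross (2, 43, 43, 2 with $n = 91$) the first gives 25.6
and the second ≈ 20.0; both are far beyond the $Z \ge 3$ definitive
threshold, so the scientific conclusion is unchanged, but the report keeps
both because the literal form is what the table prints while the standard
form is what a geneticist would compute. Two further conventions from the
same table are honored: `nTotal` is an explicit argument (the printed class
counts sum to 90 while the printed $n$ is 91, so the denominator must be
overridable), and display rounding is θ to 3 decimals, cM and LOD to 1.

## The synthetic genome and what it emulates

`buildReference()` makes a two-chromosome toy genome (default 200 kb each,
uniform random sequence): an acceptor chromosome with a 10 kb multi-exon
acceptor gene, a two-copy reference-assay gene and neutral genes; and a
donor chromosome whose 20 kb donor interval contains the driver gene and
four passenger genes, with neutral genes outside. Roughly 60 genes of 2 kb
give the coverage baseline something to average over. The scale is a
deliberate reduction of the real setting (a 245 kb BAC in a 2.7 Gb genome)
chosen so a full simulate–map–call–quantify cycle runs in seconds; nothing
in the method depends on the absolute scale.

`applyInsertion()` plants the cassette on haplotype B only — hemizygosity is
modeled as 50:50 haplotype sampling with no allele-specific bias. The
cassette is the donor fragment with the first 222 bp of the driver gene
replaced by a fixed 1 kb synthetic recombinase-marker sequence that is
absent from the reference; the marker is the transgene-only sequence tag,
and reads that cross into it cannot be anchored on both sides, exactly like
reads entering any foreign coding sequence.

With `rearranged = TRUE` (the default) the cassette is

```
donor-left + marker + retained acceptor fragment + inverted donor-right
```

inserted into the final exon of the acceptor gene with a net deletion.
This structure was chosen because it yields **exactly three
reference-mappable junctions, all inter-chromosomal, with orientation
signatures (−,+), (−,−) and (+,+)** — the pattern reported for real BAC
integrations, where several donor fragments and a stretch of acceptor
chromosome interleave and one junction abuts the foreign marker and is
therefore invisible to reference alignment. A plain internal inversion
would instead create an intra-donor-chromosome junction that the
region screen (which keeps only inter-chromosomal calls anchored in the
donor region) would discard. With `rearranged = FALSE` the cassette is the
plain fragment and plants the two flank junctions.

Truth is recorded from the derived-chromosome block structure: every
junction between two mappable blocks, with per-gene copies
(2 + tandem copies for fully contained passengers; the driver stays at 2
because its extra copy is promoter-swapped). What the simulator does *not*
emulate: indels and structure beyond the one insertion locus, realistic
base-quality and error profiles (errors are iid substitutions; qualities
constant Q30), GC or mappability bias, and multi-site integration. Tests
that pass against this truth therefore demonstrate the machinery, not
robustness to every artifact of real libraries.

`simulateReads()` draws forward–reverse templates (defaults: 100 bp reads,
40× depth, 350 ± 50 bp fragments, 0.2% substitutions, seed-deterministic to
the byte). 40× was chosen as half of a typical >80× whole-genome design so
the acceptance runs stay fast while keeping per-junction support safely
above the calling threshold.

## Mapping and breakpoint discovery

The mapper is intentionally minimal: exact k-mer seeds (k = 21, at stride k
on both strands) propose ungapped placements, the fewest-mismatch placement
wins, ties are reported as `ambiguous` and carry no coordinates (this is
the repeat guard — ambiguous records are excluded from SV evidence and
counting), and anything above a 5% mismatch fraction is unmapped. Reads
that fail full-length placement are split-mapped: shorter seeds (k = 15,
needed because a 20 bp minimum segment cannot contain a 21-mer) propose
candidate diagonals, and the breakpoint $b$ maximizing total matched bases
over ordered diagonal pairs is selected, each part at least 20 bp and
within the same mismatch budget. Ties on $b$ take the smallest $b$; ties
across diagonal pairs make the read ambiguous. Ungapped alignment suffices
because the simulation contains no indels and junction detection needs
placement, not gapped alignment.

**Breakpoint canonicalization.** When junction flanks share terminal
microhomology of length $h$, the breakpoint has $h{+}1$ equivalent
representations, and split reads sequenced from the two strands of the
derived allele would report opposite extremes. Both the truth recorder and
the caller therefore canonicalize every junction by walking the full
microhomology range (`canonicalizeAdjacency()`) and taking the
lexicographically smallest representation with canonically ordered sides.
This is what makes base-exact recovery a fair assertion: without it,
junctions that happen to carry ≥ 2 bp of homology would be "missed" by the
homology length even though the call is correct.

A pair is proper when the mates are forward–reverse on one chromosome
within `mean + 3·sd` of the fragment model; otherwise discordant
(inter-chromosomal / orientation / distance). Split reads give base-exact
junction observations; discordant pairs give interval observations on the
side their strand points to. Single-linkage clustering runs within each
(chromosome-pair, orientation-signature) stratum with window
`mean + 3·sd` (500 bp by default) — opposite signatures never merge, and
output is independent of input order. Calls need `minSupport = 4` total
observations (a conservative choice at 40–80×, where each true junction
collects ~25–40), are positioned at the lower median of split positions
(median for robustness to edge errors; lower value as the deterministic
tie-break), and are `precise` only when a split read contributed.
The screen then keeps calls with one side in the donor region of interest
and the other side on a different chromosome.

## Copy number

Coverage route: per-gene read counts (≥ 1 bp overlap, reads touching two
genes dropped, mates counted separately to match read-level coverage
semantics), TPM length normalization, and
`copies = 2 · TPM / trimmed-mean TPM`. The 10% two-sided trim exists
because in a ~60-gene toy set the five transgene-amplified genes would
otherwise inflate the "genome average" that a 27,000-gene genome renders
insensitive; the trim discards exactly that tail. ddPCR route: Poisson
inversion $\lambda = -\ln(1 - P/N)$, volume default 0.85 nL
(instrument-nominal; configurable because no published value exists),
replicate wells pooled by summing $P$ and $N$ before inversion (the
minimum-variance merge), and normalization to a two-copy reference assay.
Saturated wells ($P = N$) are rejected rather than clamped.

## qPCR

The efficiency-corrected ratio uses per-assay amplification bases
$E = 1 + \text{eff}/100$. Technical replicates are averaged on the Cq
scale; biological replicates are summarized by the geometric mean of
per-sample ratios (ratios are log-normal-ish, and the geometric mean keeps
reciprocity exact). Where a source describes the method as "2^ΔΔCq with
efficiency correction" without fixing the algebra, the ratio form is
implemented and labeled, since the two coincide exactly at equal
efficiencies — a reduction the tests assert.

## Problem sizes and determinism

The shipped tests and the acceptance checks run the full pipeline on
2 × 200 kb genomes at 40× (≈ 80,000 templates, ≈ 8 s per run including
mapping), ten seeds for junction recovery, and Monte-Carlo droplet and
backcross simulations of a few hundred replicates — sizes chosen so the
whole suite stays in the minutes range on one core. Every stochastic stage
is seeded; identical configuration and seed reproduce FASTA/FASTQ/SAM
bytes and the report exactly.

## Known limitations

The mapper is not a production aligner (no gapped alignment, no
quality-aware scoring, no paired rescue); external SAM can be supplied via
`readSam()` instead. Orientation semantics of adjacency sides follow an
explicit convention — `+` joins sequence extending right of the position on
the forward strand, `-` extending left — documented here because published
breakend notations do not always define theirs. Tandem cassettes of more
than one copy create an additional intra-donor junction between copy
boundaries that the inter-chromosomal screen intentionally drops. The
copy-number baseline assumes most genes are two-copy; a genome dominated
by amplified content would need an external baseline.
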