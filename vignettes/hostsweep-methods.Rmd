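---
title: "Host read decontamination with hostsweep: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host read decontamination with hostsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Clinical microbial sequencing almost always carries human host reads that
must be excised before data can be shared or analysed. `hostsweep`
implements the subtractive strategy: align every read against a host
reference and remove those with qualifying host evidence, keeping
everything else. The operating point matters in both directions — removal
must be near-complete (anonymity) while microbial retention losses of even
a few reads per hundred thousand are visible in assemblies and variant
calls, which is why retention percentages in this field are quoted to six
significant figures.

Formally, for a read (or pair) $r$ with alignment record set $A(r)$
against reference index $I$, the removal decision is

$$\mathrm{remove}(r) \;=\; \bigvee_{a \in A(r)} q(a), \qquad
q(a) = \mathrm{mapped}(a) \wedge \big(\text{short backend} \;\vee\;
s_1(a) \ge m\big)$$

where $s_1$ is the long-read aligner's chaining score and $m = 40$ the
minimum score accepted as host evidence. For paired data the decision is
taken at pair level: either mate qualifying removes both ("mate rescue"),
so no orphan mates are ever emitted and half-pairs of host origin cannot
leak. Reads absent from the alignment stream are kept — absence of
evidence never removes.

## Aligner backends

* **short** — minimap2, `sr` preset. The environment this package targets
  provides minimap2 but not Bowtie2, and minimap2 is an equally supported
  short-read aligner for this method; the chaining-score floor applies to
  short reads as well as long ones, which is the documented behaviour of
  the method for minimap2. This is a deliberate deviation from the design
  note naming Bowtie2, made for portability; the single point of truth for
  the argv is `plan_alignment()`, pinned by a golden test.
* **long** — minimap2, `map-ont` preset, `-m 40`.

Both invocations pass `--secondary=no` so a single primary alignment per
read is reported: the decision needs no more, and it keeps streams small.
A mapped long-read record lacking the `s1` tag is treated as evidence
(fail-safe toward removal; the threshold was already enforced at
invocation). `--offline-sam` substitutes any SAM file or stream for a live
aligner, making the whole filter engine testable hermetically.

SAM text is parsed by the package itself rather than through a BAM layer:
the streaming single-pass contract (bounded memory, no intermediate files,
subprocess stdout consumed incrementally) is part of the tool's point, and
the per-record reduction needs only the query name, flag bits and one tag.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_chain_score` | 40 | minimap2 chaining score accepted as host evidence (both backends) |
| `threads` | 8 (CLI) / 1 (API) | aligner threads; determinism guaranteed at 1 |
| `rename` | off | replace surviving read names by 1, 2, … (mates share the integer, suffixes dropped; sidecar TSV maps old to new) |
| `min_match_length` | 100 bp | minimum host–microbe similarity span masked |
| `min_identity` | 0.80 | minimum identity of a masked similarity hit |

Output compression is gzip level 6; zlib writes a fixed header (zero
mtime), so identical runs produce byte-identical files — goldens compare
decompressed content anyway to stay robust across zlib builds.

## Masked references

Host assemblies contain tracts similar to microbial genomes (conserved
genes, EBV integrations, contaminating sequence in the assembly itself);
reads from those tracts in a genuine microbial sample would be removed as
false positives. `mask_reference()` neutralises them by hard-masking with
`N`. The original procedure for building the published masked database is
not public; this package's own procedure is:

1. align each microbe genome against the host with minimap2's `asm20`
   genome-to-genome preset;
2. keep PAF hits with block length ≥ `min_match_length` and identity
   (matching bases / block length) ≥ `min_identity`;
3. merge hits into disjoint BED intervals (0-based half-open; merging via
   `IRanges::reduce`) and replace the covered host bases with `N`.

An exact shared-31-mer fallback (`method = "kmer"`) exists so unit tests
need no binary; it detects shared exact substrings of at least
`min_match_length` bp (identity is then 1 by construction, so
`min_identity` does not apply). Masking preserves sequence names, order,
lengths and case; the count of added `N`s equals the merged interval
length exactly, and adding genomes to the panel can only grow the mask.

## Synthetic data: what it emulates, and what it does not

The simulators stand in for the DWGSIM/PBSIM2 read sets used in full-scale
benchmarking. Stated-world defaults: 2x150 bp pairs (2x100 and 2x150 are
the benchmark layouts), 300 ± 50 bp inserts, 1% short-read substitution
rate (0.5% is used for the cleaner "host" sets in the acceptance fixture),
5% long-read error split 40% substitution / 30% insertion / 30% deletion,
gamma-distributed long-read lengths (mean 5 kb, shape 2, floor 200 bp).
Insert parameters and the gamma shape are this package's own choices of
typical Illumina/ONT values; they are deliberately fixed once.

Random i.i.d. genomes have no repeats, no conserved genes and no shared
ancestry, so cross-mapping between "host" and "microbe" is essentially
impossible by construction. A green accuracy test therefore establishes
the machinery (decision logic, pair semantics, masking plumbing,
accounting) — not the biological operating point on real human data, which
depends on reference completeness and true sequence similarity.
Quality strings are constants (Q25 short, Q12 long): the method never
reads them. Provenance (source, 0-based start, strand, truth class,
serial) is encoded losslessly in each read name, which is what makes exact
truth-based scoring possible downstream.

## Evaluation

`score_retention()` counts retained read units per truth class;
multi-sample aggregation sums numerators and denominators before dividing
— never a mean of per-sample percentages, which weights small samples
incorrectly. `ebv_adjust()` re-runs the full pipeline against a small
viral index (the EBV mechanism: lymphoblastoid cell lines carry EBV, whose
reads survive human-reference subtraction and inflate apparent host
retention) and reports `retained after viral subtraction / original
input`; it needs the original input count as an explicit argument since it
is not recoverable from the retained set. `compare_runs()` reports
percentage-point deltas and removed-read fold-changes with `0 → 0` defined
as fold 1 and `0 → k` as infinite, so degenerate fixtures never crash.
`fold_change_ci()` gives a seeded bootstrap percentile CI (10⁴ resamples
by default) for the mean per-sample fold-change; bootstrap is used because
it is assumption-light — the CI method behind published fold-change
intervals for this kind of comparison is not standardised. Infinite
per-sample folds (nothing removed by the baseline) are excluded from the
mean and reported separately.

## Numerical and degenerate-input choices

* Distinct-read counting is per distinct (read id, mate) unit, after
  excluding nothing: secondary/supplementary records collapse into their
  unit rather than being counted.
* Duplicate ids within one single-end file are tolerated (each record is
  decided by its id; a removed id removes all duplicates) — degenerate,
  but it must not crash.
* Empty inputs produce valid empty gzip FASTQ and an all-zero report with
  `reads_removed_proportion = 0` (no division by zero).
* Conservation (`reads_in = reads_out + reads_removed`) is asserted at
  report construction *and* serialization; a violation aborts with a
  dedicated exit code rather than writing a wrong report.
* Interval merging treats bookended intervals (`end == next start`) as
  mergeable; the covered base set is preserved exactly either way.

## Known limitations

* Alignment itself is delegated to minimap2; without it only
  `--offline-sam`, the k-mer masking route and the simulators work.
* The long-read error model is far simpler than a real ONT error profile
  (no homopolymer bias, no quality correlation); adequate for exercising
  the decontamination path, not for basecaller studies.
* Memory of the decision map grows with the number of *distinct* aligned
  reads (not with SAM records); for desk-scale inputs this is negligible.
* BAM/CRAM input, interleaved FASTQ, trimming and duplicate removal are
  out of scope.
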