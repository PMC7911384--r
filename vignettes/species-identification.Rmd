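---
title: "Identifying species from ancient mitochondrial reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying species from ancient mitochondrial reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
library(dplyr)
```

## The problem

Subfossil bones are routinely assigned to species on morphology alone, and
for canids this is unreliable: dholes (*Cuon alpinus*), wolves and jackals
overlap in size and shape, and Pleistocene dholes were larger than living
ones. Degraded DNA offers an independent line of evidence. The catch is
that ancient DNA is short (typically well under 100 bp), damaged
(post-mortem cytosine deamination read as C→T at 5′ read ends and G→A at
3′ ends), and heavily contaminated, so the identification itself has to be
built from mapping statistics that are robust to those properties.

`paleomito` implements a three-lines-of-evidence identification against a
panel of candidate mitochondrial genomes:

1. **Read counts** — map the reads independently against every candidate
   mitogenome; the conspecific reference attracts the most reads.
2. **Mapping evenness** — on the conspecific reference, reads tile the
   whole molecule; on a more divergent reference they concentrate in
   conserved pockets. Evenness is the ratio of mean coverage
   \(C = S/L\) (aligned bases over reference length) to mean read depth
   \(D = S/B\) computed over covered positions (\(B\) = positions with
   depth ≥ 1). Because both share the numerator \(S\), the ratio is
   algebraically the breadth fraction \(B/L\) — a number in \([0,1]\)
   that is near 1 for conspecific mappings and drops as the reference
   diverges. The package computes the definitional ratio *and* asserts
   the identity on every input.
3. **Phylogenetic placement** — a consensus sequence called from the best
   reference is aligned with the panel and placed in a bootstrapped
   neighbor-joining tree rooted on a designated outgroup; the sample's
   assignment is its nearest reference within the smallest clade with
   bootstrap support ≥ 50 that contains it.

The verdict is *concordant* only when every available line names the same
non-outgroup reference; otherwise *ambiguous*. The combination rule is
deliberately strict — a unanimity formalization of an argument that is
usually made case by case — and outgroup-flagged references (a human
contaminant control, the rooting taxon) can never be the verdict, though a
human reference attracting the most reads raises a "low endogenous
content" note.

## The synthetic-data generator

Every stage is testable offline because the package ships its own
generator of panels and ancient-style reads, with the ground truth
embedded losslessly in each read name.

**Panels** (`sim_panel()`) are substitution-only: a random root sequence
radiates into `n_refs` circular references, each site mutating with a rate
chosen so the realized pairwise divergence (including coincident hits)
matches the request; the default 8% reproduces the dhole–wolf scale of
mitogenome divergence (≈92% identity). Substitution-only evolution keeps
all references in a shared coordinate system, so the mutation log the
generator keeps is an exact oracle for alignment-level statistics; indel
handling is exercised separately with hand-built fixtures. Each reference
carries a synthetic control-region annotation (the last ~7% of the
molecule, the scale of the canid control region).

**Reads** (`sim_reads()`) are single-end fragments drawn uniformly from
the circle (origin-spanning fragments allowed). Fragment lengths are
lognormal with mean 55 and sd 15, truncated to [30, 75] — the
right-skewed profile of degraded DNA under a 75 bp single-end sequencing
run and a 30 bp length filter; the bounds are conventions for this kind
of library, as no empirical length distribution is published for the
emulated data. Damage follows a geometric single-strand model: at 5′
offset \(i\) a C is read as T with probability \(d_5 r^i\) (mirrored with
G→A from the 3′ end), the standard one-parameter decay approximation for
terminal deamination. Damage is applied before uniform sequencing error,
matching the physical order of events; PCR duplicates copy the damaged
template coordinates and sequence, then receive independent sequencing
error. Contaminant reads are drawn from outgroup-flagged references.
Defaults (d5 = d3 = 0.2, decay 0.5, error 0.005) sit in the range typical
of partially UDG-treated ancient libraries — strong enough to matter,
weak enough that a 10% mismatch budget absorbs them.

What the generator does *not* emulate: capture bias (reads enriched with
cross-species baits can be depleted in low-identity regions),
heteroplasmy, nuclear mitochondrial insertions, indel polymorphism, and
base-quality structure (synthetic qualities are flat Q37). Passing tests
therefore demonstrate correctness of the statistics under the stated
model, not robustness to every artefact of real libraries.

## The mapper

Reads are aligned ungapped against each reference independently
(seed-and-verify, compiled core): every read k-mer (default k = 10) is
looked up in an index of the reference extended by its first
`max_read_len − 1` bases, so origin-spanning placements are found; each
candidate diagonal is verified by mismatch counting over both strands,
and the best placement is kept if its mismatch fraction is at most 0.1
(divergence plus damage headroom). Any placement with a clean k-length
stretch somewhere along the read is guaranteed to be found — with ≤ 75 bp
reads and k = 10 that covers all placements with up to
`floor(len/k) − 1` mismatches, and the test suite checks agreement with
an exhaustive all-positions scan. Ungapped alignment is the default
because mitogenome panels at ≥ 90% identity rarely need gaps at read
scale and it keeps the brute-force oracle exact.

The mapping-quality proxy encodes placement uniqueness: 60 when no other
placement comes within 3 mismatches, 25 per mismatch of margin below
that, 0 on exact ties (repeats). Filtering at mapq ≥ 30 (i.e. a margin of
at least 2) plays the role that a conventional aligner's MAPQ ≥ 30 filter
plays in ancient-DNA pipelines. Duplicates are removed per
(start, end, strand) coordinate triple, keeping the highest-mapq record
with read-id tie-break, which makes `dedup_alignments()` deterministic
and idempotent.

## Consensus, alignment and diversity

`call_consensus()` uses the conventional ancient-DNA thresholds: a
position needs depth ≥ 3, and the unique plurality base must reach 50% of
covering reads; ties at the top and positions below depth are `N`. The
threshold comparison is inclusive (≥ 0.5), and ties yield `N` — the
conservative choices where tool behaviour is undocumented. An optional
`trim_terminal` mode excludes read termini from the pileup, which removes
most deamination miscalls when libraries are not UDG-treated.

`anchor_msa()` replaces a progressive MSA with a reference-anchored one:
every sequence is aligned pairwise to one anchor (banded global
alignment, match 1, mismatch −1, gap open −5, extend −1, band 200) and
stacked on the anchor's coordinates, dropping insertions relative to the
anchor. For mitogenomes at ≥ 90% identity this is nearly identical to a
full MSA *after* the downstream filter — `strip_columns()` keeps exactly
the columns where every sequence has a called base, and optionally drops
the control region by anchor coordinates — because any column an
insertion would create contains a gap and is removed anyway. The payoff
is exact testability; externally computed alignments can be imported with
`read_alignment()` (FASTA or NEXUS) to bypass the anchoring entirely.

Diversity statistics follow the standard definitions: variable columns
hold ≥ 2 states; parsimony-informative columns hold ≥ 2 states each in
≥ 2 sequences; pairwise differences are absolute Hamming counts with
per-group mean ± sd for groups of ≥ 2 members. Because the input is
already gap/N-free, pairwise and complete deletion coincide, so no
missing-data mode needs to be chosen.

## The median-joining network

`build_mj_network()` follows the classical construction: Hamming
distances; the ε-relaxed minimum-spanning network (an edge survives if
its length is within ε of the bottleneck — the largest edge on the
minimum-spanning-tree path between its endpoints; ε = 0, the common
default, keeps exactly the union of all tied MSTs); then, repeatedly, the
median (column-wise majority) of each connected triplet is added as an
inferred node whenever it strictly shortens the network, and medians
whose degree falls below 3 are pruned. Candidate medians come only from
connected triplets — the classical formulation — and exhaustive triplet
search is cheap at the ≤ 100-haplotype scale this targets.

Two determinism choices are worth noting. Majority ties take the state of
the first node of the triplet in a *canonical* ordering (lexicographic by
haplotype sequence, not input order), which makes the final edge set
invariant to row permutations of the input. And because the ε = 0 network
keeps all tied MST edges, its total length can exceed a single MST's when
distances tie; the meaningful optimality property — median insertion only
ever strictly shortens the network, and equals the sampled-only network
when no median helps — is what the tests assert, alongside the canonical
triplet case ({000, 110, 101} gains median 100 and drops from length 4 to
the Steiner-optimal 3).

## Phylogenetic placement

Distances (p, JC69 or K80; K80 default) and neighbor joining come from
`ape` — classical, exactly testable machinery. NJ on an additive matrix
returns the generating tree exactly, which the tests verify both by
path-length-matrix equality and by Robinson–Foulds distance on sequences
evolved along a known 8-leaf tree. This distance pipeline stands in for
heavier likelihood/Bayesian analyses: for the placement question — *which
clade does the sample join* — distance methods at mitogenome scale give
the same answer, and imported newick trees can be used instead when a
user runs ML elsewhere. Bootstrap support resamples columns with
replacement (default 100 replicates, seeded), maps bipartition
frequencies onto the full-data tree, and negative NJ branch estimates are
clamped to zero with a record of how many. Rooting is on a designated
outgroup's pendant edge. `clade_of()` formalizes visual clade-membership
reading: the smallest support-≥50 clade containing the query supplies the
candidate set, and the patristically nearest reference in it is the
assignment; trees without supports are treated as fully supported.

## Numerical and degenerate-input choices

- Evenness of a zero-coverage reference is 0 by convention (the ratio is
  0/undefined).
- Empty read sets propagate as flagged `no_data` objects, never errors,
  so batch runs degrade gracefully; `run_identify()` returns exit status
  1 for anything short of a concordant verdict.
- JC69/K80 distances refuse saturated pairs (p ≥ 0.75) naming the pair.
- The banded aligner refuses sequences whose alignment would leave the
  band rather than silently truncating.
- All stochastic components (panel, reads, bootstrap) take explicit
  integer seeds and restore the caller's RNG state; identical seeds give
  byte-identical FASTQ and JSON outputs.

## Scale of the shipped checks

The test suite and the acceptance script run the species-assignment
study at 20 replicates × 5,000 reads against a 4-member 16.5 kb panel at
8% divergence (with d5 = 0.2 and 0.5% sequencing error), damage recovery
at 20,000 reads, and consensus at ~15× depth — the scale at which the
statistics stabilize — with the algorithmic oracles (Steiner triplet,
additive matrices, brute-force column tallies) at enumeration scale.
These sizes were chosen so a full run completes in a few minutes on one
CPU.

## Known limitations

- Identification is bounded by the panel: if the sample's species is
  absent, the closest relative wins both mapping lines, which is exactly
  the failure mode the evenness statistic is meant to expose but cannot
  fully rule out. Panels should bracket the plausible candidates.
- Ungapped mapping slightly undercounts reads spanning indels between
  sample and reference; at mitogenome identities this affects a small
  fraction of reads and both lines of evidence equally.
- The anchored MSA inherits the anchor's coordinates; regions deleted in
  the anchor are invisible to downstream statistics.
- The damage model is single-exponential per end; UDG-treated libraries
  with residual CpG damage or overhang-length structure will fit it only
  approximately.
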