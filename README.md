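# paleomito

Species identification from ancient mitochondrial DNA reads.

Morphology often cannot tell closely related canids apart — dhole, wolf
and jackal bones overlap in size and shape, and Pleistocene specimens are
routinely misassigned. `paleomito` implements the genetic alternative for
anyone working with degraded (ancient) DNA from subfossil material:
competitive mapping of short sequencing reads against a panel of
candidate mitochondrial genomes, combined into a three-lines-of-evidence
species call.

For a sample's reads mapped independently against each candidate
reference, the package computes:

1. **normalized read counts** — each reference's post-filter,
   post-deduplication mapped-read count as a percentage of the
   best reference's count;
2. **mapping evenness** — the ratio of mean coverage *C = S/L* to mean
   read depth over covered positions *D = S/B*, which is algebraically
   the breadth fraction *B/L*: near 1 when reads tile a conspecific
   reference uniformly, low when mapping is confined to conserved
   pockets of a divergent reference;
3. **phylogenetic placement** — a consensus mitogenome (depth ≥ 3,
   50% plurality threshold) aligned with the panel and placed in a
   bootstrapped neighbor-joining tree rooted on a designated outgroup.

The verdict is *concordant* only when all available lines name the same
non-outgroup reference. Around this core the package provides a
seeded synthetic generator of ancient-style reads (lognormal fragment
lengths, geometric 5′ C→T / 3′ G→A deamination, sequencing error, PCR
duplicates, contaminants), a compiled seed-and-verify mapper with
circular-genome support and a MAPQ-style uniqueness filter, terminal
damage profiling for authenticity assessment, reference-anchored multiple
alignment with variable/parsimony-informative site counts and pairwise
difference tables, median-joining haplotype networks, and
SAM/FASTA/NEXUS/newick interchange so external aligners and tree
programs can slot in at any stage.

## Worked example

Simulate a 5-member panel of 16.5 kb circular mitogenomes at 8% pairwise
divergence (the dhole–wolf scale; the fifth member is flagged as
outgroup/contaminant control), draw 5,000 damaged reads from the first
reference, and run the full identification:

```r
library(paleomito)

panel <- sim_panel(n_refs = 5, ref_length = 16500, divergence = 0.08,
                   seed = 20)
reads <- sim_reads(panel, n_reads = 5000, source_mix = c(ref01 = 1),
                   d5 = 0.2, d3 = 0.2, seq_error = 0.005,
                   dup_rate = 0.05, contam_fraction = 0.02, seed = 21)
run <- run_identify(reads, panel, sample_id = "bone_A",
                    n_boot = 100, seed = 22)
run
#> Species call for bone_A: concordant (ref01)
#>   lines of evidence: count -> ref01 | evenness -> ref01 | phylogeny -> ref01
#> # A tibble: 5 × 4
#>   ref_id n_mapped normalized_pct evenness
#>   <chr>     <int>          <dbl>    <dbl>
#> 1 ref01      4703          100      1
#> 2 ref02      3102           66.0    0.953
#> 3 ref03      3144           66.9    0.960
#> 4 ref04      3196           68.0    0.968
#> 5 ref05      3128           66.5    0.959
#> exit status: 0
```

The true source attracts ~1.5× more reads than any 8%-divergent
reference and is the only one covered end to end (evenness exactly 1;
the off-target references plateau near 0.95 because only their conserved
segments recruit reads). All three lines agree, so the verdict is
concordant. The damage profile confirms the library "looks ancient" —
fitting the geometric decay model recovers the simulated deamination
parameters:

```r
fit_damage(run$damage)
#> geometric damage fit (5p, nls): d = 0.196, r = 0.530
```

(simulated with d5 = 0.2, decay 0.5). Results are plain tibbles and
objects with `tidy()`/`glance()`/`autoplot()` methods:
`tidy(run$call)` is the evidence table above, `glance(run$call)` a
one-row verdict, `autoplot(run$damage)` the classic terminal-damage
plot. `run_identify(..., out_dir = "report/")` additionally writes
per-reference SAM, coverage and damage TSVs, the consensus FASTA, the
stripped alignment, the rooted newick tree and a `call.json` evidence
summary. A command-line wrapper with the same outputs ships in
`inst/cli/identify.R`.

Downstream diversity tools work on any gap/N-free alignment:
`classify_sites()` (variable / parsimony-informative counts),
`pairwise_diffs()` (within-group mean ± sd difference tables) and
`build_mj_network()` (median-joining haplotype network, with inferred
median nodes flagged).

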