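---
title: "Purging secondary haplotigs with alignment metrics and BUSCO-guided optimisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purging secondary haplotigs with alignment metrics and BUSCO-guided optimisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopurge)
```

## The problem

Long-read assemblers applied to heterozygous diploid samples often emit
*both* haplotypes of a divergent region as separate contigs in the primary
assembly. These redundant "secondary haplotigs" inflate the assembly beyond
the true genome size, turn single-copy genes into apparent duplicates, and
confuse Hi-C scaffolding, which may join the two copies of a locus to each
other. `haplopurge` identifies secondary haplotigs from an all-by-all
pairwise contig alignment (BLAT PSL or minimap2 PAF) and removes them,
choosing how aggressively to purge by optimising a BUSCO-based cost over
the space of alignment-filter thresholds.

## The model

Every aligned contig pair is summarised by four quantities:

* **ID** — nucleotide identity of the alignment,
  $\mathrm{ID} = m / (m + m' + r)$ for $m$ matches, $m'$ mismatches and
  $r$ repeat-masked matches. For PAF input, which carries no separate
  mismatch count, mismatches are taken as
  `block_length - matches`, folding indel and substitution error together.
* **Q** — the fraction of the *query* contig covered by the alignment,
  sensitive to clipped alignments.
* **R** — the fraction of the *reference* (target) contig covered.
* **QR** = Q / R — sensitive to length differences and structural
  variation between the two contigs. QR is neither bounded by 1 nor
  symmetric, so the transform $QR' = e^{-\log_2 QR}$ is used alongside it:
  $QR = 1 \mapsto QR' = 1$, and QR and $1/QR$ map to reciprocal values.

Given thresholds $(ID_T, Q_T, QR_T)$ (and the derived $QR'_T$), a query
contig is **purged** when at least one of its alignments satisfies all
three conditions:

1. $\mathrm{ID} \ge ID_T$;
2. $Q \ge Q_T$;
3. $\min(QR_T, QR'_T) \le QR \le \max(QR_T, QR'_T)$.

The window in condition 3 is treated as inclusive at both ends; "falls
within the range" is ambiguous at the boundary, and inclusivity makes the
degenerate window $QR_T = 1$ non-empty. Purging is single-pass: a purged
contig still serves as the reference of other rows within the same
threshold application, and no iterative re-purging is performed.

Before purging, rows are restricted to plausible haplotig queries:
queries longer than 10 Mb are excluded (contigs that large are very
unlikely to be alternative haplotypes, and they remain available as
references), and a query must not be longer than its reference. For
equal-length reciprocal pairs only the row whose query name sorts
lexicographically later is kept, so exactly one of the two is eligible —
without this rule both copies of a perfect heterozygous pair could purge
each other.

## Scoring candidate assemblies

Each candidate (the retained contig set) is scored from a per-contig BUSCO
table: for each contig, the sets of Complete and Fragmented genes found on
it when BUSCO is run on that contig alone. Across the retained set, a gene
complete on exactly one contig is Single-copy (S), on several Duplicated
(D), never complete but fragmented somewhere Fragmented (F), and otherwise
Missing (M); the four counts always sum to the lineage-set size, which
must be supplied by the user (genes missing from every contig leave no
trace in per-contig tables). Two classification choices deserve note:

* a gene reported *Duplicated* within a single contig is counted as
  complete on that contig — cross-contig duplication is what haplotig
  purging targets, and per-contig tables list complete and fragmented
  genes only;
* a gene fragmented on one retained contig but complete on another counts
  toward S or D, not F — complete evidence dominates.

The candidate's cost is

$$\mathrm{Cost} = \frac{\theta_1 M + \theta_2 D + \theta_3 F}{\theta_4 S},$$

with weights in $[0,1]$ defaulting to $\theta_1 = \theta_2 = \theta_4 = 1$
and $\theta_3 = 0$ (fragmented genes ignored). A candidate with $S = 0$ is
given infinite cost rather than raising an error, so the optimiser can
pass through degenerate threshold regions.

## Hill climbing

`hill_climb()` minimises Cost over $(ID_T, Q_T, QR_T)$ with a randomised
forward-walking agent: each iteration evaluates the current thresholds and
then adds `step_increment * U(0,1)` (independent draws, default increment
`1e-4`) to each threshold. The walk restarts from fresh thresholds drawn
uniformly from $(0, 1]$ when the cost has been unchanged for
`plateau_limit` consecutive iterations (default 50) or any threshold walks
past 1.00. $QR_T$ is capped at 1 like the others: since the acceptance
window is built from $\min$ and $\max$ of $QR_T$ and $QR'_T$, thresholds
above 1 describe the same windows as their reciprocal transform and would
only duplicate search space. Cost is evaluated immediately at each restart
point, before any step is taken from it.

Iteration 0 always evaluates the default thresholds (0.70, 0.70, 0.70), so
the optimised result can never be worse than the default single purge —
users running both modes expect optimisation not to regress. All three
thresholds are stepped jointly each iteration; the plateau length and the
uniform restart distribution are package defaults, chosen once, since only
their order of magnitude matters for escaping flat regions.

The `best_x` lowest-cost candidates are retained in a bounded store
deduplicated by retained contig set. Set equality is only tested between
candidates whose retained sets have equal size (unequal sizes cannot be
equal sets), and the worst stored cost is readable without scanning, so
most pushes into a full store are rejected by one comparison. Cost ties
between distinct sets are kept, ordered by (cost, retained-set size
descending, lexicographic first difference) for full determinism.
Parallelism is expressed as independently seeded runs merged with
`merge_runs()`, which pools stores, re-deduplicates and truncates —
order-independent by construction.

## The synthetic fixture generator

`make_fixture()` builds a toy diploid-like assembly: random primary
contigs (default 8, 2–5 kb) plus planted haplotigs (default 4), each an
exact copy of a contiguous span (default 80%) of a source primary with
substitutions applied at a fixed rate (default 2%). Substitution-only
divergence keeps the alignment analytically exact:
`make_alignment_table()` can therefore emit the haplotig-to-source
alignment rows — with $Q = 1$, $R$ = span fraction and
$\mathrm{ID} = 1 - \mathrm{divergence}$ exactly — without running any
aligner, and serialise them as a valid PSL file to exercise the parser.
Decoy alignments between unrelated primaries (ID 0.30, Q 0.20) exercise
the negative path. `make_busco_catalog()` plants evenly spaced complete
genes on each primary (default 5 per contig out of a 60-gene universe);
haplotigs inherit the genes overlapping their copied span, creating the
duplicated BUSCOs that purging should eliminate. Contig names are randomly
permuted so they encode nothing about which contigs are secondary; truth
lives only in the returned labels.

The defaults describe a *strongly separated* instance — haplotigs near 98%
identity with full-length alignments, decoys far below any plausible
threshold — so perfect precision and recall on the fixture demonstrates
correctness of the machinery, not performance on real data, where
alignment clipping, repeats, segmental duplications and uneven BUSCO
density blur the margin. The generator also does not emulate indels
(an optional extension), coverage variation, or chimeric contigs.

```{r fixture}
spec <- fixture_spec(seed = 42)
fx <- make_fixture(spec)
table <- filter_eligible(make_alignment_table(fx, spec))
catalog <- make_busco_catalog(fx, spec)

cand <- score_candidate(
  candidate_assembly(table, purge_thresholds(0.70, 0.70, 0.70),
                     names(fx$contigs)),
  catalog)
cand
setequal(cand$purged, fx$truth$secondary_names)
```

```{r hillclimb}
res <- hill_climb(table, catalog, names(fx$contigs),
                  hillclimb_config(iterations = 2000, seed = 1))
store_best(res$store)$cost
tail(normalize_costs(res$trace), 3)
```

## Numerical and design notes

* Coordinates are 0-based half-open throughout, the native convention of
  PSL and PAF; strand is ignored, as all metrics are span-length based.
* The PSL identity denominator is `matches + mismatches + rep_matches`
  (indel bases excluded) — the simplest match fraction consistent with
  "percent nucleotide identity"; repeat matches count toward identity.
* Multiple alignment rows between the same contig pair are kept as
  independent rows; the purge rule fires if *any* row passes.
* N50 uses the convention that the cumulative sum of descending-sorted
  lengths must reach *at least* half the total; L50 is that contig's
  1-based rank.
* `Cost` is compared as a real number; ties among distinct candidate sets
  are resolved by the deterministic store ordering above.
* Degenerate inputs: empty alignment tables purge nothing; an empty
  retained set scores `Inf`; a constant cost trace normalises to zeros
  with a warning.

Test and example problem sizes (a dozen contigs, tens of genes, a few
thousand hill-climbing iterations) were chosen so that exhaustive
brute-force oracles — naive purge enumeration, per-gene BUSCO counting, a
full threshold grid — remain feasible companions to every stochastic
result; the algorithms themselves are vectorised and scale to assemblies
with thousands of contigs held in memory.

## Limitations

* Purging is purely alignment-driven; read-coverage evidence (the
  purge_dups / PurgeHaplotigs signal) is not considered.
* Only BUSCO v3-style tab-separated full tables are read.
* Contigs carrying no BUSCO gene influence the cost only indirectly (via
  alignments of contigs that do), so threshold optimisation cannot
  distinguish among candidates differing only in BUSCO-free contigs; the
  store's deterministic tie-break (larger retained set first) then prefers
  keeping them.
* Hill climbing with restarts makes no global guarantee; on rugged cost
  landscapes several seeds should be run and merged.
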