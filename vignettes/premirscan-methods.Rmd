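---
title: "premirscan: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{premirscan: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premirscan)
```

# The problem

The major histocompatibility complex (MHC) is a ~4 Mbp, gene-dense,
hyper-polymorphic region of chromosome 6 in which most disease-associated
variants fall outside protein-coding sequence. One hypothesis for their
function is regulation through microRNAs encoded in the region. Because
miRNA discovery from RNA-seq only sees transcripts expressed in the assayed
tissue, an *ab initio* complement is useful: enumerate every locus of a
haplotype sequence whose transcript could fold into a stable pre-miRNA
hairpin, and intersect the resulting atlas with orthogonal evidence —
conservation across haplotypes, homology to annotated miRNAs, Argonaute
(Ago) CLIP read support, Dicer dependence, and linkage disequilibrium (LD)
with disease-associated SNPs.

`premirscan` implements that pipeline as a reusable, fully tested R
package. Every input it consumes can also be *generated*, with planted
ground truth, by the seeded simulators in the package, so each stage is
testable end to end at desk scale without external downloads.

# The discovery scan

Stage by stage, for each input sequence:

1. **Window enumeration.** Every start offset (stride 1 by default) and
   every window length from 58 to 110 nt, on both strands, each window
   read 5'→3' on its own strand. The defaults correspond to the 5th/95th
   percentiles of annotated human pre-miRNA length; `derive_cutoffs()`
   recomputes them from any catalog.
2. **Prescreen.** A conservative complementarity gate: the Nussinov
   maximum pair count of the window is an upper bound on the pairs of any
   structure, and under the shipped energy model any structure below the
   energy cutoff needs at least `floor(|cutoff| / max|stack|) + 1` pairs
   (every negative term in the model is a stacking term and a structure
   with *p* pairs has at most *p* − 1 of them). Windows below the bound
   are never folded, and disabling the prescreen provably never changes
   the atlas.
3. **Folding and the energy filter.** Each surviving window is folded
   with the reference engine (below); windows with MFE ≥ −20 kcal/mol are
   removed. The boundary is strict by default (`mfe < cutoff`), matching
   the operational reading that −20 itself is removed; a documented flag
   switches to `<=`.
4. **Topology filter.** The MFE structure is loop-decomposed; windows
   whose structure is not a *linear hairpin* — exactly one hairpin loop,
   no multiloop, no bulge — are removed. Internal loops are tolerated by
   default (`reject_internal_loops` tightens this); bulges and
   multi-stem structures are what the filter is defined to exclude.
5. **Triage (optional).** A trainable classifier stage with a thin seam:
   features are documented and fixed-order (`extract_features()`), the
   default model is a logistic regression, and candidates can equally be
   exported to an external classifier. Disabling triage always yields a
   superset of the triage-enabled atlas.
6. **Exon exclusion and merging.** Entries overlapping an annotated exon
   (BED or GFF3 `exon` rows) by at least one base are removed,
   strand-blind, and the remainder is merged (`GenomicRanges::reduce`)
   into disjoint atlas loci annotated with window count and best MFE.

Batched folding makes the stride-1 scan tractable: one cubic dynamic
program per start offset yields the MFE of *every* window length at that
start (the external-loop array of the longest window contains the MFE of
each of its prefixes), so a 2,000-bp scan at full defaults — roughly
200,000 windows — folds in about 4,000 DPs and runs in ~2 minutes on one
CPU. The test suite and the acceptance script use 2,000-bp haplotypes for
this reason; a whole-MHC (4.87 Mbp) stride-1 scan is a cluster-scale run
and out of scope for the packaged tests.

# The reference energy model

The reference engine is a self-contained Zuker-style nearest-neighbor
dynamic program (no pseudoknots, minimum hairpin loop 3, interior loops
capped at 30 unpaired bases). Its model, all in `default_energy_params()`
so a parameter set can be swapped wholesale:

* Turner-style stacking free energies at 37 °C over the six canonical
  pairs (CG, GC, GU, UG, AU, UA), all ≤ 0;
* hairpin, bulge and internal-loop initiation penalties tabulated to size
  30 and extrapolated as `E(m) + 1.1·ln(n/m)` beyond;
* single-base bulges keep the stacking interaction of their flanking
  pairs (the standard nearest-neighbor rule);
* internal-loop asymmetry penalized linearly (0.6 kcal/mol per unpaired
  base of imbalance, capped at 3.0);
* a helix-end penalty of 0.5 kcal/mol for AU/UA/GU/UG closing pairs at
  every non-stack loop boundary and external/multiloop branch;
* an affine multiloop penalty (offset 3.4, 0.4 per branch including the
  closing pair, 0 per unpaired base).

Dangling ends, terminal mismatches and special tetraloop bonuses are
deliberately omitted: the standalone re-scorer `score_structure()` must
reproduce every energy the engine reports from the loop decomposition
alone, and the test suite verifies (a) that the engine's MFE equals
exhaustive enumeration of all nested structures on small sequences, and
(b) that the returned structure re-scores to the reported MFE to 1e-6.
The engine therefore makes no claim of matching any external folder's
energies; an adapter (`engine = "vienna"`) wraps `RNAfold` at tool
defaults (37 °C) for users who want the published folder's numbers, and
the reference engine is used for all tests.

**Tie-breaking.** Among equal-energy structures the traceback resolves
cases in a fixed, documented order — interior extension (smallest 5'
extension first, stacks before loops), then hairpin, then multiloop;
external positions prefer remaining unpaired. This guarantees the
determinism regression tests rely on; it intentionally does not implement
a global "maximum pairs, then lexicographic" refinement, whose extra
bookkeeping buys nothing the tests need.

**Why the topology filter has teeth.** Under this model (as under any
realistic one), composition-matched random 110-mers frequently fold below
−20 kcal/mol, but their MFE structures essentially always contain bulges
or multiloops, because single-base bulges are cheap and asymmetric
defects otherwise cost asymmetry and helix-end penalties. The bulge/
multiloop filter, not the energy cutoff, is what suppresses random
background — mirroring the design logic of the original filter chain.

# Downstream analyses

**Conservation.** Presence of a mature or precursor sequence in a
haplotype is defined as an exact, full-length match on either strand;
`find_exact()` is an exact substring search, which under the
100%-identity, full-query-length criterion is equivalent to a BLAST
search filtered to perfect full-length hits (every such hit *is* an exact
occurrence). Locus-level conservation between two atlases follows the
shortest-sequence containment rule: two loci pair iff the shorter occurs
exactly within the longer.

**Homology.** Semi-global (overlap) Needleman–Wunsch with free terminal
gaps at both ends of both sequences; default scoring +5 match, −4
mismatch, 8 per gap position, all configurable because the published
description names the algorithm but not its parameters. All catalog
entries tied at the maximal score are reported. U and T are one symbol.

**Ago support.** A read supports a miRNA iff it contains the exact,
ungapped mature sequence; support is declared at ≥ 500 reads. "Within all
datasets" is ambiguous between summing and per-dataset thresholds: the
default sums across datasets (matching the tabulation language), and
`per_dataset = TRUE` implements the stricter reading. Matching is
sense-strand by default, as CLIP reads are sense.

**Dicer dependence.** Per sample, ΔCt = Ct(target) − Ct(normalizer);
conditions are compared with a two-sided pooled-variance t-test (df = 2
at the 2v2 design). A target is dependent iff p ≤ 0.05 *and* the silenced
ΔCt mean exceeds the control mean — attenuation in the wrong direction is
never flagged. With two replicates per condition, the design has ~2.5%
realized type-I rate (two-sided test plus direction rule) and essentially
full power at a 3-cycle effect with 0.1-cycle noise; the acceptance tests
verify both by simulation (1,000 and 200 seeded runs).

**Disease LD.** LD blocks are built from user-supplied proxy tables (the
original web service is defunct; the table is the input contract): a
block spans the index SNP and all proxies with r² ≥ 0.9, collapsing to a
1-bp interval when none qualifies. Associations are strand-blind ≥ 1 bp
interval overlaps; summaries deduplicate SNPs by rsid and phenotypes by
case-folded, whitespace-trimmed labels split on `;` (the deduplication
rule is the package's own choice, as none is published). Common-SNP
overlap flags a mature miRNA iff a SNP with MAF ≥ the cutoff lies within
`[start, end)`.

# The simulators

`sim_config()` fixes the synthetic study conditions; they are the
conditions the tests run under, chosen once:

* 2,000-bp haplotypes of i.i.d. background at GC 0.41 (MHC-like); no
  repeat structure is modeled — a documented limitation, so passing tests
  say nothing about repeat-driven false positives in real genomes;
* 5 planted clean hairpins (`arm + loop + revcomp(arm)`, stems 20–28 bp,
  loops 4–8 nt, GC-rich arms) at non-overlapping recorded positions;
* a second haplotype at 2% substitutions and 0.2% indels, with half the
  hairpin loci protected verbatim and the rest guaranteed ≥ 1 stem
  substitution; indels never fall inside hairpin loci so conservation
  truth is exact;
* CLIP read sets whose supporting reads embed the mature sequence at a
  random offset, with decoys verified at generation to contain no planted
  sequence on either strand;
* a 2-replicate qPCR design with a 3-cycle planted effect and 0.1-cycle
  Gaussian noise on every Ct;
* disease SNPs with uniform MAF on (0, 0.5), 1–3 phenotype labels each,
  and proxies whose r² is drawn uniform on (0.6, 1), the truth block
  extent recorded from the drawn values.

Every generator is bit-reproducible under a fixed seed and returns its
truth alongside its output.

**The planted-scan fixture.** The acceptance check for locus recovery
demands an *empty* atlas on the dinucleotide-shuffled background. Because
composition-matched random sequence occasionally contains marginal clean
hairpins below −20 kcal/mol (this is true of any folder, including the
external one), a verified background is part of the fixture's
definition: the packaged fixture seed was chosen at construction time and
its shuffled background verified hairpin-free by exhaustive scan. The
recovery half of the fixture (≥ 4/5 planted loci found) is robust across
seeds.

# Degenerate inputs and numerical choices

* Sequences shorter than the minimum window length scan to an empty
  result with a warning; empty interval sets merge to empty.
* `N` is unpairable in folding, scores 0 against everything in
  alignment, and is preserved by reverse complement.
* Constant qPCR measurements make the t statistic undefined; the target
  is reported with `p = NA` and never flagged dependent.
* Energy comparisons in the engine and its tests use a 1e-9 tolerance;
  energies are sums of 1–2-decimal table values, so this is far below
  the model's resolution.
* Coordinates are 0-based half-open everywhere; BED writers emit
  deterministic (chrom, start, end, name) order.

# Known limitations and non-desk reproductions

The published full-scale counts (thousands of atlas loci per MHC
haplotype, their ~50% cross-haplotype conservation, the recovery of 11 of
12 annotated MHC precursors, and the specific −19.1 kcal/mol exclusion of
one annotated precursor under the external folder) depend on
multi-gigabase haplotype sequences, version-pinned annotation databases
and an external classifier, none of which ship with a desk-scale package.
They are reproducible in principle by pointing `run_pipeline()` at those
inputs with the external folding adapter and classifier seam, and are
documented here as optional full-scale runs rather than packaged tests.
The packaged evidence is property-based: oracle-verified folding,
alignment and interval semantics, and planted-truth recovery on the
synthetic study conditions above.
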