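---
title: "Methods: comparing two closely related bacterial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing two closely related bacterial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`genomepair` implements the comparative analysis that is routinely applied
to a pair of very closely related bacterial chromosomes — for example two
strains of one species isolated decades and oceans apart: reciprocal
best-hit orthology with amino-acid identity, synteny profiling and the
delineation of contiguous regions of gene-content difference, fragment-based
average nucleotide identity (ANI), and a modal codon usage test that asks
whether those regions were acquired horizontally from a donor with a
different codon usage bias. This vignette records the models, the tunable
parameters, and the design choices behind each stage, in the order the
pipeline runs them.

## Genome model and input handling

A `genome` holds a single replicon sequence and an ordered gene table.
Coordinates are stored 0-based half-open throughout the package; the
GenBank and GFF3 readers and writers convert from and to those formats'
1-based inclusive convention at the boundary. This removes a whole class
of off-by-one errors: no internal function ever needs to know the source
format. Gene ordinals (`0..n-1`) are assigned in start-coordinate order
and are the coordinate system for synteny and region calling.

CDS are translated with the bacterial genetic code (translation table 11);
annotated alternative starts (GTG/TTG) are rendered as M, matching how
deposited protein translations are produced. A CDS whose length is not a
multiple of 3 is kept in the gene table but flagged `partial` and excluded
from all protein-level analyses, with a warning; this is how frameshifted
pseudogene fragments in real annotations are handled without discarding
the rest of the genome. Codons containing ambiguity codes are skipped in
codon counting rather than discarding the whole gene. Compound (join)
locations are supported only for the two-segment origin-spanning case a
circular bacterial chromosome actually needs; anything more elaborate is
rejected loudly.

## Orthology: reciprocal best hits under global alignment

Orthologs between two proteomes are approximated by bidirectional best
hits (BBH). Pairs are scored by *global* (end-to-end) Needleman-Wunsch
alignment with affine gaps under BLOSUM62 (gap open 11, extend 1). Global
rather than local alignment is deliberate: in a near-clonal pair the
orthologs are near-full-length, and a per-gene identity over the whole
protein matches how per-pair identities are usually plotted; local
alignment would quote inflated identities for partially matching
fragments.

Amino-acid identity is the fraction of identical columns among alignment
columns *excluding terminal gap runs*. The exclusion matters for
truncated or frameshifted genes: a 60%-length fragment that matches
perfectly should read as 100% identity over the aligned region, with the
length mismatch expressed through coverage instead. A hit is accepted
when its score is positive and at least 50% of both sequences lie inside
the aligned (non-terminal-gap) region; ties on score resolve toward the
lowest counterpart ordinal so results are deterministic.

Scoring all pairs of two ~3,000-protein genomes exhaustively is wasteful,
so candidate pairs are shortlisted by a k-mer screen first. The default
screen is the installed `blastp` binary (itself a k-mer seeded search,
run with permissive settings and used *only* to nominate candidates); a
built-in shared k-mer filter and an exhaustive mode (`prefilter =
"none"`) are also available, and the test suite checks that all routes
give identical best hits on small inputs. Final ranking and acceptance
always use the package's own global alignment, never the screen's scores.

Genes are classified from the two directional best-hit tables: BBH when
each gene is the other's best hit, unidirectional when an accepted best
hit is not reciprocated, unique when no hit passes the thresholds. The
cumulative identity distribution (fraction of BBH pairs at or above 98%,
96%, ... identity) summarises how clonal the pair is.

## Synteny and regions of gene-content difference

BBH anchors ordered along genome A, with their counterpart ordinals on
genome B, form the synteny profile. Runs of strictly decreasing
counterpart ordinals (length >= 3 anchors) are flagged as inversions; runs
displaced from the median collinear offset by more than 20 ordinals are
flagged as translocations. Both defaults are deliberately coarse — the
profile is meant to detect *major* rearrangements, not micro-inversions.

Regions of gene-content difference are usually identified by eye on a
synteny plot; `call_regions()` formalises the call. Each gene is labelled
**different** (unique or unidirectional), **interrupting** (a BBH anchor
that is either below 70% identity or locally out of order relative to the
interpolated collinear trend), or **conserved** (any other BBH). A region
is a maximal interval that starts and ends with different genes, tolerates
embedded interrupting anchors as long as no more than
`max_bbh_interruptions = 3` occur *in a row*, and is terminated by any
conserved anchor. A candidate interval is reported when it contains at
least `min_nonbbh_run = 5` different genes (counted across the tolerated
interruptions — interleaved low-identity anchors do not reset the count)
and at least `min_region_genes = 20` genes in total. The interruption
bound is read as a bound on *consecutive* embedded anchors rather than a
per-region total: real difference regions can contain on the order of ten
scattered low-identity BBHs, and a total bound of 3 would forbid exactly
the regions the caller exists to find, while a run of many consecutive
conserved-order anchors genuinely separates two regions.

Regions are called independently from both genomes and paired through
their flanking anchors; for interval mapping between the genomes the
nearest flanking BBH of *any* class is used (even a low-identity anchor
maps coordinates), while the *reported* bounding anchors are the
innermost flanking conserved (high-identity) anchors, which is how such
boundaries are quoted in practice. Accounting per region (total, unique,
unidirectional, BBH genes per genome, and the fraction of chromosome-wide
unique genes captured) comes straight from the classification.

## Modal codon usage and the shuffled-pool null

Codon usage bias differs among bacterial species, so a chromosomal region
whose bias departs from the rest of the chromosome is a candidate
horizontal acquisition. The statistic used here is *modal* codon usage:
the codon usage frequency set consistent with the largest number of genes
in a collection, which is robust to minority gene classes in a way the
plain average is not.

The estimation procedure is iterative: initialise each synonymous codon
family's frequencies from the pooled usage of all genes; score each gene's
fit to the current frequencies with a multinomial goodness-of-fit
statistic summed over families; retain genes with combined p > 0.1;
re-pool over the retained genes; iterate until the conforming set is
stable (at most 50 iterations, with a `converged` flag). Pearson's X^2 is
used as the per-gene statistic (reference chi-square with df = sum of
family sizes minus the number of observed families): at the small
per-family counts of a single gene it stays much closer to its nominal
reference than the likelihood-ratio G (retention ~0.91 versus ~0.79 at the
nominal 0.90 in calibration simulations), so the conformity threshold
means what it says. Single-codon families (Met, Trp) and stop codons are
excluded everywhere — they carry no synonymous-choice information — and
initiator/terminator codons are dropped from the counts by default for
the same reason.

The distance between two modes is an amino-acid-frequency-weighted total
variation: for each family, half the L1 distance between the two
frequency vectors, averaged with weights given by the mean amino-acid
frequency of the two conforming gene sets (renormalised over the 18
multi-codon families). It is symmetric, bounded in [0, 1], zero exactly
when the family frequencies agree, and scale-free across gene sets of
different sizes. The formula is fixed here as a package design choice —
the modal-usage literature defines the mode but implementations differ in
their distance conventions — so absolute distances should be compared
against this package's own null, not across tools.

Significance comes from a shuffled gene-pool null: pool the two gene
sets, split the pool at random into two disjoint sets of the original
sizes, recompute both modes and their distance, and repeat (10 rounds by
default, mirroring the convention of the original modal-usage software;
the standard deviation from 10 rounds is noisy, and `n_rounds` can be
raised). An observed distance several null standard deviations above the
null mean indicates the two sets do not share a mode. Each round draws
from its own counter-derived RNG substream of the single master seed, so
one integer reproduces the full analysis. `hgt_report()` assembles the
standard comparison set: each region versus its chromosome excluding all
regions, region versus region, and whole chromosome versus whole
chromosome.

## Average nucleotide identity

ANI uses the fragment convention: the query is cut into consecutive
1,020-bp fragments (a short trailing fragment is discarded), each
fragment is located in the other genome by voting on the dominant shared
15-mer diagonal (both strands) and refined by local alignment within the
seeded window, and fragments with >= 30% identity over >= 70% of their
length are retained. ANI is the mean identity of retained fragments,
computed in both directions and averaged. The 1,020/0.3/0.7 defaults are
the documented convention of the standard ANI tools. The seeded-window
approach replaces an exhaustive fragment-against-genome alignment purely
for speed; on constructed inputs (identical copies, counted
substitutions) it reproduces the closed-form identities exactly, which
the test suite asserts.

## The synthetic genome-pair generator

Every stage above is tested against simulated genome pairs with known
truth, generated by `simulate_pair()`. The default configuration
(`default_pair_config()`) encodes the structure of a real
close-strain comparison at desk scale:

* a backbone of 300 ortholog pairs in conserved order (the real pair has
  ~3,000; 300 keeps a full pipeline run in seconds while leaving every
  distribution well populated — scaling `n_backbone_genes` up changes
  size only);
* per-pair amino-acid identity drawn from a right-skewed mixture with 86%
  of its mass at 98–100% and 94% at or above 96%, echoing the reference strain pair's
  identity distribution; substitutions are placed uniformly (never at the
  initiator) with replacements biased toward BLOSUM-positive residues;
* synonymous positions resampled from the backbone codon bias at rate
  0.08 per codon, and intergenic spacers inherited from a shared ancestor
  with 2% per-base divergence, so that nucleotide-level divergence (ANI
  ~97–98%) is realistic for strains of one species;
* two planted regions of 53 and 48 genes whose codons are drawn from
  donor biases at total-variation 0.4 from the backbone (two different
  donors, so the regions also differ from each other), with unique-gene
  fractions on both genomes matching the observed regions (29/53 and
  32/48 unique on one side; 25 and 56 unique genes on the other);
* gene lengths ~N(200, 60) codons (minimum 60), ~30% minus-strand genes
  (strand conserved within an ortholog pair), AT-rich wobble preference
  (third-position A/T weighted 3:1) as the backbone bias.

The generator's GC target is set to the analytic expectation of coding GC
under the default amino-acid composition and codon bias (~41%), and
intergenic sequence is sampled at that target, so realized GC is coherent
by construction. Planted blocks are laid out deterministically: unique
genes anchor both ends and homologs are interleaved with no run longer
than two, so that region boundaries are marked by unique genes and the
caller's interruption tolerance is exercised without being overwhelmed.
The donor bias construction moves each family's probability mass toward
its least-preferred codon by exactly the requested total variation, so
"donor divergence" is a single interpretable knob.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: insertions and deletions within genes (identity
targets are realized by substitutions only), rearrangements beyond the
toy inversions used in synteny tests, mobile-element sequence structure,
operon organisation, annotation error (mis-called starts, missed genes),
and compositional heterogeneity of the backbone itself (real chromosomes
have highly expressed genes with their own bias). Real-data runs should
therefore lean on the reported nulls and tolerances, not on the exact
point values the simulator reproduces.

## Numerical choices and degenerate inputs

* Ties in best-hit scoring resolve to the lowest counterpart ordinal.
* `compute_mode()` on a single gene returns that gene's own family
  frequencies (the trivial fixed point); an empty conforming set retains
  the single best-fitting gene rather than dying.
* Codon families with zero observed codons among retained genes yield
  `NA` frequencies and are skipped in distances.
* `mode_distance()` refuses modes defined over different family sets.
* Region calling returns an empty (typed) tibble for collinear genomes;
  downstream accounting and reporting handle zero regions.
* `shuffled_null()` restores the caller's RNG state; the same seed gives
  bit-identical rounds.
* All derived seeds stay below 2^31.

## Problem sizes used by the test and acceptance suites

The default suites simulate pairs of 300 backbone genes plus two planted
regions (~400 genes, ~300 kb per genome), run 20-seed recovery and
calibration studies at that scale, and use 10 shuffling rounds per null.
These sizes were chosen so the full distributional structure (identity
mixture, donor bias, null spread) is visible while a complete run stays
comfortable on a single CPU; they are stated here so that anyone scaling
the simulations up knows the defaults were a choice of scale, not of
structure.

## Known limitations

BBH orthology does not resolve paralog families; a duplicated gene can
displace the true ortholog. The region caller's parameters were chosen to
reproduce two large regions on the motivating strain pair while
suppressing singleton indels; pairs with very different divergence
profiles may need `min_nonbbh_run`/`min_region_genes` retuned. The modal
codon usage distance is this package's reconstruction of a statistic whose
existing implementations do not state their formula; compare observed
distances with the package's own shuffled null rather than with numbers
produced by other software. ANI's seeded-window search assumes the best
local match lies on the dominant seed diagonal; for genomes with heavy
repeat structure an exhaustive fragment search would be safer.
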