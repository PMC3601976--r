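---
title: "Methods: detecting and characterizing horizontally transferred genes"
author: "hgtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing horizontally transferred genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hgtrace` packages the computational chain used to detect a
host-to-parasite horizontal gene transfer (HGT) in a plant
transcriptome and to establish that the transferred gene is functional:
a taxon-aware homology screen, phylogenetic confirmation and dating,
codon-level selection analysis, gene-structure and cysteine-scaffold
validation, and stage-wise expression profiling. This vignette explains
the models behind each stage, the parameters that matter, what the
synthetic benchmark does and does not emulate, and the numerical
conventions the implementation fixes.

## The screening cascade

The screen asks, for every assembled parasite contig, whether its best
translated-homology matches look host-derived rather than vertically
inherited. Hits are produced by a translated search: both query and
subject are translated in all six frames, and frame pairs are scored by
affine-gap local alignment (BLOSUM62; gap of length $L$ costs
$11 + L$). Raw scores $S$ become bit scores
$(\lambda S - \ln K)/\ln 2$ with the standard gapped-BLOSUM62
Karlin–Altschul parameters $\lambda = 0.267$, $K = 0.041$, and e-values
$m \, n \, 2^{-\mathrm{bit}}$ with $m$ the query frame length and $n$
the database length in amino acids. These e-values rank hits; they are
not calibrated significance levels, and the default cutoff ($10^{-10}$)
mirrors common screening practice.

For speed the default engine aligns only frame pairs sharing at least
two exact 5-mer amino-acid words (`seed_k = 5`, `seed_min = 2`); this
is a deterministic seed-and-extend filter in the spirit of all seeded
search tools, and `seed_k = 0` restores the exhaustive 36-frame-pair
behavior. One consequence of score-maximal ranking worth knowing: a
query identical to a subject self-matches in *every* frame pair at
100 % identity, and a frameshifted pair can out-score frame +1 on
residue composition, so the frame of a top self-hit is not guaranteed
to be +1.

The cascade itself applies four rules, each with a fixed convention:

1. the top hit (bit score, then e-value, then subject id) must come
   from a donor-candidate species;
2. the contig must be **strictly longer than 500 nt**, the top *donor*
   hit's identity must lie in the **inclusive** range [60, 95] %, and
   that hit's query span (`qend − qstart + 1`) must cover at least half
   the contig. The identity filter is applied to the top donor hit
   only, and the span rule uses the single best hit's span rather than
   summed segments — the conservative, well-defined reading;
3. no close-relative species may occur among the 10 best hits;
4. over *all* hits, either no close-relative hit exists, or the best
   donor bit score exceeds the best close-relative bit score by a
   ratio (default 1.2). "Much better donor than close relative" is not
   a quantity the screening literature pins down; we quantify it as a
   bit-score ratio because bit scores are length-normalized and
   monotone in e-value, and every contig rescued through this clause is
   flagged in the report.

The funnel reports the input count, the combined stage-1+2 survivor
count (the conventional "initial screening" number), stage-3 survivors
and final candidates; it is non-increasing by construction, and the
cascade is a pure function of its inputs, so permuting contigs permutes
but never changes per-contig outcomes. Contig ids must be unique within
a collection — duplicated ids across libraries are rejected rather than
reconciled.

## The synthetic benchmark

The generator plants a transfer with full truth tables so every stage
is testable offline. Its defaults *are* the study conditions and were
chosen once:

* **Clades and ages.** A donor (host) clade of 6 taxa with crown age
  39 My (the calibration node), a parasite clade of 4 taxa with crown
  age 11 My, a transfer into one donor lineage 16 My ago, and a gene
  duplication 5 My ago in the subclade containing the focal parasite.
  Species trees are pure-birth in topology (random joins) with node
  ages uniform below the crown — depth is controlled exactly by the
  stated crown age, which is what the downstream checks need.
* **Rates.** 0.01 substitutions/site/My, so the parasite–donor
  divergence after a 16-My-old transfer lands mid-window (~85–90 % amino
  acid identity) for the identity filter, while close relatives of
  background families sit above the 95 % bound or simply out-rank the
  donors. κ = 2 and mildly AT-rich base frequencies.
* **Coding constraint.** Codon evolution is MG94-style: rate 0 for
  multi-nucleotide codon changes, otherwise
  $\pi_{\mathrm{target}} \kappa^{\mathrm{ts}} \omega^{\mathrm{nonsyn}}$,
  with site-wise ω classes {0.05, 0.35} at equal proportion. The six
  scaffold cysteines evolve under ω = 0, and cysteine is excluded from
  the codon state space elsewhere — a hard structural-constraint model
  that keeps the planted scaffold unambiguous. Transition matrices are
  exact matrix exponentials (spectral decomposition of the reversible
  rate matrix), not Gillespie simulation.
* **Gene structure.** One ancestral intron (GT..AG pinned, interior
  evolving at the nucleotide rate) inserted at a homologous coding
  position in every copy, mirroring transfer of a genomic segment
  rather than a cDNA.
* **Expression.** Eight stages with target RPKM spanning a 1000-fold
  range, minimum at the haustorial attachment stage (stage 3) and
  maximum in reproductive tissue (stage 6.2). Reads are error-free
  exact substrings from either strand; per-stage counts are multinomial
  with weights RPKM × length.

What the benchmark does **not** emulate: assembly artifacts and
chimeras, contamination by host RNA, indels and alignment error,
sequencing error and quality scores, rate variation among lineages, and
databases with thousands of species. Passing tests on this benchmark
therefore demonstrates correctness of the analysis chain under its
stated model, not robustness to dirty assemblies.

## Phylogenetic confirmation and dating

Tree estimation is neighbor joining on Jukes–Cantor distances
(pairwise deletion of gap/N columns; pairs with mismatch proportion
≥ 3/4 are flagged saturated and refuse a distance). A full
maximum-likelihood topology search is deliberately out of scope;
likelihood enters through per-site GTR log-likelihoods computed by
Felsenstein pruning (with per-node rescaling; optional 4-category
discrete gamma behind `gamma_categories`), evaluated on supplied or
NJ topologies whose branch lengths are optimized by `phangorn`
(`optimize_branch_lengths`).

Topology tests use RELL resampling: sites are resampled with
replacement without re-optimizing branch lengths, the KH test compares
each topology against the maximum-likelihood one with a two-sided,
centered bootstrap difference, and the SH test centers each topology's
replicates and compares against per-replicate maxima. Sites are first
put into a canonical order (lexicographic by their per-topology
log-likelihood columns), which makes the p-values exactly invariant to
the input site order. The "vertical inheritance" alternative topology
re-attaches the parasite clade next to the basal donor clade — the
closest realizable arrangement to "outside the sampled donor clade",
and always distinct from the nested placement.

Dating is strict-clock mean-path-length (MPL): each node's depth is the
mean root-to-tip path through it, a single rate is fixed by one
calibrated node (donor crown = 39 My; the calibration's published
uncertainty of ±2.4 My is reported but unused, as a point calibration),
and ages are depth/rate. Two conventions matter in practice. First,
rooting: `root_on_outgroup()` roots on the basal donor clade and
balances the two root-edge lengths so the mean depths of the two sides
agree — rooting at the outgroup attachment node (the ape default) or on
a single mid-clade tip visibly distorts MPL depths. Second, ages are
clamped so children are never older than parents, with a warning, and a
clock diagnostic (coefficient of variation of root-to-tip depths) is
always reported. On clock-like data generated under the nucleotide
model the planted 16-My transfer is recovered within a few percent at
10 kb (the acceptance suite checks 5 %); on the codon-model fixture the
same estimator *over*-estimates ages by roughly a third, because
across-site rate heterogeneity makes JC distances compress deep donor
divergences relative to shallow parasite ones. The pipeline reports
those fixture ages as-is — an honest illustration of why the original
analysis used model-based dating.

## Selection analysis

Pairwise dN/dS is Nei–Gojobori (1986) counting with two fixed
conventions: mutations to stop codons are excluded from the site
denominators, and codons differing at 2–3 positions are averaged over
all minimal mutational pathways that avoid stops (codon pairs whose
every pathway crosses a stop are skipped with a warning). Proportions
are corrected with the Jukes–Cantor formula
$d = -\tfrac34 \ln(1 - \tfrac43 p)$. NG86 counting carries the textbook
transition bias when κ > 1, so estimator-consistency checks run under a
κ = 1 generator; at κ = 2 the bias is a
few percent at moderate divergence — adequate for the qualitative
constraint claims this analysis makes, which is why a closed-form
counting method replaces ML codon-model fitting here.

Per-branch counts use Fitch/Sankoff parsimony on nucleotides
(position-wise), with *all* equally parsimonious reconstructions (up to
a cap of 256 per column) enumerated and averaged, and the implied codon
changes classified through the same pathway-averaged tables. A branch
change whose reconstructed endpoint is a stop codon counts its
differing positions as nonsynonymous. Branch counts pooled by lineage
give per-pool substitution densities dN = Nd/N-sites and
dS = Sd/S-sites; parsimony counts are event counts, not proportions of
differing sites, so no multiple-hit correction is applied to pools (the
per-pair NG86 path keeps it). The headline "synonymous outnumber
nonsynonymous" statistic is the opportunity-corrected ratio dS:dN =
(Sd/S)/(Nd/N), which equals 1/ω up to parsimony bias; the raw count
ratio Sd:Nd would be confounded by the ~3:1 excess of nonsynonymous
sites. Lineage pools are user-defined; the pipeline's default partition
(parasite / donor / backbone, by descendant tips) is one natural
choice, not the only one.

The per-site constraint scan compares each codon column's observed
parsimony nonsynonymous changes with an opportunity-scaled expectation
(tree-wide substitution intensity × the column's N-sites) and scores
$\ln(\mathrm{expected}_N / (\mathrm{observed}_N + 0.5))$; the
pseudocount keeps scores finite, and columns whose consensus amino acid
is cysteine are flagged. This is our own statistic, built to rank
constrained columns — it does not reproduce empirical-Bayes Bayes
factors, which are reported context from the original analyses, not a
target.

## Gene structure and the KNOTTIN scaffold

Intron inference assumes the single-intron gene model (the albumin-1
case): it scans all decompositions genomic = prefix + intron + suffix
with prefix + suffix = CDS (up to `max_mismatch` exonic mismatches,
default 0), prefers a solution whose intron starts GT and ends AG, then
the longest prefix. Shift-ambiguous cases — where moving the boundary
one base keeps the decomposition valid — are resolved toward the
canonical splice sites. Coordinates are 0-based half-open internally
and 1-based inclusive in GFF3 output, with intron phase recorded.
Cross-species conservation maps each intron's insertion point through a
CDS alignment (same column + same phase = same start) and measures the
shared 5′ prefix of the intron sequences.

Protein identity/similarity is computed over ungapped columns only,
with similarity = identity + positive BLOSUM62 pairs. The matrix behind
"conservative substitution" is a stated choice — published similarity
figures computed with another matrix need not be matched exactly.

The cysteine-scaffold score is an original rule-based surrogate for
KNOTTIN classifiers whose internals are unpublished. A profile
(expected cysteine count 6; per-loop length windows; C-terminal rule)
is derived from a packaged alignment of **synthetic** albumin-1-like
mature chains (`inst/extdata/albumin1_knottin_synthetic.fasta` — real
legume albumin-1 sequences are not bundled). Subscores: exact cysteine
count (10), each of the five inter-cysteine loop lengths inside its
window (3 each), no unprofiled C-terminal cysteine (2); the default
threshold 27 demands the count, the C-terminal rule and *all five*
loops, which the packaged fixtures meet exactly while ~99 % of
composition-preserving shuffles fail. The score's numeric scale is not
comparable to external tools' scales; only pass/fail and relative
ranking are meaningful. The score is invariant to non-cysteine
substitutions that keep loop lengths.

## Expression

RPKM is `count / (length/1000) / (library/10⁶)` with the library size
taken as the **total mapped reads per library** (the Methods-style
definition; the per-library denominator is logged in the report
header). The naive mapper counts a read for a gene if it matches
either strand with at most `max_mismatch` mismatches; multi-gene ties
are discarded as ambiguous rather than fractionally assigned — the
simplest defensible rule, and the ambiguous count is reported.
Fold-change recovery under multinomial sampling carries a deterministic
library-composition distortion (the per-stage weight totals differ when
the focal genes are a non-trivial share of the library); the acceptance
check bounds the recovered 1000-fold contrast by binomial error plus
that distortion term. Problem sizes throughout the test and acceptance
suites — a 52-contig screen, 10 kb dating alignments, 10,000-codon ω
recovery, 200-dataset KH calibration — are the package's chosen
desk-scale study conditions.

## Repository shape

The package exposes every stage as ordinary functions; the numbered
scripts under `analysis/` are thin narrative drivers over
`run_pipeline()`, which is also the programmatic orchestrator
(`simulate | screen | phylo | selection | structure | expression`).
There is deliberately no shell wrapper beyond those scripts: the
artifact is an analysis, and its interface is the package plus the
drivers. All randomness descends from one master seed through named
substreams (`substream_seed`), so identical seeds give byte-identical
reports while changing one stage never perturbs another.

## Known limitations

* The screen's sensitivity under assembly noise, chimerism or host
  contamination is untested by design (the generator does not model
  them).
* NJ + RELL on fixed topologies does not search tree space; a
  wrong-but-unconsidered topology is invisible to the KH/SH tests.
* MPL dating assumes a strict clock and is biased under across-site
  rate heterogeneity (quantified above on the codon fixture).
* Parsimony counts are lower bounds on substitution numbers and
  increasingly biased on long branches; pooled ω values inherit that
  bias.
* The scaffold scorer validates one architecture (six cysteines, five
  profiled loops) and is not a general disulfide-topology predictor.
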