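---
title: "Codon site models with transition bias and pretermination codons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon site models with transition bias and pretermination codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The dN/dS ratio measures selection on protein-coding genes: the number of
non-synonymous changes per non-synonymous site (dN) against the number of
synonymous changes per synonymous site (dS). How many "sites" a codon
contributes is a modelling choice. The classic Nei–Gojobori-style count
treats all nine single-base changes of a codon as equally likely, so each
codon's synonymous site value is the fraction of its nine single-base
neighbors that are synonymous, times three.

Two biological facts argue against equal rates. First, transitions (A<->G,
C<->T) occur more often than transversions — in *E. coli* roughly four
times more often. Synonymous changes in two-fold degenerate (TFD) codons
are reachable *only* by a third-position transition, while four-fold
degenerate (FFD) codons accept any third-position change, so equal-rate
counting systematically mis-weights TFD codons. Second, 18 of the 61 sense
codons sit one substitution away from a stop codon ("pretermination"
codons, 23 such nonsense substitutions in total). A nonsense change does
not merely swap one amino acid: it truncates everything downstream, is
effectively lethal in an intact gene, and should not be counted as an
ordinary non-synonymous opportunity.

`codonsites` implements both site models, the pairwise dN/dS built on them,
an observed/expected polymorphism statistic (fS) for multi-strain
alignments, and a codon substitution simulator used to validate the
method's neutral-limit behaviour.

## The site models

For a sense codon, classify its nine single-base neighbors into synonymous
transitions and transversions (`Sti`, `Stv`) and non-synonymous ones
(`Nti`, `Ntv`), with `Nti'`, `Ntv'` the subsets that create stop codons.
Every codon has exactly 3 transition and 6 transversion neighbors.

Equal-rate ("old") model:

$$S = \frac{S_{ti} + S_{tv}}{3}, \qquad NS = \frac{N_{ti} + N_{tv}}{3}$$

Modified model, with transition:transversion rate ratio $\kappa$ and
nonsense changes removed:

$$S = \frac{\kappa S_{ti} + S_{tv}}{\kappa + 2}, \qquad
NS' = \frac{\kappa (N_{ti} - N_{ti}') + (N_{tv} - N_{tv}')}{\kappa + 2}$$

The denominator $\kappa + 2$ normalises one codon position's three options
(one transition at weight $\kappa$, two transversions at weight 1), so site
values stay on the familiar 0–3 scale. At $\kappa = 1$ and away from
pretermination codons the modified model collapses onto the old one. Under
the old model $S + NS = 3$ exactly; under the modified model the deficit
from 3 is exactly the removed nonsense weight
$(\kappa N_{ti}' + N_{tv}')/(\kappa+2)$. Summed over the 61 sense codons at
$\kappa = 4$ the synonymous total is $(4 \cdot 62 + 72)/6 = 53.333$.

Worked examples: CTA/CTG (Leu) have two synonymous transitions and two
synonymous transversions, so S rises from 1.333 (old) to
$(4\cdot2+2)/6 = 1.667$; ATA (Ile) has only synonymous transversions, so S
falls from 0.667 to 0.333. TGG (Trp) has no synonymous neighbors and two of
its three transitions create stops, so NS falls from 3.000 to
$(4\cdot1+6)/6 = 1.667$ while ATG (Met) stays at 3.000.

One cell of the published $\kappa = 4$ reference table disagrees with the
formula: GGA is itself a pretermination codon (GGA -> TGA by a
first-position transversion), giving $NS' = (4\cdot2+3)/6 = 1.833$ rather
than the printed 2.000. The package computes the formula value; the test
suite documents the discrepancy explicitly.

### Numerical choices

All site values are ratios of small integers over 3 or $\kappa+2$; they are
computed as integer numerators divided once in double precision, which is
exact to below 1 ulp, so regenerating the reference tables is bit-stable.
Displayed values are rounded half-away-from-zero to 3 decimals
(`round3()`: 7/6 renders as 1.167); totals are computed from unrounded
values. `kappa` may be any positive real.

## Pairwise dN/dS

`dnds_pair()` compares two equal-length, codon-aligned CDS positionally.
Only codon pairs differing at exactly one position are classified
(synonymous vs non-synonymous by translation); pairs differing at two or
three positions are excluded and reported (`n_multi`), not pathway-averaged
— the method is deliberately a simple single-substitution count, and the
multi-hit count lets users judge the information loss. Pairs involving a
stop codon or ambiguity are excluded. Sites are averaged over the two
sequences (standard practice for pairwise counting methods; `sites =
"first"` restricts to the first sequence). Then
$pS = S_d/S_{sites}$, $pN = N_d/N_{sites}$ and $dN/dS = pN/pS$; a pair with
no synonymous differences yields an explicit `undefined` flag rather than a
silent zero. No multiple-hit distance correction is applied by default;
`jc_correction = TRUE` applies the Jukes–Cantor transform
$-\tfrac34 \log(1 - \tfrac43 p)$ to both proportions first. Terminal stop
codons are stripped; internal stops are an error by default because inputs
are expected to be intact CDS (a skip flag exists for curated exceptions).
The initiation codon is included in site sums — it contributes sites like
any other codon under both models.

`compare_dnds_methods()` scores each gene pair under both models and
reports the percent increase of the modified over the old ratio, together
with two composition covariates pooled over both sequences: the TFD:FFD
codon-count ratio and the pretermination-codon fraction, plus Pearson
correlations (via `stats::cor.test`) of the percent increase with each.
Because the difference counts cancel in the ratio of ratios, the percent
increase is a deterministic function of the sequences' codon composition —
which is exactly why it correlates with the TFD:FFD ratio.

## The fS statistic

For a multi-strain codon alignment, `extract_snps()` records one SNP per
(column, distinct non-reference allele), classified against the reference
codon; `allele_count` records how many strains carry it. Aggregating by
reference codon identity, with `s9` the codon's number of synonymous
single-base neighbors (out of 9):

$$S_e = \frac{s_9}{9}(S_o + NS_o), \qquad f_S = \frac{S_o}{S_e}$$

fS is the observed synonymous polymorphism relative to the equal-rate
expectation. ATG and TGG ($s_9 = 0$) have no defined fS, leaving the 59
comparable codons. Under neutral evolution with transition bias $\kappa$,
fS tends to $3\kappa/(\kappa+2)$ for TFD codons (= 2 at $\kappa = 4$) and
to 1 for FFD codons; split-box codons of the six-fold amino acids behave
like TFDs and family-box codons like FFDs. `fs_class_comparison()`
summarises fS per degeneracy class and applies a two-sided Wilcoxon
rank-sum (Mann–Whitney U) test, by default with the tie-corrected normal
approximation (`exact = TRUE` is available for very small classes).

Counting unit: a polymorphism is a distinct allele per column by default,
which is invariant to how many strains happen to carry it; `count =
"strains"` weights by carrier count instead. Columns whose *reference*
codon contains a gap/ambiguity (or is a stop) are skipped entirely; a
gap in a non-reference strain discards only that strain's observation.

## The simulator

`evolve_sequence()` applies a fixed number of *accepted* single-base
substitution events to a stop-free CDS. Each event picks a codon uniformly,
draws one of its nine neighbors with weights $\kappa$ (transition) : 1
(transversion), and accepts it with probability 1 if synonymous, $\omega$
if missense, 0 if nonsense (rejected events are redrawn, codon and all).
This event-count parameterisation keeps calibration tests exact-n and fast;
there is no site-rate heterogeneity, indel process or phylogenetic
structure — `simulate_alignment()` produces a star-shaped panel of
independent descendants of one reference, which is what the fS and
kappa-recovery analyses assume. Passing tests on these data therefore
validate the estimators' internal consistency under their own model, not
robustness to recombination, shared ancestry, selection heterogeneity or
codon-usage bias in real panels.

Defaults are chosen to emulate a bacterial core-gene strain panel: kappa =
4 (the *E. coli* transition:transversion estimate), neutral synonymous
evolution ($\omega = 1$), nonsense changes rejected (they are effectively
lethal in intact genes), and a substitution load of 2% of codons per strain
when not specified — the order of per-gene SNP density in enterobacterial
core-gene panels.

`estimate_kappa()` inverts the process: at third positions of four-fold and
family-box codons every change is synonymous and each site offers 1
transition vs 2 transversions, so the neutral synonymous Ti:Tv count ratio
is $\kappa:2$ and $\hat\kappa = 2\,\mathrm{Ti}/\mathrm{Tv}$. It defaults to
strain-weighted counting, which stays consistent when the same substitution
recurs in several strains.

## Calibration checks and problem sizes

The test suite validates, among others (sizes chosen to keep the full run
around ten seconds while leaving comfortable Monte-Carlo margins):

- brute-force oracle agreement of all 61 substitution profiles, and the
  global counts: 549 single-base changes, 183 transitions, 62 + 72
  synonymous Ti + Tv, 23 nonsense changes (5 Ti, 18 Tv) in 18
  pretermination codons;
- cell-by-cell reproduction of both published site tables (with the GGA
  erratum noted above);
- neutral fS calibration on a 10,000-codon, 100-strain, 20,000-event
  alignment: fourfold mean within [0.95, 1.05] and twofold/fourfold ratio
  within [1.8, 2.2] (the asymptotic ratio is slightly above 2 because
  nonsense rejection also trims the non-synonymous opportunity of
  pretermination TFD codons);
- neutral dN/dS calibration: 50 independent 1,000-codon pairs with 100
  substitutions per lineage, pooled modified-method ratio within
  [0.9, 1.1], with exact a/b symmetry;
- kappa recovery within ±20% at kappa = 1, 2, 4 from panels with >= 500
  informative SNPs;
- the directional property that the modified method raises dN/dS on
  TFD-rich genes and that the percent increase correlates positively with
  the TFD:FFD ratio (under purifying selection, $\omega = 0.25$).

## Known limitations

- Single-substitution counting discards multi-hit codons; at high
  divergence this loses information and the reported `n_multi` should be
  inspected. The optional Jukes–Cantor flag corrects proportions, not the
  discarded codons.
- The site models weight mutational opportunity only; codon-frequency or
  amino-acid-exchangeability weighting and maximum-likelihood codon models
  are out of scope.
- Degeneracy classes and the fS neutral limits assume the standard genetic
  code; alternative code tables can be loaded (any NCBI translation table
  id, or a TSV like `inst/extdata/standard_genetic_code.tsv`), and all
  counting machinery follows the loaded table, but the published reference
  values apply to the standard code only.
- The distinct-allele SNP count saturates slightly when the same allele
  recurs across many strains; at the default simulation load the effect on
  class-mean fS is within the stated tolerance bands, and strain-weighted
  counting is available where an unbiased event count matters (as in
  `estimate_kappa()`).
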