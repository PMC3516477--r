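---
title: "Models and methods behind silencerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind silencerscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silencerscan)
library(dplyr)
```

silencerscan asks a comparative-genomics question about silencer
architecture in budding yeast: Rap1 and Abf1 binding sites are common
individually, silencers contain both within tens of base pairs, so how
often does that two-factor arrangement recur in euchromatic intergenic
regions ("proto-silencers"), and do such sites show any conservation
deficit that would indicate selection against them? This vignette is the
package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic calibration does and does not
establish.

## The PWM score model

A motif of length $L$ is a probability matrix $p_{i}(b)$ over bases
$b \in \{A,C,G,T\}$ at positions $i = 1 \dots L$, built from counts with
a background-proportional pseudocount:

$$p_i(b) = \frac{c_i(b) + \kappa\, q(b)}{\sum_{b'} c_i(b') + \kappa},$$

where $q$ is the background model and $\kappa$ (`pseudocount_total`,
default 1 per column, the PATSER-family convention) is shared across
bases in proportion to $q$. A window $w$ scores
$S(w) = \sum_i \ln\left(p_i(w_i)/q(w_i)\right)$ (natural log
internally; bits appear only in `information_content()`, whose
per-position value is $2 + \sum_b p_i(b)\log_2 p_i(b)$).

The background defaults deserve a note: `gc_background(0.38)` encodes
yeast-like intergenic composition, `estimate_background()` estimates it
from the scanned sequences, and uniform 0.25 is the neutral fallback.
Log-odds, and therefore every p-value downstream, are relative to this
choice.

## Exact p-values by dynamic programming

`exact_score_distribution()` computes the distribution of $S$ for a
random background word exactly, up to discretisation: each column's four
scores are rounded to the nearest multiple of a granularity $g$ and the
per-column distributions are convolved. The default
$g = \big(\sum_i (\max_b \ell_i(b) - \min_b \ell_i(b))\big)/10{,}000$
divides the total score range into $10^4$ bins, so the accumulated
rounding error is at most $Lg/2$ — orders of magnitude below the spacing
of word scores for any realistic motif. The unit tests verify the tail
against exhaustive enumeration of all $4^L$ words for $L \le 8$ inside a
$\pm (L/2+1)g$ bracket.

`pwm_pvalue()` reads $P(S \ge s)$ with floor-to-bin lookup;
`threshold_for_pvalue()` returns the smallest representable score whose
p-value is *strictly* below $\alpha$, mirroring a "p < α" match rule,
and returns `Inf` when even the maximal word's tail is $\ge \alpha$.
That sentinel matters in practice: the minimum attainable p-value of a
motif is the background probability of its best word, which for a 13-bp
matrix is $\ge 4^{-13} \approx 1.5\times10^{-8}$ under a uniform
background. A $10^{-9}$ scanning threshold — kept as the
`analysis_config()` default because it is the canonical choice for the
long genome-scale matrices this analysis descends from — is therefore
unattainable for the 13-bp Rap1 consensus, and the synthetic
calibrations in this package scan at $10^{-6}$, the strictest decade a
13-mer supports (its exact-consensus tail is $\sim 2\times10^{-8}$).

One boundary case was genuinely open: whether the threshold at exactly
$\alpha = P(\text{max word})$ should be the maximal score or the
unattainable sentinel. We follow strictness throughout — the p-value at
the maximal score equals $P(\text{max word})$, which is not $< \alpha$,
so the sentinel is returned; anything else would let a match through
whose reported p-value violates the match rule.

## Scanning conventions

`scan_sequence()` scores every window on both strands and keeps windows
with $p < \alpha$. Coordinates are 1-based inclusive; a match's anchor
is the leftmost base on the forward strand regardless of strand, which
matches the single-coordinate convention of published site tables and is
reproducible (whether those published coordinates denote starts, centres
or ends is not documented — users joining external site maps should be
aware the anchor here is the leftmost base). Windows containing `N` are
skipped: no defensible score exists for an ambiguous base. Same-position
matches on both strands are both reported; deduplication is always an
explicit downstream step. The scanner accumulates column contributions
in position order with plain double additions, so its scores are
bit-identical to `score_word()` on the same window — the property the
oracle-equivalence tests assert.

BED input/output is 0-based half-open and conversion happens only at
the I/O boundary (`read_regions()`, `write_matches_bed()`); everything
internal is 1-based inclusive.

## Proto-silencers, conservation, and the χ² comparison

`find_proto_silencers()` emits *every* (Rap1, Abf1) pair sharing a
region with $|\Delta\text{position}| \le$ `cooccurrence_window`
(default 50 bp, boundary inclusive — the packaged 25-locus coordinate
table has a maximum distance of 49 under exactly this rule). No greedy
one-to-one matching: a region with clustered sites yields several pairs,
and the pairing is symmetric in the two factors.

Orthologous regions are resolved by reciprocal best hits
(`rbh_orthology()`): a gene pair qualifies only if each member is the
other's *unique* top-scoring cross-species hit (ties resolve nothing),
and a region maps only if both flanking genes are RBHs whose partners
flank a single region in the target species, in either orientation.
`call_conservation()` then declares a site present in a species when the
orthologous region contains any match at $p < \alpha$, anywhere, on
either strand. Presence is deliberately region-level — orthologous
intergenic regions are short, and demanding positional agreement would
require whole-genome alignment, which is out of scope. A site is
conserved when present in at least `min_species_conserved` (default 3)
of the 5 species; the reference species counts by default
(`count_reference`), exposed as a toggle because the inclusive reading
is ambiguous in the field's usage.

`compare_conservation()` builds the 2×2 table (conserved / not) ×
(proto-silencer / genome-wide), removing proto-silencer sites from the
genome-wide cells so the classes are disjoint, and applies the
closed-form Pearson χ² (`chi_square_2x2()`), without Yates correction by
default; the correction is available, and for very small tables
`fisher.test` on `$table` is the natural alternative. The type-I error
of the full comparison is verified by simulation (1000 null replicates,
equal conservation rates, rejection rate within [0.03, 0.07] at
α = 0.05).

`filter_tf_sets()` applies the ChIP filter exactly as stated: strict
$p <$ `chip_p_max` (0.05), at least `chip_min_regions` (60, inclusive)
distinct regions. `motif_frequency()` is
$n_{\text{matches}} / \sum \text{lengths} \times 10{,}000$.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws ancestral intergenic regions i.i.d. from a
GC-parameterised background (default GC 0.38; lengths log-normal with
median 500 bp, sdlog 0.3 — yeast intergenic regions are a few hundred
bp), plants motif instances sampled from the configured PWMs at
non-overlapping positions on random strands, and derives each
non-reference species from the ancestor independently (star phylogeny)
by i.i.d. substitution to one of the three other bases. Defaults:

* `n_species = 5` — the *sensu stricto* panel size; the reference
  species is the unmutated ancestor.
* `substitution_prob = 0.30` per branch — *sensu stricto* intergenic
  sequence is roughly 30–40% diverged from *S. cerevisiae*, and
  silencer-flanking sequence evolves fast even by that standard.
* `site_retention_prob = 0.8` — a planted site survives intact in a
  derived species with this probability; otherwise it is left to mutate
  like background, which *degrades but does not always destroy* it,
  matching how real conservation calls behave.
* `planting_rate = 1` (Poisson per region per motif);
  `sites_per_region` overrides the Poisson draw with an exact count.

Under exact planting of one site per region, the conserved fraction has
the closed form $P(\mathrm{Bin}(4, r) + 1 \ge 3)$ (0.9728 at $r = 0.8$),
and the calibration tests require the pipeline's estimate to fall within
3 binomial standard errors of it. Two deliberate model features bias the
estimate slightly upward and are worth knowing about: a non-retained
site occasionally still matches after 30% divergence (≈ +0.005 on the
fraction), and with Poisson planting, sites sharing a region inherit
each other's region-level presence — which is why the calibration cohort
plants exactly one site per region. Passing these tests shows the
scan→orthology→conservation chain is internally consistent and
correctly calibrated; it does not show that real yeast conservation data
behave like the generator (no indels, no alignment uncertainty, no
rate variation across sites or lineages, orthology truth known).

`emit_chip_table()` gives each factor a random bound region subset with
binding p-values uniform below 0.05 (bound) or above (unbound).
`perturb_similarities()` builds the RBH stress input: true ortholog
pairs score in 150–200, decoys in 0–140, and a `noise_prob` fraction of
true-pair scores is pooled with an equal number of decoy scores and
permuted — so a noised pair usually, but not always, loses its top rank,
giving a recovery rate that genuinely measures RBH robustness (≥ 80% of
regions at 10% noise in the packaged test).

All generators are pure functions of their configuration; the same seed
reproduces a cohort byte for byte, and `run_pipeline()` writes a
checksum manifest so full-run determinism is checkable.

## Degenerate inputs and numerical tie-breaks

* All-zero count columns error when `pseudocount_total = 0`.
* An all-uniform PWM has zero score range; the distribution falls back
  to a fixed small granularity rather than dividing by zero.
* The strict-threshold search tolerates cumulative floating-point error
  in the tail sums with a $10^{-12}$ relative guard (so `alpha = 1`
  correctly returns the minimum support score plus one bin).
* χ² marginals of zero are an error (the statistic is undefined);
  counts are cast to double before the marginal products, which
  overflow integer range at a few hundred observations.
* Region tables with `end < start`, duplicate region ids, duplicate
  FASTA ids, and non-ACGTN characters (masked to `N` with a warning)
  are all handled at the I/O boundary.

## Problem sizes used in the packaged checks

The test-suite and acceptance-script problem sizes are the package's
calibration choices: 50 random PWMs of length ≤ 8 against exhaustive
enumeration; 100 synthetic regions for scanner–oracle equivalence; a
500-region, one-site-per-region cohort for the conservation closed
form; 1000 replicates for the χ² type-I calibration; 50 regions (200
flanking-gene pairs) for RBH recovery at 10% noise. They are large
enough that the binomial acceptance bands are a few tenths of a percent
to a few percent wide, and small enough to run in well under a minute
each on one core.

## Known limitations

The substitution model is Jukes–Cantor-like with a star phylogeny — no
branch lengths, no indels, no alignment step; orthology in real data
would come from BLAST-style similarity scores, which the package
consumes but does not compute; motif discovery (MEME-style EM) and logo
rendering beyond the per-position bit vector are out of scope, as are
ORC/ACS sites, which the source analysis deliberately set aside. The
packaged Abf1 matrix is synthetic (built around the field's published
Abf1 consensus shape) because no count matrix is redistributable here;
analyses of real data should substitute a genome-derived Abf1 PWM via
`read_motif_counts()`.
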