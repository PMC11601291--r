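---
title: "Methods: RBNS site discovery and affinity estimation with mirbns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RBNS site discovery and affinity estimation with mirbns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbns)
```

## The experiment and the model

RNA Bind-n-Seq (RBNS) incubates a large random-sequence RNA library with a
purified RNA-binding species — here Argonaute loaded with a miRNA guide
(RISC) — at several concentrations, captures the bound fraction, and
sequences it. Two quantities come out of the analysis:

1. **Which motifs are bound productively** (de novo site discovery), and
2. **How tightly each site type is bound** (absolute dissociation
   constants, K~D~).

The statistical model behind both is a single-site equilibrium per library
molecule. A molecule carrying site type $s$ is bound with probability

$$p_s = \frac{A_{free}}{A_{free} + K_{D,s}},$$

and the free RISC concentration solves mass conservation over the whole
library,

$$A_{tot} = A_{free}\left(1 + \sum_s \frac{L\,f_s}{A_{free} + K_{D,s}}\right),$$

with $L$ the total RNA concentration (100 nM in the emulated design) and
$f_s$ the pool frequency of site $s$. The RNA is in vast excess over RISC
(at most ~5 nM active), so depletion of any one sequence is negligible,
but total sequestration of RISC is not — hence the self-consistent
$A_{free}$ (`solve_free_ago()`). The sequenced bound library is a
multinomial draw from $q_s \propto f_s p_s$; `negative_log_likelihood()`
is exactly this multinomial likelihood summed over the concentration
series, and `fit_kd()` maximizes it over $\log_{10} K_D$ for every site
type plus the no-site background.

## The site grammar

Site types are described by the paired guide span $[g_s, g_e]$ (1-based
guide coordinates, g1 at the 5' end), a t1A flag, and edits: G:U wobbles,
mismatched target nucleotides, bulged target insertions, and target
deletions. Position **g1 never base-pairs**: it is buried in the MID-domain
pocket, which is also why an adenosine opposite g1 (t1A) contributes
affinity without pairing. Without this convention, guides whose g1 is U
(e.g. let-7) would make "7mer-A1" and "perfect pairing from g1"
indistinguishable. Motifs are written target 5'→3', so the t1A adenosine
is the motif's last character.

Printed names follow the field's conventions: `8mer` (g2–g8 + t1A),
`7mer-m8`, `7mer-A1`, `6mer`, `6mer-m8`, `6mer-A1`; explicit ranges for
other spans (`5mer-m2.6`, `10mer-m13.22`, `11mer-m4.14`); `w`/`x`/`b`
suffixes for wobble, mismatch and bulge edits (`8mer-w8`, `7mer-m8,w2`,
`8mer-x4C`, `8mer-b5.6A`); and, as a grammar extension not printed in the
source material, `-d<k>` for target deletions. `parse_site_name()` and
printing are exact inverses over this nomenclature.

### Classifying k-mers

`classify_kmer()` ranks pairing interpretations by the number of paired
guide positions (longest first); at equal span the tiers are perfect >
wobble > bulge > mismatch, each preferring its t1A variant. Two choices
deserve comment because degenerate sequences make them visible:

* **Span-major, not window-major.** A C flanking a seed core creates a
  window one nucleotide longer that can be read as a bulged-C site with
  the *same* number of pairs. Ranking by paired span keeps a seed match a
  seed match.
* **Wobble before bulge.** A wobble interpretation pairs more guide
  positions without distorting the helix; in degenerate registers a
  bulge-first rule would rewrite the wobble-terminal types that de novo
  discovery actually reports (`8mer-w8`, `7mer-w8`) as bulged shorter
  sites.

Equivalent bulge registers (an inserted A next to a templated A) are
resolved to the smallest slot, which names the nucleation bulge `b5.6`.

## De novo discovery

Discovery uses the bound library at the highest RISC concentration only.
Each iteration counts all overlapping 10-mers, computes enrichment
$R = f_{bound}/f_{input}$ (with a +1 pseudocount: $4^{10} \approx 10^6$
k-mers against finite depth), classifies the 100 most enriched 10-mers,
selects a site type, tests it against a Z threshold frozen at iteration 0
(the 99.9th percentile of the k-mer Z distribution), masks every read
containing the accepted motif in both libraries, and recounts. Masking is
what removes "shadow" 10-mers — frame-shifted neighbours of a real site.

Two statistics differ from a naive reading, both for calibration reasons:

* **Site-level Z.** The maximum of ~10^6^ empirical Z values always
  exceeds their own 99.9th percentile, so a stopping rule applied to the
  single top 10-mer would accept a spurious site from *any* null library.
  The package instead aggregates counts over every 10-mer containing the
  site's motif and standardizes that aggregate against the iteration-0
  distribution. Aggregation has no selection bias: under a flat-affinity
  null the site-level Z sits near 0, and the loop stops immediately.
* **Absorption of nested candidates.** Among the top 10-mers, flanking
  extensions and edit-rewrites of a core motif appear as distinct
  "site types" with essentially the core's enrichment. A candidate whose
  motif contains another candidate's motif as a substring is absorbed into
  the more general type unless its aggregate enrichment is higher by more
  than 2 standard errors (`z_absorb`). The survivor with the highest
  aggregate enrichment is accepted. Candidates too rare to estimate
  (fewer than `min_support` effective occurrences in either library) are
  not considered.

### What a saturating top concentration can and cannot resolve

The absorption test has a consequence worth stating plainly. In the
simulated acceptance world (dilutions from 5 nM, truth K~D~s of 0.02, 0.08
and 0.5 nM against a 100 nM no-site background), mass conservation leaves
$A_{free} \approx 2.4$ nM at the top concentration, so the 8mer and
7mer-m8 sites are 99.2% and 96.7% occupied: their enrichments differ by
~2.5% while the input-limited standard error of any aggregate is 5–7% at
depth 10^6^. No statistic computed from that single library can order the
two, the absorption test (correctly) declares them equivalent, and
discovery reports the general core (`7mer-m8`) plus `6mer`. The t1A
information is not lost — it is carried by the concentration *series*, and
the maximum-likelihood fit recovers all four K~D~s within 2-fold with the
8mer ranked tightest. Discovery at a saturating concentration answers
"which cores are bound"; the dilution series answers "how tightly, and
does the t1A pocket matter".

## The simulator

`simulate_pool()` / `simulate_selection()` generate the stated world:
20-nt uniform-random inserts inside constant primer-binding flanks
(defaults emulate the blocker regime, retaining 4 constant nucleotides per
side in the single-stranded search region); equilibrium selection with
per-molecule weights equal to occupancy at the molecule's site K~D~, with
$A_{free}$ solved by mass conservation; multinomial sampling to a fixed
depth (selection without explicit depletion — valid because the library is
in ~20-fold excess over RISC even if every molecule were a site); and a
uniformly sampled mock library. Defaults are the experimental design
values: six 3.2-fold dilutions from 5 nM, 100 nM library, depth 10^6^,
pool diversity 10^6^ molecules (a desk-scale stand-in for the experimental
~10^12^; at these depths duplicate draws of one molecule are common but
carry no shared noise beyond the multinomial already modeled). Multi-site
molecules are weighted by their strongest site. Sequencing error is off by
default; the read filters are exercised on corrupted fixtures instead.

What a green simulation-based test does **not** establish: synthesis bias
in real pools (the analysis estimates $f_s$ from the sequenced input for
this reason), PCR amplification bias, partial RISC activity, or
non-equilibrium capture effects.

## Preprocessing

The read filter is a literal containment test, per the emulated protocol:
the first adapter trinucleotide (TGG) must sit exactly at positions 21–23,
every base call needs Phred ≥ 20, and N calls are disallowed. The adapter
suffix is then removed and the search region reconstructed as the insert
plus 0, 4 or 6 constant nucleotides per side (no blockers / blocker set
#1 / #2 — an experiment-level configuration, not a guess).

## K~D~ estimation details

* Optimization is over $\log_{10} K_D$ in [1e-5, 1e4] nM (site affinities
  span picomolar to micromolar), L-BFGS-B from 5 starts (one neutral, four
  seeded-random).
* Pool frequencies take a +1 pseudocount so every $q_s > 0$.
* Reads containing multiple or partially overlapping sites are dropped
  (and tallied; they are a trace fraction). An occurrence nested inside a
  longer occurrence is the same site, not a second one.
* Confidence intervals: each library column is resampled as a multinomial
  of its own size (equivalent to resampling reads with replacement) and
  refit; the tabled value is the median of bootstrap estimates and the CI
  its 2.5/97.5 percentiles (B = 200 by default, 100 or less at desk
  scale). The bound-concentration series is treated as known (measured
  independently by stoichiometric titration); `fit_stock_scale = TRUE`
  co-fits one global scale factor instead, under which only relative
  K~D~s are identifiable.
* Scale invariance ($c \cdot K_D$ with $c \cdot$ every concentration,
  including the library concentration, leaves the likelihood unchanged) is
  enforced as an algebra test.

The flanking-context analysis is the same fit with the site subdivided
into $4^{2f}$ context-specific types by the $f$-nucleotide flanks
(`context_catalog()`; $f = 2$ gives the 256 dinucleotide contexts). The
aggregation invariant (median context K~D~ ≈ unpartitioned K~D~) is
property-tested at $f = 1$ and reduced depth; populating 256 contexts
needs more than 5×10^6^ reads per library, beyond the test budget.

## Isotherms

The stoichiometric-titration, direct-binding and competition models are
the exact closed forms of the two-species quadratic equilibrium (no
ligand-excess approximation, as appropriate when K~D~ < [target]); each is
verified against an independent numerical root-finder on random draws.
Fits are unweighted least squares (nothing in the source protocols
specifies weights) with free parameters per assay usage: titration
(K~D~, n, f~max~); direct binding (K~D~, optionally f~max~ — exposed as a
flag because the original fits do not state it); competition (K~C~ only,
with E~T~, S~T~, K~D~ fixed from the direct experiment). Zero-residual
(noiseless) data is handled with `nls.control(scaleOffset = 1)`.

## Thermodynamics and accessibility

`nn_duplex_dG()` sums nearest-neighbor stack terms plus duplex initiation,
terminal-AU penalties and the self-complementarity symmetry term from a
versioned parameter file (Turner-2004-vintage Watson–Crick RNA/RNA block;
the file identity is recorded in the result). The packaged table contains
no G:U stack block — declared wobbles require a user-supplied table — and
predicted K~D~ ($e^{\Delta G / RT}$, default 37 °C) is defined only for
contiguous, non-t1A duplexes: the t1A adenosine is pocket-bound, not
paired, so it has no duplex energy. Binding assays run at 25 °C;
correlations with measured affinities are computed on log scale, where a
temperature-consistent offset cancels, and a temperature argument is
exposed. Correlation is Pearson on log-transformed values with a
two-sided t-based p (n − 2 df).

Accessibility scores consume precomputed unpaired-probability profiles
(RNAplfold `_lunp` output or a per-base TSV) — the partition function
itself is out of scope. When the profile carries a window column at least
the span width, the span-level probability is used; otherwise per-base
probabilities are multiplied as an independence fallback. Both behaviours
exist because published analyses do not state which was used.

## Numerical choices and degenerate inputs

* Free-RISC bisection to relative tolerance 1e-10; the bracket
  (0, A~total~] always contains exactly one root.
* `enrich_and_z()` uses the sample standard deviation; with a pseudocount
  of 0, k-mers absent from both libraries yield NaN enrichment — the
  pseudocounted default never does.
* Ties everywhere (classification registers, discovery candidates,
  bulge slots) are broken deterministically; all randomness flows from
  explicit seeds.

## Known limitations

* Motifs longer than ~10 nt cannot be discovered de novo (reads containing
  them are too sparse) and motifs above 12 nt are rejected outright.
* Bipartite sites (seed plus 3'-supplementary pairing across a loop) are
  out of scope.
* Centered-site affinities are not measurable by RBNS-style selection at
  all when the protein cleaves them; the grammar still names them
  (`11mer-m4.14`) for use in cleavage assays.
* The discovery loop's set of accepted types at a saturating top
  concentration merges t1A variants with their cores (see above); use the
  K~D~ fit to resolve them.
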