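# mirbns

Analysis of RNA Bind-n-Seq (RBNS) experiments with miRNA-loaded Argonaute
(RISC): de novo discovery of miRNA target-site types and absolute binding
affinities (K_D) for each of them, from sequencing libraries selected at a
series of RISC concentrations. Written for people quantifying miRNA
targeting biochemistry — in flies or elsewhere — who need the full path
from raw reads to per-site dissociation constants, plus the low-throughput
isotherm fits and nearest-neighbor predictions used to cross-check them.

## What it computes

**Site grammar.** Target-site types are formal objects: a paired guide
span g_start..g_end (g1 never pairs; it is the Argonaute A-pocket
position), a t1A flag, and wobble/mismatch/bulge/deletion edits. The
printed nomenclature round-trips (`8mer`, `7mer-m8`, `7mer-A1`, `6mer`,
`6mer-m8`, `6mer-A1`, `8mer-w8`, `7mer-m8,w2`, `8mer-x4C`, `8mer-b5.6A`,
`5mer-m2.6`, `10mer-m13.22`, `11mer-m4.14`, ...) and any 4–12-nt k-mer can
be classified to its best site type (`classify_kmer`).

**De novo discovery.** Overlapping 10-mers are counted in the
top-concentration bound library and the input pool; enrichment
R = f_bound/f_input is standardized as Z = (R − mean R)/sd R; the loop
classifies the top 100 10-mers, accepts the most enriched site type if its
site-level Z clears the 99.9th percentile of the iteration-0 distribution,
masks every read containing the site motif, and repeats.

**K_D estimation.** Reads are assigned to unique site categories; a
maximum-likelihood fit over the concentration series recovers one K_D per
site type (plus the no-site background), with a self-consistent free-RISC
concentration from mass conservation:

    A_tot = A_free * (1 + sum_s L*f_s / (A_free + K_D,s))
    q_s   ~ f_s * A_free / (A_free + K_D,s)        (bound-library composition)

Bootstrap resampling gives 95% CIs of the median.

**Isotherms.** Exact quadratic-equilibrium closed forms for stoichiometric
titration, direct binding and competition, with least-squares fitting
(`fit_isotherm`).

**Thermodynamics & context.** Nearest-neighbor duplex dG (Turner-2004
vintage Watson–Crick table) and predicted K_D = exp(dG/RT); Pearson
correlation of predicted vs. measured affinities on log scale; flanking
dinucleotide context partitions (4^4 = 256 context-specific sites) and
accessibility scoring from RNAplfold-style unpaired-probability profiles.

**Simulator.** `simulate_pool()`/`simulate_selection()` generate RBNS
libraries with known ground truth (equilibrium selection at site-specific
K_Ds, mass-conservation-limited free RISC, multinomial sequencing, mock
control) for validation and power analysis.

## Worked example

Simulate a small experiment with known affinities and recover them:

```r
library(mirbns)

guide <- fly_guide("let-7")
truth <- c("8mer" = 0.02, "7mer-m8" = 0.08, "6mer" = 0.5, "no-site" = 100)  # nM
cfg   <- sim_config(guide, truth, n_pool = 2e5, depth = 2e5, seed = 1)

pool <- simulate_pool(cfg)
libs <- simulate_selection(pool, cfg)

counts <- assign_reads(c(list(input = libs$input), libs$bound), libs$catalog)
fit <- fit_kd(counts, libs$series, bootstrap = 0, seed = 7)
data.frame(site = fit$site, kd_nM = signif(fit$kd, 3), truth_nM = truth[fit$site])
#>            site   kd_nM truth_nM
#> 8mer       8mer  0.0175    2e-02
#> 7mer-m8 7mer-m8  0.0837    8e-02
#> 6mer       6mer  0.5200    5e-01
#> no-site no-site 98.2000    1e+02
```

Every fitted K_D lands within ~15% of truth at this reduced depth, in the
right order — the 8mer tightest, the background weakest. De novo discovery
at full depth (the same world at `n_pool = 1e6, depth = 1e6`):

```r
res <- discover(libs$bound[[1]], libs$input, guide)
res$accepted[, c("iteration", "name", "motif", "R_original", "Z_original")]
#>   iteration    name   motif R_original Z_original
#> 1         1 7mer-m8 CTACCTC   36.59030   26.38896
#> 2         2    6mer  TACCTC   32.05661   23.01985
```

The seed cores come out ~35-fold enriched and the loop stops at the frozen
99.9th-percentile threshold. At the top concentration (~2.4 nM free RISC)
the 8mer and 7mer-m8 are both nearly saturated, so single-library
discovery reports the shared core; the t1A distinction is resolved by the
concentration-series fit above, not by one library (at the reduced README
depth, even the 7mer/6mer split collapses to `6mer`). The methods
vignette (`vignettes/mirbns-methods.Rmd`) works through why.

A command-line front end covering filtering, discovery, K_D fitting and
curve fitting is installed as `exec/rbns`.

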