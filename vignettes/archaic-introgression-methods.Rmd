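---
title: "Quantifying archaic legacies: statistics, demography and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying archaic legacies: statistics, demography and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Modern human genomes share more derived alleles with Neanderthal and
Denisovan genomes than a tree without gene flow predicts, and the excess is
geographically structured: it grows from west to east across Eurasia, much as
heterozygosity falls with distance from Africa. Two mechanisms can generate
such excess sharing: admixture from the archaic lineage into some humans, or
mutation-rate differences between human populations (a faster-mutating
population drifts further from the ancestral state and therefore from every
closely related outgroup). This package implements the statistic family used
to measure the excess, the geographic trend analyses that expose its spatial
structure, and a coalescent simulator of a serial-founder out-of-Africa
demography with archaic admixture pulses, so that the drift-plus-admixture
explanation can be tested quantitatively against the patterns it is supposed
to produce.

## The aligned site table

Every statistic consumes one structure, built either from variant calls
(`build_site_table()`) or from simulations (`sim_to_site_table()`): one row
per biallelic SNV callable in all taxa. The chimpanzee defines the ancestral
allele, written "A"; the other observed allele is "B". Rows carry
per-population B-allele frequencies and call counts, archaic allele states,
the transition/transversion class, and the B-dosage of one focal diploid
individual per population. Indels and multiallelic records are excluded
before any statistic. Missing human genotypes reduce the per-population call
count; frequencies use called alleles only.

Two site sets matter and the table keeps both. The full table holds every
site that is biallelic across all taxa, including sites monomorphic within
humans (in simulated data these arise from mutations on the chimpanzee and
archaic branches). The `hpoly` flag marks the subset polymorphic within the
pooled human samples. Averages that are defined "per callable site" (AFD,
heterozygosity) run over the full table, which is what makes simulated and
analytic values comparable across scenarios with different outgroup branch
lengths; the nd divisor N deliberately counts only human-biallelic sites,
because nd is defined as a probability per informative human site.

Archaic genomes are single ancient individuals, so their base calls pass a
homozygosity filter first (`filter_archaic_call()`): at least 10 reads,
fewer than 250, and more than 80% of reads supporting one base. Candidate
heterozygous sites become missing data rather than errors; this sacrifices a
modest number of sites but avoids coercing low read counts into genotypes.

## The statistics

**D (ABBA--BABA).** For two humans P1 and P2, an archaic P3 carrying B and
the chimpanzee carrying A, informative sites are those where P1 and P2
differ; D = (ABBA - BABA)/(ABBA + BABA), in [-1, 1]. The definition is
individual-based, and `compute_d()` defaults to fractional counting: a
diploid contributes its B-dosage/2 as the probability of showing B, which
matches the definition in expectation without an arbitrary haplotype choice.
A strict haplotype mode with a fixed seed is provided
(`mode = "haplotype"`). Conditioned variants restrict the informative sites
to those heterozygous or homozygous in one named human before counting,
which localizes which side of the comparison drives a signal. Zygosity
conditioning partitions the informative sites exactly, a property the tests
assert.

**nd (derived-archaic-allele frequency).** nd_NEA is the average frequency
in a focal population of alleles derived in the Neanderthal while the
Denisovan and chimpanzee are ancestral (joint state XXBAA); nd_DEN is the
mirror image (XXABA). Sites where both archaics carry the derived allele
(XXBBA) contribute to neither. The divisor N is the number of
human-biallelic sites callable in all taxa in the requested mutation class,
not the number of qualifying sites, so nd is a per-site probability.
Optional conditioning requires the B allele to be absent from every
conditioning-panel population with called genotypes; sites at which the
entire panel is uncalled do not qualify (the conservative choice). A panel
population therefore has conditioned nd identically zero -- a structural
fact, not a finding. Transitions and transversions can be analysed
separately; their numerators and divisors add exactly.

**f4.** The mean over sites of (p1 - p2)(p3 - p4). Without gene flow or
shared drift the paired differences are uncorrelated and f4 is zero in
expectation. Single genomes contribute frequencies 0, 1/2 or 1. Because the
quantity is often described as a correlation of paired differences, the
Pearson correlation of the two difference vectors is reported alongside the
mean product; both are tested.

**AFD and FST.** AFD is the mean absolute B-frequency difference over table
sites where both populations are called -- a plain, estimator-free genetic
distance. FST uses Hudson's two-population estimator with sample-size
correction, combined across sites as a ratio of sums, which behaves well
with rare variants. The two give essentially interchangeable orderings in
the migration sweep.

**Heterozygosity.** Mean 2p(1-p) from sample frequencies over called sites;
`heterozygosity_loss()` reports 1 - H_pop/H_ref against a reference
(conventionally African) population for the bottleneck calibration.

Undefined statistics (no informative sites, zero denominators) return
flagged results rather than NaN, so downstream aggregation never silently
propagates poison.

## The simulated demography

`demography_config()` encodes the scenario; `build_demography()` renders it
as an explicit backward-time event list (validated, unit-tested, exportable
as a classic ms-style command string via `export_ms_command()` for audit);
the bundled python helper executes it with msprime, the standard coalescent
engine. Defaults, with times in years before present at 25 years per
generation:

| parameter | default | meaning |
|---|---|---|
| `N0` | 10000 | diploid size of every deme; one coalescent unit = 4 N0 = 40000 generations |
| `fragment_length`, `num_fragments` | 500 kb, 1000 | independent fragments; theta = 4 N0 mu L = 200 per fragment |
| `mutation_rate` | 1e-8 /bp/gen | with `rho` = 100 per fragment (r = 5e-9 /bp/gen) |
| `chimp_split` | 6,000,000 | chimpanzee outgroup |
| `archaic_split` | 500,000 | human--archaic split |
| `nea_den_split` | 450,000 | Neanderthal--Denisovan split |
| `ooa_time` | 70,000 | out-of-Africa founding |
| `bottleneck_start`, `bottleneck_factor` | 68,500, 0.007 | founder size 70 diploids for 1500 years |
| `nea_pulse` | 3.4% at 60,000 | into the first non-African population |
| serial founding | 50,000 to 42,000, every 2,000 | six non-African populations |
| `den_pulse` | 3.4% at 40,000 | into the last-founded population |
| `migration_rate` | 1 | migrants/generation between adjacent non-African demes |
| samples | 1 chimp, 20 per archaic, 100 per human deme | haploid lineages (741 total) |

Two conventions are provided: `"prose"` (the default above) and
`"ms_example"` (400 kyr archaic split, 3.0% pulses), reflecting two
internally inconsistent statements of the same scenario; the exporter emits
whichever is configured. The printed site count of a classic `-r` flag is
tied here to the actual fragment length rather than carried over verbatim.

**Migration units.** `migration_rate` is literal migrant individuals per
generation: the backward per-generation rate is `migration_rate / N0`, so a
rate of 1 corresponds to an ms `-m` value of 4. We fixed this convention by
calibration: with it, AFD between the terminal non-African populations comes
out near 0.0135 at rate 1 and near 0.007 at rate 50 (the acceptance script
recomputes both), spanning the empirical Europe--East Asia range; under the
alternative reading (`-m` value = rate) the rate-50 differentiation stays
~50% too high. The sweep rates {1, 10, 20, 50} are therefore comparable to
spoken "migrants per generation" figures.

**Bottleneck calibration.** The factor-0.007 bottleneck removes about 35% of
pairwise coalescence survival in isolation; interacting with the pulses
(introgressed lineages are deeply diverged and add back diversity) and
post-split drift, the realized present-day loss of the first non-African
population relative to the African one is 22--23% under the standard
scenario -- "about a quarter", which is the empirically sensible target. The
tests assert the realized loss at the 220-fragment scale within +/-5
percentage points of 25%.

**What D this scenario yields.** With only the Neanderthal pulse active, the
individual-based D(AFR, NONAF1; NEA, chimp) computed by the acceptance
script lands near 0.09 (Monte-Carlo SE ~0.013 at 800 fragments). A
closed-form check agrees: the expected ABBA--BABA excess is the pulse
fraction times the branch between the introgressed lineages' coalescence
with the Neanderthal and the human--archaic ancestor (~4.6 mutations per
fragment), against an incomplete-lineage-sorting denominator of ~30 per
fragment. Readers comparing against published real-data values near 4--5%
should note that real comparisons involve larger ancestral diversity and a
single ancient archaic genome; within this model, matching such values would
require roughly 3x more ancestral lineage sorting or a pulse near 1%.

**Archaic allele states in simulations.** Real pipelines see one archaic
genome and keep only confident homozygotes. The default simulation rule
mirrors that: one diploid archaic individual (the first two sampled
lineages), state B when homozygous B, A when homozygous A, missing when
heterozygous. A panel rule (state B when the derived allele reaches a
configurable frequency across all 20 sampled archaic lineages) is available
for sensitivity analyses; conclusions about profile shapes are insensitive
to the choice, while absolute D shifts by tens of percent between rules --
one reason published point values of D are hard to compare across pipelines.

**Nucleotide assignment.** The coalescent is simulated under infinite sites
with abstract 0/1 alleles; `sim_to_site_table()` draws an ancestral base
uniformly and a derived base that is a transition with probability 2/3
(matching the genome-wide ~2:1 transition:transversion ratio), under a seed
derived from the simulation seed. The assignment exists so the
transition/transversion machinery is exercised end-to-end; it carries no
information about the genealogy.

**The mutation-rate extension.** `african_mutation_scale` multiplies the
mutation rate on branches whose descendants are all African samples,
emulating a higher African mutation rate after the out-of-Africa split.
Under infinite sites this adds African-private derived alleles: African
heterozygosity and African/non-African divergence rise, and the nd and f4
divisors grow (diluting those statistics), but D is untouched because its
informative sites require an archaic-derived allele that new human-private
mutations never create. Turning mutation-rate variation into a *positive* D
signal requires recurrent hits at archaic-derived positions -- back
mutations -- i.e. a finite-sites process; that is documented as out of scope
here, and no test asserts a D response.

## Geographic trends

Distances are haversine great circles (`great_circle_distance()`, mean Earth
radius 6371 km) or waypoint land routes (`land_route_distance()`): a sum of
great-circle legs through a small, documented routing table
(`default_waypoints()`: the Levant for Eurasia, plus a Bering leg for the
Americas). Waypoint routing replaces raster least-cost paths deliberately --
these distances serve as a regression covariate whose units are arbitrary,
so shape and ordering matter, geodesy does not. Two origin conventions are
common (an East African origin such as Addis Ababa for land routes; Cairo at
30 N, 31 E for great circles, which minimizes presumptions about the exit
route); the origin is always an explicit argument and is recorded in
outputs.

The regression layer is ordinary least squares: `fit_trend()` (slope,
Pearson r, two-sided p), `fit_interaction_model()` (nd_NEA ~ nd_DEN *
distance, reporting the interaction p-value), and `fit_region_glm()` (value
~ distance * region with an F-test of the interaction as the parallel-slopes
diagnostic; regions below a minimum size are excluded and counted; a single
usable region falls back to the simple trend with a warning). Two-sided
p-values throughout and no multiple-testing correction, matching how such
trend tables are conventionally reported. Degenerate inputs (zero-variance
covariates, exact collinearity) yield flagged fits rather than errors.

## Genome-scan consistency analyses

`nd_by_chromosome()` tabulates nd per chromosome (or per simulated fragment
group) and population; `leave_one_out_correlation()` correlates each
chromosome's across-population profile with the mean profile of all other
chromosomes. Under drift after a single admixture event these correlations
have no consistent sign, so a uniformly high mean r is evidence that the
geographic profile is a genome-wide property rather than the luck of a few
regions. `exclude_chromosomes()` drops labels (default chr21, which
contributes far fewer aligned sites than its size predicts in the real
data); excluding a missing label warns and is otherwise a no-op.

`windowed_f4()` tiles each chromosome with half-open windows anchored at
position 1 (final partial windows retained; windows with no usable sites
reported as missing, never zero) and satisfies the partition identity: the
site-count-weighted mean of window values reproduces the global statistic
exactly. `filter_window_outliers()` drops windows below a site-count
threshold and beyond a value clip (default 0.004, the plotting range of
megabase-scale f4 tracks). The published analyses state only the resulting
exclusion fractions (under 5%), not the rule, so the rule here is declared
and configurable: with the default `min_sites = 20`, simulated tracks lose
well under 5% of windows. `correlate_tracks()` joins two tracks on window
coordinates and reports Pearson r, n and p.

## Numerical and reproducibility choices

* All Monte-Carlo uncertainty is assessed by leave-one-fragment-out
  jackknife over fragments/chromosomes (`jackknife_se()`), the natural block
  structure of both the simulations and genome data.
* Every simulation is deterministic given (config, seed); sweep and recipe
  runs derive per-scenario seeds from the master seed with a fixed affine
  rule and record them. Recipe outputs carry a manifest (config snapshot,
  seed, package version, output digests); reruns are byte-identical.
* Site tables serialize to plain TSV with a JSON metadata header and
  round-trip bit-exactly.
* Problem sizes: the test suite simulates 15-fragment toys for unit checks,
  120-220 fragments for calibration checks, and the acceptance script uses
  800 fragments (D, heterozygosity loss) and 600 per migration rate (AFD),
  sizes at which the jackknife SEs are ~0.013, ~0.005 and ~0.0001
  respectively. The full-scale configuration (1000 fragments) is the
  default for interactive use.

## What the generator does and does not emulate

It emulates: a chimpanzee outgroup lineage; two sister archaic lineages;
an African and six serially founded non-African populations linked by
stepping-stone migration; admixture pulses from each archaic; the
out-of-Africa bottleneck; within-fragment recombination; and the same site
-table representation the real-data readers produce, so every downstream
stage runs unchanged on either source.

It does not emulate: selection (background or positive), sequencing and
alignment error, ancient-DNA damage, the sampling age of archaic genomes
(simulated archaics are sampled at present), gene conversion, variable
mutation/recombination landscapes, or finite-sites recurrent mutation.
Passing calibrations on simulated data therefore demonstrates correctness
of the machinery and the internal consistency of the drift-plus-admixture
account -- they do not certify that real-data values of these statistics
measure admixture alone, which is precisely the question the consistency
analyses (great-ape substitution, window correlations, chromosome
leave-one-out) are designed to probe.

## Known limitations

* The coalescent engine is an external python dependency (msprime),
  invoked through a subprocess; `options(archstats.python = ...)` points the
  package at a specific interpreter.
* Land-route distances are as coarse as their waypoint table; they are
  ordering covariates, not measurements.
* The VCF readers target the common biallelic-SNV dialects (GT fields for
  humans; AD/DP read counts for archaics); exotic encodings need
  pre-processing with standard tools.
* Block-jackknife standard errors for D/f4 across arbitrary block sizes,
  weighted f-statistics beyond f4, and haplotype-tract inference are out of
  scope.
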