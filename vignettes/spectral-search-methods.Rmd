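---
title: "Two-stage GC-MS spectral library search: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage GC-MS spectral library search: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msprescreen)
```

## The problem

Compound annotation in untargeted GC-MS metabolomics works by matching a
query fragmentation spectrum against a library of reference spectra. With
libraries holding tens or hundreds of thousands of electron-ionization
(EI) spectra, computing a similarity score against every library entry for
every query is the dominant cost of annotation. `msprescreen` implements a
two-stage search: a cheap *prescreening* pass that compares only the most
intense peaks and selects a small candidate set, followed by full
similarity scoring restricted to those candidates. The package also ships
the evaluation harness used to quantify what the prescreening loses (the
*inclusion rate*) and what it saves (the number of similarity
evaluations), plus a seeded synthetic-spectra generator so every claim is
testable without external data.

## The similarity model

A spectrum is a list of peaks $(mz_i, I_i)$. Before scoring, intensities
are base-peak normalized ($I_i \leftarrow I_i / \max_j I_j$, so the base
peak equals 1) and scaled as

$$A_i = \frac{I_i \, mz_i}{1 + \omega I_i}, \qquad
  \omega = \frac{1}{I - 0.5}, \qquad I = \sum_i I_i .$$

The $mz_i$ weight up-weights heavy fragments, which are the most
diagnostic ones in EI spectra; $\omega$ damps spectra dominated by a
single peak. After normalization the base peak contributes 1 to $I$, so
$I \ge 1$ and $\omega \in (0, 2]$: the singularity at $I = 0.5$ is
unreachable, and the code asserts this instead of branching around it.

Two spectra $U$ (query) and $L$ (library) are compared with the
sqrt-cosine similarity

$$S(U, L) =
  \frac{\left(\sum_{\text{matched } i} \sqrt{A_i^u A_i^l}\right)^2}
       {\sum_i A_i^u \cdot \sum_i A_i^l},$$

where the numerator runs over matched peak pairs and each denominator sum
runs over *all* peaks of the respective spectrum. By Cauchy–Schwarz
$0 \le S \le 1$, with $S = 1$ exactly for identical spectra and $S = 0$
when nothing matches.

**Peak matching.** "Matched" needs a definition: we pair peaks
one-to-one, greedily by smallest absolute m/z difference within an
absolute tolerance window, ties broken toward the lower library m/z. The
obvious alternative — pairing a query peak with *every* library peak in
its window, as a database join would — double-counts intensity and can
push $S$ above 1, so we rejected it. One-to-one greedy pairing keeps the
score bounded, symmetric in practice (verified to $10^{-9}$ on random
instances in the test suite), and identical to exact m/z binning whenever
peaks are separated by more than twice the tolerance.

**Tolerance.** The window is a configurable absolute half-width:
0.5 Th by default for unit-mass ("low-resolution") spectra and 0.01 Th
for accurate-mass ("high-resolution") spectra — conventional windows for
the two GC-MS regimes. The prescreening uses the same tolerance as the
scorer; using a single window keeps the exhaustive-parameter equivalence
property (below) exact.

## The prescreening stage

For each library spectrum an index stores the m/z values of its $m$ most
intense peaks, ordered by descending intensity with ties broken by
descending m/z (any deterministic rule works; it must only be the same
rule for queries and libraries). Given a query, its $k$-th most intense
peak ($k = 1 \dots n$) is looked up in the first $d_k$ entries of every
library list, and each library spectrum is ranked by how many of the $n$
query peaks it matched. Candidates are then taken in whole tiers of equal
matched count, from the highest count down, until at least $R$ candidates
are collected (a tier is never split, so slightly more than $R$ may be
returned); only those candidates are scored.

**The depth schedule.** The graduated scheme is defined for consecutive
increments: the largest query peak against $n$ library peaks, the second
against $n + 1$, and so on until the $n$-th against $m$ — i.e.
$d_k = n + k - 1$, which presumes $m = 2n - 1$ (the classic pairs (4,7),
(6,11), (8,15)). Equal-peak searches ($m = n$) are also standard. To
cover both families, and any other $n \le m$, with one rule we linearly
interpolate: $d_1 = m$ when $n = 1$, otherwise

$$d_k = n + \operatorname{round}\!\big((k-1)(m-n)/(n-1)\big),$$

which reduces exactly to $n + k - 1$ when $m = 2n - 1$ and to the
constant $n$ when $m = n$. Queries with fewer than $n$ peaks use all
their peaks; library lists shorter than $d_k$ are scanned in full.

These choices give two exact laws that the test suite checks by brute
force: candidate sets are nested as $R$ grows, and matched counts never
decrease as $m$ grows. With $n = m$ at least the largest peak count and
$R$ at least the library size, the candidate set is exactly the set of
library spectra sharing one within-tolerance m/z with the query, and the
two-stage search returns the same hit list as the exhaustive one.

## Search semantics

Hits must score *strictly* above the threshold (default 0.6). Ties in
score are broken by ascending spectrum id so results, and hence inclusion
rates, are reproducible. The cost of a search is reported as the number
of similarity evaluations performed rather than wall-clock time: the
operation count is the hardware-independent analogue of search speed.
The default operating point is $n = 8$, $m = 15$, $R = 50$ — eight query
peaks against a graduated window of fifteen library peaks, with a
50-candidate threshold — the configuration that balances inclusion and
cost in both regimes.

## Evaluation: the inclusion rate

For top-$N$ cutoff $N$, let $M_{orig}(N)$ be the number of top-$N$
exhaustive-search matches scoring above 0.6, summed over all queries, and
$M_{pre}(N)$ the number of those same (query, library id) matches that
the prescreened search also returns, anywhere in its hit list (rank is
ignored: what matters is whether the match survived). Then

$$\mathrm{InclusionRate}(N) = M_{pre}(N) / M_{orig}(N).$$

Counts are summed over queries *before* dividing (a micro-average), so
queries with many confident matches weigh more. When $M_{orig}(N) = 0$
the ratio is undefined and reported as `NA` with a warning — imputing 0
or 1 would silently bias parameter comparisons in opposite directions.

Because prescreening only removes candidates and never alters a score,
the prescreened hit list equals the exhaustive hit list restricted to the
candidate set. `parameter_grid()` exploits this: each query is scored
against the full library once, and every (n, m, R) triple reuses those
scores, so a 32-point grid costs one exhaustive pass plus 32 cheap
prescreens. The identity it relies on is itself a tested property (and
`prescreened_search()` always scores its candidates directly).

## The synthetic-data generator

`generate_library()` emulates the two acquisition regimes: unit-mass
libraries draw 30–150 peaks per spectrum on integer m/z channels in
50–500 Th, accurate-mass libraries draw 5–30 peaks at 4-decimal m/z kept
at least two tolerance windows apart (high-resolution spectra carry far
fewer peaks, which is exactly why prescreening pays off less there).
Intensities are exponential (rate 3) then base-peak normalized — EI
fragment abundances are heavy-tailed, and one rate parameter is enough
for a generator whose job is ordering, not spectral realism.
`generate_queries()` derives each query from a library spectrum by
dropping peaks with probability 0.2 (never the base peak), multiplying
intensities by log-normal noise (sd 0.3 on the log scale), jittering m/z
by centred noise clamped to half the matching tolerance, and adding up to
5 spurious low-intensity peaks on channels away from true peaks. The
clamping is deliberate: the fixtures test the search algorithm, not the
tolerance choice, so ground truth must remain findable by construction.
Everything is reproducible from the config seed, and ground truth is
carried in a side table rather than in MSP names so the files stay
standard.

What the generator does *not* emulate: chromatographic co-elution,
deconvolution artifacts, isotope patterns, detector saturation, or
library heterogeneity across instruments. Passing tests on these fixtures
therefore demonstrate algorithmic correctness (ordering, tiering,
equivalences, determinism) and the expected qualitative regime behaviour,
not annotation accuracy on real data.

## Shipped benchmark and problem sizes

The packaged benchmark (used by the acceptance checks) is a
1,000-spectrum unit-mass library with 200 perturbed queries at a fixed
seed, evaluated at the default operating point; a 600-spectrum
accurate-mass benchmark with 150 queries accompanies it. At these sizes
on this generator the top-1 inclusion rate is at (or extremely near) 1.0,
the high-resolution inclusion rate stays at 1.0, and the prescreened
search evaluates under a quarter of the library per query — the same
qualitative picture expected of the two-stage design at full library
scale, where the operation-count saving translates into a severalfold
speed-up for unit-mass searches. The spread between full-search scores of
true sources (high) and unrelated spectra (low) is wider on synthetic
data than on real spectra, so real-data inclusion rates at large $N$ will
be lower than these fixtures suggest; the monotone laws, equivalences and
self-retrieval guarantees are exact regardless.

## Numerical notes and edge cases

* Scores are clamped to $[0, 1]$ after the division; floating-point
  rounding can otherwise overshoot 1 by ~$10^{-16}$ on self-matches.
* Duplicate m/z values within a record are merged by summing intensities
  at construction time — the scorer assumes one intensity per channel.
* Zero-intensity peaks are dropped at parse time (with a message); a
  spectrum with no positive-intensity peak is a construction error.
* MSP output prints m/z with 1 decimal (unit-mass) or 4 decimals
  (accurate-mass) and intensities with 6 significant digits; re-reading
  and re-writing a file reproduces it byte for byte.
* The empty prescreening result (no library spectrum shares a peak) is
  valid and costs zero similarity evaluations.

## Known limitations

* Only absolute m/z tolerances are supported (no ppm windows); at GC-MS
  masses the difference is minor.
* The prescreening index is rebuilt per search session rather than
  persisted; for the in-memory scale this package targets, index
  construction is negligible next to scoring.
* No alternative similarity measures (plain cosine, entropy similarity)
  are provided; the scorer is fixed to the weighted sqrt-cosine above.
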