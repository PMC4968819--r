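---
title: "Coverage probabilities and read simulation for virome experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage probabilities and read simulation for virome experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroplan)
```

## The design question

A viral metagenomics experiment rarely fails because of too little total
sequence; it fails because the virus of interest is a small fraction of the
community. Before committing to a sequencing design, one wants the
probability that a target genome of length $L$ and relative abundance
$\alpha$ will be *completely* covered by an idealised assembly of $R$ reads
of mean length $l$ — and, if one run is not enough, how many runs will be.

`viroplan` answers this with an exact circle-covering calculation, checks
it against a Monte-Carlo simulation of the same stochastic model, and
closes the loop with a read simulator that produces benchmark datasets with
known ground truth.

## The coverage model

The target genome is modelled as a circle of circumference $L$. Each of the
$R$ community reads is independently *on-target* with probability $\alpha$;
an on-target read covers an arc of length $l$ whose start position is
uniform on the circle. Let $B$ be the number of maximal uncovered intervals
("gaps") after merging overlapping arcs — the gaps of a hypothetical ideal
assembly in which overlapping reads always merge. With
$\varphi = l/L$ and the series limiter
$\eta = \min(R, \max\{\beta : 1-\beta\varphi > 0\})$,

$$P(B=k) = \binom{R}{k} \sum_{\beta=k}^{\eta} \binom{R-k}{\beta-k}
  (-1)^{\beta-k}\, \alpha^{\beta}\, (1-\beta\varphi)^{\beta-1}\,
  (1-\beta\varphi\alpha)^{R-\beta},$$

and the full-coverage probability is the $k=0$ case. For $\alpha = 1$ this
is the classical arcs-covering-a-circle result; the $\alpha < 1$ form
arises from thinning the reads binomially before placing them. Both
reductions are verified numerically in the test suite, the first against a
separately coded classical series, the second against exact enumeration at
small $R$ and against Monte Carlo everywhere else.

Two model details deserve emphasis:

* **The series limiter is strict.** At integer $1/\varphi$ the term
  $\beta = 1/\varphi$ would contain $(1-\beta\varphi)^{\beta-1} = 0^{\beta-1}$;
  including it yields the absurd $P(B=0) = 0$ at $R = 1$, $\varphi = 1$.
  We therefore require $1-\beta\varphi > 0$ strictly, under which
  $\varphi \ge 1$ gives $\eta = 0$ and $P(B=0) = 1$: any on-target read
  covers the whole circle.
* **$B = 0$ includes the empty assembly.** If no read lands on the target,
  there are no gaps, so $P(B=0)$ contains a $(1-\alpha)^R$-flavoured
  contribution that has nothing to do with coverage. At
  $R = 2$, $\varphi = 0.6$, $\alpha = 0.5$ exact enumeration gives
  $P(B=0) = 0.25 \cdot 1 + 0.25 \cdot 0.2 = 0.30$, of which $0.25$ is the
  zero-read event. We report the raw series value and document the caveat
  rather than redefining the event: the practical consequence is that
  $P(B=0)$ is *not* monotone in $R$ for small $\alpha$, and that
  "unreachable" planner configurations only exist at high abundance.

## Why arbitrary precision

The series alternates, and its terms are enormous long before the result
is: at $R = 10^7$, $l = 150$, $L = 30000$ the binomials reach
$\binom{10^7}{200} \approx 10^{1045}$, far beyond double precision, while
the answer is a probability. All terms are therefore formed with exact
integer binomials (GMP) and multiple-precision floating point (MPFR). The
working precision is not guessed: a result is evaluated at $p$ bits and at
$2p$ bits and accepted only when the two agree to a relative tolerance
(`rel_tol`, default $10^{-12}$), doubling from `start_bits = 128` up to
`max_bits = 1048576`. Persistent disagreement raises a typed
non-convergence error carrying both estimates — never a silently wrong
number. Values below $10^{-300}$ are compared absolutely, since relative
agreement is meaningless at the underflow edge. Accepted values are clamped
to $[0,1]$ only after passing a $10^{-12}$ excursion check.

The defaults are cheap where the problem is easy (small $R$ stabilises at
the first doubling) and leave ample headroom: $\eta$ — the series length —
is at most $\lceil 1/\varphi \rceil - 1$, about $10^3$ for the shortest
reads against the largest viral genomes one would plan for.

## The run planner

`plan_runs()` takes the reads-per-run and mean read length from a
sequencing profile (or explicit flags), and evaluates
$P(B=0)$ at cumulative $R = n \cdot \text{reads per run}$ for
$n = 1, 2, \dots$, stopping at the first $n$ meeting the threshold and
capping at 10 runs; past that point the design, not the run count, is the
problem. Runs are additive in reads and nothing else. The default
threshold is 0.95 — a conventional confidence level, exposed as an
argument since the choice is the experimenter's.

## Sequencing profiles

A profile is the minimal statistical summary the simulator and planner
need: read count, read-length mean and standard deviation ("read length
variation" is taken as the SD), the maximum length, and the mean
phred-implied error probability $10^{-Q/10}$ at every position, averaged
over the reads that reach that position. Averaging on the probability
scale (not the quality scale) matches how the simulator consumes the
values. `infer_profile()` builds one from any Sanger-encoded FASTQ;
`preset_profiles()` supplies editable starting points for seven platforms
(IonTorrent, IonProton, Illumina MiSeq/HiSeq/NextSeq, PacBio, Oxford
Nanopore). The presets are constructed programmatically from compact
parametric error ramps — representative orders of magnitude, not
instrument measurements — and any of them can be exported with
`save_profile()` and edited as JSON. Profile JSON stores numbers with 17
significant digits, so a save/load cycle is binary-exact.

## The read simulator

`build_community()` samples genomes without replacement and assigns
uniform weights or exponentially decaying weights
$w_i \propto e^{-\text{decay}\, i}$ by sampled rank (default decay 0.5, a
moderately steep rank-abundance curve typical of virome data). For each
read, `draw_read()` samples a length from
$\mathcal{N}(\text{mean}, \text{SD})$ rounded and truncated to
$[1, \min(\text{max length}, \text{genome length})]$, a uniform start on
the *linear* genome, and a uniform strand; errors are injected per
position with the profile's probabilities, each error substituting a
uniformly chosen different base and marking it lowercase. Qualities encode
the profile's error probabilities as phred scores clamped to $[2, 41]$.
The key CSV (`read_id,genome_id,start,end,strand,n_errors`, 0-based
half-open coordinates) makes every read auditable: uppercasing the read
and restoring the template base at each lowercase position reproduces the
genomic substring exactly, a property the tests enforce for every read of
a 10⁴-read simulation.

Deliberate simplifications, and what they imply for interpreting results:
substitution-only errors (indels would break the position-preserving
lowercase convention), single-end reads from both strands, no GC or PCR
bias, no chimeras, and linear read placement even though the coverage
model is circular — a mismatch confined to read-length-scale effects at
genome ends. Simulated data therefore exercises pipelines' handling of
error rates, abundance skew and taxonomic composition, not
platform-specific artefact spectra.

## The Monte-Carlo oracle

`simulate_gap_counts()` runs the coverage model forward with continuous
(real-valued) arc positions and counts gaps by sorting starts and merging
arcs around the circle, exact touching counting as covered (a measure-zero
choice, consistent with the continuous model). `mc_validate()` compares
empirical gap frequencies with the series over a 45-cell grid
($R \in \{1,2,3,5,10\}$, $\varphi \in \{0.3,0.6,0.9\}$,
$\alpha \in \{0.25,0.5,1\}$) at $2\times10^5$ trials per cell, requiring
agreement within four binomial standard errors for $k \le 3$; the
empirical proportion in the band is floored at one count so that
probabilities below the Monte-Carlo resolution are not compared against a
zero-width band.

## Problem sizes and numerical choices

The shipped tests run the full 45-cell grid at $2\times10^5$ trials, a
10⁴-read closed-loop simulation on four 3 kb genomes, 20 randomised
planner configurations against a brute-force scan, and the
$R = 10^7$ precision stress point — small enough to run in well under a
minute each, large enough that every statistical band quoted above is
meaningful. Ties and degenerate inputs are pinned down explicitly:
$R = 0$ gives $P(B=0) = 1$; $k > \eta$ gives an exactly empty sum, hence
probability 0; reads longer than the genome are truncated to it.

## Limitations

The gap count refers to an idealised assembly, not to the output of a real
assembler; abundance is a fixed per-read probability, not a draw from a
community distribution; and the planner optimises for a single rarest
target rather than jointly over all community members. The preset profiles
are starting points to edit, not measurements — inferring a profile from a
run of the actual instrument is always preferable.
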