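---
title: "Predicting and screening proteasome-generated spliced peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and screening proteasome-generated spliced peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pspfinder)
```

## The model

A substrate polypeptide of length $L$ with residues $a_1 \dots a_L$ is
digested by purified 20S proteasomes. Hydrolysis yields contiguous cleavage
products $\mathrm{PCP}_{ij}$ (residues $i..j$, $1 \le i \le j \le L$);
transpeptidation at the active-site threonine can ligate any two such
fragments into a spliced product $\mathrm{PSP}_{i\text{-}j/k\text{-}n}$,
with loss of one water:
$M_r(\mathrm{PSP}) = M_r(\mathrm{PCP}_{ij}) + M_r(\mathrm{PCP}_{kn}) -
M_{\mathrm{H_2O}}$. Only fragments of length $\ge L_{ext}$ participate
(default $L_{ext} = 2$; digests screened with $L_{ext} = 1$ yielded no
identifications in practice, and the combinatorial cost explodes).

Classification of an ordered pair on one substrate:

* **cis-normal** — fragments in substrate order with a gap of at least one
  residue, $k \ge j + 2$;
* **cis-reverse** — the second fragment lies entirely before the first,
  $i \ge n + 1$ (direct adjacency $i = n+1$ included);
* **trans** — everything else: overlapping coordinates or self-pairing,
  which force the two fragments to come from two separate substrate
  molecules. Cross-molecule pairs in a two-substrate (light/heavy)
  enumeration are trans by definition.

Native-adjacent pairs ($k = j + 1$, same substrate) are excluded by default:
their spliced sequence is letter-identical to the cleavage product
$\mathrm{PCP}_{in}$ and cannot be distinguished by MS. A flag restores them,
in which case they classify as trans (they can arise that way from two
molecules).

With $M = L - L_{ext} + 1$ and $U = L - 2L_{ext} + 1$ the closed forms are

$$n_{PCP} = \binom{M+1}{2},\quad
  n_{cis\text{-}norm} = \binom{U+2}{4},\quad
  n_{cis\text{-}rev} = \binom{U+3}{4},\quad
  n_{adj} = \binom{U+2}{3},$$

and $n_{trans} = n_{PCP}^2 - n_{adj} - n_{cis\text{-}norm} -
n_{cis\text{-}rev}$. The $\binom{U+3}{4}$ form follows from counting
placements of two disjoint intervals and is verified against brute-force
enumeration for every $L \in [4,16]$, $L_{ext} \in \{1,2,3\}$ in the test
suite. The cis-reverse count deliberately includes pairs whose first
fragment is the C-terminal-most $L_{ext}$-mer: one published table's index
ranges would exclude exactly those pairs, but that restriction contradicts
both the inline defining inequality and chemical plausibility, and we treat
it as an erratum. (Consequently this package reports 715 cis-reverse
quadruples for $L=13$, $L_{ext}=2$.)

## Masses, m/z and labels

Monoisotopic residue masses are used by default: 12 of the 15 published
product masses reproduce at 2 decimals from them, and the remaining three
are internally inconsistent in the source table (one matches the [M+H]$^+$
instead of $M_r$, one the average mass) — they are excluded from exact
checks. m/z of a protonated peptide is $(M_r + z\,p)/z$ with $p = 1.00728$
Da, $z = 1..3$; the package exposes an `"integer"` convention ($p = 1$)
because low-resolution work sometimes uses it — differences stay below
0.03 m/z for $z \le 3$. Cysteine is left unmodified (substrates are
synthetic peptides, not alkylated tryptic digests); fixed modifications can
be expressed as label offsets.

Stable-isotope heavy analogues (e.g. $^{13}$C$_6$-Lys $+6.02013$ Da,
$^{15}$N-Leu $+0.99703$ Da) are modelled as per-position mass offsets. In a
mixed light/heavy digestion each splice product exists in four variants —
light/light, light/heavy, heavy/light, heavy/heavy — spaced by $0$,
$\Delta_2$, $\Delta_1$, $\Delta_1+\Delta_2$, where $\Delta_f$ sums the
offsets inside fragment $f$. The mixed variants can only be assembled from
two distinct molecules, so observing them demonstrates trans splicing.

b/y fragment ions follow the usual conventions ($b_i$ = prefix + proton,
$y_i$ = suffix + water + proton, neutral losses of water "°" and ammonia
"\*"); the y series includes $y_L$, the intact [M+H]$^+$.

## The theoretical database and clustering

All products and their per-charge m/z values form the screening database.
Because an ion trap with 0.5-Da accuracy cannot distinguish the many
near-coincident theoretical values, m/z values are clustered into groups
spanning at most 0.2 Da. The published method does not specify the
algorithm or the representative; we chose greedy left-to-right grouping
over the sorted values (deterministic, $O(n\log n)$, guarantees the span
bound) with the arithmetic mean as representative ("average" being the
published wording); fixed-width binning is available by configuration.
Clusters are built over PSP entries only by default — the published
candidate counts count PSP clusters — with a flag to include PCP. A
guardrail refuses substrates longer than 60 residues unless overridden,
since the database grows $O(L^4)$.

## MS1 screening and kinetic filtering

Inputs are centroided MS1 peak lists per digestion time point (CSV with
`mz, rt_min, intensity, digestion_time`, or MGF pseudo-spectra), including
the $t = 0$ control. The four screening stages only ever shrink the
candidate set:

1. a cluster is *matched* if any observation falls within ±0.5 Da
   (instrument accuracy) of its representative;
2. for each matched cluster an extracted ion chromatogram is built on a
   0.1-min RT grid (pooled over time points, max intensity per bin) and
   local maxima with apex $> \delta \times$ noise are kept, $\delta = 2$.
   The noise estimator is unspecified in the source; we use the median of
   the chromatogram, bounded below by a small floor (1 intensity unit) so
   that silent chromatograms do not divide by zero;
3. each (cluster, RT apex) defines a kinetic trace: per digestion time the
   maximal intensity within the m/z tolerance and ±1 min of the apex, zero
   when absent;
4. a trace survives iff its $t=0$ intensity is strictly below MAX
   ($10^7$; contaminants are present before digestion) and it rises
   monotonically to its maximum — real data need a tolerance, so a relative
   dip of $\varepsilon = 5\%$ per step is allowed
   ($I_{s+1} \ge (1-\varepsilon) I_s$) — with any subsequent decline
   required to be monotone ($I_{s+1} \le (1+\varepsilon) I_s$) and accepted
   only when the assay permitted re-entry of released products. Whether MAX
   compares strictly was unstated; we use strict `<`. $t_{max}$ is the
   digestion time of maximal intensity, earliest time on ties.

Surviving candidates are grouped by $t_{max}$; each group of size
$D_g > D_{max}$ (= 15) is split into $\lceil D_g/D_{max}\rceil$ balanced
subgroups (sizes differing by at most one — a group of exactly 15 stays
whole, reading "smaller than $D_{max}$" as a cap of $\le D_{max}$ per run).
Groups count the extra up-scaled digestions, subgroups the targeted MS
runs. Inclusion entries carry a configurable ±1-min RT window (the source
does not state how windows were derived). Final confirmation against a
synthetic peptide uses $|\Delta RT| < 0.5$ min, strict.

## The synthetic-data generator

`simulate_digest()` emulates the time-course peak lists of an in vitro
digestion so the whole pipeline is testable offline:

* **planted products** follow $I(t) = A(1 - e^{-k_{in} t})$ (saturating
  production; zero at $t=0$) or, modelling re-entry,
  $A(e^{-k_{out}t} - e^{-k_{in}t})$. Defaults $A = 5\times10^6$,
  $k_{in} = 0.4\,\mathrm{h}^{-1}$ on a 0/1/2/4/8/24-h grid spanning the
  20-min-to-48-h assay range — values chosen once as typical for such
  digests and documented here; intensities are scaled to interact
  meaningfully with MAX $= 10^7$;
* **contaminants** have constant intensity from $t = 0$ on;
* **decoys** occupy random m/z at least 1.5 Da from every planted signal
  and carry alternating (zig-zag) intensity profiles — chemical noise with
  no digestion kinetics, rejected with certainty by the monotonicity
  criterion;
* retention times come from a Kyte–Doolittle hydropathy sum mapped onto the
  LC gradient with small jitter — arbitrary but reproducible (real RTs are
  empirical);
* one seed fixes all randomness; identical configurations produce
  byte-identical files.

What a green synthetic test establishes: the screening logic (matching,
peak detection, kinetic criteria, grouping) behaves exactly as specified on
data whose ground truth is known. What it does not establish: performance
on real chromatograms with isotope envelopes, co-eluting chimeras, drifting
RT or structured noise — none of which the generator attempts to model.
The published per-step candidate counts for real digests depend on the
authors' raw LC-MS data and are not reproducible at desk scale; the test
suite substitutes the corresponding properties (monotone shrinkage, full
recall of well-behaved planted products, full rejection of $t=0$
contaminants, subgroup caps).

## Numerical and design choices

* Coordinates are 1-based inclusive; enumeration order is lexicographic
  over $(i, j, k, n)$ for reproducibility.
* The published total of "5664 PSP" for the 13-mer is not derivable from
  the documented conditions under any adjacency convention we tried
  (exhaustive enumeration gives 5864 with native-adjacent pairs excluded);
  brute force under the documented conventions is treated as ground truth.
* Printed masses are compared after round-half-even to the printed
  precision (2 d.p. for $M_r$, 1 d.p. for the ion-trap m/z).
* Self-pairing (a fragment ligated to a second copy of itself) is allowed
  and is trans.
* Degenerate inputs: `l_ext > L` yields an empty enumeration with a
  warning; traces with fewer than two time points are rejected with a
  warning; empty databases export valid empty FASTA.

## Known limitations

Whole-proteome databases are out of scope (the $O(L^4)$ growth makes
substrates beyond ~60 residues impractical without restricting rules);
MS/MS scoring is delegated to external engines via the exported FASTA;
isotope envelopes and RT prediction are not modelled.
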