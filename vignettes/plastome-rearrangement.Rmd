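---
title: "Repeat-mediated plastome rearrangement: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-mediated plastome rearrangement: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeSV)
```

## The biological model

Most angiosperm plastomes are circles of 120–160 kb with a quadripartite
layout: a large single-copy region (LSC), a small single-copy region
(SSC), and two identical inverted-repeat copies (IRb, IRa) separating
them. Because the IR copies are perfect reverse complements, the molecule
continually interconverts between two *flip-flop isomers* that differ only
in SSC orientation; neither is "the" genome, so this package fixes a
deterministic canonical form (below) rather than pretending one isomer is
real.

Short repeats are common in plastomes, and a short *inverted* pair inside
the LSC is a recombination substrate. Writing the arms as `r` and
`r* = revcomp(r)`, the pair partitions the LSC into

* **area A** — LSC start through the end of the left arm (arm included),
* **area B** — the spacer between the arms,
* **area C** — the start of the right arm through the LSC end (arm
  included),

so that `|A| + |B| + |C| = LSC` exactly. Crossovers at this pair generate
a family of alternative circular conformers:

1. **B-inversion** — intramolecular crossover; area B is
   reverse-complemented in place, size unchanged.
2. **Intermediate dimer** — intermolecular crossover between two parent
   circles; a single head-to-head fused circle of twice the parent size.
3. **A-type** (the IR-expansion product) and **reciprocal** — the dimer
   resolved by a second crossover at the two direct-orientation large-IR
   copies it contains. The A-type carries area A duplicated into the IR
   (`IR' = IR + |A|` per copy), retains B as a minute residual single-copy
   region, and has lost area C entirely; the reciprocal is its
   mass-conservation mirror (C duplicated, A lost). Their sizes satisfy
   `size(P1) + size(P2) = 2 × parent` identically.
4. **Flip-flop isomer** — intramolecular crossover at the large IR; the
   SSC inverts.

A deleted area C can carry genes; the A-type's gene complement is the
parent's minus every gene overlapping C (by ≥ 1 bp), plus a duplicate of
every gene wholly inside A. Boundary-spanning genes are reported
separately as disrupted, never silently reclassified.

Because tissues can contain conformer mixtures, existence and abundance
are read-level questions:

* a conformer-diagnostic **junction** is supported by reads covering its
  breakpoint core plus a minimum overhang on both sides;
* on the parent reference, `depth(area C)` estimates the parent
  conformer's depth and `depth(SSC) − depth(area C)` the rearranged
  conformer's, because C is private to the parent while the SSC is
  single-copy in both. Proportions follow by normalization.

## Conventions the numbers depend on

**Coordinates.** Internally 0-based half-open on the canonical
linearization; every file and printed report converts to 1-based
inclusive (BED output stays 0-based half-open, as BED requires).

**Canonical form.** Detection rotates the circle so the LSC starts at
position 0 with region order LSC→IRb→SSC→IRa, and, of the two flip-flop
isomers, keeps the one whose SSC forward strand is lexicographically
smaller. This makes detection of any rotation of the same molecule return
a byte-identical object — the property the round-trip tests rely on.
The longer single-copy region is labelled LSC by default; an explicit
homology override (`ssc_ref`) exists because in heavily rearranged
conformers the homolog of the LSC can be *shorter* than the SSC, and
labels should follow homology, not length, when comparing conformers.

**Crossover bookkeeping.** Breakpoints sit at the arm's left edge and one
arm copy survives in each product. This is the only bookkeeping under
which the partition arithmetic (`|A| + |B| + |C| = LSC` with arms inside
A and C, `IR' = IR + |A|`) is exact, which is why it was chosen. Which
physical arm copy survives is not observable (the arms are identical), so
the emitted linearizations are conventions: each resolution product is
written on the strand where the parent SSC reads forward, starting at
area A (A-type) or at `revcomp(C)` (reciprocal); the dimer is written as
the parent opened at the right arm followed by the reverse complement of
the parent opened at the left arm. The independent splice oracle uses the
same conventions, so the dual-construction test compares bytes, not
"equivalent circles".

**A surprise worth knowing about: the dimer re-detects as quadripartite.**
The head-to-head dimer is `B` and `revcomp(B)` separated by two enormous
inverted arms (`C·IRb·SSC·IRa·A` and its reverse complement), so
structure detection on it legitimately reports a two-single-copy molecule
with giant IRs rather than an ambiguity. Genuine ambiguity (two distinct
equal-length maximal IRs) is still signalled as a classed condition.

**Repeat maximality.** A reported pair can be extended neither outward
nor inward (toward each other) while preserving the orientation relation,
with overlapping arms excluded. Arms embedded in homopolymer runs admit
several shifted, equal-length maximal placements; all are reported, each
annotated with the size of its equivalence group (same orientation, arm
length and alignment diagonal), and `maximalize()` canonicalizes to the
leftmost placement. Matching is exact (no mismatches): that matches the
kind of repeat that recombines detectably and keeps the brute-force
oracle exact. One fixture is instructive: embedding the canonical arm
strings `TTTTTTTTTTC`/`GAAAAAAAAAA` in the context
`CTTTTTTTTTTCGGGAAAAAAAAAAG` yields a *12-bp* maximal pair (the flanking
C/G pair as well); the 11-bp reading is maximal only in contexts whose
boundary bases do not pair. The tests freeze the brute-force answer, not
the eyeballed one.

**Junction scoring.** A read (or its reverse complement) must align
ungapped so that the full core plus ≥ `min_overhang` bases each side lies
inside the aligned intersection, with at most `max_mismatch` substitutions
*over the whole intersection*. Scoring only the core-plus-overhang window
would be wrong in a subtle way: the short arms flanking the core are
shared between conformations, so the window `arm|core|arm*` occurs in
reads from the *other* conformation too (for the inversion junction it
occurs on the rearranged molecule's reverse strand verbatim). What
discriminates is the sequence beyond the arms, which only full-intersection
scoring sees. Related: the inversion junction's default overhang equals
the 11-bp arm length, which discriminates against parent-derived reads
(any 150-bp read extends well past the arms into mismatching flank) but
*not* against A-type-derived reads; use overhang > arm length when that
distinction matters. Defaults are 20 bp overhang (11 bp for the inversion
junction), mismatch 0 for synthetic data and 2 recommended for real
reads. Paired mates are scored independently, and a read may support
several junctions when cores share sequence — junctions are independent
hypotheses.

**Depth arithmetic.** Region means with `trim` bases (default 50)
discarded at each region end as a mapping-edge guard; area B is excluded
from depth estimation entirely because, flanked by long inverted arms, it
can form a hairpin that suppresses observed depth — a real-data artifact
this package deliberately does not model. Standard errors use an
effective sample size of region length / `corr_len` (default 150 bp,
the read length), since neighbouring positions share reads. The reference
must contain both IR copies; IR depth then halves per copy under
unique-best mapping, which never enters the arithmetic (C and SSC are
single-copy). A negative rearranged-conformer depth is floored at zero
and flagged; a deficit beyond 3 pooled standard errors (or any deficit at
zero dispersion) raises an `inconsistent` flag because it violates the
two-conformer model. Presence calls require the diagnostic depth to pass
both an absolute threshold and a z ≥ 4 guard, *or* a junction-read count
threshold; the z guard is an addition beyond the bare arithmetic, there
to keep pure-parent noise from ever being called a second conformer.

**Internal mapper, not an aligner.** Depth profiles can be ingested from
any standard three-column depth table; for self-contained simulation
work, `map_reads_depth()` places substitution-only reads by k-mer anchor
plus full-length Hamming comparison on the circular reference. It is
deliberately not indel-aware; reads from junctions absent from the
reference stay unmapped, which is exactly what the region arithmetic
assumes.

## What the synthetic world does and does not emulate

`make_toy_plastome()` draws each region i.i.d. at a stated GC (default
0.375, a typical plastome value) and plants exact arms; rejection
sampling enforces that (i) the planted short pair and the large IR are
*exactly* maximal (boundary bases that would extend them by chance are
resampled), (ii) area B is not its own reverse complement (so inversion
is observable), and (iii) at desk scale, no other inverted pair ≥
`arm_len` exists in the LSC. Defaults are |A| 600, |B| 92, |C| 500, arms
11 bp, SSC 600, IR 500 — a ~2.8-kb genome with the geometry (and the
92-bp spacer) of the motivating rearrangement, small enough that the full
suite runs in minutes. A full-scale spec (85-kb LSC, 27-kb IR) is used
in the acceptance tests for the printed arithmetic; at that scale the
uniqueness guarantee is mathematically unattainable for 11-bp arms
(spurious pairs are expected by chance), so it is switched off and the
planted pair is identified by coordinates.

`simulate_reads()` emulates 150-bp paired-end sequencing: uniform
fragment starts on each circle, normal insert sizes (350 ± 35), i.i.d.
substitution errors (default 0.1%), multinomial conformer origin with
probabilities ∝ proportion × length (so the expected depth of conformer
*i* is `depth × mixture[i]`), and full origin tags for truth evaluation.
It does **not** emulate indels, chimeras, GC-coverage bias, quality-value
structure, or the hairpin-driven depth suppression of area B. A green
test therefore establishes correctness of the *arithmetic and the
matching rules* under a clean substitution-only observation process — not
robustness to real-library artifacts, which is why the depth estimator
exposes `trim` and junction matching exposes `max_mismatch` for real
data.

Two constructions of every conformer are mandated: event-driven assembly
(fusion, resolution and inversion operators acting on the parent sequence
and coordinates) and formulaic splicing of the generator's ground-truth
pieces. They must agree byte-for-byte on every random spec; each is the
other's oracle, and the repeat finder is additionally checked against an
exhaustive `O(n³)`-style enumeration on hundreds of random sequences.

## Numerical and degenerate-input choices

* `min_arm < 4` is rejected outright (4⁻⁴ per-position chance matches
  make shorter arms noise).
* `min_ir_len ≥ 50` for structure detection; below that, "quadripartite"
  stops being meaningful.
* Mismatch-tolerant repeat detection is not implemented
  (`allow_mismatch = 0` only): the substrate of interest is exact, and
  exactness is what makes the oracles exact.
* Ties between equal-length maximal short pairs are broken by leftmost
  left arm; equal-length maximal large IRs raise an ambiguity condition
  by default (`on_ambiguity = "leftmost"` opts into determinism).
* Degenerate resolution products (empty A or C) are emitted with a
  `degenerate` flag, never suppressed; products whose lost region carries
  genes are flagged non-viable but still emitted — the undetectable
  product is part of the model and of the junction tests.
* GC fractions exclude N from numerator and denominator; an all-N region
  reports `NA`.
* Reads shorter than core + 2 × overhang can only ever count as partial
  junction evidence.

## Known limitations

Assembly, annotation generation, expression analysis and long-read
(nanopore) handling are out of scope: the package consumes an assembled
circle, an optional gene table, and short reads or a depth table. The
junction matcher is substitution-only and ungapped. Direct-repeat-mediated
deletion loops and multimer series beyond the single dimer intermediate
are not modelled. Heteroplasmy estimation assumes exactly two conformers
(parent + one rearranged form); with more, the SSC–C arithmetic returns
their aggregate.
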