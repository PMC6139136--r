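---
title: "Finding spanin genes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding spanin genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spaninscan)
```

## The problem

Spanins are the last-acting lysis proteins of phages infecting
Gram-negative bacteria: after the holin permeabilizes the inner membrane
and the endolysin degrades the peptidoglycan, the spanin disrupts the outer
membrane, most plausibly by fusing it with the inner membrane. Two designs
exist. A **two-component spanin (2CS)** couples an inner-membrane i-spanin
(a class II membrane protein with a single N-terminal transmembrane domain,
prototype lambda Rz) to an outer-membrane lipoprotein o-spanin (prototype
lambda Rz1), which interact through their C-termini across the periplasm. A
**u-spanin** does both jobs in one molecule: an N-terminal lipoprotein
signal anchors it in the outer membrane and a C-terminal transmembrane
domain in the inner membrane (prototype T1 gp11).

Spanin genes defeat standard gene callers. The o-spanin gene very often
overlaps the i-spanin gene or sits entirely inside it in a shifted reading
frame (the *embedded* architecture), and overlap-averse callers either miss
it or assign a wrong start codon. Because all of the diagnostic
signals — the transmembrane segment, the lipoprotein signal peptide, the
lipobox — are N-terminal, a wrong start makes a spanin undetectable. This
package automates a search protocol built around those two failure modes:
enumerate open reading frames exhaustively in all six frames, refine start
sites by signal validity and ribosome-binding-site evidence, and only then
type candidates by membrane topology.

## The pipeline

`call_spanins()` runs, per genome:

1. **Six-frame ORF enumeration** (`scan_orfs()`): every maximal
   stop-to-stop segment on both strands yields one candidate per admissible
   start codon (default ATG/GTG/TTG, configurable; the literature on phage
   annotation does not fix a set) at or above `min_aa` codons (default 40,
   just below the shortest o-spanins at ~45-60 aa). Candidates overlapping
   annotated genes are kept and marked `nested_in` — they are the point.
   ORFs whose translation exceeds 10% X (from N runs) are dropped as
   sequencing artifacts.
2. **Start refinement** (`refine_start()`): among sibling starts sharing a
   stop, prefer starts whose translation carries a valid membrane signal,
   ranked by Shine-Dalgarno score; with no valid start, fall back to the
   longest ORF flagged low-confidence. The SD model is a deliberately
   simple heuristic — the best ungapped match of >= 4 consecutive bases of
   AGGAGG at a spacer of 4-14 nt — because the source survey records an SD
   per gene but no model.
3. **Topology typing** (`classify_topology()`): see below.
4. **Evidence gating**: candidates not backed by any annotated CDS (pure
   six-frame recoveries) must carry SD evidence. A six-frame scan of a
   40 kb genome produces hundreds of ORF candidates, and motif-only
   lipoprotein calls on that many shots would admit spurious o-spanin
   candidates; requiring a plausible ribosome-binding site mirrors what a
   human curator checks before accepting an unannotated gene. Annotated
   genes are exempt (annotation is itself the evidence). Set
   `spanin_config(require_sd = FALSE)` to disable.
5. **Pairing and classification**: each o candidate is paired greedily (by
   ascending gap) with the nearest upstream same-strand i candidate within
   `max_gap` (default 1000 bp, after the most separated known system at
   ~1 kb; larger separations are deliberately out of reach, a limitation
   inherited from the protocol this emulates). Same-frame overlaps are not
   distinct genes and are ineligible. Each i candidate is consumed at most
   once — a spanin system is one i plus one o. Architecture is `embedded`
   (o inside i), `overlapped` (shared stretch > `sep_threshold`, default
   10 bp), else `separated`; the threshold sits between the 8 bp overlap
   the field still calls separated and the 70 bp overlaps that are clearly
   overlapped. Frame offset is `(o_start - i_start) mod 3` mapped to +1/-1,
   and the o gene position is reported in units of L, the i gene length.
   U_CAND candidates become unimolecular systems on their own.

Minus-strand arithmetic is done entirely in reading-direction coordinates
after reflection; only the final report converts back.

## Topology model

TMHMM- and LipoP-class predictors are external tools; the package uses a
self-contained, testable core instead and accepts externally computed
intervals where users prefer them.

**Transmembrane segments** are maximal runs of positions whose 19-residue
Kyte-Doolittle window mean is >= 1.6, merged across gaps of < 3, dropped
under 15 residues, and trimmed to their best 30-residue window when longer
(a single spanning helix is 15-30 residues). Window means at the termini
use truncated windows; unknown residues contribute 0.

**Lipoboxes** are searched as a Cys at residue 12-40 (lipoprotein signal
peptides are 15-40 residues; the survey text does not fix the window)
preceded by a tripeptide matching the consensus `[LVI][ASTVI][GAS]` in
strict mode. Relaxed mode also accepts tripeptides drawn entirely from
{A,L,V,I,F,G,S,T,W,M}, a definition constructed to admit the unusual but
experimentally validated boxes (AWAC, LNGC, FVGC) while rejecting
signal-less sequences. Both modes additionally demand signal-peptide
anatomy: at least one K/R in the first 7 residues (n-region), a hydrophobic
stretch of >= 6 residues from {A,C,F,I,L,M,V} (h-region) ending within 6
residues of the box, and no charged residue between that stretch and the
Cys (c-region). These composition rules are the package's reconstruction of
the survey's unenumerated "eligibility requirements"; they are isolated
behind `topology_params()` for tuning.

**Typing order** is U_CAND, then O_CAND, then I_CAND, so a lipoprotein with
a C-terminal anchor is never mistyped as an inner-membrane protein:

* U_CAND: lipobox plus a TMD wholly inside the last 35 residues;
* O_CAND: lipobox and no TMD starting after the Cys;
* I_CAND: no lipobox, exactly one TMD starting in the first 30 residues.

Sequences outside 40-350 aa are typed NONE ("length"): the gate brackets
the observed spanin range (60 aa o-spanins to ~300 aa periplasmic
complexes) and removes noise ORFs. In every branch the periplasmic domain
must additionally be soluble (mean Kyte-Doolittle index <= 0.5,
`max_peri_hydropathy`): a spanin's periplasmic domain spans an aqueous
compartment, and this solubility requirement is what rejects the
hydrophobic junk ORFs that shifted reading frames of transmembrane
segments otherwise produce — the main false-positive mode of a six-frame
scan. Real periplasmic domains sit far below the cut (around -1 to -3). The periplasmic domain is everything
C-terminal of the i-spanin TMD; for lipoproteins everything after (and
excluding) the lipoylated Cys, consistent with the prototype o-spanin whose
mature 40 aa periplasmic domain carries a distinct disulfide-bonding Cys;
for u-spanins the stretch between the Cys and the C-terminal TMD.

## Clustering

Families are connected components (single linkage, matching the behaviour
of the BLAST-based clustering tool the survey used) of the graph whose
edges join periplasmic domains sharing >= 40% identity over >= 40% of the
length. Pairwise identity comes from Smith-Waterman local alignment under
BLOSUM62 with gap open 11 / extend 1; identity is matches over aligned
columns, and the coverage rule defaults to `both` sequences (the emulated
tool's behaviour; the survey states "0.4" without naming the reference
length, so the rule is exposed as `cov_rule`). We read the survey's "score
coverage threshold ... 40" as percent identity, because its own family
definition sentence is phrased as >= 40% identity. A local score <= 0 is a
no-hit sentinel. Deep scoring matrices are unreliable on very short
alignments, so domains under 50 aa are attached afterwards
(`assign_short_sequences()`) by end-gap-free global identity under the same
40/40 rule — a deterministic replacement for the survey's manual step —
and otherwise become new singletons. Identical-sequence sets (100% identity
over 100% length, signal sequences included) are grouped by exact string
equality, which a test cross-checks against clustering at 100/100.
Representatives are the longest member, ties lexicographic (the survey
bolds representatives without stating its rule).

## Cysteine and lipobox statistics

Periplasmic cysteines mediate the intermolecular disulfide bonds that
stabilize 2CS complexes, so `cysteine_counts()` counts Cys strictly inside
each periplasmic domain (the lipoylated Cys is excluded by the domain
definition — appending a lipobox to a sequence never changes its count).
`cysteine_positions()` reports, per component, the distance of the closest
Cys to the membrane anchor and to the C-terminal interaction interface as
percent of that component's periplasmic length, and, for the complex, the
distances to the inner and outer membrane in a joint coordinate built as
the i domain (IM end first) followed by the reversed o domain (OM end
last). The survey speaks of "entire periplasmic sequences of the spanin
complexes" without giving the construction; this one is recorded here and
isolated so alternatives can be recomputed. Distances are `pos - 1` from
the N side and `len - pos` from the C side, so a boundary Cys is at 0%.
`lipobox_pfm()` emits the 20 x 4 position-frequency matrix over the three
pre-Cys residues plus the Cys — the numeric form of a sequence logo; logo
rendering is out of scope. `db_summary()` aggregates architecture and
frame counts, how often the i-spanin is the longer component, the extremes
of combined periplasmic length, and the o-gene relative-start histogram in
0.1 L bins (the granularity at which the embedded pattern — starts at
~0.4-0.5 L, ends at 0.9-1 L — is described).

## The synthetic-genome generator

`simulate_genome()` provides the study conditions for every benchmark in
the package. Per genome it plants, by default, one embedded, one
overlapped, one separated and one unimolecular system plus five decoys (a
lone lipoprotein with no i-spanin partner, then alternating soluble and
two-TMD membrane proteins), each on a random strand, separated by random
spacers of 120-350 nt. The mixes are scientist-chosen to exercise every
code path at realistic values: +1/-1 frames at 0.5 each (the survey found
no significant frame bias), lipoboxes at LSGC 0.6 / LAGC 0.2 / AWAC 0.2
(consensus boxes dominate real databases, with a minority of AWAC-class
boxes), i-spanin cysteine counts 0-3 and o-spanin 0-2 with (0, 2) most
common, overlaps of 30-200 bp and separated gaps of 20-880 bp.

Embedded and overlapped genes are genuinely dual-coding: the o gene
(protein fixed first) is reconciled into the i-spanin frame by searching
synonymous-codon space until the i frame reads through it without stops,
without unplanned cysteines and without hydrophobic runs that would fake a
second TMD; for overlapped systems the i-spanin stop codon itself is forced
inside the o gene by the same synonym search. When a bounded search fails,
the builder redraws the periplasmic tail. A planted ribosome-binding site
(AGGAGG at spacer 7) precedes every gene — inside the i-spanin coding
sequence where the o gene requires it. Annotation deliberately omits
embedded o genes and moves 20% of annotated starts to an alternative
in-frame start codon, so the caller's recovery and refinement paths are
exercised, not just its happy path. Every constructed gene is validated to
classify to its planted type before being placed — the generator's
contract is that the truth table is true.

What the simulator does **not** emulate: realistic phage codon usage and
GC content, gene density and operon structure, sequencing error beyond
start perturbation, holin/endolysin context, and homology between systems.
Passing the recovery benchmark therefore demonstrates that the decision
rules are mutually consistent and complete over the architectures, not
that real-genome sensitivity is 100%; on real data the topology heuristics
(vs TMHMM/LipoP) and the SD gate are the limiting factors.

## Numerical and procedural choices

* Internal coordinates are 0-based half-open on the forward strand;
  GenBank/GFF3 I/O converts from 1-based inclusive. ORF candidate
  intervals exclude the stop codon (so translation round-trips exactly);
  gene intervals in reports include it, matching annotation convention.
* GTG/TTG-initiated ORFs keep their literal translation (V/L initiator)
  so the translation invariant holds exactly.
* Spliced (`join()`) CDS features are skipped with a warning; they do not
  occur in the phage genomes of interest.
* Pairing ties (two i candidates at the same gap) resolve to the nearest
  upstream start and are flagged `ambiguous` rather than silently decided.
* The frame-exhaustive lipoprotein scan (`all_frame_lipoprotein_scan()`)
  refuses genomes over 50 kb unless forced, the conventional limit for
  exhaustive all-frame inspection.
* Benchmarks in the test suite use 50 simulated genomes (~6-8 kb, ~200
  ORF candidates each) and 200 random clustering instances — sizes at
  which the brute-force oracles are still exact and the whole suite runs
  in a few minutes on a laptop. The acceptance script clusters the
  i-spanin domains recovered from 20 genomes (~60 sequences, ~1800
  alignments); all-against-all alignment is quadratic and 60 domains
  already exercise every clustering rule.

## Known limitations

* Hydropathy windowing is cruder than TMHMM's HMM; marginal TMDs
  (Ala-rich, interrupted) can fall under the run-length floor. The
  override table hook accepts externally computed TMD/lipobox calls.
* The SD gate trades sensitivity for precision on unannotated candidates;
  genes with non-canonical or absent SD sites and no annotation are
  missed by design unless `require_sd = FALSE`.
* Systems separated by more than `max_gap` are not paired, and type I
  (N-out) inner-membrane proteins or outer-membrane beta-barrel proteins
  acting as spanins are outside the model entirely.
* Lysis-cassette proximity is not used as evidence either way; it is
  rhetorical context in the field, not a stated filter, so the caller
  neither requires nor rewards it.
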