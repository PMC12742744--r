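---
title: "crisprdesk: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crisprdesk: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprdesk)
```

## Overview

`crisprdesk` designs SpCas9 guide RNAs for a gene of interest against a
reference genome. The pipeline has four scientific stages — candidate
extraction, genome indexing, off-target assessment, on-target assessment —
wrapped in an event-driven orchestration engine that mimics a
serverless execution contract (queues, stateless batch workers, resource
limits, idempotent redelivery, scale-from-zero) on a single machine. This
vignette documents the models, the tunable parameters, and the decisions
taken where the design was genuinely open.

## Candidate extraction

A candidate target site is any 23-mer whose last two bases are `GG`: a
20-nt spacer followed by the `NGG` protospacer-adjacent motif that SpCas9
requires. Both strands are scanned; a reverse-strand site (pattern
`CC·N21` on the forward strand) is reported as its reverse complement so
every stored target ends in `GG`. Three conventions matter and are fixed
package-wide:

* **Every offset is tested.** Overlapping sites are biologically distinct
  cut sites, so the scanner never skips past a match the way a default
  regular-expression engine would (the implementation uses a zero-width
  lookahead; the test oracle uses a character-by-character scan).
* **Coordinates are 0-based, half-open, on the forward strand.** A
  reverse candidate's `start` is the start of its forward-strand
  footprint. This matches BED conventions, and the BED export uses
  `start, start + 23` directly.
* **Sites containing N are excluded entirely.** The 2-bit spacer encoding
  used downstream has no representation for ambiguity codes; I/O keeps N
  lossless and the policy is applied in exactly one place (extraction).

Gene candidates are assessed per locus — two loci sharing a spacer are two
rows in the results. Genome-wide spacers, by contrast, are deduplicated
into a `spacer → occurrence count` table before indexing, because the
index is a property of the sequence set, not of the loci.

## The ISSL off-target index

Off-target assessment must find, for a query spacer $s$, every indexed
spacer $t$ with Hamming distance $d(s,t) \le m$ (default $m = 4$;
insertions/deletions are out of scope). Spacers are packed 2 bits per base
(A=0, C=1, G=2, T=3, leftmost base most significant), giving 40-bit
integers that are carried as R doubles (exact below $2^{53}$) and handled
as `uint64_t` in the compiled core.

The inverted signature slice list cuts each encoded spacer into
`num_slices` equal slices and builds, per slice position, a table from
slice signature to the list of spacers carrying it. If
`num_slices` $\ge m + 1$, a neighbour within $m$ mismatches must agree
with the query on at least one whole slice (pigeonhole), so the union of
exact-signature bucket members is a superset of the Hamming ball;
verifying each gathered candidate's full distance (XOR, fold bit pairs,
popcount) yields the ball exactly. The package default is **5 slices × 4
bases**, the minimal configuration with the exact-recall guarantee at
$m = 4$; `num_slices` must divide 20, and queries refuse `max_mm >=
num_slices` rather than silently losing recall. Query results are sorted
by `(distance, encoded value)` so ties break deterministically.

The index serializes to a documented little-endian binary layout (magic,
version, geometry, values, counts, per-slice tables) and reloads
bit-exactly; a plain-text dump exists for debugging. At desk scale
(genomes up to tens of megabases) the index is built in memory; disk-
mapped builds for gigabase genomes are a non-goal.

## Off-target scoring

A single off-target hit $h$ with mismatched positions $\mathrm{mm}(h)$
scores

$$\mathrm{hit}(h) = 100 \prod_{p \in \mathrm{mm}(h)} (1 - w_p),$$

with position 1 at the 5' end and position 20 PAM-proximal. Two weight
modes exist:

* `"literature"` (default): the Hsu et al. (2013) experimentally derived
  per-position tolerance vector, embedded as `MISMATCH_WEIGHTS_HSU`.
  Seed-region (PAM-proximal) mismatches carry large weights and suppress
  a hit's score strongly; distal mismatches barely matter.
* `"uniform"`: $w_p = 0.5$ everywhere, so hit scores are the closed forms
  100, 50, 25, 12.5 … for 0–3 mismatches. Every scoring test value in the
  package is computable by hand in this mode.

Per guide, hits aggregate as
$S = 10000 / (100 + \sum_h \mathrm{hit}(h))$, giving $S \in (0, 100]$
with 100 meaning "no off-target found". **Exactly one** distance-0
occurrence is discounted as the guide's own on-target site; every
additional exact copy counts as a full-strength off-target, because a
guide whose spacer occurs twice in the genome is unsafe and must be
penalized (one duplicate halves $S$ to 50). A guide absent from the
genome has no self-hit to discount and is scored on its neighbours alone.
Adding an occurrence can never raise $S$ (monotonicity; property-tested).

The aggregation formula and both weight modes are this package's own
design: they follow the classical multiplicative-penalty single-hit /
harmonic aggregation family that off-target scorers in this field use,
chosen so that the no-off-target, one-duplicate and two-duplicate cases
have exact closed forms.

## On-target consensus

Each candidate is evaluated by three independent boolean methods and
accepted when at least `consensus_threshold` (default 2 — the minimal
majority rule) pass:

1. **G20**: the PAM-proximal spacer base is G.
2. **Composition**: GC fraction within [0.30, 0.70] (inclusive) and no
   `TTTT` run (poly-T terminates Pol III transcription of the guide).
3. **Structure**: no two non-overlapping substrings of length ≥ 6 that
   are exact reverse complements (a self-hairpin proxy). Checking length
   exactly 6 suffices, since any longer complementary pair contains a
   non-overlapping length-6 pair; the implementation scans all
   15 × 15 position pairs.

These three are deliberately simple, documented stand-ins: the consensus
*architecture* (independent methods, majority vote, per-method booleans
always recorded for auditability) is the load-bearing part, and
`assess_ontarget(methods = ...)` accepts any substitute list of
functions. Trained efficacy models and thermodynamic folding are
non-goals. All three methods are pure functions of the spacer — position
and strand never change a verdict (property-tested). All three always
run; no short-circuiting, so results are audit-complete.

## Orchestration

The engine reproduces, in one process, the execution contract of an
event-driven serverless pipeline:

* **Jobs** move `submitted → preparing_genome → indexing → assessing →
  complete`, with `failed` reachable from any non-terminal state.
  Submission is asynchronous: it persists the job, enqueues one
  genome-preparation event, and returns an opaque id. Jobs are never
  deduplicated.
* **Genome ingest**: a registered genome file is byte-range partitioned
  by `plan_chunked_fetch` — one "megabyte" is $2^{20}$ bytes and the
  default chunk is $50 \cdot 2^{20}$, matching the threshold above which
  splitting begins; the threshold is strict ("larger than"), so a file of
  exactly one chunk is fetched whole. Both constants are config-exposed
  since decimal-vs-binary and portion size are conventions, not physics.
  Portions arrive in any order and are merged by range before parsing, so
  no site can straddle a chunk boundary. Fetching goes through a
  pluggable `function(label, start, end) → bytes` contract; the package
  ships a local-file implementation, and a remote/accession fetcher is an
  extension point rather than a dependency.
* **Caching / warm runs**: genome and index are cached per label; a
  second job against the same genome enqueues no fetch or build tasks.
* **Assessment**: each of the $n$ candidates is posted once to the
  `ontarget` queue and once to the `offtarget` queue. Off-target messages
  carry candidate references, not index copies — the index is a shared
  read-only store, as a stateless worker design requires.
* **Workers** consume batches (per-queue defaults: fetch 1, build 1,
  on-target 100, off-target 10 — all configurable, since the right size
  is task-dependent). The idempotency key is `(queue, payload)`: a
  redelivered message is dropped without effect, which the
  `duplicate_delivery` stress mode exercises by delivering everything
  twice. Handler errors requeue with an incremented delivery count up to
  `retry_cap` (default 3, required for terminating failure semantics),
  then fail the affected job(s) with a recorded cause. A batch that would
  exceed `max_task_seconds` (default 900 s) stops and leaves the rest
  queued.
* **Schedule invariance**: because results are keyed by candidate and
  sorted on retrieval, the results table is byte-identical across batch
  sizes, worker counts, and duplication — verified end-to-end in the
  tests. "Workers" here vary the round-robin interleaving of queue
  draining; real parallel execution is a non-goal, the invariance of
  results under re-ordering is the property that matters.
* **Scale-from-zero**: draining returns immediately on empty queues;
  instrumentation counters verify that zero batches run when no work
  exists.
* Partial results are exposed before completion, flagged by
  `both_complete`; progress fractions are monotone under any
  interleaving. A completed job with zero candidates reports progress 1
  by convention.

The job store, queues, and result store sit behind the engine handle so
the same handlers could bind to real queue/database services; the local
binding is in-memory with an RDS snapshot (`save_engine`) that lets the
command-line interface span invocations. An HTTP facade is not provided —
the R functions and the CLI are the interface.

## Synthetic data

The fixture generator emulates the benchmark inputs the pipeline is
designed around, and every artefact is a pure function of its spec and
seed:

* `generate_genome`: i.i.d. bases with $P(G)+P(C)$ equal to the requested
  GC fraction (default 0.5; a 100 kb genome lands within ±2% of the
  target). Planted entries overwrite the background with
  `spacer + "TGG"`, mutated at exactly the requested number of positions;
  since each mutation hits a distinct position and changes the base, the
  planted Hamming distance is exact by construction and is re-verified by
  direct count before use.
* `plant_offtarget_family`: plants sites at exact distances
  around a query spacer on a non-overlapping grid — the input for index
  recall tests with known ground truth.
* `generate_gene_with_exact_guides(n)`: concatenates `n` blocks of
  `spacer + "TGG"` where spacers are rejection-sampled to contain no
  `GG`/`CC` dinucleotide and not start with G. Under those constraints
  each block's PAM is the only `GG` occurrence it introduces (including
  across junctions) and the sequence contains no `CC`, so extraction
  finds exactly `n` forward candidates and no reverse ones. The extractor
  itself re-verifies the count before the sequence is returned — the
  construction was chosen precisely because its exactness is checkable by
  the component it feeds.

What the generator does **not** emulate: repeat structure, segmental
duplication, chromosome-scale organization, and realistic GC
heterogeneity. Passing tests therefore demonstrate algorithmic
correctness (exact recall, exact counts, schedule invariance) on
homogeneous backgrounds, not performance or guide-quality claims on real
genomes — on which repetition and GC content substantially change the
number of sites and neighbours.

## Numerical and degenerate-input choices

* 40-bit encoded spacers travel as doubles across the R/C++ boundary
  (exact; R integers are 32-bit).
* Query results and result tables have total, deterministic orderings
  (`(distance, value)` and `(record_id, start, strand)` with `+` before
  `-`).
* Empty gene → the job completes with zero results; empty sequence or
  sequence shorter than 23 nt → zero candidates, no error.
* A genome with no targetable site yields no index; off-target
  assessment then reports an empty neighbour set and specificity 100.
* FASTA parsing is lossless (U→T, other non-ACGT→N, case-folded) with
  distinct named errors for missing file, zero records, and a header with
  no sequence; gzip is detected by magic bytes, not extension.
* The index build refuses empty spacer sets, zero counts, and duplicate
  spacers; encoding refuses N.

## Problem sizes

The test suite and acceptance script use a 20 kb indexed genome with 200
queries × 5 mismatch bounds for exact-recall verification, 1000 random
1 kb sequences against the naive extraction oracle, a 10 kb genome with a
25-guide gene for end-to-end schedule invariance, and artificial genes up
to 10,000 guides. These sizes exercise every code path (multi-chunk
ingest is forced by shrinking `chunk_bytes`) while keeping the full suite
under two minutes of the checks' own budget-scale; the algorithms contain
nothing size-dependent beyond memory.

## Known limitations

* Hamming distance only: bulges (insertions/deletions) and PAM-variant
  off-targets are not modelled.
* The three on-target rules are heuristics; the consensus architecture is
  the contribution surface, the rules are replaceable defaults.
* Single-process execution; concurrency is simulated as interleaving.
* In-memory index; genomes are bounded by RAM, not by streaming design.
* The remote genome fetcher is a contract, not an implementation —
  accession-based retrieval requires supplying a fetcher.
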