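# crisprdesk

Desk-scale CRISPR-Cas9 guide RNA (gRNA) design: candidate discovery,
genome-wide off-target assessment, consensus on-target filtering, and an
event-driven orchestration engine — all runnable on a single workstation,
with no cloud account and no network.

## The problem

Choosing a good SpCas9 guide means balancing two properties that must be
evaluated per genome:

* **On-target activity** — will the guide cut its intended site
  efficiently? `crisprdesk` scores each candidate with three independent
  rule-based methods (PAM-proximal G, GC/poly-T composition, a
  self-hairpin heuristic) and accepts a guide when at least 2 of 3 agree.
  The methods are pluggable stand-ins behind a common interface; any
  function from spacer to TRUE/FALSE can be substituted.
* **Off-target activity** — could the guide cut elsewhere? For a spacer
  *s*, every genomic 20-mer *t* adjacent to an NGG PAM with Hamming
  distance d(s,t) ≤ 4 is a potential off-target. `crisprdesk` finds them
  all, exactly, with an **inverted signature slice list (ISSL)** index:
  each 2-bit-encoded spacer is cut into 5 slices of 4 bases; a query
  within 4 mismatches must match at least one slice signature exactly
  (pigeonhole), so gathering slice buckets and verifying the full distance
  gives exact recall. Hits aggregate into a specificity score

      S = 10000 / (100 + Σ_h 100·Π_{p ∈ mm(h)} (1 − w_p))   ∈ (0, 100]

  where the product runs over mismatched positions of hit *h* and `w` is
  either the Hsu et al. (2013) position-weight vector (default) or a
  uniform 0.5 (closed-form testing mode). S = 100 means no off-target was
  found; one additional exact genomic copy halves it to 50.

Candidate sites are every 23-mer matching `N20·NGG` on either strand
(overlaps included, N-containing sites excluded), per the conventional
SpCas9 protospacer-adjacent-motif rule.

The pipeline itself reproduces a serverless execution contract locally:
jobs go into a store, stages communicate through message queues
(`genome_fetch`, `index_build`, `ontarget`, `offtarget`), stateless
batch workers drain them under resource limits (15-minute batch budget,
configurable batch sizes, retry caps), genomes above 50 MB are ingested as
byte-range portions and merged, re-delivered messages are idempotent
no-ops, and nothing runs while the queues are empty. Results are
byte-identical regardless of batch size, worker count, or message
duplication.

## Worked example

```r
library(crisprdesk)
set.seed(42)

# a gene with exactly six guide sites
gene <- generate_gene_with_exact_guides(6, seed = 7)

# a 50 kb genome containing the gene, plus a planted off-target family
# (one duplicate, one 2-mismatch and one 3-mismatch site) around the
# first guide's spacer
first_spacer <- extract_candidates(sequence_record("gene", gene))$spacer20[1]
spec <- genome_spec(50000, gc_fraction = 0.45, seed = 7)
spec <- plant_offtarget_family(spec, first_spacer, distances = c(0, 2, 3))
rec  <- generate_genome(spec)
genome_path <- tempfile(fileext = ".fa")
write_fasta(genome_assembly(list(
  sequence_record("chr1", paste0(gene, rec$sequence)))), genome_path)

res <- design_guides(gene, genome_path)
res[, c("start", "strand", "accepted", "consensus_votes",
        "specificity", "mm0", "mm2", "mm3")]
```

```
  start strand accepted consensus_votes specificity mm0 mm2 mm3
1     0      +     TRUE               2       36.11   2   1   1
2    23      +     TRUE               2      100.00   1   0   0
3    46      +    FALSE               1      100.00   1   0   0
4    69      +     TRUE               2      100.00   1   0   0
5    92      +     TRUE               2      100.00   1   0   0
6   115      +     TRUE               2      100.00   1   0   0
```

Guide 1 sees its planted family: two exact genomic copies (`mm0 = 2` —
one is its own on-target site, the other an unsafe duplicate) plus one
site at 2 and one at 3 mismatches, dragging its specificity down to 36.1.
The other guides occur once in the genome (`mm0 = 1`, the self-hit) and
score a clean 100. Guide 3 fails the on-target consensus (1 of 3 votes),
so it is rejected regardless of specificity.

The same run works asynchronously and from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/crisprdesk.R", package = "crisprdesk"))')
Rscript $CLI submit  --gene gene.txt --genome genome.fa --state-dir st
Rscript $CLI run     --state-dir st --workers 4
Rscript $CLI status  job-xxxxxxxx-0001 --state-dir st
Rscript $CLI results job-xxxxxxxx-0001 --state-dir st --format csv
```

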