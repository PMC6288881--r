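---
title: "Three-letter bisulfite alignment: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-letter bisulfite alignment: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylign)
```

## The problem

Sodium bisulfite converts unmethylated cytosine to uracil, which is sequenced
as thymine; methylated cytosines are protected. A bisulfite read therefore
differs from its genomic origin at every unmethylated C, and a conventional
aligner scores each of those positions as a mismatch. The three-letter
strategy removes the asymmetry by collapsing the alphabet on *both* sides
before alignment and restoring the full alphabet afterwards for methylation
calling.

## The model

**Genome preparation.** The reference is transformed four ways: the Watson
strand and its reverse complement (Crick), each under C→T and G→A
conversion, giving the converted genomes W-CT, W-GA, C-CT and C-GA. Crick
genomes are stored in Crick orientation; a hit at Crick offset $p_c$ on a
sequence of length $n$ lifts to Watson coordinate $n - p_c - L$ for a read of
length $L$.

**Read transformation and mapping.** Each read is converted in silico to its
CT and GA forms, keeping the original sequence alongside. In a
non-directional library (reads from all four bisulfite strand origins OT, OB,
CTOT, CTOB) the candidate pairs are (CT, W-CT), (CT, C-CT), (GA, W-GA),
(GA, C-GA); a directional library uses only the two CT pairs. Alignment is
ungapped and end-to-end in converted space: exact $k$-mer seeds at read
offsets $0, k, 2k, \dots$ propose placements, each verified by full-length
Hamming comparison against the converted genome with early abort beyond the
mismatch cutoff. By the pigeonhole principle every placement with at most
$\lfloor L/k \rfloor - 1$ mismatches is found, and 0-mismatch recall is
exactly 1; placements with more mismatches than that bound may be missed,
which is the documented sensitivity envelope of the built-in aligner (the
module also exposes an adapter for delegating this step to an external SAM
producing aligner).

**Resolution.** All hits of a read are merged and the placement with the
*uniquely* smallest mismatch count wins; a tie at the minimum makes the read
ambiguous and it is discarded; the mismatch cutoff is re-checked. Before the
uniqueness test, coincident placements — identical (sequence, Watson
position, strand) reached through two conversion pairs — are deduplicated.
This matters for two classes of reads: a read whose covered cytosines are all
methylated (or absent) is identical under both conversions and would
otherwise always self-tie; and a complement-strand read (CTOT/CTOB origin)
reaches its true locus through its GA pair with fewer mismatches than through
the CT pair, so the dedup keeps the *least-mismatch* representative (tag
order W-CT, W-GA, C-CT, C-GA only breaks exact ties). The retained tag
decides the methylation interpretation downstream, which is why least-mismatch
selection, not tag priority, is the correct rule.

**Methylation profiling.** Each resolved read is compared to the original,
unconverted reference. CT-type alignments inform the read's own strand: at
every reference cytosine of that strand, read C means methylated, read T
unmethylated. GA-type alignments are complement-strand reads and carry the
same information as G/A over the opposite strand's cytosines. Any other base
(a sequencing error) yields no call. Contexts are classified on the site's
own strand, 5'→3': CG* → CpG, C(non-G)G → CHG, otherwise CHH; a site within
two bases of the sequence end whose context is incomplete defaults to CHH and
is flagged. Calls use the Bismark-style alphabet (Z/X/H for CpG/CHG/CHH,
uppercase = methylated); output is SAM with `NM`, `ZC` (conversion pair) and
`ZM` (call string) tags plus a per-site TSV of counts and levels.

## The execution engine

The distributed runtime the method was designed for is modeled as a local
partitioned engine that preserves its contracts rather than its machinery:

* **Deterministic partitioning.** Keys are placed by a portable per-key hash,
  realized as FNV-1a 64-bit — any fixed, documented, process-stable hash
  satisfies the intent; the JVM-specific original is not portable to R.
* **Zero-shuffle merge.** The four per-pair hit streams are produced inside
  the read's own partition, so they share the partitioner by construction and
  the Phase-3 merge is a per-partition concatenation; a movement counter
  asserts that no record crosses partitions.
* **Rebalancing.** Two imbalance points exist: block-based input loading and
  the post-filtering survivor set. `balance = TRUE` inserts a hash
  repartition at both; plain and balance modes produce set-identical output,
  which the tests assert across partition counts 1, 2 and 8.
* **Broadcast-once.** The unconverted reference (and its context tables) is
  staged at most once per partition in Phase 4, never per read; a staging
  counter asserts this.

## The simulator: what it emulates, what it does not

The simulator generates the desk-scale stand-in for the published benchmark
(full-length human chromosome 1 with one million 95 bp reads from a
third-party simulator whose internals are not published). Defaults follow the
stated world where it is stated and field-typical values where it is not:

| parameter | default | why |
|---|---|---|
| read length | 95 bp | the benchmark's read length |
| error rates | 0 / 0.01 / 0.02 | the benchmark's three datasets |
| error profile | $p_i = A e^{-i/\tau}$, $\tau = L/3$, $A$ set so $\mathrm{mean}(p_i) = e$ | "exponential decay" is stated; the constant is not, so $\tau$ is an artifact choice |
| conversion rate | 1.0 | idealized complete bisulfite conversion |
| methylation | CpG 0.7, CHG 0.02, CHH 0.02 | mammalian-like; pinned by the recovery criterion |
| benchmark genome | 1 Mb synthetic, GC 0.41 | desk-scale stand-in for chromosome 1 (GC fraction matches it) |
| benchmark reads | 50,000 | desk-scale stand-in for 10^6 |

Methylation truth is drawn independently per covered cytosine per read, so a
genomic site's aggregated level is a binomial fraction of its coverage —
exactly what the recovery tests check. Errors are substitution-only
(consistent with the ungapped aligner), and error draws are *coupled* across
error rates: with a fixed seed the same uniforms are thresholded against the
scaled profile, so the error set at 1% is a subset of the set at 2%. That
coupling is what makes the mappability/accuracy monotonicity test a sharp
property rather than a statistical one. Qualities encode the positional error
probabilities on the Phred+33 scale (capped at Q40, floored at Q2).

What the simulator does **not** model: PCR duplicates, M-bias, indels,
quality-dependent miscalls, repeat structure beyond optionally planted
duplicated blocks, and incomplete-conversion bias along the read. A green
test therefore establishes algorithmic correctness of the pipeline under its
own stated model, not concordance with the published absolute benchmark
values, which additionally depend on the real chromosome and the unpublished
simulator internals.

## Numerical and design choices

* **Seed length** defaults to $k = 20$ (about one uniqueness-scale seed for a
  megabase-scale genome; with 95 bp reads this guarantees full recall up to 3
  mismatches, and the default cutoff `max_mm = 4` is the common three-letter
  tool default). Tests that need the guarantee to cover the whole cutoff use
  $L/k \ge 5$.
* **Degenerate inputs.** Reads shorter than $k$ are counted unmapped with a
  warning; k-mers containing N are never indexed or queried (whether the
  reference's Ns should be maskable is left open by the source method; we
  exclude them); characters outside \{A,C,G,T,N\} are rejected at parse time,
  IUPAC ambiguity codes map to N with a warning.
* **Coordinates** are 0-based half-open internally; 1-based only at SAM and
  site-report serialization.
* **Tie-breaking** beyond coincident-placement dedup: none — ties are
  discarded as ambiguous, by design.
* **Genome pack** persists the original plus four converted FASTAs and a
  metadata file (format version, k, source checksum); seed indexes are
  rebuilt deterministically at load because they are a pure function of the
  converted sequences and `k` — persisting them would add a staleness hazard
  without changing behavior.
* **Determinism.** All randomness lives in the simulator and is seeded; the
  pipeline itself is deterministic, so output invariance across partition
  counts, worker counts and balance modes is exact set equality, not
  approximate.

## Known limitations

* Ungapped end-to-end alignment only: reads spanning indels are lost, and the
  sensitivity envelope differs from gapped backends accordingly.
* Mismatch counts (`NM`) are computed in converted space, matching what a
  three-letter backend reports, not full-alphabet edit distance.
* Paired-end reads, adapter/quality trimming, duplicate removal and
  mapping-quality-based rescue of ambiguous reads are out of scope.
* The per-site report contains only covered sites; uncovered cytosines are
  absent rather than zero.

## A worked example

```{r example, eval = FALSE}
ref <- synth_genome(50000, seed = 11)
pack <- prepare_genome(ref, k = 20)
sim <- simulate_reads(sim_config(n_reads = 2000, seed = 5), ref)
res <- run_pipeline(pack, data.frame(read_id = sim$reads$read_id,
                                     seq = sim$reads$seq,
                                     qual = sim$reads$qual),
                    out_sam = "run.sam")
m <- evaluate_alignments("run.sam", sim$truth)
print(m)
```

The README shows the same chain through the command line interface, with the
numbers it prints.
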