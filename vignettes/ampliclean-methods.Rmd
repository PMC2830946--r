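---
title: "Processing 454-style amplicon surveys with ampliclean: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing 454-style amplicon surveys with ampliclean: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclean)
```

## The problem

Amplicon surveys on 454-style pyrosequencers read a pool of PCR products in
which every read has the layout

    5'  barcode | forward primer | target | rc(reverse primer) | adapter B  3'

with a parallel `.qual` file carrying one integer quality score per base.
Before any diversity analysis the reads must be cleaned: technical sequence
removed, samples separated, and the platform's characteristic errors --
above all homopolymer length errors -- filtered out. ampliclean implements
this cleaning as a fixed seven-step pipeline plus downstream table
generators (taxonomy assignment, cross-sample overlap, rarefaction inputs)
and a read simulator that provides ground-truth datasets for testing all of
it offline.

## The seven-step pipeline

`run_pipeline()` applies the steps in a fixed order; each step reports
`n_in`, `n_kept` and `n_discarded`, and construction of the report enforces
`n_in == n_kept + n_discarded` row by row.

1. **Adapter-B removal.** The adapter marks a fully read-through amplicon,
   so reads in which it cannot be found are discarded rather than passed
   through untrimmed. The search is an ungapped scan over all offsets
   tolerating `ceiling(f * m)` mismatches for matched length `m` (default
   fraction `f = 0.1`), and accepts a 3'-truncated adapter prefix of at
   least half the adapter length at the read end, because reads often stop
   inside the adapter. The leftmost acceptable occurrence wins; this is a
   deliberate, documented convention -- an adapter-like stretch earlier in
   the read would truncate conservatively rather than leave adapter
   sequence behind.
2. **Ambiguity filter.** Any read containing an `N` is discarded. `N` is
   the only ambiguity code the package keeps at parse time; other IUPAC
   letters are converted to `N` with a warning, which makes this filter
   also the gatekeeper for rare ambiguity codes.
3. **Low-frequency removal.** Sequencing errors are largely unique, so
   variants seen fewer than `min_copy_number` times (default 2, i.e.
   singleton removal) are discarded. Frequencies are exact full-string
   counts over the *pooled, still-barcoded* reads -- the step runs before
   demultiplexing, so several datasets can be combined to protect true
   low-frequency variants. `min_copy_number = 1` disables the step.
4. **Demultiplexing.** A read is assigned to a sample if its 5' prefix
   equals that sample's barcode exactly; barcode bases and their qualities
   are removed. Barcodes must be unique and equal-length (validated up
   front), which rules out prefix ambiguity; there is deliberately no
   error-tolerant barcode matching. Without barcodes the step is skipped.
5. **Length filter.** Inclusive window `[min_length, max_length]` in bp,
   measured on the adapter- and barcode-stripped read with primers still
   attached, since primer removal comes next.
6. **Primer removal with the boundary filter.** Primers must match
   *exactly* (forward at the 5' end, reverse complement of the reverse
   primer at the 3' end; a switch allows literal-orientation matching).
   Exactness is what makes the homopolymer boundary error invisible to
   primer matching, hence the dedicated filter described below.
7. **Quality filter.** The arithmetic mean of the remaining (target-only)
   qualities is compared to `min_mean_quality`; only means *strictly
   below* the threshold are discarded, with no rounding before the
   comparison. Reads that become singletons here stay in the data set --
   the frequency filter is not re-run.

After step 7 each sample is dereplicated: exact-identity grouping (indels
are informative and keep variants apart), ranked by descending copy number
with lexicographic tie-break, written as
`>sample_NR000001;size=123`. The `;size=` annotation is the interchange
format all downstream modules parse.

### The homopolymer boundary filter

Pyrosequencers miscall homopolymer lengths. When the error sits in the run
spanning the primer/target junction, the primer still matches exactly but
the whole target is shifted by one base -- a high-frequency artefact that
would masquerade as a novel indel variant. The filter exploits that in an
amplicon dataset most reads share the same first bases of target:

* the modal `boundary_window`-mer (default 8 bp) immediately after the
  forward primer across all exact-primer reads is taken as the consensus
  (ties broken lexicographically, so the result is deterministic);
* for each read the windows at offsets +1 and -1 relative to the junction
  are compared to the consensus by Hamming distance. An unshifted read
  disagrees heavily at both offsets; a shifted read matches one of them
  almost perfectly. Reads with fewer than `boundary_mismatch_threshold`
  (default 3) mismatches at either offset are discarded.

Offsets whose window would run past the read end are skipped, and a read
exactly `primer + window` long is judged on its -1 offset alone. The rule
is applied literally even to reads whose offset-0 window equals the
consensus; `exempt_exact_boundary = TRUE` exempts those reads, which
protects homopolymer-rich or tandem-repeat targets at the cost of missing
shifts that happen to reproduce the consensus. The filter is applied at the
forward junction by default; `boundary_both_junctions = TRUE` mirrors the
procedure at the reverse junction. When no read supplies a full window the
consensus is undefined and the pipeline skips the filter rather than guess.

## Gap-excluded similarity

Downstream grouping uses a percent similarity defined over a pairwise
global alignment as

    similarity = 100 * identities / (aligned columns where neither side has a gap)

Gap columns are excluded from the denominator, so at a cutoff of 100 two
sequences differing only by indels still group together -- exactly the
behaviour needed when the sequencer's dominant error mode creates spurious
indels. With zero gap-free columns the similarity is undefined and treated
as no match.

The internal engine is a Needleman--Wunsch aligner (Rcpp) with match +1,
mismatch -1 and a linear gap penalty of -2. These defaults favour compact
alignments of near-identical amplicons; they are not tuned for distant
homology. The traceback is deterministic (diagonal preferred over a gap in
the second sequence, preferred over a gap in the first), so equal-scoring
alignments resolve reproducibly. Every consumer of the similarity --
`match_across_samples()`, `pairwise_distances()`, `abundance_groups()` --
accepts an `engine` function so an external aligner can be substituted;
external engines' values are passed through untransformed.

Cross-sample overlap (`match_across_samples()`) reports, for each query
sequence, its own copy number and the *summed* frequencies of all target
sequences within the cutoff. Summation is the faithful reading of "copies
of this sequence in that sample"; `best_hit_only = TRUE` switches to the
single most similar target (ties by longer gap-free span, then id order).
Raising the cutoff can only shrink these numbers, a monotonicity property
the test suite asserts.

## Taxonomy assignment

`search_reference()` is a provider contract: any function returning hits
with query, accession, percent identity, e-value, bitscore and taxid can
stand behind it. The packaged provider aligns queries against a small
reference collection with the internal aligner and derives a deterministic
toy e-value (`m * n * 2^-score`); it exists so that assignment logic is
testable offline, not as a replacement for a production search engine,
whose tabular output can be ingested with `read_hit_table()`.

Best-hit selection resolves ties in a fixed cascade: minimal e-value;
maximal bitscore (distinct alignments can share a printed e-value);
deepest lineage -- "most detailed classification" is operationalised as the
number of named ranks on the root-to-leaf path; then a majority rule over
the remaining tied set, evaluated on path *prefixes* from the root down:
the deepest depth at which one prefix is shared by a strict majority of
the tied lineages wins and the assignment is truncated there. A tie with
no majority at the first rank is reported as `unresolved`, with the first
hit in accession order and a flag. The majority rule deliberately operates
only on the tied best-hit set, not on any wider top-N. Lineages come from
a local table (either a simple 4-column TSV or the NCBI `nodes.dmp` /
`names.dmp` dialect) -- never from live web queries, for reproducibility;
parent-pointer cycles and unknown taxids are structural errors.

## Rarefaction exports

`pairwise_distances()` converts the gap-excluded similarity to a distance
(`1 - s/100`; undefined similarity becomes 1), giving a symmetric,
zero-diagonal matrix. `write_mothur_inputs()` writes it in column format
(lower-triangle `idA idB d` lines; a square-matrix dialect is available by
flag) together with a names file in which a frequency-`f` sequence expands
to itself plus `f - 1` synthetic `_dupN` replicate ids -- the expansion is
how dereplicated abundances re-enter downstream clustering, and the suite
checks that total replicate ids equal total frequencies.
`write_abundance_list()` groups sequences by single-linkage over
within-cutoff pairs and writes one summed count per line, descending;
single linkage is the natural closure of "within the cutoff of something
in the group" and conserves total counts by construction.

## The read simulator

`simulate_sample_set()` builds reads with the exact anatomy above from a
small panel of divergent target variants shared across samples, then
injects at most one defect per read: missing adapter, an `N`, a unique
(singleton) target, a foreign barcode, a far-out-of-window length, a
substitution inside the forward primer, a one-base boundary slip
(`inject_boundary_indel()`, both directions), or low-quality bases. Two
constructive guarantees make the manifest exact rather than probabilistic:

* every defect class within a sample is emitted as a block of *identical*
  reads, so its pooled copy number clears the singleton filter and the
  read reaches precisely the step its defect violates;
* all target variants share their first 16 bases, chosen (and asserted at
  generation time) so that the boundary consensus is the shared prefix,
  every injected one-base shift matches the consensus at its offset, and
  no clean read comes within the mismatch threshold at either offset.

Clean base qualities are drawn uniformly from [30, 40] and low-quality
reads from [5, 15], so any mean-quality threshold inside (15, 30)
classifies unambiguously -- a deliberate guard against boundary flakiness
in tests. Default defect rates produce roughly 40% loss, the loss profile
typical of deeply multiplexed 454 surveys, with adapter read-through
failures and singletons dominating. Rates that would create a surviving
defect group smaller than `min_copy_number` are refused with an error
rather than silently producing a wrong manifest; with the default rates
this implies at least ~150 reads per sample.

What the simulator does *not* emulate: flowgram-level noise and true
per-cycle error accumulation, chimeras, within-variant point-mutation
clouds, length variation of clean amplicons, or correlated quality decay
along the read. Passing tests on simulated data therefore demonstrate the
pipeline's bookkeeping and filter logic under the documented error model,
not calibration against real 454 noise.

## Numerical and degenerate-input conventions

* Mismatch allowances use `ceiling(fraction * length)` computed with a
  small epsilon guard against floating-point spill (`0.1 * 20` must allow
  2, not 3).
* All threshold comparisons are documented as strict or inclusive and
  tested at the boundary: length window inclusive, quality strictly below,
  boundary filter strictly fewer than the threshold.
* All order-dependent outputs (consensus ties, dereplication ties,
  majority winners, best-hit ties) break ties lexicographically or by
  accession so identical inputs give byte-identical outputs.
* Empty inputs: an empty read set writes valid empty files; dereplicating
  nothing gives an empty table; a read with no remaining quality values is
  an error, as its mean is undefined; a consensus with no eligible window
  is an error when requested directly and a documented skip inside the
  pipeline.
* FASTA/`.qual` pairing is strict -- same order, same ids, matching
  lengths -- and violations name the offending record; silent re-pairing
  could attach wrong qualities.

## Scale of the bundled checks

The test suite and the acceptance script run entirely on generated data:
3 samples x 500 reads for the end-to-end manifest comparison, 1,000
randomized conservation trials at 30 reads per run, 500 random pairs for
the similarity oracle, and 50 constructed lineage forests for the
tie-breaking enumeration. These sizes were chosen so the full suite
exercises every code path in seconds while keeping every check exact
(manifest equality, not statistical agreement).

## Known limitations

* FASTA + `.qual` is the only input dialect; FASTQ and SFF are out of
  scope for this platform generation.
* Primer and barcode matching are deliberately exact; degraded primer
  regions cost reads rather than risking mis-assignment.
* The internal search provider's e-value is a toy statistic: monotone in
  alignment score and adequate for choosing among toy references, but not
  comparable to a database search engine's values.
* All-against-all alignment in the overlap and rarefaction modules is
  quadratic in the number of unique sequences; it is intended for
  dereplicated sample-level sets, not raw reads.
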