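---
title: "Manipulating HGVS sequence variants: models, conventions and limits"
author: "hgvsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Manipulating HGVS sequence variants: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgvsr)
```

## The problem

HGVS nomenclature describes a sequence variant as an accession, a coordinate
type and a position/edit pair: `NM_000059.3:c.201_202dupGA` duplicates two
bases of a coding transcript, `NC_000001.11:g.17028712delTinsCC` replaces one
genomic base with two. The same biological change admits many syntactically
valid descriptions (on `GCTTTA`, the deletions written at 3, 4 and 5 and two
delins forms all denote `GCTTA`), and positions live in several coordinate
systems — genomic (`g.`/`m.`), transcript (`n.`), CDS-relative (`c.`, with
negative 5′-UTR bases, `*`-anchored 3′-UTR bases and intron offsets such as
`c.387+32`) and protein (`p.`). Interpreting a variant consistently requires
parsing it, checking it against reference data, rewriting it into the one
canonical form the nomenclature prefers, and projecting it between coordinate
systems through transcript–genome alignments that are not always gap-free.

`hgvsr` implements that tool chain: a grammar-based parser and configurable
formatter, a two-stage validator with three response levels, a normalizer
(allele trimming, 3′ shifting, edit-type rewriting), a gap-aware coordinate
mapper with protein consequence prediction, a local fixture data provider,
and a seeded synthetic fixture generator used throughout the test suite.

## Variant model

A variant is `variant(ac, type, posedit)`; the posedit combines an interval
of base–offset positions with a tagged edit (`sub`, `del`, `delins`, `ins`,
`dup`, `inv`, `repeat`, `con`, `identity`). Positions carry a 1-based base
(never zero: `c.-1` abuts `c.1`), a signed intron offset (0 = exonic) and,
for `c.`, an anchor (`cds_start` or `cds_end` for `*` positions). The triple
(anchor, base, offset) gives a total order, so interval sanity (`start <=
end`) is decidable for every dialect. Reference alleles may be stored as an
explicit sequence, as a declared length (`del174`), or omitted; the three
print and validate differently. `apply_edit()` — plain allele arithmetic on
a character string — is the oracle the rest of the package is tested
against.

Internally all arithmetic uses interbase (0-based, half-open) coordinates;
the 1-based inclusive HGVS dialect exists only at the parse/format boundary
and in the stored position objects that mirror it. Interbase coordinates
make insertion points and empty intervals unambiguous, which matters
constantly in the shifting and projection code. Mitochondrial `m.` is
treated exactly as `g.` apart from the printed letter.

## Parser and formatter

`parse_hgvs()` is a hand-written recursive matcher with one alternative per
edit kind, tried longest-match-first so `delins` is never split into `del` +
`ins`. Sequence characters are upper-cased on parse; accession case is
preserved; whitespace is rejected rather than stripped, because variant
strings function as database identifiers. Declared-length references
(`del174`) are parsed and validated later; a *declared-length insertion*
(`ins8`, `delTins6`) is rejected at parse as a syntax error, since an
insertion without its sequence carries no usable information. Descriptions
the nomenclature permits but this package does not model — uncertain
positions like `(?_17019)`, compound/mosaic/chimeric alleles — raise a
dedicated `hgvs_unsupported_error`, distinct from syntax errors, so batch
audits can separate "malformed" from "out of scope". Repeats are parsed in
the unit-plus-count dialect (`GCA[12]`, `GCA(3_6)`): the count alone does
not determine the allele, so the unit is required.

`format_hgvs()` consults only a `formatter_config()`: `max_ref_length`
(default 0) suppresses or prints the reference allele of deletions,
duplications, inversions and the deleted part of delins (`c.31_35del` vs
`c.31_35delTTTTT`); `p_3_letter` (default on) and `p_term_asterisk` (default
off) control protein residue display (`p.Gly528Arg`, `p.G528R`,
`p.Gly528*`). Settings never alter the stored object, and parsing the
formatted string (at `max_ref_length = Inf`) reproduces the object exactly —
a property the suite checks on 10^4 generator-produced variants.

## Validator

Validation runs in two stages. Intrinsic criteria need no external data:
interval ordering (i1), insertion-flank adjacency (i2), accession family vs
coordinate type (i3), declared/explicit reference length vs interval span
(i4), edit arity (i5). Extrinsic criteria consult the provider: bounds (e1)
and reference agreement (e2), with the special case (e3) that an intronic
transcript variant has no transcript sequence to check — when the provider
holds the genomic sequence and alignment the intronic reference *is* checked
against the genome (becoming VALID or ERROR); otherwise the criterion
returns WARNING with a message. Every criterion returns one of three levels
— VALID, ERROR (violated), WARNING (cannot be evaluated) — and the report
keeps all outcomes; the overall level is the maximum. This separates
unambiguously valid, plausibly valid, and unambiguously invalid variants.
Adjacency across an exon junction (`c.87+2_88-1insT`) and spans that cross
the CDS/UTR seam are likewise WARNINGs intrinsically: they are decidable
only with exon structure.

In default mode validation always returns the report; in strict mode an
overall level of WARNING or worse raises an `hgvs_validation_error` carrying
it. The extrinsic stage is skipped whenever the intrinsic stage found an
ERROR — it is the more expensive stage and its answers would be moot.
Operations that require a sound variant (normalization, projection) refuse
to run on an ERROR-level report.

## Normalizer

Normalization composes three steps, each exposed for testing:

1. **Trim** (`trim_alleles()`): remove the common prefix, then the common
   suffix, of the materialized reference and alternate alleles. Prefix-first
   order is what places `3_5delTTTinsTT` at `[5,5]` directly; the choice is
   cosmetic, since step 2 re-derives the final placement either way. If both
   alleles empty out, the variant *is* the reference and an identity (`=`)
   variant over the original interval is emitted.
2. **Shift** (`shift_3prime()`): rotate the surviving indel toward 3′ while
   the allele head equals the next reference base — equivalent to comparing
   reference and altered sequence in a window but O(shift) rather than
   O(window²). Sequence is fetched through the provider in a dynamic window
   (initial `window_size` 20 bases, doubling whenever the shifted variant
   reaches the window edge) so long homopolymer runs cost a bounded number
   of provider reads. Shifting stops at the sequence end and, for `c.`/`n.`
   variants with `cross_boundaries` off (the default), at the exon junction:
   a transcript placement that silently crossed into the next exon would
   change its genomic meaning. A `5p` mode exists for VCF-style left
   alignment; `3p` is the nomenclature's canonical direction.
3. **Rewrite** (`rewrite_edit()`): re-express the change as the
   highest-priority kind that exactly represents it — substitution >
   deletion > inversion > duplication > insertion > deletion–insertion. An
   insertion equal to the immediately preceding reference bases becomes a
   duplication (`4_5insA` on `GCTA` → `4dup`); a replacement by the exact
   reverse complement (length > 1) becomes an inversion. Conversions are
   never emitted: the priority scheme ranks them, but no rewrite rule into
   or out of a conversion is defined, so `con` (and `repeat`) edits pass
   through unchanged with a notice attribute.

Intronic variants have no transcript sequence, so when the provider holds
the genome and alignment they are normalized in genomic context: projected
positionally, shifted within a window clamped to their intron (never into
an exon), and projected back. On a minus-strand transcript the transcript's
3′ direction is the genome's 5′, so the genomic shift direction is flipped
accordingly. Without genomic context the variant is returned unchanged with
a notice.

## Gap-aware projection

Transcript–genome alignments are stored per exon as runs of four ops:
`M` (match), `X` (substitution discrepancy), `TI` (transcript base absent
from the genome) and `GI` (genome base absent from the transcript). Introns
are not alignment segments; intronic positions are computed from exon
genomic edges, the offset taken to the *closest* edge and ties broken
toward the upstream exon (a `+` offset). Expanding runs into per-base
columns makes projection direct: every column knows its transcript and/or
genomic base index, and boundary arrays give the interbase coordinates
between columns.

The delicate part is a variant interval that meets a gap. The policy:

* An endpoint merely **adjacent** to a gap run takes the *tight* boundary —
  the candidate that excludes the run. Adjacency alone never changes the
  allele, so such variants project affinely; this is what keeps a
  substitution just past a 3-nt genomic insertion at its own genomic base
  (non-adjacent to its transcript neighbour) instead of smearing it across
  the gap.
* Gap columns **inside** the interval — or an insertion point sitting at or
  inside a gap run, where placement is genuinely ambiguous — trigger
  widening: the interval grows to the nearest *solid* boundaries (those
  flanked by aligned columns on both sides), and the allele is recomputed
  over the widened region. The recomputed alternate is the source side's
  edited content of that region, verbatim (reverse-complemented across
  strands). Transcript-only (`TI`) bases therefore materialize into the
  genome when a transcript edit touches them, and genome-only (`GI`) bases
  are consumed; the same rule read backwards makes genome→transcript
  projection its inverse. Renormalization afterwards turns the raw widened
  delins into the preferred ins/dup/del form.

This verbatim-region convention is self-inverse and is exactly what the
test suite's independent resplice oracle implements from the raw segment
runs: applying a transcript variant to the transcript sequence must equal
re-splicing the edited genome through the alignment, for every projected
variant including those within, exactly covering, partially covering and
extending beyond gap bounds. One consequence worth naming: a deletion that
exactly covers a transcript-insertion gap restores the genomic sequence, so
its genomic image is an identity (`=`) variant — the representation the
round-trip preference already favours.

At substitution discrepancies (`X` columns) projection preserves the
*alternate* allele and replaces the *reference* with the target sequence's
actual bases (`replace_reference()`), run strictly after coordinate
projection and before renormalization. The two sequences genuinely differ
there, so string-identity of the edited molecules is not the contract at
such sites; carrying the target's reference is.

`project_tx_to_genome()` and `project_genome_to_tx()` wire the pipeline
together: validate (ERROR aborts; out-of-bounds positions are refused, never
extrapolated), renumber `c.`↔`n.`, project through the alignment, replace
the reference, renormalize in the target context. A pseudoautosomal
transcript carries a second genomic placement; `par = "X"` (default) or
`"Y"` selects it when the variant lies in the dual-placed region.
`relevant_transcripts()` lists, in lexicographic order, every transcript
whose genomic span (either placement) contains a genomic variant.

Protein consequences (`c_to_p()`) are predicted by editing the CDS and
translating both versions, reading into the 3′ UTR for frameshifts until a
stop appears: synonymous `p.(Xaa#=)`, substitutions and stop-gains, in-frame
del/ins/dup/delins (classified by trimming the two protein sequences),
frameshifts `p.(Xaa#YaafsTer#)` with the new stop counted from the first
changed residue (itself residue 1), and stop-loss extensions in `ext`
notation (an experimental rendering here). Initiator Met is residue 1; any
change touching it, and any intronic or UTR-only input, yields `p.?` rather
than an exception — the consequence is unknowable from the CDS alone.
Predictions are marked uncertain and print in parentheses.

## Data provider and synthetic fixtures

All reference data flows through one read-only interface: `get_seq()`
(interbase slices, supporting the normalizer's windowed access),
`get_transcript()`, and the bundle constructor `fixture_bundle()`, which
verifies at load time that exon tables tile the transcript, segment sums
reconcile exon lengths on both sequences, genomic intervals respect strand
order, CDS bounds fit, and match columns agree between the stored
sequences. `write_fixture()`/`read_fixture()` persist a bundle as FASTA
plus a JSON manifest — plain text, human-diffable. No network code exists
anywhere; a remote transcript-database adapter could attach at the same
interface but is out of scope.

`generate_fixture(seed, ...)` builds the test world: a random genome
carrying multi-exon genes on both strands (defaults: 4 genes, 2–5 exons of
90–240 bp, introns of 60–200 bp — small enough to keep the suite fast,
large enough that exons dwarf every injected feature), with injected
`TI`/`GI` gaps (2 each of 1–4 bp by default) and `X` mismatches (3),
mirroring the rare but clinically important discrepancies between curated
transcripts and assemblies. Coding transcripts get a clean ORF (forced ATG,
terminal stop, no internal stop) so protein prediction behaves as on real
transcripts; one gene is dual-placed on a second accession
(pseudoautosomal-like), and a non-coding isoform shares a subset of one
gene's exons so overlap queries have a target. Every injected feature is
reported in a truth table with transcript and genomic coordinates, which is
how tests aim variants at — or away from — gap neighbourhoods. The same
seed reproduces a bit-identical bundle.

What the generator does *not* emulate: sequencing-error noise, repetitive
and low-complexity genomic structure at realistic scale, overlapping genes
on opposite strands, multi-megabase coordinates, alternative haplotypes, or
real curated alignments with their version-to-version drift. Passing tests
therefore demonstrate the correctness of the coordinate and allele algebra
under the stated alignment model, not robustness to annotation-pipeline
quirks in real RefSeq/assembly data.

## Numerical and convention choices

* Trim order is prefix-then-suffix; 3′ shifting makes the end state
  independent of that order.
* The dynamic shift window starts at 20 bases and doubles; with in-memory
  fixtures this is a bounded-read discipline rather than a performance
  necessity.
* Duplication detection only looks back as far as the active window allows
  (an exon start for transcript variants), so a "duplication" whose unit
  would live in the previous exon stays an insertion.
* Junction-adjacent insertions (`c.30_31insT` where 30 ends an exon) are
  projected to the upstream exon's genomic edge; genomic renormalization
  may then legitimately carry them into the intron. Round-trip identity is
  guaranteed for exonic variants away from junctions and gaps (the suite
  seeds them with a 20-base margin); at junctions the transcript-level
  description is genuinely ambiguous and the genomic canonical form wins.
* Degenerate inputs: identity edits re-emit canonically; substitutions
  whose replaced reference equals the alternate collapse to identity during
  reference replacement; zero-length alleles never reach the shifter.
* Validation of unknown accessions reports WARNING ("plausibly valid"),
  not ERROR: absence of data is not evidence of invalidity.

## Command line

The `hgvs_cli()` function (wrapped by the `inst/cli/hgvs` Rscript) exposes
`parse`, `validate`, `normalize`, `project` and `gen-fixture` over single
variants or line-delimited batches against a fixture directory, one JSON
record per input line with status `ok`/`warning`/`error`/`unsupported`;
per-variant failures never abort a batch, and the exit status distinguishes
clean runs (0), variant-level failures (1) and usage errors (2).

## Problem sizes in the shipped suite

The test suite runs the parse/format round trip on 10^4 generated variants,
normalization idempotence and allele preservation on 10^4, projection round
trips on 10^3 clean exonic variants, the gap resplice oracle on more than
10^3 cases covering all four gap-interaction classes in both directions,
and reference-corruption detection on 500 variants — sizes chosen so the
whole suite completes in about two minutes on one CPU while still
exercising every code path the properties quantify over.

## Known limitations

Compound, mosaic, chimeric and translocation variants, ISCN, RNA (`r.`)
coordinates and uncertain positions are rejected with a typed error.
Conversion and repeat edits parse and print but are not normalized or
projected. Liftover between genome builds is out of scope (the provider may
hold several assemblies, but no mapping between them). Splice-effect and
NMD prediction are not attempted; `ext`/initiator conventions at the
protein level are marked experimental. Variants spanning a splice junction
in transcript coordinates are projected endpoint-wise without allele
recomputation, and multi-exon allele semantics are not defined here.
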