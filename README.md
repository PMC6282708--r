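# hgvsr

Parse, validate, normalize and project sequence variants described in HGVS
nomenclature, in R.

Clinical genetics communicates variants as strings like
`NM_000059.3:c.201_202dupGA` or `NC_000001.11:g.17028712delTinsCC`. The same
biological change admits many syntactically valid spellings, positions live
in four coordinate systems (genomic `g.`/`m.`, transcript `n.`, CDS-relative
`c.` with UTR anchors and intron offsets, protein `p.`), and
transcript–genome alignments contain occasional indels and substitution
discrepancies, so naive coordinate arithmetic mis-places variants in
clinically important genes. `hgvsr` is a toolkit for people who curate,
audit or pipeline such descriptions: variant database maintainers, clinical
reporting pipelines, and anyone who needs one canonical spelling per
variant.

## What it does

* **Parse / format** — a grammar-based parser covering substitution,
  deletion, insertion, deletion–insertion, duplication, inversion,
  conversion, identity and repeat edits on `g./m./n./c.` references and the
  protein forms on `p.`; malformed input raises a syntax error with the
  failing position, while uncertain positions and compound alleles raise a
  distinct "unsupported" error. Formatting is configurable
  (`max_ref_length`, 1- vs 3-letter amino acids, `Ter` vs `*`) and never
  mutates the object.
* **Validate** — intrinsic (self-consistency) then extrinsic (against
  reference data) criteria, each answering VALID / WARNING (cannot be
  evaluated, e.g. intronic reference with no genomic context) / ERROR;
  strict mode escalates warnings to exceptions.
* **Normalize** — trim shared allele bases, shift 3′ with a dynamic window
  (stopping at exon junctions for transcript variants), and rewrite into the
  highest-priority edit type (substitution > deletion > inversion >
  duplication > insertion > delins): `4_5insA` after `GCTA` becomes `4dup`.
* **Project** — map variants between genome, transcript and protein through
  per-exon gapped alignments: validation before projection (out-of-bounds
  positions are refused, not extrapolated), gap-touching intervals widened
  and their alleles recomputed so the edited molecules agree, reference
  replacement after projection at substitution-discrepant sites, and
  renormalization on the target sequence (a minus-strand duplication
  re-shifts 3′ on the plus strand). `c_to_p()` predicts protein
  consequences including frameshift stop scanning.
* **Local data** — a read-only provider serving sequences, exon structures,
  CDS bounds and alignments from in-memory bundles or FASTA + JSON fixture
  directories, plus a seeded generator that builds synthetic multi-exon,
  dual-strand genomes with injected alignment gaps, mismatches and a
  pseudoautosomal dual placement, reporting every injected feature in a
  truth table.

## A worked example

```r
library(hgvsr)

## formatting is a view, not a rewrite
v <- parse_hgvs("NM_001166478.1:c.31_35delTTTTT")
format_hgvs(v)                                        # "NM_001166478.1:c.31_35del"
format_hgvs(v, formatter_config(max_ref_length = 10)) # "NM_001166478.1:c.31_35delTTTTT"

## every member of an equivalence class normalizes to one form
p <- fixture_bundle(sequences = c(T1 = "GCTTTA", T2 = "GCTA"))
format_hgvs(normalize_variant(parse_hgvs("T1:g.3delT"), p))          # "T1:g.5del"
format_hgvs(normalize_variant(parse_hgvs("T1:g.3_5delTTTinsTT"), p)) # "T1:g.5del"
format_hgvs(normalize_variant(parse_hgvs("T2:g.4_5insA"), p))        # "T2:g.4dup"

## a synthetic fixture world: validate, project, predict
fx <- generate_fixture(seed = 1, n_genes = 2)
pp <- fx$provider
validate_variant(parse_hgvs("NM_900101.1:c.12T>A"), pp)
#> <validation_report: VALID>
#>   [VALID] i1  start <= end
#>   [VALID] i3  accession is appropriate for the variant type
#>   [VALID] i5  edit arity matches its kind
#>   [VALID] e1  interval within bounds
#>   [VALID] e2  stated reference agrees with the sequence

format_hgvs(project_tx_to_genome(parse_hgvs("NM_900101.1:c.12T>A"), pp))
#> "NC_900001.9:g.1208A>T"      # minus-strand gene: alleles reverse-complemented
format_hgvs(c_to_p(parse_hgvs("NM_900101.1:c.12T>A"), pp))
#> "NP_900101.1:p.(Gly4=)"      # synonymous at the protein level
```

The projection output reads as it does because `NM_900101.1` lies on the
minus strand: the transcript's `T>A` is the genome's `A>T`, and the
validated, normalized genomic spelling is returned. The protein call is
parenthesized because consequences are predictions.

A command-line wrapper (`inst/cli/hgvs`) exposes `parse`, `validate`,
`normalize`, `project` and `gen-fixture` over line-delimited batches,
emitting one JSON record per input; see `?hgvs_cli`.

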