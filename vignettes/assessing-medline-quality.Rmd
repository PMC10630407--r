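---
title: "Assessing MEDLINE data quality: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing MEDLINE data quality: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medlineqc)
```

## The assessment model

MEDLINE is the curated, MeSH-indexed subset of PubMed. Its records arrive
as XML: one annual baseline export plus daily update files that revise,
insert and delete citations. `medlineqc` assesses the quality of such a
corpus along three classical dimensions, computed per field:

* **completeness** `P/N` — present values over records,
* **validity** `V/P` — lexically valid values over present ones,
* **uniqueness** `D/P` — distinct values over present ones,

where `N` is the record (or author) count, `M` the missing count,
`P = N − M`, `D` the exact distinct count of present values and `V` the
count matching the field's validation pattern. A value that is blank after
whitespace normalization counts as missing, so `D` and `V` never see
null/blank entries. Journal identifiers get a fourth measure, referential
integrity: the fraction of per-article NLM journal keys found in the
J_MEDLINE reference list, with unmatched ("dangling") keys enumerated.

The assessment is lexical by design. ORCID and ISNI carry a check digit
that the validators deliberately ignore: a well-formed but erroneous
identifier passes, matching how such audits are run in practice and
keeping validity a property of the string, not of an external registry.
The one curated exception is the all-zero ORCID `0000-0000-0000-0000`,
a known placeholder that is always rejected.

### Identifier patterns and match modes

The five shipped patterns (DOI; ORCID; ISNI in presentation and compact
form; GRID) live in `inst/extdata/identifier_patterns.tsv` so a dialect
can be swapped without code changes. The DOI pattern is anchored at both
ends and the ORCID pattern at the start; both are applied exactly as
written. The ISNI and GRID patterns carry no anchors of their own, which
leaves a genuine design choice: applied as substring searches they would
accept garbage with an embedded identifier. We default to full-match mode
for those two schemes — validity should not pass on `"see grid.1234.0a
here"` — and expose `match_mode` per call for the permissive reading.
Similarly, only the ASCII hyphen-minus is accepted inside ORCIDs;
typographic dashes in printed sources are typography, not data.

## Parsing and its quirks

`split_records()` consumes a file as a stream: a buffered scanner locates
`PubmedArticle`, `PubmedBookArticle` and `DeleteCitation` boundaries
(these elements cannot self-nest under the DTD, and a literal closing tag
cannot occur inside escaped text), and each fragment is parsed as XML on
its own. Peak memory is therefore bounded by the largest record, not the
file, which is what makes full-scale runs possible on one machine.
Book-article records are counted and skipped; the pipeline assesses
journal articles only.

Parsing decisions where the source format is genuinely ambiguous:

* **Structured abstracts.** Multi-section abstracts are concatenated in
  document order, separated by one space, section labels dropped. Length
  profiling treats the abstract as one string, and any join rule changes
  lengths by a few characters at most; one rule, stated, beats none.
* **Inline markup** in titles and abstracts (italics, sub/superscript) is
  flattened to its contained text; lengths are measured on plain text.
* **Authors.** Only `Author` entries without `ValidYN="N"` are extracted,
  and `Investigator` elements are never read. CollectiveName entries —
  whether as a child of `Author` or interleaved bare in the list — become
  author records with the personal name parts absent, preserved in
  document order, because publishers intersperse groups and members and a
  person may legitimately appear once per group. Only the first
  `Affiliation` text is stored (`affiliation_count` keeps the total);
  affiliation identifiers are read from `AffiliationInfo` under `Author`
  entries, the only placement we have observed documented.
* **References.** The DTD permits one list with many references, many
  singleton lists, and nested lists; all flatten to the same sequence.
  `nesting_depth` counts enclosing lists *beyond the outermost one*, so
  the common case is depth 0 and each extra level adds one. (The
  alternative convention — counting all ancestors — would give the common
  case depth 1; ours makes "flat" and "zero" coincide.)
* **Dates.** A wholly absent `DateRevised` is legal and sorts as oldest;
  a present-but-incomplete one is a record-level error, caught and
  tallied, never silently guessed.
* **Encoding.** Input is UTF-8 per the XML declaration. Text is kept
  under Unicode NFC so canonically equivalent spellings compare equal,
  while genuinely distinct spellings ("Istanbul" vs "İstanbul") stay
  distinct. CR, LF and TAB become single spaces and runs of spaces
  collapse; backslashes and quotes are preserved in memory — escaping
  belongs to serializers.

## Corpus assembly

Baseline and update ingestion share one rule: for each PMID the retained
record is the one with the newest `DateRevised`. The PMID `Version`
attribute is parsed and stored but never used as a merge key — it is not
a revision counter in this data. Two details the retention rule does not
determine by itself:

* **Tie-break.** On equal revision dates the record from the later
  (file, index) position wins, on the grounds that later files are later
  exports. This is our declared rule, not an inference about upstream
  behaviour; it makes replay deterministic, which the tests exploit.
* **Deletions** are replayed in file order, so update-then-delete leaves
  a PMID absent and delete-then-update reinstates it.

The assessed subset keeps records with citation status `MEDLINE`, without
a news publication type, and with a non-empty title. "News" is not
operationally defined upstream; we exclude records whose publication-type
list intersects `{"News", "Newspaper Article"}` — the NLM types that
describe journalism — and make the set configurable. Exclusions are
counted under the first matching reason in the fixed order status → news
→ title, so the selection report is deterministic and its counts always
sum to the input size.

## Field semantics

* **Publication year.** The structured `Year` wins when present.
  Otherwise the free-text MedlineDate is scanned for four-digit runs:
  the *reluctant* year is the first run (shortest-match semantics), the
  *greedy* year the last (longest-match). On a well-formed time span
  ("1999 Dec-2000 Jan") their difference is the span in years; on
  pathological values the greedy extraction can land on a page number,
  so each year carries its own viability flag against a plausibility
  window of `[1800, current year + 2]` — wide enough for the oldest
  indexed literature and articles scheduled slightly ahead.
* **Language.** Values hold MARC codes and may be concatenations
  ("fregerita" = French, German, Italian). Parsing splits into 3-char
  chunks verified against the shipped MARC table
  (`inst/extdata/marc_language_codes.tsv`, replaceable); any residue
  fails the parse with the raw value preserved. A record is
  language-invalid only when its *sole* code is `und` or `mul`; either
  code alongside others is fine.
* **Abstract truncation** is detected by sentinel phrases at the end of
  the text (`inst/extdata/truncation_sentinels.txt`, configurable): the
  parenthesised `(ABSTRACT TRUNCATED …)` markers that data-entry policy
  appended at the historical 250-word, 400-word and character limits. A
  length heuristic was the alternative; sentinels are exact on true
  positives and cannot misfire on legitimately long abstracts.
* **E-mail extraction** from affiliation tails is deliberately
  conservative — one trailing `local@domain.tld` token, optional final
  period stripped, no RFC 5322 ambition — because the address is only a
  cautionary discriminator: the placeholder `user@example.com` is flagged
  specially for exactly that reason.
* **Author anomalies** are threshold flags (all configurable, all
  monotone): one-character last names; ≥ 8 space-separated words in a
  personal name field (suspected collective); forenames ≥ 100 characters
  (affiliation concatenation); suffixes ≥ 20 characters (role/degree
  pollution); initials longer than 4 characters.

## Profiling

Character length is the Unicode code-point count; word count splits on
the space character only (U+0020), dropping empty tokens — sanitization
has already collapsed all other whitespace, so this is exact and stated.
Five-number summaries use linear interpolation between closest ranks
(`quantile` type 7) in exact mode. The approximate mode mirrors the
streaming-quantile interface used on very large corpora and guarantees a
rank error of at most `error × n`; it is implemented as nearest-rank
selection, whose rank error never exceeds one — comfortably inside the
guarantee at every size this package profiles, with no sketch structure
to maintain. Top-value tables break count ties lexicographically so
output is reproducible. Uniqueness and top-value counting operate on
sanitized values, case-sensitively by default; `case_fold = TRUE` exists
for DOI, which is case-insensitive by its own specification.

Per-year identifier prevalence uses the reluctant publication year and
excludes (but counts) records without a viable year; the unit is the
article for DOI and the author for ORCID, ISNI, GRID and the plain
affiliation string.

Rounding for display is half-up to three decimals of the percentage
(0.713734 → "71.373"), with a small epsilon against binary representation
error; the raw ratio always travels alongside the rendering, and
undefined ratios render as "N/A", never as zero.

## The synthetic corpus generator

`generate_corpus()` exists so the whole pipeline can be exercised and
*checked exactly* without downloading anything. It emits DTD-shaped
`PubmedArticleSet` XML — including decoy elements the parser must ignore —
and a manifest recording, per record, every injected pathology and the
expected downstream quantities (selection outcome, identifier counts,
publication year). Corpus and manifest are derived from one per-record
plan, so they cannot disagree, and per-record seeds are derived from
(corpus seed, record index), so injection decisions are independent of
generation order and the same seed reproduces everything bit-for-bit.

Each pathology is an independent Bernoulli event per record at the rates
in `default_pathology_rates()`. The defaults echo the *relative*
prevalence of the documented pathologies — extended characters and
reference-list quirks are common (0.05), placeholder affiliations less so
(0.01), all-zero ORCIDs and missing titles rare (0.0005, 0.0003) —
without claiming any production database's exact values. Identifier
presence defaults (ORCID 0.03 per author, affiliation 0.6, DOI ramping
linearly from 0.10 to 0.95 across the year range) likewise mimic the
observed orders of magnitude and trends. A handful of injections are
mutually exclusive on the same field (a punctuation-only affiliation
cannot also be narrative); these resolve by fixed precedence and only
what was actually injected is recorded, keeping the manifest truthful.

What the generator does **not** emulate: realistic name or language
frequency distributions beyond rank order, the full PubMed DTD (only
elements the pipeline reads, plus decoys), MeSH and chemical metadata,
and correlated pathologies (real records with one defect are likelier to
carry others). Green tests therefore demonstrate that the pipeline
recovers known defects exactly and scales linearly — not that the
generator's corpus is statistically indistinguishable from MEDLINE.

## Verification strategy and problem sizes

The suite checks three kinds of property. Worked examples freeze the
published pathological strings (322/276/211-character name-field values;
the erroneous MedlineDate forms) and assert the package reproduces their
lengths and extracted years. Oracle equivalences compare metrics,
summaries, extremes and the merge fold against independent brute-force
implementations on randomized inputs up to 10,000 values. Manifest
recovery runs the full pipeline on a seeded 10,000-record corpus and
requires the exactly-recoverable counts (missing titles, news exclusions,
excluded `ValidYN="N"` authors, all-zero ORCIDs, duplicate-ORCID
articles, solitary `und`/`mul`, dangling journal keys, truncation flags)
to equal the manifest, with Bernoulli injection counts inside exact
binomial 99.9% bands. Ten thousand records is the package's chosen
verification size: large enough that every default-rate pathology is
expected to occur and the binomial bands are meaningful, small enough to
assess in a couple of minutes on one core. The design contract — linear
time, record-bounded memory — is what makes the same code plausible at
full corpus scale, which no desk-scale test can demonstrate directly.

## Known limitations

* Validity is lexical only: checksum-valid-looking but fabricated ORCIDs
  and ISNIs pass, as do resolvable-looking but dead DOIs.
* Length-based outlier detection highlights many data issues but cannot
  catch all of them (a transposed but plausible name is invisible).
* The MARC table ships as a practical subset (~100 codes covering
  everything the generator emits and the common literature languages);
  corpora using rarer codes should supply the full table via
  `marc_language_codes(path)`.
* The truncation sentinel list is curated, not exhaustive; unknown
  sentinel variants would be missed (the list is a one-line-per-entry
  text file precisely so it can grow).
* `PubmedBookArticle` records are counted and skipped, never assessed.
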