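---
title: "Resolving orphan enzymes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving orphan enzymes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanEnzymes)
```

## The problem

An *orphan enzyme* is an enzymatic activity that has been experimentally
characterized — well enough to earn an EC number — but has no amino-acid
sequence attached to it in any major sequence database. The knowledge about
such an enzyme (its substrates, kinetics, source organisms) is stranded in
the literature, invisible to every sequence-based method. Resolving an
orphan means finding the sequence that carries the activity, which in
practice is mostly a curation exercise: the sequence often exists but is
mislabeled, annotated at class level, listed under an unindexed synonym, or
assigned a neighbouring EC number.

This package mechanizes the desk-work parts of that exercise: the census
that decides which activities are orphans, the name permutations used to
search heterogeneous sources, the error-tolerant matching of partial
N-terminal protein sequence against a proteome, the molecular-weight
cross-check, and the bookkeeping of outcomes. It deliberately does *not*
automate judgement calls — deciding whether an annotated activity "is" the
orphan activity remains an explicitly coded curator input (see
*Classification*, below).

## Census model

The census consumes two things: an EC activity catalog (ENZYME-dialect flat
file) and one evidence table per source, each row a *(source, EC,
accession)* assertion optionally carrying the original submitter. The rules
in `reconcile()` are:

* Only ACTIVE catalog entries enter the denominator. DELETED and
  TRANSFERRED entries are set aside as `removed`; a transferred entry keeps
  a pointer string to its target but contributes nothing to the statistics.
  (Whether transferred entries belong in the denominator is genuinely
  ambiguous; excluding all non-ACTIVE entries is the convention here, and
  the `removed` set is always reported so the alternative count is one
  addition away.)
* An activity is a **putative orphan** iff it has *zero unflagged evidence
  rows across all sources*. One good row in one source suffices to
  de-orphan.
* Evidence annotated only to a class-level identifier (`1.1.1.-`) is
  recorded but never de-orphans a specific activity — a class-level
  annotation is itself one of the orphan-generating conditions.
* Evidence citing an EC absent from the catalog goes to a structured
  warnings table, not to the console, and is otherwise ignored.

### Systematic mis-assignment

Large annotation errors tend to arrive in batches from a single submitter
(a sequencing center propagating one wrong EC across a genome's deposits).
`flag_systematic()` mechanizes the discard conservatively: an
*(EC, submitter)* cluster is flagged only when the submitter supports the
EC with at least `min_cluster` distinct accessions (default **3**, the
smallest count that distinguishes a batch from a coincidence) *and* no
other submitter or source mentions that EC at all. Any independent
corroboration — another submitter, a row without submitter metadata, or a
second source — vetoes the flag. The operation ignores existing flags when
deciding, which makes it idempotent and order-independent.

## Name permutation

Sources list the same activity under drifting names. Four rewrite rules
generate the candidate spellings, and `permute_name()` returns the closure
of the rules (every output re-expanded until no new normalized term
appears):

| rule | effect | example |
|---|---|---|
| `locant` | digit runs attached to hyphens removed | fluoren-9-ol → fluorenol |
| `hyphen` | hyphens become spaces | rhamnose-dehydrogenase → rhamnose dehydrogenase |
| `cofactor` | terminal parenthetical cofactor removed | mevaldate reductase (NADPH) → mevaldate reductase |
| `chirality` | leading L-, D-, DL-, (R)-, (S)-, (±)-, cis-, trans-, meso- stripped | L-rhamnose → rhamnose |

Two choices deserve a note. First, locant removal produces **both** joined
forms — the fused spelling ("fluorenol") and the hyphen-kept spelling
("rhamnose-dehydrogenase") — because real usage goes both ways and the
closure keeps whichever normalizes to something new. Second, the rules are
narrow on purpose: digits inside plain words ("Delta4") are untouched, and
cofactor parentheticals are removed only in terminal position, matching EC
naming style. The rule set is an argument (`rules =`) because the full
inventory of permutations curators use is open-ended; the default covers
the documented cases. The closure is capped at 64 terms per name (names are
short; anything past that indicates a degenerate input) with the overflow
flagged on the result.

All comparison — term against term, term against document text — goes
through one normalization: Greek transliterated, whitespace collapsed,
trailing period stripped, lower-cased. `search_corpus()` ranks documents by
(number of distinct matched terms, earliest match position, document id);
`EXACT` mode additionally requires whole-phrase boundaries.

## N-terminal identification

Edman degradation reads the first 10–33 cycles of a protein and has
well-known artifacts. The error model (`error_model()`) works in the
*observed → true* direction, since the artifacts corrupt the read while the
database sequence is ground truth:

* **Cysteine loss** — C is destroyed during the chemistry, so an
  unreadable cycle (`X`) may stand for C (on top of the configured unknown
  alphabet, default all 20 residues).
* **Deamidation** — asparagine is read as aspartate and glutamine as
  glutamate, so an observed D admits N and an observed E admits Q.
* **Initiator methionine** — the mature protein often lacks the Met the
  database sequence starts with, so the placement at offset 1 is tried on
  M-initial proteins.

`enumerate_variants()` takes the Cartesian product of the per-cycle option
sets, in lexicographic order, each variant carrying the trace of model
corrections it assumes; expansion beyond `variant_cap` (default 10,000) is
a hard error reporting the would-be count rather than a silent truncation.

`scan_proteome()` then tests every variant at every anchored placement
(offsets 0 to `max_start_offset`, default 1, plus the Met-cleavage
placement). This exhaustive scan replaces heuristic alignment: at
desk scale — hundreds of proteins, reads of a couple dozen residues — the
exhaustive search is exact, dependency-free, and fast, and its candidate
set is verified in the test suite against a naive double-loop enumeration.
Candidates are ranked by (mismatches, number of model corrections, start
offset, protein id, variant): fewer unexplained differences first, fewer
invoked error events as tie-break, and deterministic ordering regardless of
input order. Internal (non-anchored) placements are deliberately excluded
by default — an N-terminal read belongs at the N-terminus — but deeper
offsets (e.g. cleaved signal peptides) are an explicit override away.

### Molecular weight

`compute_mw()` uses **average** residue masses (one water added per chain),
not monoisotopic ones, because the experimental weights being compared
against come from gels and size-exclusion chromatography, which measure the
average mass. The default tolerance for `validate_mw()` /
`mw_only_match()` is a **15% relative deviation**, a standard allowance for
SDS-PAGE accuracy; a computed 33 kDa against an experimental 30 kDa passes
at relative deviation 0.10. kDa↔Da conversion is a factor of 1000, and
rounding happens only at presentation. The residue-mass table is pinned as
a package constant (`AA_AVERAGE_MASS`) so results cannot drift with an
external dependency.

## Classification and summaries

`classify()` maps a curator-coded annotation state to one of seven
categories via a fixed first-match ladder: `MISSING_EC`,
`MISSING_SYNONYM`, `WRONG_EC` (the *data labeling* group — the activity was
nominally attached but unfindable), then `CLASS_LEVEL_ONLY`,
`NO_ACTIVITY_ASSIGNED`, `ADDITIONAL_ACTIVITY`,
`SIMILAR_ACTIVITY_REPLACED` (the *annotation update* group — the sequence
was present, its annotation out of date). The state record is explicit
(`level`, `same_activity`, `names_listed`, `ec_state`, `also_catalyzed`)
because deciding whether an annotation denotes the orphan activity is a
judgement call the package refuses to automate; when not coded, the name
membership fields are derived by normalized comparison against the official
name set. Contradictory states (no annotation but names present; a
class-level annotation claimed to be the specific activity; a sequence
already findable under correct EC and names) are errors, not guesses.

`summary()` on a ledger reports counts and percentages with **half-up
rounding to 2 decimals**. Denominators: total ledger size for the
resolved/open split; the resolved count for category, group, and method
shares. All denominators are echoed in the output, and the invariants
(subtype counts sum to group counts, group and method counts sum to the
resolved count) are enforced by construction and checked in tests.

## Synthetic fixtures

The fixture generators exist so that every operation is testable offline
with known ground truth. Their defaults describe the regime the method is
designed for, chosen once:

* census: 200 activities, orphan fraction 0.25 (the observed orphan burden
  is about a quarter of activities), 3 evidence sources, 1 planted
  single-submitter error cluster, ~3% non-ACTIVE entries;
* proteomes: 500 proteins of 100–400 residues, uniform residue
  composition, all Met-initial;
* reads: 15–25 cycles, 2 ambiguous cycles, 2 injected errors drawn from
  {substitution, cysteine loss, deamidation} as the true residue allows.

Generation is fully deterministic under a seed (integer-state RNG, no
float-dependent branching), and the truth tables are written beside the
outputs rather than smuggled into headers, so tests must recover the
answer through the same readers a user would call.

What the fixtures do **not** emulate: real amino-acid composition (uniform
alphabet; a composition model is a config hook, not a default), homologous
or repetitive proteome structure (random sequences make near-matches
vanishingly unlikely, so planted-target recovery rates here are an upper
bound on real-proteome behaviour), literature text beyond token planting,
and the temporal churn of a live catalog (entries deleted mid-study appear
only as catalog status, not as time series). Passing the fixture-based
tests therefore demonstrates correctness of the algorithms, not
performance on real curation corpora.

## Problem sizes and verification

The bundled checks run the census oracle comparison on 200 random
instances (≤30 activities × ≤100 evidence rows), the scan oracle
comparison on 100 random proteomes (≤50 proteins × ≤500 residues,
mismatch budget ≤2), and planted-target recovery on 100 seeded N-terminal
fixtures at the default regime, where the planted protein must be
top-ranked in at least 95% of replicates. These sizes are where the
brute-force oracles stay instant while still exercising every code path;
the implementation itself has no scale-dependent behaviour.

## Known limitations

* The census treats evidence tables as given; it has no notion of evidence
  quality beyond the flagged bit.
* The permutation rules are string rewrites, not chemical nomenclature
  parsing; they will not, for example, equate "hydroxybutyrate" with
  "3-hydroxybutanoate".
* The scanner reports Hamming mismatches only — no gaps. Edman reads do
  not contain insertions or deletions relative to the true sequence, but a
  frameshifted database sequence would be missed.
* No statistical significance (E-values) is attached to matches; at desk
  scale the mismatch count and the molecular-weight cross-check carry the
  inferential weight.
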