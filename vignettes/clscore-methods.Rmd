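---
title: "CLscore: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CLscore: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clscore)
```

## The model

The ChEMBL-likeness score ranks a molecule by how much of it is built from
substructures that recur in a reference corpus of bioactive compounds. The
substructure vocabulary is the set of *molecular shingles*: for every atom
`a` and every bond radius `r` in 1–3, the connected fragment made of all
bonds whose nearer endpoint lies within `r − 1` bonds of `a`, rendered as a
canonical SMILES string that starts at `a`, with aromatic atoms lowercase
and all stereochemistry discarded. Radii at which the molecule does not
extend that far (no atom at topological distance exactly `r`) are skipped —
such balls coincide with the shingle at their true radius. Within a molecule
every shingle is counted once, however many roots produce it.

A reference table maps each shingle to the number of corpus molecules
containing it at least once (presence counts, not occurrence counts), and
drops shingles seen in fewer than `min_count` molecules (default 100, the
value used for the published bioactivity corpus). For a query molecule with
`N` unique shingles, `m` of which are present with counts `f_1 … f_m`,

$$\mathrm{CLscore} \;=\; \frac{1}{N}\sum_{i=1}^{m} \log_{10} f_i .$$

Unmatched shingles contribute zero to the numerator but inflate `N`, so the
score is a frequency-weighted fraction of familiar substructure. Counts are
at least 1, so the score is non-negative, and bounded by
`log10(n_molecules)` of the corpus. A molecule with no shingles (a single
heavy atom) scores 0 by definition rather than raising a division error.

Library subsetting proceeds in three steps: score a SMILES stream and keep
records with CLscore at or above a cutoff (inclusive, taking the published
"≥ 3.3" literally); bin the survivors by the property triplet (heavy atom
count, stereocenter class, heteroatom class); allocate and draw a uniform
sample across the occupied bins.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `minRadius`, `maxRadius` | 1, 3 | shingle bond radii (diameters 2–6 bonds) |
| `minCount` | 100 | presence cutoff for storing a shingle |
| `cutoff` | none / 3.3 | inclusive CLscore filter on streams |
| `stereoMerge` | 5 | stereocenter counts ≥ 5 collapse into one class (classes 0–4, ≥5) |
| `heteroMerge` | 8 | heteroatom counts ≥ 8 collapse (classes 0–7, ≥8) |
| `target` | — | total sample size for the even allocator |
| `seed` | — | governs every random step (shuffles, generators, reservoirs) |

The merge thresholds follow the published binning of stereocenter count
(0–4, ≥ 5) and heteroatom count (0–7, ≥ 8); the overlapping "0–8, ≥ 8"
phrasing is resolved as a merged ≥ 8 class. Both are configurable.

## Canonicalization conventions

No R binding of a full cheminformatics toolkit offers rooted canonical
fragment SMILES, so the engine implements its own, and records its
conventions in a *canonicalization tag* (`canonicalizationTag()`). Tables
store the tag; scoring refuses a table whose tag differs from the running
engine, because fragment strings from different engines (or different
aromaticity models) are not comparable keys.

* **Parsing.** Organic-subset and bracket atoms, charges, isotopes, ring
  closures (including `%nn`), branches and dot-separated components.
  Stereochemistry tokens (`@`, `@@`, `/`, `\`) are parsed and discarded.
  Bracket atoms whose explicit hydrogen count equals the standard-valence
  implicit value (and with no charge or isotope) are demoted to plain atoms,
  so `[C@H]` normalizes to `C` once chirality is stripped, while pyrrole's
  `[nH]` keeps its bracket.
* **Aromaticity.** Lowercase input is authoritative. Kekulé rings are
  aromatized under a simplified Hückel model: simple rings up to size 7
  qualify when every member either has a double bond to another ring-system
  atom (1 π) or is an N/O/S/P lone-pair donor (2 π), exocyclic double bonds
  disqualify the ring, and the π sum is 4k + 2. This perceives benzenoids,
  common 5- and 6-membered heteroaromatics and ortho-fused systems such as
  naphthalene, but not non-alternant polycyclics (azulene) or charged rings
  (tropylium) from Kekulé input — supply those in aromatic lowercase form.
  An unmarked bond between two aromatic atoms outside any ring (the biphenyl
  linker) is a single bond.
* **Canonical writing.** Atom ranks come from iterative invariant refinement
  (element, aromaticity, charge, isotope, bracket hydrogens, degree; refined
  by sorted neighbour rank/bond pairs) with the root pinned ahead of all
  other atoms. While a non-singleton cell remains, each member of the
  lowest cell is individualized in turn and the lexicographically smallest
  string wins, so canonicalization is exact rather than heuristic. Implicit
  hydrogens are never written; charges and isotopes are written as parsed.
* **Whole-molecule canonical SMILES** (used by `--dedupe` and the fixtures)
  is the minimum of the rooted canonical strings over all atoms, components
  sorted and joined by `.`.

`parseMolecule(fragment = TRUE)` re-parses shingle strings themselves, where
aromatic atoms may occur without a complete ring; under that mode every
shingle string re-canonicalizes to itself (a tested invariant).

## Stereocenter perception

Enumerated libraries carry mostly unassigned stereochemistry, so the triplet
binning counts *potential* tetrahedral centers by default: non-aromatic
carbon or silicon (or positively charged nitrogen) with four substituents
counting implicit hydrogens, at most one hydrogen, no multiple bonds, and
substituents in pairwise distinct symmetry classes from unrooted refinement.
This approximates the common toolkit definition; dependent ("para")
stereocenters of meso-symmetric molecules are not counted. A mode restricted
to input-assigned centers (`stereoCenterCount(mode = "assigned")`) is
available.

## The even allocator and the sampler

Bins are sorted by ascending size (ties by bin key). Iteratively, the
remaining target is divided by the number of remaining bins, and every bin
no larger than that quota is taken whole; the per-bin quota is
non-decreasing across passes, so the procedure terminates with all remaining
bins strictly larger than the final quota. Those receive `floor(quota)`,
topped up by one extra draw per bin in ascending-size order until the total
equals `min(target, total)`. The published procedure is silent on rounding
at the constant-quota step; floor plus largest-remainder top-up hits the
target exactly while keeping open-bin quotas within ±1 of each other. One
boundary consequence: a bin of size `floor(quota) + 1` can be exhausted by
its top-up draw even though open bins hold quota `floor(quota)`.

Within each bin, records are drawn uniformly without replacement by
reservoir sampling under a bin seed derived deterministically (a polynomial
hash) from the run seed and the bin key, so a run is byte-reproducible from
its seed alone and bins can be drawn independently, in any order, from spill
files — the census/allocate/draw phases restart from the spill directory
without recomputing anything. The sampler saves and restores the caller's
RNG state.

## Synthetic fixtures: what they emulate and what they do not

`generateReferenceCorpus()` replicates scaffolds at chosen multiplicities,
so every table count is exactly predictable (a scaffold-specific shingle
counts its multiplicity; shared shingles the sum over sharing scaffolds) —
this emulates the only property of a reference corpus the score consumes,
the shingle frequency spectrum. `generateQuerySet()` draws from homologous
families (random-tree alkanes, alcohols/ethers, amines, substituted five-
and six-membered heteroaromatics) with heavy atom counts uniform over 6–14
by default, giving controlled shingle overlap with the reference scaffolds
and occupancy of many property triplet bins. The generators do **not**
mimic real bioactivity corpora: a power-law shingle frequency spectrum,
fused polycyclics, charged or isotopic species and large rings are absent.
Green tests therefore demonstrate the correctness of the machinery
(extraction, counting, arithmetic, allocation, sampling), not any claim
about how a particular real corpus scores.

The default problem sizes — a 500-molecule reference corpus, 5,000 queries,
a 500-record sample — were chosen as the smallest scale at which the
pipeline's statistical behaviour is visible (the 60th-percentile cutoff
retains 40 % up to tie mass at the boundary; ~100 occupied bins) while a
full end-to-end run stays interactive on a single core.

## Numerical and degenerate-input choices

* Ties at the score cutoff are kept (inclusive `>=`), matching the published
  phrasing; the percentile-derived cutoff uses the empirical quantile
  (type 1), so boundary tie mass slightly raises retention.
* Duplicate corpus molecules each contribute to counts by default, mirroring
  raw corpus statistics; `dedupe` canonicalizes and deduplicates first.
* Unparseable records are skipped and counted everywhere (strict modes
  abort); an all-failed corpus yields an empty table with a warning.
* Lookup of an absent shingle is an explicit `NA`, never a zero count.
* Table files are bytewise-stable UTF-8: fixed-order `#key<TAB>value`
  headers, then entries sorted in C-locale byte order.
* Explicit `[H]` atoms fold into their heavy neighbour; charged or isotopic
  hydrogens stay graph atoms.

## Known limitations

* The aromaticity model is deliberately small; exotic aromatic systems must
  be supplied in lowercase aromatic form to be treated as such.
* Shingle strings are engine-specific dictionary keys. They are valid
  SMILES under `fragment = TRUE` parsing, but scores computed against tables
  from any other canonicalization engine are meaningless — hence the tag
  check.
* Symmetry classes from equitable refinement may merge atoms that a full
  orbit computation would separate only in pathological regular graphs;
  for the chemistry the package targets this does not occur at the fragment
  sizes involved.
* Protonation-state normalization is not performed; corpus and queries
  should be pre-standardized consistently if that matters for the
  application.
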