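---
title: "uvvisdb: methods, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{uvvisdb: methods, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvvisdb)
```

## The problem

Optical-materials discovery needs large, paired sets of experimental and
computed UV/vis absorption attributes: the wavelength of an absorption
maximum, $\lambda_{max}$ (nm), its intensity as the molar extinction
coefficient $\varepsilon$ (L mol$^{-1}$ cm$^{-1}$), and the computed
analogues — first-excitation wavelengths and oscillator strengths $f$ —
from excited-state electronic-structure methods. Text mining can
auto-generate the experimental side at a scale no manual curation
reaches, but the raw extraction output is noisy in characteristic ways:
multi-valued table cells lose their wavelength–extinction pairing,
extinction units arrive in three different printed conventions, compound
names resolve to SMILES strings that contain garbage tokens, salts and
organometallics that no high-throughput wavefunction pipeline should
attempt, and a sub-population of extinction values whose standard-form
exponent was dropped or garbled in print. `uvvisdb` implements the
curation and validation machinery for exactly this situation.

## Peak pairing from multi-valued table cells

The pairing model is deliberately minimal. A wavelength cell is a list of
numerals in printed order; a cognate extinction cell is another list.
When — and only when — the two lists have the same length $n$, the $i$-th
wavelength is paired with the $i$-th extinction. Anything else (unequal
lengths) degrades gracefully to isolated single-quantity peaks. The
invariant that matters is *value conservation*: parsing and pairing never
drop, truncate, or invent a value, so downstream statistics can trust the
peak multiset.

Unit handling covers the three conventions that dominate the literature:

* plain values, already in L mol$^{-1}$ cm$^{-1}$;
* standard form, a `x10^n` factor printed in the cell or (more commonly)
  the column header — values are multiplied by $10^n$;
* logarithmic, a `log` marker — values are mapped through $10^x$.

Decisions taken where the conventions are silent:

* separators are comma, semicolon, slash or whitespace (commas dominate);
* `log` means $\log_{10}\varepsilon$ (the universal UV/vis convention);
* when cell and header both carry an exponent, the header wins — a single
  table is assumed internally consistent;
* parenthesized annotations (shoulder marks like `(sh)`) are stripped
  before tokenization;
* a cell carrying both `log` and `x10^n` markers is refused as ambiguous
  rather than guessed at.

Only the single-cell case is implemented: matching multi-row blocks per
compound is a different (document-level) problem and out of scope.

## The five-rule opto-electronic filter

The filter turns raw text-mined SMILES into neutral, conjugated organic
chromophores cheap enough for excited-state calculations. Rules run in a
fixed order with short-circuiting, and the per-molecule report records
results only for the rules actually reached — so the order is observable.

1. **Sanitize.** Bracket tokens containing characters outside the SMILES
   alphabet (notably `<` and `>`) are removed; if nothing parseable
   remains the molecule is rejected; otherwise the survivor is
   canonicalized. Canonical SMILES and InChIKeys come from RDKit through
   a batched subprocess bridge — these are the two primitives the field
   never reimplements, and the package treats them as infrastructure. All
   *rule logic* below runs on the package's own R-side molecular graph
   (parser, implicit-hydrogen assignment, ring detection, writer), which
   doubles as an independent code path: tests cross-check its electron
   counts against the toolkit's on randomized molecules.

2. **Composition.** Allowed elements are H, B, C, N, O, F, Si, P, S, Cl,
   Se, Br, I — the organic/organochalcogen palette of dye chemistry.
   "Charged species" is read conservatively: *any* nonzero formal charge
   anywhere fails, including net-neutral zwitterions, because a formal
   charge signals either a salt form or a resonance-annotated structure,
   and both are poor starting points for a gas-phase ground-state
   calculation. Multi-fragment inputs keep the largest fragment only
   after every fragment passes composition; salts fail there anyway.

3. **Conjugation.** Pass requires an aromatic ring, or at least two
   multiple bonds joined through one single bond (a conjugated path of
   length ≥ 2 multiple bonds). A lone C=C was judged too weak a reading
   of "significant π-conjugation": an isolated alkene absorbs far below
   the UV/vis window of interest. Cumulated double bonds (C=C=C) do not
   count as a conjugated path.

4. **Trim.** Every acyclic, saturated, carbon-only substituent of ≥ 2
   carbons attached at a single atom of (or adjacent to) the conjugated
   system is replaced by one methyl carbon. The ≥ 2-carbon threshold is a
   decision — the rule's stated target is methyl, and alkyl substitution
   beyond the attachment point has negligible effect on the chromophore.
   Ring atoms, heteroatom-bearing chains, and chains that *link* two
   conjugated fragments are never touched (a linker attaches at two
   atoms, and cutting it would change the molecule's identity, not its
   cost). Trimming is idempotent and can only lower the electron count.

5. **Electron count and banding.** NEL is the total electron count of the
   neutral molecule — the sum of atomic numbers with implicit hydrogens
   included — computed **after** trimming, since trimming precedes
   banding in the rule order and the banded molecule is the one that
   would be computed. Bands: small 50–140, medium 141–220, large
   221–300, extra large 301–370; below 50 too small, above 370 too
   expensive. The band partition is exhaustive and gap-free, which the
   tests assert over the whole axis.

One consequence worth stating: a neutral closed-shell molecule always has
an even electron count, so the odd boundary values (49, 141, 221, 301,
371) are not realizable by any actual molecule. The validation suite
therefore straddles each boundary with the nearest even electron counts
(42/50, 140/142, 220/222, 300/302, 370/372 — built from substituted
polyenes whose formulas are hand-derived) and checks the odd integers
directly on the banding function.

## The record schema

One document per compound, keyed by InChIKey (`14-10-1` hyphenated
uppercase pattern). `PRISTINE` holds everything as extracted: SMILES
spellings under `SMI`, and `uvvis` entries each carrying its `doi`,
optional `solvent`, and `peaks` with `lambda`, `lambda_unit`,
`extinction`, `extinction_unit`. `FILTERED` appears only on compounds
that passed all five rules and holds the canonical trimmed SMILES, NEL,
band, and computed blocks (`orca` for sTDA, `nwchem` for TD-DFT, `mopac`
for the semi-empirical screen), each with `excited_states` ordered by
index — index 1 is the lowest-energy, longest-wavelength excitation.

Null convention: absent keys, JSON `null` and the literal string `"NULL"`
all load to one internal marker (`NA`); on write, JSON emits native
`null` and CSV emits the literal `NULL`. The CSV is the flat projection
of the schema keys, one row per (compound, peak); it is lossy by design
(no excited-state detail beyond the first sTDA state, which surfaces as
`amplitude`/`oscillator_strength`). Unknown document keys are preserved
verbatim in an opaque extras map and re-emitted on write, for forward
compatibility with richer document trees. MongoDB support means
write-compatibility of the JSON documents; no live server is used
anywhere.

Deduplication merges all instances of one InChIKey, concatenating their
UV/vis entries (each keeps its DOI) — it is idempotent and conserves the
total entry count, and records with a null key go to a rejects list
rather than being silently merged.

## Validation statistics: numerical choices

* **Histograms** are left-closed right-open, fixed origin and width. The
  wavelength analyses use origin 0 and width 12 nm; the extinction
  histogram uses width $6.25\times10^3$. The experimental-vs-computed
  intersection is computed on *proportions* (each histogram normalized by
  its own total) so unequal sample sizes compare fairly, and reuses the
  12 nm/origin-0 binning — the comparison's own binning is otherwise
  unstated, so this decision is surfaced as a parameter (`--bin-width`)
  rather than buried.
* **Skewness** is the adjusted Fisher–Pearson standardized third moment,
  $G_1 = g_1\sqrt{n(n-1)}/(n-2)$, matching common statistical software.
* **Percentiles and quartiles** use linear interpolation between closest
  ranks (R type 7). This matters for the extinction flags: the 20th/90th
  boundaries are applied with *strict* inequality on percent ranks
  $100(r-1)/(n-1)$, so a degenerate all-equal sample flags nothing, and
  the flagged fractions sit within one rank of the nominal 20%/10%.
* **Extinction range**: values outside $[10^3, 5\times10^5]$ are
  `out_of_range` (inclusive bounds — $5\times10^5$ itself is retained)
  and excluded from percentile computation.
* **The conversion** $\varepsilon_{calc} = f \cdot 2.699\times10^4 / b$
  is implemented exactly as stated. The units of the line width $b$ are
  not specified by the source of the formula; the function treats $b$ as
  dimensionally consistent with the constant and leaves interpretation to
  the caller. No optimization of $b$ is attempted.
* **Regression bands** are pointwise OLS confidence intervals for the
  mean response at the stated level (98% in the validation figures);
  $R^2$ is computed directly as $1 - RSS/TSS$ to avoid the degenerate
  perfect-fit path in `summary.lm`.
* **Solvent tally**: one count per compound per canonical solvent
  (multiple measurements of one compound in one solvent count once),
  alias spellings (EtOH/ethanol/Ethanol, DCM/dichloromethane, …)
  canonicalized case-insensitively, output ordered by increasing static
  dielectric constant. The dielectric table stores handbook values
  (toluene 2.38 … DMSO 46.7, with DMF at its 20 °C value 38.25, which
  places acetonitrile before DMF as in the validation chart). Unknown
  names are reported in an `unrecognized` bucket, never guessed.

## The synthetic world

`fixture_spec()` states the world once; generators are pure functions of
(spec, seed):

* **Wavelengths**: a 190 nm-shifted lognormal, $\sigma = 0.4$, mode near
  400 nm (mean ≈ 456 nm, median ≈ 437 nm). This reproduces the two
  features the statistics depend on — positive skew and density
  concentrated below 550 nm — on the stated support 190–1,200 nm (draws
  above 1,200 nm are resampled; < 0.1% truncation, so the closed-form
  lognormal skewness $(e^{\sigma^2}+2)\sqrt{e^{\sigma^2}-1} \approx 1.32$
  remains the test oracle). The exact law is a fixture choice, not a
  claim about any real dataset.
* **Extinctions**: log-uniform on $[10^3, 5\times10^5]$; a `corrupt_frac`
  sub-population (default 10%) carries a garbled exponent — bottom-decile
  values scaled by $10^{-1}$, top-decile by $10^{+1}$ — guaranteeing the
  corrupted values land outside the physical range, which reproduces both
  percentile-extreme anomalies the flagging stage is built to catch and
  makes "flagged ⊇ corrupted" an exact property.
* **Computed overlays**: first-state wavelength = experimental
  $\lambda_{max}$ − blueshift + Gaussian noise, defaults 55 nm and 15 nm
  — the scale of the gas-phase-vs-solution discrepancies (Stokes shifts,
  solvatochromism) seen when validating sTDA against experiment; the
  TD-DFT-like block gets 0.8× the bias, mirroring the observed MAE
  reduction. Oscillator strengths are lognormal(log 0.4, 0.6), a positive
  law with most mass in the 0.1–1.5 range typical of allowed transitions.
* **Records** carry synthetic DOIs, valid-format (but fictitious)
  InChIKeys, and solvent spellings drawn with alias variants. About 20%
  of peaks carry an extinction value, the order of magnitude seen in
  practice after unit-bearing extraction.

What a green test does and does not establish: the generator reproduces
the *statistical shape* the validation suite assumes, so green tests
establish that the statistics, flagging logic and record plumbing behave
correctly on data of that shape. They establish nothing about chemical
realism — the synthetic SMILES decorating the records are a small fixed
palette, wavelengths are not functions of structure, and no
quantum-chemistry output is ever computed (conformers, PM7, DFT, sTDA and
TD-DFT executions are explicitly out of scope; their outputs are only
*ingested* via the schema).

## Acceptance scope

Three target classes exist. Desk-reproducible arithmetic identities (the
modal-bin percentage 20.01%, the pairing improvement factor 5.3, the 762
false positives) are recomputed by `scripts/acceptance.R` from their
stated inputs. Property-based criteria (filter end-to-end on the molecule
suite, pairing round-trips, electron-count cross-checks, histogram
intersection brute force, bias recovery, conversion laws, subsample
stability at the 7,600-point scale) run offline in
`tests/testthat/test-acceptance.R`. Accession-level queries against the
published deposit require a network download and are deliberately absent
from the offline report; the loader and statistics they would exercise
are the same code the property suite covers. Not reproducible at desk
scale at all: the full-corpus extraction, and any re-run of the quantum
chemistry.

## Known limitations

* The SMILES parser targets toolkit-canonical output (aromatic lowercase
  form); Kekulé inputs are canonicalized through the bridge before graph
  analysis, so aromaticity perception is inherited from the toolkit, not
  duplicated. Exotica (radicals, dative bonds, polymers) are out of
  scope.
* The CSV dialect does not quote fields; values containing commas would
  break the projection. The deposit-style fields (keys, DOIs, numbers,
  solvent names) do not contain commas.
* CSV re-loading groups consecutive rows by (inchikey, doi, solvent);
  two *distinct* entries of one compound with identical DOI and solvent
  merge into one — invisible under the Table-1 projection, which is the
  CSV's contract.
* `epsilon_flags` assumes enough retained values for percentile ranks to
  be meaningful; with a single retained value it flags nothing.
* The filter's conjugation and trimming criteria are decisions where the
  stated rules are qualitative; both are flagged above and isolated
  behind their own functions so a sensitivity analysis can swap them.
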