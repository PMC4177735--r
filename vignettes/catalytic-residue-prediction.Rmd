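---
title: "Catalytic residue prediction from side-chain orientation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic residue prediction from side-chain orientation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catres)
```

## The signal being modelled

Catalytic residues of an enzyme tend to orient their functional side-chain
atoms toward a common point — the center of the catalytic site — so that
they are poised to contact the substrate. Noncatalytic residues show no
such concerted orientation: their side chains point in effectively random
directions. catres turns this geometric observation into a ranking of all
residues of a structure by their likelihood of being catalytic, using only
the coordinates of a single structure (no homology information), optionally
sharpened by sequence conservation.

Three residue-level signals enter the score:

* **Side-chain orientation.** For each residue $k$ of one of 12 eligible
  types, a side-chain vector $s_k = X_k^F - X_k^{C\alpha}$ points from the
  C$\alpha$ to a designated functional side-chain atom $X_k^F$ (ARG: CZ,
  ASN: CG, ASP: CG, CYS: SG, GLN: CD, GLU: CD, HIS: NE2, LYS: NZ, SER: OG,
  THR: OG1, TRP: CZ2, TYR: OH). The remaining 8 types usually act, when
  catalytic at all (roughly 5% of catalytic residues), through backbone
  atoms; they are excluded from the orientation ranking and reported
  separately (`backbone_report()`).
* **Rigidity.** The weighted contact number
  $w_k = \sum_{m \neq k} 1/r_{km}^2$ over C$\alpha$ distances; catalytic
  residues sit at rigid, tightly packed positions. The B-factor is
  deliberately not used: it is missing for NMR models and inconsistent
  between crystal forms, while WCN depends only on coordinates.
* **Amino-acid combination.** A 20×20 profile matrix $p$ whose row $p_x$
  holds the frequency with which each type co-occurs in the same catalytic
  site as type $x$, estimated from a catalytic-site annotation table.

## The scanning procedure

After removing all nonprotein content (waters, ions, ligands;
selenomethionine is kept as MET), the structure is embedded in a
$30 \times 30 \times 30$ grid of points spanning the C$\alpha$ bounding
box. Each grid point $i$ is a hypothetical site center. Its *surrounding
residues* are the vector-bearing residues with
$\lVert X_i - X_j^{C\alpha}\rVert < 10$ Å (strict). For each surrounding
residue $j$ the angle

$$\theta_{ij} = \arccos\frac{v_{ij}\cdot s_j}{\lVert v_{ij}\rVert\,\lVert s_j\rVert},
\qquad v_{ij} = X_i - X_j^{C\alpha}$$

measures how directly the side chain points at the grid point. Points with
fewer than three surrounding residues are removed, then points whose mean
angle $\bar\theta_i$ exceeds 80° (strictly) are removed. The 80° cutoff
reflects the empirical distribution of $\theta$ for catalytic residues at
their own site centers: roughly 80% of them fall at or below 80°.

For each surviving point, every combination of three surrounding residues
(a *triplet*) is scored. Each member $j$ of a triplet receives

$$S_{j,\text{triplet}} = w_n + z_j^w + z_j^a$$

where $w_n$ is the mean normalized WCN of the three members, $z_j^w$ the
residue's normalized WCN, and $z_j^a$ the normalized combination score
$a_j = p_x^y + p_x^z$ ($x$ the type of $j$; $y, z$ the types of the other
two members — asymmetric, always read from $j$'s own profile row). A
residue's structure score $S_j$ is the sum of these feature scores over
every triplet of every grid point that includes it; the ranked list is
sorted by $S$ descending. Residues that enter no triplet keep $S = 0$ and
are listed after all scored residues; all remaining ties break by chain,
residue number and insertion code, which makes runs bit-reproducible.

With a PSI-BLAST PSSM supplied, the per-position information content
$c_j$ (bits) is normalized over all positions of the chain to $z_j^c$ and
fused as $S'_j = S_j + 1.6\,z_j^c$; 1.6 is the default weight at which the
conservation term balances the structure term. With weight 0, or with a
flat conservation profile, the fused ranking reduces exactly to the
structure-only ranking. catres only parses the ASCII PSSM
(`-out_ascii_pssm`); running PSI-BLAST itself (typically 3 iterations
against nr, E-value threshold $5\times10^{-3}$) is the user's
responsibility and out of scope here.

## Normalization conventions

All three z-normalizations use **population** (divide-by-$n$) standard
deviations, computed per protein:

* $z^w$ over all residues of the processed structure (not only
  vector-bearing ones — every residue contributes to packing);
* $z^a$ over the full multiset of per-membership combination scores
  generated during triplet enumeration, collected in a first pass before
  any score is assigned. This is the one population in which every $a_j$
  value actually lives; "all residues of the protein" is ambiguous for a
  triplet-dependent quantity.
* $z^c$ over all PSSM positions of the chain.

Choosing population rather than sample SD matters less than using the same
convention in all three places; the scores are sums of z-scores and any
consistent convention only rescales them jointly. Degenerate cases are
explicit: a constant combination-score multiset (e.g. a uniform profile)
sets every $z^a$ to 0 with a warning rather than dividing by zero, and the
variance computed by the closed-form accumulator is clamped to 0 when it
falls below $10^{-8}(1 + |\bar a|)$, where cancellation noise would
otherwise be amplified by the division.

## The fast accumulator and its oracle

Enumerating $\binom{N}{3}$ triplets for 27,000 points is infeasible for
real proteins, but the triplet sum decomposes in closed form. For a point
with surrounding set $R$, $|R| = N$, and member $j$:

$$\sum_{\text{triplets} \ni j} (w_n + z_j^w)
  = \tfrac{4}{3}\binom{N-1}{2} z_j^w
  + \tfrac{N-2}{3} \sum_{m \in R \setminus j} z_m^w,
\qquad
\sum_{\text{triplets} \ni j} a_j = (N-2) \sum_{m \in R\setminus j} p_{x(j)}^{x(m)}.$$

The first two moments of the combination-score multiset, needed for the
$z^a$ normalization, are also closed-form: per residue and point the sum of
$a_j^2$ over memberships is $(N-3)Q_j + P_j^2$ with
$P_j = \sum_m p_{x(j)}^{x(m)}$ and $Q_j = \sum_m (p_{x(j)}^{x(m)})^2$.
`accumulate_scores_bruteforce()` implements the literal enumeration and is
kept as the reference oracle; the test suite and the acceptance script
verify $\max|\Delta S| < 10^{-9}$ between the two paths on randomized
fixtures (the observed agreement is at the $10^{-13}$ level).

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `grid_points` | 30 | points/axis | fixed point count keeps cost independent of protein size; spacing lands around 1.3–2.1 Å for typical proteins |
| `radius` | 10 | Å | catalytic sites fit in a ~10 Å ball; strict `<` |
| `theta_cutoff` | 80 | degrees | covers ~80% of catalytic residues' own-site angles; strict `>` removal, a mean of exactly 80° is kept |
| `min_surrounding` | 3 | residues | a triplet needs three members |
| `cons_weight` | 1.6 | – | balance of conservation vs structure score |
| `max_residues` | 5000 | residues | guard against accidental huge inputs; override with the flag |

The grid is anchored to the C$\alpha$ bounding box (origin at the minimum
corner, spacing extent/29, faces touching the box). Whether the original
scanning grid was padded or centroid-centered cannot be recovered from the
published spacing range alone; the bounding-box anchor is this package's
documented choice, and predictions very close to the box faces inherit a
mild sensitivity to it. Likewise, "NE" for histidine, "CZ" for tryptophan
and "OG" for threonine are not standard PDB atom names; catres uses NE2
(the canonical catalytic nitrogen), CZ2 and OG1, the nearest standard
atoms. These choices shift $\theta$ by a few degrees for those types.

## What the synthetic generator emulates — and what it does not

`make_toy_structure()` builds the one geometry the score reads: a planted
"catalytic site" of $\geq 3$ vector-bearing residues whose C$\alpha$ sit on
a ring (default radius 4 Å) around a center, side-chain vector atoms
displaced 2.4 Å toward that center with 8° angular jitter (the
displacement sign flips for outward controls), among decoy residues with
random side-chain directions. Decoy placement encodes the fixture's
premise — *the planted ring is the only dense, inward-pointing cluster*:

* decoys live in a shell starting at ring radius + surrounding radius
  (14 Å), so none of them can be a surrounding residue of the planted
  center;
* a 6 Å minimum separation approximates surface-residue spacing;
* a new decoy is rejected while more than one already-placed residue lies
  within 10 Å of it. Without this cap, random placement occasionally
  condenses decoys into 4–6-residue clumps tighter and more rigid than the
  planted ring — effectively a second, unlabeled site, which is not what a
  decoy is.

The generator writes ideal-geometry atoms only (C$\alpha$, the designated
vector atom, and dummy N/C/O for format validity). It does **not** emulate
backbone continuity, rotamer libraries, packing density of real protein
interiors (a real 10 Å ball holds 25–35 residues, the fixture's 3–7), side
chains of noncatalytic residues near the site, or solvent. Passing the
planted-site tests therefore demonstrates that the scoring machinery ranks
a concerted inward cluster above random-orientation background under
controlled geometry — not that the method attains its published accuracy
on real enzymes, which depends on the full density and orientation
statistics of real structures.

Problem sizes used by the test-suite and the acceptance script — 28-residue
fixtures, 100 replicates for recovery and oracle checks, 30 structures for
the synthetic dataset ROC — were chosen so each property is measured with
comfortable margins while a full run stays in the tens of seconds.

## Evaluation protocol

Per protein, a ROC curve (and a recall–precision curve) is built by a
threshold sweep over the distinct score values, ties processed together;
the AUC by trapezoid equals the Mann–Whitney statistic of the ranking.
Dataset curves are **vertical averages**: each per-protein curve is
evaluated at 101 evenly spaced x values by step (right-continuous)
interpolation and averaged per grid point; the dataset AUCROC is the
trapezoid area of the averaged curve. Step interpolation is the natural
reading of averaging empirical step curves — linear interpolation would
systematically inflate the average of extreme curves. Proteins lacking
either label class are excluded from averaging with a warning.

## Degenerate inputs and numeric choices

* Alternate locations: the highest-occupancy conformer wins; ties prefer
  altloc A, then the first seen. Multi-model files use model 1 only.
* Residues missing C$\alpha$ are dropped (warned, counted); residues
  missing their designated vector atom stay in the structure and in WCN
  but never in orientation or triplets. A vector atom coincident with
  C$\alpha$ (zero-length vector) is excluded with a warning.
* Cosines are clamped to $[-1, 1]$ before `acos`; angles are reported in
  degrees in $[0, 180]$.
* Coincident C$\alpha$ pairs make WCN undefined and raise an error naming
  the pair; zero WCN variance (e.g. two residues) makes the z-score
  undefined and is an error unless normalization is declined.
* Degenerate grid axes (planar structures) fall back to 0.5 Å spacing; a
  fully collapsed structure is an error.

## Known limitations

* The shipped co-occurrence profile is built from a small synthetic
  annotation table of textbook catalytic chemistries
  (`inst/extdata/synthetic_catalytic_sites.tsv`); it stands in for a real
  Catalytic Site Atlas-derived profile, which users should rebuild with
  `build_profiles()` from a CSA dump for production use. The annotation
  format therefore carries an `aa` column, since residue types cannot be
  recovered from the annotation alone without the structures.
* One PSSM maps to one chain; in multi-chain runs other chains keep
  $z^c = 0$.
* No structure repair, no mmCIF, no solvent-accessibility pruning, no
  probability calibration of $S$, and no clustering of top residues into
  discrete predicted sites.

## A worked synthetic example

```{r example}
pdb <- make_toy_structure(toy_site_spec(seed = 42))
pred <- predict_catalytic_residues(pdb)
head(pred$scores[, c("rank", "chain", "resno", "aa", "S", "triplet_count",
                     "z_wcn", "mean_z_a")], 5)
```

Residues 1–3 are the planted site; their $S$ separates them clearly from
the best decoy. The same pipeline is exposed on the command line as
`exec/catres predict`, `evaluate` and `make-fixture`.
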