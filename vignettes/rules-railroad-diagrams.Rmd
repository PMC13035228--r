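---
title: "Railroad diagrams for reaction rules: model, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Railroad diagrams for reaction rules: model, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulerail)
```

## The problem

Rule-based models describe signaling systems as pattern-transforming
reaction rules over site graphs: molecules carry named sites, sites carry
internal states (e.g. a tyrosine that is unphosphorylated `u` or
phosphorylated `p`) and bonds (shared `!k` indices in BNGL text). A rule
matches any species containing its reactant pattern and rewrites the
matched part. Because one pattern can match combinatorially many species,
the textual rule is compact but hard to read, and the conventional
reactant/product cartoon repeats all shared context on both sides of the
arrow.

`rulerail` takes the opposite route: one diagram per rule, in which the
required context is the railroad structure itself and the transformation is
embedded into it as marked boxes. This vignette explains the underlying
model, the conventions, and the design decisions that were genuinely open.

## Railroad algebra and what a path means

The core algebra is the classical one for syntax diagrams: `rr_terminal`,
`rr_seq`, `rr_choice`, `rr_optional` and `rr_skip`. Every left-to-right
traversal of a lane spells one word; `enumerate_words()` lists them and
`count_words()` counts them by the product/sum recursion
(sequence = product, choice = sum) without materializing the list. The two
are kept consistent by a property test over hundreds of random lanes.

```{r}
lane <- rr_seq(rr_terminal("The"), rr_optional(rr_terminal("quick")),
               rr_terminal("fox"))
count_words(lane)
```

For molecules, a "word" is a fully specified molecular form. A molecule
diagram is one lane: the molecule name, then for each multi-state site a
choice over its declared states. Site names are attached as dashed
annotations and contribute nothing to the enumeration, so the lane's word
count equals the form count computed independently by the parser:

```{r}
model <- read_bngl(system.file("extdata", "egfr_grb2.bngl", package = "rulerail"))
ctx <- model$molecule_types
egfr <- ctx[[3]]
count_words(build_molecule_diagram(egfr)$lanes[[1]])
count_forms(parse_pattern("EGFR()"), ctx)
```

This cross-module identity (diagram word count = parser expansion count) is
asserted on every synthetic fixture in the test suite.

## Species, observables, bonds

A multi-molecule species gets one lane per molecule. Explicit bonds become
solid cross-lane connections between ports placed just after the bound
site's element. All molecules of one species are additionally joined by a
*dashed* chain — connectivity markers, not traversal paths. The dashed
chain is drawn as a spanning chain (lane *i* to lane *i+1*) rather than the
complete pair set: for the two-molecule complexes that dominate real models
the two are identical, and for longer chains the spanning chain conveys the
same "same complex" relation with far less clutter.

Observables constrain connectivity in two ways and the diagram keeps them
apart without color: a site written `!+` **must** be bound and gets a solid
stub ending in an arrowhead (the bond continues to an unspecified partner);
a site written `!?` **may** be bound and gets a grey dashed stub ending in a
question mark. Unconstrained multi-state sites are expanded into state
choices, so an observable lane enumerates exactly its matching forms.
A deliberately narrow reading was chosen for "potential" bonds: only sites
the source text marks `!?` receive question-mark stubs; unmentioned sites
are unconstrained but undecorated. Decorating every unmentioned site was
the plausible alternative; it was rejected because it buries the
constraints the modeler actually wrote.

## Deriving a rule's actions

`diff_rule()` recovers the transformation a rule performs:

1. **Correspondence.** Product molecules are matched to reactant molecules
   by name, then by occurrence order among same-named molecules — the
   BioNetGen convention. Unmatched product molecules are created, unmatched
   reactant molecules deleted.
2. **Site comparison.** Within each matched pair, sites are matched by name
   and occurrence. A site stated in a different state on the two sides
   yields a `StateChange`; bond sets (expressed in reactant coordinates)
   are differenced into `AddBond` and `DeleteBond` actions.
3. **Classification.** An `AddBond` whose endpoints lie in the same
   reactant pattern is intramolecular — the molecules are already
   co-complexed, which matters kinetically (local concentration) and
   visually (the dashed chain is already present). Matched molecules with
   no action on any site are catalysts. Under this definition the dimer
   partner in a transphosphorylation rule is also reported as a catalyst:
   it is required context that the rule leaves untouched, exactly like an
   explicitly catalytic phosphatase.

Wildcard bond marks (`!+` bound-to-anything, `!?` bound-or-unbound) are
context, never action endpoints. A mark that changes wildcard class across
the rule (say `!+` on the left, unbound on the right) admits no single
elementary action; such rules are ambiguous in BNGL itself and are rejected
with an inconsistency error rather than silently guessed at.

One piece of information is *not* derivable from the action list alone:
whether severing a bond dissolves the complex. BNGL encodes it in the
product side's grouping — `A(x) + B(y)` (separate) versus `A(x).B(y)`
(still co-complexed through unwritten context). The `DeleteBond` action
therefore carries a `split` flag taken from the product grouping, and the
reverse of an intramolecular `AddBond` is a non-splitting `DeleteBond`.

**Verification oracle.** `apply_actions()` independently re-applies an
action set to the reactant patterns — rewriting bonds, states and
composition, then regrouping molecules into complexes (bond components,
plus non-splitting severed pairs, plus dot-context complexes whose
connectivity was never fully explicit). The invariant
`apply_actions(reactants, diff_rule(rule)) ≅ products` (graph isomorphism,
brute-forced over molecule permutations — patterns in rules have a handful
of molecules) is asserted for every case-study rule and over one hundred
seeded synthetic rules.

Rules that degrade a molecule still explicitly bonded to a survivor would
leave a dangling bond; `validate_degradation()` emits a diagnostic per
offending deletion (a warning by default, an error under
`strict_degradation`).

## Rendering conventions

Action boxes carry machine-readable glyphs so that diagrams work in
monochrome: downward arrow = bond creation, upward arrow = bond
destruction, vertical double-headed arrow = state transition, paired
opposite arrows = reversibility (the box class always reflects the forward
direction). State changes render as the before state, the transition box,
and the after state along one continuous path; the other states of that
site are omitted in rule diagrams because the rule already pins them.
Synthesis and degradation wrap the affected lanes in dashed boxes labelled
`synthesized` / `degraded`. Dash patterns are written as presentation
attributes on the elements, and colors only in one embedded `<style>`
block, so stripping the style sheet never loses a distinction — a property
the test suite checks by inventorying glyph classes in style-free output.

## Layout and numerical choices

Layout is a pure function of the diagram and a single geometry structure
(`rr_geometry()`: box height 22, arc radius 8, lane gap 46, all in SVG user
units, all cosmetic). Text width uses a fixed-width approximation
(characters × 7.2) so geometry never depends on installed fonts; output is
byte-identical across runs and platforms. Choices place their first child
on the main line and fan the rest downward with rounded arcs; cross-lane
links are routed orthogonally through the gutter below the lanes they
connect, one gutter level per link. Lanes are single rows; a very long rule
overflows horizontally rather than wrapping — a known limitation.

Two combinatorial guards protect interactive use: `expand_forms()` refuses
above 10,000 forms and `enumerate_words()` above 10,000 words (both
configurable); the counting functions are unbounded since they never
materialize.

Ties and degenerate inputs: bond indices are canonicalized 1..n by first
appearance (so any serialization is a fixed point after one pass);
duplicate site names within a molecule are resolved by occurrence order
against the declared order; a zero-site molecule is a one-word lane; an
empty model renders to an empty diagram set without error.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` produces seeded BNGL models whose rules are built
*action-first*: an action kind is drawn (weights 3/2/3/1/1 over bond-add /
bond-delete / state-change / synthesis / degradation), then a consistent
reactant/product pair is written around it, so the ground-truth action set
is known by construction and shipped as a manifest. Defaults (3 molecule
types, up to 3 sites, 2-state sites, 4 rules) mirror the scale of the
shipped EGFR/Grb2 example (4 sites, two 2-state tyrosines).

The generator covers every action kind, catalyzed variants, wildcard-free
patterns and homo- as well as hetero-dimerization. It does **not** emulate
several things real models contain: rules performing several simultaneous
actions, wildcard context in rules, compartments, or large complexes. A
green property suite therefore demonstrates correctness of the
parse–diff–apply–render pipeline on well-formed single-action rules, not
robustness against every construct of full BNGL; the tolerated-but-ignored
handling of unsupported blocks is tested separately on the shipped model.

## Scope and limitations

The package visualizes individual rules; it deliberately offers no
whole-model overview (that is what contact maps are for), no kinetics (rate
expressions are carried verbatim, never interpreted), no simulation or
network generation, and no compartment syntax beyond tolerant pass-through
of unsupported blocks. Kappa and SBML-multi inputs are out of scope.
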