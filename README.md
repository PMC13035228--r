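# rulerail

Railroad-style diagrams for rule-based biochemical models.

Rule-based modeling (BioNetGen, NFsim, Kappa, ...) describes a signaling
system as a set of reaction rules over multi-site molecules: each rule names
the structural context a species must match (sites, internal states, bonds)
and the transformation it performs (bond formation or breakage, a state
change such as phosphorylation, synthesis or degradation of a molecule).
Reading such rules from BNGL text is hard, and the conventional cartoon —
reactants and products on either side of an arrow — duplicates the shared
context and separates it from the change.

`rulerail` renders each molecule, species, observable and reaction rule of a
BNGL model as a single *railroad* (syntax) diagram: a flowchart in which
every left-to-right path is one valid molecular form, extended with

* solid cross-lane connections for explicit bonds and dashed connections for
  co-complex membership,
* action boxes embedded in the affected paths — a downward arrow for bond
  formation, an upward arrow for bond breakage, a vertical double-headed
  arrow between the before/after states of a state change, a paired
  arrow for reversible rules,
* required (solid) vs optional (grey, `?`) connectivity stubs for
  observables,
* dashed enclosures labelled `synthesized` / `degraded` for composition
  changes.

Every semantic distinction is carried by a glyph, dash pattern or label in
addition to an overridable color class, so the SVG output remains fully
interpretable in monochrome.

## What the package computes

For a reaction rule with reactant patterns $R_1 + \ldots + R_m$ and product
patterns $P_1 + \ldots + P_n$, the package derives the rule's **action
set** — the NFsim-style list of elementary transformations — by structural
comparison of the two sides: molecules are matched by name and occurrence
order, sites by name within each matched molecule, and the differences
decompose into `DeleteBond`, `StateChange`, `AddBond`, `DeleteMolecule` and
`CreateMolecule` actions (in that deterministic order). Bond additions whose
endpoints lie in the same reactant complex are flagged intramolecular;
matched molecules untouched by any action are reported as catalysts. The
derivation is verified by an independent oracle: re-applying the action set
to the reactants must reproduce the product side up to graph isomorphism.

A molecule with unconstrained multi-state sites stands for
$\prod_i |S_i|$ fully specified forms ($S_i$ the state sets of its
unconstrained sites); the same product/sum recursion that counts words in a
railroad diagram counts these forms, and the two counts are kept consistent
by construction.

## Worked example

```r
library(rulerail)

model <- read_bngl(system.file("extdata", "egfr_grb2.bngl", package = "rulerail"))
model
#> BNGL model: 6 molecule type(s), 3 seed species, 2 observable(s), 7 rule(s)

rule <- model$rules[[1]]
bngl_serialize(rule)
#> [1] "grb2_bind: EGFR(Y1068~p) + Grb2(SH2,SH3) -> EGFR(Y1068~p!1).Grb2(SH2!1,SH3) kp1"

diff_rule(rule)
#> AddBond(1.EGFR.Y1068, 2.Grb2.SH2)
```

The derived action says: the rule's sole effect is a new bond between the
Y1068 site of the EGFR in the first reactant pattern and the SH2 site of the
Grb2 in the second — everything else in the rule is required context (Y1068
must be phosphorylated, SH3 unbound). Rendering embeds that action as a
green add-bond box (downward arrow) on the new link between the two lanes:

```r
d <- build_rule_diagram(rule, context = model$molecule_types)
writeLines(render_svg(d), "grb2_bind.svg")
```

Counting the forms of an under-specified pattern (EGFR has two 2-state
tyrosines, so an unconstrained receptor stands for 4 species):

```r
count_forms(parse_pattern("EGFR()"), model$molecule_types)
#> [1] 4
```

A shell front end wraps the same functions (see `?rulerail_main`):

```sh
Rscript inst/cli/rulerail render inst/extdata/egfr_grb2.bngl -o diagrams/
Rscript inst/cli/rulerail actions inst/extdata/egfr_grb2.bngl
Rscript inst/cli/rulerail count 'EGFR()' --context inst/extdata/egfr_grb2.bngl
Rscript inst/cli/rulerail fixture --seed 3 --rules 5 -o synthetic.bngl
```

## SVG class names

Semantic roles in the emitted SVG (all also distinguished by a non-color
cue): `rrr-action-add`, `rrr-action-del`, `rrr-state` (action boxes),
`rrr-glyph-down`, `rrr-glyph-up`, `rrr-glyph-state`, `rrr-glyph-rev`
(arrow glyphs), `rrr-bond`, `rrr-dashed-link`, `rrr-required-stub`,
`rrr-optional-stub`, `rrr-glyph-q` (connectivity), `rrr-synth`,
`rrr-degrade` (composition enclosures), `rr-annotation` (dashed site-name
labels). Colors live in one embedded, overridable `<style>` block
(`rrr_default_style()`).

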