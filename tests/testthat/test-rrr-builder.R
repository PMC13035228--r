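# Translation of BNGL entities into railroad diagrams.

test_that("molecule diagram enumerates every molecular form", {
  ctx <- egfr_types()
  egfr <- Filter(function(t) t$name == "EGFR", ctx)[[1]]
  d <- build_molecule_diagram(egfr)
  expect_length(d$lanes, 1L)
  expect_equal(count_words(d$lanes[[1]]), 4)
  # zero-site molecule: a single-word lane
  ptp <- Filter(function(t) t$name == "PTP", ctx)[[1]]
  expect_equal(count_words(build_molecule_diagram(ptp)$lanes[[1]]), 1)
  # a single one-state site emits no choice node
  one <- parse_model(c("begin molecule types", "X(s~only)",
                       "end molecule types"))$molecule_types[[1]]
  d1 <- build_molecule_diagram(one)
  expect_equal(count_words(d1$lanes[[1]]), 1)
  has_choice <- function(n) {
    if (n$variant == "choice") return(TRUE)
    kids <- switch(n$variant, "seq" = n$children, "group_box" = list(n$child),
                   list())
    any(vapply(kids, has_choice, logical(1)))
  }
  expect_false(has_choice(d1$lanes[[1]]))
})

test_that("molecule diagram word count equals parser form count on fixtures", {
  for (s in 1:10) {
    fx <- generate_fixture(fixture_spec(seed = s))
    for (mt in fx$model$molecule_types) {
      d <- build_molecule_diagram(mt)
      p <- parse_pattern(paste0(mt$name, "()"), fx$model$molecule_types)
      expect_equal(count_words(d$lanes[[1]]),
                   count_forms(p, fx$model$molecule_types),
                   info = paste("seed", s, mt$name))
    }
  }
})

test_that("species diagram draws one lane per molecule plus bond and dashed links", {
  ctx <- egfr_types()
  p <- parse_pattern("EGFR(Y1068~p!1).Grb2(SH2!1)", ctx)
  d <- build_species_diagram(p, ctx)
  expect_length(d$lanes, 2L)
  styles <- vapply(d$links, `[[`, character(1), "style")
  expect_equal(sum(styles == "solid-bond"), 1L)
  expect_equal(sum(styles == "dashed-complex"), 1L)
  # single molecule: one lane, no links
  d1 <- build_species_diagram(parse_pattern("EGFR(Y1068~u,Y1148~u)", ctx), ctx)
  expect_length(d1$lanes, 1L)
  expect_length(d1$links, 0L)
  # three-molecule chain: 2 bonds, dashed chain of 2
  ctx3 <- parse_model(c("begin molecule types", "A(x)", "B(x,y)", "C(x)",
                        "end molecule types"))$molecule_types
  d3 <- build_species_diagram(parse_pattern("A(x!1).B(x!1,y!2).C(x!2)", ctx3), ctx3)
  styles3 <- vapply(d3$links, `[[`, character(1), "style")
  expect_equal(sum(styles3 == "solid-bond"), 2L)
  expect_equal(sum(styles3 == "dashed-complex"), 2L)
})

test_that("observable diagrams expand free states and mark connectivity", {
  m <- egfr_model()
  ctx <- m$molecule_types
  # Y1068 pinned to p, Y1148 free: two matching forms
  d1 <- build_observable_diagram(m$observables[[1]], ctx)
  expect_equal(count_words(d1$lanes[[1]]), 2)
  # r must be bound, Y1148 optionally bound
  d2 <- build_observable_diagram(m$observables[[2]], ctx)
  styles <- vapply(d2$links, `[[`, character(1), "style")
  expect_true("required-stub" %in% styles)
  expect_true("optional-stub" %in% styles)
  svg <- render_svg(d2)
  expect_match(svg, "rrr-glyph-q")
  expect_match(svg, "rrr-optional-stub")
  # an observable over a fully specified species degenerates to its diagram
  ob <- observable("full", "Molecules",
                   list(parse_pattern("EGFR(l,r,Y1068~p,Y1148~u)", ctx)))
  d3 <- build_observable_diagram(ob, ctx)
  expect_equal(count_words(d3$lanes[[1]]), 1)
})

test_that("rule diagrams embed exactly the derived actions", {
  m <- egfr_model()
  ctx <- m$molecule_types
  count_action_boxes <- function(d) {
    inline <- function(n) {
      switch(n$variant,
        "action_box" = 1L,
        "seq" = sum(vapply(n$children, inline, integer(1))),
        "choice" = sum(vapply(n$children, inline, integer(1))),
        "group_box" = inline(n$child),
        0L)
    }
    sum(vapply(d$lanes, inline, integer(1))) +
      sum(vapply(d$links, function(l) !is.null(l$action), logical(1)))
  }
  for (r in m$rules) {
    as <- diff_rule(r)
    d <- suppressWarnings(build_rule_diagram(r, as, context = ctx))
    n_box_actions <- sum(vapply(as$actions, function(a) {
      a$kind %in% c("add-bond", "delete-bond", "state-change")
    }, logical(1)))
    expect_equal(count_action_boxes(d), n_box_actions, info = r$label)
  }
})

test_that("binding rule diagram: add-bond box on the new link, SH3 unbound", {
  ctx <- egfr_types()
  r <- case_rule("grb2_bind")
  d <- build_rule_diagram(r, context = ctx)
  with_action <- Filter(function(l) !is.null(l$action), d$links)
  expect_length(with_action, 1L)
  expect_equal(with_action[[1]]$action$kind, "add-bond")
  expect_false(with_action[[1]]$action$reversible)
  svg <- render_svg(d)
  expect_match(svg, "rrr-glyph-down")
  expect_no_match(svg, "rrr-glyph-rev")
  # SH3 renders as a plain site terminal with no port
  expect_false(any(grepl("\\.s", vapply(d$links, `[[`, character(1), "a")) &
                     grepl("SH3", vapply(d$links, `[[`, character(1), "a"))))
})

test_that("reversible and intramolecular conventions appear in the diagram", {
  ctx <- egfr_types()
  d_rev <- build_rule_diagram(case_rule("grb2_bind_rev"), context = ctx)
  svg <- render_svg(d_rev)
  expect_match(svg, "rrr-glyph-rev")

  d_intra <- build_rule_diagram(case_rule("grb2_intra"), context = ctx)
  styles <- vapply(d_intra$links, `[[`, character(1), "style")
  expect_true("dashed-complex" %in% styles)  # already co-complexed (dashed)
  expect_true("required-stub" %in% styles)   # the SH3!+ anchor
})

test_that("state change renders as before/box/after; catalyst lane unlinked", {
  ctx <- egfr_types()
  d <- build_rule_diagram(case_rule("dephos"), context = ctx)
  expect_length(d$lanes, 2L)       # EGFR + separate PTP lane
  styles <- vapply(d$links, `[[`, character(1), "style")
  expect_false("dashed-complex" %in% styles)  # catalyst not co-complexed
  svg <- render_svg(d)
  expect_match(svg, "rrr-glyph-state")
  expect_match(svg, ">p<", fixed = TRUE)
  expect_match(svg, ">u<", fixed = TRUE)
})

test_that("synthesis and degradation wrap lanes in labelled dashed boxes", {
  ctx <- egfr_types()
  d <- build_rule_diagram(case_rule("proegf_processing"), context = ctx)
  roles <- vapply(d$lanes, function(n) {
    if (n$variant == "group_box") n$role else ""
  }, character(1))
  expect_true("degraded" %in% roles)
  expect_true("synthesized" %in% roles)
  svg <- render_svg(d)
  expect_match(svg, ">degraded<", fixed = TRUE)
  expect_match(svg, ">synthesized<", fixed = TRUE)
})

test_that("strict degradation aborts on an unsevered bond", {
  # a rule with a dangling product bond cannot even be written, so construct
  # the faulty action set by dropping the severing action
  deg <- case_rule("egf_degradation")
  as <- diff_rule(deg)
  as$actions <- Filter(function(a) a$kind != "delete-bond", as$actions)
  expect_warning(build_rule_diagram(deg, as, context = egfr_types()),
                 "no matching bond deletion")
  expect_error(
    build_rule_diagram(deg, as, context = egfr_types(),
                       opts = render_options(strict_degradation = TRUE)),
    "no matching bond deletion")
})

test_that("omitting molecule names shortens lanes but keeps the word counts", {
  ctx <- egfr_types()
  egfr <- Filter(function(t) t$name == "EGFR", ctx)[[1]]
  with_names <- build_molecule_diagram(egfr)
  without <- build_molecule_diagram(egfr, render_options(omit_molecule_names = TRUE))
  expect_equal(count_words(with_names$lanes[[1]]),
               count_words(without$lanes[[1]]))
  expect_no_match(render_svg(without), ">EGFR<", fixed = TRUE)
  expect_match(render_svg(with_names), ">EGFR<", fixed = TRUE)
})

test_that("generic notation swaps vocabulary without touching structure", {
  ctx <- egfr_types()
  egfr <- Filter(function(t) t$name == "EGFR", ctx)[[1]]
  d <- build_molecule_diagram(egfr, render_options(notation = "generic"))
  expect_match(d$title, "Interacting Agent")
  expect_equal(count_words(d$lanes[[1]]), 4)
})

test_that("build_all covers every entity and isolates failures", {
  m <- egfr_model()
  all <- build_all(m)
  expect_length(attr(all, "failures"), 0L)
  expect_length(all, length(m$molecule_types) + length(m$species) +
                  length(m$observables) + length(m$rules))
  expect_true(all(grepl("^(molecule|species|observable|rule)_\\d+_", names(all))))
  # empty model builds an empty list
  empty <- build_all(bngl_model())
  expect_length(empty, 0L)
  # bond-mark inconsistency in one rule does not abort the rest
  bad <- parse_model(c("begin molecule types", "A(x)", "end molecule types",
                       "begin reaction rules",
                       "r1: A(x!+) -> A(x) k1",
                       "r2: A(x) -> A(x) k2",
                       "end reaction rules"))
  res <- build_all(bad)
  expect_length(attr(res, "failures"), 1L)
  expect_match(attr(res, "failures"), "wildcard")
  expect_true("rule_2_r2" %in% names(res))
})

test_that("show_bond_indexes labels links with canonical indices", {
  ctx <- egfr_types()
  p <- parse_pattern("EGFR(Y1068~p!4).Grb2(SH2!4)", ctx)
  d <- build_species_diagram(p, ctx, render_options(show_bond_indexes = TRUE))
  labels <- vapply(d$links, function(l) {
    if (is.null(l$label)) NA_character_ else l$label
  }, character(1))
  expect_true("!1" %in% labels)   # renumbered, not the source's !4
  svg <- render_svg(d)
  expect_match(svg, "!1", fixed = TRUE)
})
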