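# Action extraction by reactant/product comparison, and its oracle.

test_that("correspondence matches by name then occurrence order", {
  bind <- case_rule("grb2_bind")
  corr <- correspond(bind)
  expect_true(all(corr$reactant$matched))
  expect_false(any(corr$product$created))
  proc <- case_rule("proegf_processing")
  corr2 <- correspond(proc)
  expect_true(corr2$reactant$deleted[corr2$reactant$name == "proEGF"])
  expect_true(corr2$product$created[corr2$product$name == "EGF"])
  # identical sides map to the identity
  r <- parse_model(c("begin reaction rules",
                     "A(x) + A(x) -> A(x) + A(x) k1",
                     "end reaction rules"))$rules[[1]]
  corr3 <- correspond(r)
  expect_equal(corr3$product$r_flat, c(1L, 2L))
})

test_that("binding rule diffs to one intermolecular bond addition", {
  as <- diff_rule(case_rule("grb2_bind"))
  expect_length(as$actions, 1L)
  a <- as$actions[[1]]
  expect_equal(a$kind, "add-bond")
  expect_false(a$intramolecular)
  expect_false(as$reversible)
  # endpoints: EGFR.Y1068 (pattern 1) and Grb2.SH2 (pattern 2)
  expect_equal(action_text(as), "AddBond(1.EGFR.Y1068, 2.Grb2.SH2)")
})

test_that("reversible binding carries the flag, actions unchanged", {
  as <- diff_rule(case_rule("grb2_bind_rev"))
  expect_length(as$actions, 1L)
  expect_equal(as$actions[[1]]$kind, "add-bond")
  expect_true(as$reversible)
})

test_that("bond formation inside one complex is flagged intramolecular", {
  as <- diff_rule(case_rule("grb2_intra"))
  expect_length(as$actions, 1L)
  expect_equal(as$actions[[1]]$kind, "add-bond")
  expect_true(as$actions[[1]]$intramolecular)
})

test_that("transphosphorylation diffs to one state change in dimer context", {
  as <- diff_rule(case_rule("transphos"))
  expect_length(as$actions, 1L)
  a <- as$actions[[1]]
  expect_equal(a$kind, "state-change")
  expect_equal(a$from, "u")
  expect_equal(a$to, "p")
  # the dimer partner is untouched, hence reported as catalytic context
  expect_length(as$catalysts, 1L)
  expect_equal(as$catalysts[[1]]$name, "EGFR")
})

test_that("dephosphorylation reports PTP as catalyst", {
  as <- diff_rule(case_rule("dephos"))
  expect_length(as$actions, 1L)
  expect_equal(as$actions[[1]]$kind, "state-change")
  expect_equal(as$actions[[1]]$from, "p")
  expect_length(as$catalysts, 1L)
  expect_equal(as$catalysts[[1]]$name, "PTP")
})

test_that("processing rule deletes proEGF and creates EGF", {
  as <- diff_rule(case_rule("proegf_processing"))
  kinds <- vapply(as$actions, `[[`, character(1), "kind")
  expect_equal(kinds, c("delete-molecule", "create-molecule"))
  expect_equal(as$actions[[2]]$molecule$name, "EGF")
})

test_that("wildcard bond marks may not change class across the rule", {
  r <- parse_model(c("begin reaction rules",
                     "A(x!+) -> A(x) k1",
                     "end reaction rules"))$rules[[1]]
  expect_error(diff_rule(r), class = "bngl_inconsistency_error")
  r2 <- parse_model(c("begin reaction rules",
                      "A(x!?) -> A(x!+) k1",
                      "end reaction rules"))$rules[[1]]
  expect_error(diff_rule(r2), class = "bngl_inconsistency_error")
})

test_that("a rule with identical sides has an empty action set", {
  r <- parse_model(c("begin reaction rules",
                     "A(x~u) -> A(x~u) k1",
                     "end reaction rules"))$rules[[1]]
  expect_length(diff_rule(r)$actions, 0L)
})

test_that("apply_actions is the identity on an empty action set", {
  r <- parse_model(c("begin reaction rules",
                     "A(x~u) -> A(x~u) k1",
                     "end reaction rules"))$rules[[1]]
  out <- apply_actions(r$reactants, diff_rule(r))
  expect_length(out, 1L)
  expect_equal(bngl_serialize(out[[1]]), "A(x~u)")
})

test_that("diff-then-apply reproduces the products of every case-study rule", {
  for (r in egfr_model()$rules) {
    as <- diff_rule(r)
    out <- apply_actions(r$reactants, as)
    expect_true(patterns_isomorphic(out, r$products),
                info = bngl_serialize(r))
  }
})

test_that("applying the binding action yields the bound complex", {
  bind <- case_rule("grb2_bind")
  out <- apply_actions(bind$reactants, diff_rule(bind))
  expect_length(out, 1L)
  expect_true(patterns_isomorphic(out[[1]],
                                  parse_pattern("EGFR(Y1068~p!1).Grb2(SH2!1,SH3)")))
})

test_that("reversing a reversible rule inverts the action set", {
  rev <- case_rule("grb2_bind_rev")
  fwd <- diff_rule(rev)
  # build the textually reversed rule and diff it
  back <- reaction_rule(rev$products, rev$reactants, reversible = TRUE,
                        rate_text = rev(rev$rate_text))
  bwd <- diff_rule(back)
  inv <- reverse_actions(fwd)
  expect_equal(vapply(bwd$actions, `[[`, character(1), "kind"),
               vapply(inv, `[[`, character(1), "kind"))
  # state change inverts from/to
  dep <- diff_rule(case_rule("dephos"))
  inv2 <- reverse_actions(dep)
  expect_equal(inv2[[1]]$from, "u")
  expect_equal(inv2[[1]]$to, "p")
})

test_that("molecules neither created nor deleted appear exactly once in the mapping", {
  for (r in egfr_model()$rules) {
    corr <- correspond(r)
    surviving <- which(corr$reactant$matched)
    mapped <- corr$product$r_flat[!corr$product$created]
    expect_equal(sort(mapped), sort(surviving), info = bngl_serialize(r))
    expect_false(anyDuplicated(mapped) > 0L)
  }
})

test_that("degradation of a bonded molecule must sever the bond", {
  deg <- case_rule("egf_degradation")
  as <- diff_rule(deg)
  kinds <- vapply(as$actions, `[[`, character(1), "kind")
  expect_equal(kinds, c("delete-bond", "delete-molecule"))
  expect_length(validate_degradation(as), 0L)

  # drop the DeleteBond: one diagnostic
  broken <- as
  broken$actions <- broken$actions[-1]
  expect_length(validate_degradation(broken), 1L)
  expect_match(validate_degradation(broken), "no matching bond deletion")

  # degradation of a free molecule is clean
  free <- parse_model(c("begin reaction rules", "A(x) -> 0 k1",
                        "end reaction rules"))$rules[[1]]
  expect_length(validate_degradation(diff_rule(free)), 0L)
})

test_that("unbinding splits a bond-connected complex but not a context complex", {
  unbind <- parse_model(c("begin reaction rules",
    "EGFR(Y1068~p!1).Grb2(SH2!1,SH3) -> EGFR(Y1068~p) + Grb2(SH2,SH3) km1",
    "end reaction rules"))$rules[[1]]
  out <- apply_actions(unbind$reactants, diff_rule(unbind))
  expect_length(out, 2L)

  intra <- case_rule("grb2_intra")
  back <- reaction_rule(intra$products, intra$reactants, reversible = TRUE,
                        rate_text = rev(intra$rate_text))
  out2 <- apply_actions(back$reactants, diff_rule(back))
  expect_length(out2, 1L)  # still one complex: the dashed chain persists
  expect_true(patterns_isomorphic(out2, back$products))
})
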