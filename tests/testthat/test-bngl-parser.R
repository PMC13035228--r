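# BNGL subset parsing, canonical serialization and form expansion.

test_that("molecule type declarations parse with sites and states", {
  m <- parse_model(c(
    "begin molecule types",
    "  EGFR(l,r,Y1068~u~p,Y1148~u~p)",
    "  PTP()",
    "end molecule types"))
  egfr <- m$molecule_types[[1]]
  expect_equal(egfr$name, "EGFR")
  expect_length(egfr$sites, 4L)
  expect_equal(vapply(egfr$sites, function(s) length(s$states), integer(1)),
               c(0L, 0L, 2L, 2L))
  expect_equal(egfr$sites[[3]]$states, c("u", "p"))
  # zero-site molecules are legal
  expect_length(m$molecule_types[[2]]$sites, 0L)
})

test_that("an empty molecule types block is not an error", {
  m <- parse_model(c("begin molecule types", "end molecule types"))
  expect_length(m$molecule_types, 0L)
})

test_that("patterns parse with states, bonds and wildcards", {
  p <- parse_pattern("EGFR(Y1068~p!1).Grb2(SH2!1)")
  expect_length(p$molecules, 2L)
  b <- pattern_bonds(p)
  expect_equal(nrow(b), 1L)
  expect_equal(p$molecules[[1]]$sites[[1]]$state, "p")
  expect_equal(p$molecules[[2]]$sites[[1]]$name, "SH2")

  q <- parse_pattern("EGFR(r!+)")
  expect_equal(q$molecules[[1]]$sites[[1]]$bond$variant, "bonded-any")
  r <- parse_pattern("EGFR(Y1148!?)")
  expect_equal(r$molecules[[1]]$sites[[1]]$bond$variant, "unspecified")
})

test_that("dangling and malformed input raise typed errors", {
  expect_error(parse_pattern("EGFR(Y1068~p!1)"), class = "bngl_reference_error")
  expect_error(parse_pattern("1EGFR(x)"), class = "bngl_syntax_error")
  expect_error(parse_pattern("EGFR(x"), class = "bngl_syntax_error")
  # undeclared site / state against a context
  ctx <- egfr_types()
  expect_error(parse_pattern("EGFR(zz)", ctx), class = "bngl_reference_error")
  expect_error(parse_pattern("EGFR(Y1068~q)", ctx), class = "bngl_reference_error")
  expect_error(parse_pattern("Unknown(x)", ctx), class = "bngl_reference_error")
})

test_that("identifiers must start with a letter (grammar conformance)", {
  expect_error(parse_model(c("begin molecule types", "2EGFR(x)",
                             "end molecule types")),
               class = "bngl_syntax_error")
  expect_error(site_def("9lives"), class = "bngl_syntax_error")
  expect_equal(site_def("a_1")$name, "a_1")
})

test_that("serialization renumbers bonds by first appearance", {
  p <- parse_pattern("Grb2(SH2!2).EGFR(Y1068~p!2)")
  expect_equal(bngl_serialize(p), "Grb2(SH2!1).EGFR(Y1068~p!1)")
  # zero-site molecule keeps its parentheses
  expect_equal(bngl_serialize(parse_pattern("PTP()")), "PTP()")
  # sites reordered into declared order when context is given
  ctx <- egfr_types()
  p2 <- parse_pattern("EGFR(Y1068~p,l)", ctx)
  expect_equal(bngl_serialize(p2, context = ctx), "EGFR(l,Y1068~p)")
})

test_that("parse/serialize round trip is a fixed point after one pass", {
  m <- egfr_model()
  once <- bngl_serialize(m)
  twice <- bngl_serialize(parse_model(strsplit(once, "\n")[[1]]))
  expect_identical(once, twice)
})

test_that("rules parse labels, reversibility and rates", {
  m <- egfr_model()
  bind <- case_rule("grb2_bind")
  expect_false(bind$reversible)
  expect_equal(bind$rate_text, "kp1")
  expect_length(bind$reactants, 2L)
  expect_length(bind$products, 1L)
  rev <- case_rule("grb2_bind_rev")
  expect_true(rev$reversible)
  expect_equal(rev$rate_text, c("kp1", "km1"))
  # reversible rule missing second rate is rejected
  expect_error(parse_model(c(
    "begin reaction rules", "A() <-> B() k1", "end reaction rules")),
    class = "bngl_syntax_error")
})

test_that("comments and unsupported blocks are preserved", {
  m <- egfr_model()
  expect_true(nrow(m$comments) >= 2L)
  expect_true(any(grepl("phosphorylated receptors", m$comments$text)))
  expect_true("parameters" %in% names(m$extra_blocks))
  expect_true(any(grepl("kp1", m$extra_blocks$parameters)))
})

test_that("form expansion matches declared state products", {
  ctx <- egfr_types()
  # EGFR with nothing constrained: 2 x 2 states
  forms <- expand_forms(parse_pattern("EGFR()"), ctx)
  expect_length(forms, 4L)
  expect_true(all(vapply(forms, function(f) {
    all(vapply(f$molecules[[1]]$sites,
               function(s) is.na(s$state) ==
                 (s$name %in% c("l", "r")), logical(1)))
  }, logical(1))))
  # fixing one tyrosine leaves the other free: 2 forms
  expect_length(expand_forms(parse_pattern("EGFR(Y1068~p)"), ctx), 2L)
  # a fully specified pattern expands to itself
  full <- parse_pattern("EGFR(l,r,Y1068~p,Y1148~u)", ctx)
  forms1 <- expand_forms(full, ctx)
  expect_length(forms1, 1L)
  expect_equal(bngl_serialize(forms1[[1]], context = ctx),
               bngl_serialize(full, context = ctx))
})

test_that("expansion count equals brute-force cartesian enumeration", {
  # oracle: cartesian product over the unconstrained multi-state sites
  brute_count <- function(pattern_text, ctx) {
    p <- complete_pattern(parse_pattern(pattern_text, ctx), ctx)
    sizes <- integer(0)
    for (mp in p$molecules) {
      mt <- Filter(function(t) t$name == mp$name, ctx)[[1]]
      for (k in seq_along(mt$sites)) {
        if (length(mt$sites[[k]]$states) > 1L && is.na(mp$sites[[k]]$state)) {
          sizes <- c(sizes, length(mt$sites[[k]]$states))
        }
      }
    }
    nrow(do.call(expand.grid, lapply(if (length(sizes)) sizes else 1L, seq_len)))
  }
  ctx <- egfr_types()
  for (txt in c("EGFR()", "EGFR(Y1068~p)", "EGFR(Y1068~p,Y1148~u)",
                "EGFR().EGFR()", "Grb2()", "PTP()",
                "EGFR(Y1068~u!1).Grb2(SH2!1)")) {
    expect_equal(length(expand_forms(parse_pattern(txt), ctx)),
                 brute_count(txt, ctx), info = txt)
    expect_equal(count_forms(parse_pattern(txt), ctx), brute_count(txt, ctx),
                 info = txt)
  }
})

test_that("expansion refuses to exceed the combinatorial cap", {
  ctx <- list(parse_model(c("begin molecule types",
                            "Big(a~u~p,b~u~p,c~u~p,d~u~p)",
                            "end molecule types"))$molecule_types[[1]])
  expect_error(expand_forms(parse_pattern("Big()"), ctx, cap = 10L),
               "cap")
  expect_length(expand_forms(parse_pattern("Big()"), ctx), 16L)
})

test_that("expansion order is lexicographic over state choices", {
  ctx <- egfr_types()
  forms <- expand_forms(parse_pattern("EGFR()"), ctx)
  lab <- vapply(forms, function(f) {
    paste(vapply(f$molecules[[1]]$sites[3:4], `[[`, character(1), "state"),
          collapse = ",")
  }, character(1))
  expect_equal(lab, c("u,u", "u,p", "p,u", "p,p"))
})

test_that("bond pairing holds in every parsed fixture pattern", {
  for (s in 1:20) {
    fx <- generate_fixture(fixture_spec(seed = s))
    m <- parse_model(fx$text)
    pats <- c(lapply(m$species, `[[`, "pattern"),
              unlist(lapply(m$rules, function(r) c(r$reactants, r$products)),
                     recursive = FALSE))
    for (p in pats) {
      b <- pattern_bonds(p)
      expect_true(all(table(b$index) == 1L))  # each index = one row = two ends
    }
  }
})

test_that("duplicate site names resolve by declared order", {
  ctx <- parse_model(c("begin molecule types", "Dup(x~u~p,x~u~p)",
                       "end molecule types"))$molecule_types
  p <- parse_pattern("Dup(x~u,x~p)", ctx)
  expect_length(expand_forms(p, ctx), 1L)
  expect_equal(bngl_serialize(p, context = ctx), "Dup(x~u,x~p)")
  # three occurrences of a twice-declared site is a reference error
  expect_error(parse_pattern("Dup(x,x,x)", ctx), class = "bngl_reference_error")
})
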