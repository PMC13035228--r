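# Railroad algebra: enumeration, counting, layout, SVG emission.

test_that("the sentence grammar enumerates 144 sentences including the examples", {
  lane <- sentence_lane()
  expect_equal(count_words(lane), 144)
  sents <- sentences_of(lane)
  expect_length(sents, 144L)
  expect_true("The quick fox walked over the lazy cat." %in% sents)
  expect_true("The brown fox ran over the dog." %in% sents)
  expect_false(anyDuplicated(sents) > 0L)
})

test_that("single terminals and small choices enumerate as expected", {
  expect_equal(enumerate_words(rr_terminal("x")), list("x"))
  expect_equal(count_words(rr_choice(rr_terminal("a"), rr_terminal("b"),
                                     rr_terminal("c"))), 3)
  # decorations contribute nothing to words
  lane <- rr_seq(rr_annotation("site"), rr_terminal("u"),
                 rr_action_box("state-change"), rr_port("p1"))
  expect_equal(enumerate_words(lane), list("u"))
})

test_that("count_words agrees with brute-force enumeration on random lanes", {
  set.seed(42)
  for (i in 1:200) {
    lane <- random_lane(depth = sample(1:4, 1L))
    n <- count_words(lane)
    if (n <= 5000) {
      expect_equal(n, length(enumerate_words(lane, cap = 5000)))
    }
  }
})

test_that("enumeration refuses lanes above the cap", {
  wide <- rr_seq(lapply(1:6, function(i) {
    rr_choice(lapply(letters[1:5], rr_terminal))
  }))
  expect_equal(count_words(wide), 5^6)
  expect_error(enumerate_words(wide, cap = 100L), "cap")
})

test_that("layout is deterministic and boxes never overlap", {
  d <- rr_diagram(list(sentence_lane()), title = "sentences")
  l1 <- rr_layout(d)
  l2 <- rr_layout(d)
  expect_identical(l1, l2)
  boxes <- Filter(function(p) p$kind == "box", l1$primitives)
  # pairwise non-overlap (group boxes excluded: they enclose by design)
  plain <- Filter(function(b) !grepl("rr-group", b$class), boxes)
  overlap <- function(a, b) {
    a$x < b$x + b$w && b$x < a$x + a$w && a$y < b$y + b$h && b$y < a$y + a$h
  }
  if (length(plain) > 1L) {
    for (i in seq_len(length(plain) - 1L)) {
      for (j in seq((i + 1L), length(plain))) {
        expect_false(overlap(plain[[i]], plain[[j]]))
      }
    }
  }
})

test_that("cross-links touch both port coordinates", {
  d <- rr_diagram(
    list(rr_seq(rr_terminal("A"), rr_port("pa")),
         rr_seq(rr_terminal("B"), rr_port("pb"))),
    links = list(rr_link("pa", "pb", style = "solid-bond")))
  l <- rr_layout(d)
  pa <- l$ports[["pa"]]
  pb <- l$ports[["pb"]]
  link <- Filter(function(p) p$kind == "path" && grepl("rrr-bond", p$class),
                 l$primitives)[[1]]
  expect_match(link$d, sprintf("M %s %s", n2 <- formatC(pa[1], format = "f", digits = 1),
                               formatC(pa[2], format = "f", digits = 1)),
               fixed = TRUE)
  expect_match(link$d, sprintf("%s %s",
                               formatC(pb[1], format = "f", digits = 1),
                               formatC(pb[2], format = "f", digits = 1)),
               fixed = TRUE)
})

test_that("links demand existing, unique ports", {
  expect_error(rr_diagram(list(rr_terminal("A")),
                          links = list(rr_link("nope", "nah"))),
               "matches no port")
  expect_error(rr_diagram(list(rr_seq(rr_port("p"), rr_port("p")))),
               "duplicate port")
})

test_that("emitted SVG is well-formed XML with an svg root", {
  skip_if_not_installed("xml2")
  d <- rr_diagram(list(sentence_lane()), title = "sentences")
  svg <- render_svg(d)
  x <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(x), "svg")
  # byte-identical on re-render
  expect_identical(svg, render_svg(rr_diagram(list(sentence_lane()),
                                              title = "sentences")))
})

test_that("action boxes carry their machine-readable glyphs", {
  mk <- function(kind, rev = FALSE) {
    render_svg(rr_diagram(list(rr_seq(rr_terminal("x"),
                                      rr_action_box(kind, reversible = rev)))))
  }
  expect_match(mk("add-bond"), "rrr-glyph-down")
  expect_match(mk("delete-bond"), "rrr-glyph-up")
  expect_match(mk("state-change"), "rrr-glyph-state")
  expect_match(mk("add-bond", rev = TRUE), "rrr-glyph-rev")
  expect_no_match(mk("add-bond"), "rrr-glyph-rev")
  expect_no_match(mk("add-bond"), "rrr-glyph-up")
})

test_that("semantics survive stripping the style block (color-agnostic)", {
  skip_if_not_installed("xml2")
  d <- rr_diagram(
    list(rr_seq(rr_terminal("a"), rr_action_box("add-bond"), rr_port("x")),
         rr_seq(rr_terminal("b"), rr_action_box("delete-bond"),
                rr_action_box("state-change"), rr_port("y"))),
    links = list(rr_link("x", "y", style = "dashed-complex")))
  svg <- render_svg(d, include_style = FALSE)
  expect_no_match(svg, "<style>")
  x <- xml2::read_xml(svg)
  # every action kind still distinguishable by its glyph class
  classes <- unlist(xml2::xml_attrs(xml2::xml_find_all(x, ".//*[@class]"), "class"))
  expect_true(any(grepl("rrr-glyph-down", classes)))
  expect_true(any(grepl("rrr-glyph-up", classes)))
  expect_true(any(grepl("rrr-glyph-state", classes)))
  # dashing is a presentation attribute, not CSS
  dashed <- xml2::xml_find_all(x, ".//*[@stroke-dasharray]")
  expect_true(length(dashed) >= 1L)
})

test_that("group boxes render dashed with their role label", {
  d <- rr_diagram(list(
    rr_group_box(rr_terminal("EGF"), "synthesized", role = "synthesized"),
    rr_group_box(rr_terminal("proEGF"), "degraded", role = "degraded")))
  svg <- render_svg(d)
  expect_match(svg, ">synthesized<", fixed = TRUE)
  expect_match(svg, ">degraded<", fixed = TRUE)
  expect_match(svg, "rrr-synth")
  expect_match(svg, "rrr-degrade")
  expect_match(svg, "stroke-dasharray")
})
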