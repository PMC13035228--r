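# Shared fixtures, built in code.

# The EGFR/Grb2 case-study model shipped with the package.
egfr_model <- function() {
  read_bngl(system.file("extdata", "egfr_grb2.bngl", package = "rulerail"))
}

egfr_types <- function() egfr_model()$molecule_types

case_rule <- function(label) {
  m <- egfr_model()
  for (r in m$rules) if (identical(r$label, label)) return(r)
  stop("no such rule: ", label)
}

# The sentence grammar of the worked railroad example: "The {quick, -}
# {-, brown, red, black} fox {jumps, ran, walked} over the {-, lazy}
# {dog, cat, turtle}."
sentence_lane <- function() {
  t <- rr_terminal
  rr_seq(
    t("The"),
    rr_optional(t("quick")),
    rr_choice(rr_skip(), t("brown"), t("red"), t("black")),
    t("fox"),
    rr_choice(t("jumps"), t("ran"), t("walked")),
    t("over the"),
    rr_optional(t("lazy")),
    rr_choice(t("dog"), t("cat"), t("turtle")))
}

sentences_of <- function(lane) {
  vapply(enumerate_words(lane),
         function(w) paste0(paste(w, collapse = " "), "."),
         character(1))
}

# Random small railroad lane for count/enumeration agreement properties.
random_lane <- function(depth = 3L) {
  labels <- c("a", "b", "c", "d", "e")
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.35) {
      if (stats::runif(1) < 0.15) return(rr_skip())
      return(rr_terminal(sample(labels, 1L)))
    }
    n <- sample(2:3, 1L)
    kids <- lapply(seq_len(n), function(i) build(d - 1L))
    pick <- stats::runif(1)
    if (pick < 0.4) rr_seq(kids)
    else if (pick < 0.8) rr_choice(kids)
    else rr_optional(build(d - 1L))
  }
  build(depth)
}
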