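#' @title Parsing BNGL text
#' @description A hand-written recursive-descent parser for the BNGL subset
#'   covered by the package: molecule type declarations, species patterns
#'   (molecules, sites, states, bonds), observables and reaction rules.
#'   Blocks outside the subset (parameters, functions, actions, ...) are
#'   preserved verbatim and ignored downstream.
#' @name bngl-parse
NULL

# ---- character scanner ------------------------------------------------------

new_scanner <- function(text) {
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(text, "", fixed = TRUE)[[1]]
  env$pos <- 1L
  env$text <- text
  env
}

sc_peek <- function(sc) {
  if (sc$pos > length(sc$chars)) "" else sc$chars[sc$pos]
}

sc_next <- function(sc) {
  ch <- sc_peek(sc)
  sc$pos <- sc$pos + 1L
  ch
}

sc_skip_ws <- function(sc) {
  while (sc_peek(sc) %in% c(" ", "\t")) sc$pos <- sc$pos + 1L
}

sc_error <- function(sc, msg, ...) {
  stop_bngl("bngl_syntax_error", paste0(sprintf(msg, ...),
            sprintf(" (at column %d of '%s')", sc$pos, sc$text)))
}

sc_expect <- function(sc, ch) {
  if (sc_peek(sc) != ch) sc_error(sc, "expected '%s', found '%s'", ch, sc_peek(sc))
  sc_next(sc)
}

# Name = Letter, {Letter | Digit | "_"}
sc_name <- function(sc, what = "identifier") {
  ch <- sc_peek(sc)
  if (!grepl("^[A-Za-z]$", ch)) {
    sc_error(sc, "expected %s (a letter), found '%s'", what, ch)
  }
  out <- character(0)
  while (grepl("^[A-Za-z0-9_]$", sc_peek(sc))) out <- c(out, sc_next(sc))
  paste(out, collapse = "")
}

sc_integer <- function(sc) {
  out <- character(0)
  while (grepl("^[0-9]$", sc_peek(sc))) out <- c(out, sc_next(sc))
  if (!length(out)) sc_error(sc, "expected a bond index digit, found '%s'", sc_peek(sc))
  as.integer(paste(out, collapse = ""))
}

# Site inside a pattern: Name ["~" Name] ["!" ("+" | "?" | integer)]
sc_site_pattern <- function(sc) {
  nm <- sc_name(sc, "site name")
  state <- NA_character_
  if (sc_peek(sc) == "~") {
    sc_next(sc)
    state <- sc_name(sc, "state name")
  }
  bond <- bond_mark("unbound")
  if (sc_peek(sc) == "!") {
    sc_next(sc)
    ch <- sc_peek(sc)
    if (ch == "+") { sc_next(sc); bond <- bond_mark("bonded-any") }
    else if (ch == "?") { sc_next(sc); bond <- bond_mark("unspecified") }
    else bond <- bond_mark("bonded", sc_integer(sc))
  }
  site_pattern(nm, state, bond)
}

# Molecule = Name, ["(", [Site, {",", Site}], ")"]
sc_molecule_pattern <- function(sc) {
  nm <- sc_name(sc, "molecule name")
  sites <- list()
  if (sc_peek(sc) == "(") {
    sc_next(sc)
    sc_skip_ws(sc)
    if (sc_peek(sc) != ")") {
      repeat {
        sc_skip_ws(sc)
        sites[[length(sites) + 1L]] <- sc_site_pattern(sc)
        sc_skip_ws(sc)
        if (sc_peek(sc) == ",") { sc_next(sc); next }
        break
      }
    }
    sc_expect(sc, ")")
  }
  molecule_pattern(nm, sites)
}

#' Parse a single species pattern
#'
#' Parses one dot-separated species pattern, e.g.
#' `"EGFR(Y1068~p!1).Grb2(SH2!1)"`. Bond indices are validated (each must
#' occur exactly twice) and, when molecule type declarations are supplied,
#' molecule, site and state names are checked against them.
#'
#' @param text Pattern source text.
#' @param context Optional list of [molecule_type_def()] objects for
#'   reference checking.
#' @return A [species_pattern()].
#' @examples
#' p <- parse_pattern("EGFR(Y1068~p!1).Grb2(SH2!1)")
#' pattern_bonds(p)
#' @export
parse_pattern <- function(text, context = NULL) {
  sc <- new_scanner(trimws(text))
  sc_skip_ws(sc)
  mols <- list()
  repeat {
    mols[[length(mols) + 1L]] <- sc_molecule_pattern(sc)
    if (sc_peek(sc) == ".") { sc_next(sc); next }
    break
  }
  sc_skip_ws(sc)
  if (sc_peek(sc) != "") {
    sc_error(sc, "unexpected trailing input '%s'", sc_peek(sc))
  }
  p <- species_pattern(mols)
  validate_pattern(p, context)
  p
}

# Molecule type declaration: sites may declare several states, e.g.
# EGFR(l,r,Y1068~u~p,Y1148~u~p)
sc_site_def <- function(sc) {
  nm <- sc_name(sc, "site name")
  states <- character(0)
  while (sc_peek(sc) == "~") {
    sc_next(sc)
    states <- c(states, sc_name(sc, "state name"))
  }
  site_def(nm, states)
}

parse_molecule_type <- function(text) {
  sc <- new_scanner(trimws(text))
  nm <- sc_name(sc, "molecule name")
  sites <- list()
  if (sc_peek(sc) == "(") {
    sc_next(sc)
    sc_skip_ws(sc)
    if (sc_peek(sc) != ")") {
      repeat {
        sc_skip_ws(sc)
        sites[[length(sites) + 1L]] <- sc_site_def(sc)
        sc_skip_ws(sc)
        if (sc_peek(sc) == ",") { sc_next(sc); next }
        break
      }
    }
    sc_expect(sc, ")")
  }
  sc_skip_ws(sc)
  if (sc_peek(sc) != "") sc_error(sc, "unexpected trailing input")
  molecule_type_def(nm, sites)
}

# ---- model-level parsing ----------------------------------------------------

# Split a string on a separator character at parenthesis depth zero,
# ignoring separators directly preceded by '!' (so 'r!+' never splits).
split_top <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  parts <- character(0)
  buf <- character(0)
  prev <- ""
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == sep && depth == 0L && prev != "!") {
      parts <- c(parts, paste(buf, collapse = ""))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
    prev <- ch
  }
  c(parts, paste(buf, collapse = ""))
}

# Parse one side of a rule: "+"-separated species patterns, or "0".
parse_rule_side <- function(text, context, line) {
  text <- trimws(text)
  if (text == "0") return(list())
  parts <- trimws(split_top(text, "+"))
  parts <- parts[nzchar(parts)]
  lapply(parts, function(pt) with_line(line, parse_pattern(pt, context)))
}

with_line <- function(line, expr) {
  tryCatch(expr, bngl_error = function(e) {
    e$message <- sprintf("line %d: %s", line, conditionMessage(e))
    stop(e)
  })
}

# Split the right-hand side of a rule into product patterns and rate text.
# Patterns contain no whitespace, so products are the leading whitespace
# tokens chained by '+'; everything after is the opaque rate expression.
split_products_rate <- function(rhs) {
  toks <- strsplit(trimws(rhs), "[ \t]+")[[1]]
  if (!length(toks)) return(list(products = "", rate = ""))
  ends_open <- function(tk) grepl("\\+$", gsub("!\\+", "", tk))
  prod <- toks[1]
  i <- 2L
  open_plus <- ends_open(toks[1])
  while (i <= length(toks)) {
    tk <- toks[i]
    if (open_plus) {
      prod <- paste0(prod, tk)
      open_plus <- ends_open(tk)
      i <- i + 1L
    } else if (tk == "+") {
      prod <- paste0(prod, "+")
      open_plus <- TRUE
      i <- i + 1L
    } else if (startsWith(tk, "+")) {
      prod <- paste0(prod, tk)
      open_plus <- ends_open(tk)
      i <- i + 1L
    } else {
      break
    }
  }
  rate <- if (i <= length(toks)) paste(toks[i:length(toks)], collapse = " ") else ""
  list(products = prod, rate = rate)
}

parse_rule_line <- function(text, context, line) {
  label <- NA_character_
  m <- regexpr("^\\s*[A-Za-z][A-Za-z0-9_]*\\s*:", text)
  if (m > 0) {
    lab <- regmatches(text, m)
    label <- sub(":\\s*$", "", trimws(lab))
    text <- substring(text, m + attr(m, "match.length"))
  } else {
    # tolerate a leading numeric rule index (BioNetGen writes them out),
    # but not a bare '0' reactant
    m2 <- regexpr("^\\s*[0-9]+\\s+", text)
    if (m2 > 0) {
      tok <- trimws(regmatches(text, m2))
      rest <- substring(text, m2 + attr(m2, "match.length"))
      if (tok != "0" && grepl("->", rest)) text <- rest
    }
  }
  reversible <- grepl("<->", text, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop_bngl("bngl_syntax_error", "line %d: rule must contain exactly one '%s'",
              line, arrow)
  }
  reactants <- parse_rule_side(sides[1], context, line)
  pr <- split_products_rate(sides[2])
  products <- parse_rule_side(pr$products, context, line)
  rate_raw <- trimws(pr$rate)
  rate_text <- if (nzchar(rate_raw)) trimws(split_top(rate_raw, ",")) else character(0)
  if (length(rate_text)) {
    need <- if (reversible) 2L else 1L
    if (length(rate_text) != need) {
      stop_bngl("bngl_syntax_error",
                "line %d: %s rule needs %d rate expression(s), found %d ('%s')",
                line, if (reversible) "reversible" else "irreversible",
                need, length(rate_text), rate_raw)
    }
  }
  reaction_rule(reactants, products, reversible = reversible,
                rate_text = rate_text, label = label, line = line)
}

parse_observable_line <- function(text, context, line) {
  toks <- strsplit(trimws(text), "[ \t]+")[[1]]
  if (length(toks) < 3L) {
    stop_bngl("bngl_syntax_error",
              "line %d: observable needs a kind, a name and at least one pattern", line)
  }
  kind <- toks[1]
  if (!(kind %in% c("Molecules", "Species"))) {
    stop_bngl("bngl_syntax_error",
              "line %d: observable kind must be 'Molecules' or 'Species', found '%s'",
              line, kind)
  }
  name <- toks[2]
  pat_text <- toks[-(1:2)]
  pat_text <- unlist(lapply(pat_text, function(s) trimws(split_top(s, ","))))
  pat_text <- pat_text[nzchar(pat_text)]
  patterns <- lapply(pat_text, function(pt) with_line(line, parse_pattern(pt, context)))
  observable(name, kind, patterns, line = line)
}

parse_species_line <- function(text, context, line) {
  toks <- strsplit(trimws(text), "[ \t]+")[[1]]
  pat <- with_line(line, parse_pattern(toks[1], context))
  list(pattern = pat,
       initial_text = paste(toks[-1], collapse = " "),
       line = line)
}

.block_aliases <- list(
  "molecule types" = "molecule_types",
  "molecules"      = "molecule_types",
  "seed species"   = "species",
  "species"        = "species",
  "observables"    = "observables",
  "reaction rules" = "rules",
  "rules"          = "rules"
)

#' Parse a BNGL model document
#'
#' Reads a block-structured BNGL document (`begin molecule types` ...
#' `end molecule types`, etc.). Both `molecule types`/`molecules` and
#' `seed species`/`species` spellings are accepted. `#` comments are captured
#' with their line numbers; blocks outside the supported subset (parameters,
#' functions, compartments, actions, ...) are stored verbatim in
#' `extra_blocks` and never visualized. Lines ending in `\` continue onto the
#' next line.
#'
#' @param text BNGL source: a single string (possibly with newlines) or a
#'   character vector of lines.
#' @return A [bngl_model()].
#' @examples
#' m <- parse_model(c(
#'   "begin molecule types",
#'   "  EGFR(l,r,Y1068~u~p,Y1148~u~p)",
#'   "end molecule types"
#' ))
#' length(m$molecule_types[[1]]$sites)
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }

  comments <- data.frame(line = integer(), text = character())
  # strip comments, record them
  code <- character(length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    hash <- regexpr("#", ln, fixed = TRUE)
    if (hash > 0) {
      comments <- rbind(comments,
                        data.frame(line = i, text = trimws(substring(ln, hash + 1L))))
      ln <- substring(ln, 1L, hash - 1L)
    }
    code[i] <- ln
  }
  # join continuation lines (trailing backslash); keep first line's number
  joined <- list()
  i <- 1L
  while (i <= length(code)) {
    ln <- code[i]
    first <- i
    while (grepl("\\\\\\s*$", ln) && i < length(code)) {
      ln <- paste(sub("\\\\\\s*$", "", ln), code[i + 1L])
      i <- i + 1L
    }
    joined[[length(joined) + 1L]] <- list(line = first, text = ln)
    i <- i + 1L
  }

  blocks <- list()          # list of list(name, lines = list(line, text))
  extra <- list()
  current <- NULL
  current_name <- NULL
  current_known <- FALSE
  for (entry in joined) {
    txt <- trimws(entry$text)
    if (!nzchar(txt)) next
    if (grepl("^begin\\s+", txt)) {
      if (!is.null(current)) {
        stop_bngl("bngl_syntax_error",
                  "line %d: 'begin %s' inside unclosed block '%s'",
                  entry$line, sub("^begin\\s+", "", txt), current_name)
      }
      current_name <- trimws(sub("^begin\\s+", "", txt))
      current <- list()
      current_known <- current_name %in% names(.block_aliases)
      next
    }
    if (grepl("^end\\s+", txt) || txt == "end") {
      end_name <- trimws(sub("^end\\s*", "", txt))
      if (is.null(current)) {
        stop_bngl("bngl_syntax_error", "line %d: 'end' without matching 'begin'",
                  entry$line)
      }
      if (nzchar(end_name) && end_name != current_name) {
        stop_bngl("bngl_syntax_error",
                  "line %d: 'end %s' does not match 'begin %s'",
                  entry$line, end_name, current_name)
      }
      if (current_known) {
        canon <- .block_aliases[[current_name]]
        blocks[[length(blocks) + 1L]] <- list(name = canon, lines = current)
      } else {
        extra[[current_name]] <- c(extra[[current_name]],
                                   vapply(current, `[[`, character(1), "text"))
      }
      current <- NULL
      current_name <- NULL
      next
    }
    if (is.null(current)) {
      stop_bngl("bngl_syntax_error",
                "line %d: statement outside any begin/end block: '%s'",
                entry$line, txt)
    }
    current[[length(current) + 1L]] <- list(line = entry$line, text = txt)
  }
  if (!is.null(current)) {
    stop_bngl("bngl_syntax_error", "unterminated block '%s'", current_name)
  }

  molecule_types <- list()
  for (b in blocks) {
    if (b$name != "molecule_types") next
    for (entry in b$lines) {
      molecule_types[[length(molecule_types) + 1L]] <-
        with_line(entry$line, parse_molecule_type(entry$text))
    }
  }
  context <- if (length(molecule_types)) molecule_types else NULL

  species <- list()
  observables <- list()
  rules <- list()
  for (b in blocks) {
    if (b$name == "species") {
      for (entry in b$lines) {
        species[[length(species) + 1L]] <-
          parse_species_line(entry$text, context, entry$line)
      }
    } else if (b$name == "observables") {
      for (entry in b$lines) {
        observables[[length(observables) + 1L]] <-
          parse_observable_line(entry$text, context, entry$line)
      }
    } else if (b$name == "rules") {
      for (entry in b$lines) {
        rules[[length(rules) + 1L]] <-
          parse_rule_line(entry$text, context, entry$line)
      }
    }
  }

  bngl_model(molecule_types = molecule_types, species = species,
             observables = observables, rules = rules,
             comments = comments, extra_blocks = extra)
}

#' Read and parse a BNGL file
#'
#' @param path Path to a BNGL text file (UTF-8).
#' @return A [bngl_model()].
#' @export
read_bngl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_model(readLines(path, warn = FALSE, encoding = "UTF-8"))
}
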