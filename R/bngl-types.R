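#' @title BNGL domain objects
#' @description Constructors for the typed representation of a parsed BNGL
#'   model: molecule type declarations, site patterns, species patterns,
#'   observables, reaction rules and whole models. All objects are plain
#'   lists with S3 classes so they print readably and serialize back to
#'   canonical BNGL text via [bngl_serialize()].
#' @name bngl-types
NULL

# Name production: a letter followed by letters, digits or underscores.
.name_rx <- "^[A-Za-z][A-Za-z0-9_]*$"

is_bngl_name <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(.name_rx, x)
}

stop_bngl <- function(class, msg, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "bngl_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  )
  stop(cond)
}

check_name <- function(x, what = "identifier") {
  if (!is_bngl_name(x)) {
    stop_bngl("bngl_syntax_error",
              "invalid %s '%s': must be a letter followed by letters, digits or underscores",
              what, as.character(x)[1])
  }
  x
}

#' Declare a site of a molecule type
#'
#' @param name Site name (letter followed by letters/digits/underscores).
#' @param states Character vector of allowed state names, in declared order;
#'   empty for a stateless site. State names must be unique within the site.
#' @return A `site_def` object.
#' @export
site_def <- function(name, states = character()) {
  check_name(name, "site name")
  states <- as.character(states)
  for (s in states) check_name(s, "state name")
  if (anyDuplicated(states)) {
    stop_bngl("bngl_syntax_error", "duplicate state names on site '%s'", name)
  }
  structure(list(name = name, states = states), class = "site_def")
}

#' Declare a molecule type
#'
#' @param name Molecule name.
#' @param sites List of [site_def()] objects, in declared order. May be empty:
#'   zero-site molecules are legal (e.g. a freely diffusing phosphatase whose
#'   sites play no role in the model).
#' @return A `molecule_type_def` object.
#' @export
molecule_type_def <- function(name, sites = list()) {
  check_name(name, "molecule name")
  if (!all(vapply(sites, inherits, logical(1), "site_def"))) {
    stop("sites must be a list of site_def objects")
  }
  structure(list(name = name, sites = sites), class = "molecule_type_def")
}

#' Bond mark on a site in a pattern
#'
#' The four ways a pattern can constrain the bond status of a site:
#' * `unbound` — the site carries no `!` mark and must be free;
#' * `bonded` — the site carries an explicit numeric bond index `!k`;
#' * `bonded-any` — `!+`, bound to an unspecified partner;
#' * `unspecified` — `!?`, bound or unbound, unconstrained.
#'
#' @param variant One of `"unbound"`, `"bonded"`, `"bonded-any"`,
#'   `"unspecified"`.
#' @param index Positive integer bond index, required iff `variant` is
#'   `"bonded"`.
#' @return A `bond_mark` object.
#' @export
bond_mark <- function(variant = "unbound", index = NA_integer_) {
  variant <- match.arg(variant, c("unbound", "bonded", "bonded-any", "unspecified"))
  if (variant == "bonded") {
    index <- as.integer(index)
    if (is.na(index) || index < 1L) {
      stop_bngl("bngl_syntax_error", "explicit bond mark needs a positive integer index")
    }
  } else {
    index <- NA_integer_
  }
  structure(list(variant = variant, index = index), class = "bond_mark")
}

#' A site occurrence inside a molecule pattern
#'
#' @param name Site name.
#' @param state Stated internal state, or `NA` when the pattern leaves the
#'   state unconstrained.
#' @param bond A [bond_mark()].
#' @return A `site_pattern` object.
#' @export
site_pattern <- function(name, state = NA_character_, bond = bond_mark()) {
  check_name(name, "site name")
  if (!is.na(state)) check_name(state, "state name")
  stopifnot(inherits(bond, "bond_mark"))
  structure(list(name = name, state = as.character(state), bond = bond),
            class = "site_pattern")
}

#' A molecule occurrence inside a species pattern
#'
#' Sites listed are a sub-multiset of the declared sites; unmentioned sites
#' are unconstrained (any state, any bond status).
#'
#' @param name Molecule name.
#' @param sites List of [site_pattern()] objects, in written order.
#' @return A `molecule_pattern` object.
#' @export
molecule_pattern <- function(name, sites = list()) {
  check_name(name, "molecule name")
  if (!all(vapply(sites, inherits, logical(1), "site_pattern"))) {
    stop("sites must be a list of site_pattern objects")
  }
  structure(list(name = name, sites = sites), class = "molecule_pattern")
}

#' A species pattern (site graph)
#'
#' An ordered list of molecule patterns joined by `.`; bonds are derived from
#' shared numeric bond indices, each of which must occur exactly twice.
#'
#' @param molecules List of [molecule_pattern()] objects.
#' @param validate Check the bond-pairing invariant (default `TRUE`).
#' @return A `species_pattern` object.
#' @export
species_pattern <- function(molecules = list(), validate = TRUE) {
  if (!all(vapply(molecules, inherits, logical(1), "molecule_pattern"))) {
    stop("molecules must be a list of molecule_pattern objects")
  }
  p <- structure(list(molecules = molecules), class = "species_pattern")
  if (validate) check_bond_pairing(p)
  p
}

#' Derive the bond list of a species pattern
#'
#' @param p A [species_pattern()].
#' @return A data frame with one row per explicit bond: columns `index`,
#'   `mol_a`, `site_a`, `mol_b`, `site_b` (molecule and site positions,
#'   1-based, ordered by first appearance of the index).
#' @export
pattern_bonds <- function(p) {
  stopifnot(inherits(p, "species_pattern"))
  hits <- list()
  for (mi in seq_along(p$molecules)) {
    sites <- p$molecules[[mi]]$sites
    for (si in seq_along(sites)) {
      b <- sites[[si]]$bond
      if (b$variant == "bonded") {
        hits[[length(hits) + 1L]] <- list(index = b$index, mol = mi, site = si)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(index = integer(), mol_a = integer(), site_a = integer(),
                      mol_b = integer(), site_b = integer()))
  }
  idx <- vapply(hits, `[[`, integer(1), "index")
  out <- lapply(unique(idx), function(k) {
    ends <- hits[idx == k]
    if (length(ends) != 2L) {
      stop_bngl("bngl_reference_error",
                "bond index %d occurs %d time(s); every bond index must occur exactly twice",
                k, length(ends))
    }
    data.frame(index = k,
               mol_a = ends[[1]]$mol, site_a = ends[[1]]$site,
               mol_b = ends[[2]]$mol, site_b = ends[[2]]$site)
  })
  do.call(rbind, out)
}

check_bond_pairing <- function(p) {
  invisible(pattern_bonds(p))
}

#' An observable: a named group of species patterns
#'
#' @param name Observable name.
#' @param kind `"Molecules"` or `"Species"` (BNGL match-counting modes; both
#'   are rendered identically, the kind is kept for round-tripping).
#' @param patterns Non-empty list of [species_pattern()] objects.
#' @param line Source line number, if parsed from a file.
#' @return An `observable` object.
#' @export
observable <- function(name, kind = c("Molecules", "Species"), patterns,
                       line = NA_integer_) {
  kind <- match.arg(kind)
  check_name(name, "observable name")
  if (!length(patterns)) {
    stop_bngl("bngl_syntax_error", "observable '%s' needs at least one pattern", name)
  }
  structure(list(name = name, kind = kind, patterns = patterns,
                 line = as.integer(line)),
            class = "observable")
}

#' A reaction rule
#'
#' @param reactants,products Lists of [species_pattern()] objects. An empty
#'   list is the BNGL `0` (pure synthesis / degradation).
#' @param reversible Logical flag; a reversible rule carries exactly two rate
#'   expressions.
#' @param rate_text Character vector of opaque rate expressions (length 1, or
#'   2 when reversible). Never interpreted.
#' @param label Optional rule label.
#' @param line Source line number, if parsed from a file.
#' @return A `reaction_rule` object.
#' @export
reaction_rule <- function(reactants, products, reversible = FALSE,
                          rate_text = character(), label = NA_character_,
                          line = NA_integer_) {
  if (length(rate_text)) {
    need <- if (reversible) 2L else 1L
    if (length(rate_text) != need) {
      stop_bngl("bngl_syntax_error",
                "%s rule must carry exactly %d rate expression(s), got %d",
                if (reversible) "reversible" else "irreversible",
                need, length(rate_text))
    }
  }
  structure(list(label = as.character(label), reactants = reactants,
                 products = products, reversible = isTRUE(reversible),
                 rate_text = as.character(rate_text), line = as.integer(line)),
            class = "reaction_rule")
}

#' A parsed BNGL model
#'
#' @param molecule_types List of [molecule_type_def()] objects.
#' @param species List of seed species, each a list with elements `pattern`
#'   (a [species_pattern()]), `initial_text` (opaque) and `line`.
#' @param observables List of [observable()] objects.
#' @param rules List of [reaction_rule()] objects.
#' @param comments Data frame with columns `line` and `text` recording every
#'   `#` comment and its position.
#' @param extra_blocks Named list of verbatim text for blocks outside the
#'   supported subset (parameters, functions, ...); preserved but never
#'   visualized.
#' @return A `bngl_model` object.
#' @export
bngl_model <- function(molecule_types = list(), species = list(),
                       observables = list(), rules = list(),
                       comments = data.frame(line = integer(), text = character()),
                       extra_blocks = list()) {
  nms <- vapply(molecule_types, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_bngl("bngl_reference_error", "duplicate molecule type name '%s'",
              nms[duplicated(nms)][1])
  }
  structure(list(molecule_types = molecule_types, species = species,
                 observables = observables, rules = rules,
                 comments = comments, extra_blocks = extra_blocks),
            class = "bngl_model")
}

#' @export
print.bngl_model <- function(x, ...) {
  cat(sprintf("BNGL model: %d molecule type(s), %d seed species, %d observable(s), %d rule(s)\n",
              length(x$molecule_types), length(x$species),
              length(x$observables), length(x$rules)))
  invisible(x)
}

#' @export
print.species_pattern <- function(x, ...) {
  cat(bngl_serialize(x), "\n")
  invisible(x)
}

#' @export
print.reaction_rule <- function(x, ...) {
  cat(bngl_serialize(x), "\n")
  invisible(x)
}

#' @export
print.molecule_type_def <- function(x, ...) {
  cat(bngl_serialize(x), "\n")
  invisible(x)
}

# Look up a molecule type by name; NULL when context is empty/absent.
find_type <- function(name, context) {
  if (is.null(context) || !length(context)) return(NULL)
  for (mt in context) if (mt$name == name) return(mt)
  stop_bngl("bngl_reference_error", "molecule '%s' is not declared", name)
}

# Map each site occurrence in a molecule pattern to a declared site position.
# Duplicate names are matched by occurrence order (k-th written occurrence of
# a name binds to the k-th declared site of that name).
resolve_sites <- function(mp, mt) {
  decl_names <- vapply(mt$sites, `[[`, character(1), "name")
  seen <- integer(0)
  out <- integer(length(mp$sites))
  for (si in seq_along(mp$sites)) {
    sp <- mp$sites[[si]]
    cand <- which(decl_names == sp$name)
    cand <- setdiff(cand, seen)
    if (!length(cand)) {
      stop_bngl("bngl_reference_error",
                "site '%s' is not declared on molecule '%s' (or is listed too many times)",
                sp$name, mt$name)
    }
    pos <- cand[1]
    seen <- c(seen, pos)
    out[si] <- pos
    if (!is.na(sp$state)) {
      states <- mt$sites[[pos]]$states
      if (!(sp$state %in% states)) {
        stop_bngl("bngl_reference_error",
                  "state '%s' is not declared for site '%s' on molecule '%s'",
                  sp$state, sp$name, mt$name)
      }
    }
  }
  out
}

# Validate a species pattern against molecule type declarations.
validate_pattern <- function(p, context) {
  if (is.null(context) || !length(context)) return(invisible(p))
  for (mp in p$molecules) {
    mt <- find_type(mp$name, context)
    resolve_sites(mp, mt)
  }
  invisible(p)
}
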