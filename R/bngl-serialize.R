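#' @title Canonical BNGL serialization and form expansion
#' @name bngl-serialize
NULL

#' Serialize a parsed entity back to canonical BNGL text
#'
#' Canonical text uses single spaces, explicit parentheses on every molecule
#' (a zero-site molecule serializes as `PTP()`), and bond indices renumbered
#' `1..n` in order of first appearance, left to right. When a `context` of
#' molecule type declarations is supplied, the sites of each molecule pattern
#' are emitted in declared order. One canonicalization pass is a fixed point:
#' `bngl_serialize(parse_pattern(bngl_serialize(p)))` equals
#' `bngl_serialize(p)`.
#'
#' @param x A [species_pattern()], [molecule_pattern()],
#'   [molecule_type_def()], [observable()], [reaction_rule()] or
#'   [bngl_model()].
#' @param ... Passed on to methods; most accept `context` (a list of
#'   [molecule_type_def()]) to reorder pattern sites into declared order.
#' @return A character scalar (for a model, one string with embedded
#'   newlines).
#' @export
bngl_serialize <- function(x, ...) UseMethod("bngl_serialize")

fmt_site_pattern <- function(sp, index_map) {
  out <- sp$name
  if (!is.na(sp$state)) out <- paste0(out, "~", sp$state)
  b <- sp$bond
  out <- switch(b$variant,
    "unbound"     = out,
    "bonded-any"  = paste0(out, "!+"),
    "unspecified" = paste0(out, "!?"),
    "bonded"      = paste0(out, "!", index_map[[as.character(b$index)]])
  )
  out
}

# Order the sites of a molecule pattern by declared position when context
# is available; stable for duplicate names (occurrence order).
order_pattern_sites <- function(mp, context) {
  if (is.null(context)) return(mp)
  mt <- tryCatch(find_type(mp$name, context), bngl_error = function(e) NULL)
  if (is.null(mt)) return(mp)
  pos <- resolve_sites(mp, mt)
  mp$sites <- mp$sites[order(pos)]
  mp
}

#' @rdname bngl_serialize
#' @param context Optional molecule type declarations used to put sites into
#'   declared order.
#' @export
bngl_serialize.species_pattern <- function(x, context = NULL, ...) {
  check_bond_pairing(x)
  mols <- lapply(x$molecules, order_pattern_sites, context = context)
  # renumber by first appearance over the (possibly reordered) site lists
  index_map <- list()
  seen <- character(0)
  next_id <- 1L
  for (mp in mols) {
    for (sp in mp$sites) {
      if (sp$bond$variant == "bonded") {
        key <- as.character(sp$bond$index)
        if (!(key %in% seen)) {
          index_map[[key]] <- next_id
          next_id <- next_id + 1L
          seen <- c(seen, key)
        }
      }
    }
  }
  txt <- vapply(mols, function(mp) {
    paste0(mp$name, "(",
           paste(vapply(mp$sites, fmt_site_pattern, character(1), index_map),
                 collapse = ","),
           ")")
  }, character(1))
  paste(txt, collapse = ".")
}

#' @export
bngl_serialize.molecule_pattern <- function(x, context = NULL, ...) {
  bngl_serialize(species_pattern(list(x), validate = FALSE), context = context)
}

#' @export
bngl_serialize.molecule_type_def <- function(x, ...) {
  sites <- vapply(x$sites, function(s) {
    paste0(s$name, paste0(rep("~", length(s$states)), s$states, collapse = ""))
  }, character(1))
  paste0(x$name, "(", paste(sites, collapse = ","), ")")
}

#' @export
bngl_serialize.observable <- function(x, context = NULL, ...) {
  pats <- vapply(x$patterns, bngl_serialize, character(1), context = context)
  paste(x$kind, x$name, paste(pats, collapse = " "))
}

#' @export
bngl_serialize.reaction_rule <- function(x, context = NULL, ...) {
  side <- function(ps) {
    if (!length(ps)) return("0")
    paste(vapply(ps, bngl_serialize, character(1), context = context),
          collapse = " + ")
  }
  arrow <- if (x$reversible) "<->" else "->"
  out <- paste(side(x$reactants), arrow, side(x$products))
  if (length(x$rate_text)) out <- paste(out, paste(x$rate_text, collapse = ", "))
  if (!is.na(x$label)) out <- paste0(x$label, ": ", out)
  out
}

#' @export
bngl_serialize.bngl_model <- function(x, ...) {
  ctx <- if (length(x$molecule_types)) x$molecule_types else NULL
  out <- character(0)
  if (length(x$molecule_types)) {
    out <- c(out, "begin molecule types",
             paste0("  ", vapply(x$molecule_types, bngl_serialize, character(1))),
             "end molecule types")
  }
  if (length(x$species)) {
    out <- c(out, "begin seed species",
             vapply(x$species, function(s) {
               paste0("  ", bngl_serialize(s$pattern, context = ctx),
                      if (nzchar(s$initial_text)) paste0(" ", s$initial_text) else "")
             }, character(1)),
             "end seed species")
  }
  if (length(x$observables)) {
    out <- c(out, "begin observables",
             paste0("  ", vapply(x$observables, bngl_serialize, character(1),
                                 context = ctx)),
             "end observables")
  }
  if (length(x$rules)) {
    out <- c(out, "begin reaction rules",
             paste0("  ", vapply(x$rules, bngl_serialize, character(1),
                                 context = ctx)),
             "end reaction rules")
  }
  paste(out, collapse = "\n")
}

# ---- form expansion ---------------------------------------------------------

#' Complete a pattern against molecule type declarations
#'
#' Rewrites each molecule pattern to list every declared site in declared
#' order: mentioned sites keep their constraints, unmentioned sites are
#' added unconstrained (free state, unbound). Molecules with no matching
#' declaration are left untouched.
#'
#' @param pattern A [species_pattern()].
#' @param context List of [molecule_type_def()] declarations.
#' @return A [species_pattern()] whose molecules list all declared sites.
#' @export
complete_pattern <- function(pattern, context) {
  mols <- lapply(pattern$molecules, function(mp) {
    mt <- tryCatch(find_type(mp$name, context), bngl_error = function(e) NULL)
    if (is.null(mt)) return(mp)
    pos <- resolve_sites(mp, mt)
    sites <- vector("list", length(mt$sites))
    for (k in seq_along(mt$sites)) {
      hit <- which(pos == k)
      if (length(hit)) {
        sites[[k]] <- mp$sites[[hit[1]]]
      } else {
        sites[[k]] <- site_pattern(mt$sites[[k]]$name)
      }
    }
    molecule_pattern(mp$name, sites)
  })
  species_pattern(mols, validate = FALSE)
}

#' Enumerate all fully specified forms of a pattern
#'
#' Completes each molecule pattern against its declaration (unmentioned sites
#' are added unbound) and expands every state-bearing site whose state is
#' left unconstrained over all of its declared states. Bond marks are never
#' expanded. The result enumerates the molecular forms the pattern stands
#' for: its length equals the product, over unconstrained multi-state sites,
#' of the number of declared states.
#'
#' @param pattern A [species_pattern()].
#' @param context List of [molecule_type_def()] declarations (required).
#' @param cap Combinatorial guard: refuse expansions larger than this many
#'   forms (default 10000).
#' @return A list of fully specified [species_pattern()] objects, in
#'   lexicographic order of state choices (sites vary fastest at the right,
#'   states in declared order).
#' @examples
#' mt <- parse_model(c("begin molecule types",
#'                     "EGFR(l,r,Y1068~u~p,Y1148~u~p)",
#'                     "end molecule types"))$molecule_types
#' length(expand_forms(parse_pattern("EGFR()"), mt))  # 4
#' @export
expand_forms <- function(pattern, context, cap = 10000L) {
  stopifnot(inherits(pattern, "species_pattern"))
  if (is.null(context) || !length(context)) {
    stop("expand_forms needs molecule type declarations as context", call. = FALSE)
  }
  validate_pattern(pattern, context)
  completed <- complete_pattern(pattern, context)$molecules

  # per-site state choices across the whole pattern
  slots <- list()   # each: list(mol, site, states)
  for (mi in seq_along(completed)) {
    mt <- find_type(completed[[mi]]$name, context)
    for (si in seq_along(completed[[mi]]$sites)) {
      sp <- completed[[mi]]$sites[[si]]
      states <- mt$sites[[si]]$states
      if (length(states) && is.na(sp$state)) {
        slots[[length(slots) + 1L]] <- list(mol = mi, site = si, states = states)
      }
    }
  }

  n_forms <- prod(vapply(slots, function(s) length(s$states), numeric(1)))
  if (n_forms > cap) {
    stop(sprintf("expansion would produce %.0f forms, above the cap of %d; raise `cap` to proceed",
                 n_forms, cap), call. = FALSE)
  }

  base <- species_pattern(completed, validate = FALSE)
  if (!length(slots)) return(list(base))

  # lexicographic enumeration: leftmost slot most significant
  counts <- vapply(slots, function(s) length(s$states), integer(1))
  out <- vector("list", n_forms)
  idx <- rep(1L, length(slots))
  for (f in seq_len(n_forms)) {
    p <- base
    for (k in seq_along(slots)) {
      sl <- slots[[k]]
      p$molecules[[sl$mol]]$sites[[sl$site]]$state <- sl$states[idx[k]]
    }
    out[[f]] <- p
    # increment rightmost-fastest
    for (k in rev(seq_along(slots))) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= counts[k]) break
      idx[k] <- 1L
    }
  }
  out
}

#' Count the fully specified forms of a pattern
#'
#' Product over unconstrained multi-state sites of their declared state
#' counts, computed without materializing the expansion.
#'
#' @inheritParams expand_forms
#' @return Integer count of forms.
#' @export
count_forms <- function(pattern, context) {
  stopifnot(inherits(pattern, "species_pattern"))
  validate_pattern(pattern, context)
  total <- 1
  for (mp in pattern$molecules) {
    mt <- find_type(mp$name, context)
    pos <- resolve_sites(mp, mt)
    for (k in seq_along(mt$sites)) {
      states <- mt$sites[[k]]$states
      hit <- which(pos == k)
      stated <- length(hit) && !is.na(mp$sites[[hit[1]]]$state)
      if (length(states) > 1L && !stated) total <- total * length(states)
    }
  }
  as.integer(total)
}
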