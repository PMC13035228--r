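#' @title Building railroad diagrams from BNGL entities
#' @description Translates parsed molecule types, species patterns,
#'   observables and reaction rules (with their derived action sets) into
#'   [rr_diagram()] structures following the rules-railroad conventions:
#'   one lane per molecule, per-site state choices, dashed site-name
#'   annotations, solid bond links, dashed co-complex links, action boxes
#'   on the affected paths and dashed synthesis/degradation enclosures.
#' @name rrr-build
NULL

#' Rendering options
#'
#' @param show_bond_indexes Label each bond link with its canonical index.
#' @param omit_molecule_names Drop the molecule-name terminal from every
#'   lane (shortens diagrams; word counts are unchanged).
#' @param show_comments Append same-line source comments to diagram titles
#'   when building from a parsed model.
#' @param notation `"bngl"` (Molecules / Species vocabulary) or `"generic"`
#'   (Interacting Agents / Initial Set) — display vocabulary only, structure
#'   unchanged.
#' @param strict_degradation Abort a rule diagram when a degraded molecule
#'   holds an unsevered bond (otherwise a warning diagnostic).
#' @return A `render_options` list.
#' @export
render_options <- function(show_bond_indexes = FALSE,
                           omit_molecule_names = FALSE,
                           show_comments = FALSE,
                           notation = c("bngl", "generic"),
                           strict_degradation = FALSE) {
  notation <- match.arg(notation)
  structure(list(show_bond_indexes = show_bond_indexes,
                 omit_molecule_names = omit_molecule_names,
                 show_comments = show_comments,
                 notation = notation,
                 strict_degradation = strict_degradation),
            class = "render_options")
}

vocab <- function(word, opts) {
  if (opts$notation != "generic") return(word)
  switch(word,
         "Molecule" = "Interacting Agent",
         "Species" = "Initial Set",
         "Molecules" = "Interacting Agents",
         word)
}

#' Diagram of a molecule type
#'
#' One lane enumerating every form of the molecule: the molecule name
#' terminal, then per site a choice over its declared states (a multi-state
#' site contributes a choice, a single-state site its lone state, a
#' stateless site a plain terminal). Site names of state-bearing sites are
#' attached as dashed annotations — they are not part of the enumeration, so
#' the lane's word count equals the number of molecular forms.
#'
#' @param m A [molecule_type_def()].
#' @param opts [render_options()].
#' @return An [rr_diagram()] with a single lane.
#' @export
build_molecule_diagram <- function(m, opts = render_options()) {
  stopifnot(inherits(m, "molecule_type_def"))
  parts <- list()
  if (!opts$omit_molecule_names) parts <- c(parts, list(rr_terminal(m$name)))
  for (s in m$sites) {
    if (!length(s$states)) {
      parts <- c(parts, list(rr_terminal(s$name)))
    } else {
      parts <- c(parts, list(rr_annotation(s$name)))
      if (length(s$states) == 1L) {
        parts <- c(parts, list(rr_terminal(s$states)))
      } else {
        parts <- c(parts, list(rr_choice(lapply(s$states, rr_terminal))))
      }
    }
  }
  if (!length(parts)) parts <- list(rr_terminal(m$name))
  rr_diagram(rr_seq(parts), title = paste0(vocab("Molecule", opts), ": ", m$name))
}

# ---- shared lane construction for patterns ---------------------------------

# Build one lane for a molecule pattern. Behaviour per site:
#  - stated state -> terminal of the state; unconstrained multi-state site ->
#    choice over all declared states (when expand_states and context allow);
#  - bonded sites get a port right after their element; wildcard marks get
#    one-ended stubs; state-change sites (overrides) render before/box/after.
# Returns list(node, links) where links are lane-local (stubs).
build_pattern_lane <- function(mp, lane_id, context, opts,
                               expand_states = FALSE,
                               state_overrides = list(),
                               port_prefix = lane_id) {
  mt <- if (!is.null(context)) {
    tryCatch(find_type(mp$name, context), bngl_error = function(e) NULL)
  }
  decl_pos <- if (!is.null(mt)) resolve_sites(mp, mt) else rep(NA_integer_, length(mp$sites))

  parts <- list()
  links <- list()
  if (!opts$omit_molecule_names) parts <- c(parts, list(rr_terminal(mp$name)))

  emit_site <- function(sp, si, decl) {
    states <- if (!is.null(mt) && !is.na(decl)) mt$sites[[decl]]$states else character(0)
    ov <- state_overrides[[as.character(si)]]
    if (!is.null(ov)) {
      # state change: before-and-after pair along the path with the
      # transition box between them; other states are omitted (the rule
      # constrains them anyway)
      parts <<- c(parts, list(rr_annotation(sp$name),
                              rr_terminal(ov$from),
                              rr_action_box("state-change",
                                            reversible = isTRUE(ov$reversible)),
                              rr_terminal(ov$to)))
    } else if (!is.na(sp$state)) {
      parts <<- c(parts, list(rr_annotation(sp$name), rr_terminal(sp$state)))
    } else if (expand_states && length(states) > 1L) {
      parts <<- c(parts, list(rr_annotation(sp$name),
                              rr_choice(lapply(states, rr_terminal))))
    } else if (expand_states && length(states) == 1L) {
      parts <<- c(parts, list(rr_annotation(sp$name), rr_terminal(states)))
    } else {
      parts <<- c(parts, list(rr_terminal(sp$name)))
    }
    v <- sp$bond$variant
    if (v != "unbound") {
      pid <- sprintf("%s.s%d", port_prefix, si)
      parts <<- c(parts, list(rr_port(pid)))
      if (v == "bonded-any") {
        links <<- c(links, list(rr_link(pid, style = "required-stub")))
      } else if (v == "unspecified") {
        links <<- c(links, list(rr_link(pid, style = "optional-stub")))
      }
    }
  }
  for (si in seq_along(mp$sites)) emit_site(mp$sites[[si]], si, decl_pos[si])

  if (!length(parts)) parts <- list(rr_terminal(mp$name))
  list(node = rr_seq(parts), links = links)
}

# dashed spanning-chain co-complex links between consecutive lanes of one
# species pattern; anchors are dedicated ports at lane heads
complex_chain_links <- function(port_prefixes) {
  out <- list()
  if (length(port_prefixes) < 2L) return(out)
  for (k in seq_len(length(port_prefixes) - 1L)) {
    out[[length(out) + 1L]] <-
      rr_link(paste0(port_prefixes[k], ".cplx"),
              paste0(port_prefixes[k + 1L], ".cplx"),
              style = "dashed-complex")
  }
  out
}

with_complex_anchor <- function(node, port_prefix) {
  rr_seq(list(rr_port(paste0(port_prefix, ".cplx")), node))
}

#' Diagram of a species pattern
#'
#' One lane per molecule. Every explicit bond becomes a solid link between
#' ports at the two bound endpoints; all molecules of the pattern are
#' additionally joined by a dashed co-complex chain (lane i to lane i+1) —
#' the dashed lines indicate connectivity and are not traversal paths.
#'
#' @param p A [species_pattern()].
#' @param context Optional molecule type declarations.
#' @param opts [render_options()].
#' @param title Diagram title; defaults to the serialized pattern.
#' @return An [rr_diagram()].
#' @export
build_species_diagram <- function(p, context = NULL, opts = render_options(),
                                  title = NULL) {
  stopifnot(inherits(p, "species_pattern"))
  bonds <- pattern_bonds(p)
  lanes <- list()
  links <- list()
  prefixes <- character(0)
  multi <- length(p$molecules) > 1L
  for (mi in seq_along(p$molecules)) {
    pref <- sprintf("m%d", mi)
    ln <- build_pattern_lane(p$molecules[[mi]], pref, context, opts)
    node <- if (multi) with_complex_anchor(ln$node, pref) else ln$node
    lanes[[length(lanes) + 1L]] <- node
    links <- c(links, ln$links)
    prefixes <- c(prefixes, pref)
  }
  for (k in seq_len(nrow(bonds))) {
    links <- c(links, list(rr_link(
      sprintf("m%d.s%d", bonds$mol_a[k], bonds$site_a[k]),
      sprintf("m%d.s%d", bonds$mol_b[k], bonds$site_b[k]),
      style = "solid-bond",
      label = if (opts$show_bond_indexes) sprintf("!%d", k) else NA_character_)))
  }
  links <- c(links, complex_chain_links(prefixes))
  if (is.null(title)) {
    title <- paste0(vocab("Species", opts), ": ", bngl_serialize(p))
  }
  rr_diagram(lanes, links, title = title)
}

#' Diagram of an observable
#'
#' Renders the observable's pattern(s) with unconstrained multi-state sites
#' expanded into choices over all declared states, so the lane enumerates
#' every matching form. Sites that must be bound (`!+`) carry a required
#' (solid) connectivity stub; sites that may be bound (`!?`) carry an
#' optional stub — grey with a question mark. An observable with several
#' patterns stacks their lanes.
#'
#' @param o An [observable()].
#' @param context Molecule type declarations (needed to expand states).
#' @param opts [render_options()].
#' @return An [rr_diagram()].
#' @export
build_observable_diagram <- function(o, context = NULL, opts = render_options()) {
  stopifnot(inherits(o, "observable"))
  lanes <- list()
  links <- list()
  for (pi in seq_along(o$patterns)) {
    p <- o$patterns[[pi]]
    if (!is.null(context)) p <- complete_pattern(p, context)
    bonds <- pattern_bonds(p)
    multi <- length(p$molecules) > 1L
    prefixes <- character(0)
    for (mi in seq_along(p$molecules)) {
      pref <- sprintf("p%dm%d", pi, mi)
      ln <- build_pattern_lane(p$molecules[[mi]], pref, context, opts,
                               expand_states = TRUE)
      node <- if (multi) with_complex_anchor(ln$node, pref) else ln$node
      lanes[[length(lanes) + 1L]] <- node
      links <- c(links, ln$links)
      prefixes <- c(prefixes, pref)
    }
    for (k in seq_len(nrow(bonds))) {
      links <- c(links, list(rr_link(
        sprintf("p%dm%d.s%d", pi, bonds$mol_a[k], bonds$site_a[k]),
        sprintf("p%dm%d.s%d", pi, bonds$mol_b[k], bonds$site_b[k]),
        style = "solid-bond",
        label = if (opts$show_bond_indexes) sprintf("!%d", k) else NA_character_)))
    }
    links <- c(links, complex_chain_links(prefixes))
  }
  rr_diagram(lanes, links,
             title = paste0("Observable (", vocab(o$kind, opts), "): ", o$name))
}

#' Diagram of a reaction rule
#'
#' A single unified diagram, not a reactant/product pair: the reactant
#' context is drawn as in species and observable diagrams, and the rule's
#' actions are embedded in it. Bond additions splice an add-bond action box
#' (downward arrow) into the new link between the two endpoints; bond
#' deletions put a delete-bond box (upward arrow) on the existing link; a
#' reversible rule carries the paired double arrow, the box class coming
#' from the forward direction. State changes render as a before-and-after
#' state pair with the transition box between them. An intramolecular bond
#' addition keeps its dot-joined lanes tied by the dashed co-complex chain.
#' Catalysts that form their own reactant pattern stand as separate,
#' unlinked lanes. Molecules the rule degrades are enclosed in a dashed box
#' labelled "degraded"; molecules it synthesizes are appended as lanes in a
#' dashed box labelled "synthesized".
#'
#' @param rule A [reaction_rule()].
#' @param actions Its `action_set` from [diff_rule()]; derived on the fly
#'   when `NULL`.
#' @param opts [render_options()].
#' @param context Optional molecule type declarations.
#' @return An [rr_diagram()]. Degradation diagnostics from
#'   [validate_degradation()] are attached as attribute `"diagnostics"` and
#'   raised as warnings (errors under `strict_degradation`).
#' @export
build_rule_diagram <- function(rule, actions = NULL, opts = render_options(),
                               context = NULL) {
  stopifnot(inherits(rule, "reaction_rule"))
  if (is.null(actions)) actions <- diff_rule(rule)
  stopifnot(inherits(actions, "action_set"))

  diags <- validate_degradation(actions)
  if (length(diags)) {
    if (opts$strict_degradation) {
      stop(paste(diags, collapse = "\n"), call. = FALSE)
    }
    for (d in diags) warning(d, call. = FALSE)
  }

  # per-site action annotations, keyed "pattern.mol.site"
  overrides <- list()       # state changes
  deleted_mols <- character(0)
  for (a in actions$actions) {
    if (a$kind == "state-change") {
      key <- sprintf("%d.%d", a$s$pattern, a$s$mol)
      overrides[[key]] <- c(overrides[[key]],
                            stats::setNames(list(list(from = a$from, to = a$to,
                                                      reversible = actions$reversible)),
                                            as.character(a$s$site)))
    } else if (a$kind == "delete-molecule") {
      deleted_mols <- c(deleted_mols, sprintf("%d.%d", a$pattern, a$mol))
    }
  }

  lanes <- list()
  links <- list()
  for (pi in seq_along(rule$reactants)) {
    p <- rule$reactants[[pi]]
    multi <- length(p$molecules) > 1L
    prefixes <- character(0)
    for (mi in seq_along(p$molecules)) {
      pref <- sprintf("r%dm%d", pi, mi)
      key <- sprintf("%d.%d", pi, mi)
      ln <- build_pattern_lane(p$molecules[[mi]], pref, context, opts,
                               state_overrides = overrides[[key]] %||% list())
      node <- if (multi) with_complex_anchor(ln$node, pref) else ln$node
      if (key %in% deleted_mols) {
        node <- rr_group_box(node, "degraded", role = "degraded")
      }
      lanes[[length(lanes) + 1L]] <- node
      links <- c(links, ln$links)
      prefixes <- c(prefixes, pref)
    }
    # context bonds present on both sides (solid links, no action box)
    bonds <- pattern_bonds(p)
    for (k in seq_len(nrow(bonds))) {
      a_ref <- site_ref(pi, bonds$mol_a[k], bonds$site_a[k])
      b_ref <- site_ref(pi, bonds$mol_b[k], bonds$site_b[k])
      key <- bond_key(a_ref, b_ref)
      box <- NULL
      for (act in actions$actions) {
        if (act$kind == "delete-bond" && bond_key(act$a, act$b) == key) {
          box <- rr_action_box("delete-bond", reversible = actions$reversible)
        }
      }
      links <- c(links, list(rr_link(
        sprintf("r%dm%d.s%d", pi, bonds$mol_a[k], bonds$site_a[k]),
        sprintf("r%dm%d.s%d", pi, bonds$mol_b[k], bonds$site_b[k]),
        style = "solid-bond", action = box,
        label = if (opts$show_bond_indexes) sprintf("!%d", k) else NA_character_)))
    }
    links <- c(links, complex_chain_links(prefixes))
  }

  # bond additions: new links carrying the add-bond box; endpoints were
  # unbound in the reactants, so their sites got no port yet — we re-build
  # lanes is avoided by pre-marking below.
  port_of <- function(ref) {
    if (!is.na(ref$created)) sprintf("new%d.s%d", ref$created, ref$site)
    else sprintf("r%dm%d.s%d", ref$pattern, ref$mol, ref$site)
  }
  add_ports_needed <- list()
  for (a in actions$actions) {
    if (a$kind == "add-bond") {
      for (e in list(a$a, a$b)) {
        add_ports_needed[[port_of(e)]] <- e
      }
    }
  }
  if (length(add_ports_needed)) {
    # splice missing ports into the affected lanes by rebuilding them with
    # the endpoint sites marked
    lanes <- list()
    lane_k <- 0L
    for (pi in seq_along(rule$reactants)) {
      p <- rule$reactants[[pi]]
      multi <- length(p$molecules) > 1L
      for (mi in seq_along(p$molecules)) {
        lane_k <- lane_k + 1L
        pref <- sprintf("r%dm%d", pi, mi)
        key <- sprintf("%d.%d", pi, mi)
        mp <- p$molecules[[mi]]
        # mark endpoint sites with a synthetic "bonded" flag so the lane
        # builder emits their ports (the link itself carries the action)
        for (pid in names(add_ports_needed)) {
          e <- add_ports_needed[[pid]]
          if (is.na(e$created) && e$pattern == pi && e$mol == mi) {
            if (mp$sites[[e$site]]$bond$variant == "unbound") {
              mp$sites[[e$site]]$bond <- bond_mark("bonded", 99L + e$site)
              # pair the synthetic index so validation passes
              attr(mp, "synthetic_ports") <- TRUE
            }
          }
        }
        ln <- build_pattern_lane(mp, pref, context, opts,
                                 state_overrides = overrides[[key]] %||% list())
        node <- if (multi) with_complex_anchor(ln$node, pref) else ln$node
        if (key %in% deleted_mols) {
          node <- rr_group_box(node, "degraded", role = "degraded")
        }
        lanes[[length(lanes) + 1L]] <- node
      }
    }
  }

  # created molecules: appended lanes inside synthesized group boxes
  created_k <- 0L
  for (a in actions$actions) {
    if (a$kind != "create-molecule") next
    created_k <- created_k + 1L
    pref <- sprintf("new%d", created_k)
    ln <- build_pattern_lane(a$molecule, pref, context, opts)
    # ports for bonds onto created molecules
    node <- ln$node
    for (pid in names(add_ports_needed)) {
      e <- add_ports_needed[[pid]]
      if (!is.na(e$created) && e$created == created_k) {
        node <- rr_seq(list(node, rr_port(pid)))
      }
    }
    lanes[[length(lanes) + 1L]] <-
      rr_group_box(node, "synthesized", role = "synthesized")
    links <- c(links, ln$links)
  }

  for (a in actions$actions) {
    if (a$kind != "add-bond") next
    links <- c(links, list(rr_link(
      port_of(a$a), port_of(a$b), style = "solid-bond",
      action = rr_action_box("add-bond", reversible = actions$reversible))))
  }

  ttl <- if (!is.na(rule$label)) rule$label else bngl_serialize(rule)
  rr_diagram(lanes, links, title = paste0("Rule: ", ttl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build every diagram of a model
#'
#' One diagram per molecule type, seed species, observable and reaction
#' rule, deterministically named `<block>_<index>_<label>`. Per-entity
#' failures are collected (attribute `"failures"`), not fatal.
#'
#' @param model A [bngl_model()].
#' @param opts [render_options()].
#' @return Named list of [rr_diagram()] objects, with a character vector of
#'   failure messages in `attr(, "failures")`.
#' @export
build_all <- function(model, opts = render_options()) {
  stopifnot(inherits(model, "bngl_model"))
  ctx <- if (length(model$molecule_types)) model$molecule_types else NULL
  out <- list()
  failures <- character(0)
  add <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      failures <<- c(failures, paste0(name, ": ", conditionMessage(res)))
    } else {
      out[[name]] <<- res
    }
  }
  sanitize <- function(s) gsub("[^A-Za-z0-9_]", "_", s)
  comment_for <- function(line) {
    if (!opts$show_comments || is.na(line)) return("")
    hit <- model$comments$text[model$comments$line == line]
    if (length(hit)) paste0("  # ", hit[1]) else ""
  }
  titled <- function(d, extra) {
    if (nzchar(extra)) d$title <- paste0(d$title, extra)
    d
  }
  for (i in seq_along(model$molecule_types)) {
    mt <- model$molecule_types[[i]]
    add(sprintf("molecule_%d_%s", i, sanitize(mt$name)),
        build_molecule_diagram(mt, opts))
  }
  for (i in seq_along(model$species)) {
    sp <- model$species[[i]]
    add(sprintf("species_%d_%s", i, sanitize(sp$pattern$molecules[[1]]$name)),
        titled(build_species_diagram(sp$pattern, ctx, opts),
               comment_for(sp$line)))
  }
  for (i in seq_along(model$observables)) {
    ob <- model$observables[[i]]
    add(sprintf("observable_%d_%s", i, sanitize(ob$name)),
        titled(build_observable_diagram(ob, ctx, opts), comment_for(ob$line)))
  }
  for (i in seq_along(model$rules)) {
    rl <- model$rules[[i]]
    lab <- if (!is.na(rl$label)) rl$label else sprintf("r%d", i)
    add(sprintf("rule_%d_%s", i, sanitize(lab)),
        titled(suppressWarnings(build_rule_diagram(rl, opts = opts, context = ctx)),
               comment_for(rl$line)))
  }
  attr(out, "failures") <- failures
  out
}
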