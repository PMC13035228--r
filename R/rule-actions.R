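#' @title Deriving rule actions by reactant/product comparison
#' @description A reaction rule transforms reactant patterns into product
#'   patterns. The transformation decomposes into a small action vocabulary
#'   (bond addition/deletion, site state change, molecule creation/deletion).
#'   This module recovers the action set of a rule by structural comparison
#'   of the two sides, classifies bond formation as intra- vs intermolecular,
#'   identifies catalysts, and can re-apply the actions to the reactants as a
#'   verification oracle.
#' @name rule-actions
NULL

#' Reference to a site on the reactant side of a rule
#'
#' @param pattern 1-based index of the reactant species pattern (`NA` with a
#'   non-`NA` `created` refers to a molecule created by the rule).
#' @param mol 1-based molecule position within the pattern.
#' @param site 1-based site position within the molecule pattern, as written.
#' @param created 1-based index into the rule's created molecules, when the
#'   endpoint lives on a molecule the rule synthesizes.
#' @return A `site_ref` object.
#' @export
site_ref <- function(pattern, mol, site, created = NA_integer_) {
  structure(list(pattern = as.integer(pattern), mol = as.integer(mol),
                 site = as.integer(site), created = as.integer(created)),
            class = "site_ref")
}

fmt_ref <- function(r, rule = NULL, side = "reactants") {
  if (!is.na(r$created)) return(sprintf("new%d.%d", r$created, r$site))
  base <- sprintf("%d.%d.%d", r$pattern, r$mol, r$site)
  if (!is.null(rule)) {
    mp <- rule[[side]][[r$pattern]]$molecules[[r$mol]]
    base <- sprintf("%d.%s.%s", r$pattern, mp$name, mp$sites[[r$site]]$name)
  }
  base
}

action <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "rrr_action")
}

#' Match product molecules to reactant molecules
#'
#' Molecules are matched by name, then by occurrence order within each side
#' among same-named molecules (the BioNetGen convention). Product molecules
#' with no partner are flagged created; reactant molecules with no partner
#' are flagged deleted.
#'
#' @param rule A [reaction_rule()].
#' @return A list with data frames `reactant` (columns `pattern`, `mol`,
#'   `name`, `matched`, `deleted`) and `product` (columns `pattern`, `mol`,
#'   `name`, `r_flat` index into the reactant table or `NA`, `created`).
#' @export
correspond <- function(rule) {
  flat <- function(side) {
    rows <- list()
    for (pi in seq_along(side)) {
      for (mi in seq_along(side[[pi]]$molecules)) {
        rows[[length(rows) + 1L]] <-
          data.frame(pattern = pi, mol = mi,
                     name = side[[pi]]$molecules[[mi]]$name)
      }
    }
    if (!length(rows)) {
      return(data.frame(pattern = integer(), mol = integer(), name = character()))
    }
    do.call(rbind, rows)
  }
  r <- flat(rule$reactants)
  p <- flat(rule$products)
  p$r_flat <- rep(NA_integer_, nrow(p))
  used <- rep(FALSE, nrow(r))
  for (nm in unique(p$name)) {
    p_idx <- which(p$name == nm)
    r_idx <- which(r$name == nm)
    k <- min(length(p_idx), length(r_idx))
    if (k > 0) p$r_flat[p_idx[seq_len(k)]] <- r_idx[seq_len(k)]
  }
  used[stats::na.omit(p$r_flat)] <- TRUE
  r$matched <- used
  r$deleted <- !used
  p$created <- is.na(p$r_flat)
  list(reactant = r, product = p)
}

# flat index of a reactant/product molecule table row for (pattern, mol)
flat_index <- function(tab, pattern, mol) {
  which(tab$pattern == pattern & tab$mol == mol)
}

# Match sites of a product molecule pattern to a reactant molecule pattern,
# by name then occurrence order. Returns an integer vector: for each product
# site, the reactant site position (NA when unmatched).
match_sites <- function(r_mp, p_mp) {
  r_names <- vapply(r_mp$sites, `[[`, character(1), "name")
  out <- integer(length(p_mp$sites))
  taken <- rep(FALSE, length(r_names))
  for (si in seq_along(p_mp$sites)) {
    cand <- which(r_names == p_mp$sites[[si]]$name & !taken)
    if (!length(cand)) { out[si] <- NA_integer_; next }
    out[si] <- cand[1]
    taken[cand[1]] <- TRUE
  }
  out
}

ref_key <- function(r) {
  if (!is.na(r$created)) sprintf("C%d.%d", r$created, r$site)
  else sprintf("R%d.%d.%d", r$pattern, r$mol, r$site)
}

bond_key <- function(a, b) {
  ks <- sort(c(ref_key(a), ref_key(b)))
  paste(ks, collapse = "|")
}

#' Derive the action set of a reaction rule
#'
#' Compares reactant and product sides (after [correspond()]) and emits the
#' rule's actions in a deterministic order: bond deletions, state changes,
#' bond additions, molecule deletions, molecule creations. Each bond
#' addition is flagged intramolecular when both endpoints lie in the same
#' reactant species pattern (the molecules are already co-complexed).
#' Catalysts are mapped molecules none of whose sites is touched by any
#' action.
#'
#' Wildcard bond marks (`!+`, `!?`) are context, never action endpoints: a
#' site whose mark changes between wildcard classes across the two sides
#' (e.g. `!+` on one side, an explicit index or unbound on the other) admits
#' no single action and raises an inconsistency error.
#'
#' @param rule A [reaction_rule()].
#' @return An `action_set`: list with `actions` (list of actions),
#'   `correspondence` (the [correspond()] result), `catalysts` (list of
#'   `(pattern, mol)` references), `reversible` flag and `rule`.
#' @export
diff_rule <- function(rule) {
  corr <- correspond(rule)
  rtab <- corr$reactant
  ptab <- corr$product

  # --- collect bonds on each side, expressed in reactant coordinates -------
  r_bonds <- list()   # key -> list(a, b)
  for (pi in seq_along(rule$reactants)) {
    bd <- pattern_bonds(rule$reactants[[pi]])
    for (k in seq_len(nrow(bd))) {
      a <- site_ref(pi, bd$mol_a[k], bd$site_a[k])
      b <- site_ref(pi, bd$mol_b[k], bd$site_b[k])
      r_bonds[[bond_key(a, b)]] <- list(a = a, b = b)
    }
  }

  # map a product (pattern, mol, site) to reactant coordinates, or a created ref
  created_idx <- which(ptab$created)
  map_end <- function(pi, mi, si) {
    fl <- flat_index(ptab, pi, mi)
    if (ptab$created[fl]) {
      return(site_ref(NA, NA, si, created = match(fl, created_idx)))
    }
    rfl <- ptab$r_flat[fl]
    r_mp <- rule$reactants[[rtab$pattern[rfl]]]$molecules[[rtab$mol[rfl]]]
    p_mp <- rule$products[[pi]]$molecules[[mi]]
    smap <- match_sites(r_mp, p_mp)
    if (is.na(smap[si])) {
      stop_bngl("bngl_reference_error",
                "site '%s' of product molecule '%s' has no counterpart among the reactant's written sites",
                p_mp$sites[[si]]$name, p_mp$name)
    }
    site_ref(rtab$pattern[rfl], rtab$mol[rfl], smap[si])
  }

  p_bonds <- list()
  for (pi in seq_along(rule$products)) {
    bd <- pattern_bonds(rule$products[[pi]])
    for (k in seq_len(nrow(bd))) {
      a <- map_end(pi, bd$mol_a[k], bd$site_a[k])
      b <- map_end(pi, bd$mol_b[k], bd$site_b[k])
      p_bonds[[bond_key(a, b)]] <- list(a = a, b = b)
    }
  }

  # --- per mapped molecule: wildcard consistency + state changes -----------
  state_changes <- list()
  for (fl in seq_len(nrow(ptab))) {
    if (ptab$created[fl]) next
    rfl <- ptab$r_flat[fl]
    r_mp <- rule$reactants[[rtab$pattern[rfl]]]$molecules[[rtab$mol[rfl]]]
    p_mp <- rule$products[[ptab$pattern[fl]]]$molecules[[ptab$mol[fl]]]
    smap <- match_sites(r_mp, p_mp)
    for (si in seq_along(p_mp$sites)) {
      if (is.na(smap[si])) {
        stop_bngl("bngl_reference_error",
                  "site '%s' of product molecule '%s' has no counterpart among the reactant's written sites",
                  p_mp$sites[[si]]$name, p_mp$name)
      }
      r_sp <- r_mp$sites[[smap[si]]]
      p_sp <- p_mp$sites[[si]]
      # wildcard classes must agree between the sides
      wild <- c("bonded-any", "unspecified")
      rv <- r_sp$bond$variant; pv <- p_sp$bond$variant
      if ((rv %in% wild || pv %in% wild) && rv != pv) {
        stop_bngl("bngl_inconsistency_error",
                  "bond mark of site '%s' on '%s' changes between wildcard classes ('%s' vs '%s'); no single action expresses this",
                  r_sp$name, r_mp$name, rv, pv)
      }
      rs <- r_sp$state; ps <- p_sp$state
      if (is.na(rs) != is.na(ps)) {
        stop_bngl("bngl_inconsistency_error",
                  "state of site '%s' on '%s' is written on only one side of the rule",
                  r_sp$name, r_mp$name)
      }
      if (!is.na(rs) && !is.na(ps) && rs != ps) {
        state_changes[[length(state_changes) + 1L]] <-
          action("state-change",
                 s = site_ref(rtab$pattern[rfl], rtab$mol[rfl], smap[si]),
                 from = rs, to = ps)
      }
    }
  }

  # --- bond set differences ------------------------------------------------
  add_keys <- setdiff(names(p_bonds), names(r_bonds))
  del_keys <- setdiff(names(r_bonds), names(p_bonds))
  adds <- unname(lapply(p_bonds[add_keys], function(bd) {
    intra <- !is.na(bd$a$pattern) && !is.na(bd$b$pattern) &&
      bd$a$pattern == bd$b$pattern
    action("add-bond", a = bd$a, b = bd$b, intramolecular = intra)
  }))
  # which product pattern each surviving reactant molecule landed in: a
  # severed pair written dot-joined on the product side stays one complex
  # (connected through unwritten context), a "+"-separated pair splits
  prod_pattern_of <- rep(NA_integer_, nrow(rtab))
  for (fl in seq_len(nrow(ptab))) {
    if (!ptab$created[fl]) prod_pattern_of[ptab$r_flat[fl]] <- ptab$pattern[fl]
  }
  dels <- unname(lapply(r_bonds[del_keys], function(bd) {
    fa <- flat_index(rtab, bd$a$pattern, bd$a$mol)
    fb <- flat_index(rtab, bd$b$pattern, bd$b$mol)
    pa <- prod_pattern_of[fa]; pb <- prod_pattern_of[fb]
    split <- is.na(pa) || is.na(pb) || pa != pb
    action("delete-bond", a = bd$a, b = bd$b, split = split)
  }))

  # --- creations / deletions ----------------------------------------------
  deletions <- list()
  for (rfl in which(rtab$deleted)) {
    deletions[[length(deletions) + 1L]] <-
      action("delete-molecule", pattern = rtab$pattern[rfl], mol = rtab$mol[rfl])
  }
  creations <- list()
  for (fl in created_idx) {
    creations[[length(creations) + 1L]] <-
      action("create-molecule",
             molecule = rule$products[[ptab$pattern[fl]]]$molecules[[ptab$mol[fl]]])
  }

  ord_ref <- function(a) sprintf("%03d.%03d.%03d",
                                 ifelse(is.na(a$pattern), 999L, a$pattern),
                                 ifelse(is.na(a$mol), 999L, a$mol), a$site)
  sort_by_ref <- function(acts, get) acts[order(vapply(acts, get, character(1)))]
  dels <- sort_by_ref(dels, function(x) ord_ref(x$a))
  adds <- sort_by_ref(adds, function(x) ord_ref(x$a))
  state_changes <- sort_by_ref(state_changes, function(x) ord_ref(x$s))

  actions <- c(dels, state_changes, adds, deletions, creations)

  # --- catalysts: mapped molecules untouched by any action -----------------
  touched <- character(0)
  touch <- function(ref) {
    if (is.na(ref$created)) sprintf("%d.%d", ref$pattern, ref$mol) else NA_character_
  }
  for (a in actions) {
    keys <- switch(a$kind,
      "add-bond"        = c(touch(a$a), touch(a$b)),
      "delete-bond"     = c(touch(a$a), touch(a$b)),
      "state-change"    = touch(a$s),
      "delete-molecule" = sprintf("%d.%d", a$pattern, a$mol),
      "create-molecule" = NA_character_)
    touched <- c(touched, keys[!is.na(keys)])
  }
  catalysts <- list()
  for (rfl in which(rtab$matched)) {
    key <- sprintf("%d.%d", rtab$pattern[rfl], rtab$mol[rfl])
    if (!(key %in% touched)) {
      catalysts[[length(catalysts) + 1L]] <-
        list(pattern = rtab$pattern[rfl], mol = rtab$mol[rfl],
             name = rtab$name[rfl])
    }
  }
  # a rule with no actions at all transforms nothing: no catalysts either
  if (!length(actions)) catalysts <- list()

  structure(list(actions = actions, correspondence = corr,
                 catalysts = catalysts, reversible = rule$reversible,
                 rule = rule),
            class = "action_set")
}

#' @export
print.action_set <- function(x, ...) {
  cat(action_text(x), sep = "\n")
  invisible(x)
}

#' Render an action set in a line-per-action text notation
#'
#' A compact, NFsim-flavoured notation useful for debugging and for
#' comparing against generator ground truth: one line per action, endpoints
#' written `pattern.Molecule.site`, followed by `Catalyst(...)` lines.
#'
#' @param x An `action_set` from [diff_rule()].
#' @return Character vector of lines (possibly empty).
#' @export
action_text <- function(x) {
  stopifnot(inherits(x, "action_set"))
  rule <- x$rule
  lines <- vapply(x$actions, function(a) {
    switch(a$kind,
      "delete-bond" = sprintf("DeleteBond(%s, %s)",
                              fmt_ref(a$a, rule), fmt_ref(a$b, rule)),
      "state-change" = sprintf("StateChange(%s, %s, %s)",
                               fmt_ref(a$s, rule), a$from, a$to),
      "add-bond" = sprintf("AddBond(%s, %s)%s",
                           fmt_ref(a$a, rule),
                           if (is.na(a$b$created)) fmt_ref(a$b, rule)
                           else sprintf("new%d.%d", a$b$created, a$b$site),
                           if (isTRUE(a$intramolecular)) " intra" else ""),
      "delete-molecule" = sprintf("DeleteMolecule(%d.%s)", a$pattern,
                                  rule$reactants[[a$pattern]]$molecules[[a$mol]]$name),
      "create-molecule" = sprintf("CreateMolecule(%s)",
                                  bngl_serialize(a$molecule)))
  }, character(1))
  cats <- vapply(x$catalysts, function(cc) {
    sprintf("Catalyst(%d.%s)", cc$pattern, cc$name)
  }, character(1))
  c(lines, cats)
}

# is a species pattern connected when only explicit bonds count as edges?
bond_connected <- function(p) {
  n <- length(p$molecules)
  if (n <= 1L) return(TRUE)
  bd <- pattern_bonds(p)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(bd))) {
    adj[[bd$mol_a[k]]] <- c(adj[[bd$mol_a[k]]], bd$mol_b[k])
    adj[[bd$mol_b[k]]] <- c(adj[[bd$mol_b[k]]], bd$mol_a[k])
  }
  seen <- rep(FALSE, n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[1L]; stack <- stack[-1L]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}

#' Apply an action set to reactant patterns
#'
#' Rewrites the reactant patterns by the actions of `actions`, serving as
#' the verification oracle for [diff_rule()]:
#' `apply_actions(rule$reactants, diff_rule(rule))` must be graph-isomorphic
#' to `rule$products` (see [patterns_isomorphic()]).
#'
#' Grouping of the result into species patterns follows complex membership:
#' a bond addition across two patterns merges them; after bond deletions a
#' pattern is re-split into its bond-connected components only when its
#' connectivity was entirely carried by explicit bonds (a dot-joined context
#' complex stays together, since the unwritten connecting chain persists).
#'
#' @param reactants List of [species_pattern()] objects.
#' @param actions An `action_set` derived from these reactants.
#' @return List of rewritten [species_pattern()] objects.
#' @export
apply_actions <- function(reactants, actions) {
  stopifnot(inherits(actions, "action_set"))

  # working state: one record per molecule, global uid
  mols <- list()
  uid_of <- function(pattern, mol) {
    for (u in seq_along(mols)) {
      m <- mols[[u]]
      if (!m$alive) next
      if (!is.na(m$pattern) && m$pattern == pattern && m$mol == mol) return(u)
    }
    stop("action references a molecule that is not present (was it deleted?)",
         call. = FALSE)
  }
  for (pi in seq_along(reactants)) {
    ctx_complex <- !bond_connected(reactants[[pi]])
    for (mi in seq_along(reactants[[pi]]$molecules)) {
      mols[[length(mols) + 1L]] <-
        list(pattern = pi, mol = mi, mp = reactants[[pi]]$molecules[[mi]],
             alive = TRUE, ctx = if (ctx_complex) pi else NA_integer_)
    }
  }
  # bonds as pairs of (uid, site)
  bonds <- list()
  for (pi in seq_along(reactants)) {
    bd <- pattern_bonds(reactants[[pi]])
    for (k in seq_len(nrow(bd))) {
      bonds[[length(bonds) + 1L]] <-
        list(a = c(uid_of(pi, bd$mol_a[k]), bd$site_a[k]),
             b = c(uid_of(pi, bd$mol_b[k]), bd$site_b[k]))
    }
  }

  resolve <- function(ref) {
    if (!is.na(ref$created)) {
      u <- created_uids[ref$created]
      return(c(u, ref$site))
    }
    c(uid_of(ref$pattern, ref$mol), ref$site)
  }
  bond_at <- function(end) {
    for (k in seq_along(bonds)) {
      if (identical(bonds[[k]]$a, end) || identical(bonds[[k]]$b, end)) return(k)
    }
    NA_integer_
  }

  created_uids <- integer(0)
  keep_pairs <- list()
  for (a in actions$actions) {
    if (a$kind == "create-molecule") {
      mols[[length(mols) + 1L]] <-
        list(pattern = NA_integer_, mol = NA_integer_, mp = a$molecule,
             alive = TRUE, ctx = NA_integer_)
      created_uids <- c(created_uids, length(mols))
    }
  }

  for (a in actions$actions) {
    if (a$kind == "delete-bond") {
      ea <- resolve(a$a); eb <- resolve(a$b)
      hit <- NA_integer_
      for (k2 in seq_along(bonds)) {
        pr <- bonds[[k2]]
        if ((identical(pr$a, ea) && identical(pr$b, eb)) ||
            (identical(pr$a, eb) && identical(pr$b, ea))) { hit <- k2; break }
      }
      if (is.na(hit)) stop("DeleteBond: endpoints share no bond in the reactants",
                           call. = FALSE)
      bonds[[hit]] <- NULL
      if (!isTRUE(a$split)) {
        # severed but still co-complexed (product side keeps them dot-joined)
        keep_pairs[[length(keep_pairs) + 1L]] <- c(ea[1], eb[1])
      }
      mols[[ea[1]]]$mp$sites[[ea[2]]]$bond <- bond_mark("unbound")
      mols[[eb[1]]]$mp$sites[[eb[2]]]$bond <- bond_mark("unbound")
    } else if (a$kind == "state-change") {
      e <- resolve(a$s)
      cur <- mols[[e[1]]]$mp$sites[[e[2]]]$state
      if (is.na(cur) || cur != a$from) {
        stop(sprintf("StateChange: site is in state '%s', expected '%s'",
                     as.character(cur), a$from), call. = FALSE)
      }
      mols[[e[1]]]$mp$sites[[e[2]]]$state <- a$to
    } else if (a$kind == "add-bond") {
      ea <- resolve(a$a); eb <- resolve(a$b)
      for (e in list(ea, eb)) {
        v <- mols[[e[1]]]$mp$sites[[e[2]]]$bond$variant
        if (v == "bonded" && !is.na(bond_at(e))) {
          stop("AddBond onto an already-bonded endpoint", call. = FALSE)
        }
      }
      bonds[[length(bonds) + 1L]] <- list(a = ea, b = eb)
      mols[[ea[1]]]$mp$sites[[ea[2]]]$bond <- bond_mark("bonded", 1L)  # renumbered later
      mols[[eb[1]]]$mp$sites[[eb[2]]]$bond <- bond_mark("bonded", 1L)
    } else if (a$kind == "delete-molecule") {
      u <- uid_of(a$pattern, a$mol)
      for (pr in bonds) {
        if (pr$a[1] == u || pr$b[1] == u) {
          stop("deleted molecule still holds an explicit bond; the rule must sever it first",
               call. = FALSE)
        }
      }
      mols[[u]]$alive <- FALSE
    }
  }

  # ---- regroup into species patterns --------------------------------------
  alive <- which(vapply(mols, `[[`, logical(1), "alive"))
  parent <- seq_along(mols)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union2 <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry)
  }
  for (pr in bonds) union2(pr$a[1], pr$b[1])
  for (kp in keep_pairs) union2(kp[1], kp[2])
  # dot-context complexes whose connectivity was never fully explicit stay joined
  for (pi in unique(stats::na.omit(vapply(mols, `[[`, integer(1), "ctx")))) {
    grp <- alive[vapply(mols[alive], function(m) !is.na(m$ctx) && m$ctx == pi,
                        logical(1))]
    if (length(grp) > 1L) for (k in seq_along(grp)[-1]) union2(grp[1], grp[k])
  }
  roots <- vapply(alive, find, integer(1))
  groups <- split(alive, roots)
  groups <- groups[order(vapply(groups, min, integer(1)))]

  # renumber bonds per group and emit patterns
  out <- list()
  for (g in groups) {
    g <- sort(g)
    mp_list <- lapply(mols[g], `[[`, "mp")
    # clear any stale numeric marks, re-assign from the bond list
    for (k in seq_along(mp_list)) {
      for (si in seq_along(mp_list[[k]]$sites)) {
        if (mp_list[[k]]$sites[[si]]$bond$variant == "bonded") {
          mp_list[[k]]$sites[[si]]$bond <- bond_mark("unbound")
        }
      }
    }
    next_id <- 1L
    for (pr in bonds) {
      ia <- match(pr$a[1], g); ib <- match(pr$b[1], g)
      if (is.na(ia) || is.na(ib)) next
      mp_list[[ia]]$sites[[pr$a[2]]]$bond <- bond_mark("bonded", next_id)
      mp_list[[ib]]$sites[[pr$b[2]]]$bond <- bond_mark("bonded", next_id)
      next_id <- next_id + 1L
    }
    out[[length(out) + 1L]] <- species_pattern(mp_list)
  }
  out
}

#' Check bonded degradation is explicitly severed
#'
#' A rule that deletes a molecule explicitly bonded to a surviving molecule
#' must also sever that bond, otherwise the surviving complex would retain a
#' dangling reference. Emits one diagnostic per offending deletion.
#'
#' @param actions An `action_set` from [diff_rule()].
#' @return Character vector of diagnostic messages (empty when clean).
#' @export
validate_degradation <- function(actions) {
  stopifnot(inherits(actions, "action_set"))
  rule <- actions$rule
  del_bond_keys <- character(0)
  deleted <- list()
  for (a in actions$actions) {
    if (a$kind == "delete-bond") del_bond_keys <- c(del_bond_keys, bond_key(a$a, a$b))
    if (a$kind == "delete-molecule") deleted[[length(deleted) + 1L]] <- a
  }
  if (!length(deleted)) return(character(0))
  del_mol_keys <- vapply(deleted, function(a) sprintf("%d.%d", a$pattern, a$mol),
                         character(1))
  diags <- character(0)
  for (a in deleted) {
    p <- rule$reactants[[a$pattern]]
    bd <- pattern_bonds(p)
    for (k in seq_len(nrow(bd))) {
      ends <- list(site_ref(a$pattern, bd$mol_a[k], bd$site_a[k]),
                   site_ref(a$pattern, bd$mol_b[k], bd$site_b[k]))
      mine <- vapply(ends, function(e) e$mol == a$mol, logical(1))
      if (!any(mine)) next
      other <- ends[[which(!mine)[1]]]
      other_key <- sprintf("%d.%d", other$pattern, other$mol)
      if (other_key %in% del_mol_keys) next  # both ends degrade together
      if (!(bond_key(ends[[1]], ends[[2]]) %in% del_bond_keys)) {
        diags <- c(diags, sprintf(
          "degraded molecule '%s' (pattern %d) holds bond %d to surviving molecule '%s' with no matching bond deletion",
          p$molecules[[a$mol]]$name, a$pattern, bd$index[k],
          p$molecules[[other$mol]]$name))
      }
    }
  }
  diags
}

#' Reverse an action set
#'
#' The action set of the reverse direction of a rule: bond additions and
#' deletions swap, state changes swap from/to, creations and deletions swap.
#' Derived on demand, never stored.
#'
#' @param actions An `action_set`.
#' @return A plain list of reversed actions (endpoint references still
#'   address the forward rule's reactant side).
#' @export
reverse_actions <- function(actions) {
  stopifnot(inherits(actions, "action_set"))
  lapply(actions$actions, function(a) {
    switch(a$kind,
      "add-bond"        = action("delete-bond", a = a$a, b = a$b,
                                 split = !isTRUE(a$intramolecular)),
      "delete-bond"     = action("add-bond", a = a$a, b = a$b,
                                 intramolecular = !isTRUE(a$split)),
      "state-change"    = action("state-change", s = a$s, from = a$to, to = a$from),
      "delete-molecule" = action("create-molecule",
        molecule = actions$rule$reactants[[a$pattern]]$molecules[[a$mol]]),
      "create-molecule" = action("delete-molecule", molecule = a$molecule))
  })
}

# ---- graph isomorphism (brute force, small patterns) -----------------------

mol_signature <- function(mp) {
  paste(mp$name,
        paste(vapply(seq_along(mp$sites), function(si) {
          sp <- mp$sites[[si]]
          v <- sp$bond$variant
          paste0(sp$name, "~", sp$state, "!", if (v == "bonded") "b" else v)
        }, character(1)), collapse = ","))
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

single_iso <- function(a, b) {
  na <- length(a$molecules); nb <- length(b$molecules)
  if (na != nb) return(FALSE)
  siga <- vapply(a$molecules, mol_signature, character(1))
  sigb <- vapply(b$molecules, mol_signature, character(1))
  if (!identical(sort(siga), sort(sigb))) return(FALSE)
  bd_a <- pattern_bonds(a); bd_b <- pattern_bonds(b)
  if (nrow(bd_a) != nrow(bd_b)) return(FALSE)
  keyset <- function(bd, perm) {
    # perm maps a-molecule index -> b-molecule index; for b use identity
    sort(vapply(seq_len(nrow(bd)), function(k) {
      ea <- sprintf("%d.%d", perm[bd$mol_a[k]], bd$site_a[k])
      eb <- sprintf("%d.%d", perm[bd$mol_b[k]], bd$site_b[k])
      paste(sort(c(ea, eb)), collapse = "|")
    }, character(1)))
  }
  target <- keyset(bd_b, seq_len(nb))
  for (perm in all_permutations(na)) {
    perm <- unlist(perm)
    if (!all(siga == sigb[perm])) next
    # perm sends a-position i to b-position perm[i]
    if (identical(keyset(bd_a, perm), target)) return(TRUE)
  }
  FALSE
}

#' Graph isomorphism between lists of species patterns
#'
#' Two pattern lists are isomorphic when they can be matched one-to-one such
#' that matched patterns agree up to a permutation of molecules preserving
#' molecule names, per-site states and bond marks, and the bond topology.
#' Brute force over molecule permutations; intended for the small patterns
#' that occur in rules (a handful of molecules).
#'
#' @param a,b Lists of [species_pattern()] objects (or single patterns).
#' @return `TRUE` or `FALSE`.
#' @export
patterns_isomorphic <- function(a, b) {
  if (inherits(a, "species_pattern")) a <- list(a)
  if (inherits(b, "species_pattern")) b <- list(b)
  if (length(a) != length(b)) return(FALSE)
  if (!length(a)) return(TRUE)
  used <- rep(FALSE, length(b))
  match_rec <- function(i) {
    if (i > length(a)) return(TRUE)
    for (j in seq_along(b)) {
      if (used[j]) next
      if (single_iso(a[[i]], b[[j]])) {
        used[j] <<- TRUE
        if (match_rec(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  match_rec(1L)
}
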