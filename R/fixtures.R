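#' @title Synthetic model generation
#' @description A seeded generator of syntactically valid BNGL models whose
#'   reaction rules are constructed action-first: an action is sampled, then
#'   a consistent reactant/product pair is written around it, so the
#'   ground-truth action set of every rule is known at construction time and
#'   emitted alongside the model as a manifest. This makes the whole
#'   pipeline testable without any external model files.
#' @name fixtures
NULL

#' Specification of a synthetic model
#'
#' @param n_molecule_types Number of molecule types to declare.
#' @param max_sites Maximum sites per molecule (each type gets 1..max).
#' @param max_states Maximum states per state-bearing site (0 = stateless;
#'   sites draw 0, 2, .. up to `max_states` states).
#' @param n_rules Number of reaction rules.
#' @param action_mix Non-negative sampling weights over the action kinds
#'   `add-bond`, `delete-bond`, `state-change`, `create`, `delete`; not all
#'   zero.
#' @param seed Integer seed; the generator is reproducible from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecule_types = 3L, max_sites = 3L, max_states = 2L,
                         n_rules = 4L,
                         action_mix = c(`add-bond` = 3, `delete-bond` = 2,
                                        `state-change` = 3, create = 1, delete = 1),
                         seed = 1L) {
  stopifnot(n_molecule_types >= 1L, max_sites >= 1L, n_rules >= 0L,
            all(action_mix >= 0), any(action_mix > 0))
  kinds <- c("add-bond", "delete-bond", "state-change", "create", "delete")
  mix <- stats::setNames(rep(0, length(kinds)), kinds)
  mix[names(action_mix)] <- action_mix
  structure(list(n_molecule_types = as.integer(n_molecule_types),
                 max_sites = as.integer(max_sites),
                 max_states = as.integer(max_states),
                 n_rules = as.integer(n_rules),
                 action_mix = mix, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic BNGL model with ground-truth actions
#'
#' @param spec A [fixture_spec()].
#' @return A list with elements `text` (character vector of BNGL lines),
#'   `model` (the parsed [bngl_model()]) and `manifest` (per rule, the
#'   construction-time action list in [action_text()] notation).
#' @examples
#' fx <- generate_fixture(fixture_spec(seed = 7))
#' identical(fx$text, generate_fixture(fixture_spec(seed = 7))$text)
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  state_pool <- c("u", "p", "a", "b", "c", "d")
  types <- list()
  for (k in seq_len(spec$n_molecule_types)) {
    nm <- sprintf("M%d", k)
    n_sites <- sample.int(spec$max_sites, 1L)
    sites <- lapply(seq_len(n_sites), function(si) {
      n_states <- if (spec$max_states >= 2L) sample(c(0L, seq(2L, spec$max_states)), 1L)
                  else 0L
      site_def(letters[si], states = state_pool[seq_len(n_states)])
    })
    types[[k]] <- molecule_type_def(nm, sites)
  }
  ctx <- types

  # helper: a fully unconstrained written form of a molecule (all sites,
  # multi-state sites pinned to a sampled state so the rule is well-formed)
  write_mol <- function(mt, pin_states = TRUE) {
    sites <- lapply(mt$sites, function(sd) {
      st <- if (length(sd$states) && pin_states) sample(sd$states, 1L) else NA_character_
      site_pattern(sd$name, state = st)
    })
    molecule_pattern(mt$name, sites)
  }

  kinds <- names(spec$action_mix)
  wts <- spec$action_mix
  rules <- list()
  manifest <- list()
  for (rk in seq_len(spec$n_rules)) {
    kind <- sample(kinds, 1L, prob = wts)
    label <- sprintf("rule%d", rk)
    if (kind == "add-bond") {
      ta <- sample(seq_along(types), 1L)
      tb <- sample(seq_along(types), 1L)
      sa <- sample(seq_along(types[[ta]]$sites), 1L)
      sb <- sample(seq_along(types[[tb]]$sites), 1L)
      ma <- write_mol(types[[ta]]); mb <- write_mol(types[[tb]])
      pa <- ma; pb <- mb
      pa$sites[[sa]]$bond <- bond_mark("bonded", 1L)
      pb$sites[[sb]]$bond <- bond_mark("bonded", 1L)
      rev <- stats::runif(1) < 0.3
      rule <- reaction_rule(list(species_pattern(list(ma)), species_pattern(list(mb))),
                            list(species_pattern(list(pa, pb))),
                            reversible = rev,
                            rate_text = if (rev) c("kf", "kr") else "kf",
                            label = label)
      manifest[[label]] <- sprintf("AddBond(1.%s.%s, 2.%s.%s)",
                                   ma$name, ma$sites[[sa]]$name,
                                   mb$name, mb$sites[[sb]]$name)
    } else if (kind == "delete-bond") {
      ta <- sample(seq_along(types), 1L)
      tb <- sample(seq_along(types), 1L)
      sa <- sample(seq_along(types[[ta]]$sites), 1L)
      sb <- sample(seq_along(types[[tb]]$sites), 1L)
      ma <- write_mol(types[[ta]]); mb <- write_mol(types[[tb]])
      ra <- ma; rb <- mb
      ra$sites[[sa]]$bond <- bond_mark("bonded", 1L)
      rb$sites[[sb]]$bond <- bond_mark("bonded", 1L)
      rule <- reaction_rule(list(species_pattern(list(ra, rb))),
                            list(species_pattern(list(ma)), species_pattern(list(mb))),
                            reversible = FALSE, rate_text = "kd", label = label)
      manifest[[label]] <- sprintf("DeleteBond(1.%s.%s, 1.%s.%s)",
                                   ra$name, ra$sites[[sa]]$name,
                                   rb$name, rb$sites[[sb]]$name)
    } else if (kind == "state-change") {
      cand <- which(vapply(types, function(mt) {
        any(vapply(mt$sites, function(s) length(s$states) >= 2L, logical(1)))
      }, logical(1)))
      if (!length(cand)) { wts["state-change"] <- 0; next }
      ta <- if (length(cand) == 1L) cand else sample(cand, 1L)
      scand <- which(vapply(types[[ta]]$sites, function(s) length(s$states) >= 2L,
                            logical(1)))
      sa <- if (length(scand) == 1L) scand else sample(scand, 1L)
      states <- types[[ta]]$sites[[sa]]$states
      fromto <- sample(states, 2L)
      ma <- write_mol(types[[ta]])
      ma$sites[[sa]]$state <- fromto[1]
      pa <- ma
      pa$sites[[sa]]$state <- fromto[2]
      reactants <- list(species_pattern(list(ma)))
      products <- list(species_pattern(list(pa)))
      lines <- sprintf("StateChange(1.%s.%s, %s, %s)",
                       ma$name, ma$sites[[sa]]$name, fromto[1], fromto[2])
      if (stats::runif(1) < 0.5) {   # catalyzed variant, enzyme unchanged
        tcat <- sample(seq_along(types), 1L)
        mc <- write_mol(types[[tcat]])
        reactants <- c(reactants, list(species_pattern(list(mc))))
        products <- c(products, list(species_pattern(list(mc))))
        lines <- c(lines, sprintf("Catalyst(2.%s)", mc$name))
      }
      rule <- reaction_rule(reactants, products, reversible = FALSE,
                            rate_text = "kc", label = label)
      manifest[[label]] <- lines
    } else if (kind == "create") {
      ta <- sample(seq_along(types), 1L)
      ma <- write_mol(types[[ta]])
      rule <- reaction_rule(list(), list(species_pattern(list(ma))),
                            reversible = FALSE, rate_text = "ks", label = label)
      manifest[[label]] <- sprintf("CreateMolecule(%s)", bngl_serialize(ma))
    } else { # delete
      ta <- sample(seq_along(types), 1L)
      ma <- write_mol(types[[ta]])
      rule <- reaction_rule(list(species_pattern(list(ma))), list(),
                            reversible = FALSE, rate_text = "kx", label = label)
      manifest[[label]] <- sprintf("DeleteMolecule(1.%s)", ma$name)
    }
    rules[[length(rules) + 1L]] <- rule
  }

  # one seed species and one observable per first two types, for coverage
  species <- lapply(seq_len(min(2L, length(types))), function(k) {
    mt <- types[[k]]
    p <- species_pattern(list(write_mol(mt)))
    list(pattern = p, initial_text = as.character(sample.int(100L, 1L)),
         line = NA_integer_)
  })
  observables <- lapply(seq_len(min(2L, length(types))), function(k) {
    observable(sprintf("obs_%s", types[[k]]$name), "Molecules",
               list(species_pattern(list(molecule_pattern(types[[k]]$name)))))
  })

  model <- bngl_model(molecule_types = types, species = species,
                      observables = observables, rules = rules)
  text <- strsplit(bngl_serialize(model), "\n", fixed = TRUE)[[1]]
  list(text = text, model = model, manifest = manifest)
}
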