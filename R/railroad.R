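#' @title Railroad diagram algebra
#' @description A railroad (syntax) diagram depicts a formal grammar as a
#'   flowchart in which every left-to-right path spells a valid word. The
#'   algebra here is the classical one — terminal, sequence, choice,
#'   optional, skip — extended with the constructs the rule diagrams need:
#'   dashed annotations, action boxes, group boxes and port marks for
#'   cross-lane links.
#' @name railroad
NULL

rr_node <- function(variant, ...) {
  structure(c(list(variant = variant), list(...)),
            class = c(paste0("rr_", variant), "rr_node"))
}

#' Railroad node constructors
#'
#' @description
#' * `rr_terminal(label)` — a boxed token on the path.
#' * `rr_seq(...)` — children traversed left to right.
#' * `rr_choice(...)` — exactly one child traversed; children in given order.
#' * `rr_optional(child)` — sugar for `rr_choice(child, rr_skip())`.
#' * `rr_skip()` — the empty traversal.
#' * `rr_annotation(label)` — dashed label on the path; contributes nothing
#'   to the enumerated words.
#' * `rr_action_box(kind, reversible, label)` — an action marker
#'   (`"add-bond"`, `"delete-bond"`, `"state-change"`); contributes nothing
#'   to words.
#' * `rr_group_box(child, label, role)` — dashed enclosure marking a lane as
#'   `"synthesized"` or `"degraded"`.
#' * `rr_port(id)` — invisible anchor that cross-lane links attach to; ids
#'   must be unique within a diagram.
#'
#' @param label Display text.
#' @param ... Child nodes.
#' @param child A single child node.
#' @param kind Action kind: `"add-bond"`, `"delete-bond"` or
#'   `"state-change"`.
#' @param reversible Draw the paired forward/backward glyph.
#' @param role `"synthesized"` or `"degraded"`.
#' @param id Port identifier (character scalar).
#' @return An `rr_node`.
#' @name rr-nodes
NULL

#' @rdname rr-nodes
#' @export
rr_terminal <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  rr_node("terminal", label = label)
}

#' @rdname rr-nodes
#' @export
rr_seq <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "rr_node")) {
    children <- children[[1]]
  }
  stopifnot(length(children) >= 1L)
  rr_node("seq", children = children)
}

#' @rdname rr-nodes
#' @export
rr_choice <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "rr_node")) {
    children <- children[[1]]
  }
  stopifnot(length(children) >= 1L)
  rr_node("choice", children = children)
}

#' @rdname rr-nodes
#' @export
rr_optional <- function(child) rr_choice(child, rr_skip())

#' @rdname rr-nodes
#' @export
rr_skip <- function() rr_node("skip")

#' @rdname rr-nodes
#' @export
rr_annotation <- function(label) rr_node("annotation", label = label)

#' @rdname rr-nodes
#' @export
rr_action_box <- function(kind = c("add-bond", "delete-bond", "state-change"),
                          reversible = FALSE, label = "") {
  kind <- match.arg(kind)
  rr_node("action_box", kind = kind, reversible = isTRUE(reversible),
          label = label)
}

#' @rdname rr-nodes
#' @export
rr_group_box <- function(child, label, role = c("synthesized", "degraded")) {
  role <- match.arg(role)
  rr_node("group_box", child = child, label = label, role = role)
}

#' @rdname rr-nodes
#' @export
rr_port <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  rr_node("port", id = id)
}

#' A cross-lane link
#'
#' Connects two ports across (or within) lanes. `solid-bond` draws the
#' smooth solid connection used for explicit bonds; `dashed-complex` draws
#' the dashed co-complex line. One-ended stubs (`b = NA`) mark required
#' (`required-stub`) or optional (`optional-stub`, grey with a question
#' mark) connectivity of a single site.
#'
#' @param a,b Port ids (`b` may be `NA` for a stub).
#' @param style `"solid-bond"`, `"dashed-complex"`, `"required-stub"` or
#'   `"optional-stub"`.
#' @param action Optional [rr_action_box()] spliced into the link path.
#' @param label Optional text drawn at the link midpoint (e.g. the canonical
#'   bond index).
#' @return An `rr_link` object.
#' @export
rr_link <- function(a, b = NA_character_,
                    style = c("solid-bond", "dashed-complex",
                              "required-stub", "optional-stub"),
                    action = NULL, label = NA_character_) {
  style <- match.arg(style)
  if (!is.na(b) && identical(a, b)) stop("link endpoints must differ")
  structure(list(a = a, b = b, style = style, action = action, label = label),
            class = "rr_link")
}

#' A railroad diagram: lanes plus cross-lane links
#'
#' @param lanes A list of `rr_node` lane roots (one lane per molecule in the
#'   RRR conventions), or a single node.
#' @param links List of [rr_link()] objects; every endpoint must resolve to
#'   an [rr_port()] in some lane.
#' @param title Diagram title (drawn above the lanes).
#' @return An `rr_diagram`.
#' @export
rr_diagram <- function(lanes, links = list(), title = "") {
  if (inherits(lanes, "rr_node")) lanes <- list(lanes)
  stopifnot(all(vapply(lanes, inherits, logical(1), "rr_node")))
  d <- structure(list(lanes = lanes, links = links, title = title),
                 class = "rr_diagram")
  ports <- collect_ports(d)
  if (anyDuplicated(ports)) {
    stop("duplicate port ids: ", paste(unique(ports[duplicated(ports)]), collapse = ", "),
         call. = FALSE)
  }
  for (ln in links) {
    for (e in c(ln$a, if (!is.na(ln$b)) ln$b)) {
      if (!(e %in% ports)) stop("link endpoint '", e, "' matches no port", call. = FALSE)
    }
  }
  d
}

collect_ports <- function(x) {
  if (inherits(x, "rr_diagram")) {
    return(unlist(lapply(x$lanes, collect_ports)))
  }
  switch(x$variant,
    "port" = x$id,
    "seq" = ,
    "choice" = unlist(lapply(x$children, collect_ports)),
    "group_box" = collect_ports(x$child),
    character(0))
}

#' @export
print.rr_diagram <- function(x, ...) {
  cat(sprintf("railroad diagram%s: %d lane(s), %d link(s)\n",
              if (nzchar(x$title)) paste0(" '", x$title, "'") else "",
              length(x$lanes), length(x$links)))
  invisible(x)
}

# ---- word enumeration -------------------------------------------------------

#' Enumerate the words of a railroad lane
#'
#' Lists every distinct left-to-right traversal of a lane as a character
#' vector of terminal labels, lexicographic by choice order. Annotations,
#' action boxes and port marks lie on the path but contribute nothing to the
#' words. Group boxes are transparent.
#'
#' @param d An `rr_node` lane, or an `rr_diagram` with a single lane.
#' @param cap Refuse enumerations larger than this many words (default
#'   10000).
#' @return A list of character vectors (one per word; the empty word is
#'   `character(0)`).
#' @examples
#' lane <- rr_seq(rr_terminal("a"), rr_choice(rr_terminal("x"), rr_terminal("y")))
#' enumerate_words(lane)
#' @export
enumerate_words <- function(d, cap = 10000L) {
  if (inherits(d, "rr_diagram")) {
    if (length(d$lanes) != 1L) {
      stop("enumerate_words works on a single lane; this diagram has ",
           length(d$lanes), call. = FALSE)
    }
    d <- d$lanes[[1]]
  }
  n <- count_words(d)
  if (n > cap) {
    stop(sprintf("lane has %.0f words, above the cap of %d; raise `cap` to proceed",
                 n, cap), call. = FALSE)
  }
  enum_rec(d)
}

enum_rec <- function(x) {
  switch(x$variant,
    "terminal" = list(x$label),
    "skip" = ,
    "annotation" = ,
    "action_box" = ,
    "port" = list(character(0)),
    "group_box" = enum_rec(x$child),
    "choice" = do.call(c, lapply(x$children, enum_rec)),
    "seq" = {
      acc <- list(character(0))
      for (ch in x$children) {
        ws <- enum_rec(ch)
        acc <- do.call(c, lapply(acc, function(pre) {
          lapply(ws, function(w) c(pre, w))
        }))
      }
      acc
    },
    stop("unknown node variant: ", x$variant))
}

#' Count the words of a railroad lane
#'
#' Product/sum recursion over the lane structure; equals
#' `length(enumerate_words(d))` without materializing the words. For a
#' multi-lane diagram, the product over lanes.
#'
#' @param d An `rr_node` or `rr_diagram`.
#' @return A numeric count.
#' @export
count_words <- function(d) {
  if (inherits(d, "rr_diagram")) {
    return(prod(vapply(d$lanes, count_words, numeric(1))))
  }
  switch(d$variant,
    "terminal" = ,
    "skip" = ,
    "annotation" = ,
    "action_box" = ,
    "port" = 1,
    "group_box" = count_words(d$child),
    "choice" = sum(vapply(d$children, count_words, numeric(1))),
    "seq" = prod(vapply(d$children, count_words, numeric(1))),
    stop("unknown node variant: ", d$variant))
}
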