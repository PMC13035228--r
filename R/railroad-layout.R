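#' @title Deterministic railroad layout
#' @description Turns an [rr_diagram()] into a flat list of positioned
#'   primitives (boxes, text, path segments, glyphs) in abstract SVG user
#'   units: origin top-left, y increasing downward. Layout is a pure
#'   function of the diagram and the geometry constants — identical input
#'   yields identical output. Text is sized with a fixed-width metric
#'   (character count times an em factor) so the geometry never depends on
#'   installed fonts.
#' @name railroad-layout
NULL

#' Geometry constants for railroad layout
#'
#' All values are in SVG user units and purely cosmetic; they carry no
#' semantics. Defaults are proportioned for a 12px monospace-ish face.
#'
#' @param char_w Width per character of label text.
#' @param box_h Height of terminal/action boxes.
#' @param pad_x Horizontal padding inside boxes.
#' @param seq_gap Gap between consecutive elements on a rail.
#' @param arc_r Corner arc radius of choice branches.
#' @param choice_vgap Vertical gap between choice branches.
#' @param lane_gap Vertical gap between lanes.
#' @param stub Length of the entry/exit rail stubs.
#' @param group_pad Padding of dashed group boxes.
#' @param margin Outer margin.
#' @return A list of geometry constants.
#' @export
rr_geometry <- function(char_w = 7.2, box_h = 22, pad_x = 8, seq_gap = 14,
                        arc_r = 8, choice_vgap = 8, lane_gap = 46, stub = 10,
                        group_pad = 10, margin = 14) {
  list(char_w = char_w, box_h = box_h, pad_x = pad_x, seq_gap = seq_gap,
       arc_r = arc_r, choice_vgap = choice_vgap, lane_gap = lane_gap,
       stub = stub, group_pad = group_pad, margin = margin,
       font = 12, title_h = 26, group_label_h = 14, link_step = 14)
}

n2 <- function(x) {
  s <- formatC(round(x, 1), format = "f", digits = 1)
  sub("^-0\\.0$", "0.0", s)
}

prim_box <- function(x, y, w, h, class, dashed = FALSE) {
  list(kind = "box", x = x, y = y, w = w, h = h, class = class, dashed = dashed)
}
prim_text <- function(x, y, str, class) {
  list(kind = "text", x = x, y = y, str = str, class = class)
}
prim_path <- function(d, class, dashed = FALSE) {
  list(kind = "path", d = d, class = class, dashed = dashed)
}
hline <- function(x1, x2, y, class = "rr-rail") {
  prim_path(sprintf("M %s %s L %s %s", n2(x1), n2(y), n2(x2), n2(y)), class)
}

text_w <- function(s, g) max(nchar(s), 1L) * g$char_w

# arrow glyphs: all drawn as stroked paths so the semantics survive with the
# style block removed
glyph_prims <- function(kind, reversible, cx, cy) {
  arrow <- function(x, dir, class) {
    # dir +1 = down, -1 = up
    tip <- cy + dir * 6
    tail <- cy - dir * 6
    prim_path(sprintf("M %s %s L %s %s M %s %s L %s %s L %s %s",
                      n2(x), n2(tail), n2(x), n2(tip),
                      n2(x - 3), n2(tip - dir * 4), n2(x), n2(tip),
                      n2(x + 3), n2(tip - dir * 4)), class)
  }
  dbl <- function(x, class) {
    # vertical double-headed arrow (state transition)
    prim_path(sprintf(
      "M %s %s L %s %s M %s %s L %s %s L %s %s M %s %s L %s %s L %s %s",
      n2(x), n2(cy - 6), n2(x), n2(cy + 6),
      n2(x - 3), n2(cy + 2), n2(x), n2(cy + 6), n2(x + 3), n2(cy + 2),
      n2(x - 3), n2(cy - 2), n2(x), n2(cy - 6), n2(x + 3), n2(cy - 2)), class)
  }
  out <- list()
  if (kind == "add-bond") {
    out <- c(out, list(arrow(if (reversible) cx - 5 else cx, +1, "rrr-glyph-down")))
    if (reversible) out <- c(out, list(arrow(cx + 5, -1, "rrr-glyph-rev")))
  } else if (kind == "delete-bond") {
    out <- c(out, list(arrow(if (reversible) cx - 5 else cx, -1, "rrr-glyph-up")))
    if (reversible) out <- c(out, list(arrow(cx + 5, +1, "rrr-glyph-rev")))
  } else if (kind == "state-change") {
    out <- c(out, list(dbl(cx, "rrr-glyph-state")))
  }
  out
}

action_box_class <- function(kind) {
  switch(kind,
         "add-bond" = "rrr-action-add",
         "delete-bond" = "rrr-action-del",
         "state-change" = "rrr-state")
}

action_box_w <- function(node, g) {
  base <- if (node$reversible && node$kind != "state-change") 30 else 24
  if (nzchar(node$label)) base <- base + text_w(node$label, g) + 4
  base
}

# ---- measurement ------------------------------------------------------------
# Every node measures to (w, above, below) relative to its rail baseline.

rr_measure <- function(node, g) {
  hb <- g$box_h / 2
  switch(node$variant,
    "terminal" = ,
    "annotation" = list(w = text_w(node$label, g) + 2 * g$pad_x,
                        above = hb, below = hb),
    "action_box" = list(w = action_box_w(node, g), above = hb, below = hb),
    "port" = list(w = 4, above = 0, below = 0),
    "skip" = list(w = 10, above = 1, below = 1),
    "seq" = {
      ms <- lapply(node$children, rr_measure, g = g)
      list(w = sum(vapply(ms, `[[`, numeric(1), "w")) +
             g$seq_gap * (length(ms) - 1L),
           above = max(vapply(ms, `[[`, numeric(1), "above")),
           below = max(vapply(ms, `[[`, numeric(1), "below")))
    },
    "choice" = {
      ms <- lapply(node$children, rr_measure, g = g)
      wmax <- max(vapply(ms, `[[`, numeric(1), "w"))
      below <- ms[[1]]$below
      if (length(ms) > 1L) {
        for (k in 2:length(ms)) {
          below <- below + g$choice_vgap + ms[[k]]$above + ms[[k]]$below
        }
      }
      list(w = wmax + 4 * g$arc_r, above = ms[[1]]$above, below = below)
    },
    "group_box" = {
      m <- rr_measure(node$child, g)
      list(w = m$w + 2 * g$group_pad,
           above = m$above + g$group_pad + g$group_label_h,
           below = m$below + g$group_pad)
    },
    stop("unknown node variant: ", node$variant))
}

# ---- emission ---------------------------------------------------------------
# acc is an environment with $prims (list) and $ports (named list of c(x,y)).

rr_emit <- function(node, x, y, g, acc) {
  m <- rr_measure(node, g)
  hb <- g$box_h / 2
  add <- function(p) acc$prims[[length(acc$prims) + 1L]] <- p
  switch(node$variant,
    "terminal" = {
      add(prim_box(x, y - hb, m$w, g$box_h, "rr-terminal"))
      add(prim_text(x + m$w / 2, y + g$font * 0.32, node$label, "rr-text"))
    },
    "annotation" = {
      add(prim_box(x, y - hb, m$w, g$box_h, "rr-annotation", dashed = TRUE))
      add(prim_text(x + m$w / 2, y + g$font * 0.32, node$label, "rr-text rr-annotation-text"))
    },
    "action_box" = {
      add(prim_box(x, y - hb, m$w, g$box_h, action_box_class(node$kind)))
      gx <- if (nzchar(node$label)) x + 14 else x + m$w / 2
      for (p in glyph_prims(node$kind, node$reversible, gx, y)) add(p)
      if (nzchar(node$label)) {
        add(prim_text(x + 24 + (m$w - 28) / 2, y + g$font * 0.32,
                      node$label, "rr-text"))
      }
    },
    "port" = {
      acc$ports[[node$id]] <- c(x + m$w / 2, y)
      add(hline(x, x + m$w, y))
    },
    "skip" = {
      add(hline(x, x + m$w, y))
    },
    "seq" = {
      cx <- x
      for (k in seq_along(node$children)) {
        cm <- rr_measure(node$children[[k]], g)
        if (k > 1L) {
          add(hline(cx, cx + g$seq_gap, y))
          cx <- cx + g$seq_gap
        }
        rr_emit(node$children[[k]], cx, y, g, acc)
        cx <- cx + cm$w
      }
    },
    "choice" = {
      r <- g$arc_r
      ms <- lapply(node$children, rr_measure, g = g)
      wmax <- max(vapply(ms, `[[`, numeric(1), "w"))
      x_in <- x + 2 * r
      x_out <- x + 2 * r + wmax
      dy <- 0
      for (k in seq_along(node$children)) {
        if (k > 1L) dy <- dy + ms[[k - 1L]]$below + g$choice_vgap + ms[[k]]$above
        cy <- y + dy
        cx <- x_in + (wmax - ms[[k]]$w) / 2
        if (k == 1L) {
          add(hline(x, cx, y))
          add(hline(cx + ms[[k]]$w, x + m$w, y))
        } else {
          # fan out: down from entry, across, and mirrored at the exit
          add(prim_path(sprintf(
            "M %s %s A %s %s 0 0 1 %s %s L %s %s A %s %s 0 0 0 %s %s L %s %s",
            n2(x), n2(y), n2(r), n2(r), n2(x + r), n2(y + r),
            n2(x + r), n2(cy - r), n2(r), n2(r), n2(x + 2 * r), n2(cy),
            n2(cx), n2(cy)), "rr-rail"))
          add(prim_path(sprintf(
            "M %s %s L %s %s A %s %s 0 0 0 %s %s L %s %s A %s %s 0 0 1 %s %s",
            n2(cx + ms[[k]]$w), n2(cy), n2(x_out), n2(cy),
            n2(r), n2(r), n2(x_out + r), n2(cy - r),
            n2(x_out + r), n2(y + r), n2(r), n2(r), n2(x_out + 2 * r), n2(y)),
            "rr-rail"))
        }
        rr_emit(node$children[[k]], cx, cy, g, acc)
      }
    },
    "group_box" = {
      cls <- if (node$role == "synthesized") "rrr-synth" else "rrr-degrade"
      add(prim_box(x, y - m$above, m$w, m$above + m$below,
                   paste("rr-group", cls), dashed = TRUE))
      add(prim_text(x + text_w(node$label, g) / 2 + 4,
                    y - m$above + g$group_label_h - 2,
                    node$label, paste0(cls, "-label")))
      rr_emit(node$child, x + g$group_pad, y, g, acc)
      # rail in/out of the enclosure
      add(hline(x, x + g$group_pad, y))
      add(hline(x + m$w - g$group_pad, x + m$w, y))
    },
    stop("unknown node variant: ", node$variant))
  invisible(m)
}

#' Lay out a railroad diagram
#'
#' Deterministic left-to-right layout: lanes stacked vertically, choices
#' fanning out and rejoining with rounded arcs, cross-lane links routed
#' orthogonally through the gutter below the lanes they connect. Returns the
#' flat primitive list consumed by [render_svg()].
#'
#' @param d An [rr_diagram()].
#' @param g Geometry constants from [rr_geometry()].
#' @return An `rr_layout`: list with `primitives`, `ports` (named
#'   coordinates), `width`, `height`.
#' @export
rr_layout <- function(d, g = rr_geometry()) {
  stopifnot(inherits(d, "rr_diagram"))
  acc <- new.env(parent = emptyenv())
  acc$prims <- list()
  acc$ports <- list()

  y0 <- g$margin + if (nzchar(d$title)) g$title_h else 0
  lane_bottom <- numeric(length(d$lanes))
  lane_top <- numeric(length(d$lanes))
  y <- y0
  widths <- numeric(length(d$lanes))
  for (i in seq_along(d$lanes)) {
    m <- rr_measure(d$lanes[[i]], g)
    base <- y + m$above
    x <- g$margin
    acc$prims[[length(acc$prims) + 1L]] <- hline(x, x + g$stub, base)
    rr_emit(d$lanes[[i]], x + g$stub, base, g, acc)
    acc$prims[[length(acc$prims) + 1L]] <-
      hline(x + g$stub + m$w, x + 2 * g$stub + m$w, base)
    widths[i] <- 2 * g$stub + m$w + g$margin
    lane_top[i] <- y
    lane_bottom[i] <- base + m$below
    y <- lane_bottom[i] + g$lane_gap
  }
  height <- (if (length(d$lanes)) max(lane_bottom) else y0) + g$margin

  # ---- cross-lane links -----------------------------------------------------
  lane_of_port <- function(px_y) {
    # lane whose vertical extent contains the port baseline
    for (i in seq_along(d$lanes)) {
      if (px_y >= lane_top[i] - 1 && px_y <= lane_bottom[i] + 1) return(i)
    }
    1L
  }
  two_ended <- Filter(function(ln) !is.na(ln$b), d$links)
  gutter_used <- 0L
  for (ln in d$links) {
    pa <- acc$ports[[ln$a]]
    if (is.null(pa)) stop("link endpoint '", ln$a, "' was never laid out")
    if (is.na(ln$b)) {
      # one-ended connectivity stub below the port
      la <- lane_of_port(pa[2])
      ylo <- lane_bottom[la] + 6
      cls <- if (ln$style == "optional-stub") "rrr-optional-stub" else "rrr-required-stub"
      acc$prims[[length(acc$prims) + 1L]] <-
        prim_path(sprintf("M %s %s L %s %s", n2(pa[1]), n2(pa[2]),
                          n2(pa[1]), n2(ylo)),
                  cls, dashed = (ln$style == "optional-stub"))
      if (ln$style == "optional-stub") {
        acc$prims[[length(acc$prims) + 1L]] <-
          prim_text(pa[1], ylo + 11, "?", "rrr-glyph-q")
      } else {
        # solid arrowhead: the bond continues to an unspecified partner
        acc$prims[[length(acc$prims) + 1L]] <-
          prim_path(sprintf("M %s %s L %s %s L %s %s",
                            n2(pa[1] - 3), n2(ylo - 4), n2(pa[1]), n2(ylo),
                            n2(pa[1] + 3), n2(ylo - 4)), cls)
      }
      next
    }
    pb <- acc$ports[[ln$b]]
    if (is.null(pb)) stop("link endpoint '", ln$b, "' was never laid out")
    gutter_used <- gutter_used + 1L
    la <- lane_of_port(pa[2]); lb <- lane_of_port(pb[2])
    gy <- max(lane_bottom[c(la, lb)]) + 8 + g$link_step * (gutter_used - 1L)
    height <- max(height, gy + g$margin + g$box_h)
    cls <- if (ln$style == "dashed-complex") "rrr-dashed-link" else "rrr-bond"
    dashed <- ln$style == "dashed-complex"
    acc$prims[[length(acc$prims) + 1L]] <-
      prim_path(sprintf("M %s %s L %s %s L %s %s L %s %s L %s %s",
                        n2(pa[1]), n2(pa[2]), n2(pa[1]), n2(gy),
                        n2(pb[1]), n2(gy), n2(pb[1]), n2(pb[2]),
                        n2(pb[1]), n2(pb[2])), cls, dashed)
    mx <- (pa[1] + pb[1]) / 2
    if (!is.null(ln$action)) {
      node <- ln$action
      bw <- action_box_w(node, rr_geometry())
      acc$prims[[length(acc$prims) + 1L]] <-
        prim_box(mx - bw / 2, gy - g$box_h / 2, bw, g$box_h,
                 action_box_class(node$kind))
      for (p in glyph_prims(node$kind, node$reversible, mx, gy)) {
        acc$prims[[length(acc$prims) + 1L]] <- p
      }
    }
    if (!is.na(ln$label)) {
      acc$prims[[length(acc$prims) + 1L]] <-
        prim_text(mx + 24, gy - 5, ln$label, "rr-bond-label")
    }
  }

  if (nzchar(d$title)) {
    acc$prims[[length(acc$prims) + 1L]] <-
      prim_text(g$margin + text_w(d$title, g) / 2, g$margin + g$font, d$title,
                "rr-title")
  }

  structure(list(primitives = acc$prims, ports = acc$ports,
                 width = max(widths, text_w(d$title, g) + 2 * g$margin, 60),
                 height = height),
            class = "rr_layout")
}

# ---- SVG emission -----------------------------------------------------------

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub("\"", "&quot;", s, fixed = TRUE)
  s
}

#' Default style block for rendered diagrams
#'
#' Colors live only here; every semantic role is also carried by a class
#' attribute plus a non-color cue (glyph shape, dash pattern or label), so a
#' diagram stripped of this block stays fully interpretable.
#'
#' @return A character scalar of CSS rules.
#' @export
rrr_default_style <- function() {
  paste(
    "path { fill: none; stroke: #333; stroke-width: 1.4; }",
    "text { font-family: 'DejaVu Sans Mono', monospace; font-size: 12px;",
    "       text-anchor: middle; fill: #222; stroke: none; }",
    "rect { fill: #fff; stroke: #333; stroke-width: 1.2; }",
    "rect.rr-annotation { stroke: #777; }",
    "text.rr-annotation-text { fill: #555; }",
    "rect.rrr-action-add { fill: #c8e6c9; stroke: #2e7d32; }",
    "rect.rrr-action-del { fill: #ffcdd2; stroke: #c62828; }",
    "rect.rrr-state { fill: #ffe0b2; stroke: #ef6c00; }",
    "rect.rrr-synth { stroke: #2e7d32; fill: none; }",
    "rect.rrr-degrade { stroke: #c62828; fill: none; }",
    "text.rrr-synth-label { fill: #2e7d32; font-size: 10px; }",
    "text.rrr-degrade-label { fill: #c62828; font-size: 10px; }",
    "path.rrr-bond { stroke: #1565c0; }",
    "path.rrr-dashed-link { stroke: #888; }",
    "path.rrr-optional-stub { stroke: #999; }",
    "text.rrr-glyph-q { fill: #999; font-weight: bold; }",
    "text.rr-title { font-weight: bold; font-size: 14px; }",
    "text.rr-bond-label { font-size: 10px; fill: #1565c0; }",
    sep = "\n")
}

#' Render a laid-out diagram to standalone SVG
#'
#' Emits well-formed SVG 1.1. Dash patterns are written as presentation
#' attributes directly on the elements (not via CSS) so that monochrome
#' interpretability survives removal of the embedded style block.
#'
#' @param l An `rr_layout` from [rr_layout()], or an [rr_diagram()] (laid
#'   out on the fly).
#' @param include_style Embed the overridable `<style>` block (default
#'   `TRUE`).
#' @param style CSS text used when `include_style` is `TRUE`.
#' @return A character scalar of SVG markup.
#' @export
render_svg <- function(l, include_style = TRUE, style = rrr_default_style()) {
  if (inherits(l, "rr_diagram")) l <- rr_layout(l)
  stopifnot(inherits(l, "rr_layout"))
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            n2(l$width), n2(l$height), n2(l$width), n2(l$height)))
  if (include_style) {
    out <- c(out, "<style>", xml_escape(style), "</style>")
  }
  for (p in l$primitives) {
    dash <- if (isTRUE(p$dashed)) " stroke-dasharray=\"5,4\"" else ""
    out <- c(out, switch(p$kind,
      "box" = sprintf("<rect class=\"%s\" x=\"%s\" y=\"%s\" width=\"%s\" height=\"%s\" rx=\"3\"%s/>",
                      p$class, n2(p$x), n2(p$y), n2(p$w), n2(p$h), dash),
      "text" = sprintf("<text class=\"%s\" x=\"%s\" y=\"%s\">%s</text>",
                       p$class, n2(p$x), n2(p$y), xml_escape(p$str)),
      "path" = sprintf("<path class=\"%s\" d=\"%s\"%s/>", p$class, p$d, dash)))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}
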