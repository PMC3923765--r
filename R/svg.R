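# SVG 1.1 emission. Deterministic: coordinates are formatted with a fixed
# number of decimals and elements are emitted in stable (id-sorted) order,
# so a fixed input and seed give byte-identical output.

fmt <- function(x) formatC(x, format = "f", digits = 2)

#' Render a laid-out graph as SVG
#'
#' Nodes are drawn as their resolved shapes (glyph nodes as embedded mini
#' bar/line charts with min/max tick labels instead of a shape), edges
#' follow their computed routes — reaction arrows as quadratic Bezier
#' paths — aggregate edges carry their multiplicity as a label, and when a
#' layered layout ran the compartment bands are drawn as background strips
#' with their layer names.
#'
#' @param rg A `bnv_render` after all three pipeline steps.
#' @param padding Canvas padding in px.
#' @param bands Draw compartment background strips (default `TRUE` when
#'   present).
#' @return SVG 1.1 as a single string.
#' @export
render_svg <- function(rg, padding = 20, bands = TRUE) {
  if (rg$stamps$layout == 0 ||
      (nrow(rg$nodes) > 0 && !"x" %in% names(rg$nodes)))
    rlang::abort("render graph is not laid out; run apply_layout() first",
                 class = "bnv_state_error")
  n <- rg$nodes[order(rg$nodes$id), ]
  e <- rg$edges[order(rg$edges$id), ]
  if (nrow(n) == 0) {
    return(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                  '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                  'width="40" height="40" viewBox="0 0 40 40"></svg>\n'))
  }
  x0 <- min(n$x - n$width / 2) - padding
  y0 <- min(n$y - n$height / 2) - padding
  x1 <- max(n$x + n$width / 2) + padding
  y1 <- max(n$y + n$height / 2) + padding
  if (!is.null(rg$bands) && bands) {
    y0 <- min(y0, min(rg$bands$y0)); y1 <- max(y1, max(rg$bands$y1))
  }
  out <- character()
  push <- function(s) out[[length(out) + 1]] <<- s
  push(sprintf(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%s" height="%s" viewBox="%s %s %s %s">'),
    fmt(x1 - x0), fmt(y1 - y0), fmt(x0), fmt(y0), fmt(x1 - x0), fmt(y1 - y0)))
  push(paste0('<defs><marker id="arrow" viewBox="0 0 10 10" refX="9" ',
    'refY="5" markerWidth="7" markerHeight="7" orient="auto-start-reverse">',
    '<path d="M 0 0 L 10 5 L 0 10 z" fill="#333333"/></marker></defs>'))

  if (!is.null(rg$bands) && bands) {
    shade <- c("#F7F7F7", "#EDEDED")
    for (i in seq_len(nrow(rg$bands))) {
      b <- rg$bands[i, ]
      push(sprintf(
        '<rect class="band" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt(x0), fmt(b$y0), fmt(x1 - x0), fmt(b$y1 - b$y0),
        shade[(i %% 2) + 1]))
      push(sprintf(
        '<text x="%s" y="%s" font-size="11" fill="#888888">%s</text>',
        fmt(x0 + 4), fmt(b$y0 + 13), xml_escape(b$name)))
    }
  }

  for (i in seq_len(nrow(e))) {
    r <- e$route[[i]]
    if (is.null(r)) next
    marker <- if (isTRUE(e$directed[i])) ' marker-end="url(#arrow)"' else ""
    style <- sprintf('stroke="%s" stroke-width="%s" fill="none"',
                     e$stroke_color[i], fmt(e$line_width[i]))
    if (identical(e$curve[i], "quadratic")) {
      p1 <- r[1, ]; p2 <- r[nrow(r), ]
      mid <- (p1 + p2) / 2
      d <- p2 - p1; len <- sqrt(sum(d^2))
      off <- if (len > 0) c(-d[2], d[1]) / len * min(20, len / 4) else c(0, 0)
      ctrl <- mid + off
      push(sprintf('<path d="M %s %s Q %s %s %s %s" %s%s/>',
                   fmt(p1[1]), fmt(p1[2]), fmt(ctrl[1]), fmt(ctrl[2]),
                   fmt(p2[1]), fmt(p2[2]), style, marker))
    } else if (nrow(r) > 2) {
      pts <- paste(fmt(r[, 1]), fmt(r[, 2]), collapse = " ")
      push(sprintf('<polyline points="%s" %s%s/>', pts, style, marker))
    } else {
      push(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" %s%s/>',
                   fmt(r[1, 1]), fmt(r[1, 2]), fmt(r[2, 1]), fmt(r[2, 2]),
                   style, marker))
    }
    if (!is.null(e$multiplicity) && e$multiplicity[i] > 1) {
      mid <- colMeans(r[c(1, nrow(r)), , drop = FALSE])
      push(sprintf(
        '<text x="%s" y="%s" font-size="10" fill="#555555">x%d</text>',
        fmt(mid[1] + 4), fmt(mid[2] - 4), e$multiplicity[i]))
    }
  }

  for (i in seq_len(nrow(n))) {
    g <- n$glyph[[i]]
    if (!is.null(g) && !is.null(g$values)) {
      push(svg_glyph(g, n$x[i], n$y[i]))
    } else {
      push(svg_shape(n$shape[i], n$x[i], n$y[i], n$width[i], n$height[i],
                     n$fill_color[i], n$stroke_color[i], n$line_width[i]))
    }
    push(sprintf(paste0('<text x="%s" y="%s" font-size="10" ',
                        'text-anchor="middle">%s</text>'),
                 fmt(n$x[i]), fmt(n$y[i] + n$height[i] / 2 + 11),
                 xml_escape(n$label[i])))
  }
  push("</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

svg_shape <- function(shape, x, y, w, h, fill, stroke, lw) {
  style <- sprintf('fill="%s" stroke="%s" stroke-width="%s"', fill, stroke,
                   fmt(lw))
  poly <- function(px, py) sprintf('<polygon points="%s" %s/>',
    paste(fmt(px), fmt(py), collapse = " "), style)
  switch(shape,
    ellipse = sprintf('<ellipse cx="%s" cy="%s" rx="%s" ry="%s" %s/>',
                      fmt(x), fmt(y), fmt(w / 2), fmt(h / 2), style),
    roundrect = sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" rx="6" %s/>',
      fmt(x - w / 2), fmt(y - h / 2), fmt(w), fmt(h), style),
    diamond = poly(c(x, x + w / 2, x, x - w / 2),
                   c(y - h / 2, y, y + h / 2, y)),
    hexagon = poly(c(x - w / 4, x + w / 4, x + w / 2, x + w / 4, x - w / 4,
                     x - w / 2),
                   c(y - h / 2, y - h / 2, y, y + h / 2, y + h / 2, y)),
    octagon = poly(c(x - w / 4, x + w / 4, x + w / 2, x + w / 2, x + w / 4,
                     x - w / 4, x - w / 2, x - w / 2),
                   c(y - h / 2, y - h / 2, y - h / 4, y + h / 4, y + h / 2,
                     y + h / 2, y + h / 4, y - h / 4)),
    parallelogram = poly(c(x - w / 4, x + w / 2, x + w / 4, x - w / 2),
                         c(y - h / 2, y - h / 2, y + h / 2, y + h / 2)),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s/>',
            fmt(x - w / 2), fmt(y - h / 2), fmt(w), fmt(h), style))
}

# 48x32 mini chart replacing the node shape; min/max tick labels annotate
# the value scale
svg_glyph <- function(g, x, y) {
  W <- 48; H <- 32
  v <- g$values
  out <- sprintf(paste0('<rect x="%s" y="%s" width="%d" height="%d" ',
                        'fill="#FFFFFF" stroke="#333333" stroke-width="1"/>'),
                 fmt(x - W / 2), fmt(y - H / 2), W, H)
  ok <- !is.na(v)
  if (any(ok)) {
    lo <- min(v[ok]); hi <- max(v[ok])
    rng <- if (hi > lo) hi - lo else 1
    k <- length(v)
    px <- x - W / 2 + (seq_len(k) - 0.5) / k * W
    py <- y + H / 2 - 2 - (v - lo) / rng * (H - 4)
    if (identical(g$kind, "line")) {
      pts <- paste(fmt(px[ok]), fmt(py[ok]), collapse = " ")
      out <- c(out, sprintf(
        '<polyline points="%s" fill="none" stroke="#1F77B4" stroke-width="1.5"/>',
        pts))
    } else {
      bw <- W / k * 0.7
      for (i in which(ok)) {
        out <- c(out, sprintf(
          '<rect x="%s" y="%s" width="%s" height="%s" fill="#1F77B4"/>',
          fmt(px[i] - bw / 2), fmt(py[i]), fmt(bw),
          fmt(y + H / 2 - 2 - py[i])))
      }
    }
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="6" fill="#777777">%s</text>',
      fmt(x + W / 2 + 2), fmt(y + H / 2), fmt(lo)))
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="6" fill="#777777">%s</text>',
      fmt(x + W / 2 + 2), fmt(y - H / 2 + 6), fmt(hi)))
  }
  paste(out, collapse = "\n")
}
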