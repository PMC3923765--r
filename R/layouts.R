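# Layout engines. All engines share conventions: coordinates are pixels,
# the origin is top-left, y increases downward, and (x, y) is a node's
# centre. Ties are broken by lexicographic node id everywhere so that every
# engine is deterministic for a fixed input and seed.

new_layout <- function(nodes, edges, engine, bands = NULL) {
  structure(list(nodes = nodes, edges = edges, engine = engine,
                 bands = bands), class = "bnv_layout")
}

#' @export
print.bnv_layout <- function(x, ...) {
  cat(sprintf("<bnv_layout> engine=%s, %d nodes, %d edge routes\n",
              x$engine, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# ---- layered (Sugiyama) ----------------------------------------------------

#' Layered (Sugiyama) layout with fixed layer assignment
#'
#' Draws the graph in horizontal bands whose order is given (here: the
#' compartment model's cell layers, extracellular at the top). Edges that
#' span more than one band are routed through invisible dummy nodes.
#' Within-band order is chosen by iterative barycenter crossing reduction
#' (8 sweeps: 4 downward, 4 upward); the best ordering seen is kept, so the
#' final crossing count never exceeds that of the initial (lexicographic)
#' ordering.
#'
#' @param nodes Tibble with columns id, width, height.
#' @param edges Tibble with columns id, source, target.
#' @param layer_map Tibble (id, layer) or named integer vector; 1 = top
#'   band. Every node must have a layer.
#' @param layer_names Optional names for the bands (for background strips).
#' @param band_height Band height in px (grown to fit the tallest node).
#' @param h_gap Horizontal gap between neighbouring nodes in a band.
#' @param sweeps Barycenter sweeps (default 8).
#' @return A `bnv_layout` with `bands`.
#' @export
layout_layered <- function(nodes, edges, layer_map, layer_names = NULL,
                           band_height = 120, h_gap = 40, sweeps = 8) {
  if (is.data.frame(layer_map))
    layer_map <- stats::setNames(layer_map$layer, layer_map$id)
  if (!all(nodes$id %in% names(layer_map)))
    rlang::abort("every node needs a layer index")
  lay <- as.integer(layer_map[nodes$id])
  L <- max(c(lay, 1L))
  band_height <- max(band_height, max(c(nodes$height, 0)) + 40)

  # dummy nodes for edges spanning > 1 layer
  segs <- list(); routes_via <- list()
  dummy_ids <- character(); dummy_layer <- integer()
  for (i in seq_len(nrow(edges))) {
    u <- edges$source[i]; v <- edges$target[i]
    lu <- layer_map[[u]]; lv <- layer_map[[v]]
    if (abs(lu - lv) <= 1) {
      segs[[length(segs) + 1]] <- c(u, v)
    } else {
      step <- sign(lv - lu)
      chain <- u
      for (l in seq(lu + step, lv - step, by = step)) {
        d <- sprintf("..dummy:%s:%d", edges$id[i], l)
        dummy_ids <- c(dummy_ids, d); dummy_layer <- c(dummy_layer, l)
        chain <- c(chain, d)
      }
      chain <- c(chain, v)
      for (j in seq_len(length(chain) - 1))
        segs[[length(segs) + 1]] <- chain[j:(j + 1)]
      routes_via[[edges$id[i]]] <- chain[-c(1, length(chain))]
    }
  }
  all_ids <- c(nodes$id, dummy_ids)
  all_layer <- stats::setNames(c(lay, dummy_layer), all_ids)
  seg_m <- if (length(segs)) do.call(rbind, segs) else
    matrix(character(), 0, 2)

  ord <- lapply(seq_len(L), function(l) sort(all_ids[all_layer == l]))
  pos_of <- function(ord) {
    p <- integer(); nm <- character()
    for (l in seq_len(L)) { p <- c(p, seq_along(ord[[l]])); nm <- c(nm, ord[[l]]) }
    stats::setNames(p, nm)
  }
  crossings <- function(ord) {
    pos <- pos_of(ord)
    total <- 0L
    for (l in seq_len(L - 1)) {
      sel <- all_layer[seg_m[, 1]] == l & all_layer[seg_m[, 2]] == l + 1 |
        all_layer[seg_m[, 1]] == l + 1 & all_layer[seg_m[, 2]] == l
      ss <- seg_m[sel, , drop = FALSE]
      if (nrow(ss) < 2) next
      a <- ifelse(all_layer[ss[, 1]] == l, ss[, 1], ss[, 2])
      b <- ifelse(all_layer[ss[, 1]] == l, ss[, 2], ss[, 1])
      pa <- pos[a]; pb <- pos[b]
      for (i in seq_len(nrow(ss) - 1)) {
        j <- (i + 1):nrow(ss)
        total <- total + sum((pa[i] - pa[j]) * (pb[i] - pb[j]) < 0)
      }
    }
    total
  }
  neighbors_in <- function(id, other_layer) {
    hit <- seg_m[, 1] == id & all_layer[seg_m[, 2]] == other_layer
    hit2 <- seg_m[, 2] == id & all_layer[seg_m[, 1]] == other_layer
    c(seg_m[hit, 2], seg_m[hit2, 1])
  }
  best <- ord; best_cross <- crossings(ord)
  if (nrow(seg_m) > 1 && L > 1) {
    for (s in seq_len(sweeps)) {
      layers_seq <- if (s %% 2 == 1) 2:L else (L - 1):1
      ref_off <- if (s %% 2 == 1) -1L else 1L
      for (l in layers_seq) {
        pos <- pos_of(ord)
        ids <- ord[[l]]
        bary <- vapply(seq_along(ids), function(i) {
          nb <- neighbors_in(ids[i], l + ref_off)
          if (length(nb) == 0) i * 1.0 else mean(pos[nb])
        }, 0)
        ord[[l]] <- ids[order(bary, ids)]
      }
      cc <- crossings(ord)
      if (cc < best_cross) { best <- ord; best_cross <- cc }
    }
  }
  ord <- best

  # coordinates
  widths <- stats::setNames(c(nodes$width, rep(0, length(dummy_ids))), all_ids)
  heights <- stats::setNames(c(nodes$height, rep(0, length(dummy_ids))), all_ids)
  xs <- numeric(0); nm <- character(0)
  for (l in seq_len(L)) {
    ids <- ord[[l]]
    if (length(ids) == 0) next
    w <- widths[ids]
    x <- cumsum(w + h_gap) - (w + h_gap) / 2
    x <- x - (sum(w + h_gap)) / 2
    xs <- c(xs, x); nm <- c(nm, ids)
  }
  xs <- stats::setNames(xs, nm)
  xs <- xs - min(xs - widths[nm] / 2) + h_gap
  ys <- (all_layer[nm] - 0.5) * band_height
  geom <- tibble::tibble(id = nm, x = unname(xs), y = unname(ys),
                         width = unname(widths[nm]),
                         height = unname(heights[nm]))
  real <- geom[!startsWith(geom$id, "..dummy:"), ]

  pt <- function(id) c(xs[[id]], ys[[id]])
  eroutes <- lapply(seq_len(nrow(edges)), function(i) {
    via <- routes_via[[edges$id[i]]]
    do.call(rbind, lapply(c(edges$source[i], via, edges$target[i]), pt))
  })
  et <- tibble::tibble(id = edges$id, curve = "straight", route = eroutes)
  bands <- tibble::tibble(
    layer = seq_len(L),
    name = if (is.null(layer_names)) sprintf("layer %d", seq_len(L))
      else layer_names[seq_len(L)],
    y0 = (seq_len(L) - 1) * band_height, y1 = seq_len(L) * band_height)
  new_layout(real, et, "layered", bands = bands)
}

# ---- force-directed --------------------------------------------------------

#' Force-directed layout with co-factor satellite placement
#'
#' Runs Fruchterman-Reingold-style iterations (seeded, hence
#' deterministic), rescales to the ideal edge length, then re-places each
#' reaction's co-factor satellites on an arc around the reaction node:
#' consumed co-factors on the incoming side and produced ones on the
#' outgoing side, the sides defined by the reaction's substrate-to-product
#' direction vector — so the satellites follow the reaction flow. A final
#' minimum-separation pass removes residual node-body overlaps.
#'
#' @param nodes Tibble (id, width, height).
#' @param edges Tibble (id, source, target).
#' @param iterations FR iterations (default 150).
#' @param seed Integer RNG seed (default 42).
#' @param ideal_edge_length Target mean edge length in px.
#' @param cofactor_orbit_radius Satellite orbit radius in px.
#' @param satellites Optional tibble (node, reaction, side) with side
#'   "substrate" or "product" marking co-factor instances to orbit.
#' @return A `bnv_layout`.
#' @export
layout_force <- function(nodes, edges, iterations = 150, seed = 42,
                         ideal_edge_length = 80,
                         cofactor_orbit_radius = 40, satellites = NULL) {
  ids <- sort(nodes$id)
  nodes <- nodes[match(ids, nodes$id), ]
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = ids))
  set.seed(seed)
  xy <- if (length(ids) == 1) matrix(c(0, 0), 1, 2)
    else igraph::layout_with_fr(g, niter = iterations, grid = "nogrid")
  rownames(xy) <- ids
  if (nrow(edges) > 0 && length(ids) > 1) {
    len <- sqrt(rowSums((xy[edges$source, , drop = FALSE] -
                           xy[edges$target, , drop = FALSE])^2))
    m <- stats::median(len)
    if (is.finite(m) && m > 0) xy <- xy * (ideal_edge_length / m)
  }
  xy[, 1] <- xy[, 1] - min(xy[, 1]) + 60
  xy[, 2] <- xy[, 2] - min(xy[, 2]) + 60

  if (!is.null(satellites) && nrow(satellites) > 0) {
    sat_ids <- satellites$node
    for (r in unique(satellites$reaction)) {
      rp <- xy[r, ]
      inn <- setdiff(edges$source[edges$target == r], sat_ids)
      out <- setdiff(edges$target[edges$source == r], sat_ids)
      dirv <- c(1, 0)
      if (length(inn) > 0 && length(out) > 0) {
        d <- colMeans(xy[out, , drop = FALSE]) -
          colMeans(xy[inn, , drop = FALSE])
        if (sum(d^2) > 0) dirv <- d / sqrt(sum(d^2))
      }
      for (side in c("substrate", "product")) {
        sat <- sort(satellites$node[satellites$reaction == r &
                                      satellites$side == side])
        if (length(sat) == 0) next
        base <- atan2(dirv[2], dirv[1]) +
          if (side == "substrate") pi else 0
        span <- pi / 2
        k <- length(sat)
        ang <- base + (seq_len(k) - (k + 1) / 2) / max(k, 1) * span
        xy[sat, 1] <- rp[1] + cofactor_orbit_radius * cos(ang)
        xy[sat, 2] <- rp[2] + cofactor_orbit_radius * sin(ang)
      }
    }
  }
  geom <- tibble::tibble(id = ids, x = unname(xy[, 1]), y = unname(xy[, 2]),
                         width = nodes$width, height = nodes$height)
  geom <- separate_overlaps(geom)
  et <- straight_routes(geom, edges)
  new_layout(geom, et, "force")
}

# ---- KEGG fixed-position layout --------------------------------------------

#' KEGG-style fixed-position layout with computed edge routes
#'
#' Nodes with KGML layout hints take their map coordinates verbatim;
#' un-hinted nodes are placed by a seeded force layout and clamped into the
#' hinted bounding box (the overlap pass also only moves un-hinted nodes,
#' so every hint is preserved exactly). KGML carries no edge routes, so the
#' layouter computes them: straight segments, replaced by a 2-bend
#' orthogonal route whenever the straight segment would cross a third
#' node's body. Edges marked `quadratic_ids` (reaction arrows) are rendered
#' as quadratic curves.
#'
#' @param nodes Tibble (id, width, height).
#' @param edges Tibble (id, source, target).
#' @param hints Tibble (id, x, y, width, height) from [read_kgml()]; at
#'   least one node must be hinted, otherwise the engine falls back to
#'   [layout_force()] with a warning.
#' @param quadratic_ids Edge ids to draw as quadratic reaction arrows.
#' @param seed Seed for the placement of un-hinted nodes.
#' @return A `bnv_layout`.
#' @export
layout_kegg <- function(nodes, edges, hints, quadratic_ids = character(),
                        seed = 42) {
  hinted <- intersect(nodes$id, hints$id)
  if (length(hinted) == 0) {
    rlang::warn("no KGML layout hints available; falling back to force layout")
    return(layout_force(nodes, edges, seed = seed))
  }
  base <- layout_force(nodes, edges, seed = seed)
  geom <- base$nodes
  hi <- match(geom$id, hints$id)
  has <- !is.na(hi)
  geom$x[has] <- hints$x[hi[has]]
  geom$y[has] <- hints$y[hi[has]]
  geom$width[has] <- ifelse(is.na(hints$width[hi[has]]), geom$width[has],
                            hints$width[hi[has]])
  geom$height[has] <- ifelse(is.na(hints$height[hi[has]]), geom$height[has],
                             hints$height[hi[has]])
  # clamp un-hinted nodes into the hinted bounding box
  if (any(!has)) {
    bx <- range(geom$x[has]); by <- range(geom$y[has])
    geom$x[!has] <- pmin(pmax(geom$x[!has], bx[1]), bx[2])
    geom$y[!has] <- pmin(pmax(geom$y[!has], by[1]), by[2])
    geom <- separate_overlaps(geom, movable = geom$id[!has])
  }
  et <- route_edges(geom, edges, quadratic_ids = quadratic_ids)
  new_layout(geom, et, "kegg")
}

# ---- shared geometry helpers -----------------------------------------------

straight_routes <- function(geom, edges, curve = "straight") {
  xs <- stats::setNames(geom$x, geom$id)
  ys <- stats::setNames(geom$y, geom$id)
  routes <- lapply(seq_len(nrow(edges)), function(i)
    rbind(c(xs[[edges$source[i]]], ys[[edges$source[i]]]),
          c(xs[[edges$target[i]]], ys[[edges$target[i]]])))
  tibble::tibble(id = edges$id, curve = curve, route = routes)
}

# iterative minimum-separation: push overlapping node bodies apart along the
# axis of least penetration; deterministic (pairs resolved in id order).
# Skipped above `max_nodes` — the pass targets desk-scale drawings; very
# large graphs are laid out for overview, not node-level readability.
separate_overlaps <- function(geom, movable = geom$id, gap = 4,
                              max_iter = 60, max_nodes = 1200) {
  ord <- order(geom$id)
  geom <- geom[ord, ]
  can_move <- geom$id %in% movable
  n <- nrow(geom)
  if (n < 2 || n > max_nodes) return(geom)
  hw <- outer(geom$width, geom$width, "+") / 2 + gap
  hh <- outer(geom$height, geom$height, "+") / 2 + gap
  for (iter in seq_len(max_iter)) {
    ox_m <- hw - abs(outer(geom$x, geom$x, "-"))
    oy_m <- hh - abs(outer(geom$y, geom$y, "-"))
    over <- ox_m > 0 & oy_m > 0
    over[lower.tri(over, diag = TRUE)] <- FALSE
    idx <- which(over, arr.ind = TRUE)
    if (nrow(idx) == 0) break
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (!can_move[i] && !can_move[j]) next
      dx <- geom$x[j] - geom$x[i]; dy <- geom$y[j] - geom$y[i]
      ox <- hw[i, j] - abs(dx); oy <- hh[i, j] - abs(dy)
      if (ox <= 0 || oy <= 0) next
      if (ox < oy) {
        push <- ox * if (dx >= 0) 1 else -1
        if (can_move[i] && can_move[j]) {
          geom$x[i] <- geom$x[i] - push / 2; geom$x[j] <- geom$x[j] + push / 2
        } else if (can_move[j]) geom$x[j] <- geom$x[j] + push
        else geom$x[i] <- geom$x[i] - push
      } else {
        push <- oy * if (dy >= 0) 1 else -1
        if (can_move[i] && can_move[j]) {
          geom$y[i] <- geom$y[i] - push / 2; geom$y[j] <- geom$y[j] + push / 2
        } else if (can_move[j]) geom$y[j] <- geom$y[j] + push
        else geom$y[i] <- geom$y[i] - push
      }
    }
  }
  geom
}

# does the open segment p1-p2 pass through the rectangle body of a node?
seg_crosses_rect <- function(p1, p2, cx, cy, w, h) {
  # Liang-Barsky clip of segment against the rectangle
  xmin <- cx - w / 2; xmax <- cx + w / 2
  ymin <- cy - h / 2; ymax <- cy + h / 2
  d <- p2 - p1
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    p <- switch(k, -d[1], d[1], -d[2], d[2])
    q <- switch(k, p1[1] - xmin, xmax - p1[1], p1[2] - ymin, ymax - p1[2])
    if (p == 0) { if (q < 0) return(FALSE) } else {
      r <- q / p
      if (p < 0) { if (r > t1) return(FALSE); if (r > t0) t0 <- r }
      else { if (r < t0) return(FALSE); if (r < t1) t1 <- r }
    }
  }
  # require a real interior crossing, not a touch at the endpoints
  t0 > 1e-9 && t1 < 1 - 1e-9 && t1 - t0 > 1e-9
}

route_blocked <- function(pts, geom, exclude) {
  others <- geom[!geom$id %in% exclude & geom$width > 0, ]
  for (s in seq_len(nrow(pts) - 1)) {
    for (k in seq_len(nrow(others))) {
      if (seg_crosses_rect(pts[s, ], pts[s + 1, ], others$x[k], others$y[k],
                           others$width[k], others$height[k])) return(TRUE)
    }
  }
  FALSE
}

# straight where possible; 2-bend orthogonal (x-first or y-first) around
# obstructing node bodies
route_edges <- function(geom, edges, quadratic_ids = character()) {
  xs <- stats::setNames(geom$x, geom$id)
  ys <- stats::setNames(geom$y, geom$id)
  routes <- vector("list", nrow(edges))
  curve <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    u <- edges$source[i]; v <- edges$target[i]
    p1 <- c(xs[[u]], ys[[u]]); p2 <- c(xs[[v]], ys[[v]])
    excl <- c(u, v)
    straight <- rbind(p1, p2)
    if (edges$id[i] %in% quadratic_ids) {
      routes[[i]] <- straight; curve[i] <- "quadratic"; next
    }
    if (!route_blocked(straight, geom, excl)) {
      routes[[i]] <- straight; curve[i] <- "straight"; next
    }
    cand <- list(rbind(p1, c(p2[1], p1[2]), p2),
                 rbind(p1, c(p1[1], p2[2]), p2))
    found <- FALSE
    for (cc in cand) {
      if (!route_blocked(cc, geom, excl)) {
        routes[[i]] <- cc; curve[i] <- "orthogonal"; found <- TRUE; break
      }
    }
    if (!found) {
      # offset detour: shift the bend outward until free (bounded search)
      for (off in seq(30, 300, by = 30)) {
        for (sgn in c(-1, 1)) {
          cc <- rbind(p1, c(p1[1], p2[2] + sgn * off),
                      c(p2[1], p2[2] + sgn * off), p2)
          if (!route_blocked(cc, geom, excl)) {
            routes[[i]] <- cc; curve[i] <- "orthogonal"; found <- TRUE; break
          }
        }
        if (found) break
      }
    }
    if (!found) { routes[[i]] <- straight; curve[i] <- "straight" }
  }
  tibble::tibble(id = edges$id, curve = curve, route = routes)
}

# ---- tidiers / plotting ----------------------------------------------------

#' Tidy a layout into a node-coordinate tibble
#' @param x A `bnv_layout`.
#' @param ... Unused.
#' @return The node tibble (id, x, y, width, height).
#' @export
tidy.bnv_layout <- function(x, ...) x$nodes

#' One-row layout summary
#' @param x A `bnv_layout`.
#' @param ... Unused.
#' @return A tibble with engine, node/edge counts and canvas size.
#' @export
glance.bnv_layout <- function(x, ...) {
  tibble::tibble(engine = x$engine, nodes = nrow(x$nodes),
                 edges = nrow(x$edges),
                 width = max(x$nodes$x + x$nodes$width / 2, 0),
                 height = max(x$nodes$y + x$nodes$height / 2, 0))
}

#' Plot a layout with ggplot2
#' @param object A `bnv_layout`.
#' @param ... Unused.
#' @return A ggplot object (y axis reversed to match screen coordinates).
#' @export
autoplot.bnv_layout <- function(object, ...) {
  seg <- dplyr::bind_rows(lapply(seq_len(nrow(object$edges)), function(i) {
    r <- object$edges$route[[i]]
    tibble::tibble(x = r[-nrow(r), 1], y = r[-nrow(r), 2],
                   xend = r[-1, 1], yend = r[-1, 2])
  }))
  p <- ggplot2::ggplot()
  if (nrow(seg) > 0)
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                               yend = .data$yend), color = "grey50")
  p + ggplot2::geom_point(
    data = object$nodes, ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
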