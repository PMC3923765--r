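# The three-step rendering pipeline: (1) construct the drawable graph
# topology from the hierarchical model, (2) assign resolved visual
# attributes to every element, (3) lay the elements out. Dirty flags on the
# model drive incremental updates that skip unaffected steps; the defining
# contract is that an incremental update equals a from-scratch render.

#' Step 1: build the drawable graph topology
#'
#' Collapsed groups become single nodes whose members' external edges are
#' re-attached and aggregated (multiplicity = number of relations
#' represented); expanded reaction hyperedges become a bipartite structure
#' (substrate -> reaction node -> product, catalyst — reaction); alias
#' instances render as separate nodes; invisible components and their
#' incident edges are omitted.
#'
#' @param model A `bnv_model`.
#' @return A `bnv_render` object (steps 2-3 still pending).
#' @export
build_topology <- function(model) {
  # visibility fast path: only ids with an explicit `visible` assignment
  # (or a kind-style setting it) need the full layer resolution
  explicit <- unique(c(
    names(Filter(function(a) !is.null(a$visible), model$layers$projection)),
    names(Filter(function(a) !is.null(a$visible), model$layers$user_override)),
    names(Filter(function(a) !is.null(a$visible), model$layers$style))))
  kinds_with_vis <- names(Filter(function(a) !is.null(a$visible),
                                 model$layers$style_kinds))
  kind_lookup <- c(
    stats::setNames(model$entities$kind, model$entities$id),
    stats::setNames(rep("group", nrow(model$groups)), model$groups$id),
    stats::setNames(rep("reaction", nrow(model$reactions)),
                    model$reactions$id),
    stats::setNames(rep("edge", nrow(model$edges)), model$edges$id))
  if (nrow(model$aliases) > 0)
    kind_lookup <- c(kind_lookup, stats::setNames(
      kind_lookup[model$aliases$entity_id], model$aliases$instance_id))
  vis <- function(id) {
    if (!id %in% explicit && !kind_lookup[[id]] %in% kinds_with_vis)
      return(TRUE)
    isTRUE(resolve_property(model, id, "visible"))
  }
  vis_vec <- function(ids) {
    if (length(explicit) == 0 && length(kinds_with_vis) == 0)
      return(rep(TRUE, length(ids)))
    vapply(ids, vis, TRUE)
  }

  aliased <- unique(model$aliases$entity_id)
  inst_of <- character()
  if (nrow(model$aliases) > 0) {
    al <- model$aliases[order(model$aliases$instance_id), ]
    al <- al[!duplicated(al$entity_id), ]
    inst_of <- stats::setNames(al$instance_id, al$entity_id)
  }

  all_node_ids <- c(setdiff(model$entities$id, aliased),
                    model$aliases$instance_id,
                    model$reactions$id,
                    model$groups$id[model$groups$collapsed])
  rep_map <- stats::setNames(render_representative(model, all_node_ids),
                             all_node_ids)
  rendered <- unique(unname(rep_map))
  rendered <- rendered[vis_vec(rendered)]

  nodes <- tibble::tibble(id = sort(rendered))
  nodes$origin <- nodes$id
  nodes$kind <- unname(kind_lookup[nodes$id])

  # map an edge endpoint to its rendered node (or NA if hidden)
  map_endpoint <- function(x) {
    if (length(x) == 0) return(character(0))
    x <- ifelse(x %in% aliased, unname(inst_of[x]), x)
    r <- unname(rep_map[x])
    r <- ifelse(is.na(r), x, r)
    ifelse(r %in% nodes$id, r, NA_character_)
  }

  e <- model$edges
  edge_vis <- vis_vec(e$id)
  src <- map_endpoint(e$source); tgt <- map_endpoint(e$target)
  remapped <- src != e$source | tgt != e$target
  keep <- edge_vis & !is.na(src) & !is.na(tgt) & src != tgt
  ed <- tibble::tibble(id = e$id, origin_ids = as.list(e$id), source = src,
                       target = tgt, relation = e$relation,
                       directed = e$directed, multiplicity = e$multiplicity,
                       remapped = remapped, reaction = FALSE)[keep, ]

  # bipartite expansion of visible reactions
  rx_rows <- which(model$reactions$id %in% nodes$id)
  rx_edges <- lapply(rx_rows, function(i) {
    r <- model$reactions[i, ]
    rid <- r$id
    cof <- r$cofactors[[1]]
    gid <- paste0(rid, "::cofactors")
    al <- model$aliases[model$aliases$context_id == gid, ]
    cof_inst <- stats::setNames(al$instance_id, al$entity_id)
    endpoint <- function(ent) {
      if (ent %in% names(cof_inst)) unname(cof_inst[ent]) else ent
    }
    sub <- r$substrates[[1]]$entity
    prod <- r$products[[1]]$entity
    cat <- r$catalysts[[1]]
    tibble::tibble(
      id = c(sprintf("re:%s:s:%s", rid, sub), sprintf("re:%s:p:%s", rid, prod),
             if (length(cat)) sprintf("re:%s:c:%s", rid, cat)),
      endpoint_a = c(vapply(sub, endpoint, ""), rep(rid, length(prod)),
                     if (length(cat)) cat),
      endpoint_b = c(rep(rid, length(sub)), vapply(prod, endpoint, ""),
                     rep(rid, length(cat))),
      directed = c(rep(TRUE, length(sub) + length(prod)),
                   rep(FALSE, length(cat))))
  })
  if (length(rx_edges) > 0) {
    rx <- dplyr::bind_rows(rx_edges)
    src <- map_endpoint(rx$endpoint_a); tgt <- map_endpoint(rx$endpoint_b)
    remapped <- src != rx$endpoint_a | tgt != rx$endpoint_b
    keep <- !is.na(src) & !is.na(tgt) & src != tgt
    ed <- dplyr::bind_rows(ed, tibble::tibble(
      id = rx$id, origin_ids = as.list(rx$id), source = src, target = tgt,
      relation = "generic", directed = rx$directed, multiplicity = 1L,
      remapped = remapped, reaction = TRUE)[keep, ])
  }

  # aggregate parallel re-attached edges; mixed relations become generic
  if (nrow(ed) > 0) {
    agg <- ed[ed$remapped, ]; plain <- ed[!ed$remapped, ]
    if (nrow(agg) > 0) {
      agg <- agg |>
        dplyr::group_by(.data$source, .data$target, .data$directed) |>
        dplyr::summarise(
          id = paste0("agg:", dplyr::first(.data$source), ":",
                      dplyr::first(.data$target)),
          origin_ids = list(unlist(.data$origin_ids)),
          relation = if (dplyr::n_distinct(.data$relation) == 1)
            dplyr::first(.data$relation) else "generic",
          multiplicity = sum(.data$multiplicity),
          reaction = any(.data$reaction), .groups = "drop")
    }
    ed <- dplyr::bind_rows(plain, agg)
  }
  ed$remapped <- NULL
  ed <- ed[order(ed$id), ]

  structure(list(
    nodes = nodes, edges = ed,
    stamps = list(topology = 1L, attributes = 0L, layout = 0L),
    bands = NULL, engine = NULL, layout_opts = NULL),
    class = "bnv_render")
}

#' @export
print.bnv_render <- function(x, ...) {
  cat(sprintf("<bnv_render> %d nodes, %d edges (stamps t=%d a=%d l=%d)\n",
              nrow(x$nodes), nrow(x$edges), x$stamps$topology,
              x$stamps$attributes, x$stamps$layout))
  invisible(x)
}

resolve_node_attrs <- function(model, ids) {
  ids <- unname(ids)
  get <- function(id, p) resolve_property(model, id, p)
  vc <- function(f, proto) vapply(ids, f, proto, USE.NAMES = FALSE)
  tibble::tibble(
    label = vc(function(i) as.character(get(i, "label")), ""),
    shape = vc(function(i) get(i, "shape"), ""),
    size = vc(function(i) {
      s <- get(i, "size")
      if (component_kind(model, i) == "reaction" && identical(s, 30)) 14
      else as.numeric(s)
    }, 0),
    fill_color = vc(function(i) get(i, "fill_color"), ""),
    stroke_color = vc(function(i) get(i, "stroke_color"), ""),
    line_width = vc(function(i) as.numeric(get(i, "line_width")), 0),
    font = vc(function(i) get(i, "font"), ""),
    glyph = lapply(ids, function(i) get(i, "glyph")))
}

resolve_edge_attrs <- function(model, origin_ids) {
  first_origin <- unname(vapply(origin_ids, function(o) o[1], ""))
  has_comp <- vapply(first_origin, function(i) has_component(model, i), TRUE)
  stroke <- rep("#000000", length(first_origin))
  lw <- rep(1, length(first_origin))
  if (any(has_comp)) {
    stroke[has_comp] <- vapply(first_origin[has_comp], function(i)
      resolve_property(model, i, "stroke_color"), "", USE.NAMES = FALSE)
    lw[has_comp] <- vapply(first_origin[has_comp], function(i)
      as.numeric(resolve_property(model, i, "line_width")), 0,
      USE.NAMES = FALSE)
  }
  tibble::tibble(stroke_color = stroke, line_width = lw)
}

#' Step 2: assign resolved visual attributes
#'
#' Every render element receives its fully resolved property set via the
#' model's layer stack ([resolve_property()]); glyph specs from time-series
#' projections are attached to their nodes. Topology is never altered.
#'
#' @param rg A `bnv_render` from [build_topology()].
#' @param model The model it was built from.
#' @return The render graph with attribute columns filled in.
#' @export
assign_attributes <- function(rg, model) {
  if (rg$stamps$topology == 0) rlang::abort("run build_topology() first")
  rg$nodes <- dplyr::bind_cols(
    rg$nodes[, c("id", "origin", "kind")],
    resolve_node_attrs(model, rg$nodes$origin))
  keepcols <- c("id", "origin_ids", "source", "target", "relation",
                "directed", "multiplicity", "reaction")
  rg$edges <- dplyr::bind_cols(rg$edges[, keepcols],
                               resolve_edge_attrs(model, rg$edges$origin_ids))
  rg$stamps$attributes <- rg$stamps$attributes + 1L
  rg
}

node_geometry_size <- function(rg) {
  w <- rg$nodes$size
  h <- pmax(rg$nodes$size * 0.66, 14)
  has_glyph <- !vapply(rg$nodes$glyph, is.null, TRUE)
  w[has_glyph] <- 48; h[has_glyph] <- 32
  list(width = w, height = h)
}

#' Step 3: lay out the graphical elements
#'
#' Runs the requested layout engine over the render graph and merges the
#' result into the node geometry and edge routes. A group with its own
#' layout (and expanded) has its members laid out independently by that
#' engine and re-centred at the position the surrounding layout assigned
#' them, supporting multiple layouts in one view; star-group members are
#' re-placed radially around their hub. Attributes are never altered.
#'
#' @param rg A `bnv_render` after [assign_attributes()].
#' @param model The model.
#' @param engine "force", "layered" or "kegg".
#' @param opts Engine options: `seed`, `iterations`, `hints` (kegg),
#'   `compartment_model` (layered), `cofactor_orbit_radius`, ...
#' @return The render graph with geometry and routes.
#' @export
apply_layout <- function(rg, model, engine = c("force", "layered", "kegg"),
                         opts = list()) {
  engine <- match.arg(engine)
  if (rg$stamps$attributes == 0) rlang::abort("run assign_attributes() first")
  gs <- node_geometry_size(rg)
  nodes <- tibble::tibble(id = rg$nodes$id, width = gs$width,
                          height = gs$height)
  edges <- rg$edges[, c("id", "source", "target")]
  seed <- opts$seed %||% 42L

  lay <- switch(engine,
    force = {
      sat <- cofactor_satellites(model, rg)
      layout_force(nodes, edges, iterations = opts$iterations %||% 150,
                   seed = seed,
                   ideal_edge_length = opts$ideal_edge_length %||% 80,
                   cofactor_orbit_radius = opts$cofactor_orbit_radius %||% 40,
                   satellites = sat)
    },
    layered = {
      cm <- opts$compartment_model %||% compartment_model()
      la <- assign_layers(model, cm)
      lm <- stats::setNames(la$layer, la$id)
      fb <- match(cm$fallback, cm$layers)
      full <- stats::setNames(
        ifelse(is.na(lm[rg$nodes$origin]), fb, lm[rg$nodes$origin]),
        rg$nodes$id)
      # alias instances inherit their entity's layer
      inst <- rg$nodes$origin %in% model$aliases$instance_id
      if (any(inst)) {
        ent <- model$aliases$entity_id[match(rg$nodes$origin[inst],
                                             model$aliases$instance_id)]
        full[rg$nodes$id[inst]] <- ifelse(is.na(lm[ent]), fb, lm[ent])
      }
      layout_layered(nodes, edges, full, layer_names = cm$layers,
                     band_height = opts$band_height %||% 120)
    },
    kegg = {
      if (is.null(opts$hints))
        rlang::abort("kegg engine requires opts$hints",
                     class = "bnv_config_error")
      layout_kegg(nodes, edges, opts$hints,
                  quadratic_ids = rg$edges$id[rg$edges$reaction],
                  seed = seed)
    })

  geom <- lay$nodes
  moved <- FALSE
  # independent layouts inside expanded groups
  own <- model$groups[!model$groups$collapsed &
                        !is.na(model$groups$own_layout), ]
  for (i in seq_len(nrow(own))) {
    memb <- intersect(own$members[[i]], geom$id)
    if (length(memb) < 2) next
    sub_nodes <- nodes[nodes$id %in% memb, ]
    sub_edges <- edges[edges$source %in% memb & edges$target %in% memb, ]
    sub <- switch(own$own_layout[i],
      layered = {
        cm <- opts$compartment_model %||% compartment_model()
        la <- assign_layers(model, cm)
        lm <- stats::setNames(la$layer, la$id)
        fb <- match(cm$fallback, cm$layers)
        sl <- stats::setNames(
          ifelse(is.na(lm[sub_nodes$id]), fb, lm[sub_nodes$id]),
          sub_nodes$id)
        layout_layered(sub_nodes, sub_edges, sl, band_height = 80, h_gap = 20)
      },
      layout_force(sub_nodes, sub_edges, seed = seed))
    sg <- sub$nodes
    ii <- match(memb, geom$id)
    ctr <- c(mean(geom$x[ii]), mean(geom$y[ii]))
    sctr <- c(mean(sg$x), mean(sg$y))
    jj <- match(memb, sg$id)
    geom$x[ii] <- sg$x[jj] - sctr[1] + ctr[1]
    geom$y[ii] <- sg$y[jj] - sctr[2] + ctr[2]
    moved <- TRUE
  }
  # star groups: members orbit the hub (first member)
  stars <- model$groups[model$groups$semantics == "star" &
                          !model$groups$collapsed, ]
  for (i in seq_len(nrow(stars))) {
    memb <- intersect(stars$members[[i]], geom$id)
    if (length(memb) < 2) next
    hub <- memb[1]; rest <- sort(memb[-1])
    hi <- match(hub, geom$id)
    ang <- 2 * pi * (seq_along(rest) - 1) / length(rest) - pi / 2
    ri <- match(rest, geom$id)
    geom$x[ri] <- geom$x[hi] + 80 * cos(ang)
    geom$y[ri] <- geom$y[hi] + 80 * sin(ang)
    moved <- TRUE
  }
  eroutes <- lay$edges
  if (moved) eroutes <- straight_routes(geom, edges)

  m <- match(rg$nodes$id, geom$id)
  rg$nodes$x <- geom$x[m]; rg$nodes$y <- geom$y[m]
  rg$nodes$width <- geom$width[m]; rg$nodes$height <- geom$height[m]
  m <- match(rg$edges$id, eroutes$id)
  rg$edges$curve <- eroutes$curve[m]
  rg$edges$curve[rg$edges$reaction] <- "quadratic"
  rg$edges$route <- eroutes$route[m]
  rg$bands <- lay$bands
  rg$engine <- engine
  rg$layout_opts <- opts
  rg$stamps$layout <- rg$stamps$layout + 1L
  rg
}

# co-factor satellite table for layout_force: instance nodes orbiting their
# reaction, sided by whether the co-factor is consumed or produced
cofactor_satellites <- function(model, rg) {
  out <- list()
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    if (length(r$cofactors[[1]]) == 0) next
    gid <- paste0(r$id, "::cofactors")
    al <- model$aliases[model$aliases$context_id == gid, ]
    if (nrow(al) == 0) next
    side <- ifelse(al$entity_id %in% r$substrates[[1]]$entity,
                   "substrate", "product")
    keep <- al$instance_id %in% rg$nodes$id & r$id %in% rg$nodes$id
    if (any(keep))
      out[[length(out) + 1]] <- tibble::tibble(
        node = al$instance_id[keep], reaction = r$id, side = side[keep])
  }
  if (length(out) == 0) NULL else dplyr::bind_rows(out)
}

#' Render a model end to end
#'
#' Convenience wrapper running all three steps and clearing the model's
#' dirty flags.
#'
#' @param model A `bnv_model`.
#' @param engine,opts See [apply_layout()].
#' @return A list with `model` (dirty flags cleared) and `graph` (the
#'   rendered `bnv_render`).
#' @export
render_network <- function(model, engine = "force", opts = list()) {
  rg <- build_topology(model)
  rg <- assign_attributes(rg, model)
  rg <- apply_layout(rg, model, engine, opts)
  list(model = clear_dirty(model), graph = rg)
}

#' Incrementally update a render graph
#'
#' Re-runs only the pipeline steps the model's dirty flags require:
#' visual-only dirt re-resolves attributes for the affected elements
#' (topology stamp unchanged), layout-only dirt re-runs step 3, and
#' topological dirt rebuilds all three steps. The result is always equal to
#' a from-scratch render — that equivalence is the defining contract of the
#' incremental path.
#'
#' @param model The edited model (carrying dirty flags).
#' @param rg The render graph from a prior full render.
#' @return The updated `bnv_render`. Clear the model's flags with
#'   [clear_dirty()] afterwards.
#' @export
incremental_update <- function(model, rg) {
  d <- model$dirty
  engine <- rg$engine %||% "force"
  opts <- rg$layout_opts %||% list()
  if (length(d$topological) > 0) {
    old <- rg$stamps
    rg2 <- build_topology(model)
    rg2 <- assign_attributes(rg2, model)
    rg2 <- apply_layout(rg2, model, engine, opts)
    rg2$stamps <- list(topology = old$topology + 1L,
                       attributes = old$attributes + 1L,
                       layout = old$layout + 1L)
    return(rg2)
  }
  if (length(d$visual) > 0) {
    hit_n <- which(rg$nodes$origin %in% d$visual)
    if (length(hit_n) > 0) {
      attrs <- resolve_node_attrs(model, rg$nodes$origin[hit_n])
      for (col in names(attrs)) rg$nodes[[col]][hit_n] <- attrs[[col]]
    }
    hit_e <- which(vapply(rg$edges$origin_ids,
                          function(o) any(o %in% d$visual), TRUE))
    if (length(hit_e) > 0) {
      ea <- resolve_edge_attrs(model, rg$edges$origin_ids[hit_e])
      rg$edges$stroke_color[hit_e] <- ea$stroke_color
      rg$edges$line_width[hit_e] <- ea$line_width
    }
    rg$stamps$attributes <- rg$stamps$attributes + 1L
    # size/glyph changes alter geometry, which the layout step owns
    if (length(hit_n) > 0 && !is.null(rg$nodes$x)) {
      gs <- node_geometry_size(rg)
      if (any(gs$width != rg$nodes$width | gs$height != rg$nodes$height))
        d$layout <- union(d$layout, d$visual)
    }
  }
  if (length(d$layout) > 0 && rg$stamps$layout > 0) {
    rg$stamps$layout <- rg$stamps$layout - 1L  # re-run replaces, not adds
    rg <- apply_layout(rg, model, engine, opts)
  }
  rg
}
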