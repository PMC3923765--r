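# Flattening the hierarchical model into a simple directed graph on which
# classical graph algorithms are valid, plus the two example algorithms
# (k shortest loopless paths, breadth-first search) and back-projection of
# their results onto the visualization as highlights.

#' A graph-flattening policy
#'
#' Every field must be set explicitly — there are no implicit defaults at
#' call sites — so an analysis is always reproducible from its policy.
#'
#' @param family_mode "split_into_members" (each member inherits every edge
#'   of the family node) or "single_node".
#' @param complex_mode "single_node", "clique" (members pairwise connected
#'   by binding edges, emitted as two directed edges — an approximation) or
#'   "star_to_members" (group node connected to each member).
#' @param reaction_mode "bipartite" (reaction nodes kept) or
#'   "substrate_to_product_edges" (one edge per substrate-product pair, the
#'   reaction recorded in the edge origin).
#' @param alias_mode "merge_instances" or "keep_instances".
#' @param include_cofactors Keep co-factor participants? (`FALSE` drops
#'   them and their edges.)
#' @return A `bnv_flatten_policy`.
#' @export
flattening_policy <- function(family_mode = c("split_into_members",
                                              "single_node"),
                              complex_mode = c("single_node", "clique",
                                               "star_to_members"),
                              reaction_mode = c("bipartite",
                                                "substrate_to_product_edges"),
                              alias_mode = c("merge_instances",
                                             "keep_instances"),
                              include_cofactors = TRUE) {
  structure(list(
    family_mode = match.arg(family_mode),
    complex_mode = match.arg(complex_mode),
    reaction_mode = match.arg(reaction_mode),
    alias_mode = match.arg(alias_mode),
    include_cofactors = isTRUE(include_cofactors)),
    class = "bnv_flatten_policy")
}

new_flatgraph <- function(nodes, edges, directed = TRUE,
                          fingerprint = NA_character_) {
  nodes <- nodes[order(nodes$id), ]
  edges <- edges[order(edges$source, edges$target), ]
  structure(list(nodes = nodes, edges = edges, directed = directed,
                 fingerprint = fingerprint), class = "bnv_flatgraph")
}

#' @export
print.bnv_flatgraph <- function(x, ...) {
  cat(sprintf("<bnv_flatgraph> %d nodes, %d edges (%s)\n", nrow(x$nodes),
              nrow(x$edges), if (x$directed) "directed" else "undirected"))
  invisible(x)
}

model_fingerprint <- function(model) {
  rlang::hash(list(model$entities$id, model$edges[, 1:5], model$groups$id,
                   lapply(model$groups$members, identity),
                   model$reactions$id, model$aliases))
}

#' Flatten a hierarchical model into a simple directed graph
#'
#' Applies the policy's per-construct rules and returns a simple directed
#' graph with invertible origin maps (flat node/edge -> the model
#' components it represents), so results computed on the flat graph can be
#' projected back onto the drawing. Undirected model edges are emitted as
#' two directed edges; parallel edges fold their multiplicity into the
#' `weight` column. The result is independent of component insertion order.
#'
#' @param model A `bnv_model`.
#' @param policy A [flattening_policy()].
#' @return A `bnv_flatgraph`.
#' @export
flatten_model <- function(model, policy = flattening_policy()) {
  ent <- model$entities$id
  drop_nodes <- character()

  # alias handling
  e <- model$edges[, c("source", "target", "relation", "directed",
                       "multiplicity")]
  e$origin <- as.list(model$edges$id)
  al <- model$aliases
  if (policy$alias_mode == "merge_instances" && nrow(al) > 0) {
    to_ent <- stats::setNames(al$entity_id, al$instance_id)
    hit <- e$source %in% names(to_ent)
    e$source[hit] <- to_ent[e$source[hit]]
    hit <- e$target %in% names(to_ent)
    e$target[hit] <- to_ent[e$target[hit]]
    node_tb <- tibble::tibble(id = ent, origin = as.list(ent))
  } else {
    inst_nodes <- tibble::tibble(
      id = al$instance_id,
      origin = lapply(seq_len(nrow(al)), function(i)
        c(al$instance_id[i], al$entity_id[i])))
    plain <- setdiff(ent, unique(al$entity_id))
    node_tb <- dplyr::bind_rows(
      tibble::tibble(id = plain, origin = as.list(plain)), inst_nodes)
  }

  # co-factor filtering
  if (!policy$include_cofactors) {
    cof_ent <- unique(unlist(model$reactions$cofactors))
    cof_inst <- al$instance_id[al$entity_id %in% cof_ent]
    drop_nodes <- c(drop_nodes, cof_ent, cof_inst)
  }

  # reactions
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    subs <- r$substrates[[1]]$entity; prods <- r$products[[1]]$entity
    cats <- r$catalysts[[1]]
    if (!policy$include_cofactors) {
      subs <- setdiff(subs, r$cofactors[[1]])
      prods <- setdiff(prods, r$cofactors[[1]])
    }
    if (policy$reaction_mode == "bipartite") {
      node_tb <- dplyr::bind_rows(node_tb, tibble::tibble(
        id = r$id, origin = list(r$id)))
      if (length(subs) + length(prods) + length(cats) > 0) {
        e <- dplyr::bind_rows(e, tibble::tibble(
          source = c(subs, rep(r$id, length(prods)), cats),
          target = c(rep(r$id, length(subs)), prods, rep(r$id, length(cats))),
          relation = "generic",
          directed = c(rep(TRUE, length(subs) + length(prods)),
                       rep(FALSE, length(cats))),
          multiplicity = 1L, origin = list(r$id)))
      }
      if (r$reversible && length(subs) > 0 && length(prods) > 0) {
        e <- dplyr::bind_rows(e, tibble::tibble(
          source = c(prods, rep(r$id, length(subs))),
          target = c(rep(r$id, length(prods)), subs),
          relation = "generic", directed = TRUE, multiplicity = 1L,
          origin = list(r$id)))
      }
    } else {
      pairs <- expand.grid(s = subs, p = prods, stringsAsFactors = FALSE)
      if (nrow(pairs) > 0) {
        e <- dplyr::bind_rows(e, tibble::tibble(
          source = pairs$s, target = pairs$p, relation = "generic",
          directed = !r$reversible, multiplicity = 1L, origin = list(r$id)))
      }
    }
  }

  # groups, processed leaves-first (deepest groups before their parents)
  depth <- function(g) {
    d <- 0L; cur <- g
    while (cur %in% names(model$parent)) { cur <- model$parent[[cur]]; d <- d + 1L }
    d
  }
  gs <- model$groups
  if (nrow(gs) > 0) gs <- gs[order(-vapply(gs$id, depth, 0L), gs$id), ]
  for (i in seq_len(nrow(gs))) {
    g <- gs[i, ]
    memb <- setdiff(g$members[[1]], drop_nodes)
    mode <- switch(g$semantics,
      family = policy$family_mode,
      complex = policy$complex_mode,
      reaction_cofactors = "transparent",
      "transparent")
    gedges <- e$source == g$id | e$target == g$id
    if (mode == "single_node") {
      node_tb <- node_tb[!node_tb$id %in% memb, ]
      node_tb <- dplyr::bind_rows(node_tb, tibble::tibble(
        id = g$id, origin = list(c(g$id, memb))))
      hit <- e$source %in% memb; e$source[hit] <- g$id
      hit <- e$target %in% memb; e$target[hit] <- g$id
    } else if (mode == "split_into_members") {
      # members inherit every edge of the group node
      if (any(gedges) && length(memb) > 0) {
        inherited <- dplyr::bind_rows(lapply(memb, function(m) {
          sub <- e[gedges, ]
          sub$source[sub$source == g$id] <- m
          sub$target[sub$target == g$id] <- m
          sub
        }))
        e <- dplyr::bind_rows(e[!gedges, ], inherited)
      }
      ii <- match(memb, node_tb$id)
      ok <- !is.na(ii)
      node_tb$origin[ii[ok]] <- lapply(node_tb$origin[ii[ok]], c, g$id)
    } else if (mode == "clique") {
      if (length(memb) > 1) {
        pr <- t(utils::combn(sort(memb), 2))
        e <- dplyr::bind_rows(e, tibble::tibble(
          source = pr[, 1], target = pr[, 2], relation = "binding",
          directed = FALSE, multiplicity = 1L, origin = list(g$id)))
      }
      if (any(gedges)) {
        inherited <- dplyr::bind_rows(lapply(memb, function(m) {
          sub <- e[gedges, ]
          sub$source[sub$source == g$id] <- m
          sub$target[sub$target == g$id] <- m
          sub
        }))
        e <- dplyr::bind_rows(e[!gedges, ], inherited)
      }
    } else if (mode == "star_to_members") {
      node_tb <- dplyr::bind_rows(node_tb, tibble::tibble(
        id = g$id, origin = list(g$id)))
      if (length(memb) > 0) {
        e <- dplyr::bind_rows(e, tibble::tibble(
          source = g$id, target = memb, relation = "generic",
          directed = FALSE, multiplicity = 1L, origin = list(g$id)))
      }
    } else {
      # transparent: re-attach the group's own edges to every member
      if (any(gedges) && length(memb) > 0) {
        inherited <- dplyr::bind_rows(lapply(memb, function(m) {
          sub <- e[gedges, ]
          sub$source[sub$source == g$id] <- m
          sub$target[sub$target == g$id] <- m
          sub
        }))
        e <- dplyr::bind_rows(e[!gedges, ], inherited)
      }
    }
  }

  node_tb <- node_tb[!node_tb$id %in% drop_nodes, ]
  e <- e[!e$source %in% drop_nodes & !e$target %in% drop_nodes, ]
  e <- e[e$source %in% node_tb$id & e$target %in% node_tb$id, ]
  e <- e[e$source != e$target, ]

  # undirected edges become two directed edges; fold parallels into weight
  if (nrow(e) > 0 && !any(!e$directed) &&
      !anyDuplicated(paste(e$source, e$target, sep = "\r"))) {
    # fast path: already simple and directed
    e <- tibble::tibble(source = e$source, target = e$target,
                        weight = as.numeric(e$multiplicity),
                        relation = e$relation, origin = e$origin)
  } else if (nrow(e) > 0) {
    und <- e[!e$directed, ]
    if (nrow(und) > 0) {
      rev <- und
      rev$source <- und$target; rev$target <- und$source
      e <- dplyr::bind_rows(e[e$directed, ], und, rev)
    }
    e <- e |>
      dplyr::group_by(.data$source, .data$target) |>
      dplyr::summarise(
        weight = as.numeric(sum(.data$multiplicity)),
        relation = if (dplyr::n_distinct(.data$relation) == 1)
          dplyr::first(.data$relation) else "generic",
        origin = list(sort(unique(unlist(.data$origin)))),
        .groups = "drop")
  } else {
    e <- tibble::tibble(source = character(), target = character(),
                        weight = numeric(), relation = character(),
                        origin = list())
  }
  node_tb$origin <- lapply(node_tb$origin, function(o) sort(unique(o)))
  new_flatgraph(node_tb, e, directed = TRUE,
                fingerprint = model_fingerprint(model))
}

#' Convert a flat graph to igraph
#' @param flat A `bnv_flatgraph`.
#' @return An igraph object with edge weights.
#' @export
as_igraph <- function(flat) {
  igraph::graph_from_data_frame(
    flat$edges[, c("source", "target", "weight")], directed = flat$directed,
    vertices = data.frame(name = flat$nodes$id))
}

# ---- path algorithms -------------------------------------------------------

# deterministic Dijkstra on the flat edge list, honouring banned nodes and
# banned edges (keys "u\rv"); ties broken towards lexicographic node ids
dijkstra_path <- function(edges, nodes, source, target,
                          banned_nodes = character(),
                          banned_edges = character()) {
  ids <- setdiff(nodes, banned_nodes)
  if (!source %in% ids || !target %in% ids) return(NULL)
  ekey <- paste(edges$source, edges$target, sep = "\r")
  ee <- edges[!ekey %in% banned_edges & edges$source %in% ids &
                edges$target %in% ids, ]
  adj <- split(seq_len(nrow(ee)), ee$source)
  dist <- stats::setNames(rep(Inf, length(ids)), ids)
  hops <- dist
  prev <- stats::setNames(rep(NA_character_, length(ids)), ids)
  dist[source] <- 0; hops[source] <- 0
  done <- stats::setNames(rep(FALSE, length(ids)), ids)
  repeat {
    open <- ids[!done[ids] & is.finite(dist[ids])]
    if (length(open) == 0) break
    u <- open[order(dist[open], hops[open], open)][1]
    if (u == target) break
    done[u] <- TRUE
    for (j in adj[[u]]) {
      v <- ee$target[j]; w <- dist[u] + ee$weight[j]
      if (w < dist[v] ||
          (w == dist[v] && (hops[u] + 1 < hops[v] ||
                            (hops[u] + 1 == hops[v] &&
                             !is.na(prev[v]) && u < prev[v])))) {
        dist[v] <- w; hops[v] <- hops[u] + 1; prev[v] <- u
      }
    }
  }
  if (!is.finite(dist[target])) return(NULL)
  path <- target
  while (path[1] != source) path <- c(prev[[path[1]]], path)
  list(path = path, weight = unname(dist[target]))
}

path_key <- function(p) paste(p, collapse = "\r")

#' k shortest loopless paths (Yen's algorithm)
#'
#' Paths are returned sorted by (total weight, hop count, lexicographic
#' node sequence); the first is a shortest path. With ties at the k-th
#' weight, every tied path is considered and the ordering key decides.
#' Fewer than `k` paths are returned when fewer exist; an unreachable
#' target yields an empty list.
#'
#' @param flat A `bnv_flatgraph`.
#' @param source,target Distinct node ids in the graph.
#' @param k Number of paths (>= 1).
#' @return List of paths; each a list with `path` (node id vector) and
#'   `weight`.
#' @export
k_shortest_paths <- function(flat, source, target, k = 1) {
  if (!source %in% flat$nodes$id) stop_not_found(source, "node")
  if (!target %in% flat$nodes$id) stop_not_found(target, "node")
  if (source == target) rlang::abort("source and target must differ")
  if (k < 1) rlang::abort("k must be >= 1")
  edges <- flat$edges
  nodes <- flat$nodes$id
  first <- dijkstra_path(edges, nodes, source, target)
  if (is.null(first)) return(list())
  A <- list(first)
  B <- list()
  bkeys <- character()
  full_key <- function(p) list(w = p$weight, h = length(p$path),
                               s = path_key(p$path))
  repeat {
    last <- A[[length(A)]]$path
    for (i in seq_len(length(last) - 1)) {
      spur <- last[i]
      root <- last[seq_len(i)]
      banned_edges <- character()
      for (p in c(A, B)) {
        pp <- p$path
        if (length(pp) > i && identical(pp[seq_len(i)], root))
          banned_edges <- c(banned_edges,
                            paste(pp[i], pp[i + 1], sep = "\r"))
      }
      banned_nodes <- root[-length(root)]
      sp <- dijkstra_path(edges, nodes, spur, target,
                          banned_nodes = banned_nodes,
                          banned_edges = banned_edges)
      if (is.null(sp)) next
      rw <- if (i > 1) sum(vapply(seq_len(i - 1), function(j) {
        hit <- edges$source == last[j] & edges$target == last[j + 1]
        min(edges$weight[hit])
      }, 0)) else 0
      cand <- list(path = c(root[-length(root)], sp$path),
                   weight = rw + sp$weight)
      ck <- path_key(cand$path)
      if (!ck %in% bkeys &&
          !ck %in% vapply(A, function(p) path_key(p$path), "")) {
        B[[length(B) + 1]] <- cand
        bkeys <- c(bkeys, ck)
      }
    }
    if (length(B) == 0) break
    ord <- order(vapply(B, `[[`, 0, "weight"),
                 vapply(B, function(p) length(p$path), 0L),
                 vapply(B, function(p) path_key(p$path), ""))
    nxt <- B[[ord[1]]]
    B <- B[-ord[1]]
    bkeys <- setdiff(bkeys, path_key(nxt$path))
    # gather every path tied with the k-th weight before truncating
    if (length(A) >= k) {
      wk <- sort(vapply(A, `[[`, 0, "weight"))[k]
      if (nxt$weight > wk) break
    }
    A[[length(A) + 1]] <- nxt
  }
  ord <- order(vapply(A, `[[`, 0, "weight"),
               vapply(A, function(p) length(p$path), 0L),
               vapply(A, function(p) path_key(p$path), ""))
  A[ord][seq_len(min(k, length(A)))]
}

#' Breadth-first hop distances
#'
#' @param flat A `bnv_flatgraph`.
#' @param source Node id.
#' @param undirected Ignore edge direction? Default `FALSE` (the flat graph
#'   is directed).
#' @return Named numeric vector of hop distances; unreachable nodes are
#'   absent.
#' @export
bfs_distances <- function(flat, source, undirected = FALSE) {
  if (!source %in% flat$nodes$id) stop_not_found(source, "node")
  g <- as_igraph(flat)
  d <- igraph::distances(g, v = source,
                         mode = if (undirected) "all" else "out",
                         weights = NA)[1, ]
  d <- d[is.finite(d)]
  d[order(names(d))]
}

#' Back-project analysis results onto the visualization
#'
#' Every model component in the origin of a result node or edge receives a
#' highlight colour in a projection-scope property layer (apply with
#' [apply_projection_layer()]). Paths highlight with a single colour;
#' distance maps through a sequential scale with distance 0 darkest.
#'
#' @param model The model the flat graph was produced from.
#' @param flat The `bnv_flatgraph` used for the analysis.
#' @param result Either a path list from [k_shortest_paths()] or a distance
#'   vector from [bfs_distances()].
#' @param color Highlight colour for path results.
#' @return A projection layer (named list id -> property list).
#' @export
backproject <- function(model, flat, result, color = "#FF8C00") {
  if (!identical(flat$fingerprint, model_fingerprint(model)))
    rlang::abort(
      "flat graph is stale: the model changed since flatten_model()",
      class = "bnv_stale_error")
  layer <- list()
  origin_of_node <- stats::setNames(flat$nodes$origin, flat$nodes$id)
  paint <- function(ids, col) {
    for (id in ids) {
      props <- if (id %in% model$edges$id)
        list(stroke_color = col, line_width = 3)
      else list(fill_color = col)
      layer[[id]] <<- utils::modifyList(layer[[id]] %||% list(), props)
    }
  }
  if (is.list(result)) {
    ekey <- paste(flat$edges$source, flat$edges$target, sep = "\r")
    for (p in result) {
      pp <- if (is.list(p)) p$path else p
      paint(unlist(origin_of_node[pp]), color)
      if (length(pp) > 1) {
        keys <- paste(pp[-length(pp)], pp[-1], sep = "\r")
        hit <- match(keys, ekey)
        paint(unlist(flat$edges$origin[hit[!is.na(hit)]]), color)
      }
    }
  } else {
    dmax <- max(result, 1)
    sc <- color_scale(domain = c(0, dmax / 2, dmax),
                      colors = c("#67000D", "#FB6A4A", "#FEE5D9"))
    for (nm in names(result)) {
      paint(unlist(origin_of_node[nm]), scale_color(sc, result[[nm]]))
    }
  }
  layer
}

# ---- tidiers ---------------------------------------------------------------

#' Tidy a flat graph into its edge list
#' @param x A `bnv_flatgraph`.
#' @param ... Unused.
#' @return The edge tibble (source, target, weight, relation, origin).
#' @export
tidy.bnv_flatgraph <- function(x, ...) x$edges

#' One-row flat-graph summary
#' @param x A `bnv_flatgraph`.
#' @param ... Unused.
#' @return A tibble with node/edge counts and directedness.
#' @export
glance.bnv_flatgraph <- function(x, ...) {
  tibble::tibble(nodes = nrow(x$nodes), edges = nrow(x$edges),
                 directed = x$directed)
}
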