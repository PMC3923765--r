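#' Create an empty hierarchical network model
#'
#' The model is a compound graph: leaf entities (proteins, genes, RNAs,
#' compounds, ...) live inside an unbounded tree of groups (complexes,
#' families, pathways, reaction co-factor satellites), connected by typed
#' binary edges and by reaction hyperedges joining substrates, products and
#' catalysts. Visual appearance is resolved through four stacked property
#' layers (built-in defaults < visual style < user override < data
#' projection) so that projected experimental data always shows on top.
#'
#' All modifying verbs (`add_entities()`, `collapse_group()`, ...) are pure:
#' they return a new model and record per-component dirty flags
#' (`topological`, `visual`, `layout`) that drive incremental re-rendering.
#'
#' @return A `bnv_model` object.
#' @export
#' @examples
#' m <- network_model() |>
#'   add_entities(id = c("A", "B"), kind = "protein") |>
#'   add_edges(source = "A", target = "B", relation = "activation")
#' entity_table(m)
network_model <- function() {
  structure(list(
    entities = tibble::tibble(
      id = character(), kind = character(), label = character(),
      xrefs = list(), compartments = list()
    ),
    edges = tibble::tibble(
      id = character(), source = character(), target = character(),
      relation = character(), directed = logical(), multiplicity = integer()
    ),
    groups = tibble::tibble(
      id = character(), semantics = character(), collapsed = logical(),
      own_layout = character(), members = list()
    ),
    reactions = tibble::tibble(
      id = character(), reversible = logical(),
      substrates = list(), products = list(),
      catalysts = list(), cofactors = list()
    ),
    aliases = tibble::tibble(
      instance_id = character(), entity_id = character(),
      context_id = character()
    ),
    parent = character(),           # child id -> enclosing group id
    layers = list(
      style_kinds = list(),         # kind -> list(prop = value)
      style = list(),               # component id -> list(prop = value)
      user_override = list(),
      projection = list()
    ),
    dirty = list(topological = character(), visual = character(),
                 layout = character()),
    counter = 0L
  ), class = "bnv_model")
}

ENTITY_KINDS <- c("protein", "gene", "rna", "compound", "complex", "family",
                  "pathway")
EDGE_RELATIONS <- c("activation", "inhibition", "phosphorylation", "binding",
                    "generic")
GROUP_SEMANTICS <- c("complex", "family", "pathway", "reaction_cofactors",
                     "generic", "star")
PROPERTY_NAMES <- c("label", "shape", "size", "fill_color", "stroke_color",
                    "line_width", "font", "visible", "glyph", "compartments")

#' @export
print.bnv_model <- function(x, ...) {
  cat(sprintf(
    "<bnv_model> %d entities, %d edges, %d groups, %d reactions, %d aliases\n",
    nrow(x$entities), nrow(x$edges), nrow(x$groups), nrow(x$reactions),
    nrow(x$aliases)))
  invisible(x)
}

component_ids <- function(model) {
  c(model$entities$id, model$groups$id, model$reactions$id,
    model$edges$id, model$aliases$instance_id)
}

has_component <- function(model, id) id %in% component_ids(model)

stop_not_found <- function(id, what = "component") {
  rlang::abort(sprintf("%s '%s' not found in model", what, id),
               class = "bnv_not_found")
}

next_id <- function(model, prefix) {
  model$counter <- model$counter + 1L
  list(model = model, id = sprintf("%s%06d", prefix, model$counter))
}

mark_dirty <- function(model, ids, kind) {
  model$dirty[[kind]] <- union(model$dirty[[kind]], ids)
  model
}

#' Clear all dirty flags
#' @param model A `bnv_model`.
#' @return The model with empty dirty sets.
#' @export
clear_dirty <- function(model) {
  model$dirty <- list(topological = character(), visual = character(),
                      layout = character())
  model
}

# ---- construction verbs ----------------------------------------------------

#' Add entities to a model
#'
#' @param model A `bnv_model`.
#' @param id Character vector of unique identifiers.
#' @param kind One of protein, gene, rna, compound, complex, family, pathway
#'   (recycled).
#' @param label Display labels; defaults to the ids.
#' @param xrefs List of character vectors of external accessions, one per
#'   entity.
#' @param compartments List of character vectors of subcellular-location
#'   terms, one per entity (may be empty vectors).
#' @return The updated model.
#' @export
add_entities <- function(model, id, kind = "protein", label = id,
                         xrefs = NULL, compartments = NULL) {
  n <- length(id)
  kind <- rep_len(kind, n)
  label <- rep_len(label, n)
  bad <- setdiff(unique(kind), ENTITY_KINDS)
  if (length(bad) > 0)
    rlang::abort(sprintf("unknown entity kind(s): %s",
                         paste(bad, collapse = ", ")))
  dup <- intersect(id, component_ids(model))
  if (length(dup) > 0)
    rlang::abort(sprintf("duplicate component id(s): %s",
                         paste(utils::head(dup, 5), collapse = ", ")))
  if (anyDuplicated(id))
    rlang::abort("entity ids must be unique")
  if (is.null(xrefs)) xrefs <- rep(list(character()), n)
  if (is.null(compartments)) compartments <- rep(list(character()), n)
  xrefs <- unname(lapply(xrefs, function(x) unname(as.character(x))))
  compartments <- unname(lapply(compartments,
                                function(x) unname(as.character(x))))
  model$entities <- dplyr::bind_rows(model$entities, tibble::tibble(
    id = id, kind = kind, label = label, xrefs = xrefs,
    compartments = compartments))
  mark_dirty(model, id, "topological")
}

#' Add typed binary edges to a model
#'
#' @param model A `bnv_model`.
#' @param source,target Component ids (entities or alias instances).
#' @param relation activation, inhibition, phosphorylation, binding or
#'   generic.
#' @param directed Logical, default `TRUE` (binding edges default to
#'   undirected).
#' @param id Optional edge ids; auto-generated when omitted.
#' @param multiplicity Integer count of underlying relations, default 1.
#' @return The updated model.
#' @export
add_edges <- function(model, source, target, relation = "generic",
                      directed = NULL, id = NULL, multiplicity = 1L) {
  n <- length(source)
  relation <- rep_len(relation, n)
  bad <- setdiff(unique(relation), EDGE_RELATIONS)
  if (length(bad) > 0)
    rlang::abort(sprintf("unknown relation(s): %s", paste(bad, collapse = ", ")))
  if (is.null(directed)) directed <- relation != "binding"
  directed <- rep_len(directed, n)
  multiplicity <- rep_len(as.integer(multiplicity), n)
  known <- component_ids(model)
  missing <- setdiff(c(source, target), known)
  if (length(missing) > 0) stop_not_found(missing[1])
  if (is.null(id)) {
    id <- character(n)
    for (i in seq_len(n)) {
      nx <- next_id(model, "e"); model <- nx$model; id[i] <- nx$id
    }
  }
  model$edges <- dplyr::bind_rows(model$edges, tibble::tibble(
    id = id, source = source, target = target, relation = relation,
    directed = directed, multiplicity = multiplicity))
  mark_dirty(model, id, "topological")
}

#' Add a group (compound node) to a model
#'
#' Groups realise complexes, families, pathways and reaction co-factor
#' satellites; they can be collapsed to a single node. A "star" group is a
#' degenerate group whose members attach radially to its first member (the
#' hub) at layout time.
#'
#' @param model A `bnv_model`.
#' @param id Group id.
#' @param members Character vector of existing component ids (non-empty).
#' @param semantics complex, family, pathway, reaction_cofactors, generic or
#'   star.
#' @param collapsed Start collapsed? Default `FALSE`.
#' @param own_layout Optional layout engine name applied to the members
#'   independently of the surrounding drawing.
#' @return The updated model.
#' @export
add_group <- function(model, id, members, semantics = "generic",
                      collapsed = FALSE, own_layout = NA_character_) {
  if (!semantics %in% GROUP_SEMANTICS)
    rlang::abort(sprintf("unknown group semantics '%s'", semantics))
  if (length(members) == 0) rlang::abort("group members must be non-empty")
  if (has_component(model, id))
    rlang::abort(sprintf("duplicate component id '%s'", id))
  missing <- setdiff(members, component_ids(model))
  if (length(missing) > 0) stop_not_found(missing[1])
  reparent <- members[members %in% names(model$parent)]
  if (length(reparent) > 0)
    rlang::abort(sprintf("component '%s' already has a parent", reparent[1]))
  # cycle check: id must not be among the (future) ancestors of itself
  anc <- id
  while (anc %in% names(model$parent)) {
    anc <- model$parent[[anc]]
    if (anc %in% members)
      rlang::abort("group membership would create a cycle")
  }
  model$groups <- dplyr::bind_rows(model$groups, tibble::tibble(
    id = id, semantics = semantics, collapsed = collapsed,
    own_layout = own_layout, members = list(members)))
  model$parent[members] <- id
  mark_dirty(model, id, "topological")
}

#' Add a reaction hyperedge to a model
#'
#' A reaction joins substrates and products (with stoichiometry), catalysing
#' enzymes, and a subset of participants flagged as co-factors (ubiquitous
#' currency metabolites such as ATP/ADP). Co-factors are wrapped in an
#' auto-created `reaction_cofactors` group holding one alias instance per
#' co-factor, so the same compound can orbit many reactions and the group
#' can be collapsed to hide the co-factors; expanding it re-integrates them
#' into the surrounding layout.
#'
#' @param model A `bnv_model`.
#' @param id Reaction id.
#' @param substrates,products Character vector of entity ids, or a data frame
#'   with columns `entity` and `stoich`. Each must be non-empty.
#' @param catalysts,cofactors Character vectors of entity ids; `cofactors`
#'   must be a subset of the substrate/product entities.
#' @param reversible Logical, default `FALSE`.
#' @return The updated model.
#' @export
add_reaction <- function(model, id, substrates, products,
                         catalysts = character(), cofactors = character(),
                         reversible = FALSE) {
  as_part <- function(x) {
    if (is.data.frame(x)) tibble::tibble(entity = as.character(x$entity),
                                         stoich = as.numeric(x$stoich))
    else tibble::tibble(entity = as.character(x), stoich = 1)
  }
  substrates <- as_part(substrates); products <- as_part(products)
  if (nrow(substrates) == 0 || nrow(products) == 0)
    rlang::abort("a reaction needs at least one substrate and one product")
  if (has_component(model, id))
    rlang::abort(sprintf("duplicate component id '%s'", id))
  parts <- unique(c(substrates$entity, products$entity))
  missing <- setdiff(c(parts, catalysts, cofactors), model$entities$id)
  if (length(missing) > 0) stop_not_found(missing[1], "entity")
  extra <- setdiff(cofactors, parts)
  if (length(extra) > 0)
    rlang::abort(sprintf(
      "co-factor '%s' is not a substrate or product of the reaction",
      extra[1]))
  model$reactions <- dplyr::bind_rows(model$reactions, tibble::tibble(
    id = id, reversible = reversible,
    substrates = list(substrates), products = list(products),
    catalysts = list(catalysts), cofactors = list(cofactors)))
  model <- mark_dirty(model, id, "topological")
  if (length(cofactors) > 0) {
    gid <- paste0(id, "::cofactors")
    inst <- character(length(cofactors))
    for (i in seq_along(cofactors)) {
      nx <- next_id(model, "a"); model <- nx$model; inst[i] <- nx$id
      model$aliases <- dplyr::bind_rows(model$aliases, tibble::tibble(
        instance_id = inst[i], entity_id = cofactors[i], context_id = gid))
    }
    model <- add_group(model, gid, inst, semantics = "reaction_cofactors")
  }
  model
}

# participant entity set of a reaction row (list-of-one-row access)
reaction_participants <- function(model, rid) {
  r <- model$reactions[model$reactions$id == rid, ]
  unique(c(r$substrates[[1]]$entity, r$products[[1]]$entity,
           r$catalysts[[1]]))
}

# ---- accessors (tibble-first surface) --------------------------------------

#' Tabular views of a model
#'
#' @param model A `bnv_model`.
#' @return A tibble of entities, edges, groups, reactions or alias instances.
#' @export
entity_table <- function(model) model$entities

#' @rdname entity_table
#' @export
edge_table <- function(model) model$edges

#' @rdname entity_table
#' @export
group_table <- function(model) model$groups

#' @rdname entity_table
#' @export
reaction_table <- function(model) model$reactions

#' @rdname entity_table
#' @export
alias_table <- function(model) model$aliases

# ---- collapse / expand -----------------------------------------------------

#' Collapse or expand a group
#'
#' Collapsing hides the members from rendering and re-attaches their external
#' edges to the group node, merging parallel re-attached edges into one
#' aggregate edge that carries the number of relations it represents as an
#' integer multiplicity. Expanding restores the member topology exactly
#' (round-trip identity). Collapsing an already-collapsed group (or
#' expanding an expanded one) is a no-op.
#'
#' @param model A `bnv_model`.
#' @param group_id Id of an existing group.
#' @return The updated model, marked topologically dirty.
#' @export
collapse_group <- function(model, group_id) {
  i <- match(group_id, model$groups$id)
  if (is.na(i)) stop_not_found(group_id, "group")
  if (model$groups$collapsed[i]) return(model)
  model$groups$collapsed[i] <- TRUE
  mark_dirty(model, group_id, "topological")
}

#' @rdname collapse_group
#' @export
expand_group <- function(model, group_id) {
  i <- match(group_id, model$groups$id)
  if (is.na(i)) stop_not_found(group_id, "group")
  if (!model$groups$collapsed[i]) return(model)
  model$groups$collapsed[i] <- FALSE
  mark_dirty(model, group_id, "topological")
}

# representative rendered component for each component id: the outermost
# collapsed ancestor group, or the component itself
render_representative <- function(model, ids) {
  collapsed <- model$groups$id[model$groups$collapsed]
  parent <- model$parent
  pn <- names(parent)
  if (length(collapsed) == 0 || length(pn) == 0) return(ids)
  vapply(ids, function(x) {
    rep <- x
    cur <- x
    while (cur %in% pn) {
      cur <- parent[[cur]]
      if (cur %in% collapsed) rep <- cur
    }
    rep
  }, character(1), USE.NAMES = FALSE)
}

# ---- aliasing --------------------------------------------------------------

#' Create an alias instance of an entity
#'
#' Aliasing renders multiple visual instances of one underlying entity in
#' different contexts (e.g. ATP in several pathway groups), reducing edge
#' clutter. Instances can be merged back with [merge_aliases()].
#'
#' @param model A `bnv_model`.
#' @param entity_id An existing entity.
#' @param context_id The group/pathway the instance appears in (or `NA` for
#'   the root context).
#' @return A list with `model` (updated) and `instance_id` (the new id).
#' @export
create_alias <- function(model, entity_id, context_id = NA_character_) {
  if (!entity_id %in% model$entities$id) stop_not_found(entity_id, "entity")
  nx <- next_id(model, "a"); model <- nx$model
  model$aliases <- dplyr::bind_rows(model$aliases, tibble::tibble(
    instance_id = nx$id, entity_id = entity_id, context_id = context_id))
  model <- mark_dirty(model, entity_id, "topological")
  list(model = model, instance_id = nx$id)
}

#' All alias instance ids of an entity
#' @param model A `bnv_model`.
#' @param entity_id An existing entity.
#' @return Character vector of instance ids (possibly empty).
#' @export
highlight_instances <- function(model, entity_id) {
  model$aliases$instance_id[model$aliases$entity_id == entity_id]
}

#' Merge all alias instances of an entity back into one
#'
#' Edges of the merged instances are re-attached to the surviving (first)
#' instance; duplicate edges collapse into one with summed multiplicity.
#' An entity with fewer than two instances is returned unchanged.
#'
#' @param model A `bnv_model`.
#' @param entity_id An existing entity.
#' @return The updated model.
#' @export
merge_aliases <- function(model, entity_id) {
  inst <- highlight_instances(model, entity_id)
  if (length(inst) < 2) return(model)
  keep <- inst[1]; drop <- inst[-1]
  e <- model$edges
  e$source[e$source %in% drop] <- keep
  e$target[e$target %in% drop] <- keep
  model$edges <- merge_parallel_edges(e)
  model$aliases <- model$aliases[!model$aliases$instance_id %in% drop, ]
  model$parent <- model$parent[!names(model$parent) %in% drop]
  model$groups$members <- lapply(model$groups$members, setdiff, y = drop)
  mark_dirty(model, entity_id, "topological")
}

# merge parallel edges (same endpoints + relation + directedness), summing
# multiplicity; first id wins
merge_parallel_edges <- function(e) {
  if (nrow(e) == 0) return(e)
  key <- paste(e$source, e$target, e$relation, e$directed, sep = "\r")
  e |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      id = dplyr::first(.data$id), source = dplyr::first(.data$source),
      target = dplyr::first(.data$target),
      relation = dplyr::first(.data$relation),
      directed = dplyr::first(.data$directed),
      multiplicity = sum(.data$multiplicity), .groups = "drop") |>
    dplyr::select(-".key")
}

# ---- neighborhood expansion ------------------------------------------------

#' Expand the neighborhood of an entity from a reference network
#'
#' Copies all edges incident to `entity_id` in the requested direction from
#' the `source` model (the in-memory database), together with their endpoint
#' entities, into `model`. Existing components are never duplicated, so the
#' operation is idempotent.
#'
#' @param model A `bnv_model` to grow.
#' @param entity_id Entity to expand around (must exist in `model`).
#' @param direction "upstream" (incoming), "downstream" (outgoing) or "both".
#' @param source The reference `bnv_model`.
#' @return The updated model. If the entity is absent from `source`, the
#'   model is returned unchanged with a warning.
#' @export
expand_neighborhood <- function(model, entity_id,
                                direction = c("both", "upstream", "downstream"),
                                source) {
  direction <- match.arg(direction)
  if (!entity_id %in% model$entities$id) stop_not_found(entity_id, "entity")
  if (!entity_id %in% source$entities$id) {
    rlang::warn(sprintf("entity '%s' absent from source network; nothing added",
                        entity_id))
    return(model)
  }
  e <- source$edges
  pick <- switch(direction,
    upstream   = e$target == entity_id,
    downstream = e$source == entity_id,
    both       = e$source == entity_id | e$target == entity_id)
  e <- e[pick, ]
  new_ents <- setdiff(unique(c(e$source, e$target)), component_ids(model))
  if (length(new_ents) > 0) {
    ent <- source$entities[source$entities$id %in% new_ents, ]
    model$entities <- dplyr::bind_rows(model$entities, ent)
    model <- mark_dirty(model, ent$id, "topological")
  }
  e <- e[!e$id %in% model$edges$id, ]
  # drop edges identical to ones already present (by endpoints + relation)
  if (nrow(e) > 0) {
    have <- paste(model$edges$source, model$edges$target, model$edges$relation)
    e <- e[!paste(e$source, e$target, e$relation) %in% have, ]
  }
  if (nrow(e) > 0) {
    model$edges <- dplyr::bind_rows(model$edges, e)
    model <- mark_dirty(model, e$id, "topological")
  }
  model
}

#' Build a radial "star" group
#'
#' A star is a degenerate group whose members attach radially to one hub
#' member at layout time. The first member is the hub.
#'
#' @inheritParams add_group
#' @export
add_star <- function(model, id, members, collapsed = FALSE) {
  add_group(model, id, members, semantics = "star", collapsed = collapsed)
}
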