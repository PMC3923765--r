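# Visual property layering: built-in defaults < visual style < user
# override < data projection. Projections are applied last so that data
# always shows; clearing the projection layer restores the override.

BUILTIN_DEFAULTS <- list(
  label = NULL,               # falls back to the component's label/id
  shape = NULL,               # per-kind, see default_shape()
  size = 30,
  fill_color = "#D0D0D0",
  stroke_color = "#000000",
  line_width = 1,
  font = "sans 10",
  visible = TRUE,
  glyph = NULL,
  compartments = NULL
)

default_shape <- function(kind) {
  switch(kind,
    protein = "roundrect", gene = "rect", rna = "parallelogram",
    compound = "ellipse", complex = "hexagon", family = "octagon",
    pathway = "rect", reaction = "diamond", group = "rect",
    "rect")
}

component_kind <- function(model, id) {
  i <- match(id, model$entities$id)
  if (!is.na(i)) return(model$entities$kind[i])
  if (id %in% model$groups$id) return("group")
  if (id %in% model$reactions$id) return("reaction")
  if (id %in% model$aliases$instance_id) {
    eid <- model$aliases$entity_id[match(id, model$aliases$instance_id)]
    return(component_kind(model, eid))
  }
  if (id %in% model$edges$id) return("edge")
  stop_not_found(id)
}

#' Set a visual style (per-kind property bundle)
#'
#' A style maps component kinds (protein, compound, reaction, group, edge,
#' ...) to property assignments, applied below user overrides.
#'
#' @param model A `bnv_model`.
#' @param style Named list: kind -> named list of property values, e.g.
#'   `list(protein = list(fill_color = "#AABBCC"))`.
#' @return The updated model, all components marked visually dirty.
#' @export
set_style <- function(model, style) {
  bad <- setdiff(unique(unlist(lapply(style, names))), PROPERTY_NAMES)
  if (length(bad) > 0)
    rlang::abort(sprintf("unknown property name(s): %s",
                         paste(bad, collapse = ", ")))
  model$layers$style_kinds <- style
  mark_dirty(model, component_ids(model), "visual")
}

#' Assign a property on a specific layer
#'
#' @param model A `bnv_model`.
#' @param id Component id.
#' @param property One of label, shape, size, fill_color, stroke_color,
#'   line_width, font, visible (plus the extended targets glyph and
#'   compartments used by projections).
#' @param value The value to assign.
#' @param layer "user_override" (default), "style" or "projection".
#' @return The updated model, the component marked visually dirty.
#' @export
set_property <- function(model, id, property, value,
                         layer = c("user_override", "style", "projection")) {
  layer <- match.arg(layer)
  if (!property %in% PROPERTY_NAMES)
    rlang::abort(sprintf("unknown property name '%s'", property))
  if (!has_component(model, id)) stop_not_found(id)
  asg <- model$layers[[layer]]
  if (is.null(asg[[id]])) asg[[id]] <- list()
  asg[[id]][[property]] <- value
  model$layers[[layer]] <- asg
  # visibility decides what is rendered at all, so it is a topological change
  mark_dirty(model, id, if (property == "visible") "topological" else "visual")
}

#' Resolve a component's visual property through the layer stack
#'
#' Looks up `property` in the projection layer, then the user override
#' layer, then the per-component and per-kind style, and finally the
#' built-in defaults — the query is total: it always yields a value.
#'
#' @param model A `bnv_model`.
#' @param id Component id.
#' @param property Property name (see [set_property()]).
#' @return The resolved value.
#' @export
resolve_property <- function(model, id, property) {
  if (!property %in% PROPERTY_NAMES)
    rlang::abort(sprintf("unknown property name '%s'", property))
  for (layer in c("projection", "user_override", "style")) {
    v <- model$layers[[layer]][[id]][[property]]
    if (!is.null(v)) return(v)
  }
  kind <- component_kind(model, id)
  v <- model$layers$style_kinds[[kind]][[property]]
  if (!is.null(v)) return(v)
  v <- BUILTIN_DEFAULTS[[property]]
  if (property == "label" && is.null(v)) {
    i <- match(id, model$entities$id)
    if (!is.na(i)) return(model$entities$label[i])
    if (kind %in% c("protein", "gene", "rna", "compound", "complex",
                    "family", "pathway")) {
      eid <- model$aliases$entity_id[match(id, model$aliases$instance_id)]
      return(model$entities$label[match(eid, model$entities$id)])
    }
    return(id)
  }
  if (property == "shape" && is.null(v)) return(default_shape(kind))
  v
}

#' Remove the projection layer, restoring the prior appearance
#' @param model A `bnv_model`.
#' @return The updated model.
#' @export
clear_projection_layer <- function(model) {
  touched <- names(model$layers$projection)
  had_vis <- names(Filter(function(a) !is.null(a$visible),
                          model$layers$projection))
  model$layers$projection <- list()
  if (length(touched) > 0) model <- mark_dirty(model, touched, "visual")
  if (length(had_vis) > 0) model <- mark_dirty(model, had_vis, "topological")
  model
}

#' Install a projection property layer on a model
#'
#' @param model A `bnv_model`.
#' @param layer A projection layer as returned by [project_series()] or
#'   [backproject()]: a named list component id -> named property list.
#' @return The updated model.
#' @export
apply_projection_layer <- function(model, layer) {
  for (id in names(layer)) {
    for (p in names(layer[[id]])) {
      model <- set_property(model, id, p, layer[[id]][[p]],
                            layer = "projection")
    }
  }
  model
}
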