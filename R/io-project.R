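# Versioned JSON project format: the full visualization state — model
# components, hierarchy, property layers, loaded data series, projection
# specs and node geometry — saved losslessly.

PROJECT_SCHEMA_VERSION <- "1.0"

#' Save / load a complete visualization project as JSON
#'
#' The project document contains the model (components + hierarchy +
#' property layers), all loaded data series, the projection specs applied,
#' and optional node geometry. The round trip through [read_project()] is
#' lossless; the schema is versioned and a version mismatch is an explicit
#' error.
#'
#' @param model A `bnv_model`.
#' @param series List of `bnv_series` objects.
#' @param projections List of projection specs ([projection_spec()]).
#' @param geometry Optional tibble (id, x, y, width, height).
#' @return JSON as a single string.
#' @export
write_project <- function(model, series = list(), projections = list(),
                          geometry = NULL) {
  ser_series <- lapply(series, function(s) list(
    name = s$name, row_ids = lapply(s$row_ids, as.list),
    samples = as.list(s$samples),
    groups = lapply(s$groups, as.list),
    values = apply(s$values, 1, as.list, simplify = FALSE),
    annotations = as.list(s$annotations)))
  doc <- list(
    schema_version = PROJECT_SCHEMA_VERSION,
    model = model_to_list(model),
    series = ser_series,
    projections = lapply(projections, spec_to_list),
    geometry = if (is.null(geometry)) NULL else list(
      id = as.list(geometry$id), x = as.list(geometry$x),
      y = as.list(geometry$y), width = as.list(geometry$width),
      height = as.list(geometry$height)))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                na = "null", digits = I(17)))
}

#' @rdname write_project
#' @param text JSON content (string) or a file path.
#' @return For `read_project()`: a list with `model`, `series`,
#'   `projections` and `geometry`.
#' @export
read_project <- function(text) {
  if (length(text) == 1 && !grepl("{", text, fixed = TRUE) &&
      file.exists(text)) text <- paste(readLines(text, warn = FALSE),
                                       collapse = "\n")
  doc <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  ver <- doc$schema_version
  if (!identical(ver, PROJECT_SCHEMA_VERSION))
    rlang::abort(sprintf(
      "project schema version mismatch: file has '%s', reader supports '%s'",
      ver %||% "<missing>", PROJECT_SCHEMA_VERSION))
  series <- lapply(doc$series, function(s) {
    vals <- do.call(rbind, lapply(s$values, function(r)
      vapply(r, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)))
    if (is.null(vals)) vals <- matrix(numeric(), 0, length(s$samples))
    data_series(vals, lapply(s$row_ids, function(r) as.character(unlist(r))),
                samples = as.character(unlist(s$samples)),
                groups = lapply(s$groups, function(g) as.character(unlist(g))),
                name = s$name,
                annotations = as.character(unlist(s$annotations)))
  })
  projections <- lapply(doc$projections, spec_from_list)
  geometry <- NULL
  if (!is.null(doc$geometry)) {
    g <- doc$geometry
    geometry <- tibble::tibble(
      id = as.character(unlist(g$id)), x = as.numeric(unlist(g$x)),
      y = as.numeric(unlist(g$y)), width = as.numeric(unlist(g$width)),
      height = as.numeric(unlist(g$height)))
  }
  list(model = model_from_list(doc$model), series = series,
       projections = projections, geometry = geometry)
}

# projection specs carry S3-classed scales; remember the class so the
# round trip restores a working spec
spec_to_list <- function(spec) {
  out <- unclass(spec)
  if (!is.null(out$scale) && inherits(out$scale, c("bnv_color_scale",
                                                   "bnv_size_scale"))) {
    cls <- class(out$scale)[1]
    out$scale <- unclass(out$scale)
    out$scale$.class <- cls
  }
  out
}

spec_from_list <- function(p) {
  p <- restore_value(p)
  if (!is.null(p$scale$.class)) {
    cls <- p$scale$.class
    p$scale$.class <- NULL
    p$scale <- structure(p$scale, class = cls)
  }
  structure(p, class = "bnv_projection_spec")
}

model_to_list <- function(model) {
  tb <- function(t, listcols = character()) {
    out <- lapply(names(t), function(nm) {
      col <- t[[nm]]
      if (nm %in% listcols) lapply(col, function(v) {
        if (is.data.frame(v)) lapply(v, as.list) else as.list(v)
      }) else as.list(col)
    })
    stats::setNames(out, names(t))
  }
  list(
    entities = tb(model$entities, c("xrefs", "compartments")),
    edges = tb(model$edges),
    groups = tb(model$groups, "members"),
    reactions = tb(model$reactions,
                   c("substrates", "products", "catalysts", "cofactors")),
    aliases = tb(model$aliases),
    parent = list(child = as.list(names(model$parent)),
                  group = as.list(unname(model$parent))),
    layers = model$layers,
    counter = model$counter)
}

model_from_list <- function(ml) {
  chr <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_character_ else as.character(v), "")
  lgl <- function(x) vapply(x, function(v)
    if (is.null(v)) NA else as.logical(v), TRUE)
  int <- function(x) vapply(x, function(v)
    if (is.null(v)) NA_integer_ else as.integer(v), 0L)
  chrlist <- function(x) lapply(x, function(v) as.character(unlist(v)))
  model <- network_model()
  e <- ml$entities
  model$entities <- tibble::tibble(
    id = chr(e$id), kind = chr(e$kind), label = chr(e$label),
    xrefs = chrlist(e$xrefs), compartments = chrlist(e$compartments))
  d <- ml$edges
  model$edges <- tibble::tibble(
    id = chr(d$id), source = chr(d$source), target = chr(d$target),
    relation = chr(d$relation), directed = lgl(d$directed),
    multiplicity = int(d$multiplicity))
  g <- ml$groups
  model$groups <- tibble::tibble(
    id = chr(g$id), semantics = chr(g$semantics), collapsed = lgl(g$collapsed),
    own_layout = chr(g$own_layout), members = chrlist(g$members))
  r <- ml$reactions
  part <- function(x) lapply(x, function(p) tibble::tibble(
    entity = as.character(unlist(p$entity)),
    stoich = as.numeric(unlist(p$stoich))))
  model$reactions <- tibble::tibble(
    id = chr(r$id), reversible = lgl(r$reversible),
    substrates = part(r$substrates), products = part(r$products),
    catalysts = chrlist(r$catalysts), cofactors = chrlist(r$cofactors))
  a <- ml$aliases
  model$aliases <- tibble::tibble(
    instance_id = chr(a$instance_id), entity_id = chr(a$entity_id),
    context_id = chr(a$context_id))
  model$parent <- if (length(ml$parent$child) == 0) character()
    else stats::setNames(chr(ml$parent$group), chr(ml$parent$child))
  model$layers <- list(
    style_kinds = restore_value(ml$layers$style_kinds) %||% list(),
    style = restore_value(ml$layers$style) %||% list(),
    user_override = restore_value(ml$layers$user_override) %||% list(),
    projection = restore_value(ml$layers$projection) %||% list())
  model$counter <- as.integer(ml$counter)
  model
}

# undo jsonlite's list-of-scalars representation: unnamed lists of atomic
# scalars collapse back to vectors, named lists recurse
restore_value <- function(v) {
  if (!is.list(v)) return(v)
  if (length(v) == 0) return(if (is.null(names(v))) list() else v)
  if (is.null(names(v))) {
    parts <- lapply(v, restore_value)
    if (all(vapply(parts, function(p)
      is.atomic(p) && length(p) == 1 && !is.null(p), TRUE)))
      return(unlist(parts))
    return(parts)
  }
  lapply(v, restore_value)
}
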