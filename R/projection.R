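# Generic omics-projection framework: map identifier-keyed rows onto model
# entities, derive temporary samples (means or formula-based), and turn
# values into visual attributes via configurable scales.

#' Map series rows to model entities
#'
#' A row maps to every entity whose id or xrefs intersect the row's
#' identifier set, optionally after translating the row identifiers through
#' a mapping table. Unmapped rows are a normal outcome and are reported via
#' the `"unmapped"` attribute. The mapping is independent of row order.
#'
#' @param series A `bnv_series`.
#' @param model A `bnv_model`.
#' @param mapping Optional tibble from [read_id_mapping()].
#' @return A tibble with columns `row` (row index) and `entity_id`; zero or
#'   more entities per row.
#' @export
map_rows_to_entities <- function(series, model, mapping = NULL) {
  lookup <- tibble::tibble(
    key = c(model$entities$id, unlist(model$entities$xrefs)),
    entity_id = c(model$entities$id,
                  rep(model$entities$id, lengths(model$entities$xrefs))))
  rows <- tibble::tibble(
    row = rep(seq_along(series$row_ids), lengths(series$row_ids)),
    key = unlist(series$row_ids) %||% character())
  if (!is.null(mapping) && nrow(rows) > 0) {
    extra <- dplyr::inner_join(rows, mapping,
                               by = c(key = "source"),
                               relationship = "many-to-many")
    rows <- dplyr::bind_rows(rows, tibble::tibble(row = extra$row,
                                                  key = extra$target))
  }
  hits <- dplyr::inner_join(rows, lookup, by = "key",
                            relationship = "many-to-many") |>
    dplyr::distinct(.data$row, .data$entity_id) |>
    dplyr::arrange(.data$row, .data$entity_id)
  unmapped <- setdiff(seq_along(series$row_ids), hits$row)
  if (length(unmapped) > 0)
    message(sprintf("projection mapping: %d of %d rows unmapped",
                    length(unmapped), length(series$row_ids)))
  attr(hits, "unmapped") <- unmapped
  hits
}

#' Mean of selected samples
#'
#' Computes a temporary sample holding, per row, the arithmetic mean over
#' the non-missing selected values; a row missing everywhere stays missing.
#' Selecting one sample returns that sample unchanged.
#'
#' @param series A `bnv_series`.
#' @param samples Character vector of sample names (>= 1).
#' @return Named numeric vector, one value per row.
#' @export
mean_sample <- function(series, samples) {
  missing <- setdiff(samples, series$samples)
  if (length(missing) > 0)
    rlang::abort(sprintf("unknown sample '%s'", missing[1]))
  sub <- series$values[, samples, drop = FALSE]
  out <- rowMeans(sub, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

# ---- formula evaluator -----------------------------------------------------

EVAL_FUNCTIONS <- new.env(parent = emptyenv())

#' Register a custom function for the sample-formula evaluator
#'
#' The evaluator ships with mean, log2, log10, abs, min, max and zscore; an
#' external statistical backend can be plugged in by registering additional
#' callables under new names.
#'
#' @param name Function name as used in formulas.
#' @param fn A function of numeric vectors returning a numeric vector.
#' @return Invisibly, the previous binding (or NULL).
#' @export
register_sample_function <- function(name, fn) {
  old <- EVAL_FUNCTIONS[[name]]
  assign(name, fn, envir = EVAL_FUNCTIONS)
  invisible(old)
}

builtin_sample_functions <- function(series) {
  list(
    mean = function(...) {
      m <- cbind(...)
      out <- rowMeans(m, na.rm = TRUE); out[is.nan(out)] <- NA_real_; out
    },
    log2 = function(x) suppressWarnings(log2(x)),
    log10 = function(x) suppressWarnings(log10(x)),
    abs = abs,
    min = function(...) do.call(pmin, c(list(...), na.rm = TRUE)),
    max = function(...) do.call(pmax, c(list(...), na.rm = TRUE)),
    zscore = function(x) {
      mu <- mean(x, na.rm = TRUE); sd <- stats::sd(x, na.rm = TRUE)
      if (is.na(sd) || sd == 0) return(rep(NA_real_, length(x)))
      (x - mu) / sd
    })
}

#' Derive a new sample from a formula
#'
#' Evaluates an arithmetic expression over sample names row-wise. The
#' syntax supports `+ - * / ^`, parentheses, and the built-ins mean, log2,
#' log10, abs, min, max and zscore (zscore normalises over the rows of its
#' argument); further functions can be added with
#' [register_sample_function()]. Any missing operand yields a missing
#' result for that row; division by zero yields missing with a warning.
#' Unknown sample or function names are parse errors naming the token.
#'
#' @param series A `bnv_series`.
#' @param expression Formula text, e.g. `"log2(treated/control)"`.
#' @param name Name for the derived sample (default: the expression).
#' @return The series with the new sample appended (its own group).
#' @export
derive_sample <- function(series, expression, name = expression) {
  expr <- tryCatch(str2lang(expression), error = function(e)
    rlang::abort(sprintf("cannot parse formula '%s': %s", expression,
                         conditionMessage(e))))
  funs <- builtin_sample_functions(series)
  for (nm in ls(EVAL_FUNCTIONS)) funs[[nm]] <- EVAL_FUNCTIONS[[nm]]
  ops <- c("+", "-", "*", "/", "^", "(")
  check <- function(e) {
    if (is.call(e)) {
      fname <- as.character(e[[1]])
      if (!fname %in% ops && !fname %in% names(funs))
        rlang::abort(sprintf("unknown function '%s' in formula", fname))
      lapply(as.list(e)[-1], check)
    } else if (is.name(e)) {
      v <- as.character(e)
      if (!v %in% series$samples)
        rlang::abort(sprintf("unknown sample '%s' in formula", v))
    } else if (!is.numeric(e)) {
      rlang::abort(sprintf("unsupported token '%s' in formula",
                           deparse(e)))
    }
    invisible(NULL)
  }
  check(expr)
  env <- new.env(parent = baseenv())
  for (nm in names(funs)) assign(nm, funs[[nm]], envir = env)
  for (s in series$samples) assign(s, series$values[, s], envir = env)
  vals <- eval(expr, env)
  vals <- rep_len(as.numeric(vals), nrow(series$values))
  if (any(is.infinite(vals) | is.nan(vals))) {
    rlang::warn(sprintf(
      "formula '%s': %d row(s) undefined (division by zero or domain error); set to missing",
      expression, sum(is.infinite(vals) | is.nan(vals))))
    vals[is.infinite(vals) | is.nan(vals)] <- NA_real_
  }
  series$values <- cbind(series$values, stats::setNames(
    data.frame(vals), name) |> as.matrix())
  colnames(series$values)[ncol(series$values)] <- name
  series$samples <- c(series$samples, name)
  series$groups[[name]] <- name
  series
}

# ---- scales ----------------------------------------------------------------

#' Three-anchor diverging colour scale
#'
#' Linear per-RGB-channel interpolation between three anchored colours.
#' The default is the conventional down/neutral/up diverging scale blue -
#' white - red with a domain symmetric about zero.
#'
#' @param domain Numeric (min, mid, max), non-decreasing.
#' @param colors Character (min, mid, max) as `#RRGGBB`.
#' @return A `bnv_color_scale`.
#' @export
color_scale <- function(domain = c(-2, 0, 2),
                        colors = c("#0000FF", "#FFFFFF", "#FF0000")) {
  if (length(domain) != 3 || is.unsorted(domain))
    rlang::abort("scale domain must be non-decreasing (min, mid, max)")
  if (!all(grepl("^#[0-9A-Fa-f]{6}$", colors)))
    rlang::abort("scale colors must be #RRGGBB")
  structure(list(domain = domain, colors = toupper(colors)),
            class = "bnv_color_scale")
}

#' Evaluate a colour scale
#' @param scale A [color_scale()].
#' @param x Numeric values (NA allowed).
#' @return Character vector of `#RRGGBB` colours (`NA` for missing input).
#' @export
scale_color <- function(scale, x) {
  rgb_of <- function(cc) t(grDevices::col2rgb(cc))
  lo <- rgb_of(scale$colors[1]); mi <- rgb_of(scale$colors[2])
  hi <- rgb_of(scale$colors[3])
  d <- scale$domain
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    v <- min(max(v, d[1]), d[3])
    if (v <= d[2]) {
      t <- if (d[2] > d[1]) (v - d[1]) / (d[2] - d[1]) else 1
      ch <- round(lo + t * (mi - lo))
    } else {
      t <- if (d[3] > d[2]) (v - d[2]) / (d[3] - d[2]) else 0
      ch <- round(mi + t * (hi - mi))
    }
    sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
  }, "")
}

#' Linear size / width scale
#' @param domain Numeric (min, max).
#' @param range Output (min, max) in pixels.
#' @return A `bnv_size_scale`.
#' @export
size_scale <- function(domain = c(0, 1), range = c(10, 60)) {
  structure(list(domain = domain, range = range), class = "bnv_size_scale")
}

scale_size <- function(scale, x) {
  d <- scale$domain; r <- scale$range
  t <- (pmin(pmax(x, d[1]), d[2]) - d[1]) / max(d[2] - d[1], .Machine$double.eps)
  r[1] + t * (r[2] - r[1])
}

# ---- projection specs ------------------------------------------------------

#' Describe a data projection
#'
#' @param series Series name.
#' @param samples Sample selection: one or several sample names, or a
#'   one-element character starting with `"="` holding a formula (e.g.
#'   `"=log2(t1/t0)"`). Several names are averaged via [mean_sample()].
#' @param target One of fill_color, node_size, line_width, visibility,
#'   time_series_glyph, compartment, reaction_direction.
#' @param scale A [color_scale()] (fill_color), [size_scale()] (node_size /
#'   line_width), a threshold spec `list(predicate = "abs(x) >= 1")`
#'   (visibility), or a glyph spec `list(kind = "bar", groups = c(...))`
#'   (time_series_glyph).
#' @param missing_policy What unmapped entities do: "default_appearance"
#'   (keep style), "hide", or "neutral_color".
#' @return A `bnv_projection_spec`.
#' @export
projection_spec <- function(series, samples, target, scale = NULL,
                            missing_policy = c("default_appearance", "hide",
                                               "neutral_color")) {
  target <- match.arg(target, c("fill_color", "node_size", "line_width",
                                "visibility", "time_series_glyph",
                                "compartment", "reaction_direction"))
  missing_policy <- match.arg(missing_policy)
  if (is.null(scale)) {
    scale <- switch(target,
      fill_color = color_scale(), node_size = size_scale(),
      line_width = size_scale(range = c(1, 8)),
      visibility = list(predicate = "abs(x) >= 1"),
      time_series_glyph = list(kind = "bar", groups = NULL),
      compartment = list(), reaction_direction = list())
  }
  ok <- switch(target,
    fill_color = inherits(scale, "bnv_color_scale"),
    node_size = , line_width = inherits(scale, "bnv_size_scale"),
    visibility = is.list(scale) && !is.null(scale$predicate),
    time_series_glyph = is.list(scale) && !is.null(scale$kind),
    TRUE)
  if (!ok)
    rlang::abort(sprintf("scale type does not match projection target '%s'",
                         target), class = "bnv_config_error")
  structure(list(series = series, samples = samples, target = target,
                 scale = scale, missing_policy = missing_policy),
            class = "bnv_projection_spec")
}

# per-entity value vector for a spec: mean over samples / formula; rows
# mapping to one entity with multiple values are averaged before scaling
entity_values <- function(series, spec_samples, row_mapping) {
  if (length(spec_samples) == 1 && startsWith(spec_samples, "=")) {
    nm <- "..derived.."
    series <- derive_sample(series, sub("^=", "", spec_samples), name = nm)
    vals <- series$values[, nm]
  } else {
    vals <- mean_sample(series, spec_samples)
  }
  tibble::tibble(row = row_mapping$row, entity_id = row_mapping$entity_id,
                 value = vals[row_mapping$row]) |>
    dplyr::group_by(.data$entity_id) |>
    dplyr::summarise(value = {
      v <- .data$value[!is.na(.data$value)]
      if (length(v) == 0) NA_real_ else mean(v)
    }, .groups = "drop")
}

#' Project a data series onto visual attributes
#'
#' Produces a projection-scope property layer (applied on top of user
#' overrides, see [apply_projection_layer()]): per mapped entity the target
#' attribute is computed from the entity's value through the spec's scale.
#' The visibility target hides entities whose value fails the threshold
#' predicate; unmapped entities follow the spec's missing policy. The
#' reaction_direction target flips the rendered direction of *reversible*
#' reactions whose value is negative; irreversible reactions are never
#' flipped.
#'
#' @param model A `bnv_model`.
#' @param series A `bnv_series` (its name must match the spec's).
#' @param spec A [projection_spec()].
#' @param row_mapping Result of [map_rows_to_entities()]; computed when
#'   omitted.
#' @param mapping Optional identifier-mapping table.
#' @return A projection layer: named list entity id -> property list.
#' @export
project_series <- function(model, series, spec, row_mapping = NULL,
                           mapping = NULL) {
  if (!identical(series$name, spec$series))
    rlang::abort(sprintf("spec expects series '%s', got '%s'", spec$series,
                         series$name), class = "bnv_config_error")
  if (spec$target == "time_series_glyph")
    return(project_time_series(model, series,
                               groups = spec$scale$groups %||%
                                 names(series$groups),
                               kind = spec$scale$kind %||% "bar",
                               row_mapping = row_mapping, mapping = mapping))
  if (is.null(row_mapping))
    row_mapping <- map_rows_to_entities(series, model, mapping)
  ev <- entity_values(series, spec$samples, row_mapping)
  layer <- list()
  for (i in seq_len(nrow(ev))) {
    id <- ev$entity_id[i]; v <- ev$value[i]
    if (is.na(v)) {
      if (spec$missing_policy == "hide") layer[[id]] <- list(visible = FALSE)
      else if (spec$missing_policy == "neutral_color")
        layer[[id]] <- list(fill_color = "#BBBBBB")
      next
    }
    val <- switch(spec$target,
      fill_color = list(fill_color = scale_color(spec$scale, v)),
      node_size = list(size = scale_size(spec$scale, v)),
      line_width = list(line_width = scale_size(spec$scale, v)),
      visibility = list(visible = isTRUE(eval(
        str2lang(spec$scale$predicate), list(x = v, abs = abs)))),
      compartment = list(compartments = as.character(v)),
      reaction_direction = NULL)
    if (!is.null(val)) layer[[id]] <- val
  }
  if (spec$target == "reaction_direction") {
    flip <- ev$entity_id[!is.na(ev$value) & ev$value < 0]
    flip <- intersect(flip, model$reactions$id[model$reactions$reversible])
    for (id in flip) layer[[id]] <- list(glyph = list(kind = "flip"))
  }
  layer
}

#' Project a time series as per-node chart glyphs
#'
#' Per entity, the vector of group means (missing-tolerant, the
#' [mean_sample()] policy) is attached as a glyph drawn instead of the node
#' shape: a small bar or line chart. Unmapped entities keep their default
#' shape.
#'
#' @param model A `bnv_model`.
#' @param series A `bnv_series`.
#' @param groups Ordered group names to plot (default: all series groups).
#' @param kind "bar" or "line".
#' @param row_mapping,mapping See [project_series()].
#' @return A projection layer with a `glyph` property per mapped entity.
#' @export
project_time_series <- function(model, series, groups = names(series$groups),
                                kind = c("bar", "line"), row_mapping = NULL,
                                mapping = NULL) {
  kind <- match.arg(kind)
  if (any(lengths(series$groups[groups]) == 0) ||
      !all(groups %in% names(series$groups)))
    rlang::abort("every glyph group must exist and be non-empty")
  if (is.null(row_mapping))
    row_mapping <- map_rows_to_entities(series, model, mapping)
  gm <- vapply(groups, function(g) mean_sample(series, series$groups[[g]]),
               numeric(nrow(series$values)))
  gm <- matrix(gm, nrow = nrow(series$values),
               dimnames = list(NULL, groups))
  layer <- list()
  for (id in unique(row_mapping$entity_id)) {
    rows <- row_mapping$row[row_mapping$entity_id == id]
    v <- colMeans(gm[rows, , drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    layer[[id]] <- list(glyph = list(kind = kind, groups = groups,
                                     values = unname(v)))
  }
  layer
}

#' Compartment-annotation ambiguity colour
#'
#' Encodes the reliability of a subcellular-location annotation: exactly
#' one annotated compartment is unambiguous (red), two or more is ambiguous
#' (rose), none means no information (white).
#'
#' @param compartments Character vector of compartment terms (or a
#'   one-row slice of `entity_table()`).
#' @param palette Colours for (unambiguous, ambiguous, none).
#' @return A `#RRGGBB` colour.
#' @export
compartment_ambiguity_color <- function(compartments,
                                        palette = c("#FF0000", "#FFC0CB",
                                                    "#FFFFFF")) {
  if (is.data.frame(compartments)) compartments <- compartments$compartments[[1]]
  n <- length(unique(compartments))
  if (n == 1) palette[1] else if (n >= 2) palette[2] else palette[3]
}
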