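# SIF (simple interaction format, Cytoscape dialect) import.
# One interaction per line: `source relation target [target ...]`.
# The delimiter is tab when the line contains any tab, otherwise runs of
# spaces. Multi-target lines expand pairwise. How each relation-type string
# is translated into the model is configurable.

#' SIF relation-translation configuration
#'
#' Maps relation-type strings found in a SIF file to model actions:
#' `"edge:<relation>"` creates a typed edge (activation, inhibition,
#' phosphorylation, binding, generic), `"complex_membership"` collects the
#' two endpoints into a complex group (connected membership lines form one
#' complex), `"reaction_cofactor"` attaches the source as a satellite
#' co-factor of the target, and `"ignore"` drops the line.
#'
#' @param map Named character vector, relation type -> action.
#' @param default Action for relation types absent from `map`.
#' @return A `bnv_sif_config` list.
#' @export
sif_config <- function(map = c(activation = "edge:activation",
                               inhibition = "edge:inhibition",
                               phosphorylation = "edge:phosphorylation",
                               pp = "edge:generic",
                               pd = "edge:activation",
                               complex = "complex_membership",
                               cofactor = "reaction_cofactor"),
                       default = "edge:generic") {
  ok <- function(a) a == "ignore" || a == "complex_membership" ||
    a == "reaction_cofactor" ||
    (startsWith(a, "edge:") && sub("^edge:", "", a) %in% EDGE_RELATIONS)
  bad <- Filter(Negate(ok), c(map, default))
  if (length(bad) > 0)
    rlang::abort(sprintf("invalid SIF action(s): %s",
                         paste(unique(bad), collapse = ", ")))
  structure(list(map = map, default = default), class = "bnv_sif_config")
}

#' Read a SIF interaction file into a network model
#'
#' Entities are created on their first mention. Duplicate identical
#' interactions collapse to a single edge. Lines with exactly one token
#' create isolated entities (standard SIF); lines with two tokens are
#' skipped with a warning.
#'
#' @param text SIF content as a single string or character vector of lines,
#'   or a file path.
#' @param config A [sif_config()]; the default translates the common
#'   relation vocabulary.
#' @param mapping Optional identifier-mapping table (see
#'   [read_id_mapping()]): raw SIF identifiers are translated to canonical
#'   ids before entity creation, and a `kind` column (if present) sets the
#'   entity kind (otherwise protein).
#' @return A `bnv_model`. The numbers of entities and flat edges are
#'   reported via `message()` and attached as the `"sif_stats"` attribute.
#' @export
read_sif <- function(text, config = sif_config(), mapping = NULL) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  has_tab <- grepl("\t", lines, fixed = TRUE)
  toks <- vector("list", length(lines))
  toks[has_tab] <- strsplit(lines[has_tab], "\t", fixed = TRUE)
  toks[!has_tab] <- strsplit(trimws(lines[!has_tab]), " +")
  toks <- lapply(toks, function(x) trimws(x)[nzchar(trimws(x))])
  nt <- lengths(toks)
  if (any(nt == 2)) {
    rlang::warn(sprintf("skipped %d SIF line(s) with 2 tokens", sum(nt == 2)))
  }
  singles <- unlist(toks[nt == 1], use.names = FALSE)
  inter <- toks[nt >= 3]
  # pairwise expansion of multi-target lines
  src <- rep(vapply(inter, `[[`, "", 1), vapply(inter, length, 0L) - 2L)
  rel <- rep(vapply(inter, `[[`, "", 2), vapply(inter, length, 0L) - 2L)
  tgt <- unlist(lapply(inter, function(x) x[-(1:2)]), use.names = FALSE)

  # identifier mapping (first match wins for many-to-many)
  kind_of <- NULL
  if (!is.null(mapping)) {
    mp <- mapping[!duplicated(mapping$source), ]
    translate <- function(x) {
      i <- match(x, mp$source)
      ifelse(is.na(i), x, mp$target[i])
    }
    src <- translate(src); tgt <- translate(tgt)
    singles <- translate(singles)
    if ("kind" %in% names(mp))
      kind_of <- stats::setNames(mp$kind, mp$target)
  }

  act <- unname(config$map[rel])
  act[is.na(act)] <- config$default

  is_edge <- startsWith(act, "edge:")
  is_cplx <- act == "complex_membership"
  is_cof <- act == "reaction_cofactor"

  ids <- unique(c(src[!act == "ignore"], tgt[!act == "ignore"], singles))
  kinds <- rep("protein", length(ids))
  if (!is.null(kind_of)) {
    k <- kind_of[ids]
    kinds[!is.na(k)] <- k[!is.na(k)]
  }
  model <- network_model()
  model <- add_entities(model, ids, kind = kinds)

  # edges: dedupe identical (source, relation, target) triples
  if (any(is_edge)) {
    er <- sub("^edge:", "", act[is_edge])
    ed <- tibble::tibble(source = src[is_edge], target = tgt[is_edge],
                         relation = er)
    ed <- dplyr::distinct(ed)
    n <- nrow(ed)
    eid <- sprintf("e%06d", model$counter + seq_len(n))
    model$counter <- model$counter + n
    model$edges <- dplyr::bind_rows(model$edges, tibble::tibble(
      id = eid, source = ed$source, target = ed$target,
      relation = ed$relation, directed = ed$relation != "binding",
      multiplicity = 1L))
    model <- mark_dirty(model, eid, "topological")
  }

  # complex membership: connected components of membership pairs
  if (any(is_cplx)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = src[is_cplx], to = tgt[is_cplx]), directed = FALSE)
    comp <- igraph::components(g)
    memb <- split(names(comp$membership), comp$membership)
    memb <- memb[order(vapply(memb, min, ""))]
    for (i in seq_along(memb)) {
      model <- add_group(model, sprintf("complex:%03d", i),
                         sort(memb[[i]]), semantics = "complex")
    }
  }

  # co-factor satellites: source orbits target as an aliased co-factor
  if (any(is_cof)) {
    for (tg in unique(tgt[is_cof])) {
      cof <- unique(src[is_cof & tgt == tg])
      inst <- character(length(cof))
      gid <- paste0(tg, "::sif_cofactors")
      for (j in seq_along(cof)) {
        al <- create_alias(model, cof[j], gid)
        model <- al$model; inst[j] <- al$instance_id
      }
      model <- add_group(model, gid, inst, semantics = "reaction_cofactors")
      model <- add_edges(model, inst, rep(tg, length(inst)), "generic")
    }
  }

  stats <- c(entities = nrow(model$entities), edges = nrow(model$edges))
  message(sprintf("SIF import: %d entities, %d edges", stats[1], stats[2]))
  attr(model, "sif_stats") <- stats
  model
}

#' Read a two-column identifier-mapping table
#'
#' A TSV with columns `source` and `target` (header optional; an optional
#' third column `kind` carries entity kinds). Many-to-many rows are kept.
#'
#' @param text TSV content or a file path.
#' @return A tibble with columns `source`, `target` and optionally `kind`.
#' @export
read_id_mapping <- function(text) {
  lines <- as_lines(text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) rlang::abort("empty mapping table")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  first <- parts[[1]]
  has_header <- identical(tolower(first[1:2]), c("source", "target"))
  if (has_header) parts <- parts[-1]
  nc <- max(lengths(parts))
  tb <- tibble::tibble(
    source = vapply(parts, `[[`, "", 1),
    target = vapply(parts, `[[`, "", 2))
  if (nc >= 3)
    tb$kind <- vapply(parts, function(x) if (length(x) >= 3) x[3] else
      NA_character_, "")
  if (any(!nzchar(tb$source)) || any(!nzchar(tb$target)))
    rlang::abort("mapping table contains empty identifiers")
  tb
}

# read a string (possibly with newlines), character vector of lines, or file
as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  if (length(text) == 1) return(strsplit(text, "\n", fixed = TRUE)[[1]])
  text
}
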