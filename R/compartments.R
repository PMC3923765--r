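# Layered cell model: an ordered list of compartment bands (extracellular at
# the top, nucleus at the bottom, matching the textbook cell drawing) plus a
# term-alias map translating free-text subcellular-location terms (GO
# cellular-component style) to bands.

#' An ordered compartment (cell-layer) model
#'
#' @param layers Ordered layer names, top of the drawing first.
#' @param term_map Named character vector mapping location terms to layer
#'   names; every target must be a layer.
#' @param fallback Layer for nodes with no mapped term (default cytoplasm,
#'   or the middle layer if absent).
#' @return A `bnv_compartment_model`.
#' @export
compartment_model <- function(layers = c("extracellular", "plasma_membrane",
                                         "cytoplasm", "nuclear_membrane",
                                         "nucleus"),
                              term_map = default_term_map(),
                              fallback = NULL) {
  if (anyDuplicated(layers)) rlang::abort("layer names must be unique")
  bad <- setdiff(unique(term_map), layers)
  if (length(bad) > 0)
    rlang::abort(sprintf("term map targets unknown layer(s): %s",
                         paste(bad, collapse = ", ")))
  if (is.null(fallback))
    fallback <- if ("cytoplasm" %in% layers) "cytoplasm"
      else layers[ceiling(length(layers) / 2)]
  structure(list(layers = layers, term_map = term_map, fallback = fallback),
            class = "bnv_compartment_model")
}

default_term_map <- function() {
  c("extracellular" = "extracellular",
    "extracellular region" = "extracellular",
    "extracellular space" = "extracellular",
    "secreted" = "extracellular",
    "plasma_membrane" = "plasma_membrane",
    "plasma membrane" = "plasma_membrane",
    "cell membrane" = "plasma_membrane",
    "membrane" = "plasma_membrane",
    "cytoplasm" = "cytoplasm", "cytosol" = "cytoplasm",
    "mitochondrion" = "cytoplasm", "endoplasmic reticulum" = "cytoplasm",
    "golgi apparatus" = "cytoplasm",
    "nuclear_membrane" = "nuclear_membrane",
    "nuclear envelope" = "nuclear_membrane",
    "nuclear membrane" = "nuclear_membrane",
    "nucleus" = "nucleus", "nucleoplasm" = "nucleus",
    "nucleolus" = "nucleus", "chromatin" = "nucleus")
}

#' Load a compartment model from a YAML or JSON file
#'
#' The document has keys `layers` (ordered list), `term_map` (mapping) and
#' optionally `fallback`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `bnv_compartment_model`.
#' @export
read_compartment_model <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::fromJSON(path, simplifyVector = TRUE)
  compartment_model(layers = unlist(doc$layers),
                    term_map = unlist(doc$term_map),
                    fallback = doc$fallback)
}

#' Assign compartment layers to model components
#'
#' Each node's location terms are mapped through the compartment model's
#' term map; when several terms map to different layers the topmost layer
#' in the ordered list wins, and the number of distinct mapped layers is
#' reported as the node's ambiguity count. Terms absent from the map are
#' ignored (counted as unmapped); a node with no mapped term falls back to
#' the configured fallback layer with ambiguity 0.
#'
#' @param model A `bnv_model`.
#' @param cm A [compartment_model()].
#' @return A tibble with columns id, layer (1-based index, 1 = top),
#'   layer_name, ambiguity, unmapped_terms.
#' @export
assign_layers <- function(model, cm = compartment_model()) {
  fallback_idx <- match(cm$fallback, cm$layers)
  res <- lapply(seq_len(nrow(model$entities)), function(i) {
    terms <- model$entities$compartments[[i]]
    mapped <- cm$term_map[terms]
    unmapped <- sum(is.na(mapped))
    mapped <- mapped[!is.na(mapped)]
    idx <- unique(match(mapped, cm$layers))
    if (length(idx) == 0)
      c(layer = fallback_idx, ambiguity = 0L, unmapped = unmapped)
    else
      c(layer = min(idx), ambiguity = length(idx), unmapped = unmapped)
  })
  m <- do.call(rbind, res)
  if (is.null(m)) m <- matrix(integer(), 0, 3)
  tibble::tibble(
    id = model$entities$id,
    layer = as.integer(m[, 1]),
    layer_name = cm$layers[m[, 1]],
    ambiguity = as.integer(m[, 2]),
    unmapped_terms = as.integer(m[, 3]))
}
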