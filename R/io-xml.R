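# KGML (KEGG XML), SBML core subset, and GraphML import/export via xml2.

#' Read a KGML (KEGG XML) pathway file
#'
#' Entries become entities (enzymes/genes as proteins, compounds as
#' compounds, linked maps as pathways), reaction elements become reaction
#' hyperedges with the entries whose `reaction` attribute names them as
#' catalysts, and relation elements become edges. KGML carries node
#' positions but no edge routes, so each entry's graphics element is
#' returned as a layout hint (top-left-anchored pixel coordinates, y
#' increasing downward) for [layout_kegg()], which computes the routes.
#' An entry that references several KEGG ids keeps them all as xrefs on one
#' entity.
#'
#' @param xml KGML content as a string or a file path.
#' @return A list with `model` (a `bnv_model`) and `hints` (a tibble with
#'   columns id, x, y, width, height — one row per entry with graphics).
#' @export
read_kgml <- function(xml) {
  doc <- read_xml_input(xml)
  xml2::xml_ns_strip(doc)
  entries <- xml2::xml_find_all(doc, ".//entry")
  eid <- xml2::xml_attr(entries, "id")
  etype <- xml2::xml_attr(entries, "type")
  enames <- xml2::xml_attr(entries, "name")
  ereact <- xml2::xml_attr(entries, "reaction")
  kind <- dplyr::case_match(etype,
    c("enzyme", "gene", "ortholog") ~ "protein",
    "compound" ~ "compound",
    "map" ~ "pathway",
    "group" ~ "complex",
    .default = "protein")
  gr <- lapply(entries, function(e) xml2::xml_find_first(e, "./graphics"))
  glabel <- vapply(gr, function(g)
    if (inherits(g, "xml_missing")) NA_character_
    else xml2::xml_attr(g, "name"), "")
  num_attr <- function(a) vapply(gr, function(g)
    if (inherits(g, "xml_missing")) NA_real_
    else suppressWarnings(as.numeric(xml2::xml_attr(g, a))), 0)
  hints <- tibble::tibble(id = eid, x = num_attr("x"), y = num_attr("y"),
                          width = num_attr("width"), height = num_attr("height"))
  hints <- hints[!is.na(hints$x) & !is.na(hints$y), ]
  if (any(hints$x < 0 | hints$y < 0, na.rm = TRUE))
    rlang::abort("KGML graphics coordinates must be non-negative")

  label <- ifelse(is.na(glabel) | !nzchar(glabel),
                  sub(" .*", "", enames), sub(",.*", "", glabel))
  model <- network_model()
  model <- add_entities(model, eid, kind = kind, label = label,
                        xrefs = strsplit(enames, " +"))

  reactions <- xml2::xml_find_all(doc, ".//reaction")
  for (r in reactions) {
    rname <- xml2::xml_attr(r, "name")
    rid <- xml2::xml_attr(r, "id")
    if (is.na(rid)) rid <- rname
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "id")
    prod <- xml2::xml_attr(xml2::xml_find_all(r, "./product"), "id")
    cata <- eid[!is.na(ereact) &
                  vapply(strsplit(ereact, " +"),
                         function(x) rname %in% x, TRUE)]
    if (length(subs) == 0 || length(prod) == 0) next
    model <- add_reaction(model, paste0("rx:", rid), subs, prod,
                          catalysts = cata,
                          reversible = identical(xml2::xml_attr(r, "type"),
                                                 "reversible"))
  }

  rels <- xml2::xml_find_all(doc, ".//relation")
  if (length(rels) > 0) {
    r1 <- xml2::xml_attr(rels, "entry1")
    r2 <- xml2::xml_attr(rels, "entry2")
    sub1 <- vapply(rels, function(r) {
      s <- xml2::xml_find_first(r, "./subtype")
      if (inherits(s, "xml_missing")) NA_character_ else xml2::xml_attr(s, "name")
    }, "")
    relation <- dplyr::case_match(sub1,
      "activation" ~ "activation", "inhibition" ~ "inhibition",
      "phosphorylation" ~ "phosphorylation", "binding/association" ~ "binding",
      .default = "generic")
    keep <- r1 %in% model$entities$id & r2 %in% model$entities$id
    if (any(keep))
      model <- add_edges(model, r1[keep], r2[keep], relation[keep])
  }
  list(model = clear_dirty(model), hints = hints)
}

#' Read an SBML core subset (species + reactions)
#'
#' Supports SBML Level 2/3 core: listOfCompartments, listOfSpecies and
#' listOfReactions with reactants, products and modifiers. Species become
#' entities annotated with their compartment's name; reactions become
#' reaction hyperedges with modifiers as catalysts and the `reversible`
#' flag honoured. Rules, events and other constructs are ignored with a
#' logged count.
#'
#' @param xml SBML content as a string or a file path.
#' @return A `bnv_model`.
#' @export
read_sbml_subset <- function(xml) {
  doc <- read_xml_input(xml)
  xml2::xml_ns_strip(doc)
  comps <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  cmap <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comps, "name")),
           xml2::xml_attr(comps, "id"), xml2::xml_attr(comps, "name")),
    xml2::xml_attr(comps, "id"))
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sid <- xml2::xml_attr(sp, "id")
  sname <- xml2::xml_attr(sp, "name")
  scomp <- xml2::xml_attr(sp, "compartment")
  comp_terms <- lapply(scomp, function(cc) {
    if (is.na(cc)) character() else unname(cmap[cc])
  })
  model <- network_model()
  model <- add_entities(model, sid, kind = "compound",
                        label = ifelse(is.na(sname), sid, sname),
                        compartments = comp_terms)
  unsupported <- length(xml2::xml_find_all(
    doc, ".//listOfRules/* | .//listOfEvents/*"))
  if (unsupported > 0)
    message(sprintf("SBML import: ignored %d unsupported construct(s)",
                    unsupported))
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  for (r in rx) {
    part <- function(path) {
      refs <- xml2::xml_find_all(r, path)
      tibble::tibble(
        entity = xml2::xml_attr(refs, "species"),
        stoich = {
          s <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
          ifelse(is.na(s), 1, s)
        })
    }
    subs <- part("./listOfReactants/speciesReference")
    prod <- part("./listOfProducts/speciesReference")
    mods <- xml2::xml_attr(
      xml2::xml_find_all(r, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    if (nrow(subs) == 0 || nrow(prod) == 0) next
    rev <- xml2::xml_attr(r, "reversible")
    model <- add_reaction(model, xml2::xml_attr(r, "id"), subs, prod,
                          catalysts = mods,
                          reversible = identical(rev, "true"))
  }
  clear_dirty(model)
}

# ---- GraphML ---------------------------------------------------------------

#' Write a flat graph as GraphML 1.0
#'
#' Node attributes (label, origin) and edge attributes (relation, weight,
#' multiplicity, origin) are declared as GraphML keys. The output round
#' trips losslessly through [read_graphml()].
#'
#' @param flat A `bnv_flatgraph` (see [flatten_model()]).
#' @return GraphML as a single string.
#' @export
write_graphml <- function(flat) {
  esc <- xml_escape
  n <- flat$nodes; e <- flat$edges
  keys <- paste0(
    '  <key id="d0" for="node" attr.name="label" attr.type="string"/>\n',
    '  <key id="d1" for="node" attr.name="origin" attr.type="string"/>\n',
    '  <key id="d2" for="edge" attr.name="relation" attr.type="string"/>\n',
    '  <key id="d3" for="edge" attr.name="weight" attr.type="double"/>\n',
    '  <key id="d4" for="edge" attr.name="multiplicity" attr.type="int"/>\n',
    '  <key id="d5" for="edge" attr.name="origin" attr.type="string"/>\n')
  node_xml <- if (nrow(n) == 0) "" else paste0(
    '    <node id="', esc(n$id), '">',
    '<data key="d0">',
    esc(if ("label" %in% names(n)) n$label else n$id), '</data>',
    '<data key="d1">', esc(vapply(n$origin, paste, "", collapse = ";")),
    '</data></node>\n', collapse = "")
  edge_xml <- if (nrow(e) == 0) "" else paste0(
    '    <edge source="', esc(e$source), '" target="', esc(e$target), '">',
    '<data key="d2">',
    esc(if ("relation" %in% names(e)) e$relation
        else rep("generic", nrow(e))), '</data>',
    '<data key="d3">', format(e$weight, digits = 15, scientific = FALSE,
                              trim = TRUE), '</data>',
    '<data key="d4">',
    if ("multiplicity" %in% names(e)) e$multiplicity else rep(1L, nrow(e)),
    '</data>',
    '<data key="d5">', esc(vapply(e$origin, paste, "", collapse = ";")),
    '</data></edge>\n', collapse = "")
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">\n', keys,
         '  <graph id="G" edgedefault="',
         if (isTRUE(flat$directed)) "directed" else "undirected", '">\n',
         node_xml, edge_xml, "  </graph>\n</graphml>\n")
}

#' Read GraphML written by [write_graphml()]
#' @param xml GraphML content as a string or a file path.
#' @return A `bnv_flatgraph`.
#' @export
read_graphml <- function(xml) {
  doc <- read_xml_input(xml)
  xml2::xml_ns_strip(doc)
  keyel <- xml2::xml_find_all(doc, ".//key")
  keytab <- data.frame(id = xml2::xml_attr(keyel, "id"),
                       name = xml2::xml_attr(keyel, "attr.name"),
                       scope = xml2::xml_attr(keyel, "for"))
  get_data <- function(el, name, scope) {
    ids <- keytab$id[keytab$name == name & keytab$scope == scope]
    if (length(ids) == 0) return(NA_character_)
    d <- xml2::xml_find_first(el, sprintf("./data[@key='%s']", ids[1]))
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nodes <- xml2::xml_find_all(doc, ".//node")
  edges <- xml2::xml_find_all(doc, ".//edge")
  split_origin <- function(x) {
    lapply(x, function(s) if (is.na(s) || !nzchar(s)) character()
           else strsplit(s, ";", fixed = TRUE)[[1]])
  }
  nt <- tibble::tibble(
    id = xml2::xml_attr(nodes, "id"),
    label = vapply(nodes, get_data, "", name = "label", scope = "node"),
    origin = split_origin(vapply(nodes, get_data, "", name = "origin",
                                 scope = "node")))
  et <- tibble::tibble(
    source = xml2::xml_attr(edges, "source"),
    target = xml2::xml_attr(edges, "target"),
    relation = vapply(edges, get_data, "", name = "relation",
                      scope = "edge"),
    weight = as.numeric(vapply(edges, get_data, "", name = "weight",
                               scope = "edge")),
    multiplicity = as.integer(vapply(edges, get_data, "",
                                     name = "multiplicity", scope = "edge")),
    origin = split_origin(vapply(edges, get_data, "", name = "origin",
                                 scope = "edge")))
  et$weight[is.na(et$weight)] <- 1
  et$multiplicity[is.na(et$multiplicity)] <- 1L
  g <- xml2::xml_find_first(doc, ".//graph")
  new_flatgraph(nt, et,
                directed = !identical(xml2::xml_attr(g, "edgedefault"),
                                      "undirected"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

read_xml_input <- function(xml) {
  if (length(xml) == 1 && !grepl("<", xml, fixed = TRUE) && file.exists(xml))
    xml2::read_xml(xml)
  else xml2::read_xml(paste(xml, collapse = "\n"))
}
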