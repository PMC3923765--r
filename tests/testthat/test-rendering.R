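test_that("expanded reactions build the bipartite structure", {
  m <- network_model() |>
    add_entities(c("S1", "S2", "P1"), kind = "compound") |>
    add_entities("E1", kind = "protein")
  m <- add_reaction(m, "R1", c("S1", "S2"), "P1", catalysts = "E1")
  rg <- build_topology(m)
  # 2 substrates + 1 product + 1 reaction node + 1 enzyme
  expect_equal(nrow(rg$nodes), 5)
  expect_equal(nrow(rg$edges), 4)
  expect_setequal(rg$edges$source[rg$edges$directed],
                  c("S1", "S2", "R1"))
  # catalyst edge is undirected
  expect_equal(sum(!rg$edges$directed), 1)
  # empty model -> empty render graph
  empty <- build_topology(network_model())
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("collapsing the co-factor group hides co-factors inside it", {
  m <- reaction_model()
  open_rg <- build_topology(m)
  cof_inst <- alias_table(m)$instance_id
  expect_true(all(cof_inst %in% open_rg$nodes$id))
  closed <- collapse_group(m, "R1::cofactors")
  rg <- build_topology(closed)
  expect_false(any(cof_inst %in% rg$nodes$id))
  expect_true("R1::cofactors" %in% rg$nodes$id)
  # expanding re-integrates the co-factors
  rg2 <- build_topology(expand_group(closed, "R1::cofactors"))
  expect_identical(rg2$nodes$id, open_rg$nodes$id)
})

test_that("attribute assignment resolves styles and projections per element", {
  m <- fan_model()
  m <- set_style(m, list(protein = list(fill_color = "#AABBCC")))
  rg <- assign_attributes(build_topology(m), m)
  prot <- rg$nodes[rg$nodes$kind == "protein", ]
  expect_true(all(prot$fill_color == "#AABBCC"))
  m2 <- set_property(m, "A", "fill_color", "#00FF00", layer = "projection")
  rg2 <- assign_attributes(build_topology(m2), m2)
  expect_equal(rg2$nodes$fill_color[rg2$nodes$id == "A"], "#00FF00")
  # no layers -> built-in defaults everywhere
  m3 <- fan_model()
  rg3 <- assign_attributes(build_topology(m3), m3)
  expect_true(all(rg3$nodes$fill_color == "#D0D0D0"))
})

test_that("step 2 never alters topology and step 3 never alters attributes", {
  m <- reaction_model()
  rg1 <- build_topology(m)
  rg2 <- assign_attributes(rg1, m)
  expect_identical(rg2$nodes$id, rg1$nodes$id)
  expect_identical(rg2$edges[, c("id", "source", "target")],
                   rg1$edges[, c("id", "source", "target")])
  rg3 <- apply_layout(rg2, m, "force", list(seed = 1))
  attr_cols <- c("label", "shape", "size", "fill_color", "stroke_color",
                 "line_width", "font")
  expect_identical(rg3$nodes[attr_cols], rg2$nodes[attr_cols])
})

test_that("a group's own layout applies to its members inside the parent drawing", {
  m <- network_model() |>
    add_entities(c("out1", "out2")) |>
    add_entities(c("gm1", "gm2", "gm3"),
                 compartments = list("plasma membrane", "cytoplasm",
                                     "nucleus")) |>
    add_edges(c("gm1", "gm2", "out1"), c("gm2", "gm3", "gm1")) |>
    add_group("grp", c("gm1", "gm2", "gm3"), own_layout = "layered")
  res <- render_network(m, "force", list(seed = 6))
  g <- res$graph$nodes
  y <- stats::setNames(g$y, g$id)
  expect_true(y[["gm1"]] < y[["gm2"]])
  expect_true(y[["gm2"]] < y[["gm3"]])
})

test_that("re-rendering without changes reproduces identical geometry", {
  m <- gen_regulatory_model(10, seed = 2)$model
  a <- render_network(m, "force", list(seed = 3))$graph
  b <- render_network(m, "force", list(seed = 3))$graph
  expect_render_equal(a, b)
})

test_that("visual-only edits update incrementally without re-running step 1", {
  m <- gen_regulatory_model(10, seed = 2)$model
  full <- render_network(m, "layered")
  m <- full$model; rg <- full$graph
  stamp1 <- rg$stamps$topology
  m <- set_property(m, m$entities$id[2], "fill_color", "#224488")
  inc <- incremental_update(m, rg)
  expect_equal(inc$stamps$topology, stamp1)
  expect_render_equal(inc, render_network(m, "layered")$graph)
  # no dirt -> returned unchanged
  m <- clear_dirty(m)
  expect_identical(incremental_update(m, inc), inc)
})

test_that("topological edits (collapse) update incrementally to the full-rebuild result", {
  m <- gen_regulatory_model(10, seed = 2)$model
  m <- add_group(m, "blob", m$entities$id[1:3], semantics = "complex")
  full <- render_network(m, "force", list(seed = 8))
  m <- full$model; rg <- full$graph
  m <- collapse_group(m, "blob")
  inc <- incremental_update(m, rg)
  expect_render_equal(inc, render_network(m, "force", list(seed = 8))$graph)
})

test_that("SVG output is valid, styled, and deterministic", {
  m <- add_entities(network_model(), "solo")
  m <- set_property(m, "solo", "fill_color", "#FF0000")
  res <- render_network(m, "force", list(seed = 1))
  svg <- render_svg(res$graph)
  doc <- xml2::read_xml(svg)  # parses => well-formed
  expect_match(svg, 'fill="#FF0000"')
  expect_equal(xml2::xml_name(doc), "svg")

  # reaction arrows are quadratic Bezier paths
  rx <- render_network(reaction_model(), "force", list(seed = 2))
  svg_rx <- render_svg(rx$graph)
  expect_match(svg_rx, '<path d="M [-0-9.]+ [-0-9.]+ Q ')

  # empty graph -> valid SVG with no shapes
  svg_empty <- render_svg(build_topology(network_model()) |>
                            (\(x) { x$stamps$layout <- 1L; x })())
  expect_equal(length(xml2::xml_find_all(xml2::read_xml(svg_empty), ".//*")), 0)

  # byte-for-byte determinism
  expect_identical(svg, render_svg(render_network(m, "force",
                                                  list(seed = 1))$graph))
  # un-laid-out graph is a state error
  expect_error(render_svg(build_topology(fan_model())),
               class = "bnv_state_error")
})

test_that("aggregate-edge multiplicity appears as an edge label", {
  m <- collapse_group(fan_model(), "G")
  res <- render_network(m, "force", list(seed = 1))
  expect_match(render_svg(res$graph), ">x3</text>")
})

test_that("compartment bands appear as background strips after a layered run", {
  m <- gen_regulatory_model(8, seed = 4)$model
  svg <- render_svg(render_network(m, "layered")$graph)
  expect_match(svg, 'class="band"')
  expect_match(svg, ">nucleus</text>")
  svg_off <- render_svg(render_network(m, "layered")$graph, bands = FALSE)
  expect_false(grepl('class="band"', svg_off))
})
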