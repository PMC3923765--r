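test_that("construction enforces the model invariants", {
  m <- network_model()
  expect_error(add_entities(m, "A", kind = "enzymoid"), "unknown entity kind")
  m <- add_entities(m, c("A", "B"))
  expect_error(add_entities(m, "A"), "duplicate")
  expect_error(add_edges(m, "A", "Z"), class = "bnv_not_found")
  expect_error(add_group(m, "G", character()), "non-empty")
  m <- add_group(m, "G", c("A", "B"))
  expect_error(add_group(m, "G2", c("A")), "already has a parent")
  expect_error(add_reaction(add_entities(m, "S"), "R", "S", character()),
               "at least one substrate and one product")
  # co-factors must be participants
  m2 <- add_entities(network_model(), c("S", "P", "ATP"), kind = "compound")
  expect_error(add_reaction(m2, "R", "S", "P", cofactors = "ATP"),
               "not a substrate or product")
})

test_that("collapsing a group aggregates external edges with multiplicity", {
  m <- collapse_group(fan_model(), "G")
  rg <- build_topology(m)
  expect_setequal(rg$nodes$id, c("G", "X"))
  expect_equal(nrow(rg$edges), 1)
  expect_equal(rg$edges$multiplicity, 3L)
  expect_setequal(rg$edges$origin_ids[[1]], edge_table(fan_model())$id)
  # aggregate-edge conservation: multiplicity sum == original external edges
  expect_equal(sum(rg$edges$multiplicity), 3)
  # no external edges -> collapsed node with no edges
  m2 <- network_model() |> add_entities(c("A", "B")) |>
    add_edges("A", "B") |> add_group("G", c("A", "B")) |>
    collapse_group("G")
  rg2 <- build_topology(m2)
  expect_equal(rg2$nodes$id, "G")
  expect_equal(nrow(rg2$edges), 0)
})

test_that("collapse/expand is a render-topology round trip and a no-op when repeated", {
  m <- fan_model()
  before <- build_topology(m)
  round <- build_topology(expand_group(collapse_group(m, "G"), "G"))
  expect_identical(before$nodes, round$nodes)
  expect_identical(before$edges, round$edges)
  expect_identical(collapse_group(collapse_group(m, "G"), "G"),
                   collapse_group(m, "G"))
  expect_identical(expand_group(m, "G"), m)
  expect_error(collapse_group(m, "nope"), class = "bnv_not_found")
  # collapse marks the group topologically dirty
  expect_true("G" %in% collapse_group(m, "G")$dirty$topological)
})

test_that("aliasing creates instances, highlights them, and merges back", {
  m <- add_entities(network_model(), c("ATP", "R1", "R2"))
  a1 <- create_alias(m, "ATP", "ctx1"); m <- a1$model
  a2 <- create_alias(m, "ATP", "ctx2"); m <- a2$model
  expect_equal(nrow(alias_table(m)), 2)
  expect_equal(nrow(entity_table(m)), 3)
  expect_setequal(highlight_instances(m, "ATP"),
                  c(a1$instance_id, a2$instance_id))
  expect_error(create_alias(m, "nope"), class = "bnv_not_found")

  # disjoint edges -> union on the surviving instance
  m <- add_edges(m, c(a1$instance_id, a2$instance_id), c("R1", "R2"))
  mm <- merge_aliases(m, "ATP")
  expect_equal(nrow(alias_table(mm)), 1)
  expect_equal(nrow(edge_table(mm)), 2)
  expect_setequal(edge_table(mm)$source, a1$instance_id)

  # identical duplicate edge -> one edge, multiplicity 2
  m2 <- add_entities(network_model(), c("ATP", "R1"))
  b1 <- create_alias(m2, "ATP"); m2 <- b1$model
  b2 <- create_alias(m2, "ATP"); m2 <- b2$model
  m2 <- add_edges(m2, c(b1$instance_id, b2$instance_id), c("R1", "R1"),
                  "generic")
  mm2 <- merge_aliases(m2, "ATP")
  expect_equal(nrow(edge_table(mm2)), 1)
  expect_equal(edge_table(mm2)$multiplicity, 2L)

  # single instance -> no-op
  m3 <- add_entities(network_model(), "X")
  expect_identical(merge_aliases(m3, "X"), m3)
})

test_that("alias conservation: merging every entity's instances restores the flat entity set", {
  set.seed(7)
  m <- add_entities(network_model(), sprintf("e%d", 1:6))
  for (e in c("e1", "e1", "e3", "e5")) m <- create_alias(m, e)$model
  for (e in unique(entity_table(m)$id)) m <- merge_aliases(m, e)
  # every entity has at most one instance left; entity set unchanged
  expect_setequal(entity_table(m)$id, sprintf("e%d", 1:6))
  expect_true(all(table(alias_table(m)$entity_id) <= 1))
})

test_that("neighborhood expansion is directional, idempotent, and warns on unknown entities", {
  src <- network_model() |>
    add_entities(c("N", "u1", "u2", "d1", "d2", "d3")) |>
    add_edges(c("u1", "u2"), c("N", "N"), "activation") |>
    add_edges(c("N", "N", "N"), c("d1", "d2", "d3"), "inhibition")
  m <- add_entities(network_model(), "N")
  up <- expand_neighborhood(m, "N", "upstream", src)
  expect_equal(nrow(edge_table(up)), 2)
  expect_setequal(entity_table(up)$id, c("N", "u1", "u2"))
  down <- expand_neighborhood(m, "N", "downstream", src)
  expect_equal(nrow(edge_table(down)), 3)
  both <- expand_neighborhood(m, "N", "both", src)
  expect_equal(nrow(edge_table(both)), 5)
  expect_identical(expand_neighborhood(both, "N", "both", src)$edges,
                   both$edges)
  # isolated node in source -> unchanged
  iso <- add_entities(network_model(), "Z")
  srcz <- add_entities(src, "Z")
  expect_equal(nrow(edge_table(expand_neighborhood(iso, "Z", "both", srcz))), 0)
  expect_warning(expand_neighborhood(iso, "Z", "both", src), "absent")
})

test_that("property resolution is total and layered default < style < override < projection", {
  m <- add_entities(network_model(), "A", kind = "protein")
  expect_equal(resolve_property(m, "A", "fill_color"), "#D0D0D0")
  expect_equal(resolve_property(m, "A", "shape"), "roundrect")
  expect_error(resolve_property(m, "A", "bogus"), "unknown property")

  m <- set_style(m, list(protein = list(fill_color = "#AABBCC")))
  expect_equal(resolve_property(m, "A", "fill_color"), "#AABBCC")
  m <- set_property(m, "A", "fill_color", "#111111")
  expect_equal(resolve_property(m, "A", "fill_color"), "#111111")
  m <- set_property(m, "A", "fill_color", "#FF0000", layer = "projection")
  expect_equal(resolve_property(m, "A", "fill_color"), "#FF0000")
  # clearing the projection restores the override
  m <- clear_projection_layer(m)
  expect_equal(resolve_property(m, "A", "fill_color"), "#111111")

  # totality across every property for every layer combination
  for (p in c("label", "shape", "size", "fill_color", "stroke_color",
              "line_width", "font", "visible")) {
    expect_false(is.null(resolve_property(m, "A", p)))
  }
})

test_that("hierarchy rejects cycles and supports unbounded nesting", {
  m <- add_entities(network_model(), c("a", "b", "c"))
  m <- add_group(m, "g1", c("a", "b"))
  m <- add_group(m, "g2", c("g1", "c"))
  m <- add_group(m, "g3", "g2")
  expect_equal(unname(m$parent[["g2"]]), "g3")
  expect_error(add_group(m, "g0", c("g3", "g0")), class = "bnv_not_found")
  # collapsing an outer group hides the whole subtree
  rg <- build_topology(collapse_group(m, "g3"))
  expect_equal(rg$nodes$id, "g3")
})

test_that("star groups place members radially around their hub", {
  m <- add_entities(network_model(), c("hub", "s1", "s2", "s3"))
  m <- add_star(m, "st", c("hub", "s1", "s2", "s3"))
  res <- render_network(m, "force", list(seed = 4))
  g <- res$graph$nodes
  hub <- g[g$id == "hub", ]
  spokes <- g[g$id %in% c("s1", "s2", "s3"), ]
  d <- sqrt((spokes$x - hub$x)^2 + (spokes$y - hub$y)^2)
  expect_true(all(abs(d - 80) < 1e-6))
})
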