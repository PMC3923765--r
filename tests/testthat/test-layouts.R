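test_that("layer assignment: topmost mapped term wins, ambiguity counted, fallback applies", {
  cm <- compartment_model()
  m <- add_entities(network_model(), c("n1", "n2", "n3", "n4"),
                    compartments = list("nucleus",
                                        c("nucleus", "cytoplasm"),
                                        character(),
                                        c("weird term", "nucleus")))
  la <- assign_layers(m, cm)
  expect_equal(la$layer_name[la$id == "n1"], "nucleus")
  expect_equal(la$ambiguity[la$id == "n1"], 1L)
  # cytoplasm is above nucleus in the cell model: topmost wins
  expect_equal(la$layer_name[la$id == "n2"], "cytoplasm")
  expect_equal(la$ambiguity[la$id == "n2"], 2L)
  expect_equal(la$layer_name[la$id == "n3"], "cytoplasm")  # fallback
  expect_equal(la$ambiguity[la$id == "n3"], 0L)
  expect_equal(la$unmapped_terms[la$id == "n4"], 1L)
  expect_error(compartment_model(layers = c("a", "a")), "unique")
  expect_error(compartment_model(term_map = c(x = "nowhere")), "unknown layer")
})

test_that("layered layout keeps strict band order and beats or matches the initial crossings", {
  # K2,2: brute-force minimum crossings is the oracle
  nodes <- tibble::tibble(id = c("t1", "t2", "b1", "b2"), width = 20,
                          height = 10)
  edges <- tibble::tibble(id = sprintf("e%d", 1:4),
                          source = c("t1", "t1", "t2", "t2"),
                          target = c("b1", "b2", "b1", "b2"))
  lm <- c(t1 = 1, t2 = 1, b1 = 2, b2 = 2)
  lay <- layout_layered(nodes, edges, lm)
  got <- count_crossings_from_layout(lay, edges)
  best <- min_crossings_2layer(c("t1", "t2"), c("b1", "b2"), edges)
  expect_equal(best, 1)  # K2,2 always has >= 1 crossing
  expect_lte(got, best + 0)  # barycenter reaches the brute-force minimum
  # strict band separation for all edges spanning layers
  ys <- stats::setNames(lay$nodes$y, lay$nodes$id)
  expect_true(all(ys[edges$source] < ys[edges$target]))
  # single node centres in its band
  single <- layout_layered(tibble::tibble(id = "s", width = 10, height = 10),
                           edges[0, ], c(s = 1), band_height = 120)
  expect_equal(single$nodes$y, 60)
})

test_that("a membrane-to-nucleus cascade renders as a monotone downward drawing", {
  m <- network_model() |>
    add_entities(c("REC", "KIN", "TF"),
                 compartments = list("plasma membrane", "cytoplasm",
                                     "nucleus")) |>
    add_edges(c("REC", "KIN"), c("KIN", "TF"), "activation")
  res <- render_network(m, "layered")
  g <- res$graph$nodes
  y <- stats::setNames(g$y, g$id)
  expect_true(y[["REC"]] < y[["KIN"]])
  expect_true(y[["KIN"]] < y[["TF"]])
  expect_equal(res$graph$bands$name,
               compartment_model()$layers)
})

test_that("edges spanning several layers route through dummy points inside each band", {
  nodes <- tibble::tibble(id = c("top", "bot", "mid"), width = 20, height = 10)
  edges <- tibble::tibble(id = "e1", source = "top", target = "bot")
  lay <- layout_layered(nodes, edges, c(top = 1, mid = 2, bot = 3),
                        band_height = 100)
  r <- lay$edges$route[[1]]
  expect_equal(nrow(r), 3)            # start, one dummy, end
  expect_true(r[2, 2] > 100 && r[2, 2] < 200)
})

test_that("force layout is seed-deterministic and keeps connected nodes near the ideal length", {
  nodes <- tibble::tibble(id = c("a", "b"), width = 20, height = 14)
  edges <- tibble::tibble(id = "e1", source = "a", target = "b")
  l1 <- layout_force(nodes, edges, seed = 5, ideal_edge_length = 80)
  l2 <- layout_force(nodes, edges, seed = 5, ideal_edge_length = 80)
  expect_identical(l1$nodes, l2$nodes)
  d <- sqrt(diff(l1$nodes$x)^2 + diff(l1$nodes$y)^2)
  expect_gte(d, 0.5 * 80)
  expect_lte(d, 2.0 * 80)
})

test_that("consumed co-factors sit on the incoming side of the reaction flow", {
  # left-to-right reaction: substrate at the left, product at the right
  nodes <- tibble::tibble(id = c("S", "R1", "P", "cofS", "cofP"),
                          width = 20, height = 14)
  edges <- tibble::tibble(id = sprintf("e%d", 1:4),
                          source = c("S", "R1", "cofS", "R1"),
                          target = c("R1", "P", "R1", "cofP"))
  sat <- tibble::tibble(node = c("cofS", "cofP"), reaction = "R1",
                        side = c("substrate", "product"))
  lay <- layout_force(nodes, edges, seed = 3, satellites = sat,
                      cofactor_orbit_radius = 40)
  g <- lay$nodes
  xr <- g$x[g$id == "R1"]; xs <- g$x[g$id == "S"]; xp <- g$x[g$id == "P"]
  flow_right <- xp > xs
  cofs <- g$x[g$id == "cofS"]; cofp <- g$x[g$id == "cofP"]
  if (flow_right) {
    expect_lt(cofs, xr)
    expect_gt(cofp, xr)
  } else {
    expect_gt(cofs, xr)
    expect_lt(cofp, xr)
  }
  # satellites sit on the orbit radius
  expect_equal(sqrt((cofs - xr)^2 + (g$y[g$id == "cofS"] - g$y[g$id == "R1"])^2),
               40, tolerance = 1e-6)
})

test_that("KEGG layout preserves hints exactly, routes around obstacles, falls back without hints", {
  nodes <- tibble::tibble(id = c("a", "b", "wall"), width = 30, height = 20)
  edges <- tibble::tibble(id = "e1", source = "a", target = "b")
  hints <- tibble::tibble(id = c("a", "b", "wall"),
                          x = c(0, 200, 100), y = c(0, 0, 0),
                          width = c(30, 30, 30), height = c(20, 20, 20))
  lay <- layout_kegg(nodes, edges, hints)
  g <- lay$nodes
  expect_equal(g$x[match(c("a", "b", "wall"), g$id)], c(0, 200, 100))
  expect_equal(g$y[match(c("a", "b", "wall"), g$id)], c(0, 0, 0))
  # straight route would pierce the wall: must be a bent orthogonal route
  expect_equal(lay$edges$curve, "orthogonal")
  r <- lay$edges$route[[1]]
  for (s in seq_len(nrow(r) - 1)) {
    expect_false(bionetviz:::seg_crosses_rect(r[s, ], r[s + 1, ], 100, 0,
                                              30, 20))
  }
  # no obstacle -> all routes straight
  lay2 <- layout_kegg(nodes[1:2, ], edges, hints[1:2, ])
  expect_equal(lay2$edges$curve, "straight")
  expect_warning(layout_kegg(nodes, edges, hints[0, ]), "falling back")
})

test_that("no two node bodies overlap in any engine's output", {
  g <- gen_regulatory_model(25, seed = 13)$model
  for (engine in c("force", "layered")) {
    res <- render_network(g, engine, list(seed = 2))
    expect_no_overlaps(res$graph$nodes)
  }
  kg <- read_kgml(gen_metabolic_kgml(6, seed = 4)$kgml)
  res <- render_network(kg$model, "kegg", list(hints = kg$hints, seed = 2))
  expect_no_overlaps(res$graph$nodes)
})

test_that("layouts are bit-for-bit deterministic for identical input and seed", {
  g <- gen_regulatory_model(15, seed = 21)$model
  for (engine in c("force", "layered")) {
    a <- render_network(g, engine, list(seed = 9))$graph
    b <- render_network(g, engine, list(seed = 9))$graph
    expect_identical(a$nodes, b$nodes)
    expect_identical(a$edges, b$edges)
  }
})

test_that("compartment models load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("layers: [outside, inside]",
               "term_map:", "  out: outside", "  in: inside",
               "fallback: inside"), path)
  cm <- read_compartment_model(path)
  expect_equal(cm$layers, c("outside", "inside"))
  expect_equal(unname(cm$term_map["out"]), "outside")
  expect_equal(cm$fallback, "inside")
})
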