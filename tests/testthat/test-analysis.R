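test_that("families split into members that inherit every family edge", {
  m <- network_model() |>
    add_entities(c("f1", "f2", "f3", "x", "y")) |>
    add_group("FAM", c("f1", "f2", "f3"), semantics = "family")
  m <- add_edges(m, c("FAM", "x"), c("x", "FAM"), "activation")
  m <- add_edges(m, "FAM", "y", "inhibition")
  fl <- flatten_model(m, flattening_policy(family_mode = "split_into_members"))
  # 3 members x 3 family edges
  expect_equal(sum(vapply(fl$edges$origin, function(o)
    any(startsWith(o, "e")), TRUE)), 9)
  expect_false("FAM" %in% fl$nodes$id)
  # members' origins name both the member and the family group
  f1o <- fl$nodes$origin[[match("f1", fl$nodes$id)]]
  expect_setequal(f1o, c("f1", "FAM"))
  # single_node keeps one node carrying all members in its origin
  fl2 <- flatten_model(m, flattening_policy(family_mode = "single_node"))
  expect_true("FAM" %in% fl2$nodes$id)
  expect_setequal(fl2$nodes$origin[[match("FAM", fl2$nodes$id)]],
                  c("FAM", "f1", "f2", "f3"))
})

test_that("reaction flattening: bipartite keeps reaction nodes, s2p makes pair edges", {
  m <- add_entities(network_model(), c("s1", "s2", "p1", "p2"),
                    kind = "compound")
  m <- add_reaction(m, "R1", c("s1", "s2"), c("p1", "p2"))
  bi <- flatten_model(m, flattening_policy(reaction_mode = "bipartite"))
  expect_true("R1" %in% bi$nodes$id)
  expect_equal(nrow(bi$edges), 4)
  s2p <- flatten_model(m, flattening_policy(
    reaction_mode = "substrate_to_product_edges"))
  expect_false("R1" %in% s2p$nodes$id)
  expect_equal(nrow(s2p$edges), 4)  # 2 substrates x 2 products
  expect_true(all(vapply(s2p$edges$origin, function(o) "R1" %in% o, TRUE)))
})

test_that("co-factors can be excluded and cliques expand complexes", {
  m <- reaction_model()
  keep <- flatten_model(m, flattening_policy(include_cofactors = TRUE))
  drop <- flatten_model(m, flattening_policy(include_cofactors = FALSE))
  expect_true(all(c("ATP", "ADP") %in% keep$nodes$id))
  expect_false(any(c("ATP", "ADP") %in% drop$nodes$id))

  mc <- network_model() |>
    add_entities(c("a", "b", "c")) |>
    add_group("CPX", c("a", "b", "c"), semantics = "complex")
  cl <- flatten_model(mc, flattening_policy(complex_mode = "clique"))
  expect_equal(nrow(cl$edges), 6)  # 3 pairs x 2 directions
  st <- flatten_model(mc, flattening_policy(complex_mode = "star_to_members"))
  expect_true("CPX" %in% st$nodes$id)
  expect_equal(nrow(st$edges), 6)  # hub-spoke undirected -> both directions
})

test_that("the identity policy on a flat model reproduces the input graph", {
  m <- triangle_model()
  fl <- flatten_model(m, flattening_policy())
  expect_setequal(fl$nodes$id, c("A", "B", "C"))
  expect_equal(nrow(fl$edges), 3)
  expect_identical(tidy(fl), fl$edges)
  expect_equal(glance(fl)$nodes, 3)
})

test_that("flatten conservation: split+merge preserves the leaf entity set", {
  m <- gen_regulatory_model(15, seed = 6)$model
  m <- add_group(m, "fam", m$entities$id[1:4], semantics = "family")
  a <- create_alias(m, m$entities$id[6]); m <- a$model
  fl <- flatten_model(m, flattening_policy(
    family_mode = "split_into_members", alias_mode = "merge_instances"))
  leaves <- setdiff(unique(unlist(fl$nodes$origin)),
                    c(group_table(m)$id, reaction_table(m)$id))
  expect_setequal(leaves, entity_table(m)$id)
})

test_that("flatten is insensitive to component insertion order", {
  build <- function(order) {
    m <- add_entities(network_model(), order)
    add_edges(m, c("A", "B"), c("B", "C"), id = c("E1", "E2"))
  }
  f1 <- flatten_model(build(c("A", "B", "C")), flattening_policy())
  f2 <- flatten_model(build(c("C", "B", "A")), flattening_policy())
  expect_identical(f1$nodes, f2$nodes)
  expect_identical(f1$edges, f2$edges)
})

test_that("k shortest paths on the triangle match the hand enumeration", {
  fl <- flatten_model(triangle_model(), flattening_policy())
  ps <- k_shortest_paths(fl, "A", "C", k = 2)
  expect_equal(length(ps), 2)
  expect_equal(unname(ps[[1]]$path), c("A", "C"))
  expect_equal(ps[[1]]$weight, 1)
  expect_equal(unname(ps[[2]]$path), c("A", "B", "C"))
  expect_equal(ps[[2]]$weight, 2)
  # k larger than the number of paths: return what exists
  expect_equal(length(k_shortest_paths(fl, "A", "C", k = 10)), 2)
  # unreachable -> empty, unknown -> error, same node -> error
  expect_equal(k_shortest_paths(fl, "C", "A", k = 1), list())
  expect_error(k_shortest_paths(fl, "A", "zz", 1), class = "bnv_not_found")
  expect_error(k_shortest_paths(fl, "A", "A", 1), "must differ")
})

test_that("k=1 matches an independent shortest-path search on random graphs", {
  set.seed(99)
  for (i in 1:40) {
    m <- random_flat_model(6, p = 0.35)
    fl <- flatten_model(m, flattening_policy())
    ids <- fl$nodes$id
    st <- sample(ids, 2)
    oracle <- enumerate_simple_paths(fl$edges, st[1], st[2])
    got <- k_shortest_paths(fl, st[1], st[2], k = 1)
    if (length(oracle) == 0) {
      expect_equal(length(got), 0)
    } else {
      expect_equal(unname(got[[1]]$path), unname(oracle[[1]]$path))
      expect_equal(got[[1]]$weight, oracle[[1]]$weight)
    }
  }
})

test_that("BFS distances match a queue oracle and respect direction flags", {
  m <- network_model() |> add_entities(c("a", "b", "c", "d")) |>
    add_edges(c("a", "b", "c"), c("b", "c", "d"))
  fl <- flatten_model(m, flattening_policy())
  d <- bfs_distances(fl, "a")
  expect_equal(unname(d[c("a", "b", "c", "d")]), c(0, 1, 2, 3))
  # direction respected: nothing upstream of a, everything with --undirected
  expect_equal(names(bfs_distances(fl, "d")), "d")
  expect_equal(length(bfs_distances(fl, "d", undirected = TRUE)), 4)
  expect_error(bfs_distances(fl, "zz"), class = "bnv_not_found")
  set.seed(17)
  for (i in 1:20) {
    mm <- random_flat_model(7, p = 0.3)
    ffl <- flatten_model(mm, flattening_policy())
    s <- sample(ffl$nodes$id, 1)
    expect_equal(bfs_distances(ffl, s), bfs_oracle(ffl$edges, s, ffl$nodes$id))
  }
})

test_that("back-projection highlights the origins of path results", {
  m <- network_model() |>
    add_entities(c("f1", "f2", "s", "t")) |>
    add_group("FAM", c("f1", "f2"), semantics = "family")
  m <- add_edges(m, c("s", "FAM"), c("FAM", "t"), id = c("E1", "E2"))
  fl <- flatten_model(m, flattening_policy(
    family_mode = "split_into_members"))
  ps <- k_shortest_paths(fl, "s", "t", k = 1)
  layer <- backproject(m, fl, ps, color = "#FF8C00")
  # the member on the path and its family group are both highlighted
  expect_equal(layer$f1$fill_color, "#FF8C00")
  expect_equal(layer$FAM$fill_color, "#FF8C00")
  expect_equal(layer$E1$stroke_color, "#FF8C00")
  # empty path list -> empty layer
  expect_length(backproject(m, fl, list()), 0)
})

test_that("distance maps back-project through a sequential scale, darkest at zero", {
  fl <- flatten_model(triangle_model(), flattening_policy())
  d <- bfs_distances(fl, "A")
  layer <- backproject(triangle_model(), fl, d)
  expect_equal(layer$A$fill_color, "#67000D")
  lum <- function(cc) sum(grDevices::col2rgb(cc))
  expect_true(lum(layer$A$fill_color) < lum(layer$C$fill_color))
})

test_that("a stale flat graph is rejected by back-projection", {
  m <- triangle_model()
  fl <- flatten_model(m, flattening_policy())
  m2 <- add_entities(m, "newcomer")
  expect_error(backproject(m2, fl, list()), class = "bnv_stale_error")
})
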