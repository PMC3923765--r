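test_that("read_table handles CSV/TSV/SOFT dialects, missing cells and id sets", {
  s <- read_table("id\ts1\ts2\nP1\t1\t2\nP2\t\t4\nP3\t5\t6", "tsv")
  expect_equal(dim(s$values), c(3, 2))
  expect_equal(sum(is.na(s$values)), 1)

  soft <- paste(
    "!Series_title = test", "!Sample_count = 2", "!platform = x",
    "!extra = 1", "!more = 2",
    "!sample_table_begin",
    "ID\tGSM1\tGSM2", "r1\t1\t2", "r2\t3\t4", "r3\t5\t6", "r4\t7\t8",
    "!sample_table_end", sep = "\n")
  ss <- read_table(soft, "soft")
  expect_equal(nrow(ss$values), 4)
  expect_equal(length(ss$annotations), 5)

  cs <- read_table("id,s1\n\"P1;P2\",3", "csv")
  expect_setequal(cs$row_ids[[1]], c("P1", "P2"))

  expect_error(read_table("id\ts1\nP1\tabc", "tsv"), "no numeric column")
  dup <- read_table("id\ts1\nP1\t1\nP1\t2", "tsv")
  expect_equal(nrow(dup$values), 2)
  expect_equal(attr(dup, "duplicate_rows"), "P1")
})

test_that("rows map to entities through ids, xrefs, and the mapping table", {
  m <- add_entities(network_model(), c("E1", "E2"),
                    xrefs = list("P1", character()))
  s <- data_series(matrix(1:3, 3), list("P1", "X9", "E2"))
  hit <- suppressMessages(map_rows_to_entities(s, m))
  expect_equal(hit$entity_id[hit$row == 1], "E1")
  expect_equal(hit$entity_id[hit$row == 3], "E2")
  expect_equal(attr(hit, "unmapped"), 2L)
  map <- tibble::tibble(source = "X9", target = "P1")
  hit2 <- suppressMessages(map_rows_to_entities(s, m, map))
  expect_equal(hit2$entity_id[hit2$row == 2], "E1")
  # permutation invariance
  s_rev <- data_series(matrix(3:1, 3), list("E2", "X9", "P1"))
  hit3 <- suppressMessages(map_rows_to_entities(s_rev, m, map))
  expect_setequal(paste(s$row_ids[hit2$row], hit2$entity_id),
                  paste(s_rev$row_ids[hit3$row], hit3$entity_id))
})

test_that("mean_sample averages non-missing values and passes single samples through", {
  s <- data_series(matrix(c(2, 5, NA, 4, NA, NA), 3),
                   list("a", "b", "c"), samples = c("s1", "s2"))
  m <- mean_sample(s, c("s1", "s2"))
  expect_equal(unname(m), c(3, 5, NA))
  expect_equal(mean_sample(s, "s1"), s$values[, "s1"])
  expect_error(mean_sample(s, "zz"), "unknown sample")
  # k identical samples: mean equals the sample
  sk <- data_series(matrix(rep(c(1, 2), 3), 2), list("a", "b"),
                    samples = c("x", "y", "z"))
  expect_equal(unname(mean_sample(sk, c("x", "y", "z"))), c(1, 2))
})

test_that("derive_sample evaluates formulas row-wise with missing propagation", {
  s <- data_series(matrix(c(8, 2, 4, 2, 1, 4), 3,
                          dimnames = list(NULL, c("treated", "control"))),
                   list("a", "b", "c"))
  d <- derive_sample(s, "log2(treated/control)", name = "lfc")
  expect_equal(unname(d$values[1, "lfc"]), 2)
  expect_true("lfc" %in% d$samples)
  expect_error(derive_sample(s, "treated -"), "cannot parse")
  expect_error(derive_sample(s, "nosuch / control"), "unknown sample 'nosuch'")
  expect_error(derive_sample(s, "frobnicate(control)"),
               "unknown function 'frobnicate'")
  # division by zero -> missing with a warning
  s0 <- data_series(matrix(c(1, 0), 1), list("a"), samples = c("u", "v"))
  expect_warning(d0 <- derive_sample(s0, "u/v"), "division by zero")
  expect_true(is.na(d0$values[1, "u/v"]))
  # missing operand -> missing result
  sna <- data_series(matrix(c(NA, 3), 1), list("a"), samples = c("u", "v"))
  expect_true(is.na(derive_sample(sna, "u+v")$values[1, "u+v"]))
  # user-registered functions extend the evaluator
  register_sample_function("double_it", function(x) 2 * x)
  expect_equal(unname(derive_sample(s0, "double_it(u)")$values[1, 3]), 2)
})

test_that("derive_sample mean() agrees with mean_sample on random series", {
  set.seed(42)
  for (i in 1:20) {
    v <- matrix(stats::rnorm(12), 4)
    v[stats::runif(12) < 0.2] <- NA
    s <- data_series(v, as.list(letters[1:4]), samples = c("s1", "s2", "s3"))
    d <- derive_sample(s, "mean(s1, s2, s3)", name = "m")
    expect_equal(unname(d$values[, "m"]),
                 unname(mean_sample(s, c("s1", "s2", "s3"))))
  }
})

test_that("colour scales are exact at anchors and channel-wise linear between", {
  sc <- color_scale(domain = c(-2, 0, 2),
                    colors = c("#0000FF", "#FFFFFF", "#FF0000"))
  expect_equal(scale_color(sc, -2), "#0000FF")
  expect_equal(scale_color(sc, 0), "#FFFFFF")
  expect_equal(scale_color(sc, 2), "#FF0000")
  # midpoint of min and mid: channel-wise average
  expect_equal(scale_color(sc, -1), "#8080FF")
  expect_true(is.na(scale_color(sc, NA)))
  # monotone per channel on a grid
  reds <- vapply(seq(-2, 2, by = 0.25), function(v)
    strtoi(substr(scale_color(sc, v), 2, 3), 16L), 0)
  expect_true(all(diff(reds) >= 0))
  expect_error(color_scale(domain = c(1, 0, 2)), "non-decreasing")
  expect_error(color_scale(colors = c("red", "#FFFFFF", "#FF0000")),
               "RRGGBB")
})

test_that("project_series maps values onto targets and honours missing policy", {
  m <- add_entities(network_model(), c("E1", "E2", "E3"))
  s <- data_series(matrix(c(-2, 0.5, NA), 3), list("E1", "E2", "E3"),
                   samples = "s1", name = "dat")
  rm <- suppressMessages(map_rows_to_entities(s, m))
  spec <- projection_spec("dat", "s1", "fill_color",
                          color_scale(c(-2, 0, 2)))
  layer <- project_series(m, s, spec, rm)
  expect_equal(layer$E1$fill_color, "#0000FF")
  expect_null(layer$E3)
  hide <- projection_spec("dat", "s1", "fill_color", color_scale(c(-2, 0, 2)),
                          missing_policy = "hide")
  expect_false(project_series(m, s, hide, rm)$E3$visible)

  vis <- projection_spec("dat", "s1", "visibility",
                         list(predicate = "abs(x) >= 1"))
  lv <- project_series(m, s, vis, rm)
  expect_true(lv$E1$visible)
  expect_false(lv$E2$visible)

  expect_error(projection_spec("dat", "s1", "fill_color",
                               size_scale()), class = "bnv_config_error")

  # projection layers never mutate the model or series
  m2 <- apply_projection_layer(m, layer)
  expect_identical(clear_projection_layer(m2)$layers$projection, list())
  expect_identical(m$entities, m2$entities)
})

test_that("node_size and line_width targets scale linearly", {
  m <- add_entities(network_model(), "E1")
  s <- data_series(matrix(0.5, 1), list("E1"), samples = "s1", name = "d")
  rm <- suppressMessages(map_rows_to_entities(s, m))
  sz <- project_series(m, s, projection_spec("d", "s1", "node_size",
                                             size_scale(c(0, 1), c(10, 60))),
                       rm)
  expect_equal(sz$E1$size, 35)
  lw <- project_series(m, s, projection_spec("d", "s1", "line_width",
                                             size_scale(c(0, 1), c(1, 9))),
                       rm)
  expect_equal(lw$E1$line_width, 5)
})

test_that("time-series glyphs carry per-group means and replace node shapes", {
  m <- add_entities(network_model(), c("E1", "E2"))
  v <- matrix(c(1, 2, 3, 2, 4, 6), 1)  # one row: three groups x 2 reps
  s <- data_series(v, list("E1"),
                   samples = c("t1a", "t2a", "t3a", "t1b", "t2b", "t3b"),
                   groups = list(t1 = c("t1a", "t1b"), t2 = c("t2a", "t2b"),
                                 t3 = c("t3a", "t3b")), name = "ts")
  rm <- suppressMessages(map_rows_to_entities(s, m))
  layer <- project_time_series(m, s, kind = "bar", row_mapping = rm)
  expect_equal(layer$E1$glyph$values, c(1.5, 3, 4.5))
  expect_null(layer$E2)
  # glyph nodes render as mini charts, not shapes
  m2 <- apply_projection_layer(m, layer)
  res <- render_network(m2, "force", list(seed = 1))
  svg <- render_svg(res$graph)
  expect_match(svg, 'fill="#1F77B4"')
  # empty mapping -> zero glyphs
  s2 <- data_series(matrix(1, 1), list("ZZZ"), samples = "t1", name = "ts")
  expect_length(project_time_series(m, s2, groups = "t1",
                                    row_mapping = suppressMessages(
                                      map_rows_to_entities(s2, m))), 0)
})

test_that("ambiguity colouring: one compartment red, several rose, none white", {
  expect_equal(compartment_ambiguity_color("nucleus"), "#FF0000")
  expect_equal(compartment_ambiguity_color(c("nucleus", "cytoplasm")),
               "#FFC0CB")
  expect_equal(compartment_ambiguity_color(character()), "#FFFFFF")
})

test_that("reaction_direction projections flip only reversible reactions", {
  m <- add_entities(network_model(), c("S", "P"), kind = "compound")
  m <- add_reaction(m, "Rrev", "S", "P", reversible = TRUE)
  m <- add_reaction(m, "Rirr", "S", "P", reversible = FALSE)
  s <- data_series(matrix(c(-1, -1), 2), list("Rrev", "Rirr"),
                   samples = "s1", name = "d")
  # reactions are matched by id through the row mapping hook
  rm <- tibble::tibble(row = c(1L, 2L), entity_id = c("Rrev", "Rirr"))
  layer <- project_series(m, s, projection_spec("d", "s1",
                                                "reaction_direction"), rm)
  expect_equal(names(layer), "Rrev")
})
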