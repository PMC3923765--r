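# Small models built in code, shared across test files.

# three proteins in a complex, each wired to one external hub
fan_model <- function() {
  network_model() |>
    add_entities(c("A", "B", "C", "X")) |>
    add_edges(c("A", "B", "C"), c("X", "X", "X"), "activation") |>
    add_group("G", c("A", "B", "C"), semantics = "complex")
}

# one reaction: S1 + S2 + ATP -> P1 + ADP, catalysed by E, ATP/ADP co-factors
reaction_model <- function() {
  m <- network_model() |>
    add_entities(c("S1", "S2", "P1", "ATP", "ADP"), kind = "compound") |>
    add_entities("E", kind = "protein")
  add_reaction(m, "R1", c("S1", "S2", "ATP"), c("P1", "ADP"),
               catalysts = "E", cofactors = c("ATP", "ADP"))
}

# triangle with a shortcut: A -> B -> C plus A -> C, unit weights
triangle_model <- function() {
  network_model() |>
    add_entities(c("A", "B", "C")) |>
    add_edges(c("A", "A", "B"), c("C", "B", "C"))
}

# directed random graph as a flat model (for path-algorithm tests)
random_flat_model <- function(n, p = 0.4) {
  ids <- sprintf("n%02d", seq_len(n))
  m <- add_entities(network_model(), ids)
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  pick <- stats::runif(nrow(pairs)) < p
  if (any(pick))
    m <- add_edges(m, pairs$s[pick], pairs$t[pick], "generic",
                   directed = TRUE)
  m
}

expect_render_equal <- function(a, b) {
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$bands, b$bands)
}

# rectangles (with a small tolerance) must not overlap pairwise
expect_no_overlaps <- function(geom, tol = 0.5) {
  n <- nrow(geom)
  if (n < 2) return(invisible(TRUE))
  bad <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ox <- (geom$width[i] + geom$width[j]) / 2 - abs(geom$x[i] - geom$x[j])
    oy <- (geom$height[i] + geom$height[j]) / 2 - abs(geom$y[i] - geom$y[j])
    if (ox > tol && oy > tol) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
}
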