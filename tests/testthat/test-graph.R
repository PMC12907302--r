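# independent brute-force edge enumeration used as the oracle for connect()
brute_edges <- function(pre, post, kind, radius = NULL, sigma_p = NULL,
                        trunc_sigma = 4) {
  pp <- cell_position(pre)
  qq <- cell_position(post)
  intra <- identical(pre$name, post$name)
  out <- list()
  for (i in seq_len(nrow(pp))) {
    for (j in seq_len(nrow(qq))) {
      d <- sqrt(sum((pp[i, ] - qq[j, ])^2))
      self <- intra && i == j
      keep <- switch(kind,
        one_to_one = d == 0 && !self || (intra && i == j && FALSE),
        fully_connected = TRUE,
        radius = !self && d > 0 && d <= radius,
        gaussian = d <= trunc_sigma * sigma_p,
        NA)
      if (kind == "one_to_one") keep <- !intra && d == 0
      if (is.na(keep)) next
      if (keep) out[[length(out) + 1L]] <- c(i, j, d)
    }
  }
  # nearest-neighbor kinds: minimal strictly positive distance per cell
  if (kind %in% c("nearest_neighbors", "neighbor_4_plus_1")) {
    out <- list()
    for (i in seq_len(nrow(pp))) {
      d <- sqrt((pp[i, 1] - qq[, 1])^2 + (pp[i, 2] - qq[, 2])^2)
      if (intra) d[i] <- NA
      dpos <- d[!is.na(d) & d > 0]
      if (!length(dpos)) next
      dmin <- min(dpos)
      sel <- which(!is.na(d) & d > 0 & abs(d - dmin) < 1e-9)
      if (kind == "neighbor_4_plus_1") sel <- c(sel, which(!is.na(d) & d == 0))
      for (j in sel) out[[length(out) + 1L]] <- c(i, j, d[j])
    }
  }
  do.call(rbind, out)
}

test_that("cell positions are row-major with the grid spacing", {
  ly <- layer_spec("L", "linear_cell", 3, 3, spacing = 1, origin = c(2, 5))
  expect_equal(unname(cell_position(ly, 1)), cbind(2, 5))
  expect_equal(unname(cell_position(ly, 5)), cbind(3, 6))  # center of 3x3
  # adjacent cells are one spacing apart
  expect_equal(euclidean_distance(cell_position(ly, 1), cell_position(ly, 2)),
               1)
  expect_error(cell_position(ly, 10), class = "retinet_validation_error")
})

test_that("distance is planar (vertical separation ignored) and symmetric", {
  a <- layer_spec("A", "linear_cell", 2, 2, spacing = 1, z = 0)
  b <- layer_spec("B", "linear_cell", 2, 2, spacing = 1, z = 7)
  expect_equal(euclidean_distance(cell_position(a, 1), cell_position(b, 1)),
               0)
  expect_equal(euclidean_distance(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(euclidean_distance(cbind(1, 2), cbind(-3, 7)),
               euclidean_distance(cbind(-3, 7), cbind(1, 2)))
})

test_that("the Gaussian weight profile is normalized and decreasing", {
  expect_equal(gaussian_weight(0, 1), 1 / (2 * pi))
  expect_equal(gaussian_weight(1, 1), exp(-0.5) / (2 * pi))
  expect_equal(gaussian_weight(2, 2), exp(-0.5) / (2 * pi * 4))
  d <- seq(0, 5, by = 0.1)
  expect_true(all(diff(gaussian_weight(d, 1.3)) < 0))
})

test_that("all six connectivity kinds match brute-force enumeration on lattices up to 6x6", {
  for (n in c(2, 3, 5, 6)) {
    pre <- layer_spec("pre", "linear_cell", n, n, spacing = 1)
    post <- layer_spec("post", "linear_cell", n, n, spacing = 1, z = 1)
    cases <- list(
      list(kind = "one_to_one", a = pre, b = post),
      list(kind = "fully_connected", a = pre, b = post),
      list(kind = "nearest_neighbors", a = pre, b = pre),
      list(kind = "nearest_neighbors", a = pre, b = post),
      list(kind = "neighbor_4_plus_1", a = pre, b = post),
      list(kind = "radius", a = pre, b = pre, radius = 1.1),
      list(kind = "radius", a = pre, b = pre, radius = 2.2),
      list(kind = "gaussian", a = pre, b = pre, sigma_p = 0.8)
    )
    for (cs in cases) {
      got <- connect(cs$a, cs$b, cs$kind, "linear", radius = cs$radius,
                     sigma_p = cs$sigma_p)
      want <- brute_edges(cs$a, cs$b, cs$kind, radius = cs$radius,
                          sigma_p = cs$sigma_p)
      expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want),
                   info = paste(cs$kind, n))
      got_keys <- sort(paste(got$pre_index, got$post_index))
      want_keys <- sort(paste(want[, 1], want[, 2]))
      expect_identical(got_keys, want_keys, info = paste(cs$kind, n))
    }
  }
})

test_that("edge counts match the lattice geometry", {
  a3 <- layer_spec("a", "linear_cell", 3, 3, spacing = 1)
  b3 <- layer_spec("b", "linear_cell", 3, 3, spacing = 1, z = 1)
  expect_equal(nrow(connect(a3, b3, "one_to_one", "linear")), 9L)
  a2 <- layer_spec("a", "linear_cell", 2, 2, spacing = 1)
  b33 <- layer_spec("b", "linear_cell", 3, 3, spacing = 1, z = 1)
  expect_equal(nrow(connect(a2, b33, "fully_connected", "linear")), 36L)

  # 5x5 intra-layer: interior cells have out-degree 4 for nearest neighbors
  # and for radius 1.1 spacing
  a5 <- layer_spec("a", "linear_cell", 5, 5, spacing = 1)
  nn <- connect(a5, a5, "nearest_neighbors", "linear")
  deg <- table(factor(nn$pre_index, levels = 1:25))
  center <- 13L
  expect_equal(unname(deg[center]), 4L)
  expect_equal(unname(deg["1"]), 2L)  # corner
  rr <- connect(a5, a5, "radius", "linear", radius = 1.1)
  expect_equal(sum(rr$pre_index == center), 4L)

  # grid mismatch is rejected for the equal-count kinds
  expect_error(connect(a2, b33, "one_to_one", "linear"),
               class = "retinet_validation_error")
  expect_error(connect(a2, b33, "neighbor_4_plus_1", "linear"),
               class = "retinet_validation_error")
})

test_that("intra-layer Gaussian connectivity is symmetric with equal weights", {
  a <- layer_spec("a", "linear_cell", 4, 5, spacing = 0.5)
  ed <- connect(a, a, "gaussian", "linear", sigma_p = 0.7)
  key <- paste(ed$pre_index, ed$post_index)
  rev_key <- paste(ed$post_index, ed$pre_index)
  expect_true(all(rev_key %in% key))
  w_by_key <- setNames(ed$weight, key)
  expect_equal(unname(w_by_key[rev_key]), ed$weight)
})

test_that("total Gaussian weight from a cell approaches 1/spacing^2 on a wide lattice", {
  sp <- 0.2
  a <- layer_spec("a", "linear_cell", 41, 41, spacing = sp)
  ed <- connect(a, a, "gaussian", "linear", sigma_p = 0.6, trunc_sigma = 6)
  center <- 21L * 41L - 20L  # row 21, col 21
  s <- sum(ed$weight[ed$pre_index == center])
  expect_equal(s * sp^2, 1, tolerance = 0.01)
})

test_that("graphs round-trip through JSON and invalid files are rejected", {
  a <- layer_spec("a", "morris_lecar_ach_sahp", 3, 2, spacing = 0.05)
  ed <- connect(a, a, "nearest_neighbors", "acetylcholine")
  g <- sim_graph(list(a), ed,
                 initial_values = list(a = list(V = runif(6, -70, -50),
                                                N = 0, A = 0, R = 0, S = 0)))
  f <- withr::local_tempfile(fileext = ".json")
  save_graph(g, f)
  g2 <- load_graph(f)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$initial_values$a$V, g$initial_values$a$V)
  expect_equal(g2$layers$a[names(g$layers$a)], unclass(g$layers$a))
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".json")
  save_graph(g2, f2)
  expect_identical(readLines(f, warn = FALSE), readLines(f2, warn = FALSE))

  # missing initial values fail validation
  g_bad <- sim_graph(list(a), ed, initial_values = list(a = list(V = -60)))
  expect_error(validate_graph(g_bad, the_registry),
               class = "retinet_validation_error")
  # unknown synapse type fails validation
  ed2 <- ed; ed2$synapse_type <- "no_such_synapse"
  g_bad2 <- sim_graph(list(a), ed2, initial_values = g$initial_values)
  expect_error(validate_graph(g_bad2, the_registry),
               class = "retinet_notfound_error")
  # output-kind mismatch: a current synapse onto a cell without that slot
  b <- layer_spec("b", "linear_cell", 6, 1)
  ed3 <- edge_df("a", 1, "b", 1, "acetylcholine")
  g_bad3 <- sim_graph(list(a, b), ed3,
                      initial_values = c(g$initial_values,
                                         list(b = list(V = -60))))
  expect_error(validate_graph(g_bad3, the_registry),
               class = "retinet_validation_error")
})
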