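test_that("rk4 on the linear cell matches the closed form under 1e-6 mV", {
  g <- linear_graph(V0 = -50)
  m <- assemble(g, the_registry, dt = 1e-4, t_end = 1)
  rec <- simulate_model(m, "rk4")
  closed <- -60 + 10 * exp(-rec$L.V$time / 0.05)
  expect_lt(max(abs(rec$L.V$values[, 1] - closed)), 1e-6)
})

test_that("empirical convergence orders are ~1, ~2 and ~4 for euler/rk2/rk4", {
  g <- linear_graph(V0 = -20)
  err_at <- function(dt, solver) {
    m <- assemble(g, the_registry, dt = dt, t_end = 0.4)
    rec <- simulate_model(m, solver)
    v_end <- rec$L.V$values[nrow(rec$L.V$values), 1]
    abs(v_end - (-60 + 40 * exp(-0.4 / 0.05)))
  }
  for (case in list(c("euler", 1), c("rk2", 2), c("rk4", 4))) {
    e1 <- err_at(0.008, case[1])
    e2 <- err_at(0.004, case[1])
    slope <- log2(e1 / e2)
    expect_gt(slope, as.numeric(case[2]) - 0.3)
    expect_lt(slope, as.numeric(case[2]) + 0.3)
  }
})

test_that("rk45 reports on the fixed grid and agrees with the closed form", {
  g <- linear_graph(V0 = -50)
  m <- assemble(g, the_registry, dt = 0.01, t_end = 0.5)
  rec <- simulate_model(m, "rk45")
  expect_equal(length(rec$L.V$time), 51L)
  closed <- -60 + 10 * exp(-rec$L.V$time / 0.05)
  expect_lt(max(abs(rec$L.V$values[, 1] - closed)), 1e-5)
})

test_that("a zero vector field leaves the state unchanged", {
  # at the equilibrium V = E_L with no input, every solver is exact
  g <- linear_graph(V0 = -60)
  m <- assemble(g, the_registry, dt = 0.01, t_end = 0.1)
  for (solver in c("euler", "rk2", "rk4", "rk45")) {
    rec <- simulate_model(m, solver)
    expect_true(all(rec$L.V$values == -60), info = solver)
  }
})

test_that("the assembled derivative equals a naive per-cell per-edge loop on a mixed graph", {
  a <- layer_spec("A", "morris_lecar_ach", 2, 1, spacing = 0.1)
  b <- layer_spec("B", "linear_cell", 3, 1, spacing = 0.1, z = 1)
  edges <- rbind(
    edge_df("A", 1, "A", 2, "acetylcholine", weight = 0.8),
    edge_df("A", 2, "A", 1, "acetylcholine", weight = 1.2),
    edge_df("A", 1, "B", 1, "linear", weight = 0.3),
    edge_df("A", 2, "B", 3, "rectified", weight = 0.7),
    edge_df("B", 1, "B", 2, "gap_junction", weight = 1),
    edge_df("B", 2, "B", 1, "gap_junction", weight = 1),
    edge_df("B", 3, "B", 2, "linear", weight = -0.5)
  )
  g <- sim_graph(list(a, b), edges, initial_values = list(
    A = list(V = c(-42, -55), N = c(0.2, 0.4), A = c(3, 7)),
    B = list(V = c(-61, -52, -47))))
  m <- assemble(g, the_registry, dt = 1e-4, t_end = 1e-3)
  st <- init_state(m)
  dt <- 1e-4
  st1 <- step(m, st, dt, "euler")
  engine_deriv <- (st1$X - st$X) / dt

  # independent route: hand-coded cell models + the brute-force edge loop
  aml <- as.list(get_type(the_registry, "morris_lecar_ach")$params)
  lin <- as.list(get_type(the_registry, "linear_cell")$params)
  sA <- list(V = c(-42, -55), N = c(0.2, 0.4), A = c(3, 7))
  sB <- list(V = c(-61, -52, -47))
  outsA <- list(V = sA$V, N = sA$N, A = sA$A)
  naive <- list(A = vector("list", 2), B = vector("list", 3))
  for (i in 1:2) {
    inc <- edges[edges$post_layer == "A" & edges$post_index == i, ]
    inc$pre <- lapply(seq_len(nrow(inc)), function(k)
      lapply(outsA, `[`, inc$pre_index[k]))
    ti <- total_input(inc, lapply(outsA, `[`, i), the_registry)
    naive$A[[i]] <- morris_lecar_rhs(lapply(sA, `[`, i), aml, ti$I_syn,
                                     ach = TRUE)
  }
  for (i in 1:3) {
    inc <- edges[edges$post_layer == "B" & edges$post_index == i, ]
    inc$pre <- lapply(seq_len(nrow(inc)), function(k) {
      src <- if (inc$pre_layer[k] == "A") outsA else list(V = sB$V)
      lapply(src, `[`, inc$pre_index[k])
    })
    ti <- total_input(inc, list(V = sB$V[i]), the_registry)
    naive$B[[i]] <- list(V = linear_cell_rhs(sB$V[i], lin, ti$V_syn))
  }
  naive_flat <- c(
    vapply(naive$A, function(d) d$V, 0), vapply(naive$A, function(d) d$N, 0),
    vapply(naive$A, function(d) d$A, 0), vapply(naive$B, function(d) d$V, 0))
  expect_lt(max(rel_diff(engine_deriv, naive_flat)), 1e-12)
})

test_that("an infinite conduction velocity reproduces the instantaneous simulation", {
  e <- layer_spec("E", "cortical_excitatory", 3, 3, spacing = 0.1)
  i <- layer_spec("I", "cortical_inhibitory", 3, 3, spacing = 0.1, z = 0.1)
  mk_graph <- function(syn) {
    edges <- rbind(
      connect(e, i, "fully_connected", syn, weight_const = 0.05),
      connect(i, e, "one_to_one", "cortical_rate", weight_const = -0.5))
    sim_graph(list(e, i), edges, initial_values = list(
      E = list(V_pop = seq(2, 18, length.out = 9)),
      I = list(V_pop = 0)))
  }
  run_one <- function(graph, params = list()) {
    m <- assemble(graph, the_registry, dt = 1e-3, t_end = 0.2,
                  params = params)
    simulate_model(m, "rk4",
                   record = list(list(layer = "E", var = "V_pop"),
                                 list(layer = "I", var = "V_pop")))
  }
  fast <- run_one(mk_graph("cortical_rate_delayed"),
                  params = list(cortical_rate_delayed =
                                  list(conduction_velocity = 1e12)))
  inst <- run_one(mk_graph("cortical_rate"),
                  params = list(cortical_rate = list(w = 1)))
  expect_lt(max(abs(fast$E.V_pop$values - inst$E.V_pop$values)), 1e-12)
  expect_lt(max(abs(fast$I.V_pop$values - inst$I.V_pop$values)), 1e-12)

  # a finite velocity genuinely delays the interaction
  slow <- run_one(mk_graph("cortical_rate_delayed"),
                  params = list(cortical_rate_delayed =
                                  list(conduction_velocity = 1)))
  expect_gt(max(abs(slow$I.V_pop$values - inst$I.V_pop$values)), 1e-6)
})

test_that("a gap-junction pair conserves the coupling sum and converges to a common voltage", {
  pair <- function(coupled) {
    edges <- if (coupled) rbind(
      edge_df("L", 1, "L", 2, "gap_junction"),
      edge_df("L", 2, "L", 1, "gap_junction")) else empty_edges_df()
    g <- sim_graph(list(layer_spec("L", "linear_cell", 2, 1)),
                   edges, initial_values = list(L = list(V = c(-80, -30))))
    m <- assemble(g, the_registry, dt = 1e-3, t_end = 1)
    simulate_model(m, "rk4")$L.V$values
  }
  v_coupled <- pair(TRUE)
  v_free <- pair(FALSE)
  # voltages converge to a common value
  expect_lt(abs(diff(v_coupled[nrow(v_coupled), ])), 1e-3)
  # the two coupling terms cancel at every step: the pair sum evolves
  # exactly as the uncoupled pair sum
  expect_lt(max(abs(rowSums(v_coupled) - rowSums(v_free))), 1e-9)
})

test_that("recording is non-invasive and runs are deterministic", {
  b <- build_retinal_waves(nx = 3, ny = 3, t_end = 0.2)
  r1 <- run(b$session)
  r2 <- run(b$session)
  expect_identical(r1$sac.V$values, r2$sac.V$values)

  s_less <- b$session
  s_less$record <- list(list(layer = "sac", var = "V", cells = c(1L, 5L)))
  r3 <- run(s_less)
  expect_identical(r3$sac.V$values, r1$sac.V$values[, c(1, 5)])
})

test_that("recording bookkeeping: all cells of a 3x3 layer over 1 s at 1 ms give 9 x 1001 samples", {
  g <- sim_graph(list(layer_spec("L", "linear_cell", 3, 3)),
                 initial_values = list(L = list(V = -50)))
  m <- assemble(g, the_registry, dt = 1e-3, t_end = 1)
  rec <- simulate_model(m, "rk4",
                        record = list(list(layer = "L", var = "V",
                                           cells = "all")))
  expect_equal(dim(rec$L.V$values), c(1001L, 9L))
  expect_equal(length(rec$L.V$time), 1001L)
  expect_true(all(diff(rec$L.V$time) > 0))
})

test_that("worker 'none' ignores a configured stimulus with a warning", {
  g <- linear_graph()
  stim <- make_full_field(100, 0.1, 10, size = c(4, 4))
  expect_warning(
    m <- assemble(g, the_registry, dt = 1e-3, t_end = 0.01, worker = "none",
                  stim = stim),
    "ignored")
  expect_null(m$drive$L)
})

test_that("a diverging trajectory raises a structured integration error naming the cell", {
  g <- linear_graph(V0 = -50)
  m <- assemble(g, the_registry, dt = 1e-3, t_end = 2,
                params = list(linear_cell = list(tau = -1e-3)))
  err <- tryCatch(simulate_model(m, "rk4"), error = function(e) e)
  expect_s3_class(err, "retinet_integration_error")
  expect_match(conditionMessage(err), "layer 'L'")
  expect_false(is.na(err$t))
})
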