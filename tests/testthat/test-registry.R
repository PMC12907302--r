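builtin_cells <- subset(list_models(the_registry), kind == "cell")$name
builtin_syns <- subset(list_models(the_registry), kind == "synapse")$name

test_that("every builtin cell type compiles to the hand-coded vector field (1e-12, 100 random points)", {
  for (nm in builtin_cells) {
    def <- get_type(the_registry, nm)
    ref <- retinet:::.builtin_cell_rhs[[nm]]
    out_ref <- retinet:::.builtin_cell_outputs[[nm]]
    expect_false(is.null(ref), info = nm)
    compiled <- cell_rhs_fun(def)
    compiled_out <- cell_outputs_fun(def)
    for (pt in random_cell_points(def, 100, seed = match(nm, builtin_cells))) {
      a <- unlist(compiled(pt$state, pt$params, pt$inputs))
      b <- unlist(ref(pt$state, pt$params, pt$inputs))
      expect_lt(max(rel_diff(a, b[names(a)])), 1e-12)
      ao <- unlist(compiled_out(pt$state, pt$params))
      bo <- unlist(out_ref(pt$state, pt$params))
      expect_lt(max(rel_diff(ao, bo[names(ao)])), 1e-12)
    }
  }
})

test_that("every builtin synapse rule matches its hand-coded reference (1e-12, random points)", {
  set.seed(7)
  n <- 100
  V_pre <- runif(n, -80, 20); V_post <- runif(n, -80, 20)
  A <- runif(n, 0, 50); nn <- runif(n, 0, 1); nu <- runif(n, 0, 80)
  br <- runif(n, 0, 20); fr <- runif(n, 0, 40); w_edge <- runif(n, -2, 2)
  pre <- list(V = V_pre, A = A, n = nn, nu = nu, bipolarResponse = br,
              firingRate = fr, f = runif(n))
  post <- list(V = V_post, nu = runif(n, 0, 80))
  check <- function(name, ref_fun) {
    def <- get_type(the_registry, name)
    p <- as.list(def$params)
    got <- synapse_rule_fun(def)(pre, post, w_edge, p)
    expect_lt(max(rel_diff(got, ref_fun(p) * w_edge)), 1e-12)
  }
  check("acetylcholine", function(p) ach_current(A, V_post, p))
  check("rectified", function(p) rectified_psp(V_pre, p))
  check("linear", function(p) linear_psp(V_pre, p))
  check("bipolar_pooling", function(p) linear_psp(br, p))
  check("gap_junction", function(p) gap_junction_psp(V_pre, V_post, p))
  check("cortical_rate", function(p) cortical_rate_coupling(pre$nu, p))
  check("cortical_rate_delayed", function(p) cortical_rate_coupling(pre$nu, p))
  check("gaba_a", function(p) ligand_gated_psp(nn, V_post, p))
  check("ampa", function(p) ligand_gated_psp(nn, V_post, p))
  check("retino_cortical", function(p) retino_cortical_rate(fr, p))
  # literal mode of the ligand-gated rule drives with the pre voltage
  def <- get_type(the_registry, "gaba_a")
  p <- modifyList(as.list(def$params), list(literal = 1))
  got <- synapse_rule_fun(def)(pre, post, w_edge, p)
  expect_lt(max(rel_diff(got, ligand_gated_psp(nn, V_pre, p) * w_edge)),
            1e-12)
})

test_that("model definitions round-trip through JSON identically", {
  for (nm in c("linear_cell", "morris_lecar_ach_sahp", "hodgkin_huxley",
               "acetylcholine", "retino_cortical")) {
    def <- get_type(the_registry, nm)
    f1 <- withr::local_tempfile(fileext = ".json")
    f2 <- withr::local_tempfile(fileext = ".json")
    save_type(def, f1)
    def2 <- load_type(f1)
    save_type(def2, f2)
    expect_identical(jsonlite::read_json(f1), jsonlite::read_json(f2),
                     info = nm)
    expect_equal(def2$params, def$params)
    expect_identical(def2$src, def$src)
  }
})

test_that("the linear cell builtin has one state variable driven by V_syn", {
  def <- get_type(the_registry, "linear_cell")
  expect_identical(names(def$state_vars), "V")
  expect_identical(def$input_slots, "synaptic_voltage_rate")
})

test_that("schema violations are reported with the failing field", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "broken", kind = "cell",
                            state_vars = list(list(name = "V", unit = "mV"))),
                       f, auto_unbox = TRUE)
  err <- tryCatch(load_type(f), error = function(e) e)
  expect_s3_class(err, "retinet_validation_error")
  expect_match(conditionMessage(err), "rhs")

  # rhs not covering the state vars
  expect_error(
    cell_type_def("x", c(V = "mV", W = "mV"), list(tau = 1),
                  rhs = list(V = "-V/tau"), outputs = list(V = "V")),
    class = "retinet_validation_error")
})

test_that("delayed synapses are exactly those with a conduction_velocity parameter", {
  expect_false(get_type(the_registry, "cortical_rate")$delayed)
  expect_true(get_type(the_registry, "cortical_rate_delayed")$delayed)
  d <- synapse_type_def("s", list(w = 1, conduction_velocity = 100),
                        "voltage_rate", "w*w_edge*V_pre")
  expect_true(d$delayed)
})

test_that("protected definitions cannot be overwritten or deleted; user types can", {
  dir <- withr::local_tempdir()
  reg <- model_registry(user_dir = dir)
  # the two cortical populations ship protected
  expect_true(get_type(reg, "cortical_excitatory")$protected)
  expect_true(get_type(reg, "cortical_inhibitory")$protected)
  expect_error(delete_type(reg, "cortical_excitatory"),
               class = "retinet_protection_error")
  expect_error(add_type(reg, cell_type_def(
    "cortical_excitatory", c(V_pop = "mV"), list(tau = 1),
    rhs = list(V_pop = "-V_pop/tau"), outputs = list(V_pop = "V_pop"))),
    class = "retinet_protection_error")
  expect_error(delete_type(reg, "no_such_type"),
               class = "retinet_notfound_error")

  mine <- cell_type_def("my_cell", c(V = "mV"), list(tau = 0.1),
                        rhs = list(V = "-V/tau"), outputs = list(V = "V"))
  add_type(reg, mine)
  expect_true("my_cell" %in% list_models(reg)$name)
  expect_true(file.exists(file.path(dir, "my_cell.json")))
  delete_type(reg, "my_cell")
  expect_false("my_cell" %in% list_models(reg)$name)
  expect_false(file.exists(file.path(dir, "my_cell.json")))
})
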