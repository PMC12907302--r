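# Reference cell models. Small dense RK4 loops over the hand-coded rhs are
# used as trajectory oracles where a closed form is not available.

rk4_traj <- function(rhs, state, dt, n_steps) {
  out <- matrix(NA_real_, n_steps + 1L, length(state))
  colnames(out) <- names(state)
  out[1L, ] <- unlist(state)
  vars <- names(state)
  for (k in seq_len(n_steps)) {
    s <- as.list(out[k, ])
    k1 <- unlist(rhs(s))
    k2 <- unlist(rhs(as.list(out[k, ] + dt / 2 * k1)))
    k3 <- unlist(rhs(as.list(out[k, ] + dt / 2 * k2)))
    k4 <- unlist(rhs(as.list(out[k, ] + dt * k3)))
    out[k + 1L, ] <- out[k, ] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

test_that("the rectifier is piecewise linear with a strict threshold", {
  th <- -48
  expect_equal(rectifier(th, th), 0)
  expect_equal(rectifier(th + 2, th), 2)
  expect_equal(rectifier(th - 5, th), 0)
  expect_equal(rectifier(c(-60, -48, -40), th), c(0, 0, 8))
})

test_that("linear and pharma cells have the stated equilibria and slopes", {
  p <- list(tau = 0.1, E_L = -60)
  expect_equal(linear_cell_rhs(-60, p, 0), 0)
  expect_equal(linear_cell_rhs(-50, p, 0), -100)

  pp <- list(C = 0.1, g_L = 1, g_P = 1, E_L = -60, E_P = 0)
  # equilibrium V* = (g_L E_L + g_P E_P)/(g_L + g_P) = -30
  expect_equal(pharma_cell_rhs(-30, pp, 0), 0)
  # g_P = 0 reduces to the leak-only form
  pp0 <- modifyList(pp, list(g_P = 0))
  V <- seq(-80, 0, by = 10)
  expect_equal(pharma_cell_rhs(V, pp0, 0),
               -(V - pp0$E_L) * (pp0$g_L / pp0$C))
})

test_that("neurotransmitter amacrine production saturates and half-activates", {
  def <- get_type(the_registry, "amacrine_gaba")
  p <- as.list(def$params)
  # V = E_N: production at half rate
  d <- neurotransmitter_amacrine_rhs(list(T = 0, V = p$E_N, n = 0), p, 0)
  expect_equal(d$T, p$k_p / 2)
  # V -> -Inf: pure decay of T
  d2 <- neurotransmitter_amacrine_rhs(list(T = 2, V = -1e4, n = 0), p, 0)
  expect_equal(d2$T, -p$k_d * 2, tolerance = 1e-12)
  # T = n = 0 freezes n
  expect_equal(d$n, 0)
})

test_that("gain-control cells relax to their rectified fixed points", {
  def <- get_type(the_registry, "bipolar_gain_control")
  p <- as.list(def$params)
  # below threshold the activity decays
  d <- gain_control_bipolar_rhs(list(A_B = 1, V = p$theta_B - 1), p, 0, 0)
  expect_equal(d$A_B, -1 / p$tau_AB)
  # clamped above threshold: A_B* = tau_AB h_B (V - theta_B)
  Vc <- p$theta_B + 4
  Astar <- p$tau_AB * p$h_B * (Vc - p$theta_B)
  expect_equal(gain_control_bipolar_rhs(list(A_B = Astar, V = Vc), p,
                                        0, 0)$A_B, 0)
  expect_equal(gain_control_bipolar_rhs(list(A_B = 0, V = p$E_L), p,
                                        0, 0)$V, 0)

  gdef <- get_type(the_registry, "ganglion_gain_control")
  gp <- as.list(gdef$params)
  expect_equal(gain_control_ganglion_rhs(list(V = gp$V_L, A_G = 0),
                                         modifyList(gp, list(g_T = 0)),
                                         0)$V, 0)
  # A_G fixed point under clamped V
  Vc <- gp$theta_G + 6
  Ag <- gp$tau_G * gp$H_G * (Vc - gp$theta_G)
  expect_equal(gain_control_ganglion_rhs(list(V = Vc, A_G = Ag), gp, 0)$A_G,
               0)
  # firing rate is zero below threshold, divisive above
  expect_equal(ganglion_firing_rate(list(V = gp$theta_G - 10, A_G = 0), gp),
               0)
  expect_equal(ganglion_firing_rate(list(V = gp$theta_G + 3, A_G = 1), gp),
               gp$rate_gain * 3 / 2)
})

test_that("the electrode integrates its input with the stated step response", {
  p <- list(tau = 0.01, C = 0.1)
  expect_equal(electrode_rhs(0.5 * p$tau * 80 / p$C, p, 80),
               0.5 * 80 / p$C)
  # closed-form step response: V(t) = tau I/C (1 - exp(-t/tau))
  dt <- 1e-5
  tr <- rk4_traj(function(s) list(V = electrode_rhs(s$V, p, 40)),
                 list(V = 0), dt, 2000)
  tt <- seq(0, by = dt, length.out = 2001)
  expect_lt(max(abs(tr[, "V"] - p$tau * 40 / p$C * (1 - exp(-tt / p$tau)))),
            1e-8)
})

test_that("Morris-Lecar rests subthreshold, oscillates suprathreshold, keeps N in [0,1]", {
  def <- get_type(the_registry, "morris_lecar")
  p <- as.list(def$params)
  run_ml <- function(I, t_end = 3) {
    rk4_traj(function(s) morris_lecar_rhs(s, p, I),
             list(V = -60, N = 0), 1e-4, round(t_end / 1e-4))
  }
  sub <- run_ml(60)
  # subthreshold: converges to a rest point (late samples nearly constant)
  late <- sub[(nrow(sub) - 2000):nrow(sub), "V"]
  expect_lt(diff(range(late)), 0.05)
  sup <- run_ml(120)
  late_sup <- sup[(nrow(sup) - 10000):nrow(sup), "V"]
  # sustained oscillation: large sustained voltage excursions
  expect_gt(diff(range(late_sup)), 30)
  expect_true(all(sub[, "N"] >= 0 & sub[, "N"] <= 1))
  expect_true(all(sup[, "N"] >= 0 & sup[, "N"] <= 1))
})

test_that("ACh concentration stays non-negative and decays when production is off", {
  def <- get_type(the_registry, "morris_lecar_ach")
  p <- as.list(def$params)
  p0 <- modifyList(p, list(mu_A = 0))
  tr <- rk4_traj(function(s) morris_lecar_rhs(s, p0, 80, ach = TRUE),
                 list(V = -60, N = 0, A = 3), 1e-4, 20000)
  expect_true(all(tr[, "A"] >= 0))
  expect_equal(unname(tr[nrow(tr), "A"]), 3 * exp(-2 / p$tau_Ach),
               tolerance = 1e-6)

  tr2 <- rk4_traj(function(s) morris_lecar_rhs(s, p, 100, ach = TRUE),
                  list(V = -60, N = 0, A = 0), 1e-4, 20000)
  expect_true(all(tr2[, "A"] >= 0))
})

test_that("Hodgkin-Huxley has a quiescent root and spikes under strong current", {
  def <- get_type(the_registry, "hodgkin_huxley")
  p <- as.list(def$params)
  am <- function(V) 1000 * 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
  bm <- function(V) 1000 * 4 * exp(-(V + 65) / 18)
  ah <- function(V) 1000 * 0.07 * exp(-(V + 65) / 20)
  bh <- function(V) 1000 / (1 + exp(-(V + 35) / 10))
  an <- function(V) 1000 * 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
  bn <- function(V) 1000 * 0.125 * exp(-(V + 65) / 80)
  inf <- function(V) list(m = am(V) / (am(V) + bm(V)),
                          h = ah(V) / (ah(V) + bh(V)),
                          n = an(V) / (an(V) + bn(V)))
  dV <- function(V) {
    s <- inf(V)
    hodgkin_huxley_rhs(c(list(V = V), s), p, 0)$V
  }
  Vrest <- stats::uniroot(dV, c(-75, -56), tol = 1e-12)$root
  d <- hodgkin_huxley_rhs(c(list(V = Vrest), inf(Vrest)), p, 0)
  expect_true(all(abs(unlist(d)) < 1e-6))

  tr <- rk4_traj(function(s) hodgkin_huxley_rhs(s, p, 10000),
                 c(list(V = Vrest), inf(Vrest)), 1e-5, 10000)  # 100 ms
  expect_gt(max(tr[, "V"]), 0)  # at least one spike
  expect_true(all(tr[, c("m", "h", "n")] >= 0 & tr[, c("m", "h", "n")] <= 1))
})

test_that("cortical columns integrate rates with a monotone non-negative transfer", {
  def <- get_type(the_registry, "cortical_excitatory")
  p <- as.list(def$params)
  expect_equal(cortical_column_rhs(list(V_pop = p$baseline), p, 0)$V_pop, 0)
  V <- seq(-40, 60, by = 0.5)
  nu <- cortical_rate(list(V_pop = V), p)
  expect_true(all(nu >= 0))
  expect_true(all(diff(nu) >= 0))
  # steady state under constant input matches the fixed-point solve
  FRin <- 30
  Vstar <- p$baseline + p$k_in * FRin
  expect_equal(cortical_column_rhs(list(V_pop = Vstar), p, FRin)$V_pop, 0)
})
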