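test_that("resident equilibrium has zero invader compartments and tiny
           residual", {
  p <- model_params()
  eq <- resident_equilibrium(p)
  expect_equal(unname(eq[c("p_i", "m_i")]), c(0, 0))
  expect_lt(max(abs(full_rhs(eq, p))), 1e-9)
  expect_true(attr(eq, "pair_viable"))
  # mirrored parameters give mirrored resident equilibria
  eqi <- resident_equilibrium(p, "invasive")
  expect_equal(unname(swap_state(eqi)), unname(eq), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("a resident host without exchange settles at its logistic
           equilibrium alone", {
  p <- model_params(alpha_nn = 0, beta_nn = 0, r_pn = 1, mu_pn = 0.5)
  eq <- resident_equilibrium(p)
  expect_equal(unname(eq), c(2, 0, 0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_false(attr(eq, "pair_viable"))
  expect_error(resident_equilibrium(p, require_pair = TRUE),
               "cannot persist")
})

test_that("outcome classification thresholds the persistence pattern", {
  o1 <- classify_outcome(c(0.8, 0.5, 1e-9, 1e-9))
  expect_equal(o1$label, "native_resistance")
  expect_equal(unname(o1$pattern), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(classify_outcome(c(1e-9, 0.5, 0.9, 1e-9))$label,
               "host_invasion_native_symbionts")
  expect_equal(classify_outcome(c(1e-9, 1e-9, 0.7, 0.6))$label,
               "co_invasion")
  expect_equal(classify_outcome(c(0.8, 0.5, 0.7, 0.6))$label,
               "full_coexistence")
  expect_equal(classify_outcome(c(0.8, 1e-9, 1e-9, 0.6))$label,
               "microbial_invasion_native_host")
  expect_equal(classify_outcome(c(1e-9, 1e-9, 1e-9, 1e-9))$label,
               "collapse/partial_0000")
  # threshold is relative to the supplied scale
  expect_equal(unname(classify_outcome(c(0.5, 0.5, 1e-4, 1e-4),
                                       scale = 1000)$pattern),
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("pathway_trace reports only permanent down-crossings, ordered in
           time", {
  mk_traj <- function(times, states) {
    structure(list(times = times, states = states, converged = TRUE,
                   reduced = FALSE, solver = list()),
              class = "sv_trajectory")
  }
  t <- seq(0, 100, by = 5)
  st <- cbind(p_n = rep(1, 21), m_n = rep(1, 21),
              p_i = ifelse(t >= 55, 1e-9, 0.5),
              m_i = ifelse(t >= 40, 1e-9, 0.5))
  tr <- mk_traj(t, st)
  pw <- pathway_trace(tr)
  expect_equal(pw$compartment, c("m_i", "p_i"))
  expect_equal(pw$time, c(40, 55))

  # a dip with recovery is not an extinction
  st2 <- st
  st2[, "p_i"] <- ifelse(t == 55, 1e-9, 0.5)
  pw2 <- pathway_trace(mk_traj(t, st2))
  expect_equal(pw2$compartment, "m_i")

  expect_equal(nrow(pathway_trace(mk_traj(t, st[, c(1, 2, 1, 2)] * 1))),
               0L)
})

test_that("a zero propagule leaves the resident equilibrium untouched", {
  p <- model_params()
  inv <- invasion_experiment(p, propagule_spec(size = 0))
  expect_equal(inv$outcome$label, "native_resistance")
  expect_equal(unname(inv$final),
               unname(resident_equilibrium(p)), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(inv$biomass$delta, 0, tolerance = 1e-7)
})

test_that("with symmetric traits the larger propagule wins, and roles
           reverse when sizes swap", {
  p <- scenario1_params()
  s <- 0.05
  big_invader <- run_to_convergence(p, c(s, s, 2 * s, 2 * s))
  big_native <- run_to_convergence(p, c(2 * s, 2 * s, s, s))
  expect_equal(classify_outcome(big_invader$state)$label, "co_invasion")
  expect_equal(classify_outcome(big_native$state)$label,
               "native_resistance")
})

test_that("parasitic invasive symbionts drive co-invasion and parasitic
           native symbionts drive resistance", {
  inv6 <- invasion_experiment(scenario6_params())
  expect_equal(inv6$outcome$label, "co_invasion")
  expect_true(inv6$converged)
  # natives go extinct before the invaders ever do
  expect_true(all(inv6$pathway$compartment %in% c("p_n", "m_n")))

  inv4 <- invasion_experiment(scenario4_params())
  expect_equal(inv4$outcome$label, "native_resistance")
})

test_that("a low-quality mutualist invader displaces natives into a smaller
           community", {
  inv <- invasion_experiment(low_quality_invader_params())
  expect_false(inv$outcome$pattern[["p_n"]])
  expect_true(inv$outcome$pattern[["p_i"]])
  expect_lt(inv$biomass$delta, 0)
})

test_that("experiments on swapped parameters mirror the original outcome", {
  p <- scenario6_params()
  inv <- invasion_experiment(p)
  # swapped world: invasive community resident, natives invading
  ps <- swap_params(p)
  resident_s <- resident_equilibrium(ps)
  expect_equal(unname(resident_s),
               unname(swap_state(resident_equilibrium(swap_params(ps),
                                                      "invasive"))),
               tolerance = 1e-9, ignore_attr = TRUE)
  init <- resident_equilibrium(ps)
  amount <- 1e-3 * sum(init)
  init[c("p_i", "m_i")] <- init[c("p_i", "m_i")] + amount / 2
  run_s <- run_to_convergence(ps, init)
  run_o <- run_to_convergence(p, swap_state(init))
  expect_equal(unname(run_s$state), unname(swap_state(run_o$state)),
               tolerance = 1e-6)
})

test_that("invasive symbionts that establish from rare have positive
           linearized growth at the resident equilibrium", {
  set.seed(54)
  tested <- 0L
  while (tested < 15L) {
    # native pair mutualistic; invasive symbionts interact with the
    # native host through a random (alpha_in, beta_ni) cross edge
    p <- sample_params(c(pn_mn = "mutualistic"), seed = 1000 + tested,
                       competition = 0.5)
    p$alpha_in <- exp(stats::runif(1, log(0.05), log(5)))
    p$beta_ni <- exp(stats::runif(1, log(0.05), log(5)))
    res <- try(resident_equilibrium(p, require_pair = TRUE),
               silent = TRUE)
    tested <- tested + 1L
    if (inherits(res, "try-error")) next
    scale <- sum(res)
    m0 <- 1e-8 * scale
    init <- res; init[["m_i"]] <- m0
    rate <- full_rhs(init, p)[["m_i"]] / m0
    out <- run_to_convergence(p, init, max_time = 2e4)
    established <- out$state[["m_i"]] > 1e-6 * scale
    if (established) expect_gt(rate, 0)
  }
})

test_that("biomass comparison is plain arithmetic on totals", {
  b <- biomass_comparison(c(1, 1, 0, 0), c(0, 0, 0.6, 0.5))
  expect_equal(b$total_pre, 2)
  expect_equal(b$total_post, 1.1)
  expect_equal(b$delta, -0.9)
  expect_equal(biomass_comparison(1:4, 1:4)$delta, 0)
})

test_that("repeated experiments are deterministic", {
  p <- scenario6_params()
  a <- invasion_experiment(p)
  b <- invasion_experiment(p)
  expect_identical(a$outcome$label, b$outcome$label)
  expect_identical(a$final, b$final)
})
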