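test_that("unit efficiencies collapse the mutualism wedge to the diagonal", {
  p <- model_params(q_hpn = 1, q_cpn = 1, q_cmi = 1, q_hmi = 1, d = 1)
  rm <- regime_region_map(p, "pn_mi", grid = 41)
  expect_equal(unname(rm$boundaries), c(1, 1))
  expect_false("mutualistic" %in% rm$labels)
  off_diag <- rm$labels[abs(outer(rm$alpha, rm$beta, "-")) > 1e-9]
  expect_true(all(off_diag %in%
                    c("parasitic_for_host", "parasitic_for_symbiont")))
})

test_that("default efficiencies open the wedge 0.5*beta < alpha < 2*beta", {
  rm <- regime_region_map(model_params(), "pn_mi", grid = 41)
  expect_equal(unname(rm$boundaries),
               c(2, 0.5))  # host slope q_hp/q_cp, symbiont q_hm/q_cm
  i <- which.min(abs(rm$alpha - 1))
  j <- which.min(abs(rm$beta - 1))
  expect_equal(rm$labels[i, j], "mutualistic")
})

test_that("grid labels agree with direct inequality evaluation everywhere", {
  set.seed(61)
  p <- rand_params()
  rm <- regime_region_map(p, "pi_mn", grid = 31)
  for (i in seq_along(rm$alpha)) {
    for (j in seq_along(rm$beta)) {
      Qp <- p$q_hpi * rm$alpha[i] / p$d - p$q_cpi * rm$beta[j]
      Qm <- p$q_cmn * rm$beta[j] - p$q_hmn * rm$alpha[i] / p$d
      expect_equal(rm$labels[i, j], classify_regime(c(Qp, Qm)))
    }
  }
})

test_that("empirical label boundaries fall within one cell of the analytic
           lines", {
  rm <- regime_region_map(model_params(), "pn_mi", grid = 101)
  da <- diff(rm$alpha[1:2])
  for (j in seq_along(rm$beta)) {
    col <- rm$labels[, j]
    flips <- which(col[-1] != col[-length(col)])
    for (f in flips) {
      a_flip <- (rm$alpha[f] + rm$alpha[f + 1]) / 2
      # analytic crossing alphas at this beta for the two lines
      a_lines <- rm$beta[j] / rm$boundaries
      expect_lt(min(abs(a_flip - a_lines)), da)
    }
  }
})

test_that("a degenerate 1x1 phase diagram equals a direct experiment", {
  p <- scenario6_params()
  pd <- outcome_phase_diagram(
    p,
    axis1 = list(name = "beta_ni", values = 2),
    axis2 = list(name = "alpha_in", values = 0.01))
  direct <- invasion_experiment(p)
  expect_equal(pd$labels[1, 1], direct$outcome$label)
})

test_that("outcome labels shift across the regime wedge along a cross-edge
           sweep", {
  # sweeping beta_ni from exploitative (scenario 6) through the wedge
  # changes the endpoint away from co-invasion
  pd <- outcome_phase_diagram(
    model_params(alpha_in = 0.8),
    axis1 = list(name = "beta_ni", values = c(0.1, 3)),
    axis2 = list(name = "c_m_in", values = 0.5))
  expect_false(pd$labels[1, 1] == pd$labels[2, 1])
})

test_that("sample_params is deterministic under a seed and honours its
           constraints", {
  a <- sample_params(c(pn_mn = "mutualistic", pi_mi = "mutualistic"),
                     seed = 7)
  b <- sample_params(c(pn_mn = "mutualistic", pi_mi = "mutualistic"),
                     seed = 7)
  expect_identical(a, b)

  set.seed(99)
  for (s in 1:20) {
    p <- sample_params(c(pn_mn = "mutualistic",
                         pn_mi = "parasitic_for_symbiont"), seed = s)
    reg <- all_edge_regimes(p)
    expect_equal(unname(reg[["pn_mn"]]), "mutualistic")
    expect_equal(unname(reg[["pn_mi"]]), "parasitic_for_symbiont")
    # unconstrained cross edge defaults to neutral (no shared partners)
    expect_equal(unname(reg[["pi_mn"]]), "neutral")
    expect_equal(p$alpha_ni, 0)
    expect_equal(p$beta_in, 0)
  }
})

test_that("neutral constraints force the edge coefficients to zero", {
  p <- sample_params(c(pn_mn = "neutral", pn_mi = "neutral",
                       pi_mn = "neutral", pi_mi = "neutral"), seed = 3)
  expect_equal(p$alpha_nn, 0)
  expect_equal(p$beta_ii, 0)
  expect_equal(scenario_id(p), "1")
})
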