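# Resource-exchange fluxes and the model right-hand sides.
#
# The aggregate flux into each compartment is a q-weighted sum of per-pair
# kernels. With state x = (p_n, m_n, p_i, m_i) and shared denominators
#   D_alpha = p_n/d + p_i/d + m_n + m_i   (symbiont -> host stream)
#   D_beta  = p_n + p_i + d*m_n + d*m_i   (host -> symbiont stream)
# the kernels are
#   kernel_alpha[j,k] = alpha_jk * m_j * p_k / D_alpha  (symbiont j supplies host k)
#   kernel_beta[j,k]  = beta_jk  * p_j * m_k / D_beta   (host j supplies symbiont k)
# so that one kernel carries both the receiver's gain and the supplier's
# cost, scaled by the respective conversion efficiencies.

#' Resource-exchange fluxes at a state
#'
#' Evaluates the density-dependent resource-exchange terms of the model:
#' the gain and cost components of the net flux into each of the four
#' compartments, together with the sixteen per-pair kernels they
#' aggregate. The saturating denominators make the transfer limited by
#' the partner with the lower (d-adjusted) biomass. At the all-zero
#' state both denominators vanish and every flux is defined as 0, so
#' that total extinction is an equilibrium.
#'
#' @param state biomass 4-vector `(p_n, m_n, p_i, m_i)`, nonnegative.
#' @param params an [model_params()] object.
#' @return A list of class `sv_fluxes` with components:
#'   \describe{
#'     \item{gain, cost}{named 4-vectors: the gain and cost parts of the
#'       net flux into `p_n`, `m_n`, `p_i`, `m_i` (per time).}
#'     \item{net}{`gain - cost`, the net flux `F` entering each equation.}
#'     \item{kernel_alpha}{2x2 matrix, rows = supplying symbiont
#'       (`n`, `i`), cols = receiving host; q-free kernels.}
#'     \item{kernel_beta}{2x2 matrix, rows = supplying host, cols =
#'       receiving symbiont.}
#'     \item{D_alpha, D_beta}{the shared denominators.}
#'   }
#' @examples
#' exchange_fluxes(c(1, 1, 0, 0), model_params())
#' @export
exchange_fluxes <- function(state, params) {
  stopifnot(inherits(params, "sv_params"))
  s <- check_state(state)
  p_n <- s[["p_n"]]; m_n <- s[["m_n"]]; p_i <- s[["p_i"]]; m_i <- s[["m_i"]]
  d <- params$d

  D_alpha <- (p_n + p_i) / d + m_n + m_i
  D_beta <- p_n + p_i + d * (m_n + m_i)

  dimn <- list(supplier = c("n", "i"), receiver = c("n", "i"))
  ka <- matrix(0, 2, 2, dimnames = dimn)
  kb <- matrix(0, 2, 2, dimnames = dimn)
  if (D_alpha > 0) {
    ka["n", "n"] <- params$alpha_nn * m_n * p_n / D_alpha
    ka["n", "i"] <- params$alpha_ni * m_n * p_i / D_alpha
    ka["i", "n"] <- params$alpha_in * m_i * p_n / D_alpha
    ka["i", "i"] <- params$alpha_ii * m_i * p_i / D_alpha
  }
  if (D_beta > 0) {
    kb["n", "n"] <- params$beta_nn * p_n * m_n / D_beta
    kb["n", "i"] <- params$beta_ni * p_n * m_i / D_beta
    kb["i", "n"] <- params$beta_in * p_i * m_n / D_beta
    kb["i", "i"] <- params$beta_ii * p_i * m_i / D_beta
  }

  gain <- c(
    p_n = params$q_hpn * (ka["n", "n"] + ka["i", "n"]),
    m_n = params$q_cmn * (kb["n", "n"] + kb["i", "n"]),
    p_i = params$q_hpi * (ka["i", "i"] + ka["n", "i"]),
    m_i = params$q_cmi * (kb["i", "i"] + kb["n", "i"])
  )
  cost <- c(
    p_n = params$q_cpn * (kb["n", "n"] + kb["n", "i"]),
    m_n = params$q_hmn * (ka["n", "n"] + ka["n", "i"]),
    p_i = params$q_cpi * (kb["i", "n"] + kb["i", "i"]),
    m_i = params$q_hmi * (ka["i", "n"] + ka["i", "i"])
  )

  structure(list(gain = gain, cost = cost, net = gain - cost,
                 kernel_alpha = ka, kernel_beta = kb,
                 D_alpha = D_alpha, D_beta = D_beta),
            class = "sv_fluxes")
}

#' Right-hand side of the four-compartment model
#'
#' Time derivative of the biomass state: intrinsic host growth plus net
#' resource-exchange flux, minus interspecific competition and
#' self-limitation. The system is autonomous.
#'
#' @inheritParams exchange_fluxes
#' @return Named numeric 4-vector of derivatives
#'   `(dp_n/dt, dm_n/dt, dp_i/dt, dm_i/dt)`.
#' @examples
#' full_rhs(c(1, 0, 0, 0), model_params(r_pn = 1, mu_pn = 0.5))
#' @export
full_rhs <- function(state, params) {
  fl <- exchange_fluxes(state, params)
  s <- check_state(state)
  p_n <- s[["p_n"]]; m_n <- s[["m_n"]]; p_i <- s[["p_i"]]; m_i <- s[["m_i"]]
  with(params, c(
    p_n = r_pn * p_n + fl$net[["p_n"]] - c_p_in * p_n * p_i - mu_pn * p_n^2,
    m_n = fl$net[["m_n"]] - c_m_in * m_n * m_i - mu_mn * m_n^2,
    p_i = r_pi * p_i + fl$net[["p_i"]] - c_p_ni * p_n * p_i - mu_pi * p_i^2,
    m_i = fl$net[["m_i"]] - c_m_ni * m_n * m_i - mu_mi * m_i^2
  ))
}

#' Right-hand side of the reduced one-host/one-symbiont model
#'
#' The two-equation reduction: `dp/dt = r_p p + Q_p p m / (p/d + m) -
#' mu_p p^2` and `dm/dt = Q_m p m / (p/d + m) - mu_m m^2`, where
#' `(Q_p, Q_m)` is the edge's net-interaction pair ([compute_Q()]). At
#' the origin the saturating term is defined as 0.
#'
#' @param state2 biomass 2-vector `(p, m)`, nonnegative.
#' @param rp an [reduced_params()] object.
#' @return Named numeric 2-vector `(dp/dt, dm/dt)`.
#' @examples
#' reduced_rhs(c(1, 1), reduced_params())
#' @export
reduced_rhs <- function(state2, rp) {
  stopifnot(inherits(rp, "sv_reduced_params"))
  s <- check_state(state2, n = 2L)
  p <- s[["p"]]; m <- s[["m"]]
  q <- compute_Q(rp)
  D <- p / rp$d + m
  flux <- if (D > 0) p * m / D else 0
  c(p = rp$r_p * p + q$Q_p * flux - rp$mu_p * p^2,
    m = q$Q_m * flux - rp$mu_m * m^2)
}
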