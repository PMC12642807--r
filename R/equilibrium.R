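# Jacobians (analytic where the fluxes are smooth, one-sided finite
# differences on the boundary) and equilibrium location by damped
# projected Newton iteration.

# gradient of one aggregate flux term  f = q * x[ip] * (a . x) / (w . x)
# with respect to the state vector x; valid wherever w . x > 0
.flux_term_grad <- function(x, q, ip, a, w) {
  S <- sum(a * x)
  D <- sum(w * x)
  g <- q * (x[ip] * a / D - x[ip] * S * w / D^2)
  g[ip] <- g[ip] + q * S / D
  g
}

.full_jacobian_analytic <- function(params, state) {
  x <- unname(state)
  d <- params$d
  wa <- c(1 / d, 1, 1 / d, 1)   # D_alpha weights over (p_n, m_n, p_i, m_i)
  wb <- c(1, d, 1, d)           # D_beta weights
  J <- matrix(0, 4, 4, dimnames = list(.sv_state_names, .sv_state_names))
  with(params, {
    # row p_n: + alpha gains (supplier m_n/m_i), - beta costs
    J[1, ] <<- .flux_term_grad(x, q_hpn, 1, c(0, alpha_nn, 0, alpha_in), wa) -
      .flux_term_grad(x, q_cpn, 1, c(0, beta_nn, 0, beta_ni), wb)
    # row m_n: + beta gains from hosts, - alpha costs
    J[2, ] <<- .flux_term_grad(x, q_cmn, 2, c(beta_nn, 0, beta_in, 0), wb) -
      .flux_term_grad(x, q_hmn, 2, c(alpha_nn, 0, alpha_ni, 0), wa)
    J[3, ] <<- .flux_term_grad(x, q_hpi, 3, c(0, alpha_ni, 0, alpha_ii), wa) -
      .flux_term_grad(x, q_cpi, 3, c(0, beta_in, 0, beta_ii), wb)
    J[4, ] <<- .flux_term_grad(x, q_cmi, 4, c(beta_ni, 0, beta_ii, 0), wb) -
      .flux_term_grad(x, q_hmi, 4, c(alpha_in, 0, alpha_ii, 0), wa)
    # growth, competition, self-limitation
    J[1, 1] <<- J[1, 1] + r_pn - c_p_in * x[3] - 2 * mu_pn * x[1]
    J[1, 3] <<- J[1, 3] - c_p_in * x[1]
    J[2, 2] <<- J[2, 2] - c_m_in * x[4] - 2 * mu_mn * x[2]
    J[2, 4] <<- J[2, 4] - c_m_in * x[2]
    J[3, 3] <<- J[3, 3] + r_pi - c_p_ni * x[1] - 2 * mu_pi * x[3]
    J[3, 1] <<- J[3, 1] - c_p_ni * x[3]
    J[4, 4] <<- J[4, 4] - c_m_ni * x[2] - 2 * mu_mi * x[4]
    J[4, 2] <<- J[4, 2] - c_m_ni * x[4]
  })
  J
}

.reduced_jacobian_analytic <- function(rp, state) {
  p <- state[[1]]; m <- state[[2]]
  q <- compute_Q(rp)
  D <- p / rp$d + m
  dfdp <- m^2 / D^2          # d/dp [p m / D]
  dfdm <- p^2 / (rp$d * D^2) # d/dm [p m / D]
  matrix(c(
    rp$r_p + q$Q_p * dfdp - 2 * rp$mu_p * p, q$Q_p * dfdm,
    q$Q_m * dfdp, q$Q_m * dfdm - 2 * rp$mu_m * m
  ), 2, 2, byrow = TRUE, dimnames = list(c("p", "m"), c("p", "m")))
}

.fd_jacobian <- function(params, state, rhs_fun) {
  n <- length(state)
  f0 <- rhs_fun(state, params)
  J <- matrix(0, n, n)
  scale <- pmax(abs(state), 1)
  for (j in seq_len(n)) {
    h <- 1e-6 * scale[j]
    up <- state; up[j] <- up[j] + h
    if (state[j] >= h) {
      dn <- state; dn[j] <- dn[j] - h
      J[, j] <- (rhs_fun(up, params) - rhs_fun(dn, params)) / (2 * h)
    } else {
      # one-sided stencil on the nonnegativity boundary
      J[, j] <- (rhs_fun(up, params) - f0) / h
    }
  }
  dimnames(J) <- list(names(f0), names(f0))
  J
}

#' Jacobian of the model right-hand side
#'
#' Exact analytic partial derivatives of the full 4-compartment (or
#' reduced 2-compartment) right-hand side. The exchange fluxes are
#' rational functions and smooth away from the origin; for states with
#' zero components the analytic expressions are replaced by one-sided
#' finite differences, which is also the method used at the origin
#' where the fluxes are not differentiable.
#'
#' @param params an [model_params()] or [reduced_params()] object.
#' @param state nonnegative state (4-vector, or 2-vector for reduced).
#' @param method `"analytic"` (with boundary fallback) or `"fd"`
#'   (central finite differences, for cross-checking).
#' @return The Jacobian matrix (4x4 or 2x2) with named dimensions.
#' @export
jacobian <- function(params, state, method = c("analytic", "fd")) {
  method <- match.arg(method)
  reduced <- .sv_is_reduced(params)
  neq <- if (reduced) 2L else 4L
  s <- check_state(state, n = neq)
  rhs_fun <- if (reduced) reduced_rhs else full_rhs
  if (method == "fd" || any(s == 0))
    return(.fd_jacobian(params, s, rhs_fun))
  if (reduced) .reduced_jacobian_analytic(params, s)
  else .full_jacobian_analytic(params, s)
}

.stability_label <- function(eig, tol = 1e-10) {
  re <- Re(eig)
  if (all(re < -tol)) "stable"
  else if (any(re > tol)) "unstable"
  else "marginal"
}

#' Locate an equilibrium of the model
#'
#' Damped Newton iteration on the right-hand side, projected onto the
#' nonnegative orthant, started from `guess`. The step is halved until
#' the residual decreases (up to 30 halvings). An equilibrium is
#' reported only when the residual infinity norm falls below `tol`
#' (default `1e-10`, always below the `1e-9` reporting contract);
#' otherwise a non-converged result is returned rather than an error.
#' Stability is read from the eigenvalues of the Jacobian at the root:
#' `stable` when all real parts are below `-1e-10`, `unstable` when any
#' exceeds `1e-10`, `marginal` otherwise.
#'
#' @param params an [model_params()] or [reduced_params()] object.
#' @param guess nonnegative starting state.
#' @param tol residual infinity-norm target.
#' @param max_iter Newton iteration cap.
#' @return An object of class `sv_equilibrium`: list with `state`,
#'   `residual` (infinity norm), `converged`, `eigenvalues`,
#'   `stability`.
#' @examples
#' find_equilibrium(reduced_params(alpha = 0, beta = 0, r_p = 1,
#'                                 mu_p = 0.5), c(1, 0))
#' @export
find_equilibrium <- function(params, guess, tol = 1e-10, max_iter = 100L) {
  reduced <- .sv_is_reduced(params)
  neq <- if (reduced) 2L else 4L
  x <- check_state(guess, n = neq)
  rhs_fun <- if (reduced) reduced_rhs else full_rhs
  f <- rhs_fun(x, params)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) < tol) break
    J <- jacobian(params, x)
    step <- try(solve(J, f), silent = TRUE)
    if (inherits(step, "try-error")) {
      # ridge-regularised step through a near-singular Jacobian
      step <- solve(J + diag(1e-8, neq), f)
    }
    lambda <- 1
    improved <- FALSE
    for (k in 1:30) {
      xn <- pmax(x - lambda * step, 0)
      fn <- rhs_fun(xn, params)
      if (max(abs(fn)) < max(abs(f))) {
        x <- xn; f <- fn; improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
  }
  converged <- max(abs(f)) < tol
  J <- jacobian(params, x)
  eig <- eigen(J, only.values = TRUE)$values
  structure(list(
    state = x,
    residual = max(abs(f)),
    converged = converged,
    eigenvalues = eig,
    stability = if (converged) .stability_label(eig) else NA_character_
  ), class = "sv_equilibrium")
}

#' @export
print.sv_equilibrium <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Equilibrium (%s), residual %.3g\n", x$stability,
                x$residual))
  } else {
    cat(sprintf("No equilibrium found (residual %.3g)\n", x$residual))
  }
  print(x$state, ...)
  invisible(x)
}
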