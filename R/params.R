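# Parameter containers for the four-compartment host-symbiont model and
# its one-host/one-symbiont reduction.

# canonical field order; also the order of the parameter vector handed to
# the compiled derivative functions
.sv_param_names <- c(
  "r_pn", "r_pi",
  "alpha_nn", "alpha_ni", "alpha_in", "alpha_ii",
  "beta_nn", "beta_ni", "beta_in", "beta_ii",
  "q_hpn", "q_cpn", "q_hpi", "q_cpi",
  "q_cmn", "q_hmn", "q_cmi", "q_hmi",
  "c_p_in", "c_p_ni", "c_m_in", "c_m_ni",
  "mu_pn", "mu_mn", "mu_pi", "mu_mi",
  "d"
)

.sv_reduced_names <- c(
  "r_p", "q_hp", "q_cp", "q_cm", "q_hm",
  "alpha", "beta", "mu_p", "mu_m", "d"
)

.sv_state_names <- c("p_n", "m_n", "p_i", "m_i")

#' Model parameters for the four-compartment invasion model
#'
#' Builds and validates the full parameter set of the two-host /
#' two-symbiont-community consumer-resource model. Hosts (`p_n`, `p_i`)
#' are facultative mutualists with intrinsic growth rates `r_pn`, `r_pi`;
#' symbiont communities (`m_n`, `m_i`) are obligate and have no intrinsic
#' growth. Resource transfer from symbionts to hosts is quantified by the
#' `alpha_jk` coefficients and from hosts to symbionts by the `beta_jk`
#' coefficients, with the first subscript naming the supplying species
#' and the second the receiving species (`n` = native, `i` = invasive).
#' The `q` coefficients convert received (`h`, benefit) or supplied
#' (`c`, cost) resources into biomass; the `c_*` coefficients are
#' interspecific competition rates (`c_p_in` multiplies the loss term of
#' the native-host equation, `c_p_ni` that of the invasive-host
#' equation, and analogously for symbionts); `mu_*` are self-limitation
#' (maintenance) rates; `d` is the single dimensionless biomass-adjustment
#' factor appearing in the flux denominators.
#'
#' The defaults describe two mirror-image mutualistic resident pairs
#' (native host with native symbionts, invasive host with invasive
#' symbionts) that do not share partners: all cross exchange
#' coefficients (`alpha_ni`, `alpha_in`, `beta_ni`, `beta_in`) are zero.
#'
#' @param r_pn,r_pi host intrinsic growth rates (per time), `>= 0`.
#' @param alpha_nn,alpha_ni,alpha_in,alpha_ii symbiont-to-host supply
#'   coefficients (dimensionless exchange capacity), `>= 0`.
#' @param beta_nn,beta_ni,beta_in,beta_ii host-to-symbiont supply
#'   coefficients, `>= 0`.
#' @param q_hpn,q_cpn,q_hpi,q_cpi host conversion efficiencies for
#'   benefit (`h`) and cost (`c`) streams, `>= 0`.
#' @param q_cmn,q_hmn,q_cmi,q_hmi symbiont conversion efficiencies for
#'   benefit (`c`) and cost (`h`) streams, `>= 0`.
#' @param c_p_in,c_p_ni,c_m_in,c_m_ni interspecific competition
#'   coefficients (per biomass per time), `>= 0`.
#' @param mu_pn,mu_mn,mu_pi,mu_mi self-limitation coefficients (per
#'   biomass per time), strictly `> 0` (required for bounded dynamics).
#' @param d biomass-adjustment factor in the flux denominators,
#'   strictly `> 0`.
#' @return An object of class `sv_params`: a named list with the 27
#'   fields above.
#' @examples
#' p <- model_params()
#' p$alpha_nn
#' cross_pair_regimes(model_params(alpha_in = 1, beta_ni = 1))
#' @export
model_params <- function(r_pn = 0.5, r_pi = 0.5,
                         alpha_nn = 1, alpha_ni = 0, alpha_in = 0, alpha_ii = 1,
                         beta_nn = 1, beta_ni = 0, beta_in = 0, beta_ii = 1,
                         q_hpn = 2, q_cpn = 1, q_hpi = 2, q_cpi = 1,
                         q_cmn = 2, q_hmn = 1, q_cmi = 2, q_hmi = 1,
                         c_p_in = 0.5, c_p_ni = 0.5, c_m_in = 0.5, c_m_ni = 0.5,
                         mu_pn = 1, mu_mn = 1, mu_pi = 1, mu_mi = 1,
                         d = 1) {
  p <- mget(.sv_param_names)
  validate_params(p)
  structure(p, class = "sv_params")
}

#' Reduced one-host/one-symbiont parameters
#'
#' Parameters of the two-equation reduction of the model, describing a
#' single host population `p` exchanging resources with a single
#' symbiont community `m`. The reduction carries the same consumer-resource
#' structure as the full model with all cross-community and competition
#' terms removed; its net interaction is summarised by the pair
#' ([compute_Q()]) `Q_p = q_hp * alpha / d - q_cp * beta` and
#' `Q_m = q_cm * beta - q_hm * alpha / d`.
#'
#' @param r_p host intrinsic growth rate, `>= 0`.
#' @param q_hp,q_cp host benefit/cost conversion efficiencies, `>= 0`.
#' @param q_cm,q_hm symbiont benefit/cost conversion efficiencies, `>= 0`.
#' @param alpha symbiont-to-host supply coefficient, `>= 0`.
#' @param beta host-to-symbiont supply coefficient, `>= 0`.
#' @param mu_p,mu_m self-limitation coefficients, `> 0`.
#' @param d biomass-adjustment factor, `> 0`.
#' @return An object of class `sv_reduced_params`.
#' @examples
#' rp <- reduced_params()
#' compute_Q(rp)
#' @export
reduced_params <- function(r_p = 0.5, q_hp = 2, q_cp = 1, q_cm = 2, q_hm = 1,
                           alpha = 1, beta = 1, mu_p = 1, mu_m = 1, d = 1) {
  p <- mget(.sv_reduced_names)
  validate_params(p, reduced = TRUE)
  structure(p, class = "sv_reduced_params")
}

validate_params <- function(p, reduced = FALSE) {
  want <- if (reduced) .sv_reduced_names else .sv_param_names
  miss <- setdiff(want, names(p))
  if (length(miss) > 0L)
    stop("missing parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(p), want)
  if (length(extra) > 0L)
    stop("unknown parameter(s): ", paste(extra, collapse = ", "), call. = FALSE)
  for (nm in want) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be nonnegative (got ", v, ")",
           call. = FALSE)
  }
  strict <- c(grep("^mu_", want, value = TRUE), "d")
  for (nm in strict) {
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive (got ",
           p[[nm]], ")", call. = FALSE)
  }
  invisible(TRUE)
}

param_vector <- function(params) {
  if (inherits(params, "sv_reduced_params"))
    return(unlist(params[.sv_reduced_names]))
  unlist(params[.sv_param_names])
}

#' @export
print.sv_params <- function(x, ...) {
  cat("Four-compartment host-symbiont model parameters\n")
  v <- unlist(x[.sv_param_names])
  print(v, ...)
  invisible(x)
}

#' @export
print.sv_reduced_params <- function(x, ...) {
  cat("Reduced one-host/one-symbiont parameters\n")
  v <- unlist(x[.sv_reduced_names])
  print(v, ...)
  q <- compute_Q(x)
  cat(sprintf("Q_p = %.6g, Q_m = %.6g (%s)\n", q$Q_p, q$Q_m,
              classify_regime(q)))
  invisible(x)
}

check_state <- function(state, n = 4L) {
  if (!is.numeric(state) || length(state) != n)
    stop("state must be a numeric vector of length ", n, call. = FALSE)
  if (any(!is.finite(state)))
    stop("state components must be finite", call. = FALSE)
  if (any(state < 0))
    stop("state components must be nonnegative", call. = FALSE)
  s <- unname(as.numeric(state))
  names(s) <- if (n == 4L) .sv_state_names else c("p", "m")
  s
}

#' Swap native and invasive roles in a parameter set
#'
#' Returns the parameter set with all native (`n`) and invasive (`i`)
#' subscripts exchanged. Running the model with swapped parameters from
#' a role-swapped initial state reproduces the original trajectory with
#' compartments relabelled, which the test suite uses as a symmetry
#' oracle.
#'
#' @param params an [model_params()] object.
#' @return An `sv_params` object with the `n` and `i` roles exchanged.
#' @export
swap_params <- function(params) {
  stopifnot(inherits(params, "sv_params"))
  swap <- c(
    r_pn = "r_pi", r_pi = "r_pn",
    alpha_nn = "alpha_ii", alpha_ii = "alpha_nn",
    alpha_ni = "alpha_in", alpha_in = "alpha_ni",
    beta_nn = "beta_ii", beta_ii = "beta_nn",
    beta_ni = "beta_in", beta_in = "beta_ni",
    q_hpn = "q_hpi", q_hpi = "q_hpn",
    q_cpn = "q_cpi", q_cpi = "q_cpn",
    q_cmn = "q_cmi", q_cmi = "q_cmn",
    q_hmn = "q_hmi", q_hmi = "q_hmn",
    c_p_in = "c_p_ni", c_p_ni = "c_p_in",
    c_m_in = "c_m_ni", c_m_ni = "c_m_in",
    mu_pn = "mu_pi", mu_pi = "mu_pn",
    mu_mn = "mu_mi", mu_mi = "mu_mn",
    d = "d"
  )
  out <- params
  for (nm in names(swap)) out[[nm]] <- params[[swap[[nm]]]]
  out
}

#' Swap native and invasive compartments of a state vector
#'
#' Pure relabelling, applicable to any compartment-indexed 4-vector
#' (biomass states, derivatives, propagules).
#'
#' @param state 4-vector ordered `(p_n, m_n, p_i, m_i)`.
#' @return The vector `(p_i, m_i, p_n, m_n)` with standard names.
#' @export
swap_state <- function(state) {
  stopifnot(is.numeric(state), length(state) == 4L)
  out <- as.numeric(state)[c(3L, 4L, 1L, 2L)]
  names(out) <- .sv_state_names
  out
}

#' Extract the reduced parameters of one host-symbiont edge
#'
#' The four directed host-symbiont associations of the full model (native
#' host with native or invasive symbionts, invasive host with native or
#' invasive symbionts) each define a one-host/one-symbiont reduction whose
#' `(Q_p, Q_m)` pair classifies the edge on the mutualism-parasitism
#' continuum.
#'
#' @param params an [model_params()] object.
#' @param edge one of `"pn_mn"`, `"pn_mi"`, `"pi_mn"`, `"pi_mi"`; the
#'   host appears first.
#' @return An `sv_reduced_params` object for that edge.
#' @export
edge_params <- function(params,
                        edge = c("pn_mn", "pn_mi", "pi_mn", "pi_mi")) {
  stopifnot(inherits(params, "sv_params"))
  edge <- match.arg(edge)
  pick <- switch(edge,
    pn_mn = list(r = "r_pn", a = "alpha_nn", b = "beta_nn",
                 qhp = "q_hpn", qcp = "q_cpn", qcm = "q_cmn", qhm = "q_hmn",
                 mup = "mu_pn", mum = "mu_mn"),
    pn_mi = list(r = "r_pn", a = "alpha_in", b = "beta_ni",
                 qhp = "q_hpn", qcp = "q_cpn", qcm = "q_cmi", qhm = "q_hmi",
                 mup = "mu_pn", mum = "mu_mi"),
    pi_mn = list(r = "r_pi", a = "alpha_ni", b = "beta_in",
                 qhp = "q_hpi", qcp = "q_cpi", qcm = "q_cmn", qhm = "q_hmn",
                 mup = "mu_pi", mum = "mu_mn"),
    pi_mi = list(r = "r_pi", a = "alpha_ii", b = "beta_ii",
                 qhp = "q_hpi", qcp = "q_cpi", qcm = "q_cmi", qhm = "q_hmi",
                 mup = "mu_pi", mum = "mu_mi")
  )
  reduced_params(
    r_p = params[[pick$r]],
    q_hp = params[[pick$qhp]], q_cp = params[[pick$qcp]],
    q_cm = params[[pick$qcm]], q_hm = params[[pick$qhm]],
    alpha = params[[pick$a]], beta = params[[pick$b]],
    mu_p = params[[pick$mup]], mu_m = params[[pick$mum]],
    d = params[["d"]]
  )
}
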