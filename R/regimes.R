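# The mutualism-parasitism algebra: net-interaction coefficients
# (Q_p, Q_m), sign-pattern classification, per-edge regimes, and the
# scenario taxonomy of the cross-community edges.

#' Net-interaction coefficients of a host-symbiont edge
#'
#' Computes the signed coefficients that summarise the net effect of a
#' one-host/one-symbiont association: `Q_p = q_hp * alpha / d - q_cp *
#' beta` (net effect on the host) and `Q_m = q_cm * beta - q_hm * alpha
#' / d` (net effect on the symbiont community). Their signs place the
#' association on the mutualism-parasitism continuum.
#'
#' @param rp an [reduced_params()] object.
#' @return A list of class `sv_qpair` with numeric fields `Q_p`, `Q_m`.
#' @examples
#' compute_Q(reduced_params(alpha = 0.4, beta = 0.3, d = 2))
#' @export
compute_Q <- function(rp) {
  stopifnot(inherits(rp, "sv_reduced_params"))
  structure(list(
    Q_p = rp$q_hp * rp$alpha / rp$d - rp$q_cp * rp$beta,
    Q_m = rp$q_cm * rp$beta - rp$q_hm * rp$alpha / rp$d
  ), class = "sv_qpair")
}

# |Q| below this absolute tolerance is treated as exactly zero when
# classifying; the regime boundaries are measure-zero lines and float
# noise must not flip a commensal edge into a parasitic one.
.sv_q_tol <- 1e-12

#' Classify an interaction regime from its (Q_p, Q_m) pair
#'
#' Maps the sign pattern of the net-interaction coefficients to a named
#' regime: both positive is `mutualistic`; `Q_p < 0 < Q_m` is
#' `parasitic_for_host` (the symbionts exploit the host); `Q_m < 0 <
#' Q_p` is `parasitic_for_symbiont` (the host exploits the symbionts).
#' `Q_p = 0` with `Q_m > 0` is `commensal_host`, `Q_m = 0` with `Q_p >
#' 0` is `commensal_symbiont`, and both zero is `neutral` (no effective
#' exchange on the edge). Zero-testing uses an absolute tolerance of
#' `1e-12`.
#'
#' Any pattern in which neither partner gains (`Q_p <= 0` and `Q_m <=
#' 0`, not both zero) is reported as `invalid_exchange`: the continuum
#' taxonomy has no such region, and with all conversion efficiencies
#' positive it cannot arise unless both benefit streams vanish.
#'
#' @param q an `sv_qpair` (from [compute_Q()]) or a numeric 2-vector
#'   `(Q_p, Q_m)`.
#' @param tol absolute zero tolerance.
#' @return A single string, one of `"mutualistic"`,
#'   `"parasitic_for_host"`, `"parasitic_for_symbiont"`,
#'   `"commensal_host"`, `"commensal_symbiont"`, `"neutral"`,
#'   `"invalid_exchange"`.
#' @examples
#' classify_regime(c(0.1, 0.2))
#' classify_regime(c(-0.1, 0.2))
#' @export
classify_regime <- function(q, tol = .sv_q_tol) {
  if (inherits(q, "sv_qpair")) q <- c(q$Q_p, q$Q_m)
  stopifnot(is.numeric(q), length(q) == 2L, all(is.finite(q)))
  sp <- if (abs(q[1]) < tol) 0L else sign(q[1])
  sm <- if (abs(q[2]) < tol) 0L else sign(q[2])
  if (sp == 0L && sm == 0L) return("neutral")
  if (sp > 0L && sm > 0L) return("mutualistic")
  if (sp < 0L && sm > 0L) return("parasitic_for_host")
  if (sp > 0L && sm < 0L) return("parasitic_for_symbiont")
  if (sp == 0L && sm > 0L) return("commensal_host")
  if (sm == 0L && sp > 0L) return("commensal_symbiont")
  "invalid_exchange"
}

#' Regimes of the two cross-community edges
#'
#' Classifies the two novel associations an invasion can create: the
#' native host with the invasive symbiont community (`pn_mi` edge,
#' governed by `alpha_in` and `beta_ni`) and the invasive host with the
#' native symbiont community (`pi_mn` edge, governed by `alpha_ni` and
#' `beta_in`). Each edge is mutualistic exactly when its supply
#' coefficients fall inside the wedge `alpha > (q_cp/q_hp) * beta * d`
#' and `beta > (q_hm/q_cm) * alpha / d` opened by the host and symbiont
#' break-even lines.
#'
#' @param params an [model_params()] object.
#' @return Named character 2-vector with elements `pn_mi` and `pi_mn`.
#' @examples
#' cross_pair_regimes(model_params(alpha_in = 1, beta_ni = 1))
#' @export
cross_pair_regimes <- function(params) {
  stopifnot(inherits(params, "sv_params"))
  c(pn_mi = classify_regime(compute_Q(edge_params(params, "pn_mi"))),
    pi_mn = classify_regime(compute_Q(edge_params(params, "pi_mn"))))
}

# scenario number for a single active cross edge
.sv_edge_scenario <- function(edge, regime) {
  tab <- if (edge == "pi_mn") {
    c(mutualistic = "2", parasitic_for_host = "4",
      parasitic_for_symbiont = "5")
  } else {
    c(mutualistic = "3", parasitic_for_host = "6",
      parasitic_for_symbiont = "7")
  }
  out <- unname(tab[regime])
  if (is.na(out)) paste0(edge, ":", regime) else out
}

#' Invasion scenario label of a parameter set
#'
#' Names the parameter region a full parameter set occupies, from the
#' regimes of its two cross-community edges. When neither edge is
#' active (native and invasive species share neither hosts nor
#' symbionts) the scenario is `"1"`. With exactly one active edge the
#' scenario is one of `"2"`-`"7"`: mutualism on the invasive-host /
#' native-symbiont edge is `"2"` and on the native-host /
#' invasive-symbiont edge `"3"`; native symbionts exploiting invasive
#' hosts is `"4"` and invasive symbionts exploiting native hosts `"6"`;
#' invasive hosts exploiting native symbionts is `"5"` and native hosts
#' exploiting invasive symbionts `"7"`. When both edges are active the
#' label is the combination of the two single-edge labels, e.g.
#' `"2+6"`. Commensal edges (one coefficient exactly on its break-even
#' line) are labelled by edge and regime.
#'
#' @param params an [model_params()] object.
#' @return A single string.
#' @examples
#' scenario_id(model_params())                      # "1"
#' scenario_id(model_params(alpha_ni = 1, beta_in = 1))  # "2"
#' @export
scenario_id <- function(params) {
  reg <- cross_pair_regimes(params)
  active <- reg != "neutral"
  if (!any(active)) return("1")
  labs <- character(0)
  for (edge in c("pi_mn", "pn_mi")) {
    if (reg[[edge]] != "neutral")
      labs <- c(labs, .sv_edge_scenario(edge, reg[[edge]]))
  }
  paste(labs, collapse = "+")
}

#' Regimes of all four host-symbiont edges
#'
#' @param params an [model_params()] object.
#' @return Named character 4-vector over edges `pn_mn`, `pn_mi`,
#'   `pi_mn`, `pi_mi`.
#' @export
all_edge_regimes <- function(params) {
  stopifnot(inherits(params, "sv_params"))
  edges <- c("pn_mn", "pn_mi", "pi_mn", "pi_mi")
  vapply(edges, function(e)
    classify_regime(compute_Q(edge_params(params, e))), character(1))
}
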