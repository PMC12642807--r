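# The invasion-experiment protocol: bring the resident community to its
# equilibrium, introduce a small invader propagule, integrate to the
# asymptotic state, classify the persistence pattern, and trace the
# order of competitive exclusions.

.sv_epsilon <- 1e-6   # extinction threshold, relative to resident biomass
.sv_propagule <- 1e-3 # default propagule, relative to resident biomass

#' Equilibrium of a single resident community
#'
#' Computes the equilibrium of the model when only one host-symbiont
#' pair (native or invasive) is present: the other community's
#' compartments are exactly zero and the resident pair sits at the
#' attractor of its reduced dynamics, found by integrating to
#' convergence and polishing with Newton iteration. If the resident
#' symbionts cannot persist on their host (for example, zero exchange
#' on the resident edge), the host settles at its logistic equilibrium
#' `r_p / mu_p` alone and the symbiont compartment is zero; set
#' `require_pair = TRUE` to treat that as an error instead.
#'
#' @param params an [model_params()] object.
#' @param community `"native"` or `"invasive"`.
#' @param require_pair error if the resident symbionts go extinct.
#' @param epsilon relative extinction threshold used for the viability
#'   check.
#' @return A biomass 4-vector with the non-resident compartments 0, with
#'   attributes `residual` (infinity norm of the full right-hand side)
#'   and `pair_viable` (logical: symbionts persist).
#' @examples
#' resident_equilibrium(model_params())
#' @export
resident_equilibrium <- function(params,
                                 community = c("native", "invasive"),
                                 require_pair = FALSE,
                                 epsilon = .sv_epsilon) {
  stopifnot(inherits(params, "sv_params"))
  community <- match.arg(community)
  idx <- if (community == "native") 1:2 else 3:4

  # resident-pair dynamics = the full model with the other community
  # absent (its compartments are invariant at zero)
  embed <- function(x2) {
    s <- c(0, 0, 0, 0)
    s[idx] <- pmax(x2, 0)
    s
  }
  g <- function(x2) full_rhs(embed(x2), params)[idx]

  run <- run_to_convergence(params, embed(c(1, 1)))
  s2 <- run$state[idx]
  # damped Newton polish on the restricted system
  f <- g(s2)
  for (it in 1:100) {
    if (max(abs(f)) < 1e-12) break
    J <- jacobian(params, embed(s2))[idx, idx]
    step <- try(solve(J, f), silent = TRUE)
    if (inherits(step, "try-error")) step <- solve(J + diag(1e-8, 2), f)
    lambda <- 1
    repeat {
      xn <- pmax(s2 - lambda * step, 0)
      fn <- g(xn)
      if (max(abs(fn)) < max(abs(f))) { s2 <- xn; f <- fn; break }
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
  }
  # a symbiont stranded below threshold is extinct; re-polish host-only
  host_scale <- max(s2[1], 1e-12)
  if (s2[2] < epsilon * host_scale) {
    s2[2] <- 0
    f <- g(s2)
    for (it in 1:50) {
      if (max(abs(f)) < 1e-12) break
      J <- jacobian(params, embed(s2))[idx, idx]
      s2 <- pmax(s2 - solve(J + diag(1e-12, 2), f), 0)
      s2[2] <- 0
      f <- g(s2)
    }
  }
  pair_viable <- s2[2] > 0
  if (require_pair && !pair_viable)
    stop("resident ", community,
         " symbionts cannot persist (no viable resident pair)",
         call. = FALSE)
  if (s2[1] <= 0 && s2[2] <= 0)
    stop("resident ", community, " community is not viable", call. = FALSE)

  state <- c(p_n = 0, m_n = 0, p_i = 0, m_i = 0)
  state[idx] <- s2
  res <- max(abs(full_rhs(state, params)))
  attr(state, "residual") <- res
  attr(state, "pair_viable") <- pair_viable
  state
}

#' Propagule specification for an invasion experiment
#'
#' @param compartments which invader compartments are introduced:
#'   `"both"`, `"host"`, or `"symbiont"`.
#' @param size total introduced biomass as a fraction of the resident
#'   community's total biomass (default `1e-3`), split equally over the
#'   introduced compartments.
#' @return A list of class `sv_propagule`.
#' @export
propagule_spec <- function(compartments = c("both", "host", "symbiont"),
                           size = .sv_propagule) {
  compartments <- match.arg(compartments)
  if (!is.numeric(size) || length(size) != 1L || size < 0)
    stop("propagule size must be a single nonnegative number",
         call. = FALSE)
  structure(list(compartments = compartments, size = size),
            class = "sv_propagule")
}

#' Classify an asymptotic invasion outcome
#'
#' Thresholds each compartment of the final state at `epsilon * scale`
#' and names the resulting persistence pattern. The named endpoints
#' are: `(1,1,0,0)` native resistance (no invasion); `(0,0,1,1)`
#' co-invasion with displacement of the native community; `(1,1,1,1)`
#' full coexistence; `(0,1,1,0)` host invasion retaining native
#' symbionts (a novel `p_i`-`m_n` association); `(1,0,0,1)` microbial
#' invasion alongside the native host (`p_n`-`m_i` association);
#' `(1,1,0,1)` symbiont invasion with the native community intact; and
#' `(1,1,1,0)` host invasion without its own symbionts. All other
#' patterns are collapse or partial-collapse states and are labelled by
#' their pattern string.
#'
#' @param final biomass 4-vector at the endpoint.
#' @param epsilon relative extinction threshold (`> 0`).
#' @param scale biomass scale the threshold is relative to (typically
#'   the resident community's total biomass).
#' @return A list of class `sv_outcome` with `pattern` (named logical
#'   4-vector), `label`, `final`.
#' @examples
#' classify_outcome(c(0.8, 0.5, 1e-9, 1e-9))
#' @export
classify_outcome <- function(final, epsilon = .sv_epsilon, scale = 1) {
  stopifnot(epsilon > 0, scale > 0)
  s <- check_state(final)
  pattern <- s > epsilon * scale
  key <- paste(as.integer(pattern), collapse = "")
  label <- switch(key,
    "1100" = "native_resistance",
    "0011" = "co_invasion",
    "1111" = "full_coexistence",
    "0110" = "host_invasion_native_symbionts",
    "1001" = "microbial_invasion_native_host",
    "1101" = "symbiont_invasion_native_community",
    "1110" = "host_invasion_without_symbionts",
    paste0("collapse/partial_", key)
  )
  structure(list(pattern = pattern, label = label, final = s),
            class = "sv_outcome")
}

#' @export
print.sv_outcome <- function(x, ...) {
  cat(sprintf("Outcome: %s [pattern %s]\n", x$label,
              paste(as.integer(x$pattern), collapse = "")))
  print(x$final, ...)
  invisible(x)
}

#' Trace the order of extinctions along a trajectory
#'
#' For each compartment, finds the earliest time it crosses below
#' `epsilon * scale` and never exceeds that threshold again. Transient
#' dips followed by recovery are not reported. Events are returned
#' sorted by crossing time.
#'
#' @param traj an `sv_trajectory` from [integrate_model()] or the
#'   trajectory element of an invasion experiment.
#' @param epsilon relative extinction threshold.
#' @param scale biomass scale.
#' @return A data frame with columns `compartment` and `time` (zero
#'   rows when nothing goes extinct).
#' @export
pathway_trace <- function(traj, epsilon = .sv_epsilon, scale = 1) {
  stopifnot(inherits(traj, "sv_trajectory"), epsilon > 0, scale > 0)
  if (length(traj$times) < 2L)
    stop("trajectory must have at least 2 points", call. = FALSE)
  thr <- epsilon * scale
  events <- data.frame(compartment = character(0), time = numeric(0))
  for (k in seq_len(ncol(traj$states))) {
    v <- traj$states[, k]
    above <- v >= thr
    if (above[length(v)]) next          # alive at the end: no extinction
    last_above <- if (any(above)) max(which(above)) else 0L
    if (last_above == length(v)) next
    events <- rbind(events, data.frame(
      compartment = colnames(traj$states)[k],
      time = traj$times[last_above + 1L]))
  }
  events[order(events$time), , drop = FALSE]
}

#' Run an invasion experiment
#'
#' The resident native community is placed at its equilibrium, an
#' invader propagule is added to the invasive compartments, and the
#' system is integrated until it settles ([run_to_convergence()]). The
#' endpoint is classified ([classify_outcome()]) with the extinction
#' threshold taken relative to the resident community's total biomass,
#' and the exclusion ordering is traced ([pathway_trace()]).
#'
#' @param params an [model_params()] object.
#' @param propagule an [propagule_spec()] object.
#' @param epsilon relative extinction threshold.
#' @param max_time hard cap on integration time.
#' @return A list of class `sv_invasion` with elements `outcome` (an
#'   `sv_outcome`, carrying `converged` and `limit_cycle` flags),
#'   `pathway` (extinction events), `trajectory` (final integration
#'   window), `initial`, `final`, `biomass` (totals before/after and
#'   their difference), and `scale`.
#' @examples
#' \donttest{
#' inv <- invasion_experiment(model_params(alpha_ni = 1, beta_in = 1))
#' inv$outcome$label
#' }
#' @export
invasion_experiment <- function(params, propagule = propagule_spec(),
                                epsilon = .sv_epsilon, max_time = 1e5) {
  stopifnot(inherits(params, "sv_params"),
            inherits(propagule, "sv_propagule"))
  resident <- resident_equilibrium(params, "native")
  scale <- sum(resident)
  init <- unclass(resident)
  attributes(init) <- list(names = names(resident))

  amount <- propagule$size * scale
  targets <- switch(propagule$compartments,
                    both = c("p_i", "m_i"),
                    host = "p_i",
                    symbiont = "m_i")
  init[targets] <- init[targets] + amount / length(targets)

  run <- run_to_convergence(params, init, max_time = max_time)
  outcome <- classify_outcome(run$state, epsilon = epsilon, scale = scale)
  outcome$converged <- run$converged
  outcome$limit_cycle <- run$limit_cycle

  # retrace the whole run at coarse resolution for the pathway ordering
  full_tr <- integrate_model(params, init,
                             horizon = max(run$time, 1),
                             n_out = 2001L, stop_on_convergence = TRUE)
  pathway <- pathway_trace(full_tr, epsilon = epsilon, scale = scale)

  biomass <- biomass_comparison(resident, run$state)
  structure(list(
    outcome = outcome, pathway = pathway, trajectory = full_tr,
    initial = init, final = run$state, biomass = biomass,
    scale = scale, converged = run$converged,
    limit_cycle = run$limit_cycle
  ), class = "sv_invasion")
}

#' @export
print.sv_invasion <- function(x, ...) {
  print(x$outcome, ...)
  cat(sprintf("Total biomass: %.4g -> %.4g (delta %+.4g)%s\n",
              x$biomass$total_pre, x$biomass$total_post, x$biomass$delta,
              if (x$limit_cycle) " [limit cycle]" else ""))
  if (nrow(x$pathway) > 0) {
    cat("Exclusion order:",
        paste(sprintf("%s (t=%.3g)", x$pathway$compartment,
                      x$pathway$time), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare total biomass before and after invasion
#'
#' @param pre,post biomass 4-vectors.
#' @return A list with `total_pre`, `total_post`, `delta`
#'   (`post - pre`).
#' @examples
#' biomass_comparison(c(1, 1, 0, 0), c(0, 0, 0.6, 0.5))
#' @export
biomass_comparison <- function(pre, post) {
  list(total_pre = sum(pre), total_post = sum(post),
       delta = sum(post) - sum(pre))
}
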