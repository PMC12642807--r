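# Parameter-space exploration: regime-region maps over the (alpha, beta)
# plane of one cross-community edge, outcome phase diagrams over
# arbitrary parameter axes, and constrained rejection sampling of
# parameter sets.

#' Regime-region map of a cross-community edge
#'
#' Classifies every cell of an (alpha, beta) grid for one of the two
#' cross-community edges, substituting the cell's coordinates for the
#' edge's supply coefficients. The analytic boundary lines are also
#' returned: the host break-even line `beta = alpha * q_hp / (q_cp *
#' d)` (above it the host is exploited) and the symbiont break-even
#' line `beta = alpha * q_hm / (q_cm * d)` (below it the symbionts are
#' exploited); the mutualism wedge lies between them.
#'
#' @param params an [model_params()] object supplying the conversion
#'   efficiencies and `d`.
#' @param edge `"pn_mi"` (native host, invasive symbionts) or
#'   `"pi_mn"` (invasive host, native symbionts).
#' @param alpha_range,beta_range positive length-2 ranges.
#' @param grid number of cells per axis (`>= 2`).
#' @return A list of class `sv_region_map`: `alpha`, `beta` (grid
#'   coordinates), `labels` (character matrix, `grid x grid`, rows
#'   indexed by alpha), `boundaries` (slopes of the two break-even
#'   lines in the beta-vs-alpha plane), `edge`.
#' @examples
#' rm <- regime_region_map(model_params(), "pn_mi", grid = 21)
#' table(rm$labels)
#' @export
regime_region_map <- function(params, edge = c("pn_mi", "pi_mn"),
                              alpha_range = c(0.02, 2),
                              beta_range = c(0.02, 2),
                              grid = 101L) {
  stopifnot(inherits(params, "sv_params"))
  edge <- match.arg(edge)
  grid <- as.integer(grid)
  if (grid < 2L) stop("grid must be at least 2 per axis", call. = FALSE)
  if (any(alpha_range <= 0) || any(beta_range <= 0))
    stop("axis ranges must be positive", call. = FALSE)

  rp0 <- edge_params(params, edge)
  alpha <- seq(alpha_range[1], alpha_range[2], length.out = grid)
  beta <- seq(beta_range[1], beta_range[2], length.out = grid)
  labels <- matrix(NA_character_, grid, grid)
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      rp <- rp0
      rp$alpha <- alpha[i]
      rp$beta <- beta[j]
      labels[i, j] <- classify_regime(compute_Q(rp))
    }
  }
  # Q_p = 0  <=>  beta = alpha * q_hp / (q_cp * d)
  # Q_m = 0  <=>  beta = alpha * q_hm / (q_cm * d)
  boundaries <- c(
    host_break_even = rp0$q_hp / (rp0$q_cp * rp0$d),
    symbiont_break_even = rp0$q_hm / (rp0$q_cm * rp0$d)
  )
  structure(list(alpha = alpha, beta = beta, labels = labels,
                 boundaries = boundaries, edge = edge),
            class = "sv_region_map")
}

#' @export
print.sv_region_map <- function(x, ...) {
  cat(sprintf("Regime map for edge %s (%d x %d cells)\n", x$edge,
              length(x$alpha), length(x$beta)))
  print(table(x$labels))
  cat(sprintf("Break-even slopes: host %.4g, symbiont %.4g\n",
              x$boundaries[["host_break_even"]],
              x$boundaries[["symbiont_break_even"]]))
  invisible(x)
}

#' Outcome phase diagram over two parameter axes
#'
#' Runs a full invasion experiment in every cell of a two-parameter
#' grid and records the outcome label. Cells whose dynamics do not
#' settle within the time cap are labelled `"non_converged"`; cells
#' whose experiment errors (for example, no viable resident) carry an
#' `"error"` label. Cells are evaluated independently, so the result
#' does not depend on evaluation order.
#'
#' @param base_params an [model_params()] object; the swept fields are
#'   overwritten per cell.
#' @param axis1,axis2 lists with fields `name` (a [model_params()]
#'   field), `values` (numeric grid vector).
#' @param propagule an [propagule_spec()].
#' @param max_time per-cell integration cap.
#' @return A list of class `sv_outcome_map`: `axis1`, `axis2`, `labels`
#'   (character matrix, rows indexed by axis1 values).
#' @export
outcome_phase_diagram <- function(base_params, axis1, axis2,
                                  propagule = propagule_spec(),
                                  max_time = 1e4) {
  stopifnot(inherits(base_params, "sv_params"))
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || !all(c("name", "values") %in% names(ax)))
      stop("each axis needs fields 'name' and 'values'", call. = FALSE)
    if (!ax$name %in% .sv_param_names)
      stop("unknown parameter axis: ", ax$name, call. = FALSE)
  }
  n1 <- length(axis1$values); n2 <- length(axis2$values)
  labels <- matrix(NA_character_, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      p <- base_params
      p[[axis1$name]] <- axis1$values[i]
      p[[axis2$name]] <- axis2$values[j]
      res <- try(invasion_experiment(p, propagule, max_time = max_time),
                 silent = TRUE)
      labels[i, j] <- if (inherits(res, "try-error")) {
        "error"
      } else if (!res$converged && !res$limit_cycle) {
        "non_converged"
      } else {
        res$outcome$label
      }
    }
  }
  structure(list(axis1 = axis1, axis2 = axis2, labels = labels),
            class = "sv_outcome_map")
}

#' Sample a parameter set under regime constraints
#'
#' Draws free parameters log-uniformly over `[1e-2, 1e1]` and rejects
#' draws until each requested host-symbiont edge falls in its required
#' interaction regime. Edges constrained to `"neutral"` have their
#' exchange coefficients forced to zero rather than sampled.
#' Deterministic under a fixed seed.
#'
#' @param constraints named character vector: names from `pn_mn`,
#'   `pn_mi`, `pi_mn`, `pi_mi`; values are [classify_regime()] labels.
#'   Unconstrained cross edges default to `"neutral"`; unconstrained
#'   resident edges are sampled freely.
#' @param seed integer seed.
#' @param range log-uniform sampling range for free coefficients.
#' @param max_draws rejection-sampling cap.
#' @param competition fixed competition coefficient applied to all four
#'   `c` parameters (sampled when `NA`).
#' @return An [model_params()] object satisfying the constraints.
#' @examples
#' p <- sample_params(c(pn_mn = "mutualistic", pi_mi = "mutualistic"),
#'                    seed = 1)
#' all_edge_regimes(p)
#' @export
sample_params <- function(constraints = c(pn_mn = "mutualistic",
                                          pi_mi = "mutualistic"),
                          seed = 1L, range = c(1e-2, 1e1),
                          max_draws = 10000L, competition = NA) {
  edges <- c("pn_mn", "pn_mi", "pi_mn", "pi_mi")
  if (is.null(names(constraints)) ||
      !all(names(constraints) %in% edges))
    stop("constraint names must be host-symbiont edges (",
         paste(edges, collapse = ", "), ")", call. = FALSE)
  full <- c(pn_mn = NA_character_, pn_mi = "neutral",
            pi_mn = "neutral", pi_mi = NA_character_)
  full[names(constraints)] <- constraints

  edge_coef <- list(pn_mn = c("alpha_nn", "beta_nn"),
                    pn_mi = c("alpha_in", "beta_ni"),
                    pi_mn = c("alpha_ni", "beta_in"),
                    pi_mi = c("alpha_ii", "beta_ii"))
  runif_log <- function(n) exp(stats::runif(n, log(range[1]), log(range[2])))

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  for (draw in seq_len(max_draws)) {
    v <- as.list(stats::setNames(runif_log(length(.sv_param_names)),
                                 .sv_param_names))
    v$d <- 1
    if (!is.na(competition))
      v[c("c_p_in", "c_p_ni", "c_m_in", "c_m_ni")] <- competition
    for (e in edges) {
      if (identical(full[[e]], "neutral")) v[edge_coef[[e]]] <- 0
    }
    p <- try(do.call(model_params, v), silent = TRUE)
    if (inherits(p, "try-error")) next
    ok <- TRUE
    for (e in edges) {
      want <- full[[e]]
      if (is.na(want)) next
      got <- classify_regime(compute_Q(edge_params(p, e)))
      if (got != want) { ok <- FALSE; break }
    }
    if (ok) return(p)
  }
  stop("could not satisfy regime constraints within ", max_draws,
       " draws", call. = FALSE)
}
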