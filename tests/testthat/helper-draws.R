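# Random states and parameter sets for property-style tests, plus an
# independent term-by-term evaluation of the exchange fluxes used as an
# oracle against the package's kernel-based implementation.

rand_state <- function(n = 4L, max = 5) stats::runif(n, 0, max)

rand_params <- function() {
  v <- as.list(stats::setNames(
    exp(stats::runif(length(symbiovade:::.sv_param_names),
                     log(1e-2), log(1e1))),
    symbiovade:::.sv_param_names))
  v$d <- stats::runif(1, 0.5, 2)
  do.call(model_params, v)
}

rand_reduced <- function() {
  v <- as.list(stats::setNames(
    exp(stats::runif(length(symbiovade:::.sv_reduced_names),
                     log(1e-2), log(1e1))),
    symbiovade:::.sv_reduced_names))
  v$d <- stats::runif(1, 0.5, 2)
  do.call(reduced_params, v)
}

# a random reduced parameter set conditioned to be mutualistic
rand_mutualistic_reduced <- function(max_tries = 1000L) {
  for (k in seq_len(max_tries)) {
    rp <- rand_reduced()
    q <- compute_Q(rp)
    if (q$Q_p > 1e-6 && q$Q_m > 1e-6) return(rp)
  }
  stop("no mutualistic draw found")
}

# direct transcription of the four net-flux expressions, written as one
# arithmetic formula per compartment (no shared kernel machinery)
oracle_net_flux <- function(state, pr) {
  pn <- state[1]; mn <- state[2]; pi_ <- state[3]; mi <- state[4]
  d <- pr$d
  Da <- pn / d + pi_ / d + mn + mi
  Db <- pn + pi_ + d * mn + d * mi
  sdiv <- function(num, den) if (den > 0) num / den else 0
  c(
    p_n = pr$q_hpn * pn * sdiv(pr$alpha_nn * mn + pr$alpha_in * mi, Da) -
      pr$q_cpn * pn * sdiv(pr$beta_nn * mn + pr$beta_ni * mi, Db),
    m_n = pr$q_cmn * mn * sdiv(pr$beta_nn * pn + pr$beta_in * pi_, Db) -
      pr$q_hmn * mn * sdiv(pr$alpha_nn * pn + pr$alpha_ni * pi_, Da),
    p_i = pr$q_hpi * pi_ * sdiv(pr$alpha_ii * mi + pr$alpha_ni * mn, Da) -
      pr$q_cpi * pi_ * sdiv(pr$beta_ii * mi + pr$beta_in * mn, Db),
    m_i = pr$q_cmi * mi * sdiv(pr$beta_ii * pi_ + pr$beta_ni * pn, Db) -
      pr$q_hmi * mi * sdiv(pr$alpha_ii * pi_ + pr$alpha_in * pn, Da)
  )
}

# parameter sets used by the scenario-endpoint regression tests
scenario1_params <- function() {
  model_params(c_p_in = 2, c_p_ni = 2, c_m_in = 2, c_m_ni = 2)
}

scenario4_params <- function() {
  model_params(alpha_ni = 0.01, beta_in = 2)
}

scenario6_params <- function() {
  model_params(alpha_in = 0.01, beta_ni = 2)
}

low_quality_invader_params <- function() {
  model_params(alpha_ni = 1, beta_in = 0.6, beta_ii = 0.6,
               c_p_in = 1, c_p_ni = 1, c_m_in = 1, c_m_ni = 1)
}
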