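# ---------------------------------------------------------------------------
# Minimal Hamiltonian Monte Carlo over log-branch-lengths: the intended
# consumer of the linear-time gradient.  Sampling is done on
# theta = log(b) with the Jacobian term, which removes the b >= 0
# boundary; the prior is independent exponential on each branch length.
# Identity mass matrix, no adaptation.
# ---------------------------------------------------------------------------

#' HMC configuration
#'
#' @param step_size Leapfrog step size epsilon (> 0) on the log-branch
#'   scale.
#' @param leapfrog_steps Number of leapfrog steps L per proposal (>= 1).
#' @param iterations Number of MCMC iterations.
#' @param seed Integer seed fixing the chain.
#' @param prior_mean Mean of the independent exponential prior on each
#'   branch length (expected-substitution units).
#' @return An `hmc_config` list.
#' @export
hmc_config <- function(step_size = 0.05, leapfrog_steps = 10L,
                       iterations = 1000L, seed = 1L, prior_mean = 0.1) {
  if (step_size <= 0 || leapfrog_steps < 1)
    pg_stop("invalid_parameter",
            "invalid-parameter: need step_size > 0 and leapfrog_steps >= 1")
  structure(list(step_size = step_size,
                 leapfrog_steps = as.integer(leapfrog_steps),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), prior_mean = prior_mean),
            class = "hmc_config")
}

#' Log-posterior and its gradient over branch lengths
#'
#' Log posterior = engine log-likelihood + independent exponential
#' log-prior + log-Jacobian of the log transform; the gradient (wrt
#' theta = log b) follows from the engine branch gradient by the chain
#' rule.
#'
#' @param b Positive branch-length vector (length 2N-2).
#' @param inst An `engine_instance`.
#' @param prior_mean Exponential prior mean.
#' @return List with `value` (log posterior), `grad_theta` (gradient wrt
#'   log b), `grad_b` (likelihood gradient wrt b) and `log_likelihood`.
#' @export
log_posterior_and_gradient <- function(b, inst, prior_mean = 0.1) {
  if (any(b <= 0))
    pg_stop("invalid_parameter", "invalid-parameter: branch lengths must be > 0")
  inst <- engine_set_branch_lengths(inst, b)
  res <- engine_run(inst, gradient = TRUE)
  gb <- unname(res$gradient$per_branch)
  lp <- res$log_likelihood + sum(stats::dexp(b, 1 / prior_mean, log = TRUE)) +
    sum(log(b))                                    # Jacobian of theta=log b
  gt <- (gb - 1 / prior_mean) * b + 1
  list(value = lp, grad_theta = gt, grad_b = gb,
       log_likelihood = res$log_likelihood)
}

#' Leapfrog integrator
#'
#' Standard velocity leapfrog on (theta, momentum) with unit mass.
#' Exposed for testing integrator reversibility and the O(epsilon^2)
#' energy-error scaling.
#'
#' @param theta Position (log branch lengths).
#' @param momentum Momentum vector of the same length.
#' @param eps Step size.
#' @param L Number of steps.
#' @param grad_fn Function `theta -> list(value, grad)` for the target
#'   log-density and gradient.
#' @return List with final `theta`, `momentum`, and the target `value` and
#'   `grad` at the endpoint.
#' @export
hmc_leapfrog <- function(theta, momentum, eps, L, grad_fn) {
  g <- grad_fn(theta)
  momentum <- momentum + 0.5 * eps * g$grad
  for (l in seq_len(L)) {
    theta <- theta + eps * momentum
    g <- grad_fn(theta)
    if (l < L) momentum <- momentum + eps * g$grad
  }
  momentum <- momentum + 0.5 * eps * g$grad
  list(theta = theta, momentum = momentum, value = g$value, grad = g$grad)
}

#' Run Hamiltonian Monte Carlo over branch lengths
#'
#' Leapfrog proposals with a Metropolis accept/reject step on the joint
#' Hamiltonian; a non-finite Hamiltonian rejects the step and is counted.
#'
#' @param inst An `engine_instance`; its current branch lengths (floored
#'   at 1e-6) are the initial state.
#' @param cfg An [hmc_config()].
#' @return List with `chain` (iterations x branches matrix of branch
#'   lengths), `log_posterior` trace, `acceptance_rate`, and
#'   `divergences` (non-finite proposals).
#' @export
hmc_run <- function(inst, cfg = hmc_config()) {
  set.seed(cfg$seed)
  nb <- inst$tree$n_nodes - 1L
  theta <- log(pmax(inst$tree$brlen[seq_len(nb)], 1e-6))
  target <- function(th) {
    out <- tryCatch(log_posterior_and_gradient(exp(th), inst,
                                               cfg$prior_mean),
                    phylograd_error = function(e)
                      list(value = -Inf, grad_theta = rep(0, nb)))
    list(value = out$value, grad = out$grad_theta)
  }
  cur <- target(theta)
  chain <- matrix(NA_real_, cfg$iterations, nb)
  lp <- numeric(cfg$iterations)
  accepted <- 0L; divergences <- 0L
  for (it in seq_len(cfg$iterations)) {
    p0 <- stats::rnorm(nb)
    H0 <- -cur$value + 0.5 * sum(p0^2)
    prop <- hmc_leapfrog(theta, p0, cfg$step_size, cfg$leapfrog_steps,
                         target)
    H1 <- -prop$value + 0.5 * sum(prop$momentum^2)
    if (!is.finite(H1)) {
      divergences <- divergences + 1L
    } else if (log(stats::runif(1)) < H0 - H1) {
      theta <- prop$theta
      cur <- list(value = prop$value, grad = prop$grad)
      accepted <- accepted + 1L
    }
    chain[it, ] <- exp(theta)
    lp[it] <- cur$value
  }
  list(chain = chain, log_posterior = lp,
       acceptance_rate = accepted / cfg$iterations,
       divergences = divergences, config = cfg)
}

#' Write an HMC chain as TSV
#'
#' Columns: iteration, log_posterior, then one column per branch
#' (`b<child-node id>`), suitable for standard MCMC trace viewers.
#'
#' @param run Output of [hmc_run()].
#' @param path Output path.
#' @export
write_chain_tsv <- function(run, path) {
  df <- data.frame(iteration = seq_len(nrow(run$chain)),
                   log_posterior = run$log_posterior, run$chain)
  names(df)[-(1:2)] <- paste0("b", seq_len(ncol(run$chain)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
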