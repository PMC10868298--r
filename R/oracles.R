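# ---------------------------------------------------------------------------
# Independent, slow, obviously-correct computations used to validate the
# engine: the O(N^2) matrix-derivative gradient, central finite
# differences, and exhaustive likelihood enumeration over internal states.
# ---------------------------------------------------------------------------

# per-pattern site likelihoods from an unscaled pruning pass
site_likelihoods <- function(ws, root_prior, rates) {
  root <- ws$tree$n_nodes
  L <- numeric(ws$C)
  for (r in seq_len(ws$R))
    L <- L + rates$weights[r] * colSums(ws$post[[root]][[r]] * root_prior)
  L * exp(ws$cumlog[root, ])
}

#' O(N^2) matrix-derivative gradient oracle
#'
#' For each branch i in turn, reruns the pruning recursion with the
#' transition matrix on branch i replaced by its branch-length derivative;
#' the per-pattern ratio of the two root evaluations is the per-pattern
#' log-likelihood derivative, reduced by the pattern weights.  O(N) per
#' branch, O(N^2) total.
#'
#' @param tree A `phylogeny`.
#' @param tips List of N dense S x C tip indicator matrices in tree tip
#'   order.
#' @param Q A `generator_matrix`.
#' @param rates A `rate_categories`.
#' @param weights Pattern weights.
#' @param root_prior Root prior (default stationary).
#' @param per_category Optional per-category generators Q^(r).
#' @return Numeric vector of 2N-2 branch-length derivatives.
#' @export
gradient_matrix_derivative <- function(tree, tips, Q, rates, weights,
                                       root_prior = Q$stationary,
                                       per_category = NULL) {
  sched <- traversal_schedule(tree)
  cfg <- engine_config(scaling = "off")
  cfg$allow_negative <- TRUE     # derivative matrices have negative entries
  mats <- branch_matrix_sets(tree, Q, rates, per_category = per_category)
  dmats <- branch_matrix_sets(tree, Q, rates, derivative = TRUE,
                              per_category = per_category)
  ws <- postorder_pass(tree, sched, tips, mats, cfg)
  L <- site_likelihoods(ws, root_prior, rates)
  if (any(L <= 0))
    pg_stop("numerical_failure",
            "numerical-failure: zero site likelihood in oracle")
  nb <- tree$n_nodes - 1L
  grad <- numeric(nb)
  for (i in seq_len(nb)) {
    mats_i <- mats
    mats_i[[i]] <- dmats[[i]]
    wsd <- postorder_pass(tree, sched, tips, mats_i, cfg)
    dL <- site_likelihoods(wsd, root_prior, rates)
    grad[i] <- sum(weights * dL / L)
  }
  grad
}

#' Finite-difference gradient oracle
#'
#' Central differences of the pruning log-likelihood per branch;
#' one-sided (forward) at branch lengths shorter than the step.
#'
#' @inheritParams gradient_matrix_derivative
#' @param step Difference step on branch lengths (default 1e-6).
#' @return Numeric vector of 2N-2 approximate derivatives.
#' @export
gradient_finite_difference <- function(tree, tips, Q, rates, weights,
                                       root_prior = Q$stationary,
                                       step = 1e-6,
                                       per_category = NULL) {
  if (step <= 0) pg_stop("invalid_parameter", "invalid-parameter: step <= 0")
  sched <- traversal_schedule(tree)
  cfg <- engine_config(scaling = "always")
  ll_at <- function(tr) {
    mats <- branch_matrix_sets(tr, Q, rates, per_category = per_category)
    ws <- postorder_pass(tr, sched, tips, mats, cfg)
    log_likelihood(ws, root_prior, rates, weights)
  }
  nb <- tree$n_nodes - 1L
  grad <- numeric(nb)
  for (i in seq_len(nb)) {
    b0 <- tree$brlen[i]
    tp <- tree; tm <- tree
    if (b0 >= step) {
      tp$brlen[i] <- b0 + step
      tm$brlen[i] <- b0 - step
      grad[i] <- (ll_at(tp) - ll_at(tm)) / (2 * step)
    } else {
      tp$brlen[i] <- b0 + step
      grad[i] <- (ll_at(tp) - ll_at(tree)) / step
    }
  }
  grad
}

#' Exhaustive likelihood by enumeration over internal states
#'
#' Sums the joint probability over every assignment of states to the
#' internal and root nodes (tips marginalize over their compatibility
#' sets), for every rate category.  Refuses instances with
#' `S^(N-1) > 1e6` assignments.
#'
#' @inheritParams gradient_matrix_derivative
#' @param log Return the log-likelihood (default) rather than the
#'   likelihood.
#' @param derivative_branch Optional branch id: substitute that branch's
#'   transition matrices with their branch-length derivatives, so the
#'   enumerated per-pattern values are the derivatives dL_c/db_i (used to
#'   assemble a fully enumerated gradient).
#' @param site_values Return the length-C vector of per-pattern values
#'   instead of the weighted total.
#' @return Log-likelihood (or likelihood, or per-pattern values) as
#'   numeric.
#' @export
likelihood_exhaustive <- function(tree, tips, Q, rates, weights,
                                  root_prior = Q$stationary, log = TRUE,
                                  per_category = NULL,
                                  derivative_branch = NULL,
                                  site_values = FALSE) {
  N <- tree$n_tips
  S <- Q$size
  if (S^(N - 1) > 1e6)
    pg_stop("invalid_parameter",
            "invalid-parameter: instance too large for exhaustive oracle")
  C <- ncol(tips[[1]])
  R <- rates$count
  internals <- (N + 1L):tree$n_nodes   # root included
  nI <- length(internals)
  # transition matrices per branch per rate (shared primitive, not engine)
  P <- vector("list", tree$n_nodes - 1L)
  for (i in seq_len(tree$n_nodes - 1L)) {
    deriv <- !is.null(derivative_branch) && i == derivative_branch
    P[[i]] <- if (is.null(per_category)) {
      if (deriv) transition_derivative(Q, rates, tree$brlen[i])$matrices
      else transition_probabilities(Q, rates, tree$brlen[i])$matrices
    } else {
      lapply(per_category, function(g) {
        E <- generator_expm(g, tree$brlen[i])
        if (deriv) unname(g$Q %*% E) else E
      })
    }
  }
  L <- numeric(C)
  states <- rep(1L, nI)
  repeat {
    assign_of <- function(node) states[node - N]
    for (r in seq_len(R)) {
      # probability of this internal assignment and the tip data
      base <- root_prior[assign_of(tree$n_nodes)]
      contrib <- rep(base * rates$weights[r], C)
      for (i in seq_len(tree$n_nodes - 1L)) {
        k <- tree$parent[i]
        sk <- assign_of(k)
        if (i <= N) {
          contrib <- contrib * colSums(P[[i]][[r]][sk, ] * tips[[i]])
        } else {
          contrib <- contrib * P[[i]][[r]][sk, assign_of(i)]
        }
      }
      L <- L + contrib
    }
    # odometer increment over internal-state assignments
    pos <- 1L
    while (pos <= nI) {
      states[pos] <- states[pos] + 1L
      if (states[pos] <= S) break
      states[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > nI) break
  }
  if (site_values) return(L)
  if (log) sum(weights * base::log(L)) else prod(L^weights)
}

#' Max deviation with magnitude floor
#'
#' `max |a - b| / max(|b|, floor)`; the floor keeps near-zero entries from
#' inflating the relative error.
#'
#' @param a,b Numeric vectors of equal length.
#' @param floor Magnitude floor (default 1).
#' @return A single non-negative number.
#' @export
max_rel_dev <- function(a, b, floor = 1) {
  max(abs(a - b) / pmax(abs(b), floor))
}

#' Cross-validate the engine gradient against both oracles
#'
#' Computes the linear-time engine gradient, the O(N^2) matrix-derivative
#' oracle and the finite-difference oracle on one instance and reports
#' maximum deviations.
#'
#' @param tree,pa,model,rates,cfg Instance ingredients as in
#'   [engine_build()].
#' @param fd_step Finite-difference step.
#' @param tol_md,tol_fd Pass tolerances for the two comparisons.
#' @return An `oracle_report` list: instance descriptor, per-comparison
#'   max deviations, and pass flags.
#' @export
oracle_check <- function(tree, pa, model, rates = rate_categories(1),
                         cfg = engine_config(), fd_step = 1e-6,
                         tol_md = 1e-8, tol_fd = 1e-5) {
  inst <- engine_build(tree, pa, model, rates, cfg = cfg)
  res <- engine_run(inst, gradient = TRUE)
  g_engine <- res$gradient$per_branch
  g_md <- gradient_matrix_derivative(tree, inst$tips, model, rates,
                                     pa$weights)
  g_fd <- gradient_finite_difference(tree, inst$tips, model, rates,
                                     pa$weights, step = fd_step)
  dev_md <- max_rel_dev(g_engine, g_md)
  dev_fd <- max_rel_dev(g_engine, g_fd)
  structure(list(descriptor = list(N = tree$n_tips, S = model$size,
                                   R = rates$count, C = pa$pattern_count),
                 log_likelihood = res$log_likelihood,
                 dev_matrix_derivative = dev_md,
                 dev_finite_difference = dev_fd,
                 pass_matrix_derivative = dev_md <= tol_md,
                 pass_finite_difference = dev_fd <= tol_fd),
            class = "oracle_report")
}

#' @export
print.oracle_report <- function(x, ...) {
  d <- x$descriptor
  cat(sprintf("oracle report (N=%d S=%d R=%d C=%d): logL = %.6f\n",
              d$N, d$S, d$R, d$C, x$log_likelihood))
  cat(sprintf("  vs matrix-derivative: %.3e [%s]\n",
              x$dev_matrix_derivative,
              if (x$pass_matrix_derivative) "ok" else "FAIL"))
  cat(sprintf("  vs finite-difference: %.3e [%s]\n",
              x$dev_finite_difference,
              if (x$pass_finite_difference) "ok" else "FAIL"))
  invisible(x)
}
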