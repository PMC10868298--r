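# ---------------------------------------------------------------------------
# Likelihood engine: post-order pruning with underflow-safe rescaling, the
# pre-order recursion, the any-node likelihood identity, and the
# linear-time gradient of the log-likelihood wrt all branch lengths.
#
# Scaling bookkeeping.  With scaling active every internal node k gets one
# scaler per pattern, M_kc = max over (rate, state) of the freshly computed
# partials, shared across rate categories so the rate mixture in the
# likelihood stays valid.  We track
#   ownlog[k, c] = log M_kc
#   cumlog[k, c] = sum of ownlog over the subtree rooted at k
# so the root-pattern log-likelihood is log(p-hat' pi) + cumlog[root, c].
# The pre-order partials are built from rescaled post-order partials and
# are never rescaled themselves; they inherit the deficit
#   qcum[i, c] = qcum[k, c] + cumlog[sibling, c]
# (the parent's own scaler divides p_k, never q_k), so the any-node
# evaluation restores cumlog[i, c] + qcum[i, c] and matches the root
# exactly under rescaling.  The gradient ratio shares the same scalers in
# numerator and denominator, so they cancel there.
# ---------------------------------------------------------------------------

#' Engine configuration
#'
#' @param engine_variant `"reference"` (per-rate recursion, no padding) or
#'   `"batched"` (contiguous rate-by-pattern blocks per node, two-stage
#'   pre-order products, rate-serial gradient accumulation -- a faithful
#'   CPU analog of the batched array layout).
#' @param scaling `"always"` (default; rescale every internal node),
#'   `"off"`, or `"auto"` (rescale a pattern only when its partial maximum
#'   drops below `auto_threshold`).
#' @param pad_states Batched variant only: zero-pad the state dimension to
#'   the next multiple of 16 (e.g. 61 -> 64) mirroring aligned batched
#'   access; never changes results.
#' @param auto_threshold Rescaling trigger for `scaling = "auto"`.
#' @return An `engine_config` list.
#' @export
engine_config <- function(engine_variant = c("reference", "batched"),
                          scaling = c("always", "off", "auto"),
                          pad_states = FALSE,
                          auto_threshold = 1e-100) {
  structure(list(engine_variant = match.arg(engine_variant),
                 scaling = match.arg(scaling),
                 pad_states = isTRUE(pad_states),
                 auto_threshold = auto_threshold),
            class = "engine_config")
}

next_multiple_16 <- function(S) as.integer(16 * ceiling(S / 16))

# column maxima of a matrix (S small, C possibly large)
col_max <- function(M) do.call(pmax, c(asplit(M, 1), list(0)))

# transition (and optionally derivative) matrix sets for every branch
branch_matrix_sets <- function(tree, Q, rates, derivative = FALSE,
                               per_category = NULL) {
  out <- vector("list", tree$n_nodes - 1L)
  for (i in seq_len(tree$n_nodes - 1L)) {
    b <- tree$brlen[i]
    if (is.null(per_category)) {
      out[[i]] <- if (derivative) transition_derivative(Q, rates, b)
                  else transition_probabilities(Q, rates, b)
    } else {
      mats <- lapply(per_category, function(g) {
        if (derivative) g$Q %*% generator_expm(g, b)
        else generator_expm(g, b)
      })
      out[[i]] <- new_tmset(mats, per_category[[1]]$size,
                            if (derivative) "derivative" else "probability")
    }
  }
  out
}

get_post <- function(ws, node, r) {
  if (node <= ws$n_tips) ws$tips[[node]] else ws$post[[node]][[r]]
}

#' Post-order pruning pass
#'
#' Runs Felsenstein's pruning recursion over the whole tree: for every
#' internal node k with children i and j,
#' `p_k = (P_i p_i) * (P_j p_j)` elementwise per rate category and
#' pattern, with optional per-(node, pattern) rescaling.
#'
#' @param tree A `phylogeny`.
#' @param schedule Output of [traversal_schedule()].
#' @param tips List of N dense S x C indicator matrices (tip order = tree
#'   tip ids), e.g. `encode_tips(pa)$partials` reordered to the tree.
#' @param matrices List over branch ids (1..2N-2) of
#'   `transition_matrix_set`s.
#' @param cfg An [engine_config()].
#' @return A `partials_workspace` (post-order partials, log-scalers, and
#'   metadata) ready for [log_likelihood()] and [preorder_pass()].
#' @export
postorder_pass <- function(tree, schedule, tips, matrices,
                           cfg = engine_config()) {
  if (cfg$engine_variant == "batched")
    return(postorder_pass_batched(tree, schedule, tips, matrices, cfg))
  N <- tree$n_tips; M <- tree$n_nodes
  R <- length(matrices[[1]]$matrices)
  S <- nrow(tips[[1]]); C <- ncol(tips[[1]])
  post <- vector("list", M)
  cumlog <- matrix(0, M, C)
  ownlog <- matrix(0, M, C)
  for (row in seq_len(nrow(schedule$postorder))) {
    k <- schedule$postorder[row, 1]
    i <- schedule$postorder[row, 2]
    j <- schedule$postorder[row, 3]
    pk <- vector("list", R)
    for (r in seq_len(R)) {
      A <- matrices[[i]]$matrices[[r]] %*% get_post_ref(post, tips, N, i, r)
      B <- matrices[[j]]$matrices[[r]] %*% get_post_ref(post, tips, N, j, r)
      pk[[r]] <- A * B
      if (any(!is.finite(pk[[r]])) ||
          (!isTRUE(cfg$allow_negative) && any(pk[[r]] < 0)))
        pg_stop("numerical_failure",
                "numerical-failure: invalid partial at node ", k)
    }
    scal <- NULL
    if (cfg$scaling != "off") {
      cm <- Reduce(pmax, lapply(pk, col_max))
      scal <- rep(1, C)
      if (cfg$scaling == "always") {
        use <- cm > 0
      } else {
        use <- cm > 0 & cm < cfg$auto_threshold
      }
      scal[use] <- cm[use]
      if (any(use)) {
        inv <- 1 / scal
        for (r in seq_len(R)) pk[[r]] <- pk[[r]] * rep(inv, each = S)
        ownlog[k, ] <- log(scal)
      }
    }
    cumlog[k, ] <- cumlog[i, ] + cumlog[j, ] + ownlog[k, ]
    post[[k]] <- pk
  }
  structure(list(tree = tree, schedule = schedule, tips = tips,
                 post = post, cumlog = cumlog, ownlog = ownlog,
                 n_tips = N, S = S, C = C, R = R, cfg = cfg,
                 post_done = TRUE, pre_done = FALSE),
            class = "partials_workspace")
}

get_post_ref <- function(post, tips, N, node, r) {
  if (node <= N) tips[[node]] else post[[node]][[r]]
}

#' @export
print.partials_workspace <- function(x, ...) {
  cat("partials_workspace: S =", x$S, "C =", x$C, "R =", x$R,
      "| post:", x$post_done, "pre:", x$pre_done,
      "| scaling:", x$cfg$scaling, "\n")
  invisible(x)
}

#' Log-likelihood from a completed post-order pass
#'
#' Per pattern c the site likelihood is the rate mixture
#' `sum_r (p-hat_root' pi) P(gamma_r)` corrected by the accumulated
#' log-scalers; the total is the weighted sum of pattern log-likelihoods.
#'
#' @param ws A `partials_workspace` after [postorder_pass()].
#' @param root_prior Root state prior (usually the stationary
#'   distribution).
#' @param rates A `rate_categories`.
#' @param weights Integer pattern weights.
#' @return The log-likelihood (a single double).
#' @export
log_likelihood <- function(ws, root_prior, rates, weights) {
  if (!isTRUE(ws$post_done))
    pg_stop("invalid_state", "invalid-state: post-order pass not run")
  root <- ws$tree$n_nodes
  pi_ <- pad_vector(root_prior, ws$S)
  L <- numeric(ws$C)
  for (r in seq_len(ws$R))
    L <- L + rates$weights[r] * colSums(ws$post[[root]][[r]] * pi_)
  bad <- which(!is.finite(L) | L <= 0)
  if (length(bad))
    pg_stop("numerical_failure",
            "numerical-failure: zero or invalid site likelihood ",
            "(underflow or impossible data) at pattern ", bad[1])
  sum(weights * (log(L) + ws$cumlog[root, ]))
}

pad_vector <- function(v, S) {
  if (length(v) == S) v else c(v, rep(0, S - length(v)))
}

#' Pre-order partial-likelihood pass
#'
#' Starting from `q_root = pi`, computes for every non-root node i with
#' parent k and sibling j the pre-order partials
#' `q_i = P_i' (q_k * (P_j p_j))` per rate category -- the two-stage split
#' (sibling product, then transposed-matrix product).  Pre-order partials
#' are computed at tips too (dense).
#'
#' @inheritParams postorder_pass
#' @param ws Workspace from [postorder_pass()].
#' @param tmatrices Transposed transition matrices
#'   ([transpose_for_preorder()]), one set per branch.
#' @param root_prior Root state prior.
#' @return The workspace extended with pre-order partials and their scaler
#'   bookkeeping.
#' @export
preorder_pass <- function(tree, schedule, ws, matrices, tmatrices,
                          root_prior, cfg = ws$cfg) {
  if (!isTRUE(ws$post_done))
    pg_stop("invalid_state", "invalid-state: post-order pass not run")
  if (cfg$engine_variant == "batched")
    return(preorder_pass_batched(tree, schedule, ws, matrices, tmatrices,
                                 root_prior, cfg))
  M <- tree$n_nodes; N <- tree$n_tips
  S <- ws$S; C <- ws$C; R <- ws$R
  pre <- vector("list", M)
  qcum <- matrix(0, M, C)
  pi_ <- pad_vector(root_prior, S)
  pre[[M]] <- lapply(seq_len(R), function(r) matrix(pi_, S, C))
  for (row in seq_len(nrow(schedule$preorder))) {
    i <- schedule$preorder[row, 1]
    k <- schedule$preorder[row, 2]
    j <- schedule$preorder[row, 3]
    qi <- vector("list", R)
    for (r in seq_len(R)) {
      h <- matrices[[j]]$matrices[[r]] %*% get_post(ws, j, r)   # stage 1
      qi[[r]] <- tmatrices[[i]]$matrices[[r]] %*% (pre[[k]][[r]] * h) # stage 2
      if (any(!is.finite(qi[[r]])))
        pg_stop("numerical_failure",
                "numerical-failure: non-finite pre-order partial at node ", i)
    }
    pre[[i]] <- qi
    qcum[i, ] <- qcum[k, ] + ws$cumlog[j, ]
  }
  ws$pre <- pre
  ws$qcum <- qcum
  ws$root_prior <- root_prior
  ws$pre_done <- TRUE
  ws
}

#' Log-likelihood evaluated at any node
#'
#' Uses the identity that per pattern
#' `sum_r (p_i' q_i) P(gamma_r)` is the same site likelihood for every
#' node i, so the weighted total must match [log_likelihood()] at the root
#' (with the scaler bookkeeping restored).
#'
#' @param ws Workspace after both passes.
#' @param node Node id in 1..(2N-1).
#' @param rates A `rate_categories`.
#' @param weights Pattern weights.
#' @return The log-likelihood evaluated at `node`.
#' @export
log_likelihood_at_node <- function(ws, node, rates, weights) {
  if (!isTRUE(ws$pre_done))
    pg_stop("invalid_state", "invalid-state: pre-order pass not run")
  L <- numeric(ws$C)
  for (r in seq_len(ws$R))
    L <- L + rates$weights[r] *
      colSums(get_post(ws, node, r) * ws$pre[[node]][[r]])
  bad <- which(!is.finite(L) | L <= 0)
  if (length(bad))
    pg_stop("numerical_failure",
            "numerical-failure: zero site likelihood at pattern ", bad[1])
  sum(weights * (log(L) + ws$cumlog[node, ] + ws$qcum[node, ]))
}

#' Linear-time gradient wrt all branch lengths
#'
#' For every branch i (indexed by child node) and pattern c the
#' contribution is the ratio of rate mixtures
#' `[sum_r gamma_r (p' Q' q) P(gamma_r)] / [sum_r (p' q) P(gamma_r)]`,
#' accumulated rate-serially; pattern contributions are then reduced by
#' their weights.  Rescaling constants cancel in the ratio, so the result
#' is identical with scaling on or off.
#'
#' @param ws Workspace after both passes.
#' @param tree The `phylogeny` (must match the workspace).
#' @param Q The `generator_matrix` (ignored when `per_category` given).
#' @param rates A `rate_categories`.
#' @param weights Pattern weights.
#' @param per_pattern Keep the (2N-2) x C table of per-pattern
#'   contributions.
#' @param per_category Optional list of R generators for the generalized
#'   case where Q^(r) varies arbitrarily; the gamma_r factor is then
#'   omitted (it lives inside Q^(r)).
#' @return A `gradient_result` with `per_branch` (length 2N-2, named by
#'   child node) and optionally `per_pattern`.
#' @export
branch_gradient <- function(ws, tree, Q, rates, weights,
                            per_pattern = FALSE, per_category = NULL) {
  if (!isTRUE(ws$pre_done))
    pg_stop("invalid_state", "invalid-state: pre-order pass not run")
  nb <- tree$n_nodes - 1L
  S <- ws$S; C <- ws$C; R <- ws$R
  if (is.null(per_category)) {
    tQ <- t(pad_matrix(Q$Q, S))
  } else {
    tQl <- lapply(per_category, function(g) t(pad_matrix(g$Q, S)))
  }
  per_branch <- numeric(nb)
  pp <- if (per_pattern) matrix(0, nb, C) else NULL
  for (i in seq_len(nb)) {
    numer <- numeric(C); denom <- numeric(C)
    for (r in seq_len(R)) {                       # rate-serial accumulation
      p <- get_post(ws, i, r)
      q <- ws$pre[[i]][[r]]
      w <- rates$weights[r]
      denom <- denom + w * colSums(p * q)
      if (is.null(per_category)) {
        numer <- numer + w * rates$rates[r] * colSums(p * (tQ %*% q))
      } else {
        numer <- numer + w * colSums(p * (tQl[[r]] %*% q))
      }
    }
    bad <- which(denom <= 0 | !is.finite(denom))
    if (length(bad))
      pg_stop("numerical_failure",
              "numerical-failure: zero gradient denominator at branch ", i,
              ", pattern ", bad[1])
    contrib <- numer / denom
    per_branch[i] <- reduce_site_contributions(contrib, weights)
    if (per_pattern) pp[i, ] <- contrib
  }
  new_gradient_result(per_branch, pp)
}

new_gradient_result <- function(per_branch, per_pattern = NULL) {
  names(per_branch) <- seq_along(per_branch)
  structure(list(per_branch = per_branch, per_pattern = per_pattern),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat("gradient over", length(x$per_branch), "branches; |g|_max =",
      max(abs(x$per_branch)), "\n")
  invisible(x)
}

#' Reduce per-pattern contributions to per-branch values
#'
#' Weighted summation over patterns in fixed ascending pattern order, so
#' repeated runs are bit-reproducible.
#'
#' @param contributions Numeric vector (length C) or (branches x C)
#'   matrix of per-pattern gradient contributions.
#' @param weights Integer pattern weights.
#' @return A scalar (vector input) or per-branch vector (matrix input).
#' @export
reduce_site_contributions <- function(contributions, weights) {
  if (is.matrix(contributions))
    return(as.vector(contributions %*% weights))
  sum(contributions * weights)
}

#' Reduce the gradient over sets of branches
#'
#' Sums per-branch gradient entries within each (disjoint) branch set --
#' e.g. the two root-child branches for the unrooted convention, or all
#' branches under a strict molecular clock.
#'
#' @param grad A `gradient_result`.
#' @param branch_sets Named list of disjoint integer vectors of branch
#'   ids.
#' @return Named numeric vector, one scalar per set.
#' @export
reduce_branch_set <- function(grad, branch_sets) {
  all_ids <- unlist(branch_sets)
  if (anyDuplicated(all_ids))
    pg_stop("invalid_parameter", "invalid-parameter: branch sets overlap")
  if (any(all_ids < 1 | all_ids > length(grad$per_branch)))
    pg_stop("invalid_parameter", "invalid-parameter: branch id out of range")
  vapply(branch_sets, function(s) sum(grad$per_branch[s]), numeric(1))
}

# ---------------------------------------------------------------------------
# Batched variant: one contiguous S_pad x (R*C) block per node (rate-major
# columns), padded matrices, precomputed transposes, two sequenced batched
# products for the pre-order stage and a rate-serial state-matrix
# accumulation for the gradient.  Numerically identical to the reference
# path (zero padding adds exact zeros).
# ---------------------------------------------------------------------------

pad_tmset <- function(tmset, pad) {
  out <- tmset
  out$matrices <- lapply(tmset$matrices, pad_matrix, pad = pad)
  out$pad_width <- pad
  out
}

rate_cols <- function(r, C) ((r - 1L) * C + 1L):(r * C)

postorder_pass_batched <- function(tree, schedule, tips, matrices, cfg) {
  N <- tree$n_tips; M <- tree$n_nodes
  R <- length(matrices[[1]]$matrices)
  S <- nrow(tips[[1]]); C <- ncol(tips[[1]])
  Sp <- if (cfg$pad_states) next_multiple_16(S) else S
  mats <- lapply(matrices, pad_tmset, pad = Sp)
  # tip blocks: indicator partials replicated across rate-major columns
  tipblk <- lapply(tips, function(m) {
    mp <- if (Sp > S) rbind(m, matrix(0, Sp - S, C)) else m
    mp[, rep(seq_len(C), times = R), drop = FALSE]
  })
  post <- vector("list", M)
  cumlog <- matrix(0, M, C)
  ownlog <- matrix(0, M, C)
  blk <- function(node) if (node <= N) tipblk[[node]] else post[[node]]
  for (row in seq_len(nrow(schedule$postorder))) {
    k <- schedule$postorder[row, 1]
    i <- schedule$postorder[row, 2]
    j <- schedule$postorder[row, 3]
    bi <- blk(i); bj <- blk(j)
    pk <- matrix(0, Sp, R * C)
    for (r in seq_len(R)) {
      cols <- rate_cols(r, C)
      pk[, cols] <- (mats[[i]]$matrices[[r]] %*% bi[, cols, drop = FALSE]) *
                    (mats[[j]]$matrices[[r]] %*% bj[, cols, drop = FALSE])
    }
    if (any(!is.finite(pk)) ||
        (!isTRUE(cfg$allow_negative) && any(pk < 0)))
      pg_stop("numerical_failure",
              "numerical-failure: invalid partial at node ", k)
    if (cfg$scaling != "off") {
      cm <- numeric(C)
      for (r in seq_len(R))
        cm <- pmax(cm, col_max(pk[, rate_cols(r, C), drop = FALSE]))
      use <- if (cfg$scaling == "always") cm > 0
             else cm > 0 & cm < cfg$auto_threshold
      if (any(use)) {
        scal <- rep(1, C); scal[use] <- cm[use]
        pk <- pk * rep(rep(1 / scal, times = R), each = Sp)
        ownlog[k, ] <- log(scal)
      }
    }
    cumlog[k, ] <- cumlog[i, ] + cumlog[j, ] + ownlog[k, ]
    post[[k]] <- pk
  }
  # expose the same per-rate view as the reference engine
  post_view <- vector("list", M)
  for (k in (N + 1L):M)
    post_view[[k]] <- lapply(seq_len(R), function(r)
      post[[k]][seq_len(S), rate_cols(r, C), drop = FALSE])
  structure(list(tree = tree, schedule = schedule, tips = tips,
                 post = post_view, post_blocks = post, tip_blocks = tipblk,
                 cumlog = cumlog, ownlog = ownlog,
                 n_tips = N, S = S, S_pad = Sp, C = C, R = R, cfg = cfg,
                 post_done = TRUE, pre_done = FALSE),
            class = "partials_workspace")
}

preorder_pass_batched <- function(tree, schedule, ws, matrices, tmatrices,
                                  root_prior, cfg) {
  M <- tree$n_nodes; N <- tree$n_tips
  S <- ws$S; Sp <- ws$S_pad; C <- ws$C; R <- ws$R
  mats <- lapply(matrices, pad_tmset, pad = Sp)
  tmats <- lapply(tmatrices, pad_tmset, pad = Sp)
  pre <- vector("list", M)
  qcum <- matrix(0, M, C)
  pi_ <- pad_vector(root_prior, Sp)
  pre[[M]] <- matrix(pi_, Sp, R * C)
  blk <- function(node) if (node <= N) ws$tip_blocks[[node]]
                        else ws$post_blocks[[node]]
  for (row in seq_len(nrow(schedule$preorder))) {
    i <- schedule$preorder[row, 1]
    k <- schedule$preorder[row, 2]
    j <- schedule$preorder[row, 3]
    bj <- blk(j)
    qi <- matrix(0, Sp, R * C)
    for (r in seq_len(R)) {
      cols <- rate_cols(r, C)
      h <- mats[[j]]$matrices[[r]] %*% bj[, cols, drop = FALSE]  # stage 1
      qi[, cols] <- tmats[[i]]$matrices[[r]] %*%
        (pre[[k]][, cols, drop = FALSE] * h)                     # stage 2
    }
    if (any(!is.finite(qi)))
      pg_stop("numerical_failure",
              "numerical-failure: non-finite pre-order partial at node ", i)
    pre[[i]] <- qi
    qcum[i, ] <- qcum[k, ] + ws$cumlog[j, ]
  }
  pre_view <- vector("list", M)
  for (k in seq_len(M))
    pre_view[[k]] <- lapply(seq_len(R), function(r)
      pre[[k]][seq_len(S), rate_cols(r, C), drop = FALSE])
  ws$pre <- pre_view
  ws$pre_blocks <- pre
  ws$qcum <- qcum
  ws$root_prior <- root_prior
  ws$pre_done <- TRUE
  ws
}

# ---------------------------------------------------------------------------
# One-stop instance API used by the CLI, the sampler and most tests
# ---------------------------------------------------------------------------

#' Build a likelihood-engine instance
#'
#' Bundles tree, encoded tip data, model and rate categories, precomputes
#' per-branch transition matrices and their transposes, and exposes
#' log-likelihood and gradient computations.
#'
#' @param tree A `phylogeny`.
#' @param pa A `pattern_alignment` covering all tree taxa.
#' @param model A `generator_matrix`.
#' @param rates A `rate_categories` (default: one unit-rate category).
#' @param root_prior Root state prior (default: the model's stationary
#'   distribution).
#' @param cfg An [engine_config()].
#' @param per_category Optional list of R generators for per-category
#'   processes Q^(r); default ties Q^(r) = gamma_r Q.
#' @return An `engine_instance` list.
#' @export
engine_build <- function(tree, pa, model, rates = rate_categories(1),
                         root_prior = NULL, cfg = engine_config(),
                         per_category = NULL) {
  if (!all(tree$taxon_names %in% pa$taxon_names))
    pg_stop("input_error", "input-error: alignment is missing taxa: ",
            paste(setdiff(tree$taxon_names, pa$taxon_names), collapse = ", "))
  enc <- encode_tips(pa)
  ord <- match(tree$taxon_names, pa$taxon_names)
  tips <- enc$partials[ord]
  if (is.null(root_prior)) root_prior <- model$stationary
  sched <- traversal_schedule(tree)
  mats <- branch_matrix_sets(tree, model, rates, per_category = per_category)
  tmats <- lapply(mats, transpose_for_preorder)
  structure(list(tree = tree, pa = pa, model = model, rates = rates,
                 root_prior = root_prior, cfg = cfg, schedule = sched,
                 tips = tips, matrices = mats, tmatrices = tmats,
                 per_category = per_category,
                 weights = pa$weights),
            class = "engine_instance")
}

#' @export
print.engine_instance <- function(x, ...) {
  cat("engine_instance: N =", x$tree$n_tips, "C =", x$pa$pattern_count,
      "S =", x$pa$state_count, "R =", x$rates$count,
      "variant =", x$cfg$engine_variant, "\n")
  invisible(x)
}

#' Run the engine: log-likelihood and/or gradient
#'
#' @param inst An `engine_instance`.
#' @param gradient Also compute the branch-length gradient.
#' @param per_pattern Retain per-pattern gradient contributions.
#' @return List with `log_likelihood`, and when requested `gradient` (a
#'   `gradient_result`) and the `workspace`.
#' @export
engine_run <- function(inst, gradient = TRUE, per_pattern = FALSE) {
  ws <- postorder_pass(inst$tree, inst$schedule, inst$tips, inst$matrices,
                       inst$cfg)
  ll <- log_likelihood(ws, inst$root_prior, inst$rates, inst$weights)
  out <- list(log_likelihood = ll, workspace = ws)
  if (gradient) {
    ws <- preorder_pass(inst$tree, inst$schedule, ws, inst$matrices,
                        inst$tmatrices, inst$root_prior, inst$cfg)
    out$workspace <- ws
    out$gradient <- branch_gradient(ws, inst$tree, inst$model, inst$rates,
                                    inst$weights, per_pattern = per_pattern,
                                    per_category = inst$per_category)
  }
  out
}

#' Re-evaluate an instance at new branch lengths
#'
#' Rebuilds only the per-branch transition matrices (the expensive
#' eigendecomposition is cached inside the generator), leaving tip
#' encodings and schedules untouched.
#'
#' @param inst An `engine_instance`.
#' @param brlen Numeric vector of 2N-2 branch lengths (by child node id).
#' @return The updated instance.
#' @export
engine_set_branch_lengths <- function(inst, brlen) {
  nb <- inst$tree$n_nodes - 1L
  if (length(brlen) != nb || any(!is.finite(brlen)) || any(brlen < 0))
    pg_stop("invalid_parameter",
            "invalid-parameter: need ", nb, " finite nonnegative lengths")
  inst$tree$brlen[seq_len(nb)] <- brlen
  inst$matrices <- branch_matrix_sets(inst$tree, inst$model, inst$rates,
                                      per_category = inst$per_category)
  inst$tmatrices <- lapply(inst$matrices, transpose_for_preorder)
  inst
}

#' Maximum-likelihood branch lengths by gradient-based optimization
#'
#' Maximizes the engine log-likelihood over all branch lengths with
#' L-BFGS-B on log-branch-lengths, using the linear-time analytic
#' gradient via the chain rule.
#'
#' @param inst An `engine_instance`.
#' @param init Initial branch lengths (default: the instance's current
#'   lengths floored at `min_length`).
#' @param min_length Lower floor applied to initial values (log
#'   parameterization requires positive lengths).
#' @param control Passed to [stats::optim()] (default
#'   `list(maxit = 200)`).
#' @return List with `branch_lengths` (the optimum), `log_likelihood`,
#'   `convergence` (0 = converged) and the optimizer `counts`.
#' @export
optimize_branch_lengths <- function(inst, init = NULL, min_length = 1e-4,
                                    control = list(maxit = 200)) {
  nb <- inst$tree$n_nodes - 1L
  if (is.null(init)) init <- inst$tree$brlen[seq_len(nb)]
  theta0 <- log(pmax(init, min_length))
  negll <- function(theta) {
    ii <- engine_set_branch_lengths(inst, exp(theta))
    -engine_run(ii, gradient = FALSE)$log_likelihood
  }
  neggrad <- function(theta) {
    ii <- engine_set_branch_lengths(inst, exp(theta))
    g <- engine_run(ii, gradient = TRUE)$gradient$per_branch
    -unname(g) * exp(theta)
  }
  fit <- stats::optim(theta0, negll, neggrad, method = "L-BFGS-B",
                      control = control)
  list(branch_lengths = exp(fit$par), log_likelihood = -fit$value,
       convergence = fit$convergence, counts = fit$counts)
}
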