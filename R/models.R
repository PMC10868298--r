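# ---------------------------------------------------------------------------
# GeneratorMatrix: an S x S CTMC infinitesimal generator with stationary
# distribution pi.  Reversible generators carry a cached symmetric
# eigendecomposition (via the pi^{1/2} similarity transform) that is reused
# for every (rate category, branch length) exponentiation.
# ---------------------------------------------------------------------------

new_generator <- function(Q, pi, reversible, code_tag = NULL) {
  S <- nrow(Q)
  g <- structure(
    list(size = S, Q = Q, stationary = pi, reversible = reversible,
         code_tag = code_tag, eig = NULL),
    class = "generator_matrix"
  )
  if (reversible) g$eig <- symmetric_eigen(Q, pi)
  g
}

# eigendecomposition of D^{1/2} Q D^{-1/2} (symmetric for reversible Q)
symmetric_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2        # symmetrize away rounding noise
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = e$vectors / sp,        # D^{-1/2} U  (columns)
       left = t(e$vectors * sp))      # U' D^{1/2}  (rows)
}

#' @export
print.generator_matrix <- function(x, ...) {
  cat("CTMC generator: S =", x$size,
      if (x$reversible) "(reversible)" else "(non-reversible)",
      if (!is.null(x$code_tag)) paste0("[", x$code_tag, "]") else "", "\n")
  invisible(x)
}

validate_generator <- function(g, tol_row = 1e-12, tol_pi = 1e-10) {
  Q <- g$Q
  offd <- Q; diag(offd) <- 0
  stopifnot(all(offd >= -1e-14))
  stopifnot(max(abs(rowSums(Q))) < tol_row * max(1, max(abs(Q))))
  stopifnot(max(abs(g$stationary %*% Q)) < tol_pi * max(1, max(abs(Q))))
  stopifnot(abs(sum(g$stationary) - 1) < 1e-12, all(g$stationary >= 0))
  invisible(TRUE)
}

# mean substitution rate -sum_s pi_s Q_ss
mean_rate <- function(Q, pi) -sum(pi * diag(Q))

# stationary distribution of an arbitrary generator: least-squares solution
# of pi Q = 0 with sum(pi) = 1 (SVD-based, tolerant of rank deficiency --
# e.g. a block-diagonal composite with zero switching)
stationary_distribution <- function(Q) {
  S <- nrow(Q)
  A <- rbind(t(Q), rep(1, S))
  b <- c(rep(0, S), 1)
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  pi <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  pi <- as.vector(pi)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' General time-reversible (GTR) nucleotide generator
#'
#' Builds the 4-state GTR infinitesimal generator with off-diagonal rates
#' `Q[s,t] = r_st * pi_t` where `r_st` are the six symmetric
#' exchangeabilities in the order AC, AG, AT, CG, CT, GT over the state
#' alphabet (A, C, G, T).
#'
#' @param exchangeabilities Six non-negative reals (AC, AG, AT, CG, CT, GT).
#' @param base_frequencies Four strictly positive frequencies summing to 1
#'   (A, C, G, T).
#' @param normalize If `TRUE` (default), rescale so the expected
#'   substitution rate at stationarity is 1, i.e. branch lengths are in
#'   expected-substitutions units.
#' @return A `generator_matrix` object.
#' @examples
#' g <- gtr_generator(rep(1, 6), rep(0.25, 4))  # Jukes-Cantor
#' g$Q
#' @export
gtr_generator <- function(exchangeabilities, base_frequencies,
                          normalize = TRUE) {
  if (length(exchangeabilities) != 6 || any(exchangeabilities < 0))
    stop("invalid-parameter: need 6 nonnegative exchangeabilities")
  if (all(exchangeabilities == 0))
    stop("invalid-parameter: all exchangeabilities are zero")
  if (length(base_frequencies) != 4 || any(base_frequencies <= 0))
    stop("invalid-parameter: base frequencies must be strictly positive")
  if (abs(sum(base_frequencies) - 1) > 1e-8)
    stop("invalid-parameter: base frequencies must sum to 1")
  pi <- base_frequencies / sum(base_frequencies)
  R <- matrix(0, 4, 4, dimnames = list(c("A","C","G","T"), c("A","C","G","T")))
  R[1,2] <- R[2,1] <- exchangeabilities[1]  # AC
  R[1,3] <- R[3,1] <- exchangeabilities[2]  # AG
  R[1,4] <- R[4,1] <- exchangeabilities[3]  # AT
  R[2,3] <- R[3,2] <- exchangeabilities[4]  # CG
  R[2,4] <- R[4,2] <- exchangeabilities[5]  # CT
  R[3,4] <- R[4,3] <- exchangeabilities[6]  # GT
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  if (normalize) Q <- Q / mean_rate(Q, pi)
  new_generator(Q, pi, reversible = TRUE)
}

#' Goldman-Yang-style codon model generator
#'
#' State space: the sense codons of `genetic_code`, indexed
#' lexicographically over (T, C, A, G).  The rate from codon `s` to codon
#' `t` differing at exactly one nucleotide position is
#' `pi_t * kappa^[transition] * omega^[nonsynonymous]`; codons differing at
#' two or more positions do not exchange directly.  The generator is
#' normalized to mean rate 1 at stationarity.
#'
#' @param kappa Transition:transversion rate ratio (> 0).
#' @param omega Nonsynonymous:synonymous rate ratio (dN/dS, >= 0).
#' @param codon_frequencies Stationary codon frequencies, one per sense
#'   codon (default: equal).
#' @param code Genetic-code name (see [genetic_code()]).
#' @return A `generator_matrix` with `code_tag` recording the code.
#' @export
codon_generator <- function(kappa, omega, codon_frequencies = NULL,
                            code = "universal") {
  if (!is.numeric(kappa) || kappa <= 0)
    stop("invalid-parameter: kappa must be > 0")
  if (!is.numeric(omega) || omega < 0)
    stop("invalid-parameter: omega must be >= 0")
  tab <- genetic_code(code)
  codons <- names(tab)[tab != "*"]
  aa <- tab[tab != "*"]
  S <- length(codons)
  if (is.null(codon_frequencies)) codon_frequencies <- rep(1 / S, S)
  if (length(codon_frequencies) != S)
    stop("invalid-parameter: need ", S, " codon frequencies for code '",
         code, "'")
  if (any(codon_frequencies <= 0) ||
      abs(sum(codon_frequencies) - 1) > 1e-8)
    stop("invalid-parameter: codon frequencies must be positive and sum to 1")
  pi <- codon_frequencies / sum(codon_frequencies)

  cmat <- do.call(rbind, strsplit(codons, ""))
  purines <- c("A", "G")
  is_transition <- function(x, y) {
    (x %in% purines) == (y %in% purines)  # same chemical class, x != y
  }
  Q <- matrix(0, S, S, dimnames = list(codons, codons))
  for (s in seq_len(S)) {
    for (t in seq_len(S)) {
      if (s == t) next
      diff <- which(cmat[s, ] != cmat[t, ])
      if (length(diff) != 1L) next
      rate <- pi[t]
      if (is_transition(cmat[s, diff], cmat[t, diff])) rate <- rate * kappa
      if (aa[s] != aa[t]) rate <- rate * omega
      Q[s, t] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  mr <- mean_rate(Q, pi)
  if (mr <= 0) stop("invalid-parameter: degenerate codon generator")
  Q <- Q / mr
  new_generator(Q, pi, reversible = TRUE, code_tag = code)
}

#' Markov-modulated composite generator
#'
#' Stacks several equal-size component generators into one block generator:
#' diagonal blocks are the component generators, off-diagonal block (u, v)
#' is `switching[u, v]` times the identity, so the hidden component process
#' switches without a simultaneous character substitution.  The composite
#' is normalized to mean rate 1 under its own stationary distribution.
#'
#' @param components List of >= 2 `generator_matrix` objects of equal size.
#' @param switching Non-negative square matrix of between-component rates;
#'   its diagonal is ignored.
#' @param normalize Rescale composite to mean rate 1 (default `TRUE`).
#' @return A `generator_matrix` of size `length(components) * S0`,
#'   non-reversible in general.
#' @export
markov_modulated_generator <- function(components, switching,
                                       normalize = TRUE) {
  K <- length(components)
  if (K < 2) stop("invalid-parameter: need at least 2 components")
  sizes <- vapply(components, function(g) g$size, integer(1))
  if (length(unique(sizes)) != 1)
    stop("invalid-parameter: component state-space sizes differ")
  S0 <- sizes[1]
  switching <- as.matrix(switching)
  if (!all(dim(switching) == c(K, K)) || any(switching[row(switching) != col(switching)] < 0))
    stop("invalid-parameter: switching must be a KxK nonnegative matrix")
  S <- K * S0
  Q <- matrix(0, S, S)
  for (u in seq_len(K)) {
    iu <- (u - 1) * S0 + seq_len(S0)
    Q[iu, iu] <- components[[u]]$Q
    for (v in seq_len(K)) {
      if (u == v) next
      iv <- (v - 1) * S0 + seq_len(S0)
      Q[iu, iv] <- Q[iu, iv] + diag(switching[u, v], S0)
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  pi <- stationary_distribution(Q)
  if (normalize) {
    mr <- mean_rate(Q, pi)
    if (mr > 0) Q <- Q / mr
  }
  new_generator(Q, pi, reversible = FALSE,
                code_tag = components[[1]]$code_tag)
}

# ---------------------------------------------------------------------------
# RateCategories: discrete-gamma among-site rate variation
# ---------------------------------------------------------------------------

#' Discrete-gamma rate categories
#'
#' Approximates gamma-distributed among-site rate variation with `R`
#' equal-weight categories.  Category rates are the means of the
#' gamma(shape, shape) distribution over equal-probability quantile bands
#' (computed via the incomplete-gamma identity), then renormalized so the
#' mixture mean is exactly 1.
#'
#' @param shape Gamma shape parameter alpha (> 0); small alpha = strong
#'   rate heterogeneity.
#' @param category_count Number of categories `R` (>= 1).
#' @return A `rate_categories` list with `count`, ascending `rates`, and
#'   equal `weights`.
#' @examples
#' discrete_gamma(0.5, 4)$rates
#' @export
discrete_gamma <- function(shape, category_count = 4L) {
  if (!is.numeric(shape) || shape <= 0)
    stop("invalid-parameter: gamma shape must be > 0")
  R <- as.integer(category_count)
  if (R < 1) stop("invalid-parameter: need at least one rate category")
  if (R == 1L) return(rate_categories(1, 1))
  q <- stats::qgamma(seq(0, 1, length.out = R + 1), shape = shape,
                     rate = shape)
  # mean of X ~ Gamma(a, a) over band (q_l, q_u]:
  #   E[X; band] = F_{a+1}(q_u) - F_{a+1}(q_l)   (since E[X] = 1)
  upper <- stats::pgamma(q[-1], shape = shape + 1, rate = shape)
  lower <- stats::pgamma(q[-(R + 1)], shape = shape + 1, rate = shape)
  rates <- R * (upper - lower)
  rates <- rates / mean(rates)          # pin the mixture mean at exactly 1
  rate_categories(rates, rep(1 / R, R))
}

#' Explicit rate categories
#'
#' @param rates Non-negative category rate scalars, ascending.
#' @param weights Category probabilities (default equal), summing to 1.
#' @return A `rate_categories` list.
#' @export
rate_categories <- function(rates, weights = NULL) {
  R <- length(rates)
  if (is.null(weights)) weights <- rep(1 / R, R)
  if (length(weights) != R || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-10)
    stop("invalid-parameter: weights must be probabilities summing to 1")
  if (any(rates < 0) || is.unsorted(rates))
    stop("invalid-parameter: rates must be nonnegative and ascending")
  structure(list(count = R, rates = as.numeric(rates),
                 weights = as.numeric(weights)),
            class = "rate_categories")
}

# ---------------------------------------------------------------------------
# Finite-time transition probabilities P^(r)(b) = exp(gamma_r * b * Q) and
# their branch-length derivatives gamma_r * Q * P^(r)(b).
# ---------------------------------------------------------------------------

# exp(tQ): cached symmetric eigendecomposition for reversible generators,
# scaling-and-squaring (Matrix::expm) otherwise
generator_expm <- function(g, t) {
  if (t == 0) return(diag(g$size))
  if (g$reversible) {
    e <- g$eig
    P <- e$right %*% (exp(e$values * t) * e$left)
  } else {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(g$Q * t)))
  }
  if (any(!is.finite(P)))
    stop("numerical-failure: non-finite transition probabilities")
  P[P < 0] <- 0
  dimnames(P) <- NULL
  P
}

#' Transition probability matrices for one branch
#'
#' For each rate category r computes `P^(r)(b) = exp(gamma_r * b * Q)`.
#'
#' @param Q A `generator_matrix`.
#' @param rates A `rate_categories` object (default: single unit rate).
#' @param branch_length Branch length b >= 0 in expected-substitution units.
#' @return A `transition_matrix_set`: list of R row-stochastic S x S
#'   matrices (field `matrices`), plus `pad_width = S` (no padding in the
#'   reference path) and `kind = "probability"`.
#' @export
transition_probabilities <- function(Q, rates = rate_categories(1),
                                     branch_length) {
  check_branch_length(branch_length)
  mats <- lapply(rates$rates, function(g) generator_expm(Q, g * branch_length))
  new_tmset(mats, Q$size, "probability")
}

#' Branch-length derivatives of transition probabilities
#'
#' For each rate category r computes
#' `dP^(r)/db = gamma_r * Q * exp(gamma_r * b * Q)`; rows sum to zero.
#'
#' @inheritParams transition_probabilities
#' @return A `transition_matrix_set` with `kind = "derivative"`.
#' @export
transition_derivative <- function(Q, rates = rate_categories(1),
                                  branch_length) {
  check_branch_length(branch_length)
  mats <- lapply(rates$rates, function(g) {
    unname(g * (Q$Q %*% generator_expm(Q, g * branch_length)))
  })
  new_tmset(mats, Q$size, "derivative")
}

check_branch_length <- function(b) {
  if (!is.numeric(b) || length(b) != 1 || !is.finite(b) || b < 0)
    stop("invalid-parameter: branch length must be finite and >= 0")
}

new_tmset <- function(mats, S, kind, pad_width = S) {
  structure(list(matrices = mats, size = S, pad_width = pad_width,
                 kind = kind),
            class = "transition_matrix_set")
}

#' Transpose a transition matrix set for the pre-order pass
#'
#' The pre-order recursion multiplies by the transpose of the child-branch
#' transition matrix; this mirrors precomputing all transposes before the
#' pre-order traversal.  Padding, if any, is preserved.
#'
#' @param tmset A `transition_matrix_set`.
#' @return The element-wise transposed set.
#' @export
transpose_for_preorder <- function(tmset) {
  out <- tmset
  out$matrices <- lapply(tmset$matrices, t)
  out
}

# zero-pad an S x S matrix to pad x pad (rows/cols beyond S exactly 0)
pad_matrix <- function(M, pad) {
  S <- nrow(M)
  if (pad == S) return(M)
  out <- matrix(0, pad, pad)
  out[seq_len(S), seq_len(S)] <- M
  out
}

#' @export
print.transition_matrix_set <- function(x, ...) {
  cat("transition_matrix_set:", length(x$matrices), "rate categories, S =",
      x$size, "pad =", x$pad_width, "kind =", x$kind, "\n")
  invisible(x)
}
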