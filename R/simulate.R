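# ---------------------------------------------------------------------------
# Synthetic data under the exact generative model: random trees by
# sequential coalescence and CTMC-evolved alignments with discrete rate
# heterogeneity.  One seeded random stream per simulation, consumed in
# documented order (per column: rate category, root state, then pre-order
# branch transitions), so outputs are exactly reproducible.
# ---------------------------------------------------------------------------

#' Random rooted bifurcating tree
#'
#' Builds the topology by random sequential coalescence: starting from N
#' lineages, repeatedly joins two uniformly chosen lineages until one
#' remains.  Branch lengths are i.i.d. draws from the named distribution.
#'
#' @param N Number of taxa (>= 2).
#' @param branch_lengths Either a distribution descriptor
#'   `list(dist = "exponential", mean = 0.1)` (the default),
#'   `list(dist = "constant", value = x)`, or a function `n ->` n draws.
#' @param seed Integer seed fixing topology and lengths.
#' @return A `phylogeny` with taxa named `t1..tN`.
#' @export
random_tree <- function(N, branch_lengths = list(dist = "exponential",
                                                 mean = 0.1),
                        seed = 1L) {
  N <- as.integer(N)
  if (N < 2) pg_stop("invalid_parameter", "invalid-parameter: N >= 2")
  set.seed(seed)
  draw <- branch_length_sampler(branch_lengths)
  M <- 2L * N - 1L
  parent <- integer(M)
  children <- matrix(NA_integer_, M, 2)
  active <- seq_len(N)
  nxt <- N + 1L
  while (length(active) > 1L) {
    pick <- sample(length(active), 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    parent[a] <- nxt; parent[b] <- nxt
    children[nxt, ] <- c(a, b)
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  brlen <- c(draw(M - 1L), NA_real_)
  new_phylogeny(N, parent, children, brlen, paste0("t", seq_len(N)))
}

branch_length_sampler <- function(spec) {
  if (is.function(spec)) return(spec)
  switch(spec$dist,
    exponential = function(n) stats::rexp(n, rate = 1 / spec$mean),
    constant = function(n) rep(spec$value, n),
    uniform = function(n) stats::runif(n, spec$min, spec$max),
    pg_stop("invalid_parameter",
            "invalid-parameter: unknown branch-length distribution '",
            spec$dist, "'")
  )
}

#' Simulate state matrices under the CTMC model
#'
#' Per column: draw a rate category from its weights, a root state from
#' the root prior, then child states down the tree via the rows of
#' `P^(r)(b)`.
#'
#' @param tree A `phylogeny`.
#' @param Q A `generator_matrix`.
#' @param rates A `rate_categories`.
#' @param C Number of columns.
#' @param seed Integer seed.
#' @param root_prior Root state prior (default stationary).
#' @return List: `tip_states` (N x C integer matrix), `node_states`
#'   ((2N-1) x C), and `rate_category` (length-C integer vector).
#' @export
simulate_states <- function(tree, Q, rates, C, seed = 1L,
                            root_prior = Q$stationary) {
  set.seed(seed)
  C <- as.integer(C)
  if (C < 1) pg_stop("invalid_parameter", "invalid-parameter: C >= 1")
  S <- Q$size
  M <- tree$n_nodes
  sched <- traversal_schedule(tree)
  P <- vector("list", M - 1L)
  for (i in seq_len(M - 1L))
    P[[i]] <- transition_probabilities(Q, rates, tree$brlen[i])$matrices
  node_states <- matrix(0L, M, C)
  rate_cat <- integer(C)
  for (c in seq_len(C)) {
    r <- sample.int(rates$count, 1L, prob = rates$weights)
    rate_cat[c] <- r
    node_states[M, c] <- sample.int(S, 1L, prob = root_prior)
    for (row in seq_len(nrow(sched$preorder))) {
      i <- sched$preorder[row, 1]
      k <- sched$preorder[row, 2]
      node_states[i, c] <-
        sample.int(S, 1L, prob = P[[i]][[rate_cat[c]]][node_states[k, c], ])
    }
  }
  list(tip_states = node_states[seq_len(tree$n_tips), , drop = FALSE],
       node_states = node_states, rate_category = rate_cat)
}

#' Simulate an alignment under the CTMC model
#'
#' Wraps [simulate_states()] and renders tip states as sequence text:
#' A/C/G/T for 4-state models, sense-codon triplets for codon models
#' (identified by the generator's `code_tag`).
#'
#' @inheritParams simulate_states
#' @return An `alignment`.
#' @export
simulate_alignment <- function(tree, Q, rates, C, seed = 1L,
                               root_prior = Q$stationary) {
  sim <- simulate_states(tree, Q, rates, C, seed, root_prior)
  if (Q$size == 4L) {
    alphabet <- c("A", "C", "G", "T")
    width <- 1L; tag <- NULL
  } else if (!is.null(Q$code_tag)) {
    alphabet <- sense_codons(Q$code_tag)
    if (length(alphabet) != Q$size)
      pg_stop("invalid_parameter",
              "invalid-parameter: generator size does not match its code")
    width <- 3L; tag <- Q$code_tag
  } else {
    pg_stop("invalid_parameter",
            "invalid-parameter: no text alphabet for S = ", Q$size,
            "; use simulate_states()")
  }
  rows <- apply(sim$tip_states, 1, function(s)
    paste(alphabet[s], collapse = ""))
  new_alignment(tree$taxon_names, rows, width = width, code_tag = tag)
}

#' Deterministic benchmark fixtures
#'
#' Named dataset shapes used across tests and scaling runs:
#' \describe{
#'   \item{small-nt}{N = 16, C = 100 nucleotide columns, GTR + 4-category
#'     discrete gamma.}
#'   \item{small-codon}{N = 8, C = 60 codon columns (180 nt), universal
#'     codon model, 2 rate categories.}
#'   \item{tall-tree}{N = 512, C = 100, all branch lengths 1.0, GTR + 4
#'     categories -- deep enough that unscaled pruning underflows.}
#' }
#'
#' @param preset One of `"small-nt"`, `"small-codon"`, `"tall-tree"`.
#' @return List with `tree`, `alignment`, `pa` (compressed patterns),
#'   `model`, `rates`, and the preset `name`.
#' @export
benchmark_fixture <- function(preset) {
  spec <- switch(preset,
    "small-nt" = list(N = 16L, C = 100L, seed = 101L,
                      bl = list(dist = "exponential", mean = 0.1)),
    "small-codon" = list(N = 8L, C = 60L, seed = 202L,
                         bl = list(dist = "exponential", mean = 0.08)),
    "tall-tree" = list(N = 512L, C = 100L, seed = 303L,
                       bl = list(dist = "constant", value = 1.0)),
    pg_stop("invalid_parameter", "invalid-parameter: unknown preset '",
            preset, "'")
  )
  if (preset == "small-codon") {
    model <- codon_generator(kappa = 4, omega = 0.3)
    rates <- discrete_gamma(0.7, 2L)
  } else {
    model <- gtr_generator(c(1.2, 3.0, 0.8, 1.1, 3.5, 1.0),
                           c(0.30, 0.21, 0.24, 0.25))
    rates <- discrete_gamma(0.5, 4L)
  }
  tree <- random_tree(spec$N, spec$bl, seed = spec$seed)
  aln <- simulate_alignment(tree, model, rates, spec$C,
                            seed = spec$seed + 1L)
  pa <- compress_patterns(aln)
  list(name = preset, tree = tree, alignment = aln, pa = pa,
       model = model, rates = rates)
}
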