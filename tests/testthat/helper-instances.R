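# Shared fixture builders and independent oracle helpers.  Everything is
# generated in code under fixed seeds; no data files.

default_gtr <- function() {
  gtr_generator(c(1.0, 2.5, 0.7, 1.2, 3.0, 1.0), c(0.1, 0.2, 0.3, 0.4))
}

jc_model <- function() gtr_generator(rep(1, 6), rep(0.25, 4))

# random instance: tree + simulated data + encoded tips, optionally with
# ambiguity codes injected and zero-length branches
make_instance <- function(N, S = 4, R = 1, C = 10, seed = 1,
                          ambiguity = FALSE, zero_branch = FALSE,
                          model = NULL, gamma_shape = 0.5) {
  if (is.null(model)) {
    model <- if (S == 4) default_gtr() else codon_generator(2.5, 0.4)
  }
  rates <- if (R == 1) rate_categories(1) else discrete_gamma(gamma_shape, R)
  tree <- random_tree(N, seed = seed)
  if (zero_branch) tree$brlen[c(1, N)] <- 0
  aln <- simulate_alignment(tree, model, rates, C, seed = seed + 1000L)
  if (ambiguity) {
    set.seed(seed + 2000L)
    rows <- aln$rows
    if (aln$width == 1L) {
      # ambiguity codes that still contain the true base, so patterns stay
      # possible even across zero-length branches
      widen <- list(A = c("N", "-", "R", "W", "M"),
                    C = c("N", "-", "Y", "S", "M"),
                    G = c("N", "-", "R", "S", "K"),
                    T = c("N", "-", "Y", "W", "K"))
      for (n in seq_along(rows)) {
        pos <- sample(nchar(rows[n]), max(1, nchar(rows[n]) %/% 10))
        for (p in pos)
          substr(rows[n], p, p) <- sample(widen[[substr(rows[n], p, p)]], 1)
      }
    } else {
      # blank whole codons to NNN
      Cc <- nchar(rows[1]) %/% 3
      for (n in seq_along(rows)) {
        pos <- sample(Cc, max(1, Cc %/% 10))
        for (p in pos)
          substr(rows[n], 3 * p - 2, 3 * p) <- "NNN"
      }
    }
    aln$rows <- rows
  }
  pa <- compress_patterns(aln)
  enc <- encode_tips(pa)
  tips <- enc$partials[match(tree$taxon_names, pa$taxon_names)]
  list(tree = tree, aln = aln, pa = pa, model = model, rates = rates,
       tips = tips, weights = pa$weights)
}

run_engine <- function(ins, cfg = engine_config(), ...) {
  inst <- engine_build(ins$tree, ins$pa, ins$model, ins$rates, cfg = cfg, ...)
  engine_run(inst, gradient = TRUE)
}

# compensated (Kahan) summation: high-precision oracle for reductions
kahan_sum <- function(x) {
  s <- 0; comp <- 0
  for (v in x) {
    y <- v - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  s
}

# independent topological-order validation of a traversal schedule
schedule_is_valid <- function(tree, sched) {
  post_pos <- rep(NA_integer_, tree$n_nodes)
  for (r in seq_len(nrow(sched$postorder)))
    post_pos[sched$postorder[r, 1]] <- r
  ok <- TRUE
  for (r in seq_len(nrow(sched$postorder))) {
    k <- sched$postorder[r, 1]
    for (ch in sched$postorder[r, 2:3])
      if (ch > tree$n_tips) ok <- ok && !is.na(post_pos[ch]) &&
          post_pos[ch] < r
  }
  pre_pos <- rep(NA_integer_, tree$n_nodes)
  pre_pos[tree$n_nodes] <- 0L
  for (r in seq_len(nrow(sched$preorder)))
    pre_pos[sched$preorder[r, 1]] <- r
  for (r in seq_len(nrow(sched$preorder))) {
    k <- sched$preorder[r, 2]
    ok <- ok && !is.na(pre_pos[k]) && pre_pos[k] < r
  }
  ok && nrow(sched$preorder) == 2L * tree$n_tips - 2L &&
    !anyNA(pre_pos)
}

# brute-force pre-order partial oracle: q[s] = P(Y_i = s, data not below i)
# for one rate category, by enumeration over states of all nodes outside
# the subtree of i
brute_force_preorder <- function(tree, tips, P, root_prior, node_i) {
  S <- length(root_prior)
  below <- rep(FALSE, tree$n_nodes)
  mark <- function(n) {
    if (n > tree$n_tips) for (ch in tree$children[n, ]) {
      below[ch] <<- TRUE; mark(ch)
    }
  }
  mark(node_i)
  C <- ncol(tips[[1]])
  upper_internal <- setdiff(which(!below), c(node_i, seq_len(tree$n_tips)))
  q <- matrix(0, S, C)
  n_up <- length(upper_internal)
  states <- rep(1L, n_up)
  get_state <- function(n, s_i) {
    if (n == node_i) return(s_i)
    states[match(n, upper_internal)]
  }
  repeat {
    for (s_i in seq_len(S)) {
      term <- rep(1, C)
      rootn <- tree$n_nodes
      term <- term * root_prior[get_state(rootn, s_i)]
      for (br in seq_len(tree$n_nodes - 1L)) {
        if (below[br]) next                      # strictly below i: excluded
        par <- tree$parent[br]
        sp <- get_state(par, s_i)
        if (br <= tree$n_tips && br != node_i) {
          term <- term * colSums(P[[br]][sp, ] * tips[[br]])
        } else {
          term <- term * P[[br]][sp, get_state(br, s_i)]
        }
      }
      q[s_i, ] <- q[s_i, ] + term
    }
    if (n_up == 0) break
    pos <- 1L
    while (pos <= n_up) {
      states[pos] <- states[pos] + 1L
      if (states[pos] <= S) break
      states[pos] <- 1L; pos <- pos + 1L
    }
    if (pos > n_up) break
  }
  q
}

# the seeded randomized cross-validation suite used by the acceptance
# checks: spans N in {2,4,8,16}, S in {4,61}, R in {1,4}, C in {1,10,50},
# including ambiguous tips and zero-length branches
acceptance_suite_specs <- function() {
  list(
    list(N = 2,  S = 4,  R = 1, C = 1,  seed = 211),
    list(N = 4,  S = 4,  R = 4, C = 10, seed = 223, ambiguity = TRUE),
    list(N = 8,  S = 4,  R = 4, C = 50, seed = 227, zero_branch = TRUE),
    list(N = 16, S = 4,  R = 1, C = 50, seed = 229),
    list(N = 5,  S = 4,  R = 2, C = 10, seed = 233),
    list(N = 8,  S = 4,  R = 1, C = 10, seed = 239, ambiguity = TRUE,
         zero_branch = TRUE),
    list(N = 2,  S = 61, R = 4, C = 1,  seed = 241),
    list(N = 4,  S = 61, R = 1, C = 10, seed = 251),
    list(N = 8,  S = 61, R = 4, C = 10, seed = 257, ambiguity = TRUE),
    list(N = 16, S = 61, R = 4, C = 50, seed = 263)
  )
}
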