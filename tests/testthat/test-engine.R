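test_that("post-order pass reproduces tip indicators and the P(0) limit", {
  tr <- parse_newick("((A:0.0,B:0.0):0.1,C:0.2);")
  a <- phylograd:::new_alignment(c("A", "B", "C"), c("AC", "GC", "TT"))
  pa <- compress_patterns(a)
  ins <- engine_build(tr, pa, jc_model())
  ws <- postorder_pass(tr, ins$schedule, ins$tips, ins$matrices,
                       engine_config(scaling = "off"))
  # tips hold 0/1 indicators
  expect_true(all(ins$tips[[1]] %in% c(0, 1)))
  expect_identical(ins$tips[[1]][, 1], c(1, 0, 0, 0))
  # both child branches 0: parent partial = product of child indicators
  cherry <- 4L  # internal node above A, B
  expect_equal(ws$post[[cherry]][[1]],
               ins$tips[[1]] * ins$tips[[2]], tolerance = 1e-15)
})

test_that("likelihood matches exhaustive enumeration on small instances", {
  for (seed in c(3, 9)) {
    ins <- make_instance(4, S = 4, R = 2, C = 8, seed = seed)
    res <- run_engine(ins)
    ll_br <- likelihood_exhaustive(ins$tree, ins$tips, ins$model, ins$rates,
                                   ins$weights)
    expect_equal(res$log_likelihood, ll_br, tolerance = 1e-10)
  }
  # with ambiguity and a zero-length branch
  ins <- make_instance(5, S = 4, R = 2, C = 6, seed = 17,
                       ambiguity = TRUE, zero_branch = TRUE)
  res <- run_engine(ins)
  expect_equal(res$log_likelihood,
               likelihood_exhaustive(ins$tree, ins$tips, ins$model,
                                     ins$rates, ins$weights),
               tolerance = 1e-10)
})

test_that("two-taxon JC69 likelihood and gradient match the closed forms", {
  b <- 0.37
  tr <- parse_newick(sprintf("(A:%.17g,B:0.0);", b))
  a <- phylograd:::new_alignment(c("A", "B"), c("AG", "AC"))  # match+mismatch
  pa <- compress_patterns(a)
  inst <- engine_build(tr, pa, jc_model())
  res <- engine_run(inst, gradient = TRUE)
  e <- exp(-4 * b / 3)
  match_lik <- (1 / 4) * (1 / 4 + (3 / 4) * e)
  mismatch_lik <- (1 / 4) * (1 / 4 - (1 / 4) * e)
  expect_equal(res$log_likelihood, log(match_lik) + log(mismatch_lik),
               tolerance = 1e-12)
  # d/db log f with f = 1/16 + 3/16 e^{-4b/3} (match),
  #                f = 1/16 - 1/16 e^{-4b/3} (mismatch)
  dmatch <- (-(1 / 4) * e) / match_lik
  dmismatch <- ((1 / 12) * e * 4 / 3 * 3 / 4) / mismatch_lik
  closed <- dmatch + dmismatch
  expect_equal(unname(res$gradient$per_branch[1]), closed,
               tolerance = 1e-10)
  # symbolic-oracle cross-checks
  gmd <- gradient_matrix_derivative(tr, inst$tips, jc_model(),
                                    rate_categories(1), pa$weights)
  expect_equal(gmd[1], closed, tolerance = 1e-10)
})

test_that("fully ambiguous data give log-likelihood 0 and zero gradient", {
  tr <- random_tree(5, seed = 2)
  a <- phylograd:::new_alignment(paste0("t", 1:5),
                                 rep(strrep("N", 4), 5))
  pa <- compress_patterns(a)
  inst <- engine_build(tr, pa, default_gtr(), discrete_gamma(0.5, 4))
  res <- engine_run(inst, gradient = TRUE)
  expect_equal(res$log_likelihood, 0, tolerance = 1e-12)
  expect_equal(unname(res$gradient$per_branch),
               rep(0, 8), tolerance = 1e-12)
})

test_that("pre-order pass seeds the root with pi and obeys identity limits", {
  ins <- make_instance(4, R = 2, C = 5, seed = 23)
  res <- run_engine(ins)
  ws <- res$workspace
  root <- ins$tree$n_nodes
  for (r in 1:2)
    expect_equal(ws$pre[[root]][[r]],
                 matrix(ins$model$stationary, 4, ws$C), tolerance = 1e-15)

  # b_i = b_j = 0 with a fully ambiguous sibling: q_i = q_parent
  tr <- parse_newick("((A:0.0,B:0.0):0.1,C:0.2);")
  a <- phylograd:::new_alignment(c("A", "B", "C"), c("A", "N", "C"))
  pa <- compress_patterns(a)
  inst <- engine_build(tr, pa, jc_model())
  r2 <- engine_run(inst, gradient = TRUE)
  ws2 <- r2$workspace
  expect_equal(ws2$pre[[1]][[1]], ws2$pre[[4]][[1]], tolerance = 1e-14)
})

test_that("pre-order partials match brute-force enumeration", {
  ins <- make_instance(5, S = 4, R = 2, C = 3, seed = 29)
  inst <- engine_build(ins$tree, ins$pa, ins$model, ins$rates,
                       cfg = engine_config(scaling = "off"))
  res <- engine_run(inst, gradient = TRUE)
  ws <- res$workspace
  for (r in 1:2) {
    P <- lapply(seq_len(ins$tree$n_nodes - 1L),
                function(i) inst$matrices[[i]]$matrices[[r]])
    for (node in c(1, 3, 6, 8)) {
      q_oracle <- brute_force_preorder(ins$tree, ins$tips, P,
                                       ins$model$stationary, node)
      expect_equal(ws$pre[[node]][[r]], q_oracle, tolerance = 1e-10)
    }
  }
})

test_that("any-node likelihood identity holds with and without rescaling", {
  for (sc in c("always", "off", "auto")) {
    ins <- make_instance(6, R = 4, C = 20, seed = 37, ambiguity = TRUE)
    res <- run_engine(ins, cfg = engine_config(scaling = sc))
    ws <- res$workspace
    lls <- vapply(seq_len(ins$tree$n_nodes), function(i)
      log_likelihood_at_node(ws, i, ins$rates, ins$weights), numeric(1))
    expect_lt(max(abs(lls - res$log_likelihood)), 1e-10)
  }
})

test_that("gradient agrees with both oracles and cancels scalers", {
  ins <- make_instance(8, R = 4, C = 30, seed = 41, zero_branch = TRUE)
  res_on <- run_engine(ins, cfg = engine_config(scaling = "always"))
  res_off <- run_engine(ins, cfg = engine_config(scaling = "off"))
  expect_lt(max(abs(res_on$gradient$per_branch -
                    res_off$gradient$per_branch)), 1e-10)
  gmd <- gradient_matrix_derivative(ins$tree, ins$tips, ins$model,
                                    ins$rates, ins$weights)
  gfd <- gradient_finite_difference(ins$tree, ins$tips, ins$model,
                                    ins$rates, ins$weights)
  expect_lt(max_rel_dev(res_on$gradient$per_branch, gmd), 1e-8)
  expect_lt(max_rel_dev(res_on$gradient$per_branch, gfd), 1e-5)
  # per-pattern table reduces to per-branch
  res_pp <- engine_run(engine_build(ins$tree, ins$pa, ins$model, ins$rates),
                       per_pattern = TRUE)
  expect_equal(reduce_site_contributions(res_pp$gradient$per_pattern,
                                         ins$weights),
               unname(res_pp$gradient$per_branch), tolerance = 1e-10)
})

test_that("generalized per-category generators reproduce the tied default", {
  ins <- make_instance(5, R = 3, C = 12, seed = 47)
  res <- run_engine(ins)
  # Q^(r) = gamma_r * Q supplied explicitly through the generalized path
  qlist <- lapply(ins$rates$rates, function(g) {
    gg <- ins$model
    gg$Q <- g * gg$Q
    gg$eig <- phylograd:::symmetric_eigen(gg$Q, gg$stationary)
    gg
  })
  inst_g <- engine_build(ins$tree, ins$pa, ins$model,
                         rate_categories(ins$rates$rates,
                                         ins$rates$weights),
                         per_category = qlist)
  res_g <- engine_run(inst_g, gradient = TRUE)
  expect_equal(res_g$log_likelihood, res$log_likelihood, tolerance = 1e-10)
  expect_equal(res_g$gradient$per_branch, res$gradient$per_branch,
               tolerance = 1e-10)
})

test_that("site and branch-set reductions are exact linear operations", {
  set.seed(51)
  contrib <- matrix(rnorm(6 * 40), 6, 40)
  w <- sample(1:5, 40, TRUE)
  red <- reduce_site_contributions(contrib, w)
  oracle <- apply(contrib, 1, function(row) kahan_sum(row * w))
  expect_equal(red, oracle, tolerance = 1e-12)
  expect_identical(reduce_site_contributions(contrib[, 1, drop = FALSE],
                                             1L), unname(contrib[, 1]))
  expect_equal(reduce_site_contributions(contrib, 2 * w), 2 * red,
               tolerance = 1e-14)

  g <- phylograd:::new_gradient_result(rnorm(8))
  expect_equal(unname(reduce_branch_set(g, as.list(1:8))),
               unname(g$per_branch))
  expect_equal(unname(reduce_branch_set(g, list(all = 1:8))),
               sum(g$per_branch), tolerance = 1e-12)
  two <- reduce_branch_set(g, list(a = c(1, 4, 5), b = c(2, 3, 6, 7, 8)))
  expect_equal(unname(sum(two)), sum(g$per_branch), tolerance = 1e-12)
  expect_error(reduce_branch_set(g, list(1:3, 3:5)), "invalid-parameter")
})

test_that("reference, batched, and padded batched engines agree to 1e-12", {
  for (args in list(list(N = 6, S = 4, R = 4, C = 20, seed = 61),
                    list(N = 4, S = 61, R = 2, C = 10, seed = 67))) {
    ins <- do.call(make_instance, args)
    res_ref <- run_engine(ins, cfg = engine_config("reference"))
    for (pad in c(FALSE, TRUE)) {
      res_b <- run_engine(ins, cfg = engine_config("batched",
                                                   pad_states = pad))
      expect_lt(abs(res_b$log_likelihood - res_ref$log_likelihood), 1e-12)
      expect_lt(max(abs(res_b$gradient$per_branch -
                        res_ref$gradient$per_branch)), 1e-12)
    }
  }
})

test_that("underflow is detected unscaled and survived with rescaling", {
  tr <- random_tree(700, list(dist = "constant", value = 1.5), seed = 9)
  aln <- simulate_alignment(tr, jc_model(), rate_categories(1), 10,
                            seed = 10)
  pa <- compress_patterns(aln)
  i_off <- engine_build(tr, pa, jc_model(),
                        cfg = engine_config(scaling = "off"))
  err <- tryCatch(engine_run(i_off, gradient = FALSE), error = identity)
  expect_s3_class(err, "numerical_failure")
  expect_match(conditionMessage(err), "pattern")
  i_on <- engine_build(tr, pa, jc_model(),
                       cfg = engine_config(scaling = "always"))
  res <- engine_run(i_on, gradient = TRUE)
  expect_true(is.finite(res$log_likelihood))
  expect_true(all(is.finite(res$gradient$per_branch)))
})

test_that("stale or missing passes raise invalid-state", {
  ins <- make_instance(4, C = 5, seed = 71)
  inst <- engine_build(ins$tree, ins$pa, ins$model, ins$rates)
  ws <- postorder_pass(ins$tree, inst$schedule, inst$tips, inst$matrices)
  err <- tryCatch(log_likelihood_at_node(ws, 1, ins$rates, ins$weights),
                  error = identity)
  expect_s3_class(err, "invalid_state")
  err2 <- tryCatch(branch_gradient(ws, ins$tree, ins$model, ins$rates,
                                   ins$weights), error = identity)
  expect_s3_class(err2, "invalid_state")
})
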