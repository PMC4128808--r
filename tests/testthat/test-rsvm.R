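test_that("problem assembly builds the signed system with a positive penalty", {
  inst <- random_instance(30L, 8L, seed = 4L)
  kern <- kernel_params(0.5)
  prob <- assemble_problem(inst$pool, inst$basis, kern)
  m <- nrow(inst$pool$X)
  mbar <- nrow(inst$basis$X)
  expect_equal(dim(prob$H), c(m, mbar + 1L))
  expect_gt(prob$nu, 0)
  # H = D [K Dbar, -e] entrywise
  K <- rect_kernel(inst$pool$X, inst$basis$X, kern)
  expect_equal(unname(prob$H[, mbar + 1L]), -inst$pool$labels)
  expect_equal(unname(prob$H[3L, 2L]),
               inst$pool$labels[3L] * K[3L, 2L] * inst$basis$labels[2L])
  # dual-side matrix I/nu + H H' is positive definite by construction
  Q <- diag(m) / prob$nu + tcrossprod(prob$H)
  expect_gt(min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values), 0)
  # class weights: native rows carry C_neg = C_pos * n_dec / n_nat
  n_nat <- sum(inst$pool$labels == -1)
  n_dec <- sum(inst$pool$labels == 1)
  expect_equal(unique(prob$w[inst$pool$labels == -1]),
               prob$nu * n_dec / n_nat)
  expect_equal(unique(prob$w[inst$pool$labels == 1]), prob$nu * 1)
  # one-class pools are rejected
  expect_error(
    assemble_problem(
      structure(list(X = inst$pool$X, labels = rep(1, m), ids = inst$pool$ids),
                class = "training_pool"),
      inst$basis, kern
    ),
    "one class"
  )
})

test_that("the assembled objective matches naive matrix arithmetic", {
  inst <- random_instance(30L, 8L, seed = 9L)
  prob <- assemble_problem(inst$pool, inst$basis, kernel_params(0.4))
  withr::with_seed(2L, v <- rnorm(9L))
  naive <- 0.5 * sum(v^2) +
    0.5 * sum(prob$w * pmax(1 - prob$H %*% v, 0)^2)
  expect_equal(rsvm_objective(prob, v), naive)
})

test_that("Newton converges finitely with a monotone objective trace", {
  for (seed in c(1L, 2L, 3L)) {
    inst <- random_instance(50L, 12L, seed = seed)
    prob <- assemble_problem(inst$pool, inst$basis, kernel_params(0.5))
    st <- solve_newton(prob)
    expect_true(st$converged)
    expect_lt(st$iterations, prob$params$max_iter)
    expect_true(all(diff(st$trace) <= 1e-10 * (1 + abs(st$trace[-length(st$trace)]))))
    expect_lte(st$gradient_norm, prob$grad_tol)
  }
})

test_that("Newton restarted at its own solution terminates immediately", {
  inst <- random_instance(40L, 10L, seed = 6L)
  prob <- assemble_problem(inst$pool, inst$basis, kernel_params(0.5))
  st <- solve_newton(prob)
  again <- solve_newton(prob, start = st$v)
  expect_equal(again$iterations, 0L)
  expect_equal(again$v, st$v)
})

test_that("a separable two-point problem is classified with margin", {
  pool <- training_pool(rbind(c(0, 0), c(4, 4)), c(-1, 1), ids = c("n", "d"))
  basis <- basis_set(pool$X, pool$labels, ids = pool$ids)
  model <- train_rsvm(pool, basis, kernel = kernel_params(0.5))
  f <- fitness(model, pool$X)
  expect_lt(f[1L], 0)
  expect_gt(f[2L], 0)
})

test_that("Newton attains the QP-oracle optimum on random instances", {
  skip_if_not_installed("quadprog")
  for (seed in c(11L, 12L, 13L, 14L)) {
    inst <- random_instance(40L, 10L, seed = seed)
    prob <- assemble_problem(inst$pool, inst$basis, kernel_params(0.5))
    st <- solve_newton(prob)
    qp <- qp_oracle(prob)
    expect_lt(abs(st$objective - qp$objective) / abs(qp$objective), 1e-6)
    model_n <- fitness_model(inst$basis, st$u, st$gamma, kernel_params(0.5))
    model_q <- fitness_model(inst$basis, qp$u, qp$gamma, kernel_params(0.5))
    expect_lt(max(abs(fitness(model_n, inst$pool$X) -
                        fitness(model_q, inst$pool$X))), 1e-5)
  }
})

test_that("raising the native-side cost never adds misclassified natives", {
  for (seed in c(3L, 8L)) {
    inst <- random_instance(60L, 12L, seed = seed)
    kern <- kernel_params(0.5)
    mis <- vapply(c(1, 4, 16, 64), function(cneg) {
      model <- train_rsvm(inst$pool, inst$basis, kernel = kern,
                          params = solver_params(C_pos = 1, C_neg = cneg))
      sum(fitness(model, inst$pool$X[inst$pool$labels == -1, , drop = FALSE]) > 0)
    }, 0)
    expect_true(all(diff(mis) <= 0))
  }
})

test_that("fitness evaluation reduces to the basis expansion", {
  inst <- random_instance(20L, 6L, seed = 15L)
  kern <- kernel_params(0.7)
  model <- train_rsvm(inst$pool, inst$basis, kernel = kern)
  # brute-force sum over basis terms
  x <- inst$pool$X[7L, ]
  naive <- sum(vapply(seq_len(nrow(model$basis$X)), function(j) {
    gaussian_kernel(x, model$basis$X[j, ], kern) *
      model$basis$labels[j] * model$u[j]
  }, 0)) - model$gamma
  expect_equal(fitness(model, x), naive)
  # u = 0 -> constant -gamma
  m0 <- fitness_model(model$basis, rep(0, nrow(model$basis$X)), 0.25, kern)
  expect_equal(fitness(m0, inst$pool$X), rep(-0.25, nrow(inst$pool$X)))
  # concentrated-u limit: x on a native basis vector, huge mu kills cross terms
  bnat <- which(model$basis$labels == -1)[1L]
  sharp <- kernel_params(1e6)
  u <- rep(0, nrow(model$basis$X))
  u[bnat] <- 2
  m1 <- fitness_model(model$basis, u, 0.1, sharp)
  expect_equal(fitness(m1, model$basis$X[bnat, ]), -2 - 0.1, tolerance = 1e-8)
  expect_error(fitness(model, c(1, 2, 3)), "mismatch")
})

test_that("classification and design-rank verdicts follow the sign convention", {
  inst <- random_instance(20L, 6L, seed = 18L)
  model <- train_rsvm(inst$pool, inst$basis, kernel = kernel_params(0.5))
  res <- classify(model, inst$pool$X, ids = inst$pool$ids)
  expect_equal(res$label, ifelse(res$fitness < 0, -1, 1))
  expect_error(classify(model, inst$pool$X[0, , drop = FALSE]), "empty")
  # strict best-rank semantics, ties fail
  native <- inst$pool$X[which(inst$pool$labels == -1)[1L], ]
  tie <- design_rank(model, native, rbind(native))
  expect_false(tie$success)
  # verdict agrees with the explicit rank computation
  decoys <- inst$pool$X[inst$pool$labels == 1, , drop = FALSE]
  dr <- design_rank(model, native, decoys)
  expect_equal(dr$success,
               fitness(model, native) < min(fitness(model, decoys)))
  expect_equal(dr$best_decoy_fitness, min(fitness(model, decoys)))
})

test_that("training is deterministic and the container round-trips exactly", {
  inst <- random_instance(30L, 8L, seed = 23L)
  m1 <- train_rsvm(inst$pool, inst$basis, kernel = kernel_params(0.5))
  m2 <- train_rsvm(inst$pool, inst$basis, kernel = kernel_params(0.5))
  expect_identical(m1$u, m2$u)
  expect_identical(m1$gamma, m2$gamma)
  path <- withr::local_tempfile(fileext = ".json")
  save_fitness_model(m1, path)
  back <- load_fitness_model(path)
  expect_identical(back$u, m1$u)
  expect_identical(back$gamma, m1$gamma)
  expect_identical(back$kernel$mu, m1$kernel$mu)
  expect_identical(back$basis$X, m1$basis$X)
  expect_identical(back$basis$labels, m1$basis$labels)
  expect_identical(back$basis$ids, m1$basis$ids)
  # serialized twice -> byte-identical files
  p2 <- withr::local_tempfile(fileext = ".json")
  save_fitness_model(m1, p2)
  expect_identical(readLines(path), readLines(p2))
  # scoring with the reloaded model is value-exact
  expect_identical(fitness(back, inst$pool$X[1L, ]),
                   fitness(m1, inst$pool$X[1L, ]))
})
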