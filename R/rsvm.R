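#' Labeled training pool of contact vectors
#'
#' The data matrix of the reduced SVM: one contact vector per row plus a
#' class label. Natives carry label -1 and decoys +1, so that the fitted
#' fitness behaves as an energy (native sequences lowest).
#'
#' @param X m x d numeric matrix (rows = vectors; d = 210 for contact
#'   vectors).
#' @param labels Length-m vector in {-1 (native), +1 (decoy)}.
#' @param ids Optional record identifiers (default: rownames or V1..Vm).
#' @return Object of class `training_pool`.
#' @export
training_pool <- function(X, labels, ids = NULL) {
  X <- as.matrix(X)
  labels <- as.numeric(labels)
  if (nrow(X) != length(labels)) stop("labels do not match rows")
  if (!all(labels %in% c(-1, 1))) stop("labels must be -1 (native) or +1 (decoy)")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(ids)) ids <- rownames(X) %||% paste0("v", seq_len(nrow(X)))
  rownames(X) <- ids
  structure(list(X = X, labels = labels, ids = as.character(ids)),
            class = "training_pool")
}

#' Basis set parameterizing the fitness function
#'
#' The reduced subset of contact vectors whose kernel terms span the
#' fitness landscape (rows of the rectangular kernel's column block).
#'
#' @inheritParams training_pool
#' @return Object of class `basis_set`.
#' @export
basis_set <- function(X, labels, ids = NULL) {
  out <- training_pool(X, labels, ids)
  if (nrow(out$X) < 2L) stop("basis set needs at least 2 vectors")
  class(out) <- "basis_set"
  out
}

#' @export
print.training_pool <- function(x, ...) {
  cat("<training_pool>", nrow(x$X), "vectors (", sum(x$labels == -1), "native /",
      sum(x$labels == 1), "decoy ), dim", ncol(x$X), "\n")
  invisible(x)
}

#' @export
print.basis_set <- function(x, ...) {
  cat("<basis_set>", nrow(x$X), "vectors (", sum(x$labels == -1), "native /",
      sum(x$labels == 1), "decoy ), dim", ncol(x$X), "\n")
  invisible(x)
}

#' Solver parameters for the reduced-SVM Newton method
#'
#' @param C_pos,C_neg Misclassification cost multipliers for the decoy
#'   (+1) and native (-1) classes. `C_neg = NULL` (default) resolves at
#'   assembly time to `C_pos * n_decoys / n_natives`, so native-side
#'   errors outweigh decoy-side errors in proportion to the class
#'   imbalance.
#' @param nu_factor Safety multiplier (> 1) for the penalty parameter
#'   nu = nu_factor * ||H||_2^2 (2-norm from SVD), which must be large
#'   enough that the regularized problem is strongly convex.
#' @param armijo_delta Sufficient-decrease fraction of the Armijo rule,
#'   in (0, 1/2); default 0.25.
#' @param grad_tol Convergence threshold on the gradient norm;
#'   `NULL` resolves to 1e-8 * m_bar at assembly time.
#' @param max_iter Maximum Newton iterations (default 250).
#' @return Object of class `solver_params`.
#' @export
solver_params <- function(C_pos = 1, C_neg = NULL, nu_factor = 2,
                          armijo_delta = 0.25, grad_tol = NULL, max_iter = 250L) {
  stopifnot(C_pos > 0, is.null(C_neg) || C_neg > 0, nu_factor > 1,
            armijo_delta > 0, armijo_delta < 0.5,
            is.null(grad_tol) || grad_tol > 0, max_iter >= 1L)
  structure(list(C_pos = C_pos, C_neg = C_neg, nu_factor = nu_factor,
                 armijo_delta = armijo_delta, grad_tol = grad_tol,
                 max_iter = as.integer(max_iter)),
            class = "solver_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the reduced-SVM problem matrices
#'
#' Builds the signed rectangular system H = D [K(A, Abar') Dbar, -e]
#' (kernel block with class signs and an appended bias column), the
#' penalty parameter nu = nu_factor * ||H||_2^2 (2-norm computed by SVD),
#' and the per-row cost weights w_i = nu * C_class(i). Everything is kept
#' at size m x (m_bar + 1); no m x m matrix is ever formed.
#'
#' The associated optimization problem, whose optimum defines the fitness
#' function, is the unconstrained piecewise-quadratic equivalent of the
#' reduced-SVM quadratic program with 2-norm slack and bias-squared term:
#'   min over v = (u, gamma) of 0.5 ||v||^2 + 0.5 sum_i w_i (1 - (Hv)_i)_+^2,
#' the slack being y = (e - Hv)_+ at any optimum of the constrained form.
#'
#' @param pool A [training_pool()].
#' @param basis A [basis_set()].
#' @param kernel [kernel_params()].
#' @param params [solver_params()].
#' @return A `rsvm_problem` list with elements `H`, `w`, `nu`, `grad_tol`,
#'   the resolved costs and the input containers.
#' @export
assemble_problem <- function(pool, basis, kernel, params = solver_params()) {
  if (ncol(pool$X) != ncol(basis$X)) stop("pool/basis dimension mismatch")
  if (length(unique(pool$labels)) < 2L) stop("degenerate pool: one class only")
  if (nrow(basis$X) > nrow(pool$X)) {
    warning("basis set larger than training pool (m_bar > m)")
  }
  K <- rect_kernel(pool$X, basis$X, kernel)
  E <- cbind(sweep(K, 2L, basis$labels, "*"), -1)
  H <- E * pool$labels # row-wise class signs
  nu <- params$nu_factor * norm(H, type = "2")^2
  n_nat <- sum(pool$labels == -1)
  n_dec <- sum(pool$labels == 1)
  C_neg <- params$C_neg %||% (params$C_pos * n_dec / n_nat)
  w <- nu * ifelse(pool$labels == -1, C_neg, params$C_pos)
  mbar <- nrow(basis$X)
  structure(
    list(H = H, w = w, nu = nu,
         C_pos = params$C_pos, C_neg = C_neg,
         grad_tol = params$grad_tol %||% (1e-8 * mbar),
         params = params, kernel = kernel, pool = pool, basis = basis),
    class = "rsvm_problem"
  )
}

#' Objective of the assembled reduced-SVM problem
#'
#' 0.5 ||v||^2 + 0.5 sum_i w_i ((1 - (Hv)_i)_+)^2 at coefficient vector
#' v = (u, gamma).
#'
#' @param problem An `rsvm_problem` from [assemble_problem()].
#' @param v Numeric vector of length m_bar + 1.
#' @return Scalar objective value.
#' @export
rsvm_objective <- function(problem, v) {
  a <- pmax(1 - as.numeric(problem$H %*% v), 0)
  0.5 * sum(v^2) + 0.5 * sum(problem$w * a^2)
}

#' Finite Newton solver with Armijo line search
#'
#' Minimizes the piecewise-quadratic reduced-SVM objective by a
#' generalized Newton iteration: at each step the active-set Hessian
#' I + H_S' W_S H_S (S = rows with positive margin residual, the step
#' function of the plus-function pieces) defines the Newton direction
#' through an LU-factorized linear solve, and the step length follows
#' the Armijo rule (backtracking by halving until the decrease is at
#' least `armijo_delta` times the predicted linear decrease). The
#' iteration terminates in finitely many steps for this problem class.
#'
#' @param problem An `rsvm_problem` from [assemble_problem()].
#' @param start Optional start vector (default zero).
#' @return A `newton_state`: list with coefficient iterate `v` (split as
#'   `u`, `gamma`), `objective`, `gradient_norm`, `iterations`,
#'   `converged`, and the per-iteration objective `trace`.
#' @export
solve_newton <- function(problem, start = NULL) {
  H <- problem$H
  w <- problem$w
  p <- ncol(H)
  delta <- problem$params$armijo_delta
  v <- start %||% numeric(p)
  if (length(v) != p) stop("start vector has wrong length")
  trace <- numeric(0)
  converged <- FALSE
  f0 <- rsvm_objective(problem, v)
  iter <- 0L
  while (iter < problem$params$max_iter) {
    iter <- iter + 1L
    r <- 1 - as.numeric(H %*% v)
    a <- pmax(r, 0)
    grad <- v - as.numeric(crossprod(H, w * a))
    gn <- sqrt(sum(grad^2))
    if (!is.finite(gn)) stop("non-finite gradient at iteration ", iter)
    if (gn <= problem$grad_tol) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    S <- which(r > 0) # step function: 1 for positive argument, else 0
    M <- diag(p)
    if (length(S) > 0L) {
      Hs <- H[S, , drop = FALSE] * sqrt(w[S])
      M <- M + crossprod(Hs)
    }
    d <- solve(M, -grad) # LU with partial pivoting (LAPACK)
    gd <- sum(grad * d)
    if (!is.finite(gd) || gd >= 0) stop("ascent direction at iteration ", iter)
    lam <- 1
    repeat {
      f1 <- rsvm_objective(problem, v + lam * d)
      if (is.finite(f1) && f1 <= f0 + delta * lam * gd) break
      lam <- lam / 2
      if (lam < 1e-16) stop("Armijo line search failed at iteration ", iter)
    }
    v <- v + lam * d
    if (!all(is.finite(v))) stop("non-finite iterate at iteration ", iter)
    if (f1 > f0 + 1e-10 * (1 + abs(f0))) {
      stop("objective increased across an accepted step at iteration ", iter)
    }
    f0 <- f1
    trace <- c(trace, f1)
  }
  if (!converged) {
    r <- 1 - as.numeric(H %*% v)
    gn <- sqrt(sum((v - as.numeric(crossprod(H, w * pmax(r, 0))))^2))
    converged <- gn <= problem$grad_tol
    if (!converged) {
      warning("Newton method hit max_iter without convergence (grad norm ",
              format(gn), ")")
    }
  }
  structure(
    list(v = v, u = v[-p], gamma = v[p], objective = f0,
         gradient_norm = gn, iterations = iter, converged = converged,
         trace = trace),
    class = "newton_state"
  )
}

#' @export
print.newton_state <- function(x, ...) {
  cat(sprintf("<newton_state> %d iterations, objective %.6g, |grad| %.3g, %s\n",
              x$iterations, x$objective, x$gradient_norm,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Train a reduced-SVM fitness model
#'
#' Convenience wrapper: assembles the problem, runs the finite Newton
#' solver, and packages the result as a [fitness_model()].
#'
#' @inheritParams assemble_problem
#' @param length_model Optional [fit_length_model()] fit stored with the
#'   model (the normalization its inputs were produced with).
#' @param provenance Optional named list recorded verbatim in the model.
#' @return A `fitness_model`.
#' @export
train_rsvm <- function(pool, basis, kernel = NULL, params = solver_params(),
                       length_model = NULL, provenance = list()) {
  kernel <- kernel %||% median_heuristic_mu(pool$X)
  problem <- assemble_problem(pool, basis, kernel, params)
  state <- solve_newton(problem)
  fitness_model(basis = basis, u = state$u, gamma = state$gamma,
                kernel = kernel, length_model = length_model,
                provenance = c(provenance, list(
                  iterations = state$iterations, converged = state$converged,
                  objective = state$objective, nu = problem$nu,
                  C_pos = problem$C_pos, C_neg = problem$C_neg
                )))
}

#' Fitness model (nonlinear fitness landscape)
#'
#' The fitted fitness function
#'   f(x) = K(x, Abar') Dbar u - gamma,
#' parameterized by the basis set, its class signs, the coefficient
#' vector and the bias. Negative fitness means native-like, positive
#' decoy-like; the native sequence of a structure should attain the
#' lowest fitness among itself and all its decoys.
#'
#' @param basis A [basis_set()].
#' @param u Coefficient vector of length m_bar.
#' @param gamma Scalar bias.
#' @param kernel [kernel_params()].
#' @param length_model Optional `length_model` used to normalize inputs.
#' @param provenance Named list of free-form provenance entries.
#' @return Object of class `fitness_model`.
#' @export
fitness_model <- function(basis, u, gamma, kernel, length_model = NULL,
                          provenance = list()) {
  stopifnot(inherits(basis, "basis_set"), length(u) == nrow(basis$X),
            all(is.finite(u)), is.finite(gamma))
  structure(
    list(basis = basis, u = as.numeric(u), gamma = as.numeric(gamma),
         kernel = kernel, length_model = length_model,
         provenance = provenance),
    class = "fitness_model"
  )
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("<fitness_model>", nrow(x$basis$X), "basis vectors (",
      sum(x$basis$labels == -1), "native /", sum(x$basis$labels == 1),
      "decoy ), mu =", format(x$kernel$mu), "\n")
  invisible(x)
}

#' Evaluate the fitness function
#'
#' @param model A [fitness_model()].
#' @param x A single contact vector, or a matrix with one vector per row
#'   (normalized the same way as the model's training inputs).
#' @return Numeric fitness value(s); negative = native-like.
#' @export
fitness <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (ncol(X) != ncol(model$basis$X)) {
    stop("dimension mismatch: ", ncol(X), " vs basis ", ncol(model$basis$X))
  }
  K <- rect_kernel(X, model$basis$X, model$kernel)
  as.numeric(K %*% (model$basis$labels * model$u)) - model$gamma
}

#' Classify contact vectors by fitness sign
#'
#' @param model A [fitness_model()].
#' @param x Matrix of vectors (rows) or a single vector.
#' @param ids Optional identifiers.
#' @return data.frame with `id`, `fitness` and predicted `label`
#'   (-1 native-like for negative fitness, +1 decoy-like otherwise).
#' @export
classify <- function(model, x, ids = NULL) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
  if (nrow(X) == 0L) stop("empty input")
  f <- fitness(model, X)
  data.frame(
    id = ids %||% rownames(X) %||% paste0("v", seq_len(nrow(X))),
    fitness = f,
    label = ifelse(f < 0, -1, 1)
  )
}

#' Design-rank verdict for one native against its decoys
#'
#' Sequence design succeeds for a native protein iff its fitness is
#' strictly the lowest among itself and all decoys mounted on its
#' structure; ties count as failures.
#'
#' @param model A [fitness_model()].
#' @param native Contact vector of the native (sequence, structure) pair.
#' @param decoys Matrix of decoy vectors (rows), same structure.
#' @return List with `success` (logical), `native_fitness`,
#'   `best_decoy_fitness`.
#' @export
design_rank <- function(model, native, decoys) {
  fn <- fitness(model, native)
  if (!is.matrix(decoys)) decoys <- matrix(as.numeric(decoys), nrow = 1L)
  fd <- fitness(model, decoys)
  list(success = fn < min(fd), native_fitness = fn,
       best_decoy_fitness = min(fd))
}
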