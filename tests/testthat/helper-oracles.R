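# Independent oracles and small fixture builders shared across tests.

# Delaunay edge list from scipy (independent of the package's LP-based
# edge test), filtered to residue contacts by cutoff + separation.
scipy_residue_contacts <- function(coords, res, cutoff, min_sep) {
  tf <- tempfile(fileext = ".csv")
  of <- tempfile(fileext = ".csv")
  pf <- tempfile(fileext = ".py")
  on.exit(unlink(c(tf, of, pf)), add = TRUE)
  utils::write.table(coords, tf, row.names = FALSE, col.names = FALSE, sep = ",")
  writeLines(c(
    "import numpy as np, csv",
    "from scipy.spatial import Delaunay",
    sprintf("P = np.loadtxt(%s, delimiter=%s)", shQuote(tf), shQuote(",")),
    "tri = Delaunay(P)",
    "edges = set()",
    "for s in tri.simplices:",
    "    for a in range(4):",
    "        for b in range(a+1,4):",
    "            i,j = sorted((int(s[a]), int(s[b]))); edges.add((i,j))",
    sprintf("with open(%s, 'w') as f:", shQuote(of)),
    "    w = csv.writer(f)",
    "    for e in sorted(edges): w.writerow(e)"
  ), pf)
  msg <- system2("python", pf, stdout = TRUE, stderr = TRUE)
  if (!file.exists(of)) stop("scipy oracle failed: ", paste(msg, collapse = "\n"))
  e <- utils::read.csv(of, header = FALSE) + 1L
  d <- sqrt(rowSums((coords[e[, 1L], ] - coords[e[, 2L], ])^2))
  keep <- d <= cutoff & abs(res[e[, 1L]] - res[e[, 2L]]) >= min_sep
  e <- e[keep, , drop = FALSE]
  rp <- unique(data.frame(
    i = pmin(res[e[, 1L]], res[e[, 2L]]),
    j = pmax(res[e[, 1L]], res[e[, 2L]])
  ))
  rp <- rp[order(rp$i, rp$j), , drop = FALSE]
  rownames(rp) <- NULL
  rp
}

# Generic QP solve of the reduced-SVM program in its constrained form
# (variables (v, y); 0.5||v||^2 + 0.5 y'Wy s.t. Hv + y >= e), by quadprog.
qp_oracle <- function(problem) {
  H <- problem$H
  w <- problem$w
  m <- nrow(H)
  p <- ncol(H)
  Dmat <- diag(c(rep(1, p), w))
  Amat <- t(cbind(H, diag(m))) # constraints t(Amat) z >= bvec
  sol <- quadprog::solve.QP(Dmat, rep(0, p + m), Amat, rep(1, m))
  list(objective = sol$value, v = sol$solution[seq_len(p)],
       u = sol$solution[seq_len(p - 1L)], gamma = sol$solution[p])
}

# Random small labeled instance in low dimension (both classes present).
random_instance <- function(m, mbar, dim = 6L, seed = 1L) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(m * dim), m, dim)
    lab <- sample(c(-1, 1), m, replace = TRUE, prob = c(0.3, 0.7))
    lab[1:2] <- c(-1, 1)
    bidx <- sample(m, mbar)
    while (length(unique(lab[bidx])) < 2L) bidx <- sample(m, mbar)
    list(pool = training_pool(X, lab),
         basis = basis_set(X[bidx, , drop = FALSE], lab[bidx]))
  })
}

# Naive per-type recount of a contact vector (independent of tabulate()).
brute_recount <- function(map, sequence) {
  counts <- stats::setNames(numeric(210L), contact_type_names())
  for (k in seq_len(nrow(map))) {
    a <- sort(c(sequence[map$i[k]], sequence[map$j[k]]))
    counts[paste0(a[1L], "-", a[2L])] <- counts[paste0(a[1L], "-", a[2L])] + 1
  }
  unname(counts)
}

# A tiny synthetic cohort for fast end-to-end tests.
tiny_cohort <- function(seed = 5L, n_natives = 16L, decoys_per_native = 12L,
                        native_signal = 0.6) {
  make_vector_cohort(synth_config(
    n_natives = n_natives, decoys_per_native = decoys_per_native,
    native_signal = native_signal, seed = seed
  ))
}

design_success_rate <- function(model, part) {
  mean(vapply(seq_along(part$natives$ids), function(k) {
    rows <- part$universe$native_id == part$natives$ids[k]
    design_rank(model, part$natives$X[k, ],
                part$universe$X[rows, , drop = FALSE])$success
  }, TRUE))
}
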