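#' Residue contact map from Delaunay-filtered heavy-atom contacts
#'
#' Two residues are in contact when some heavy-atom pair, one atom from
#' each residue, (a) is an edge of the Delaunay triangulation of all
#' heavy atoms of the chain and (b) lies within `cutoff` Angstrom, and
#' (c) the residues are at least `min_separation` apart in sequence.
#' The Delaunay filter keeps only nearest-neighbour atoms in physical
#' contact and discards pairs that are close in distance but separated
#' by intervening atoms; it approximates the edge set of the alpha
#' complex of the structure.
#'
#' The Delaunay edge test is exact (up to a small numerical tolerance):
#' an atom pair is a Delaunay edge iff it admits an empty circumsphere,
#' which is decided by a two-dimensional linear-program feasibility test
#' on the perpendicular bisector plane of the pair.
#'
#' @param chain A [protein_chain].
#' @param cutoff Distance cutoff in Angstrom between heavy atoms
#'   (default 4.5). `cutoff = 0` yields an empty map.
#' @param min_separation Minimum sequence separation |i - j| between
#'   contacting residues (default 2, excluding i and i+-1).
#' @return A `contact_map`: data.frame with columns `i`, `j` (1-based
#'   residue indices, `i < j`), with attributes `n` (chain length),
#'   `cutoff` and `min_separation`.
#' @export
build_contact_map <- function(chain, cutoff = 4.5, min_separation = 2L) {
  stopifnot(inherits(chain, "protein_chain"))
  if (cutoff < 0) stop("cutoff must be >= 0")
  coords <- chain_coords(chain)
  if (nrow(coords) < 5L) {
    stop("degenerate triangulation: chain has fewer than 5 atoms")
  }
  edges <- residue_contacts(coords, chain$atoms$res, cutoff, min_separation)
  contact_map(edges, n = length(chain$res_type), cutoff = cutoff,
              min_separation = min_separation)
}

contact_map <- function(edges, n, cutoff = NA_real_, min_separation = NA_integer_) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0L) {
    ii <- pmin(edges$i, edges$j)
    jj <- pmax(edges$i, edges$j)
    edges <- unique(data.frame(i = as.integer(ii), j = as.integer(jj)))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
    if (any(edges$i == edges$j)) stop("self-contact in map")
    if (any(edges$j > n) || any(edges$i < 1L)) stop("residue index out of range")
  } else {
    edges <- data.frame(i = integer(), j = integer())
  }
  structure(edges, n = n, cutoff = cutoff, min_separation = min_separation,
            class = c("contact_map", "data.frame"))
}

#' @export
as.data.frame.contact_map <- function(x, ...) {
  data.frame(i = x$i, j = x$j)
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map>", nrow(x), "contacts over", attr(x, "n"), "residues\n")
  invisible(x)
}

# Shared engine: residue-pair contacts from an atom set.
# coords: m x 3 matrix; res: residue index per atom (arbitrary integers;
# |res_i - res_j| >= min_separation is required for a contact).
residue_contacts <- function(coords, res, cutoff, min_separation) {
  m <- nrow(coords)
  if (cutoff <= 0) {
    return(data.frame(i = integer(), j = integer()))
  }
  cand <- candidate_pairs(coords, res, cutoff, min_separation)
  if (nrow(cand) == 0L) {
    return(data.frame(i = integer(), j = integer()))
  }
  key <- paste(cand$ri, cand$rj)
  out_i <- integer()
  out_j <- integer()
  for (k in unique(key)) {
    grp <- cand[key == k, , drop = FALSE]
    grp <- grp[order(grp$d2), , drop = FALSE]
    for (t in seq_len(nrow(grp))) {
      if (is_delaunay_edge(coords, grp$a[t], grp$b[t])) {
        out_i <- c(out_i, grp$ri[1L])
        out_j <- c(out_j, grp$rj[1L])
        break
      }
    }
  }
  data.frame(i = out_i, j = out_j)
}

# Atom pairs within cutoff whose residues are >= min_separation apart,
# computed in column blocks to bound memory.
candidate_pairs <- function(coords, res, cutoff, min_separation) {
  m <- nrow(coords)
  c2 <- cutoff^2
  sq <- rowSums(coords^2)
  block <- max(1L, min(m, as.integer(2e6 / m)))
  acc <- vector("list", ceiling(m / block))
  bi <- 0L
  for (start in seq(1L, m, by = block)) {
    cols <- start:min(m, start + block - 1L)
    d2 <- outer(sq, sq[cols], "+") - 2 * coords %*% t(coords[cols, , drop = FALSE])
    hit <- which(d2 <= c2, arr.ind = TRUE)
    a <- hit[, 1L]
    b <- cols[hit[, 2L]]
    keep <- a < b & abs(res[a] - res[b]) >= min_separation
    bi <- bi + 1L
    acc[[bi]] <- data.frame(
      a = a[keep], b = b[keep],
      ri = pmin(res[a[keep]], res[b[keep]]),
      rj = pmax(res[a[keep]], res[b[keep]]),
      d2 = d2[hit][keep]
    )
  }
  do.call(rbind, acc[seq_len(bi)])
}

#' Delaunay edge test by the empty-circumsphere criterion
#'
#' An atom pair (i, j) is an edge of the Delaunay triangulation iff some
#' sphere through both atoms contains no other atom. Sphere centres
#' equidistant from i and j form the bisector plane; emptiness against
#' every other atom is one linear inequality per atom in the plane
#' coordinates, so the test reduces to a 2D feasibility LP solved by a
#' Seidel-style incremental method. A Gabriel prefilter (smallest sphere
#' through the pair empty) answers most contact-range pairs without the LP.
#'
#' @param coords m x 3 coordinate matrix.
#' @param i,j Atom indices.
#' @param tol Geometric tolerance in Angstrom (boundary-inclusive).
#' @return Logical.
#' @keywords internal
is_delaunay_edge <- function(coords, i, j, tol = 1e-7) {
  p <- coords[i, ]
  q <- coords[j, ]
  others <- coords[-c(i, j), , drop = FALSE]
  if (nrow(others) == 0L) {
    return(TRUE)
  }
  mid <- (p + q) / 2
  r2 <- sum((q - p)^2) / 4
  # Gabriel prefilter: diameter sphere empty => Delaunay edge
  dm <- sweep(others, 2L, mid)
  if (min(rowSums(dm^2)) >= r2 - tol) {
    return(TRUE)
  }
  d <- q - p
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) {
    return(FALSE) # coincident atoms: no valid edge
  }
  # orthonormal basis (u, v) of the bisector plane
  ref <- if (abs(d[1L]) < 0.9 * nd) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - d * sum(ref * d) / nd^2
  u <- u / sqrt(sum(u^2))
  v <- c(
    d[2L] * u[3L] - d[3L] * u[2L],
    d[3L] * u[1L] - d[1L] * u[3L],
    d[1L] * u[2L] - d[2L] * u[1L]
  ) / nd
  # constraint per other atom r:  alpha s + beta t <= gamma
  nr <- sweep(others, 2L, p)
  alpha <- 2 * as.numeric(nr %*% u)
  beta <- 2 * as.numeric(nr %*% v)
  gamma <- rowSums(others^2) - sum(p^2) - 2 * as.numeric(nr %*% mid)
  seidel2_feasible(cbind(alpha, beta), gamma, bound = 1e6, tol = tol)
}

# Feasibility of {x in R^2 : A x <= b} intersected with [-bound, bound]^2,
# by Seidel's incremental LP with a deterministic constraint shuffle.
seidel2_feasible <- function(A, b, bound = 1e6, tol = 1e-7) {
  nrm <- sqrt(rowSums(A^2))
  zero <- nrm < 1e-12
  if (any(zero & b < -tol)) {
    return(FALSE)
  }
  A <- A[!zero, , drop = FALSE]
  b <- b[!zero]
  if (nrow(A) > 0L) {
    A <- A / nrm[!zero]
    b <- b / nrm[!zero]
  }
  k <- nrow(A)
  ord <- order(sin(seq_len(k) * 12.9898 + 78.233)) # deterministic scramble
  Ap <- rbind(
    c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
    A[ord, , drop = FALSE]
  )
  bp <- c(bound, bound, bound, bound, b[ord])
  cx <- c(1, 1e-9) # lexicographic-ish objective for a unique optimum
  x <- c(-bound, -bound)
  for (t in seq(5L, length.out = k)) {
    ai <- Ap[t, ]
    if (sum(ai * x) <= bp[t] + tol) next
    # re-optimize on the boundary line of constraint t
    x0 <- ai * bp[t]
    dir <- c(-ai[2L], ai[1L])
    Aj <- Ap[seq_len(t - 1L), , drop = FALSE]
    coef <- as.numeric(Aj %*% dir)
    rhs <- as.numeric(bp[seq_len(t - 1L)] - Aj %*% x0)
    par <- abs(coef) < 1e-12
    if (any(par & rhs < -tol)) {
      return(FALSE)
    }
    lo <- -Inf
    hi <- Inf
    pos <- which(coef > 1e-12)
    neg <- which(coef < -1e-12)
    if (length(pos)) hi <- min(rhs[pos] / coef[pos])
    if (length(neg)) lo <- max(rhs[neg] / coef[neg])
    if (lo > hi + tol) {
      return(FALSE)
    }
    tau <- if (sum(cx * dir) > 0) lo else hi
    x <- x0 + tau * dir
  }
  TRUE
}

#' Contact-count vector for a (structure, sequence) pair
#'
#' Counts, per unordered residue-type pair, the contacts of `map` under
#' the residue types of `sequence`. `sequence` may differ from the
#' chain's native sequence: this is how threading and swap decoy vectors
#' are produced (native contact map, alternative sequence).
#'
#' @param chain A [protein_chain] (provides the length and default
#'   sequence).
#' @param map A `contact_map` built on `chain`.
#' @param sequence Residue-type vector of the same length as the chain
#'   (default: the chain's native sequence).
#' @param id Optional record identifier.
#' @return A `contact_vector`: numeric length-210 vector in the canonical
#'   pair order of [contact_type_names()], with attributes `length`,
#'   `normalized = FALSE` and `id`.
#' @export
contact_vector <- function(chain, map, sequence = chain$res_type, id = NULL) {
  n <- length(chain$res_type)
  if (length(sequence) != n) {
    stop("sequence length (", length(sequence), ") != chain length (", n, ")")
  }
  new_contact_vector(count_contact_types(map, sequence), length = n,
                     id = if (is.null(id)) chain$chain_id else id)
}

count_contact_types <- function(map, sequence) {
  counts <- numeric(210L)
  if (nrow(map) > 0L) {
    idx <- contact_type_index(sequence[map$i], sequence[map$j])
    tab <- tabulate(idx, nbins = 210L)
    counts <- as.numeric(tab)
  }
  counts
}

new_contact_vector <- function(counts, length, normalized = FALSE, id = NULL) {
  stopifnot(base::length(counts) == 210L, all(is.finite(counts)), all(counts >= 0))
  structure(as.numeric(counts), length = as.integer(length),
            normalized = isTRUE(normalized), id = id, class = "contact_vector")
}

#' @export
print.contact_vector <- function(x, ...) {
  cat("<contact_vector>", if (isTRUE(attr(x, "normalized"))) "normalized," else "raw,",
      "length", attr(x, "length"), ", total", format(sum(x)), "\n")
  invisible(x)
}

#' Linear model of total contact count versus chain length
#'
#' Native proteins show a near-linear growth of total contact count with
#' residue count. The ordinary least-squares fit Nc = a + b n of total
#' contacts on length, refit on the training natives of each run, drives
#' the length normalization of [normalize_length()].
#'
#' @param natives Either a list of raw `contact_vector`s or a data.frame
#'   with columns `length` and `total`.
#' @return A `length_model` with fields `a` (intercept, contacts) and `b`
#'   (slope, contacts per residue).
#' @export
fit_length_model <- function(natives) {
  if (is.data.frame(natives)) {
    df <- natives[c("length", "total")]
  } else {
    df <- data.frame(
      length = vapply(natives, function(v) as.numeric(attr(v, "length")), 0),
      total = vapply(natives, function(v) sum(v), 0)
    )
  }
  if (nrow(df) < 2L) stop("need at least 2 native points")
  if (length(unique(df$length)) < 2L) {
    stop("singular fit: all chain lengths identical")
  }
  fit <- stats::lm(total ~ length, data = df)
  co <- stats::coef(fit)
  # an exactly collinear fit has zero residual variance; its se is simply 0
  se <- suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))))
  structure(
    list(a = unname(co[1L]), b = unname(co[2L]),
         se = se, n = nrow(df)),
    class = "length_model"
  )
}

#' @export
print.length_model <- function(x, ...) {
  cat(sprintf("<length_model> Nc = %.4f + %.4f n  (fit on %d natives)\n",
              x$a, x$b, x$n))
  invisible(x)
}

#' Predicted total contact count at a given chain length
#' @param model A `length_model`.
#' @param n Residue count(s).
#' @return Numeric predicted totals a + b n.
#' @export
predict_contacts <- function(model, n) {
  model$a + model$b * as.numeric(n)
}

#' Length-normalize a contact vector
#'
#' Removes the linear dependence of contact counts on chain length. The
#' default divides every entry by the predicted total contact count
#' a + b n at the vector's length, so the entries become fractions of the
#' expected contact total; `method = "reference-length"` instead rescales
#' counts to a common reference length by the factor
#' (a + b ref) / (a + b n).
#'
#' @param v Raw `contact_vector`.
#' @param model A fitted `length_model`.
#' @param method `"predicted-total"` (default) or `"reference-length"`.
#' @param ref_length Reference length for the alternative method.
#' @return Normalized `contact_vector` (attribute `normalized = TRUE`;
#'   attribute `scale` records the multiplier applied).
#' @export
normalize_length <- function(v, model, method = c("predicted-total", "reference-length"),
                             ref_length = 100L) {
  method <- match.arg(method)
  if (isTRUE(attr(v, "normalized"))) stop("contact vector is already normalized")
  n <- attr(v, "length")
  pred <- predict_contacts(model, n)
  if (!is.finite(pred) || pred <= 0) {
    stop("predicted contact count non-positive at length ", n)
  }
  s <- switch(method,
    "predicted-total" = 1 / pred,
    "reference-length" = predict_contacts(model, ref_length) / pred
  )
  out <- new_contact_vector(as.numeric(v) * s, length = n, normalized = TRUE,
                            id = attr(v, "id"))
  attr(out, "scale") <- s
  out
}

#' Undo [normalize_length()]
#' @param v Normalized `contact_vector` carrying a `scale` attribute.
#' @return Raw-scale `contact_vector`.
#' @export
denormalize_length <- function(v) {
  if (!isTRUE(attr(v, "normalized"))) stop("vector is not normalized")
  s <- attr(v, "scale")
  if (is.null(s)) stop("no scale attribute recorded")
  new_contact_vector(as.numeric(v) / s, length = attr(v, "length"),
                     normalized = FALSE, id = attr(v, "id"))
}
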