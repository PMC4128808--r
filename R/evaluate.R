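#' Confusion counts for native/decoy discrimination
#'
#' Positives are the native proteins (the minority class the evaluation
#' up-weights), regardless of the -1/+1 training labels: TP = natives
#' recognized as native, FN = misclassified natives, FP = decoys
#' classified as native, TN = decoys classified as decoy.
#'
#' @param TP,FP,FN,TN Non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN, TN = 0L) {
  x <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(x < 0)) stop("counts must be non-negative")
  structure(as.list(x), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' F-beta score
#'
#' F_beta = (1 + beta^2) P R / (beta^2 P + R) with precision
#' P = TP / (TP + FP) and recall R = TP / (TP + FN). beta > 1 weights
#' recall (native recovery) over precision; the package default beta = 10
#' suits the strongly imbalanced native-versus-decoy setting where the
#' small native class carries the weight. Zero denominators yield 0 with
#' a warning.
#'
#' @param counts A [confusion_counts()].
#' @param beta Positive weight (default 10).
#' @return F-beta score in [0, 1].
#' @export
fbeta <- function(counts, beta = 10) {
  if (beta <= 0) stop("beta must be positive")
  tp <- counts$TP
  if ((tp + counts$FP) == 0 || (tp + counts$FN) == 0 || tp == 0) {
    warning("zero denominator in F-beta; returning 0")
    return(0)
  }
  P <- tp / (tp + counts$FP)
  R <- tp / (tp + counts$FN)
  (1 + beta^2) * P * R / (beta^2 * P + R)
}

#' Evaluate a fitness model over natives and a decoy stream
#'
#' Scores every native and every decoy, counting misclassified natives
#' (fitness > 0) and misclassified decoys (fitness < 0). Decoys may be
#' given as an in-memory matrix, as a generator function (called
#' repeatedly, returning a matrix chunk or `NULL` when exhausted), or as
#' a path to a contact-vector TSV which is streamed in chunks, so the
#' decoy set may be larger than memory.
#'
#' @param model A [fitness_model()].
#' @param natives Matrix of native vectors (rows), rownames as ids.
#' @param decoys Matrix, generator function, or TSV path.
#' @param chunk Rows per streamed chunk (default 4096).
#' @return List with `counts` ([confusion_counts()], positives =
#'   natives), `native_table` (id, fitness, misclassified; sorted by
#'   fitness ascending), and `misclassified_natives` (the positive-
#'   fitness subset, the failure report layout).
#' @export
evaluate_universe <- function(model, natives, decoys, chunk = 4096L) {
  natives <- as.matrix(natives)
  if (nrow(natives) == 0L) stop("empty native set")
  fn <- score_universe(model, natives)
  mis_dec <- 0L
  n_dec <- 0L
  consume <- function(X) {
    X <- as.matrix(X)
    f <- score_universe(model, X, chunk = chunk)
    mis_dec <<- mis_dec + sum(f < 0)
    n_dec <<- n_dec + length(f)
  }
  if (is.function(decoys)) {
    repeat {
      X <- decoys()
      if (is.null(X) || NROW(X) == 0L) break
      consume(X)
    }
  } else if (is.character(decoys)) {
    stream_vectors_tsv(decoys, chunk = chunk, callback = function(tab) {
      consume(tab$X)
    })
  } else {
    consume(decoys)
  }
  nat_tab <- data.frame(
    id = rownames(natives) %||% paste0("n", seq_len(nrow(natives))),
    fitness = fn,
    misclassified = fn > 0
  )
  nat_tab <- nat_tab[order(nat_tab$fitness, nat_tab$id), , drop = FALSE]
  rownames(nat_tab) <- NULL
  counts <- confusion_counts(
    TP = sum(fn <= 0), FN = sum(fn > 0),
    FP = mis_dec, TN = n_dec - mis_dec
  )
  list(counts = counts, native_table = nat_tab,
       misclassified_natives = nat_tab[nat_tab$misclassified, , drop = FALSE])
}

#' Misclassification curves over swap decoys
#'
#' Tabulates the fraction of misclassified swap decoys (fitness < 0) per
#' (protein-length bin, number of swaps) and per sequence-identity bin,
#' mirroring the usual diagnostics for composition-preserving decoy sets.
#' Zero-swap controls (identical to the native sequence) are excluded by
#' default since labeling them decoys is a deliberate mislabeling.
#'
#' @param model A [fitness_model()].
#' @param swaps data.frame as returned by (rows bound over)
#'   [swap_decoys()], with list-column `vector` plus `n_swaps` and
#'   `identity`; native length is read from each vector.
#' @param length_bin Length bin width in residues (default 50).
#' @param identity_bin Identity bin width (default 0.1).
#' @param include_controls Include `n_swaps == 0` rows (default FALSE).
#' @return List of two data.frames: `by_swaps` (length_bin, n_swaps, n,
#'   misclassified, rate) and `by_identity` (length_bin, identity_bin, n,
#'   misclassified, rate). Empty bins are absent, not zero.
#' @export
swap_curves <- function(model, swaps, length_bin = 50, identity_bin = 0.1,
                        include_controls = FALSE) {
  if (!include_controls) swaps <- swaps[swaps$n_swaps > 0L, , drop = FALSE]
  if (nrow(swaps) == 0L) stop("no swap decoys to evaluate")
  X <- do.call(rbind, lapply(swaps$vector, as.numeric))
  len <- vapply(swaps$vector, function(v) as.numeric(attr(v, "length")), 0)
  f <- score_universe(model, X)
  mis <- f < 0
  lb <- floor(len / length_bin) * length_bin
  lab <- sprintf("[%d,%d)", as.integer(lb), as.integer(lb + length_bin))
  by_swaps <- stats::aggregate(
    cbind(n = rep(1L, length(mis)), misclassified = as.integer(mis)),
    by = list(length_bin = lab, n_swaps = swaps$n_swaps), FUN = sum
  )
  by_swaps$rate <- by_swaps$misclassified / by_swaps$n
  ib <- pmin(floor(swaps$identity / identity_bin) * identity_bin,
             1 - identity_bin)
  ilab <- sprintf("[%.1f,%.1f)", ib, ib + identity_bin)
  by_identity <- stats::aggregate(
    cbind(n = rep(1L, length(mis)), misclassified = as.integer(mis)),
    by = list(length_bin = lab, identity_bin = ilab), FUN = sum
  )
  by_identity$rate <- by_identity$misclassified / by_identity$n
  list(by_swaps = by_swaps, by_identity = by_identity)
}
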