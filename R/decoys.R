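#' Sequence decoys by gapless threading
#'
#' Threads the sequence of a (longer) guest protein through the structure
#' of the host: every contiguous window of the guest sequence of the
#' host's length is mounted on the host's native contact map, giving
#' exactly L - l + 1 decoys for guest length L and host length l. All
#' native contacts are retained, so these sequence decoys are
#' deliberately challenging. Windows whose sequence coincides with the
#' host's native sequence are flagged (`is_native = TRUE`), not dropped.
#'
#' @param host A [protein_chain] (the structure donor).
#' @param map The host's `contact_map` from [build_contact_map()].
#' @param guest_sequence Residue-type vector with length >= host length.
#' @param normalizer Optional [fit_length_model()] fit; when supplied,
#'   each decoy vector is length-normalized at the host length.
#' @param guest_id Identifier of the guest protein for provenance.
#' @return data.frame with columns `host_id`, `guest_id`, `window_start`
#'   (1-based offset into the guest sequence), `is_native`, plus the
#'   decoy `contact_vector`s in list-column `vector`.
#' @export
thread_decoys <- function(host, map, guest_sequence, normalizer = NULL,
                          guest_id = "guest") {
  l <- length(host$res_type)
  L <- length(guest_sequence)
  if (L < l) stop("guest sequence (", L, ") shorter than host (", l, ")")
  guest_sequence <- toupper(as.character(guest_sequence))
  starts <- seq_len(L - l + 1L)
  vecs <- vector("list", length(starts))
  is_native <- logical(length(starts))
  for (k in seq_along(starts)) {
    win <- guest_sequence[starts[k]:(starts[k] + l - 1L)]
    v <- contact_vector(host, map, sequence = win,
                        id = paste0(host$chain_id, "|", guest_id, "@", starts[k]))
    if (!is.null(normalizer)) v <- normalize_length(v, normalizer)
    vecs[[k]] <- v
    is_native[k] <- identical(win, host$res_type)
  }
  out <- data.frame(
    host_id = host$chain_id, guest_id = guest_id,
    window_start = starts, is_native = is_native
  )
  out$vector <- vecs
  out
}

#' Composition-preserving random swap decoys
#'
#' Permutes the native sequence by `n_swaps` independent uniformly random
#' transpositions of two distinct positions and mounts the permuted
#' sequence on the native contact map (Decoy Set 2 style). The amino-acid
#' composition is conserved exactly; a swap of two positions holding the
#' same residue type still counts as a swap. `n_swaps = 0` is allowed as
#' a control and reproduces the native sequence.
#'
#' @param native A [protein_chain].
#' @param map The native `contact_map`.
#' @param n_swaps Number of transpositions per replicate (>= 0).
#' @param n_replicates Number of independent decoys to generate (> 0).
#' @param seed Integer seed; the generator is reproducible under it.
#' @param normalizer Optional [fit_length_model()] fit for normalization.
#' @return data.frame with columns `source_id`, `n_swaps`, `replicate`,
#'   `identity` (sequence identity to the native, in [0, 1]), `seed`,
#'   list-columns `sequence` and `vector`.
#' @export
swap_decoys <- function(native, map, n_swaps, n_replicates, seed,
                        normalizer = NULL) {
  if (n_swaps < 0L) stop("n_swaps must be >= 0")
  if (n_replicates <= 0L) stop("n_replicates must be positive")
  l <- length(native$res_type)
  if (l < 2L) stop("chain too short to swap")
  withr::with_seed(as.integer(seed), {
    seqs <- vector("list", n_replicates)
    vecs <- vector("list", n_replicates)
    ident <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      s <- native$res_type
      for (k in seq_len(n_swaps)) {
        ij <- sample.int(l, 2L) # distinct positions, types may coincide
        s[ij] <- s[rev(ij)]
      }
      ident[r] <- sequence_identity(s, native$res_type)
      v <- contact_vector(native, map, sequence = s,
                          id = paste0(native$chain_id, "|swap", n_swaps, ".", r))
      if (!is.null(normalizer)) v <- normalize_length(v, normalizer)
      seqs[[r]] <- s
      vecs[[r]] <- v
    }
    out <- data.frame(
      source_id = native$chain_id, n_swaps = as.integer(n_swaps),
      replicate = seq_len(n_replicates), identity = ident,
      seed = as.integer(seed)
    )
    out$sequence <- seqs
    out$vector <- vecs
    out
  })
}

#' Fraction of positions with identical residue type
#' @param a,b Residue-type vectors of equal length.
#' @return Identity fraction in [0, 1].
#' @export
sequence_identity <- function(a, b) {
  if (length(a) != length(b)) {
    stop("sequence length mismatch: ", length(a), " vs ", length(b))
  }
  mean(toupper(as.character(a)) == toupper(as.character(b)))
}
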