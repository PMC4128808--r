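#' Synthetic cohort configuration
#'
#' Parameters of the synthetic contact-vector generator used for
#' end-to-end testing without structure downloads. Defaults emulate the
#' statistical structure of a curated monomeric protein set: chain
#' lengths uniform on 46..500 residues, total contact counts on the line
#' Nc = a0 + b0 n with Gaussian noise, decoy composition drifted away
#' from the native composition by `native_signal` while the total
#' contact count is conserved (as threading and swap decoys conserve
#' it).
#'
#' @param n_natives Number of native proteins in the cohort (train +
#'   test; default 100).
#' @param length_range Chain length bounds (default c(46, 500)).
#' @param contacts_intercept,contacts_slope Ground-truth line of total
#'   contacts versus length (default 10 + 3 n).
#' @param contacts_noise_sd Gaussian noise of the total contact count
#'   (default 10).
#' @param native_signal Separation scale in [0, 1]: mixture weight
#'   pulling each decoy's composition from its native profile toward a
#'   background profile. 0 makes natives and decoys exchangeable
#'   (default 0.5).
#' @param decoys_per_native Decoys per native (default 50).
#' @param train_fraction Fraction of natives in the training split
#'   (default 0.65; no native is shared between splits).
#' @param tilt_sd Log-normal spread of per-protein composition tilts
#'   around the cohort profile (default 0.15).
#' @param seed Integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_natives = 100L, length_range = c(46L, 500L),
                         contacts_intercept = 10, contacts_slope = 3,
                         contacts_noise_sd = 10, native_signal = 0.5,
                         decoys_per_native = 50L, train_fraction = 0.65,
                         tilt_sd = 0.15, seed = 1L) {
  stopifnot(n_natives >= 4L, length_range[1L] >= 5L,
            length_range[2L] >= length_range[1L],
            contacts_slope > 0, native_signal >= 0, native_signal <= 1,
            decoys_per_native >= 1L, train_fraction > 0, train_fraction < 1)
  structure(
    list(n_natives = as.integer(n_natives),
         length_range = as.integer(length_range),
         contacts_intercept = contacts_intercept,
         contacts_slope = contacts_slope,
         contacts_noise_sd = contacts_noise_sd,
         native_signal = native_signal,
         decoys_per_native = as.integer(decoys_per_native),
         train_fraction = train_fraction,
         tilt_sd = tilt_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Compact self-avoiding toy chain
#'
#' Generates a compact 3D pseudo-protein: alpha-carbon positions follow a
#' self-avoiding random walk with 3.8 Angstrom virtual bonds, biased
#' toward the centroid so the chain stays inside a globule of radius
#' ~3.3 n^(1/3); each residue also gets one jittered side-chain
#' pseudo-atom. Non-adjacent alpha carbons keep at least 4.0 Angstrom
#' separation (the collision radius). The sequence is uniform over the
#' 20 residue types. Deterministic under `seed`.
#'
#' @param length Number of residues (>= 5).
#' @param seed Integer seed.
#' @param chain_id Chain identifier (default "A").
#' @return A [protein_chain] with 2 heavy atoms per residue.
#' @export
make_toy_chain <- function(length, seed, chain_id = "A") {
  if (length < 5L) stop("toy chain needs length >= 5")
  bond <- 3.8
  collide <- 4.0
  radius <- 3.3 * length^(1 / 3) + 2
  withr::with_seed(as.integer(seed), {
    ca <- matrix(NA_real_, length, 3L)
    ca[1L, ] <- c(0, 0, 0)
    for (i in 2:length) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        dir <- stats::rnorm(3L)
        # bias toward the origin keeps the walk compact
        bias <- -ca[i - 1L, ] / max(radius, 1)
        dir <- dir / sqrt(sum(dir^2)) + bias
        dir <- dir / sqrt(sum(dir^2))
        cand <- ca[i - 1L, ] + bond * dir
        if (sqrt(sum(cand^2)) > radius) next
        if (i > 2L) {
          d2 <- rowSums(sweep(ca[seq_len(i - 2L), , drop = FALSE], 2L, cand)^2)
          if (min(d2) < collide^2) next
        }
        ca[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { # restart-free fallback: relax the globule
        radius <- radius * 1.15
        i_dir <- stats::rnorm(3L)
        i_dir <- i_dir / sqrt(sum(i_dir^2))
        ca[i, ] <- ca[i - 1L, ] + bond * i_dir
      }
    }
    side <- ca + matrix(stats::rnorm(3L * length, sd = 0.9), ncol = 3L) + 1.5 / sqrt(3)
    res_type <- sample(AA3, length, replace = TRUE)
    atoms <- data.frame(
      res = rep(seq_len(length), each = 2L),
      x = as.numeric(rbind(ca[, 1L], side[, 1L])),
      y = as.numeric(rbind(ca[, 2L], side[, 2L])),
      z = as.numeric(rbind(ca[, 3L], side[, 3L]))
    )
    protein_chain(chain_id, res_type, atoms)
  })
}

# draw a composition profile: base profile perturbed log-normally
tilt_profile <- function(base, sd) {
  p <- base * exp(stats::rnorm(length(base), sd = sd))
  p / sum(p)
}

#' Synthetic labeled contact-vector cohort
#'
#' Draws native contact vectors from length-scaled multinomial counts
#' concentrated on a cohort-level "native composition" profile (with
#' per-protein tilts), and decoys from the same totals with composition
#' mixed toward a background profile by weight `native_signal`. Totals
#' are conserved between a native and its decoys, mirroring threading
#' and swap decoys on a fixed contact map. The cohort is split into
#' train and test with no native shared; a contacts-versus-length model
#' is fitted on the raw training natives and (by default) applied to
#' every vector.
#'
#' @param config A [synth_config()].
#' @param normalize Length-normalize all vectors with the model fitted
#'   on the training natives (default TRUE).
#' @return List with `train` and `test` (each: `natives` = list(X, ids,
#'   lengths), `universe` = [decoy_universe()]), `length_model`, `raw`
#'   (raw per-native totals/lengths data.frame) and `config`.
#' @export
make_vector_cohort <- function(config = synth_config(), normalize = TRUE) {
  withr::with_seed(config$seed, {
    n <- config$n_natives
    lens <- sample(seq(config$length_range[1L], config$length_range[2L]), n,
                   replace = TRUE)
    totals <- pmax(30, round(config$contacts_intercept +
                               config$contacts_slope * lens +
                               stats::rnorm(n, sd = config$contacts_noise_sd)))
    p0 <- tilt_profile(rep(1, 210L), sd = 0.5) # cohort native profile
    bg0 <- tilt_profile(rep(1, 210L), sd = 0.5) # decoy background profile
    ids <- sprintf("nat%03d", seq_len(n))
    natX <- matrix(0, n, 210L, dimnames = list(ids, contact_type_names()))
    dec_list <- vector("list", n)
    dec_native <- character(0)
    dec_ids <- character(0)
    for (i in seq_len(n)) {
      p_i <- tilt_profile(p0, sd = config$tilt_sd)
      natX[i, ] <- as.numeric(stats::rmultinom(1L, totals[i], p_i))
      D <- matrix(0, config$decoys_per_native, 210L)
      for (j in seq_len(config$decoys_per_native)) {
        r <- tilt_profile(bg0, sd = 0.3)
        q <- (1 - config$native_signal) * p_i + config$native_signal * r
        D[j, ] <- as.numeric(stats::rmultinom(1L, totals[i], q))
      }
      dec_list[[i]] <- D
      dec_native <- c(dec_native, rep(ids[i], config$decoys_per_native))
      dec_ids <- c(dec_ids, sprintf("%s.d%03d", ids[i],
                                    seq_len(config$decoys_per_native)))
    }
    decX <- do.call(rbind, dec_list)
    rownames(decX) <- dec_ids
    dec_lens <- lens[match(dec_native, ids)]

    n_train <- max(2L, round(config$train_fraction * n))
    tr <- sort(sample.int(n, n_train))
    te <- setdiff(seq_len(n), tr)
    lm_fit <- fit_length_model(data.frame(length = lens[tr], total = totals[tr]))

    scale_rows <- function(X, l) {
      if (!normalize) return(X)
      X / predict_contacts(lm_fit, l)
    }
    part <- function(idx) {
      drows <- which(dec_native %in% ids[idx])
      list(
        natives = list(X = scale_rows(natX[idx, , drop = FALSE], lens[idx]),
                       ids = ids[idx], lengths = lens[idx]),
        universe = decoy_universe(
          scale_rows(decX[drows, , drop = FALSE], dec_lens[drows]),
          native_id = dec_native[drows], ids = dec_ids[drows]
        )
      )
    }
    list(train = part(tr), test = part(te), length_model = lm_fit,
         raw = data.frame(id = ids, length = lens, total = totals,
                          split = ifelse(seq_len(n) %in% tr, "train", "test")),
         config = config)
  })
}
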