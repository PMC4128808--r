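#' Configuration of the iterative pool/basis selection
#'
#' Controls how the data matrix C (training pool) and the basis set Abar
#' are rebuilt from round to round. At the full scale of an 800-native
#' input the defaults reproduce the canonical bookkeeping: pool C = 800
#' natives + 8,000 decoys (10 per native), basis = 480 natives (60%) +
#' 3,200 decoys (40% of the pool decoys) = 3,680 basis vectors; the
#' initial round keeps 1 decoy per native (pool 800 + 800, basis
#' 480 + 320).
#'
#' @param decoys_per_native_pool Decoys sampled/selected per native for
#'   the pool in each round (default 10).
#' @param native_basis_fraction Fraction of natives entering the basis
#'   (default 0.60).
#' @param decoy_basis_fraction Fraction of the pool's decoys entering the
#'   basis (default 0.40).
#' @param strategy Selection strategy, 1 or 2.
#' @param strategy2_preselect_native_fraction For Strategy 2: fraction of
#'   natives pre-selected as hardest (fitness closest to 0 from below)
#'   before random fill to `native_basis_fraction` (default 0.50).
#' @param strategy2_preselect_top_decoys For Strategy 2: number of
#'   hardest correctly-classified decoys per native pre-selected for the
#'   basis before random fill (default 1).
#' @param seed Integer seed driving every random choice in the loop.
#' @param max_rounds Maximum number of strategy rounds (default 10).
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(decoys_per_native_pool = 10L,
                             native_basis_fraction = 0.60,
                             decoy_basis_fraction = 0.40,
                             strategy = 2L,
                             strategy2_preselect_native_fraction = 0.50,
                             strategy2_preselect_top_decoys = 1L,
                             seed = 1L,
                             max_rounds = 10L) {
  stopifnot(decoys_per_native_pool >= 1L,
            native_basis_fraction > 0, native_basis_fraction <= 1,
            decoy_basis_fraction > 0, decoy_basis_fraction <= 1,
            strategy %in% c(1L, 2L),
            strategy2_preselect_native_fraction > 0,
            strategy2_preselect_native_fraction <= 1,
            strategy2_preselect_top_decoys >= 1L,
            max_rounds >= 1L)
  structure(
    list(decoys_per_native_pool = as.integer(decoys_per_native_pool),
         native_basis_fraction = native_basis_fraction,
         decoy_basis_fraction = decoy_basis_fraction,
         strategy = as.integer(strategy),
         strategy2_preselect_native_fraction = strategy2_preselect_native_fraction,
         strategy2_preselect_top_decoys = as.integer(strategy2_preselect_top_decoys),
         seed = as.integer(seed),
         max_rounds = as.integer(max_rounds)),
    class = "selection_config"
  )
}

#' Decoy universe container
#'
#' The full decoy collection, each decoy attached to one native protein.
#'
#' @param X Matrix of decoy vectors (rows).
#' @param native_id Character vector: owning native per decoy row.
#' @param ids Optional decoy identifiers.
#' @return Object of class `decoy_universe`.
#' @export
decoy_universe <- function(X, native_id, ids = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(native_id))
  if (is.null(ids)) ids <- rownames(X) %||% paste0("d", seq_len(nrow(X)))
  rownames(X) <- ids
  structure(list(X = X, native_id = as.character(native_id),
                 ids = as.character(ids)),
            class = "decoy_universe")
}

#' @export
print.decoy_universe <- function(x, ...) {
  cat("<decoy_universe>", nrow(x$X), "decoys for",
      length(unique(x$native_id)), "natives\n")
  invisible(x)
}

# Score a block of vectors in chunks, returning fitness values; the
# universe is never held in kernel space all at once.
score_universe <- function(model, X, chunk = 4096L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    out[rows] <- fitness(model, X[rows, , drop = FALSE])
  }
  out
}

# round(f * n) with a floor of 1 (never an empty slice of a non-empty set)
frac_count <- function(f, n) {
  if (n == 0L) return(0L)
  max(1L, min(n, as.integer(round(f * n))))
}

# Assemble a basis from chosen native rows + decoy rows of the pool.
make_basis <- function(natives, nat_idx, decoy_X, decoy_ids) {
  X <- rbind(natives$X[nat_idx, , drop = FALSE], decoy_X)
  labels <- c(rep(-1, length(nat_idx)), rep(1, nrow(decoy_X)))
  basis_set(X, labels, ids = c(natives$ids[nat_idx], decoy_ids))
}

#' Initial pool and basis
#'
#' Samples `decoys_per_native_pool` candidate decoys per native (the
#' per-native short list kept by later rounds), keeps one of them per
#' native for the initial pool C = natives + one decoy each, and draws
#' the initial basis as `native_basis_fraction` of the natives plus
#' `decoy_basis_fraction` of C's decoys. Natives without any decoys are
#' skipped with a warning.
#'
#' @param natives A [training_pool()] containing only natives (labels all
#'   -1) or a list with `X`/`ids`.
#' @param universe A [decoy_universe()].
#' @param config A [selection_config()].
#' @return List with `pool` (training_pool C), `basis` (basis_set Abar),
#'   and `state` (per-native candidate lists used by later rounds).
#' @export
init_round <- function(natives, universe, config) {
  n_nat <- nrow(natives$X)
  withr::with_seed(config$seed, {
    shortlist <- vector("list", n_nat)
    names(shortlist) <- natives$ids
    kept <- integer(0) # universe row kept per native for initial C
    skipped <- character(0)
    for (k in seq_len(n_nat)) {
      rows <- which(universe$native_id == natives$ids[k])
      if (length(rows) == 0L) {
        skipped <- c(skipped, natives$ids[k])
        next
      }
      take <- min(config$decoys_per_native_pool, length(rows))
      if (take < config$decoys_per_native_pool) {
        warning("native ", natives$ids[k], " has only ", take, " decoys")
      }
      sel <- if (length(rows) == 1L) rows else sample(rows, take)
      shortlist[[k]] <- sel
      kept <- c(kept, sel[1L])
    }
    if (length(skipped) > 0L) {
      warning("no decoys for native(s): ", paste(skipped, collapse = ", "))
    }
    active <- which(!vapply(shortlist, is.null, TRUE))
    pool <- training_pool(
      rbind(natives$X[active, , drop = FALSE],
            universe$X[kept, , drop = FALSE]),
      labels = c(rep(-1, length(active)), rep(1, length(kept))),
      ids = c(natives$ids[active], universe$ids[kept])
    )
    n_b_nat <- frac_count(config$native_basis_fraction, length(active))
    n_b_dec <- frac_count(config$decoy_basis_fraction, length(kept))
    nat_idx <- active[sample(length(active), n_b_nat)]
    dec_pick <- sample(length(kept), n_b_dec)
    basis <- make_basis(natives, nat_idx,
                        universe$X[kept[dec_pick], , drop = FALSE],
                        universe$ids[kept[dec_pick]])
    list(pool = pool, basis = basis,
         state = list(shortlist = shortlist, selected = shortlist,
                      skipped = skipped))
  })
}

#' One Strategy-1 round
#'
#' Per native, the misclassified decoys (negative fitness) are sorted by
#' fitness in descending order so the least-violating ones come first,
#' and up to `decoys_per_native_pool` of them are selected; short lists
#' are topped up from the previous round's selection for that native,
#' and a native with no misclassified decoys in any round keeps its
#' previous decoys. The new pool C is natives + the selected decoys; the
#' basis is a random `native_basis_fraction` of the natives plus a random
#' `decoy_basis_fraction` of C's decoys.
#'
#' @param model Current [fitness_model()].
#' @param natives Native pool (as in [init_round()]).
#' @param universe A [decoy_universe()].
#' @param prev_state `state` list returned by the previous round.
#' @param config A [selection_config()].
#' @param round_seed Seed for this round's random draws.
#' @return List with `pool`, `basis`, `state`.
#' @export
strategy1_round <- function(model, natives, universe, prev_state, config,
                            round_seed = config$seed) {
  fit_u <- score_universe(model, universe$X)
  n_nat <- nrow(natives$X)
  withr::with_seed(as.integer(round_seed), {
    selected <- vector("list", n_nat)
    names(selected) <- natives$ids
    for (k in seq_len(n_nat)) {
      rows <- which(universe$native_id == natives$ids[k])
      if (length(rows) == 0L) next
      mis <- rows[fit_u[rows] < 0]
      # least violation first: descending fitness, stable by id
      mis <- mis[order(-fit_u[mis], universe$ids[mis])]
      sel <- utils::head(mis, config$decoys_per_native_pool)
      if (length(sel) < config$decoys_per_native_pool) {
        prev <- setdiff(prev_state$selected[[k]], sel)
        sel <- c(sel, utils::head(prev, config$decoys_per_native_pool - length(sel)))
      }
      if (length(sel) == 0L) sel <- prev_state$selected[[k]]
      selected[[k]] <- sel
    }
    active <- which(!vapply(selected, is.null, TRUE))
    dec_rows <- unlist(selected[active], use.names = FALSE)
    pool <- training_pool(
      rbind(natives$X[active, , drop = FALSE],
            universe$X[dec_rows, , drop = FALSE]),
      labels = c(rep(-1, length(active)), rep(1, length(dec_rows))),
      ids = c(natives$ids[active], universe$ids[dec_rows])
    )
    n_b_nat <- frac_count(config$native_basis_fraction, length(active))
    n_b_dec <- frac_count(config$decoy_basis_fraction, length(dec_rows))
    nat_idx <- active[sample(length(active), n_b_nat)]
    dec_pick <- sample(length(dec_rows), n_b_dec)
    basis <- make_basis(natives, nat_idx,
                        universe$X[dec_rows[dec_pick], , drop = FALSE],
                        universe$ids[dec_rows[dec_pick]])
    list(pool = pool, basis = basis,
         state = list(shortlist = prev_state$shortlist, selected = selected,
                      skipped = prev_state$skipped))
  })
}

#' One Strategy-2 round
#'
#' Per native, the hardest correctly-classified decoys (positive fitness,
#' smallest values, ascending order) form the pool short list (random
#' fill from that native's remaining decoys when fewer exist). The basis
#' natives are the pre-selected hardest fraction (correctly classified,
#' fitness closest to 0 from below, descending order) topped up with
#' random natives to `native_basis_fraction`; the basis decoys are the
#' per-native top `strategy2_preselect_top_decoys` hardest decoys from
#' the pool plus random per-native fill to the per-native basis quota.
#'
#' @inheritParams strategy1_round
#' @return List with `pool`, `basis`, `state`.
#' @export
strategy2_round <- function(model, natives, universe, prev_state, config,
                            round_seed = config$seed) {
  fit_u <- score_universe(model, universe$X)
  fit_n <- score_universe(model, natives$X)
  n_nat <- nrow(natives$X)
  withr::with_seed(as.integer(round_seed), {
    selected <- vector("list", n_nat)
    names(selected) <- natives$ids
    fill_used <- 0L
    for (k in seq_len(n_nat)) {
      rows <- which(universe$native_id == natives$ids[k])
      if (length(rows) == 0L) next
      ok <- rows[fit_u[rows] > 0]
      ok <- ok[order(fit_u[ok], universe$ids[ok])] # hardest (smallest positive) first
      sel <- utils::head(ok, config$decoys_per_native_pool)
      if (length(sel) < config$decoys_per_native_pool) {
        rest <- setdiff(rows, sel)
        need <- min(config$decoys_per_native_pool - length(sel), length(rest))
        if (need > 0L) {
          sel <- c(sel, if (length(rest) == 1L) rest else sample(rest, need))
          fill_used <- fill_used + need
        }
      }
      selected[[k]] <- sel
    }
    active <- which(!vapply(selected, is.null, TRUE))
    dec_rows <- unlist(selected[active], use.names = FALSE)
    pool <- training_pool(
      rbind(natives$X[active, , drop = FALSE],
            universe$X[dec_rows, , drop = FALSE]),
      labels = c(rep(-1, length(active)), rep(1, length(dec_rows))),
      ids = c(natives$ids[active], universe$ids[dec_rows])
    )
    # -- basis natives: hardest correctly classified, then random fill
    n_b_nat <- frac_count(config$native_basis_fraction, length(active))
    n_pre <- min(frac_count(config$strategy2_preselect_native_fraction,
                            length(active)), n_b_nat)
    correct <- active[fit_n[active] < 0]
    correct <- correct[order(-fit_n[correct], natives$ids[correct])] # closest to 0 first
    hard_nat <- utils::head(correct, n_pre)
    rest_nat <- setdiff(active, hard_nat)
    fill_n <- min(n_b_nat - length(hard_nat), length(rest_nat))
    nat_idx <- c(hard_nat,
                 if (fill_n > 0L) {
                   if (length(rest_nat) == 1L) rest_nat else sample(rest_nat, fill_n)
                 })
    # -- basis decoys: per-native top-k hardest + random per-native fill
    k_top <- config$strategy2_preselect_top_decoys
    quota <- frac_count(config$decoy_basis_fraction,
                        config$decoys_per_native_pool)
    dec_keep <- integer(0)
    for (k in active) {
      sel <- selected[[k]] # already hardest-first
      top <- utils::head(sel, min(k_top, length(sel)))
      rest <- setdiff(sel, top)
      need <- min(quota - length(top), length(rest))
      if (need > 0L) {
        top <- c(top, if (length(rest) == 1L) rest else sample(rest, need))
      }
      dec_keep <- c(dec_keep, top)
    }
    basis <- make_basis(natives, nat_idx,
                        universe$X[dec_keep, , drop = FALSE],
                        universe$ids[dec_keep])
    list(pool = pool, basis = basis,
         state = list(shortlist = prev_state$shortlist, selected = selected,
                      skipped = prev_state$skipped, random_fill = fill_used))
  })
}

#' Iterative reduced-SVM training over a decoy universe
#'
#' Alternates training on the current (C, Abar) with scoring of the full
#' training universe and a strategy round rebuilding (C, Abar), until the
#' total misclassification count (natives with positive fitness + decoys
#' with negative fitness) stops strictly improving, or `max_rounds` is
#' reached; three consecutive strict increases abort the loop with a
#' divergence flag. The best-scoring model over all rounds is returned,
#' not the last one.
#'
#' @param natives Native [training_pool()] (labels all -1, or a list with
#'   `X`/`ids`).
#' @param universe A [decoy_universe()].
#' @param config A [selection_config()].
#' @param kernel [kernel_params()] or `NULL` for the median heuristic on
#'   the initial pool.
#' @param params [solver_params()].
#' @param length_model Optional normalization model stored with the fit.
#' @param verbose Emit per-round progress messages.
#' @return List with `model` (best [fitness_model()]), `reports`
#'   (data.frame of per-round counts), `best_round`, `diverged`.
#' @export
run_training <- function(natives, universe, config = selection_config(),
                         kernel = NULL, params = solver_params(),
                         length_model = NULL, verbose = FALSE) {
  rd <- init_round(natives, universe, config)
  kernel <- kernel %||% median_heuristic_mu(rd$pool$X, seed = config$seed)
  reports <- list()
  best <- NULL
  increases <- 0L
  diverged <- FALSE
  prev_total <- Inf
  for (round in 0:config$max_rounds) {
    if (round > 0L) {
      round_seed <- (config$seed + 104729L * round) %% .Machine$integer.max
      rd <- if (config$strategy == 1L) {
        strategy1_round(best$model_for_round, natives, universe, rd$state,
                        config, round_seed = round_seed)
      } else {
        strategy2_round(best$model_for_round, natives, universe, rd$state,
                        config, round_seed = round_seed)
      }
    }
    model <- train_rsvm(rd$pool, rd$basis, kernel = kernel, params = params,
                        length_model = length_model,
                        provenance = list(strategy = config$strategy,
                                          round = round, seed = config$seed))
    fit_n <- score_universe(model, natives$X)
    fit_u <- score_universe(model, universe$X)
    mis_nat <- sum(fit_n > 0)
    mis_dec <- sum(fit_u < 0)
    total <- mis_nat + mis_dec
    reports[[round + 1L]] <- data.frame(
      round = round, mis_natives = mis_nat, mis_decoys = mis_dec,
      total = total, basis_size = nrow(rd$basis$X),
      pool_size = nrow(rd$pool$X), converged = model$provenance$converged
    )
    if (verbose) {
      message(sprintf("round %d: %d/%d misclassified (basis %d)",
                      round, mis_nat, mis_dec, nrow(rd$basis$X)))
    }
    if (is.null(best) || total < best$total) {
      best <- list(model = model, total = total, round = round,
                   model_for_round = model)
      improved <- TRUE
    } else {
      best$model_for_round <- model # strategies score with the current model
      improved <- FALSE
    }
    increases <- if (total > prev_total) increases + 1L else 0L
    if (increases >= 3L) {
      diverged <- TRUE
      warning("misclassifications increased 3 rounds running; stopping")
      break
    }
    if (round > 0L && !improved) break
    prev_total <- total
  }
  list(model = best$model, reports = do.call(rbind, reports),
       best_round = best$round, diverged = diverged)
}
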