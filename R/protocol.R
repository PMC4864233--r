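#' Construct a decoy set
#'
#' Holds the decoys of one target: ids, structures, docked COM distances
#' and a growing table of per-replicate binding free energies.
#'
#' @param ids Character vector of unique decoy ids.
#' @param dock_com Numeric vector of docked COM distances (nm), one per id.
#' @param structures Optional named list of `dock_structure` objects.
#' @param tier Optional character vector of generative tier labels.
#' @return A `decoy_set`.
#' @export
decoy_set <- function(ids, dock_com, structures = NULL, tier = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("decoy ids must be unique")
  stopifnot(length(dock_com) == length(ids), all(dock_com > 0))
  if (!is.null(structures)) stopifnot(all(ids %in% names(structures)))
  tab <- data.frame(id = ids, dock_com = dock_com,
                    tier = if (is.null(tier)) NA_character_ else tier,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, structures = structures,
                 dg = matrix(NA_real_, nrow = length(ids), ncol = 0,
                             dimnames = list(ids, NULL))),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("Decoy set:", nrow(x$table), "decoys")
  if (!all(is.na(x$table$tier)))
    cat(" (tiers: ", paste(names(table(x$table$tier)), table(x$table$tier),
                           sep = "=", collapse = " "), ")", sep = "")
  cat("\n")
  if (ncol(x$dg) > 0)
    cat("  replicates scored:", ncol(x$dg), "\n")
  invisible(x)
}

rank_scores <- function(scores, stage) {
  ord <- order(scores, names(scores))
  out <- data.frame(rank = seq_along(scores), id = names(scores)[ord],
                    score = unname(scores[ord]), stage = stage,
                    stringsAsFactors = FALSE)
  class(out) <- c("dock_ranking", "data.frame")
  out
}

#' Stage-1 ranking from single-replicate binding free energies
#'
#' Ascending sort on the replicate-1 binding free energy (lower = more
#' stable = better); ties broken lexicographically by decoy id.
#'
#' @param decoys A `decoy_set` with at least one scored replicate, or a
#'   named numeric vector of binding free energies.
#' @return A `dock_ranking`: data.frame with `rank`, `id`, `score`,
#'   `stage`.
#' @export
stage1_rank <- function(decoys) {
  scores <- if (inherits(decoys, "decoy_set")) {
    if (ncol(decoys$dg) < 1) stop("no replicate-1 scores in decoy set")
    stats::setNames(decoys$dg[, 1], rownames(decoys$dg))
  } else {
    if (is.null(names(decoys))) stop("scores must be named by decoy id")
    decoys
  }
  if (any(is.na(scores))) stop("decoy missing replicate-1 score: ",
                               paste(names(scores)[is.na(scores)], collapse = ", "))
  rank_scores(scores, "stage1")
}

#' Keep the best half of a ranking
#'
#' The first ceiling(N/2) decoys (the median decoy survives on odd N).
#'
#' @param ranking A `dock_ranking`.
#' @return Character vector of surviving decoy ids, in rank order.
#' @export
select_best_half <- function(ranking) {
  stopifnot(inherits(ranking, "dock_ranking"), nrow(ranking) >= 1)
  ranking$id[seq_len(ceiling(nrow(ranking) / 2))]
}

#' First k decoys of a ranking
#'
#' @param ranking A `dock_ranking`.
#' @param k Selection size (>= 1); clamped to the ranking length.
#' @return Character vector of decoy ids.
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "dock_ranking"), k >= 1)
  ranking$id[seq_len(min(k, nrow(ranking)))]
}

#' Staged replicate ranking of a decoy set
#'
#' The staged protocol: every decoy is scored once (replicate 1) and ranked;
#' the best (lowest) half survives; survivors receive `n_extra_replicates`
#' further replicates; the final ranking orders survivors by their mean
#' binding free energy over all replicates (stage-1 replicate included),
#' with the cut decoys appended afterwards in stage-1 order, flagged by the
#' `stage` column.
#'
#' @param decoys A `decoy_set`.
#' @param engine Force-sampling callable
#'   `function(id, index, schedule, replicate)` returning a window-sample
#'   data.frame (see [profile_engine()] and [dynamics_engine()]).
#' @param n_extra_replicates Replicates added for survivors (default 4, for
#'   five in total).
#' @param temperature Temperature (K) used in the PMF integration.
#' @param jacobian Apply the radial Jacobian correction (default `TRUE`).
#' @return A `dock_ranking` with attributes `dg` (the per-decoy
#'   per-replicate value matrix) and `stage1` (the stage-1 ranking).
#' @export
run_full_protocol <- function(decoys, engine, n_extra_replicates = 4,
                              temperature = 300, jacobian = TRUE) {
  stopifnot(inherits(decoys, "decoy_set"), is.function(engine),
            n_extra_replicates >= 0)
  ids <- decoys$table$id
  n_rep <- 1 + n_extra_replicates
  dg <- matrix(NA_real_, nrow = length(ids), ncol = n_rep,
               dimnames = list(ids, NULL))
  score_one <- function(id, idx, rep) {
    sched <- make_schedule(decoys$table$dock_com[idx])
    samples <- tryCatch(engine(id, idx, sched, rep),
                        error = function(e) stop("engine failed for decoy '", id,
                                                 "', replicate ", rep, ": ",
                                                 conditionMessage(e), call. = FALSE))
    extract_dgoff(integrate_pmf(samples, temperature, jacobian))$value
  }
  for (i in seq_along(ids)) dg[i, 1] <- score_one(ids[i], i, 1)
  stage1 <- rank_scores(stats::setNames(dg[, 1], ids), "stage1")
  survivors <- select_best_half(stage1)
  if (n_extra_replicates > 0) {
    for (id in survivors) {
      i <- match(id, ids)
      for (rep in 2:n_rep) dg[i, rep] <- score_one(id, i, rep)
    }
  }
  mean_dg <- rowMeans(dg[survivors, , drop = FALSE])
  final_surv <- rank_scores(mean_dg, "final")
  cut <- setdiff(stage1$id, survivors)
  if (length(cut) > 0) {
    cut_df <- stage1[match(cut, stage1$id), , drop = FALSE]
    cut_df$stage <- "stage1-cut"
    final <- rbind(final_surv, cut_df)
  } else final <- final_surv
  final$rank <- seq_len(nrow(final))
  rownames(final) <- NULL
  class(final) <- c("dock_ranking", "data.frame")
  attr(final, "dg") <- dg
  attr(final, "stage1") <- stage1
  final
}

#' @export
print.dock_ranking <- function(x, n = 10, ...) {
  cat("Decoy ranking (", nrow(x), " decoys, stage: ",
      paste(unique(x$stage), collapse = "/"), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Engine sampling forces from synthetic radial potentials
#'
#' Returns a callable for [run_full_protocol()] that produces window
#' samples with [make_force_profiles()], using one radial potential per
#' decoy and seeds derived from (base seed, decoy index, replicate).
#'
#' @param potentials Named list of [radial_potential()] objects, one per
#'   decoy id.
#' @param noise_sd Gaussian noise on each mean force (kJ/mol/nm).
#' @param base_seed Base seed for the deterministic seed derivation.
#' @param temperature Temperature (K) for the Jacobian term.
#' @param include_jacobian Add the + 2 k_B T / r term so the profiles look
#'   like raw constraint forces (default `TRUE`).
#' @return `function(id, index, schedule, replicate)`.
#' @export
profile_engine <- function(potentials, noise_sd = 0, base_seed = 1,
                           temperature = 300, include_jacobian = TRUE) {
  force(potentials); force(noise_sd); force(base_seed)
  function(id, index, schedule, replicate) {
    make_force_profiles(schedule, potentials[[id]], noise_sd = noise_sd,
                        seed = derive_seed(base_seed, index, 0, replicate),
                        temperature = temperature,
                        include_jacobian = include_jacobian,
                        replicate = replicate)
  }
}

#' Engine running the rigid-body dynamics per decoy
#'
#' @param models Named list of `bead_model` objects, one per decoy id.
#' @param params A [sim_params()] object.
#' @param base_seed Base seed for the per-window seed derivation.
#' @param potentials Optional named list of [radial_potential()] objects
#'   injected in place of the bead-bead interaction.
#' @return `function(id, index, schedule, replicate)` for
#'   [run_full_protocol()].
#' @export
dynamics_engine <- function(models, params = sim_params(), base_seed = 1,
                            potentials = NULL) {
  force(models); force(params); force(base_seed); force(potentials)
  function(id, index, schedule, replicate) {
    run_replicate(models[[id]], schedule, params, replicate = replicate,
                  base_seed = base_seed, decoy = index,
                  potential = if (is.null(potentials)) NULL else potentials[[id]])
  }
}

#' Score the native (crystal) reference at higher replication
#'
#' Runs `n_replicates` independent replicates of the full window series for
#' one model and averages the binding free energies.
#'
#' @param id Decoy/reference id passed to the engine.
#' @param dock_com Docked COM distance (nm).
#' @param engine Force-sampling callable as in [run_full_protocol()].
#' @param n_replicates Number of replicates (default 20).
#' @inheritParams run_full_protocol
#' @return A `dg_off` with `replicate = "mean"`.
#' @export
crystal_reference <- function(id, dock_com, engine, n_replicates = 20,
                              temperature = 300, jacobian = TRUE) {
  stopifnot(n_replicates >= 1)
  sched <- make_schedule(dock_com)
  per <- lapply(seq_len(n_replicates), function(rep)
    extract_dgoff(integrate_pmf(engine(id, 0L, sched, rep),
                                temperature, jacobian)))
  average_dgoff(per)
}
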