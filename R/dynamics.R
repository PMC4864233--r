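#' Simulation parameters for the rigid-body engine
#'
#' Bundles the knobs of the overdamped Langevin engine. The bead-bead
#' interaction is a shifted-truncated Lennard-Jones potential with a well
#' depth per particle-class pair plus a Debye-screened Coulomb term between
#' charged beads. The epsilon table orders like-class contacts strongest
#' (charged and apolar pairs cohesive, apolar-polar penalised); it is
#' configuration, not a fitted force field.
#'
#' @param temperature Temperature in K (> 0).
#' @param dt_fs Time step in fs.
#' @param n_steps Total number of steps (equilibration included).
#' @param equil_frac Fraction of steps discarded as equilibration, in [0, 1).
#' @param friction Friction coefficient in 1/ps.
#' @param epsilon 4x4 symmetric matrix of LJ well depths (kJ/mol) with rows
#'   and columns named P, N, C, Q.
#' @param sigma LJ radius in nm.
#' @param cutoff LJ cutoff in nm (energy shifted to zero there).
#' @param coul_pref Electrostatic prefactor in kJ/mol nm per unit-charge
#'   pair (default: Coulomb constant over a relative permittivity of 15).
#' @param debye Debye screening length in nm.
#' @param max_step_nm Cap on the deterministic per-step displacement of a
#'   body (nm); keeps steep-repulsion start-ups stable.
#' @param check_every Interval (steps) for constraint/rigidity diagnostics.
#' @return A `sim_params` list.
#' @export
sim_params <- function(temperature = 300, dt_fs = 20, n_steps = 5e4,
                       equil_frac = 0.2, friction = 10,
                       epsilon = default_epsilon(), sigma = 0.47,
                       cutoff = 1.2, coul_pref = 138.935 / 15, debye = 1.0,
                       max_step_nm = 0.05, check_every = 1000) {
  stopifnot(temperature > 0, dt_fs > 0, n_steps >= 1,
            equil_frac >= 0, equil_frac < 1, friction > 0,
            is.matrix(epsilon), all(dim(epsilon) == c(4, 4)),
            isTRUE(all.equal(epsilon, t(epsilon))),
            sigma > 0, cutoff > 0, debye > 0)
  p <- list(temperature = temperature, dt = dt_fs / 1000, n_steps = as.integer(n_steps),
            equil_frac = equil_frac, friction = friction, epsilon = epsilon,
            sigma = sigma, cutoff = cutoff, coul_pref = coul_pref, debye = debye,
            max_step = max_step_nm, check_every = as.integer(check_every))
  class(p) <- "sim_params"
  p
}

#' Default LJ well-depth table (kJ/mol) over the four particle classes
#' @return 4x4 symmetric matrix with dimnames P, N, C, Q.
#' @export
default_epsilon <- function() {
  cls <- c("P", "N", "C", "Q")
  e <- matrix(0, 4, 4, dimnames = list(cls, cls))
  e["P", "P"] <- 4.0; e["N", "N"] <- 3.5; e["C", "C"] <- 4.5; e["Q", "Q"] <- 5.0
  e["P", "Q"] <- e["Q", "P"] <- 4.5
  e["C", "P"] <- e["P", "C"] <- 2.0
  e["C", "Q"] <- e["Q", "C"] <- 1.8
  e["N", "P"] <- e["P", "N"] <- 3.0
  e["N", "Q"] <- e["Q", "N"] <- 2.8
  e["N", "C"] <- e["C", "N"] <- 3.2
  e
}

#' Radial test potential acting between the two centres of mass
#'
#' Used to inject an analytically known interaction in place of the bead
#' sums, for validation and for synthetic decoy scoring.
#' Types: `"harmonic"` is U(r) = depth ((r - r0)/width)^2; `"gauss"` is a
#' well U(r) = -depth exp(-(r - r0)^2 / (2 width^2)).
#'
#' @param type `"harmonic"` or `"gauss"`.
#' @param depth Energy scale, kJ/mol (well depth for `"gauss"`).
#' @param r0 Location of the minimum, nm.
#' @param width Width parameter, nm.
#' @return A `radial_potential` with fields `u(r)` and `dudr(r)`.
#' @export
radial_potential <- function(type = c("gauss", "harmonic"), depth, r0, width) {
  type <- match.arg(type)
  stopifnot(depth >= 0, r0 > 0, width > 0)
  if (type == "harmonic") {
    u <- function(r) depth * ((r - r0) / width)^2
    dudr <- function(r) 2 * depth * (r - r0) / width^2
  } else {
    u <- function(r) -depth * exp(-(r - r0)^2 / (2 * width^2))
    dudr <- function(r) depth * (r - r0) / width^2 * exp(-(r - r0)^2 / (2 * width^2))
  }
  structure(list(type = type, depth = depth, r0 = r0, width = width,
                 u = u, dudr = dudr),
            class = "radial_potential")
}

pot_code <- function(potential) {
  if (is.null(potential)) return(list(code = 0L, par = c(0, 0, 1)))
  stopifnot(inherits(potential, "radial_potential"))
  list(code = if (potential$type == "harmonic") 1L else 2L,
       par = c(potential$depth, potential$r0, potential$width))
}

#' Sample the mean constraint force at one COM distance
#'
#' Places the ligand along the current receptor-ligand COM axis at distance
#' `r`, then runs rigid-body overdamped Langevin dynamics of the two groups.
#' After every step the COM-COM distance is projected back to `r` exactly
#' (mass-weighted displacement of both bodies along the inter-COM axis);
#' the restoring displacement converted to a force via the friction
#' coefficient is the recorded constraint force. Its sign is such that net
#' attraction gives a negative mean once the radial (Jacobian) term
#' 2 k_B T / r is subtracted: non-interacting bodies average to exactly
#' + 2 k_B T / r.
#'
#' Identical `(model, r, params, seed)` give bit-identical output.
#'
#' @param model A `bead_model` with non-empty receptor and ligand groups.
#' @param r Constrained COM distance, nm (> 0).
#' @param params A [sim_params()] object.
#' @param seed Integer RNG seed for this window.
#' @param potential Optional [radial_potential()] replacing the bead-bead
#'   interaction.
#' @param replicate Replicate id stored in the output.
#' @return One-row data.frame (`window_sample`): `r_nm`,
#'   `mean_force_kJ_mol_nm`, `stderr`, `n_eff`, `n_samples`, `replicate`,
#'   `seed`, plus diagnostics `max_constraint_violation` and
#'   `max_rigid_deviation` (nm) as attributes `diagnostics`.
#' @export
simulate_window <- function(model, r, params = sim_params(), seed = 1,
                            potential = NULL, replicate = NA_integer_) {
  validate_bead_model(model)
  stopifnot(inherits(params, "sim_params"), is.numeric(r), length(r) == 1, r > 0)
  if (!any(model$group == "receptor") || !any(model$group == "ligand"))
    stop("model must have two non-empty rigid groups")
  set.seed(as.integer(seed))

  pos <- as.matrix(model[, c("x", "y", "z")])
  grp <- ifelse(model$group == "receptor", 0L, 1L)
  type_idx <- match(model$type, c("P", "N", "C", "Q")) - 1L

  # place the ligand on the COM axis at distance r
  comR <- center_of_mass(model, "receptor")
  comL <- center_of_mass(model, "ligand")
  axis <- comL - comR
  na <- sqrt(sum(axis^2))
  axis <- if (na < 1e-9) c(1, 0, 0) else axis / na
  shift <- comR + axis * r - comL
  pos[grp == 1L, ] <- sweep(pos[grp == 1L, , drop = FALSE], 2, shift, "+")

  if (is.null(potential)) {
    # reject placements with hard clashes; retry with random ligand spins
    min_sep <- 0.15
    comL2 <- comR + axis * r
    ok <- min_intergroup_dist(pos, grp) >= min_sep
    attempts <- 0
    base <- sweep(pos[grp == 1L, , drop = FALSE], 2, comL2)
    while (!ok && attempts < 1000) {
      rot <- random_rotation()
      pos[grp == 1L, ] <- sweep(base %*% t(rot), 2, comL2, "+")
      ok <- min_intergroup_dist(pos, grp) >= min_sep
      attempts <- attempts + 1
    }
    if (!ok)
      stop("no overlap-free placement found at r = ", r,
           " nm after 1000 attempts")
  }

  pc <- pot_code(potential)
  out <- cpp_simulate_window(pos, model$mass, type_idx, as.numeric(model$charge),
                             grp, r, unclass(params), pc$code, pc$par)
  res <- data.frame(r_nm = r, mean_force_kJ_mol_nm = out$mean_force,
                    stderr = out$stderr, n_eff = out$n_eff,
                    n_samples = out$n_samples,
                    replicate = replicate, seed = as.integer(seed))
  attr(res, "diagnostics") <- list(
    max_constraint_violation = out$max_constraint_violation,
    max_rigid_deviation = out$max_rigid_deviation,
    final_positions = out$final_positions
  )
  class(res) <- c("window_sample", "data.frame")
  res
}

min_intergroup_dist <- function(pos, grp) {
  a <- pos[grp == 0L, , drop = FALSE]
  b <- pos[grp == 1L, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Deterministic per-window seed
#'
#' Mixes (base seed, decoy index, window index, replicate id) into a single
#' 31-bit seed with a Lehmer-style multiplicative hash, so every
#' (decoy, window, replicate) triple gets an independent, reproducible
#' random stream.
#'
#' @param base Base seed (integer).
#' @param decoy Decoy index (integer, 0 for none).
#' @param window Window index (1-based).
#' @param replicate Replicate id (1-based).
#' @return Integer seed in [1, 2^31 - 1].
#' @export
derive_seed <- function(base, decoy = 0, window = 1, replicate = 1) {
  m <- 2147483647
  h <- abs(as.numeric(base)) %% m
  for (v in c(decoy, window, replicate))
    h <- (h * 48271 + abs(as.numeric(v)) + 1) %% m
  as.integer(h + 1)
}

#' Run one replicate of the full window series
#'
#' One [simulate_window()] call per scheduled distance, with the per-window
#' seed derived deterministically from (base seed, decoy index, window
#' index, replicate id).
#'
#' @param model A `bead_model`.
#' @param schedule A [make_schedule()] object.
#' @param params A [sim_params()] object.
#' @param replicate Replicate id (1-based).
#' @param base_seed Base seed for the seed derivation.
#' @param decoy Decoy index used in the seed derivation.
#' @param potential Optional [radial_potential()] forwarded to every window.
#' @return data.frame of window samples in ascending `r_nm`.
#' @export
run_replicate <- function(model, schedule, params = sim_params(),
                          replicate = 1, base_seed = 1, decoy = 0,
                          potential = NULL) {
  stopifnot(inherits(schedule, "window_schedule"))
  rs <- schedule$distances
  if (length(rs) == 0) stop("empty window schedule")
  out <- vector("list", length(rs))
  for (w in seq_along(rs)) {
    s <- derive_seed(base_seed, decoy, w, replicate)
    out[[w]] <- tryCatch(
      simulate_window(model, rs[w], params, seed = s,
                      potential = potential, replicate = replicate),
      error = function(e) stop("window ", w, " (r = ", rs[w], " nm): ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  res <- do.call(rbind, lapply(out, function(x) { attr(x, "diagnostics") <- NULL; x }))
  rownames(res) <- NULL
  res
}
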