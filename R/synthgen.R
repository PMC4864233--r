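#' Configuration for the synthetic complex generator
#'
#' The generator builds toy two-chain complexes from backbone-only residue
#' stubs (N, CA, C, O at ideal local geometry) facing each other across a
#' flat interface, then derives decoys by rigid-body perturbation of the
#' ligand. Tier perturbation magnitudes are chosen so that the four
#' generative tiers land in (roughly) the four CAPRI categories; the
#' generative label is never used as truth downstream -- classification is.
#'
#' @param n_residues Residues per chain (>= 2).
#' @param interface_size Number of directly juxtaposed residue pairs
#'   (>= 1, <= `n_residues`); each contributes one native contact.
#' @param tiers Named list of per-tier perturbation ranges: each element
#'   `list(trans = c(lo, hi), rot = c(lo, hi))` in Angstrom / degrees.
#' @param n_per_tier Named integer vector of decoys per tier.
#' @param seed Base seed; fixed seed gives byte-identical output.
#' @param potential Injected radial potential spec used when synthesising
#'   force profiles: list with `type`, `depth` (kJ/mol), `r0` (nm),
#'   `width` (nm).
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_residues = 12, interface_size = 10,
                         tiers = list(
                           High = list(trans = c(0, 0.5), rot = c(0, 2)),
                           Medium = list(trans = c(0.5, 2), rot = c(2, 8)),
                           Acceptable = list(trans = c(2, 6), rot = c(8, 25)),
                           Incorrect = list(trans = c(15, 40), rot = c(90, 180))),
                         n_per_tier = c(High = 5, Medium = 10,
                                        Acceptable = 15, Incorrect = 70),
                         seed = 1,
                         potential = list(type = "gauss", depth = 50,
                                          r0 = NA, width = 0.25)) {
  stopifnot(n_residues >= 2, interface_size >= 1,
            interface_size <= n_residues,
            all(names(n_per_tier) %in% names(tiers)), all(n_per_tier >= 1))
  structure(list(n_residues = as.integer(n_residues),
                 interface_size = as.integer(interface_size),
                 tiers = tiers, n_per_tier = n_per_tier,
                 seed = as.integer(seed), potential = potential),
            class = "synth_config")
}

# 20 standard residues cycled so every particle class appears in a chain
synth_sequence <- function(n) {
  pool <- c("LYS", "GLU", "SER", "LEU", "ALA", "ARG", "ASP", "THR", "PHE",
            "MET", "GLN", "VAL", "HIS", "GLY", "ILE", "CYS", "TYR", "PRO",
            "ASN", "TRP")
  rep_len(pool, n)
}

# backbone template (Angstrom, CA at the origin); y > 0 side faces away
# from the partner chain
backbone_template <- matrix(
  c(-1.20, 0.70, 0.00,   # N
     0.00, 0.00, 0.00,   # CA
     1.20, 0.70, 0.00,   # C
     1.20, 1.90, 0.00),  # O
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O"), NULL))

#' Generate a toy native two-chain complex
#'
#' Chain A (receptor) and chain B (ligand) are extended strands of
#' backbone-only residues running antiparallel to the interface plane,
#' with `interface_size` residue pairs directly juxtaposed; each aligned
#' pair contributes one heavy-atom contact within 5 Angstrom. Deterministic
#' under the config seed.
#'
#' @param config A [synth_config()].
#' @return A `dock_structure` (chain A = receptor, chain B = ligand).
#' @export
make_native <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_residues
  iface <- config$interface_size
  if (iface < 1) stop("interface size must be >= 1")
  spacing <- 3.8
  gap <- 7.0 # CA-plane separation; closest O..O pairs sit at 3.2 A
  seqs <- synth_sequence(n)
  build_chain <- function(chain, y0, flip, x0, resno0) {
    rows <- lapply(seq_len(n), function(i) {
      tpl <- backbone_template
      if (flip) tpl[, 2] <- -tpl[, 2]
      tpl[, 3] <- tpl[, 3] + 0.3 * sin(i) # mild out-of-plane texture
      data.frame(chain = chain, resno = resno0 + i, ins = "",
                 resid = as.character(resno0 + i), resname = seqs[i],
                 atom = rownames(backbone_template),
                 element = c("N", "C", "C", "O"),
                 x = tpl[, 1] + x0 + (i - 1) * spacing,
                 y = tpl[, 2] + y0, z = tpl[, 3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  # ligand aligned with the last `iface` receptor residues
  offset <- (n - iface) * spacing
  atoms <- rbind(build_chain("A", 0, flip = FALSE, x0 = 0, resno0 = 0),
                 build_chain("B", gap, flip = TRUE, x0 = offset, resno0 = 100))
  rownames(atoms) <- NULL
  new_structure(atoms, c(A = "receptor", B = "ligand"))
}

#' Generate a decoy set by rigid-body perturbation of the ligand
#'
#' For each requested tier, translation magnitudes and rotation angles are
#' drawn uniformly from the tier's ranges (direction and axis uniform on
#' the sphere) and applied to the ligand about its centre of mass. The
#' docked COM distance of each decoy is computed from its coarse-grained
#' model. Output is fully deterministic under the config seed.
#'
#' @param native A `dock_structure` (see [make_native()]).
#' @param config A [synth_config()].
#' @return A `decoy_set` with structures, generative tier labels, and ids
#'   `"<tier>_<k>"`.
#' @export
make_decoys <- function(native, config = synth_config()) {
  validate_structure(native)
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ids <- character(0); tiers <- character(0)
  structures <- list(); dock <- numeric(0)
  trans <- numeric(0); rot_deg <- numeric(0)
  for (tier in names(config$n_per_tier)) {
    rng <- config$tiers[[tier]]
    for (k in seq_len(config$n_per_tier[[tier]])) {
      id <- sprintf("%s_%03d", tolower(tier), k)
      tmag <- stats::runif(1, rng$trans[1], rng$trans[2])
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ang <- stats::runif(1, rng$rot[1], rng$rot[2]) * pi / 180
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      rot <- rotation_about_axis(axis, ang)
      dec <- transform_role(native, "ligand", rot = rot, shift = tmag * dir)
      ids <- c(ids, id); tiers <- c(tiers, tier)
      trans <- c(trans, tmag); rot_deg <- c(rot_deg, ang * 180 / pi)
      structures[[id]] <- dec
      dock <- c(dock, com_distance(coarse_grain(dec)))
    }
  }
  out <- decoy_set(ids, dock, structures = structures, tier = tiers)
  out$table$trans_A <- trans
  out$table$rot_deg <- rot_deg
  out
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

#' Synthesise window samples from an analytically known radial potential
#'
#' Produces the force profile a perfect constraint-force measurement of the
#' potential would give: mean force -dU/dr at each scheduled distance, plus
#' the radial 2 k_B T / r term when `include_jacobian` is on (mirroring raw
#' constraint forces), plus optional Gaussian noise.
#'
#' @param schedule A [make_schedule()] object.
#' @param potential A [radial_potential()].
#' @param noise_sd Gaussian noise standard deviation (kJ/mol/nm).
#' @param seed RNG seed.
#' @param temperature Temperature (K) for the Jacobian term.
#' @param include_jacobian Add + 2 k_B T / r (default `TRUE`).
#' @param replicate Replicate id stored in the output.
#' @return data.frame of window samples (`r_nm`, `mean_force_kJ_mol_nm`,
#'   `stderr`, `n_eff`, `n_samples`, `replicate`, `seed`).
#' @export
make_force_profiles <- function(schedule, potential, noise_sd = 0, seed = 1,
                                temperature = 300, include_jacobian = TRUE,
                                replicate = 1L) {
  stopifnot(inherits(schedule, "window_schedule"),
            inherits(potential, "radial_potential"), noise_sd >= 0)
  set.seed(as.integer(seed))
  r <- schedule$distances
  f <- -potential$dudr(r)
  if (include_jacobian) f <- f + 2 * kB * temperature / r
  if (noise_sd > 0) f <- f + stats::rnorm(length(r), 0, noise_sd)
  out <- data.frame(r_nm = r, mean_force_kJ_mol_nm = f,
                    stderr = rep(noise_sd, length(r)),
                    n_eff = 1L, n_samples = 1L,
                    replicate = as.integer(replicate),
                    seed = as.integer(seed))
  class(out) <- c("window_sample", "data.frame")
  out
}
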