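#' Residue class table for coarse-graining
#'
#' Each of the 20 standard amino acids is assigned one of four particle
#' classes -- polar (P), nonpolar (N), apolar (C) or charged (Q) -- and an
#' integer charge. The assignment follows hydropathy and protonation state
#' at pH 7 (histidine neutral polar). The table is a default, not a claim
#' about any particular published mapping: pass a modified copy to
#' `coarse_grain()` to change it.
#'
#' @return data.frame with columns `resname`, `type`, `charge`.
#' @export
residue_classes <- function() {
  data.frame(
    resname = c("ASP", "GLU", "LYS", "ARG",
                "SER", "THR", "ASN", "GLN", "HIS", "TYR", "TRP", "GLY",
                "ALA", "CYS", "MET", "PRO",
                "VAL", "LEU", "ILE", "PHE"),
    type = c(rep("Q", 4), rep("P", 8), rep("N", 4), rep("C", 4)),
    charge = c(-1L, -1L, 1L, 1L, rep(0L, 16)),
    stringsAsFactors = FALSE
  )
}

# heavy-atom element masses (amu)
element_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, SE = 78.971)

#' Coarse-grain a complex to one bead per residue
#'
#' Each residue becomes a single interaction centre at the unweighted
#' centroid of its heavy atoms, carrying the summed heavy-atom mass and a
#' particle class/charge from the residue table. Bead positions are in nm
#' (the all-atom structure is in Angstrom); each bead belongs to the rigid
#' group of its chain's role.
#'
#' @param structure A `dock_structure`.
#' @param class_table Residue class table, see [residue_classes()].
#' @param strict If `TRUE` (default) a residue name absent from the table is
#'   an error; if `FALSE` such residues are skipped with a warning.
#' @return A `bead_model`: data.frame with columns `chain`, `resid`,
#'   `resname`, `x`, `y`, `z` (nm), `mass` (amu), `type` (P/N/C/Q),
#'   `charge`, `group` (`"receptor"`/`"ligand"`).
#' @examples
#' \donttest{
#' m <- coarse_grain(make_native(synth_config(seed = 1)))
#' table(m$type)
#' }
#' @export
coarse_grain <- function(structure, class_table = residue_classes(),
                         strict = TRUE) {
  validate_structure(structure)
  a <- structure$atoms
  known <- a$resname %in% class_table$resname
  if (!all(known)) {
    bad <- unique(a$resname[!known])
    if (strict) stop("non-standard residue(s): ", paste(bad, collapse = ", "))
    warning("skipping non-standard residue(s): ", paste(bad, collapse = ", "))
    a <- a[known, , drop = FALSE]
    if (nrow(a) == 0) stop("no standard residues left")
  }
  mknown <- a$element %in% names(element_masses)
  if (!all(mknown))
    stop("unknown element(s): ", paste(unique(a$element[!mknown]), collapse = ", "))

  key <- paste(a$chain, a$resid, sep = "\r")
  ukey <- unique(key)
  f <- factor(key, levels = ukey)
  first <- !duplicated(key)
  beads <- data.frame(
    chain = a$chain[first],
    resid = a$resid[first],
    resname = a$resname[first],
    x = as.numeric(tapply(a$x, f, mean)) / 10,
    y = as.numeric(tapply(a$y, f, mean)) / 10,
    z = as.numeric(tapply(a$z, f, mean)) / 10,
    mass = as.numeric(tapply(element_masses[a$element], f, sum)),
    stringsAsFactors = FALSE
  )
  i <- match(beads$resname, class_table$resname)
  beads$type <- class_table$type[i]
  beads$charge <- as.integer(class_table$charge[i])
  beads$group <- unname(structure$roles[beads$chain])
  class(beads) <- c("bead_model", "data.frame")
  validate_bead_model(beads)
  beads
}

validate_bead_model <- function(m) {
  stopifnot(inherits(m, "bead_model"))
  if (!all(is.finite(c(m$x, m$y, m$z)))) stop("non-finite bead positions")
  if (!all(m$type %in% c("P", "N", "C", "Q"))) stop("invalid bead type")
  if (!all(m$group %in% c("receptor", "ligand"))) stop("invalid rigid group")
  if (any(m$mass <= 0)) stop("non-positive bead mass")
  invisible(m)
}

#' Centre of mass of a rigid group
#'
#' @param model A `bead_model`.
#' @param group `"receptor"` or `"ligand"`.
#' @return Numeric length-3 vector (nm).
#' @export
center_of_mass <- function(model, group = c("receptor", "ligand")) {
  group <- match.arg(group)
  sub <- model[model$group == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty rigid group: ", group)
  w <- sub$mass / sum(sub$mass)
  c(sum(w * sub$x), sum(w * sub$y), sum(w * sub$z))
}

#' Receptor-ligand centre-of-mass distance of a bead model
#'
#' The docked COM distance (`dock_COM`) that anchors the window schedule.
#'
#' @param model A `bead_model`.
#' @return Distance in nm.
#' @export
com_distance <- function(model) {
  sqrt(sum((center_of_mass(model, "ligand") -
              center_of_mass(model, "receptor"))^2))
}

#' @export
print.bead_model <- function(x, ...) {
  cat("Coarse-grained bead model:", nrow(x), "beads\n")
  cat("  receptor:", sum(x$group == "receptor"),
      " ligand:", sum(x$group == "ligand"), "\n")
  cat("  types:", paste(names(table(x$type)), table(x$type),
                        sep = "=", collapse = " "), "\n")
  cat(sprintf("  COM distance: %.3f nm\n", com_distance(x)))
  invisible(x)
}
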