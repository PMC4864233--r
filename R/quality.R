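backbone_atoms <- c("N", "CA", "C", "O")

#' Residue-residue contacts across the interface
#'
#' A receptor residue and a ligand residue are in contact when any pair of
#' their heavy atoms lies within the cutoff (CAPRI convention: 5 Angstrom).
#'
#' @param receptor,ligand Atom data.frames (as in `dock_structure$atoms` or
#'   from [split_roles()]); both non-empty.
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @return Character vector of contact keys
#'   `"chain:resid--chain:resid"` (receptor first), sorted.
#' @export
residue_contacts <- function(receptor, ligand, cutoff = 5.0) {
  stopifnot(nrow(receptor) > 0, nrow(ligand) > 0, cutoff > 0)
  a <- as.matrix(receptor[, c("x", "y", "z")])
  b <- as.matrix(ligand[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(character(0))
  rk <- paste(receptor$chain, receptor$resid, sep = ":")[hit[, 1]]
  lk <- paste(ligand$chain, ligand$resid, sep = ":")[hit[, 2]]
  sort(unique(paste(rk, lk, sep = "--")))
}

#' Fraction of native contacts reproduced by a decoy (CAPRI Recall)
#'
#' @param decoy_contacts,native_contacts Contact sets from
#'   [residue_contacts()]; the native set must be non-empty.
#' @return Fraction in [0, 1].
#' @export
fnat <- function(decoy_contacts, native_contacts) {
  if (length(native_contacts) == 0) stop("native contact set is empty")
  length(intersect(decoy_contacts, native_contacts)) / length(unique(native_contacts))
}

#' Fraction of a decoy's contacts that are non-native
#'
#' Precision in the CAPRI sense is 1 - fnonnat. A decoy with no contacts
#' has fnonnat 0 by convention.
#'
#' @inheritParams fnat
#' @return Fraction in [0, 1].
#' @export
fnonnat <- function(decoy_contacts, native_contacts) {
  if (length(decoy_contacts) == 0) return(0)
  length(setdiff(decoy_contacts, native_contacts)) / length(unique(decoy_contacts))
}

# matched backbone coordinate pairs between decoy and native for a set of
# residue keys; residues/atoms present in only one structure are dropped
matched_backbone <- function(decoy, native, keys = NULL) {
  pick <- function(a) {
    a <- a[a$atom %in% backbone_atoms, , drop = FALSE]
    if (!is.null(keys)) a <- a[paste(a$chain, a$resid, sep = ":") %in% keys, , drop = FALSE]
    a
  }
  d <- pick(decoy$atoms)
  n <- pick(native$atoms)
  kd <- paste(d$chain, d$resid, d$atom, sep = "\r")
  kn <- paste(n$chain, n$resid, n$atom, sep = "\r")
  if (anyDuplicated(kd) || anyDuplicated(kn))
    stop("duplicate backbone atoms; cannot establish correspondence")
  common <- intersect(kd, kn)
  if (length(common) == 0) stop("no matching backbone atoms")
  list(decoy = as.matrix(d[match(common, kd), c("x", "y", "z")]),
       native = as.matrix(n[match(common, kn), c("x", "y", "z")]),
       keys = common)
}

# least-squares superposition of decoy onto native using a fit subset,
# returning transformed decoy coordinate matrix for the rmsd subset
superpose_rmsd <- function(decoy_fit, native_fit, decoy_rmsd, native_rmsd) {
  nfit <- nrow(native_fit)
  fixed <- as.vector(t(native_fit))
  mobile <- as.vector(t(rbind(decoy_fit, decoy_rmsd)))
  moved <- bio3d::fit.xyz(fixed, mobile,
                          fixed.inds = seq_len(3 * nfit),
                          mobile.inds = seq_len(3 * nfit))
  moved <- matrix(moved, ncol = 3, byrow = TRUE)
  moved_rmsd <- moved[(nfit + 1):nrow(moved), , drop = FALSE]
  sqrt(mean(rowSums((moved_rmsd - native_rmsd)^2)))
}

#' Ligand RMSD after receptor superposition (L-rms)
#'
#' The decoy receptor backbone is least-squares fitted onto the native
#' receptor backbone; the RMSD is then taken over the ligand backbone atoms
#' without re-fitting.
#'
#' @param decoy,native `dock_structure` objects of the same target (same
#'   chain/residue/atom naming).
#' @return RMSD in Angstrom.
#' @export
l_rms <- function(decoy, native) {
  validate_structure(decoy); validate_structure(native)
  rrole <- function(s) names(s$roles)[s$roles == "receptor"]
  rec_keys <- with(native$atoms, unique(paste(chain, resid, sep = ":")[chain %in% rrole(native)]))
  lig_keys <- with(native$atoms, unique(paste(chain, resid, sep = ":")[!(chain %in% rrole(native))]))
  fit <- matched_backbone(decoy, native, rec_keys)
  rms <- matched_backbone(decoy, native, lig_keys)
  superpose_rmsd(fit$decoy, fit$native, rms$decoy, rms$native)
}

# residue keys of the native interface: any heavy atom within cutoff of the
# opposite role
interface_keys <- function(native, cutoff = 10.0) {
  parts <- split_roles(native)
  a <- as.matrix(parts$receptor[, c("x", "y", "z")])
  b <- as.matrix(parts$ligand[, c("x", "y", "z")])
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  hit <- d2 <= cutoff^2
  rk <- paste(parts$receptor$chain, parts$receptor$resid, sep = ":")
  lk <- paste(parts$ligand$chain, parts$ligand$resid, sep = ":")
  sort(unique(c(rk[apply(hit, 1, any)], lk[apply(hit, 2, any)])))
}

#' Interface RMSD (I-rms)
#'
#' Interface residues are taken from the native structure (any heavy atom
#' within `interface_cutoff` of the other chain, CAPRI convention:
#' 10 Angstrom). The decoy is superposed on the native over the interface
#' backbone atoms and the RMSD is computed over that same atom set.
#'
#' @inheritParams l_rms
#' @param interface_cutoff Heavy-atom cutoff defining interface residues
#'   (Angstrom).
#' @return RMSD in Angstrom.
#' @export
i_rms <- function(decoy, native, interface_cutoff = 10.0) {
  validate_structure(decoy); validate_structure(native)
  keys <- interface_keys(native, interface_cutoff)
  if (length(keys) == 0) stop("native structure has no interface residues")
  m <- matched_backbone(decoy, native, keys)
  superpose_rmsd(m$decoy, m$native, m$decoy, m$native)
}

#' CAPRI four-tier classification
#'
#' Applies the CAPRI quality rules in order High, Medium, Acceptable,
#' Incorrect; within each rule "and" binds tighter than "or", and the first
#' matching tier wins:
#' \itemize{
#' \item High: fnat >= 0.5 and L-rms <= 1.0 and I-rms <= 1.0
#' \item Medium: (fnat >= 0.5 and L-rms > 1.0 and I-rms > 1.0) or
#'   (0.3 <= fnat < 0.5 and (L-rms <= 5.0 or I-rms <= 2.0))
#' \item Acceptable: (fnat >= 0.3 and L-rms > 5.0 and I-rms > 2.0) or
#'   (0.1 <= fnat < 0.3 and (L-rms <= 10.0 or I-rms <= 4.0))
#' \item Incorrect: everything else (fnat < 0.1, or L-rms > 10.0 and
#'   I-rms > 4.0).
#' }
#' Note the Medium and Acceptable "or" branches carry no upper RMSD bounds;
#' the official CAPRI criteria differ in that detail, and this function
#' follows the rule set as stated above with ordered evaluation.
#'
#' @param fnat,l_rms,i_rms Numeric vectors (recycled to a common length):
#'   fraction of native contacts, ligand RMSD and interface RMSD (Angstrom).
#' @return Character vector of categories
#'   (`"High"`, `"Medium"`, `"Acceptable"`, `"Incorrect"`).
#' @examples
#' classify_capri(c(0.5, 0.4, 0.05), c(1, 8, 0), c(1, 1.5, 0))
#' @export
classify_capri <- function(fnat, l_rms, i_rms) {
  n <- max(length(fnat), length(l_rms), length(i_rms))
  f <- rep_len(fnat, n); l <- rep_len(l_rms, n); i <- rep_len(i_rms, n)
  stopifnot(all(f >= 0 & f <= 1), all(l >= 0), all(i >= 0))
  out <- rep("Incorrect", n)
  high <- f >= 0.5 & l <= 1.0 & i <= 1.0
  med <- (f >= 0.5 & l > 1.0 & i > 1.0) |
    (f >= 0.3 & f < 0.5 & (l <= 5.0 | i <= 2.0))
  acc <- (f >= 0.3 & l > 5.0 & i > 2.0) |
    (f >= 0.1 & f < 0.3 & (l <= 10.0 | i <= 4.0))
  out[acc] <- "Acceptable"
  out[med] <- "Medium"
  out[high] <- "High"
  out
}

#' Full quality assessment of one decoy against the native structure
#'
#' @inheritParams l_rms
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom).
#' @param interface_cutoff Interface-residue cutoff (Angstrom).
#' @return One-row data.frame (`quality_record`): `fnat`, `fnonnat`,
#'   `lrms_A`, `irms_A`, `category`.
#' @export
assess_decoy <- function(decoy, native, contact_cutoff = 5.0,
                         interface_cutoff = 10.0) {
  pn <- split_roles(native)
  pd <- split_roles(decoy)
  nat <- residue_contacts(pn$receptor, pn$ligand, contact_cutoff)
  dec <- residue_contacts(pd$receptor, pd$ligand, contact_cutoff)
  fn <- fnat(dec, nat)
  fnn <- fnonnat(dec, nat)
  lr <- l_rms(decoy, native)
  ir <- i_rms(decoy, native, interface_cutoff)
  out <- data.frame(fnat = fn, fnonnat = fnn, lrms_A = lr, irms_A = ir,
                    category = classify_capri(fn, lr, ir),
                    stringsAsFactors = FALSE)
  class(out) <- c("quality_record", "data.frame")
  out
}
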