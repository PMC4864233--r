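#' Read a two-chain complex from a PDB file
#'
#' Parses fixed-column `ATOM` records (first model only, hydrogens and
#' `HETATM` records dropped) and labels each chain as receptor or ligand.
#' For alternate locations the highest-occupancy copy is kept (ties: first
#' encountered); insertion codes are appended to the residue key.
#'
#' @param path Path to a PDB file.
#' @param receptor_chains Character vector of chain identifiers forming the
#'   receptor.
#' @param ligand_chains Character vector of chain identifiers forming the
#'   ligand.
#' @return A `dock_structure`: list with `atoms` (data.frame with columns
#'   `chain`, `resno`, `ins`, `resid`, `resname`, `atom`, `element`, `x`,
#'   `y`, `z`; coordinates in Angstrom) and `roles` (named character vector
#'   mapping chain id to `"receptor"` or `"ligand"`).
#' @examples
#' \donttest{
#' cfg <- synth_config(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(make_native(cfg), f)
#' s <- read_pdb(f, receptor_chains = "A", ligand_chains = "B")
#' nrow(s$atoms)
#' }
#' @export
read_pdb <- function(path, receptor_chains, ligand_chains) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  receptor_chains <- as.character(receptor_chains)
  ligand_chains <- as.character(ligand_chains)
  if (length(intersect(receptor_chains, ligand_chains)) > 0)
    stop("a chain cannot be both receptor and ligand")
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | trimws(elem) == ""
  if (any(bad))
    elem[bad] <- substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", at$elety[bad])), 1, 1)
  elem <- toupper(trimws(elem))
  keep <- elem != "H" & elem != "D" & at$chain %in% c(receptor_chains, ligand_chains)
  at <- at[keep, , drop = FALSE]
  elem_all <- elem[keep]
  for (ch in c(receptor_chains, ligand_chains))
    if (!any(at$chain == ch)) stop("chain '", ch, "' not present in ", path)
  if (nrow(at) == 0) stop("no atoms left after filtering")

  ins <- at$insert
  ins[is.na(ins)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  # alternate locations: keep the highest-occupancy copy, ties -> first
  key <- paste(at$chain, at$resno, ins, trimws(at$elety), sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(-occ, seq_along(key))
    sel <- sort(ord[!duplicated(key[ord])])
    at <- at[sel, , drop = FALSE]
    elem_all <- elem_all[sel]
    ins <- ins[sel]
  }

  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    ins = ins,
    resid = paste0(at$resno, ins),
    resname = toupper(trimws(at$resid)),
    atom = trimws(at$elety),
    element = elem_all,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  roles <- c(
    stats::setNames(rep("receptor", length(receptor_chains)), receptor_chains),
    stats::setNames(rep("ligand", length(ligand_chains)), ligand_chains)
  )
  new_structure(atoms, roles)
}

new_structure <- function(atoms, roles) {
  s <- structure(list(atoms = atoms, roles = roles), class = "dock_structure")
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  stopifnot(inherits(s, "dock_structure"))
  a <- s$atoms
  if (nrow(a) == 0) stop("structure has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite coordinates")
  if (!all(a$chain %in% names(s$roles))) stop("atom chain without a role")
  if (!any(s$roles == "receptor") || !any(s$roles == "ligand"))
    stop("need at least one receptor and one ligand chain")
  invisible(s)
}

#' Write a structure as fixed-column PDB ATOM records
#'
#' Chains are written in the order they appear in the structure; occupancy
#' 1.00 and B-factor 0.00 throughout.
#'
#' @param structure A `dock_structure`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  validate_structure(structure)
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  lines <- sprintf(
    "ATOM  %5d %s%-3s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000,
    ifelse(nchar(a$atom) >= 4, "", " "),
    substr(a$atom, 1, 4),
    substr(a$resname, 1, 3),
    substr(a$chain, 1, 1),
    a$resno %% 10000,
    substr(paste0(a$ins, " "), 1, 1),
    a$x, a$y, a$z, 1, 0,
    substr(a$element, 1, 2)
  )
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Split a complex into its receptor and ligand parts
#'
#' @param structure A `dock_structure`.
#' @return List with elements `receptor` and `ligand`, each a data.frame of
#'   atoms (same columns as `structure$atoms`).
#' @export
split_roles <- function(structure) {
  validate_structure(structure)
  role <- structure$roles[structure$atoms$chain]
  list(
    receptor = structure$atoms[role == "receptor", , drop = FALSE],
    ligand = structure$atoms[role == "ligand", , drop = FALSE]
  )
}

#' @export
print.dock_structure <- function(x, ...) {
  role <- x$roles[x$atoms$chain]
  cat("Receptor/ligand complex:", nrow(x$atoms), "heavy atoms\n")
  for (r in c("receptor", "ligand")) {
    ch <- names(x$roles)[x$roles == r]
    nres <- length(unique(paste(x$atoms$chain, x$atoms$resid)[role == r]))
    cat(sprintf("  %-8s chain(s) %s: %d residues, %d atoms\n",
                r, paste(ch, collapse = ","), nres, sum(role == r)))
  }
  invisible(x)
}

# apply a rigid transform (3x3 rotation + translation, Angstrom) to the
# atoms of one role; used by the decoy generator
transform_role <- function(structure, role, rot = diag(3), shift = c(0, 0, 0),
                           about = NULL) {
  validate_structure(structure)
  idx <- which(structure$roles[structure$atoms$chain] == role)
  xyz <- as.matrix(structure$atoms[idx, c("x", "y", "z")])
  if (is.null(about)) about <- colMeans(xyz)
  xyz <- sweep(xyz, 2, about) %*% t(rot)
  xyz <- sweep(xyz, 2, about + shift, "+")
  structure$atoms[idx, c("x", "y", "z")] <- xyz
  structure
}
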