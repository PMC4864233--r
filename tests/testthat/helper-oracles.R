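# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

KB_REF <- 0.0083144621

# Kabsch superposition via SVD: rotate+translate `mobile` onto `fixed`
# (n x 3 matrices), return the moved coordinates.
oracle_kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  H <- t(sweep(mobile, 2, cm)) %*% sweep(fixed, 2, cf)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cf, "+")
}

oracle_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# brute-force all-pairs residue contact scan
oracle_contacts <- function(rec, lig, cutoff = 5) {
  out <- character(0)
  rkeys <- unique(paste(rec$chain, rec$resid, sep = ":"))
  lkeys <- unique(paste(lig$chain, lig$resid, sep = ":"))
  for (rk in rkeys) {
    ra <- rec[paste(rec$chain, rec$resid, sep = ":") == rk, ]
    for (lk in lkeys) {
      la <- lig[paste(lig$chain, lig$resid, sep = ":") == lk, ]
      hit <- FALSE
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(la))) {
        d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                    (ra$z[i] - la$z[j])^2)
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) out <- c(out, paste(rk, lk, sep = "--"))
    }
  }
  sort(out)
}

# independently coded CAPRI truth table (first-match-wins, and over or)
oracle_classify <- function(f, l, i) {
  if (f >= 0.5 && l <= 1.0 && i <= 1.0) return("High")
  if ((f >= 0.5 && l > 1.0 && i > 1.0) ||
      (f >= 0.3 && f < 0.5 && (l <= 5.0 || i <= 2.0))) return("Medium")
  if ((f >= 0.3 && l > 5.0 && i > 2.0) ||
      (f >= 0.1 && f < 0.3 && (l <= 10.0 || i <= 4.0))) return("Acceptable")
  "Incorrect"
}

# brute-force binding free energy: lowest PMF value minus the highest PMF
# at any strictly larger distance (0 when the minimum is last)
oracle_dgoff <- function(pmf) {
  n <- length(pmf)
  imin <- seq_len(n)[pmf == min(pmf)][1]
  if (imin == n) return(0)
  pmf[imin] - max(pmf[(imin + 1):n])
}

# selection-sort ranking oracle: repeatedly pick the lowest remaining score,
# ties by id
oracle_rank <- function(scores) {
  ids <- names(scores)
  out <- character(0)
  while (length(ids) > 0) {
    s <- scores[ids]
    lo <- ids[s == min(s)]
    pick <- sort(lo)[1]
    out <- c(out, pick)
    ids <- setdiff(ids, pick)
  }
  out
}

# small helpers for building structures by hand
make_atoms <- function(chain, resid, atom, x, y, z, resname = "ALA",
                       element = NULL) {
  if (is.null(element)) element <- substr(atom, 1, 1)
  data.frame(chain = chain, resno = suppressWarnings(as.integer(resid)),
             ins = "", resid = as.character(resid), resname = resname,
             atom = atom, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

tiny_complex <- function() {
  # two single-residue chains, 4 heavy atoms each
  a <- make_atoms("A", 1, c("N", "CA", "C", "O"),
                  c(0, 1.5, 3, 3.2), c(0, 0.5, 0, 1.6), c(0, 0, 0, 0))
  b <- make_atoms("B", 1, c("N", "CA", "C", "O"),
                  c(0, 1.5, 3, 3.2), c(4, 4.5, 4, 5.6), c(0.5, 0.5, 0.5, 0.5))
  cgdock:::new_structure(rbind(a, b), c(A = "receptor", B = "ligand"))
}

free_params <- function(n_steps = 2e4, temperature = 300, ...) {
  e0 <- matrix(0, 4, 4, dimnames = list(c("P", "N", "C", "Q"),
                                        c("P", "N", "C", "Q")))
  sim_params(n_steps = n_steps, temperature = temperature, epsilon = e0,
             coul_pref = 0, ...)
}

uncharged <- function(model) { model$charge <- 0L; model }

default_native <- function(seed = 1, ...) make_native(synth_config(seed = seed, ...))
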