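kB <- 0.0083144621 # kJ/mol/K

#' Build the distance-window schedule for a docked conformation
#'
#' Starting from the decoy's receptor-ligand COM distance `dock_com`, the
#' schedule holds 23 inner distances spaced 0.05 nm apart beginning 0.1 nm
#' below `dock_com`, plus 9 outer distances spaced 0.1 nm apart beginning
#' 1.15 nm beyond `dock_com` (32 windows in all).
#'
#' @param dock_com Docked COM distance in nm (must exceed 0.1 nm so that no
#'   window is at a non-positive distance).
#' @return A `window_schedule`: list with `dock_com` and `distances`
#'   (strictly increasing, nm).
#' @examples
#' s <- make_schedule(3.0)
#' length(s$distances) # 32
#' @export
make_schedule <- function(dock_com) {
  stopifnot(is.numeric(dock_com), length(dock_com) == 1)
  if (dock_com <= 0.1)
    stop("dock_com must exceed 0.1 nm; got ", dock_com)
  inner <- dock_com - 0.1 + 0.05 * (0:22)
  outer <- dock_com + 1.15 + 0.1 * (0:8)
  structure(list(dock_com = dock_com, distances = c(inner, outer)),
            class = "window_schedule")
}

#' @export
print.window_schedule <- function(x, ...) {
  cat(sprintf("Window schedule: %d distances, %.3f - %.3f nm (dock_COM %.3f nm)\n",
              length(x$distances), min(x$distances), max(x$distances), x$dock_com))
  invisible(x)
}

#' Integrate a force profile into a potential of mean force
#'
#' Trapezoidal integration of the mean constraint force from each window
#' distance out to the largest one, which is the zero reference. With the
#' Jacobian correction on (default), the radial entropic term 2 k_B T / r
#' is subtracted from every force sample first, so that non-interacting
#' bodies give a flat profile. Window standard errors, when present, are
#' propagated linearly through the quadrature weights.
#'
#' @param samples data.frame of window samples for one replicate with
#'   columns `r_nm` and `mean_force_kJ_mol_nm` (optionally `stderr`),
#'   sorted ascending in `r_nm`, at least two windows, no duplicates.
#' @param temperature Temperature in K used for the Jacobian term.
#' @param jacobian Logical; subtract the 2 k_B T / r term (default `TRUE`).
#' @return A `pmf_profile`: data.frame with `r_nm`, `pmf_kJ_mol` and (when
#'   input errors exist) `se_kJ_mol`; attributes `temperature`, `jacobian`.
#' @export
integrate_pmf <- function(samples, temperature = 300, jacobian = TRUE) {
  stopifnot(is.data.frame(samples),
            all(c("r_nm", "mean_force_kJ_mol_nm") %in% names(samples)))
  r <- samples$r_nm
  n <- length(r)
  if (n < 2) stop("need at least two windows")
  if (any(duplicated(r))) stop("duplicate window distances")
  if (is.unsorted(r, strictly = TRUE)) stop("windows must be sorted ascending in r")
  g <- samples$mean_force_kJ_mol_nm
  if (jacobian) g <- g - 2 * kB * temperature / r
  pmf <- numeric(n)
  for (i in (n - 1):1)
    pmf[i] <- pmf[i + 1] + 0.5 * (g[i] + g[i + 1]) * (r[i + 1] - r[i])
  out <- data.frame(r_nm = r, pmf_kJ_mol = pmf)
  if ("stderr" %in% names(samples) && all(is.finite(samples$stderr))) {
    se <- numeric(n)
    dr <- diff(r)
    for (i in seq_len(n - 1)) {
      # quadrature weight of each force sample in PMF_i (linear propagation)
      w <- numeric(n)
      w[i] <- 0.5 * dr[i]
      w[n] <- w[n] + 0.5 * dr[n - 1]
      if (n - 1 >= i + 1)
        for (j in (i + 1):(n - 1)) w[j] <- 0.5 * (r[j + 1] - r[j - 1])
      se[i] <- sqrt(sum((w * samples$stderr)^2))
    }
    out$se_kJ_mol <- se
  }
  structure(out, class = c("pmf_profile", "data.frame"),
            temperature = temperature, jacobian = jacobian)
}

#' Extract the binding free energy from a PMF profile
#'
#' The binding free energy is the difference between the lowest PMF value
#' (at `r_min`; ties resolved to the smallest distance) and the highest PMF
#' value at any larger distance (`r_max`; ties resolved to the largest
#' distance), so it is always non-positive. If the minimum sits at the
#' largest scheduled distance the profile has no dissociation barrier in
#' range and the value is 0 (flagged degenerate).
#'
#' @param profile A [integrate_pmf()] result (or data.frame with `r_nm`,
#'   `pmf_kJ_mol`).
#' @return A `dg_off`: list with `value` (kJ/mol), `r_min`, `r_max` (nm),
#'   `replicate`, `per_replicate`, `degenerate`.
#' @export
extract_dgoff <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("r_nm", "pmf_kJ_mol") %in% names(profile)))
  r <- profile$r_nm
  p <- profile$pmf_kJ_mol
  imin <- which(p == min(p))[1] # ties -> smallest r (input sorted ascending)
  if (imin == length(p)) {
    dg <- list(value = 0, r_min = r[imin], r_max = r[imin],
               replicate = "single", per_replicate = NULL, degenerate = TRUE)
  } else {
    later <- (imin + 1):length(p)
    pm <- max(p[later])
    imax <- later[max(which(p[later] == pm))] # ties -> largest r
    dg <- list(value = p[imin] - pm, r_min = r[imin], r_max = r[imax],
               replicate = "single", per_replicate = NULL, degenerate = FALSE)
  }
  class(dg) <- "dg_off"
  dg
}

#' Average binding free energies over replicates
#'
#' Averaging happens at the level of the per-replicate binding free
#' energies (not of the underlying forces); the individual values are
#' carried along.
#'
#' @param per_replicate List of `dg_off` objects (or numeric vector of
#'   values), one per replicate, at least one.
#' @return A `dg_off` with `replicate = "mean"` and `per_replicate` set.
#' @export
average_dgoff <- function(per_replicate) {
  if (length(per_replicate) == 0) stop("no replicate values")
  vals <- if (is.numeric(per_replicate)) as.numeric(per_replicate)
          else vapply(per_replicate, function(d) d$value, numeric(1))
  rmin <- rmax <- NA_real_
  if (!is.numeric(per_replicate)) {
    rmin <- mean(vapply(per_replicate, function(d) d$r_min, numeric(1)))
    rmax <- mean(vapply(per_replicate, function(d) d$r_max, numeric(1)))
  }
  structure(list(value = mean(vals), r_min = rmin, r_max = rmax,
                 replicate = "mean", per_replicate = vals,
                 degenerate = FALSE),
            class = "dg_off")
}

#' @export
print.dg_off <- function(x, ...) {
  cat(sprintf("Binding free energy: %.3f kJ/mol", x$value))
  if (is.finite(x$r_min)) cat(sprintf("  (r_min %.3f nm, r_max %.3f nm)", x$r_min, x$r_max))
  cat("\n")
  if (!is.null(x$per_replicate))
    cat("  replicates:", paste(sprintf("%.3f", x$per_replicate), collapse = ", "), "\n")
  if (isTRUE(x$degenerate)) cat("  degenerate: minimum at the largest distance\n")
  invisible(x)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d windows, %.3f - %.3f nm (T = %g K, Jacobian %s)\n",
              nrow(x), min(x$r_nm), max(x$r_nm), attr(x, "temperature"),
              if (isTRUE(attr(x, "jacobian"))) "on" else "off"))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  plot(x$r_nm, x$pmf_kJ_mol, type = "b", pch = 16,
       xlab = "COM distance (nm)", ylab = "PMF (kJ/mol)", ...)
  if ("se_kJ_mol" %in% names(x))
    graphics::arrows(x$r_nm, x$pmf_kJ_mol - x$se_kJ_mol,
                     x$r_nm, x$pmf_kJ_mol + x$se_kJ_mol,
                     angle = 90, code = 3, length = 0.02)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
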