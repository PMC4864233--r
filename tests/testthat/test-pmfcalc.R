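test_that("the window schedule reproduces the printed series", {
  s <- make_schedule(3.0)
  expect_length(s$distances, 32)
  expect_equal(s$distances[1], 2.90)
  expect_equal(s$distances[23], 4.00)
  expect_equal(s$distances[24], 4.15)
  expect_equal(s$distances[32], 4.95)
  expect_error(make_schedule(0.05), "exceed")
})

test_that("schedule structure holds for any valid dock_COM", {
  set.seed(1)
  for (d in c(runif(20, 0.11, 10), 0.11, 0.2)) {
    s <- make_schedule(d)
    expect_length(s$distances, 32)
    expect_true(all(s$distances > 0))
    expect_true(all(diff(s$distances) > 0))
    gaps <- round(diff(s$distances), 10)
    expect_equal(min(gaps), 0.05)
    expect_equal(gaps[23], 0.15) # gap between the inner and outer series
    expect_equal(unique(gaps[24:31]), 0.10)
  }
})

test_that("zero forces integrate to an identically zero PMF", {
  sam <- data.frame(r_nm = seq(1, 2, 0.1), mean_force_kJ_mol_nm = 0)
  p <- integrate_pmf(sam, jacobian = FALSE)
  expect_equal(p$pmf_kJ_mol, rep(0, 11))
  expect_equal(p$pmf_kJ_mol[nrow(p)], 0) # reference at the largest distance
})

test_that("harmonic forces integrate back to the analytic potential", {
  pot <- radial_potential("harmonic", depth = 30, r0 = 3.0, width = 0.8)
  sch <- make_schedule(3.0)
  sam <- make_force_profiles(sch, pot, noise_sd = 0, include_jacobian = FALSE)
  p <- integrate_pmf(sam, jacobian = FALSE)
  truth <- pot$u(p$r_nm) - pot$u(max(p$r_nm))
  # trapezoid is exact for a linear integrand; 2% of well depth is the bound
  expect_lt(max(abs(p$pmf_kJ_mol - truth)), 0.02 * 30)
  dg <- extract_dgoff(p)
  expect_equal(dg$value, pot$u(3.0) - pot$u(max(p$r_nm)), tolerance = 1e-8)
  expect_equal(dg$r_min, 3.0)
  expect_equal(dg$r_max, max(p$r_nm))
})

test_that("input validation catches unsorted and duplicated windows", {
  sam <- data.frame(r_nm = c(1, 1, 2), mean_force_kJ_mol_nm = 0)
  expect_error(integrate_pmf(sam), "duplicate")
  sam <- data.frame(r_nm = c(2, 1), mean_force_kJ_mol_nm = 0)
  expect_error(integrate_pmf(sam), "sorted")
  expect_error(integrate_pmf(data.frame(r_nm = 1, mean_force_kJ_mol_nm = 0)),
               "two windows")
})

test_that("binding free energy extraction follows the min/later-max rule", {
  mkprof <- function(pmf) data.frame(r_nm = seq_along(pmf), pmf_kJ_mol = pmf)
  expect_equal(extract_dgoff(mkprof(rep(0, 5)))$value, 0)
  d <- extract_dgoff(mkprof(seq(-50, 0, length.out = 6)))
  expect_equal(d$value, -50)
  expect_equal(d$r_max, 6)
  d <- extract_dgoff(mkprof(c(-10, -30, -5, 5, 0)))
  expect_equal(d$value, -35)
  expect_equal(d$r_min, 2)
  expect_equal(d$r_max, 4)
  # degenerate: minimum at the last point
  d <- extract_dgoff(mkprof(c(3, 2, 1, 0, -1)))
  expect_equal(d$value, 0)
  expect_true(d$degenerate)
  # ties: smallest r for the minimum, largest r for the maximum
  d <- extract_dgoff(mkprof(c(-5, -5, 2, 2, 0)))
  expect_equal(d$r_min, 1)
  expect_equal(d$r_max, 4)
})

test_that("extraction agrees with the brute-force oracle on random profiles", {
  set.seed(7)
  for (i in 1:200) {
    pmf <- round(rnorm(sample(3:12, 1), 0, 20), 2)
    pmf[length(pmf)] <- 0
    d <- extract_dgoff(data.frame(r_nm = seq_along(pmf), pmf_kJ_mol = pmf))
    expect_equal(d$value, oracle_dgoff(pmf))
    expect_lte(d$value, 0)
  }
})

test_that("replicate averaging happens at the free-energy level", {
  expect_equal(average_dgoff(c(-50))$value, -50)
  expect_equal(average_dgoff(c(-40, -60, -50, -45, -55))$value, -50)
  expect_error(average_dgoff(numeric(0)), "no replicate")
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(5, -40, 15)
    dgs <- lapply(v, function(x)
      structure(list(value = x, r_min = 1, r_max = 2), class = "dg_off"))
    expect_equal(average_dgoff(dgs)$value, sum(v) / 5)
    expect_equal(average_dgoff(dgs)$per_replicate, v)
  }
})

test_that("the free energy is invariant to the PMF reference offset", {
  set.seed(11)
  pmf <- c(rnorm(9, 0, 10), 0)
  prof <- data.frame(r_nm = 1:10, pmf_kJ_mol = pmf)
  d0 <- extract_dgoff(prof)$value
  for (c0 in c(-100, -1, 3, 250)) {
    prof2 <- data.frame(r_nm = 1:10, pmf_kJ_mol = pmf + c0)
    expect_equal(extract_dgoff(prof2)$value, d0)
  }
})

test_that("a uniform force offset changes the free energy continuously", {
  pot <- radial_potential("gauss", depth = 25, r0 = 3.0, width = 0.3)
  sch <- make_schedule(3.0)
  sam <- make_force_profiles(sch, pot, noise_sd = 0, include_jacobian = FALSE)
  span <- max(sam$r_nm) - min(sam$r_nm)
  cs <- seq(-10, 10, by = 0.25)
  dgs <- vapply(cs, function(c0) {
    s2 <- sam
    s2$mean_force_kJ_mol_nm <- s2$mean_force_kJ_mol_nm + c0
    extract_dgoff(integrate_pmf(s2, jacobian = FALSE))$value
  }, numeric(1))
  # no discontinuity: increments bounded by the affine slope of the offset
  expect_true(all(abs(diff(dgs)) <= 0.25 * span + 1e-8))
})

test_that("propagated PMF errors grow toward short distances", {
  sch <- make_schedule(2.0)
  sam <- make_force_profiles(sch, radial_potential("gauss", 10, 2.0, 0.3),
                             noise_sd = 1.5, seed = 3)
  p <- integrate_pmf(sam)
  expect_true(all(diff(p$se_kJ_mol) <= 1e-12))
  expect_equal(p$se_kJ_mol[nrow(p)], 0)
})
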