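test_that("stage-1 ranking sorts ascending with lexicographic tie-break", {
  r <- stage1_rank(c(a = -50, b = -70, c = -60))
  expect_equal(r$id, c("b", "c", "a"))
  expect_equal(r$score, c(-70, -60, -50))
  r <- stage1_rank(c(z = -5, a = -5, m = -5))
  expect_equal(r$id, c("a", "m", "z"))
  set.seed(3)
  scores <- setNames(round(rnorm(200, -50, 20), 1), sprintf("d%03d", 1:200))
  expect_equal(stage1_rank(scores)$id, oracle_rank(scores))
})

test_that("best-half selection uses the ceiling rule", {
  mk <- function(n) stage1_rank(setNames(seq_len(n) * -1.0, sprintf("d%02d", n:1)))
  expect_length(select_best_half(mk(10)), 5)
  expect_length(select_best_half(mk(11)), 6)
  expect_length(select_best_half(mk(1)), 1)
})

test_that("top-k clamps to the ranking length", {
  r <- stage1_rank(c(a = -50, b = -70, c = -60))
  expect_equal(top_k(r, 1), "b")
  expect_equal(top_k(r, 100), c("b", "c", "a"))
  set.seed(4)
  scores <- setNames(rnorm(50), sprintf("d%02d", 1:50))
  expect_equal(top_k(stage1_rank(scores), 5), oracle_rank(scores)[1:5])
})

test_that("the staged protocol recovers injected well depths in order", {
  depths <- c(d60 = 60, d40 = 40, d20 = 20, d05 = 5)
  pots <- lapply(depths, function(d) radial_potential("gauss", d, 3.0, 0.25))
  ds <- decoy_set(names(depths), dock_com = rep(3.0, 4))
  eng <- profile_engine(pots, noise_sd = 0.5, base_seed = 17)
  rk <- run_full_protocol(ds, eng)
  expect_equal(rk$id, c("d60", "d40", "d20", "d05"))
  expect_equal(rk$stage, c("final", "final", "stage1-cut", "stage1-cut"))
  dg <- attr(rk, "dg")
  expect_equal(dim(dg), c(4, 5))
  expect_equal(sum(is.na(dg)), 8) # two cut decoys lack replicates 2..5
  expect_lt(max(abs(rowMeans(dg[c("d60", "d40"), ]) + depths[1:2])), 3)
})

test_that("with no extra replicates the protocol reduces to stage 1", {
  set.seed(8)
  pots <- setNames(lapply(runif(6, 5, 60), function(d)
    radial_potential("gauss", d, 2.5, 0.25)), sprintf("d%d", 1:6))
  ds <- decoy_set(names(pots), dock_com = rep(2.5, 6))
  eng <- profile_engine(pots, noise_sd = 1, base_seed = 2)
  rk <- run_full_protocol(ds, eng, n_extra_replicates = 0)
  s1 <- attr(rk, "stage1")
  surv <- select_best_half(s1)
  expect_equal(rk$id[seq_along(surv)], surv)
  expect_equal(rk$score, s1$score[match(rk$id, s1$id)])
})

test_that("duplicated identical decoys share their fate deterministically", {
  pots <- list(a1 = radial_potential("gauss", 30, 3, 0.25),
               a2 = radial_potential("gauss", 30, 3, 0.25),
               b1 = radial_potential("gauss", 10, 3, 0.25),
               b2 = radial_potential("gauss", 10, 3, 0.25))
  ds <- decoy_set(names(pots), dock_com = rep(3, 4))
  eng <- profile_engine(pots, noise_sd = 0, base_seed = 1)
  rk <- run_full_protocol(ds, eng)
  surv <- rk$id[rk$stage == "final"]
  expect_setequal(surv, c("a1", "a2"))
})

test_that("rankings are reproducible and invariant to monotone transforms", {
  set.seed(12)
  pots <- setNames(lapply(runif(8, 5, 80), function(d)
    radial_potential("gauss", d, 3, 0.25)), sprintf("d%d", 1:8))
  ds <- decoy_set(names(pots), dock_com = rep(3, 8))
  eng <- profile_engine(pots, noise_sd = 2, base_seed = 5)
  rk1 <- run_full_protocol(ds, eng)
  rk2 <- run_full_protocol(ds, eng)
  expect_identical(rk1, rk2)
  # monotone invariance at the ranking level
  scores <- setNames(rnorm(30), sprintf("x%02d", 1:30))
  for (f in list(function(x) 2 * x + 7, function(x) x^3, exp)) {
    expect_identical(stage1_rank(scores)$id, stage1_rank(f(scores))$id)
  }
})

test_that("decoys cut at stage 1 never enter the final top half", {
  set.seed(19)
  pots <- setNames(lapply(runif(11, 5, 80), function(d)
    radial_potential("gauss", d, 3, 0.25)), sprintf("d%02d", 1:11))
  ds <- decoy_set(names(pots), dock_com = rep(3, 11))
  eng <- profile_engine(pots, noise_sd = 3, base_seed = 23)
  rk <- run_full_protocol(ds, eng)
  surv <- select_best_half(attr(rk, "stage1"))
  for (k in 1:ceiling(11 / 2))
    expect_true(all(top_k(rk, k) %in% surv))
})

test_that("the crystal reference averages the requested replicate count", {
  pot <- list(native = radial_potential("gauss", 70, 3, 0.25))
  eng <- profile_engine(pot, noise_sd = 1, base_seed = 3)
  cr <- crystal_reference("native", 3.0, eng, n_replicates = 20)
  expect_length(cr$per_replicate, 20)
  expect_equal(cr$value, mean(cr$per_replicate))
  expect_lt(abs(cr$value + 70), 2)
})

test_that("engine failures abort with decoy provenance", {
  ds <- decoy_set(c("good", "bad"), dock_com = c(3, 3))
  eng <- function(id, index, schedule, replicate) {
    if (id == "bad") stop("boom")
    make_force_profiles(schedule, radial_potential("gauss", 20, 3, 0.25))
  }
  expect_error(run_full_protocol(ds, eng), "decoy 'bad'")
})
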