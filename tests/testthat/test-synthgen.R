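test_that("the generated native has a genuine contact interface", {
  nat <- make_native(synth_config())
  p <- split_roles(nat)
  ct <- residue_contacts(p$receptor, p$ligand, 5.0)
  expect_gte(length(ct), 10)
  expect_error(synth_config(interface_size = 0))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- synth_config(seed = 77)
  f1 <- tempfile(); f2 <- tempfile()
  write_pdb(make_native(cfg), f1)
  write_pdb(make_native(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  d1 <- make_decoys(make_native(cfg), cfg)
  d2 <- make_decoys(make_native(cfg), cfg)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$structures[[5]]$atoms, d2$structures[[5]]$atoms)
})

test_that("unperturbed and destroyed tiers land at the extremes", {
  cfg <- synth_config(
    tiers = list(High = list(trans = c(0, 0), rot = c(0, 0)),
                 Incorrect = list(trans = c(50, 50), rot = c(0, 0))),
    n_per_tier = c(High = 2, Incorrect = 2), seed = 5)
  nat <- make_native(cfg)
  dec <- make_decoys(nat, cfg)
  for (id in dec$table$id[dec$table$tier == "High"]) {
    q <- assess_decoy(dec$structures[[id]], nat)
    expect_equal(q$category, "High")
    expect_equal(q$lrms_A, 0, tolerance = 1e-8)
  }
  for (id in dec$table$id[dec$table$tier == "Incorrect"]) {
    q <- assess_decoy(dec$structures[[id]], nat)
    expect_equal(q$category, "Incorrect")
    expect_equal(q$fnat, 0)
  }
})

test_that("translation magnitude drives ligand RMSD", {
  cfg <- synth_config(
    tiers = list(all = list(trans = c(0, 25), rot = c(0, 5))),
    n_per_tier = c(all = 200), seed = 11)
  nat <- make_native(cfg)
  dec <- make_decoys(nat, cfg)
  lr <- vapply(dec$table$id, function(id)
    l_rms(dec$structures[[id]], nat), numeric(1))
  rho <- cor(dec$table$trans_A, lr, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("all four categories appear when all tiers are requested", {
  cfg <- synth_config(seed = 2)
  nat <- make_native(cfg)
  dec <- make_decoys(nat, cfg)
  cats <- vapply(dec$table$id, function(id)
    assess_decoy(dec$structures[[id]], nat)$category, character(1))
  expect_setequal(unique(cats), c("High", "Medium", "Acceptable", "Incorrect"))
})

test_that("synthetic force profiles reproduce the injected potential", {
  sch <- make_schedule(3.0)
  flat <- make_force_profiles(sch, radial_potential("harmonic", 0, 3, 1),
                              noise_sd = 0, include_jacobian = FALSE)
  expect_equal(flat$mean_force_kJ_mol_nm, rep(0, 32))
  pot <- radial_potential("harmonic", depth = 20, r0 = 3.0, width = 0.6)
  sam <- make_force_profiles(sch, pot, noise_sd = 0, include_jacobian = FALSE)
  p <- integrate_pmf(sam, jacobian = FALSE)
  expect_equal(p$pmf_kJ_mol, pot$u(p$r_nm) - pot$u(max(p$r_nm)),
               tolerance = 1e-8)
  # with the Jacobian term included, correction-on integration recovers it too
  sam2 <- make_force_profiles(sch, pot, noise_sd = 0, include_jacobian = TRUE,
                              temperature = 300)
  p2 <- integrate_pmf(sam2, temperature = 300, jacobian = TRUE)
  expect_equal(p2$pmf_kJ_mol, p$pmf_kJ_mol, tolerance = 1e-10)
})

test_that("five replicates estimate free energies better than one", {
  # steep harmonic wells: the PMF minimum and barrier grid points are
  # unambiguous, so estimates are unbiased and averaging shrinks the error;
  # judged over a panel of well depths per seed, as one would over a decoy set
  sch <- make_schedule(3.0)
  wins <- 0
  for (seed in 1:10) {
    errs <- sapply(seq(10, 60, by = 10), function(depth) {
      pot <- radial_potential("harmonic", depth = depth, r0 = 3.0,
                              width = 0.15)
      truth <- pot$u(3.0) - pot$u(max(sch$distances))
      single <- extract_dgoff(integrate_pmf(
        make_force_profiles(sch, pot, noise_sd = 8,
                            seed = derive_seed(seed, depth, 0, 1))))$value
      five <- average_dgoff(lapply(1:5, function(rep)
        extract_dgoff(integrate_pmf(
          make_force_profiles(sch, pot, noise_sd = 8,
                              seed = derive_seed(seed, depth, 0, rep))))))$value
      c(abs(single - truth), abs(five - truth))
    })
    if (mean(errs[2, ]) <= mean(errs[1, ])) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
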