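test_that("contact detection honours the heavy-atom cutoff", {
  r1 <- make_atoms("A", 1, "CA", 0, 0, 0, element = "C")
  near <- make_atoms("B", 1, "CA", 4.9, 0, 0, element = "C")
  far <- make_atoms("B", 1, "CA", 5.1, 0, 0, element = "C")
  expect_length(residue_contacts(r1, near), 1)
  expect_length(residue_contacts(r1, far), 0)
  gone <- make_atoms("B", 1, "CA", 100, 0, 0, element = "C")
  expect_length(residue_contacts(r1, gone), 0)
})

test_that("contacts match a brute-force all-pairs scan on a toy interface", {
  set.seed(13)
  for (rep in 1:5) {
    rec <- do.call(rbind, lapply(1:5, function(i)
      make_atoms("A", i, c("N", "CA", "C", "O"),
                 rnorm(4, i * 3, 1.5), rnorm(4, 0, 1.5), rnorm(4, 0, 1.5))))
    lig <- do.call(rbind, lapply(1:5, function(i)
      make_atoms("B", i, c("N", "CA", "C", "O"),
                 rnorm(4, i * 3, 1.5), rnorm(4, 5, 1.5), rnorm(4, 0, 1.5))))
    expect_identical(residue_contacts(rec, lig), oracle_contacts(rec, lig))
  }
})

test_that("fnat and fnonnat follow set semantics", {
  nat <- paste0("A:", 1:10, "--B:", 1:10)
  expect_equal(fnat(nat, nat), 1.0)
  expect_equal(fnonnat(nat, nat), 0.0)
  other <- paste0("A:", 11:14, "--B:", 11:14)
  expect_equal(fnat(other, nat), 0)
  expect_equal(fnonnat(other, nat), 1)
  dec <- c(nat[1:6], other[1:2])
  expect_equal(fnat(dec, nat), 0.6)
  expect_equal(fnonnat(dec, nat), 0.25)
  expect_equal(fnonnat(character(0), nat), 0)
  expect_error(fnat(dec, character(0)), "empty")
  # coverage count is an integer multiple of 1/|native|
  expect_equal(fnat(dec, nat) * length(nat), round(fnat(dec, nat) * length(nat)))
})

test_that("ligand RMSD is zero for identity and superposition-invariant", {
  nat <- default_native()
  expect_equal(l_rms(nat, nat), 0, tolerance = 1e-8)
  rot <- cgdock:::rotation_about_axis(c(1, -1, 2), 0.8)
  # same rigid transform applied to the whole complex
  whole <- nat
  xyz <- as.matrix(whole$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  whole$atoms[, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2,
                                           ctr + c(3, 4, 5), "+")
  expect_equal(l_rms(whole, nat), 0, tolerance = 1e-8)
  expect_equal(i_rms(whole, nat), 0, tolerance = 1e-8)
})

test_that("a pure ligand translation gives L-rms equal to the shift", {
  nat <- default_native()
  dec <- cgdock:::transform_role(nat, "ligand", shift = c(0, 2, 0))
  expect_equal(l_rms(dec, nat), 2.0, tolerance = 1e-8)
})

test_that("interface RMSD matches an independent Kabsch reference", {
  set.seed(23)
  nat <- default_native()
  for (rep in 1:5) {
    ang <- runif(1, 0.05, 0.5)
    shift <- rnorm(3, 0, 2)
    rot <- cgdock:::rotation_about_axis(rnorm(3), ang)
    dec <- cgdock:::transform_role(nat, "ligand", rot = rot, shift = shift)
    keys <- cgdock:::interface_keys(nat, 10)
    m <- cgdock:::matched_backbone(dec, nat, keys)
    ref <- oracle_rmsd(oracle_kabsch(m$native, m$decoy), m$native)
    expect_equal(i_rms(dec, nat), ref, tolerance = 1e-6)
    ml <- cgdock:::matched_backbone(dec, nat,
                                    unique(paste(nat$atoms$chain, nat$atoms$resid,
                                                 sep = ":")[nat$atoms$chain == "B"]))
    mr <- cgdock:::matched_backbone(dec, nat,
                                    unique(paste(nat$atoms$chain, nat$atoms$resid,
                                                 sep = ":")[nat$atoms$chain == "A"]))
    # receptor fit, ligand RMSD without re-fitting (receptor unmoved here)
    expect_equal(l_rms(dec, nat), oracle_rmsd(ml$decoy, ml$native),
                 tolerance = 1e-6)
  }
})

test_that("classification reproduces the printed worked examples", {
  expect_equal(classify_capri(0.5, 1.0, 1.0), "High")
  expect_equal(classify_capri(0.4, 8.0, 1.5), "Medium")
  expect_equal(classify_capri(0.05, 0.0, 0.0), "Incorrect")
  expect_equal(classify_capri(0.2, 20, 20), "Incorrect")
  expect_equal(classify_capri(0.2, 9.9, 20), "Acceptable")
})

test_that("classification is total and matches the independent truth table", {
  grid <- expand.grid(f = seq(0, 1, 0.05), l = seq(0, 12, 0.5),
                      i = seq(0, 5, 0.25))
  got <- classify_capri(grid$f, grid$l, grid$i)
  expect_true(all(got %in% c("High", "Medium", "Acceptable", "Incorrect")))
  want <- mapply(oracle_classify, grid$f, grid$l, grid$i)
  expect_identical(got, unname(want))
})

test_that("quality never worsens as fnat grows at a perfect pose", {
  lev <- c(Incorrect = 0, Acceptable = 1, Medium = 2, High = 3)
  ranks <- lev[classify_capri(seq(0, 1, 0.01), 0, 0)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("RMSD measures are invariant to global rigid motions of the decoy", {
  set.seed(31)
  nat <- default_native()
  dec <- cgdock:::transform_role(nat, "ligand", shift = c(1.5, 0.5, -1))
  l0 <- l_rms(dec, nat)
  i0 <- i_rms(dec, nat)
  for (rep in 1:3) {
    rot <- cgdock:::rotation_about_axis(rnorm(3), runif(1, 0, pi))
    shift <- rnorm(3, 0, 20)
    g <- dec
    xyz <- as.matrix(g$atoms[, c("x", "y", "z")])
    g$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(rot), 2, shift, "+")
    expect_equal(l_rms(g, nat), l0, tolerance = 1e-6)
    expect_equal(i_rms(g, nat), i0, tolerance = 1e-6)
  }
})

test_that("assess_decoy bundles the four measures coherently", {
  nat <- default_native()
  q <- assess_decoy(nat, nat)
  expect_equal(q$fnat, 1)
  expect_equal(q$fnonnat, 0)
  expect_equal(q$category, "High")
  far <- cgdock:::transform_role(nat, "ligand", shift = c(50, 0, 0))
  q2 <- assess_decoy(far, nat)
  expect_equal(q2$fnat, 0)
  expect_equal(q2$category, "Incorrect")
})
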