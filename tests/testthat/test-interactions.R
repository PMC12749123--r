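test_that("opposite unit charges at 1 nm give the Coulomb prefactor exactly", {
  sys <- unit_charge_system(1.0)
  e <- pair_energy(sys$frame, sys$topology, 1L, 2L)
  expect_equal(e$coulomb, -138.935485, tolerance = 1e-12)
  expect_equal(e$lennard_jones, 0)
})

test_that("pairs beyond the cutoff contribute exactly zero", {
  sys <- unit_charge_system(1.3)   # > 1.2 nm default cutoff
  e <- pair_energy(sys$frame, sys$topology, 1L, 2L)
  expect_identical(e$coulomb, 0)
  expect_identical(e$lennard_jones, 0)
})

test_that("the LJ term vanishes algebraically at r = sigma_ij", {
  atoms <- data.frame(serial = 1:2, atom_name = c("A1", "B1"),
                      res_name = c("RNDA", "RNDB"), res_id = 1:2,
                      x = c(1, 1.4), y = 5, z = 5)
  top <- default_topology()
  top$params <- rbind(top$params,
                      data.frame(res_name = c("RNDA", "RNDB"),
                                 atom_name = c("A1", "B1"),
                                 charge = 0, sigma = 0.4, epsilon = 0.8))
  fr <- mem_frame(atoms, c(10, 10, 10))
  e <- pair_energy(fr, top, 1L, 2L)
  expect_equal(e$lennard_jones, 0, tolerance = 1e-12)
})

test_that("pair_energy matches the double-loop oracle to 1e-9 relative", {
  for (seed in 1:6) {
    sys <- random_charged_system(na = 8, nb = 12, seed = seed)
    e <- pair_energy(sys$frame, sys$topology, sys$set_a, sys$set_b)
    o <- brute_pair_energy(sys$frame, sys$topology, sys$set_a, sys$set_b)
    expect_equal(e$coulomb, o$coulomb, tolerance = 1e-9)
    expect_equal(e$lennard_jones, o$lennard_jones, tolerance = 1e-9)
    # symmetry under swapping the two sets
    sw <- pair_energy(sys$frame, sys$topology, sys$set_b, sys$set_a)
    expect_equal(sw$coulomb, e$coulomb, tolerance = 1e-12)
    expect_equal(sw$lennard_jones, e$lennard_jones, tolerance = 1e-12)
  }
  sys <- random_charged_system(4, 4, seed = 99)
  expect_error(pair_energy(sys$frame, sys$topology, 1:4, 4:8), "overlap")
})

test_that("charge flips and parameter zeroing behave algebraically", {
  sys <- random_charged_system(6, 9, seed = 17)
  e <- pair_energy(sys$frame, sys$topology, sys$set_a, sys$set_b)
  flipped <- sys$topology
  rows <- flipped$params$res_name == "RNDA"
  flipped$params$charge[rows] <- -flipped$params$charge[rows]
  ef <- pair_energy(sys$frame, flipped, sys$set_a, sys$set_b)
  expect_equal(ef$coulomb, -e$coulomb, tolerance = 1e-12)
  expect_equal(ef$lennard_jones, e$lennard_jones, tolerance = 1e-12)
  zeroed <- sys$topology
  zeroed$params$epsilon[] <- 0
  ez <- pair_energy(sys$frame, zeroed, sys$set_a, sys$set_b)
  expect_identical(ez$lennard_jones, 0)
  noq <- sys$topology
  noq$params$charge[] <- 0
  expect_identical(pair_energy(sys$frame, noq, sys$set_a, sys$set_b)$coulomb, 0)
})

test_that("residue-decade blocks sum to the totals and localise charge", {
  gen <- small_bilayer(16, seed = 3)
  pp <- generate_probe_protein(gen$frame, gen$topology, n_residues = 60,
                               placement = 0.3,
                               charges = c(rep(1, 10), rep(0, 50)))
  ge <- group_energy(pp$frame, pp$topology)
  tot <- pair_energy(pp$frame, pp$topology,
                     which(memdefect:::protein_atom_sel(pp$frame, pp$topology)),
                     which(memdefect:::lipid_atom_sel(pp$frame, pp$topology)))
  expect_equal(sum(ge$blocks_coulomb), tot$coulomb, tolerance = 1e-6)
  expect_equal(sum(ge$blocks_lj), tot$lennard_jones, tolerance = 1e-6)
  # all Coulomb energy sits in the charged first decade
  coul_by_group <- rowSums(ge$blocks_coulomb)
  expect_true(all(abs(coul_by_group[-1]) < 1e-9))
  expect_gt(abs(coul_by_group["1-10"]), 0)
})

test_that("blocks match a per-block brute-force double loop", {
  gen <- small_bilayer(16, seed = 8)
  pp <- generate_probe_protein(gen$frame, gen$topology, n_residues = 12,
                               placement = 0.25, charges = c(0.5, -0.3, 0.1))
  ge <- group_energy(pp$frame, pp$topology)
  atoms <- pp$frame$atoms
  for (g in c("1-10", "11-20")) for (s in c("LPC", "LPS")) {
    lo <- as.integer(sub("-.*", "", g)); hi <- as.integer(sub(".*-", "", g))
    pa <- which(memdefect:::protein_atom_sel(pp$frame, pp$topology) &
                  atoms$res_id >= lo & atoms$res_id <= hi)
    mb <- which(atoms$res_name == s)
    o <- brute_pair_energy(pp$frame, pp$topology, pa, mb)
    expect_equal(ge$blocks_coulomb[g, s], o$coulomb, tolerance = 1e-9)
    expect_equal(ge$blocks_lj[g, s], o$lennard_jones, tolerance = 1e-9)
  }
})

test_that("residues outside 1-60 fall into an 'other' group with a warning", {
  gen <- small_bilayer(16, seed = 3)
  pp <- generate_probe_protein(gen$frame, gen$topology, n_residues = 5,
                               placement = 0.3, charges = 0.2)
  fr <- pp$frame
  fr$atoms$res_id[fr$atoms$res_name == "S005"] <- 61L
  expect_warning(ge <- group_energy(fr, pp$topology), "other")
  expect_true("other" %in% rownames(ge$blocks_coulomb))
})

test_that("per-lipid energy divides by contact lipids only", {
  gen <- small_bilayer(16, seed = 3)
  pp <- generate_probe_protein(gen$frame, gen$topology, n_residues = 4,
                               placement = 0.3, charges = 0.5)
  pl <- per_lipid_energy(pp$frame, pp$topology)
  expect_true(pl$defined)
  expect_gt(pl$n_contact_lipids, 0)
  expect_equal(pl$per_lipid_total,
               (pl$total$coulomb + pl$total$lennard_jones) / pl$n_contact_lipids)
  # a lipid far outside the cutoff changes nothing
  far <- pp$frame
  lip1 <- which(far$atoms$res_name %in% c("LPC", "LPE", "LPS"))[1:7]
  add <- far$atoms[lip1, ]
  add$res_id <- max(far$atoms$res_id) + 1L
  add$serial <- max(far$atoms$serial) + seq_len(nrow(add))
  add$z <- add$z - 50   # far below everything
  far2 <- mem_frame(rbind(far$atoms, add), c(far$box[1], far$box[2], 200))
  pl2 <- per_lipid_energy(far2, pp$topology)
  expect_equal(pl2$n_contact_lipids, pl$n_contact_lipids)
  expect_equal(pl2$per_lipid_total, pl$per_lipid_total, tolerance = 1e-9)
  # protein far above: zero contacts, undefined average
  pp5 <- generate_probe_protein(gen$frame, gen$topology, n_residues = 4,
                                placement = 5, charges = 0.5)
  pl5 <- per_lipid_energy(pp5$frame, pp5$topology)
  expect_false(pl5$defined)
  expect_equal(pl5$n_contact_lipids, 0)
  expect_true(is.na(pl5$per_lipid_total))
})

test_that("a constructed N-H...O contact is found iff within the criteria", {
  sys <- aimed_contact_system()
  hb <- find_hbonds(sys$frame, sys$topology)
  expect_equal(nrow(hb), 1)
  expect_lt(hb$distance, 0.35)
  expect_lt(hb$angle, 30)
  # stretch the donor beyond d_max: same geometry at 0.40 nm
  fr <- sys$frame
  prot <- fr$atoms$res_name == "S001"
  fr$atoms$z[prot] <- fr$atoms$z[prot] + 0.11
  expect_equal(nrow(find_hbonds(fr, sys$topology)), 0)
  # hydrogen-free structures are rejected with advice
  noh <- sys$frame
  noh$atoms <- noh$atoms[noh$atoms$element != "H", ]
  expect_error(find_hbonds(noh, sys$topology), "no hydrogens")
})

test_that("H-bond counts survive rigid rototranslations", {
  sys <- aimed_contact_system()
  base <- nrow(find_hbonds(sys$frame, sys$topology))
  expect_gte(base, 1)
  set.seed(23)
  for (k in 1:10) {
    fr <- rotate_frame(sys$frame, runif(3, 0, 2 * pi), runif(3, -2, 2))
    expect_equal(nrow(find_hbonds(fr, sys$topology)), base)
  }
})

test_that("time series statistics follow the run-mean conventions", {
  sys <- aimed_contact_system()
  tr <- mem_trajectory(list(sys$frame, sys$frame, sys$frame))
  ts <- hbond_timeseries(tr, sys$topology)
  expect_equal(unlist(ts$counts), rep(1L, 3))
  expect_equal(ts$mean, 1)
  expect_equal(ts$sd, 0)
  expect_error(hbond_timeseries(list(), sys$topology), "empty")

  # two runs with different constant energies -> ensemble mean of run means
  s1 <- unit_charge_system(1.0)
  s2 <- unit_charge_system(0.5)
  e1 <- pair_energy(s1$frame, s1$topology, 1L, 2L)$coulomb
  e2 <- pair_energy(s2$frame, s2$topology, 1L, 2L)$coulomb
  ts2 <- energy_timeseries(list(mem_trajectory(list(s1$frame, s1$frame)),
                                mem_trajectory(list(s2$frame))),
                           s1$topology, protein_sel = 1L, membrane_sel = 2L)
  expect_equal(ts2$ensemble_mean, mean(c(e1, e2)), tolerance = 1e-12)
  expect_equal(ts2$ensemble_sd, abs(e1 - e2) / 2, tolerance = 1e-12)
  one <- energy_timeseries(mem_trajectory(list(s1$frame, s1$frame)),
                           s1$topology, protein_sel = 1L, membrane_sel = 2L)
  expect_equal(one$per_frame$coulomb, rep(e1, 2))
  expect_equal(one$ensemble_sd, 0)
})
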