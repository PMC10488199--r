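test_that("a single close lipid yields a single contact", {
  sys <- toy_system(
    prot = data.frame(residue_id = 1L, x = 0.3, y = 0, z = 0),
    heads = data.frame(molecule_id = 2L, species = "PS",
                       x = 0.4, y = 0, z = 0))
  cc <- detect_contacts(sys$frame, sys$topology)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$lipid_id, 2L)
  expect_equal(cc$distance, 0.1, tolerance = 1e-12)
})

test_that("a farther lipid is excluded by nearest-lipid exclusivity", {
  sys <- toy_system(
    prot = data.frame(residue_id = 1L, x = 0.3, y = 0, z = 0),
    heads = data.frame(molecule_id = c(2L, 3L), species = c("PS", "PC"),
                       x = c(0.4, 0.8), y = 0, z = 0))
  cc <- detect_contacts(sys$frame, sys$topology)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$lipid_id, 2L)   # the 0.5 nm lipid is blocked, not added
  # a closer lipid of another species blocks even within cutoff
  sys2 <- toy_system(
    prot = data.frame(residue_id = 1L, x = 0.3, y = 0, z = 0),
    heads = data.frame(molecule_id = c(2L, 3L), species = c("PS", "PC"),
                       x = c(0.5, 0.35), y = 0, z = 0))
  cc2 <- detect_contacts(sys2$frame, sys2$topology)
  expect_equal(cc2$species, "PC")
})

test_that("periodic wrap in x/y is honoured; ties go to the lowest lipid id", {
  sys <- toy_system(
    prot = data.frame(residue_id = 1L, x = 0.1, y = 2, z = 1),
    heads = data.frame(molecule_id = 2L, species = "PS",
                       x = 9.8, y = 2, z = 1))
  cc <- detect_contacts(sys$frame, sys$topology)
  expect_equal(cc$distance, 0.3, tolerance = 1e-12)
  sys2 <- toy_system(
    prot = data.frame(residue_id = 1L, x = 5, y = 5, z = 1),
    heads = data.frame(molecule_id = c(7L, 3L), species = c("PS", "PC"),
                       x = c(5.2, 4.8), y = 5, z = 1))
  cc2 <- detect_contacts(sys2$frame, sys2$topology)
  expect_equal(cc2$lipid_id, 3L)
})

test_that("contact engine matches the exhaustive oracle on random frames", {
  set.seed(42)
  for (i in 1:25) {
    sys <- rand_system()
    got <- detect_contacts(sys$frame, sys$topology)
    want <- brute_contacts(sys$frame, sys$topology)
    expect_equal(got$residue_id, want$residue_id)
    expect_equal(got$lipid_id, want$lipid_id)
  }
})

test_that("contacts are invariant under global frame translation", {
  set.seed(7)
  sys <- rand_system()
  got <- detect_contacts(sys$frame, sys$topology)
  shift <- c(3.7, -1.2, 0.9)
  fr2 <- sys$frame
  fr2$xyz <- sweep(fr2$xyz, 2, shift, `+`)
  fr2$xyz[, 1] <- fr2$xyz[, 1] %% fr2$box[1]
  fr2$xyz[, 2] <- fr2$xyz[, 2] %% fr2$box[2]
  got2 <- detect_contacts(fr2, sys$topology)
  expect_equal(got$residue_id, got2$residue_id)
  expect_equal(got$lipid_id, got2$lipid_id)
})

test_that("the stricter multi-bead reading is available behind min_beads", {
  # residue with two beads: only one is within cutoff of the lipid
  sys <- toy_system(
    prot = data.frame(residue_id = c(1L, 1L), x = c(0.3, 2.0), y = 0, z = 0),
    heads = data.frame(molecule_id = 2L, species = "PS",
                       x = 0.4, y = 0, z = 0))
  expect_equal(nrow(detect_contacts(sys$frame, sys$topology)), 1)
  expect_equal(nrow(detect_contacts(sys$frame, sys$topology, min_beads = 2L)), 0)
  # both beads within cutoff: accepted under either reading
  sys2 <- toy_system(
    prot = data.frame(residue_id = c(1L, 1L), x = c(0.3, 0.6), y = 0, z = 0),
    heads = data.frame(molecule_id = 2L, species = "PS",
                       x = 0.4, y = 0, z = 0))
  expect_equal(nrow(detect_contacts(sys2$frame, sys2$topology, min_beads = 2L)), 1)
})

test_that("contact probabilities normalize counts by frame count", {
  # residue in contact for exactly 50 of 100 frames
  n <- 100
  coords <- array(NA_real_, c(2, 3, n))
  for (f in 1:n) {
    coords[1, , f] <- c(5, 5, 1)
    coords[2, , f] <- c(5 + ifelse(f <= 50, 0.3, 3), 5, 1)
  }
  topo <- bead_topology(data.frame(
    bead_id = 1:2, molecule_id = c(1L, 2L),
    molecule_type = c("protein", "PS"), residue_id = c(1L, NA),
    bead_name = c("BB", "PO4"), role = c("protein", "headgroup")))
  traj <- new_trajectory(coords, matrix(c(10, 10, 6), n, 3, byrow = TRUE))
  p <- contact_probabilities(traj, topo)
  expect_equal(p$probability[p$species == "PS"], 0.5)
  expect_equal(p$count[p$species == "PS"], 50)
  # concatenating the trajectory with itself keeps the probability
  p2 <- contact_probabilities(list(traj, traj), topo)
  expect_equal(attr(p2, "frames"), 200)
  expect_equal(p2$probability[p2$species == "PS"], 0.5)
})

test_that("never-contacting residues report zero for all species", {
  sys <- toy_system(
    prot = data.frame(residue_id = 1L, x = 5, y = 5, z = 3),
    heads = data.frame(molecule_id = 2L, species = "PS", x = 1, y = 1, z = 0))
  traj <- new_trajectory(array(sys$frame$xyz, c(2, 3, 1)),
                         matrix(sys$frame$box, 1, 3))
  p <- contact_probabilities(traj, sys$topology)
  expect_true(all(p$probability == 0))
})

test_that("report layer applies the 15% label and 5% highlight thresholds", {
  prof <- data.frame(residue_id = 1:4, species = "PS",
                     count = c(20, 10, 4, 1),
                     probability = c(0.20, 0.10, 0.04, 0.15))
  rep <- contact_report(prof, "PS")
  expect_equal(rep$residue_id[rep$labeled], 1L)            # > 15% only
  expect_setequal(rep$residue_id[rep$highlighted], c(1L, 2L, 4L))  # >= 5%
})
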