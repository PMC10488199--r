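test_that("leaflet assignment matches the generator ground truth exactly", {
  g <- gen_membrane_trajectory(membrane_gen_config(n_frames = 3, seed = 14))
  lf <- assign_leaflets(get_frame(g$trajectory, 2), g$topology)
  truth <- g$ground_truth$lipid_leaflet
  expect_equal(unname(lf[names(truth)]), unname(truth))
  expect_equal(sum(lf == "upper"), 262)
  expect_equal(sum(lf == "lower"), 262)
})

test_that("lipids above the midplane-defining set are all upper", {
  heads <- data.frame(molecule_id = 2:5, species = "PC",
                      x = 1:4, y = 1, z = c(4, 4, 4, 1))
  sys <- toy_system(prot = data.frame(residue_id = 1L, x = 5, y = 5, z = 3),
                    heads = heads)
  lf <- assign_leaflets(sys$frame, sys$topology)
  expect_equal(unname(lf[c("2", "3", "4")]), rep("upper", 3))
  expect_equal(unname(lf[["5"]]), "lower")
})

test_that("one static lipid produces the single-occupant 2D density", {
  heads <- data.frame(molecule_id = 2L, species = "PS", x = 5.01, y = 5.01,
                      z = 4)
  low <- data.frame(molecule_id = 3L, species = "PS", x = 2, y = 2, z = 1)
  sys <- toy_system(prot = data.frame(residue_id = 1L, x = 5, y = 5, z = 2.5),
                    heads = rbind(heads, low))
  traj <- new_trajectory(array(sys$frame$xyz, c(3, 3, 1)),
                         matrix(sys$frame$box, 1, 3))
  m <- density_map_2d(traj, sys$topology, "PS", "upper", spacing = 0.02)
  expect_equal(max(m$values), 1 / 0.02^2)   # 2500 nm^-2
  expect_equal(sum(m$values > 0), 1)
  expect_equal(sum(m$values) * m$spacing^2, 1, tolerance = 1e-12)
})

test_that("2D and 3D densities conserve the mean per-frame count to 1e-9", {
  g <- gen_membrane_trajectory(membrane_gen_config(
    n_frames = 40, n_lipids_total = 80,
    composition = c(PS = 0.25, PC = 0.75), seed = 31))
  al <- align_frames(g$trajectory, g$topology)
  for (sp in c("PS", "PC")) for (lf in c("upper", "lower")) {
    m <- density_map_2d(al, g$topology, sp, lf, spacing = 0.05)
    expect_equal(sum(m$values) * m$spacing^2, m$mean_count,
                 tolerance = 1e-9)
  }
  for (selection in c("headgroup", "all")) {
    gr <- density_grid_3d(al, g$topology, "PS", selection, spacing = 0.1)
    expect_equal(sum(gr$values) * gr$spacing^3, gr$mean_count,
                 tolerance = 1e-9)
  }
})

test_that("a single static bead gives the single-voxel 3D density", {
  heads <- data.frame(molecule_id = 2L, species = "PS", x = 5.01, y = 5.01,
                      z = 4.01)
  sys <- toy_system(prot = data.frame(residue_id = 1L, x = 2, y = 2, z = 2),
                    heads = heads)
  traj <- new_trajectory(array(sys$frame$xyz, c(2, 3, 1)),
                         matrix(sys$frame$box, 1, 3))
  gr <- density_grid_3d(traj, sys$topology, "PS", "headgroup", spacing = 0.1)
  expect_equal(max(gr$values), 1000)        # 1 / 0.1^3
  expect_equal(sum(gr$values > 0), 1)
  # display isovalue defaults follow the bead selection
  expect_equal(gr$isovalue, 3)
  gr_all <- density_grid_3d(traj, sys$topology, "PS", "all", spacing = 0.1)
  expect_equal(gr_all$isovalue, 4)
})

test_that("uniform random lipids give near-uniform cell densities", {
  g <- gen_membrane_trajectory(membrane_gen_config(
    n_frames = 1000, n_lipids_total = 200,
    composition = c(PC = 1), seed = 77))
  m <- density_map_2d(g$trajectory, g$topology, "PC", "upper", spacing = 1)
  expected <- 100 / (13 * 13)
  se <- stats::sd(m$values) / sqrt(length(m$values))
  expect_lt(abs(mean(m$values) - expected), 3 * se + 1e-9)
})

test_that("enrichment normalizes to the uniform expectation", {
  vals <- matrix(2, 5, 5)
  vals[3, 3] <- 4   # one cell at twice the background
  m <- structure(list(values = vals, spacing = 1, origin = c(0, 0),
                      species = "PS", leaflet = "upper", frames = 10,
                      box = c(5, 5), mean_count = 2 * 25 + 2),
                 class = "density_map_2d")
  e <- enrichment_map(m, n_expected = 2 * 25)
  expect_equal(e$values[3, 3], 2.0)
  expect_equal(e$values[1, 1], 1.0)
  expect_error(enrichment_map(m, n_expected = 0), "degenerate")
})

test_that("density exports write valid TSV and OpenDX text", {
  g <- gen_membrane_trajectory(membrane_gen_config(
    n_frames = 2, n_lipids_total = 20, seed = 5))
  dir <- withr::local_tempdir()
  m <- density_map_2d(g$trajectory, g$topology, "PS", "upper", spacing = 0.5)
  tsv <- file.path(dir, "m.tsv")
  write_density_tsv(m, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(sum(back$value) * m$spacing^2, m$mean_count, tolerance = 1e-9)
  hdr <- jsonlite::read_json(paste0(tsv, ".json"))
  expect_equal(hdr$spacing, 0.5)
  expect_equal(hdr$species, "PS")
  gr <- density_grid_3d(g$trajectory, g$topology, "PS", "headgroup", 0.5)
  dx <- file.path(dir, "g.dx")
  write_dx(gr, dx)
  lines <- readLines(dx)
  expect_match(lines[2], "gridpositions counts")
  counts <- as.integer(strsplit(lines[2], " +")[[1]][6:8])
  expect_equal(prod(counts), length(gr$values))
})
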