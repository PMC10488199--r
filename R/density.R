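#' Assign every lipid of a frame to a leaflet
#'
#' The bilayer midplane is the mean z of all lipid headgroup beads in the
#' frame; a lipid is `upper` iff the mean z of its headgroup beads exceeds
#' the midplane (ties go to `lower`).
#'
#' @param frame A frame from [get_frame()].
#' @param topology The matching [bead_topology()].
#' @return Named character vector, `molecule_id` -> `"upper"`/`"lower"`.
#' @export
assign_leaflets <- function(frame, topology) {
  hg <- which(topology$role == "headgroup")
  if (!length(hg)) stop_config("topology contains no headgroup beads")
  z <- frame$xyz[hg, 3]
  mol <- topology$molecule_id[hg]
  zlip <- tapply(z, mol, mean)
  mid <- mean(z)
  stats::setNames(as.vector(ifelse(zlip > mid, "upper", "lower")),
                  names(zlip))
}

.grid_dims <- function(L, spacing) {
  n <- round(L / spacing)
  if (abs(n * spacing - L) > 1e-6 * max(1, L)) n <- ceiling(L / spacing)
  max(1L, as.integer(n))
}

#' Time-averaged 2D headgroup number density of one species in one leaflet
#'
#' For every frame, lipids of `species` in `leaflet` are located by the
#' centroid of their headgroup beads and binned into half-open square cells
#' `[i*h, (i+1)*h)` anchored at the box corner; counts are averaged over
#' frames and divided by the cell area, giving nm^-2. The map satisfies
#' `sum(values) * cell_area == mean per-frame count` exactly.
#'
#' @param traj An aligned `cg_trajectory`.
#' @param topology The matching [bead_topology()].
#' @param species Lipid species name.
#' @param leaflet `"upper"` or `"lower"`.
#' @param spacing Grid spacing in nm (default 0.02).
#' @return A `density_map_2d`: list with `values` (matrix `[nx, ny]`),
#'   `spacing`, `origin`, `species`, `leaflet`, `frames`, `box`,
#'   `mean_count`.
#' @export
density_map_2d <- function(traj, topology, species, leaflet = "upper",
                           spacing = 0.02) {
  if (spacing <= 0) stop_config("spacing must be positive")
  box <- traj$box[1, ]
  nx <- .grid_dims(box[1], spacing); ny <- .grid_dims(box[2], spacing)
  hg <- which(topology$role == "headgroup" &
                topology$molecule_type == species)
  if (!length(hg)) stop_config("no headgroup beads for species '%s'", species)
  mol <- topology$molecule_id[hg]
  counts <- numeric(nx * ny)
  total_sel <- 0
  for (f in seq_len(n_frames(traj))) {
    frame <- get_frame(traj, f)
    lf <- assign_leaflets(frame, topology)
    keep_mol <- names(lf)[lf == leaflet]
    sel <- hg[as.character(mol) %in% keep_mol]
    if (!length(sel)) next
    gx <- tapply(frame$xyz[sel, 1], topology$molecule_id[sel], mean)
    gy <- tapply(frame$xyz[sel, 2], topology$molecule_id[sel], mean)
    ix <- pmin(floor(wrap_coord(gx, box[1]) / spacing), nx - 1)
    iy <- pmin(floor(wrap_coord(gy, box[2]) / spacing), ny - 1)
    idx <- iy * nx + ix + 1
    counts <- counts + tabulate(idx, nbins = nx * ny)
    total_sel <- total_sel + length(gx)
  }
  T <- n_frames(traj)
  structure(list(values = matrix(counts / (T * spacing^2), nx, ny),
                 spacing = spacing, origin = c(0, 0),
                 species = species, leaflet = leaflet, frames = T,
                 box = box[1:2], mean_count = total_sel / T),
            class = "density_map_2d")
}

#' Convert a 2D density map to an enrichment map
#'
#' Divides every cell by the uniform expectation `n / (Lx * Ly)`, so 1
#' means no enrichment. By default `n` is the map's own mean per-frame
#' lipid count; pass `n_expected` (e.g. the known per-leaflet species
#' count) to normalize against the composition instead.
#'
#' @param map2d A [density_map_2d()] result.
#' @param n_expected Expected lipid count of the species in the leaflet.
#' @return A `density_map_2d` with dimensionless values and
#'   `enrichment = TRUE`.
#' @export
enrichment_map <- function(map2d, n_expected = NULL) {
  n <- n_expected %||% map2d$mean_count
  if (!is.finite(n) || n <= 0)
    stop_config("degenerate composition: expected count %g", n)
  expected <- n / prod(map2d$box)
  out <- map2d
  out$values <- map2d$values / expected
  out$enrichment <- TRUE
  out
}

#' Time-averaged 3D number density of lipid beads
#'
#' Bins the selected beads (all beads of a species, or its headgroup beads
#' only) into cubic voxels anchored at the box corner, averages counts over
#' frames and divides by the voxel volume (nm^-3). Conservation holds
#' exactly: `sum(values) * voxel_volume == mean per-frame selected count`.
#' Typical display isovalues are 3 nm^-3 for headgroup-bead grids and
#' 4 nm^-3 for all-bead grids.
#'
#' @param traj An aligned `cg_trajectory`.
#' @param topology The matching [bead_topology()].
#' @param species Lipid species name.
#' @param selection `"all"` beads of the species or `"headgroup"` only.
#' @param spacing Voxel edge in nm (default 0.1).
#' @return A `density_grid_3d`: list with `values` (array `[nx, ny, nz]`),
#'   `spacing`, `selection`, `species`, `frames`, `box`, `mean_count`,
#'   `isovalue`.
#' @export
density_grid_3d <- function(traj, topology, species,
                            selection = c("headgroup", "all"),
                            spacing = 0.1) {
  selection <- match.arg(selection)
  if (spacing <= 0) stop_config("spacing must be positive")
  sel <- which(topology$molecule_type == species &
                 (selection == "all" | topology$role == "headgroup"))
  if (!length(sel)) stop_config("empty selection for species '%s'", species)
  box <- traj$box[1, ]
  nx <- .grid_dims(box[1], spacing); ny <- .grid_dims(box[2], spacing)
  nz <- .grid_dims(box[3], spacing)
  counts <- numeric(nx * ny * nz)
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[sel, , f, drop = FALSE]
    ix <- pmin(floor(wrap_coord(xyz[, 1, 1], box[1]) / spacing), nx - 1)
    iy <- pmin(floor(wrap_coord(xyz[, 2, 1], box[2]) / spacing), ny - 1)
    iz <- pmin(pmax(floor(xyz[, 3, 1] / spacing), 0), nz - 1)
    counts <- counts + tabulate((iz * ny + iy) * nx + ix + 1,
                                nbins = nx * ny * nz)
  }
  T <- n_frames(traj)
  structure(list(values = array(counts / (T * spacing^3), c(nx, ny, nz)),
                 spacing = spacing, selection = selection, species = species,
                 frames = T, box = box, mean_count = length(sel),
                 isovalue = if (selection == "headgroup") 3 else 4),
            class = "density_grid_3d")
}

#' Export a 2D density map as TSV plus a JSON header
#'
#' Writes nonzero cells as `i`, `j`, `value` (0-based indices) and a
#' `<path>.json` sidecar with origin, spacing, leaflet and species.
#'
#' @param map2d A [density_map_2d()] result.
#' @param path Output TSV path.
#' @export
write_density_tsv <- function(map2d, path) {
  nz <- which(map2d$values != 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(i = nz[, 1] - 1L, j = nz[, 2] - 1L,
               value = map2d$values[nz]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(origin = map2d$origin, spacing = map2d$spacing,
                            dims = dim(map2d$values),
                            leaflet = map2d$leaflet, species = map2d$species,
                            frames = map2d$frames,
                            enrichment = isTRUE(map2d$enrichment)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a 3D density grid in OpenDX text format
#'
#' @param grid A [density_grid_3d()] result.
#' @param path Output `.dx` path.
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# %s %s-bead density (nm^-3), isovalue %g",
            grid$species, grid$selection, grid$isovalue),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    "origin 0.0 0.0 0.0",
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX expects z fastest
  v <- aperm(grid$values, c(3, 2, 1))
  vals <- as.vector(v)
  pad <- (-length(vals)) %% 3
  if (pad) vals <- c(vals, rep(NA, pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(format(r[!is.na(r)], scientific = TRUE, digits = 6), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
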