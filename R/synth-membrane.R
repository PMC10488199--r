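#' Hotspot specification for the bilayer generator
#'
#' Declares a planted high-affinity lipid interaction site: lipids of
#' `species` in the leaflet of the named residues are biased to remain
#' within `radius` of those residues, with outward displacement attempts
#' rejected with probability `strength / (1 + strength)`. `strength = 0`
#' disables the bias.
#'
#' @param residue_ids Protein residue ids hosting the site (must exist in
#'   the generated protein).
#' @param species Lipid species name (e.g. `"PS"`).
#' @param strength Dimensionless affinity, >= 0.
#' @param radius Capture radius in nm.
#' @return A `hotspot_spec` object.
#' @export
hotspot_spec <- function(residue_ids, species, strength = 0, radius = 1) {
  if (strength < 0) stop_config("hotspot strength must be >= 0")
  if (radius <= 0) stop_config("hotspot radius must be positive")
  structure(list(residue_ids = as.integer(residue_ids), species = species,
                 strength = strength, radius = radius),
            class = "hotspot_spec")
}

#' Configuration for a synthetic coarse-grained bilayer trajectory
#'
#' The generated system mimics the geometry of a coarse-grained
#' membrane-protein simulation: a static helix-bundle scaffold spanning a
#' bilayer whose lipids perform leaflet-confined 2D Brownian motion with
#' periodic wrapping in x and y. Headgroup beads sit at +/- 2 nm from the
#' midplane and three tail beads are spaced evenly toward z = 0.
#'
#' Defaults reproduce the simulated study conditions: 524 lipids distributed
#' symmetrically over both leaflets with a PS:PC 10:90 molar composition.
#'
#' @param box Box lengths `(Lx, Ly, Lz)` in nm.
#' @param n_lipids_total Total lipid count; must be even (symmetric leaflets).
#' @param composition Named molar fractions summing to 1.
#' @param hotspots List of [hotspot_spec()] objects.
#' @param n_frames Number of frames to emit (>= 1).
#' @param diffusion_step Per-frame Brownian step sd in nm.
#' @param seed Integer root seed.
#' @param protein_layout List with `n_helices`, `n_res_per_helix`,
#'   `beads_per_residue`, `radius` (nm) describing the helix circle.
#' @return A `membrane_gen_config` object.
#' @export
membrane_gen_config <- function(box = c(13, 13, 9),
                                n_lipids_total = 524,
                                composition = c(PS = 0.1, PC = 0.9),
                                hotspots = list(),
                                n_frames = 100,
                                diffusion_step = 0.3,
                                seed = 1L,
                                protein_layout = list(n_helices = 10,
                                                      n_res_per_helix = 12,
                                                      beads_per_residue = 1,
                                                      radius = 2)) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop_config("composition fractions must sum to 1 (got %g)", sum(composition))
  if (n_lipids_total %% 2 != 0)
    stop_config("n_lipids_total must be even for symmetric leaflets")
  if (n_frames < 1) stop_config("n_frames must be >= 1")
  if (any(box <= 0)) stop_config("box lengths must be positive")
  n_res <- protein_layout$n_helices * protein_layout$n_res_per_helix
  for (h in hotspots) {
    if (!inherits(h, "hotspot_spec")) stop_config("hotspots must be hotspot_spec objects")
    if (any(h$residue_ids < 1 | h$residue_ids > n_res))
      stop_config("hotspot residue ids must exist in the generated protein (1..%d)", n_res)
    if (!h$species %in% names(composition))
      stop_config("hotspot species '%s' not in composition", h$species)
  }
  structure(list(box = box, n_lipids_total = as.integer(n_lipids_total),
                 composition = composition, hotspots = hotspots,
                 n_frames = as.integer(n_frames),
                 diffusion_step = diffusion_step, seed = as.integer(seed),
                 protein_layout = protein_layout),
            class = "membrane_gen_config")
}

# z geometry of the generated bilayer (nm from midplane)
.headgroup_z <- 2
.tail_z <- c(1.5, 1, 0.5)
.helix_span <- c(-2.2, 2.2)

#' Largest-remainder apportionment of lipid counts
#'
#' Rounds `fractions * n` to integers summing exactly to `n`: floors first,
#' then hands remaining units out by decreasing fractional remainder, ties
#' going to the majority species so any deficit is absorbed there.
#'
#' @param fractions Named molar fractions summing to 1.
#' @param n Total count to apportion.
#' @return Named integer vector summing to `n`.
#' @export
largest_remainder <- function(fractions, n) {
  ideal <- fractions * n
  base <- floor(ideal)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(ideal - base), -fractions)  # remainder desc, majority first
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

.protein_scaffold <- function(cfg) {
  lay <- cfg$protein_layout
  cx <- cfg$box[1] / 2; cy <- cfg$box[2] / 2
  # bilayer midplane sits at Lz/2; all z are box coordinates in [0, Lz)
  zlev <- cfg$box[3] / 2 +
    seq(.helix_span[1], .helix_span[2], length.out = lay$n_res_per_helix)
  rows <- list()
  res_id <- 0L
  for (h in seq_len(lay$n_helices)) {
    ang <- 2 * pi * (h - 1) / lay$n_helices
    hx <- cx + lay$radius * cos(ang)
    hy <- cy + lay$radius * sin(ang)
    for (r in seq_len(lay$n_res_per_helix)) {
      res_id <- res_id + 1L
      for (b in seq_len(lay$beads_per_residue)) {
        off <- if (b == 1) c(0, 0) else
          0.1 * c(cos(2 * pi * b / lay$beads_per_residue),
                  sin(2 * pi * b / lay$beads_per_residue))
        rows[[length(rows) + 1L]] <-
          c(hx + off[1], hy + off[2], zlev[r], res_id, b)
      }
    }
  }
  m <- do.call(rbind, rows)
  list(xyz = m[, 1:3, drop = FALSE], residue_id = as.integer(m[, 4]),
       bead_in_res = as.integer(m[, 5]))
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' @param cfg A [membrane_gen_config()].
#' @return A list with elements `trajectory` (a [new_trajectory()] object),
#'   `topology` (a [bead_topology()] data frame) and `ground_truth` (planted
#'   hotspot residues per species, per-leaflet species counts, and the true
#'   leaflet of every lipid molecule).
#' @export
gen_membrane_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "membrane_gen_config"))
  prot <- .protein_scaffold(cfg)
  n_prot <- nrow(prot$xyz)
  n_per_leaflet <- cfg$n_lipids_total %/% 2L
  counts <- largest_remainder(cfg$composition, n_per_leaflet)

  species <- rep(rep(names(counts), counts), 2)
  leaflet <- rep(c("upper", "lower"), each = n_per_leaflet)
  n_lip <- length(species)
  zsign <- ifelse(leaflet == "upper", 1, -1)

  # per-lipid hotspot bias bookkeeping (leaflet-specific)
  hs_x <- hs_y <- hs_strength <- hs_radius <- NULL
  biased <- rep(FALSE, n_lip)
  if (length(cfg$hotspots)) {
    hs <- lapply(cfg$hotspots, function(h) {
      idx <- prot$residue_id %in% h$residue_ids
      zm <- mean(prot$xyz[idx, 3])
      list(x = mean(prot$xyz[idx, 1]), y = mean(prot$xyz[idx, 2]),
           leaflet = if (zm > cfg$box[3] / 2) "upper" else "lower",
           species = h$species, strength = h$strength, radius = h$radius)
    })
    for (h in hs) biased <- biased | (species == h$species & leaflet == h$leaflet)
    hs_x <- vapply(hs, `[[`, 0, "x"); hs_y <- vapply(hs, `[[`, 0, "y")
    hs_strength <- vapply(hs, `[[`, 0, "strength")
    hs_radius <- vapply(hs, `[[`, 0, "radius")
    hs_species <- vapply(hs, `[[`, "", "species")
    hs_leaflet <- vapply(hs, `[[`, "", "leaflet")
  }

  Lx <- cfg$box[1]; Ly <- cfg$box[2]
  n_bias <- sum(biased)
  coords <- array(NA_real_, dim = c(n_prot + 4L * n_lip, 3, cfg$n_frames))

  local_seed(cfg$seed, {
    x <- stats::runif(n_lip, 0, Lx)
    y <- stats::runif(n_lip, 0, Ly)
    for (f in seq_len(cfg$n_frames)) {
      if (f > 1) {
        dx <- stats::rnorm(n_lip, sd = cfg$diffusion_step)
        dy <- stats::rnorm(n_lip, sd = cfg$diffusion_step)
        u <- if (n_bias) stats::runif(n_bias) else numeric(0)
        if (n_bias) {
          bi <- which(biased)
          # distance to the nearest applicable hotspot, before and after
          d_old <- rep(Inf, n_bias); d_new <- rep(Inf, n_bias)
          near <- rep(NA_integer_, n_bias)
          nx <- wrap_coord(x[bi] + dx[bi], Lx); ny <- wrap_coord(y[bi] + dy[bi], Ly)
          for (k in seq_along(hs_x)) {
            appl <- species[bi] == hs_species[k] & leaflet[bi] == hs_leaflet[k]
            do_k <- sqrt(min_image(x[bi] - hs_x[k], Lx)^2 +
                         min_image(y[bi] - hs_y[k], Ly)^2)
            dn_k <- sqrt(min_image(nx - hs_x[k], Lx)^2 +
                         min_image(ny - hs_y[k], Ly)^2)
            upd <- appl & do_k < d_old
            near[upd] <- k
            d_old[upd] <- do_k[upd]
            d_new[upd] <- dn_k[upd]
          }
          s <- ifelse(is.na(near), 0, hs_strength[near])
          r <- ifelse(is.na(near), Inf, hs_radius[near])
          reject <- d_new > d_old & d_old <= r & u < s / (1 + s)
          dx[bi][reject] <- 0
          dy[bi][reject] <- 0
        }
        x <- wrap_coord(x + dx, Lx)
        y <- wrap_coord(y + dy, Ly)
      }
      lipz <- rbind(.headgroup_z, .tail_z[1], .tail_z[2], .tail_z[3])
      zmat <- cfg$box[3] / 2 + lipz %*% t(zsign)   # 4 x n_lip, box coords
      coords[seq_len(n_prot), , f] <- prot$xyz
      idx <- n_prot + seq_len(4L * n_lip)
      coords[idx, 1, f] <- rep(x, each = 4)
      coords[idx, 2, f] <- rep(y, each = 4)
      coords[idx, 3, f] <- as.vector(zmat)
    }
  })

  topo <- data.frame(
    bead_id = seq_len(n_prot + 4L * n_lip),
    molecule_id = c(rep(1L, n_prot), rep(seq_len(n_lip) + 1L, each = 4)),
    molecule_type = c(rep("protein", n_prot), rep(species, each = 4)),
    residue_id = c(prot$residue_id, rep(NA_integer_, 4L * n_lip)),
    bead_name = c(ifelse(prot$bead_in_res == 1, "BB",
                         paste0("SC", prot$bead_in_res - 1L)),
                  rep(c("PO4", "C1A", "C2A", "C3A"), n_lip)),
    role = c(rep("protein", n_prot),
             rep(c("headgroup", "tail", "tail", "tail"), n_lip)),
    stringsAsFactors = FALSE)
  topo <- bead_topology(topo)

  leaflet_counts <- expand.grid(leaflet = c("upper", "lower"),
                                species = names(counts),
                                stringsAsFactors = FALSE)
  leaflet_counts$n <- as.integer(counts[leaflet_counts$species])

  truth <- list(
    hotspots = lapply(cfg$hotspots, function(h)
      list(species = h$species, residue_ids = h$residue_ids)),
    leaflet_counts = leaflet_counts,
    lipid_leaflet = stats::setNames(leaflet, seq_len(n_lip) + 1L))

  list(trajectory = new_trajectory(coords, matrix(cfg$box, nrow = cfg$n_frames,
                                                  ncol = 3, byrow = TRUE)),
       topology = topo,
       ground_truth = truth)
}
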