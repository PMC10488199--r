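# periodic separable Gaussian smoothing of a matrix (sigma in cells)
.smooth_periodic <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(mat) {
    n <- nrow(mat)
    if (2 * r + 1 > n) {
      # tiny grids: explicit circular convolution
      out <- mat
      for (i in seq_len(n)) {
        idx <- ((i - 1 + (-r:r)) %% n) + 1
        out[i, ] <- colSums(mat[idx, , drop = FALSE] * k)
      }
      return(out)
    }
    ext <- rbind(mat[(n - r + 1):n, , drop = FALSE], mat,
                 mat[1:r, , drop = FALSE])
    f <- stats::filter(ext, k, sides = 2)
    matrix(f[(r + 1):(r + n), ], n, ncol(mat))
  }
  t(smooth1(t(smooth1(m))))
}

# local maxima (strictly greater than all 8 periodic neighbours)
.local_maxima <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sh <- function(di, dj) m[((seq_len(nx) - 1 + di) %% nx) + 1,
                           ((seq_len(ny) - 1 + dj) %% ny) + 1]
  ok <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & (m > sh(di, dj))
  }
  which(ok, arr.ind = TRUE)
}

#' Call lipid interaction sites from an enrichment map
#'
#' Smooths the enrichment map with a periodic Gaussian (sigma
#' `sigma_cells` cells), finds local maxima above `min_enrichment`, merges
#' maxima closer than `merge_radius` (minimum image), and attaches the
#' contact residues of the map's species with probability at least
#' `min_probability` whose mean in-plane position lies within
#' `capture_radius` of the site centroid. Sites are labeled `A`, `B`, ...
#' by decreasing peak enrichment.
#'
#' @param enrichment An [enrichment_map()] for one species and leaflet.
#' @param profile A [contact_probabilities()] result from the same
#'   trajectory.
#' @param residue_pos Residue positions from [residue_positions()].
#' @param min_enrichment Detection threshold on the smoothed map.
#' @param merge_radius Maxima closer than this (nm) are one site.
#' @param capture_radius Residue-to-centroid association radius (nm).
#' @param sigma_cells Smoothing sigma in grid cells.
#' @param min_probability Contact-probability threshold for member residues.
#' @return Data frame of sites (`label`, `leaflet`, `x`, `y`,
#'   `peak_enrichment`, `n_maxima`) with a list column `residues`
#'   (each a data frame `residue_id`, `probability`). Zero rows if no cell
#'   exceeds the threshold.
#' @export
find_sites <- function(enrichment, profile, residue_pos,
                       min_enrichment = 2, merge_radius = 1,
                       capture_radius = 1, sigma_cells = 2,
                       min_probability = 0.05) {
  if (!isTRUE(enrichment$enrichment))
    stop_config("find_sites expects an enrichment map (see enrichment_map())")
  sm <- .smooth_periodic(enrichment$values, sigma_cells)
  mx <- .local_maxima(sm)
  h <- enrichment$spacing
  Lx <- enrichment$box[1]; Ly <- enrichment$box[2]
  empty <- data.frame(label = character(), leaflet = character(),
                      x = numeric(), y = numeric(),
                      peak_enrichment = numeric(), n_maxima = integer())
  empty$residues <- list()
  if (!nrow(mx)) return(empty)
  val <- sm[mx]
  keep <- val > min_enrichment
  if (!any(keep)) return(empty)
  mx <- mx[keep, , drop = FALSE]; val <- val[keep]
  px <- (mx[, 1] - 0.5) * h; py <- (mx[, 2] - 0.5) * h
  ord <- order(-val)
  cl_peak_x <- cl_peak_y <- cl_val <- numeric(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    if (length(cl_val)) {
      d <- sqrt(min_image(px[i] - cl_peak_x, Lx)^2 +
                min_image(py[i] - cl_peak_y, Ly)^2)
      j <- which.min(d)
      if (d[j] <= merge_radius) {
        members[[j]] <- c(members[[j]], i)
        placed <- TRUE
      }
    }
    if (!placed) {
      cl_peak_x <- c(cl_peak_x, px[i]); cl_peak_y <- c(cl_peak_y, py[i])
      cl_val <- c(cl_val, val[i])
      members[[length(members) + 1L]] <- i
    }
  }
  # enrichment-weighted centroid per cluster (min image relative to peak)
  cx <- cy <- numeric(length(members))
  for (j in seq_along(members)) {
    m <- members[[j]]
    w <- val[m] / sum(val[m])
    cx[j] <- wrap_coord(cl_peak_x[j] +
                          sum(w * min_image(px[m] - cl_peak_x[j], Lx)), Lx)
    cy[j] <- wrap_coord(cl_peak_y[j] +
                          sum(w * min_image(py[m] - cl_peak_y[j], Ly)), Ly)
  }
  pr <- profile[profile$species == enrichment$species &
                  profile$probability >= min_probability, , drop = FALSE]
  rp <- merge(pr, residue_pos, by = "residue_id")
  res_list <- lapply(seq_along(members), function(j) {
    if (!nrow(rp)) return(data.frame(residue_id = integer(),
                                     probability = numeric()))
    d <- sqrt(min_image(rp$x - cx[j], Lx)^2 + min_image(rp$y - cy[j], Ly)^2)
    sel <- rp[d <= capture_radius, c("residue_id", "probability")]
    sel[order(-sel$probability), ]
  })
  labels <- c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))
  out <- data.frame(label = labels[seq_along(members)],
                    leaflet = enrichment$leaflet,
                    x = cx, y = cy, peak_enrichment = cl_val,
                    n_maxima = lengths(members))
  out$residues <- res_list
  out
}
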