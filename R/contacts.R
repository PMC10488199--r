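# Precompute index structures for the contact engine.
# Protein beads are grouped by residue, lipid headgroup beads by molecule;
# lipid groups are ordered by molecule_id so that ties at equal distance
# resolve to the lowest lipid id.
.contact_index <- function(topology) {
  prot_rows <- which(topology$role == "protein")
  prot_rows <- prot_rows[order(topology$residue_id[prot_rows])]
  prot_res_id <- topology$residue_id[prot_rows]
  res_ids <- unique(prot_res_id)
  head_rows <- which(topology$role == "headgroup")
  head_rows <- head_rows[order(topology$molecule_id[head_rows])]
  head_lip_id <- topology$molecule_id[head_rows]
  lip_ids <- unique(head_lip_id)
  species <- topology$molecule_type[head_rows][match(lip_ids, head_lip_id)]
  list(prot_rows = prot_rows, prot_res = match(prot_res_id, res_ids),
       res_ids = res_ids, one_bead_res = !anyDuplicated(prot_res_id),
       head_rows = head_rows, head_lip = match(head_lip_id, lip_ids),
       lip_ids = lip_ids, one_bead_lip = !anyDuplicated(head_lip_id),
       species = species)
}

# min-reduce rows of matrix m over groups g (1..n); rows already grouped
.group_min_rows <- function(m, g, n) {
  if (n == nrow(m)) return(m)
  out <- matrix(Inf, n, ncol(m))
  for (i in seq_len(nrow(m))) out[g[i], ] <- pmin(out[g[i], ], m[i, ])
  out
}

.detect_contacts_idx <- function(xyz, box, ci, cutoff, min_beads = 1L) {
  px <- xyz[ci$prot_rows, 1]; py <- xyz[ci$prot_rows, 2]; pz <- xyz[ci$prot_rows, 3]
  hx <- xyz[ci$head_rows, 1]; hy <- xyz[ci$head_rows, 2]; hz <- xyz[ci$head_rows, 3]
  dx <- abs(outer(px, hx, `-`)); dx <- pmin(dx, box[1] - dx)
  dy <- abs(outer(py, hy, `-`)); dy <- pmin(dy, box[2] - dy)
  dz <- outer(pz, hz, `-`)
  d2b <- dx * dx + dy * dy + dz * dz             # bead-level distances
  d2 <- d2b
  if (!ci$one_bead_res) d2 <- .group_min_rows(d2, ci$prot_res, length(ci$res_ids))
  if (!ci$one_bead_lip) d2 <- t(.group_min_rows(t(d2), ci$head_lip, length(ci$lip_ids)))
  j <- max.col(-d2, ties.method = "first")      # nearest lipid, lowest id on ties
  best <- d2[cbind(seq_along(j), j)]
  hit <- best <= cutoff^2
  if (min_beads > 1L && any(hit)) {
    # stricter reading: the nearest lipid must have >= min_beads protein
    # beads of the residue within the cutoff
    for (r in which(hit)) {
      rows <- which(ci$prot_res == r)
      cols <- which(ci$head_lip == j[r])
      n_in <- sum(apply(d2b[rows, cols, drop = FALSE], 1, min) <= cutoff^2)
      if (n_in < min_beads) hit[r] <- FALSE
    }
  }
  data.frame(residue_id = ci$res_ids[hit], lipid_id = ci$lip_ids[j[hit]],
             species = ci$species[j[hit]],
             distance = sqrt(best[hit]))
}

#' Detect residue-lipid headgroup contacts in one frame
#'
#' A protein residue contacts the lipid whose headgroup beads come closest
#' to any of the residue's beads, and only that lipid, provided that minimum
#' distance is at most `cutoff`: no other lipid may be closer ("nearest
#' lipid" exclusivity, applied across all species). Distances use the
#' minimum-image convention in x and y (the membrane plane); z is treated
#' as non-periodic. Ties at exactly equal distance go to the lowest lipid
#' id. Each residue therefore has at most one contact per frame.
#'
#' @param frame A frame as returned by [get_frame()].
#' @param topology The matching [bead_topology()].
#' @param cutoff Contact cutoff in nm (default 0.55).
#' @param min_beads Minimum number of the residue's beads that must lie
#'   within the cutoff of the nearest lipid (default 1, a single
#'   qualifying pair; 2 gives the stricter multi-bead reading).
#' @return Data frame with `residue_id`, `lipid_id`, `species`, `distance`.
#' @export
detect_contacts <- function(frame, topology, cutoff = 0.55, min_beads = 1L) {
  ci <- .contact_index(topology)
  .detect_contacts_idx(frame$xyz, frame$box, ci, cutoff, min_beads)
}

#' Per-residue, per-species contact probabilities over a trajectory
#'
#' Counts, for every protein residue and lipid species, the frames in which
#' the residue's exclusive nearest-lipid contact is a lipid of that species,
#' and normalizes by the number of frames. Pass a list of trajectories to
#' concatenate replicas before normalization.
#'
#' @param traj A `cg_trajectory` or a list of them (replicas).
#' @param topology The matching [bead_topology()].
#' @param cutoff Contact cutoff in nm.
#' @param min_beads Passed to [detect_contacts()].
#' @return A `contact_profile` data frame (`residue_id`, `species`, `count`,
#'   `probability`) with attribute `frames`.
#' @export
contact_probabilities <- function(traj, topology, cutoff = 0.55,
                                  min_beads = 1L) {
  if (inherits(traj, "cg_trajectory")) traj <- list(traj)
  ci <- .contact_index(topology)
  spp <- sort(unique(ci$species))
  counts <- matrix(0L, length(ci$res_ids), length(spp),
                   dimnames = list(NULL, spp))
  total <- 0L
  for (tr in traj) {
    for (f in seq_len(n_frames(tr))) {
      cc <- .detect_contacts_idx(tr$coords[, , f, drop = TRUE], tr$box[f, ],
                                 ci, cutoff, min_beads)
      if (nrow(cc)) {
        idx <- cbind(match(cc$residue_id, ci$res_ids), match(cc$species, spp))
        counts[idx] <- counts[idx] + 1L
      }
    }
    total <- total + n_frames(tr)
  }
  out <- data.frame(residue_id = rep(ci$res_ids, length(spp)),
                    species = rep(spp, each = length(ci$res_ids)),
                    count = as.vector(counts),
                    probability = as.vector(counts) / total)
  attr(out, "frames") <- total
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Label and highlight contact residues by probability thresholds
#'
#' Residues with contact probability above 15% are labeled; residues at or
#' above 5% are highlighted (the display conventions of the contact maps).
#'
#' @param profile A [contact_probabilities()] result.
#' @param species Lipid species to report.
#' @param label_threshold Labeling threshold (default 0.15).
#' @param highlight_threshold Highlighting threshold (default 0.05).
#' @return The species subset with logical columns `labeled`, `highlighted`.
#' @export
contact_report <- function(profile, species,
                           label_threshold = 0.15,
                           highlight_threshold = 0.05) {
  p <- profile[profile$species == species, , drop = FALSE]
  p$labeled <- p$probability > label_threshold
  p$highlighted <- p$probability >= highlight_threshold
  p[order(-p$probability), ]
}
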