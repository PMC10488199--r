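# Independent oracles and fixture builders used across the suite.

# Build a one-frame toy system from explicit bead tables.
# prot: data.frame(residue_id, x, y, z); heads: data.frame(molecule_id,
# species, x, y, z) -- one row per headgroup bead.
toy_system <- function(prot, heads, box = c(10, 10, 6)) {
  topo <- data.frame(
    bead_id = seq_len(nrow(prot) + nrow(heads)),
    molecule_id = c(rep(1L, nrow(prot)), heads$molecule_id),
    molecule_type = c(rep("protein", nrow(prot)), heads$species),
    residue_id = c(prot$residue_id, rep(NA_integer_, nrow(heads))),
    bead_name = c(rep("BB", nrow(prot)), rep("PO4", nrow(heads))),
    role = c(rep("protein", nrow(prot)), rep("headgroup", nrow(heads))),
    stringsAsFactors = FALSE)
  xyz <- rbind(as.matrix(prot[, c("x", "y", "z")]),
               as.matrix(heads[, c("x", "y", "z")]))
  dimnames(xyz) <- NULL
  list(frame = list(xyz = xyz, box = box), topology = bead_topology(topo))
}

# Random multi-bead system: n_res residues x bpr beads, n_lip lipids x hpl
# headgroup beads, uniform positions.
rand_system <- function(n_res = 10, bpr = 3, n_lip = 30, hpl = 2,
                        box = c(10, 10, 6)) {
  np <- n_res * bpr
  prot <- data.frame(residue_id = rep(seq_len(n_res), each = bpr),
                     x = runif(np, 0, box[1]), y = runif(np, 0, box[2]),
                     z = runif(np, 0, box[3]))
  nh <- n_lip * hpl
  heads <- data.frame(molecule_id = rep(seq_len(n_lip) + 1L, each = hpl),
                      species = rep(sample(c("PS", "PC"), n_lip, TRUE),
                                    each = hpl),
                      x = runif(nh, 0, box[1]), y = runif(nh, 0, box[2]),
                      z = runif(nh, 0, box[3]))
  toy_system(prot, heads, box)
}

# Exhaustive O(res x lip x beads^2) contact oracle implementing the rule
# directly: minimum-image distance in x/y, plain z, nearest lipid wins
# (lowest molecule_id on ties), contact iff within cutoff.
brute_contacts <- function(frame, topo, cutoff = 0.55) {
  box <- frame$box
  res_ids <- sort(unique(topo$residue_id[topo$role == "protein"]))
  lip_ids <- sort(unique(topo$molecule_id[topo$role == "headgroup"]))
  out <- NULL
  for (r in res_ids) {
    pr <- which(topo$role == "protein" & topo$residue_id == r)
    best_d <- Inf; best_l <- NA
    for (l in lip_ids) {
      hb <- which(topo$role == "headgroup" & topo$molecule_id == l)
      dmin <- Inf
      for (i in pr) for (j in hb) {
        dx <- frame$xyz[i, 1] - frame$xyz[j, 1]
        dx <- dx - round(dx / box[1]) * box[1]
        dy <- frame$xyz[i, 2] - frame$xyz[j, 2]
        dy <- dy - round(dy / box[2]) * box[2]
        dz <- frame$xyz[i, 3] - frame$xyz[j, 3]
        d <- sqrt(dx^2 + dy^2 + dz^2)
        if (d < dmin) dmin <- d
      }
      if (dmin < best_d) { best_d <- dmin; best_l <- l }
    }
    if (best_d <= cutoff)
      out <- rbind(out, data.frame(residue_id = r, lipid_id = best_l))
  }
  if (is.null(out)) data.frame(residue_id = integer(), lipid_id = integer())
  else out
}

# Closed-form OLS slope.
ols_slope <- function(t, y) sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)

# Hand-coded Tukey-Kramer oracle (means, pooled MSE, studentized range).
tukey_oracle <- function(groups) {
  k <- length(groups); n <- lengths(groups)
  means <- vapply(groups, mean, 0)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (sum(n) - k)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    se <- sqrt(mse / 2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    q <- abs(means[pr[2]] - means[pr[1]]) / se
    data.frame(group1 = pr[1], group2 = pr[2],
               p = stats::ptukey(q, k, sum(n) - k, lower.tail = FALSE))
  }))
}

# All cliques of the non-significance graph (adjacency matrix), for the
# minimal-letter-count enumeration oracle.
all_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  for (sz in seq_len(n)) {
    for (sel in utils::combn(n, sz, simplify = FALSE)) {
      sub <- adj[sel, sel, drop = FALSE]
      diag(sub) <- TRUE
      if (all(sub)) out[[length(out) + 1L]] <- sel
    }
  }
  out
}

# Minimal number of letters: smallest family of cliques covering every
# ns-edge and every group.
min_letters_oracle <- function(adj) {
  n <- nrow(adj)
  cl <- all_cliques(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edge_in <- function(sel) {
    if (!nrow(edges)) return(TRUE)
    all(apply(edges, 1, function(e) any(vapply(sel, function(s)
      all(e %in% s), TRUE))))
  }
  for (t in seq_len(length(cl))) {
    for (fam in utils::combn(length(cl), t, simplify = FALSE)) {
      sel <- cl[fam]
      if (length(unique(unlist(sel))) == n && edge_in(sel)) return(t)
    }
  }
  stop("no cover found")
}

# Grid-search + Levenberg-free polish oracle for the Boltzmann V50.
v50_grid_oracle <- function(x, y) {
  vs <- seq(min(x), max(x), length.out = 400)
  sl <- seq(0.2, (max(x) - min(x)) / 2, length.out = 120)
  best <- c(Inf, NA)
  for (v in vs) for (s in sl) {
    f <- 1 / (1 + exp((x - v) / s))
    # linear in (bottom, top-bottom): solve by least squares
    A <- cbind(1, f)
    cf <- tryCatch(qr.solve(A, y), error = function(e) NULL)
    if (is.null(cf)) next
    rss <- sum((A %*% cf - y)^2)
    if (rss < best[1]) best <- c(rss, v)
  }
  best[2]
}

# standard hotspot test fixture: two PS sites on opposite helices, hosted
# by the two headgroup-level residues of each helix
hotspot_fixture <- function(strength, seed, n_frames = 400, radius = 1) {
  hs <- list(hotspot_spec(c(11L, 12L), "PS", strength, radius),
             hotspot_spec(c(71L, 72L), "PS", strength, radius))
  cfg <- membrane_gen_config(n_frames = n_frames, hotspots = hs, seed = seed)
  list(cfg = cfg, planted = c(11L, 12L, 71L, 72L),
       out = gen_membrane_trajectory(cfg))
}
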