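#' Bead-resolved trajectory container
#'
#' @param coords Numeric array `[n_beads, 3, n_frames]`, coordinates in nm.
#' @param box Numeric matrix `[n_frames, 3]` of box lengths `(Lx, Ly, Lz)` nm.
#' @return A `cg_trajectory` object.
#' @export
new_trajectory <- function(coords, box) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  box <- matrix(box, ncol = 3)
  if (nrow(box) != dim(coords)[3])
    stop_config("box must have one row per frame")
  if (any(box <= 0)) stop_config("box dimensions must be positive")
  structure(list(coords = coords, box = box), class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d beads, %d frames, box %.2f x %.2f x %.2f nm\n",
              dim(x$coords)[1], n_frames(x),
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Validate a bead topology table
#'
#' Columns: `bead_id`, `molecule_id`, `molecule_type` (`"protein"` or a lipid
#' species name), `residue_id` (1-based, protein beads only), `bead_name`,
#' `role` (`protein` / `headgroup` / `tail`). Every lipid molecule must carry
#' at least one headgroup bead; protein residue ids must be contiguous.
#'
#' @param df Data frame with the columns above.
#' @return The validated data frame with class `bead_topology`.
#' @export
bead_topology <- function(df) {
  need <- c("bead_id", "molecule_id", "molecule_type", "residue_id",
            "bead_name", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_config("topology lacks columns: %s",
                                paste(miss, collapse = ", "))
  if (!all(df$role %in% c("protein", "headgroup", "tail")))
    stop_config("role must be protein/headgroup/tail")
  lip <- df[df$role != "protein", ]
  if (nrow(lip)) {
    has_head <- tapply(lip$role == "headgroup", lip$molecule_id, any)
    if (!all(has_head))
      stop_config("lipid molecule(s) without headgroup bead: %s",
                  paste(names(has_head)[!has_head], collapse = ", "))
  }
  prot <- df[df$role == "protein", ]
  if (nrow(prot)) {
    rid <- sort(unique(prot$residue_id))
    if (any(is.na(rid)) || !identical(rid, seq(min(rid), max(rid))))
      stop_config("protein residue ids must be contiguous")
  }
  class(df) <- c("bead_topology", "data.frame")
  df
}

#' Write / read the topology TSV
#' @param topo A [bead_topology()].
#' @param path TSV path.
#' @export
write_topology <- function(topo, path) {
  utils::write.table(as.data.frame(topo), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  bead_topology(df)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' One GRO block per frame (title, atom count, fixed-width atom records with
#' positions in nm to 0.001 nm, box line).
#'
#' @param traj A `cg_trajectory`.
#' @param topology The matching [bead_topology()].
#' @param path Output path.
#' @export
write_gro <- function(traj, topology, path) {
  n <- dim(traj$coords)[1]
  if (n != nrow(topology)) stop_config("trajectory/topology bead counts differ")
  resnum <- topology$molecule_id %% 100000L
  atomnum <- topology$bead_id %% 100000L
  resname <- substr(ifelse(topology$role == "protein", "PROT",
                           topology$molecule_type), 1, 5)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , f]
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resnum, resname, substr(topology$bead_name, 1, 5),
                     atomnum, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(sprintf("frame %d", f), sprintf("%5d", n), lines,
                 sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1],
                         traj$box[f, 2], traj$box[f, 3])), con)
  }
  invisible(path)
}

.read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) ) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n)) stop_config("malformed GRO at line %d: bad atom count", i + 1L)
    if (i + 1L + n + 1L > length(lines))
      stop_config("truncated GRO frame starting at line %d", i)
    at <- lines[(i + 2L):(i + 1L + n)]
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop_config("malformed GRO coordinates in frame starting at line %d", i)
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    bx <- as.numeric(strsplit(trimws(lines[i + 1L + n + 1L]), "\\s+")[[1]])
    boxes[[length(boxes) + 1L]] <- bx[1:3]
    i <- i + n + 3L
  }
  list(frames = frames, boxes = boxes)
}

#' Read a trajectory with its bead topology
#'
#' Accepts one or more multi-frame GRO files (or multi-MODEL PDB files with
#' coordinates in Angstrom, converted to nm); replica files are concatenated
#' in the order given.
#'
#' @param paths Character vector of trajectory files.
#' @param topology_path Path to the topology TSV (see [write_topology()]).
#' @return List with `trajectory` and `topology`.
#' @export
read_trajectory <- function(paths, topology_path) {
  topo <- read_topology(topology_path)
  frames <- list(); boxes <- list()
  for (p in paths) {
    got <- if (grepl("\\.pdb$", p, ignore.case = TRUE)) .read_pdb_frames(p)
           else .read_gro_frames(p)
    for (k in seq_along(got$frames)) {
      if (nrow(got$frames[[k]]) != nrow(topo))
        stop_config("frame %d of %s has %d beads but topology has %d",
                    k, p, nrow(got$frames[[k]]), nrow(topo))
    }
    frames <- c(frames, got$frames)
    boxes <- c(boxes, got$boxes)
  }
  if (!length(frames)) stop_config("no frames found in input")
  coords <- array(unlist(frames), dim = c(nrow(topo), 3, length(frames)))
  list(trajectory = new_trajectory(coords, do.call(rbind, boxes)),
       topology = topo)
}

# minimal multi-MODEL PDB reader (ATOM/HETATM records, Angstrom -> nm)
.read_pdb_frames <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_break <- cumsum(rec == "MODEL ")
  if (max(model_break) == 0) model_break <- rep(1L, length(lines))
  cryst <- lines[rec == "CRYST1"]
  box <- if (length(cryst)) as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33))) / 10
         else stop_config("PDB lacks a CRYST1 record; box unknown")
  frames <- list()
  for (m in unique(model_break[is_atom])) {
    at <- lines[is_atom & model_break == m]
    frames[[length(frames) + 1L]] <-
      cbind(as.numeric(substr(at, 31, 38)),
            as.numeric(substr(at, 39, 46)),
            as.numeric(substr(at, 47, 54))) / 10
  }
  list(frames = frames, boxes = rep(list(box), length(frames)))
}
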