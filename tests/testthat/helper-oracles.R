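## Independent oracles, deliberately coded by different routes than the
## package implementations they cross-check.

## Signed dihedral via projection onto the plane perpendicular to the
## central bond (clockwise positive viewed from p2 towards p3).
oracle_dihedral <- function(p1, p2, p3, p4) {
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2); u <- u - sum(u * b) * b
  w <- (p4 - p3); w <- w - sum(w * b) * b
  atan2(sum(b * cross(w, u)), sum(u * w)) * 180 / pi
}

## Minimal OpenDX scalar-field reader: returns origin, spacing (per axis),
## counts and the value array with the file's z-fastest ordering undone.
oracle_read_dx <- function(path) {
  lines <- readLines(path)
  counts <- as.integer(strsplit(
    sub(".*gridpositions counts ", "",
        grep("gridpositions", lines, value = TRUE)[1]), "\\s+")[[1]])
  origin <- as.numeric(strsplit(
    sub("^origin ", "", grep("^origin", lines, value = TRUE)[1]),
    "\\s+")[[1]])
  deltas <- t(vapply(grep("^delta", lines, value = TRUE),
                     function(l) as.numeric(strsplit(sub("^delta ", "", l),
                                                     "\\s+")[[1]]),
                     numeric(3)))
  start <- grep("data follows", lines) + 1
  end <- grep("^attribute", lines)[1] - 1
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+"))))
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  list(counts = counts, origin = origin, spacing = diag(deltas),
       values = arr)
}

## Bottleneck (minimax) level between two voxels by Dijkstra widest-path:
## best[v] = minimal over paths of the maximal value along the path.
oracle_minimax_level <- function(values, mask, a, b) {
  dims <- dim(values)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ijk_of <- function(lin) {
    lin0 <- lin - 1
    c(lin0 %% dims[1], (lin0 %/% dims[1]) %% dims[2],
      lin0 %/% (dims[1] * dims[2])) + 1
  }
  lin_of <- function(ijk)
    (ijk[1] - 1) + dims[1] * ((ijk[2] - 1) + dims[2] * (ijk[3] - 1)) + 1
  n <- length(values)
  best <- rep(Inf, n)
  best[a] <- values[a]
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(best))
    if (!length(cand)) return(NA_real_)
    u <- cand[which.min(best[cand])]
    if (u == b) return(best[b])
    done[u] <- TRUE
    ijk <- ijk_of(u)
    for (r in seq_len(nrow(offs))) {
      nb <- ijk + offs[r, ]
      if (any(nb < 1) || any(nb > dims)) next
      v <- lin_of(nb)
      if (mask[v]) next
      best[v] <- min(best[v], max(best[u], values[v]))
    }
  }
}

## Coordinates of a named atom in a structure_model fixture.
fixture_xyz <- function(st, name)
  as.numeric(st[trimws(st$name) == name, c("x", "y", "z")])

## Small deterministic multi-atom trajectory for IO tests.
toy_trajectory <- function(n_frames = 3, n_atoms = 4, seed = 1,
                           stride_ps = 50) {
  set.seed(seed)
  coords <- array(round(runif(n_frames * n_atoms * 3, -20, 60), 3),
                  c(n_frames, n_atoms, 3))
  atoms <- data.frame(name = c("O1", "O2", "CA", "CB")[seq_len(n_atoms)],
                      resname = "UNK", resno = seq_len(n_atoms),
                      chain = "A",
                      element = c("O", "O", "C", "C")[seq_len(n_atoms)],
                      stringsAsFactors = FALSE)
  trajectory(coords, atoms,
             times_ns = (seq_len(n_frames) - 1) * stride_ps / 1000)
}
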