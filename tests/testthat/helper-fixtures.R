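# Shared fixtures and independent brute-force oracles.

# three-tip tree with hand-checkable path sums:
# d(A,B) = 2, d(A,C) = d(B,C) = 4; total branch length 5
abc_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# star tree: k tips, each on a unit branch from the root
star_tree <- function(k = 3) {
  ape::read.tree(text = paste0(
    "(", paste(LETTERS[seq_len(k)], ":1", collapse = ","), ");"))
}

tiny_stems <- function() {
  data.frame(
    stem_id = c("s1", "s2", "s3"),
    x = c(1, 6, 12), y = c(1, 2, 3),
    species = c("A", "B", "A"),
    dbh_cm = c(10, 20, 4),
    stringsAsFactors = FALSE
  )
}

random_stems <- function(n, side, n_species = 10, seed = 1) {
  withr::with_seed(seed, data.frame(
    stem_id = sprintf("r%04d", seq_len(n)),
    x = runif(n, 0, side), y = runif(n, 0, side),
    species = sample(sprintf("sp%02d", seq_len(n_species)), n, replace = TRUE),
    dbh_cm = 1 + rlnorm(n, 1.3, 1),
    stringsAsFactors = FALSE
  ))
}

# --- independent oracles ------------------------------------------------

# MPD/MNTD by explicit double loops over the present species
oracle_mpd <- function(species, dmat) {
  sp <- unique(species)
  if (length(sp) < 2) return(NA_real_)
  tot <- 0; k <- 0
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i < j) { tot <- tot + dmat[sp[i], sp[j]]; k <- k + 1 }
  }
  tot / k
}

oracle_mntd <- function(species, dmat) {
  sp <- unique(species)
  if (length(sp) < 2) return(NA_real_)
  mean(vapply(sp, function(a) min(dmat[a, setdiff(sp, a)]), numeric(1)))
}

# PD as the total length of edges on any root-to-tip path of the community,
# found via ape::nodepath (machinery independent of faith_pd's edge marking)
oracle_pd <- function(species, tree) {
  sp <- unique(species)
  if (!length(sp)) return(0)
  root <- length(tree$tip.label) + 1L
  edges <- unique(do.call(rbind, lapply(match(sp, tree$tip.label), function(tip) {
    p <- ape::nodepath(tree, from = root, to = tip)
    cbind(p[-length(p)], p[-1])
  })))
  sum(apply(edges, 1L, function(e) {
    tree$edge.length[which(tree$edge[, 1] == e[1] & tree$edge[, 2] == e[2])]
  }))
}

# Hegyi CI by the O(n^2) double loop
oracle_hegyi <- function(table, radius) {
  n <- nrow(table)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((table$x[i] - table$x[j])^2 + (table$y[i] - table$y[j])^2)
      if (d > 0 && d <= radius) {
        ci[i] <- ci[i] + (table$dbh_cm[j] / table$dbh_cm[i]) / d
      }
    }
  }
  ci
}

# windowed terrain metrics by an explicit per-cell 3x3 loop, with the same
# edge rules as the implementation (available neighbours; Horn replicates
# the focal cell for missing neighbours)
oracle_window <- function(z, fun) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    nbr <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) nbr <- c(nbr, z[rr, cc])
    }
    out[r, c] <- fun(z[r, c], nbr)
  }
  out
}

oracle_tpi <- function(z) oracle_window(z, function(ctr, nbr) ctr - mean(nbr))
oracle_tri <- function(z) oracle_window(z, function(ctr, nbr)
  sqrt(mean((nbr - mean(nbr))^2)))
oracle_roughness <- function(z) oracle_window(z, function(ctr, nbr)
  max(c(ctr, nbr)) - min(c(ctr, nbr)))

oracle_horn_slope <- function(z, cell) {
  nr <- nrow(z); nc <- ncol(z)
  at <- function(r, c) z[min(max(r, 1), nr), min(max(c, 1), nc)]
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx <- ((at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
           (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))) / (8 * cell)
    gy <- ((at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1)) -
           (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1))) / (8 * cell)
    out[r, c] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  out
}

# plane DEM helpers: z = a*x + b*y + c on a cell-centre grid (row 1 = north)
plane_dem <- function(n, cell, a = 0, b = 0, c = 0) {
  xs <- (seq_len(n) - 0.5) * cell
  ys <- (n - seq_len(n) + 0.5) * cell
  dem_grid(c + outer(ys * b, xs * a, `+`), cell = cell)
}
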