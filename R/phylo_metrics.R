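#' Cophenetic (tip-to-tip) distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips,
#' ordered as `tree$tip.label`.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning the community's
#' species and the root (root-inclusive, so a single-species community has
#' PD equal to that tip's depth, and the full community's PD equals the
#' total tree length). An empty community has PD 0.
#'
#' @param species character vector of species present (must be tips).
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return PD in branch-length units.
#' @export
faith_pd <- function(species, tree) {
  species <- unique(species)
  if (length(species) == 0) return(0)
  idx <- match(species, tree$tip.label)
  if (anyNA(idx)) {
    stop("species not in tree: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  parent <- parent_edges(tree)
  marked <- logical(length(parent$parent))
  for (tip in idx) {
    node <- tip
    while (!is.na(parent$edge_of[node]) && !marked[node]) {
      marked[node] <- TRUE
      node <- parent$parent[node]
    }
  }
  sum(tree$edge.length[parent$edge_of[marked]])
}

# parent node and incoming-edge row per node (NA at the root)
parent_edges <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, nn)
  edge_of <- rep(NA_integer_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  list(parent = parent, edge_of = edge_of)
}

#' Mean pairwise and mean nearest-taxon distance
#'
#' Presence-based (unweighted): `mpd()` averages the cophenetic distance
#' over all unordered pairs of distinct species present; `mntd()` averages,
#' over species present, the distance to the nearest other species present.
#' Both are undefined (NA) for communities of fewer than two species.
#'
#' @param species character vector of species present.
#' @param dmat cophenetic distance matrix (from [cophenetic_distances()]).
#' @return a single numeric value (NA if fewer than 2 species).
#' @export
mpd <- function(species, dmat) {
  i <- match(unique(species), rownames(dmat))
  if (anyNA(i)) stop("species not in distance matrix", call. = FALSE)
  s <- length(i)
  if (s < 2) return(NA_real_)
  sum(dmat[i, i]) / (s * (s - 1))
}

#' @rdname mpd
#' @export
mntd <- function(species, dmat) {
  i <- match(unique(species), rownames(dmat))
  if (anyNA(i)) stop("species not in distance matrix", call. = FALSE)
  s <- length(i)
  if (s < 2) return(NA_real_)
  m <- dmat[i, i]
  diag(m) <- Inf
  mean(m[cbind(seq_len(s), max.col(-m, ties.method = "first"))])
}

#' Null-model configuration for standardized effect sizes
#'
#' The null shuffles the tip labels of the cophenetic distance matrix
#' (`taxa_shuffle`): observed community composition, richness and occupancy
#' are held fixed while species identities are randomized across the pool
#' (all species present in the community matrix).
#'
#' @param method currently only `"taxa_shuffle"`.
#' @param n_rand number of randomizations (default 999; fewer than 99 gives
#'   a warning because the resulting SES is too noisy to report).
#' @param seed integer RNG seed; the same seed reproduces NRI/NTI exactly.
#' @return an object of class `"null_model_config"`.
#' @export
null_model_config <- function(method = "taxa_shuffle", n_rand = 999, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.numeric(n_rand), n_rand >= 1)
  if (n_rand < 99) warning("n_rand < 99: standardized effect sizes will be noisy")
  structure(list(method = method, n_rand = as.integer(n_rand),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Per-quadrat phylogenetic structure metrics with a randomization null
#'
#' For every quadrat (row) of a community matrix, computes SR, Faith's PD,
#' MPD and MNTD, and their standardized effect sizes against a tip-label
#' shuffle null:
#' `NRI = -(MPD_obs - mean(MPD_null)) / sd(MPD_null)` and NTI likewise from
#' MNTD. Positive values indicate phylogenetic clustering, negative values
#' overdispersion. Quadrats with fewer than two species, or whose null
#' distribution is degenerate (zero sd, e.g. a community containing the
#' whole pool), get NA and `valid = FALSE`. Two-sided rank p-values of the
#' observed MPD/MNTD within the null distribution are also returned.
#'
#' @param cm community matrix from [build_community_matrix()].
#' @param tree phylogeny covering all matrix species (extra tips are pruned).
#' @param cfg a [null_model_config()].
#' @return `data.frame` with one row per quadrat: `quadrat`, `sr`, `pd`,
#'   `mpd_obs`, `mntd_obs`, null means/sds, `nri`, `nti`, `mpd_p`,
#'   `mntd_p`, `valid`.
#' @export
ses_metrics <- function(cm, tree, cfg = null_model_config()) {
  stopifnot(inherits(cfg, "null_model_config"))
  species <- colnames(cm)
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    stop("community species absent from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ptree <- if (length(setdiff(tree$tip.label, species))) {
    prune_to_species(tree, species)
  } else tree
  dmat <- cophenetic_distances(ptree)[species, species, drop = FALSE]
  S <- length(species)
  Q <- nrow(cm)

  idx <- apply(cm > 0, 1L, which, simplify = FALSE)
  sr <- lengths(idx)
  pd <- vapply(idx, function(i) faith_pd(species[i], ptree), numeric(1))

  pair_stats <- function(i) {
    s <- length(i)
    m <- dmat[i, i]
    mpd_v <- sum(m) / (s * (s - 1))
    diag(m) <- Inf
    mntd_v <- mean(m[cbind(seq_len(s), max.col(-m, ties.method = "first"))])
    c(mpd_v, mntd_v)
  }
  live <- which(sr >= 2)
  obs <- matrix(NA_real_, Q, 2L)
  for (q in live) obs[q, ] <- pair_stats(idx[[q]])

  n_rand <- cfg$n_rand
  sum1 <- matrix(0, Q, 2L); sum2 <- matrix(0, Q, 2L)
  less <- matrix(0L, Q, 2L); eq <- matrix(0L, Q, 2L)
  with_seed(cfg$seed, {
    for (r in seq_len(n_rand)) {
      perm <- sample.int(S)
      for (q in live) {
        v <- pair_stats(perm[idx[[q]]])
        sum1[q, ] <- sum1[q, ] + v
        sum2[q, ] <- sum2[q, ] + v^2
        less[q, ] <- less[q, ] + (v < obs[q, ] - 1e-12)
        eq[q, ] <- eq[q, ] + (abs(v - obs[q, ]) <= 1e-12)
      }
    }
  })
  null_mean <- sum1 / n_rand
  null_sd <- sqrt(pmax(sum2 / n_rand - null_mean^2, 0) * n_rand / (n_rand - 1))
  dead <- setdiff(seq_len(Q), live)
  null_mean[dead, ] <- NA_real_
  null_sd[dead, ] <- NA_real_

  # a null sd at (floating-point) zero means every shuffle returns the same
  # value — e.g. the community holds the whole pool — and the SES is undefined
  sd_tol <- 1e-6 * pmax(abs(null_mean), 1)
  degenerate_col <- !is.na(obs) & null_sd <= sd_tol
  null_sd[degenerate_col] <- NA_real_
  ses <- -(obs - null_mean) / null_sd
  ses[!is.finite(ses)] <- NA_real_
  # two-sided rank p: rank of the observation among (nulls + itself)
  rank_obs <- less + 0.5 * eq + 1
  pval <- 2 * pmin(rank_obs, n_rand + 2 - rank_obs) / (n_rand + 1)
  pval <- pmin(pval, 1)
  pval[is.na(obs)] <- NA_real_
  degenerate <- degenerate_col[, 1L]

  data.frame(
    quadrat = as.integer(rownames(cm)),
    sr = as.integer(sr),
    pd = pd,
    mpd_obs = obs[, 1L], mntd_obs = obs[, 2L],
    mpd_null_mean = null_mean[, 1L], mpd_null_sd = null_sd[, 1L],
    mntd_null_mean = null_mean[, 2L], mntd_null_sd = null_sd[, 2L],
    nri = ses[, 1L], nti = ses[, 2L],
    mpd_p = pval[, 1L], mntd_p = pval[, 2L],
    valid = sr >= 2 & !degenerate,
    row.names = NULL
  )
}

#' Stage-level summary of NRI/NTI against zero
#'
#' Mean, standard error and a two-sided one-sample t-test against 0 of NRI
#' and NTI over valid quadrats, per (scale, stage) group — the tabular
#' analogue of a violin plot of quadrat SES values against the null line.
#' Groups with fewer than 3 valid quadrats are flagged and left NA.
#'
#' @param rows metric table with columns `scale`, `stage`, `nri`, `nti`.
#' @return `data.frame` with one row per (scale, stage):
#'   `n`, `nri_mean`, `nri_se`, `nri_t`, `nri_p`, and the same for NTI.
#' @export
stage_summary <- function(rows) {
  stopifnot(all(c("scale", "stage", "nri", "nti") %in% names(rows)))
  groups <- unique(rows[, c("scale", "stage")])
  groups <- groups[order(groups$scale, groups$stage), , drop = FALSE]
  one <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3) return(c(n = length(v), mean = NA, se = NA, t = NA, p = NA))
    tt <- t.test(v, mu = 0)
    c(n = length(v), mean = mean(v), se = sd(v) / sqrt(length(v)),
      t = unname(tt$statistic), p = tt$p.value)
  }
  res <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- rows[rows$scale == groups$scale[g] & rows$stage == groups$stage[g], ]
    a <- one(sub$nri); b <- one(sub$nti)
    data.frame(scale = groups$scale[g], stage = groups$stage[g],
               n = unname(a["n"]),
               nri_mean = unname(a["mean"]), nri_se = unname(a["se"]),
               nri_t = unname(a["t"]), nri_p = unname(a["p"]),
               nti_mean = unname(b["mean"]), nti_se = unname(b["se"]),
               nti_t = unname(b["t"]), nti_p = unname(b["p"]))
  })
  do.call(rbind, res)
}
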