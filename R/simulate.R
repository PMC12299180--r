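#' Assembly scenario for the synthetic forest
#'
#' Describes the community-assembly process injected into a simulated stem
#' map. `"neutral"` places stems uniformly at random; `"filtering"` sorts
#' species along an environmental gradient according to a phylogenetically
#' conserved affinity (Brownian motion on the tree), so co-occurring species
#' are close relatives and quadrat-level NRI/NTI are pushed positive
#' (clustering); `"repulsion"` thins placements next to phylogenetically
#' close neighbours within 10 m, pushing NRI/NTI negative (overdispersion).
#' `intensity = 0` makes all three modes behave identically (pure neutral),
#' bit-for-bit at a fixed seed.
#'
#' @param mode one of `"neutral"`, `"filtering"`, `"repulsion"`.
#' @param intensity non-negative strength of the assembly process
#'   (dimensionless; 0 collapses to neutral).
#' @param env_covariate environmental field used by the filtering mode:
#'   `"elevation"`, `"tpi"` or `"flowdir"` (log10 flow accumulation).
#' @param seed integer RNG seed.
#' @return an object of class `"assembly_scenario"`.
#' @export
assembly_scenario <- function(mode = c("neutral", "filtering", "repulsion"),
                              intensity = 0,
                              env_covariate = c("elevation", "tpi", "flowdir"),
                              seed = 1L) {
  mode <- match.arg(mode)
  env_covariate <- match.arg(env_covariate)
  stopifnot(is.numeric(intensity), length(intensity) == 1L, intensity >= 0)
  structure(list(mode = mode, intensity = intensity,
                 env_covariate = env_covariate, seed = as.integer(seed)),
            class = "assembly_scenario")
}

#' DBH distribution model
#'
#' Right-skewed diameter distribution for simulated stems:
#' `dbh = min_dbh + lognormal(meanlog, sdlog)` (cm), so every stem exceeds
#' the census floor. The defaults give roughly 52% saplings (< 5 cm),
#' 38% juveniles (5-15 cm) and 10% adults (>= 15 cm), i.e. a community
#' dominated by small stems with every life stage well represented.
#'
#' @param meanlog,sdlog lognormal parameters on the cm scale.
#' @param min_dbh census floor in cm (default 1; all sampled DBH exceed it).
#' @return an object of class `"dbh_model"`.
#' @export
dbh_model <- function(meanlog = 1.3, sdlog = 1.0, min_dbh = 1) {
  stopifnot(sdlog > 0, min_dbh >= 0)
  structure(list(meanlog = meanlog, sdlog = sdlog, min_dbh = min_dbh),
            class = "dbh_model")
}

#' Simulate an ultrametric species phylogeny
#'
#' Pure-birth (Yule) tree with birth rate 1, rescaled so every tip sits at
#' depth 1.0 (relative time units). Tips are labelled `sp001`, `sp002`, ...
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer RNG seed; the same `(n_species, seed)` pair always
#'   yields the identical Newick string.
#' @return a rooted, binary, ultrametric `ape::phylo` tree.
#' @export
simulate_phylogeny <- function(n_species, seed = 1L) {
  if (!is.numeric(n_species) || length(n_species) != 1L || n_species < 2) {
    stop("n_species must be a single integer >= 2", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Simulate a smooth digital elevation model
#'
#' Planar trend plus low-pass-filtered Gaussian noise on a regular square
#' grid. The noise field is smoothed with a separable Gaussian kernel
#' (`smoothness` cells standard deviation) and rescaled so its range equals
#' `relief_amplitude` metres; `relief_amplitude = 0` with a zero trend gives
#' a constant surface.
#'
#' @param side plot side in metres; must be divisible by `cell`.
#' @param cell raster cell size in metres.
#' @param relief_amplitude range (max - min) of the smoothed noise, metres.
#' @param seed integer RNG seed.
#' @param trend gradient of the planar trend, metres of elevation per metre
#'   in (x, y); default a gentle south-west-facing hillside.
#' @param base_elevation elevation at the plot origin, metres.
#' @param smoothness Gaussian smoothing radius in cells.
#' @return a [dem_grid()] with `side/cell` rows and columns.
#' @export
simulate_dem <- function(side, cell = 5, relief_amplitude = 15, seed = 1L,
                         trend = c(0.08, 0.05), base_elevation = 1100,
                         smoothness = 4) {
  n <- cells_per_side(side, cell)
  stopifnot(length(trend) == 2L, is.numeric(trend))
  # cell-centre coordinates; matrix row 1 is the northern edge (max y)
  xs <- (seq_len(n) - 0.5) * cell
  ys <- (n - seq_len(n) + 0.5) * cell
  z <- base_elevation + outer(ys * trend[2], xs * trend[1], `+`)
  if (relief_amplitude > 0) {
    noise <- with_seed(seed, matrix(rnorm(n * n), n, n))
    noise <- gaussian_smooth(noise, smoothness)
    rng <- range(noise)
    if (diff(rng) > 0) {
      noise <- (noise - mean(noise)) / diff(rng) * relief_amplitude
      z <- z + noise
    }
  }
  dem_grid(z, cell = cell)
}

# separable Gaussian convolution with edge renormalisation (kernel weights
# falling outside the grid are dropped and the remainder rescaled to sum 1)
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  smooth_1d <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- k[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(v[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2L, smooth_1d)
  t(apply(m, 1L, smooth_1d))
}

#' Simulate a stem map with controllable assembly structure
#'
#' Places `n_stems` stems inside the plot covered by `dem`. Species are
#' drawn from a geometric rank-abundance distribution (ratio
#' `abundance_ratio`), giving a realistic dominance structure with a few
#' dominant species. Placement depends on the [assembly_scenario()]:
#'
#' * `neutral` - uniform placement;
#' * `filtering` - a species' placement probability over DEM cells is
#'   proportional to `exp(intensity * affinity * env)`, where `affinity` is
#'   a Brownian trait simulated on the tree (phylogenetically conserved)
#'   and `env` is the z-scored environmental field of the scenario;
#' * `repulsion` - sequential placement where a proposal near established
#'   stems is accepted with probability `exp(-intensity * penalty)`, the
#'   penalty summing `1 - cophenetic/diameter` over neighbours within 10 m.
#'
#' All modes share one code path so `intensity = 0` reproduces the neutral
#' output exactly at the same seed. Coordinates are continuous (uniform
#' jitter within the selected cell), not cell-snapped.
#'
#' @param tree phylogeny whose tips are the species pool (>= 2 tips).
#' @param dem a [dem_grid()] defining the plot extent and the environment.
#' @param n_stems number of stems to place (>= 1).
#' @param dbh a [dbh_model()].
#' @param scenario an [assembly_scenario()]; its seed drives all randomness.
#' @param abundance_ratio geometric ratio of successive species ranks.
#' @return a stem table `data.frame` with columns
#'   `stem_id`, `x`, `y`, `species`, `dbh_cm`.
#' @export
simulate_stem_map <- function(tree, dem, n_stems,
                              dbh = dbh_model(),
                              scenario = assembly_scenario(),
                              abundance_ratio = 0.94) {
  stopifnot(inherits(scenario, "assembly_scenario"), inherits(dbh, "dbh_model"))
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 tips", call. = FALSE)
  if (!is.numeric(n_stems) || n_stems < 1) stop("n_stems must be >= 1", call. = FALSE)
  n_stems <- as.integer(n_stems)

  n <- nrow(dem$z)
  cell <- dem$cell
  side <- n * cell
  S <- length(tree$tip.label)
  abund <- abundance_ratio^(seq_len(S) - 1L)
  abund <- abund / sum(abund)

  filt_int <- if (scenario$mode == "filtering") scenario$intensity else 0
  rep_int <- if (scenario$mode == "repulsion") scenario$intensity else 0

  # environmental field and conserved affinities are only consulted when the
  # filtering intensity is positive; cell weights are always passed to
  # sample.int so the RNG stream is identical across modes at intensity 0
  env <- NULL
  affinity <- NULL
  if (filt_int > 0) {
    env_layer <- switch(scenario$env_covariate,
      elevation = dem$z,
      tpi       = tpi(dem),
      flowdir   = log10(1 + flow_direction(dem)$flow_accum))
    env <- as.vector(env_layer)
    if (sd(env) > 0) env <- (env - mean(env)) / sd(env) else env <- env * 0
  }
  coph <- NULL
  diam <- NULL
  if (rep_int > 0) {
    coph <- cophenetic_distances(tree)
    diam <- max(coph)
  }

  out <- with_seed(scenario$seed, {
    # abundance ranks are assigned to tips in randomized order so dominance
    # is phylogenetically unstructured (tip numbering follows topology, and
    # rank-by-label would make the dominant species close relatives,
    # biasing NRI under neutrality)
    abund <- abund[order(sample.int(S))]
    if (filt_int > 0) {
      # early-burst conservatism: affinity differs between, and is nearly
      # constant within, the major clades, so sorting along the gradient
      # assembles close relatives (clade-by-environment filtering)
      affinity <- simulate_brownian_trait(tree, decay = 6)
      affinity <- (affinity - mean(affinity)) / sd(affinity)
    }
    uniform_w <- rep(1, n * n)
    cell_weights <- function(sp) {
      if (filt_int > 0) {
        w <- exp(filt_int * affinity[sp] * env)
        w / sum(w)
      } else uniform_w
    }
    x <- numeric(n_stems); y <- numeric(n_stems); sp_idx <- integer(n_stems)
    # 10 m bucket grid for the repulsion neighbourhood search
    bucket_size <- 10
    nb <- ceiling(side / bucket_size)
    buckets <- vector("list", nb * nb)
    bucket_of <- function(px, py) {
      bx <- min(nb - 1L, as.integer(px / bucket_size))
      by <- min(nb - 1L, as.integer(py / bucket_size))
      by * nb + bx + 1L
    }
    for (i in seq_len(n_stems)) {
      accepted <- FALSE
      tries <- 0L
      while (!accepted) {
        tries <- tries + 1L
        sp <- sample.int(S, 1L, prob = abund)
        idx <- sample.int(n * n, 1L, prob = cell_weights(sp))
        r <- ((idx - 1L) %% n) + 1L          # matrix row (1 = north)
        cc <- ((idx - 1L) %/% n) + 1L        # matrix column
        px <- (cc - 1L) * cell + runif(1L) * cell
        py <- (n - r) * cell + runif(1L) * cell
        u <- runif(1L)
        if (rep_int > 0 && i > 1L) {
          bx <- as.integer(px / bucket_size); by <- as.integer(py / bucket_size)
          js <- integer(0)
          for (dx in -1:1) for (dy in -1:1) {
            qx <- bx + dx; qy <- by + dy
            if (qx < 0 || qy < 0 || qx >= nb || qy >= nb) next
            js <- c(js, buckets[[qy * nb + qx + 1L]])
          }
          penalty <- 0
          if (length(js)) {
            d2 <- (x[js] - px)^2 + (y[js] - py)^2
            near <- js[d2 <= 100]
            if (length(near)) {
              # mean kernel weight over 10 m neighbours, bounded in [0, 1],
              # so the acceptance probability never collapses as density grows
              penalty <- mean(1 - coph[sp, sp_idx[near]] / diam)
            }
          }
          accepted <- (u < exp(-rep_int * penalty)) || tries >= 100L
        } else {
          accepted <- TRUE   # u < 1 always; draw kept for stream parity
        }
      }
      x[i] <- px; y[i] <- py; sp_idx[i] <- sp
      b <- bucket_of(px, py)
      buckets[[b]] <- c(buckets[[b]], i)
    }
    dbh_cm <- dbh$min_dbh + rlnorm(n_stems, dbh$meanlog, dbh$sdlog)
    data.frame(stem_id = sprintf("stem%05d", seq_len(n_stems)),
               x = x, y = y,
               species = tree$tip.label[sp_idx],
               dbh_cm = dbh_cm,
               stringsAsFactors = FALSE)
  })
  out
}

# Gaussian trait evolution along the tree edges, returned per tip in
# tip-label order. `decay = 0` is standard Brownian motion with variance
# rate 1 per unit branch length. `decay > 0` is an early-burst model: the
# rate falls off as exp(-decay * depth), concentrating trait variance on
# the deep branches so major clades get well-separated, internally similar
# values; total root-to-tip variance is normalised to 1 either way.
simulate_brownian_trait <- function(tree, decay = 0) {
  ntip <- length(tree$tip.label)
  val <- numeric(ntip + tree$Nnode)
  ord <- ape::reorder.phylo(tree, "postorder")
  depth <- ape::node.depth.edgelength(tree)
  t1 <- depth[ord$edge[, 1L]]
  t2 <- depth[ord$edge[, 2L]]
  if (decay > 0) {
    total <- max(depth)
    s0 <- decay / (1 - exp(-decay * total))   # unit tip variance
    evar <- s0 / decay * (exp(-decay * t1) - exp(-decay * t2))
  } else {
    evar <- t2 - t1
  }
  steps <- rnorm(nrow(ord$edge), sd = sqrt(evar))
  for (e in rev(seq_len(nrow(ord$edge)))) {   # root-to-tip order
    val[ord$edge[e, 2L]] <- val[ord$edge[e, 1L]] + steps[e]
  }
  setNames(val[seq_len(ntip)], tree$tip.label)
}

#' Simulate a regression fixture with known coefficients
#'
#' Generates a quadrat-style design table under the exact generative model
#' the stage models assume: standardized predictors drawn i.i.d. N(0, 1),
#' plus a group random intercept and Gaussian residual noise. The predictor
#' set matches the NRI/NTI model (competition index, six terrain covariates
#' and species richness), so `beta` has length 9: intercept followed by
#' slopes for `ci, elevation, aspect, slope, tpi, tri, flowdir, sr`.
#'
#' @param beta numeric length-9 coefficient vector (intercept + 8 slopes).
#' @param noise_sd residual standard deviation (response units).
#' @param n_groups number of random-effect groups.
#' @param group_sd standard deviation of the group random intercepts.
#' @param n_per_group rows per group.
#' @param seed integer RNG seed.
#' @return a `data.frame` with the response `y`, the eight predictors and a
#'   `group` factor; total rows `n_groups * n_per_group`.
#' @export
simulate_regression_dataset <- function(beta, noise_sd = 1, n_groups = 20,
                                        group_sd = 0.5, n_per_group = 100,
                                        seed = 1L) {
  preds <- c("ci", "elevation", "aspect", "slope", "tpi", "tri", "flowdir", "sr")
  if (length(beta) != length(preds) + 1L) {
    stop("beta must have length ", length(preds) + 1L,
         " (intercept + ", length(preds), " slopes)", call. = FALSE)
  }
  n <- n_groups * n_per_group
  with_seed(seed, {
    X <- matrix(rnorm(n * length(preds)), n, length(preds),
                dimnames = list(NULL, preds))
    group <- factor(rep(seq_len(n_groups), each = n_per_group))
    b_g <- rnorm(n_groups, sd = group_sd)
    y <- beta[1] + drop(X %*% beta[-1]) + b_g[as.integer(group)] +
      rnorm(n, sd = noise_sd)
    cbind(data.frame(y = y), as.data.frame(X), data.frame(group = group))
  })
}
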