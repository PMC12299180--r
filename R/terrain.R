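# Windowed terrain derivatives on a dem_grid. Matrix row 1 = north.
# Edge policy: TPI/TRI/roughness use the neighbours that exist (no padding);
# the Horn gradient replicates the nearest edge cell for missing neighbours
# (clamped indexing), the usual GIS edge rule. Oracle tests replicate both
# rules cell by cell.

# out[r, c] = z[r + dr, c + dc], NA outside the grid
shift_mat <- function(z, dr, dc) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- z[rs, cs]
  out
}

# out[r, c] = z[clamp(r + dr), clamp(c + dc)] — replicate edge padding
shift_mat_clamped <- function(z, dr, dc) {
  nr <- nrow(z); nc <- ncol(z)
  rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  z[rs, cs, drop = FALSE]
}

# the 8 neighbours, ESRI D8 code order: E, SE, S, SW, W, NW, N, NE
d8_codes <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L)
d8_dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
d8_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
d8_dist <- sqrt(d8_dr^2 + d8_dc^2)

neighbour_stack <- function(z) {
  lapply(seq_along(d8_codes), function(k) shift_mat(z, d8_dr[k], d8_dc[k]))
}

#' Slope and aspect score from an elevation grid
#'
#' Gradient by Horn's 8-neighbour weighted finite differences. Slope is
#' `atan(|grad z|)` in degrees. Aspect (the downslope compass bearing) is
#' folded to a single "southness" score, `-cos(aspect)`: +1 for a slope
#' dipping due south (high irradiance), -1 due north, 0 for flat cells.
#' This keeps the covariate continuous and bounded instead of wrapping at
#' 0/360 degrees.
#'
#' @param dem a [dem_grid()] with at least 3 x 3 cells.
#' @return list of matrices `slope` (degrees) and `aspect_score` ([-1, 1]).
#' @export
slope_aspect <- function(dem) {
  z <- check_terrain_grid(dem)
  cell <- dem$cell
  nb <- lapply(seq_along(d8_codes), function(k)
    shift_mat_clamped(z, d8_dr[k], d8_dc[k]))
  names(nb) <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")
  gx <- ((nb$NE + 2 * nb$E + nb$SE) - (nb$NW + 2 * nb$W + nb$SW)) / (8 * cell)
  gy <- ((nb$NW + 2 * nb$N + nb$NE) - (nb$SW + 2 * nb$S + nb$SE)) / (8 * cell)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect_score <- -cos(atan2(-gx, -gy))
  aspect_score[gx == 0 & gy == 0] <- 0
  list(slope = slope, aspect_score = aspect_score)
}

#' Terrain position index
#'
#' Focal-cell elevation minus the mean of its (available) 8 neighbours;
#' ridges positive, depressions negative.
#'
#' @inheritParams slope_aspect
#' @return matrix of TPI values (metres).
#' @export
tpi <- function(dem) {
  z <- check_terrain_grid(dem)
  nb <- neighbour_stack(z)
  tot <- Reduce(`+`, lapply(nb, function(m) ifelse(is.na(m), 0, m)))
  cnt <- Reduce(`+`, lapply(nb, function(m) !is.na(m)))
  z - tot / cnt
}

#' Terrain ruggedness index
#'
#' Population standard deviation of the elevations of the (available) 8
#' neighbouring cells.
#'
#' @inheritParams slope_aspect
#' @return matrix of TRI values (metres).
#' @export
tri <- function(dem) {
  z <- check_terrain_grid(dem)
  nb <- neighbour_stack(z)
  cnt <- Reduce(`+`, lapply(nb, function(m) !is.na(m)))
  s1 <- Reduce(`+`, lapply(nb, function(m) ifelse(is.na(m), 0, m)))
  s2 <- Reduce(`+`, lapply(nb, function(m) ifelse(is.na(m), 0, m^2)))
  v <- s2 / cnt - (s1 / cnt)^2
  sqrt(pmax(v, 0))
}

#' Roughness (elevation range)
#'
#' Max minus min elevation over the full 3 x 3 window (focal cell included).
#'
#' @inheritParams slope_aspect
#' @return matrix of roughness values (metres).
#' @export
roughness <- function(dem) {
  z <- check_terrain_grid(dem)
  nb <- neighbour_stack(z)
  hi <- Reduce(function(a, b) pmax(a, b, na.rm = TRUE), nb, accumulate = FALSE, init = z)
  lo <- Reduce(function(a, b) pmin(a, b, na.rm = TRUE), nb, accumulate = FALSE, init = z)
  hi - lo
}

#' D8 flow direction and flow accumulation
#'
#' Each cell drains to its steepest-descent neighbour among 8 (ESRI codes
#' E=1, SE=2, S=4, SW=8, W=16, NW=32, N=64, NE=128; drop divided by
#' centre-to-centre distance). Ties take the lowest code; cells with no
#' lower neighbour (pits, flats) get code 0 and stop the flow. Flow
#' accumulation counts the cells draining through each cell, the cell
#' itself included (so every cell has accumulation >= 1), by accumulating
#' over the D8 graph in order of decreasing elevation.
#'
#' @inheritParams slope_aspect
#' @return list of matrices `flowdir_code` (integer codes) and
#'   `flow_accum` (cells).
#' @export
flow_direction <- function(dem) {
  z <- check_terrain_grid(dem)
  nr <- nrow(z); nc <- ncol(z)
  best_drop <- matrix(0, nr, nc)
  code <- matrix(0L, nr, nc)
  recv <- matrix(NA_integer_, nr, nc)   # linear index of the receiving cell
  lin <- matrix(seq_len(nr * nc), nr, nc)
  for (k in seq_along(d8_codes)) {       # ascending code order => ties keep lowest
    znb <- shift_mat(z, d8_dr[k], d8_dc[k])
    drop <- (z - znb) / (d8_dist[k] * dem$cell)
    rnb <- shift_mat(lin, d8_dr[k], d8_dc[k])
    better <- !is.na(drop) & drop > best_drop
    best_drop[better] <- drop[better]
    code[better] <- d8_codes[k]
    recv[better] <- rnb[better]
  }
  accum <- rep(1, nr * nc)
  ord <- order(as.vector(z), decreasing = TRUE)
  rv <- as.vector(recv)
  for (i in ord) {
    if (!is.na(rv[i])) accum[rv[i]] <- accum[rv[i]] + accum[i]
  }
  list(flowdir_code = code, flow_accum = matrix(accum, nr, nc))
}

check_terrain_grid <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  z <- dem$z
  if (nrow(z) < 3 || ncol(z) < 3) {
    stop("windowed terrain metrics need at least a 3 x 3 grid", call. = FALSE)
  }
  z
}

#' All terrain layers at once
#'
#' @inheritParams slope_aspect
#' @return list of per-cell matrices: `elevation`, `slope`, `aspect_score`,
#'   `tpi`, `tri`, `roughness`, `flowdir_code`, `flow_accum`.
#' @export
terrain_layers <- function(dem) {
  sa <- slope_aspect(dem)
  fd <- flow_direction(dem)
  list(elevation = dem$z, slope = sa$slope, aspect_score = sa$aspect_score,
       tpi = tpi(dem), tri = tri(dem), roughness = roughness(dem),
       flowdir_code = fd$flowdir_code, flow_accum = fd$flow_accum)
}

#' Aggregate terrain layers to quadrat covariates
#'
#' Per-quadrat covariates are the mean of the cell values whose centres
#' fall inside the quadrat. When the grain is finer than the DEM cell (e.g.
#' 2.5 m quadrats on a 5 m raster) a quadrat may contain no cell centre; it
#' then takes the value of the cell containing its own centre. The flow
#' covariate is the mean of `log10(1 + flow_accum)` — a wetness proxy that
#' grows with the drained area — not the categorical D8 code.
#'
#' @param layers output of [terrain_layers()].
#' @param grid a [quadrat_grid()].
#' @param dem the [dem_grid()] the layers came from (must cover the plot).
#' @return `data.frame` with one row per quadrat: `quadrat`, `elevation`,
#'   `slope`, `aspect`, `tpi`, `tri`, `roughness`, `flowdir`.
#' @export
quadrat_terrain <- function(layers, grid, dem) {
  stopifnot(inherits(grid, "quadrat_grid"), inherits(dem, "dem_grid"))
  nr <- nrow(dem$z); nc <- ncol(dem$z)
  if (dem$xll > 0 || dem$yll > 0 ||
      dem$xll + nc * dem$cell < grid$side || dem$yll + nr * dem$cell < grid$side) {
    stop("DEM does not cover the ", grid$side, " m plot", call. = FALSE)
  }
  cols <- c(elevation = "elevation", slope = "slope", aspect = "aspect_score",
            tpi = "tpi", tri = "tri", roughness = "roughness")
  r <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  cx <- dem$xll + (cc - 0.5) * dem$cell
  cy <- dem$yll + (nr - r + 0.5) * dem$cell
  inside <- cx >= 0 & cx < grid$side & cy >= 0 & cy < grid$side
  qid <- floor(cy[inside] / grid$scale) * grid$n_side + floor(cx[inside] / grid$scale)
  logacc <- log10(1 + layers$flow_accum)
  vals <- cbind(vapply(cols, function(l) as.vector(layers[[l]])[inside],
                       numeric(sum(inside))),
                flowdir = as.vector(logacc)[inside])
  qf <- factor(qid, levels = seq_len(grid$n_quadrats) - 1L)
  agg <- apply(vals, 2L, function(v) tapply(v, qf, mean))
  agg <- matrix(agg, nrow = grid$n_quadrats,
                dimnames = list(levels(qf), c(names(cols), "flowdir")))
  miss <- which(is.na(agg[, 1L]))
  if (length(miss)) {
    # quadrat centre -> containing DEM cell
    q0 <- miss - 1L
    qx <- (q0 %% grid$n_side + 0.5) * grid$scale
    qy <- (q0 %/% grid$n_side + 0.5) * grid$scale
    ci <- pmin(nc, 1L + floor((qx - dem$xll) / dem$cell))
    ri <- nr - pmin(nr, 1L + floor((qy - dem$yll) / dem$cell)) + 1L
    for (j in seq_along(cols)) {
      agg[miss, j] <- layers[[cols[j]]][cbind(ri, ci)]
    }
    agg[miss, "flowdir"] <- logacc[cbind(ri, ci)]
  }
  data.frame(quadrat = seq_len(grid$n_quadrats) - 1L, agg, row.names = NULL)
}

#' Z-score covariate columns
#'
#' Standardizes each named column to mean 0, sd 1 across rows. A constant
#' column (zero variance) is an error: a covariate with no variation cannot
#' be standardized or carry information.
#'
#' @param df data.frame of per-quadrat covariates.
#' @param cols columns to standardize (default: every numeric column except
#'   `quadrat`).
#' @return `df` with the named columns standardized.
#' @export
zscore_covariates <- function(df, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "quadrat")
  }
  for (col in cols) {
    v <- df[[col]]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("covariate '", col, "' has zero variance; cannot z-score", call. = FALSE)
    }
    df[[col]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  df
}
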