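#' Quadrat tiling of a square plot
#'
#' Tiles the plot into `(side/scale)^2` square quadrats of a given grain.
#' Cells are half-open `[i*s, (i+1)*s)` so every stem falls in exactly one
#' quadrat; the far plot boundary (`x` or `y == side`) folds into the last
#' cell. Quadrat ids are 0-based row-major from the south-west corner:
#' `id = floor(y/s) * (side/s) + floor(x/s)`. The grains nest: each 2.5 m
#' quadrat lies in exactly one 5 m quadrat, each 5 m in one 10 m.
#'
#' @param side plot side in metres.
#' @param scale quadrat side in metres; must divide `side`.
#' @return an object of class `"quadrat_grid"` with elements
#'   `side`, `scale`, `n_side`, `n_quadrats`.
#' @export
quadrat_grid <- function(side, scale) {
  n_side <- cells_per_side(side, scale)
  structure(list(side = side, scale = scale, n_side = n_side,
                 n_quadrats = n_side^2L),
            class = "quadrat_grid")
}

#' @export
print.quadrat_grid <- function(x, ...) {
  cat(sprintf("<quadrat_grid> %g m plot at %g m grain: %d x %d = %d quadrats\n",
              x$side, x$scale, x$n_side, x$n_side, x$n_quadrats))
  invisible(x)
}

#' Assign stems to quadrats
#'
#' @param table a stem table (columns `x`, `y` in metres).
#' @param grid a [quadrat_grid()].
#' @return integer vector of 0-based quadrat ids, one per stem.
#' @export
assign_quadrats <- function(table, grid) {
  stopifnot(inherits(grid, "quadrat_grid"))
  if (any(table$x < 0 | table$x > grid$side | table$y < 0 | table$y > grid$side)) {
    stop("stem coordinates outside the ", grid$side, " m plot", call. = FALSE)
  }
  cx <- pmin(grid$n_side - 1L, floor(table$x / grid$scale))
  cy <- pmin(grid$n_side - 1L, floor(table$y / grid$scale))
  as.integer(cy * grid$n_side + cx)
}

life_stage_levels <- c("sapling", "juvenile", "adult")

#' Classify stems into life-history stages by DBH
#'
#' Stage bins follow the census convention: sapling (DBH < 5 cm), juvenile
#' (5 <= DBH < 15 cm), adult (DBH >= 15 cm). DBH at or below the 1 cm
#' census floor is an error (such stems are not recorded).
#'
#' @param dbh numeric DBH in cm.
#' @return factor with levels `sapling`, `juvenile`, `adult`.
#' @export
classify_life_stage <- function(dbh) {
  if (any(!is.finite(dbh) | dbh <= 1)) {
    stop("DBH must exceed the 1 cm census floor", call. = FALSE)
  }
  factor(ifelse(dbh < 5, "sapling", ifelse(dbh < 15, "juvenile", "adult")),
         levels = life_stage_levels)
}

#' Build a quadrat-by-species community matrix
#'
#' Counts stems of the requested life stage per quadrat and species. All
#' quadrats of the grid are retained as rows (empty ones as all-zero rows);
#' columns are exactly the species present after the stage filter. Row
#' names are the 0-based quadrat ids.
#'
#' @param table a stem table with a `dbh_cm` column.
#' @param grid a [quadrat_grid()].
#' @param stage `"all"` or one of `"sapling"`, `"juvenile"`, `"adult"`.
#' @return an integer matrix with attributes `scale` and `stage`;
#'   `attr(, "empty")` flags all-zero rows.
#' @export
build_community_matrix <- function(table, grid, stage = "all") {
  stage <- match.arg(stage, c("all", life_stage_levels))
  q <- assign_quadrats(table, grid)
  if (stage != "all") {
    keep <- classify_life_stage(table$dbh_cm) == stage
    table <- table[keep, , drop = FALSE]
    q <- q[keep]
  }
  species <- sort(unique(table$species))
  cm <- matrix(0L, nrow = grid$n_quadrats, ncol = length(species),
               dimnames = list(as.character(seq_len(grid$n_quadrats) - 1L), species))
  if (nrow(table)) {
    counts <- table(factor(q, levels = seq_len(grid$n_quadrats) - 1L),
                    factor(table$species, levels = species))
    cm[] <- as.integer(counts)
  }
  attr(cm, "scale") <- grid$scale
  attr(cm, "stage") <- stage
  attr(cm, "empty") <- rowSums(cm) == 0L
  cm
}
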