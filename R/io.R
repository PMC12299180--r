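#' Regular elevation grid
#'
#' Container for a square-celled elevation raster. Row 1 of `z` is the
#' northern edge of the plot (the ESRI ASCII convention); the cell centre of
#' `z[r, c]` sits at `x = xll + (c - 0.5) * cell`,
#' `y = yll + (nrow - r + 0.5) * cell` in plot coordinates (origin at the
#' south-west corner).
#'
#' @param z numeric matrix of elevations (metres).
#' @param cell cell size in metres (> 0).
#' @param xll,yll plot coordinates of the lower-left corner of the grid.
#' @param nodata value used to mark missing cells on disk.
#' @return an object of class `"dem_grid"`.
#' @export
dem_grid <- function(z, cell, xll = 0, yll = 0, nodata = -9999) {
  z <- as.matrix(z)
  stopifnot(is.numeric(z), is.numeric(cell), cell > 0)
  if (!all(is.finite(z))) stop("elevation grid contains non-finite values", call. = FALSE)
  structure(list(z = z, cell = cell, xll = xll, yll = yll, nodata = nodata),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("<dem_grid> %d x %d cells, %.3g m cell size, elevation %.1f-%.1f m\n",
              nrow(x$z), ncol(x$z), x$cell, min(x$z), max(x$z)))
  invisible(x)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of elevations from north to south.
#'
#' @param path file path.
#' @return `read_ascii_grid()` returns a [dem_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  missing <- setdiff(need, names(hdr))
  if (length(missing)) stop("ASCII grid header missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  z[z == hdr$nodata_value] <- NA_real_
  if (anyNA(z)) stop("ASCII grid contains NODATA cells; the plot DEM must be complete",
                     call. = FALSE)
  dem_grid(z, cell = hdr$cellsize, xll = hdr$xllcorner, yll = hdr$yllcorner,
           nodata = hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @param dem a [dem_grid()] (or bare numeric matrix for `write_ascii_grid`,
#'   in which case `cell`, `xll`, `yll` default to a unit grid at the origin).
#' @export
write_ascii_grid <- function(dem, path) {
  if (!inherits(dem, "dem_grid")) dem <- dem_grid(as.matrix(dem), cell = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(dem$z)),
    paste("nrows", nrow(dem$z)),
    paste("xllcorner", format(dem$xll, scientific = FALSE)),
    paste("yllcorner", format(dem$yll, scientific = FALSE)),
    paste("cellsize", format(dem$cell, scientific = FALSE)),
    paste("NODATA_value", format(dem$nodata, scientific = FALSE))
  ), con)
  body <- apply(dem$z, 1L, function(row)
    paste(format(row, trim = TRUE, scientific = FALSE, digits = 10), collapse = " "))
  writeLines(body, con)
  invisible(path)
}

stem_table_columns <- c("stem_id", "x", "y", "species", "dbh_cm")

#' Read and validate a stem census table
#'
#' The table is a CSV with one row per stem and columns
#' `stem_id, x, y, species, dbh_cm`: coordinates in metres from the
#' south-west plot corner, DBH in cm. Validation enforces the census
#' conventions: numeric coordinates and DBH, DBH strictly above the 1 cm
#' census floor, non-empty species codes, and (when `plot_side` is given)
#' coordinates inside the plot. Errors name the offending row.
#'
#' @param path CSV file path.
#' @param plot_side optional plot side in metres for the coordinate check.
#' @return a validated stem table `data.frame`.
#' @export
read_stem_table <- function(path, plot_side = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(stem_table_columns, names(tab))
  if (length(missing)) {
    stop("stem table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_stem_table(tab, plot_side = plot_side)
}

#' @rdname read_stem_table
#' @param table a stem table `data.frame`.
#' @export
write_stem_table <- function(table, path) {
  validate_stem_table(table)
  write.csv(table[, stem_table_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_stem_table <- function(tab, plot_side = NULL) {
  for (col in c("x", "y", "dbh_cm")) {
    v <- tab[[col]]
    if (is.null(v)) stop("stem table is missing column(s): ", col, call. = FALSE)
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric ", col, " in stem table row ", bad[1], call. = FALSE)
      }
      tab[[col]] <- vn
      v <- vn
    }
    if (anyNA(v)) stop("missing ", col, " in stem table row ", which(is.na(v))[1],
                       call. = FALSE)
  }
  low <- which(tab$dbh_cm <= 1)
  if (length(low)) {
    stop("stem table row ", low[1], " has dbh_cm = ", tab$dbh_cm[low[1]],
         "; the census records only stems with DBH > 1 cm", call. = FALSE)
  }
  empty <- which(is.na(tab$species) | !nzchar(trimws(as.character(tab$species))))
  if (length(empty)) stop("empty species code in stem table row ", empty[1],
                          call. = FALSE)
  if (!is.null(plot_side)) {
    out <- which(tab$x < 0 | tab$x > plot_side | tab$y < 0 | tab$y > plot_side)
    if (length(out)) {
      stop("stem table row ", out[1], " lies outside the ", plot_side,
           " m plot: (", tab$x[out[1]], ", ", tab$y[out[1]], ")", call. = FALSE)
    }
  }
  tab$species <- as.character(tab$species)
  tab$stem_id <- as.character(tab$stem_id)
  tab
}

#' Read a rooted phylogeny from a Newick file
#'
#' Requires branch lengths (relative time units) on every edge; tip labels
#' are the species codes used in the stem table.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("phylogeny has no branch lengths: ", path, call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree", call. = FALSE)
  tree
}

#' Prune a phylogeny to a species checklist
#'
#' Retains exactly the requested tips, removing internal degree-2 nodes and
#' summing their branch lengths so every retained tip-to-tip (and
#' tip-to-root) path length is preserved.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param species character vector of tip labels to keep.
#' @return the pruned tree.
#' @export
prune_to_species <- function(tree, species) {
  species <- unique(as.character(species))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) {
    stop("species absent from the phylogeny: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  ape::keep.tip(tree, species)
}
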