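#' Pipeline configuration
#'
#' Declarative description of a full run: either the three input paths
#' (stem CSV, Newick tree, ESRI ASCII DEM) or a synthetic-forest scenario.
#' All randomness derives from `seed`: the tree uses `seed`, the DEM
#' `seed + 1`, the stem map `seed + 2` and the null model `seed + 3`, so a
#' config reproduces its run exactly.
#'
#' @param side plot side in metres (must be divisible by every scale).
#' @param scales analysis grains in metres (default 2.5, 5, 10).
#' @param stages stage groupings analysed (community-wide `"all"` plus the
#'   three life stages).
#' @param dem_cell DEM cell size in metres.
#' @param relief_amplitude DEM relief range in metres (simulation only).
#' @param n_species,n_stems synthetic community size.
#' @param scenario_mode,intensity,env_covariate assembly scenario
#'   (see [assembly_scenario()]).
#' @param n_rand null-model randomizations.
#' @param ci_mode Hegyi neighbourhood: `"radius"` or `"quadrat"`.
#' @param group random-intercept grouping: `"dominant_species"` or
#'   `"block"`.
#' @param block_scale census block side in metres (grouping/bookkeeping).
#' @param stem_path,tree_path,dem_path optional input files; when all three
#'   are given the simulation step is skipped.
#' @param seed global integer seed.
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(side = 150, scales = c(2.5, 5, 10),
                            stages = c("all", "sapling", "juvenile", "adult"),
                            dem_cell = 5, relief_amplitude = 15,
                            n_species = 50, n_stems = 8000,
                            scenario_mode = "neutral", intensity = 0,
                            env_covariate = "elevation",
                            n_rand = 999, ci_mode = "radius",
                            group = "dominant_species", block_scale = NULL,
                            stem_path = NULL, tree_path = NULL,
                            dem_path = NULL, seed = 1L) {
  for (s in scales) cells_per_side(side, s)
  block_scale <- block_scale %||% if (side %% 20 == 0) 20 else max(scales)
  cells_per_side(side, block_scale)
  structure(list(side = side, scales = scales, stages = stages,
                 dem_cell = dem_cell, relief_amplitude = relief_amplitude,
                 n_species = n_species, n_stems = n_stems,
                 scenario_mode = scenario_mode, intensity = intensity,
                 env_covariate = env_covariate, n_rand = n_rand,
                 ci_mode = ci_mode, group = group, block_scale = block_scale,
                 stem_path = stem_path, tree_path = tree_path,
                 dem_path = dem_path, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate a census / tree / DEM triple
#'
#' Machine-readable consistency report: species coverage of the tree,
#' DEM coverage of the plot, the DBH census floor, coordinate range and
#' coincident stems. An empty `detail` with `ok = TRUE` on every row means
#' the inputs are clean.
#'
#' @param stems stem table.
#' @param tree phylogeny.
#' @param dem a [dem_grid()].
#' @param side plot side in metres.
#' @return `data.frame` with columns `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(stems, tree, dem, side) {
  checks <- list()
  miss <- setdiff(unique(stems$species), tree$tip.label)
  checks[["species_in_tree"]] <- if (length(miss)) {
    paste("missing from tree:", paste(sort(miss), collapse = ", "))
  } else ""
  covered <- dem$xll <= 0 && dem$yll <= 0 &&
    dem$xll + ncol(dem$z) * dem$cell >= side &&
    dem$yll + nrow(dem$z) * dem$cell >= side
  checks[["dem_covers_plot"]] <- if (!covered) {
    sprintf("DEM extent %g x %g m from (%g, %g) does not cover the %g m plot",
            ncol(dem$z) * dem$cell, nrow(dem$z) * dem$cell, dem$xll, dem$yll, side)
  } else ""
  low <- sum(stems$dbh_cm <= 1)
  checks[["dbh_census_floor"]] <- if (low) {
    paste(low, "stems at or below the 1 cm census floor")
  } else ""
  out <- sum(stems$x < 0 | stems$x > side | stems$y < 0 | stems$y > side)
  checks[["stems_inside_plot"]] <- if (out) {
    paste(out, "stems outside the plot")
  } else ""
  dup <- duplicated(stems[, c("x", "y")])
  checks[["no_coincident_stems"]] <- if (any(dup)) {
    paste("coincident stems, e.g.", stems$stem_id[which(dup)[1]])
  } else ""
  data.frame(check = names(checks), ok = !nzchar(unlist(checks)),
             detail = unlist(checks), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assemble the per-quadrat metric table
#'
#' The model input: for every scale and stage grouping, one row per quadrat
#' holding SR, PD, NRI, NTI (tip-label shuffle null), the quadrat-mean
#' Hegyi CI at the matching neighbourhood, the terrain covariates
#' aggregated from the DEM, and the grouping columns (`dominant_species`,
#' the quadrat's highest-basal-area species; `block`, the parent census
#' block id). Stage groupings whose community holds fewer than two species
#' are skipped with a warning.
#'
#' @param stems stem table.
#' @param tree phylogeny covering the census species.
#' @param dem a [dem_grid()] covering the plot.
#' @param side plot side in metres.
#' @param scales analysis grains.
#' @param stages stage groupings (`"all"` plus life stages).
#' @param null_cfg a [null_model_config()]; each scale x stage run derives
#'   its own sub-seed from it so runs are independent but reproducible.
#' @param ci_mode Hegyi neighbourhood mode.
#' @param block_scale census block side in metres.
#' @return long `data.frame`, one row per (scale, stage, quadrat).
#' @export
build_metric_table <- function(stems, tree, dem, side,
                               scales = c(2.5, 5, 10),
                               stages = c("all", "sapling", "juvenile", "adult"),
                               null_cfg = null_model_config(),
                               ci_mode = "radius", block_scale = NULL) {
  stems <- validate_stem_table(stems, plot_side = side)
  tree <- prune_to_species(tree, unique(stems$species))
  layers <- terrain_layers(dem)
  block_scale <- block_scale %||% if (side %% 20 == 0) 20 else max(scales)
  block_grid <- quadrat_grid(side, block_scale)
  out <- list()
  run <- 0L
  for (sc in scales) {
    grid <- quadrat_grid(side, sc)
    terr <- quadrat_terrain(layers, grid, dem)
    records <- if (ci_mode == "quadrat") {
      hegyi_ci(stems, radius = sc, mode = "quadrat", grid = grid)
    } else {
      hegyi_ci(stems, radius = sc)
    }
    # dominant (highest basal area) species and parent block per quadrat
    q <- assign_quadrats(stems, grid)
    ba <- tapply(stems$dbh_cm^2, list(factor(q, levels = 0:(grid$n_quadrats - 1L)),
                                      stems$species), sum)
    dom <- colnames(ba)[apply(ba, 1L, function(r) {
      if (all(is.na(r))) NA_integer_ else which.max(replace(r, is.na(r), -Inf))
    })]
    q0 <- seq_len(grid$n_quadrats) - 1L
    qx <- (q0 %% grid$n_side + 0.5) * sc
    qy <- (q0 %/% grid$n_side + 0.5) * sc
    block <- floor(qy / block_scale) * block_grid$n_side + floor(qx / block_scale)
    for (st in stages) {
      run <- run + 1L
      cm <- build_community_matrix(stems, grid, stage = st)
      if (ncol(cm) < 2) {
        warning("stage '", st, "' at ", sc, " m has < 2 species; skipped")
        next
      }
      cfg <- null_model_config(n_rand = null_cfg$n_rand,
                               seed = null_cfg$seed + run)
      ses <- ses_metrics(cm, tree, cfg)
      qci <- quadrat_ci(records, stems, grid, stage = st)
      row <- data.frame(scale = sc, stage = st, ses,
                        ci = qci$ci, n_focal = qci$n_focal,
                        terr[, -1L, drop = FALSE],
                        dominant_species = dom, block = as.integer(block),
                        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the stem census, phylogeny and DEM; validates them;
#' builds the metric table at every scale and stage; summarises NRI/NTI
#' against zero; fits the mixed-effects models for every response x scale x
#' stage; and writes everything under `out_dir` together with a manifest
#' echoing the config and all seeds. Re-running with the same config
#' produces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the metric table, stage summary,
#'   coefficient grid and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  simulated <- is.null(config$stem_path)
  if (simulated) {
    tree <- simulate_phylogeny(config$n_species, seed = config$seed)
    dem <- simulate_dem(config$side, cell = config$dem_cell,
                        relief_amplitude = config$relief_amplitude,
                        seed = config$seed + 1L)
    scen <- assembly_scenario(mode = config$scenario_mode,
                              intensity = config$intensity,
                              env_covariate = config$env_covariate,
                              seed = config$seed + 2L)
    stems <- simulate_stem_map(tree, dem, config$n_stems, scenario = scen)
  } else {
    stems <- read_stem_table(config$stem_path, plot_side = config$side)
    tree <- read_newick(config$tree_path)
    dem <- read_ascii_grid(config$dem_path)
  }
  report <- validate_inputs(stems, tree, dem, config$side)
  if (!all(report$ok)) {
    bad <- report[!report$ok, ]
    stop("input validation failed: ",
         paste(sprintf("[%s] %s", bad$check, bad$detail), collapse = "; "),
         call. = FALSE)
  }
  paths <- list(
    stems = file.path(out_dir, "stems.csv"),
    tree = file.path(out_dir, "tree.nwk"),
    dem = file.path(out_dir, "dem.asc"),
    metrics = file.path(out_dir, "metric_table.csv"),
    summary = file.path(out_dir, "stage_summary.csv"),
    coefficients = file.path(out_dir, "coefficients.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_stem_table(stems, paths$stems)
  ape::write.tree(tree, paths$tree)
  write_ascii_grid(dem, paths$dem)

  null_cfg <- null_model_config(n_rand = config$n_rand, seed = config$seed + 3L)
  metrics <- build_metric_table(stems, tree, dem, config$side,
                                scales = config$scales, stages = config$stages,
                                null_cfg = null_cfg, ci_mode = config$ci_mode,
                                block_scale = config$block_scale)
  write.csv(metrics, paths$metrics, row.names = FALSE, quote = FALSE)

  summary_tab <- stage_summary(metrics)
  write.csv(summary_tab, paths$summary, row.names = FALSE, quote = FALSE)

  fits <- list()
  skipped <- character(0)
  for (resp in c("SR", "PD", "NRI", "NTI")) {
    for (sc in config$scales) {
      for (st in config$stages) {
        tag <- paste(resp, sc, st, sep = "/")
        fit <- tryCatch(
          suppressWarnings(fit_lmm(build_design(metrics, resp, sc, st,
                                                group = config$group))),
          error = function(e) conditionMessage(e))
        if (inherits(fit, "phylo_fit")) {
          fits[[tag]] <- fit
        } else {
          skipped <- c(skipped, paste0(tag, ": ", fit))
        }
      }
    }
  }
  grid_tab <- if (length(fits)) coefficient_grid(fits) else NULL
  if (!is.null(grid_tab)) {
    write.csv(grid_tab, paths$coefficients, row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    package = "phylotopo",
    version = as.character(utils::packageVersion("phylotopo")),
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    simulated_inputs = simulated,
    n_stems = nrow(stems),
    n_species = length(unique(stems$species)),
    quadrats = setNames(as.list(vapply(config$scales, function(s)
      quadrat_grid(config$side, s)$n_quadrats, numeric(1))),
      paste0("scale_", config$scales)),
    fits = names(fits),
    skipped_fits = skipped
  )
  writeLines(to_json(manifest), paths$manifest)
  invisible(list(metrics = metrics, stage_summary = summary_tab,
                 coefficients = grid_tab, paths = paths, manifest = manifest))
}

# minimal JSON serialiser for the manifest (named lists, vectors, scalars)
to_json <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (length(x) == 0) return(if (is.null(names(x))) "[]" else "{}")
    inner <- paste0(indent, "  ")
    if (!is.null(names(x))) {
      body <- vapply(seq_along(x), function(i)
        paste0(inner, '"', esc(names(x)[i]), '": ', to_json(x[[i]], inner)),
        character(1))
      return(paste0("{\n", paste(body, collapse = ",\n"), "\n", indent, "}"))
    }
    body <- vapply(x, to_json, character(1), indent = inner)
    return(paste0("[", paste(body, collapse = ", "), "]"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste(vapply(x, to_json, character(1)), collapse = ", "), "]"))
  }
  if (is.character(x)) return(paste0('"', esc(x), '"'))
  if (is.logical(x)) return(if (x) "true" else "false")
  format(x, scientific = FALSE)
}
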