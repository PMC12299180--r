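test_that("stem tables round-trip through CSV and are validated on read", {
  st <- tiny_stems()
  path <- withr::local_tempfile(fileext = ".csv")
  write_stem_table(st, path)
  back <- read_stem_table(path, plot_side = 20)
  expect_equal(back, st)

  bad <- st; bad$dbh_cm[2] <- 0.5
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path2, row.names = FALSE)
  expect_error(read_stem_table(path2), "census|1 cm")

  noy <- st; noy$y <- NULL
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(noy, path3, row.names = FALSE)
  expect_error(read_stem_table(path3), "missing column")

  far <- st; far$x[1] <- 25
  path4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(far, path4, row.names = FALSE)
  expect_error(read_stem_table(path4, plot_side = 20), "outside")
})

test_that("pruning preserves path lengths and names missing species", {
  tr <- abc_tree()
  pruned <- prune_to_species(tr, c("A", "C"))
  expect_setequal(pruned$tip.label, c("A", "C"))
  expect_equal(unname(cophenetic_distances(pruned)["A", "C"]), 4.0)

  all3 <- prune_to_species(tr, c("A", "B", "C"))
  expect_equal(cophenetic_distances(all3)[tr$tip.label, tr$tip.label],
               cophenetic_distances(tr))

  expect_error(prune_to_species(tr, c("A", "B", "Z")), "Z")
})

test_that("newick IO requires branch lengths and round-trips simulated trees", {
  tr <- simulate_phylogeny(12, seed = 3)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(cophenetic_distances(back)[tr$tip.label, tr$tip.label],
               cophenetic_distances(tr), tolerance = 1e-8)

  path2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A,B),C);", path2)   # topology only
  expect_error(read_newick(path2), "branch length")
})

test_that("ESRI ASCII grids round-trip with their georeferencing", {
  dem <- simulate_dem(60, cell = 5, relief_amplitude = 9, seed = 4)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(dem, path)
  hdr <- readLines(path, n = 6)
  expect_match(hdr[1], "^ncols 12$")
  expect_match(hdr[6], "^NODATA_value")
  back <- read_ascii_grid(path)
  expect_equal(back$z, dem$z, tolerance = 1e-8)
  expect_equal(back$cell, 5)
})

test_that("quadrat tiling matches the census arithmetic and nests across grains", {
  expect_equal(quadrat_grid(340, 20)$n_quadrats, 289L)
  expect_equal(quadrat_grid(340, 5)$n_quadrats, 4624L)
  expect_equal(quadrat_grid(340, 2.5)$n_quadrats, 18496L)
  expect_error(quadrat_grid(340, 7), "divisible")

  # half-open cells, far boundary folded into the last cell
  g5 <- quadrat_grid(340, 5)
  pts <- data.frame(x = c(0, 5, 4.999, 340), y = c(0, 0, 0, 340))
  expect_equal(assign_quadrats(pts, g5), c(0L, 1L, 0L, 4623L))

  # nesting conservation: child 2.5 m counts sum to the parent 5 m counts
  st <- random_stems(800, side = 40, seed = 6)
  g_fine <- quadrat_grid(40, 2.5); g_mid <- quadrat_grid(40, 5); g_coarse <- quadrat_grid(40, 10)
  cm_fine <- build_community_matrix(st, g_fine)
  cm_mid <- build_community_matrix(st, g_mid)
  cm_coarse <- build_community_matrix(st, g_coarse)
  parent_of <- function(q, fine, coarse) {
    fx <- (q %% fine$n_side) * fine$scale; fy <- (q %/% fine$n_side) * fine$scale
    floor(fy / coarse$scale) * coarse$n_side + floor(fx / coarse$scale)
  }
  rolled <- rowsum(cm_fine, parent_of(as.integer(rownames(cm_fine)), g_fine, g_mid))
  expect_equal(unname(rolled), unname(cm_mid[rownames(rolled), ]))
  rolled2 <- rowsum(cm_mid, parent_of(as.integer(rownames(cm_mid)), g_mid, g_coarse))
  expect_equal(unname(rolled2), unname(cm_coarse[rownames(rolled2), ]))
})

test_that("life stages split at 5 and 15 cm with the census floor enforced", {
  expect_equal(as.character(classify_life_stage(c(4.99, 5, 14.99, 15, 40))),
               c("sapling", "juvenile", "juvenile", "adult", "adult"))
  expect_error(classify_life_stage(1.0), "census floor")
  expect_error(classify_life_stage(c(5, 0.2)), "census floor")
})

test_that("community matrices count stems, filter stages, and partition by stage", {
  st <- tiny_stems()  # A(10cm), B(20cm) in different quadrats at 5 m; A(4cm)
  g <- quadrat_grid(20, 5)
  cm <- build_community_matrix(st, g)
  expect_equal(sum(cm), 3)
  expect_equal(unname(cm["0", "A"]), 1L)

  adult <- build_community_matrix(st, g, stage = "adult")
  expect_equal(sum(adult), 1L)
  expect_equal(colnames(adult), "B")

  # stage partition: the three stage matrices sum to the all-stages matrix
  big <- random_stems(600, side = 40, seed = 7)
  gb <- quadrat_grid(40, 5)
  all_cm <- build_community_matrix(big, gb)
  total <- matrix(0L, nrow(all_cm), ncol(all_cm), dimnames = dimnames(all_cm))
  for (stg in c("sapling", "juvenile", "adult")) {
    part <- build_community_matrix(big, gb, stage = stg)
    total[, colnames(part)] <- total[, colnames(part)] + part
  }
  expect_equal(total, all_cm, ignore_attr = TRUE)
  # row sums conserve the stem count
  expect_equal(sum(all_cm), nrow(big))
  # empty quadrats are retained and flagged
  expect_equal(sum(attr(all_cm, "empty")), sum(rowSums(all_cm) == 0))
})
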