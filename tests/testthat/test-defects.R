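make_grid_frame <- function(box = c(2, 2, 5)) {
  atoms <- data.frame(serial = 1:2, atom_name = c("Q1", "G1"),
                      res_name = "LPC", res_id = 1:2,
                      x = 1, y = 1, z = c(1.4, 1.0))
  mem_frame(atoms, box)
}

test_that("grid cell counts follow round(L/cell) and tile the box exactly", {
  fr <- make_grid_frame(c(20, 20, 12))
  g <- build_grid(fr, 0.1)
  expect_equal(c(g$nx, g$ny), c(200L, 200L))
  expect_equal(memdefect:::cell_area(g), 0.01)
  g2 <- build_grid(make_grid_frame(c(2.05, 2.0, 5)), 0.1)
  expect_true(g2$nx %in% c(20L, 21L))
  expect_equal(g2$nx * g2$cell_x, 2.05)  # exact tiling after recompute
  expect_error(build_grid(fr, 0), "positive")
  expect_error(build_grid(make_grid_frame(c(0.04, 0.04, 5)), 0.1),
               "smaller than one grid cell")
})

test_that("glycerol plane is the mean z of the leaflet's glycerol atoms", {
  atoms <- data.frame(serial = 1:6,
                      atom_name = rep(c("Q1", "G1"), 3),
                      res_name = "LPC", res_id = rep(1:3, each = 2),
                      x = c(1, 1, 2, 2, 3, 3), y = 1,
                      z = c(2.4, 2.0, 2.6, 2.2, 1.0, 0.6))
  # residues 1-2 upper (heads at 2.4/2.6), residue 3 lower
  fr <- mem_frame(atoms, c(4, 4, 4))
  top <- default_topology()
  expect_equal(compute_glycerol_plane(fr, top, "upper"), 2.1)
  # a sterol-only leaflet has no glycerol atoms
  st <- data.frame(serial = 1:4, atom_name = rep(c("R1", "E1"), 2),
                   res_name = "LST", res_id = rep(1:2, each = 2),
                   x = c(1, 1, 2, 2), y = 1, z = c(2.3, 1.9, 0.3, 0.7))
  fr2 <- mem_frame(st, c(4, 4, 4))
  expect_error(compute_glycerol_plane(fr2, top, "upper"), "no glycerol")
})

test_that("the overlap inequality covers exactly the cells within the atom radius", {
  # one lipid with a single headgroup atom of radius 0.17 (element C)
  path <- withr::local_tempfile(fileext = ".toml")
  writeLines(c("[lipids.XHD]", 'headgroup = ["C1"]', 'glycerol = ["G1"]'),
             path)
  top <- load_topology_spec(path)
  atoms <- data.frame(serial = 1:4, atom_name = c("C1", "G1", "C1", "G1"),
                      res_name = "XHD", res_id = c(1L, 1L, 2L, 2L),
                      x = c(1.05, 1.05, 1.05, 1.05), y = 1.05,
                      z = c(2.4, 2.0, 0.6, 1.0))
  fr <- mem_frame(atoms, c(2, 2, 4))
  g <- build_grid(fr, 0.1)
  map <- project_and_classify_cells(fr, top, g, "upper")
  centers <- expand.grid(x = memdefect:::grid_centers_x(g),
                         y = memdefect:::grid_centers_y(g))
  d <- sqrt((centers$x - 1.05)^2 + (centers$y - 1.05)^2)
  expect_identical(as.vector(map$covered_head), d <= 0.17)
})

test_that("a leaflet with zero atoms leaves every cell uncovered", {
  # lower leaflet only; analyse upper against a manual assignment
  atoms <- data.frame(serial = 1:4, atom_name = rep(c("Q1", "G1"), 2),
                      res_name = "LPC", res_id = rep(1:2, each = 2),
                      x = c(1, 1, 3, 3), y = 1, z = c(2.4, 2.0, 2.5, 2.1))
  fr <- mem_frame(atoms, c(4, 4, 4))
  top <- default_topology()
  asg <- assign_leaflets(fr, top)
  asg$leaflet[] <- "lower"   # force all residues into the lower leaflet
  g <- build_grid(fr, 0.1)
  map <- project_and_classify_cells(fr, top, g, "upper", assignment = asg,
                                    glycerol_z = 2.0)
  expect_false(any(map$covered_head))
  expect_false(any(map$covered_above))
  expect_true(all(is.na(map$max_z)))
  expect_true(all(detect_defect_cells(map) == "deep"))
})

test_that("coverage maps match the brute-force all-atoms x all-cells oracle", {
  for (seed in 1:6) {
    n <- c(16, 25, 36)[(seed %% 3) + 1]
    gen <- small_bilayer(n, seed = seed, preset = "chol40",
                         kappa = runif(1))
    g <- build_grid(gen$frame, 0.1)
    map <- project_and_classify_cells(gen$frame, gen$topology, g, "upper")
    oracle <- brute_coverage(gen$frame, gen$topology, g, "upper")
    expect_identical(map$covered_head, oracle$covered_head)
    expect_identical(map$covered_above, oracle$covered_above)
    expect_equal(map$max_z, oracle$max_z, tolerance = 1e-12)
  }
})

test_that("defect cells classify by headgroup coverage and the deep plane", {
  map <- list(grid = build_grid(make_grid_frame(c(0.3, 0.1, 5)), 0.1),
              covered_head = matrix(c(TRUE, FALSE, FALSE), 3, 1),
              covered_above = matrix(c(TRUE, TRUE, FALSE), 3, 1),
              max_z = matrix(c(2.0, 1.95, 1.8), 3, 1),
              glycerol_z = 2.0, deep_plane_z = 1.9, leaflet = "upper",
              leaflet_sign = 1)
  class(map) <- "defect_cell_map"
  cls <- detect_defect_cells(map)
  # covered -> none; uncovered with atom at glycerol-0.05 -> shallow;
  # uncovered with highest atom at glycerol-0.2 -> deep
  expect_equal(as.vector(cls), c("none", "shallow", "deep"))
})

test_that("cells merge iff within 0.3 nm, including across the periodic boundary", {
  g <- build_grid(make_grid_frame(c(4, 4, 5)), 0.1)
  cls <- matrix("none", g$nx, g$ny)
  cls[10, 10] <- "shallow"; cls[12, 10] <- "shallow"   # 0.2 nm apart
  cls[25, 25] <- "shallow"; cls[30, 25] <- "shallow"   # 0.5 nm apart
  d <- merge_cells_to_defects(cls, g)
  expect_equal(nrow(d), 3)
  expect_equal(sort(d$n_cells), c(1, 1, 2))
  expect_equal(d$area_nm2[d$n_cells == 2], 0.02)
  # defect spanning the periodic boundary: cells at x ~ 0 and x ~ Lx
  cls2 <- matrix("none", g$nx, g$ny)
  cls2[1, 5] <- "deep"; cls2[g$nx, 5] <- "deep"        # gap 0.1 nm across
  d2 <- merge_cells_to_defects(cls2, g)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$n_cells, 2)
  expect_warning(merge_cells_to_defects(cls2, g, merge_distance = 0.05),
                 "degenerate")
})

test_that("merged components match the all-pairs oracle on random cell sets", {
  g <- build_grid(make_grid_frame(c(3, 3, 5)), 0.1)
  set.seed(11)
  for (rep in 1:8) {
    cls <- matrix("none", g$nx, g$ny)
    pick <- sample(g$nx * g$ny, 40)
    cls[pick] <- "shallow"
    d <- merge_cells_to_defects(cls, g)
    oracle <- brute_merge(which(cls == "shallow", arr.ind = TRUE), g)
    expect_identical(component_signature(attr(d, "cells")),
                     component_signature(oracle))
  }
})

test_that("merge modes handle depth class per the deep-member rule", {
  g <- build_grid(make_grid_frame(c(2, 2, 5)), 0.1)
  cls <- matrix("none", g$nx, g$ny)
  cls[5, 5] <- "deep"; cls[6, 5] <- "shallow"
  per <- merge_cells_to_defects(cls, g, mode = "per_class")
  expect_equal(nrow(per), 2)
  expect_setequal(per$class, c("deep", "shallow"))
  all_mode <- merge_cells_to_defects(cls, g, mode = "all")
  expect_equal(nrow(all_mode), 1)
  expect_equal(all_mode$class, "deep")
  expect_equal(all_mode$n_cells, 2)
})

test_that("frame statistics report counts, areas and flags", {
  g <- build_grid(make_grid_frame(c(2, 2, 5)), 0.1)
  cls <- matrix("none", g$nx, g$ny)
  cls[2, 2] <- "deep"; cls[3, 2] <- "deep"                    # area 0.02
  cls[10, 10] <- "shallow"; cls[10, 11] <- "shallow"
  cls[11, 10] <- "shallow"; cls[11, 11] <- "shallow"          # area 0.04
  st <- frame_defect_stats(merge_cells_to_defects(cls, g))
  expect_equal(st$total_area_nm2[st$class == "total"], 0.06)
  expect_equal(st$mean_area_nm2[st$class == "total"], 0.03)
  expect_equal(st$area_fraction[st$class == "total"], 0.06 / 4)
  empty <- frame_defect_stats(merge_cells_to_defects(
    matrix("none", g$nx, g$ny), g))
  expect_equal(empty$n_defects, c(0L, 0L, 0L))
  expect_true(all(is.na(empty$mean_area_nm2)))
  expect_false(any(empty$mean_defined))
})

test_that("aggregation uses population SD and reference ratios", {
  g <- build_grid(make_grid_frame(c(2, 2, 5)), 0.1)
  mk <- function(n_cells_apart) {
    cls <- matrix("none", g$nx, g$ny)
    for (k in seq_len(n_cells_apart)) cls[k * 5, 3] <- "shallow"
    frame_defect_stats(merge_cells_to_defects(cls, g))
  }
  agg <- aggregate_trajectory_stats(list(mk(2), mk(4)))
  tot <- agg[agg$class == "total", ]
  expect_equal(tot$n_defects_mean, 3)
  expect_equal(tot$n_defects_sd, 1)      # population SD of {2, 4}
  self_ratio <- aggregate_trajectory_stats(list(mk(2), mk(4)), reference = agg)
  expect_equal(self_ratio$ratio_to_reference[self_ratio$class == "total"], 1)
  expect_error(aggregate_trajectory_stats(list()), "no per-frame")
  zero <- aggregate_trajectory_stats(list(mk(0)))
  expect_error(aggregate_trajectory_stats(list(mk(2)), reference = zero),
               "zero mean")
})

test_that("defect statistics are invariant under lattice-commensurate xy shifts", {
  gen <- small_bilayer(36, seed = 13, preset = "chol40", kappa = 0.5)
  base <- analyze_defects(gen$frame, gen$topology, leaflet = "upper")
  g <- build_grid(gen$frame, 0.1)
  for (shift in list(c(5, 0), c(0, 17), c(23, 41))) {
    fr <- gen$frame
    fr$atoms$x <- memdefect:::wrap_coord(fr$atoms$x + shift[1] * g$cell_x,
                                         fr$box[1])
    fr$atoms$y <- memdefect:::wrap_coord(fr$atoms$y + shift[2] * g$cell_y,
                                         fr$box[2])
    moved <- analyze_defects(fr, gen$topology, leaflet = "upper")
    expect_equal(moved$per_frame$n_defects, base$per_frame$n_defects)
    expect_equal(moved$per_frame$total_area_nm2,
                 base$per_frame$total_area_nm2, tolerance = 1e-12)
    expect_equal(sort(moved$areas_A2$all), sort(base$areas_A2$all),
                 tolerance = 1e-9)
  }
})

test_that("total defect area equals cell area times defect-cell count every frame", {
  for (seed in c(3, 8)) {
    gen <- small_bilayer(49, seed = seed, preset = "chol40", kappa = 0.6)
    g <- build_grid(gen$frame, 0.1)
    map <- project_and_classify_cells(gen$frame, gen$topology, g, "upper")
    cls <- detect_defect_cells(map)
    d <- merge_cells_to_defects(cls, g)
    expect_equal(sum(d$area_nm2),
                 sum(cls != "none") * memdefect:::cell_area(g),
                 tolerance = 1e-12)
    # partition: per-class defects jointly cover all defect cells, disjointly
    expect_equal(sum(d$n_cells), sum(cls != "none"))
  }
})

test_that("halving the grid cell changes total defect area by less than 20%", {
  gen <- small_bilayer(64, seed = 21, preset = "chol40", kappa = 0.7)
  coarse <- analyze_defects(gen$frame, gen$topology, cell_size = 0.1)
  fine <- analyze_defects(gen$frame, gen$topology, cell_size = 0.05)
  a1 <- coarse$per_frame$total_area_nm2[coarse$per_frame$class == "total"]
  a2 <- fine$per_frame$total_area_nm2[fine$per_frame$class == "total"]
  expect_lt(abs(a2 - a1) / a1, 0.2)
})
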