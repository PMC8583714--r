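test_that("the reference geometry meshes with the documented layout", {
  m <- build_mesh(do_geometry(), callus_size = 0.25)
  # callus annulus spans r in [6, 8] with 4 rows across the 1 mm gap
  callus <- m$region == "callus"
  expect_true(all(m$centroids[callus, "r"] > 6 & m$centroids[callus, "r"] < 8))
  expect_equal(length(unique(round(m$centroids[callus, "z"], 9))), 4)
  expect_setequal(unique(m$region), c("cortex", "marrow", "callus"))
  # area conservation against the analytic region area
  expect_equal(sum(m$areas), analytic_mesh_area(m),
               tolerance = 1e-9)
  # boundary tagging: every boundary node carries exactly one tag
  expect_true(all(is.na(m$tag) | m$tag %in%
                    c("bottom_fixed", "top_loaded", "axis", "free")))
  expect_gt(sum(m$tag == "axis", na.rm = TRUE), 0)
  expect_gt(sum(m$tag == "bottom_fixed", na.rm = TRUE), 0)
})

test_that("degenerate geometries are rejected with diagnostics", {
  expect_error(do_geometry(initial_gap = 0), "initial_gap")
  expect_error(do_geometry(endosteal_diameter = 16, periosteal_diameter = 16),
               "wall thickness")
  expect_error(do_geometry(current_gap = 0.5), "current_gap")
  expect_error(build_mesh(do_geometry(), callus_size = 2), "initial gap")
})

test_that("a widened gap meshes to exactly the new callus height", {
  m <- build_mesh(do_geometry(current_gap = 15), callus_size = 0.5)
  callus_z <- m$nodes[unique(as.vector(
    m$elem[m$region == "callus", ])), "z"]
  expect_equal(range(callus_z), c(0, 15))
})

test_that("remesh is idempotent and conserves area through a distraction chain", {
  m <- build_mesh(do_geometry(), callus_size = 0.25)
  m_same <- remesh(m, m$geometry$current_gap)
  expect_identical(m$nodes, m_same$nodes)
  expect_identical(m$elem, m_same$elem)
  expect_error(remesh(m, 0.5), "smaller")

  # 30 successive 0.5 mm increments: 1 mm -> 16 mm
  mm <- m
  for (k in 1:30) mm <- remesh(mm, mm$geometry$current_gap + 0.5)
  expect_equal(mm$geometry$current_gap, 16)
  expect_equal(sum(mm$areas), analytic_mesh_area(mm), tolerance = 1e-9)
  # positive Jacobians throughout (the FE setup checks and would stop)
  expect_silent(dosim:::.fe_setup(mm))
  # aspect ratios bounded
  el <- mm$elem
  dr <- mm$nodes[el[, 2], 1] - mm$nodes[el[, 1], 1]
  dz <- mm$nodes[el[, 4], 2] - mm$nodes[el[, 1], 2]
  expect_lt(max(pmax(dr / dz, dz / dr)), 5)
})

test_that("field transfer preserves constants, identity and the convex hull", {
  m <- build_mesh(do_geometry(current_gap = 5), callus_size = 0.5)
  m2 <- remesh(m, 5.5)
  n <- nrow(m$elem)

  f <- data.frame(conn = rep(40, n))
  tf <- transfer_fields(m, f, m2, new_volume = "slab")
  old_band <- m2$region != "callus" | m2$centroids[, "z"] <= 5 - 1e-9
  expect_equal(tf$conn[old_band], rep(40, sum(old_band)), tolerance = 1e-12)
  # freshly distracted slab reset to connective tissue
  expect_equal(unique(tf$conn[!old_band]), 100)

  # centre insertion: the virgin band appears at mid-gap, fronts preserved
  tfc <- transfer_fields(m, f, m2, new_volume = "center")
  zc <- m2$centroids[, "z"]
  mid_band <- m2$region == "callus" & zc > 2.5 & zc < 3.0
  ends <- m2$region == "callus" & (zc < 2 | zc > 3.5)
  expect_equal(unique(tfc$conn[mid_band]), 100)
  expect_equal(tfc$conn[ends], rep(40, sum(ends)), tolerance = 1e-9)

  # identity on an unchanged mesh, even for a non-constant field
  zfield <- data.frame(x = m$centroids[, "z"] + 3 * m$centroids[, "r"])
  expect_equal(transfer_fields(m, zfield, m, fresh_values = list())$x,
               zfield$x, tolerance = 1e-9)

  # convex hull: transferred values bounded by source range
  rnd <- data.frame(x = sin(seq_len(n)) * 50 + 50)
  tx <- transfer_fields(m, rnd, m2, fresh_values = list(x = min(rnd$x)))$x
  expect_true(all(tx >= min(rnd$x) - 1e-12 & tx <= max(rnd$x) + 1e-12))
})

test_that("transfer reproduces a linear axial profile on a refined mesh", {
  m <- build_mesh(do_geometry(current_gap = 10), callus_size = 0.5)
  m_fine <- build_mesh(do_geometry(current_gap = 10), callus_size = 0.25)
  lin <- data.frame(x = 10 * m$centroids[, "z"])
  tf <- transfer_fields(m, lin, m_fine,
                        spec = field_transfer_spec(sigma = 0.5),
                        fresh_values = list(x = 0))
  callus <- m_fine$region == "callus"
  interior <- callus & m_fine$centroids[, "z"] > 1 &
    m_fine$centroids[, "z"] < 9
  expected <- 10 * m_fine$centroids[interior, "z"]
  expect_lt(max(abs(tf$x[interior] - expected) / abs(expected)), 0.05)
})

test_that("VTK snapshots serialise the mesh and cell fields", {
  m <- build_mesh(do_geometry(), callus_size = 0.25)
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(m, data.frame(bone = seq_len(nrow(m$elem))), path)
  txt <- readLines(path)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^CELL_DATA", txt)))
  expect_true(any(grepl("SCALARS bone double 1", txt)))
  npts <- as.integer(strsplit(grep("^POINTS", txt, value = TRUE), " ")[[1]][2])
  expect_equal(npts, nrow(m$nodes))
})
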