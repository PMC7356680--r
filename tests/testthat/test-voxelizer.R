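test_that("study-size tablet fits the reference 293^3 grid at 74 um", {
  f <- formulation(component("x", 1, 1.3928, "soluble", 1L, "api"))
  tb <- tablet_spec(list(layer_spec(f, 1000, 0.07, "L", thickness_mm = 10.75)),
                    21.5, 10)
  g <- voxelize(tb, pitch_um = 74, margin_voxels = 1L)
  expect_true(all(dim(g$state) <= 293))
  expect_equal(dim(g$state)[1], 293)
  expect_error(voxelize(tb, pitch_um = 74, max_dim = 100), "max_dim")
})

test_that("voxelized cross-section area matches the closed form within 1%", {
  f <- formulation(component("x", 1, 1.4, "soluble", 1L, "api"))
  tb <- tablet_spec(list(layer_spec(f, 1000, 0.07, "L", thickness_mm = 2)),
                    21.5, 10)
  g <- voxelize(tb, pitch_um = 74)
  z_mid <- ceiling(dim(g$state)[3] / 2)
  count <- sum(g$layer[, , z_mid] > 0)
  expect_equal(count * 0.074^2, cross_section_area(tb), tolerance = 0.01)
})

test_that("zero-thickness layers warn and contribute no voxels", {
  f <- formulation(component("x", 1, 1.4, "soluble", 1L, "api"))
  tb <- tablet_spec(list(layer_spec(f, 500, 0.1, "a", thickness_mm = 2),
                         layer_spec(f, 0, 0.1, "b", thickness_mm = 0)),
                    8, 5)
  expect_warning(g <- voxelize(tb, pitch_um = 400), "Zero-thickness")
  expect_equal(sum(g$layer == 2), 0)
})

test_that("achieved porosity matches the target within 0.5 points", {
  fx <- paper_formulations()
  g <- assign_components(voxelize(fx$asa_tablet, pitch_um = 200), seed = 7)
  s <- grid_summary(g)$layers
  expect_gt(s$voxels, 1e4)
  expect_lt(abs(s$achieved_porosity - 0.071), 0.005)
  # MA layer inside the bilayer, target 11.1%
  gb <- assign_components(voxelize(fx$bilayer, pitch_um = 180), seed = 7)
  sb <- grid_summary(gb)$layers
  ma <- sb[sb$label == "MA layer", ]
  expect_gt(ma$voxels, 1e4)
  expect_lt(abs(ma$achieved_porosity - 0.111), 0.005)
})

test_that("components with equal volume fractions get equal counts", {
  f <- formulation(component("a", 0.5, 1.3, "soluble", 1L, "api"),
                   component("b", 0.5, 1.3, "soluble", 1L, "diluent"))
  tb <- tablet_spec(list(layer_spec(f, 800, 0.0, "L")), 10, 8)
  g <- assign_components(voxelize(tb, pitch_um = 150), seed = 11)
  na <- sum(g$state == 1L)
  nb <- sum(g$state == 2L)
  n <- na + nb
  expect_lt(abs(na - n / 2), 3 * sqrt(n * 0.25)) # binomial 3 sigma
})

test_that("voxel counts are conserved and assignment is reproducible", {
  fx <- paper_formulations()
  g0 <- voxelize(fx$triple_layer, pitch_um = 700)
  s0 <- grid_summary(g0)$states
  expect_equal(sum(s0$count), prod(dim(g0$state)))
  g1 <- assign_components(g0, seed = 3)
  g2 <- assign_components(g0, seed = 3)
  expect_identical(g1$state, g2$state)
  expect_equal(sum(grid_summary(g1)$states$count), prod(dim(g1$state)))
  # assignment relabels tablet voxels only
  expect_equal(sum(g1$state == 0L), sum(g0$layer == 0L))
  g3 <- assign_components(g0, seed = 4)
  expect_false(identical(g1$state, g3$state))
})

test_that("porosity error shrinks as the layer grows (law of large numbers)", {
  fx <- paper_formulations()
  dev <- function(pitch, seed) {
    g <- assign_components(voxelize(fx$asa_tablet, pitch_um = pitch), seed)
    s <- grid_summary(g)$layers
    abs(s$achieved_porosity - s$target_porosity)
  }
  coarse <- mean(vapply(1:5, function(s) dev(900, s), numeric(1)))
  fine <- mean(vapply(1:5, function(s) dev(200, s), numeric(1)))
  expect_lt(fine, coarse)
})

test_that("pore network spans only above the percolation threshold", {
  g0 <- make_cube_grid(40, porosity = 0)
  expect_false(percolation_check(g0, 1))
  g_hi <- make_cube_grid(40, porosity = 0.9, seed = 2)
  expect_true(percolation_check(g_hi, 1))
  g_lo <- make_cube_grid(40, porosity = 0.05, seed = 2)
  expect_false(percolation_check(g_lo, 1))
  expect_error(percolation_check(g_hi, 5), "Unknown layer")
  expect_true(percolation_check(g_hi, "cube"))
})

test_that("flood fill agrees with a queue-based oracle on small grids", {
  bfs_spans <- function(grid) {
    pores <- grid$state == -1L & grid$layer == 1L
    d <- dim(pores)
    zs <- which(apply(grid$layer == 1L, 3, any))
    z_lo <- min(zs); z_hi <- max(zs); z_mid <- floor((z_lo + z_hi) / 2)
    seen <- array(FALSE, d)
    queue <- which(pores & slice_mask(d, c(z_lo, z_hi)))
    seen[queue] <- TRUE
    offs <- c(-1, 1, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
    coord <- function(i) arrayInd(i, d)
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      ci <- coord(i)
      for (k in 1:6) {
        cj <- ci + rbind(c(-1,0,0),c(1,0,0),c(0,-1,0),c(0,1,0),
                         c(0,0,-1),c(0,0,1))[k, ]
        if (any(cj < 1) || any(cj > d)) next
        j <- cj[1] + (cj[2] - 1) * d[1] + (cj[3] - 1) * d[1] * d[2]
        if (pores[j] && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    any(seen & slice_mask(d, z_mid))
  }
  slice_mask <- function(d, zs) {
    m <- array(FALSE, d); m[, , zs] <- TRUE; m
  }
  for (s in 1:4) {
    for (eps in c(0.2, 0.35, 0.6)) {
      g <- make_cube_grid(10, porosity = eps, seed = s, margin = 0L)
      expect_identical(percolation_check(g, 1), bfs_spans(g),
                       label = sprintf("eps=%g seed=%d", eps, s))
    }
  }
})
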