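test_that("a single wetted voxel dissolves exactly at its resistance", {
  for (r in c(1L, 3L, 5L)) {
    g <- make_cube_grid(1, resistance = r)
    res <- ca_run(ca_initialize(g, oracle_rules(), seed = 1))
    expect_equal(res$steps, r)
    prof <- res$profile[res$profile$species == "X", ]
    expect_equal(prof$released_pct[prof$time_s < r], rep(0, r))
    expect_equal(prof$released_pct[prof$time_s == r], 100)
  }
})

test_that("3x3x3 unit-resistance cube dissolves shell-then-core in 2 steps", {
  g <- make_cube_grid(3)
  st <- ca_initialize(g, oracle_rules(), seed = 1)
  st1 <- ca_step(st)
  expect_equal(sum(st1$grid$state == 1L), 1L) # core survives step 1
  expect_equal(st1$ledger$dissolved_voxels, 26L)
  st2 <- ca_step(st1)
  expect_equal(sum(st2$grid$state == 1L), 0L)
  expect_equal(st2$ledger$dissolved_voxels, 27L)
})

test_that("cubes dissolve as a unit-speed erosion front (brute-force oracle)", {
  for (W in 2:7) {
    g <- make_cube_grid(W)
    res <- ca_run(ca_initialize(g, oracle_rules(), seed = 1))
    expect_equal(res$steps, ceiling(W / 2), label = paste("W =", W))
    expect_equal(res$steps, erosion_front_steps(W), label = paste("W =", W))
  }
})

test_that("insoluble material never releases and blocks liquid", {
  rules <- ca_rules(ingress_probability = 0.9, detachment_threshold = 2L)
  g <- make_cube_grid(4, solubility = "insoluble")
  res <- suppressWarnings(ca_run(ca_initialize(g, rules, seed = 2),
                                 max_steps = 50))
  expect_equal(res$ledger$dissolved_voxels, 0L)
  expect_true(is.na(disintegration_time(res)))
  # soluble voxel sealed inside an insoluble shell is never wetted
  sealed <- suppressWarnings(
    ca_run(ca_initialize(make_sealed_grid(), rules, seed = 2),
           max_steps = 60))
  expect_equal(sealed$ledger$dissolved_voxels, c(0L, 0L))
  expect_equal(sum(sealed$final_state$grid$state == 1L), 1L)
})

test_that("per-species mass ledger balances exactly at every step", {
  toys <- toy_tablets(scale = 14, seed = 5)
  st <- ca_initialize(toys$triple, default_rules(), seed = 9)
  prev_rel <- rep(0L, nrow(st$ledger))
  for (k in 1:40) {
    st <- ca_step(st)
    remaining <- vapply(st$ledger$species_id, function(id)
      sum(st$grid$state == id), integer(1))
    expect_identical(remaining + st$ledger$dissolved_voxels +
                       st$ledger$detached_voxels,
                     st$ledger$initial_voxels)
    # cumulative release is monotone
    expect_true(all(st$ledger$dissolved_voxels >= prev_rel))
    prev_rel <- st$ledger$dissolved_voxels
  }
  # insoluble species (PCL, MgSt, MCC) never enter the dissolved ledger
  insol <- st$ledger$solubility_class == "insoluble"
  expect_equal(st$ledger$dissolved_voxels[insol],
               rep(0L, sum(insol)))
})

test_that("runs are bit-identical for identical grid, rules and seed", {
  toys <- toy_tablets(scale = 12, seed = 3)
  a <- simulate_release(toys$bilayer, default_rules(), seed = 21,
                        max_steps = 500)
  b <- simulate_release(toys$bilayer, default_rules(), seed = 21,
                        max_steps = 500)
  expect_identical(a$profile, b$profile)
  expect_identical(a$final_state$grid$state, b$final_state$grid$state)
  c <- simulate_release(toys$bilayer, default_rules(), seed = 22,
                        max_steps = 500)
  expect_false(identical(a$profile, c$profile))
})

test_that("raising a species' resistance never accelerates its release", {
  for (s in 1:3) {
    toys <- toy_tablets(scale = 14, seed = s)
    r_fast <- default_rules(); r_fast$resistance_override <- c(ASA = 4)
    r_slow <- default_rules(); r_slow$resistance_override <- c(ASA = 8)
    a <- simulate_release(toys$bilayer, r_fast, seed = s + 50, max_steps = 600)
    b <- simulate_release(toys$bilayer, r_slow, seed = s + 50, max_steps = 600)
    pa <- a$profile[a$profile$species == "ASA", ]
    pb <- b$profile[b$profile$species == "ASA", ]
    tt <- intersect(pa$time_s, pb$time_s)
    expect_true(all(pb$released_pct[match(tt, pb$time_s)] <=
                      pa$released_pct[match(tt, pa$time_s)] + 1e-12))
  }
})

test_that("release curves are monotone, bounded and reach completion", {
  toys <- toy_tablets(scale = 12, seed = 8)
  res <- simulate_release(toys$asa, default_rules(), seed = 4, max_steps = 800)
  by_sp <- split(res$profile, res$profile$species)
  for (p in by_sp) {
    p <- p[order(p$time_s), ]
    expect_true(all(diff(p$released_pct) >= -1e-12))
    expect_true(all(p$released_pct >= 0 & p$released_pct <= 100 + 1e-9))
    expect_equal(p$released_pct[nrow(p)], 100)
  }
})

test_that("disintegration endpoint and time calibration", {
  g <- make_cube_grid(1, resistance = 4)
  res <- ca_run(ca_initialize(g, oracle_rules(seconds_per_step = 2.5), seed = 1))
  expect_equal(disintegration_time(res), 4 * 2.5)
  # bilayer disintegrates slower than either single-layer tablet
  toys <- toy_tablets(scale = 20, seed = 5)
  dt <- vapply(toys[c("ma", "asa", "bilayer")], function(g)
    disintegration_time(ca_run(ca_initialize(g, default_rules(), seed = 7),
                               max_steps = 2000)), numeric(1))
  expect_gt(dt[["bilayer"]], dt[["ma"]])
  expect_gt(dt[["bilayer"]], dt[["asa"]])
  # calibration rescales the anchor to the target time
  ref <- ca_run(ca_initialize(toys$asa, default_rules(), seed = 7),
                max_steps = 2000)
  spp <- calibrate_seconds_per_step(ref, "ASA", target_time_s = 81)
  expect_equal(time_to_release(ref, "ASA", 80) * spp, 81, tolerance = 1e-9)
})

test_that("missing rule inputs are rejected", {
  toys <- toy_tablets(scale = 10, seed = 1)
  bad <- ca_rules(ingress_probability = c("ASA layer" = 0.9))
  expect_error(ca_initialize(toys$bilayer, bad, seed = 1), "missing")
  expect_error(ca_rules(ingress_probability = 0), "\\(0, 1\\]")
  expect_error(ca_rules(resistance_override = c(2, 3)), "named")
})
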