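test_that("layout presets give the documented travel-distance distributions", {
  g <- device_layout("G", tcycle = 0.5)
  expect_identical(g$distinct_dtravel, 1L)
  expect_identical(g$occurrences, 5040L)
  a <- device_layout("A", tcycle = 0.75)
  expect_length(a$distinct_dtravel, 1260L)
  expect_identical(a$Ncollection, 5040L)
  d <- device_layout("D", tcycle = 0.5)
  expect_length(d$distinct_dtravel, 70L)
  for (nm in c("B", "C", "E", "F")) {
    l <- device_layout(nm)
    expect_identical(l$Ncollection, 5040L)
    expect_identical(length(l$distinct_dtravel) * l$occurrences, l$Ncollection)
  }
  expect_identical(device_layout("H")$Ncollection, 10080L)
  expect_identical(device_layout("I")$Ncollection, 10080L)
  expect_error(device_layout("Z"), "presets")
  custom <- device_layout("mini", n_distinct = 4, occurrences = 2)
  expect_identical(custom$Ncollection, 8L)
})

test_that("travel time is the product of distance and cycle time", {
  expect_equal(travel_time(1260, 0.75), 945)
  expect_equal(travel_time(1, 0.25), 0.25)
  expect_equal(travel_time(10, 0.5), 5)
  expect_error(travel_time(0, 0.5), "dtravel")
})

test_that("gland placement draws distinct sites reproducibly", {
  lay <- device_layout("D")
  p1 <- assign_glands(lay, 11, seed = 42)
  p2 <- assign_glands(lay, 11, seed = 42)
  expect_identical(p1, p2)
  expect_identical(anyDuplicated(p1$site), 0L)
  expect_true(all(p1$dtravel %in% lay$distinct_dtravel))
  # single-distance layout: every gland shares the travel distance
  pg <- assign_glands(device_layout("G"), 3, seed = 1)
  expect_identical(unique(pg$dtravel), 1L)
  expect_error(assign_glands(device_layout("mini", n_distinct = 2,
                                           occurrences = 1), 3),
               "collection sites")
})

test_that("two-gland collision probability matches the sampling design", {
  # layout A: 4 sites per distance; P(shared distance) = 3/5039
  lay <- device_layout("A")
  hits <- vapply(1:4000, function(s) {
    p <- assign_glands(lay, 2, seed = s)
    p$dtravel[1] == p$dtravel[2]
  }, NA)
  p_hat <- mean(hits)
  p_true <- 3 / 5039
  expect_lt(abs(p_hat - p_true), 4 * sqrt(p_true * (1 - p_true) / 4000))
})

test_that("Poisson occupancy check reproduces the device sizing argument", {
  # ~0.5 cm^2 total area at 10 glands/cm^2 gives lambda = 5
  d_um <- 2 * sqrt(1e-4 / pi) * 1e4 # site diameter for 1e-4 cm^2 per site
  occ <- occupancy_check(10, d_um, 5000)
  expect_equal(occ$lambda_total, 5, tolerance = 1e-6)
  expect_equal(occ$p_at_least_one_overall, 1 - exp(-5), tolerance = 1e-6)
  # the tail above 11 glands is ~0.5%, not the advertised < 0.01%
  expect_equal(occ$p_exceeds_nsg_max, 1 - ppois(11, 5), tolerance = 1e-9)
  expect_gt(occ$p_exceeds_nsg_max, 1e-3)
  expect_equal(occupancy_check(10, 1e-6, 1)$p_at_most_one_per_site, 1,
               tolerance = 1e-6)
})

test_that("transport is a pure delay and equal-time arrivals merge", {
  lay <- device_layout("D", tcycle = 0.5)
  ev <- simulate_gland(gland_params(0.7), n_cycles = 2, tcycle = 0.5)
  # single gland: pure shift by dtravel ticks
  pl1 <- data.frame(gland_id = 1L, site = 1L, dtravel = 7L)
  sig1 <- synthesize_signal(lay, pl1, list(ev))
  expect_equal(sig1$tick, ev$tick + 7L)
  expect_equal(sig1$volume_nL, ev$volume_nL)
  expect_equal(diff(sig1$time_s), diff(ev$time_s))
  # two glands, same distance: full merging by volume summation
  pl2 <- data.frame(gland_id = 1:2, site = 1:2, dtravel = c(7L, 7L))
  sig2 <- synthesize_signal(lay, pl2, list(ev, ev))
  expect_equal(sig2$tick, ev$tick + 7L)
  expect_equal(sig2$volume_nL, 2 * ev$volume_nL)
  # three glands, two shared distances: delayed third stream
  pl3 <- data.frame(gland_id = 1:3, site = 1:3, dtravel = c(7L, 7L, 20L))
  sig3 <- synthesize_signal(lay, pl3, list(ev, ev, ev))
  expect_equal(sum(sig3$volume_nL), 3 * sum(ev$volume_nL), tolerance = 1e-12)
  first_arrivals <- sig3$volume_nL[sig3$tick %in% (ev$tick + 7L)]
  expect_true(all(abs(first_arrivals - 2 * ev$volume_nL) < 1e-12))
})

test_that("merging is order-independent and conserves volume", {
  lay <- device_layout("C", tcycle = 0.5)
  ev <- simulate_gland(gland_params(0.9), n_cycles = 2, tcycle = 0.5)
  pl <- data.frame(gland_id = 1:4, site = 1:4, dtravel = c(3L, 9L, 3L, 30L))
  sig <- synthesize_signal(lay, pl, list(ev, ev, ev, ev))
  perm <- c(4L, 2L, 1L, 3L)
  sigp <- synthesize_signal(lay, pl[perm, ], list(ev, ev, ev, ev))
  expect_equal(as.data.frame(sig), as.data.frame(sigp))
  expect_equal(sum(sig$volume_nL), 4 * sum(ev$volume_nL), tolerance = 1e-12)
  expect_true(all(diff(sig$tick) > 0))
})

test_that("simulated signals carry their ground truth out of the estimator's reach", {
  sig <- simulate_signal(device_layout("D"), 4, gland_params(0.4), seed = 8)
  tr <- attr(sig, "truth")
  expect_identical(tr$n_glands, 4L)
  expect_identical(tr$n_cycles, 5L)
  expect_identical(nrow(tr$placement), 4L)
  # estimator input columns carry no gland identity
  expect_named(as.data.frame(sig), c("tick", "time_s", "volume_nL"))
})
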