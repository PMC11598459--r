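lay <- device_layout("D", tcycle = 0.5)

test_that("single-gland signals at low and medium rates are uniquely resolved", {
  for (SRg in c(0.4, 0.7)) {
    fit <- estimate_nsg(simulate_signal(lay, 1, gland_params(SRg), seed = 2))
    for (r in fit$results) {
      expect_identical(r$nsg_candidates, 1L)
      expect_identical(r$status, "unique")
    }
  }
})

test_that("a single gland at four droplets per period admits the halved-rate twin", {
  fit <- estimate_nsg(simulate_signal(lay, 1, gland_params(0.8), seed = 3))
  r <- fit$results[[1]]
  expect_identical(r$nsg_candidates, c(1L, 2L))
  expect_identical(r$status, "ambiguous")
  expect_true(3L %in% r$ambiguity_types)
})

test_that("the estimator recovers moderate gland counts across layouts", {
  for (nm in c("B", "D", "F", "H")) {
    l <- device_layout(nm, tcycle = 0.5)
    for (n in c(2L, 6L, 11L)) {
      fit <- estimate_nsg(simulate_signal(l, n, gland_params(0.4), seed = 17))
      for (r in fit$results)
        expect_true(n %in% r$nsg_candidates,
                    label = sprintf("layout %s NSG=%d", nm, n))
    }
  }
})

test_that("ambiguity classification distinguishes count and interval ambiguity", {
  # interval ambiguity (different spacing sets)
  d1 <- data.frame(dt_travel_s = 0, dt_droplet_s = 7.5, nd = 4L)
  d2 <- data.frame(dt_travel_s = c(0, 7.5), dt_droplet_s = c(15, 15),
                   nd = c(2L, 2L))
  res <- list(nsg_candidates = c(1L, 2L), status = "ambiguous",
              failure_step = NA_character_, ambiguity_types = integer(0),
              quantizations = list(list(vsg_hat = 0.2)),
              decompositions = list(d1, d2))
  class(res) <- "segment_result"
  expect_identical(classify_ambiguity(res), 3L)
  # count ambiguity (same interval, different allocation)
  d3 <- data.frame(dt_travel_s = c(0, 36), dt_droplet_s = c(12, 12),
                   nd = c(3L, 3L))
  d4 <- data.frame(dt_travel_s = c(0, 24, 48), dt_droplet_s = c(12, 12, 12),
                   nd = c(2L, 2L, 2L))
  res$decompositions <- list(d3, d4)
  expect_identical(classify_ambiguity(res), 2L)
  res$decompositions <- list(d1)
  expect_identical(classify_ambiguity(res), integer(0))
  # two admissible quantizations mark type 1
  res$quantizations <- list(list(vsg_hat = 0.2), list(vsg_hat = 0.21))
  expect_identical(classify_ambiguity(res), 1L)
})

test_that("segmentation-infeasible layouts propagate as per-segment failures", {
  layA <- device_layout("A", tcycle = 0.75)
  sig <- suppressWarnings(simulate_signal(layA, 2, gland_params(0.4), seed = 1))
  fit <- estimate_nsg(sig)
  expect_length(fit$results, 5L)
  for (r in fit$results) {
    expect_identical(r$status, "failure")
    expect_identical(r$failure_step, "segmentation")
    expect_equal(segment_error(r, 2), 100)
  }
})

test_that("fully merged single-distance signals stay quantizable and correct", {
  # all droplets merge on layout G; the shared volume is still the unique
  # admissible quantization and the stacked patterns give the true count
  layG <- device_layout("G", tcycle = 0.5)
  for (n in c(3L, 5L, 8L)) {
    fit <- estimate_nsg(simulate_signal(layG, n, gland_params(0.4), seed = 4))
    expect_true(all(vapply(fit$results, function(r)
      n %in% r$nsg_candidates, NA)))
  }
})

test_that("fit accessors expose candidates, fitted pulse trains and residuals", {
  sig <- simulate_signal(lay, 3, gland_params(0.4), seed = 11)
  fit <- estimate_nsg(sig)
  co <- coef(fit)
  expect_identical(nrow(co), 5L)
  expect_named(co, c("segment", "status", "nsg_candidates", "ambiguity_types"))
  ft <- fitted(fit)
  rs <- residuals(fit)
  for (i in seq_along(ft)) {
    seg <- fit$segments[[i]]
    expect_identical(ft[[i]]$tick, seg$tick)
    expect_equal(ft[[i]]$volume_nL, seg$volume_nL, tolerance = 1e-9)
    expect_equal(rs[[i]], rep(0, nrow(seg)), tolerance = 1e-9)
  }
  expect_output(print(fit), "unique")
  expect_output(summary(fit), "candidate")
})

test_that("the full pipeline is deterministic for a fixed seed", {
  f1 <- estimate_nsg(simulate_signal(lay, 7, gland_params(0.7), seed = 123))
  f2 <- estimate_nsg(simulate_signal(lay, 7, gland_params(0.7), seed = 123))
  expect_identical(coef(f1), coef(f2))
  f3 <- estimate_nsg(simulate_signal(lay, 7, gland_params(0.7), seed = 124))
  expect_false(identical(as.data.frame(f1$signal), as.data.frame(f3$signal)))
})
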