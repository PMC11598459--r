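lay_d <- device_layout("D", tcycle = 0.5)

test_that("minimal and split pattern enumeration matches the worked cases", {
  # two pulses at an admissible spacing: exactly one explanation
  seg <- data.frame(tick = c(0L, 30L), time_s = c(0, 15),
                    volume_nL = c(0.2, 0.2))
  q <- quantize_segment(seg, 0.2, 0.5)[[1]]
  ds <- decompose_segment(q, seg, lay_d)
  expect_length(ds, 1L)
  expect_identical(ds[[1]]$nd, 2L)
  expect_equal(ds[[1]]$dt_droplet_s, 15)

  # four evenly spaced pulses: one gland at the full rate or two glands at
  # half the rate with doubled spacing
  seg4 <- data.frame(tick = c(0L, 15L, 30L, 45L), time_s = c(0, 7.5, 15, 22.5),
                     volume_nL = rep(0.2, 4))
  q4 <- quantize_segment(seg4, 0.2, 0.5)[[1]]
  ds4 <- decompose_segment(q4, seg4, lay_d)
  expect_setequal(vapply(ds4, nrow, 0L), c(1L, 2L))
  sp <- vapply(ds4, function(d) unique(d$dt_droplet_s), 0)
  expect_setequal(sp, c(7.5, 15))

  # six pulses at a spacing whose physiology admits two or three droplets:
  # two glands of three or three glands of two, same interval (the span
  # needs layout B's wider travel-time range)
  lay_b <- device_layout("B", tcycle = 0.5)
  seg6 <- data.frame(tick = seq(0L, 120L, by = 24L),
                     time_s = seq(0, 60, by = 12), volume_nL = rep(0.2, 6))
  q6 <- quantize_segment(seg6, 0.2, 0.5)[[1]]
  ds6 <- decompose_segment(q6, seg6, lay_b)
  expect_setequal(vapply(ds6, nrow, 0L), c(2L, 3L))
  expect_true(all(vapply(ds6, function(d) all(d$dt_droplet_s == 12), NA)))
})

test_that("decomposition equals brute-force partition enumeration on small segments", {
  set.seed(71)
  n_checked <- 0L
  for (case in 1:40) {
    n_glands <- sample(1:3, 1)
    SRg <- sample(c(0.4, 0.5, 0.55, 0.6, 0.7), 1)
    ev <- simulate_gland(gland_params(SRg), n_cycles = 1, tcycle = 0.5)
    d <- sort(sample(lay_d$distinct_dtravel, n_glands))
    arr <- unlist(lapply(d, function(x) ev$tick + x))
    tab <- table(arr)
    ticks <- as.integer(names(tab))
    mult <- as.integer(tab)
    if (sum(mult) > 8L) next
    seg <- data.frame(tick = ticks, time_s = ticks * 0.5,
                      volume_nL = mult * ev$volume_nL[1])
    q <- quantize_segment(seg, 0.2, 0.5)[[1]]
    got <- decomposition_signatures(decompose_segment(q, seg, lay_d), 0.5)
    rel <- ticks - ticks[1]
    cand_s <- candidate_intervals(seg, 30, 0.5)
    cand_s <- cand_s[cand_s >= 0.2 * 30 / 1]
    cand_t <- as.integer(round(cand_s / 0.5))
    if (q$vsg_hat - 0.2 > 1e-12)
      cand_t <- cand_t[cand_t < q$vsg_hat / (q$vsg_hat - 0.2) - 1e-9]
    want <- oracle_decompose(rel, q$mult, cand_t,
                             span_ticks = 60L, dmax = 69L)
    expect_identical(got, want,
                     label = sprintf("case %d (SRg=%g, d=%s)", case, SRg,
                                     paste(d, collapse = ",")))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 15L)
})

test_that("every decomposition re-synthesizes the quantized train exactly", {
  set.seed(5)
  for (case in 1:10) {
    n_glands <- sample(1:6, 1)
    SRg <- sample(c(0.4, 0.7, 0.8, 1.0), 1)
    sig <- simulate_signal(lay_d, n_glands, gland_params(SRg),
                           seed = sample.int(1e6, 1))
    seg <- segment_signal(sig)[[1]]
    q <- quantize_segment(seg, 0.2, 0.5)[[1]]
    ds <- decompose_segment(q, seg, lay_d)
    expect_gt(length(ds), 0L)
    for (dcp in ds) {
      re <- resynthesize_decomposition(dcp, 0.5)
      expect_identical(re$tick + seg$tick[1L], seg$tick)
      expect_identical(re$mult, q$mult)
    }
  }
})

test_that("the count-set estimator path agrees with full enumeration", {
  set.seed(99)
  for (case in 1:12) {
    n_glands <- sample(1:8, 1)
    SRg <- sample(c(0.4, 0.7, 0.8), 1)
    sig <- simulate_signal(lay_d, n_glands, gland_params(SRg),
                           seed = sample.int(1e6, 1))
    seg <- segment_signal(sig)[[1]]
    res <- estimate_segment(seg, lay_d, anchor_mode = "range")
    q <- quantize_segment(seg, 0.2, 0.5)
    full <- integer(0)
    for (qi in q)
      full <- union(full, vapply(decompose_segment(qi, seg, lay_d), nrow, 0L))
    expect_identical(res$nsg_candidates, sort(full),
                     label = sprintf("case %d NSG=%d SRg=%g", case, n_glands,
                                     SRg))
  }
})

test_that("pattern spans are confined to one active period", {
  # five pulses at 6 s could not come from a gland dripping past the period
  seg <- data.frame(tick = seq(0L, 48L, by = 12L),
                    time_s = seq(0, 24, by = 6), volume_nL = rep(0.2, 5))
  q <- quantize_segment(seg, 0.2, 0.5)[[1]]
  ds <- decompose_segment(q, seg, lay_d)
  for (d in ds)
    expect_true(all((d$nd - 1) * d$dt_droplet_s <= 30 - 0.5))
  # a two-droplet pattern at 6 s spacing would leave the rest of the period
  # silent; it must not appear
  expect_false(any(vapply(ds, function(d)
    any(d$nd == 2 & d$dt_droplet_s == 6), NA)))
})
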