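# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the gland oracle integrates the volume on a fine
# time grid, and the decomposition oracle enumerates set partitions of the
# pulse instances.

# Fine-step accumulation oracle for a single gland: volume grows at SRg/tAP
# during the active period; at every activation (multiples of tcycle) the
# whole accumulated volume leaves if it has reached Vmin.
oracle_gland <- function(SRg, n_cycles, tcycle, Vmin = 0.2, tAP = 30,
                         tRP = 150) {
  rate <- SRg / tAP
  dt <- tcycle / 64 # binary fraction of the activation interval
  period <- tAP + tRP
  t_end <- n_cycles * period
  n_steps <- round(t_end / dt)
  vol <- 0
  times <- numeric(0); vols <- numeric(0); cycles <- integer(0)
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1) * dt
    t1 <- k * dt
    cyc <- floor(t0 / period + 1e-12)
    within_ap <- (t0 - cyc * period) < tAP - 1e-12
    if (within_ap) vol <- vol + rate * dt
    on_grid <- abs(t1 / tcycle - round(t1 / tcycle)) < 1e-9
    if (on_grid && vol >= Vmin - 1e-9) {
      times <- c(times, t1); vols <- c(vols, vol)
      cycles <- c(cycles, as.integer(floor((t1 - 1e-9) / period)) + 1L)
      vol <- 0
    }
  }
  list(time = times, volume = vols, cycle = cycles, Vres = vol)
}

# All set partitions of 1..n (blocks as index vectors).
set_partitions <- function(n) {
  if (n == 0L) return(list(list()))
  out <- list()
  rec <- function(i, blocks) {
    if (i > n) {
      out[[length(out) + 1L]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks; nb[[b]] <- c(nb[[b]], i)
      rec(i + 1L, nb)
    }
    rec(i + 1L, c(blocks, list(i)))
  }
  rec(2L, list(1L))
  out
}

# Brute-force decomposition oracle: enumerates every partition of the pulse
# instances into blocks, keeps partitions in which all blocks are evenly
# spaced runs sharing one common spacing from the candidate set, with the
# droplet count each spacing physiologically admits (the pattern must span
# the whole active period) and anchors within the admissible offset.
oracle_decompose <- function(ticks, mult, cand, span_ticks, dmax,
                             nd_min = 2L, nd_max = 120L, nsg_max = 27L) {
  inst <- rep(ticks, mult)
  stopifnot(length(inst) <= 9L)
  sols <- character(0)
  for (p in set_partitions(length(inst))) {
    if (length(p) > nsg_max) next
    for (s in cand) {
      lo <- max(nd_min, (span_ticks + s) %/% s - 1L)
      hi <- min(nd_max, (span_ticks - 1L) %/% s + 1L)
      ok <- TRUE
      pat <- character(0)
      for (b in p) {
        tk <- sort(inst[b])
        n <- length(tk)
        if (n < lo || n > hi) { ok <- FALSE; break }
        if (n > 1L && !all(diff(tk) == s)) { ok <- FALSE; break }
        if (n == 1L) { ok <- FALSE; break }
        if (tk[1L] > dmax) { ok <- FALSE; break }
        pat <- c(pat, paste(tk[1L], s, n))
      }
      if (ok) sols <- c(sols, paste(sort(pat), collapse = ";"))
    }
  }
  sort(unique(sols))
}

# Canonical signatures of decompose_segment() output for oracle comparison.
decomposition_signatures <- function(decomps, tcycle) {
  sort(unique(vapply(decomps, function(d) {
    paste(sort(paste(round(d$dt_travel_s / tcycle),
                     round(d$dt_droplet_s / tcycle), d$nd)),
          collapse = ";")
  }, "")))
}

# Hand-rolled percentile + published BCa formulas are exercised through
# boot::boot.ci in test-evaluate.R; this helper just centralises the sample.
skewed_sample <- function(n = 40, seed = 421) {
  set.seed(seed)
  round(rexp(n, rate = 0.05), 1)
}
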