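#' Exhaustively decompose a quantized segment into per-gland patterns
#'
#' Explains the integer pulse train of a quantized segment as a superposition
#' of per-gland droplet patterns. Each pattern is an evenly spaced run
#' (travel-time anchor, inter-droplet interval \code{dt_droplet}, droplet
#' count \code{nd}) contributing one droplet per position. A backtracking
#' search repeatedly explains the earliest unexplained pulse with a pattern
#' anchored there, subtracting multiplicities; a decomposition is emitted
#' whenever the residual is exactly zero and all constraints hold:
#' \itemize{
#'   \item at most \code{nsg_max} patterns;
#'   \item all patterns share one inter-droplet interval (all glands share
#'     one per-gland sweat rate) and each spans the whole active period
#'     (\code{(nd-1)*dt <= tAP - tcycle} and \code{nd*dt >= tAP + tcycle - dt});
#'   \item \code{nd} in \code{[nd_min, nd_max]} (default 2--120);
#'   \item \code{dt_droplet} drawn from the segment's candidate intervals
#'     ([candidate_intervals()]), hence within \code{[tcycle, tAP/2]};
#'   \item every anchor offset from the first pattern realizable as a
#'     difference of two travel times of the layout.
#' }
#' All distinct decompositions are enumerated (the search is exhaustive and
#' deduplicated); an empty result is the failure signal.
#'
#' @param quantized One quantization from [quantize_segment()].
#' @param segment The segment the quantization belongs to.
#' @param layout A [device_layout()].
#' @param gland A [gland_params()] supplying \code{tAP}.
#' @param srg_max Upper bound of the per-gland sweat rate (nL/tAP); sets
#'   the smallest admissible inter-droplet interval \code{Vmin*tAP/srg_max}.
#' @param nsg_max,nd_min,nd_max Search bounds (defaults 27, 2, 120);
#'   \code{nsg_max} exceeds the simulated 1--11 gland range so that
#'   doubled-gland explanations of high-rate signals are enumerated.
#' @return A list of decompositions, each a data frame with columns
#'   \code{dt_travel_s} (anchor offset from the segment's first droplet),
#'   \code{dt_droplet_s} and \code{nd}; each carries the segment's
#'   \code{vsg_hat} as an attribute. \code{n_glands} of a decomposition is
#'   its number of rows.
#' @examples
#' seg <- data.frame(tick = c(0L, 30L), time_s = c(0, 15), volume_nL = c(0.2, 0.2))
#' q <- quantize_segment(seg, Vmin = 0.2, tcycle = 0.5)[[1]]
#' decompose_segment(q, seg, device_layout("D", tcycle = 0.5))
#' @export
decompose_segment <- function(quantized, segment, layout,
                              gland = gland_params(), srg_max = 1,
                              nsg_max = 27L, nd_min = 2L, nd_max = 120L) {
  stopifnot(inherits(layout, "device_layout"))
  tc <- layout$tcycle
  ticks <- as.integer(segment$tick - segment$tick[1L])
  cand_s <- candidate_intervals(segment, tAP = gland$tAP, tcycle = tc)
  cand_s <- cand_s[cand_s >= layout$Vmin * gland$tAP / srg_max - 1e-9]
  if (length(cand_s) == 0L || length(ticks) < 2L) return(list())
  cand_ticks <- as.integer(round(cand_s / tc))
  cand_ticks <- cand_ticks[spacing_consistent(cand_ticks, quantized$vsg_hat,
                                              layout$Vmin)]
  if (length(cand_ticks) == 0L) return(list())
  dmax <- as.integer(max(layout$distinct_dtravel) - min(layout$distinct_dtravel))
  sols <- decompose_ticks(ticks, as.integer(quantized$mult), cand_ticks,
                          as.integer(nsg_max), as.integer(nd_min),
                          as.integer(nd_max), dmax,
                          as.integer(round(gland$tAP / tc)))
  lapply(sols, function(m) {
    structure(data.frame(dt_travel_s = m[, "anchor"] * tc,
                         dt_droplet_s = m[, "spacing"] * tc,
                         nd = m[, "count"]),
              vsg_hat = quantized$vsg_hat)
  })
}

# volume/spacing consistency: a gland dripping every s activations at
# per-activation rate delta releases droplets of volume s*delta with
# ceil(Vmin/delta) = s, i.e. volume in [Vmin, Vmin*s/(s-1)); an observed
# non-merged droplet volume v therefore admits spacing s only when
# v < Vmin*s/(s-1) (any s when v is at the Vmin boundary)
spacing_consistent <- function(s_ticks, vsg_hat, Vmin) {
  excess <- vsg_hat - Vmin
  if (excess <= 1e-12) return(rep(TRUE, length(s_ticks)))
  s_ticks < vsg_hat / excess - 1e-9
}

## --- component machinery -----------------------------------------------
##
## A pattern can only step between pulses that are both present at one of
## the candidate spacings, so the pulse train splits into connected
## components that decompose independently; the set of full decompositions
## is the Cartesian product of the per-component sets. Working per component
## avoids enumerating that product explicitly: the gland-count candidate set
## is combined by dynamic programming over the per-component counts, and
## ambiguity classification uses the (much smaller) product of distinct
## per-component signatures.

# split pulse indices into connected components under candidate spacings
split_pulse_components <- function(ticks, cand_ticks) {
  n <- length(ticks)
  if (n == 0L) return(list())
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  pos <- integer(max(ticks) + 1L); pos[ticks + 1L] <- seq_len(n)
  for (i in seq_len(n)) for (s in cand_ticks) {
    t2 <- ticks[i] + s
    if (t2 <= max(ticks) && pos[t2 + 1L] > 0L) {
      a <- find(i); b <- find(pos[t2 + 1L])
      if (a != b) comp[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(split(seq_len(n), roots))
}

# longest evenly spaced run present in a tick subset (for capacity bounds)
longest_run <- function(ticks, cand_ticks, nd_max, span_ticks) {
  lmax <- 1L
  present <- rep(FALSE, max(ticks) + 1L); present[ticks + 1L] <- TRUE
  for (t in ticks) for (s in cand_ticks) {
    n_cap <- min(nd_max, (span_ticks - 1L) %/% s + 1L)
    L <- 1L; t2 <- t + s
    while (L < n_cap && t2 <= max(ticks) && present[t2 + 1L]) {
      L <- L + 1L; t2 <- t2 + s
    }
    if (L > lmax) lmax <- L
  }
  lmax
}

# decompose a segment component-wise; returns NULL on failure, else a list
# with nsg_set, n_decomp, witness (one full decomposition), and per-
# component signature lists for ambiguity classification
decompose_componentwise <- function(ticks, mult, cand_ticks, dmax, tc,
                                    vsg_hat, span_ticks, nsg_max = 27L,
                                    nd_min = 2L, nd_max = 120L) {
  comps <- split_pulse_components(ticks, cand_ticks)
  lb <- vapply(comps, function(idx)
    max(1L, as.integer(ceiling(sum(mult[idx]) /
      longest_run(ticks[idx], cand_ticks, nd_max, span_ticks)))), 0L)
  if (sum(lb) > nsg_max) return(NULL)
  sols <- vector("list", length(comps))
  counts <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    idx <- comps[[ci]]
    budget <- nsg_max - sum(lb[-ci])
    s <- decompose_count_set(ticks[idx], mult[idx], cand_ticks,
                             as.integer(budget), as.integer(nd_min),
                             as.integer(nd_max), as.integer(dmax),
                             as.integer(span_ticks))
    if (!isTRUE(attr(s, "complete"))) return("incomplete")
    if (length(attr(s, "k_set")) == 0L) return(NULL)
    sols[[ci]] <- s
    counts[[ci]] <- sort(attr(s, "k_set"))
  }
  nsg_set <- 0L
  for (k in counts) {
    nsg_set <- sort(unique(as.integer(outer(nsg_set, k, "+"))))
    nsg_set <- nsg_set[nsg_set <= nsg_max]
    if (length(nsg_set) == 0L) return(NULL)
  }
  witness <- NULL
  if (all(vapply(sols, length, 0L) > 0L)) {
    witness <- do.call(rbind, lapply(sols, function(s) {
      i <- which.min(vapply(s, nrow, 0L))
      m <- s[[i]]
      data.frame(dt_travel_s = m[, "anchor"] * tc,
                 dt_droplet_s = m[, "spacing"] * tc, nd = m[, "count"])
    }))
    attr(witness, "vsg_hat") <- vsg_hat
  }
  sigs <- lapply(sols, function(s) {
    u <- lapply(s, function(m) {
      list(n = nrow(m),
           sp = sort(unique(m[, "spacing"])),
           alloc = sort(paste(m[, "spacing"], m[, "count"])))
    })
    keys <- vapply(u, function(x)
      paste(x$n, paste(x$sp, collapse = ","),
            paste(x$alloc, collapse = ";")), "")
    u <- u[!duplicated(keys)]
    if (length(u) > 200L) u <- u[seq_len(200L)] # signature diversity cap
    u
  })
  list(nsg_set = nsg_set,
       n_decomp = prod(vapply(sols, length, 0L)),
       witness = witness, comp_sigs = sigs, comp_sols = sols)
}

# distinct global signatures (capped product over component signatures)
combine_signatures <- function(comp_sigs, nsg_max, cap = 20000L) {
  combos <- list(list(n = 0L, sp = integer(0), alloc = character(0)))
  for (sigs in comp_sigs) {
    out <- list()
    for (a in combos) {
      if (length(out) >= cap) break
      for (b in sigs) {
        n <- a$n + b$n
        if (n > nsg_max) next
        out[[length(out) + 1L]] <- list(n = n, sp = sort(unique(c(a$sp, b$sp))),
                                        alloc = sort(c(a$alloc, b$alloc)))
        if (length(out) >= cap) break
      }
    }
    keys <- vapply(out, function(x)
      paste(x$n, paste(x$sp, collapse = ","), paste(x$alloc, collapse = ";")),
      "")
    combos <- out[!duplicated(keys)]
    if (length(combos) == 0L) break
  }
  combos
}

# ambiguity types 2/3 from a set of global decomposition signatures
types_from_signatures <- function(sigs, max_sigs = 300L) {
  types <- integer(0)
  if (length(sigs) < 2L) return(types)
  keys <- vapply(sigs, function(x)
    paste(x$n, paste(x$sp, collapse = ","), paste(x$alloc, collapse = ";")),
    "")
  sigs <- sigs[!duplicated(keys)]
  if (length(sigs) > max_sigs) sigs <- sigs[seq_len(max_sigs)]
  if (length(sigs) < 2L) return(types)
  for (i in seq_len(length(sigs) - 1L)) {
    for (j in seq(i + 1L, length(sigs))) {
      shared <- length(intersect(sigs[[i]]$sp, sigs[[j]]$sp)) > 0L
      same_sets <- identical(sigs[[i]]$sp, sigs[[j]]$sp)
      same_alloc <- identical(sigs[[i]]$alloc, sigs[[j]]$alloc)
      if (shared && !same_alloc) types <- union(types, 2L)
      if (!same_sets) types <- union(types, 3L)
      if (length(types) == 2L) return(sort(types))
    }
  }
  sort(types)
}

#' Re-synthesize the integer pulse train implied by a decomposition
#'
#' Utility used for soundness checks and fitted values: superposes the
#' decomposition's patterns back into per-tick integer multiplicities.
#'
#' @param decomposition One decomposition from [decompose_segment()].
#' @param tcycle Tile activation interval (s).
#' @return A data frame with columns \code{tick} and \code{mult}.
#' @export
resynthesize_decomposition <- function(decomposition, tcycle) {
  ticks <- integer(0)
  for (i in seq_len(nrow(decomposition))) {
    a <- as.integer(round(decomposition$dt_travel_s[i] / tcycle))
    s <- as.integer(round(decomposition$dt_droplet_s[i] / tcycle))
    ticks <- c(ticks, a + s * (seq_len(decomposition$nd[i]) - 1L))
  }
  tab <- table(ticks)
  data.frame(tick = as.integer(names(tab)), mult = as.integer(tab))
}
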