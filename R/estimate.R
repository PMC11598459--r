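#' Estimate the gland count for one segment
#'
#' Runs quantization and exhaustive decomposition on one segment, unions the
#' decompositions over all admissible quantizations, deduplicates the
#' estimated gland counts and classifies ambiguities.
#'
#' @param segment One segment from [segment_signal()].
#' @param layout A [device_layout()].
#' @param gland A [gland_params()].
#' @param srg_max Upper bound of the per-gland sweat rate assumed by the
#'   estimator (nL/tAP): it sets the quantizer's volume range and the
#'   smallest admissible inter-droplet interval \code{Vmin*tAP/srg_max}.
#' @param nsg_max,nd_min,nd_max Decomposition search bounds. \code{nsg_max}
#'   caps the number of patterns enumerated; it deliberately exceeds the
#'   simulated 1--11 gland range because a signal from n glands at four or
#'   more droplets per active period is equally explained by 2n glands at
#'   half the rate, and those explanations are genuine candidates.
#' @param anchor_mode How pattern anchors (relative travel-time offsets) are
#'   constrained: \code{"window"} (default) admits any anchor inside the
#'   segment window; \code{"range"} additionally requires the offset from
#'   the first pattern to be a realizable travel-time difference of the
#'   layout. The window reading reproduces the reported high-rate error
#'   floors; see the methods vignette.
#' @return A list of class \code{"segment_result"}: \code{nsg_candidates}
#'   (sorted distinct gland-count estimates), \code{status} (\code{"unique"},
#'   \code{"ambiguous"} or \code{"failure"}), \code{failure_step}
#'   (\code{NA}, \code{"segmentation"}, \code{"quantization"},
#'   \code{"decomposition"} or \code{"budget"} for a search that hit its
#'   resource bounds), \code{ambiguity_types} (subset of 1:3),
#'   \code{quantizations} and \code{decompositions}.
#' @examples
#' sig <- simulate_signal(device_layout("D"), 1, gland_params(0.4), seed = 2)
#' seg <- segment_signal(sig)[[1]]
#' estimate_segment(seg, attr(sig, "layout"))$nsg_candidates # 1
#' @export
estimate_segment <- function(segment, layout, gland = gland_params(),
                             srg_max = 1, nsg_max = 27L, nd_min = 2L,
                             nd_max = 120L,
                             anchor_mode = c("window", "range")) {
  quants <- quantize_segment(segment, Vmin = layout$Vmin,
                             tcycle = layout$tcycle, srg_max = srg_max,
                             tAP = gland$tAP)
  if (length(quants) == 0L)
    return(segment_result(integer(0), "failure", "quantization",
                          list(), list()))
  tc <- layout$tcycle
  ticks <- as.integer(segment$tick - segment$tick[1L])
  cand_s <- candidate_intervals(segment, tAP = gland$tAP, tcycle = tc)
  # an interval below Vmin*tAP/SRg_max would need a per-gland rate above
  # the physiological maximum assumed by the quantizer
  cand_s <- cand_s[cand_s >= layout$Vmin * gland$tAP / srg_max - 1e-9]
  cand_ticks <- as.integer(round(cand_s / tc))
  anchor_mode <- match.arg(anchor_mode)
  dmax <- if (anchor_mode == "range")
    as.integer(max(layout$distinct_dtravel) - min(layout$distinct_dtravel))
  else as.integer(max(ticks))
  nsg <- integer(0); witnesses <- list(); sigs <- list()
  n_decomp <- 0; budget_hit <- FALSE
  # all glands secrete at one common rate, so a decomposition uses a single
  # inter-droplet interval throughout: each candidate spacing is tried on
  # its own across all components of the pulse train
  for (q in quants) {
    if (length(ticks) < 2L || length(cand_ticks) == 0L) next
    # a gland dripping every s activations releases droplets of volume
    # s*delta in [Vmin, Vmin*s/(s-1)), so the recovered droplet volume
    # bounds the admissible spacings
    cand_q <- cand_ticks[spacing_consistent(cand_ticks, q$vsg_hat,
                                            layout$Vmin)]
    for (s in cand_q) {
      cw <- decompose_componentwise(ticks, as.integer(q$mult), s, dmax,
                                    tc, q$vsg_hat,
                                    span_ticks = as.integer(round(gland$tAP / tc)),
                                    nsg_max = nsg_max, nd_min = nd_min,
                                    nd_max = nd_max)
      if (identical(cw, "incomplete")) { budget_hit <- TRUE; next }
      if (is.null(cw)) next
      nsg <- union(nsg, cw$nsg_set)
      if (!is.null(cw$witness))
        witnesses[[length(witnesses) + 1L]] <- cw$witness
      sigs <- c(sigs, combine_signatures(cw$comp_sigs, nsg_max))
      n_decomp <- n_decomp + cw$n_decomp
    }
  }
  if (length(nsg) == 0L)
    return(segment_result(integer(0), "failure",
                          if (budget_hit) "budget" else "decomposition",
                          quants, list()))
  nsg <- sort(nsg)
  status <- if (length(nsg) > 1L) "ambiguous" else "unique"
  res <- segment_result(nsg, status, NA_character_, quants, witnesses)
  res$n_decompositions <- n_decomp
  res$ambiguity_types <- sort(union(if (length(quants) > 1L) 1L else integer(0),
                                    types_from_signatures(sigs)))
  res
}

segment_result <- function(nsg, status, failure_step, quants, decomps) {
  structure(list(nsg_candidates = nsg, status = status,
                 failure_step = failure_step, ambiguity_types = integer(0),
                 quantizations = quants, decompositions = decomps),
            class = "segment_result")
}

#' @export
print.segment_result <- function(x, ...) {
  cat("Segment result:", x$status)
  if (x$status == "failure") {
    cat(" (", x$failure_step, " step)\n", sep = "")
  } else {
    cat("; NSG candidates:", paste(x$nsg_candidates, collapse = ", "))
    if (length(x$ambiguity_types))
      cat("; ambiguity type(s):", paste(x$ambiguity_types, collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' Classify the ambiguity types of a segment result
#'
#' Type 1 (ambiguous quantization): more than one admissible non-merged
#' droplet volume. Type 2 (ambiguous droplet count): two decompositions share
#' an inter-droplet interval but allocate droplets to glands differently.
#' Type 3 (ambiguous interval): two decompositions use different
#' inter-droplet interval sets. A segment can carry several types.
#'
#' @param result A \code{"segment_result"}.
#' @return Integer vector, a subset of \code{c(1L, 2L, 3L)}.
#' @export
classify_ambiguity <- function(result) {
  types <- integer(0)
  if (length(result$quantizations) > 1L) types <- 1L
  ds <- result$decompositions
  if (length(ds) > 1L) {
    specs <- lapply(ds, function(d)
      list(sp = sort(unique(d$dt_droplet_s)),
           nd = sort(paste(d$dt_droplet_s, d$nd))))
    for (i in seq_along(ds)[-length(ds)]) {
      for (j in seq((i + 1L), length(ds))) {
        shared <- length(intersect(specs[[i]]$sp, specs[[j]]$sp)) > 0L
        same_sets <- identical(specs[[i]]$sp, specs[[j]]$sp)
        same_alloc <- identical(specs[[i]]$nd, specs[[j]]$nd)
        if (shared && !same_alloc) types <- union(types, 2L)
        if (!same_sets) types <- union(types, 3L)
      }
    }
  }
  sort(types)
}

#' Estimate the number of active sweat glands from a sensed signal
#'
#' The package's fitting function: segments the pulse train, quantizes each
#' window to integer droplet multiplicities, exhaustively decomposes each
#' window into per-gland patterns, and collects the per-segment gland-count
#' candidate lists. The estimator never consults the ground truth attached to
#' simulated signals.
#'
#' @param signal A \code{"sweat_signal"} (simulated or read from file).
#' @param layout A [device_layout()]; defaults to the signal's layout.
#' @param gland A [gland_params()] supplying the activity timing assumed by
#'   the estimator (the per-gland rate itself is unknown to it).
#' @param srg_max Upper bound of the per-gland sweat rate (nL/tAP) for the
#'   quantizer's volume range.
#' @param nsg_max,nd_min,nd_max Decomposition search bounds.
#' @return An object of class \code{"sg_fit"}: list with \code{segments},
#'   \code{results} (one \code{"segment_result"} per segment),
#'   \code{layout}, \code{signal}, and \code{call}. Methods:
#'   \code{print}, \code{summary}, \code{coef} (per-segment candidate
#'   table), \code{fitted} (re-synthesized pulse train of each segment's
#'   first solution), \code{residuals}, \code{plot}.
#' @examples
#' sig <- simulate_signal(device_layout("D"), 2, gland_params(0.4), seed = 5)
#' fit <- estimate_nsg(sig)
#' summary(fit)
#' @export
estimate_nsg <- function(signal, layout = attr(signal, "layout"),
                         gland = gland_params(), srg_max = 1, nsg_max = 27L,
                         nd_min = 2L, nd_max = 120L,
                         anchor_mode = c("window", "range")) {
  anchor_mode <- match.arg(anchor_mode)
  stopifnot(inherits(layout, "device_layout"))
  segs <- withCallingHandlers(
    segment_signal(signal, layout, gland),
    warning = function(w) invokeRestart("muffleWarning"))
  if (identical(attr(segs, "failure"), "segmentation")) {
    n_expected <- n_expected_segments(signal, gland)
    results <- rep(list(segment_result(integer(0), "failure", "segmentation",
                                       list(), list())), n_expected)
    segs <- list()
  } else {
    results <- lapply(segs, estimate_segment, layout = layout, gland = gland,
                      srg_max = srg_max, nsg_max = nsg_max, nd_min = nd_min,
                      nd_max = nd_max, anchor_mode = anchor_mode)
  }
  structure(list(segments = segs, results = results, layout = layout,
                 gland = gland, signal = signal, call = match.call()),
            class = "sg_fit")
}

n_expected_segments <- function(signal, gland) {
  tr <- attr(signal, "truth")
  if (!is.null(tr)) return(tr$n_cycles)
  if (nrow(signal) == 0L) return(0L)
  max(1L, as.integer(floor(max(signal$time_s) / (gland$tAP + gland$tRP))) + 1L)
}

#' @export
print.sg_fit <- function(x, ...) {
  cat("Active sweat-gland estimation (layout ", x$layout$name, ", tcycle ",
      x$layout$tcycle, " s)\n", sep = "")
  cat(sprintf("  %d segment(s): %d unique, %d ambiguous, %d failure\n",
              length(x$results),
              sum(vapply(x$results, function(r) r$status == "unique", NA)),
              sum(vapply(x$results, function(r) r$status == "ambiguous", NA)),
              sum(vapply(x$results, function(r) r$status == "failure", NA))))
  for (i in seq_along(x$results)) {
    r <- x$results[[i]]
    cat(sprintf("  segment %d: %s", i, r$status))
    if (r$status != "failure")
      cat("; NSG in {", paste(r$nsg_candidates, collapse = ", "), "}", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.sg_fit <- function(object, ...) {
  df <- coef(object)
  cat("Estimated number of active sweat glands per segment\n")
  print(df, row.names = FALSE)
  modal <- table(unlist(lapply(object$results, `[[`, "nsg_candidates")))
  if (length(modal)) {
    best <- as.integer(names(modal)[which.max(modal)])
    cat(sprintf("Most frequent candidate across segments: %d gland(s)\n", best))
  }
  invisible(df)
}

#' @export
coef.sg_fit <- function(object, ...) {
  data.frame(
    segment = seq_along(object$results),
    status = vapply(object$results, `[[`, "", "status"),
    nsg_candidates = vapply(object$results, function(r)
      paste(r$nsg_candidates, collapse = ","), ""),
    ambiguity_types = vapply(object$results, function(r)
      paste(r$ambiguity_types, collapse = ","), ""))
}

#' @export
fitted.sg_fit <- function(object, ...) {
  tc <- object$layout$tcycle
  lapply(seq_along(object$results), function(i) {
    r <- object$results[[i]]
    if (length(r$decompositions) == 0L) return(NULL)
    d <- r$decompositions[[1L]]
    re <- resynthesize_decomposition(d, tc)
    seg <- object$segments[[i]]
    re$tick <- re$tick + seg$tick[1L]
    re$time_s <- re$tick * tc
    re$volume_nL <- re$mult * attr(d, "vsg_hat")
    re
  })
}

#' @export
residuals.sg_fit <- function(object, ...) {
  ft <- fitted(object)
  lapply(seq_along(object$results), function(i) {
    seg <- object$segments[[i]]
    if (is.null(ft[[i]])) return(rep(NA_real_, nrow(seg)))
    seg$volume_nL - ft[[i]]$volume_nL[match(seg$tick, ft[[i]]$tick)]
  })
}

#' @export
plot.sg_fit <- function(x, ...) {
  sig <- x$signal
  graphics::plot(sig$time_s, sig$volume_nL, type = "h", lwd = 2,
                 xlab = "time (s)", ylab = "sensed droplet volume (nL)",
                 main = "Segmented pulse train", ...)
  for (seg in x$segments)
    graphics::abline(v = attr(seg, "start_s"), lty = 3, col = "grey40")
  invisible(x)
}
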