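# Breadth-threshold detection model. A genome truly present at mean depth
# d is expected to show a coverage breadth following an exponential
# saturation curve a * b^d + c (a < 0, 0 < b < 1, 0 < c <= 100); the
# asymptote c reflects the core-genome fraction shared across strains of a
# species. A species is called detected when breadth exceeds a fixed
# cutoff (default 50%), or -- at lower breadth -- when breadth is at least
# a floor and exceeds the depth-dependent threshold curve.

#' Construct a breadth-threshold model
#'
#' `threshold(d) = a * b^d + c`: strictly increasing in depth, with
#' asymptote `c` as `d -> Inf`.
#'
#' @param a Amplitude (negative).
#' @param b Decay base in (0, 1).
#' @param c Asymptote in (0, 100\].
#' @param source `"fitted"` or `"reference"`.
#' @param rmse Residual RMSE of the fit, if any.
#' @param genome_id Optional id of the calibration genome.
#' @return An object of class `threshold_model`.
#' @export
threshold_model <- function(a, b, c, source = "fitted", rmse = NA_real_,
                            genome_id = NA_character_) {
  .check_number(a, "a", upper = 0, upper_open = TRUE)
  .check_number(b, "b", lower = 0, upper = 1, lower_open = TRUE,
                upper_open = TRUE)
  .check_number(c, "c", lower = 0, upper = 100, lower_open = TRUE)
  source <- match.arg(source, c("fitted", "reference"))
  structure(list(a = a, b = b, c = c, source = source, rmse = rmse,
                 genome_id = genome_id),
            class = "threshold_model")
}

#' The package's reference breadth-threshold calibration
#'
#' Detection-threshold curve `-255.58 * 0.358^depth + 75.27`, a published
#' calibration obtained by stepwise read subsampling of deep freshwater
#' metagenome mappings onto conspecific bacterial genomes differing in
#' accessory gene content; its asymptote (75.27% breadth) reflects the
#' core-genome fraction of such a species.
#'
#' @return A `threshold_model` with `source = "reference"`.
#' @examples
#' breadth_threshold(default_threshold_model(), c(0, 5, 50))
#' @export
default_threshold_model <- function() {
  threshold_model(a = -255.58, b = 0.358, c = 75.27, source = "reference")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> breadth(d) = %.6g * %.6g^d + %.6g  [%s%s]\n",
              x$a, x$b, x$c, x$source,
              if (is.finite(x$rmse)) sprintf(", rmse %.3g", x$rmse) else ""))
  invisible(x)
}

#' Evaluate the breadth-threshold curve
#'
#' @param model A [threshold_model].
#' @param mean_depth Non-negative mean coverage depth (vectorized). Values
#'   at low depth may be negative (any breadth passes the curve there).
#' @return Threshold breadth in percent.
#' @export
breadth_threshold <- function(model, mean_depth) {
  stopifnot(inherits(model, "threshold_model"))
  if (any(is.na(mean_depth)) || any(mean_depth < 0))
    .stopf("`mean_depth` must be non-negative")
  model$a * model$b^mean_depth + model$c
}

#' Saturation series by stepwise read subsampling
#'
#' Re-creates the calibration input: mapped reads are subsampled without
#' replacement at each fraction and coverage depth/breadth recorded.
#' Subsamples are nested (the reads at a smaller fraction are a subset of
#' those at any larger fraction) so each series is monotone by
#' construction; independent re-draws are available via `nested = FALSE`.
#'
#' @param alignments An `alignment_set` of mapped reads.
#' @param ref The matching [build_reference()] result.
#' @param fractions Strictly increasing subsample fractions in (0, 1\].
#' @param total_reads Total input reads of the metagenome (scaled per
#'   fraction for the mapped-read percentage).
#' @param seed Optional integer seed.
#' @param nested Nested subsampling (default) or independent draws.
#' @return Named list of `saturation_series` objects, one per genome with
#'   mapped reads: fields `genome_id` and `points` (data frame `fraction`,
#'   `mean_depth`, `breadth_pct`).
#' @export
subsample_series <- function(alignments, ref,
                             fractions = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 1),
                             total_reads = NROW(alignments), seed = NULL,
                             nested = TRUE) {
  if (!NROW(alignments)) .stopf("`alignments` is empty")
  if (!length(fractions)) .stopf("`fractions` must be non-empty")
  if (any(fractions <= 0 | fractions > 1) || is.unsorted(fractions, strictly = TRUE))
    .stopf("`fractions` must be strictly increasing within (0, 1]")
  n <- nrow(alignments)
  with_seed(seed, {
    perm <- sample.int(n)
    per_fraction <- lapply(fractions, function(f) {
      idx <- if (nested) perm[seq_len(max(1L, round(f * n)))]
      else sample.int(n, max(1L, round(f * n)))
      compute_coverage(alignments[idx, , drop = FALSE], ref,
                       total_reads = max(length(idx), round(f * total_reads)))
    })
    out <- list()
    for (gid in names(ref$genomes)) {
      pts <- data.frame(
        fraction = fractions,
        mean_depth = vapply(per_fraction, function(p) p[[gid]]$mean_depth,
                            numeric(1)),
        breadth_pct = vapply(per_fraction, function(p) p[[gid]]$breadth_pct,
                             numeric(1)))
      if (all(pts$mean_depth == 0)) next  # genome absent from the mapping
      out[[gid]] <- structure(list(genome_id = gid, points = pts),
                              class = "saturation_series")
    }
    out
  })
}

#' Fit the exponential saturation curve to a series
#'
#' Bounded nonlinear least squares of `breadth = a * b^depth + c` with
#' `a < 0`, `0 < b < 1`, `0 < c <= 100`, multi-start initialization
#' (`c0` in {max breadth, 75, 95}; `b0` in {0.2, 0.358, 0.6};
#' `a0 = min breadth - c0`), Levenberg-Marquardt convergence tolerance
#' 1e-10 and at most 5000 evaluations per start.
#'
#' @param series A `saturation_series` (or a data frame with columns
#'   `mean_depth` and `breadth_pct`) of at least 5 points spanning at
#'   least a 2-fold depth range.
#' @return A fitted [threshold_model] carrying the residual RMSE.
#' @export
fit_saturation <- function(series) {
  gid <- NA_character_
  if (inherits(series, "saturation_series")) {
    gid <- series$genome_id
    pts <- series$points
  } else pts <- as.data.frame(series)
  if (!all(c("mean_depth", "breadth_pct") %in% names(pts)))
    .stopf("series needs columns mean_depth and breadth_pct")
  pts <- pts[is.finite(pts$mean_depth) & is.finite(pts$breadth_pct), ,
             drop = FALSE]
  if (nrow(pts) < 5L) .stopf("need at least 5 saturation points")
  dpos <- pts$mean_depth[pts$mean_depth > 0]
  if (!length(dpos) || max(dpos) / min(dpos) < 2)
    .stopf("saturation points must span at least a 2-fold depth range")
  if (sd(pts$breadth_pct) < 1e-8)
    .stopf("degenerate saturation series: breadth is constant at %.3f",
           pts$breadth_pct[1])

  dat <- data.frame(d = pts$mean_depth, y = pts$breadth_pct)
  starts <- expand.grid(c0 = unique(c(max(dat$y), 75, 95)),
                        b0 = c(0.2, 0.358, 0.6))
  best <- NULL
  best_rss <- Inf
  diagnostics <- character()
  for (i in seq_len(nrow(starts))) {
    c0 <- min(max(starts$c0[i], 1e-3), 100)
    a0 <- min(min(dat$y) - c0, -1e-3)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * b^d + c, data = dat,
        start = list(a = a0, b = starts$b0[i], c = c0),
        lower = c(a = -1e6, b = 1e-8, c = 1e-8),
        upper = c(a = -1e-9, b = 1 - 1e-9, c = 100),
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                             maxiter = 1000, maxfev = 5000)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(resid(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best))
    .stopf("saturation fit did not converge from any start: %s",
           paste(unique(diagnostics), collapse = "; "))
  p <- coef(best)
  threshold_model(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                  source = "fitted",
                  rmse = sqrt(mean(resid(best)^2)), genome_id = gid)
}

#' Select the smallest-asymptote model
#'
#' Among per-genome calibration fits, the model with the smallest
#' asymptote `c` reflects the core-genome fraction and yields the most
#' conservative detection threshold. Ties break by lexicographic
#' `genome_id`.
#'
#' @param models Non-empty list of [threshold_model] objects.
#' @return The selected model.
#' @export
select_min_asymptote <- function(models) {
  if (inherits(models, "threshold_model")) models <- list(models)
  if (!length(models)) .stopf("`models` must be non-empty")
  stopifnot(all(vapply(models, inherits, logical(1), "threshold_model")))
  cs <- vapply(models, function(m) m$c, numeric(1))
  ids <- vapply(models, function(m)
    if (is.na(m$genome_id)) "" else m$genome_id, character(1))
  models[[order(cs, ids)[1L]]]
}

#' Call species detection from a coverage profile
#'
#' Detected if breadth exceeds `breadth_cutoff_pct`, or else if breadth is
#' at least `floor_pct` and exceeds the depth-dependent threshold curve.
#' The breadth floor implements the low-coverage guard of the decision
#' rule; `min_depth` switches in the alternative reading of that guard as
#' a minimum mean depth. The comparison against the cutoff is strict
#' ("more than").
#'
#' @param profile A `coverage_profile` (any list with `breadth_pct` and
#'   `mean_depth` works).
#' @param model A [threshold_model].
#' @param breadth_cutoff_pct Breadth above which detection is immediate
#'   (default 50).
#' @param floor_pct Minimum breadth for the curve comparison (default 10).
#' @param min_depth Optional minimum mean depth for the curve comparison.
#' @return An object of class `detection_call`: `genome_id`,
#'   `breadth_pct`, `mean_depth`, `threshold_pct`, `floor_pct`, `detected`
#'   and the `rule` that decided (`breadth_above_cutoff`, `curve_pass`,
#'   `curve_fail`, `floor_fail`, `depth_floor_fail`).
#' @export
classify_detection <- function(profile, model, breadth_cutoff_pct = 50,
                               floor_pct = 10, min_depth = NULL) {
  stopifnot(inherits(model, "threshold_model"))
  b <- profile$breadth_pct
  d <- profile$mean_depth
  thr <- breadth_threshold(model, d)
  if (b > breadth_cutoff_pct) {
    detected <- TRUE
    rule <- "breadth_above_cutoff"
  } else if (b < floor_pct) {
    detected <- FALSE
    rule <- "floor_fail"
  } else if (!is.null(min_depth) && d < min_depth) {
    detected <- FALSE
    rule <- "depth_floor_fail"
  } else if (b > thr) {
    detected <- TRUE
    rule <- "curve_pass"
  } else {
    detected <- FALSE
    rule <- "curve_fail"
  }
  structure(list(
    genome_id = profile$genome_id %||% NA_character_,
    breadth_pct = b, mean_depth = d, threshold_pct = thr,
    floor_pct = floor_pct, detected = detected, rule = rule),
    class = "detection_call")
}

#' @export
print.detection_call <- function(x, ...) {
  cat(sprintf("<detection_call> %s: %s (rule %s; breadth %.2f%%, depth %.3fx, threshold %.2f%%)\n",
              x$genome_id, if (x$detected) "DETECTED" else "not detected",
              x$rule, x$breadth_pct, x$mean_depth, x$threshold_pct))
  invisible(x)
}

#' Detection report over a reference set
#'
#' One row per genome of the reference: coverage summary, threshold and
#' verdict, in stable reference order; directly TSV-serializable.
#'
#' @param profiles List of `coverage_profile` objects
#'   (see [compute_coverage()]).
#' @param model A [threshold_model].
#' @param metagenome_id Identifier of the metagenome, repeated per row.
#' @param ... Passed to [classify_detection()].
#' @return Data frame with columns `metagenome_id`, `genome_id`,
#'   `unmasked_length`, `mapped_reads`, `mapped_read_pct`, `mean_depth`,
#'   `breadth_pct`, `threshold_pct`, `detected`, `rule`.
#' @export
detection_report <- function(profiles, model, metagenome_id = "metagenome",
                             ...) {
  rows <- lapply(profiles, function(p) {
    call <- classify_detection(p, model, ...)
    data.frame(metagenome_id = metagenome_id, genome_id = p$genome_id,
               unmasked_length = p$unmasked_length,
               mapped_reads = p$mapped_reads,
               mapped_read_pct = p$mapped_read_pct,
               mean_depth = p$mean_depth, breadth_pct = p$breadth_pct,
               threshold_pct = call$threshold_pct, detected = call$detected,
               rule = call$rule, stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
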