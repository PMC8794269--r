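# Junction-intensity and apical/basal polarity ratio quantifications.
#
# Both statistics are ratios of intensity averages measured along
# caller-annotated membrane segments, so they are invariant under global
# intensity rescaling; the polarity ratio-of-ratios is additionally
# invariant under independent rescaling of each channel.

#' Sample an image along a line segment
#'
#' Points are placed at fixed 1-px arc-length spacing (endpoints included)
#' and looked up with bilinear interpolation, making the measurement
#' deterministic and resolution independent.
#'
#' @param image numeric matrix.
#' @param x0,y0,x1,y1 segment endpoints (px).
#' @param spacing sample spacing along the segment (px).
#' @return numeric vector of sampled intensities.
#' @export
sample_segment <- function(image, x0, y0, x1, y1, spacing = 1) {
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len == 0) stop("degenerate segment (zero length)")
  n <- max(2L, floor(len / spacing) + 1L)
  t <- seq(0, 1, length.out = n)
  bilinear_sample(image, x0 + t * (x1 - x0), y0 + t * (y1 - y0))
}

#' Measure mean and maximum intensity along annotated interfaces
#'
#' @param image numeric matrix.
#' @param segments data.frame with columns `id`, `label`, `x0`, `y0`, `x1`,
#'   `y1` (px), one row per cell-cell interface.
#' @return data.frame `id, label, mean_intensity, max_intensity`.
#' @export
measure_interfaces <- function(image, segments) {
  out <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    v <- sample_segment(image, segments$x0[i], segments$y0[i],
                        segments$x1[i], segments$y1[i])
    data.frame(id = segments$id[i], label = segments$label[i],
               mean_intensity = mean(v), max_intensity = max(v))
  }))
  rownames(out) <- NULL
  out
}

#' Interface intensity ratio between two cell populations
#'
#' The across-interface average of the chosen per-interface statistic
#' (mean or maximum intensity) for the numerator population, divided by the
#' same average for the denominator population — e.g. junctional signal of
#' luminal cells over that of abluminal cells.
#'
#' @param measurements data.frame as from [measure_interfaces()].
#' @param numerator_label,denominator_label interface group labels.
#' @param statistic `"mean"` (default) or `"max"` per-interface statistic.
#' @return the ratio (scalar).
#' @export
interface_ratio <- function(measurements, numerator_label, denominator_label,
                            statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "mean") "mean_intensity" else "max_intensity"
  num <- measurements[measurements$label == numerator_label, col]
  den <- measurements[measurements$label == denominator_label, col]
  if (length(num) == 0 || length(den) == 0) {
    stop("both interface groups must be non-empty")
  }
  m <- mean(den)
  if (m == 0) stop("denominator interfaces have zero average intensity")
  mean(num) / m
}

#' Apical/basal polarity ratio-of-ratios
#'
#' For each z-slice, the mean green and red signal are measured along the
#' apical and the basal membrane segments.  The embryo-level statistic is
#'
#'   `(sum_s apical_green / sum_s apical_red) / (sum_s basal_green / sum_s basal_red)`
#'
#' where the sums run over slices; values above 1 indicate apical enrichment
#' of the green signal normalized by the membrane (red) channel.  Per-slice
#' channel means are returned as well so an averaging convention over slices
#' remains recoverable.
#'
#' @param slices a single `list(green =, red =)` pair of matrices, or a list
#'   of such pairs (one per z-slice, at most ~2 um apart in the original
#'   protocol).
#' @param apical_segments,basal_segments data.frames with columns
#'   `x0, y0, x1, y1` (px): shared across slices, or lists with one
#'   data.frame per slice.
#' @return object of class `polarity_measurement`: list with `ratio` and
#'   `per_slice` (data.frame `slice, apical_green, apical_red, basal_green,
#'   basal_red, slice_ratio`).
#' @export
polarity_ratio <- function(slices, apical_segments, basal_segments) {
  if (!is.null(slices$green)) slices <- list(slices)
  n_slices <- length(slices)
  seg_for <- function(segs, si) if (is.data.frame(segs)) segs else segs[[si]]
  side_mean <- function(image, segs) {
    vals <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      sample_segment(image, segs$x0[i], segs$y0[i], segs$x1[i], segs$y1[i])
    }))
    mean(vals)
  }
  per_slice <- do.call(rbind, lapply(seq_len(n_slices), function(si) {
    ch <- slices[[si]]
    if (is.null(ch$green) || is.null(ch$red)) {
      stop("each slice needs both a green and a red channel")
    }
    ap <- seg_for(apical_segments, si)
    ba <- seg_for(basal_segments, si)
    if (nrow(ap) == 0 || nrow(ba) == 0) stop("segments must be non-degenerate")
    data.frame(slice = si,
               apical_green = side_mean(ch$green, ap),
               apical_red = side_mean(ch$red, ap),
               basal_green = side_mean(ch$green, ba),
               basal_red = side_mean(ch$red, ba))
  }))
  if (sum(per_slice$apical_red) <= 0 || sum(per_slice$basal_red) <= 0) {
    stop("zero red (membrane) signal on one side; ratio undefined")
  }
  basal_ratio <- sum(per_slice$basal_green) / sum(per_slice$basal_red)
  if (basal_ratio <= 0) stop("basal green/red ratio must be positive")
  per_slice$slice_ratio <- (per_slice$apical_green / per_slice$apical_red) /
    (per_slice$basal_green / per_slice$basal_red)
  ratio <- (sum(per_slice$apical_green) / sum(per_slice$apical_red)) / basal_ratio
  structure(list(ratio = ratio, per_slice = per_slice),
            class = "polarity_measurement")
}

#' @export
print.polarity_measurement <- function(x, ...) {
  cat(sprintf("polarity ratio-of-ratios: %.4g (%d slice(s))\n",
              x$ratio, nrow(x$per_slice)))
  invisible(x)
}

#' One-sample rank test against a theoretical value
#'
#' Wilcoxon signed-rank test of per-embryo ratios against a theoretical
#' null value (typically 1), the statistically coherent one-sample analogue
#' of the two-sample rank-sum test.  The exact null distribution is used for
#' n <= 25 (when free of ties and zeros); larger samples use the normal
#' approximation.  Two-sided p-values are reported.
#'
#' @param values per-embryo ratios (n >= 5).
#' @param null_value theoretical value under the null (default 1).
#' @param log test `log(values) - log(null_value)` instead of
#'   `values - null_value`, appropriate when deviations are multiplicative.
#' @return list with `statistic` (V), `p_value`, `n`, `method`, and
#'   `degenerate` (`TRUE` with `p_value = 1` when every value equals the
#'   null exactly).
#' @export
one_sample_rank_test <- function(values, null_value = 1, log = FALSE) {
  n <- length(values)
  if (n < 5) stop("at least 5 values are required")
  x <- if (log) base::log(values) - base::log(null_value) else values - null_value
  if (all(x == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n = n,
                method = "degenerate (all values equal the null)",
                degenerate = TRUE))
  }
  exact <- n <= 25 && !any(duplicated(abs(x[x != 0]))) && !any(x == 0)
  ht <- suppressWarnings(stats::wilcox.test(x, mu = 0, exact = exact,
                                            correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       method = if (exact) "exact signed-rank" else "normal approximation",
       degenerate = FALSE)
}
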