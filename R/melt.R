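#' @title Thermal-shift melting-curve analysis
#' @name melt
#' @description
#' Analysis of dye-based thermal denaturation (thermal shift / differential
#' scanning fluorimetry) curves: min-max normalization, melting-point
#' detection as the most prominent local extremum of the smoothed first
#' derivative within the analysis segment, relative-binding normalization
#' of ligand panels against a positive reference (100%) and a no-ligand
#' control (0%), and one-sided Welch significance testing of replicate
#' melting points. A seeded two-state curve simulator provides ground-truth
#' data.
NULL

#' Construct a melting curve
#'
#' @param temperatures Strictly increasing temperature series (deg C).
#' @param fluorescence Same-length fluorescence series (RFU).
#' @param well Optional well label.
#' @return data.frame with columns `temperature`, `fluorescence`; class
#'   `"melting_curve"`, attribute `"well"`.
#' @export
melting_curve <- function(temperatures, fluorescence, well = NA_character_) {
  stopifnot(is.numeric(temperatures), is.numeric(fluorescence))
  if (length(temperatures) != length(fluorescence))
    stop("temperature and fluorescence series must have equal length")
  if (length(temperatures) < 20)
    stop("melting curve needs at least 20 points")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  structure(data.frame(temperature = temperatures,
                       fluorescence = fluorescence),
            class = c("melting_curve", "data.frame"), well = well)
}

#' Min-max normalize a melting curve
#'
#' Scales fluorescence to [0, 1] (min 0, max 1); temperatures are
#' untouched. Idempotent and invariant under positive affine transforms of
#' the input fluorescence.
#'
#' @param curve A `"melting_curve"`.
#' @return Normalized `"melting_curve"`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  f <- curve$fluorescence
  rng <- range(f)
  if (diff(rng) == 0) stop("constant fluorescence: no signal to normalize")
  melting_curve(curve$temperature, (f - rng[1]) / diff(rng),
                attr(curve, "well"))
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  sm <- stats::filter(x, k, sides = 2)
  # shrink the window at the edges instead of dropping points
  n <- length(x)
  half <- (window - 1) %/% 2
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i] <- mean(x[lo:hi])
  }
  as.numeric(sm)
}

#' Detect the melting point of a curve
#'
#' Normalizes the curve, smooths the fluorescence with a centered moving
#' average, takes the numerical first derivative dF/dT, and reports the
#' melting point Tm as the temperature of the most prominent interior
#' local extremum of dF within the analysis segment. By convention the
#' readout analyzed here descends through the unfolding transition, so the
#' melting point appears as a local *minimum* of dF (the default); pass
#' `extremum = "max"` for ascending-readout instruments.
#'
#' Minima at the segment boundary are flagged (`boundary-minimum`) and not
#' reported as Tm; a segment with no interior extremum yields the
#' `no-minimum` flag and an absent Tm.
#'
#' @param curve A `"melting_curve"`.
#' @param segment Temperature window analyzed, default c(35, 90) deg C
#'   (the transition segment of the peptide-binding superdomain).
#' @param smooth_window Centered moving-average width in points (default
#'   5).
#' @param extremum `"min"` (default) or `"max"`.
#' @return Object of class `"melt_result"`: list with `tm` (NA if not
#'   detected), `derivative` (data.frame `temperature`, `dF`), `segment`,
#'   `flags` (character vector).
#' @export
melting_point <- function(curve, segment = c(35, 90), smooth_window = 5,
                          extremum = c("min", "max")) {
  extremum <- match.arg(extremum)
  curve <- normalize_curve(curve)
  if (segment[1] < min(curve$temperature) - 1e-8 ||
      segment[2] > max(curve$temperature) + 1e-8)
    stop("analysis segment outside the curve's temperature range")
  f <- moving_average(curve$fluorescence, smooth_window)
  tt <- curve$temperature
  d <- diff(f) / diff(tt)
  tm_mid <- (tt[-1] + tt[-length(tt)]) / 2
  inside <- tm_mid >= segment[1] & tm_mid <= segment[2]
  d_seg <- d[inside]; t_seg <- tm_mid[inside]
  flags <- character(0)
  tm <- NA_real_
  if (length(d_seg) >= 3 && diff(range(d_seg)) > 1e-9) {
    v <- if (extremum == "min") d_seg else -d_seg
    # interior local minima of v: no higher than both neighbours and
    # strictly lower than at least one (flat plateaus are not extrema)
    idx <- 2:(length(v) - 1)
    is_ext <- v[idx] <= v[idx - 1] & v[idx] <= v[idx + 1] &
      (v[idx] < v[idx - 1] | v[idx] < v[idx + 1])
    cand <- idx[is_ext]
    # prominence filter: keep only candidates within 10% of the segment's
    # deepest derivative value, so numerical ripple in flat regions never
    # outranks a transition pinned at the segment boundary
    cand <- cand[v[cand] <= min(v) + 0.1 * diff(range(v))]
    if (length(cand) == 0) {
      g <- which.min(v)
      flags <- if (diff(range(v)) > 1e-12 && (g == 1 || g == length(v)))
        "boundary-minimum" else "no-minimum"
    } else {
      best <- cand[which.min(v[cand])]  # most prominent extremum
      # parabolic vertex interpolation through the extremum and its
      # neighbours: recovers a symmetric transition midpoint exactly
      y0 <- v[best - 1]; y1 <- v[best]; y2 <- v[best + 1]
      denom <- y0 - 2 * y1 + y2
      offset <- if (abs(denom) > 1e-15) 0.5 * (y0 - y2) / denom else 0
      offset <- max(min(offset, 0.5), -0.5)
      step <- t_seg[best + 1] - t_seg[best]
      tm <- t_seg[best] + offset * step
    }
  } else flags <- "no-minimum"
  structure(list(tm = tm,
                 derivative = data.frame(temperature = tm_mid, dF = d),
                 segment = segment, extremum = extremum, flags = flags,
                 well = attr(curve, "well")),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  if (is.na(x$tm))
    cat("no melting point detected (", paste(x$flags, collapse = ", "),
        ")\n")
  else cat(sprintf("Tm = %.2f degC (segment %.0f-%.0f)\n", x$tm,
                   x$segment[1], x$segment[2]))
  invisible(x)
}

#' Relative binding from replicate melting points
#'
#' Maps ligand melting points linearly onto the control span: the mean
#' melting point of the no-ligand control defines 0% and the mean of the
#' positive reference defines 100%, i.e.
#' `rel = 100 * (Tm - mean(Tm_neg)) / (mean(Tm_pos) - mean(Tm_neg))`,
#' computed per replicate and summarized as mean and standard deviation.
#'
#' @param ligand_tms Replicate melting points of the ligand (deg C).
#' @param positive_tms Replicate melting points of the positive reference.
#' @param negative_tms Replicate melting points of the no-ligand control.
#' @return List with `per_replicate` (percent), `mean`, `sd`.
#' @export
relative_binding <- function(ligand_tms, positive_tms, negative_tms) {
  stopifnot(length(positive_tms) >= 1, length(negative_tms) >= 1,
            length(ligand_tms) >= 1)
  if (anyNA(c(ligand_tms, positive_tms, negative_tms)))
    stop("undetected melting points (NA) in the panel")
  span <- mean(positive_tms) - mean(negative_tms)
  if (span == 0) stop("identical control means: zero dynamic range")
  rel <- 100 * (ligand_tms - mean(negative_tms)) / span
  list(per_replicate = rel, mean = mean(rel),
       sd = if (length(rel) > 1) stats::sd(rel) else NA_real_)
}

#' One-sided Welch t-test of replicate measurements
#'
#' Tests whether `sample` is greater than `control` (unequal variances,
#' Welch-Satterthwaite degrees of freedom); the null hypothesis is that the
#' sample distribution is not greater than the control distribution. If
#' both groups have zero variance and equal means the p-value is 1 by
#' convention (and 0/1 by direction when the constant means differ).
#'
#' @param sample,control Numeric replicate vectors, at least 2 values
#'   each.
#' @return p-value.
#' @export
welch_one_sided <- function(sample, control) {
  stopifnot(length(sample) >= 2, length(control) >= 2)
  if (stats::sd(sample) == 0 && stats::sd(control) == 0) {
    if (mean(sample) == mean(control)) return(1)
    return(if (mean(sample) > mean(control)) 0 else 1)
  }
  stats::t.test(sample, control, alternative = "greater",
                var.equal = FALSE)$p.value
}

#' Simulate a two-state melting curve
#'
#' Two-state sigmoid in temperature with the unfolding transition centered
#' at `tm_true`. The default readout descends through the transition (so
#' the melting point is a local minimum of dF, matching the default of
#' [melting_point()]); `direction = "ascending"` simulates a
#' dye-fluorescence gain with an optional post-transition dye-quench decay
#' (`quench`). Additive Gaussian noise, seeded.
#'
#' @param tm_true True melting point (deg C), inside `grid`.
#' @param amplitude Transition amplitude (RFU), default 1.
#' @param slope Transition width parameter (deg C), default 1.5.
#' @param baseline Baseline fluorescence, default 0.1.
#' @param noise_sd Gaussian noise standard deviation (RFU), default 0.
#' @param seed Integer seed.
#' @param grid Temperature grid, default `seq(25, 99, by = 0.5)`.
#' @param direction `"descending"` (default) or `"ascending"`.
#' @param quench Exponential post-transition quench rate (1/degC) applied
#'   in ascending mode, default 0.
#' @param well Optional well label.
#' @return A `"melting_curve"`.
#' @export
#' @examples
#' melting_point(simulate_curve(62))$tm
simulate_curve <- function(tm_true, amplitude = 1, slope = 1.5,
                           baseline = 0.1, noise_sd = 0, seed = 1,
                           grid = seq(25, 99, by = 0.5),
                           direction = c("descending", "ascending"),
                           quench = 0, well = NA_character_) {
  direction <- match.arg(direction)
  if (tm_true < min(grid) || tm_true > max(grid))
    stop("tm_true must lie inside the temperature grid")
  u <- 1 / (1 + exp((tm_true - grid) / slope))  # unfolded fraction
  f <- if (direction == "descending") {
    baseline + amplitude * (1 - u)
  } else {
    decay <- ifelse(grid > tm_true, exp(-quench * (grid - tm_true)), 1)
    baseline + amplitude * u * decay
  }
  if (noise_sd > 0) {
    set.seed(as.integer(child_seed(seed, 3)))
    f <- f + stats::rnorm(length(grid), 0, noise_sd)
  }
  melting_curve(grid, f, well)
}

#' Read plate-reader melting curves from long-format CSV
#'
#' Expected columns: `well`, `temperature`, `fluorescence` (one row per
#' reading, as exported by real-time PCR instruments).
#'
#' @param path CSV file path.
#' @return Named list of `"melting_curve"` objects, one per well.
#' @export
read_melting_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "temperature", "fluorescence")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$well), function(d) {
    d <- d[order(d$temperature), ]
    melting_curve(d$temperature, d$fluorescence, d$well[1])
  })
}

#' Summarize a replicate binding panel
#'
#' Computes per-ligand relative binding (mean, sd) against the positive
#' and negative control melting points and the one-sided Welch p-value of
#' each ligand's melting points against the no-ligand control.
#'
#' @param ligand_tms Named list of replicate melting-point vectors, one
#'   per ligand.
#' @param positive_tms,negative_tms Control replicate melting points.
#' @return data.frame with columns `ligand`, `n`, `relative_mean`,
#'   `relative_sd`, `p_value`.
#' @export
binding_panel <- function(ligand_tms, positive_tms, negative_tms) {
  stopifnot(is.list(ligand_tms), length(ligand_tms) > 0)
  rows <- lapply(names(ligand_tms), function(lig) {
    tms <- ligand_tms[[lig]]
    rb <- relative_binding(tms, positive_tms, negative_tms)
    data.frame(ligand = lig, n = length(tms), relative_mean = rb$mean,
               relative_sd = rb$sd,
               p_value = welch_one_sided(tms, negative_tms),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
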