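# Melt-curve (-dF/dT) analysis: derivative profiles, Tm peak calling,
# single/double-peak resolution, taxon classification by Tm window,
# and per-group heterogeneity summaries.

#' Construct a melt curve
#'
#' Validated container for one well's temperature-indexed fluorescence
#' record from the post-amplification melt programme.
#'
#' @param sample_id,target Identifiers.
#' @param temperatures Strictly increasing temperatures in degrees C,
#'   spanning at least 10 C with grid spacing <= 0.5 C.
#' @param fluorescence Fluorescence (RFU), same length.
#' @return An object of class `"melt_curve"`.
#' @export
melt_curve <- function(sample_id, target, temperatures, fluorescence) {
  temperatures <- as.numeric(temperatures)
  if (any(diff(temperatures) <= 0))
    stop("malformed temperature grid: must be strictly increasing")
  if (max(temperatures) - min(temperatures) < 10)
    stop("temperature span must be at least 10 degrees C")
  if (max(diff(temperatures)) > 0.5 + 1e-9)
    stop("temperature grid spacing must be <= 0.5 degrees C")
  if (length(fluorescence) != length(temperatures))
    stop("`fluorescence` and `temperatures` must have equal length")
  if (any(!is.finite(fluorescence)))
    stop("`fluorescence` contains non-finite values")
  structure(list(sample_id = sample_id, target = target,
                 temperatures = temperatures,
                 fluorescence = as.numeric(fluorescence)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s / %s (%.1f-%.1f C, %d points)\n",
              x$sample_id, x$target, min(x$temperatures),
              max(x$temperatures), length(x$temperatures)))
  invisible(x)
}

#' Smoothed negative melt derivative (-dF/dT)
#'
#' Computes the Savitzky-Golay smoothed negative first derivative of
#' fluorescence over temperature on the interior grid, the standard
#' melt-peak representation. Endpoints are trimmed by half the window
#' so every reported point has full smoothing support.
#'
#' @param curve A [melt_curve()].
#' @param smoothing_window Odd window length in grid points (>= 5,
#'   default 7; on a 0.1 C grid that spans 0.7 C).
#' @param smoothing_degree Polynomial degree (default 3).
#' @return An object of class `"melt_derivative"`: list with
#'   `sample_id`, `target`, `temperature`, `neg_dfdt`.
#' @export
derivative_profile <- function(curve, smoothing_window = 7,
                               smoothing_degree = 3) {
  stopifnot(inherits(curve, "melt_curve"))
  if (smoothing_window < 5 || smoothing_window %% 2 == 0)
    stop("`smoothing_window` must be odd and >= 5")
  step <- mean(diff(curve$temperatures))
  d <- -signal::sgolayfilt(curve$fluorescence, p = smoothing_degree,
                           n = smoothing_window, m = 1, ts = step)
  half <- (smoothing_window - 1) / 2
  keep <- (half + 1):(length(d) - half)
  structure(list(sample_id = curve$sample_id, target = curve$target,
                 temperature = curve$temperatures[keep],
                 neg_dfdt = d[keep]),
            class = "melt_derivative")
}

# Prominence of local maximum i in series y: height above the higher of
# the two minima separating it from nearer higher terrain (or the series
# ends).
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(i) {
    left <- y[seq_len(i)]
    higher_l <- which(left > y[i])
    base_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- y[i:length(y)]
    higher_r <- which(right > y[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    y[i] - max(base_l, base_r)
  }, numeric(1))
}

#' Call melt peaks and classify the profile shape
#'
#' Finds local maxima of the -dF/dT profile, refines each Tm to
#' sub-grid precision by quadratic interpolation, keeps peaks whose
#' topographic prominence is at least `min_prominence_frac` of the
#' tallest peak's height (above the profile minimum), and merges peaks
#' closer than `min_separation` (keeping the taller; ties toward lower
#' Tm). The tallest surviving peak is the major peak. The profile
#' class is `none`, `single`, `double` or `multi` by surviving peak
#' count; only `single` profiles are admissible for quantification.
#'
#' @param profile A `"melt_derivative"` from [derivative_profile()] (a
#'   [melt_curve()] is accepted and differentiated with defaults).
#' @param min_prominence_frac Relative prominence threshold
#'   (default 0.10).
#' @param min_separation Minimum peak separation in degrees C
#'   (default 1.0).
#' @return An object of class `"melt_profile"`: `sample_id`, `target`,
#'   `peaks` (data frame `tm`, `height`, `prominence`, `is_major`,
#'   major first), `n_peaks`, `profile_class`, `taxon_call`
#'   (`NA` until [classify_taxon()] is applied).
#' @export
call_peaks <- function(profile, min_prominence_frac = 0.10,
                       min_separation = 1.0) {
  if (inherits(profile, "melt_curve")) profile <- derivative_profile(profile)
  stopifnot(inherits(profile, "melt_derivative"))
  tt <- profile$temperature
  y <- profile$neg_dfdt
  n <- length(y)
  cand <- which(diff(sign(diff(y))) < 0) + 1L  # strict local maxima
  # a profile with negligible dynamic range is flat (numerical ripples
  # from smoothing must not become peaks)
  if (diff(range(y)) <= 1e-9 * max(abs(y), .Machine$double.xmin))
    cand <- integer(0)
  peaks <- data.frame(tm = numeric(0), height = numeric(0),
                      prominence = numeric(0), is_major = logical(0))
  if (length(cand)) {
    floor_y <- min(y)
    prom <- .peak_prominence(y, cand)
    tallest <- max(y[cand]) - floor_y
    keep <- prom >= min_prominence_frac * tallest
    cand <- cand[keep]; prom <- prom[keep]
    if (length(cand)) {
      # sub-grid Tm refinement: quadratic through the 3 points around max
      tm <- vapply(cand, function(i) {
        if (i <= 1L || i >= n) return(tt[i])
        y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
        den <- y1 - 2 * y2 + y3
        if (den == 0) return(tt[i])
        tt[i] + 0.5 * (y1 - y3) / den * (tt[2] - tt[1])
      }, numeric(1))
      height <- y[cand] - floor_y
      ord <- order(-height, tm)   # taller first; ties toward lower Tm
      tm <- tm[ord]; height <- height[ord]; prom <- prom[ord]
      sel <- logical(0); sel_tm <- numeric(0)
      for (j in seq_along(tm)) {
        if (!length(sel_tm) || all(abs(tm[j] - sel_tm) >= min_separation)) {
          sel <- c(sel, j); sel_tm <- c(sel_tm, tm[j])
        }
      }
      peaks <- data.frame(tm = tm[sel], height = height[sel],
                          prominence = prom[sel],
                          is_major = seq_along(sel) == 1L)
    }
  }
  np <- nrow(peaks)
  structure(list(sample_id = profile$sample_id, target = profile$target,
                 peaks = peaks, n_peaks = np,
                 profile_class = switch(as.character(min(np, 3L)),
                                        "0" = "none", "1" = "single",
                                        "2" = "double", "3" = "multi"),
                 taxon_call = NA_character_, taxon_flags = character(0)),
            class = "melt_profile")
}

#' @export
print.melt_profile <- function(x, ...) {
  cat(sprintf("<melt_profile> %s / %s: %s", x$sample_id, x$target,
              x$profile_class))
  if (x$n_peaks) cat(sprintf(" (Tm %s)",
                             paste(sprintf("%.2f", x$peaks$tm), collapse = ", ")))
  if (!is.na(x$taxon_call)) cat(" ->", x$taxon_call)
  cat("\n")
  invisible(x)
}

#' Tm-window taxon configuration
#'
#' Per-primer-set decision windows for classifying amplicons by
#' melting temperature. By default only the rbcL-LL primer set is
#' discriminative: \emph{Prochlorococcus}-like amplicons melt at
#' 81-86 C and \emph{Synechococcus}-like amplicons at 88-89 C, with
#' 86-87.5 C left as an explicit ambiguous buffer (the configured
#' \emph{Synechococcus} window is widened to 87.5-90 C so draws just
#' outside the canonical 88-89 C range are still assigned). All other
#' primer sets return `non_discriminative`.
#'
#' @param windows Named list, one entry per discriminative target, each
#'   a list with numeric length-2 `prochlorococcus` and
#'   `synechococcus` intervals (disjoint).
#' @return An object of class `"tm_window_config"`.
#' @export
tm_windows <- function(windows = list(
  `rbcL-LL` = list(prochlorococcus = c(81, 86),
                   synechococcus = c(87.5, 90)))) {
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (!all(c("prochlorococcus", "synechococcus") %in% names(w)))
      stop("window for ", nm, " needs prochlorococcus and synechococcus intervals")
    p <- sort(w$prochlorococcus); s <- sort(w$synechococcus)
    if (max(min(p), min(s)) < min(max(p), max(s)))
      stop("windows for ", nm, " must be disjoint")
  }
  structure(list(windows = windows), class = "tm_window_config")
}

.in_window <- function(tm, w) tm >= min(w) & tm <= max(w)

#' Classify a melt profile by Tm window
#'
#' For discriminative primer sets the major peak's window determines
#' `taxon_call` (`prochlorococcus`, `synechococcus`, or `ambiguous`
#' when the major Tm falls in neither window). A double profile with
#' one peak in each window is called `ambiguous` with
#' `taxon_flags = c("prochlorococcus", "synechococcus")`, reporting
#' mixed presence of both genera. Non-discriminative primer sets
#' return `non_discriminative`; profiles without peaks return
#' `ambiguous` with a `no_peaks` flag.
#'
#' @param profile A `"melt_profile"` from [call_peaks()].
#' @param config A [tm_windows()] configuration.
#' @return The profile with `taxon_call` (and `taxon_flags`) set.
#' @export
classify_taxon <- function(profile, config = tm_windows()) {
  stopifnot(inherits(profile, "melt_profile"),
            inherits(config, "tm_window_config"))
  w <- config$windows[[profile$target]]
  if (is.null(w)) {
    profile$taxon_call <- "non_discriminative"
    return(profile)
  }
  if (profile$n_peaks == 0L) {
    profile$taxon_call <- "ambiguous"
    profile$taxon_flags <- "no_peaks"
    return(profile)
  }
  hit <- function(tm) {
    c(prochlorococcus = .in_window(tm, w$prochlorococcus),
      synechococcus = .in_window(tm, w$synechococcus))
  }
  per_peak <- vapply(profile$peaks$tm, hit, logical(2))
  both <- rowSums(per_peak) > 0
  if (profile$n_peaks >= 2L && all(both)) {
    profile$taxon_call <- "ambiguous"
    profile$taxon_flags <- c("prochlorococcus", "synechococcus")
    return(profile)
  }
  major <- hit(profile$peaks$tm[profile$peaks$is_major][1L])
  profile$taxon_call <- if (major["prochlorococcus"]) "prochlorococcus"
    else if (major["synechococcus"]) "synechococcus"
    else "ambiguous"
  profile
}

#' Melt heterogeneity summary
#'
#' Per target x group descriptive statistics of amplicon sequence
#' heterogeneity: mean and sd of the major-peak Tm, the percentage of
#' profiles resolved into two or more peaks ("double peaks"), and the
#' percentage of major peaks lying more than two group standard
#' deviations from the group mean Tm ("non-average major peaks").
#'
#' @param profiles List of `"melt_profile"` objects.
#' @param grouping Character vector (recycled) assigning each profile
#'   to a group, e.g. its depth class; defaults to a single `"all"`
#'   group.
#' @return Data frame with columns `target`, `group`, `n`, `tm_mean`,
#'   `tm_sd`, `pct_double_peaks`, `pct_nonaverage_major_peaks`. Groups
#'   with fewer than 2 profiles are skipped with a message.
#' @export
heterogeneity_summary <- function(profiles, grouping = "all") {
  stopifnot(all(vapply(profiles, inherits, logical(1), "melt_profile")))
  grouping <- rep_len(as.character(grouping), length(profiles))
  targets <- vapply(profiles, `[[`, character(1), "target")
  major_tm <- vapply(profiles, function(p) {
    if (p$n_peaks) p$peaks$tm[p$peaks$is_major][1L] else NA_real_
  }, numeric(1))
  n_peaks <- vapply(profiles, `[[`, integer(1), "n_peaks")
  key <- paste(targets, grouping, sep = "\r")
  out <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    if (length(idx) < 2L) {
      message("skipping group with fewer than 2 profiles: ",
              sub("\r", " / ", k))
      return(NULL)
    }
    tm <- major_tm[idx]
    mu <- mean(tm, na.rm = TRUE)
    sdv <- stats::sd(tm, na.rm = TRUE)
    nonavg <- sum(abs(tm - mu) > 2 * sdv, na.rm = TRUE)
    data.frame(target = targets[idx[1L]], group = grouping[idx[1L]],
               n = length(idx), tm_mean = mu, tm_sd = sdv,
               pct_double_peaks = 100 * sum(n_peaks[idx] >= 2L) / length(idx),
               pct_nonaverage_major_peaks = 100 * nonavg / length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    stop("no group had at least 2 profiles")
  rownames(out) <- NULL
  out
}

#' Tabulate melt profiles
#'
#' Flattens a list of melt profiles into the long `melt_profiles`
#' table emitted by the pipeline.
#'
#' @param profiles List of `"melt_profile"` objects.
#' @return Data frame `sample_id, target, n_peaks, tm_major, tm_minor,
#'   profile_class, taxon_call`.
#' @export
melt_profile_table <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "melt_profile")))
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, target = p$target,
               n_peaks = p$n_peaks,
               tm_major = if (p$n_peaks) p$peaks$tm[1L] else NA_real_,
               tm_minor = if (p$n_peaks >= 2L) p$peaks$tm[2L] else NA_real_,
               profile_class = p$profile_class,
               taxon_call = p$taxon_call,
               stringsAsFactors = FALSE)
  }))
}
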