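# Specific heat of an annealing run: C(T) = var(HI samples at T) / T^2.
# Peaks in C mark the phase transitions of the search; the temperature of
# the (largest) peak is the critical temperature.

#' Specific heat of a sample of cost values
#'
#' `C = var(samples) / temperature^2`, with the sample variance using the
#' count-1 denominator.
#'
#' @param samples numeric vector of cost (HI) samples, length >= 2.
#' @param temperature positive temperature.
#' @return Non-negative specific heat.
#' @examples
#' specific_heat(c(0.4, 0.6), 0.5)  # 0.02 / 0.25 = 0.08
#' @export
specific_heat <- function(samples, temperature) {
  if (length(samples) < 2L)
    amp_stop("specific heat needs at least 2 samples", "thermo_error")
  if (!is.numeric(temperature) || temperature <= 0)
    amp_stop("specific heat needs a positive temperature", "thermo_error")
  stats::var(samples) / temperature^2
}

#' Specific-heat profile of an annealing trace
#'
#' One (temperature, C) point per completed temperature block (blocks cut
#' short by a move budget are dropped), in cooling order.
#'
#' @param trace an [anneal()] trace with at least 3 completed blocks.
#' @return A `data.frame` of class `"heat_profile"` with columns `block`,
#'   `temperature`, `C`; the run identifier is kept in attribute
#'   `"provenance"`.
#' @export
heat_profile <- function(trace) {
  stopifnot(inherits(trace, "sa_trace"))
  full <- trace$config$n %/% trace$config$l
  done <- trace$blocks$n_samples == full & trace$blocks$n_samples >= 2L
  if (sum(done) < 3L)
    amp_stop("need at least 3 completed temperature blocks", "thermo_error")
  bl <- trace$blocks[done, ]
  hi <- trace$hi[trace$hi$block %in% bl$block, ]
  v <- tapply(hi$hi, factor(hi$block, levels = bl$block), stats::var)
  out <- data.frame(block = bl$block, temperature = bl$temperature,
                    C = as.numeric(v) / bl$temperature^2)
  class(out) <- c("heat_profile", "data.frame")
  attr(out, "provenance") <- trace$alignment_id
  out
}

#' Plot a specific-heat profile
#'
#' Temperature on the abscissa with the axis reversed, so the search
#' progresses left to right along the cooling direction reads right to
#' left, as is conventional for annealing profiles.
#'
#' @param x a [heat_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.heat_profile <- function(x, ...) {
  graphics::plot(x$temperature, x$C, type = "l", xlim = rev(range(x$temperature)),
                 xlab = "temperature", ylab = "specific heat C", ...)
  invisible(x)
}

# centred moving average with shrinking windows at the profile edges
.smooth_ma <- function(x, w) {
  half <- (as.integer(w) - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# interior local maxima of a series, plateaus collapsed to their first index
.local_maxima <- function(s) {
  r <- rle(s)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in 2:(k - 1L)) {
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      out <- c(out, starts[j])
  }
  out
}

# topographic prominence of s[i]: height above the higher of the two lowest
# points separating the peak from higher terrain (or the series ends)
.prominence <- function(s, i) {
  n <- length(s)
  left <- s[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (s[j] > s[i]) break
    left <- min(left, s[j])
  }
  right <- s[i]
  j <- i
  while (j < n) {
    j <- j + 1L
    if (s[j] > s[i]) break
    right <- min(right, s[j])
  }
  s[i] - max(left, right)
}

#' Detect specific-heat peaks and classify the transition
#'
#' The profile is smoothed with a centred moving average; interior local
#' maxima whose topographic prominence reaches `prominence_frac` times the
#' smoothed global maximum are retained and reported in order of decreasing
#' magnitude. The transition is classified `"double"` when the two largest
#' retained maxima are at least 3 smoothed points apart, `"single"` when at
#' least one maximum is retained, and `"none"` for flat/degenerate profiles.
#' At most two peaks enter the classification; any further raw maxima are
#' still listed for diagnostics.
#'
#' @param profile a [heat_profile()].
#' @param smooth_window moving-average window in points (default 5).
#' @param prominence_frac retention threshold as a fraction of the global
#'   smoothed maximum (default 0.25).
#' @return An object of class `"peak_report"`: `peaks` (`data.frame` with
#'   `index`, `temperature` = T_c, `C` = magnitude, `prominence`),
#'   `n_peaks` (0, 1 or 2), and `classification`.
#' @export
detect_peaks <- function(profile, smooth_window = 5L, prominence_frac = 0.25) {
  stopifnot(inherits(profile, "heat_profile"))
  if (nrow(profile) < smooth_window)
    amp_stop("profile shorter than the smoothing window", "thermo_error")
  s <- .smooth_ma(profile$C, smooth_window)
  cand <- .local_maxima(s)
  peaks <- data.frame(index = integer(0), temperature = numeric(0),
                      C = numeric(0), prominence = numeric(0))
  if (length(cand) && diff(range(s)) > 0) {
    prom <- vapply(cand, function(i) .prominence(s, i), numeric(1))
    keep <- prom >= prominence_frac * max(s)
    cand <- cand[keep]
    prom <- prom[keep]
    if (length(cand)) {
      o <- order(profile$C[cand], decreasing = TRUE)
      cand <- cand[o]
      prom <- prom[o]
      peaks <- data.frame(index = cand,
                          temperature = profile$temperature[cand],
                          C = profile$C[cand], prominence = prom)
    }
  }
  n_peaks <- min(2L, nrow(peaks))
  classification <- if (n_peaks == 0L) "none"
    else if (n_peaks == 2L && abs(peaks$index[1] - peaks$index[2]) >= 3L)
      "double"
    else "single"
  if (classification == "single") n_peaks <- 1L
  structure(list(peaks = peaks, n_peaks = n_peaks,
                 classification = classification,
                 smooth_window = as.integer(smooth_window),
                 prominence_frac = prominence_frac,
                 provenance = attr(profile, "provenance")),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  cat(sprintf("Peak report (%s transition): %d classified peak(s)\n",
              x$classification, x$n_peaks))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Critical temperature from replicate peak reports
#'
#' The critical temperature of one run is the temperature of its largest
#' specific-heat peak; over replicates it is estimated as the arithmetic
#' mean of those temperatures. Peakless replicates are ignored.
#'
#' @param reports a [detect_peaks()] report or list of reports.
#' @return Mean critical temperature.
#' @export
critical_temperature <- function(reports) {
  if (inherits(reports, "peak_report")) reports <- list(reports)
  tc <- vapply(reports, function(r)
    if (r$n_peaks >= 1L) r$peaks$temperature[1] else NA_real_, numeric(1))
  tc <- tc[!is.na(tc)]
  if (length(tc) == 0L)
    amp_stop("no report contains a peak", "thermo_error")
  mean(tc)
}
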