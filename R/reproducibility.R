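# Inter-study reproducibility: signed differences and Bland-Altman.

#' Signed differences between paired measurements
#'
#' @param day1,day2 paired measurement vectors (same subjects, same order)
#' @return list with `mean` and `sd` of day2 - day1 (n-1 denominator) and
#'   the differences themselves
#' @export
signedDifferences <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("day1 and day2 must be paired")
  ok <- !is.na(day1) & !is.na(day2)
  d <- day2[ok] - day1[ok]
  if (length(d) < 2) stop("at least two complete pairs are required")
  list(mean = mean(d), sd = stats::sd(d), differences = d)
}

#' Bland-Altman agreement analysis
#'
#' Per-pair means and differences (day2 - day1), the bias (mean
#' difference) and the agreement limits bias +/- 2 SD.
#'
#' @param day1,day2 paired measurement vectors
#' @return list with `means`, `differences`, `bias`, `lower`, `upper`
#' @export
blandAltman <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("day1 and day2 must be paired")
  ok <- !is.na(day1) & !is.na(day2)
  if (sum(ok) < 2) stop("at least two complete pairs are required")
  d1 <- day1[ok]; d2 <- day2[ok]
  diffs <- d2 - d1
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  list(
    means = (d1 + d2) / 2, differences = diffs, bias = bias,
    lower = bias - 2 * s, upper = bias + 2 * s
  )
}

#' Plot a Bland-Altman diagram
#'
#' @param ba result of \code{\link{blandAltman}}
#' @param file optional PNG path
#' @param xlab,ylab,main plot labels
#' @return invisibly, the `ba` list
#' @export
plotBlandAltman <- function(ba, file = NULL, xlab = "mean of measurements",
                            ylab = "difference (day 2 - day 1)",
                            main = "Bland-Altman") {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 500)
    on.exit(grDevices::dev.off())
  }
  ylim <- range(c(ba$differences, ba$lower, ba$upper))
  graphics::plot(ba$means, ba$differences, pch = 18, col = "blue",
                 xlab = xlab, ylab = ylab, main = main, ylim = ylim)
  graphics::abline(h = c(ba$lower, ba$bias, ba$upper), lty = 2, col = "blue")
  invisible(ba)
}

#' Fixed-length conversion of a TTP percentage difference
#'
#' For paired differences the diastolic offset of the fixed-length
#' conversion cancels, leaving the affine rule: delta_ms = delta_percent *
#' avgSystole/100 (3.5 ms per percent, systolic) or * avgDiastole/100
#' (6.5 ms per percent, diastolic).
#'
#' @param deltaPercent difference of TTP percentages
#' @param class "systolic" or "diastolic"
#' @param constants from \code{\link{normalizationConstants}}
#' @return difference in fixed-length ms
#' @export
ttpFixedDifference <- function(deltaPercent,
                               class = c("systolic", "diastolic"),
                               constants = normalizationConstants()) {
  class <- match.arg(class)
  slope <- if (class == "systolic") {
    constants$avgSystole / 100
  } else {
    constants$avgDiastole / 100
  }
  deltaPercent * slope
}

#' Inter-study reproducibility table
#'
#' Mean and SD of the signed differences (day 2 - day 1) for every peak
#' parameter across matched subjects: amplitude (cm/s), TTP from the
#' R-wave (ms), TTP as a percentage of systole/diastole, and the
#' fixed-length ms difference computed from the percentage differences by
#' the affine rule. Subjects present on only one day are excluded with a
#' warning; a peak absent on either day contributes no pair for that
#' parameter.
#'
#' @param day1,day2 named lists (by subject) of lists of
#'   \linkS4class{PeakSet}s (one per direction)
#' @param constants from \code{\link{normalizationConstants}}
#' @param digits when non-NULL, round the summary columns half away from
#'   zero to this many decimals, as printed tables do
#' @return data.frame with one row per peak parameter
#' @export
reproducibilityTable <- function(day1, day2,
                                 constants = normalizationConstants(),
                                 digits = NULL) {
  common <- intersect(names(day1), names(day2))
  dropped <- setdiff(union(names(day1), names(day2)), common)
  if (length(dropped) > 0) {
    warning("unmatched subject(s) excluded: ", paste(dropped, collapse = ", "))
  }
  flatten <- function(visit, subj) {
    do.call(rbind, lapply(visit[[subj]], function(ps) {
      p <- ps@peaks
      p$subject <- subj
      p
    }))
  }
  t1 <- do.call(rbind, lapply(common, function(s) flatten(day1, s)))
  t2 <- do.call(rbind, lapply(common, function(s) flatten(day2, s)))

  peaks <- unique(t1$peak)
  rows <- lapply(peaks, function(pk) {
    a <- t1[t1$peak == pk, ]
    b <- t2[t2$peak == pk, ]
    m <- match(a$subject, b$subject)
    b <- b[m, ]
    ok <- a$present & b$present & !is.na(m)
    if (sum(ok) < 2) {
      return(data.frame(
        peak = pk, class = a$class[1], n = sum(ok),
        amp_mean = NA_real_, amp_sd = NA_real_,
        ttp_ms_mean = NA_real_, ttp_ms_sd = NA_real_,
        pct_mean = NA_real_, pct_sd = NA_real_,
        fixed_ms_mean = NA_real_, fixed_ms_sd = NA_real_
      ))
    }
    dAmp <- signedDifferences(a$amplitude[ok], b$amplitude[ok])
    dTtp <- signedDifferences(a$ttp_ms[ok], b$ttp_ms[ok])
    dPct <- signedDifferences(a$ttp_percent[ok], b$ttp_percent[ok])
    cls <- a$class[1]
    data.frame(
      peak = pk, class = cls, n = sum(ok),
      amp_mean = dAmp$mean, amp_sd = dAmp$sd,
      ttp_ms_mean = dTtp$mean, ttp_ms_sd = dTtp$sd,
      pct_mean = dPct$mean, pct_sd = dPct$sd,
      fixed_ms_mean = ttpFixedDifference(dPct$mean, cls, constants),
      fixed_ms_sd = ttpFixedDifference(dPct$sd, cls, constants)
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
    out[num] <- lapply(out[num], roundHalfAway, digits = digits)
  }
  out
}
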