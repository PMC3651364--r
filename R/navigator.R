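# Respiratory trace simulation and dual-navigator acceptance.

#' Simulate a respiratory diaphragm trace
#'
#' One diaphragm position sample per cardiac cycle (mm, positive = caudal
#' displacement from the end-expiratory pause position). Two modes:
#' "free" breathing is a sinusoid with slow amplitude/baseline drift plus
#' noise; "guided" emulates visual-feedback breathing as alternating
#' near-end-expiratory holds and breathing excursions, the pattern most
#' subjects adopt when shown their own trace.
#'
#' @param nCycles number of cardiac cycles
#' @param mode "guided" or "free"
#' @param amplitude breathing excursion amplitude, mm
#' @param period breathing period in cardiac cycles (free mode)
#' @param holdLength,breathLength mean lengths (cycles) of the hold and
#'   breathing segments in guided mode
#' @param noiseSd within-hold position noise, mm
#' @param seed integer seed
#' @return numeric vector of diaphragm positions, mm
#' @export
respiratoryTrace <- function(nCycles, mode = c("guided", "free"),
                             amplitude = 8, period = 5,
                             holdLength = 12, breathLength = 8,
                             noiseSd = 0.8, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "free") {
    drift <- cumsum(stats::rnorm(nCycles, 0, 0.2))
    pos <- amplitude / 2 * (1 - cos(2 * pi * seq_len(nCycles) / period)) +
      drift + stats::rnorm(nCycles, 0, noiseSd)
    return(pos)
  }
  pos <- numeric(0)
  while (length(pos) < nCycles) {
    h <- max(3, round(stats::rnorm(1, holdLength, holdLength / 4)))
    b <- max(2, round(stats::rnorm(1, breathLength, breathLength / 4)))
    hold <- stats::rnorm(h, 0, noiseSd)
    breath <- amplitude * sin(pi * seq_len(b) / (b + 1)) +
      stats::rnorm(b, 0, noiseSd)
    pos <- c(pos, hold, breath)
  }
  pos[seq_len(nCycles)]
}

#' Dual-navigator respiratory gating
#'
#' A cardiac cycle's data are accepted only when the navigators immediately
#' before and after that acquisition both fall inside the acceptance
#' window, i.e. cycle i is accepted iff |position(i)| <= window/2 and
#' |position(i+1)| <= window/2. The final cycle has no following navigator
#' and is rejected.
#'
#' @param trace diaphragm positions, one per cardiac cycle (mm)
#' @param window acceptance window width, mm
#' @return list with `accepted` (logical mask per cycle) and `efficiency`
#'   (accepted fraction)
#' @examples
#' simulateNavigatorGating(rep(0, 10), window = 5)$efficiency  # 9/10
#' @export
simulateNavigatorGating <- function(trace, window = 5) {
  n <- length(trace)
  if (n < 2) stop("trace must contain at least two cycles")
  inWin <- abs(trace) <= window / 2
  accepted <- inWin & c(inWin[-1], FALSE)
  list(accepted = accepted, efficiency = mean(accepted))
}
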