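# Quantitative observables extracted from relaxation traces and sweep
# results: energy barriers, equilibrium energy steppings, plateau
# detection and conformational-cap length estimation.

#' Energy barrier and equilibrium stepping of one closure trace
#'
#' The barrier is the transient peak of the total potential energy above the
#' pre-closure equilibrium; the stepping is the difference between the two
#' equilibrium levels. Both are invariant to a uniform energy offset of the
#' trace.
#'
#' @param trace an \code{mt_trace} from a converged relaxation.
#' @param E_before pre-event equilibrium energy, nN*nm.
#' @param params \code{mt_params} (for the kBT conversion).
#' @return named numeric: \code{barrier} and \code{stepping} in kBT.
#' @export
extract_barrier_and_stepping <- function(trace, E_before, params) {
  if (!isTRUE(trace$converged))
    stop("trace did not converge; barrier/stepping undefined")
  c(barrier = energy_to_kBT(trace$peak_energy - E_before, params),
    stepping = energy_to_kBT(trace$e_final - E_before, params))
}

#' Minimum sheet length that stabilizes growth
#'
#' Detects the long-sheet barrier plateau as the longest suffix of sweep
#' conditions whose pairwise spread stays within the tolerance, then reports
#' the smallest sheet length whose barrier reaches at least
#' \code{(1 - tolerance)} of the plateau mean, converted to dimer layers
#' (monomers / 2, rounded up). Invariant to a uniform rescaling of all
#' barriers.
#'
#' @param sweep data.frame with columns \code{sheet_length} (monomers) and
#'   \code{barrier_kBT}, ordered or orderable by length.
#' @param tolerance relative tolerance defining "on the plateau"
#'   (default 0.1).
#' @return minimum stable cap length in dimer layers.
#' @export
minimum_stable_cap <- function(sweep, tolerance = 0.1) {
  sweep <- sweep[order(sweep$sheet_length), ]
  b <- sweep$barrier_kBT
  n <- length(b)
  if (n < 2) stop("sweep must cover at least two sheet lengths")
  # longest suffix with relative spread within tolerance
  start <- n
  for (i in rev(seq_len(n))) {
    seg <- b[i:n]
    if ((max(seg) - min(seg)) <= tolerance * max(seg)) start <- i else break
  }
  if (start == n)
    stop("no plateau detectable in the sweep")
  plateau <- mean(b[start:n])
  ok <- which(b >= (1 - tolerance) * plateau)
  if (length(ok) == 0) stop("no condition reaches the plateau")
  as.integer(ceiling(sweep$sheet_length[min(ok)] / 2))
}
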