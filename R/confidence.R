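# Mapping per-trial uncertainty onto the 1-5 post-decision betting scale via
# the inverse-CDF scheme: pooled uncertainties are rank-ordered and cut at
# the cumulative probabilities of a discrete Gaussian prior over bets.

#' Discrete Gaussian prior over the betting scale
#'
#' Probabilities proportional to `exp(-(k-3)^2/2)` over the integers 1-5
#' (a discrete normal centered at 3 with unit variance, normalized to sum to
#' one).
#'
#' @return list of class `bet_prior` with `support` (1:5) and
#'   `probabilities`.
#' @export
discrete_gaussian_bet_prior <- function() {
  k <- 1:5
  p <- exp(-(k - 3)^2 / 2)
  structure(list(support = k, probabilities = p / sum(p)), class = "bet_prior")
}

# largest-remainder apportionment of n among probabilities p; ties in the
# remainder go to the lower index for determinism
largest_remainder_counts <- function(n, p) {
  x <- n * p
  base <- floor(x)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(x - base), seq_along(p))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign discrete bets from pooled uncertainties
#'
#' Uncertainties (pooled over all trials of an experiment) are sorted in
#' descending order; the most uncertain `round(N*p(1))` trials receive bet 1,
#' the next block bet 2, and so on, with largest-remainder rounding so the
#' block sizes sum to N. Higher uncertainty therefore never receives a higher
#' bet, ties are broken by original trial order (stable sort), and the
#' multiset of (uncertainty, bet) pairs is invariant to input order.
#'
#' @param uncertainties numeric vector (HPD widths, entropies, or mode-local
#'   variances; any monotone uncertainty measure).
#' @param prior a [discrete_gaussian_bet_prior()].
#' @return integer vector of bets in 1-5, aligned with the input order.
#' @export
assign_bets <- function(uncertainties, prior = discrete_gaussian_bet_prior()) {
  n <- length(uncertainties)
  stopifnot(n >= 1)
  counts <- largest_remainder_counts(n, prior$probabilities)
  ord <- order(-uncertainties, seq_len(n))   # descending, stable
  bets_sorted <- rep(prior$support, times = counts)
  bets <- integer(n)
  bets[ord] <- bets_sorted
  bets
}
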