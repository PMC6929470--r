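## MG94xHKY codon rate matrix. Off-diagonal rates are nonzero only for
## single-nucleotide codon changes and proportional to
##   kappa^(is transition) * omega^(is nonsynonymous) * pi_target-codon,
## i.e. MG94-style counting of single-nucleotide changes with HKY-type
## transition/transversion weighting and target-codon equilibrium
## frequencies (which makes the chain time-reversible for any valid pi).
## A matrix is conventionally scaled so the expected number of
## substitutions per unit time is 1 at its own stationary distribution.

#' Build an MG94xHKY codon rate matrix
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param codon_freqs Numeric vector of 61 stationary codon frequencies in
#'   [sense_codons()] order, summing to 1.
#' @param scale If `TRUE` (default), scale so that the expected substitution
#'   rate at stationarity is 1.
#' @return 61 x 61 rate matrix `Q` with rows summing to 0.
#' @export
codon_rate_matrix <- function(kappa, omega, codon_freqs, scale = TRUE) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0) {
    stop("omega must be a single non-negative number")
  }
  check_codon_freqs(codon_freqs)
  ch <- codon_change_table()
  sense <- sense_codons()
  Q <- matrix(0, 61, 61, dimnames = list(sense, sense))
  rate_ij <- kappa^ch$transition * omega^ch$nonsyn * codon_freqs[ch$j]
  rate_ji <- kappa^ch$transition * omega^ch$nonsyn * codon_freqs[ch$i]
  Q[cbind(ch$i, ch$j)] <- rate_ij
  Q[cbind(ch$j, ch$i)] <- rate_ji
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(codon_freqs * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  Q
}

## Expected substitution rate (before scaling) of the MG94xHKY chain as a
## function of omega: rate(omega) = A + omega * B, with A the synonymous and
## B the nonsynonymous flux at kappa, pi. Used to put the whole category
## mixture on a common branch-length scale.
substitution_rate_coefs <- function(kappa, codon_freqs) {
  ch <- codon_change_table()
  flux <- kappa^ch$transition *
    codon_freqs[ch$i] * codon_freqs[ch$j]
  c(A = 2 * sum(flux[ch$nonsyn == 0]),
    B = 2 * sum(flux[ch$nonsyn == 1]))
}

#' Transition probability matrix P = exp(Qt)
#'
#' Computed through the symmetric eigendecomposition available for
#' time-reversible chains.
#'
#' @param Q Rate matrix from [codon_rate_matrix()] (or any reversible rate
#'   matrix with stationary distribution `pi`).
#' @param t Elapsed time (branch length), `t >= 0`.
#' @param pi Stationary distribution of `Q`; if `NULL` it is recovered from
#'   the left null vector of `Q`.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t, pi = NULL) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("t must be a single non-negative number")
  }
  if (is.null(pi)) pi <- stationary_distribution(Q)
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  d <- sqrt(pi)
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2  # symmetrise against round-off
  eg <- eigen(S, symmetric = TRUE)
  P <- outer(1 / d, d) * (eg$vectors %*%
    (exp(eg$values * t) * t(eg$vectors)))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Stationary distribution of a reversible rate matrix
#'
#' @param Q Rate matrix (rows summing to zero).
#' @return Probability vector `pi` with `pi %*% Q = 0`.
#' @export
stationary_distribution <- function(Q) {
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(Q))
}
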