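# Concentration cap: A(kappa) saturates near 1 long before 500 and the
# Best-Fisher sampler stays numerically safe there.
KAPPA_MAX <- 500

#' Mean resultant length of a von Mises distribution
#'
#' A(kappa) = I1(kappa) / I0(kappa), evaluated with exponentially scaled
#' Bessel functions so large kappa does not overflow.
#'
#' @param kappa concentration, >= 0; vectorized.
#' @return mean resultant length in [0, 1).
#' @export
vm_resultant_length <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Concentration from a mean resultant length
#'
#' Inverts A(kappa) = I1(kappa)/I0(kappa) by bracketed root-finding.
#' R = 0 maps to 0; R within 1e-9 of 1 (or beyond A(KAPPA_MAX)) maps to
#' the cap of 500.
#'
#' @param rbar mean resultant length in [0, 1].
#' @return concentration kappa in [0, 500].
#' @export
resultant_to_concentration <- function(rbar) {
  if (rbar < 0 || rbar > 1) stop("rbar must lie in [0, 1]")
  # A(k) ~ k/2 as k -> 0; avoids a degenerate root bracket
  if (rbar < 1e-8) return(2 * rbar)
  if (rbar >= 1 - 1e-9 || rbar >= vm_resultant_length(KAPPA_MAX)) {
    return(KAPPA_MAX)
  }
  stats::uniroot(function(k) vm_resultant_length(k) - rbar,
                 lower = 1e-12, upper = KAPPA_MAX, tol = 1e-12)$root
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. kappa = 0 degenerates to the
#' circular uniform. Draws come from R's global RNG stream, so results
#' are reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return headings in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) break
    }
    out[i] <- sign(u[3] - 0.5) * acos(f)
  }
  wrap_angle(out + mu)
}

#' Fuse own and observed headings into a von Mises estimate
#'
#' Weighted-resultant fusion of an individual's inherent heading sample
#' with the observed headings of detectable conspecifics. The location
#' resultant is the weighted sum alpha * u(own) + (1 - alpha) *
#' sum of neighbour unit vectors; the concentration resultant is the
#' same construction with beta, its length clamped to 1 before
#' inversion. The fused mean direction is the argument of the location
#' resultant and the fused concentration inverts the (clamped) length of
#' the concentration resultant.
#'
#' The neighbour term is deliberately the unnormalized resultant of the
#' observed set, not its mean: dividing by the neighbour count makes the
#' expected unit vector of the redrawn heading exactly linear in the
#' inputs, which contracts the population's mean heading vector to the
#' solitary value for any group size and erases the many-wrongs benefit
#' of collective navigation. The saturating sum preserves the benefit: a
#' large, well-aligned observed set pins the redrawn heading to the
#' group consensus while the own-sample term steers the consensus toward
#' the target (see the methods vignette).
#'
#' With no neighbours the individual keeps its own sample exactly
#' (concentration capped), the solitary-navigation limit. A zero
#' resultant yields concentration 0 and a uniformly random tie-break
#' direction.
#'
#' @param own the individual's inherent heading sample, radians.
#' @param neighbours numeric vector of observed headings (may be empty).
#' @param alpha weight on own heading for the mean direction, in [0, 1].
#' @param beta weight on own heading for the concentration, in [0, 1].
#' @return list with `mu` (radians) and `kappa`.
#' @export
fuse_headings <- function(own, neighbours, alpha = 0.5, beta = 0.5) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  if (length(neighbours) == 0) {
    return(list(mu = wrap_angle(own), kappa = KAPPA_MAX))
  }
  nb <- colSums(heading_unit(neighbours))
  dim(nb) <- NULL
  r_loc <- alpha * c(cos(own), sin(own)) + (1 - alpha) * nb
  r_con <- beta * c(cos(own), sin(own)) + (1 - beta) * nb
  len_loc <- sqrt(sum(r_loc^2))
  mu <- if (len_loc < 1e-12) stats::runif(1, -pi, pi) else
    atan2(r_loc[2], r_loc[1])
  kappa <- resultant_to_concentration(min(sqrt(sum(r_con^2)), 1))
  list(mu = wrap_angle(mu), kappa = kappa)
}
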