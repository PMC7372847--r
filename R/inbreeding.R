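#' Inbreeding coefficient under full-sib mating
#'
#' Classical diploid full-sib recursion
#' \deqn{F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4, \quad F_0 = F_{-1} = 0.}
#' This is the analytic reference usually quoted for inbred line panels even
#' when the organism is haplodiploid; the explicit haplodiploid pedigree in
#' [simulate_inbred_lines()] loses heterozygosity faster.
#'
#' @param t number of generations (non-negative integer, vectorised).
#' @param scheme currently only `"full-sib-diploid"`.
#' @return inbreeding coefficient(s) F in `[0, 1)`.
#' @examples
#' inbreeding_coefficient(0:10)
#' @export
inbreeding_coefficient <- function(t, scheme = "full-sib-diploid") {
  scheme <- match.arg(scheme)
  if (any(t < 0) || any(t != floor(t))) stop("t must be a non-negative integer")
  tmax <- max(t, 1)
  f <- numeric(tmax + 1)  # f[k+1] = F_k
  fm1 <- 0                # F_{-1}
  f[1] <- 0
  if (tmax >= 1) f[2] <- (1 + 2 * f[1] + fm1) / 4
  if (tmax >= 2)
    for (k in 2:tmax) f[k + 1] <- (1 + 2 * f[k] + f[k - 1]) / 4
  f[t + 1]
}

#' Expected fraction of sites still segregating within a line
#'
#' For inbreeding coefficient F the expected within-line heterozygosity
#' (relative to the founder value) is 1 - F.
#'
#' @param F inbreeding coefficient(s) in `[0, 1]`.
#' @return expected segregating fraction 1 - F.
#' @examples
#' expected_segregating_fraction(0.87)  # 0.13
#' @export
expected_segregating_fraction <- function(F) {
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  1 - F
}
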