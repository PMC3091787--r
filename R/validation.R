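#' Deletion-allele frequency from a homozygote count
#'
#' Under Hardy-Weinberg proportions the frequency of
#' deletion-homozygous individuals is the square of the deletion-allele
#' frequency, so observing `k` homozygotes among `n` individuals gives
#' the point estimate `sqrt(k / n)`.
#'
#' @param k observed number of deletion-homozygous individuals
#' @param n sample size (individuals)
#' @return allele frequency (fraction in `[0, 1]`)
#' @examples
#' allele_hat <- alleleFreqFromHomozygotes(2, 132)  # ~0.123, i.e. 12%
#' round(100 * allele_hat)
#' @export
alleleFreqFromHomozygotes <- function(k, n) {
    stopifnot(n >= 1)
    if (any(k < 0) || any(k > n))
        stop("k must satisfy 0 <= k <= n")
    sqrt(k / n)
}

#' Exact Poisson confidence interval for a homozygote count
#'
#' The number of deletion homozygotes in a sample is modelled as
#' Poisson; the exact (Garwood) interval for its mean is
#' `lower = qchisq(alpha/2, 2k) / 2` (0 when `k = 0`) and
#' `upper = qchisq(1 - alpha/2, 2k + 2) / 2`. The interval is
#' asymmetric, which matters at the small counts typical of rare
#' homozygotes.
#'
#' @param k observed count
#' @param level confidence level in (0, 1), default 0.95
#' @return named numeric vector `c(lower, upper)` on the count scale
#' @examples
#' poissonCiHomozygotes(2)  # upper endpoint ~7.22
#' @export
poissonCiHomozygotes <- function(k, level = 0.95) {
    stopifnot(k >= 0)
    if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
        stop("level must lie strictly between 0 and 1")
    alpha <- 1 - level
    lower <- ifelse(k == 0, 0, stats::qchisq(alpha / 2, 2 * k) / 2)
    upper <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
    c(lower = unname(lower), upper = unname(upper))
}

#' Confidence interval for the deletion-allele frequency
#'
#' Maps the exact Poisson interval for the homozygote count through the
#' monotone transform `f = sqrt(lambda / n)` onto the allele-frequency
#' scale, in percent. Monotonicity preserves the coverage of the count
#' interval.
#'
#' @inheritParams alleleFreqFromHomozygotes
#' @inheritParams poissonCiHomozygotes
#' @return list: `estimate` (percent), `lower`, `upper` (percent),
#'   `countCi` (the underlying count-scale interval), `level`
#' @examples
#' alleleFreqCi(2, 132)  # upper ~23.4%
#' @export
alleleFreqCi <- function(k, n, level = 0.95) {
    est <- alleleFreqFromHomozygotes(k, n)
    ci <- poissonCiHomozygotes(k, level)
    list(estimate = 100 * est,
        lower = 100 * sqrt(ci[["lower"]] / n),
        upper = 100 * sqrt(ci[["upper"]] / n),
        countCi = ci, level = level)
}
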