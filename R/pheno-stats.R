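#' Reference-normalized group quantification
#'
#' Normalizes per-plant measurements (expression, metabolite
#' concentration, ...) to the mean of all plants in the reference group(s):
#' the reference mean pools every measurement from rows flagged as
#' reference (so multiple reference subgroups are weighted by their sizes),
#' and each group's relative value is its mean divided by that pooled
#' reference mean. Report values are additionally rounded to 2 decimals;
#' the unrounded values are retained.
#'
#' @param measurements a `data.frame` with columns `label` (group),
#'   `value` (one measurement per row), and `reference` (logical).
#' @return A `data.frame` with one row per group: `label`, `n`, `mean`,
#'   `relative` (unrounded), `relative_rounded`.
#' @examples
#' df <- data.frame(
#'   label = rep(c("GSL.a", "GSL.b", "het"), each = 5),
#'   value = rep(c(0.69, 0.56, 1.10), each = 5),
#'   reference = rep(c(TRUE, TRUE, FALSE), each = 5))
#' relativeToReference(df)  # het: 1.76
#' @export
relativeToReference <- function(measurements) {
    stopifnot(is.data.frame(measurements),
              all(c("label", "value", "reference") %in%
                  colnames(measurements)))
    if (!any(measurements$reference))
        stop("at least one reference group is required")
    refMean <- mean(measurements$value[measurements$reference])
    if (refMean == 0)
        stop("reference mean is zero; cannot normalize")
    labels <- unique(measurements$label)
    means <- vapply(labels, function(l)
        mean(measurements$value[measurements$label == l]), numeric(1L))
    ns <- vapply(labels, function(l)
        sum(measurements$label == l), integer(1L))
    data.frame(label = labels, n = ns, mean = means,
               relative = means / refMean,
               relative_rounded = round(means / refMean, 2L),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation with two-sided t-test
#'
#' Product-moment correlation between two equal-length vectors, with the
#' squared coefficient and the two-sided p-value from the t transform on
#' n - 2 degrees of freedom (as computed by [stats::cor.test()]).
#'
#' @param x,y numeric vectors, equal length >= 3, each with nonzero
#'   variance.
#' @return A list with `r`, `r_squared`, `p`, and `n`.
#' @importFrom stats cor.test sd
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("degenerate input: zero variance")
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    r <- unname(ct$estimate)
    list(r = r, r_squared = r^2, p = ct$p.value, n = length(x))
}

#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit of observed class counts against expected
#' proportions, e.g. the 1:1:2 ratio expected among self-progeny of a
#' heterozygote when both homozygote classes are phenotypically
#' distinguishable from the heterozygote.
#'
#' @param observed non-negative integer counts per phenotypic class
#'   (length >= 2, total > 0).
#' @param expectedRatio positive weights, same length (default `c(1, 1, 2)`
#'   for three classes).
#' @return A list with `chi_squared`, `df` (= classes - 1), `p`, and
#'   `expected` counts.
#' @examples
#' segregationTest(c(30, 20, 50))  # chi-squared 2, df 2
#' @importFrom stats chisq.test
#' @export
segregationTest <- function(observed, expectedRatio = c(1, 1, 2)) {
    if (length(observed) < 2L)
        stop("degenerate input: need at least two classes")
    if (length(observed) != length(expectedRatio))
        stop("observed and expectedRatio lengths differ")
    if (any(expectedRatio <= 0))
        stop("expected weights must be positive")
    if (sum(observed) <= 0)
        stop("observed total must be positive")
    p <- expectedRatio / sum(expectedRatio)
    ht <- suppressWarnings(stats::chisq.test(observed, p = p))
    list(chi_squared = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, expected = unname(ht$expected))
}
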