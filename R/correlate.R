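#' Correlation coefficient with p-value, three methods
#'
#' Pearson's product-moment r with the exact t reference (df = n - 2);
#' Spearman's rho as Pearson on average ranks with the same t approximation;
#' Kendall's tau-b (tie-corrected) with the large-sample normal
#' approximation \eqn{z = 3\tau\sqrt{n(n-1)} / \sqrt{2(2n+5)}}. All p-values
#' are two-sided. A constant input vector makes the coefficient undefined:
#' the result is flagged rather than silently 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method one of \code{"pearson"}, \code{"spearman"},
#'   \code{"kendall"}.
#' @return list with \code{estimate}, \code{p}, \code{n},
#'   \code{undefined} (TRUE when either vector is constant, estimate and p
#'   then NA).
#' @examples
#' corWithP(1:5, c(2, 1, 4, 3, 6), "pearson")$estimate   # 10/sqrt(148)
#' corWithP(1:5, c(2, 1, 4, 3, 6), "spearman")$estimate  # 0.8
#' corWithP(1:5, c(2, 1, 4, 3, 6), "kendall")$estimate   # 0.6
#' @export
corWithP <- function(x, y, method = c("pearson", "spearman", "kendall")) {
    method <- match.arg(method)
    if (length(x) != length(y)) stop("x and y must have equal length")
    n <- length(x)
    if (n < 3) stop("need at least 3 paired observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(estimate = NA_real_, p = NA_real_, n = n,
                    undefined = TRUE))
    est <- stats::cor(x, y, method = method)
    p <- .corPValue(est, n, method)
    list(estimate = est, p = p, n = n, undefined = FALSE)
}

# Vectorized p-values from a coefficient (matrix or vector).
.corPValue <- function(est, n, method) {
    if (method == "kendall") {
        z <- 3 * est * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
        2 * stats::pnorm(-abs(z))
    } else {
        r2 <- pmin(est^2, 1)
        t <- abs(est) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.xmin))
        p <- 2 * stats::pt(-t, n - 2)
        ifelse(r2 >= 1, 0, p)
    }
}

#' Full correlation triple for one gene pair
#'
#' @inheritParams corWithP
#' @return one-row data.frame: r_pearson, p_pearson, rho_spearman,
#'   p_spearman, tau_kendall, p_kendall, n_patients.
#' @export
correlationTriple <- function(x, y) {
    pe <- corWithP(x, y, "pearson")
    sp <- corWithP(x, y, "spearman")
    ke <- corWithP(x, y, "kendall")
    data.frame(r_pearson = pe$estimate, p_pearson = pe$p,
               rho_spearman = sp$estimate, p_spearman = sp$p,
               tau_kendall = ke$estimate, p_kendall = ke$p,
               n_patients = pe$n)
}
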