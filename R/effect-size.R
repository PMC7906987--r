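#' Hedges' g standardized mean difference with sampling variance
#'
#' The per-study effect size: the case-minus-control mean difference divided
#' by the pooled standard deviation, with Hedges' small-sample bias
#' correction \eqn{J = 1 - 3 / (4(n_1+n_2-2) - 1)}. The sampling variance is
#' \eqn{(n_1+n_2)/(n_1 n_2) + g^2 / (2(n_1+n_2))}.
#'
#' @param case,control numeric vectors, each of length >= 2.
#' @return list with \code{g}, \code{var_g}, \code{n_case}, \code{n_control},
#'   and \code{degenerate} (TRUE when the pooled SD is zero, in which case
#'   \code{g} and \code{var_g} are NA and the gene is excluded from pooling).
#' @examples
#' hedgesG(c(3, 4, 5), c(1, 2, 3))  # g = 1.6, var_g = 0.88
#' @export
hedgesG <- function(case, control) {
    n1 <- length(case); n2 <- length(control)
    if (n1 < 2 || n2 < 2)
        stop("need at least 2 samples per group for an effect size")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) / df
    if (sp2 <= 0)
        return(list(g = NA_real_, var_g = NA_real_, n_case = n1,
                    n_control = n2, degenerate = TRUE))
    J <- 1 - 3 / (4 * df - 1)
    g <- J * (mean(case) - mean(control)) / sqrt(sp2)
    var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
    list(g = g, var_g = var_g, n_case = n1, n_control = n2,
         degenerate = FALSE)
}

# Vectorized per-gene Hedges' g for one dataset; returns data.frame keyed by
# gene. Must agree with hedgesG() exactly (unit-tested).
.hedgesGMatrix <- function(x, group) {
    case <- x[, group == "case", drop = FALSE]
    ctrl <- x[, group == "control", drop = FALSE]
    n1 <- ncol(case); n2 <- ncol(ctrl)
    df <- n1 + n2 - 2
    m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
    v1 <- rowSums((case - m1)^2) / (n1 - 1)
    v2 <- rowSums((ctrl - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    J <- 1 - 3 / (4 * df - 1)
    g <- ifelse(sp2 > 0, J * (m1 - m2) / sqrt(sp2), NA_real_)
    var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
    data.frame(gene = rownames(x), g = g, var_g = var_g,
               n_case = n1, n_control = n2, log2fc = m1 - m2,
               degenerate = !(sp2 > 0), row.names = NULL)
}

#' Fixed-effect inverse-variance pooling of per-study effect sizes
#'
#' Combines one gene's study-specific Hedges' g values into a single pooled
#' effect \eqn{f_{meta} = \sum w_i g_i / \sum w_i} with weights
#' \eqn{w_i = 1 / var(g_i)}; \eqn{se = \sqrt{1 / \sum w_i}},
#' \eqn{z = f_{meta}/se}, and a two-sided normal p-value.
#'
#' @param g numeric vector of per-study effect sizes.
#' @param var_g matching vector of sampling variances (> 0).
#' @return list with \code{f_meta}, \code{se}, \code{z}, \code{p},
#'   \code{n_datasets_used}, plus the heterogeneity statistics \code{Q} and
#'   \code{I2} (logged downstream; they do not gate calls).
#' @examples
#' combineEffectSizes(c(1, 3), c(1, 1))  # f_meta = 2, se = sqrt(0.5)
#' @export
combineEffectSizes <- function(g, var_g) {
    keep <- is.finite(g) & is.finite(var_g) & var_g > 0
    g <- g[keep]; var_g <- var_g[keep]
    if (!length(g)) stop("no usable effect-size records for this gene")
    w <- 1 / var_g
    f <- sum(w * g) / sum(w)
    se <- sqrt(1 / sum(w))
    z <- f / se
    Q <- sum(w * (g - f)^2)
    k <- length(g)
    I2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) else 0
    list(f_meta = f, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
         n_datasets_used = k, Q = Q, I2 = I2)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (via \code{stats::p.adjust}), with input
#' validation: any p outside [0, 1] is an error rather than an NA.
#'
#' @param p numeric vector of p-values.
#' @return q-values in the input order.
#' @export
bhFdr <- function(p) {
    if (any(!is.finite(p) | p < 0 | p > 1))
        stop("p-values must all lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
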