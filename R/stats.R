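## Nonparametric comparison battery for per-run summaries: Kruskal-Wallis
## omnibus, Conover-Iman post hoc with Holm correction, Mann-Whitney U.

checkGroups <- function(groups, min = 2L) {
    if (!is.list(groups) || length(groups) < min)
        stop("need at least ", min, " groups")
    if (any(vapply(groups, length, 0L) == 0L))
        stop("every group must be non-empty")
    invisible(groups)
}

#' Kruskal-Wallis rank-sum omnibus test
#'
#' Tie-corrected H statistic with the chi-squared approximation on k - 1
#' degrees of freedom.
#'
#' @param groups named list of at least two non-empty numeric vectors.
#' @return list with `statistic` (H), `df` and `p.value`.
#' @examples
#' kruskalWallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$statistic  # 3.857
#' @export
kruskalWallis <- function(groups) {
    checkGroups(groups)
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
    kt <- stats::kruskal.test(values, g)
    list(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p.value = kt$p.value)
}

#' Conover-Iman post hoc test on ranks
#'
#' All-pairs comparisons following a Kruskal-Wallis omnibus: t statistics
#' on the pooled ranks with the tie-corrected pooled variance, referred to
#' the t distribution on N - k degrees of freedom. Raw (unadjusted)
#' two-sided p-values; pair with [holmAdjust()] for the family correction.
#'
#' @param groups named list of at least two non-empty numeric vectors.
#' @return list with symmetric matrices `statistic` (diagonal 0) and
#'   `p.value` (diagonal 1), dimnames taken from group names.
#' @export
conoverPosthoc <- function(groups) {
    checkGroups(groups)
    k <- length(groups)
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
    n <- vapply(groups, length, 0L)
    N <- sum(n)
    values <- unlist(groups, use.names = FALSE)
    r <- rank(values)
    g <- rep(seq_len(k), n)
    meanRank <- tapply(r, g, mean)
    H <- kruskalWallis(groups)$statistic
    S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
    scale2 <- S2 * (N - 1 - H) / (N - k)
    scale2 <- max(scale2, .Machine$double.eps)
    stat <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
    pv <- matrix(1, k, k, dimnames = dimnames(stat))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        se <- sqrt(scale2 * (1 / n[i] + 1 / n[j]))
        t <- (meanRank[i] - meanRank[j]) / se
        p <- 2 * stats::pt(-abs(t), df = N - k)
        stat[i, j] <- t
        stat[j, i] <- -t
        pv[i, j] <- pv[j, i] <- min(p, 1)
    }
    list(statistic = stat, p.value = pv, df = N - k)
}

#' Holm step-down p-value adjustment
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order: the i-th smallest raw p is
#'   multiplied by (m - i + 1), the running maximum is enforced, and values
#'   are capped at 1. Always `>=` the raw values.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmAdjust <- function(pvals) {
    if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvals, method = "holm")
}

#' Mann-Whitney U test
#'
#' Two-sided; reports `U = min(U_a, U_b)`. The p-value comes from exact
#' enumeration of all group assignments when both samples have at most 8
#' observations (ties handled by mid-ranks within each permutation), and
#' from the normal approximation with tie correction and continuity
#' correction otherwise.
#'
#' @param a,b non-empty numeric samples.
#' @return list with `U` and `p.value`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))$U  # 0
#' @export
mannWhitney <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    na <- length(a); nb <- length(b)
    pooled <- c(a, b)
    r <- rank(pooled)
    Ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    U <- min(Ua, na * nb - Ua)
    if (na <= 8 && nb <= 8) {
        combos <- utils::combn(na + nb, na)
        ucount <- 0L
        for (c_ in seq_len(ncol(combos))) {
            ra <- sum(r[combos[, c_]]) - na * (na + 1) / 2
            if (min(ra, na * nb - ra) <= U + 1e-9) ucount <- ucount + 1L
        }
        p <- ucount / ncol(combos)
    } else {
        N <- na + nb
        ties <- table(pooled)
        sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) /
                                  (N * (N - 1)))
        z <- (U - na * nb / 2 + 0.5) / sqrt(sigma2)
        p <- min(1, 2 * stats::pnorm(z))
    }
    list(U = U, p.value = p)
}

#' Statistical comparison report
#'
#' The omnibus result plus the pairwise table (raw and Holm-adjusted
#' p-values and the rank direction of each pair) for one metric.
#'
#' @slot metric metric name the groups carry (e.g. `"min_val_loss"`).
#' @slot omnibusStatistic Kruskal-Wallis H (or Mann-Whitney U for two
#'   groups).
#' @slot omnibusP omnibus p-value.
#' @slot omnibusTest `"kruskal-wallis"` or `"mann-whitney"`.
#' @slot pairwise data.frame: group1, group2, statistic, p, p_adj, smaller
#'   (which group has the smaller mean rank; empty for two-group reports).
#' @export
setClass("StatReport", slots = c(metric = "character",
                                 omnibusStatistic = "numeric",
                                 omnibusP = "numeric",
                                 omnibusTest = "character",
                                 pairwise = "data.frame"))

setValidity("StatReport", function(object) {
    msg <- character()
    p <- c(object@omnibusP, object@pairwise$p, object@pairwise$p_adj)
    if (any(p < 0 | p > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
    if (nrow(object@pairwise) &&
        any(object@pairwise$p_adj < object@pairwise$p - 1e-12))
        msg <- c(msg, "adjusted p must be >= raw p")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StatReport", function(object) {
    cat(sprintf("StatReport [%s]: %s statistic %.4f, p = %.4g\n",
                object@metric, object@omnibusTest,
                object@omnibusStatistic, object@omnibusP))
    if (nrow(object@pairwise)) print(object@pairwise, row.names = FALSE)
})

#' Compare groups of per-run summaries
#'
#' For three or more groups: Kruskal-Wallis omnibus plus Conover post hoc
#' with Holm correction across all pairs (the correction family is the full
#' set of pairwise comparisons for the one metric). For exactly two
#' groups: Mann-Whitney U.
#'
#' @param groups named list of numeric vectors (e.g. per-variant minimum
#'   validation losses).
#' @param metric label for the report.
#' @return A [StatReport-class].
#' @export
compareGroups <- function(groups, metric = "metric") {
    checkGroups(groups)
    if (is.null(names(groups)))
        names(groups) <- paste0("g", seq_along(groups))
    meanRank <- tapply(rank(unlist(groups, use.names = FALSE)),
                       rep(seq_along(groups),
                           vapply(groups, length, 0L)), mean)
    if (length(groups) == 2L) {
        mw <- mannWhitney(groups[[1]], groups[[2]])
        pw <- data.frame(group1 = names(groups)[1],
                         group2 = names(groups)[2],
                         statistic = mw$U, p = mw$p.value,
                         p_adj = mw$p.value,
                         smaller = names(groups)[which.min(meanRank)])
        return(new("StatReport", metric = metric,
                   omnibusStatistic = mw$U, omnibusP = mw$p.value,
                   omnibusTest = "mann-whitney", pairwise = pw))
    }
    kw <- kruskalWallis(groups)
    co <- conoverPosthoc(groups)
    pairs <- utils::combn(names(groups), 2)
    pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ])
    pw$statistic <- mapply(function(i, j) co$statistic[i, j],
                           pw$group1, pw$group2)
    pw$p <- mapply(function(i, j) co$p.value[i, j], pw$group1, pw$group2)
    pw$p_adj <- holmAdjust(pw$p)
    pw$smaller <- mapply(function(i, j)
        if (meanRank[match(i, names(groups))] <=
            meanRank[match(j, names(groups))]) i else j,
        pw$group1, pw$group2)
    new("StatReport", metric = metric, omnibusStatistic = kw$statistic,
        omnibusP = kw$p.value, omnibusTest = "kruskal-wallis",
        pairwise = pw)
}

#' Statistical battery for a condition result
#'
#' Applies [compareGroups()] separately to the two per-run summary
#' metrics — minimum validation loss and epochs to reach it — across the
#' condition's trained variants.
#'
#' @param result a [ConditionResult-class].
#' @return Named list of two [StatReport-class] objects
#'   (`min_val_loss`, `epoch_of_min`).
#' @export
conditionStats <- function(result) {
    s <- result@summary
    grp <- function(col) split(s[[col]], s$variant)
    list(min_val_loss = compareGroups(grp("min_val_loss"), "min_val_loss"),
         epoch_of_min = compareGroups(grp("epoch_of_min"), "epoch_of_min"))
}
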