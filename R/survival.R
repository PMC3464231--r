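# Survival machinery built from first principles: product-limit (KM)
# estimation, the two-group log-rank test, Mantel-Haenszel and
# one-covariate Cox hazard ratios, and ROC/Youden cutoff selection.
# Convention throughout: at a tied time, events precede censorings, so
# individuals censored at an event time still count as at risk there.

#' Kaplan-Meier product-limit curve
#'
#' @param time positive follow-up times.
#' @param event logical/0-1 event indicator (FALSE = censored).
#' @return a [KMCurve-class] over the distinct observed times.
#' @examples
#' survProb(kmCurve(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
#' @export
kmCurve <- function(time, event) {
    stopifnot(length(time) == length(event))
    if (!length(time)) stop("empty group")
    if (any(!is.finite(time)) || any(time <= 0))
        stop("times must be finite and > 0")
    event <- as.logical(event)
    tt <- sort(unique(time))
    nRisk <- vapply(tt, function(t) sum(time >= t), 0L)
    nEvent <- vapply(tt, function(t) sum(event & time == t), 0L)
    nCensor <- vapply(tt, function(t) sum(!event & time == t), 0L)
    surv <- cumprod(1 - nEvent / nRisk)
    new("KMCurve", time = tt, nRisk = nRisk, nEvent = nEvent,
        nCensor = nCensor, surv = surv)
}

# Shared O/E/V tabulation over distinct event times for two groups.
# Returns per-time at-risk and event counts plus the group-1 (first factor
# level) expectation and hypergeometric variance contributions.
logrankTable <- function(time, event, group) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2) stop("need exactly two non-empty groups")
    event <- as.logical(event)
    if (!any(event)) stop("no events in the data")
    g1 <- group == levels(group)[1]
    et <- sort(unique(time[event]))
    n1 <- vapply(et, function(t) sum(g1 & time >= t), 0L)
    nTot <- vapply(et, function(t) sum(time >= t), 0L)
    d1 <- vapply(et, function(t) sum(g1 & event & time == t), 0L)
    dTot <- vapply(et, function(t) sum(event & time == t), 0L)
    e1 <- dTot * n1 / nTot
    v1 <- ifelse(nTot > 1,
                 dTot * (n1 / nTot) * (1 - n1 / nTot) * (nTot - dTot) /
                     (nTot - 1), 0)
    list(levels = levels(group), time = et, n1 = n1, nTot = nTot, d1 = d1,
         dTot = dTot, e1 = e1, v1 = v1)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' At each distinct event time the group-1 event count is compared with its
#' hypergeometric expectation given the margins; the 1-df chi-square is
#' \eqn{(O_1 - E_1)^2 / V}.
#'
#' @param time,event per-sample follow-up and event indicator.
#' @param group two-level factor.
#' @return a [LogrankResult-class].
#' @export
logrankTest <- function(time, event, group) {
    lt <- logrankTable(time, event, group)
    o1 <- sum(lt$d1); e1 <- sum(lt$e1); v <- sum(lt$v1)
    oTot <- sum(lt$dTot)
    if (v <= 0) stop("zero log-rank variance: no informative event times")
    chisq <- (o1 - e1)^2 / v
    new("LogrankResult",
        observed = setNames(c(o1, oTot - o1), lt$levels),
        expected = setNames(c(e1, oTot - e1), lt$levels),
        variance = v, chisq = chisq,
        p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Two-group hazard ratio with 95\% confidence interval
#'
#' Default is the Mantel-Haenszel (log-rank O/E) estimator,
#' \eqn{\ln HR = (O_1 - E_1)/V}, \eqn{SE = 1/\sqrt{V}}, consistent with the
#' log-rank test; \code{method = "cox"} fits the one-covariate Cox partial
#' likelihood by Newton iteration (Breslow tie handling) as a cross-check.
#' The ratio is for the first factor level relative to the second. If one
#' group has no events the estimate is a bound and a warning is raised.
#'
#' @inheritParams logrankTest
#' @param method \code{"mantelhaenszel"} or \code{"cox"}.
#' @param conf confidence level, default 0.95.
#' @return a [HazardRatioResult-class].
#' @export
hazardRatio <- function(time, event, group,
                        method = c("mantelhaenszel", "cox"), conf = 0.95) {
    method <- match.arg(method)
    lt <- logrankTable(time, event, group)
    o1 <- sum(lt$d1); e1 <- sum(lt$e1); v <- sum(lt$v1)
    if (v <= 0) stop("zero variance: hazard ratio undefined")
    if (o1 == 0 || o1 == sum(lt$dTot))
        warning("a group has no events; hazard ratio is a boundary estimate")
    if (method == "mantelhaenszel") {
        logHr <- (o1 - e1) / v
        se <- 1 / sqrt(v)
    } else {
        fit <- coxNewton(time, event, group)
        logHr <- fit$beta
        se <- fit$se
    }
    z <- qnorm(1 - (1 - conf) / 2)
    new("HazardRatioResult", hr = exp(logHr), ciLow = exp(logHr - z * se),
        ciHigh = exp(logHr + z * se), method = method, logHr = logHr,
        se = se)
}

# One-covariate Cox partial likelihood (x = 1 for the first group level),
# Breslow ties, Newton-Raphson from beta = 0.
coxNewton <- function(time, event, group, tol = 1e-9, maxIter = 30) {
    group <- droplevels(as.factor(group))
    x <- as.numeric(group == levels(group)[1])
    event <- as.logical(event)
    et <- sort(unique(time[event]))
    atRisk <- lapply(et, function(t) which(time >= t))
    dAt <- lapply(et, function(t) which(event & time == t))
    beta <- 0
    for (iter in seq_len(maxIter)) {
        U <- 0; I <- 0
        for (j in seq_along(et)) {
            r <- atRisk[[j]]
            w <- exp(beta * x[r])
            s0 <- sum(w); s1 <- sum(w * x[r])
            p <- s1 / s0
            d <- length(dAt[[j]])
            U <- U + sum(x[dAt[[j]]]) - d * p
            I <- I + d * p * (1 - p)
        }
        if (I <= 0) break
        step <- U / I
        beta <- beta + step
        if (abs(step) < tol) break
    }
    list(beta = beta, se = if (I > 0) 1 / sqrt(I) else Inf, iter = iter)
}

#' ROC-optimal dichotomization cutoff (Youden's J)
#'
#' Scans every midpoint between adjacent distinct marker values; "positive"
#' means marker value below the cutoff (a low marker predicts the event).
#' The cutoff maximizing J = sensitivity + specificity - 1 is returned;
#' ties break toward higher sensitivity, then toward the lower cutoff.
#'
#' @param values marker values.
#' @param labels event labels (logical/0-1); both classes must be present.
#' @return a [CutoffResult-class].
#' @export
rocOptimalCutoff <- function(values, labels) {
    labels <- as.logical(labels)
    stopifnot(length(values) == length(labels))
    if (!any(labels) || all(labels))
        stop("both outcome classes must be present")
    u <- sort(unique(values))
    if (length(u) < 2) stop("constant marker: no candidate cutoffs")
    cand <- (u[-1] + u[-length(u)]) / 2
    sens <- vapply(cand, function(c) mean(values[labels] < c), 0)
    spec <- vapply(cand, function(c) mean(values[!labels] >= c), 0)
    J <- sens + spec - 1
    best <- which(J >= max(J) - 1e-12)
    best <- best[order(-sens[best], cand[best])][1]
    new("CutoffResult", cutoff = cand[best], sensitivity = sens[best],
        specificity = spec[best], youdenJ = J[best])
}

#' Stratify a cohort by a marker and compare survival end-to-end
#'
#' Chooses a cutoff (ROC/Youden on the event label, the within-dataset
#' median, or an explicit value), splits samples into low/high marker
#' groups (at-or-below the cutoff = low), and runs KM estimation, the
#' log-rank test and hazard-ratio estimation. The marker may be a gene
#' symbol or a precomputed per-sample numeric (e.g. [scores()] of a
#' [ScoreResult-class]).
#'
#' @param cohort an [ExpressionCohort-class] with clinical annotation.
#' @param marker gene symbol, or named numeric vector of marker values.
#' @param cutoffPolicy \code{"median"}, \code{"roc"} or \code{"explicit"}.
#' @param cutoff required when \code{cutoffPolicy = "explicit"}.
#' @param hrMethod passed to [hazardRatio()].
#' @return list: \code{cutoffResult} (ROC policy only), \code{cutoff},
#'   \code{groups}, \code{curves} (KM per group), \code{logrank},
#'   \code{hazardRatio}.
#' @export
stratifyAndCompare <- function(cohort, marker = "ING4",
                               cutoffPolicy = c("median", "roc", "explicit"),
                               cutoff = NULL,
                               hrMethod = c("mantelhaenszel", "cox")) {
    cutoffPolicy <- match.arg(cutoffPolicy)
    cl <- clinicalData(cohort)
    if (!nrow(cl)) stop("cohort has no clinical annotation")
    v <- if (is.character(marker) && length(marker) == 1)
        markerValues(cohort, marker) else marker
    if (is.null(names(v))) stop("marker values must be named by sample")
    v <- v[cl$sample]
    if (anyNA(v)) stop("marker value missing for some clinical samples")
    cutoffResult <- NULL
    cut <- switch(cutoffPolicy,
        median = median(v),
        roc = {
            cutoffResult <- rocOptimalCutoff(v, cl$event)
            cutoff(cutoffResult)
        },
        explicit = {
            if (is.null(cutoff)) stop("explicit policy needs a cutoff")
            cutoff
        })
    groups <- factor(ifelse(v <= cut, "low", "high"),
                     levels = c("low", "high"))
    names(groups) <- names(v)
    if (any(table(groups) == 0)) stop("cutoff leaves an empty group")
    curves <- lapply(split(seq_along(v), groups), function(i)
        kmCurve(cl$time[i], cl$event[i]))
    list(cutoffResult = cutoffResult, cutoff = cut, groups = groups,
         curves = curves,
         logrank = logrankTest(cl$time, cl$event, groups),
         hazardRatio = hazardRatio(cl$time, cl$event, groups,
                                   method = match.arg(hrMethod)))
}
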