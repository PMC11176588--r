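#' Read a survival table
#'
#' @param path TSV with columns sample, time, event (1 = death observed,
#'   0 = censored).
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
readSurvival <- function(path) {
    s <- read.delim(path, stringsAsFactors = FALSE)
    names(s)[1:3] <- c("sample", "time", "event")
    validateSurvival(s)
    s
}

validateSurvival <- function(s) {
    if (any(s$time <= 0)) stopf("survival times must be positive")
    if (!all(s$event %in% c(0, 1))) stopf("event must be 0 or 1")
    invisible(s)
}

#' Per-sample risk score
#'
#' The coefficient-weighted sum of expression over the cluster genes,
#' `sum_i Exp_i * beta_i`.
#'
#' @param expr numeric matrix, genes in rows, samples in columns.
#' @param beta named numeric coefficients; names must match `rownames(expr)`
#'   as a set.
#' @return Named numeric vector of per-sample scores.
#' @export
riskScore <- function(expr, beta) {
    if (is.null(names(beta))) {
        if (length(beta) != nrow(expr)) stopf("beta length does not match genes")
        names(beta) <- rownames(expr)
    }
    if (!setequal(names(beta), rownames(expr)))
        stopf("beta genes do not match expression genes")
    colSums(expr[names(beta), , drop = FALSE] * beta)
}

#' Median split of risk scores into high/low groups
#'
#' Scores strictly above the median are `"high"`; scores at or below the
#' median are `"low"` (ties, including the median sample at odd n, go to the
#' low-risk group).
#'
#' @param scores named numeric vector (>= 4 samples).
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
medianSplit <- function(scores) {
    if (length(scores) < 4) stopf("median split needs >= 4 samples")
    if (length(unique(scores)) == 1)
        stopf("all risk scores identical; no split possible")
    med <- median(scores)
    stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param surv data.frame with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival` (the step function value at
#'   that time; censored times reduce the risk set without a step).
#' @examples
#' kmEstimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
#' @export
kmEstimate <- function(surv) {
    validateSurvival(data.frame(sample = seq_len(nrow(surv)),
                                time = surv$time, event = surv$event))
    times <- sort(unique(surv$time))
    s <- 1
    out <- data.frame(time = times, n_risk = NA_real_, n_event = NA_real_,
                      n_censor = NA_real_, survival = NA_real_)
    for (i in seq_along(times)) {
        t <- times[i]
        atRisk <- sum(surv$time >= t)
        d <- sum(surv$time == t & surv$event == 1)
        c <- sum(surv$time == t & surv$event == 0)
        if (d > 0) s <- s * (1 - d / atRisk)
        out$n_risk[i] <- atRisk
        out$n_event[i] <- d
        out$n_censor[i] <- c
        out$survival[i] <- s
    }
    out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic on one degree of freedom: at every distinct
#' event time, the observed events in group A are compared with their
#' hypergeometric expectation given the pooled risk sets.
#'
#' @param groupA,groupB data.frames with columns `time` and `event`.
#' @return list with `chi2` and two-sided `p`.
#' @export
logrankTest <- function(groupA, groupB) {
    if (!nrow(groupA) || !nrow(groupB)) stopf("both groups must be non-empty")
    if (sum(groupA$event) + sum(groupB$event) == 0)
        stopf("no events observed; log-rank undefined")
    eventTimes <- sort(unique(c(groupA$time[groupA$event == 1],
                                groupB$time[groupB$event == 1])))
    O <- E <- V <- 0
    for (t in eventTimes) {
        n1 <- sum(groupA$time >= t)
        n2 <- sum(groupB$time >= t)
        n <- n1 + n2
        d1 <- sum(groupA$time == t & groupA$event == 1)
        d2 <- sum(groupB$time == t & groupB$event == 1)
        d <- d1 + d2
        if (n1 == 0 || n2 == 0) next
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    if (V == 0) return(list(chi2 = 0, p = 1))
    chi2 <- (O - E)^2 / V
    list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Evaluate the prognostic value of a gene cluster
#'
#' Fits a multivariate Cox proportional-hazards model on the cluster genes
#' (delegated to [survival::coxph()]) unless fixed coefficients are supplied,
#' computes per-sample risk scores, splits the cohort at the median score,
#' estimates a Kaplan-Meier curve per risk group and compares the groups with
#' the log-rank test.
#'
#' @param expr numeric matrix of expression, genes in rows, samples in
#'   columns.
#' @param surv data.frame with columns `sample`, `time`, `event`; samples
#'   must cover the expression columns.
#' @param genes cluster genes (default all rows of `expr`).
#' @param beta optional named fixed coefficients; when supplied the Cox fit
#'   is skipped and the pipeline is fully deterministic.
#' @return list with `model` (a [RiskModel-class]), `km` (list of
#'   Kaplan-Meier tables for `high` and `low`), and `logrank` (list with
#'   `chi2`, `p`).
#' @export
evaluateCluster <- function(expr, surv, genes = rownames(expr), beta = NULL) {
    if (!all(genes %in% rownames(expr)))
        stopf("cluster genes missing from expression: %s",
              paste(setdiff(genes, rownames(expr)), collapse = ", "))
    validateSurvival(surv)
    if (!all(colnames(expr) %in% surv$sample))
        stopf("survival table does not cover all expression samples")
    surv <- surv[match(colnames(expr), surv$sample), ]
    x <- t(expr[genes, , drop = FALSE])
    if (is.null(beta)) {
        fit <- tryCatch(
            survival::coxph(survival::Surv(surv$time, surv$event) ~ x),
            warning = function(w) {
                if (grepl("converge|infinite", conditionMessage(w)))
                    stopf("Cox model did not converge: %s", conditionMessage(w))
                suppressWarnings(
                    survival::coxph(survival::Surv(surv$time, surv$event) ~ x))
            })
        beta <- stats::setNames(unname(stats::coef(fit)), genes)
        if (any(!is.finite(beta)))
            stopf("Cox model produced non-finite coefficients")
    } else {
        if (is.null(names(beta))) names(beta) <- genes
        if (!setequal(names(beta), genes)) stopf("beta names do not match genes")
    }
    scores <- riskScore(expr[genes, , drop = FALSE], beta)
    groups <- medianSplit(scores)
    model <- methods::new("RiskModel", genes = genes, beta = beta,
                          scores = scores, threshold = median(scores),
                          groups = groups)
    high <- surv[groups == "high", ]
    low <- surv[groups == "low", ]
    list(model = model,
         km = list(high = kmEstimate(high), low = kmEstimate(low)),
         logrank = logrankTest(high, low))
}
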