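test_that("riskScore is the coefficient-weighted expression sum", {
    expr <- rbind(g1 = c(1, 2), g2 = c(2, 0))
    colnames(expr) <- c("s1", "s2")
    expect_equal(riskScore(expr, c(g1 = 0, g2 = 0)), c(s1 = 0, s2 = 0))
    expect_equal(riskScore(expr, c(g1 = 0.5, g2 = 1))[["s1"]], 2.5)
    # permuting genes with the matching beta permutation leaves scores unchanged
    expect_equal(riskScore(expr[2:1, ], c(g2 = 1, g1 = 0.5)),
                 riskScore(expr, c(g1 = 0.5, g2 = 1)))
    # linearity
    expect_equal(riskScore(3 * expr, c(g1 = 0.5, g2 = 1)),
                 3 * riskScore(expr, c(g1 = 0.5, g2 = 1)))
    expect_error(riskScore(expr, c(gX = 1, g2 = 1)), "match")
})

test_that("medianSplit assigns ties and the median sample to low risk", {
    s <- c(a = 1, b = 2, c = 3, d = 4)
    expect_equal(medianSplit(s), c(a = "low", b = "low", c = "high", d = "high"))
    s5 <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
    expect_equal(unname(medianSplit(s5)["c"]), "low")
    expect_error(medianSplit(rep(1, 5)), "identical")
    expect_error(medianSplit(c(1, 2, 3)), ">= 4")
})

test_that("kmEstimate reproduces hand and survfit computations", {
    # no events: flat survival
    km0 <- kmEstimate(data.frame(time = c(1, 2, 3), event = 0))
    expect_true(all(km0$survival == 1))

    # all events at 1, 2, 3: S = 2/3, 1/3, 0
    km1 <- kmEstimate(data.frame(time = c(1, 2, 3), event = 1))
    expect_equal(km1$survival, c(2 / 3, 1 / 3, 0))

    # event, censor, event: S(1) = 2/3, S(3) = 0
    km2 <- kmEstimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
    expect_equal(km2$survival, c(2 / 3, 2 / 3, 0))

    # survfit oracle on a random cohort, compared at event times
    set.seed(9)
    surv <- data.frame(time = round(rexp(40, 0.2), 3),
                       event = rbinom(40, 1, 0.7))
    km <- kmEstimate(surv)
    sf <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
    at <- km$time[km$n_event > 0]
    expect_equal(km$survival[km$time %in% at],
                 sf$surv[match(at, sf$time)], tolerance = 1e-12)

    # invariants: S starts at 1 before the first event, non-increasing, in [0,1]
    expect_true(all(diff(km$survival) <= 1e-15))
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    firstEvent <- min(km$time[km$n_event > 0])
    expect_true(all(km$survival[km$time < firstEvent] == 1))
})

test_that("logrankTest matches survdiff and its symmetries", {
    a <- data.frame(time = c(2, 4, 6, 8, 10, 12), event = c(1, 1, 0, 1, 1, 0))
    b <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 0, 1, 1))
    lr <- logrankTest(a, b)
    sd <- survival::survdiff(
        survival::Surv(c(a$time, b$time), c(a$event, b$event)) ~
            rep(c("a", "b"), each = 6))
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-8)
    expect_equal(lr$p, 1 - pchisq(sd$chisq, 1), tolerance = 1e-8)

    # identical groups: chi2 = 0, p = 1
    same <- logrankTest(a, a)
    expect_equal(same$chi2, 0)
    expect_equal(same$p, 1)

    # label swap leaves the statistic unchanged
    swapped <- logrankTest(b, a)
    expect_equal(swapped$chi2, lr$chi2, tolerance = 1e-12)
    expect_true(lr$chi2 >= 0)
    expect_true(lr$p > 0 && lr$p <= 1)

    expect_error(logrankTest(a[0, ], b), "non-empty")
    expect_error(logrankTest(data.frame(time = 1:4, event = 0),
                             data.frame(time = 1:4, event = 0)), "no events")
})

test_that("evaluateCluster runs the full risk-stratification pipeline", {
    set.seed(12)
    n <- 60
    expr <- matrix(rnorm(2 * n), 2, n,
                   dimnames = list(c("g1", "g2"), sprintf("P%02d", 1:n)))
    haz <- 0.1 * exp(1.2 * expr["g1", ])
    tEvent <- rexp(n, haz)
    tCens <- runif(n, 0, 25)
    surv <- data.frame(sample = colnames(expr), time = pmin(tEvent, tCens),
                       event = as.integer(tEvent <= tCens))

    res <- evaluateCluster(expr, surv)
    expect_s4_class(res$model, "RiskModel")
    expect_equal(sort(unique(riskGroups(res$model))), c("high", "low"))
    expect_equal(abs(sum(riskGroups(res$model) == "high") -
                     sum(riskGroups(res$model) == "low")) <= 1, TRUE)
    expect_true(res$logrank$p < 0.05)  # strong planted hazard signal
    expect_named(res$km, c("high", "low"))

    # fixed user beta skips fitting and is fully deterministic
    res2 <- evaluateCluster(expr, surv, genes = "g1", beta = c(g1 = 1))
    res3 <- evaluateCluster(expr, surv, genes = "g1", beta = c(g1 = 1))
    expect_identical(res2, res3)
    expect_equal(unname(res2$model@beta), 1)

    expect_error(evaluateCluster(expr, surv, genes = c("g1", "gX")), "missing")
    expect_error(evaluateCluster(expr, surv[1:10, ]), "cover")
})
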