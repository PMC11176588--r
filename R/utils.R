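# Internal helpers shared across modules.

# Canonical unordered pair key "a|b" with a < b.
pairKey <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Order the two gene columns of an edge data.frame canonically (gene_a < gene_b).
canonicalizePairs <- function(df, colA = 1L, colB = 2L) {
    a <- as.character(df[[colA]])
    b <- as.character(df[[colB]])
    swap <- a > b
    if (any(swap)) {
        tmp <- a[swap]
        a[swap] <- b[swap]
        b[swap] <- tmp
    }
    df[[colA]] <- a
    df[[colB]] <- b
    df
}

# Vectorised two-sided Welch t-test on the rows of two matrices.
# Degenerate rows (both group variances zero) get t = 0, p = 1 when the means
# agree and p = 0 when they differ.
welchRows <- function(x, y) {
    nx <- ncol(x)
    ny <- ncol(y)
    mx <- rowMeans(x)
    my <- rowMeans(y)
    vx <- rowSums((x - mx)^2) / (nx - 1)
    vy <- rowSums((y - my)^2) / (ny - 1)
    se2 <- vx / nx + vy / ny
    t <- (mx - my) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    p <- 2 * pt(abs(t), df, lower.tail = FALSE)
    zero <- se2 == 0
    if (any(zero)) {
        same <- zero & (mx == my)
        p[same] <- 1
        t[same] <- 0
        p[zero & !same] <- 0
        t[zero & !same] <- Inf * sign(mx - my)[zero & !same]
        df[zero] <- NA_real_
    }
    list(estimate = mx - my, t = t, df = df, p = p)
}

welchVec <- function(x, y) {
    r <- welchRows(matrix(x, nrow = 1), matrix(y, nrow = 1))
    lapply(r, `[`, 1L)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
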