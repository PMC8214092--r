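test_that("Kruskal-Wallis matches the hand rank-sum computation", {
    ## ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
    g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
    kw <- kruskalWallis(g)
    expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
                 tolerance = 1e-12)
    expect_equal(round(kw$statistic, 3), 3.857)
    expect_equal(kw$df, 1)

    ## interleaved groups with the same sizes have a smaller H
    kwInter <- kruskalWallis(list(a = c(1, 3, 5), b = c(2, 4, 6)))
    expect_lt(kwInter$statistic, kw$statistic)

    ## permuting group order leaves H unchanged
    expect_equal(kruskalWallis(rev(g))$statistic, kw$statistic)

    expect_error(kruskalWallis(list(a = 1:3)), "at least 2")
    expect_error(kruskalWallis(list(a = 1:3, b = numeric())), "non-empty")
})

test_that("Conover post hoc separates well-separated groups symmetrically", {
    g <- list(lo = c(1, 2, 3), mid = c(101, 102, 103),
              hi = c(201, 202, 203))
    co <- conoverPosthoc(g)
    expect_true(all(co$p.value[upper.tri(co$p.value)] < 0.05))
    expect_equal(co$p.value, t(co$p.value))
    expect_equal(co$statistic, -t(co$statistic))
    expect_equal(co$df, 6)  # N - k = 9 - 3

    ## duplicated group compares to itself with statistic 0, p = 1
    dup <- conoverPosthoc(list(a = c(1, 5, 9), b = c(1, 5, 9),
                               c = c(2, 6, 10)))
    expect_equal(dup$statistic["a", "b"], 0)
    expect_equal(dup$p.value["a", "b"], 1)
})

test_that("Holm adjustment reproduces the hand step-down computation", {
    ## sorted (0.01, 0.03, 0.04) * (3, 2, 1) -> (0.03, 0.06, 0.04),
    ## running max -> (0.03, 0.06, 0.06), reordered
    expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
    expect_equal(holmAdjust(0.2), 0.2)
    expect_equal(holmAdjust(rep(1, 4)), rep(1, 4))
    expect_error(holmAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

    ## adjusted >= raw, and the smallest raw p is multiplied by m pre-cap
    p <- c(0.001, 0.2, 0.04, 0.9, 0.5, 0.012)
    adj <- holmAdjust(p)
    expect_true(all(adj >= p))
    expect_equal(adj[which.min(p)], min(p) * length(p))
})

test_that("Mann-Whitney U and exact enumeration behave as expected", {
    ## fully separated samples: no a exceeds any b
    mw <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(mw$U, 0)
    expect_equal(mw$p.value, 2 / 20)  # 2 of the C(6,3)=20 assignments

    ## identical samples: U = n^2 / 2 by tie symmetry
    x <- c(2, 4, 6, 8)
    expect_equal(mannWhitney(x, x)$U, length(x)^2 / 2)

    ## symmetric in the argument order
    a <- c(3, 1, 4, 1, 5); b <- c(9, 2, 6, 5)
    expect_equal(mannWhitney(a, b)$U, mannWhitney(b, a)$U)
    expect_equal(mannWhitney(a, b)$p.value, mannWhitney(b, a)$p.value)

    expect_error(mannWhitney(numeric(), 1:3), "non-empty")
})

test_that("large-sample Mann-Whitney agrees with the normal approximation", {
    set.seed(42)
    a <- rnorm(30); b <- rnorm(25, mean = 1)
    mw <- mannWhitney(a, b)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    expect_equal(mw$U, min(wt$statistic, 30 * 25 - wt$statistic),
                 ignore_attr = TRUE)
    expect_equal(mw$p.value, wt$p.value, tolerance = 1e-10)
})

test_that("two-group Kruskal-Wallis is rank-equivalent to Mann-Whitney", {
    ## both statistics must induce the same ordering across datasets
    set.seed(11)
    hs <- us <- numeric(20)
    for (i in 1:20) {
        a <- rnorm(6); b <- rnorm(6, mean = i / 10)
        hs[i] <- kruskalWallis(list(a, b))$statistic
        us[i] <- abs(mannWhitney(a, b)$U - 18)  # distance from null mean
    }
    expect_equal(order(hs), order(us))
})

test_that("compareGroups builds a coherent report for 4 and 2 groups", {
    set.seed(5)
    g4 <- list(base = rnorm(10, 1), exp = rnorm(10, 0),
               expanded = rnorm(10, 1.1), const = rnorm(10, 0.9))
    rep4 <- compareGroups(g4, metric = "min_val_loss")
    expect_s4_class(rep4, "StatReport")
    expect_equal(rep4@omnibusTest, "kruskal-wallis")
    expect_equal(nrow(rep4@pairwise), 6)
    expect_true(all(rep4@pairwise$p_adj >= rep4@pairwise$p))
    expect_true(all(rep4@pairwise$smaller %in% names(g4)))

    rep2 <- compareGroups(g4[1:2], metric = "epoch_of_min")
    expect_equal(rep2@omnibusTest, "mann-whitney")
    expect_equal(nrow(rep2@pairwise), 1)
})

test_that("omnibus test holds its nominal type-I error under the null", {
    set.seed(2024)
    nSim <- 2000
    rejections <- 0L
    for (i in seq_len(nSim)) {
        g <- split(rnorm(40), rep(1:4, each = 10))
        if (kruskalWallis(g)$p.value < 0.05) rejections <- rejections + 1L
    }
    rate <- rejections / nSim
    se <- sqrt(0.05 * 0.95 / nSim)
    expect_lt(abs(rate - 0.05), 3 * se)
})
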