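test_that("uniqueness score follows its closed form and bounds", {
    expect_equal(uniquenessScore(4, 4), 0.0)
    expect_equal(uniquenessScore(1, 4), 0.5)
    expect_equal(uniquenessScore(2, 8), 0.5)
    ## strictly decreasing in L_i for fixed L_n
    u <- uniquenessScore(1:10, 10)
    expect_true(all(diff(u) < 0))
    expect_true(all(u >= 0 & u < 1))
    expect_error(uniquenessScore(5, 4), "value error")
    expect_error(uniquenessScore(0, 4), "value error")
})

test_that("marker weight follows its closed form and floors pct_bg", {
    expect_equal(markerWeight(1.0, 1.0, 1.0), 1.0)
    expect_equal(markerWeight(0.5, 0.8, 0.2), 1.6)
    expect_equal(markerWeight(2.0, 0.5, 0.0), 500.0)  # floor engages
    expect_error(markerWeight(-0.1, 0.5, 0.5), "value error")
    expect_error(markerWeight(1, 1.5, 0.5), "value error")
})

test_that("basic CSS equals brute-force Jaccard on random set pairs", {
    expect_equal(cssBasic(c("a", "b"), c("a", "b")), 1.0)
    expect_equal(cssBasic(c("a", "b"), c("c", "d")), 0.0)
    expect_equal(cssBasic(c("a", "b", "c"), c("a", "b", "d")), 0.5)
    expect_equal(cssBasic(character(0), character(0)), 0.0)
    set.seed(101)
    pool <- paste0("g", 1:30)
    for (i in 1:1000) {
        a <- sample(pool, sample(0:12, 1))
        b <- sample(pool, sample(0:12, 1))
        expect_identical(cssBasic(a, b), oracleJaccard(a, b))
    }
})

test_that("enhanced CSS matches the worked decomposition", {
    ## shared {g1,g2} (L=2), unique g3/g4 (L=1), all weights 1, L_n = 4
    a <- mkMarkers(c("g1", "g2", "g3"), "0", lfc = 1, pct1 = 1, pct2 = 1)
    b <- mkMarkers(c("g1", "g2", "g4"), "1", lfc = 1, pct1 = 1, pct2 = 1)
    ctx <- list(counts = c(g1 = 2L, g2 = 2L, g3 = 1L, g4 = 1L), total = 4L)
    got <- cssEnhanced(a, b, ctx)
    num <- 4 * (1 - sqrt(1 / 2))
    expect_equal(got, num / (num + 1), tolerance = 1e-12)
    expect_equal(got, 1.171573 / 2.171573, tolerance = 1e-6)
})

test_that("enhanced CSS handles degenerate inputs by the 0 convention", {
    a <- mkMarkers(c("g1", "g2"), "0")
    b <- mkMarkers(c("g1", "g2"), "1")
    ## identical lists, some uniqueness -> 1
    ctx <- list(counts = c(g1 = 2L, g2 = 2L), total = 4L)
    expect_equal(cssEnhanced(a, b, ctx), 1.0)
    ## every gene marks every cluster -> all uniqueness 0 -> 0/0 -> 0
    ctx0 <- list(counts = c(g1 = 4L, g2 = 4L), total = 4L)
    expect_equal(cssEnhanced(a, b, ctx0), 0.0)
    ## empty marker sets -> 0
    e <- mkMarkers(character(0))
    expect_equal(cssEnhanced(e, e, ctx), 0.0)
    ## gene missing from the context is a consistency error
    expect_error(cssEnhanced(a, b, list(counts = c(g1 = 2L), total = 4L)),
                 "consistency error")
})

test_that("enhanced CSS equals a straight-line oracle on random fixtures", {
    set.seed(202)
    for (i in 1:1000) {
        fx <- randomCssFixture()
        ctx <- list(counts = unlist(fx$L), total = fx$Ln)
        got <- cssEnhanced(fx$a, fx$b, ctx)
        expect_equal(got, oracleCssEnh(fx$a, fx$b, fx$L, fx$Ln),
                     tolerance = 1e-12)
        ## symmetry and range
        expect_equal(got, cssEnhanced(fx$b, fx$a, ctx), tolerance = 1e-12)
        expect_gte(got, 0); expect_lte(got, 1)
    }
})

test_that("with equal weights and uniqueness the score has a closed form", {
    for (C12 in 0:5) for (U1 in 0:5) for (U2 in 0:5) {
        genes <- paste0("g", seq_len(C12 + U1 + U2))
        sh <- head(genes, C12)
        ua <- genes[seq_len(U1) + C12]
        ub <- genes[seq_len(U2) + C12 + U1]
        a <- mkMarkers(c(sh, ua), "0")
        b <- mkMarkers(c(sh, ub), "1")
        ctx <- list(counts = setNames(rep(2L, length(genes)), genes),
                    total = 8L)
        want <- if (C12 + U1 + U2 == 0) 0 else
            2 * C12 / (2 * C12 + U1 + U2)
        expect_equal(cssEnhanced(a, b, ctx), want, tolerance = 1e-15)
    }
})

test_that("shared markers never decrease and unique never increase the score", {
    set.seed(303)
    for (i in 1:50) {
        fx <- randomCssFixture()
        if (!nrow(fx$a) || !nrow(fx$b)) next
        L <- fx$L; L[["gnew"]] <- 1L
        ctx0 <- list(counts = unlist(fx$L), total = fx$Ln)
        ctx <- list(counts = unlist(L), total = fx$Ln)
        base <- cssEnhanced(fx$a, fx$b, ctx0)
        add <- mkMarkers("gnew", lfc = runif(1, 0.1, 2),
                         pct1 = runif(1, 0.1, 1), pct2 = runif(1, 0, 0.8))
        both <- cssEnhanced(rbind(fx$a, add), rbind(fx$b, add), ctx)
        one <- cssEnhanced(rbind(fx$a, add), fx$b, ctx)
        expect_gte(both, base - 1e-12)
        expect_lte(one, base + 1e-12)
    }
})

test_that("CSS matrices have unit diagonal against themselves", {
    tab <- rbind(mkMarkers(c("g1", "g2"), "0"),
                 mkMarkers(c("g3", "g4"), "1"),
                 mkMarkers(c("g5"), "2"))
    css <- buildCSSMatrix(tab, tab)
    v <- cssValues(css)
    expect_equal(unname(diag(v)), rep(1, 3))
    expect_true(all(v <= 1 & v >= 0))
})

test_that("CSS matrix construction is shape-correct and equivariant", {
    a <- rbind(mkMarkers(c("g1", "g2"), "0"),
               mkMarkers(c("g3", "g4", "g5"), "1"))
    b <- rbind(mkMarkers(c("g1", "g6"), "0"),
               mkMarkers(c("g3", "g4"), "1"),
               mkMarkers(c("g7"), "2"))
    css <- buildCSSMatrix(a, b, res = 0.4, npcs = 10)
    expect_identical(dim(css), c(2L, 3L))
    expect_true(all(cssValues(css) >= 0 & cssValues(css) <= 1))
    expect_identical(cssParams(css), list(res = 0.4, npcs = 10L))

    ## permuting cluster labels of b permutes columns, values unchanged
    b2 <- b
    b2$cluster <- c("2" = "0", "0" = "1", "1" = "2")[b$cluster]
    css2 <- buildCSSMatrix(a, b2)
    expect_equal(unname(cssValues(css2)[, c("1", "2", "0")]),
                 unname(cssValues(css)), tolerance = 1e-15)

    ## unfiltered tables are rejected; empty cluster sets are errors
    bad <- mkMarkers("g1", padj = 0.5)
    expect_error(buildCSSMatrix(bad, b), "value error")
    expect_error(buildCSSMatrix(a[0, ], b[0, ]), "value error")
    ## a cluster with no retained markers yields a zero column + warning
    expect_warning(css3 <- buildCSSMatrix(a, b, clusters_b = c("0", "1", "2", "3")),
                   "no retained markers")
    expect_equal(unname(cssValues(css3)[, "3"]), c(0, 0))
})
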