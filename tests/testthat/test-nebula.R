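## Small labelled fixture: two focal clusters plus extra background cells.
nebulaFixture <- function(seed = 15, n_genes = 60, per = 40) {
    set.seed(seed)
    n <- per * 3
    counts <- matrix(rnbinom(n_genes * n, mu = 1, size = 2), n_genes, n,
                     dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                     sprintf("c%03d", seq_len(n))))
    labels <- setNames(rep(c("ILR", "NPR", "other"), each = per),
                       colnames(counts))
    ## plant blocks: A-specific, shared, B-specific
    counts[1:12, labels == "ILR"] <- counts[1:12, labels == "ILR"] + rpois(12 * per, 8)
    counts[13:24, labels == "NPR"] <- counts[13:24, labels == "NPR"] + rpois(12 * per, 8)
    counts[25:36, labels != "other"] <- counts[25:36, labels != "other"] + rpois(24 * per, 8)
    list(counts = counts, labels = labels)
}

nebulaMarkers <- function(fx) {
    mka <- filterMarkers(findClusterMarkers(fx$counts, fx$labels, "ILR"))
    mkb <- filterMarkers(findClusterMarkers(fx$counts, fx$labels, "NPR"))
    list(a = mka, b = mkb)
}

test_that("gene selection partitions by membership and ranks by weight", {
    ## disjoint marker sets -> empty shared block
    a <- mkMarkers(c("g1", "g2"), "A")
    b <- mkMarkers(c("g3", "g4"), "B")
    expect_warning(p <- selectNebulaGenes(a, b, k_specific = 2, k_shared = 2),
                   "shared")
    expect_identical(p$shared, character(0))
    expect_setequal(p$specific_a, c("g1", "g2"))

    ## identical marker sets -> empty specific blocks
    ## both specific blocks are short, so two warnings are raised
    expect_warning(expect_warning(
        p2 <- selectNebulaGenes(a, a, k_specific = 2, k_shared = 2),
        "specific"), "specific")
    expect_identical(p2$specific_a, character(0))
    expect_identical(p2$specific_b, character(0))
    expect_setequal(p2$shared, c("g1", "g2"))

    ## 30-gene fixture with known weights matches a brute-force sort
    set.seed(505)
    genes <- sprintf("w%02d", 1:30)
    ma <- mkMarkers(genes[1:20], "A", lfc = runif(20, 0.1, 2),
                    pct1 = runif(20, 0.1, 1), pct2 = runif(20, 0.01, 0.9))
    mb <- mkMarkers(genes[11:30], "B", lfc = runif(20, 0.1, 2),
                    pct1 = runif(20, 0.1, 1), pct2 = runif(20, 0.01, 0.9))
    p3 <- selectNebulaGenes(ma, mb, k_specific = 5, k_shared = 4)
    wa <- with(ma, setNames(avg_logFC * pct.1^2 / pmax(pct.2, 0.001), gene))
    wb <- with(mb, setNames(avg_logFC * pct.1^2 / pmax(pct.2, 0.001), gene))
    expect_identical(p3$specific_a,
                     names(sort(wa[genes[1:10]], decreasing = TRUE))[1:5])
    expect_identical(p3$specific_b,
                     names(sort(wb[genes[21:30]], decreasing = TRUE))[1:5])
    ms <- (wa[genes[11:20]] + wb[genes[11:20]]) / 2
    expect_identical(p3$shared, names(sort(ms, decreasing = TRUE))[1:4])
})

test_that("nebula data layer computes diamonds, fractions and ordering", {
    fx <- nebulaFixture()
    mk <- nebulaMarkers(fx)
    part <- suppressWarnings(selectNebulaGenes(mk$a, mk$b, 6, 4))
    spec <- prepareNebulaData(fx$counts, fx$labels, "ILR", "NPR", part)
    g <- nebulaGenes(spec)
    expect_identical(g$position, seq_len(nrow(g)))
    expect_true(all(g$frac_a >= 0 & g$frac_a <= 1))

    ## left block monotone non-increasing in diamond_a
    left <- g$diamond_a[g$group == "specific_a"]
    expect_true(all(diff(left) <= 1e-12))
    ## right block monotone non-decreasing in diamond_b
    right <- g$diamond_b[g$group == "specific_b"]
    expect_true(all(diff(right) >= -1e-12))
    ## center block unimodal about its maximum mean diamond
    mid <- (g$diamond_a + g$diamond_b)[g$group == "shared"] / 2
    pk <- which.max(mid)
    expect_true(all(diff(mid[seq_len(pk)]) >= -1e-12))
    expect_true(all(diff(mid[pk:length(mid)]) <= 1e-12))

    ## fractions mirror the marker-detection convention (count > 0)
    in_a <- fx$labels == "ILR"
    for (i in sample(nrow(g), 3))
        expect_equal(g$frac_a[i], mean(fx$counts[g$gene[i], in_a] > 0))

    ## a gene expressed in every focal cell has fraction 1
    fx$counts["g01", in_a] <- pmax(fx$counts["g01", in_a], 1L)
    spec2 <- prepareNebulaData(fx$counts, fx$labels, "ILR", "NPR", part)
    expect_equal(nebulaGenes(spec2)$frac_a[nebulaGenes(spec2)$gene == "g01"], 1.0)

    expect_error(prepareNebulaData(fx$counts, fx$labels, "ILR", "NPR",
                                   list(specific_a = "nope", shared = character(0),
                                        specific_b = character(0))),
                 "key error")
    expect_error(prepareNebulaData(fx$counts, fx$labels, "ILR", "zzz", part),
                 "key error")
})

test_that("center-out placement follows the worked three-gene example", {
    ## shared mean diamonds (5, 9, 2): the 9-gene sits centrally, flanked
    ## by the 5-gene and then the 2-gene
    slots <- cassidi:::.centerOutSlots(3)
    ranked <- c("g9", "g5", "g2")   # sorted by decreasing mean
    out <- character(3); out[slots] <- ranked
    expect_identical(out, c("g2", "g9", "g5"))
    ## even count alternates right-then-left around the center
    slots4 <- cassidi:::.centerOutSlots(4)
    expect_identical(slots4, c(2L, 3L, 1L, 4L))
    expect_identical(cassidi:::.centerOutSlots(1), 1L)
})

test_that("ordering rules hold on random specs", {
    for (seed in 1:5) {
        fx <- nebulaFixture(seed = 100 + seed)
        mk <- nebulaMarkers(fx)
        if (nrow(mk$a) < 2 || nrow(mk$b) < 2) next
        part <- suppressWarnings(selectNebulaGenes(mk$a, mk$b, 5, 5))
        g <- nebulaGenes(prepareNebulaData(fx$counts, fx$labels,
                                           "ILR", "NPR", part))
        expect_true(all(diff(g$diamond_a[g$group == "specific_a"]) <= 1e-12))
        expect_true(all(diff(g$diamond_b[g$group == "specific_b"]) >= -1e-12))
        mid <- (g$diamond_a + g$diamond_b)[g$group == "shared"] / 2
        if (length(mid) > 1) {
            pk <- which.max(mid)
            expect_true(all(diff(mid[seq_len(pk)]) >= -1e-12))
            expect_true(all(diff(mid[pk:length(mid)]) <= 1e-12))
        }
    }
})

test_that("rendering produces deterministic image files", {
    fx <- nebulaFixture()
    mk <- nebulaMarkers(fx)
    part <- suppressWarnings(selectNebulaGenes(mk$a, mk$b, 3, 2))
    spec <- prepareNebulaData(fx$counts, fx$labels, "ILR", "NPR", part)
    f1 <- withr::local_tempfile(fileext = ".svg")
    f2 <- withr::local_tempfile(fileext = ".svg")
    renderNebula(spec, f1)
    renderNebula(spec, f2)
    expect_gt(file.size(f1), 0)
    expect_identical(readLines(f1), readLines(f2))
    ## large spec renders without error (layout smoke test)
    part40 <- suppressWarnings(selectNebulaGenes(mk$a, mk$b, 15, 10))
    spec40 <- prepareNebulaData(fx$counts, fx$labels, "ILR", "NPR", part40)
    f3 <- withr::local_tempfile(fileext = ".png")
    renderNebula(spec40, f3, format = "png")
    expect_gt(file.size(f3), 0)
})
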