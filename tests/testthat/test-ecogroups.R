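# Ecological grouping: size factors, one-sided phase contrasts, BH
# control, category calls.

test_that("size factors follow the median-of-ratios definition", {
    a <- c(4, 10, 20, 6)
    counts <- rbind(A = a, B = 2 * a)
    colnames(counts) <- paste0("o", 1:4)
    sf <- size_factors(counts)
    expect_equal(unname(sf["B"] / sf["A"]), 2)

    single <- matrix(c(4, 9), 2, 1,
                     dimnames = list(c("A", "B"), "o1"))
    expect_equal(unname(size_factors(single)), c(4 / 6, 9 / 6))

    # invariant to OTU ordering
    set.seed(22)
    m <- matrix(rpois(40, 10) + 1, 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("o", 1:10)))
    expect_equal(size_factors(m), size_factors(m[, sample(10)]))

    disjoint <- matrix(c(5, 0, 0, 7), 2, 2,
                       dimnames = list(c("A", "B"), c("o1", "o2")))
    expect_error(size_factors(disjoint), "pseudocount",
                 class = "micasm_invalid_argument")
    expect_true(all(size_factors(disjoint, pseudocount = 1) > 0))
})

test_that("size factors agree with the DESeq2 reference", {
    skip_if_not_installed("DESeq2")
    # odd OTU count: the ratio-scale median equals DESeq2's log-scale
    # median exactly (no interpolation between middle values)
    set.seed(23)
    m <- matrix(rpois(54, 20) + 1, 6, 9,
                dimnames = list(paste0("s", 1:6), paste0("o", 1:9)))
    ref <- DESeq2::estimateSizeFactorsForMatrix(t(m))  # genes x samples
    expect_equal(unname(size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("phase contrasts are one-sided with the expected reversal", {
    ph <- rep(1:2, c(6, 9))
    vals <- c(10:15 + 0.5, 1:9)   # phase 1 strictly above phase 2
    expect_lt(phase_contrast_test(vals, ph, 1, 2), 0.01)
    expect_gt(phase_contrast_test(vals, ph, 2, 1), 0.99)

    # identical distributions: p averages ~0.5 over seeds
    set.seed(24)
    ps <- replicate(200, {
        v <- rnorm(8)
        phase_contrast_test(v, rep(1:2, each = 4), 1, 2)
    })
    expect_lt(abs(mean(ps) - 0.5), 0.06)

    # exact-test reversal identity: p> + p< = 1 + P(U = u_obs)
    a <- c(3, 9, 12); b <- c(1, 5, 7, 11)
    u_all <- exact_u_dist(c(a, b), 3)
    u_obs <- rank_sum_test(a, b)$statistic
    pg <- rank_sum_test(a, b, "greater")$p.value
    pl <- rank_sum_test(a, b, "less")$p.value
    expect_equal(pg + pl, 1 + mean(u_all == u_obs), tolerance = 1e-12)

    expect_error(phase_contrast_test(1:5, c(1, 1, 2, 2, 2), 1, 3),
                 class = "micasm_invalid_argument")
})

test_that("bh_adjust matches the step-up definition and brute force", {
    expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bh_adjust(0.2), 0.2)
    expect_error(bh_adjust(c(0.1, 1.2)), class = "micasm_invalid_argument")

    set.seed(25)
    for (k in 1:20) {
        p <- runif(50)
        adj <- bh_adjust(p)
        expect_equal(adj, bh_brute(p), tolerance = 1e-12)
        # monotone nondecreasing in sorted order
        expect_false(is.unsorted(adj[order(p)]))
    }
    # one long brute-force comparison
    p <- runif(1000)
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
})

test_that("classify_otus assigns categories by phase-peak contrasts", {
    # 21 samples over 7 batches, 3 replicates; OTU o1 is ~100x higher in
    # phase 1, o2 flat, o3 higher in phase 3
    set.seed(26)
    batches <- rep(paste0("B", 1:7), each = 3)
    ph <- paper_phases()[batches]
    n <- length(batches)
    o1 <- rpois(n, ifelse(ph == 1, 400, 4))
    o2 <- rpois(n, 50)
    o3 <- rpois(n, ifelse(ph == 3, 300, 3))
    filler <- matrix(rpois(n * 5, 30), n, 5)
    counts <- cbind(o1, o2, o3, filler)
    colnames(counts) <- paste0("OTU_", 1:8)
    ct <- make_table(counts, treatment = "TCS", batch = batches,
                     replicate = rep(1:3, 7),
                     day = 5 * as.integer(sub("B", "", batches)))
    calls <- classify_otus(ct, "TCS", paper_phases())
    expect_equal(calls$category[calls$otu_id == "OTU_1"], "sensitive")
    expect_equal(calls$category[calls$otu_id == "OTU_2"], "unclassified")
    expect_equal(calls$category[calls$otu_id == "OTU_3"], "tolerant")

    # calls are mutually exclusive and summaries count them
    expect_true(all(table(calls$otu_id) == 1))
    summ <- summarize_groups(calls)
    expect_equal(summ["TCS", "sensitive"] +
                 summ["TCS", "opportunistic"] +
                 summ["TCS", "tolerant"] +
                 summ["TCS", "unclassified"], nrow(calls))

    expect_error(classify_otus(ct, "TCS", setNames(rep(1L, 7),
                                                   paste0("B", 1:7))),
                 class = "micasm_invalid_argument")
})
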