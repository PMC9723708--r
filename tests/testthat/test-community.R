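# Dissimilarity, rarefaction, removal and rank-test conventions.

test_that("bray_curtis matches hand arithmetic and is a bounded semimetric", {
    expect_equal(bray_curtis(c(1, 2, 3), c(3, 2, 1)), 4 / 12)
    expect_equal(bray_curtis(c(5, 1), c(5, 1)), 0)
    expect_equal(bray_curtis(c(1, 0), c(0, 7)), 1)
    expect_error(bray_curtis(c(0, 0), c(0, 0)),
                 class = "micasm_undefined_input")
    expect_error(bray_curtis(1:3, 1:2), class = "micasm_invalid_argument")

    set.seed(1)
    for (k in 1:25) {
        x <- rpois(10, 3); y <- rpois(10, 3)
        if (sum(x) + sum(y) == 0) next
        b <- bray_curtis(x, y)
        expect_gte(b, 0); expect_lte(b, 1)
        expect_equal(b, bray_curtis(y, x))
        expect_equal(b, vegan::vegdist(rbind(x, y))[1], tolerance = 1e-12)
    }
})

test_that("rarefy subsamples without replacement to exact depth", {
    ct <- make_table(matrix(c(10, 0, 0, 6, 3, 1), 2, 3, byrow = TRUE))
    same <- rarefy(ct, depth = 10, seed = 1)
    expect_equal(unname(same$counts[1, ]), c(10, 0, 0))

    forced <- rarefy(make_table(matrix(c(10, 0, 0), 1)), depth = 5, seed = 1)
    expect_equal(unname(forced$counts[1, ]), c(5, 0, 0))

    expect_error(rarefy(ct, depth = 11), "s02",
                 class = "micasm_depth_error")

    # hypergeometric oracle: sample (5,5) at depth 4 has mean first-entry 2
    big <- make_table(matrix(rep(c(5, 5), each = 1e4), ncol = 2))
    r <- rarefy(big, depth = 4, seed = 2)
    expect_true(all(rowSums(r$counts) == 4))
    se <- sqrt(4 * 0.5 * 0.5 * (10 - 4) / (10 - 1) / 1e4)
    expect_lt(abs(mean(r$counts[, 1]) - 2), 3 * se)

    # never invents taxa
    set.seed(3)
    tab <- make_table(matrix(rpois(50, 2) * rbinom(50, 1, 0.6), 5, 10))
    rr <- rarefy(tab, depth = min(rowSums(tab$counts)), seed = 4)
    expect_true(all(rr$counts[tab$counts == 0] == 0))
})

test_that("removal_rate follows the day0-vs-day5 definition", {
    chem <- data.frame(microcosm_id = c("m1", "m1", "m2", "m2", "m3", "m3"),
                       treatment = "T", batch = "B1", replicate = 1,
                       compound = "BPA", day = c(0, 5, 0, 5, 0, 5),
                       concentration_ugL = c(1, 0.2, 1, 1.1, 0, 0))
    expect_warning(rr <- removal_rate(chem), "m3")
    expect_equal(rr$removal_percent[rr$microcosm_id == "m1"], 80)
    expect_equal(rr$removal_percent[rr$microcosm_id == "m2"], -10)
    expect_false("m3" %in% rr$microcosm_id)

    # unit invariance
    scaled <- chem; scaled$concentration_ugL <- scaled$concentration_ugL * 1000
    expect_warning(rs <- removal_rate(scaled))
    expect_equal(rs$removal_percent, rr$removal_percent)
})

test_that("rank_sum_test: exact enumeration, ties, and normal approximation", {
    expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
    expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
    expect_equal(rank_sum_test(rep(2, 4), rep(2, 5))$p.value, 1)

    # against base R exact test on tie-free samples
    set.seed(7)
    for (k in 1:20) {
        a <- sample(100, 4); b <- sample(100, 5) + 0.5
        ours <- rank_sum_test(a, b)
        ref <- wilcox.test(a, b, exact = TRUE)
        expect_equal(ours$statistic, unname(ref$statistic))
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
        g <- rank_sum_test(a, b, "greater")
        rg <- wilcox.test(a, b, alternative = "greater", exact = TRUE)
        expect_equal(g$p.value, rg$p.value, tolerance = 1e-12)
    }

    # normal approximation close to exact at n = 6 per group
    set.seed(8)
    diffs <- replicate(100, {
        a <- rnorm(6); b <- rnorm(6)
        abs(rank_sum_test(a, b, exact_max = 12)$p.value -
            rank_sum_test(a, b, exact_max = 0)$p.value)
    })
    expect_lt(max(diffs), 0.01 + 1e-9)
})

test_that("kruskal_wallis matches hand values and base R", {
    expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p.value, 1)
    expect_equal(kruskal_wallis(list(1, 2, 3))$statistic, 2)

    set.seed(9)
    for (k in 1:10) {
        g <- split(rnorm(30), rep(1:3, 10))
        ours <- kruskal_wallis(g)
        ref <- kruskal.test(g)
        expect_equal(ours$statistic, unname(ref$statistic),
                     tolerance = 1e-12)
        expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    }

    # two groups: consistent ordering with the rank-sum test
    a <- c(1, 5, 9, 12); b <- c(2, 3, 4, 6)
    expect_equal(kruskal_wallis(list(a, b))$p.value,
                 kruskal.test(list(a, b))$p.value)
})

test_that("turnover regression recovers exact and degenerate slopes", {
    # control fixed at (100, 0); treatment at batch b is (100 - 10b, 10b),
    # so BC = b/10 exactly and the slope is 0.02 per day (days 5..35)
    counts <- rbind(t(vapply(1:7, function(b) c(100 - 10 * b, 10 * b),
                             numeric(2))),
                    matrix(rep(c(100, 0), 7), 7, 2, byrow = TRUE))
    ct <- make_table(counts,
                     treatment = rep(c("T", "Control"), each = 7),
                     batch = rep(paste0("B", 1:7), 2),
                     replicate = 1, day = rep(5 * (1:7), 2))
    ts <- turnover_regression(ct, "T")
    expect_equal(ts$slope, 0.02, tolerance = 1e-12)
    expect_lt(ts$p_value, 1e-6)

    flat <- rbind(matrix(rep(c(80, 20), 7), 7, 2, byrow = TRUE),
                  matrix(rep(c(100, 0), 7), 7, 2, byrow = TRUE))
    cf <- make_table(flat,
                     treatment = rep(c("T", "Control"), each = 7),
                     batch = rep(paste0("B", 1:7), 2),
                     replicate = 1, day = rep(5 * (1:7), 2))
    expect_equal(turnover_regression(cf, "T")$slope, 0)

    two <- make_table(counts[c(1, 2, 8, 9), ],
                      treatment = c("T", "T", "Control", "Control"),
                      batch = c("B1", "B2", "B1", "B2"),
                      replicate = 1, day = c(5, 10, 5, 10))
    expect_error(turnover_regression(two, "T"),
                 class = "micasm_invalid_argument")
})

test_that("selection regime produces positive seeded turnover slopes", {
    hits <- vapply(1:20, function(s) {
        sim <- simulate_experiment(sim_config(
            n_otus = 30, sequencing_depth = 3000, seed = s,
            treatments = list(Control = c(), TCS = c(TCS = 1))))
        rar <- rarefy(sim$community, seed = s)
        ts <- turnover_regression(rar, "TCS")
        ts$slope > 0 && ts$p_value < 0.05
    }, logical(1))
    expect_gt(mean(hits), 0.5)
})

test_that("summarize_removal aggregates and tests per treatment", {
    set.seed(10)
    chem <- do.call(rbind, lapply(1:7, function(b)
        data.frame(microcosm_id = paste0("TCS.1.B", b), treatment = "TCS",
                   replicate = 1, batch = paste0("B", b),
                   compound = rep(c("BPA", "TCS"), each = 2),
                   day = rep(c(0, 5), 2),
                   concentration_ugL = c(1, runif(1, 0, 0.3),
                                         1, runif(1, 0.4, 0.9)))))
    rs <- summarize_removal(removal_rate(chem))
    expect_equal(nrow(rs$summary), 2)
    expect_true(all(rs$consecutive_batches$p_value >= 0 &
                    rs$consecutive_batches$p_value <= 1))
    expect_equal(nrow(rs$between_compounds), 1)
    expect_lt(rs$between_compounds$p_value, 0.05)  # clearly separated guilds
})
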