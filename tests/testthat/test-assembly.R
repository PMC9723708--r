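# beta-MNTD / beta-NTI and Raup-Crick null models, and the five-process
# classification.

test_that("bmntd matches hand computations and the loop oracle", {
    D <- patristic_matrix(four_leaf_tree())
    expect_equal(bmntd(c(A = 0.5, B = 0.5), c(C = 0.5, D = 0.5), D), 4)
    expect_equal(bmntd(c(A = 1), c(B = 0.5, C = 0.5), D), 2.5)
    expect_equal(bmntd(c(A = 0.3, C = 0.7), c(A = 0.3, C = 0.7), D), 0)

    set.seed(11)
    tr <- simulate_tree(20)
    Dr <- patristic_matrix(tr)
    for (k in 1:10) {
        x <- setNames(rexp(20) * rbinom(20, 1, 0.6), rownames(Dr))
        y <- setNames(rexp(20) * rbinom(20, 1, 0.6), rownames(Dr))
        if (sum(x) == 0 || sum(y) == 0) next
        x <- x / sum(x); y <- y / sum(y)
        expect_equal(bmntd(x, y, Dr), naive_bmntd(x, y, Dr),
                     tolerance = 1e-12)
        expect_equal(bmntd(x, y, Dr), bmntd(y, x, Dr), tolerance = 1e-12)
        # invariance under joint permutation of taxa and matrix
        p <- sample(20)
        expect_equal(bmntd(x[p], y[p], Dr[p, p]), bmntd(x, y, Dr),
                     tolerance = 1e-12)
    }
    expect_error(bmntd(c(A = 0), c(B = 1), D),
                 class = "micasm_empty_community")
})

test_that("bmntd agrees with an independent comdistnt implementation", {
    skip_if_not_installed("picante")
    set.seed(12)
    tr <- simulate_tree(25)
    D <- patristic_matrix(tr)
    comm <- matrix(rpois(3 * 25, 2), 3, 25,
                   dimnames = list(paste0("s", 1:3), tr$tip.label))
    comm[comm == 0] <- 0
    rel <- sweep(comm, 1, rowSums(comm), "/")
    ref <- as.matrix(picante::comdistnt(rel, D, abundance.weighted = TRUE))
    for (i in 1:2) for (j in (i + 1):3)
        expect_equal(bmntd(rel[i, ], rel[j, ], D), ref[i, j],
                     tolerance = 1e-10)
})

test_that("bnti reproduces a seeded loop reimplementation exactly", {
    D <- patristic_matrix(four_leaf_tree())
    x <- c(A = 0.6, B = 0.4); y <- c(C = 0.3, D = 0.7)
    res <- bnti(x, y, D, n_null = 999, seed = 21)

    # independent loop-based oracle consuming the same RNG stream
    set.seed(21)
    perms <- vapply(1:999, function(k) sample.int(4) - 1L, integer(4))
    xs <- setNames(c(0.6, 0.4, 0, 0), rownames(D))
    ys <- setNames(c(0, 0, 0.3, 0.7), rownames(D))
    nulls <- apply(perms + 1L, 2, function(p) {
        Dp <- D[p, p]
        rownames(Dp) <- colnames(Dp) <- rownames(D)
        naive_bmntd(xs, ys, Dp)
    })
    obs <- naive_bmntd(xs, ys, D)
    expect_equal(res$observed, obs, tolerance = 1e-12)
    expect_equal(res$null_mean, mean(nulls), tolerance = 1e-10)
    expect_equal(res$bnti, (obs - mean(nulls)) / sd(nulls),
                 tolerance = 1e-10)
})

test_that("bnti rejects degenerate null distributions (star phylogeny)", {
    n <- 6
    D <- matrix(2, n, n); diag(D) <- 0
    rownames(D) <- colnames(D) <- paste0("t", 1:n)
    x <- setNames(c(0.5, 0.5, 0, 0, 0, 0), rownames(D))
    y <- setNames(c(0, 0, 0.5, 0.5, 0, 0), rownames(D))
    expect_error(bnti(x, y, D, n_null = 99, seed = 1),
                 class = "micasm_degenerate_null")
})

test_that("raup_crick_bray hits its analytic anchors", {
    set.seed(13)
    counts <- matrix(rpois(10 * 20, 5), 10, 20,
                     dimnames = list(paste0("s", 1:10), paste0("t", 1:20)))
    pool <- build_regional_pool(counts)

    # identical samples: observed BC = 0 sits below every null draw
    expect_equal(raup_crick_bray(counts[1, ], counts[1, ], pool,
                                 n_null = 999, seed = 2), -1)

    # disjoint samples: observed BC = 1 is extreme relative to the null
    xd <- setNames(c(rep(10, 10), rep(0, 10)), colnames(counts))
    yd <- setNames(c(rep(0, 10), rep(10, 10)), colnames(counts))
    expect_gt(raup_crick_bray(xd, yd, pool, n_null = 999, seed = 2), 0.95)

    expect_error(raup_crick_bray(c(zz = 3), counts[1, ], pool),
                 class = "micasm_missing_taxa")
})

test_that("raup_crick_bray matches exhaustive enumeration on a 2-taxon pool", {
    # occupancy: A in 3/5 samples, B in 2/5; richness-1 samples always
    # receive their full count on the single drawn taxon, so null BC is 0
    # (same taxon drawn) or 1 (different taxa); with observed BC = 1,
    # RC = P(same) = fA^2 + fB^2 over normalized occupancies
    cm <- rbind(c(5, 0), c(3, 0), c(2, 0), c(0, 4), c(0, 6))
    dimnames(cm) <- list(paste0("m", 1:5), c("A", "B"))
    pool <- build_regional_pool(cm)
    exact <- 0.6^2 + 0.4^2
    mc <- raup_crick_bray(c(A = 7, B = 0), c(A = 0, B = 9), pool,
                          n_null = 9999, seed = 5)
    expect_lt(abs(mc - exact), 0.02)
})

test_that("classify_pair applies the five-process rule", {
    expect_equal(classify_pair(2.5, 0.1), "variable_selection")
    expect_equal(classify_pair(-2.5, 0.1), "homogeneous_selection")
    expect_equal(classify_pair(-0.5, 0.97), "dispersal_limitation")
    expect_equal(classify_pair(0.5, -0.99), "homogenizing_dispersal")
    expect_equal(classify_pair(1.0, 0.2), "drift")
    # configurable sign convention
    expect_equal(classify_pair(2.5, 0.1, invert_selection = TRUE),
                 "homogeneous_selection")
    expect_error(classify_pair(NaN, 0), class = "micasm_invalid_argument")
})

test_that("process fractions are a distribution over the five processes", {
    sim <- simulate_experiment(sim_config(
        n_otus = 40, sequencing_depth = 3000, seed = 6,
        treatments = list(Control = c(), TCS = c(TCS = 1))))
    rar <- rarefy(sim$community, seed = 6)
    pf <- process_fractions(rar, sim$tree, "TCS", paper_phases(),
                            n_null = 99, seed = 6)
    for (ph in unique(pf$fractions$phase)) {
        f <- pf$fractions$fraction[pf$fractions$phase == ph]
        expect_equal(sum(f), 1, tolerance = 1e-12)
        expect_true(all(f >= 0))
    }
    expect_equal(nrow(pf$pairs), 153)  # 36 + 36 + 81 cross pairs
    expect_true(all(pf$pairs$rc_bray >= -1 & pf$pairs$rc_bray <= 1))

    # a phase without treatment samples is reported by name
    bad <- paper_phases()
    bad[] <- c(1L, 1L, 1L, 1L, 1L, 1L, 4L)
    sub <- rar
    keep <- !(sub$metadata$treatment == "TCS" & sub$metadata$batch == "B7")
    sub <- community_table(sub$counts[keep, ], sub$metadata[keep, ])
    expect_error(process_fractions(sub, sim$tree, "TCS", bad, n_null = 99),
                 "4", class = "micasm_invalid_argument")
})
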