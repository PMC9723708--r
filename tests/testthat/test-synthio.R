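# The synthetic serial-transfer generator: tree, traits, copy numbers,
# and the full experiment with its latent/chemistry invariants.

test_that("simulate_tree produces valid seeded coalescent trees", {
    t2 <- simulate_tree(2, seed = 1)
    expect_equal(length(t2$tip.label), 2)
    expect_equal(t2$Nnode, 1)

    n1 <- ape::write.tree(simulate_tree(50, seed = 1))
    n2 <- ape::write.tree(simulate_tree(50, seed = 1))
    expect_identical(n1, n2)

    tr <- simulate_tree(50, seed = 1)
    # brute-force traversal: tips are exactly the edges ending in 1..n
    tips <- sum(tr$edge[, 2] <= length(tr$tip.label))
    expect_equal(tips, 50)
    D <- patristic_matrix(tr)
    expect_true(all(D[upper.tri(D)] > 0))
    expect_true(all(tr$edge.length > 0))

    expect_error(simulate_tree(1), class = "micasm_invalid_argument")
})

test_that("tolerance trait carries phylogenetic signal; degrader edge cases hold", {
    tr <- simulate_tree(30, seed = 5)
    flat <- simulate_traits(tr, trait_bm_sigma = 0, seed = 1)
    expect_true(all(flat$tolerance == flat$tolerance[1]))

    none <- simulate_traits(tr, degrader_fraction = 0, seed = 1)
    all_ <- simulate_traits(tr, degrader_fraction = 1, seed = 1)
    expect_false(any(none$degrader))
    expect_true(all(all_$degrader))
    expect_error(simulate_traits(tr, degrader_fraction = 1.2),
                 class = "micasm_invalid_argument")

    # Monte-Carlo oracle: mean correlation between trait distance and
    # patristic distance is positive under Brownian motion
    set.seed(42)
    rs <- replicate(50, {
        tree <- simulate_tree(200)
        tol <- simulate_traits(tree, trait_bm_sigma = 1)$tolerance
        D <- patristic_matrix(tree)
        td <- abs(outer(tol, tol, "-"))
        cor(td[upper.tri(td)], D[upper.tri(D)])
    })
    expect_gt(mean(rs), 0)
})

test_that("copy-number maps respect range, coverage and missingness", {
    tr <- simulate_tree(40, seed = 3)
    iid <- simulate_copy_numbers(tr, seed = 1, autocorrelated = FALSE)
    expect_true(all(iid >= 1 & iid <= 15 & iid == round(iid)))
    expect_equal(length(iid), 40)

    full <- simulate_copy_numbers(tr, seed = 1, unassigned_fraction = 0)
    expect_setequal(names(full), tr$tip.label)

    big <- simulate_tree(1000, seed = 4)
    part <- simulate_copy_numbers(big, seed = 2, unassigned_fraction = 0.2)
    n_missing <- 1000 - length(part)
    ci <- qbinom(c(0.005, 0.995), 1000, 0.2)
    expect_gte(n_missing, ci[1])
    expect_lte(n_missing, ci[2])
})

test_that("experiment emits the full design with reproducible outputs", {
    cfg <- sim_config(n_otus = 25, sequencing_depth = 2000, seed = 7)
    sim <- simulate_experiment(cfg)
    expect_equal(nrow(sim$community$counts), 105)  # 5 arms x 3 reps x 7 batches
    expect_equal(ncol(sim$community$counts), 25)

    sim_b <- simulate_experiment(cfg)
    expect_identical(sim$community$counts, sim_b$community$counts)
    expect_identical(sim$chem, sim_b$chem)
    sim_c <- simulate_experiment(sim_config(n_otus = 25,
                                            sequencing_depth = 2000,
                                            seed = 8))
    expect_false(identical(sim$community$counts, sim_c$community$counts))

    # latent compositions sum to 1 wherever recorded
    sums <- apply(sim$truth$latent, c(1, 2), sum)
    expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))

    # with no library-size jitter, reads sum exactly to sequencing_depth
    even <- simulate_experiment(sim_config(n_otus = 25, n_batches = 2,
                                           sequencing_depth = 2000,
                                           depth_jitter = 0, seed = 7))
    expect_true(all(rowSums(even$community$counts) == 2000))
})

test_that("abiotic bottles leave every compound untouched", {
    sim <- simulate_experiment(sim_config(n_otus = 10, n_batches = 2,
                                          abiotic = TRUE, seed = 1))
    expect_null(sim$community)
    c0 <- sim$chem[sim$chem$day == 0, ]
    c5 <- sim$chem[sim$chem$day == 5, ]
    key <- function(d) paste(d$microcosm_id, d$compound)
    expect_equal(c5$concentration_ugL[match(key(c0), key(c5))],
                 c0$concentration_ugL)
})

test_that("neutral regime is drift only: no systematic abundance trend", {
    # 200 seeded control-only runs; per seed, OLS slope of a focal OTU's
    # end-of-batch latent abundance on batch index; the mean slope's 95%
    # CI must cover 0
    set.seed(99)
    slopes <- replicate(200, {
        sim <- simulate_experiment(sim_config(
            n_otus = 15, n_replicates = 1, sequencing_depth = 500,
            treatments = list(Control = c()), selection_strength = 0,
            effective_size = 2000, seed = sample.int(1e6, 1)))
        lat <- sim$truth$latent[, "5", ]   # batches x otus (7 samples)
        y <- lat[, which.max(lat[1, ])]    # most abundant OTU at B1
        coef(lm(y ~ seq_along(y)))[2]
    })
    ci <- mean(slopes) + c(-1.96, 1.96) * sd(slopes) / sqrt(length(slopes))
    expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("stress selection favours tolerant taxa by the final batch", {
    wins <- vapply(1:5, function(s) {
        sim <- simulate_experiment(sim_config(
            n_otus = 60, sequencing_depth = 5000, seed = s,
            treatments = list(Control = c(), TCS = c(TCS = 1))))
        lat <- sim$truth$latent
        final <- grep("^TCS\\..\\.B7$", rownames(lat))
        ab <- colMeans(lat[final, "5", ])
        tol <- sim$truth$tolerance01
        mean(ab[tol >= quantile(tol, 0.9)]) >
            mean(ab[tol <= quantile(tol, 0.1)])
    }, logical(1))
    expect_gt(mean(wins), 0.5)
})

test_that("subsidy removal rises with degrader abundance", {
    # same seed (same tree/inoculum), increasing degrader fraction
    rem <- vapply(c(0.05, 0.2, 0.5), function(f) {
        sim <- simulate_experiment(sim_config(
            n_otus = 40, n_batches = 2, sequencing_depth = 2000, seed = 3,
            degrader_fraction = f,
            treatments = list(Control = c(), BPA = c(BPA = 1))))
        mean(removal_rate(sim$chem)$removal_percent)
    }, numeric(1))
    expect_true(all(diff(rem) > 0))
})
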