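# Core dissimilarity, rarefaction, removal-rate and turnover-regression
# computations, with the nonparametric test conventions used throughout
# the package.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; a bounded
#' semimetric on non-negative vectors (symmetric, zero on identical
#' inputs, range [0, 1]).
#'
#' @param x,y equal-length non-negative numeric vectors; at least one
#'   must have positive total.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
    if (length(x) != length(y))
        micasm_stop("micasm_invalid_argument", "vectors differ in length")
    if (any(x < 0) || any(y < 0))
        micasm_stop("micasm_invalid_argument", "negative abundances")
    tot <- sum(x) + sum(y)
    if (tot == 0)
        micasm_stop("micasm_undefined_input",
                    "Bray-Curtis undefined: both vectors all-zero")
    sum(abs(x - y)) / tot
}

#' Rarefy a community table to even depth
#'
#' Per-sample subsampling of reads without replacement (multivariate
#' hypergeometric) so that every sample sums exactly to \code{depth};
#' zero entries are never inflated. Sampling is delegated to
#' \code{\link[vegan]{rrarefy}}.
#'
#' @param table a \code{\link{community_table}}.
#' @param depth target depth; must not exceed any sample total. The
#'   default \code{"min"} uses the smallest library size.
#' @param seed optional integer seed (NULL = use current RNG stream).
#' @return a rarefied \code{\link{community_table}}.
#' @export
rarefy <- function(table, depth = "min", seed = NULL) {
    stopifnot(inherits(table, "community_table"))
    totals <- rowSums(table$counts)
    if (identical(depth, "min")) depth <- min(totals)
    if (!is_count(depth, min = 1))
        micasm_stop("micasm_invalid_argument", "depth must be a positive integer")
    short <- rownames(table$counts)[totals < depth]
    if (length(short))
        micasm_stop("micasm_depth_error",
                    "samples below rarefaction depth %d: %s", depth,
                    paste(short, collapse = ", "))
    # vegan warns heuristically on very small totals; validation above
    # already guarantees a legal subsampling request
    counts <- with_seed(seed,
                        suppressWarnings(vegan::rrarefy(table$counts,
                                                        depth)))
    community_table(counts, table$metadata)
}

#' Per-batch micropollutant removal
#'
#' Removal over one microcosm batch is the decrease in concentration
#' relative to the spiked (day-0) concentration:
#' \eqn{100 (C_0 - C_5) / C_0} percent. Negative values (apparent
#' production) are reported as-is. Records with a zero day-0
#' concentration are skipped with a warning.
#'
#' @param chem chemistry data.frame as returned by
#'   \code{\link{read_chem}} or \code{\link{simulate_experiment}}; one
#'   (microcosm, compound) series must contain day-0 and day-5 records.
#' @param day_end day whose concentration is compared against day 0
#'   (default 5, the end of a batch).
#' @return data.frame with one row per (microcosm, compound):
#'   \code{microcosm_id}, \code{compound}, \code{removal_percent}, plus
#'   any treatment/batch/replicate columns present in \code{chem}.
#' @export
removal_rate <- function(chem, day_end = 5) {
    need <- c("microcosm_id", "compound", "day", "concentration_ugL")
    stopifnot(all(need %in% names(chem)))
    keep_cols <- intersect(c("treatment", "batch", "replicate"), names(chem))
    key <- interaction(chem$microcosm_id, chem$compound, drop = TRUE)
    out <- lapply(split(chem, key), function(g) {
        c0 <- g$concentration_ugL[g$day == 0]
        c5 <- g$concentration_ugL[g$day == day_end]
        if (length(c0) != 1 || length(c5) != 1)
            micasm_stop("micasm_format_error",
                        "missing day-0 or day-%d record for %s / %s",
                        day_end, g$microcosm_id[1], g$compound[1])
        if (c0 == 0) {
            warning(sprintf("skipping %s / %s: day-0 concentration is zero",
                            g$microcosm_id[1], g$compound[1]),
                    call. = FALSE)
            return(NULL)
        }
        cbind(data.frame(microcosm_id = g$microcosm_id[1],
                         compound = g$compound[1],
                         removal_percent = 100 * (c0 - c5) / c0,
                         stringsAsFactors = FALSE),
              g[1, keep_cols, drop = FALSE])
    })
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    rownames(out) <- NULL
    out
}

# --- rank-based tests ------------------------------------------------------
#
# Conventions: Mann-Whitney U with exact enumeration over all
# C(n_a + n_b, n_a) group assignments (ties included) when n_a + n_b <= 12,
# tie-corrected normal approximation with continuity correction otherwise;
# if every value in both samples is identical, p = 1 by convention. Exact
# computation with ties is why this is not a plain wilcox.test() call.

rank_sum_u <- function(a, n_a, ranks_pooled, idx) {
    sum(ranks_pooled[idx]) - n_a * (n_a + 1) / 2
}

#' Rank-sum (Mann-Whitney / Wilcoxon) test
#'
#' @param a,b non-empty numeric samples.
#' @param alternative \code{"two.sided"}, \code{"greater"} (a tends
#'   larger than b) or \code{"less"}.
#' @param exact_max combined size up to which the exact permutation
#'   distribution of U is enumerated (ties handled exactly).
#' @return list with \code{statistic} (U for sample \code{a}) and
#'   \code{p.value}.
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "greater", "less"),
                          exact_max = 12) {
    alternative <- match.arg(alternative)
    a <- as.numeric(a); b <- as.numeric(b)
    if (!length(a) || !length(b) || anyNA(a) || anyNA(b))
        micasm_stop("micasm_invalid_argument", "samples must be non-empty, no NA")
    n_a <- length(a); n_b <- length(b); n <- n_a + n_b
    pooled <- c(a, b)
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
    if (length(unique(pooled)) == 1L)
        return(list(statistic = u_obs, p.value = 1))
    if (n <= exact_max) {
        combs <- combn(n, n_a)
        u_all <- apply(combs, 2, function(idx)
            sum(r[idx]) - n_a * (n_a + 1) / 2)
        p_le <- mean(u_all <= u_obs + 1e-9)
        p_ge <- mean(u_all >= u_obs - 1e-9)
        p <- switch(alternative,
                    two.sided = min(1, 2 * min(p_le, p_ge)),
                    greater   = p_ge,
                    less      = p_le)
    } else {
        mu <- n_a * n_b / 2
        tie_tab <- table(pooled)
        tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
        sigma <- sqrt(n_a * n_b / 12 * ((n + 1) - tie_term))
        # Edgeworth-corrected normal CDF with continuity correction: the
        # U distribution is symmetric but platykurtic (exact excess
        # kurtosis below, tie-free case), and the kurtosis term matters
        # at moderate sample sizes
        g2 <- -(6 / 5) * (n_a^2 + n_b^2 + n_a * n_b + n) /
            (n_a * n_b * (n + 1))
        u_cdf <- function(z) pnorm(z) - g2 / 24 * (z^3 - 3 * z) * dnorm(z)
        p_le <- u_cdf((u_obs - mu + 0.5) / sigma)
        p_ge <- 1 - u_cdf((u_obs - mu - 0.5) / sigma)
        p <- switch(alternative,
                    two.sided = min(1, 2 * min(p_le, p_ge)),
                    greater   = max(0, min(1, p_ge)),
                    less      = max(0, min(1, p_le)))
    }
    list(statistic = u_obs, p.value = p)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-squared reference distribution
#' (k - 1 df). All values identical across all groups gives p = 1 by
#' convention.
#'
#' @param groups list of non-empty numeric vectors (>= 2 groups).
#' @return list with \code{statistic} (H) and \code{p.value}.
#' @export
kruskal_wallis <- function(groups) {
    stopifnot(is.list(groups), length(groups) >= 2)
    if (any(!vapply(groups, length, 1L)))
        micasm_stop("micasm_invalid_argument", "empty group")
    pooled <- unlist(groups, use.names = FALSE)
    n <- length(pooled)
    if (length(unique(pooled)) == 1L)
        return(list(statistic = 0, p.value = 1))
    r <- rank(pooled)
    grp <- rep(seq_along(groups), lengths(groups))
    h <- 12 / (n * (n + 1)) *
        sum(tapply(r, grp, sum)^2 / lengths(groups)) - 3 * (n + 1)
    tie_tab <- table(pooled)
    h <- h / (1 - sum(tie_tab^3 - tie_tab) / (n^3 - n))
    list(statistic = h,
         p.value = pchisq(h, df = length(groups) - 1, lower.tail = FALSE))
}

#' Community turnover relative to controls over time
#'
#' For each batch, the Bray-Curtis dissimilarity of every treatment
#' sample against every contemporaneous control sample (all cross pairs
#' by default; \code{matched} pairs replicate i against replicate i,
#' matching the pairwise transfer lines). An ordinary least-squares
#' regression of dissimilarity on sampling day quantifies the turnover
#' rate; additionally each later batch's dissimilarities are compared to
#' batch B1 by a rank-sum test (the initial-community legacy contrast).
#'
#' @param table a rarefied \code{\link{community_table}}.
#' @param treatment treatment label to compare against controls.
#' @param control_label metadata label of the control arm.
#' @param pairs \code{"cross"} (default) or \code{"matched"}.
#' @return object of class \code{turnover_series}: list with
#'   \code{points} (batch, day, dissimilarity), \code{slope},
#'   \code{intercept}, \code{p_value}, and \code{wilcoxon_vs_first}
#'   (named vector of p-values, later batches vs the first).
#' @export
turnover_regression <- function(table, treatment, control_label = "Control",
                                pairs = c("cross", "matched")) {
    stopifnot(inherits(table, "community_table"))
    pairs <- match.arg(pairs)
    md <- table$metadata
    batches <- batch_levels(md$batch)
    pts <- list()
    for (b in batches) {
        trt <- which(md$treatment == treatment & md$batch == b)
        ctl <- which(md$treatment == control_label & md$batch == b)
        if (!length(ctl))
            micasm_stop("micasm_invalid_argument",
                        "no control samples in batch %s", b)
        for (i in trt) for (j in ctl) {
            if (pairs == "matched" && md$replicate[i] != md$replicate[j])
                next
            pts[[length(pts) + 1L]] <- data.frame(
                batch = b, day = md$day[i],
                dissimilarity = bray_curtis(table$counts[i, ],
                                            table$counts[j, ]))
        }
    }
    pts <- do.call(rbind, pts)
    if (length(unique(pts$day)) < 3)
        micasm_stop("micasm_invalid_argument",
                    "turnover slope needs >= 3 distinct days")
    fit <- lm(dissimilarity ~ day, data = pts)
    # exact linear or constant dissimilarities are legitimate degenerate
    # inputs; the perfect-fit warning is expected there
    coefs <- suppressWarnings(summary(fit))$coefficients
    first <- batches[1]
    later <- setdiff(batches, first)
    wil <- vapply(later, function(b)
        rank_sum_test(pts$dissimilarity[pts$batch == b],
                      pts$dissimilarity[pts$batch == first])$p.value,
        numeric(1))
    structure(list(points = pts,
                   slope = unname(coefs["day", "Estimate"]),
                   intercept = unname(coefs["(Intercept)", "Estimate"]),
                   p_value = unname(coefs["day", "Pr(>|t|)"]),
                   wilcoxon_vs_first = wil,
                   treatment = treatment),
              class = "turnover_series")
}

#' @export
print.turnover_series <- function(x, ...) {
    cat(sprintf("turnover_series (%s vs control): slope %.4g per day (p = %.3g), %d pairs\n",
                x$treatment, x$slope, x$p_value, nrow(x$points)))
    invisible(x)
}

#' Summary statistics and tests for removal rates
#'
#' Per (treatment, compound): mean and sd of removal; a rank-sum test
#' between each pair of consecutive batches (does removal change between
#' batches?); and, within each treatment, a Kruskal-Wallis test across
#' compounds using per-batch removal values as replicates.
#'
#' @param removal data.frame from \code{\link{removal_rate}} with
#'   treatment and batch columns.
#' @return list with elements \code{summary} (data.frame),
#'   \code{consecutive_batches} (data.frame of rank-sum p-values) and
#'   \code{between_compounds} (data.frame of Kruskal-Wallis results).
#' @export
summarize_removal <- function(removal) {
    stopifnot(all(c("treatment", "batch", "compound", "removal_percent")
                  %in% names(removal)))
    key <- interaction(removal$treatment, removal$compound, drop = TRUE)
    summ <- do.call(rbind, lapply(split(removal, key), function(g)
        data.frame(treatment = g$treatment[1], compound = g$compound[1],
                   mean_removal = mean(g$removal_percent),
                   sd_removal = sd(g$removal_percent))))
    cons <- do.call(rbind, lapply(split(removal, key), function(g) {
        bl <- batch_levels(g$batch)
        if (length(bl) < 2) return(NULL)
        do.call(rbind, lapply(seq_len(length(bl) - 1), function(k) {
            a <- g$removal_percent[g$batch == bl[k]]
            b <- g$removal_percent[g$batch == bl[k + 1]]
            data.frame(treatment = g$treatment[1], compound = g$compound[1],
                       batches = paste(bl[k], bl[k + 1], sep = "-"),
                       p_value = rank_sum_test(a, b)$p.value)
        }))
    }))
    rownames(cons) <- NULL
    kw <- do.call(rbind, lapply(split(removal, removal$treatment), function(g) {
        comps <- unique(g$compound)
        if (length(comps) < 2) return(NULL)
        res <- kruskal_wallis(split(g$removal_percent, g$compound))
        data.frame(treatment = g$treatment[1], H = res$statistic,
                   p_value = res$p.value)
    }))
    rownames(kw) <- NULL
    list(summary = summ, consecutive_batches = cons, between_compounds = kw)
}
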