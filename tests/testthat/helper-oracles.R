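# Independent oracles and small fixture builders. Oracles are written as
# plain loops, independent of the implementation paths they check.

# Naive double-loop beta-MNTD over named relative-abundance vectors.
naive_bmntd <- function(x, y, D) {
    xs <- names(x)[x > 0]; ys <- names(y)[y > 0]
    s <- 0
    for (i in xs) s <- s + x[i] * min(D[i, ys])
    for (j in ys) s <- s + y[j] * min(D[j, xs])
    unname(s / 2)
}

# Step-up BH adjustment, written directly from the definition.
bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
        vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
        adj[o[i]] <- min(1, min(vals))
    }
    adj
}

# Exact distribution of the Mann-Whitney U statistic for sample sizes
# (n_a, n_b) over pooled values (ties included), by full enumeration.
exact_u_dist <- function(pooled, n_a) {
    r <- rank(pooled)
    combs <- combn(length(pooled), n_a)
    apply(combs, 2, function(idx) sum(r[idx]) - n_a * (n_a + 1) / 2)
}

# Recursive enumeration of contiguous partitions (independent of the
# combn-cut construction in the package); returns assignment vectors in
# lexicographic order of block boundaries.
recursive_partitions <- function(n, K) {
    if (K == 1) return(list(rep(1L, n)))
    out <- list()
    for (first in seq_len(n - K + 1)) {
        for (rest in recursive_partitions(n - first, K - 1))
            out[[length(out) + 1L]] <- c(rep(1L, first), rest + 1L)
    }
    out
}

# Oracle for the contiguity-constrained minimal within-phase SS split,
# with the same tie rule as the package (min size variance, then first).
oracle_phases <- function(profiles, K) {
    parts <- recursive_partitions(nrow(profiles), K)
    ss <- vapply(parts, function(a) {
        tot <- 0
        for (ph in unique(a)) {
            rows <- profiles[a == ph, , drop = FALSE]
            mu <- colMeans(rows)
            for (r in seq_len(nrow(rows)))
                tot <- tot + sum((rows[r, ] - mu)^2)
        }
        tot
    }, numeric(1))
    best <- which(ss <= min(ss) + 1e-12)
    if (length(best) > 1) {
        imb <- vapply(parts[best], function(a)
            stats::var(as.numeric(table(a))), numeric(1))
        best <- best[imb <= min(imb) + 1e-12]
    }
    parts[[best[1]]]
}

# Small community_table: counts matrix with minimal valid metadata.
make_table <- function(counts, treatment = "T", batch = NULL,
                       replicate = NULL, day = NULL) {
    n <- nrow(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("s%02d", seq_len(n))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("OTU_%04d", seq_len(ncol(counts)))
    md <- data.frame(sample_id = rownames(counts),
                     treatment = rep_len(treatment, n),
                     batch = if (is.null(batch)) rep("B1", n) else batch,
                     replicate = if (is.null(replicate)) seq_len(n)
                                 else replicate,
                     day = if (is.null(day)) rep(5, n) else day)
    community_table(counts, md)
}

# The four-leaf reference tree used in the hand-computed examples.
four_leaf_tree <- function() {
    ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}
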