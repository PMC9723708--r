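# Dissimilarity-overlap analysis: do communities that share taxa also
# share dynamics? For every within-treatment sample pair the overlap
# (shared-taxon abundance mass) is plotted against the root
# Jensen-Shannon dissimilarity of the renormalized shared fractions; a
# negative slope at high overlap is the signature of "universal"
# (host/environment-independent) taxon dynamics.

#' Overlap of two communities
#'
#' With S the set of taxa present in both samples,
#' \eqn{O = \frac{1}{2}\sum_{i \in S}(x_i + y_i)}: the mean fraction of
#' each community occupied by shared taxa.
#'
#' @param x,y relative-abundance vectors (each summing to 1).
#' @return overlap in [0, 1], or \code{NA} when the supports are
#'   disjoint (pair excluded from the analysis rather than an error).
#' @export
overlap <- function(x, y) {
    if (length(x) != length(y))
        micasm_stop("micasm_invalid_argument", "vectors differ in length")
    s <- x > 0 & y > 0
    if (!any(s)) return(NA_real_)
    sum(x[s] + y[s]) / 2
}

#' Root Jensen-Shannon divergence
#'
#' \eqn{rJSD(x, y) = \sqrt{\tfrac12 KL(x \| M) + \tfrac12 KL(y \| M)}}
#' with \eqn{M = (x + y)/2} and base-2 logarithms, so the value lies in
#' [0, 1]; \eqn{0 \log 0} terms are taken as 0. rJSD is a metric on the
#' probability simplex.
#'
#' @param x,y probability vectors on the same support (each sums to 1).
#' @return dissimilarity in [0, 1].
#' @export
rjsd <- function(x, y) {
    if (length(x) != length(y))
        micasm_stop("micasm_invalid_argument", "vectors differ in length")
    if (any(x < 0) || any(y < 0) ||
        abs(sum(x) - 1) > 1e-8 || abs(sum(y) - 1) > 1e-8)
        micasm_stop("micasm_invalid_argument",
                    "inputs must be probability vectors summing to 1")
    m <- (x + y) / 2
    kl <- function(p, q) {
        i <- p > 0
        sum(p[i] * log2(p[i] / q[i]))
    }
    sqrt(pmax(0, 0.5 * kl(x, m) + 0.5 * kl(y, m)))
}

# One DOC point from two relative-abundance vectors, or NULL when no
# taxon is shared.
doc_point <- function(x, y) {
    s <- x > 0 & y > 0
    if (!any(s)) return(NULL)
    o <- sum(x[s] + y[s]) / 2
    xs <- x[s] / sum(x[s]); ys <- y[s] / sum(y[s])
    c(overlap = o, dissimilarity = rjsd(xs, ys))
}

#' Dissimilarity-overlap analysis for one treatment
#'
#' All unordered within-treatment sample pairs are converted to
#' (overlap, rJSD) points; an ordinary least-squares slope is fitted to
#' the points whose overlap exceeds the cutoff (the median overlap by
#' default, as only the high-overlap branch is informative about shared
#' dynamics). The supporting statistic is the fraction of bootstrap
#' realizations with a negative slope, where the bootstrap resamples
#' whole SAMPLES with replacement (pairs sharing a sample are not
#' independent, so resampling pairs would understate uncertainty);
#' pairs of two copies of the same sample are excluded.
#'
#' @param table a rarefied \code{\link{community_table}}.
#' @param treatment treatment arm to analyse (>= 3 samples).
#' @param cutoff \code{"median"} (default) or a numeric overlap
#'   threshold in [0, 1].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return object of class \code{doc_result}: list with \code{points}
#'   (data.frame sample_a, sample_b, overlap, dissimilarity),
#'   \code{cutoff}, \code{slope}, \code{intercept},
#'   \code{fraction_negative}, \code{n_boot} (effective bootstrap
#'   count), \code{n_pairs}.
#' @export
doc_analysis <- function(table, treatment, cutoff = "median",
                         n_boot = 1000, seed = NULL) {
    stopifnot(inherits(table, "community_table"))
    idx <- which(table$metadata$treatment == treatment)
    if (length(idx) < 3)
        micasm_stop("micasm_invalid_argument",
                    "need >= 3 samples in treatment %s", treatment)
    rel <- sweep(table$counts[idx, , drop = FALSE], 1,
                 rowSums(table$counts[idx, , drop = FALSE]), "/")
    ids <- rownames(rel)
    points_of <- function(rows) {
        prs <- combn(length(rows), 2)
        out <- vector("list", ncol(prs))
        for (k in seq_len(ncol(prs))) {
            i <- rows[prs[1, k]]; j <- rows[prs[2, k]]
            if (i == j) next   # bootstrap duplicate of one sample
            pt <- doc_point(rel[i, ], rel[j, ])
            if (!is.null(pt))
                out[[k]] <- data.frame(sample_a = ids[i], sample_b = ids[j],
                                       overlap = pt["overlap"],
                                       dissimilarity = pt["dissimilarity"],
                                       row.names = NULL)
        }
        do.call(rbind, out)
    }
    pts <- points_of(seq_along(idx))
    if (is.null(pts) || !nrow(pts))
        micasm_stop("micasm_doc_degenerate", "no pairs share any taxon")
    cut_val <- if (identical(cutoff, "median")) median(pts$overlap)
               else {
                   stopifnot(is_prob(cutoff))
                   cutoff
               }
    fit_slope <- function(p) {
        hi <- p[p$overlap > cut_val, , drop = FALSE]
        if (nrow(hi) < 3 || var(hi$overlap) == 0 ||
            var(hi$dissimilarity) == 0) return(NULL)
        unname(coef(lm(dissimilarity ~ overlap, data = hi)))
    }
    ab <- fit_slope(pts)
    if (is.null(ab))
        micasm_stop("micasm_doc_degenerate",
                    "slope undefined: < 3 informative points above cutoff %.3f",
                    cut_val)
    boot <- with_seed(seed, {
        slopes <- rep(NA_real_, n_boot)
        for (b in seq_len(n_boot)) {
            rows <- sample(seq_along(idx), replace = TRUE)
            p <- points_of(rows)
            if (is.null(p) || !nrow(p)) next
            s <- fit_slope(p)
            if (!is.null(s)) slopes[b] <- s[2]
        }
        slopes
    })
    ok <- !is.na(boot)
    structure(list(points = pts, cutoff = cut_val, slope = ab[2],
                   intercept = ab[1],
                   fraction_negative = mean(boot[ok] < 0),
                   n_boot = sum(ok), n_pairs = nrow(pts),
                   treatment = treatment),
              class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
    cat(sprintf("doc_result (%s): %d pairs, cutoff %.3f\n", x$treatment,
                x$n_pairs, x$cutoff))
    cat(sprintf("  slope m = %.4g; fraction of %d bootstrap slopes < 0: %.3f\n",
                x$slope, x$n_boot, x$fraction_negative))
    invisible(x)
}
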