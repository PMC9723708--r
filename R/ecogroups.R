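# Ecological grouping of OTUs by their growth-phase abundance profile:
# sensitive (peak in phase 1), opportunistic (peak in phase 2), tolerant
# (peak in phase 3), with Benjamini-Hochberg control over all
# (OTU x contrast) tests in a treatment.

#' Median-of-ratios size factors
#'
#' Per sample: the median, over the OTUs whose geometric mean across
#' samples is positive (i.e. OTUs present everywhere), of the ratio
#' count / geometric mean. The standard library-size normalization for
#' count tables with compositional differences.
#'
#' @param counts sample x OTU count matrix.
#' @param pseudocount added to every count before computing geometric
#'   means (default 0); use 1 when no OTU is present in all samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts, pseudocount = 0) {
    counts <- as.matrix(counts) + pseudocount
    log_gm <- colMeans(log(counts))
    use <- is.finite(log_gm)
    if (!any(use))
        micasm_stop("micasm_invalid_argument",
                    paste("no OTU present in every sample; rerun with a",
                          "pseudocount (e.g. size_factors(x, pseudocount = 1))"))
    sf <- apply(counts[, use, drop = FALSE], 1, function(row)
        median(exp(log(row) - log_gm[use])))
    if (any(!is.finite(sf) | sf <= 0))
        micasm_stop("micasm_invalid_argument",
                    "non-positive size factor; consider a pseudocount")
    sf
}

#' One-sided phase contrast for a single OTU
#'
#' Rank-sum test (see \code{\link{rank_sum_test}}) that the normalized
#' abundances in \code{phase_a} tend to be larger than in
#' \code{phase_b}. This rank-based test is the package's default
#' differential-abundance engine; a caller may plug in any other test
#' via the \code{test_fun} argument of \code{\link{classify_otus}}
#' (e.g. a negative-binomial GLM Wald p-value).
#'
#' @param values normalized abundances of one OTU across samples.
#' @param phase_labels integer phase index per sample.
#' @param phase_a,phase_b the contrast (a > b).
#' @return one-sided p-value.
#' @export
phase_contrast_test <- function(values, phase_labels, phase_a, phase_b) {
    a <- values[phase_labels == phase_a]
    b <- values[phase_labels == phase_b]
    if (length(a) < 2 || length(b) < 2)
        micasm_stop("micasm_invalid_argument",
                    "each phase needs >= 2 samples (phases %s, %s)",
                    phase_a, phase_b)
    rank_sum_test(a, b, alternative = "greater")$p.value
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over \code{stats::p.adjust(method = "BH")}:
#' sorted ascending, \eqn{adj_{(i)} = \min_{j \ge i} m p_{(j)} / j}
#' capped at 1, returned in the original order.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvalues) {
    if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
        micasm_stop("micasm_invalid_argument", "p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

ECO_CATEGORIES <- c("sensitive", "opportunistic", "tolerant")

# category -> its two defining one-sided contrasts (winning phase first)
eco_contrasts <- list(sensitive     = list(c(1, 2), c(1, 3)),
                      opportunistic = list(c(2, 1), c(2, 3)),
                      tolerant      = list(c(3, 1), c(3, 2)))

#' Classify OTUs as sensitive / opportunistic / tolerant
#'
#' For each OTU of a treatment arm, six one-sided phase contrasts are
#' run on size-factor-normalized counts (1>2, 1>3, 2>1, 2>3, 3>1, 3>2);
#' p-values are Benjamini-Hochberg adjusted jointly across all (OTU x
#' contrast) tests in the treatment. An OTU is \emph{sensitive} when
#' phase 1 is significantly higher than phases 2 and 3, by both adjusted
#' contrasts; \emph{opportunistic} when phase 2 beats 1 and 3;
#' \emph{tolerant} when phase 3 beats 1 and 2; otherwise
#' \emph{unclassified}. The three categories are mutually exclusive by
#' construction (their defining contrast directions conflict).
#'
#' @param table a \code{\link{community_table}}.
#' @param treatment treatment arm to analyse.
#' @param phases named integer vector, batch label -> phase index
#'   (three phases required).
#' @param alpha adjusted significance level (default 0.05).
#' @param prevalence_min minimum fraction of the treatment's samples in
#'   which an OTU must occur to be tested (default 0.1).
#' @param test_fun optional replacement test:
#'   \code{function(a, b) -> p} for the one-sided hypothesis that
#'   \code{a} tends larger than \code{b}.
#' @param pseudocount passed to \code{\link{size_factors}}.
#' @return data.frame with one row per tested OTU: \code{otu_id},
#'   \code{treatment}, \code{category}, adjusted p-values of the six
#'   contrasts (\code{padj_1gt2}, ...), and per-phase mean relative
#'   abundances (\code{mean_rel_phase1}, ...).
#' @export
classify_otus <- function(table, treatment, phases, alpha = 0.05,
                          prevalence_min = 0.1, test_fun = NULL,
                          pseudocount = 0) {
    stopifnot(inherits(table, "community_table"))
    md <- table$metadata
    idx <- which(md$treatment == treatment)
    if (!length(idx))
        micasm_stop("micasm_invalid_argument", "unknown treatment %s",
                    treatment)
    ph <- unname(phases[as.character(md$batch[idx])])
    if (anyNA(ph))
        micasm_stop("micasm_invalid_argument", "batches without phase")
    if (length(unique(ph)) != 3)
        micasm_stop("micasm_invalid_argument", "three phases required")
    counts <- table$counts[idx, , drop = FALSE]
    sf <- size_factors(counts, pseudocount = pseudocount)
    norm <- sweep(counts, 1, sf, "/")
    rel <- sweep(counts, 1, rowSums(counts), "/")
    prev <- colMeans(counts > 0)
    otus <- colnames(counts)[prev >= prevalence_min]
    if (!length(otus))
        micasm_stop("micasm_invalid_argument",
                    "no OTU passes the prevalence filter")
    contrasts <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
    cname <- vapply(contrasts, function(ct)
        sprintf("padj_%dgt%d", ct[1], ct[2]), character(1))
    test1 <- function(a, b) {
        if (is.null(test_fun)) rank_sum_test(a, b, "greater")$p.value
        else test_fun(a, b)
    }
    praw <- matrix(NA_real_, length(otus), length(contrasts),
                   dimnames = list(otus, cname))
    for (o in otus) for (k in seq_along(contrasts)) {
        ct <- contrasts[[k]]
        praw[o, k] <- test1(norm[ph == ct[1], o], norm[ph == ct[2], o])
    }
    padj <- matrix(bh_adjust(as.vector(praw)), nrow(praw),
                   dimnames = dimnames(praw))
    category <- vapply(otus, function(o) {
        hits <- vapply(ECO_CATEGORIES, function(cat) {
            all(vapply(eco_contrasts[[cat]], function(ct)
                padj[o, sprintf("padj_%dgt%d", ct[1], ct[2])] < alpha,
                logical(1)))
        }, logical(1))
        stopifnot(sum(hits) <= 1)  # directions conflict by construction
        if (any(hits)) ECO_CATEGORIES[which(hits)] else "unclassified"
    }, character(1))
    mean_rel <- vapply(1:3, function(p)
        colMeans(rel[ph == p, otus, drop = FALSE]), numeric(length(otus)))
    out <- data.frame(otu_id = otus, treatment = treatment,
                      category = unname(category),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(padj),
                 setNames(as.data.frame(mean_rel),
                          paste0("mean_rel_phase", 1:3)))
    rownames(out) <- NULL
    out
}

#' Category counts per treatment
#'
#' @param calls output of \code{\link{classify_otus}} (possibly several
#'   treatments row-bound).
#' @return data.frame treatment x category counts.
#' @export
summarize_groups <- function(calls) {
    tab <- table(calls$treatment,
                 factor(calls$category,
                        levels = c(ECO_CATEGORIES, "unclassified")))
    as.data.frame.matrix(tab)
}
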