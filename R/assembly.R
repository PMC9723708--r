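# Null-model quantification of community assembly processes:
# beta-MNTD / beta-NTI (phylogenetic turnover vs a tip-shuffle null) and
# Raup-Crick Bray-Curtis (taxonomic turnover vs a regional-pool null),
# classified into five ecological processes.

# Internal: support indices (0-based) and renormalized weights of a
# relative-abundance vector aligned to the pool.
support_of <- function(x, pool_ids) {
    if (!is.null(names(x))) {
        missing <- setdiff(names(x)[x > 0], pool_ids)
        if (length(missing))
            micasm_stop("micasm_missing_taxa",
                        "taxa absent from distance matrix: %s",
                        paste(missing, collapse = ", "))
        v <- setNames(numeric(length(pool_ids)), pool_ids)
        common <- intersect(names(x), pool_ids)
        v[common] <- x[common]
        x <- v
    } else if (length(x) != length(pool_ids)) {
        micasm_stop("micasm_invalid_argument",
                    "unnamed vector must match distance matrix dimension")
    }
    idx <- which(x > 0)
    if (!length(idx))
        micasm_stop("micasm_empty_community", "empty community")
    list(idx0 = idx - 1L, w = x[idx] / sum(x[idx]))
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' \deqn{\beta MNTD = \frac{1}{2}\Big[\sum_{i} x_i \min_{j} D_{ij}
#'   + \sum_{j} y_j \min_{i} D_{ji}\Big]}
#' with sums over taxa present in each community: the mean phylogenetic
#' distance from each taxon in one community to its nearest relative in
#' the other, weighted by relative abundance. Symmetric, zero when the
#' two communities are identical.
#'
#' @param x,y relative-abundance vectors, either named by OTU id or
#'   aligned to the rows of \code{D}.
#' @param D patristic distance matrix covering all present taxa
#'   (see \code{\link{patristic_matrix}}).
#' @return non-negative scalar in tree-distance units.
#' @export
bmntd <- function(x, y, D) {
    ids <- rownames(D)
    sx <- support_of(x, ids); sy <- support_of(y, ids)
    cpp_bmntd(D, sx$idx0, sx$w, sy$idx0, sy$w)
}

#' Beta nearest taxon index (standardized beta-MNTD deviate)
#'
#' The observed beta-MNTD is compared against a null distribution
#' obtained by shuffling taxon identities across the tips of the
#' phylogeny (equivalently: applying a random permutation to the rows
#' and columns of the patristic matrix restricted to the regional pool)
#' and recomputing beta-MNTD \code{n_null} times:
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \mu_{null}) / \sigma_{null}.}
#' |beta-NTI| > 2 indicates a stronger/weaker phylogenetic turnover than
#' expected by chance, i.e. selection.
#'
#' @inheritParams bmntd
#' @param n_null number of randomizations (>= 99; 999 by default).
#' @param seed optional integer seed (NULL = use current RNG stream).
#' @return list with \code{bnti}, \code{observed}, \code{null_mean},
#'   \code{null_sd}, \code{n_null}.
#' @export
bnti <- function(x, y, D, n_null = 999, seed = NULL) {
    if (!is_count(n_null, min = 99))
        micasm_stop("micasm_invalid_argument", "n_null must be >= 99")
    ids <- rownames(D)
    sx <- support_of(x, ids); sy <- support_of(y, ids)
    obs <- cpp_bmntd(D, sx$idx0, sx$w, sy$idx0, sy$w)
    nulls <- with_seed(seed, {
        perms <- vapply(seq_len(n_null),
                        function(k) sample.int(nrow(D)) - 1L,
                        integer(nrow(D)))
        cpp_bmntd_null(D, sx$idx0, sx$w, sy$idx0, sy$w, perms)
    })
    mu <- mean(nulls); sdev <- sd(nulls)
    if (!is.finite(sdev) || sdev == 0)
        micasm_stop("micasm_degenerate_null",
                    "null beta-MNTD distribution has zero spread (degenerate tree)")
    list(bnti = (obs - mu) / sdev, observed = obs, null_mean = mu,
         null_sd = sdev, n_null = n_null)
}

#' Regional species pool for the Raup-Crick null model
#'
#' Occupancy frequency (fraction of samples containing each taxon) and
#' mean relative abundance across a set of samples; both weight the null
#' community draws.
#'
#' @param counts sample x OTU count matrix.
#' @return list with named vectors \code{occupancy} and
#'   \code{abundance}.
#' @export
build_regional_pool <- function(counts) {
    counts <- as.matrix(counts)
    occ <- colMeans(counts > 0)
    rel <- sweep(counts, 1, rowSums(counts), "/")
    ab <- colMeans(rel)
    keep <- occ > 0
    list(occupancy = occ[keep], abundance = ab[keep])
}

#' Raup-Crick metric with Bray-Curtis dissimilarity
#'
#' Each null replicate reassembles both samples from the regional pool:
#' a sample's observed richness of taxa is drawn without replacement
#' with probability proportional to occupancy frequency; each drawn
#' taxon receives one individual and the remainder of the sample's
#' observed total count is allocated multinomially in proportion to
#' regional relative abundance. The observed Bray-Curtis value is then
#' located within the null distribution, with ties taking half weight:
#' \deqn{RC_{bray} = 2\,[\#(null < obs) + 0.5\,\#(null = obs)]/n_{null} - 1
#' \in [-1, 1].}
#' Values > 0.95 (more dissimilar than the null) or < -0.95 (more
#' similar) indicate departures from stochastic assembly.
#'
#' @param x,y count vectors named by OTU id (or aligned to the pool).
#' @param pool regional pool from \code{\link{build_regional_pool}};
#'   must cover every taxon observed in \code{x} or \code{y}.
#' @param n_null number of null replicates (999 by default).
#' @param seed optional integer seed.
#' @return scalar in [-1, 1].
#' @export
raup_crick_bray <- function(x, y, pool, n_null = 999, seed = NULL) {
    taxa <- names(pool$occupancy)
    align <- function(v) {
        if (is.null(names(v))) {
            if (length(v) != length(taxa))
                micasm_stop("micasm_invalid_argument",
                            "unnamed count vector must match pool size")
            return(setNames(as.numeric(v), taxa))
        }
        missing <- setdiff(names(v)[v > 0], taxa)
        if (length(missing))
            micasm_stop("micasm_missing_taxa", "pool missing taxa: %s",
                        paste(missing, collapse = ", "))
        out <- setNames(numeric(length(taxa)), taxa)
        common <- intersect(names(v), taxa)
        out[common] <- v[common]
        out
    }
    x <- align(x); y <- align(y)
    rich <- c(sum(x > 0), sum(y > 0))
    if (any(rich < 1))
        micasm_stop("micasm_empty_community", "empty community")
    tot <- c(sum(x), sum(y))
    obs <- bray_curtis(x, y)
    occ <- pool$occupancy; ab <- pool$abundance
    n_taxa <- length(taxa)
    draw_null <- function(r, n_reads) {
        sel <- sample.int(n_taxa, r, prob = occ)
        cnt <- numeric(n_taxa)
        cnt[sel] <- 1
        extra <- n_reads - r
        if (extra > 0 && sum(ab[sel]) > 0)
            cnt[sel] <- cnt[sel] + rmultinom(1, extra, ab[sel])[, 1]
        cnt
    }
    nulls <- with_seed(seed, vapply(seq_len(n_null), function(k)
        bray_curtis(draw_null(rich[1], tot[1]), draw_null(rich[2], tot[2])),
        numeric(1)))
    eps <- 1e-12
    2 * (sum(nulls < obs - eps) + 0.5 * sum(abs(nulls - obs) <= eps)) /
        n_null - 1
}

PROCESS_LABELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "drift")

#' Classify a sample pair into one of five assembly processes
#'
#' Decision rule on the two null-model deviates: beta-NTI beyond +/-2
#' indicates selection (variable if the pair is more phylogenetically
#' divergent than the null, homogeneous if less); otherwise RC_bray
#' beyond +/-0.95 indicates dispersal processes (limitation if
#' divergent, homogenizing if convergent); otherwise ecological drift.
#'
#' @param bnti beta-NTI z-score.
#' @param rc_bray Raup-Crick Bray-Curtis value in [-1, 1].
#' @param invert_selection if TRUE, swap the variable/homogeneous
#'   selection sign convention (the framework default maps beta-NTI > +2
#'   to variable selection).
#' @return one of \code{"variable_selection"},
#'   \code{"homogeneous_selection"}, \code{"dispersal_limitation"},
#'   \code{"homogenizing_dispersal"}, \code{"drift"}.
#' @export
classify_pair <- function(bnti, rc_bray, invert_selection = FALSE) {
    if (!is.finite(bnti) || !is.finite(rc_bray))
        micasm_stop("micasm_invalid_argument", "non-finite classification input")
    if (bnti > 2)
        return(if (invert_selection) "homogeneous_selection" else "variable_selection")
    if (bnti < -2)
        return(if (invert_selection) "variable_selection" else "homogeneous_selection")
    if (rc_bray > 0.95) return("dispersal_limitation")
    if (rc_bray < -0.95) return("homogenizing_dispersal")
    "drift"
}

#' Assembly process fractions per growth phase
#'
#' For every growth phase, all (treatment sample x control sample) pairs
#' whose batches fall in that phase are scored with
#' \code{\link{bnti}} and \code{\link{raup_crick_bray}} and classified
#' with \code{\link{classify_pair}}; the relative contribution of each
#' process is the fraction of pairs carrying its label. The regional
#' pool and the patristic matrix are restricted to the taxa observed in
#' the two compared groups within the phase, so phases are
#' self-contained (\code{pool = "global"} uses the whole table instead).
#'
#' @param table a rarefied \code{\link{community_table}}.
#' @param tree rooted phylogeny whose tips cover the table's OTUs.
#' @param treatment treatment arm to compare against the control.
#' @param phases named integer vector mapping batch label to phase index
#'   (see \code{\link{paper_phases}} / \code{\link{phase_clustering}}).
#' @param control_label metadata label of the control arm.
#' @param n_null randomizations for both null models.
#' @param seed optional integer seed.
#' @param pool \code{"phase"} (default) or \code{"global"}.
#' @param invert_selection passed to \code{\link{classify_pair}}.
#' @return object of class \code{assembly_result}: list with
#'   \code{pairs} (per-pair data.frame: ids, phase, bmntd, bnti,
#'   bray_curtis, rc_bray, process) and \code{fractions} (data.frame
#'   treatment x phase x process; fractions sum to 1 within phase).
#' @export
process_fractions <- function(table, tree, treatment, phases,
                              control_label = "Control", n_null = 999,
                              seed = NULL, pool = c("phase", "global"),
                              invert_selection = FALSE) {
    stopifnot(inherits(table, "community_table"))
    pool <- match.arg(pool)
    md <- table$metadata
    miss <- setdiff(unique(md$batch), names(phases))
    if (length(miss))
        micasm_stop("micasm_invalid_argument",
                    "batches without phase assignment: %s",
                    paste(miss, collapse = ", "))
    run <- function() {
        pair_rows <- list()
        for (ph in sort(unique(phases))) {
            ph_batches <- names(phases)[phases == ph]
            trt <- which(md$treatment == treatment & md$batch %in% ph_batches)
            ctl <- which(md$treatment == control_label &
                         md$batch %in% ph_batches)
            if (!length(trt) || !length(ctl))
                micasm_stop("micasm_invalid_argument",
                            "no sample pairs in phase %s", ph)
            grp_idx <- if (pool == "phase") c(trt, ctl)
                       else seq_len(nrow(md))
            sub <- table$counts[grp_idx, , drop = FALSE]
            taxa <- colnames(sub)[colSums(sub) > 0]
            D <- patristic_matrix(tree, taxa)
            reg <- build_regional_pool(
                table$counts[c(trt, ctl), taxa, drop = FALSE])
            for (i in trt) for (j in ctl) {
                xc <- table$counts[i, taxa]; yc <- table$counts[j, taxa]
                # pairs with identical supports have beta-MNTD = 0 under
                # every tip shuffle (each taxon is its own nearest
                # neighbour): no measurable phylogenetic deviation, so
                # beta-NTI is 0 and the pair is classified by RC_bray
                bn <- tryCatch(
                    bnti(rel_abund(xc), rel_abund(yc), D, n_null),
                    micasm_degenerate_null = function(e)
                        list(bnti = 0,
                             observed = bmntd(rel_abund(xc),
                                              rel_abund(yc), D),
                             null_mean = NA_real_, null_sd = 0,
                             n_null = n_null))
                rc <- raup_crick_bray(xc, yc, reg, n_null)
                pair_rows[[length(pair_rows) + 1L]] <- data.frame(
                    sample_a = rownames(table$counts)[i],
                    sample_b = rownames(table$counts)[j],
                    phase = ph, bmntd = bn$observed, bnti = bn$bnti,
                    bray_curtis = bray_curtis(xc, yc), rc_bray = rc,
                    process = classify_pair(bn$bnti, rc, invert_selection),
                    stringsAsFactors = FALSE)
            }
        }
        do.call(rbind, pair_rows)
    }
    pairs <- with_seed(seed, run())
    fr <- do.call(rbind, lapply(split(pairs, pairs$phase), function(g) {
        tab <- table(factor(g$process, levels = PROCESS_LABELS))
        data.frame(treatment = treatment, phase = g$phase[1],
                   process = PROCESS_LABELS,
                   fraction = as.numeric(tab) / nrow(g),
                   stringsAsFactors = FALSE)
    }))
    rownames(fr) <- NULL
    structure(list(pairs = pairs, fractions = fr, treatment = treatment),
              class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
    cat(sprintf("assembly_result: %s vs control, %d pairs\n",
                x$treatment, nrow(x$pairs)))
    wide <- tapply(x$fractions$fraction,
                   list(phase = x$fractions$phase,
                        process = x$fractions$process), sum)
    print(round(wide, 3))
    invisible(x)
}
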