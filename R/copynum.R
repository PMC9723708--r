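# Community-aggregated 16S rRNA gene copy number (a proxy for community
# growth strategy: fast growers carry more rRNA operons) and growth-phase
# inference by contiguity-constrained hierarchical clustering of batches.

#' Abundance-weighted mean 16S copy number of one sample
#'
#' Restricted to the OTUs with a copy-number assignment, their relative
#' abundances are renormalized to sum to 1 and the weighted mean
#' \eqn{\sum_i f_i c_i} returned. Read abundances are used as weights
#' as-is (no copy-number correction); set \code{correct = TRUE} to
#' weight by copy-number-corrected cell abundances instead.
#'
#' @param counts named count (or abundance) vector of one sample.
#' @param map named copy-number vector (possibly partial).
#' @param correct divide abundances by copy number before weighting.
#' @return weighted mean copy number (>= 1 for a map with values >= 1).
#' @export
weighted_mean_copy_number <- function(counts, map, correct = FALSE) {
    present <- names(counts)[counts > 0]
    assigned <- intersect(present, names(map))
    if (!length(assigned))
        micasm_stop("micasm_invalid_argument",
                    "no OTU in this sample has a copy-number assignment")
    f <- counts[assigned]
    if (correct) f <- f / map[assigned]
    f <- f / sum(f)
    sum(f * map[assigned])
}

#' Per-batch copy-number profiles of the treated microcosms
#'
#' Builds the matrix clustered by \code{\link{phase_clustering}}: one
#' row per batch (in batch order), one column per treated microcosm
#' (treatment x replicate), entries the weighted mean copy number of
#' that microcosm's sample in that batch. Controls are excluded.
#'
#' @param table a \code{\link{community_table}}.
#' @param map copy-number map.
#' @param control_label treatment label to exclude.
#' @param correct passed to \code{\link{weighted_mean_copy_number}}.
#' @return numeric matrix, batches x microcosms.
#' @export
batch_copy_profiles <- function(table, map, control_label = "Control",
                                correct = FALSE) {
    stopifnot(inherits(table, "community_table"))
    md <- table$metadata
    keep <- md$treatment != control_label
    wm <- vapply(which(keep), function(i)
        weighted_mean_copy_number(table$counts[i, ], map, correct),
        numeric(1))
    line <- paste(md$treatment[keep], md$replicate[keep], sep = ".")
    batches <- batch_levels(md$batch[keep])
    lines <- unique(line)
    prof <- matrix(NA_real_, length(batches), length(lines),
                   dimnames = list(batches, lines))
    prof[cbind(match(md$batch[keep], batches), match(line, lines))] <- wm
    if (anyNA(prof))
        micasm_stop("micasm_invalid_argument",
                    "missing (batch, microcosm) combinations in profile")
    prof
}

# All contiguous partitions of n ordered items into K blocks, as a list
# of integer assignment vectors. C(n-1, K-1) of them.
contiguous_partitions <- function(n, K) {
    cuts <- combn(n - 1, K - 1)
    lapply(seq_len(ncol(cuts)), function(j) {
        bounds <- c(0, cuts[, j], n)
        rep(seq_len(K), diff(bounds))
    })
}

# Within-phase sum of squared deviations from the phase-mean profile.
partition_ss <- function(profiles, assign) {
    sum(vapply(unique(assign), function(ph) {
        rows <- profiles[assign == ph, , drop = FALSE]
        sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
}

#' Growth-phase assignment of batches
#'
#' Complete-linkage hierarchical clustering of the per-batch
#' copy-number profiles under the Bray-Curtis dissimilarity, cut into
#' \code{K} groups. Because growth phases must respect the time
#' continuity of the serial inoculation, a non-contiguous cut is
#' replaced by the contiguous partition minimizing the within-phase sum
#' of squares (exhaustive search over the C(n-1, K-1) contiguous
#' partitions; ties broken towards equal phase sizes, then earliest
#' boundaries). Phases are numbered 1..K in batch order.
#'
#' @param profiles batches x microcosms matrix from
#'   \code{\link{batch_copy_profiles}} (rows in batch order).
#' @param K number of phases (default 3).
#' @return named integer vector (class \code{phase_assignment}) mapping
#'   batch label to phase index, with attribute \code{"contiguous_fix"}
#'   indicating whether the contiguity fallback was applied.
#' @export
phase_clustering <- function(profiles, K = 3) {
    profiles <- as.matrix(profiles)
    n <- nrow(profiles)
    if (!is_count(K, min = 1) || K > n)
        micasm_stop("micasm_invalid_argument",
                    "K must be an integer in [1, n_batches]")
    d <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
        if (i < j) d[i, j] <- d[j, i] <-
            bray_curtis(profiles[i, ], profiles[j, ])
    cl <- cutree(hclust(as.dist(d), method = "complete"), k = K)
    # contiguous iff no cluster label recurs after being left; identical
    # profiles (all distances zero) go straight to the tie-break rule
    contiguous <- length(rle(cl)$values) == K && max(d) > 0
    fixed <- FALSE
    if (contiguous) {
        assign <- match(cl, unique(cl))  # renumber 1..K in batch order
    } else {
        fixed <- TRUE
        parts <- contiguous_partitions(n, K)
        ss <- vapply(parts, function(a) partition_ss(profiles, a),
                     numeric(1))
        best <- which(ss <= min(ss) + 1e-12)
        if (length(best) > 1) {
            imbalance <- vapply(parts[best], function(a)
                var(as.numeric(table(a))), numeric(1))
            best <- best[order(imbalance)][1]
        }
        assign <- parts[[best[1]]]
    }
    structure(setNames(as.integer(assign), rownames(profiles)),
              class = "phase_assignment", contiguous_fix = fixed)
}

#' @export
print.phase_assignment <- function(x, ...) {
    for (ph in sort(unique(unclass(x))))
        cat(sprintf("phase %d: %s\n", ph,
                    paste(names(x)[unclass(x) == ph], collapse = ", ")))
    invisible(x)
}

#' Reference growth-phase assignment for a 7-batch design
#'
#' Early / mid / late exposure phases: B1-B2, B3-B4, B5-B7.
#'
#' @return named integer vector usable wherever a phase assignment is
#'   expected.
#' @export
paper_phases <- function() {
    setNames(c(1L, 1L, 2L, 2L, 3L, 3L, 3L),
             paste0("B", 1:7))
}
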