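# Readers/writers for the artifact formats: OTU table + metadata TSV,
# Newick trees, chemistry TSV, copy-number TSV. All readers validate and
# reject malformed values rather than coercing.

REQUIRED_METADATA_COLS <- c("sample_id", "treatment", "batch", "replicate",
                            "day")

#' Construct a community table
#'
#' Bundles a non-negative integer OTU count matrix (rows = samples,
#' columns = OTUs) with its per-sample metadata (treatment, batch,
#' replicate, day). All analysis functions in the package consume this
#' container.
#'
#' @param counts integer matrix, samples x OTUs, with unique row names
#'   (sample ids) and unique column names (OTU ids).
#' @param metadata data.frame with columns \code{sample_id},
#'   \code{treatment}, \code{batch}, \code{replicate}, \code{day},
#'   covering every row of \code{counts}.
#' @return An object of class \code{community_table}: a list with
#'   elements \code{counts} and \code{metadata} (metadata ordered as the
#'   count rows).
#' @export
community_table <- function(counts, metadata) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        micasm_stop("micasm_format_error",
                    "count matrix must have sample row names and OTU column names")
    if (anyDuplicated(rownames(counts)))
        micasm_stop("micasm_format_error", "duplicate sample ids: %s",
                    paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                          collapse = ", "))
    if (anyDuplicated(colnames(counts)))
        micasm_stop("micasm_format_error", "duplicate OTU ids: %s",
                    paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                          collapse = ", "))
    if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
        any(counts != round(counts)))
        micasm_stop("micasm_format_error",
                    "counts must be non-negative integers")
    storage.mode(counts) <- "integer"
    missing_cols <- setdiff(REQUIRED_METADATA_COLS, names(metadata))
    if (length(missing_cols))
        micasm_stop("micasm_format_error", "metadata lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
    missing_samples <- setdiff(rownames(counts), metadata$sample_id)
    if (length(missing_samples))
        micasm_stop("micasm_format_error",
                    "samples absent from metadata: %s",
                    paste(missing_samples, collapse = ", "))
    metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
    structure(list(counts = counts, metadata = metadata),
              class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
    cat(sprintf("community_table: %d samples x %d OTUs\n",
                nrow(x$counts), ncol(x$counts)))
    cat(sprintf("  treatments: %s\n",
                paste(unique(x$metadata$treatment), collapse = ", ")))
    cat(sprintf("  batches:    %s\n",
                paste(batch_levels(x$metadata$batch), collapse = ", ")))
    cat(sprintf("  total reads: %d (min sample %d, max %d)\n",
                sum(x$counts), min(rowSums(x$counts)),
                max(rowSums(x$counts))))
    invisible(x)
}

# Batch labels ordered by numeric suffix (B1, B2, ..., B10), not
# lexically.
batch_levels <- function(batches) {
    u <- unique(as.character(batches))
    u[order(as.numeric(sub("^\\D*", "", u)))]
}

# Sampling day of a batch: communities are sampled at the end of the
# 5-day incubation, just before the next inoculation.
batch_day <- function(batch, batch_days = 5) {
    as.numeric(sub("^\\D*", "", as.character(batch))) * batch_days
}

#' Read / write a community table
#'
#' TSV on disk: the count file has a \code{sample_id} first column and
#' one column per OTU; the metadata file has the columns
#' \code{sample_id}, \code{treatment}, \code{batch}, \code{replicate},
#' \code{day}.
#'
#' @param counts_path,metadata_path file paths.
#' @return \code{read_community} returns a \code{\link{community_table}}.
#' @export
read_community <- function(counts_path, metadata_path) {
    raw <- suppressWarnings(
        read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character")))
    if (names(raw)[1] != "sample_id")
        micasm_stop("micasm_format_error",
                    "count table must start with a sample_id column")
    counts <- as.matrix(raw[, -1, drop = FALSE])
    rownames(counts) <- raw$sample_id
    # label columns are read as character so that labels like "T" are
    # not coerced to logicals
    metadata <- suppressWarnings(
        read.delim(metadata_path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  treatment = "character",
                                  batch = "character")))
    community_table(counts, metadata)
}

#' @param table a \code{\link{community_table}}.
#' @rdname read_community
#' @export
write_community <- function(table, counts_path, metadata_path) {
    stopifnot(inherits(table, "community_table"))
    df <- data.frame(sample_id = rownames(table$counts), table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, counts_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(c(counts_path, metadata_path))
}

#' Read a rooted phylogeny
#'
#' Thin validated wrapper over \code{\link[ape]{read.tree}}: the tree
#' must parse, be rooted, have unique tip labels and branch lengths.
#'
#' @param path Newick file.
#' @return an \code{ape} \code{phylo} object.
#' @export
read_tree <- function(path) {
    tree <- ape::read.tree(path)
    if (is.null(tree))
        micasm_stop("micasm_format_error", "could not parse Newick file %s",
                    path)
    validate_tree(tree)
    tree
}

validate_tree <- function(tree) {
    if (!inherits(tree, "phylo"))
        micasm_stop("micasm_format_error", "not a phylo object")
    if (anyDuplicated(tree$tip.label))
        micasm_stop("micasm_format_error", "duplicate tip labels in tree")
    if (is.null(tree$edge.length))
        micasm_stop("micasm_format_error", "tree has no branch lengths")
    if (!ape::is.rooted(tree))
        micasm_stop("micasm_format_error", "tree must be rooted")
    invisible(tree)
}

#' Patristic (cophenetic) distance matrix of a tree
#'
#' Tip-to-tip distances as sums of branch lengths along the connecting
#' path; symmetric with a zero diagonal.
#'
#' @param tree a rooted \code{phylo} with branch lengths.
#' @param otu_ids optional ids that must all be tips; missing ids raise
#'   an error listing them.
#' @return numeric matrix, tips x tips.
#' @export
patristic_matrix <- function(tree, otu_ids = NULL) {
    validate_tree(tree)
    if (!is.null(otu_ids)) {
        absent <- setdiff(otu_ids, tree$tip.label)
        if (length(absent))
            micasm_stop("micasm_missing_taxa",
                        "OTU ids absent from tree: %s",
                        paste(absent, collapse = ", "))
    }
    D <- stats::cophenetic(tree)
    if (!is.null(otu_ids)) D <- D[otu_ids, otu_ids, drop = FALSE]
    D
}

#' Read / write a micropollutant concentration time series
#'
#' TSV with columns \code{microcosm_id}, \code{compound}, \code{day},
#' \code{concentration_ugL}; any further columns (treatment, batch,
#' replicate) are preserved. Unknown compound labels are kept as-is.
#'
#' @param path TSV file.
#' @return data.frame of typed records.
#' @export
read_chem <- function(path) {
    chem <- suppressWarnings(
        read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(microcosm_id = "character",
                                  compound = "character",
                                  treatment = "character",
                                  batch = "character")))
    need <- c("microcosm_id", "compound", "day", "concentration_ugL")
    missing_cols <- setdiff(need, names(chem))
    if (length(missing_cols))
        micasm_stop("micasm_format_error", "chemistry file lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
    if (anyNA(chem$concentration_ugL) ||
        !is.numeric(chem$concentration_ugL) ||
        any(chem$concentration_ugL < 0))
        micasm_stop("micasm_format_error",
                    "concentrations must be non-negative numbers")
    chem
}

#' @param chem chemistry data.frame.
#' @rdname read_chem
#' @export
write_chem <- function(chem, path) {
    write.table(chem, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a 16S copy-number map
#'
#' TSV with columns \code{otu_id} and \code{copy_number}; values must be
#' >= 1 (a 16S-bearing genome has at least one operon). The map may be
#' partial: OTUs without an rrnDB-style assignment are simply absent.
#'
#' @param path TSV file.
#' @return named numeric vector (OTU id -> copy number).
#' @export
read_copy_numbers <- function(path) {
    df <- suppressWarnings(
        read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(otu_id = "character")))
    missing_cols <- setdiff(c("otu_id", "copy_number"), names(df))
    if (length(missing_cols))
        micasm_stop("micasm_format_error", "copy-number file lacks columns: %s",
                    paste(missing_cols, collapse = ", "))
    if (anyNA(df$copy_number) || !is.numeric(df$copy_number) ||
        any(df$copy_number < 1))
        micasm_stop("micasm_format_error", "copy numbers must be >= 1")
    if (anyDuplicated(df$otu_id))
        micasm_stop("micasm_format_error", "duplicate OTU ids in copy-number map")
    setNames(df$copy_number, df$otu_id)
}

#' @param map named numeric vector of copy numbers.
#' @rdname read_copy_numbers
#' @export
write_copy_numbers <- function(map, path) {
    write.table(data.frame(otu_id = names(map), copy_number = unname(map)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
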