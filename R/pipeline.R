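# One-call orchestration: simulate (or load) -> rarefy -> growth phases
# -> assembly partitioning -> dissimilarity-overlap -> ecological groups
# -> removal statistics, under a single seed, with a machine-readable
# report.

#' Run configuration for the full pipeline
#'
#' Exactly one of \code{sim} (arguments for \code{\link{sim_config}})
#' or \code{inputs} (named file paths: \code{counts}, \code{metadata},
#' \code{tree}, \code{copy_numbers}, \code{chem}) must be supplied.
#'
#' @param sim named list passed to \code{\link{sim_config}} (its seed
#'   defaults to the run seed).
#' @param inputs named list of input file paths.
#' @param rarefy_depth \code{"min"} or an integer depth.
#' @param n_null randomizations for the assembly null models.
#' @param n_boot bootstrap replicates for the DOC slope.
#' @param K number of growth phases to infer.
#' @param alpha adjusted significance level for ecological grouping.
#' @param prevalence_min prevalence filter for ecological grouping.
#' @param phases \code{"infer"} (cluster the copy-number profiles) or a
#'   named batch -> phase vector such as \code{\link{paper_phases}()}.
#' @param control_label treatment label of the control arm.
#' @param seed integer seed propagated to every stochastic stage.
#' @param out_dir optional directory; when set, stage outputs (TSV) and
#'   the JSON report are written there.
#' @return validated list of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, inputs = NULL, rarefy_depth = "min",
                       n_null = 999, n_boot = 1000, K = 3, alpha = 0.05,
                       prevalence_min = 0.1, phases = "infer",
                       control_label = "Control", seed = 1,
                       out_dir = NULL) {
    if (is.null(sim) == is.null(inputs))
        micasm_stop("micasm_invalid_argument",
                    "exactly one of `sim` or `inputs` must be given")
    if (!is.null(inputs)) {
        need <- c("counts", "metadata", "tree", "copy_numbers", "chem")
        missing_in <- setdiff(need, names(inputs))
        if (length(missing_in))
            micasm_stop("micasm_invalid_argument",
                        "inputs lacks paths: %s",
                        paste(missing_in, collapse = ", "))
    }
    stopifnot(is_count(n_null, 99), is_count(n_boot, 1), is_count(K, 1),
              is_prob(alpha), is_prob(prevalence_min))
    structure(list(sim = sim, inputs = inputs,
                   rarefy_depth = rarefy_depth, n_null = n_null,
                   n_boot = n_boot, K = K, alpha = alpha,
                   prevalence_min = prevalence_min, phases = phases,
                   control_label = control_label, seed = seed,
                   out_dir = out_dir),
              class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   \code{\link{run_config}}.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$sim$treatments))
        y$sim$treatments <- lapply(y$sim$treatments, unlist)
    if (!is.null(y$phases) && !identical(y$phases, "infer"))
        y$phases <- unlist(y$phases)
    do.call(run_config, y)
}

stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        micasm_stop("micasm_stage_error", "stage '%s' failed: %s", name,
                    conditionMessage(e))
    })
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order under one seed; the report is
#' identical for identical configuration and seed.
#'
#' @param config a \code{\link{run_config}} (or a YAML path readable by
#'   \code{\link{read_run_config}}).
#' @return object of class \code{micasm_report}: list with elements
#'   \code{phases}, \code{assembly} (per-treatment
#'   \code{assembly_result}s), \code{doc} (per-treatment
#'   \code{doc_result}s), \code{turnover}, \code{removal},
#'   \code{groups}, \code{group_summary}, \code{config_digest}.
#' @export
run_all <- function(config) {
    if (is.character(config)) config <- read_run_config(config)
    stopifnot(inherits(config, "run_config"))
    set.seed(config$seed)
    if (!is.null(config$sim)) {
        sim_args <- config$sim
        if (is.null(sim_args$seed)) sim_args$seed <- config$seed
        sim <- stage("simulate",
                     simulate_experiment(do.call(sim_config, sim_args)))
        community <- sim$community
        tree <- sim$tree
        chem <- sim$chem
        cn_map <- stage("copy_numbers", simulate_copy_numbers(tree))
    } else {
        community <- stage("load",
                           read_community(config$inputs$counts,
                                          config$inputs$metadata))
        tree <- stage("load", read_tree(config$inputs$tree))
        chem <- stage("load", read_chem(config$inputs$chem))
        cn_map <- stage("load",
                        read_copy_numbers(config$inputs$copy_numbers))
    }
    # controls are never silently dropped: rarefy() errors if any sample
    # (control or otherwise) falls below the requested depth
    rarefied <- stage("rarefy",
                      rarefy(community, depth = config$rarefy_depth))
    treatments <- setdiff(unique(rarefied$metadata$treatment),
                          config$control_label)
    profiles <- stage("phases",
                      batch_copy_profiles(rarefied, cn_map,
                                          config$control_label))
    phases <- if (identical(config$phases, "infer"))
        stage("phases", phase_clustering(profiles, K = config$K))
    else config$phases
    assembly <- stage("assembly", lapply(setNames(nm = treatments),
        function(tr) process_fractions(rarefied, tree, tr, phases,
                                       config$control_label,
                                       n_null = config$n_null)))
    doc <- stage("doc", lapply(setNames(nm = treatments),
        function(tr) doc_analysis(rarefied, tr,
                                  n_boot = config$n_boot)))
    turnover <- stage("turnover", lapply(setNames(nm = treatments),
        function(tr) turnover_regression(rarefied, tr,
                                         config$control_label)))
    removal <- NULL; removal_summary <- NULL
    if (nrow(chem)) {
        removal <- stage("removal", removal_rate(chem))
        removal_summary <- stage("removal", summarize_removal(removal))
    }
    groups <- stage("groups", do.call(rbind, lapply(treatments,
        function(tr) classify_otus(rarefied, tr, phases,
                                   alpha = config$alpha,
                                   prevalence_min = config$prevalence_min))))
    report <- structure(
        list(phases = phases,
             copy_number_profiles = profiles,
             assembly = assembly,
             doc = doc,
             turnover = turnover,
             removal = removal,
             removal_summary = removal_summary,
             groups = groups,
             group_summary = summarize_groups(groups),
             n_samples = nrow(rarefied$counts),
             rarefy_depth = min(rowSums(community$counts)),
             seed = config$seed),
        class = "micasm_report")
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
}

#' @export
print.micasm_report <- function(x, ...) {
    cat(sprintf("micasm_report: %d samples, seed %d\n", x$n_samples,
                x$seed))
    cat("growth phases:\n"); print(x$phases)
    for (tr in names(x$assembly)) print(x$assembly[[tr]])
    for (tr in names(x$doc)) print(x$doc[[tr]])
    if (!is.null(x$removal_summary)) {
        cat("mean removal (%):\n")
        print(x$removal_summary$summary, row.names = FALSE)
    }
    cat("ecological groups:\n"); print(x$group_summary)
    invisible(x)
}

# Flatten the report into plain lists/data.frames for JSON.
report_to_list <- function(report) {
    list(seed = report$seed,
         n_samples = report$n_samples,
         rarefy_depth = report$rarefy_depth,
         phases = as.list(unclass(report$phases)),
         process_fractions = do.call(rbind, lapply(report$assembly,
                                                   `[[`, "fractions")),
         doc = lapply(report$doc, function(d)
             d[c("cutoff", "slope", "intercept", "fraction_negative",
                 "n_boot", "n_pairs")]),
         turnover = lapply(report$turnover, function(t)
             t[c("slope", "intercept", "p_value")]),
         removal_summary = report$removal_summary$summary,
         group_summary = cbind(treatment =
                                   rownames(report$group_summary),
                               report$group_summary))
}

#' Write a pipeline report to disk
#'
#' JSON report plus TSVs of the pair-level assembly results, DOC points,
#' removal records and group calls.
#'
#' @param report a \code{micasm_report}.
#' @param out_dir output directory (created if needed).
#' @return the report path, invisibly.
#' @export
write_report <- function(report, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = 10, dataframe = "rows")
    for (tr in names(report$assembly))
        write.table(report$assembly[[tr]]$pairs,
                    file.path(out_dir, sprintf("assembly_pairs_%s.tsv", tr)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    for (tr in names(report$doc))
        write.table(report$doc[[tr]]$points,
                    file.path(out_dir, sprintf("doc_points_%s.tsv", tr)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(report$removal))
        write.table(report$removal, file.path(out_dir, "removal.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$groups, file.path(out_dir, "group_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
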