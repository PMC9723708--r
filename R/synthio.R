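# Synthetic serial-transfer microcosm experiments: a random coalescent
# phylogeny, phylogenetically conserved tolerance traits, latent
# community dynamics with selection imposed by subsidy (carbon-source)
# and stress (growth-inhibiting) micropollutants, first-order chemical
# decay coupled to degrader/tolerant biomass, 10% serial transfer with
# demographic bottlenecks, and multinomial read sampling. Every stage of
# the downstream analysis can be exercised against this generator's
# ground truth.

# Which response a compound elicits: subsidy compounds are consumed as
# carbon sources by degrader taxa, stress compounds inhibit sensitive
# (low-tolerance) taxa. BPS/TCC are the lower-concentration analogs of
# BPA/TCS and share their response type.
DEFAULT_COMPOUND_TYPES <- c(BPA = "subsidy", BPS = "subsidy",
                            TCS = "stress", TCC = "stress")

#' Treatment arms of the reference design
#'
#' Control (no micropollutants), single compounds BPA and TCS at
#' 1 ug/L, mixture MI (BPA + TCS, 1 ug/L each) and mixture MII
#' (BPA 1, BPS 0.1, TCS 1, TCC 0.1 ug/L; the analogs an order of
#' magnitude below their parent compounds).
#'
#' @return named list of named concentration vectors (ug/L).
#' @export
default_treatments <- function() {
    list(Control = c(),
         BPA = c(BPA = 1),
         TCS = c(TCS = 1),
         MI  = c(BPA = 1, TCS = 1),
         MII = c(BPA = 1, BPS = 0.1, TCS = 1, TCC = 0.1))
}

#' Configuration of a synthetic serial-transfer experiment
#'
#' Defaults reproduce the reference design: 5 treatment arms x 3
#' replicates x 7 batches of 5 days, 10% transfer (60 mL inoculum into
#' 600 mL total), chemistry recorded at days 0/2/5 of every batch,
#' multinomial sequencing at a nominal depth of 36000 reads.
#'
#' @param n_otus number of OTUs in the regional pool.
#' @param n_batches serial-transfer batches (default 7).
#' @param batch_days days per batch (default 5).
#' @param treatments named list of compound concentration vectors
#'   (ug/L); see \code{\link{default_treatments}}.
#' @param n_replicates replicate bottles per arm (default 3).
#' @param inoculum_volume,total_volume mL; their ratio is the transfer
#'   fraction (defaults 60, 600).
#' @param transfer_fraction dilution at each transfer; must equal
#'   \code{inoculum_volume / total_volume} when both are given.
#' @param sequencing_depth nominal reads per sample (default 36000).
#' @param depth_jitter relative library-size spread: each sample's depth
#'   is uniform in \code{[1 - j, 1 + j] * sequencing_depth} (default
#'   0.1; set 0 for exactly even depths).
#' @param selection_strength dimensionless >= 0; 0 switches the
#'   generator to the neutral regime (pure drift).
#' @param trait_bm_sigma Brownian-motion rate of the tolerance trait on
#'   the tree (per unit branch length; default 1).
#' @param degrader_fraction fraction of OTUs able to consume subsidy
#'   compounds (default 0.2).
#' @param decay_coupling per-day chemical removal coefficient per unit
#'   of active biomass fraction (default 0.8).
#' @param stress_decay_scale multiplier < 1 applied to
#'   \code{decay_coupling} for the co-metabolic, tolerance-gated decay
#'   of stress compounds (default 0.45).
#' @param subsidy_gain,stress_penalty per-day growth-rate modifiers per
#'   ug/L of compound (defaults 0.5, 1).
#' @param base_growth per-day logistic growth rate of total biomass
#'   (default 1.2: regrowth to carrying capacity within one batch).
#' @param effective_size number of cells in the latent pool resampled
#'   daily (demographic drift; default 1e4). \code{Inf} disables drift.
#' @param lognormal_sigma log-scale sd of the initial rank-abundance
#'   distribution (default 1.5).
#' @param compound_types named character vector mapping compound to
#'   \code{"subsidy"} or \code{"stress"}.
#' @param abiotic if TRUE, bottles contain no cells: chemistry is
#'   emitted but no community (the abiotic control experiment).
#' @param seed integer master seed; every output is reproducible from
#'   it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_otus = 150, n_batches = 7, batch_days = 5,
                       treatments = default_treatments(),
                       n_replicates = 3,
                       inoculum_volume = 60, total_volume = 600,
                       transfer_fraction = inoculum_volume / total_volume,
                       sequencing_depth = 36000, depth_jitter = 0.1,
                       selection_strength = 1, trait_bm_sigma = 1,
                       degrader_fraction = 0.2, decay_coupling = 0.8,
                       stress_decay_scale = 0.45, subsidy_gain = 0.5,
                       stress_penalty = 1, base_growth = 1.2,
                       effective_size = 1e4, lognormal_sigma = 1.5,
                       compound_types = DEFAULT_COMPOUND_TYPES,
                       abiotic = FALSE, seed = 1) {
    if (!is_count(n_otus, min = 2))
        micasm_stop("micasm_invalid_argument", "n_otus must be >= 2")
    stopifnot(is_count(n_batches, 1), is_count(n_replicates, 1),
              is_count(sequencing_depth, 1),
              batch_days >= 1, batch_days == round(batch_days))
    if (inoculum_volume <= 0 || total_volume <= 0)
        micasm_stop("micasm_invalid_argument", "volumes must be positive")
    if (!is_prob(transfer_fraction) || transfer_fraction == 0 ||
        transfer_fraction == 1)
        micasm_stop("micasm_invalid_argument",
                    "transfer_fraction must lie in (0, 1)")
    if (abs(transfer_fraction - inoculum_volume / total_volume) > 1e-8)
        micasm_stop("micasm_invalid_argument",
                    "transfer_fraction must equal inoculum_volume / total_volume")
    if (!is_prob(degrader_fraction))
        micasm_stop("micasm_invalid_argument",
                    "degrader_fraction must lie in [0, 1]")
    if (selection_strength < 0 || trait_bm_sigma < 0)
        micasm_stop("micasm_invalid_argument",
                    "selection_strength and trait_bm_sigma must be >= 0")
    if (is.null(names(treatments)) || anyDuplicated(names(treatments)))
        micasm_stop("micasm_invalid_argument",
                    "treatments must be uniquely named")
    for (arm in names(treatments)) {
        comp <- treatments[[arm]]
        if (!length(comp)) next
        if (any(comp < 0))
            micasm_stop("micasm_invalid_argument",
                        "negative concentration in arm %s", arm)
        untyped <- setdiff(names(comp), names(compound_types))
        if (length(untyped))
            micasm_stop("micasm_invalid_argument",
                        "compounds without a response type: %s",
                        paste(untyped, collapse = ", "))
    }
    structure(list(n_otus = n_otus, n_batches = n_batches,
                   batch_days = batch_days, treatments = treatments,
                   n_replicates = n_replicates,
                   inoculum_volume = inoculum_volume,
                   total_volume = total_volume,
                   transfer_fraction = transfer_fraction,
                   sequencing_depth = sequencing_depth,
                   depth_jitter = depth_jitter,
                   selection_strength = selection_strength,
                   trait_bm_sigma = trait_bm_sigma,
                   degrader_fraction = degrader_fraction,
                   decay_coupling = decay_coupling,
                   stress_decay_scale = stress_decay_scale,
                   subsidy_gain = subsidy_gain,
                   stress_penalty = stress_penalty,
                   base_growth = base_growth,
                   effective_size = effective_size,
                   lognormal_sigma = lognormal_sigma,
                   compound_types = compound_types,
                   abiotic = abiotic, seed = seed),
              class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
    cat(sprintf("sim_config: %d OTUs, %d arms x %d replicates x %d batches (%g-day), %s regime\n",
                x$n_otus, length(x$treatments), x$n_replicates,
                x$n_batches,
                x$batch_days,
                if (x$selection_strength == 0) "neutral" else "selection"))
    cat(sprintf("  transfer %.0f%%, depth %d, effective size %s, seed %d\n",
                100 * x$transfer_fraction, x$sequencing_depth,
                format(x$effective_size), x$seed))
    invisible(x)
}

#' Simulate a random coalescent phylogeny
#'
#' Lineages are merged pairwise uniformly at random with exponential
#' waiting times (\code{\link[ape]{rcoal}}); tips are relabelled
#' \code{OTU_0001 ...}. Rooted, binary, all branch lengths positive.
#'
#' @param n_otus number of tips (>= 2).
#' @param seed optional integer seed.
#' @return an \code{ape} \code{phylo} object.
#' @export
simulate_tree <- function(n_otus, seed = NULL) {
    if (!is_count(n_otus, min = 2))
        micasm_stop("micasm_invalid_argument", "n_otus must be >= 2")
    tree <- with_seed(seed, ape::rcoal(n_otus))
    tree$tip.label <- sprintf("OTU_%04d", seq_len(n_otus))
    tree
}

#' Simulate tolerance and degrader traits on a tree
#'
#' Tolerance evolves by Brownian motion along the branches (rate
#' \code{trait_bm_sigma}), so close relatives have similar stress
#' tolerance -- the phylogenetic signal that makes selection visible to
#' beta-NTI. Degrader status (ability to consume subsidy compounds) is
#' assigned to a fixed fraction of OTUs drawn uniformly at random.
#'
#' @param tree a \code{phylo} object.
#' @param trait_bm_sigma Brownian-motion rate (0 = every OTU equals the
#'   root value).
#' @param degrader_fraction fraction of OTUs flagged as degraders.
#' @param seed optional integer seed.
#' @return list with \code{tolerance} (named numeric, raw BM values) and
#'   \code{degrader} (named logical).
#' @export
simulate_traits <- function(tree, trait_bm_sigma = 1,
                            degrader_fraction = 0.2, seed = NULL) {
    validate_tree(tree)
    if (!is_prob(degrader_fraction))
        micasm_stop("micasm_invalid_argument",
                    "degrader_fraction must lie in [0, 1]")
    with_seed(seed, {
        tol <- ape::rTraitCont(tree, model = "BM", sigma = trait_bm_sigma,
                               root.value = 0)
        n <- length(tree$tip.label)
        deg <- setNames(logical(n), tree$tip.label)
        k <- round(degrader_fraction * n)
        if (k > 0) deg[sample.int(n, k)] <- TRUE
        list(tolerance = tol, degrader = deg)
    })
}

# Map a raw trait onto (0, 1) by its empirical z-score; constant traits
# map to 0.5.
to_unit <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(setNames(rep(0.5, length(x)),
                                                 names(x)))
    pnorm((x - mean(x)) / s)
}

#' Simulate a 16S copy-number map
#'
#' Integer copy numbers in [1, 15] (the observed range of rRNA operon
#' counts) with phylogenetic autocorrelation: a Brownian trait is
#' rank-mapped onto the integer range, so related OTUs get similar
#' values. A fraction of OTUs can be left unassigned (dropped from the
#' map) to emulate incomplete database coverage.
#'
#' @param tree a \code{phylo} object.
#' @param seed optional integer seed.
#' @param autocorrelated if FALSE, copy numbers are i.i.d. uniform
#'   integers in [1, 15].
#' @param unassigned_fraction i.i.d. probability that an OTU is missing
#'   from the map (default 0).
#' @return named numeric vector (assigned OTUs only).
#' @export
simulate_copy_numbers <- function(tree, seed = NULL, autocorrelated = TRUE,
                                  unassigned_fraction = 0) {
    validate_tree(tree)
    if (!is_prob(unassigned_fraction))
        micasm_stop("micasm_invalid_argument",
                    "unassigned_fraction must lie in [0, 1]")
    with_seed(seed, {
        n <- length(tree$tip.label)
        if (autocorrelated) {
            z <- ape::rTraitCont(tree, model = "BM", sigma = 1,
                                 root.value = 0)
            u <- (rank(z, ties.method = "first") - 0.5) / n
            cn <- 1 + floor(u * 15)
        } else {
            cn <- sample.int(15, n, replace = TRUE)
        }
        cn <- setNames(pmin(15, pmax(1, as.numeric(cn))), tree$tip.label)
        if (unassigned_fraction > 0)
            cn <- cn[runif(n) >= unassigned_fraction]
        cn
    })
}

# Per-batch chemistry integration: daily first-order decay of each
# compound driven by the biomass fraction of the responding guild.
# `activity` is a function(day) -> named vector of per-compound decay
# rates (per day). Returns concentrations recorded at the given days.
chem_batch <- function(spike, activity, batch_days = 5,
                       record_days = c(0, 2, 5)) {
    conc <- spike
    rec <- list()
    if (0 %in% record_days) rec[["0"]] <- conc
    for (d in seq_len(batch_days)) {
        conc <- conc * exp(-activity(d))
        if (d %in% record_days) rec[[as.character(d)]] <- conc
    }
    rec
}

# Logistic biomass trajectory over one batch (fraction of carrying
# capacity), starting from the transferred fraction.
biomass_curve <- function(b0, rate, days) {
    b <- numeric(days + 1)
    b[1] <- b0
    for (d in seq_len(days))
        b[d + 1] <- b[d] + rate * b[d] * (1 - b[d])
    b
}

#' Simulate a full serial-transfer micropollutant experiment
#'
#' One bottle per (treatment, replicate, batch). Within a batch, each
#' day: (i) per-OTU growth-rate modifiers are applied to the latent
#' composition -- degraders gain \code{subsidy_gain} per ug/L of subsidy
#' compound, low-tolerance taxa lose \code{stress_penalty * (1 -
#' tolerance)} per ug/L of stress compound, all scaled by
#' \code{selection_strength}; (ii) the pool is resampled multinomially
#' at \code{effective_size} cells (demographic drift); (iii) compound
#' concentrations decay as \eqn{dC/dt = -k \cdot a(t) \cdot C} where
#' \eqn{a(t)} is the biomass fraction of the responding guild (degraders
#' for subsidy compounds; tolerance-weighted biomass, scaled by
#' \code{stress_decay_scale}, for stress compounds). At each transfer,
#' cells are binomially thinned to \code{transfer_fraction} and regrown;
#' compounds are freshly re-spiked. Sequencing draws each sample's reads
#' multinomially from the end-of-batch composition. The control arm (no
#' compounds) is always part of the design.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{microcosm_sim} with elements
#'   \code{community} (a \code{\link{community_table}}; NULL when
#'   \code{abiotic}), \code{chem} (chemistry data.frame with columns
#'   microcosm_id, treatment, replicate, batch, compound, day,
#'   concentration_ugL), \code{tree}, \code{truth} (list: tolerance,
#'   tolerance01, degrader, regime, chem_params, latent array
#'   [sample, day 0/2/5, otu]), and \code{config}.
#' @export
simulate_experiment <- function(config) {
    stopifnot(inherits(config, "sim_config"))
    cfg <- config
    with_seed(cfg$seed, {
        tree <- simulate_tree(cfg$n_otus)
        traits <- simulate_traits(tree, cfg$trait_bm_sigma,
                                  cfg$degrader_fraction)
        tol01 <- to_unit(traits$tolerance)
        deg <- traits$degrader
        otus <- tree$tip.label
        n <- cfg$n_otus
        # shared initial inoculum: lognormal rank-abundance profile
        p0 <- exp(rnorm(n, 0, cfg$lognormal_sigma))
        p0 <- p0 / sum(p0)
        ne <- cfg$effective_size
        finite_ne <- is.finite(ne)
        bio <- biomass_curve(cfg$transfer_fraction, cfg$base_growth,
                             cfg$batch_days)
        record_days <- sort(unique(pmin(c(0, 2, cfg$batch_days),
                                        cfg$batch_days)))
        arms <- names(cfg$treatments)
        sample_ids <- character(0)
        meta_rows <- list(); count_rows <- list(); chem_rows <- list()
        latent <- list()
        for (arm in arms) {
            spike <- cfg$treatments[[arm]]
            types <- cfg$compound_types[names(spike)]
            for (rep_i in seq_len(cfg$n_replicates)) {
                # inoculation of B1 from the shared source community
                p <- if (cfg$abiotic) rep(0, n)
                     else if (finite_ne) rmultinom(1, ne, p0)[, 1] / ne
                     else p0
                for (b in seq_len(cfg$n_batches)) {
                    sid <- sprintf("%s.%d.B%d", arm, rep_i, b)
                    conc <- spike
                    lat <- matrix(NA_real_, length(record_days), n,
                                  dimnames = list(as.character(record_days),
                                                  otus))
                    if (0 %in% record_days) lat["0", ] <- p
                    if (length(conc))
                        for (cmp in names(conc))
                            chem_rows[[length(chem_rows) + 1L]] <-
                                data.frame(microcosm_id = sid,
                                           treatment = arm,
                                           replicate = rep_i,
                                           batch = paste0("B", b),
                                           compound = cmp, day = 0,
                                           concentration_ugL = conc[[cmp]])
                    for (d in seq_len(cfg$batch_days)) {
                        if (!cfg$abiotic && sum(p) > 0) {
                            if (cfg$selection_strength > 0 && length(conc)) {
                                csub <- sum(conc[types == "subsidy"])
                                cstr <- sum(conc[types == "stress"])
                                g <- exp(cfg$selection_strength *
                                         (cfg$subsidy_gain * deg * csub -
                                          cfg$stress_penalty *
                                          (1 - tol01) * cstr))
                                p <- p * g
                                p <- p / sum(p)
                            }
                            if (finite_ne)
                                p <- rmultinom(1, ne, p)[, 1] / ne
                        }
                        # chemical decay over this day
                        if (length(conc)) {
                            bmid <- (bio[d] + bio[d + 1]) / 2
                            act <- ifelse(types == "subsidy",
                                          cfg$decay_coupling * sum(p * deg),
                                          cfg$decay_coupling *
                                          cfg$stress_decay_scale *
                                          sum(p * tol01))
                            if (cfg$abiotic) act[] <- 0
                            conc <- conc * exp(-act * bmid)
                            if (d %in% record_days)
                                for (cmp in names(conc))
                                    chem_rows[[length(chem_rows) + 1L]] <-
                                        data.frame(microcosm_id = sid,
                                                   treatment = arm,
                                                   replicate = rep_i,
                                                   batch = paste0("B", b),
                                                   compound = cmp, day = d,
                                                   concentration_ugL =
                                                       conc[[cmp]])
                        }
                        if (d %in% record_days && !cfg$abiotic)
                            lat[as.character(d), ] <- p
                    }
                    latent[[sid]] <- lat
                    if (!cfg$abiotic) {
                        jit <- if (cfg$depth_jitter > 0)
                            runif(1, 1 - cfg$depth_jitter,
                                  1 + cfg$depth_jitter) else 1
                        depth <- max(1L, as.integer(round(
                            cfg$sequencing_depth * jit)))
                        reads <- rmultinom(1, depth, p)[, 1]
                        count_rows[[sid]] <- reads
                        meta_rows[[sid]] <- data.frame(
                            sample_id = sid, treatment = arm,
                            batch = paste0("B", b), replicate = rep_i,
                            day = b * cfg$batch_days)
                        sample_ids <- c(sample_ids, sid)
                    }
                    # serial transfer: binomial thinning, then regrowth
                    if (b < cfg$n_batches && !cfg$abiotic && sum(p) > 0) {
                        if (finite_ne) {
                            cells <- round(p * ne)
                            trans <- rbinom(n, cells,
                                            cfg$transfer_fraction)
                            if (sum(trans) == 0)
                                trans <- cells  # vanishing inoculum guard
                            p <- rmultinom(1, ne, trans / sum(trans))[, 1] / ne
                        }
                        # infinite pool: dilution leaves composition as-is
                    }
                }
            }
        }
        community <- NULL
        if (!cfg$abiotic) {
            counts <- do.call(rbind, count_rows)
            rownames(counts) <- sample_ids
            colnames(counts) <- otus
            community <- community_table(counts,
                                         do.call(rbind, meta_rows))
        }
        chem <- if (length(chem_rows)) do.call(rbind, chem_rows)
                else data.frame(microcosm_id = character(0),
                                treatment = character(0),
                                replicate = integer(0),
                                batch = character(0),
                                compound = character(0),
                                day = numeric(0),
                                concentration_ugL = numeric(0))
        rownames(chem) <- NULL
        lat_arr <- array(NA_real_,
                         dim = c(length(latent), length(record_days), n),
                         dimnames = list(names(latent),
                                         as.character(record_days), otus))
        for (i in seq_along(latent)) lat_arr[i, , ] <- latent[[i]]
        truth <- list(tolerance = traits$tolerance, tolerance01 = tol01,
                      degrader = deg,
                      regime = if (cfg$selection_strength == 0) "neutral"
                               else "selection",
                      chem_params = list(
                          decay_coupling = cfg$decay_coupling,
                          stress_decay_scale = cfg$stress_decay_scale,
                          compound_types = cfg$compound_types),
                      latent = lat_arr)
        structure(list(community = community, chem = chem, tree = tree,
                       truth = truth, config = cfg),
                  class = "microcosm_sim")
    })
}

#' @export
print.microcosm_sim <- function(x, ...) {
    cat(sprintf("microcosm_sim (%s regime, seed %d)\n",
                x$truth$regime, x$config$seed))
    if (!is.null(x$community)) print(x$community)
    cat(sprintf("  chemistry records: %d\n", nrow(x$chem)))
    invisible(x)
}

#' Simulate communities with shared ("universal") dynamics
#'
#' Every sample is a noisy multinomial draw around one latent
#' composition, with per-sample noise levels spanning
#' \code{noise_range}: low-noise pairs share more taxa (high overlap)
#' and are less dissimilar, so the dissimilarity-overlap relationship is
#' negative by construction. Useful as a positive control for
#' \code{\link{doc_analysis}}.
#'
#' @param n_samples number of samples (default 21, one treatment arm of
#'   the reference design).
#' @param n_otus pool size.
#' @param noise_range c(min, max) log-scale perturbation sd across
#'   samples.
#' @param depth reads per sample.
#' @param seed optional integer seed.
#' @param lognormal_sigma base-composition spread.
#' @return a \code{\link{community_table}} with a single treatment
#'   \code{"U"}.
#' @export
simulate_universal_community <- function(n_samples = 21, n_otus = 150,
                                         noise_range = c(0.2, 1.5),
                                         depth = 5000, seed = NULL,
                                         lognormal_sigma = 1.5) {
    stopifnot(is_count(n_samples, 3), is_count(n_otus, 2),
              is_count(depth, 1))
    with_seed(seed, {
        base <- exp(rnorm(n_otus, 0, lognormal_sigma))
        base <- base / sum(base)
        noise <- seq(noise_range[1], noise_range[2],
                     length.out = n_samples)
        counts <- t(vapply(noise, function(s) {
            p <- base * exp(rnorm(n_otus, 0, s))
            rmultinom(1, depth, p / sum(p))[, 1]
        }, integer(n_otus)))
        rownames(counts) <- sprintf("U.%02d", seq_len(n_samples))
        colnames(counts) <- sprintf("OTU_%04d", seq_len(n_otus))
        md <- data.frame(sample_id = rownames(counts), treatment = "U",
                         batch = paste0("B", rep(1:7,
                                                 length.out = n_samples)),
                         replicate = seq_len(n_samples), day = 5)
        community_table(counts, md)
    })
}
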