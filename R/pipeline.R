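.defaultConfig <- function() {
    list(selection = "name CA", n_segments = 100L, segment_length = 20L,
         take = "tail", variance_fraction = 0.90, fixed_m = NULL,
         domain_threshold = 0.0015, threshold_grid = NULL,
         min_domain_size = 3L, min_largest_fraction = 0.10,
         superpose_reference = "mean",
         contact_cutoffs = as.list(.defaultCutoffs), seed = 1L)
}

.loadConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop("config file not found: ", config)
        ext <- tolower(tools::file_ext(config))
        config <- if (ext %in% c("yml", "yaml")) {
            if (!requireNamespace("yaml", quietly = TRUE))
                stop("YAML configs need the 'yaml' package; use JSON instead")
            yaml::read_yaml(config)
        } else jsonlite::read_json(config, simplifyVector = TRUE)
    }
    if (!is.list(config)) stop("config must be a list or a JSON/YAML path")
    cfg <- utils::modifyList(.defaultConfig(), config)
    cfg
}

#' Run the full ECD analysis workflow
#'
#' Reads a trajectory, selects the analysis atoms, slices segments, and
#' computes the segment-averaged correlation map, the flexibility profile,
#' and the dynamic-domain partition; all artifacts (TSV/JSON, plus a resolved
#' copy of the configuration for provenance) are written under `outputDir`.
#' Deterministic given inputs and configuration.
#'
#' Config keys (defaults in parentheses): `trajectory` — multi-model PDB
#' path, or `topology` + `trajectory` for DCD; `selection` (`"name CA"`);
#' `n_segments` (100); `segment_length` (20 frames); `take` (`"tail"`);
#' `variance_fraction` (0.90) or `fixed_m`; `domain_threshold` (0.0015) or
#' `threshold_grid` (numeric vector, or `"auto"` for the data-driven grid of
#' [selectThreshold()]); `min_domain_size` (3); `min_largest_fraction` (0.10);
#' `contact_cutoffs` (4.0/3.5/4.5/5.0 A); `contact_group_a`/`contact_group_b`
#' selection expressions (optional; contacts are skipped when absent);
#' `bfactor_reference` — PDB path for flexibility-vs-B-factor comparison
#' (optional); `seed` (1).
#'
#' @param config named list, or path to a JSON/YAML config file.
#' @param outputDir output directory (created if needed).
#' @param traj optionally, a pre-loaded [Trajectory-class] (overrides the
#'   `trajectory` config key).
#' @return (invisibly) list with `map`, `flexibility`, `partition`,
#'   `summary`, and when configured `contacts`, `bfactors`, `agreement`.
#' @export
runAnalyze <- function(config, outputDir, traj = NULL) {
    cfg <- .loadConfig(config)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(traj)) {
        if (is.null(cfg$trajectory))
            stop("config lacks 'trajectory' (and no trajectory object given)")
        traj <- if (!is.null(cfg$topology))
            readTrajectory(cfg$topology, cfg$trajectory)
        else readPDB(cfg$trajectory)
    }
    jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                         file.path(outputDir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    sel <- selectAtoms(traj, cfg$selection)
    ens <- segmentTrajectory(traj, cfg$n_segments, cfg$segment_length,
                             take = cfg$take)
    map <- correlationMap(ens, sel, sel,
                          fraction = cfg$variance_fraction,
                          fixedM = cfg$fixed_m)
    writeCorrelationMap(map, file.path(outputDir, "correlation_map.tsv"))
    flex <- flexibilityProfile(ens, sel, fraction = cfg$variance_fraction,
                               fixedM = cfg$fixed_m)
    writeProfile(flex, file.path(outputDir, "flexibility.tsv"))
    if (!is.null(cfg$threshold_grid)) {
        grid <- if (identical(cfg$threshold_grid, "auto")) NULL
                else cfg$threshold_grid
        thr <- selectThreshold(map, grid = grid,
                               minLargestFraction = cfg$min_largest_fraction,
                               minDomainSize = cfg$min_domain_size)
        utils::write.table(thr$diagnostics,
                           file.path(outputDir, "threshold_diagnostics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dc <- thr$threshold
    } else dc <- cfg$domain_threshold
    part <- clusterDomains(map, threshold = dc,
                           minDomainSize = cfg$min_domain_size)
    atoms <- atomTable(traj)[sel@indices, , drop = FALSE]
    writeDomainPartition(part, atoms, file.path(outputDir, "domains.tsv"))
    summ <- domainSummary(part, atoms)
    utils::write.table(summ, file.path(outputDir, "domain_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- list(map = map, flexibility = flex, partition = part,
                summary = summ)
    if (!is.null(cfg$contact_group_a) && !is.null(cfg$contact_group_b)) {
        frame1 <- initialize(traj,
            coords = traj@coords[1L, , , drop = FALSE])
        contacts <- interfaceContacts(frame1,
            selectAtoms(traj, cfg$contact_group_a),
            selectAtoms(traj, cfg$contact_group_b),
            cutoffs = unlist(cfg$contact_cutoffs))
        writeContacts(contacts, file.path(outputDir, "contacts.tsv"))
        out$contacts <- contacts
    }
    if (!is.null(cfg$bfactor_reference)) {
        bf <- extractBFactors(readPDB(cfg$bfactor_reference,
                                      modelPolicy = "first"))
        norm <- normalizeProfile(flex, bf)
        writeProfile(bf, file.path(outputDir, "bfactors.tsv"))
        writeProfile(norm, file.path(outputDir, "flexibility_normalized.tsv"))
        agr <- profileAgreement(flex, bf)
        jsonlite::write_json(agr, file.path(outputDir, "agreement.json"),
                             auto_unbox = TRUE, digits = NA)
        out$bfactors <- bf
        out$agreement <- agr
    }
    .logInfo("analysis artifacts written to %s", outputDir)
    invisible(out)
}

#' Simulate a synthetic trajectory with ground-truth sidecars
#'
#' Runs [generateENMTrajectory()] for a spec (object or JSON file, see
#' [readENMSpec()]) and writes the trajectory as multi-model PDB and DCD,
#' plus a JSON ground-truth sidecar (block labels, analytic per-atom MSF).
#'
#' @param spec an [ENMSpec-class] or path to an ENM spec JSON file.
#' @param outputDir output directory (created if needed).
#' @return (invisibly) list with `trajectory` and the written `paths`.
#' @export
runSimulate <- function(spec, outputDir) {
    if (is.character(spec)) spec <- readENMSpec(spec)
    stopifnot(is(spec, "ENMSpec"))
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    traj <- generateENMTrajectory(spec)
    paths <- c(pdb = file.path(outputDir, "trajectory.pdb"),
               dcd = file.path(outputDir, "trajectory.dcd"),
               truth = file.path(outputDir, "ground_truth.json"),
               spec = file.path(outputDir, "resolved_spec.json"))
    writePDB(traj, paths[["pdb"]])
    writeDCD(traj, paths[["dcd"]])
    writeGroundTruth(spec, paths[["truth"]])
    writeENMSpec(spec, paths[["spec"]])
    .logInfo("simulation artifacts written to %s", outputDir)
    invisible(list(trajectory = traj, paths = paths))
}
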