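#' Validate a pipeline run configuration
#'
#' Checks a parsed config (or YAML path) and returns every violation found
#' (no fail-fast); an empty character vector means the config is runnable.
#'
#' Expected layout (all stages optional, toggled under `stages`):
#' ```
#' seed: 1
#' output_dir: out/
#' stages: {kinetics: yes, membrane: yes, conservation: yes}
#' kinetics:
#'   reference: PC
#'   window_s: 30
#'   conditions: {PC: 1.0, PS: 5.3}    # rate multipliers (generator mode)
#'   base_rate: 0.004
#'   n_traces: 9
#'   noise_sd: 0.005
#'   manifest: path/to/manifest.tsv    # alternative: measured traces
#' membrane:
#'   n_frames: 200
#'   n_lipids_total: 524
#'   composition: {PS: 0.1, PC: 0.9}
#'   cutoff: 0.55
#'   spacing_2d: 0.02
#'   spacing_3d: 0.1
#'   site_spacing: 0.05
#'   trajectory: path.gro              # alternative: measured trajectory
#'   topology: top.tsv
#' conservation:
#'   alignment: aln.fasta
#'   format: fasta
#'   reference_id: AHA2
#'   contact_residues: [842]
#'   ref_offset: 0
#' ```
#'
#' @param config A list, or the path of a YAML file.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file not found: %s", config))
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop_config("config does not parse as YAML: %s", conditionMessage(e)))
  }
  v <- character()
  add <- function(...) v <<- c(v, sprintf(...))
  if (is.null(config$output_dir)) add("output_dir: missing")
  if (is.null(config$seed)) add("seed: missing")
  else if (!is.numeric(config$seed)) add("seed: must be an integer")
  st <- config$stages %||% list()
  on <- function(s) isTRUE(st[[s]])
  if (!any(vapply(c("kinetics", "membrane", "conservation"), on, TRUE)))
    add("stages: no stage enabled")
  kin <- config$kinetics
  if (on("kinetics")) {
    if (is.null(kin$reference)) add("kinetics.reference: missing")
    w <- kin$window_s %||% 30
    if (!is.numeric(w) || w <= 0) add("kinetics.window_s: must be positive")
    if (is.null(kin$manifest)) {
      if (is.null(kin$conditions)) add("kinetics.conditions: missing (no manifest either)")
      else if (!is.null(kin$reference) &&
               !kin$reference %in% names(kin$conditions))
        add("kinetics.reference: '%s' not among conditions", kin$reference)
    } else if (!file.exists(kin$manifest)) {
      add("kinetics.manifest: file not found: %s", kin$manifest)
    }
  }
  mem <- config$membrane
  if (on("membrane")) {
    cutoff <- mem$cutoff %||% 0.55
    if (!is.numeric(cutoff) || cutoff <= 0) add("membrane.cutoff: must be positive")
    for (fld in c("spacing_2d", "spacing_3d", "site_spacing")) {
      x <- mem[[fld]]
      if (!is.null(x) && (!is.numeric(x) || x <= 0))
        add("membrane.%s: must be positive", fld)
    }
    if (!is.null(mem$trajectory)) {
      if (!file.exists(mem$trajectory))
        add("membrane.trajectory: file not found: %s", mem$trajectory)
      if (is.null(mem$topology)) add("membrane.topology: missing")
      else if (!file.exists(mem$topology))
        add("membrane.topology: file not found: %s", mem$topology)
    } else {
      comp <- mem$composition %||% c(PS = 0.1, PC = 0.9)
      if (abs(sum(unlist(comp)) - 1) > 1e-9)
        add("membrane.composition: fractions must sum to 1")
      nl <- mem$n_lipids_total %||% 524
      if (nl %% 2 != 0) add("membrane.n_lipids_total: must be even")
    }
  }
  cons <- config$conservation
  if (on("conservation")) {
    if (is.null(cons$alignment)) add("conservation.alignment: missing")
    else if (!file.exists(cons$alignment))
      add("conservation.alignment: file not found: %s", cons$alignment)
    if (is.null(cons$reference_id)) add("conservation.reference_id: missing")
  }
  v
}

.log_line <- function(con, stage, level, msg) {
  line <- sprintf("%s\t%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level, msg)
  writeLines(line, con)
  message(line)
}

.run_kinetics_stage <- function(cfg, outdir, seed, log) {
  kin <- cfg$kinetics
  window_s <- kin$window_s %||% 30
  if (!is.null(kin$manifest)) {
    res <- analyze_traces(kin$manifest, kin$reference, window_s)
  } else {
    base <- kin$base_rate %||% 0.001
    n <- kin$n_traces %||% 9
    noise <- kin$noise_sd %||% 0.005
    # all conditions share one quench time constant: faster pumping quenches
    # to a proportionally deeper plateau, so initial-slope ratios stay
    # faithful to the configured rate ratios
    k0 <- kin$quench_k %||% 0.006
    conds <- kin$conditions
    .log_line(log, "kinetics", "INFO",
              sprintf("generating %d traces x %d conditions (base rate %g/s, noise %g)",
                      n, length(conds), base, noise))
    per <- list()
    for (cname in names(conds)) {
      for (r in seq_len(n)) {
        rate_c <- base * conds[[cname]]
        tc <- trace_gen_config(rate = rate_c,
                               plateau = max(0.05, 1 - rate_c / k0),
                               noise_sd = noise,
                               seed = seed + 1000L * match(cname, names(conds)) + r)
        nt <- normalize_trace(gen_acma_trace(tc))
        pr <- initial_rate(nt, window_s)
        per[[length(per) + 1L]] <- data.frame(
          trace_path = NA_character_, condition = cname, replicate = r,
          rate = pr$rate, slope = pr$slope, r_squared = pr$r_squared,
          n_points = pr$n_points, active = classify_active(nt))
      }
    }
    per_trace <- do.call(rbind, per)
    folds <- fold_changes(split(per_trace, per_trace$condition), kin$reference)
    res <- list(per_trace = per_trace,
                folds = data.frame(condition = names(folds),
                                   fold = unname(folds)))
  }
  utils::write.table(res$per_trace, file.path(outdir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$folds, file.path(outdir, "folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  act <- res$per_trace[res$per_trace$active, ]
  groups <- split(act$rate, act$condition)
  outputs <- c(file.path(outdir, "rates.tsv"), file.path(outdir, "folds.tsv"))
  if (length(groups) >= 2 && all(lengths(groups) >= 2)) {
    aov1 <- anova_oneway(groups)
    tk <- tukey_hsd(groups, cfg$alpha %||% 0.05)
    cld <- letter_display(tk, group_order = names(groups))
    utils::write.table(as.data.frame(tk), file.path(outdir, "tukey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(condition = names(cld), letters = unname(cld)),
                       file.path(outdir, "letters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .log_line(log, "kinetics", "INFO",
              sprintf("ANOVA F=%.3g p=%.3g; letters: %s", aov1$F, aov1$p,
                      paste(names(cld), cld, sep = "=", collapse = " ")))
    outputs <- c(outputs, file.path(outdir, c("tukey.tsv", "letters.tsv")))
  }
  outputs
}

.run_membrane_stage <- function(cfg, outdir, seed, log) {
  mem <- cfg$membrane
  cutoff <- mem$cutoff %||% 0.55
  if (!is.null(mem$trajectory)) {
    got <- read_trajectory(mem$trajectory, mem$topology)
    traj <- got$trajectory; topo <- got$topology
    species <- mem$species %||% "PS"
  } else {
    comp <- unlist(mem$composition %||% c(PS = 0.1, PC = 0.9))
    hotspots <- lapply(mem$hotspots %||% list(), function(h)
      hotspot_spec(h$residue_ids, h$species, h$strength %||% 0,
                   h$radius %||% 1))
    gcfg <- membrane_gen_config(
      n_lipids_total = mem$n_lipids_total %||% 524,
      composition = comp, hotspots = hotspots,
      n_frames = mem$n_frames %||% 200, seed = seed)
    .log_line(log, "membrane", "INFO",
              sprintf("generating bilayer: %d lipids (%s), %d frames",
                      gcfg$n_lipids_total,
                      paste(names(comp), comp, sep = ":", collapse = " "),
                      gcfg$n_frames))
    got <- gen_membrane_trajectory(gcfg)
    traj <- got$trajectory; topo <- got$topology
    species <- mem$species %||% names(comp)[1]
    jsonlite::write_json(got$ground_truth,
                         file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  aligned <- align_frames(traj, topo)
  profile <- contact_probabilities(traj, topo, cutoff)
  utils::write.table(as.data.frame(profile),
                     file.path(outdir, "contact_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  map <- density_map_2d(aligned, topo, species, "upper",
                        mem$site_spacing %||% 0.05)
  enr <- enrichment_map(map)
  write_density_tsv(enr, file.path(outdir,
                                   sprintf("enrichment_%s_upper.tsv", species)))
  grid <- density_grid_3d(aligned, topo, species, "headgroup",
                          mem$spacing_3d %||% 0.1)
  write_dx(grid, file.path(outdir, sprintf("density3d_%s_head.dx", species)))
  sites <- find_sites(enr, profile, residue_positions(aligned, topo),
                      min_enrichment = mem$min_enrichment %||% 2)
  .log_line(log, "membrane", "INFO",
            sprintf("%d site(s) called for %s", nrow(sites), species))
  sites_flat <- sites[setdiff(names(sites), "residues")]
  sites_flat$residues <- vapply(sites$residues, function(r)
    paste(r$residue_id, collapse = ","), "")
  utils::write.table(sites_flat, file.path(outdir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  file.path(outdir, c("contact_profile.tsv",
                      sprintf("enrichment_%s_upper.tsv", species),
                      sprintf("density3d_%s_head.dx", species), "sites.tsv"))
}

.run_conservation_stage <- function(cfg, outdir, log) {
  cons <- cfg$conservation
  aln <- read_alignment(cons$alignment, cons$format %||% "fasta")
  res <- unlist(cons$contact_residues %||% default_contact_residues())
  rep <- site_report(aln, cons$reference_id, res,
                     ref_offset = cons$ref_offset %||% 0)
  utils::write.table(rep, file.path(outdir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_line(log, "conservation", "INFO",
            sprintf("%d/%d contact residue column(s) identical in all sequences",
                    sum(rep$identical_in_all), nrow(rep)))
  file.path(outdir, "conservation.tsv")
}

#' Run the full analysis pipeline from one config
#'
#' Executes the enabled stages (kinetics, membrane, conservation) in order,
#' writing all outputs below `output_dir`. A failing stage stops its
#' dependents but already-written outputs are kept. The run manifest
#' (config hash, per-stage outputs with md5 checksums, log path) is written
#' last; deterministic stages reproduce identical checksums when re-run
#' with the same config and seed.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @return The manifest, invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  violations <- validate_config(config)
  if (length(violations))
    stop_config("invalid config:\n- %s", paste(violations, collapse = "\n- "))
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log <- file(log_path, "w")
  on.exit(close(log))
  seed <- as.integer(config$seed)
  st <- config$stages %||% list()
  stage_outputs <- list()
  for (stage in c("kinetics", "membrane", "conservation")) {
    if (!isTRUE(st[[stage]])) next
    .log_line(log, stage, "INFO",
              sprintf("start (seed %d, params %s)", seed,
                      jsonlite::toJSON(config[[stage]], auto_unbox = TRUE,
                                       null = "null")))
    out <- tryCatch(switch(stage,
      kinetics = .run_kinetics_stage(config, outdir, seed, log),
      membrane = .run_membrane_stage(config, outdir, seed, log),
      conservation = .run_conservation_stage(config, outdir, log)),
      error = function(e) e)
    if (inherits(out, "error")) {
      .log_line(log, stage, "ERROR", conditionMessage(out))
      stop_config("stage '%s' failed: %s", stage, conditionMessage(out))
    }
    stage_outputs[[stage]] <- out
    .log_line(log, stage, "INFO", "done")
  }
  manifest <- list(
    config_hash = unname(tools::md5sum(
      tf <- {tf0 <- tempfile(); writeLines(
        jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"), tf0); tf0})),
    package_version = as.character(utils::packageVersion("pumplipid")),
    seed = seed,
    stages = lapply(stage_outputs, function(paths)
      list(outputs = paths,
           checksums = unname(tools::md5sum(paths)))),
    log = log_path)
  unlink(tf)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
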