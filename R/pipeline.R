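#' Assemble and validate a pipeline configuration
#'
#' A single configuration drives an end-to-end run: input paths (or a
#' simulation specification), the confidence filter, mapping policy,
#' terminome options, replicate aggregation, condition ordering and the
#' control label, plus the seed. Exactly one of `quant_table` and
#' `simulation` must be given.
#'
#' @param out_dir Output directory (created if absent).
#' @param fasta Path to the parent-protein FASTA (optional when
#'   `simulation` generates random proteins).
#' @param quant_table Path to a peptide quantification table.
#' @param simulation Simulation spec: list with `n_proteins`,
#'   `protein_length`, `conditions` (named list: label to list with
#'   per-subsite weight lists and `efficiency`), and optional digestion
#'   `params` overrides (see [digest_params()]).
#' @param confidence_threshold Confidence filter on load.
#' @param policy,match_mode Mapping options, see [map_peptidome()].
#' @param weighting,normalization Matrix options, see
#'   [compute_specificity_matrix()].
#' @param aggregate Replicate summary.
#' @param exclude_met_excision,dedupe_cuts Event options, see
#'   [extract_cleavage_events()].
#' @param split_termini Also emit N-side-only and C-side-only matrices.
#' @param control Control condition label for contrasts (default: first
#'   condition).
#' @param render_figures Write heatmap/bar figures (needs a PNG device).
#' @param seed Integer seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            fasta = NULL,
                            quant_table = NULL,
                            simulation = NULL,
                            confidence_threshold = 0.95,
                            policy = "split_weight",
                            match_mode = "exact",
                            weighting = "intensity",
                            normalization = "frequency",
                            aggregate = "mean",
                            exclude_met_excision = FALSE,
                            dedupe_cuts = FALSE,
                            split_termini = FALSE,
                            control = NULL,
                            render_figures = TRUE,
                            seed = 1L) {
  if (is.null(quant_table) == is.null(simulation))
    stop("exactly one of `quant_table` and `simulation` must be given")
  if (!is.null(quant_table) && !file.exists(quant_table))
    stop("quantification table not found: ", quant_table)
  if (!is.null(fasta) && !file.exists(fasta))
    stop("FASTA file not found: ", fasta)
  if (is.null(simulation) && is.null(fasta))
    stop("a FASTA file is required when mapping a measured table")
  structure(list(out_dir = out_dir, fasta = fasta,
                 quant_table = quant_table, simulation = simulation,
                 confidence_threshold = confidence_threshold,
                 policy = policy, match_mode = match_mode,
                 weighting = weighting, normalization = normalization,
                 aggregate = aggregate,
                 exclude_met_excision = exclude_met_excision,
                 dedupe_cuts = dedupe_cuts,
                 split_termini = split_termini,
                 control = control,
                 render_figures = render_figures,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML path.
#' @param overrides Named list of values taking precedence over the file
#'   (e.g. from command-line flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  do.call(pipeline_config, cfg)
}

# Build protease models from the nested-list simulation spec.
build_condition_models <- function(spec) {
  out <- lapply(names(spec), function(lab) {
    cs <- spec[[lab]]
    as_weights <- function(x) if (is.null(x)) NULL else unlist(x)
    # [[ indexing only: $ would partially match "P2" against "P2p"
    protease_model(name = cs[["name"]] %||% lab,
                   P2 = as_weights(cs[["P2"]]),
                   P1 = as_weights(cs[["P1"]]),
                   P1p = as_weights(cs[["P1p"]] %||% cs[["P1'"]]),
                   P2p = as_weights(cs[["P2p"]] %||% cs[["P2'"]]),
                   efficiency = cs[["efficiency"]] %||% 0.1)
  })
  stats::setNames(out, names(spec))
}

#' Run the full peptidome-to-terminome pipeline
#'
#' simulate (or load) -> confidence-filter -> map -> cleavage events ->
#' per-condition specificity matrices -> condition contrasts ->
#' per-protein degradation table -> run report. All artifacts are
#' written under `config$out_dir`; the run is deterministic given
#' (config, seed) and re-running overwrites the same files identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory objects (`proteins`,
#'   `quant`, `located`, `events`, `matrices`, `contrasts`,
#'   `degradation`, `report`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  pth <- function(...) file.path(config$out_dir, ...)
  logf <- file(pth("run.log"), "w")
  on.exit(close(logf))
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(msg, logf)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim_spec <- config$simulation
    proteins <- if (!is.null(config$fasta)) read_fasta(config$fasta)
    else random_proteins(sim_spec$n_proteins %||% 50L,
                         sim_spec$protein_length %||% 300L)
    params <- do.call(digest_params, sim_spec$params %||% list())
    models <- build_condition_models(sim_spec$conditions)
    say("simulating digestion of ", nrow(proteins), " protein(s) under ",
        length(models), " condition(s)")
    sim <- simulate_experiment(proteins, models, params,
                               seed = config$seed)
    truth <- sim$truth
    quant_path <- pth("quant_table.tsv")
    utils::write.table(sim$table, quant_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (is.null(config$fasta)) write_fasta(proteins, pth("proteins.fasta"))
  } else {
    proteins <- read_fasta(config$fasta)
    quant_path <- config$quant_table
  }

  quant <- withCallingHandlers(
    read_peptide_quant(quant_path, config$confidence_threshold),
    message = function(m) { writeLines(conditionMessage(m), logf)
      invokeRestart("muffleMessage") })
  conds <- quant_conditions(quant)
  control <- config$control %||% conds[1]
  if (!control %in% conds)
    stop("pipeline stage 'contrast': control condition '", control,
         "' absent from table ", quant_path)
  say("retained ", length(quant_peptides(quant)), " peptide(s) across ",
      length(conds), " condition(s): ", paste(conds, collapse = ", "))

  located <- withCallingHandlers(
    map_peptidome(quant, proteins, policy = config$policy,
                  match_mode = config$match_mode),
    message = function(m) { writeLines(conditionMessage(m), logf)
      invokeRestart("muffleMessage") })
  write_located_peptides(located, pth("mapped_peptides.tsv"))

  bg <- if (config$normalization == "enrichment")
    background_composition(proteins) else NULL

  events <- list(); matrices <- list(); contrasts <- list()
  for (cn in conds) {
    ev <- extract_cleavage_events(located, proteins, quant, cn,
                                  aggregate = config$aggregate,
                                  exclude_met_excision =
                                    config$exclude_met_excision,
                                  dedupe_cuts = config$dedupe_cuts)
    events[[cn]] <- ev
    write_cleavage_events(ev, pth(paste0("events_", cn, ".tsv")))
    m <- compute_specificity_matrix(ev, weighting = config$weighting,
                                    normalization = config$normalization,
                                    background = bg, condition = cn)
    matrices[[cn]] <- m
    write_specificity_matrix(m, pth(paste0("specificity_", cn, ".tsv")))
    if (isTRUE(config$render_figures))
      render_heatmap(m, pth(paste0("specificity_", cn, ".png")))
    if (isTRUE(config$split_termini)) {
      for (sd in c("N", "C")) {
        sub <- ev[ev$side == sd, , drop = FALSE]
        class(sub) <- class(ev); attr(sub, "condition") <- cn
        ms <- compute_specificity_matrix(sub, weighting = config$weighting,
                                         normalization = config$normalization,
                                         background = bg,
                                         condition = paste0(cn, ":", sd))
        write_specificity_matrix(ms, pth(paste0("specificity_", cn, "_",
                                                sd, "term.tsv")))
      }
    }
    say("condition ", cn, ": ", nrow(ev), " cleavage event(s)")
  }
  for (cn in setdiff(conds, control)) {
    ctr <- compare_conditions(matrices[[cn]], matrices[[control]])
    contrasts[[cn]] <- ctr
    write_contrast(ctr, pth(paste0("contrast_", cn, "_vs_", control,
                                   ".tsv")))
  }

  degr <- degradation_table(located, quant, conditions = conds,
                            aggregate = config$aggregate)
  write_degradation_table(degr, pth("degradation_table.tsv"))
  if (isTRUE(config$render_figures))
    plot_degradation(degr, pth("degradation.png"))

  opts <- config[setdiff(names(config),
                         c("out_dir", "fasta", "quant_table",
                           "simulation"))]
  report <- list(
    counts = list(
      peptides_read = attr(quant, "n_read") %||%
        length(quant_peptides(quant)),
      peptides_filtered_out = attr(quant, "n_filtered"),
      peptides_retained = length(quant_peptides(quant)),
      peptides_mapped = length(unique(located$peptide)),
      peptides_unmatched = length(attr(located, "unmatched")),
      peptides_discarded_ambiguous = length(attr(located, "discarded")),
      mapped_sites = nrow(located),
      events_per_condition = lapply(events, nrow),
      proteins_quantified = nrow(degr)),
    options = opts,
    control = control,
    conditions = as.list(conds),
    mapping_policy_note = if (config$policy == "split_weight")
      paste("multi-mapping peptides split 1/n_sites over sites;",
            "total intensity conserved") else config$policy,
    tool = "terminomeR",
    version = as.character(utils::packageVersion("terminomeR")),
    seed = config$seed)
  jsonlite::write_json(report, pth("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(c(
    "terminomeR run report",
    paste0("  seed: ", config$seed),
    paste0("  peptides read/filtered/retained: ",
           report$counts$peptides_read, "/",
           report$counts$peptides_filtered_out, "/",
           report$counts$peptides_retained),
    paste0("  mapped/unmatched/discarded: ",
           report$counts$peptides_mapped, "/",
           report$counts$peptides_unmatched, "/",
           report$counts$peptides_discarded_ambiguous),
    paste0("  events: ",
           paste(names(events), vapply(events, nrow, integer(1)),
                 sep = "=", collapse = ", ")),
    paste0("  proteins quantified: ", report$counts$proteins_quantified)),
    pth("run_report.txt"))
  say("pipeline finished; artifacts in ", config$out_dir)

  invisible(list(proteins = proteins, quant = quant, located = located,
                 events = events, matrices = matrices,
                 contrasts = contrasts, degradation = degr,
                 report = report, truth = truth))
}
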