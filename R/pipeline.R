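#' Configuration of an end-to-end screen run
#'
#' Bundles everything a reproducible two-stage screen needs: the seed, the
#' channel model, the planted treatment effects, plate geometry, gates and
#' hit criteria. A run is reproducible from its config alone.
#'
#' @param seed Integer seed driving all randomness of the run.
#' @param library_size Number of miRNAs in the (simulated) library.
#' @param effects Named list of [effect_profile()]s for treatments with a
#'   real effect; all other miRNAs are nulls.
#' @param model A [channel_model()].
#' @param gates A [gate_config()] (quantile rules are resolved against a
#'   dedicated no-bead control well simulated at the start of the run).
#' @param criteria A [hit_criteria()].
#' @param n_events Events acquired per well.
#' @param wells_per_plate,nt_per_plate,cytod_per_plate,untreated_per_plate,replicates
#'   Plate geometry, see [build_plate_layouts()].
#' @param mirna_ids Optional explicit miRNA labels.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, library_size = 100, effects = list(),
                       model = channel_model(), gates = gate_config(),
                       criteria = hit_criteria(), n_events = 5000,
                       wells_per_plate = 96, nt_per_plate = 6,
                       cytod_per_plate = 2, untreated_per_plate = 1,
                       replicates = 3, mirna_ids = NULL) {
  structure(list(
    seed = as.integer(seed), library_size = as.integer(library_size),
    effects = effects, model = model, gates = gates, criteria = criteria,
    n_events = n_events, wells_per_plate = wells_per_plate,
    nt_per_plate = nt_per_plate, cytod_per_plate = cytod_per_plate,
    untreated_per_plate = untreated_per_plate, replicates = replicates,
    mirna_ids = mirna_ids
  ), class = "run_config")
}

planted_treatments <- function(effects) {
  is_planted <- vapply(effects, function(e) {
    e$phago_effect != 1 || e$bead_effect != 1
  }, logical(1))
  setdiff(names(effects)[is_planted], "CytoD")
}

#' Run a two-stage phagocytosis screen end to end
#'
#' Simulates the primary screen (every library miRNA in replicate wells with
#' on-plate NT and CytoD controls), gates every well as it is generated,
#' calls stage-1 hits, re-screens the stage-1 `hit_any` miRNAs on fresh
#' plates as the secondary screen, intersects the stages and reports the
#' final hits with their Venn partition. When ground truth is available
#' (planted effect profiles), the report includes the confusion matrix of
#' final hit calls against the planted truth.
#'
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, all intermediate tables are
#'   written as CSV and the report as JSON.
#' @return A list: `stage1`, `stage2` (hit tables), `final` (the
#'   [two_stage_intersect()] table), `venn`, `confusion` (or NULL),
#'   `summaries1`, `summaries2`, `identity_ok`, `config`.
#' @export
run_screen <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  gates <- config$gates
  sim_stage <- function(ids, effects) {
    simulate_screen(
      library_size = length(ids), effects = effects, model = config$model,
      n_events = config$n_events, seed = NULL,
      wells_per_plate = config$wells_per_plate,
      nt_per_plate = config$nt_per_plate,
      cytod_per_plate = config$cytod_per_plate,
      untreated_per_plate = config$untreated_per_plate,
      replicates = config$replicates, mirna_ids = ids,
      reduce = function(ev) gate_well(ev, gates)
    )
  }

  result <- with_seed(config$seed, {
    if (!gates_concrete(gates)) {
      ## resolve quantile rules against a dedicated no-bead control well
      no_bead <- simulate_well(config$model,
                               effect_profile("no_bead", phago_effect = 1e-12),
                               n_events = config$n_events, seed = NULL)
      gates <- resolve_gates(list(no_bead = no_bead), gates)
    }
    ids <- config$mirna_ids %||%
      sprintf("miR-sim-%04d", seq_len(config$library_size))
    sim1 <- sim_stage(ids, config$effects)
    summaries1 <- gate_screen(sim1, gates)
    stage1 <- screen_stage(summaries1, config$criteria)

    retest <- stage1$mirna[stage1$hit_any]
    if (length(retest) > 0L) {
      sim2 <- sim_stage(retest, config$effects)
      summaries2 <- gate_screen(sim2, gates)
      stage2 <- screen_stage(summaries2, config$criteria)
      final <- two_stage_intersect(stage1, stage2)
    } else {
      summaries2 <- NULL
      stage2 <- NULL
      final <- two_stage_intersect(stage1, stage1[0, , drop = FALSE])
    }
    list(summaries1 = summaries1, stage1 = stage1,
         summaries2 = summaries2, stage2 = stage2, final = final)
  })

  venn <- attr(result$final, "venn")
  identity_ok <- venn$pct + venn$mfi - venn$union == venn$both

  planted <- planted_treatments(config$effects)
  confusion <- NULL
  if (length(config$effects) > 0L) {
    all_ids <- result$stage1$mirna
    hits <- result$final$mirna[result$final$final_hit]
    confusion <- list(
      tp = sum(hits %in% planted),
      fp = sum(!hits %in% planted),
      fn = sum(!planted %in% hits),
      tn = sum(!all_ids %in% c(hits, planted))
    )
  }

  report <- list(
    n_mirna = config$library_size,
    n_stage1_hits = sum(result$stage1$hit_any),
    n_final_hits = venn$union,
    venn = venn,
    identity_ok = identity_ok,
    confusion = confusion,
    seed = config$seed
  )
  out <- c(result, list(venn = venn, identity_ok = identity_ok,
                        confusion = confusion, report = report,
                        gates = gates, config = config))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$summaries1,
                     file.path(outdir, "stage1_well_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(result$stage1, file.path(outdir, "stage1_hits.csv"),
                     row.names = FALSE)
    if (!is.null(result$stage2)) {
      utils::write.csv(result$summaries2,
                       file.path(outdir, "stage2_well_summaries.csv"),
                       row.names = FALSE)
      utils::write.csv(result$stage2, file.path(outdir, "stage2_hits.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(result$final, file.path(outdir, "final_hits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "screen_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
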