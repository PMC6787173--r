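#' Gating configuration
#'
#' Thresholds for the hierarchical gating scheme
#' cells (FSC/SSC) -> viable (PI-) -> transfected (AF647+) -> phagocytic
#' (FITC+). Each threshold is either a concrete intensity or a quantile rule
#' created with [gate_rule()] that is resolved against designated control
#' wells by [resolve_gates()]. Positivity uses a strict inequality: an event
#' is positive on a channel iff its intensity is strictly greater than the
#' threshold; viable means *not* PI-positive.
#'
#' The default thresholds are concrete and sit at least 3 lognormal standard
#' deviations away from both class modes of the default [channel_model()].
#'
#' @param fsc_min,ssc_min Lower bounds of the rectangular scatter (cell) gate;
#'   events must exceed both to count as cells. This is the only gate that
#'   removes free beads and debris.
#' @param pi_threshold PI intensity above which an event is PI+ (necrotic).
#' @param af647_threshold AF647 intensity above which an event is transfected.
#' @param fitc_threshold FITC intensity above which an event is bead-positive.
#' @param mfi_statistic `"arithmetic"` (default) or `"geometric"` mean for the
#'   MFI readouts.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(fsc_min = exp(9.5), ssc_min = exp(9.0),
                        pi_threshold = exp(3), af647_threshold = exp(4.3),
                        fitc_threshold = exp(4.2),
                        mfi_statistic = c("arithmetic", "geometric")) {
  cfg <- list(
    fsc_min = fsc_min, ssc_min = ssc_min, pi_threshold = pi_threshold,
    af647_threshold = af647_threshold, fitc_threshold = fitc_threshold,
    mfi_statistic = match.arg(mfi_statistic)
  )
  for (f in c("fsc_min", "ssc_min", "pi_threshold", "af647_threshold",
              "fitc_threshold")) {
    v <- cfg[[f]]
    if (inherits(v, "gate_rule")) next
    check_positive(v, f)
  }
  structure(cfg, class = "gate_config")
}

#' Quantile rule for data-driven gate resolution
#'
#' A threshold defined as a quantile of one channel in a designated control
#' well, e.g. the FITC gate as the 99.5th percentile of a no-bead control.
#'
#' @param quantile Probability in (0, 1).
#' @param control Role label of the control well to use (a key of the
#'   `control_events` map passed to [resolve_gates()]).
#' @param channel Channel name (`"FSC"`, `"SSC"`, `"PI"`, `"AF647"`, `"FITC"`).
#' @return An object of class `gate_rule`.
#' @export
gate_rule <- function(quantile, control, channel) {
  check_probability(quantile, "quantile")
  if (quantile <= 0 || quantile >= 1) {
    stop_invalid("quantile", "must lie strictly in (0, 1)")
  }
  structure(list(quantile = quantile, control = control, channel = channel),
            class = "gate_rule")
}

#' Resolve quantile gate rules against control wells
#'
#' Replaces every [gate_rule()] in the configuration by the corresponding
#' empirical quantile (type-7) of the referenced control well's channel.
#' Idempotent on already-concrete configurations.
#'
#' @param control_events Named list mapping control roles (e.g. `"no_bead"`)
#'   to event tables.
#' @param cfg A [gate_config()].
#' @return A fully numeric `gate_config`.
#' @export
resolve_gates <- function(control_events, cfg) {
  stopifnot(inherits(cfg, "gate_config"))
  for (f in c("fsc_min", "ssc_min", "pi_threshold", "af647_threshold",
              "fitc_threshold")) {
    v <- cfg[[f]]
    if (!inherits(v, "gate_rule")) next
    ev <- control_events[[v$control]]
    if (is.null(ev)) {
      stop(sprintf("gate '%s' references control role '%s' which was not supplied",
                   f, v$control), call. = FALSE)
    }
    if (!v$channel %in% names(ev)) {
      stop(sprintf("control '%s' has no channel '%s'", v$control, v$channel),
           call. = FALSE)
    }
    cfg[[f]] <- as.numeric(stats::quantile(ev[[v$channel]], v$quantile,
                                           names = FALSE))
  }
  cfg
}

gates_concrete <- function(cfg) {
  !any(vapply(cfg, inherits, logical(1), what = "gate_rule"))
}

#' Reduce one well's events to the assay readouts
#'
#' Applies the gates strictly in the order cells -> PI- -> AF647+ -> FITC+ and
#' reports per-well summary statistics on the stated parent populations:
#' `pct_cells` (of acquired events), `pct_viable` (PI- of cells),
#' `pct_transfected` (AF647+ of PI- cells), `pct_fitc_pos` (FITC+ of
#' PI- AF647+ cells), `mfi_fitc` (mean FITC of the FITC+ events) and
#' `mfi_pi_neg` (mean PI of the PI- cells). An empty FITC+ population yields
#' `mfi_fitc = NA` (never 0); a well where no events survive the scatter gate
#' is returned with NA readouts and `quality_flag = "no_cells"` rather than
#' raising an error.
#'
#' @param events Event table (as from [simulate_well()] or
#'   [read_event_table()]); must contain columns `FSC`, `SSC`, `PI`, `AF647`,
#'   `FITC`.
#' @param cfg A concrete [gate_config()] (pass through [resolve_gates()]
#'   first if it contains quantile rules).
#' @return A one-row `data.frame` (`well_summary`): `well_id`,
#'   `n_events_acquired`, `pct_cells`, `pct_viable`, `pct_transfected`,
#'   `pct_fitc_pos`, `mfi_fitc`, `mfi_pi_neg`, `quality_flag`.
#' @export
gate_well <- function(events, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  if (!gates_concrete(cfg)) {
    stop("gate_config still contains quantile rules; call resolve_gates() first",
         call. = FALSE)
  }
  need <- c("FSC", "SSC", "PI", "AF647", "FITC")
  if (!all(need %in% names(events))) {
    stop("event table must contain columns FSC, SSC, PI, AF647, FITC",
         call. = FALSE)
  }
  n <- nrow(events)
  if (n == 0L) stop("event table is empty", call. = FALSE)
  well_id <- if ("well_id" %in% names(events)) events$well_id[1] else NA_character_

  mfi <- function(x) {
    if (length(x) == 0L) return(NA_real_)
    if (cfg$mfi_statistic == "geometric") exp(mean(log(x))) else mean(x)
  }

  cells <- events$FSC > cfg$fsc_min & events$SSC > cfg$ssc_min
  if (!any(cells)) {
    return(data.frame(
      well_id = well_id, n_events_acquired = n, pct_cells = 0,
      pct_viable = NA_real_, pct_transfected = NA_real_,
      pct_fitc_pos = NA_real_, mfi_fitc = NA_real_, mfi_pi_neg = NA_real_,
      quality_flag = "no_cells", stringsAsFactors = FALSE
    ))
  }
  viable <- cells & !(events$PI > cfg$pi_threshold)
  transfected <- viable & events$AF647 > cfg$af647_threshold
  fitc_pos <- transfected & events$FITC > cfg$fitc_threshold

  pct <- function(child, parent) {
    if (parent == 0L) NA_real_ else 100 * child / parent
  }
  data.frame(
    well_id = well_id,
    n_events_acquired = n,
    pct_cells = 100 * sum(cells) / n,
    pct_viable = pct(sum(viable), sum(cells)),
    pct_transfected = pct(sum(transfected), sum(viable)),
    pct_fitc_pos = pct(sum(fitc_pos), sum(transfected)),
    mfi_fitc = mfi(events$FITC[fitc_pos]),
    mfi_pi_neg = mfi(events$PI[viable]),
    quality_flag = "",
    stringsAsFactors = FALSE
  )
}

#' Gate every well of a simulated screen
#'
#' Convenience wrapper: applies [gate_well()] to each element of
#' `sim$wells` (or accepts a list of already-reduced one-row summaries, as
#' produced by `simulate_screen(..., reduce = ...)`) and joins the layout.
#'
#' @param sim Result of [simulate_screen()].
#' @param cfg A concrete [gate_config()].
#' @return A `data.frame`: layout columns plus the [gate_well()] summary
#'   columns, one row per well.
#' @export
gate_screen <- function(sim, cfg = gate_config()) {
  wells <- sim$wells
  summaries <- lapply(names(wells), function(key) {
    w <- wells[[key]]
    s <- if (is.data.frame(w) && "pct_fitc_pos" %in% names(w)) w else gate_well(w, cfg)
    s$well_key <- key
    s
  })
  summaries <- do.call(rbind, summaries)
  layout <- sim$layout
  layout$well_key <- paste(layout$plate_id, layout$well, sep = "_")
  merged <- merge(layout, summaries, by = "well_key", sort = FALSE)
  merged[order(merged$plate_id, merged$well), , drop = FALSE]
}
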