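#' Hit-calling criteria
#'
#' The screen's dual cut-off: a treatment is a hit on a readout when its
#' plate-normalized relative value changes by at least 20% in either direction
#' (relative value <= 0.8 or >= 1.2) *and* the Dunnett-adjusted p-value from
#' the raw triplicates is <= 0.01. All three boundaries are inclusive.
#'
#' @param rel_low,rel_high Relative-value cut-offs (defaults 0.8 and 1.2).
#' @param alpha Adjusted p-value cut-off (default 0.01).
#' @return An object of class `hit_criteria`.
#' @export
hit_criteria <- function(rel_low = 0.8, rel_high = 1.2, alpha = 0.01) {
  if (!(rel_low > 0 && rel_low < 1 && rel_high > 1)) {
    stop_invalid("rel_low/rel_high", "need 0 < rel_low < 1 < rel_high")
  }
  if (!(alpha > 0 && alpha < 1)) stop_invalid("alpha", "must lie in (0, 1)")
  structure(list(rel_low = rel_low, rel_high = rel_high, alpha = alpha),
            class = "hit_criteria")
}

#' Normalize one plate's readout to its on-plate NT controls
#'
#' Divides every well's readout by the mean of the same plate's non-targeting
#' (NT) control wells, so that the NT wells' normalized values average exactly
#' 1 and values are comparable across plates.
#'
#' @param plate_summaries Per-well summaries of a single plate (rows of
#'   [gate_screen()] output with a `role` column).
#' @param readout Column name to normalize (e.g. `"pct_fitc_pos"`).
#' @return The input with an added column `rel_<readout>`.
#' @export
normalize_plate <- function(plate_summaries, readout) {
  if (length(unique(plate_summaries$plate_id)) != 1L) {
    stop("normalize_plate() expects the summaries of exactly one plate",
         call. = FALSE)
  }
  nt <- plate_summaries[[readout]][plate_summaries$role == "NT"]
  nt <- nt[is.finite(nt)]
  if (length(nt) == 0L) {
    stop(sprintf("plate %s has no NT well with a defined '%s' readout",
                 plate_summaries$plate_id[1], readout), call. = FALSE)
  }
  nt_mean <- mean(nt)
  if (!is.finite(nt_mean) || nt_mean == 0) {
    stop(sprintf("NT mean of '%s' on plate %s is zero or undefined", readout,
                 plate_summaries$plate_id[1]), call. = FALSE)
  }
  plate_summaries[[paste0("rel_", readout)]] <-
    plate_summaries[[readout]] / nt_mean
  plate_summaries
}

#' Apply the dual cut-off to one screening stage
#'
#' @param stats Per-miRNA table with columns `rel_pct`, `rel_mfi`,
#'   `p_adj_pct`, `p_adj_mfi`.
#' @param criteria A [hit_criteria()].
#' @return The input with added columns `direction_pct`, `direction_mfi`
#'   (`"increase"`/`"decrease"`), `hit_pct`, `hit_mfi`, `hit_any`.
#' @export
call_hits <- function(stats, criteria = hit_criteria()) {
  hit1 <- function(rel, p) {
    !is.na(rel) & !is.na(p) &
      (rel <= criteria$rel_low | rel >= criteria$rel_high) &
      p <= criteria$alpha
  }
  dir1 <- function(rel) ifelse(is.na(rel), NA_character_,
                               ifelse(rel >= 1, "increase", "decrease"))
  stats$direction_pct <- dir1(stats$rel_pct)
  stats$direction_mfi <- dir1(stats$rel_mfi)
  stats$hit_pct <- hit1(stats$rel_pct, stats$p_adj_pct)
  stats$hit_mfi <- hit1(stats$rel_mfi, stats$p_adj_mfi)
  stats$hit_any <- stats$hit_pct | stats$hit_mfi
  stats
}

#' Run the hit-calling statistics of one screening stage
#'
#' For every plate: normalizes both readouts (% FITC+ of viable transfected
#' cells, and MFI of the FITC+ population) to the on-plate NT mean, and runs
#' a one-way ANOVA with Dunnett's many-to-one adjustment on the *raw*
#' replicate values of all miRNAs on that plate against the plate's NT wells.
#' Relative values are the mean of the per-replicate normalized values. Wells
#' with an undefined MFI (empty FITC+ gate) are dropped from that readout; a
#' miRNA needs at least two finite replicates per readout to be tested.
#'
#' @param summaries Output of [gate_screen()] for one stage.
#' @param criteria A [hit_criteria()].
#' @return A `hit table`: one row per miRNA with `mirna`, `plate_id`,
#'   `rel_pct`, `rel_mfi`, `p_unadj_pct`, `p_unadj_mfi`, `p_adj_pct`,
#'   `p_adj_mfi`, directions and hit flags (see [call_hits()]).
#' @export
screen_stage <- function(summaries, criteria = hit_criteria()) {
  readouts <- c(pct = "pct_fitc_pos", mfi = "mfi_fitc")
  out <- list()
  for (pid in unique(summaries$plate_id)) {
    plate <- summaries[summaries$plate_id == pid, , drop = FALSE]
    mirnas <- unique(plate$treatment_id[plate$role == "miRNA"])
    if (length(mirnas) == 0L) next
    res <- data.frame(mirna = mirnas, plate_id = pid,
                      stringsAsFactors = FALSE)
    for (r in names(readouts)) {
      col <- readouts[[r]]
      plate_n <- normalize_plate(plate, col)
      relcol <- paste0("rel_", col)
      rel <- vapply(mirnas, function(m) {
        v <- plate_n[[relcol]][plate_n$treatment_id == m]
        v <- v[is.finite(v)]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1))
      groups <- lapply(mirnas, function(m) {
        v <- plate[[col]][plate$treatment_id == m]
        v[is.finite(v)]
      })
      names(groups) <- mirnas
      nt <- plate[[col]][plate$role == "NT"]
      ok <- vapply(groups, function(v) length(v) >= 2L, logical(1))
      if (any(!ok)) {
        warning(sprintf(
          "plate %s: %d miRNA(s) with < 2 finite '%s' replicates left untested",
          pid, sum(!ok), col), call. = FALSE)
      }
      p_adj <- p_unadj <- rep(NA_real_, length(mirnas))
      if (any(ok)) {
        ad <- anova_dunnett(c(groups[ok], list(NT = nt[is.finite(nt)])),
                            control = "NT")
        idx <- match(ad$treatment, mirnas)
        p_adj[idx] <- ad$p_adj
        p_unadj[idx] <- ad$p_unadj
      }
      res[[paste0("rel_", r)]] <- unname(rel)
      res[[paste0("p_unadj_", r)]] <- p_unadj
      res[[paste0("p_adj_", r)]] <- p_adj
    }
    out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0L) {
    stop("no miRNA wells found in the supplied summaries", call. = FALSE)
  }
  call_hits(do.call(rbind, out), criteria)
}

#' Intersect primary and secondary screening stages
#'
#' A miRNA is a final hit on a readout when it met the criteria for that
#' readout in both stages *with the same direction of change*; a direction
#' conflict between stages disqualifies that readout. Final hits are
#' partitioned into Venn classes `"pct_only"`, `"mfi_only"` and `"both"`,
#' and the inclusion-exclusion identity |pct| + |mfi| - |any| = |both| holds
#' by construction.
#'
#' @param stage1,stage2 Hit tables from [screen_stage()]; `stage2` should
#'   contain only miRNAs that were `hit_any` in stage 1.
#' @return A `data.frame` of stage-1 `hit_any` miRNAs with columns
#'   `final_hit_pct`, `final_hit_mfi`, `final_hit`, `venn_class` (NA for
#'   non-hits), plus the per-stage relative values; the Venn counts are
#'   attached as `attr(, "venn")`.
#' @export
two_stage_intersect <- function(stage1, stage2) {
  s1 <- stage1[stage1$hit_any, , drop = FALSE]
  extra <- setdiff(stage2$mirna, s1$mirna)
  if (length(extra) > 0L) {
    stop("stage 2 contains miRNAs that were not stage-1 hits: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  m <- merge(s1, stage2, by = "mirna", suffixes = c("_s1", "_s2"))
  same_dir <- function(d1, d2) !is.na(d1) & !is.na(d2) & d1 == d2
  m$final_hit_pct <- m$hit_pct_s1 & m$hit_pct_s2 &
    same_dir(m$direction_pct_s1, m$direction_pct_s2)
  m$final_hit_mfi <- m$hit_mfi_s1 & m$hit_mfi_s2 &
    same_dir(m$direction_mfi_s1, m$direction_mfi_s2)
  m$final_hit <- m$final_hit_pct | m$final_hit_mfi
  m$venn_class <- ifelse(!m$final_hit, NA_character_,
                         ifelse(m$final_hit_pct & m$final_hit_mfi, "both",
                                ifelse(m$final_hit_pct, "pct_only", "mfi_only")))
  venn <- venn_counts(sum(m$final_hit_pct), sum(m$final_hit_mfi),
                      sum(m$final_hit))
  structure(m, venn = venn)
}

#' Venn arithmetic for two overlapping hit sets
#'
#' By inclusion-exclusion, the number of elements in both sets is
#' `n_pct + n_mfi - n_union`.
#'
#' @param n_pct,n_mfi Sizes of the two per-readout hit sets.
#' @param n_union Size of their union (miRNAs hitting either readout).
#' @return A list with `pct`, `mfi`, `union`, `both`, `pct_only`, `mfi_only`.
#' @export
venn_counts <- function(n_pct, n_mfi, n_union) {
  both <- n_pct + n_mfi - n_union
  if (both < 0 || both > min(n_pct, n_mfi)) {
    stop("inconsistent set sizes: |both| outside [0, min(|pct|, |mfi|)]",
         call. = FALSE)
  }
  list(pct = n_pct, mfi = n_mfi, union = n_union, both = both,
       pct_only = n_pct - both, mfi_only = n_mfi - both)
}

#' Fold change between two group means
#'
#' @param a,b Group means; returns `a / b`.
#' @return The ratio `a / b`.
#' @export
fold_change <- function(a, b) {
  check_positive(b, "b")
  a / b
}
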