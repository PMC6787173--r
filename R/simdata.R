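#' Channel model for synthetic flow-cytometry events
#'
#' Describes the population structure of one well of a bead-uptake
#' phagocytosis assay: the mixture of debris/free beads and cells, the
#' viability and transfection rates among cells, the probability that a viable
#' macrophage internalizes at least one bead, and class-conditional lognormal
#' intensity distributions for the five recorded channels (FSC, SSC, PI,
#' AF647, FITC).
#'
#' The defaults describe a non-targeting (NT) control well of PMA-activated
#' THP-1 macrophages: ~80% viable, ~80% transfected, 51% of viable cells
#' phagocytic, and a mean bead load of 3 beads per phagocytic cell (beads
#' are drawn from a zero-truncated Poisson so every phagocytic cell carries at
#' least one bead). Channel scales are arbitrary fluorescence units chosen so
#' that the default gates (see [gate_config()]) sit at least 3 lognormal
#' standard deviations away from both class modes.
#'
#' @param debris_fraction Fraction of acquired events that are debris or free
#'   beads rather than cells.
#' @param viability Probability that a cell is viable (PI-negative).
#' @param transfection Probability that a viable cell is transfected
#'   (AF647-positive).
#' @param phago_prob Probability that a viable cell has internalized at least
#'   one bead.
#' @param bead_mean Mean of the bead-count Poisson law before zero truncation.
#' @param bead_brightness_logmean,bead_brightness_logsd Lognormal parameters of
#'   the FITC signal contributed by a single bead.
#' @param autofluor_logmean,autofluor_logsd Lognormal FITC autofluorescence of
#'   a cell without beads.
#' @param pi_pos_logmean,pi_pos_logsd,pi_neg_logmean,pi_neg_logsd Lognormal PI
#'   intensity for necrotic (PI+) vs viable (PI-) cells.
#' @param af647_pos_logmean,af647_pos_logsd,af647_neg_logmean,af647_neg_logsd
#'   Lognormal AF647 intensity for transfected vs untransfected cells.
#' @param fsc_cell_logmean,fsc_cell_logsd,ssc_cell_logmean,ssc_cell_logsd
#'   Lognormal scatter parameters of intact cells.
#' @param fsc_debris_logmean,fsc_debris_logsd,ssc_debris_logmean,ssc_debris_logsd
#'   Lognormal scatter parameters of debris and free beads.
#' @param free_bead_fraction Fraction of debris events that are free beads and
#'   therefore carry a single-bead FITC signal.
#'
#' @return An object of class `channel_model` (a validated named list).
#' @seealso [effect_profile()], [simulate_well()]
#' @export
channel_model <- function(debris_fraction = 0.10,
                          viability = 0.80,
                          transfection = 0.80,
                          phago_prob = 0.51,
                          bead_mean = 3,
                          bead_brightness_logmean = log(400),
                          bead_brightness_logsd = 0.30,
                          autofluor_logmean = log(10),
                          autofluor_logsd = 0.40,
                          pi_pos_logmean = log(300),
                          pi_pos_logsd = 0.40,
                          pi_neg_logmean = log(1.5),
                          pi_neg_logsd = 0.40,
                          af647_pos_logmean = log(1200),
                          af647_pos_logsd = 0.45,
                          af647_neg_logmean = log(5),
                          af647_neg_logsd = 0.45,
                          fsc_cell_logmean = 10.8,
                          fsc_cell_logsd = 0.25,
                          ssc_cell_logmean = 10.0,
                          ssc_cell_logsd = 0.30,
                          fsc_debris_logmean = 8.0,
                          fsc_debris_logsd = 0.45,
                          ssc_debris_logmean = 7.5,
                          ssc_debris_logsd = 0.45,
                          free_bead_fraction = 0.5) {
  m <- list(
    debris_fraction = debris_fraction, viability = viability,
    transfection = transfection, phago_prob = phago_prob,
    bead_mean = bead_mean,
    bead_brightness_logmean = bead_brightness_logmean,
    bead_brightness_logsd = bead_brightness_logsd,
    autofluor_logmean = autofluor_logmean, autofluor_logsd = autofluor_logsd,
    pi_pos_logmean = pi_pos_logmean, pi_pos_logsd = pi_pos_logsd,
    pi_neg_logmean = pi_neg_logmean, pi_neg_logsd = pi_neg_logsd,
    af647_pos_logmean = af647_pos_logmean, af647_pos_logsd = af647_pos_logsd,
    af647_neg_logmean = af647_neg_logmean, af647_neg_logsd = af647_neg_logsd,
    fsc_cell_logmean = fsc_cell_logmean, fsc_cell_logsd = fsc_cell_logsd,
    ssc_cell_logmean = ssc_cell_logmean, ssc_cell_logsd = ssc_cell_logsd,
    fsc_debris_logmean = fsc_debris_logmean,
    fsc_debris_logsd = fsc_debris_logsd,
    ssc_debris_logmean = ssc_debris_logmean,
    ssc_debris_logsd = ssc_debris_logsd,
    free_bead_fraction = free_bead_fraction
  )
  for (f in c("debris_fraction", "viability", "transfection", "phago_prob",
              "free_bead_fraction")) {
    check_probability(m[[f]], f)
  }
  check_positive(m$bead_mean, "bead_mean")
  for (f in grep("_logsd$", names(m), value = TRUE)) check_positive(m[[f]], f)
  for (f in grep("_logmean$", names(m), value = TRUE)) check_finite(m[[f]], f)
  structure(m, class = "channel_model")
}

#' Multiplicative treatment effect on the channel model
#'
#' A treatment (miRNA mimic, cytochalasin D, ...) acts on the simulated well
#' through multipliers on the phagocytosis probability, the mean bead load of
#' phagocytic cells, and the viability and transfection rates. The identity
#' profile (all multipliers 1) leaves the channel model unchanged.
#'
#' @param treatment_id Label of the treatment.
#' @param phago_effect Multiplier on the phagocytosis probability (the
#'   resulting probability is clipped to `[0, 1]`).
#' @param bead_effect Multiplier on the mean bead count of phagocytic cells.
#' @param viability_effect,transfection_effect Multipliers on the viability and
#'   transfection probabilities (clipped to `[0, 1]`).
#'
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(treatment_id = "treatment",
                           phago_effect = 1,
                           bead_effect = 1,
                           viability_effect = 1,
                           transfection_effect = 1) {
  for (f in c("phago_effect", "bead_effect", "viability_effect",
              "transfection_effect")) {
    check_positive(get(f), f)
  }
  structure(
    list(treatment_id = as.character(treatment_id),
         phago_effect = phago_effect, bead_effect = bead_effect,
         viability_effect = viability_effect,
         transfection_effect = transfection_effect),
    class = "effect_profile"
  )
}

#' Cytochalasin D functional-control effect profile
#'
#' Cytochalasin D blocks actin polymerization and thereby phagocytosis; in the
#' assay it reduces the phagocytic fraction from ~51% to ~7.4% without
#' affecting viability or transfection. The default multiplier is 7.4/51.
#'
#' @param phago_effect Multiplier on the phagocytosis probability.
#' @return An `effect_profile` labelled `"CytoD"`.
#' @export
cytod_profile <- function(phago_effect = 7.4 / 51) {
  effect_profile("CytoD", phago_effect = phago_effect)
}

apply_effect <- function(model, effect) {
  list(
    phago_prob = min(1, model$phago_prob * effect$phago_effect),
    bead_mean = model$bead_mean * effect$bead_effect,
    viability = min(1, model$viability * effect$viability_effect),
    transfection = min(1, model$transfection * effect$transfection_effect)
  )
}

## Zero-truncated Poisson sampler via the inverse-CDF trick: draw the uniform
## above P(X = 0) and invert the untruncated CDF. Cross-checked in the tests
## against a rejection sampler.
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  p0 <- exp(-lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

#' Simulate the flow-cytometry events of one well
#'
#' Draws `n_events` events hierarchically: debris vs cell; cells viable or
#' necrotic; viable cells transfected or not and phagocytic or not; phagocytic
#' cells carry a zero-truncated Poisson number of beads whose per-bead
#' lognormal FITC brightnesses add on top of cellular autofluorescence. PI,
#' AF647 and scatter intensities come from the class-conditional lognormals of
#' the channel model. The hidden ground-truth labels (`is_cell`, `is_viable`,
#' `is_transfected`, `bead_count`) are recorded alongside the intensities.
#'
#' @param model A [channel_model()].
#' @param effect An [effect_profile()]; the identity profile reproduces the
#'   model unchanged.
#' @param n_events Number of events to draw (>= 1).
#' @param well_id Well label stored in the output.
#' @param seed Optional integer seed; identical seeds give identical tables.
#'   `NULL` draws from the current RNG stream.
#'
#' @return A `data.frame` (one row per event) with columns `well_id`, `FSC`,
#'   `SSC`, `PI`, `AF647`, `FITC`, `is_cell`, `is_viable`, `is_transfected`,
#'   `bead_count`.
#' @export
simulate_well <- function(model, effect = effect_profile("NT"),
                          n_events = 5000, well_id = "A01", seed = NULL) {
  stopifnot(inherits(model, "channel_model"), inherits(effect, "effect_profile"))
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1) {
    stop_invalid("n_events", "must be >= 1")
  }
  n <- as.integer(n_events)
  eff <- apply_effect(model, effect)
  with_seed(seed, {
    is_cell <- stats::runif(n) >= model$debris_fraction
    is_viable <- is_cell & (stats::runif(n) < eff$viability)
    is_transfected <- is_viable & (stats::runif(n) < eff$transfection)
    is_phago <- is_viable & (stats::runif(n) < eff$phago_prob)
    bead_count <- integer(n)
    bead_count[is_phago] <- rztpois(sum(is_phago), eff$bead_mean)

    rln <- function(k, mu, sd) stats::rlnorm(k, meanlog = mu, sdlog = sd)
    pick <- function(cond, mu1, sd1, mu0, sd0) {
      out <- numeric(n)
      out[cond] <- rln(sum(cond), mu1, sd1)
      out[!cond] <- rln(sum(!cond), mu0, sd0)
      out
    }

    fsc <- pick(is_cell, model$fsc_cell_logmean, model$fsc_cell_logsd,
                model$fsc_debris_logmean, model$fsc_debris_logsd)
    ssc <- pick(is_cell, model$ssc_cell_logmean, model$ssc_cell_logsd,
                model$ssc_debris_logmean, model$ssc_debris_logsd)
    ## debris and dead cells are PI-stained differently: dead cells are PI+,
    ## debris/free beads do not take up the dye
    pi_pos <- is_cell & !is_viable
    pi_int <- pick(pi_pos, model$pi_pos_logmean, model$pi_pos_logsd,
                   model$pi_neg_logmean, model$pi_neg_logsd)
    af647 <- pick(is_transfected, model$af647_pos_logmean, model$af647_pos_logsd,
                  model$af647_neg_logmean, model$af647_neg_logsd)

    fitc <- rln(n, model$autofluor_logmean, model$autofluor_logsd)
    if (any(is_phago)) {
      idx <- which(is_phago)
      k <- bead_count[idx]
      bright <- rln(sum(k), model$bead_brightness_logmean,
                    model$bead_brightness_logsd)
      fitc[idx] <- fitc[idx] +
        as.numeric(rowsum(bright, rep(seq_along(idx), k)))
    }
    ## free latex beads: bright in FITC but debris-like scatter
    free_bead <- !is_cell & (stats::runif(n) < model$free_bead_fraction)
    if (any(free_bead)) {
      fitc[free_bead] <- fitc[free_bead] +
        rln(sum(free_bead), model$bead_brightness_logmean,
            model$bead_brightness_logsd)
    }

    data.frame(
      well_id = well_id, FSC = fsc, SSC = ssc, PI = pi_int, AF647 = af647,
      FITC = fitc, is_cell = is_cell, is_viable = is_viable,
      is_transfected = is_transfected, bead_count = bead_count,
      stringsAsFactors = FALSE
    )
  })
}

#' Build the plate layouts of a screen
#'
#' Assigns `library_size` miRNAs to 96-well plates. Each plate carries its own
#' non-targeting (NT) control wells, cytochalasin D functional-control wells
#' and optionally untreated wells; every miRNA is placed with all of its
#' replicate wells on a single plate.
#'
#' @param library_size Number of distinct miRNAs to place.
#' @param wells_per_plate,nt_per_plate,cytod_per_plate,untreated_per_plate
#'   Plate geometry; defaults are 96 wells with 6 NT, 2 CytoD and 1 untreated
#'   well per plate.
#' @param replicates Wells per miRNA on its plate (default 3).
#' @param mirna_ids Optional character vector of miRNA labels (length
#'   `library_size`).
#' @param max_plates Abort with a sizing error if more plates would be needed.
#'
#' @return A `data.frame` with columns `plate_id`, `well`, `treatment_id`,
#'   `role` (one of `"NT"`, `"miRNA"`, `"CytoD"`, `"untreated"`, `"empty"`)
#'   and `replicate`.
#' @export
build_plate_layouts <- function(library_size,
                                wells_per_plate = 96,
                                nt_per_plate = 6,
                                cytod_per_plate = 2,
                                untreated_per_plate = 1,
                                replicates = 3,
                                mirna_ids = NULL,
                                max_plates = Inf) {
  library_size <- as.integer(library_size)
  n_control <- nt_per_plate + cytod_per_plate + untreated_per_plate
  capacity <- (wells_per_plate - n_control) %/% replicates
  if (nt_per_plate < 3) stop_invalid("nt_per_plate", "every plate needs >= 3 NT wells")
  if (capacity < 1 && library_size > 0) {
    stop("plate layout infeasible: no room for miRNA triplicates after controls",
         call. = FALSE)
  }
  n_plates <- if (library_size == 0L) 1L else ceiling(library_size / capacity)
  if (n_plates > max_plates) {
    stop(sprintf("library of %d miRNAs needs %d plates, exceeding max_plates = %s",
                 library_size, n_plates, format(max_plates)), call. = FALSE)
  }
  if (is.null(mirna_ids)) {
    mirna_ids <- sprintf("miR-sim-%04d", seq_len(library_size))
  }
  stopifnot(length(mirna_ids) == library_size, !anyDuplicated(mirna_ids))

  wells <- as.vector(t(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0)))
  wells <- wells[seq_len(wells_per_plate)]
  out <- vector("list", n_plates)
  assigned <- 0L
  for (p in seq_len(n_plates)) {
    ids <- character(wells_per_plate)
    role <- character(wells_per_plate)
    rep_idx <- integer(wells_per_plate)
    i <- 1L
    place <- function(treat, r, k) {
      sel <- i:(i + k - 1L)
      ids[sel] <<- treat
      role[sel] <<- r
      rep_idx[sel] <<- seq_len(k)
      i <<- i + k
    }
    place("NT", "NT", nt_per_plate)
    if (cytod_per_plate > 0) place("CytoD", "CytoD", cytod_per_plate)
    if (untreated_per_plate > 0) place("untreated", "untreated", untreated_per_plate)
    n_here <- min(capacity, library_size - assigned)
    for (j in seq_len(n_here)) {
      place(mirna_ids[assigned + j], "miRNA", replicates)
    }
    assigned <- assigned + n_here
    if (i <= wells_per_plate) {
      sel <- i:wells_per_plate
      ids[sel] <- NA_character_
      role[sel] <- "empty"
    }
    out[[p]] <- data.frame(
      plate_id = p, well = wells, treatment_id = ids, role = role,
      replicate = rep_idx, stringsAsFactors = FALSE
    )
  }
  layout <- do.call(rbind, out)
  layout[layout$role != "empty", , drop = FALSE]
}

#' Simulate a whole plate-based screen
#'
#' Generates the plate layouts via [build_plate_layouts()] and one event table
#' per well via [simulate_well()]. Treatments not present in `effects` (and
#' all NT/untreated wells) use the identity effect; CytoD wells default to
#' [cytod_profile()].
#'
#' @inheritParams build_plate_layouts
#' @param effects Named list of [effect_profile()]s keyed by treatment id;
#'   miRNAs absent from the list are simulated as nulls.
#' @param model The [channel_model()] shared by all wells.
#' @param n_events Events acquired per well.
#' @param seed Integer seed; the whole screen is reproducible from it.
#' @param reduce Optional function applied to each well's event table as soon
#'   as it is generated (e.g. [gate_well()] with fixed gates); when supplied,
#'   the returned `wells` list contains the reduced objects instead of event
#'   tables, which keeps large screens in bounded memory.
#'
#' @return A list with `layout` (data frame) and `wells` (named list keyed
#'   `"<plate>_<well>"` of event tables, or of `reduce()` results).
#' @export
simulate_screen <- function(library_size, effects = list(),
                            model = channel_model(),
                            n_events = 5000, seed = 1L,
                            wells_per_plate = 96, nt_per_plate = 6,
                            cytod_per_plate = 2, untreated_per_plate = 1,
                            replicates = 3, mirna_ids = NULL,
                            max_plates = Inf, reduce = NULL) {
  layout <- build_plate_layouts(
    library_size, wells_per_plate = wells_per_plate,
    nt_per_plate = nt_per_plate, cytod_per_plate = cytod_per_plate,
    untreated_per_plate = untreated_per_plate, replicates = replicates,
    mirna_ids = mirna_ids, max_plates = max_plates
  )
  identity_eff <- effect_profile("NT")
  cytod <- effects[["CytoD"]] %||% cytod_profile()
  wells <- vector("list", nrow(layout))
  names(wells) <- paste(layout$plate_id, layout$well, sep = "_")
  with_seed(seed, {
    for (i in seq_len(nrow(layout))) {
      treat <- layout$treatment_id[i]
      eff <- if (layout$role[i] == "CytoD") {
        cytod
      } else {
        effects[[treat]] %||% identity_eff
      }
      ev <- simulate_well(model, eff, n_events = n_events,
                          well_id = names(wells)[i], seed = NULL)
      wells[[i]] <- if (is.null(reduce)) ev else reduce(ev)
    }
  })
  list(layout = layout, wells = wells)
}

#' Multiplicity of infection
#'
#' Particles (beads or bacteria) added per cell, e.g. 5e5 opsonized beads on
#' 5e4 macrophages give an MOI of 10.
#'
#' @param particles Number of particles added.
#' @param cells Number of cells in the well.
#' @return `particles / cells`.
#' @export
moi <- function(particles, cells) {
  check_positive(cells, "cells")
  particles / cells
}
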