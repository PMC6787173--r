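#' Generate UTR sequences with planted miRNA seed sites
#'
#' Builds random-background 3'UTR sequences (one per requested site) with a
#' seed-complementary site of the requested class planted at a known,
#' recorded position. The bases flanking each planted site are constrained so
#' the planted coordinates carry no accidental overlapping site of a
#' *stronger* class (e.g. the base 3' of a planted 7mer-m8 is never an A,
#' which would upgrade it to an 8mer).
#'
#' @param mirna_seq miRNA sequence 5'->3' (RNA alphabet, length >= 8) or a
#'   [mirna()] object.
#' @param n_sites Number of sites (and UTR sequences) to plant; 0 gives
#'   pure-background sequences.
#' @param site_types Character vector of site classes (recycled to
#'   `n_sites`); any of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param seed Integer seed.
#' @param utr_length Length of each UTR (default 300 nt).
#' @param n_background Number of extra site-free-by-construction background
#'   sequences when `n_sites = 0` (default 3).
#' @return A list: `utrs` (named character vector) and `sites` (annotation
#'   `data.frame` with `seq_id`, `start`, `end` 0-based half-open,
#'   `site_type`).
#' @export
generate_utr_fixture <- function(mirna_seq, n_sites, site_types = "8mer",
                                 seed = 1L, utr_length = 300,
                                 n_background = 3) {
  mir <- if (inherits(mirna_seq, "mirna")) {
    mirna_seq
  } else {
    mirna("mirna", mirna_seq)
  }
  bad <- setdiff(site_types, SITE_TYPES)
  if (length(bad) > 0L) {
    stop_invalid("site_types", paste("unknown site type:", bad[1]))
  }
  pats <- site_patterns(mir)
  mdna <- rna_to_dna(mir$sequence)
  c8 <- revcomp_dna(substr(mdna, 8, 8))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                  collapse = "")
    if (n_sites == 0L) {
      utrs <- stats::setNames(
        vapply(seq_len(n_background), function(i) rand_seq(utr_length),
               character(1)),
        paste0("utr_", seq_len(n_background))
      )
      return(list(utrs = utrs,
                  sites = data.frame(seq_id = character(), start = integer(),
                                     end = integer(), site_type = character(),
                                     stringsAsFactors = FALSE)))
    }
    types <- rep_len(site_types, n_sites)
    utrs <- character(n_sites)
    ann <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      type <- types[i]
      pat <- pats[[type]]
      w <- nchar(pat)
      start <- sample(seq(10L, utr_length - w - 10L), 1L)
      s <- strsplit(rand_seq(utr_length), "")[[1]]
      s[(start + 1L):(start + w)] <- strsplit(pat, "")[[1]]
      ## guard flanks against upgrading the planted site to a stronger class
      if (type %in% c("6mer", "7mer-A1")) {
        s[start] <- sample(setdiff(bases, c8), 1L)       # no m8 extension 5'
      }
      if (type %in% c("6mer", "7mer-m8")) {
        s[start + w + 1L] <- sample(setdiff(bases, "A"), 1L)  # no A1 adenine 3'
      }
      utrs[i] <- paste(s, collapse = "")
      ann[[i]] <- data.frame(seq_id = sprintf("utr_%03d", i), start = start,
                             end = start + w, site_type = type,
                             stringsAsFactors = FALSE)
    }
    names(utrs) <- sprintf("utr_%03d", seq_len(n_sites))
    list(utrs = utrs, sites = do.call(rbind, ann))
  })
}

#' Simulate a qPCR cycle-threshold table
#'
#' Generates per-sample target and reference CT values consistent with given
#' true relative expressions under the single-normalizer model
#' `CT_target = CT_reference - log2(rel)` plus Gaussian cycle noise. A true
#' relative expression of 0 yields a not-detected sample (`detected = FALSE`,
#' `NA` target CT).
#'
#' @param true_rel Named vector of true relative expressions per sample.
#' @param ct_reference_mean Mean reference-gene CT (default 20 cycles).
#' @param noise_sd Per-measurement CT noise standard deviation (cycles).
#' @param seed Integer seed.
#' @return A `data.frame`: `sample_id`, `ct_target`, `ct_reference`,
#'   `detected`, `true_rel`.
#' @export
simulate_qpcr_table <- function(true_rel, ct_reference_mean = 20,
                                noise_sd = 0.2, seed = 1L) {
  n <- length(true_rel)
  ids <- names(true_rel) %||% paste0("sample_", seq_len(n))
  with_seed(seed, {
    ct_ref <- stats::rnorm(n, ct_reference_mean, noise_sd)
    detected <- true_rel > 0
    ct_t <- ifelse(detected,
                   ct_ref - log2(pmax(true_rel, .Machine$double.xmin)) +
                     stats::rnorm(n, 0, noise_sd),
                   NA_real_)
    data.frame(sample_id = ids, ct_target = ct_t, ct_reference = ct_ref,
               detected = detected, true_rel = unname(true_rel),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a dual-luciferase reporter plate
#'
#' Wells carry a firefly reporter with a wild-type or mutated binding-site
#' insert, co-transfected with either the miRNA mimic or the NT control;
#' Renilla luminescence controls for transfection. The miRNA arm represses
#' the firefly/Renilla ratio of each construct by the given multiplier.
#'
#' @param repression Named vector of true residual activity per construct
#'   under the miRNA arm (e.g. `c(WT = 0.6, MUT = 1.0)`).
#' @param n_wells Replicate wells per construct and arm.
#' @param renilla_logmean,renilla_logsd Lognormal Renilla luminescence (RLU).
#' @param base_ratio Mean firefly/Renilla ratio under the NT arm.
#' @param noise_sd Lognormal sd of the well-to-well ratio noise.
#' @param mirna_label Label of the miRNA arm.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `construct`, `arm`, `firefly`,
#'   `renilla` suitable for [luciferase_relative()].
#' @export
simulate_luciferase_plate <- function(repression = c(WT = 0.6, MUT = 1.0),
                                      n_wells = 6,
                                      renilla_logmean = log(5e4),
                                      renilla_logsd = 0.2,
                                      base_ratio = 2, noise_sd = 0.1,
                                      mirna_label = "miR", seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (con in names(repression)) {
      for (arm in c("NT", mirna_label)) {
        ren <- stats::rlnorm(n_wells, renilla_logmean, renilla_logsd)
        mult <- if (arm == "NT") 1 else repression[[con]]
        ff <- ren * base_ratio * mult * stats::rlnorm(n_wells, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          construct = con, arm = arm, firefly = ff, renilla = ren,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a spot-plated serial-dilution series
#'
#' Draws Poisson colony counts for six (by default) fixed-volume spots at
#' each 10-fold dilution of a sample with known titre, the generative inverse
#' of [cfu_per_ml()].
#'
#' @param titer_cfu_ml True titre of the undiluted sample (CFU/ml).
#' @param dilutions Vector of 10-fold dilution exponents.
#' @param n_spots Spots per dilution (default 6).
#' @param spot_volume_ul Volume per spot in microliters (default 10).
#' @param seed Integer seed.
#' @return A list: `counts` (matrix dilutions x spots) and `dilutions`.
#' @export
simulate_spot_series <- function(titer_cfu_ml, dilutions = 0:6, n_spots = 6,
                                 spot_volume_ul = 10, seed = 1L) {
  check_positive(titer_cfu_ml, "titer_cfu_ml")
  with_seed(seed, {
    mu <- titer_cfu_ml * (spot_volume_ul / 1000) * 10^(-dilutions)
    counts <- matrix(stats::rpois(length(dilutions) * n_spots, rep(mu, n_spots)),
                     nrow = length(dilutions))
    list(counts = counts, dilutions = dilutions)
  })
}
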