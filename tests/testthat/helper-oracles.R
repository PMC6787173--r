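# Independent oracles used across the suite. These deliberately re-derive
# results with different algorithms (loops, rejection sampling, brute-force
# string comparison, Monte Carlo) than the package's implementations.

# Zero-truncated Poisson by rejection: draw Poisson, reject zeros.
rztpois_rejection <- function(n, lambda) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- rpois(2 * n, lambda)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

# Per-event recount of the gating hierarchy with an explicit loop.
gate_well_oracle <- function(events, cfg) {
  n_cells <- n_viable <- n_trans <- n_fitc <- 0L
  fitc_sum <- 0
  pi_sum <- 0
  for (i in seq_len(nrow(events))) {
    if (!(events$FSC[i] > cfg$fsc_min && events$SSC[i] > cfg$ssc_min)) next
    n_cells <- n_cells + 1L
    if (events$PI[i] > cfg$pi_threshold) next
    n_viable <- n_viable + 1L
    pi_sum <- pi_sum + events$PI[i]
    if (!(events$AF647[i] > cfg$af647_threshold)) next
    n_trans <- n_trans + 1L
    if (!(events$FITC[i] > cfg$fitc_threshold)) next
    n_fitc <- n_fitc + 1L
    fitc_sum <- fitc_sum + events$FITC[i]
  }
  list(
    pct_cells = 100 * n_cells / nrow(events),
    pct_viable = if (n_cells > 0) 100 * n_viable / n_cells else NA_real_,
    pct_transfected = if (n_viable > 0) 100 * n_trans / n_viable else NA_real_,
    pct_fitc_pos = if (n_trans > 0) 100 * n_fitc / n_trans else NA_real_,
    mfi_fitc = if (n_fitc > 0) fitc_sum / n_fitc else NA_real_,
    mfi_pi_neg = if (n_viable > 0) pi_sum / n_viable else NA_real_
  )
}

# Monte-Carlo null distribution of the maximum |t| in a many-to-one layout:
# simulate group means and the pooled variance from normal errors directly.
mc_max_abs_t <- function(n, control_idx, df, B, seed) {
  set.seed(seed)
  k <- length(n)
  s <- sqrt(rchisq(B, df) / df)
  m0 <- rnorm(B, sd = sqrt(1 / n[control_idx]))
  mx <- rep(0, B)
  for (j in setdiff(seq_len(k), control_idx)) {
    mj <- rnorm(B, sd = sqrt(1 / n[j]))
    tj <- abs(mj - m0) / (s * sqrt(1 / n[j] + 1 / n[control_idx]))
    mx <- pmax(mx, tj)
  }
  mx
}

# Brute-force sliding-window seed-site scanner. Builds the expected site
# strings with its own complement table and compares every window; dominance
# is resolved by marking covered positions of stronger types first.
scan_sites_oracle <- function(mir_seq, utrs) {
  comp <- c(A = "T", C = "G", G = "C", U = "A", T = "A")
  dna <- function(x) ifelse(x == "U", "T", x)
  m <- strsplit(toupper(mir_seq), "")[[1]]
  rc <- function(positions) {
    paste(rev(unname(comp[m[positions]])), collapse = "")
  }
  pats <- list(
    "8mer" = paste0(rc(2:8), "A"),
    "7mer-m8" = rc(2:8),
    "7mer-A1" = paste0(rc(2:7), "A"),
    "6mer" = rc(2:7)
  )
  rows <- list()
  for (id in names(utrs)) {
    s <- toupper(utrs[[id]])
    L <- nchar(s)
    kept <- list()
    for (type in names(pats)) {
      pat <- pats[[type]]
      w <- nchar(pat)
      for (start0 in 0:(L - w)) {
        if (substr(s, start0 + 1, start0 + w) != pat) next
        overlapped <- FALSE
        for (kk in kept) {
          if (kk$type == type) next  # only stronger classes suppress a match
          if (start0 < kk$end && kk$start < start0 + w) {
            overlapped <- TRUE
            break
          }
        }
        if (!overlapped) {
          kept[[length(kept) + 1]] <- list(start = start0, end = start0 + w,
                                           type = type)
        }
      }
    }
    for (kk in kept) {
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = id, start = kk$start, end = kk$end, site_type = kk$type,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$seq_id, out$start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Watson-Crick pairing check between a UTR site and the miRNA seed region.
site_pairs_seed <- function(site_seq, mir_seq, site_type) {
  comp <- c(A = "U", C = "G", G = "C", T = "A")
  s <- strsplit(toupper(site_seq), "")[[1]]
  m <- strsplit(toupper(mir_seq), "")[[1]]
  k <- if (site_type %in% c("8mer", "7mer-m8")) 8 else 7
  seed_len <- k - 1            # miRNA positions 2..k
  # the site's first seed-paired base pairs miRNA position k, read inward
  for (j in seq_len(seed_len)) {
    target_base <- s[j]
    mir_base <- m[k - j + 1]
    if (comp[[target_base]] != mir_base) return(FALSE)
  }
  if (site_type %in% c("8mer", "7mer-A1")) {
    if (s[length(s)] != "A") return(FALSE)
  }
  TRUE
}

random_utrs <- function(n, len, seed) {
  set.seed(seed)
  setNames(
    vapply(seq_len(n),
           function(i) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                             collapse = ""),
           character(1)),
    paste0("r", seq_len(n))
  )
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
}
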