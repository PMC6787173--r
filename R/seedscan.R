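#' A microRNA with its seed region
#'
#' @param name miRNA label (e.g. `"miR-124-5p"`).
#' @param sequence Mature miRNA sequence 5'->3' in RNA alphabet
#'   (`A`, `C`, `G`, `U`), length >= 8.
#' @return An object of class `mirna` with fields `name`, `sequence` and
#'   `seed` (positions 2-8).
#' @export
mirna <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 8L) {
    stop_invalid("sequence", "miRNA must be at least 8 nt long")
  }
  if (grepl("[^ACGU]", sequence)) {
    stop_invalid("sequence", "alphabet must be {A, C, G, U}")
  }
  structure(list(name = name, sequence = sequence,
                 seed = substr(sequence, 2, 8)),
            class = "mirna")
}

## RNA -> DNA and reverse complement for short seed strings (DNA space)
rna_to_dna <- function(x) chartr("U", "T", toupper(x))

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## The canonical site classes, strongest first. Each site is the sense-strand
## (5'->3') DNA subsequence of the UTR: the reverse complement of miRNA
## positions 2..7 (6mer) or 2..8 (m8 types), with an adenine opposite miRNA
## position 1 (i.e. at the 3' end of the site) for the A1 classes.
SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

site_patterns <- function(mir) {
  stopifnot(inherits(mir, "mirna"))
  m <- rna_to_dna(mir$sequence)
  m2_7 <- substr(m, 2, 7)
  m2_8 <- substr(m, 2, 8)
  c("8mer" = paste0(revcomp_dna(m2_8), "A"),
    "7mer-m8" = revcomp_dna(m2_8),
    "7mer-A1" = paste0(revcomp_dna(m2_7), "A"),
    "6mer" = revcomp_dna(m2_7))
}

check_utr_alphabet <- function(utrs) {
  for (id in names(utrs)) {
    hit <- regexpr("[^ACGTN]", utrs[[id]])
    if (hit > 0L) {
      stop(sprintf("invalid character in sequence '%s' at position %d", id,
                   as.integer(hit)), call. = FALSE)
    }
  }
}

as_utr_set <- function(utrs) {
  if (inherits(utrs, "DNAStringSet")) {
    utrs <- stats::setNames(as.character(utrs), names(utrs))
  }
  if (is.null(names(utrs)) || any(names(utrs) == "")) {
    names(utrs) <- paste0("utr_", seq_along(utrs))
  }
  utrs <- toupper(utrs)
  check_utr_alphabet(utrs)
  utrs
}

#' Scan 3'UTR sequences for canonical miRNA seed sites
#'
#' Reports every occurrence of the four canonical site classes (6mer,
#' 7mer-A1, 7mer-m8, 8mer; all defined against miRNA seed positions 2-8 with
#' the adenine-opposite-position-1 rule for the A1 classes) on the sense
#' strand of DNA-alphabet UTRs. When matches of different classes overlap,
#' only the strongest class is reported (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#' `N` bases never match. Coordinates are 0-based half-open.
#'
#' @param mir A [mirna()].
#' @param utrs Named character vector of UTR sequences (alphabet
#'   `{A,C,G,T,N}`, 5'->3' sense strand) or a [Biostrings::DNAStringSet].
#' @return A `data.frame` with columns `seq_id`, `start`, `end` (0-based
#'   half-open) and `site_type`, sorted by sequence and position.
#' @export
scan_sites <- function(mir, utrs) {
  utrs <- as_utr_set(utrs)
  pats <- site_patterns(mir)
  rows <- list()
  for (id in names(utrs)) {
    subject <- Biostrings::DNAString(utrs[[id]])
    found <- list()
    for (type in SITE_TYPES) {
      mt <- Biostrings::matchPattern(pats[[type]], subject, fixed = TRUE)
      if (length(mt) == 0L) next
      found[[type]] <- data.frame(
        seq_id = id,
        start = IRanges::start(mt) - 1L,
        end = IRanges::end(mt),
        site_type = type,
        stringsAsFactors = FALSE
      )
    }
    if (length(found) == 0L) next
    ## dominance: drop any site overlapping an already-kept stronger site
    kept <- NULL
    for (type in SITE_TYPES) {
      f <- found[[type]]
      if (is.null(f)) next
      if (!is.null(kept) && nrow(f) > 0L) {
        overlaps <- vapply(seq_len(nrow(f)), function(i) {
          any(f$start[i] < kept$end & kept$start < f$end[i])
        }, logical(1))
        f <- f[!overlaps, , drop = FALSE]
      }
      kept <- rbind(kept, f)
    }
    rows[[id]] <- kept
  }
  if (length(rows) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$seq_id, out$start, out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## positions of a site (relative, 0-based) that pair with miRNA seed bases,
## together with the miRNA position each pairs with. The site is read 5'->3',
## so its first base pairs the highest miRNA position; a trailing A1 adenine
## pairs miRNA position 1 and is not part of the seed proper.
seed_paired_positions <- function(site_type) {
  switch(site_type,
    "6mer" = list(offsets = 0:5, mir_pos = 7:2),
    "7mer-A1" = list(offsets = 0:5, mir_pos = 7:2),
    "7mer-m8" = list(offsets = 0:6, mir_pos = 8:2),
    "8mer" = list(offsets = 0:6, mir_pos = 8:2),
    stop_invalid("site_type", paste("unknown site type", site_type))
  )
}

#' Mutate a seed-matched binding site so it no longer pairs
#'
#' Implements the binding-site mutagenesis rule used for reporter constructs:
#' at every position of the site that pairs with the miRNA seed, the target
#' base is replaced by the base *identical* to the miRNA base at that
#' position (in DNA alphabet), which abolishes Watson-Crick complementarity
#' at every seed position. The output has the same length as the input and
#' contains no seed site for the same miRNA. Applying the function to an
#' already-mutated site returns it unchanged (idempotence); any other input
#' without a seed match is an error.
#'
#' @param site_seq DNA sequence containing a canonical seed site for `mir`.
#' @param mir A [mirna()].
#' @return The mutated DNA sequence.
#' @export
mutate_site <- function(site_seq, mir) {
  site_seq <- toupper(site_seq)
  sites <- scan_sites(mir, c(site = site_seq))
  if (nrow(sites) == 0L) {
    ## idempotence: recognize sequences that already carry the mutated motif
    pats <- site_patterns(mir)
    mutated_motifs <- vapply(SITE_TYPES, function(type) {
      mutate_window(pats[[type]], type, mir)
    }, character(1))
    if (any(vapply(mutated_motifs, grepl, logical(1), x = site_seq,
                   fixed = TRUE))) {
      return(site_seq)
    }
    stop("no canonical seed site for this miRNA found in 'site_seq'",
         call. = FALSE)
  }
  out <- site_seq
  for (round in 1:10) {
    for (i in seq_len(nrow(sites))) {
      window <- substr(out, sites$start[i] + 1L, sites$end[i])
      repl <- mutate_window(window, sites$site_type[i], mir)
      substr(out, sites$start[i] + 1L, sites$end[i]) <- repl
    }
    ## chance leftovers (e.g. a match straddling a mutated window's flank)
    sites <- scan_sites(mir, c(site = out))
    if (nrow(sites) == 0L) return(out)
  }
  stop("mutation did not converge to a site-free sequence", call. = FALSE)
}

mutate_window <- function(window, site_type, mir) {
  pairing <- seed_paired_positions(site_type)
  mdna <- rna_to_dna(mir$sequence)
  chars <- strsplit(window, "")[[1]]
  for (j in seq_along(pairing$offsets)) {
    chars[pairing$offsets[j] + 1L] <-
      substr(mdna, pairing$mir_pos[j], pairing$mir_pos[j])
  }
  paste(chars, collapse = "")
}

#' Emit wild-type and mutated reporter insert sequences for a site
#'
#' Extracts the site with symmetric flanking sequence from its UTR (clipped
#' to the sequence bounds with a warning) and returns the wild-type insert
#' together with the seed-mutated version, ready to be written as FASTA for
#' reporter cloning. The two inserts differ only within the site coordinates.
#'
#' @param utrs Named character vector (or `DNAStringSet`) containing the
#'   site's sequence.
#' @param site One row of a [scan_sites()] table (`seq_id`, `start`, `end`,
#'   `site_type`).
#' @param mir The [mirna()] the site matches.
#' @param flank Number of flanking bases on each side (>= 0).
#' @return A list: `wt`, `mut` (character sequences), `insert_start`
#'   (0-based start of the insert on the UTR), `site_offset` (0-based offset
#'   of the site within the insert).
#' @export
emit_reporter_inserts <- function(utrs, site, mir, flank = 20) {
  if (flank < 0) stop_invalid("flank", "must be >= 0")
  utrs <- as_utr_set(utrs)
  if (!site$seq_id %in% names(utrs)) {
    stop_invalid("site", "seq_id not found in 'utrs'")
  }
  seq <- utrs[[site$seq_id]]
  len <- nchar(seq)
  from <- max(0L, site$start - as.integer(flank))
  to <- min(len, site$end + as.integer(flank))
  if (from > site$start - flank || to < site$end + flank) {
    warning("flank clipped to sequence bounds", call. = FALSE)
  }
  wt <- substr(seq, from + 1L, to)
  offset <- site$start - from
  window <- substr(seq, site$start + 1L, site$end)
  mut <- wt
  substr(mut, offset + 1L, offset + nchar(window)) <-
    mutate_window(window, site$site_type, mir)
  list(wt = wt, mut = mut, insert_start = from, site_offset = offset)
}
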