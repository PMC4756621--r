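#' Read a minimal variant table
#'
#' Tab-delimited `contig pos1 ref alt` with 1-based positions (the VCF
#' convention); a header row or `#` comment lines are skipped.
#'
#' @param path file path.
#' @return Data frame with `contig`, `pos` (0-based), `ref`, `alt`.
#' @export
read_variants <- function(path) {
  lines <- readLines(path)
  keep <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(keep) && grepl("^contig", keep[1L], ignore.case = TRUE)) {
    keep <- keep[-1L]
  }
  if (length(keep) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(keep), "[ \t]+")
  bad <- which(lengths(f) < 4L)
  if (length(bad)) {
    stop("malformed variant line: expected 4 fields (contig pos1 ref alt)",
         call. = FALSE)
  }
  pos1 <- as.integer(vapply(f, `[`, character(1L), 2L))
  if (anyNA(pos1) || any(pos1 < 1L)) {
    stop("variant positions must be 1-based positive integers",
         call. = FALSE)
  }
  data.frame(contig = vapply(f, `[`, character(1L), 1L),
             pos = pos1 - 1L,
             ref = toupper(vapply(f, `[`, character(1L), 3L)),
             alt = toupper(vapply(f, `[`, character(1L), 4L)),
             stringsAsFactors = FALSE)
}

complement_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

#' Motif consequences of variants
#'
#' For every variant overlapping a motif match, reports the 0-based
#' position of the variant within the motif (strand-aware: minus-strand
#' matches index from the match's 3'-most genomic base and alleles are
#' complemented), whether that motif column carries at least `bits_min`
#' bits of information (a "highly informative position"), and the
#' binding-score change obtained by substituting the alternate allele:
#' `logodds[position, alt] - logodds[position, ref]` in log2-odds units.
#' Swapping ref and alt negates the score change.
#'
#' Only single-nucleotide substitutions get a score change; other
#' variants overlapping a match are reported with `is_snv = FALSE` and
#' `score_change = NA`. Variants overlapping no match produce no rows.
#'
#' @param variants data frame from [read_variants()] (`contig`, `pos`
#'   0-based, `ref`, `alt`).
#' @param matches motif-match data frame (must carry `strand` and
#'   `pwm_id`).
#' @param pwms a [pwm()], or a list of them covering every `pwm_id` in
#'   `matches`.
#' @param thresh a [thresholds()]; `bits_min` and `pseudocount` are used.
#' @return Data frame, one row per (variant, overlapping match):
#'   `contig`, `pos`, `ref`, `alt`, `pwm_id`, `match_start`, `match_end`,
#'   `match_strand`, `in_motif`, `motif_position`, `high_information`,
#'   `score_change`, `is_snv`.
#' @export
motif_consequence <- function(variants, matches, pwms,
                              thresh = thresholds()) {
  thresh <- as_thresholds(thresh)
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  names(pwms) <- vapply(pwms, `[[`, character(1L), "id")
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      pwm_id = character(), match_start = integer(),
                      match_end = integer(), match_strand = character(),
                      in_motif = logical(), motif_position = integer(),
                      high_information = logical(),
                      score_change = numeric(), is_snv = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || nrow(matches) == 0L) return(empty)
  # a point variant occupies [pos, pos + 1)
  vint <- data.frame(contig = variants$contig, start = variants$pos,
                     end = variants$pos + 1L, strand = ".",
                     stringsAsFactors = FALSE)
  hits <- overlap_pairs(vint, matches, type = "any")
  if (nrow(hits) == 0L) return(empty)
  rows <- vector("list", nrow(hits))
  for (j in seq_len(nrow(hits))) {
    v <- variants[hits$query[j], ]
    m <- matches[hits$subject[j], ]
    p <- pwms[[m$pwm_id]]
    if (is.null(p)) {
      stop("no PWM supplied for match pwm_id '", m$pwm_id, "'",
           call. = FALSE)
    }
    is_snv <- nchar(v$ref) == 1L && nchar(v$alt) == 1L &&
      v$ref %in% DNA_ALPHABET && v$alt %in% DNA_ALPHABET
    mp <- if (m$strand == "-") {
      (m$end - 1L) - v$pos
    } else {
      v$pos - m$start
    }
    hi <- column_information(p, mp, thresh) >= thresh$bits_min
    sc <- NA_real_
    if (is_snv) {
      sm <- to_log_odds(p, thresh)
      ref_b <- if (m$strand == "-") complement_base(v$ref) else v$ref
      alt_b <- if (m$strand == "-") complement_base(v$alt) else v$alt
      sc <- sm$logodds[mp + 1L, alt_b] - sm$logodds[mp + 1L, ref_b]
    }
    rows[[j]] <- data.frame(
      contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
      pwm_id = m$pwm_id, match_start = m$start, match_end = m$end,
      match_strand = m$strand, in_motif = TRUE,
      motif_position = as.integer(mp), high_information = hi,
      score_change = sc, is_snv = is_snv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write variant motif consequences
#'
#' @param consequences data frame from [motif_consequence()].
#' @param path output path (tab-delimited with header).
#' @export
write_consequences <- function(consequences, path) {
  df <- consequences
  df$pos1 <- df$pos + 1L
  cols <- c("contig", "pos1", "ref", "alt", "pwm_id", "match_start",
            "match_end", "match_strand", "in_motif", "motif_position",
            "high_information", "score_change", "is_snv")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
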