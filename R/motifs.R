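DNA_ALPHABET <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM holds an `L x 4` non-negative count matrix over the fixed
#' alphabet order A, C, G, T (rows are motif positions) plus a background
#' base composition on the simplex.
#'
#' @param id matrix identifier (e.g. a JASPAR accession).
#' @param name TF name; defaults to `id`.
#' @param counts `L x 4` non-negative numeric matrix (or a 4-vector for a
#'   single-position motif).
#' @param background length-4 base composition summing to 1; uniform by
#'   default.
#' @return Object of class `"pwm"`.
#' @examples
#' pwm("M1", counts = rbind(c(10, 0, 0, 0), c(0, 10, 0, 0)))
#' @export
pwm <- function(id, name = id, counts, background = rep(0.25, 4)) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L) {
    stop("pwm '", id, "': counts must have 4 columns (A, C, G, T)",
         call. = FALSE)
  }
  if (nrow(counts) < 1L) stop("pwm '", id, "': empty matrix", call. = FALSE)
  if (any(counts < 0) || anyNA(counts)) {
    stop("pwm '", id, "': negative or missing counts", call. = FALSE)
  }
  background <- as.numeric(background)
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop("pwm '", id, "': background must be a 4-vector on the simplex",
         call. = FALSE)
  }
  colnames(counts) <- DNA_ALPHABET
  rownames(counts) <- NULL
  structure(list(id = as.character(id), name = as.character(name),
                 counts = counts, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM ", x$id, " (", x$name, "), ", nrow(x$counts),
      " positions, consensus ", consensus_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' Per-position arg-max base, ties resolved in A < C < G < T order.
#'
#' @param x a [pwm()] or score matrix from [to_log_odds()].
#' @return Character scalar of length `L`.
#' @export
consensus_sequence <- function(x) {
  m <- if (inherits(x, "pwm")) x$counts else x$logodds
  paste(DNA_ALPHABET[max.col(m, ties.method = "first")], collapse = "")
}

#' Read PWMs in JASPAR matrix format
#'
#' Parses both common dialects: four bracketed rows
#' (`A  [ 4 19  0 ]`) and four plain count rows, each preceded by a
#' `>id name` header. Rows are taken in A, C, G, T order; when base
#' letters are present they are checked.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @param background background composition assigned to every matrix.
#' @return List of [pwm()] objects (possibly empty).
#' @seealso [write_jaspar()]
#' @export
read_jaspar <- function(path = NULL, text = NULL,
                        background = rep(0.25, 4)) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- which(startsWith(lines, ">"))
  if (length(headers) == 0L) {
    if (length(lines) == 0L) return(list())
    stop("no JASPAR headers ('>') found", call. = FALSE)
  }
  out <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    h <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(h, "[ \t]+")[[1L]]
    id <- parts[1L]
    name <- if (length(parts) >= 2L) {
      paste(parts[-1L], collapse = " ")
    } else id
    body <- lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    if (length(body) != 4L) {
      stop("JASPAR matrix '", id, "': expected 4 count rows, got ",
           length(body), call. = FALSE)
    }
    rows <- vector("list", 4L)
    for (r in seq_len(4L)) {
      ln <- body[r]
      letter <- regmatches(ln, regexpr("^[ACGTacgt]", ln))
      if (length(letter) == 1L) {
        if (toupper(letter) != DNA_ALPHABET[r]) {
          stop("JASPAR matrix '", id, "': row ", r, " labelled '",
               letter, "', expected '", DNA_ALPHABET[r], "'",
               call. = FALSE)
        }
        ln <- sub("^[ACGTacgt]", "", ln)
      }
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(
        as.numeric(strsplit(trimws(ln), "[ \t]+")[[1L]]))
      if (length(vals) == 0L || anyNA(vals)) {
        stop("JASPAR matrix '", id, "': unparseable count row ", r,
             call. = FALSE)
      }
      if (any(vals < 0)) {
        stop("JASPAR matrix '", id, "': negative counts in row ", r,
             call. = FALSE)
      }
      rows[[r]] <- vals
    }
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("JASPAR matrix '", id, "': ragged rows (lengths ",
           paste(lens, collapse = ", "), ")", call. = FALSE)
    }
    counts <- t(do.call(rbind, rows))  # rows become positions
    out[[i]] <- pwm(id, name, counts, background)
  }
  out
}

#' Write PWMs in JASPAR (bracketed) format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @export
write_jaspar <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$name), con)
    for (r in seq_len(4L)) {
      writeLines(paste0(DNA_ALPHABET[r], "  [ ",
                        paste(format(p$counts[, r], trim = TRUE,
                                     scientific = FALSE),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

# pseudocounted probability matrix shared by scoring and information content
pwm_probabilities <- function(p, pseudocount) {
  counts <- p$counts
  colsum <- rowSums(counts)
  if (any(colsum + pseudocount <= 0)) {
    stop("pwm '", p$id, "': zero count column and no pseudocount",
         call. = FALSE)
  }
  bg <- matrix(p$background, nrow(counts), 4L, byrow = TRUE)
  (counts + pseudocount * bg * colsum) / (colsum * (1 + pseudocount))
}

#' Log-odds score matrix from a PWM
#'
#' Per-position probabilities are regularized with a
#' background-proportional pseudocount,
#' `p[i,b] = (counts[i,b] + c * bg_b * colsum_i) / (colsum_i * (1 + c))`,
#' then converted to `log2(p[i,b] / bg_b)`. A window's binding score is
#' the sum of its per-position log-odds; `max_score`/`min_score` are the
#' best and worst attainable scores.
#'
#' @param p a [pwm()].
#' @param thresh a [thresholds()]; `pseudocount` is used.
#' @return Object of class `"score_matrix"` with fields `pwm_id`,
#'   `logodds` (`L x 4`), `max_score`, `min_score`, `background`.
#' @export
to_log_odds <- function(p, thresh = thresholds()) {
  stopifnot(inherits(p, "pwm"))
  thresh <- as_thresholds(thresh)
  if (any(p$background <= 0)) {
    stop("pwm '", p$id, "': background must be strictly positive for ",
         "log-odds scoring", call. = FALSE)
  }
  prob <- pwm_probabilities(p, thresh$pseudocount)
  if (any(prob == 0)) {
    stop("pwm '", p$id, "': zero probability cell; increase pseudocount",
         call. = FALSE)
  }
  lo <- log2(prob / matrix(p$background, nrow(prob), 4L, byrow = TRUE))
  colnames(lo) <- DNA_ALPHABET
  structure(list(pwm_id = p$id,
                 logodds = lo,
                 max_score = sum(apply(lo, 1L, max)),
                 min_score = sum(apply(lo, 1L, min)),
                 background = p$background),
            class = "score_matrix")
}

#' Information content of a PWM column
#'
#' `2 + sum_b p_b log2 p_b` in bits, using the same pseudocounted
#' probabilities as [to_log_odds()]; ranges from 0 (uninformative) to 2
#' (fully specific).
#'
#' @param p a [pwm()].
#' @param i 0-based motif position index.
#' @param thresh a [thresholds()]; `pseudocount` is used.
#' @return Information content in bits, in `[0, 2]`.
#' @examples
#' m <- pwm("M1", counts = c(1, 0, 0, 0))
#' column_information(m, 0, thresholds(pseudocount = 0))  # 2 bits
#' @export
column_information <- function(p, i, thresh = thresholds()) {
  stopifnot(inherits(p, "pwm"))
  thresh <- as_thresholds(thresh)
  L <- nrow(p$counts)
  if (any(i < 0) || any(i >= L)) {
    stop("column index out of range [0, ", L - 1L, "]", call. = FALSE)
  }
  prob <- pwm_probabilities(p, thresh$pseudocount)
  vapply(i, function(ii) {
    pv <- prob[ii + 1L, ]
    terms <- ifelse(pv > 0, pv * log2(pv), 0)
    max(0, min(2, 2 + sum(terms)))
  }, numeric(1L))
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], DNA_ALPHABET)
}

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over A, C, G, T, N (case-insensitive).
#' @return Reverse-complemented upper-case string.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(seq), "", fixed = TRUE)[[1L]]),
               collapse = ""))
}

# scores of all windows of one strand; NA where the window contains N
window_scores <- function(code, lo) {
  L <- nrow(lo)
  nw <- length(code) - L + 1L
  if (nw < 1L) return(numeric(0L))
  scores <- numeric(nw)
  for (i in seq_len(L)) {
    scores <- scores + lo[i, ][code[i:(i + nw - 1L)]]
  }
  scores
}

#' Scan a sequence for motif matches
#'
#' Slides the score matrix over every window of the sequence; windows
#' scoring at least `threshold` become matches. With
#' `both_strands = TRUE` the reverse strand is scored as well (windows
#' scored on their reverse complement, matches reported on forward
#' coordinates with strand `"-"`). Windows containing `N` are skipped.
#'
#' @param seq nucleotide string over A, C, G, T, N.
#' @param sm a `"score_matrix"` from [to_log_odds()].
#' @param threshold minimum score to report; defaults to 60% of
#'   `max_score` — a deliberately lenient pre-filter, the empirical
#'   p-value filter being the real gate.
#' @param both_strands scan the reverse strand too?
#' @param contig contig name recorded on the matches.
#' @return Motif-match data frame: `contig`, `start`, `end`, `strand`,
#'   `pwm_id`, `score`, `p_emp` (`NA` before calibration), ordered by
#'   position then strand.
#' @examples
#' m <- pwm("M1", counts = rbind(c(9, 1, 0, 0), c(0, 0, 0, 10)))
#' sm <- to_log_odds(m)
#' scan_sequence("CCATCC", sm, threshold = 0)
#' @export
scan_sequence <- function(seq, sm, threshold = NULL, both_strands = TRUE,
                          contig = "seq") {
  stopifnot(inherits(sm, "score_matrix"))
  if (is.null(threshold)) threshold <- 0.6 * sm$max_score
  code <- encode_dna(seq)
  L <- nrow(sm$logodds)
  fwd <- window_scores(code, sm$logodds)
  hits <- list()
  sel <- which(!is.na(fwd) & fwd >= threshold)
  if (length(sel)) {
    hits[[1L]] <- data.frame(contig = contig, start = sel - 1L,
                             end = sel - 1L + L, strand = "+",
                             pwm_id = sm$pwm_id, score = fwd[sel],
                             stringsAsFactors = FALSE)
  }
  if (both_strands) {
    # scoring the forward window with the reversed-complemented matrix
    # equals scoring the window's reverse complement with the original
    lo_rc <- sm$logodds[L:1, 4:1, drop = FALSE]
    rev_ <- window_scores(code, lo_rc)
    sel <- which(!is.na(rev_) & rev_ >= threshold)
    if (length(sel)) {
      hits[[length(hits) + 1L]] <-
        data.frame(contig = contig, start = sel - 1L, end = sel - 1L + L,
                   strand = "-", pwm_id = sm$pwm_id, score = rev_[sel],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      pwm_id = character(), score = numeric(),
                      p_emp = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$p_emp <- NA_real_
  out
}

#' Empirical score null for a PWM
#'
#' Scores `n_samples` windows whose bases are drawn i.i.d. from the given
#' background composition; the sorted scores form the empirical null used
#' for single-tail p-values. Deterministic given `seed`.
#'
#' @param sm a `"score_matrix"`.
#' @param background base composition to sample from; defaults to the
#'   score matrix's own background.
#' @param n_samples number of null windows (>= `min_size`).
#' @param seed RNG seed.
#' @param min_size floor on the null size.
#' @return Object of class `"empirical_null"`: `pwm_id`, sorted `scores`,
#'   `size`.
#' @export
build_empirical_null <- function(sm, background = NULL,
                                 n_samples = 100000L, seed = 1L,
                                 min_size = 1000L) {
  stopifnot(inherits(sm, "score_matrix"))
  if (is.null(background)) background <- sm$background
  background <- as.numeric(background)
  stopifnot(length(background) == 4L, all(background >= 0),
            abs(sum(background) - 1) < 1e-9)
  if (n_samples < min_size) {
    stop("n_samples must be at least ", min_size, call. = FALSE)
  }
  L <- nrow(sm$logodds)
  scores <- with_preserved_seed(seed, {
    draws <- matrix(sample.int(4L, n_samples * L, replace = TRUE,
                               prob = background),
                    nrow = n_samples, ncol = L)
    s <- numeric(n_samples)
    for (i in seq_len(L)) s <- s + sm$logodds[i, ][draws[, i]]
    s
  })
  structure(list(pwm_id = sm$pwm_id, scores = sort(scores),
                 size = as.integer(n_samples)),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat("empirical null for ", x$pwm_id, ": ", x$size, " scores, range [",
      format(min(x$scores), digits = 4), ", ",
      format(max(x$scores), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Write / read an empirical null
#'
#' @param null an `"empirical_null"`.
#' @param path file path.
#' @export
write_null <- function(null, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# empirical_null\t", null$pwm_id, "\t", null$size),
             con)
  writeLines(format(null$scores, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_null
#' @export
read_null <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  scores <- as.numeric(lines[-1L])
  structure(list(pwm_id = hdr[2L], scores = sort(scores),
                 size = length(scores)),
            class = "empirical_null")
}

#' Single-tail empirical p-value of motif scores
#'
#' Upper-tail, add-one estimator:
#' `p = (1 + #\{null >= score\}) / (size + 1)`; never exactly zero,
#' monotone non-increasing in the score.
#'
#' @param score numeric vector of match scores.
#' @param null an `"empirical_null"` (same PWM).
#' @return P-values in `(0, 1]`.
#' @export
empirical_pvalue <- function(score, null) {
  stopifnot(inherits(null, "empirical_null"), null$size >= 1L)
  n_less <- findInterval(score, null$scores, left.open = TRUE)
  (1 + (null$size - n_less)) / (null$size + 1)
}

#' Filter motif matches by empirical p-value
#'
#' Populates `p_emp` on every match from the null, then retains exactly
#' the matches with `p_emp <= thresholds$p_max` (default 5%).
#'
#' @param matches motif-match data frame from [scan_sequence()].
#' @param null matching `"empirical_null"`.
#' @param thresh a [thresholds()]; `p_max` is used.
#' @return Filtered matches with `p_emp` populated.
#' @export
filter_matches <- function(matches, null, thresh = thresholds()) {
  thresh <- as_thresholds(thresh)
  if (nrow(matches) == 0L) return(matches)
  if (!all(matches$pwm_id == null$pwm_id)) {
    stop("matches and null refer to different PWMs", call. = FALSE)
  }
  matches$p_emp <- empirical_pvalue(matches$score, null)
  out <- matches[matches$p_emp <= thresh$p_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict matches to those lying within peaks
#'
#' Keeps matches fully contained in at least one peak interval
#' (containment, not mere overlap).
#'
#' @param matches motif-match data frame.
#' @param peaks peak data frame (see [read_bed()] type `"peak"`).
#' @return The contained subset of `matches`.
#' @export
within_peaks <- function(matches, peaks) {
  if (nrow(matches) == 0L) return(matches)
  hits <- overlap_pairs(matches, peaks, type = "within")
  out <- matches[sort(unique(hits$query)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate matches with overlapping features
#'
#' Maps every match to the identifiers of all features overlapping it by
#' at least one base.
#'
#' @param matches motif-match data frame.
#' @param features data frame of peaks or regulatory features; feature ids
#'   are taken from `stable_id`, `source`, or failing those the row index.
#' @return Named list, one (possibly empty) character vector of feature
#'   ids per match row.
#' @export
associate_matches <- function(matches, features) {
  ids <- if ("stable_id" %in% names(features)) {
    features$stable_id
  } else if ("source" %in% names(features) &&
             !anyNA(features$source)) {
    features$source
  } else {
    as.character(seq_len(nrow(features)))
  }
  hits <- overlap_pairs(matches, features, type = "any")
  out <- rep(list(character()), nrow(matches))
  if (nrow(hits)) {
    sp <- split(ids[hits$subject], hits$query)
    out[as.integer(names(sp))] <- lapply(sp, unname)
  }
  names(out) <- rownames(matches)
  out
}

#' Binding-score ratio of a match
#'
#' The match score divided by the PWM's optimal attainable score; 1 for a
#' consensus placement, possibly non-positive for poor matches (reported
#' as-is).
#'
#' @param match one or more motif-match rows (uses `score`).
#' @param sm the `"score_matrix"` that scored the match.
#' @return Numeric vector of ratios.
#' @export
score_ratio <- function(match, sm) {
  stopifnot(inherits(sm, "score_matrix"))
  if (sm$max_score == 0) {
    stop("score ratio undefined: max_score is 0", call. = FALSE)
  }
  match$score / sm$max_score
}

#' Associate PWMs with genes
#'
#' A PWM's protein identifier is mapped to a gene either by a direct
#' same-species cross-reference or, failing that, by the best protein
#' alignment hit; both tables are precomputed elsewhere. A direct
#' cross-reference always wins; PWMs absent from both tables are left
#' unmapped.
#'
#' @param xrefs data frame with columns `pwm_id`, `gene` (direct
#'   cross-references); at most one row per PWM.
#' @param besthits data frame with columns `pwm_id`, `gene` (best
#'   alignment hits).
#' @return Named character vector `pwm_id -> gene`.
#' @export
associate_pwm_to_gene <- function(xrefs, besthits) {
  stopifnot(all(c("pwm_id", "gene") %in% names(xrefs)),
            all(c("pwm_id", "gene") %in% names(besthits)))
  conf <- unique(xrefs[, c("pwm_id", "gene")])
  dup <- unique(conf$pwm_id[duplicated(conf$pwm_id)])
  if (length(dup)) {
    stop("conflicting direct cross-references for PWM(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bh <- besthits[!duplicated(besthits$pwm_id), , drop = FALSE]
  bh <- bh[!(bh$pwm_id %in% conf$pwm_id), , drop = FALSE]
  out <- c(stats::setNames(as.character(conf$gene), conf$pwm_id),
           stats::setNames(as.character(bh$gene), bh$pwm_id))
  out[order(names(out))]
}

#' Write / read a motif-match table
#'
#' Tab-delimited with a commented header; records the add-one empirical
#' p-value estimator in the header comment.
#'
#' @param matches motif-match data frame.
#' @param path file path.
#' @export
write_matches <- function(matches, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# motif matches; p_emp = (1 + #{null >= score})/(size + 1)",
               "contig\tstart0\tend\tstrand\tpwm_id\tscore\tp_emp"), con)
  if (nrow(matches)) {
    writeLines(paste(matches$contig, matches$start, matches$end,
                     matches$strand, matches$pwm_id,
                     format(matches$score, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     ifelse(is.na(matches$p_emp), ".",
                            format(matches$p_emp, digits = 17,
                                   trim = TRUE, scientific = FALSE)),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matches
#' @export
read_matches <- function(path) {
  lines <- readLines(path)
  keep <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(keep) && startsWith(keep[1L], "contig")) keep <- keep[-1L]
  if (length(keep) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      pwm_id = character(), score = numeric(),
                      p_emp = numeric(), stringsAsFactors = FALSE))
  }
  f <- strsplit(keep, "\t", fixed = TRUE)
  data.frame(
    contig = vapply(f, `[`, character(1L), 1L),
    start = as.integer(vapply(f, `[`, character(1L), 2L)),
    end = as.integer(vapply(f, `[`, character(1L), 3L)),
    strand = vapply(f, `[`, character(1L), 4L),
    pwm_id = vapply(f, `[`, character(1L), 5L),
    score = as.numeric(vapply(f, `[`, character(1L), 6L)),
    p_emp = suppressWarnings(
      as.numeric(ifelse(vapply(f, `[`, character(1L), 7L) == ".",
                        NA, vapply(f, `[`, character(1L), 7L)))),
    stringsAsFactors = FALSE)
}
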