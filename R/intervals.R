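#' Genomic intervals
#'
#' Constructs a data frame of genomic intervals in the package's internal
#' convention: 0-based, half-open `[start, end)`, strand one of `"+"`,
#' `"-"`, `"."`. Most functions in the package accept and return data
#' frames with at least the columns `contig`, `start`, `end`, `strand`.
#'
#' @param contig contig (chromosome) names; non-empty strings.
#' @param start 0-based inclusive start offsets.
#' @param end exclusive end offsets; must satisfy `start < end`.
#' @param strand `"+"`, `"-"` or `"."` (strandless).
#' @return A data frame with columns `contig`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 0, 10)
#' @export
genomic_intervals <- function(contig, start, end, strand = ".") {
  strand <- rep(as.character(strand), length.out = length(contig))
  df <- data.frame(contig = as.character(contig),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  req <- c("contig", "start", "end")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(what, " data frame lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$contig)) || anyNA(df$contig)) {
    stop(what, ": contig must be non-empty", call. = FALSE)
  }
  if (anyNA(df$start) || anyNA(df$end)) {
    stop(what, ": start/end must not be NA", call. = FALSE)
  }
  bad <- df$start < 0 | df$start >= df$end
  if (any(bad)) {
    stop(what, ": require 0 <= start < end; violated at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop(what, ": strand must be one of '+', '-', '.'", call. = FALSE)
  }
  invisible(df)
}

# internal: 0-based half-open data frame -> GRanges (1-based inclusive)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = "*"
  )
}

granges_to_df0 <- function(gr) {
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = ".",
             stringsAsFactors = FALSE)
}

#' Shared bases between two intervals
#'
#' Number of base positions covered by both intervals; 0 when contigs
#' differ or the intervals are disjoint (half-open abutment shares no base).
#'
#' @param a,b single-row interval data frames or lists with `contig`,
#'   `start`, `end`.
#' @return Non-negative integer overlap length.
#' @examples
#' a <- genomic_intervals("chr1", 0, 10)
#' b <- genomic_intervals("chr1", 5, 15)
#' overlap_length(a, b)  # 5
#' @export
overlap_length <- function(a, b) {
  if (as.character(a$contig[1L]) != as.character(b$contig[1L])) return(0L)
  max(0L, min(a$end[1L], b$end[1L]) - max(a$start[1L], b$start[1L]))
}

#' Merge intervals closer than a gap
#'
#' Merges, per contig, every run of intervals separated by at most
#' `min_gap` bases. With `min_gap = 0` this is the union of covered bases
#' (abutting half-open intervals merge, intervals separated by one or more
#' bases do not). The result is sorted and the operation is idempotent and
#' insensitive to input order.
#'
#' @param xs interval data frame (`contig`, `start`, `end`, ...).
#' @param min_gap merge intervals separated by `<= min_gap` bases.
#' @return Sorted interval data frame with pairwise gaps `> min_gap`.
#' @examples
#' xs <- genomic_intervals("chr1", c(0, 3), c(5, 8))
#' merge_intervals(xs)  # single interval [0, 8)
#' @export
merge_intervals <- function(xs, min_gap = 0L) {
  stopifnot(min_gap >= 0)
  validate_intervals(xs)
  if (nrow(xs) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  gr <- GenomicRanges::reduce(as_granges0(xs),
                              min.gapwidth = as.integer(min_gap) + 1L)
  out <- granges_to_df0(gr)
  # lexicographic contig order, independent of input seqlevel order
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all (query, subject) index pairs overlapping by >= 1 base, or with the
# query fully contained in the subject when type = "within"
overlap_pairs <- function(query, subject, type = c("any", "within")) {
  type <- match.arg(type)
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(query),
                                      as_granges0(subject),
                                      type = type, ignore.strand = TRUE)
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}
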