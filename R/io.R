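#' Read a BED file
#'
#' Reads BED (0-based half-open) into the package's data-frame
#' representation. Three dialects are supported:
#'
#' * `"interval"` — standard BED3-6 (`chrom start end [name score strand]`);
#'   a missing score column becomes 0.
#' * `"peak"` — evidence peaks:
#'   `chrom start end feature_type score strand cell_type summit source`,
#'   with columns 5-9 optional. `feature_type` is the TF name, open-chromatin
#'   assay or histone mark; `summit` is an absolute 0-based offset inside
#'   the peak, `.` when absent.
#' * `"segment"` — genome-segmentation states:
#'   `chrom start end label cell_type` with `label` from the eight-state
#'   vocabulary (see [consolidate_segmentations()]).
#'
#' @param path file path.
#' @param type one of `"interval"`, `"peak"`, `"segment"`.
#' @return A data frame; always includes `contig`, `start`, `end`, `strand`.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path, type = c("interval", "peak", "segment")) {
  type <- match.arg(type)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  min_cols <- switch(type, interval = 3L, peak = 4L, segment = 5L)
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < min_cols) {
      stop("malformed BED line ", i, " in ", path, ": expected >= ",
           min_cols, " fields, got ", length(f), call. = FALSE)
    }
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("malformed BED line ", i, " in ", path,
           ": non-numeric coordinates", call. = FALSE)
    }
    rows[[j]] <- f
  }
  empty <- switch(type,
    interval = genomic_intervals(character(), integer(), integer()),
    peak = data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_type = character(), score = numeric(),
                      cell_type = character(), summit = integer(),
                      source = character(), stringsAsFactors = FALSE),
    segment = data.frame(contig = character(), start = integer(),
                         end = integer(), strand = character(),
                         label = character(), cell_type = character(),
                         stringsAsFactors = FALSE))
  if (length(rows) == 0L) return(empty)
  field <- function(k, default) {
    vapply(rows, function(f) if (length(f) >= k && f[k] != ".") f[k]
           else default, character(1L))
  }
  contig <- field(1L, NA_character_)
  start <- as.integer(field(2L, NA_character_))
  end <- as.integer(field(3L, NA_character_))
  df <- switch(type,
    interval = data.frame(
      contig = contig, start = start, end = end,
      strand = {
        s <- field(6L, ".")
        ifelse(s %in% c("+", "-"), s, ".")
      },
      name = field(4L, NA_character_),
      score = {
        sc <- suppressWarnings(as.numeric(field(5L, "0")))
        ifelse(is.na(sc), 0, sc)
      },
      stringsAsFactors = FALSE),
    peak = data.frame(
      contig = contig, start = start, end = end,
      strand = {
        s <- field(6L, ".")
        ifelse(s %in% c("+", "-"), s, ".")
      },
      feature_type = field(4L, NA_character_),
      score = {
        sc <- suppressWarnings(as.numeric(field(5L, "0")))
        ifelse(is.na(sc), 0, sc)
      },
      cell_type = field(7L, NA_character_),
      summit = suppressWarnings(as.integer(field(8L, NA_character_))),
      source = field(9L, NA_character_),
      stringsAsFactors = FALSE),
    segment = data.frame(
      contig = contig, start = start, end = end, strand = ".",
      label = field(4L, NA_character_),
      cell_type = field(5L, NA_character_),
      stringsAsFactors = FALSE))
  validate_intervals(df, what = paste0("BED (", path, ")"))
  if (type == "peak") {
    bad <- !is.na(df$summit) & (df$summit < df$start | df$summit >= df$end)
    if (any(bad)) {
      stop("BED (", path, "): summit outside its peak at data row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  df
}

#' Write intervals, peaks or segmentation states to BED
#'
#' Inverse of [read_bed()]; `read_bed(write_bed(x))` restores the
#' coordinates and annotation columns exactly.
#'
#' @param xs data frame as produced/accepted by [read_bed()].
#' @param path output path.
#' @param type BED dialect; see [read_bed()].
#' @return `path`, invisibly.
#' @export
write_bed <- function(xs, path, type = c("interval", "peak", "segment")) {
  type <- match.arg(type)
  validate_intervals(xs, what = "BED output")
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- if (nrow(xs) == 0L) character() else switch(type,
    interval = paste(xs$contig, xs$start, xs$end,
                     dot(if ("name" %in% names(xs)) xs$name else NA),
                     if ("score" %in% names(xs)) xs$score else 0,
                     xs$strand, sep = "\t"),
    peak = paste(xs$contig, xs$start, xs$end, dot(xs$feature_type),
                 xs$score, xs$strand, dot(xs$cell_type), dot(xs$summit),
                 dot(xs$source), sep = "\t"),
    segment = paste(xs$contig, xs$start, xs$end, xs$label, xs$cell_type,
                    sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

gff3_unescape <- function(x) {
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Write regulatory features to GFF3
#'
#' Emits one GFF3 record per feature, 1-based inclusive coordinates, with
#' attributes `ID`, `feature_class` and one `activity_<cell>` attribute per
#' cell type (`active`/`inactive`). Motif-match data frames may also be
#' written: their attributes are `pwm_id`, `score` and, when present,
#' `p_emp` and `score_ratio`.
#'
#' @param features regulatory-feature data frame (see
#'   [regulatory_build()]) or motif-match data frame.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @seealso [read_gff3()]
#' @export
write_gff3 <- function(features, path, source = "regbuildr") {
  validate_intervals(features, what = "GFF3 output")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) == 0L) return(invisible(path))
  is_motif <- "pwm_id" %in% names(features)
  for (i in seq_len(nrow(features))) {
    if (is_motif) {
      type <- "TF_binding_site"
      attrs <- c(sprintf("ID=%s", gff3_escape(
                   if ("match_id" %in% names(features))
                     features$match_id[i]
                   else sprintf("motif_%06d", i))),
                 sprintf("pwm_id=%s", gff3_escape(features$pwm_id[i])),
                 sprintf("score=%s", format(features$score[i], digits = 10)))
      if ("p_emp" %in% names(features) && !is.na(features$p_emp[i])) {
        attrs <- c(attrs, sprintf("p_emp=%s",
                                  format(features$p_emp[i], digits = 10)))
      }
      if ("score_ratio" %in% names(features) &&
          !is.na(features$score_ratio[i])) {
        attrs <- c(attrs, sprintf("score_ratio=%s",
                                  format(features$score_ratio[i],
                                         digits = 10)))
      }
      score_col <- format(features$score[i], digits = 10)
    } else {
      type <- features$feature_class[i]
      attrs <- c(sprintf("ID=%s", gff3_escape(
                   if ("stable_id" %in% names(features))
                     features$stable_id[i]
                   else sprintf("feature_%06d", i))),
                 sprintf("feature_class=%s",
                         gff3_escape(features$feature_class[i])))
      if ("activity" %in% names(features)) {
        act <- features$activity[[i]]
        if (length(act)) {
          attrs <- c(attrs, sprintf("activity_%s=%s",
                                    gff3_escape(names(act)),
                                    unname(act)))
        }
      }
      score_col <- "."
    }
    writeLines(paste(features$contig[i], source, type,
                     features$start[i] + 1L, features$end[i], score_col,
                     if ("strand" %in% names(features))
                       features$strand[i] else ".",
                     ".", paste(attrs, collapse = ";"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a regulatory-feature GFF3 file
#'
#' Parses GFF3 written by [write_gff3()] back into the internal 0-based
#' half-open representation, recovering `stable_id`, `feature_class` and
#' the per-cell `activity` map.
#'
#' @param path GFF3 path.
#' @return Regulatory-feature data frame with an `activity` list-column.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) {
      stop("malformed GFF3 line ", i, " in ", path, ": expected 9 fields",
           call. = FALSE)
    }
    start1 <- suppressWarnings(as.integer(f[4L]))
    end1 <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 < start1) {
      stop("malformed GFF3 line ", i, " in ", path,
           ": bad coordinates", call. = FALSE)
    }
    kv <- strsplit(strsplit(f[9L], ";", fixed = TRUE)[[1L]], "=",
                   fixed = TRUE)
    keys <- vapply(kv, `[`, character(1L), 1L)
    vals <- gff3_unescape(vapply(kv, function(p)
      if (length(p) >= 2L) p[2L] else "", character(1L)))
    names(vals) <- keys
    act_idx <- startsWith(keys, "activity_")
    activity <- vals[act_idx]
    names(activity) <- gff3_unescape(sub("^activity_", "", keys[act_idx]))
    out[[j]] <- list(contig = f[1L], start = start1 - 1L, end = end1,
                     strand = if (f[7L] %in% c("+", "-")) f[7L] else ".",
                     stable_id = unname(vals["ID"]),
                     feature_class = unname(vals["feature_class"]),
                     activity = activity)
  }
  if (length(out) == 0L) return(empty_features())
  df <- data.frame(
    contig = vapply(out, `[[`, character(1L), "contig"),
    start = vapply(out, `[[`, integer(1L), "start"),
    end = vapply(out, `[[`, integer(1L), "end"),
    strand = vapply(out, `[[`, character(1L), "strand"),
    stable_id = vapply(out, `[[`, character(1L), "stable_id"),
    feature_class = vapply(out, `[[`, character(1L), "feature_class"),
    stringsAsFactors = FALSE)
  df$activity <- lapply(out, `[[`, "activity")
  df
}

#' Read a bisulfite cytosine count table
#'
#' Tab-delimited with columns `contig`, `pos0` (0-based), `strand` (`+`/`-`),
#' `converted`, `total`. A header row naming the columns is accepted and
#' skipped; comment lines start with `#`.
#'
#' @param path file path.
#' @return Data frame with columns `contig`, `pos`, `strand`, `converted`,
#'   `total` (counts satisfy `0 <= converted <= total`, `total >= 1`).
#' @seealso [write_counts_table()], [merge_replicates()]
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  empty <- data.frame(contig = character(), pos = integer(),
                      strand = character(), converted = integer(),
                      total = integer(), stringsAsFactors = FALSE)
  if (length(keep) == 0L) return(empty)
  first <- strsplit(trimws(lines[keep[1L]]), "[ \t]+")[[1L]]
  if (identical(tolower(first[1L]), "contig")) keep <- keep[-1L]
  if (length(keep) == 0L) return(empty)
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 5L) {
      stop("malformed count-table line ", i, " in ", path,
           ": expected 5 fields", call. = FALSE)
    }
    f
  })
  df <- data.frame(
    contig = vapply(rows, `[`, character(1L), 1L),
    pos = suppressWarnings(as.integer(vapply(rows, `[`, character(1L), 2L))),
    strand = vapply(rows, `[`, character(1L), 3L),
    converted = suppressWarnings(
      as.integer(vapply(rows, `[`, character(1L), 4L))),
    total = suppressWarnings(
      as.integer(vapply(rows, `[`, character(1L), 5L))),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$pos) | is.na(df$converted) | is.na(df$total))
  if (length(bad)) {
    stop("malformed count-table line ", keep[bad[1L]], " in ", path,
         ": non-numeric field", call. = FALSE)
  }
  validate_sites(df)
  df
}

#' @rdname read_counts_table
#' @param sites methylation-site data frame.
#' @export
write_counts_table <- function(sites, path) {
  validate_sites(sites)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("contig\tpos0\tstrand\tconverted\ttotal", con)
  if (nrow(sites)) {
    writeLines(paste(sites$contig, sites$pos, sites$strand,
                     sites$converted, sites$total, sep = "\t"), con)
  }
  invisible(path)
}

validate_sites <- function(sites) {
  req <- c("contig", "pos", "strand", "converted", "total")
  missing <- setdiff(req, names(sites))
  if (length(missing)) {
    stop("count table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(sites) == 0L) return(invisible(sites))
  if (!all(sites$strand %in% c("+", "-"))) {
    stop("count table: strand must be '+' or '-'", call. = FALSE)
  }
  bad <- sites$pos < 0 | sites$converted < 0 | sites$total < 1 |
    sites$converted > sites$total
  if (any(bad)) {
    stop("count table: require 0 <= converted <= total, total >= 1, ",
         "pos >= 0; violated at row(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  invisible(sites)
}

#' Read/write FASTA sequences
#'
#' Thin wrappers around Biostrings returning plain named character vectors.
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
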