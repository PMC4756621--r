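SEGMENT_LABELS <- c("tss", "flank", "transcribed", "enhancer", "ctcf",
                    "repressed", "low", "heterochromatin")

# the four feature-generating labels, in priority order, and their classes
LABEL_TO_CLASS <- c(tss = "promoter_with_tss",
                    flank = "promoter_flank",
                    enhancer = "enhancer",
                    ctcf = "ctcf_binding_site")

FEATURE_CLASSES <- c("promoter_with_tss", "promoter_flank", "enhancer",
                     "ctcf_binding_site", "tf_binding_site",
                     "open_chromatin")

# assay names treated as open-chromatin evidence rather than TF binding
OPEN_CHROMATIN_ASSAYS <- c("DNase1", "DNase", "DNase-seq", "FAIRE",
                           "ATAC", "ATAC-seq")

empty_features <- function() {
  df <- data.frame(contig = character(), start = integer(),
                   end = integer(), strand = character(),
                   stable_id = character(), feature_class = character(),
                   stringsAsFactors = FALSE)
  df$activity <- list()
  df
}

validate_segments <- function(states) {
  validate_intervals(states, what = "segmentation")
  req <- c("label", "cell_type")
  missing <- setdiff(req, names(states))
  if (length(missing)) {
    stop("segmentation lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(states$label), SEGMENT_LABELS)
  if (length(unknown)) {
    stop("unknown segmentation label(s): ",
         paste(unknown, collapse = ", "),
         "; expected one of ", paste(SEGMENT_LABELS, collapse = ", "),
         call. = FALSE)
  }
  invisible(states)
}

inactive_map <- function(cells) {
  stats::setNames(rep("inactive", length(cells)), cells)
}

#' Consolidate segmentation states into candidate regulatory features
#'
#' For each of the four feature-generating labels (`tss`, `flank`,
#' `enhancer`, `ctcf`) the union of that label's segments across all cell
#' types is merged (gap 0) into candidate features of the corresponding
#' class (`promoter_with_tss`, `promoter_flank`, `enhancer`,
#' `ctcf_binding_site`). Overlaps between classes are resolved by the
#' priority `tss > flank > enhancer > ctcf`: the footprint of every
#' higher-priority class is subtracted from lower-priority candidates, so
#' same-class (indeed all-class) features end up pairwise disjoint. The
#' other four labels (`transcribed`, `repressed`, `low`,
#' `heterochromatin`) never create features. Activity starts `"inactive"`
#' for every cell type seen in `states`; see [annotate_activity()].
#'
#' @param states segmentation data frame (`contig`, `start`, `end`,
#'   `label`, `cell_type`), e.g. from [read_bed()] type `"segment"`.
#' @return Regulatory-feature data frame (no stable ids yet): `contig`,
#'   `start`, `end`, `strand`, `feature_class`, `activity` list-column.
#' @export
consolidate_segmentations <- function(states) {
  validate_segments(states)
  if (length(unique(states$cell_type)) < 1L) {
    stop("need at least one cell type", call. = FALSE)
  }
  cells <- sort(unique(states$cell_type))
  taken <- NULL  # GRanges footprint of higher-priority classes
  parts <- list()
  for (label in names(LABEL_TO_CLASS)) {
    seg <- states[states$label == label, , drop = FALSE]
    if (nrow(seg) == 0L) next
    gr <- GenomicRanges::reduce(as_granges0(seg))
    if (!is.null(taken)) {
      gr <- GenomicRanges::setdiff(gr, taken, ignore.strand = TRUE)
    }
    taken <- if (is.null(taken)) gr else
      GenomicRanges::reduce(c(taken, gr))
    if (length(gr) == 0L) next
    df <- granges_to_df0(GenomicRanges::sort(gr))
    df$feature_class <- LABEL_TO_CLASS[[label]]
    parts[[label]] <- df
  }
  if (length(parts) == 0L) {
    out <- empty_features()
    return(out)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$contig, out$start,
                   match(out$feature_class, FEATURE_CLASSES)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$activity <- rep(list(inactive_map(cells)), nrow(out))
  out
}

#' Add features for experimental evidence the segmentation missed
#'
#' Peaks that overlap no existing feature are "unexplained" evidence:
#' they are merged (gap 0) per evidence kind and become new features of
#' class `open_chromatin` (when `feature_type` is an open-chromatin
#' assay) or `tf_binding_site` (otherwise). Peaks overlapping an existing
#' feature spawn nothing.
#'
#' @param features regulatory-feature data frame (e.g. from
#'   [consolidate_segmentations()]).
#' @param peaks peak data frame with `feature_type` and `cell_type`.
#' @param open_chromatin_assays `feature_type` values classed as open
#'   chromatin.
#' @return `features` plus any new unannotated-evidence features, sorted.
#' @export
add_unexplained_evidence <- function(features, peaks,
                                     open_chromatin_assays =
                                       OPEN_CHROMATIN_ASSAYS) {
  validate_intervals(peaks, what = "peaks")
  if (nrow(peaks) == 0L) return(features)
  hits <- overlap_pairs(peaks, features, type = "any")
  unexplained <- setdiff(seq_len(nrow(peaks)), hits$query)
  if (length(unexplained) == 0L) return(features)
  cells <- sort(unique(c(
    unlist(lapply(features$activity, names)),
    peaks$cell_type[!is.na(peaks$cell_type)])))
  un <- peaks[unexplained, , drop = FALSE]
  kind <- ifelse(un$feature_type %in% open_chromatin_assays,
                 "open_chromatin", "tf_binding_site")
  parts <- list(features[, setdiff(names(features), "activity"),
                         drop = FALSE])
  acts <- features$activity
  for (cl in c("tf_binding_site", "open_chromatin")) {
    sub <- un[kind == cl, , drop = FALSE]
    if (nrow(sub) == 0L) next
    df <- merge_intervals(sub)
    df$feature_class <- cl
    if ("stable_id" %in% names(features)) df$stable_id <- NA_character_
    parts[[cl]] <- df[, names(parts[[1L]]), drop = FALSE]
    acts <- c(acts, rep(list(inactive_map(cells)), nrow(df)))
  }
  out <- do.call(rbind, parts)
  out$activity <- acts
  # re-pad pre-existing activity maps with any newly seen cell types
  out$activity <- lapply(out$activity, function(a) {
    miss <- setdiff(cells, names(a))
    c(a, inactive_map(miss))[cells]
  })
  ord <- order(out$contig, out$start,
               match(out$feature_class, FEATURE_CLASSES))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate per-cell-type activity of regulatory features
#'
#' A feature is `"active"` in cell type `c` iff it overlaps (by >= 1
#' base) a segment of `c` whose label maps to the feature's class, or it
#' overlaps any peak observed in `c`; otherwise `"inactive"`. Cell types
#' are the union of those seen in `states` and `peaks`; a cell with no
#' data leaves every feature inactive (with a warning).
#'
#' @param features regulatory-feature data frame.
#' @param states segmentation data frame.
#' @param peaks peak data frame.
#' @return `features` with the `activity` list-column filled in for every
#'   cell type.
#' @export
annotate_activity <- function(features, states, peaks) {
  validate_segments(states)
  cells <- sort(unique(c(states$cell_type,
                         peaks$cell_type[!is.na(peaks$cell_type)],
                         unlist(lapply(features$activity, names)))))
  no_data <- setdiff(cells, c(states$cell_type, peaks$cell_type))
  if (length(no_data)) {
    warning("no segmentation or peak data for cell type(s): ",
            paste(no_data, collapse = ", "),
            "; all features inactive there", call. = FALSE)
  }
  class_label <- stats::setNames(names(LABEL_TO_CLASS), LABEL_TO_CLASS)
  activity <- matrix("inactive", nrow(features), length(cells),
                     dimnames = list(NULL, cells))
  for (cell in cells) {
    seg <- states[states$cell_type == cell, , drop = FALSE]
    if (nrow(seg)) {
      seg$class <- unname(LABEL_TO_CLASS[seg$label])
      seg <- seg[!is.na(seg$class), , drop = FALSE]
      if (nrow(seg)) {
        hits <- overlap_pairs(features, seg, type = "any")
        if (nrow(hits)) {
          ok <- features$feature_class[hits$query] ==
            seg$class[hits$subject]
          activity[unique(hits$query[ok]), cell] <- "active"
        }
      }
    }
    pk <- peaks[!is.na(peaks$cell_type) & peaks$cell_type == cell, ,
                drop = FALSE]
    if (nrow(pk)) {
      hits <- overlap_pairs(features, pk, type = "any")
      if (nrow(hits)) activity[unique(hits$query), cell] <- "active"
    }
  }
  features$activity <- lapply(seq_len(nrow(features)), function(i) {
    stats::setNames(activity[i, ], cells)
  })
  features
}

#' Assign deterministic stable identifiers
#'
#' Features are sorted by `(contig, start, feature_class)` and numbered
#' `prefix` + zero-padded rank; rebuilding identical input reproduces
#' identical ids.
#'
#' @param features regulatory-feature data frame.
#' @param prefix id prefix.
#' @return Sorted features with a `stable_id` column.
#' @export
assign_stable_ids <- function(features, prefix = "RBR") {
  ord <- order(features$contig, features$start,
               match(features$feature_class, FEATURE_CLASSES))
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  features$stable_id <- sprintf("%s%08d", prefix,
                                seq_len(nrow(features)))
  cols <- c("contig", "start", "end", "strand", "stable_id",
            "feature_class",
            setdiff(names(features),
                    c("contig", "start", "end", "strand", "stable_id",
                      "feature_class")))
  features[, cols, drop = FALSE]
}

#' Run the full consensus regulatory build
#'
#' Consolidates segmentation states into classed candidate features
#' ([consolidate_segmentations()]), adds unannotated TF-binding-site and
#' open-chromatin features for unexplained peaks
#' ([add_unexplained_evidence()]), annotates per-cell-type activity
#' ([annotate_activity()]) and assigns stable ids
#' ([assign_stable_ids()]). The result is the cell-type-agnostic
#' consensus ("MultiCell") feature set; a per-cell view is the same
#' features filtered by their activity flag.
#'
#' @param states segmentation data frame.
#' @param peaks peak data frame.
#' @param prefix stable-id prefix.
#' @return Regulatory-feature data frame with `stable_id`,
#'   `feature_class` and the per-cell `activity` list-column.
#' @examples
#' states <- data.frame(contig = "chr1", start = c(100, 400),
#'                      end = c(200, 600),
#'                      label = c("tss", "enhancer"),
#'                      cell_type = c("A", "A"))
#' peaks <- data.frame(contig = "chr1", start = 450, end = 520,
#'                     strand = ".", feature_type = "CTCF", score = 5,
#'                     cell_type = "A", summit = NA, source = "pk1")
#' regulatory_build(states, peaks)
#' @export
regulatory_build <- function(states, peaks = NULL, prefix = "RBR") {
  if (is.null(peaks)) {
    peaks <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        feature_type = character(), score = numeric(),
                        cell_type = character(), summit = integer(),
                        source = character(), stringsAsFactors = FALSE)
  }
  features <- consolidate_segmentations(states)
  features <- add_unexplained_evidence(features, peaks)
  features <- annotate_activity(features, states, peaks)
  assign_stable_ids(features, prefix = prefix)
}

#' Per-class feature counts
#'
#' @param features regulatory-feature data frame.
#' @return Data frame with columns `feature_class` and `n`, one row per
#'   class present.
#' @export
build_summary <- function(features) {
  tab <- table(factor(features$feature_class, levels = FEATURE_CLASSES))
  tab <- tab[tab > 0]
  data.frame(feature_class = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
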