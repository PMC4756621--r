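test_that("consolidation turns single segments into classed features", {
  states <- make_segmentation(list(
    A = data.frame(contig = "chr1", start = 100, end = 200,
                   label = "tss")))
  f <- consolidate_segmentations(states)
  expect_equal(nrow(f), 1L)
  expect_identical(f$feature_class, "promoter_with_tss")
  expect_equal(c(f$start, f$end), c(100L, 200L))
  expect_identical(f$activity[[1L]], c(A = "inactive"))
})

test_that("class priority subtracts higher-priority footprints", {
  states <- make_segmentation(list(
    A = data.frame(contig = "chr1", start = 100, end = 200,
                   label = "tss"),
    B = data.frame(contig = "chr1", start = 150, end = 300,
                   label = "flank")))
  f <- consolidate_segmentations(states)
  expect_equal(f$feature_class, c("promoter_with_tss", "promoter_flank"))
  expect_equal(f$start, c(100L, 200L))
  expect_equal(f$end, c(200L, 300L))
})

test_that("unknown labels are rejected", {
  states <- data.frame(contig = "chr1", start = 0L, end = 10L,
                       strand = ".", label = "promoter", cell_type = "A")
  expect_error(consolidate_segmentations(states), "unknown")
})

test_that("per-class coverage equals the union-minus-higher-priority oracle", {
  set.seed(50)
  labels <- c("tss", "flank", "enhancer", "ctcf", "transcribed", "low")
  for (rep in 1:10) {
    n <- 60L
    start <- sample.int(950, n, replace = TRUE) - 1L
    states <- data.frame(
      contig = "chr1", start = start,
      end = start + sample.int(50, n, replace = TRUE), strand = ".",
      label = sample(labels, n, replace = TRUE),
      cell_type = sample(c("A", "B", "C"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    f <- consolidate_segmentations(states)
    taken <- logical(1100)
    for (lab in c("tss", "flank", "enhancer", "ctcf")) {
      cl <- c(tss = "promoter_with_tss", flank = "promoter_flank",
              enhancer = "enhancer", ctcf = "ctcf_binding_site")[[lab]]
      want <- coverage_bits(states[states$label == lab, ], "chr1") & !taken
      got <- coverage_bits(f[f$feature_class == cl, ], "chr1")
      expect_identical(got, want)
      taken <- taken | want
    }
    # non-generating labels create no features
    expect_true(all(f$feature_class %in%
                      c("promoter_with_tss", "promoter_flank", "enhancer",
                        "ctcf_binding_site")))
    # all-class disjointness (stronger than same-class)
    ends <- f[order(f$start), ]
    if (nrow(ends) > 1L) {
      expect_true(all(ends$start[-1L] >= ends$end[-nrow(ends)]))
    }
  }
})

test_that("unexplained peaks become unannotated features, explained do not", {
  states <- make_segmentation(list(
    A = data.frame(contig = "chr1", start = 100, end = 300,
                   label = "enhancer")))
  feats <- consolidate_segmentations(states)
  peaks <- data.frame(
    contig = "chr1", start = c(150L, 500L, 560L, 800L),
    end = c(250L, 600L, 700L, 900L), strand = ".",
    feature_type = c("CTCF", "DNase1", "DNase1", "MYC"),
    score = 1, cell_type = "A", summit = NA_integer_,
    source = sprintf("p%d", 1:4), stringsAsFactors = FALSE)
  out <- add_unexplained_evidence(feats, peaks)
  # TF peak inside the enhancer spawns nothing; the two overlapping DNase
  # peaks merge into one open_chromatin feature; the isolated MYC peak
  # becomes a tf_binding_site
  expect_equal(build_summary(out),
               data.frame(feature_class = c("enhancer", "tf_binding_site",
                                            "open_chromatin"),
                          n = c(1L, 1L, 1L)))
  oc <- out[out$feature_class == "open_chromatin", ]
  expect_equal(c(oc$start, oc$end), c(500L, 700L))
  tf <- out[out$feature_class == "tf_binding_site", ]
  expect_equal(c(tf$start, tf$end), c(800L, 900L))
})

test_that("no evidence peak is silently dropped", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 40L
    start <- sample.int(900, n, replace = TRUE) - 1L
    states <- data.frame(
      contig = "chr1", start = start,
      end = start + sample.int(60, n, replace = TRUE), strand = ".",
      label = sample(c("tss", "enhancer", "low"), n, replace = TRUE),
      cell_type = sample(c("A", "B"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    pstart <- sample.int(900, 25, replace = TRUE) - 1L
    peaks <- data.frame(
      contig = "chr1", start = pstart,
      end = pstart + sample.int(40, 25, replace = TRUE), strand = ".",
      feature_type = sample(c("CTCF", "DNase1"), 25, replace = TRUE),
      score = 1, cell_type = "A", summit = NA_integer_, source = "p",
      stringsAsFactors = FALSE)
    feats <- add_unexplained_evidence(consolidate_segmentations(states),
                                      peaks)
    # every peak overlaps some feature afterwards
    for (i in seq_len(nrow(peaks))) {
      ov <- pmin(feats$end, peaks$end[i]) -
        pmax(feats$start, peaks$start[i])
      expect_true(any(ov >= 1))
    }
    # count of new features equals the brute-force classification
    base <- consolidate_segmentations(states)
    unexplained <- vapply(seq_len(nrow(peaks)), function(i) {
      all(pmin(base$end, peaks$end[i]) -
            pmax(base$start, peaks$start[i]) < 1)
    }, logical(1L))
    for (cl in c("tf_binding_site", "open_chromatin")) {
      kind <- if (cl == "open_chromatin") "DNase1" else "CTCF"
      sub <- peaks[unexplained & peaks$feature_type == kind, , drop = FALSE]
      want <- if (nrow(sub)) nrow(merge_intervals(sub)) else 0L
      expect_equal(sum(feats$feature_class == cl), want)
    }
  }
})

test_that("activity requires class-matching segments or any peak", {
  states <- make_segmentation(list(
    A = data.frame(contig = "chr1", start = c(100, 400),
                   end = c(200, 500), label = c("tss", "enhancer")),
    B = data.frame(contig = "chr1", start = 100, end = 200,
                   label = "transcribed")))
  peaks <- data.frame(contig = "chr1", start = 420L, end = 480L,
                      strand = ".", feature_type = "MYC", score = 1,
                      cell_type = "B", summit = NA_integer_, source = "p",
                      stringsAsFactors = FALSE)
  f <- regulatory_build(states, peaks)
  prom <- f[f$feature_class == "promoter_with_tss", ]
  enh <- f[f$feature_class == "enhancer", ]
  # matching tss segment in A -> active; B's transcribed segment maps to
  # no class, so the promoter stays inactive in B
  expect_identical(prom$activity[[1L]], c(A = "active", B = "inactive"))
  # enhancer: segment evidence in A, peak evidence in B
  expect_identical(enh$activity[[1L]], c(A = "active", B = "active"))
})

test_that("a cell without data leaves everything inactive, with warning", {
  states <- make_segmentation(list(
    A = data.frame(contig = "chr1", start = 100, end = 200,
                   label = "tss")))
  f <- consolidate_segmentations(states)
  f$activity <- list(c(A = "inactive", ghost = "inactive"))
  expect_warning(
    out <- annotate_activity(f, states,
                             data.frame(contig = character(),
                                        start = integer(),
                                        end = integer(),
                                        strand = character(),
                                        cell_type = character())),
    "ghost")
  expect_identical(out$activity[[1L]][["ghost"]], "inactive")
  expect_identical(out$activity[[1L]][["A"]], "active")
})

test_that("constitutive promoter vs single-cell CTCF activity scenario", {
  cells <- c("GM12878", "H1ESC", "HeLa", "K562")
  design <- lapply(cells, function(cell) {
    segs <- data.frame(contig = "chr1", start = 1000, end = 1400,
                       label = "tss")
    if (cell == "K562") {
      segs <- rbind(segs, data.frame(contig = "chr1", start = 5000,
                                     end = 5200, label = "ctcf"))
    }
    segs
  })
  names(design) <- cells
  states <- make_segmentation(design)
  f <- regulatory_build(states)
  prom <- f[f$feature_class == "promoter_with_tss", ]
  ctcf <- f[f$feature_class == "ctcf_binding_site", ]
  expect_identical(unname(prom$activity[[1L]]), rep("active", 4L))
  expect_identical(ctcf$activity[[1L]],
                   c(GM12878 = "inactive", H1ESC = "inactive",
                     HeLa = "inactive", K562 = "active"))
})

test_that("stable ids are positional, zero-padded and permutation-proof", {
  f <- data.frame(contig = c("chr2", "chr1", "chr1"),
                  start = c(5L, 50L, 7L), end = c(10L, 60L, 20L),
                  strand = ".",
                  feature_class = c("enhancer", "enhancer",
                                    "promoter_with_tss"),
                  stringsAsFactors = FALSE)
  f$activity <- rep(list(c(A = "inactive")), 3L)
  ids <- assign_stable_ids(f, prefix = "RBR")
  expect_identical(ids$stable_id,
                   c("RBR00000001", "RBR00000002", "RBR00000003"))
  expect_identical(ids$contig, c("chr1", "chr1", "chr2"))
  perm <- assign_stable_ids(f[c(3, 1, 2), ], prefix = "RBR")
  expect_identical(perm, ids)
})

test_that("the build is deterministic, idempotent and monotone in cells", {
  set.seed(52)
  mkstates <- function(cells) {
    parts <- lapply(cells, function(cell) {
      n <- 20L
      start <- sample.int(2000, n, replace = TRUE) - 1L
      data.frame(contig = "chr1", start = start,
                 end = start + sample.int(80, n, replace = TRUE),
                 strand = ".",
                 label = sample(c("tss", "flank", "enhancer", "ctcf"),
                                n, replace = TRUE),
                 cell_type = cell, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  states3 <- mkstates(c("A", "B", "C"))
  f1 <- regulatory_build(states3)
  f2 <- regulatory_build(states3)
  g1 <- withr::local_tempfile(fileext = ".gff3")
  g2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(f1, g1)
  write_gff3(f2, g2)
  expect_identical(readLines(g1), readLines(g2))

  # consolidating the build's own footprint is a fixed point
  as_states <- f1
  as_states$label <- c(promoter_with_tss = "tss", promoter_flank = "flank",
                       enhancer = "enhancer",
                       ctcf_binding_site = "ctcf")[f1$feature_class]
  as_states$cell_type <- "A"
  refeat <- consolidate_segmentations(
    as_states[, c("contig", "start", "end", "strand", "label",
                  "cell_type")])
  expect_equal(refeat[, c("contig", "start", "end", "feature_class")],
               f1[, c("contig", "start", "end", "feature_class")],
               ignore_attr = TRUE)

  # adding a cell type never shrinks the top-priority class nor the
  # union of covered bases (lower-priority classes can legitimately lose
  # bases to a new cell's higher-priority segments)
  states4 <- rbind(states3, mkstates("D"))
  f4 <- regulatory_build(states4)
  cov <- function(f, cl = NULL) {
    sub <- if (is.null(cl)) f else f[f$feature_class == cl, ]
    sum(sub$end - sub$start)
  }
  expect_gte(cov(f4, "promoter_with_tss"), cov(f1, "promoter_with_tss"))
  expect_gte(cov(f4), cov(f1))
})

test_that("build output survives a GFF3 round-trip", {
  states <- make_segmentation(list(
    A = data.frame(contig = "chr1", start = c(10, 500),
                   end = c(100, 700), label = c("tss", "ctcf"))))
  f <- regulatory_build(states)
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(f, p)
  back <- read_gff3(p)
  expect_equal(back[, c("contig", "start", "end", "stable_id",
                        "feature_class")],
               f[, c("contig", "start", "end", "stable_id",
                     "feature_class")],
               ignore_attr = TRUE)
  expect_identical(back$activity, f$activity)
})
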