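#' Simulate a bisulfite methylome count table
#'
#' Draws a hidden state per site from the model's mixing weights, then a
#' converted-read count from that state's distribution: beta-binomial for
#' the methylated and unmethylated states, discrete uniform on
#' `{0, ..., n}` for the undetermined state. Coverage follows a shifted
#' Poisson, `n = 1 + Poisson(mean)`, guaranteeing at least one read.
#' Regenerating with the same seed reproduces the table exactly.
#'
#' @param model generating [methylation_model()].
#' @param n_sites number of cytosines to simulate.
#' @param coverage_mean Poisson mean of the coverage law (before the +1
#'   shift).
#' @param seed RNG seed.
#' @param contig contig name for the simulated positions.
#' @return List with `table` (count table: `contig`, `pos`, `strand`,
#'   `converted`, `total`) and `truth` (the table plus the generating
#'   `state` per site and the `model` and `seed` as attributes).
#' @examples
#' m <- methylation_model(2, 38, 38, 2, c(0.45, 0.45, 0.1))
#' sim <- simulate_methylome(m, 100, seed = 7)
#' table(sim$truth$state)
#' @export
simulate_methylome <- function(model, n_sites, coverage_mean = 15,
                               seed = 1L, contig = "chr1") {
  stopifnot(inherits(model, "methylation_model"), n_sites >= 1L,
            coverage_mean > 0)
  with_preserved_seed(seed, {
    n <- 1L + stats::rpois(n_sites, coverage_mean)
    state_idx <- sample.int(3L, n_sites, replace = TRUE,
                            prob = model$weights)
    k <- integer(n_sites)
    im <- state_idx == 1L
    iu <- state_idx == 2L
    i0 <- state_idx == 3L
    if (any(im)) {
      pm <- stats::rbeta(sum(im), model$alpha_m, model$beta_m)
      k[im] <- stats::rbinom(sum(im), n[im], pm)
    }
    if (any(iu)) {
      pu <- stats::rbeta(sum(iu), model$alpha_u, model$beta_u)
      k[iu] <- stats::rbinom(sum(iu), n[iu], pu)
    }
    if (any(i0)) {
      # uniform on {0..n}: floor of (n + 1) uniforms
      k[i0] <- as.integer(floor(stats::runif(sum(i0)) * (n[i0] + 1L)))
      k[i0] <- pmin(k[i0], n[i0])
    }
    tab <- data.frame(contig = contig,
                      pos = 2L * seq_len(n_sites),  # distinct CpG offsets
                      strand = "+",
                      converted = k, total = n,
                      stringsAsFactors = FALSE)
    truth <- tab
    truth$state <- c("methylated", "unmethylated",
                     "undetermined")[state_idx]
    attr(truth, "model") <- model
    attr(truth, "seed") <- seed
    list(table = tab, truth = truth)
  })
}

#' Simulate a random genome sequence
#'
#' Bases drawn i.i.d. from `composition` (A, C, G, T order);
#' deterministic given `seed`.
#'
#' @param length sequence length in bases.
#' @param composition base composition on the simplex.
#' @param seed RNG seed.
#' @return Character scalar of length `length`.
#' @export
simulate_genome <- function(length, composition = rep(0.25, 4),
                            seed = 1L) {
  stopifnot(length >= 1L, length(composition) == 4L,
            all(composition >= 0),
            abs(sum(composition) - 1) < 1e-9)
  with_preserved_seed(seed, {
    paste(sample(DNA_ALPHABET, length, replace = TRUE,
                 prob = composition), collapse = "")
  })
}

#' Plant motif consensus occurrences in a sequence
#'
#' Overwrites `n` non-overlapping windows with the PWM's consensus
#' sequence (or, with `sample_from_pwm = TRUE`, with draws from the
#' pseudocounted PWM probabilities). Planting positions are drawn
#' uniformly without overlap; deterministic given `seed`.
#'
#' @param seq genome string.
#' @param p a [pwm()].
#' @param n number of occurrences to plant.
#' @param seed RNG seed.
#' @param sample_from_pwm sample each planted window from the PWM instead
#'   of writing the consensus.
#' @return List with `seq` (modified sequence) and `positions` (sorted
#'   0-based start offsets of the plants).
#' @export
plant_motifs <- function(seq, p, n, seed = 1L, sample_from_pwm = FALSE) {
  stopifnot(inherits(p, "pwm"), n >= 1L)
  L <- nrow(p$counts)
  len <- nchar(seq)
  if (n * L > len) {
    stop("cannot plant ", n, " non-overlapping motifs of length ", L,
         " in ", len, " bases", call. = FALSE)
  }
  with_preserved_seed(seed, {
    starts <- integer(0L)
    tries <- 0L
    while (length(starts) < n) {
      tries <- tries + 1L
      if (tries > 1000L * n) {
        stop("failed to place ", n, " non-overlapping motifs; ",
             "sequence too crowded", call. = FALSE)
      }
      cand <- sample.int(len - L + 1L, 1L) - 1L
      if (!any(abs(cand - starts) < L)) starts <- c(starts, cand)
    }
    starts <- sort(starts)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    prob <- pwm_probabilities(p, 0)
    cons <- strsplit(consensus_sequence(p), "", fixed = TRUE)[[1L]]
    for (s in starts) {
      word <- if (sample_from_pwm) {
        vapply(seq_len(L), function(i) {
          sample(DNA_ALPHABET, 1L, prob = prob[i, ])
        }, character(1L))
      } else cons
      chars[(s + 1L):(s + L)] <- word
    }
    list(seq = paste(chars, collapse = ""), positions = starts)
  })
}

#' Build peaks around planted motif positions
#'
#' One peak per planted position, extending `flank` bases on each side of
#' the motif window (clipped at 0).
#'
#' @param positions 0-based motif start offsets.
#' @param motif_length motif window length.
#' @param flank bases added on each side.
#' @param contig contig name.
#' @param cell_type cell type recorded on the peaks.
#' @param feature_type assay/TF name recorded on the peaks.
#' @return Peak data frame (see [read_bed()] type `"peak"`).
#' @export
make_peaks <- function(positions, motif_length, flank = 50L,
                       contig = "seq", cell_type = "cellA",
                       feature_type = "TF1") {
  if (length(positions) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      feature_type = character(), score = numeric(),
                      cell_type = character(), summit = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  start <- pmax(0L, as.integer(positions) - as.integer(flank))
  end <- as.integer(positions) + as.integer(motif_length) +
    as.integer(flank)
  data.frame(contig = contig, start = start, end = end, strand = ".",
             feature_type = feature_type, score = 1000,
             cell_type = cell_type,
             summit = as.integer(positions + motif_length %/% 2L),
             source = sprintf("sim_peak_%04d", seq_along(positions)),
             stringsAsFactors = FALSE)
}

#' Materialize a segmentation design
#'
#' The design is a list mapping cell type to a data frame of segments
#' (`contig`, `start`, `end`, `label`); the returned states honor it
#' exactly.
#'
#' @param design named list of per-cell segment data frames.
#' @return Segmentation data frame (`contig`, `start`, `end`, `strand`,
#'   `label`, `cell_type`) accepted by [consolidate_segmentations()].
#' @export
make_segmentation <- function(design) {
  stopifnot(is.list(design), length(design) >= 1L,
            !is.null(names(design)), all(nzchar(names(design))))
  parts <- lapply(names(design), function(cell) {
    d <- design[[cell]]
    data.frame(contig = d$contig, start = as.integer(d$start),
               end = as.integer(d$end), strand = ".",
               label = d$label, cell_type = cell,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  validate_segments(out)
  out
}

#' Generate a random PWM
#'
#' Each position's counts are a multinomial draw over a random base
#' preference; `sharpness` controls how concentrated the preferred base
#' is. Useful as a self-contained synthetic motif.
#'
#' @param length number of motif positions.
#' @param seed RNG seed.
#' @param total counts per position.
#' @param sharpness probability mass on the preferred base.
#' @param id,name identifiers for the resulting [pwm()].
#' @return A [pwm()].
#' @export
random_pwm <- function(length = 10L, seed = 1L, total = 100L,
                       sharpness = 0.7, id = "SYN0001",
                       name = "synthetic") {
  stopifnot(length >= 1L, sharpness > 0.25, sharpness <= 1)
  with_preserved_seed(seed, {
    counts <- t(vapply(seq_len(length), function(i) {
      pref <- sample.int(4L, 1L)
      prob <- rep((1 - sharpness) / 3, 4L)
      prob[pref] <- sharpness
      as.numeric(stats::rmultinom(1L, total, prob))
    }, numeric(4L)))
    pwm(id, name, counts)
  })
}
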