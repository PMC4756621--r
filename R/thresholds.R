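#' Analysis thresholds
#'
#' Bundles the tunable cutoffs shared across the toolkit:
#'
#' * `tau` — posterior discard threshold for methylation calling. A site is
#'   discarded when *all three* state posteriors exceed `tau`, i.e. kept only
#'   if at least one state can be ruled out at this level. Default `1e-4`.
#' * `p_max` — single-tail empirical p-value cutoff for motif matches.
#'   Default `0.05`.
#' * `bits_min` — information content (bits) above which a motif column
#'   counts as a highly informative position for variant consequences.
#'   Default `1.5`.
#' * `pseudocount` — background-proportional regularizer applied to PWM
#'   count columns before forming probabilities. Default `1e-3`.
#'
#' @param tau posterior discard threshold, in `(0, 1/3)`.
#' @param p_max motif empirical p-value cutoff, in `(0, 1)`.
#' @param bits_min informative-position cutoff in bits, in `[0, 2]`.
#' @param pseudocount non-negative PWM probability regularizer.
#' @return An object of class `"thresholds"` (a named list).
#' @examples
#' thresholds()
#' thresholds(p_max = 0.01, pseudocount = 0)
#' @export
thresholds <- function(tau = 1e-4, p_max = 0.05, bits_min = 1.5,
                       pseudocount = 1e-3) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau < 1 / 3)
  stopifnot(is.numeric(p_max), length(p_max) == 1L, p_max > 0, p_max < 1)
  stopifnot(is.numeric(bits_min), length(bits_min) == 1L,
            bits_min >= 0, bits_min <= 2)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount >= 0)
  structure(list(tau = tau, p_max = p_max, bits_min = bits_min,
                 pseudocount = pseudocount),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat("thresholds: tau=", format(x$tau),
      " p_max=", format(x$p_max),
      " bits_min=", format(x$bits_min),
      " pseudocount=", format(x$pseudocount), "\n", sep = "")
  invisible(x)
}

as_thresholds <- function(x) {
  if (inherits(x, "thresholds")) return(x)
  do.call(thresholds, as.list(x))
}
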