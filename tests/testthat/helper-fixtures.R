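# shared generators for property-style tests

random_interval_set <- function(n, contigs = c("chr1", "chr2"),
                                max_pos = 1000L, max_len = 50L) {
  start <- sample.int(max_pos - max_len, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(contig = sample(contigs, n, replace = TRUE),
             start = start, end = start + len, strand = ".",
             stringsAsFactors = FALSE)
}

# brute-force covered-base set per contig as a logical vector
coverage_bits <- function(df, contig, len = 1100L) {
  bits <- logical(len)
  sub <- df[df$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    if (sub$end[i] > sub$start[i]) {
      bits[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    }
  }
  bits
}

# quadrature oracle for the beta-binomial pmf: tanh-sinh (double
# exponential) nodes absorb the Beta endpoint singularities when a shape
# is < 1. p and 1-p are computed independently via plogis(+-2u) and the
# integrand evaluated through the exact reflection dbinom(k,n,p) =
# dbinom(n-k,n,1-p), dbeta(p,a,b) = dbeta(1-p,b,a) on whichever side is
# small, avoiding 1-p cancellation; accurate to ~1e-14 relative
betabinom_pmf_quadrature <- function(k, n, alpha, beta, h = 5e-4,
                                     tmax = 6) {
  t <- seq(-tmax, tmax, by = h)
  u <- (pi / 2) * sinh(t)
  pl <- stats::plogis(2 * u)
  pm <- stats::plogis(-2 * u)
  w <- h * (pi / 4) * cosh(t) / cosh(u)^2
  lv <- numeric(length(u))
  low <- pl <= 0.5
  lv[low] <- stats::dbinom(k, n, pl[low], log = TRUE) +
    stats::dbeta(pl[low], alpha, beta, log = TRUE)
  lv[!low] <- stats::dbinom(n - k, n, pm[!low], log = TRUE) +
    stats::dbeta(pm[!low], beta, alpha, log = TRUE)
  ok <- is.finite(lv) & w > 0
  sum(w[ok] * exp(lv[ok]))
}

toy_pwm <- function() {
  pwm("TOY1", "ToyTF",
      rbind(c(10, 0, 0, 0),
            c(0, 10, 0, 0),
            c(0, 0, 10, 0),
            c(0, 0, 0, 10),
            c(10, 0, 0, 0)))
}

toy_peaks <- function(df) {
  cbind(df,
        data.frame(feature_type = "TF1", score = 1, cell_type = "cellA",
                   summit = NA_integer_, source = "pk",
                   stringsAsFactors = FALSE))
}
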