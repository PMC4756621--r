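#' Three-state methylation mixture model
#'
#' Bisulfite conversion counts are modelled per cytosine as a mixture of
#' three states. Conversion indicates *un*methylation, so:
#'
#' * **methylated** — beta-binomial on the converted count with shapes
#'   `(alpha_m, beta_m)`; its mean converted fraction
#'   `alpha_m / (alpha_m + beta_m)` is low.
#' * **unmethylated** — beta-binomial with shapes `(alpha_u, beta_u)`;
#'   high mean converted fraction.
#' * **undetermined** — discrete uniform on `{0, ..., n}` given the total
#'   read count `n`, pmf `1/(n + 1)`.
#'
#' The identifiability convention is that the methylated component has the
#' lower mean converted fraction; [em_fit()] enforces it by swapping
#' components after fitting if needed.
#'
#' @param alpha_m,beta_m shapes of the methylated (low-conversion)
#'   beta-binomial; strictly positive.
#' @param alpha_u,beta_u shapes of the unmethylated (high-conversion)
#'   beta-binomial; strictly positive.
#' @param weights mixing weights `(pi_m, pi_u, pi_0)` on the simplex.
#' @return An object of class `"methylation_model"`.
#' @examples
#' methylation_model(2, 38, 38, 2, c(0.45, 0.45, 0.10))
#' @export
methylation_model <- function(alpha_m, beta_m, alpha_u, beta_u,
                              weights = c(0.45, 0.45, 0.10)) {
  shapes <- c(alpha_m, beta_m, alpha_u, beta_u)
  if (any(!is.finite(shapes)) || any(shapes <= 0)) {
    stop("beta-binomial shapes must be strictly positive and finite",
         call. = FALSE)
  }
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be a non-negative 3-vector summing to 1",
         call. = FALSE)
  }
  if (alpha_m / (alpha_m + beta_m) > alpha_u / (alpha_u + beta_u) + 1e-12) {
    stop("identifiability: methylated component must have the lower mean ",
         "converted fraction (conversion marks unmethylated cytosines)",
         call. = FALSE)
  }
  structure(list(alpha_m = alpha_m, beta_m = beta_m,
                 alpha_u = alpha_u, beta_u = beta_u,
                 weights = weights),
            class = "methylation_model")
}

#' @export
print.methylation_model <- function(x, ...) {
  cat("methylation mixture model\n")
  cat(sprintf("  methylated   BB(%.4g, %.4g)  mean conv %.4f  pi = %.4f\n",
              x$alpha_m, x$beta_m, x$alpha_m / (x$alpha_m + x$beta_m),
              x$weights[1L]))
  cat(sprintf("  unmethylated BB(%.4g, %.4g)  mean conv %.4f  pi = %.4f\n",
              x$alpha_u, x$beta_u, x$alpha_u / (x$alpha_u + x$beta_u),
              x$weights[2L]))
  cat(sprintf("  undetermined uniform{0..n}                    pi = %.4f\n",
              x$weights[3L]))
  invisible(x)
}

#' Serialize / restore a methylation model
#'
#' @param model a `methylation_model`.
#' @param path JSON path.
#' @return `read_methylation_model` returns the restored model.
#' @export
write_methylation_model <- function(model, path) {
  stopifnot(inherits(model, "methylation_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_methylation_model
#' @export
read_methylation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  methylation_model(x$alpha_m, x$beta_m, x$alpha_u, x$beta_u, x$weights)
}

#' Merge replicate count tables
#'
#' Sums converted and total counts per `(contig, pos, strand)` across
#' replicate tables; a position present in any table appears once.
#'
#' @param tables list of count-table data frames (see
#'   [read_counts_table()]).
#' @return Single merged count table, sorted by contig and position.
#' @export
merge_replicates <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  for (t in tables) validate_sites(t)
  all <- do.call(rbind, tables)
  if (nrow(all) == 0L) return(all)
  key_pos <- paste(all$contig, all$pos, sep = "\r")
  pairs <- unique(data.frame(k = key_pos, s = all$strand,
                             stringsAsFactors = FALSE))
  if (anyDuplicated(pairs$k)) {
    # same (contig, pos) observed on both strands across replicates
    clash <- pairs$k[duplicated(pairs$k)]
    stop("conflicting strands at position(s): ",
         paste(utils::head(gsub("\r", ":", clash), 5L), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(key_pos, all$strand, sep = "\r")
  converted <- rowsum(all$converted, key)
  total <- rowsum(all$total, key)
  parts <- strsplit(rownames(converted), "\r", fixed = TRUE)
  out <- data.frame(
    contig = vapply(parts, `[`, character(1L), 1L),
    pos = as.integer(vapply(parts, `[`, character(1L), 2L)),
    strand = vapply(parts, `[`, character(1L), 3L),
    converted = as.integer(converted[, 1L]),
    total = as.integer(total[, 1L]),
    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Beta-binomial log pmf
#'
#' `P(K = k | n, alpha, beta)` for the binomial with success probability
#' integrated over `Beta(alpha, beta)`, computed in log space via
#' `lchoose` and `lbeta` so large counts do not overflow.
#'
#' @param k observed counts, `0 <= k <= n` (vectorized).
#' @param n totals, `n >= 0`.
#' @param alpha,beta strictly positive shape parameters.
#' @return Log probabilities.
#' @examples
#' exp(betabinom_logpmf(0:4, 4, 1, 1))  # uniform 1/5
#' @export
betabinom_logpmf <- function(k, n, alpha, beta) {
  if (any(!is.finite(c(alpha, beta))) || any(c(alpha, beta) <= 0)) {
    stop("alpha and beta must be strictly positive", call. = FALSE)
  }
  if (any(k < 0) || any(k > n)) {
    stop("require 0 <= k <= n", call. = FALSE)
  }
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

# per-site 3-column matrix of log component densities (m, u, uniform)
component_logdens <- function(k, n, model) {
  cbind(betabinom_logpmf(k, n, model$alpha_m, model$beta_m),
        betabinom_logpmf(k, n, model$alpha_u, model$beta_u),
        -log(n + 1))
}

#' Mixture log-likelihood of count data
#'
#' Sum over sites of the log mixture density
#' `pi_m BB(k; n, alpha_m, beta_m) + pi_u BB(k; n, alpha_u, beta_u)
#'  + pi_0 / (n + 1)`.
#'
#' @param sites count-table data frame (`converted`, `total`).
#' @param model a [methylation_model()].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(sites, model) {
  stopifnot(inherits(model, "methylation_model"))
  validate_sites(sites)
  if (nrow(sites) == 0L) stop("no sites supplied", call. = FALSE)
  ld <- component_logdens(sites$converted, sites$total, model)
  lw <- matrix(log(model$weights), nrow(ld), 3L, byrow = TRUE)
  sum(row_log_sum_exp(ld + lw))
}

#' Posterior state probabilities per site
#'
#' `(p_methylated, p_unmethylated, p_undetermined)` for each site, i.e.
#' the mixing-weight-times-density vector normalized to sum 1, computed
#' stably in log space.
#'
#' @inheritParams mixture_loglik
#' @return `nrow(sites) x 3` matrix with columns `p_m`, `p_u`, `p_0`;
#'   rows sum to 1.
#' @export
posteriors <- function(sites, model) {
  stopifnot(inherits(model, "methylation_model"))
  validate_sites(sites)
  ld <- component_logdens(sites$converted, sites$total, model)
  lw <- matrix(log(model$weights), nrow(ld), 3L, byrow = TRUE)
  lj <- ld + lw
  p <- exp(lj - row_log_sum_exp(lj))
  p <- p / rowSums(p)
  colnames(p) <- c("p_m", "p_u", "p_0")
  p
}

# method-of-moments Beta fit to fractions, clamped to the EM shape box
fit_beta_mom <- function(frac, lower = 1e-3, upper = 1e4) {
  m <- mean(frac)
  v <- stats::var(frac)
  m <- min(max(m, 1e-4), 1 - 1e-4)
  if (!is.finite(v) || v <= 0 || v >= m * (1 - m)) {
    conc <- 10
  } else {
    conc <- m * (1 - m) / v - 1
  }
  a <- min(max(m * conc, lower), upper)
  b <- min(max((1 - m) * conc, lower), upper)
  c(a, b)
}

default_em_init <- function(sites) {
  frac <- sites$converted / sites$total
  qs <- stats::quantile(frac, c(1 / 3, 2 / 3), names = FALSE)
  lo <- frac[frac <= qs[1L]]
  hi <- frac[frac >= qs[2L]]
  if (length(lo) < 2L) lo <- frac
  if (length(hi) < 2L) hi <- frac
  m <- fit_beta_mom(lo)
  u <- fit_beta_mom(hi)
  # terciles can invert on degenerate data; force the ordering
  if (m[1L] / sum(m) > u[1L] / sum(u)) {
    tmp <- m; m <- u; u <- tmp
  }
  methylation_model(m[1L], m[2L], u[1L], u[2L], c(0.45, 0.45, 0.10))
}

# responsibility-weighted beta-binomial shape update on (log a, log b)
update_shapes <- function(k, n, w, init, lower = 1e-3, upper = 1e4) {
  if (sum(w) < 1e-12) return(list(shapes = init, collapsed = TRUE))
  negll <- function(p) {
    a <- exp(p[1L]); b <- exp(p[2L])
    -sum(w * betabinom_logpmf(k, n, a, b))
  }
  fit <- tryCatch(
    stats::optim(log(pmin(pmax(init, lower), upper)), negll,
                 method = "L-BFGS-B",
                 lower = rep(log(lower), 2L), upper = rep(log(upper), 2L),
                 control = list(maxit = 200L)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(shapes = init, collapsed = TRUE))
  list(shapes = exp(fit$par), collapsed = FALSE)
}

#' Fit the three-state mixture by expectation maximization
#'
#' EM over all sites of one dataset. The E-step computes per-site state
#' responsibilities; the M-step sets each mixing weight to the mean
#' responsibility and re-estimates the two beta-binomial shape pairs by
#' bounded numerical maximization of the responsibility-weighted
#' log-likelihood in `(log alpha, log beta)` (shapes clamped to
#' `[1e-3, 1e4]`; no closed form exists). Sites are aggregated by unique
#' `(converted, total)` pair first — responsibilities depend only on the
#' counts, so this is exact and much faster.
#'
#' Iteration stops when the relative log-likelihood change drops below
#' `tol` or after `max_iter` iterations; the trajectory is non-decreasing.
#' If a component's total responsibility collapses to zero its shapes are
#' kept at bounds and a warning is raised. The returned model satisfies
#' the identifiability ordering (components swapped post hoc if needed).
#'
#' @param sites count table with >= 3 rows.
#' @param init optional starting [methylation_model()]; by default a
#'   deterministic method-of-moments fit on the lower/upper terciles of
#'   the conversion fraction with weights `(0.45, 0.45, 0.10)`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param seed unused by the deterministic default initializer; accepted
#'   so callers can treat all fitting entry points uniformly.
#' @return List with elements `model` (the fitted
#'   [methylation_model()]) and `trajectory` (log-likelihood after each
#'   iteration, starting with the initial model's).
#' @examples
#' truth <- methylation_model(2, 38, 38, 2, c(0.45, 0.45, 0.1))
#' sim <- simulate_methylome(truth, n_sites = 2000, seed = 1)
#' fit <- em_fit(sim$table)
#' fit$model
#' @export
em_fit <- function(sites, init = NULL, tol = 1e-6, max_iter = 500L,
                   seed = NULL) {
  validate_sites(sites)
  if (nrow(sites) < 3L) stop("need at least 3 sites", call. = FALSE)
  stopifnot(tol > 0, max_iter >= 1L)
  model <- if (is.null(init)) default_em_init(sites) else init
  stopifnot(inherits(model, "methylation_model"))

  # aggregate identical (k, n) observations
  key <- paste(sites$converted, sites$total)
  tab <- table(key)
  first <- !duplicated(key)
  k <- sites$converted[first]
  n <- sites$total[first]
  w_site <- as.numeric(tab[paste(k, n)])
  n_total <- sum(w_site)

  loglik_of <- function(mod) {
    ld <- component_logdens(k, n, mod)
    lw <- matrix(log(mod$weights), length(k), 3L, byrow = TRUE)
    sum(w_site * row_log_sum_exp(ld + lw))
  }

  trajectory <- loglik_of(model)
  collapsed_warned <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    ld <- component_logdens(k, n, model)
    lw <- matrix(log(model$weights), length(k), 3L, byrow = TRUE)
    lj <- ld + lw
    r <- exp(lj - row_log_sum_exp(lj))
    r <- r / rowSums(r)
    # M-step
    wr <- r * w_site
    new_weights <- colSums(wr) / n_total
    upd_m <- update_shapes(k, n, wr[, 1L],
                           c(model$alpha_m, model$beta_m))
    upd_u <- update_shapes(k, n, wr[, 2L],
                           c(model$alpha_u, model$beta_u))
    if ((upd_m$collapsed || upd_u$collapsed) && !collapsed_warned) {
      warning("a mixture component collapsed; shapes held at bounds",
              call. = FALSE)
      collapsed_warned <- TRUE
    }
    candidate <- structure(
      list(alpha_m = upd_m$shapes[1L], beta_m = upd_m$shapes[2L],
           alpha_u = upd_u$shapes[1L], beta_u = upd_u$shapes[2L],
           weights = new_weights / sum(new_weights)),
      class = "methylation_model")
    model <- candidate
    ll <- loglik_of(model)
    trajectory <- c(trajectory, ll)
    prev <- trajectory[length(trajectory) - 1L]
    if (abs(ll - prev) < tol * (abs(prev) + .Machine$double.eps)) break
  }

  # enforce identifiability: methylated = lower mean converted fraction
  mean_m <- model$alpha_m / (model$alpha_m + model$beta_m)
  mean_u <- model$alpha_u / (model$alpha_u + model$beta_u)
  if (mean_m > mean_u) {
    model <- structure(
      list(alpha_m = model$alpha_u, beta_m = model$beta_u,
           alpha_u = model$alpha_m, beta_u = model$beta_m,
           weights = model$weights[c(2L, 1L, 3L)]),
      class = "methylation_model")
  }
  model <- methylation_model(model$alpha_m, model$beta_m,
                             model$alpha_u, model$beta_u, model$weights)
  list(model = model, trajectory = trajectory)
}

#' Call per-site methylation states
#'
#' Applies the posterior discard rule: a site is **discarded** when all
#' three state posteriors exceed `thresholds$tau` (no state can be ruled
#' out); otherwise it is called with the arg-max state, ties broken in the
#' fixed order methylated, unmethylated, undetermined. The methylation
#' level `(n - k)/n` (fraction of unconverted reads) is reported for every
#' site regardless of status.
#'
#' @inheritParams mixture_loglik
#' @param thresh a [thresholds()] object; `tau` is used.
#' @return Data frame: the site columns plus `p_m`, `p_u`, `p_0`,
#'   `status` (`"called"`/`"discarded"`), `state` (`"methylated"`,
#'   `"unmethylated"`, `"undetermined"`, or `NA` when discarded) and
#'   `level`.
#' @export
call_states <- function(sites, model, thresh = thresholds()) {
  thresh <- as_thresholds(thresh)
  p <- posteriors(sites, model)
  discarded <- apply(p, 1L, min) > thresh$tau
  state_idx <- max.col(p, ties.method = "first")
  states <- c("methylated", "unmethylated", "undetermined")[state_idx]
  states[discarded] <- NA_character_
  out <- cbind(sites,
               as.data.frame(p),
               data.frame(status = ifelse(discarded, "discarded", "called"),
                          state = states,
                          level = (sites$total - sites$converted) /
                            sites$total,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Write / read a methylation calls table
#'
#' Tab-delimited with header `contig pos0 strand converted total p_m p_u
#' p_0 status state level`.
#'
#' @param calls data frame from [call_states()].
#' @param path file path.
#' @export
write_calls_table <- function(calls, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste("contig", "pos0", "strand", "converted", "total",
                   "p_m", "p_u", "p_0", "status", "state", "level",
                   sep = "\t"), con)
  if (nrow(calls)) {
    writeLines(paste(calls$contig, calls$pos, calls$strand, calls$converted,
                     calls$total,
                     format(calls$p_m, digits = 10),
                     format(calls$p_u, digits = 10),
                     format(calls$p_0, digits = 10),
                     calls$status,
                     ifelse(is.na(calls$state), ".", calls$state),
                     format(calls$level, digits = 10), sep = "\t"), con)
  }
  invisible(path)
}
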