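# Histogramming and distribution distances.  Divergences are in natural
# log units (nats); the Jensen-Shannon divergence is bounded by ln 2.

#' Construct a response-time histogram
#'
#' @param bin_edges strictly increasing numeric edges (seconds).
#' @param probabilities nonnegative values summing to 1, one per bin.
#' @param n_samples integer count behind the histogram.
#' @return An object of class `rt_histogram`.
#' @export
rt_histogram <- function(bin_edges, probabilities, n_samples = NA_integer_) {
  if (length(probabilities) != length(bin_edges) - 1) {
    stop_gridrt("gridrt_binning_error",
                "need length(probabilities) == length(bin_edges) - 1")
  }
  if (any(diff(bin_edges) <= 0)) {
    stop_gridrt("gridrt_binning_error", "bin_edges must be strictly increasing")
  }
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-12) {
    stop_gridrt("gridrt_binning_error",
                "probabilities must be nonnegative and sum to 1")
  }
  structure(list(bin_edges = as.numeric(bin_edges),
                 probabilities = as.numeric(probabilities),
                 n_samples = n_samples),
            class = "rt_histogram")
}

#' Bin response times into a fixed-width histogram
#'
#' Half-open fixed-width bins `[lo, hi)` covering `[0, cap)`; samples at
#' or beyond `cap` are pooled into the last bin.  The default, 0.1 s
#' bins over a 300 s clock budget (3000 bins), matches the blitz-game
#' time resolution.
#'
#' @param samples RT values in seconds (must be nonnegative).
#' @param bin_width bin width in seconds (default 0.1).
#' @param cap pooling cap in seconds (default 300).
#' @return An `rt_histogram`.
#' @examples
#' h <- bin_rt(c(0.25, 1.3, 400), bin_width = 0.1, cap = 300)
#' sum(h$probabilities)
#' @export
bin_rt <- function(samples, bin_width = 0.1, cap = 300) {
  if (length(samples) == 0) {
    stop_gridrt("gridrt_empty_input", "no samples to bin")
  }
  bin_width <- check_number(bin_width, "bin_width", 0, Inf, strict_lo = TRUE)
  cap <- check_number(cap, "cap", bin_width, Inf)
  if (any(samples < 0)) {
    stop_gridrt("gridrt_invalid_parameter", "RT samples must be nonnegative")
  }
  n_bins <- as.integer(round(cap / bin_width))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(samples, edges), n_bins), nbins = n_bins)
  rt_histogram(edges, counts / length(samples), length(samples))
}

# Bin onto an existing histogram's edges (fitting needs model and target
# histograms on identical supports).
bin_on_edges <- function(samples, edges) {
  n_bins <- length(edges) - 1
  counts <- tabulate(pmax(1, pmin(findInterval(samples, edges), n_bins)),
                     nbins = n_bins)
  rt_histogram(edges, counts / length(samples), length(samples))
}

check_same_edges <- function(P, Q) {
  stopifnot(inherits(P, "rt_histogram"), inherits(Q, "rt_histogram"))
  if (length(P$bin_edges) != length(Q$bin_edges) ||
      max(abs(P$bin_edges - Q$bin_edges)) > 1e-9) {
    stop_gridrt("gridrt_binning_error",
                "histograms are not on identical bin edges")
  }
}

#' Kullback-Leibler divergence between histograms
#'
#' `KL(P || Q) = sum p_i * ln(p_i / q_i)` in nats, with `0 * ln 0 = 0`.
#' Requires `Q > 0` wherever `P > 0` (always true when `Q` is a
#' Jensen-Shannon mixture).
#'
#' @param P,Q `rt_histogram` objects on identical bin edges.
#' @return Nonnegative divergence in nats.
#' @export
kl_divergence <- function(P, Q) {
  check_same_edges(P, Q)
  p <- P$probabilities
  q <- Q$probabilities
  on <- p > 0
  if (any(q[on] == 0)) {
    stop_gridrt("gridrt_divergence_undefined",
                "P has mass where Q has none; KL(P||Q) is undefined")
  }
  sum(p[on] * log(p[on] / q[on]))
}

#' Jensen-Shannon divergence between histograms
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`:
#' symmetric, finite for any pair, bounded by `ln 2` (attained on
#' disjoint supports).  This is the fitting objective used for matching
#' model to human RT distributions.
#'
#' @param P,Q `rt_histogram` objects on identical bin edges.
#' @return Divergence in `[0, ln 2]` nats.
#' @export
jsd <- function(P, Q) {
  check_same_edges(P, Q)
  m <- rt_histogram(P$bin_edges, (P$probabilities + Q$probabilities) / 2)
  kl_divergence(P, m) / 2 + kl_divergence(Q, m) / 2
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` computed exactly; the p-value comes from
#' the asymptotic Kolmogorov distribution with effective sample size
#' `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples.
#' @return List with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_gridrt("gridrt_empty_input", "both samples must be non-empty")
  }
  na <- as.numeric(length(a))
  nb <- as.numeric(length(b))
  w <- c(a, b)
  o <- order(w)
  z <- cumsum(ifelse(o <= na, 1 / na, -1 / nb))
  # at tied values only the cumulative jump after the full tie group counts
  ws <- w[o]
  keep <- c(diff(ws) != 0, TRUE)
  d <- max(abs(z[keep]))
  ne <- na * nb / (na + nb)
  lambda2 <- ne * d^2
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda2))
  list(statistic = d, p_value = min(1, max(0, p)))
}

#' Write / read an RT histogram as CSV
#'
#' Columns `bin_lo`, `bin_hi`, `probability`.
#'
#' @param hist an `rt_histogram`.
#' @param path file path.
#' @return `path` invisibly; `hist_from_csv` returns an `rt_histogram`.
#' @export
hist_to_csv <- function(hist, path) {
  stopifnot(inherits(hist, "rt_histogram"))
  e <- hist$bin_edges
  utils::write.csv(
    data.frame(bin_lo = head(e, -1), bin_hi = e[-1],
               probability = hist$probabilities),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname hist_to_csv
#' @export
hist_to_json <- function(hist, path) {
  stopifnot(inherits(hist, "rt_histogram"))
  jsonlite::write_json(
    list(bin_edges = hist$bin_edges, probabilities = hist$probabilities,
         n_samples = hist$n_samples),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hist_to_csv
#' @export
hist_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rt_histogram(obj$bin_edges, obj$probabilities,
               if (is.null(obj$n_samples)) NA_integer_ else obj$n_samples)
}

#' @rdname hist_to_csv
#' @export
hist_from_csv <- function(path) {
  d <- utils::read.csv(path)
  rt_histogram(c(d$bin_lo, d$bin_hi[[length(d$bin_hi)]]), d$probability)
}

#' @export
print.rt_histogram <- function(x, ...) {
  occ <- sum(x$probabilities > 0)
  cat(sprintf("<rt_histogram> %d bins on [%g, %g] s, %d occupied, n = %s\n",
              length(x$probabilities), min(x$bin_edges), max(x$bin_edges),
              occ, format(x$n_samples)))
  invisible(x)
}
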