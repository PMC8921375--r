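# Optimal univariate k-means (dynamic programming) and the 10-scale LAD size
# model used to build predictors.

#' Optimal 1-D k-means clustering
#'
#' Exact dynamic program over the sorted values minimizing the total
#' within-cluster sum of squares; clusters are contiguous in sorted order and
#' the optimum is global and deterministic.
#'
#' @param values numeric vector (n >= k).
#' @param k number of clusters.
#' @return A list: `cluster` (1-based index per input value, in input order,
#'   ordered by cluster mean), `centers`, `sizes`, `boundaries` (k−1
#'   midpoints between adjacent cluster extremes) and `wss` (total
#'   within-cluster sum of squares).
#' @export
ckmeans_1d <- function(values, k) {
  n <- length(values)
  assert_that(k >= 1, "parameter error: k must be >= 1")
  assert_that(k <= n, "parameter error: k exceeds the number of values")
  o <- order(values)
  xs <- values[o]
  asg_sorted <- .ckmeans_dp_cpp(xs, as.integer(k))
  cluster <- integer(n)
  cluster[o] <- asg_sorted
  centers <- vapply(seq_len(k), function(q) mean(xs[asg_sorted == q]), numeric(1))
  sizes <- tabulate(asg_sorted, nbins = k)
  wss <- sum((xs - centers[asg_sorted])^2)
  boundaries <- if (k > 1) {
    vapply(seq_len(k - 1), function(q) {
      (max(xs[asg_sorted == q]) + min(xs[asg_sorted == q + 1])) / 2
    }, numeric(1))
  } else numeric(0)
  list(cluster = cluster, centers = centers, sizes = sizes,
       boundaries = boundaries, wss = wss)
}

#' Fit a 10-scale LAD size model
#'
#' Pools LAD values across training subjects (per lesion pool: inspiratory
#' emphysema clusters, or expiratory fSAD clusters), clusters them into `k`
#' size scales with [ckmeans_1d()], and keeps the boundary midpoints so new
#' LADs are assigned by lookup (scale 1 = smallest; out-of-range values clamp
#' to the end scales).
#'
#' @param pooled_lads numeric LAD values (fractions of parenchyma).
#' @param k number of scales (default 10).
#' @param provenance `"inspiratory"` or `"expiratory"` pool label.
#' @return Object of class `scale_model` with `k`, `boundaries`, `centers`,
#'   `sizes`, `wss`, `provenance`.
#' @export
fit_scale_model <- function(pooled_lads, k = 10,
                            provenance = c("inspiratory", "expiratory")) {
  provenance <- match.arg(provenance)
  pooled_lads <- pooled_lads[is.finite(pooled_lads)]
  assert_that(length(unique(pooled_lads)) >= k,
              "degenerate-scale error: fewer distinct LAD values than scales")
  fit <- ckmeans_1d(pooled_lads, k)
  structure(list(k = k, boundaries = fit$boundaries, centers = fit$centers,
                 sizes = fit$sizes, wss = fit$wss, provenance = provenance),
            class = "scale_model")
}

#' @export
print.scale_model <- function(x, ...) {
  cat(sprintf("<scale_model> %d scales (%s pool), boundaries: %s\n",
              x$k, x$provenance,
              paste(signif(x$boundaries, 3), collapse = ", ")))
  invisible(x)
}

#' Assign LAD values to scales
#'
#' @param model a [fit_scale_model()] object.
#' @param lads numeric LAD values.
#' @return Integer scale indices in 1..k (boundaries extended to ±Inf).
#' @export
assign_scale <- function(model, lads) {
  findInterval(lads, model$boundaries) + 1L
}

#' Scale-occupancy summary of a scale model
#'
#' @param x a `scale_model`.
#' @param ... unused.
#' @return A tibble with one row per scale: center, size, boundaries.
#' @export
tidy.scale_model <- function(x, ...) {
  lo <- c(-Inf, x$boundaries)
  hi <- c(x$boundaries, Inf)
  tibble::tibble(scale = seq_len(x$k), center = x$centers, n = x$sizes,
                 lower = lo, upper = hi)
}

#' @export
autoplot.scale_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$scale), y = .data$center)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "LAD scale", y = "cluster center (LAD fraction)",
                  title = sprintf("LAD size scales (%s pool)", object$provenance))
}
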