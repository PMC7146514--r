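#' Rank-ordered calibration/validation split
#'
#' Samples are sorted in ascending order of SOM (stable sort; ties broken by
#' sample id), grouped into consecutive triplets, and one member of each
#' complete triplet is assigned to the validation set with the other two to
#' calibration. Samples beyond the last complete triplet go to calibration.
#' This yields a 2:1 split whose validation set spans the SOM range: 168
#' samples give 112 calibration and 56 validation samples. The split is
#' deterministic (no randomness).
#'
#' @param dataset A [soil_dataset] with at least 3 samples.
#' @param validation_member Which member of each ascending triplet enters
#'   validation (1, 2 or 3). Default 2 (the middle member), so validation
#'   never claims either extreme of a triplet.
#' @return List of class \code{split_result}: \code{calibration} and
#'   \code{validation} ([soil_dataset]s, in ascending SOM order) and
#'   \code{assignment}, a data.frame mapping each input sample id to its set.
#' @export
rank_order_split <- function(dataset, validation_member = 2L) {
  stopifnot(inherits(dataset, "soil_dataset"))
  n <- length(dataset$som)
  if (n < 3L) stop("need at least 3 samples to split")
  validation_member <- as.integer(validation_member)
  if (!validation_member %in% 1:3) stop("validation_member must be 1, 2 or 3")
  ord <- order(dataset$som, dataset$sample_ids, method = "radix")
  pos_in_triplet <- ((seq_len(n) - 1L) %% 3L) + 1L
  complete <- seq_len(n) <= 3L * (n %/% 3L)
  is_val <- complete & pos_in_triplet == validation_member
  val_idx <- ord[is_val]
  cal_idx <- ord[!is_val]
  assignment <- data.frame(
    sample_id = dataset$sample_ids,
    set = ifelse(seq_len(n) %in% val_idx, "validation", "calibration"),
    stringsAsFactors = FALSE
  )
  structure(
    list(calibration = subset_samples(dataset, cal_idx),
         validation = subset_samples(dataset, val_idx),
         assignment = assignment),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Rank-ordered split: %d calibration / %d validation\n",
              length(x$calibration$som), length(x$validation$som)))
  invisible(x)
}

#' Descriptive statistics of a SOM vector
#'
#' Reports min, mean, max, standard deviation (n-1 denominator), IQR
#' (linear-interpolation quantiles, R type 7), CV (\code{100 * sd / mean}, %),
#' skewness and kurtosis. Skewness uses the small-sample adjusted moment
#' estimator \eqn{g_1 \sqrt{n(n-1)}/(n-2)}; kurtosis is reported raw (normal
#' reference = 3, excess not subtracted), small-sample adjusted:
#' \eqn{(n-1)\left[(n+1) g_2 + 6\right] / \left[(n-2)(n-3)\right] + 3}
#' with \eqn{g_2 = m_4/m_2^2 - 3}.
#'
#' @param values Numeric vector (n >= 2), e.g. SOM in g/kg.
#' @return A one-row data.frame with columns \code{n, min, mean, max, std,
#'   iqr, cv_percent, skewness, kurtosis}.
#' @export
describe_values <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  s <- stats::sd(values)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  ctr <- values - m
  m2 <- mean(ctr^2)
  if (m2 > 0) {
    g1 <- mean(ctr^3) / m2^1.5
    g2 <- mean(ctr^4) / m2^2 - 3
    skew <- if (n > 2) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
    kurt <- if (n > 3) (n - 1) * ((n + 1) * g2 + 6) / ((n - 2) * (n - 3)) + 3 else g2 + 3
  } else {
    skew <- 0
    kurt <- 0
  }
  data.frame(
    n = n, min = min(values), mean = m, max = max(values), std = s,
    iqr = q[2] - q[1], cv_percent = 100 * s / m,
    skewness = skew, kurtosis = kurt
  )
}

#' One-way ANOVA p-value for two groups
#'
#' Fixed-effects one-way ANOVA comparing the group means; with two groups
#' this equals the two-sided pooled-variance t-test. Used to verify that the
#' calibration and validation SOM distributions do not differ significantly
#' (p < 0.05 would flag an unbalanced split).
#'
#' Degenerate conventions: if both groups have zero within-group variance and
#' equal means, p = 1; zero within-group variance with different means gives
#' p = 0.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return p-value in [0, 1].
#' @export
anova_p <- function(group_a, group_b) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  n <- length(y)
  k <- 2L
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  if (ssw <= 0) {
    return(if (ssb <= 0) 1 else 0)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}
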