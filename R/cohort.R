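#' Friedman rank test for repeated measures
#'
#' Nonparametric test for differences across k repeated conditions
#' (here: staging, interim and end-of-treatment scans) on n subjects.
#' Within-subject mid-ranks are used for ties and the tie-corrected
#' statistic `Q = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` is computed,
#' with `A` the sum of squared ranks and `C = n k (k+1)^2 / 4`; without
#' ties this reduces to the classical `12/(n k (k+1)) * sum_j (...)^2`.
#' The p-value comes from the chi-square distribution with k-1 degrees of
#' freedom, or from the exact within-row permutation distribution when
#' `exact = TRUE` (feasible for small n; the statistic is monotone in the
#' column-rank-sum dispersion, which is convolved row by row).
#'
#' @param values numeric matrix, subjects in rows, conditions in columns;
#'   no missing cells.
#' @param exact use the exact permutation null distribution
#'   (supported for k <= 4 and n <= 12).
#' @return An object of class `htest`.
#' @export
friedman_test <- function(values, exact = FALSE) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing cells are not allowed")
  n <- nrow(values); k <- ncol(values)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  R <- t(apply(values, 1, rank))
  Q <- friedman_statistic(R, n, k)
  if (exact) {
    if (k > 4 || n > 12)
      stop("exact Friedman p supported for k <= 4 and n <= 12")
    p <- friedman_exact_p(R, n, k)
    method <- "Friedman rank test (exact permutation p)"
  } else {
    p <- pchisq(Q, df = k - 1, lower.tail = FALSE)
    method <- "Friedman rank test (chi-square approximation)"
  }
  structure(list(statistic = c("Friedman chi-squared" = Q),
                 parameter = c(df = k - 1), p.value = p,
                 method = method,
                 data.name = deparse(substitute(values))),
            class = "htest")
}

friedman_statistic <- function(R, n, k) {
  Rj <- colSums(R)
  A <- sum(R^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 1e-12) return(0)  # every row fully tied
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}

# Exact permutation p-value: distribution of the column rank sums under
# independent uniform within-row permutations, built by convolution.
friedman_exact_p <- function(R, n, k) {
  S_obs <- sum((colSums(R) - n * (k + 1) / 2)^2)
  dist <- new.env(parent = emptyenv())
  assign(paste(rep(0, k), collapse = ","), 1, envir = dist)
  for (i in seq_len(n)) {
    perms <- unique_row_perms(R[i, ])
    w <- 1 / nrow(perms)
    nxt <- new.env(parent = emptyenv())
    for (key in ls(dist)) {
      base <- as.numeric(strsplit(key, ",")[[1]])
      pr <- get(key, envir = dist)
      for (j in seq_len(nrow(perms))) {
        s <- base + perms[j, ]
        k2 <- paste(s, collapse = ",")
        prev <- if (exists(k2, envir = nxt)) get(k2, envir = nxt) else 0
        assign(k2, prev + pr * w, envir = nxt)
      }
    }
    dist <- nxt
  }
  p <- 0
  for (key in ls(dist)) {
    Rj <- as.numeric(strsplit(key, ",")[[1]])
    S <- sum((Rj - n * (k + 1) / 2)^2)
    if (S >= S_obs - 1e-9) p <- p + get(key, envir = dist)
  }
  min(1, p)
}

unique_row_perms <- function(r) {
  k <- length(r)
  P <- pracma::perms(seq_len(k))
  M <- t(apply(P, 1, function(o) r[o]))
  unique(M)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided test: zero differences are dropped, absolute
#' differences receive mid-ranks, and the statistic is the sum of ranks of
#' the positive differences. The exact null distribution over the 2^m sign
#' assignments is built by convolution (doubled ranks keep it on an integer
#' lattice even with ties) whenever m <= 50; otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. If every difference is zero, p = 1 by convention and the result is
#' flagged `degenerate`.
#'
#' @param x,y paired numeric vectors (or `x` a vector of differences when
#'   `y` is `NULL`).
#' @return An object of class `htest` with extra field `degenerate`.
#' @export
signed_rank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  dn <- d[d != 0]
  m <- length(dn)
  if (m == 0) {
    res <- list(statistic = c(V = 0), p.value = 1,
                method = "Wilcoxon signed-rank test (degenerate: all zero differences)",
                data.name = "paired differences", degenerate = TRUE)
    class(res) <- "htest"
    return(res)
  }
  r <- rank(abs(dn))
  W <- sum(r[dn > 0])
  if (m <= 50) {
    r2 <- round(2 * r)
    # P(2W = t): convolution over sign assignments
    f <- c(1)
    for (ri in r2) {
      g <- numeric(length(f) + ri)
      g[seq_along(f)] <- f / 2
      g[seq_along(f) + ri] <- g[seq_along(f) + ri] + f / 2
      f <- g
    }
    w2 <- round(2 * W)
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Wilcoxon signed-rank test (exact)"
  } else {
    mu <- m * (m + 1) / 4
    sig2 <- sum(r^2) / 4
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank test (normal approximation)"
  }
  structure(list(statistic = c(V = W), p.value = p, method = method,
                 data.name = "paired differences", degenerate = FALSE),
            class = "htest")
}

#' Post-hoc pairwise comparisons after a Friedman test
#'
#' Wilcoxon signed-rank tests for every pair of conditions with Bonferroni
#' adjustment (`adjusted_p = min(1, n_pairs * p)`).
#'
#' @param values numeric matrix, subjects in rows, conditions in columns
#'   (column names label the conditions).
#' @param alpha nominal familywise level (recorded in the output).
#' @return A data.frame with one row per pair: `pair`, `statistic`,
#'   `p_value`, `adjusted_p`, `degenerate`, `significant`.
#' @export
posthoc_pairwise <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2) stop("need at least 2 conditions")
  cn <- colnames(values)
  if (is.null(cn)) cn <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2)
  np <- ncol(pairs)
  out <- data.frame(pair = character(np), statistic = numeric(np),
                    p_value = numeric(np), adjusted_p = numeric(np),
                    degenerate = logical(np), significant = logical(np),
                    stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ht <- signed_rank_test(values[, a], values[, b])
    out$pair[i] <- paste(cn[a], cn[b], sep = " vs ")
    out$statistic[i] <- unname(ht$statistic)
    out$p_value[i] <- ht$p.value
    out$adjusted_p[i] <- min(1, np * ht$p.value)
    out$degenerate[i] <- isTRUE(ht$degenerate)
    out$significant[i] <- out$adjusted_p[i] < alpha
  }
  out
}

#' Point-biserial correlation
#'
#' Pearson correlation between a continuous measurement and a dichotomous
#' label coded 0/1, with the usual t transform for the p-value
#' (`t = r * sqrt((N-2)/(1-r^2))`, N-2 df). For a scan pair (A -> B), code
#' A = 0 and B = 1 so that a positive r means the metric is higher at the
#' later scan.
#'
#' @param x numeric measurements.
#' @param labels vector with exactly two levels (factor, character, or
#'   0/1); the *second* sorted level is coded 1.
#' @return An object of class `htest` with `estimate = r`.
#' @export
point_biserial <- function(x, labels) {
  if (length(x) != length(labels)) stop("lengths differ")
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must take exactly two values")
  g <- as.numeric(f) - 1
  if (min(table(f)) < 2) stop("need at least 2 observations per level")
  if (stats::var(x) == 0) stop("zero variance in the measurements")
  r <- cor(x, g)
  N <- length(x)
  if (abs(r) >= 1) {
    tval <- Inf * sign(r); p <- 0
  } else {
    tval <- r * sqrt((N - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tval), df = N - 2)
  }
  structure(list(statistic = c(t = tval), parameter = c(df = N - 2),
                 estimate = c(r = r), p.value = p,
                 method = "point-biserial correlation",
                 data.name = "x by labels"),
            class = "htest")
}

#' Mean +/- SD summary tables per regimen and stage
#'
#' Mirrors the usual longitudinal cohort summary: for each metric and scan
#' stage, mean, sample SD (n-1) and n per chemotherapy regimen plus the
#' combined (`"Both"`) group. Groups with a single record get `NA` SD;
#' empty groups are omitted with a warning.
#'
#' @param records data.frame with columns `patient_id`, `regimen`, `stage`
#'   and one numeric column per metric.
#' @param metrics character vector of metric columns; defaults to all
#'   numeric columns other than the id columns.
#' @return A tibble with columns `metric`, `stage`, `group`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_cohort <- function(records, metrics = NULL) {
  stopifnot(all(c("patient_id", "regimen", "stage") %in% names(records)))
  if (is.null(metrics)) {
    metrics <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                       c("patient_id"))
  }
  if (!length(metrics)) stop("no metric columns found")
  long <- tidyr::pivot_longer(records, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  both <- dplyr::mutate(long, group = "Both")
  per <- dplyr::mutate(long, group = as.character(.data$regimen))
  all <- dplyr::bind_rows(per, both)
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$metric, .data$stage, .data$group),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value[is.finite(.data$value)]),
    sd = if (sum(is.finite(.data$value)) > 1)
      stats::sd(.data$value[is.finite(.data$value)]) else NA_real_,
    .groups = "drop")
  empty <- out$n == 0
  if (any(empty)) {
    warning("omitting empty group(s): ",
            paste(unique(out$group[empty]), collapse = ", "))
    out <- out[!empty, ]
  }
  out
}

#' Simulate a longitudinal three-scan cohort metric
#'
#' Generates one metric (SLUR-like, in percent) for n patients across the
#' staging, interim and end-of-treatment scans: patient baselines are
#' normal with a between-patient SD, stage effects act multiplicatively,
#' and independent within-scan noise is added. Defaults emulate a cohort
#' with SLUR near the literature-normal 80% and a total cross-sectional
#' spread of about 9-10 points, split into between-patient (8) and
#' scan-to-scan (5) components; `stage_multipliers = c(1, 1, 1)` is the
#' no-effect (null) configuration.
#'
#' @param n_patients number of patients.
#' @param baseline_mean population mean of the patient baselines.
#' @param between_sd SD of patient baselines.
#' @param within_sd SD of the per-scan noise.
#' @param stage_multipliers numeric(3) multiplicative stage effects
#'   (staging, interim, eot).
#' @param seed optional RNG seed (local to this call).
#' @return A numeric matrix n x 3 with columns `staging`, `interim`,
#'   `eot`.
#' @export
simulate_cohort <- function(n_patients = 24, baseline_mean = 80,
                            between_sd = 8, within_sd = 5,
                            stage_multipliers = c(1, 1, 1),
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  base <- rnorm(n_patients, baseline_mean, between_sd)
  X <- vapply(1:3, function(j)
    base * stage_multipliers[j] + rnorm(n_patients, 0, within_sd),
    numeric(n_patients))
  X <- matrix(X, nrow = n_patients, ncol = 3,
              dimnames = list(NULL, c("staging", "interim", "eot")))
  X
}
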