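#' ROUT outlier removal for a univariate sample
#'
#' The robust-fit-plus-FDR outlier procedure specialized to a location-only
#' model, as used on per-image PLA measurements before group comparison.
#' The robust center is fitted by iteratively reweighted averaging with
#' Lorentzian weights `1 / (1 + (r/RSDR)^2)`; the robust standard deviation
#' of the residuals (RSDR) is the 68.27th percentile of the absolute
#' residuals scaled by `n/(n-K)` with `K = 1` fitted parameter. Candidate
#' outliers are then tested largest absolute residual first: two-tailed
#' p-values from the t distribution with `n-K` degrees of freedom are passed
#' through a Benjamini-Hochberg-style gate at FDR level `Q`, and at most
#' `floor(n/2)` points can ever be removed. Constant samples are returned
#' untouched.
#'
#' @param values numeric sample, `n >= 3`.
#' @param Q FDR level; the workflow uses 0.001 (0.1 percent), which removes
#'   only definite outliers.
#' @param max_iter,tol robust-fit iteration controls.
#' @return An object of class `rout_result`: `kept`, `outlier_indices`,
#'   `outliers`, `robust_center`, `rsdr`, `p_values`, `Q`.
#' @export
rout_outliers <- function(values, Q = 0.001, max_iter = 100L, tol = 1e-10) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("ROUT needs at least 3 values")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  if (Q <= 0 || Q >= 1) stop("'Q' must be in (0, 1)")
  K <- 1L
  center <- stats::median(values)
  rsdr <- 0
  for (it in seq_len(max_iter)) {
    resid <- values - center
    rsdr <- stats::quantile(abs(resid), 0.6827, names = FALSE, type = 7) *
      n / (n - K)
    if (rsdr == 0) break
    w <- 1 / (1 + (resid / rsdr)^2)
    new_center <- sum(w * values) / sum(w)
    if (abs(new_center - center) < tol * (1 + abs(center))) {
      center <- new_center
      break
    }
    center <- new_center
  }
  resid <- values - center
  rsdr <- stats::quantile(abs(resid), 0.6827, names = FALSE, type = 7) *
    n / (n - K)
  if (rsdr == 0) {
    # >= 68% of the sample sits exactly at the center; any point off it is
    # arbitrarily many robust SDs away
    p <- ifelse(resid == 0, 1, 0)
  } else {
    p <- 2 * stats::pt(-abs(resid) / rsdr, df = n - K)
  }
  ord <- order(p, -abs(resid))
  k_gate <- which(sort(p) <= seq_len(n) * Q / n)
  k <- if (length(k_gate)) min(max(k_gate), n %/% 2L) else 0L
  out_idx <- if (k > 0L) sort(ord[seq_len(k)]) else integer(0)
  structure(list(kept = if (k > 0L) values[-out_idx] else values,
                 outlier_indices = out_idx,
                 outliers = values[out_idx],
                 robust_center = center, rsdr = rsdr,
                 p_values = p, Q = Q, n = n),
            class = "rout_result")
}

#' @export
print.rout_result <- function(x, ...) {
  cat(sprintf("<rout_result> n = %d, Q = %g: %d outlier(s) removed\n",
              x$n, x$Q, length(x$outlier_indices)))
  cat(sprintf("  robust center %.6g, RSDR %.6g\n", x$robust_center, x$rsdr))
  if (length(x$outliers))
    cat("  removed:", paste(signif(x$outliers, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Two-tailed Student's t test between two samples
#'
#' Pooled-variance Student's t with `df = n_a + n_b - 2` (the equal-variance
#' form; Welch's correction is available behind a flag). Two degenerate
#' zero-variance inputs are resolved by convention: equal means give
#' `t = 0, p = 1`; different means give `p = 0` with a degeneracy flag.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param welch use Welch's unequal-variance form instead.
#' @return An object of class `comparison_result` with means, SEMs, the fold
#'   change of `b` relative to `a`, `t`, `df`, two-tailed `p`, group sizes
#'   and a significance flag at p < 0.05.
#' @export
t_test_two_tailed <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("both samples need n >= 2")
  if (anyNA(c(a, b)) || any(!is.finite(c(a, b)))) stop("values must be finite")
  degenerate <- FALSE
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                 parameter = length(a) + length(b) - 2, p.value = 0)
      degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    tt <- list(statistic = unname(ht$statistic), parameter = unname(ht$parameter),
               p.value = ht$p.value)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sem_a = stats::sd(a) / sqrt(length(a)),
                 sem_b = stats::sd(b) / sqrt(length(b)),
                 fold_change_b_vs_a = if (mean(a) != 0) mean(b) / mean(a)
                                      else NA_real_,
                 t_statistic = tt$statistic, df = tt$parameter,
                 p_value = tt$p.value, n_a = length(a), n_b = length(b),
                 significant = tt$p.value < 0.05, welch = welch,
                 degenerate = degenerate),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> n = %d vs %d\n", x$n_a, x$n_b))
  cat(sprintf("  mean +/- SEM: %.6g +/- %.3g vs %.6g +/- %.3g\n",
              x$mean_a, x$sem_a, x$mean_b, x$sem_b))
  cat(sprintf("  fold change (b vs a): %.4g\n", x$fold_change_b_vs_a))
  cat(sprintf("  %s t = %.4f, df = %.4g, two-tailed p = %.4g%s\n",
              if (x$welch) "Welch" else "Student's",
              x$t_statistic, x$df, x$p_value,
              if (x$significant) " (*)" else ""))
  if (!is.null(x$rout_a))
    cat(sprintf("  ROUT (Q = %g): removed %d (a), %d (b)\n", x$rout_a$Q,
                length(x$rout_a$outlier_indices), length(x$rout_b$outlier_indices)))
  invisible(x)
}

#' Compare two groups of per-image measurements
#'
#' The statistical layer applied to PLA measurements: optional per-group
#' ROUT outlier removal at level `Q`, then a two-tailed Student's t test and
#' the fold change of `b` relative to the calibrator group `a`.
#'
#' @param a calibrator-group values; @param b comparison-group values.
#' @param rout_q FDR level for ROUT, or `NULL` to skip outlier removal.
#' @param welch use Welch's t instead of pooled-variance Student's t.
#' @return A `comparison_result` carrying the per-group `rout_result`s.
#' @export
compare_groups <- function(a, b, rout_q = 0.001, welch = FALSE) {
  ra <- rb <- NULL
  if (!is.null(rout_q)) {
    # ROUT needs n >= 3; smaller groups pass through untouched
    if (length(a) >= 3L) { ra <- rout_outliers(a, Q = rout_q); a <- ra$kept }
    if (length(b) >= 3L) { rb <- rout_outliers(b, Q = rout_q); b <- rb$kept }
  }
  res <- t_test_two_tailed(a, b, welch = welch)
  res$rout_a <- ra; res$rout_b <- rb
  res
}

#' Fold change relative to a calibrator group
#'
#' Every value is divided by the calibrator mean, so the calibrator group
#' maps to mean 1 exactly.
#'
#' @param calibrator calibrator-group values (non-zero mean).
#' @param sample comparison-group values.
#' @return List with `fold_values`, `mean_fold`, `calibrator_fold_values`.
#' @export
fold_change_vs_calibrator <- function(calibrator, sample) {
  m <- mean(calibrator)
  if (m == 0) stop("calibrator mean is zero; fold change undefined")
  list(fold_values = sample / m, mean_fold = mean(sample) / m,
       calibrator_fold_values = calibrator / m)
}

#' Relative expression by the delta-delta-CT method
#'
#' Technical duplicates are averaged per (sample, gene) first. Per sample,
#' `dCT = CT_target - mean(CT of the reference genes)`; `ddCT` subtracts the
#' mean dCT of the calibrator group and `RQ = 2^(-ddCT)`. With a single
#' calibrator sample (or averaged calibrator CTs) the calibrator RQ is
#' exactly 1. Adding any constant to every CT leaves all RQs unchanged.
#'
#' @param data data frame with columns `sample`, `group`, `gene`, `ct`.
#' @param target target gene name.
#' @param references reference gene names (default the dual endogenous
#'   reference RPL27 + HPRT1).
#' @param calibrator calibrator group label.
#' @return Data frame with one row per sample: `sample`, `group`, `dct`,
#'   `ddct`, `rq`.
#' @export
delta_delta_ct <- function(data, target, references = c("RPL27", "HPRT1"),
                           calibrator) {
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(data)))
    stop("'data' needs columns: ", paste(need, collapse = ", "))
  if (any(data$ct <= 0)) stop("CT values must be positive")
  if (!calibrator %in% data$group)
    stop(sprintf("calibrator group '%s' not present", calibrator))
  # average technical duplicates
  agg <- stats::aggregate(ct ~ sample + group + gene, data = data, FUN = mean)
  dct <- do.call(rbind, lapply(split(agg, agg$sample), function(d) {
    if (!target %in% d$gene)
      stop(sprintf("sample '%s' lacks target gene '%s'", d$sample[1], target))
    if (!all(references %in% d$gene))
      stop(sprintf("sample '%s' lacks reference gene CT(s): %s", d$sample[1],
                   paste(setdiff(references, d$gene), collapse = ", ")))
    data.frame(sample = d$sample[1], group = d$group[1],
               dct = d$ct[d$gene == target] -
                 mean(d$ct[d$gene %in% references]),
               stringsAsFactors = FALSE)
  }))
  cal <- mean(dct$dct[dct$group == calibrator])
  dct$ddct <- dct$dct - cal
  dct$rq <- 2^(-dct$ddct)
  rownames(dct) <- NULL
  dct
}

#' Censor measurements below the detection limit
#'
#' Every value strictly below the limit of detection is assigned half the
#' limit; values at or above it are unchanged.
#'
#' @param values concentrations.
#' @param lod limit of detection (> 0).
#' @return List with `values` (censored vector) and `n_censored`.
#' @export
censor_below_lod <- function(values, lod) {
  if (!is.numeric(lod) || length(lod) != 1L || !is.finite(lod) || lod <= 0)
    stop("'lod' must be a single positive number")
  below <- values < lod
  values[below] <- lod / 2
  list(values = values, n_censored = sum(below))
}
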