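# Agreement and correlation statistics for paired manual/auto metrics:
# Bland-Altman limits of agreement, Wilcoxon paired signed-rank test with
# exact small-sample tail, Spearman rank correlation, and the dosimetric
# difference (delta-dose) / correlation tables.

#' Bland-Altman agreement analysis
#'
#' Paired differences `d_i = auto_i - manual_i`; bias is their mean and the
#' 95% limits of agreement are `bias +/- 1.96 * SD` (sample SD, n-1). The
#' P-value for zero bias comes from a two-sided one-sample t-test, gated by a
#' Shapiro-Wilk normality pre-check at alpha = 0.05: when normality fails the
#' agreement call is marked not applicable (`applicable = FALSE`), since the
#' t-based bias test is not trusted for clearly non-normal differences.
#' `P > 0.05` (with normality holding) is read as agreement of the two
#' segmentation methods.
#'
#' @param manual,auto paired per-case metric values, equal length `n >= 3`.
#' @return Object of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`, `n_outside`, `p_bias`, `shapiro_p`, `normal`,
#'   `applicable`, `agreement`, `differences`, `means`.
#' @export
bland_altman <- function(manual, auto) {
  if (length(manual) != length(auto))
    stop("manual and auto must be paired (equal length)", call. = FALSE)
  ok <- !(is.na(manual) | is.na(auto))
  manual <- manual[ok]; auto <- auto[ok]
  n <- length(manual)
  if (n < 3) stop("Bland-Altman requires at least 3 pairs", call. = FALSE)
  d <- auto - manual
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  n_outside <- sum(d < loa_low | d > loa_high)
  degenerate <- s == 0
  if (degenerate) {
    p_bias <- if (bias == 0) 1 else 0
    shapiro_p <- NA_real_
    normal <- NA
  } else {
    p_bias <- stats::t.test(d)$p.value
    shapiro_p <- if (n <= 5000) stats::shapiro.test(d)$p.value else NA_real_
    normal <- !is.na(shapiro_p) && shapiro_p > 0.05
  }
  structure(list(bias = bias, sd = s, loa_low = loa_low, loa_high = loa_high,
                 n = n, n_outside = n_outside, p_bias = p_bias,
                 shapiro_p = shapiro_p, normal = normal,
                 applicable = !degenerate && isTRUE(normal),
                 degenerate = degenerate,
                 agreement = !is.na(p_bias) && p_bias > 0.05,
                 differences = d, means = (manual + auto) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.4g LoA=[%.4g, %.4g] p_bias=%.3g%s\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$p_bias,
              if (!x$applicable) " (normality not met: agreement call n/a)"
              else ""))
  invisible(x)
}

# exact two-sided P for the signed-rank statistic given the (mid-)ranks of
# the nonzero |differences|, by dynamic programming over all 2^n equally
# likely sign assignments. Doubled ranks are integers even under midrank ties.
signed_rank_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)  # counts[s+1] = #assignments with 2*W+ == s
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts <- counts / sum(counts)
  w2 <- round(2 * w_plus)
  p_le <- sum(counts[seq_len(w2 + 1)])
  p_ge <- sum(counts[seq(w2 + 1, total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon paired signed-rank test
#'
#' Differences `auto - manual`; zero differences are dropped (Wilcoxon's
#' original treatment) and ties in `|d|` receive mid-ranks. For up to 25
#' nonzero differences the two-sided P is exact, by enumeration of all sign
#' assignments (conditional on the observed ranks, so ties are handled
#' exactly); for larger samples the normal approximation with tie-corrected
#' variance and continuity correction is used. The reported `z_statistic`
#' always comes from the normal approximation, as commonly printed alongside
#' signed-rank P-values. `P < 0.05` indicates a statistically significant
#' difference.
#'
#' @param manual,auto paired per-case values; at least 5 nonzero differences
#'   are required unless all differences are zero (which returns the flagged
#'   no-difference result with `p_value = 1`).
#' @param exact_max largest `n_nonzero` for which the exact tail is used.
#' @return Object of class `signed_rank_test`: `z_statistic`, `p_value`,
#'   `n_pairs`, `n_nonzero`, `w_plus`, `method`, `no_difference`.
#' @export
wilcoxon_signed_rank <- function(manual, auto, exact_max = 25) {
  if (length(manual) != length(auto))
    stop("manual and auto must be paired (equal length)", call. = FALSE)
  ok <- !(is.na(manual) | is.na(auto))
  d <- (auto - manual)[ok]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(z_statistic = 0, p_value = 1, n_pairs = n_pairs,
                          n_nonzero = 0, w_plus = NA_real_,
                          method = "degenerate", no_difference = TRUE),
                     class = "signed_rank_test"))
  }
  if (n < 5)
    stop("signed-rank test requires >= 5 nonzero differences (got ", n, ")",
         call. = FALSE)
  r <- rank(abs(d))  # mid-ranks for ties
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  cc <- if (w_plus == mu) 0 else 0.5 * sign(w_plus - mu)
  z <- if (sigma > 0) (w_plus - mu - cc) / sigma else 0
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w_plus)
    method <- "exact"
  } else {
    p <- if (sigma > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal"
  }
  structure(list(z_statistic = z, p_value = p, n_pairs = n_pairs,
                 n_nonzero = n, w_plus = w_plus, method = method,
                 no_difference = FALSE),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("<signed_rank_test> n=%d (nonzero %d) W+=%.1f Z=%.3f P=%.4g (%s)%s\n",
              x$n_pairs, x$n_nonzero,
              if (is.na(x$w_plus)) NA else x$w_plus,
              x$z_statistic, x$p_value, x$method,
              if (x$no_difference) " [no difference]" else ""))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided P from the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 4`; neither may be
#'   constant.
#' @return List: `r`, `p_value`, `n`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("Spearman correlation requires n >= 4", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined for a constant input vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Per-case dosimetric differences
#'
#' The dosimetric difference between the two segmentation methods is the
#' magnitude `|auto - manual|` per case, structure and metric of record (a
#' magnitude, so that better geometric overlap corresponds to a *smaller*
#' difference).
#'
#' @param paired_dvi data.frame with columns `case_id`, `structure`,
#'   `metric`, `manual`, `auto` (from [evaluate_dosimetry()] pairs across a
#'   cohort).
#' @return The input with a `delta` column; incomplete pairs are excluded
#'   (with a message).
#' @export
delta_dose <- function(paired_dvi) {
  needed <- c("case_id", "structure", "metric", "manual", "auto")
  stopifnot(all(needed %in% names(paired_dvi)))
  incomplete <- is.na(paired_dvi$manual) | is.na(paired_dvi$auto)
  if (any(incomplete))
    message(sum(incomplete), " case-structure pairs missing a provenance; ",
            "excluded from delta-dose")
  out <- paired_dvi[!incomplete, , drop = FALSE]
  out$delta <- abs(out$auto - out$manual)
  rownames(out) <- NULL
  out
}

#' Correlate geometric metrics with dosimetric differences
#'
#' For every structure and its dosimetric metric of record, the Spearman
#' correlation between the per-case dosimetric difference and each of DSC,
#' 95%HD and JC. An entry is classified `strong` when `|r| >= 0.8`. Cells
#' with fewer than `min_n` complete cases or a constant vector are `NA`.
#'
#' @param geom_table per-case geometry table with columns `case_id`,
#'   `structure`, `dsc`, `jc`, `hd95_mm`.
#' @param delta_table output of [delta_dose()].
#' @param min_n minimum complete cases per cell (default 4).
#' @return List: `table` (structure, delta_metric, geom_metric, r, p_value,
#'   n, strong) and `heatmap` (rows structure x delta_metric, columns DSC /
#'   95%HD / JC).
#' @export
correlation_table <- function(geom_table, delta_table, min_n = 4) {
  geom_cols <- c(DSC = "dsc", `95%HD` = "hd95_mm", JC = "jc")
  keys <- unique(delta_table[c("structure", "metric")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    nm <- keys$structure[i]; met <- keys$metric[i]
    dsub <- delta_table[delta_table$structure == nm &
                          delta_table$metric == met, ]
    gsub <- geom_table[geom_table$structure == nm, ]
    merged <- merge(dsub, gsub, by = c("case_id", "structure"))
    for (g in names(geom_cols)) {
      x <- merged[[geom_cols[[g]]]]
      y <- merged$delta
      ok <- !(is.na(x) | is.na(y))
      res <- if (sum(ok) >= min_n &&
                 length(unique(x[ok])) > 1 && length(unique(y[ok])) > 1) {
        spearman_rank(x[ok], y[ok])
      } else {
        list(r = NA_real_, p_value = NA_real_, n = sum(ok))
      }
      rows[[paste(nm, met, g)]] <- data.frame(
        structure = nm, delta_metric = paste0("delta_", met),
        geom_metric = g, r = res$r, p_value = res$p_value, n = res$n,
        strong = !is.na(res$r) && abs(res$r) >= 0.8)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  key <- paste(tab$structure, tab$delta_metric, sep = " ")
  ukey <- unique(key)
  heat <- matrix(NA_real_, nrow = length(ukey), ncol = length(geom_cols),
                 dimnames = list(ukey, names(geom_cols)))
  for (i in seq_len(nrow(tab)))
    heat[key[i], tab$geom_metric[i]] <- tab$r[i]
  list(table = tab, heatmap = heat)
}
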