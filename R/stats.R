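new_comparison <- function(design, statistic = NA_real_, p_raw = NA_real_,
                           p_corrected = p_raw, n = NA_integer_,
                           estimate = NA_real_, degenerate = FALSE,
                           bins = NULL, terms = NULL, m = NA_integer_,
                           alpha = NA_real_) {
  structure(
    list(design = design, statistic = statistic, p_raw = p_raw,
         p_corrected = p_corrected, n = n, estimate = estimate,
         degenerate = degenerate, bins = bins, terms = terms, m = m,
         alpha = alpha),
    class = "sleep_comparison"
  )
}

#' @export
print.sleep_comparison <- function(x, ...) {
  cat(sprintf("<sleep_comparison: %s>\n", x$design))
  print(glance(x))
  invisible(x)
}

#' Tidy / summarize a comparison result
#'
#' `tidy()` returns per-bin rows for bin-wise spectral tests, per-term rows
#' for ANOVA results, and a one-row table otherwise. `glance()` always
#' returns one row.
#'
#' @param x A `sleep_comparison` from [paired_contrast()],
#'   [binwise_spectral_test()] or [rm_anova()].
#' @param ... Unused.
#' @method tidy sleep_comparison
#' @export
tidy.sleep_comparison <- function(x, ...) {
  if (!is.null(x$bins)) return(x$bins)
  if (!is.null(x$terms)) return(x$terms)
  tibble(statistic = x$statistic, p_raw = x$p_raw,
         p_corrected = x$p_corrected, estimate = x$estimate,
         n = x$n[1], degenerate = x$degenerate)
}

#' @rdname tidy.sleep_comparison
#' @method glance sleep_comparison
#' @export
glance.sleep_comparison <- function(x, ...) {
  tibble(design = x$design, statistic = x$statistic, p_raw = x$p_raw,
         p_corrected = x$p_corrected,
         n = paste(x$n, collapse = "/"),
         degenerate = x$degenerate,
         n_flagged = if (!is.null(x$bins)) sum(x$bins$flagged) else NA_integer_)
}

#' Within-animal paired contrast
#'
#' Two-sided paired t test via standard routines, with the effect direction
#' reported as the mean difference `treatment - baseline`. Zero-variance
#' differences are degenerate: a flat zero difference yields statistic 0 and
#' p = 1; a constant non-zero shift is flagged (`degenerate = TRUE`, p `NA`)
#' rather than reported as an untestable certainty.
#'
#' @param x_baseline,x_treatment Equal-length numeric vectors (n >= 2),
#'   paired by animal.
#' @return A `sleep_comparison` (design `"paired"`).
#' @export
paired_contrast <- function(x_baseline, x_treatment) {
  .assert(length(x_baseline) == length(x_treatment),
          "paired vectors must have equal length")
  n <- length(x_baseline)
  .assert(n >= 2, "need at least 2 pairs")
  d <- x_treatment - x_baseline
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(new_comparison("paired", statistic = 0, p_raw = 1, n = n,
                            estimate = 0))
    }
    return(new_comparison("paired", statistic = NA_real_, p_raw = NA_real_,
                          n = n, estimate = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x_treatment, x_baseline, paired = TRUE)
  new_comparison("paired", statistic = unname(tt$statistic),
                 p_raw = tt$p.value, n = n, estimate = mean(d))
}

#' Unpaired two-group contrast
#'
#' Two-sided two-sample t test (pooled variance, matching the parametric
#' group comparisons this layer mirrors).
#'
#' @param x_a,x_b Numeric vectors (each n >= 2).
#' @return A `sleep_comparison` (design `"unpaired"`).
#' @export
unpaired_contrast <- function(x_a, x_b) {
  .assert(length(x_a) >= 2 && length(x_b) >= 2, "need >= 2 values per group")
  if (stats::sd(c(x_a - mean(x_a), x_b - mean(x_b))) == 0) {
    deg <- mean(x_a) == mean(x_b)
    return(new_comparison("unpaired",
                          statistic = if (deg) 0 else NA_real_,
                          p_raw = if (deg) 1 else NA_real_,
                          n = c(length(x_a), length(x_b)),
                          estimate = mean(x_a) - mean(x_b),
                          degenerate = !deg))
  }
  tt <- stats::t.test(x_a, x_b, var.equal = TRUE)
  new_comparison("unpaired", statistic = unname(tt$statistic),
                 p_raw = tt$p.value, n = c(length(x_a), length(x_b)),
                 estimate = mean(x_a) - mean(x_b))
}

#' Sidak multiple-comparison adjustment
#'
#' Closed form `p_corr = 1 - (1 - p)^m`, evaluated as
#' `-expm1(m * log1p(-p))` for numerical accuracy. Monotone in both `p` and
#' `m`; reduces to the identity at `m = 1`.
#'
#' @param p Raw p value(s) in `[0, 1]`.
#' @param m Number of comparisons (>= 1).
#' @return Adjusted p value(s) in `[p, 1]`.
#' @examples
#' sidak_adjust(0.01, 15)
#' @export
sidak_adjust <- function(p, m) {
  .assert(all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  .assert(all(m >= 1), "`m` must be >= 1")
  -expm1(m * log1p(-p))
}

#' Bin-wise spectral comparison with Sidak correction
#'
#' Per-frequency-bin two-sided t test between two groups of spectra
#' (paired or unpaired), Sidak-corrected over the number of bins actually
#' tested in the requested range (override with `m` when a different family
#' size is intended). Bins are flagged when the corrected p falls below
#' `alpha`.
#'
#' @param spectra_a,spectra_b Long tibbles with columns `id` (subject),
#'   `bin_start` and `power`, on identical bin grids.
#' @param range Optional half-open frequency range `[lo, hi)` restricting
#'   the tested bins (e.g. `c(0.5, 4)` for the SWA range).
#' @param paired Paired design (same subjects in both groups)?
#' @param alpha Familywise significance level.
#' @param m Override for the Sidak family size (defaults to the number of
#'   bins tested).
#' @return A `sleep_comparison` (design `"binwise"`) whose `bins` element
#'   has `bin_start`, `statistic`, `p_raw`, `p_corrected`, `flagged`.
#' @export
binwise_spectral_test <- function(spectra_a, spectra_b, range = NULL,
                                  paired = FALSE, alpha = 0.05, m = NULL) {
  for (sp in list(spectra_a, spectra_b)) {
    .assert(all(c("id", "bin_start", "power") %in% names(sp)),
            "spectra need columns id, bin_start, power")
  }
  bins_a <- sort(unique(spectra_a$bin_start))
  bins_b <- sort(unique(spectra_b$bin_start))
  .assert(identical(bins_a, bins_b), "bin grids differ between groups")
  bins <- bins_a
  if (!is.null(range)) bins <- bins[bins >= range[1] & bins < range[2]]
  .assert(length(bins) >= 1, "no bins in the requested range")
  n_a <- length(unique(spectra_a$id))
  n_b <- length(unique(spectra_b$id))
  .assert(n_a >= 2 && n_b >= 2, "need >= 2 spectra per group")
  if (paired) .assert(n_a == n_b, "paired design needs equal group sizes")
  m_eff <- m %||% length(bins)

  wide <- function(sp) {
    sub <- sp[sp$bin_start %in% bins, ]
    tidyr::pivot_wider(sub[, c("id", "bin_start", "power")],
                       names_from = "bin_start", values_from = "power")
  }
  wa <- wide(spectra_a); wb <- wide(spectra_b)
  if (paired) {
    wa <- wa[order(wa$id), ]; wb <- wb[order(wb$id), ]
  }
  res <- purrr::map(as.character(bins), function(bn) {
    tt <- stats::t.test(wa[[bn]], wb[[bn]], paired = paired,
                        var.equal = !paired)
    tibble(bin_start = as.numeric(bn), statistic = unname(tt$statistic),
           p_raw = tt$p.value)
  })
  tab <- dplyr::bind_rows(res)
  tab$p_corrected <- sidak_adjust(tab$p_raw, m_eff)
  tab$flagged <- tab$p_corrected < alpha
  new_comparison("binwise", n = c(n_a, n_b), bins = tab, m = m_eff,
                 alpha = alpha,
                 p_raw = min(tab$p_raw), p_corrected = min(tab$p_corrected))
}

#' (Repeated-measures) ANOVA behind a thin contract
#'
#' Delegates to `stats::aov`: between factors enter as crossed fixed
#' effects; a within factor adds an `Error(subject/within)` stratum. The
#' package asserts only the shape of the result and the validity of the p
#' values — the heavy inference machinery is standard and not re-derived
#' here.
#'
#' @param data Long-format data frame.
#' @param dv Dependent-variable column (tidy-eval).
#' @param between,within Optional factor column names (character).
#' @param subject Subject-id column name (required with `within`).
#' @return A `sleep_comparison` (design `"anova"`) whose `terms` element
#'   has `term`, `df`, `df_resid`, `statistic`, `p_raw`.
#' @export
rm_anova <- function(data, dv, between = NULL, within = NULL,
                     subject = NULL) {
  .assert(length(between) + length(within) >= 1,
          "at least one factor required")
  if (!is.null(within)) {
    .assert(!is.null(subject), "`subject` is required with a within factor")
  }
  dvq <- rlang::enquo(dv)
  dat <- dplyr::mutate(data, .dv = !!dvq)
  for (f in c(between, within, subject)) {
    .assert(f %in% names(dat), sprintf("column `%s` not found", f))
    dat[[f]] <- factor(dat[[f]])
  }
  rhs <- paste(c(between, within), collapse = " * ")
  if (!is.null(within)) {
    rhs <- paste0(rhs, " + Error(", subject, "/", within, ")")
  }
  fml <- stats::as.formula(paste(".dv ~", rhs))
  fit <- stats::aov(fml, data = dat)
  smry <- summary(fit)
  flat <- if (inherits(fit, "aovlist")) unlist(smry, recursive = FALSE) else smry
  rows <- purrr::map(flat, function(tabl) {
    tabl <- as.data.frame(tabl)
    has_f <- "F value" %in% names(tabl)
    if (!has_f) return(NULL)
    resid_df <- tabl$Df[trimws(rownames(tabl)) == "Residuals"]
    keep <- !is.na(tabl$`F value`)
    tibble(term = trimws(rownames(tabl))[keep],
           df = tabl$Df[keep],
           df_resid = if (length(resid_df)) resid_df else NA_real_,
           statistic = tabl$`F value`[keep],
           p_raw = tabl$`Pr(>F)`[keep])
  })
  terms <- dplyr::bind_rows(rows)
  .assert(nrow(terms) >= 1, "rank-deficient design: no testable terms")
  .assert(all(terms$p_raw >= 0 & terms$p_raw <= 1), "invalid p values")
  new_comparison("anova", statistic = terms$statistic[1],
                 p_raw = terms$p_raw[1], n = nrow(dat), terms = terms)
}
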