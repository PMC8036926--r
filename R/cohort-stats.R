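# Descriptive statistics and the severity-group comparison: exact
# Mann-Whitney U for the quantitative variables, chi-square for the
# qualitative ones, Pearson correlation for score/variable association.
# The exact Mann-Whitney core enumerates all group-label assignments with
# mid-rank tie handling, which is what makes p-values meaningful at n = 11.

#' Mean and standard deviation
#'
#' Both divisor conventions are computed because small-sample published
#' tables mix them (at n = 5 the two SDs differ by 11%); the `divisor`
#' argument selects which one is reported as `sd`.
#'
#' @param values numeric vector; `NA`s are removed first.
#' @param divisor `"n_minus_1"` (sample SD) or `"n"` (population SD).
#' @return list with `n`, `mean`, `sd`, `sd_n`, `sd_n_minus_1`.
#' @export
describe <- function(values, divisor = c("n_minus_1", "n")) {
  divisor <- match.arg(divisor)
  x <- values[!is.na(values)]
  if (!length(x)) stop("no non-missing values to describe", call. = FALSE)
  n <- length(x)
  m <- mean(x)
  ss <- sum((x - m)^2)
  sd_n1 <- if (n > 1) sqrt(ss / (n - 1)) else NA_real_
  sd_n <- sqrt(ss / n)
  list(n = n, mean = m,
       sd = if (divisor == "n") sd_n else sd_n1,
       sd_n = sd_n, sd_n_minus_1 = sd_n1)
}

# Mann-Whitney U statistic of group x against group y from mid-ranks.
mw_u_statistic <- function(x, y) {
  r <- rank(c(x, y))  # mid-ranks for ties
  n1 <- length(x)
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' In `exact` mode the test enumerates all `choose(n1+n2, n1)` assignments
#' of the pooled observations to the two group labels, computes U from
#' mid-ranks for each, and reports the point-symmetric two-sided p-value
#' `P(|U - E[U]| >= |U_obs - E[U]|)` with `E[U] = n1 n2 / 2`. This
#' definition is well defined under ties and reduces to the classical
#' doubling rule without them. `auto` mode falls back to the tie-corrected
#' normal approximation (with continuity correction) when the enumeration
#' exceeds `exact_cap` assignments.
#'
#' @param x,y numeric vectors (ties allowed; `NA`s removed).
#' @param mode `"exact"` or `"auto"`.
#' @param exact_cap maximum number of enumerated assignments in auto mode.
#' @return list of class `lopd_group_comparison` with `statistic` (U of the
#'   first group), `p_two_sided`, `method` (`"mw_exact"` or
#'   `"mw_normal_tie_corrected"`), and per-group `n`.
#' @export
mann_whitney <- function(x, y, mode = c("exact", "auto"),
                         exact_cap = 2e5) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n < 2 || n1 < 1 || n2 < 1) {
    stop("need at least one observation per group", call. = FALSE)
  }
  u_obs <- mw_u_statistic(x, y)
  eu <- n1 * n2 / 2
  n_assign <- choose(n, n1)
  if (mode == "exact" || n_assign <= exact_cap) {
    r <- rank(c(x, y))
    idx <- utils::combn(n, n1)
    offs <- n1 * (n1 + 1) / 2
    u_all <- colSums(matrix(r[idx], nrow = n1)) - offs
    p <- mean(abs(u_all - eu) >= abs(u_obs - eu) - 1e-9)
    method <- "mw_exact"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u_obs - eu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "mw_normal_tie_corrected"
  }
  structure(list(statistic = u_obs, p_two_sided = p, method = method,
                 n = c(n1 = n1, n2 = n2)),
            class = "lopd_group_comparison")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed-form `sum((O-E)^2/E)` with optional Yates continuity correction.
#' With 11 patients every expected count is below 5, so the small-count
#' warning fires on all cohort tables; it is a warning, not an error,
#' mirroring the published analysis which applied chi-square regardless.
#'
#' @param contingency 2x2 matrix of non-negative integers.
#' @param correct apply the Yates correction.
#' @return list of class `lopd_group_comparison` with `statistic`,
#'   `p_two_sided`, `method = "chisq"`, `expected`.
#' @export
chi_square <- function(contingency, correct = FALSE) {
  m <- as.matrix(contingency)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    stop("contingency must be a 2x2 table of non-negative integers",
         call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(e < 5)) {
    warning("expected count below 5; chi-square approximation is poor",
            call. = FALSE)
  }
  dev <- abs(m - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(statistic = stat, p_two_sided = p, method = "chisq",
                 expected = e, n = sum(m)),
            class = "lopd_group_comparison")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length; pairwise-complete filtering
#'   is applied and at least 3 complete pairs are required.
#' @return list with `r`, `n` and the variable pair.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  list(r = stats::cor(x, y), n = length(x))
}

# Registry of reportable variables: display label -> record field and type.
ASSOC_VARIABLES <- data.frame(
  label = c("Age", "AAO", "MMT", "6MWT", "GSGC", "FVC", "DFVC", "BMI",
            "VDD", "BMD-TB", "BMD-FN", "BMD-LS", "IgG-titre",
            "Sex", "BF", "BAD", "MVP", "ERT-AE"),
  field = c("age_dx", "aao", "mmt_mrc", "six_mwt", "gscg", "fvc_upright",
            "delta_fvc", "bmi", "vdd", "bmd_tb", "bmd_fn", "bmd_ls",
            "igg_rhgaa", "sex", "bf", "bad", "mvp", "ert_ae"),
  type = c(rep("quantitative", 13), rep("qualitative", 5)),
  stringsAsFactors = FALSE
)

#' Severity-group association report
#'
#' For each requested clinical variable, compares the two severity groups
#' (SI > 20 dichotomy): quantitative variables get per-group means/SDs
#' (missing values excluded per group, so group sizes can differ by
#' variable) and an exact Mann-Whitney p; qualitative variables get a 2x2
#' chi-square. Optionally annotates Benjamini-Hochberg q-values; the default
#' reports unadjusted p-values as the published analysis did.
#'
#' @param ds an `lopd_clinical` dataset.
#' @param groups named vector (`patient_id` -> `"VM_M"`/`"M_S"`) as returned
#'   by [dichotomize()].
#' @param variables character vector of variable labels (see the `label`
#'   column of the internal registry: "6MWT", "FVC", "DFVC", "VDD", "GSGC",
#'   "BMD-FN", "Sex", "BF", ...).
#' @param divisor SD convention for the reported `sd` column.
#' @param bh_adjust add a `q_value` column of Benjamini-Hochberg adjusted
#'   p-values.
#' @return data frame with one row per variable and group, columns
#'   `variable`, `group`, `n`, `mean`, `sd`, `sd_n`, `statistic`, `p`,
#'   `method`.
#' @export
severity_association_report <- function(ds, groups, variables,
                                        divisor = c("n_minus_1", "n"),
                                        bh_adjust = FALSE) {
  stopifnot(inherits(ds, "lopd_clinical"))
  divisor <- match.arg(divisor)
  if (!length(variables)) {
    return(data.frame(variable = character(), group = character(),
                      n = integer(), mean = double(), sd = double(),
                      sd_n = double(), statistic = double(), p = double(),
                      method = character(), stringsAsFactors = FALSE))
  }
  rec <- ds$records
  grp <- groups[rec$patient_id]
  rows <- list()
  for (v in variables) {
    k <- match(v, ASSOC_VARIABLES$label)
    if (is.na(k)) stop("unknown variable: ", v, call. = FALSE)
    field <- ASSOC_VARIABLES$field[k]
    if (ASSOC_VARIABLES$type[k] == "quantitative") {
      xs <- rec[[field]][grp == "VM_M"]
      ys <- rec[[field]][grp == "M_S"]
      mw <- mann_whitney(xs, ys, mode = "exact")
      for (g in c("VM_M", "M_S")) {
        d <- describe(if (g == "VM_M") xs else ys, divisor = divisor)
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = g, n = d$n, mean = d$mean, sd = d$sd,
          sd_n = d$sd_n, statistic = mw$statistic, p = mw$p_two_sided,
          method = mw$method, stringsAsFactors = FALSE)
      }
    } else {
      val <- rec[[field]]
      if (field == "sex") val <- val == "F"
      tab <- table(factor(grp, c("VM_M", "M_S")),
                   factor(val, c(FALSE, TRUE)))
      res <- tryCatch(chi_square(tab),
                      error = function(e) NULL)
      for (g in c("VM_M", "M_S")) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, group = g, n = sum(grp == g & !is.na(val)),
          mean = mean(val[grp == g], na.rm = TRUE), sd = NA_real_,
          sd_n = NA_real_,
          statistic = if (is.null(res)) NA_real_ else res$statistic,
          p = if (is.null(res)) NA_real_ else res$p_two_sided,
          method = if (is.null(res)) "chisq_degenerate" else res$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (bh_adjust) {
    pv <- out$p[!duplicated(out$variable)]
    qv <- stats::p.adjust(pv, method = "BH")
    out$q_value <- qv[match(out$variable, out$variable[!duplicated(out$variable)])]
  }
  out
}

#' Write an association report as TSV
#'
#' p-values are rounded to two decimals only here, at the formatting
#' boundary; internal values are never rounded.
#'
#' @param report data frame from [severity_association_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(report, path) {
  out <- report
  for (col in c("mean", "sd", "sd_n", "statistic")) {
    if (col %in% names(out)) out[[col]] <- round(out[[col]], 4)
  }
  if ("p" %in% names(out)) out$p <- round(out$p, 2)
  write_tsv_plain(out, path)
}
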