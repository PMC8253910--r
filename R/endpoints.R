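#' Creatinine-normalized POD3 fold change over baseline
#'
#' For one urinary analyte: each animal's concentration is divided by its
#' urinary creatinine at the same timepoint, and the POD3 ratio expressed
#' as a fold change over the baseline ratio. Unit choices cancel, so any
#' consistent concentration units work.
#'
#' @param records Data frame with columns `animal_id`, `group`,
#'   `timepoint` (containing `"BL"` and `"POD3"` rows), `concentration`
#'   and `urinary_creatinine` (> 0).
#' @return Data frame `animal_id`, `group`, `fold_change`. Animals missing
#'   either timepoint are excluded with a warning.
#' @export
normalize_and_fold_change <- function(records) {
  needed <- c("animal_id", "group", "timepoint", "concentration",
              "urinary_creatinine")
  stopifnot(all(needed %in% names(records)))
  if (any(records$urinary_creatinine <= 0)) {
    stop("urinary_creatinine must be positive", call. = FALSE)
  }
  ratio <- records$concentration / records$urinary_creatinine
  animals <- unique(records$animal_id)
  out <- lapply(animals, function(a) {
    rec <- records[records$animal_id == a, , drop = FALSE]
    r <- ratio[records$animal_id == a]
    bl <- r[rec$timepoint == "BL"]
    p3 <- r[rec$timepoint == "POD3"]
    if (length(bl) != 1 || length(p3) != 1) {
      warning("animal ", a, " lacks a unique baseline or POD3 record; excluded",
              call. = FALSE)
      return(NULL)
    }
    if (bl == 0) stop("zero baseline ratio for animal ", a, call. = FALSE)
    data.frame(animal_id = a, group = rec$group[1], fold_change = p3 / bl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Mann-Whitney (Wilcoxon rank-sum) test with exact small-sample path
#'
#' Two-sided test of `group_a` versus `group_b`. With combined n <= 12 and
#' no ties the exact null distribution of U is obtained by enumerating all
#' group labelings; otherwise a tie-corrected normal approximation with
#' continuity correction is used. The returned `method` records which path
#' ran.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param exact_max_n Combined-size cutoff for the exact path.
#' @return List: `U` (for `group_a`), `p`, `method`
#'   (`"exact"`/`"normal_approx"`).
#' @export
mann_whitney <- function(group_a, group_b, exact_max_n = 12) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  m <- length(group_a); n <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (m + n <= exact_max_n && !ties) {
    # enumerate all C(m+n, m) assignments of ranks to group A
    combos <- utils::combn(m + n, m)
    u_all <- colSums(matrix(rank(pooled)[combos], nrow = m)) -
      m * (m + 1) / 2
    # two-sided: fold around the center mn/2
    dev <- abs(u_all - m * n / 2)
    p <- mean(dev >= abs(U - m * n / 2) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- m * n / 2
  tie_tab <- table(pooled)
  N <- m + n
  sig2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sig2 == 0) return(list(U = U, p = 1, method = "normal_approx"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal_approx")
}

#' Treatment effect on longitudinal serum creatinine (polynomial model)
#'
#' Fits `creatinine ~ treatment + day + day^2` (optionally with
#' treatment-by-day interactions) and tests all treatment terms jointly by
#' an F-test against the model containing only the time polynomial. Also
#' reports the whole-model F against the intercept-only model, since
#' either reading of "a polynomial regression ... was performed (F-test)"
#' may be wanted.
#'
#' @param series Data frame with `animal_id`, `group`, `day` (integer),
#'   `serum_creatinine` (> 0).
#' @param interactions Include `treatment:day` and `treatment:day^2`.
#' @return List: `F_treatment`, `df_treatment`, `p_treatment`,
#'   `F_model`, `p_model`, `fit` (the full `lm`).
#' @export
creatinine_polynomial_test <- function(series, interactions = FALSE) {
  stopifnot(all(c("animal_id", "group", "day", "serum_creatinine") %in%
                names(series)))
  if (anyDuplicated(series[, c("animal_id", "day")])) {
    stop("one value per (animal, day) required", call. = FALSE)
  }
  if (length(unique(series$day)) < 3) {
    stop("need at least 3 distinct days for a quadratic", call. = FALSE)
  }
  d <- data.frame(y = series$serum_creatinine,
                  g = factor(series$group),
                  day = as.numeric(series$day))
  if (nlevels(d$g) < 2 || any(table(d$g) < 2)) {
    stop("need >= 2 animals in each of two groups", call. = FALSE)
  }
  full_form <- if (interactions) y ~ g * (day + I(day^2)) else
    y ~ g + day + I(day^2)
  full <- stats::lm(full_form, data = d)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reduced <- stats::lm(y ~ day + I(day^2), data = d)
  cmp <- stats::anova(reduced, full)
  null_cmp <- stats::anova(stats::lm(y ~ 1, data = d), full)
  list(F_treatment = cmp$F[2],
       df_treatment = c(cmp$Df[2], cmp$Res.Df[2]),
       p_treatment = cmp$`Pr(>F)`[2],
       F_model = null_cmp$F[2],
       p_model = null_cmp$`Pr(>F)`[2],
       fit = full)
}
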