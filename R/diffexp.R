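# Precompute everything about the design that per-protein tests reuse:
# orthonormal bases of the four nested models (for Type-II sums of squares
# by model comparison) and cell membership for the post-hoc contrasts.
anova_engine <- function(group, time) {
  g <- droplevels(factor(group))
  tt <- droplevels(factor(time))
  n <- length(g)
  stopifnot(length(tt) == n)
  cell <- interaction(g, tt, sep = ":", drop = FALSE, lex.order = TRUE)
  counts <- table(cell)
  if (any(counts == 0)) stop("empty (group, time) cell", call. = FALSE)
  cell <- droplevels(cell)
  ind <- stats::model.matrix(~ cell - 1)
  cn <- colSums(ind)
  qbase <- function(X) qr.Q(qr(X))
  # single-level factors (degenerate one-way layouts) reduce to ~1
  X_g <- if (nlevels(g) > 1) stats::model.matrix(~g) else matrix(1, n, 1)
  X_t <- if (nlevels(tt) > 1) stats::model.matrix(~tt) else matrix(1, n, 1)
  X_gt <- if (nlevels(g) > 1 && nlevels(tt) > 1) {
    stats::model.matrix(~ g + tt)
  } else if (nlevels(g) > 1) X_g else X_t
  Q <- list(g = qbase(X_g), t = qbase(X_t), gt = qbase(X_gt),
            full = qbase(ind))
  list(n = n, group = g, time = tt, cell = cell,
       cell_levels = levels(cell), cell_n = as.numeric(cn),
       mean_op = t(ind) / cn,            # (ncells x n): Y -> cell means
       Q = Q,
       df = c(treatment = nlevels(g) - 1L,
              time = nlevels(tt) - 1L,
              interaction = nlevels(cell) - nlevels(g) - nlevels(tt) + 1L),
       dfe = n - nlevels(cell))
}

# Residual sum of squares of each column of Y under the model spanned by Q.
rss_cols <- function(Q, Y) {
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

# Type-II two-way ANOVA for every column of Y (samples x proteins).
# Returns list of p x 3 matrices: ss, F, p (treatment, time, interaction).
anova_terms_cols <- function(Y, eng, tol = 1e-10) {
  rss_g <- rss_cols(eng$Q$g, Y)
  rss_t <- rss_cols(eng$Q$t, Y)
  rss_gt <- rss_cols(eng$Q$gt, Y)
  sse <- rss_cols(eng$Q$full, Y)
  ss <- cbind(treatment = rss_t - rss_gt,
              time = rss_g - rss_gt,
              interaction = rss_gt - sse)
  ss[ss < 0] <- 0  # numerical guard
  dfe <- eng$dfe
  mse <- sse / dfe
  Fm <- sweep(ss, 2, eng$df, "/") / mse
  pm <- matrix(NA_real_, nrow(ss), 3,
               dimnames = list(NULL, colnames(ss)))
  for (k in 1:3) {
    pm[, k] <- stats::pf(Fm[, k], eng$df[k], dfe, lower.tail = FALSE)
  }
  degen <- mse <= tol * (pmax(colSums(Y^2), 1) / nrow(Y))
  if (any(degen)) {
    warning("zero residual variance for some proteins; p set to 0/1",
            call. = FALSE)
    for (k in 1:3) {
      pm[degen, k] <- ifelse(ss[degen, k] > tol, 0, 1)
      Fm[degen, k] <- ifelse(ss[degen, k] > tol, Inf, 0)
    }
  }
  list(ss = ss, F = Fm, p = pm, sse = sse, mse = mse)
}

#' Two-way ANOVA for a single protein
#'
#' Fixed-effects two-way analysis of variance with treatment (2 levels),
#' time (3 levels in the study design) and their interaction, using
#' Type-II sums of squares so the unbalanced 28-sample design is handled
#' by model comparison: SS(treatment) = RSS(~time) - RSS(~treatment+time),
#' and analogously for time; the interaction is tested against the full
#' cell-means model. Type I (sequential, treatment first) and Type III
#' are available for comparison.
#'
#' @param values Numeric vector, one value per design row.
#' @param design Data frame with `group` and `timepoint` columns (any
#'   factor levels; every crossed cell must be non-empty).
#' @param ss_type `"II"` (default), `"I"` or `"III"`.
#' @return An `anova_terms` list: per term `F`, `p`, `ss`, `df`, plus
#'   `sse`, `mse`, `dfe`.
#' @examples
#' d <- data.frame(group = rep(c("A", "B"), each = 4),
#'                 timepoint = rep(c("t1", "t2"), 4))
#' anova_two_way(c(1, 3, 2, 4, 5, 7, 6, 8), d)
#' @export
anova_two_way <- function(values, design, ss_type = c("II", "I", "III")) {
  ss_type <- match.arg(ss_type)
  eng <- anova_engine(design$group, design$timepoint)
  stopifnot(length(values) == eng$n)
  if (any(table(eng$cell) < 2)) {
    stop("every (group, time) cell needs >= 2 values", call. = FALSE)
  }
  Y <- matrix(as.numeric(values), ncol = 1)
  if (ss_type == "II") {
    res <- anova_terms_cols(Y, eng)
    ss <- res$ss[1, ]
    Fv <- res$F[1, ]
    pv <- res$p[1, ]
    sse <- res$sse[1]
  } else {
    g <- eng$group; tt <- eng$time
    y <- as.numeric(values)
    sse <- sum(stats::lm.fit(stats::model.matrix(~ g * tt), y)$residuals^2)
    rssf <- function(form) sum(stats::lm.fit(stats::model.matrix(form), y)$residuals^2)
    if (ss_type == "I") {
      ss <- c(treatment = sum((y - mean(y))^2) - rssf(~g),
              time = rssf(~g) - rssf(~ g + tt),
              interaction = rssf(~ g + tt) - sse)
    } else {
      # Type III via sum-to-zero contrasts: drop each term from the full model
      X <- stats::model.matrix(~ g * tt,
             contrasts.arg = list(g = "contr.sum", tt = "contr.sum"))
      asg <- attr(X, "assign")
      drop_rss <- function(a) {
        sum(stats::lm.fit(X[, asg != a, drop = FALSE], y)$residuals^2)
      }
      ss <- c(treatment = drop_rss(1) - sse,
              time = drop_rss(2) - sse,
              interaction = drop_rss(3) - sse)
    }
    mse <- sse / eng$dfe
    Fv <- ss / eng$df / mse
    pv <- stats::pf(Fv, eng$df, eng$dfe, lower.tail = FALSE)
    if (mse <= 1e-12) {
      warning("zero residual variance; p set to 0/1", call. = FALSE)
      pv <- ifelse(ss > 1e-12, 0, 1)
      Fv <- ifelse(ss > 1e-12, Inf, 0)
    }
  }
  structure(list(F = Fv, p = pv, ss = ss, df = eng$df,
                 sse = unname(sse), mse = unname(sse) / eng$dfe,
                 dfe = eng$dfe, ss_type = ss_type),
            class = "anova_terms")
}

# Contrast bookkeeping for Tukey HSD over the crossed cells.
tukey_setup <- function(eng) {
  k <- length(eng$cell_levels)
  pairs <- utils::combn(k, 2)
  se_half <- sqrt((1 / eng$cell_n[pairs[1, ]] +
                   1 / eng$cell_n[pairs[2, ]]) / 2)  # Tukey-Kramer
  list(pairs = pairs, k = k, se_half = se_half,
       labels_a = eng$cell_levels[pairs[1, ]],
       labels_b = eng$cell_levels[pairs[2, ]])
}

# Fast studentized-range upper tail for a fixed (nmeans, df): a monotone
# spline of log p on a dense q-grid, cached per design. stats::ptukey is
# exact but ~0.5 ms/call, prohibitive at ensemble scale (proteins x
# contrasts x replicates); the spline agrees to ~1e-8 relative error and
# clamps to ptukey's own numerical tail plateau beyond the grid.
tukey_tail_fun <- function(k, dfe, qmax = 30, n_grid = 2000) {
  key <- paste0("ptukey_", k, "_", dfe)
  cached <- .miprot_cache[[key]]
  if (!is.null(cached)) return(cached)
  grid <- seq(0, qmax, length.out = n_grid)
  lp <- log(stats::ptukey(grid, k, dfe, lower.tail = FALSE))
  keep <- is.finite(lp) & !duplicated(lp)
  sf <- stats::splinefun(grid[keep], lp[keep], method = "hyman")
  top <- max(grid[keep])
  f <- function(q) exp(sf(pmax(0, pmin(q, top))))
  .miprot_cache[[key]] <- f
  f
}

# Tukey HSD adjusted p for every column of Y at once.
# Returns list: diff and p, both (ncontrasts x nproteins); cellmeans.
tukey_cols <- function(Y, eng, ts, mse, tol = 1e-10, ptail = NULL) {
  M <- eng$mean_op %*% Y                      # ncells x p cell means
  D <- M[ts$pairs[1, ], , drop = FALSE] - M[ts$pairs[2, ], , drop = FALSE]
  SE <- outer(ts$se_half, sqrt(mse))
  q <- abs(D) / SE
  pv <- if (is.null(ptail)) {
    stats::ptukey(q, ts$k, eng$dfe, lower.tail = FALSE)
  } else {
    ptail(q)
  }
  p <- matrix(pv, nrow = nrow(q))
  degen <- mse <= tol
  if (any(degen)) {
    p[, degen] <- ifelse(abs(D[, degen, drop = FALSE]) > tol, 0, 1)
  }
  list(diff = D, p = p, q = q, cellmeans = M)
}

#' Tukey HSD post-hoc contrasts for a single protein
#'
#' All pairwise comparisons among the (group x time) cell means, with the
#' studentized-range adjustment at the full family size and the
#' Tukey-Kramer standard error `sqrt(MSE/2 * (1/n_i + 1/n_j))` for
#' unequal cell sizes. The pooled MSE comes from the full cell-means
#' model (identical to the interaction-model residual).
#'
#' @inheritParams anova_two_way
#' @return Data frame with one row per unordered cell pair: `cell_a`,
#'   `cell_b`, `mean_difference` (a minus b), `q`, `adjusted_p`.
#' @export
tukey_hsd <- function(values, design) {
  eng <- anova_engine(design$group, design$timepoint)
  stopifnot(length(values) == eng$n)
  if (any(table(eng$cell) < 2)) {
    stop("every (group, time) cell needs >= 2 values", call. = FALSE)
  }
  Y <- matrix(as.numeric(values), ncol = 1)
  sse <- rss_cols(eng$Q$full, Y)
  mse <- sse / eng$dfe
  ts <- tukey_setup(eng)
  res <- tukey_cols(Y, eng, ts, mse)
  data.frame(cell_a = ts$labels_a, cell_b = ts$labels_b,
             mean_difference = res$diff[, 1],
             q = res$q[, 1],
             adjusted_p = res$p[, 1],
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH adjusted p-values ("q-values"): sort ascending, multiply by
#' `m / rank`, enforce monotonicity by a cumulative minimum from the
#' largest p down, cap at 1, and return in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  assert_probability(p_values)
  n <- length(p_values)
  if (n == 0) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p_values[o]))[ro]
}

bh_adjust_cols <- function(P) {
  apply(P, 2, bh_adjust)
}

#' Pool p-values across imputation replicates by geometric mean
#'
#' `exp(mean(log(p)))`. Zeros (numerical underflow) are floored at
#' `1e-300` with a warning before taking logs.
#'
#' @param values_across_replicates Numeric vector of (adjusted) p-values,
#'   one per replicate.
#' @return A single pooled value.
#' @export
pool_geometric <- function(values_across_replicates) {
  p <- values_across_replicates
  if (length(p) == 0) stop("cannot pool an empty set", call. = FALSE)
  assert_probability(p)
  if (any(p == 0)) {
    warning("zero p-values floored at 1e-300 before pooling",
            call. = FALSE)
    p <- pmax(p, P_FLOOR)
  }
  exp(mean(log(p)))
}

#' Call differential expression from an imputation ensemble
#'
#' For each imputation replicate: per-protein two-way ANOVA (Type-II) and
#' Tukey HSD over all 15 cell pairs; BH adjustment of each ANOVA term's
#' p-values across proteins within the replicate. Adjusted values are then
#' pooled per protein across replicates by geometric mean. A protein is
#' called significant when its pooled interaction q-value falls below
#' `alpha` (mode `"interaction"`; mode `"main"` requires both pooled main
#' effect q-values below `alpha` instead). The time point of significance
#' is the timepoint whose within-time between-group Tukey contrast has the
#' smallest pooled adjusted p among those below `alpha` (ties to the
#' earliest timepoint; if none is below `alpha`, the overall smallest);
#' the direction is the arm with the larger pooled mean at that timepoint.
#'
#' @param ensemble An [build_ensemble()] result.
#' @param alpha Significance threshold on pooled q-values.
#' @param de_mode `"interaction"` (default) or `"main"`.
#' @return A `de_result` data frame: `protein_id`, pooled `q_treatment`,
#'   `q_time`, `q_interaction`, per-timepoint pooled within-time contrast
#'   p (`p_group_BL` etc.), `significant`, `timepoint_of_significance`,
#'   `direction`. Attribute `"contrasts"` holds the pooled adjusted p for
#'   all cell pairs.
#' @export
call_de <- function(ensemble, alpha = 0.05,
                    de_mode = c("interaction", "main")) {
  de_mode <- match.arg(de_mode)
  stopifnot(inherits(ensemble, "imputed_ensemble"))
  design <- ensemble$source$design
  eng <- anova_engine(design$group, design$timepoint)
  if (any(table(eng$cell) < 2)) {
    stop("every (group, timepoint) cell needs >= 2 samples", call. = FALSE)
  }
  ts <- tukey_setup(eng)
  R <- length(ensemble$replicates)
  pids <- rownames(ensemble$source$values)
  np <- length(pids)

  ptail <- tukey_tail_fun(ts$k, eng$dfe)
  acc_terms <- matrix(0, np, 3)
  acc_con <- matrix(0, ncol(ts$pairs), np)
  acc_means <- matrix(0, ts$k, np)
  for (r in seq_len(R)) {
    Y <- t(ensemble$replicates[[r]])
    av <- anova_terms_cols(Y, eng)
    qm <- bh_adjust_cols(av$p)
    acc_terms <- acc_terms + log(pmax(qm, P_FLOOR))
    tk <- tukey_cols(Y, eng, ts, av$mse, ptail = ptail)
    acc_con <- acc_con + log(pmax(tk$p, P_FLOOR))
    acc_means <- acc_means + tk$cellmeans
  }
  q_pool <- exp(acc_terms / R)
  con_pool <- exp(acc_con / R)
  cellmeans <- acc_means / R
  rownames(con_pool) <- paste(ts$labels_a, ts$labels_b, sep = " vs ")
  rownames(cellmeans) <- eng$cell_levels

  # within-time between-group contrasts, in timepoint order
  tps <- levels(eng$time)
  grs <- levels(eng$group)
  wt_idx <- vapply(tps, function(tp) {
    a <- paste(grs[1], tp, sep = ":")
    b <- paste(grs[2], tp, sep = ":")
    which((ts$labels_a == a & ts$labels_b == b) |
          (ts$labels_a == b & ts$labels_b == a))
  }, integer(1))
  wt_p <- t(con_pool[wt_idx, , drop = FALSE])  # np x ntimepoints
  colnames(wt_p) <- tps

  significant <- if (de_mode == "interaction") {
    q_pool[, 3] < alpha
  } else {
    q_pool[, 1] < alpha & q_pool[, 2] < alpha
  }

  pick_tp <- apply(wt_p, 1, function(p) {
    hit <- which(p < alpha)
    if (!length(hit)) hit <- seq_along(p)
    hit[which.min(p[hit])]
  })
  tp_sig <- ifelse(significant, tps[pick_tp], NA_character_)
  direction <- rep(NA_character_, np)
  for (i in which(significant)) {
    tp <- tps[pick_tp[i]]
    m1 <- cellmeans[paste(grs[1], tp, sep = ":"), i]
    m2 <- cellmeans[paste(grs[2], tp, sep = ":"), i]
    direction[i] <- if (m1 >= m2) grs[1] else grs[2]
  }

  out <- data.frame(protein_id = pids,
                    q_treatment = q_pool[, 1],
                    q_time = q_pool[, 2],
                    q_interaction = q_pool[, 3],
                    significant = significant,
                    timepoint_of_significance = tp_sig,
                    direction = direction,
                    stringsAsFactors = FALSE)
  for (tp in tps) out[[paste0("p_group_", tp)]] <- wt_p[, tp]
  attr(out, "contrasts") <- con_pool
  attr(out, "cellmeans") <- cellmeans
  attr(out, "alpha") <- alpha
  attr(out, "de_mode") <- de_mode
  attr(out, "n_replicates") <- R
  class(out) <- c("de_result", "data.frame")
  out
}

#' Write a differential-expression table as TSV
#'
#' @param de A `de_result` from [call_de()].
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
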