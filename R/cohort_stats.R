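# Cohort-level inference on composite scores: age/sex effects, composite
# inter-correlations, cross-timepoint stability, within-subject stability,
# and developmental-outcome (ASQ) mixed models.

#' Percentile ranks
#'
#' Cohort percentile of each value: `rank / (n + 1) * 100` with mean ranks
#' for ties (invariant to monotone transforms of the scores).
#'
#' @param x numeric vector (NAs keep NA).
#' @return percentiles in `(0, 100)`.
#' @export
percentile_rank <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  out[ok] <- rank(x[ok], ties.method = "average") / (sum(ok) + 1) * 100
  out
}

#' Spearman correlation with a large-sample p-value
#'
#' @param x,y numeric vectors (pairwise-complete).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Linear age and sex models per composite
#'
#' Fits `score ~ exact_age + sex` per composite; with a list of score tables
#' (one per imputation) the coefficients are pooled by Rubin's rules.
#'
#' @param scores data.frame with columns `exact_age`, `sex`
#'   (factor/character, reference male) and one column per composite -- or a
#'   list of such data.frames (one per imputation).
#' @param composites composite column names (default [composite_names()]).
#' @return data.frame with one row per composite x term (`age`,
#'   `sexfemale`): estimate, se, df, p.
#' @export
age_sex_models <- function(scores, composites = composite_names()) {
  tables <- if (is.data.frame(scores)) list(scores) else scores
  out <- list()
  for (comp in composites) {
    est <- se <- matrix(NA_real_, length(tables), 2)
    for (i in seq_along(tables)) {
      d <- tables[[i]]
      d$female <- as.integer(d$sex %in% c("female", "F", "f", 1))
      fit <- stats::lm(d[[comp]] ~ d$exact_age + d$female)
      sm <- summary(fit)$coefficients
      est[i, ] <- sm[2:3, 1]
      se[i, ] <- sm[2:3, 2]
    }
    pooled <- if (length(tables) > 1L) pool_rubin(est, se)
      else data.frame(estimate = est[1, ], se = se[1, ], df = Inf)
    out[[comp]] <- data.frame(composite = comp, term = c("age", "sexfemale"),
                              estimate = pooled$estimate, se = pooled$se,
                              df = pooled$df)
  }
  res <- do.call(rbind, out)
  res$p <- 2 * stats::pt(-abs(res$estimate / res$se), df = res$df)
  rownames(res) <- NULL
  res
}

#' Pairwise Spearman correlations between composites
#'
#' @param scores matrix/data.frame of composite scores (pooled assessments).
#' @param alpha familywise level (default 0.05, Bonferroni over the
#'   `choose(k, 2)` pairs).
#' @return list with `rho` (k x k), `p` (k x k), `significant` (logical),
#'   `alpha_adjusted`.
#' @export
composite_correlations <- function(scores, alpha = 0.05) {
  scores <- as.data.frame(scores)
  k <- ncol(scores)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(names(scores), names(scores)))
  diag(rho) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    st <- spearman_test(scores[[i]], scores[[j]])
    rho[i, j] <- rho[j, i] <- st$rho
    p[i, j] <- p[j, i] <- st$p
  }
  alpha_adj <- alpha / choose(k, 2)
  list(rho = rho, p = p, significant = p < alpha_adj & row(p) != col(p),
       alpha_adjusted = alpha_adj)
}

#' Cross-timepoint stability of composites
#'
#' Spearman correlations of each composite between assessment timepoints,
#' with Bonferroni correction over all composite x pair tests.
#'
#' @param scores data.frame with `participant_id`, `timepoint` (e.g. "3m"),
#'   and composite columns.
#' @param composites composite column names.
#' @param timepoints ordered timepoint labels (default c("3m","6m","12m")).
#' @param alpha familywise level (default 0.05).
#' @return data.frame: composite, pair, rho, p, n, significant (p below
#'   `alpha / (n_composites * n_pairs)`; with the defaults 0.05/15 = 0.0033).
#' @export
stability_table <- function(scores, composites = composite_names(),
                            timepoints = c("3m", "6m", "12m"), alpha = 0.05) {
  pairs <- utils::combn(timepoints, 2, simplify = FALSE)
  n_tests <- length(composites) * length(pairs)
  rows <- list()
  for (comp in composites) for (pr in pairs) {
    a <- scores[scores$timepoint == pr[1], c("participant_id", comp)]
    b <- scores[scores$timepoint == pr[2], c("participant_id", comp)]
    mg <- merge(a, b, by = "participant_id")
    st <- spearman_test(mg[[2]], mg[[3]])
    rows[[length(rows) + 1L]] <- data.frame(
      composite = comp, pair = paste(pr, collapse = " vs "),
      rho = st$rho, p = st$p, n = st$n,
      significant = !is.na(st$p) & st$p < alpha / n_tests)
  }
  res <- do.call(rbind, rows)
  attr(res, "alpha_adjusted") <- alpha / n_tests
  res
}

#' Within-subject stability: percentile range across timepoints
#'
#' For each composite, participants are percentile-ranked within each
#' timepoint; a participant's stability is the range (max - min) of their
#' percentiles across timepoints. Participants observed at fewer than 2
#' timepoints are excluded.
#'
#' @param scores data.frame with `participant_id`, `timepoint`, composite
#'   columns (typically from one imputation).
#' @param composites composite column names.
#' @return list with `ranges` (data.frame participant x composite range)
#'   and `mean_range` (named vector per composite).
#' @export
within_subject_stability <- function(scores, composites = composite_names()) {
  sc <- scores
  for (comp in composites) {
    sc[[paste0(".pct.", comp)]] <- stats::ave(sc[[comp]], sc$timepoint,
                                              FUN = percentile_rank)
  }
  ids <- unique(sc$participant_id)
  rows <- lapply(ids, function(pid) {
    d <- sc[sc$participant_id == pid, ]
    if (nrow(d) < 2L) return(NULL)
    rng <- vapply(composites, function(comp) {
      v <- d[[paste0(".pct.", comp)]]
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else max(v) - min(v)
    }, numeric(1))
    data.frame(participant_id = pid, t(rng), check.names = FALSE)
  })
  ranges <- do.call(rbind, rows)
  list(ranges = ranges,
       mean_range = colMeans(ranges[, composites, drop = FALSE], na.rm = TRUE))
}

#' Paired t-test contrasting composite vs single-variable stability
#'
#' @param composite_range,variable_range matched per-participant percentile
#'   ranges.
#' @return list with `t`, `df`, `p`, `mean_diff`, `degenerate` (TRUE when
#'   the differences have zero variance, in which case t/p are NA).
#' @export
stability_contrast <- function(composite_range, variable_range) {
  ok <- !is.na(composite_range) & !is.na(variable_range)
  d <- composite_range[ok] - variable_range[ok]
  if (length(d) < 2L || stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(composite_range[ok], variable_range[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Flag outliers by the 1.5 IQR rule
#'
#' @param x numeric vector.
#' @return logical: TRUE when below Q1 - 1.5 IQR or above Q3 + 1.5 IQR.
#' @export
outlier_flags <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  !is.na(x) & (x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
}

#' Longitudinal mixed models of developmental outcomes on composites
#'
#' Per outcome: `outcome ~ composites + exact_age + sex + (1 + tp_index |
#' participant)` fit with lme4; on a singular or failed fit the random slope
#' is dropped with a warning. With a list of score tables the fixed effects
#' are pooled by Rubin's rules.
#'
#' @param scores data.frame (or list of data.frames, one per imputation)
#'   with `participant_id`, `timepoint`, `tp_index` (assessment number),
#'   `exact_age`, `sex`, composite columns and the outcome columns.
#' @param outcomes outcome column names (e.g. `c("asq_collective")`).
#' @param composites composite predictors; pass a single name (e.g. "Sleep
#'   Day") for the reduced model.
#' @return data.frame: outcome, term, estimate, se, df, p.
#' @export
asq_models <- function(scores, outcomes = "asq_collective",
                       composites = composite_names()) {
  tables <- if (is.data.frame(scores)) list(scores) else scores
  res <- list()
  for (outc in outcomes) {
    terms <- c("(Intercept)", composites, "exact_age", "female")
    est <- se <- matrix(NA_real_, length(tables), length(terms))
    for (i in seq_along(tables)) {
      d <- tables[[i]]
      d$female <- as.integer(d$sex %in% c("female", "F", "f", 1))
      d <- d[!is.na(d[[outc]]), ]
      cnames <- make.names(composites)
      names(d)[match(composites, names(d))] <- cnames
      form <- stats::as.formula(paste(
        outc, "~", paste(c(cnames, "exact_age", "female"), collapse = " + "),
        "+ (1 + tp_index | participant_id)"))
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(form, data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
      if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
        form2 <- stats::as.formula(paste(
          outc, "~", paste(c(cnames, "exact_age", "female"), collapse = " + "),
          "+ (1 | participant_id)"))
        fit <- suppressWarnings(suppressMessages(
          lme4::lmer(form2, data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE))))
      }
      sm <- summary(fit)$coefficients
      want <- c("(Intercept)", cnames, "exact_age", "female")
      est[i, ] <- sm[want, 1]
      se[i, ] <- sm[want, 2]
    }
    pooled <- if (length(tables) > 1L) pool_rubin(est, se)
      else data.frame(estimate = est[1, ], se = se[1, ], df = Inf)
    res[[outc]] <- data.frame(outcome = outc, term = terms,
                              estimate = pooled$estimate, se = pooled$se,
                              df = pooled$df)
  }
  out <- do.call(rbind, res)
  out$p <- 2 * stats::pt(-abs(out$estimate / out$se), df = out$df)
  rownames(out) <- NULL
  out
}
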