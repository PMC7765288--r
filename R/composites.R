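# Composite extraction: multiple imputation, component-count selection,
# PCA with promax rotation, loading-based pruning/assignment, unweighted
# composite scoring, and Rubin pooling.

#' Multiple imputation by chained predictive mean matching
#'
#' Chained-equations imputation where each incomplete variable is regressed
#' on the assessment age, the participant's observed mean of that variable
#' (a pragmatic stand-in for a two-level random intercept) and the most
#' correlated other variables; missing entries receive the observed value of
#' a randomly drawn nearest-prediction donor. Deterministic given `seed`.
#'
#' @param mat numeric matrix (assessments x variables) with NAs.
#' @param m number of completed copies (default 20; scale up for production
#'   runs).
#' @param maxit chained iterations per copy (default 10).
#' @param seed integer seed.
#' @param age optional numeric covariate per row (exact age in months).
#' @param id optional participant id per row (enables the participant-mean
#'   predictor).
#' @param n_pred number of most-correlated companion predictors (default 10).
#' @param donors donor pool size for predictive mean matching (default 5).
#' @return object of class `imputation_set`: list with `imputations` (list
#'   of m complete matrices), `m`, and `missing_pattern`.
#' @export
impute_pmm <- function(mat, m = 20L, maxit = 10L, seed = 1L,
                       age = NULL, id = NULL, n_pred = 10L, donors = 5L) {
  mat <- as.matrix(mat)
  p <- ncol(mat)
  miss <- is.na(mat)
  if (any(colSums(!miss) == 0L)) stop("variable with no observed values cannot be imputed")
  if (!any(miss)) {
    return(structure(list(imputations = replicate(m, mat, simplify = FALSE),
                          m = m, missing_pattern = miss),
                     class = "imputation_set"))
  }
  set.seed(seed)
  cols_na <- which(colSums(miss) > 0L)
  cm <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  id_mean <- function(j, cur) {
    if (is.null(id)) return(NULL)
    mu <- tapply(ifelse(miss[, j], NA, mat[, j]), id, mean, na.rm = TRUE)
    v <- as.numeric(mu[as.character(id)])
    v[!is.finite(v)] <- mean(mat[, j], na.rm = TRUE)
    v
  }

  impute_once <- function() {
    cur <- mat
    for (j in seq_len(p)) {   # initial fill: random observed draws
      nj <- which(miss[, j])
      if (length(nj)) cur[nj, j] <- sample(mat[!miss[, j], j], length(nj),
                                           replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (j in cols_na) {
        others <- setdiff(order(abs(cm[, j]), decreasing = TRUE), j)
        others <- utils::head(others, n_pred)
        X <- cur[, others, drop = FALSE]
        if (!is.null(age)) X <- cbind(X, age = age)
        im <- id_mean(j, cur)
        if (!is.null(im)) X <- cbind(X, id_mean = im)
        obs <- which(!miss[, j])
        nj <- which(miss[, j])
        fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), mat[obs, j])
        beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
        pred_all <- as.numeric(cbind(1, X) %*% beta)
        for (i in nj) {
          d <- abs(pred_all[obs] - pred_all[i])
          pool <- obs[order(d)[seq_len(min(donors, length(obs)))]]
          cur[i, j] <- mat[sample(pool, 1L), j]
        }
      }
    }
    cur
  }
  imps <- replicate(m, impute_once(), simplify = FALSE)
  structure(list(imputations = imps, m = m, missing_pattern = miss),
            class = "imputation_set")
}

#' Component count by parallel analysis
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' chosen quantile of eigenvalues from uncorrelated normal data of the same
#' dimensions; the suggested count is the number of leading components whose
#' eigenvalue exceeds its random-data threshold (stopping at the first that
#' does not, which is also where the scree elbow is sought).
#'
#' @param mat numeric matrix (rows = assessments), complete.
#' @param n_sim random datasets simulated (default 100).
#' @param quantile threshold quantile of the random eigenvalues
#'   (default 0.95).
#' @param seed seed for the simulated datasets (default 1).
#' @return list with `n_components`, `eigenvalues`, `thresholds`.
#' @export
choose_k <- function(mat, n_sim = 100L, quantile = 0.95, seed = 1L) {
  mat <- as.matrix(mat)
  stopifnot(!anyNA(mat))
  n <- nrow(mat); p <- ncol(mat)
  ev <- eigen(stats::cor(mat), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  sim <- matrix(NA_real_, n_sim, p)
  for (s in seq_len(n_sim)) {
    sim[s, ] <- eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)),
                      symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- apply(sim, 2, stats::quantile, probs = quantile)
  above <- ev > thr
  k <- if (!above[1]) 0L else (which(!above)[1] - 1L)
  if (is.na(k)) k <- p
  list(n_components = as.integer(k), eigenvalues = ev, thresholds = thr)
}

#' PCA with promax rotation
#'
#' Principal components of the correlation matrix (columns are z-scored, so
#' the mixed units of the sleep variables are irrelevant), retained loadings
#' rotated obliquely by promax (which varimax-rotates first). Component signs
#' are fixed so each component's largest-magnitude variable loads
#' positively.
#'
#' @param mat complete numeric matrix (assessments x variables).
#' @param k number of components (default 5).
#' @param power promax power (default 4).
#' @return list with `loadings` (pattern matrix), `Phi` (inter-component
#'   correlations), `eigenvalues`, `variance_explained` (per component,
#'   SS-loadings / p), `k`.
#' @export
fit_pca_promax <- function(mat, k = 5L, power = 4) {
  mat <- as.matrix(mat)
  stopifnot(!anyNA(mat))
  R <- stats::cor(mat)
  e <- eigen(R, symmetric = TRUE)
  if (k > sum(e$values > 1e-10)) stop("k exceeds the rank of the correlation matrix")
  L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(e$values[seq_len(k)]), k)
  rownames(L) <- colnames(mat)
  if (k == 1L) {
    pat <- L
    Phi <- matrix(1, 1, 1)
  } else {
    pr <- stats::promax(L, m = power)
    pat <- unclass(pr$loadings)
    U <- pr$rotmat
    Phi <- solve(t(U) %*% U)
    Phi <- stats::cov2cor(Phi)
  }
  # sign convention
  for (j in seq_len(ncol(pat))) {
    i <- which.max(abs(pat[, j]))
    if (pat[i, j] < 0) {
      pat[, j] <- -pat[, j]
      if (ncol(pat) > 1L) {
        Phi[j, ] <- -Phi[j, ]
        Phi[, j] <- -Phi[, j]
        Phi[j, j] <- 1
      }
    }
  }
  colnames(pat) <- paste0("C", seq_len(k))
  dimnames(Phi) <- list(colnames(pat), colnames(pat))
  list(loadings = pat, Phi = Phi, eigenvalues = e$values,
       variance_explained = colSums(pat^2) / ncol(mat), k = k)
}

#' Prune variables by loading and assign each to one composite
#'
#' Variables whose largest absolute loading falls below `cutoff` are
#' dropped, as are explicitly listed variables; when a data matrix is
#' supplied the PCA is refit on the retained set. Each retained variable is
#' assigned to its largest-|loading| component with the loading's sign.
#' Components are labelled by majority vote of their variables' published
#' composite membership when recognisable, else `C1..Ck`.
#'
#' @param loadings variable x component loading matrix (rownames = variable
#'   ids); e.g. [published_loadings()] or a [fit_pca_promax()] fit.
#' @param cutoff minimum absolute loading (default 0.512, the recommended
#'   threshold for samples above 100).
#' @param drop variable ids (character or integer) dropped regardless of
#'   loading (e.g. Sleep Duration 24 h, id 38, for interpretability).
#' @param mat optional complete data matrix (columns named by variable id)
#'   enabling the refit.
#' @param refit refit the PCA on the retained variables (default TRUE when
#'   `mat` is given).
#' @param power promax power for the refit.
#' @return object of class `composite_solution`: list with `loadings`
#'   (final), `assignment` (data.frame id/component/sign/loading),
#'   `retained`, `dropped_low`, `dropped_explicit`, `k`, `component_names`,
#'   `variance_explained` (NA when no refit).
#' @export
prune_and_assign <- function(loadings, cutoff = 0.512, drop = integer(),
                             mat = NULL, refit = !is.null(mat), power = 4) {
  ids <- rownames(loadings)
  drop <- as.character(drop)
  in_drop <- ids %in% drop
  max_abs <- apply(abs(loadings), 1, max)
  low <- max_abs < cutoff & !in_drop
  retained <- ids[!low & !in_drop]
  if (length(retained) < ncol(loadings)) stop("fewer retained variables than components")

  variance_explained <- NA
  if (refit) {
    if (is.null(mat)) stop("refit requires the data matrix")
    fit <- fit_pca_promax(mat[, retained, drop = FALSE], k = ncol(loadings),
                          power = power)
    final <- fit$loadings
    variance_explained <- fit$variance_explained
  } else {
    final <- loadings[retained, , drop = FALSE]
  }

  comp <- apply(abs(final), 1, which.max)
  load_val <- final[cbind(seq_len(nrow(final)), comp)]
  if (any(tabulate(comp, ncol(final)) == 0L)) {
    stop("a component was left without any assigned variable")
  }
  assignment <- data.frame(id = rownames(final),
                           component = comp,
                           sign = ifelse(load_val >= 0, 1, -1),
                           loading = load_val,
                           stringsAsFactors = FALSE)

  # label components by majority membership in the published solution
  pub <- published_loadings()
  pub_comp <- apply(abs(pub), 1, which.max)
  pub_names <- composite_names()[pub_comp]
  names(pub_names) <- rownames(pub)
  labels <- vapply(seq_len(ncol(final)), function(j) {
    members <- assignment$id[assignment$component == j]
    known <- pub_names[members[members %in% names(pub_names)]]
    if (length(known) == 0L) return(paste0("C", j))
    names(sort(table(known), decreasing = TRUE))[1]
  }, character(1))
  if (anyDuplicated(labels)) labels <- paste0("C", seq_len(ncol(final)))

  # orient labelled components to the published direction (e.g. larger
  # Sleep Activity = more nocturnal wake), using the signed agreement with
  # the published loadings of shared variables
  for (j in seq_len(ncol(final))) {
    if (!labels[j] %in% colnames(pub)) next
    shared <- intersect(rownames(final), rownames(pub))
    if (length(shared) == 0L) next
    s <- sum(final[shared, j] * pub[shared, labels[j]])
    if (s < 0) final[, j] <- -final[, j]
  }
  comp <- apply(abs(final), 1, which.max)
  load_val <- final[cbind(seq_len(nrow(final)), comp)]
  assignment$sign <- ifelse(load_val >= 0, 1, -1)
  assignment$loading <- load_val
  assignment$composite <- labels[assignment$component]
  colnames(final) <- labels

  structure(list(loadings = final, assignment = assignment,
                 retained = retained,
                 dropped_low = ids[low], dropped_explicit = ids[in_drop],
                 k = ncol(final), component_names = labels,
                 variance_explained = variance_explained),
            class = "composite_solution")
}

#' Composite scores: signed unweighted averages of z-scored variables
#'
#' @param mat complete numeric matrix with columns named by variable id
#'   (pooled over all assessments; z-scoring is done here, over rows).
#' @param solution a `composite_solution`.
#' @return numeric matrix (rows as `mat`, one column per composite).
#' @export
score_composites <- function(mat, solution) {
  mat <- as.matrix(mat)
  if (anyNA(mat[, solution$assignment$id])) {
    stop("composite scoring requires complete data; impute first")
  }
  z <- scale(mat[, solution$assignment$id, drop = FALSE])
  z[is.nan(z)] <- 0   # zero-variance column safeguard
  out <- sapply(unique(solution$assignment$composite), function(nm) {
    rows <- solution$assignment[solution$assignment$composite == nm, ]
    zz <- sweep(z[, rows$id, drop = FALSE], 2, rows$sign, `*`)
    rowMeans(zz)
  })
  colnames(out) <- unique(solution$assignment$composite)
  out
}

#' Pool estimates over imputations by Rubin's rules
#'
#' @param est m x q matrix of per-imputation estimates (or a vector for
#'   q = 1).
#' @param se m x q matrix of per-imputation standard errors.
#' @return data.frame with `estimate`, `se`, `df`, `between_var`,
#'   `within_var` per quantity.
#' @export
pool_rubin <- function(est, se) {
  if (is.null(dim(est))) { est <- cbind(est); se <- cbind(se) }
  if (nrow(est) == 1L) {
    warning("single imputation: pass-through, no between-imputation variance")
    return(data.frame(estimate = as.numeric(est), se = as.numeric(se),
                      df = Inf, between_var = 0,
                      within_var = as.numeric(se)^2))
  }
  m <- nrow(est)
  qbar <- colMeans(est)
  W <- colMeans(se^2)
  B <- apply(est, 2, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  data.frame(estimate = qbar, se = sqrt(Tv), df = df,
             between_var = B, within_var = W)
}
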