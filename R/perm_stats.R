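#' @keywords internal
#' All permutations of 1..n as an n! x n matrix (lexicographic-ish order).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, factorial(n), n)
  blk <- nrow(sub)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[(i - 1L) * blk + seq_len(blk), ] <- cbind(i, matrix(rest[sub], blk))
  }
  out
}

pairwise_complete <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Spearman's rank correlation
#'
#' Spearman's \eqn{\rho}: the Pearson correlation of mid-ranks (ties get
#' average ranks).  Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors of equal length (at least 3 complete pairs).
#' @return \eqn{\rho \in [-1, 1]}.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  pc <- pairwise_complete(x, y)
  if (pc$n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(pc$x) == 0 || stats::sd(pc$y) == 0)
    stop("undefined correlation: constant vector")
  stats::cor(pc$x, pc$y, method = "spearman")
}

#' Permutation test of Spearman's rank correlation
#'
#' Computes \eqn{\rho} and a permutation p-value p' by permuting `y`
#' against `x`.  For \eqn{n \le 7} complete pairs (or when
#' `exhaustive = TRUE`) all \eqn{n!} permutations are enumerated and p' is
#' exact — the proportion of permutations (the identity included) whose
#' statistic is as or more extreme in the stated direction.  Otherwise
#' `n_perm` random permutations are drawn with the given seed and the
#' add-one rule \eqn{p' = (1 + k)/(n_{perm} + 1)} applies, so p' is never
#' exactly zero.  The asymptotic p-value of the ordinary Spearman test is
#' reported alongside.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of random permutations (ignored when exhaustive).
#' @param seed integer seed for the permutation draw.
#' @param alternative `"greater"` (default; positive association), `"less"`
#'   or `"two_sided"`.
#' @param exhaustive `"auto"` (exhaustive iff \eqn{n \le 7}), `TRUE` or
#'   `FALSE`.
#' @return a `correlation_result` list with fields `rho`, `p_asym`,
#'   `p_perm`, `n`, `n_perm` (`NA` when exhaustive), `exhaustive`,
#'   `alternative`, `seed`.
#' @export
perm_spearman <- function(x, y, n_perm = 19999, seed = 1,
                          alternative = c("greater", "less", "two_sided"),
                          exhaustive = "auto") {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  pc <- pairwise_complete(x, y)
  n <- pc$n
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(pc$x) == 0 || stats::sd(pc$y) == 0)
    stop("undefined correlation: constant vector")
  do_exhaustive <- if (identical(exhaustive, "auto")) n <= 7L else isTRUE(exhaustive)
  rx <- rank(pc$x); ry <- rank(pc$y)
  rho_obs <- stats::cor(rx, ry)

  rxc <- rx - mean(rx)
  sxy <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
  tol <- 1e-10
  extreme <- function(r) switch(alternative,
    greater = r >= rho_obs - tol,
    less = r <= rho_obs + tol,
    two_sided = abs(r) >= abs(rho_obs) - tol)

  if (do_exhaustive) {
    if (n > 9L) stop("exhaustive enumeration limited to n <= 9")
    P <- all_permutations(n)
    # element [i, j] of ry[P] is ry under permutation i at position j
    rho_all <- as.vector(matrix(ry[P], nrow = nrow(P)) %*% rxc) / sxy
    p_perm <- mean(extreme(rho_all))
    n_used <- NA_integer_
  } else {
    if (n_perm < 999) stop("n_perm must be at least 999")
    G <- withr::with_seed(seed,
      vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    rho_perm <- as.vector(crossprod(matrix(ry[G], nrow = n), rxc)) / sxy
    p_perm <- (1 + sum(extreme(rho_perm))) / (n_perm + 1)
    n_used <- as.integer(n_perm)
  }
  alt_r <- switch(alternative, greater = "greater", less = "less",
                  two_sided = "two.sided")
  p_asym <- tryCatch(
    suppressWarnings(stats::cor.test(pc$x, pc$y, method = "spearman",
                                     alternative = alt_r)$p.value),
    error = function(e) NA_real_)
  structure(list(rho = rho_obs, p_asym = p_asym, p_perm = p_perm, n = n,
                 n_perm = n_used, exhaustive = do_exhaustive,
                 alternative = alternative, seed = seed),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d), p = %.4f, permutation p' = %.4f%s\n",
              x$rho, x$n, x$p_asym, x$p_perm,
              if (x$exhaustive) " [exhaustive]" else
                sprintf(" [%d permutations]", x$n_perm)))
  invisible(x)
}

#' Pairwise permutation Spearman correlations of cohort variables
#'
#' Lower-triangular table of [perm_spearman()] results over all variable
#' pairs, with pairwise-complete deletion per pair.  No multiplicity
#' adjustment is applied: the permutation p-values are reported per pair,
#' with an optional Benjamini-Hochberg column as a post-hoc extra.
#'
#' @param table cohort data.frame.
#' @param variables character vector of numeric column names.
#' @param n_perm,seed,alternative passed to [perm_spearman()]; each pair
#'   uses the sub-seed `seed + pair index`.
#' @param fdr logical; append a BH-adjusted column (default `FALSE`).
#' @return data.frame with one row per unordered pair: `var1`, `var2`,
#'   `n`, `rho`, `p_asym`, `p_perm` (and `p_perm_bh` when `fdr`).
#' @export
correlation_matrix <- function(table, variables, n_perm = 19999, seed = 1,
                               alternative = "greater", fdr = FALSE) {
  missing <- setdiff(variables, names(table))
  if (length(missing) > 0)
    stop("unknown cohort variable(s): ", paste(missing, collapse = ", "))
  pairs <- utils::combn(variables, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    v1 <- pairs[1, k]; v2 <- pairs[2, k]
    r <- perm_spearman(table[[v1]], table[[v2]], n_perm = n_perm,
                       seed = seed + k, alternative = alternative)
    data.frame(var1 = v1, var2 = v2, n = r$n, rho = r$rho,
               p_asym = r$p_asym, p_perm = r$p_perm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (isTRUE(fdr)) out$p_perm_bh <- stats::p.adjust(out$p_perm, "BH")
  out
}

prepare_design <- function(y, X) {
  X <- as.data.frame(X)
  for (j in seq_along(X)) {
    col <- X[[j]]
    if (is.character(col) || is.factor(col) || is.logical(col)) {
      lev <- sort(unique(as.character(col)))
      if (length(lev) != 2)
        stop("non-numeric predictor '", names(X)[j],
             "' must be binary to be coded 0/1")
      X[[j]] <- as.numeric(as.character(col) == lev[2])
    }
  }
  ok <- is.finite(y) & stats::complete.cases(X) &
    apply(as.matrix(X), 1, function(r) all(is.finite(r)))
  list(y = y[ok], X = as.matrix(X[ok, , drop = FALSE]), n_dropped = sum(!ok))
}

zscore <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  if (any(s == 0)) stop("constant column cannot be standardized: ",
                        paste(colnames(m)[s == 0], collapse = ", "))
  sweep(sweep(m, 2, mu), 2, s, "/")
}

#' Permutation multiple regression
#'
#' Least-squares regression on the standardized (z-scored) response and
#' predictors — binary predictors such as sex are coded 0/1 and then
#' z-scored — with permutation p-values instead of parametric ones.  Under
#' the default Manly scheme the raw response is permuted wholesale and the
#' model refitted `n_perm` times; each term's p' compares \eqn{|t_j|}
#' against its permutation distribution, and the overall model p' uses the
#' F statistic.  The Freedman-Lane scheme permutes, per term, the
#' residuals of the reduced model without that term.  Reported alongside:
#' standardized coefficients \eqn{\beta}, t statistics, \eqn{R^2},
#' adjusted \eqn{R^2}, Gaussian-likelihood AIC
#' (\eqn{n\ln(RSS/n) + n\ln 2\pi + n + 2(k+2)}, identical to
#' `stats::AIC()` on the same fit) and per-predictor VIF.
#'
#' @param y numeric response.
#' @param X data.frame of predictors (binary columns allowed).
#' @param n_perm number of permutations (fixed-count, seeded).
#' @param seed integer seed.
#' @param scheme `"manly"` (default) or `"freedman_lane"`.
#' @return a `perm_regression_result` list: `terms`, `beta_std`, `t_stats`,
#'   `p_perm`, `r2`, `adj_r2`, `f_stat`, `p_perm_model`, `aic`, `vif`,
#'   `n`, `n_dropped`, `n_perm`, `scheme`, `seed`.
#' @export
fit_perm_regression <- function(y, X, n_perm = 19999, seed = 1,
                                scheme = c("manly", "freedman_lane")) {
  scheme <- match.arg(scheme)
  pd <- prepare_design(y, X)
  n <- length(pd$y)
  p <- ncol(pd$X)
  if (n < p + 2) stop("need at least ", p + 2, " complete rows")
  terms <- colnames(pd$X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))

  qrX <- qr(cbind(1, pd$X))
  if (qrX$rank < p + 1) {
    dep <- terms[qrX$pivot[(qrX$rank + 1):(p + 1)] - 1L]
    stop("multicollinearity: predictor(s) linearly dependent: ",
         paste(dep, collapse = ", "))
  }
  ys <- as.vector(zscore(matrix(pd$y)))
  Xs <- zscore(pd$X)
  Xd <- cbind(`(Intercept)` = 1, Xs)
  XtX <- crossprod(Xd)
  XtXinv <- solve(XtX)
  H <- XtXinv %*% t(Xd)                       # (p+1) x n projector

  fit_t <- function(yv) {
    b <- H %*% yv
    res <- yv - Xd %*% b
    rss <- sum(res^2)
    s2 <- rss / (n - p - 1)
    list(b = b[-1], t = b[-1] / sqrt(s2 * diag(XtXinv)[-1]), rss = rss)
  }
  obs <- fit_t(ys)
  tss <- sum((ys - mean(ys))^2)
  r2 <- 1 - obs$rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f_stat <- (r2 / p) / ((1 - r2) / (n - p - 1))
  aic <- n * log(obs$rss / n) + n * log(2 * pi) + n + 2 * (p + 2)
  vifs <- if (p > 1) vif(pd$X) else stats::setNames(1, terms)

  tol <- 1e-10
  G <- withr::with_seed(seed,
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))

  perm_t <- function(Ystar) {
    # columns of Ystar are permuted responses
    B <- H %*% Ystar                           # (p+1) x n_perm
    RSS <- colSums((Ystar - Xd %*% B)^2)
    S <- sqrt(RSS / (n - p - 1))
    Tm <- B[-1, , drop = FALSE] / (S[col(B[-1, , drop = FALSE])] *
                                     sqrt(diag(XtXinv)[-1]))
    list(Tm = Tm, RSS = RSS)
  }

  if (scheme == "manly") {
    Ystar <- matrix(ys[G], nrow = n)
    pt_ <- perm_t(Ystar)
    p_perm <- vapply(seq_len(p), function(j)
      (1 + sum(abs(pt_$Tm[j, ]) >= abs(obs$t[j]) - tol)) / (n_perm + 1),
      numeric(1))
    TSSstar <- colSums(sweep(Ystar, 2, colMeans(Ystar))^2)
    Fstar <- ((TSSstar - pt_$RSS) / p) / (pt_$RSS / (n - p - 1))
    p_model <- (1 + sum(Fstar >= f_stat - tol)) / (n_perm + 1)
  } else {
    p_perm <- numeric(p)
    for (j in seq_len(p)) {
      Xr <- cbind(1, Xs[, -j, drop = FALSE])
      br <- qr.solve(Xr, ys)
      fitted_r <- as.vector(Xr %*% br)
      er <- ys - fitted_r
      Ystar <- fitted_r + matrix(er[G], nrow = n)
      pt_ <- perm_t(Ystar)
      p_perm[j] <- (1 + sum(abs(pt_$Tm[j, ]) >= abs(obs$t[j]) - tol)) /
        (n_perm + 1)
    }
    # model-level reduced model is the intercept: equivalent to Manly
    Ystar <- matrix(ys[G], nrow = n)
    pt_ <- perm_t(Ystar)
    TSSstar <- colSums(sweep(Ystar, 2, colMeans(Ystar))^2)
    Fstar <- ((TSSstar - pt_$RSS) / p) / (pt_$RSS / (n - p - 1))
    p_model <- (1 + sum(Fstar >= f_stat - tol)) / (n_perm + 1)
  }

  structure(list(terms = terms, beta_std = stats::setNames(as.vector(obs$b), terms),
                 t_stats = stats::setNames(as.vector(obs$t), terms),
                 p_perm = stats::setNames(p_perm, terms),
                 r2 = r2, adj_r2 = adj_r2, f_stat = f_stat,
                 p_perm_model = p_model, aic = aic,
                 vif = vifs, n = n, n_dropped = pd$n_dropped,
                 n_perm = n_perm, scheme = scheme, seed = seed),
            class = "perm_regression_result")
}

#' @export
print.perm_regression_result <- function(x, ...) {
  cat(sprintf("Permutation multiple regression (%s scheme, %d permutations, n = %d)\n",
              x$scheme, x$n_perm, x$n))
  tab <- data.frame(beta_std = round(x$beta_std, 4),
                    t = round(x$t_stats, 4),
                    p_perm = round(x$p_perm, 4),
                    vif = round(x$vif[x$terms], 4))
  print(tab)
  cat(sprintf("R2 = %.4f, adj R2 = %.4f, F = %.4f (model p' = %.4f), AIC = %.2f\n",
              x$r2, x$adj_r2, x$f_stat, x$p_perm_model, x$aic))
  invisible(x)
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1/(1 - R^2_j)} where \eqn{R^2_j} comes from regressing
#' predictor j on all the others (with intercept).  Values below 5 are
#' conventionally read as no multicollinearity concern.  Perfect
#' collinearity yields `Inf` with a warning.
#'
#' @param X data.frame or matrix of predictors (at least 2 columns and
#'   `ncol + 2` rows).
#' @return named numeric vector of VIFs (all \eqn{\ge 1}).
#' @export
vif <- function(X) {
  X <- as.matrix(as.data.frame(X))
  p <- ncol(X)
  if (p < 2) stop("VIF needs at least 2 predictors")
  if (nrow(X) < p + 2) stop("need at least ", p + 2, " rows")
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  out <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 > 1 - 1e-12) {
      warning("perfect collinearity for predictor ", terms[j])
      Inf
    } else {
      1 / (1 - r2)
    }
  }, numeric(1))
  stats::setNames(out, terms)
}

#' AIC ladder over candidate predictor sets
#'
#' Fits an ordinary least-squares model of the response on every candidate
#' term set (rows complete across the union of terms, so all AICs share
#' one sample) and ranks the candidates by Gaussian-likelihood AIC,
#' \eqn{AIC = n\ln(RSS/n) + n\ln 2\pi + n + 2(k+2)} with k predictors plus
#' intercept and variance.  Under this fixed constant convention the
#' absolute values match `stats::AIC()`; only AIC differences are
#' meaningful for ranking.
#'
#' @param data data.frame holding the response and predictors.
#' @param response response column name.
#' @param candidates list of character vectors of predictor names.
#' @return a `model_ladder` data.frame sorted by ascending AIC with
#'   columns `model`, `k`, `n`, `rss`, `aic`, `best`.
#' @export
aic_ladder <- function(data, response, candidates) {
  all_terms <- unique(unlist(candidates))
  missing <- setdiff(c(response, all_terms), names(data))
  if (length(missing) > 0)
    stop("unknown column(s): ", paste(missing, collapse = ", "))
  sub <- data[, c(response, all_terms), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  y <- sub[[response]]
  n <- length(y)
  rows <- lapply(candidates, function(terms) {
    Xd <- cbind(1, as.matrix(sub[, terms, drop = FALSE]))
    fit <- stats::lm.fit(Xd, y)
    rss <- sum(fit$residuals^2)
    k <- length(terms)
    data.frame(model = paste(terms, collapse = " + "), k = k, n = n,
               rss = rss,
               aic = n * log(rss / n) + n * log(2 * pi) + n + 2 * (k + 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aic), , drop = FALSE]
  out$best <- seq_len(nrow(out)) == 1L
  rownames(out) <- NULL
  class(out) <- c("model_ladder", "data.frame")
  out
}
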