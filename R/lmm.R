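#' Random-intercept linear mixed model by profiled REML
#'
#' Fits `y ~ X + (1 | subject)` — the only random-effects structure used
#' anywhere in this pipeline — by direct profiling of the REML criterion over
#' the variance ratio `lambda = tau^2 / sigma^2`. For a single grouping
#' factor the marginal covariance is block diagonal and everything reduces to
#' per-group sufficient statistics, making one fit cheap enough for
#' thousand-cell mass screening. Fixed-effect tests are Type-III-style Wald F
#' tests under sum-to-zero contrasts with between-within denominator degrees
#' of freedom `n - p - (n_groups - 1)`.
#'
#' @param formula fixed-effects formula (e.g. `y ~ choice_type * feedback`);
#'   character predictors are converted to sum-coded factors
#' @param data data.frame with the model variables
#' @param subject grouping vector (random intercept), length `nrow(data)`
#' @param reml logical, REML (default) or ML
#' @return object of class `lmm_ri` with elements `beta`, `vcov`, `sigma2`,
#'   `tau2`, `lambda`, `fitted`, `ranef`, `ddf`, `assign`, `term_labels`,
#'   `xlevels`, `contrasts`, `singular`
#' @export
lmm_ri <- function(formula, data, subject, reml = TRUE) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  for (v in vars)
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  mf <- stats::model.frame(formula, data)
  fac <- names(mf)[vapply(mf, is.factor, logical(1))]
  ctr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  X <- stats::model.matrix(attr(mf, "terms"), mf,
                           contrasts.arg = if (length(fac)) ctr else NULL)
  y <- stats::model.response(mf)
  g <- factor(subject)
  fit <- .lmm_ri_fit(y, X, g, reml = reml)
  fit$assign <- attr(X, "assign")
  fit$term_labels <- attr(stats::terms(mf), "term.labels")
  fit$xlevels <- lapply(mf[fac], levels)
  fit$contrasts <- attr(X, "contrasts")
  fit$terms <- attr(mf, "terms")
  fit$coef_names <- colnames(X)
  fit$y <- y
  fit
}

# core fitter on a prebuilt design matrix
.lmm_ri_fit <- function(y, X, g, reml = TRUE) {
  n <- length(y); p <- ncol(X)
  if (nlevels(g) < 2) stop("need at least 2 subjects for a random intercept")
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)[, 1]
  yty <- sum(y * y)
  S <- rowsum(X, g)
  Tg <- rowsum(y, g)[, 1]
  nsz <- as.vector(table(g))
  stats_env <- list(XtX = XtX, Xty = Xty, yty = yty, S = S, Tg = Tg,
                    nsz = nsz, n = n, p = p)
  obj <- function(loglam) .lmm_ri_crit(exp(loglam), stats_env, reml)$crit
  opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-8)
  # compare against the boundary tau2 -> 0
  at0 <- .lmm_ri_crit(exp(-20), stats_env, reml)
  lam <- if (at0$crit < opt$objective) 0 else exp(opt$minimum)
  sol <- .lmm_ri_crit(max(lam, 1e-12), stats_env, reml, want_fit = TRUE)
  beta <- sol$beta
  names(beta) <- colnames(X)
  dfres <- if (reml) n - p else n
  sigma2 <- sol$rss / dfres
  vcov <- sigma2 * sol$Ainv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  fitted_marg <- as.vector(X %*% beta)
  resid_sum <- rowsum(y - fitted_marg, g)[, 1]
  u <- lam * resid_sum / (1 + lam * nsz)
  structure(list(beta = beta, vcov = vcov, sigma2 = sigma2,
                 tau2 = lam * sigma2, lambda = lam,
                 fitted = fitted_marg + u[as.integer(g)],
                 fitted_marginal = fitted_marg,
                 ranef = stats::setNames(u, levels(g)),
                 group = g, n = n, p = p,
                 ddf = n - p - (nlevels(g) - 1L),
                 reml = reml, singular = lam <= 0),
            class = "lmm_ri")
}

# profiled criterion at a given lambda; optionally return beta/vcov pieces
.lmm_ri_crit <- function(lam, st, reml, want_fit = FALSE) {
  cvec <- lam / (1 + lam * st$nsz)
  A <- st$XtX - crossprod(st$S, st$S * cvec)
  b <- st$Xty - crossprod(st$S, cvec * st$Tg)[, 1]
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf, beta = NULL))
  cb <- backsolve(ch, b, transpose = TRUE)
  yVy <- st$yty - sum(cvec * st$Tg^2)
  rss <- max(yVy - sum(cb * cb), 1e-300)
  logdetV <- sum(log1p(lam * st$nsz))
  crit <- if (reml)
    (st$n - st$p) * log(rss) + logdetV + 2 * sum(log(diag(ch)))
  else st$n * log(rss) + logdetV
  if (!want_fit) return(list(crit = crit))
  beta <- backsolve(ch, cb)
  list(crit = crit, beta = beta, rss = rss, Ainv = chol2inv(ch))
}

#' Type-III-style Wald F tests for an `lmm_ri` fit
#'
#' Each model term's coefficient block is tested jointly against zero using
#' the REML fixed-effect covariance; with sum-to-zero contrasts this matches
#' the usual Type-III analysis. Denominator df use the between-within
#' approximation stored in the fit.
#'
#' @param fit an [lmm_ri()] object
#' @return data.frame: `term`, `F`, `df1`, `df2`, `p`
#' @export
anova_lmm <- function(fit) {
  stopifnot(inherits(fit, "lmm_ri"))
  labs <- fit$term_labels
  out <- data.frame(term = labs, F = NA_real_, df1 = NA_integer_,
                    df2 = fit$ddf, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(labs)) {
    idx <- which(fit$assign == i)
    bi <- fit$beta[idx]
    vi <- fit$vcov[idx, idx, drop = FALSE]
    Fv <- tryCatch(
      drop(t(bi) %*% solve(vi, bi)) / length(idx),
      error = function(e) NA_real_)
    out$F[i] <- Fv
    out$df1[i] <- length(idx)
    out$p[i] <- stats::pf(Fv, length(idx), fit$ddf, lower.tail = FALSE)
  }
  out
}

#' Estimated marginal means from an `lmm_ri` fit
#'
#' Cell predictions on a reference grid of all factor-level combinations
#' (continuous covariates held at their observed mean), averaged with equal
#' weights over the factors not named in `margin` — the usual EMM
#' construction.
#'
#' @param fit an [lmm_ri()] fit of a model containing at least one factor
#' @param margin character vector of factor names to retain
#' @param data the data the model was fitted on (for covariate means)
#' @return list: `grid` (data.frame of margin levels), `emm`, `vcov`, `L`
#' @export
emm_lmm <- function(fit, margin, data) {
  stopifnot(inherits(fit, "lmm_ri"), length(fit$xlevels) >= 1,
            all(margin %in% names(fit$xlevels)))
  grid <- expand.grid(fit$xlevels, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = TRUE)
  tl <- stats::delete.response(fit$terms)
  covs <- setdiff(all.vars(tl), names(fit$xlevels))
  for (v in covs) grid[[v]] <- mean(as.data.frame(data)[[v]], na.rm = TRUE)
  Xg <- stats::model.matrix(tl, grid, contrasts.arg = fit$contrasts)
  combo <- interaction(grid[margin], drop = FALSE, lex.order = TRUE)
  L <- t(vapply(levels(combo), function(lv) {
    colMeans(Xg[combo == lv, , drop = FALSE])
  }, numeric(ncol(Xg))))
  emm <- as.vector(L %*% fit$beta)
  vc <- L %*% fit$vcov %*% t(L)
  mg <- unique(grid[order(combo), margin, drop = FALSE])
  rownames(mg) <- NULL
  list(grid = mg, levels = levels(combo), emm = emm, vcov = vc, L = L)
}

#' Tukey HSD contrasts on estimated marginal means
#'
#' All pairwise differences between the EMMs of `margin`, with standard
#' errors from the fixed-effect covariance and p-values from the studentized
#' range distribution (`ptukey`) over the family of `k` means — the Tukey
#' honestly-significant-difference adjustment.
#'
#' @param fit an [lmm_ri()] fit
#' @param margin factor name(s) defining the family of means
#' @param data the model data (for covariate means)
#' @return data.frame of class `contrast_table`: `lhs`, `rhs`, `estimate`,
#'   `se`, `t`, `df`, `p_tukey`, plus attribute `emm`
#' @export
tukey_lmm <- function(fit, margin, data) {
  e <- emm_lmm(fit, margin, data)
  k <- length(e$emm)
  pr <- utils::combn(k, 2)
  est <- e$emm[pr[1, ]] - e$emm[pr[2, ]]
  se <- sqrt(e$vcov[cbind(pr[1, ], pr[1, ])] +
               e$vcov[cbind(pr[2, ], pr[2, ])] -
               2 * e$vcov[cbind(pr[1, ], pr[2, ])])
  tv <- est / se
  p <- stats::ptukey(sqrt(2) * abs(tv), nmeans = k, df = fit$ddf,
                     lower.tail = FALSE)
  out <- data.frame(lhs = e$levels[pr[1, ]], rhs = e$levels[pr[2, ]],
                    estimate = est, se = se, t = tv, df = fit$ddf,
                    p_tukey = p, stringsAsFactors = FALSE)
  attr(out, "emm") <- stats::setNames(e$emm, e$levels)
  class(out) <- c("contrast_table", class(out))
  out
}

#' Mass-univariate screening fits over a grid of cells
#'
#' Fits the screening model `value ~ choice_type * feedback + (1 | subject)`
#' independently in every column of `Y` (one column per frame x sensor cell)
#' and returns omnibus p-values for the two main effects and the
#' interaction. Shares the design-side sufficient statistics across cells so
#' the whole 17 x 102 grid fits in seconds. Cells whose fit fails (e.g.
#' rank deficiency) get `p = 1` and a diagnostic flag — never silently
#' dropped.
#'
#' @param Y numeric matrix, trials x cells, of frame-averaged dB values
#' @param labels data.frame with `choice_type`, `feedback`, `subject_id`
#'   (one row per trial, aligned with `Y` rows)
#' @return list: `p` (cells x 3 matrix, columns `choice_type`, `feedback`,
#'   `interaction`), `failed` (logical per cell)
#' @export
lmm_grid_screen <- function(Y, labels) {
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(labels))
  ct <- factor(labels$choice_type, levels = c("HP", "pre-LP", "LP", "post-LP"))
  fb <- factor(labels$feedback, levels = c("gain", "loss"))
  g <- factor(labels$subject_id)
  if (nlevels(g) < 2) stop("need at least 2 subjects")
  if (any(table(ct, fb) == 0))
    stop("empty choice_type x feedback cell in the pooled design")
  X <- stats::model.matrix(~ ct * fb, contrasts.arg =
                             list(ct = "contr.sum", fb = "contr.sum"))
  asgn <- attr(X, "assign")
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  S <- rowsum(X, g)
  nsz <- as.vector(table(g))
  XtY <- crossprod(X, Y)            # p x m
  TY <- rowsum(Y, g)                # n_g x m
  yty <- colSums(Y * Y)
  ddf <- n - p - (nlevels(g) - 1L)
  m <- ncol(Y)
  pmat <- matrix(1, m, 3,
                 dimnames = list(NULL, c("choice_type", "feedback",
                                         "interaction")))
  failed <- logical(m)
  term_idx <- lapply(1:3, function(i) which(asgn == i))
  for (j in seq_len(m)) {
    st <- list(XtX = XtX, Xty = XtY[, j], yty = yty[j], S = S, Tg = TY[, j],
               nsz = nsz, n = n, p = p)
    res <- tryCatch({
      obj <- function(loglam) .lmm_ri_crit(exp(loglam), st, TRUE)$crit
      opt <- stats::optimize(obj, interval = c(-14, 14), tol = 1e-7)
      at0 <- .lmm_ri_crit(exp(-20), st, TRUE)$crit
      lam <- if (at0 < opt$objective) 1e-12 else exp(opt$minimum)
      sol <- .lmm_ri_crit(lam, st, TRUE, want_fit = TRUE)
      if (is.null(sol$beta)) stop("singular")
      sigma2 <- sol$rss / (n - p)
      vc <- sigma2 * sol$Ainv
      vapply(term_idx, function(idx) {
        bi <- sol$beta[idx]
        Fv <- drop(t(bi) %*% solve(vc[idx, idx, drop = FALSE], bi)) /
          length(idx)
        stats::pf(Fv, length(idx), ddf, lower.tail = FALSE)
      }, numeric(1))
    }, error = function(e) NULL)
    if (is.null(res)) failed[j] <- TRUE else pmat[j, ] <- res
  }
  list(p = pmat, failed = failed, ddf = ddf)
}
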