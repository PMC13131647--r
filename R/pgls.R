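#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits the linear model `y = X b + e` with `e ~ N(0, sigma2 * C)`, where `C`
#' is the Brownian-motion phylogenetic covariance matrix (shared root-to-MRCA
#' path lengths), correcting for the non-independence of species trait
#' values. With `tree` and `vcv` both `NULL` the covariance is the identity
#' and the fit is ordinary least squares — the uncorrected baseline.
#'
#' The estimator is closed-form generalized least squares:
#' `b = (X' C^-1 X)^-1 X' C^-1 y`, residual variance
#' `s2 = (y - Xb)' C^-1 (y - Xb) / (n - p)`, standard errors from
#' `s2 * diag((X' C^-1 X)^-1)`, and two-sided p-values from the t
#' distribution with `n - p` degrees of freedom. Internally the model is
#' whitened through the Cholesky factor of `C`, so no explicit inverse is
#' formed.
#'
#' @param formula Model formula, e.g. `log10_lifespan ~ site_density`.
#'   Logical predictors are encoded 0/1 by the model matrix.
#' @param data A `data.frame` with one row per species. Species are
#'   identified by the `species` column name (default `"species_id"`) or,
#'   failing that, by row names.
#' @param tree An [ape::phylo] object covering all species in `data`; its
#'   Brownian covariance is computed with [brownian_vcv()]. Ignored if `vcv`
#'   is supplied.
#' @param vcv Optional precomputed covariance matrix with species dim names
#'   (rows of `data` are matched to it by name).
#' @param species Name of the species-id column in `data`.
#' @param ridge If the Cholesky factorization of `C` fails, `ridge *
#'   mean(diag(C))` is added to the diagonal (once) with a message; set to 0
#'   to disable.
#' @return An object of class `pgls` with components `coefficients`, `se`,
#'   `tstat`, `pvalue`, `sigma2`, `df.residual`, `n`, `model` (`"PGLS"` or
#'   `"OLS"`), `fitted.values`, `residuals` (response scale), `vcov_unscaled`
#'   (`(X' C^-1 X)^-1`), `C`, `taxa`, `formula`, `terms`, `call`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' d <- data.frame(species_id = c("A", "B", "C"),
#'                 y = c(1, 2, 4), x = c(0.5, 1, 2))
#' fit <- pgls(y ~ x, d, tree = tr)
#' summary(fit)
#' @seealso [ols()], [lifespan_screen()], [brownian_vcv()]
#' @export
pgls <- function(formula, data, tree = NULL, vcv = NULL,
                 species = "species_id", ridge = 1e-8) {
  cl <- match.call()
  stopifnot(is.data.frame(data))
  taxa <- if (species %in% names(data)) as.character(data[[species]])
          else rownames(data)
  if (anyDuplicated(taxa)) stop("duplicate species in data")
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more species (", n, ") than coefficients (", p, ")")

  if (!is.null(vcv)) {
    if (is.null(dimnames(vcv)[[1]]))
      stop("vcv needs species names as dim names")
    if (!all(taxa %in% rownames(vcv)))
      stop("species missing from vcv: ",
           paste(setdiff(taxa, rownames(vcv)), collapse = ", "))
    C <- vcv[taxa, taxa, drop = FALSE]
    model <- "PGLS"
  } else if (!is.null(tree)) {
    if (!all(taxa %in% tree$tip.label))
      stop("species missing from tree: ",
           paste(setdiff(taxa, tree$tip.label), collapse = ", "))
    C <- brownian_vcv(tree, taxa)
    model <- "PGLS"
  } else {
    C <- diag(n)
    dimnames(C) <- list(taxa, taxa)
    model <- "OLS"
  }

  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U)) {
    if (ridge <= 0) stop("covariance matrix is not positive definite")
    message("pgls: covariance matrix singular; adding ridge of ",
            format(ridge), " * mean(diag(C))")
    C <- C + diag(ridge * mean(diag(C)), n)
    U <- chol(C)
  }
  # whiten: C = U'U  =>  solve(t(U)) maps e ~ N(0, s2 C) to iid
  ystar <- backsolve(U, y, transpose = TRUE)
  Xstar <- backsolve(U, X, transpose = TRUE)
  colnames(Xstar) <- colnames(X)
  qrX <- qr(Xstar)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("collinear predictors (X' C^-1 X singular): ",
         paste(aliased, collapse = ", "))
  }
  beta <- stats::setNames(qr.coef(qrX, ystar), colnames(X))
  rss <- sum(qr.resid(qrX, ystar)^2)
  df <- n - p
  sigma2 <- rss / df
  unpiv <- order(qrX$pivot)
  XtX_inv <- chol2inv(qr.R(qrX))[unpiv, unpiv, drop = FALSE]
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  fitted <- drop(X %*% beta)
  structure(list(
    coefficients = beta, se = se, tstat = tstat, pvalue = pval,
    sigma2 = sigma2, df.residual = df, n = n, model = model,
    fitted.values = stats::setNames(fitted, taxa),
    residuals = stats::setNames(y - fitted, taxa),
    vcov_unscaled = XtX_inv, C = C, chol_C = U, taxa = taxa,
    formula = formula, terms = attr(mf, "terms"), call = cl),
    class = "pgls")
}

#' Ordinary least squares baseline
#'
#' Convenience wrapper: [pgls()] with an identity covariance (`model` tag
#' `"OLS"`). On an ultrametric star phylogeny PGLS reduces to this exactly.
#'
#' @inheritParams pgls
#' @return A `pgls` object with `model = "OLS"`.
#' @export
ols <- function(formula, data, species = "species_id") {
  out <- pgls(formula, data, tree = NULL, vcv = NULL, species = species)
  out$call <- match.call()
  out
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat(x$model, "fit:", deparse(x$formula), "\n")
  cat("n =", x$n, " residual df =", x$df.residual,
      " sigma2 =", format(x$sigma2, digits = digits), "\n")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$tstat,
               `Pr(>|t|)` = object$pvalue)
  structure(list(call = object$call, model = object$model,
                 formula = object$formula, coefficients = tab,
                 sigma2 = object$sigma2, df.residual = object$df.residual,
                 n = object$n),
            class = "summary.pgls")
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat(x$model, "regression:", deparse(x$formula), "\n")
  cat("n =", x$n, ", residual df =", x$df.residual, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat("\nResidual variance (sigma2):", format(x$sigma2, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$sigma2 * object$vcov_unscaled

#' @export
nobs.pgls <- function(object, ...) object$n

#' @export
fitted.pgls <- function(object, ...) object$fitted.values

#' @export
confint.pgls <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, object$df.residual)
  out <- cbind(cf[parm] - q * object$se[parm], cf[parm] + q * object$se[parm])
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  out
}

#' Residuals of a PGLS fit
#'
#' @param object A `pgls` fit.
#' @param type `"response"` for raw residuals `y - Xb`; `"normalized"` for
#'   phylogenetically whitened residuals `L^-1 (y - Xb) / s` which are
#'   approximately iid standard normal under the model.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  r <- object$residuals
  if (type == "response") return(r)
  stats::setNames(
    drop(backsolve(object$chol_C, r, transpose = TRUE)) / sqrt(object$sigma2),
    object$taxa)
}

#' Predict from a PGLS fit
#'
#' Population-level prediction `X b` for new predictor values (no
#' phylogenetic conditioning on observed residuals).
#'
#' @param object A `pgls` fit.
#' @param newdata Optional `data.frame` of predictors; default returns fitted
#'   values.
#' @param se.fit Also return standard errors of the linear predictor.
#' @param ... Unused.
#' @return Numeric vector, or a list with `fit` and `se.fit`.
#' @export
predict.pgls <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  if (is.null(newdata)) {
    if (se.fit) stop("se.fit requires newdata")
    return(object$fitted.values)
  }
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  fit <- drop(X %*% object$coefficients)
  if (!se.fit) return(fit)
  se <- sqrt(rowSums((X %*% vcov(object)) * X))
  list(fit = fit, se.fit = se)
}

#' Simulate responses from a fitted PGLS model
#'
#' Draws `y* ~ N(X b, s2 C)` using the stored Cholesky factor, the parametric
#' bootstrap under the fitted Brownian model.
#'
#' @param object A `pgls` fit.
#' @param nsim Number of response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A `data.frame` with `nsim` columns, rows named by species.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  Z <- matrix(stats::rnorm(n * nsim), n, nsim)
  sims <- object$fitted.values +
    sqrt(object$sigma2) * crossprod(object$chol_C, Z)
  out <- as.data.frame(sims, row.names = object$taxa)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot for a PGLS fit
#'
#' Normalized (whitened) residuals against fitted values; under a correct
#' Brownian model these should look like iid standard normal noise.
#'
#' @param x A `pgls` fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot.pgls <- function(x, ...) {
  graphics::plot(x$fitted.values, residuals(x, type = "normalized"),
                 xlab = "fitted values", ylab = "normalized residuals",
                 main = paste(x$model, "residual diagnostic"), ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(NULL)
}

#' @export
logLik.pgls <- function(object, ...) {
  n <- object$n
  # ML variance (not the df-corrected one) for the Gaussian log-likelihood
  r <- backsolve(object$chol_C, object$residuals, transpose = TRUE)
  s2_ml <- sum(r^2) / n
  ldetC <- 2 * sum(log(diag(object$chol_C)))
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + ldetC + n)
  structure(ll, df = length(object$coefficients) + 1L, nobs = n,
            class = "logLik")
}

#' Screen sequence features against lifespan, one predictor at a time
#'
#' Regresses the (optionally log10-transformed) maximum lifespan on each
#' named sequence feature separately — the features are screened
#' individually, not jointly — under both the phylogenetically corrected
#' model (PGLS) and the uncorrected OLS baseline. A joint fit over all
#' predictors is available via `joint = TRUE`.
#'
#' @param traits `data.frame` with `species_id`, a lifespan column, and the
#'   feature columns.
#' @param tree Phylogeny covering the species (already matched; use
#'   [prune_and_match()] first).
#' @param predictors Character vector of feature column names.
#' @param response Name of the response column (default
#'   `"max_lifespan_years"`).
#' @param log10_response Apply log10 to the response first (default `TRUE`;
#'   lifespans must then be positive).
#' @param models Which models to fit.
#' @param joint If `TRUE`, fit all predictors jointly in a single model
#'   instead of one at a time.
#' @return `data.frame` with columns `predictor`, `beta`, `se`, `t`, `p`,
#'   `n`, `model` (slope rows only; intercepts are not reported).
#' @export
lifespan_screen <- function(traits, tree, predictors,
                            response = "max_lifespan_years",
                            log10_response = TRUE,
                            models = c("PGLS", "OLS"),
                            joint = FALSE) {
  stopifnot(is.data.frame(traits), "species_id" %in% names(traits))
  missing_cols <- setdiff(c(response, predictors), names(traits))
  if (length(missing_cols))
    stop("trait table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  models <- match.arg(models, several.ok = TRUE)
  d <- traits
  if (log10_response) {
    if (any(d[[response]] <= 0))
      stop("response must be positive for log10 transform")
    d$.y <- log10(d[[response]])
  } else d$.y <- d[[response]]
  # booleans are encoded 0/1 so coefficients keep the plain predictor name
  for (p in predictors) if (is.logical(d[[p]])) d[[p]] <- as.numeric(d[[p]])
  vcv <- if ("PGLS" %in% models) brownian_vcv(tree, d$species_id) else NULL
  pred_sets <- if (joint) list(predictors) else as.list(predictors)
  rows <- list()
  for (ps in pred_sets) {
    fml <- stats::reformulate(ps, response = ".y")
    for (m in models) {
      fit <- tryCatch(
        if (m == "PGLS") pgls(fml, d, vcv = vcv) else ols(fml, d),
        error = function(e) e)
      if (inherits(fit, "error")) {
        # e.g. a constant predictor (no variation in this species set)
        warning("lifespan_screen: ", paste(ps, collapse = "+"), " [", m,
                "]: ", conditionMessage(fit))
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = paste(ps, collapse = "+"), beta = NA_real_,
          se = NA_real_, t = NA_real_, p = NA_real_, n = nrow(d), model = m)
        next
      }
      keep <- setdiff(names(stats::coef(fit)), "(Intercept)")
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = keep,
        beta = unname(fit$coefficients[keep]),
        se = unname(fit$se[keep]),
        t = unname(fit$tstat[keep]),
        p = unname(fit$pvalue[keep]),
        n = fit$n, model = m)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-predictor regression results as TSV
#'
#' @param results Result of [lifespan_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regression_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
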