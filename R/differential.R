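#' Specify a two-group contrast with covariate adjustment
#'
#' @param name label for the contrast
#' @param group_a,group_b group labels; the reported log2 fold change is
#'   `group_a - group_b`
#' @param covariates character vector of covariate column names in the sample
#'   metadata (numeric or 0/1 indicators), e.g. `c("age", "pmi", "sex",
#'   "apoe4", "lewy", "log2_ptau")`
#' @return an object of class `ContrastSpec`
#' @export
contrast_spec <- function(name, group_a, group_b, covariates = character(0)) {
  if (identical(group_a, group_b)) stop("groups must differ")
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 covariates = covariates), class = "ContrastSpec")
}

#' Per-protein covariate-adjusted differential abundance
#'
#' Fits, for every protein entry, an ordinary least-squares model
#' `value ~ group + covariates` on the subjects of the two contrast groups
#' with present values (complete-case per protein). The group coefficient is
#' the model-based log2 fold change (`group_a - group_b`). With
#' `moderate = TRUE`, residual variances are shrunk toward a common prior by
#' empirical-Bayes moderation: the prior degrees of freedom and prior
#' variance are estimated from the distribution of residual variances by
#' moment matching on the log scale, the posterior variance is the
#' df-weighted combination of observed and prior variance, and t statistics
#' and degrees of freedom are adjusted accordingly. P-values are two-sided;
#' Benjamini-Hochberg adjustment is applied across proteins.
#'
#' @param pm a `ProteinMatrix`
#' @param meta sample metadata with columns `sample`, `group`, and any
#'   covariates named in `spec`
#' @param spec a `ContrastSpec`
#' @param moderate apply empirical-Bayes variance moderation (default TRUE)
#' @return a `DifferentialResult`: data.frame with columns `protein`,
#'   `log2fc`, `se`, `t`, `df`, `p`, `p_adj`; attributes `contrast`, `n_a`,
#'   `n_b`, `df_prior`, `var_prior`. Proteins whose design is rank-deficient
#'   on their non-missing subjects are reported with missing statistics.
#' @export
fit_contrast <- function(pm, meta, spec, moderate = TRUE) {
  stopifnot(inherits(pm, "ProteinMatrix"), inherits(spec, "ContrastSpec"))
  miss_cov <- setdiff(spec$covariates, names(meta))
  if (length(miss_cov))
    stop("covariates not in metadata: ", paste(miss_cov, collapse = ", "))
  meta <- meta[meta$group %in% c(spec$group_a, spec$group_b), , drop = FALSE]
  meta <- meta[meta$sample %in% colnames(pm$values), , drop = FALSE]
  n_a <- sum(meta$group == spec$group_a)
  n_b <- sum(meta$group == spec$group_b)
  if (n_a < 2 || n_b < 2) stop("need at least 2 subjects per group")

  Y <- pm$values[, meta$sample, drop = FALSE]
  grp <- as.numeric(meta$group == spec$group_a)
  X <- cbind(`(Intercept)` = 1, group = grp)
  for (cv in spec$covariates) {
    v <- meta[[cv]]
    if (!is.numeric(v)) stop("covariate ", cv, " must be numeric")
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  p <- ncol(X)
  nprot <- nrow(Y)
  beta <- se_unit <- s2 <- df_res <- rep(NA_real_, nprot)
  failed <- logical(nprot)

  complete <- rowSums(is.na(Y)) == 0
  if (any(complete)) {
    if (qr(X)$rank < p) {
      failed[complete] <- TRUE
    } else {
      xtxi <- chol2inv(chol(crossprod(X)))
      B <- Y[complete, , drop = FALSE] %*% X %*% xtxi
      fitted <- B %*% t(X)
      res <- Y[complete, , drop = FALSE] - fitted
      beta[complete] <- B[, 2]
      df_res[complete] <- nrow(X) - p
      s2[complete] <- rowSums(res^2) / (nrow(X) - p)
      se_unit[complete] <- sqrt(xtxi[2, 2])
    }
  }
  for (i in which(!complete)) {
    obs <- !is.na(Y[i, ])
    Xi <- X[obs, , drop = FALSE]
    if (sum(obs) <= p || qr(Xi)$rank < p) { failed[i] <- TRUE; next }
    fit <- lm.fit(Xi, Y[i, obs])
    beta[i] <- fit$coefficients[2]
    df_res[i] <- sum(obs) - p
    s2[i] <- sum(fit$residuals^2) / df_res[i]
    se_unit[i] <- sqrt(chol2inv(chol(crossprod(Xi)))[2, 2])
  }

  ok <- !failed & is.finite(s2) & df_res > 0
  if (moderate && sum(ok) >= 2) {
    sq <- squeeze_var(s2[ok], df_res[ok])
    var_post <- s2
    var_post[ok] <- sq$var_post
    df_total <- df_res
    df_total[ok] <- df_res[ok] + sq$df_prior
    df_prior <- sq$df_prior
    var_prior <- sq$var_prior
  } else {
    var_post <- s2
    df_total <- df_res
    df_prior <- 0
    var_prior <- NA_real_
  }
  se <- se_unit * sqrt(var_post)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df_total)
  padj <- p.adjust(pval, method = "BH")
  out <- data.frame(protein = rownames(Y), log2fc = beta, se = se, t = tstat,
                    df = df_total, p = pval, p_adj = padj,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("DifferentialResult", "data.frame"),
            contrast = spec$name, n_a = n_a, n_b = n_b,
            df_prior = df_prior, var_prior = var_prior)
}

#' Empirical-Bayes squeezing of residual variances
#'
#' Shrinks observed residual variances toward a common prior estimated from
#' their distribution. On the hierarchical model `s2 | sigma2 ~ sigma2 *
#' chisq(df)/df`, `sigma2 ~ var_prior * df_prior / chisq(df_prior)`, the
#' prior parameters are estimated by matching the mean and variance of
#' `log(s2)` (method of moments via digamma/trigamma), and the posterior
#' variance is `(df * s2 + df_prior * var_prior) / (df + df_prior)`. When the
#' observed variances show no excess spread the prior degrees of freedom are
#' infinite and every posterior variance equals the common mean variance.
#'
#' @param s2 vector of residual variances (positive)
#' @param df residual degrees of freedom (scalar or vector)
#' @return list with `var_post`, `df_prior`, `var_prior`
#' @export
squeeze_var <- function(s2, df) {
  if (length(df) == 1) df <- rep(df, length(s2))
  if (any(!is.finite(s2) | s2 <= 0) || any(df <= 0))
    stop("variances must be positive with positive df")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    df_prior <- Inf
    var_prior <- mean(s2)
    var_post <- rep(var_prior, length(s2))
  } else {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df * s2 + df_prior * var_prior) / (df + df_prior)
  }
  list(var_post = var_post, df_prior = df_prior, var_prior = var_prior)
}

# Solve trigamma(y) = x by Newton iteration on the monotone decreasing
# trigamma function; accurate to ~1e-8 over the useful range.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' One-sample test of a global shift in fold changes
#'
#' Two-sided one-sample t-test of the per-protein log2 fold-change vector
#' against mean zero, quantifying a coordinated shift of the whole proteome;
#' degrees of freedom are the number of finite fold changes minus one.
#'
#' @param result a `DifferentialResult` or a numeric vector of log2 fold
#'   changes
#' @return list with elements `t`, `df`, `p`
#' @export
global_shift_test <- function(result) {
  fc <- if (is.data.frame(result)) result$log2fc else result
  fc <- fc[is.finite(fc)]
  if (length(fc) < 2) stop("need at least 2 finite fold changes")
  if (sd(fc) == 0) stop("zero variance in fold changes")
  tt <- t.test(fc, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Differentially expressed protein set at a p-value threshold
#'
#' @param result a `DifferentialResult`
#' @param alpha p-value threshold (default 0.05)
#' @param adjusted threshold the BH-adjusted p instead of the raw p
#' @return character vector of protein ids with attribute `"n"`
#' @export
de_set <- function(result, alpha = 0.05, adjusted = FALSE) {
  p <- if (adjusted) result$p_adj else result$p
  sel <- !is.na(p) & p < alpha
  out <- result$protein[sel]
  attr(out, "n") <- sum(sel)
  out
}
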