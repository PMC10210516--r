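# Group-comparison layer: log-link gamma (or gaussian) regressions with
# treatment x covariate interactions, likelihood-ratio tests, estimated
# marginal means at exact target covariate values, multivariate-t
# multiplicity adjustment, and percent-difference summaries.
#
# Repeated measures within a sample (e.g. three strain steps per scleral
# button) are handled with a cluster-robust covariance for the GLM rather
# than a full random-effects fit; on balanced one-observation-per-animal
# designs the two coincide in their point estimates.

#' Fit a group-comparison model
#'
#' Fits a generalized linear model for one outcome with treatment, an
#' optional covariate and their interaction. Family is gamma with log link
#' (strictly positive outcomes: moduli, conductivity, lengths) or gaussian
#' with identity link (outcomes that can be negative, e.g. refractive
#' error).
#'
#' @param data Data frame with at least the outcome column and `treatment`.
#' @param outcome Name of the outcome column.
#' @param covariate Optional name of a numeric/factor covariate (strain
#'   percent, timepoint); interacts with treatment when `interaction = TRUE`.
#' @param family `"gamma"` (log link) or `"gaussian"`.
#' @param interaction Include treatment:covariate interaction. Default TRUE
#'   when a covariate is given.
#' @param extra_covariates Character vector of additional additive
#'   covariates (e.g. centered age deviation).
#' @param cluster Optional name of a clustering column (e.g. `sample_id`);
#'   when given, a cluster-robust (CR0 with G/(G-1) correction) covariance
#'   is attached and used by downstream contrasts.
#' @param rhs Optional explicit right-hand side of the model formula
#'   (character), overriding the `covariate`/`interaction` construction.
#'   Used to build the null models of [likelihood_ratio_test()], e.g.
#'   `rhs = "1"` for an intercept-only null.
#'
#' @return An object of class `sf_model`: list with the `glm` fit, `vcov`,
#'   family label and metadata.
#' @export
fit_model <- function(data, outcome, covariate = NULL,
                      family = c("gamma", "gaussian"),
                      interaction = !is.null(covariate),
                      extra_covariates = character(),
                      cluster = NULL, rhs = NULL) {
  family <- match.arg(family)
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome)
  y <- data[[outcome]]
  if (family == "gamma" && any(y <= 0, na.rm = TRUE)) {
    bad <- which(y <= 0)
    stop("gamma family requires strictly positive outcomes; offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (is.null(rhs)) {
    if (!"treatment" %in% names(data)) stop("data needs a treatment column")
    if (length(unique(data$treatment)) < 2L) stop("need >= 2 treatment levels")
    rhs <- "treatment"
    if (!is.null(covariate)) {
      rhs <- if (interaction) paste0("treatment * ", covariate) else
        paste0("treatment + ", covariate)
    }
    if (length(extra_covariates)) {
      rhs <- paste(c(rhs, extra_covariates), collapse = " + ")
    }
  } else if (grepl("treatment", rhs) &&
             length(unique(data$treatment)) < 2L) {
    stop("need >= 2 treatment levels")
  }
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fam <- if (family == "gamma") stats::Gamma(link = "log") else stats::gaussian()
  fit <- stats::glm(fml, family = fam, data = data)
  if (!fit$converged) stop("GLM did not converge (possible separation/singularity)")
  if (any(is.na(stats::coef(fit)))) stop("singular model matrix (aliased coefficients)")
  V <- if (is.null(cluster)) stats::vcov(fit) else
    cluster_robust_vcov(fit, data[[cluster]])
  structure(list(
    glm = fit, vcov = V, family = family, outcome = outcome,
    covariate = covariate, cluster = !is.null(cluster),
    formula = fml
  ), class = "sf_model")
}

# CR0 cluster-robust covariance with a G/(G-1) small-sample factor.
cluster_robust_vcov <- function(fit, cluster_id) {
  X <- stats::model.matrix(fit)
  if (length(cluster_id) != nrow(X)) {
    stop("cluster column length does not match the fitted rows (NAs in data?)")
  }
  wres <- stats::residuals(fit, type = "working") * fit$weights
  disp <- summary(fit)$dispersion
  scores <- X * wres / disp
  G <- length(unique(cluster_id))
  bread <- stats::vcov(fit)
  meat <- crossprod(rowsum(scores, cluster_id))
  V <- bread %*% meat %*% bread * G / (G - 1)
  dimnames(V) <- dimnames(bread)
  V
}

#' Likelihood-ratio test between nested models
#'
#' Twice the log-likelihood difference between a full and a nested null
#' model, referred to a chi-square distribution with degrees of freedom
#' equal to the difference in parameter count.
#'
#' @param full,null `sf_model` objects (null nested in full).
#' @return A data frame with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, null) {
  stopifnot(inherits(full, "sf_model"), inherits(null, "sf_model"))
  tf <- attr(stats::terms(full$glm), "term.labels")
  tn <- attr(stats::terms(null$glm), "term.labels")
  if (!all(tn %in% tf)) stop("null model is not nested in the full model")
  df <- length(stats::coef(full$glm)) - length(stats::coef(null$glm))
  if (df < 0) stop("null model has more parameters than the full model")
  stat <- max(0, 2 * (as.numeric(stats::logLik(full$glm)) -
                        as.numeric(stats::logLik(null$glm))))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  data.frame(statistic = stat, df = df, p = p)
}

#' Estimated marginal means and group contrasts at fixed covariate values
#'
#' Model-based group means on the response scale, evaluated at exact target
#' covariate values (e.g. strains 0/5/10/15%), with delta-method standard
#' errors, and treated-minus-control contrasts at each value. Requesting a
#' covariate value outside the observed range (e.g. 0% strain) is an
#' extrapolation and is flagged.
#'
#' @param model An `sf_model` from [fit_model()].
#' @param at Numeric vector of covariate values (ignored if the model has no
#'   covariate).
#' @param control Reference treatment level. Default `"Ctrl"`.
#'
#' @return A list with `emm` (treatment x at grid: mean, se, extrapolated),
#'   `contrasts` (at, estimate, se, t, df, p raw) and `vcov` (covariance of
#'   the contrast estimates, used for multiplicity adjustment).
#' @export
emm_at <- function(model, at = NULL, control = "Ctrl") {
  stopifnot(inherits(model, "sf_model"))
  fit <- model$glm
  mf <- stats::model.frame(fit)
  trt <- mf$treatment
  levs <- if (is.factor(trt)) levels(trt) else sort(unique(trt))
  if (!control %in% levs) stop("control level not found: ", control)
  others <- setdiff(levs, control)

  has_cov <- !is.null(model$covariate)
  if (has_cov && is.null(at)) stop("covariate values `at` required")
  if (!has_cov) at <- NA_real_
  cov_obs <- if (has_cov) range(mf[[model$covariate]]) else c(NA, NA)

  grid <- expand.grid(treatment = levs, at = at, stringsAsFactors = FALSE)
  newdata <- data.frame(treatment = factor(grid$treatment, levels = levs))
  if (has_cov) newdata[[model$covariate]] <- grid$at
  # hold any extra covariates at their mean
  for (v in setdiff(all.vars(stats::delete.response(stats::terms(fit))),
                    c("treatment", model$covariate))) {
    newdata[[v]] <- mean(mf[[v]])
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), newdata,
                           xlev = fit$xlevels)
  beta <- stats::coef(fit)
  eta <- drop(X %*% beta)
  linkinv <- fit$family$linkinv
  mu_eta <- fit$family$mu.eta
  mu <- linkinv(eta)
  # delta method on the response scale: grad = mu.eta(eta) * x
  Gmat <- X * mu_eta(eta)
  V_mu <- Gmat %*% model$vcov %*% t(Gmat)
  emm <- data.frame(
    treatment = grid$treatment, at = grid$at, mean = mu,
    se = sqrt(pmax(diag(V_mu), 0)),
    extrapolated = has_cov & (grid$at < cov_obs[1L] | grid$at > cov_obs[2L])
  )

  # contrasts: other - control at each covariate value
  cons <- list(); Cmat <- NULL
  for (a in at) {
    for (o in others) {
      i_o <- which(grid$treatment == o & (is.na(a) | grid$at == a))
      i_c <- which(grid$treatment == control & (is.na(a) | grid$at == a))
      cvec <- rep(0, nrow(grid)); cvec[i_o] <- 1; cvec[i_c] <- -1
      Cmat <- rbind(Cmat, cvec)
      cons[[length(cons) + 1L]] <- data.frame(
        contrast = paste(o, "-", control), at = a)
    }
  }
  cons <- do.call(rbind, cons)
  est <- drop(Cmat %*% mu)
  Vc <- Cmat %*% V_mu %*% t(Cmat)
  se <- sqrt(pmax(diag(Vc), 0))
  df <- stats::df.residual(fit)
  tstat <- est / se
  cons$estimate <- est
  cons$se <- se
  cons$t <- tstat
  cons$df <- df
  cons$p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(emm = emm, contrasts = cons, vcov = Vc)
}

#' Multiplicity adjustment by the multivariate-t (max-|t|) method
#'
#' Family-wise adjusted p values for a set of correlated contrasts:
#' `p_adj_i = P(max_j |T_j| >= |t_i|)` under the joint multivariate t
#' distribution implied by the contrast covariance, computed by Monte Carlo
#' with a fixed internal seed. Falls back to Bonferroni (with a warning)
#' when the contrast correlation matrix is singular.
#'
#' @param contrasts The `contrasts` data frame from [emm_at()] (needs
#'   columns `t` and `df`).
#' @param vcov Covariance matrix of the contrast estimates.
#' @param nsim Monte-Carlo draws (>= 1e5 recommended).
#' @param seed Seed for the internal RNG stream (restored afterwards).
#'
#' @return The contrasts data frame with `p_adj` and `adjustment` columns;
#'   `p_adj` is always >= the raw `p` and monotone in it.
#' @export
adjust_multiplicity <- function(contrasts, vcov, nsim = 1e5, seed = 421L) {
  k <- nrow(contrasts)
  if (k == 1L) {
    contrasts$p_adj <- contrasts$p
    contrasts$adjustment <- "none"
    return(contrasts)
  }
  R <- suppressWarnings(stats::cov2cor(vcov))
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch) || any(!is.finite(R))) {
    warning("singular contrast covariance; falling back to Bonferroni")
    contrasts$p_adj <- pmin(1, contrasts$p * k)
    contrasts$adjustment <- "bonferroni"
    return(contrasts)
  }
  df <- contrasts$df[1L]
  maxT <- with_preserved_seed(seed, {
    Z <- matrix(stats::rnorm(nsim * k), nsim, k) %*% ch
    s <- sqrt(stats::rchisq(nsim, df) / df)
    apply(abs(Z / s), 1L, max)
  })
  p_adj <- vapply(abs(contrasts$t), function(ti) mean(maxT >= ti), numeric(1))
  # enforce p_adj >= raw p and monotonicity in raw p
  ord <- order(contrasts$p)
  p_adj <- pmax(p_adj, contrasts$p)
  p_adj[ord] <- cummax(p_adj[ord])
  contrasts$p_adj <- pmin(1, p_adj)
  contrasts$adjustment <- "mvt"
  contrasts
}

# Evaluate expr under a temporary RNG state; the caller's stream resumes
# unchanged afterwards.
with_preserved_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Percent difference from a reference group
#'
#' Per-sample percent differences `100 * (x - ref_mean) / ref_mean`, where
#' the reference is the mean of the control group within the same stratum
#' (e.g. the same strain step), summarized as mean and SD per treatment and
#' stratum.
#'
#' @param data Data frame with `treatment`, the value column, and optionally
#'   a stratum column.
#' @param value Name of the value column.
#' @param stratum Optional name of the stratum column.
#' @param control Reference treatment label. Default `"Ctrl"`.
#'
#' @return A list with `per_sample` (input rows plus `pct_diff`) and
#'   `summary` (treatment x stratum mean, sd, n).
#' @export
percent_difference <- function(data, value, stratum = NULL, control = "Ctrl") {
  if (!value %in% names(data)) stop("value column not found: ", value)
  strata <- if (is.null(stratum)) rep("all", nrow(data)) else data[[stratum]]
  pct <- rep(NA_real_, nrow(data))
  for (s in unique(strata)) {
    in_s <- strata == s
    ref <- mean(data[[value]][in_s & data$treatment == control], na.rm = TRUE)
    if (!is.finite(ref) || ref == 0) stop("empty or zero-mean reference stratum: ", s)
    pct[in_s] <- 100 * (data[[value]][in_s] - ref) / ref
  }
  out <- data
  out$pct_diff <- pct
  key <- interaction(data$treatment, strata, drop = TRUE)
  summ <- do.call(rbind, lapply(split(seq_len(nrow(out)), key), function(i) {
    data.frame(treatment = data$treatment[i[1L]], stratum = strata[i[1L]],
               mean = mean(pct[i], na.rm = TRUE),
               sd = stats::sd(pct[i]), n = length(i))
  }))
  rownames(summ) <- NULL
  list(per_sample = out, summary = summ)
}
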