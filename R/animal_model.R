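# Bayesian "animal model": Gibbs sampling of the Gaussian mixed model
#   y = X beta + a (+ m) + e,   a ~ N(0, A sigma2_A),
#   m ~ N(0, I sigma2_M) over dam levels,  e ~ N(0, I sigma2_E),
# yielding the posterior of h2 = sigma2_A / (sigma2_A + sigma2_E).
#
# The sampler works in the eigenbasis of the relationship matrix
# restricted to the phenotyped individuals: with A_pp = U D U', the
# rotated breeding values have independent Gaussian full conditionals,
# making each Gibbs sweep O(n). This is exact for the marginal model of
# the phenotyped individuals because their breeding values are jointly
# N(0, sigma2_A * A_pp) regardless of unphenotyped relatives.

#' MCMC settings for the animal model
#'
#' Defaults are desk-scale: 60,000 iterations, 10% burn-in, thinning 25
#' (2,160 retained samples). Publication-scale settings (e.g. 1.5e6
#' iterations with thinning 800 or 250) can be requested explicitly.
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Burn-in fraction in `[0, 1)`.
#' @param thin Thinning interval (>= 1).
#' @param seed Optional integer seed; identical seeds give identical chains.
#' @return List of class `"mcmc_settings"`.
#' @export
mcmc_settings <- function(n_iter = 60000L, burn_in = 0.1, thin = 25L,
                          seed = NULL) {
  if (burn_in < 0 || burn_in >= 1) stop_symh2("burn_in must lie in [0, 1)")
  if (thin < 1L) stop_symh2("thin must be >= 1")
  if (n_iter < 10L) stop_symh2("n_iter too small")
  structure(list(n_iter = as.integer(n_iter), burn_in = burn_in,
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_settings")
}

#' Inverse-gamma priors for the variance components
#'
#' The conventional weakly-informative choice shape = rate = 0.001 on
#' each variance is the default; both parameters are configurable per
#' component.
#'
#' @param shape,rate Shared shape/rate applied to every variance.
#' @return List with elements `va`, `ve`, `vm`, each `c(shape, rate)`.
#' @export
ig_prior <- function(shape = 0.001, rate = 0.001) {
  p <- c(shape = shape, rate = rate)
  list(va = p, ve = p, vm = p)
}

#' Specify an animal model
#'
#' @param y Numeric trait values, one per phenotyped individual.
#' @param individual Ids of the phenotyped individuals (rows of A).
#' @param maternal_group Optional factor/character of dam identity per
#'   record, enabling a maternal-environment random effect.
#' @param fixed Optional data.frame of fixed-effect covariates (an
#'   intercept is always included).
#' @param prior Variance priors, see [ig_prior()].
#' @return List of class `"model_spec"`.
#' @export
model_spec <- function(y, individual, maternal_group = NULL, fixed = NULL,
                       prior = ig_prior()) {
  if (length(y) != length(individual))
    stop_symh2("y and individual must have equal length")
  if (length(y) < 3L) stop_symh2("need at least 3 phenotyped individuals")
  if (any(!is.finite(y))) stop_symh2("trait values must be finite")
  if (!is.null(maternal_group) && length(maternal_group) != length(y))
    stop_symh2("maternal_group must have one entry per record")
  structure(list(y = as.numeric(y), individual = as.character(individual),
                 maternal_group = if (!is.null(maternal_group))
                   as.character(maternal_group),
                 fixed = fixed, prior = prior),
            class = "model_spec")
}

rinvgamma1 <- function(shape, rate) 1 / stats::rgamma(1L, shape = shape, rate = rate)

# univariate slice sampler (stepping out + shrinkage; Neal 2003);
# f0 = logf(x0) may be supplied to save one evaluation
slice1 <- function(logf, x0, w = 1, max_steps = 50L, f0 = NULL) {
  if (is.null(f0)) f0 <- logf(x0)
  y <- f0 - stats::rexp(1L)
  L <- x0 - stats::runif(1L) * w
  R <- L + w
  for (k in seq_len(max_steps)) { if (logf(L) <= y) break; L <- L - w }
  for (k in seq_len(max_steps)) { if (logf(R) <= y) break; R <- R + w }
  repeat {
    x1 <- stats::runif(1L, L, R)
    f1 <- logf(x1)
    if (f1 > y) return(c(x1, f1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Gibbs sampler for the Bayesian animal model
#'
#' Each sweep updates, in a partially collapsed Gibbs cycle: the additive
#' and residual variances by slice sampling of their posterior with the
#' fixed effects and breeding values integrated out analytically (cheap
#' in the eigenbasis of A restricted to the phenotyped individuals, where
#' the marginal covariance is diagonal); then the fixed effects (flat
#' prior, GLS draw), the rotated breeding values (independent scalar
#' conditionals), and the maternal effects and their variance (inverse-
#' gamma conditional plus a non-centered interweaving update) if present.
#' Collapsing the location effects out of the variance updates removes
#' the funnel-shaped coupling between breeding values and sigma2_A that
#' makes the classic single-site cycle mix slowly when h2 is weakly
#' identified. Chains are thinned after burn-in;
#' `h2 = sigma2_A / (sigma2_A + sigma2_E)` per retained sample (the
#' maternal variance is excluded from the denominator by default).
#'
#' The trait is standardized to unit variance before sampling and the
#' variance chains are back-transformed afterwards; h2 is scale-free, and
#' this makes the inverse-gamma prior weakly informative regardless of
#' the trait's units (an IG rate of 0.001 would otherwise act as a strong
#' floor on a trait whose variance is far below 1).
#'
#' @param spec A [model_spec()].
#' @param A Additive relationship matrix covering `spec$individual`.
#' @param settings A [mcmc_settings()].
#' @param h2_denominator `"additive_residual"` (default) or `"total"`
#'   (includes the maternal variance when fitted).
#' @return Object of class `"h2_posterior"`: retained chains, posterior
#'   mode/mean/SD and 95% credibility interval of h2, DIC, diagnostics.
#' @export
gibbs_animal_model <- function(spec, A, settings = mcmc_settings(),
                               h2_denominator = c("additive_residual", "total")) {
  stopifnot(inherits(spec, "model_spec"))
  h2_denominator <- match.arg(h2_denominator)
  y <- spec$y
  n <- length(y)
  if (stats::var(y) == 0)
    stop_symh2("degenerate data: trait has zero variance")
  sdy <- stats::sd(y)
  y <- y / sdy
  if (is.null(rownames(A)))
    stop_symh2("A must have individual ids as dimnames")
  miss <- setdiff(spec$individual, rownames(A))
  if (length(miss))
    stop_symh2(sprintf("phenotyped individual(s) not in A: %s",
                       paste(miss, collapse = ", ")))
  App <- A[spec$individual, spec$individual, drop = FALSE]
  eg <- eigen((App + t(App)) / 2, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stop_symh2("relationship matrix is not positive semi-definite")
  d <- pmax(eg$values, 1e-10 * max(eg$values))
  U <- eg$vectors

  # design in the rotated basis
  X <- if (is.null(spec$fixed)) matrix(1, n, 1L) else
    stats::model.matrix(~., data = spec$fixed)
  Xt <- crossprod(U, X)
  yt <- as.vector(crossprod(U, y))
  maternal <- !is.null(spec$maternal_group)
  if (maternal) {
    gm <- factor(spec$maternal_group)
    if (nlevels(gm) < 2L)
      stop_symh2("maternal variance unidentifiable with a single dam level")
    Zm <- stats::model.matrix(~ gm - 1)
    Wt <- crossprod(U, Zm)
    q_m <- ncol(Zm)
  }

  prior <- spec$prior %||% ig_prior()
  if (!is.null(settings$seed)) set.seed(settings$seed)

  vy <- stats::var(y)
  s2a <- vy / 2; s2e <- vy / 2; s2m <- vy / 4
  at <- numeric(n)
  m <- if (maternal) numeric(q_m)
  beta <- numeric(ncol(X))

  burn <- floor(settings$burn_in * settings$n_iter)
  keep_at <- seq.int(burn + settings$thin, settings$n_iter, by = settings$thin)
  n_keep <- length(keep_at)
  if (n_keep < 1L) stop_symh2("settings retain no samples")
  chains <- matrix(NA_real_, n_keep, 5L,
                   dimnames = list(NULL, c("sigma2_A", "sigma2_e", "sigma2_m",
                                           "h2", "deviance")))
  k <- 0L
  p <- ncol(X)
  # log of the (beta, a)-integrated posterior density of the variances,
  # given the current maternal effects; flat prior on beta, V diagonal in
  # the eigenbasis. Used by the slice updates of log sigma2_A/log sigma2_E.
  x1 <- if (p == 1L) as.vector(Xt)
  # fully marginal log-likelihood (beta, a and m all integrated out) of
  # the variances; V = s2a D + s2e I + s2m W W' handled by Woodbury.
  # Used for the marginal-focus deviance that feeds DIC.
  log_marg_all <- function(s2a_, s2e_, s2m_) {
    v <- s2a_ * d + s2e_
    w <- 1 / v
    if (maternal && s2m_ > 0) {
      WtW <- crossprod(Wt, Wt * w)
      S <- diag(1 / s2m_, q_m) + WtW
      cS <- chol(S)
      Vi <- function(b) {
        wb <- w * b
        wb - w * (Wt %*% backsolve(cS, backsolve(cS, crossprod(Wt, wb),
                                                 transpose = TRUE)))
      }
      logdet <- sum(log(v)) + 2 * sum(log(diag(cS))) + q_m * log(s2m_)
    } else {
      Vi <- function(b) w * b
      logdet <- sum(log(v))
    }
    Viy <- Vi(yt)
    ViX <- Vi(Xt)
    XtViX <- crossprod(Xt, ViX)
    xv <- crossprod(Xt, Viy)
    quad <- sum(yt * Viy) - sum(xv * solve(XtViX, xv))
    ld2 <- if (p == 1L) log(XtViX[1L, 1L]) else determinant(XtViX)$modulus[1L]
    -0.5 * (logdet + ld2 + quad + (n - p) * log(2 * pi))
  }
  log_marg <- function(s2a_, s2e_, rv) {
    v <- s2a_ * d + s2e_
    w <- 1 / v
    if (p == 1L) {
      xtvx <- sum(x1 * x1 * w)
      xv <- sum(x1 * w * rv)
      quad <- sum(rv * rv * w) - xv * xv / xtvx
      return(-0.5 * (sum(log(v)) + log(xtvx) + quad))
    }
    Xw <- Xt * w
    XtVX <- crossprod(Xt, Xw)
    xv <- crossprod(Xw, rv)
    quad <- sum(rv^2 * w) - sum(xv * solve(XtVX, xv))
    -0.5 * (sum(log(v)) + determinant(XtVX)$modulus[1L] + quad)
  }
  log_ig <- function(s, pr) -(pr[1L] + 1) * log(s) - pr[2L] / s
  lm_cur <- NA_real_  # cached log_marg at the current state (constant rv only)
  for (it in seq_len(settings$n_iter)) {
    wm <- if (maternal) as.vector(Wt %*% m) else 0
    rv <- yt - wm
    if (maternal) lm_cur <- NA_real_  # rv changed with m
    # variances from the (beta, a)-collapsed posterior: slice updates on
    # the log scale (collapse first, then redraw the collapsed effects)
    ra <- slice1(function(z)
      log_marg(exp(z), s2e, rv) + log_ig(exp(z), prior$va) + z, log(s2a),
      f0 = if (is.na(lm_cur)) NULL else
        lm_cur + log_ig(s2a, prior$va) + log(s2a))
    lm_cur <- ra[2L] - log_ig(exp(ra[1L]), prior$va) - ra[1L]
    s2a <- exp(ra[1L])
    re <- slice1(function(z)
      log_marg(s2a, exp(z), rv) + log_ig(exp(z), prior$ve) + z, log(s2e),
      f0 = lm_cur + log_ig(s2e, prior$ve) + log(s2e))
    lm_cur <- re[2L] - log_ig(exp(re[1L]), prior$ve) - re[1L]
    s2e <- exp(re[1L])
    # fixed effects: GLS draw from their a-marginal conditional
    v <- s2a * d + s2e
    w <- 1 / v
    Xw <- Xt * w
    XtVX <- crossprod(Xt, Xw)
    cv <- chol(XtVX)
    bhat <- backsolve(cv, backsolve(cv, crossprod(Xw, rv), transpose = TRUE))
    beta <- as.vector(bhat) + as.vector(backsolve(cv, stats::rnorm(p)))
    xb <- as.vector(Xt %*% beta)
    # rotated breeding values: independent scalar conditionals
    r <- yt - xb - wm
    prec <- 1 / s2e + 1 / (d * s2a)
    at <- (r / s2e) / prec + stats::rnorm(n) / sqrt(prec)
    # maternal effects (diagonal crossprod: one dam per record), with an
    # interweaving (non-centered) update of sigma2_M
    if (maternal) {
      r <- yt - xb - at
      precm <- colSums(Wt^2) / s2e + 1 / s2m
      mum <- as.vector(crossprod(Wt, r)) / s2e / precm
      m <- mum + stats::rnorm(q_m) / sqrt(precm)
      s2m <- rinvgamma1(prior$vm[1L] + q_m / 2, prior$vm[2L] + 0.5 * sum(m^2))
      um <- m / sqrt(s2m)
      wu <- as.vector(Wt %*% um)
      uum <- sum(wu^2)
      rum <- sum(r * wu)
      s2m <- exp(slice1(function(z) {
        s <- exp(z)
        log_ig(s, prior$vm) - (s * uum - 2 * sqrt(s) * rum) / (2 * s2e) + z
      }, log(s2m))[1L])
      m <- um * sqrt(s2m)
      wm <- as.vector(Wt %*% m)
    }
    if (k < n_keep && it == keep_at[k + 1L]) {
      k <- k + 1L
      # marginal-focus deviance: -2 log p(y | variances) with all
      # location effects integrated out. The conditional-focus deviance
      # (given sampled breeding values) rides the sigma2_A/sigma2_E
      # identifiability ridge and makes DIC comparisons noise-dominated.
      dev <- -2 * log_marg_all(s2a, s2e, if (maternal) s2m else 0)
      denom <- s2a + s2e + if (maternal && h2_denominator == "total") s2m else 0
      chains[k, ] <- c(s2a, s2e, if (maternal) s2m else NA_real_,
                       s2a / denom, dev)
    }
  }

  warnings <- character(0)
  if (n_keep < 50L)
    warnings <- c(warnings, sprintf("only %d retained samples (< 50)", n_keep))

  d_bar <- mean(chains[, "deviance"])
  d_hat <- -2 * log_marg_all(mean(chains[, "sigma2_A"]),
                             mean(chains[, "sigma2_e"]),
                             if (maternal) mean(chains[, "sigma2_m"]) else 0)
  p_d <- d_bar - d_hat
  dic <- d_bar + p_d
  # back to the original trait scale (h2 and pD are scale-free)
  scale2 <- sdy^2
  chains[, c("sigma2_A", "sigma2_e", "sigma2_m")] <-
    chains[, c("sigma2_A", "sigma2_e", "sigma2_m")] * scale2
  chains[, "deviance"] <- chains[, "deviance"] + (n - p) * log(scale2)
  dic <- dic + (n - p) * log(scale2)

  h2 <- chains[, "h2"]
  summ <- posterior_summary(h2)
  rho1 <- if (n_keep > 2L)
    stats::cor(h2[-1L], h2[-n_keep]) else NA_real_
  ess <- ess_autocorr(h2)

  structure(list(
    chains = data.frame(iteration = keep_at, chains, check.names = FALSE),
    h2_mode = summ$mode, h2_mean = summ$mean, h2_sd = summ$sd,
    ci95 = summ$ci95, dic = dic, p_d = p_d, n_retained = n_keep,
    maternal = maternal, h2_denominator = h2_denominator,
    settings = settings, prior = prior,
    diagnostics = list(lag1_autocorr = rho1, ess = ess),
    warnings = warnings), class = "h2_posterior")
}

# effective sample size from the initial positive sequence of
# autocorrelations (Geyer-style truncation at the first negative lag)
ess_autocorr <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 500L), plot = FALSE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Summaries of a posterior sample
#'
#' Mean, SD, central 95% credibility interval, and the posterior mode
#' estimated as the argmax of a Gaussian kernel density (bandwidth by the
#' standard `nrd0` reference rule). The mode is the headline estimate.
#'
#' @param samples Numeric vector of posterior draws (>= 50).
#' @return List: mean, sd, mode, ci95 (length-2 vector).
#' @export
posterior_summary <- function(samples) {
  if (length(samples) < 50L)
    stop_symh2("need at least 50 posterior samples to summarize")
  m <- mean(samples); s <- stats::sd(samples)
  if (s == 0) {
    return(list(mean = m, sd = 0, mode = m, ci95 = c(m, m)))
  }
  dens <- stats::density(samples, bw = "nrd0")
  list(mean = m, sd = s, mode = dens$x[which.max(dens$y)],
       ci95 = unname(stats::quantile(samples, c(0.025, 0.975))))
}

#' Deviance information criterion of a fitted animal model
#'
#' `DIC = mean posterior deviance + pD`, with
#' `pD = mean deviance - deviance at the posterior means` of the variance
#' components; lower is better. The deviance has marginal focus: the
#' Gaussian likelihood of the trait with fixed effects, breeding values
#' and maternal effects integrated out, which is the appropriate focus
#' for comparing random-effect structures (the conditional-focus deviance
#' is dominated by the weakly identified split between breeding values
#' and residuals).
#'
#' @param fit An `"h2_posterior"` from [gibbs_animal_model()].
#' @return The DIC value.
#' @export
dic <- function(fit) {
  if (!inherits(fit, "h2_posterior") || is.null(fit$dic))
    stop_symh2("fit does not carry stored deviances")
  fit$dic
}

#' Fit and compare models with and without a maternal-environment effect
#'
#' Fits the animal model twice under the same settings and seed — once
#' with and once without the dam-level random effect — and selects the
#' model with the lower DIC.
#'
#' @param spec A [model_spec()] with `maternal_group` set.
#' @param A Additive relationship matrix.
#' @param settings A [mcmc_settings()].
#' @return List of class `"maternal_comparison"`: `no_maternal`,
#'   `maternal` (both `"h2_posterior"`), `delta_dic`
#'   (DIC maternal - DIC no-maternal) and `selected`.
#' @export
compare_maternal_models <- function(spec, A, settings = mcmc_settings()) {
  if (is.null(spec$maternal_group))
    stop_symh2("spec has no maternal grouping")
  if (length(unique(spec$maternal_group)) < 2L)
    stop_symh2("maternal variance unidentifiable with a single dam level")
  spec0 <- spec
  spec0$maternal_group <- NULL
  fit0 <- gibbs_animal_model(spec0, A, settings)
  fit1 <- gibbs_animal_model(spec, A, settings)
  delta <- dic(fit1) - dic(fit0)
  structure(list(no_maternal = fit0, maternal = fit1, delta_dic = delta,
                 selected = if (delta < 0) "maternal" else "no_maternal"),
            class = "maternal_comparison")
}

#' @export
print.h2_posterior <- function(x, ...) {
  cat("Bayesian animal model posterior (", x$n_retained, " retained samples)\n",
      sep = "")
  cat(sprintf("  h2 mode %.3f  mean %.3f (SD %.3f)  95%% CI [%.3f, %.3f]\n",
              x$h2_mode, x$h2_mean, x$h2_sd, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  DIC %.2f (pD %.2f)%s\n", x$dic, x$p_d,
              if (x$maternal) "  [maternal effect fitted]" else ""))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write retained MCMC chains to TSV
#' @param fit An `"h2_posterior"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(fit, path) {
  utils::write.table(fit$chains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
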