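#' P_ST from variance components
#'
#' Phenotypic differentiation index, the P_ST analogue of Q_ST computed
#' from total (not additive) variances and scaled by the additive
#' contribution ratio r = c/h^2:
#' \deqn{P_{ST} = \frac{r\,\sigma^2_B}{r\,\sigma^2_B + 2\,\sigma^2_W}.}
#' Monotone increasing in both \eqn{\sigma^2_B} and r. At c = h^2 (r = 1)
#' this is the best-case approximation to Q_ST.
#'
#' @param sigma_b2 between-population variance (vectorized, >= 0).
#' @param sigma_w2 within-population (residual) variance (vectorized, >= 0;
#'   not both zero).
#' @param c_over_h2 ratio c/h^2 (> 0); default 1.
#' @return P_ST in [0, 1].
#' @examples
#' pstFromVariances(2, 1)        # 0.5
#' pstFromVariances(1, 1, 2)     # 0.5
#' @export
pstFromVariances <- function(sigma_b2, sigma_w2, c_over_h2 = 1) {
  if (any(c_over_h2 <= 0)) stop("c_over_h2 must be positive")
  if (any(sigma_b2 < 0) || any(sigma_w2 < 0))
    stop("variances must be non-negative")
  num <- c_over_h2 * sigma_b2
  den <- num + 2 * sigma_w2
  if (any(den == 0))
    stop("P_ST undefined when both variances are zero")
  num / den
}

#' Model specification for the hierarchical trait model
#'
#' @param trait name of the trait column to model.
#' @param sex_effect \code{"none"}, \code{"shared"} (one sample-wide male
#'   effect, females the baseline) or \code{"island_specific"} (one male
#'   effect per population).
#' @param covariates character vector of covariate column names (centered
#'   at their sample mean before fitting).
#' @param correlation_between_effects when TRUE (requires
#'   \code{sex_effect = "island_specific"}), the per-island (intercept,
#'   male-effect) pairs get a joint bivariate-normal prior whose
#'   correlation has a uniform(-1, 1) prior.
#' @return A list of class \code{"ModelSpec"}.
#' @export
modelSpec <- function(trait, sex_effect = c("none", "shared",
                                            "island_specific"),
                      covariates = character(0),
                      correlation_between_effects = FALSE) {
  sex_effect <- match.arg(sex_effect)
  if (correlation_between_effects && sex_effect != "island_specific")
    stop("correlation_between_effects requires sex_effect = 'island_specific'")
  structure(list(trait = trait, sex_effect = sex_effect,
                 covariates = covariates,
                 correlation_between_effects = correlation_between_effects),
            class = "ModelSpec")
}

#' MCMC configuration for [fitTraitModel()]
#'
#' Defaults: burn-in of 25,000 iterations followed by 25,000 more, thinned
#' every 25 (1,000 retained draws per chain), 2 chains, half-Cauchy scale
#' 100 on both standard deviations (prior variance of at least 10,000 on
#' the variance scale).
#'
#' @param n_chains number of chains (>= 2, needed for PSRF).
#' @param burn_in discarded initial iterations per chain.
#' @param n_iter post-burn-in iterations per chain.
#' @param thin thinning interval (>= 1); \code{n_iter/thin} retained draws
#'   per chain must be >= 200.
#' @param seed integer seed; chain seeds are derived deterministically.
#' @param prior_scale_sd half-Cauchy scale for both standard deviations.
#' @return A list of class \code{"McmcConfig"}.
#' @export
mcmcConfig <- function(n_chains = 2L, burn_in = 25000L, n_iter = 25000L,
                       thin = 25L, seed = 1L, prior_scale_sd = 100) {
  if (n_chains < 2L) stop("need at least 2 chains (PSRF requires them)")
  if (thin < 1L) stop("thin must be >= 1")
  if (n_iter / thin < 200)
    stop("retained draws per chain (n_iter/thin) must be >= 200")
  if (prior_scale_sd <= 0) stop("prior_scale_sd must be positive")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_scale_sd = prior_scale_sd),
            class = "McmcConfig")
}

# deterministic 32-bit chain seed derived from the user seed
chainSeed <- function(seed, chain) {
  as.integer((as.numeric(seed) %% 2147483629) * 7919 + chain * 104729) %%
    2147483629L
}

# inverse-gamma sampler: density proportional to x^(-shape-1) exp(-scale/x)
rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1, shape, rate = scale)

#' Fit the Bayesian hierarchical trait model
#'
#' Samples the posterior of
#' \deqn{y_{ij} = \mu + a_j + s_{[j],\mathrm{sex}(i)} + \sum_k \beta_k x_{ik} + \varepsilon_{ij},}
#' with island (population) effects \eqn{a_j \sim N(0, \sigma^2_B)},
#' residuals \eqn{\varepsilon \sim N(0, \sigma^2_W)}, half-Cauchy priors
#' (scale \code{prior_scale_sd}) on both standard deviations, and diffuse
#' normal priors (sd 1000) on the grand mean, sex effects and covariate
#' coefficients. The male sex effect is coded with females as the
#' baseline. With \code{correlation_between_effects}, the per-island
#' (intercept, male-effect) pairs are jointly bivariate normal with a
#' half-Cauchy prior on the sex-effect sd and a uniform(-1, 1) prior on
#' the correlation.
#'
#' The sampler is a component-wise Gibbs scheme: all location parameters
#' and (via the inverse-gamma auxiliary-variable representation of the
#' half-Cauchy) both variances have conjugate updates; in the correlated
#' model the covariance parameters (log sd's and atanh correlation) are
#' updated by random-walk Metropolis. P_ST is computed per retained draw
#' at c = h^2. Deterministic given \code{cfg$seed}.
#'
#' Records with missing trait or covariate values are dropped with a
#' message, as are records of unknown sex whenever a sex effect is in the
#' specification.
#'
#' With only two populations, \eqn{\sigma^2_B} is weakly identified and
#' its posterior (hence the P_ST posterior) is sensitive to the
#' half-Cauchy scale; this is inherent to the design, not a sampler
#' artefact.
#'
#' @param data data.frame with columns \code{individual_id},
#'   \code{population}, \code{sex} (\code{female}/\code{male}/
#'   \code{unknown}) and the trait/covariate columns.
#' @param spec a [modelSpec()].
#' @param cfg an [mcmcConfig()].
#' @return A [TraitFit-class] object.
#' @export
fitTraitModel <- function(data, spec, cfg = mcmcConfig()) {
  stopifnot(inherits(spec, "ModelSpec"), inherits(cfg, "McmcConfig"))
  need <- c("population", "sex", spec$trait, spec$covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))

  keep <- stats::complete.cases(data[, c(spec$trait, spec$covariates),
                                     drop = FALSE])
  if (any(!keep))
    message(sprintf("dropping %d record(s) with missing trait/covariate values",
                    sum(!keep)))
  data <- data[keep, , drop = FALSE]
  if (spec$sex_effect != "none") {
    bad_sex <- !data$sex %in% c("female", "male")
    if (any(bad_sex))
      message(sprintf("dropping %d record(s) of unknown sex", sum(bad_sex)))
    data <- data[!bad_sex, , drop = FALSE]
  }

  pop <- factor(as.character(data$population))
  if (nlevels(pop) < 2L) stop("need at least 2 populations")
  if (any(table(pop) < 2L))
    stop("every population needs >= 2 individuals with the modeled trait")

  y <- as.numeric(data[[spec$trait]])
  male <- as.numeric(data$sex == "male")
  J <- nlevels(pop)
  j_of <- as.integer(pop)
  X <- if (length(spec$covariates)) {
    Xm <- as.matrix(data[, spec$covariates, drop = FALSE])
    sweep(Xm, 2, colMeans(Xm))               # centered at sample mean
  } else NULL

  n_keep <- cfg$n_iter %/% cfg$thin
  par_names <- c("mu", paste0("a.", levels(pop)),
    switch(spec$sex_effect,
           none = character(0),
           shared = "sex_male",
           island_specific = paste0("sex_male.", levels(pop))),
    if (length(spec$covariates)) paste0("beta.", spec$covariates),
    if (spec$correlation_between_effects) c("sigma_s2", "rho"),
    "sigma_b2", "sigma_w2", "pst")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  all_draws <- vector("list", cfg$n_chains)
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(chainSeed(cfg$seed, ch))
    all_draws[[ch]] <- runChain(y, j_of, J, male, X, spec, cfg, n_keep,
                                par_names, chain_id = ch)
  }
  all_draws <- lapply(all_draws, function(m) {
    colnames(m) <- par_names
    m
  })
  draws <- do.call(rbind, all_draws)
  chain <- rep(seq_len(cfg$n_chains), each = n_keep)

  diag_df <- data.frame(parameter = par_names,
    psrf = vapply(par_names, function(p)
      psrf(lapply(all_draws, function(m) m[, p])), numeric(1)),
    ess = vapply(par_names, function(p)
      sum(vapply(all_draws, function(m)
        effectiveSampleSize(m[, p]), numeric(1))), numeric(1)),
    row.names = NULL)

  used <- data.frame(individual_id = if ("individual_id" %in% names(data))
                       as.character(data$individual_id) else
                       as.character(seq_along(y)),
                     population = as.character(pop),
                     sex = as.character(data$sex), y = y,
                     stringsAsFactors = FALSE)
  if (!is.null(X)) used <- cbind(used, as.data.frame(X))

  new("TraitFit", draws = draws, chain = chain, diagnostics = diag_df,
      spec = unclass(spec), config = unclass(cfg), data_used = used)
}

# One MCMC chain. Location parameters and both variances are conjugate
# (half-Cauchy via inverse-gamma auxiliary: sigma^2 | aux ~ IG(1/2, 1/aux),
# aux ~ IG(1/2, 1/scale^2) gives sigma ~ half-Cauchy(scale)); the
# correlated covariance block uses univariate random-walk Metropolis on
# (log sigma_b, log sigma_s, atanh rho).
runChain <- function(y, j_of, J, male, X, spec, cfg, n_keep, par_names,
                     chain_id) {
  n <- length(y)
  A2 <- cfg$prior_scale_sd^2
  prior_prec_fixed <- 1 / 1000^2            # diffuse normal, sd 1000
  idx_pop <- split(seq_len(n), j_of)
  n_pop <- lengths(idx_pop)
  correlated <- isTRUE(spec$correlation_between_effects)
  island_sex <- spec$sex_effect == "island_specific"
  shared_sex <- spec$sex_effect == "shared"
  K <- if (is.null(X)) 0L else ncol(X)

  # initial values; overdisperse the mean start across chains
  mu <- mean(y) + (chain_id - 1.5) * stats::sd(y) * 0.5
  a <- rep(0, J)
  s_island <- rep(0, J)
  delta <- 0
  beta <- rep(0, K)
  sigma_w2 <- max(stats::var(y), 1e-6)
  sigma_b2 <- max(stats::var(tapply(y, j_of, mean)), 1e-6)
  sigma_s2 <- 1
  rho <- 0
  aux_w <- 1; aux_b <- 1; aux_s <- 1
  step <- c(0.5, 0.5, 0.8)                  # RW sd for log sb, log ss, z(rho)

  xb <- if (K) drop(X %*% beta) else 0
  out <- matrix(NA_real_, n_keep, length(par_names))
  total <- cfg$burn_in + cfg$n_iter
  kept <- 0L

  for (it in seq_len(total)) {
    sex_term <- if (shared_sex) delta * male else
      if (island_sex) s_island[j_of] * male else 0

    # grand mean
    r <- y - a[j_of] - sex_term - xb
    prec <- n / sigma_w2 + prior_prec_fixed
    mu <- stats::rnorm(1, sum(r) / sigma_w2 / prec, sqrt(1 / prec))

    if (!correlated) {
      # island intercepts
      r <- y - mu - sex_term - xb
      for (j in seq_len(J)) {
        prec <- n_pop[j] / sigma_w2 + 1 / sigma_b2
        a[j] <- stats::rnorm(1, sum(r[idx_pop[[j]]]) / sigma_w2 / prec,
                             sqrt(1 / prec))
      }
      # sex effects
      if (shared_sex) {
        r <- y - mu - a[j_of] - xb
        sm <- sum(male)
        prec <- sm / sigma_w2 + prior_prec_fixed
        delta <- stats::rnorm(1, sum(r * male) / sigma_w2 / prec,
                              sqrt(1 / prec))
      } else if (island_sex) {
        r <- y - mu - a[j_of] - xb
        for (j in seq_len(J)) {
          ij <- idx_pop[[j]]
          mj <- male[ij]
          prec <- sum(mj) / sigma_w2 + prior_prec_fixed
          s_island[j] <- stats::rnorm(1, sum(r[ij] * mj) / sigma_w2 / prec,
                                      sqrt(1 / prec))
        }
      }
      # group-translation (sweep) move: shifting mass between mu and the
      # island effects is a valid Gibbs step on the translation group and
      # breaks the additive confounding that stalls mixing with few groups
      prec_t <- J / sigma_b2 + prior_prec_fixed
      mean_t <- (sum(a) / sigma_b2 - mu * prior_prec_fixed) / prec_t
      tshift <- stats::rnorm(1, mean_t, sqrt(1 / prec_t))
      a <- a - tshift
      mu <- mu + tshift
      # between-population variance (conjugate via auxiliary)
      aux_b <- rinvgamma1(1, 1 / A2 + 1 / sigma_b2)
      sigma_b2 <- rinvgamma1((J + 1) / 2, 1 / aux_b + sum(a^2) / 2)
    } else {
      # joint (intercept, male effect) pair per island, bivariate conjugate
      Sigma <- matrix(c(sigma_b2, rho * sqrt(sigma_b2 * sigma_s2),
                        rho * sqrt(sigma_b2 * sigma_s2), sigma_s2), 2)
      Sinv <- solve(Sigma)
      r <- y - mu - xb
      for (j in seq_len(J)) {
        ij <- idx_pop[[j]]
        mj <- male[ij]
        ZtZ <- matrix(c(length(ij), sum(mj), sum(mj), sum(mj)), 2)
        P <- ZtZ / sigma_w2 + Sinv
        b <- c(sum(r[ij]), sum(r[ij] * mj)) / sigma_w2
        U <- chol(P)
        mean_j <- backsolve(U, forwardsolve(t(U), b))
        z <- stats::rnorm(2)
        pair <- mean_j + backsolve(U, z)
        a[j] <- pair[1]; s_island[j] <- pair[2]
      }
      # sweep move on the translation group (see uncorrelated branch);
      # the island-effect prior contribution uses the current Sinv
      prec_t <- J * Sinv[1, 1] + prior_prec_fixed
      lin_t <- sum(Sinv[1, 1] * a + Sinv[1, 2] * s_island) -
        mu * prior_prec_fixed
      tshift <- stats::rnorm(1, lin_t / prec_t, sqrt(1 / prec_t))
      a <- a - tshift
      mu <- mu + tshift
      # covariance parameters: univariate RW Metropolis on transformed scale
      eta <- c(log(sqrt(sigma_b2)), log(sqrt(sigma_s2)), atanh(rho))
      for (p in 1:3) {
        prop <- eta
        prop[p] <- prop[p] + stats::rnorm(1, 0, step[p])
        if (covLogPost(prop, a, s_island, A2) -
            covLogPost(eta, a, s_island, A2) > log(stats::runif(1)))
          eta <- prop
      }
      sigma_b2 <- exp(2 * eta[1]); sigma_s2 <- exp(2 * eta[2])
      rho <- tanh(eta[3])
    }

    # covariate coefficients
    if (K) {
      sex_term <- if (shared_sex) delta * male else
        if (island_sex) s_island[j_of] * male else 0
      for (k in seq_len(K)) {
        xb_k <- if (K > 1) drop(X[, -k, drop = FALSE] %*% beta[-k]) else 0
        r <- y - mu - a[j_of] - sex_term - xb_k
        xk <- X[, k]
        prec <- sum(xk^2) / sigma_w2 + prior_prec_fixed
        beta[k] <- stats::rnorm(1, sum(r * xk) / sigma_w2 / prec,
                                sqrt(1 / prec))
      }
      xb <- drop(X %*% beta)
    }

    # residual variance (conjugate via auxiliary)
    sex_term <- if (shared_sex) delta * male else
      if (island_sex) s_island[j_of] * male else 0
    resid <- y - mu - a[j_of] - sex_term - xb
    aux_w <- rinvgamma1(1, 1 / A2 + 1 / sigma_w2)
    sigma_w2 <- rinvgamma1((n + 1) / 2, 1 / aux_w + sum(resid^2) / 2)

    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- c(mu, a,
        if (shared_sex) delta else if (island_sex) s_island,
        if (K) beta,
        if (correlated) c(sigma_s2, rho),
        sigma_b2, sigma_w2,
        pstFromVariances(sigma_b2, sigma_w2, 1))
    }
  }
  out
}

# log posterior of the island-effect covariance block, on the transformed
# scale eta = (log sigma_b, log sigma_s, atanh rho), Jacobians included
covLogPost <- function(eta, a, s, A2) {
  sb <- exp(eta[1]); ss <- exp(eta[2]); rho <- tanh(eta[3])
  if (!is.finite(sb) || !is.finite(ss)) return(-Inf)
  det_fac <- 1 - rho^2
  if (det_fac <= 0) return(-Inf)
  J <- length(a)
  q <- sum(a^2 / sb^2 - 2 * rho * a * s / (sb * ss) + s^2 / ss^2) / det_fac
  ll <- -J * (eta[1] + eta[2] + 0.5 * log(det_fac)) - q / 2
  # half-Cauchy(sqrt(A2)) on each sd, log-scale Jacobian sb, ss;
  # uniform(-1,1) on rho with Jacobian (1 - rho^2) from atanh
  lp <- -log1p(sb^2 / A2) + eta[1] - log1p(ss^2 / A2) + eta[2] +
    log(det_fac)
  ll + lp
}

#' Gelman–Rubin potential scale reduction factor
#'
#' \deqn{\widehat{R} = \sqrt{\frac{(n-1)/n\; W + B/n}{W}},}
#' with W the mean within-chain variance and B the between-chain variance
#' of chain means scaled by n (i.e. \eqn{B = \frac{n}{m-1}\sum_j
#' (\bar x_j - \bar x)^2} over m chains of length n). Approaches 1 at
#' convergence.
#'
#' @param chains list of numeric vectors (>= 2 chains, equal lengths
#'   >= 10).
#' @return PSRF (numeric scalar). When every chain has zero within-chain
#'   variance: 1 if the chains are identical, \code{Inf} otherwise.
#' @export
psrf <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2L)
  lens <- lengths(chains)
  if (length(unique(lens)) != 1L || lens[1] < 10L)
    stop("chains must have equal lengths >= 10")
  n <- lens[1]; m <- length(chains)
  W <- mean(vapply(chains, stats::var, numeric(1)))
  means <- vapply(chains, mean, numeric(1))
  B <- n / (m - 1) * sum((means - mean(means))^2)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size of an MCMC draw sequence
#'
#' \deqn{\mathrm{ESS} = \frac{n}{1 + 2\sum_t \rho_t},}
#' with autocorrelations \eqn{\rho_t} accumulated in consecutive pairs
#' \eqn{(\rho_1+\rho_2), (\rho_3+\rho_4), \ldots} until the first
#' non-positive pair (initial-positive-sequence truncation).
#'
#' @param x numeric vector of >= 100 draws.
#' @return ESS (numeric scalar). A constant sequence returns n with
#'   attribute \code{constant = TRUE}.
#' @export
effectiveSampleSize <- function(x) {
  n <- length(x)
  if (n < 100L) stop("need at least 100 draws")
  if (stats::var(x) == 0)
    return(structure(as.numeric(n), constant = TRUE))
  lag_max <- min(n - 1L, 1000L)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  s <- 0; t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2L
  }
  n / (1 + 2 * s)
}

#' Posterior predictive check of the trait model
#'
#' Simulates \code{n_rep} replicate datasets from the fitted model (one
#' per retained parameter vector, evenly spaced through the posterior),
#' recomputes the per-(population x sex) mean and standard deviation for
#' each replicate, and reports for each observed statistic the posterior
#' predictive p-value \eqn{P(T^{rep} \ge T^{obs})} (ties counted half),
#' which is ~0.5 when the observed statistic sits at the replicate median
#' and drifts into the tails under model misfit.
#'
#' @param fit a [TraitFit-class] object.
#' @param data the trait table the model was fitted to (only used for its
#'   column names; the records actually modeled are stored in the fit).
#' @param n_rep number of replicate datasets (1 <= n_rep <= retained
#'   draws).
#' @param seed integer RNG seed.
#' @return data.frame with columns population, sex, statistic, observed
#'   and p_value.
#' @export
posteriorPredictiveCheck <- function(fit, data = NULL, n_rep = 200L,
                                     seed = 1L) {
  stopifnot(methods::is(fit, "TraitFit"))
  n_draws <- nrow(fit@draws)
  if (n_rep < 1L) stop("n_rep must be >= 1")
  if (n_rep > n_draws)
    stop("n_rep exceeds the number of retained draws")

  used <- fit@data_used
  grp <- interaction(used$population, used$sex, drop = TRUE, sep = "|")
  obs_mean <- tapply(used$y, grp, mean)
  obs_sd <- tapply(used$y, grp, stats::sd)

  pick <- round(seq(1, n_draws, length.out = n_rep))
  dn <- colnames(fit@draws)
  pops <- sub("^a\\.", "", dn[startsWith(dn, "a.")])
  j_of <- match(used$population, pops)
  male <- as.numeric(used$sex == "male")
  covs <- fit@spec$covariates
  Xc <- if (length(covs)) as.matrix(used[, covs, drop = FALSE]) else NULL

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  rep_means <- matrix(NA_real_, n_rep, nlevels(grp))
  rep_sds <- matrix(NA_real_, n_rep, nlevels(grp))
  for (i in seq_len(n_rep)) {
    th <- fit@draws[pick[i], ]
    mu_vec <- th["mu"] + th[paste0("a.", pops)][j_of]
    if (fit@spec$sex_effect == "shared")
      mu_vec <- mu_vec + th["sex_male"] * male
    if (fit@spec$sex_effect == "island_specific")
      mu_vec <- mu_vec + th[paste0("sex_male.", pops)][j_of] * male
    if (!is.null(Xc))
      mu_vec <- mu_vec + drop(Xc %*% th[paste0("beta.", covs)])
    y_rep <- stats::rnorm(length(mu_vec), mu_vec, sqrt(th["sigma_w2"]))
    rep_means[i, ] <- tapply(y_rep, grp, mean)
    rep_sds[i, ] <- tapply(y_rep, grp, stats::sd)
  }

  ppv <- function(reps, obs)
    (colSums(sweep(reps, 2, obs, ">")) +
       0.5 * colSums(sweep(reps, 2, obs, "=="))) / nrow(reps)
  cells <- do.call(rbind, strsplit(levels(grp), "|", fixed = TRUE))
  rbind(
    data.frame(population = cells[, 1], sex = cells[, 2],
               statistic = "mean", observed = as.numeric(obs_mean),
               p_value = ppv(rep_means, obs_mean)),
    data.frame(population = cells[, 1], sex = cells[, 2],
               statistic = "sd", observed = as.numeric(obs_sd),
               p_value = ppv(rep_sds, obs_sd))
  )
}
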