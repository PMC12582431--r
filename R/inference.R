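#' Sampler settings for the Bayesian models
#'
#' Defaults are a reduced-draw mode (2 chains x 750 kept draws) sized for
#' routine runs; increase `chains`/`draws` for final inference. Convergence
#' is summarised by split chains (potential scale reduction factor) and
#' effective sample size on the reported parameters; fits warn when the
#' largest Rhat exceeds `rhat_warn`, and error instead when
#' `require_convergence = TRUE`.
#'
#' @param chains number of MCMC chains.
#' @param adapt,burn adaptation and burn-in iterations.
#' @param draws kept draws per chain.
#' @param thin thinning interval.
#' @param seed integer seed; chain c runs with seed `seed + c`.
#' @param rhat_warn Rhat threshold for the convergence warning.
#' @param require_convergence error (rather than warn) on Rhat above the
#'   threshold.
#' @param quiet suppress JAGS progress output.
#' @return list of class `sampler_control`.
#' @export
sampler_control <- function(chains = 2L, adapt = 300L, burn = 500L,
                            draws = 750L, thin = 1L, seed = 1L,
                            rhat_warn = 1.05, require_convergence = FALSE,
                            quiet = TRUE) {
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burn = as.integer(burn), draws = as.integer(draws),
                 thin = as.integer(thin), seed = as.integer(seed),
                 rhat_warn = rhat_warn,
                 require_convergence = isTRUE(require_convergence),
                 quiet = isTRUE(quiet)),
            class = "sampler_control")
}

# ---- shared machinery -----------------------------------------------------

.run_jags <- function(model_string, data, monitor, control, inits = NULL) {
  base_inits <- lapply(seq_len(control$chains), function(ch) {
    ini <- if (is.null(inits)) list() else inits
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- control$seed + ch
    ini
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = base_inits, n.chains = control$chains,
                          n.adapt = control$adapt, quiet = control$quiet)
  update(jm, control$burn, progress.bar = if (control$quiet) "none" else "text")
  rjags::coda.samples(jm, monitor, n.iter = control$draws * control$thin,
                      thin = control$thin,
                      progress.bar = if (control$quiet) "none" else "text")
}

.convergence_report <- function(samples, pars, control) {
  keep <- unlist(lapply(pars, function(p) {
    grep(paste0("^", gsub("\\[", "\\\\[", p)), coda::varnames(samples),
         value = TRUE)
  }))
  keep <- unique(keep)
  sub <- samples[, keep, drop = FALSE]
  ess <- coda::effectiveSize(sub)
  rhat <- if (length(samples) >= 2) {
    coda::gelman.diag(sub, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  } else {
    rep(NA_real_, length(keep))
  }
  rep_df <- data.frame(parameter = keep, rhat = unname(rhat),
                       ess = unname(ess[keep]))
  worst <- suppressWarnings(max(rep_df$rhat, na.rm = TRUE))
  if (is.finite(worst) && worst > control$rhat_warn) {
    msg <- sprintf(
      "possible non-convergence: max Rhat %.3f (min ESS %.0f); increase draws",
      worst, min(rep_df$ess, na.rm = TRUE))
    if (control$require_convergence) stop(msg) else warning(msg)
  }
  rep_df
}

.draw_matrix <- function(samples) {
  do.call(rbind, lapply(samples, as.matrix))
}

# language contrast: first level +1/2, second -1/2, so an outcome that is
# larger in the second condition yields a negative printed effect
.lang_code <- function(language, levels) {
  ifelse(language == levels[1], 0.5, -0.5)
}

.loc_levels <- c("pre-sentence", "pre-word", "within-word")

# two location contrasts: before-sentence vs before-word, and within-word
# vs before-word-or-sentence
.loc_codes <- function(location) {
  c1 <- ifelse(location == "pre-sentence", 0.5,
               ifelse(location == "pre-word", -0.5, 0))
  c2 <- ifelse(location == "within-word", 0.5, -0.25)
  cbind(c1 = c1, c2 = c2)
}

.fixed_design <- function(df, lang_levels) {
  n <- nrow(df)
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  xl <- rep(0, n)
  if (length(lang_levels) == 2) {
    xl <- .lang_code(df$language, lang_levels)
    X <- cbind(X, language = xl)
  }
  has_loc <- "location" %in% names(df) && length(unique(df$location)) > 1
  if (has_loc) {
    lc <- .loc_codes(df$location)
    X <- cbind(X, loc_bs_bw = lc[, 1], loc_ww_rest = lc[, 2])
    if (length(lang_levels) == 2) {
      X <- cbind(X, `language:loc_bs_bw` = xl * lc[, 1],
                 `language:loc_ww_rest` = xl * lc[, 2])
    }
  }
  list(X = X, xl = xl)
}

.cell_grid <- function(df, lang_levels) {
  cells <- unique(df[intersect(c("language", "location"), names(df))])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rownames(cells) <- NULL
  des <- .fixed_design(cells, lang_levels)
  cells$xl <- des$xl
  list(cells = cells, X = des$X)
}

.new_fit <- function(family, samples, control, lang_levels, cells, Xcells,
                     extra = list()) {
  conv_pars <- switch(family,
    mixture = c("mu_f", "delta", "eta", "sig_f", "sig_h"),
    c("b", "sigma", "r"))
  conv_pars <- intersect(conv_pars,
                         unique(sub("\\[.*", "", coda::varnames(samples))))
  conv <- .convergence_report(samples, conv_pars, control)
  structure(c(list(family = family, samples = samples, control = control,
                   lang_levels = lang_levels, cells = cells,
                   Xcells = Xcells, convergence = conv), extra),
            class = "scribeye_fit")
}

#' @export
print.scribeye_fit <- function(x, ...) {
  cat("<scribeye_fit>", x$family, "model,",
      length(x$samples), "chains x", nrow(x$samples[[1]]), "draws\n")
  cat("max Rhat:", round(suppressWarnings(max(x$convergence$rhat, na.rm = TRUE)), 3),
      " min ESS:", round(min(x$convergence$ess, na.rm = TRUE)), "\n")
  invisible(x)
}

.glmm_model_string <- function(family, K) {
  lik <- switch(family,
    binomial = "
    y[i] ~ dbin(p[i], trials[i])
    logit(p[i]) <- inprod(X[i,], b) + u0[pp[i]] + u1[pp[i]] * xl[i]",
    lognormal = "
    y[i] ~ dnorm(mu[i], tau_e)
    mu[i] <- inprod(X[i,], b) + u0[pp[i]] + u1[pp[i]] * xl[i]",
    negbinomial = "
    y[i] ~ dnegbin(q[i], r)
    q[i] <- r / (r + mu[i])
    log(mu[i]) <- inprod(X[i,], b) + u0[pp[i]] + u1[pp[i]] * xl[i]")
  extra <- switch(family,
    binomial = "",
    lognormal = "
  sigma ~ dnorm(0, 1) T(0,)
  tau_e <- pow(sigma, -2)",
    negbinomial = "
  r ~ dgamma(2, 0.05)")
  paste0("model {
  for (i in 1:N) {", lik, "
  }
  for (k in 1:K) { b[k] ~ dnorm(prior_mean[k], prior_prec[k]) }
  for (j in 1:P) {
    u0[j] ~ dnorm(0, tau_u0)
    u1[j] ~ dnorm(0, tau_u1)
  }
  s_u0 ~ dnorm(0, 1) T(0,)
  s_u1 ~ dnorm(0, 1) T(0,)
  tau_u0 <- pow(s_u0, -2)
  tau_u1 <- pow(s_u1, -2)", extra, "
}")
}

.fit_glmm <- function(family, df, y, control, lang_levels, trials = NULL) {
  des <- .fixed_design(df, lang_levels)
  pp <- as.integer(factor(df$participant))
  K <- ncol(des$X)
  data <- list(y = y, X = des$X, xl = des$xl, pp = pp, N = nrow(df),
               P = max(pp), K = K,
               prior_mean = rep(0, K), prior_prec = rep(1, K))
  if (family == "binomial") data$trials <- trials
  monitor <- c("b", "s_u0", "s_u1",
               switch(family, lognormal = "sigma", negbinomial = "r",
                      character(0)))
  samples <- .run_jags(.glmm_model_string(family, K), data, monitor, control)
  grid <- .cell_grid(df, lang_levels)
  .new_fit(family, samples, control, lang_levels, grid$cells, grid$X,
           extra = list(terms = colnames(des$X)))
}

# ---- model fits -----------------------------------------------------------

#' Fit a binomial mixed model for cell proportions
#'
#' Models successes/trials per participant x language x location cell with
#' logit-scale fixed effects for language, two location contrasts
#' (before-sentence vs before-word; within-word vs before-word-or-sentence)
#' and their interactions, plus participant random intercepts and
#' by-participant language slopes. Priors: Normal(0, 1) on logit-scale
#' effects, half-Normal(0, 1) on random-effect SDs. Used for the
#' proportion of editing transitions and for lookback probability.
#'
#' @param df data.frame with columns `participant`, `language`,
#'   `successes`, `trials`, and optionally `location`.
#' @param control a [sampler_control()].
#' @param lang_levels order of the language factor; the first level is
#'   coded +1/2.
#' @return a `scribeye_fit`; see [fixed_effects()] and [cell_estimates()].
#' @export
fit_binomial <- function(df, control = sampler_control(),
                         lang_levels = sort(unique(df$language))) {
  stopifnot(all(c("successes", "trials", "participant") %in% names(df)))
  .fit_glmm("binomial", df, as.integer(df$successes), control, lang_levels,
            trials = as.integer(df$trials))
}

#' Fit a lognormal mixed model for positive durations
#'
#' Linear mixed model on log duration with the fixed/random structure of
#' [fit_binomial()]. Cell means are reported in ms as
#' `exp(mu + sigma^2/2)`. Used for lookback durations.
#'
#' @param df data.frame with `participant`, `language`, `y` (duration, ms),
#'   optionally `location`.
#' @inheritParams fit_binomial
#' @return a `scribeye_fit`.
#' @export
fit_lognormal_lmm <- function(df, control = sampler_control(),
                              lang_levels = sort(unique(df$language))) {
  stopifnot(all(c("y", "participant") %in% names(df)), all(df$y > 0))
  if (stats::sd(log(df$y)) < 1e-10) {
    stop("degenerate input: log-durations have zero variance")
  }
  .fit_glmm("lognormal", df, log(df$y), control, lang_levels)
}

#' Fit a negative-binomial mixed model for counts
#'
#' Log-link negative-binomial with the fixed/random structure of
#' [fit_binomial()]; the dispersion parameter `r` has a Gamma(2, 0.05)
#' prior (large `r` recovers the Poisson limit). Used for the number of
#' words fixated and for lookback depth in sentences.
#'
#' @param df data.frame with `participant`, `language`, `y` (count),
#'   optionally `location`.
#' @inheritParams fit_binomial
#' @return a `scribeye_fit`.
#' @export
fit_negbinomial <- function(df, control = sampler_control(),
                            lang_levels = sort(unique(df$language))) {
  stopifnot(all(c("y", "participant") %in% names(df)),
            all(df$y >= 0), all(df$y == round(df$y)))
  .fit_glmm("negbinomial", df, as.integer(df$y), control, lang_levels)
}

#' Posterior summaries of fixed effects
#'
#' Reports each population-level coefficient with posterior mean, 95%
#' probability interval, and a Savage-Dickey Bayes factor against its
#' point-null (computed from the Normal(0, 1) prior and a Gaussian kernel
#' density estimate of the posterior at 0).
#'
#' @param fit a `scribeye_fit` from one of the `fit_*` functions.
#' @return data.frame with one row per coefficient.
#' @export
fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "scribeye_fit"), fit$family != "mixture")
  dm <- .draw_matrix(fit$samples)
  K <- length(fit$terms)
  b <- dm[, paste0("b[", seq_len(K), "]"), drop = FALSE]
  colnames(b) <- fit$terms
  out <- do.call(rbind, lapply(fit$terms, function(tm) {
    x <- b[, tm]
    bf <- if (tm == "intercept") NA_real_ else
      bayes_factor_savage_dickey(x, prior = list(mean = 0, sd = 1))$bf10
    data.frame(term = tm, estimate = mean(x),
               q2.5 = unname(stats::quantile(x, 0.025)),
               q97.5 = unname(stats::quantile(x, 0.975)),
               bf10 = bf)
  }))
  rownames(out) <- NULL
  out
}

#' Posterior cell estimates on the response scale
#'
#' Cell-level estimates (language x location) with 95% probability
#' intervals, transformed to the response scale: probabilities for the
#' binomial family, ms-scale means `exp(mu + sigma^2/2)` for the lognormal
#' family, counts for the negative binomial. Estimates are
#' population-level (at a typical participant, random effects at zero).
#'
#' @inheritParams fixed_effects
#' @return data.frame with one row per cell.
#' @export
cell_estimates <- function(fit) {
  stopifnot(inherits(fit, "scribeye_fit"), fit$family != "mixture")
  dm <- .draw_matrix(fit$samples)
  K <- ncol(fit$Xcells)
  b <- dm[, paste0("b[", seq_len(K), "]"), drop = FALSE]
  out <- fit$cells
  est <- matrix(NA_real_, nrow(out), 3)
  for (i in seq_len(nrow(out))) {
    lp <- as.vector(b %*% fit$Xcells[i, ])
    resp <- switch(fit$family,
      binomial = stats::plogis(lp),
      lognormal = exp(lp + dm[, "sigma"]^2 / 2),
      negbinomial = exp(lp))
    est[i, ] <- c(mean(resp), stats::quantile(resp, c(0.025, 0.975)))
  }
  out$estimate <- est[, 1]
  out$q2.5 <- est[, 2]
  out$q97.5 <- est[, 3]
  out$xl <- NULL
  out
}

# ---- the IKI mixture ------------------------------------------------------

.mixture_model_string <- "model {
  for (i in 1:N) {
    z[i] ~ dbern(theta[pp[i], cell[i]])
    mu[i] <- mu_f + u0[pp[i]] + z[i] * dcell[pp[i], cell[i]]
    y[i] ~ dlnorm(mu[i], tauz[z[i] + 1])
  }
  for (j in 1:P) {
    for (c in 1:C) {
      logit(theta[j, c]) <- eta[c] + v0[j] + v1[j] * xlc[c]
      dcell[j, c] <- delta[c] + w[j] * xlc[c]
    }
    u0[j] ~ dnorm(0, tau_u0)
    v0[j] ~ dnorm(0, tau_v0)
    v1[j] ~ dnorm(0, tau_v1)
    w[j] ~ dnorm(0, tau_w)
  }
  mu_f ~ dnorm(prior_mu_mean, prior_mu_prec)
  for (c in 1:C) {
    delta[c] ~ dnorm(0, 1) T(0,)
    eta[c] ~ dnorm(0, 1)
  }
  sig_f ~ dnorm(prior_sf_mean, prior_sf_prec) T(0,)
  sig_h ~ dnorm(prior_sh_mean, prior_sh_prec) T(0,)
  tauz[1] <- pow(sig_f, -2)
  tauz[2] <- pow(sig_h, -2)
  s_u0 ~ dnorm(0, 1) T(0,)
  s_v0 ~ dnorm(0, 1) T(0,)
  s_v1 ~ dnorm(0, 0.25) T(0,)
  s_w ~ dnorm(0, 0.25) T(0,)
  tau_u0 <- pow(s_u0, -2)
  tau_v0 <- pow(s_v0, -2)
  tau_v1 <- pow(s_v1, -2)
  tau_w <- pow(s_w, -2)
}"

#' Fit the two-component inter-keystroke-interval mixture model
#'
#' IKIs are modelled as a finite mixture of two lognormal distributions:
#' a fluent component whose location is constrained not to vary across
#' language or text location (but varies across participants, capturing
#' typing motor skill), and a hesitation component whose location is the
#' fluent location plus a positive shift per language x location cell.
#' Mixing proportions vary by cell and, on the logit scale, by participant
#' (intercept and language slope); a by-participant language slope also
#' enters the hesitation shift. Priors: Normal(log 150, 0.5) on the fluent
#' location, positive-truncated Normal(0, 1) on the shifts, Normal(0, 1)
#' on logit mixing cells, half-Normal on SDs.
#'
#' Component scales carry weakly-informative priors centred on a narrow
#' fluent component (`prior_sig_f`) and a broad hesitation component
#' (`prior_sig_h`); these aid identification — without them a single
#' lognormal can be split into two near-identical components — and are
#' overridable. Latent component indicators are initialised by
#' thresholding the IKIs at `init_split_ms`, which keeps the chains out of
#' the label-degenerate mode.
#'
#' @param transitions data.frame of writing transitions (already filtered
#'   and subsampled), with `participant`, `language`, `iki` (ms), and
#'   optionally `location`.
#' @param control a [sampler_control()].
#' @param lang_levels order of the language factor (first level +1/2).
#' @param init_split_ms threshold used to initialise component indicators.
#' @param prior_mu `c(mean, sd)` of the normal prior on the fluent
#'   log-location.
#' @param prior_sig_f,prior_sig_h `c(mean, sd)` of the positive-truncated
#'   normal priors on the component scales (log-scale SDs).
#' @return a `scribeye_fit` of family `mixture`; summarise with
#'   [iki_mixture_summary()].
#' @export
fit_iki_mixture <- function(transitions, control = sampler_control(),
                            lang_levels = sort(unique(transitions$language)),
                            init_split_ms = 250,
                            prior_mu = c(log(150), 0.5),
                            prior_sig_f = c(0.3, 0.2),
                            prior_sig_h = c(0.7, 0.2)) {
  df <- transitions
  if ("mode" %in% names(df)) df <- df[df$mode == "writing", , drop = FALSE]
  stopifnot(nrow(df) > 0, all(df$iki > 0))
  if (!"location" %in% names(df)) df$location <- "pre-word"
  cell_f <- interaction(df$language, df$location, drop = TRUE, sep = "|")
  cells <- do.call(rbind, strsplit(levels(cell_f), "|", fixed = TRUE))
  cells <- data.frame(language = cells[, 1], location = cells[, 2],
                      stringsAsFactors = FALSE)
  cells$xl <- if (length(lang_levels) == 2) {
    .lang_code(cells$language, lang_levels)
  } else 0
  pp <- as.integer(factor(df$participant))
  cell <- as.integer(cell_f)
  y <- df$iki

  zinit <- as.integer(y > init_split_ms)
  mu_init <- if (any(zinit == 0)) mean(log(y[zinit == 0])) else log(150)
  delta_init <- vapply(seq_len(nrow(cells)), function(c) {
    sel <- cell == c & zinit == 1
    if (any(sel)) max(0.1, mean(log(y[sel])) - mu_init) else 0.5
  }, 0)
  eta_init <- vapply(seq_len(nrow(cells)), function(c) {
    p <- mean(zinit[cell == c])
    stats::qlogis(min(max(p, 0.02), 0.98))
  }, 0)

  data <- list(y = y, pp = pp, cell = cell, N = length(y), P = max(pp),
               C = nrow(cells), xlc = cells$xl,
               prior_mu_mean = prior_mu[1], prior_mu_prec = 1 / prior_mu[2]^2,
               prior_sf_mean = prior_sig_f[1],
               prior_sf_prec = 1 / prior_sig_f[2]^2,
               prior_sh_mean = prior_sig_h[1],
               prior_sh_prec = 1 / prior_sig_h[2]^2)
  inits <- list(z = zinit, mu_f = mu_init, delta = delta_init,
                eta = eta_init, sig_f = 0.3, sig_h = 0.7)
  monitor <- c("mu_f", "delta", "eta", "sig_f", "sig_h",
               "s_u0", "s_v0", "s_v1", "s_w")
  samples <- .run_jags(.mixture_model_string, data, monitor, control, inits)
  .new_fit("mixture", samples, control, lang_levels, cells, NULL)
}

#' Summarise an IKI mixture fit on the millisecond and proportion scales
#'
#' Derives, per posterior draw: the fluent-component mean
#' `exp(mu_f + sigma_f^2/2)`, per-cell hesitation means
#' `exp(mu_f + delta_c + sigma_h^2/2)`, and per-cell mixing proportions,
#' all population-level (participant effects at zero). Language effects
#' per location are contrasts first-level minus second-level on the log
#' (durations) and logit (proportions) scales, with Savage-Dickey Bayes
#' factors computed against their induced priors.
#'
#' @param fit a mixture `scribeye_fit` from [fit_iki_mixture()].
#' @return list with `fluent` (data.frame), `cells` (per language x
#'   location: hesitation mean and mixing proportion with 95% PIs), and
#'   `effects` (per location, when both languages are present).
#' @export
iki_mixture_summary <- function(fit) {
  stopifnot(inherits(fit, "scribeye_fit"), fit$family == "mixture")
  dm <- .draw_matrix(fit$samples)
  cells <- fit$cells
  C <- nrow(cells)
  # coda drops the [1] suffix on length-one parameter vectors
  col_of <- function(base, c) {
    nm <- paste0(base, "[", c, "]")
    if (nm %in% colnames(dm)) dm[, nm] else dm[, base]
  }
  mu_sw <- dm[, "mu_f"]
  sig_f <- dm[, "sig_f"]; sig_h <- dm[, "sig_h"]
  fluent_draws <- exp(mu_sw + sig_f^2 / 2)
  qs <- function(x) c(mean(x), stats::quantile(x, c(0.025, 0.975)))
  fluent <- data.frame(estimate_ms = mean(fluent_draws),
                       q2.5 = stats::quantile(fluent_draws, 0.025),
                       q97.5 = stats::quantile(fluent_draws, 0.975),
                       row.names = NULL)
  delta_sw <- sapply(seq_len(C), function(c) col_of("delta", c))
  eta_sw <- sapply(seq_len(C), function(c) col_of("eta", c))
  hes <- exp(mu_sw + delta_sw + sig_h^2 / 2)
  th <- stats::plogis(eta_sw)
  cell_out <- cells[c("language", "location")]
  cell_out$hesitation_mean_ms <- colMeans(hes)
  cell_out$hes_q2.5 <- apply(hes, 2, stats::quantile, 0.025)
  cell_out$hes_q97.5 <- apply(hes, 2, stats::quantile, 0.975)
  cell_out$mixing_proportion <- colMeans(th)
  cell_out$mix_q2.5 <- apply(th, 2, stats::quantile, 0.025)
  cell_out$mix_q97.5 <- apply(th, 2, stats::quantile, 0.975)

  effects <- NULL
  if (length(fit$lang_levels) == 2) {
    locs <- unique(cells$location)
    eff_rows <- list()
    n_prior <- 20000L
    half_n <- function(n) abs(stats::rnorm(n))
    for (loc in locs) {
      i1 <- which(cells$location == loc & cells$language == fit$lang_levels[1])
      i2 <- which(cells$location == loc & cells$language == fit$lang_levels[2])
      if (length(i1) != 1 || length(i2) != 1) next
      d_eff <- delta_sw[, i1] - delta_sw[, i2]
      p_eff <- eta_sw[, i1] - eta_sw[, i2]
      prior_d <- half_n(n_prior) - half_n(n_prior)
      prior_p <- stats::rnorm(n_prior, 0, sqrt(2))
      eff_rows[[loc]] <- data.frame(
        location = loc,
        duration_effect = mean(d_eff),
        dur_q2.5 = stats::quantile(d_eff, 0.025),
        dur_q97.5 = stats::quantile(d_eff, 0.975),
        dur_bf10 = bayes_factor_savage_dickey(d_eff, prior = prior_d)$bf10,
        proportion_effect = mean(p_eff),
        prop_q2.5 = stats::quantile(p_eff, 0.025),
        prop_q97.5 = stats::quantile(p_eff, 0.975),
        prop_bf10 = bayes_factor_savage_dickey(p_eff, prior = prior_p)$bf10)
    }
    effects <- do.call(rbind, eff_rows)
    rownames(effects) <- NULL
  }
  rownames(cell_out) <- NULL
  list(fluent = fluent, cells = cell_out, effects = effects)
}

# ---- multivariate text model ----------------------------------------------

#' Fit the multivariate text-measures model
#'
#' Jointly models a set of text measures as a function of language, with
#' participant intercepts per measure. Positive measures are
#' log-transformed, then each measure is standardised (z-scored), so the
#' language coefficients are standardised effects comparable across
#' measures. Unlike the duration/proportion models (whose effects contrast
#' first minus second condition), the text-measure effect is the change
#' *from* the first condition *to* the second: a measure that is lower in
#' the second condition prints a negative effect.
#'
#' @param df data.frame with `participant`, `language`, and one numeric
#'   column per measure.
#' @param measures names of the measure columns (default: all numeric
#'   columns other than `participant`).
#' @param control a [sampler_control()].
#' @param lang_levels order of the language factor.
#' @return list with `effects` (per measure: standardised language effect,
#'   95% PI, Savage-Dickey BF10 against Normal(0, 1)) and `samples`.
#' @export
fit_multivariate_text_model <- function(df, measures = NULL,
                                        control = sampler_control(),
                                        lang_levels = sort(unique(df$language))) {
  if (is.null(measures)) {
    measures <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], "participant")
  }
  Y <- as.matrix(df[measures])
  for (m in seq_along(measures)) {
    col <- Y[, m]
    if (all(col > 0, na.rm = TRUE)) col <- log(col)
    Y[, m] <- as.vector(scale(col))
  }
  xl <- -.lang_code(df$language, lang_levels)   # second condition +1/2
  pp <- as.integer(factor(df$participant))
  model <- "model {
  for (i in 1:N) {
    for (m in 1:M) {
      y[i, m] ~ dnorm(b0[m] + bL[m] * xl[i] + u[pp[i], m], tau_e[m])
    }
  }
  for (m in 1:M) {
    b0[m] ~ dnorm(0, 1)
    bL[m] ~ dnorm(0, 1)
    sigma[m] ~ dnorm(0, 1) T(0,)
    tau_e[m] <- pow(sigma[m], -2)
    s_u[m] ~ dnorm(0, 1) T(0,)
    tau_u[m] <- pow(s_u[m], -2)
    for (j in 1:P) { u[j, m] ~ dnorm(0, tau_u[m]) }
  }
}"
  samples <- .run_jags(model, list(y = Y, xl = xl, pp = pp, N = nrow(Y),
                                   M = length(measures), P = max(pp)),
                       c("b0", "bL", "sigma", "s_u"), control)
  dm <- .draw_matrix(samples)
  effects <- do.call(rbind, lapply(seq_along(measures), function(m) {
    x <- dm[, paste0("bL[", m, "]")]
    data.frame(measure = measures[m], effect = mean(x),
               q2.5 = unname(stats::quantile(x, 0.025)),
               q97.5 = unname(stats::quantile(x, 0.975)),
               bf10 = bayes_factor_savage_dickey(
                 x, prior = list(mean = 0, sd = 1))$bf10)
  }))
  rownames(effects) <- NULL
  list(effects = effects, samples = samples)
}
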