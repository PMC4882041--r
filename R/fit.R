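#' Sampler configuration presets
#'
#' The `"paper"` preset (4 chains of 50,000 iterations, first half discarded
#' as burn-in, every 5th kept) matches the full-length runs used for the
#' headline meta-analytic estimates; `"test"` scales the chain length down
#' to 5,000 iterations with the same burn-in and thinning fractions, which
#' is ample for this conditionally conjugate model and keeps automated runs
#' fast.
#'
#' @param preset `"test"` or `"paper"`.
#' @param chains,iterations,thin Optional overrides.
#' @return A list with `chains`, `iterations`, `burn`, `thin`.
#' @export
sampler_config <- function(preset = c("test", "paper"), chains = 4,
                           iterations = NULL, thin = 5) {
  preset <- match.arg(preset)
  if (is.null(iterations)) iterations <- if (preset == "paper") 50000L else 5000L
  iterations <- as.integer(iterations)
  burn <- iterations %/% 2L
  list(preset = preset, chains = as.integer(chains), iterations = iterations,
       burn = burn, thin = as.integer(thin))
}

#' Fit the three-level hierarchical model
#'
#' Fits `y = mu + P_phylum + S_species + error` with normal components at
#' every level, parameterized by hierarchical centering: species means are
#' centered on their phylum mean, phylum means on a weakly informative
#' common location `mu ~ N(mean(y), (10 sd(y))^2)`. The three standard
#' deviations (among phyla, among species within phyla, residual) carry
#' independent half-Cauchy(0, `5 sd(y)`) priors and are updated by slice
#' sampling; all location parameters have conjugate Gibbs updates.
#' Initialization is data-derived (group sample means, pooled SDs), jittered
#' per chain, and observations are canonically reordered internally so the
#' fit is invariant to input row order.
#'
#' @param data A data frame with the response and grouping columns
#'   (e.g. an observation tibble, or a ratio table with `log_value`).
#' @param response Name of the response column.
#' @param species,phylum Names of the grouping columns; every species must
#'   nest in exactly one phylum.
#' @param config A list from [sampler_config()].
#' @param seed Integer seed; identical inputs and seed give identical draws.
#' @param fix Optional named list fixing parameters instead of sampling them:
#'   any of `sigma_phylum`, `sigma_species`, `sigma_resid`, `mu`.
#' @param keep_species Keep species-level draws (needed by
#'   [shrinkage_check()]).
#' @param rhat_threshold Convergence flag threshold for split-R-hat.
#' @return An object of class `macro_fit`.
#' @export
fit_hierarchical <- function(data, response = "value", species = "species_key",
                             phylum = "phylum", config = sampler_config("test"),
                             seed = 1L, fix = NULL, keep_species = TRUE,
                             rhat_threshold = 1.01) {
  y <- data[[response]]
  if (length(y) == 0) stop("no observations to fit")
  if (!all(is.finite(y))) stop("response contains non-finite values")
  sp_chr <- as.character(data[[species]])
  ph_chr <- as.character(data[[phylum]])

  sp_levels <- sort(unique(sp_chr))
  sp_idx <- match(sp_chr, sp_levels)
  ph_of_sp_chr <- vapply(sp_levels, function(s) {
    u <- unique(ph_chr[sp_chr == s])
    if (length(u) != 1) stop("species '", s, "' is not nested in a single phylum")
    u
  }, character(1))
  ph_levels <- sort(unique(ph_of_sp_chr))
  ph_of_sp <- match(ph_of_sp_chr, ph_levels)
  P <- length(ph_levels); S <- length(sp_levels)

  # canonical observation order makes floating-point reductions, and hence
  # the chains, independent of input row order
  ord <- order(sp_idx, y)
  y <- y[ord]; sp_idx <- sp_idx[ord]

  y_mean <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- max(abs(y_mean), 1)
  prior_scale <- rep(5 * y_scale, 3)
  m0 <- y_mean; v0 <- 10 * y_scale
  sigma_floor <- 1e-9 * y_scale

  sp_means <- as.numeric(tapply(y, sp_idx, mean))
  ph_means <- as.numeric(tapply(sp_means, ph_of_sp, mean))
  resid0 <- y - sp_means[sp_idx]
  sig0 <- c(
    max(sd(ph_means), 0.1 * y_scale, na.rm = TRUE),
    max(sd(sp_means - ph_means[ph_of_sp]), 0.1 * y_scale, na.rm = TRUE),
    max(sd(resid0), 0.1 * y_scale, na.rm = TRUE)
  )
  sig0[!is.finite(sig0)] <- y_scale

  fix <- fix %||% list()
  fix_sigma <- c(!is.null(fix$sigma_phylum), !is.null(fix$sigma_species),
                 !is.null(fix$sigma_resid))
  fixed_sigma <- c(fix$sigma_phylum %||% 0, fix$sigma_species %||% 0,
                   fix$sigma_resid %||% 0)
  fix_mu <- !is.null(fix$mu)
  fixed_mu <- fix$mu %||% 0

  n_keep <- length(seq(config$burn, config$iterations - 1L, by = config$thin))
  mu_draws <- matrix(NA_real_, n_keep, config$chains)
  phi_draws <- array(NA_real_, c(n_keep, config$chains, P))
  sigma_draws <- array(NA_real_, c(n_keep, config$chains, 3))
  theta_draws <- if (keep_species) array(NA_real_, c(n_keep, config$chains, S)) else NULL

  set.seed(as.integer(seed))
  for (ch in seq_len(config$chains)) {
    jitter_scale <- 0.1 * y_scale
    init_theta <- sp_means + rnorm(S, 0, jitter_scale)
    init_phi <- ph_means + rnorm(P, 0, jitter_scale)
    init_mu <- mean(ph_means) + rnorm(1, 0, jitter_scale)
    init_sigma <- sig0 * exp(rnorm(3, 0, 0.1))
    res <- gibbs_hierarchy_cpp(
      y, sp_idx - 1L, ph_of_sp - 1L, P,
      config$iterations, config$burn, config$thin,
      m0, v0, prior_scale,
      init_theta, init_phi, init_mu, init_sigma,
      fix_sigma, fixed_sigma, fix_mu, fixed_mu,
      sigma_floor, keep_species
    )
    mu_draws[, ch] <- res$mu
    phi_draws[, ch, ] <- res$phi
    sigma_draws[, ch, ] <- res$sigma
    if (keep_species) theta_draws[, ch, ] <- res$theta
  }
  dimnames(phi_draws)[[3]] <- ph_levels
  dimnames(sigma_draws)[[3]] <- c("sigma_phylum", "sigma_species", "sigma_resid")
  if (keep_species) dimnames(theta_draws)[[3]] <- sp_levels

  n_by_sp <- as.integer(table(factor(sp_idx, levels = seq_len(S))))
  n_by_ph <- as.integer(tapply(n_by_sp, ph_of_sp, sum))

  fit <- structure(list(
    draws = list(mu = mu_draws, phylum = phi_draws, species = theta_draws,
                 sigma = sigma_draws),
    levels = list(phylum = ph_levels, species = sp_levels,
                  phylum_of_species = ph_of_sp),
    n_obs = list(total = length(y),
                 by_phylum = setNames(n_by_ph, ph_levels),
                 by_species = setNames(n_by_sp, sp_levels)),
    data_stats = list(mean = y_mean, sd = y_scale,
                      species_means = setNames(sp_means, sp_levels)),
    response = response,
    config = c(config, list(seed = as.integer(seed), fix = fix,
                            rhat_threshold = rhat_threshold))
  ), class = "macro_fit")
  fit$convergence <- diagnose(fit)
  fit
}

# flatten [iter, chain] or [iter, chain, k] draws to [iter*chain(, k)]
.flatten <- function(x) {
  if (length(dim(x)) == 3) {
    out <- apply(x, 3, as.numeric)
    colnames(out) <- dimnames(x)[[3]]
    out
  } else {
    as.numeric(x)
  }
}

#' Extract flattened posterior draws from a fit
#'
#' @param fit A `macro_fit`.
#' @return `phylum_draws()`: a draws-by-phylum matrix; `sigma_draws()`: a
#'   draws-by-3 matrix (`sigma_phylum`, `sigma_species`, `sigma_resid`);
#'   `species_draws()`: a draws-by-species matrix.
#' @export
phylum_draws <- function(fit) .flatten(fit$draws$phylum)

#' @rdname phylum_draws
#' @export
sigma_draws <- function(fit) .flatten(fit$draws$sigma)

#' @rdname phylum_draws
#' @export
species_draws <- function(fit) {
  if (is.null(fit$draws$species)) stop("fit was run with keep_species = FALSE")
  .flatten(fit$draws$species)
}

.split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  if (half < 1L) return(mat)
  do.call(cbind, lapply(seq_len(ncol(mat)), function(j) {
    cbind(mat[seq_len(half), j], mat[seq.int(n - half + 1L, n), j])
  }))
}

.split_rhat <- function(mat) {
  sm <- .split_chains(mat)
  m <- ncol(sm); n <- nrow(sm)
  if (m < 2L || n < 4L) return(NA_real_)
  means <- colMeans(sm)
  vars <- apply(sm, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(mat) {
  sm <- .split_chains(mat)
  m <- ncol(sm); n <- nrow(sm)
  if (n < 4L) return(NA_real_)
  vars <- apply(sm, 2, var)
  W <- mean(vars)
  B <- if (m > 1) n * var(colMeans(sm)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(m * n)
  lag_max <- min(n - 2L, 500L)
  acov <- sapply(seq_len(m), function(j) {
    as.numeric(acf(sm[, j], lag.max = lag_max, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf)
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # Geyer initial monotone positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(npair)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  max(m * n / tau, 1)
}

#' Convergence diagnostics for a fit
#'
#' Computes split-R-hat and effective sample size for every monitored
#' parameter (the location, each phylum mean and the three SDs) from the
#' kept draws; deterministic given the draws. The report passes when all
#' R-hat values are below the configured threshold and the design identifies
#' all levels (at least two phyla and two species).
#'
#' @param fit A `macro_fit` (at least 2 chains for R-hat).
#' @return A list of class `macro_convergence` with a per-parameter tibble
#'   and a `pass` flag.
#' @export
diagnose <- function(fit) {
  stopifnot(inherits(fit, "macro_fit"))
  mats <- c(
    list(mu = fit$draws$mu),
    setNames(lapply(seq_along(fit$levels$phylum), function(p) fit$draws$phylum[, , p, drop = TRUE]),
             paste0("phylum:", fit$levels$phylum)),
    setNames(lapply(1:3, function(k) fit$draws$sigma[, , k, drop = TRUE]),
             dimnames(fit$draws$sigma)[[3]])
  )
  single_chain <- ncol(fit$draws$mu) < 2
  tab <- tibble::tibble(
    parameter = names(mats),
    rhat = vapply(mats, function(m) {
      m <- as.matrix(m); if (single_chain) NA_real_ else .split_rhat(m)
    }, numeric(1)),
    ess = vapply(mats, function(m) .ess(as.matrix(m)), numeric(1))
  )
  notes <- character()
  if (single_chain) notes <- c(notes, "single chain: split-R-hat unavailable")
  if (length(fit$levels$phylum) < 2) {
    notes <- c(notes, "fewer than 2 phyla: among-phylum variance weakly identified")
  }
  if (length(fit$levels$species) < 2) {
    notes <- c(notes, "fewer than 2 species: among-species variance weakly identified")
  }
  if (fit$n_obs$total <= length(fit$levels$species)) {
    notes <- c(notes, "at most one observation per species: residual variance weakly identified")
  }
  threshold <- fit$config$rhat_threshold %||% 1.01
  rhat_ok <- !single_chain && all(is.finite(tab$rhat)) && all(tab$rhat < threshold)
  structure(list(parameters = tab, pass = rhat_ok && length(notes) == 0,
                 threshold = threshold, notes = notes),
            class = "macro_convergence")
}

#' @export
print.macro_convergence <- function(x, ...) {
  cat("convergence:", if (x$pass) "PASS" else "FLAGGED",
      sprintf("(max split-R-hat %.4f, min ESS %.0f)\n",
              suppressWarnings(max(x$parameters$rhat, na.rm = TRUE)),
              suppressWarnings(min(x$parameters$ess, na.rm = TRUE))))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
print.macro_fit <- function(x, ...) {
  cat("hierarchical fit of '", x$response, "': ",
      x$n_obs$total, " observations, ",
      length(x$levels$species), " species, ",
      length(x$levels$phylum), " phyla\n", sep = "")
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d kept draws\n",
              x$config$chains, x$config$iterations, x$config$burn,
              x$config$thin, nrow(x$draws$mu) * ncol(x$draws$mu)))
  print(x$convergence)
  invisible(x)
}

#' Partial-pooling (shrinkage) diagnostics per species
#'
#' For every species, compares the posterior species-mean estimate with the
#' raw sample mean, both measured as deviations from the posterior phylum
#' median. Partial pooling shrinks species estimates toward their phylum
#' mean, most strongly for sparsely observed species.
#'
#' @param fit A `macro_fit` run with `keep_species = TRUE`.
#' @param mc_tol Monte-Carlo slack added to the raw deviation when setting
#'   the `shrunk` flag.
#' @return A tibble with per-species posterior and raw deviations.
#' @export
shrinkage_check <- function(fit, mc_tol = 2 * fit$data_stats$sd / sqrt(nrow(fit$draws$mu) * ncol(fit$draws$mu))) {
  th <- species_draws(fit)
  ph <- phylum_draws(fit)
  ph_med <- apply(ph, 2, median)[fit$levels$phylum_of_species]
  post_med <- apply(th, 2, median)
  raw <- fit$data_stats$species_means
  tibble::tibble(
    species_key = fit$levels$species,
    phylum = fit$levels$phylum[fit$levels$phylum_of_species],
    n_obs = as.integer(fit$n_obs$by_species),
    posterior_median = post_med,
    raw_mean = as.numeric(raw),
    phylum_median = ph_med,
    posterior_deviation = abs(post_med - ph_med),
    raw_deviation = abs(as.numeric(raw) - ph_med),
    shrunk = abs(post_med - ph_med) <= abs(as.numeric(raw) - ph_med) + mc_tol
  )
}
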