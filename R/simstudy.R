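## Monte-Carlo study comparing iQTL, qQTL, and xQTL detection under the
## genotype-by-factor interaction model
##   Y = b0 + bG G + bF F + bI G x F + C'bC + e,
## with G and F drawn as HWE dosages, 45 standard-normal covariates, and
## Gaussian residuals, plus the directionality and quantile-heterogeneity
## summaries of the detected signals.

#' Simulation study configuration
#'
#' Default parameters of the interaction-model Monte-Carlo study: n = 400
#' individuals, genotype MAF 0.1, factor MAF 0.15, 45 iid N(0,1) covariates,
#' residual variance 0.2667, main effects {0, 0.15, 0.3} crossed with
#' interaction effects {0, +/-0.1, ..., +/-0.8}, 1000 replicates per cell,
#' detection thresholds 0.05 and 1e-6. Covariate coefficients default to
#' zero (covariates are projected out by every test, so the summaries are
#' insensitive to them); `draw_beta_c = TRUE` instead draws them once from
#' N(0, 0.1^2) at `seed`. Heterogeneity slopes are estimated at the same
#' 19-level grid the quantile scan tests, matching the detection machinery.
#'
#' @param n sample size.
#' @param p_g,p_f genotype and factor minor-allele frequencies.
#' @param beta_g_grid,beta_i_grid effect grids.
#' @param beta_f factor main effect.
#' @param resid_var residual variance (`resid_sd_mode = "sd"` reinterprets it
#'   as a standard deviation for sensitivity analysis).
#' @param n_covar number of covariates.
#' @param n_reps replicates per configuration.
#' @param alphas detection thresholds.
#' @param het_taus quantile levels for the heterogeneity slope profile.
#' @param draw_beta_c draw covariate coefficients from N(0, 0.1^2)?
#' @param seed seed for the one-time covariate-coefficient draw.
#' @param resid_sd_mode "var" (default) or "sd".
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n = 400L, p_g = 0.1, p_f = 0.15,
                       beta_g_grid = c(0, 0.15, 0.3),
                       beta_i_grid = c(0, seq(-0.8, -0.1, by = 0.1),
                                       seq(0.1, 0.8, by = 0.1)),
                       beta_f = 0, resid_var = 0.2667, n_covar = 45L,
                       n_reps = 1000L, alphas = c(0.05, 1e-6),
                       het_taus = seq(0.05, 0.95, by = 0.05),
                       draw_beta_c = FALSE, seed = 1L,
                       resid_sd_mode = c("var", "sd")) {
  resid_sd_mode <- match.arg(resid_sd_mode)
  noise_sd <- if (resid_sd_mode == "var") sqrt(resid_var) else resid_var
  beta_c <- rep(0, n_covar)
  if (draw_beta_c) {
    set.seed(seed)
    beta_c <- stats::rnorm(n_covar, 0, 0.1)
  }
  structure(list(n = n, p_g = p_g, p_f = p_f, beta_g_grid = beta_g_grid,
                 beta_i_grid = beta_i_grid, beta_f = beta_f,
                 noise_sd = noise_sd, n_covar = n_covar, beta_c = beta_c,
                 n_reps = n_reps, alphas = alphas, het_taus = het_taus),
            class = "SimConfig")
}

## Deterministic replicate seed: unique for master mod 4096, up to 64 cells
## and 8192 replicates per cell; always < 2^31.
.rep_seed <- function(master, cell, rep) {
  as.integer((master %% 4096) * 524288 + (cell %% 64) * 8192 + (rep %% 8192))
}

#' Run one Monte-Carlo replicate
#'
#' Simulates (G, F, C, Y) under the interaction model at the given effects,
#' then analyzes the single variant three ways: the linear test (OLS slope),
#' the 19-level quantile rank-score scan with Cauchy combination, and the
#' interaction model fit on the inverse-normal-transformed response. When the
#' combined quantile p-value falls below `slopes_if_below`, per-quantile
#' slopes are refitted at `config$het_taus` and the Chatterjee heterogeneity
#' p-value is recorded. Monomorphic genotype or constant-factor draws are
#' redrawn with an incremented seed (count recorded).
#'
#' @param config a [sim_config()].
#' @param beta_g,beta_i effect sizes for this cell.
#' @param rep_seed replicate RNG seed.
#' @param slopes_if_below compute heterogeneity slopes when p_qqtl is below
#'   this value (default 0.05; set 0 to skip, 1 to always compute).
#' @return one-row data.frame(p_xqtl, p_qqtl, p_iqtl, p_g, beta_g_hat,
#'   beta_i_hat, direction, p_xi, redraws).
#' @export
run_replicate <- function(config, beta_g, beta_i, rep_seed,
                          slopes_if_below = 0.05) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n
  redraws <- 0L
  repeat {
    set.seed(rep_seed + redraws * 1000003L)
    g <- stats::rbinom(n, 2L, config$p_g)
    f <- stats::rbinom(n, 2L, config$p_f)
    if (stats::var(g) > 0 && stats::var(f) > 0) break
    redraws <- redraws + 1L
  }
  C <- matrix(stats::rnorm(n * config$n_covar), n, config$n_covar)
  eps <- stats::rnorm(n, sd = config$noise_sd)
  y <- beta_g * g + config$beta_f * f + beta_i * g * f +
    as.numeric(C %*% config$beta_c) + eps

  p_x <- .ols_scan(y, matrix(g, ncol = 1), C)$p
  scan <- map_qqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), C,
                   method = "fn")
  p_q <- scan$pairs$p_nominal[1]
  iq <- map_iqtl(y, matrix(g, ncol = 1, dimnames = list(NULL, "v1")), f, C,
                 maf_min = 0)
  p_xi <- NA_real_
  if (!is.na(p_q) && p_q < slopes_if_below) {
    sl <- quantile_slopes(y, g, C, taus = config$het_taus, method = "fn")
    p_xi <- chatterjee_xi(config$het_taus, sl)$p
  }
  data.frame(p_xqtl = p_x, p_qqtl = p_q, p_iqtl = iq$p_nominal[1],
             p_g = iq$p_g[1], beta_g_hat = iq$beta_g[1],
             beta_i_hat = iq$beta_i[1],
             direction = iq$direction[1], p_xi = p_xi, redraws = redraws,
             stringsAsFactors = FALSE)
}

#' Run the Monte-Carlo grid
#'
#' Runs [run_replicate()] over a grid of (beta_g, beta_i) cells and
#' aggregates detection and classification proportions per cell and per
#' detection threshold.
#'
#' @param config a [sim_config()].
#' @param cells data.frame(beta_g, beta_i); defaults to the full configured
#'   grid.
#' @param n_reps replicates per cell (default `config$n_reps`).
#' @param seed master seed; replicate seeds derive from it deterministically.
#' @param slopes_if_below see [run_replicate()]; default 0.05 computes
#'   heterogeneity for every quantile-test detection at the lenient threshold.
#' @return a `SimSummary` data.frame, one row per (cell, alpha), with
#'   detection proportions, joint qQTL/xQTL category proportions, and the
#'   fraction of quantile-test detections with Chatterjee heterogeneity below
#'   the matched threshold.
#' @export
run_grid <- function(config = sim_config(), cells = NULL,
                     n_reps = config$n_reps, seed = 1L,
                     slopes_if_below = 0.05) {
  if (is.null(cells))
    cells <- expand.grid(beta_g = config$beta_g_grid,
                         beta_i = config$beta_i_grid)
  out <- vector("list", nrow(cells) * length(config$alphas))
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    reps <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      run_replicate(config, cells$beta_g[ci], cells$beta_i[ci],
                    rep_seed = .rep_seed(seed, ci, r),
                    slopes_if_below = slopes_if_below)
    }))
    for (alpha in config$alphas) {
      qd <- reps$p_qqtl < alpha
      xd <- reps$p_xqtl < alpha
      det_q <- sum(qd)
      het <- if (det_q > 0) mean(reps$p_xi[qd] < alpha, na.rm = FALSE) else NA_real_
      row <- row + 1L
      out[[row]] <- data.frame(
        beta_g = cells$beta_g[ci], beta_i = cells$beta_i[ci], alpha = alpha,
        n_reps = n_reps,
        prop_iqtl = mean(reps$p_iqtl < alpha),
        prop_qqtl = mean(qd), prop_xqtl = mean(xd),
        prop_shared = mean(qd & xd),
        prop_qqtl_only = mean(qd & !xd),
        prop_xqtl_only = mean(!qd & xd),
        prop_neither = mean(!qd & !xd),
        n_qqtl_detected = det_q,
        prop_het_given_qqtl = het,
        prop_amplifying = mean(reps$direction == "amplifying"),
        prop_counteracting = mean(reps$direction == "counteracting"),
        prop_uncertain = mean(reps$direction == "uncertain"))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("SimSummary", "data.frame")
  res
}

#' Amplifying configuration grid
#'
#' Cells with a positive main effect and a same-sign interaction effect:
#' beta_g in {0.15, 0.3} crossed with beta_i in {0.1, ..., 0.8}.
#'
#' @param strong_only restrict to the strong-interaction cells
#'   (beta_g = 0.3, beta_i in {0.6, 0.7, 0.8}).
#' @return data.frame(beta_g, beta_i).
#' @export
amplifying_cells <- function(strong_only = FALSE) {
  if (strong_only)
    return(expand.grid(beta_g = 0.3, beta_i = c(0.6, 0.7, 0.8)))
  expand.grid(beta_g = c(0.15, 0.3), beta_i = seq(0.1, 0.8, by = 0.1))
}

#' Summaries of the simulation grid
#'
#' `sim_shared_rate`: proportion of replicates detected by BOTH the combined
#' quantile test and the linear test, pooled over the given cells at one
#' threshold. `sim_het_rate`: fraction of quantile-test detections with
#' Chatterjee heterogeneity below the matched threshold, averaged across
#' cells (cells without detections are excluded from the average).
#'
#' @param summary a `SimSummary` from [run_grid()].
#' @param alpha detection threshold to summarize at.
#' @return a proportion in [0, 1].
#' @export
sim_shared_rate <- function(summary, alpha = 0.05) {
  s <- summary[summary$alpha == alpha, ]
  if (nrow(s) == 0L) stop("no rows at alpha = ", alpha)
  stats::weighted.mean(s$prop_shared, s$n_reps)
}

#' @rdname sim_shared_rate
#' @param min_detections cells with fewer quantile-test detections than this
#'   are excluded from the average (their conditional fraction is too noisy
#'   to estimate; default 1 = exclude only empty cells).
#' @export
sim_het_rate <- function(summary, alpha = 0.05, min_detections = 1L) {
  s <- summary[summary$alpha == alpha &
                 summary$n_qqtl_detected >= min_detections, ]
  if (nrow(s) == 0L) return(NA_real_)
  mean(s$prop_het_given_qqtl)
}
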