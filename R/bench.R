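# Monte Carlo benchmark harness: error vs noise level, grid-size scaling,
# prior mismatch, and the template-bias ("Einstein from Noise") study.

.new_bench <- function(trials, summary, experiment, meta = list()) {
  structure(list(trials = trials, summary = summary,
                 experiment = experiment, meta = meta),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat("<bench_result>", x$experiment, ":", nrow(x$trials), "trial rows\n")
  print(x$summary, n = 20)
  invisible(x)
}

#' @export
tidy.bench_result <- function(x, ...) x$trials

#' @export
glance.bench_result <- function(x, ...) x$summary

.summarize_trials <- function(trials, ...) {
  trials |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_d_G = mean(.data$d_G), se_d_G = sd(.data$d_G) / sqrt(dplyr::n()),
      mean_d_F2 = mean(.data$d_F^2),
      se_d_F2 = sd(.data$d_F^2) / sqrt(dplyr::n()),
      .groups = "drop")
}

# derive a stream of sub-seeds from one master seed (kept below 2^31)
.subseeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# ---- error vs SNR -----------------------------------------------------------

#' Estimation error versus noise level
#'
#' For each SNR, simulates `n_trials` observations of `V` under the
#' no-projection 3D model with ground-truth rotations drawn from
#' `truth_prior`, runs the requested estimators on a shared template bank,
#' and records chordal and geodesic errors per trial.
#'
#' @param V Reference [vol3].
#' @param snr Vector of signal-to-noise ratios (mean signal power / sigma^2).
#' @param L Rotation-grid size target.
#' @param n_trials Trials per SNR (`>= 2`).
#' @param methods Subset of `c("mle", "map", "mmse")`.
#' @param truth_prior Prior the true rotations are drawn from.
#' @param prior Prior assumed by the Bayes estimators.
#' @param seed Master seed; every cell derives its own sub-seed.
#' @return A `bench_result` with `$trials` (long tibble: `snr`, `sigma`,
#'   `method`, `trial`, `d_F`, `d_G`) and `$summary` (per-cell means and
#'   standard errors).
#' @export
run_error_vs_snr <- function(V, snr, L = 1000, n_trials = 200,
                             methods = c("mle", "mmse"),
                             truth_prior = prior_haar(),
                             prior = prior_haar(), seed = 1L) {
  stopifnot(n_trials >= 2, length(snr) >= 1)
  grid <- so3_grid(L)
  bank <- build_templates(V, grid, "no_projection_3d")
  seeds <- .subseeds(seed, length(snr))
  trials <- purrr::map2(snr, seeds, function(s, sd_i) {
    sig <- sigma_for_snr(V, s)
    b <- simulate_batch(V, truth_prior, sig, "no_projection_3d", n_trials,
                        seed = sd_i)
    .batch_errors(b$Y, b$g_true, bank, sig, methods = methods, prior = prior) |>
      dplyr::mutate(snr = s, sigma = sig)
  }) |> dplyr::bind_rows()
  .new_bench(trials, .summarize_trials(trials, .data$snr, .data$method),
             "error_vs_snr", list(L = grid$L, seed = seed))
}

# ---- grid scaling -----------------------------------------------------------

#' Grid-resolution scaling of the estimation error
#'
#' At a fixed (typically high) SNR, measures the mean geodesic error of the
#' MLE and MMSE estimators on grids of increasing size and fits the log-log
#' regression of mean error on `L`. In the noise-free limit the error is
#' pure discretization, and with three rotational degrees of freedom the
#' per-axis resolution improves as `L^(1/3)`, so the expected slope is -1/3.
#' Confidence intervals come from a trial bootstrap.
#'
#' @param V Reference [vol3].
#' @param L_values At least 3 grid sizes, ideally spanning a decade.
#' @param snr Signal-to-noise ratio of the observations.
#' @param n_trials Trials per grid size.
#' @param methods Estimators to fit.
#' @param seed Master seed.
#' @param n_boot Bootstrap resamples for the slope CI (default 500).
#' @return A `bench_result`; `$fit` holds a tibble with `method`, `slope`,
#'   `ci_lo`, `ci_hi`.
#' @export
run_grid_scaling <- function(V, L_values = c(300, 1000, 3000), snr = 1e3,
                             n_trials = 300, methods = c("mle", "mmse"),
                             seed = 1L, n_boot = 500L) {
  if (length(L_values) < 3)
    stop("need at least 3 grid sizes to fit a slope", call. = FALSE)
  sig <- sigma_for_snr(V, snr)
  seeds <- .subseeds(seed, length(L_values))
  trials <- purrr::map2(L_values, seeds, function(L, sd_i) {
    grid <- so3_grid(L)
    bank <- build_templates(V, grid, "no_projection_3d")
    b <- simulate_batch(V, prior_haar(), sig, "no_projection_3d", n_trials,
                        seed = sd_i)
    .batch_errors(b$Y, b$g_true, bank, sig, methods = methods) |>
      dplyr::mutate(L = grid$L, snr = snr, sigma = sig)
  }) |> dplyr::bind_rows()
  summary <- .summarize_trials(trials, .data$L, .data$method)
  fit <- purrr::map(methods, function(m) {
    tr <- dplyr::filter(trials, .data$method == m)
    means <- tr |> dplyr::group_by(.data$L) |>
      dplyr::summarize(mean_d_G = mean(.data$d_G), .groups = "drop")
    slope <- coef(lm(log10(mean_d_G) ~ log10(L), data = means))[2]
    boot <- vapply(seq_len(n_boot), function(b) {
      bm <- tr |> dplyr::group_by(.data$L) |>
        dplyr::summarize(m = mean(sample(.data$d_G, dplyr::n(), replace = TRUE)),
                         .groups = "drop")
      coef(lm(log10(m) ~ log10(L), data = bm))[2]
    }, numeric(1))
    tibble::tibble(method = m, slope = unname(slope),
                   ci_lo = unname(quantile(boot, 0.025)),
                   ci_hi = unname(quantile(boot, 0.975)))
  }) |> dplyr::bind_rows()
  out <- .new_bench(trials, summary, "grid_scaling",
                    list(snr = snr, seed = seed))
  out$fit <- fit
  out
}

# ---- prior mismatch ---------------------------------------------------------

#' Prior-mismatch study
#'
#' Simulates observations whose true rotations follow `truth_prior`
#' (typically a concentrated isotropic Gaussian) and estimates them under a
#' list of assumed priors. The MLE baseline ignores the prior entirely. An
#' MMSE estimator under an IG-SO(3) prior uses a Monte Carlo grid drawn from
#' that prior with equal weights (importance-sampling discretization of the
#' prior-weighted posterior integral); the uniform-prior MMSE and the MLE
#' share a quadrature grid of the same size.
#'
#' @param V Reference [vol3].
#' @param truth_prior Prior generating the true rotations.
#' @param assumed_priors Named list of [so3_prior]s for the MMSE estimator;
#'   names label the rows (e.g. `list(eta0.1 = prior_igso3(0.1))`).
#' @param snr Signal-to-noise ratio(s).
#' @param L Grid size for every estimator.
#' @param n_trials Trials per SNR.
#' @param seed Master seed.
#' @return A `bench_result`; `$trials` has one row per
#'   (snr, trial, estimator) with `estimator` one of `"mle"` or
#'   `"mmse:<name>"`. All estimators see the same observations.
#' @export
run_prior_mismatch <- function(V, truth_prior = prior_igso3(0.1),
                               assumed_priors = list(
                                 eta0.1 = prior_igso3(0.1),
                                 eta0.5 = prior_igso3(0.5),
                                 uniform = prior_haar()),
                               snr = 0.05, L = 2976, n_trials = 500,
                               seed = 1L) {
  uni_grid <- so3_grid(L)
  uni_bank <- build_templates(V, uni_grid, "no_projection_3d")
  # trial seeds are drawn first so the simulated observations (and hence the
  # MLE rows) do not depend on which priors are being assessed
  trial_seeds <- .subseeds(seed, length(snr))
  grid_seeds <- .subseeds(seed + 1L, length(assumed_priors))
  banks <- purrr::imap(assumed_priors, function(p, nm) {
    if (p$kind == "haar_uniform") uni_bank
    else {
      g <- so3_grid_from_prior(
        p, uni_grid$L, seed = grid_seeds[[match(nm, names(assumed_priors))]])
      build_templates(V, g, "no_projection_3d")
    }
  })
  trials <- purrr::map2(snr, trial_seeds, function(s, sd_i) {
    sig <- sigma_for_snr(V, s)
    b <- simulate_batch(V, truth_prior, sig, "no_projection_3d", n_trials,
                        seed = sd_i)
    rows <- list(
      .batch_errors(b$Y, b$g_true, uni_bank, sig, methods = "mle") |>
        dplyr::mutate(estimator = "mle"))
    for (nm in names(assumed_priors)) {
      rows[[nm]] <- .batch_errors(b$Y, b$g_true, banks[[nm]], sig,
                                  methods = "mmse") |>
        dplyr::mutate(estimator = paste0("mmse:", nm))
    }
    dplyr::bind_rows(rows) |> dplyr::mutate(snr = s, sigma = sig)
  }) |> dplyr::bind_rows()
  summary <- .summarize_trials(trials, .data$snr, .data$estimator)
  .new_bench(trials, summary, "prior_mismatch",
             list(L = uni_grid$L, seed = seed))
}

# ---- Einstein from Noise ----------------------------------------------------

#' Template-bias ("Einstein from Noise") study on the polar model
#'
#' Runs soft- and hard-assignment refinement from the same biased template
#' on the same observations, across noise levels down to pure noise (no
#' signal at all), and reports the Pearson correlation of each final
#' reconstruction against the truth and against the template (maximized over
#' the global cyclic-shift gauge), plus the mutual PCC of the two
#' reconstructions.
#'
#' @param truth True [polar_img] generating the observations (ignored in the
#'   pure-noise condition).
#' @param template Initial template [polar_img] (must differ from `truth`).
#' @param snr Vector of SNR values; `0` means pure noise.
#' @param M Observations per replicate.
#' @param n_replicates Independent replicates per SNR.
#' @param sigma_pure Noise standard deviation used when `snr == 0`.
#' @param max_iter,tol EM controls (defaults 100 and 1e-3).
#' @param seed Master seed.
#' @return A `bench_result`; `$trials` has one row per
#'   (snr, replicate, assignment) with `pcc_truth`, `pcc_template`,
#'   `pcc_mutual`, `iterations`.
#' @export
run_einstein_from_noise <- function(truth, template, snr = c(0, 0.1, 10),
                                    M = 2000, n_replicates = 20,
                                    sigma_pure = 1, max_iter = 100L,
                                    tol = 1e-3, seed = 1L) {
  stopifnot(inherits(truth, "polar_img"), inherits(template, "polar_img"))
  d <- nrow(truth); La <- ncol(truth)
  cells <- tidyr::expand_grid(snr = snr, replicate = seq_len(n_replicates))
  seeds <- .subseeds(seed, nrow(cells))
  trials <- purrr::pmap(list(cells$snr, cells$replicate, seeds),
                        function(s, rep_i, sd_i) {
    set.seed(sd_i)
    if (s == 0) {
      sig <- sigma_pure
      Y <- matrix(rnorm(d * La * M, sd = sig), d * La, M)
    } else {
      sig <- sigma_for_snr(truth, s)
      ks <- sample.int(La, M, replace = TRUE) - 1L
      Y <- matrix(0, d * La, M)
      for (i in seq_len(M))
        Y[, i] <- as.numeric(unclass(rotate_polar(truth, ks[i])))
      Y <- Y + matrix(rnorm(d * La * M, sd = sig), d * La, M)
    }
    fits <- purrr::map(c("soft", "hard"), function(a)
      run_refinement_polar(template, Y,
                           em_config(max_iter = max_iter, tol = tol,
                                     assignment = a, sigma = sig),
                           truth = truth, template = template))
    names(fits) <- c("soft", "hard")
    mutual <- pcc_polar(fits$soft$V_hat, fits$hard$V_hat)
    purrr::imap(fits, function(f, a) {
      last <- f$trajectory[nrow(f$trajectory), ]
      tibble::tibble(snr = s, sigma = sig, replicate = rep_i, assignment = a,
                     pcc_truth = last$pcc_truth,
                     pcc_template = last$pcc_template,
                     pcc_mutual = mutual, iterations = f$iterations,
                     converged = f$converged)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- trials |>
    dplyr::group_by(.data$snr, .data$assignment) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_pcc_truth = mean(.data$pcc_truth),
      se_pcc_truth = sd(.data$pcc_truth) / sqrt(dplyr::n()),
      mean_pcc_template = mean(.data$pcc_template),
      se_pcc_template = sd(.data$pcc_template) / sqrt(dplyr::n()),
      mean_pcc_mutual = mean(.data$pcc_mutual),
      .groups = "drop")
  .new_bench(trials, summary, "einstein_from_noise",
             list(M = M, d = d, L_ang = La, seed = seed))
}

# ---- plotting ---------------------------------------------------------------

#' Plot a benchmark result
#'
#' Error-versus-SNR and grid-scaling results are drawn as mean curves with
#' 2-standard-error ribbons on log axes; template-bias results as PCC-vs-SNR
#' panels per assignment.
#'
#' @param object A `bench_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bench_result <- function(object, ...) {
  s <- object$summary
  if (object$experiment == "grid_scaling") {
    return(ggplot2::ggplot(s, ggplot2::aes(.data$L, .data$mean_d_G,
                                           color = .data$method)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_d_G - 2 * .data$se_d_G,
                                        ymax = .data$mean_d_G + 2 * .data$se_d_G,
                                        fill = .data$method),
                           alpha = 0.2, color = NA) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
      ggplot2::labs(x = "grid size L", y = "mean geodesic error (rad)"))
  }
  if (object$experiment == "einstein_from_noise") {
    return(ggplot2::ggplot(s, ggplot2::aes(.data$snr + 1e-6,
                                           .data$mean_pcc_template,
                                           color = .data$assignment)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = .data$mean_pcc_template - 2 * .data$se_pcc_template,
        ymax = .data$mean_pcc_template + 2 * .data$se_pcc_template),
        width = 0.05) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "SNR (0 = pure noise)",
                    y = "PCC(reconstruction, template)"))
  }
  grp <- if ("estimator" %in% names(s)) "estimator" else "method"
  ggplot2::ggplot(s, ggplot2::aes(.data$snr, .data$mean_d_G,
                                  color = .data[[grp]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_d_G - 2 * .data$se_d_G,
                                      ymax = .data$mean_d_G + 2 * .data$se_d_G,
                                      fill = .data[[grp]]),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "SNR", y = "mean geodesic error (rad)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
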