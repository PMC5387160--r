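# Model-comparison statistics: free-energy differences and posterior model
# probabilities, dipole localisation error, sensitivity/specificity, and
# group-level random-effects Bayesian model selection with the Bayes
# omnibus risk.

#' Compare two anatomical models by free energy
#'
#' `delta_F = F_combined - F_cortical`; under equal model priors the
#' posterior probability of the combined model is `1 / (1 + exp(-dF))`.
#' `|dF| > 3` (an evidence ratio of about exp(3) ~ 20:1) is taken as
#' decisive, with the sign recording which model wins.
#'
#' @param F_combined,F_cortical free energies (nats) of the two models for
#'   the same data.
#' @return object of class `model_comparison`: `delta_F`,
#'   `posterior_prob_combined`, `significant`, `winner`.
#' @export
compare_models <- function(F_combined, F_cortical) {
  stopifnot(is.finite(F_combined), is.finite(F_cortical))
  dF <- F_combined - F_cortical
  structure(list(delta_F = dF,
                 posterior_prob_combined = 1 / (1 + exp(-dF)),
                 significant = abs(dF) >= 3,
                 winner = if (dF >= 0) "combined" else "cortical"),
            class = "model_comparison")
}

#' Dipole localisation error
#'
#' Euclidean distance between the true source vertex and the maximum of
#' the reconstructed per-vertex source amplitude, plus the structure
#' (cortical / hippocampal) owning the maximum. Amplitude ties are broken
#' by the lowest vertex index.
#'
#' @param truth_vertex index of the simulated seed in the concatenated
#'   source list of `space`.
#' @param result an `inversion_result` computed over `space`.
#' @param space the `source_space` of the inversion.
#' @return list with `dle_mm`, `argmax_vertex`, `winning_structure`.
#' @export
dipole_localisation_error <- function(truth_vertex, result, space) {
  amp <- result$posterior_source_amplitude
  if (length(amp) != n_sources(space))
    stop("result does not match the source space")
  if (all(amp == 0)) stop("all-zero posterior amplitudes")
  amax <- which.max(amp)   # which.max returns the first (lowest-index) max
  sv <- space_vertices(space)$vertices
  list(dle_mm = vnorm(sv[truth_vertex, ] - sv[amax, ]),
       argmax_vertex = amax,
       winning_structure = source_structures(space)[amax])
}

#' Sensitivity and specificity of structure classification
#'
#' Sensitivity: fraction of hippocampal-truth simulations whose amplitude
#' maximum lands on the hippocampal mesh. Specificity: fraction of
#' cortical-truth simulations whose maximum lands on the cortical mesh.
#'
#' @param truth character vector of true structures per dataset.
#' @param winner character vector of winning structures per dataset.
#' @return list with `sensitivity_pct`, `specificity_pct` (NA with a
#'   warning for an empty class), `n_hippocampal`, `n_cortical`.
#' @export
classification_rates <- function(truth, winner) {
  stopifnot(length(truth) == length(winner), length(truth) > 0)
  hip <- truth == "hippocampal"
  sens <- if (any(hip)) 100 * mean(winner[hip] == "hippocampal") else {
    warning("no hippocampal-truth datasets: sensitivity undefined"); NA_real_
  }
  spec <- if (any(!hip)) 100 * mean(winner[!hip] == "cortical") else {
    warning("no cortical-truth datasets: specificity undefined"); NA_real_
  }
  list(sensitivity_pct = sens, specificity_pct = spec,
       n_hippocampal = sum(hip), n_cortical = sum(!hip))
}

#' Random-effects Bayesian model selection with Bayes omnibus risk
#'
#' Variational Dirichlet scheme over per-dataset log evidences for K
#' models: iterate responsibilities
#' `u_nk propto exp(F_nk + psi(alpha_k) - psi(sum alpha))` and
#' `alpha_k = alpha0 + sum_n u_nk` to convergence. Returns the Dirichlet
#' posterior, the expected model frequencies, the posterior probability
#' that the second column's model ("combined" by convention) is the more
#' frequent, and the Bayes omnibus risk
#' `BOR = 1 / (1 + exp(F_rfx - F_null))`, the posterior probability that
#' all models are equally frequent; BOR < 0.05 rejects model equivalence.
#'
#' @param log_evidences n_datasets x 2 matrix; column 1 = cortical model,
#'   column 2 = combined model (column names are respected if given).
#' @param alpha0 Dirichlet prior concentration per model (default 1).
#' @param tol convergence tolerance on alpha.
#' @param max_iter iteration cap.
#' @param win_statistic `"exceedance"` (posterior probability that the
#'   combined frequency exceeds 1/2; default) or `"posterior_mean"`.
#' @return object of class `group_bms`: `dirichlet_alpha`,
#'   `expected_frequencies`, `prob_combined_wins`, `bor`, `F_rfx`,
#'   `F_null`, `responsibilities`.
#' @export
rfx_bms <- function(log_evidences, alpha0 = 1, tol = 1e-6, max_iter = 500,
                    win_statistic = c("exceedance", "posterior_mean")) {
  win_statistic <- match.arg(win_statistic)
  Fm <- as.matrix(log_evidences)
  if (any(!is.finite(Fm))) stop("non-finite log evidences")
  n <- nrow(Fm); K <- ncol(Fm)
  stopifnot(n >= 2, K == 2)
  Fc <- Fm - apply(Fm, 1, max)        # per-row shift, cancels in u_nk
  alpha <- rep(alpha0, K)
  for (it in seq_len(max_iter)) {
    lu <- sweep(Fc, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(lu - apply(lu, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)
  # free energy of the RFX model (variational bound)
  dga <- digamma(alpha) - digamma(sum(alpha))
  F_rfx <- sum(u * Fc) + sum(u %*% dga) +
    (lgamma(K * alpha0) - K * lgamma(alpha0) + sum((alpha0 - 1) * dga)) -
    sum(u * log(pmax(u, .Machine$double.xmin))) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * dga))
  # null model: fixed equal frequencies r = 1/K
  F_null <- sum(log(rowMeans(exp(Fc))))
  bor <- 1 / (1 + exp(F_rfx - F_null))
  prob_win <- if (win_statistic == "exceedance") {
    # r_combined ~ Beta(alpha_2, alpha_1)
    stats::pbeta(0.5, alpha[2], alpha[1], lower.tail = FALSE)
  } else ef[2]
  structure(list(dirichlet_alpha = alpha,
                 expected_frequencies = ef,
                 prob_combined_wins = prob_win,
                 bor = bor, F_rfx = F_rfx, F_null = F_null,
                 responsibilities = u,
                 win_statistic = win_statistic),
            class = "group_bms")
}

#' @export
print.group_bms <- function(x, ...) {
  cat(sprintf("<group_bms: E[freq] = (%.3f, %.3f), P(combined wins) = %.3f, BOR = %.3g>\n",
              x$expected_frequencies[1], x$expected_frequencies[2],
              x$prob_combined_wins, x$bor))
  invisible(x)
}
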