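# Empirical-Bayes source inversion. The generative model for the reduced
# sensor data Y (channels x temporal modes, each mode an i.i.d. draw) is
#   Y ~ N(0, Sigma),  Sigma = exp(l0) I + sum_i exp(l_i) L Q_i L'
# with source-covariance components Q_i set by the MNE / EBB / MSP scheme
# and log-hyperparameters l under broad Gaussian hyperpriors. ReML /
# Fisher-scoring maximizes the variational free energy
#   F = log p(Y | l_hat) - KL[q(l) || p(l)]   (accuracy - complexity),
# a lower bound on the log model evidence used for anatomical model
# comparison.

#' Reduce sensor data to its dominant temporal modes
#'
#' Projects the channels x samples matrix onto its `n_modes` dominant
#' right singular vectors. Inversion operates on the reduced channels x
#' modes matrix; a single mode suffices for narrow-band data, 16 modes are
#' used for broad-band mixtures.
#'
#' @param data channels x samples matrix.
#' @param n_modes number of temporal modes to retain.
#' @return object of class `temporal_modes`: `reduced_data` (channels x
#'   n_modes), `mode_vectors` (samples x n_modes, orthonormal), `n_modes`,
#'   `retained_variance_fraction`.
#' @export
reduce_temporal_modes <- function(data, n_modes = 1) {
  data <- as.matrix(data)
  k <- as.integer(n_modes)
  if (k < 1 || k > min(dim(data)))
    stop("n_modes must be in [1, min(channels, samples)]")
  sv <- svd(data, nu = 0, nv = k)
  structure(list(reduced_data = data %*% sv$v,
                 mode_vectors = sv$v,
                 n_modes = k,
                 retained_variance_fraction = sum(sv$d[seq_len(k)]^2) / sum(sv$d^2)),
            class = "temporal_modes")
}

## prior component sets ------------------------------------------------------

new_prior_set <- function(scheme, components, labels = NULL) {
  structure(list(scheme = scheme, components = components,
                 component_labels = labels %||% names(components)),
            class = "prior_component_set")
}

#' @export
print.prior_component_set <- function(x, ...) {
  cat(sprintf("<prior_component_set: %s, %d component(s)>\n",
              x$scheme, length(x$components)))
  invisible(x)
}

#' Minimum-norm (MNE) source-covariance prior
#'
#' A single identity component over all vertices of the space: equal prior
#' variance everywhere, no correlations, no depth re-weighting.
#'
#' @param space a `source_space`.
#' @return a `prior_component_set` with one identity component.
#' @export
build_prior_mne <- function(space) {
  new_prior_set("MNE",
                list(list(kind = "identity", n = n_sources(space))),
                labels = "mne_identity")
}

#' Empirical Bayes beamformer (EBB) source-covariance prior
#'
#' A single diagonal component whose per-vertex variance is the unit-gain
#' minimum-variance (beamformer) power estimate from the reduced data:
#' `q_j = 1 / (l_j' C^-1 l_j)` with `l_j` the unit-normalized j-th gain
#' column and `C` the ridge-regularized sensor covariance of the reduced
#' data; variances are normalized to unit maximum.
#'
#' @param leadfield a `lead_field`.
#' @param modes a `temporal_modes` object.
#' @param ridge ridge factor on the mean diagonal of `C` (default 1e-3).
#' @return a `prior_component_set` with one diagonal component.
#' @export
build_prior_ebb <- function(leadfield, modes, ridge = 1e-3) {
  Y <- modes$reduced_data
  if (nrow(Y) != nrow(leadfield$gain))
    stop("lead field and reduced data have inconsistent channel counts")
  C <- tcrossprod(Y) / ncol(Y)
  C <- C + ridge * mean(diag(C)) * diag(nrow(C))
  Ci <- chol2inv(chol(C))
  L <- leadfield$gain
  cn <- sqrt(colSums(L^2))
  cn[cn < .Machine$double.eps] <- 1
  Ln <- sweep(L, 2, cn, `/`)
  q <- 1 / colSums(Ln * (Ci %*% Ln))
  q <- q / max(q)
  new_prior_set("EBB", list(list(kind = "diag", q = q)), labels = "ebb_variance")
}

#' Multiple sparse priors (MSP) source-covariance components
#'
#' One rank-1 covariance component per seed vertex, `Q_i = q_i q_i'` with
#' `q_i` the geodesic Gaussian patch-weight column of seed i. The paper-
#' style preset uses 100 components: 90 cortical patches shared between
#' anatomical models plus 10 model-specific patches (cortical for the
#' cortex-only model, hippocampal for the combined model).
#'
#' @param space a `source_space` (MSP always uses the combined geometry;
#'   the model identity lives in the choice of seeds).
#' @param seed_vertices distinct indices into the concatenated source list.
#' @param fwhm_mm patch full-width half-maximum (default 6 mm).
#' @return a `prior_component_set` with one rank-1 component per seed.
#' @export
build_prior_msp <- function(space, seed_vertices, fwhm_mm = 6) {
  seeds <- as.integer(seed_vertices)
  if (anyDuplicated(seeds)) stop("duplicate MSP seed vertices")
  ns <- n_sources(space)
  if (any(seeds < 1 | seeds > ns)) stop("MSP seed vertex out of range")
  offs <- c(space$vertex_offset, ns + 1L)
  # group seeds per mesh so each mesh graph is built once
  mi <- findInterval(seeds, offs[-length(offs)])
  comps <- vector("list", length(seeds))
  for (m in unique(mi)) {
    sel <- which(mi == m)
    loc <- seeds[sel] - space$vertex_offset[m] + 1L
    D <- geodesic_distances(space$meshes[[m]], loc)
    sigma <- fwhm_mm / sqrt(8 * log(2))
    for (k in seq_along(sel)) {
      w <- exp(-D[k, ]^2 / (2 * sigma^2))
      w[w < 1e-3] <- 0
      qv <- numeric(ns)
      qv[space$vertex_offset[m] - 1L + seq_along(w)] <- w
      comps[[sel[k]]] <- list(kind = "rank1", q = qv, seed = seeds[sel[k]])
    }
  }
  new_prior_set("MSP", comps, labels = sprintf("msp_patch_%d", seeds))
}

# project source-level components to sensor level, trace-normalized.
# returns list(dense = list of p x p, dense_scale, Gmat = p x m matrix of
# rank-1 factors, r1_scale, comp_kind, src = original components)
sensor_components <- function(priors, leadfield) {
  L <- leadfield$gain
  p <- nrow(L)
  dense <- list(); dense_scale <- numeric(0); dense_pos <- integer(0)
  g_list <- list(); r1_scale <- numeric(0); r1_pos <- integer(0)
  for (i in seq_along(priors$components)) {
    cmp <- priors$components[[i]]
    if (cmp$kind == "identity") {
      G <- tcrossprod(L)
      sc <- p / sum(diag(G))
      dense[[length(dense) + 1L]] <- G * sc
      dense_scale <- c(dense_scale, sc); dense_pos <- c(dense_pos, i)
    } else if (cmp$kind == "diag") {
      G <- tcrossprod(sweep(L, 2, sqrt(cmp$q), `*`))
      sc <- p / sum(diag(G))
      dense[[length(dense) + 1L]] <- G * sc
      dense_scale <- c(dense_scale, sc); dense_pos <- c(dense_pos, i)
    } else if (cmp$kind == "rank1") {
      sup <- which(cmp$q > 0)
      g <- as.vector(L[, sup, drop = FALSE] %*% cmp$q[sup])
      nrm <- sum(g^2)
      if (nrm < .Machine$double.eps) nrm <- 1
      sc <- p / nrm
      g_list[[length(g_list) + 1L]] <- g * sqrt(sc)
      r1_scale <- c(r1_scale, sc); r1_pos <- c(r1_pos, i)
    } else stop("unknown component kind")
  }
  Gmat <- if (length(g_list)) do.call(cbind, g_list) else matrix(0, p, 0)
  list(dense = dense, dense_scale = dense_scale, dense_pos = dense_pos,
       Gmat = Gmat, r1_scale = r1_scale, r1_pos = r1_pos)
}

## ReML ----------------------------------------------------------------------

#' ReML / free-energy optimization of covariance hyperparameters
#'
#' Fisher-scoring maximization of the variational free energy of the
#' Gaussian sensor model over log-hyperparameters (one per source
#' component plus one identity sensor-noise term) with broad Gaussian
#' hyperpriors. Components whose log-hyperparameter falls below
#' `lambda_floor` are clamped there and removed from the active set
#' (ARD-style pruning, deterministic by component index).
#'
#' @param modes a `temporal_modes` object.
#' @param leadfield the `lead_field` of the anatomical model under test.
#' @param priors a `prior_component_set` (MNE, EBB or MSP).
#' @param hyper_mean,hyper_var Gaussian hyperprior mean and variance on
#'   the log-hyperparameters (relative to the data scale).
#' @param max_iter,tol iteration cap and |dF| convergence tolerance (nats).
#' @param lambda_floor pruning floor for log-hyperparameters.
#' @param model_label optional anatomy label stored in the result
#'   (defaults to the lead field's source-space kind).
#' @return object of class `inversion_result`: `free_energy`, `accuracy`,
#'   `complexity` (`F = accuracy - complexity`), `hyperparameters`
#'   (log-scale, including the sensor-noise term), `posterior_mean`
#'   (sources x modes), `posterior_source_amplitude` (per-vertex rms over
#'   modes), `fitted` (predicted reduced data), `variance_explained_pct`,
#'   `scheme`, `anatomy_kind`, `converged`, `n_iter`.
#' @export
reml_optimize <- function(modes, leadfield, priors,
                          hyper_mean = -5, hyper_var = 256,
                          max_iter = 128, tol = 1e-3,
                          lambda_floor = -12, model_label = NULL) {
  stopifnot(inherits(modes, "temporal_modes"),
            inherits(leadfield, "lead_field"),
            inherits(priors, "prior_component_set"))
  Y <- as.matrix(modes$reduced_data)
  p <- nrow(Y); N <- ncol(Y)
  if (nrow(leadfield$gain) != p) stop("lead field / data channel mismatch")
  if (!length(priors$components)) stop("at least one prior component required")

  s2 <- mean(diag(tcrossprod(Y) / N))   # data scale (mean power per channel)
  if (s2 <= 0) stop("zero data: cannot invert")
  Yn <- Y / sqrt(s2)
  Cn <- tcrossprod(Yn) / N

  sc <- sensor_components(priors, leadfield)
  nd <- length(sc$dense); nr <- ncol(sc$Gmat)
  m <- nd + nr                       # source components
  D_all <- m + 1L                    # + sensor noise
  # lambda order: [noise, dense components..., rank-1 components...]
  lam <- c(log(0.5), rep(log(0.5 / m), m))
  mu <- rep(hyper_mean, D_all)
  pv <- hyper_var
  active <- rep(TRUE, D_all)

  Ip <- diag(p)
  assemble <- function(lam) {
    Sg <- exp(lam[1]) * Ip
    if (nd) for (k in seq_len(nd)) Sg <- Sg + exp(lam[1 + k]) * sc$dense[[k]]
    if (nr) {
      el <- exp(lam[1 + nd + seq_len(nr)])
      Sg <- Sg + sc$Gmat %*% (el * t(sc$Gmat))
    }
    Sg
  }
  objective <- function(lam, act) {
    Sg <- assemble(lam)
    ch <- tryCatch(chol(Sg), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE))
    logdet <- 2 * sum(log(diag(ch)))
    P <- chol2inv(ch)
    loglik <- -N / 2 * (p * log(2 * pi) + logdet + sum(P * Cn))
    list(ok = TRUE, P = P, loglik = loglik, logdet = logdet)
  }
  # gradient and expected curvature over the active set
  grad_hess <- function(lam, P, act) {
    B <- P %*% Yn
    PCP <- tcrossprod(B) / N
    idx <- which(act)
    g <- numeric(D_all)
    Hm <- matrix(0, D_all, D_all)
    PD <- list()          # P %*% dense_k (incl. noise at slot 0)
    # noise component (identity)
    g[1] <- exp(lam[1]) * N / 2 * (sum(diag(PCP)) - sum(diag(P)))
    for (k in seq_len(nd)) {
      Gk <- sc$dense[[k]]
      g[1 + k] <- exp(lam[1 + k]) * N / 2 * (sum(PCP * Gk) - sum(P * Gk))
      PD[[k]] <- P %*% Gk
    }
    if (nr) {
      U <- P %*% sc$Gmat                      # p x nr
      el <- exp(lam[1 + nd + seq_len(nr)])
      gPCPg <- colSums(sc$Gmat * (PCP %*% sc$Gmat))
      gPg <- colSums(sc$Gmat * U)
      g[1 + nd + seq_len(nr)] <- el * N / 2 * (gPCPg - gPg)
    }
    # curvature blocks
    # noise-noise
    Hm[1, 1] <- exp(2 * lam[1]) * N / 2 * sum(P * P)
    for (k in seq_len(nd)) {
      Hm[1, 1 + k] <- Hm[1 + k, 1] <-
        exp(lam[1] + lam[1 + k]) * N / 2 * sum(P * PD[[k]])
      for (l in k:nd) {
        v <- exp(lam[1 + k] + lam[1 + l]) * N / 2 * sum(PD[[k]] * t(PD[[l]]))
        Hm[1 + k, 1 + l] <- Hm[1 + l, 1 + k] <- v
      }
    }
    if (nr) {
      U <- P %*% sc$Gmat
      el <- exp(lam[1 + nd + seq_len(nr)])
      M <- crossprod(sc$Gmat, U)              # g_i' P g_j
      rr <- N / 2 * (el %o% el) * M^2
      ri <- 1 + nd + seq_len(nr)
      Hm[ri, ri] <- rr
      # noise x rank1: tr(P I P g g') = g' P P g = |U_j|^2
      Hm[1, ri] <- Hm[ri, 1] <-
        exp(lam[1]) * el * N / 2 * colSums(U^2)
      for (k in seq_len(nd)) {
        w <- colSums(U * (sc$dense[[k]] %*% U))  # u_j' G_k u_j
        Hm[1 + k, ri] <- Hm[ri, 1 + k] <-
          exp(lam[1 + k]) * el * N / 2 * w
      }
    }
    g <- g - (lam - mu) / pv
    Hm <- Hm + diag(rep(1 / pv, D_all))
    list(g = g[idx], H = Hm[idx, idx, drop = FALSE], H_full = Hm)
  }
  free_energy <- function(loglik, lam, Hsub, act) {
    idx <- which(act)
    Dact <- length(idx)
    Sq <- tryCatch(chol2inv(chol(Hsub)), error = function(e) NULL)
    if (is.null(Sq)) Sq <- solve(Hsub + diag(1e-8, Dact))
    kl <- 0.5 * (sum(diag(Sq)) / pv + sum((lam[idx] - mu[idx])^2) / pv -
                 Dact + Dact * log(pv) - determinant(Sq)$modulus[1])
    acc <- loglik - N * p / 2 * log(s2)
    list(F = acc - kl, accuracy = acc, complexity = as.numeric(kl))
  }

  ob <- objective(lam, active)
  if (!ob$ok) stop("initial covariance not positive definite")
  gh <- grad_hess(lam, ob$P, active)
  fe <- free_energy(ob$loglik, lam, gh$H, active)
  F_cur <- fe$F
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    idx <- which(active)
    Hreg <- gh$H + diag(1e-8 * max(diag(gh$H)), length(idx))
    dl <- tryCatch(solve(Hreg, gh$g), error = function(e) NULL)
    if (is.null(dl)) break
    # trust step: cap the largest log step
    cap <- max(abs(dl))
    if (cap > 4) dl <- dl * (4 / cap)
    step <- 1
    improved <- FALSE
    for (half in 1:8) {
      lam_try <- lam
      lam_try[idx] <- lam[idx] + step * dl
      ob_try <- objective(lam_try, active)
      if (ob_try$ok) {
        gh_try <- grad_hess(lam_try, ob_try$P, active)
        fe_try <- free_energy(ob_try$loglik, lam_try, gh_try$H, active)
        if (is.finite(fe_try$F) && fe_try$F >= F_cur - 1e-9) {
          lam <- lam_try; ob <- ob_try; gh <- gh_try
          dF <- fe_try$F - F_cur
          F_cur <- fe_try$F; fe <- fe_try
          improved <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    # ARD pruning: clamp collapsed components (never the noise term)
    drop <- which(active & c(FALSE, rep(TRUE, m)) & lam < lambda_floor)
    if (length(drop)) {
      lam[drop] <- lambda_floor
      active[drop] <- FALSE
      ob <- objective(lam, active)
      gh <- grad_hess(lam, ob$P, active)
      fe <- free_energy(ob$loglik, lam, gh$H, active)
      F_cur <- fe$F
    }
    if (improved && abs(dF) < tol) { converged <- TRUE; break }
  }

  ## posterior source estimates ---------------------------------------------
  P <- ob$P
  PY <- P %*% Yn                       # p x N (normalized scale)
  L <- leadfield$gain
  ns <- ncol(L)
  J <- matrix(0, ns, N)
  for (k in seq_len(nd)) {
    cmp <- priors$components[[sc$dense_pos[k]]]
    w <- exp(lam[1 + k]) * sc$dense_scale[k]
    if (cmp$kind == "identity") {
      J <- J + w * crossprod(L, PY)
    } else {                            # diag
      J <- J + w * (cmp$q * crossprod(L, PY))
    }
  }
  if (nr) {
    el <- exp(lam[1 + nd + seq_len(nr)])
    # row i: e^li * n_i * (g_i' P Y) with g_i the unscaled sensor factor;
    # Gmat holds g_i * sqrt(n_i), so the product contributes sqrt(n_i) once more
    amps <- (el * sqrt(sc$r1_scale)) * crossprod(sc$Gmat, PY)
    for (k in seq_len(nr)) {
      cmp <- priors$components[[sc$r1_pos[k]]]
      sup <- which(cmp$q > 0)
      J[sup, ] <- J[sup, ] + cmp$q[sup] %o% amps[k, ]
    }
  }
  J <- J * sqrt(s2)
  fitted <- L %*% J
  resid <- Y - fitted
  ve <- 100 * (1 - sum(resid^2) / sum(Y^2))
  ve_clipped <- max(ve, 0)

  hyp <- lam
  names(hyp) <- c("sensor_noise",
                  priors$component_labels %||% sprintf("component_%d", seq_len(m)))
  structure(list(free_energy = fe$F,
                 accuracy = fe$accuracy,
                 complexity = fe$complexity,
                 hyperparameters = hyp,
                 active_components = active,
                 posterior_mean = J,
                 posterior_source_amplitude = sqrt(rowMeans(J^2)),
                 fitted = fitted,
                 variance_explained_pct = ve_clipped,
                 variance_explained_raw = ve,
                 scheme = priors$scheme,
                 anatomy_kind = model_label %||%
                   sub("/.*$", "", leadfield$source_space_ref),
                 n_modes = N,
                 data_scale = s2,
                 converged = converged,
                 n_iter = it),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result: %s/%s, F = %.2f (acc %.2f - cplx %.2f), VE %.2f%%, %d iter%s>\n",
              x$scheme, x$anatomy_kind, x$free_energy, x$accuracy,
              x$complexity, x$variance_explained_pct, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Percentage of sensor-level variance explained
#'
#' `100 (1 - ||Y - Yhat||_F^2 / ||Y||_F^2)` on the reduced data, with
#' `Yhat` the lead-field projection of the posterior mean sources.
#' Negative values (worse than predicting zero) are clipped to 0 with a
#' warning.
#'
#' @param result an `inversion_result`.
#' @param modes the `temporal_modes` the result was computed from.
#' @return percentage in [0, 100].
#' @export
variance_explained <- function(result, modes) {
  Y <- as.matrix(modes$reduced_data)
  if (sum(Y^2) == 0) stop("zero-data input")
  if (!all(dim(Y) == dim(result$fitted)))
    stop("result was not produced from these temporal modes")
  ve <- 100 * (1 - sum((Y - result$fitted)^2) / sum(Y^2))
  if (ve < 0) {
    warning(sprintf("variance explained %.1f%% clipped to 0", ve))
    ve <- 0
  }
  ve
}

#' Independent evaluation of the free-energy objective
#'
#' Recomputes accuracy, complexity and F directly from the data, the
#' sensor-level covariance components and the supplied log-hyperparameters
#' using dense linear algebra (eigendecomposition for the log-determinant
#' and an explicit KL term). Used as a self-consistency oracle for
#' [reml_optimize()]; shares no code path with the Fisher-scoring loop.
#'
#' @param modes a `temporal_modes` object.
#' @param leadfield the `lead_field` used.
#' @param priors the `prior_component_set` used.
#' @param result the `inversion_result` to audit.
#' @inheritParams reml_optimize
#' @return list with `F`, `accuracy`, `complexity`.
#' @export
evaluate_free_energy <- function(modes, leadfield, priors, result,
                                 hyper_mean = -5, hyper_var = 256) {
  Y <- as.matrix(modes$reduced_data)
  p <- nrow(Y); N <- ncol(Y)
  s2 <- mean(diag(tcrossprod(Y) / N))
  Yn <- Y / sqrt(s2)
  lam <- result$hyperparameters
  act <- result$active_components
  # dense sensor-level components, trace-normalized (independent assembly)
  L <- leadfield$gain
  Gs <- lapply(priors$components, function(cmp) {
    G <- switch(cmp$kind,
                identity = tcrossprod(L),
                diag = L %*% (cmp$q * t(L)),
                rank1 = {
                  g <- as.vector(L %*% cmp$q)
                  outer(g, g)
                })
    G * (p / sum(diag(G)))
  })
  Sg <- exp(lam[1]) * diag(p)
  for (i in seq_along(Gs)) Sg <- Sg + exp(lam[1 + i]) * Gs[[i]]
  ev <- eigen(Sg, symmetric = TRUE)
  logdet <- sum(log(ev$values))
  Si <- ev$vectors %*% (t(ev$vectors) / ev$values)
  trPC <- sum(diag(Si %*% tcrossprod(Yn) / N))
  loglik <- -N / 2 * (p * log(2 * pi) + logdet + trPC)
  accuracy <- loglik - N * p / 2 * log(s2)
  # curvature at lam over active set (expected information + prior)
  idx <- which(act)
  Dm <- length(idx)
  Qall <- c(list(diag(p)), Gs)
  H <- matrix(0, Dm, Dm)
  for (a in seq_len(Dm)) for (b in a:Dm) {
    ia <- idx[a]; ib <- idx[b]
    v <- N / 2 * exp(lam[ia] + lam[ib]) *
      sum((Si %*% Qall[[ia]]) * t(Si %*% Qall[[ib]]))
    H[a, b] <- H[b, a] <- v
  }
  H <- H + diag(rep(1 / hyper_var, Dm))
  Sq <- solve(H)
  kl <- 0.5 * (sum(diag(Sq)) / hyper_var +
               sum((lam[idx] - hyper_mean)^2) / hyper_var -
               Dm + Dm * log(hyper_var) - determinant(Sq)$modulus[1])
  list(F = accuracy - as.numeric(kl), accuracy = accuracy,
       complexity = as.numeric(kl))
}
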