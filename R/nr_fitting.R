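#' Reduce specular count data to reflectivity
#'
#' R(Q) = (I - I_B) / I_0 with the background I_B taken as the linear
#' interpolation (midpoint) of the two off-specular bracketing
#' intensities. Poisson uncertainties on all count channels are
#' propagated in quadrature. Negative net intensities are retained, not
#' clipped. Bins with zero incident intensity are masked (NA).
#'
#' @param counts A list with fields `Q`, `I` (specular counts),
#'   `I_off_lo`, `I_off_hi` (bracketing off-specular counts), `I0`
#'   (incident intensity) and optionally `dQ`.
#' @return A reflectivity curve: list with `Q`, `R`, `dR`, `dQ`.
#' @export
reduce_counts <- function(counts) {
  stopifnot(all(c("Q", "I", "I_off_lo", "I_off_hi", "I0") %in% names(counts)))
  if (any(counts$I < 0) || any(counts$I0 < 0))
    stop("counts must be non-negative")
  I0 <- counts$I0
  mask <- I0 <= 0
  I0[mask] <- NA_real_
  IB <- (counts$I_off_lo + counts$I_off_hi) / 2
  R <- (counts$I - IB) / I0
  var_net <- counts$I + (counts$I_off_lo + counts$I_off_hi) / 4
  dR <- sqrt(var_net / I0^2 + R^2 / I0)
  list(Q = counts$Q, R = R, dR = dR,
       dQ = if (is.null(counts$dQ)) 0.025 * counts$Q else counts$dQ)
}

# ---- ensemble MCMC --------------------------------------------------------

#' Affine-invariant ensemble sampler (stretch move)
#'
#' Minimal implementation of the Goodman-Weare stretch-move ensemble
#' sampler used for posterior sampling of reflectivity models.
#'
#' @param log_post Function of a parameter vector returning the log
#'   posterior density (may be -Inf).
#' @param p0 Matrix of initial walker positions (nwalkers x ndim).
#' @param nsteps Number of ensemble steps.
#' @param a Stretch parameter (default 2).
#' @param indep_proposal Optional list with `mean` (length ndim) and
#'   `chol` (upper-triangular Cholesky factor of the proposal
#'   covariance). When given, every other step replaces the stretch move
#'   by a Metropolis-Hastings independence move drawn from this Gaussian,
#'   which sharply reduces walker autocorrelation when the proposal
#'   resembles the posterior (e.g. a Laplace approximation).
#' @return List with `chain` (nsteps x nwalkers x ndim array), `logp`
#'   (nsteps x nwalkers), and the acceptance fraction.
#' @export
ensemble_sample <- function(log_post, p0, nsteps, a = 2,
                            indep_proposal = NULL) {
  nw <- nrow(p0); nd <- ncol(p0)
  if (nw < 2 * nd) stop("need at least 2*ndim walkers")
  chain <- array(NA_real_, c(nsteps, nw, nd))
  logp <- matrix(NA_real_, nsteps, nw)
  cur <- p0
  lp <- apply(cur, 1, log_post)
  if (!any(is.finite(lp))) stop("no walker has finite initial posterior")
  n_acc <- 0
  half <- nw %/% 2
  sets <- list(1:half, (half + 1):nw)
  logq <- NULL
  if (!is.null(indep_proposal)) {
    Li <- backsolve(indep_proposal$chol, diag(nd))
    logq <- function(x) {
      u <- drop(crossprod(Li, x - indep_proposal$mean))
      -0.5 * sum(u^2)
    }
    lq_cur <- apply(cur, 1, logq)
  }
  for (s in 1:nsteps) {
    if (!is.null(indep_proposal) && s %% 2 == 0) {
      # independence move: propose from the fixed Gaussian for each walker
      for (i in 1:nw) {
        prop <- indep_proposal$mean +
          drop(stats::rnorm(nd) %*% indep_proposal$chol)
        lp_prop <- log_post(prop)
        lq_prop <- logq(prop)
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < (lp_prop - lq_prop) - (lp[i] - lq_cur[i])) {
          cur[i, ] <- prop; lp[i] <- lp_prop; lq_cur[i] <- lq_prop
          n_acc <- n_acc + 1
        }
      }
    } else {
      for (k in 1:2) {
        move <- sets[[k]]; other <- sets[[3 - k]]
        zz <- (1 + (a - 1) * stats::runif(length(move)))^2 / a
        partner <- sample(other, length(move), replace = TRUE)
        for (ii in seq_along(move)) {
          i <- move[ii]
          prop <- cur[partner[ii], ] + zz[ii] * (cur[i, ] - cur[partner[ii], ])
          lp_prop <- log_post(prop)
          log_ratio <- (nd - 1) * log(zz[ii]) + lp_prop - lp[i]
          if (is.finite(lp_prop) && log(stats::runif(1)) < log_ratio) {
            cur[i, ] <- prop; lp[i] <- lp_prop; n_acc <- n_acc + 1
            if (!is.null(indep_proposal)) lq_cur[i] <- logq(prop)
          }
        }
      }
    }
    chain[s, , ] <- cur
    logp[s, ] <- lp
  }
  list(chain = chain, logp = logp, accept = n_acc / (nsteps * nw))
}

#' Split-chain potential scale reduction statistic
#'
#' Each walker chain is split in half and the standard between/within
#' variance ratio is computed per parameter; values close to 1 indicate
#' convergence.
#'
#' @param chain nsteps x nwalkers x ndim array (post burn-in).
#' @return Vector of R-hat values, one per parameter.
#' @export
split_rhat <- function(chain) {
  ns <- dim(chain)[1]; nw <- dim(chain)[2]; nd <- dim(chain)[3]
  half <- ns %/% 2
  vapply(seq_len(nd), function(p) {
    segs <- c(lapply(1:nw, function(w) chain[1:half, w, p]),
              lapply(1:nw, function(w) chain[(half + 1):(2 * half), w, p]))
    m <- vapply(segs, mean, numeric(1))
    v <- vapply(segs, stats::var, numeric(1))
    W <- mean(v); B <- half * stats::var(m)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
}

# ---- joint multi-contrast fitting ----------------------------------------

.assemble_pars <- function(template, theta, free, contrast_index = NULL) {
  p <- template
  for (j in seq_along(free)) {
    nm <- free[j]
    if (grepl("^rho_[sb]_", nm)) next
    p[[nm]] <- theta[j]
  }
  if (!is.null(contrast_index)) {
    nm_s <- paste0("rho_s_", contrast_index)
    nm_b <- paste0("rho_b_", contrast_index)
    if (nm_s %in% free) {
      p$rho_solvent <- theta[match(nm_s, free)]
    } else if (nm_b %in% free) {
      # the free parameter is the bulk-solution (backing) SLD; the solvent
      # SLD follows from the PEG bulk fraction. This parameterization
      # avoids the curved solvent/polymer trade-off ridge.
      p$rho_solvent <- (theta[match(nm_b, free)] -
                          p$c_inf * .sld_refs$peg) / (1 - p$c_inf)
    }
  }
  p
}

#' Joint multi-contrast optimization and posterior sampling
#'
#' Fits one composition-space model simultaneously to several
#' reflectivity curves measured under different solvent contrasts.
#' Structural parameters are shared across contrasts; the solvent SLD of
#' contrast i is freed either directly (`rho_s_i`) or, preferably,
#' through the bulk-solution backing SLD (`rho_b_i`), which is much less
#' correlated with the polymer bulk fraction. The Gaussian likelihood
#' over all curves is first maximized (L-BFGS-B in unit-box coordinates),
#' a Laplace approximation seeds an ensemble that mixes stretch moves
#' with Metropolis-Hastings independence moves, the proposal is refit to
#' the empirical covariance after a short adaptation stage, and the final
#' chains are checked with the split-chain statistic; if any parameter
#' exceeds 1.05 the result is flagged and interval summaries are
#' withheld by [exclusion_ci()].
#'
#' @param curves List of reflectivity curves (each with `Q`, `R`, `dR`,
#'   `dQ`), one per contrast.
#' @param template Full parameter list for [composition_model()]; entries
#'   named in `free` are starting values.
#' @param free Character vector of free parameter names; `rho_s_i` frees
#'   the solvent SLD of contrast i, `rho_b_i` the bulk-solution backing
#'   SLD (solvent SLD then derived from the polymer fraction).
#' @param lower,upper Named numeric vectors of prior box bounds for the
#'   free parameters.
#' @param nwalkers,nsteps,burn Ensemble sampler settings; `burn` is the
#'   fraction of steps discarded.
#' @param seed Integer seed controlling walker initialisation and
#'   sampling.
#' @param slab Microslab thickness passed to [model_reflectivity()].
#' @return An object of class `nr_fit`: list with `map` (named vector),
#'   `samples` (matrix, one named column per free parameter), `logp`,
#'   `rhat`, `converged`, `chi2` (per curve, at the MAP), `free`,
#'   `template`, `curves`.
#' @export
joint_fit <- function(curves, template, free, lower, upper,
                      nwalkers = 16, nsteps = 400, burn = 0.3, seed = 1,
                      slab = 1) {
  stopifnot(length(lower) == length(free), length(upper) == length(free))
  lower <- lower[free]; upper <- upper[free]
  nc <- length(curves)
  neg_chi2_half <- function(theta) {
    if (any(theta < lower) || any(theta > upper)) return(-Inf)
    tot <- 0
    for (ci in seq_len(nc)) {
      p <- .assemble_pars(template, theta, free, ci)
      m <- try(composition_model(p), silent = TRUE)
      if (inherits(m, "try-error")) return(-Inf)
      Rm <- model_reflectivity(m, curves[[ci]]$Q, curves[[ci]]$dQ, slab = slab)
      ok <- is.finite(curves[[ci]]$R) & curves[[ci]]$dR > 0
      tot <- tot + sum(((Rm[ok] - curves[[ci]]$R[ok]) / curves[[ci]]$dR[ok])^2)
    }
    -tot / 2
  }
  theta0 <- vapply(free, function(nm) {
    if (!is.null(template[[nm]])) return(template[[nm]])
    if (grepl("^rho_[sb]_", nm)) {
      ci <- as.integer(sub("^rho_[sb]_", "", nm))
      v <- template[[paste0("rho_solvent_", ci)]]
      if (is.null(v)) v <- template$rho_solvent
      if (grepl("^rho_b_", nm))
        v <- (1 - template$c_inf) * v + template$c_inf * .sld_refs$peg
      return(v)
    }
    stop("no starting value for free parameter ", nm)
  }, numeric(1))
  theta0 <- pmin(pmax(theta0, lower), upper)
  set.seed(seed)
  # work in unit-box coordinates: u = (theta - lower) / (upper - lower);
  # this keeps the Hessian well conditioned across parameter units
  sc <- upper - lower
  lpu <- function(u) neg_chi2_half(lower + u * sc)
  u0 <- (theta0 - lower) / sc
  nd <- length(free)
  # infeasible models (occupancy > 1) get a finite penalty so the line
  # search can back away from them
  opt <- stats::optim(u0, function(u) {
    v <- lpu(pmin(pmax(u, 0), 1))
    if (is.finite(v)) -v else 1e10
  },
                      method = "L-BFGS-B", lower = rep(0, nd),
                      upper = rep(1, nd),
                      control = list(maxit = 50, factr = 1e9,
                                     ndeps = rep(1e-5, nd)))
  u_map <- opt$par
  map <- stats::setNames(lower + u_map * sc, free)
  # Laplace approximation at the MAP: walkers start from an estimate of
  # the posterior itself, so the ensemble equilibrates quickly
  lp0 <- lpu(u_map)
  cl <- function(u) lpu(pmin(pmax(u, 0), 1))
  laplace_chol <- function(h) {
    H <- matrix(0, nd, nd)
    for (j in seq_len(nd)) {
      ej <- replace(numeric(nd), j, h)
      H[j, j] <- -(cl(u_map + ej) - 2 * lp0 + cl(u_map - ej)) / h^2
      for (k in seq_len(j - 1)) {
        ek <- replace(numeric(nd), k, h)
        H[j, k] <- H[k, j] <- -(cl(u_map + ej + ek) - cl(u_map + ej - ek) -
                                  cl(u_map - ej + ek) + cl(u_map - ej - ek)) /
          (4 * h^2)
      }
    }
    ed <- eigen(H, symmetric = TRUE)
    # floor the spectrum: directions with spurious negative curvature get
    # a wide (conservative) proposal scale rather than breaking the factor
    lam <- pmax(ed$values, max(ed$values) * 1e-6)
    S <- ed$vectors %*% (t(ed$vectors) / lam)
    list(L = chol((S + t(S)) / 2), n_floored = sum(ed$values <= 0))
  }
  lap <- laplace_chol(2e-3)
  if (lap$n_floored > 0) lap <- laplace_chol(6e-3)
  L <- lap$L
  p0 <- t(vapply(seq_len(nwalkers), function(i) pmin(pmax(
    u_map + drop(stats::rnorm(nd) %*% L), 1e-12), 1 - 1e-12), numeric(nd)))
  # adaptation stage: equilibrate briefly under the Laplace proposal, then
  # refit the proposal to the empirical posterior covariance
  nad <- max(40L, floor(nsteps / 3))
  run0 <- ensemble_sample(lpu, p0, nad,
                          indep_proposal = list(mean = u_map, chol = L))
  flat0 <- matrix(run0$chain[(nad %/% 2 + 1):nad, , ], ncol = nd)
  mu_e <- colMeans(flat0)
  S_e <- stats::cov(flat0)
  ed <- eigen(S_e, symmetric = TRUE)
  lam <- pmax(ed$values, max(ed$values) * 1e-8)
  L_e <- chol(ed$vectors %*% (t(ed$vectors) * lam)) * 1.05
  p1 <- run0$chain[nad, , ]
  run <- ensemble_sample(lpu, p1, nsteps,
                         indep_proposal = list(mean = mu_e, chol = L_e))
  nb <- max(1L, floor(nsteps * burn))
  keep <- (nb + 1):nsteps
  post <- run$chain[keep, , , drop = FALSE]
  rhat <- split_rhat(post)
  samples <- matrix(aperm(post, c(1, 2, 3)), ncol = length(free))
  samples <- sweep(sweep(samples, 2, sc, "*"), 2, lower, "+")
  colnames(samples) <- free
  chi2 <- vapply(seq_len(nc), function(ci) {
    p <- .assemble_pars(template, map, free, ci)
    m <- composition_model(p)
    Rm <- model_reflectivity(m, curves[[ci]]$Q, curves[[ci]]$dQ, slab = slab)
    ok <- is.finite(curves[[ci]]$R) & curves[[ci]]$dR > 0
    sum(((Rm[ok] - curves[[ci]]$R[ok]) / curves[[ci]]$dR[ok])^2)
  }, numeric(1))
  structure(list(map = map, samples = samples,
                 logp = run$logp[keep, ], rhat = rhat,
                 converged = all(is.finite(rhat)) && max(rhat) < 1.05,
                 accept = run$accept, chi2 = chi2, free = free,
                 template = template, curves = curves, slab = slab),
            class = "nr_fit")
}

#' Posterior exclusion-distance summary
#'
#' Applies [exclusion_distance()] to every posterior sample (deriving the
#' plane-of-charge position and hydrophobic-interface origin from each
#' sample's structural parameters) and reports the median with central
#' 68 and 95 percent intervals, formatted the way exclusion regions are
#' tabulated (median with asymmetric bounds).
#'
#' @param fit An `nr_fit` from [joint_fit()].
#' @return List with `median`, `ci68`, `ci95` (each in Angstrom),
#'   `censored_fraction` (samples with E0 <= ln 2), and `censored`
#'   (TRUE when more than half the samples have no half-density
#'   crossing, in which case intervals are NA). Errors if the sampler had
#'   not converged.
#' @export
exclusion_ci <- function(fit) {
  stopifnot(inherits(fit, "nr_fit"))
  if (!fit$converged)
    stop("sampler not converged (split R-hat >= 1.05); intervals withheld")
  n <- nrow(fit$samples)
  dx <- vapply(seq_len(n), function(i) {
    p <- .assemble_pars(fit$template, fit$samples[i, ], fit$free, NULL)
    m <- composition_model(p, z = c(0, 1))  # geometry only
    if (p$E0 <= log(2)) return(NA_real_)
    prof <- peg_exclusion_profile(p$c_inf, p$kappa, m$z0, p$E0)
    exclusion_distance(prof, hydrophobic_z = m$z_hydrophobic)
  }, numeric(1))
  cf <- mean(is.na(dx))
  if (cf > 0.5)
    return(list(median = NA_real_, ci68 = c(NA_real_, NA_real_),
                ci95 = c(NA_real_, NA_real_), censored_fraction = cf,
                censored = TRUE, samples = dx))
  qs <- stats::quantile(dx, c(0.025, 0.16, 0.5, 0.84, 0.975), na.rm = TRUE)
  list(median = unname(qs[3]), ci68 = unname(qs[c(2, 4)]),
       ci95 = unname(qs[c(1, 5)]), censored_fraction = cf,
       censored = FALSE, samples = dx)
}
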