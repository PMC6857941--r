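# The sigmoid conjugation-capacity model. Capacity of a variant-substrate
# pair is
#
#   P_c = sigma * kappa * (1 / (1 + exp(-gamma * (S_DH/S_DT - mu))))^beta + epsilon
#
# with beta = S_DT / S_DH(wild) fixed per substrate, kappa the promoter
# (*28) genotype factor, and epsilon = 0 for in vitro work. Constants
# (sigma, gamma, mu[, epsilon]) are estimated by minimizing the sum of
# squared errors against in vitro capacities over the fit set M: the
# variants with known capacity and a correctly bound coenzyme.

#' Model constants of the capacity model
#'
#' @param sigma Overall scale, in capacity units (> 0).
#' @param gamma Sigmoid slope, dimensionless (> 0).
#' @param mu Sigmoid midpoint on the oriented-pose fraction scale, in [0, 1].
#' @param epsilon Environment offset in capacity units; 0 for in vitro
#'   predictions.
#' @param beta Sigmoid exponent, `S_DT / S_DH(wild)` for the substrate (> 0).
#' @return An object of class `model_params`.
#' @export
model_params <- function(sigma, gamma, mu, epsilon = 0, beta) {
  stopifnot(sigma > 0, gamma > 0, mu >= 0, mu <= 1, beta > 0,
            is.finite(epsilon))
  structure(list(sigma = sigma, gamma = gamma, mu = mu,
                 epsilon = epsilon, beta = beta),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> sigma=%.6g gamma=%.6g mu=%.6g epsilon=%.6g beta=%.6g\n",
    x$sigma, x$gamma, x$mu, x$epsilon, x$beta))
  invisible(x)
}

#' Sigmoid exponent from the wild-type docking summary
#'
#' `beta = S_DT / S_DH(wild)`: the total pose count divided by the wild-type
#' oriented-pose count for the substrate. Computed once per substrate and
#' shared by all its variants.
#'
#' @param S_DT Total number of docking poses.
#' @param S_DH_wild Oriented-pose count of the wild-type enzyme.
#' @return The exponent as a double.
#' @export
compute_beta <- function(S_DT, S_DH_wild) {
  stopifnot(S_DT > 0)
  if (S_DH_wild <= 0) {
    stop("wild-type substrate has no oriented poses; beta undefined",
         call. = FALSE)
  }
  S_DT / S_DH_wild
}

#' Inner logistic of the substrate contribution
#'
#' @param f Oriented-pose fraction `S_DH / S_DT`, in [0, 1].
#' @param gamma Slope (> 0).
#' @param mu Midpoint, in [0, 1].
#' @return `1 / (1 + exp(-gamma * (f - mu)))`, in (0, 1); vectorized over `f`.
#' @export
sigmoid_term <- function(f, gamma, mu) {
  stopifnot(all(f >= 0 & f <= 1), gamma > 0)
  1 / (1 + exp(-gamma * (f - mu)))
}

#' Substrate contribution S of a docking summary
#'
#' The sigmoid of the oriented-pose fraction raised to the exponent `beta`.
#'
#' @param summary A `docking_summary` (or any list with `S_DH`, `S_DT`).
#' @param params A `model_params` with `beta` set from the wild-type summary
#'   of the same substrate.
#' @return The S term, in (0, 1).
#' @export
substrate_contribution <- function(summary, params) {
  if (summary$S_DT <= 0) stop("S_DT must be positive", call. = FALSE)
  f <- summary$S_DH / summary$S_DT
  sigmoid_term(f, params$gamma, params$mu)^params$beta
}

#' Per-variant docking summary
#'
#' @param variant Variant name (e.g. `"wild"`, `"G71R"`).
#' @param ligand Substrate name.
#' @param S_DT Total pose count (> 0).
#' @param S_DH Oriented pose count, `0 <= S_DH <= S_DT`.
#' @param udpga_correct_count Number of docking runs with the coenzyme in the
#'   correct binding mode; 0 marks a variant whose coenzyme site is disrupted.
#' @return An object of class `docking_summary`.
#' @export
docking_summary <- function(variant, ligand, S_DT, S_DH, udpga_correct_count) {
  stopifnot(S_DT > 0, S_DH >= 0, S_DH <= S_DT, udpga_correct_count >= 0)
  structure(list(variant = variant, ligand = ligand,
                 S_DT = as.integer(S_DT), S_DH = as.integer(S_DH),
                 udpga_correct_count = as.integer(udpga_correct_count)),
            class = "docking_summary")
}

#' Promoter genotype factor kappa
#'
#' The TA-repeat promoter polymorphism (*28) reduces UGT1A1 expression;
#' capacity scales by the Vmax ratio of each genotype to wild-type/wild-type
#' (Vmax 16.2, 12.0 and 3.4 nmol/min/mg for wild/wild, wild/*28 and
#' *28/*28). `mode = "printed"` returns the conventional two-decimal values
#' 1.0 / 0.74 / 0.21; `mode = "exact"` returns the unrounded ratios.
#'
#' @param genotype One of `"wild/wild"`, `"wild/*28"`, `"*28/*28"`.
#' @param mode `"printed"` (default) or `"exact"`.
#' @return The factor kappa; vectorized over `genotype`.
#' @export
kappa <- function(genotype, mode = c("printed", "exact")) {
  mode <- match.arg(mode)
  vmax <- c("wild/wild" = 16.2, "wild/*28" = 12.0, "*28/*28" = 3.4)
  unknown <- setdiff(unique(genotype), names(vmax))
  if (length(unknown) > 0L) {
    stop("unknown genotype: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  exact <- vmax[genotype] / vmax[["wild/wild"]]
  out <- if (mode == "printed") round(exact, 2) else exact
  unname(out)
}

#' Predict absolute conjugation capacity
#'
#' `P_c = sigma * kappa * S + epsilon`. A variant whose coenzyme never binds
#' correctly (`udpga_correct_count = 0`) lies outside the model's fit set and
#' is predicted 0 by rule, flagged via the `"no_udpga_binding"` attribute.
#'
#' @inheritParams substrate_contribution
#' @param genotype Promoter genotype (see [kappa()]).
#' @param kappa_mode Passed to [kappa()].
#' @return Predicted capacity in the units of `sigma`, with attribute
#'   `no_udpga_binding` (logical).
#' @export
predict_absolute <- function(summary, genotype = "wild/wild", params,
                             kappa_mode = "printed") {
  if (summary$udpga_correct_count == 0L) {
    return(structure(0, no_udpga_binding = TRUE))
  }
  k <- kappa(genotype, kappa_mode)
  s <- substrate_contribution(summary, params)
  structure(params$sigma * k * s + params$epsilon, no_udpga_binding = FALSE)
}

#' Predict relative conjugation capacity (percent of wild-type)
#'
#' With `epsilon = 0` the scale cancels and the prediction reduces to
#' `100 * kappa * S(mutant) / S(wild)`; with a nonzero offset the full ratio
#' `100 * (sigma*kappa*S + eps) / (sigma*S_wild + eps)` is used.
#'
#' @inheritParams predict_absolute
#' @param wild_summary The wild-type `docking_summary` for the same substrate.
#' @return Percent of wild-type capacity, with attribute `no_udpga_binding`.
#' @export
predict_relative <- function(summary, genotype = "wild/wild", params,
                             wild_summary, kappa_mode = "printed") {
  if (summary$udpga_correct_count == 0L) {
    return(structure(0, no_udpga_binding = TRUE))
  }
  s_wild <- substrate_contribution(wild_summary, params)
  if (s_wild <= 0) stop("wild-type S term is zero", call. = FALSE)
  k <- kappa(genotype, kappa_mode)
  s <- substrate_contribution(summary, params)
  out <- if (params$epsilon == 0) {
    100 * k * s / s_wild
  } else {
    100 * (params$sigma * k * s + params$epsilon) /
      (params$sigma * s_wild + params$epsilon)
  }
  structure(out, no_udpga_binding = FALSE)
}

#' Fit control settings
#'
#' @param n_starts Number of random restarts of the bounded local optimizer.
#' @param seed Integer seed making the restarts (and hence the fit)
#'   deterministic.
#' @param free_epsilon Release the environment offset epsilon (default fixed
#'   at 0, the in vitro convention).
#' @param kappa_mode Passed to [kappa()].
#' @param gamma_bounds,mu_bounds Box constraints of the optimizer.
#' @param include_nd Treat not-detected capacities as 0 and include them in
#'   the fit (default `FALSE`: ND is censored, not zero).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 20L, seed = 17L, free_epsilon = FALSE,
                        kappa_mode = "printed",
                        gamma_bounds = c(1e-3, 100), mu_bounds = c(0, 1),
                        include_nd = FALSE) {
  stopifnot(n_starts >= 1, gamma_bounds[1] > 0, mu_bounds[1] >= 0,
            mu_bounds[2] <= 1)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 free_epsilon = isTRUE(free_epsilon), kappa_mode = kappa_mode,
                 gamma_bounds = gamma_bounds, mu_bounds = mu_bounds,
                 include_nd = isTRUE(include_nd)),
            class = "fit_control")
}

# Profile the conditionally linear constants out of the SSE. Given (gamma,
# mu), predictions are sigma * w + epsilon with w = kappa * sigmoid^beta, so
# the optimal sigma (and epsilon, when released) solve a linear least-squares
# problem. Returns list(sigma, epsilon, sse).
.profiled_sse <- function(gamma, mu, f, kap, beta, v, free_epsilon) {
  w <- kap * sigmoid_term(f, gamma, mu)^beta
  if (free_epsilon) {
    X <- cbind(w, 1)
    coefs <- tryCatch(qr.solve(X, v), error = function(e) c(NA_real_, NA_real_))
    if (any(!is.finite(coefs)) || coefs[1] <= 0) {
      # keep sigma positive: fall back to epsilon = 0 profile
      sigma <- max(sum(w * v) / sum(w * w), .Machine$double.eps)
      eps <- 0
    } else {
      sigma <- coefs[1]; eps <- coefs[2]
    }
  } else {
    denom <- sum(w * w)
    sigma <- if (denom > 0) max(sum(w * v) / denom, .Machine$double.eps) else
      .Machine$double.eps
    eps <- 0
  }
  list(sigma = sigma, epsilon = eps, sse = sum((sigma * w + eps - v)^2))
}

#' Estimate the model constants by least squares
#'
#' Minimizes the sum of squared errors between predicted and in vitro
#' capacities over the panel's fit set M (members with known capacity and a
#' correctly bound coenzyme). `sigma` (and `epsilon`, when released) is
#' conditionally linear and solved exactly inside the search, which runs
#' bounded L-BFGS-B over `(gamma, mu)` from `n_starts` seeded random starts.
#'
#' @param panel A `capacity_panel` (see [capacity_panel()]).
#' @param control A [fit_control()].
#' @return List of class `capacity_fit` with elements `params`
#'   (`model_params`), `sse`, `fitted` (per-variant data frame), `fit_set`
#'   (variant names used), `diagnostics` (per-restart table), and `control`.
#' @export
fit_parameters <- function(panel, control = fit_control()) {
  m <- fit_set(panel, include_nd = control$include_nd)
  n_free <- 3L + as.integer(control$free_epsilon)  # sigma, gamma, mu[, eps]
  if (nrow(m) < n_free) {
    stop(sprintf("fit set has %d usable members but the model has %d free constants",
                 nrow(m), n_free), call. = FALSE)
  }
  v <- m$V_c
  if (length(unique(v)) == 1L) {
    stop("model unidentifiable: all in vitro capacities identical", call. = FALSE)
  }
  beta <- compute_beta(panel$wild_summary$S_DT, panel$wild_summary$S_DH)
  f <- m$S_DH / m$S_DT
  kap <- kappa(m$genotype, control$kappa_mode)

  obj <- function(par) {
    .profiled_sse(par[1], par[2], f, kap, beta, v, control$free_epsilon)$sse
  }

  # seeded starts; RNG state restored afterwards
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(control$seed)
  gamma0 <- exp(stats::runif(control$n_starts, log(0.5), log(50)))
  mu0 <- stats::runif(control$n_starts, control$mu_bounds[1], control$mu_bounds[2])

  lower <- c(control$gamma_bounds[1], control$mu_bounds[1])
  upper <- c(control$gamma_bounds[2], control$mu_bounds[2])
  diagnostics <- vector("list", control$n_starts)
  best <- NULL
  for (i in seq_len(control$n_starts)) {
    res <- tryCatch(
      stats::optim(c(gamma0[i], mu0[i]), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) {
      diagnostics[[i]] <- data.frame(start = i, gamma0 = gamma0[i],
                                     mu0 = mu0[i], sse = NA_real_,
                                     converged = FALSE)
      next
    }
    diagnostics[[i]] <- data.frame(start = i, gamma0 = gamma0[i], mu0 = mu0[i],
                                   sse = res$value,
                                   converged = res$convergence == 0)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer restarts failed", call. = FALSE)

  prof <- .profiled_sse(best$par[1], best$par[2], f, kap, beta, v,
                        control$free_epsilon)
  params <- model_params(sigma = prof$sigma, gamma = best$par[1],
                         mu = best$par[2], epsilon = prof$epsilon, beta = beta)
  w <- kap * sigmoid_term(f, params$gamma, params$mu)^beta
  fitted <- data.frame(
    variant = m$variant, genotype = m$genotype, fraction = f,
    observed = v, predicted = params$sigma * w + params$epsilon
  )
  structure(list(params = params, sse = prof$sse, fitted = fitted,
                 fit_set = m$variant,
                 diagnostics = do.call(rbind, diagnostics),
                 control = control),
            class = "capacity_fit")
}

#' @export
print.capacity_fit <- function(x, ...) {
  cat(sprintf("<capacity_fit> n=%d variants, SSE=%.6g\n",
              nrow(x$fitted), x$sse))
  print(x$params)
  invisible(x)
}
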