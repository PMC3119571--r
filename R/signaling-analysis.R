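# Sensitivity analysis, the ErbB3 resistance scenario, and rate-constant
# fitting for the signaling model.

# A perturbable quantity is a rate constant, a receptor surface level
# (EGFR/ErbB2/ErbB3 map to their monomer species), a ligand dose, or any
# species initial amount.
SENSITIVITY_SPECIES_ALIAS <- c(EGFR = "R1", ErbB2 = "R2", ErbB3 = "R3",
                               Ras = "RasGDP", PIP = "PIP2")

get_parameter <- function(model, name) {
  if (name %in% names(model$params)) return(model$params[[name]])
  sp <- SENSITIVITY_SPECIES_ALIAS[name]
  sp <- if (is.na(sp)) name else unname(sp)
  i <- match(sp, model$species$name)
  if (is.na(i)) abort_lookup("unknown parameter or species '%s'", name)
  model$species$initial[i]
}

set_parameter <- function(model, name, value) {
  if (name %in% names(model$params)) {
    model$params[[name]] <- value
    return(model)
  }
  sp <- SENSITIVITY_SPECIES_ALIAS[name]
  sp <- if (is.na(sp)) name else unname(sp)
  i <- match(sp, model$species$name)
  if (is.na(i)) abort_lookup("unknown parameter or species '%s'", name)
  model$species$initial[i] <- value
  model
}

# `species` may be a vector; the readout is then the sum of the per-species
# metrics (used for the joint pERK/pAKT screens).
eval_metric <- function(model, species, metric, t_end, dt = 0.5) {
  res <- simulate_model(model, t_end = t_end, dt = dt)
  sum(vapply(species, function(s) output_metric(res, s, metric), numeric(1)))
}

#' Local (logarithmic) parameter sensitivity
#'
#' Normalized coefficients S = d log(metric) / d log(parameter) by central
#' finite differences. Parameters may be rate constants, species initial
#' amounts, or the receptor aliases EGFR/ErbB2/ErbB3.
#'
#' @param model ModelSpec.
#' @param parameters character vector of parameter/species names.
#' @param species readout species (default "AKTp").
#' @param metric readout metric (default "peak").
#' @param rel_step relative perturbation in (0, 0.1].
#' @param t_end simulation horizon, minutes.
#' @return data.frame (parameter, coefficient) sorted by |coefficient|,
#'   class `SensitivityResult`.
#' @export
local_sensitivity <- function(model, parameters, species = "AKTp", metric = "peak",
                              rel_step = 0.05, t_end = 60) {
  if (rel_step <= 0 || rel_step > 0.1) abort_usage("rel_step must be in (0, 0.1]")
  y0 <- eval_metric(model, species, metric, t_end)
  if (y0 <= 0) abort_stat("metric is zero at the base point; sensitivity undefined")
  coef <- vapply(parameters, function(pn) {
    p0 <- get_parameter(model, pn)
    if (p0 <= 0) return(0)
    up <- eval_metric(set_parameter(model, pn, p0 * (1 + rel_step)), species, metric, t_end)
    dn <- eval_metric(set_parameter(model, pn, p0 * (1 - rel_step)), species, metric, t_end)
    if (up <= 0 || dn <= 0) return(NA_real_)
    (log(up) - log(dn)) / (log(1 + rel_step) - log(1 - rel_step))
  }, numeric(1))
  out <- data.frame(parameter = parameters, coefficient = coef,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$coefficient)), ]
  rownames(out) <- NULL
  structure(out, class = c("SensitivityResult", "data.frame"),
            metric = paste0(species, "-", metric), mode = "local")
}

# partial rank correlation of each column of X with y
prcc <- function(X, y) {
  Xr <- apply(X, 2, rank)
  yr <- rank(y)
  k <- ncol(X)
  out <- numeric(k)
  for (j in seq_len(k)) {
    others <- cbind(1, Xr[, -j, drop = FALSE])
    rx <- Xr[, j] - others %*% qr.solve(others, Xr[, j])
    ry <- yr - others %*% qr.solve(others, yr)
    out[j] <- if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) 0 else
      stats::cor(rx, ry)
  }
  out
}

#' Global sensitivity analysis (Latin hypercube + PRCC)
#'
#' Samples parameters log-uniformly over the given ranges with a Latin
#' hypercube design and reports the partial rank correlation coefficient
#' of each parameter against the readout.
#'
#' @param model ModelSpec.
#' @param ranges named list of `c(lo, hi)` ranges; a plain character
#'   vector means 0.2x to 5x of the base value.
#' @param n_samples number of LHS samples (at least 10 per parameter).
#' @param species,metric readout, as in [local_sensitivity()].
#' @param seed integer seed.
#' @param t_end simulation horizon, minutes.
#' @return data.frame (parameter, coefficient) sorted by |coefficient|,
#'   class `SensitivityResult`.
#' @export
global_sensitivity <- function(model, ranges, n_samples = NULL, species = "AKTp",
                               metric = "peak", seed = 1, t_end = 60) {
  if (is.character(ranges)) {
    ranges <- stats::setNames(lapply(ranges, function(pn) {
      b <- get_parameter(model, pn); c(b * 0.2, b * 5)
    }), ranges)
  }
  k <- length(ranges)
  if (is.null(n_samples)) n_samples <- 10L * k
  if (n_samples < 10 * k) abort_usage("need at least 10 samples per parameter")
  degenerate <- vapply(ranges, function(r) r[1] >= r[2], logical(1))
  if (any(degenerate))
    warning("degenerate range(s) reported as coefficient 0: ",
            paste(names(ranges)[degenerate], collapse = ", "))
  local_seed(seed, {
    U <- lhs::randomLHS(n_samples, k)
    X <- matrix(0, n_samples, k, dimnames = list(NULL, names(ranges)))
    for (j in seq_len(k)) {
      r <- ranges[[j]]
      X[, j] <- if (degenerate[j]) r[1] else
        exp(log(r[1]) + U[, j] * (log(r[2]) - log(r[1])))
    }
    y <- vapply(seq_len(n_samples), function(i) {
      m <- model
      for (j in seq_len(k)) m <- set_parameter(m, names(ranges)[j], X[i, j])
      eval_metric(m, species, metric, t_end, dt = 1)
    }, numeric(1))
    coef <- prcc(X[, !degenerate, drop = FALSE], y)
    full <- stats::setNames(numeric(k), names(ranges))
    full[!degenerate] <- coef
    out <- data.frame(parameter = names(ranges), coefficient = full,
                      stringsAsFactors = FALSE)
    out <- out[order(-abs(out$coefficient)), ]
    rownames(out) <- NULL
    structure(out, class = c("SensitivityResult", "data.frame"),
              metric = paste0(species, "-", metric), mode = "global")
  })
}

#' ErbB3-mediated resistance scenario
#'
#' Simulates the NRG-1beta-stimulated network under lapatinib with an
#' increased surface ErbB3 level and/or reduced phosphatase activity, and
#' compares the pAKT readout with the matching no-inhibitor, unmodified
#' control.
#'
#' @param erbb3_fold fold increase in surface ErbB3 (> 0).
#' @param phosphatase_scale scale on the ErbB phosphatase level (> 0).
#' @param nrg_nM NRG-1beta dose, nM.
#' @param lapatinib_nM lapatinib dose, nM (default: saturating).
#' @param config extra configuration merged into both models.
#' @param species,metric readout (default peak pAKT over 0-60 min).
#' @param t_end horizon, minutes.
#' @return list with `ratio` (treated / control), `treated`, `control`
#'   metric values and the two configurations.
#' @export
resistance_scenario <- function(erbb3_fold = 2, phosphatase_scale = 1,
                                nrg_nM = 25, lapatinib_nM = 10000,
                                config = list(), species = "AKTp",
                                metric = "peak", t_end = 60) {
  if (erbb3_fold <= 0 || phosphatase_scale <= 0)
    abort_usage("folds and scales must be positive")
  treated_cfg <- utils::modifyList(config, list(
    nrg_nM = nrg_nM, lapatinib_nM = lapatinib_nM,
    erbb3_fold = erbb3_fold, phosphatase_scale = phosphatase_scale))
  control_cfg <- utils::modifyList(config, list(
    nrg_nM = nrg_nM, lapatinib_nM = 0, erbb3_fold = 1, phosphatase_scale = 1))
  treated <- eval_metric(build_model(treated_cfg), species, metric, t_end)
  control <- eval_metric(build_model(control_cfg), species, metric, t_end)
  list(ratio = treated / control, treated = treated, control = control,
       treated_config = treated_cfg, control_config = control_cfg)
}

#' Fit rate constants to observed time courses
#'
#' Multi-start least-squares minimisation of trajectory residuals over up
#' to 5 free parameters (log-scaled internally, box-bounded).
#'
#' @param model ModelSpec.
#' @param observed list with `times` (minutes) and `data` (time x species
#'   matrix with species column names); replicates may be stacked as a
#'   list of such matrices sharing `times`.
#' @param free character vector of free parameter names (max 5).
#' @param bounds named list of `c(lo, hi)` per free parameter (default:
#'   0.01x to 100x the current value).
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of starts (default 5).
#' @return list with `estimates` (named), `objective`, `identifiable`
#'   (logical per parameter), `converged`.
#' @export
fit_rate_constants <- function(model, observed, free, bounds = NULL,
                               seed = 1, n_starts = 5) {
  if (length(free) > 5) abort_usage("at most 5 free parameters")
  datasets <- if (is.list(observed$data)) observed$data else list(observed$data)
  base <- vapply(free, function(pn) get_parameter(model, pn), numeric(1))
  if (is.null(bounds))
    bounds <- stats::setNames(lapply(base, function(b) c(b * 0.01, b * 100)), free)
  lo <- log(vapply(bounds, `[`, numeric(1), 1))
  hi <- log(vapply(bounds, `[`, numeric(1), 2))
  species <- colnames(datasets[[1]])
  scale <- vapply(species, function(s) max(1, max(vapply(datasets, function(d)
    max(d[, s]), numeric(1)))), numeric(1))
  obj <- function(lp) {
    m <- model
    for (j in seq_along(free)) m <- set_parameter(m, free[j], exp(lp[j]))
    res <- tryCatch(simulate_model(m, t_end = max(observed$times),
                                   dt = min(diff(sort(unique(observed$times))))),
                    error = function(e) NULL)
    if (is.null(res)) return(1e12)
    pred <- vapply(species, function(s)
      stats::approx(res$times, res$state[, s], xout = observed$times)$y,
      numeric(length(observed$times)))
    sum(vapply(datasets, function(d)
      sum(((d - pred) / rep(scale, each = nrow(d)))^2), numeric(1)))
  }
  local_seed(seed, {
    starts <- c(list(log(base)), lapply(seq_len(n_starts - 1), function(i)
      stats::runif(length(free), lo, hi)))
    fits <- lapply(starts, function(s0)
      stats::optim(pmin(pmax(s0, lo), hi), obj, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200, factr = 1e9)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    est <- stats::setNames(exp(best$par), free)
    # flat-objective identifiability probe
    identifiable <- vapply(seq_along(free), function(j) {
      up <- best$par; up[j] <- min(up[j] + log(1.5), hi[j])
      dn <- best$par; dn[j] <- max(dn[j] - log(1.5), lo[j])
      (obj(up) - best$value) + (obj(dn) - best$value) >
        1e-6 * max(best$value, 1e-8)
    }, logical(1))
    if (!all(identifiable))
      warning("non-identifiable parameter(s): ",
              paste(free[!identifiable], collapse = ", "))
    list(estimates = est, objective = best$value,
         identifiable = stats::setNames(identifiable, free),
         converged = best$convergence == 0)
  })
}
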