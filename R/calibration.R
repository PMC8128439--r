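#' Validate a dose-response readout table
#'
#' A readout table holds replicate relative-expression measurements:
#' columns `dose` (fractions in \[0, 1\]), `replicate` (index), and
#' `expression` (positive, relative to the induced untreated control).
#' Errors name the first offending row.
#'
#' @param table A data frame.
#' @return The table as a tibble, invisibly valid.
#' @export
validate_readouts <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("dose", "expression")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("readout table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(table)) table$replicate <- 1L
  bad_dose <- which(!is.finite(table$dose) | table$dose < 0 | table$dose > 1)
  if (length(bad_dose)) {
    stop("row ", bad_dose[1], ": dose must lie in [0, 1] (got ",
         format(table$dose[bad_dose[1]]), ")", call. = FALSE)
  }
  bad_expr <- which(!is.finite(table$expression) | table$expression <= 0)
  if (length(bad_expr)) {
    stop("row ", bad_expr[1], ": expression must be positive (got ",
         format(table$expression[bad_expr[1]]), ")", call. = FALSE)
  }
  table
}

# internal: per-dose mean expression
readout_means <- function(table) {
  table |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(expression = mean(.data$expression), .groups = "drop") |>
    dplyr::arrange(.data$dose)
}

# internal: bounded multi-start Levenberg-Marquardt over a residual function
lm_multistart <- function(resid_fn, starts, lower) {
  fits <- lapply(starts, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("all optimizer starts failed", call. = FALSE)
  dev <- vapply(fits, stats::deviance, numeric(1))
  fits[[which.min(dev)]]
}

# internal: standard errors from an nls.lm fit, NA when not estimable
lm_se <- function(fit) {
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(fit$par)))
  if (length(se) != length(fit$par)) se <- rep(NA_real_, length(fit$par))
  unname(se)
}

#' Estimate a hyperbolic dose-response constant from readouts
#'
#' Nonlinear least squares of the single-agent model
#' `phi(x) = 1 / (1 + K x)` against the per-dose mean expression, with
#' `K >= 0` box-constrained. The optimizer is bounded Levenberg-Marquardt
#' started from K in \{0.1, 1, 10\} (best deviance kept), convergence
#' tolerance 1e-10, deterministic given the data. The loss is on the
#' expression scale by default, matching how relative-expression readouts
#' are reported; `log_scale = TRUE` fits on log expression instead.
#'
#' @param table A readout table (see [validate_readouts()]); at least 3
#'   distinct doses.
#' @param log_scale Fit on the log-expression scale?
#' @return An object of class `"k_fit"` with the estimate, its standard
#'   error, residual RMSE and a convergence flag; see [tidy()] and
#'   [glance()] methods.
#' @examples
#' tbl <- simulate_readouts(build_n1(), "meki", seq(0, 1, 0.1),
#'                          noise_sd = 0, seed = 1)
#' fit_hyperbolic_K(tbl)
#' @export
fit_hyperbolic_K <- function(table, log_scale = FALSE) {
  table <- validate_readouts(table)
  means <- readout_means(table)
  if (nrow(means) < 3L) {
    stop("need at least 3 distinct doses to fit K (got ", nrow(means), ")",
         call. = FALSE)
  }
  x <- means$dose
  y <- means$expression
  resid_fn <- if (log_scale) {
    function(par) log(y) - log(1 / (1 + par[1] * x))
  } else {
    function(par) y - 1 / (1 + par[1] * x)
  }
  fit <- lm_multistart(resid_fn, starts = list(0.1, 1, 10), lower = 0)
  res <- resid_fn(fit$par)
  structure(list(
    estimate = unname(fit$par[1]),
    std_error = lm_se(fit)[1],
    rmse = sqrt(mean(res^2)),
    converged = fit$info %in% 1:4,
    n_doses = nrow(means),
    n_obs = nrow(table),
    log_scale = log_scale,
    means = means,
    model = "hyperbolic"
  ), class = "k_fit")
}

#' Jointly estimate combination dose-response constants
#'
#' Least squares of the additive combination model
#' `phi(x) = max(0, 1 - sum_i K_i x / (1 + K_i x))` over the scenario's
#' drugs against per-dose mean expression. Constants named in `fixed` are
#' held at the given values; the rest are free (box-constrained >= 0) and
#' fitted by bounded multi-start Levenberg-Marquardt with deliberately
#' asymmetric starts (equal starts would leave identical constants
#' indistinguishable to the optimizer). Errors when the table has fewer
#' informative (nonzero) doses than free constants.
#'
#' The additive model is exchangeable in its constants: permuting the
#' `K_i` leaves `phi` unchanged, so with every constant free only the
#' multiset of constants is identifiable, and the drug labels attached to
#' the estimates are a convention of the optimizer. Fixing all but one
#' constant (the typical calibration use) removes the ambiguity.
#'
#' @param table A readout table.
#' @param scen A [scenario()] or preset name; drug names define the
#'   constants.
#' @param fixed Named numeric vector of constants to hold, e.g.
#'   `c(p38i = 2)`.
#' @param log_scale Fit on the log-expression scale?
#' @return An object of class `"scenario_fit"`; [tidy()] gives one row
#'   per drug with estimate, standard error and whether it was fixed.
#' @examples
#' tbl <- simulate_readouts(build_n1(), "4d_mapki", seq(0, 0.5, 0.05),
#'                          noise_sd = 0, seed = 1)
#' fit_scenario(tbl, "4d_mapki", fixed = c(p38i = 2, JNKi = 0.475628))
#' @export
fit_scenario <- function(table, scen, fixed = NULL, log_scale = FALSE) {
  if (is.character(scen)) scen <- scenario_preset(scen)
  stopifnot(inherits(scen, "scenario"))
  table <- validate_readouts(table)
  means <- readout_means(table)
  drug_names <- vapply(scen$drugs, `[[`, character(1), "name")
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), drug_names)
    if (length(bad)) {
      stop("fixed constant(s) not in scenario: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  free <- setdiff(drug_names, names(fixed))
  n_inform <- sum(means$dose > 0)
  if (length(free) > n_inform) {
    stop("unidentifiable: ", length(free), " free constant(s) but only ",
         n_inform, " informative (nonzero) dose(s)", call. = FALSE)
  }
  x <- means$dose
  y <- means$expression

  model_phi <- function(k_all) {
    removed <- Reduce(`+`, lapply(k_all, function(K) K * x / (1 + K * x)))
    pmax(0, 1 - removed)
  }
  assemble <- function(par) {
    k_all <- stats::setNames(numeric(length(drug_names)), drug_names)
    k_all[names(fixed)] <- fixed
    k_all[free] <- par
    k_all
  }
  resid_fn <- if (log_scale) {
    function(par) log(y) - log(pmax(model_phi(assemble(par)), 1e-12))
  } else {
    function(par) y - model_phi(assemble(par))
  }

  if (length(free)) {
    starts <- lapply(c(0.2, 1, 5), function(s) {
      s * seq(0.5, 1.5, length.out = length(free))
    })
    fit <- lm_multistart(resid_fn, starts = starts,
                         lower = rep(0, length(free)))
    est <- stats::setNames(unname(fit$par), free)
    se <- stats::setNames(lm_se(fit), free)
    converged <- fit$info %in% 1:4
    res <- resid_fn(fit$par)
  } else {
    est <- stats::setNames(numeric(0), character(0))
    se <- est
    converged <- TRUE
    res <- resid_fn(numeric(0))
  }

  k_hat <- assemble(unname(est))
  structure(list(
    estimates = k_hat,
    std_errors = stats::setNames(
      ifelse(drug_names %in% free, se[drug_names], NA_real_), drug_names),
    fixed = drug_names %in% names(fixed),
    rmse = sqrt(mean(res^2)),
    converged = converged,
    n_doses = nrow(means),
    n_obs = nrow(table),
    scenario = scen$name,
    log_scale = log_scale,
    means = means
  ), class = "scenario_fit")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_hyperbolic_K
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.k_fit <- function(x, ...) {
  tibble::tibble(term = "K", estimate = x$estimate, std.error = x$std_error)
}

#' @rdname fit_hyperbolic_K
#' @export
glance.k_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged,
                 n_doses = x$n_doses, n_obs = x$n_obs)
}

#' @rdname fit_scenario
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.scenario_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$std_errors),
    fixed = x$fixed
  )
}

#' @rdname fit_scenario
#' @export
glance.scenario_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, converged = x$converged,
                 n_doses = x$n_doses, n_obs = x$n_obs)
}

#' @export
print.k_fit <- function(x, ...) {
  cat(sprintf("<k_fit> K = %.6g (se %.3g), rmse %.3g, %s\n",
              x$estimate, x$std_error, x$rmse,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.scenario_fit <- function(x, ...) {
  cat(sprintf("<scenario_fit '%s'> rmse %.3g, %s\n", x$scenario, x$rmse,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}
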