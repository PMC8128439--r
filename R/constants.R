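#' Model constants for the stress MAPK driver network
#'
#' Returns the dose-response and redirection constants used throughout the
#' treatment and surplus models. `K1`, `K2`, `K4` tune the hyperbolic
#' dose-response of p38i, MEKi and MLKi respectively; `K3` governs the
#' inactivation of JNK (node 6) under JNKi; `gamma3` and `gamma4` set the
#' Hill-type redirection of MLK- and TAOK-derived flow toward p38 (node 8)
#' as JNK activity falls. All are dimensionless: doses are fractions of the
#' maximal inhibitor dose on \[0, 1\] and flows are fractions of the total
#' stress input.
#'
#' `gamma1` and `gamma2`, the strengths of the TAOK->ERK and JNK->ERK
#' repressions, are retained as slots but unassigned (`NA`): under maximal
#' stress node-4 (ERK) activity is treated as constant, so the repressions
#' carry no mass flow and never enter the computation.
#'
#' @param ... Named overrides, e.g. `mapk_constants(K2 = 0.5)`.
#' @return A named list with elements `K1`, `K2`, `K3`, `K4`, `gamma3`,
#'   `gamma4`, `gamma1`, `gamma2`.
#' @examples
#' mapk_constants()$K1
#' mapk_constants(K2 = 0.5)$K2
#' @export
mapk_constants <- function(...) {
  defaults <- list(
    K1 = 2,
    K2 = 0.4,
    K3 = 0.475628,
    K4 = 0.1,
    gamma3 = 1.520908,
    gamma4 = 1.435780,
    gamma1 = NA_real_,
    gamma2 = NA_real_
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown constant(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (!is.numeric(val) || length(val) != 1L || (!is.na(val) && val < 0)) {
        stop("constant '", nm, "' must be a single nonnegative number", call. = FALSE)
      }
      defaults[[nm]] <- as.numeric(val)
    }
  }
  defaults
}

#' Split fractions for the N1 driver-network topology
#'
#' Constructs and validates the branching fractions of the nine-node stress
#' network. At the signal-splitting node the three outgoing fractions are
#' `alpha1` (to RAF), `alpha2` (to MLK) and the derived `A12 = 1 - alpha1 -
#' alpha2` (to TAOK). At each two-way branch `k = 3..6` the fractions are
#' `alphak` and the derived `Ak = 1 - alphak`:
#' `alpha3`/`A3` split MLK output between JNK and p38, `alpha4`/`A4` split
#' TAOK output between JNK and p38, `alpha5`/`A5` split p38 output between
#' the BACH1 output and ERK, and `alpha6`/`A6` split ERK output between the
#' BACH1 output and JNK.
#'
#' `alpha1 = 0.2` is the one printed value for the N1 network; the
#' remaining defaults (`alpha2 = 0.2`, `alpha3..alpha6 = 0.5`) are the
#' package's documented defaults, and every closed-form result shipped with
#' the package is independent of them.
#'
#' @param alpha1,alpha2 Fractions of the stress signal routed to RAF and
#'   MLK; must satisfy `alpha1 + alpha2 <= 1`.
#' @param alpha3,alpha4,alpha5,alpha6 Two-way branch fractions, each in
#'   \[0, 1\].
#' @return A list of class `"split_params"` containing the six alphas and
#'   the derived complements `A12`, `A3`, `A4`, `A5`, `A6`.
#' @examples
#' split_params()
#' split_params(alpha3 = 1, alpha4 = 0, alpha5 = 1, alpha6 = 1) # N2 settings
#' @export
split_params <- function(alpha1 = 0.2, alpha2 = 0.2, alpha3 = 0.5,
                         alpha4 = 0.5, alpha5 = 0.5, alpha6 = 0.5) {
  vals <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
               alpha4 = alpha4, alpha5 = alpha5, alpha6 = alpha6)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("split fraction '", nm, "' must be a single number in [0, 1]",
           call. = FALSE)
    }
  }
  if (alpha1 + alpha2 > 1 + 1e-12) {
    stop("invalid splits: alpha1 + alpha2 must not exceed 1 (got ",
         format(alpha1 + alpha2), ")", call. = FALSE)
  }
  out <- c(vals, list(
    A12 = 1 - alpha1 - alpha2,
    A3 = 1 - alpha3,
    A4 = 1 - alpha4,
    A5 = 1 - alpha5,
    A6 = 1 - alpha6
  ))
  structure(out, class = "split_params")
}

#' @export
print.split_params <- function(x, ...) {
  cat("<split_params>\n")
  cat(sprintf("  alpha1..alpha6: %s\n",
              paste(format(unlist(x[paste0("alpha", 1:6)]), digits = 4),
                    collapse = ", ")))
  cat(sprintf("  derived A12, A3..A6: %s\n",
              paste(format(unlist(x[c("A12", paste0("A", 3:6))]), digits = 4),
                    collapse = ", ")))
  invisible(x)
}

# internal: deterministic sub-stream seed per purpose, kept within 32-bit range
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(seed) * 48271 + h) %% 2147483647L)
}
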