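#' Specify an inhibitor drug
#'
#' A drug targets one kinase node and carries a dose-response constant `K`.
#' p38i, MEKi and MLKi use the hyperbolic model, under which relative
#' BACH1 output is `1 / (1 + K x)` at dose fraction `x`; JNKi uses the
#' redirection model (`model = "jnk_redirection"`), in which inhibiting
#' JNK reroutes MLK- and TAOK-derived flow toward p38 through Hill-type
#' crosstalk capacities.
#'
#' @param name Drug name; one of `"p38i"`, `"MEKi"`, `"JNKi"`, `"MLKi"`.
#' @param target_node Node id of the targeted kinase.
#' @param K Nonnegative dose-response constant.
#' @param model `"hyperbolic"` or `"jnk_redirection"` (the latter only for
#'   JNKi).
#' @return A list of class `"drug_spec"`.
#' @seealso [drug_preset()]
#' @export
drug_spec <- function(name, target_node, K,
                      model = c("hyperbolic", "jnk_redirection")) {
  model <- match.arg(model)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K < 0) {
    stop("K must be a single nonnegative number", call. = FALSE)
  }
  if (model == "jnk_redirection" && name != "JNKi") {
    stop("the jnk_redirection model is reserved for JNKi", call. = FALSE)
  }
  if (name == "JNKi" && model != "jnk_redirection") {
    stop("JNKi must use the jnk_redirection model", call. = FALSE)
  }
  structure(list(name = name, target_node = as.integer(target_node),
                 K = as.numeric(K), model = model),
            class = "drug_spec")
}

#' Preset drugs of the four-drug MAPK inhibitor panel
#'
#' Returns the canonical [drug_spec()] for one of the four inhibitors of
#' the 4D-MAPKi combination, with its printed dose-response constant:
#' p38i (SB203580, node 8, K1 = 2), MEKi (trametinib, node 3, K2 = 0.4),
#' JNKi (SP600125, node 6, K3 = 0.475628), MLKi (URMC-099, node 5,
#' K4 = 0.1).
#'
#' @param name One of `"p38i"`, `"meki"`, `"jnki"`, `"mlki"`
#'   (case-insensitive).
#' @param constants Constant set from [mapk_constants()], allowing K
#'   overrides.
#' @return A `drug_spec`.
#' @examples
#' drug_preset("meki")
#' @export
drug_preset <- function(name, constants = mapk_constants()) {
  switch(tolower(name),
    "p38i" = drug_spec("p38i", 8L, constants$K1, "hyperbolic"),
    "meki" = drug_spec("MEKi", 3L, constants$K2, "hyperbolic"),
    "jnki" = drug_spec("JNKi", 6L, constants$K3, "jnk_redirection"),
    "mlki" = drug_spec("MLKi", 5L, constants$K4, "hyperbolic"),
    stop("unknown drug preset '", name, "'", call. = FALSE)
  )
}

#' Define a treatment scenario
#'
#' A scenario is a set of drugs applied jointly at a common dose fraction,
#' optionally with an inhibition cap (e.g. 0.3 for the restricted-dose
#' 4D-MAPKi regimen). Drugs must target distinct nodes.
#'
#' @param drugs A list of [drug_spec()] objects (or a single one).
#' @param name Scenario name used to tag results.
#' @param inhibition_cap Optional fraction in (0, 1); stored for use by
#'   restricted-dose analyses such as [max_dose_for_cap()].
#' @return A list of class `"scenario"`.
#' @seealso [scenario_preset()]
#' @export
scenario <- function(drugs, name = "custom", inhibition_cap = NULL) {
  if (inherits(drugs, "drug_spec")) drugs <- list(drugs)
  stopifnot(all(vapply(drugs, inherits, logical(1), "drug_spec")))
  targets <- vapply(drugs, `[[`, integer(1), "target_node")
  if (anyDuplicated(targets)) {
    stop("scenario drugs must target distinct nodes", call. = FALSE)
  }
  if (!is.null(inhibition_cap) &&
      (inhibition_cap <= 0 || inhibition_cap >= 1)) {
    stop("inhibition_cap must lie in (0, 1)", call. = FALSE)
  }
  structure(list(name = name, drugs = drugs, inhibition_cap = inhibition_cap),
            class = "scenario")
}

#' Preset treatment scenarios
#'
#' `"p38i"`, `"meki"`, `"jnki"`, `"mlki"` are the single-agent scenarios;
#' `"4d_mapki"` is the four-drug combination with its 0.3 inhibition cap.
#'
#' @param name Preset name (case-insensitive).
#' @param constants Constant set from [mapk_constants()].
#' @return A `scenario`.
#' @examples
#' scenario_preset("4d_mapki")
#' @export
scenario_preset <- function(name, constants = mapk_constants()) {
  key <- tolower(name)
  if (key %in% c("p38i", "meki", "jnki", "mlki")) {
    return(scenario(drug_preset(key, constants), name = key))
  }
  if (key %in% c("4d_mapki", "4d-mapki", "4d")) {
    return(scenario(
      lapply(c("p38i", "meki", "jnki", "mlki"), drug_preset, constants = constants),
      name = "4d_mapki", inhibition_cap = 0.3
    ))
  }
  stop("unknown scenario preset '", name, "'", call. = FALSE)
}

#' Fractional reduction of a target kinase's activity
#'
#' At dose fraction `x`, the activity of the targeted node falls by
#' `xi = (K / inflow) * x / (1 + K x)`, so that the absorbed-signal loss
#' `xi * inflow = K x / (1 + K x)` depends on the drug constant only. With
#' the printed constants the raw `xi` can exceed 1 at high dose when the
#' target's untreated inflow is small; the value is returned unclamped and
#' a coherence warning is emitted, since the closed-form treatment curves
#' take precedence over per-node bookkeeping.
#'
#' @param drug A [drug_spec()].
#' @param x Dose fraction(s) in \[0, 1\].
#' @param inflow The target node's untreated inflow (a positive fraction
#'   of total input).
#' @param warn Emit the coherence warning when `xi > 1`? Default `TRUE`.
#' @return `xi`, same length as `x`.
#' @examples
#' node_inhibition(drug_preset("meki"), 0.16, inflow = 0.2)
#' @export
node_inhibition <- function(drug, x, inflow, warn = TRUE) {
  stopifnot(inherits(drug, "drug_spec"))
  if (!is.numeric(inflow) || length(inflow) != 1L || inflow <= 0) {
    stop("inflow must be a single positive number (xi is undefined at 0)",
         call. = FALSE)
  }
  check_dose(x)
  xi <- (drug$K / inflow) * x / (1 + drug$K * x)
  if (warn && any(xi > 1)) {
    warning("coherence: raw xi exceeds 1 for ", drug$name,
            " (target inflow ", format(inflow),
            " smaller than the signal the dose removes)", call. = FALSE)
  }
  xi
}

#' Hyperbolic relative BACH1 output
#'
#' The single-agent dose-response model for drugs whose surplus is not
#' redirected within the network (p38i, MEKi, MLKi): relative BACH1
#' transcription `phi = 1 / (1 + K x)` at dose fraction `x`.
#'
#' @param K Nonnegative dose-response constant.
#' @param x Dose fraction(s) in \[0, 1\].
#' @return `phi` in (0, 1], same length as `x`.
#' @examples
#' bach1_hyperbolic(2, c(0, 0.5, 1))
#' @export
bach1_hyperbolic <- function(K, x) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 0)
  check_dose(x)
  1 / (1 + K * x)
}

#' JNK (node 6) inflow under JNKi treatment
#'
#' The inflow of the JNK node at dose fraction `x` is its untreated inflow
#' attenuated hyperbolically, `Y6(x) = Y6(0) / (1 + K3 x)`. When MLKi is
#' co-administered (`mlki_active = TRUE`), the MLK-derived contribution
#' inside `Y6(0)` is first rebalanced by `1 / (1 + K4 x)`; this is
#' computed by running [propagate()] with the MLK node's activity scaled,
#' not by a transcribed closed form.
#'
#' @param topology An N1-like `network_topology` (must contain nodes
#'   labeled "JNK" and "MLK").
#' @param x Dose fraction(s) in \[0, 1\].
#' @param mlki_active Is MLKi applied at the same dose fraction?
#' @param constants Constant set from [mapk_constants()].
#' @return `Y6(x)`, same length as `x`.
#' @export
jnk_inflow <- function(topology, x, mlki_active = FALSE,
                       constants = mapk_constants()) {
  check_dose(x)
  vapply(x, function(xi) {
    act <- if (mlki_active) {
      activity_profile(topology, MLK = 1 / (1 + constants$K4 * xi))
    } else {
      activity_profile(topology)
    }
    fs <- propagate(topology, act)
    y6 <- fs$inflow[fs$label == "JNK"]
    if (!length(y6)) stop("topology has no node labeled 'JNK'", call. = FALSE)
    y6 / (1 + constants$K3 * xi)
  }, numeric(1))
}

#' Hill-type crosstalk redirection capacity
#'
#' The capacity of the MLK->p38 and TAOK->p38 crosstalk increases as JNK
#' activity falls: `Gamma = 1 / (1 + (gamma * y6)^4)`, a decreasing Hill
#' function of the JNK inflow `y6` with exponent 4 and midpoint at
#' `gamma * y6 = 1`.
#'
#' @param gamma Redirection constant (`gamma3` or `gamma4` of
#'   [mapk_constants()]).
#' @param y6 JNK inflow value(s), nonnegative.
#' @return `Gamma` in (0, 1], same length as `y6`.
#' @examples
#' hill_redirection(1.520908, jnk_inflow(build_n1(), 1))
#' @export
hill_redirection <- function(gamma, y6) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0)
  if (any(y6 < 0)) stop("y6 must be nonnegative", call. = FALSE)
  1 / (1 + (gamma * y6)^4)
}

#' Relative BACH1 output under single-agent JNKi
#'
#' JNK represses ERK and has compensatory crosstalk with p38, so JNKi uses
#' a redirection model rather than the hyperbolic form: p38 absorbs two
#' thirds of the flow rerouted from MLK and TAOK as JNK activity falls,
#' and the remaining third, `eps6(x) = (1/3) * (Gamma3(x) + Gamma4(x) -
#' Gamma3(0) - Gamma4(0))`, escapes the network. Relative output is
#' `phi = 1 - eps6(x)`, clamped into \[0, 1\].
#'
#' @inheritParams jnk_inflow
#' @return `phi`, same length as `x`.
#' @examples
#' bach1_jnki(build_n1(), c(0, 0.5, 1))
#' @export
bach1_jnki <- function(topology, x, constants = mapk_constants()) {
  eps6 <- surplus_node6(topology, x, mlki_active = FALSE, constants = constants)
  pmin(pmax(1 - eps6, 0), 1)
}

#' Relative BACH1 output under an additive drug combination
#'
#' For a multi-drug scenario at common dose fraction `x` the effects are
#' additive to first approximation: each drug removes `xi_i * Y_i =
#' K_i x / (1 + K_i x)` of the signal, and
#' `phi = max(0, 1 - sum_i K_i x / (1 + K_i x))`. The JNKi term enters in
#' the same hyperbolic form (via K3); the redirection machinery is the
#' single-agent JNKi model.
#'
#' @param topology A `network_topology` (tags the result; the additive
#'   closed form itself depends only on the drug constants).
#' @param scen A [scenario()].
#' @param x Dose fraction(s) in \[0, 1\].
#' @return `phi` in \[0, 1\], same length as `x`.
#' @examples
#' bach1_combo(build_n1(), scenario_preset("4d_mapki"), 0.3)
#' @export
bach1_combo <- function(topology, scen, x) {
  stopifnot(inherits(scen, "scenario"))
  check_dose(x)
  if (!length(scen$drugs)) return(rep(1, length(x)))
  removed <- Reduce(`+`, lapply(scen$drugs, function(d) {
    d$K * x / (1 + d$K * x)
  }))
  pmax(0, 1 - removed)
}

#' Predicted dose-response curve of relative BACH1 output
#'
#' Evaluates the scenario-appropriate output model across a dose grid:
#' the hyperbolic closed form for single-agent p38i/MEKi/MLKi, the
#' redirection model for single-agent JNKi on a topology with active
#' crosstalk, the pure branch-loss form `1 - K3 x / (1 + K3 x)` for JNKi
#' on a crosstalk-free topology (no p38 redirection available; the whole
#' surplus is exported), and the additive combination for multi-drug
#' scenarios.
#'
#' @param topology A `network_topology`.
#' @param scen A [scenario()] or preset name understood by
#'   [scenario_preset()].
#' @param doses Sorted dose grid in \[0, 1\]; default `seq(0, 1, 0.01)`.
#' @param constants Constant set from [mapk_constants()].
#' @return A tibble of class `"dose_response_curve"` with columns `dose`,
#'   `phi_bach1`, `suppression_pct`, `scenario`, `topology`.
#' @examples
#' dose_response(build_n1(), "p38i", c(0, 0.5, 1))
#' @export
dose_response <- function(topology, scen, doses = seq(0, 1, by = 0.01),
                          constants = mapk_constants()) {
  if (is.character(scen)) scen <- scenario_preset(scen, constants)
  stopifnot(inherits(scen, "scenario"))
  check_dose(doses)
  if (is.unsorted(doses)) stop("doses must be sorted increasing", call. = FALSE)

  phi <- if (length(scen$drugs) == 1L) {
    d <- scen$drugs[[1]]
    if (d$model == "hyperbolic") {
      bach1_hyperbolic(d$K, doses)
    } else if (crosstalk_present(topology)) {
      bach1_jnki(topology, doses, constants = constants)
    } else {
      pmax(0, 1 - d$K * doses / (1 + d$K * doses))
    }
  } else {
    bach1_combo(topology, scen, doses)
  }

  curve <- tibble::tibble(
    dose = doses,
    phi_bach1 = phi,
    suppression_pct = 100 * (1 - phi),
    scenario = scen$name,
    topology = topology$name
  )
  class(curve) <- c("dose_response_curve", class(curve))
  curve
}

#' Largest dose keeping target inhibition at or below a cap
#'
#' Solves `xi(x*) = cap` analytically for the restricted-dose regimen:
#' with `Delta = K / inflow`, `x* = cap / (Delta - K * cap)`. Errors when
#' the cap is unattainable within the model (`Delta <= K * cap`).
#'
#' @param drug A [drug_spec()].
#' @param inflow The target node's untreated inflow.
#' @param cap Desired activity-reduction fraction in \[0, 1).
#' @return The dose fraction `x*` (0 when `cap = 0`).
#' @examples
#' max_dose_for_cap(drug_preset("meki"), inflow = 0.2, cap = 0.3)
#' @export
max_dose_for_cap <- function(drug, inflow, cap) {
  stopifnot(inherits(drug, "drug_spec"))
  if (!is.numeric(inflow) || length(inflow) != 1L || inflow <= 0) {
    stop("inflow must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(cap) || length(cap) != 1L || cap < 0 || cap >= 1) {
    stop("cap must lie in [0, 1)", call. = FALSE)
  }
  if (cap == 0) return(0)
  delta <- drug$K / inflow
  denom <- delta - drug$K * cap
  if (denom <= 0) {
    stop("cap ", format(cap), " unreachable for ", drug$name,
         ": K/inflow = ", format(delta), " <= K*cap = ",
         format(drug$K * cap), call. = FALSE)
  }
  cap / denom
}

# internal: dose-grid validation shared by the treatment functions
check_dose <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop("dose fractions must be numeric values in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s: target node %d, K = %s, model = %s\n",
              x$name, x$target_node, format(x$K), x$model))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'>: %s%s\n", x$name,
              paste(vapply(x$drugs, `[[`, character(1), "name"),
                    collapse = " + "),
              if (!is.null(x$inhibition_cap)) {
                sprintf(" (inhibition cap %.0f%%)", 100 * x$inhibition_cap)
              } else ""))
  invisible(x)
}
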