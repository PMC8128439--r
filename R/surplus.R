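#' Surplus signal exported from RAF under MEKi
#'
#' Inhibiting MEK leaves part of the RAF product unabsorbed:
#' `eps_RAF(x) = K2 x / (1 + K2 x)` as a fraction of the total stress
#' input. The same function describes the RAF surplus under the 4D-MAPKi
#' combination, since the network nodes operate at maximal capacity and
#' the surplus is not redirected within the network absent a repressive
#' interaction.
#'
#' @param x Dose fraction(s) in \[0, 1\].
#' @param K MEKi dose-response constant (default `K2 = 0.4`).
#' @return Surplus fraction(s), same length as `x`.
#' @examples
#' surplus_raf(c(0.3, 1)) # ~0.107 at the restricted dose, ~0.286 maximal
#' @export
surplus_raf <- function(x, K = mapk_constants()$K2) {
  check_dose(x)
  K * x / (1 + K * x)
}

#' Surplus stress signal exported upstream of MLK under MLKi
#'
#' `eps_SIG(x) = K4 x / (1 + K4 x)`: the fraction of raw stress signal the
#' inhibited MLK node fails to absorb, assumed not redirected within the
#' driver network.
#'
#' @inheritParams surplus_raf
#' @param K MLKi dose-response constant (default `K4 = 0.1`).
#' @return Surplus fraction(s).
#' @export
surplus_signal <- function(x, K = mapk_constants()$K4) {
  check_dose(x)
  K * x / (1 + K * x)
}

#' Surplus generated at p38 (node 8) under p38i
#'
#' `eps8(x) = K1 x / (1 + K1 x)`: the combination of the surplus signals
#' generated by treatment targeting JNK and p38 itself, as a fraction of
#' total input. Identically `1 - bach1_hyperbolic(K1, x)`.
#'
#' @inheritParams surplus_raf
#' @param K p38i dose-response constant (default `K1 = 2`).
#' @return Surplus fraction(s).
#' @export
surplus_node8 <- function(x, K = mapk_constants()$K1) {
  check_dose(x)
  K * x / (1 + K * x)
}

#' Surplus escaping the network at JNK (node 6) under JNKi
#'
#' When JNK is inhibited, p38 absorbs two thirds of the flow rerouted from
#' MLK and TAOK; the remaining third escapes toward compensatory networks:
#' `eps6(x) = (1/3) * (Gamma3(x) + Gamma4(x) - Gamma3(0) - Gamma4(0))`
#' with `Gammak = 1 / (1 + (gammak * Y6)^4)` evaluated at the treated JNK
#' inflow [jnk_inflow()]. Zero at `x = 0`, nonnegative and below 1/3 by
#' construction.
#'
#' @inheritParams jnk_inflow
#' @return `eps6`, same length as `x`.
#' @examples
#' surplus_node6(build_n1(), c(0, 1))
#' @export
surplus_node6 <- function(topology, x, mlki_active = FALSE,
                          constants = mapk_constants()) {
  check_dose(x)
  y6x <- jnk_inflow(topology, x, mlki_active = mlki_active, constants = constants)
  y60 <- jnk_inflow(topology, 0, mlki_active = FALSE, constants = constants)
  (hill_redirection(constants$gamma3, y6x) +
     hill_redirection(constants$gamma4, y6x) -
     hill_redirection(constants$gamma3, y60) -
     hill_redirection(constants$gamma4, y60)) / 3
}

#' Allocate the JNKi/p38i surplus to the upstream kinases MLK and TAOK
#'
#' The surpluses generated at JNK (`eps6`) and p38 (`eps8`) originate from
#' the upstream MLK and TAOK nodes, in proportion to the absorption
#' capacity of the respective crosstalk pathways:
#' `eps_MLK = eps6 * Gamma3(x) + alpha4 * eps8(x)` and
#' `eps_TAOK = eps6 * (1 - Gamma3(x)) + A4 * eps8(x)`. Since
#' `alpha4 + A4 = 1`, the allocation conserves: `eps_MLK + eps_TAOK =
#' eps6 + eps8` for every dose and split.
#'
#' @inheritParams jnk_inflow
#' @param jnki_active,p38i_active Which of the two generating treatments
#'   are applied (their component is 0 otherwise).
#' @return A tibble with columns `dose`, `eps_mlk`, `eps_taok`,
#'   `eps_node6`, `eps_node8`.
#' @examples
#' allocate_upstream_surplus(build_n1(), 0.3)
#' @export
allocate_upstream_surplus <- function(topology, x, mlki_active = FALSE,
                                      jnki_active = TRUE, p38i_active = TRUE,
                                      constants = mapk_constants()) {
  check_dose(x)
  alpha4 <- topology$splits[["alpha4"]]
  A4 <- topology$splits[["A4"]]
  if (is.null(alpha4) || is.null(A4)) {
    stop("topology does not carry the alpha4/A4 split (not N1-like)",
         call. = FALSE)
  }
  eps6 <- if (jnki_active) {
    surplus_node6(topology, x, mlki_active = mlki_active, constants = constants)
  } else rep(0, length(x))
  eps8 <- if (p38i_active) surplus_node8(x, K = constants$K1) else rep(0, length(x))
  g3 <- hill_redirection(
    constants$gamma3,
    jnk_inflow(topology, x, mlki_active = mlki_active, constants = constants)
  )
  tibble::tibble(
    dose = x,
    eps_mlk = eps6 * g3 + alpha4 * eps8,
    eps_taok = eps6 * (1 - g3) + A4 * eps8,
    eps_node6 = eps6,
    eps_node8 = eps8
  )
}

#' Threshold policy for compensatory-network activation
#'
#' A compensatory kinase network (e.g. PI3K/AKT) is assumed to switch on
#' when the surplus funneled to it reaches the activation threshold
#' `theta`, a fraction of the total stress input. The default 0.3 reflects
#' the experimentally observed onset of AKT activation once ERK inhibition
#' reaches about 30%; it is a policy parameter, not a fitted constant.
#'
#' @param theta Activation threshold in (0, 1).
#' @return A list of class `"threshold_policy"`.
#' @export
threshold_policy <- function(theta = 0.3) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("theta must lie in (0, 1)", call. = FALSE)
  }
  structure(list(theta = theta), class = "threshold_policy")
}

#' Per-kinase surplus report across a dose grid
#'
#' Evaluates, for each dose of a scenario, the surplus signal exported
#' toward compensatory networks from each upstream kinase: RAF (from
#' MEKi), raw signal (from MLKi), and MLK/TAOK (carrying the allocated
#' JNKi/p38i surpluses). The total is the sum of the four exported
#' components. Activation flags compare each component with the policy
#' threshold.
#'
#' @param topology A `network_topology` (N1-like when JNKi or p38i is in
#'   the scenario).
#' @param scen A [scenario()] or preset name; any subset of the 4D-MAPKi
#'   panel.
#' @param doses Dose grid in \[0, 1\].
#' @param policy A [threshold_policy()].
#' @param constants Constant set from [mapk_constants()].
#' @return A tibble of class `"surplus_report"` with columns `dose`,
#'   `eps_raf`, `eps_sig`, `eps_mlk`, `eps_taok`, `eps_node6`,
#'   `eps_node8`, `total`, the per-kinase activation flags `act_raf`,
#'   `act_sig`, `act_mlk`, `act_taok`, and `any_activated`.
#' @examples
#' total_surplus(build_n1(), "4d_mapki", c(0, 0.3, 1))
#' @export
total_surplus <- function(topology, scen, doses = seq(0, 1, by = 0.01),
                          policy = threshold_policy(),
                          constants = mapk_constants()) {
  if (is.character(scen)) scen <- scenario_preset(scen, constants)
  stopifnot(inherits(scen, "scenario"), inherits(policy, "threshold_policy"))
  check_dose(doses)
  drug_names <- vapply(scen$drugs, `[[`, character(1), "name")
  has <- function(d) d %in% drug_names

  ks <- stats::setNames(vapply(scen$drugs, `[[`, numeric(1), "K"), drug_names)
  eps_raf <- if (has("MEKi")) surplus_raf(doses, K = ks[["MEKi"]]) else rep(0, length(doses))
  eps_sig <- if (has("MLKi")) surplus_signal(doses, K = ks[["MLKi"]]) else rep(0, length(doses))
  if (has("JNKi") || has("p38i")) {
    alloc <- allocate_upstream_surplus(
      topology, doses, mlki_active = has("MLKi"),
      jnki_active = has("JNKi"), p38i_active = has("p38i"),
      constants = constants
    )
  } else {
    alloc <- tibble::tibble(dose = doses, eps_mlk = 0, eps_taok = 0,
                            eps_node6 = 0, eps_node8 = 0)
  }

  theta <- policy$theta
  rep_tbl <- tibble::tibble(
    dose = doses,
    eps_raf = eps_raf,
    eps_sig = eps_sig,
    eps_mlk = alloc$eps_mlk,
    eps_taok = alloc$eps_taok,
    eps_node6 = alloc$eps_node6,
    eps_node8 = alloc$eps_node8,
    total = eps_raf + eps_sig + alloc$eps_mlk + alloc$eps_taok,
    act_raf = eps_raf >= theta,
    act_sig = eps_sig >= theta,
    act_mlk = alloc$eps_mlk >= theta,
    act_taok = alloc$eps_taok >= theta
  )
  rep_tbl$any_activated <- rep_tbl$act_raf | rep_tbl$act_sig |
    rep_tbl$act_mlk | rep_tbl$act_taok
  class(rep_tbl) <- c("surplus_report", class(rep_tbl))
  attr(rep_tbl, "theta") <- theta
  attr(rep_tbl, "scenario") <- scen$name
  attr(rep_tbl, "topology") <- topology$name
  rep_tbl
}

#' Re-evaluate activation flags of a surplus report under a policy
#'
#' Compares each exported surplus component with the activation threshold
#' and returns the report with refreshed per-kinase flags and the
#' `any_activated` summary. Flags are monotone in dose because every
#' surplus component is nondecreasing.
#'
#' @param report A `"surplus_report"` tibble from [total_surplus()].
#' @param policy A [threshold_policy()].
#' @return The report with updated flag columns and `theta` attribute.
#' @examples
#' rep <- total_surplus(build_n1(), "meki", c(0, 0.5, 1))
#' compensatory_activation(rep, threshold_policy(0.25))
#' @export
compensatory_activation <- function(report, policy = threshold_policy()) {
  stopifnot(inherits(report, "surplus_report"),
            inherits(policy, "threshold_policy"))
  theta <- policy$theta
  report$act_raf <- report$eps_raf >= theta
  report$act_sig <- report$eps_sig >= theta
  report$act_mlk <- report$eps_mlk >= theta
  report$act_taok <- report$eps_taok >= theta
  report$any_activated <- report$act_raf | report$act_sig |
    report$act_mlk | report$act_taok
  attr(report, "theta") <- theta
  report
}
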