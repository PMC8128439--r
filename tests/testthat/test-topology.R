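test_that("N1 has the canonical node and edge structure", {
  n1 <- build_n1(split_params(alpha1 = 0.2, alpha2 = 0.2))
  expect_equal(nrow(n1$nodes), 9)
  mass <- n1$edges[n1$edges$kind != "repression", ]
  expect_equal(nrow(mass), 14)
  expect_equal(sum(n1$edges$kind == "crosstalk"), 4)
  expect_equal(sum(n1$edges$kind == "repression"), 2)
  # repressions point at ERK from TAOK and JNK
  repr <- n1$edges[n1$edges$kind == "repression", ]
  expect_setequal(repr$src, c(6L, 7L))
  expect_true(all(repr$dst == 4L))
})

test_that("invalid split parameters are rejected", {
  expect_error(split_params(alpha1 = 0.7, alpha2 = 0.5), "alpha1 \\+ alpha2")
  expect_error(split_params(alpha3 = 1.2), "must be a single number")
  expect_error(build_n1(split_params(alpha1 = 0.7, alpha2 = 0.5)))
})

test_that("untreated propagation conserves the full input signal", {
  fs1 <- propagate(build_n1())
  expect_identical(output_flow(fs1), 1)
  expect_equal(conservation_residual(fs1), 0, tolerance = 1e-15)
  # inflow/outflow equal at every node when untreated
  expect_equal(fs1$inflow, fs1$outflow)

  withr::with_seed(101, {
    for (i in 1:200) {
      fs <- propagate(build_n1(random_split_params()))
      expect_lt(abs(output_flow(fs) - 1), 1e-12)
    }
  })
})

test_that("propagation reproduces the hand-derived N1 flow pattern", {
  # alpha1=alpha2=0.2, branch fractions 0.5: Y8=0.4, Y4=0.4, Y6=0.6
  fs <- propagate(build_n1())
  expect_equal(fs$inflow[fs$label == "RAF"], 0.2)
  expect_equal(fs$inflow[fs$label == "MLK"], 0.2)
  expect_equal(fs$inflow[fs$label == "TAOK"], 0.6)
  expect_equal(fs$inflow[fs$label == "p38"], 0.4)
  expect_equal(fs$inflow[fs$label == "ERK"], 0.4)
  expect_equal(fs$inflow[fs$label == "JNK"], 0.6)
})

test_that("degenerate splits collapse N1 to a single chain", {
  fs <- propagate(build_n1(split_params(alpha1 = 1, alpha2 = 0)))
  get <- function(lab) fs$inflow[fs$label == lab]
  expect_equal(get("RAF"), 1)
  expect_equal(get("MEK"), 1)
  expect_equal(get("ERK"), 1)
  expect_equal(get("MLK"), 0)
  expect_equal(get("TAOK"), 0)
  expect_identical(output_flow(fs), 1)
})

test_that("N2 is crosstalk-free and each chain carries its source split", {
  n2 <- build_n2(alpha1 = 0.3, alpha2 = 0.25)
  fs <- propagate(n2)
  # per-branch flows alpha1, alpha2, A12 arrive intact at the terminal kinases
  expect_equal(fs$inflow[fs$label == "ERK"], 0.3)
  expect_equal(fs$inflow[fs$label == "JNK"], 0.25)
  expect_equal(fs$inflow[fs$label == "p38"], 0.45)
  expect_identical(output_flow(fs), 1)

  # no kinase receives flow along more than one nonzero edge
  mass <- n2$edges[n2$edges$kind != "repression", ]
  frac <- vapply(mass$fraction_name, function(nm) {
    if (nm == "one") 1 else n2$splits[[nm]]
  }, numeric(1))
  live <- mass[frac > 0, ]
  kin <- n2$nodes$id[n2$nodes$role == "kinase"]
  indeg <- table(factor(live$dst, levels = kin))
  expect_true(all(indeg <= 1))
})

test_that("N2 flows equal N1 flows at the crosstalk-free parameter point", {
  n1_at_n2 <- build_n1(split_params(alpha1 = 0.2, alpha2 = 0.2,
                                    alpha3 = 1, alpha4 = 0,
                                    alpha5 = 1, alpha6 = 1))
  fs_a <- propagate(n1_at_n2)
  fs_b <- propagate(build_n2())
  expect_equal(fs_a$inflow, fs_b$inflow, tolerance = 1e-15)
  expect_equal(fs_a$outflow, fs_b$outflow, tolerance = 1e-15)
})

test_that("treated propagation books the deficit as node-local loss", {
  n1 <- build_n1()
  fs <- propagate(n1, activity_profile(n1, MEK = 0.5))
  expect_equal(fs$loss[fs$label == "MEK"], 0.5 * 0.2)
  expect_lt(conservation_residual(fs), 1e-9)
  expect_lt(output_flow(fs), 1)

  # corrupting the bookkeeping is detected
  bad <- fs
  bad$loss[2] <- bad$loss[2] + 0.05
  expect_gt(conservation_residual(bad), 0.04)
})

test_that("structural violations are rejected with informative errors", {
  nodes <- tibble::tibble(id = 1:3, label = c("signal", "K", "OUT"),
                          role = c("source", "kinase", "output"))
  # cycle in the mass subgraph
  expect_error(network_topology(
    nodes,
    tibble::tibble(src = c(1L, 2L, 3L), dst = c(2L, 3L, 2L),
                   fraction_name = "one", kind = "pathway"),
    splits = list()
  ), "output node must not emit|cycle")
  # unresolved fraction name
  expect_error(network_topology(
    nodes,
    tibble::tibble(src = c(1L, 2L), dst = c(2L, 3L),
                   fraction_name = c("mystery", "one"), kind = "pathway"),
    splits = list()
  ), "unresolved fraction")
  # fractions not summing to one
  expect_error(network_topology(
    nodes,
    tibble::tibble(src = c(1L, 1L, 2L), dst = c(2L, 3L, 3L),
                   fraction_name = c("a", "a", "one"), kind = "pathway"),
    splits = list(a = 0.4)
  ), "do not sum to 1")
  # two sources
  expect_error(network_topology(
    tibble::tibble(id = 1:3, label = c("s1", "s2", "OUT"),
                   role = c("source", "source", "output")),
    tibble::tibble(src = c(1L, 2L), dst = c(3L, 3L),
                   fraction_name = "one", kind = "pathway"),
    splits = list()
  ), "exactly one source")
})

test_that("activity profiles resolve labels and clamp to the unit interval", {
  n1 <- build_n1()
  act <- activity_profile(n1, p38 = 0.7, "3" = 0.4)
  expect_equal(unname(act[["8"]]), 0.7)
  expect_equal(unname(act[["3"]]), 0.4)
  expect_true(all(act >= 0 & act <= 1))
  expect_equal(unname(activity_profile(n1, MEK = -0.5)[["3"]]), 0)
  expect_error(activity_profile(n1, NOTANODE = 0.5), "unknown node")
})
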