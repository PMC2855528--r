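test_that("a constant-speed source grows linearly at every sampled point", {
  net <- single_source_net("1.0")
  tr <- simulate_net(net, end = 10, dt = 0.01)
  expect_identical(nrow(tr), 1000L)
  expect_equal(tr$p[1000], 9.99, tolerance = 1e-12)
  expect_lt(max(abs(tr$p - tr$time)), 1e-9)   # closed form M[p](x) = x
})

test_that("a net with no enabled transition stays at its initial marking", {
  net <- hfpne_net(
    places = list(place("p", "continuous", initial = 0.4)),
    transitions = transition("t", "continuous"),
    arcs = list(arc("p", "t", "normal", activity = "1.0", update = "1.0"),
                arc("t", "p", "normal", update = "2.0")))
  tr <- simulate_net(net, end = 2, dt = 0.01)
  expect_true(all(tr$p == 0.4))
})

test_that("a delay-2 discrete firing moves tokens exactly at x + 2", {
  tr <- simulate_net(transfer_net(delay = 2, initial = 5), end = 3, dt = 0.01)
  at <- function(x) which(abs(tr$time - x) < 1e-9)
  expect_identical(tr$`in`[at(1.99)], 5)
  expect_identical(tr$out[at(1.99)], 0)
  expect_identical(tr$`in`[at(2.00)], 4)
  expect_identical(tr$out[at(2.00)], 1)
  # elapsed-delay bookkeeping: time since trigger while pending
  expect_equal(tr$`delay:t`[at(1.0)], 1.0, tolerance = 1e-9)
  # token conservation across the transfer
  expect_true(all(tr$`in` + tr$out == 5))
  # still enabled after firing: re-triggers and fires again every 2 [pt]
  expect_identical(tr$`in`[at(2.99)], 4)
})

test_that("a switched-off continuous transition contributes nothing", {
  # source enabled only while p < 1: growth must stop once p reaches 1
  net <- hfpne_net(
    places = place("p", "continuous", initial = 0),
    transitions = transition("src", "continuous"),
    arcs = list(arc("p", "src", "inhibitory", activity = "1.0"),
                arc("src", "p", "normal", update = "1.0")))
  tr <- simulate_net(net, end = 3, dt = 0.01)
  expect_lt(max(tr$p), 1.0 + 0.01 + 1e-9)
  expect_equal(tr$p[300], max(tr$p), tolerance = 1e-12)
})

test_that("conflicts resolve greedily in priority order", {
  demands <- data.frame(transition = c("t_a", "t_b"),
                        place = c("p", "p"), amount = c(1, 1))
  expect_identical(resolve_conflicts(demands, c(p = 1)), "t_a")
  # no conflict when the summed demand fits
  demands2 <- data.frame(transition = c("t_a", "t_b"),
                         place = c("p", "p"), amount = c(1, 2))
  expect_identical(resolve_conflicts(demands2, c(p = 5)), c("t_a", "t_b"))
  expect_identical(resolve_conflicts(demands[0, ], c(p = 5)), character(0))
  # greedy is maximal: a later small demand still fits after a rejection
  demands3 <- data.frame(transition = c("t_a", "t_b", "t_c"),
                         place = "p", amount = c(2, 4, 1))
  expect_identical(resolve_conflicts(demands3, c(p = 3)), c("t_a", "t_c"))
})

test_that("two discrete transitions contending for one token: one fires", {
  net <- hfpne_net(
    places = list(place("p", "discrete", initial = 1),
                  place("q1", "discrete"), place("q2", "discrete")),
    transitions = list(transition("t_a", "discrete", delay = "1"),
                       transition("t_b", "discrete", delay = "1")),
    arcs = list(arc("p", "t_a", "normal", activity = "0", update = "1"),
                arc("t_a", "q1", "normal", update = "1"),
                arc("p", "t_b", "normal", activity = "0", update = "1"),
                arc("t_b", "q2", "normal", update = "1")))
  tr <- simulate_net(net, end = 2, dt = 0.01)
  last <- nrow(tr)
  expect_identical(tr$q1[last], 1)   # declaration-order priority wins
  expect_identical(tr$q2[last], 0)
  expect_true(any(grepl("conflict", attr(tr, "log"))))
})

test_that("premature disable follows the configured policy", {
  # a continuous drain pulls the input below threshold before the delay
  net <- hfpne_net(
    places = list(place("p", "continuous", initial = 1.5),
                  place("q", "continuous"), place("sink", "continuous")),
    transitions = list(transition("td", "discrete", delay = "2"),
                       transition("drain", "continuous")),
    arcs = list(arc("p", "td", "normal", activity = "1.0", update = "1"),
                arc("td", "q", "normal", update = "1"),
                arc("p", "drain", "normal", activity = "0", update = "1.0"),
                arc("drain", "sink", "normal", update = "1.0")))
  tr <- simulate_net(net, sim_config(3, 0.01))
  expect_true(all(tr$q == 0))
  expect_true(any(grepl("disabled before", attr(tr, "log"))))
  expect_error(
    simulate_net(net, sim_config(3, 0.01, on_premature_disable = "error")),
    "disabled before")
})

test_that("generic firing replaces the mark using trigger-time values", {
  net <- hfpne_net(
    places = list(place("mode", "generic", initial = "wt"),
                  place("lvl", "continuous", initial = 2)),
    transitions = transition("flip", "generic", delay = "1"),
    arcs = list(arc("lvl", "flip", "test", activity = "lvl > 1"),
                arc("flip", "mode", "normal", update = '"ko"')),
    id = "generic_flip")
  tr <- simulate_net(net, end = 2, dt = 0.5)
  expect_identical(tr$mode, c("wt", "wt", "ko", "ko"))
})

test_that("identical net and config give a bit-identical trace", {
  net <- toy_oscillator()
  t1 <- simulate_net(net, end = 5, dt = 0.01)
  t2 <- simulate_net(net, end = 5, dt = 0.01)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("the trace carries exactly end/dt points", {
  expect_identical(nrow(simulate_net(single_source_net(), end = 1.5,
                                     dt = 0.01)), 150L)
  expect_error(sim_config(1, 0.3), "divide")
})
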