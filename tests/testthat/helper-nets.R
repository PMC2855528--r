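# Shared net builders for the test suite.  All fixtures are built in code.

# One always-enabled continuous transition feeding place p at constant speed.
single_source_net <- function(rate = "1.0") {
  hfpne_net(
    places = place("p", "continuous", initial = 0),
    transitions = transition("src", "continuous"),
    arcs = arc("src", "p", "normal", update = rate),
    id = "single_source")
}

# Discrete transfer: in --(u=1, thr 0)--> t[delay] --(u=1)--> out.
transfer_net <- function(delay = 2, initial = 5) {
  hfpne_net(
    places = list(place("in", "discrete", initial = initial),
                  place("out", "discrete", initial = 0)),
    transitions = transition("t", "discrete", delay = format(delay)),
    arcs = list(arc("in", "t", "normal", activity = "0", update = "1"),
                arc("t", "out", "normal", update = "1")),
    id = "transfer")
}

# The worked repressed-transition configuration: transition t with a
# satisfied normal input arc c1, an inhibitory arc c2 whose threshold is
# exceeded (active repression), and an output arc; extraction must retain
# exactly {t, the inhibiting place, c2}.
repressed_net <- function() {
  hfpne_net(
    places = list(place("pl1", "continuous", initial = 5),
                  place("pl2", "continuous", initial = 2),
                  place("po1", "continuous", initial = 0)),
    transitions = transition("t", "continuous"),
    arcs = list(arc("pl1", "t", "normal", activity = "0", update = "1.0",
                    id = "c1"),
                arc("pl2", "t", "inhibitory", activity = "1.0", id = "c2"),
                arc("t", "po1", "normal", update = "1.0", id = "aout")),
    id = "repressed")
}

# Hand-built subnet record (for feeding build_astd directly).
make_subnet <- function(places, transitions, arcs, time = 0,
                        net_id = "hand") {
  structure(list(net_id = net_id, times = time,
                 places = places, transitions = transitions, arcs = arcs),
            class = "hfpne_subnet")
}

# Continuous random-net spec used by the resimulation properties.
cont_spec <- function(seed, n_places = 5, n_transitions = 4,
                      n_arcs = 9)
  fixture_spec(seed, n_places, n_transitions, n_arcs,
               kind_mix = c(discrete = 0, continuous = 1, generic = 0))

# Independent brute-force classification of one input arc (test oracle,
# evaluated straight from the definitions, bypassing classify_arcs()).
oracle_arc_status <- function(net, a, marks) {
  vars <- lapply(net$places, `[[`, "variable")
  env <- list()
  for (pid in names(marks)) env[[vars[[pid]]]] <- marks[[pid]]
  w <- eval_expr(a$activity, env)
  val <- marks[[a$from]]
  if (a$label == "inhibitory") {
    if (is.logical(w)) isTRUE(w) else w < val      # enabled-inhibitory?
  } else {
    if (is.logical(w)) isFALSE(w) else w >= val    # disabled?
  }
}

# Wrap a plain data frame as a trace object.
new_trace_for_test <- function(df, dt) {
  hfpne:::new_trace(df, dt = dt, net_id = "test",
                    place_ids = setdiff(names(df), "time"),
                    delay_ids = character(0))
}

# Marking from a trace row.
row_marks <- function(net, trace, i) {
  marks <- lapply(names(net$places), function(pid) trace[[pid]][[i]])
  names(marks) <- names(net$places)
  marks
}
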