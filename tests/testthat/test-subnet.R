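test_that("arc classification follows the printed set definitions", {
  net <- repressed_net()
  m <- hfpne_marking(net)
  cls <- classify_arcs(net, m)
  expect_identical(cls$t$enabled_inhibitory, "c2")   # 1.0 < 2
  expect_identical(cls$t$disabled, character(0))     # 0 < 5: c1 enabled
  # boundary of the printed >=: threshold 0 against value 0 is disabled
  m$marks$pl1 <- 0
  expect_identical(classify_arcs(net, m)$t$disabled, "c1")
})

test_that("classification agrees with per-arc brute force on random nets", {
  for (seed in 1:30) {
    net <- random_net(fixture_spec(seed, 6, 5, 12,
                                   kind_mix = c(discrete = 0.2,
                                                continuous = 0.8,
                                                generic = 0)))
    m <- hfpne_marking(net)
    cls <- classify_arcs(net, m)
    for (tid in names(net$transitions)) {
      ti <- net$index$trans[[tid]]
      for (aid in c(ti$in_normal, ti$in_test))
        expect_identical(aid %in% cls[[tid]]$disabled,
                         oracle_arc_status(net, net$arcs[[aid]], m$marks),
                         info = paste(seed, aid))
      for (aid in ti$in_inhib)
        expect_identical(aid %in% cls[[tid]]$enabled_inhibitory,
                         oracle_arc_status(net, net$arcs[[aid]], m$marks),
                         info = paste(seed, aid))
    }
  }
})

test_that("an actively repressed transition keeps only its inhibitory arc", {
  net <- repressed_net()
  s <- extract_temporal_subnet(net, hfpne_marking(net))
  expect_identical(s$places, "pl2")        # the inhibiting place survives
  expect_identical(s$transitions, "t")     # t cannot be removed
  expect_identical(s$arcs, "c2")           # c1, aout deleted; pl1, po1 swept
})

test_that("a fully enabled net is retained whole; a fully disabled one empties", {
  net <- hfpne_net(
    places = list(place("a", "continuous", initial = 2),
                  place("b", "continuous", initial = 2)),
    transitions = transition("t", "continuous"),
    arcs = list(arc("a", "t", "normal", activity = "1.0", update = "0.1"),
                arc("t", "b", "normal", update = "0.1")))
  s <- extract_temporal_subnet(net, hfpne_marking(net))
  expect_setequal(s$places, c("a", "b"))
  expect_identical(s$transitions, "t")
  expect_setequal(s$arcs, names(net$arcs))
  # below threshold everywhere: everything is swept away
  m <- hfpne_marking(net, marks = list(a = 0.5, b = 0.5))
  s0 <- extract_temporal_subnet(net, m)
  expect_length(s0$places, 0)
  expect_length(s0$transitions, 0)
  expect_length(s0$arcs, 0)
})

test_that("quiescent inhibitory arcs are pruned from a firing transition", {
  net <- repressed_net()
  m <- hfpne_marking(net, marks = list(pl1 = 5, pl2 = 0.5, po1 = 0))
  s <- extract_temporal_subnet(net, m)   # inhibition off, t fires
  expect_setequal(s$arcs, c("c1", "aout"))
  expect_setequal(s$places, c("pl1", "po1"))
})

test_that("extraction is idempotent and monotone, with no isolated elements", {
  for (seed in 1:20) {
    net <- random_net(cont_spec(seed))
    m <- hfpne_marking(net)
    s <- extract_temporal_subnet(net, m)
    expect_true(all(s$places %in% names(net$places)))
    expect_true(all(s$transitions %in% names(net$transitions)))
    expect_true(all(s$arcs %in% names(net$arcs)))
    # no isolated element survives
    for (aid in s$arcs) {
      a <- net$arcs[[aid]]
      expect_true(all(c(a$from, a$to) %in% c(s$places, s$transitions)))
    }
    for (tid in s$transitions) {
      ti <- net$index$trans[[tid]]
      expect_true(any(c(ti$in_arcs, ti$out_arcs) %in% s$arcs))
    }
    for (pid in s$places) {
      pi <- net$index$place[[pid]]
      expect_true(any(c(pi$in_arcs, pi$out_arcs) %in% s$arcs))
    }
    # idempotence: extracting from the subnet reproduces the subnet
    if (length(s$transitions)) {
      sub <- subnet_net(net, s)
      m2 <- hfpne_marking(sub, marks = m$marks[s$places])
      s2 <- extract_temporal_subnet(sub, m2)
      expect_setequal(s2$places, s$places)
      expect_setequal(s2$transitions, s$transitions)
      expect_setequal(s2$arcs, s$arcs)
    }
  }
})

test_that("extract_all returns one subnet per time point, duplicates kept", {
  net <- toy_oscillator()
  tr <- simulate_net(net, end = 30, dt = 0.01)
  sn <- extract_all(net, tr)
  expect_length(sn, 3000L)
  keys <- vapply(sn, canonical_key, "")
  expect_gte(length(unique(keys)), 2L)
  # per-point extraction agrees with the vectorised path
  for (i in c(1L, 500L, 2999L)) {
    s1 <- extract_temporal_subnet(net, hfpne_marking(net, row_marks(net, tr, i),
                                                     time = tr$time[i]))
    expect_identical(canonical_key(s1), keys[[i]])
  }
  # a model whose enabling never changes yields one structure throughout
  src <- single_source_net()
  tr2 <- simulate_net(src, end = 1, dt = 0.01)
  expect_length(unique(vapply(extract_all(src, tr2), canonical_key, "")), 1L)
  # place-name mismatch is a descriptive error
  expect_error(extract_all(net, tr2), "lacks column")
})

test_that("one-step resimulation of the subnet matches the full model", {
  bad <- 0L
  for (seed in 1:40) {
    net <- random_net(cont_spec(seed))
    tr <- simulate_net(net, end = 0.5, dt = 0.01)
    sn <- extract_all(net, tr)
    for (i in c(1L, 10L, 30L)) {
      s <- sn[[i]]
      if (length(s$transitions) == 0L) next
      sub <- subnet_net(net, s)
      nxt <- euler_step(sub, row_marks(net, tr, i)[s$places], 0.01)
      for (pid in s$places)
        if (!identical(nxt[[pid]], tr[[pid]][i + 1L])) bad <- bad + 1L
    }
  }
  expect_identical(bad, 0L)
})

test_that("deleting any retained arc perturbs a one-step outcome", {
  # enumerated tiny nets: 1..3 transitions, each with a normal or an
  # inhibitory input arc, source mark below or above the threshold 1
  one_step_profile <- function(net, marks) {
    en <- vapply(names(net$transitions), function(tid)
      is_transition_enabled(net, tid, hfpne_marking(net, marks)), TRUE)
    list(en = en, step = euler_step(net, marks, 0.1))
  }
  configs <- expand.grid(rep(list(1:4), 3))
  for (nt in 1:3) {
    cases <- unique(configs[seq_len(nrow(configs)), seq_len(nt), drop = FALSE])
    for (r in seq_len(nrow(cases))) {
      places <- list()
      transitions <- list()
      arcs <- list()
      marks <- list()
      for (k in seq_len(nt)) {
        cfg <- cases[r, k]   # 1: normal/low 2: normal/high 3: inhib/low 4: inhib/high
        pin <- paste0("p", k) ; pout <- paste0("q", k) ; tid <- paste0("t", k)
        places <- c(places, list(place(pin, "continuous"),
                                 place(pout, "continuous")))
        transitions <- c(transitions, list(transition(tid, "continuous")))
        lab <- if (cfg <= 2) "normal" else "inhibitory"
        arcs <- c(arcs, list(
          arc(pin, tid, lab, activity = "1",
              update = if (lab == "normal") "0.5"),
          arc(tid, pout, "normal", update = "0.5")))
        marks[[pin]] <- if (cfg %% 2 == 1) 0.5 else 1.5
        marks[[pout]] <- 0
      }
      net <- hfpne_net(places, transitions, arcs, id = "tiny")
      s <- extract_temporal_subnet(net, hfpne_marking(net, marks))
      if (length(s$arcs) == 0L) next
      sub <- subnet_net(net, s)
      base <- one_step_profile(sub, marks[s$places])
      for (aid in s$arcs) {
        pruned <- hfpne_net(sub$places, sub$transitions,
                            sub$arcs[setdiff(s$arcs, aid)], id = "pruned")
        prof <- one_step_profile(pruned, marks[s$places])
        changed <- !identical(prof$en, base$en) ||
          !identical(prof$step[s$places], base$step[s$places])
        expect_true(changed, info = paste("nt", nt, "case", r, "arc", aid))
      }
    }
  }
})
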