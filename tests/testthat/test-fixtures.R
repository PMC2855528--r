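test_that("the toy oscillator is valid and cycles through several states", {
  net <- toy_oscillator()
  expect_identical(nrow(validate_net(net)), 0L)
  tr <- simulate_net(net, end = 150, dt = 0.01)
  astd <- build_astd(extract_all(net, tr))
  # frozen regression values for the packaged configuration
  expect_identical(length(astd$nodes), 7L)
  expect_gte(length(astd$nodes), 2L)
  # recurring states (entered more than once) form one strongly
  # connected cycle once the initial transient is discarded
  entries <- table(rle(astd$Q)$values)
  recurring <- as.integer(names(entries)[entries > 1])
  e <- astd$edges
  e <- e[e$src %in% recurring & e$dst %in% recurring, ]
  g <- igraph::graph_from_data_frame(e[, c("src", "dst")],
                                     vertices = data.frame(name = recurring))
  comp <- igraph::components(g, mode = "strong")
  expect_identical(as.integer(comp$no), 1L)
  expect_gte(igraph::girth(g)$girth, 3)
  # determinism of the packaged configuration
  astd2 <- build_astd(extract_all(net, simulate_net(net, end = 150, dt = 0.01)))
  expect_identical(astd2$keys, astd$keys)
  expect_identical(astd2$edges, astd$edges)
})

test_that("the random-net generator is a pure function of its spec", {
  s <- fixture_spec(7, 5, 4, 9)
  n1 <- random_net(s)
  n2 <- random_net(s)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_net(n1, f1); write_net(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_length(n1$places, 5L)
  expect_length(n1$transitions, 4L)
  expect_length(n1$arcs, 9L)
})

test_that("generated nets always validate, across kind mixes", {
  mixes <- list(c(discrete = 0, continuous = 1, generic = 0),
                c(discrete = 0.4, continuous = 0.6, generic = 0),
                c(discrete = 0.3, continuous = 0.5, generic = 0.2))
  for (mix in mixes)
    for (seed in 1:20) {
      net <- random_net(fixture_spec(seed, 6, 5, 12, kind_mix = mix))
      expect_identical(nrow(validate_net(net)), 0L,
                       info = paste(seed, paste(mix, collapse = "/")))
    }
  expect_error(random_net(fixture_spec(1, 3, 2, 4,
    kind_mix = c(discrete = 1, continuous = 0, generic = 0))), NA)
  expect_error(random_net(fixture_spec(1, 0, 2, 4,
    kind_mix = c(discrete = 0, continuous = 1, generic = 0))),
    "infeasible")
})

test_that("the circadian scaffold wires in the printed fragments", {
  net <- circadian_scaffold()
  expect_identical(nrow(validate_net(net)), 0L)
  rates <- vapply(net$arcs, function(a)
    if (is.null(a$update)) "" else a$update$text, "")
  expect_true("m_7*m_12/1000" %in% rates)   # PER/DBT complex formation
  expect_true("m_1/5" %in% rates)           # dCLK translation
  # two inhibitory arcs from PER/TIM into the transcription transitions
  inhib <- Filter(function(a) a$label == "inhibitory" &&
                    a$from == "PER_TIM", net$arcs)
  expect_setequal(vapply(inhib, `[[`, "", "to"),
                  c("per_transcription", "tim_transcription"))
  # TIM translation gated at the printed threshold 1.0
  tim_arc <- Filter(function(a) a$to == "TIM_translation", net$arcs)[[1]]
  expect_identical(tim_arc$activity$text, "1.0")
  # missing parameters are reported all at once
  p <- circadian_default_params()
  p$r_per_txn <- NULL; p$th_per_tln <- NULL
  err <- tryCatch(circadian_scaffold(p), error = conditionMessage)
  expect_match(err, "r_per_txn")
  expect_match(err, "th_per_tln")
})

test_that("the dbt-long mutant changes exactly the formation formula", {
  net <- circadian_scaffold()
  mut <- make_dbt_mutant(net, "m_7*m_12/5000")
  expect_identical(names(mut$places), names(net$places))
  expect_identical(names(mut$arcs), names(net$arcs))
  changed <- names(net$arcs)[vapply(names(net$arcs), function(aid) {
    a <- net$arcs[[aid]]; b <- mut$arcs[[aid]]
    !identical(if (is.null(a$update)) "" else a$update$text,
               if (is.null(b$update)) "" else b$update$text)
  }, TRUE)]
  # all changed slots carry the single formation formula
  ti <- net$index$trans$per_dbt_formation
  expect_setequal(changed, c(ti$in_normal, ti$out_arcs))
  olds <- unique(vapply(net$arcs[changed], function(a) a$update$text, ""))
  expect_identical(olds, "m_7*m_12/1000")
  # identity transform: replacing with the old rate changes nothing
  same <- make_dbt_mutant(net, "m_7*m_12/1000")
  expect_identical(lapply(same$arcs, function(a)
    if (is.null(a$update)) "" else a$update$text),
    lapply(net$arcs, function(a)
      if (is.null(a$update)) "" else a$update$text))
  expect_error(make_dbt_mutant(toy_oscillator(), "1.0"), "no transition")
})

test_that("net files round-trip through the YAML schema", {
  net <- random_net(fixture_spec(3, 5, 4, 9,
    kind_mix = c(discrete = 0.3, continuous = 0.5, generic = 0.2)))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_net(net, f)
  back <- read_net(f)
  expect_identical(names(back$places), names(net$places))
  expect_identical(names(back$arcs), names(net$arcs))
  expect_identical(vapply(back$arcs, function(a)
    if (is.null(a$activity)) "" else a$activity$text, ""),
    vapply(net$arcs, function(a)
      if (is.null(a$activity)) "" else a$activity$text, ""))
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_net(back, f2)
  expect_identical(readLines(f), readLines(f2))
})
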