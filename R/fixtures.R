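#' Two-species relaxation oscillator
#'
#' A minimal continuous net exhibiting sustained state cycling: an
#' activator A is synthesised at constant speed while a repressor B is
#' below threshold, A drives B's synthesis through a test arc once A
#' exceeds threshold, and both degrade at first-order speeds.  The
#' negative feedback through the inhibitory arc (threshold 1.0) makes the
#' enabling pattern - and hence the temporal subnet - cycle through
#' several structurally distinct states.
#'
#' @return An [hfpne_net()] that passes [validate_net()].
#' @examples
#' tr <- simulate_net(toy_oscillator(), end = 30, dt = 0.01)
#' astd <- build_astd(extract_all(toy_oscillator(), tr))
#' astd
#' @export
toy_oscillator <- function() {
  hfpne_net(
    places = list(
      place("A", "continuous", initial = 0, variable = "a",
            name = "activator"),
      place("B", "continuous", initial = 0, variable = "b",
            name = "repressor")),
    transitions = list(
      transition("A_syn", "continuous", name = "A synthesis"),
      transition("A_deg", "continuous", name = "A degradation"),
      transition("B_syn", "continuous", name = "B synthesis"),
      transition("B_deg", "continuous", name = "B degradation")),
    arcs = list(
      arc("B", "A_syn", "inhibitory", activity = "1.0"),
      arc("A_syn", "A", "normal", update = "1.0"),
      arc("A", "A_deg", "normal", activity = "0", update = "0.3*a"),
      arc("A", "B_syn", "test", activity = "1.0"),
      arc("B_syn", "B", "normal", update = "0.5"),
      arc("B", "B_deg", "normal", activity = "0", update = "0.2*b")),
    id = "toy_oscillator")
}

#' Specification for the seeded random-net generator
#'
#' @param seed Integer seed; the generated net is a pure function of the
#'   spec.
#' @param n_places,n_transitions,n_arcs Element counts (>= 0);
#'   `n_arcs` defaults to two per transition.
#' @param kind_mix Named fractions (`discrete`, `continuous`, `generic`)
#'   summing to 1, applied to places and transitions alike.
#' @param name Label recorded as the net id.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_places, n_transitions,
                         n_arcs = 2L * n_transitions,
                         kind_mix = c(discrete = 0, continuous = 1,
                                      generic = 0),
                         name = paste0("random-", seed)) {
  stopifnot(n_places >= 0, n_transitions >= 0, n_arcs >= 0,
            abs(sum(kind_mix) - 1) < 1e-9)
  mix <- c(discrete = 0, continuous = 0, generic = 0)
  mix[names(kind_mix)] <- kind_mix
  structure(list(name = name, seed = as.integer(seed),
                 n_places = as.integer(n_places),
                 n_transitions = as.integer(n_transitions),
                 n_arcs = as.integer(n_arcs), kind_mix = mix),
            class = "fixture_spec")
}

# Run expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Largest-remainder apportionment of n elements across the kind mix.
apportion_kinds <- function(n, mix) {
  if (n == 0L) return(character(0))
  raw <- mix * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

#' Generate a random valid HFPNe net
#'
#' Property-test driver: builds a net with the requested element counts
#' and kind mix, enforcing the typing rules by construction (normal arcs
#' of continuous transitions touch only continuous places; normal input
#' places of discrete transitions are non-generic).  Thresholds are
#' constants; update speeds are positive constants or linear in the arc's
#' own endpoint place, so every expression is closed over the places the
#' transition connects.  The same spec always yields the identical net.
#'
#' @param spec A [fixture_spec()].
#' @return An [hfpne_net()].
#' @export
random_net <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    pkinds <- sample(apportion_kinds(spec$n_places, spec$kind_mix))
    tkinds <- sample(apportion_kinds(spec$n_transitions, spec$kind_mix))
    if (any(tkinds == "continuous") && !any(pkinds == "continuous"))
      stop("infeasible spec: continuous transitions need at least one ",
           "continuous place", call. = FALSE)
    if (any(tkinds == "discrete") && all(pkinds == "generic"))
      stop("infeasible spec: discrete transitions need a non-generic place",
           call. = FALSE)
    places <- lapply(seq_len(spec$n_places), function(i) {
      k <- pkinds[[i]]
      init <- switch(k,
                     discrete = sample(0:5, 1),
                     continuous = round(stats::runif(1, 0, 2), 6),
                     generic = sample(c("wt", "ko", "gf"), 1))
      place(paste0("p", i), k, initial = init, variable = paste0("m", i))
    })
    names(places) <- vapply(places, `[[`, "", "id")
    transitions <- lapply(seq_len(spec$n_transitions), function(i) {
      k <- tkinds[[i]]
      transition(paste0("t", i), k,
                 delay = if (k != "continuous")
                   format(sample(c(0.5, 1, 2), 1)))
    })
    cont_p <- names(places)[pkinds == "continuous"]
    nongen_p <- names(places)[pkinds != "generic"]
    arcs <- list()
    for (j in seq_len(spec$n_arcs)) {
      ti <- ((j - 1L) %% max(spec$n_transitions, 1L)) + 1L
      tid <- paste0("t", ti)
      tkind <- tkinds[[ti]]
      # the first arc a transition receives is an input arc
      input <- j <= spec$n_transitions || stats::runif(1) < 0.5
      label <- if (!input) "normal"
               else sample(c("normal", "test", "inhibitory"), 1,
                           prob = c(0.6, 0.2, 0.2))
      pool <- if (label == "normal" && tkind == "continuous") cont_p
              else if (tkind == "generic") names(places)
              else nongen_p
      if (length(pool) == 0L) pool <- names(places)
      pid <- sample(pool, 1)
      pvar <- places[[pid]]$variable
      thr <- if (tkind == "generic") {
        if (places[[pid]]$kind == "generic")
          sprintf('%s == "wt"', pvar)
        else sprintf("%s > %.4f", pvar, stats::runif(1, 0, 2))
      } else format(round(stats::runif(1, 0, 1.5), 4))
      upd <- if (tkind == "discrete") "1"
             else if (tkind == "generic") format(round(stats::runif(1, 0, 2), 4))
             else if (stats::runif(1) < 0.5)
               format(round(stats::runif(1, 0.1, 1), 4))
             else sprintf("%.4f*%s", round(stats::runif(1, 0.05, 0.5), 4), pvar)
      arcs[[j]] <- if (input)
        arc(pid, tid, label, activity = thr, update =
              if (label == "normal") upd, id = paste0("a", j))
      else arc(tid, pid, "normal", update = upd, id = paste0("a", j))
    }
    hfpne_net(places, transitions, arcs, id = spec$name)
  })
}

#' Default parameter set for the circadian scaffold
#'
#' SYNTHETIC values: the full parameter set of the original circadian
#' model is not publicly printed, so these defaults are a plausible,
#' non-authoritative completion chosen once for the unprinted slots.  The
#' printed fragments (dCLK translation speed `m_1/5`, PER/DBT formation
#' speed `m_7*m_12/1000`, tim-translation threshold 1.0) are wired into
#' the scaffold itself and are not part of this list.
#'
#' @return Named list of rate expressions and thresholds.
#' @export
circadian_default_params <- function() {
  list(
    th_dclkcyc_inhibit  = "1.0",   # dCLK/CYC represses dClk transcription
    th_pertim_activate  = "0.5",   # PER/TIM activates dClk transcription
    th_dclkcyc_activate = "0.5",   # dCLK/CYC activates per/tim transcription
    th_pertim_inhibit   = "1.0",   # PER/TIM represses per/tim transcription
    th_dClk_tln = "0.1", th_per_tln = "0.1",
    r_dClk_txn = "1.0", r_per_txn = "1.5", r_tim_txn = "1.5",
    r_CYC_syn = "0.5", r_DBT_syn = "0.3",
    r_PER_tln = "m_5/5", r_TIM_tln = "m_6/5",
    r_dclkcyc_form = "m_2*m_3/10", r_pertim_form = "m_7*m_8/10",
    r_deg_dClk_mRNA = "m_1/10", r_deg_per_mRNA = "m_5/10",
    r_deg_tim_mRNA = "m_6/10", r_deg_dCLK = "m_2/10",
    r_deg_CYC = "m_3/10", r_deg_PER = "m_7/10", r_deg_TIM = "m_8/10",
    r_deg_PER_TIM = "m_9/10", r_deg_PER_DBT = "m_10/10",
    r_deg_dCLK_CYC = "m_4/10", r_deg_DBT = "m_12/10")
}

#' Circadian-clock model scaffold
#'
#' A parameter-configurable HFPNe of the Drosophila circadian oscillator:
#' two interlocked negative feedback loops in which PER/TIM represses per
#' and tim transcription (two inhibitory arcs) while activating dClk
#' transcription, and dCLK/CYC activates per/tim transcription while
#' repressing dClk transcription.  The printed fragments are wired in by
#' default: dCLK is translated at speed `m_1/5`, PER and DBT form PER/DBT
#' at speed `m_7*m_12/1000` (the `per_dbt_formation` transition targeted
#' by [make_dbt_mutant()]), and TIM translation requires tim mRNA above
#' 1.0.  Every other rate and threshold comes from `params`; the shipped
#' defaults ([circadian_default_params()]) are synthetic.
#'
#' @param params Named list supplying every unprinted rate/threshold; a
#'   missing slot raises an error listing all missing slots.
#' @return An [hfpne_net()].
#' @export
circadian_scaffold <- function(params = circadian_default_params()) {
  need <- names(circadian_default_params())
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("missing circadian parameter slot(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- params
  sp <- function(id, var, init, name) place(id, "continuous", init,
                                            name = name, variable = var)
  places <- list(
    sp("dClk_mRNA", "m_1", 1.0, "dClk mRNA"),
    sp("dCLK", "m_2", 0.5, "dCLK protein"),
    sp("CYC", "m_3", 0.5, "CYC protein"),
    sp("dCLK_CYC", "m_4", 0, "dCLK/CYC complex"),
    sp("per_mRNA", "m_5", 1.0, "per mRNA"),
    sp("tim_mRNA", "m_6", 1.0, "tim mRNA"),
    sp("PER", "m_7", 0.5, "PER protein"),
    sp("TIM", "m_8", 0.5, "TIM protein"),
    sp("PER_TIM", "m_9", 0, "PER/TIM complex"),
    sp("PER_DBT", "m_10", 0, "PER/DBT complex"),
    sp("DBT", "m_12", 0.5, "DBT kinase"))
  ct <- function(id, name) transition(id, "continuous", name = name)
  transitions <- list(
    ct("dClk_transcription", "dClk transcription"),
    ct("dCLK_translation", "dCLK translation"),
    ct("CYC_synthesis", "CYC synthesis"),
    ct("dclkcyc_formation", "dCLK/CYC complex formation"),
    ct("per_transcription", "per transcription"),
    ct("tim_transcription", "tim transcription"),
    ct("PER_translation", "PER translation"),
    ct("TIM_translation", "TIM translation"),
    ct("pertim_formation", "PER/TIM complex formation"),
    ct("per_dbt_formation", "PER/DBT complex formation"),
    ct("DBT_synthesis", "DBT synthesis"))
  deg <- list(dClk_mRNA = p$r_deg_dClk_mRNA, per_mRNA = p$r_deg_per_mRNA,
              tim_mRNA = p$r_deg_tim_mRNA, dCLK = p$r_deg_dCLK,
              CYC = p$r_deg_CYC, PER = p$r_deg_PER, TIM = p$r_deg_TIM,
              PER_TIM = p$r_deg_PER_TIM, PER_DBT = p$r_deg_PER_DBT,
              dCLK_CYC = p$r_deg_dCLK_CYC, DBT = p$r_deg_DBT)
  for (pid in names(deg))
    transitions[[length(transitions) + 1L]] <-
      ct(paste0(pid, "_degradation"), paste0(pid, " degradation"))
  pdbt_rate <- "m_7*m_12/1000"
  arcs <- c(list(
    # dClk transcription: repressed by dCLK/CYC, activated by PER/TIM
    arc("dCLK_CYC", "dClk_transcription", "inhibitory",
        activity = p$th_dclkcyc_inhibit),
    arc("PER_TIM", "dClk_transcription", "test",
        activity = p$th_pertim_activate),
    arc("dClk_transcription", "dClk_mRNA", "normal", update = p$r_dClk_txn),
    # dCLK translation at the printed speed m_1/5
    arc("dClk_mRNA", "dCLK_translation", "test", activity = p$th_dClk_tln),
    arc("dCLK_translation", "dCLK", "normal", update = "m_1/5"),
    arc("CYC_synthesis", "CYC", "normal", update = p$r_CYC_syn),
    # dCLK/CYC formation consumes both partners
    arc("dCLK", "dclkcyc_formation", "normal", activity = "0",
        update = p$r_dclkcyc_form),
    arc("CYC", "dclkcyc_formation", "normal", activity = "0",
        update = p$r_dclkcyc_form),
    arc("dclkcyc_formation", "dCLK_CYC", "normal",
        update = p$r_dclkcyc_form),
    # per transcription: activated by dCLK/CYC, repressed by PER/TIM
    arc("dCLK_CYC", "per_transcription", "test",
        activity = p$th_dclkcyc_activate),
    arc("PER_TIM", "per_transcription", "inhibitory",
        activity = p$th_pertim_inhibit),
    arc("per_transcription", "per_mRNA", "normal", update = p$r_per_txn),
    # tim transcription: same regulation
    arc("dCLK_CYC", "tim_transcription", "test",
        activity = p$th_dclkcyc_activate),
    arc("PER_TIM", "tim_transcription", "inhibitory",
        activity = p$th_pertim_inhibit),
    arc("tim_transcription", "tim_mRNA", "normal", update = p$r_tim_txn),
    arc("per_mRNA", "PER_translation", "test", activity = p$th_per_tln),
    arc("PER_translation", "PER", "normal", update = p$r_PER_tln),
    # TIM translation requires tim mRNA above the printed threshold 1.0
    arc("tim_mRNA", "TIM_translation", "test", activity = "1.0"),
    arc("TIM_translation", "TIM", "normal", update = p$r_TIM_tln),
    arc("PER", "pertim_formation", "normal", activity = "0",
        update = p$r_pertim_form),
    arc("TIM", "pertim_formation", "normal", activity = "0",
        update = p$r_pertim_form),
    arc("pertim_formation", "PER_TIM", "normal", update = p$r_pertim_form),
    # PER/DBT formation at the printed speed m_7*m_12/1000
    arc("PER", "per_dbt_formation", "normal", activity = "0",
        update = pdbt_rate),
    arc("DBT", "per_dbt_formation", "normal", activity = "0",
        update = pdbt_rate),
    arc("per_dbt_formation", "PER_DBT", "normal", update = pdbt_rate),
    arc("DBT_synthesis", "DBT", "normal", update = p$r_DBT_syn)),
    unlist(lapply(names(deg), function(pid) list(
      arc(pid, paste0(pid, "_degradation"), "normal", activity = "0",
          update = deg[[pid]],
          id = paste0(pid, "->", pid, "_degradation")))),
      recursive = FALSE))
  hfpne_net(places, transitions, arcs, id = "circadian_scaffold")
}

#' Slow the PER/DBT complex-formation speed (dbt long-period mutant)
#'
#' Returns a copy of the net in which only the designated PER/DBT
#' formation transition's speed expression is replaced (on every normal
#' arc of that transition, which all share the single formation formula);
#' every other element is unchanged.  Slowing this speed leaves more PER
#' free to bind TIM, prolonging PER/TIM repression of per/tim
#' transcription and lengthening the oscillation period.
#'
#' @param net An [hfpne_net()] containing the formation transition.
#' @param new_rate Replacement speed expression (e.g. `"m_7*m_12/5000"`).
#' @param transition_id Id of the formation transition; defaults to the
#'   scaffold's `"per_dbt_formation"`.
#' @return An [hfpne_net()].
#' @export
make_dbt_mutant <- function(net, new_rate,
                            transition_id = "per_dbt_formation") {
  if (!transition_id %in% names(net$transitions))
    stop("net has no transition '", transition_id, "'", call. = FALSE)
  new_rate <- hfpne_expr(new_rate)
  ti <- net$index$trans[[transition_id]]
  for (aid in c(ti$in_normal, ti$out_arcs)) {
    if (net$arcs[[aid]]$label == "normal")
      net$arcs[[aid]]$update <- new_rate
  }
  net$id <- paste0(net$id, "_dbtL")
  net
}
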