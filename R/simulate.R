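#' Simulation configuration
#'
#' @param end End time `x_sim` (> 0, model time units).
#' @param dt Sampling interval (> 0); must divide `end` to within floating
#'   tolerance.  The canonical circadian run uses `end = 150`, `dt = 0.01`.
#' @param conflict Conflict-resolution policy for simultaneous discrete
#'   firings: `"priority"` (rank order, default) or `"random"` (seeded
#'   shuffle).
#' @param seed Integer seed; required when `conflict = "random"`.
#' @param on_premature_disable What to do when a scheduled discrete/generic
#'   firing finds its transition disabled before its fire time:
#'   `"cancel"` (drop and log, default) or `"error"`.
#' @param substeps Integer >= 1: internal Euler refinement factor; marks
#'   are still reported only at multiples of `dt`.
#' @return A `hfpne_sim_config` list.
#' @export
sim_config <- function(end, dt, conflict = c("priority", "random"),
                       seed = NULL,
                       on_premature_disable = c("cancel", "error"),
                       substeps = 1L) {
  conflict <- match.arg(conflict)
  on_premature_disable <- match.arg(on_premature_disable)
  stopifnot(end > 0, dt > 0, substeps >= 1)
  n <- round(end / dt)
  if (abs(n * dt - end) > 1e-6 * dt)
    stop("dt must divide end to within floating tolerance", call. = FALSE)
  if (conflict == "random" && is.null(seed))
    stop("seed is required when conflict = 'random'", call. = FALSE)
  structure(list(end = end, dt = dt, conflict = conflict, seed = seed,
                 on_premature_disable = on_premature_disable,
                 substeps = as.integer(substeps)),
            class = "hfpne_sim_config")
}

#' Resolve a discrete firing conflict
#'
#' Several discrete transitions firing at the same instant conflict on a
#' place when their summed token demands exceed the place's effective
#' mark.  Resolution selects a maximal subset greedily: transitions are
#' visited in priority order (or a seeded random order) and accepted when
#' all their demands still fit; rejected firings are canceled.
#'
#' @param demands Data frame with columns `transition`, `place`, `amount`
#'   (one row per normal input arc of each candidate firing).
#' @param available Named numeric vector (or [hfpne_marking()]) of the
#'   effective marks of the places involved.
#' @param policy `"priority"` or `"random"`.
#' @param seed Seed for the random policy.
#' @param order Transition ids in priority rank order; defaults to first
#'   appearance in `demands`.
#' @return Character vector of selected transition ids.
#' @export
resolve_conflicts <- function(demands, available,
                              policy = c("priority", "random"),
                              seed = NULL, order = NULL) {
  policy <- match.arg(policy)
  if (inherits(available, "hfpne_marking")) {
    av <- vapply(available$marks, function(m) if (is.numeric(m)) m else NA_real_,
                 0)
  } else av <- available
  if (NROW(demands) == 0L) return(character(0))
  if (is.null(order)) order <- unique(demands$transition)
  if (policy == "random") {
    if (is.null(seed)) stop("seed is required for policy = 'random'",
                            call. = FALSE)
    order <- local_shuffle(order, seed)
  }
  selected <- character(0)
  for (tid in order) {
    d <- demands[demands$transition == tid, , drop = FALSE]
    fits <- all(d$amount <= av[d$place] + 1e-12)
    if (fits) {
      av[d$place] <- av[d$place] - d$amount
      selected <- c(selected, tid)
    }
  }
  selected
}

# Seeded shuffle that leaves the global RNG stream untouched.
local_shuffle <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample(x)
}

# Synchronous forward-Euler core over the continuous transitions.
# Iterates transitions in declaration order and arcs in index order so the
# floating-point summation order is reproducible; a subnet built from the
# same net preserves relative order and therefore reproduces sums
# bit-for-bit.  Negative marks are clamped to zero (marking invariant).
euler_step_core <- function(net, mnum, mgen, dt, substeps, env, vars, log) {
  h <- dt / substeps
  cont <- names(net$transitions)[
    vapply(net$transitions, `[[`, "", "kind") == "continuous"]
  for (s in seq_len(substeps)) {
    for (j in seq_along(mnum)) assign(vars[[names(mnum)[j]]], mnum[[j]], env)
    delta <- numeric(length(mnum))
    names(delta) <- names(mnum)
    for (tid in cont) {
      if (!transition_enabled_core(net, tid, mnum, mgen, env)) next
      ti <- net$index$trans[[tid]]
      for (aid in ti$in_normal) {
        a <- net$arcs[[aid]]
        delta[[a$from]] <- delta[[a$from]] - eval_expr(a$update, env) * h
      }
      for (aid in ti$out_arcs) {
        a <- net$arcs[[aid]]
        if (a$label == "normal")
          delta[[a$to]] <- delta[[a$to]] + eval_expr(a$update, env) * h
      }
    }
    mnum <- mnum + delta
    neg <- mnum < 0
    if (any(neg)) {
      log$add(paste0("clamped negative mark(s) to 0: ",
                     paste(names(mnum)[neg], collapse = ", ")))
      mnum[neg] <- 0
    }
  }
  mnum
}

# Enabling check against split numeric/generic marks sharing one env.
transition_enabled_core <- function(net, tid, mnum, mgen, env) {
  t <- net$transitions[[tid]]
  generic <- t$kind == "generic"
  for (aid in net$index$trans[[tid]]$in_arcs) {
    a <- net$arcs[[aid]]
    w <- eval_expr(a$activity, env)
    val <- if (a$from %in% names(mnum)) mnum[[a$from]] else mgen[[a$from]]
    if (a$label == "inhibitory") {
      ok <- if (generic) isFALSE(w) else val < w
    } else {
      ok <- if (generic) isTRUE(w) else val > w
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

# Tiny append-only logger (closure over a character vector).
new_log <- function() {
  msgs <- character(0)
  list(add = function(m) msgs[[length(msgs) + 1L]] <<- m,
       get = function() msgs)
}

#' Advance the continuous dynamics of a net by one sampling step
#'
#' Applies the same synchronous forward-Euler update as [simulate_net()]
#' (discrete/generic transitions do not act here).  Exposed so that a
#' temporal subnet can be re-simulated for a single step and compared with
#' the full model.
#'
#' @param net An [hfpne_net()].
#' @param marks Named list of marks by place id.
#' @param dt Step size.
#' @param substeps Internal refinement factor.
#' @return Named list of marks after one step of length `dt`.
#' @export
euler_step <- function(net, marks, dt, substeps = 1L) {
  kinds <- vapply(net$places, `[[`, "", "kind")
  vars <- lapply(net$places, `[[`, "variable")
  numeric_p <- names(net$places)[kinds != "generic"]
  generic_p <- names(net$places)[kinds == "generic"]
  mnum <- vapply(marks[numeric_p], as.numeric, 0)
  names(mnum) <- numeric_p
  mgen <- marks[generic_p]
  env <- marking_env(stats::setNames(marks, unlist(vars[names(marks)])))
  log <- new_log()
  mnum <- euler_step_core(net, mnum, mgen, dt, as.integer(substeps), env,
                          vars, log)
  out <- marks
  for (pid in numeric_p) out[[pid]] <- mnum[[pid]]
  out
}

#' Simulate an HFPNe net
#'
#' Fixed-step execution producing a time-course trace.  Time points are
#' `x_i = i*dt` for `i = 0 ... end/dt - 1` (so a 150/0.01 run yields
#' 15,000 points).  At each point, scheduled discrete/generic firings
#' whose fire time has arrived are applied (token moves for discrete
#' transitions, value replacement for generic ones, both using amounts
#' snapshotted at the trigger time); newly enabled discrete/generic
#' transitions schedule a firing at `x + d(t)[M(x)]`; then the marking is
#' recorded and the continuous transitions advance by forward Euler over
#' `[x, x + dt)`.  A transition still enabled after firing re-triggers
#' immediately, so a persistently enabled discrete transition fires every
#' delay period.  Token reservation is disabled (the alpha = 0
#' convention): the reserved marking stays identically zero.
#'
#' @param net An [hfpne_net()]; must pass [validate_net()].
#' @param config A [sim_config()]; alternatively supply `end` and `dt`.
#' @param end,dt Shortcut for `config = sim_config(end, dt)`.
#' @return An `hfpne_trace` (see [read_edf()]): a data frame with a `time`
#'   column, one column per place, and one elapsed-delay column per
#'   discrete/generic transition (`-1` when idle).  Simulation log lines
#'   are attached as `attr(x, "log")`.
#' @examples
#' net <- toy_oscillator()
#' tr <- simulate_net(net, end = 30, dt = 0.01)
#' nrow(tr)  # 3000
#' @export
simulate_net <- function(net, config = NULL, end = NULL, dt = NULL) {
  if (is.null(config)) config <- sim_config(end, dt)
  v <- validate_net(net)
  if (nrow(v) > 0)
    stop("net fails validation: ", paste(v$message, collapse = "; "),
         call. = FALSE)
  n_pts <- round(config$end / config$dt)
  times <- (seq_len(n_pts) - 1L) * config$dt
  eps <- 1e-9 * max(1, config$dt)

  kinds <- vapply(net$places, `[[`, "", "kind")
  vars <- lapply(net$places, `[[`, "variable")
  numeric_p <- names(net$places)[kinds != "generic"]
  generic_p <- names(net$places)[kinds == "generic"]
  mnum <- vapply(net$places[numeric_p], function(p) as.numeric(p$initial), 0)
  names(mnum) <- numeric_p
  mgen <- lapply(net$places[generic_p], `[[`, "initial")

  tkinds <- vapply(net$transitions, `[[`, "", "kind")
  dg <- names(net$transitions)[tkinds != "continuous"]
  prio <- vapply(net$transitions[dg], `[[`, 1L, "priority")
  dg_order <- dg[order(prio)]
  pending <- stats::setNames(vector("list", length(dg)), dg)

  env <- marking_env(stats::setNames(list(0), "..init"))
  log <- new_log()
  sync_env <- function() {
    for (j in seq_along(mnum)) assign(vars[[numeric_p[j]]], mnum[[j]], env)
    for (pid in generic_p) assign(vars[[pid]], mgen[[pid]], env)
  }

  num_trace <- matrix(NA_real_, nrow = n_pts, ncol = length(numeric_p),
                      dimnames = list(NULL, numeric_p))
  gen_trace <- stats::setNames(
    lapply(generic_p, function(p) vector("list", n_pts)), generic_p)
  delay_trace <- matrix(-1, nrow = n_pts, ncol = length(dg),
                        dimnames = list(NULL, dg))

  snapshot_amounts <- function(tid) {
    ti <- net$index$trans[[tid]]
    ins <- lapply(net$arcs[ti$in_normal], function(a)
      list(place = a$from, value = eval_expr(a$update, env)))
    outs <- lapply(net$arcs[ti$out_arcs], function(a)
      if (a$label == "normal") list(place = a$to,
                                    value = eval_expr(a$update, env)))
    list(ins = ins, outs = Filter(Negate(is.null), outs))
  }

  fire_set <- function(fire_ids, x) {
    if (length(fire_ids) == 0L) return(invisible())
    disc <- fire_ids[tkinds[fire_ids] == "discrete"]
    gen <- fire_ids[tkinds[fire_ids] == "generic"]
    if (length(disc)) {
      rows <- do.call(rbind, lapply(disc, function(tid) {
        ins <- pending[[tid]]$amounts$ins
        if (length(ins) == 0L)
          return(data.frame(transition = tid, place = NA_character_,
                            amount = 0)[0, ])
        data.frame(transition = tid,
                   place = vapply(ins, `[[`, "", "place"),
                   amount = vapply(ins, `[[`, 0, "value"))
      }))
      selected <- resolve_conflicts(rows, mnum, policy = config$conflict,
                                    seed = if (!is.null(config$seed))
                                      config$seed + round(x / config$dt),
                                    order = disc)
      canceled <- setdiff(disc, selected)
      if (length(canceled))
        log$add(paste0("t=", x, ": conflict canceled firing of ",
                       paste(canceled, collapse = ", ")))
      for (tid in selected) {
        amt <- pending[[tid]]$amounts
        for (a in amt$ins) mnum[[a$place]] <<- mnum[[a$place]] - a$value
        for (a in amt$outs) mnum[[a$place]] <<- mnum[[a$place]] + a$value
      }
    }
    for (tid in gen) {
      amt <- pending[[tid]]$amounts
      repl <- c(amt$ins, amt$outs)
      for (a in repl) {
        if (a$place %in% numeric_p) mnum[[a$place]] <<- as.numeric(a$value)
        else mgen[[a$place]] <<- a$value
      }
    }
    for (tid in fire_ids) pending[[tid]] <<- NULL
    invisible()
  }

  for (i in seq_len(n_pts)) {
    x <- times[[i]]
    sync_env()

    # premature-disable check on pending firings
    for (tid in dg_order) {
      if (is.null(pending[[tid]])) next
      if (!transition_enabled_core(net, tid, mnum, mgen, env)) {
        msg <- paste0("t=", x, ": transition '", tid,
                      "' disabled before its scheduled fire time")
        if (config$on_premature_disable == "error")
          stop("simulation error: ", msg, call. = FALSE)
        log$add(msg)
        pending[[tid]] <- NULL
      }
    }

    # fire pendings that are due
    due <- dg_order[vapply(dg_order, function(tid)
      !is.null(pending[[tid]]) && pending[[tid]]$sched <= x + eps, TRUE)]
    if (length(due)) {
      fire_set(due, x)
      sync_env()
    }

    # trigger newly enabled discrete/generic transitions
    immediate <- character(0)
    for (tid in dg_order) {
      if (!is.null(pending[[tid]])) next
      if (!transition_enabled_core(net, tid, mnum, mgen, env)) next
      d <- eval_expr(net$transitions[[tid]]$delay, env)
      pending[[tid]] <- list(trigger = x, sched = x + d,
                             amounts = snapshot_amounts(tid))
      if (d <= eps) immediate <- c(immediate, tid)
    }
    if (length(immediate)) {
      fire_set(immediate, x)
      sync_env()
    }

    # record the marking at x_i
    num_trace[i, ] <- mnum
    for (pid in generic_p) gen_trace[[pid]][[i]] <- mgen[[pid]]
    for (tid in dg)
      if (!is.null(pending[[tid]]))
        delay_trace[i, tid] <- x - pending[[tid]]$trigger

    # continuous dynamics over [x, x + dt)
    mnum <- euler_step_core(net, mnum, mgen, config$dt, config$substeps,
                            env, vars, log)
  }

  df <- data.frame(time = times)
  for (pid in names(net$places)) {
    df[[pid]] <- if (pid %in% numeric_p) num_trace[, pid]
    else unlist(lapply(gen_trace[[pid]], function(v)
      if (is.null(v)) NA else v))
  }
  for (tid in dg) df[[paste0("delay:", tid)]] <- delay_trace[, tid]
  new_trace(df, dt = config$dt, net_id = net$id,
            place_ids = names(net$places), delay_ids = dg,
            place_kinds = kinds, log = log$get())
}
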