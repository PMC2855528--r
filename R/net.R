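#' Build an HFPNe place
#'
#' A place holds a mark: a non-negative integer (discrete), a non-negative
#' real concentration (continuous), or any serializable value such as a
#' string (generic).
#'
#' @param id Unique identifier.
#' @param kind `"discrete"`, `"continuous"` or `"generic"`.
#' @param initial Initial mark, in the place's domain.
#' @param name Human-readable label (defaults to `id`).
#' @param variable Symbol usable in expressions (defaults to `id`).
#' @return A `hfpne_place` list.
#' @export
place <- function(id, kind = c("continuous", "discrete", "generic"),
                  initial = 0, name = id, variable = id) {
  kind <- match.arg(kind)
  structure(list(id = as.character(id), name = name, kind = kind,
                 initial = initial, variable = variable),
            class = "hfpne_place")
}

#' Build an HFPNe transition
#'
#' Continuous transitions fire continuously at expression-valued speeds;
#' discrete and generic transitions fire after an expression-valued delay.
#'
#' @param id Unique identifier.
#' @param kind `"continuous"`, `"discrete"` or `"generic"`.
#' @param delay Delay expression (discrete/generic only; evaluates to a
#'   time >= 0 in model time units). Continuous transitions take none.
#' @param priority Integer rank used for conflict resolution; lower fires
#'   first. Defaults to declaration order.
#' @param name Human-readable label.
#' @return A `hfpne_transition` list.
#' @export
transition <- function(id, kind = c("continuous", "discrete", "generic"),
                       delay = NULL, priority = NA_integer_, name = id) {
  kind <- match.arg(kind)
  if (kind == "continuous" && !is.null(delay))
    stop("continuous transitions have no delay", call. = FALSE)
  if (kind != "continuous" && is.null(delay)) delay <- "0"
  structure(list(id = as.character(id), name = name, kind = kind,
                 delay = if (!is.null(delay)) hfpne_expr(delay),
                 priority = as.integer(priority)),
            class = "hfpne_transition")
}

#' Build an HFPNe arc
#'
#' Input arcs (place to transition) carry an activity expression: a numeric
#' threshold for discrete/continuous transitions, a boolean condition for
#' generic ones.  Normal arcs also carry an update expression (amount
#' consumed/produced, continuous speed, or generic replacement value).
#' Test and inhibitory arcs are read-only conditions and run place to
#' transition only.  An arc's kind (discrete/continuous/generic) is that of
#' its transition.
#'
#' @param from,to Endpoint ids (one a place, the other a transition).
#' @param label `"normal"`, `"test"` or `"inhibitory"`.
#' @param activity Activity expression `w` (input arcs only).
#' @param update Update expression `u` (normal arcs).
#' @param id Unique identifier; defaults to `"from->to"`.
#' @return A `hfpne_arc` list.
#' @export
arc <- function(from, to, label = c("normal", "test", "inhibitory"),
                activity = NULL, update = NULL,
                id = paste0(from, "->", to)) {
  label <- match.arg(label)
  structure(list(id = as.character(id), from = as.character(from),
                 to = as.character(to), label = label,
                 activity = if (!is.null(activity)) hfpne_expr(activity),
                 update = if (!is.null(update)) hfpne_expr(update)),
            class = "hfpne_arc")
}

#' Assemble an HFPNe net
#'
#' The net H = (P, T, A, tau, w, u, d): typed places, transitions and arcs
#' with expression-valued thresholds, speeds, updates and delays.  Lookup
#' indices (input/output arcs per transition, split by arc label, and
#' incident arcs per place) are built once here and reused by the
#' simulator and the subnet extractor.
#'
#' @param places List of [place()]s.
#' @param transitions List of [transition()]s.
#' @param arcs List of [arc()]s.
#' @param id Net identifier recorded in traces.
#' @return An object of class `hfpne_net`.
#' @seealso [validate_net()], [simulate_net()], [extract_temporal_subnet()]
#' @export
hfpne_net <- function(places, transitions, arcs, id = "net") {
  if (inherits(places, "hfpne_place")) places <- list(places)
  if (inherits(transitions, "hfpne_transition")) transitions <- list(transitions)
  if (inherits(arcs, "hfpne_arc")) arcs <- list(arcs)
  names(places) <- vapply(places, `[[`, "", "id")
  names(transitions) <- vapply(transitions, `[[`, "", "id")
  names(arcs) <- vapply(arcs, `[[`, "", "id")
  # default priorities follow declaration order
  for (i in seq_along(transitions))
    if (is.na(transitions[[i]]$priority))
      transitions[[i]]$priority <- i
  net <- structure(list(id = id, places = places, transitions = transitions,
                        arcs = arcs),
                   class = "hfpne_net")
  net$index <- build_index(net)
  net
}

# Per-transition and per-place arc indices. Arc direction is inferred from
# which endpoint is a place.
build_index <- function(net) {
  pids <- names(net$places)
  tids <- names(net$transitions)
  idx <- list(trans = list(), place = list())
  for (tid in tids)
    idx$trans[[tid]] <- list(in_arcs = character(0), out_arcs = character(0),
                             in_normal = character(0), in_test = character(0),
                             in_inhib = character(0))
  for (pid in pids)
    idx$place[[pid]] <- list(in_arcs = character(0), out_arcs = character(0))
  for (a in net$arcs) {
    if (a$from %in% pids && a$to %in% tids) {
      idx$trans[[a$to]]$in_arcs <- c(idx$trans[[a$to]]$in_arcs, a$id)
      slot <- switch(a$label, normal = "in_normal", test = "in_test",
                     inhibitory = "in_inhib")
      idx$trans[[a$to]][[slot]] <- c(idx$trans[[a$to]][[slot]], a$id)
      idx$place[[a$from]]$out_arcs <- c(idx$place[[a$from]]$out_arcs, a$id)
    } else if (a$from %in% tids && a$to %in% pids) {
      idx$trans[[a$from]]$out_arcs <- c(idx$trans[[a$from]]$out_arcs, a$id)
      idx$place[[a$to]]$in_arcs <- c(idx$place[[a$to]]$in_arcs, a$id)
    }
  }
  idx
}

#' @export
print.hfpne_net <- function(x, ...) {
  kinds <- table(vapply(x$places, `[[`, "", "kind"))
  tkinds <- table(vapply(x$transitions, `[[`, "", "kind"))
  cat("<hfpne_net> '", x$id, "': ", length(x$places), " places (",
      paste(names(kinds), kinds, sep = ":", collapse = ", "), "), ",
      length(x$transitions), " transitions (",
      paste(names(tkinds), tkinds, sep = ":", collapse = ", "), "), ",
      length(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

is_input_arc <- function(net, a) a$from %in% names(net$places)

arc_kind <- function(net, a) {
  tid <- if (is_input_arc(net, a)) a$to else a$from
  net$transitions[[tid]]$kind
}

#' Construct a marking
#'
#' A marking assigns a mark to every place at a time point.  The reserved
#' marking is kept in the data model so its invariant (identically zero for
#' discrete/continuous places and null for generic ones, the alpha = 0
#' convention under which the effective marking equals M) is checkable, but
#' it never receives tokens.
#'
#' @param net An [hfpne_net()].
#' @param marks Named list of marks by place id; defaults to the initial
#'   marking.
#' @param time Time point x >= 0, in model time units.
#' @return An object of class `hfpne_marking`.
#' @export
hfpne_marking <- function(net, marks = NULL, time = 0) {
  if (is.null(marks))
    marks <- lapply(net$places, `[[`, "initial")
  stopifnot(setequal(names(marks), names(net$places)))
  marks <- marks[names(net$places)]
  reserved <- lapply(net$places, function(p)
    if (p$kind == "generic") NULL else 0)
  structure(list(time = time, marks = marks, reserved = reserved,
                 net_id = net$id),
            class = "hfpne_marking")
}

# Environment binding each place's expression variable to its mark.
net_marking_env <- function(net, marks) {
  vars <- lapply(net$places, `[[`, "variable")
  v <- marks
  names(v) <- unlist(vars[names(marks)])
  marking_env(v)
}

effective_mark <- function(marking, pid) {
  # alpha = 0: no reservation, so the effective marking equals M
  marking$marks[[pid]]
}

#' Is an input arc enabled?
#'
#' For a discrete or continuous arc the source place's effective mark must
#' strictly exceed the threshold `w`; equality disables.  For a generic arc
#' the condition `w` must evaluate to `TRUE`.
#'
#' @param net An [hfpne_net()].
#' @param a An input [arc()] of `net` (or its id).
#' @param marking An [hfpne_marking()].
#' @return `TRUE` or `FALSE`.
#' @export
is_arc_enabled <- function(net, a, marking) {
  if (is.character(a)) a <- net$arcs[[a]]
  if (!is_input_arc(net, a))
    stop("is_arc_enabled() is defined for input arcs only (arc '", a$id, "')",
         call. = FALSE)
  env <- net_marking_env(net, marking$marks)
  w <- eval_expr(a$activity, env)
  if (arc_kind(net, a) == "generic") return(isTRUE(w))
  effective_mark(marking, a$from) > w
}

#' Is a transition enabled?
#'
#' A transition is enabled when every non-inhibitory input arc satisfies
#' its threshold/condition and every inhibitory input arc is below its
#' threshold (strictly) or its condition is `FALSE`.  A transition with no
#' input arcs is enabled (vacuous conjunction).
#'
#' @param net An [hfpne_net()].
#' @param t A [transition()] of `net` (or its id).
#' @param marking An [hfpne_marking()].
#' @return `TRUE` or `FALSE`.
#' @export
is_transition_enabled <- function(net, t, marking) {
  if (is.character(t)) t <- net$transitions[[t]]
  env <- net_marking_env(net, marking$marks)
  transition_enabled_env(net, t$id, marking$marks, env)
}

# Internal fast path sharing one evaluation environment per time point.
transition_enabled_env <- function(net, tid, marks, env) {
  t <- net$transitions[[tid]]
  generic <- t$kind == "generic"
  for (aid in net$index$trans[[tid]]$in_arcs) {
    a <- net$arcs[[aid]]
    w <- eval_expr(a$activity, env)
    if (a$label == "inhibitory") {
      ok <- if (generic) isFALSE(w) else marks[[a$from]] < w
    } else {
      ok <- if (generic) isTRUE(w) else marks[[a$from]] > w
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Validate an HFPNe net
#'
#' Checks the structural typing rules: endpoints exist; test/inhibitory
#' arcs run place to transition only; output arcs carry no activity
#' expression; normal arcs of a continuous transition touch only
#' continuous places; normal input places of a discrete transition are
#' discrete or continuous; continuous transitions have no delay; priority
#' ranks are unique; initial marks respect their place's domain.
#'
#' @param net An [hfpne_net()].
#' @return A data frame of violations (`rule`, `element`, `message`);
#'   zero rows means valid.  The net is never mutated.
#' @export
validate_net <- function(net) {
  bad <- list()
  note <- function(rule, element, message)
    bad[[length(bad) + 1L]] <<- data.frame(rule = rule, element = element,
                                           message = message)
  pids <- names(net$places)
  tids <- names(net$transitions)
  if (anyDuplicated(c(pids, tids)))
    note("unique-ids", "", "place/transition ids are not unique")
  if (anyDuplicated(names(net$arcs)))
    note("unique-ids", "", "arc ids are not unique")
  pr <- vapply(net$transitions, `[[`, 1L, "priority")
  if (anyDuplicated(pr))
    note("priority", "", "priority ranks are not unique")
  for (p in net$places) {
    if (p$kind == "discrete" &&
        (!is.numeric(p$initial) || p$initial < 0 || p$initial != round(p$initial)))
      note("domain", p$id, "discrete initial mark must be an integer >= 0")
    if (p$kind == "continuous" && (!is.numeric(p$initial) || p$initial < 0))
      note("domain", p$id, "continuous initial mark must be a real >= 0")
  }
  for (a in net$arcs) {
    from_p <- a$from %in% pids
    to_p <- a$to %in% pids
    if (!(a$from %in% c(pids, tids)) || !(a$to %in% c(pids, tids))) {
      note("endpoint", a$id, "arc endpoint does not exist")
      next
    }
    if (from_p == to_p) {
      note("endpoint", a$id, "arc must connect a place and a transition")
      next
    }
    input <- from_p
    if (!input && a$label != "normal")
      note("direction", a$id,
           "test/inhibitory arcs are only directed from a place to a transition")
    if (input && is.null(a$activity))
      note("activity", a$id, "input arc lacks an activity expression")
    if (!input && !is.null(a$activity))
      note("activity", a$id, "output arcs carry no activity expression")
    if (a$label == "normal" && is.null(a$update))
      note("update", a$id, "normal arc lacks an update expression")
    tid <- if (input) a$to else a$from
    pid <- if (input) a$from else a$to
    tkind <- net$transitions[[tid]]$kind
    pkind <- net$places[[pid]]$kind
    if (tkind == "continuous" && a$label == "normal" && pkind != "continuous")
      note("typing", a$id,
           "normal arcs of a continuous transition touch only continuous places")
    if (tkind == "discrete" && a$label == "normal" && input &&
        pkind == "generic")
      note("typing", a$id,
           "normal input places of a discrete transition are discrete or continuous")
  }
  for (t in net$transitions)
    if (t$kind == "continuous" && !is.null(t$delay))
      note("delay", t$id, "continuous transitions have no delay")
  if (length(bad) == 0L)
    return(data.frame(rule = character(0), element = character(0),
                      message = character(0)))
  do.call(rbind, bad)
}
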