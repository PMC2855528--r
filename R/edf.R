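#' Time-course traces (EDF)
#'
#' A trace records the marking of every place at every sampled time point,
#' plus, for each discrete/generic transition, the elapsed delay since its
#' trigger time (`-1` when no firing is pending).  On disk this is the EDF
#' (expression data format) dialect defined by this package: a UTF-8 CSV
#' with header `time,<place ids...>,delay:<transition ids...>`, one row
#' per time point, generic values quoted as strings, numbers written with
#' full (17 significant digit) precision so a write/read round trip is
#' exact.
#'
#' @name edf
NULL

new_trace <- function(df, dt, net_id, place_ids, delay_ids,
                      place_kinds = NULL, log = character(0)) {
  structure(df, class = c("hfpne_trace", "data.frame"),
            dt = dt, net_id = net_id, place_ids = place_ids,
            delay_ids = delay_ids, place_kinds = place_kinds, log = log)
}

#' @export
print.hfpne_trace <- function(x, ...) {
  cat("<hfpne_trace> net '", attr(x, "net_id"), "': ", nrow(x),
      " time points at dt = ", attr(x, "dt"), ", ",
      length(attr(x, "place_ids")), " places, ",
      length(attr(x, "delay_ids")), " delay column(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("... (", nrow(x) - 4, " more rows)\n", sep = "")
  invisible(x)
}

fmt_num <- function(v) {
  out <- vapply(v, function(x) format(x, digits = 17, scientific = FALSE,
                                      trim = TRUE), "")
  out[is.na(v)] <- "NA"
  out
}

#' Write a trace to an EDF file
#'
#' @param trace An `hfpne_trace` (from [simulate_net()] or [read_edf()]).
#' @param path Output path (`.edf` by convention).
#' @return `path`, invisibly.
#' @export
write_edf <- function(trace, path) {
  stopifnot(inherits(trace, "hfpne_trace"))
  cols <- names(trace)
  header <- paste(cols, collapse = ",")
  fields <- lapply(cols, function(cn) {
    v <- trace[[cn]]
    if (is.numeric(v)) fmt_num(v)
    else paste0('"', gsub('"', '""', as.character(v)), '"')
  })
  lines <- do.call(paste, c(fields, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a trace from an EDF file
#'
#' Parses and verifies the trace invariants: strictly increasing time with
#' a constant interval, rectangular rows, numeric place columns.  Quoted
#' columns are preserved verbatim as character (generic marks).
#' Elapsed-delay columns (`delay:` prefix) are optional; without them a
#' trace still supports subnet extraction, but one-step resimulation
#' equivalence is only guaranteed for nets without discrete/generic
#' delays.
#'
#' @param path Path to an EDF file.
#' @return An `hfpne_trace`.
#' @export
read_edf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_net <- "net"
  if (length(lines) && startsWith(lines[[1]], "#")) {
    m <- regmatches(lines[[1]], regexec("net=(\\S+)", lines[[1]]))[[1]]
    if (length(m) == 2) meta_net <- m[[2]]
    lines <- lines[-1]
  }
  if (length(lines) < 2L)
    stop("EDF parse error: no data rows in '", path, "'", call. = FALSE)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    f <- scan(text = body[[i]], what = character(), sep = ",",
              quote = '"', quiet = TRUE)
    if (length(f) != length(header))
      stop("EDF parse error at data row ", i, " (line ", i + 1, "): ",
           length(f), " fields, expected ", length(header), call. = FALSE)
    f
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  # a column holds generic (string) marks iff its fields are quoted;
  # the dialect quotes consistently, so the first data row decides
  tok <- regmatches(body[[1]],
                    gregexpr('("([^"]|"")*")|([^,]+)', body[[1]]))[[1]]
  quoted <- if (length(tok) == length(header)) startsWith(tok, '"')
            else rep(FALSE, length(header))
  names(quoted) <- header
  df <- data.frame(row.names = seq_len(nrow(mat)))
  for (cn in header) {
    v <- mat[, cn]
    if (quoted[[cn]]) {
      df[[cn]] <- v
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & v != "NA"))
        stop("EDF parse error: non-numeric value in unquoted column '",
             cn, "'", call. = FALSE)
      df[[cn]] <- num
    }
  }
  if (!"time" %in% header)
    stop("EDF parse error: missing 'time' column", call. = FALSE)
  tm <- df$time
  if (anyNA(tm) || any(diff(tm) <= 0))
    stop("EDF parse error: time must be strictly increasing", call. = FALSE)
  if (length(tm) > 1) {
    dts <- diff(tm)
    dt <- dts[[1]]
    if (any(abs(dts - dt) > 1e-9 * max(1, dt)))
      stop("EDF parse error: inconsistent time interval", call. = FALSE)
  } else dt <- NA_real_
  delay_ids <- sub("^delay:", "", grep("^delay:", header, value = TRUE))
  place_ids <- setdiff(header, c("time", paste0("delay:", delay_ids)))
  new_trace(df, dt = dt, net_id = meta_net, place_ids = place_ids,
            delay_ids = delay_ids)
}
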