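# Input tables: digitized curve coordinates and published numbers at risk.
#
# Both arrive as delimited text exported from graph-digitizing software; the
# delimiter (comma or tab) is auto-detected and files may or may not carry a
# header line or a leading index column.

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("file '", path, "' is empty", call. = FALSE)
  sep <- detect_sep(first)
  fields <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields))))
  read.table(path, sep = sep, header = has_header,
             stringsAsFactors = FALSE, strip.white = TRUE)
}

#' Construct a digitized Kaplan-Meier curve
#'
#' A `km_curve` holds the ordered coordinates clicked off a published KM
#' plot: times `T_k` on the publication's axis unit and survival
#' probabilities `S_k`. By convention the first coordinate is (0, 1).
#'
#' @param time numeric vector of x-axis coordinates, starting at 0.
#' @param surv numeric vector of y-axis survival probabilities, starting at 1.
#' @param arm label for the treatment arm the curve belongs to.
#' @return A data frame of class `km_curve` with columns `k`, `time`, `surv`.
#' @seealso [read_km_curve()], [repair_curve()]
#' @export
km_curve <- function(time, surv, arm = "arm") {
  if (length(time) != length(surv))
    stop("time and surv must have equal length", call. = FALSE)
  if (length(time) < 2L)
    stop("a digitized curve needs at least 2 coordinates", call. = FALSE)
  if (!is.numeric(time) || !is.numeric(surv) || anyNA(time) || anyNA(surv))
    stop("time and surv must be numeric with no missing values", call. = FALSE)
  if (abs(time[1]) > 1e-9 || abs(surv[1] - 1) > 1e-9)
    stop("row 1 must be the coordinate (0, 1): the curve starts at time 0 ",
         "with survival 1 (first row read was (", time[1], ", ", surv[1], "))",
         call. = FALSE)
  out <- data.frame(k = seq_along(time), time = as.numeric(time),
                    surv = as.numeric(surv))
  attr(out, "arm") <- as.character(arm)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Read digitized curve coordinates from a delimited text file
#'
#' Accepts the export format of common digitizing tools: two numeric columns
#' (time, survival), optionally preceded by an index column, comma- or
#' tab-separated, with or without a header row. Anomalies such as
#' non-monotone survival values are *not* corrected here; see
#' [repair_curve()].
#'
#' @param path path to the delimited text file.
#' @param arm arm label to attach to the curve.
#' @return A [km_curve()] object.
#' @export
read_km_curve <- function(path, arm = "arm") {
  d <- read_delim_auto(path)
  if (ncol(d) == 3L) d <- d[, 2:3]
  if (ncol(d) != 2L)
    stop("curve file must have 2 columns (time, survival) or 3 (k, time, survival); ",
         "found ", ncol(d), call. = FALSE)
  for (j in 1:2) {
    v <- suppressWarnings(as.numeric(d[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value in column ", j, ", data row ", bad, call. = FALSE)
    }
    d[[j]] <- v
  }
  if (nrow(d) < 2L)
    stop("curve file must contain at least 2 coordinate rows", call. = FALSE)
  km_curve(d[[1]], d[[2]], arm = arm)
}

#' Construct a published numbers-at-risk table
#'
#' Each row is one reporting interval: the time `trisk_i` at which the
#' publication states a number at risk `nrisk_i`, and the first (`lower_i`)
#' and last (`upper_i`) rows of the digitized curve falling in the interval
#' \[`trisk_i`, `trisk_{i+1}`). `lower_1` is always row 1 at time 0.
#'
#' @param time times at which numbers at risk are published, starting at 0.
#' @param lower,upper 1-based coordinate-row bounds of each interval.
#' @param nrisk published numbers at risk, positive and non-increasing.
#' @return A data frame of class `km_risk` with columns
#'   `interval`, `time`, `lower`, `upper`, `nrisk`.
#' @export
km_risk <- function(time, lower, upper, nrisk) {
  n <- length(time)
  if (n < 1L) stop("risk table needs at least one interval", call. = FALSE)
  if (length(lower) != n || length(upper) != n || length(nrisk) != n)
    stop("time, lower, upper, nrisk must have equal length", call. = FALSE)
  if (abs(time[1]) > 1e-9)
    stop("the first risk-table time must be 0", call. = FALSE)
  if (lower[1] != 1L)
    stop("the first interval must start at coordinate row 1", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("risk-table times must be strictly increasing", call. = FALSE)
  if (any(lower > upper))
    stop("each interval needs lower <= upper", call. = FALSE)
  if (n > 1L && any(lower[-1] != upper[-n] + 1L))
    stop("risk-table rows must be contiguous: lower[i+1] must equal upper[i] + 1",
         call. = FALSE)
  if (any(nrisk <= 0))
    stop("numbers at risk must be strictly positive", call. = FALSE)
  if (any(diff(nrisk) > 0))
    stop("number at risk must be non-increasing over time", call. = FALSE)
  out <- data.frame(interval = seq_len(n), time = as.numeric(time),
                    lower = as.integer(lower), upper = as.integer(upper),
                    nrisk = as.integer(nrisk))
  class(out) <- c("km_risk", "data.frame")
  out
}

#' Read a numbers-at-risk table from a delimited text file
#'
#' Expects five columns in order: interval index, time, lower coordinate
#' row, upper coordinate row, number at risk. Delimiter and header are
#' auto-detected as in [read_km_curve()].
#'
#' @inheritParams read_km_curve
#' @return A [km_risk()] object with rows ordered by interval index.
#' @export
read_risk_table <- function(path) {
  d <- read_delim_auto(path)
  if (ncol(d) != 5L)
    stop("risk-table file must have 5 columns (i, time, lower, upper, nrisk); ",
         "found ", ncol(d), call. = FALSE)
  for (j in 1:5) {
    v <- suppressWarnings(as.numeric(d[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric value in column ", j, ", data row ", bad, call. = FALSE)
    }
    d[[j]] <- v
  }
  d <- d[order(d[[1]]), ]
  km_risk(d[[2]], d[[3]], d[[4]], d[[5]])
}

#' Validate a curve against its risk table and repair digitization anomalies
#'
#' Publication quality and click error produce small anomalies in digitized
#' coordinates: survival values that rise instead of fall, or values just
#' outside \[0, 1\]. These are repaired (each offending `S_k` is clamped to
#' `S_{k-1}`, values clipped into \[0, 1\]) and every repair is logged.
#' Coordinates are first ordered by time. Structural inconsistencies with
#' the risk table -- row bounds outside the curve, or a published risk time
#' that does not match the curve coordinate it claims to sit on -- cannot be
#' repaired and raise errors.
#'
#' @param curve a [km_curve()].
#' @param risk optionally, a [km_risk()] to cross-check against the curve.
#' @param strict if `TRUE`, anomalies are errors instead of repairs.
#' @param tol_abs,tol_rel absolute and relative tolerance when matching a
#'   published risk time against its curve coordinate; digitization makes
#'   exact equality unreliable.
#' @return The repaired `km_curve`, with a character vector of repair
#'   messages in `attr(, "repairs")` (empty if nothing was changed).
#' @export
repair_curve <- function(curve, risk = NULL, strict = FALSE,
                         tol_abs = 1e-6, tol_rel = 1e-4) {
  stopifnot(inherits(curve, "km_curve"))
  log <- character(0)
  tm <- curve$time
  sv <- curve$surv
  if (is.unsorted(tm)) {
    ord <- order(tm)
    tm <- tm[ord]; sv <- sv[ord]
    log <- c(log, "coordinates re-ordered by time")
  }
  clip <- sv > 1 | sv < 0
  if (any(clip)) {
    log <- c(log, sprintf("row %d: survival %.6g clipped into [0, 1]",
                          which(clip), sv[clip]))
    sv <- pmin(pmax(sv, 0), 1)
  }
  for (k in seq_along(sv)[-1]) {
    if (sv[k] > sv[k - 1]) {
      log <- c(log, sprintf(
        "row %d: survival %.6g exceeds previous value %.6g; clamped",
        k, sv[k], sv[k - 1]))
      sv[k] <- sv[k - 1]
    }
  }
  if (strict && length(log))
    stop("curve anomalies in strict mode:\n  ",
         paste(log, collapse = "\n  "), call. = FALSE)
  if (!is.null(risk)) {
    stopifnot(inherits(risk, "km_risk"))
    N <- length(tm)
    if (any(risk$lower < 1L) || any(risk$upper > N))
      stop("risk-table row bounds fall outside the ", N,
           "-coordinate curve", call. = FALSE)
    tol <- tol_abs + tol_rel * pmax(1, abs(risk$time))
    off <- abs(tm[risk$lower] - risk$time) > tol
    if (any(off))
      stop("published risk time(s) ", paste(risk$time[off], collapse = ", "),
           " do not match the curve coordinates at rows ",
           paste(risk$lower[off], collapse = ", "),
           "; every time with a reported number at risk must be digitized",
           call. = FALSE)
  }
  out <- km_curve(tm, sv, arm = attr(curve, "arm"))
  attr(out, "repairs") <- log
  if (length(log)) warning(length(log), " digitization anomaly(ies) repaired",
                           call. = FALSE)
  out
}

fmt_num <- function(x) sub("e([+-])0(\\d)$", "e\\1\\2", sprintf("%.17g", x))

#' Write and read reconstructed individual patient data
#'
#' IPD files are comma-separated with header `time,event,arm`; rows are
#' ordered by time, events before censorings at ties. Times are written at
#' full double precision so that a write/read round trip is exact.
#'
#' @param ipd data frame with numeric `time`, integer `event` (1 = event,
#'   0 = censored) and character `arm` columns.
#' @param path file path.
#' @return `write_ipd` returns `path` invisibly; `read_ipd` returns the IPD
#'   data frame.
#' @export
write_ipd <- function(ipd, path) {
  if (!is.data.frame(ipd) || nrow(ipd) == 0L)
    stop("no records to write: refusing to create an empty IPD file",
         call. = FALSE)
  if (!all(c("time", "event", "arm") %in% names(ipd)))
    stop("IPD needs columns time, event, arm", call. = FALSE)
  if (!all(ipd$event %in% c(0L, 1L)))
    stop("event indicator must be 0 or 1", call. = FALSE)
  if (any(ipd$time < 0)) stop("times must be non-negative", call. = FALSE)
  ipd <- ipd[order(ipd$time, -ipd$event), ]
  txt <- c("time,event,arm",
           paste(fmt_num(ipd$time), as.integer(ipd$event), ipd$arm, sep = ","))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  d <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("time", "event", "arm") %in% names(d)))
    stop("IPD file must have header time,event,arm", call. = FALSE)
  d$event <- as.integer(d$event)
  d$arm <- as.character(d$arm)
  d
}

#' Write reconstructed Kaplan-Meier data to a delimited file
#'
#' Exports the per-coordinate reconstruction: columns `k`, `time`, `n_hat`
#' (at risk), `d_hat` (events), `cen_hat` (censorings), `S_km`
#' (reconstructed product-limit estimate).
#'
#' @param x a `km_recon` fit from [km_reconstruct()].
#' @param path file path.
#' @export
write_km_data <- function(x, path) {
  stopifnot(inherits(x, "km_recon"))
  km <- x$km
  txt <- c("k,time,n_hat,d_hat,cen_hat,S_km",
           paste(km$k, fmt_num(km$time), km$n_hat, km$d_hat, km$cen_hat,
                 fmt_num(km$S_km), sep = ","))
  writeLines(txt, path)
  invisible(path)
}
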