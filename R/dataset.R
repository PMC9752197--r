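#' NONMEM-style PK analysis dataset
#'
#' The analysis dataset is a data.frame with one row per dose or observation
#' event, using the conventional columns:
#' \describe{
#'   \item{ID}{subject identifier}
#'   \item{TIME}{time in hours since the subject's first dose, non-decreasing
#'     within subject}
#'   \item{AMT}{dose amount (mg) on dose rows, missing on observations}
#'   \item{RATE}{infusion rate (mg/h); 0 means bolus/oral}
#'   \item{EVID}{0 = observation, 1 = dose}
#'   \item{CMT}{1 = absorption depot (PO doses), 2 = central (IV doses and
#'     all observations); transit compartments are internal to the model and
#'     never addressed in datasets}
#'   \item{DV}{observed concentration (mg/L) on observation rows}
#'   \item{MDV}{missing-DV flag; 1 on dose rows and ignored observations}
#'   \item{WT}{body weight (kg), constant within subject}
#'   \item{FED}{1 = fed, 0 = fasted (meaningful for PO dose rows)}
#'   \item{ROUTE}{"IV" or "PO"}
#'   \item{STUDY}{study label}
#' }
#' On disk the dataset is a plain CSV; "." or an empty field is read as
#' missing and missing values are written as empty fields.
#'
#' @param path file path of a CSV dataset
#' @return a validated data.frame of class \code{pk_dataset}
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c(".", "", "NA"))
  validate_pk_dataset(raw)
}

#' @rdname read_pk_dataset
#' @param data a \code{pk_dataset} (or conforming data.frame) to write
#' @export
write_pk_dataset <- function(data, path) {
  data <- validate_pk_dataset(data)
  utils::write.csv(data, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

.pk_columns <- c("ID", "TIME", "AMT", "RATE", "EVID", "CMT", "DV", "MDV",
                 "WT", "FED", "ROUTE", "STUDY")

#' @rdname read_pk_dataset
#' @export
validate_pk_dataset <- function(data) {
  miss <- setdiff(.pk_columns, names(data))
  if (length(miss))
    stop("dataset is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  data <- data[, .pk_columns]
  if (nrow(data) == 0L) {
    class(data) <- c("pk_dataset", class(data))
    return(data)
  }
  problems <- character()
  bad <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems,
                     sprintf("%s (row%s %s)", msg,
                             if (length(rows) > 1L) "s" else "",
                             paste(utils::head(rows, 5L), collapse = ", ")))
  }
  obs <- which(data$EVID == 0L)
  dos <- which(data$EVID == 1L)
  bad(which(!data$EVID %in% c(0L, 1L)), "EVID must be 0 or 1")
  bad(obs[is.na(data$DV[obs])], "observation rows (EVID=0) must have DV")
  bad(obs[!is.na(data$AMT[obs])], "observation rows must not carry AMT")
  bad(dos[is.na(data$AMT[dos]) | data$AMT[dos] <= 0],
      "dose rows (EVID=1) must have AMT > 0")
  bad(dos[!is.na(data$DV[dos])], "dose rows must not carry DV")
  bad(dos[data$MDV[dos] != 1L], "dose rows must have MDV = 1")
  bad(which(is.na(data$TIME) | data$TIME < 0), "TIME must be >= 0")
  bad(which(is.na(data$WT) | data$WT <= 0), "WT must be > 0")
  bad(which(!data$ROUTE %in% c("IV", "PO")), "ROUTE must be IV or PO")
  bad(dos[data$ROUTE[dos] == "PO" & data$CMT[dos] != 1L],
      "PO dose rows must have CMT = 1")
  bad(dos[data$ROUTE[dos] == "IV" & data$CMT[dos] != 2L],
      "IV dose rows must have CMT = 2")
  bad(obs[data$CMT[obs] != 2L], "observation rows must have CMT = 2")
  for (id in unique(data$ID)) {
    ri <- which(data$ID == id)
    if (is.unsorted(data$TIME[ri]))
      problems <- c(problems,
                    sprintf("TIME not non-decreasing within ID %s", id))
    if (length(unique(data$WT[ri])) != 1L)
      problems <- c(problems, sprintf("WT not constant within ID %s", id))
  }
  if (length(problems))
    stop("invalid PK dataset:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  if (!inherits(data, "pk_dataset"))
    class(data) <- c("pk_dataset", class(data))
  data
}

## Split a pk_dataset into per-subject design/observation structures used by
## simulation, estimation and diagnostics. Rows with MDV = 1 on EVID = 0 are
## kept in `obs_all` (for dataset reconstruction) but excluded from the
## likelihood observations.
.prep_subjects <- function(data) {
  data <- validate_pk_dataset(data)
  row0 <- seq_len(nrow(data))
  ids <- unique(data$ID)
  lapply(ids, function(id) {
    sel <- data$ID == id
    d <- data[sel, , drop = FALSE]
    rows <- row0[sel]
    isdose <- d$EVID == 1L
    isobs <- d$EVID == 0L & d$MDV == 0L
    dr <- d[isdose, , drop = FALSE]
    ob <- d[isobs, , drop = FALSE]
    list(id = id, wt = d$WT[1L], study = d$STUDY[1L],
         doses = data.frame(time = dr$TIME, amount = dr$AMT,
                            route = dr$ROUTE,
                            duration = ifelse(!is.na(dr$RATE) & dr$RATE > 0,
                                              dr$AMT / dr$RATE, 0),
                            fed = ifelse(dr$ROUTE == "PO",
                                         dr$FED == 1L, NA)),
         obs_time = ob$TIME, dv = ob$DV, obs_rows = rows[isobs])
  })
}
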