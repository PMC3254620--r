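# Names of the eight linear unguis measurements (mm). FSA (degrees) is the
# ninth shape variable but is never size-standardized.
LINEAR_VARS <- c("BH", "BW", "TPL", "SH14", "SW14", "SH34", "SW34", "VFL")
PHALANX_VARS <- c(LINEAR_VARS, "FSA")
UNGUIS_GROUPS <- c("falcular", "grooming", "ungular", "tegular",
                   "unassigned", "fossil")

#' Validate a table of distal-phalanx measurement records
#'
#' A phalanx record holds the nine raw unguis measurements of one specimen:
#' the eight linear measurements \code{BH, BW, TPL, SH14, SW14, SH34, SW34,
#' VFL} in millimetres and the facet-shaft angle \code{FSA} in degrees, plus
#' \code{specimen_id}, \code{taxon}, \code{digit} and \code{unguis_group}
#' labels. Checks positivity of linear measurements, \code{0 < FSA < 180},
#' and the anatomical constraints \code{VFL <= TPL} and
#' \code{SH14, SH34 < TPL}. Missing (\code{NA}) measurements are allowed and
#' simply excluded from checks; they are handled downstream.
#'
#' @param x data.frame with at least \code{specimen_id} and the measurement
#'   columns present in the data.
#' @return \code{x} invisibly, with \code{unguis_group} checked against the
#'   known vocabulary where present.
#' @export
validate_phalanx <- function(x) {
  stopifnot(is.data.frame(x), "specimen_id" %in% names(x))
  for (v in intersect(LINEAR_VARS, names(x))) {
    bad <- which(!is.na(x[[v]]) & x[[v]] <= 0)
    if (length(bad))
      stop(sprintf("invalid measurement: %s must be > 0 (row %d)", v, bad[1]))
  }
  if ("FSA" %in% names(x)) {
    bad <- which(!is.na(x$FSA) & (x$FSA <= 0 | x$FSA >= 180))
    if (length(bad))
      stop(sprintf("invalid measurement: FSA must lie in (0, 180) (row %d)",
                   bad[1]))
  }
  if (all(c("VFL", "TPL") %in% names(x))) {
    bad <- which(!is.na(x$VFL) & !is.na(x$TPL) & x$VFL > x$TPL)
    if (length(bad))
      stop(sprintf("invalid measurement: VFL exceeds TPL (row %d)", bad[1]))
  }
  for (v in intersect(c("SH14", "SH34"), names(x))) {
    bad <- which(!is.na(x[[v]]) & !is.na(x$TPL) & x[[v]] >= x$TPL)
    if (length(bad))
      stop(sprintf("invalid measurement: %s must be < TPL (row %d)", v, bad[1]))
  }
  if ("unguis_group" %in% names(x)) {
    ug <- x$unguis_group[!is.na(x$unguis_group)]
    if (!all(ug %in% UNGUIS_GROUPS))
      stop("unknown unguis_group: ",
           paste(setdiff(unique(ug), UNGUIS_GROUPS), collapse = ", "))
  }
  invisible(x)
}

#' Geometric mean of the eight linear unguis measurements
#'
#' The size variable used for shape standardization: the 8th root of the
#' product of \code{BH, BW, TPL, SH14, SW14, SH34, SW34, VFL}. Computed in
#' the log domain for numerical stability.
#'
#' @param record a one-row data.frame or named list/vector with the eight
#'   linear measurements.
#' @return positive scalar, in mm.
#' @export
#' @examples
#' geometric_mean(c(BH = 2, BW = 2, TPL = 2, SH14 = 2, SW14 = 2,
#'                  SH34 = 2, SW34 = 2, VFL = 2))  # 2
geometric_mean <- function(record) {
  x <- as.numeric(unlist(record[LINEAR_VARS]))
  names(x) <- LINEAR_VARS
  if (anyNA(x))
    stop("invalid measurement: missing value for ",
         paste(LINEAR_VARS[is.na(x)], collapse = ", "))
  if (any(x <= 0))
    stop("invalid measurement: non-positive ",
         paste(LINEAR_VARS[x <= 0], collapse = ", "))
  exp(mean(log(x)))
}

#' Convert raw measurements to geometric-mean-standardized shape variables
#'
#' Each linear measurement is divided by the record's geometric mean; FSA is
#' passed through unchanged (an angle is already size-free). By
#' construction the product of the eight standardized values is 1.
#'
#' @param records data.frame of phalanx records (see
#'   \code{\link{validate_phalanx}}). Rows with any missing linear
#'   measurement are dropped with a message.
#' @return data.frame with columns \code{specimen_id}, the eight
#'   standardized variables named \code{<VAR>_GM}, \code{FSA} and \code{GM}.
#' @export
standardize_phalanx <- function(records) {
  stopifnot(is.data.frame(records))
  keep <- stats::complete.cases(records[LINEAR_VARS])
  if (any(!keep))
    message(sum(!keep), " record(s) with missing linear measurements ",
            "excluded from GM standardization")
  records <- records[keep, , drop = FALSE]
  gm <- vapply(seq_len(nrow(records)),
               function(i) geometric_mean(records[i, ]), numeric(1))
  out <- records[LINEAR_VARS] / gm
  names(out) <- paste0(LINEAR_VARS, "_GM")
  cbind(data.frame(specimen_id = records$specimen_id,
                   stringsAsFactors = FALSE),
        out,
        FSA = if ("FSA" %in% names(records)) records$FSA else NA_real_,
        GM = gm)
}

#' Simple shape ratios of a distal phalanx
#'
#' The three dimensionless indices used alongside the GM-standardized
#' variables: \code{VFL/TPL} (relative volar-feature length),
#' \code{SH14/SH34} (distal tapering of shaft height) and \code{SW34/TPL}
#' (relative apical-tuft width).
#'
#' @param records data.frame of phalanx records; ratios whose components are
#'   missing come back \code{NA}.
#' @return data.frame with \code{specimen_id}, \code{VFL_TPL},
#'   \code{SH14_SH34}, \code{SW34_TPL}.
#' @export
phalanx_ratios <- function(records) {
  stopifnot(is.data.frame(records))
  div <- function(num, den) {
    if (is.null(num) || is.null(den)) return(rep(NA_real_, nrow(records)))
    bad <- which(!is.na(den) & den == 0)
    if (length(bad))
      stop(sprintf("invalid measurement: zero denominator (row %d)", bad[1]))
    num / den
  }
  data.frame(specimen_id = records$specimen_id,
             VFL_TPL = div(records$VFL, records$TPL),
             SH14_SH34 = div(records$SH14, records$SH34),
             SW34_TPL = div(records$SW34, records$TPL),
             stringsAsFactors = FALSE)
}
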