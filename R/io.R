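# Delimited-text readers/writers and report formatting. Comma and tab
# delimited files are both accepted (UTF-8, header row required).

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a distal-phalanx or foot measurement table
#'
#' Validates column names and measurement ranges; errors carry the
#' offending column and row number.
#'
#' @param path delimited text file (comma or tab), header row naming the
#'   measurement columns (\code{BH, BW, TPL, SH14, SW14, SH34, SW34, VFL,
#'   FSA} plus \code{specimen_id}, \code{taxon}, \code{digit},
#'   \code{unguis_group} for phalanx tables; \code{mt1..mt5, pp1..pp5,
#'   ip2, ip3, ip5} plus \code{individual_id}, \code{taxon} and group
#'   labels for foot tables).
#' @param type \code{"phalanx"} or \code{"foot"}.
#' @return validated data.frame (possibly zero rows).
#' @export
read_measurements <- function(path, type = c("phalanx", "foot")) {
  type <- match.arg(type)
  x <- read_delim_auto(path)
  if (type == "phalanx") {
    if (!"specimen_id" %in% names(x))
      stop("validation error: missing specimen_id column")
    known <- c("specimen_id", "taxon", "digit", "unguis_group",
               PHALANX_VARS)
    unknown <- setdiff(names(x), known)
    if (length(unknown))
      stop("validation error: unknown column(s) ",
           paste(unknown, collapse = ", "))
    num <- intersect(PHALANX_VARS, names(x))
  } else {
    if (!"individual_id" %in% names(x))
      stop("validation error: missing individual_id column")
    known <- c("individual_id", "taxon", "dfa_group", "ratio_group",
               "gradistic_group", FOOT_ELEMENTS)
    unknown <- setdiff(names(x), known)
    if (length(unknown))
      stop("validation error: unknown column(s) ",
           paste(unknown, collapse = ", "))
    num <- intersect(FOOT_ELEMENTS, names(x))
  }
  for (v in num) {
    if (nrow(x) == 0 || all(is.na(x[[v]]))) {
      x[[v]] <- as.numeric(x[[v]])
      next
    }
    if (!is.numeric(x[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[v]]))) &
                     !is.na(x[[v]]) & x[[v]] != "")
      stop("validation error: non-numeric value in ", v,
           if (length(bad)) paste0(" (row ", bad[1], ")"))
    }
  }
  if (type == "phalanx") validate_phalanx(x)
  else {
    for (v in num) {
      bad <- which(!is.na(x[[v]]) & x[[v]] <= 0)
      if (length(bad))
        stop(sprintf("validation error: %s must be > 0 (row %d)",
                     v, bad[1]))
    }
  }
  x
}

#' Write a table as delimited text
#'
#' @param x data.frame.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_measurements <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Format analysis results for reporting
#'
#' Produces the human-readable summary lines of a result object: for a
#' parsimony result the ensemble-statistics line
#' \code{"TL = 42, CI = 0.8571, HI = 0.1429, RI = 0.9016, RC = 0.7728"};
#' for a classification report the per-variable t table rounded to two
#' decimals with the combined verdict.
#'
#' @param x a \code{"parsimony_result"} or \code{"unguis_classification"}.
#' @param ... unused.
#' @return character vector of report lines.
#' @export
report <- function(x, ...) UseMethod("report")

#' @export
report.parsimony_result <- function(x, ...) {
  stopifnot(length(x$trees) >= 1)
  st <- tree_stats(x)
  c(sprintf("%d most parsimonious tree(s) [%s search]",
            length(x$trees), x$method),
    sprintf("TL = %d, CI = %.4f, HI = %.4f, RI = %.4f, RC = %.4f",
            st$TL, st$CI, st$HI, st$RI, st$RC),
    vapply(mp_trees(x), write_newick, ""))
}

#' @export
report.unguis_classification <- function(x, ...) {
  tab <- x$tests
  c(paste("specimen:", x$specimen_id),
    sprintf("%-10s tU = %6.2f  tG = %6.2f  nearest = %s",
            tab$variable, tab$t_ungular, tab$t_grooming, tab$nearest),
    sprintf("verdict: %s (alpha = %.4f)", x$verdict, x$alpha))
}
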