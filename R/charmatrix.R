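#' Construct a discrete character matrix
#'
#' The container for cladistic data: taxa by characters, with small
#' non-negative integer states, ambiguity/polymorphism sets, missing cells
#' and per-character ordering flags. Cells are stored as strings of state
#' digits: \code{"1"} a single state, \code{"02"} the set \{0, 2\},
#' \code{"?"} missing.
#'
#' @param cells character matrix (rows = taxa, must have rownames) of cell
#'   strings.
#' @param ordered logical vector, one per character: \code{TRUE} for
#'   ordered (Wagner, cost |i - j|) characters, \code{FALSE} for unordered
#'   (Fitch). Recycled if length 1.
#' @param outgroup taxon name used to root displayed trees.
#' @param labels optional character labels.
#' @param nstates optional integer vector of alphabet sizes; defaults to
#'   1 + the largest observed state per character.
#' @return object of class \code{"character_matrix"}.
#' @export
character_matrix <- function(cells, ordered = TRUE, outgroup = NULL,
                             labels = NULL, nstates = NULL) {
  cells <- as.matrix(cells)
  if (is.null(rownames(cells))) stop("cells must have taxon rownames")
  taxa <- rownames(cells)
  if (anyDuplicated(taxa)) stop("taxon names must be unique")
  nc <- ncol(cells)
  ordered <- rep_len(as.logical(ordered), nc)
  if (is.null(labels)) labels <- colnames(cells)
  if (is.null(labels)) labels <- paste0("char", seq_len(nc))
  obs_max <- apply(cells, 2, function(col) {
    d <- unlist(strsplit(col[col != "?"], ""))
    if (!length(d)) -1L else max(as.integer(d))
  })
  if (is.null(nstates)) nstates <- pmax(obs_max + 1L, 2L)
  if (any(obs_max + 1L > nstates))
    stop("cell state outside declared alphabet in character ",
         which(obs_max + 1L > nstates)[1])
  bad <- !grepl("^([0-9]+|\\?)$", cells)
  if (any(bad))
    stop("malformed cell '", cells[which(bad)[1]], "'")
  if (is.null(outgroup)) outgroup <- taxa[1]
  if (!outgroup %in% taxa) stop("outgroup '", outgroup, "' not among taxa")
  colnames(cells) <- NULL
  structure(list(taxa = taxa, cells = cells,
                 ordered = ordered, labels = labels,
                 nstates = as.integer(nstates), outgroup = outgroup),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$taxa), "taxa x", ncol(x$cells),
      "characters\n")
  cat("Ordered:", sum(x$ordered), " unordered:", sum(!x$ordered),
      " outgroup:", x$outgroup, "\n")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

#' Describe one edit to a character matrix
#'
#' @param op one of \code{"recode-character"}, \code{"change-cell"},
#'   \code{"add-character"}, \code{"add-taxon"}, \code{"set-ordering"}.
#' @param character character index (1-based) the edit targets.
#' @param taxon taxon name, for cell-level edits.
#' @param value new cell string, for \code{change-cell}.
#' @param states new state alphabet, for recode/add.
#' @param ordered ordering flag, for recode/add/set-ordering.
#' @param cells named vector of cell strings, for \code{add-character}
#'   (names = taxa) or \code{add-taxon} (names ignored, one per character).
#' @param label character label, for \code{add-character}.
#' @param note free-text provenance note carried into the audit log.
#' @return a \code{"matrix_edit"} object.
#' @export
matrix_edit <- function(op, character = NULL, taxon = NULL, value = NULL,
                        states = NULL, ordered = NULL, cells = NULL,
                        label = NULL, note = "") {
  op <- match.arg(op, c("recode-character", "change-cell", "add-character",
                        "add-taxon", "set-ordering"))
  structure(list(op = op, character = character, taxon = taxon,
                 value = value, states = states, ordered = ordered,
                 cells = cells, label = label, note = note),
            class = "matrix_edit")
}

#' Apply a list of edits to a character matrix
#'
#' Each edit is validated against the current matrix; an audit log of every
#' changed cell (taxon, character, old value, new value, note) is attached
#' to the result as attribute \code{"audit"}.
#'
#' @param cm a \code{\link{character_matrix}}.
#' @param edits list of \code{\link{matrix_edit}} objects.
#' @return the edited \code{character_matrix}.
#' @export
apply_edits <- function(cm, edits) {
  stopifnot(inherits(cm, "character_matrix"))
  if (inherits(edits, "matrix_edit")) edits <- list(edits)
  audit <- list()
  log_change <- function(taxon, char, old, new, note)
    audit[[length(audit) + 1L]] <<- data.frame(
      taxon = taxon, character = char, old = old, new = new, note = note,
      stringsAsFactors = FALSE)
  for (e in edits) {
    stopifnot(inherits(e, "matrix_edit"))
    if (e$op %in% c("recode-character", "change-cell", "set-ordering")) {
      j <- e$character
      if (is.null(j) || j < 1 || j > ncol(cm$cells))
        stop("edit error: unknown character ", j)
    }
    switch(e$op,
      "recode-character" = {
        j <- e$character
        cm$nstates[j] <- length(e$states)
        if (!is.null(e$ordered)) cm$ordered[j] <- e$ordered
        log_change(NA_character_, j, NA_character_, NA_character_,
                   paste("recode:", e$note))
      },
      "change-cell" = {
        j <- e$character
        if (!e$taxon %in% cm$taxa)
          stop("edit error: unknown taxon ", e$taxon)
        i <- match(e$taxon, cm$taxa)
        old <- cm$cells[i, j]
        cm$cells[i, j] <- e$value
        log_change(e$taxon, j, old, e$value, e$note)
      },
      "add-character" = {
        cells <- rep("?", length(cm$taxa))
        if (!is.null(e$cells)) {
          unknown <- setdiff(names(e$cells), cm$taxa)
          if (length(unknown))
            stop("edit error: unknown taxon ", unknown[1])
          cells[match(names(e$cells), cm$taxa)] <- unname(e$cells)
        }
        cm$cells <- cbind(cm$cells, cells)
        colnames(cm$cells) <- NULL
        cm$ordered <- c(cm$ordered, isTRUE(e$ordered))
        cm$labels <- c(cm$labels,
                       if (is.null(e$label)) paste0("char", ncol(cm$cells))
                       else e$label)
        cm$nstates <- c(cm$nstates,
                        if (is.null(e$states)) 2L else length(e$states))
        log_change(NA_character_, ncol(cm$cells), NA_character_,
                   NA_character_, paste("add-character:", e$note))
      },
      "add-taxon" = {
        if (e$taxon %in% cm$taxa)
          stop("edit error: taxon ", e$taxon, " already present")
        row <- rep("?", ncol(cm$cells))
        if (!is.null(e$cells)) row[seq_along(e$cells)] <- e$cells
        cm$cells <- rbind(cm$cells, row)
        rownames(cm$cells) <- cm$taxa <- c(cm$taxa, e$taxon)
        log_change(e$taxon, NA_integer_, NA_character_, NA_character_,
                   paste("add-taxon:", e$note))
      },
      "set-ordering" = {
        j <- e$character
        cm$ordered[j] <- e$ordered
        log_change(NA_character_, j, NA_character_, NA_character_,
                   paste("set-ordering:", e$note))
      })
  }
  # revalidate through the constructor
  cells <- cm$cells
  rownames(cells) <- cm$taxa
  out <- character_matrix(cells, cm$ordered, cm$outgroup, cm$labels,
                          cm$nstates)
  attr(out, "audit") <- if (length(audit)) do.call(rbind, audit)
                        else data.frame()
  out
}
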