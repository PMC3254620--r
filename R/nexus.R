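# NEXUS reading and writing, covering the subset used for morphological
# cladistic matrices: DATA/CHARACTERS blocks (DIMENSIONS, FORMAT with
# SYMBOLS/MISSING, MATRIX with "(..)"/"{..}" ambiguity and "?"),
# ASSUMPTIONS blocks (TYPESET with ord/unord ranges) and an outgroup
# declared in a PAUP or SETS block via OUTGROUP. parse_nexus() and
# write_nexus() round-trip losslessly on this data model.

#' Parse a NEXUS character matrix
#'
#' @param text a single string, a character vector of lines, or a path to a
#'   NEXUS file.
#' @return a \code{\link{character_matrix}}.
#' @export
parse_nexus <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1) text <- strsplit(text, "\n")[[1]]
  lines <- text
  strip <- function(s) gsub("\\[[^]]*\\]", "", s)  # NEXUS comments
  lines <- vapply(lines, strip, "", USE.NAMES = FALSE)
  if (!grepl("#NEXUS", toupper(lines[1])))
    stop("parse error at line 1: missing #NEXUS header")
  up <- toupper(lines)

  find_block <- function(name) {
    beg <- grep(paste0("^\\s*BEGIN\\s+", name, "\\s*;"), up)
    if (!length(beg)) return(NULL)
    fin <- grep("^\\s*END\\s*;", up)
    fin <- fin[fin > beg[1]][1]
    if (is.na(fin))
      stop("parse error: unterminated ", name, " block at line ", beg[1])
    list(from = beg[1], to = fin)
  }

  blk <- find_block("DATA")
  if (is.null(blk)) blk <- find_block("CHARACTERS")
  if (is.null(blk)) stop("parse error: no DATA or CHARACTERS block")
  body <- lines[blk$from:blk$to]
  ubody <- toupper(body)

  dim_line <- body[grep("DIMENSIONS", ubody)[1]]
  if (is.na(dim_line)) stop("parse error: DIMENSIONS missing")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dim_line,
                         ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dim_line,
                           ignore.case = TRUE))
  if (is.na(ntax) || is.na(nchar_))
    stop("parse error: DIMENSIONS must give NTAX and NCHAR (line ",
         blk$from + grep("DIMENSIONS", ubody)[1] - 1, ")")

  symbols <- "0123456789"
  fmt <- grep("FORMAT", ubody)
  if (length(fmt)) {
    fl <- body[fmt[1]]
    if (grepl("SYMBOLS", fl, ignore.case = TRUE))
      symbols <- gsub("[\" ]", "",
                      sub(".*SYMBOLS\\s*=\\s*\"([^\"]*)\".*", "\\1", fl,
                          ignore.case = TRUE))
  }
  sym <- strsplit(symbols, "")[[1]]

  mstart <- grep("^\\s*MATRIX\\s*$|^\\s*MATRIX\\b", ubody)
  if (!length(mstart)) stop("parse error: MATRIX missing")
  rows <- body[(mstart[1] + 1):length(body)]
  rows <- rows[!grepl("^\\s*$", rows)]
  stop_at <- grep("^\\s*;", rows)
  if (length(stop_at)) rows <- rows[seq_len(stop_at[1] - 1)]
  if (length(rows) != ntax)
    stop("parse error: MATRIX has ", length(rows), " rows, NTAX is ", ntax)

  taxa <- character(ntax)
  cellrows <- vector("list", ntax)
  for (i in seq_len(ntax)) {
    r <- trimws(rows[i])
    if (startsWith(r, "'")) {
      m <- regexpr("^'([^']|'')*'", r)
      if (m < 0) stop("parse error in MATRIX row ", i, ": unclosed quote")
      len <- attr(m, "match.length")
      taxa[i] <- substr(r, 2, len - 1)
      rest <- trimws(substr(r, len + 1, nchar(r)))
    } else {
      sp <- regexpr("\\s", r)
      if (sp < 0) stop("parse error in MATRIX row ", i, ": no states")
      taxa[i] <- substr(r, 1, sp - 1)
      rest <- trimws(substr(r, sp + 1, nchar(r)))
    }
    taxa[i] <- gsub("''", "'", taxa[i])
    states <- gsub("\\s", "", rest)
    toks <- regmatches(states,
                       gregexpr("\\([^)]*\\)|\\{[^}]*\\}|.", states))[[1]]
    if (length(toks) != nchar_)
      stop("parse error in MATRIX row ", i, " ('", taxa[i], "'): ",
           length(toks), " cells, NCHAR is ", nchar_)
    cells <- vapply(toks, function(tk) {
      if (grepl("^[({]", tk)) tk <- substr(tk, 2, nchar(tk) - 1)
      if (tk %in% c("?", "-")) return("?")
      d <- strsplit(tk, "")[[1]]
      bad <- setdiff(d, sym)
      if (length(bad))
        stop("parse error in MATRIX row ", i, ": undeclared symbol '",
             bad[1], "'")
      paste(sort(match(d, sym) - 1L), collapse = "")
    }, "", USE.NAMES = FALSE)
    cellrows[[i]] <- cells
  }
  cells <- do.call(rbind, cellrows)
  rownames(cells) <- taxa

  # ASSUMPTIONS: TYPESET ... = ord: 1-24 26, unord: 25;
  ordered <- rep(TRUE, nchar_)
  ab <- find_block("ASSUMPTIONS")
  if (!is.null(ab)) {
    abody <- paste(lines[ab$from:ab$to], collapse = " ")
    ts <- regmatches(abody,
                     regexpr("TYPESET[^;]*;", abody, ignore.case = TRUE))
    if (length(ts)) {
      spec <- sub(".*=", "", sub(";$", "", ts))
      parts <- strsplit(spec, ",")[[1]]
      for (p in parts) {
        kv <- strsplit(p, ":")[[1]]
        if (length(kv) != 2) next
        type <- trimws(tolower(kv[1]))
        idx <- parse_index_ranges(kv[2], nchar_)
        if (grepl("^unord", type)) ordered[idx] <- FALSE
        else if (grepl("^ord", type)) ordered[idx] <- TRUE
      }
    }
  }

  outgroup <- NULL
  og <- grep("OUTGROUP", up)
  if (length(og)) {
    o <- sub(";.*$", "", sub(".*OUTGROUP\\s+", "", lines[og[1]],
                             ignore.case = TRUE))
    outgroup <- gsub("^'|'$", "", trimws(o))
  }

  character_matrix(cells, ordered = ordered, outgroup = outgroup)
}

# "1-24 26 28-30" -> integer vector
parse_index_ranges <- function(s, nmax) {
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  idx <- unlist(lapply(toks, function(t) {
    if (grepl("-", t)) {
      ab <- as.integer(strsplit(t, "-")[[1]])
      seq(ab[1], ab[2])
    } else as.integer(t)
  }))
  if (any(is.na(idx) | idx < 1 | idx > nmax))
    stop("parse error: character index out of range in '", s, "'")
  idx
}

#' Write a character matrix as NEXUS text
#'
#' Emits a DATA block, an ASSUMPTIONS block with the ordered/unordered
#' typeset, and a PAUP block declaring the outgroup. Taxon names containing
#' whitespace are single-quoted.
#'
#' @param cm a \code{\link{character_matrix}}.
#' @param file optional path; if omitted the text is returned.
#' @return character vector of lines (invisibly when written to file).
#' @export
write_nexus <- function(cm, file = NULL) {
  stopifnot(inherits(cm, "character_matrix"))
  quote_name <- function(x)
    ifelse(grepl("[\\s()\\[\\]{};']", x, perl = TRUE),
           paste0("'", gsub("'", "''", x), "'"), x)
  fmt_cell <- function(s) {
    if (s == "?") "?"
    else if (nchar(s) > 1) paste0("(", s, ")")
    else s
  }
  nm <- quote_name(cm$taxa)
  pad <- max(nchar(nm)) + 2
  rows <- vapply(seq_along(cm$taxa), function(i) {
    paste0(formatC(nm[i], width = -pad),
           paste(vapply(cm$cells[i, ], fmt_cell, ""), collapse = ""))
  }, "")
  runs <- function(idx) {
    if (!length(idx)) return("")
    idx <- sort(idx)
    brk <- c(0, which(diff(idx) > 1), length(idx))
    paste(vapply(seq_len(length(brk) - 1), function(k) {
      a <- idx[brk[k] + 1]; b <- idx[brk[k + 1]]
      if (a == b) as.character(a) else paste0(a, "-", b)
    }, ""), collapse = " ")
  }
  ts <- c(if (any(cm$ordered)) paste0("ord: ", runs(which(cm$ordered))),
          if (any(!cm$ordered)) paste0("unord: ", runs(which(!cm$ordered))))
  out <- c("#NEXUS",
           "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;",
                   length(cm$taxa), ncol(cm$cells)),
           sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=?;",
                   paste(0:(max(cm$nstates) - 1), collapse = "")),
           "  MATRIX",
           rows,
           "  ;",
           "END;",
           "BEGIN ASSUMPTIONS;",
           sprintf("  TYPESET * default = %s;", paste(ts, collapse = ", ")),
           "END;",
           "BEGIN PAUP;",
           sprintf("  OUTGROUP %s;", quote_name(cm$outgroup)),
           "END;")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
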