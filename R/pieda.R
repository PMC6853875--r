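# PIEDA table parsing and interchange.
#
# A pie_table holds one record per fragment pair with the decomposition
# terms (electrostatic, exchange-repulsion, charge-transfer+mix,
# dispersion, optional solvation) in kcal/mol as printed by the quantum
# chemistry code; totals are never silently corrected.

PIE_COMPONENTS <- c("e_es", "e_ex", "e_ct_mix", "e_di", "g_sol")

#' Construct a pair-interaction-energy table
#'
#' @param records data.frame with columns `frag_i`, `frag_j`, `e_es`,
#'   `e_ex`, `e_ct_mix`, `e_di`, `g_sol` (may be `NA` throughout), `total`;
#'   optional `label_i`, `label_j`.  Pairs are normalized to
#'   `frag_i < frag_j`.
#' @param n_fragments number of fragments in the underlying system.
#' @param metadata free-form list (level of theory, solvent model, source).
#' @return object of class `pie_table`.
#' @export
pie_table <- function(records, n_fragments, metadata = list()) {
  need <- c("frag_i", "frag_j", "e_es", "e_ex", "e_ct_mix", "e_di", "total")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("pie_table records lack columns: %s",
                          paste(miss, collapse = ", "))
  if (!"g_sol" %in% names(records)) records$g_sol <- NA_real_
  swap <- records$frag_i > records$frag_j
  if (any(swap)) {
    tmp <- records$frag_i[swap]
    records$frag_i[swap] <- records$frag_j[swap]
    records$frag_j[swap] <- tmp
  }
  if (any(records$frag_i == records$frag_j))
    stopf("self-pair (i == j) in pie_table")
  key <- paste(records$frag_i, records$frag_j)
  if (anyDuplicated(key)) stopf("duplicate fragment pair in pie_table")
  if (any(records$frag_j > n_fragments))
    stopf("fragment index exceeds n_fragments")
  records <- records[order(records$frag_i, records$frag_j), , drop = FALSE]
  rownames(records) <- NULL
  out <- list(records = records, n_fragments = as.integer(n_fragments),
              metadata = metadata)
  class(out) <- "pie_table"
  out
}

#' @export
print.pie_table <- function(x, ...) {
  cat(sprintf("<pie_table> %d pair records over %d fragments%s\n",
              nrow(x$records), x$n_fragments,
              if (all(is.na(x$records$g_sol))) " (no solvation column)" else ""))
  invisible(x)
}

#' Total pair interaction energy from the decomposition terms
#'
#' Sum of electrostatic, exchange-repulsion, charge-transfer+mix and
#' dispersion terms plus the solvation term when present (`NA` solvation is
#' treated as 0).
#'
#' @param x a `pie_table`, or a data.frame with the component columns.
#' @return numeric vector of totals, kcal/mol.
#' @export
total_pie <- function(x) {
  rec <- if (inherits(x, "pie_table")) x$records else x
  g <- rec$g_sol %||% rep(NA_real_, nrow(rec))
  g[is.na(g)] <- 0
  rec$e_es + rec$e_ex + rec$e_ct_mix + rec$e_di + g
}

#' Column-name dialect for PIEDA summary tables
#'
#' The parser is table-driven: a dialect maps the package's component names
#' to the column headers printed by a particular program version, so
#' another dialect is a configuration entry rather than new code.
#'
#' @param header_pattern regex identifying the table header line.
#' @param columns named character vector mapping `frag_i`, `frag_j`,
#'   `e_es`, `e_ex`, `e_ct_mix`, `e_di`, `g_sol`, `total` to header tokens.
#' @return dialect list.
#' @export
pieda_dialect <- function(header_pattern = "^\\s*I\\s+J\\s+DL\\s+Z\\s+R\\b",
                          columns = c(frag_i = "I", frag_j = "J",
                                      e_es = "ES", e_ex = "EX",
                                      e_ct_mix = "CT+MIX", e_di = "DI",
                                      g_sol = "SOL", total = "TOTAL")) {
  list(header_pattern = header_pattern, columns = columns)
}

#' Parse a PIEDA pair-interaction table from program output text
#'
#' Locates the PIEDA summary block (arbitrary preamble is ignored), splits
#' rows on whitespace so column-width drift is harmless, and returns one
#' record per listed pair.  A missing solvation column leaves `g_sol` as
#' `NA` and totals are the four-term sums.  Rows whose printed total
#' deviates from the component sum by more than `check_tol` are flagged in
#' a `consistent` column (with a warning), never corrected.  Duplicate
#' pairs (restart blocks) keep the last occurrence with a warning.
#'
#' @param text output text: a single string, a character vector of lines,
#'   or a file path.
#' @param dialect a [pieda_dialect()].
#' @param check_tol tolerance (kcal/mol) for the total-vs-components check.
#' @return a [pie_table()].
#' @export
parse_fmo_output <- function(text, dialect = pieda_dialect(),
                             check_tol = 1e-2) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  hdr <- grep(dialect$header_pattern, lines)
  if (length(hdr) == 0L)
    stopf("no PIEDA block found in output text")
  rows <- list()
  for (h in hdr) {
    toks <- strsplit(trimws(lines[h]), "\\s+")[[1]]
    colpos <- match(dialect$columns, toks)
    names(colpos) <- names(dialect$columns)
    required <- setdiff(names(dialect$columns), "g_sol")
    if (any(is.na(colpos[required])))
      stopf("PIEDA header lacks required column(s): %s",
            paste(dialect$columns[required][is.na(colpos[required])],
                  collapse = ", "))
    j <- h + 1L
    while (j <= length(lines)) {
      ln <- trimws(lines[j])
      if (!nzchar(ln)) { j <- j + 1L; next }
      tk <- strsplit(ln, "\\s+")[[1]]
      if (!grepl("^[0-9]+$", tk[1])) break
      if (length(tk) < max(colpos, na.rm = TRUE)) {
        warnf("malformed PIEDA row at line %d skipped", j)
        j <- j + 1L; next
      }
      num <- suppressWarnings(as.numeric(tk))
      vals <- lapply(colpos, function(p) if (is.na(p)) NA_real_ else num[p])
      if (any(is.na(unlist(vals[required])))) {
        warnf("malformed PIEDA row at line %d skipped", j)
        j <- j + 1L; next
      }
      rows[[length(rows) + 1L]] <- as.data.frame(vals)
      j <- j + 1L
    }
  }
  if (length(rows) == 0L) stopf("PIEDA block contains no data rows")
  rec <- do.call(rbind, rows)
  rec$frag_i <- as.integer(rec$frag_i)
  rec$frag_j <- as.integer(rec$frag_j)
  swap <- rec$frag_i > rec$frag_j
  tmp <- rec$frag_i[swap]; rec$frag_i[swap] <- rec$frag_j[swap]
  rec$frag_j[swap] <- tmp
  key <- paste(rec$frag_i, rec$frag_j)
  if (anyDuplicated(key)) {
    warnf("duplicate pair rows in PIEDA block; keeping last occurrence")
    rec <- rec[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  dev <- abs(rec$total - total_pie(rec))
  rec$consistent <- dev <= check_tol
  if (any(!rec$consistent))
    warnf("%d PIEDA row(s) have totals deviating from component sums by > %g kcal/mol",
          sum(!rec$consistent), check_tol)
  nf <- regmatches(text, regexpr("NFRAG\\s*=\\s*[0-9]+", text))
  nf <- suppressWarnings(as.integer(sub(".*=\\s*", "", unlist(nf))))
  n_fragments <- if (length(nf) && !all(is.na(nf))) max(nf, na.rm = TRUE)
                 else max(rec$frag_j)
  pie_table(rec, n_fragments,
            metadata = list(source = "parsed", solvation =
                              !all(is.na(rec$g_sol))))
}

#' Write / read the CSV interchange form of a pie_table
#'
#' Columns: `frag_i, frag_j, label_i, label_j, e_es, e_ex, e_ct_mix, e_di,
#' g_sol, total`.  An absent solvation term is written as an empty field
#' and survives the round trip as `NA`.
#'
#' @param table a `pie_table`.
#' @param path CSV path.
#' @param plan optional `spies_plan` used to fill the label columns.
#' @return `path` invisibly (writer); a `pie_table` (reader).
#' @export
write_pie_table <- function(table, path, plan = NULL) {
  rec <- table$records
  if (!is.null(plan)) {
    rec$label_i <- plan$fragments$label[rec$frag_i]
    rec$label_j <- plan$fragments$label[rec$frag_j]
  }
  if (!"label_i" %in% names(rec)) rec$label_i <- ""
  if (!"label_j" %in% names(rec)) rec$label_j <- ""
  cols <- c("frag_i", "frag_j", "label_i", "label_j",
            "e_es", "e_ex", "e_ct_mix", "e_di", "g_sol", "total")
  utils::write.csv(rec[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pie_table
#' @export
read_pie_table <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frag_i", "frag_j", "e_es", "e_ex", "e_ct_mix", "e_di", "total")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stopf("pie table CSV lacks mandatory column(s): %s",
                          paste(miss, collapse = ", "))
  if (!"g_sol" %in% names(rec)) rec$g_sol <- NA_real_
  rec$g_sol <- as.numeric(rec$g_sol)
  pie_table(rec, n_fragments = max(rec$frag_j),
            metadata = list(source = path))
}
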