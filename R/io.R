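## Profile CSV plumbing.
##
## Format: '#'-prefixed metadata lines (#unit:, #total_uM:, #label:,
## optionally #seed:), then a 'congener,value' header and one row per
## congener. The writer emits congeners in descending value order.

#' Read / write congener profile CSV files
#'
#' The profile CSV carries a \code{congener,value} table preceded by
#' metadata lines: \code{#unit: mol_percent|weight_percent} (required),
#' \code{#total_uM: <float>} and \code{#label: <text>} (optional). Unknown
#' congener names and duplicate rows are rejected with the offending line
#' numbers. Writing then reading a profile returns an equal profile
#' (lossless up to float formatting).
#'
#' @param path file path.
#' @return \code{readProfile} returns a
#'   \code{\linkS4class{CongenerProfile}}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeProfile(congenerProfile(c("245-245-CB" = 100), totalConc = 81), f)
#' readProfile(f)
#' @export
readProfile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta_idx <- which(startsWith(trimws(lines), "#"))
  meta <- list()
  for (ln in lines[meta_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", trimws(ln)))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  if (is.null(meta$unit))
    stop("missing '#unit:' metadata line in ", path)
  if (!meta$unit %in% c("mol_percent", "weight_percent"))
    stop("unknown unit '", meta$unit, "' in ", path)
  body_idx <- setdiff(seq_along(lines), meta_idx)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (!length(body_idx)) stop("no data rows in ", path)
  header <- body_idx[1]
  if (tolower(gsub("\\s", "", lines[header])) != "congener,value")
    stop("expected header 'congener,value' at line ", header, " of ", path)
  rows <- body_idx[-1]
  if (!length(rows)) stop("no data rows in ", path)
  parts <- strsplit(lines[rows], ",", fixed = TRUE)
  bad <- rows[lengths(parts) != 2]
  if (length(bad))
    stop("malformed row(s) at line(s) ", paste(bad, collapse = ", "),
         " of ", path)
  nm_raw <- vapply(parts, function(p) trimws(p[1]), character(1))
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  if (anyNA(val))
    stop("non-numeric value at line(s) ",
         paste(rows[is.na(val)], collapse = ", "), " of ", path)
  nm <- character(length(nm_raw))
  for (i in seq_along(nm_raw)) {
    nm[i] <- tryCatch(.canonicalEntryName(nm_raw[i]), error = function(e)
      stop("line ", rows[i], " of ", path, ": ", conditionMessage(e),
           call. = FALSE))
  }
  if (anyDuplicated(nm)) {
    d <- nm[duplicated(nm)][1]
    stop("duplicate congener '", d, "' at lines ",
         paste(rows[nm == d], collapse = " and "), " of ", path)
  }
  congenerProfile(setNames(val, nm), unit = meta$unit,
                  totalConc = if (is.null(meta$total_uM)) NA_real_
                              else as.numeric(meta$total_uM),
                  label = meta$label %||% "")
}

#' @rdname readProfile
#' @param p a \code{CongenerProfile}.
#' @param seed optional integer recorded as a \code{#seed:} metadata line
#'   (provenance only; not used on read).
#' @export
writeProfile <- function(p, path, seed = NULL) {
  e <- sort(p@entries, decreasing = TRUE)
  lines <- c(sprintf("#unit: %s", p@unit),
             if (!is.na(p@totalConc)) sprintf("#total_uM: %.10g", p@totalConc),
             if (nzchar(p@label)) sprintf("#label: %s", p@label),
             if (!is.null(seed)) sprintf("#seed: %d", as.integer(seed)),
             "congener,value",
             sprintf("%s,%.10g", names(e), e))
  writeLines(lines, path)
  invisible(path)
}
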