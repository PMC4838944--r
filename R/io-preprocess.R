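# Reading, writing and collapsing XRF scan tables.
#
# Scan-table dialect: UTF-8 CSV with a header row; metadata columns
# specimen_id, species, sex, site_long, site_trans, layer; every remaining
# column is an element with relative abundance (ppm or percent).

element_columns <- function(tab) setdiff(names(tab), META_COLS)

#' Convert relative percent abundance to ppm
#'
#' Handheld XRF units report semi-quantified relative abundances as percent
#' of total; downstream analysis works in ppm, obtained as percent x 10,000.
#'
#' @param value Numeric vector of percentages in [0, 100].
#' @return ppm values (value x 10,000).
#' @export
percent_to_ppm <- function(value) {
  if (!is.numeric(value)) stop("percent values must be numeric")
  bad <- value[!is.na(value) & (value < 0 | value > 100)]
  if (length(bad))
    stop("percent values must lie in [0, 100]; offending value: ", bad[[1]])
  value * 10000
}

normalise_code <- function(x, allowed) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x) | !(x %in% allowed)] <- "unknown"
  x
}

validate_scan_table <- function(tab) {
  miss <- setdiff("specimen_id", names(tab))
  if (length(miss)) stop("scan table lacks required column: specimen_id")
  els <- element_columns(tab)
  if (!length(els)) stop("scan table contains no element columns")
  for (m in setdiff(META_COLS, names(tab))) tab[[m]] <- "unknown"
  tab$specimen_id <- as.character(tab$specimen_id)
  if (any(is.na(tab$specimen_id) | !nzchar(tab$specimen_id)))
    stop("empty specimen_id")
  tab$species <- normalise_code(tab$species, c("Asian", "African"))
  tab$sex <- normalise_code(tab$sex, c("male", "female"))
  tab$site_long <- normalise_code(tab$site_long, LONG_SITES)
  tab$site_trans <- normalise_code(tab$site_trans, TRANS_SITES)
  tab$layer <- normalise_code(tab$layer, c("enamel", "dentine"))
  tab[c(META_COLS, els)]
}

#' Read a table of XRF scan records
#'
#' Reads the CSV scan-table dialect, converts percent input to ppm, imputes
#' missing element cells as 0 ppm (non-detect) with a logged count, and
#' rejects rows with non-numeric abundances.
#'
#' @param path File path.
#' @param unit Unit of the element columns: \code{"ppm"} (default) or
#'   \code{"percent"} (converted via [percent_to_ppm()]).
#' @return data.frame of typed scan records (ppm).
#' @export
read_scan_table <- function(path, unit = c("ppm", "percent")) {
  unit <- match.arg(unit)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = c("NA", ""))
  if (!"specimen_id" %in% names(raw))
    stop("scan table header lacks required column: specimen_id")
  els <- element_columns(raw)
  n_imputed <- 0L
  drop <- rep(FALSE, nrow(raw))
  for (e in els) {
    x <- raw[[e]]
    blank <- is.na(x)
    num <- suppressWarnings(as.numeric(x))
    bad <- !blank & is.na(num)
    if (any(bad)) drop <- drop | bad
    num[blank] <- 0
    n_imputed <- n_imputed + sum(blank & !bad)
    raw[[e]] <- num
  }
  if (any(drop)) {
    message(sum(drop), " row(s) rejected: non-numeric abundance values")
    raw <- raw[!drop, , drop = FALSE]
  }
  if (n_imputed > 0)
    message(n_imputed, " missing element cell(s) imputed as 0 ppm (non-detect)")
  if (unit == "percent")
    for (e in els) raw[[e]] <- percent_to_ppm(raw[[e]])
  tab <- validate_scan_table(raw)
  for (e in els) {
    if (any(tab[[e]] < 0)) stop("negative abundance in column ", e)
    if (any(tab[[e]] > 1e6)) stop("abundance above 1,000,000 ppm in column ", e)
  }
  key <- interaction(tab$specimen_id, tab$site_long, tab$site_trans,
                     tab$layer, drop = TRUE)
  if (anyDuplicated(key))
    warning("duplicate (specimen, site, layer) scan keys present; ",
            "all rows retained")
  rownames(tab) <- NULL
  tab
}

#' Write a table of XRF scan records
#'
#' @param tab Scan table as returned by [generate_scans()] or
#'   [read_scan_table()].
#' @param path Destination CSV path.
#' @return \code{path}, invisibly.
#' @export
write_scan_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse replicate scans into per-specimen panels
#'
#' Arithmetic mean of each element across a specimen's scans. Model building
#' uses the enamel layer by default (whole-tusk surface scans measure
#' enamel); set \code{layer = "all"} to pool layers, or
#' \code{group_by_layer = TRUE} to keep one panel per specimen x layer (as
#' needed for enamel-vs-dentine contrasts).
#'
#' @param scans Scan table.
#' @param group_by_layer Keep layers separate instead of pooling.
#' @param layer Which layer(s) to retain before averaging: \code{"enamel"}
#'   (default) or \code{"all"}. Ignored when \code{group_by_layer} is TRUE.
#' @return data.frame with columns \code{specimen_id, species, sex}
#'   (+ \code{layer} if grouped), \code{n_scans}, and one mean-ppm column per
#'   element. Warns when a specimen has fewer than 3 scans.
#' @export
average_panels <- function(scans, group_by_layer = FALSE, layer = c("enamel", "all")) {
  layer <- match.arg(layer)
  scans <- validate_scan_table(scans)
  if (!group_by_layer && layer == "enamel" && any(scans$layer == "enamel"))
    scans <- scans[scans$layer == "enamel", , drop = FALSE]
  if (nrow(scans) == 0) {
    out <- scans[0, c("specimen_id", "species", "sex"), drop = FALSE]
    out$n_scans <- integer(0)
    return(out)
  }
  keys <- if (group_by_layer) c("specimen_id", "layer") else "specimen_id"
  g <- interaction(scans[keys], drop = TRUE, lex.order = TRUE)
  els <- element_columns(scans)
  first <- !duplicated(g)
  out <- scans[first, c("specimen_id", "species", "sex",
                        if (group_by_layer) "layer"), drop = FALSE]
  ord <- order(match(g[first], levels(g)))
  out <- out[ord, , drop = FALSE]
  out$n_scans <- as.integer(table(g))
  means <- vapply(els, function(e) as.numeric(tapply(scans[[e]], g, mean)),
                  numeric(nlevels(g)))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1, dimnames = list(NULL, els))
  out <- cbind(out, as.data.frame(means, check.names = FALSE))
  if (any(out$n_scans < 3))
    warning(sum(out$n_scans < 3),
            " specimen panel(s) averaged from fewer than 3 scans")
  rownames(out) <- NULL
  out
}
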