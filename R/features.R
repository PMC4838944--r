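# Ratio features over a selected denominator element, with validity
# accounting ("valid data %": specimens whose denominator was detected).

#' Assess elements as candidate ratio denominators
#'
#' Applies the three suitability criteria for a ratio denominator:
#' (i) detected in both species with coefficient of variation below
#' \code{cv_max} in each; (ii) at most slightly heterogeneous across
#' non-longitudinal dimensions -- no significant enamel/dentine difference
#' and transverse-site ANOVA p above \code{trans_alpha} (longitudinal
#' gradients do not disqualify: scans are averaged along the tusk);
#' (iii) significantly different between the species. Contrasts that could
#' not be computed (single layer, etc.) are treated as compatible with
#' homogeneity.
#'
#' @param screen An [screen_elements()] report.
#' @param cv_max CV bound for criterion (i); default 1.
#' @param species_alpha Significance level for criterion (iii); default 0.05.
#' @param layer_alpha Level at which an enamel/dentine difference counts as
#'   heterogeneous; default 0.05.
#' @param trans_alpha Transverse ANOVA p below this counts as strongly
#'   heterogeneous; default 0.01.
#' @return data.frame with one row per element: logical flags \code{cv_ok},
#'   \code{homogeneity_ok}, \code{species_diff_ok} and their conjunction
#'   \code{eligible}, in element order.
#' @export
assess_denominators <- function(screen, cv_max = 1, species_alpha = 0.05,
                                layer_alpha = 0.05, trans_alpha = 0.01) {
  stopifnot(is.data.frame(screen), "element" %in% names(screen))
  detected <- screen$mean_asian > 0 & screen$mean_african > 0
  cv_ok <- detected &
    !is.na(screen$cv_asian) & !is.na(screen$cv_african) &
    screen$cv_asian < cv_max & screen$cv_african < cv_max
  layer_ok <- is.na(screen$ttest_p_layer) | screen$ttest_p_layer > layer_alpha
  trans_ok <- is.na(screen$anova_p_transverse) |
    screen$anova_p_transverse > trans_alpha
  homogeneity_ok <- layer_ok & trans_ok
  species_diff_ok <- !is.na(screen$ttest_p_species) &
    screen$ttest_p_species < species_alpha
  data.frame(
    element = screen$element,
    cv_ok = unname(cv_ok),
    homogeneity_ok = unname(homogeneity_ok),
    species_diff_ok = unname(species_diff_ok),
    eligible = unname(cv_ok & homogeneity_ok & species_diff_ok),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build ratio features over a denominator element
#'
#' Divides every other element by the chosen denominator. Specimens whose
#' denominator is a non-detect (0 ppm) are invalid: they are excluded from
#' the feature matrix and counted in \code{valid_fraction} (the "valid
#' data %" of the denominator). \code{denominator = "none"} returns the raw
#' ppm panels (all specimens valid); \code{denominator = "combined"}
#' concatenates the ratio blocks of \code{combine} denominators, a specimen
#' being valid only when every one of them is detected.
#'
#' @param panels Specimen panels.
#' @param denominator Element symbol, \code{"none"}, or \code{"combined"}.
#' @param combine Denominators pooled by \code{"combined"}.
#' @return Object of class \code{ratio_features}: list with
#'   \code{denominator}, \code{features} (matrix, valid specimens x ratios),
#'   \code{specimen_id}, \code{species} (labels of valid rows),
#'   \code{valid_mask} (named logical over all specimens),
#'   \code{valid_fraction}.
#' @export
build_ratios <- function(panels, denominator = "Zr",
                         combine = c("Zr", "P", "Ag", "Cd", "Sn", "Sb")) {
  els <- setdiff(element_columns(panels), "n_scans")
  ids <- panels$specimen_id
  species <- if ("species" %in% names(panels)) panels$species else
    rep("unknown", nrow(panels))

  block <- function(den) {
    num <- setdiff(els, den)
    M <- as.matrix(panels[num]) / panels[[den]]
    colnames(M) <- paste0(num, "/", den)
    M
  }

  if (identical(denominator, "none")) {
    X <- as.matrix(panels[els])
    valid <- rep(TRUE, nrow(panels))
  } else if (identical(denominator, "combined")) {
    combine <- intersect(combine, els)
    if (!length(combine)) stop("no pooled denominators present in panels")
    valid <- Reduce(`&`, lapply(combine, function(d) panels[[d]] > 0))
    X <- do.call(cbind, lapply(combine, block))
  } else {
    if (!denominator %in% els)
      stop("denominator '", denominator, "' not present in panels")
    valid <- panels[[denominator]] > 0
    X <- block(denominator)
  }
  if (!any(valid))
    stop("no valid data: denominator undetected in every specimen")
  X <- X[valid, , drop = FALSE]
  rownames(X) <- ids[valid]
  structure(
    list(denominator = denominator,
         features = X,
         specimen_id = ids[valid],
         species = species[valid],
         valid_mask = stats::setNames(valid, ids),
         valid_fraction = mean(valid)),
    class = "ratio_features"
  )
}

#' @export
print.ratio_features <- function(x, ...) {
  cat(sprintf("Ratio features (denominator: %s)\n", x$denominator))
  cat(sprintf("  %d valid specimens x %d ratios; valid data %.1f%%\n",
              nrow(x$features), ncol(x$features), 100 * x$valid_fraction))
  invisible(x)
}
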