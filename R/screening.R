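# Element-level screening: site homogeneity, group contrasts, CVs,
# correlations, Ca/P ratios and exploratory hierarchical clustering.

#' One-way ANOVA of element abundance across scan sites
#'
#' Tests, per element, whether scans differ across the four longitudinal
#' regions (E0 tip to E3 base) or the four transverse planes.
#'
#' @param scans Scan table.
#' @param direction \code{"longitudinal"} (E0--E3) or \code{"transverse"}.
#' @return data.frame with columns \code{element}, \code{p_value},
#'   \code{f_statistic}, \code{flagged} (TRUE when the test is undefined,
#'   e.g. a site with a single scan and no residual variance).
#' @export
site_homogeneity <- function(scans, direction = c("longitudinal", "transverse")) {
  direction <- match.arg(direction)
  scans <- validate_scan_table(scans)
  site <- if (direction == "longitudinal") scans$site_long else scans$site_trans
  keep <- site != "unknown"
  scans <- scans[keep, , drop = FALSE]
  site <- factor(site[keep])
  if (nlevels(site) < 2 || any(table(site) < 2))
    stop("need at least two sites with two or more scans each")
  els <- element_columns(scans)
  res <- lapply(els, function(e) {
    y <- scans[[e]]
    if (stats::var(y) == 0)        # identical values everywhere: F = 0
      return(c(p = 1, f = 0, flag = 0))
    fit <- tryCatch(stats::oneway.test(y ~ site, var.equal = TRUE),
                    error = function(err) NULL)
    if (is.null(fit) || !is.finite(fit$p.value))
      return(c(p = NA_real_, f = NA_real_, flag = 1))
    c(p = fit$p.value, f = unname(fit$statistic), flag = 0)
  })
  res <- do.call(rbind, res)
  data.frame(element = els, p_value = res[, "p"], f_statistic = res[, "f"],
             flagged = res[, "flag"] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Two-group contrast of specimen panels
#'
#' Welch two-sample t-test of each element between the two levels of a
#' grouping factor (species, sex, or enamel/dentine layer), with group means.
#'
#' @param panels Specimen panels (see [average_panels()]); for
#'   \code{factor = "layer"} they must have been built with
#'   \code{group_by_layer = TRUE}.
#' @param factor One of \code{"species"}, \code{"sex"}, \code{"layer"}.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return data.frame with per-element \code{p_value}, group means,
#'   and \code{flagged} when a level has fewer than 2 observations or the
#'   test is undefined.
#' @export
group_contrast <- function(panels, factor = c("species", "sex", "layer"),
                           var_equal = FALSE) {
  factor <- match.arg(factor)
  lv <- switch(factor, species = c("Asian", "African"),
               sex = c("male", "female"), layer = c("enamel", "dentine"))
  if (!factor %in% names(panels))
    stop("panels lack a '", factor, "' column")
  g <- as.character(panels[[factor]])
  keep <- g %in% lv
  panels <- panels[keep, , drop = FALSE]
  g <- factor(g[keep], levels = lv)
  if (nlevels(droplevels(g)) < 2)
    stop("both levels of '", factor, "' must be present")
  els <- element_columns(panels)
  els <- setdiff(els, "n_scans")
  res <- lapply(els, function(e) {
    y <- panels[[e]]
    m1 <- mean(y[g == lv[1]]); m2 <- mean(y[g == lv[2]])
    if (min(table(g)) < 2)
      return(c(p = NA_real_, m1 = m1, m2 = m2, flag = 1))
    tt <- tryCatch(stats::t.test(y ~ g, var.equal = var_equal),
                   error = function(err) NULL)
    if (is.null(tt) || !is.finite(tt$p.value))
      return(c(p = NA_real_, m1 = m1, m2 = m2, flag = 1))
    c(p = tt$p.value, m1 = m1, m2 = m2, flag = 0)
  })
  res <- do.call(rbind, res)
  out <- data.frame(element = els, p_value = res[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out[[paste0("mean_", tolower(lv[1]))]] <- res[, "m1"]
  out[[paste0("mean_", tolower(lv[2]))]] <- res[, "m2"]
  out$flagged <- res[, "flag"] == 1
  out
}

#' Coefficient of variation per element and species
#'
#' CV = sd/mean of the specimen mean-ppm panels, computed within each
#' species. Undefined (NA, flagged) when the species mean is 0.
#'
#' @param panels Specimen panels with a species column.
#' @return data.frame with \code{element}, \code{cv_asian}, \code{cv_african}.
#' @export
cv_by_species <- function(panels) {
  els <- setdiff(element_columns(panels), "n_scans")
  cv1 <- function(y) {
    m <- mean(y)
    if (m == 0) NA_real_ else stats::sd(y) / m
  }
  data.frame(
    element = els,
    cv_asian = vapply(els, function(e) cv1(panels[[e]][panels$species == "Asian"]),
                      numeric(1)),
    cv_african = vapply(els, function(e) cv1(panels[[e]][panels$species == "African"]),
                        numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pearson correlation matrix between elements
#'
#' @param panels Specimen panels (species pooled, as in exploratory
#'   correlation heatmaps of tusk elements).
#' @return Symmetric element x element matrix of Pearson r, unit diagonal.
#'   Zero-variance elements give NA rows/columns with a warning.
#' @export
correlation_matrix <- function(panels) {
  els <- setdiff(element_columns(panels), "n_scans")
  X <- as.matrix(panels[els])
  if (nrow(X) < 3) stop("need at least 3 panels for correlations")
  v <- apply(X, 2, stats::var)
  if (any(v == 0))
    warning("zero-variance element(s): ", paste(els[v == 0], collapse = ", "),
            "; correlations undefined (NA)")
  suppressWarnings(R <- stats::cor(X))
  diag(R) <- ifelse(v == 0, NA_real_, 1)
  R
}

#' Hierarchical clustering of specimen panels
#'
#' Agglomerative (Ward) clustering of z-scored panels on Euclidean distance;
#' with k = 2 this is the exploratory grouping that precedes discriminant
#' analysis. When species labels are present a cluster x species
#' cross-tabulation is attached.
#'
#' @param panels Specimen panels.
#' @param k Number of clusters to cut.
#' @return data.frame \code{specimen_id}, \code{cluster}; attribute
#'   \code{"crosstab"} holds the cluster x species table when labels exist.
#' @export
hierarchical_clusters <- function(panels, k = 2) {
  if (k < 1) stop("k must be at least 1")
  if (nrow(panels) < k) stop("more clusters than specimens")
  els <- setdiff(element_columns(panels), "n_scans")
  X <- scale(as.matrix(panels[els]))
  X[, !is.finite(colSums(X))] <- 0   # constant elements carry no signal
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  out <- data.frame(specimen_id = panels$specimen_id, cluster = unname(cl),
                    stringsAsFactors = FALSE)
  if ("species" %in% names(panels) && any(panels$species != "unknown"))
    attr(out, "crosstab") <- table(cluster = cl, species = panels$species)
  out
}

#' Ca/P ratio summaries by species and by scan site
#'
#' @param panels Specimen panels (for the species summary).
#' @param scans Optional scan table; when given, mean Ca/P is also reported
#'   per longitudinal and per transverse site.
#' @return List with \code{by_species} (mean of per-specimen Ca/P) and,
#'   when scans are supplied, \code{by_site_long} and \code{by_site_trans}.
#' @export
ca_p_ratio <- function(panels, scans = NULL) {
  stopifnot(all(c("Ca", "P") %in% names(panels)))
  r <- panels$Ca / panels$P
  by_species <- tapply(r, panels$species, mean)
  out <- list(by_species = by_species)
  if (!is.null(scans)) {
    rs <- scans$Ca / scans$P
    out$by_site_long <- tapply(rs, scans$site_long, mean)
    out$by_site_trans <- tapply(rs, scans$site_trans, mean)
  }
  out
}

#' Full element screening report
#'
#' Assembles, per element: one-way ANOVA p-values across longitudinal and
#' transverse sites (from the scans), Welch t-test p-values for species,
#' sex and layer contrasts (from panels), species CVs and species means.
#' Contrasts whose factor has a single level (e.g. layer in an enamel-only
#' data set, or sex with no labelled females) are returned as NA.
#'
#' @param scans Scan table.
#' @return data.frame, one row per element (class \code{element_screen}).
#' @export
screen_elements <- function(scans) {
  scans <- validate_scan_table(scans)
  panels <- suppressWarnings(average_panels(scans))
  els <- setdiff(element_columns(panels), "n_scans")

  safe_p <- function(expr) {
    tab <- tryCatch(expr, error = function(err) NULL)
    if (is.null(tab)) return(stats::setNames(rep(NA_real_, length(els)), els))
    stats::setNames(tab$p_value[match(els, tab$element)], els)
  }
  p_long <- safe_p(site_homogeneity(scans, "longitudinal"))
  p_trans <- safe_p(site_homogeneity(scans, "transverse"))
  sp <- group_contrast(panels, "species")
  p_sex <- safe_p(group_contrast(panels, "sex"))
  panels_layer <- suppressWarnings(average_panels(scans, group_by_layer = TRUE))
  p_layer <- safe_p(group_contrast(panels_layer, "layer"))
  cv <- cv_by_species(panels)

  out <- data.frame(
    element = els,
    anova_p_longitudinal = unname(p_long[els]),
    anova_p_transverse = unname(p_trans[els]),
    ttest_p_species = sp$p_value[match(els, sp$element)],
    ttest_p_sex = unname(p_sex[els]),
    ttest_p_layer = unname(p_layer[els]),
    cv_asian = cv$cv_asian[match(els, cv$element)],
    cv_african = cv$cv_african[match(els, cv$element)],
    mean_asian = sp$mean_asian[match(els, sp$element)],
    mean_african = sp$mean_african[match(els, sp$element)],
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("element_screen", "data.frame")
  out
}
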