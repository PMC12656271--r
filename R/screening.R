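# Pearson screening of candidate features against LAI. Applied on the full
# modeling set for the deployed feature lists and re-applied inside each
# training fold during cross-validation so no held-out sample influences
# selection.

#' Pearson correlation with two-sided p-value
#'
#' Product-moment coefficient with the p-value from the t transform on
#' n - 2 degrees of freedom (delegates to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return named numeric vector `c(r, p)`.
#' @examples
#' pearsonR(c(1, 2, 3), c(1, 3, 2))
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant input")
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen feature groups against LAI
#'
#' Within each group, retains features correlated with LAI at p < alpha,
#' ranked by |r| descending. An optional `restrict` list (group name ->
#' allowed feature names) additionally intersects a group's retained set
#' with an explicit list, as when reproducing a fixed reference
#' configuration.
#'
#' @param feature_table data.frame, samples in rows.
#' @param lai numeric response.
#' @param alpha significance level in (0, 1).
#' @param feature_groups named list: group -> character vector of column
#'   names.
#' @param restrict optional named list: group -> allowed feature names.
#' @return named list per group: data.frame (feature, r, p, retained),
#'   ranked by |r|; attribute `retained` holds the retained names per
#'   group.
#' @export
screenFeatures <- function(feature_table, lai, alpha = 0.05,
                           feature_groups, restrict = NULL) {
  stopifnot(alpha > 0, alpha <= 1, nrow(feature_table) == length(lai))
  out <- list()
  for (g in names(feature_groups)) {
    feats <- intersect(feature_groups[[g]], names(feature_table))
    rows <- lapply(feats, function(f) {
      v <- feature_table[[f]]
      ok <- !is.na(v) & !is.na(lai)
      if (sum(ok) < 3 || sd(v[ok]) == 0)
        return(data.frame(feature = f, r = NA_real_, p = NA_real_,
                          retained = FALSE))
      rp <- pearsonR(v[ok], lai[ok])
      data.frame(feature = f, r = rp[["r"]], p = rp[["p"]],
                 retained = rp[["p"]] < alpha)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(restrict[[g]]))
      tab$retained <- tab$retained & tab$feature %in% restrict[[g]]
    tab <- tab[order(!tab$retained, -abs(tab$r)), , drop = FALSE]
    rownames(tab) <- NULL
    if (!any(tab$retained))
      stop("no feature retained in group '", g, "'")
    out[[g]] <- tab
  }
  attr(out, "retained") <- lapply(out, function(t) t$feature[t$retained])
  out
}

#' Retained feature names from a screening result
#'
#' @param screening result of [screenFeatures()].
#' @return character vector over all groups, in group order.
#' @export
retainedFeatures <- function(screening) {
  unlist(attr(screening, "retained"), use.names = FALSE)
}

#' Write a screening report as CSV
#'
#' Columns: feature, group, r, p, retained.
#' @param screening result of [screenFeatures()].
#' @param path output file.
#' @export
writeScreeningReport <- function(screening, path) {
  tabs <- lapply(names(screening), function(g) {
    t <- screening[[g]]; t$group <- g
    t[, c("feature", "group", "r", "p", "retained")]
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
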