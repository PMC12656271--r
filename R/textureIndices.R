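# Two- and three-component texture indices built from selected GLCM
# features, combinatorial candidate enumeration, and correlation ranking
# against LAI.

#' Evaluate a texture index over a feature table
#'
#' Formulas, with T1, T2 (and T3) the ordered component features:
#' NDTI = (T1-T2)/(T1+T2); DTI = T1-T2; RTI = T1/T2;
#' NDTTI = (T1-T2-T3)/(T1+T2+T3); DTTI = T1-T2-T3; RTTI = T1/(T2 T3).
#' A zero denominator yields `NA` for that sample.
#'
#' @param spec a [TextureIndexSpec-class].
#' @param tf_values data.frame (or named numeric vector for one sample)
#'   holding the component texture features.
#' @return numeric vector, one value per sample.
#' @examples
#' sp <- textureIndexSpec("NDTI", c("B_con", "R_dis"))
#' evaluateIndex(sp, data.frame(B_con = 0.6, R_dis = 0.2))
#' @export
evaluateIndex <- function(spec, tf_values) {
  stopifnot(is(spec, "TextureIndexSpec"))
  if (!is.data.frame(tf_values))
    tf_values <- as.data.frame(as.list(tf_values))
  miss <- setdiff(spec@components, names(tf_values))
  if (length(miss))
    stop("missing component features: ", paste(miss, collapse = ", "))
  T1 <- tf_values[[spec@components[1]]]
  T2 <- tf_values[[spec@components[2]]]
  T3 <- if (length(spec@components) == 3) tf_values[[spec@components[3]]]
  div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  switch(spec@indexType,
         NDTI  = div(T1 - T2, T1 + T2),
         DTI   = T1 - T2,
         RTI   = div(T1, T2),
         NDTTI = div(T1 - T2 - T3, T1 + T2 + T3),
         DTTI  = T1 - T2 - T3,
         RTTI  = div(T1, T2 * T3))
}

#' Enumerate candidate texture-index specifications
#'
#' All ordered 2-permutations of the feature pool for the 2-D families and
#' ordered 3-permutations for the 3-D families, after removing
#' combinations equivalent under each formula's exact symmetries: NDTTI,
#' DTTI and RTTI are symmetric in T2 and T3, so only the canonical
#' ordering (T2 < T3 lexicographically) is kept.
#'
#' @param selected_tf_names texture-feature pool (>= 2 names; >= 3 for
#'   any 3-D family).
#' @param index_types index families to enumerate (default all six).
#' @return list of [TextureIndexSpec-class] objects.
#' @examples
#' length(enumerateCandidates(c("a", "b", "c"), "NDTTI"))
#' @export
enumerateCandidates <- function(selected_tf_names,
                                index_types = c(TI_2D, TI_3D)) {
  nm <- unique(selected_tf_names)
  n <- length(nm)
  if (any(index_types %in% TI_2D) && n < 2)
    stop("need at least 2 texture features for 2-D indices")
  if (any(index_types %in% TI_3D) && n < 3)
    stop("need at least 3 texture features for 3-D indices")
  out <- list()
  for (ty in index_types) {
    if (ty %in% TI_2D) {
      for (a in nm) for (b in nm) {
        if (a == b) next
        out[[length(out) + 1L]] <- textureIndexSpec(ty, c(a, b))
      }
    } else {
      for (a in nm) for (b in nm) for (cc in nm) {
        if (a == b || a == cc || b == cc) next
        if (b > cc) next  # T2 <-> T3 symmetry: keep canonical order
        out[[length(out) + 1L]] <- textureIndexSpec(ty, c(a, b, cc))
      }
    }
  }
  out
}

#' Rank candidate texture indices by correlation with LAI
#'
#' Evaluates each candidate over the table, computes Pearson r (and its
#' two-sided p) against LAI on pairwise-complete samples, drops candidates
#' with p >= 0.05 or undefined correlation, ranks the remainder by |r|
#' descending (ties broken lexicographically by index type then
#' components), and returns the top k.
#'
#' @param candidates list of [TextureIndexSpec-class].
#' @param feature_table data.frame of texture features (samples in rows).
#' @param lai numeric response, one value per row.
#' @param k number of indices to retain.
#' @param alpha significance threshold.
#' @return list: `specs` (top-k [TextureIndexSpec-class] list), `table`
#'   (data.frame: index_type, components, r, p, selected for every
#'   non-degenerate candidate, ranked).
#' @export
selectTopIndices <- function(candidates, feature_table, lai, k = 10L,
                             alpha = 0.05) {
  stopifnot(k >= 1, nrow(feature_table) == length(lai))
  rows <- lapply(candidates, function(sp) {
    v <- evaluateIndex(sp, feature_table)
    ok <- !is.na(v) & !is.na(lai)
    if (sum(ok) < 3 || sd(v[ok]) == 0) return(NULL)
    ct <- cor.test(v[ok], lai[ok])
    data.frame(index_type = sp@indexType,
               components = paste(sp@components, collapse = ";"),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0)
    stop("all candidate indices are degenerate")
  keep <- tab$p < alpha
  tab <- tab[keep, , drop = FALSE]
  specs <- candidates[!vapply(rows, is.null, logical(1))][keep]
  if (nrow(tab) == 0) stop("no candidate index passes the significance filter")
  ord <- order(-abs(tab$r), tab$index_type, tab$components)
  tab <- tab[ord, , drop = FALSE]
  specs <- specs[ord]
  k <- min(k, nrow(tab))
  tab$selected <- seq_len(nrow(tab)) <= k
  rownames(tab) <- NULL
  list(specs = specs[seq_len(k)], table = tab)
}

#' Append texture-index columns to a feature table
#'
#' @param feature_table data.frame containing the component features.
#' @param specs list of [TextureIndexSpec-class].
#' @return the table with one added column per spec, named
#'   `<type>.<c1;c2[;c3]>`.
#' @export
addIndexColumns <- function(feature_table, specs) {
  for (sp in specs) {
    nm <- paste0(sp@indexType, ".", paste(sp@components, collapse = ";"))
    feature_table[[nm]] <- evaluateIndex(sp, feature_table)
  }
  feature_table
}

#' Write a ranked texture-index table as CSV
#'
#' Columns: index_type, components (semicolon-joined), r, p, selected.
#' @param ranked result of [selectTopIndices()].
#' @param path output file.
#' @export
writeIndexRanking <- function(ranked, path) {
  write.csv(ranked$table, path, row.names = FALSE)
  invisible(path)
}
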