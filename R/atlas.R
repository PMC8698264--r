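# Atlas-based lobe attribution: proportion of a lesion mask in each of
# eight merged lobes, dominant-lobe location, and the supra/infratentorial
# and temporal/extratemporal classes used for subgroup analysis.

#' The eight merged lobes
#'
#' Order doubles as the tie-break order when two lobes hold equal shares
#' of a lesion.
#' @export
MERGED_LOBES <- c("frontal", "temporal", "parietal", "occipital",
                  "limbic", "sublobar", "cerebellum", "brainstem")

SUPRATENTORIAL <- c("frontal", "temporal", "parietal", "occipital",
                    "sublobar", "limbic")
INFRATENTORIAL <- c("cerebellum", "brainstem")
TEMPORAL_GROUP <- c("temporal", "limbic")

#' Raw-region to merged-lobe mapping
#'
#' Validates a mapping from raw atlas region names to the eight merged
#' lobes (cerebellum merges its anterior/posterior lobes, brainstem merges
#' medulla/midbrain/pons, etc.). `"none"` marks raw regions outside the
#' eight lobes.
#'
#' @param x named character vector: names are raw region names, values one
#'   of [MERGED_LOBES] or `"none"`.
#' @return The validated mapping, class `lobe_merge_table`.
#' @export
lobe_merge_table <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("merge table must be a named character vector (raw region -> lobe)")
  bad <- setdiff(unique(x), c(MERGED_LOBES, "none"))
  if (length(bad))
    stop("unknown merged lobes: ", paste(bad, collapse = ", "))
  structure(as.character(stats::setNames(x, names(x))),
            names = names(x), class = "lobe_merge_table")
}

#' Proportion of a lesion in each merged lobe
#'
#' For every merged lobe, the fraction of in-lesion voxels whose atlas
#' label maps to that lobe. Voxels outside the atlas (label 0) or mapped
#' to `"none"` carry no lobe; raw labels missing from the merge table are
#' counted as `"none"` with a warning. Proportions therefore sum to
#' `coverage`, the fraction of the lesion inside any lobe.
#'
#' @param mask a nonempty [lesion_mask()].
#' @param labels a [label_volume()] on the same grid.
#' @param merge a [lobe_merge_table()].
#' @return An object of class `lobe_profile`: list with `proportions`
#'   (named numeric over [MERGED_LOBES]), `coverage`, `dominant_lobe`
#'   (`NA` when coverage is 0), `n_ccm`.
#' @export
lobe_proportions <- function(mask, labels, merge) {
  stopifnot(inherits(mask, "lesion_mask"),
            inherits(labels, "label_volume"),
            inherits(merge, "lobe_merge_table"))
  assert_same_grid(mask, labels)
  if (mask$n_voxels == 0L) stop("empty lesion label")
  codes <- labels$data[mask$data == 1L]
  raw <- rep("none", length(codes))
  inside <- codes > 0L
  raw[inside] <- labels$label_names[as.character(codes[inside])]
  lobe <- unname(merge[raw])
  unmapped <- inside & is.na(lobe)
  if (any(unmapped)) {
    warning("raw atlas labels not in merge table, counted as 'none': ",
            paste(unique(raw[unmapped]), collapse = ", "))
    lobe[unmapped] <- "none"
  }
  lobe[!inside] <- "none"
  counts <- vapply(MERGED_LOBES, function(l) sum(lobe == l), numeric(1))
  prop <- counts / mask$n_voxels
  coverage <- sum(prop)
  dominant <- if (coverage == 0) NA_character_ else {
    top <- which(prop == max(prop))
    if (length(top) > 1L)
      warning("dominant lobe tied (",
              paste(MERGED_LOBES[top], collapse = ", "),
              "); first in fixed lobe order used")
    MERGED_LOBES[top[1]]
  }
  structure(list(proportions = prop, coverage = coverage,
                 dominant_lobe = dominant, n_ccm = mask$n_voxels),
            class = "lobe_profile")
}

#' @export
print.lobe_profile <- function(x, ...) {
  cat("<lobe_profile>", format_lobe_report(x), "\n")
  cat(sprintf("  dominant: %s, coverage %.1f%%\n",
              x$dominant_lobe, 100 * x$coverage))
  invisible(x)
}

#' Human-readable lobe report
#'
#' Renders nonzero lobe shares in decreasing order, e.g.
#' `"sublobar (89%), frontal lobe (6%), limbic lobe (4%)"`.
#'
#' @param profile a `lobe_profile`.
#' @param digits decimals on the percentages.
#' @return A single string.
#' @export
format_lobe_report <- function(profile, digits = 0) {
  stopifnot(inherits(profile, "lobe_profile"))
  p <- profile$proportions[profile$proportions > 0]
  if (!length(p)) return("outside atlas")
  p <- sort(p, decreasing = TRUE)
  disp <- c(frontal = "frontal lobe", temporal = "temporal lobe",
            parietal = "parietal lobe", occipital = "occipital lobe",
            limbic = "limbic lobe", sublobar = "sublobar",
            cerebellum = "cerebellum", brainstem = "brainstem")
  paste(sprintf("%s (%s%%)", disp[names(p)],
                formatC(100 * p, format = "f", digits = digits)),
        collapse = ", ")
}

#' Location class of a lesion
#'
#' Classifies a lesion by its dominant lobe: supratentorial (frontal,
#' temporal, parietal, occipital, sublobar, limbic) vs infratentorial
#' (cerebellum, brainstem); supratentorial lesions are further split into
#' temporal (temporal or limbic lobe) vs extratemporal. The temporal class
#' is `NA` for infratentorial lesions.
#'
#' @param profile a `lobe_profile`.
#' @return list with `tentorial` (`"supratentorial"`, `"infratentorial"`
#'   or `"unclassified"`) and `temporal_class` (`"temporal"`,
#'   `"extratemporal"` or `NA`).
#' @export
assign_location_class <- function(profile) {
  stopifnot(inherits(profile, "lobe_profile"))
  dom <- profile$dominant_lobe
  if (profile$coverage == 0 || is.na(dom))
    return(list(tentorial = "unclassified", temporal_class = NA_character_))
  if (dom %in% INFRATENTORIAL)
    return(list(tentorial = "infratentorial",
                temporal_class = NA_character_))
  list(tentorial = "supratentorial",
       temporal_class = if (dom %in% TEMPORAL_GROUP) "temporal"
                        else "extratemporal")
}
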