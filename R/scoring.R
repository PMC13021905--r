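# Three-section fracture/callus scoring. The keel is split into three equal
# sections from cranial to caudal; per section and category (fresh fracture,
# callus) the count is scored 0 / 1 / 2-or-more, and the six scores collapse
# to a binary any-damage outcome for prevalence analysis. Scores are
# observer-entered; this module is the data model and collapse logic.

KEEL_SECTIONS <- c("cranial", "middle", "caudal")

#' Partition the keel into three equal sections
#'
#' Splits the straight cranial->caudal segment at 1/3 and 2/3 of its length;
#' each section is the band of the keel between consecutive split lines
#' perpendicular to the segment.
#'
#' @param annotation a [radiograph_annotation()] (only the tip landmarks are
#'   used).
#' @return list with `fractions` `c(1/3, 2/3)` and `boundaries`, a 2 x 2
#'   matrix of the split points on the segment (pixel coordinates).
#' @export
partition_sections <- function(annotation) {
  cr <- require_landmark(annotation, "cranial_tip")
  ca <- require_landmark(annotation, "caudal_tip")
  if (point_dist_px(cr, ca) == 0)
    stop("annotation error: degenerate cranial-caudal segment")
  f <- c(1, 2) / 3
  boundaries <- rbind(cr + f[1] * (ca - cr), cr + f[2] * (ca - cr))
  rownames(boundaries) <- c("third", "two_thirds")
  list(fractions = f, boundaries = boundaries)
}

#' Section membership of a point
#'
#' Projects a marked lesion center onto the cranial->caudal axis and returns
#' the section it falls in. A projection exactly on a boundary goes to the
#' more caudal section.
#'
#' @param annotation a [radiograph_annotation()].
#' @param point `(x, y)` pixel point.
#' @return `"cranial"`, `"middle"` or `"caudal"`.
#' @export
section_of_point <- function(annotation, point) {
  cr <- require_landmark(annotation, "cranial_tip")
  ca <- require_landmark(annotation, "caudal_tip")
  axis <- ca - cr
  len2 <- sum(axis^2)
  if (len2 == 0)
    stop("annotation error: degenerate cranial-caudal segment")
  s <- sum((as.numeric(point) - cr) * axis) / len2
  if (s < 1 / 3) "cranial" else if (s < 2 / 3) "middle" else "caudal"
}

#' Section scores
#'
#' Caps per-section fresh-fracture and callus counts at 2 ("two or more").
#'
#' @param fresh,callus nonnegative integer counts for
#'   (cranial, middle, caudal).
#' @return an object of class `section_scores`: named integer vectors
#'   `fresh` and `callus` with values in {0, 1, 2}.
#' @export
section_scores <- function(fresh = c(0L, 0L, 0L), callus = c(0L, 0L, 0L)) {
  score_sections(fresh, callus)
}

#' @rdname section_scores
#' @export
score_sections <- function(fresh, callus) {
  for (v in list(fresh, callus))
    if (length(v) != 3 || any(!is.finite(v)) || any(v < 0) ||
        any(v != round(v)))
      stop("domain error: counts must be three nonnegative integers")
  structure(list(fresh = stats::setNames(pmin(as.integer(fresh), 2L),
                                         KEEL_SECTIONS),
                 callus = stats::setNames(pmin(as.integer(callus), 2L),
                                          KEEL_SECTIONS)),
            class = "section_scores")
}

#' Binary fracture outcome
#'
#' Collapses the six section scores to the prevalence outcome: 1 if at least
#' one fresh fracture or callus in any section, 0 otherwise. Non-evaluable
#' images (e.g., strong superimpositions of the leg and the caudal tip)
#' carry no outcome, only an exclusion reason.
#'
#' @param scores a [section_scores()].
#' @param evaluable logical.
#' @param reason optional exclusion reason for non-evaluable images.
#' @return list with `any_damage` (0/1, or `NA` when not evaluable),
#'   `evaluable` and `exclusion_reason`.
#' @export
binarize <- function(scores, evaluable = TRUE, reason = NULL) {
  stopifnot(inherits(scores, "section_scores"))
  if (!isTRUE(evaluable))
    return(list(any_damage = NA_integer_, evaluable = FALSE,
                exclusion_reason = if (is.null(reason))
                  "not evaluable" else reason))
  list(any_damage = as.integer(any(c(scores$fresh, scores$callus) > 0)),
       evaluable = TRUE, exclusion_reason = NULL)
}

#' Score a batch of observer records
#'
#' Long observer input (one row per image x section) to the wide per-image
#' scoring table with the binary outcome.
#'
#' @param df data.frame with columns `image_id`, `section`, `fresh_count`,
#'   `callus_count`, `evaluable` and optionally `reason`.
#' @return data.frame with one row per image: six capped scores,
#'   `any_damage` (`NA` when excluded) and `evaluable`.
#' @export
score_batch <- function(df) {
  need <- c("image_id", "section", "fresh_count", "callus_count", "evaluable")
  if (!all(need %in% names(df)))
    stop("input must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$image_id), function(d) {
    fresh <- callus <- stats::setNames(integer(3), KEEL_SECTIONS)
    fresh[d$section] <- d$fresh_count
    callus[d$section] <- d$callus_count
    sc <- score_sections(fresh, callus)
    b <- binarize(sc, evaluable = all(d$evaluable),
                  reason = if (!is.null(d$reason)) d$reason[1] else NULL)
    data.frame(image_id = d$image_id[1],
               fresh_cranial = sc$fresh[["cranial"]],
               fresh_middle = sc$fresh[["middle"]],
               fresh_caudal = sc$fresh[["caudal"]],
               callus_cranial = sc$callus[["cranial"]],
               callus_middle = sc$callus[["middle"]],
               callus_caudal = sc$callus[["caudal"]],
               any_damage = b$any_damage, evaluable = b$evaluable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
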